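#' Filter methylation probes
#'
#' Removes probes that overlap SNPs, interrogate a non-CpG context, lie on
#' a sex chromosome, or have any missing beta value. Removal reasons are
#' counted individually and as an overlap-free union.
#'
#' @param beta Tibble: `probe_id` + one numeric column per sample (may
#'   contain `NA`).
#' @param manifest Probe manifest tibble with columns `probe_id`, `chrom`,
#'   `pos`, `design_type`, `snp_overlap`, `context_nonCpG`, `sex_chrom`.
#' @return The filtered beta tibble, with a `"removal_report"` attribute
#'   (see [filter_report()]).
#' @export
filter_probes <- function(beta, manifest) {
  missing_probes <- setdiff(beta$probe_id, manifest$probe_id)
  if (length(missing_probes)) {
    abort(paste0("probes in beta absent from manifest: ",
                 paste(head(missing_probes, 5), collapse = ", "),
                 if (length(missing_probes) > 5) ", ..."))
  }
  man <- manifest[match(beta$probe_id, manifest$probe_id), ]
  has_na <- rowSums(is.na(beta[setdiff(names(beta), "probe_id")])) > 0
  drop_snp <- man$snp_overlap
  drop_ctx <- man$context_nonCpG
  drop_sex <- man$sex_chrom
  drop_any <- drop_snp | drop_ctx | drop_sex | has_na
  report <- tibble(
    reason = c("snp_overlap", "context_nonCpG", "sex_chrom", "missing_value",
               "total_removed", "retained"),
    n = c(sum(drop_snp), sum(drop_ctx), sum(drop_sex), sum(has_na),
          sum(drop_any), sum(!drop_any))
  )
  out <- beta[!drop_any, ]
  attr(out, "removal_report") <- report
  out
}

#' Removal report of a filtered beta table
#' @param x Output of [filter_probes()].
#' @return Tibble of per-reason removal counts.
#' @export
filter_report <- function(x) attr(x, "removal_report")

#' Stratified between-sample quantile normalization of beta values
#'
#' Quantile-normalizes beta values across samples separately within the
#' Infinium type-I and type-II probe strata, so that within each stratum
#' every sample has the same sorted values (the per-rank mean over
#' samples). Output stays in \[0, 1\]. A stratum with fewer than 2 probes
#' is passed through unchanged with a warning.
#'
#' @inheritParams filter_probes
#' @return A beta tibble of the same shape.
#' @export
normalize_betas <- function(beta, manifest) {
  man <- manifest[match(beta$probe_id, manifest$probe_id), ]
  if (anyNA(man$probe_id)) abort("all probes must be present in the manifest")
  m <- df_to_matrix(beta, "probe_id")
  if (anyNA(m)) abort("normalize_betas expects filtered (complete) beta values")
  for (stratum in unique(man$design_type)) {
    idx <- which(man$design_type == stratum)
    if (length(idx) < 2) {
      warn(paste0("design-type-", stratum,
                  " stratum has < 2 probes; passed through unchanged"))
      next
    }
    sub <- m[idx, , drop = FALSE]
    ranks <- apply(sub, 2, rank, ties.method = "first")
    target <- rowMeans(apply(sub, 2, sort))
    for (j in seq_len(ncol(sub))) sub[, j] <- target[ranks[, j]]
    m[idx, ] <- sub
  }
  matrix_to_df(m, "probe_id")
}

#' Beta to M-value transform
#'
#' `M = log2((beta + eps) / (1 - beta + eps))`: the logit2 transform onto
#' the variance-stabilized scale used for linear modeling of array
#' methylation.
#'
#' @param beta Numeric vector or matrix of beta values in \[0, 1\].
#' @param eps Non-negative offset guarding against infinities at 0 and 1
#'   (default 0.01).
#' @return M-values, same shape as `beta`.
#' @export
#' @examples
#' beta_to_m(c(0.5, 0.8), eps = 0)
beta_to_m <- function(beta, eps = 0.01) {
  if (eps < 0) abort("eps must be >= 0")
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    abort("beta values must lie in [0, 1]")
  }
  log2((beta + eps) / (1 - beta + eps))
}

#' Moderated t-test for differentially methylated positions
#'
#' Two-group comparison per probe on M-values with empirical-Bayes
#' variance moderation: the prior degrees of freedom `d0` and prior
#' variance `s0^2` are fitted by method of moments on the log residual
#' variances across probes (matching the moments of the log-F
#' distribution implied by the hierarchical model), and each probe's
#' posterior variance is the `d0`/`d`-weighted average of prior and
#' sample variance. The reported effect `delta_beta` is the difference of
#' group mean betas (alternative minus reference); the statistic is
#' computed on the M scale.
#'
#' @param beta Filtered, normalized beta tibble (`probe_id` + samples).
#' @param design Sample design tibble.
#' @param contrast `c(reference, alternative)`.
#' @param fdr DMP threshold on the BH-adjusted p-value.
#' @param eps Offset for [beta_to_m()].
#' @param prior_df `NULL` to fit the prior degrees of freedom from the
#'   data (default); `0` disables moderation (ordinary t-test).
#' @return A tibble of class `"methlink_dmp"`: `probe_id`, `contrast`,
#'   `delta_beta`, `t_mod`, `df`, `p`, `q`, `is_dmp`.
#' @export
test_dmp <- function(beta, design, contrast, fdr = 0.05, eps = 0.01,
                     prior_df = NULL) {
  check_design(design)
  grp <- contrast_samples(design, contrast)
  na <- length(grp$a); nb <- length(grp$b)
  if (na < 2 || nb < 2) abort("both contrast conditions need >= 2 replicates")
  d_res <- na + nb - 2
  if (d_res < 1) abort("zero residual degrees of freedom")
  bmat <- df_to_matrix(beta, "probe_id")
  mmat <- beta_to_m(bmat, eps)
  ma_b <- rowMeans(bmat[, grp$a, drop = FALSE])
  mb_b <- rowMeans(bmat[, grp$b, drop = FALSE])
  ma <- rowMeans(mmat[, grp$a, drop = FALSE])
  mb <- rowMeans(mmat[, grp$b, drop = FALSE])
  s2 <- ((na - 1) * apply(mmat[, grp$a, drop = FALSE], 1, var) +
         (nb - 1) * apply(mmat[, grp$b, drop = FALSE], 1, var)) / d_res

  if (is.null(prior_df)) {
    fit <- fit_variance_prior(s2, d_res)
  } else if (prior_df == 0) {
    fit <- list(d0 = 0, s0sq = NA_real_)
  } else {
    fit <- list(d0 = prior_df, s0sq = exp(mean(log(pmax(s2, 1e-12)))))
  }
  d0 <- fit$d0
  df_pooled <- length(s2) * d_res
  if (is.finite(d0) && d0 > 0) {
    s2_post <- (d0 * fit$s0sq + d_res * s2) / (d0 + d_res)
    df_total <- min(d0 + d_res, df_pooled)
  } else if (is.infinite(d0)) {
    s2_post <- rep(fit$s0sq, length(s2))
    # the prior itself is estimated from finitely many probes
    df_total <- df_pooled
  } else {
    s2_post <- s2
    df_total <- d_res
  }
  t_mod <- (mb - ma) / sqrt(s2_post * (1 / na + 1 / nb))
  t_mod[!is.finite(t_mod)] <- 0
  p <- 2 * pt(-abs(t_mod), df = df_total)
  res <- tibble(
    probe_id = rownames(bmat),
    contrast = paste(contrast[[2]], "vs", contrast[[1]]),
    delta_beta = unname(mb_b - ma_b),
    t_mod = unname(t_mod),
    df = df_total,
    p = unname(p)
  ) %>%
    mutate(q = p.adjust(.data$p, "BH"), is_dmp = .data$q < fdr)
  attr(res, "contrast") <- contrast
  attr(res, "fdr") <- fdr
  attr(res, "prior") <- fit
  class(res) <- c("methlink_dmp", class(res))
  res
}

# Method-of-moments fit of the variance prior (d0, s0^2) from log sample
# variances: E[log s^2] and Var[log s^2] under the scaled-F model give
# closed-form moment equations solved with a trigamma inversion.
fit_variance_prior <- function(s2, d) {
  z <- log(s2[s2 > 0 & is.finite(s2)])
  if (length(z) < 2) return(list(d0 = 0, s0sq = NA_real_))
  ev <- var(z) - trigamma(d / 2)
  if (ev <= 0) {
    # variances are exchangeable; the prior collapses to their mean
    d0 <- Inf
    s0sq <- mean(exp(z))
  } else {
    d0 <- 2 * trigamma_inverse(ev)
    s0sq <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0sq = s0sq)
}

#' Aggregate DMPs into promoter and gene-body regions
#'
#' Defines, per gene, a strand-oriented promoter window (default 1500 bp
#' upstream to 500 bp downstream of the TSS) and the gene body
#' (start to end), collects member probes by position containment, and
#' combines their one-sided evidence by a direction-signed Stouffer
#' statistic: `z_comb = sum(sign(delta_beta_i) * z_i) / sqrt(k)` with
#' `z_i` the normal quantile of the one-sided p-value. Regions with fewer
#' than 2 member probes are excluded (counted in the `"excluded"`
#' attribute). Q-values are BH within each region kind.
#'
#' @param dmps A [test_dmp()] result (all probes, not only significant).
#' @param annotation Gene annotation tibble (`gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `tss`).
#' @param manifest Probe manifest (for probe positions).
#' @param fdr DMR threshold on the BH-adjusted p-value.
#' @param promoter_up,promoter_down Promoter window extent upstream /
#'   downstream of the TSS, in bp.
#' @return A tibble of class `"methlink_dmr"`: `region_id`, `region_kind`,
#'   `gene_id`, `chrom`, `start`, `end`, `n_probes`, `mean_delta_beta`,
#'   `z_comb`, `p`, `q`, `direction`, `is_dmr`.
#' @export
aggregate_dmrs <- function(dmps, annotation, manifest, fdr = 0.05,
                           promoter_up = 1500, promoter_down = 500) {
  pos <- manifest %>% select("probe_id", "chrom", "pos") %>%
    mutate(chrom = norm_chrom(.data$chrom))
  probes <- dmps %>% inner_join(pos, by = "probe_id")
  regions <- bind_rows(
    annotation %>% mutate(
      region_kind = "promoter",
      r_start = ifelse(.data$strand == "+", .data$tss - promoter_up,
                       .data$tss - promoter_down),
      r_end = ifelse(.data$strand == "+", .data$tss + promoter_down,
                     .data$tss + promoter_up)
    ),
    annotation %>% mutate(region_kind = "gene_body",
                          r_start = .data$start, r_end = .data$end)
  ) %>%
    mutate(chrom = norm_chrom(.data$chrom),
           region_id = paste0(.data$gene_id, ":", .data$region_kind))

  memb <- regions %>%
    select("region_id", "region_kind", "gene_id", "chrom", "r_start", "r_end") %>%
    inner_join(probes, by = "chrom", relationship = "many-to-many") %>%
    filter(.data$pos >= .data$r_start, .data$pos <= .data$r_end)

  stats_tbl <- memb %>%
    mutate(
      p_one = pmax(pmin(.data$p / 2, 1 - 1e-15), 1e-15),
      z_i = qnorm(1 - .data$p_one)
    ) %>%
    group_by(.data$region_id, .data$region_kind, .data$gene_id,
             .data$chrom, .data$r_start, .data$r_end) %>%
    summarise(
      n_probes = dplyr::n(),
      mean_delta_beta = mean(.data$delta_beta),
      z_comb = sum(sign(.data$delta_beta) * .data$z_i) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  excluded <- stats_tbl %>% filter(.data$n_probes < 2)
  res <- stats_tbl %>%
    filter(.data$n_probes >= 2) %>%
    mutate(p = 2 * pnorm(-abs(.data$z_comb))) %>%
    group_by(.data$region_kind) %>%
    mutate(q = p.adjust(.data$p, "BH")) %>%
    ungroup() %>%
    mutate(
      direction = ifelse(.data$mean_delta_beta < 0, "hypo", "hyper"),
      is_dmr = .data$q < fdr
    ) %>%
    rename(start = "r_start", end = "r_end") %>%
    arrange(.data$region_kind, .data$gene_id)
  attr(res, "excluded") <- excluded$region_id
  attr(res, "fdr") <- fdr
  class(res) <- c("methlink_dmr", class(res))
  res
}
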