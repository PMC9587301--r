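#' Median-of-ratios size factors
#'
#' Per-sample normalization constants for count data, computed exactly as
#' in the classic RNA-seq median-of-ratios scheme: each sample's factor is
#' the median, over genes with a positive geometric mean, of the ratio of
#' that sample's count to the gene's geometric mean across samples.
#'
#' @param counts Tibble with a `gene_id` column followed by one numeric
#'   column per sample.
#' @return A tibble with columns `sample_id`, `size_factor`.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = c("a", "b", "c"),
#'                          s1 = c(100, 50, 10), s2 = c(200, 100, 20))
#' size_factors(counts)
size_factors <- function(counts) {
  m <- df_to_matrix(counts, "gene_id")
  log_gm <- rowMeans(log(m))
  use <- is.finite(log_gm)
  if (!any(use)) {
    abort("no gene has all-positive counts; cannot compute median-of-ratios size factors")
  }
  # median taken on the log scale (the reference convention; identical to
  # the plain median for an odd number of usable genes)
  s <- apply(m[use, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_gm[use]))
  })
  tibble(sample_id = colnames(m), size_factor = unname(s))
}

#' Size-factor-normalized counts
#'
#' Divides each sample's counts by its size factor, giving the normalized
#' expression table used for cis correlation.
#'
#' @inheritParams size_factors
#' @param factors Optional precomputed [size_factors()].
#' @return A tibble of the same shape as `counts` with normalized values.
#' @export
normalize_counts <- function(counts, factors = NULL) {
  if (is.null(factors)) factors <- size_factors(counts)
  m <- df_to_matrix(counts, "gene_id")
  s <- setNames(factors$size_factor, factors$sample_id)
  matrix_to_df(sweep(m, 2, s[colnames(m)], "/"), "gene_id")
}

#' Negative-binomial Wald test for differential expression
#'
#' Tests one two-condition contrast per gene on size-factor-normalized
#' counts. The per-gene dispersion is a method-of-moments estimate from
#' the pooled within-group variance, floored at 1e-8; the log2 fold change
#' uses a pseudocount of 0.5 on the group means; its standard error comes
#' from the NB mean-variance relation by the delta method; the two-sided
#' p-value uses a t reference with `n_a + n_b - 2` degrees of freedom,
#' which keeps the test calibrated at small replicate numbers. Q-values
#' are Benjamini-Hochberg over all tested genes. Genes with zero counts in
#' every sample of both groups are excluded from testing and listed in the
#' `"excluded"` attribute.
#'
#' @param counts Tibble: `gene_id` + one numeric column per sample.
#' @param design Sample design tibble (`sample_id`, `condition`,
#'   `replicate`).
#' @param contrast Length-2 character: `c(reference, alternative)`;
#'   `log2fc` is alternative over reference.
#' @param factors Optional precomputed [size_factors()]; computed from
#'   `counts` when `NULL`.
#' @param fdr DEG threshold on the BH-adjusted p-value (default 0.05).
#' @param pseudocount Added to normalized group means before the log ratio.
#' @return A tibble of class `"methlink_de"` with columns `gene_id`,
#'   `contrast`, `base_mean`, `log2fc`, `se`, `stat`, `p`, `q`, `is_deg`.
#' @export
test_de <- function(counts, design, contrast, factors = NULL,
                    fdr = 0.05, pseudocount = 0.5) {
  check_design(design)
  grp <- contrast_samples(design, contrast)
  if (length(grp$a) < 2 || length(grp$b) < 2) {
    abort("both contrast conditions need >= 2 replicates")
  }
  m <- df_to_matrix(counts, "gene_id")
  missing_samples <- setdiff(c(grp$a, grp$b), colnames(m))
  if (length(missing_samples)) {
    abort(paste0("samples in design but not in counts: ",
                 paste(missing_samples, collapse = ", ")))
  }
  if (is.null(factors)) factors <- size_factors(counts)
  s <- setNames(factors$size_factor, factors$sample_id)
  norm <- sweep(m, 2, s[colnames(m)], "/")

  ya <- norm[, grp$a, drop = FALSE]
  yb <- norm[, grp$b, drop = FALSE]
  all_zero <- rowSums(m[, c(grp$a, grp$b), drop = FALSE]) == 0
  na <- length(grp$a); nb <- length(grp$b)

  ma <- rowMeans(ya); mb <- rowMeans(yb)
  s2a <- apply(ya, 1, var); s2b <- apply(yb, 1, var)
  s2p <- ((na - 1) * s2a + (nb - 1) * s2b) / (na + nb - 2)
  mp <- (na * ma + nb * mb) / (na + nb)
  alpha <- pmax((s2p - mp) / mp^2, 1e-8)
  va <- ma + alpha * ma^2
  vb <- mb + alpha * mb^2
  log2fc <- log2((mb + pseudocount) / (ma + pseudocount))
  se <- sqrt(va / (na * (ma + pseudocount)^2) +
             vb / (nb * (mb + pseudocount)^2)) / log(2)
  stat <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * pt(-abs(stat), df = na + nb - 2)
  p[log2fc == 0] <- 1

  keep <- !all_zero
  res <- tibble(
    gene_id = rownames(m)[keep],
    contrast = paste(contrast[[2]], "vs", contrast[[1]]),
    base_mean = unname(mp[keep]),
    log2fc = unname(log2fc[keep]),
    se = unname(se[keep]),
    stat = unname(stat[keep]),
    p = unname(p[keep])
  ) %>%
    mutate(q = p.adjust(.data$p, method = "BH"),
           is_deg = .data$q < fdr)
  attr(res, "excluded") <- rownames(m)[all_zero]
  attr(res, "contrast") <- contrast
  attr(res, "fdr") <- fdr
  attr(res, "pseudocount") <- pseudocount
  class(res) <- c("methlink_de", class(res))
  res
}
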