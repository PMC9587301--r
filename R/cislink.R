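#' Link methylation positions to gene TSSs within a cis window
#'
#' Emits one candidate pair per (gene, probe) combination on the same
#' chromosome with the probe within `window` bp of the gene's
#' transcription start site (closed interval, symmetric). A probe may pair
#' with several genes and vice versa. The reported `distance` is
#' strand-oriented (probe position minus TSS, sign flipped for minus-strand
#' genes, so positive means downstream).
#'
#' @param dmps Tibble with a `probe_id` column; typically the significant
#'   rows of a [test_dmp()] result.
#' @param annotation Gene annotation tibble; pass only the genes of
#'   interest (e.g. DEGs).
#' @param manifest Probe manifest (for probe chromosome/position).
#' @param window Half-width of the cis window in bp (default 5000).
#' @return Tibble of pairs: `gene_id`, `probe_id`, `distance`.
#' @export
link_dmps_to_genes <- function(dmps, annotation, manifest, window = 5000) {
  pos <- manifest %>%
    filter(.data$probe_id %in% dmps$probe_id) %>%
    select("probe_id", "chrom", "pos") %>%
    mutate(chrom = norm_chrom(.data$chrom))
  genes <- annotation %>%
    select("gene_id", "chrom", "strand", "tss") %>%
    mutate(chrom = norm_chrom(.data$chrom))
  if (nrow(pos) && nrow(genes) &&
      !length(intersect(pos$chrom, genes$chrom))) {
    abort(paste0(
      "no shared chromosome between probes and genes after 'chr' ",
      "normalization; probes: {", paste(unique(pos$chrom), collapse = ", "),
      "}, genes: {", paste(unique(genes$chrom), collapse = ", "), "}"
    ))
  }
  genes %>%
    inner_join(pos, by = "chrom", relationship = "many-to-many") %>%
    filter(abs(.data$pos - .data$tss) <= window) %>%
    mutate(distance = ifelse(.data$strand == "+",
                             .data$pos - .data$tss,
                             .data$tss - .data$pos)) %>%
    select("gene_id", "probe_id", "distance") %>%
    arrange(.data$gene_id, .data$probe_id)
}

#' Spearman rank correlation with asymptotic p-value
#'
#' Pearson correlation of average-rank vectors (ties get average ranks),
#' with a two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. The asymptotic p is reported
#' for reference; pair significance in the pipeline comes from the
#' permutation FDR.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return A list with elements `rho` and `p`; both `NA` (with a warning)
#'   when either vector has zero rank variance.
#' @export
#' @examples
#' spearman_rho(c(1, 2, 3), c(10, 20, 30))$rho
spearman_rho <- function(x, y) {
  n <- length(x)
  if (n != length(y)) abort("x and y must have equal length")
  if (n < 3) abort("spearman_rho needs n >= 3")
  rx <- rank(x); ry <- rank(y)
  sx <- sum((rx - mean(rx))^2); sy <- sum((ry - mean(ry))^2)
  if (sx == 0 || sy == 0) {
    warn("zero rank variance; Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_))
  }
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) / sqrt(sx * sy)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p)
}

#' Correlate expression and methylation for candidate cis pairs
#'
#' Computes the Spearman correlation between a gene's normalized
#' expression and a probe's beta value across all samples, for each
#' linked pair. Pairs whose expression or methylation has zero rank
#' variance are dropped with a warning (counted in the `"dropped"`
#' attribute).
#'
#' @param pairs Output of [link_dmps_to_genes()].
#' @param expr Normalized expression tibble (`gene_id` + samples),
#'   e.g. counts divided by size factors.
#' @param beta Beta tibble (`probe_id` + samples). Must cover the same
#'   sample set as `expr`.
#' @return `pairs` with columns `rho` and `p_asym` added.
#' @export
correlate_pairs <- function(pairs, expr, beta) {
  es <- setdiff(names(expr), "gene_id")
  bs <- setdiff(names(beta), "probe_id")
  if (!setequal(es, bs)) {
    abort("expression and methylation sample sets differ")
  }
  em <- df_to_matrix(expr, "gene_id")
  bm <- df_to_matrix(beta, "probe_id")[, colnames(em), drop = FALSE]
  res <- pairs %>%
    mutate(stats = map2(.data$gene_id, .data$probe_id, function(g, p) {
      # degenerate pairs are reported once, below
      suppressWarnings(spearman_rho(em[g, ], bm[p, ]))
    }),
    rho = map_dbl(.data$stats, "rho"),
    p_asym = map_dbl(.data$stats, "p")) %>%
    select(-"stats")
  dropped <- res %>% filter(is.na(.data$rho))
  out <- res %>% filter(!is.na(.data$rho))
  if (nrow(dropped)) {
    warn(paste0(nrow(dropped),
                " pair(s) dropped: zero rank variance in one member"))
  }
  attr(out, "dropped") <- dropped %>% select("gene_id", "probe_id")
  out
}

#' Permutation-based FDR for cis-pair correlations
#'
#' Builds the null by permuting the sample correspondence between the two
#' modalities: each permutation applies one shared reordering to all
#' methylation columns (preserving cross-probe and cross-gene structure)
#' and recomputes every pair's |rho|. The per-pair empirical p-value is
#' `(1 + #{null |rho| >= |rho_obs|}) / (n_perm + 1)` over that pair's own
#' permutations; the q-value is the plug-in estimator
#' `q(t) = min(1, mean-per-permutation #{null |rho| >= t} /
#' max(#{observed |rho| >= t}, 1))` at `t = |rho_obs|`, made monotone
#' non-increasing in |rho|. When `n_samples!` does not exceed
#' `exhaustive_cap`, all permutations are enumerated instead of sampled
#' and the +1 correction is dropped.
#'
#' @inheritParams correlate_pairs
#' @param pairs Output of [correlate_pairs()] (needs `rho`).
#' @param n_perm Number of sampled permutations (ignored in exhaustive
#'   mode).
#' @param seed Integer seed for the sampled permutations.
#' @param exhaustive_cap Enumerate all permutations when `n_samples!` is
#'   at most this value (default 720, i.e. up to 6 samples).
#' @param scheme `"shared"` (default; one permutation for all probes) or
#'   `"independent"` (each pair permuted independently — overstates the
#'   effective null sample; for comparison only).
#' @return `pairs` with `p_perm` and `q_perm` added; attribute
#'   `"n_permutations"` records the null size, `"exhaustive"` the mode.
#' @export
permutation_fdr <- function(pairs, expr, beta, n_perm = 1000, seed = 1,
                            exhaustive_cap = 720,
                            scheme = c("shared", "independent")) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) abort("n_perm must be >= 1")
  if (!nrow(pairs)) abort("no pairs with defined rho")
  if (anyNA(pairs$rho)) abort("pairs must have defined rho (drop NAs first)")
  em <- df_to_matrix(expr, "gene_id")
  bm <- df_to_matrix(beta, "probe_id")[, colnames(em), drop = FALSE]
  n <- ncol(em)

  row_ranks <- function(m) t(apply(m, 1, rank))
  normalize_rows <- function(r) {
    c_ <- r - rowMeans(r)
    ss <- sqrt(rowSums(c_^2))
    c_ / ss
  }
  xn <- normalize_rows(row_ranks(em[pairs$gene_id, , drop = FALSE]))
  yn <- normalize_rows(row_ranks(bm[pairs$probe_id, , drop = FALSE]))
  obs <- abs(rowSums(xn * yn))

  exhaustive <- factorial(n) <= exhaustive_cap
  if (exhaustive) {
    perms <- all_permutations(n)
  } else {
    perms <- with_substream(seed, 21L, {
      t(replicate(n_perm, sample.int(n)))
    })
  }
  nb <- nrow(perms)
  m_pairs <- nrow(pairs)
  null_abs <- matrix(0, m_pairs, nb)
  for (b in seq_len(nb)) {
    if (scheme == "shared") {
      null_abs[, b] <- abs(rowSums(xn * yn[, perms[b, ], drop = FALSE]))
    } else {
      yb <- with_substream(seed, 22L + b, {
        t(apply(yn, 1, function(r) r[sample.int(n)]))
      })
      null_abs[, b] <- abs(rowSums(xn * yb))
    }
  }

  exceed_own <- rowSums(null_abs >= obs - 1e-12)
  p_perm <- if (exhaustive) exceed_own / nb else (1 + exceed_own) / (nb + 1)

  pooled <- sort(as.vector(null_abs))
  total_null <- length(pooled)
  obs_sorted <- sort(obs)
  q_raw <- vapply(obs, function(t) {
    v <- (total_null - findInterval(t - 1e-12, pooled)) / nb
    r <- m_pairs - findInterval(t - 1e-12, obs_sorted)
    min(1, v / max(r, 1))
  }, numeric(1))
  ord <- order(obs)
  q_mono <- numeric(m_pairs)
  q_mono[ord] <- cummin(q_raw[ord])

  out <- pairs %>% mutate(p_perm = p_perm, q_perm = q_mono)
  attr(out, "n_permutations") <- nb
  attr(out, "exhaustive") <- exhaustive
  attr(out, "scheme") <- scheme
  out
}

#' Classify cis pairs as canonical or non-canonical
#'
#' A pair is `canonical` when methylation and expression are negatively
#' correlated (`rho < 0`) at `q_perm` below the threshold (methylation
#' consistent with repression), `non_canonical` when positively correlated
#' and significant, and `ns` otherwise.
#'
#' @param pairs Output of [permutation_fdr()].
#' @param fdr Threshold on `q_perm`.
#' @return `pairs` with a `pair_class` column, classed
#'   `"methlink_pairs"`. Use [summarize_gene_labels()] for the gene-level
#'   view.
#' @export
classify_pairs <- function(pairs, fdr = 0.05) {
  out <- pairs %>%
    mutate(pair_class = dplyr::case_when(
      .data$q_perm < fdr & .data$rho < 0 ~ "canonical",
      .data$q_perm < fdr & .data$rho > 0 ~ "non_canonical",
      TRUE ~ "ns"
    ))
  attr(out, "fdr") <- fdr
  class(out) <- c("methlink_pairs", class(out))
  out
}

#' Gene-level labels from classified cis pairs
#'
#' A gene carries a label when at least one of its pairs has that class
#' (a gene may carry both). The representative correlation per gene is
#' taken from its significant pair with the largest |rho| (ties broken by
#' smaller `q_perm`, then lexicographic probe id) — used for
#' cross-dataset direction comparison.
#'
#' @param pairs A [classify_pairs()] result.
#' @return One row per gene in the linked universe: `gene_id`, `n_pairs`,
#'   `n_sig_pairs`, `canonical`, `non_canonical`, `rep_probe_id`,
#'   `rep_rho`, `rep_q`.
#' @export
summarize_gene_labels <- function(pairs) {
  rep_pick <- pairs %>%
    filter(.data$pair_class != "ns") %>%
    group_by(.data$gene_id) %>%
    arrange(dplyr::desc(abs(.data$rho)), .data$q_perm, .data$probe_id,
            .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select("gene_id", rep_probe_id = "probe_id", rep_rho = "rho",
           rep_q = "q_perm")
  pairs %>%
    group_by(.data$gene_id) %>%
    summarise(
      n_pairs = dplyr::n(),
      n_sig_pairs = sum(.data$pair_class != "ns"),
      canonical = any(.data$pair_class == "canonical"),
      non_canonical = any(.data$pair_class == "non_canonical")
    ) %>%
    left_join(rep_pick, by = "gene_id")
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate, in (0, 1].
#' @param m Number of tests, >= 1.
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 11475)
bonferroni_threshold <- function(alpha, m) {
  if (alpha <= 0 || alpha > 1) abort("alpha must be in (0, 1]")
  if (m < 1) abort("m must be >= 1")
  alpha / m
}
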