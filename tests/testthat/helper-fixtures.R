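# Shared fixtures and independent oracle helpers.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# Small two-group beta fixture: n probes x (2 x n_rep) samples.
make_beta_fixture <- function(n_probes, n_rep = 4, shift_idx = integer(),
                              shift = 0, sd = 0.3, seed = 1) {
  set.seed(seed)
  base <- stats::qlogis(pmin(pmax(stats::rbeta(n_probes, 2, 2), 0.02), 0.98))
  ns <- 2L * n_rep
  m <- matrix(base, n_probes, ns) + matrix(rnorm(n_probes * ns, 0, sd),
                                           n_probes, ns)
  m[shift_idx, (n_rep + 1):ns] <- m[shift_idx, (n_rep + 1):ns] + shift
  beta <- as_tibble(stats::plogis(m),
                    .name_repair = ~ paste0(rep(c("A", "B"), each = n_rep),
                                            "_", rep(seq_len(n_rep), 2)))
  bind_cols(tibble(probe_id = sprintf("p%03d", seq_len(n_probes))), beta)
}

two_group_design <- function(n_rep = 4) {
  tibble(
    sample_id = paste0(rep(c("A", "B"), each = n_rep), "_",
                       rep(seq_len(n_rep), 2)),
    condition = rep(c("A", "B"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2)
  )
}

plain_manifest <- function(probe_ids, chrom = "chr1", pos = NULL) {
  tibble(
    probe_id = probe_ids,
    chrom = chrom,
    pos = pos %||% seq(1000, by = 1000, length.out = length(probe_ids)),
    design_type = "II",
    snp_overlap = FALSE,
    context_nonCpG = FALSE,
    sex_chrom = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Size-factor-normalized expression tibble from a simulation.
normalized_expr <- function(sim) normalize_counts(sim$counts)

# Independent permutation enumerator (Heap's algorithm), used by the
# brute-force permutation-FDR oracle so it shares no code with the package.
heap_perms <- function(n) {
  out <- matrix(0L, factorial(n), n)
  row <- 0L
  a <- seq_len(n)
  rec <- function(k) {
    if (k == 1L) {
      row <<- row + 1L
      out[row, ] <<- a
      return(invisible())
    }
    for (i in seq_len(k)) {
      rec(k - 1L)
      j <- if (k %% 2L == 0L) i else 1L
      tmp <- a[j]; a[j] <<- a[k]; a[k] <<- tmp
    }
  }
  rec(n)
  out
}

# Brute-force permutation-FDR oracle: enumerates every permutation,
# recomputes Spearman correlations with stats::cor, and applies the
# plug-in estimator directly.
perm_fdr_oracle <- function(expr_rows, meth_rows) {
  n <- ncol(expr_rows)
  perms <- heap_perms(n)
  m <- nrow(expr_rows)
  obs <- vapply(seq_len(m), function(i) {
    abs(cor(expr_rows[i, ], meth_rows[i, ], method = "spearman"))
  }, numeric(1))
  null_abs <- matrix(0, m, nrow(perms))
  for (b in seq_len(nrow(perms))) {
    for (i in seq_len(m)) {
      null_abs[i, b] <- abs(cor(expr_rows[i, ], meth_rows[i, perms[b, ]],
                                method = "spearman"))
    }
  }
  p <- vapply(seq_len(m), function(i) {
    mean(null_abs[i, ] >= obs[i] - 1e-12)
  }, numeric(1))
  q_raw <- vapply(obs, function(t) {
    v <- sum(null_abs >= t - 1e-12) / nrow(perms)
    r <- sum(obs >= t - 1e-12)
    min(1, v / max(r, 1))
  }, numeric(1))
  ord <- order(obs)
  q <- numeric(m)
  q[ord] <- cummin(q_raw[ord])
  list(p = p, q = q, obs = obs)
}
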