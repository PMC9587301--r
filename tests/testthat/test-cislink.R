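test_that("window linkage respects the closed boundary and strand", {
  ann <- tibble::tibble(
    gene_id = c("plus", "minus"), chrom = c("chr1", "chr1"),
    start = c(100000, 50000), end = c(110000, 60000),
    strand = c("+", "-"), tss = c(100000, 60000)
  )
  man <- plain_manifest(paste0("p", 1:4),
                        pos = c(95000, 94999, 58000, 105000))
  dmps <- tibble::tibble(probe_id = man$probe_id)
  pairs <- link_dmps_to_genes(dmps, ann, man, window = 5000)
  # p1 at exactly tss - 5000 is linked; p2 one bp further is not
  expect_true(any(pairs$gene_id == "plus" & pairs$probe_id == "p1"))
  expect_false(any(pairs$probe_id == "p2"))
  expect_equal(pairs$distance[pairs$probe_id == "p1" &
                                pairs$gene_id == "plus"], -5000)
  # minus-strand gene: tss = end; probe 2 kb left of the tss is downstream
  expect_equal(pairs$distance[pairs$probe_id == "p3"], 2000)
  # a probe within both windows pairs with both genes
  ann2 <- ann
  ann2$tss <- c(100000, 103000)
  ann2$chrom <- "chr1"
  p <- link_dmps_to_genes(tibble::tibble(probe_id = "p4"), ann2, man, 5000)
  expect_equal(sort(p$gene_id), c("minus", "plus"))
})

test_that("chromosome namespaces are normalized and mismatches rejected", {
  ann <- tibble::tibble(gene_id = "g", chrom = "1", start = 1e5, end = 2e5,
                        strand = "+", tss = 1e5)
  man <- plain_manifest("p1", chrom = "chr1", pos = 99000)
  pairs <- link_dmps_to_genes(tibble::tibble(probe_id = "p1"), ann, man, 5000)
  expect_equal(nrow(pairs), 1)
  man2 <- plain_manifest("p1", chrom = "chr9", pos = 99000)
  expect_error(
    link_dmps_to_genes(tibble::tibble(probe_id = "p1"), ann, man2, 5000),
    "no shared chromosome")
})

test_that("spearman_rho matches the rank-then-Pearson definition", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_rho(1:3, c(3, 2, 1))$rho, -1)
  # ties: average ranks (1, 2.5, 2.5, 4) vs (1, 3, 2, 4)
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  expect_equal(spearman_rho(x, y)$rho, cor(rank(x), rank(y)))
  # property: invariant under strictly monotone transforms
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8)
    r0 <- spearman_rho(a, b)$rho
    expect_equal(spearman_rho(exp(a), b)$rho, r0)
    expect_equal(spearman_rho(a, 3 * b - 10)$rho, r0)
  }
  expect_error(spearman_rho(1:2, 1:2), "n >= 3")
  expect_warning(out <- spearman_rho(c(1, 1, 1), 1:3), "zero rank variance")
  expect_true(is.na(out$rho))
})

test_that("pair correlation drops degenerate pairs and ignores sample order", {
  sim <- simulate_experiment(synth_config(n_genes = 30, background_probes = 10,
                                          missing_rate = 0), seed = 3)
  expr <- normalized_expr(sim)
  beta <- sim$beta
  beta[2, -1] <- as.list(rep(0.5, ncol(beta) - 1))  # constant probe
  pairs <- tibble::tibble(gene_id = sim$annotation$gene_id[1:3],
                          probe_id = beta$probe_id[1:3], distance = 0L)
  expect_warning(out <- correlate_pairs(pairs, expr, beta), "dropped")
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "dropped")$probe_id, beta$probe_id[2])
  # jointly permuting samples in both matrices leaves rho unchanged
  perm <- sample(setdiff(names(expr), "gene_id"))
  expr_p <- expr[c("gene_id", perm)]
  beta_p <- beta[c("probe_id", perm)]
  expect_warning(out_p <- correlate_pairs(pairs, expr_p, beta_p))
  expect_equal(out_p$rho, out$rho)
  expect_error(correlate_pairs(pairs, expr[-2], beta), "sample sets differ")
})

test_that("exhaustive permutation FDR matches the brute-force oracle", {
  # 3 pairs, 4 samples: all 24 permutations enumerated on both routes
  set.seed(7)
  em <- matrix(rnorm(12), 3, 4,
               dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  bm <- matrix(runif(12, 0.1, 0.9), 3, 4,
               dimnames = list(c("p1", "p2", "p3"), paste0("s", 1:4)))
  bm[1, ] <- plogis(-scale(em[1, ])[, 1])  # strongly anticorrelated pair
  expr <- tibble::as_tibble(em, rownames = "gene_id")
  beta <- tibble::as_tibble(bm, rownames = "probe_id")
  pairs <- tibble::tibble(gene_id = rownames(em), probe_id = rownames(bm),
                          distance = 0L)
  pairs <- correlate_pairs(pairs, expr, beta)
  res <- permutation_fdr(pairs, expr, beta, n_perm = 10, seed = 1)
  expect_true(attr(res, "exhaustive"))
  expect_equal(attr(res, "n_permutations"), 24)
  oracle <- perm_fdr_oracle(em, bm)
  expect_equal(res$p_perm, oracle$p, tolerance = 1e-12)
  expect_equal(res$q_perm, oracle$q, tolerance = 1e-12)
})

test_that("a perfectly monotone pair has exhaustive p = 2/24 at n = 4", {
  expr <- tibble::tibble(gene_id = "g1", s1 = 1, s2 = 2, s3 = 3, s4 = 4)
  beta <- tibble::tibble(probe_id = "p1", s1 = 0.1, s2 = 0.2, s3 = 0.3,
                         s4 = 0.4)
  pairs <- correlate_pairs(tibble::tibble(gene_id = "g1", probe_id = "p1",
                                          distance = 0L), expr, beta)
  expect_equal(pairs$rho, 1)
  res <- permutation_fdr(pairs, expr, beta, n_perm = 5, seed = 1)
  # only the identity and the full reversal reach |rho| = 1
  expect_equal(res$p_perm, 2 / 24)
})

test_that("sampled and exhaustive permutation modes agree at depth", {
  set.seed(9)
  em <- matrix(rnorm(20), 5, 4,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  bm <- matrix(runif(20, 0.1, 0.9), 5, 4,
               dimnames = list(paste0("p", 1:5), paste0("s", 1:4)))
  bm[1, ] <- plogis(-em[1, ])
  expr <- tibble::as_tibble(em, rownames = "gene_id")
  beta <- tibble::as_tibble(bm, rownames = "probe_id")
  pairs <- correlate_pairs(tibble::tibble(gene_id = rownames(em),
                                          probe_id = rownames(bm),
                                          distance = 0L), expr, beta)
  ex <- permutation_fdr(pairs, expr, beta, seed = 1)
  sm <- permutation_fdr(pairs, expr, beta, n_perm = 10000, seed = 1,
                        exhaustive_cap = 1)
  expect_false(attr(sm, "exhaustive"))
  expect_lt(max(abs(sm$q_perm - ex$q_perm)), 0.02)
  expect_true(all(sm$p_perm > 0))
})

test_that("q_perm is a valid, |rho|-monotone FDR estimate", {
  sim <- simulate_experiment(synth_config(n_genes = 50, background_probes = 20,
                                          missing_rate = 0), seed = 19)
  expr <- normalized_expr(sim)
  pairs <- link_dmps_to_genes(sim$beta, sim$annotation, sim$manifest, 5000)
  pairs <- suppressWarnings(correlate_pairs(pairs, expr, sim$beta))
  res <- permutation_fdr(pairs, expr, sim$beta, n_perm = 200, seed = 5)
  expect_true(all(res$q_perm >= 0 & res$q_perm <= 1))
  ord <- order(abs(res$rho))
  expect_true(all(diff(res$q_perm[ord]) <= 1e-12))
  expect_error(permutation_fdr(res, expr, sim$beta, n_perm = 0), "n_perm")
})

test_that("pair and gene labels follow the correlation sign rule", {
  pairs <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g3"),
    probe_id = c("p1", "p2", "p3", "p4"),
    distance = 0L,
    rho = c(-0.9, 0.8, 0.5, -0.3),
    p_perm = c(0.001, 0.001, 0.2, 0.5),
    q_perm = c(0.01, 0.01, 0.3, 0.6)
  )
  cls <- classify_pairs(pairs, fdr = 0.05)
  expect_equal(cls$pair_class, c("canonical", "non_canonical", "ns", "ns"))
  labels <- summarize_gene_labels(cls)
  g1 <- labels[labels$gene_id == "g1", ]
  expect_true(g1$canonical && g1$non_canonical)   # both labels allowed
  expect_equal(g1$rep_probe_id, "p1")             # max |rho| wins
  g2 <- labels[labels$gene_id == "g2", ]
  expect_false(g2$canonical || g2$non_canonical)
  expect_true(is.na(g2$rep_rho))
})

test_that("bonferroni_threshold divides alpha by the test count", {
  expect_equal(signif(bonferroni_threshold(0.05, 11475), 3), 4.36e-6)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
  expect_error(bonferroni_threshold(1.5, 10), "alpha")
})
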