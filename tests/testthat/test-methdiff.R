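test_that("probe filtering removes the union of flagged and missing probes", {
  beta <- make_beta_fixture(10)
  man <- plain_manifest(beta$probe_id)
  man$snp_overlap[1:2] <- TRUE
  man$sex_chrom[3] <- TRUE
  man$context_nonCpG[4] <- TRUE
  beta$A_2[5] <- NA
  filt <- filter_probes(beta, man)
  expect_equal(nrow(filt), 5)
  rep <- filter_report(filt)
  expect_equal(rep$n[rep$reason == "total_removed"], 5)
  # overlapping flags count once in the union
  man2 <- plain_manifest(beta$probe_id)
  man2$snp_overlap[1] <- TRUE
  man2$sex_chrom[1] <- TRUE
  beta2 <- make_beta_fixture(10)
  filt2 <- filter_probes(beta2, man2)
  expect_equal(nrow(filt2), 9)
  expect_equal(filter_report(filt2)$n[filter_report(filt2)$reason == "total_removed"], 1)
  # identity when nothing is flagged
  filt3 <- filter_probes(beta2, plain_manifest(beta2$probe_id))
  expect_equal(nrow(filt3), 10)
  expect_true(all(filter_report(filt3)$n[1:5] == 0))
  # idempotence
  refilt <- filter_probes(filt, man)
  expect_identical(refilt$probe_id, filt$probe_id)
  expect_equal(as.matrix(refilt[-1]), as.matrix(filt[-1]))
  expect_error(filter_probes(beta, man[-1, ]), "absent from manifest")
})

test_that("quantile normalization equalizes sorted values within strata", {
  # two samples, one stratum: normalized sorted values are the mean of
  # the two sorted inputs (hand-checkable on 4 probes)
  beta <- tibble::tibble(probe_id = paste0("p", 1:4),
                         s1 = c(0.1, 0.4, 0.2, 0.8),
                         s2 = c(0.3, 0.9, 0.5, 0.7))
  man <- plain_manifest(beta$probe_id)
  out <- normalize_betas(beta, man)
  target <- (sort(beta$s1) + sort(beta$s2)) / 2  # 0.2 0.35 0.55 0.85
  expect_equal(sort(out$s1), target)
  expect_equal(sort(out$s2), target)
  expect_equal(target, c(0.2, 0.35, 0.55, 0.85))
  # rank order within each sample is preserved
  expect_equal(order(out$s1), order(beta$s1))
  # identical samples are a fixed point
  same <- tibble::tibble(probe_id = paste0("p", 1:4),
                         s1 = c(0.1, 0.4, 0.2, 0.8),
                         s2 = c(0.1, 0.4, 0.2, 0.8))
  expect_equal(normalize_betas(same, man), same)
})

test_that("normalization is stratified by design type and warns on tiny strata", {
  beta <- make_beta_fixture(21, seed = 5)
  man <- plain_manifest(beta$probe_id)
  man$design_type <- c(rep("I", 10), rep("II", 11))
  out <- normalize_betas(beta, man)
  sam <- setdiff(names(out), "probe_id")
  for (st in c("I", "II")) {
    idx <- which(man$design_type == st)
    sorted <- sapply(sam, function(s) sort(out[[s]][idx]))
    expect_true(all(apply(sorted, 1, function(r) diff(range(r)) < 1e-12)))
  }
  expect_true(all(as.matrix(out[-1]) >= 0 & as.matrix(out[-1]) <= 1))
  man$design_type <- c("I", rep("II", 20))
  expect_warning(normalize_betas(beta, man), "stratum")
})

test_that("beta_to_m evaluates the logit2 transform", {
  expect_equal(beta_to_m(0.5, eps = 0), 0)
  expect_equal(beta_to_m(0.8, eps = 0), 2)
  expect_equal(beta_to_m(0, eps = 0.01), log2(0.01 / 1.01))
  b <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(beta_to_m(b, eps = 0.01)) > 0))
  expect_equal(beta_to_m(b, eps = 0), -beta_to_m(1 - b, eps = 0))
  expect_error(beta_to_m(1.2), "\\[0, 1\\]")
  expect_error(beta_to_m(0.5, eps = -1), ">= 0")
})

test_that("disabling moderation reproduces the ordinary t-test", {
  beta <- make_beta_fixture(20, shift_idx = 1:5, shift = 1, seed = 8)
  res <- test_dmp(beta, two_group_design(), c("A", "B"), eps = 0,
                  prior_df = 0)
  m <- log2(as.matrix(beta[-1]) / (1 - as.matrix(beta[-1])))
  for (i in seq_len(nrow(beta))) {
    tt <- t.test(m[i, 5:8], m[i, 1:4], var.equal = TRUE)
    expect_equal(res$t_mod[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated statistics agree with the reference empirical-Bayes fit", {
  beta <- make_beta_fixture(60, shift_idx = 1:10, shift = 1.2, seed = 9)
  res <- test_dmp(beta, two_group_design(), c("A", "B"), eps = 0)
  m <- log2(as.matrix(beta[-1]) / (1 - as.matrix(beta[-1])))
  fit <- limma::eBayes(limma::lmFit(m, cbind(1, rep(c(0, 1), each = 4))))
  expect_equal(attr(res, "prior")$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "prior")$s0sq, fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_mod, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("identical groups give zero moderated t and p = 1", {
  beta <- make_beta_fixture(10, seed = 3)
  sam <- setdiff(names(beta), "probe_id")
  beta[sam[5:8]] <- beta[sam[1:4]]
  res <- test_dmp(beta, two_group_design(), c("A", "B"))
  expect_equal(res$t_mod, rep(0, 10))
  expect_equal(res$p, rep(1, 10))
})

test_that("DMP q-values dominate p and contrast swap negates effects", {
  beta <- make_beta_fixture(40, shift_idx = 1:10, shift = 1, seed = 10)
  fwd <- test_dmp(beta, two_group_design(), c("A", "B"))
  rev <- test_dmp(beta, two_group_design(), c("B", "A"))
  expect_true(all(fwd$q >= fwd$p))
  expect_equal(rev$delta_beta, -fwd$delta_beta)
  expect_equal(rev$t_mod, -fwd$t_mod)
  expect_equal(rev$p, fwd$p)
  nz <- fwd$delta_beta != 0 & fwd$t_mod != 0
  expect_true(all(sign(fwd$delta_beta[nz]) == sign(fwd$t_mod[nz])))
})

test_that("region aggregation combines one-sided evidence by signed Stouffer", {
  ann <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 10000,
                        end = 20000, strand = "+", tss = 10000)
  # promoter [tss-1500, tss+500]; two probes inside, same direction,
  # one-sided p 0.01 and 0.02 -> z_comb = (2.3263 + 2.0537)/sqrt(2)
  dmps <- tibble::tibble(
    probe_id = c("p1", "p2", "p3"),
    contrast = "B vs A",
    delta_beta = c(-0.2, -0.3, -0.1),
    t_mod = c(-3, -3.5, -1), df = 6,
    p = c(0.02, 0.04, 0.5),       # two-sided; one-sided = 0.01, 0.02
    q = c(0.05, 0.05, 0.5), is_dmp = c(TRUE, TRUE, FALSE)
  )
  man <- plain_manifest(c("p1", "p2", "p3"),
                        pos = c(9000, 9900, 15000))
  dmr <- aggregate_dmrs(dmps, ann, man)
  prom <- dmr[dmr$region_kind == "promoter", ]
  expect_equal(prom$n_probes, 2)
  expect_equal(prom$z_comb, -(qnorm(0.99) + qnorm(0.98)) / sqrt(2),
               tolerance = 1e-4)
  expect_equal(abs(prom$z_comb), 3.097, tolerance = 1e-3)
  expect_equal(prom$direction, "hypo")
  # gene body holds only p3 -> excluded with < 2 probes
  expect_false(any(dmr$region_kind == "gene_body"))
  expect_true("g1:gene_body" %in% attr(dmr, "excluded"))
})

test_that("opposite directions with equal evidence cancel to p = 1", {
  ann <- tibble::tibble(gene_id = "g1", chrom = "chr1", start = 10000,
                        end = 20000, strand = "+", tss = 10000)
  dmps <- tibble::tibble(
    probe_id = c("p1", "p2"), contrast = "B vs A",
    delta_beta = c(-0.2, 0.2), t_mod = c(-3, 3), df = 6,
    p = c(0.02, 0.02), q = 0.05, is_dmp = TRUE
  )
  man <- plain_manifest(c("p1", "p2"), pos = c(9000, 9900))
  dmr <- aggregate_dmrs(dmps, ann, man)
  prom <- dmr[dmr$region_kind == "promoter", ]
  expect_equal(prom$z_comb, 0, tolerance = 1e-12)
  expect_equal(prom$p, 1)
})

test_that("promoter windows follow strand orientation", {
  ann <- tibble::tibble(gene_id = c("plus", "minus"),
                        chrom = "chr1",
                        start = c(10000, 30000), end = c(20000, 40000),
                        strand = c("+", "-"),
                        tss = c(10000, 40000))
  # for "minus": promoter upstream means larger coordinates
  dmps <- tibble::tibble(
    probe_id = paste0("p", 1:4), contrast = "B vs A",
    delta_beta = -0.2, t_mod = -3, df = 6, p = 0.02, q = 0.05, is_dmp = TRUE
  )
  man <- plain_manifest(dmps$probe_id,
                        pos = c(8600, 10400, 41400, 39600))
  dmr <- aggregate_dmrs(dmps, ann, man)
  prom <- dmr[dmr$region_kind == "promoter", ]
  expect_equal(sort(prom$gene_id), c("minus", "plus"))
  expect_equal(prom$n_probes, c(2, 2))
})
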