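#' Simulate a paired methylome-transcriptome experiment
#'
#' Generates a complete synthetic dataset with known ground truth: a sample
#' design table, gene annotation, probe manifest, an RNA-seq count matrix,
#' a beta-value methylation matrix, and effect tables recording every
#' planted effect (for parameter-recovery benchmarking).
#'
#' The generative model:
#' * Counts for gene g in sample j are NB with mean
#'   `s_j * mu_g * 2^(x_j * log2fc_g + 0.1 * k * z_gj)` and dispersion
#'   `alpha_g`, where `x_j` is 1 in conditions where the gene is
#'   dysregulated (the knockout always; a rescue condition only when the
#'   gene is *not* rescued by that isoform) and `z_gj` is a shared latent
#'   variable present only for methylation-coupled genes.
#' * Beta values are logit-normal around bimodal probe baselines.
#'   Background probes carry the global knockout methylation effect: a
#'   fraction shifts down (hypomethylation) and a small fraction up, each
#'   probe with its own rescue status determining which conditions revert.
#'   Probes linked to a coupled gene shift with sign opposite (canonical)
#'   or equal (non-canonical) to the gene's fold change and additionally
#'   load on the gene's latent variable, producing negative or positive
#'   expression-methylation correlation.
#'
#' Output is deterministic given `(config, seed)`; independent stages draw
#' from fixed seed sub-streams so enlarging the gene set does not reshuffle
#' earlier draws.
#'
#' @param config A [synth_config()] object.
#' @param seed Integer master seed.
#' @param gene_effects Optional precomputed gene-effect assignment (as
#'   produced internally); used by [simulate_twin_experiment()] to share
#'   planted truth across species. Most callers leave this `NULL`.
#' @return A list of class `"methlink_sim"` with tibbles `design`,
#'   `annotation`, `manifest`, `counts`, `beta`, `truth_genes`,
#'   `truth_probes`, plus the `config` and `seed` used.
#' @export
#' @examples
#' sim <- simulate_experiment(synth_config(n_genes = 40, background_probes = 30), seed = 1)
#' dim(df_counts <- sim$counts)
#' sim$truth_genes
simulate_experiment <- function(config, seed, gene_effects = NULL) {
  stopifnot(inherits(config, "methlink_config"))
  cfg <- config
  conds <- .designs[[cfg$design]]
  prefix <- if (cfg$species == "human") "g" else "mmu_g"
  probe_prefix <- if (cfg$species == "human") "cg" else "cg_m"

  design <- tibble(
    sample_id = paste0(rep(conds, each = cfg$n_replicates), "_",
                       rep(seq_len(cfg$n_replicates), length(conds))),
    condition = rep(conds, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), length(conds)),
    species = cfg$species
  )
  n_samples <- nrow(design)

  # --- layout: annotation and manifest (sub-stream 1) -----------------------
  layout <- with_substream(seed, 1L, {
    chrom <- paste0("chr", rep_len(seq_len(cfg$n_chroms), cfg$n_genes))
    idx_on_chrom <- stats::ave(seq_len(cfg$n_genes), chrom, FUN = seq_along)
    tss <- 100000L + (idx_on_chrom - 1L) * cfg$gene_spacing
    strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
    len <- sample(2000:15000, cfg$n_genes, replace = TRUE)
    annotation <- tibble(
      gene_id = sprintf("%s%04d", prefix, seq_len(cfg$n_genes)),
      chrom = chrom,
      start = ifelse(strand == "+", tss, tss - len),
      end = ifelse(strand == "+", tss + len, tss),
      strand = strand,
      tss = as.integer(tss)
    )
    n_linked <- cfg$n_genes * cfg$probes_per_gene
    offs <- sample(seq(-cfg$probe_offset_max, cfg$probe_offset_max),
                   n_linked, replace = TRUE)
    linked <- tibble(
      gene_id = rep(annotation$gene_id, each = cfg$probes_per_gene),
      chrom = rep(annotation$chrom, each = cfg$probes_per_gene),
      pos = rep(annotation$tss, each = cfg$probes_per_gene) + offs
    )
    n_bg <- cfg$background_probes
    n_bg_x <- round(n_bg * cfg$sex_chrom_fraction)
    bg_chrom <- c(sample(paste0("chr", seq_len(cfg$n_chroms)), n_bg - n_bg_x,
                         replace = TRUE), rep("chrX", n_bg_x))
    # background probes sit far outside any cis window
    bg_pos <- 10000000L + sample.int(5000000L, n_bg, replace = TRUE)
    probes <- bind_rows(
      linked %>% mutate(role = "gene_adjacent"),
      tibble(gene_id = NA_character_, chrom = bg_chrom, pos = bg_pos,
             role = "background")
    ) %>%
      mutate(
        probe_id = sprintf("%s%07d", probe_prefix, dplyr::row_number()),
        design_type = ifelse(runif(dplyr::n()) < cfg$design_type_II_fraction,
                             "II", "I"),
        snp_overlap = runif(dplyr::n()) < cfg$snp_overlap_rate,
        context_nonCpG = runif(dplyr::n()) < cfg$context_noncpg_rate,
        sex_chrom = chrom %in% c("chrX", "chrY")
      )
    list(annotation = annotation, probes = probes)
  })
  annotation <- layout$annotation
  probes <- layout$probes

  # --- planted gene effects (sub-stream 2) ----------------------------------
  if (is.null(gene_effects)) {
    gene_effects <- with_substream(seed, 2L, {
      assign_gene_effects(annotation$gene_id, cfg)
    })
  } else {
    stopifnot(identical(gene_effects$gene_id, annotation$gene_id))
  }

  # linked probes of coupled genes carry the planted cis methylation effect
  linked_map <- probes %>%
    filter(.data$role == "gene_adjacent") %>%
    select("probe_id", "gene_id") %>%
    inner_join(gene_effects %>% filter(.data$coupling != "none") %>%
                 select("gene_id", "coupling", "rescue_truth", "de_sign"),
               by = "gene_id")

  # --- baselines (sub-stream 3) ---------------------------------------------
  base <- with_substream(seed, 3L, {
    mu <- 2^runif(cfg$n_genes, cfg$baseline_log2_mu_range[1],
                  cfg$baseline_log2_mu_range[2])
    alpha <- runif(cfg$n_genes, cfg$dispersion_range[1], cfg$dispersion_range[2])
    conc <- cfg$beta_mode_concentration
    mode <- sample(c(1L, 2L), nrow(probes), replace = TRUE)
    m <- cfg$beta_modes[mode]
    beta0 <- stats::rbeta(nrow(probes), m * conc, (1 - m) * conc)
    beta0 <- pmin(pmax(beta0, 0.01), 0.99)
    # background probes draw their own condition effect and rescue status
    n_bg <- sum(probes$role == "background")
    affected <- runif(n_bg) < cfg$meth_affected_fraction
    u <- runif(n_bg)
    bg_dir <- ifelse(u < cfg$meth_hypo_fraction, -1,
                     ifelse(u < cfg$meth_hypo_fraction + cfg$meth_hyper_fraction,
                            1, 0))
    bg_dir[!affected] <- 0
    bg_rescue <- sample(names(cfg$rescue_props_probe), n_bg, replace = TRUE,
                        prob = cfg$rescue_props_probe)
    list(mu = mu, alpha = alpha, logit0 = qlogis(beta0),
         bg_dir = bg_dir, bg_rescue = bg_rescue)
  })

  # --- library sizes (sub-stream 4) -----------------------------------------
  libsize <- with_substream(seed, 4L, {
    2^rnorm(n_samples, 0, cfg$libsize_log2_sd)
  })

  # --- latent coupling variables (sub-stream 5) -----------------------------
  coupled_ids <- gene_effects$gene_id[gene_effects$coupling != "none"]
  latent <- with_substream(seed, 5L, {
    if (length(coupled_ids)) {
      matrix(rnorm(length(coupled_ids) * n_samples),
             nrow = length(coupled_ids),
             dimnames = list(coupled_ids, design$sample_id))
    } else {
      matrix(0, 0, n_samples)
    }
  })
  k_expr <- 0.1 * cfg$coupling_strength
  k_meth <- 0.3 * cfg$coupling_strength

  # condition multiplier per feature: 1 where the feature stays dysregulated
  x_cond <- function(rescue_truth) {
    vapply(design$condition, function(cond) {
      switch(cond,
        WT = 0, FLFL = 0,
        KO = 1, DIEC = 1,
        R1 = if (rescue_truth %in% c("both", "R1_only")) 0 else 1,
        R2 = if (rescue_truth %in% c("both", "R2_only")) 0 else 1
      )
    }, numeric(1), USE.NAMES = FALSE)
  }

  # --- counts (sub-stream 6) ------------------------------------------------
  counts_mat <- with_substream(seed, 6L, {
    out <- matrix(0L, cfg$n_genes, n_samples,
                  dimnames = list(annotation$gene_id, design$sample_id))
    for (g in seq_len(cfg$n_genes)) {
      eff <- gene_effects[g, ]
      log2mu <- log2(base$mu[g])
      if (eff$de_status != "null") {
        log2mu <- log2mu + eff$de_sign * cfg$log2fc * x_cond(eff$rescue_truth)
      }
      if (eff$coupling != "none") {
        log2mu <- log2mu + k_expr * latent[eff$gene_id, ]
      }
      out[g, ] <- rnbinom(n_samples, mu = libsize * 2^log2mu,
                          size = 1 / base$alpha[g])
    }
    out
  })

  # --- methylation (sub-stream 7) -------------------------------------------
  beta_mat <- with_substream(seed, 7L, {
    n_probes <- nrow(probes)
    logit <- matrix(rep(base$logit0, n_samples), n_probes, n_samples) +
      matrix(rnorm(n_probes * n_samples, 0, cfg$meth_noise_sd),
             n_probes, n_samples)
    dimnames(logit) <- list(probes$probe_id, design$sample_id)
    bg_idx <- which(probes$role == "background")
    for (i in seq_along(bg_idx)) {
      d <- base$bg_dir[i]
      if (d != 0) {
        logit[bg_idx[i], ] <- logit[bg_idx[i], ] +
          d * cfg$meth_shift * x_cond(base$bg_rescue[i])
      }
    }
    if (nrow(linked_map)) {
      for (i in seq_len(nrow(linked_map))) {
        lm <- linked_map[i, ]
        dir <- if (lm$coupling == "canonical") -lm$de_sign else lm$de_sign
        load <- if (lm$coupling == "canonical") -k_meth else k_meth
        logit[lm$probe_id, ] <- logit[lm$probe_id, ] +
          dir * cfg$meth_shift * x_cond(lm$rescue_truth) +
          load * latent[lm$gene_id, ]
      }
    }
    plogis(logit)
  })

  # --- missing values (sub-stream 8) ----------------------------------------
  if (cfg$missing_rate > 0) {
    beta_mat <- with_substream(seed, 8L, {
      hit <- which(runif(nrow(beta_mat)) < cfg$missing_rate)
      for (i in hit) beta_mat[i, sample.int(n_samples, 1L)] <- NA_real_
      beta_mat
    })
  }

  truth_genes <- gene_effects %>%
    left_join(
      linked_map %>% group_by(.data$gene_id) %>%
        summarise(linked_probe_ids = list(.data$probe_id)),
      by = "gene_id"
    ) %>%
    mutate(
      linked_probe_ids = map(.data$linked_probe_ids, ~ .x %||% character(0)),
      log2fc_KO = ifelse(.data$de_status == "null", 0,
                         .data$de_sign * cfg$log2fc),
      delta_beta_KO = ifelse(
        .data$coupling == "none", 0,
        ifelse(.data$coupling == "canonical", -1, 1) * .data$de_sign *
          cfg$meth_shift),
      baseline_mu = base$mu,
      dispersion = base$alpha
    ) %>%
    select("gene_id", "de_status", "rescue_truth", "linked_probe_ids",
           "coupling", "log2fc_KO", "delta_beta_KO", "baseline_mu",
           "dispersion")

  bg_rows <- probes$role == "background"
  truth_probes <- probes %>%
    select("probe_id", "gene_id", "role") %>%
    mutate(
      shift_logit = 0,
      rescue_truth = "not_applicable"
    )
  truth_probes$shift_logit[bg_rows] <- base$bg_dir * cfg$meth_shift
  truth_probes$rescue_truth[bg_rows] <-
    ifelse(base$bg_dir == 0, "not_applicable", base$bg_rescue)
  if (nrow(linked_map)) {
    j <- match(linked_map$probe_id, truth_probes$probe_id)
    truth_probes$shift_logit[j] <-
      ifelse(linked_map$coupling == "canonical", -1, 1) *
      linked_map$de_sign * cfg$meth_shift
    truth_probes$rescue_truth[j] <- linked_map$rescue_truth
  }
  truth_probes <- truth_probes %>%
    mutate(direction = ifelse(.data$shift_logit < 0, "hypo",
                              ifelse(.data$shift_logit > 0, "hyper", "none")))

  structure(list(
    design = design,
    annotation = annotation,
    manifest = probes %>% select("probe_id", "chrom", "pos", "design_type",
                                 "snp_overlap", "context_nonCpG", "sex_chrom"),
    counts = matrix_to_df(counts_mat, "gene_id"),
    beta = matrix_to_df(beta_mat, "probe_id"),
    truth_genes = truth_genes,
    truth_probes = truth_probes,
    config = cfg,
    seed = as.integer(seed)
  ), class = "methlink_sim")
}

# Draw per-gene planted effects: DE status/sign, rescue truth, coupling.
assign_gene_effects <- function(gene_ids, cfg) {
  n <- length(gene_ids)
  is_de <- runif(n) < cfg$de_fraction
  de_sign <- ifelse(runif(n) < cfg$de_up_fraction, 1, -1)
  de_sign[!is_de] <- 0
  rescue <- rep("not_applicable", n)
  if (cfg$design == "ko_rescue") {
    rescue[is_de] <- sample(names(cfg$rescue_props_gene), sum(is_de),
                            replace = TRUE, prob = cfg$rescue_props_gene)
  } else {
    rescue[is_de] <- "none"
  }
  coupling <- rep("none", n)
  if (any(is_de) && sum(cfg$coupling_props) > 0) {
    p <- c(cfg$coupling_props,
           none = max(0, 1 - sum(cfg$coupling_props)))
    coupling[is_de] <- sample(names(p), sum(is_de), replace = TRUE, prob = p)
  }
  tibble(
    gene_id = gene_ids,
    de_status = ifelse(!is_de, "null",
                       ifelse(de_sign > 0, "up_in_KO", "down_in_KO")),
    de_sign = de_sign,
    rescue_truth = rescue,
    coupling = coupling
  )
}

#' Simulate a 1:1 ortholog map between two annotations
#'
#' @param annotation_a,annotation_b Gene annotations (tibbles with a
#'   `gene_id` column).
#' @param frac_mapped Fraction of the smaller gene set that is mapped.
#' @param seed Integer seed.
#' @return A tibble with columns `gene_a`, `gene_b`; a bijection on the
#'   mapped subset.
#' @export
simulate_ortholog_map <- function(annotation_a, annotation_b,
                                  frac_mapped = 1, seed = 1) {
  if (frac_mapped < 0 || frac_mapped > 1) {
    abort_config("frac_mapped must be in [0, 1]")
  }
  n <- round(frac_mapped * min(nrow(annotation_a), nrow(annotation_b)))
  with_substream(seed, 11L, {
    tibble(
      gene_a = sample(annotation_a$gene_id, n),
      gene_b = sample(annotation_b$gene_id, n)
    ) %>% arrange(.data$gene_a)
  })
}

#' Simulate a second species dataset sharing planted truth through orthologs
#'
#' Generates a dataset whose mapped genes inherit the DE status, direction
#' and coupling class of their orthologs in an existing simulation, so that
#' cross-species concordance has a known ground truth. Unmapped genes draw
#' fresh effects.
#'
#' @param config A [synth_config()] for the second dataset (typically
#'   `design = "two_group"`, `species = "mouse"`).
#' @param seed Integer master seed for the second dataset.
#' @param truth_genes The `truth_genes` table of the first simulation.
#' @param ortholog_map Tibble `gene_a` (first dataset) / `gene_b` (this
#'   dataset) as from [simulate_ortholog_map()].
#' @return A `"methlink_sim"` list (see [simulate_experiment()]).
#' @export
simulate_twin_experiment <- function(config, seed, truth_genes, ortholog_map) {
  stopifnot(inherits(config, "methlink_config"))
  gene_ids <- sprintf("%s%04d",
                      if (config$species == "human") "g" else "mmu_g",
                      seq_len(config$n_genes))
  eff <- with_substream(seed, 2L, assign_gene_effects(gene_ids, config))
  j <- match(ortholog_map$gene_b, eff$gene_id)
  i <- match(ortholog_map$gene_a, truth_genes$gene_id)
  ok <- !is.na(i) & !is.na(j)
  src <- truth_genes[i[ok], ]
  eff$de_status[j[ok]] <- src$de_status
  eff$de_sign[j[ok]] <- sign(src$log2fc_KO)
  eff$coupling[j[ok]] <- src$coupling
  eff$rescue_truth[j[ok]] <- ifelse(
    src$de_status == "null", "not_applicable",
    if (config$design == "two_group") "none" else src$rescue_truth
  )
  simulate_experiment(config, seed, gene_effects = eff)
}
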