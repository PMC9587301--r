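#' Pipeline configuration
#'
#' Validates the complete parameter set for [run_pipeline()]: simulator
#' settings for the primary (knockout/rescue) dataset and an optional
#' second (two-group, other-species) dataset, all module thresholds, and
#' the master seed. Unknown simulator keys are rejected.
#'
#' @param synthio Named list of [synth_config()] overrides for the primary
#'   dataset.
#' @param synthio_b Named list of overrides for the second dataset, or
#'   `NULL` to skip the cross-species stages. Defaults to a two-group
#'   mouse design.
#' @param frac_mapped Fraction of genes carried by the simulated ortholog
#'   map.
#' @param deg_fdr,dmp_fdr,dmr_fdr FDR thresholds for the respective calls.
#' @param pair_fdr Threshold on the permutation q-value for cis pairs.
#' @param window Cis window in bp.
#' @param n_perm Sampled permutations for the permutation FDR.
#' @param exhaustive_cap See [permutation_fdr()].
#' @param require_reversal See [classify_rescue()].
#' @param rescued_only Restrict the cis-linkage gene universe of the
#'   knockout/rescue dataset to DEGs rescued by both isoforms (default,
#'   mirroring the screening of rescued genes); `FALSE` uses all DEGs.
#' @param seed Master seed; every stage seed derives from it.
#' @return A list of class `"methlink_pipeline_config"`.
#' @export
pipeline_config <- function(synthio = list(),
                            synthio_b = list(design = "two_group",
                                             species = "mouse"),
                            frac_mapped = 1,
                            deg_fdr = 0.05, dmp_fdr = 0.05, dmr_fdr = 0.05,
                            pair_fdr = 0.05,
                            window = 5000, n_perm = 1000,
                            exhaustive_cap = 720,
                            require_reversal = TRUE,
                            rescued_only = TRUE,
                            seed = 1) {
  known <- names(formals(synth_config))
  check_keys <- function(x, label) {
    bad <- setdiff(names(x), known)
    if (length(bad)) {
      abort_config(paste0("unknown ", label, " key(s): ",
                          paste(bad, collapse = ", ")))
    }
  }
  check_keys(synthio, "synthio")
  if (!is.null(synthio_b)) check_keys(synthio_b, "synthio_b")
  for (f in c(deg_fdr, dmp_fdr, dmr_fdr, pair_fdr)) {
    if (f <= 0 || f >= 1) abort_config("FDR thresholds must be in (0, 1)")
  }
  if (window <= 0) abort_config("window must be > 0")
  if (n_perm < 1) abort_config("n_perm must be >= 1")
  if (frac_mapped < 0 || frac_mapped > 1) {
    abort_config("frac_mapped must be in [0, 1]")
  }
  cfg_a <- do.call(synth_config, modifyList(list(window = window), synthio))
  cfg_b <- if (is.null(synthio_b)) NULL else {
    do.call(synth_config, modifyList(
      list(design = "two_group", species = "mouse", window = window),
      synthio_b))
  }
  structure(list(
    synthio = cfg_a, synthio_b = cfg_b, frac_mapped = frac_mapped,
    deg_fdr = deg_fdr, dmp_fdr = dmp_fdr, dmr_fdr = dmr_fdr,
    pair_fdr = pair_fdr, window = as.integer(window),
    n_perm = as.integer(n_perm), exhaustive_cap = exhaustive_cap,
    require_reversal = require_reversal, rescued_only = rescued_only,
    seed = as.integer(seed)
  ), class = "methlink_pipeline_config")
}

ko_contrasts <- list(c("WT", "KO"), c("WT", "R1"), c("WT", "R2"),
                     c("KO", "R1"), c("KO", "R2"))
contrast_tag <- function(ct) paste0(ct[[2]], "_vs_", ct[[1]])

pfile <- function(dir, ...) file.path(dir, paste0(...))

#' Run one pipeline stage against a run directory
#'
#' Stages read their inputs from files written by earlier stages into
#' `dir` and write their own outputs there (write-once), so a run can be
#' driven stage by stage (as the command-line interface does) or all at
#' once via [run_pipeline()].
#'
#' @param stage One of `"simulate"`, `"de"`, `"dmp"`, `"rescue"`,
#'   `"integrate"`, `"xspecies"`.
#' @param config A [pipeline_config()].
#' @param dir Run directory.
#' @return Invisibly, the file paths written by the stage.
#' @export
run_stage <- function(stage, config, dir) {
  stopifnot(inherits(config, "methlink_pipeline_config"))
  fn <- switch(stage,
    simulate = stage_simulate, de = stage_de, dmp = stage_dmp,
    rescue = stage_rescue, integrate = stage_integrate,
    xspecies = stage_xspecies,
    abort_config(paste0("unknown stage: ", stage))
  )
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withCallingHandlers(
    fn(config, dir),
    error = function(e) {
      if (!inherits(e, "methlink_config_error")) {
        message("stage '", stage, "' failed: ", conditionMessage(e))
      }
    }
  )
}

datasets_of <- function(config) {
  ds <- list(a = config$synthio)
  if (!is.null(config$synthio_b)) ds$b <- config$synthio_b
  ds
}

stage_simulate <- function(config, dir) {
  written <- character()
  w <- function(path) {
    written <<- c(written, path)
    path
  }
  sim_a <- simulate_experiment(config$synthio, seed = config$seed)
  sims <- list(a = sim_a)
  if (!is.null(config$synthio_b)) {
    ann_b_ids <- config$synthio_b$n_genes
    map_seed <- config$seed + 2000L
    # twin dataset shares planted truth through the ortholog map
    ann_a <- sim_a$annotation
    dummy_b <- tibble(gene_id = sprintf("mmu_g%04d", seq_len(ann_b_ids)))
    omap <- simulate_ortholog_map(ann_a, dummy_b, config$frac_mapped,
                                  seed = map_seed)
    sim_b <- simulate_twin_experiment(config$synthio_b,
                                      seed = config$seed + 1000L,
                                      truth_genes = sim_a$truth_genes,
                                      ortholog_map = omap)
    sims$b <- sim_b
    write_methlink_tsv(omap, w(pfile(dir, "ortholog_map.tsv")),
                       meta = c(seed = map_seed))
  }
  for (tag in names(sims)) {
    sim <- sims[[tag]]
    meta <- c(seed = sim$seed, design = sim$config$design)
    write_methlink_tsv(sim$design, w(pfile(dir, tag, "_design.tsv")), meta)
    write_methlink_tsv(sim$counts, w(pfile(dir, tag, "_counts.tsv")), meta)
    write_methlink_tsv(sim$beta, w(pfile(dir, tag, "_beta.tsv")), meta)
    write_manifest_csv(sim$manifest, w(pfile(dir, tag, "_manifest.csv")))
    write_annotation_gtf(sim$annotation, w(pfile(dir, tag, "_annotation.gtf")))
    write_annotation_bed(sim$annotation, w(pfile(dir, tag, "_annotation.bed")))
    write_methlink_tsv(sim$truth_genes,
                       w(pfile(dir, tag, "_truth_genes.tsv")), meta)
    write_methlink_tsv(sim$truth_probes,
                       w(pfile(dir, tag, "_truth_probes.tsv")), meta)
  }
  invisible(written)
}

stage_de <- function(config, dir) {
  written <- character()
  for (tag in names(datasets_of(config))) {
    counts <- read_methlink_tsv(pfile(dir, tag, "_counts.tsv"))
    design <- read_methlink_tsv(pfile(dir, tag, "_design.tsv"))
    sf <- size_factors(counts)
    p <- pfile(dir, tag, "_size_factors.tsv")
    write_methlink_tsv(sf, p); written <- c(written, p)
    contrasts <- if (tag == "a" && config$synthio$design == "ko_rescue") {
      ko_contrasts
    } else {
      list(.designs[[datasets_of(config)[[tag]]$design]])
    }
    for (ct in contrasts) {
      de <- test_de(counts, design, ct, factors = sf, fdr = config$deg_fdr)
      p <- pfile(dir, tag, "_de_", contrast_tag(ct), ".tsv")
      write_methlink_tsv(de, p, meta = c(fdr = config$deg_fdr))
      written <- c(written, p)
    }
  }
  invisible(written)
}

stage_dmp <- function(config, dir) {
  written <- character()
  for (tag in names(datasets_of(config))) {
    beta <- read_methlink_tsv(pfile(dir, tag, "_beta.tsv"))
    manifest <- read_manifest_csv(pfile(dir, tag, "_manifest.csv"))
    design <- read_methlink_tsv(pfile(dir, tag, "_design.tsv"))
    annotation <- read_annotation_gtf(pfile(dir, tag, "_annotation.gtf"))
    filtered <- filter_probes(beta, manifest)
    p <- pfile(dir, tag, "_filter_report.tsv")
    write_methlink_tsv(filter_report(filtered), p); written <- c(written, p)
    normed <- normalize_betas(filtered, manifest)
    p <- pfile(dir, tag, "_beta_normalized.tsv")
    write_methlink_tsv(normed, p); written <- c(written, p)
    ds_cfg <- datasets_of(config)[[tag]]
    contrasts <- if (ds_cfg$design == "ko_rescue") ko_contrasts else {
      list(.designs[[ds_cfg$design]])
    }
    for (ct in contrasts) {
      dmp <- test_dmp(normed, design, ct, fdr = config$dmp_fdr)
      p <- pfile(dir, tag, "_dmp_", contrast_tag(ct), ".tsv")
      write_methlink_tsv(dmp, p, meta = c(fdr = config$dmp_fdr))
      written <- c(written, p)
    }
    # DMRs for the knockout contrast
    ct0 <- contrasts[[1]]
    dmp0 <- read_methlink_tsv(pfile(dir, tag, "_dmp_", contrast_tag(ct0), ".tsv"))
    dmr <- aggregate_dmrs(dmp0, annotation, manifest, fdr = config$dmr_fdr)
    p <- pfile(dir, tag, "_dmr_", contrast_tag(ct0), ".tsv")
    write_methlink_tsv(dmr, p, meta = c(fdr = config$dmr_fdr))
    written <- c(written, p)
    sig <- dmr %>% filter(.data$is_dmr)
    if (nrow(sig)) {
      p <- pfile(dir, tag, "_dmr_", contrast_tag(ct0), ".bed")
      write_annotation_bed(
        sig %>% mutate(gene_id = .data$region_id, strand = "*") %>%
          select("gene_id", "chrom", "start", "end", "strand"),
        p)
      written <- c(written, p)
    }
  }
  invisible(written)
}

stage_rescue <- function(config, dir) {
  if (config$synthio$design != "ko_rescue") {
    abort_config("rescue stage requires the ko_rescue design")
  }
  written <- character()
  for (kind in c("de", "dmp")) {
    tabs <- map(ko_contrasts, function(ct) {
      read_methlink_tsv(pfile(dir, "a_", kind, "_", contrast_tag(ct), ".tsv"))
    })
    resc <- classify_rescue(tabs[[1]], tabs[[2]], tabs[[3]], tabs[[4]],
                            tabs[[5]], fdr = config$deg_fdr,
                            require_reversal = config$require_reversal)
    fk <- if (kind == "de") "genes" else "probes"
    p <- pfile(dir, "a_rescue_", fk, ".tsv")
    write_methlink_tsv(resc, p); written <- c(written, p)
    summ <- rescue_summary(resc)
    p <- pfile(dir, "a_rescue_", fk, "_summary.tsv")
    write_methlink_tsv(
      summ %>% mutate(fraction_rescued = attr(summ, "fraction_rescued")), p)
    written <- c(written, p)
  }
  invisible(written)
}

stage_integrate <- function(config, dir) {
  written <- character()
  for (tag in names(datasets_of(config))) {
    ds_cfg <- datasets_of(config)[[tag]]
    ct0 <- if (ds_cfg$design == "ko_rescue") c("WT", "KO") else c("FLFL", "DIEC")
    de <- read_methlink_tsv(pfile(dir, tag, "_de_", contrast_tag(ct0), ".tsv"))
    dmp <- read_methlink_tsv(pfile(dir, tag, "_dmp_", contrast_tag(ct0), ".tsv"))
    annotation <- read_annotation_gtf(pfile(dir, tag, "_annotation.gtf"))
    manifest <- read_manifest_csv(pfile(dir, tag, "_manifest.csv"))
    counts <- read_methlink_tsv(pfile(dir, tag, "_counts.tsv"))
    beta <- read_methlink_tsv(pfile(dir, tag, "_beta_normalized.tsv"))
    design <- read_methlink_tsv(pfile(dir, tag, "_design.tsv"))
    sf <- read_methlink_tsv(pfile(dir, tag, "_size_factors.tsv"))

    genes_keep <- de %>% filter(.data$is_deg) %>% pull("gene_id")
    if (tag == "a" && config$rescued_only) {
      resc <- read_methlink_tsv(pfile(dir, "a_rescue_genes.tsv"))
      genes_keep <- intersect(genes_keep,
                              resc$feature_id[resc$status == "both"])
    }
    deg_ann <- annotation %>% filter(.data$gene_id %in% genes_keep)
    sig_dmps <- dmp %>% filter(.data$is_dmp)
    pairs <- link_dmps_to_genes(sig_dmps, deg_ann, manifest,
                                window = config$window)
    norm_expr <- normalize_counts(counts, factors = sf)
    if (!nrow(pairs)) {
      write_methlink_tsv(tibble(gene_id = character(), probe_id = character()),
                         pfile(dir, tag, "_pairs.tsv"))
      written <- c(written, pfile(dir, tag, "_pairs.tsv"))
      next
    }
    pairs <- correlate_pairs(pairs, norm_expr, beta)
    perm_seed <- config$seed + 3000L + as.integer(tag == "b")
    pairs <- permutation_fdr(pairs, norm_expr, beta, n_perm = config$n_perm,
                             seed = perm_seed,
                             exhaustive_cap = config$exhaustive_cap)
    pairs <- classify_pairs(pairs, fdr = config$pair_fdr)
    p <- pfile(dir, tag, "_pairs.tsv")
    write_methlink_tsv(pairs, p, meta = c(
      seed = perm_seed, n_permutations = attr(pairs, "n_permutations"),
      window = config$window))
    written <- c(written, p)
    labels <- summarize_gene_labels(pairs)
    p <- pfile(dir, tag, "_gene_labels.tsv")
    write_methlink_tsv(labels, p); written <- c(written, p)
    sigp <- pairs %>% filter(.data$pair_class != "ns") %>%
      inner_join(manifest %>% select("probe_id", "chrom", "pos"),
                 by = "probe_id") %>%
      distinct(.data$probe_id, .keep_all = TRUE)
    if (nrow(sigp)) {
      p <- pfile(dir, tag, "_sig_pair_probes.bed")
      write_annotation_bed(
        sigp %>% mutate(gene_id = .data$probe_id, start = .data$pos,
                        end = .data$pos, strand = "*") %>%
          select("gene_id", "chrom", "start", "end", "strand"),
        p)
      written <- c(written, p)
    }
  }
  invisible(written)
}

stage_xspecies <- function(config, dir) {
  if (is.null(config$synthio_b)) {
    abort_config("xspecies stage requires synthio_b")
  }
  labels_a <- read_methlink_tsv(pfile(dir, "a_gene_labels.tsv"))
  labels_b <- read_methlink_tsv(pfile(dir, "b_gene_labels.tsv"))
  omap <- read_methlink_tsv(pfile(dir, "ortholog_map.tsv"))
  conc <- intersect_linked_genes(labels_a, labels_b, omap)
  p <- pfile(dir, "concordance.tsv")
  write_methlink_tsv(conc, p, meta = c(
    n_shared = attr(conc, "n_shared"),
    n_same_direction = attr(conc, "n_same_direction")))
  invisible(p)
}

#' Run the full pipeline
#'
#' Executes simulate, differential expression, differential methylation,
#' rescue classification, cis integration and (when a second dataset is
#' configured) the cross-species intersection, writing every stage output
#' into `dir` plus a run manifest (`manifest.json`) recording the package
#' version, master seed, derived stage seeds, a configuration hash and a
#' content hash per output file. Re-running with the same configuration
#' and seed reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, dir) {
  stopifnot(inherits(config, "methlink_pipeline_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stages <- c("simulate", "de", "dmp",
              if (config$synthio$design == "ko_rescue") "rescue",
              "integrate",
              if (!is.null(config$synthio_b)) "xspecies")
  for (st in stages) run_stage(st, config, dir)
  files <- sort(setdiff(list.files(dir), "manifest.json"))
  hashes <- vapply(files, function(f) {
    rlang::hash(readBin(file.path(dir, f), "raw",
                        n = file.info(file.path(dir, f))$size))
  }, character(1))
  manifest <- list(
    package = "methlink",
    version = as.character(packageVersion("methlink")),
    seed = config$seed,
    derived_seeds = list(
      dataset_a = config$seed, dataset_b = config$seed + 1000L,
      ortholog_map = config$seed + 2000L,
      permutation_a = config$seed + 3000L,
      permutation_b = config$seed + 3001L
    ),
    config_hash = rlang::hash(config),
    stages = stages,
    files = as.list(hashes)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
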