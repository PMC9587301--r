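#' Configuration for the paired methylome-transcriptome simulator
#'
#' Builds and validates the parameter set consumed by
#' [simulate_experiment()]. Defaults emulate a four-condition
#' knockout/rescue cell-line experiment: a wild-type line (`WT`), a DNMT3A
#' knockout (`KO`), and the knockout with either isoform re-expressed
#' (`R1`, `R2`), with four replicates per condition. A two-group in vivo
#' design (`FLFL` control vs `DIEC` conditional deletion) is available via
#' `design = "two_group"`.
#'
#' @param design `"ko_rescue"` (conditions WT/KO/R1/R2) or `"two_group"`
#'   (FLFL/DIEC).
#' @param n_genes Number of simulated genes.
#' @param probes_per_gene Methylation probes placed near each gene's TSS
#'   (within `probe_offset_max` bp).
#' @param background_probes Intergenic probes carrying the global
#'   knockout methylation effects.
#' @param n_replicates Replicates per condition (>= 2).
#' @param gene_spacing Distance in bp between consecutive TSSs on a
#'   chromosome; keeps cis windows of neighbouring genes disjoint.
#' @param n_chroms Autosomes used for gene placement (`chr1`..`chrN`).
#' @param de_fraction Fraction of genes differentially expressed in the
#'   knockout.
#' @param de_up_fraction Fraction of DE genes upregulated in the knockout.
#' @param log2fc Magnitude of the planted expression log2 fold change.
#' @param rescue_props_gene,rescue_props_probe Named proportions
#'   (`both`, `R1_only`, `R2_only`, `none`) of DE genes / affected probes
#'   whose dysregulation is reverted in the rescue conditions. Must sum
#'   to 1. Ignored for the two-group design.
#' @param coupling_props Named proportions (`canonical`, `non_canonical`)
#'   of DE genes whose cis probes are coupled to expression; the
#'   remainder are uncoupled. Must sum to <= 1.
#' @param coupling_strength Scale of the shared per-sample latent variable
#'   loading: expression gains `0.1 * coupling_strength` log2 units and
#'   linked-probe logit-beta `0.3 * coupling_strength` logit units per
#'   latent SD (sign negative for canonical coupling).
#' @param baseline_log2_mu_range Range of per-gene baseline mean counts
#'   (log2 scale).
#' @param dispersion_range Range of per-gene NB dispersions (uniform).
#' @param libsize_log2_sd SD of per-sample log2 library-size factors.
#' @param meth_shift Magnitude (logit scale) of planted condition-driven
#'   methylation shifts; 1.5 gives a beta-scale change of roughly 0.2 for
#'   intermediate to high baselines.
#' @param meth_affected_fraction Fraction of background probes belonging
#'   to the compartment that carries the global knockout methylation
#'   effect. Chosen so the differentially methylated share of all probes
#'   is of the order seen on real arrays (roughly 10%).
#' @param meth_hypo_fraction,meth_hyper_fraction Within the affected
#'   compartment, the fractions shifted down (global knockout
#'   hypomethylation) and up (the minority hypermethylated compartment);
#'   the remainder is untouched.
#' @param meth_noise_sd Replicate noise SD on the logit-beta scale.
#' @param beta_modes Locations of the two modes of the bimodal baseline
#'   beta distribution.
#' @param beta_mode_concentration Beta-distribution concentration
#'   (a + b) at each mode.
#' @param window Cis window (bp) used for planted probe placement.
#' @param probe_offset_max Maximum |offset| of a gene-adjacent probe from
#'   the TSS; must be <= `window`.
#' @param snp_overlap_rate,context_noncpg_rate,missing_rate Per-probe
#'   rates of SNP-overlap flags, non-CpG-context flags, and of one
#'   missing beta value.
#' @param sex_chrom_fraction Fraction of background probes placed on chrX.
#' @param design_type_II_fraction Fraction of Infinium type-II probes.
#' @param species `"human"` or `"mouse"`; controls identifier prefixes.
#'
#' @return A validated list of class `"methlink_config"`.
#' @export
#' @examples
#' cfg <- synth_config(n_genes = 50, background_probes = 40)
#' str(cfg[c("n_genes", "de_fraction", "window")])
synth_config <- function(design = c("ko_rescue", "two_group"),
                         n_genes = 500,
                         probes_per_gene = 3,
                         background_probes = 1000,
                         n_replicates = 4,
                         gene_spacing = 25000,
                         n_chroms = 5,
                         de_fraction = 0.3,
                         de_up_fraction = 0.5,
                         log2fc = 1,
                         rescue_props_gene = c(both = 0.6, R1_only = 0.15,
                                               R2_only = 0.15, none = 0.1),
                         rescue_props_probe = c(both = 0.70, R1_only = 0.08,
                                                R2_only = 0.07, none = 0.15),
                         coupling_props = c(canonical = 0.3, non_canonical = 0.2),
                         coupling_strength = 1,
                         baseline_log2_mu_range = c(log2(20), log2(2000)),
                         dispersion_range = c(0.005, 0.05),
                         libsize_log2_sd = 0.15,
                         meth_shift = 1.5,
                         meth_affected_fraction = 0.2,
                         meth_hypo_fraction = 0.7,
                         meth_hyper_fraction = 0.05,
                         meth_noise_sd = 0.3,
                         beta_modes = c(0.1, 0.9),
                         beta_mode_concentration = 10,
                         window = 5000,
                         probe_offset_max = 4000,
                         snp_overlap_rate = 0.02,
                         context_noncpg_rate = 0.01,
                         missing_rate = 0.005,
                         sex_chrom_fraction = 0.03,
                         design_type_II_fraction = 0.8,
                         species = c("human", "mouse")) {
  cfg <- list(
    design = match.arg(design),
    n_genes = as.integer(n_genes),
    probes_per_gene = as.integer(probes_per_gene),
    background_probes = as.integer(background_probes),
    n_replicates = as.integer(n_replicates),
    gene_spacing = as.integer(gene_spacing),
    n_chroms = as.integer(n_chroms),
    de_fraction = de_fraction,
    de_up_fraction = de_up_fraction,
    log2fc = log2fc,
    rescue_props_gene = rescue_props_gene,
    rescue_props_probe = rescue_props_probe,
    coupling_props = coupling_props,
    coupling_strength = coupling_strength,
    baseline_log2_mu_range = baseline_log2_mu_range,
    dispersion_range = dispersion_range,
    libsize_log2_sd = libsize_log2_sd,
    meth_shift = meth_shift,
    meth_affected_fraction = meth_affected_fraction,
    meth_hypo_fraction = meth_hypo_fraction,
    meth_hyper_fraction = meth_hyper_fraction,
    meth_noise_sd = meth_noise_sd,
    beta_modes = beta_modes,
    beta_mode_concentration = beta_mode_concentration,
    window = as.integer(window),
    probe_offset_max = as.integer(probe_offset_max),
    snp_overlap_rate = snp_overlap_rate,
    context_noncpg_rate = context_noncpg_rate,
    missing_rate = missing_rate,
    sex_chrom_fraction = sex_chrom_fraction,
    design_type_II_fraction = design_type_II_fraction,
    species = match.arg(species)
  )
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  fracs <- c(
    de_fraction = cfg$de_fraction, de_up_fraction = cfg$de_up_fraction,
    meth_affected_fraction = cfg$meth_affected_fraction,
    meth_hypo_fraction = cfg$meth_hypo_fraction,
    meth_hyper_fraction = cfg$meth_hyper_fraction,
    snp_overlap_rate = cfg$snp_overlap_rate,
    context_noncpg_rate = cfg$context_noncpg_rate,
    missing_rate = cfg$missing_rate,
    sex_chrom_fraction = cfg$sex_chrom_fraction,
    design_type_II_fraction = cfg$design_type_II_fraction,
    cfg$rescue_props_gene, cfg$rescue_props_probe, cfg$coupling_props
  )
  bad <- names(fracs)[fracs < 0 | fracs > 1]
  if (length(bad)) {
    abort_config(paste0("fractions outside [0,1]: ", paste(bad, collapse = ", ")))
  }
  if (abs(sum(cfg$rescue_props_gene) - 1) > 1e-8) {
    abort_config("rescue_props_gene must sum to 1")
  }
  if (abs(sum(cfg$rescue_props_probe) - 1) > 1e-8) {
    abort_config("rescue_props_probe must sum to 1")
  }
  if (sum(cfg$coupling_props) > 1 + 1e-8) {
    abort_config("coupling_props must sum to <= 1")
  }
  if (!setequal(names(cfg$rescue_props_gene), c("both", "R1_only", "R2_only", "none"))) {
    abort_config("rescue_props_gene needs names both, R1_only, R2_only, none")
  }
  if (!setequal(names(cfg$coupling_props), c("canonical", "non_canonical"))) {
    abort_config("coupling_props needs names canonical, non_canonical")
  }
  if (cfg$n_replicates < 2) abort_config("n_replicates must be >= 2")
  if (cfg$meth_hypo_fraction + cfg$meth_hyper_fraction > 1 + 1e-8) {
    abort_config("meth_hypo_fraction + meth_hyper_fraction must be <= 1")
  }
  if (cfg$probe_offset_max > cfg$window) {
    abort_config("probe_offset_max must be <= window")
  }
  if (cfg$window <= 0) abort_config("window must be > 0")
  structure(cfg, class = "methlink_config")
}

#' A fully null simulator configuration
#'
#' Convenience wrapper around [synth_config()] with every planted effect
#' switched off (no differential expression, no methylation shifts, no
#' coupling): the exchangeable null used for type-I-error and FDR-control
#' checks.
#'
#' @param ... Passed on to [synth_config()].
#' @return A `"methlink_config"`.
#' @export
synth_config_null <- function(...) {
  synth_config(de_fraction = 0, meth_affected_fraction = 0,
               meth_hypo_fraction = 0, meth_hyper_fraction = 0,
               coupling_props = c(canonical = 0, non_canonical = 0),
               snp_overlap_rate = 0, context_noncpg_rate = 0, missing_rate = 0,
               ...)
}
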