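# methlink

Integrated analysis of paired DNA methylation arrays and RNA-seq counts in
knockout/rescue designs — with a ground-truth simulator for benchmarking
every step.

## The problem

Deleting a de novo DNA methyltransferase (e.g. DNMT3A in intestinal
epithelial cells) dysregulates both the transcriptome and the methylome.
Re-expressing individual isoforms in the knockout asks which changes each
isoform can revert, and correlating methylation with expression near
transcription start sites asks which expression changes are plausibly
methylation-driven. `methlink` implements that full analysis chain for a
four-condition design — wild type (WT), knockout (KO), and the knockout
rescued with either of two isoforms (R1, R2), n replicates each — plus a
two-group in vivo design, and a cross-species intersection of the results:

1. **Differential expression** — median-of-ratios size factors
   `s_j = exp(median_g log(c_gj / gm_g))` and a per-gene negative-binomial
   Wald test: method-of-moments dispersion `α̂ = max((s² − m̄)/m̄², 10⁻⁸)`,
   `log2FC` with pseudocount 0.5, delta-method standard error from
   `Var(Y) = μ + αμ²`, two-sided p from *t*(n₁+n₂−2), Benjamini–Hochberg
   FDR; DEG at q < 0.05.
2. **Differential methylation** — probe filtering (SNP overlap, non-CpG
   context, sex chromosomes, missing values), design-type-stratified
   quantile normalization of beta values, M-values
   `M = log2((β+ε)/(1−β+ε))`, and a moderated t-test whose variance prior
   (d₀, s₀²) is fitted by method of moments on the log residual variances;
   promoter ([−1500, +500] around the TSS) and gene-body regions are
   aggregated by a direction-signed Stouffer statistic
   `z = Σ sign(Δβᵢ)·zᵢ / √k` over member probes (≥ 2 required).
3. **Rescue classification** — a KO-dysregulated feature is *rescued* by an
   isoform when it is no longer significant versus WT **and** shows a
   significant sign-reversing change versus KO (the reversal clause is a
   toggle); statuses: both / R1_only / R2_only / none.
4. **Cis integration** — each differentially methylated position within
   ±5 kb of a DEG's TSS is paired with the gene; Spearman ρ across all
   samples; significance by a permutation FDR that permutes the sample
   correspondence between the two modalities with one shared permutation
   per iteration (exhaustive enumeration when n! is small); pairs with
   ρ < 0 are *canonical* (methylation consistent with repression), ρ > 0
   *non-canonical*.
5. **Cross-species concordance** — gene-level results from two datasets are
   intersected through a 1:1 ortholog map and the signs of representative
   correlations compared.

All of it runs on synthetic paired data from the built-in generator
(`simulate_experiment()`), which plants known fold changes, logit-scale
methylation shifts, rescue structure and coupled gene–probe pairs, and
returns the ground truth alongside the data — so sensitivity, sign
concordance, FDR control and label recovery are measurable.

## Worked example

```r
library(methlink)
library(dplyr)

cfg <- synth_config(n_genes = 300, background_probes = 500)
sim <- simulate_experiment(cfg, seed = 42)

de <- test_de(sim$counts, sim$design, contrast = c("WT", "KO"))
glance(de)
#>   n_tested n_excluded n_deg  n_up n_down   fdr contrast
#> 1      300          0    79    48     31  0.05 KO vs WT

beta <- sim$beta |> filter_probes(sim$manifest) |> normalize_betas(sim$manifest)
dmp <- test_dmp(beta, sim$design, contrast = c("WT", "KO"))
glance(dmp)
#>   n_tested n_dmp n_hypo n_hyper prior_df prior_var   fdr contrast
#> 1     1331   201    138      63     9.12     0.121  0.05 KO vs WT
```

79 of 300 genes are differentially expressed in the knockout (48 up, 31
down), and 201 of 1331 retained probes are differentially methylated, with
the hypomethylated majority (138 vs 63) reflecting the simulated global
loss of de novo methylation. Linking DMPs to DEG transcription start sites
and scoring pairs:

```r
expr <- normalize_counts(sim$counts)

pairs <- link_dmps_to_genes(filter(dmp, is_dmp),
                            filter(sim$annotation, gene_id %in% filter(de, is_deg)$gene_id),
                            sim$manifest, window = 5000) |>
  correlate_pairs(expr, beta) |>
  permutation_fdr(expr, beta, n_perm = 1000, seed = 42) |>
  classify_pairs(fdr = 0.05)
glance(pairs)
#>   n_pairs n_sig_pairs n_genes_linked n_genes_canonical n_genes_non_canonical
#> 1     102          88             40                25                    13

head(summarize_gene_labels(pairs), 3)
#>   gene_id n_pairs n_sig_pairs canonical non_canonical rep_probe_id rep_rho
#> 1 g0002         3           3 TRUE      FALSE         cg0000006     -0.882
#> 2 g0008         2           2 TRUE      FALSE         cg0000024     -0.665
#> 3 g0017         3           3 FALSE     TRUE          cg0000050      0.635
```

Of 40 DEGs with at least one cis-linked DMP, 25 carry a canonical
(negative-correlation) label and 13 a non-canonical one — close to the
planted 30% / 20% coupling fractions. `autoplot()` methods and
`plot_volcano()`, `plot_pairs()`, `plot_rescue_summary()`,
`plot_concordance()` give the standard graphical views; `tidy()` and
`glance()` return per-feature and one-row summaries of every result type.

The whole chain — including the second-species dataset, rescue tables and
the cross-species concordance report — runs from one configuration via
`run_pipeline(pipeline_config(...), dir)` or the CLI in `exec/methlink`
(`simulate`, `de`, `dmp`, `rescue`, `integrate`, `xspecies`, `run-all`).
Outputs are plain TSV/CSV/GTF/BED plus a JSON run manifest with content
hashes; identical configuration and seed reproduce byte-identical files.

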