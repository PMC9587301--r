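---
title: "Models and methods behind methlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methlink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methlink)
```

`methlink` analyses paired methylome/transcriptome experiments built
around a knockout-and-rescue design: a wild-type line (WT), a DNA
methyltransferase knockout (KO), and the knockout with one of two enzyme
isoforms re-expressed (R1, R2), with replicated RNA-seq counts and
methylation-array beta values for each condition. This vignette explains
the statistical models, the choices made where several defensible options
existed, and what the synthetic benchmark does and does not demonstrate.

## Differential expression

Counts are normalized by median-of-ratios size factors,
$s_j = \exp\{\mathrm{median}_g(\log c_{gj} - \log \mathrm{gm}_g)\}$, where
$\mathrm{gm}_g$ is the gene's geometric mean across samples and only
genes with all-positive counts enter the median. The median is taken on
the log scale; for an odd number of usable genes this is the plain median
of ratios, and it agrees exactly with the widely used reference
implementation. Note that the factors are only *relatively* identified:
multiplying one sample by $c$ multiplies its factor by $c^{1-1/n}$ and
every other factor by $c^{1/n}$ (their ratio by exactly $c$), because the
scaled sample also inflates every geometric mean.

Per gene, the two-group contrast is tested on normalized counts with a
negative-binomial Wald statistic. The dispersion is a method-of-moments
estimate from the pooled within-group variance,
$\hat\alpha = \max\{(s^2-\bar m)/\bar m^2,\,10^{-8}\}$; the fold change is
$\log_2\{(\bar m_b + 0.5)/(\bar m_a + 0.5)\}$ (the pseudocount avoids
$\log 0$ for group means near zero); and the standard error follows from
$\mathrm{Var}(Y) = \mu + \alpha\mu^2$ by the delta method. The two-sided
p-value uses a $t$ reference with $n_a + n_b - 2$ degrees of freedom
rather than the standard normal: with an estimated dispersion at four
replicates per group the Wald ratio behaves like a $t$ statistic, and the
normal reference would roughly double the nominal type-I error (we
measured ~9% at $n = 4$ vs 4, against ~4–5% for the $t$ reference). This
is a deliberately simplified fit — no dispersion shrinkage across genes,
no independent filtering, no outlier handling — so its outputs are
calibrated against its own type-I error and parameter recovery, not
against numerical equality with heavier machinery. No fold-change cutoff
is applied: a DEG is any gene with Benjamini–Hochberg adjusted p below
0.05, the stated discovery rule.

## Differential methylation

Probes are removed when they overlap a SNP, interrogate a non-CpG
context, lie on a sex chromosome, or contain any missing beta value; the
removal report counts each reason and the overlap-free union, and the
whole-probe removal policy avoids per-test imputation. Beta values are
then quantile-normalized between samples separately within the Infinium
type-I and type-II strata. This beta-level normalization stands in for
intensity-level normalization (dasen), which operates on raw
methylated/unmethylated channel intensities this pipeline never sees; it
is a deliberate substitution, not an emulation. Its known cost is that a
genuinely global methylation difference between conditions is partially
absorbed into the normalization map — the benchmark keeps the
differentially methylated fraction of probes near the ~10% seen on real
arrays, where the attenuation is mild.

Testing happens on M-values, $M = \log_2\{(\beta+\varepsilon)/(1-\beta+
\varepsilon)\}$ with $\varepsilon = 0.01$ guarding the boundaries, using
a moderated two-group $t$: the prior $(d_0, s_0^2)$ is fitted by method
of moments on $\log s_g^2$, matching the mean and variance of the log-F
distribution implied by the hierarchical model, with the trigamma
inversion solved by Newton iteration. When the observed log-variance
spread falls below the pure chi-square baseline the prior degrees of
freedom are infinite and the prior variance collapses to the mean sample
variance; the total degrees of freedom are capped at the pooled residual
degrees of freedom since the prior itself is estimated. A test
cross-checks the whole fit against the reference empirical-Bayes
implementation to machine precision, and setting `prior_df = 0` recovers
the ordinary per-probe $t$-test exactly.

Differentially methylated regions replace an adaptive rank-cutoff
procedure with an explicit, reproducible rule: promoters are
$[\mathrm{TSS}-1500, \mathrm{TSS}+500]$ oriented by strand (a common
promoter convention; the source analysis defines none), gene bodies are
the annotated interval, membership is by position containment, and
regions with at least two member probes are scored by a direction-signed
Stouffer statistic $z = \sum_i \mathrm{sign}(\Delta\beta_i)\,z_i /
\sqrt{k}$ with $z_i$ the normal quantile of the one-sided p-value, BH
adjustment within region kind.

## Rescue classification

"Rescue" is not operationally defined in the source material, so both
plausible definitions are implemented. The default calls a
knockout-dysregulated feature rescued by an isoform when it is (a) no
longer significant versus WT **and** (b) significantly changed versus KO
in the direction opposite the knockout effect. The reversal clause (b)
guards against calling low-power features rescued merely because their
vs-WT test lacks evidence; `require_reversal = FALSE` gives the
permissive loss-of-significance definition, and the strict rescued set is
provably a subset of the permissive one. One threshold (0.05) applies to
all five contrasts by default. On knockout DMPs the two definitions
bracket the planted truth from opposite sides: the strict rule loses a
few true rescues to reversal power, the permissive rule gains false ones
from null probes that were never truly dysregulated.

## Cis integration and the permutation FDR

Significant DMPs are paired with differentially expressed genes whose TSS
lies within a closed, symmetric ±5 kb window (the stated window;
"upstream and downstream" implies no asymmetry), with the reported
distance strand-oriented. Each pair is scored by Spearman's rank
correlation across **all** samples of all conditions — the correlation is
driven jointly by condition structure and within-condition covariation —
with average ranks for ties and an asymptotic $t$ p-value reported for
reference only.

Significance comes from a permutation scheme: each iteration applies one
shared random permutation to the methylation sample columns, breaking the
expression–methylation correspondence while preserving all cross-probe
and cross-gene structure (independent per-pair shuffles, offered as an
alternative, would overstate the effective null sample). The per-pair
empirical p-value is $(1 + \#\{|\rho^0| \ge |\rho|\})/(B+1)$ — never
exactly zero in sampled mode — and the q-value is the plug-in estimator
$q(t) = \min\{1, \overline{V}(t)/\max(R(t),1)\}$, where $\overline V(t)$
is the mean number of null exceedances per permutation pooled over pairs
and $R(t)$ the observed count, made monotone non-increasing in $|\rho|$.
When $n!$ is at most `exhaustive_cap` (720 by default, i.e. up to six
samples) all permutations are enumerated and the $+1$ correction is
dropped; an independent brute-force oracle reproduces both p and q
exactly on the exhaustive fixture. Pairs significant with $\rho < 0$ are
*canonical* (methylation consistent with repression), with $\rho > 0$
*non-canonical*; a gene carries every label among its pairs, so a gene
can be both, and the representative correlation for cross-dataset
comparison is the significant pair with the largest $|\rho|$ (ties:
smaller q, then lexicographic probe id — fully deterministic).

## Cross-species intersection

Gene-level summaries from two datasets are joined through an explicit 1:1
ortholog map (the map is always an input; no orthology is inferred).
Shared genes are those significant in both datasets; concordance is the
agreement of representative correlation signs. Swapping the dataset roles
transposes the report without changing the counts.

## The synthetic benchmark

The generator emulates the study conditions: four conditions with four
replicates (or a two-group in vivo design), negative-binomial counts with
per-gene baselines (20–2000 expected counts) and dispersions
(0.005–0.05, the low biological variability of clonal cell lines),
per-sample library-size factors, and logit-normal beta values around a
bimodal baseline (Beta-mixture modes near 0.1 and 0.9, concentration 10)
with replicate noise of 0.3 on the logit scale — within-condition
variances are unreported for either platform, so these noise magnitudes
are realistic choices, not calibrations to the deposited data.

Planted structure: 30% of genes are differentially expressed at
$|\log_2\mathrm{FC}| = 1$, each with a rescue status (60% both, 15% per
single isoform, 10% none) that determines which conditions revert to the
wild-type mean. Global knockout hypomethylation lives on a background
(intergenic) probe compartment: 20% of background probes are affected,
of which 70% shift down and 5% up by 1.5 logits (a beta change of roughly
0.2 at intermediate baselines), each with its own rescue status (85%
revert in at least one isoform — the structural template for the rescued
fraction). Methylation–expression coupling marks 30%/20% of DE genes as
canonical/non-canonical: their TSS-adjacent probes (three per gene within
±4 kb) receive the condition shift with sign opposite/equal to the gene's
fold change, plus a shared per-sample latent variable loading 0.1 log2
units on expression and 0.3 logits on methylation. Two generator choices
deserve emphasis:

* Probes near *non-coupled* DE genes receive no condition shift. A
  condition-driven methylation shift next to any DE gene would correlate
  with expression through the shared condition structure alone, making
  "uncoupled" genes indistinguishable from coupled ones and destroying
  the planted label fractions; keeping the global effect on intergenic
  probes keeps the cis-window content controlled by the coupling plan.
* The latent loadings are small relative to replicate noise. Across the
  16 samples most of the pair correlation is carried by the aligned
  condition patterns; the latent adds genuine within-condition
  covariation without inflating the per-gene variance enough to mask the
  planted fold changes from the Wald test.

Sampling is deterministic given `(config, seed)`, with fixed sub-stream
offsets per stage so that enlarging one component does not reshuffle the
draws of another. A twin-dataset mode reuses the planted DE/coupling
assignments through an ortholog map, giving cross-species concordance a
known truth.

What passing the benchmark does **not** show: the generator has no batch
or covariate structure, no probe cross-reactivity beyond boolean flags,
no intensity-level artefacts (the dasen substitution is untested against
real channel data), no count outliers, and independent noise across
probes apart from the planted coupling — real arrays and libraries
violate all of these. Recovery rates measured here are upper bounds for
data of equal effect size.

## Numerical and operational choices

* Problem sizes: the test suite and the acceptance script use 300–2000
  features and 500–1000 permutations — large enough for stable
  Monte-Carlo bands (type-I error within [0.03, 0.07] at 2000 features),
  small enough to run interactively.
* Degenerate inputs: pairs with zero rank variance are dropped with one
  summary warning; normalization strata with fewer than two probes pass
  through unchanged with a warning; genes with all-zero counts in both
  contrast groups are excluded and listed; empty coupling or empty
  ortholog maps are valid and yield empty results.
* Tie-breaks are deterministic everywhere (quantile-normalization ranks
  use first-occurrence ties, which preserves within-sample order;
  representative pairs break ties by q then probe id).
* The pipeline writes every stage output once, hashes file contents into
  a JSON run manifest together with the master seed and each derived
  stage seed, and reproduces byte-identical files for identical
  configuration and seed.
* Headline counts from the motivating experimental system (thousands of
  rescued features, hundreds of correlated genes) depend on the deposited
  datasets and are not reproduction targets at simulation scale; the
  package reproduces the *procedures* and validates them by parameter
  recovery.
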