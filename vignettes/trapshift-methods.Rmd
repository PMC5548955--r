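---
title: "Models and methods behind trapshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind trapshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experimental design the package models

trapshift analyses cell-type-specific translatome profiling (TRAP-seq)
experiments with a paired case/control design.  Each littermate pair
contributes one knockout (KO) and one wild-type (WT) animal; from each
animal two RNA-seq libraries are made, the immunoprecipitated
ribosome-bound fraction (IP) and the total starting RNA (Input).  With
six pairs the default design has 24 libraries.  Comparing KO and WT
within the IP fraction reads out differential *translation*; the same
comparison in the Input fraction reads out differential *transcript
abundance*.  A translation-specific effect appears in IP and not in
Input.

Three downstream questions drive the remaining modules: whether a
predefined target gene set (for instance, the mRNA targets of a
translational repressor such as FMRP) shows a coherent shift in its
fold-change distribution; whether the differentially expressed genes
are functionally similar to those targets, measured by Pfam-clan
enrichment; and whether a behavioural phenotype (audiogenic seizure
incidence) differs between groups, measured by exact 2x2 statistics.

## Differential expression model

Counts for gene $g$ in sample $j$ are modelled as negative binomial,

$$ K_{gj} \sim \mathrm{NB}(\mu_{gj},\ \alpha_g), \qquad
   \mathrm{Var}(K_{gj}) = \mu_{gj} + \alpha_g \mu_{gj}^2, $$

with $\log \mu_{gj} = \log s_j + x_j^\top \beta_g$.  Size factors $s_j$
come from the median-of-ratios method (per-gene geometric means over
genes positive in every sample; no pseudocounts).  The default design
matrix is `~ pair + genotype`: littermate blocking absorbs pair-level
variation and the genotype coefficient, reported in log2, is the KO/WT
fold change.  An unpaired design is available by argument.  IP and
Input fractions are analysed separately; no interaction model is fitted.

GLMs are fitted per gene by iteratively reweighted least squares with
the log size-factor offset, convergence declared when the deviance
change falls below `1e-8` (relative), capped at 50 iterations;
non-converged genes are flagged untested.  Standard errors come from
the inverse expected Fisher information $X^\top W X$ with
$W = \mu/(1 + \alpha\mu)$.

### Dispersion estimation

Dispersion is the critical nuisance parameter at $n = 12$ samples and
$p = 7$ coefficients (5 residual df).  The package uses a two-pass
scheme:

1. **Moment pass.** For normalized counts $q_{gj} = K_{gj}/s_j$, the
   residual variance of an OLS fit of the design gives
   $\hat\alpha^{\mathrm{mom}}_g = \max\{(\widehat{\mathrm{var}}_g -
   \bar q_g)/\bar q_g^2,\ 10^{-8}\}$.  A mean-dispersion trend
   $\alpha_{\mathrm{tr}}(\mu) = a_1/\mu + a_0$ is fitted by iteratively
   trimmed least squares (genes with estimate/trend ratio outside
   $[10^{-2}, 15]$ trimmed each round).
2. **Likelihood pass.** With fitted means from a preliminary GLM run,
   each gene's Cox-Reid adjusted profile log-likelihood in
   $\ln\alpha$ is maximized (the CR term
   $-\tfrac12 \log\det X^\top W X$ corrects for the residual degrees of
   freedom absorbed by the mean fit).  The trend is refitted on these
   likelihood estimates, and the final dispersion maximizes the CR
   likelihood plus a log-normal prior with sd 0.5 centred on the trend.
   Genes whose likelihood estimate exceeds 10x the trend keep it
   unshrunk (dispersion outliers are never shrunk down).

A simpler alternative — geometrically interpolating the moment
estimate and the trend at a fixed weight — was evaluated and rejected:
moment estimates of $\ln\alpha$ at few residual df are very noisy, and
fixed-weight interpolation leaves a heavy lower tail of underestimated
dispersions that surfaces as spurious BH-significant genes under the
global null.  The likelihood-based pass removes that tail; the shipped
null-calibration check (twenty 15,000-gene global-null replicates,
`test-acceptance.R`) verifies the resulting control.

### The Wald reference distribution

With the dispersion *known*, the Wald statistic
$\hat\beta_g/\widehat{\mathrm{se}}_g$ referred to the standard normal
is well calibrated, but with *estimated* dispersions the plug-in
inflates the far tail of the null distribution — exactly the tail that
determines how often a 15,000-gene screen produces spurious
BH-significant genes.  The package therefore refers the statistic to a
t distribution whose degrees of freedom add the dispersion prior's
effective information to the residual degrees of freedom,

$$ \nu \;=\; (n - p) \;+\; 2\,\psi_1^{-1}(\sigma^2_{\mathrm{prior}}), $$

with $\psi_1^{-1}$ the inverse trigamma ($\nu \approx 14$ for the
default design), the same moderated-test device used by the
quasi-likelihood and moderated-t frameworks in this field.  The
shipped checks quantify the trade: the twenty-replicate null
calibration passes with a median of zero discoveries, and sensitivity
for the planted twofold effects stays far above the 80% the recovery
check requires.  `wald_dist = "normal"` restores the plain normal
reference.

Benjamini–Hochberg adjustment is applied per fraction over the tested
genes; the default significance rule is `padj < 0.1`.  Genes with all
zero counts or mean normalized count below 0.5 are not tested.  There
is no independent filtering, no count-outlier replacement and no
fold-change shrinkage: the stage is kept auditable, and fold changes
are reported unshrunk.

## Target-set shift test

Expression level confounds fold-change comparisons, so the target set
is compared only against genes of similar abundance: the closed window
$10^{lo} \le \mathrm{baseMean} \le 10^{hi}$, by default
$(2.5, 4.25)$ for the Input fraction and $(2.75, 4.75)$ for IP.
"Between" is read as inclusive; the boundary choice is documented
because it is ambiguous in prose descriptions of such windows.

Within the window, the log2 fold-change distributions of target genes
versus **all** window genes (targets included — the comparison is
against the total population; a targets-excluded background is a flag
away) are compared with the two-sample Kolmogorov–Smirnov test.  The
statistic is the supremum of the ECDF difference over pooled points,
with ties handled by evaluating after each tie group.  The p value
uses the asymptotic Kolmogorov distribution at
$\lambda = \sqrt{n_e}\,D$, $n_e = nm/(n+m)$.  We evaluated the
one-sample finite-sample multiplier
$(\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})$ sometimes carried over to the
two-sample case and rejected it: at moderate sample sizes it sits
systematically below the exact permutation p value, while the plain
$\lambda$ stays within the 10%-of-permutation agreement the shipped
check (`test-acceptance.R`) verifies at $n = m = 50$.  Below $\lambda = 0.2$
the alternating series is truncated to $p = 1$ (the survival function
is 1 to machine precision there).

Two companions calibrate and complement the K-S comparison: `k` random
gene sets of the target's size drawn without replacement from the
window (default 5, seeded, reproducible), each tested the same way;
and a Fisher exact test comparing up/down-regulation proportions
between targets and non-targets.

Whether random sets should be drawn from the abundance window or from
all expressed genes is a genuinely open choice; the window is the
default here because it preserves the abundance matching that
motivates the analysis.

## Clan enrichment

The background is every gene with TPM > 0 in at least one sample; the
target list is additionally restricted to genes with TPM > 0 in at
least one IP library (detected in the translating fraction).  For each
Pfam clan represented in a gene list, a 2x2 table of clan membership
versus list membership over the background is tested two-sided with
the package's Fisher engine; a clan is called enriched when `p < 0.01`
and its proportion in the list exceeds its background proportion.
Genes without any clan annotation stay in the table — the background
is gene-based, not annotation-based — and a gene in several clans
counts once in each clan's table.  No multiplicity correction is
applied by default (the fixed `p < 0.01` rule is the convention being
reproduced); BH adjustment is available behind a flag.  Enriched-clan
lists from two analyses are intersected into an "x out of y" overlap
report.

## Exact 2x2 statistics

`fisher_exact` conditions on the margins and sums hypergeometric
probabilities of all tables no more probable than the observed one
(probability-mass two-sided rule, with a $1 + 10^{-7}$ factor guarding
floating-point ties), computing terms through log-gamma.  Seizure
incidence percentages are rounded to the nearest integer, half away
from zero, and severity tables follow the maximal-stage convention:
each animal contributes only the most severe stage reached (wild
running < clonic < tonic), so stage counts partition the seizing
animals.

## The synthetic data generator

`simulate_trap()` draws counts with exactly the structure the DE model
assumes:

$$ \mu_{gj} = b_g \cdot s_j \cdot a_{(j)} \cdot e_g^{[\mathrm{IP}]}
   \cdot 2^{\beta_{g,\mathrm{frac}}[\mathrm{KO}]}, \qquad
   K_{gj} \sim \mathrm{NB}(\mu_{gj}, \alpha_g), $$

with log-normal baselines $b_g$ (meanlog $\log 60$, sdlog 1.8),
library size factors $s_j$ (sdlog 0.15), per-animal littermate
multipliers $a_{(j)}$ shared between an animal's Input and IP
libraries (sdlog 0.05), per-gene IP enrichment $e_g$ (sdlog 0.5,
median 1) and dispersions on the trend $2/\mu + 0.01$ with log-normal
gene noise (sdlog 0.25) — plausible bulk RNA-seq values; the study the
design mirrors does not report library sizes or dispersions, so these
are generic, not estimates of any deposited dataset.

The planted signal mirrors the biology being emulated: 90 upregulated
and 31 downregulated genes (together 121) with |log2 fold change| near
1, applied in the IP fraction only (translation-specific); an 800-gene
target set with a subtle −0.2 log2 shift applied in *both* fractions,
because the corresponding shift is observed in Input and IP alike; and
40 clans of which 2 recruit extra upregulated genes.  Planted DE genes
are drawn from baselines in the $10^2$–$10^4$ decade and targets from
$10^{2.3}$–$10^{4.2}$: detected differential genes and target mRNAs
live in the quantifiable abundance range (the analysis windows
themselves span $10^{2.5}$–$10^{4.75}$), and planting signal on genes
with a handful of counts would test the generator's tails rather than
the pipeline.  All randomness flows from one seed; per-component
sub-seeds are derived with `derive_seed()` so stages can be re-run in
isolation.

What the generator does *not* emulate: GC and length biases,
batch effects beyond littermate blocking, read-level noise,
transcript-isoform structure, and correlated gene modules.  Passing
recovery tests on these simulations therefore demonstrates that the
statistical machinery is correct under its own assumptions, not that
those assumptions hold in any particular real dataset.

## Numerical choices and degenerate inputs

* Size factors require at least one gene positive in every sample; no
  pseudocount fallback is applied (the strict convention).
* TPM columns with all-zero counts return zero with a warning; genes
  missing a length are an error naming the gene.
* Heatmap normalization drops genes with zero WT mean or zero variance,
  with warnings, and z-scores rows.
* The GLM clamps means to $[10^{-10}, 10^{12}]$ and coefficient steps
  to $\pm 10$ per iteration; singular per-gene systems flag the gene
  untested.
* BH propagates `NA` p values and excludes them from the test count.
* Incidence requires a non-zero group size; severity validation
  rejects duplicate animals and unknown stages.

## Problem sizes used in the shipped checks

The packaged tests exercise the full default design (15,000 genes, six
pairs) for the recovery and enrichment checks, twenty 15,000-gene
global-null replicates for FDR calibration, a 12,000-gene window with
an 800-gene target set for shift power, 200 random sets for shift
type-I error, exhaustive 2x2 tables with margins up to 12 for the
Fisher engine, and 1,000 random instances for the K-S statistic and BH
step-up equivalences.  Smaller gene counts (a few thousand) are used
where a property does not depend on scale.

## Known limitations

* The DE stage is a re-implementation in the spirit of the established
  negative-binomial tools, not a numerical clone: no Cook's-distance
  outlier handling, no independent filtering, no LFC shrinkage, and a
  moderated-t rather than normal Wald reference.  Gene lists from real
  data will differ in detail from those tools' output.
* TPM is computed at gene level from supplied effective lengths;
  transcript-level abundance estimation is out of scope.
* The Fisher engine covers 2x2 tables only (no mid-p, no conditional
  MLE odds ratio).
* The asymptotic K-S p is accurate for moderate sample sizes but is
  not an exact small-sample p; the random-set null provides a
  design-matched calibration where that matters.
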