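---
title: "Methods: translational-control analysis with riboTE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: translational-control analysis with riboTE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboTE)
```

## The model

riboTE analyzes a paired design: each condition is profiled by RNA-seq
(mRNA abundance) and Ribo-seq (ribosome-footprint abundance), with
replicates. Counts for gene $g$ in sample $j$ are modeled as negative
binomial,

$$K_{gj} \sim \mathrm{NB}(\mu_{gj},\ \alpha_g), \qquad
\mathrm{Var}(K_{gj}) = \mu_{gj} + \alpha_g \mu_{gj}^2,$$

with $\mu_{gj} = s_j\, q_{g,\mathrm{cell}(j)}$, where $s_j$ is a
median-of-ratios size factor (rescaled to geometric mean 1) and
$q_{g,\mathrm{cell}}$ is the expected normalized abundance of the gene in
the sample's assay × condition cell. $\alpha = 0$ is the Poisson limit.

Three contrasts are tested between two conditions $A$ (reference) and $B$:

* mRNA shift: $\log_2 q_{\mathrm{rna},B} - \log_2 q_{\mathrm{rna},A}$;
* footprint shift: the same for the ribo cells;
* TE shift: the assay × condition interaction,
  $\Delta\log_2 \mathrm{TE} = \Delta\log_2 q_\mathrm{ribo} -
  \Delta\log_2 q_\mathrm{rna}$.

Both two-group designs and the 2×2 interaction design are *saturated*: the
maximum-likelihood cell abundances are the arithmetic means of the
normalized counts, for any dispersion (this is the fixed point of the
`nb_irls()` fitter, which is exported for general designs with its 100
iteration / 1e-8 coefficient-change defaults). Contrast point estimates are
therefore log ratios of cell means, and `test_te_shift` is exactly
consistent with the difference of two `test_assay_shift` runs.

Translation efficiency itself is reported per condition as

$$\mathrm{TE}_{g,c} = \frac{\bar n^{\mathrm{ribo}}_{g,c} + p}
                           {\bar n^{\mathrm{rna}}_{g,c} + p},$$

mean normalized counts with pseudocount $p = 0.5$ (configurable), keeping
TE finite and positive when a cell has zero counts. Genes with
$\mathrm{TE} > 3$ or $\mathrm{TE} < 0.33$ are flagged as extreme.

## The Wald variance, and why it is scale-free

The natural NB Wald variance of a log cell mean, $(1 + \alpha m)/(n\,m)$,
contains a shot-noise term $1/m$ whose value depends on the *count scale*
of the normalized data. That scale is not invariant to rescaling a single
sample's counts: under median-of-ratios normalization with the
geometric-mean-1 convention, multiplying one of $n$ samples by $c$
multiplies every normalized count by exactly $c^{1/n}$. Any variance
estimate that uses the shot-noise term therefore drifts (at the $10^{-3}$
level in p-values for a tenfold rescale) even though the data are the same
up to depth.

We want the stronger contract — depth changes of any single library change
no fold change, p-value or category — so the default Wald variance is built
from scale-free quantities only: the per-gene **total squared coefficient
of variation** $\hat\phi_g$, pooled across all assay × condition cells
(shared dispersion across assays and conditions, which keeps the 2-replicate
design identifiable), with

$$\mathrm{Var}(\widehat{\log \text{contrast}}) =
  \tilde\phi_g \sum_{\text{cells in contrast}} w^2_{\text{cell}} /
  n_{\text{cell}},$$

where $w$ are the ±1 contrast weights. $\hat\phi$ absorbs both shot noise
and overdispersion empirically ($E[\hat\phi] \approx 1/m + \alpha$), so no
explicit $1/m$ term is needed. Because squared CVs, the residual degrees of
freedom, and log-mean *differences* are all unchanged when every normalized
count is multiplied by a constant — and the moderation trend below is fit
on log means, where a global rescale is a horizontal shift that lowess
treats equivariantly — the whole inference is exactly invariant (the test
suite checks ≤ 1e-6; observed drift is ~1e-14, pure floating point).

With 6 residual df in the default 12-library design, raw per-gene CVs are
noisy, so $\hat\phi$ is moderated toward a lowess trend on the gene's mean
normalized count:

$$\tilde\phi_g = \frac{d\,\hat\phi_g + d_0\,\phi_0(\bar n_g)}{d + d_0},$$

with prior weight $d_0 = 4$ (chosen once: roughly doubling the information
of the 6-df design, in line with standard small-replicate moderation
practice). The Wald statistic is referred to a $t$ distribution with
$d + d_0$ degrees of freedom. The classic NB information variance remains
available via `variance = "nb"` together with `estimate_dispersion()`, the
method-of-moments estimator
$\hat\alpha = \max\{0, (s^2 - \bar\mu)/\bar\mu^2\}$ pooled over
within-group residuals (optionally shrunk toward the same kind of trend).

P-values are adjusted by Benjamini–Hochberg over tested genes only; genes
with a zero mean in any contrast cell are flagged `tested = FALSE` and
excluded from the FDR computation.

## Classification

With thresholds $|\log_2\mathrm{FC}| > 1$ and $\mathrm{FDR} < 0.01$
(strict inequalities, both configurable and applied uniformly to all three
contrasts), `classify_genes()` applies the decision tree:

1. TE significantly up: `translationally_induced` if footprints are also
   significantly up, else `rna_down_te_up` (buffering);
2. TE significantly down: `translationally_repressed` if footprints are
   significantly down, else `rna_up_te_down` (buffering);
3. TE not significant: `up_te_constant` / `down_te_constant` when both
   assays move significantly in the same direction, else `unregulated`.

Design choices made where the taxonomy is genuinely open:

* the buffering classes are keyed on TE significance plus footprint
  *non*-significance only; the mRNA direction is recorded in the output for
  audit but not required, matching the class descriptions at face value;
* a gene with significant mRNA change but neither footprint nor TE
  significance is `unregulated` — the concordant classes are defined by
  agreement of both assays;
* strict inequalities resolve threshold ties mechanically (a gene exactly
  at twofold is not significant).

These rules make the seven labels exhaustive and mutually exclusive, so the
category counts always partition the background, and
`buffered + translation_driven = te_changed` holds as an identity.
Raising the FDR ceiling can only move genes out of `unregulated`, never
into it; swapping the contrast order maps each class to its mirror.

## The synthetic-data generator

`simulate_counts()` emulates the study design the analysis assumes: three
conditions (NPC, early differentiation, neuron) × two assays × two
replicates = 12 libraries. Per-gene baselines are log-uniform on
[10, 5000] counts (a realistic dynamic range for libraries of tens of
millions of reads over ~14,000 genes), NB dispersion defaults to 0.05
(typical for well-behaved bulk replicates), and planted categories follow
the composition observed in neuronal differentiation at study scale
(~63.5% unregulated, 15.2% concordant DE, 12.1% buffered, 9.2%
translation-driven). Effects of $|\log_2\mathrm{FC}| = 2$ are applied to
the neuron condition only; the intermediate condition stays at baseline,
mirroring the observation that early differentiation shows no TE changes.
Category counts are allocated exactly by largest remainder (deterministic
tie-break by category order) and then shuffled under the seed, so recovery
tests know the exact composition.

What the generator does *not* emulate: GC/length biases, correlated
dispersion structure, batch effects, isoform-level ambiguity, or any
sequence-level biology (codons, uORFs, UTRs). Passing recovery tests on
this generator demonstrates the statistical machinery under the stated
noise model, not robustness to those real-data artifacts.

`simulate_fastq()` plants 5′ homopolymer runs (poly-C/poly-T, lengths 3–8)
on footprint-length inserts (26–34 nt) and records the clean insert in the
FASTQ comment. Reads whose insert itself starts with a qualifying
artifact-base run (or whose first base equals the planted artifact base)
are flagged non-recoverable: for them, trimming is ambiguous *by
construction*, which is also exactly the set on which a second trim pass
could differ from the first. `simulate_gene_lists()` draws weighted
samples without replacement, oversampling one category by a chosen factor.

## Trimming and filtering

`trim_artifacts()` removes at most one maximal homopolymer run of a single
artifact base (default bases C and T, 5′ end, minimum run 3) together with
its quality values, then flags reads shorter than 20 nt. The protocol
motivating it adds non-templated bases at one cDNA end; run length, end and
base set are configurable because protocol dialects differ, and whether 3′
runs should also be trimmed is protocol-dependent (default: 5′ only).
Reads with non-ACGTN characters pass through untrimmed with a warning.

`filter_background()` implements the expression background: count ≥ 1 in
*every* library (both assays, all conditions) on raw, pre-normalization
counts. The background is the denominator of every downstream test and
enrichment.

## Enrichment

`fisher_overlap()` intersects each gene list with the background before
tabulation and computes the one-sided enrichment p-value as the upper
hypergeometric tail $P(\mathrm{overlap} \ge a)$ — identical to Fisher's
exact test with `alternative = "greater"`; one-sided is the default because
the analysis asks for enrichment (two-sided is available). The odds ratio
uses a 0.5 continuity correction only when a zero cell occurs, and the row
is annotated when it does. Gene identifiers are matched as exact strings;
mapping between identifier systems is the caller's responsibility.

## Numerical and degenerate-input policy

* Size factors require at least one gene expressed in all samples; the
  error suggests filtering first.
* Dispersion estimation requires a replicated group; constant genes clamp
  at $\hat\alpha = 0$.
* All-zero (or zero-cell) genes are untested and unclassifiable; they are
  reported, not silently dropped.
* Empty gene sets or categories yield `testable = FALSE` enrichment rows
  with missing p.
* Pipeline errors carry the failing stage name in a classed condition
  (`riboTE_error`), and configuration is validated before any computation.
* All randomness flows through explicit seeds; generators restore the
  caller's RNG state.

## Problem sizes used by the test suite

The suite simulates at desk scale, chosen to finish in well under a minute
while leaving Monte-Carlo margins comfortably wide: 2,000-gene experiments
for the FDR-control (20 seeds) and category-recovery checks, 800 genes for
the invariance check, 10,000 reads for the trimming round trip, and an
exhaustive enumeration of all 2×2 tables with background ≤ 60 for the
Fisher oracle. The acceptance script additionally fits one study-scale
(14,159-gene) experiment.

## Known limitations

* The TE test assumes a shared per-gene variability across assays and
  conditions; strongly assay-specific dispersion would be diluted.
* No fold-change shrinkage, outlier replacement or independent-filtering
  optimization is performed.
* The quasi (total-CV) variance trades a little efficiency at very low
  counts for exact depth invariance; with many replicates the `"nb"` mode
  is slightly more powerful.
* Enrichment treats gene lists as flat sets; no ontology structure is
  used.
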