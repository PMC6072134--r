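---
title: "Methods: models and design choices in wormassays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices in wormassays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormassays)
```

# Scope

`wormassays` packages the five quantitative arms of an epidermal
innate-immunity study in *Caenorhabditis elegans*: calling specific bait
interactors from label-free quantification (LFQ) pull-down tables,
quantifying candidate-list overlap, delta-delta-Ct analysis of qRT-PCR and
ChIP-qPCR cycling thresholds, per-worm sorter reporter quantification, and
censored-survival comparison. Each stage consumes plain tabular input,
exposes its parameters with the study's values as defaults, and has a
matching synthetic-data generator so the whole pipeline can be exercised
and calibrated without any external data.

# The bait-interactor caller

## Model

An affinity-purification mass-spectrometry (AP-MS) experiment compares
`n_bait` anti-GFP pull-downs against `n_control` blocked-resin pull-downs
(here 3 vs 3). The upstream quantification suite reports one LFQ intensity
per protein group and sample, with 0 meaning "not quantified". The caller
proceeds:

1. **Decoy/contaminant removal.** Rows flagged `Reverse` or
   `Potential contaminant` are dropped first. The order relative to the
   replicate filter is a free choice; removing them at the start keeps all
   later stages blind to artefact rows and cannot change which genuine
   proteins survive the filter.
2. **Replicate filter.** Only proteins quantified in at least `min_valid`
   bait replicates are kept (default 2 of 3; `min_valid` may equal the bait
   count, as in a 2-of-2 design). Control presence is deliberately not a
   criterion: a protein seen only in bait pull-downs is the most
   interesting case, not a defect.
3. **Log2 transform**, guarded by a scale tag so it cannot be applied
   twice.
4. **Down-shifted imputation.** Missingness in LFQ data is
   missing-not-at-random: low-abundance proteins fall below the detection
   limit. Each sample column with observed mean $\mu$ and standard
   deviation $\sigma$ has its missing cells replaced by draws from
   $\mathcal{N}(\mu - \mathrm{shift}\cdot\sigma,\;
   (\mathrm{width}\cdot\sigma)^2)$ with width 0.3 and shift 1.8 —
   simulated low-intensity values below the noise floor. Imputation is per
   pull-down replicate, never matrix-wide, because detection limits differ
   between runs. Each column draws from a stream derived from
   `(seed, column index)`, so reordering columns never silently changes
   another column's draws. Within a column the draws are positional, so
   protein order is part of the imputation's reproducibility contract (the
   deterministic stages — filtering, transform, flagging — are fully
   permutation-equivariant).
5. **Statistic.** Per protein, an equal-variance two-sample t on the
   imputed log2 values gives the mean difference $\Delta$ (bait minus
   control), its pooled standard error $se$, $t = \Delta/se$ and a
   two-sided p with $n_a + n_b - 2$ degrees of freedom. The SAM-style
   modified statistic is
   $$d = \frac{\Delta}{se + s_0},$$
   with fudge factor $s_0 = 1.5$: adding a constant to the denominator
   spread damps proteins whose tiny variance would otherwise make trivial
   differences look decisive. At $s_0 = 0$, $d$ reduces to $t$ exactly.
6. **Combined threshold.** A protein is called when $d \ge t_0$ (default
   $t_0 = 1.2$; the methods-accepted range 0.9–1.5 is available through
   the parameter). In volcano coordinates $(\Delta, -\log_{10} p)$ this
   decision traces a hyperbola: for $\Delta > t_0 s_0$ the critical spread
   is $s^* = \Delta/t_0 - s_0$ and the critical p the two-sided t tail at
   $\Delta/s^*$; no protein with $\Delta \le t_0 s_0 = 1.8$ can be called
   at any p. `significance_curve()` emits the curve for plotting, and the
   tests verify the curve decision is exactly the $d \ge t_0$ decision.
7. **Sidedness.** Calling is one-sided for enrichment ($\Delta > 0$) by
   default, because an interactor screen calls co-purifying partners;
   both-sided calling is available for the symmetric curve.
8. **Blacklist.** Proteins cross-reactive with the affinity resin
   (identified in a pull-down from a strain lacking the tagged bait) are
   flagged and can never be significant, whatever their $d$.

The caller uses $d \ge t_0$ alone, with no additional raw-p cutoff: the
threshold already combines effect size and precision, and a second cut
would make the published parameter values impossible to interpret on
their own.

## What the generator emulates

`gen_lfq()` draws each protein's true log2 abundance from
$\mathcal{N}(25, 2)$ (typical of LFQ log2 intensity ranges), adds the
planted bait-specific effect, per-cell noise of sd 0.5, and then masks
each cell missing with probability
$\mathrm{logistic}((\mathrm{midpoint} - \mathrm{value}) \cdot
\mathrm{slope})$ with midpoint 22.5 and slope 1 — the simplest mechanism
consistent with missingness concentrating below the detection limit.
Bait-only proteins arise naturally when a true partner's control abundance
sits below the midpoint. These four values were fixed once as realistic
study conditions and are the defaults throughout the tests.

`gen_study_pulldown_synthetic()` is a labelled synthetic stand-in for the
study-scale experiment (the deposited quantification tables are not
redistributable with the package): ~1400 protein groups, 53 true partners
with enrichments spread over 4–10 log2 units, and the six NuRD/MEC
chromatin-remodelling subunits (LIN-40, LIN-53, LET-418, HDA-1, MEP-1,
DCP-66) modelled as stoichiometric complex members — baseline abundance
one log2 unit above the background mean, 7 log2 units of enrichment — so
they are quantified in every pull-down replicate, as core complex
subunits are in practice. Passing the recovery tests on this stand-in
shows the pipeline recovers a planted truth of the study's shape; it does
not re-derive the published list from the deposited spectra.

What the generator does *not* emulate: correlated peptide-level noise,
between-replicate normalization artefacts, shared-peptide protein-group
ambiguity, and intensity-dependent variance. Calibration results on
synthetic data (sensitivity ≥ 90%, background calls ≤ 2%, null fraction
≤ 1%) are therefore statements about the statistical machinery, not about
any particular instrument.

# Candidate-list overlap

`overlap_test()` computes the exact intersection of two harmonized
identifier lists and the hypergeometric upper tail
$P[X \ge k]$ for $X \sim \mathrm{Hypergeom}(N, K, n)$ — equivalently a
one-sided Fisher exact test. The universe size $N$ is a required explicit
argument: overlap significance is meaningless without it, and defaulting
it would invite silent nonsense. Identifier harmonization (gene-name
uniformization) is an input contract, not a service of the package.

# Cycling-threshold analyses

All Ct arithmetic assumes amplification efficiency 2 (one cycle = one
doubling); no efficiency calibration is modelled because none is part of
the assay description.

- $\Delta Ct = Ct_{target} - Ct_{reference}$, each sample normalized to
  its own reference-gene (act-1) measurement.
- Fold induction $= 2^{-\Delta\Delta Ct}$ with
  $\Delta\Delta Ct = \Delta Ct_{treated} - \Delta Ct_{reference}$.
- The **ratio paired t test** is a one-sample t of $\log_2(\mathrm{fold})$
  against 0 with $n - 1$ degrees of freedom, one per independent
  experiment (technical replicates are averaged on the Ct scale at read
  time; biological replicates are never merged). The log base is
  irrelevant to $t$; base 2 matches the Ct arithmetic. The one-tailed
  default direction is "greater" (induction). Fold-scale and
  log-fold-scale summaries are both emitted, since error bars can
  reasonably live on either scale.
- **Percent input**: the input aliquot is a fraction $f$ (default 0.05) of
  the chromatin, so its Ct is adjusted by $\log_2(1/f)$ cycles before
  computing $100 \cdot 2^{Ct_{input,adj} - Ct_{sample}}$.
- **ChIP fold enrichment** is the percent-input ratio of the specific to
  the nonspecific immunoprecipitation; with a shared input it reduces to
  $2^{Ct_{nonspecific} - Ct_{chip}}$, and the common 50-fold pre-qPCR
  dilution of all three samples cancels entirely (it is kept in run
  configuration for provenance only).

# Worm-sorter quantification

Per-worm green fluorescence is normalized by size as Green/TOF;
population summaries are scaled so the control group's arithmetic mean is
exactly 1 (the convention's "ratio of 1" is read as the mean, the usual
summary for these figures). Group comparisons use the Kruskal–Wallis
omnibus and Dunn's z against the control on the pooled average ranks with
tie correction,
$$z = \frac{\bar R_i - \bar R_c}
{\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3 - t)}{12(N-1)}\right)
\left(\frac{1}{n_i} + \frac{1}{n_c}\right)}},$$
two-sided normal p, Bonferroni-adjusted over the vs-control comparisons
by default (`adjust = "none"` available). Only vs-control contrasts are
reported because that is how the assay is interpreted; the star-band
utility reproduces the usual figure conventions (ns above 0.05 down to
**** below 1e-4).

# Survival comparison

Kaplan–Meier curves and the log-rank statistic are computed through the
`survival` package; tied deaths share one risk-set update and censored
animals leave the risk set without a survival drop. The one-sided
convention: the two-sided chi-square p is halved only when the group
observed to fare worse (more deaths than expected) is the one
hypothesized a priori to fare worse, else the one-sided p is
$1 - p_{two}/2$. Times are arbitrary non-negative reals so daily counts
and ~20-minute imaging intervals both fit. Censoring policy for real data
(lost or bagged worms) is the user's; the generator censors explicitly at
the follow-up horizon.

# Numerical choices and degenerate inputs

- Zero pooled variance: $t = \pm\infty$, $p = 0$ with a warning when the
  difference is nonzero; $t = 0$, $p = 1$ when it is zero. Such rows are
  legal only in pathological synthetic cases after imputation.
- A sample column with fewer than 2 observed values has no defined
  $\sigma$ and stops imputation with an error rather than guessing.
- All-censored cohorts raise an undefined-statistic error for the
  log-rank test instead of returning a vacuous p.
- Full-precision (17 significant digits) formatting in the results writer
  makes write/read round trips exact to double precision and fixed-seed
  runs byte-identical.
- Seeds: one master seed per run; derived streams use a fixed linear map
  kept below $2^{31}$.

# Problem sizes in the tests

The test-suite simulations use the study's design points at sizes that
characterize the statistics well while keeping the suite quick: parameter
recovery on 2000 background + 50 planted proteins over 10 seeds, null
calibration over 20 seeds, study-scale recovery (1403 protein groups)
over 5 seeds, 50-seed null calibrations for the qPCR and sorter arms, and
a 200-seed uniformity check for the log-rank null. One caveat found while
calibrating: with 50 animals per group (~100 events) the one-sided
log-rank power at a doubled hazard is about 0.83 at $\alpha = 0.01$ and
0.95 at $\alpha = 0.05$ — a property of the test, not of the
implementation — and the power assertions are set accordingly.

# Known limitations

- The caller consumes protein-group tables; peptide-level inference,
  cross-run normalization and run matching are upstream and out of scope.
- No permutation-based false-discovery estimate accompanies the combined
  threshold; the published analysis thresholds, it does not report an
  FDR.
- Overlap significance requires the caller to supply a defensible
  universe; the package will not invent one.
- qPCR efficiency is fixed at 2; assays with calibrated efficiencies need
  pre-corrected Cts.
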