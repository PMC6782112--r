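---
title: "Modeling single-cell G1 length distributions and their WNT control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling single-cell G1 length distributions and their WNT control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g1dist)
```

## The problem

Human pluripotent stem cells are heterogeneous in the absolute duration of
their G1 phase, and the *distribution* of single-cell G1 lengths in a
population — not the fraction of cells in G1 — predicts how that population
will differentiate. `g1dist` implements the quantitative core of this
analysis: deriving absolute phase lengths from FUCCI time-lapse event tables,
characterizing G1 distributions and sister-cell asymmetry, and fitting a
shifted-Poisson regression that links a population's WNT activity (read out
as AXIN2 expression relative to GAPDH) to its single-cell G1 distribution.
A companion module scores per-gene 5-hydroxymethylcytosine (5-hmC) density,
the epigenetic mark proposed to couple G1 length to lineage priming.

## From FUCCI events to phase lengths

A FUCCI reporter marks mid/late G1 in red (a CDT1 fragment) and S/G2/M in
green (a GEMININ fragment); early G1 shows no color. Tracks are tables of
0-based frame indices at which each color turns on or off, at a fixed frame
interval (10 min by default). Phase lengths are defined as:

* **G1** — red-on to green-on;
* **S/G2/M** — red-off to green-off;
* **early G1** — division to red-on, reported in minutes and *not* added to
  G1 (with a fast-maturing red fluorophore it is sub-frame in most cells).

A phase whose defining events are not both inside the movie is flagged
censored and excluded from all distribution statistics; no survival-style
correction is attempted, matching the practice of scoring complete phases
only. All lengths are integer multiples of the frame interval, so a 10-min
movie quantizes lengths to 1/6 h.

## Distribution statistics

`summarize_lengths()` reports mean, SD (n−1 denominator), range, CV = sd/mean
and a histogram (1-h bins by default). Two-sample comparisons use the
two-sided Kolmogorov-Smirnov test (asymptotic p, recorded as such in the
result) and the Mann-Whitney U test with midrank tie handling. The U test's
p-value is exact — computed from the permutation distribution of the rank sum
by dynamic programming over the midrank multiset, which handles ties exactly —
whenever `n1*n2 <= 400`, and otherwise uses the tie-corrected normal
approximation without continuity correction. Human-readable output reports
p-values below 2.2e-16 as "< 2.2e-16" while the raw float is retained in
the result object.

## Sister-cell asymmetry

Sister pairs are scored by ΔG1/⟨G1⟩, the absolute difference in sister G1
lengths over their mean; the ratio lives in [0, 2). A pair is *asymmetric*
when the ratio exceeds a cutoff (0.2 by default); a pair exactly at the
cutoff counts as symmetric, a deliberate closure of the boundary on the
symmetric side. `sliding_profile()` repeats the classification over a cutoff
grid; the resulting fraction is non-increasing by construction, so the choice
of cutoff cannot reverse a between-population ordering. Pearson correlation
on unordered pairs is order-dependent, so `sister_correlation()` randomizes
the (a, b) assignment once under a fixed seed (a double-entry symmetrized
variant is available). Pairs with a censored member are dropped and counted.

## The shifted-Poisson WNT model

Raw G1 does not satisfy the Poisson property var ≈ mean, but the *shifted*
variable G1* = G1 − c does, where c is a single constant: the minimum G1 over
the whole pooled data set (`pooled_shift()`), applied identically to every
sample. The model is a log-link Poisson regression

\[ \mu^*_i = \exp(\beta_0 + \beta_1 x_i), \]

with x the population AXIN2 level and the response the per-condition *mean*
of G1* (a per-cell mode exists but is not the default, because the published
dose-response fit regresses condition averages). Because G1* is continuous,
the likelihood extends the factorial by the gamma function,
\(P(g) = \mu^g e^{-\mu}/\Gamma(g+1)\) — a special case of a gamma density —
and the fit is run as a quasi-Poisson IRLS (identical maximizer, no
integer-response warnings) with per-condition cell counts as prior weights,
convergence tolerance 1e-10 and at most 100 iterations via `stats::glm`.

The model predicts the full single-cell distribution at any WNT level
(`predicted_distribution()`) and its CV:

\[ \mathrm{CV}(G1) = \frac{\sqrt{\mu^*}}{\mu^* + c} = \frac{\sqrt{\mu - c}}{\mu}, \]

so lower WNT simultaneously lengthens mean G1 and widens its relative
spread — the central qualitative claim. Note the formula caps the CV at
\(1/(2\sqrt{c})\) (25% for c = 4 h); empirical CVs above that reflect
overdispersion relative to the idealized model.

Diagnostics (`model_diagnostics()`): a q-q plot of log(G1*) against normal
quantiles at plotting positions (i−0.5)/n; a Box-Cox profile log-likelihood
over λ ∈ [−2, 2] in steps of 0.001 (λ_max near 0 singles out the log link
among power transforms); and the dispersion ratio var(G1*)/mean(G1*).
G1* values of exactly 0 — the pooled minimum itself — are offset by half a
frame (5 min) for the log/Box-Cox branches only; the likelihood handles 0
natively. A quadratic term x² is refit alongside the main model and its Wald
p-value reported; large values (> 0.1) justify the first-order model.

### Choices where the design was open

* **Pseudo-R².** "Adjusted R²" is not uniquely defined for a Poisson GLM. We
  use the squared Pearson correlation between observed and fitted condition
  means, adjusted by (n−1)/(n−p−1) with p = 1, and record the definition in
  the model's metadata. Other definitions can differ by several hundredths.
* **Train vs. test.** Evaluating a trained model on a combined data set
  (`evaluate_fit()`) predicts from the trained coefficients without
  refitting; refitting is available as an option.
* **The ε term.** The link-scale noise term in the regression equation is
  treated as unmodeled residual; it does not enter the fitted likelihood,
  which reports only the two coefficients.

## 5-hmC gene scoring

Sites arrive as BED3+1 (0-based, unit-width intervals with a count column);
transcripts as a 0-based half-open table (1-based inputs are converted on
read). Each transcript's bin is the gene body ± 1 kb, clamped at chromosome
ends, start-inclusive/end-exclusive. The transcript score is the summed site
count in the bin divided by the number of forward-strand CG dinucleotides in
the bin (CG is its own reverse complement at the dinucleotide level, so
forward counting covers both strands; case-insensitive, ambiguous bases never
match). A gene's score is the *sum* of its isoforms' ratios — shared exons
deliberately count once per isoform, reproducing the published summation
rule rather than merging isoforms. Genes whose bins contain no CG are
excluded and reported. `compare_gene_sets()` builds per-set ECDFs and runs
pairwise Mann-Whitney U tests; the set "total" means all scored genes,
including members of the named sets.

## What the synthetic generator does and does not emulate

`simulate_population()` draws G1* from Gamma(shape = μ, rate = 1) — the
continuous analogue of the Poisson, with mean and variance both μ — with
μ = exp(β₀ + β₁·AXIN2); adds the shift c; draws the total cycle from a
truncated normal so that S/G2/M = T − G1 inversely correlates with G1;
shares a single G1* draw between sisters (plus Normal jitter) except in a
fraction `p_asym` of independently drawing pairs; and quantizes everything
to the frame grid before emitting event frames. Default parameters are the
study conditions: c = 4 h (the lower edge of the observed G1 range),
β₀ = 3.2, β₁ = −6380, total cycle 34 ± 4 h (so S/G2/M spans roughly
20–40 h), p_asym = 0.25, jitter 0.25 h, 10-min frames, 48-h movies with
division times in the first 24 h — which reproduces the published pattern
that G1 is complete for every tracked cell while only about half the cells
have a complete S/G2/M. The condition panels and their AXIN2 levels
(`default_study_conditions()`) use the published per-panel sample sizes;
AXIN2 values (order 1e-4 relative to GAPDH, as on the published axes) were
calibrated once so the exponential link reproduces the qualitative mean-G1
ordering of the panels, and are not revisited.

Known gaps between the generator and real data:

* **No biological or covariate noise around the link.** Condition means sit
  exactly on the exponential curve up to sampling error, so synthetic fits
  are *tighter* than the published ones (adjusted R² ≈ 0.9–0.98 rather than
  0.84–0.86). Passing fit-quality checks on synthetic data therefore says
  nothing about fit quality on real data.
* **CV ceiling.** With c = 4 the model-implied CV cannot exceed 25%;
  published empirical CVs above that (e.g. 36.6%) reflect raw-data moments
  the idealized generator does not reproduce.
* **Clamping bias.** Sister jitter is clamped at G1* = 0; at the lowest-mean
  condition this raises the condition mean slightly and biases recovered
  |β₁| down by ~2–3%, well inside the 5% tolerance used for recovery checks
  but visible in replicate medians.
* **Detection of asymmetric pairs.** An independently drawing pair exceeds
  the 0.2 asymmetry cutoff only with probability ≈ 0.55 at the low-WNT
  condition, so the asymmetric *fraction* underestimates `p_asym`;
  recovery checks invert this with calibration rates estimated from
  generator runs at `p_asym` = 0 and 1.
* One generation only; no imaging noise, colony structure, or fluorophore
  maturation kinetics.

The 5-hmC fixture plants genes in non-overlapping padded slots of a random
genome and places unit-count sites at CG positions with per-set Bernoulli
rates (lineage- and hESC-specific sets at twice the background rate by
default), so every gene's expected score is the site rate times its set's
multiplier.

## Numerical and testing notes

Problem sizes in the test suite are chosen to keep the full run within a few
minutes on one CPU: coefficient-recovery checks use medians over 50–200
replicate dose series at the published per-dose sample sizes (a single
series carries ~10% relative SE on β₁, so a one-shot 5% check would be
uninformative); dispersion checks use one population of 10⁴ cells and 10⁵
gamma draws; enrichment detection uses 20 replicate fixtures at 50 genes per
set. The KS p-value uses the asymptotic Kolmogorov series (first 100 terms);
its type-I error at n = 500 per group is within Monte-Carlo error of the
nominal 5%. The exact Mann-Whitney tail is computed by a subset-sum dynamic
program over doubled midranks, verified against full enumeration for small
samples. Since the study's underlying per-cell spreadsheet is not shipped,
distribution-level checks against published summary values run on synthetic
reconstructions calibrated to the published n and CV, and are labelled as
such where they appear.
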