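---
title: "Methods: proteome allocation, growth physiology, and the synthetic generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome allocation, growth physiology, and the synthetic generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allocsaw)
```

This vignette is the package's account of its science: the quantities it
computes, the assumptions behind them, the choices made where the design was
genuinely open, and what the synthetic-data generator does and does not
emulate.

## Proteome mass fractions

Label-free proteomics yields two intensity summaries per protein and
sample. iBAQ intensity divides summed peptide intensity by the number of
theoretically observable peptides and is treated as a proxy for protein
copy number; LFQ intensity is cross-sample-normalized and is a proxy for
*relative* abundance. The package follows the standard division of labor:

- **absolute allocation** uses iBAQ: the "iBAQ mass" of protein *i* in
  sample *s* is iBAQ~is~ × MW~i~ (MW in kDa), and its mass fraction is the
  iBAQ mass divided by the per-sample total. Fractions sum to 1 and are
  invariant to any positive rescaling of a sample's intensities —
  `compute_mass_fractions()` enforces both, and errors on an all-zero
  sample rather than emitting NaNs.
- **relative comparisons** use LFQ: `fold_changes()` divides replicate-group
  means. Both bases are selectable; the default basis for fold changes is
  LFQ.

Missing intensities are encoded as 0 and read as "not detected"; no
imputation is performed. This keeps mass fractions well-defined (an
undetected protein simply contributes no mass) at the cost of a known
truncation bias for proteins near the detection limit — a property of
label-free data generally, not of this implementation.

Fold change is the **ratio of replicate means**, not the mean of per-pair
ratios: replicates are unpaired, and the ratio of means is well-defined
when individual replicates contain zeros. A protein undetected in the
denominator group gets `fold = NA` with an `undefined` flag — never
infinity — and downstream steps count these rather than dropping them
silently.

Sector fractions sum the mass fractions of a gene set's members per sample,
then report mean ± SD over the replicates of each (strain, condition)
group; SD is 0 for singleton groups. Overlapping sets (e.g. GO-derived
groups) are computed independently with no double-count correction; only a
catalog declared `disjoint = TRUE` is validated as a partition. Identifiers
join on the **locus tag**, case-insensitively, because locus tags are
unique in bacterial genome annotation while gene names are not; gene names
are display-only.

## Enrichment of regulated genes

`select_regulated()` thresholds fold changes symmetrically (fold ≥ t for
"up", ≤ 1/t for "down"; t > 1), excludes undefined folds with a count, and
returns a sorted list so the result is independent of row order.
`hypergeom_enrichment()` then applies the standard over-representation
test: the one-sided upper-tail hypergeometric probability P(X ≥ k) for an
overlap of k between the list and each set, with Benjamini–Hochberg
q-values across all sets of the catalog tested together. Three choices
were open and are made explicit:

- the test is one-sided upper-tail (over-representation only), the field's
  default for "which groups are enriched among upregulated proteins";
- multiple-testing correction is BH across the catalog — conservative
  familywise methods would be mismatched to an exploratory scan;
- the **universe is the detected proteome** of the compared samples
  (`detected_universe()`), not the whole genome. Using the genome would
  reward sets of highly expressed proteins for mere detectability.

The implementation calls `stats::phyper`; the test suite checks it against
an exhaustive enumeration of all C(N, n) draws for small universes and
verifies the null calibration (the fraction of random gene lists reaching
p ≤ 0.05 sits near 0.05) on a catalog of 20 random sets in a
2,000-protein universe.

## Growth rates and downshift lag times

Growth rates are fitted by OLS of ln(OD600) on time — natural log, λ in
1/h — restricted to points with OD inside a window, default **0.05–0.5**,
the conventional exponential-phase range for optical-density readings
(below ~0.05 instrument noise dominates; above ~0.5 self-shading bends the
curve). The window is inclusive and a fit needs at least 3 points; fewer is
an explicit error stating the count.

A nutrient-downshift curve is modeled as: exponential growth at the
pre-shift rate until the transition time, a lag at the transition OD, then
exponential growth at the post-shift rate. The lag is extracted by the
classical geometric (back-extrapolation) construction:

1. locate the post-shift exponential range;
2. fit F(t) = exp(a + λt) on it;
3. solve F(T~resume~) = OD~ini~, i.e. T~resume~ = (ln OD~ini~ − a)/λ;
4. T~lag~ = T~resume~ − T~transition~.

OD~ini~ — the OD measured immediately after the transition — is an **input
datum**, never estimated from the fit: estimating it from the same curve
would make the lag partially self-referential. Negative computed lags,
possible under noise, clamp to 0 with a quality flag rather than erroring.
An alternative reading of "the time when growth has just fully resumed" —
the first observed point within a tolerance band of the fitted line — was
considered and rejected as the default because it depends on the sampling
grid; the back-extrapolated time does not.

**Window selection.** The exponential range is found deterministically in
two steps (`select_postshift_window()`). First, the longest contiguous
trailing run of post-shift points whose log-linear fit reaches r² ≥ 0.995
(≥ 4 points), found by shrinking from the earliest post-shift point. An r²
criterion alone is insufficient: with a long exponential tail the total
variance is dominated by the exponential range, so a window still carrying
a few flat lag points can exceed 0.995 and would bias the intercept and
hence the lag. Second, therefore, leading points whose absolute residual
exceeds max(3 × RMSE of the window's later half, 10⁻⁸) are trimmed one at
a time. The later-half RMSE estimates the measurement noise from the part
of the window that is certainly exponential; the 10⁻⁸ floor prevents the
degenerate all-points-are-outliers case on noiseless data. On noiseless
piecewise curves this recovers the lag exactly (the test grid spans lags
0–4 h and rates 0.2–1.0 /h); under 2% multiplicative OD noise the median
lag error across seeded replicates stays below 0.1 h. The window can also
be supplied explicitly, and `r2_min` is tunable for noisier readers.

## Stress survival

Viability is CFU per OD600 unit at each sampling time, normalized to the
pre-stress time point (value 1 at t = 0). CFU/OD is consumed as a single
precomputed column; normalizing by OD at sampling time (rather than at
t = 0) is the literal reading of "CFU/OD" and is what the constructors
expect. Interpolation between sampling times is **log-linear**, matching
exponential-death kinetics: percent loss at time t is 100 × (1 − v(t)) with
ln v interpolated linearly between the bracketing points. The death rate is
the negated OLS slope of ln(relative viability) on time; a nondecreasing
curve yields a flagged rate ≤ 0 with a warning, since "no killing" is a
result, not an error.

## The synthetic-data generator

The generator exists so every pipeline stage can be validated against known
ground truth at the scale of a real experiment. `gen_proteome()` builds a
~2,500-protein proteome (the coverage of a modern high-resolution
label-free run on *E. coli*):

1. genes are randomly assigned to functional sectors with fixed sizes;
2. within-sector baseline mass weights are lognormal (σ~log~ = 1, the
   within-category spread typical of protein abundance distributions),
   scaled so each sector sums to its configured baseline fraction φ~s~;
   defaults place ~26% of mass in the translation apparatus, 12% in
   amino-acid biosynthesis and 3% in basal stress response, typical of
   glucose-minimal-medium growth;
3. per condition, sector folds multiply gene masses and the proteome is
   renormalized to sum 1 — renormalization alone produces the seesaw
   coupling (one sector's gain is everyone else's loss) with no extra
   parameters;
4. per-gene overrides and regulon genes are **pinned at their observed
   folds**: the target fold is imposed after renormalization (closed form:
   pinned genes take q = o·q₀; the remaining mass is rescaled
   compositionally). Observed fold changes are what experiments report, so
   presets that encode a "5-fold induction of RpoS" must mean the observed
   quantity; pinning also makes the rpoS-null attenuation parameter exactly
   recoverable from observed folds, which a naive fold-on-top-of-fold
   construction would not be;
5. in the rpoS-null strain the rpoS gene is deleted and each regulon gene's
   observed fold f is attenuated to 1 + α(f − 1); α (default 0.5)
   interpolates linearly between no induction (α→0) and full retention
   (α = 1), encoding "compromised but retained" regulon activation;
6. replicate noise is i.i.d. multiplicative lognormal with mean 1 at a
   given CV, applied to masses which are then renormalized; the default CV
   of 10% is a documented assumption — typical between-culture variability
   for label-free proteomics — not a measured value;
7. intensities are emitted as iBAQ ∝ fraction/MW and LFQ ∝ fraction, with
   MW lognormal (median 35 kDa, σ~log~ 0.4, matching the bacterial protein
   size distribution). The intensity scale constants are arbitrary since
   every downstream statistic is scale-invariant.

RNG streams are split per component (assignment, weights, per-sample
noise), so changing the noise CV does not change which gene sits in which
sector at a fixed seed, and the whole generator is a pure function of its
spec. A ground-truth sidecar records per-gene fractions and realized folds,
sector fractions, the regulon and α, so recovery tests read truth from the
sidecar, never from constants repeated in test code.

What the generator does **not** emulate: peptide-level sampling and
missingness (detection is all-or-nothing at the protein level),
intensity-dependent noise (CV is uniform across abundance), correlated
replicate structure (batch effects), and any mechanistic link between
alarmone concentration and sector folds — it is phenomenological. Passing
recovery tests therefore demonstrate the *estimators* are correct and
well-calibrated under the stated noise model, not that real data meet that
model.

Growth and viability generators follow the piecewise-exponential and
exponential-decay models above, with multiplicative lognormal noise.
`preset()` bundles encode the study conditions: growth at 0.95 /h
(wild type) vs 0.45 /h (moderate induction) sampled every 10 min for 4 h
from OD 0.02; hyperosmotic death at 0.666 /h (95% loss by 4.5 h) vs 0.04 /h
for the induced strain, sampled half-hourly to 6 h; and three paired
downshift scenarios starting at OD~ini~ = 0.1 with lags of 2.5–4 h
(uninduced) against 1.0–1.5 h (induced) — ratios of 2.5–2.7, inside the
observed 2–3× band — with slightly lower post-shift rates under induction.
Presets are read-only parameter bundles; the seed is the only field a
caller is expected to change.

## Heatmap standardization

The condition-comparison heatmap matrix log-transforms LFQ with a
**scale-adaptive pseudocount** — half the smallest nonzero intensity in the
matrix — so undetected values land just below the detection floor instead
of at an arbitrary constant, then z-scores each protein across samples.
Whether to z-score rows or show log-ratios was open; z-scoring is adopted
as the presentation choice because it makes expression *patterns*
comparable across proteins of very different absolute abundance.
Zero-variance rows are dropped with a reported count (a z-score is
undefined for them), and row/column order follows the input, so the output
is deterministic.

## Numerical and interface conventions

- Natural logarithm throughout; rates in 1/h; MW in kDa; times in hours.
- Proteomaps exports are two-column tab-separated (locus tag, mass
  fraction), no header, LF endings, descending value with lexicographic
  tie-break — a canonical order so diffs are meaningful.
- The abundance-table writer serializes intensities at full precision
  (`%.17g`) and the reader parses with correctly rounded `strtod`, so a
  write/read round trip is bit-exact.
- Study runners (`run_allocation_study()`, `run_phenotype_study()`) write
  every numeric output at full double precision, copy their config into the
  output directory, and produce a summary JSON that is byte-identical on
  rerun at the same seed; any stage failure aborts with the stage name and
  a manifest of partial outputs.

## Problem sizes used by the test suite

The suite exercises the estimators at the study's native scale where that
is cheap (2,500-protein proteomes, 3 replicates) and at reduced scale where
iteration count dominates: 20 seeds for generator-recovery checks, 100–200
seeded replicates for Monte-Carlo noise-robustness checks, 1,000 simulated
gene lists for the enrichment null calibration, and exhaustive enumeration
up to a 12-protein universe for the hypergeometric oracle. These sizes were
chosen so each property is tested with comfortable statistical power while
the whole suite stays quick to run during development.

## Known limitations

- No differential-expression statistics (no moderated t-tests): the
  package reports fold changes and sector fractions with replicate SDs,
  matching its descriptive scope.
- No GO DAG propagation; annotation groups are flat GMT sets.
- No whole-curve growth models (logistic/Gompertz); only exponential-phase
  procedures.
- No biphasic (persister) survival model; a single exponential death rate.
- The packaged sector and regulon catalogs generated from synthetic truth
  are stand-ins with realistic structure, not any organism's curated
  annotation; analyses of real data should supply curated GMT files.
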