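---
title: "Knockout-calibrated ChIP-chip target calling: models and methods"
author: "nullchip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knockout-calibrated ChIP-chip target calling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`nullchip` implements a complete analysis chain for locating the promoters
bound by a transcription factor in vivo, when the experiment hybridises
chromatin immunoprecipitated (ChIP) DNA to a promoter tiling array and —
crucially — runs the identical protocol on tissue from protein-null
(knockout) littermates. Because the null tissue contains no protein to pull
down, everything the protocol recovers from it is background: antibody
cross-reactivity, amplification bias, hybridisation noise. The null arrays
therefore furnish an *empirical null distribution* against which the
wild-type signal is judged, replacing any parametric model of array noise.

This vignette is the package's own account of the statistics it
implements, the knobs that matter, the choices made where the procedure
was genuinely open, and what the synthetic-data generator does and does
not emulate.

## The enrichment model

### Array geometry

The assumed platform is a two-colour promoter tiling array: each of
~17,000 promoter regions is tiled by ~25 probes (60-mers) spanning 5.5 kb
upstream to 2.5 kb downstream of the transcription start site, spaced
100–300 bp apart. ChIP material is hybridised against total input DNA, so
the raw measurement per probe is a log2(ChIP/input) ratio. All distances
in the package are measured between probe interval midpoints (coordinates
are 0-based half-open on disk).

### Probe scores

Per genotype, replicate arrays are quantile-normalised against each other
(`quantile_normalize()`, delegating to limma's tie-averaging
implementation), and the **probe score** is the replicate-mean log-ratio
clipped at zero (`compute_probe_scores()`):

$$ s_i = \max\!\left(\tfrac1R \sum_{r=1}^R m_{ir},\; 0\right). $$

On this scale a score of 1 means 2-fold enrichment of ChIP over input
(`score_to_fold()`). Negative means carry no binding information for a
pulldown assay and are clipped rather than dropped, keeping the probe
lattice intact for the window step. When raw paired channel intensities
are supplied instead of log-ratios, `normalize_within_array()` first
removes the intensity-dependent dye bias by a robust locally weighted
regression of M on A (tricube weights, span 0.3, two robustness
iterations; non-positive intensities floored at 0.5 intensity units with a
message; fewer than 20 probes falls back to median-centering).

### Window-adjusted scores

Chromatin shearing yields 300–1000 bp fragments, so a genuine binding
event elevates several adjacent probes, with enrichment decaying as probes
move away from the site. A single hot probe is more plausibly an artefact.
The **window-adjusted score** (`window_scores()`) encodes exactly this:
for probe $p$, the window set is $p$ plus its nearest neighbour on either
side within 500 bp (midpoint to midpoint); the score is the median of the
window set's probe scores, set to zero unless at least three window
members have a probe score strictly above background (zero). Windows never
cross promoter-region boundaries.

Consequences worth knowing:

* window sets have at most 3 members, so the median is always the odd
  middle value and no even-median tie-break is ever exercised in the
  default mode;
* edge probes of a densely tiled promoter have window sets of size 2 and
  are forced to zero — the rule deliberately sacrifices the outermost
  probes to guard against edge artefacts;
* `mode = "all_in_window"` offers a sensitivity variant (median over *all*
  probes within ±500 bp); there the even-median convention applies.

The "nearest neighbour on either side" reading (window of ≤3) was chosen
over "all probes in ±500 bp" as the default because the three-probe median
is the more conservative statistic and the zeroing clause is phrased in
terms of exactly three probes; the variant is retained behind the mode
switch for sensitivity analysis. Likewise, confining windows to their
promoter region (rather than letting abutting regions communicate) is a
choice: tiled regions of this design are almost never adjacent in the
genome, and cross-region windows would mix unrelated TSS contexts.

### The empirical null threshold

`derive_null_threshold()` takes the window scores of the null-genotype
arrays and returns the value that excludes 99% of them (configurable
percentile). The rule is rank-based: the smallest *observed* score with at
least $\lceil 0.99\,n \rceil$ null scores strictly below it. Two numerical
details:

* **Ties.** Window scores tie frequently, because adjacent windows share
  probes and a median equals one of its member values. A plain order
  statistic at rank $\lceil p n \rceil + 1$ can therefore exclude
  marginally *less* than the nominal fraction. Advancing past ties makes
  the exclusion guarantee exact; the count of ties at the threshold is
  reported.
* **Rank versus interpolation.** An interpolated quantile
  (`method = "interpolate"`, type-7) is available, but interpolated values
  fall between observed scores and carry no exclusion guarantee; the rank
  rule is the default precisely because "excludes 99% of null data points"
  is the property the downstream calling relies on.

If the null scores are too tied to exclude the requested fraction (e.g.
all zero), the maximum is returned with a degeneracy warning.

### Two-tier calling, gene mapping, and null cross-filtering

`call_enriched_promoters()` calls a promoter region when at least one of
its probes reaches the threshold (comparison is `>=`). The window score
itself already demands three locally positive probes, so this rule is not
a single-probe criterion in disguise; a stricter "at least 2 enriched
probes" rule sits behind `min_enriched_probes`. The reported peak interval
is the maximal contiguous run of at-threshold probes containing the
maximal probe — the most likely stretch to contain the binding site. Two
tiers are produced: the *long* tier at the empirical null threshold and a
*strict* tier at a fixed window score of 1.5 (~2.8-fold).

`map_regions_to_genes()` expands regions to (region, gene) pairs — a
region lying between two divergent TSSs yields two gene rows, which is why
gene counts can exceed region counts. `filter_against_null()` then removes
any called gene whose promoter carries a null-genotype window score
*strictly above* the threshold (calling is `>=`, exclusion is `>`; the
asymmetry follows the tier definitions), recording the offending probe.
The strict tier reuses the same null filter. The filter is idempotent and
order-independent.

## Motif over-representation

The motif component answers: which 8-base degenerate patterns are
over-represented in target promoter sequences relative to background
promoters? The published description of the original search survives only
in outline, so the algorithm here is a documented reconstruction with the
test statistic isolated for drop-in replacement:

1. collect every concrete 8-mer present in the targets (either strand;
   a word and its reverse complement are one motif, represented by the
   lexicographically smaller);
2. test each word's per-promoter *presence* (not occurrence count)
   against the background with a one-sided hypergeometric test;
3. greedily merge significant words differing at a single position into
   degenerate patterns, at most two alternative bases per position and at
   most four degenerate positions (mirroring the degeneracy of published
   degenerate-motif tables);
4. report each merged motif with its target-promoter count, combined
   presence p-value, and the p-value range across its concrete variants.

The background is the caller's to choose; `run_pipeline()` uses a
size-matched random sample of promoters not called at the long tier.
Backgrounds of fewer than 10 sequences are refused (presence frequencies
too unstable). `match_known()` compares any degenerate motif against the
published forkhead consensus patterns (RYMAAYA, TATTTRT, AATTTGT) over all
gapless alignments on both strands: *complete* when every concrete variant
instantiates the consensus across the overlap, *partial* at ≥6 compatible
positions, *none* otherwise.

## Expression: preprocessing and litter-aware inference

The expression arm models a bead-array comparison of wild-type versus
mutant littermate embryos with litter structure:

* `background_correct()` subtracts each array's mean negative-control
  signal (values may go negative — intended).
* `vst_glog()` applies a per-array affine calibration (medians and MADs
  brought to common values) followed by the generalized log
  $\mathrm{glog}_2(x) = \log_2\!\big((x + \sqrt{x^2 + c^2})/2\big)$, with
  $c$ per array estimated as the MAD of the below-median values, i.e. the
  additive-noise-dominated regime. The transform is monotone, tends to
  $\log_2 x$ for $x \gg c$, is linear near zero, and equals
  $\log_2(c/2)$ at $x=0$. A constant array makes the calibration
  degenerate and is an error.
* `detection_filter()` keeps a gene iff its detection score is ≥0.95 in
  at least one sample.
* `qc_outliers()` flags samples whose median inter-sample correlation
  falls strictly more than 3 MADs below the cohort median; more than 25%
  flagged aborts with diagnostics (that is a cohort problem, not an
  outlier). The strict inequality makes boundary decisions deterministic
  and order-independent.
* `fit_de()` fits, per gene, `value ~ genotype + litter` by least squares,
  with litter as a **fixed** blocking factor (the plain reading of a
  genotype-plus-litter model at three litters; a random effect would be
  poorly estimated from three levels anyway) and genotype coded mutant = 1,
  so "down" means lower in mutant. Both ordinary (exact residual df) and
  moderated t statistics are reported. Moderation squeezes per-gene
  variances toward a prior estimated by log-scale moment matching across
  genes (digamma/trigamma equations), adding the prior df to the residual
  df; it defaults to primary because it is the standard small-n behaviour,
  while the ordinary statistic remains available for exact calibration.
  A design in which genotype is constant within every litter is
  confounded and refused. With a single litter the blocking term drops and
  the model reduces to the ordinary two-sample t-test.
* `bh_fdr()` applies the Benjamini–Hochberg step-up adjustment.
* `litter_permutation_test()` enumerates every genotype-label
  reassignment that preserves each litter's genotype counts, refits, and
  counts genes significant at `alpha`; the report states how many
  permutations reach at least the observed tally (the identity is always
  one of them, so the empirical p is ≥ 1/total). The default simulated
  design — litters splitting 2/2, 2/2 and 1/2 wild-type/mutant, 11
  samples — admits exactly
  $\binom{4}{2}\binom{4}{2}\binom{3}{2} = 108$ constrained permutations.
  The study this design emulates did not record its litter sizes; this
  composition was chosen as a plausible one, and the report always states
  the count for the design actually given, never a hard-coded number.
  Beyond $10^6$ permutations the test switches to seeded uniform sampling
  and reports a binomial confidence interval.

## The synthetic-data generator

Every module is exercised against data from `gen_design()`,
`gen_chip_arrays()`, `gen_expression()` and `gen_promoter_sequences()`,
with all planted truth recorded and every generator stream derived from a
single recorded seed (outputs round-trip byte-identically).

What it emulates: the array geometry above (integer-bp spacings drawn
uniformly from the configured range, keeping the bounds exact); a
configurable fraction of promoter regions linked to two divergent genes
(default 3%, matching the few-percent excess of genes over regions such
designs show); binding peaks whose expected log2 enrichment decays
linearly (triangular kernel) from the site amplitude to zero at the
half-width — the natural shape when overlapping sheared fragments carry
the signal — with a Gaussian alternative behind `peak_shape`; half-width
default 750 bp, the midpoint of the 300–1000 bp shear range; binding
sites placed uniformly over each bound promoter's probe-covered extent so
every planted peak is observable; null arrays of pure zero-mean Gaussian
log-ratio noise (default sd 0.35 per probe and replicate, a typical
two-colour log-ratio dispersion), with an off-by-default
`null_contamination` knob planting peaks in the nulls to mimic antibody
cross-reactivity; an 11-sample, three-litter expression study with
additive per-gene litter effects; and promoter sequences with a planted
degenerate 8-mer at configurable target/background prevalence (uppercase
ACGT only, no N handling).

What it does not emulate — and therefore what passing tests do *not*
establish about real arrays:

* **Correlated array noise.** Real null hybridisations concentrate their
  strongest background in a few promoters (cross-reacting proteins, copy
  number, sequence-driven hybridisation artefacts). The generator's null
  is independent across probes. This matters for one headline property:
  with iid noise, the 1% of null-level window scores that exceed an
  exact-99% threshold are *scattered*, so at 25 probes per promoter a
  non-trivial share of unbound promoters (of the order of 10–15%) shows
  at least one super-threshold window in wild-type data as well, and the
  long tier's promoter-level precision on iid synthetic data is
  correspondingly low even though its recall is essentially 1 and the
  strict tier is essentially pure. On real data, where null exceedances
  cluster, the same threshold yields promoter-level false-positive rates
  an order of magnitude lower. The package reports both tiers and the
  exclusion tables precisely so this behaviour is visible rather than
  hidden.
* Scanner-level artefacts, spatial effects, dye-swap structure, or raw
  two-colour image processing (log-ratios are generated directly; a raw
  intensity mode exists only for the expression arm's
  background-correction/VST path).
* Probe-sequence effects (GC, cross-hybridisation) and probe-to-gene
  annotation error.

## Problem sizes and numerical conventions

The shipped tests run the generator at 50–2,000 promoters and 400–10,000
genes — sizes chosen so the full suite completes in well under a minute of
compute per file while keeping every statistical check adequately powered
(e.g. the null-calibration and recovery checks use 2,000 promoters ×
~25 probes × 3 replicates; the DE calibration uses 10,000 genes). The
full 17,000-promoter default runs in a few tens of seconds and is the
intended analysis scale.

Other conventions: probe positions are interval midpoints; threshold
comparisons are `>=` for calling and `>` for null exclusion; gene
identifiers are matched exactly after upper-casing (no alias resolution);
report files contain no timestamps so reruns under one seed are
byte-identical.

## Known limitations

* The empirical threshold is exactly as good as the null arrays: too few
  null window scores (<100) are refused, and a contaminated null (real
  binding in the "null" genotype) biases the threshold upward.
* The motif search is a reconstruction; its exact published counterpart
  is not recoverable, so numerical agreement with historical motif tables
  is not claimed — only the statistical design (presence-based
  hypergeometric ranking of degenerate 8-mers) is.
* The moderated-variance estimator assumes a common scaled-F model for
  per-gene variances; with very few genes (<~50) the prior df estimate is
  unstable, and the ordinary statistics should be preferred.
* The glog VST is a robust approximation, not a maximum-likelihood fit of
  the calibration parameters; it stabilises variance well in the
  generator's regime but is not a reimplementation of any specific
  published calibration package.
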