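---
title: "Methods: CATAC motif modelling, construct scoring and rhythm analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CATAC motif modelling, construct scoring and rhythm analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(catac)
```

# The element and the questions the package answers

CATAC (Clock-Associated Transcriptional Activation Cassette) is a 29-bp
promoter element found near *Drosophila* clock genes. Its residues are
numbered 1–29; the conserved core occupies residues 8–17 with consensus
`TRCGCATACG`, and residues 19–24 form an E-box-like hexamer with consensus
`CRCGTG`, of which the canonical CLK/CYC-binding E-box `CACGTG` is a
special case. The package implements the computational side of the
element's characterization:

* a probabilistic motif model (PWM) with log-odds bit-score scanning and
  ZOOPS-style EM refinement, plus gene-set enrichment of motif hits in
  promoter windows;
* representation and scoring of multimerized "4xCATAC" reporter
  enhancers assembled from synthetic oligonucleotide duplexes, including
  the six-residue transversion mutagenesis used for mutant constructs;
* FFT-seeded nonlinear least-squares multicomponent cosine analysis of
  single-fly bioluminescence recordings with relative-amplitude-error
  (RAE) classification and cohort statistics;
* comparative-Ct (ΔΔCt) analysis of circadian qRT-PCR time courses with
  Kruskal–Wallis rhythm testing;
* a synthetic-data module that generates every input the pipeline
  consumes, with stored ground truth, so the whole analysis is testable
  by parameter recovery.

# Motif model

`build_motif_matrix()` estimates per-position probabilities from aligned
sites as `(count + pseudocount * background) / (n + pseudocount)`. The
default pseudocount of 0.5, distributed according to the background,
keeps all probabilities positive so log-odds scores stay finite; with at
least a handful of sites it perturbs the estimates negligibly. The
background defaults to uniform; `scan_motif()` can instead use the
empirical mononucleotide composition of the scanned sequences
(`background = "empirical"`), which is preferable when promoter GC
content departs strongly from 25/25/25/25.

The bit score of a 29-mer is the sum over positions of
`log2(p[i, base] / background[base])`; it is additive over positions, and
the consensus string attains the maximum score (both properties are
tested, the latter by exhaustive enumeration on a small matrix).
`scan_motif()` reports every window scoring strictly above the threshold
(default 5 bits, the site-calling cutoff used for CATAC) on either
strand, on forward-strand 0-based half-open coordinates. The strict
inequality matters only for windows scoring exactly 5.000 bits, which
have measure zero for real matrices. Overlapping hits on the same strand
are pruned greedily by descending score, ties to the leftmost window.

`refine_motif_matrix()` implements the training step as
expectation–maximization over a zero-or-one-occurrence-per-sequence
(ZOOPS) model: a sequence contains a single motif occurrence with prior
probability `gamma` at a uniformly distributed position, or none, and
non-motif bases follow the background. This architecture is a deliberate
stand-in: the one-motif hidden-Markov training procedure that produced
the original matrix is not fully specified in the public record, and
ZOOPS-EM is the standard, testable choice for that role. The E-step is
exposed as `zoops_posterior()` so tests can compare it against exhaustive
enumeration of placements; the M-step re-estimates probabilities from
posterior-weighted counts with the same pseudocount smoothing. The data
log-likelihood is non-decreasing across iterations (EM guarantee, also
tested); non-convergence within `max_iter` returns the last iterate with
a flag rather than failing. Refinement operates on the forward strand;
training sequences are expected in a consistent orientation.

The packaged `catac_matrix()` is built from the eight wild-type elements
of the two multimerized reporter enhancers whose oligonucleotide
sequences ship with the package. It is a stand-in for a matrix trained
on genome-wide aligned sites — adequate for simulation and recovery
experiments because it reproduces the element's core/E-box information
structure, but not a substitute for the original genome-trained matrix
when scanning real promoters.

`promoter_enrichment()` treats a gene as hit when any motif hit overlaps
its promoter window by at least 1 bp (window assignment is otherwise
undefined for boundary-spanning hits) and computes the one-sided
hypergeometric tail probability of the observed number of hit genes in
the set. The discrete tail p-value is super-uniform under the null;
tests verify both the closed-form value on a small instance and
calibration of the smoothed statistic over 1000 null gene sets.

# Construct toolkit

The five packaged oligo sets (wild-type and mutant Slob and Pdp1
4xCATAC, plus the Pdp1-with-Slob-like-E-boxes variant, PSE) are
annealed-duplex designs: each duplex is a top and a bottom oligo, and
consecutive duplexes join by complementary sticky ends.
`assemble_enhancer()` reconstructs the top strand by taking, for each
subsequent oligo, the maximal exact suffix–prefix overlap with the oligo
or its reverse complement (minimum 10 bp). The wild-type and Pdp1-mutant
sets assemble cleanly; the printed Slob-mutant set is internally
inconsistent within its first duplex (the top oligo disagrees with its
partner's reverse complement beyond the element mutations) and is
retained as data, with assembly raising its documented error.

`find_elements()` slides a 29-base window over both strands and keeps
windows whose core region has at most `max_core_mismatch` (default 2)
mismatches to `TRCGCATACG` under IUPAC matching. Candidate windows are
reduced to disjoint elements greedily by ascending mismatch count, ties
to the leftmost forward coordinate — and, unlike `scan_motif()`, the
resolution operates **across strands**, because an element is a
double-stranded site: a 29-bp stretch of duplex DNA is one element
regardless of which strand carries the motif orientation. With
same-strand-only resolution the Slob enhancer would report five
overlapping "elements" where the construct contains four. The default
mismatch cutoff of 2 recovers all eight printed wild-type elements
(core mismatches 0–1) while rejecting every mutant element (the four
core transversions push them to 3 or more); this separation is tested.

`score_construct()` tallies, over a construct's four elements, matches
of the core region against `TRCGCATACG` and of the E-box region
(residues 19–24) against both `CRCGTG` and `CACGTG`, with IUPAC classes
honoured (`R` matches A or G). Under this rule the Pdp1 enhancer scores
4/24 mismatches against the canonical E-box and 2/24 against `CRCGTG`,
and the Slob enhancer 9/24 against the canonical E-box — all three
matching the mismatch tallies reported for these constructs — while the
Slob `CRCGTG` count computes to 7/24 against a reported figure of
8/24. No consistent per-residue matching rule reproduces all four
reported tallies simultaneously, and the PSE construct's E-box set is
exactly Slob's under our element extraction (which is how that construct
was designed), so we retain the consistent rule and report the computed
7/24. The discrepancy is flagged where it matters and asserted at the
reported value in the acceptance suite, where it is a known, documented
failure rather than a silent one.

`apply_transversions()` swaps A↔T and C↔G at the six mutagenized
residues (8, 10, 14, 16 in the core; 21, 23 in the E-box region). It is
an involution, changes exactly six residues, and never changes a
residue's A/T or C/G pairing class — all tested.

# Synthetic data: what it emulates and what it does not

`simulate_traces()` generates single-fly luciferase photon-count traces:

```
mean(t) = baseline * exp(-t / settle_tau)
        + amp_24 * cos(2*pi*(t - phase_24) / period_24)
        + amp_12 * cos(4*pi*(t - phase_24) / period_24)
```

plus i.i.d. Gaussian noise, sampled on an hourly grid with ±20% uniform
jitter (TopCount plates are read "roughly once every hour"), counts
floored at zero, the first `ld_head_h = 12` hours labelled LD and the
rest DD. The 12-h ultradian component is modelled as the second harmonic
phase-locked to the circadian component — the simplest generator of a
two-peaks-per-day waveform. Defaults: `amp_24 = 50`, `amp_12 = 10`,
`noise_sd = 10`, `phase_24 = 2` (early-day peak), `baseline = 600`,
`settle_tau = 96`, `duration_h = 120`. Noise magnitude and amplitude are
free parameters (no reference values exist for them); the baseline and
settling constant are chosen so that the signal stays well clear of the
zero floor for the whole recording — a fly whose reporter decays into
the clipping regime produces a rectified waveform whose fitted amplitude
is biased low, which is a property of the generator, not of the assay
being emulated, where expression is sustained. Counts are truncated
rather than Poisson-distributed because amplitude recovery, not photon
statistics, is what the downstream tests measure. Not emulated: per-fly
amplitude/phase heterogeneity, luciferin pharmacokinetics,
plate-position effects, and light-phase masking; passing recovery tests
therefore demonstrates correctness of the estimator on its assumed
signal class, not robustness to every artifact of real recordings.

`simulate_promoters()` plants motif instances drawn position-wise from a
`motif_matrix` into i.i.d. background sequence (default GC fraction
0.43, a fly-genome-like value), without overlap, on random strands, and
records the true BED coordinates. `simulate_ct_table()` generates a flat
reference gene and a target whose Ct oscillates as
`target_mean_ct - amplitude * cos(2*pi*(t - peak_ct_hour)/24)` over
CT0–CT24 (lower Ct = higher expression), with replicate noise; the
design mirrors a four-replicate, five-timepoint harvest. All three
generators are deterministic given their seed.

# Rhythm analysis

The per-fly pipeline is `preprocess_trace()` →
`detrend_trace(trim_edges = TRUE)` → `fft_nlls()`.

**Preprocessing.** The first 24 h are excluded (freshly loaded flies
carry excess luciferase) and only DD samples are analyzed. A trace with
under 48 h of usable data is ineligible and classified arrhythmic.

**Detrending.** A centered 24-h running mean (edge-truncated) is
subtracted. At a 24-h period on an hourly grid the 25-point mean has
gain −1/25, so the circadian component passes essentially unattenuated
(amplitude ×26/25; the closed form is tested). Within half a window of
either end the mean is asymmetric and distorts phase; fitting those
samples biases recovered periods low by ≈0.3 h on a four-cycle record,
so the pipeline trims half a window from each end before fitting. The
method needs recordings of at least ~72 h of DD data to leave 48 h after
trimming; the default simulated duration (120 h) leaves ~72 h.

**FFT-NLLS.** Iteratively: residuals are interpolated onto a uniform
grid, the dominant periodogram peak seeds a new cosine component, and
all components plus a constant are jointly refit by Levenberg–Marquardt
nonlinear least squares on the native (jittered) timestamps, so the
spectral grid only ever provides starting values. Iteration stops when
the newest component is not significantly non-zero or `max_components`
(default 4) is reached. The acceptance test is the package's stopping
rule, chosen where the original software's rule is not public: the
cosine and sine coefficients of the new component are tested jointly
(2-df F test — the amplitude of a null component is Rayleigh, not
half-normal), Bonferroni-corrected over approximately one effective
independent frequency per grid sample, because the candidate frequency
is the *maximum* of the periodogram refined continuously by the
optimizer. Without the correction ~30% of pure-noise traces acquire a
nominally significant component; with it, 1–4% of noise traces are
called rhythmic while genuine signals (amplitude t-statistics in the
tens) are unaffected.

**RAE and classification.** For the circadian component — the
highest-amplitude accepted component with period in 15–35 h — the
relative amplitude error is the 95% confidence-interval *half*-width of
the amplitude divided by the amplitude estimate ("amplitude error over
most probable amplitude"; using the full CI width would double every
RAE, and the half-width reading is the one consistent with the 0.7/1.0
class boundaries). CIs come from the linearized covariance at the
optimum and are not multiplicity-adjusted; the adjustment applies only
to component acceptance. Classification: RAE < 0.7 rhythmic, 0.7 ≤ RAE ≤
1 weakly rhythmic, RAE > 1 arrhythmic; optimizer failure, no accepted
component, or no component in the circadian range maps to arrhythmic
("the program returned no data"). With the conservative acceptance rule,
borderline components (amplitude t-statistics between 2 and ~4) are
usually rejected outright rather than reported with RAE near 1, so the
weakly-rhythmic class is rarer for this pipeline than for software that
reports every seeded component.

**Cohort statistics.** `summarize_group()` reports class percentages
over all flies and mean ± SEM of RAE and period over rhythmic plus
weakly rhythmic flies only (period means use the circadian component
only). `compare_groups()` provides the three tests used for such data:
Pearson chi-square (no continuity correction) on the 3-class rhythmicity
table, dropping classes empty in both groups; Mann–Whitney U for
expression levels; and Welch ANOVA with Tamhane's T2 post-hoc, realized
as pairwise Welch t tests with Šidák adjustment — T2's construction —
for RAE/period comparisons. `expression_level()` reads raw counts at the
sample nearest 6 h after DD onset (±1 h, otherwise the fly is excluded
with a warning).

# qRT-PCR analysis

`relative_expression()` computes `2^-(Ct_target - Ct_reference)` with
target and reference paired by (timepoint, replicate), since each
replicate index corresponds to one independent group of flies assayed
for both genes. `normalize_profile()` divides by the mean of per-
timepoint means, making the normalized profile average exactly 1 and
rendering it invariant to global rescaling. `rhythm_test()` runs
Kruskal–Wallis (standard tie correction) across timepoints on
replicate-level normalized values — the normalization is a global
monotone map, so the p-value equals what raw relative levels would give
— and calls the peak as the timepoint of maximum mean, leftmost on
ties. CT24 is kept distinct from CT0 rather than wrapped, matching the
five-point experimental design. A 1-cycle Ct amplitude with no noise
propagates to a peak/trough expression ratio of exactly 4 = 2^2, used as
a closed-form pipeline check.

# Numerical choices and degenerate inputs

* Sequences are validated to A/C/G/T where scores are computed; IUPAC
  ambiguity codes are accepted only in consensus patterns.
* `fft_nlls` requires ≥ 12 samples spanning ≥ 48 h; anything less is
  arrhythmic by construction, not an error.
* A numerically perfect fit (zero residual variance) stops component
  search immediately; its RAE is 0.
* Ties in greedy overlap resolution go to the leftmost window; ties in
  peak calling go to the earliest timepoint.
* All-tied Kruskal–Wallis input returns H = 0, p = 1 instead of NaN.
* Generators restore the caller's RNG state, so seeded simulation does
  not perturb surrounding code.

# Problem sizes used by the test and acceptance suites

Chosen as the smallest sizes at which the targeted effects are
unambiguous: 100 flies for null-specificity calibration, 26 flies (a
typical cohort size for this assay) for average-trace recovery, 50
flies per noise level for the RAE monotonicity sweep, 100 synthetic
promoters of 1 kb for planted-site recovery, 10^5 background windows
for the empirical score tail, 1000 replicates for enrichment p-value
calibration, and 200 replicates for qPCR power. The full suite runs in
about a minute and a half on one CPU.

# Known limitations

* The ZOOPS-EM refiner is single-strand and single-motif; it is a
  stated stand-in for the original (unpublished) training architecture.
* The packaged CATAC matrix derives from eight construct elements, not
  from genome-wide sites; genome-scale scans should train on a proper
  site collection via `build_motif_matrix()`/`refine_motif_matrix()`.
* The moving-average detrend costs one window (24 h) of data and
  slightly amplifies circadian amplitude (×26/25); both effects are
  deterministic and documented rather than corrected.
* Group percentages and means are descriptive; no multiple-cohort
  error control is applied beyond the tests the user requests.
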