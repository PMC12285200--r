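---
title: "tailscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tailscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tailscan)
```

# Scope

`tailscan` implements three connected analyses around the 3'-end maturation
of a noncoding RNA — the motivating system is the telomerase RNA component
(TERC), whose 451-nt mature form can be found truncated, exactly mature,
genomically extended, mono-adenylated, or carrying short untemplated
oligo(A) tails that mark immature or degradation-targeted molecules:

1. **3' RACE tail profiling**: classify every sequenced amplicon read by
   where its templated sequence ends and what untemplated tail follows.
2. **Proximity-labeling proteomics screening**: reduce an iBAQ
   quantification table from a biotin-ligase proximity experiment to a
   fold-change / t-test enrichment call per protein.
3. **Quantitative assay reductions**: comparative-CT (ddCT) fold changes,
   qPCR-based relative telomerase activity (RTA), and densitometric mean
   terminal restriction fragment (TRF) length.

Every input has a seeded generator with planted truth, so each stage can be
validated end to end without any external data.

# The tail-profiling model

## Read geometry and coordinates

A 3' RACE library ligates a linker to RNA 3' ends and amplifies between a
gene-specific forward primer and a linker primer, so each read runs in RNA
sense from a fixed 5' start, across the 3' terminus and its tail, into the
linker. The reference ([`reference_locus()`]) spans the amplicon 5' start
through the mature 3' end plus downstream genomic flank. Coordinates are
0-based; `mature_end` indexes the last mature base and every call carries a
signed offset `d = last templated position - mature_end`, so `d = 0` is an
exactly mature end, `d < 0` a truncation, and `d > 0` a genomically encoded
extension.

## Matching policy

Three rules, all substitutions-only (no indels anywhere):

* **Linker trimming** (`trim_linker()`): leftmost full-length window within
  `linker_max_mismatch` (default 1) substitutions of the linker; the insert
  is everything before it. The leftmost rule reflects that the biological
  insert precedes the ligated linker — a tail that merely resembles the
  linker further right cannot pre-empt a genuine upstream occurrence. Reads
  whose linker is clipped by the read end are rescued through a 3' partial
  overlap of at least `min_linker_overlap` nt (default 8) at a
  proportionally scaled allowance. Inserts shorter than
  `min_post_trim_len` (default `anchor_len + 1`) are rejected and counted,
  never silently dropped.
* **Anchor acceptance** (`match_anchor()`): the first base must match the
  reference exactly and the following 18 bases may differ by at most one
  substitution (defaults `anchor_len = 19`, `anchor_max_mismatch = 1`,
  `first_base_exact = TRUE`). This admits only reads genuinely starting at
  the amplicon 5' start.
* **Boundary calling** (`call_terminus()`): the templated prefix is the
  *largest* `k` such that the first `k` insert bases match the first `k`
  reference bases within the mismatch budget **and the k-th base itself
  matches**. Template-maximality resolves ambiguous terminal adenosines
  template-first; the end-on-match constraint is the package's own
  refinement, added because a budgeted maximization without it would absorb
  leading tail bases as "templated with mismatch" — a two-adenosine tail
  over a non-A flank would otherwise be swallowed whole and the class
  structure destroyed. With the constraint, the boundary is unique and
  identifiable, and an exhaustive split-point enumeration (the test-suite
  oracle) returns the identical answer on every randomized case.

The mismatch budget is shared between anchor and body by default
(`body_mismatch_budget = 1`, `shared_budget = TRUE`): the assay convention
fixes only the anchor allowance, and a small shared budget keeps a single
sequencing error from truncating the templated region while staying
maximally conservative at the junction. Whether the allowance should be
shared with or separate from matching beyond the anchor is genuinely open;
both are exposed. For noisy data the budget must scale with the expected error
count: `mismatch_budget_for(error_rate, templated_len)` returns the 99.9%
binomial quantile (8 for 0.5% error over ~470 nt), chosen from the error
model, not fitted to data.

## Terminus classes

`classify_terminus()` applies the reporting convention of 3'-end
profiling: empty tail is `GENOMIC` at its offset; a single untemplated
adenosine is `MONO_A`; two or more adenosines and nothing else is
`OLIGO_A` at any offset (an extended-and-oligoadenylated molecule is still
oligoadenylated); any tail containing a non-A is `OTHER_TAIL`. Two edge
rules deserve note:

* When the flank itself begins with 'A', a read ending `...mature end + A`
  is indistinguishable from a one-base templated extension.
  Template-maximality calls it `d = +1` with an empty tail, and the class
  is `MONO_A` with `possibly_genomic_A = TRUE` — the ambiguity is
  surfaced, not guessed away.
* A lone-A tail at `d != 0` falls outside the canonical three-class
  legend; it is classified `MONO_A` (a single untemplated adenosine at its
  offset) so that every assigned read lands in exactly one class and the
  profile's mass balance is exact.

`profile_termini()` normalises counts by the number of assigned reads —
the denominator reported in this kind of profiling counts accepted reads
only — and reads rejected at trimming or anchoring are reported per status
alongside.

# The synthetic read generator

`simulate_race_reads()` draws a terminus per read from a
[`truth_mix()`] — per-offset genomic probabilities, class probabilities
for mono(A)/oligo(A)/other tails, tail-length distributions, per-base
substitution error, and read length — then assembles
`prefix + tail + linker + filler` and applies errors. Defaults encode a
plausible partially processed population: 50% genomic termini spread over
offsets −5..+3 (mass at the mature end), 20% mono(A), 25% oligo(A) of
length 2–4, 5% mixed tails.

Two generator choices matter for interpretation:

* **Read length** defaults to 520 nt. The emulated instrument reads are
  250-bp paired-end, but pair merging is deliberately not simulated (the
  downstream counting uses single left-end reads); a single-end read must
  span amplicon start → mature end (451 nt) → tail → 20-nt linker to
  report the junction at all, so the generator produces the merged-pair
  equivalent directly.
* **Identifiability of planted tails.** A tail base that coincides with
  the genomic continuation at its position is provably absorbed by any
  caller obeying the template-maximal rule. The generator therefore plants
  only identifiable configurations: A-tails go to offsets whose downstream
  flank window is A-free (falling back to the nearest identifiable
  truncation offset when every configured offset collides), and mixed
  tails are built base-by-base to mismatch the continuation. This
  reweights placement *within* a tailed class; the class mixture itself is
  untouched, which is what the recovery checks measure. The one
  deliberately ambiguous configuration (mono(A) over an A-starting flank,
  `make_reference(post_mature_A = TRUE)`) exists to exercise the
  `possibly_genomic_A` path.

What the generator does **not** emulate: PCR amplification bias and
duplicates, indel errors (the matching policy disallows indels, so indel
noise would only inflate the rejected classes), quality-score structure,
or chimeric reads. Passing recovery tests therefore demonstrate the
correctness of the calling logic under the stated noise model, not
robustness to every artefact of a real library.

# Proteomics screening

The screen reduces an iBAQ matrix (proteins × replicates, bait vs
control) in four steps:

1. **Unique-peptide filter**: proteins with fewer than 2 unique peptides
   are labelled `FILTERED_PEPTIDES` (boundary inclusive).
2. **FOT normalisation**: each iBAQ value divided by its replicate's
   total, so columns sum to 1 and fold changes are invariant to
   per-replicate depth. Reported FOT variants differ in exactly which
   iBAQ total forms the denominator; since the purpose is cross-sample
   normalisation, the within-sample total (standard FOT, giving unit
   column sums) is used here.
3. **Replicate QC**: pairwise Pearson correlation on log10(FOT +
   pseudocount); zero-variance replicates yield NA with a warning.
4. **Enrichment test**: fold change = (bait mean FOT + ε)/(control mean
   FOT + ε), p-value from a two-tailed unpaired Student t-test on
   log10(FOT + ε) (Welch available via `var_equal = FALSE`). `ENRICHED`
   requires fold ≥ 3, p ≤ 0.05, and the peptide filter. No multiple
   testing correction is applied to the headline screen — it is a
   candidate screen at raw p — but BH q-values are reported alongside.

The pseudocount ε defaults to half the smallest nonzero FOT in the table:
scale-aware, keeps ratios finite, and retains proteins entirely absent
from one group (the interesting extreme of a proximity experiment) rather
than dropping them. Whether the original p-values were computed on raw or
log intensities is unstated; the log scale is variance-stabilising for
multiplicative noise and is the default here.

The generator (`simulate_proteomics()`) plants log-normal abundances
(meanlog log(1e6), sdlog 1.5 — the spread a label-free experiment
typically covers), multiplicative replicate noise at a given CV, a
planted fold on the bait mean of enriched proteins, optional dropout
zeros, and a configurable fraction of single-peptide background proteins.
Planted hits always carry ≥ 2 peptides (bait-proximal preys are well
covered in practice); the filter is still exercised by the background.
Note one real effect the screen inherits: planting 30 × 8-fold proteins
inflates the bait totals, so FOT compresses measured fold changes (≈ 8
planted → ≈ 5 measured). The screen's thresholds are applied to the
measured values, exactly as they would be on real data.

# Quantitative assay reductions

**ddCT** (`delta_delta_ct()`): per sample, ΔCt = Ct(target) −
Ct(reference gene); ΔΔCt subtracts the calibrator-group mean; fold =
`efficiency^(−ΔΔCt)` with efficiency 2 by default (no efficiency
calibration is assumed; the parameter is exposed). Group summaries are
geometric means — the calibrator is exactly 1 by construction. One noise
fact worth knowing: with independent N(0, σ) noise on every Ct, the
group-mean ΔΔCt has standard deviation `σ·sqrt(4/n)` (two genes × two
groups over n replicates), i.e. 0.115 cycles at σ = 0.1, n = 3, so a
planted 2-fold change is recovered within ±10% in only ≈ 80% of runs —
the validation script computes this in-band rate, and it is a property of
the assay's noise propagation, not of the estimator (the geometric mean
is the maximum-likelihood reduction here).

**q-TRAP RTA** (`qtrap_rta()`): RTA = `efficiency^(−(Ct − mean control
Ct))` per replicate, geometric-mean summaries, control exactly 1 (or
100%). The ΔCt mode is the default standardisation; a standard-curve mode
is intentionally out of scope — calibrated Ct input is assumed.

**TRF length** (`trf_mean_length()`): sizes are assigned to lane bins by
linear interpolation of log(size) against ladder band positions (the
log-linear agarose regime), background is subtracted (default: modal
intensity outside the analysis window, 0 when the window covers the
lane), and the mean is the intensity-weighted harmonic form
`sum(I) / sum(I / L)`. Gel-quantification workflows typically report only
the imaging software used, not a formula, so the reduction is a package
choice: the harmonic form weights the smear by molar abundance (probe
signal scales with fragment length, so intensity/length counts molecules)
and is the canonical densitometric reduction; it is scale-invariant,
monotone under size shifts, and bounded
by the window's size range. Degenerate inputs — all-zero windows, windows
outside the ladder, non-monotone ladders — are errors, not NaNs. The lane
generator places a log-Gaussian smear and its ladder through the same
monotone migration map; with the default sd_log = 0.15 the analytic bias
of the harmonic mean under a log-Gaussian profile is exp(−sd_log²/2) ≈
1.1%, comfortably inside the 5% recovery target.

# Validation sizes and determinism

All generators are seed-deterministic (identical seeds give bit-identical
output). The shipped validation uses: 10,000 error-free reads for exact
round-trip recovery; 1,000 randomized read/reference pairs against the
exhaustive boundary oracle; 50,000 reads at 0.5% per-base error for
proportion recovery (observed maximum class error ≈ 0.6 points); 20
seeds × (300 background + 30 planted) proteins for screen sensitivity and
FDR plus 50 null seeds; 100 seeds each for the ddCT and RTA recoveries;
and two TRF lanes plus a closed-form two-spike case (16/3 kb exactly).
These sizes were chosen so each property is measured well inside its
tolerance while the whole suite runs in well under a minute per stage.

# Known limitations

* The profiler is amplicon-scale by design: no genome-wide alignment, no
  PCR-duplicate handling, no quality-aware calling, and no statistical
  test between group profiles (proportions are reported; comparison is
  left to the caller).
* Terminus classes follow the three-class reporting legend plus
  `OTHER_TAIL`; mixed tails are not decomposed further.
* The proteomics module starts from quantified tables — no spectrum
  search, protein inference, GO enrichment, or network retrieval (only
  node/edge export against a user-supplied interaction list).
* TRF profiles arrive already digitised; gel image processing is out of
  scope.
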