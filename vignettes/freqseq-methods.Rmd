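---
title: "Counting alleles from barcoded amplicon reads: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting alleles from barcoded amplicon reads: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(freqseq)
```

This vignette explains the models behind `freqseq`, the parameters that
matter, what the simulator does and does not emulate, and the design
choices made where the underlying protocol leaves the computational policy
open.

## The read model

Every read produced by the two-round bridging-primer protocol has a fixed
architecture, 0-based half-open coordinates from the sequencing end:

* `[0, 6)` — the 6-nt sample barcode, the very first bases sequenced;
* `[6, 23)` — the 17-nt M13f universal adapter `GTAAAACGACGGCCAGT`;
* `[23, …)` — the locus-specific forward primer (the *anchor*, typically
  around 22 nt), followed by the *diagnostic window* in which the alleles
  differ.

The consumed prefix is therefore 23 + anchor length, about 40–45 bases,
which is why on 50-bp reads a polymorphism must sit within the first
handful of window bases to be visible. `build_read()` constructs exactly
this layout; `locate_m13f()` tests it at the fixed offset rather than
scanning, because the construct defines the position — a scan would only
admit reads the protocol cannot produce. Since pooled flow-cell lanes
carry unrelated material, reads failing the M13f test are categorised
`NO_M13F` and dropped, not errors.

## Barcode design

Barcodes are drawn from the full 4^6 space by a seeded shuffle with greedy
acceptance under the pairwise Hamming-distance constraint, restarting until
the composition constraint also holds, and failing explicitly if the
request is infeasible. Two constraints matter:

* **Minimum pairwise distance, default 2.** A distance-2 code makes every
  single substitution *detectable* (the corrupted barcode matches nothing)
  but not *correctable* (it may be at distance 1 from two library members).
  Demultiplexing is therefore exact-match only, and reads with corrupted
  barcodes are discarded as `BAD_BARCODE` rather than guessed. A
  `min_dist = 3` option exists for libraries that need correction
  capability.
* **Composition balance over the first four cycles.** Illumina cluster
  identification degrades when the first sequencing cycles are
  base-biased. We enforce each base frequency at positions 1–4 to lie
  within `tol = max(0.15, 2*sqrt(3/16/n))` of 1/4 — the binomial
  two-sigma band around uniform usage, floored at 0.15 so that small
  libraries are not asked for impossible balance. The per-position
  chi-square statistic against uniformity is reported
  (`validate_barcodes()`) but is deliberately not the accept/reject rule,
  since no principled threshold exists at these small n.

The bridging primer for a barcode is the fixed 58-nt prefix, the barcode,
then the M13f tail — 81 nt in total; its first 17 nt and the reverse
complement of its last 17 nt are the two amplification primers used to
regenerate the library.

## The simulator, and what passing its tests shows

`simulate_sample()` draws each read's source allele iid from the declared
frequencies (a multinomial overall), applies iid per-base substitutions
(uniform over the three alternative bases), and emits constant Phred-30
qualities. Every draw and every mutated position is recorded in a truth
manifest, which is what makes the counting engine testable read-for-read.

Defaults are chosen to match the protocol's realistic operating point:
read length 50 (the binding constraint for window placement), per-base
error rate up to 10^-3 in the standard scenarios, and 1.5×10^5 reads per
sample for depth-sensitive checks — the order of magnitude a pooled lane
delivers per locus and timepoint.

The simulator deliberately does **not** model: PCR amplification
stochasticity or polymerase errors, cluster-calling bias, indel
sequencing errors (available as an option, off by default), quality-score
variation, or day-to-day error-rate drift. Consequently, passing
simulation-based tests demonstrates that the *counting and estimation
machinery* is correct and unbiased under a clean substitution-error
channel; it does not certify accuracy on real data, where amplification
bias exists — that is precisely what the calibration layer and
pure-sample controls are for.

## Allele assignment

For each candidate allele the engine computes the global unit-cost edit
distance between the read segment from offset 23 and the allele's
anchor-plus-window reference, both truncated to the shorter length, by
banded dynamic programming (Rcpp). The read is assigned to the
minimal-distance allele iff that distance is at most `max_edits` **and**
the runner-up is at least `min_margin` further away; equal-best reads are
`AMBIGUOUS_ALLELE`, everything worse than `max_edits` is `NO_ALLELE`.

Numerical and policy choices:

* `max_edits` defaults to `ceiling(compared_length / 10)` — roughly a 10%
  divergence budget that scales with how much of the reference the read
  actually covers; it is configurable because the original analysis
  software's thresholds are not published.
* `min_margin` defaults to 1: one substitution in the diagnostic base must
  not be silently resolved in favour of either allele.
* The DP band is `(max allele length difference) + max_edits +
  max(1, min_margin)`; distances inside the band are exact, larger ones
  are reported as the cap `band + 1`. The cap preserves ordering and
  margins at the decision boundary while keeping the scan linear in read
  count; tests verify exact agreement with full unbanded DP whenever the
  band covers the compared length.
* Junction alleles carry allele-specific anchors, so anchor and window are
  compared jointly: a read can only score well against the allele whose
  anchor it actually contains.
* Base qualities are parsed and reported per category but not used in
  assignment; a quality-aware error model is future work.
* Reads are taken as written on the sequencing strand; no
  reverse-complement search (the construct fixes the orientation).
* Ties and all thresholds are deterministic, so shuffling input order can
  never change a count (tested as a property).

## From counts to frequencies

Within a sample all allele counts share the total-assigned denominator, so
frequencies sum to one exactly. Intervals are Wilson score by default —
well-behaved at the extreme frequencies (0.1–1%) this assay is used for,
where the Wald interval collapses; Clopper-Pearson is available when a
conservative exact interval is preferred. Empirical coverage at the 95%
level is verified in the test suite to lie in [0.93, 0.97] at
p ∈ {0.001, 0.01, 0.5}, n = 10^5.

**Calibration.** Control mixtures with flow-cytometry-determined expected
frequencies are fit per locus as `observed = a·expected² + b·expected + c`
by unconstrained least squares (an endpoint-pinned option exists, off by
default, since nothing forces the fit through (0,0) and (1,1)).
Correction inverts the map: the closed-form quadratic root on the
monotone branch, a linear fallback when `|a| < 1e-10`, and bisection if
the discriminant degenerates numerically. Monotonicity on [0, 1]
(`b ≥ 0` and `2a + b ≥ 0`) is a hard precondition for inversion; a
non-monotone fit warns at fit time and errors at inversion time.
Observations outside the fitted range on [0, 1] are clamped to the
nearest endpoint and flagged rather than extrapolated.

**Pure-sample error rates.** A sample consisting of a single allele
estimates the detection floor as discordant/total over *assigned* reads
only — discarded reads never enter the denominator, since the floor of
interest is the rate at which a read is confidently assigned to the wrong
type. Rates are summarised by the median across control samples.

**Between-run comparison.** Error rates from different sequencing dates
are compared per locus by grouped-binomial logistic regression of the
discordant proportion on run identity, judged by the deviance test
against the intercept-only model. A run with zero (or saturated)
discordant counts puts the MLE on the boundary, so a Haldane-Anscombe
continuity correction (+0.5 discordant, +1 total for every run of that
locus) is applied and flagged in the output. P-values are reported per
locus without multiplicity adjustment, which is stated in the printout.

## Problem sizes and runtime choices

The test suite runs every statistical property at the sizes it needs to be
informative rather than at maximal scale: depth-sensitive recovery checks
use 1.5×10^5 reads per mixture (the assay's realistic depth), interval
coverage uses 1,000 replicates per operating point, Monte-Carlo fit checks
use 50 seeds, and the exhaustive barcode-code oracle runs on the length-2
space where exact enumeration is feasible. The acceptance script's
pipeline target uses one 150,000-read sample and completes in seconds.

## Known limitations

* The assignment policy (edit-distance scoring, thresholds, tie-breaking)
  is this package's own declared policy, configurable but not claimed to
  be identical to the original closed-source analysis tool, whose scoring
  is unpublished.
* The substitution-only error channel understates real Illumina error
  structure (context effects, quality decay along the read, rare indels).
* A hierarchical model of day-to-day error variation, and using base
  qualities as covariates in assignment, are out of scope; the between-run
  comparison quantifies *that* runs differ, not why.
* Barcode demultiplexing never error-corrects; with distance-2 libraries
  roughly `1 - (1 - e)^6` of reads are lost to barcode errors at per-base
  error rate `e`. This is a deliberate trade of yield for purity.
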