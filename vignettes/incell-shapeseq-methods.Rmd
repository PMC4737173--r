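---
title: "Methods: from probing reads to reactivities, structures and function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from probing reads to reactivities, structures and function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapeseqr)
```

## The experiment the package models

In a targeted in-cell chemical probing experiment, a fast-acting SHAPE
reagent (e.g. 1M7) acylates the 2'-OH of conformationally flexible RNA
nucleotides inside living cells; a solvent-only culture provides the control.
Reverse transcription (RT) from a highly specific primer then converts each
RNA into a cDNA whose 5' end records where the enzyme halted — one nucleotide
before a modification, or at a position of natural polymerase drop-off.
Paired-end sequencing of these cDNAs, demultiplexed into the reagent (+) and
control (−) channels by a short handle sequence, yields per-nucleotide stop
counts that are the sufficient statistic of the experiment. Because the
probing is performed on the same culture whose fluorescent-reporter output is
measured, per-nucleotide structural information can be coupled directly to
gene expression.

The package covers the computational side of this experiment end to end:
read processing, reactivity estimation, reactivity-constrained secondary
structure prediction, structure–function statistics, cleavage QC, and a
generative simulator used throughout the test suite.

## Coordinates and the stop convention

Position 1 is the transcription start of the target; the probed region
`[1, n]` lies strictly 5' of the RT primer site. RT walks the template 3'→5',
so it encounters modification site `n` first. A cDNA whose 5'-most covered
target position is `p` implies a stop at modification site `k = p − 1`;
coverage of position 1 (`p = 1`) is a full-length cDNA. Consequently the
transcripts that *reached* site `k` — and could have stopped there — are
exactly those that stopped at a site `i ≤ k` or ran to full length. The
aligner enforces this geometry: placements may soft-clip a 3' overhang
(adapter remnants shorter than the trimmer's minimum overlap, anchored on at
least 12 target nucleotides), because every genuine cDNA ends at the
target's 3' end; reads that would imply a stop inside the primer region are
rejected as no-hits rather than miscounted.

## The reactivity model

Let `X_k`, `Y_k` be the (+) and (−) channel stop counts and `X_full`,
`Y_full` the full-length counts. The per-encounter stop frequencies are

    beta_k  = X_k / (sum_{i<=k} X_i + X_full)      (+ channel)
    gamma_k = Y_k / (sum_{i<=k} Y_i + Y_full)      (− channel)

These are the per-site maximum-likelihood estimates of the RT stop process,
because the walk factorizes into independent binomial experiments per site
(reads reaching the site either stop or continue). Under the single-hit
Poisson modification model, the reagent-attributable modification intensity
at site `k` is the natural-drop-off-corrected log survival deficit

    raw_k = max(0, ln(1 − gamma_k) − ln(1 − beta_k))

and `theta = raw / sum(raw)` is its projection onto the probability simplex,
so `theta_k` is the probability that a modification-bearing transcript was
modified at site `k`. The test suite requires that this closed form agree,
to 1e−3, with a dense grid search of the explicit two-channel binomial
likelihood on every random count table it generates — so any discrepancy
between the algebra and the underlying stop-process model surfaces as a test
failure rather than silent drift.

Numerical policy: negative raw intensities (more natural drop-off than
signal) are truncated to zero *before* normalization; frequencies of exactly
1 (every surviving transcript stopped) are clamped to `1 − 1e−6` with a
warning; sites never reached by any cDNA are flagged unobserved and written
with the `−999` sentinel in all output formats. An all-zero signal returns a
flagged degenerate profile rather than an error, because orthogonal-pair
controls legitimately produce near-null signal.

Reactivities are reported on the mean-1 scale, `rho = n * theta`, which is
the scale on which the class thresholds live: `rho > 1.25` highly reactive,
`0.5 ≤ rho ≤ 1.25` moderately reactive, `rho < 0.5` weakly reactive (both
boundaries are assigned to the moderate class; the thresholds are arguments
of `classify_reactivity()`). `estimate_theta()` normalizes over the probed
sites only — the "no modification" outcome is not a simplex coordinate; the
unnormalized intensities are recoverable as they are proportional to
`theta`, and the mean-1 `rho` convention is consistent with class thresholds
centered near 1.

Replicates are combined positionwise by arithmetic mean and sample standard
deviation (n−1), and conditions are compared with one-sided Welch tests
(Satterthwaite degrees of freedom). With only three replicates per group the
Welch test is known to be conservative (empirical size ≈ 0.09 at a nominal
0.10); the package's calibration check therefore draws 10 values per group,
where the t-approximation is in force, and users should read p-values from
triplicate data with that conservatism in mind. DMS-mode data can be
restricted to its informative bases with `mask_by_base()` (A/C by default),
which sets other positions to missing — distinct from a zero reactivity.

## Folding constraints

Reactivity is converted to a per-nucleotide pseudo-free-energy term

    dG_i = m * ln(rho_i + 1) + b        (kcal/mol)

with defaults `m = 1.1`, `b = −0.3`, the parameter pair used for in-cell
probing data on this platform; missing positions contribute nothing. Free
energy minimization itself is delegated to the ViennaRNA `RNAfold` engine
(Turner nearest-neighbor parameters) through its standard SHAPE-restraint
mechanism, with the `m`/`b` pair passed through; the engine name and version
are recorded on every returned model. The package's contribution is the
constraint generation and bookkeeping, not the thermodynamics. Predicted
energies from different engines or parameter vintages can differ by a few
tenths of a kcal/mol for hairpin-sized inputs; comparisons against energies
computed elsewhere should allow about ±0.5 kcal/mol unless the engine and
parameter set are matched. `subsequence_mfe_energy()` folds the extracted
interval in isolation, deliberately blind to flanking context.

## Structure–function statistics

Gene expression is read out as corrected FL/OD: fluorescence and OD600 are
blank-subtracted, fluorescence is divided by OD, and the FL/OD of an
autofluorescence-control culture is subtracted. Fold changes are ratios of
replicate means (not means of ratios), matching the convention of
normalizing to the control state's mean.

To locate the functional Shine-Dalgarno sequence inside an AG-rich ribosome
binding region, reactivities are summed over every six-nucleotide window in
the ON and OFF states and the window with the largest ON−OFF difference is
taken (ties resolve to the 5'-most start). Missing reactivities contribute 0
to window sums by default; a `"skip"` policy that invalidates windows
containing missing values is available. The reactivity fold change over a
window is the ratio of window sums; the window is an explicit parameter so
that sub-windows (e.g. the 5' four nucleotides of the RBS, where increases
concentrate) can be reported alongside the scan's winner.

## Cleavage-spike QC

A double-stranded RNase cleavage event truncates transcripts in both
channels alike, whereas modification signal lives in the (+) channel only.
`detect_spikes()` therefore requires a coincident outlier in BOTH raw
fragment distributions: robust z-score `(count − median)/(1.4826·MAD) ≥ 5`
and at least 5% of the channel's reads at the site, in both channels.
Median/MAD statistics resist the heavy-tailed stop distributions genuine
reactivity produces; full-length counts are excluded from the background.
The thresholds are engineering defaults validated by simulation: planted
dual-channel spikes carrying ≥20% of reads are always called, and the
false-call rate on flat Poisson backgrounds is below 1% per target. Called
positions should be treated as cleavage-confounded in downstream reactivity
interpretation.

## The simulator and what passing tests mean

`simulate_stop_counts()` draws each channel's counts in a single multinomial
step from the exact stop-process distribution: RT walks sites `n → 1`,
stopping at site `k` with probability `gamma_k` (both channels) plus, in the
(+) channel, the modification-induced probability `1 − exp(−theta_true_k)`
— i.e. `theta_true` holds Poisson modification intensities, so the
estimator's log-survival inversion recovers `theta_true/sum(theta_true)`
exactly in expectation and parameter-recovery tests measure statistical
error only. `simulate_reads()` turns counts into read pairs: a concrete
handle instance, target-derived sequence starting at the stop-encoding
position, adapter read-through for short fragments, and an optional fraction
of handle-less RT-primer/adapter ligation dimers. Default conditions are
2×35 bp reads, a 60-nt probed region with a 20-nt primer site, 1e5 reads
per channel, natural drop-off uniform in [0.001, 0.01] per site and total
modification intensity 0.5 — a deeply covered targeted experiment in the
single-hit regime.

The simulator emulates: single-hit modification, position-dependent natural
drop-off, full-length reads, handle barcodes, adapter read-through and
ligation dimers. It does not emulate PCR amplification bias,
ligation-efficiency gradients, sequencing errors (off by default; a uniform
substitution rate exists only to stress the aligner) or base-calling
quality. Passing round-trip and recovery tests therefore demonstrates
correctness of the inference given the assay's idealized generative model —
not robustness to library-preparation artifacts, which real data QC (dimer
fraction, spike calls, replicate SDs) must assess.

Problem sizes used by the shipped checks — 500 grid-oracle tables (n ≤ 5,
≤ 200 reads), recovery at depths 1e4/1e5/1e6 on a 50-nt target, a
10,000-read pipeline round trip, 1,000-profile normalization sweeps, 1,000
null spike simulations and 10,000 Welch trials — were chosen so the whole
suite runs in well under a minute per module on a single CPU while keeping
Monte-Carlo standard errors an order of magnitude below the asserted
tolerances.

## Known limitations

* The estimator has no sequencing-error or PCR-bias model beyond what the
  (−) channel subtracts.
* Multi-mapping reads are discarded, not fractionally assigned: targets in a
  run are assumed orthogonal, and ambiguity is treated as a configuration
  error.
* Pseudoknots are outside the folding model (a kissing-loop interaction
  appears only as unexplained high loop reactivity).
* The channel handle sequences are run configuration, defaulting to the
  disjoint IUPAC patterns `RRRY`/`YYYR`; the exact handles of any given
  library prep must be supplied.
* Reactivity classes and spike thresholds are conventions, not inferences;
  both are exposed as arguments.
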