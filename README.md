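# shapeseqr

Analysis pipeline for **targeted in-cell SHAPE-Seq** experiments: chemical
probing of RNA structure performed directly in living bacterial cells,
coupled to a fluorescence measurement of gene expression from the same
culture. The package takes an experiment from raw probing reads to
per-nucleotide reactivities, reactivity-constrained secondary-structure
models, and quantitative statistics linking RNA structural change to
expression change — and ships a generative simulator so every stage is
testable without external data.

## What it computes

**Reactivity estimation.** SHAPE reagents acylate flexible nucleotides;
reverse transcription halts one nucleotide before each modification, so the
5' ends of cDNAs encode modification positions. With stop counts `X_k`
(reagent, "+") and `Y_k` (solvent control, "−") and per-encounter stop
frequencies

```
beta_k  = X_k / (Σ_{i≤k} X_i + X_full)
gamma_k = Y_k / (Σ_{i≤k} Y_i + Y_full)
```

the drop-off-corrected modification probabilities and mean-1 reactivities are

```
theta_k ∝ max(0, ln(1 − gamma_k) − ln(1 − beta_k)),   Σ theta = 1
rho_k   = n · theta_k
```

with `rho > 1.25` highly, `0.5–1.25` moderately and `< 0.5` weakly reactive.

**Around the estimator:** adapter trimming, IUPAC-handle channel
demultiplexing, a targeted stop-aware aligner, ligation-dimer QC; pseudo-free
energy constraints `ΔG_i = m·ln(rho_i+1) + b` (defaults m = 1.1, b = −0.3
kcal/mol) fed to ViennaRNA's `RNAfold` for MFE structure prediction;
FL/OD expression normalization, six-nucleotide Shine-Dalgarno window scans
and window/expression fold changes; dual-channel robust-z detection of
double-stranded RNase cleavage spikes; and a seeded simulator of the whole
experiment.

## Worked example

Simulate a deeply covered probing experiment, estimate reactivities, and
couple a structural change to function:

```r
library(shapeseqr)

tg    <- synthetic_target()                       # 60-nt probed region + primer
truth <- simulation_truth(tg, depth_plus = 50000, depth_minus = 50000, seed = 7)
counts <- simulate_stop_counts(truth)
counts$plus
#> <fragment_counts> synthRNA (plus) n = 60  total = 50000  full-length = 21917

theta <- estimate_theta(counts$plus, counts$minus)
rho   <- theta_to_rho(theta)
round(head(rho$rho, 10), 3)
#>  [1] 0.544 0.220 0.152 0.444 0.107 0.776 0.005 0.759 0.106 2.857
table(classify_reactivity(rho$rho))
#>     weak moderate     high
#>       28       14       18

recovery_metrics(theta, truth)     # estimate vs simulated ground truth
#> $max_abs_error   0.00437
#> $rmse            0.00124
#> $rank_correlation 0.993
```

The ten reactivities are the first probed nucleotides on the mean-1 `rho`
scale (2.857 at position 10 is a highly reactive, likely unpaired site;
0.005 at position 7 a strongly protected one), and the recovery metrics show
the estimator reproducing the simulated modification probabilities to a few
parts in a thousand at this depth.

Structure–function: scan for the Shine-Dalgarno window whose exposure
changes most between functional states, then fold with reactivity
constraints:

```r
pr   <- synthetic_rbs_profiles()            # riboregulator-like ON/OFF fixture
scan <- sd_window_scan(pr$on, pr$off)
c(scan$best_start, scan$best_diff)
#> [1] 36.0  9.6                     # RBS at nucleotides 36-41
window_fold_change(pr$on, pr$off, pr$rbs_window)
#> [1] 6.333333                      # RBS reactivity increase, ON vs OFF

fold_mfe("GGCGCAAGGCUAGCUUAGCGCC", rho = rep(0.2, 22))
#> GGCGCAAGGCUAGCUUAGCGCC
#> ((((((((.....))).))))) (-12.70 kcal/mol, probing-constrained)
```

FASTQ-level processing is driven by a YAML run configuration
(`run_pipeline()`, or `inst/scripts/incell-shapeseq.R` from the shell), and
produces stop-count tables, reactivity tables (with `-999` marking
unobserved sites) and a JSON QC summary including the ligation-dimer
fraction.

See `vignettes/incell-shapeseq-methods.Rmd` for the model, its assumptions,
numerical policies and limitations.

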