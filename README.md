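# flexbench

Benchmarking per-residue protein flexibility predictions against NMR
ensembles and crystallographic B-factors.

## What it does

Methods that predict protein flexibility — coarse-grained simulations,
normal-mode models — all emit a per-residue root mean square fluctuation
(RMSF) profile. `flexbench` evaluates such predictions the way flexibility
benchmarks are actually run:

* **Experimental profiles.** From a multi-model NMR ensemble: iterative
  superposition (Kabsch) onto a converged mean structure, then
  `RMSF_i = sqrt( (1/M) Σ_j |x_i(j) − ⟨x_i⟩|² )`. From an X-ray structure:
  the Debye–Waller conversion `RMSF_i = sqrt(3 B_i / 8π²)` of the C-alpha
  B-factor column.
* **Built-in predictor.** An anisotropic elastic network on the C-alpha
  trace — identical springs between all residue pairs within a cutoff
  (default 12 Å), potential `E = (γ/2) Σ (d_ij − d⁰_ij)²` — diagonalized
  into normal modes; predicted fluctuations are the mode covariance
  `⟨Δr_i²⟩ ∝ Σ_{k>6} λ_k⁻¹ |v_k,i|²` over the internal modes.
* **Pre-processing.** Terminal segments whose fluctuation exceeds the
  profile mean + 1 SD are truncated (iteratively for NMR, one pass for
  X-ray); profiles are normalized to unit maximum (RMSFN) and replicate
  predictions are normalize-averaged.
* **Statistics.** Per-protein Pearson (`r_p`) and Spearman (`r_s`)
  correlations over the kept residues; group means, 0.1-bin histograms,
  cumulative counts and distribution skewness; two-way ANOVA
  (method × secondary-structure class, Type II SS) per structure
  determination method; paired Student's tests and a signed significance
  matrix of method comparisons.
* **Synthetic ground truth.** Generators for idealized C-alpha traces,
  Gaussian ensembles with inflated termini, B-factor-encoded structures
  and whole benchmarks with tunable method fidelity — every pipeline stage
  is testable against known answers.

PDB input/output is plain fixed-column text (multi-model `MODEL`/`ENDMDL`
supported); results are emitted as CSV tables.

## Worked example

```r
library(flexbench)

# a synthetic benchmark: 8 proteins, NMR + X-ray, two simulated methods
bench <- make_benchmark(8, methods = c(good = 0.9, poor = 0.3), seed = 11)
res <- evaluate_benchmark(bench)
print(res)
#> Benchmark results: 8 proteins x 2 methods (0 failed)
#>  method expt_method n  mean_r_p  mean_r_s
#>    good         nmr 4 0.6598258 0.6437953
#>    poor         nmr 4 0.3529999 0.3306712
#>    good        xray 4 0.9450537 0.8593124
#>    poor        xray 4 0.2028233 0.1763674
print(res$matrices$nmr)
#> Significance matrix (alpha = 0.05; upper: r_p, lower: r_s)
#>      good poor
#> good .    +
#> poor -    .
```

The fidelity-0.9 method tracks the true fluctuation profile closely
(`r_p` ≈ 0.66 against sampled NMR-style ensembles, ≈ 0.95 against exact
X-ray B-factors), the fidelity-0.3 method barely correlates, and the
significance matrix marks the difference positive-significant for both
coefficients (`+` above the diagonal: Pearson; `-` below: the mirrored
Spearman cell).

Per-protein evaluation shows the truncation stage at work — the boosted
termini of the experimental profile are removed before comparison:

```r
ref  <- make_trace(60, "mixed", seed = 7)
sig  <- terminal_sigma_profile(60, 0.25, terminal_boost = 4, terminal_length = 6)
expt <- make_ensemble(ref, sig, n_models = 25, seed = 8)
truncate_termini(ensemble_rmsf(expt, source = "nmr"), iterate = TRUE)
#> Truncation: keep residues 7-54 (removed 6 N-terminal, 6 C-terminal)
```

A `write_benchmark_results(res, "out/")` call (or
`evaluate_benchmark(..., out_dir = "out/")`) writes `per_protein.csv`,
`group_means.csv`, `histograms.csv`, `cumulative.csv`, `skewness.csv`,
`anova.csv`, `pairs.csv`, `matrix.csv`, `length_dependence.csv` and
`failures.csv`.

A thin command-line wrapper over the same functions ships in
`inst/scripts/flexbench.R` (subcommands `predict-enm`, `profile`,
`truncate`, `compare`, `synth`, `benchmark`).

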