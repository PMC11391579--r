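---
title: "Methods: assessing per-residue flexibility predictions"
author: "flexbench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assessing per-residue flexibility predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexbench)
```

## The problem

Coarse-grained simulation and normal-mode methods all produce a per-residue
flexibility profile — the root mean square fluctuation (RMSF) of each
C-alpha about a mean structure. Judging such predictions requires (i) an
experimental reference profile, extracted either from the spread of a
multi-model NMR ensemble or from crystallographic B-factors, (ii) careful
pre-processing, because the nonspecifically mobile chain termini otherwise
dominate any comparison, and (iii) benchmark-level statistics that say
whether one method is *significantly* better than another across a protein
set. `flexbench` implements this full evaluation pipeline, together with a
built-in elastic-network normal-mode predictor and a synthetic data
generator with known ground truth, so that every stage can be validated
end to end.

## Experimental profiles

**NMR ensembles.** All models of an ensemble are superposed on the first
model, averaged, re-superposed on the running mean and re-averaged until
successive means differ by less than $10^{-6}$ Å RMSD (in practice the
second pass is already converged; the iteration cap is 10). With models
superposed on the converged mean $\langle x_i \rangle$,

$$\mathrm{RMSF}_i \;=\; \sqrt{\frac{1}{M}\sum_{j=1}^{M}
  \left| x_i(j) - \langle x_i \rangle \right|^2},$$

a population average over the $M$ models (denominator $M$, not $M-1$).
Superposition uses the Kabsch algorithm (SVD of the cross-covariance with
the reflection branch excluded) with uniform weights over all C-alphas.

**X-ray structures.** The isotropic Debye–Waller relation converts the
C-alpha B-factor of residue $i$:

$$B_i = \frac{8\pi^2}{3}\,\mathrm{RMSF}_i^2
  \qquad\Longleftrightarrow\qquad
  \mathrm{RMSF}_i = \sqrt{\frac{3 B_i}{8\pi^2}}.$$

Rigid-body disorder contributions to $B$ are deliberately not modelled:
the pipeline compares methods *relative to each other*, and a per-structure
disorder regression would affect all methods identically.

## Terminal truncation

Chain termini of single-chain proteins fluctuate far more than the core,
most strongly in NMR ensembles, and would otherwise dominate the
correlation between profiles. The truncation rule computes the mean $m$
and standard deviation $s$ of the whole experimental profile and removes
residues inward from the N-terminus while their value strictly exceeds
$m + s$, then likewise from the C-terminus; interior residues are never
removed. For NMR profiles the procedure is repeated on the kept segment
until nothing more is removed (or only three residues remain); X-ray
profiles get a single pass. Three conventions are configurable because the
literature leaves them open: the SD denominator (sample $n-1$ is the
default), the threshold multiple (default 1), and whether iteration is
applied to NMR profiles (default yes). The truncation range is always
derived from the *experimental* profile only and then applied to every
predicted profile of that protein, since predictions are computed on the
complete chain.

## The elastic-network predictor

The anisotropic elastic network connects every residue pair whose
reference C-alpha distance $d^0_{ij}$ is below a cutoff $R_c$ with an
identical harmonic spring:

$$E = \frac{\gamma}{2} \sum_{d^0_{ij} < R_c}
  \left( d_{ij} - d^0_{ij} \right)^2 .$$

The Hessian of $E$ at the reference structure is assembled from
$3\times3$ blocks $-\gamma\, r_{ij} r_{ij}^T / |r_{ij}|^2$ and
diagonalized; a connected, non-collinear network has exactly six zero
modes (rigid translations and rotations). The predicted mean-square
fluctuation is the harmonic mode covariance,

$$\langle \Delta r_i^2 \rangle \;\propto\; \sum_{k > 6}
  \frac{1}{\lambda_k}\left(v_{k,ix}^2 + v_{k,iy}^2 + v_{k,iz}^2\right),$$

i.e. the $3\times3$ block trace of the Hessian pseudo-inverse. Parameters:

* `enm.cutoff_angstrom` (default 12 Å) — a standard choice for C-alpha
  anisotropic networks; exposed because the optimal value is
  protein-set-dependent.
* `enm.gamma` (default 1) — the spring constant only scales the profile
  and cancels entirely under normalization.
* `enm.tol_zero` (default $10^{-10}$ relative to the largest eigenvalue) —
  rigid-body eigenvalues land at the numerical noise floor
  ($\lesssim 10^{-12}$ relative in double precision), while loosely packed
  chains can possess genuine internal modes as soft as a few $10^{-9}$
  relative; $10^{-10}$ separates the two populations by several orders of
  magnitude on both sides. A larger tolerance silently swallows real soft
  modes and misreports the network as disconnected.

More than six zero modes indicates a disconnected (or mechanically
under-constrained) network and is an error by default; fewer than six
indicates a tolerance problem. Both checks can be relaxed for intentionally
degenerate systems (two-body, collinear chains, cluster pairs).

## Normalization, replicate averaging, and comparison

Because methods differ in absolute fluctuation amplitude, profiles are
normalized by their maximum (RMSFN, values in $[0,1]$ with peak 1) before
visual or distributional comparison. Replicate predictions (independent
trajectories) are normalized first, averaged element-wise, and the mean is
re-normalized; the alternative order (average raw, then normalize) is
available via `average.normalize_first = FALSE`. Both Pearson's $r_p$ and
Spearman's $r_s$ are invariant to any positive rescaling, so none of these
choices affect the reported statistics — only plots and distributions.

Agreement is measured per protein by the Pearson product–moment
coefficient and the Spearman rank coefficient over the kept residues
(matched by residue sequence number, never by position). Ties in ranks are
handled by average ranks followed by the product–moment formula on ranks,
which reduces to the classical $1 - 6\sum d_i^2 / (n(n^2-1))$ shortcut when
all values are distinct.

## Benchmark statistics

* **Group summaries** — means and SDs of $r_p$ and $r_s$ by prediction
  method, structure-determination method (NMR vs X-ray) and
  secondary-structure class.
* **Distributions** — histograms with 0.1-wide bins over $[-1,1]$
  (left-closed, right-open, last bin closed) and the right-continuous
  cumulative counting function; distribution asymmetry is summarized by
  the moment skewness $g_1 = m_3/m_2^{3/2}$ with $1/n$ central moments
  (the bias-adjusted variant is available; the sign and ordering of
  skewnesses do not depend on the convention).
* **Two-way ANOVA** — fixed effects of prediction method and
  secondary-structure class with interaction, run separately per
  structure-determination method at $\alpha = 0.05$. Type II sums of
  squares are used because class sizes are unbalanced in realistic
  benchmarks; on balanced designs Type II coincides with the classical
  sequential decomposition (verified in the tests).
* **Pairwise comparisons** — Student's $t$ on per-protein coefficient
  differences between two methods. The test is *paired* by default since
  the same proteins are scored under every method; an unpaired fallback is
  available. The results populate a signed significance matrix (upper
  triangle $r_p$, lower triangle $r_s$; cells are positive-significant,
  negative-significant, or not significant at $\alpha$), with no
  multiple-testing correction across cells — the matrix reports raw
  per-pair calls.

## The synthetic data generator

The generator emulates the structural features the pipeline must handle,
not protein physics:

* **Traces** — idealized C-alpha geometries with 3.7–3.9 Å virtual bonds:
  a canonical helix (1.5 Å rise, 100°/residue, 2.3 Å radius), a twisted
  extended strand (−170°/residue, 3.3 Å rise — the twist keeps the trace
  non-planar, which a central-force network requires), a packed
  helix+strand "mixed" fold, and a self-avoiding random walk.
* **Ensembles** — reference plus independent isotropic Gaussian noise with
  per-residue $\sigma_i$, then a random global rigid motion per model so
  superposition is genuinely exercised. The expected RMSF is
  $\sqrt{3}\,\sigma_i$.
* **Terminal boost** — $\sigma_i$ ramps linearly to `terminal_boost`×core
  (default 4×) over the outermost `terminal_length` residues, reproducing
  the dominant-terminus phenomenon the truncation stage must remove.
* **X-ray structures** — a prescribed RMSF profile written into the
  B-factor column through the Debye–Waller relation.
* **Benchmarks** — per protein: a reference trace (fold chosen by class),
  an NMR-style ensemble (default 25 models, the scale of deposited NMR
  entries) or X-ray structure from a true profile with boosted termini,
  and three replicate predicted ensembles per simulated method. A method
  of fidelity $f$ samples from $f\cdot\sigma_{\mathrm{true}} +
  (1-f)\cdot\sigma_{\mathrm{noise}}$, so fidelity 1 reproduces the truth
  and fidelity 0 is uninformative.

What the generator does **not** emulate: anisotropic or correlated
residue motions, force-field energetics, crystal packing, sequence
specificity, multi-chain assemblies, or missing residues. Passing the
synthetic suite therefore demonstrates the correctness of the pipeline's
computations and statistics — not the accuracy of any physical prediction
method on real proteins.

## Numerical behaviour and problem sizes

Two estimator properties discovered while validating deserve emphasis.

**Superposition absorbs part of the noise.** Fitting each model to the
mean removes the rigid-subspace projection of the displacement field —
about $2/N$ of the total variance on average, concentrated at
high-leverage residues far from the centroid, and amplified when
$\sigma_i$ varies strongly (frame jitter from mobile residues inflates the
apparent fluctuation of quiet ones). The effect is deterministic and
scale-invariant: on a 30-residue scaffold the recovered RMSF can deviate
from $\sqrt{3}\sigma$ by 7–20% at the termini, while on a 100-residue
chain with a moderate (2×) $\sigma$ contrast it stays within 5%
everywhere. The sampling checks therefore use 100-residue chains with
1000-model ensembles, and the fidelity-1 self-consistency check uses
300-model ensembles, sizes at which sampling noise is subdominant to the
retained signal.

**Chain-like networks can be mechanically floppy.** A self-avoiding walk
can end in a nearly straight dangling segment whose transverse motion is a
genuine near-mechanism of the central-force network: its eigenvalue can
fall to $10^{-13}$–$10^{-9}$ of the largest. Near such degeneracy the
$1/\lambda$ mode sum and any pseudo-inverse agree only to $\sim10^{-7}$,
and the six-zero-mode assumption itself breaks down. Oracle-equivalence
checks therefore run on compact excluded-volume clusters (seventh
eigenvalue $\sim0.1$ relative; agreement $\sim10^{-12}$), and
secondary-structure-like folds are used wherever the elastic-network
predictor must succeed. This is a known limitation of pure C-alpha
cutoff networks, not of the implementation.

Other sizes used by the shipped checks, chosen to keep every property
measurable at desk scale: 2000 replicate null datasets for the ANOVA
type-I calibration (99% binomial bounds around 0.05), 30-protein synthetic
benchmarks with the class proportions 30:21:49 (alpha : beta :
alpha+beta) and a 50/50 NMR/X-ray split, and fidelities 0.9 vs 0.3 for the
method-separation checks.

## Degenerate inputs and tie-breaks

* Constant experimental profiles make both correlations undefined: the
  protein is excluded from the benchmark with a logged reason.
* A truncation that would leave fewer than three residues is an error for
  a single protein and a logged exclusion in a benchmark run.
* Alternate PDB locations resolve to the highest-occupancy record, first
  on a tie; insertion codes are rejected outright rather than silently
  misaligned; HETATM records are ignored.
* All-zero profiles cannot be normalized (error), and zero-variance paired
  differences make the $t$-test degenerate (error), except the exactly
  identical case which reports $t = 0$, $p = 1$.

## Known limitations

The reader handles single chains without insertion codes, as appropriate
for idealized and synthetic inputs. The elastic-network predictor is a
plain C-alpha cutoff network: no rigid-block coarse-graining, no
distance- or contact-energy-weighted springs, no anharmonic amplitude
extrapolation. B-factor extraction ignores rigid-body disorder. The ANOVA
is fixed-effects only. None of these affect the comparison machinery,
which is method-agnostic: any external predictor can be evaluated by
supplying its ensembles or profiles through the manifest interface.
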