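---
title: "Models and methods in nmrdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in nmrdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrdyn)
```

# Scope

`nmrdyn` analyses solution-NMR protein structure ensembles and ^15^N
backbone relaxation data. It covers four connected tasks:

1. **Ensemble statistics** — an unbiased mean structure from the
   ensemble-averaged inter-atomic distance matrix, and RMSD spreads about
   it after Kabsch superposition.
2. **Model-free dynamics** — Lipari–Szabo (simple and extended) fitting of
   per-residue R1, R2 and heteronuclear-NOE data, with motional-model
   selection and Monte-Carlo parameter errors.
3. **Rotational correlation time** — per-residue apparent tumbling times
   from the R2/R1 ratio, filtered and averaged into a molecular
   `tau_m`.
4. **Validation** — Ramachandran region summaries, Cys~4~–Zn coordination
   geometry checks, and data-driven assignment of cysteines to zinc
   clusters.

A synthetic-data module generates every input class with known ground
truth, so the full pipeline is testable without any structural-database
download.

# The unbiased mean structure

Superposing all conformers onto an arbitrarily chosen reference biases
the resulting average toward that reference. The package instead averages
the full inter-atomic distance matrix over conformers,

$$\bar D_{ij} = \frac{1}{M}\sum_{m=1}^{M} \lVert x_i^{(m)} - x_j^{(m)} \rVert,$$

and back-projects $\bar D$ into Cartesian space by classical scaling
(metric MDS): double-centre $-\tfrac12 \bar D^2$, eigendecompose, and embed
on the top three eigenvectors scaled by the square roots of their
eigenvalues. For a matrix of exact 3-D distances this recovers the point
set up to isometry and reflection (verified to 10^-6^ Å in the test
suite). Averaged matrices are in general non-Euclidean; negative
eigenvalues beyond rank three are expected and reported rather than
treated as errors.

Numerical choices:

* **Degeneracy.** A collinear point set (fewer than two positive Gram
  eigenvalues) cannot be embedded and is an error. A *planar* set embeds
  with a near-zero third eigenvalue and is accepted — the third axis is
  simply flat. A substantially *negative* third eigenvalue means the
  distances are incompatible with any 3-D geometry and is an error.
* **Chirality.** Classical scaling is blind to handedness, so the mirror
  image with the lower Kabsch RMSD to the first conformer is chosen. The
  choice is deterministic; since $\bar D$ is invariant under conformer
  reordering, so is the embedding itself.
* **Superposition.** Kabsch's SVD construction with the determinant
  correction, so a proper rotation is always returned; mirror-image sets
  superpose with a non-zero residual by design. No mass or B-factor
  weighting is applied anywhere (weights are available as an argument).

Ensemble spread is summarised both as the arithmetic mean and as the
root-mean-square of the per-model RMSDs, because reporting conventions
differ between programs; `mean <= rms` always. "Backbone" may be taken as
N/CA/C (`backbone`) or N/CA/C/O (`backbone_O`, the PROCHECK-style
convention); both are one flag apart because published numbers rarely say
which was used.

# Model-free relaxation analysis

The spectral density for an isotropic tumbler with overall correlation
time $\tau_m$ is

$$J(\omega) = \frac{2}{5}\left[\frac{S^2\,\tau_m}{1+(\omega\tau_m)^2}
  + \frac{(S_f^2 - S^2)\,\tau'}{1+(\omega\tau')^2}\right],
  \qquad \frac{1}{\tau'} = \frac{1}{\tau_m} + \frac{1}{\tau_e},$$

the extended two-timescale form; the simple form is the special case
$S_f^2 = 1$. R1, R2 and NOE follow the standard ^15^N dipolar + CSA
expressions, with any chemical-exchange contribution $R_{ex}$ added to R2
only. The five motional models fix parameter subsets:

| model | free parameters        |
|-------|------------------------|
| 1     | $S^2$                  |
| 2     | $S^2,\ \tau_e$         |
| 3     | $S^2,\ R_{ex}$         |
| 4     | $S^2,\ \tau_e,\ R_{ex}$|
| 5     | $S^2,\ \tau_e,\ S_f^2$ |

**Physical constants.** N–H bond length 1.02 Å and ^15^N CSA −160 ppm by
default — conventional model-free values, both overridable in
`fieldConfig()` because published analyses vary (1.00–1.04 Å, −160 to
−172 ppm). The ^15^N gyromagnetic ratio is kept negative so the NOE sign
convention emerges naturally (extreme narrowing limit ≈ −3.5 at 600 MHz
including the CSA contribution to R1).

**Fitting.** $\chi^2 = \sum_k \left[(o_k - p_k)/\sigma_k\right]^2$ over the
three observables, minimised within bounds ($S^2, S_f^2 \in [0,1]$,
$\tau_e \in [0, \tau_m]$, $R_{ex} \in [0, 50\,\mathrm{s^{-1}}]$) from a
deterministic 4-point-per-parameter start grid; the grid is scored in
full and the best four starts are polished with bounded quasi-Newton
iterations. Model 5 is parameterised internally as
$(S_f^2,\ S^2/S_f^2,\ \tau_e)$ so the constraint $S^2 \le S_f^2$ is
enforced structurally rather than by penalty. Agreement with a dense
brute-force grid is asserted in the tests.

**Selection** is Mandel-style, single field: model 1 is accepted if its
$\chi^2$ passes the goodness-of-fit test; otherwise models 2/3 need both a
goodness-of-fit pass and a significant F-test improvement over model 1
(α = 0.20); otherwise the exactly-determined models 4/5 (0 degrees of
freedom) are accepted only when they fit essentially perfectly
($\chi^2 < \chi^2_{0.95,1}$, a deliberately conservative cut — an F-test
against a 0-dof fit is undefined). If nothing passes, the residue is
reported as *fitted to no model*, which is the correct outcome for
physically inconsistent rates. The goodness-of-fit critical value is the
analytic $\chi^2$ quantile by default; a seeded Monte-Carlo null
(`gof = "mc"`, 500 draws by default) is available and reproduces the
analytic cut for well-specified models at these degrees of freedom, at
roughly a 500-fold refitting cost per residue. All thresholds
(α~gof~ = 0.05, α~F~ = 0.20, draw count, 0-dof cut) are arguments.

**Errors.** `mcErrors()` refits the chosen model on noise-perturbed
back-predictions and reports the SD of each refitted parameter;
deterministic for a fixed seed, linear in the noise level (verified to
within ±30% in tests).

# Rotational correlation time from R2/R1

For a rigid residue ($S^2 = 1$, $\tau_e = 0$, $R_{ex} = 0$) the R2/R1
ratio is a monotone function of the tumbling time, so each residue's
apparent $\tau_c$ is obtained by Brent root-finding on a 0.5–50 ns
bracket (peptides to large domains; configurable). Aggregation follows a
two-step, single-pass filter:

1. remove residues with NOE < 0.6 (fast internal motion biases the
   ratio);
2. over the survivors, remove residues whose ratio lies more than one
   standard deviation from the mean (exchange broadening or anisotropy) —
   a *strict* inequality, so an all-identical set loses nothing.

$\tau_m$ is the arithmetic mean of the surviving per-residue $\tau_c$
values. The spread is reported both as SD and SEM because "±" conventions
in published values are ambiguous. The NOE step needs at least two
survivors (an SD must exist); the SD trim may legitimately leave a single
residue, which then defines $\tau_m$ with zero spread. The single pass is
the default reading; `iterate = TRUE` repeats the SD trim to convergence
for sensitivity analysis. Residues whose ratio has no root in the bracket
are reported by number rather than silently dropped.

# Validation

**Ramachandran.** Torsions are computed with the signed IUPAC convention
and classified on a packaged 10°×10° four-region grid in the Morris
style: rectangular core and additional regions around the α, β and
left-handed-α basins, a generous band obtained as a 20° torus dilation of
core+additional, and disallowed elsewhere. Gly (different map), Pro
(ring-restricted φ) and chain-terminal residues are excluded from the
percentages, which are taken over all conformers pooled. The grid is an
approximation to the historical PROCHECK data file — region borders can
shift individual residues by a bin, which is why no test pins an exact
percentage split.

**Zinc sites.** `zincGeometry()` measures the four S–Zn distances, six
S–Zn–S angles and the per-cysteine Cα–Cβ–S, Cβ–S–Zn and (when β-hydrogens
are present) Hβ–Cβ–S angles; `checkZincRestraints()` compares them with
tetrahedral thiolate-zinc targets (S–Zn 2.3 Å, Cα–Cβ–S 114.3558°,
Cβ–S–Zn 109.5°, Hβ–Cβ–S 107.9185°, S–Zn–S 109.5°). The targets carry no
published tolerances; the defaults of 0.1 Å on bonds and 5° on angles are
a package choice sized to typical restrained-refinement deviations.

**Cysteine clustering.** Average-linkage hierarchical clustering of the
ensemble-mean SG–SG distance matrix, cut at two clusters, mirrors the
observation that zinc-ligating cysteines cluster spatially even in
calculations run without zinc restraints. With eight cysteines, any split
other than 4+4 is an error that reports the offending partition; a mean
silhouette width quantifies the separation.

# The synthetic-data generators

All generators are pure functions of their arguments and a seed, and they
restore the caller's RNG state.

* `makeTemplate()` builds ideal-geometry backbones by internal-coordinate
  chain extension (standard bond lengths/angles; helix φ = −57°,
  ψ = −47°; coil torsions drawn uniformly from the favoured+additional
  regions). The `mixed` motif reproduces a two-zinc-cluster domain layout
  — flexible N-terminus, rigid segment, flexible loop, rigid segment,
  flexible C-terminus — with the ranges recorded in an attribute.
* `perturbEnsemble()` adds Gaussian displacements drawn per residue and
  smoothed along the chain (moving average over 3 residues, rescaled to
  keep the marginal SD at the profile value), so neighbouring residues
  move coherently; side-chain atoms can receive extra independent spread.
* `makeZincSite()` constructs an exactly tetrahedral Cys~4~–Zn site from
  the restraint-target geometry, optionally Gaussian-distorted.
* `simulateRelaxation()` back-computes R1/R2/NOE from true motional
  parameters and adds relative Gaussian noise (the NOE receives
  $\sigma = f\sqrt{1 + \mathrm{NOE}^2}$, the error-propagation form for an
  intensity ratio), optionally emitting raw T1/T2 decay series at the
  standard delay lists and saturated/reference intensity pairs.

`syntheticDeposit()` combines these into a 20-conformer, 56-residue
(167–222) stand-in for a two-zinc-cluster domain deposit: cysteines at
176/179/182/188/191/194/210/215, proline 199, rigid segments 175–196 and
208–217 versus a flexible 197–207 loop and termini. The displacement
scale — 0.44 Å backbone SD in the rigid segments, i.e. $0.751/\sqrt3$,
with side chains 2.2× wider, loop/termini 2.0/2.5 Å — was fixed from the
ensemble precision typical of a well-restrained deposit of this size
(backbone spread ≈ 0.75 Å, all-heavy ≈ 1.0 Å); the measured spread comes
out a few percent below $\sqrt3\,\sigma$ because superposition absorbs
six degrees of freedom per conformer.

**What the stand-in does not emulate.** Displacements are Cartesian, so
local covalent geometry degrades with σ: torsions of residues at
rigid/flexible boundaries scatter far more than in a real restrained
ensemble, which disorders loops in *torsion* space while keeping bond
geometry ideal. Consequently the stand-in's well-defined region scores
around 94% favoured+additional rather than the ≳97% a water-refined
experimental ensemble reaches, and passing tests on the stand-in say
nothing about force-field-level realism. Interpreting Ramachandran
percentages measured on synthetic ensembles therefore requires this
caveat; the validation machinery itself is exercised independently on
noiseless templates (exactly 100% most favoured by construction).

# Problem sizes and determinism

The test-suite and acceptance-script studies use sizes chosen to make
sampling error negligible relative to the asserted tolerances while
keeping runs interactive: 20-model ensembles; point clouds of 4–50 atoms
for the embedding-exactness property; 100 seeded replicates per motional
model class for the recovery study (family accuracy is pooled over all
500); 40-residue relaxation sets for the $\tau_m$ recovery. Every
stochastic step takes an explicit seed and is reproducible bit-for-bit.

# Known limitations

* Isotropic tumbling only — no axially symmetric or fully anisotropic
  diffusion tensors, and $\tau_m$ is never fitted jointly with internal
  parameters.
* Single-field fitting (three observables per residue), so models 4 and 5
  are exactly determined; their parameter errors rest entirely on the
  Monte-Carlo procedure.
* The Ramachandran grid is a documented approximation, not the historical
  data file; percentages near region borders can differ by a few points.
* PDB input follows a fixed altloc policy (blank or `A`), author
  numbering only, no insertion codes, no mmCIF.
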