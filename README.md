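# nmrdyn

Analysis of solution-NMR protein structure ensembles and ¹⁵N backbone
relaxation, for structural biologists working with multi-model PDB
deposits and per-residue R1/R2/heteronuclear-NOE tables.

The package covers the computational core of a typical solution-structure
study of a small zinc-binding domain:

* **Unbiased mean structure and ensemble RMSD.** The mean is obtained by
  averaging the inter-atomic distance matrix over conformers,
  `D̄ᵢⱼ = (1/M) Σₘ ‖xᵢ⁽ᵐ⁾ − xⱼ⁽ᵐ⁾‖`, and back-projecting it into 3-D by
  classical scaling — no reference conformer, hence no superposition
  bias. Each conformer is then Kabsch-superposed onto the mean and the
  per-model RMSDs are pooled (both mean- and rms-over-models reported).
* **Lipari–Szabo model-free dynamics.** The spectral density
  `J(ω) = (2/5)[S²τₘ/(1+(ωτₘ)²) + (Sf²−S²)τ′/(1+(ωτ′)²)]`,
  `1/τ′ = 1/τₘ + 1/τₑ`, drives the standard ¹⁵N dipolar+CSA expressions
  for R1, R2 (plus `Rex`) and NOE. Motional models 1–5 (`S²`; `S²,τₑ`;
  `S²,Rex`; `S²,τₑ,Rex`; `S²,τₑ,Sf²`) are fitted by bounded χ²
  minimisation with deterministic multi-start and selected by a
  Mandel-style goodness-of-fit/F-test cascade; parameter errors come from
  seeded Monte-Carlo refits.
* **Rotational correlation time.** Per-residue apparent τc is the root of
  the rigid-limit R2/R1 ratio curve; residues with NOE < 0.6 or with a
  ratio more than one SD from the mean are filtered out and τₘ is the
  mean of the rest (SD and SEM both reported).
* **Validation.** Ramachandran four-region classification on a 10°×10°
  Morris-style grid, Cys₄–Zn site geometry against tetrahedral restraint
  targets (S–Zn 2.3 Å, S–Zn–S 109.5°, …), and average-linkage clustering
  of ensemble-mean SG–SG distances to assign cysteines to zinc sites.
* **Synthetic data.** Ideal-geometry templates, Gaussian-perturbed
  ensembles with per-residue displacement profiles, toy zinc sites and
  relaxation datasets generated from ground-truth motional parameters —
  everything needed to exercise the pipeline end-to-end with known
  answers, including a 20-model deposit-scale stand-in
  (`syntheticDeposit()`; entirely synthetic, no real coordinates).

## Worked example

```r
library(nmrdyn)
cfg <- fieldConfig(600.13)          # 600.13 MHz 1H, rNH 1.02 A, CSA -160 ppm

## a 20-model synthetic two-zinc-cluster domain (residues 167-222)
ens <- syntheticDeposit(seed = 1)
ensembleRMSD(ens, atomSelection("175-196,208-217", atoms = "backbone_O"))
#> RmsdReport over 20 conformers
#>   mean-over-models RMSD: 0.681 A
#>   rms-over-models  RMSD: 0.685 A
#>   per-model range: 0.564 - 0.815 A

## relaxation: 40-residue rigid core + flexible tail, truth tau_m = 5.67 ns
truth <- coreTailTruth(nRes = 40, nTail = 8, tauM = 5.67)
recs <- simulateRelaxation(truth, tauM = 5.67, noiseFraction = 0.02, seed = 11)
estimateTauM(recs, cfg)
#> TaucResult: tau_m = 5.667 ns (SD 0.094, SEM 0.017) from 32 residues
#>   excluded: low_NOE=7, ratio_outlier=1

## motional-model selection for one residue
selectModelFree(recs[recs$resSeq == 10, ], tauM = 5.67, cfg = cfg)
#> ModelFreeResult: model 4 | S2=0.806 tauE=31.6 ps Rex=0.23 /s Sf2=1.000
#>   chi2 = 5.733e-20 on 0 dof
#>   selection trace:
#>  model         chi2 dof critical gofPass fPass selected
#>      1 1.150699e+01   2 5.991465   FALSE    NA    FALSE
#>      2 1.202348e+00   1 3.841459    TRUE FALSE    FALSE
#>      3 1.118030e+01   1 3.841459   FALSE FALSE    FALSE
#>      4 5.733191e-20   0 3.841459    TRUE    NA     TRUE
#>      5 1.202348e+00   0 3.841459    TRUE    NA    FALSE

## assign cysteines to zinc clusters from geometry alone
assignCysClusters(makeCysClusterEnsemble(seed = 1))
#> ClusterAssignment (mean silhouette 0.750 )
#>   cluster 1 : 176, 179, 182, 215
#>   cluster 2 : 188, 191, 194, 210
```

Reading the output: the well-defined segments of the synthetic ensemble
spread ~0.68 Å about the unbiased mean (they were generated with a
0.44 Å backbone displacement SD, and √3·0.44 less the superposition
shrink lands there). The τₘ estimate recovers the 5.67 ns ground truth to
0.1% after the NOE and ratio filters discard the flexible tail. The
selection trace for residue 10 shows the cascade explicitly: model 1
fails the χ² test, model 2 fits but its F-test improvement over model 1
is not significant at α = 0.20, so the exactly-determined model 4 is
accepted — its fitted S² of 0.806 is close to the generating 0.83 and the
spurious exchange term is tiny (0.23 s⁻¹). The cysteine clustering
recovers the two generating Cys₄ sites exactly.

Real deposits are read the same way: `readEnsemble("file.pdb")` parses a
multi-MODEL PDB into the same `NMREnsemble` container, and every function
above applies unchanged.

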