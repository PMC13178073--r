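# bindmode

Binding-mode energetics and pharmacology for nuclear-receptor ligands.

Pentacyclic triterpenoids such as pomolic acid and hederagenin bind the
PPARγ ligand-binding domain, but close structural analogues (caulophyllogenin,
betulinic acid) occupy the pocket in two roughly inverted orientations, so a
candidate ligand's binding mode cannot be read off a single docked pose.
`bindmode` implements the computational layer used to settle such questions
from snapshot ensembles and plate data:

- **Single-trajectory MM-GBSA.** Per-frame receptor–ligand interaction
  energies E_int = E^ELE + E^vdW (Coulomb with interior dielectric ε, 12-6
  Lennard-Jones with Lorentz–Berthelot combining), generalized-Born polar
  solvation in the OBC flavor (the igb=2 parameter set: α = 0.8, β = 0,
  γ = 2.909125, 0.09 Å intrinsic-radius offset) plus a γ·SASA nonpolar term,
  combined as

  ΔG_bind = ΔH − TΔS,  ΔH = ΔE_MM + ΔG_solv

  with every species evaluated at the complex-frame geometry.
- **Interaction entropy.** −TΔS = k_B T ln ⟨e^{βΔE_int}⟩ over the per-frame
  interaction-energy fluctuations, computed in log space, with convergence
  diagnostics (the estimator degrades sharply once the energy spread exceeds
  ~2 k_B T).
- **Per-residue decomposition** of the electrostatic and van der Waals
  interaction energy, summing exactly to the totals.
- **Trajectory stability metrics.** Kabsch superposition, RMSD series over
  arbitrary fit/measure selections (backbone, binding site, ligand),
  per-residue RMSF with region reports, per-frame complex SASA
  (Shrake–Rupley).
- **Pose ranking.** Per-pose binding estimates assembled across replicas
  (mean ± SD) and compared by ΔG, with margins and tie flags.
- **Fingerprint similarity.** Radius-2 circular (Morgan/ECFP-style)
  fingerprints with Tanimoto similarity, count-based and folded-bitset.
- **TR-FRET pharmacology.** 520/495 ratios, four-parameter logistic fits,
  Cheng–Prusoff K_i = IC50/(1 + [tracer]/K_d), efficacy normalization and a
  ligand-profile decision table (full agonist / partial–selective modulator /
  neutral antagonist / antagonist / inverse agonist).
- **Synthetic generators** for every input: a host–guest complex with a
  planted pose ordering, Gaussian interaction-energy streams, and 4PL
  dose–response plates — so the whole pipeline is testable with known ground
  truth, without microsecond MD trajectories.

## Worked example

The numbered scripts under `analysis/` run the full workflow on synthetic
data (each writes its tables under `results/`):

```sh
Rscript analysis/01_simulate.R      # host-guest ensembles, energy streams, plates
Rscript analysis/02_mmgbsa.R        # MM-GBSA estimates + pose ranking
Rscript analysis/03_entropy.R       # interaction-entropy convergence
Rscript analysis/04_metrics.R       # RMSD / RMSF / SASA
Rscript analysis/05_similarity.R    # fingerprint similarity matrix
Rscript analysis/06_pharmacology.R  # 4PL fits, Ki, classification
```

`02_mmgbsa.R` prints, for the two planted hypotheses:

```
<binding_estimate> guest / A (planted): E_int -97.8 (-84.9, -12.9), dG_solv 85.0, dH -12.8, TdS -0.8, dG -12.0 kcal/mol
<binding_estimate> guest / B (shallow): E_int -30.4 (-28.8, -1.6), dG_solv 28.1, dH -2.3, TdS -0.0, dG -2.3 kcal/mol
pose ranking: A (planted) preferred by 9.78 kcal/mol
```

i.e. the deep pose pays a large desolvation penalty (dG_solv +85.0) that
cancels most of its gas-phase electrostatics — the expected GB behavior —
but keeps the deeper van der Waals well and wins by ~10 kcal/mol.
`06_pharmacology.R` fits the simulated competitive plate (IC50 4.79 µM
against a planted 4.98 µM), converts printed IC50s with the kit tracer
constants (5 nM tracer, K_d 2.8 nM):

```
printed-pair conversions: Ki(Po) 1.79 uM, Ki(Hede) 4.86 uM
                   ligand    ki_uM    coact corep              classification
1       pomolic-acid-like 1.787692  0.00000     0          neutral antagonist
2        hederagenin-like 4.860513 19.63537     0 partial/selective modulator
3 inverse-agonist control 0.000640  0.00000   100             inverse agonist
```

and `05_similarity.R` reports the count-based radius-2 Tanimoto matrix: the
two test triterpenoids score ≤ 0.04 against rosiglitazone and 0.47–0.79
against the two control triterpenoids.

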