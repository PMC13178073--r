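---
title: "bindmode: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{bindmode: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindmode)
```

# The model

`bindmode` estimates relative binding free energies of receptor--ligand pose
hypotheses from snapshot ensembles with the end-point MM-GBSA decomposition

$$\Delta G_\mathrm{bind} = \Delta H - T\Delta S, \qquad
  \Delta H = \Delta E_\mathrm{MM} + \Delta G_\mathrm{solv},$$

under the **single-trajectory protocol**: receptor and ligand conformations
are extracted from the complex frames, so all intramolecular (bonded and
internal nonbonded) terms cancel between the complex and the separated
species, and $\Delta E_\mathrm{MM}$ reduces to the intermolecular nonbonded
energy $E_\mathrm{int} = E^\mathrm{ELE} + E^\mathrm{vdW}$. This matches how
such results are conventionally tabulated -- an interaction energy split
into electrostatic and van der Waals columns, with no bonded contribution --
and is the reason the package never needs force-field topologies beyond
per-atom charges, radii and Lennard-Jones parameters.

Assumptions worth keeping in mind:

* the ensemble must sample the bound state only (the protocol says nothing
  about unbinding pathways);
* strain energy of ligand or receptor is not captured (a known limitation
  of single-trajectory end-point methods);
* solvation is implicit; structured waters are invisible.

## Gas-phase terms

The electrostatic term is a plain pairwise Coulomb sum over
receptor--ligand pairs, $k_e q_i q_j / (\varepsilon_\mathrm{in} r_{ij})$
with $k_e = 332.0637$ kcal·Å/(mol·e²); the van der Waals term is 12-6
Lennard-Jones in the $r_\mathrm{min}$ parameterization,
$\varepsilon_{ij}[(r_{\mathrm{min},ij}/r)^{12} - 2(r_{\mathrm{min},ij}/r)^6]$,
with Lorentz--Berthelot combining. No cutoff is applied: the systems are
finite and rescoring is exact (distance cutoffs belong to the MD engine
that generated the frames, not to the analysis). The interior dielectric
$\varepsilon_\mathrm{in}$ defaults to 2. A single configuration key
controls $\varepsilon_\mathrm{in}$ in both the Coulomb term and the GB
prefactor; whether a reference implementation applies it to one or both is
ambiguous in the field's common tooling, so sharing the key (and logging
it) makes the choice explicit and reversible.

## Generalized-Born solvation (OBC, igb=2-style)

Polar solvation uses effective Born radii from the
Hawkins--Cramer--Truhlar pairwise-descreening integral with OBC rescaling:

$$R_i^{-1} = \tilde\rho_i^{-1} - \rho_i^{-1}
  \tanh(\alpha\Psi_i - \beta\Psi_i^2 + \gamma\Psi_i^3),$$

with $\tilde\rho_i = \rho_i - 0.09$ Å and the igb=2 parameter set
$\alpha = 0.8$, $\beta = 0$, $\gamma = 2.909125$. An isolated atom's
effective radius is therefore its intrinsic radius minus the offset. The
pair energy is the Still expression with
$f_{GB} = \sqrt{r^2 + R_iR_j\,e^{-r^2/(4R_iR_j)}}$, diagonal included (the
Born self terms), prefactor
$-(k_e/2)(1/\varepsilon_\mathrm{in} - 1/\varepsilon_\mathrm{out})$,
$\varepsilon_\mathrm{out} = 78.5$. Salt screening is off by default
($\kappa = 0$); a Debye factor $e^{-\kappa f_{GB}}$ on the solvent part is
available by configuration. Intrinsic radii travel in the PQR file and
descreening scale factors in the JSON sidecar (defaulting by element to the
usual HCT values, 0.8 when unknown), so the radius set is always explicit
input rather than a guess.

The nonpolar term is $\gamma \cdot \mathrm{SASA} + b$ with
$\gamma = 0.0072$ kcal/mol/Å², $b = 0$, probe 1.4 Å -- the conventions of
the standard MM-GBSA post-processing tools. SASA comes from Shrake--Rupley
quadrature with 960 near-uniform sphere points (a golden-spiral lattice).
The reported $\Delta G_\mathrm{solv}$ column includes this nonpolar term,
which is also the convention of those tools.

Because complex, receptor and ligand share one geometry per frame, the
descreening matrix and the SASA point-burial tests are computed once per
frame and subset per species; this is exactly equal to three independent
single-species evaluations (a regression test asserts it) and is what makes
ensemble scoring fast in pure R.

## Interaction entropy

The entropic term is the exponential-average estimator

$$-T\Delta S = k_B T \ln \langle e^{\beta\,\Delta E_\mathrm{int}} \rangle,
  \qquad \Delta E_\mathrm{int} = E_\mathrm{int} - \langle E_\mathrm{int}\rangle,$$

with $k_B = 0.0019872$ kcal/mol/K and $T = 298$ K by default. It is
nonnegative for any input (Jensen's inequality) and zero for constant
samples; for Gaussian fluctuations of spread $\sigma$ it has the closed
form $\sigma^2/(2k_BT)$, which the tests use as an oracle. The average is
evaluated in log space with a max shift, since $\beta|\Delta E|$ can exceed
700 and overflow `exp()`. Entropy is computed from the same snapshot window
as the enthalpy, per replica, with the spread across replicas reported --
pooling replicas would let one replica's tail dominate the exponential
average of all three.

The estimator's known fragility is surfaced, not hidden: the estimate is
flagged unreliable when the sample SD exceeds $2k_BT$ (≈ 1.18 kcal/mol at
298 K), the regime where a handful of frames carry essentially all the
weight, and `entropy_convergence()` reports per-block and cumulative
estimates so a drifting or outlier-dominated stream is visible.

## Trajectory metrics

Superposition is Kabsch (SVD with a determinant correction, so always a
proper rotation). RMSD series fit on one selection and measure on another;
fitting on the backbone and measuring the ligand reproduces the usual
ligand-RMSD convention. The backbone selection is atoms named N, CA, C, O
(the conventional heavy-atom backbone); the binding-site selection is every
residue with an atom within 5 Å of the ligand in the reference frame, the
radius being configurable because no universal value exists. RMSF is
computed per atom about the time-averaged structure after superposition and
averaged within residues; region reports (e.g. helix H11/H12 windows) take
explicit residue intervals from configuration and are labelled approximate,
since helix boundaries are a modelling choice, not data.

## Fingerprints and similarity

Circular fingerprints are ECFP-style: initial atom identifiers hash
(atomic number, heavy degree, attached hydrogens, formal charge, ring
flag); each iteration rehashes the identifier with the sorted
(bond code, neighbor identifier) pairs; environments covering an identical
bond set are deduplicated; radius 2 by default. Hashing is a stable 32-bit
polynomial mix, so fingerprints are reproducible across platforms.
Chirality is ignored (the ECFP default) and aromaticity is perceived from
SDF flags or Kekulé alternation in 6-rings.

Tanimoto similarity is offered on two representations: the folded bitset
(2048 bits by default) and the **count multiset** (sum of minima over sum
of maxima of environment counts). The count form is the default and the
one used for the packaged triterpenoid comparisons: for molecules of this
size the binary folded variant discards multiplicity of the many repeated
aliphatic ring environments and systematically deflates
triterpenoid--triterpenoid similarity (e.g. a hederagenin/betulinic-acid
pair drops from ≈ 0.47 to ≈ 0.35), pushing it below the 0.4--0.8 band in
which such analogue pairs are reported to fall. The count similarity
depends only on how atoms partition into environments, not on hash values,
so it also cross-validates bit-for-bit against an independent
cheminformatics implementation.

## TR-FRET dose--response analysis

Responses are 520/495 emission ratios (the ratio cancels well-to-well
donor variation; fitting the ratio is the kit-standard choice). The 4PL
model

$$y = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
  {1 + 10^{\,\mathrm{hill}\,(\log_{10}\mathrm{mid} - \log_{10} x)}}$$

is fit by Levenberg--Marquardt least squares from a grid of starts (three
midpoint guesses × both hill signs), keeping the lowest residual sum of
squares. Two numerical choices matter: the parameterization is degenerate
under (bottom, top, hill) → (top, bottom, −hill), so fits are canonicalized
to top ≥ bottom; and a fit whose span is indistinguishable from its
residual noise (|top − bottom| < 2 × residual SD) is reported as
non-convergent rather than returned -- flat data should fail loudly. The
95% CI of the log-midpoint uses the t quantile with the fit's residual
degrees of freedom. Concentrations are handled in log10 molar; plate CSVs
carry an explicit unit column.

Cheng--Prusoff, $K_i = \mathrm{IC}_{50}/(1 + [\mathrm{tracer}]/K_d)$, uses
tracer constants of 5 nM and $K_d$ = 2.8 nM by default -- the published
constants of the competitive-binding kit this analysis targets, validated
against both printed (IC50, $K_i$) pairs they reproduce to 2 decimals, and
overridable in configuration. Efficacy is normalized as
$100(\mathrm{top}-\mathrm{bottom})/(\mathrm{top}_\mathrm{ref}-\mathrm{bottom}_\mathrm{ref})$.
Ligand classification is an explicit decision table over coactivator and
corepressor efficacies with thresholds at 10% (partial) and 80% (full),
stated in configuration precisely because the underlying reasoning in the
literature is qualitative; the defaults separate the canonical profiles
(silent antagonist 0%/0%, partial modulator ~19%/0%, inverse agonist
0%/100%, antagonist 0%/~36%).

# The synthetic generators

The generators produce every input with known ground truth.

**Host--guest complex.** A 60-atom ring "receptor" (radius 5 Å, six
10-atom residues) carries a −0.25 e charge on each atom of one residue (the
pocket); a 10-atom guest carries four +0.25 e charges. Pose A sits at the
ring center against the pocket (deep Lennard-Jones contact, favorable
Coulomb); pose B sits outside the ring on the far side. Frames are the
rigid pose plus i.i.d. Gaussian coordinate jitter (0.08 Å by default --
small enough that no frame develops steric clashes, large enough that
per-frame energies fluctuate). Parameters are made-up but physically sane
(charges ≤ 1 e, radii 1.2--2.2 Å). What this emulates is the *logical
structure* of a dual-pose-hypothesis comparison: a planted energetic
ordering that the pipeline must recover, including the realistic GB
behavior that desolvation cancels most of the gas-phase electrostatic
preference, leaving the van der Waals complementarity decisive. What it
does **not** emulate: conformational transitions, induced fit, internal
ligand strain, water-mediated contacts, or the microsecond-scale
correlation structure of real trajectories. Passing the recovery tests
therefore demonstrates correctness of the scoring machinery, not accuracy
of MM-GBSA on real complexes.

**Energy streams and plates.** Gaussian interaction-energy streams
exercise the entropy estimator against its closed form; 4PL plates
(log-spaced doses over 1 pM--100 µM, the standard assay range, with
Gaussian response noise emitted as 520/495 channel pairs) exercise
parameter recovery and CI calibration.

All generators are pure functions of (parameters, seed); byte-identical
outputs across runs are asserted in the tests.

# Problem sizes and tolerances

The test suite runs the pose-recovery property at 40 seeds × 50 frames ×
2 poses (~70-atom systems) and the 4PL coverage property at 100 simulated
plates of 10 doses × 3 replicates at 2% noise -- sizes chosen so the full
suite completes in a few minutes on one core while keeping the binomial
pass criteria (≥95% pose recovery, ≥90/100 CI coverage) statistically
meaningful. Energy identities are asserted at 1e-6 kcal/mol, brute-force
pair-sum agreement at 1e-10, the Born-ion closed form at 1%, and the
Gaussian entropy closed form at 3% over 20 seeds of 10⁵ samples.

Two numerical caveats are deliberate: Shrake--Rupley SASA with a fixed
point lattice is orientation-dependent at the quadrature level (~0.5% at
960 points; rotational invariance is therefore asserted at 1% for the
nonpolar term, while all analytic terms meet 1e-6), and SASA totals
stabilize to ≤0.5% between 960 and 5000 points.

# Known limitations

* No Poisson--Boltzmann route; igb=5/7/8 parameter sets are not provided
  (the configuration hook exists, unimplemented).
* Absolute binding free energies from microsecond trajectories of real
  complexes are out of reach by construction -- the package rescoring a
  handful of synthetic frames cannot and does not claim to reproduce
  published absolute ΔG tables; its worked-example arithmetic, closed-form
  oracles and planted-recovery properties are the verifiable surface.
* The SDF reader handles V2000 connection tables only; trajectory formats
  beyond multi-MODEL PDB (DCD/XTC/NetCDF) are out of scope.
* Fingerprints ignore stereochemistry; enantiomers are identical to them.
* The interaction-entropy estimator is exponentially sample-hungry; outside
  the small-fluctuation regime its flag should be trusted over its value.
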