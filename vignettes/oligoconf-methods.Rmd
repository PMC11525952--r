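---
title: "Methods: models, conventions and design choices in oligoconf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in oligoconf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoconf)
```

oligoconf models gas-phase, protonated peptide oligomers — the worked
system is diphenylalanine, whose neutral repeating unit is C18H20N2O3 —
and implements the computational chain that connects electrospray mass
spectra and cold-ion IR spectra to candidate three-dimensional structures.
This vignette records the models, the tunable parameters with their units
and defaults, the numerical conventions, and the places where the design
was genuinely open and a choice had to be made.

Units are fixed package-wide: coordinates in Angstrom, energies in
kcal/mol, frequencies in cm^-1, torsions in degrees wrapped into
[-180, 180), masses in amu, m/z in Th.

## Topologies and protonation states

A residue template (shipped: neutral L-phenylalanine, generated once from
standard small-molecule geometry) carries atoms, bonds, aromatic rings and
derived donor/acceptor and rotatable-torsion lists. Two phenylalanines
condense (losing one water) into the dipeptide unit; `build_oligomer()`
replicates that unit n times as a non-covalent complex.

Protonation is restricted to the chemically relevant sites of this system:
N-terminal amines accept the extra proton, C-terminal carboxyls deprotonate
in zwitterions. Phenyl side chains are not ionizable. A unit is therefore
`neutral`, `protonated` (+1, ammonium) or `zwitterion` (net 0, ammonium +
carboxylate); a protonated-neutral dimer is the charge-solvated (pn) form
and a protonated-zwitterion dimer the salt-bridge (pz) form.

**Initial placement.** Units are placed on a grid with seeded random
orientations. The nominal pitch is 6 A, but a diphenylalanine unit's own
bounding radius is about 7 A, so a literal 6 A pitch starts the complex
with sub-0.4 A interatomic clashes. The builder therefore widens the pitch
to `2 * unit_radius + 2` A whenever units would overlap. This only affects
the starting point of a search; optimized geometries do not remember it.

Inter-unit orientation is handled as rigid-body freedom (6 degrees of
freedom per additional unit, reported as `n_rigid_dof`) rather than as
pseudo-torsions; the intra-unit rotatable list covers backbone phi/psi,
side-chain chi and the carboxyl OH torsion.

## Geometric predicates

Hydrogen bonds use standard structural-biology defaults, configurable in
`geometric_criteria()`: donor-acceptor heavy-atom distance <= 3.5 A and
D-H...A angle >= 120 degrees (closed boundaries, with a 1e-9 floating-point
guard so a geometry constructed exactly at the threshold is detected).

The proton-pi predicate is a declared convention, not something the
spectroscopy defines geometrically: a contact exists when the ammonium
nitrogen is within 5.0 A of an aromatic-ring centroid. The 5.0 A default is
chosen so that a known charge-solvated dimer contact at 4.8 A — described
as remote but structurally decisive — qualifies.

The free-OH diagnostic asks whether any carboxyl OH hydrogen participates
as the shared hydrogen in a detected hydrogen bond; a zwitterionic unit has
no OH on its carboxylate and contributes nothing. The UV-derived constraint
filter encodes the charge-chromophore proximity argument: in monomer mode
the ammonium must contact the C-terminal residue's own ring; in dimer mode
at least one contacted ring must belong to a *different* residue than the
charged terminus. Conformers failing the predicate are partitioned out, not
deleted.

## The PPO conformer generator

The generator is a small policy network over discrete torsion moves:

- **State**: sin/cos of every torsion plus a charge-location one-hot, so a
  single policy serves all protonation states of a given size without
  retraining.
- **Actions**: pick one torsion and rotate it by one of
  {±30, ±60, ±120, 180} degrees; the episode horizon defaults to 3x the
  torsion count.
- **Reward** (terminal): `-w_E * E + w_N * novelty`, novelty being the
  minimum TFD to an archive of previously generated conformers (1.0 when
  the archive is empty). Defaults w_E = w_N = 1 balance the two terms on
  the kcal/mol-scale toy landscapes used for validation.
- **Update**: the clipped-surrogate objective
  `min(r A, clip(r, 1 - eps, 1 + eps) A)` with eps = 0.2, advantage =
  return - value baseline normalized per batch (normalization is skipped
  when the batch advantage is degenerate, so an all-zero-advantage batch
  provably leaves parameters unchanged), Adam at 3e-3, 4 epochs per batch
  of 32 episodes, 2x32 hidden tanh units in both nets.
- **Stopping**: training ends when the advantage trace plateaus. The rule
  is windowed relative variation: over the trailing window (default 10
  iterations) the spread `max - min` divided by the mean magnitude must
  fall below the tolerance (default 1%). This reading makes a constant
  trace a plateau and any trace still climbing steeply not one, and treats
  a trace like (..., 3, 3.0001, 3.0002) as converged regardless of its
  early history.
- **Budget**: 200 iterations by default, CPU-only; all randomness flows
  from explicit seeds and generation is bit-reproducible.

Every generated conformation must clear the minimum-interatomic-distance
invariant (0.7 A); invalid samples are rejected and resampled so the
requested count is always delivered.

What the toy landscape validates — and what it does not: the double-well
per-torsion surface (global minimum 0, local minimum +2a1, ridge at ±120
degrees) has known basins, so learning is measurable as the excess of
generated samples in the global basin over uniform sampling. A green test
establishes that the policy machinery learns a low-energy bias; it says
nothing about force-field quality or real peptide energetics.

## TFD and uniqueness

TFD between two conformers of the same topology is the weighted mean of
per-torsion periodic deviations normalized by 180 degrees, in [0, 1].
Weights default to uniform (the original depth-based weighting is available
by passing explicit weights); symmetry periods are auto-assigned — 180
degrees for torsions terminating on 2-fold symmetric groups (phenyl rings,
carboxylates), 360 otherwise — so a carboxylate flip is no deviation.
The triangle inequality is not guaranteed and is not asserted anywhere.

Deduplication is a greedy single pass in input order with a default
threshold of 0.05: nothing canonical is claimed for that number; the tests
assert the exact greedy semantics against an independent O(n^2) oracle and
the monotone shrinkage of the kept set as the threshold grows.

## Energy backends and optimization

The internal backend is force-field-level: harmonic bonds (reference
lengths from covalent radii), harmonic angles (109.5/120 degrees by
hybridization), Lennard-Jones and Coulomb with crude partial charges that
are constrained to sum to the formal charge; 1-2 and 1-3 pairs are
excluded, 1-4 scaled by 0.5. It orders conformers sensibly and supports
Hessians; it does not — and is not meant to — reproduce quantum-chemistry
energy gaps of a few tenths of a kcal/mol. DFT-level results enter only
through the external-adapter contract (`external_optimize()`), which
writes XYZ, invokes a user-declared command and parses the result back,
erroring loudly rather than falling back internally.

Minimization is BFGS with Armijo backtracking, monotone by construction
(the energy trace over accepted steps never increases), gradient
infinity-norm tolerance 1e-4, at most 2000 steps; non-convergence flags
the result but keeps it. A zero-gradient saddle can legitimately terminate
a gradient-only optimizer; consumers that need true minima verify
curvature (the tests classify stationary points against the landscape
before comparing to the exhaustive grid).

Hessians are central finite differences of the analytic gradient (default
step 0.005 A), symmetrized, then mass-weighted. The soft rotational modes
carry O(step) contamination from anharmonicity — about 10 cm^-1 at the
default step, under 2.5 cm^-1 at 0.001 A — so zero-mode counting tests use
the smaller step. Frequencies convert via
sqrt(kcal/mol/A^2/amu) = 108.59 cm^-1.

## Families and the candidate funnel

Family identity is exact equality of the interaction fingerprint: sorted
hydrogen-bond (donor, acceptor) pairs, sorted proton-pi (site, ring) pairs
and the charge-location label. Fuzzy matching was considered and rejected:
exact keys make the partition property trivially checkable and reproducible,
at the cost of splitting families that differ by one marginal contact.

Candidate selection keeps each family's energy minimum iff it lies within
the cutoff (default 10 kcal/mol) of the pool's global minimum. Whether the
cutoff should be measured globally or per charge-location stratum is not
decidable from the source material, so both relative energies are reported
(`relative_energy`, `relative_energy_stratum`) and the cutoff is applied to
the global one.

## Harmonic IR prediction and matching

Region-wise empirical scaling multiplies frequencies >= 2500 cm^-1 by 0.955
(the 3 um hydride-stretch region) and those below by 0.983 (the 6 um
fingerprint region). The 2500 cm^-1 boundary is a package choice: the
regions are named only by wavelength (about 1430-1800 and 2800-3700 cm^-1),
and any boundary in the empty 1800-2800 cm^-1 gap is equivalent; 2500 sits
safely inside it. Double scaling is refused.

Broadening is a sum of unit-area Gaussians (FWHM default 8 cm^-1, the
cold-ion linewidth scale). Matching mean-centers both curves on the common
grid and computes cosine similarity, so the score is invariant to positive
rescaling, a trace matches itself at +1 and its negation at -1; depletion
traces are inverted to positive-going first. The free-OH window is the
closed interval 3550-3600 cm^-1 on scaled spectra.

Harmonic frequencies of strongly H-bonded groups are systematically poor;
the package applies the standard empirical scaling and does not attempt
anharmonic corrections.

## Thermochemistry and the crossover mechanism

`free_energy()` evaluates the standard closed forms: harmonic-oscillator
vibrations (always), rigid-rotor rotations (when moments of inertia are
given), ideal-gas translations at 1 atm (when the mass is given), so
G -> E + ZPE as T -> 0 for vibration-only inputs. Symmetry numbers default
to 1; an optional quasi-harmonic flag raises frequencies below 50 cm^-1 to
50 cm^-1 (off by default — the treatment used for the published analysis is
unknown, so the raw harmonic result is the default).

The physical mechanism under test: a salt-bridge conformer's strong
NH3+...COO- interaction makes it torsionally stiffer, its entropy grows
more slowly with temperature, and the softer charge-solvated conformer —
even if higher in E + ZPE — becomes the free-energy minimum above a
crossover temperature. `crossover_temperature()` scans dG on a 1 K grid
over 10-400 K (the span between cryogenic-trap and pre-trap conditions)
and refines each sign change by bisection; multiple crossings are all
reported and flagged. The package deliberately does not claim any specific
crossover temperature for real diphenylalanine dimers: that number depends
on quantum-chemistry frequencies it does not compute. The tests assert the
mechanism on constructed pairs where a uniformly stiffer spectrum must give
lower entropy at every temperature and the bisection must agree with the
grid scan.

## Mass spectrometry

m/z is (sum of atomic masses + z protons) / z, monoisotopic or average;
the electron mass is neglected (three orders below the resolution that
matters here) and integer labels use round-half-up. Both mass conventions
are computed everywhere because the observed peak labels of the oligomer
series mix them: 313, 625 and 1250 Th are monoisotopic-consistent while
938 Th is average-mass-consistent, and `assign_peak()` reports candidates
under both.

Isotope envelopes are exact convolutions over embedded IUPAC abundance
tables (H, C, N, O, S), aggregated into unit nominal-mass bins (spacing
1/z Th) by default with a profile mode behind a flag, pruned at a relative
threshold and renormalized. Mixture decomposition aligns component peaks
onto the measured grid (nearest within 0.5/z Th) and solves non-negative
least squares (Lawson-Hanson active set), renormalizing fractions to sum
to one; the fit is scale-invariant in the measured intensities and
near-identical components are flagged as degenerate rather than erroring.

## Synthetic fixtures: what a green test establishes

`make_fixture()` emits, deterministically from one seed: the toy torsion
landscape with its exhaustive-grid reference minima; synthetic "measured"
IR traces built by broadening a known conformer's sticks (8 random sticks
in 1000-3700 cm^-1, plus decoys) with optional Gaussian noise; and a
synthetic envelope mixture at the trimer/hexamer overlap with ground-truth
fractions 0.33/0.67 — the composition used throughout as the worked
decomposition example. These fixtures emulate the *structure* of real data
(overlapping isotope series, conformer-specific stick patterns, multi-basin
torsion landscapes) but not its pathologies: no baseline drift, no
calibration error, no anharmonic shifts, no force-field bias. Green tests
therefore establish algorithmic correctness — the right arithmetic, the
right selection semantics, a learning signal — not predictive accuracy for
real spectra.

## Known limitations

- Internal energetics are classical and crude; all quantitative energy
  claims require the external optimizer adapter.
- The generator's architecture and reward weights are package choices; no
  claim is made that they match any particular published network.
- Family identity by exact fingerprint equality can oversplit.
- Hexamer-scale (and larger) structure solution is out of scope; the
  machinery is validated at desk scale.
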