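---
title: "Methods: dual-target screening analytics with MM-PBSA decomposition"
author: "atroscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-target screening analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atroscreen)
```

# Scope and model

`atroscreen` implements the analysis layer of an ensemble-docking virtual
screen against the PI3K&alpha;/mTOR dual-target axis, from pose validation
through binding-energy bookkeeping to hit triage. It deliberately does *not*
contain a docking search engine, a molecular-dynamics integrator or a
finite-difference Poisson–Boltzmann solver: those are external engines whose
outputs this package consumes, validates and summarises. Everything the
pipeline reads can also be produced by the package's own seeded synthetic
generators, so every stage is testable end to end without external binaries.

## Pose metrics and receptor-ensemble selection

Docking poses are compared with the crystallographic ligand by heavy-atom,
order-matched RMSD *without* superposition (`rmsd_nofit`), the natural
convention when poses and reference share the fixed receptor frame. A
self- or cross-docking cell succeeds when the lowest-score pose over all
pooled repeats (ties by lowest run index) lies strictly below 3 &Aring;.
The threshold is configurable; "strictly below" is a deliberate reading of
the success rule, so an RMSD of exactly 3.0 &Aring; fails. Pose RMSD is not
symmetry-corrected: for ligands with topological symmetry (e.g. a
para-substituted ring flip) the reported RMSD can overestimate the
geometric error. This is a documented limitation, not an option.

Receptor-ensemble construction is a set-cover problem: find the smallest
receptor set whose successful cells cover every coverable ligand. `exact`
mode enumerates subsets in increasing cardinality (guaranteed minimum,
intended for the &le; 20 receptors typical of crystallographic ensembles)
and prefers the lexicographically smallest among equal-size covers;
`greedy` adds the receptor recovering most uncovered ligands, ties
lexicographic. Apo structures, which add binding-site plasticity but may
recover no ligand, enter through `must_include` and are seeded into the
selection before either strategy runs. Uncoverable ligands are reported,
never raised as errors: a ligand no conformer recovers is a finding, not a
bug.

Trajectory-level metrics use Kabsch superposition (SVD with the determinant
correction); RMSF superposes all frames on their mean structure (one
fixed-point iteration of the mean). With fewer than three non-collinear
atoms the superposition is degenerate and falls back, with a warning, to
translation-only.

## Single-trajectory MM-PBSA

Binding energy is the end-state difference
\[
\Delta G_{bind} = G_{complex} - (G_{protein} + G_{ligand}),\qquad
G = \langle E_{MM}\rangle + \langle G_{polar}\rangle +
    \langle G_{nonpolar}\rangle - \langle TS\rangle .
\]
Under the single-trajectory approximation all three species share the
complex trajectory, so bonded and intra-unit nonbonded terms are identical
on both sides and cancel exactly; `single_traj_binding` therefore computes
only the surviving terms per frame: intermolecular Coulomb
(\(k_e = 332.0636\) kcal&nbsp;&Aring;/(mol&nbsp;e&sup2;), vacuum dielectric)
and Lennard-Jones (12-6, Lorentz–Berthelot combining) energies, plus polar
and nonpolar solvation differences. The cancellation is exercised in the
test suite by comparing against a full end-state evaluation with explicit
bonded constants. The entropy term is omitted by default, matching common
MM-PBSA practice for relative rankings; a `TS` hook exists in
`EnergyComponents` for users who compute it externally.

Frames are taken evenly spaced (default 100) inside a time window; the
defaults ship two windows, 90–100 ns and 190–200 ns, and
`window_convergence` reports the absolute difference between their means.
The test suite uses far smaller problems (tens of atoms, a handful of
frames): the arithmetic being verified is scale-free, and the package's own
choice is to keep the default suite in seconds.

### Nonpolar term

\(G_{nonpolar} = \gamma A + b\) with SASA from a Shrake–Rupley
implementation using a deterministic Fibonacci-spiral sphere sampling
(default 960 points, probe 1.4 &Aring;). Per-atom areas sum to the total by
construction. Defaults \(\gamma = 0.0054\) kcal/(mol&nbsp;&Aring;&sup2;)
and \(b = 0.92\) kcal/mol are in the range commonly used with
PB/SASA pipelines; the upstream study defers its exact values to prior
work, so these are explicit, configurable surrogates and absolute energies
computed here are not comparable to published tables.

### Polar term

The polar contract is pluggable: any function
`(Structure, SolvationParams) -> list(total, per_atom)` can stand behind
`polar_solvation`. The bundled `born_polar_solver` is an analytic
surrogate — per-atom Born self-energies with a pairwise
\(a_j^3/(2r_{ij}^4)\) descreening of the inverse effective radius (floored
at 1/30 &Aring;&sup1;) — chosen because it is exact for a single ion
(the Born closed form, verified to 1e-9), additive for well-separated
groups, and exactly decomposable per atom. It is *not* a
Poisson–Boltzmann solver and is documented as such; rankings that depend
on fine polar effects should plug in a real solver.

### Per-residue decomposition

Each receptor residue receives its atoms' interaction terms with the
ligand plus its atoms' polar/nonpolar solvation differences
(complex-minus-isolated, per atom, summed by residue). The ligand's own
solvation shares — including the net \(-b\) left by the three linear SASA
constants — form one additional `ligand` row, so contributions sum to the
total binding energy *exactly* (to 1e-6 by test, in practice to machine
precision). Attributing per-atom first and summing second is what makes
that conservation an identity rather than an approximation.

## Radial profiles and the convergence radius

Each residue's radial coordinate is its minimum heavy-atom distance to the
ligand. Cumulative energy is accumulated on a 0.5 &Aring; grid from 2.0 to
10.0 &Aring; (profiles start at 2.0 &Aring; because shorter contacts are
sterically impossible). The convergence radius is the smallest grid radius
\(r^\*\) whose forward 2 &Aring; window stays within 10% of
\(|E(r^\*)|\). The published rule is verbal; three readings were possible
(deviation from the window start, from the window mean, or from the
asymptote) and the window-start reading is implemented because it is local,
monotone under tolerance relaxation, and testable by construction. Two
guards make the criterion total: when \(|E(r^\*)| \le \varepsilon_0\)
(default 0.1 kcal/mol) an absolute test against \(\varepsilon_0\) replaces
the relative one (a percentage of a near-zero baseline is meaningless), and
an identically-zero profile reports no radius at all. Radii whose forward
window leaves the grid are not certified.

## Axial chirality

Atropisomeric biflavonoids carry an axial stereocentre on the
interflavonoid bond; the sign of the dihedral across that bond encodes the
sense of twist. The dihedral uses the standard IUPAC sign convention.
Which sign is *Ra* and which *Sa* depends on the four atoms chosen and on
CIP priorities; rather than hard-coding a stereochemical claim, the
mapping is configuration (`positive_is_Sa` by default) and is validated
for internal consistency only — mirror-image structures provably flip the
label. Torsions within 15&deg; of planarity (0&deg; or 180&deg;) are
labelled `undefined`: at the rotation barrier the descriptor is not
meaningful. The 15&deg; default is a conservative guard, far below the
~60–120&deg; twists typical of hindered biaryls.

Enantiopreference per (compound, target) follows the agreement rule on the
two docking outcomes: if the retained poses of both input enantiomers
carry the same configuration, that configuration is the preference;
if each input keeps its own configuration, the target accepts both and
the verdict is `none`. Whether the "output" configuration should come from
the single best-score pose or a majority over docking repeats is left open
upstream; the package takes the best-score pose (consistent with the
best-pose convention elsewhere) and the table-driven interface
(`enantio_preference_table`) accepts labels from any aggregation.

## Triage

The screening funnel keeps `floor(0.10 n)` records with the lowest scores
per target (floor reproduces the published 1745 &rarr; 174 count), with
boundary ties broken by compound id. The dual-inhibition rule is
configurable (`both_top_decile` or `both_below_cutoff`) because the
upstream description does not define it operationally; consequently the
intermediate count it produced (102) is not a reproduction target.
`dual_classification` works at configuration level (rows with computed
energies for both targets); `dual_molecule_count` pools configurations by
parent compound, so a compound whose *Ra* form binds one kinase and whose
*Sa* form binds the other is dual at the molecule level.

Rule-of-five violations are counted per threshold (MW &le; 500, logP
&le; 5, HBD &le; 5, HBA &le; 10; the `swissadme` variant uses MLOGP &le;
4.15). MW, HBD and HBA are exact and computed via Open Babel; logP is
estimator-dependent, and the default is an own implementation of the
Moriguchi MLOGP core terms (CX, NO, PRX, UB, POL, ring and H-bond
dummies; ionic and special-group corrections omitted as they vanish for
neutral polyphenols). The Wildman–Crippen estimate is the named
alternative; on polyphenols the two differ by more than a log unit
(amentoflavone: ~1.4 vs ~5.1), which flips the logP rule — the MLOGP
default matches the ADME panel the screening campaign used.

## Synthetic generators

Generators are pure functions of (parameters, seed) and restore the
ambient RNG stream. Their defaults are the study's conditions: 1745
compounds, scores N(−7, 1.5&sup2;) kcal/mol per target (the realistic
range of docking scores for drug-like binders), inter-target correlation
0.6 (two ATP-competitive kinase sites rank similar chemotypes similarly),
10 docking repeats, a 3 &Aring; success threshold. Each planted truth
(exact minimal cover, minimum distances, torsion, convergence radius) is
re-verified by the consuming module's own check at generation time and
generation fails loudly on an infeasible plant — a generator bug cannot
silently become a passing test.

What the generators do *not* emulate: real force-field topologies,
chemically valid geometry, Vina's score distribution beyond a normal
model, or conformational correlation along MD trajectories (frames are
i.i.d. noise around a base structure, optionally with linear drift).
Passing tests therefore demonstrate the correctness of the bookkeeping,
selection and classification logic under known ground truth — not the
physical accuracy of docking or MD, which no desk-scale test could.

## Numerical choices

* Coulomb constant 332.0636 kcal&nbsp;&Aring;/(mol&nbsp;e&sup2;); Born
  prefactor half of it. Energies kcal/mol, coordinates &Aring;;
  converters to/from kJ/mol are provided.
* No nonbonded cutoff by default (toy-scale sums are exact); a cutoff
  argument exists for larger systems.
* Coincident atoms raise singularity errors rather than returning
  infinities.
* Alternate locations and insertion codes in PDB input: first occurrence
  wins, with a warning.
* All tie-breaks (pose score, decile boundary, cover selection, residue
  ranking) are lexicographic/deterministic, so byte-identical reruns are a
  tested contract.
* Default problem sizes in the test-suite: toy complexes of 3–5 residues,
  2–20 frames, 960-point SASA spheres; the full suite and the acceptance
  script each run in well under a minute on one CPU.

## Known limitations

No symmetry-corrected RMSD; no CIP-based stereodescriptors; the polar
surrogate is not PB; shipped LJ/radius parameters are generic surrogates
(the upstream force-field assignments are not reproduced); absolute
binding energies are therefore only meaningful relative to one another
within a consistent configuration.
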