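---
title: "Modelling lanthipeptide ensembles with ensemble-averaged NOE restraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lanthipeptide ensembles with ensemble-averaged NOE restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lanthifold)
```

## The problem and the model

Lanthipeptides carry thioether bridges (lanthionine from Dha + Cys,
methyllanthionine from Dhb + Cys) and often unreacted dehydrated residues
whose sp2 α-carbons reshape their backbone torsion preferences. NMR yields
NOE distance restraints that are population averages over the solution
ensemble: the measured intensity scales with r⁻⁶, so short distances in a
minority of states dominate the observation. Forcing every conformer of a
deposited ensemble to satisfy every restraint therefore *understates*
flexibility. This package takes the ensemble view: a candidate ensemble of
N equally populated conformers predicts, for each restraint between atom
groups α and β,

$$d^{*}_{\alpha\beta} = \left( \frac{1}{N}\sum_{i=1}^{N} d_{\alpha\beta,i}^{-6} \right)^{-1/6},$$

and is scored by the sum of squared residuals between \(d^*\) and the
observed distances. Two r⁻⁶ combinations appear and are kept deliberately
distinct: *within* one conformer, ambiguous groups (methyls, glycine HA
pairs) combine by the r⁻⁶ **sum** over cross-pairs — the NMR pseudoatom
convention, where more equivalent protons shorten the effective distance —
while *across* ensemble members the r⁻⁶ **mean** implements equal state
populations.

The workflow is: (1) generate a conformer pool consistent with the ring
topology; (2) optionally remove atropisomer classes that the data do not
support; (3) search subsets of the pool by Monte Carlo for the
lowest-scoring ensemble; (4) report flexibility profiles and RMSD tables.

### Assumptions

* States are *equally populated*; the selector can up-weight a conformer
  only if `allow_duplicates` is enabled (off by default).
* Restraints are independent and unnormalized: the score is a plain sum of
  squared residuals over however many restraints exist. No per-restraint
  weighting is applied.
* The minimal atom model (backbone + amide/α hydrogens + CB/SG/γ-methyl
  heavy atoms) is sufficient for ring geometry, clash detection and the
  NOE groups used here; methyl pseudoatoms resolve to the carrier carbon.

## Conformer construction and ring closure

Chains are built in internal coordinates (NeRF) at ideal bond lengths and
angles. L-residues place CB at a torsion of −122.6° about the N–CA axis
(referenced from C), a constant calibrated once against an independently
embedded L-alanine dipeptide; D-residues mirror it, and Dha/Dhb get planar
sp2 α-carbons (120° angles, C=C bond to CB, Z-configured γ-methyl for Dhb).

Ring closure is cyclic coordinate descent (CCD) over the backbone φ/ψ
torsions inside the ring span plus the acceptor χ1 (the SG rides on the
acceptor sidechain; with χ1 frozen many starts cannot reach the
flanking-angle targets). Each CCD update is a *Cartesian rigid rotation of
the downstream atoms about one bond axis*, so bond lengths, bond angles and
all torsions outside the span are preserved exactly — a property the test
suite checks by exhaustive internal-coordinate comparison. Per torsion, the
objective (squared C–S bond-length gap plus softly weighted flanking-angle
deviations) is scanned on a 15° grid and polished with a bounded 1-D
optimizer; sweeps stop at convergence, stall, or `max_iter`.

Multiple rings are closed in a caller-chosen order; the unstructured
sampler tries order permutations (capped at 24, randomly subsampled beyond
4 rings) because closing one ring can reopen another, and re-verifies all
rings at the end. Non-convergence is a *result*, not an exception: the
caller retries from a new random start and drops the model after a
configured number of attempts.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `cs_bond_length` | 1.81 | Å | thioether C–S bond |
| flanking angles | 109.5 / 98 | deg | sp3 C / C–S–C thioether values |
| crosslink dihedrals | 180, 180, 180 | deg | anti preference, soft weights |
| melan improper | −34.2 | deg | tetrahedral stereocentre at donor CB |
| `bond_tol` / `angle_tol` | 0.02 / 20 | Å / deg | closure acceptance |
| torsion-table spacing | 15 | deg | coarse digitized grids |
| sampling `temperature` | 1.0 | table units | Boltzmann cell sampling |
| `burn_in` / `production` | 1000 / 9000 | steps | faithful refinement schedule |
| `n_models` | 500 | – | desk-scale default; the faithful preset is 150k–200k with a 2.5% filter |
| `top_fraction` | 0.025 | – | stage-2 filter |
| selector `steps` | 500000 | – | faithful preset; small pools converge orders of magnitude earlier |
| selector size bounds | 10–30, init 20 | members | ensemble-size window |
| selector `temperature` | 1.0 | Å² | score is in Å²; no principled value exists, so it is exposed — rerun at 0.3×/3× and compare best scores to test sensitivity |
| probe `tolerance` | 0.1 | Å | degenerate-probe guard |

The crosslink dihedral targets and weights are configurable data, not
ground truth: the harmonic form stands in for unpublished force-field
torsion potentials, with weights soft enough that closure is driven by the
bond and angle terms.

## Torsion tables

Tables ship as plain text (header + one row per φ/ψ cell: energy and a
disallowed flag) and are bilinearly interpolated on the periodic grid.
The Dha/Dhb tables are *coarse digitized basin models*, not quantum-chemical
scans: symmetric low-energy bands implementing the (φ, ψ) → (−φ, −ψ)
symmetry of an sp2 α-carbon, with Dhb additionally masking the basins where
its Z γ-methyl would collide with the backbone — making Dhb's allowed set a
strict subset of Dha's, which the tests assert. The file format is
documented precisely so users with QM-derived tables can drop them in.
Energies are meaningful up to an additive constant and a temperature
factor; sampling draws cells ∝ exp(−E/T) and jitters uniformly within the
cell, and masked cells have sampling probability exactly zero.

## The simplified conformer score

Pool ranking uses a four-term score: soft inverse-power clash repulsion
((dmin/d)⁶ − 1 below contact distance, capped), torsion-table energies, a
−1-per-contact backbone hydrogen-bond reward (H···O < 2.5 Å, N–H···O
> 120°), and the crosslink deviation penalty. It is declared plumbing: its
job is to rank conformers sensibly, not to approximate a physical free
energy, and nothing downstream depends on its absolute scale. Pairs within
a residue, between sequence neighbours, and across each ring's bridge are
excluded from the clash term.

## Ensemble selection

The search state is a subset of pool indices within configured size
bounds. Moves — add, remove, swap, proposed uniformly (the proposal
distribution is a design choice; nothing in the method fixes it) — are
rejected outright if they leave the bounds and otherwise accepted by the
Metropolis criterion; the lowest-scoring state *ever seen* is returned, so
the reported ensemble never depends on where the chain happens to end.
Upper-limit restraints contribute one-sided residuals by default
(`mode = "kind"`); a strictly symmetric mode exists because the
sum-of-squared-differences reading and NOE practice genuinely differ, and
the choice is surfaced rather than hidden. Scores use a precomputed
member × restraint matrix of d⁻⁶ values, so a move costs O(restraints).

When chemical shifts are supplied, the ensemble value is the *arithmetic*
mean of per-member predictions (shifts average linearly, unlike NOE
intensities) and only residues that are canonical with canonical sequence
neighbours contribute, since empirical shift predictors are unreliable
next to noncanonical residues; a missing terminal neighbour does not
disqualify a terminus.

`exhaustive_select()` enumerates every subset (refusing blowups past 10⁶)
and is the oracle the Monte-Carlo path is tested against;
`select_by_filter()` implements the alternative two-stage path — top
`n_restraint` (default 200) by NOE agreement, then top `n_final` (default
20) by energy — with stable-order tie-breaking.

## Atropisomer classification

Overlapping-ring lanthipeptides can be kinetically trapped in
non-interconvertible classes. The classifier computes, per probe quad, the
sign of the scalar triple product of three plane CAs and a probe CA — a
pseudoscalar: invariant under proper rigid motion, negated by mirroring.
Near-degenerate geometry (collinear plane, |signed distance| < 0.1 Å) is an
error, never a sign. Probe quads are the analyst's choice;
`discriminating_probes()` automates the selection against known candidate
classes (greedy cover of candidate pairs), and `suggest_probes()` offers a
topology-only heuristic. Majority filtering keeps the modal class and
refuses ties, requiring an explicit reference key; how to choose the
reference when majority and NOE support disagree is left to the user, who
must state the rule.

## Synthetic fixtures: what they do and do not emulate

The generators plant ground truth: `make_two_state_pool()` draws
ring-closed states separated by ≥ 1 Å backbone RMSD (default two states
among 40 decoys obtained by 60° torsion perturbation and re-closure), and
`make_noe_set()` computes observations *through the same r⁻⁶ machinery*
from the equal planted mixture, adds Gaussian noise (default 0.1 Å,
truncated at 0.5 Å), and keeps only observable pairs (d* ≤ 7 Å). The
default peptide (15 residues, two adjacent lanthionine rings, one Dha) is
small enough for exhaustive oracles.

These fixtures emulate multi-state averaging, restraint noise and ring
topology. They do **not** emulate spin diffusion, peak overlap, assignment
ambiguity beyond pseudoatoms, anisotropic motion, or unequal state
populations — so passing the recovery tests demonstrates that the selector
correctly inverts r⁻⁶ averaging under the stated noise model, not that
real spectra would be interpreted correctly end to end.
`make_ring_flip()` mirrors a ring span through the ring's best-fit plane:
an isometry of the span, so the thioether survives exactly and atoms
outside the span do not move; the junction bonds absorb the small mirror
displacement and the mirrored span has inverted local chirality — it is a
classifier fixture, not a claimed accessible conformation.

## Numerical choices

* Angles in degrees at every interface, radians internally; Å throughout;
  1-based residue numbering everywhere.
* Ring spans are inclusive intervals [min(donor, acceptor), max(...)];
  rings are direction-agnostic; identical spans are a degenerate
  classification error.
* φ of residue 1 and ψ of the last residue are recovered from the amide H
  and carbonyl O placements, so build → measure round-trips the full
  torsion set.
* Superposition uses Kabsch with the determinant correction: only proper
  rotations, so mirror images never superpose to zero.
* Ties in `select_by_filter()` break by stable input order; the ensemble
  state stores members sorted.
* Degenerate inputs error early and name the offender: missing atoms by
  residue/atom, malformed topology lines by line number, fully masked
  tables, empty ensembles, pools smaller than the size bounds.

## Test problem sizes

The suite exercises the full method at sizes chosen for exhaustive
verifiability: a 12-member pool with size-2–4 bounds (781 subsets) for
selector-vs-oracle comparisons over 50 seeds; the default 42-member
two-state fixture with 50 restraints and 20 seeded selector runs for the
recovery property; 10³–10⁵ draws for distributional checks. The sampler's
faithful presets (10⁵-scale pools, 500k selector steps) are configuration,
not test conditions.

## Known limitations

* The simplified score cannot reproduce force-field energetics; pool
  ranking quality is correspondingly coarse, and `select_by_filter()`
  accepts externally computed energies for that reason.
* CCD closure is sequential per ring; heavily entangled topologies may
  need many restarts (the sampler's permutation-and-retry loop is the
  mitigation, and failures are reported with their final gap).
* Proline is modelled without its ring (φ freely rotatable but its torsion
  table is tightly restricted); sidechains beyond the γ level do not
  exist in the atom model, so long-sidechain NOEs cannot be expressed.
* Chemical-shift prediction is a hook: the package consumes prediction
  tables, it does not compute them.
* Ring-topology and chirality *prediction* from sequence is out of scope
  by design; topologies are inputs.
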