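---
title: "Detecting transient peptide binding sites from trajectories: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transient peptide binding sites from trajectories: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peptscan)
```

## Scope and model

`peptscan` analyses molecular dynamics trajectories of a rigid-ish
folded receptor surrounded by mobile, unstructured peptide fragments,
and calls the receptor surface regions the fragments transiently bind.
It does not run dynamics: trajectories come from outside (or from the
package's own kinematic generator, used for validation). The two core
observables are a geometric one — RASAS, a solvent-accessibility ratio
that reports how much of a site the ligand occludes — and an energetic
one, the switched-cutoff pairwise nonbonded interaction energy. Site
calls require both: proximity alone (contact pairing) nominates
candidates, and the energy screen, splitting, merging and re-scoring
steps decide which survive.

The underlying assumptions: the ligand is disordered (no single pose to
dock, so per-frame occupancy statistics are the signal); binding is
dominated by surface electrostatics and shape, not induced fit; and the
receptor is stable enough that a site's residue set is meaningful
across the trajectory. For systems with large receptor conformational
changes the RASAS construction still cancels conformational SASA
changes (the same receptor context appears in numerator and
denominator), but the residue-set reporting becomes less meaningful.

## RASAS

For a site $S$ with ligand $L$ at frame $t$:

$$\mathrm{RASAS}(S,t) = \frac{\mathrm{SASA}(S,t \mid \text{$L$ present})}
                             {\mathrm{SASA}(S,t \mid \text{$L$ ignored})}$$

Both quantities are recomputed every frame. The target atoms are the
site's side chains by default, matching the intuition that side chains
form the interaction surface; glycine contributes its CA so its ratio
remains defined. Backbone atoms, the rest of the receptor, and any
cofactor role all occlude identically in numerator and denominator, so
the ratio isolates ligand occlusion. A value of 1 means no ligand
contact; lower values mean higher occupancy. With probe radius $p$, a
ligand atom starts stealing surface points exactly when its vdW surface
comes within $2p$ of a target atom's vdW surface — 2.8 Å for the water
probe of 1.4 Å used in site analysis. Run over the whole receptor with
$p = 2.5$ Å, $1-\mathrm{RASAS}$ is the fraction of receptor surface
covered within a 5 Å proximity.

### SASA numerics

SASA is computed by deterministic sphere-point sampling: each atom's
probe-expanded sphere carries a generalized-spiral (Fibonacci) point
set, and a point is occluded when it falls inside any other atom's
probe-expanded sphere. The spiral set needs no random seed, so every
result is bit-reproducible and the discretization error is testable:
for an isolated atom the sampled area equals $4\pi(r+p)^2$ by
construction, and the test suite asserts the relative error bound
$3/\sqrt{n}$ at $n \in \{200, 960, 5000\}$. The default is
`n_points = 960`; a floor of 100 points is enforced because coarser
sampling makes per-residue areas unreliable. Proximity detection at the
$2p$ threshold is sharp to roughly the angular spacing of the point
set; at 960 points the onset gap is recovered within about 0.01 Å on
the scan the acceptance script runs.

Two degenerate-input policies are worth stating. A sample point lying
*exactly* on an occluder's expanded sphere (within $10^{-9}$ Å) counts
as occluded only if the occluder precedes the target atom in atom
order; consequently two exactly coincident duplicate atoms contribute
one sphere's worth of area in total (first atom fully exposed, second
fully occluded) instead of zero or two, and no error is raised —
robustness on noisy synthetic input was preferred over strictness.
Waters and ions never occlude: they are dropped at file reading unless
explicitly kept, because the surface concept here is a protein surface.

## Nonbonded energies

The interaction energy between two atom groups is the sum over pairs of
a Coulomb term $332.0636\, q_i q_j / (\varepsilon_r r)$ (kcal/mol with
charges in e and distances in Å; relative dielectric 1 by default,
configurable) and a Lennard-Jones term
$\varepsilon_{ij}[(r_{min,ij}/r)^{12} - 2(r_{min,ij}/r)^6]$ with
Lorentz–Berthelot-style combination, both damped by the standard cubic
switching function: unity below 10 Å, zero beyond 12 Å,
$C^1$-continuous in between. These cutoffs mirror common simulation
practice; continuity is asserted on a fine radial grid in the tests.
No mesh Ewald or solvation terms enter the analysis — the energies are
interpretable interaction scores, not free energies.

The bundled nonbonded parameter table is deliberately reduced: element
vdW radii (C 1.7, N 1.55, O 1.52, S 1.8, H 1.2 Å), formal side-chain
charges localized on terminal polar atoms (Asp/Glu carboxylate oxygens
−0.5 each, Lys NZ +1, Arg NH1/NH2 +0.5 each), and generic per-element
LJ parameters. It is a TSV config; users with hydrogens and a real
force field can substitute full parameters without code changes.
Because charges sit on heavy atoms, hydrogen-free systems (such as the
synthetic fixtures) are handled naturally. Parameter assignment is
total-or-error: an atom that matches neither a specific row nor an
element fallback aborts the run, and missing parameters are `NA`, never
silent zeros.

Salt bridges are contacts between side-chain carboxylate oxygens
(Asp/Glu, or C-terminal OXT) and basic side-chain nitrogens (Lys NZ,
Arg NH1/NH2/NE) at ≤ 3.2 Å. Histidine ND1/NE2 participation is
optional and off by default, since neutral His is the common state at
physiological pH. Each (acidic atom, basic atom) pair that forms in at
least one frame is one event, carrying per-frame flags and an occupancy
fraction.

## The site-calling pipeline

1. **Contact pairing (7 Å).** A receptor residue is paired with a
   fragment in a frame when its centroid (unweighted mean of atom
   coordinates) lies within 7 Å of the centroid of *any* residue of
   that fragment. The centroid-to-centroid reading is the most direct
   codification of a per-residue proximity net; 7 Å is deliberately
   permissive, since later stages thin the candidates.
2. **Fragment splitting (gap ≥ 5, persistence 50 %).** A fragment
   residue is "attached" if it has contacts in at least half of the
   fragment's contact frames; a run of five or more consecutive
   unattached residues between attached stretches splits the pairing
   into independent interactions. Both numbers codify what a careful
   visual inspection would call "separate patches with slack chain in
   between", and both are exposed parameters.
3. **Energy screen (3 kcal/mol per residue).** A candidate region
   survives when the mean total interaction energy between its paired
   receptor residues and the whole fragment is at or below −3 kcal/mol
   × (number of paired receptor residues), averaged over the full
   trajectory. Averaging over all frames (not only contact frames)
   means sensitivity genuinely decays as dwell time shrinks — a
   fragment must both bind strongly and stay.
4. **Merging (5 Å, transitive).** Candidates merge when any heavy-atom
   pair between their residue sets is within 5 Å in the
   trajectory-average structure; merging is by connected components, so
   chains of adjacent patches collapse into one site whose fragment set
   is the union. Output order is deterministic (ascending minimum
   residue number).
5. **Re-scoring.** Each merged site's energy is recomputed against the
   union of its contributing fragments. Residues whose own mean energy
   is weaker than −0.5 kcal/mol are pruned (negligible contributors),
   as are residues whose ligand-ignored side-chain SASA averages below
   5 Å² (buried positions cannot bind). Sites failing the 3
   kcal/mol-per-residue screen after pruning are dropped. Every
   surviving call therefore satisfies the threshold after final
   re-scoring — an invariant the tests assert on all outputs — and is
   reported with mean ± sd energy, mean ± sd RASAS, per-residue
   energies and salt bridges.

Open choices, resolved as follows. Whether "per residue" counts
fragment residues is ambiguous in a two-sided pairing; here it counts
paired receptor residues only, which makes the threshold a property of
the called site. Whether reported means should use all frames or
post-binding frames only is equally open; all frames are used, which
penalizes short dwells and is stated wherever means are reported.

## The fragmenter

Unstructured tails are segmented into fragments of nominal length 30
(maximum 44) with 10-residue overlaps, so no binding region can be
destroyed by a cut without surviving intact in a neighbour. A fragment
end is extended while a proline lies within 3 residues of the end or of
the next fragment's start — prolines near termini distort peptide
conformations — and the final fragment is anchored to the sequence end
and back-extended to full length. Extension is forward-only until
`max_len`; if the window cannot be cleaned the nominal end is kept with
a warning rather than silently producing an over-long fragment. On a
proline-free 664-residue tail the defaults give exactly 33 fragments.

## Conservation classification

Alignment columns (against a user-supplied MSA; the package never
computes alignments) are classified per reference residue:
`fully_conserved` when all non-gap symbols are identical,
`group_conserved` when they share one charge/polarity group,
`gap_majority` when more than half the rows are gaps, else
`not_conserved` — tested in that order, so identical survivors in a
gappy column still count as conserved. The default groups are acidic
{D,E}, basic {K,R,H}, polar uncharged {S,T,N,Q,C,Y,G}, nonpolar
{A,V,L,I,M,F,W,P}; group membership is a documented convention and an
argument, not a constant, because reasonable schemes differ (notably
for G, C and H).

## The synthetic generator, and what passing tests mean

`make_toy_receptor()` builds a rigid coarse chain — four backbone atoms
plus a compact 1–2-atom side chain per residue — on a smooth planar
arc, side chains outward, with designated patches built as glutamate
(−1 e) or lysine (+1 e) and everything else neutral. Side chains are
kept compact so that residue centroids of contacting partners fall
within the 7 Å pairing distance, as they do for real side chains.
`make_binding_trajectory()` moves rigid fragments along scripted
approach / dwell / retreat paths: at rest a fragment sits 25 Å out
(never nearer than 15 Å), approaches to a 6 Å staging gap, then dwells
at the scheduled vdW surface gap (default 0 Å — a van der Waals
contact, as formed by a salt bridge). Isotropic Gaussian noise (default
σ = 0.2 Å) is added to fragment atoms; the receptor stays rigid. With
zero noise, the frames below the 2.8 Å RASAS proximity are *exactly*
the dwell frames, which is what makes the generator a ground-truth
oracle.

The generator emulates: charged-patch surface binding, transient
attach/detach kinetics, multiple simultaneous fragments, positional
noise. It does not emulate: internal fragment flexibility, induced fit,
solvent, competing non-specific adsorption, or force-field physics of
any kind (motion is kinematic). Passing the recovery tests therefore
shows that the *analysis chain* is correct and sharp at its thresholds
— not that the thresholds are optimal for any particular real system,
where dwell fractions, charge densities and noise differ. The test
suite and acceptance checks run on a 100-residue receptor with three
4-residue patches, three hexapeptide fragments and 45 frames (about
600 atoms), a size chosen so the full pipeline runs in seconds while
still exercising splitting, merging and re-scoring; recovery is
asserted across five independent seeds with noise on.

## Known limitations

- Energies use the reduced united-atom parameter table unless a real
  force-field table is supplied; absolute magnitudes on real systems
  should be interpreted comparatively, not thermodynamically.
- RASAS is sampled, not analytic; per-atom areas carry
  $O(1/\sqrt{n})$ noise, though ratios of identical point sets are
  exact at 1 when nothing occludes.
- The splitting persistence rule (50 % of contact frames) is a
  codified heuristic for "attached"; pathological on/off flickering
  near the threshold can move a split by a residue or two.
- Trajectories are held in memory as dense arrays; the design targets
  per-site analyses over hundreds of frames, not multi-microsecond
  whole-system scans.
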