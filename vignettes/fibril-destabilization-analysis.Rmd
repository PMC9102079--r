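---
title: "Methods: beta-sheet breaker design and protofibril destabilization analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beta-sheet breaker design and protofibril destabilization analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Amyloid-beta protofibrils of the U-shaped polymorph are pentamers of
A&beta;17--42 chains stacked in register along the fibril axis. Three classes
of interactions hold the stack together: inter-chain backbone hydrogen-bond
ladders, &pi;--&pi; stacking between the phenylalanine rings of F19 and F20
(internal positions 3 and 4 of each 26-residue chain), and Asp23--Lys28
salt bridges (internal positions 7 and 12), both within a chain and between
a chain and its successor. Hexapeptide beta-sheet breakers (BSBs) derived
from LPFFFD --- two hydrophobic residues, three consecutive aromatics, an
acidic C-terminus --- are designed to intercalate into this interaction
network and pry chains off the stack.

`fibrilbreak` implements the full in-silico battery around that idea:
generating the combinatorial BSB library, building an idealized pentamer
with or without a bound hexapeptide, simulating stand-in structural
ensembles with controllable interaction statistics, and quantifying
destabilization through interaction occupancies, radius of gyration,
secondary structure, RMSD clustering, and a single-trajectory MM-GBSA
binding free energy decomposition.

## Peptide library combinatorics

The substitution scheme allows, per position of LPFFFD: L &rarr;
{A,G,I,M,P,V}; P &rarr; {A,G,I,L,M,V}; each F &rarr; {W,Y}; D &rarr; {E}.
The number of sequences with exactly *k* substituted positions is the *k*-th
elementary symmetric polynomial of the per-position alternative counts
(6, 6, 2, 2, 2, 1): 1, 19, 138, 488 for *k* = 0..3. The widely quoted
627-member library equals reference + doubles + triples (1 + 138 + 488);
including single mutants gives 646. `generate_library()` therefore defaults
to `mutation_counts = c(0, 2, 3)` to match the canonical library size, with
`c(0, 1, 2, 3)` one argument away; `count_variants()` provides the
closed-form check. Output is deduplicated and lexicographically sorted so
the library is reproducible byte for byte.

## The synthetic fibril and what it does (not) emulate

`build_pentamer()` constructs a pseudo-atom pentamer whose geometry
*guarantees* the detection criteria rather than approximating a real force
field minimum:

* each chain traces a U-shaped path in the plane perpendicular to the
  fibril axis (10-residue strand, 6-residue turn, 10-residue strand,
  3.47 &Aring; per residue), and chains stack at a 4.8 &Aring; cross-beta
  rise;
* the amide hydrogen of residue *i* points along the fibril axis toward the
  neighbouring chain, alternating direction with residue parity, and the
  carbonyl oxygen of residue *i* sits collinearly on the donor column of
  residue *i*&minus;1 of the facing chain. This alternating ladder is what
  makes the Kabsch--Sander *parallel*-bridge patterns hold for every
  neighbouring chain pair, so the stable pentamer scores as parallel beta
  sheet and every adjacent pair carries 25 backbone hydrogen bonds
  satisfying the 3.2 &Aring;/120&deg; criterion with margin;
* Phe rings at positions 3 and 4 are regular hexagons in the chain plane,
  so neighbouring ring centroids sit exactly one rise apart
  (4.8 &le; 5.5 &Aring;);
* the Asp-7 carboxylate carbon and Lys-12 ammonium nitrogen are placed on a
  shared axis between the turn strands, giving CG--NZ distances of
  2.0 &Aring; (intra-chain) and 2.8 &Aring; (chain *i* &rarr; *i*+1). The
  contract here is satisfaction of the distance criteria, not rotamer
  realism; the side-chain pseudo-atoms are deliberately schematic.

`simulate_trajectory()` adds i.i.d. Gaussian noise to the *ideal*
coordinates every frame --- never a random walk --- so interaction
occupancies are stationary and analytically checkable. Three scenario kinds
cover the analysis space: `stable` (noise only), `perturbed` (a per-frame
Bernoulli toggle rigidly displaces designated chains 2 &Aring; outward, so
every interaction involving them holds in &asymp; `target_occupancy` of
frames), and `dissociation` (from `t_start`, designated chains drift
outward at `drift_velocity` with slow tumbling). Default noise is
0.1 &Aring; (0.05 &Aring; for `perturbed`, small against the 0.3 &Aring;
hydrogen-bond margin so the toggle, not the noise, sets the occupancy).
Everything is deterministic given the scenario seed.

What the generator does *not* emulate: force-field energetics, water,
thermalized fluctuation spectra, side-chain rotamers, partial unfolding, or
ligand-induced conformational change. Green tests on synthetic ensembles
therefore certify the *analyzers* (their geometry, statistics and
bookkeeping), not any biophysical prediction about real fibrils.

## Interaction detectors and occupancy statistics

| criterion | default | units | notes |
|---|---|---|---|
| H-bond donor--acceptor distance | 3.2 | &Aring; | plus donor-H-acceptor angle &ge; 120&deg; |
| ring stacking (centroid) | 5.5 | &Aring; | `method = "minatom"` selectable |
| salt bridge CG--NZ | 4.5 | &Aring; | intra-chain and chain *i* &rarr; *i*+1 |
| molecular contact (heavy atom) | 4.5 | &Aring; | chosen to match the salt-bridge scale |
| occupancy tiers | 30/50/70 | % | lower edge inclusive |

Donors are backbone amide N (an ideal planar H at 1.01 &Aring; on the
C(prev)--N/CA--N bisector is reconstructed when the structure has no
hydrogens; a chain-start N without H is skipped with a warning) plus
template side-chain N/O with attached hydrogens; acceptors are backbone O
plus side-chain oxygens. Stacking distance is measured between ring
centroids by default because a residue-level cutoff needs a representative
point; the closest-ring-atom alternative is exposed. Tier boundaries are
inclusive at the lower edge (occupancy exactly 0.70 counts as "&ge;70%").
`occupancy()` reports the union of interactions ever observed; the global
salt-bridge occurrence is the sum of per-pair occupancies &times; 100, so
it ranges 0--500% (intra) and 0--400% (inter) and values above 100 simply
mean several pairs persist simultaneously.

Pose ranking combines the three selection criteria (most contacts, most
favourable interaction energy, most favourable overall energy) by mean
rank, with ties broken by contact rank and then input order. The
combination rule is this package's choice; the three criteria themselves
are standard, but no canonical aggregation exists, so the mean rank was
picked as the simplest symmetric rule and is documented as such.

## Conformational analyses

RMSD series superpose each frame on a reference (first frame by default)
with the Kabsch algorithm (SVD with reflection correction) before
measuring, over backbone or C-alpha selections, with and without the
ligand. The radius of gyration is mass-weighted.

Clustering operates on pre-fitted C-alpha coordinates, where Euclidean
distance over flattened coordinates divided by sqrt(n_atoms) *is* the
pairwise RMSD. Agglomerative average-linkage merging stops when the minimum
inter-cluster average distance exceeds `epsilon` (default 4.5 &Aring;,
implemented as a tree cut, which is equivalent because average-linkage
merge heights are monotone). Because no single rule combines the epsilon
cut with the three quality indices, the result reports Davies--Bouldin,
pseudo-F and SSR/SST both at the cut and one merge earlier/later
(`metrics_neighbors`), leaving the final cluster-count choice to the user.
For a single cluster DBI and pSF are undefined and reported as `NA`, and
SSR/SST is 0.

Secondary structure is a self-contained Kabsch--Sander implementation:
backbone hydrogen bonds scored by
E = 0.084 &middot; 332 &middot; (1/r~ON~ + 1/r~CH~ &minus; 1/r~OH~ &minus; 1/r~CN~)
kcal/mol, bonded when E < &minus;0.5; parallel/antiparallel bridges by the
standard residue-index patterns (restricted to sequence separation &ge; 3
or different chains, since ladders between sequence neighbours are
meaningless); helices from consecutive i&rarr;i+3/4/5 turns; bend from
C-alpha curvature above 70&deg;. Priority: helix > sheet > turn > bend >
coil, with parallel taking precedence over antiparallel on ties. Residues
with missing backbone atoms fall back to coil with a warning.

## Energetics

The single-trajectory binding free energy is
&Delta;G~bind~ = &Delta;E~ele~ + &Delta;E~vdW~ + &Delta;G~GB~ + &Delta;G~np~,
each delta being complex &minus; receptor &minus; ligand with receptor and
ligand coordinates extracted from the complex frame. The internal
(bonded) term then cancels identically, which the code asserts rather than
assumes, and the solute entropy term is deliberately not computed.
Gas-phase terms use dielectric 1 and no cutoff; 1-2/1-3 exclusions and 1-4
scaling (1/1.2 electrostatic, 1/2 Lennard-Jones) are supported when a
bonded topology is supplied, and default to none for the synthetic
pseudo-topology.

The polar term is a generalized Born model with OBC-style rescaled
pairwise descreening (tanh coefficients 1, 0.8, 4.85; dielectric offset
0.09 &Aring;; uniform screening scale 0.8; all argument-pinned so results
are deterministic), solute/solvent dielectrics 1/78.5, and the standard
f~GB~ interpolation including the i = j self term. The non-polar term is
&gamma;&middot;SASA with &gamma; = 0.0072 kcal/(mol &Aring;&sup2;) ---
&gamma; and the radii set are not canonical, so both are configuration
knobs with the defaults stated here.

SASA uses the LCPO (linear combination of pairwise overlaps) construction.
The published per-atom-type parameter tables are fits to bonded protein
geometry; this package's pseudo-atoms are not in those tables, so the
default `"generic"` parameter set was fitted once, by least squares against
numerically integrated reference areas of random sphere clusters, in
exactly the way LCPO sets are produced (training seed fixed and distinct
from all test seeds; independent evaluation error &le; ~4% of total area).
Atoms without overlapping neighbours always get the exact sphere area, so
isolated and far-separated atoms are exact. `mmgbsa()` defaults to the
published Amber sp3-carbon set instead, because molecular interiors are in
the bonded-geometry regime that set was fitted for.

The synthetic topology ships a minimal self-consistent parameter set
(&plusmn;1 e on the salt-bridge sites, small amide-group partial charges,
uniform per-element Lennard-Jones classes and GB radii). It is *not* a
protein force field, so absolute binding energies of the synthetic complex
are illustrative only; the tested claims are the decomposition identities,
the closed-form Born-ion limit, and oracle agreement of each term.

## Dissociation events

Chain dissociation is detected from two signals that both must hold
continuously for at least `contact_free_span` (ns): zero heavy-atom
contacts (4.5 &Aring;) between the chain and the remaining fibril, and a
minimum separation of at least `distance_floor` (8 &Aring;). The onset is
the first frame of the qualifying span and the event is persistent when the
span reaches the trajectory end. Narrative descriptions of dissociation do
not fix a quantitative rule, so this criterion is the package's own; both
knobs are exposed and recorded in the run manifest.

## Problem sizes and determinism

The test-suite and the reproduction script run entirely on synthetic
inputs sized for a laptop-class single core: occupancy-recovery ensembles
of 2000 frames, contrast scenarios of 300--400 frames with secondary
structure strided 3--4&times;, clustering on &le; 100 strided frames,
MM-GBSA on a handful of frames, and oracle-equivalence sweeps of 1000+
randomized small systems. These sizes were chosen so each statistical
check retains comfortable power (e.g. the binomial 3-sigma band at
n = 2000 is &plusmn;2.7% at p = 0.2) while the whole battery stays fast.
All randomness flows through explicit scenario seeds; identical
configuration and seed give byte-identical trajectories and report tables.

## Known limitations

* The synthetic generator validates analyzers, not biophysics; no
  conclusion about real fibrils follows from green tests alone.
* The energy backend is an end-state continuum model with a toy parameter
  set: no PB solver, no entropy, no per-residue decomposition.
* The secondary-structure assigner covers the standard categories but not
  polyproline or bridge-versus-extended distinctions.
* PDB I/O reads ATOM/HETATM multi-model files only; binary trajectory
  formats and topology files are out of scope.
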