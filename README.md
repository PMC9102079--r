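# fibrilbreak

Design and in-silico evaluation of hexapeptide **beta-sheet breakers
(BSBs)** against the U-shaped amyloid-beta protofibril.

The U-shaped polymorph of the A&beta;17–42 protofibril is a pentamer of
identical chains stacked in register along the fibril axis. Its stability
rests on three interaction networks: inter-chain backbone hydrogen-bond
ladders, &pi;–&pi; stacking of the F19/F20 phenylalanine rings (internal
positions 3 and 4), and D23–K28 salt bridges (internal positions 7 and 12),
both intra-chain and between successive chains. BSB hexapeptides derived
from LPFFFD — two hydrophobic residues, three consecutive aromatic
residues, an acidic C-terminus — target this network. `fibrilbreak` is for
structural bioinformaticians who want to reproduce, test, or extend the
analysis pipeline around that idea without a molecular-dynamics engine in
the loop.

The package provides:

* **Peptide library generation** — all variants of LPFFFD under the
  per-position substitution scheme (L→AGIMPV, P→AGILMV, F→WY, D→E). The
  number of k-substitution variants is the k-th elementary symmetric
  polynomial of the alternative counts (6,6,2,2,2,1): 1, 19, 138, 488. The
  default library (reference + doubles + triples) has **627** members; with
  single mutants, 646.
* **A synthetic protofibril** — `build_pentamer()` constructs an idealized
  five-chain U-shaped model (26 residues per chain, dual numbering:
  internal 1–26 ↔ A&beta; 17–42 ↔ continuous serials 1–130, ligand
  131–136) whose geometry guarantees the interaction criteria by
  construction, and `simulate_trajectory()` produces deterministic,
  seed-controlled stand-in ensembles with programmable interaction
  occupancies and chain-dissociation events.
* **Interaction analysis** — hydrogen bonds (donor–acceptor ≤ 3.2 Å,
  donor-H-acceptor ≥ 120°), ring stacking (centroids ≤ 5.5 Å), Asp–Lys
  salt bridges (CG–NZ ≤ 4.5 Å), heavy-atom contacts, per-interaction
  occupancies tiered at 30/50/70 %, and docking-pose ranking.
* **Conformational analysis** — Kabsch superposition, RMSD series with and
  without the ligand, mass-weighted radius of gyration, average-linkage
  RMSD clustering with an epsilon cut (default 4.5 Å) plus
  Davies–Bouldin / pseudo-F / SSR-SST quality indices, and a
  Kabsch–Sander secondary-structure assigner.
* **Energetics** — a self-contained single-trajectory MM-GBSA
  decomposition: ΔG_bind = ΔE_ele + ΔE_vdW + ΔG_GB + ΔG_np, with
  dielectrics 1/78.5, OBC-style generalized Born radii, LCPO surface
  areas and γ·SASA non-polar term; ΔE_int vanishes identically in
  single-trajectory mode.
* **A pipeline** — `run_pipeline()` drives everything from a (YAML-able)
  configuration to a TSV report bundle with a reproducibility manifest;
  `detect_dissociation()` flags chains that lose all inter-chain contacts.

## Worked example

```r
library(fibrilbreak)

lib <- generate_library()
nrow(lib)
#> [1] 627
head(lib, 3)
#>   sequence n_mutations
#> 1   AAFFFD           2
#> 2   AAFFFE           3
#> 3   AAFFWD           3

model <- build_pentamer(ligand = "MIFFFE", ligand_site = "core")
model
#> fibril_model: 910 atoms, 5 fibril chain(s) + ligand

tr <- simulate_trajectory(model, scenario("stable", seed = 42), n_frames = 200)

hb <- occupancy(tr, "hbond")        # inter-chain hydrogen bonds
tier_counts(hb)
#>         >=30%         >=50%         >=70% total_present
#>           100           100           100           100

round(ss_occupancy(tr, stride = 4), 1)
#>     parallel-beta antiparallel-beta         helix-310       helix-alpha
#>              92.3               0.0               0.0               0.0
#>          helix-pi              turn              bend              coil
#>               0.0               0.0               0.0               7.7
#>          sum_beta
#>              92.3

global_salt_bridge_occurrence(tr)
#> intra_percent inter_percent
#>           500           400
```

Reading the numbers: the stable complex keeps all 100 inter-chain backbone
hydrogen bonds (25 per neighbouring chain pair) in the ≥ 70 % occupancy
tier; 92.3 % of (residue, frame) pairs are parallel beta sheet (the chain
termini are coil); and all five intra-chain plus all four inter-chain salt
bridges persist in every frame, giving the maximal global occurrences of
500 % and 400 %. In a dissociation scenario
(`scenario("dissociation", chains = "E")`) the same battery shows the
destabilization signature instead: higher fibril radius of gyration, lower
beta-sheet occupancy, fewer top-tier hydrogen bonds and reduced
position-3/4 stacking.

A thin command-line front-end ships in `inst/scripts/fibrilbreak.R`
(`library`, `simulate`, `run --config config.yaml` subcommands).

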