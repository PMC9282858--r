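# memdyn

Trajectory-analysis battery for membrane-protein molecular dynamics,
built around one scientific question: does a lipid bilayer stabilize an
intramembrane protease's substrate-engaged conformation better than a
detergent micelle? The package implements the standard metric set used
to answer it — per-residue flexibility, secondary-structure stability of
a marker helix, enzyme–substrate β-sheet hydrogen bonding, residue water
accessibility, active-site geometry occupancy, and the order and packing
of the surrounding amphiphiles — together with a deterministic synthetic
trajectory generator so that every metric can be validated against known
ground truth without multi-microsecond simulation data.

The intended user analyzes simulations of an aspartyl intramembrane
protease (a presenilin/SPP-family enzyme bound to an amyloid-precursor
C-terminal fragment) reconstituted either in a POPC bilayer or a DDM
micelle, with three replicate runs per environment.

## The metrics

* **RMSF** — for residue *i* with backbone atoms *a* and window frames *t*
  after superposition onto the iteratively refined time-average
  structure:
  RMSF(i) = sqrt( mean over t, a of || x_a(t) − ⟨x_a⟩ ||² ), in Å.
  Replicates are aggregated as the mean of the per-trajectory values
  with the **SD of the mean** (the sample SD of the n = 3 per-trajectory
  means) as the uncertainty.
* **Secondary structure** — a reduced three-state DSSP: backbone
  hydrogen bonds by the Kabsch–Sander energy
  E = q₁q₂(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)·332 kcal/mol
  (q₁ = 0.42 e, q₂ = 0.20 e, accepted when E < −0.5), α-helix from two
  consecutive i→i+4 turns, strand from bridge patterns; helicity of a
  region is its per-frame fraction of H residues.
* **Hydrogen-bond occupancy** — counts of inter-strand backbone bonds
  between the enzyme β2-strand and the substrate β3-strand, by a
  geometric criterion (N···O ≤ 3.5 Å, N–H···O ≥ 135°) or the
  Kabsch–Sander energy.
* **Water accessibility** — mean number of water molecules with any atom
  within 5 Å of any atom of a residue, per frame, minimum-image.
* **Active-site geometry** — the Cγ–Cγ distance of the two catalytic
  aspartates; the fraction of frames below 7.0 Å (a
  proteolysis-compatible geometry) with a block-bootstrap CI.
* **Lipid order** — S_CH = ⟨(3 cos²θ − 1)/2⟩ of each tail C–H vector
  against the membrane normal (or protein principal axis); **area per
  lipid** by periodic 2-D Voronoi tessellation of headgroup positions,
  per leaflet.

## Worked example

Two synthetic systems with the package's default study conditions
(three replicates each; the micelle mode has the elevated marker-helix
mobility, scheduled helix–coil transitions and lower active-geometry
occupancy):

```r
library(memdyn)
for (mode in c("bilayer", "micelle")) {
  spec  <- synthetic_spec(mode, seed = 7, n_frames = 150, n_replicates = 3)
  trajs <- generate_protein_trajectory(spec)
  tr    <- trajs[[1]]
  ds  <- distance_series(tr, distance_spec("chain A and resid 162 and name CG",
                                           "chain A and resid 220 and name CG"))
  fb  <- fraction_below(ds, threshold = 7.0, seed = 1)
  flex <- resolve_selection(tr$topology, "chain A and resid 171-177")
  hel  <- helicity_series(assign_secondary_structure(tr, flex), flex,
                          top = tr$topology)
  fit  <- resolve_selection(tr$topology, "chain A and backbone")
  agg  <- aggregate_replicates(lapply(trajs, function(t)
            rmsf_profile(t, fit, window = 1/3)))
  marker <- grepl("^A/17[1-7]/", agg$label)
  cat(sprintf("%-8s active fraction %.3f [%.3f-%.3f] | helicity %.2f | TMD6a-like RMSF %.2f +/- %.2f A\n",
              mode, fb$fraction, fb$ci[1], fb$ci[2], mean(hel$series$values),
              mean(agg$mean[marker]), mean(agg$sd_of_mean[marker])))
}
```

prints

```
bilayer  active fraction 0.827 [0.773-0.880] | helicity 0.72 | TMD6a-like RMSF 0.42 +/- 0.06 A
micelle  active fraction 0.640 [0.573-0.707] | helicity 0.08 | TMD6a-like RMSF 2.24 +/- 0.23 A
```

Read: in the bilayer-mode system the catalytic pair samples the
proteolysis-compatible geometry (< 7 Å) in ~83% of frames of this
150-frame replicate, the marker helix stays helical and rigid; in
micelle mode the active fraction drops toward its generator truth of
0.63, the helix unfolds and its backbone fluctuates five-fold more. The
full battery over whole bundles runs through `simulate_bundle()`,
`run_analysis()` and `compare_environments()`, which also writes every
table as CSV/JSON; `inst/cli/memprot-dyn.R` wraps the same three verbs
for shell use.

Real trajectories enter through `read_pdb()` (fixed-column PDB, also
multi-model) or the package's plain-text `xyz-table` CSV dialect
(`read_trajectory()`), with selections such as
`"chain B and resid 171-177 and backbone"`.

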