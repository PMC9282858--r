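---
title: "Methods: trajectory metrics for the micelle-versus-bilayer contrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory metrics for the micelle-versus-bilayer contrast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and model of the data

`memdyn` analyzes molecular-dynamics trajectories of a membrane-embedded
enzyme–substrate complex — the motivating system is an archaeal
presenilin/SPP-homolog protease bound to an amyloid-precursor C83
fragment, simulated in either a DDM detergent micelle or a POPC lipid
bilayer, three replicate runs per environment. The package does not run
dynamics; its inputs are a topology (PDB) and coordinate frames
(multi-model PDB or a documented plain-text table), and its outputs are
the metric battery used to compare the two hydrophobic environments:

* backbone RMSF per residue, about a time-averaged reference,
* three-state secondary structure and helicity of a marker helix
  (TMD6a, enzyme residues 171–177 in the motivating system),
* hydrogen-bond occupancy of the enzyme–substrate hybrid β-sheet
  (β2-strand 213–217 against substrate β3-strand 50–54),
* residue-wise water accessibility (5 Å criterion),
* the Cγ–Cγ distance between the catalytic aspartates (162/220) and the
  fraction of frames below 7 Å,
* lipid-tail order parameters S_CH and area per lipid.

All coordinates are in Å. Only orthorhombic periodic boxes are
supported: the reconstituted micelle and bilayer systems this package
targets are simulated in rectangular cells, and minimum-image
arithmetic in a triclinic cell would complicate every kernel for no
supported use case; a triclinic `CRYST1` record raises an explicit
error. Chain identities (which chain is the enzyme, which the
substrate) are never guessed — configs name them explicitly, because
deposited models differ in their chain lettering.

# The RMSF protocol

The flexibility readout follows the convention of analyzing the final
stretch of each run against its own time-average structure, fitted on
backbone atoms. Because a time-average structure itself depends on the
superposition, the reference is refined iteratively: frames are fitted
to an initial reference (the window's first frame), averaged, re-fitted
to that average, and re-averaged, until the mean structure moves less
than `tol` (default 1e-3 Å RMSD) or `max_iter` passes (default 2) are
exhausted. Two passes are sufficient in practice: the first pass
removes the arbitrary global orientation, the second fits against an
already consistent average; further passes change the mean by less than
the tolerance. The procedure is deterministic.

"Last 200 ns of 600 ns" generalizes to a trailing *fraction* of frames
(default 1/3), because synthetic trajectories carry no physical time;
an explicit frame range is accepted where times exist. Windows shorter
than 10 frames are refused — an average over fewer frames is not a
meaningful reference.

Superposition uses the Kabsch SVD solution with the determinant
correction, uniform weights (no mass weighting is implied by the
protocol this mirrors), and an error on collinear references. Whether
the original stability analyses fitted backbone-only or all heavy atoms
is not documented; the default here is backbone (N, CA, C, O),
configurable through the selection grammar.

Replicate aggregation everywhere is the **SD of the mean**: the sample
standard deviation of the n per-trajectory means. This is deliberately
*not* SD/sqrt(n) of pooled frames — frames within a run are strongly
autocorrelated, and the replicate-level spread is the honest
uncertainty at n = 3.

# Hydrogen bonds and the reduced DSSP

Two bond criteria are implemented and both are reported, because the
criterion behind published β-sheet bond counts is typically left
unstated:

* geometric (the common trajectory-tool default, made explicit):
  donor–acceptor N···O ≤ 3.5 Å **and** N–H···O angle ≥ 135°;
* Kabsch–Sander: E = 0.42·0.20·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)
  kcal/mol, accepted when E < −0.5, with any distance below 0.5 Å
  treated as a clash. The Kabsch–Sander criterion is strictly more
  permissive near the cutoff: on the package's ideal antiparallel sheet
  fixture it accepts the same strong ladder as the geometric criterion
  plus four marginal bonds at E ≈ −0.53 kcal/mol.

Amide hydrogens are reconstructed when absent: H at 1.01 Å from N along
the outward bisector of C(prev)–N–CA, the standard DSSP placement;
prolines and chain N-termini get none.

Secondary structure is a reduced three-state DSSP (H/E/C): residues
i..i+3 become H when two consecutive i→i+4 turns start at i−1 and i;
strand (E) comes from the parallel/antiparallel bridge patterns between
non-adjacent residues; all else is coil. 3-10 and π helices count as
coil: the scientific readout is the strict α-helix-versus-loop
dichotomy of the marker helix, and folding 3-10 turns into H would blur
exactly the transition being monitored. Helix takes precedence over
strand. Consecutive residues with CA–CA above 4.5 Å split the
assignment into segments. The H-bond network is computed over the
selection's residues plus four flanking residues per side — enough
context for every i→i+4 turn at the region edges — rather than over
whole chains, keeping the per-frame cost quadratic in the region, not
the protein.

Helicity of a region is its per-frame fraction of H residues.
Transition events are threshold crossings (default 0.5) that persist
for at least `min_dwell` frames (default 5) on both sides; shorter
excursions are treated as noise and merged.

# Solvation

A residue's water accessibility in a frame is the number of water
*molecules* (not atoms) with any atom within 5 Å of any atom of the
residue, minimum-image when a box is present. "Any atom" includes
hydrogens when present; a heavy-atom-only mode exists because some
workflows strip hydrogens. Neighbor search uses a cell list with cell
edges at least the cutoff, scanning the 27 neighboring cells; the
result is exactly the all-pairs answer (this identity, not an
approximation, is what the tests assert).

# Lipid metrics

S_CH for tail carbon k is the average of (3 cos²θ − 1)/2 over all C–H
vectors of that position, all lipids and all frames, with θ against the
reference axis. The axis defaults to the box normal (z) for bilayers
and the protein principal axis (dominant eigenvector of the gyration
tensor) for micelles — mirroring the alignment convention in which the
protein axis coincides with the membrane normal once embedded. S_CH is
reported signed (1 = parallel, −0.5 = perpendicular, 0 = isotropic)
with an absolute-value column alongside, since published order plots do
not always disclose sign handling. Missing hydrogens are reconstructed
tetrahedrally from the flanking carbons; a perfectly collinear local
chain leaves the azimuth undefined, in which case a deterministic
perpendicular is chosen (and terminal carbons without hydrogens are
skipped with a warning).

Leaflets are assigned from headgroup z: midplane at the mean, leaflet
by sign, lipids within 2 Å of the midplane unassigned. The bilayer
check is a bimodality test on |z − midplane| (spread/mean ≤ 0.3, both
leaflets populated, ≤ 20 % unassigned); a mean-separation test alone
cannot reject a micelle, whose uniform z profile happily splits into
two "leaflets". Micelles therefore get S_CH but *no* area per lipid —
the quantity is undefined without leaflets, and the tool refuses with
"not a bilayer" rather than returning a number.

Area per lipid offers `box_ratio` (lateral box area / leaflet count)
and `voronoi`: a periodic 2-D Voronoi tessellation of headgroup
positions projected on the xy-plane. Each cell is built by half-plane
clipping: the point's own periodic images reduce exactly to the
starting rectangle p ± box/2, and other generators (their nine images)
are applied nearest-first with a rigorous stopping bound — a generator
farther than twice the current maximal vertex radius cannot cut the
cell — so the tessellation is exact, and cell areas sum to the lateral
box area to floating-point accuracy. The per-leaflet Voronoi mean
necessarily equals the box ratio (conservation); the added value of the
tessellation is the per-lipid area distribution.

# The synthetic generator

The generator produces data with the *statistical structure* the
metrics assume — it is pseudo-physical validation machinery, not
molecular dynamics. No force field, no energetics, no thermostat; a
"trajectory" is a reference geometry plus stochastic processes chosen
so that every downstream estimate has a known truth, emitted in a
ground-truth sidecar (JSON) next to the data.

What it emulates, and how:

* **Architecture.** Chains are poly-alanine backbones built from ideal
  bond geometry (NeRF chain construction) as 30-residue helical
  segments arranged as a bundle — a crude transmembrane-fold stand-in
  that keeps a 290-residue chain inside an 80 × 80 × 100 Å box. The
  defaults mirror the motivating system: enzyme chain A of 290
  residues with the marker helix at 171–177 and catalytic pseudo-CG
  atoms at residues 162 and 220; substrate chain B of 83 residues.
* **Fluctuations.** Each residue carries a rigid displacement following
  a stationary AR(1) process (frame correlation 0.9) with per-residue
  amplitude σ (default 0.3 Å per coordinate; micelle mode triples it in
  the marker region). Per-residue (rather than per-atom) displacement
  preserves local bond geometry, so secondary-structure assignment
  stays meaningful at realistic noise. The AR(1) correlation is there
  deliberately: SD-of-mean aggregation and block-bootstrap CIs are only
  meaningfully exercised on autocorrelated frames.
* **Rigid-body motion.** A uniformly random rotation plus a Gaussian
  translation (sd 2 Å) is applied to every frame, so superposition is
  actually load-bearing in every test that uses the generator.
* **Helix schedule.** In micelle mode the marker-helix dihedrals
  interpolate between helical (−57°, −47°) and extended (−139°, 135°)
  values on a helix/coil/helix schedule (thirds of the run, 5-frame
  ramps), hinging at the segment start. Bilayer mode stays helical.
* **Active-site distance.** A two-state Markov process: means 6.8 Å
  (active) and 8.5 Å (inactive), within-state jitter 0.04 Å — five
  sigma from the 7 Å threshold, so below-threshold occupancy equals the
  stationary active probability exactly (0.76 bilayer, 0.63 micelle).
  The switching rate parameter is 0.5 per frame, chosen at design time
  from a power analysis: with ~300-frame replicates the integrated
  autocorrelation then leaves enough effective samples that the
  0.76-vs-0.63 contrast stands above the replicate SD of the mean. The
  two pseudo-CG atoms realize the drawn distance exactly, so the
  trajectory-measured series *is* the process.
* **Waters.** n uniform waters take wrapped diffusive steps (sd 0.3
  Å/frame); they exist to exercise the solvation kernel, not to model
  hydration structure.
* **Amphiphiles.** Bilayer mode: two leaflets on a jittered lattice,
  tail directors drawn per lipid per frame from a von Mises–Fisher
  distribution about the inward normal with concentration κ (default
  20); micelle mode: headgroups on a sphere, directors about the inward
  radial with κ = 0.5. Tails are all-trans chains with both hydrogens
  exactly perpendicular to the director, which makes the implied order
  parameter analytic — E[S_CH] = −½·E[P2(director·axis)] — and the
  sidecar tabulates it by direct Monte Carlo over the director
  distribution. The bilayer's lateral box (66 × 66 Å for 64 lipids per
  leaflet) is sized to give an area per lipid of ~68 Å², the value
  expected of a POPC membrane.
* **Determinism.** The spec seed fully determines all output; replicate
  r uses seed + r, the amphiphile system seed + 100 + r.

What it does **not** emulate — and what passing tests therefore cannot
show about real data: no real energetics or packing (clashes are
ignored), no coupling between protein and lipids or waters, no
hybrid β-sheet geometry between the β2/β3 selections (sheet detection
is validated on constructed ideal-geometry fixtures instead), no
sequence effects (poly-alanine throughout), and no physical time
scale. Recovery tests certify the estimators; they say nothing about
force-field quality.

# Numerical choices and degenerate inputs

* Kabsch: determinant-corrected SVD; collinear references error out;
  weights uniform unless given.
* `fraction_below` uses strict `<` at the threshold; ties count above.
  Immaterial for continuous data, documented for reproducibility.
* Block bootstrap: 1000 resamples, circular blocks of 50 frames,
  seeded; the CI respects autocorrelation, no effort is made to
  estimate the autocorrelation time itself.
* Cell list: cell edge ≥ cutoff, exact equality with the all-pairs scan
  is a tested invariant (integer counts, no tolerance).
* Sheet fixture: the second strand's rigid placement is found by a
  deterministic coarse-then-fine grid search maximizing the geometric
  bond count (Kabsch–Sander count as tiebreak); ties resolve to the
  first grid point, so the fixture is reproducible to the bit.
* Duplicate PDB serials are renumbered with a warning; malformed
  records fail with their line number; empty selections warn rather
  than error (an empty report selection is a user mistake worth
  surfacing, but not necessarily fatal).
* Histogram bins are anchored at a multiple of the bin width at or
  below the minimum, densities normalized so Σ density·width = 1.

# Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
systems sized for a laptop-class machine: 60–290 residue chains,
60–2000 frames, up to three replicates, 128 lipids, 500 waters. These
sizes were chosen so each statistical recovery test has comfortable
margin (e.g. RMSF recovery uses 3 × 2000 frames, where the AR(1)
effective sample size still leaves per-residue errors well under the
5 % tolerance), while the full suite completes in minutes. The
end-to-end contrast (simulate → analyze → compare in both modes) uses
the default 300-frame, 3-replicate bundles.

# Known limitations

* Orthorhombic boxes only; no triclinic minimum image.
* Three-state DSSP without β-bulge/chirality bookkeeping; π/3-10
  helices fold into coil by design.
* The selection grammar covers chain/resid/name/element/role and
  boolean algebra, not distance-based or within-style selections.
* Binary trajectory formats (DCD/XTC) are out of scope; convert to
  multi-model PDB or the xyz-table dialect first.
* `sd_of_mean` with n = 2 replicates is a legal but weak uncertainty;
  the pipeline requires only n ≥ 1 and reports NA where undefined.
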