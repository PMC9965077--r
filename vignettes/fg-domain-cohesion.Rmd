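---
title: "Comparing conformational ensembles of FG-repeat domains"
author: "fgcohesion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing conformational ensembles of FG-repeat domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgcohesion)
```

## The scientific question

Nucleoporin FG domains are intrinsically disordered regions rich in
phenylalanine–glycine (FG) and Gly-Leu-Phe-Gly (GLFG) motifs. The
phenylalanines of these motifs act as intramolecular cohesion elements:
transient F–F contacts compact the disordered chain into globule-like
ensembles, and that compaction underlies the permeability barrier the
domains form in the nuclear pore. A point substitution near an FG motif —
for example a glycine replaced by a charged aspartate — can weaken the
local cohesion, and the interesting, experimentally testable consequence
is *ensemble-level*: the mutant domain should be less compact (larger
hydrodynamic radius), its F–F pairs should sit farther apart, and the
substituted residue may bury itself among the motifs it perturbs.

Because a disordered domain has no single structure, these are statements
about conformational ensembles, typically sampled by replica molecular
dynamics. `fgcohesion` packages the complete downstream comparison — replica
stability, representative selection, compaction, cohesion, exposure — plus
a coarse-grained generator so the whole analysis can be exercised and
validated at desk scale.

## The ensemble generator

The generator is a bead-per-residue Metropolis Monte Carlo model:

* one bead per residue, consecutive beads joined by rigid virtual bonds of
  3.8 Å (the canonical CA–CA distance);
* hard-core excluded volume of radius 1.9 Å per bead (hard-sphere contact
  at exactly one bond length), enforced exactly — a move that creates an
  overlap is rejected;
* a square-well attraction of depth `cohesion_epsilon` (in units of kT)
  and range `cohesion_cutoff` (9 Å) between the phenylalanine beads of
  FG-family motifs — the model's representation of F–F cohesion;
* pivot, crankshaft and end-bead rotation moves, all of which preserve
  bond lengths exactly;
* every replica starts from the fully extended chain, as replica MD of
  disordered domains conventionally does.

A point variant is modelled as a *local weakening* of cohesion: every F–F
pair with at least one site within ±10 residues of the variant position
has its well depth multiplied by `variant_penalty`. An optional square
shoulder (`variant_repulsion`) lets the variant bead itself repel F beads,
mimicking the steric/electrostatic disruption of a charged side chain;
the default model is weakening only, because that is the minimal
mechanism that produces the ensemble-level phenotype.

Defaults were fixed once, from pilot runs, as the package's study
conditions: `cohesion_epsilon = 3` kT produces a clear cohesion-driven
collapse of the wild-type chain (a per-contact strength of order an
aromatic interaction free energy), and `variant_penalty = 0.3` produces a
distinct but still partially collapsed variant ensemble. At
`cohesion_epsilon = 0` the model reduces to a self-avoiding chain, and its
end-to-end scaling reproduces the Flory exponent ν ≈ 0.588 within
tolerance — a useful check that the move set equilibrates the coil state.

Time in this model is nominal: one sweep (N attempted moves) is labelled
0.005 ns, so the default 25 000 sweeps span a nominal 125 ns and the
conventional analysis stride of 0.01 ns is an integer multiple of the
frame interval. The labelling exists so that window logic ("the final
25 ns, sampled every 0.01 ns") carries over unchanged to externally
produced trajectories; it implies nothing about physical kinetics.

Replica sub-seeds are derived from the master seed by a counter-based
rule (`master + 2654435769 · replica_id mod 2^32`, scrambled through a
splitmix64 generator inside the sampler), so replica k is bit-reproducible
in isolation and adding replicas never changes existing ones.

### What the generator does and does not emulate

It emulates the features the downstream statistics consume: independent
replicas from an extended start, tunable F–F cohesion that drives
compaction, and stochastic replica-to-replica variability in convergence.
It does not emulate a force field, solvent, secondary structure or
realistic kinetics. Passing tests on synthetic ensembles therefore
validate the *analysis machinery* and the *direction* of cohesion-driven
effects, not any quantitative property of real NUP98 ensembles; headline
numbers from all-atom studies (hydrodynamic radii of ~20 Å, specific
stable-replica counts) are not desk-scale reproducible and are not claimed.

## Replica stability

Convergence is diagnosed per replica by the RMSD of each frame against the
replica's initial conformation after optimal (Kabsch) superposition. A
replica is called stable when, over the assessment window, the series has
sd ≤ `sd_threshold` and an absolute least-squares drift slope ≤
`slope_threshold` — an operational plateau criterion; published work often
judges the same plateaus by eye, so both thresholds are exposed and a
manual override list is provided. The function defaults (assessment from
40 ns, sd ≤ 2 Å, slope ≤ 0.02 Å/ns) suit all-atom-like series whose
plateau fluctuations are a couple of Å. The coarse-grained model
fluctuates more — collapsed 156-bead globules show plateau sds of 1–3 Å
and partially collapsed variants ~5 Å — so desk-scale analyses in this
package (tests and the acceptance script) classify with sd ≤ 6 Å and
slope ≤ 0.2 Å/ns over windows scaled to their shorter runs. These were
fixed from pilot diagnostics of the generator's conditions, before the
comparisons they gate were run.

Representative conformations come from single-linkage clustering of the
pairwise superposed-RMSD matrix within each stable replica's analysis
window, cut at 3 Å; the representative is the medoid of the largest
cluster, with ties broken toward the earliest frame — both choices made
for determinism and auditability rather than statistical optimality. For
quadratic-cost safety the window is thinned evenly to at most 250 frames
before clustering.

## Compaction: the hull hydrodynamic radius

The hydrodynamic radius of each representative is estimated from the
convex hull of its coordinates:

1. hull volume V gives the equivalent-sphere radius `(3V/4π)^{1/3}`;
2. a Perrin-type shape correction multiplies it: the translational
   friction factor of the ellipsoid whose principal second moments match
   those of the uniform solid hull (semi-axes `a_i = sqrt(5 λ_i)`), with
   the Perrin integral evaluated numerically to 1e-10 relative tolerance
   (validated against the prolate closed form);
3. a hydration shell (default 0 in analyses here; 2.8 Å is a typical
   physical value) is added last.

This is a deliberately simple, fully documented estimator in the spirit of
hull-based hydrodynamic predictors; parity with any particular server's
parameterisation is a non-goal. The hull itself is computed by an
incremental beneath–beyond algorithm written for this package (no
installed R package provides 3-D hulls) and is cross-validated in the test
suite against closed forms and an independent implementation.

## Cohesion: F–F distance matrices and networks

For every stable replica, the mean distance between each pair of
phenylalanine sites is computed over the analysis window (in
bead-per-residue mode the bead *is* the residue's centre of mass; for
all-atom input a mass-weighted whole-residue centre is the documented
choice, side-chain-only being a config switch). Per-condition matrices are
the mean of replica-mean matrices — each stable replica weighted equally —
rather than a pool of all frames; with equal window lengths the two
aggregations differ only in second order, and frame pooling can be
obtained by passing pooled matrices explicitly.

The comparison reports, per F–F pair, the percent variation
`|d_var − d_wt| / d_wt × 100` (relative to wild type, matching the
direction of the scientific question), flags pairs above a 25% threshold,
and summarises the flagged fraction and the grand-mean off-diagonal
distance per condition. GLFG phenylalanines are included in the site set
by default (`include_glfg = FALSE` restricts to FG dipeptides): the pair
set of interest is "phenylalanines of FG-family motifs", and excluding
GLFG would silently shrink it. Networks are complete weighted graphs over
the F sites; the drawing convention maps *thicker* edges to *longer*
distances, so the pairs that moved apart dominate the picture —
counter-intuitive but deliberate, as the expanded pairs are the signal.

## Exposure of the variant residue

For all-atom input the package implements Shrake–Rupley SASA with a
deterministic golden-spiral test-point lattice (960 points per atom by
default; the lattice makes results reproducible to the lattice's angular
resolution, and rotating a structure changes per-atom values only within
that resolution). Relative SASA against the Gly-X-Gly extended tripeptide
reference classifies the residue exposed at ≥ 0.25 — the common
convention, as no threshold is standard in the source analyses. Hydrogen
bonds use the standard geometric criterion (donor–acceptor ≤ 3.5 Å;
D–H···A ≥ 120° when explicit hydrogens are present; heavy-atom distance
only otherwise) with a documented donor/acceptor typing table.

Coarse bead ensembles have no atomic surface, so the pipeline substitutes
a clearly labelled neighbour-count proxy: the variant bead is buried in a
frame when ≥ 12 non-bonded beads lie within 10 Å. The proxy's output
carries `method = "ca_neighbor_proxy"` so downstream consumers cannot
mistake it for a true SASA.

## The pipeline and its determinism

`run_comparison()` chains sequence → simulation (or externally supplied
ensembles) → stability → clustering → compaction → cohesion → exposure and
returns a single serialisable report. With an output directory the
ensembles are persisted as multi-model CA-only PDB plus JSON sidecars, and
*every* downstream stage consumes the persisted artifact rather than the
in-memory object; a rerun over the same directory therefore skips the
simulation and regenerates the report bit-identically. PDB fixed-width
output quantises coordinates to 1e-3 Å, which is why the persisted
artifact, not the in-memory array, is the canonical input.

Degenerate inputs are handled explicitly: fewer than 4 non-coplanar
points is a geometry error for the hull; a window longer than the
trajectory span is a window error; a stride that does not divide the
frame spacing (tolerance 1e-9 ns) is a stride error; a condition with
zero stable replicas aborts the comparison with a stage-tagged message.
The trailing window is half-open, `(t_end − window, t_end]`, anchored at
the final frame; when the window covers the whole span the first frame is
included, which keeps full-span sampling an identity and repeated
sampling idempotent.

## Desk-scale problem sizes

The analyses shipped in the test suite and the acceptance script use
chains of 30–156 beads, 3–10 replicas per condition and runs of
3000–8000 sweeps (nominal 15–40 ns), with windows and assessment starts
scaled accordingly; these sizes were chosen so that the full suite
exercises every stage in minutes while the ensembles still show clear,
seed-robust cohesion effects (the paired-seed direction check passes
10/10 in pilots). The defaults embedded in `sim_config()` describe the
full nominal protocol (20 replicas × 125 ns) for users who want to mirror
a complete replica study.

## Known limitations

* The generator's square-well/hard-sphere model has no notion of
  temperature beyond kT units, no chain stiffness, and no sequence
  effects outside the F sites; linker composition affects nothing but
  labels.
* The hull radius is a geometric estimator; it systematically
  underestimates hydrodynamic radii of very open coils, where the hull
  encloses substantial empty volume but friction is dominated by chain
  segments.
* The burial proxy on bead chains is a topological statement, not a
  surface-area one; its threshold (12 neighbours within 10 Å) was chosen
  to separate core from surface beads in collapsed globules of the sizes
  used here.
* Replica-specific hydrogen-bond partner lists from all-atom studies
  cannot be reproduced without the original trajectories; the package
  reports what it detects in the structures it is given.
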