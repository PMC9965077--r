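# fgcohesion

Conformational-ensemble comparison for intrinsically disordered FG-repeat
nucleoporin domains: does a point variant make the domain less
intramolecularly cohesive and more elongated than wild type?

FG domains (such as the 156-residue N-terminal domain of NUP98) are
disordered chains studded with FG and GLFG motifs whose phenylalanines form
transient F–F contacts that compact the ensemble. `fgcohesion` implements
the complete ensemble-level comparison between a wild-type domain and a
point variant:

* **Replica stability** — per-replica RMSD-versus-initial series after
  Kabsch superposition; a replica is *stable* when the series plateaus
  (sd ≤ s, |least-squares slope| ≤ m over the assessment window).
* **Representative conformations** — single-linkage clustering of the
  pairwise-RMSD matrix within each stable replica's trailing analysis
  window (default: final 25 ns sampled every 0.01 ns); the representative
  is the medoid of the largest cluster.
* **Compaction** — hull-based hydrodynamic radius per representative:
  R_h = f_P · (3V/4π)^(1/3) + shell, where V is the convex-hull volume and
  f_P the Perrin translational friction factor of the ellipsoid matching
  the hull's principal second moments.
* **Cohesion** — mean F–F distance matrices over stable replicas, percent
  variation per pair |d_var − d_wt|/d_wt · 100, pairs flagged above 25%,
  and complete weighted network graphs (GraphML/TSV export).
* **Exposure** — Shrake–Rupley SASA with exposed/buried classification
  against Gly-X-Gly reference values and geometric hydrogen-bond
  detection for all-atom input; a labelled neighbour-count burial proxy
  for bead-per-residue ensembles.
* **A coarse-grained ensemble generator** — bead-per-residue Metropolis
  Monte Carlo (pivot/crankshaft/end moves, hard-core excluded volume,
  square-well F–F attraction, variant modelled as local cohesion
  weakening), standing in for replica MD so the whole pipeline can be
  exercised and validated at desk scale. Ensembles read/write as
  multi-model CA-only PDB with JSON sidecars, so externally produced
  trajectories can be analysed through the same pipeline.

## Worked example

```r
library(fgcohesion)

wt  <- random_fg_sequence(60, seed = 42, id = "demo_fg")
v   <- variant_spec("G", 22, "D")        # glycine -> aspartate at 22
cfg <- sim_config(n_replicas = 4, n_sweeps = 4000,
                  record_interval_ns = 0.05, seed = 1)

rep <- run_comparison(wt, v, sim = cfg,
                      window = analysis_window(5, 0.05),
                      assessment_start_ns = 10,
                      sd_threshold = 6, slope_threshold = 0.3)
print(rep)
#> <comparison_report> demo_fg p.G22D
#>   stable replicas: WT 2/4, variant 3/4
#>   mean Rh: WT 13.51 A, variant 16.09 A
#>   grand-mean F-F: WT 10.60 A, variant 25.06 A; 100.0% of pairs > 25% variation
#>   variant residue exposed in 94% of frames (ca_neighbor_proxy)
```

Reading the output: of the 4 replicas per condition, those whose RMSD
series plateaued are kept; the variant ensemble is less compact (mean
hydrodynamic radius 16.1 Å vs 13.5 Å) and less cohesive (grand-mean F–F
distance 25.1 Å vs 10.6 Å, with every F–F pair changed by more than 25%
at this small scale — cohesion weakening near residue 22 propagates
through the whole contact network of a 60-residue chain); the substituted
residue is exposed in most frames by the bead-chain burial proxy. Passing
`out_dir =` persists ensembles (multi-model PDB), RMSD tables, cohesion
CSVs, networks and the JSON report, and makes reruns bit-reproducible;
`report_figures()` emits the radius box plot, flagged-pair bar chart and
network drawings as SVG.

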