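# lamellr

Post-simulation analysis of planar lamellar lipid membranes, built around
the question of how lipid-acid stereochemistry steers two-tailed
glycerolipids (monomycoloyl glycerol, MMG, and its analogs) between
noninterdigitated gel (L<sub>β</sub>) and interdigitated subgel
(L<sub>c′</sub>) phases. It is aimed at molecular-simulation practitioners
who have gel-phase membrane trajectories and want the full property
battery — geometry, chain order, conformational motifs, interface
dynamics — with every estimator testable against planted ground truth.

## What it computes

* **Membrane geometry** — area per lipid from box dimensions
  (APL<sub>xy</sub> = L<sub>x</sub>·L<sub>y</sub>/n<sub>leaflet</sub>) and
  per lipid from periodic 2D Voronoi tessellation of the water-facing
  leaflets (APL<sub>vor</sub>); electron/mass/number density profiles along
  the normal; block-averaged peak-to-peak membrane and per-bilayer
  thickness.
* **Chain order** — deuterium order parameters
  S<sub>CD</sub> = (3⟨cos²θ⟩ − 1)/2 with ideal-geometry hydrogen
  reconstruction; tail tilt, splay and head–tail angle distributions; P1
  rotational autocorrelation C(t) = ⟨û(τ)·û(τ+t)⟩; in-plane tail–tail RDFs.
* **Conformational motifs** — per-lipid radial–angular three-particle
  correlation fingerprints g₃(r, cos θ) on a 201 × 101 grid (15 Å cutoff),
  pairwise structural-similarity (SSIM) matrix, 2D t-SNE embedding
  (perplexity 100, early exaggeration 4), HDBSCAN clustering (minimum
  cluster size 50) with PCA validation, and characterisation of clusters
  into the four-motif taxonomy (closed/splayed × ordered/disordered) via
  trans/gauche and inter-tail-band masses.
* **Interface** — geometric hydrogen-bond detection (3.5 Å, ≤ 30°),
  per-molecule and per-oxygen-group statistics, intermittent bond
  autocorrelation with plateau correction, and double-exponential fits
  a₁e^(−t/τ₁) + a₂e^(−t/τ₂) + b of glycerol-vector rotational decays.
* **Synthetic membranes** — a generator for single/double/interdigitated
  lamellar systems with controlled motif composition, gauche statistics,
  tilt, two-timescale headgroup rotation and planted hydrogen bonds, so
  every stage above can be validated against known truth.

## Worked example

```r
library(lamellr)

spec <- synthetic_system_spec(n_per_leaflet = 100, n_frames = 8,
                              apl_target = 39.8, seed = 5)
sm   <- generate_membrane_trajectory(spec)   # 200 lipids + ground truth
leaf <- assign_leaflets(sm$traj, n_leaflets = 2)

apl_xy(sm$traj, n_per_leaflet = 100)$mean
#> [1] 39.8
h  <- compute_g3_all(sm$traj)                # 201 x 101 x 200 fingerprints
S  <- build_similarity_matrix(h)
cl <- embed_and_cluster(S, perplexity = 30, min_cluster_size = 20, seed = 1)
cl
#> <cluster_result> 200 samples, 4 clusters (+0 noise)
mclust::adjustedRandIndex(cl$labels, sm$motif)
#> [1] 0.9865989
ch <- characterize_clusters(cl, h)
ch$scores
#>   cluster tg_ratio    packing motif
#> 1       0 1.557414 0.07093037     2
#> 2       1 3.663577 0.02526603     3
#> 3       2 2.862092 0.07921349     0
#> 4       3 3.574905 0.09874886     1
```

The four planted conformational families come back as four clusters in
near-perfect agreement with the ground truth (adjusted Rand index 0.987);
the score table shows the two characterisation axes — trans/gauche mass
ratio (chain order) and inter-tail band mass (packing) — and the motif id
each cluster maps to: the tightest, most ordered family (motif 1) has the
highest packing mass, the disordered splayed family (motif 2) the lowest
order ratio.

For file-based work, `load_trajectory()` reads GRO coordinate and
multi-frame GRO trajectory streams, `run_pipeline()` +
`analysis_config()`/`read_analysis_config()` drive the whole battery from a
YAML config, and `inst/cli/lamellr-pipeline.R` wraps that as a shell
command with `fixtures from / geometry / order / motifs / interface / all`
subcommands.

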