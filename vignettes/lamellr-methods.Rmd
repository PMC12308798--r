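---
title: "Methods: lamellar membrane analysis and conformational motif discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lamellar membrane analysis and conformational motif discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(lamellr)
```

# Scope and model

`lamellr` analyses molecular-dynamics trajectories of planar lamellar
membranes built from two-tailed glycerolipids — the motivating system is
monomycoloyl glycerol (MMG), whose lipid-acid stereoisomers assemble into
noninterdigitated gel (L~β~) or interdigitated subgel (L~c′~) phases. All
analyses assume a planar membrane whose normal is the z axis, the standard
setting for gel-phase lamellar stacks. Internally everything is Angstrom and
picosecond; GRO input (nm) is converted on read.

Atom identity comes solely from a name map (`lipid_topology()`), following
the conventional MMG numbering: glycerol carbons C1–C3 with the primary
hydroxyl O1, carbonyl C4, branching carbon C5, tails C7–C20 and C21–C35,
oxygens O1–O5 with hydroxyl hydrogens on O1/O3/O5. No force-field topology
is parsed.

# Membrane geometry

**Area per lipid.** `apl_xy()` is box arithmetic, `Lx·Ly / n_leaflet`.
`apl_voronoi()` tessellates the projected headgroup centres of mass of the
water-facing leaflets. Periodicity is handled by explicit 8-image
replication and half-plane clipping against perpendicular bisectors, which
is exact up to floating point; per-leaflet cell areas must therefore sum to
the box area (asserted at 1e-6 relative in the tests, alongside a
raster-oracle comparison at 0.05 Å resolution). The distribution mode is
read off a 0.5 Å² histogram; the bin width is a package choice, made
explicit because reported "maxima" of per-lipid area distributions depend
on it.

**Density and thickness.** `density_profile()` histograms a selection along
z with electron, mass or number weighting. Electron counts are atomic
number minus an optional partial charge; the default is charge-free since
charge conventions differ between simulation toolchains. Thickness is
peak-to-peak: per frame block (five equal blocks by default), local maxima
are located on a lightly boxcar-smoothed profile with quadratic sub-bin
refinement, and candidate maxima closer than 4 Å to a taller one are
treated as sampling shoulders of the same layer — distinct leaflet peaks in
lamellar stacks are tens of Ångström apart, so the merge radius is safely
below any real peak spacing. `overall` takes the outermost peak separation
(whole stack), `per_bilayer` the mean outer-peak to central-peak distance
used for multilamellar configurations. Block means and standard deviations
are reported; with identical blocks the sd is exactly zero.

# Chain order and orientation

**Deuterium order parameters.** Hydrogens are reconstructed from carbon
positions with ideal tetrahedral geometry: the two C–H directions lie in
the plane perpendicular to the C(i−1)–C(i+1) axis, symmetric about the
bisector. Terminal methyls are excluded. `S_CD = (3⟨cos²θ⟩ − 1)/2` against
the z axis is averaged within five frame blocks; the analytic limits (−0.5
for an all-trans chain along z; 0 for isotropic orientations; +0.25 for a
chain perpendicular to z averaged over spin) are exact test anchors.
Whether published error bars are sd or sem across blocks is often left
unstated; this package reports the block sd and labels it as such.

**Angles.** Tail tilt uses the terminal-to-first-carbon vectors (C20→C7,
C35→C21) against each leaflet's *outward* normal, folded to [0°, 90°].
Leaflet-aware normals are a documented choice: the alternative (global +z)
would fold lower-leaflet angles to the same range but flips asymmetric
distributions. Splay angles are vertex angles at C5 (C9/C22 for splay 1,
C20/C35 for splay 2); head–tail angles pair the C1→C3 glycerol vector with
C5→terminal tail vectors, unfolded over [0°, 180°].

**Dynamics and packing.** `vector_acf()` is the P1 orientational
autocorrelation ⟨û(τ)·û(τ+t)⟩ using every frame as a time origin with lags
to half the window — the standard bias/variance compromise. It matches a
brute-force double loop to 1e-10. `rdf_2d()` computes in-plane pair
distributions of per-lipid centres of mass per leaflet with the
minimum-image convention, normalised by the ideal-gas annulus density.

# Conformational motif stage

Each lipid is fingerprinted by the radial–angular three-particle
correlation g₃: for every selection atom B (lipid-acid carbons C5–C35,
excluding the carbonyl C4), A is its nearest selection neighbour (ties to
the lowest index, for determinism) and every other selection atom C within
15 Å deposits weight at (r~BC~, cos θ~ABC~) on a 201 × 101 grid. C ranges
over all selection atoms except B itself — including A, which contributes
the singular first peak at cos θ = 1. The histogram is frame-averaged and
normalised to unit mass so fingerprints are comparable across lipids; the
axis is uniform in cos θ. All restrictions are intramolecular: the
fingerprint describes one lipid in isolation.

Fingerprints are compared with the structural similarity index (SSIM):
7 × 7 uniform windows, valid-region mean, stabilisation constants
(0.01 L)² and (0.03 L)² with L the global data range of the histogram set,
and sample-covariance normalisation — the standard reference formulation,
cross-checked against scikit-image in the tests. The pairwise matrix is
computed once per pair with integral-image window sums.

Similarities convert to dissimilarities as 1 − s (the simplest monotone
map), are embedded to 2D by exact t-SNE (perplexity 100, early
exaggeration 4, random initialisation under the caller's seed) and
clustered with HDBSCAN (minimum cluster size 50, excess-of-mass selection).
Because no t-SNE or HDBSCAN implementation exists in the supported
dependency set, both algorithms are implemented in the package in their
reference forms; HDBSCAN allows the root cluster to be selected so that a
homogeneous input yields one cluster rather than all noise, and data sets
smaller than the minimum cluster size are all noise. t-SNE is stochastic,
so cluster membership — not layout geometry — is the contract, and an
independent PCA embedding of the same dissimilarities validates that
clusters remain separated (positive silhouette).

Clusters are characterised on two axes with integration windows fixed from
ideal rotamer geometry (1.53 Å bonds, 111° angles). The second-neighbour
shell (r ≈ 2.52 Å) is dihedral-independent, so the discriminating shell is
the third neighbour: trans ≈ 3.9 Å versus gauche ≈ 3.0 Å. The windows are
r ∈ [3.6, 4.2] (trans) and r ∈ [2.7, 3.4] (gauche), any angle; the
trans/gauche mass ratio scores chain order. Intramolecular tail packing is
the mass at r ∈ (4, 6) Å away from the chain axis (|cos θ| < 0.5). Clusters
above the across-cluster median packing are "closed", above the median
order ratio "ordered", giving the four-quadrant taxonomy: 0 closed/less
ordered, 1 tightly closed/ordered, 2 splayed/disordered, 3 splayed/ordered.
Median thresholds are a deliberate choice: they are scale-free and exact
for the canonical four-cluster case.

# Interface analysis

Hydrogen bonds use the geometric criterion: donor–acceptor distance
≤ 3.5 Å and acceptor–donor–hydrogen angle ≤ 30°, with minimum-image
distances. Hydroxyl groups donate and accept; carbonyl/ester oxygens (O2,
O4) only accept — that is the chemistry of the headgroup, and it fixes the
per-group water-bond bookkeeping. Counts are reported per molecule.

The hydrogen-bond autocorrelation uses the *intermittent* indicator (a
bond may break and reform), matching the ⟨h(τ)h(τ+t)⟩ correlation form.
"Tail-corrected" is interpreted as subtraction of the long-lag plateau
(mean over the last fifth of lags) with renormalisation to C(0) = 1; the
uncorrected series and the plateau value remain available because the term
has no unique definition.

Rotational decays are fitted with `a₁e^{−t/τ₁} + a₂e^{−t/τ₂} + b` by
Levenberg–Marquardt least squares with multi-start initialisation over a
grid of 8 log-spaced time constants — two-exponential fits are notoriously
initialisation-sensitive. The offset b is fitted freely and reported.
Results are relabelled so τ₁ ≤ τ₂; fits with τ₂/τ₁ < 1.2 or a vanishing
amplitude are flagged degenerate (effectively single-exponential).

# Synthetic membrane generator

The generator provides planted ground truth, not physics: chains are pure
rotamer models (fixed 1.53 Å bonds, 111° angles, trans/gauche dihedrals at
a controlled gauche probability) with no excluded-volume relaxation, no
energetics and no self-assembly. Lipids sit on a jittered square lattice at
the target area per lipid; the interdigitated arrangement interleaves the
two leaflets of each unit on offset lattices inside one shared tail slab,
which reproduces the qualitative signatures of interdigitation (thinner
stack, larger per-leaflet area) without simulating it.

Each lipid is built so constructed quantities are exactly recoverable: the
initial tail segments leave the branching carbon such that the measured
splay-1 angle equals the motif's target; the distal segments run along a
common tilted axis, with tail 2 steered to settle near the motif's tail
separation. The four default motif parameterisations (gauche probability
0.12/0.02/0.40/0.05, splay 95/95/120/120°, separation 5.2/4.3/8.5/8.5 Å)
were fixed once to make the families geometrically distinct in the way the
field's taxonomy describes them; they are study conditions, not tuning
knobs.

Headgroup dynamics are simulated directly on the glycerol C1–C3 vector:
each lipid joins a fast, slow or frozen pool (fractions a₁, a₂, 1−a₁−a₂,
drawn with deterministic counts so amplitudes are exact) and mobile vectors
perform rotational diffusion with per-step angle N(0, √(2Δt/τ)), whose P1
autocorrelation is e^{−t/τ}. The population average is therefore exactly
the two-exponential-plus-offset target. Default time scales (2.1/57.3 ns,
amplitudes 0.23/0.12) are the single-bilayer reference conditions. A
configurable fraction of outer-leaflet neighbour pairs is planted in
O–H···O geometry (2.9 Å, aligned) for hydrogen-bond bookkeeping tests, and
optional three-site waters populate the slabs beyond the outer leaflets.

What the generator does **not** emulate: thermal positional disorder of the
lattice beyond jitter, membrane undulations and ripples, chain
excluded-volume correlations, water structure, or coupling between headgroup
dynamics and tail conformation. Passing tests therefore demonstrate that the
estimators recover planted statistical structure, not that real membranes
behave like the generator.

# Problem sizes and numerical choices

Tests and the acceptance script run at sizes chosen so each stage still has
statistical power: the motif-recovery fixture uses 1000 lipids (250 per
family, 12 frames of fingerprint averaging) at the full hyperparameter set
(15 Å cutoff, 201 × 101 grid, perplexity 100, early exaggeration 4, minimum
cluster size 50); the glycerol round trip uses 1000 lipids × 500 frames at
400 ps spacing, which covers four slow periods of the 50 ns mode — the
level at which both time constants fit back within 15 %. Smaller unit tests
use the smallest systems whose expected values are exact or have analytic
error bounds (binomial, Poisson, CLT).

Degenerate inputs are errors, not guesses: fewer marker z-bands than
leaflets, collinear Voronoi sites, profiles without the required number of
peaks, empty selections, windows selecting no frames, and decay fits where
no start converges. Nearest-neighbour ties in the fingerprint resolve to
the lowest atom index; t-SNE is the only stage whose output geometry is
seed-dependent, and every caller seeds it explicitly.

# Known limitations

Leaflet assignment clusters marker-atom z coordinates and assumes planar,
non-wrapped membranes; strongly undulating or z-wrapped systems need
re-centring first. The GRO reader handles single- and multi-frame text
streams only — compressed binary trajectory formats should be converted
on export. The trans/gauche windows assume ideal alkyl geometry and would
need re-derivation for force fields with markedly different equilibrium
bond parameters. HDBSCAN and t-SNE follow the reference algorithms but are
plain R implementations: adequate into the low tens of thousands of
samples, not beyond.
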