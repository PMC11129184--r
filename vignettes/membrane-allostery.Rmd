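---
title: "Methods: perturbation response scanning and lipid site mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perturbation response scanning and lipid site mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memallo)
```

## Scope and model

`memallo` analyzes molecular dynamics trajectories of membrane proteins to
answer two linked questions: *where do lipids such as cholesterol bind, and
for how long?* and *which residues, when pushed, move the structure along a
functional conformational change?* The motivating systems are pentameric
ligand-gated ion channels, whose transmembrane helices (M1–M4) form
lipid-exposed grooves where sterols can occupy state-dependent sites, but
nothing in the code is specific to that family.

The package deliberately stops at analysis: force-field setup, equilibration
and the simulations themselves are out of scope, as are coarse-grained →
atomistic back-mapping and curved-pore annotation.

## Perturbation response scanning

### Linear response

For a structure fluctuating about its mean, linear response theory gives the
expected displacement of all nodes under a small external force applied at
one node:

$$\Delta R = \frac{1}{k_B T}\, C\, F,$$

where $C$ is the $3N \times 3N$ positional covariance of the $N$ Cα nodes
and $F$ the $3N$ embedding of the point force. The package drops the
$1/k_BT$ prefactor: the hotspot score below is invariant to any positive
scaling of $C$, $F$ or the target, so temperature only matters for absolute
displacement magnitudes, which this analysis never uses.

### Overlap score

A node's response is scored against a target conformational change
$\Delta S$ — typically the Cα difference vector between the simulated state
and an experimental endpoint structure, computed by `target_displacement()`
after Kabsch superposition — with the absolute cosine

$$O_i = \frac{|\Delta R \cdot \Delta S|}{|\Delta R|\,|\Delta S|} \in [0, 1].$$

The absolute value is a deliberate convention: a force and its negation
probe the same direction of motion, so sign is meaningless. `prs_scan()`
samples, per node, `n_directions` (default 1000) uniform unit forces per
repeat for `n_repeats` (default 5) repeats and keeps the best overlap and
its direction; `max` aggregation across repeats is the default, with `mean`
available, since best-over-forces is what a per-residue "best overlap"
ranking consumes. Nodes with $O_i \ge 0.6$ (the conventional significance
threshold for this class of analysis, kept configurable) are reported by
`rank_hotspots()`, ties broken by ascending residue number so output is
deterministic.

### Closed-form oracle

For one node the overlap depends on the force direction only through the
node's three covariance columns $C_b$: maximizing
$(f^\top a)^2 / (f^\top B f)$ with $a = C_b^\top \Delta S$ and
$B = C_b^\top C_b$ is a 3-dimensional generalized Rayleigh problem with
solution $f^* \propto B^{-1} a$ (pseudo-inverse when $B$ is singular).
`analytic_best_force()` implements this and serves as the independent
oracle the random scan is validated against: the scan can never exceed it,
and approaches it as the number of sampled directions grows (median gap
below 0.01 at 10^4 directions in the test suite).

### Covariance construction

`compute_covariance()` superposes every frame onto an iteratively refined
mean structure (align to frame 1, compute the mean, re-align to the mean,
recompute — two passes by default, which is cheap and stable for
equilibrated trajectories; the pass count is configurable) and accumulates
$C = \langle \delta x\, \delta x^\top \rangle$ with the frame-count
denominator $n$. The population/sample denominator choice is immaterial to
the overlap (a global scale), and is stated here only for reproducibility.
`converged_start()` supports the convention of beginning covariance
accumulation at an equilibrated frame: it returns the first frame of the
longest trajectory suffix whose Cα RMSD to the final frame stays below a
bound (default 1 Å).

Force directions are sampled by normalizing standard 3-dimensional normal
draws, which is exactly uniform on the sphere.

## Lipid occupancy grids

`compute_occupancy()` bins selected particles into a voxel grid covering
the (constant, orthorhombic) box: half-open bins
$[\mathrm{origin} + k s, \mathrm{origin} + (k+1)s)$ with spacing $s$
(default 1 Å), particles wrapped into the primary image, origin at the box
minimum corner. The voxel value is the fraction of frames in which at least
one selected particle falls in the voxel — occupancy, not mass density; no
Gaussian smearing is applied.

The reporting filter (`threshold_grid()`) zeroes voxels below a fraction
threshold, default 0.5 ("present in at least half of the frames"), with the
threshold itself kept (inclusive comparison). Whether such a filter should
count voxel occupancy alone or occupancy *while in contact with the
protein* is genuinely ambiguous in common practice; the package brackets
both readings by making a protein-proximity mask (default cutoff 6 Å from
the mean structure, `proximity_mask()`) an optional second filter, and the
pipeline writes both the raw and the filtered grid. Grids are exported as
OpenDX scalar fields (`write_dx()`), the format VMD Volmap emits, and the
writer is validated by round-trip and by a third-party reader.

## Contact events, residence times and binding sites

### Dual-cutoff events

A contact event for a (lipid, residue) pair starts at the first frame where
the minimum interparticle distance drops below `r_on` (default 4.75 Å) and
ends at the first subsequent frame where it exceeds `r_off` (default
7.0 Å). The hysteresis suppresses flicker when a distance oscillates around
a single cutoff. The defaults mirror common coarse-grained practice and are
fully configurable — they are the kind of parameter a study rarely prints,
so nothing downstream hard-codes them. Event times are half-open
$[t_\mathrm{start}, t_\mathrm{end})$ with the end one frame spacing past
the last contacted frame, so a $k$-frame contact has duration $k\,dt$.
Optional gap stitching (`stitch_events()`) merges events of the same pair
separated by at most a configurable number of frames; it is off by default
because hysteresis already absorbs boundary noise and the un-stitched event
stream is what the hand-traceable semantics above describe.

### Residence time

`fit_residence_time()` builds the survival curve $S(\ell)$ = fraction of
events with duration at least $\ell$ and fits $\log S$ against $\ell$ by
least squares, restricted to the well-sampled part of the curve
($S \ge 0.05$) so a handful of extreme events cannot dominate the slope;
the residence time is $1/k_\mathrm{off} = -1/\mathrm{slope}$. With fewer
than 5 events (or a degenerate fit) it falls back to the mean duration. A
single-exponential fit, not a bi-exponential bootstrap, is intentional:
the synthetic generator plants single-exponential kinetics, and validation
against that truth is the package's correctness story.

### Site clustering

`cluster_sites()` builds a residue graph with an edge between residues
$i, j$ when — among frames where either residue contacts some lipid — the
*same* lipid contacts both in at least `co_occurrence_min` (default 0.5) of
those frames. Connected components with at least two residues become sites.
Thresholded connected components were chosen over community detection:
deterministic, dependency-light, and adequate for planted-truth validation;
this is a simplification relative to stochastic community-based tools, and
is stated as such. A site-level event is a maximal run of frames in which
one lipid touches at least two site residues simultaneously; the site
residence time is fitted from those durations, and the representative pose
is the midpoint frame of the longest site event (earliest on ties). The
long-lived flag (default 3000 ns) is purely a reporting toggle and never
changes the site list.

## Atomistic interaction analyses

Hydrogen bonds require donor-heavy-atom-to-acceptor distance ≤ 3.5 Å *and*
D–H–A angle ≥ 130°. The distance cutoff is the conventional fingerprint
default; the angle is the companion default of fingerprint tools and is
configurable and logged, since published work often prints only the
distance. Donors are restricted to N/O with an attached hydrogen (resolved
structurally: an H of the same residue within 1.25 Å, robust to naming
schemes); acceptors to N/O/F. Hydrophobic contacts pair carbon/sulfur atoms
within 4.5 Å at residue level. Aromatic-stacking and cation–π classes are
omitted as chemically irrelevant to sterols. All detectors compare
inclusively (≤ distance, ≥ angle) and use the minimum image when a box is
present; `hbond_fixture()` constructs 4-atom geometries with exact requested
distance/angle to probe the boundaries constructively.

`pair_distance_series()` reports per-frame minimum-image distances with
per-copy and pooled mean ± population SD — the multi-copy path mirrors the
common situation of one ligand per subunit of a homopentamer.
`rmsd_series()` is per-frame Kabsch RMSD. `pore_profile()` is a
straight-axis radius profile: per 1 Å slab, the minimum over atoms of
(distance to the principal axis − van der Waals radius), with empty slabs
flagged `NA` rather than zero-filled; it deliberately replaces
curved-pathway channel annotation with something transparent and testable.
The bundled vdW radii are the standard Bondi values.

## The synthetic-data module

The generators produce data with *exactly* the statistical structure the
analyses assume, so every stage can be validated against planted truth:

* `generate_gaussian_ensemble()` draws frames from a multivariate normal
  with a known covariance — isotropic, spiked ($\sigma^2 I + \lambda
  uu^\top$, the hotspot-recovery test bed), or an elastic-network covariance
  (pseudo-inverse of an ANM Hessian) for correlated fluctuations.
* `generate_lipid_walk()` diffuses single-bead lipids (per-component step
  SD $= \mathrm{step}/\sqrt{3}$, so `diffusion_step` is the RMS frame
  displacement) in a reflecting box around a fixed toy protein; entering
  within `r_bind` of a site center freezes the lipid for an
  Exponential(`mean_dwell`) dwell. After release the lipid is *refractory*
  until it first exits the capture radius — without this, release would be
  followed by instant recapture every frame and the realized dwell
  distribution would not be the planted one. One seeded stream drives both
  the walk and the dwell draws, so runs replay bit-for-bit.
* `hbond_fixture()` and `mole_percents()` cover the interaction-geometry
  and composition calculators. The bundled asymmetric neuronal-membrane
  composition uses CHARMM-style lipid names; its outer-leaflet percents as
  published are internally inconsistent at the 0.1% level between table and
  prose in the source literature, so validation targets the self-consistent
  inner leaflet (plus the outer POPE entry, which both agree on), and the
  calculator reports from counts only. Rounding is half-away-from-zero to
  one decimal.

Default toy-site conditions were fixed once, on physical grounds: a
4-residue cage of circumradius 3 Å (so a captured lipid is within contact
range of several residues at once, the geometry site clustering needs),
capture radius 3 Å, frame spacing 1 ns, and a 6 Å RMS step per frame —
about $D = 6\ \text{Å}^2/\text{ns}$, the order of lipid diffusivity in
coarse-grained membranes, and fast enough that a released lipid escapes the
contact shell instead of artifactually re-extending its event.

What the generators do **not** emulate: force fields, lipid shape and
orientation, membrane leaflets, correlated lipid motion, multi-exponential
binding kinetics, or anharmonic protein dynamics. Passing the planted-truth
suite therefore shows the *estimators* are correct, not that any particular
biological conclusion transfers; on real trajectories the usual caveats of
sampling and model quality apply.

## Numerical and interface choices

* Units Å/ns everywhere; nm-based formats (GRO) convert at the boundary.
* Orthorhombic boxes only; triclinic input errors explicitly. Minimum-image
  convention for all interparticle distances when a box is present.
* DCD is the supported binary trajectory dialect (single-precision, so
  round-trips are exact to ~1e-6 relative); XTC input is rejected with a
  clear error rather than half-supported. PDB insertion codes are rejected
  because residue lookup is by (chain, residue number).
* Kabsch superposition via SVD with the determinant correction, proper
  rotations only; (near-)collinear references are rejected as ill-posed.
* Covariance eigenvalues are clamped at zero below an $10^{-8}$ relative
  tolerance when sampling; anything more negative is a spec error.
* The analysis pipeline (`run_pipeline()`) is a plain R function over a
  layered config (defaults ← YAML file ← list), serializes the resolved
  config next to its outputs, and exposes every threshold above as a named
  default in `memallo_defaults()`. The package's interface is R functions
  plus this pipeline; no shell wrapper is shipped.
* Test problem sizes (10-node ensembles at 10^4 frames, 30–50 lipids at
  2000–8000 frames) were chosen as the smallest sizes at which the
  stochastic recovery targets are statistically comfortable.

## Known limitations

* Residence-time estimates from contact events inherit contact-definition
  bias: an event extends while the lipid lingers inside `r_off`, so fitted
  times sit slightly above the planted dwell under slow diffusion.
* Site clustering assumes sites are residue-disjoint (connected
  components); overlapping sites would merge.
* The pore profile uses a straight principal axis; strongly curved or
  tilted pores need dedicated tools.
* PRS assumes harmonic fluctuations about one basin; it ranks candidate
  hotspots and does not by itself establish causality in gating.
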