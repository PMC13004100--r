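---
title: "Methods: conformational exposure analysis and summary-statistic causal genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational exposure analysis and summary-statistic causal genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models, parameter
choices and limitations.  It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

# The scientific question

A missense substitution in Domain V of β2-glycoprotein I sits inside a
phospholipid-binding loop, yet carriers show *higher* autoantibody levels
against the protein and *lower* venous-thromboembolism risk.  Two analysis
chains probe this: (i) a conformational-ensemble analysis asking how the
substitution changes the solvent exposure of the phospholipid-binding
loops (Domain V) and of the autoantibody epitope motifs (Domains I–II)
across the protein's conformational states; and (ii) a summary-statistic
causal-genetics chain (fine-mapped credible set, Wald-ratio MR,
approximate-Bayes-factor colocalization, criteria-based prioritization)
asking whether that substitution is the causal variant behind the
association.  `conformgen` implements both as reusable, tested functions,
with synthetic generators standing in for the restricted inputs.

# Ensemble analysis

## Alignment

Frames are superposed by the Kabsch construction (SVD of the 3×3
cross-covariance with the reflection correction, so the rotation is always
proper).  The ensemble is aligned in two passes: every frame is fitted to
frame 1, the mean structure of the fitted coordinates is computed, and
every frame is refitted to that mean.  A mean-structure reference avoids
privileging an arbitrary frame; two passes are sufficient because a third
fit to the pass-2 mean changes coordinates at roundoff level (the
alignment is idempotent, which the tests check).  The default alignment
mask is all atoms; PCA masks backbone (CA) beads only, the usual
ensemble-PCA choice that keeps dimensionality modest.

## Coordinate PCA and clustering

PCA is the eigendecomposition of the covariance of the flattened masked
coordinates of the *combined* ensemble (all models, all starting shapes),
so every repeat is scored in one shared component basis.  Two invariants
pin the implementation: the eigenvalue sum equals the total aligned
coordinate variance, and reconstruction from all components reproduces the
centred coordinates to 1e-8.

Conformations are clustered by average-linkage agglomeration on Euclidean
distance over the first 4 component scores, cut to exactly `n_clusters`;
ids are relabelled by first occurrence so cluster 1 is always the cluster
of the first frame.  Cluster display names ("O-Shape", "J-Shape", ...) are
supplied by the analyst through a labelling table — naming conformations
is an interpretive act, not something the algorithm should guess.

An elbow rule (`select_k_elbow`) suggests `k` from the k-means
within-cluster sum of squares, maximising the second difference of the WSS
*relative to the WSS at that k*.  The relative form matters: a
structureless cloud has WSS decaying smoothly (roughly 1/k, relative
curvature `2/(k²−1) < 1` everywhere), while genuine structure makes the
WSS collapse at the true k and the relative curvature explode.  When the
winning curvature stays below 1 the choice is flagged low-confidence.
Among near-tied curvatures the smallest k wins (parsimony).  On the
default synthetic geometry the honest elbow is k = 2 — the circular-versus-
extended split dwarfs the J/S distinction — which is why the analysis
scripts pass `n_clusters` explicitly rather than relying on the elbow.

## SASA

Shrake–Rupley with a deterministic golden-spiral lattice (no RNG, so areas
are bit-stable): per atom, the fraction of `n_points` test points on the
expanded sphere `r_vdw + r_probe` outside every neighbour's expanded
sphere, times the expanded-sphere area.  Defaults: probe 1.4 Å (water),
960 points (isolated-sphere error well under 1%; the acceptance script
recomputes it).  Neighbour search uses the exact cutoff
`r_i + r_j + 2 r_probe`.  Per-residue SASA sums all atoms present in the
file — no heavy-atom filtering — and the vignette's advice to users with
hydrogens in their structures is to strip them beforehand if they want
heavy-atom areas.  The kernel is a short piece of C++ (Rcpp) because it is
the innermost loop of the exposure table (thousands of frames × hundreds
of atoms × hundreds of points).

## Exposure and antigenicity deltas

The exposure table averages per-residue SASA within each (model, cluster)
stratum.  Motif-level exposure is the *sum* of member-residue means (the
loop treated as one unit, matching how loop-level mean SASA is reported in
the structural literature); percent change is computed on that motif sum,
`100·(target − reference)/reference`, negative meaning more buried.  Both
comparison modes are emitted: against a reference cluster within the same
model (how the conformational change exposes a motif) and against the same
cluster in a reference model (what the substitution does within one
conformation).  Dispersion is reported as the per-residue SD over frames;
no inferential test is attached, because the frame-level observations
within a trajectory are autocorrelated and any p-value computed as if they
were independent would be anticonservative.

Antigenicity uses the same stratum/delta machinery on per-residue scores.
Scores come either from an external epitope-prediction server's CSV export
(imported and validated against the topology; absent residues stay absent
rather than becoming zeros) or from the built-in surrogate: residue SASA
divided by the residue's isolated maximum accessibility, a per-residue
*constant* computed as the median over scored frames of the
exploded-geometry (inter-residue occlusion removed) residue area.  A
constant normaliser mirrors standard relative-accessibility practice and
makes the surrogate exactly rank-preserving in SASA within a run.  The
surrogate is a transparent exposure proxy, not a trained epitope model; it
exists so the full pipeline runs and is testable offline, and outputs are
tagged `surrogate_rel_sasa` so nobody mistakes its provenance.  Sampling
of frames for scoring is uniform without replacement with an explicit
seed, 100 frames per stratum by default.

# The synthetic conformer generator

Each residue is two beads: a backbone bead (CA, vdW 1.9 Å) and a side bead
(CB, vdW 2.0 Å) offset 2.5 Å.  Three state geometries: **O** — backbone
beads on a circle of radius `3.8/(2 sin(π/n))` (3.8 Å neighbour spacing);
**J** — a straight 3.8 Å-spaced line with the last ⌈n/6⌉ residues bent
90°; **S** — a line with two opposite 90° bends.  Defaults: 60 residues,
200 frames per repeat at 0.1 ns spacing, 4 repeats per (model, start
shape), isotropic Gaussian coordinate noise of 0.5 Å.

**Transition schedule.**  Circular starts interpolate O→J→S with logistic
switches; linear starts stay pinned at J (emulating runs started from the
crystal-structure conformation, which remain extended).  The WT's first
midpoint is frame 60, the VARIANT's frame 90 (the planted analogue of a
slower ring-opening), the second transition follows 70 frames later, and
each repeat jitters its midpoints by a Gaussian of SD 5 frames so the
ensemble-level departure from the circular state looks gradual.  The
logistic slope default (15/frame) makes the switch complete within one
coordinate-save interval, and midpoints snap to half-integer frame indices
so the switch is half-complete *between* saved frames: every saved frame
sits at a state geometry plus noise.  This is the metastable-hop picture —
transit times short against dwell times and against the save interval —
and it is also what the state-recovery checks presuppose, since a frame
halfway along the O→J path belongs to no state.  Users wanting visibly
interpolating trajectories can lower `transition_rate`.

**Planted burial and exposure.**  In the extended states the designated
loop's side beads protrude a further 2 Å in both models — the
membrane-insertion-loop analogue of a hydrophobic loop standing out of the
surface.  In the VARIANT they are pulled from that protruded position
toward the midpoint of the flanking backbone beads by a tuck factor, and
the designated epitope-like motif's side beads are pushed further outward.
Both displacement magnitudes are *calibrated*, by root-finding on the
noiseless J geometry, so the loop's SASA is exactly `(1 − 0.30)` times its
WT value and the motif's exactly `(1 + 0.15)` times — the planted −30%
burial and +15% exposure are definitions, not hopes.  A plain two-bead
chain cannot reach 30% burial by tucking alone (every bead keeps a free
solvent corridor), which is why the WT-protruded baseline exists.

**What the generator does not emulate.**  No physics: no force field,
solvent, thermostat, or glycans; noise is isotropic and uncorrelated
between atoms and frames, so there are no collective fluctuations; states
are exact geometries rather than basins with internal structure; and the
burial/exposure changes are planted directly rather than emerging from a
substitution.  Passing recovery tests therefore demonstrates that the
*measurement chain* (alignment → PCA → clustering → stratified SASA →
deltas) is correct and unbiased at realistic noise, not that any
particular protein behaves this way.

# The two-trait GWAS generator

Genotypes: a latent Gaussian per allele, thresholded at the locus allele
frequency (two independent alleles per individual, Hardy–Weinberg by
construction).  Two deliberate choices:

* **One locus-level MAF** (drawn from 0.05–0.5) shared by all 50 variants.
  Two binary variables with different frequencies cannot reach high
  correlation, so per-variant iid MAFs would make the AR(1) LD target
  unattainable; real tight LD blocks do share allele frequency (the
  published credible set's effect-allele frequencies are 0.05–0.06 across
  all 18 variants).
* **Calibrated latent correlations.**  Thresholding attenuates
  correlation (a latent 0.9 yields dosage correlation ≈ 0.6), so the
  latent correlation for each lag is solved numerically such that the
  *realized dosage* correlation matches `ρ^|i−j|` (ρ = 0.9 by default).
  The tests check a mean absolute deviation below 0.05 at n = 5000.

Traits: the causal variant's dosage scaled to 1% variance explained plus
unit Gaussian noise, in independent cohorts of n = 5000; per-variant
marginal OLS gives β/SE/p.  With `shared = FALSE` the second trait's
causal variant is drawn ≥ 20 positions away (dosage r² ≈ 0.9⁴⁰ ≈ 0.015,
genuinely distinct signals).

# Causal-genetics choices

* **Wald ratio / NOME.**  `se_ratio = se_out/|β_exp|` treats the exposure
  effect as known; the parametric-bootstrap oracle in the tests draws only
  the outcome effect accordingly.  The instrument F-statistic is
  `(β_exp/se_exp)²`.
* **Harmonization.**  Swapped alleles flip the outcome beta (and EAF);
  anything not resolvable by a swap is an error.  Strand-ambiguous (A/T,
  C/G) variants are kept with a warning and an EAF cross-check when
  frequencies are available — the worked-example instrument is itself a
  G/C variant, so silently dropping ambiguous variants was not an option.
* **Colocalization priors.**  `p1 = p2 = 1e-4`, `p12 = 1e-5`, and effect
  prior SD 0.15 for quantitative traits (SD units) / 0.2 for binary
  (log-odds), the conventions of the ABF colocalization framework; all are
  arguments.  Only the single-signal enumeration is implemented — the
  multi-signal extension requires an external fine-mapping fit and is out
  of scope.  Posterior arithmetic is in log space with log-sum-exp; the
  H3 term uses `log(e^{s1+s2} − e^{s12})` computed stably via `log1p`.
* **Credible sets.**  Sort by PIP descending (ties by variant id),
  accumulate to coverage; minimality is then structural.  A total PIP
  below the coverage level is an error that reports the achievable
  coverage rather than silently returning everything.
* **Prioritization.**  The ≥ 2-of-4 rule for non-coding variants counts
  narrow-peak-supported regulatory overlap only; gapped-peak-only overlap
  is recorded in its own column but never counted.  Coding non-synonymous
  variants are carried forward with their deleterious vote fraction; the
  package does not re-run any variant-effect predictor — their verdicts
  are inputs.

# Numerical and degenerate-input conventions

Superposition requires ≥ 3 non-collinear atoms (second singular value
above 1e-8 of the first); midpoint ties break to the lowest frame index;
cluster-frame sampling with a stratum at or below the requested size
returns the whole stratum with a note; a reference stratum with zero mean
yields an undefined-percent flag with the absolute change still reported;
occupancy bins with no frames are `NA`, and a model that never leaves the
reference cluster has an absent (NA) half-departure time.  Every
stochastic step takes an explicit seed and all generators are
bit-reproducible under it.

# Problem sizes

The default study conditions — 60 residues, 3200 frames, 960 SASA lattice
points, 50 variants at n = 5000, 10 ensemble seeds and 20 colocalization
seeds in the acceptance runs — keep a full verification run in the
low-minutes range on one core while leaving all planted effects several
standard errors from their decision boundaries.  They are the package's
standard conditions, stated here so that anyone scaling up (more repeats,
longer chains, denser lattices) knows the baseline they are changing.

# Known limitations

The surrogate antigenicity scorer is an exposure proxy and will not
reproduce a trained predictor's calibration, only (approximately) its
exposure-driven component.  The exposure deltas are descriptive, without
inferential error bars.  The PDB reader targets cleaned single-chain
structures (first altLoc kept, insertion codes rejected).  The LD
generator produces one AR(1) block, not realistic human haplotype
structure.  And the ensemble analysis assumes the trajectory frames fit in
memory three times over (raw, aligned, and the PCA design matrix), which
is comfortable at desk scale but would need chunking for microsecond
all-atom trajectories.
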