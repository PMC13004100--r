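# conformgen

Tools for asking, end to end, how a missense variant changes a protein's
conformational behaviour and whether that variant is the causal signal
behind a genetic association — the two analytical halves of studies that
tie a fine-mapped coding variant to a structural mechanism.

The motivating system is β2-glycoprotein I (β2GPI, apolipoprotein H), a
five-domain plasma glycoprotein: Domain V binds anionic phospholipids
through exposed loops (aPL loop 1 = K303/K305/K306, aPL loop 2 =
L332/F334/W335, the anti-A1 loop), while Domains I–II carry the epitopes of
pathogenic anti-β2GPI autoantibodies.  The Domain V substitution W335S
(residue numbering includes the signal peptide; the same site is W316S
without it) sits inside aPL loop 2.  The package quantifies how such a
substitution changes the solvent exposure of phospholipid-binding loops and
epitope motifs across the protein's conformational states (circular
O-Shape, extended J- and S-Shapes), and runs the summary-statistic genetics
chain that nominates the variant in the first place.

## What it computes

**Conformational ensembles.**  Multi-model PDB trajectories are combined
into one ensemble, aligned by a two-pass Kabsch superposition (fit to frame
1, refit to the mean structure), and reduced by coordinate PCA: the
eigendecomposition of the covariance of the flattened, aligned coordinates.
Conformations are clustered by average-linkage agglomeration on Euclidean
distance over the first 4 principal components, cut to a chosen number of
clusters; each cluster is characterised by its midpoint frame (member
closest to the PC-space centroid), within-cluster RMSD, radius of gyration
`R_g = sqrt(Σ w_i |r_i − r̄|² / Σ w_i)`, and occupancy over time.
Solvent-accessible surface area uses the Shrake–Rupley construction: per
atom, the fraction of a deterministic golden-spiral lattice on the expanded
sphere of radius `r_vdw + r_probe` not occluded by any neighbour, times
`4π(r_vdw + r_probe)²`.  Motif-level exposure deltas compare a (model,
cluster) stratum against a reference cluster within the model, or against
the same cluster in a reference model; a surrogate antigenicity scorer
(relative solvent exposure, SASA over the residue's isolated maximum) and
an importer for external epitope-prediction scores feed the same delta
machinery.

**Causal genetics.**  For a single instrument the Wald ratio is
`β_out / β_exp` with first-order NOME standard error `se_out / |β_exp|` and
instrument strength `F = (β_exp / se_exp)²`.  Colocalization follows the
Wakefield approximate Bayes factor: with `z = β/se` and
`r = W²/(W² + se²)`, `log ABF = ½(log(1 − r) + r z²)` per variant and
trait; the five configuration posteriors PP0–PP4 (no signal / trait-1 only
/ trait-2 only / two distinct variants / one shared variant) combine the
per-variant ABFs with priors `p1 = p2 = 1e-4`, `p12 = 1e-5`, and the
per-variant shared-signal posterior is the normalised `exp(labf1 + labf2)`.
A 95% credible set takes variants in decreasing posterior inclusion
probability until the cumulative PIP reaches 0.95.  Variant prioritization
applies the four-criteria rule: a non-coding variant is prioritized only
when at least two of {narrow-peak regulatory overlap, predicted
enhancer–gene link, association with *increased* target expression, QTL
colocalization} hold; coding non-synonymous variants are carried forward
with their deleterious-predictor vote fraction.

**Synthetic data.**  Because the real inputs (restricted genotypes,
microsecond-scale MD) are not redistributable, the package ships
generators: a two-bead-per-residue chain that transitions from a circular
to extended conformations under a logistic schedule with planted
residue-level burial (−30%) and exposure (+15%) changes and a slower
transition in the variant model, and a two-trait GWAS simulator with
AR(1)-style LD and a known causal variant.  Every planted effect has a
ground-truth record, so recovery is testable.

## Worked example

The genetics chain on the bundled worked-example tables:

```r
library(conformgen)

pips <- read.delim(system.file("extdata", "apoh_finemap_pips.tsv",
                               package = "conformgen"), comment.char = "#")
credible_set_from_pips(setNames(pips$pip, pips$variant_id), coverage = 0.95)
#> 95% credible set: 18 variants, cumulative PIP 0.960

sim <- simulate_two_trait_summary_stats(seed = 1, shared = TRUE)
coloc_abf(sim$trait1, sim$trait2)
#> ABF colocalization over 50 variants
#> PP0 PP1 PP2 PP3 PP4
#>   0   0   0   0   1
#> lead shared-signal variant: var25 (per-variant PP4 = 1.000)
```

All 18 variants of the published fine-mapping table are needed to reach 95%
coverage (the top 17 stop at 0.94), and on simulated data with a shared
causal variant the colocalization posterior concentrates on PP4 with the
planted variant (var25) as the lead candidate.

The ensemble half on the synthetic scenario (`analysis/02_ensemble.R`):

```
clustering (4 PCs, average linkage, k = 3): ARI vs planted states = 1.000
 cluster cluster_label n_frames mean_rmsd  mean_rg n_WT n_VARIANT
       1       O-Shape      608  1.221761 37.58421  248       360
       2       J-Shape     2150  1.260806 61.58459 1081      1069
       3       S-Shape      442  1.278638 56.27524  271       171
half-departure from the circular cluster (ns):
VARIANT      WT
 9.5525  6.5675
```

The three planted states are recovered exactly; the extended clusters have
the larger radius of gyration, and the variant model leaves the circular
cluster ~3 ns later than the wild type — the planted transition lag.  The
exposure step (`analysis/03_exposure.R`) recovers the planted −30% burial
of the Domain-V-like loop as −28.8% and the planted +15% motif exposure as
+14.5% (means over 10 seeds, correct sign in 10/10).

The numbered scripts under `analysis/` run the whole study in order:
`01_simulate.R` (synthetic trajectories and summary statistics),
`02_ensemble.R` (pipeline over the combined ensemble), `03_exposure.R`
(exposure-delta recovery), `04_antigenicity.R` (surrogate antigenicity),
`05_genetics.R` (credible set, Wald ratio, colocalization,
prioritization); outputs land under `results/`.

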