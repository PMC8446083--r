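# poleward

Analysis pipeline for the latitudinal structure of marine algal
microbiomes: where, along the pole-to-pole temperature gradient, does one
microbial community regime give way to another, and how does that boundary
move as the upper ocean warms?

The package is written for microbial ecologists working with station-by-
feature abundance tables from ocean transects — 16S rDNA counts at genus
level, 18S rDNA counts at species level, and Pfam-level transcript counts —
together with per-station environmental data (latitude, temperature,
salinity, macronutrients) and gridded sea-surface temperature fields. It
implements, end to end and with a synthetic-transect generator carrying
planted ground truth, the chain:

1. **Copy-number normalization.** rRNA gene counts overestimate taxa with
   many gene copies. 16S counts are divided by taxonomy-averaged rrnDB-style
   copy numbers (strain values averaged per species, propagated up the tree
   by averaging children, and imputed for missing taxa from the nearest
   valued ancestor). 18S copy numbers are predicted from genome size through
   the log-log regression `f(x) = 0.66x + 0.75` (copies vs genome size in
   Mbp, R² ≈ 0.55), refit on a reference table. Tables are then rescaled to
   hits per million, and can be rolled up to a target rank with "Nc."
   (no-class) and "U." (unknown, internal-node) pseudo-taxa.
2. **Diversity.** Shannon `H' = −Σ pᵢ ln pᵢ`, per-feature
   occupancy/dispersion evenness, Hellinger transform, Bray-Curtis
   dissimilarity `BC = Σ|n_ik − n_jk| / Σ(n_ik + n_jk)`, backward covariate
   selection for a Gaussian GLM, and single-constraint CCA (fraction of
   community inertia explained by one environmental variable).
3. **Co-occurrence networks.** Soft-power adjacency `a_ij = |r_ij|^β`
   (β = 11 for combined 16S+18S taxa, 12 for Pfams) on log10 profiles, the
   topological overlap measure
   `TOM_ij = (Σ_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)`,
   average-linkage clustering on 1 − TOM with a static cut, module
   eigengenes (first principal component of a module), and eigengene-
   environment Pearson correlations with t-distribution p-values.
4. **Beta-diversity breakpoints.** Presence-absence, pairwise Sørensen
   dissimilarity `β_sor = (b + c)/(2a + b + c)`, a per-station beta
   summary, bagplot-style bivariate outlier removal (exact Tukey halfspace
   depth), and a minimum-MSE continuous broken stick
   `y = b₀ + b₁x + b₂·max(0, x − ψ)` searched over candidate breakpoints ψ,
   with an F-test against the straight line. Latitude can enter as
   "altered latitude" (North pole 0°, Equator 90°, South pole 180°), and
   gap-fill scenarios reconstruct missing transect regions from donor
   stations by nearest latitude.
5. **Warming projection.** Delta-method bias correction
   (`corrected = projection + observed − modelled historical`),
   classification of SST grids into the breakpoint-defined bands
   (blue < 9.49 °C ≤ yellow < 13.96 °C ≤ orange < 18.06 °C ≤ red), ice
   masking from the observed climatology, and band-shift summaries within a
   latitude belt.

## Worked example

Simulate a transect with a planted regime switch at 14 °C and recover the
breakpoint from the 18S table:

```r
library(poleward)
sim <- simulate_transect(transect_config(threshold_T = 14, seed = 7))
pa  <- presence_absence(sim$tables$taxon_18S)
beta <- station_beta(sorensen_matrix(pa), "adjacent",
                     order_by = sim$env$latitude)
x <- sim$env$temperature
out <- bag_outliers(x, beta)
fit_breakpoint(x[!out], beta[!out], search_range = c(7, 29.02))
#> <breakpoint_fit> psi = 13.608 (MSE 0.00368, p = 1.85e-06, n = 60, window [7.00, 29.02])
#>   y = 0.006734 + 0.01383 x + -0.02142 max(0, x - psi)

fit_copy_number_model(sim$truth$genome_sizes, sim$truth$copy_numbers)
#> <copy_number_model> log10(copies) = 0.708 * log10(genome Mbp) + 0.672  (R2 = 0.594, n = 94)
```

The fitted breakpoint ψ = 13.6 °C sits 0.4 °C from the planted 14 °C
switch; the p-value compares the broken stick against a straight line. The
copy-number refit recovers the planted power law (slope 0.66, intercept
0.75) within ordinary least-squares sampling error at 94 species.

## The analysis workflow

The numbered drivers under `analysis/` run the whole study on the
synthetic transect, writing artifacts under `results/pipeline/`:

```sh
Rscript analysis/01_simulate.R    # transect + SST grids with planted truth
Rscript analysis/02_normalize.R   # copy numbers, imputation, hits/million
Rscript analysis/03_diversity.R   # Shannon, evenness, Bray-Curtis, GLM, CCA
Rscript analysis/04_network.R     # adjacency, TOM, modules, eigengenes
Rscript analysis/05_breakpoint.R  # Sorensen, bagplot, broken stick
Rscript analysis/06_project.R     # bias correction, temperature bands
```

Every step is a thin wrapper over `run_pipeline()`, so the same chain is
available programmatically.

## Vignette

`vignettes/poleward-methods.Rmd` documents the statistical models, the
design of the synthetic-transect generator (and what it deliberately does
not emulate), numerical conventions, and known limitations.
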