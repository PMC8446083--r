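---
title: "Methods: latitudinal regime boundaries in algal microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: latitudinal regime boundaries in algal microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(poleward)
```

This vignette is the package's own account of the statistics it
implements, the design of its synthetic-transect generator, and the
numerical conventions that a user of the results should know about.

## The scientific question

Upper-ocean microbial communities differ between cold, nutrient-rich
high-latitude waters and warm, stratified, nutrient-poor waters. If that
difference is a regime boundary rather than a smooth cline, community
turnover (beta diversity) should change behaviour abruptly at some
temperature ψ along a pole-to-pole transect, and a warming ocean should
move the geographic expression of ψ poleward. The pipeline quantifies this
with three linked analyses: copy-number-aware normalization of the
community tables, weighted co-occurrence networks correlated with the
environment, and a broken-stick (segmented) regression of per-station beta
diversity on temperature, whose breakpoints then define temperature bands
projected under warming scenarios.

## Normalization model

rRNA gene counts confound organismal abundance with gene copy number.

* **16S.** Reference copy numbers arrive as strain-level entries; the
  arithmetic mean per species is propagated up the taxonomy, each internal
  node receiving the mean of its children's (propagated) values. Dataset
  taxa missing a value take the value of their nearest valued ancestor.
  Counts are divided by the assigned copy number.
* **18S.** No curated copy-number database covers eukaryotes, but copy
  number scales with genome size approximately as a power law; on the
  log10–log10 scale the pipeline fits `log10(copies) = a·log10(G) + b` by
  ordinary least squares and divides counts by the predicted copy number
  `10^(a·log10 G + b)`. Genome size enters in **Mbp**: with the published
  coefficients (a = 0.66, b = 0.75) this yields copy numbers of order
  10²–10³ for typical protist genomes (tens to hundreds of Mbp), which is
  the biologically plausible range; a base-pair scale would only shift the
  intercept, so the slope comparison is unaffected. Missing genome sizes
  are imputed by the same nearest-ancestor rule before prediction.
* Each station row is then rescaled to **hits per million** (sum 10⁶).
  Division precedes rescaling; the division rule for 18S mirrors the
  explicit 16S rule, and rank aggregation (below) defaults to running
  after normalization.
* **Rank aggregation.** Features at or below the target rank are summed
  into the rank-level node. Leaf-side features whose lineage skips the
  rank are pooled as `Nc. <ancestor>` (no class), named by the nearest
  ancestor ranked above the target; abundance sitting directly on internal
  nodes between the target rank and the root keeps its own name prefixed
  `U.` (unknown); abundance on the root is dropped and the dropped
  fraction reported.

## Diversity and ordination

Shannon `H′ = −Σ pᵢ ln pᵢ` (natural log) summarizes within-station
diversity; a per-feature *dispersion* index — Pielou-style evenness
`H′/ln S` of a feature's abundance across the stations it occupies,
defined as 1 at occupancy 1 — summarizes how evenly a taxon spreads along
the transect. Beta diversity uses Bray-Curtis in its ratio-of-sums form
`Σ|n_ik − n_jk| / Σ(n_ik + n_jk)` (the typeset per-feature-ratio variant
is not a standard index and disagrees with the vegan-based workflow the
form mirrors); Bray-Curtis is a semimetric, so only bounds and symmetry
are guaranteed. Covariate selection for `H′` is backward elimination on a
Gaussian GLM, dropping the single least-significant covariate per
iteration until all remaining p-values fall below 0.05; ties break by
column order, making the procedure deterministic. Constrained ordination
is a textbook single-constraint CCA, reported as constrained inertia over
total inertia (delegated to vegan and cross-checked in the tests against
an explicit chi-square-standardized projection).

On strongly collinear environmental sets — and on a thermally structured
transect every nutrient is close to a linear function of temperature —
backward selection retains one representative of the collinear family,
not necessarily temperature itself; the CCA fractions of the collinear
covariates likewise differ only marginally. The workflow reports this
rather than pretending the covariates are separable.

## Co-occurrence networks

Feature profiles are log10(x+1)-transformed hits-per-million (zeros are
pervasive in amplicon tables). The adjacency is `|r|^β` with Pearson r —
the stated construction, which is the *unsigned* convention even where
such analyses are sometimes labelled "signed"; a true signed variant
`((1+r)/2)^β` is available but off by default. β = 11 is used for the
combined genus-level 16S + species-level 18S table (inner-joined on
stations) and β = 12 for Pfams. The topological overlap measure

TOM_ij = (Σ_{u≠i,j} a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 − a_ij)

with `k_i = Σ_{u≠i} a_iu` measures shared neighbourhoods; modules are
found by average-linkage clustering on 1 − TOM with a **static cut**
(default height 0.99, minimum module size 30 for Pfams and 10 for taxa)
rather than a dynamic tree-cut: the planted two-regime structure does not
need adaptive cutting, and a fixed height keeps the procedure
deterministic and transparent. Clusters below the size floor are left
`grey` (unassigned), the conventional name. Module eigengenes are the
first principal component of the standardized member profiles, scaled to
unit variance and oriented so the mean correlation with members is
positive; eigengene–environment association uses Pearson r with the exact
t-distribution p-value on n − 2 degrees of freedom. Latitude enters as
*altered latitude* (90 − latitude: North pole 0°, Equator 90°, South pole
180°) so a pole-to-pole transect is monotone on one axis.

## Breakpoint analysis

Presence–absence (strictly positive abundance; a configurable threshold
uses strict inequality so a value equal to the threshold is absent) feeds
the pairwise Sørensen dissimilarity `(b + c)/(2a + b + c)`. The pairwise
matrix is reduced to one beta value per station before regression. The
reduction is configurable: `mean` dissimilarity to all other stations,
`nearest` neighbour dissimilarity, or `adjacent` — the mean dissimilarity
to the latitudinally neighbouring stations. The workflow default is
**adjacent**. The reasoning is geometric: the mean-to-all reduction of any
distance-decay community is governed by each station's position relative
to the transect's median composition — its slope is σ′(T)·(2F(T) − 1),
with F the station CDF — so it bends wherever F crosses ½, not where the
ecology changes; the neighbour-based reduction measures the local turnover
rate, which is exactly the quantity whose behaviour changes at a regime
boundary. `mean` and `nearest` remain available for sensitivity analysis.

Bivariate outliers of (gradient, beta) are removed with a bagplot rule
built on exact Tukey halfspace depth (computed by the rotating-line
method; the fence is the 50%-deepest-point hull inflated threefold about
the depth median; degenerate inputs — under 10 points or collinear — flag
nothing, with a warning). For the amplicon datasets the gradient window is
restricted to 7–29.02 °C first, then outliers are flagged.

The broken stick is the continuous three-parameter model
`y = b₀ + b₁x + b₂·max(0, x − ψ)`. Candidate breakpoints are midpoints of
consecutive sorted unique x values (midpoints avoid degenerate segment
assignment at observed x), each leaving at least `min_segment = 3` points
per side; the reported ψ minimizes the mean squared error, by construction
equal to an exhaustive search. The p-value is an F-test of the broken
stick against the straight line with two extra parameters (ψ and b₂);
because ψ is unidentified under the null this p-value is approximate (the
Davies problem) and is labelled as such. Gap-fill scenarios reconstruct
masked transect regions from donors — nearest station by |Δlatitude| among
all stations, a named donor region, a second region, or both pooled —
with latitude ties resolved to the northern donor.

## Warming projection

Delta-method bias correction adds the per-cell difference between the
observed climatology and the modelled historical field to the projection;
on the calibration period this is exact by construction (an identity the
tests verify to 10⁻¹²). Cells containing sea ice in the observed
climatology (freezing proxy −1.8 °C) are excluded throughout. Band
classification uses half-open intervals assigned upward — a cell exactly
at 9.49 °C is yellow — because strict inequalities on both sides would
leave boundary cells undefined; the convention is documented rather than
silent. Band shifts are summarized inside a latitude belt (default
40–60° N) as per-band cell fractions and a 4×4 transition matrix.

## The synthetic-transect generator

The generator is first-class, tested code: it defines the study
conditions under which every downstream claim is verified.

* **Environment.** Stations are equally spaced in latitude (default 60
  stations, ±85°, or a single hemisphere). Temperature declines linearly
  with distance from the equator from 30 °C to −2 °C; salinity tracks
  temperature positively; nitrate+nitrite, phosphate and silicate track it
  negatively with small Gaussian noise — the cold-rich/warm-poor nutrient
  pattern.
* **Community regimes.** Each taxon's occupancy is logistic in
  temperature (scale 1.5 °C). Cold taxa switch *off* around the planted
  threshold ψ\* (midpoints jittered by 1 °C). Half the warm taxa switch
  *on* there; the other half have onset midpoints spread over the warm
  range with density increasing toward the equator (niche packing), so
  species turnover accumulates approximately linearly above ψ\* and is
  flat below it — which is what makes ψ\* identifiable by a single-kink
  broken stick on local turnover. A small set of ubiquitous taxa is
  present throughout. Observed abundances are the expectation times
  lognormal noise (σ = 0.2 on log10 by default); presence requires the
  noisy activation to exceed half its plateau, so detection is centred on
  the turnover midpoint rather than biased by abundance.
* **Modules.** Pfam features stay detected everywhere and modulate
  expression: a temperature response of one log10 unit through the same
  logistic, plus a shared per-station regime factor (σ = 0.5 log10) that
  gives module members correlated fluctuations beyond temperature —
  without it, unsigned adjacency cannot distinguish a module from its
  anti-correlated counterpart. Three hundred background Pfams with
  independent variability (0.5 log10 units) emulate the non-module
  majority of a real metatranscriptome; they also keep station totals
  stable so hits-per-million closure does not imprint the regime signal
  on every feature (with only module Pfams present, the closure term
  dominates the correlations and merges the planted modules — a
  compositional artefact worth knowing about in real data too).
* **Copy numbers.** 18S genome sizes are log10-normal (mean 1.5, sd 0.5,
  Mbp); copy numbers follow the planted law (slope 0.66, intercept 0.75)
  with Gaussian scatter σ = 0.3 on log10, chosen a priori so the refit R²
  is near 0.55: R² = 0.66²·0.25 / (0.66²·0.25 + 0.3²) ≈ 0.55. Thirty
  percent of species lack genome sizes in the emitted reference, to
  exercise imputation. 16S copy numbers are small integer-like operon
  counts known at genus level.
* **Taxonomy.** A balanced four-level tree (root/domain, class, genus,
  species) covering the 16S genera and 18S species. The fixtures for the
  `Nc.`/`U.` aggregation rules use a separate hand-built tree with a
  rank-skipping lineage.
* **SST grids.** A squared-cosine meridional profile with a zonal ripple;
  the model historical field adds a smooth spatial bias; the projection
  adds a uniform warming offset; ice is masked where the observed field is
  at or below −1.8 °C.

**What the generator does not emulate** — and therefore what passing tests
do *not* establish about real data: ocean circulation and fronts,
seasonality, sequencing depth variation and read-level error, compositional
count noise (noise is lognormal, not Poisson/multinomial, since only
relative structure matters after hits-per-million), hemispheric asymmetry,
and any taxonomic realism beyond tree shape. Tests on the generator verify
that the implementation recovers planted structure under these idealized
conditions; they do not validate the ecological model itself.

## Problem sizes and determinism

The default verification sizes are 60 stations, 94 taxa per amplicon
table, and 420 Pfams; breakpoint-recovery properties use 100 transects
with thresholds drawn uniformly in 8–20 °C, module recovery uses planted
two-module tables at noise σ = 0.3, and oracle-equivalence checks run on
hundreds of random 5–8-node instances. These sizes give stable medians
while keeping the full suite around ten seconds. All randomness flows
through explicit integer seeds; identical configuration and seed reproduce
every artifact byte for byte.

## Known limitations

* The breakpoint p-value ignores the search over ψ (Davies problem); it
  is useful for ranking fits, not as an exact test level.
* Exactly one breakpoint is modelled; multiple-regime transects would
  need a different model.
* The bagplot fence uses the exact-depth bag without the interpolated
  "loop" of full bagplot implementations; on small n the flagging is
  slightly more conservative.
* The static tree cut is appropriate for well-separated planted modules;
  real tables with nested module structure may need adaptive cutting.
* CCA inertia fractions for strongly collinear covariates differ by less
  than their sampling noise; ranking them is then not meaningful.
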