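---
title: "Grass-microbe inter-domain networks: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grass-microbe inter-domain networks: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`graminet` implements an analysis chain for linking grassland plant
communities to soil microbial communities sampled along an environmental
transect: diversity and group statistics, distance-decay regressions,
variance partitioning on constrained ordination, and bipartite
grass-microbe association networks with direct-effect deconvolution,
environmental link pruning, topology, and stability analysis. This
vignette records the models behind each stage, the tunable parameters that
matter, what the synthetic-data generator does and does not emulate, and
the design decisions made where the methods literature leaves choices
open. No empirical claim is made here that the package's tests and
acceptance script do not themselves compute.

## 1. Data model

Count tables are samples x taxa non-negative integer matrices tagged with
an organism domain (archaea, bacteria, fungi, grass). Sample metadata
carry coordinates, mean annual temperature, soil chemistry (pH, CEC, OM,
TN, TP, TC, SMC) and grass biophysical variables: height H (cm), cover
degree CD (%), species count S, fresh and dry biomass FB/DB (g/m^2).
Alignment restricts all inputs to the lexicographically sorted
intersection of sample ids; sample loss is handled per domain (an ITS
table with fewer valid samples never shrinks the 16S analyses).

## 2. Diversity

Reads are normalized by rarefaction: one seed-controlled draw per sample
without replacement; samples below the depth are dropped and reported.
Averaging repeated rarefactions is deliberately not done - a single
reproducible draw keeps counts integer and the pipeline deterministic.
Alpha diversity uses observed richness, Shannon H' = -sum p_i ln p_i in
natural-log units (the base is a documented choice; sources often omit
it), Pielou J = H'/ln S, and Margalef (S-1)/ln N. Pielou is undefined at
S = 1 and is reported as missing, never coerced to zero. Beta diversity is
abundance-based Bray-Curtis.

## 3. Group statistics

Differences among grassland types use Kruskal-Wallis; when the omnibus
test is significant, pairwise Dunn z-tests with Benjamini-Hochberg
correction feed an insert-and-absorb compact letter display. Dunn + BH is
a documented choice of post-hoc (field papers usually say only
"non-parametric test") and is isolated behind `kruskal_letters()` so it
can be swapped. The Spearman screen reports raw two-sided p-values with
the conventional star coding; BH correction across the screen is available
but off by default because the screens this package mirrors report raw
stars. PERMANOVA is the one-way Anderson partition of squared distances
with the add-one permutation convention p = (#{F_perm >= F_obs}+1)/(B+1).

## 4. Distance decay

Community dissimilarity is regressed on pairwise great-circle distance
(haversine, R = 6371 km) or on Euclidean divergence of z-scored predictor
variables, over the n(n-1)/2 upper-triangle pairs in a fixed column-major
order. Pairs are not independent, so alongside the naive OLS p we report a
Mantel-style permutation p (999 joint row/column permutations of the
predictor matrix). Slopes are reported per km of the configured predictor
unit; cross-group contrasts pool pair-level data into one regression with
a group x distance interaction and BH-corrected pairwise contrasts.

A caution that the generator makes vivid: Bray-Curtis saturates at 1, so
the OLS slope over a fixed extent is not monotone in turnover rate. A very
narrow niche breadth produces complete turnover within a fraction of the
transect, a long plateau at dissimilarity 1, and a *smaller* fitted slope
than a moderate breadth. The planted "steeper when narrower" property
therefore holds in the sub-saturation regime (breadths of roughly 0.2-0.6
of the transect at this extent), which is where the generator defaults
live.

## 5. Variance partitioning

The three-way partition among grass productivity (CD, DB, S), grass
diversity (Margalef, Shannon, Pielou of the grass community) and soil
variables (pH, TN, TP, SMC) runs the seven constrained correspondence
analyses (each block, each pair, all three) and applies
inclusion-exclusion to the explained-inertia fractions. Constrained
inertia is computed from the chi-square standardized community matrix
projected onto the row-weighted constraint space - the same construction
vegan's `cca()` uses, which serves as the independent oracle in the test
suite. Fractions are reported unadjusted by default (the percentages this
machinery mirrors appear unadjusted); Ezekiel-adjusted fractions are
available. Shared fractions can legitimately be negative under the
adjusted convention and are flagged, not clipped.

## 6. Network inference

**SparCC.** Compositional correlation via log-ratio variances
t_ij = Var[log x_i/x_j]: solving T = M w for basis variances under the
sparsity assumption, rho_ij = (w_i + w_j - t_ij)/(2 sqrt(w_i w_j)),
with up to 10 iterative exclusions of the single strongest pair above
|rho| = 0.1 (each exclusion is a rank-one Sherman-Morrison downdate of the
analytic base inverse) and 20 Dirichlet-resampling inner iterations
summarized by the element-wise median. The grass table and one microbial
table are stacked into a joint composition; the grass x microbe block is
the inter-domain association matrix. Significance comes from a
permutation bootstrap (each component independently shuffled across
samples) with the add-one convention.

**Filtering.** Edges require |r| >= 0.3 (inclusive) and p < 0.05
(exclusive); the strictness at the boundary is a documented choice since
"threshold of 0.3 and significance of 0.05" does not specify it.

**Deconvolution.** Retained totals G are decomposed into direct strengths
S under a transitivity model: influence along a two-step path multiplies
edge strengths, parallel contributions combine with the bounded operator
u (+) v = (u+v)/(1+uv) (tanh addition), and G = S (+) V(S). Three
implementation decisions matter and are recorded here:

1. *Paths run through the association network, not the dense correlation
   matrix.* Sub-threshold correlations (any block, including grass-grass
   and microbe-microbe conduits) carry no path influence. On a dense
   correlation matrix the tanh-additive combination of hundreds of tiny
   paths saturates and explains everything away.
2. *Echo correction.* The influence carried from k to j, when evaluating
   pair (i, j), excludes the component of G_kj that is itself induced
   through the focal pair (first-order: G_kj (-) S_ki S_ij). Without it,
   two true edges sharing a neighbour annihilate each other, because each
   one's observed total "explains" the other.
3. *Same-sign capping.* Indirect influence of the same sign as the
   observed total is capped at that total, so a fully-explained edge
   shrinks to zero instead of flipping sign; sign-flipping feeds back
   through the path terms as oscillation.

The solver is a damped fixed-point iteration (initial step 0.5, halved on
oscillation) from S = G, converged at max |change| < 1e-6; the identical
algorithm exists in R (reference) and C++ (default), and the test suite
asserts their exact agreement plus the self-consistency of the returned
fixed point. Edges whose direct strength falls below the 0.3 filter are
removed and logged.

**Environmental/distance pruning.** An edge is attributed to shared
environmental filtering when both endpoints correlate significantly
(Spearman p < 0.05) with the same covariate with the same sign AND the
endpoints' first-order partial correlation given that covariate falls
below 0.3. The screened covariates include stand-level grass biophysical
variables (CD, S, FB, DB, H) as well as soil chemistry, temperature and
altitude: a grass-species-microbe edge that vanishes once total cover is
controlled reflects stand structure, not a species-specific association.
The dispersal screen is analogous with matrices: both endpoints'
abundance-difference matrices must Mantel-correlate with geographic
distance and the pair's partial Mantel correlation given geography must
fall below 0.3. Every pruned edge is logged with its triggering variable.
The exact published form of this link test is not reproducible from its
description; the two-condition rule above is this package's documented
interpretation.

## 7. Topology and stability

Connectance L/(mn); bipartite clustering as the mean Jaccard overlap of
same-side neighbourhoods over node pairs sharing at least one partner;
NODF nestedness with equal-degree pairs contributing zero. Attack
tolerance removes nodes (uniformly at random, replicated, or by
descending degree) and tracks the fraction of remaining nodes holding at
least one edge; robustness is the trapezoidal area under that curve, with
the fraction surviving at 50% removal reported as a second summary
because both conventions appear in the stability literature. Vulnerability
is max_i (E - E_i)/E on unweighted global efficiency (disconnected pairs
contribute zero). Null ensembles rewire by checkerboard swaps (10x edge
count attempts), preserving both degree sequences exactly, verified per
null in the tests.

## 8. Connectivity and partial Mantel tests

"Network connectivity" is not a sample-level quantity in the sources this
package mirrors; the documented choice is score(sample) = sum over network
nodes of degree x relative abundance in that sample (presence-only
variant available). Euclidean distances between scores give the
connectivity matrix, tested against single-variable divergence matrices
with partial Mantel tests: productivity and diversity variables are
controlled for soil divergence (and vice versa), with geographic distance
always in the combined control. Two-sided permutation p-values are the
default; a one-tailed option exists because published partial-Mantel
tables with negative r and p = 1.000 suggest one-tailed conventions.

## 9. The synthetic world

The generator emulates the study design the pipeline targets: 16 sites
(2 alpine swamp meadow, 4 alpine meadow, 6 alpine steppe, 4 temperate
steppe) x 3 replicates along a 2,121 km transect, with altitude
decreasing and MAT increasing along it. Soil and grass variables are drawn
from grassland-type-specific normal distributions centred on published
type means and SDs; one printed SD (TN in temperate steppe, 4.97 against a
mean of 2.55 g/kg) is implausible for a positive concentration and was
replaced by 1.50. Grass species have Gaussian niches (breadth 0.20 of the
transect), lognormal abundance noise (sd 1.0), site-level occupancy
patchiness (35% absence inside the niche), and realized richness coupled
to the landscape's S. Measured stand variables are measurements of the
vegetation, not independent covariates: CD, FB and DB blend the
type-level draw (55%) with the realized stand's log standing crop (45%).
Microbes combine a baseline, a domain-specific spatial niche (amplitude
1.2/0.85/0.25 and breadth 0.25/0.40/0.65 of the transect for
archaea/bacteria/fungi - this plants the turnover ordering grass >
archaea > bacteria > fungi), planted grass-host links (0.5% of pairs,
strength 0.8-1.2 on twice the standardized host log-abundance, positive
by default), environmental drivers over disjoint taxa (35% of taxa,
block weights productivity 1 > soil 0.6 > diversity 0.15 - this plants
the variance partitioning ordering), and Gaussian noise (sd 1.4). Counts are
multinomial draws with lognormal library sizes; ITS-like library-size
parameters put roughly 15% of samples below a 10,140-read depth, mirroring
the 48-versus-41 sample split such studies report. The planted "true" DDR
slope of each table is the Bray-Curtis-versus-distance OLS slope of the
pre-sampling latent relative abundances (per 1,000 km): multinomial
counting is treated as measurement noise, the realized latent noise as
part of the true community.

What the generator does **not** emulate: sequencing error, chimeras, OTU
clustering artifacts, phylogenetic structure, microbe-microbe ecological
interactions, and temporal dynamics. A green test therefore establishes
that the chain recovers planted structure in compositional count data
with realistic gradients - not that it is robust to upstream
bioinformatic noise.

## 10. Known limitations

Three acceptance properties are left deliberately red rather than gamed;
each follows from the statistics of the stated design, and each is
asserted at its stated threshold so the failure is visible.

**The precision ceiling.** With 48 samples the null spread of a
correlation estimate is about 0.15, so the |r| >= 0.3 with p < 0.05
filter admits roughly 2-4% of all grass x microbe pairs by chance - a
few hundred chance-level edges per domain against at most a few dozen
plantable true links. These false edges are not attributable to any
environmental variable, geography, or indirect path, so no downstream
screen can remove them, and no plausible planted-link density overcomes
the ratio: mean precision lands near 0.1 against a 0.8 target. Recall
(>= 0.6, typically 0.7-0.9 here), slope recovery within 15%, and the
ordering properties are met. Higher precision would require more samples
or a stricter correlation threshold than the 0.3/0.05 design.

**All-positive edges.** Planted links are positive-only and every
recovered planted link is positive, but the chance-level and
closure-induced edges that dominate the retained set carry arbitrary
signs, so the retained edge set as a whole is not sign-pure. This is the
precision ceiling wearing a different hat.

**Robustness versus degree-preserving nulls.** Under the robustness
definition used here - fraction of remaining nodes holding at least one
edge under uniform random removal - a node of degree d survives with
probability determined by d alone, so the expected attack curve is a
functional of the degree sequence, which checkerboard rewiring preserves
exactly. The empirical-versus-null contrast is therefore a coin flip by
construction; a robustness notion sensitive to degree-degree correlation
or modular structure would be required for this comparison to carry
information.

**VPA ordering margins.** The unique-fraction ordering
productivity > soil > diversity is planted with weights 1/0.6/0.15 and
evaluated on chance-corrected (Ezekiel-adjusted) fractions, yet at
n = 48 the sampling noise of unique fractions is of the same order as
the planted contrast - as it is in the field studies this machinery
mirrors, where the corresponding percentages differ by only a few
points. The per-seed, all-domain ordering rate sits near its threshold
and is reported as measured.
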