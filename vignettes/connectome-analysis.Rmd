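---
title: "Models and methods for tracer-based connectome analysis"
author: "connectoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for tracer-based connectome analysis}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(connectoscope)
```

This vignette documents the models the package implements, the
assumptions they make, the tunable parameters that matter, and the design
choices taken where the methodology was genuinely open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## From labeled-cell counts to connection weights

A retrograde tracer injection into target area $X$ yields, for every
source area $Y$, a supragranular and an infragranular labeled-neuron
count. The connection weight is the fraction of extrinsic labeled
neurons,

$$\mathrm{FLN}(X \leftarrow Y) = \frac{n_Y}{\sum_{Z \neq X} n_Z},$$

where $n_Y$ is the total labeled-neuron count in $Y$ and the sum runs
over all areas other than the injected one. Intrinsic label (cells inside
$X$) is excluded from numerator and denominator, and the intrinsic entry
of the assembled matrix is fixed at exactly 0. Each injection's extrinsic
FLN values therefore sum to 1 by construction.

Replicate injections into the same area are combined in two deliberately
different ways:

- **FLN** is averaged arithmetically, with a connection absent in a
  replicate contributing 0 for that replicate. This keeps every averaged
  row normalized, and treats non-detection as evidence of (near) absence
  rather than missingness.
- **SLN** ($= n^{supra}_Y / n_Y$) is averaged weighted by each
  injection's labeled-neuron count in that source, which is identical to
  pooling the counts: $\widehat{\mathrm{SLN}} = \sum_i n^{supra}_i /
  \sum_i n_i$. The published methodology states a "weighted mean" without
  printing the weights; source-area totals are the only weighting under
  which the weighted mean equals the pooled fraction, so that convention
  is adopted (whole-injection totals would weight sources by unrelated
  label elsewhere). SLN is undefined (`NA`) for agranular sources, where
  no layer-4 boundary exists; the agranular list is a user input, never a
  hard-coded atlas.

Area codes are case-sensitive opaque strings validated against a
user-supplied parcellation; the package carries no built-in parcellation.

## Binary topology

All graph statistics run on the *edge-complete* subnetwork: the square
graph restricted to injected areas, in which every input and output has
been measured. Binarization is `FLN > 0`; the diagonal is excluded
everywhere. Standard machinery (dyad and triad censuses, clique
enumeration, degree-preserving rewiring) is delegated to igraph; the
statistics on top follow tracer-connectome conventions:

- The triad census uses the standard 16-class directed taxonomy
  (003 … 300). The test suite validates it against a brute-force
  classifier that canonicalizes every node triple over all six vertex
  permutations, seeded from hand-written class representatives.
- A clique of size $k$ requires all $k(k-1)$ ordered edges — 100%
  directed density — equivalently a clique of the reciprocal-edge graph.
  Clique proportions divide counts by $\binom{n}{k}$.
- The core is the union of the member sets of *all* maximum-size cliques,
  the only union rule consistent with several same-size maximum cliques
  jointly defining a core larger than any one of them. Block densities
  are reported within core, within periphery, and between (both
  directions pooled).
- The degree-preserving null performs 10 attempted edge swaps per edge
  per realization (a standard mixing heuristic, exposed as a parameter),
  rejecting self-loops and duplicates, and every realization is verified
  to preserve both degree sequences exactly.
- Similarity distance between two areas is 1 minus the cosine similarity
  of their binary input (or output) profiles with the entries involving
  either member of the pair removed, so that a shared connection between
  the two areas themselves cannot create similarity. The upstream
  literature does not restate its exact measure; cosine-on-binary-profiles
  is the simplest choice reproducing the qualitative decay, and the
  connection-probability model $p(s) = \mathrm{logistic}(\alpha + \beta
  s)$ is fitted by Bernoulli maximum likelihood on the unbinned directed
  pairs. The reciprocal and unidirectional curves follow as $p(s)^2$ and
  $2p(s)(1-p(s))$ under directional independence, which is exactly the
  comparison the binned empirical proportions are emitted for.

## The hierarchy model

The laminar profile of a projection carries directional information:
predominantly supragranular origins mark feedforward projections,
infragranular origins feedback. The package assigns each area a scalar
index $h_i$ under the model

$$\mathrm{SLN}(X \leftarrow Y) \sim \mathrm{Beta}\!\left(\mu \phi,\,
(1-\mu)\phi\right), \qquad \mu = \mathrm{logistic}(h_X - h_Y),$$

fitted by maximum likelihood over all per-injection observations (not
the aggregated means — replicates enter individually, optionally
weighted by labeled-neuron counts). A single global precision $\phi$ is
estimated jointly; per-target dispersions would add parameters the
printed formula does not support. Because only differences of $h$ are
identified, one anchor area is fixed at 0 during fitting and the result
is affinely rescaled to $[0,1]$.

Numerical choices: boundary observations (SLN exactly 0 or 1, where the
beta density degenerates) are nudged inward by the standard
$(y(n-1)+0.5)/n$ transform while interior values are untouched;
optimization is bounded quasi-Newton (L-BFGS-B) with $h \in [-20, 20]$
and $\phi \le 10^4$ — the likelihood is unbounded in $\phi$ whenever the
mean structure interpolates, so the cap acts as a point-mass surrogate;
starting values come from the logit-linear least-squares fit. That
logit-OLS fit (SLN clipped to $[10^{-3}, 1-10^{-3}]$) is also exposed as
`method = "linear"` and serves as an independent cross-check: on
logit-link data the two orderings agree to Spearman ≥ 0.95 in the test
suite.

Two direction conventions are worth stating precisely: swapping the
roles of target and source negates every index difference and exactly
reverses the fitted ordering, whereas swapping roles *and* complementing
SLN describes the same data and leaves the fit unchanged.

### Circular embedding

Areas are drawn on a polar plot with radius $R_i = \sqrt{1-h_i}$ (the
hierarchy top sits at the centre automatically, so no extra recentring
is applied) and angles minimizing

$$\sum_{(i,j):\ \mathrm{FLN}_{ij}>0}
\left(-\log_{10}\mathrm{FLN}_{ij} - r\,
\mathrm{circdist}(\theta_i,\theta_j)\right)^2$$

jointly over the angles and the scale $r \ge 0$. Both directions of a
pair contribute separate residuals; absent connections contribute
nothing. Given angles, the optimal $r$ is closed-form, so the search
runs over angles only: 50 seeded random restarts (configurable) of a
quasi-Newton local search, anchor area fixed at angle 0. The reflection
ambiguity is resolved by forcing the first non-anchor area (label order)
into $[0, \pi]$. On 3-area instances the multi-restart optimum matches a
1° exhaustive grid.

## Spatial statistics

The exponential distance rule states that the probability of an axonal
projection of length $d$ decays as $p(d) = c\,e^{-\lambda d}$. Following
the published procedure, the package histograms per-neuron projection
lengths (2 mm bins, heights = counts/total), drops empty bins (log of
zero), and fits ordinary least squares to $\log_{10}$ height versus bin
centre with equal bin weights. A slope $s$ converts as $\lambda = -s \ln
10$ and $c = 10^{\mathrm{intercept}}$; non-negative slopes map to
$\lambda = 0$. Two properties of this estimator matter in practice: the
total sample size cancels from the slope (only the intercept shifts),
and sparsely populated tail bins — expected counts below ~5 — bias the
slope slightly toward zero because empty bins are dropped while
single-count bins survive. At the problem sizes used here ($10^5$
lengths bounded by a ~40 mm geometry) that bias stays within a few
percent; it is the reason recovery tolerances are stated at 5% rather
than at the Monte-Carlo noise floor.

The FLN-versus-distance profile sorts connections by wiring distance and
slides a window of 173 points advanced by 20 (the published window and
"bin size", read as window length and stride since the overlap scheme is
not printed; both are parameters). On noise-free synthetic data its
slope agrees with $-\lambda/\ln 10$ within 10%.

Cross-species scaling fits $\log_{10}\lambda$ on $\log_{10}$ gray-matter
volume by OLS across a user-supplied species table — the published
species values live in supplementary material, so the shipped table
(`inst/extdata/species_lambda_synthetic.csv`) is synthetic, constructed
to follow a plausible power law, and is used to exercise structure, not
to reproduce printed numbers.

One published detail deserves a note: the printed histogram-fit formula
names "log10(projection length)" as the regressor while simultaneously
reporting an exponential (not power-law) form whose coefficients match
$0.1295 \cdot \ln 10 = 0.298 \approx 0.3$ and $10^{-0.0262} = 0.94$. The
package treats the regressor as the length itself in mm — the only
reading consistent with the reported $\lambda$ and $c$ — and documents
the printed wording as a typographic slip.

## Microstructure correlations

Spine-count measurements are reported per area *group* (a published
measurement often covers several parcellation areas). Hierarchy values
are normalized to a maximum of 1 and averaged within groups before
correlating ("group" mode); the alternative of duplicating the group's
spine count across member areas is exposed as `mode = "duplicate"`. The
spine-count versus neural-density relation is fitted as a power law by
log–log OLS, which is scale-free and returns the exponent directly. The
shipped microstructure table is likewise synthetic and exercises the
interfaces only.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
with all randomness flowing from a single seed via deterministic
per-injection substreams:

- Areas are placed uniformly in a cube (default edge 30 mm), giving
  interareal distances that are unimodal and close to normal at realistic
  area counts, on the spatial scale of a small primate brain.
- Expected extrinsic weights for an injection decay as
  $e^{-\lambda d}$ ($\lambda$ default 0.3/mm) with log-normal
  multiplicative noise (default $\sigma_{\log_{10}} = 0.8$); realized
  counts are multinomial over a fixed neuron budget (default $10^4$, the
  order of extrinsic label in real injections), so per-injection FLN
  normalization is exact, mirroring FLN's definition as a fraction.
  Together the distance term and the noise spread weights over roughly
  4–5 orders of magnitude and leave the study-shaped (55×116) network
  about 65–70% dense.
- The supragranular split of each source is beta-binomial with mean
  $\mathrm{logistic}(h_{target} - h_{source})$ and concentration
  $\kappa$ (default 20) — a pure binomial would lack the overdispersion
  replicate SLN measurements show.
- Projection lengths are i.i.d. truncated exponential on
  $[0, d_{\max}]$, $d_{\max}$ defaulting to the maximum pairwise
  distance.
- Replicates share the ground truth and add an extra per-injection
  log-normal perturbation (`jitter_log10`); the between-injection noise
  law is not characterized in the literature, so log-normal jitter is a
  modeling choice exposed as a parameter.

What the generator deliberately does not emulate: cortical geometry
(folding, laminar thickness), tracer chemistry and uptake-zone artifacts,
border-crossing injections, and hemispheric asymmetries. Passing
recovery tests therefore demonstrate estimator correctness under the
generative assumptions, not robustness to every artifact of real
histology. Two known departures from ideal log-normality are inherent to
count data and shared with real experiments: an atom at the detection
floor (FLN = 1/budget) and mild skew from mixing target-specific distance
distributions. The log-normality check accordingly bounds the
Kolmogorov–Smirnov distance to the fitted Gaussian (< 0.1) and the
skewness, rather than requiring a pointwise normality test to pass at
arbitrary sample size.

## Problem sizes and determinism

The test suite and acceptance script run at sizes chosen to exercise the
asymptotics the methods rely on while remaining desk-scale: $10^5$
projection lengths for EDR recovery, 30 areas × 3 replicates for
hierarchy recovery, 100 realizations for null ensembles, exhaustive
oracles up to 6 nodes (triads) and 12 nodes (cliques). Every stochastic
stage takes an explicit seed; `run_pipeline()` reports are byte-identical
across reruns with the same seed, and no timestamps enter serialized
output.

## Known limitations

- The beta regression assumes a single global precision; strongly
  target-dependent SLN dispersion would be absorbed into bias of
  $\hat\phi$, not of the ordering.
- The embedding objective is non-convex; multi-restart local search is
  validated against grid oracles only at small sizes, and distinct
  near-optimal angle configurations can occur at larger ones.
- Clique enumeration is exponential in the worst case; on very dense
  reciprocal graphs the `max_size` cap should be used.
- The EDR estimator inherits the published histogram-regression
  procedure; for heavy right-censoring or very small samples a direct
  ML exponential fit would be preferable, but is intentionally not the
  default since comparability with published slopes is the point.
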