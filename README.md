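# connectoscope

Statistical analysis of mesoscale cortical connectomes built from
retrograde tracer injections.

Retrograde tracing experiments inject a fluorescent tracer into one
cortical area (the *target*) and count the labeled neurons that appear in
every other area (the *sources*), split by laminar position relative to
layer 4. From those per-injection labeled-cell tables this package
computes the field's standard connection statistics and the models layered
on top of them:

- **FLN** (fraction of extrinsic labeled neurons), the connection weight
  `FLN(X←Y) = (labeled neurons in Y) / (all extrinsic labeled neurons)`,
  averaged arithmetically across replicate injections, and **SLN** (fraction
  of supragranular labeled neurons), the laminar profile
  `SLN(X←Y) = supragranular / (supra + infragranular)`, pooled across
  replicates by labeled-neuron count.
- **Binary topology** of the edge-complete subnetwork (the square graph on
  injected areas where every input and output is known): density
  `ρ = M/(N(N−1))`, degree distributions, dyad and triad motif censuses
  compared against degree-preserving edge-swap null ensembles, directed
  clique enumeration, the core–periphery partition (core = union of all
  maximum cliques), and connection probability as a function of the
  cosine similarity distance of input/output profiles.
- **Hierarchy**: per-area indices `h` estimated by beta regression so that
  `SLN(X←Y) ≈ logistic(h_X − h_Y)`, with a single jointly estimated
  precision φ; projections classify as feedforward (SLN > 0.5) or feedback
  (SLN < 0.5). A circular embedding places areas at radius `R = √(1−h)`
  with angles fitted so that `−log10 FLN ≈ r·circdist(θ_i, θ_j)`.
- **Spatial statistics**: the exponential distance rule (EDR)
  `p(d) = c·exp(−λd)` fitted as a linear regression on the base-10 log of
  the projection-length histogram, sliding-window profiles of log10 FLN
  versus wiring distance, and the cross-species allometric power law
  `log10 λ = slope·log10(GM volume) + intercept`.
- **Microstructure**: correlations of hierarchy with layer-3 pyramidal
  spine counts, the spine-count versus neural-density power law, and
  rostrocaudal gradients.
- A **synthetic-connectome generator** with known ground truth (latent
  positions, hierarchy, λ, noise levels) so that every stage is testable
  without access to the source atlas.

## Worked example

```r
library(connectoscope)

gt  <- synthetic_ground_truth(30, lambda_true = 0.3, seed = 42)
sim <- simulate_connectome(gt, replicates = 2, n_lengths = 2e4)

cm <- build_connectome(sim$injections, sources = gt$areas)
cm
#> Interareal connectome: 30 injected target areas x 30 source areas
#>   831 present connections of 870 possible (95.5%)
#>   injections per target: 2-2

fit <- fit_hierarchy(sln_observations(sim$injections), method = "beta")
fit
#> Cortical hierarchy fit (beta regression, 1454 SLN observations)
#>   precision phi = 21.13
#>   predicted-observed SLN correlation = 0.381
#>   lowest: A020 (0.00), A019 (0.02), A025 (0.03)
#>   highest: A022 (0.88), A021 (0.96), A027 (1.00)

cor(gt$h_true, coef(fit)[names(gt$h_true)], method = "spearman")
#> [1] 0.8941046

fit_edr(sim$lengths)
#> Exponential distance rule fit (20000 projection lengths, 2 mm bins)
#>   log10 p(d) = -0.1219 d + -0.2921
#>   p(d) = 0.51 exp(-0.281 d)
```

The hierarchy fit recovers the generating ordering (Spearman ≈ 0.89 at
this small problem size; ≥ 0.95 at the precision used in the test suite),
and the EDR fit on 2×10⁴ simulated lengths returns λ̂ ≈ 0.28/mm against a
true 0.3/mm; the slope −0.1219 log10-units per mm converts as
λ = −slope·ln 10. A 30-area connectome at this budget is denser (95.5%)
than a realistically parcellated one; at the 55×116 study shape the same
defaults give ≈ 65–70% density.

The same stages run end to end, with JSON/CSV reports, via

```r
report <- run_pipeline(sim$files$injections,
                       distances = sim$files$distances,
                       lengths   = sim$files$lengths,
                       seed = 1, out_dir = "reports")
```

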