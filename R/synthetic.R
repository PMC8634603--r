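#' Ground truth for a synthetic connectome
#'
#' Bundles the latent quantities from which synthetic injection data are
#' generated: area positions and wiring distances, a true hierarchy, the
#' exponential-distance-rule decay rate, and the noise parameters. The
#' generator emulates the statistical structure tracer connectomes show:
#' log-normal connection weights spanning several orders of magnitude,
#' approximately normal interareal distances, exponentially distributed
#' projection lengths, laminar fractions driven by hierarchy differences
#' through a logit link, and replicate-injection variability.
#'
#' @param n_areas Number of cortical areas (>= 2).
#' @param lambda_true EDR decay rate in 1/mm (default 0.3, the order observed
#'   in small primate cortices).
#' @param sigma_log10 Between-connection multiplicative noise, SD on the
#'   log10 scale (default 0.8; together with the distance term this spreads
#'   weights over roughly 4-5 orders of magnitude).
#' @param kappa Beta-binomial concentration of the laminar split (default 20;
#'   lower values give the overdispersion replicate SLN measurements show).
#' @param neurons_per_injection Expected labeled-cell budget per injection
#'   (default 10000, the order of magnitude of extrinsic labeled neurons per
#'   real injection).
#' @param box_extent_mm Edge length of the cube areas are placed in
#'   (default 30 mm, giving distances on the scale of a small primate brain).
#' @param h_true Optional per-area hierarchy in `[0, 1]`; drawn uniformly if
#'   omitted.
#' @param seed Integer seed; all randomness flows from it.
#' @return Object of class `synthetic_ground_truth` with fields `n_areas`,
#'   `areas`, `positions`, `distances`, `h_true`, `lambda_true`,
#'   `sigma_log10`, `kappa`, `neurons_per_injection`, `d_max`, `seed`.
#' @export
synthetic_ground_truth <- function(n_areas, lambda_true = 0.3,
                                   sigma_log10 = 0.8, kappa = 20,
                                   neurons_per_injection = 10000,
                                   box_extent_mm = 30, h_true = NULL,
                                   seed = 1L) {
  stopifnot(n_areas >= 2, lambda_true >= 0, sigma_log10 >= 0, kappa > 0,
            neurons_per_injection >= 1)
  geo <- generate_areas(n_areas, box_extent_mm, seed = seed)
  if (is.null(h_true)) {
    set.seed(seed + 1L)
    h_true <- stats::runif(n_areas)
  }
  stopifnot(length(h_true) == n_areas, all(h_true >= 0 & h_true <= 1))
  names(h_true) <- geo$areas
  structure(list(n_areas = n_areas, areas = geo$areas,
                 positions = geo$positions, distances = geo$distances,
                 h_true = h_true, lambda_true = lambda_true,
                 sigma_log10 = sigma_log10, kappa = kappa,
                 neurons_per_injection = neurons_per_injection,
                 d_max = max(geo$distances), seed = as.integer(seed)),
            class = "synthetic_ground_truth")
}

#' @export
print.synthetic_ground_truth <- function(x, ...) {
  cat("Synthetic connectome ground truth: ", x$n_areas, " areas, lambda = ",
      x$lambda_true, " /mm, sigma_log10 = ", x$sigma_log10, ", kappa = ",
      x$kappa, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Place synthetic areas and compute their distance matrix
#'
#' Areas are placed uniformly at random in a cube; pairwise Euclidean
#' distances between uniformly placed points are unimodal and close to
#' normal, matching the shape of measured interareal wiring-distance
#' distributions.
#'
#' @param n_areas Number of areas (>= 2).
#' @param box_extent_mm Positive edge length of the cube in mm.
#' @param seed Integer seed.
#' @return List with `areas` (codes), `positions` (n x 3, mm), `distances`
#'   (symmetric, zero diagonal, mm).
#' @export
generate_areas <- function(n_areas, box_extent_mm = 30, seed = 1L) {
  stopifnot(n_areas >= 2)
  if (box_extent_mm <= 0) stop("box extent must be positive")
  set.seed(seed)
  pos <- matrix(stats::runif(3L * n_areas, 0, box_extent_mm), ncol = 3L)
  areas <- sprintf("A%03d", seq_len(n_areas))
  rownames(pos) <- areas
  d <- as.matrix(stats::dist(pos))
  dimnames(d) <- list(areas, areas)
  list(areas = areas, positions = pos, distances = d)
}

# Expected extrinsic weights for an injection into target t:
# w_j proportional to exp(-lambda d_tj) * 10^eps, eps ~ N(0, sigma);
# an optional extra log10 jitter models between-replicate variability.
expected_weights <- function(target_index, gt, jitter_log10 = 0) {
  d <- gt$distances[target_index, -target_index]
  w <- exp(-gt$lambda_true * d)
  sigma <- sqrt(gt$sigma_log10^2 + jitter_log10^2)
  if (sigma > 0)
    w <- w * 10^stats::rnorm(length(w), 0, sigma)
  if (all(w == 0)) stop("degenerate expected weights: all zero")
  w
}

#' Generate one synthetic tracer injection
#'
#' Draws a labeled-cell table for an injection into one area. Expected
#' extrinsic weights decay exponentially with wiring distance and carry
#' log-normal multiplicative noise; realized counts are multinomial over a
#' fixed neuron budget (so the per-injection FLN values are exact fractions);
#' the supragranular/infragranular split of each source is beta-binomial
#' with mean `plogis(h_target - h_source)` and concentration `kappa`.
#'
#' @param target_index Index of the injected area in `gt$areas`.
#' @param gt A [synthetic_ground_truth()].
#' @param jitter_log10 Extra per-injection log10 SD on the expected weights
#'   (replicate variability), default 0.
#' @param injection_id Identifier; autogenerated if `NULL`.
#' @param seed Integer seed; defaults to a stream derived from `gt$seed` and
#'   the target index.
#' @return An [injection_record()].
#' @export
generate_injection <- function(target_index, gt, jitter_log10 = 0,
                               injection_id = NULL, seed = NULL) {
  stopifnot(inherits(gt, "synthetic_ground_truth"),
            target_index >= 1, target_index <= gt$n_areas)
  if (is.null(seed)) seed <- (gt$seed + 7919L * target_index) %% .Machine$integer.max
  set.seed(seed)
  w <- expected_weights(target_index, gt, jitter_log10)
  counts <- as.vector(stats::rmultinom(1L, gt$neurons_per_injection, w))
  names(counts) <- names(w)
  counts <- counts[counts > 0]
  if (!length(counts)) stop("degenerate injection: no labeled neurons")
  target <- gt$areas[target_index]
  mu <- stats::plogis(gt$h_true[target] - gt$h_true[names(counts)])
  p <- stats::rbeta(length(counts), mu * gt$kappa, (1 - mu) * gt$kappa)
  supra <- stats::rbinom(length(counts), counts, p)
  if (is.null(injection_id))
    injection_id <- sprintf("inj_%s_%d", target, seed %% 100000L)
  injection_record(injection_id, target,
                   data.frame(source_area = names(counts),
                              supra_count = supra,
                              infra_count = counts - supra,
                              stringsAsFactors = FALSE),
                   tracer = "DY")
}

#' Generate per-neuron projection lengths under the EDR
#'
#' i.i.d. draws from an exponential distribution with rate `lambda_true`,
#' truncated to `[0, d_max]`, via the inverse CDF.
#'
#' @param gt A [synthetic_ground_truth()], or any list with `lambda_true`
#'   and `d_max`.
#' @param n_neurons Number of lengths (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of lengths in mm.
#' @export
generate_projection_lengths <- function(gt, n_neurons, seed = 1L) {
  stopifnot(n_neurons >= 1)
  lambda <- gt$lambda_true
  if (is.null(lambda) || lambda <= 0) stop("lambda must be positive")
  d_max <- if (is.null(gt$d_max)) Inf else gt$d_max
  set.seed(seed)
  u <- stats::runif(n_neurons)
  mass <- 1 - exp(-lambda * d_max)    # probability mass inside [0, d_max]
  -log(1 - u * mass) / lambda
}

#' Generate replicate injections into the same target
#'
#' Independent injections sharing the ground truth, each with its own
#' log-normal perturbation of the expected weights, emulating the
#' between-injection variability replicate tracer experiments show.
#'
#' @inheritParams generate_injection
#' @param k Number of replicates (>= 1).
#' @return List of `k` [injection_record()]s.
#' @export
generate_replicates <- function(target_index, k, gt, jitter_log10 = 0.2) {
  if (k < 1) stop("k must be >= 1")
  lapply(seq_len(k), function(i)
    generate_injection(target_index, gt, jitter_log10 = jitter_log10,
                       injection_id = sprintf("inj_%s_r%02d",
                                              gt$areas[target_index], i),
                       seed = (gt$seed + 7919L * target_index + 104729L * i) %%
                         .Machine$integer.max))
}

#' Simulate a full synthetic connectome dataset
#'
#' Generates replicate injections into every area (or a subset), optionally
#' writes the injection table, distance matrix, projection lengths and a
#' ground-truth JSON sidecar to a directory in the package's delimited-text
#' formats.
#'
#' @param gt A [synthetic_ground_truth()].
#' @param targets Indices of injected areas (default: all).
#' @param replicates Injections per target.
#' @param jitter_log10 Replicate variability (log10 SD).
#' @param n_lengths Number of projection lengths to draw (0 to skip).
#' @param out_dir Optional output directory.
#' @return List with `injections`, `lengths`, `gt`, and (if written) `files`.
#' @export
simulate_connectome <- function(gt, targets = seq_len(gt$n_areas),
                                replicates = 1L, jitter_log10 = 0.2,
                                n_lengths = 0L, out_dir = NULL) {
  injections <- unlist(lapply(targets, function(t)
    generate_replicates(t, replicates, gt, jitter_log10)), recursive = FALSE)
  lengths <- if (n_lengths > 0)
    generate_projection_lengths(gt, n_lengths, seed = gt$seed + 3L)
  out <- list(injections = injections, lengths = lengths, gt = gt)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(injections = file.path(out_dir, "injections.csv"),
                  distances = file.path(out_dir, "distances.csv"),
                  ground_truth = file.path(out_dir, "ground_truth.json"))
    write_injections(injections, files$injections)
    write_matrix_csv(gt$distances, files$distances)
    if (!is.null(lengths)) {
      files$lengths <- file.path(out_dir, "lengths.csv")
      utils::write.table(data.frame(length_mm = lengths), files$lengths,
                         sep = ",", row.names = FALSE, quote = FALSE)
    }
    sidecar <- list(n_areas = gt$n_areas, areas = gt$areas,
                    h_true = as.list(gt$h_true),
                    lambda_true = gt$lambda_true,
                    sigma_log10 = gt$sigma_log10, kappa = gt$kappa,
                    neurons_per_injection = gt$neurons_per_injection,
                    d_max = gt$d_max, seed = gt$seed)
    jsonlite::write_json(sidecar, files$ground_truth, auto_unbox = TRUE,
                         digits = NA)
    out$files <- files
  }
  out
}
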