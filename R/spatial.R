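#' Fit the exponential distance rule to projection lengths
#'
#' Histograms the per-neuron projection lengths (bar height = counts divided
#' by the total count), then fits an ordinary least-squares line to the
#' base-10 logarithm of the nonempty bar heights against the bin-centre
#' distance. A negative slope `s` (log10 per mm) corresponds to the
#' exponential distance rule `p(d) = c exp(-lambda d)` with
#' `lambda = -s ln(10)` and `c = 10^intercept`. Empty bins are dropped
#' (log of zero undefined) and bins are weighted equally.
#'
#' @param projection_lengths Per-neuron lengths in mm (>= 100 values).
#' @param bin_size Histogram bin width in mm (default 2).
#' @return Object of class `edr_fit` with `slope_log10`, `intercept_log10`,
#'   `lambda` (1/mm), `c`, `bin_size_mm`, `n_lengths`, `histogram`.
#' @export
fit_edr <- function(projection_lengths, bin_size = 2) {
  if (length(projection_lengths) < 100)
    stop("need at least 100 projection lengths")
  if (bin_size <= 0) stop("bin size must be positive")
  idx <- floor(projection_lengths / bin_size)
  counts <- tabulate(idx + 1L, nbins = max(idx) + 1L)
  centers <- (seq_along(counts) - 0.5) * bin_size
  height <- counts / length(projection_lengths)
  keep <- counts > 0
  if (sum(keep) < 3) stop("fewer than 3 nonempty bins")
  fit <- stats::lm(log10(height[keep]) ~ centers[keep])
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  structure(list(slope_log10 = slope, intercept_log10 = intercept,
                 lambda = edr_lambda_from_slope(slope),
                 c = 10^intercept,
                 bin_size_mm = bin_size,
                 n_lengths = length(projection_lengths),
                 histogram = data.frame(center_mm = centers[keep],
                                        height = height[keep])),
            class = "edr_fit")
}

#' Convert a log10 histogram slope to an EDR decay rate
#'
#' A slope `s` (log10 units per mm) of the log-histogram line corresponds to
#' `lambda = -s ln(10)` per mm; non-negative slopes give `lambda = 0` (no
#' decay).
#'
#' @param slope_log10 Fitted slope in log10 per mm.
#' @return Decay rate in 1/mm.
#' @export
edr_lambda_from_slope <- function(slope_log10) {
  ifelse(slope_log10 < 0, -slope_log10 * log(10), 0)
}

#' @export
print.edr_fit <- function(x, ...) {
  cat("Exponential distance rule fit (", x$n_lengths, " projection lengths, ",
      x$bin_size_mm, " mm bins)\n", sep = "")
  cat("  log10 p(d) = ", signif(x$slope_log10, 4), " d + ",
      signif(x$intercept_log10, 4), "\n", sep = "")
  cat("  p(d) = ", signif(x$c, 3), " exp(-", signif(x$lambda, 3),
      " d)\n", sep = "")
  invisible(x)
}

#' @export
coef.edr_fit <- function(object, ...) {
  c(lambda = object$lambda, c = object$c)
}

#' @export
predict.edr_fit <- function(object, newdata, ...) {
  d <- if (is.data.frame(newdata)) newdata[[1]] else newdata
  object$c * exp(-object$lambda * d)
}

#' Sliding-window profile of log10 FLN versus distance
#'
#' Sorts connections by wiring distance and advances a window of
#' `window_points` connections by `stride`, reporting the mean distance and
#' the mean and SD of log10 FLN within each window.
#'
#' @param fln Positive connection weights.
#' @param distances Matching wiring distances in mm.
#' @param window_points Window size in data points (default 173).
#' @param stride Window advance in data points (default 20).
#' @return Data frame with `distance_mm`, `mean_log10_fln`, `sd_log10_fln`,
#'   `n`.
#' @export
fln_distance_profile <- function(fln, distances, window_points = 173,
                                 stride = 20) {
  stopifnot(length(fln) == length(distances))
  keep <- !is.na(fln) & !is.na(distances) & fln > 0 & is.finite(distances)
  fln <- fln[keep]; distances <- distances[keep]
  ord <- order(distances)
  l10 <- log10(fln[ord]); d <- distances[ord]
  n <- length(d)
  window_points <- min(window_points, n)
  starts <- seq(1L, max(1L, n - window_points + 1L), by = stride)
  do.call(rbind, lapply(starts, function(s) {
    i <- s:(s + window_points - 1L)
    data.frame(distance_mm = mean(d[i]),
               mean_log10_fln = mean(l10[i]),
               sd_log10_fln = stats::sd(l10[i]),
               n = length(i))
  }))
}

#' Compare two wiring-distance samples
#'
#' Two-sided two-sample Kolmogorov-Smirnov test (e.g. distances among all
#' area pairs versus the injected subset), plus ML Gaussian fits of both
#' samples.
#'
#' @param all_pairs,sampled_pairs Numeric distance samples in mm.
#' @return List with `ks_statistic`, `ks_p`, and `fit_all` / `fit_sampled`
#'   (mean, sd).
#' @export
compare_distance_distributions <- function(all_pairs, sampled_pairs) {
  stopifnot(length(all_pairs) > 0, length(sampled_pairs) > 0)
  ks <- suppressWarnings(stats::ks.test(all_pairs, sampled_pairs,
                                        alternative = "two.sided"))
  gfit <- function(x) c(mean = mean(x), sd = sqrt(mean((x - mean(x))^2)))
  list(ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
       fit_all = gfit(all_pairs), fit_sampled = gfit(sampled_pairs))
}

#' Allometric scaling of the EDR decay rate with brain volume
#'
#' Ordinary least squares of `log10(lambda)` on `log10(gray-matter volume)`
#' across species, i.e. a power law `lambda = 10^intercept * volume^slope`.
#'
#' @param species_table Data frame with columns `species`, `lambda`
#'   (1/mm), `gm_volume` (mm^3); at least 2 species, all values positive.
#' @return Object of class `allometric_fit` with `slope`, `intercept`,
#'   `species_table`, and a `predict` method mapping volumes to predicted
#'   decay rates.
#' @export
fit_allometric <- function(species_table) {
  tab <- as.data.frame(species_table)
  stopifnot(all(c("species", "lambda", "gm_volume") %in% names(tab)))
  if (nrow(tab) < 2) stop("need at least 2 species")
  if (any(tab$lambda <= 0) || any(tab$gm_volume <= 0))
    stop("lambda and volumes must be positive")
  fit <- stats::lm(log10(lambda) ~ log10(gm_volume), data = tab)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 species_table = tab),
            class = "allometric_fit")
}

#' @export
print.allometric_fit <- function(x, ...) {
  cat("Allometric scaling of the EDR decay rate (",
      nrow(x$species_table), " species)\n", sep = "")
  cat("  log10(lambda) = ", signif(x$slope, 4), " log10(GM volume) + ",
      signif(x$intercept, 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.allometric_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' Predict the EDR decay rate for a gray-matter volume
#'
#' @param object An `allometric_fit`.
#' @param newdata Numeric vector of gray-matter volumes (mm^3), or a data
#'   frame with a `gm_volume` column.
#' @param ... Unused.
#' @return Predicted decay rates in 1/mm.
#' @export
predict.allometric_fit <- function(object, newdata, ...) {
  v <- if (is.data.frame(newdata)) newdata$gm_volume else newdata
  if (any(v <= 0)) stop("volumes must be positive")
  10^object$intercept * v^object$slope
}
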