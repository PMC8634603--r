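#' Maximum-likelihood Gaussian fit of log10 connection weights
#'
#' Tracer connection weights (FLN) are approximately log-normal; this fits a
#' Gaussian to the base-10 logarithms by maximum likelihood (sample mean, SD
#' with denominator n) and reports the span in orders of magnitude.
#'
#' @param fln_values Positive connection weights (absent connections must be
#'   filtered out first).
#' @return Object of class `lognormal_fit` with `mu_log10`, `sigma_log10`,
#'   `n_values`, `span_orders`.
#' @export
fit_log10_normal <- function(fln_values) {
  if (length(fln_values) < 1) stop("need at least one value")
  if (any(fln_values <= 0)) stop("all values must be positive; filter absent connections first")
  l <- log10(fln_values)
  mu <- mean(l)
  sigma <- sqrt(mean((l - mu)^2))   # ML estimate (denominator n)
  structure(list(mu_log10 = mu, sigma_log10 = sigma,
                 n_values = length(l), span_orders = max(l) - min(l)),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat("Gaussian ML fit of log10 weights: mu = ", signif(x$mu_log10, 4),
      ", sigma = ", signif(x$sigma_log10, 4), " (n = ", x$n_values,
      ", span ", signif(x$span_orders, 3), " orders of magnitude)\n", sep = "")
  invisible(x)
}

#' @export
coef.lognormal_fit <- function(object, ...) {
  c(mu_log10 = object$mu_log10, sigma_log10 = object$sigma_log10)
}

#' Normalized density histogram
#'
#' Bar heights are counts divided by the bin size and by `n_total`, so that
#' the heights integrate to the fraction of `n_total` covered (1 when all
#' values are included). Bins are anchored at integer multiples of
#' `bin_size` starting from the data minimum, making histograms reproducible.
#'
#' @param values Numeric values.
#' @param bin_size Positive bin width.
#' @param n_total Normalizing count (defaults to `length(values)`).
#' @return Data frame with `bin_left`, `bin_center`, `count`, `height`.
#' @export
density_histogram <- function(values, bin_size, n_total = length(values)) {
  if (bin_size <= 0) stop("bin size must be positive")
  if (!length(values))
    return(data.frame(bin_left = numeric(), bin_center = numeric(),
                      count = integer(), height = numeric()))
  left0 <- floor(min(values) / bin_size) * bin_size
  idx <- floor((values - left0) / bin_size)
  counts <- tabulate(idx + 1L, nbins = max(idx) + 1L)
  lefts <- left0 + bin_size * (seq_along(counts) - 1L)
  data.frame(bin_left = lefts, bin_center = lefts + bin_size / 2,
             count = counts, height = counts / (bin_size * n_total))
}

#' Compare feedforward and feedback connection weights
#'
#' Splits connections into feedforward (SLN > 0.5) and feedback (SLN < 0.5)
#' classes and compares their log10 FLN distributions with a two-sided
#' two-sample Kolmogorov-Smirnov test, an equal-variance t-test, an F-test
#' of variances, and Hedges' g (pooled-SD standardized mean difference with
#' the small-sample correction).
#'
#' @param fln_values Positive weights, paired with `sln_values`.
#' @param sln_values Laminar fractions in `[0, 1]`; `NA` and exact 0.5
#'   (unclassifiable) entries are dropped.
#' @return Object of class `fffb_comparison` with group means, `ks_p`,
#'   `t_p`, `f_p`, `hedges_g`, and group sizes.
#' @export
compare_ff_fb <- function(fln_values, sln_values) {
  stopifnot(length(fln_values) == length(sln_values))
  keep <- !is.na(sln_values) & !is.na(fln_values) & fln_values > 0
  cls <- classify_projections(sln_values[keep])
  l10 <- log10(fln_values[keep])
  ff <- l10[cls == "FF"]; fb <- l10[cls == "FB"]
  if (length(ff) < 2 || length(fb) < 2)
    stop("each class needs at least 2 connections")
  ks <- suppressWarnings(stats::ks.test(ff, fb, alternative = "two.sided"))
  tt <- stats::t.test(ff, fb, var.equal = TRUE)
  ft <- stats::var.test(ff, fb)
  structure(list(mean_log10_ff = mean(ff), mean_log10_fb = mean(fb),
                 n_ff = length(ff), n_fb = length(fb),
                 ks_p = ks$p.value, t_p = tt$p.value, f_p = ft$p.value,
                 hedges_g = hedges_g(ff, fb)),
            class = "fffb_comparison")
}

#' @export
print.fffb_comparison <- function(x, ...) {
  cat("FF vs FB log10 weight comparison\n")
  cat("  mean log10 FLN: FF ", signif(x$mean_log10_ff, 4), " (n=", x$n_ff,
      "), FB ", signif(x$mean_log10_fb, 4), " (n=", x$n_fb, ")\n", sep = "")
  cat("  Hedges' g = ", signif(x$hedges_g, 3),
      ";  KS p = ", format(x$ks_p, digits = 3),
      ", t p = ", format(x$t_p, digits = 3),
      ", F p = ", format(x$f_p, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Hedges' g standardized mean difference
#'
#' Pooled-SD effect size with the small-sample bias correction
#' J = 1 - 3 / (4(n1 + n2) - 9).
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @return Signed effect size (positive when `mean(x) > mean(y)`).
#' @export
hedges_g <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 2, n2 >= 2)
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
               (n1 + n2 - 2))
  j <- 1 - 3 / (4 * (n1 + n2) - 9)
  j * (mean(x) - mean(y)) / sp
}
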