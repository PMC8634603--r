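#' Fit a cortical hierarchy from laminar fractions
#'
#' Estimates a scalar hierarchy index for every area such that the
#' difference of indices predicts the supragranular fraction of each
#' projection through a logit link: `SLN(X <- Y) = plogis(h_X - h_Y)`.
#'
#' `method = "beta"` (default) maximizes the beta likelihood with mean
#' `plogis(h_target - h_source)` and a single precision `phi` estimated
#' jointly; boundary observations (SLN of exactly 0 or 1), for which the
#' beta density is degenerate, are nudged inward with the standard
#' `(y (n - 1) + 0.5) / n` transform while interior values are untouched. `method = "linear"`
#' is ordinary least squares on logit-transformed SLN (clipped to
#' `[1e-3, 1 - 1e-3]`) and serves as an independent cross-check.
#'
#' Only differences of indices are identified; one area (`anchor`, defaulting
#' to the first in alphabetical order) is fixed at 0 during fitting and the
#' result is affinely rescaled to `[0, 1]`.
#'
#' @param observations Data frame with columns `target`, `source`, `sln`
#'   (one row per projection per injection) and optional `weight` (e.g.
#'   labeled-neuron counts; default 1).
#' @param method `"beta"` or `"linear"`.
#' @param anchor Area code fixed at 0 during fitting.
#' @return Object of class `hierarchy_fit` with `h` (named, in `[0, 1]`),
#'   `phi` (beta precision, `NA` for linear), `pred_obs_correlation`,
#'   `method`, `logLik`, `n_obs`, and the raw (unrescaled) indices `h_raw`.
#' @export
fit_hierarchy <- function(observations, method = c("beta", "linear"),
                          anchor = NULL) {
  method <- match.arg(method)
  obs <- as.data.frame(observations)
  stopifnot(all(c("target", "source", "sln") %in% names(obs)))
  obs <- obs[!is.na(obs$sln), , drop = FALSE]
  if (!nrow(obs)) stop("no SLN observations")
  if (any(obs$sln < 0 | obs$sln > 1)) stop("SLN must lie in [0, 1]")
  w <- if ("weight" %in% names(obs)) as.numeric(obs$weight) else
    rep(1, nrow(obs))
  areas <- sort(unique(c(obs$target, obs$source)))
  comp <- observation_components(obs, areas)
  if (max(comp) > 1L)
    warning("observation graph is disconnected; components fitted jointly share only a gauge")
  if (is.null(anchor)) anchor <- areas[1] else stopifnot(anchor %in% areas)
  free <- setdiff(areas, anchor)
  # signed incidence: row r has +1 at target(r), -1 at source(r)
  X <- matrix(0, nrow(obs), length(free), dimnames = list(NULL, free))
  ti <- match(obs$target, free); si <- match(obs$source, free)
  ok_t <- !is.na(ti); ok_s <- !is.na(si)
  X[cbind(which(ok_t), ti[ok_t])] <- 1
  X[cbind(which(ok_s), si[ok_s])] <- X[cbind(which(ok_s), si[ok_s])] - 1

  eps <- 1e-3
  y_lin <- pmin(pmax(obs$sln, eps), 1 - eps)
  h_free_start <- stats::lm.wfit(X, stats::qlogis(y_lin), w)$coefficients
  h_free_start[is.na(h_free_start)] <- 0

  if (method == "linear") {
    h_free <- h_free_start
    phi <- NA_real_
    ll <- NA_real_
  } else {
    n <- nrow(obs)
    y <- obs$sln
    bound <- y == 0 | y == 1
    y[bound] <- (y[bound] * (n - 1) + 0.5) / n   # pull 0/1 off the boundary
    nll <- function(par) {
      h <- par[seq_along(free)]
      phi <- exp(par[length(par)])
      mu <- stats::plogis(as.vector(X %*% h))
      mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
      ld <- stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
      ld[!is.finite(ld)] <- -1e8    # keep the search inside finite territory
      -sum(w * ld)
    }
    start <- c(pmin(pmax(h_free_start, -15), 15), log_phi = log(10))
    # phi is bounded above: with an interpolating mean the beta likelihood
    # is unbounded in phi, so cap the precision at a point-mass surrogate
    opt <- stats::optim(start, nll, method = "L-BFGS-B",
                        lower = c(rep(-20, length(free)), log(1e-2)),
                        upper = c(rep(20, length(free)), log(1e4)),
                        control = list(maxit = 500, factr = 1e4))
    h_free <- opt$par[seq_along(free)]
    phi <- exp(opt$par[length(opt$par)])
    ll <- -opt$value
  }
  h_raw <- c(stats::setNames(0, anchor), h_free)[areas]
  names(h_raw) <- areas
  rng <- range(h_raw)
  h <- if (diff(rng) > 0) (h_raw - rng[1]) / diff(rng) else
    stats::setNames(rep(0.5, length(h_raw)), areas)  # degenerate: flat fit
  mu_hat <- stats::plogis(h_raw[obs$target] - h_raw[obs$source])
  pred_obs <- if (stats::sd(mu_hat) > 0 && stats::sd(obs$sln) > 0)
    stats::cor(mu_hat, obs$sln) else NA_real_
  structure(list(h = h, h_raw = h_raw, phi = phi, method = method,
                 anchor = anchor, pred_obs_correlation = pred_obs,
                 logLik = ll, n_obs = nrow(obs), degenerate = diff(rng) == 0),
            class = "hierarchy_fit")
}

# Connected components of the undirected observation graph (areas linked by
# at least one observation).
observation_components <- function(obs, areas) {
  g <- igraph::graph_from_data_frame(obs[, c("target", "source")],
                                     directed = FALSE,
                                     vertices = data.frame(name = areas))
  igraph::components(g)$membership
}

#' @export
print.hierarchy_fit <- function(x, ...) {
  cat("Cortical hierarchy fit (", x$method, " regression, ", x$n_obs,
      " SLN observations)\n", sep = "")
  if (!is.na(x$phi)) cat("  precision phi = ", signif(x$phi, 4), "\n", sep = "")
  cat("  predicted-observed SLN correlation = ",
      signif(x$pred_obs_correlation, 3), "\n", sep = "")
  ord <- order(x$h)
  show <- c(utils::head(ord, 3), utils::tail(ord, 3))
  cat("  lowest: ", paste(sprintf("%s (%.2f)", names(x$h)[utils::head(ord, 3)],
                                  x$h[utils::head(ord, 3)]), collapse = ", "),
      "\n  highest: ", paste(sprintf("%s (%.2f)", names(x$h)[utils::tail(ord, 3)],
                                     x$h[utils::tail(ord, 3)]), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.hierarchy_fit <- function(object, ...) object$h

#' @export
summary.hierarchy_fit <- function(object, ...) {
  out <- list(h = sort(object$h), phi = object$phi,
              method = object$method,
              pred_obs_correlation = object$pred_obs_correlation,
              n_obs = object$n_obs)
  class(out) <- "summary.hierarchy_fit"
  out
}

#' @export
print.summary.hierarchy_fit <- function(x, ...) {
  cat("Hierarchy (", x$method, " fit, n = ", x$n_obs, ", r(pred, obs) = ",
      signif(x$pred_obs_correlation, 3), ")\n", sep = "")
  print(round(x$h, 3))
  invisible(x)
}

#' Predict SLN from a fitted hierarchy
#'
#' @param object A `hierarchy_fit`.
#' @param newdata Data frame with columns `target` and `source`.
#' @param ... Unused.
#' @return Predicted SLN values `plogis(h_target - h_source)`.
#' @export
predict.hierarchy_fit <- function(object, newdata, ...) {
  stopifnot(all(c("target", "source") %in% names(newdata)))
  h <- object$h_raw
  unknown <- setdiff(unique(c(newdata$target, newdata$source)), names(h))
  if (length(unknown)) stop("area(s) not in fit: ", paste(unknown, collapse = ", "))
  stats::plogis(h[newdata$target] - h[newdata$source])
}

#' Extract per-injection SLN observations from injection records
#'
#' One observation per (injection, extrinsic source) pair, with the
#' labeled-neuron total as the optional weight.
#'
#' @param injections List of [injection_record()]s.
#' @param agranular Area codes with undefined SLN, dropped from the table.
#' @return Data frame with `target`, `source`, `sln`, `weight`.
#' @export
sln_observations <- function(injections, agranular = character()) {
  do.call(rbind, lapply(injections, function(inj) {
    r <- inj$rows[inj$rows$source_area != inj$target_area &
                    !(inj$rows$source_area %in% agranular), , drop = FALSE]
    if (!nrow(r)) return(NULL)
    data.frame(target = inj$target_area, source = r$source_area,
               sln = r$supra_count / (r$supra_count + r$infra_count),
               weight = r$supra_count + r$infra_count,
               stringsAsFactors = FALSE)
  }))
}

#' Classify projections as feedforward or feedback
#'
#' Feedforward (`"FF"`) when SLN > 0.5, feedback (`"FB"`) when SLN < 0.5,
#' `"unclassified"` at exactly 0.5; `NA` propagates.
#'
#' @param sln Numeric vector of laminar fractions.
#' @return Character vector of the same length.
#' @export
classify_projections <- function(sln) {
  out <- ifelse(sln > 0.5, "FF", ifelse(sln < 0.5, "FB", "unclassified"))
  out[is.na(sln)] <- NA_character_
  out
}
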