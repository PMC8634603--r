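#' Circular hierarchy-plus-weights embedding
#'
#' Places every area on a polar plot: the radial coordinate encodes the
#' hierarchy, `R_i = sqrt(1 - h_i)` (the top of the hierarchy sits at the
#' centre), and the angles are chosen so that strong connections subtend
#' small angles. The angles and a common angular scale `r` jointly minimize
#'
#'   sum over connected ordered pairs of
#'     ( -log10 FLN_ij - r * circdist(theta_i, theta_j) )^2,
#'
#' where `circdist` is the circular distance `min(|d|, 2 pi - |d|)`. Both
#' directions of a pair enter as separate residuals; absent connections
#' contribute nothing. Given angles, the optimal `r >= 0` has a closed form,
#' so optimization is over angles only, by multi-restart quasi-Newton local
#' search with the anchor area fixed at angle 0. The reflection ambiguity
#' (negating every angle leaves the objective unchanged) is resolved by
#' requiring the first non-anchor area, in label order, to have an angle in
#' `[0, pi]`.
#'
#' @param h Named hierarchy indices in `[0, 1]` (e.g. `coef()` of a
#'   [fit_hierarchy()] result).
#' @param fln_matrix Square FLN matrix over the same areas (targets x
#'   sources); entries of 0 mark absent connections.
#' @param anchor Area fixed at angle 0 (default: first area).
#' @param n_restarts Number of random restarts (default 50).
#' @param seed Integer seed for the restarts.
#' @return Object of class `circular_embedding` with `R`, `theta` (radians
#'   in `[0, 2 pi)`), `r_scale`, `objective_value`, `anchor`.
#' @export
circular_embedding <- function(h, fln_matrix, anchor = NULL,
                               n_restarts = 50, seed = 1L) {
  areas <- names(h)
  stopifnot(!is.null(areas), all(areas %in% rownames(fln_matrix)),
            all(areas %in% colnames(fln_matrix)))
  if (length(areas) < 3) stop("need at least 3 connected areas")
  if (is.null(anchor)) anchor <- areas[1] else stopifnot(anchor %in% areas)
  F <- fln_matrix[areas, areas]
  pairs <- which(F > 0 & row(F) != col(F), arr.ind = TRUE)
  if (!nrow(pairs)) stop("no connected pairs")
  wgt <- -log10(F[pairs])                 # target angular separations (up to r)
  ai <- pairs[, 1]; aj <- pairs[, 2]
  n <- length(areas)
  anchor_idx <- match(anchor, areas)
  free <- setdiff(seq_len(n), anchor_idx)

  objective <- function(theta_free) {
    th <- numeric(n); th[free] <- theta_free
    d <- abs(th[ai] - th[aj]) %% (2 * pi)
    cd <- pmin(d, 2 * pi - d)
    denom <- sum(cd^2)
    r <- if (denom > 0) max(0, sum(wgt * cd) / denom) else 0
    sum((wgt - r * cd)^2)
  }
  best <- NULL
  for (k in seq_len(n_restarts)) {
    set.seed((seed + 2741L * k) %% .Machine$integer.max)
    start <- stats::runif(length(free), 0, 2 * pi)
    opt <- stats::optim(start, objective, method = "BFGS",
                        control = list(maxit = 300))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  th <- numeric(n); th[free] <- best$par
  th <- th %% (2 * pi)
  # reflection convention: first non-anchor area in [0, pi]
  ref <- free[order(areas[free])][1]
  if (th[ref] > pi) th <- (-th) %% (2 * pi)
  d <- abs(th[ai] - th[aj]) %% (2 * pi)
  cd <- pmin(d, 2 * pi - d)
  r <- if (sum(cd^2) > 0) max(0, sum(wgt * cd) / sum(cd^2)) else 0
  structure(list(R = stats::setNames(sqrt(1 - h), areas),
                 theta = stats::setNames(th, areas),
                 r_scale = r, objective_value = best$value,
                 anchor = anchor, n_pairs = nrow(pairs)),
            class = "circular_embedding")
}

#' @export
print.circular_embedding <- function(x, ...) {
  cat("Circular embedding of ", length(x$theta), " areas (anchor ",
      x$anchor, " at angle 0)\n", sep = "")
  cat("  angular scale r = ", signif(x$r_scale, 4),
      ", residual sum of squares = ", signif(x$objective_value, 4),
      " over ", x$n_pairs, " directed connections\n", sep = "")
  invisible(x)
}

#' @export
plot.circular_embedding <- function(x, ...) {
  xy <- cbind(x$R * cos(x$theta), x$R * sin(x$theta))
  graphics::plot(xy, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1,
                 xlab = "", ylab = "", pch = 19,
                 main = "Hierarchy-weight circular embedding", ...)
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE,
                    fg = "gray")
  graphics::text(xy, labels = names(x$theta), pos = 3, cex = 0.7)
  invisible(x)
}
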