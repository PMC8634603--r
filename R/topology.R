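# Binary-graph analyses of the edge-complete network. Standard graph
# machinery (censuses, clique enumeration, degree-preserving rewiring) is
# delegated to igraph; the statistics layered on top follow the conventions
# of mesoscale tracer-connectome studies.

as_adjacency <- function(G) {
  if (inherits(G, "edge_complete")) G <- G$adjacency
  if (igraph::is_igraph(G))
    G <- as.matrix(igraph::as_adjacency_matrix(G)) > 0
  m <- as.matrix(G)
  if (nrow(m) != ncol(m)) stop("adjacency must be square")
  storage.mode(m) <- "logical"
  diag(m) <- FALSE
  if (is.null(rownames(m))) {
    lab <- sprintf("n%02d", seq_len(nrow(m)))
    dimnames(m) <- list(lab, lab)
  }
  m
}

as_igraph_directed <- function(G) {
  igraph::graph_from_adjacency_matrix(as_adjacency(G) * 1, mode = "directed")
}

#' Directed graph density
#'
#' Fraction of existing directed connections among all possible ones,
#' `rho = M / (N (N - 1))`; self-connections are excluded.
#'
#' @param G Square logical/numeric adjacency matrix, igraph object, or an
#'   `edge_complete` network.
#' @return Density in `[0, 1]`.
#' @export
graph_density <- function(G) {
  A <- as_adjacency(G)
  n <- nrow(A)
  if (n < 2) stop("need at least 2 nodes")
  sum(A) / (n * (n - 1))
}

#' Degree sequences and their Gaussian fits
#'
#' In- and out-degrees of every node (self-connections excluded) together
#' with ML Gaussian fits and binned normalized degree densities (counts
#' divided by bin size and node count).
#'
#' @inheritParams graph_density
#' @param bin_size Degree bin width for the density histograms (default 5).
#' @return List with `k_in`, `k_out`, per-direction `fit` (mean, sd) and
#'   `histogram`.
#' @export
degree_sequences <- function(G, bin_size = 5) {
  A <- as_adjacency(G)
  k_in <- colSums(A); k_out <- rowSums(A)
  gfit <- function(k) c(mean = mean(k), sd = sqrt(mean((k - mean(k))^2)))
  list(k_in = k_in, k_out = k_out,
       fit_in = gfit(k_in), fit_out = gfit(k_out),
       hist_in = density_histogram(k_in, bin_size),
       hist_out = density_histogram(k_out, bin_size))
}

#' Dyad census as fractions of unordered pairs
#'
#' Classifies every unordered node pair as reciprocal (both directions
#' present), unidirectional, or absent, and returns the fractions over all
#' `choose(n, 2)` pairs.
#'
#' @inheritParams graph_density
#' @return Named numeric vector `(reciprocal, unidirectional, absent)`
#'   summing to 1.
#' @export
dyad_census_fractions <- function(G) {
  g <- as_igraph_directed(G)
  cen <- igraph::dyad_census(g)
  n <- igraph::vcount(g)
  out <- c(reciprocal = cen$mut, unidirectional = cen$asym, absent = cen$null) /
    choose(n, 2)
  out
}

# Canonical representatives of the 16 directed triad classes in the standard
# Davis-Leinhardt order (003, 012, 102, 021D, 021U, 021C, 111D, 111U, 030T,
# 030C, 201, 120D, 120U, 120C, 210, 300); edges as from-to pairs on {1,2,3}.
triad_class_edges <- function() {
  list(
    `003`  = cbind(integer(), integer()),
    `012`  = rbind(c(1, 2)),
    `102`  = rbind(c(1, 2), c(2, 1)),
    `021D` = rbind(c(2, 1), c(2, 3)),
    `021U` = rbind(c(1, 2), c(3, 2)),
    `021C` = rbind(c(1, 2), c(2, 3)),
    `111D` = rbind(c(1, 2), c(2, 1), c(3, 2)),
    `111U` = rbind(c(1, 2), c(2, 1), c(2, 3)),
    `030T` = rbind(c(1, 2), c(3, 2), c(1, 3)),
    `030C` = rbind(c(1, 2), c(2, 3), c(3, 1)),
    `201`  = rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2)),
    `120D` = rbind(c(2, 1), c(2, 3), c(1, 3), c(3, 1)),
    `120U` = rbind(c(1, 2), c(3, 2), c(1, 3), c(3, 1)),
    `120C` = rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 1)),
    `210`  = rbind(c(1, 2), c(2, 3), c(3, 2), c(1, 3), c(3, 1)),
    `300`  = rbind(c(1, 2), c(2, 1), c(2, 3), c(3, 2), c(1, 3), c(3, 1)))
}

#' Directed triad census
#'
#' Counts of unordered node triples per directed 3-node isomorphism class,
#' in the standard 16-class taxonomy. Counts sum to `choose(n, 3)`.
#'
#' @inheritParams graph_density
#' @return Named integer vector of length 16 (003 ... 300).
#' @export
triad_census_counts <- function(G) {
  g <- as_igraph_directed(G)
  if (igraph::vcount(g) < 3) stop("need at least 3 nodes")
  cen <- igraph::triad_census(g)
  names(cen) <- names(triad_class_edges())
  cen
}

#' Degree-preserving null ensemble
#'
#' Randomizes a directed graph by repeated edge swaps that keep every node's
#' in- and out-degree fixed (no self-loops, no duplicate edges), the standard
#' configuration-model null for motif analysis.
#'
#' @inheritParams graph_density
#' @param n_realizations Ensemble size (>= 1).
#' @param seed Integer seed; the ensemble is reproducible given the seed.
#' @param swaps_per_edge Attempted swaps per edge (default 10).
#' @return List of adjacency matrices with the same dimnames as `G`.
#' @export
degree_preserving_null <- function(G, n_realizations = 100, seed = 1L,
                                   swaps_per_edge = 10) {
  if (n_realizations < 1) stop("need at least one realization")
  A <- as_adjacency(G)
  g <- as_igraph_directed(A)
  m <- igraph::ecount(g)
  if (m < 2) {
    warning("graph has too few edges to rewire; returning copies")
    return(replicate(n_realizations, A, simplify = FALSE))
  }
  lapply(seq_len(n_realizations), function(i) {
    set.seed((seed + 49999L * i) %% .Machine$integer.max)
    r <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                  niter = swaps_per_edge * m))
    B <- as.matrix(igraph::as_adjacency_matrix(r)) > 0
    dimnames(B) <- dimnames(A)
    B
  })
}

#' Motif over/under-representation against a null ensemble
#'
#' Ratios of the observed dyad and triad class counts to their means over a
#' degree-preserving null ensemble, with the ensemble SD as the error bar.
#' Classes with null mean 0 get an `NA` ratio.
#'
#' @inheritParams graph_density
#' @param ensemble List of adjacency matrices (e.g. from
#'   [degree_preserving_null()]).
#' @return Object of class `motif_report` with `dyad_fractions`,
#'   `triad_counts`, `dyad_null_mean`/`sd`/`ratio` and triad equivalents.
#' @export
motif_ratio <- function(G, ensemble) {
  if (!length(ensemble)) stop("ensemble must be nonempty")
  dy <- dyad_census_fractions(G)
  tr <- triad_census_counts(G)
  dy_null <- vapply(ensemble, dyad_census_fractions, numeric(3))
  tr_null <- vapply(ensemble, triad_census_counts, numeric(16))
  ratio <- function(obs, null_mean) {
    r <- obs / null_mean
    r[null_mean == 0] <- NA_real_
    r
  }
  structure(list(dyad_fractions = dy,
                 dyad_null_mean = rowMeans(dy_null),
                 dyad_null_sd = apply(dy_null, 1, stats::sd),
                 dyad_ratio = ratio(dy, rowMeans(dy_null)),
                 triad_counts = tr,
                 triad_null_mean = rowMeans(tr_null),
                 triad_null_sd = apply(tr_null, 1, stats::sd),
                 triad_ratio = ratio(tr, rowMeans(tr_null)),
                 n_realizations = length(ensemble)),
            class = "motif_report")
}

#' @export
print.motif_report <- function(x, ...) {
  cat("Motif report over", x$n_realizations, "degree-preserving null realizations\n")
  cat("  dyad data/null ratios: ",
      paste(sprintf("%s %.2f", names(x$dyad_ratio), x$dyad_ratio),
            collapse = ", "), "\n", sep = "")
  nz <- x$triad_counts > 0 & !is.na(x$triad_ratio)
  cat("  triad ratios (nonzero classes): ",
      paste(sprintf("%s %.2f", names(x$triad_ratio)[nz], x$triad_ratio[nz]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Undirected graph of reciprocal edges: a directed k-clique (all k(k-1)
# ordered edges present) is exactly a clique of this graph.
reciprocal_graph <- function(A) {
  igraph::graph_from_adjacency_matrix((A & t(A)) * 1, mode = "undirected")
}

#' Enumerate directed cliques
#'
#' A clique of size k is a subnetwork in which all `k (k - 1)` ordered
#' connections are present (100% density); equivalently a clique of the
#' reciprocal-edge graph. Counts all cliques of every size `k >= 2` and the
#' proportion relative to the `choose(n, k)` possible subsets.
#'
#' @inheritParams graph_density
#' @param max_size Optional cap on the clique size searched.
#' @return Object of class `clique_report` with `clique_counts` (named by
#'   size), `clique_proportion`, `max_clique_size`.
#' @export
enumerate_cliques <- function(G, max_size = NULL) {
  A <- as_adjacency(G)
  n <- nrow(A)
  if (n < 2) stop("need at least 2 nodes")
  g <- reciprocal_graph(A)
  cl <- if (is.null(max_size)) igraph::cliques(g, min = 2)
        else igraph::cliques(g, min = 2, max = max_size)
  sizes <- lengths(cl)
  max_k <- if (length(sizes)) max(sizes) else 1L
  counts <- if (length(sizes)) tabulate(sizes, nbins = max_k)[-1] else integer()
  ks <- seq_len(max_k)[-1]
  names(counts) <- ks
  structure(list(clique_counts = counts,
                 clique_proportion = counts / choose(n, as.integer(ks)),
                 max_clique_size = max_k,
                 n = n),
            class = "clique_report")
}

#' @export
print.clique_report <- function(x, ...) {
  cat("Directed cliques on ", x$n, " areas: maximum size ",
      x$max_clique_size, "\n", sep = "")
  if (length(x$clique_counts))
    cat("  counts by size: ",
        paste(sprintf("%s:%d", names(x$clique_counts), x$clique_counts),
              collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Core-periphery partition from maximum cliques
#'
#' The core is the union of the member sets of all maximum-size cliques; the
#' rest is the periphery. Directed connection densities are reported within
#' the core, within the periphery, and between the two (both directions
#' pooled).
#'
#' @inheritParams graph_density
#' @return Object of class `core_report` with `core_members`,
#'   `periphery_members`, `max_clique_size`, `n_max_cliques`, and
#'   `densities` (core, periphery, between).
#' @export
extract_core <- function(G) {
  A <- as_adjacency(G)
  g <- reciprocal_graph(A)
  lc <- igraph::largest_cliques(g)
  core <- sort(unique(unlist(lapply(lc, function(v) names(v)))))
  if (is.null(core)) core <- character()
  peri <- setdiff(rownames(A), core)
  block_density <- function(rows, cols) {
    if (!length(rows) || !length(cols)) return(NA_real_)
    sub <- A[rows, cols, drop = FALSE]
    possible <- length(rows) * length(cols) -
      length(intersect(rows, cols))       # exclude diagonal cells
    if (possible == 0) return(NA_real_)
    sum(sub) / possible
  }
  between <- if (length(core) && length(peri))
    (sum(A[core, peri]) + sum(A[peri, core])) /
      (2 * length(core) * length(peri)) else NA_real_
  structure(list(core_members = core, periphery_members = peri,
                 max_clique_size = if (length(lc)) length(lc[[1]]) else 1L,
                 n_max_cliques = length(lc),
                 densities = c(core = block_density(core, core),
                               periphery = block_density(peri, peri),
                               between = between)),
            class = "core_report")
}

#' @export
print.core_report <- function(x, ...) {
  cat("Core-periphery partition: ", length(x$core_members), " core areas (",
      x$n_max_cliques, " maximum cliques of size ", x$max_clique_size,
      "), ", length(x$periphery_members), " periphery areas\n", sep = "")
  cat(sprintf("  densities: core %.2f%%, periphery %.2f%%, between %.2f%%\n",
              100 * x$densities["core"], 100 * x$densities["periphery"],
              100 * x$densities["between"]))
  invisible(x)
}

#' Similarity distance between connection profiles
#'
#' For every unordered pair of areas, 1 minus the cosine similarity of their
#' binary input profiles (`mode = "in"`, adjacency columns) or output
#' profiles (`mode = "out"`, rows), with the entries involving the two areas
#' themselves removed. Pairs for which either pruned profile is all-zero are
#' `NA`.
#'
#' @inheritParams graph_density
#' @param mode `"in"` or `"out"`.
#' @return Symmetric matrix in `[0, 1]` with zero diagonal.
#' @export
similarity_distance <- function(G, mode = c("in", "out")) {
  mode <- match.arg(mode)
  A <- as_adjacency(G)
  n <- nrow(A)
  if (n < 3) stop("need at least 3 nodes")
  P <- if (mode == "in") t(A) else A      # row i = profile of node i
  D <- matrix(0, n, n, dimnames = dimnames(A))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    keep <- setdiff(seq_len(n), c(i, j))
    u <- P[i, keep]; v <- P[j, keep]
    nu <- sqrt(sum(u)); nv <- sqrt(sum(v))
    D[i, j] <- D[j, i] <- if (nu == 0 || nv == 0) NA_real_ else
      1 - sum(u & v) / (nu * nv)
  }
  D
}

#' Connection probability versus similarity distance
#'
#' Bernoulli maximum-likelihood logistic fit of directed connection presence
#' on the similarity distance of the node pair,
#' `p(s) = plogis(alpha + beta s)`, on the unbinned data. Also returns the
#' implied reciprocal-pair curve `p(s)^2`, the unidirectional curve
#' `2 p(s) (1 - p(s))`, and binned empirical proportions.
#'
#' @inheritParams similarity_distance
#' @param distances Optional precomputed similarity-distance matrix.
#' @param bin_size Bin width for the empirical proportions (default 0.05).
#' @return Object of class `similarity_fit` with `mode`, `alpha`, `beta`,
#'   `separation` flag, `curve(s)` function, and `binned` data frame.
#' @export
fit_connection_probability <- function(G, mode = c("in", "out"),
                                       distances = NULL, bin_size = 0.05) {
  mode <- match.arg(mode)
  A <- as_adjacency(G)
  if (is.null(distances)) distances <- similarity_distance(A, mode)
  n <- nrow(A)
  s <- c(); y <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    d <- distances[i, j]
    if (!is.na(d)) { s <- c(s, d); y <- c(y, A[i, j]) }
  }
  if (length(s) < 10) stop("need at least 10 pairs with defined similarity")
  fit <- suppressWarnings(stats::glm(y ~ s, family = stats::binomial()))
  separation <- !fit$converged || any(abs(stats::coef(fit)) > 20)
  alpha <- unname(stats::coef(fit)[1]); beta <- unname(stats::coef(fit)[2])
  p <- function(x) stats::plogis(alpha + beta * x)
  bins <- floor(s / bin_size)
  binned <- do.call(rbind, lapply(sort(unique(bins)), function(b) {
    k <- bins == b
    data.frame(s_center = (b + 0.5) * bin_size,
               n = sum(k), p_connected = mean(y[k]))
  }))
  structure(list(mode = mode, alpha = alpha, beta = beta,
                 separation = separation, p = p,
                 p_reciprocal = function(x) p(x)^2,
                 p_unidirectional = function(x) 2 * p(x) * (1 - p(x)),
                 binned = binned, n_pairs = length(s)),
            class = "similarity_fit")
}

#' @export
print.similarity_fit <- function(x, ...) {
  cat("Logistic fit of connection probability vs ", x$mode,
      "-similarity distance (", x$n_pairs, " directed pairs)\n", sep = "")
  cat("  p(s) = plogis(", signif(x$alpha, 4), " + ", signif(x$beta, 4),
      " s)", if (x$separation) "  [possible separation]", "\n", sep = "")
  invisible(x)
}

#' @export
coef.similarity_fit <- function(object, ...) {
  c(alpha = object$alpha, beta = object$beta)
}
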