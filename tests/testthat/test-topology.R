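complete_digraph <- function(n) {
  A <- matrix(TRUE, n, n); diag(A) <- FALSE
  dimnames(A) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  A
}

test_that("density counts directed edges over ordered pairs", {
  expect_equal(graph_density(complete_digraph(5)), 1)
  A <- matrix(FALSE, 4, 4)
  A[cbind(c(1, 1, 2, 3, 4, 4), c(2, 3, 1, 4, 1, 2))] <- TRUE
  expect_equal(graph_density(A), 0.5)  # 6 of 12
})

test_that("degree sequences satisfy the handshake identity", {
  A <- random_digraph(25, 0.4, seed = 61)
  ds <- degree_sequences(A)
  expect_equal(sum(ds$k_in), sum(A))
  expect_equal(sum(ds$k_out), sum(A))
  expect_equal(unname(degree_sequences(complete_digraph(6))$k_in), rep(5, 6))
})

test_that("random-graph degree spread matches the binomial law", {
  A <- random_digraph(200, 0.5, seed = 62)
  ds <- degree_sequences(A)
  expect_equal(ds$fit_in[["sd"]], sqrt(200 * 0.5 * 0.5), tolerance = 0.1)
  expect_equal(ds$fit_out[["sd"]], sqrt(200 * 0.5 * 0.5), tolerance = 0.1)
})

test_that("dyad census classifies pairs as reciprocal/unidirectional/absent", {
  A <- matrix(FALSE, 3, 3)
  A[1, 2] <- A[2, 1] <- TRUE   # reciprocal
  A[1, 3] <- TRUE              # unidirectional
  expect_equal(dyad_census_fractions(A),
               c(reciprocal = 1/3, unidirectional = 1/3, absent = 1/3))
  expect_equal(dyad_census_fractions(complete_digraph(7)),
               c(reciprocal = 1, unidirectional = 0, absent = 0))
  for (seed in 1:3) {
    f <- dyad_census_fractions(random_digraph(12, 0.5, seed))
    expect_equal(sum(f), 1, tolerance = 1e-12)
  }
})

test_that("triad census matches exhaustive enumeration", {
  tc <- triad_census_counts(complete_digraph(3))
  expect_equal(unname(tc["300"]), 1)
  expect_equal(sum(tc), 1)
  empty5 <- matrix(FALSE, 5, 5)
  expect_equal(unname(triad_census_counts(empty5)["003"]), 10)

  # all 64 labeled digraphs on 3 nodes
  for (code in 0:63) {
    A <- matrix(FALSE, 3, 3)
    bits <- as.logical(bitwAnd(code, 2^(0:5)))
    A[cbind(c(1, 1, 2, 2, 3, 3), c(2, 3, 1, 3, 1, 2))] <- bits
    expect_equal(unname(triad_census_counts(A)), unname(oracle_triad_census(A)))
  }
  # random graphs up to 6 nodes
  for (n in 3:6) for (p in c(0.2, 0.5, 0.8)) {
    A <- random_digraph(n, p, seed = 100 * n + round(10 * p))
    tc <- triad_census_counts(A)
    expect_equal(unname(tc), unname(oracle_triad_census(A)))
    expect_equal(sum(tc), choose(n, 3))
  }
})

test_that("degree-preserving null keeps degree vectors exactly", {
  A <- random_digraph(10, 0.4, seed = 71)
  ens <- degree_preserving_null(A, 100, seed = 5)
  for (B in ens) {
    expect_equal(rowSums(B), rowSums(A))
    expect_equal(colSums(B), colSums(A))
    expect_false(any(diag(B)))
  }
  # reproducible by seed, and well-mixed
  ens2 <- degree_preserving_null(A, 100, seed = 5)
  expect_identical(ens, ens2)
  overlap <- mean(vapply(ens, function(B) sum(B & A) / sum(A), numeric(1)))
  expect_lt(overlap, 0.9)
})

test_that("motif ratios are unity against the graph itself", {
  A <- random_digraph(9, 0.5, seed = 81)
  rep1 <- motif_ratio(A, list(A))
  expect_equal(unname(rep1$dyad_ratio), rep(1, 3))
  nz <- rep1$triad_counts > 0
  expect_equal(unname(rep1$triad_ratio[nz]), rep(1, sum(nz)))
  expect_true(all(is.na(rep1$triad_ratio[!nz])))
})

test_that("spatially ruled graphs over-represent reciprocal and absent dyads", {
  gt <- synthetic_ground_truth(35, seed = 83)
  sim <- simulate_connectome(gt, replicates = 1)
  cm <- build_connectome(sim$injections, sources = gt$areas)
  A <- build_edge_complete(cm)$adjacency
  ens <- degree_preserving_null(A, 50, seed = 7)
  mr <- motif_ratio(A, ens)
  expect_gt(mr$dyad_ratio[["reciprocal"]], 1)
  expect_gt(mr$dyad_ratio[["absent"]], 1)
  expect_lt(mr$dyad_ratio[["unidirectional"]], 1)
})

test_that("clique counts match brute-force subset enumeration", {
  # fully reciprocal 5-clique: choose(5, 3) triangles
  expect_equal(unname(enumerate_cliques(complete_digraph(5))$clique_counts["3"]),
               choose(5, 3))
  # one unidirectional edge breaks the triangle
  A <- complete_digraph(3); A[2, 1] <- FALSE
  expect_equal(enumerate_cliques(A)$max_clique_size, 2)

  for (seed in 1:4) {
    A <- random_digraph(12, 0.6, seed = 200 + seed)
    got <- enumerate_cliques(A)$clique_counts
    want <- oracle_clique_counts(A)
    expect_equal(got[names(want)], want[names(want)])
  }
})

test_that("spatially ruled graphs hold more cliques than degree-matched nulls", {
  gt <- synthetic_ground_truth(30, seed = 85)
  sim <- simulate_connectome(gt, replicates = 1)
  A <- build_edge_complete(build_connectome(sim$injections,
                                            sources = gt$areas))$adjacency
  data_cl <- enumerate_cliques(A)
  ens <- degree_preserving_null(A, 20, seed = 3)
  null_max <- vapply(ens, function(B) enumerate_cliques(B)$max_clique_size,
                     numeric(1))
  # larger maximum clique than a typical degree-matched random graph
  expect_gte(data_cl$max_clique_size, max(null_max))
  k <- as.character(max(null_max))
  null_k <- vapply(ens, function(B) {
    cc <- enumerate_cliques(B)$clique_counts
    if (k %in% names(cc)) cc[[k]] else 0
  }, numeric(1))
  expect_gt(data_cl$clique_counts[[k]], mean(null_k))
})

test_that("core is the union of maximum cliques with block densities", {
  core1 <- extract_core(complete_digraph(6))
  expect_equal(length(core1$core_members), 6)
  expect_equal(core1$densities[["core"]], 1)
  expect_equal(length(core1$periphery_members), 0)

  # two disjoint reciprocal triangles: core = all six members
  A <- matrix(FALSE, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  for (s in list(1:3, 4:6))
    for (i in s) for (j in s) if (i != j) A[i, j] <- TRUE
  core2 <- extract_core(A)
  expect_equal(sort(core2$core_members), letters[1:6])
  expect_equal(core2$n_max_cliques, 2)
  expect_equal(core2$max_clique_size, 3)

  # planted core: dense reciprocal block + sparse periphery
  set.seed(91)
  B <- random_digraph(14, 0.15, seed = 92)
  B[1:6, 1:6] <- TRUE; diag(B) <- FALSE
  core3 <- extract_core(B)
  expect_true(all(rownames(B)[1:6] %in% core3$core_members))
  expect_gt(core3$densities[["core"]], core3$densities[["periphery"]])
})

test_that("similarity distance equals a direct cosine computation", {
  A <- matrix(FALSE, 4, 4)
  A[3, 1] <- A[4, 1] <- TRUE; A[3, 2] <- A[4, 2] <- TRUE
  # nodes 1 and 2 have identical in-profiles
  D <- similarity_distance(A, "in")
  expect_equal(D[1, 2], 0)
  # orthogonal out-profiles
  B <- matrix(FALSE, 4, 4)
  B[1, 3] <- TRUE; B[2, 4] <- TRUE
  expect_equal(similarity_distance(B, "out")[1, 2], 1)

  for (seed in 1:3) {
    G <- random_digraph(8, 0.5, seed = 300 + seed)
    for (mode in c("in", "out")) {
      D <- similarity_distance(G, mode)
      P <- if (mode == "in") t(G) else G
      for (pair in list(c(1, 5), c(2, 7), c(3, 8))) {
        i <- pair[1]; j <- pair[2]
        keep <- setdiff(1:8, pair)
        want <- oracle_cosine_distance(P[i, keep], P[j, keep])
        expect_equal(D[i, j], want)
      }
      expect_true(isSymmetric(unname(D)))
    }
  }
})

test_that("logistic connection-probability fit recovers known coefficients", {
  set.seed(110)
  n <- 101  # ~1e4 directed pairs
  S <- matrix(0, n, n)
  S[upper.tri(S)] <- runif(n * (n - 1) / 2)
  S <- S + t(S)
  A <- matrix(FALSE, n, n)
  off <- row(A) != col(A)
  A[off] <- rbinom(sum(off), 1, plogis(2 - 5 * S[off])) == 1
  fit <- fit_connection_probability(A, distances = S)
  expect_equal(fit$alpha, 2, tolerance = 0.2)   # within 10% of the truth
  expect_equal(fit$beta, -5, tolerance = 0.5)

  G <- random_digraph(40, 0.5, seed = 111)
  sf <- fit_connection_probability(G, mode = "out")
  expect_true(is.finite(sf$alpha) && is.finite(sf$beta))
  ss <- seq(0, 1, by = 0.05)
  expect_true(all(sf$p_reciprocal(ss) <= sf$p(ss) + 1e-12))
  expect_true(all(sf$p(ss) >= 0 & sf$p(ss) <= 1))
})

test_that("dense graphs yield near-unity connection probability", {
  A <- complete_digraph(12)
  A[1, 2] <- FALSE  # leave one hole so the response is not constant
  sf <- suppressWarnings(fit_connection_probability(A, mode = "out"))
  ss <- seq(0, 0.2, by = 0.05)
  expect_true(all(sf$p(ss) > 0.9))
})
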