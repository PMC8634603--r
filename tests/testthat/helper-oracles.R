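# Independent brute-force oracles used to validate the implementation.
# Everything here is written from first principles and shares no code with
# the package internals it checks.

# --- directed triad classification by canonical form ----------------------

# 6-bit code of a labeled 3-node digraph: bits for the ordered pairs
# (1,2),(1,3),(2,1),(2,3),(3,1),(3,2)
triple_code <- function(A3) {
  bits <- c(A3[1, 2], A3[1, 3], A3[2, 1], A3[2, 3], A3[3, 1], A3[3, 2])
  sum(bits * 2^(0:5))
}

# canonical code = minimum over all 6 vertex permutations
canonical_triple_code <- function(A3) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  min(vapply(perms, function(p) triple_code(A3[p, p]), numeric(1)))
}

# canonical codes of the standard 16 triad classes, built from hand-written
# representatives in Davis-Leinhardt order
triad_oracle_codes <- local({
  reps <- list(
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
  vapply(reps, function(e) {
    A <- matrix(FALSE, 3, 3)
    if (nrow(e)) A[e] <- TRUE
    canonical_triple_code(A)
  }, numeric(1))
})

# full triad census by exhaustive enumeration of node triples
oracle_triad_census <- function(A) {
  A <- A > 0; diag(A) <- FALSE
  n <- nrow(A)
  counts <- setNames(numeric(16), names(triad_oracle_codes))
  if (n < 3) return(counts)
  for (trip in utils::combn(n, 3, simplify = FALSE)) {
    code <- canonical_triple_code(A[trip, trip])
    cls <- names(triad_oracle_codes)[triad_oracle_codes == code]
    counts[cls] <- counts[cls] + 1
  }
  counts
}

# --- clique counting by subset enumeration --------------------------------

# counts of node subsets of each size k >= 2 with all ordered edges present
oracle_clique_counts <- function(A, max_k = nrow(A)) {
  A <- A > 0; diag(A) <- FALSE
  n <- nrow(A)
  R <- A & t(A)
  counts <- integer(0)
  for (k in 2:max_k) {
    ck <- 0
    for (s in utils::combn(n, k, simplify = FALSE)) {
      sub <- R[s, s]
      if (all(sub[upper.tri(sub)])) ck <- ck + 1
    }
    counts[as.character(k)] <- ck
    if (ck == 0) break
  }
  counts[counts > 0]
}

# --- misc -----------------------------------------------------------------

oracle_cosine_distance <- function(u, v) {
  1 - sum(u * v) / sqrt(sum(u^2) * sum(v^2))
}

random_digraph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(runif(n^2) < p, n, n)
  diag(A) <- FALSE
  dimnames(A) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  A
}

sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}

# small helper to build an injection record from a named count matrix
make_injection <- function(id, target, sources, supra, infra, ...) {
  injection_record(id, target,
                   data.frame(source_area = sources, supra_count = supra,
                              infra_count = infra, stringsAsFactors = FALSE),
                   ...)
}

# logit-link SLN observations from a known hierarchy with beta noise
make_recovery_obs <- function(n_areas, phi, reps, seed) {
  set.seed(seed)
  h <- runif(n_areas)
  areas <- sprintf("A%02d", seq_len(n_areas))
  names(h) <- areas
  obs <- do.call(rbind, lapply(seq_len(reps), function(r) {
    pairs <- expand.grid(target = areas, source = areas,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$target != pairs$source, ]
    mu <- plogis(h[pairs$target] - h[pairs$source])
    pairs$sln <- rbeta(nrow(pairs), mu * phi, (1 - mu) * phi)
    pairs
  }))
  list(h = h, obs = obs)
}
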