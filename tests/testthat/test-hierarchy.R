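two_area_obs <- function(sln_xy, sln_yx) {
  data.frame(target = c("X", "Y"), source = c("Y", "X"),
             sln = c(sln_xy, sln_yx))
}

test_that("symmetric laminar fractions imply equal hierarchy indices", {
  for (m in c("beta", "linear")) {
    fit <- fit_hierarchy(two_area_obs(0.5, 0.5), method = m)
    expect_equal(unname(diff(fit$h_raw)), 0, tolerance = 1e-4)
  }
})

test_that("a two-area asymmetry inverts the logit link", {
  fit <- fit_hierarchy(two_area_obs(0.73, 0.27), method = "beta")
  expect_equal(fit$h_raw[["X"]] - fit$h_raw[["Y"]], qlogis(0.73),
               tolerance = 0.05)
  lin <- fit_hierarchy(two_area_obs(0.73, 0.27), method = "linear")
  expect_equal(lin$h_raw[["X"]] - lin$h_raw[["Y"]], qlogis(0.73),
               tolerance = 1e-8)
})

test_that("beta regression recovers a known hierarchy", {
  sim <- make_recovery_obs(30, phi = 20, reps = 3, seed = 401)
  fit <- fit_hierarchy(sim$obs, method = "beta")
  expect_gte(cor(sim$h, fit$h[names(sim$h)], method = "spearman"), 0.95)
  expect_gt(fit$phi, 5)            # precision estimated, near truth
  expect_lt(fit$phi, 80)
  expect_gt(fit$pred_obs_correlation, 0.3)
  expect_true(all(fit$h >= 0 & fit$h <= 1))
})

test_that("linear and beta fits agree in rank on logit-link data", {
  sim <- make_recovery_obs(20, phi = 30, reps = 2, seed = 402)
  fb <- fit_hierarchy(sim$obs, method = "beta")
  fl <- fit_hierarchy(sim$obs, method = "linear")
  expect_gte(cor(fb$h, fl$h[names(fb$h)], method = "spearman"), 0.95)
})

test_that("direction conventions act on the fit as expected", {
  sim <- make_recovery_obs(12, phi = 25, reps = 2, seed = 403)
  fwd <- fit_hierarchy(sim$obs, method = "beta")

  # swapping the roles of target and source negates every index difference
  swapped <- data.frame(target = sim$obs$source, source = sim$obs$target,
                        sln = sim$obs$sln)
  bwd <- fit_hierarchy(swapped, method = "beta")
  expect_equal(cor(fwd$h, bwd$h[names(fwd$h)], method = "spearman"), -1)

  # swapping roles AND complementing SLN describes the same data, so the
  # fitted ordering is unchanged
  both <- data.frame(target = sim$obs$source, source = sim$obs$target,
                     sln = 1 - sim$obs$sln)
  same <- fit_hierarchy(both, method = "beta")
  expect_equal(cor(fwd$h, same$h[names(fwd$h)], method = "spearman"), 1)
})

test_that("anchor choice only re-gauges the indices", {
  sim <- make_recovery_obs(10, phi = 25, reps = 2, seed = 404)
  f1 <- fit_hierarchy(sim$obs, method = "linear", anchor = "A01")
  f2 <- fit_hierarchy(sim$obs, method = "linear", anchor = "A07")
  # raw indices shift by a constant; normalized indices coincide
  shifts <- f1$h_raw - f2$h_raw[names(f1$h_raw)]
  expect_lt(diff(range(shifts)), 1e-8)
  expect_equal(f1$h, f2$h[names(f1$h)], tolerance = 1e-8)
})

test_that("per-injection observations flow from records into the fit", {
  gt <- synthetic_ground_truth(25, kappa = 20, seed = 405)
  sim <- simulate_connectome(gt, replicates = 3)
  obs <- sln_observations(sim$injections)
  expect_true(all(c("target", "source", "sln", "weight") %in% names(obs)))
  expect_true(all(obs$sln >= 0 & obs$sln <= 1))
  fit <- fit_hierarchy(obs, method = "beta")
  expect_gte(cor(gt$h_true, fit$h[names(gt$h_true)], method = "spearman"),
             0.9)
  # prediction interface
  pred <- predict(fit, data.frame(target = "A001", source = "A002"))
  expect_equal(unname(pred),
               plogis(fit$h_raw[["A001"]] - fit$h_raw[["A002"]]))
})

test_that("projections classify by the 0.5 laminar boundary", {
  expect_equal(classify_projections(c(0.75, 0.27, 0.5, NA)),
               c("FF", "FB", "unclassified", NA))
})

test_that("disconnected observation graphs are flagged", {
  obs <- rbind(two_area_obs(0.6, 0.4),
               data.frame(target = c("P", "Q"), source = c("Q", "P"),
                          sln = c(0.7, 0.3)))
  expect_warning(fit_hierarchy(obs, method = "linear"), "disconnected")
})

test_that("degenerate flat SLN data are flagged", {
  obs <- data.frame(target = c("X", "Y", "Z"), source = c("Y", "Z", "X"),
                    sln = c(0.5, 0.5, 0.5))
  fit <- fit_hierarchy(obs, method = "linear")
  expect_true(fit$degenerate || diff(range(fit$h_raw)) < 1e-6)
})

test_that("circular embedding maps hierarchy to radius", {
  h <- c(A = 1, B = 0.5, C = 0)
  F <- matrix(0.01, 3, 3, dimnames = list(names(h), names(h)))
  diag(F) <- 0
  emb <- circular_embedding(h, F, n_restarts = 10, seed = 2)
  expect_equal(unname(emb$R), sqrt(1 - unname(h)))
  expect_equal(emb$theta[["A"]], 0)  # anchor
})

test_that("equal-weight triangle embeds at 120-degree spacing", {
  h <- c(A = 0.2, B = 0.5, C = 0.8)
  F <- matrix(10^-2, 3, 3, dimnames = list(names(h), names(h)))
  diag(F) <- 0
  emb <- circular_embedding(h, F, n_restarts = 20, seed = 3)
  th <- sort(emb$theta %% (2 * pi))
  gaps <- diff(c(th, th[1] + 2 * pi))
  expect_equal(unname(gaps), rep(2 * pi / 3, 3), tolerance = 0.02)

  # brute-force 1-degree grid oracle over the two free angles
  wgt <- 2  # -log10 of every weight
  circ <- function(a, b) { d <- abs(a - b) %% (2 * pi); pmin(d, 2 * pi - d) }
  obj <- function(t2, t3) {
    cd <- c(circ(0, t2), circ(0, t3), circ(t2, t3))
    cd <- rep(cd, 2)                       # both directions
    r <- if (sum(cd^2) > 0) sum(wgt * cd) / sum(cd^2) else 0
    sum((wgt - r * cd)^2)
  }
  grid <- seq(0, 2 * pi, by = pi / 180)
  best <- Inf
  for (t2 in grid) {
    vals <- vapply(grid, function(t3) obj(t2, t3), numeric(1))
    best <- min(best, min(vals))
  }
  expect_lte(emb$objective_value, best * 1.01 + 1e-9)
})

test_that("embedding separates strong from weak connections angularly", {
  # two tight pairs weakly coupled to each other
  areas <- c("A", "B", "C", "D")
  F <- matrix(1e-4, 4, 4, dimnames = list(areas, areas))
  F["A", "B"] <- F["B", "A"] <- 0.3
  F["C", "D"] <- F["D", "C"] <- 0.3
  diag(F) <- 0
  h <- c(A = 0.1, B = 0.3, C = 0.6, D = 0.9)
  emb <- circular_embedding(h, F, n_restarts = 30, seed = 6)
  circ <- function(a, b) { d <- abs(a - b) %% (2 * pi); min(d, 2 * pi - d) }
  th <- emb$theta
  expect_lt(circ(th[["A"]], th[["B"]]), circ(th[["A"]], th[["C"]]))
  expect_lt(circ(th[["C"]], th[["D"]]), circ(th[["B"]], th[["D"]]))
})
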