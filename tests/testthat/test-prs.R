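test_that("covariance of a frozen ensemble is zero and needs >= 2 frames", {
  topo <- make_structure(memallo:::default_mean_coords(6), resids = 1:6)
  frames <- replicate(5, topo$coords, simplify = FALSE)
  tr <- new_trajectory(topo, frames)
  C <- compute_covariance(tr, align = FALSE)
  expect_equal(max(abs(C$matrix)), 0)
  C2 <- compute_covariance(tr, align = TRUE)
  expect_lt(max(abs(C2$matrix)), 1e-12)
  tr1 <- new_trajectory(topo, frames[1])
  expect_error(compute_covariance(tr1), "insufficient")
})

test_that("two-frame single-node displacement gives variance d^2/4", {
  topo <- make_structure(memallo:::default_mean_coords(5), resids = 1:5)
  f1 <- topo$coords
  f2 <- topo$coords
  d <- 2.4
  f2[3, 1] <- f2[3, 1] + d
  tr <- new_trajectory(topo, list(f1, f2))
  C <- compute_covariance(tr, align = FALSE)
  expect_equal(C$matrix[7, 7], d^2 / 4)        # node 3, x coordinate
  others <- C$matrix; others[7, 7] <- 0
  expect_equal(max(abs(others)), 0)
})

test_that("linear response is the covariance-force product", {
  Ci <- as_covariance(diag(1, 12))
  dr <- linear_response(Ci, 2, c(1, 0, 0))
  expect_equal(as.numeric(dr), c(0, 0, 0, 1, 0, 0, rep(0, 6)))
  # doubling C doubles the response but not the overlap
  C2 <- as_covariance(diag(2, 12))
  dr2 <- linear_response(C2, 2, c(1, 0, 0))
  expect_equal(as.numeric(dr2), 2 * as.numeric(dr))
  dS <- rnorm(12)
  expect_equal(overlap(dr, dS), overlap(dr2, dS))
  expect_error(linear_response(Ci, 5, c(1, 0, 0)), "out of range")

  # spiked covariance response verified against the dense matvec oracle
  u <- spike_vector(4, 2, c(0, 1, 0))
  Cs <- as_covariance(diag(0.01, 12) + 0.5 * tcrossprod(u))
  f <- c(0.3, -0.4, 0.86)
  dr3 <- linear_response(Cs, 3, f, magnitude = 2)
  Fv <- numeric(12); Fv[7:9] <- 2 * f / sqrt(sum(f^2))
  expect_equal(as.numeric(dr3), as.numeric(Cs$matrix %*% Fv),
               tolerance = 1e-12)
})

test_that("overlap is the absolute cosine with documented edge cases", {
  a <- c(1, 2, 3, 4, 5, 6)
  expect_equal(overlap(a, a), 1)
  expect_equal(overlap(a, -a), 1)
  b <- c(-2, 1, 0, 0, 0, 0)
  expect_equal(overlap(a, b), abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))
  perp <- c(2, -1, 0, 0, 0, 0)
  expect_equal(overlap(perp, a), 0, tolerance = 1e-12)
  expect_equal(overlap(numeric(6), a), 0)
  expect_error(overlap(a, numeric(6)), "zero norm")
  expect_error(overlap(a, c(1, 2)), "different node sets")
})

test_that("overlap is invariant under positive rescaling of C, target and force", {
  C <- random_psd_covariance(5, seed = 17)
  memallo:::with_seed(18, {
    dS <- rnorm(15)
    for (i in 1:5) {
      a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10); cc <- runif(1, 0.1, 10)
      dir <- rnorm(3)
      o1 <- overlap(linear_response(C, 2, dir, 1), dS)
      Ca <- as_covariance(a * C$matrix)
      o2 <- overlap(linear_response(Ca, 2, dir, cc), b * dS)
      expect_equal(o1, o2, tolerance = 1e-12)
    }
  })
})

test_that("analytic best force matches hand algebra for identity covariance", {
  C <- as_covariance(diag(1, 15))
  memallo:::with_seed(19, {
    dS <- rnorm(15)
    for (node in c(1, 3, 5)) {
      ab <- analytic_best_force(C, node, dS)
      blk <- (3 * node - 2):(3 * node)
      expect_equal(ab$direction, dS[blk] / sqrt(sum(dS[blk]^2)),
                   tolerance = 1e-9)
      expect_equal(ab$overlap, sqrt(sum(dS[blk]^2)) / sqrt(sum(dS^2)),
                   tolerance = 1e-9)
    }
  })
})

test_that("analytic best force dominates dense Monte-Carlo direction search", {
  memallo:::with_seed(23, {
    for (trial in 1:3) {
      C <- as_covariance(crossprod(matrix(rnorm(18 * 18), 18)) / 18)
      dS <- rnorm(18)
      for (node in 1:6) {
        ab <- analytic_best_force(C, node, dS)
        dirs <- memallo:::random_unit_vectors(100000)
        blk <- (3 * node - 2):(3 * node)
        Rsp <- C$matrix[, blk] %*% dirs
        ov <- abs(as.numeric(crossprod(Rsp, dS))) /
          (sqrt(colSums(Rsp^2)) * sqrt(sum(dS^2)))
        expect_gte(ab$overlap, max(ov) - 1e-12)
        expect_lt(ab$overlap - max(ov), 1e-3)
      }
    }
  })
})

test_that("spiked covariance focuses the optimal response on the planted node", {
  u <- spike_vector(8, 4)
  C <- as_covariance(diag(0.001, 24) + 1 * tcrossprod(u))  # lambda/sigma2 = 1000
  ab <- analytic_best_force(C, 4, u)
  expect_gt(ab$overlap, 0.999)
  # a node with no route to the target is degenerate
  dS_far <- spike_vector(8, 4, c(0, 0, 1))
  C0 <- as_covariance(diag(c(rep(1, 3), rep(0, 21))))
  ab0 <- analytic_best_force(C0, 6, c(rep(0, 3), rnorm(21)))
  expect_equal(ab0$overlap, 0)
  expect_true(ab0$degenerate)
})

test_that("random scan approaches the analytic optimum and never exceeds it", {
  C <- random_psd_covariance(6, seed = 29)
  memallo:::with_seed(30, dS <- rnorm(18))
  prof <- prs_scan(C, dS, n_directions = 2000, n_repeats = 5, seed = 31)
  expect_equal(attr(prof, "n_directions_sampled"), 10000)
  gaps <- vapply(1:6, function(i)
    analytic_best_force(C, i, dS)$overlap - prof$best_overlap[i], numeric(1))
  expect_true(all(gaps >= -1e-12))
  expect_lt(stats::median(gaps), 0.01)
  expect_true(all(prof$best_overlap >= 0 & prof$best_overlap <= 1))
  # reported best direction reproduces the reported overlap
  i <- which.max(prof$best_overlap)
  dr <- linear_response(C, i, c(prof$fx[i], prof$fy[i], prof$fz[i]))
  expect_equal(overlap(dr, dS), prof$best_overlap[i], tolerance = 1e-9)
})

test_that("scan is reproducible under a fixed seed and monotone in sampling", {
  C <- random_psd_covariance(4, seed = 41)
  memallo:::with_seed(42, dS <- rnorm(12))
  p1 <- prs_scan(C, dS, 500, 2, seed = 7)
  p2 <- prs_scan(C, dS, 500, 2, seed = 7)
  expect_identical(p1$best_overlap, p2$best_overlap)
  # more repeats with the same stream prefix can only improve the best
  p3 <- prs_scan(C, dS, 500, 4, seed = 7)
  expect_true(all(p3$best_overlap >= p1$best_overlap - 1e-12))
})

test_that("planted-residue recovery works end to end from sampled frames", {
  u <- spike_vector(10, 7)
  spec <- gaussian_ensemble_spec(10, cov_spiked(0.01, 1, u), 10000, seed = 51)
  g <- generate_gaussian_ensemble(spec)
  C <- compute_covariance(g$trajectory, align = FALSE)
  prof <- prs_scan(C, u, n_directions = 500, n_repeats = 2, seed = 52)
  expect_equal(prof$resid[which.max(prof$best_overlap)], 7L)
  hot <- rank_hotspots(prof, 0.6)
  expect_equal(hot$resid[1], 7L)
})

test_that("hotspot ranking applies threshold and tie rules deterministically", {
  prof <- data.frame(chain = "A", resid = c(10L, 4L, 7L, 2L),
                     best_overlap = c(0.55, 0.80, 0.80, 0.60),
                     fx = 1, fy = 0, fz = 0)
  class(prof) <- c("OverlapProfile", "data.frame")
  attr(prof, "threshold") <- 0.6
  hot <- rank_hotspots(prof)
  expect_equal(hot$resid, c(4L, 7L, 2L))      # ties: lower resid first
  expect_equal(hot$best_overlap, c(0.80, 0.80, 0.60))  # 0.6 inclusive
  none <- rank_hotspots(prof, threshold = 0.9)
  expect_equal(nrow(none), 0L)
})

test_that("target displacement handles rigid motion and correspondence", {
  init <- make_structure(memallo:::default_mean_coords(5), resids = 1:5)
  expect_error(overlap(rnorm(15),
                       target_displacement(init, init, superpose = FALSE)),
               "zero norm")
  a <- 35 * pi / 180
  R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  rot <- make_structure(sweep(init$coords %*% t(R), 2, c(3, -2, 7), "+"),
                        resids = 1:5)
  expect_lt(max(abs(target_displacement(init, rot))), 1e-9)
  # single-node translation with superposition disabled: exact 2 A entry
  tgt <- init
  tgt$coords[2, 3] <- tgt$coords[2, 3] + 2
  d <- target_displacement(init, tgt, superpose = FALSE)
  expect_equal(as.numeric(d), c(0, 0, 0, 0, 0, 2, rep(0, 9)))
  short <- make_structure(matrix(rnorm(12), 4, 3), resids = 1:4)
  expect_error(target_displacement(init, short), "correspondence")
})

test_that("converged-interval start frame is the longest stable suffix", {
  topo <- make_structure(memallo:::default_mean_coords(6), resids = 1:6)
  drift <- topo$coords
  # early frames are internally deformed (one node pulled out), later
  # frames fluctuate mildly around the final conformation
  bend <- function(d) { x <- drift; x[1, ] <- x[1, ] + c(d, 0, 0); x }
  set.seed(99)
  frames <- list(bend(6), bend(4),
                 drift + matrix(rnorm(18, sd = 0.05), 6, 3),
                 drift + matrix(rnorm(18, sd = 0.05), 6, 3),
                 drift)
  tr <- new_trajectory(topo, frames)
  expect_equal(converged_start(tr, rmsd_bound = 1), 3L)
})
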