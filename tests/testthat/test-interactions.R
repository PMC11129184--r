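test_that("hydrogen-bond detector classifies constructive fixtures", {
  don <- "resname SER and name OG"
  acc <- "resname CHL1 and name O3"
  # comfortably inside both cutoffs
  expect_equal(nrow(hbond_contacts(hbond_fixture(2.9, 165), don, acc)), 1L)
  # boundary-inclusive on both distance and angle
  expect_equal(nrow(hbond_contacts(hbond_fixture(3.5, 180), don, acc)), 1L)
  expect_equal(nrow(hbond_contacts(hbond_fixture(2.9, 130), don, acc)), 1L)
  # rejected by angle, rejected by distance
  expect_equal(nrow(hbond_contacts(hbond_fixture(2.9, 100), don, acc)), 0L)
  expect_equal(nrow(hbond_contacts(hbond_fixture(4.0, 180), don, acc)), 0L)
  # reported geometry matches the constructed one
  hb <- hbond_contacts(hbond_fixture(3.2, 150), don, acc)
  expect_equal(hb$distance, 3.2, tolerance = 1e-9)
  expect_equal(hb$angle, 150, tolerance = 1e-6)
  expect_equal(hb$donor_name, "OG")
  expect_equal(hb$acceptor_resid, 400L)
  # donors without hydrogens are skipped with a warning
  s <- hbond_fixture(2.9, 165)
  expect_warning(
    out <- hbond_contacts(s, "resname CHL1 and name O3",
                          "resname SER and name OG"),
    "no resolvable")
  expect_equal(nrow(out), 0L)
})

test_that("hydrophobic detector applies the inclusive cutoff per residue pair", {
  two_carbons <- function(d) {
    make_structure(rbind(c(0, 0, 0), c(d, 0, 0)),
                   chains = c("A", "L"), resids = c(1, 9),
                   names = c("CD1", "C20"), resnames = c("LEU", "CHL1"),
                   elements = c("C", "C"))
  }
  expect_equal(nrow(hydrophobic_contacts(two_carbons(4.0), "chain A",
                                         "chain L")), 1L)
  expect_equal(nrow(hydrophobic_contacts(two_carbons(4.5), "chain A",
                                         "chain L")), 1L)
  expect_equal(nrow(hydrophobic_contacts(two_carbons(4.6), "chain A",
                                         "chain L")), 0L)
  # non-carbon atoms are excluded from the hydrophobic class
  s <- make_structure(rbind(c(0, 0, 0), c(3, 0, 0)),
                      chains = c("A", "L"), resids = c(1, 9),
                      names = c("OG", "C20"), resnames = c("SER", "CHL1"),
                      elements = c("O", "C"))
  expect_equal(nrow(hydrophobic_contacts(s, "chain A", "chain L")), 0L)
})

test_that("toy cholesterol beside a leucine matches the all-pairs oracle", {
  # leucine-like side chain carbons + small sterol fragment at 4.2 A closest
  leu <- cbind(c(0, 1.4, 2.1, 2.1), c(0, 0.6, -0.6, 1.6), c(0, 0, 0, 0))
  chl <- cbind(c(0, 1.2), c(0, 0.8), c(4.2, 5.0))
  s <- make_structure(rbind(leu, chl),
                      chains = c(rep("A", 4), "L", "L"),
                      resids = c(rep(305L, 4), 400L, 400L),
                      names = c("CB", "CG", "CD1", "CD2", "C20", "C21"),
                      resnames = c(rep("LEU", 4), "CHL1", "CHL1"),
                      elements = "C")
  got <- hydrophobic_contacts(s, "chain A", "chain L", d_max = 4.5)
  expect_equal(nrow(got), 1L)
  # brute-force all-pairs oracle
  D <- as.matrix(stats::dist(rbind(leu, chl)))[1:4, 5:6]
  expect_equal(got$min_distance, min(D))
  expect_equal(min(D) <= 4.5, TRUE)
})

test_that("fingerprint frequencies equal a per-frame recount", {
  # persistent H-bond geometry: frequency 1.0 in the donor class
  s <- hbond_fixture(2.9, 165)
  frames <- replicate(6, s$coords, simplify = FALSE)
  tr <- new_trajectory(new_structure(s$atoms, s$coords), frames)
  fp <- fingerprint(tr, "resname CHL1", "resname SER")
  expect_equal(fp$hbond_donor[fp$resid == 283], 1)

  # ligand moved far away for half the frames: frequency 0.5
  far <- s$coords
  far[3:4, ] <- far[3:4, ] + 50
  tr2 <- new_trajectory(new_structure(s$atoms, s$coords),
                        c(replicate(3, s$coords, simplify = FALSE),
                          replicate(3, far, simplify = FALSE)))
  fp2 <- fingerprint(tr2, "resname CHL1", "resname SER")
  expect_equal(fp2$hbond_donor[fp2$resid == 283], 0.5)

  # alternating bound/unbound: exact agreement with a manual recount
  alt <- lapply(1:7, function(f) if (f %% 2 == 1) s$coords else far)
  tr3 <- new_trajectory(new_structure(s$atoms, s$coords), alt)
  fp3 <- fingerprint(tr3, "resname CHL1", "resname SER")
  manual <- mean(vapply(1:7, function(f) {
    fr <- get_frame(tr3, f)
    nrow(hbond_contacts(fr, "resname SER and name OG",
                        "resname CHL1 and name O3")) > 0
  }, logical(1)))
  expect_equal(fp3$hbond_donor[fp3$resid == 283], manual)
  expect_error(fingerprint(tr3, "resname XXX", "resname SER"),
               "empty ligand")
})

test_that("replica fingerprints pool by frame weighting", {
  s <- hbond_fixture(2.9, 165)
  far <- s$coords; far[3:4, ] <- far[3:4, ] + 50
  topo <- new_structure(s$atoms, s$coords)
  r1 <- new_trajectory(topo, replicate(4, s$coords, simplify = FALSE))  # 1.0
  r2 <- new_trajectory(topo, replicate(12, far, simplify = FALSE))     # 0.0
  fp <- fingerprint(list(r1, r2), "resname CHL1", "resname SER")
  expect_equal(fp$hbond_donor[fp$resid == 283], 4 / 16)
  expect_length(attr(fp, "replicas"), 2L)
})

test_that("pair distance series reports mean, population SD and minimum image", {
  topo <- make_structure(rbind(c(0, 0, 0), c(5, 0, 0)),
                         chains = c("A", "L"), resids = c(283L, 400L),
                         names = c("HG1", "O3"), resnames = c("SER", "CHL1"),
                         elements = c("H", "O"))
  frames <- replicate(4, topo$coords, simplify = FALSE)
  tr <- new_trajectory(topo, frames)
  ds <- pair_distance_series(tr, "name HG1", "name O3")
  expect_equal(ds$mean, 5)
  expect_equal(ds$sd, 0)

  # stepping 3,4,5: mean 4, population SD sqrt(2/3)
  frames2 <- lapply(c(3, 4, 5), function(d) rbind(c(0, 0, 0), c(d, 0, 0)))
  tr2 <- new_trajectory(topo, frames2)
  ds2 <- pair_distance_series(tr2, "name HG1", "name O3")
  expect_equal(ds2$mean, 4)
  expect_equal(ds2$sd, sqrt(2 / 3))
  # symmetry in the arguments
  ds2b <- pair_distance_series(tr2, "name O3", "name HG1")
  expect_equal(ds2b$series, ds2$series)

  # periodic box: x = 1 vs x = 9 in a 10 A box is 2 A apart
  frames3 <- list(rbind(c(1, 0, 0), c(9, 0, 0)))
  tr3 <- new_trajectory(topo, frames3, box = c(10, 10, 10))
  expect_equal(pair_distance_series(tr3, "name HG1", "name O3")$mean, 2)
  expect_error(pair_distance_series(tr3, "name XX", "name O3"),
               "lookup failed")
})

test_that("multi-copy distance series pairs copies and pools stats", {
  # five ligand copies at distances 2..6 from their subunit reference atoms
  n <- 5
  prot <- data.frame(atom_name = "HG1", element = "H", resid = 283L,
                     resname = "SER", chain = LETTERS[1:n],
                     stringsAsFactors = FALSE)
  lig <- data.frame(atom_name = "O3", element = "O", resid = 400L,
                    resname = "CHL1", chain = LETTERS[1:n],
                    stringsAsFactors = FALSE)
  coords <- rbind(cbind(0, (1:n) * 100, 0),
                  cbind(2:6, (1:n) * 100, 0))
  topo <- new_structure(rbind(prot, lig), coords)
  tr <- new_trajectory(topo, list(coords, coords))
  ds <- pair_distance_series(tr, "name HG1", "name O3")
  expect_equal(ds$per_copy$mean, c(2, 3, 4, 5, 6))
  expect_equal(ds$mean, 4)
  expect_equal(dim(ds$series), c(2L, 5L))
})

test_that("RMSD series vanishes on rigid motion and matches the Gaussian law", {
  topo <- make_structure(memallo:::default_mean_coords(8), resids = 1:8)
  a <- 25 * pi / 180
  R <- matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3,
              byrow = TRUE)
  frames <- list(topo$coords,
                 sweep(topo$coords %*% t(R), 2, c(1, 2, 3), "+"))
  tr <- new_trajectory(topo, frames)
  r <- rmsd_series(tr, "name CA", get_frame(tr, 1))
  expect_lt(max(r), 1e-9)

  # isotropic Gaussian ensemble: mean RMSD ~ sqrt(sigma2 * (3N - 6) / N)
  N <- 20
  spec <- gaussian_ensemble_spec(N, cov_isotropic(0.01), 400, seed = 81)
  g <- generate_gaussian_ensemble(spec)
  ref <- new_structure(g$trajectory$topology$atoms, spec$mean_coords)
  r2 <- rmsd_series(g$trajectory, "name CA", ref)
  expect_lt(abs(mean(r2) - sqrt(0.01 * (3 * N - 6) / N)) /
              sqrt(0.01 * (3 * N - 6) / N), 0.10)
  expect_error(rmsd_series(tr, "name CA",
                           make_structure(matrix(rnorm(9), 3, 3))),
               "correspondence")
})

test_that("detectors are invariant under a global rigid transform", {
  s <- hbond_fixture(3.2, 150)
  a <- 77 * pi / 180
  R <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  s2 <- new_structure(s$atoms, sweep(s$coords %*% t(R), 2, c(7, -3, 2), "+"))
  don <- "resname SER and name OG"; acc <- "resname CHL1 and name O3"
  h1 <- hbond_contacts(s, don, acc); h2 <- hbond_contacts(s2, don, acc)
  expect_equal(h1$distance, h2$distance, tolerance = 1e-9)
  expect_equal(h1$angle, h2$angle, tolerance = 1e-6)
})

test_that("pore profile reproduces ring geometry and flags empty slabs", {
  # 20 carbons ringed at 5 A in one slab: radius 5 - 1.7 = 3.3
  t <- seq(0, 2 * pi, length.out = 21)[-21]
  ring <- cbind(5 * cos(t), 5 * sin(t), 0)
  axis_atoms <- cbind(0.3 * cos(t[1:10]), 0.3 * sin(t[1:10]),
                      seq(-10, 10, length.out = 10))
  s <- make_structure(rbind(ring, axis_atoms),
                      resids = seq_len(30),
                      names = c(rep("C1", 20), rep("CA", 10)))
  pp <- pore_profile(s, lining_sel = "name C1", axis_sel = "name CA",
                     slab = 2)
  mid <- which.min(abs(pp$z))
  expect_equal(pp$radius[mid], 3.3, tolerance = 0.05)

  # ideal cylinder: flat profile R - 1.7 at every slab
  zs <- seq(-6, 6, by = 1)
  cyl <- do.call(rbind, lapply(zs, function(z) cbind(6 * cos(t), 6 * sin(t), z)))
  axis2 <- cbind(0, 0, seq(-6, 6, length.out = 8))
  s2 <- make_structure(rbind(cyl, axis2),
                       resids = seq_len(nrow(cyl) + 8),
                       names = c(rep("C1", nrow(cyl)), rep("CA", 8)))
  pp2 <- pore_profile(s2, lining_sel = "name C1", axis_sel = "name CA",
                      slab = 1)
  inner <- pp2[abs(pp2$z) < 5.5 & !is.na(pp2$radius), ]
  expect_true(all(abs(inner$radius - 4.3) < 1e-6))

  # a gap in the stack yields an undefined (NA) slab, not zero
  gap <- rbind(cbind(4 * cos(t), 4 * sin(t), -3),
               cbind(4 * cos(t), 4 * sin(t), 3))
  s3 <- make_structure(rbind(gap, cbind(0, 0, seq(-3, 3, length.out = 5))),
                       resids = seq_len(nrow(gap) + 5),
                       names = c(rep("C1", nrow(gap)), rep("CA", 5)))
  pp3 <- pore_profile(s3, lining_sel = "name C1", axis_sel = "name CA",
                      slab = 1)
  expect_true(any(is.na(pp3$radius)))
  expect_true(all(pp3$radius >= 0, na.rm = TRUE))
})

test_that("van der Waals radii cover common elements with a carbon fallback", {
  expect_equal(vdw_radius(c("C", "O", "N", "S", "H")),
               c(1.70, 1.52, 1.55, 1.80, 1.20))
  expect_equal(vdw_radius("XX"), 1.70)
})
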