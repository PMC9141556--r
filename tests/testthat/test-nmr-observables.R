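bead_restraint <- function(i, j, limit, kind = "noe") {
  distance_restraint(
    data.frame(residue_index = i, residue_name = "BEA", atom_name = "H"),
    data.frame(residue_index = j, residue_name = "BEA", atom_name = "H"),
    limit, kind)
}

test_that("effective distance: constants, hand value, convexity bounds", {
  g <- gen_toy_chain(2, bond_length = 3.0, fluctuation_sd = 0, n_frames = 5,
                     seed = 1)
  r <- bead_restraint(1, 2, 5.0)
  expect_equal(effective_distance(g$traj, r), 3.0, tolerance = 1e-12)
  # two equal-weight frames at 2 and 4 A: hand evaluation of r^-6 average
  arr <- array(0, dim = c(2, 2, 3))
  arr[1, 2, 1] <- 2; arr[2, 2, 1] <- 4
  topo <- gen_toy_chain(2, n_frames = 1, seed = 1)$traj$topology
  tr <- trajectory(arr, kind = "cartesian", topology = topo)
  expect_equal(effective_distance(tr, r), ((2^-6 + 4^-6) / 2)^(-1 / 6),
               tolerance = 1e-12)
  # uniform weights equal the unweighted definition exactly
  expect_equal(effective_distance(tr, r, weights = c(2, 2)),
               effective_distance(tr, r), tolerance = 1e-14)
  # r_eff decreases when any single frame distance decreases
  arr2 <- arr; arr2[2, 2, 1] <- 3.5
  tr2 <- trajectory(arr2, kind = "cartesian", topology = topo)
  expect_lt(effective_distance(tr2, r), effective_distance(tr, r))
  expect_error(effective_distance(tr, r, weights = c(0, 0)), "weights")
})

test_that("r^-6 averaging matches the generator's exact distance record", {
  g <- gen_toy_chain(4, n_frames = 200, seed = 5)
  for (p in seq_len(nrow(g$pairs))) {
    r <- bead_restraint(g$pairs$i[p], g$pairs$j[p], 5.0)
    oracle <- mean(g$distances[, p]^(-6))^(-1 / 6)
    expect_equal(effective_distance(g$traj, r), oracle, tolerance = 1e-10)
    # convexity bounds from the record
    expect_gte(effective_distance(g$traj, r), min(g$distances[, p]) - 1e-12)
    expect_lte(effective_distance(g$traj, r), mean(g$distances[, p]) + 1e-12)
  }
})

test_that("pseudoatom groups use pairwise r^-6 sum-averaging", {
  # 1 proton vs a 2-proton group at distances 2.5 and 3.5 A
  atoms <- data.frame(name = c("HA", "HD11", "HD12"), element = "H",
                      residue_index = c(1L, 2L, 2L),
                      residue_name = c("ALA", "LEU", "LEU"))
  coords <- rbind(c(0, 0, 0), c(2.5, 0, 0), c(0, 3.5, 0))
  topo <- structure_model(atoms, coords)
  tr <- trajectory(array(coords, dim = c(1, 3, 3)), kind = "cartesian",
                   topology = topo)
  r <- distance_restraint(
    data.frame(residue_index = 1, residue_name = "ALA", atom_name = "HA"),
    data.frame(residue_index = 2, residue_name = "LEU",
               atom_name = c("HD11", "HD12")), 5.0)
  expect_equal(effective_distance(tr, r),
               ((2.5^-6 + 3.5^-6) / 2)^(-1 / 6), tolerance = 1e-12)
})

test_that("violation report flags exactly the engineered violations", {
  g <- gen_toy_chain(6, bond_length = 3.0, fluctuation_sd = 0,
                     n_frames = 3, seed = 2)
  # distances between beads i<j are exactly 3*(j-i); engineer 3 violations
  limits <- c("1_2" = 3.5, "2_3" = 2.7, "3_4" = 3.5, "4_5" = 2.9,
              "5_6" = 3.5, "1_3" = 6.5, "2_4" = 5.0, "3_5" = 6.5,
              "4_6" = 6.5, "1_4" = 9.5)
  rs <- lapply(names(limits), function(nm) {
    ij <- as.integer(strsplit(nm, "_")[[1]])
    bead_restraint(ij[1], ij[2], unname(limits[nm]))
  })
  rep <- violation_report(g$traj, rs, threshold = 0.2)
  expect_equal(rep$n_violated, 3L)
  viol_idx <- rep$table$restraint[rep$table$violation > 0]
  expect_setequal(viol_idx, which(names(limits) %in% c("2_3", "4_5", "2_4")))
  expect_equal(rep$table$violation[rep$table$restraint == viol_idx[1]],
               0.3, tolerance = 1e-9)
  expect_equal(rep$n_above_threshold, 2L)  # 0.3, 1.0 above; 0.1 below
  expect_equal(rep$n_at_or_below_threshold, 1L)
  # all satisfied -> zero violations
  rs_ok <- lapply(seq_along(rs), function(i) {
    r <- rs[[i]]; r$upper_limit <- 99; r
  })
  expect_equal(violation_report(g$traj, rs_ok)$n_violated, 0L)
  # topology mismatch guard: >10% unmatched is a hard error
  bad <- c(rs, list(bead_restraint(90, 91, 5), bead_restraint(92, 93, 5)))
  expect_error(violation_report(g$traj, bad, 0.2), "unmatched")
})

test_that("S2 second moment: static, isotropic, cone closed form", {
  static <- trajectory(matrix(rep(c(0, 0, 1), each = 50), 50, 3),
                       kind = "vector")
  expect_equal(unname(s2_second_moment(static)), 1, tolerance = 1e-12)
  # isotropic: 0 within 3 SE (estimator bias is +1/n to leading order)
  set.seed(40)
  reps <- replicate(8, {
    z <- rnorm(5000); y <- rnorm(5000); x <- rnorm(5000)
    v <- cbind(x, y, z) / sqrt(x^2 + y^2 + z^2)
    unname(s2_second_moment(trajectory(v, kind = "vector")))
  })
  expect_lt(abs(mean(reps) - 1 / 5000), 3 * sd(reps) / sqrt(8))
  # cone model, hand-derived closed form at 60 degrees
  g <- gen_cone_vectors(60, 5e4, frame_correlation = 0.9, seed = 17)
  expect_lt(abs(unname(s2_second_moment(g$traj)) - 0.140625), 0.02)
  expect_error(s2_second_moment(trajectory(matrix(c(0, 0, 1), 1, 3),
                                           kind = "vector")), "2 frames")
})

test_that("S2 estimators agree, are rotation invariant, match two-site law", {
  g <- gen_cone_vectors(40, 4e4, frame_correlation = 0.9, seed = 23)
  m <- s2_second_moment(g$traj)
  p <- s2_correlation_plateau(g$traj)
  expect_lt(abs(unname(m) - unname(p)), 0.02)
  # global rotation invariance (both estimators)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  vr <- matrix(g$traj$data, ncol = 3) %*% R
  gr <- trajectory(vr, kind = "vector")
  expect_equal(unname(s2_second_moment(gr)), unname(m), tolerance = 1e-10)
  expect_equal(as.numeric(s2_correlation_plateau(gr)), as.numeric(p),
               tolerance = 1e-8)
  # fast two-site jump between orthogonal orientations, equal occupancy:
  # exhaustive 4-term P2 average oracle
  mu1 <- c(0, 0, 1); mu2 <- c(1, 0, 0)
  p2 <- function(c) (3 * c^2 - 1) / 2
  oracle <- mean(c(p2(sum(mu1 * mu1)), p2(sum(mu1 * mu2)),
                   p2(sum(mu2 * mu1)), p2(sum(mu2 * mu2))))
  set.seed(7)
  sites <- sample(0:1, 2e4, replace = TRUE)
  v <- rbind(mu1, mu2)[sites + 1, ]
  s2 <- unname(s2_second_moment(trajectory(v, kind = "vector")))
  expect_equal(s2, oracle, tolerance = 0.02)
  expect_equal(oracle, 0.25)  # hand check of the 4-term average
  # static vector: C(t) = 1 for all lags
  static <- trajectory(matrix(rep(c(0, 1, 0), each = 64), 64, 3),
                       kind = "vector")
  expect_equal(as.numeric(s2_correlation_plateau(static)), 1,
               tolerance = 1e-12)
})

test_that("N-H vector extraction removes global tumbling when asked", {
  m <- build_peptide(phi = c(NA, -60, -60, -60), psi = c(-45, -45, -45, -45))
  nf <- 40
  arr <- array(0, dim = c(nf, nrow(m$atoms), 3))
  for (f in seq_len(nf)) arr[f, , ] <- random_rigid(m$coords, seed = 100 + f)
  tr <- trajectory(arr, kind = "cartesian", topology = m)
  # with superposition (default): rigid body -> S2 = 1 for every residue
  v <- suppressWarnings(nh_vectors(tr))
  expect_true(all(abs(s2_second_moment(v) - 1) < 1e-9))
  # without superposition the same rigid motion looks like disorder
  v_raw <- suppressWarnings(nh_vectors(tr, superpose_selection = NA))
  expect_true(all(s2_second_moment(v_raw) < 0.9))
  # direction check on a hand-built two-atom residue
  topo <- structure_model(
    data.frame(name = c("N", "H"), element = c("N", "H"),
               residue_index = 1L, residue_name = "ALA"),
    rbind(c(0, 0, 0), c(0, 0, 1.01)))
  tr1 <- trajectory(array(rep(topo$coords, each = 2), dim = c(2, 2, 3)),
                    kind = "cartesian", topology = topo)
  v1 <- nh_vectors(tr1, superpose_selection = NA)
  expect_equal(v1$data[1, 1, ], c(0, 0, 1), tolerance = 1e-12)
})
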