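test_that("featurization maps torsions to unit-circle pairs", {
  traj <- trajectory(matrix(c(90, 0, -90, 450), ncol = 1), kind = "torsion",
                     labels = "psi_1")
  f <- featurize(traj)
  expect_equal(unclass(f)[1, ], c(sin_psi_1 = 1, cos_psi_1 = 0),
               tolerance = 1e-12)
  expect_equal(unclass(f)[2, ], c(sin_psi_1 = 0, cos_psi_1 = 1),
               tolerance = 1e-12)
  # +360 shift leaves features unchanged; sin^2+cos^2 = 1
  shifted <- trajectory(traj$data + 360, kind = "torsion", labels = "psi_1")
  expect_equal(unclass(featurize(shifted)), unclass(f), tolerance = 1e-12)
  expect_equal(rowSums(unclass(f)^2), rep(1, 4), tolerance = 1e-12)
  # undefined torsion in selection is an error naming the torsion
  bad <- trajectory(matrix(c(10, NA), ncol = 1), kind = "torsion",
                    labels = "psi_9")
  expect_error(featurize(bad), "psi_9")
})

test_that("collective variable evaluation matches term-by-term summation", {
  k <- 4
  cv1 <- collective_variable(1:k, rep(1, k), rep(0, k))
  ang <- matrix(90, 3, k)
  expect_equal(eval_cv(ang, cv1), rep(k, 3), tolerance = 1e-12)
  cv0 <- collective_variable(1:k, rep(0, k), rep(0, k))
  expect_equal(eval_cv(ang, cv0), rep(0, 3))
  set.seed(8)
  a <- rnorm(k); b <- rnorm(k)
  angles <- matrix(runif(10 * k, -180, 180), 10, k)
  cv <- collective_variable(1:k, a, b)
  oracle <- sapply(seq_len(10), function(i) {
    s <- 0
    for (j in seq_len(k)) {
      s <- s + a[j] * sin(angles[i, j] * pi / 180) +
        b[j] * cos(angles[i, j] * pi / 180)
    }
    s
  })
  expect_equal(eval_cv(angles, cv), oracle, tolerance = 1e-12)
  # agreement between raw-torsion and featurized input
  tr <- trajectory(angles, kind = "torsion")
  expect_equal(eval_cv(featurize(tr), cv), oracle, tolerance = 1e-12)
  expect_error(eval_cv(angles[, 1:2], collective_variable(1:3, 1:3, 1:3)),
               "mismatch")
})

test_that("tICA equals a dense generalized-eigensolver oracle", {
  set.seed(21)
  X <- matrix(rnorm(400 * 5), 400, 5) %*% matrix(runif(25, -1, 1), 5)
  for (j in 2:nrow(X)) X[j, ] <- 0.7 * X[j - 1, ] + 0.3 * X[j, ]
  eps <- 1e-6; L <- 2L
  mod <- tica_fit(X, lag = L, epsilon = eps)
  # oracle: direct nonsymmetric solve of C0^-1 Ct on independently coded
  # estimators
  X0 <- X[1:(nrow(X) - L), ]; Xt <- X[(1 + L):nrow(X), ]
  mu <- colMeans(rbind(X0, Xt))
  X0 <- sweep(X0, 2, mu); Xt <- sweep(Xt, 2, mu)
  N <- nrow(X0)
  C0 <- (crossprod(X0) + crossprod(Xt)) / (2 * N) + diag(eps, 5)
  Ct <- (crossprod(X0, Xt) + crossprod(Xt, X0)) / (2 * N)
  Ct <- (Ct + t(Ct)) / 2
  ev <- eigen(solve(C0, Ct))
  expect_lt(max(abs(Im(ev$values))), 1e-10)
  expect_equal(mod$eigenvalues, sort(Re(ev$values), decreasing = TRUE),
               tolerance = 1e-8)
  # eigenvector agreement up to sign/scale: check C0-orthonormality and the
  # eigen relation instead of vector identity
  V <- mod$components
  expect_equal(t(V) %*% C0 %*% V, diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(Ct %*% V, C0 %*% V %*% diag(mod$eigenvalues),
               tolerance = 1e-8, ignore_attr = TRUE)
  # affine feature rescaling leaves eigenvalues unchanged (epsilon off)
  S <- diag(c(2, 0.5, 1, 3, 1.5))
  mod2 <- tica_fit(X %*% S, lag = L, epsilon = 0)
  mod0 <- tica_fit(X, lag = L, epsilon = 0)
  expect_equal(mod2$eigenvalues, mod0$eigenvalues, tolerance = 1e-8)
  # degenerate input reported
  expect_error(tica_fit(matrix(1, 50, 3), lag = 2), "degenerate")
  expect_error(tica_fit(X, lag = 1000), "lag")
})

test_that("tICA transform projects the mean to the origin and separates states", {
  centers <- rbind(c(-60, 120, -40), c(60, -120, 140))
  g <- gen_two_state_loop(3, centers, hop_probability = 0.02,
                          angular_noise_sd = 15, n_frames = 20000, seed = 13)
  f <- featurize(g$traj)
  mod <- tica_fit(f, lag = 5)
  expect_true(all(abs(tica_transform(mod, mod$mean)) < 1e-10))
  Y <- tica_transform(mod, f, n_components = 2)
  # threshold separability on tIC1 against generator labels
  thr <- mean(tapply(Y[, 1], g$labels, mean))
  pred <- as.integer(Y[, 1] > thr)
  err <- min(mean(pred != g$labels), mean(pred != (1 - g$labels)))
  expect_lt(err, 0.05)
  # out-of-sample projection equals in-sample projection of the same frame
  expect_equal(tica_transform(mod, unclass(f)[10, ]),
               tica_transform(mod, f)[10, , drop = FALSE],
               tolerance = 1e-12)
  expect_error(tica_transform(mod, matrix(0, 2, 3)), "dimensionality")
})

test_that("free-energy surfaces obey the Boltzmann relation", {
  set.seed(31)
  # uniform points: dG ~ 0 everywhere
  u <- cbind(runif(60000), runif(60000))
  fes_u <- free_energy_surface(u, bins = 5, temperature = 300)
  expect_equal(sum(fes_u$counts), 60000)
  expect_equal(min(fes_u$dG, na.rm = TRUE), 0)
  expect_lt(max(fes_u$dG, na.rm = TRUE), 0.05)
  # two equal blobs: equal depth within noise
  n <- 30000
  b2 <- rbind(cbind(rnorm(n, -3, 0.2), rnorm(n, 0, 0.2)),
              cbind(rnorm(n, 3, 0.2), rnorm(n, 0, 0.2)))
  fes2 <- free_energy_surface(b2, bins = 16, temperature = 300)
  left <- min(fes2$dG[fes2$x_mid < 0, ], na.rm = TRUE)
  right <- min(fes2$dG[fes2$x_mid > 0, ], na.rm = TRUE)
  expect_lt(abs(left - right), 0.05)
  # single occupied bin is a valid surface
  one <- free_energy_surface(matrix(1, 5, 2), bins = 4)
  expect_equal(sum(one$counts > 0), 1)
  expect_equal(min(one$dG, na.rm = TRUE), 0)
  expect_true(anyNA(one$dG))  # unsampled bins marked, not infinite
})

test_that("average-linkage clustering matches an exhaustive enumeration", {
  # independent oracle: recompute every merge by brute-force averaging of
  # frame-level distances (no Lance-Williams shortcut)
  exhaustive_al <- function(D, cutoff) {
    cl <- as.list(seq_len(nrow(D)))
    repeat {
      if (length(cl) == 1L) break
      best <- c(NA, NA); bd <- Inf
      for (i in seq_along(cl)) {
        for (j in seq_along(cl)) {
          if (i >= j) next
          d <- mean(D[cl[[i]], cl[[j]]])
          if (d < bd - 1e-12) { bd <- d; best <- c(i, j) }
        }
      }
      if (bd > cutoff) break
      cl[[best[1]]] <- sort(c(cl[[best[1]]], cl[[best[2]]]))
      cl <- cl[-best[2]]
    }
    cl <- cl[order(vapply(cl, `[`, integer(1), 1L))]
    out <- integer(nrow(D))
    for (k in seq_along(cl)) out[cl[[k]]] <- k
    out
  }
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:8, 1)
    tr <- two_conformer_traj(n, labels = sample(0:1, n, replace = TRUE),
                             seed = seed * 17)
    D <- pairwise_rmsd(tr)
    D <- D + matrix(runif(n * n, 0, 1e-4), n, n)  # break exact ties
    D <- (D + t(D)) / 2; diag(D) <- 0
    for (cutoff in c(0.5, 1.2, 3, 10)) {
      got <- average_linkage_cluster(tr, cutoff = cutoff, dist_matrix = D)
      expect_identical(got$assignment, exhaustive_al(D, cutoff),
                       info = sprintf("seed %d cutoff %.1f", seed, cutoff))
    }
  }
})

test_that("clustering recovers well-separated conformers and medoids", {
  labels <- c(0, 1, 0, 1, 1, 0, 0, 1, 0, 1)
  tr <- two_conformer_traj(10, labels, seed = 3)
  cl <- average_linkage_cluster(tr, cutoff = 1.2)
  expect_equal(cl$n_clusters, 2L)
  expect_true(all(tapply(labels, cl$assignment, function(x)
    length(unique(x))) == 1))
  # medoid belongs to its own cluster
  expect_equal(cl$assignment[cl$representatives], seq_len(cl$n_clusters))
  # all frames identical -> one cluster
  one <- two_conformer_traj(5, rep(0, 5), seed = 2)
  expect_equal(average_linkage_cluster(one, cutoff = 1.2)$n_clusters, 1L)
  # frame-order permutation invariance (up to cluster relabeling)
  perm <- c(3, 1, 5, 2, 4, 9, 10, 6, 8, 7)
  tr_p <- trajectory(tr$data[perm, , , drop = FALSE], dt = 1,
                     kind = "cartesian", topology = tr$topology)
  cl_p <- average_linkage_cluster(tr_p, cutoff = 1.2)
  expect_true(all(tapply(cl$assignment[perm], cl_p$assignment,
                         function(x) length(unique(x))) == 1))
})
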