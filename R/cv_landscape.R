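# Torsion featurization, sine/cosine collective variables, tICA, free-energy
# surfaces and average-linkage RMSD clustering.

.kB_kcal <- 0.0019872041  # kcal/mol/K
.kB_kJ <- 0.0083144621    # kJ/mol/K

#' Sine/cosine featurization of a torsion trajectory
#'
#' Maps each selected torsion (degrees) to the (sin, cos) pair, the standard
#' wrap-safe embedding for circular backbone angles. Column order: for each
#' torsion in selection order, sin then cos.
#'
#' @param traj torsion-kind [trajectory()] (degrees).
#' @param torsion_selection column indices or labels to featurize
#'   (default: all).
#' @return `torsion_features` matrix (n_frames x 2k) with attributes `dt`
#'   and `labels`; every (sin, cos) pair satisfies sin^2 + cos^2 = 1.
#' @export
featurize <- function(traj, torsion_selection = NULL) {
  stopifnot(inherits(traj, "trajectory"), traj$kind == "torsion")
  ang <- traj$data
  labs <- traj$labels
  if (is.null(labs)) labs <- paste0("torsion_", seq_len(ncol(ang)))
  if (is.null(torsion_selection)) torsion_selection <- seq_len(ncol(ang))
  if (is.character(torsion_selection)) {
    idx <- match(torsion_selection, labs)
    if (anyNA(idx)) stop("unknown torsion label: ",
                         torsion_selection[is.na(idx)][1L])
    torsion_selection <- idx
  }
  sel <- ang[, torsion_selection, drop = FALSE]
  if (anyNA(sel)) {
    bad <- torsion_selection[colSums(is.na(sel)) > 0][1L]
    stop("selection hits an undefined torsion: ", labs[bad])
  }
  rad <- sel * pi / 180
  k <- ncol(rad)
  feats <- matrix(0, nrow(rad), 2L * k)
  feats[, 2L * seq_len(k) - 1L] <- sin(rad)
  feats[, 2L * seq_len(k)] <- cos(rad)
  colnames(feats) <- as.vector(rbind(paste0("sin_", labs[torsion_selection]),
                                     paste0("cos_", labs[torsion_selection])))
  structure(feats, dt = traj$dt, labels = labs[torsion_selection],
            class = c("torsion_features", "matrix", "array"))
}

#' Construct a sine/cosine collective variable
#'
#' The biased coordinate of the enhanced-sampling protocol: a linear
#' combination s = sum_i (a_i sin psi_i + b_i cos psi_i) over selected
#' torsions. Smooth in the torsions and invariant under 360-degree shifts.
#'
#' @param selection torsion indices or labels.
#' @param sin_weights,cos_weights numeric weights a_i, b_i (same length as
#'   selection).
#' @return object of class `collective_variable`.
#' @export
collective_variable <- function(selection, sin_weights, cos_weights) {
  stopifnot(length(sin_weights) == length(selection),
            length(cos_weights) == length(selection))
  structure(list(selection = selection, sin_weights = sin_weights,
                 cos_weights = cos_weights),
            class = "collective_variable")
}

#' Evaluate a collective variable on torsions
#'
#' @param x torsion-kind [trajectory()], a torsion matrix in degrees, or a
#'   `torsion_features` matrix from [featurize()].
#' @param cv a [collective_variable()].
#' @return numeric vector, one scalar per frame.
#' @export
eval_cv <- function(x, cv) {
  if (inherits(x, "trajectory")) x <- x$data
  if (inherits(x, "torsion_features")) {
    k <- length(cv$selection)
    sel <- if (is.character(cv$selection)) {
      match(cv$selection, attr(x, "labels"))
    } else as.integer(cv$selection)
    if (anyNA(sel) || max(sel) * 2L > ncol(x)) stop("weight/selection length mismatch")
    s <- x[, 2L * sel - 1L, drop = FALSE]
    c <- x[, 2L * sel, drop = FALSE]
  } else {
    x <- as.matrix(x)
    sel <- cv$selection
    if (is.character(sel)) stop("label selection requires torsion_features input")
    if (max(sel) > ncol(x)) stop("weight/selection length mismatch")
    rad <- x[, sel, drop = FALSE] * pi / 180
    s <- sin(rad); c <- cos(rad)
  }
  drop(s %*% cv$sin_weights + c %*% cv$cos_weights)
}

# ---- tICA -----------------------------------------------------------------

#' Fit a time-lagged independent component analysis model
#'
#' Solves the generalized eigenproblem C_tau v = lambda C0 v with the
#' symmetrized (reversible) estimators C_tau = (X0'Xt + Xt'X0)/2N and
#' C0 = (X0'X0 + Xt'Xt)/2N over all lagged pairs, C0 regularized by
#' epsilon * I. Components are scaled to unit C0-norm; the sign is fixed so
#' the largest-magnitude loading is positive. With a list of feature
#' matrices (combined tICA across trajectories) lagged pairs are formed
#' within each trajectory only — no pair spans a concatenation boundary.
#'
#' @param features `torsion_features` matrix, plain numeric matrix, or a
#'   list of such matrices.
#' @param lag lag time in the trajectory's time units (converted to frames
#'   with `dt`).
#' @param epsilon diagonal regularization added to C0 (default 1e-6).
#' @param dt time per frame; defaults to the `dt` attribute or 1.
#' @return object of class `tica_model` with fields `mean`, `C0`, `Ct`,
#'   `lag`, `lag_frames`, `eigenvalues` (descending), `components` (one
#'   column per eigenvalue), `epsilon`.
#' @export
tica_fit <- function(features, lag, epsilon = 1e-6, dt = NULL) {
  if (!is.list(features)) features <- list(features)
  if (is.null(dt)) {
    dt <- attr(features[[1L]], "dt")
    if (is.null(dt)) dt <- 1
  }
  L <- as.integer(round(lag / dt))
  if (L < 1L) stop("lag must be at least one frame")
  mats <- lapply(features, function(f) unclass(as.matrix(f)))
  d <- ncol(mats[[1L]])
  if (any(vapply(mats, nrow, integer(1)) <= L + 2L)) {
    stop("lag too long for trajectory length (need n_frames > lag/dt + 2)")
  }
  X0 <- do.call(rbind, lapply(mats, function(m) m[1:(nrow(m) - L), , drop = FALSE]))
  Xt <- do.call(rbind, lapply(mats, function(m) m[(1L + L):nrow(m), , drop = FALSE]))
  mu <- colMeans(rbind(X0, Xt))
  X0 <- sweep(X0, 2L, mu); Xt <- sweep(Xt, 2L, mu)
  N <- nrow(X0)
  C0 <- (crossprod(X0) + crossprod(Xt)) / (2 * N)
  Ct <- (crossprod(X0, Xt) + crossprod(Xt, X0)) / (2 * N)
  Ct <- (Ct + t(Ct)) / 2
  if (all(diag(C0) < 1e-12)) stop("degenerate input: features are constant in time")
  C0r <- C0 + diag(epsilon, d)
  U <- tryCatch(chol(C0r), error = function(e) {
    stop(sprintf("C0 singular beyond epsilon rescue (condition number %.3g)",
                 kappa(C0r)))
  })
  A <- forwardsolve(t(U), Ct)       # U'^-1 Ct
  B <- t(forwardsolve(t(U), t(A)))  # U'^-1 Ct U^-1
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  V <- backsolve(U, eg$vectors)
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  structure(list(mean = mu, C0 = C0, Ct = Ct, lag = lag, lag_frames = L,
                 eigenvalues = eg$values, components = V,
                 epsilon = epsilon),
            class = "tica_model")
}

#' @export
print.tica_model <- function(x, ...) {
  cat(sprintf("<tica_model> %d features, lag %g (%d frames); leading eigenvalues: %s\n",
              length(x$mean), x$lag, x$lag_frames,
              paste(signif(utils::head(x$eigenvalues, 3L), 4), collapse = ", ")))
  invisible(x)
}

#' Project features onto tICA components
#'
#' Works for out-of-sample data, e.g. a single crystal-structure frame
#' featurized the same way as the training trajectories.
#'
#' @param model a [tica_model()].
#' @param features matrix (or single-frame vector) with the model's feature
#'   dimensionality.
#' @param n_components number of leading components to return (default all).
#' @return matrix of projected coordinates (tIC1, tIC2, ...).
#' @export
tica_transform <- function(model, features, n_components = NULL) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  features <- unclass(as.matrix(features))
  if (ncol(features) != length(model$mean)) {
    stop("feature dimensionality does not match model")
  }
  if (is.null(n_components)) n_components <- ncol(model$components)
  Y <- sweep(features, 2L, model$mean) %*%
    model$components[, seq_len(n_components), drop = FALSE]
  colnames(Y) <- paste0("tIC", seq_len(ncol(Y)))
  Y
}

# ---- free-energy surface --------------------------------------------------

#' Free-energy surface over two projected coordinates
#'
#' Bins the points on a regular 2-D grid and converts counts to
#' dG(bin) = -kB T ln(count / max_count) in kcal/mol, so the global minimum
#' over occupied bins is exactly 0. Unsampled bins carry `NA` ("unsampled"),
#' never infinite arithmetic. Optional per-point weights (e.g. metadynamics
#' reweighting factors exp(+V_bias/kBT)) replace raw counts by weight sums.
#'
#' @param points n x 2 matrix of (tIC1, tIC2) coordinates.
#' @param bins bins per axis (scalar or length-2; >= 2).
#' @param temperature K.
#' @param weights optional non-negative per-point weights.
#' @return object of class `free_energy_surface`: `x_mid`, `y_mid`,
#'   `counts`, `dG` (kcal/mol, `NA` = unsampled), `temperature`.
#' @export
free_energy_surface <- function(points, bins = 50L, temperature = 300,
                                weights = NULL) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2L, nrow(points) >= 1L)
  bins <- rep(as.integer(bins), length.out = 2L)
  if (any(bins < 2L)) stop("need at least 2 bins per axis")
  rng_x <- range(points[, 1L]); rng_y <- range(points[, 2L])
  pad <- function(r) if (diff(r) == 0) r + c(-0.5, 0.5) else r
  rng_x <- pad(rng_x); rng_y <- pad(rng_y)
  xe <- seq(rng_x[1L], rng_x[2L], length.out = bins[1L] + 1L)
  ye <- seq(rng_y[1L], rng_y[2L], length.out = bins[2L] + 1L)
  ix <- pmin(findInterval(points[, 1L], xe, rightmost.closed = TRUE), bins[1L])
  iy <- pmin(findInterval(points[, 2L], ye, rightmost.closed = TRUE), bins[2L])
  if (is.null(weights)) weights <- rep(1, nrow(points))
  if (any(weights < 0) || all(weights == 0)) stop("invalid weights")
  counts <- matrix(0, bins[1L], bins[2L])
  for (p in seq_len(nrow(points))) {
    counts[ix[p], iy[p]] <- counts[ix[p], iy[p]] + weights[p]
  }
  dG <- matrix(NA_real_, bins[1L], bins[2L])
  occ <- counts > 0
  dG[occ] <- -.kB_kcal * temperature * log(counts[occ] / max(counts))
  structure(list(x_mid = (xe[-1L] + xe[-length(xe)]) / 2,
                 y_mid = (ye[-1L] + ye[-length(ye)]) / 2,
                 x_edges = xe, y_edges = ye,
                 counts = counts, dG = dG, temperature = temperature),
            class = "free_energy_surface")
}

#' Write a free-energy surface as a plain-text grid
#' @param fes a [free_energy_surface()].
#' @param path output path (columns x, y, count, dG; unsampled dG = NA).
#' @return `path`, invisibly.
#' @export
write_fes_table <- function(fes, path) {
  df <- expand.grid(x = fes$x_mid, y = fes$y_mid)
  df$count <- as.vector(fes$counts)
  df$dG <- as.vector(fes$dG)
  write.table(df, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- average-linkage RMSD clustering --------------------------------------

#' Pairwise best-fit RMSD matrix of a cartesian trajectory
#' @param traj cartesian [trajectory()].
#' @param selection integer atom indices used for the fit (default all; >= 3).
#' @return symmetric n_frames x n_frames matrix (A).
#' @export
pairwise_rmsd <- function(traj, selection = NULL) {
  stopifnot(traj$kind == "cartesian")
  n <- n_frames(traj)
  if (is.null(selection)) selection <- seq_len(dim(traj$data)[2L])
  if (length(selection) < 3L) stop("selection must contain >= 3 atoms")
  coords <- lapply(seq_len(n), function(i) {
    matrix(traj$data[i, selection, ], ncol = 3L)
  })
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- kabsch(coords[[i]], coords[[j]])$rmsd
    }
  }
  D
}

#' Average-linkage hierarchical clustering with an RMSD cutoff
#'
#' Agglomerates frames by average inter-cluster best-fit RMSD until the
#' minimum average linkage exceeds `cutoff` (the cpptraj-style criterion).
#' Ties are broken deterministically: the pair containing the lowest frame
#' index merges first. The representative of each cluster is its medoid, the
#' frame minimizing the summed RMSD to its cluster mates.
#'
#' @param traj cartesian [trajectory()] (or a precomputed distance matrix via
#'   `dist_matrix`).
#' @param selection atom indices for the fit (default all).
#' @param cutoff linkage cutoff, Angstrom.
#' @param dist_matrix optional precomputed symmetric distance matrix.
#' @return object of class `cluster_result`: `assignment` (frame ->
#'   cluster id, numbered by first frame), `representatives` (medoid frame
#'   per cluster), `cutoff`, `n_clusters`.
#' @export
average_linkage_cluster <- function(traj, selection = NULL, cutoff,
                                    dist_matrix = NULL) {
  D <- if (is.null(dist_matrix)) pairwise_rmsd(traj, selection) else dist_matrix
  n <- nrow(D)
  members <- as.list(seq_len(n))
  # cluster-level average-linkage distances (Lance-Williams update)
  CD <- D
  diag(CD) <- Inf
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  while (sum(active) > 1L) {
    idx <- which(active)
    sub <- CD[idx, idx, drop = FALSE]
    m <- min(sub)
    if (m > cutoff) break
    hit <- which(sub == m, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    # deterministic tie-break: lowest first-frame index pair
    firsts <- cbind(vapply(idx[hit[, 1L]], function(a) members[[a]][1L], integer(1)),
                    vapply(idx[hit[, 2L]], function(a) members[[a]][1L], integer(1)))
    ord <- order(pmin(firsts[, 1L], firsts[, 2L]), pmax(firsts[, 1L], firsts[, 2L]))
    a <- idx[hit[ord[1L], 1L]]; b <- idx[hit[ord[1L], 2L]]
    keep <- setdiff(which(active), c(a, b))
    new_d <- (sizes[a] * CD[a, keep] + sizes[b] * CD[b, keep]) /
      (sizes[a] + sizes[b])
    members[[a]] <- sort(c(members[[a]], members[[b]]))
    sizes[a] <- sizes[a] + sizes[b]
    active[b] <- FALSE
    CD[a, keep] <- new_d; CD[keep, a] <- new_d
    CD[a, a] <- Inf
  }
  clusters <- members[active]
  clusters <- clusters[order(vapply(clusters, `[`, integer(1), 1L))]
  assignment <- integer(n)
  reps <- integer(length(clusters))
  for (ci in seq_along(clusters)) {
    fr <- clusters[[ci]]
    assignment[fr] <- ci
    if (length(fr) == 1L) {
      reps[ci] <- fr
    } else {
      sums <- rowSums(D[fr, fr, drop = FALSE])
      reps[ci] <- fr[which.min(sums)]
    }
  }
  structure(list(assignment = assignment, representatives = reps,
                 cutoff = cutoff, n_clusters = length(clusters)),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d clusters at cutoff %.2f A; sizes: %s\n",
              x$n_clusters, x$cutoff,
              paste(tabulate(x$assignment), collapse = ", ")))
  invisible(x)
}
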