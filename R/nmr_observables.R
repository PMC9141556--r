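# NOE effective distances with r^-6 averaging, violation reports, and
# Lipari-Szabo order parameters (S2) from unit bond-vector trajectories.

# Resolve a restraint group onto a topology; returns integer atom indices
# (possibly length 0 if atoms are missing).
resolve_group <- function(topology, group) {
  idx <- integer(0)
  for (r in seq_len(nrow(group))) {
    i <- which(topology$atoms$residue_index == group$residue_index[r] &
                 topology$atoms$name == group$atom_name[r])
    idx <- c(idx, i)
  }
  idx
}

# Per-frame effective distance of one restraint: r^-6 sum-average over all
# inter-group atom pairs (the pseudoatom convention), one value per frame.
frame_effective_distances <- function(traj, restraint) {
  stopifnot(traj$kind == "cartesian", !is.null(traj$topology))
  ia <- resolve_group(traj$topology, restraint$group_a)
  ib <- resolve_group(traj$topology, restraint$group_b)
  if (length(ia) == 0L || length(ib) == 0L) return(NULL)
  nf <- n_frames(traj)
  inv6 <- matrix(0, nf, length(ia) * length(ib))
  p <- 0L
  for (a in ia) {
    for (b in ib) {
      p <- p + 1L
      d <- matrix(traj$data[, a, ] - traj$data[, b, ], nrow = nf)
      r2 <- rowSums(d^2)
      if (any(r2 == 0)) stop("zero distance between restrained atoms (overlap)")
      inv6[, p] <- r2^(-3)
    }
  }
  rowMeans(inv6)^(-1 / 6)
}

#' NOE effective distance with r^-6 time and ensemble averaging
#'
#' The NOE intensity scales as r^-6, so the distance an ensemble reports is
#' r_eff = (sum_t w_t <r^-6>_t / sum_t w_t)^(-1/6), where <r^-6>_t is the
#' mean over all inter-group proton pairs at frame t (pseudoatom
#' convention). Uniform weights reproduce the plain time average exactly.
#'
#' @param traj cartesian [trajectory()] with a topology.
#' @param restraint a [distance_restraint()].
#' @param weights optional non-negative per-frame weights (not all zero),
#'   e.g. metadynamics reweighting factors.
#' @return effective distance, Angstrom.
#' @export
effective_distance <- function(traj, restraint, weights = NULL) {
  reff_t <- frame_effective_distances(traj, restraint)
  if (is.null(reff_t)) stop("restraint atoms not found in topology")
  if (is.null(weights)) weights <- rep(1, length(reff_t))
  if (length(weights) != length(reff_t)) stop("weights length mismatch")
  if (any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative and not all zero")
  }
  (sum(weights * reff_t^(-6)) / sum(weights))^(-1 / 6)
}

#' Restraint violation report for a trajectory or ensemble
#'
#' Default convention (`mode = "ensemble"`): a restraint is violated when
#' the r^-6-averaged effective distance over all frames/models exceeds its
#' upper limit. `mode = "per_model"` instead counts a restraint as violated
#' if its per-model effective distance exceeds the limit in any model (the
#' stricter convention some structure-calculation programs report).
#'
#' @param x cartesian [trajectory()] or [ensemble()].
#' @param restraints list of [distance_restraint()].
#' @param threshold violation-magnitude threshold, Angstrom (default 0.2).
#' @param mode `"ensemble"` or `"per_model"`.
#' @return list with `table` (per matched restraint: limit, r_eff, min/mean/
#'   max instantaneous distance, violation), `n_violated`,
#'   `n_at_or_below_threshold`, `n_above_threshold`, `unmatched` (indices of
#'   restraints whose atoms were not found).
#' @export
violation_report <- function(x, restraints, threshold = 0.2,
                             mode = c("ensemble", "per_model")) {
  mode <- match.arg(mode)
  traj <- if (inherits(x, "ensemble")) ensemble_to_trajectory(x) else x
  n <- length(restraints)
  rows <- vector("list", n)
  unmatched <- integer(0)
  for (i in seq_len(n)) {
    r <- restraints[[i]]
    reff_t <- frame_effective_distances(traj, r)
    if (is.null(reff_t)) {
      unmatched <- c(unmatched, i)
      next
    }
    reff <- if (mode == "ensemble") {
      mean(reff_t^(-6))^(-1 / 6)
    } else {
      max(reff_t)  # worst model drives the violation call
    }
    rows[[i]] <- data.frame(
      restraint = i, kind = r$kind, upper_limit = r$upper_limit,
      r_eff = reff, r_min = min(reff_t), r_mean = mean(reff_t),
      r_max = max(reff_t), violation = max(0, reff - r$upper_limit))
  }
  if (n > 0 && length(unmatched) > 0.1 * n) {
    stop(sprintf("%d of %d restraints unmatched on topology (>10%%): topology mismatch",
                 length(unmatched), n))
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tab)) tab <- data.frame()
  viol <- if (nrow(tab)) tab$violation else numeric(0)
  list(table = tab,
       n_violated = sum(viol > 0),
       n_at_or_below_threshold = sum(viol > 0 & viol <= threshold),
       n_above_threshold = sum(viol > threshold),
       unmatched = unmatched, threshold = threshold, mode = mode)
}

# ---- order parameters -----------------------------------------------------

normalize_vectors <- function(v) {
  # v: n_frames x 3
  nrm <- sqrt(rowSums(v^2))
  if (any(abs(nrm - 1) > 1e-3)) {
    warning("vector norms deviate from 1 by more than 1e-3; renormalizing")
  }
  v / nrm
}

s2_from_moments <- function(v) {
  # S2 = 3/2 (<x2>^2 + <y2>^2 + <z2>^2 + 2<xy>^2 + 2<xz>^2 + 2<yz>^2) - 1/2
  M <- crossprod(v) / nrow(v)  # <mu_a mu_b>
  1.5 * sum(M^2) - 0.5
}

#' Lipari-Szabo order parameter by the second-moment estimator
#'
#' S2 = (3/2) sum_ab <mu_a mu_b>^2 - 1/2 over all frames. Equals 1 for a
#' static vector and 0 for isotropic orientations; invariant under any
#' global rotation applied to all frames.
#'
#' @param vectors vector-kind [trajectory()] of unit vectors (n_frames x
#'   n_vec x 3); renormalized internally with a warning if norms are off by
#'   more than 1e-3.
#' @return numeric vector of S2, one per vector channel.
#' @export
s2_second_moment <- function(vectors) {
  stopifnot(inherits(vectors, "trajectory"), vectors$kind == "vector")
  if (n_frames(vectors) < 2L) stop("need at least 2 frames")
  nv <- dim(vectors$data)[2L]
  out <- vapply(seq_len(nv), function(k) {
    v <- normalize_vectors(matrix(vectors$data[, k, ], ncol = 3L))
    s2_from_moments(v)
  }, numeric(1))
  names(out) <- vectors$labels
  out
}

# FFT-based <p(t) p(t+tau)> for one product series, lags 0..max_lag
acf_unnorm <- function(x, max_lag) {
  n <- length(x)
  m <- stats::nextn(2L * n)
  f <- fft(c(x, rep(0, m - n)))
  s <- Re(fft(f * Conj(f), inverse = TRUE)) / m
  s[1:(max_lag + 1L)] / (n - 0:max_lag)
}

#' Lipari-Szabo order parameter from the correlation-function plateau
#'
#' Computes the internal orientational correlation function
#' C(t) = <P2(mu(0) . mu(t))> averaged over time origins (FFT-accelerated)
#' and returns the mean of C over the final `plateau_window` fraction of the
#' computed lags (lags up to half the trajectory). If the plateau slope
#' exceeds `slope_tol` per lag the estimate is flagged as non-converged via
#' the `converged` attribute — flagged, never suppressed.
#'
#' @param vectors vector-kind [trajectory()] of unit vectors.
#' @param plateau_window final fraction of lags averaged (default 0.2).
#' @param slope_tol plateau slope tolerance per lag (default 1e-3).
#' @return numeric vector of S2 with attribute `converged` (logical per
#'   channel).
#' @export
s2_correlation_plateau <- function(vectors, plateau_window = 0.2,
                                   slope_tol = 1e-3) {
  stopifnot(inherits(vectors, "trajectory"), vectors$kind == "vector")
  nf <- n_frames(vectors)
  if (nf < 4L) stop("trajectory too short for a correlation plateau")
  max_lag <- floor(nf / 2)
  nv <- dim(vectors$data)[2L]
  s2 <- numeric(nv)
  conv <- logical(nv)
  for (k in seq_len(nv)) {
    v <- normalize_vectors(matrix(vectors$data[, k, ], ncol = 3L))
    # C(t) = 3/2 sum_ab <p_ab(0) p_ab(t)> - 1/2 with p_ab = mu_a mu_b
    acc <- numeric(max_lag + 1L)
    for (a in 1:3) {
      for (b in a:3) {
        w <- if (a == b) 1 else 2
        acc <- acc + w * acf_unnorm(v[, a] * v[, b], max_lag)
      }
    }
    C <- 1.5 * acc - 0.5
    lags <- seq_along(C) - 1L
    win <- lags >= (1 - plateau_window) * max_lag
    s2[k] <- mean(C[win])
    fit <- stats::lm.fit(cbind(1, lags[win]), C[win])
    conv[k] <- abs(fit$coefficients[2L]) <= slope_tol
  }
  if (!all(conv)) {
    warning("plateau not converged for ", sum(!conv), " vector channel(s)")
  }
  names(s2) <- vectors$labels
  attr(s2, "converged") <- conv
  s2
}

#' Extract per-residue backbone amide N-H unit vectors
#'
#' Frames are first least-squares superposed onto the reference topology
#' over `superpose_selection` (by default all backbone N/CA/C atoms, i.e.
#' global tumbling is removed so downstream S2 reports internal motion
#' only). Residues lacking an amide proton (prolines, N-terminus) are
#' skipped with a warning.
#'
#' @param traj cartesian [trajectory()] with a topology.
#' @param residues residue indices (default: all with both N and H/HN).
#' @param superpose_selection integer atom indices used for the fit; NULL
#'   fits on all backbone N, CA, C atoms; NA skips superposition.
#' @param h_names candidate amide proton names, tried in order.
#' @return vector-kind [trajectory()] (n_frames x n_residues x 3) with
#'   residue indices as labels.
#' @export
nh_vectors <- function(traj, residues = NULL, superpose_selection = NULL,
                       h_names = c("H", "HN")) {
  stopifnot(traj$kind == "cartesian", !is.null(traj$topology))
  topo <- traj$topology
  nf <- n_frames(traj)
  data <- traj$data
  if (!(length(superpose_selection) == 1L && is.na(superpose_selection[1L]))) {
    if (is.null(superpose_selection)) {
      superpose_selection <- atom_select(topo, atom_names = c("N", "CA", "C"))
    }
    ref <- topo$coords[superpose_selection, , drop = FALSE]
    for (f in seq_len(nf)) {
      P <- matrix(data[f, superpose_selection, ], ncol = 3L)
      k <- kabsch(P, ref)
      all_f <- sweep(matrix(data[f, , ], ncol = 3L), 2L, k$center_mobile)
      data[f, , ] <- sweep(all_f %*% k$rotation, 2L, k$center_ref, `+`)
    }
  }
  if (is.null(residues)) residues <- sort(unique(topo$atoms$residue_index))
  keep <- integer(0); ni <- integer(0); hi <- integer(0)
  for (r in residues) {
    n_idx <- which(topo$atoms$residue_index == r & topo$atoms$name == "N")
    h_idx <- integer(0)
    for (hn in h_names) {
      h_idx <- which(topo$atoms$residue_index == r & topo$atoms$name == hn)
      if (length(h_idx) == 1L) break
    }
    if (length(n_idx) == 1L && length(h_idx) == 1L) {
      keep <- c(keep, r); ni <- c(ni, n_idx); hi <- c(hi, h_idx)
    }
  }
  if (length(keep) < length(residues)) {
    warning(sprintf("skipped %d residue(s) without an amide N-H pair",
                    length(residues) - length(keep)))
  }
  if (length(keep) == 0L) stop("no residues with N-H vectors found")
  vecs <- array(0, dim = c(nf, length(keep), 3L))
  for (q in seq_along(keep)) {
    d <- matrix(data[, hi[q], ] - data[, ni[q], ], nrow = nf)
    vecs[, q, ] <- d / sqrt(rowSums(d^2))
  }
  trajectory(vecs, dt = traj$dt, kind = "vector", labels = keep)
}

#' Side-by-side comparison of two per-residue S2 profiles
#' @param calc named numeric vector (names = residue indices) of computed S2.
#' @param exper data.frame with columns `residue_index`, `s2` (experimental).
#' @return data.frame with `residue_index`, `s2_calc`, `s2_exp`, `delta`;
#'   attribute `rmsd` holds the RMS deviation over common residues.
#' @export
compare_s2 <- function(calc, exper) {
  res <- intersect(as.integer(names(calc)), exper$residue_index)
  df <- data.frame(residue_index = res,
                   s2_calc = calc[as.character(res)],
                   s2_exp = exper$s2[match(res, exper$residue_index)])
  df$delta <- df$s2_calc - df$s2_exp
  attr(df, "rmsd") <- sqrt(mean(df$delta^2))
  df
}
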