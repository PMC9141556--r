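# Synthetic generators with analytically known ground truth. Every generator
# takes one explicit seed and uses its own RNG stream (restored on exit), so
# cross-module analyses never share streams. Ground truth always travels with
# the returned object, never as a constant buried in a test.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- diffusion in a cone --------------------------------------------------

#' Generate unit bond vectors diffusing in a cone
#'
#' Draws orientations uniformly over the spherical cap of semi-angle
#' `semi_angle` about +z. Frame-to-frame correlation is introduced by a
#' jump process: each frame keeps the previous orientation with probability
#' `frame_correlation` and otherwise redraws uniformly on the cap, so the
#' stationary distribution is exactly uniform on the cap and the orientational
#' correlation function decays geometrically. The Lipari-Szabo order
#' parameter of this model has the closed form
#' S2 = (cos(t0) * (1 + cos(t0)) / 2)^2 with t0 the semi-angle; it is
#' attached as `ground_truth_s2`.
#'
#' @param semi_angle cone semi-angle, degrees, in (0, 90].
#' @param n_frames number of frames.
#' @param frame_correlation per-frame keep probability in [0, 1).
#' @param seed integer RNG seed.
#' @param dt time per frame, ps.
#' @return list with `traj` (a vector-kind [trajectory()], n_frames x 1 x 3)
#'   and `ground_truth_s2`.
#' @export
gen_cone_vectors <- function(semi_angle, n_frames, frame_correlation = 0,
                             seed = 1L, dt = 1) {
  if (!is.finite(semi_angle) || semi_angle <= 0 || semi_angle > 90) {
    stop("semi_angle must be in (0, 90] degrees")
  }
  if (frame_correlation < 0 || frame_correlation >= 1) {
    stop("frame_correlation must be in [0, 1)")
  }
  t0 <- semi_angle * pi / 180
  c0 <- cos(t0)
  draw <- function(n) {
    # uniform on the cap: cos(theta) ~ U[cos t0, 1]
    ct <- runif(n, c0, 1)
    st <- sqrt(pmax(0, 1 - ct^2))
    ph <- runif(n, 0, 2 * pi)
    cbind(st * cos(ph), st * sin(ph), ct)
  }
  vecs <- with_seed(seed, {
    v <- draw(n_frames)
    if (frame_correlation > 0 && n_frames > 1L) {
      keep <- runif(n_frames - 1L) < frame_correlation
      for (i in which(keep)) v[i + 1L, ] <- v[i, ]
    }
    v
  })
  s2 <- (c0 * (1 + c0) / 2)^2
  list(traj = trajectory(vecs, dt = dt, kind = "vector"),
       ground_truth_s2 = s2)
}

# ---- two-state torsion loop -----------------------------------------------

#' Generate a metastable two-state torsion trajectory
#'
#' A symmetric Markov chain hops between two loop conformations (vectors of
#' psi-like torsion centers) with per-frame probability `hop_probability`;
#' wrapped Gaussian angular noise is added about the active center. Because
#' the hop rule is symmetric, the stationary occupancies are 0.5/0.5. The
#' per-frame state labels are returned for clustering/tICA validation.
#'
#' @param n_residues number of torsions.
#' @param state_centers 2 x n_residues matrix of torsion centers, degrees.
#' @param hop_probability per-frame hop probability in (0, 1); 0 is allowed
#'   and freezes the chain in its initial state.
#' @param angular_noise_sd Gaussian noise SD, degrees.
#' @param n_frames number of frames.
#' @param seed integer RNG seed.
#' @param dt time per frame, ps.
#' @param start_state initial state, 0 or 1.
#' @return list with `traj` (torsion-kind [trajectory()], degrees) and
#'   `labels` (integer vector of 0/1 states).
#' @export
gen_two_state_loop <- function(n_residues, state_centers, hop_probability,
                               angular_noise_sd, n_frames, seed = 1L,
                               dt = 1, start_state = 0L) {
  state_centers <- matrix(state_centers, nrow = 2L)
  stopifnot(ncol(state_centers) == n_residues)
  if (hop_probability < 0 || hop_probability >= 1) {
    stop("hop_probability must be in [0, 1)")
  }
  out <- with_seed(seed, {
    hops <- if (n_frames > 1L) runif(n_frames - 1L) < hop_probability else logical(0)
    state <- c(start_state, (start_state + cumsum(hops)) %% 2L)
    noise <- matrix(rnorm(n_frames * n_residues, sd = angular_noise_sd),
                    n_frames, n_residues)
    ang <- state_centers[state + 1L, , drop = FALSE] + noise
    list(ang = wrap_angle(ang), labels = as.integer(state))
  })
  labels_chr <- paste0("psi_", seq_len(n_residues))
  list(traj = trajectory(out$ang, dt = dt, kind = "torsion",
                         labels = labels_chr),
       labels = out$labels)
}

# ---- 1-D double-well Langevin particle ------------------------------------

#' Analytic double-well potential
#'
#' U(x) = h * ((x/a)^2 - 1)^2 with barrier height `h` (kJ/mol) between wells
#' at x = -a and x = +a. In 1-D the free-energy profile equals the potential
#' up to an additive constant.
#'
#' @param x positions (reduced units).
#' @param barrier_height h, kJ/mol.
#' @param well_separation a (half-distance between wells), reduced units.
#' @return potential values, kJ/mol.
#' @export
double_well_potential <- function(x, barrier_height, well_separation = 1) {
  barrier_height * ((x / well_separation)^2 - 1)^2
}

#' Generate an overdamped Langevin trajectory in a double well
#'
#' Integrates x <- x - U'(x)/(gamma m) dt + sqrt(2 kB T dt/(gamma m)) xi with
#' unit mass. A stability heuristic requires dt * friction < 0.1.
#'
#' @param barrier_height kJ/mol (0 gives free diffusion on a flat profile).
#' @param well_separation reduced units (wells at +-a).
#' @param temperature K.
#' @param friction gamma, ps^-1.
#' @param dt time step, ps.
#' @param n_steps number of steps.
#' @param seed integer RNG seed.
#' @param x0 initial position (default -well_separation).
#' @param grid positions at which the analytic free energy is tabulated.
#' @return list with `traj` (scalar-kind [trajectory()]), `free_energy`
#'   (data.frame x, F with min 0, kJ/mol) and the parameters.
#' @export
gen_double_well <- function(barrier_height, well_separation = 1,
                            temperature = 300, friction = 1, dt = 0.01,
                            n_steps = 10000L, seed = 1L, x0 = NULL,
                            grid = NULL) {
  if (temperature <= 0 || friction <= 0) {
    stop("temperature and friction must be positive")
  }
  if (dt * friction >= 0.1) {
    warning("dt * friction >= 0.1: integration may be inaccurate")
  }
  if (is.null(x0)) x0 <- -well_separation
  if (is.null(grid)) {
    grid <- seq(-2 * well_separation, 2 * well_separation, length.out = 201L)
  }
  x <- with_seed(seed,
    langevin_double_well(n_steps, dt, temperature, friction,
                         barrier_height, well_separation, x0))
  fa <- double_well_potential(grid, barrier_height, well_separation)
  fa <- fa - min(fa)
  list(traj = trajectory(matrix(x, ncol = 1L), dt = dt, kind = "scalar"),
       free_energy = data.frame(x = grid, F = fa),
       barrier_height = barrier_height, well_separation = well_separation,
       temperature = temperature, friction = friction)
}

# ---- fluctuating bead chain -----------------------------------------------

#' Generate a toy fluctuating linear chain
#'
#' Beads sit on a line at spacing `bond_length` and receive i.i.d. Gaussian
#' displacements per frame per coordinate. Alongside the cartesian
#' trajectory, the generator emits the exact distance of every bead pair in
#' every frame (computed at generation time) so that downstream r^-6
#' averaging can be checked against an independent record.
#'
#' @param n_atoms number of beads (>= 2).
#' @param bond_length spacing, Angstrom.
#' @param fluctuation_sd per-coordinate Gaussian SD, Angstrom.
#' @param n_frames number of frames.
#' @param seed integer RNG seed.
#' @param dt time per frame, ps.
#' @return list with `traj` (cartesian [trajectory()] with a bead topology:
#'   one residue per bead, atom name "H"), `pairs` (data.frame i, j) and
#'   `distances` (n_frames x n_pairs matrix of exact distances, Angstrom).
#' @export
gen_toy_chain <- function(n_atoms, bond_length = 3.8, fluctuation_sd = 0.3,
                          n_frames = 100L, seed = 1L, dt = 1) {
  if (n_atoms < 2L) stop("n_atoms must be >= 2")
  base <- cbind((seq_len(n_atoms) - 1L) * bond_length, 0, 0)
  arr <- with_seed(seed, {
    a <- array(rnorm(n_frames * n_atoms * 3L, sd = fluctuation_sd),
               dim = c(n_frames, n_atoms, 3L))
    for (k in 1:3) {
      a[, , k] <- sweep(matrix(a[, , k], n_frames), 2L, base[, k], `+`)
    }
    a
  })
  topo <- structure_model(
    data.frame(name = "H", element = "H",
               residue_index = seq_len(n_atoms),
               residue_name = "BEA", stringsAsFactors = FALSE),
    base)
  pairs <- which(upper.tri(matrix(0, n_atoms, n_atoms)), arr.ind = TRUE)
  pairs <- data.frame(i = pairs[, 1L], j = pairs[, 2L])
  dist_rec <- matrix(0, n_frames, nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    d <- arr[, pairs$i[p], , drop = FALSE] - arr[, pairs$j[p], , drop = FALSE]
    dist_rec[, p] <- sqrt(rowSums(matrix(d, nrow = n_frames)^2))
  }
  list(traj = trajectory(arr, dt = dt, kind = "cartesian", topology = topo),
       pairs = pairs, distances = dist_rec)
}
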