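# Flat-bottom upper-limit restraints and exponential-memory time-averaged
# restrained Langevin dynamics on toy bead chains.

#' Construct a restraint-memory state
#'
#' Holds the exponentially weighted running average of r^-p for one
#' restraint. `p` is the averaging exponent (1, 3 or 6); `tau` the memory
#' time constant in ps (default 100 ps, the standard choice for
#' time-averaged NOE restraints).
#'
#' @param tau memory time constant, ps (> 0).
#' @param p averaging exponent, one of 1, 3, 6.
#' @return object of class `restraint_memory` with fields `m` (running
#'   average of r^-p; NA before the first update), `r_bar`, `tau`, `p`.
#' @export
restraint_memory <- function(tau = 100, p = 3) {
  if (!(p %in% c(1, 3, 6))) stop("p must be 1, 3 or 6")
  if (tau <= 0) stop("tau must be > 0")
  structure(list(m = NA_real_, r_bar = NA_real_, tau = tau, p = p),
            class = "restraint_memory")
}

#' Update a restraint memory with a new instantaneous distance
#'
#' m <- m * exp(-dt/tau) + r^-p * (1 - exp(-dt/tau)); r_bar = m^(-1/p).
#' The first update initializes m = r^-p, so r_bar starts at the first
#' observed distance. With constant input the fixed point is r_bar = r, and
#' the update is exactly independent of how dt is partitioned.
#'
#' @param state a [restraint_memory()].
#' @param r_t instantaneous distance, Angstrom (> 0).
#' @param dt elapsed time, ps (> 0).
#' @return updated [restraint_memory()].
#' @export
memory_update <- function(state, r_t, dt) {
  if (r_t <= 0) stop("distance must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  w <- exp(-dt / state$tau)
  rp <- r_t^(-state$p)
  state$m <- if (is.na(state$m)) rp else state$m * w + rp * (1 - w)
  state$r_bar <- state$m^(-1 / state$p)
  state
}

#' Construct a flat-bottom upper-limit restraint
#' @param restraint a [distance_restraint()].
#' @param k force constant, kJ/(mol A^2).
#' @return object of class `flat_bottom_restraint`.
#' @export
flat_bottom_restraint <- function(restraint, k = 20) {
  stopifnot(inherits(restraint, "distance_restraint"), k > 0)
  structure(list(restraint = restraint, k = k),
            class = "flat_bottom_restraint")
}

#' Flat-bottom restraint energy and force
#'
#' E = 0 for r <= U; E = k/2 (r - U)^2 above the limit. Energy and force
#' are continuous at the limit; the returned force is -dE/dr (negative
#' beyond the limit, i.e. pulling the pair back together).
#'
#' @param r_bar driving distance (instantaneous or time-averaged), Angstrom.
#' @param fb a [flat_bottom_restraint()].
#' @return list with `energy` (kJ/mol) and `force` (-dE/dr, kJ/(mol A)).
#' @export
restraint_energy_force <- function(r_bar, fb) {
  if (any(r_bar <= 0)) stop("distance must be > 0")
  over <- pmax(0, r_bar - fb$restraint$upper_limit)
  list(energy = 0.5 * fb$k * over^2, force = -fb$k * over)
}

#' Run restrained Langevin dynamics on a toy bead chain
#'
#' A linear chain with harmonic bonds evolves under underdamped Langevin
#' dynamics (BAOAB; `friction = 0` gives plain velocity-Verlet NVE) with
#' flat-bottom upper-limit restraints added. In `mode = "time_averaged"`
#' the restraint force is driven by the exponentially averaged r_bar
#' (memory constant `tau`, exponent `p`) instead of the instantaneous
#' distance, allowing transient excursions above the limit; the force is
#' applied along the current pair vector without the formal
#' (r_bar/r)^(p+1) correction factor (a stability choice on toys).
#'
#' @param chain result of [gen_toy_chain()] (or any list with `traj` whose
#'   topology is a bead chain) — frame 1 provides initial coordinates.
#' @param restraints list of [flat_bottom_restraint()]; their selectors are
#'   resolved on the chain topology by residue index.
#' @param mode `"instantaneous"` or `"time_averaged"`.
#' @param n_steps number of integration steps.
#' @param tau memory time constant, ps.
#' @param p averaging exponent (1, 3 or 6; default 3, the common MD-engine
#'   default for time-averaged NOE restraints).
#' @param temperature K.
#' @param friction ps^-1 (0 = NVE).
#' @param dt ps.
#' @param k_bond bond force constant, kJ/(mol A^2).
#' @param seed integer RNG seed.
#' @param sample_every store every k-th frame.
#' @return list with `traj` (cartesian [trajectory()]), `restraint_energy`
#'   (per sampled frame, kJ/mol), `total_energy` (potential + kinetic) and
#'   `r_bar` (per sampled frame per restraint).
#' @export
run_restrained <- function(chain, restraints = list(),
                           mode = c("instantaneous", "time_averaged"),
                           n_steps = 10000L, tau = 100, p = 3,
                           temperature = 300, friction = 1, dt = 0.01,
                           k_bond = 500, seed = 1L, sample_every = 10L) {
  mode <- match.arg(mode)
  traj <- chain$traj
  topo <- traj$topology
  coords0 <- matrix(traj$data[1L, , ], ncol = 3L)
  bl <- if (!is.null(chain$bond_length)) chain$bond_length else {
    mean(sqrt(rowSums((coords0[-1L, , drop = FALSE] -
                         coords0[-nrow(coords0), , drop = FALSE])^2)))
  }
  ri <- rj <- integer(0); ru <- numeric(0); kr <- 20
  for (fb in restraints) {
    ia <- resolve_group(topo, fb$restraint$group_a)
    ib <- resolve_group(topo, fb$restraint$group_b)
    if (length(ia) != 1L || length(ib) != 1L) {
      stop("bead-chain restraints must resolve to single atoms per group")
    }
    ri <- c(ri, ia); rj <- c(rj, ib); ru <- c(ru, fb$restraint$upper_limit)
    kr <- fb$k
  }
  res <- with_seed(seed,
    run_chain_dynamics(coords0, bl, k_bond, temperature, friction, dt,
                       as.integer(n_steps), as.integer(sample_every),
                       as.integer(ri), as.integer(rj), ru, kr,
                       if (mode == "time_averaged") 1L else 0L, tau, p))
  list(traj = trajectory(res$coords, dt = dt * sample_every,
                         kind = "cartesian", topology = topo),
       restraint_energy = res$e_restraint,
       total_energy = res$e_total,
       r_bar = res$r_bar)
}
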