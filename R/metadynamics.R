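# Well-tempered metadynamics on low-dimensional toy Langevin systems.
# Units: energies kJ/mol, CV widths in rad (angular CVs) or reduced units.

#' Construct a metadynamics bias record
#'
#' @param hills data.frame with columns `center`, `height` (kJ/mol, already
#'   tempered), `width` (rad or reduced units), `step` (deposit step).
#' @param bias_factor gamma > 1.
#' @param pace steps between deposits.
#' @param temperature K.
#' @param periodic if TRUE, Gaussians are evaluated on the minimum-image
#'   angular distance with the given `period`.
#' @param period CV period (e.g. 2*pi), used when `periodic`.
#' @return object of class `metad_bias`.
#' @export
metad_bias <- function(hills, bias_factor, pace, temperature = 300,
                       periodic = FALSE, period = 2 * pi) {
  hills <- as.data.frame(hills)
  if (nrow(hills) > 0) {
    stopifnot(all(hills$height > 0), all(hills$width > 0))
  }
  if (bias_factor <= 1) stop("bias_factor must be > 1")
  structure(list(hills = hills, bias_factor = bias_factor, pace = pace,
                 temperature = temperature, periodic = periodic,
                 period = period),
            class = "metad_bias")
}

#' @export
print.metad_bias <- function(x, ...) {
  cat(sprintf("<metad_bias> %d hills, gamma=%g, pace=%d, T=%g K\n",
              nrow(x$hills), x$bias_factor, x$pace, x$temperature))
  invisible(x)
}

#' Evaluate the accumulated bias potential
#'
#' V(s) = sum_i h_i exp(-(s - c_i)^2 / (2 w_i^2)); periodic CVs use the
#' minimum-image distance.
#'
#' @param bias a [metad_bias()].
#' @param s CV value(s).
#' @return bias potential, kJ/mol (vectorized over `s`).
#' @export
bias_value <- function(bias, s) {
  h <- bias$hills
  if (nrow(h) == 0L) return(rep(0, length(s)))
  vapply(s, function(si) {
    d <- si - h$center
    if (bias$periodic) {
      d <- d - bias$period * round(d / bias$period)
    }
    sum(h$height * exp(-0.5 * d^2 / h$width^2))
  }, numeric(1))
}

#' Gradient of the bias potential
#' @param bias a [metad_bias()].
#' @param s CV value(s).
#' @return dV/ds, kJ/mol per CV unit.
#' @export
bias_gradient <- function(bias, s) {
  h <- bias$hills
  if (nrow(h) == 0L) return(rep(0, length(s)))
  vapply(s, function(si) {
    d <- si - h$center
    if (bias$periodic) d <- d - bias$period * round(d / bias$period)
    sum(-h$height * d / h$width^2 * exp(-0.5 * d^2 / h$width^2))
  }, numeric(1))
}

#' Run well-tempered metadynamics on a 1-D toy Langevin system
#'
#' The particle evolves by overdamped Langevin dynamics in the chosen
#' potential with the bias force added; the CV is the particle position.
#' Deposited height at step t is height0 * exp(-V(s_t)/(kB * dT)) with
#' dT = (gamma - 1) * T, the standard well-tempered (deposit-time bias)
#' convention. Default parameters follow the enhanced-sampling protocol:
#' height0 10.0 kJ/mol, width 0.3, pace 1000 steps, bias factor 10, 300 K.
#' With `height0 = 0` the run reproduces the unbiased trajectory for the
#' same seed exactly (deposits consume no random numbers).
#'
#' The default friction (5 ps^-1) is higher than the unbiased toy default:
#' the overdamped Euler update is stable only where the local curvature
#' satisfies U'' < 2 gamma / dt, and biased runs push the particle further
#' up the steep quartic walls than unbiased ones do.
#'
#' @param system list describing the potential: either
#'   `list(kind = "double_well", barrier_height =, well_separation =)` or
#'   `list(kind = "harmonic", k =)` (plus optional `x0`).
#' @param n_steps number of integration steps.
#' @param height0 initial Gaussian height, kJ/mol.
#' @param width Gaussian width (CV units).
#' @param pace steps between deposits.
#' @param bias_factor gamma > 1.
#' @param temperature K.
#' @param friction ps^-1.
#' @param dt ps.
#' @param seed integer RNG seed.
#' @param sample_every store every k-th frame (default 10).
#' @return list with `traj` (scalar [trajectory()] of sampled positions) and
#'   `bias` (a [metad_bias()] holding the full hill history).
#' @export
run_wt_metad <- function(system, n_steps, height0 = 10.0, width = 0.3,
                         pace = 1000L, bias_factor = 10, temperature = 300,
                         friction = 5, dt = 0.01, seed = 1L,
                         sample_every = 10L) {
  if (bias_factor <= 1) stop("bias_factor must be > 1")
  kind <- match.arg(system$kind, c("double_well", "harmonic"))
  if (kind == "double_well") {
    pot <- 0L; pa <- system$barrier_height
    pb <- if (is.null(system$well_separation)) 1 else system$well_separation
    x0 <- if (is.null(system$x0)) -pb else system$x0
  } else {
    pot <- 1L; pa <- system$k; pb <- 1
    x0 <- if (is.null(system$x0)) 0 else system$x0
  }
  res <- with_seed(seed,
    metad_langevin_1d(as.integer(n_steps), dt, temperature, friction, pot,
                      pa, pb, x0, height0, width, as.integer(pace),
                      bias_factor, as.integer(sample_every)))
  hills <- if (length(res$hill_center) == 0L) {
    data.frame(center = numeric(0), height = numeric(0), width = numeric(0),
               step = integer(0))
  } else {
    data.frame(center = res$hill_center, height = res$hill_height,
               width = width, step = res$hill_step)
  }
  list(traj = trajectory(matrix(res$x, ncol = 1L), dt = dt * sample_every,
                         kind = "scalar"),
       bias = metad_bias(hills, bias_factor, pace, temperature))
}

#' Well-tempered free-energy estimate from a bias record
#'
#' F_hat(s) = -(gamma/(gamma-1)) V(s) + const, the standard well-tempered
#' estimator, with the constant chosen so that min F_hat = 0 on the grid.
#'
#' @param bias a [metad_bias()] with at least one hill.
#' @param grid CV values at which to evaluate.
#' @return data.frame with columns `s` and `F` (kJ/mol, min 0).
#' @export
estimate_free_energy <- function(bias, grid) {
  if (nrow(bias$hills) < 1L) stop("bias contains no hills")
  g <- bias$bias_factor
  f <- -(g / (g - 1)) * bias_value(bias, grid)
  data.frame(s = grid, F = f - min(f))
}

#' One bias-exchange swap attempt between neighboring replicas
#'
#' Proposes a random neighbor pair (i, i+1) and accepts the configuration
#' swap with the Metropolis probability
#' min(1, exp(-(V_i(x_j) + V_j(x_i) - V_i(x_i) - V_j(x_j)) / kB T)),
#' evaluated from both replicas' biases at both configurations. Identical
#' (or empty) biases therefore always accept.
#'
#' @param replicas list of `list(state = <CV value>, bias = <metad_bias>)`.
#' @param temperature common temperature, K.
#' @return list with `replicas` (states possibly swapped), `pair`
#'   (attempted neighbor pair), `accepted` (logical), `p_accept`.
#' @export
bias_exchange_step <- function(replicas, temperature = 300) {
  if (length(replicas) < 2L) stop("need >= 2 replicas")
  i <- sample.int(length(replicas) - 1L, 1L)
  j <- i + 1L
  xi <- replicas[[i]]$state; xj <- replicas[[j]]$state
  vi <- function(x) bias_value(replicas[[i]]$bias, x)
  vj <- function(x) bias_value(replicas[[j]]$bias, x)
  delta <- (vi(xj) + vj(xi)) - (vi(xi) + vj(xj))
  p <- min(1, exp(-delta / (.kB_kJ * temperature)))
  accepted <- runif(1L) < p
  if (accepted) {
    replicas[[i]]$state <- xj
    replicas[[j]]$state <- xi
  }
  list(replicas = replicas, pair = c(i, j), accepted = accepted,
       p_accept = p)
}

#' Write a hill history in a PLUMED-HILLS-like plain-text format
#' @param bias a [metad_bias()].
#' @param path output path (columns: time, center, width, height, biasf).
#' @param dt time per step, ps (to convert deposit steps to time).
#' @return `path`, invisibly.
#' @export
write_hills <- function(bias, path, dt = 1) {
  h <- bias$hills
  df <- data.frame(time = h$step * dt, center = h$center, sigma = h$width,
                   height = h$height, biasf = bias$bias_factor)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("#! FIELDS time center sigma height biasf", con)
  write.table(format(df, digits = 10, scientific = FALSE, trim = TRUE), con,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a HILLS-style plain-text file
#' @param path file written by [write_hills()].
#' @param pace steps between deposits (metadata; default inferred 1).
#' @param temperature K.
#' @param dt time per step used at write time.
#' @return a [metad_bias()].
#' @export
read_hills <- function(path, pace = 1L, temperature = 300, dt = 1) {
  df <- read.table(path, header = FALSE, comment.char = "#")
  names(df) <- c("time", "center", "sigma", "height", "biasf")
  metad_bias(data.frame(center = df$center, height = df$height,
                        width = df$sigma, step = round(df$time / dt)),
             bias_factor = df$biasf[1L], pace = pace,
             temperature = temperature)
}
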