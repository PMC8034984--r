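#' DPD parameter set
#'
#' Parameters of the dissipative particle dynamics fluid, in standard
#' reduced DPD units: cutoff `rc` is the length unit, particle mass is the
#' mass unit, and the thermostat temperature is fixed at `kBT = 1`. The
#' defaults are the common water-compressibility parametrization:
#' conservative amplitude `a = 25 kBT/rc` at number density `rho = 3`,
#' dissipative coefficient `gamma = 4.5`, timestep `dt = 0.01`. The
#' random-force amplitude is not free: `sigma = sqrt(2 gamma kBT)` by the
#' fluctuation-dissipation pairing, and the weight functions satisfy
#' `omega_D = omega_R^2` with `omega_R(r) = 1 - r/rc`.
#'
#' @param a conservative force amplitude (energy / length).
#' @param gamma dissipative coefficient.
#' @param rc interaction cutoff (DPD length unit).
#' @param rho fluid number density (particles / rc^3).
#' @param box length-3 box edge vector, DPD length units.
#' @param dt timestep, DPD time units.
#' @param kBT thermostat temperature; the DPD energy scale (default 1).
#' @param lambda velocity-prediction parameter of the modified
#'   velocity-Verlet integrator (default 0.5).
#' @param v_cap abort threshold on fluid particle speed (stability guard).
#' @return An object of class `dpd_params`; `sigma` is derived, not free.
#' @export
dpd_params <- function(a = 25, gamma = 4.5, rc = 1, rho = 3,
                       box = c(10, 10, 10), dt = 0.01, kBT = 1,
                       lambda = 0.5, v_cap = 50) {
  stopifnot(a >= 0, gamma >= 0, rc > 0, rho > 0, dt > 0, kBT >= 0,
            length(box) == 3, all(box > 0))
  structure(list(a = a, gamma = gamma, sigma = sqrt(2 * gamma * kBT),
                 rc = rc, rho = rho, box = as.numeric(box), dt = dt,
                 kBT = kBT, lambda = lambda, v_cap = v_cap),
            class = "dpd_params")
}

#' DPD pairwise forces of a configuration (reference implementation)
#'
#' Plain-R evaluation of the three DPD pair forces for every particle of a
#' configuration, under periodic minimum image: the soft conservative
#' repulsion `F_C = a (1 - r/rc) rhat` for `r` below `rc`, the dissipative force
#' `F_D = -gamma omega_R(r)^2 (rhat . v_ij) rhat`, and the random force
#' `F_R = sigma omega_R(r) xi rhat / sqrt(dt)` with one symmetric Gaussian
#' `xi` per pair. Forces are pairwise equal and opposite (Newton's third
#' law), so they sum to zero over the configuration. This is the readable
#' oracle for the compiled engine and for force spot checks; `run_dpd()`
#' uses the compiled loop.
#'
#' @param positions n x 3 matrix.
#' @param velocities n x 3 matrix.
#' @param params a [dpd_params()].
#' @param xi optional n x n symmetric matrix of pair random numbers; 0 turns
#'   the random force off; NULL draws standard normals.
#' @return list with `forces` (n x 3 total per-particle force) and the
#'   per-component totals `conservative`, `dissipative`, `random`.
#' @export
dpd_pair_forces <- function(positions, velocities, params, xi = NULL) {
  positions <- as.matrix(positions); velocities <- as.matrix(velocities)
  n <- nrow(positions)
  if (is.null(xi)) {
    xi <- matrix(0, n, n)
    xi[upper.tri(xi)] <- rnorm(n * (n - 1) / 2)
    xi <- xi + t(xi)
  } else if (length(xi) == 1) {
    xi <- matrix(xi, n, n)
  }
  FC <- FD <- FR <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      rv <- positions[i, ] - positions[j, ]
      rv <- rv - params$box * round(rv / params$box)
      r <- sqrt(sum(rv^2))
      if (r >= params$rc) next
      e <- if (r < 1e-12) c(1, 0, 0) else rv / r
      w <- 1 - r / params$rc
      fc <- params$a * w * e
      fd <- -params$gamma * w^2 * sum(e * (velocities[i, ] - velocities[j, ])) * e
      fr <- params$sigma * w * xi[i, j] / sqrt(params$dt) * e
      FC[i, ] <- FC[i, ] + fc; FC[j, ] <- FC[j, ] - fc
      FD[i, ] <- FD[i, ] + fd; FD[j, ] <- FD[j, ] - fd
      FR[i, ] <- FR[i, ] + fr; FR[j, ] <- FR[j, ] - fr
    }
  }
  list(forces = FC + FD + FR, conservative = FC, dissipative = FD,
       random = FR)
}

#' DPD simulation of a fluid with an embedded rigid body
#'
#' Runs a dissipative particle dynamics fluid (unit-mass particles at
#' density `rho`) with an optional rigid coarse-grained body whose beads are
#' DPD interaction sites of the same type as the fluid. Net force and torque
#' on the body drive its centre of mass and angular momentum; the
#' orientation quaternion is renormalized every step. Integration is the
#' modified velocity-Verlet scheme; pair random numbers are drawn in a fixed
#' pair order from the seeded RNG, so a run is reproducible bit for bit.
#'
#' The body COM is recorded unwrapped (for mean-square displacements); fluid
#' positions are wrapped into the box. Equilibration steps run before
#' recording starts and are excluded from the returned trajectory.
#'
#' @param model a [rigid_body_model()] in DPD length units, or NULL for a
#'   fluid-only run. The body must fit in half the box (minimum image).
#' @param params a [dpd_params()].
#' @param n_steps production steps.
#' @param snapshot_every record every k-th production step.
#' @param equil_steps equilibration steps excluded from output.
#' @param seed integer seed.
#' @param body_mass total body mass in DPD mass units (default: one unit
#'   per bead); `body_mass_scale` multiplies it, for mass-independence
#'   checks.
#' @param body_mass_scale multiplier on the body mass (default 1).
#' @param fluid_pos,fluid_vel optional initial fluid state (matrices); by
#'   default positions are drawn uniformly (the soft potential tolerates
#'   overlap) and velocities from the Maxwell distribution with the net
#'   momentum removed.
#' @return An [rb_trajectory()] in DPD units with extra fields in
#'   `$params`: per-snapshot fluid `temperature`, total `momentum`
#'   (n x 3), and the final fluid state.
#' @export
run_dpd <- function(model = NULL, params = dpd_params(), n_steps = 1000,
                    snapshot_every = 10, equil_steps = 0, seed = 1,
                    body_mass = NULL, body_mass_scale = 1,
                    fluid_pos = NULL, fluid_vel = NULL) {
  stopifnot(inherits(params, "dpd_params"))
  box <- params$box
  body_pos <- matrix(0, 0, 3)
  inertia <- matrix(0, 3, 3)
  if (!is.null(model)) {
    body_pos <- model$positions
    diam <- model_diameter(model)
    if (diam >= min(box) / 2) {
      stop("rigid body larger than half the box: minimum image violated")
    }
    if (min(box) < 2 * diam) {
      warning("box edge below twice the body diameter; ",
              "finite-size effects will be strong")
    }
    if (is.null(body_mass)) body_mass <- nrow(body_pos)
    body_mass <- body_mass * body_mass_scale
    mb <- body_mass / nrow(body_pos)
    inertia <- matrix(0, 3, 3)
    for (i in seq_len(nrow(body_pos))) {
      p <- body_pos[i, ]
      inertia <- inertia + mb * (sum(p^2) * diag(3) - tcrossprod(p))
    }
  } else {
    body_mass <- 0
  }
  out <- with_seed(seed, {
    nf <- round(params$rho * prod(box))
    if (is.null(fluid_pos)) {
      fluid_pos <- cbind(runif(nf, 0, box[1]), runif(nf, 0, box[2]),
                         runif(nf, 0, box[3]))
    }
    nf <- nrow(fluid_pos)
    if (is.null(fluid_vel)) {
      fluid_vel <- matrix(rnorm(3 * nf, sd = sqrt(params$kBT)), nf, 3)
      fluid_vel <- sweep(fluid_vel, 2, colMeans(fluid_vel))
    }
    run_dpd_cpp(fluid_pos, fluid_vel, body_pos, body_mass, inertia,
                com0 = box / 2, quat0 = c(1, 0, 0, 0),
                a = params$a, gamma = params$gamma, sigma = params$sigma,
                rc = params$rc, box = box, dt = params$dt,
                lambda = params$lambda, n_steps = as.integer(n_steps),
                equil_steps = as.integer(equil_steps),
                snapshot_every = as.integer(snapshot_every),
                vcap = params$v_cap)
  })
  if (out$n_zero_dist > 0) {
    message(sprintf("DPD: %d coincident pair(s) perturbed deterministically",
                    as.integer(out$n_zero_dist)))
  }
  times <- out$step * params$dt
  rb_trajectory(times, out$com, out$quat, engine = "dpd", seed = seed,
                units = list(length = "rc", time = "dpd"),
                params = list(dpd = unclass(params), n_steps = n_steps,
                              equil_steps = equil_steps,
                              body_mass = body_mass,
                              temperature = out$temperature,
                              momentum = out$momentum,
                              fluid_pos = out$fluid_pos,
                              fluid_vel = out$fluid_vel))
}
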