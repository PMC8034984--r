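#' Overdamped rigid-body Brownian dynamics
#'
#' Fast surrogate generator of rigid-body trajectories with the same
#' statistical structure as a hydrodynamic simulation: anisotropic,
#' shape-coupled translational and rotational diffusion. Each step draws a
#' 6-vector Gaussian displacement with covariance `2 * D * dt` in the
#' current body frame (translation then rotation), applies the translation
#' in the lab frame through the current orientation and composes the
#' rotation via the quaternion exponential map, renormalizing every step.
#' Because the diffusion tensor is fixed in the body frame, lab-frame
#' translational increments correlate with the orientation history - exactly
#' the translation-rotation coupling whose neglect the decoupling
#' approximations introduce.
#'
#' The overdamped limit is appropriate above the momentum relaxation time,
#' where centre-of-mass motion is already diffusive; inertial behaviour
#' below that time is the domain of [run_langevin_point()] and [run_dpd()].
#'
#' @param model a [rigid_body_model()] (metadata; the propagator needs only
#'   the tensor).
#' @param D a [diffusion_tensor()] in the body frame. Units set the
#'   trajectory units (e.g. Angstrom^2/ns and rad^2/ns with `dt` in ns).
#' @param dt time step. Must satisfy `sqrt(2 tr(rr) dt) < 0.2` rad so the
#'   exponential-map rotation step stays accurate; enforced.
#' @param n_steps number of steps.
#' @param seed integer seed; the trajectory is deterministic for a fixed
#'   seed.
#' @param snapshot_every store every k-th step (default 1).
#' @param com0,quat0 initial state.
#' @return An [rb_trajectory()] with `n_steps / snapshot_every + 1` frames.
#' @export
run_bd <- function(model, D, dt, n_steps, seed = 1, snapshot_every = 1,
                   com0 = c(0, 0, 0), quat0 = c(1, 0, 0, 0)) {
  stopifnot(inherits(D, "diffusion_tensor"))
  if (dt <= 0) stop("dt must be positive")
  if (n_steps < 0) stop("n_steps must be non-negative")
  rot_rms <- sqrt(2 * sum(diag(D$rr)) * dt)
  if (rot_rms >= 0.2) {
    stop(sprintf(paste0("rotational step RMS %.3f rad exceeds 0.2; ",
                        "reduce dt below %.3g"), rot_rms,
                 0.2^2 / (2 * sum(diag(D$rr)))))
  }
  D6 <- assemble_tensor6(D)
  # PSD was checked at tensor construction; pivoted Cholesky handles
  # semi-definite blocks (e.g. rr = 0 for translation-only motion)
  ch <- suppressWarnings(chol(2 * D6 * dt, pivot = TRUE))
  piv <- attr(ch, "pivot")
  r <- attr(ch, "rank")
  L <- matrix(0, 6, 6)
  L[piv, seq_len(6)] <- t(ch)
  if (r < 6) L[, (r + 1):6] <- 0
  out <- with_seed(seed, run_bd_cpp(L, com0, quat0, as.integer(n_steps),
                                    as.integer(snapshot_every)))
  times <- seq(0, by = dt * snapshot_every, length.out = nrow(out$com))
  rb_trajectory(times, out$com, out$quat, engine = "bd", seed = seed,
                params = list(dt = dt, n_steps = n_steps,
                              snapshot_every = snapshot_every,
                              D0 = mean(diag(D$tt)), Dr = mean(diag(D$rr))))
}

#' Inertial Langevin dynamics of a free point particle
#'
#' Underdamped Langevin integration of a free particle of mass `m` with
#' friction `gamma` at temperature `kBT`, used to exercise the
#' ballistic-to-diffusive crossover of the mean-square displacement at the
#' momentum relaxation time `tau_B = m / gamma`. The velocity
#' Ornstein-Uhlenbeck process is sampled exactly each step (symmetric
#' splitting), so equipartition `<v_x^2> = kBT/m` holds at any `dt`; the
#' position integrates the velocity with `dt < tau_B / 10` enforced to
#' resolve the crossover.
#'
#' @param mass particle mass.
#' @param gamma friction coefficient (force * time / length); `gamma = 0`
#'   gives free ballistic flight.
#' @param kBT thermal energy (default 1).
#' @param dt time step.
#' @param n_steps number of steps.
#' @param seed integer seed.
#' @param v0 initial velocity vector, or a scalar initial speed along a
#'   random direction, or NULL for a Maxwell draw.
#' @param snapshot_every store every k-th step.
#' @return An [rb_trajectory()] (identity orientation) with COM positions
#'   and velocities.
#' @export
run_langevin_point <- function(mass, gamma, kBT = 1, dt, n_steps, seed = 1,
                               v0 = NULL, snapshot_every = 1) {
  if (mass <= 0) stop("mass must be positive")
  if (gamma < 0) stop("gamma must be non-negative")
  if (dt <= 0) stop("dt must be positive")
  if (gamma > 0 && dt >= mass / gamma / 10) {
    stop("dt must be below tau_B / 10 = mass / gamma / 10")
  }
  out <- with_seed(seed, {
    vv <- if (is.null(v0)) {
      rnorm(3, sd = sqrt(kBT / mass))
    } else if (length(v0) == 1) {
      u <- rnorm(3); v0 * u / sqrt(sum(u^2))
    } else as.numeric(v0)
    run_langevin_cpp(mass, gamma, kBT, dt, as.integer(n_steps), vv,
                     as.integer(snapshot_every))
  })
  times <- seq(0, by = dt * snapshot_every, length.out = nrow(out$pos))
  rb_trajectory(times, out$pos, NULL, velocities = out$vel,
                engine = "langevin", seed = seed,
                params = list(mass = mass, gamma = gamma, kBT = kBT, dt = dt,
                              tau_B = if (gamma > 0) mass / gamma else Inf))
}
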