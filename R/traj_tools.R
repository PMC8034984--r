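#' Decompose a bead trajectory into centre-of-mass and rotational parts
#'
#' Splits the overall motion `r_i(t)` into the centre-of-mass track
#' `r_com(t) = r_c(t)` and the COM-removed bead cloud
#' `r_i,rot(t) = r_i(t) - r_c(t)`, so that the original positions recombine
#' exactly as `r_i(t) = r_c(t) + r_i,rot(t)`.
#'
#' @param x either a numeric array of bead positions with dimension
#'   `c(n_frames, n_beads, 3)`, or an [rb_trajectory()] (then `model` must
#'   be given and beads are reconstructed first).
#' @param model a [rigid_body_model()]; required when `x` is a trajectory.
#'   Its masses weight the centre of mass (equal masses by default).
#' @return list with `com` (n x 3 matrix) and `rot` (n x N x 3 array).
#' @export
decompose_trajectory <- function(x, model = NULL) {
  if (inherits(x, "rb_trajectory")) {
    if (is.null(model)) stop("model required to reconstruct bead positions")
    x <- reconstruct_beads(x, model)
  }
  stopifnot(is.array(x), length(dim(x)) == 3, dim(x)[3] == 3)
  n <- dim(x)[1]; N <- dim(x)[2]
  w <- if (is.null(model)) rep(1 / N, N) else model$masses / sum(model$masses)
  com <- matrix(NA_real_, n, 3)
  rot <- x
  for (f in seq_len(n)) {
    com[f, ] <- colSums(x[f, , , drop = TRUE] * w)
    rot[f, , ] <- sweep(x[f, , , drop = TRUE], 2, com[f, ])
  }
  list(com = com, rot = rot)
}

#' Multi-time-origin mean square displacement
#'
#' `<r^2(lag)>` of a track, averaged over time origins. Origins are strided
#' (default every 10 frames) to bound the quadratic cost; the lag grid is
#' log-spaced by default so the ballistic and diffusive regimes carry
#' similar weight in later fits.
#'
#' @param x an [rb_trajectory()] (its COM track is used) or an n x 3 matrix.
#' @param times time vector when `x` is a matrix (uniform grid).
#' @param origin_stride use every k-th frame as a time origin (default 10).
#' @param lags integer vector of frame lags, or NULL for a log-spaced grid
#'   up to half the trajectory.
#' @param n_lags size of the default log-spaced grid.
#' @return data frame of class `msd_curve`: `lag_time`, `msd`, `n_pairs`.
#' @export
msd <- function(x, times = NULL, origin_stride = 10, lags = NULL,
                n_lags = 60) {
  if (inherits(x, "rb_trajectory")) {
    times <- x$times
    x <- x$com
  }
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(times)) times <- seq_len(n) - 1
  if (n < 2) stop("need at least two frames")
  if (is.null(lags)) {
    lags <- unique(round(exp(seq(0, log(max(1, n %/% 2)),
                                 length.out = n_lags))))
  }
  lags <- sort(unique(c(0L, as.integer(lags))))
  lags <- lags[lags < n]
  origins <- seq(1L, n, by = as.integer(origin_stride)) - 1L
  m <- msd_cpp(x, origins, lags)
  out <- data.frame(lag_time = times[lags + 1] - times[1],
                    msd = m[, 1], n_pairs = as.integer(m[, 2]))
  class(out) <- c("msd_curve", "data.frame")
  out
}

#' Analytic mean square displacement of a free Langevin particle
#'
#' Three-dimensional MSD of a free underdamped Langevin particle with fixed
#' initial speed `nu0`, friction `gamma`, mass `m = gamma * tau_B`:
#' \deqn{\langle r^2(t)\rangle = \tau_B^2 (1 - e^{-t/\tau_B})^2
#'   (\nu_0^2 - 3 k_B T/m) + (6 k_B T/\gamma)\,[t - \tau_B(1 - e^{-t/\tau_B})]}
#' derived from the velocity Ornstein-Uhlenbeck process. Limits:
#' `nu0^2 t^2` (ballistic) as `t -> 0` and slope `6 kBT / gamma`
#' (diffusive) as `t -> Inf`.
#'
#' @param t time (vector).
#' @param tau_B momentum relaxation time `m / gamma`.
#' @param gamma friction coefficient.
#' @param nu0 initial speed.
#' @param kBT thermal energy.
#' @return numeric vector of MSD values.
#' @export
msd_langevin_model <- function(t, tau_B, gamma, nu0, kBT = 1) {
  m <- gamma * tau_B
  e <- exp(-t / tau_B)
  tau_B^2 * (1 - e)^2 * (nu0^2 - 3 * kBT / m) +
    (6 * kBT / gamma) * (t - tau_B * (1 - e))
}

#' Fit the Langevin MSD model to an MSD curve
#'
#' Nonlinear least squares of [msd_langevin_model()] to a measured MSD,
#' recovering the momentum relaxation time `tau_B`, the friction
#' coefficient `gamma` and the initial speed `nu0`; the noise amplitude is
#' fixed by the fluctuation-dissipation relation `g = 2 gamma kBT` (per
#' dimension) and is not a free parameter. The curve should cover both the
#' ballistic region (`t < tau_B`) and the diffusive region (`t >> tau_B`);
#' with a purely diffusive input the ballistic parameters are not
#' identifiable and the fit is flagged degenerate.
#'
#' Weighting is uniform over the (log-spaced) lag grid, which balances the
#' two regimes.
#'
#' @param msd_curve a data frame from [msd()] (columns `lag_time`, `msd`).
#' @param kBT thermal energy (default 1).
#' @param mass if supplied, `gamma` is constrained to `mass / tau_B`.
#' @param fit_window optional `c(t_min, t_max)` restriction.
#' @return list of class `msd_fit`: `tau_B`, `gamma`, `nu0`, `mass`, `g`,
#'   `D_long` (= kBT/gamma), `cov`, `window`, `degenerate`, `fit`.
#' @export
fit_langevin_msd <- function(msd_curve, kBT = 1, mass = NULL,
                             fit_window = NULL) {
  df <- as.data.frame(msd_curve)
  df <- df[df$lag_time > 0 & is.finite(df$msd), , drop = FALSE]
  if (!is.null(fit_window)) {
    df <- df[df$lag_time >= fit_window[1] & df$lag_time <= fit_window[2], ,
             drop = FALSE]
  }
  if (nrow(df) < 5) stop("too few MSD points to fit")
  t <- df$lag_time; y <- df$msd
  # starts: diffusive slope from the last third, ballistic speed from the
  # first points, tau_B from their crossing
  ilate <- t >= stats::quantile(t, 2 / 3)
  slope <- unname(coef(lm(y[ilate] ~ t[ilate]))[2])
  if (!is.finite(slope) || slope <= 0) slope <- max(y) / max(t)
  gamma0 <- 6 * kBT / slope
  nu00 <- sqrt(max(y[1] / t[1]^2, 1e-12))
  tau0 <- max(min(slope / max(nu00^2, 1e-12), max(t) / 3), min(t) / 2)
  # relative residuals: equalizes the ballistic (tiny MSD) and diffusive
  # (large MSD) regimes on the log-spaced lag grid
  w <- 1 / y^2
  fit <- tryCatch(if (is.null(mass)) {
    minpack.lm::nlsLM(
      y ~ msd_langevin_model(t, tau_B, gamma, nu0, kBT),
      start = list(tau_B = tau0, gamma = gamma0, nu0 = nu00),
      lower = c(tau_B = min(t) / 100, gamma = 1e-12, nu0 = 0),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 500))
  } else {
    minpack.lm::nlsLM(
      y ~ msd_langevin_model(t, tau_B, mass / tau_B, nu0, kBT),
      start = list(tau_B = tau0, nu0 = nu00),
      lower = c(tau_B = min(t) / 100, nu0 = 0),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 500))
  }, error = function(e) {
    stop("Langevin MSD fit degenerate or non-convergent (",
         conditionMessage(e),
         "); a purely diffusive input has no resolvable tau_B")
  })
  cf <- coef(fit)
  tau_B <- unname(cf["tau_B"])
  gamma <- if (is.null(mass)) unname(cf["gamma"]) else mass / tau_B
  if (tau_B <= 0 || gamma <= 0) stop("fit returned non-positive tau_B or gamma")
  degenerate <- tau_B <= 2 * min(t)
  if (degenerate) {
    warning("fitted tau_B is below the time resolution: ",
            "ballistic regime not resolved; fit is degenerate")
  }
  structure(list(tau_B = tau_B, gamma = gamma, nu0 = unname(cf["nu0"]),
                 mass = gamma * tau_B, g = 2 * gamma * kBT,
                 D_long = kBT / gamma, cov = vcov(fit),
                 window = range(t), degenerate = degenerate, fit = fit),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf(paste0("Langevin MSD fit: tau_B = %.4g, gamma = %.4g, ",
                     "nu0 = %.4g, D = kBT/gamma = %.4g%s\n"),
              x$tau_B, x$gamma, x$nu0, x$D_long,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Write an MSD curve as CSV
#' @param msd_curve data frame from [msd()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_msd <- function(msd_curve, path) {
  utils::write.csv(as.data.frame(msd_curve), path, row.names = FALSE)
  invisible(path)
}
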