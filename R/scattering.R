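#' Coherent intermediate scattering functions of a rigid-body trajectory
#'
#' The coherent ISF measured by Neutron Spin Echo for a single particle,
#' after orientational averaging, reduces to a double sum over bead pairs
#' with the spherical kernel,
#' \deqn{I(Q,t) = \langle \sum_{m,n} b_m b_n\,
#'   \mathrm{sinc}\!\big(Q\,|r_m(t_0) - r_n(t_0+t)|\big) \rangle_{t_0},}
#' normalized by its lag-0 value. The four components differ only in which
#' part of the motion enters the cross-time distance:
#' \describe{
#'   \item{total}{full bead positions (COM + rotation) at both times.}
#'   \item{com}{centre of mass only: `<sinc(Q |dr_c(t)|)>`.}
#'   \item{rot}{COM-removed bead cloud at both times (pure rotation; for a
#'     rigid body this is the intra-particle ISF).}
#'   \item{trans}{structure-weighted translation: the orientation is frozen
#'     at the time origin while the COM moves, so the COM correlator is
#'     weighted by the frozen-orientation form-factor amplitude.}
#' }
#' A single-origin estimate is noisy for trajectories of modest length, so
#' the sum is averaged over strided time origins; every origin must
#' accommodate the largest lag.
#'
#' @param traj an [rb_trajectory()].
#' @param model a [rigid_body_model()] (body-frame beads and scattering
#'   lengths). Not needed for `isf_com`.
#' @param Q numeric vector of wavevector magnitudes (> 0; inverse length in
#'   the trajectory's units).
#' @param lags integer vector of frame lags (lag 0 is added automatically
#'   for normalization), or NULL for a default grid.
#' @param origin_stride spacing between time origins, frames. The default
#'   aims at >= 100 origins.
#' @param n_lags size of the default lag grid.
#' @return A data frame of class `isf_curve` in long format with columns
#'   `component`, `Q`, `lag`, `value` (normalized to 1 at lag 0),
#'   `n_origins`, and attribute `dt`.
#' @name isf
NULL

# shared front end: resolve lags/origins, call the compiled kernel, normalize
.isf_run <- function(traj, model, Q, lags, origin_stride, n_lags, mode,
                     component) {
  n <- n_frames(traj)
  if (n < 2) stop("trajectory too short for an ISF")
  if (any(Q < 0)) stop("Q must be non-negative")
  if (is.null(lags)) {
    lags <- unique(round(exp(seq(0, log(max(1, n %/% 4)),
                                 length.out = n_lags))))
  }
  lags <- sort(unique(c(0L, as.integer(lags))))
  drop <- lags >= n
  if (any(drop)) {
    warning(sprintf("%d lag(s) beyond the trajectory length dropped",
                    sum(drop)))
    lags <- lags[!drop]
  }
  if (is.null(origin_stride)) {
    origin_stride <- max(1L, (n - max(lags)) %/% 100L)
  }
  origins <- seq(1L, n - max(lags), by = as.integer(origin_stride)) - 1L
  if (length(origins) == 0) stop("no usable time origins for the given lags")
  raw <- if (mode < 0) {
    isf_com_cpp(traj$com, origins, lags, Q)
  } else {
    isf_pairsum_cpp(model$positions, model$scattering_lengths, traj$com,
                    traj$quat, origins, lags, Q, as.integer(mode))
  }
  norm <- raw[, 1] # lag 0 column
  vals <- raw / norm
  out <- data.frame(component = component,
                    Q = rep(Q, times = length(lags)),
                    lag = rep(traj$times[lags + 1] - traj$times[1],
                              each = length(Q)),
                    value = as.vector(vals),
                    n_origins = length(origins))
  attr(out, "dt") <- frame_dt(traj)
  class(out) <- c("isf_curve", "data.frame")
  out
}

#' @rdname isf
#' @export
isf_total <- function(traj, model, Q, lags = NULL, origin_stride = NULL,
                      n_lags = 25) {
  .isf_run(traj, model, Q, lags, origin_stride, n_lags, 0L, "total")
}

#' @rdname isf
#' @export
isf_com <- function(traj, Q, lags = NULL, origin_stride = NULL,
                    n_lags = 25) {
  if (!inherits(traj, "rb_trajectory")) {
    traj <- rb_trajectory(seq_len(nrow(traj)) - 1, traj)
  }
  .isf_run(traj, NULL, Q, lags, origin_stride, n_lags, -1L, "com")
}

#' @rdname isf
#' @export
isf_rot <- function(traj, model, Q, lags = NULL, origin_stride = NULL,
                    n_lags = 25) {
  .isf_run(traj, model, Q, lags, origin_stride, n_lags, 1L, "rot")
}

#' @rdname isf
#' @export
isf_trans_weighted <- function(traj, model, Q, lags = NULL,
                               origin_stride = NULL, n_lags = 25) {
  .isf_run(traj, model, Q, lags, origin_stride, n_lags, 2L, "trans")
}

#' All four ISF components of one trajectory
#'
#' Convenience wrapper returning the row-bound [isf] components on a shared
#' lag and origin grid.
#'
#' @inheritParams isf
#' @param components subset of `c("total", "com", "rot", "trans")`.
#' @return long `isf_curve` data frame.
#' @export
isf_all <- function(traj, model, Q, lags = NULL, origin_stride = NULL,
                    n_lags = 25,
                    components = c("total", "com", "rot", "trans")) {
  pieces <- list()
  if ("total" %in% components) {
    pieces$total <- isf_total(traj, model, Q, lags, origin_stride, n_lags)
  }
  if ("com" %in% components) {
    pieces$com <- isf_com(traj, Q, lags, origin_stride, n_lags)
  }
  if ("rot" %in% components) {
    pieces$rot <- isf_rot(traj, model, Q, lags, origin_stride, n_lags)
  }
  if ("trans" %in% components) {
    pieces$trans <- isf_trans_weighted(traj, model, Q, lags, origin_stride,
                                       n_lags)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "dt") <- attr(pieces[[1]], "dt")
  class(out) <- c("isf_curve", "data.frame")
  out
}

#' Add the reduced-time axis D0 Q^2 t to an ISF table
#'
#' On the reduced axis `D0 Q^2 t` the ISFs of a rigid spherical particle at
#' all Q collapse onto `exp(-D0 Q^2 t)`; departures from that collapse are
#' the signature of shape anisotropy.
#'
#' @param isf an `isf_curve` data frame.
#' @param D0 free diffusion coefficient in matching units.
#' @return the data frame with an extra `reduced_time` column.
#' @export
add_reduced_time <- function(isf, D0) {
  isf$reduced_time <- D0 * isf$Q^2 * isf$lag
  isf
}

#' Characteristic diffusion time tau_c
#'
#' Time for a particle to diffuse a distance of its own diameter,
#' `tau_c = sigma^2 / (6 D0)`. ISF values are only reproducible between
#' independent finite trajectories for `t / tau_c` small; the paper-scale
#' analogue is a run of ~0.5 tau_c with agreement up to `t/tau_c ~ 0.003`.
#'
#' @param sigma effective particle diameter (length units), e.g.
#'   [model_diameter()].
#' @param D0 free diffusion coefficient.
#' @return tau_c in matching time units.
#' @export
characteristic_time <- function(sigma, D0) sigma^2 / (6 * D0)

#' Write an ISF table as CSV
#' @param isf an `isf_curve` data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_isf <- function(isf, path) {
  utils::write.csv(as.data.frame(isf), path, row.names = FALSE)
  invisible(path)
}
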