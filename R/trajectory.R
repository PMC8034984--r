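#' Rigid-body trajectory container
#'
#' Time series of centre-of-mass position and orientation of a rigid body,
#' sampled on a uniform time grid. The orientation is a unit quaternion
#' (w, x, y, z) mapping body-frame to lab-frame coordinates; the COM track is
#' unwrapped (no periodic jumps), which is what mean-square displacements and
#' ISFs need.
#'
#' @param times numeric vector, strictly increasing, uniformly spaced.
#' @param com n x 3 matrix of COM positions (length units).
#' @param quat n x 4 matrix of unit quaternions; NULL for a non-rotating
#'   track (identity orientation).
#' @param velocities optional n x 3 matrix of COM velocities (inertial
#'   engines only).
#' @param engine one of `"dpd"`, `"bd"`, `"langevin"`, `"external"`.
#' @param seed integer seed used to generate the trajectory (metadata).
#' @param units list of unit metadata, e.g. `list(length = "A",
#'   time = "ns")`; DPD trajectories are in reduced DPD units.
#' @param params engine parameters (metadata, carried into outputs).
#' @return An object of class `rb_trajectory`.
#' @export
rb_trajectory <- function(times, com, quat = NULL, velocities = NULL,
                          engine = "external", seed = NA_integer_,
                          units = list(length = "A", time = "ns"),
                          params = list()) {
  times <- as.numeric(times)
  com <- as.matrix(com)
  n <- length(times)
  stopifnot(nrow(com) == n, ncol(com) == 3)
  if (n > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("times must be strictly increasing")
    if (max(abs(dt - dt[1])) > 1e-8 * max(dt[1], 1e-300)) {
      stop("times must be uniformly spaced")
    }
  }
  if (is.null(quat)) {
    quat <- matrix(rep(c(1, 0, 0, 0), each = n), n, 4)
  }
  quat <- as.matrix(quat)
  stopifnot(nrow(quat) == n, ncol(quat) == 4)
  qn <- sqrt(rowSums(quat^2))
  if (any(abs(qn - 1) > 1e-9)) stop("orientation quaternions must be unit norm")
  structure(
    list(times = times, com = unname(com), quat = unname(quat),
         velocities = if (is.null(velocities)) NULL else unname(as.matrix(velocities)),
         engine = engine, seed = seed, units = units, params = params),
    class = "rb_trajectory")
}

#' @export
print.rb_trajectory <- function(x, ...) {
  cat(sprintf("rb_trajectory [%s]: %d frames, dt = %.4g %s, seed = %s\n",
              x$engine, length(x$times),
              if (length(x$times) > 1) diff(x$times)[1] else NA,
              x$units$time, x$seed))
  invisible(x)
}

#' Number of frames and time step
#' @param traj an [rb_trajectory()].
#' @return scalar.
#' @export
n_frames <- function(traj) length(traj$times)

#' @rdname n_frames
#' @export
frame_dt <- function(traj) {
  if (n_frames(traj) < 2) return(NA_real_)
  traj$times[2] - traj$times[1]
}

# rotation matrices (body -> lab) for selected frames
quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Reconstruct lab-frame bead positions from a trajectory and a model
#'
#' @param traj an [rb_trajectory()].
#' @param model a [rigid_body_model()] giving body-frame bead coordinates.
#' @param frames integer frame indices (default all).
#' @return numeric array of dimension `c(n_frames, n_beads, 3)`.
#' @export
reconstruct_beads <- function(traj, model, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(traj))
  p <- model$positions
  out <- array(NA_real_, c(length(frames), nrow(p), 3))
  for (k in seq_along(frames)) {
    f <- frames[k]
    R <- quat_to_matrix(traj$quat[f, ])
    out[k, , ] <- sweep(p %*% t(R), 2, traj$com[f, ], "+")
  }
  out
}

#' Write / read a trajectory as CSV plus a JSON metadata sidecar
#'
#' The CSV holds columns `time, com_x, com_y, com_z, quat_w, quat_x, quat_y,
#' quat_z` (plus velocities when present); `<path>.json` records engine,
#' seed, units and parameters so a trajectory round-trips exactly.
#'
#' @param traj an [rb_trajectory()].
#' @param path CSV file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns the reconstructed [rb_trajectory()].
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time = traj$times,
                   com_x = traj$com[, 1], com_y = traj$com[, 2],
                   com_z = traj$com[, 3],
                   quat_w = traj$quat[, 1], quat_x = traj$quat[, 2],
                   quat_y = traj$quat[, 3], quat_z = traj$quat[, 4])
  if (!is.null(traj$velocities)) {
    df$vel_x <- traj$velocities[, 1]
    df$vel_y <- traj$velocities[, 2]
    df$vel_z <- traj$velocities[, 3]
  }
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(engine = traj$engine, seed = traj$seed, units = traj$units,
               params = traj$params)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path)
  metafile <- paste0(path, ".json")
  meta <- if (file.exists(metafile)) {
    jsonlite::read_json(metafile, simplifyVector = TRUE)
  } else list(engine = "external", seed = NA, units = list(length = "A", time = "ns"),
              params = list())
  vel <- if (all(c("vel_x", "vel_y", "vel_z") %in% names(df))) {
    as.matrix(df[, c("vel_x", "vel_y", "vel_z")])
  } else NULL
  rb_trajectory(df$time,
                as.matrix(df[, c("com_x", "com_y", "com_z")]),
                as.matrix(df[, c("quat_w", "quat_x", "quat_y", "quat_z")]),
                velocities = vel,
                engine = meta$engine,
                seed = if (is.null(meta$seed)) NA_integer_ else meta$seed,
                units = as.list(meta$units), params = as.list(meta$params))
}
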