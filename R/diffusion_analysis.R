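#' Short-time effective diffusion coefficient Deff(Q) from an ISF
#'
#' `Deff(Q) = -(1/Q^2) d ln I(Q,t) / dt` at short times, estimated per Q by
#' a linear fit of `ln I` against lag over a fit window. The window should
#' start above the momentum relaxation time (so the motion is diffusive,
#' not ballistic) and end well inside the region where independent
#' trajectories still agree (small `t / tau_c`); both bounds are the
#' caller's responsibility and the window actually used is recorded.
#'
#' @param isf an `isf_curve` data frame (a single component, or a multi-
#'   component table - each component is fitted separately).
#' @param fit_window `c(t_min, t_max)` in the ISF's time units.
#' @param tau_B optional momentum relaxation time; if given, `t_min` is
#'   checked against it.
#' @return data frame of class `deff_curve`: `component`, `Q`, `Deff`,
#'   `se`, `n_pts`; attribute `fit_window`.
#' @export
extract_deff <- function(isf, fit_window, tau_B = NULL) {
  stopifnot(length(fit_window) == 2, fit_window[1] < fit_window[2])
  if (!is.null(tau_B) && fit_window[1] < tau_B) {
    warning("fit window starts below tau_B: short-time fit may pick up ",
            "ballistic motion")
  }
  df <- as.data.frame(isf)
  pieces <- lapply(split(df, df[, c("component", "Q")], drop = TRUE),
                   function(d) {
    d <- d[d$lag >= fit_window[1] & d$lag <= fit_window[2], , drop = FALSE]
    if (nrow(d) < 3) {
      stop(sprintf("component %s, Q = %g: fewer than 3 lag points in window",
                   d$component[1], d$Q[1]))
    }
    if (any(d$value <= 0)) {
      stop(sprintf(paste0("component %s, Q = %g: ISF non-positive in the ",
                          "fit window (log undefined)"),
                   d$component[1], d$Q[1]))
    }
    f <- lm(log(value) ~ lag, data = d)
    q <- d$Q[1]
    # exact inputs give a perfect fit; the se is then 0, not unreliable
    sm <- suppressWarnings(summary(f))
    data.frame(component = d$component[1], Q = q,
               Deff = -coef(f)[2] / q^2,
               se = sm$coefficients[2, 2] / q^2,
               n_pts = nrow(d))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out <- out[order(out$component, out$Q), ]
  attr(out, "fit_window") <- fit_window
  class(out) <- c("deff_curve", "data.frame")
  out
}

# Gauss-Legendre x uniform-azimuth nodes on the unit sphere
.sphere_nodes <- function(order) {
  gl <- pracma::gaussLegendre(order, -1, 1)
  nphi <- 2 * order
  phi <- (seq_len(nphi) - 0.5) * 2 * pi / nphi
  ct <- rep(gl$x, each = nphi)
  st <- sqrt(pmax(0, 1 - ct^2))
  w <- rep(gl$w, each = nphi) / (2 * nphi)
  list(dirs = cbind(st * cos(phi), st * sin(phi), ct), w = w)
}

#' Theoretical structure-weighted translational diffusion coefficient
#'
#' Orientational average over the unit sphere of the squared form-factor
#' amplitude times the directional translational diffusion coefficient,
#' \deqn{D_{trans}(Q) = \langle |F(Q\hat{Q})|^2\, (\hat{Q}\cdot D_{tt}\cdot
#'   \hat{Q}) \rangle_\theta / P(Q),}
#' evaluated by deterministic Gauss-Legendre quadrature in `cos(theta)`
#' times a uniform azimuthal grid. The quadrature order is doubled until
#' the result changes by less than 0.1% (or `max_order` is hit, an error).
#' For an isotropic tensor the weight factors out and `Dtrans(Q) = D0`
#' exactly; as `Q -> 0`, `F` becomes flat and `Dtrans -> tr(tt)/3`.
#'
#' @param model a [rigid_body_model()].
#' @param D a [diffusion_tensor()]; by default only the `tt` block enters.
#' @param Q numeric vector of wavevector magnitudes.
#' @param quadrature_order starting Gauss-Legendre order (>= 4).
#' @param rtol convergence tolerance on order doubling (default 1e-3).
#' @param max_order hard cap on the doubled order.
#' @return data frame: `Q`, `Dtrans`, plus attribute `order` (the order at
#'   which convergence was declared).
#' @export
dtrans_theoretical <- function(model, D, Q, quadrature_order = 16,
                               rtol = 1e-3, max_order = 256) {
  stopifnot(inherits(D, "diffusion_tensor"))
  if (quadrature_order < 4) stop("quadrature_order must be at least 4")
  eval_order <- function(order) {
    nd <- .sphere_nodes(order)
    dirs <- nd$dirs
    w <- nd$w
    dq <- rowSums((dirs %*% D$tt) * dirs) # Qhat . tt . Qhat
    p <- model$positions
    b <- model$scattering_lengths
    vapply(Q, function(q) {
      ph <- p %*% t(q * dirs) # N x n_nodes phases
      f2 <- (as.vector(b %*% cos(ph)))^2 + (as.vector(b %*% sin(ph)))^2
      sum(w * f2 * dq) / sum(w * f2)
    }, numeric(1))
  }
  order <- quadrature_order
  cur <- eval_order(order)
  repeat {
    if (2 * order > max_order) {
      stop(sprintf("sphere quadrature not converged at order %d", order))
    }
    nxt <- eval_order(2 * order)
    if (max(abs(nxt - cur) / pmax(abs(nxt), 1e-300)) < rtol) {
      out <- data.frame(Q = Q, Dtrans = nxt)
      attr(out, "order") <- 2 * order
      return(out)
    }
    order <- 2 * order
    cur <- nxt
  }
}

#' Normalize Deff curves by the free diffusion coefficient D0
#'
#' `D0` is taken as the structure-weighted translational coefficient at the
#' reference Q (default 0.01 inverse length units, effectively the
#' infinitesimal-Q diffusion coefficient); if no `trans` component is
#' present the `com` component supplies it.
#'
#' @param deff a `deff_curve` data frame (any set of components).
#' @param Q_ref reference Q at which D0 is read (must be on the grid).
#' @param D0 override: use this value instead of reading it off the curve.
#' @return list with `curves` (the input plus a `Deff_norm` column) and
#'   `D0` (with a `source` attribute).
#' @export
normalize_by_D0 <- function(deff, Q_ref = 0.01, D0 = NULL) {
  df <- as.data.frame(deff)
  src <- "user"
  if (is.null(D0)) {
    comp <- if ("trans" %in% df$component) "trans" else "com"
    hit <- df$component == comp & abs(df$Q - Q_ref) < 1e-9
    if (!any(hit)) {
      stop(sprintf("reference Q = %g not on the %s grid (available: %s)",
                   Q_ref, comp,
                   paste(signif(sort(unique(df$Q)), 3), collapse = ", ")))
    }
    D0 <- mean(df$Deff[hit])
    src <- sprintf("%s component at Q = %g", comp, Q_ref)
  }
  df$Deff_norm <- df$Deff / D0
  attr(D0, "source") <- src
  cl <- class(deff)
  class(df) <- if ("deff_curve" %in% cl) cl else c("deff_curve", "data.frame")
  list(curves = df, D0 = D0)
}

#' Quantify the translation-rotation decoupling errors
#'
#' Builds the comparison at the heart of the analysis: per Q, the relative
#' error of the centre-of-mass decoupling `Dtotal ~ Dcom + Drot`
#' (`err_com = (Dcom + Drot - Dtotal)/Dtotal`) and of the structure-
#' weighted decoupling `Dtotal ~ Dtrans + Drot`
#' (`err_trans = (Dtrans + Drot - Dtotal)/Dtotal`). With replicate seeds the
#' per-seed errors are averaged and their min-max spread reported; the
#' factorization residuals `max_t |I_total - I_com * I_rot|` (and the trans
#' analogue) are added when an ISF table is supplied.
#'
#' @param deff a `deff_curve` data frame containing components `total`,
#'   `com`, `rot` and (optionally) `trans`, with an optional `seed` column
#'   for replicates. `Dtrans` may instead be supplied via `dtrans`.
#' @param dtrans optional data frame `Q`, `Dtrans` from
#'   [dtrans_theoretical()] (used for every seed).
#' @param isf optional multi-component `isf_curve` table (with optional
#'   `seed` column) for the factorization residuals.
#' @return object of class `decoupling_report`: list with `table` (per-Q
#'   means and spreads), `summary` (max |error| and its arg-max Q),
#'   `residuals` (or NULL), `n_seeds`.
#' @export
compare_decoupling <- function(deff, dtrans = NULL, isf = NULL) {
  df <- as.data.frame(deff)
  if (!"seed" %in% names(df)) df$seed <- 1L
  need <- c("total", "com", "rot")
  if (!all(need %in% df$component)) {
    stop("deff must contain components total, com and rot")
  }
  wide_of <- function(d) {
    qs <- sort(unique(d$Q))
    get <- function(comp) {
      sub <- d[d$component == comp, ]
      if (nrow(sub) == 0) return(rep(NA_real_, length(qs)))
      if (!isTRUE(all.equal(sort(sub$Q), qs))) {
        stop("Deff components are not on a shared Q grid")
      }
      sub$Deff[order(sub$Q)]
    }
    out <- data.frame(Q = qs, total = get("total"), com = get("com"),
                      rot = get("rot"), trans = get("trans"))
    if (!is.null(dtrans)) {
      if (!isTRUE(all.equal(sort(dtrans$Q), qs))) {
        stop("dtrans is not on the Deff Q grid")
      }
      out$trans <- dtrans$Dtrans[order(dtrans$Q)]
    }
    out
  }
  per_seed <- lapply(split(df, df$seed), function(d) {
    wd <- wide_of(d)
    wd$err_com <- (wd$com + wd$rot - wd$total) / wd$total
    wd$err_trans <- (wd$trans + wd$rot - wd$total) / wd$total
    wd
  })
  qs <- per_seed[[1]]$Q
  agg <- function(col) {
    m <- sapply(per_seed, function(w) w[[col]])
    m <- matrix(m, nrow = length(qs))
    data.frame(mean = rowMeans(m), min = apply(m, 1, min),
               max = apply(m, 1, max))
  }
  ec <- agg("err_com"); et <- agg("err_trans")
  dtot <- agg("total"); drot <- agg("rot")
  tab <- data.frame(Q = qs,
                    Dtotal = dtot$mean, Drot = drot$mean,
                    Dcom = agg("com")$mean, Dtrans = agg("trans")$mean,
                    err_com = ec$mean, err_com_min = ec$min,
                    err_com_max = ec$max,
                    err_trans = et$mean, err_trans_min = et$min,
                    err_trans_max = et$max)
  imax_c <- which.max(abs(tab$err_com))
  summ <- data.frame(approximation = "com+rot",
                     max_abs_err = abs(tab$err_com[imax_c]),
                     signed_err = tab$err_com[imax_c],
                     argmax_Q = tab$Q[imax_c])
  if (any(is.finite(tab$err_trans))) {
    imax_t <- which.max(abs(tab$err_trans))
    summ <- rbind(summ, data.frame(approximation = "trans+rot",
                                   max_abs_err = abs(tab$err_trans[imax_t]),
                                   signed_err = tab$err_trans[imax_t],
                                   argmax_Q = tab$Q[imax_t]))
  }
  res <- NULL
  if (!is.null(isf)) {
    idf <- as.data.frame(isf)
    if (!"seed" %in% names(idf)) idf$seed <- 1L
    res <- do.call(rbind, lapply(split(idf, idf[, c("seed", "Q")],
                                       drop = TRUE), function(d) {
      wide <- function(comp) {
        s <- d[d$component == comp, ]
        s$value[order(s$lag)]
      }
      tot <- wide("total"); com <- wide("com"); rot <- wide("rot")
      tr <- if ("trans" %in% d$component) wide("trans") else NULL
      data.frame(seed = d$seed[1], Q = d$Q[1],
                 resid_com = max(abs(tot - com * rot)),
                 resid_trans = if (is.null(tr)) NA_real_
                               else max(abs(tot - tr * rot)))
    }))
    rownames(res) <- NULL
  }
  structure(list(table = tab, summary = summ, residuals = res,
                 n_seeds = length(per_seed)),
            class = "decoupling_report")
}

#' @export
print.decoupling_report <- function(x, ...) {
  cat(sprintf("decoupling report (%d seed%s):\n", x$n_seeds,
              if (x$n_seeds > 1) "s" else ""))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-10s max |err| = %5.2f%% (signed %+5.2f%%) at Q = %g\n",
                s$approximation[i], 100 * s$max_abs_err[i],
                100 * s$signed_err[i], s$argmax_Q[i]))
  }
  invisible(x)
}

#' Across-seed reproducibility of ISF curves
#'
#' For replicate trajectories of the same system, ISF values agree at small
#' lag and drift apart as the lag approaches the trajectory length (a
#' finite-sampling effect, not physics). This reports, per Q, the earliest
#' lag at which the across-seed spread exceeds a threshold - the onset of
#' the non-reproducible region - plus the full spread curve.
#'
#' @param isf an `isf_curve` table with a `seed` column (one component).
#' @param threshold spread (max - min of normalized ISF) defining the onset.
#' @param tau_c optional characteristic time; if given, onsets are also
#'   reported as `t / tau_c`.
#' @return list with `spread` (per Q and lag) and `onset` (per Q).
#' @export
reproducibility_onset <- function(isf, threshold = 0.02, tau_c = NULL) {
  df <- as.data.frame(isf)
  if (!"seed" %in% names(df)) stop("isf needs a seed column (replicates)")
  if (length(unique(df$component)) != 1) {
    stop("give one ISF component at a time")
  }
  spread <- do.call(rbind, lapply(split(df, df[, c("Q", "lag")], drop = TRUE),
                                  function(d) {
    data.frame(Q = d$Q[1], lag = d$lag[1],
               spread = max(d$value) - min(d$value),
               n_seeds = nrow(d))
  }))
  spread <- spread[order(spread$Q, spread$lag), ]
  rownames(spread) <- NULL
  onset <- do.call(rbind, lapply(split(spread, spread$Q), function(d) {
    over <- d$lag[d$spread > threshold]
    data.frame(Q = d$Q[1],
               onset = if (length(over)) min(over) else Inf)
  }))
  rownames(onset) <- NULL
  if (!is.null(tau_c)) {
    onset$onset_over_tau_c <- onset$onset / tau_c
    spread$t_over_tau_c <- spread$lag / tau_c
  }
  list(spread = spread, onset = onset)
}
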