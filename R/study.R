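#' Configuration of an end-to-end decoupling study
#'
#' Collects every knob of the pipeline - model, engine, seeds, Q grid, lag
#' grid, Deff fit window, output directory - into one fully serializable
#' list, so a study re-run from its emitted configuration (same seeds)
#' reproduces the same numbers bit for bit. Defaults are a desk-scale
#' Brownian-surrogate study of the synthetic Y-shaped antibody model on the
#' NSE Q grid (0.05-0.2 inverse Angstrom, plus 0.01 for the D0 reference).
#'
#' @param model list: either `type = "synthetic_mab"` with
#'   [make_synthetic_mab()] arguments, `type = "shell"` with
#'   [make_spherical_shell()] arguments, or `type = "pdb"` with a `path`.
#' @param engine `"bd"` (overdamped surrogate) or `"dpd"`.
#' @param tensor list of [estimate_diffusion_tensor()] arguments
#'   (BD engine).
#' @param dpd list of [dpd_params()] arguments (DPD engine) plus
#'   `length_scale` (Angstrom per DPD length unit).
#' @param seeds integer vector of replicate seeds (default 3 replicates).
#' @param dt,n_steps,snapshot_every BD integration settings (time unit ns
#'   when the tensor carries Angstrom^2/ns).
#' @param Q Q grid, inverse Angstrom.
#' @param Q_ref reference Q for the D0 normalization.
#' @param lags frame-lag grid for the ISFs (NULL = default).
#' @param origin_stride time-origin stride (NULL = aim at >= 100 origins).
#' @param fit_window Deff fit window `c(t_min, t_max)`, time units.
#' @param components ISF components to compute.
#' @param out_dir output directory, or NULL to keep results in memory only.
#' @return list of class `study_config`.
#' @export
study_config <- function(model = list(type = "synthetic_mab"),
                         engine = c("bd", "dpd"),
                         tensor = list(bead_radius = 4.5, D0 = 3.7),
                         dpd = list(),
                         seeds = c(101, 202, 303),
                         dt = 1, n_steps = 20000, snapshot_every = 1,
                         Q = c(0.01, 0.05, 0.1, 0.15, 0.2),
                         Q_ref = 0.01,
                         lags = NULL, origin_stride = NULL,
                         fit_window = c(2, 10),
                         components = c("total", "com", "rot", "trans"),
                         out_dir = NULL) {
  engine <- match.arg(engine)
  cfg <- list(model = model, engine = engine, tensor = tensor, dpd = dpd,
              seeds = as.integer(seeds), dt = dt,
              n_steps = as.integer(n_steps),
              snapshot_every = as.integer(snapshot_every), Q = Q,
              Q_ref = Q_ref, lags = lags, origin_stride = origin_stride,
              fit_window = fit_window, components = components,
              out_dir = out_dir)
  class(cfg) <- c("study_config", "list")
  cfg
}

#' @rdname study_config
#' @param path YAML file written by [write_study_config()].
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(study_config, raw)
}

#' @rdname study_config
#' @param config a `study_config`.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# build the model a config describes
.study_model <- function(cfg) {
  m <- cfg$model
  args <- m[setdiff(names(m), "type")]
  switch(m$type,
         synthetic_mab = do.call(make_synthetic_mab, args),
         shell = do.call(make_spherical_shell, args),
         pdb = coarse_grain_pdb(readLines(m$path),
                                scheme = if (is.null(m$scheme)) "centroid"
                                         else m$scheme),
         stop("unknown model type: ", m$type))
}

#' Run a full decoupling study from a configuration
#'
#' End-to-end pipeline: build the model and its diffusion tensor, generate
#' one trajectory per seed, compute the configured ISF components, the COM
#' mean-square displacement, the per-seed Deff curves, the theoretical
#' Dtrans(Q), and the decoupling report. When `out_dir` is set, every table
#' is written (CSV), together with the model (XYZ + JSON), the emitted
#' configuration (YAML) and a provenance manifest (JSON: configuration
#' hash, content hash, seeds, package version, per-stage status). Stages
#' that completed before a failure remain on disk; the manifest marks the
#' failure point.
#'
#' @param config a [study_config()].
#' @return list of class `study_result` with elements `model`, `tensor`,
#'   `isf` (long table with seed column), `msd`, `deff`, `dtrans`,
#'   `report`, `D0`, `tau_c`, `manifest`. Invisibly when written to disk.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  cfg_scientific <- unclass(config)
  cfg_scientific$out_dir <- NULL # hash the science, not the disk layout
  manifest <- list(config_hash = rlang::hash(cfg_scientific),
                   seeds = config$seeds,
                   package_version = as.character(
                     utils::packageVersion("rigidISF")),
                   stages = list())
  emit <- function(name, obj, writer) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, name))
    manifest$stages[[name]] <<- "ok"
  }
  fail_manifest <- function(stage, err) {
    manifest$stages[[stage]] <<- paste("failed:", conditionMessage(err))
    if (!is.null(out_dir)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    stop(err)
  }

  model <- tryCatch(.study_model(config),
                    error = function(e) fail_manifest("model", e))
  emit("model.xyz", model, write_model_xyz)

  tensor <- NULL
  if (config$engine == "bd") {
    tensor <- do.call(estimate_diffusion_tensor,
                      c(list(model = model), config$tensor))
  }

  run_one <- function(seed) {
    if (config$engine == "bd") {
      run_bd(model, tensor, dt = config$dt, n_steps = config$n_steps,
             seed = seed, snapshot_every = config$snapshot_every)
    } else {
      dpd_args <- config$dpd
      ls <- if (is.null(dpd_args$length_scale)) 25 else dpd_args$length_scale
      dpd_args$length_scale <- NULL
      pars <- do.call(dpd_params, dpd_args)
      scaled <- model
      scaled$positions <- model$positions / ls
      run_dpd(scaled, pars, n_steps = config$n_steps,
              snapshot_every = config$snapshot_every, seed = seed)
    }
  }

  isf_tabs <- list(); msd_tabs <- list(); deff_tabs <- list()
  for (seed in config$seeds) {
    traj <- tryCatch(run_one(seed),
                     error = function(e) fail_manifest(
                       paste0("trajectory_seed", seed), e))
    if (!is.null(out_dir)) {
      write_trajectory(traj, file.path(out_dir,
                                       sprintf("traj_seed%d.csv", seed)))
    }
    manifest$stages[[sprintf("traj_seed%d", seed)]] <- "ok"
    icurve <- tryCatch(
      isf_all(traj, model, config$Q, lags = config$lags,
              origin_stride = config$origin_stride,
              components = config$components),
      error = function(e) fail_manifest(paste0("isf_seed", seed), e))
    icurve$seed <- seed
    isf_tabs[[as.character(seed)]] <- icurve
    mtab <- msd(traj)
    mtab$seed <- seed
    msd_tabs[[as.character(seed)]] <- mtab
    dtab <- extract_deff(icurve, config$fit_window)
    dtab$seed <- seed
    deff_tabs[[as.character(seed)]] <- dtab
  }
  isf_long <- do.call(rbind, isf_tabs); rownames(isf_long) <- NULL
  msd_long <- do.call(rbind, msd_tabs); rownames(msd_long) <- NULL
  deff_long <- do.call(rbind, deff_tabs); rownames(deff_long) <- NULL
  emit("isf.csv", isf_long, write_isf)
  emit("msd.csv", msd_long, write_msd)
  emit("deff.csv", deff_long,
       function(o, p) utils::write.csv(o, p, row.names = FALSE))

  dtrans <- NULL
  if (!is.null(tensor)) {
    dtrans <- tryCatch(dtrans_theoretical(model, tensor, config$Q),
                       error = function(e) fail_manifest("dtrans", e))
    emit("dtrans.csv", dtrans,
         function(o, p) utils::write.csv(o, p, row.names = FALSE))
  }

  report <- tryCatch(
    compare_decoupling(deff_long,
                       dtrans = if ("trans" %in% config$components) NULL
                                else dtrans,
                       isf = isf_long),
    error = function(e) fail_manifest("report", e))
  emit("decoupling_table.csv", report$table,
       function(o, p) utils::write.csv(o, p, row.names = FALSE))

  nrm <- normalize_by_D0(deff_long, Q_ref = config$Q_ref)
  D0 <- nrm$D0
  tau_c <- characteristic_time(model_diameter(model), D0)

  results_hash <- rlang::hash(list(isf_long, msd_long, deff_long,
                                   report$table))
  manifest$results_hash <- results_hash
  if (!is.null(out_dir)) {
    write_study_config(config, file.path(out_dir, "config.yaml"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res <- structure(
    list(model = model, tensor = tensor, isf = isf_long, msd = msd_long,
         deff = deff_long, dtrans = dtrans, report = report, D0 = D0,
         tau_c = tau_c, manifest = manifest),
    class = "study_result")
  if (is.null(out_dir)) res else invisible(res)
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result: %d seeds, D0 = %.4g, tau_c = %.4g\n",
              length(x$manifest$seeds), x$D0, x$tau_c))
  print(x$report)
  invisible(x)
}
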