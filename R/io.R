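#' Write / read a rigid model as XYZ with a JSON sidecar
#'
#' The XYZ file carries one "C" pseudo-atom per bead (coordinates in
#' Angstrom, comment line = label); scattering lengths and masses, which
#' XYZ cannot hold, go to `<path>.json`. A model written and read back is
#' identical up to printing precision.
#'
#' @param model a [rigid_body_model()].
#' @param path XYZ file path.
#' @param digits coordinate precision (default 6).
#' @return `write_model_xyz` returns `path` invisibly; `read_model_xyz`
#'   returns a [rigid_body_model()].
#' @export
write_model_xyz <- function(model, path, digits = 6) {
  p <- model$positions
  lines <- c(
    as.character(nrow(p)),
    model$label,
    sprintf("C %.*f %.*f %.*f", digits, p[, 1], digits, p[, 2], digits,
            p[, 3]))
  writeLines(lines, path)
  jsonlite::write_json(
    list(label = model$label,
         scattering_lengths = model$scattering_lengths,
         masses = model$masses),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_xyz
#' @export
read_model_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  label <- lines[2]
  fields <- do.call(rbind, strsplit(trimws(lines[3:(2 + n)]), "\\s+"))
  pos <- matrix(as.numeric(fields[, 2:4]), n, 3)
  b <- NULL; m <- NULL
  metafile <- paste0(path, ".json")
  if (file.exists(metafile)) {
    meta <- jsonlite::read_json(metafile, simplifyVector = TRUE)
    b <- meta$scattering_lengths
    m <- meta$masses
    if (!is.null(meta$label)) label <- meta$label
  }
  rigid_body_model(pos, scattering_lengths = b, masses = m, label = label,
                   recenter = FALSE)
}
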