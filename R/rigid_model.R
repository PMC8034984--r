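#' Rigid coarse-grained bead model of a protein
#'
#' A `rigid_body_model` holds one bead per coarse-grained site: body-frame
#' coordinates (Angstrom), per-bead scattering lengths and masses. On
#' construction the model is re-centred so that the mass-weighted centroid is
#' exactly at the origin; all scattering sums and diffusion tensors are taken
#' about this point.
#'
#' @param positions numeric N x 3 matrix of bead coordinates, Angstrom.
#' @param scattering_lengths numeric vector of N scattering lengths
#'   (dimensionless; default 1 for every bead, the convention used when only
#'   the shape matters).
#' @param masses numeric vector of N bead masses (dimensionless; default
#'   equal mass per bead, i.e. mass evenly distributed among residues).
#' @param label free-text label carried through outputs.
#' @param recenter re-centre to the mass-weighted centroid (default TRUE).
#' @return An object of class `rigid_body_model` with elements `positions`,
#'   `scattering_lengths`, `masses`, `label`.
#' @export
rigid_body_model <- function(positions,
                             scattering_lengths = NULL,
                             masses = NULL,
                             label = "",
                             recenter = TRUE) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  n <- nrow(positions)
  if (n < 1) stop("a rigid body model needs at least one bead")
  if (!all(is.finite(positions))) stop("all bead coordinates must be finite")
  if (is.null(scattering_lengths)) scattering_lengths <- rep(1, n)
  if (is.null(masses)) masses <- rep(1, n)
  stopifnot(length(scattering_lengths) == n, length(masses) == n)
  if (any(masses <= 0)) stop("bead masses must be positive")
  if (recenter) {
    com <- colSums(positions * masses) / sum(masses)
    positions <- sweep(positions, 2, com)
  }
  structure(
    list(positions = unname(positions),
         scattering_lengths = as.numeric(scattering_lengths),
         masses = as.numeric(masses),
         label = label),
    class = "rigid_body_model")
}

#' @export
print.rigid_body_model <- function(x, ...) {
  cat(sprintf("rigid_body_model '%s': %d beads, diameter %.1f A, Rg %.1f A\n",
              x$label, nrow(x$positions), model_diameter(x),
              gyration_radius(x)))
  invisible(x)
}

#' Number of beads in a model
#' @param model a [rigid_body_model()].
#' @return integer bead count.
#' @export
n_beads <- function(model) nrow(model$positions)

#' Mass-weighted centre of mass of a model
#' @param model a [rigid_body_model()].
#' @return length-3 numeric vector (Angstrom); ~0 after construction.
#' @export
model_com <- function(model) {
  colSums(model$positions * model$masses) / sum(model$masses)
}

#' Gyration radius and overall diameter
#'
#' `gyration_radius` is the mass-weighted root-mean-square bead distance from
#' the centre of mass. `model_diameter` is the maximum bead-bead distance,
#' used as the effective diameter sigma in the characteristic diffusion time
#' tau_c = sigma^2 / (6 D0).
#'
#' @param model a [rigid_body_model()].
#' @return scalar, Angstrom.
#' @export
gyration_radius <- function(model) {
  w <- model$masses / sum(model$masses)
  sqrt(sum(w * rowSums(model$positions^2)))
}

#' @rdname gyration_radius
#' @export
model_diameter <- function(model) {
  if (n_beads(model) == 1) return(0)
  max(stats::dist(model$positions))
}

#' Gyration tensor of the bead cloud
#' @param model a [rigid_body_model()].
#' @return 3 x 3 mass-weighted gyration tensor (Angstrom^2).
#' @export
gyration_tensor <- function(model) {
  w <- model$masses / sum(model$masses)
  p <- model$positions
  crossprod(p * sqrt(w))
}

# Standard amino-acid residue names accepted during coarse graining.
.aa3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL", "MSE", "SEC", "PYL")

#' Coarse grain a PDB structure to one bead per residue
#'
#' Builds a rigid bead model from standard PDB ATOM records: one bead per
#' amino-acid residue, placed either at the residue heavy-atom centroid
#' (default) or at the C-alpha position. Every bead gets scattering length 1
#' and equal mass. Only the first model of a multi-model file is used and
#' alternate location A is preferred. The result is re-centred to its centre
#' of mass.
#'
#' @param pdb_text character scalar (or vector of lines) with PDB-format
#'   text, or a path to a PDB file.
#' @param scheme bead placement: `"centroid"` (residue heavy-atom centroid)
#'   or `"CA"`.
#' @param label model label; defaults to something derived from the input.
#' @return A [rigid_body_model()] with one bead per residue.
#' @export
coarse_grain_pdb <- function(pdb_text, scheme = c("centroid", "CA"),
                             label = "pdb model") {
  scheme <- match.arg(scheme)
  path <- pdb_text
  cleanup <- FALSE
  if (length(pdb_text) > 1 || grepl("\n", pdb_text) ||
      grepl("^(ATOM|HETATM|HEADER|REMARK|MODEL|TITLE)", pdb_text[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(if (length(pdb_text) > 1) pdb_text
               else strsplit(pdb_text, "\n", fixed = TRUE)[[1]], path)
    cleanup <- TRUE
  }
  if (cleanup) on.exit(unlink(path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% .aa3, , drop = FALSE]
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]
  if (nrow(at) == 0) stop("no amino-acid residues found in PDB input")
  # drop hydrogens for the heavy-atom centroid
  elty <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                substr(trimws(at$elety), 1, 1), at$elesy)))
  at <- at[elty != "H", , drop = FALSE]
  if (nrow(at) == 0) stop("no amino-acid residues found in PDB input")
  key <- paste(at$chain, at$resno, at$insert, sep = "|")
  keys <- unique(key)
  pos <- matrix(NA_real_, length(keys), 3)
  for (i in seq_along(keys)) {
    rows <- at[key == keys[i], , drop = FALSE]
    if (scheme == "CA") {
      ca <- rows[trimws(rows$elety) == "CA", , drop = FALSE]
      if (nrow(ca) == 0) {
        stop(sprintf("residue %s %s%s has no CA atom under the CA scheme",
                     rows$resid[1], rows$chain[1], rows$resno[1]))
      }
      pos[i, ] <- c(ca$x[1], ca$y[1], ca$z[1])
    } else {
      pos[i, ] <- c(mean(rows$x), mean(rows$y), mean(rows$z))
    }
  }
  rigid_body_model(pos, label = label)
}

#' Synthetic Y-shaped mAb-like rigid model
#'
#' Generates a three-lobe rigid bead cloud emulating the overall shape of an
#' IgG-class monoclonal antibody: two Fab-like lobes and one Fc-like lobe
#' arranged in a planar Y around a hinge. Beads are drawn quasi-uniformly
#' inside each spherical lobe with a seeded RNG, so the model is
#' deterministic for a fixed seed. Defaults give an overall diameter of
#' about 100 Angstrom (a ~10 nm particle).
#'
#' @param lobe_radii radii of the three lobes (Fab, Fab, Fc), Angstrom.
#' @param arm_length distance from the hinge point to each lobe centre,
#'   Angstrom.
#' @param hinge_angle angle between the two Fab arms, degrees.
#' @param beads_per_lobe beads per lobe (>= 10).
#' @param seed integer seed for the bead placement.
#' @param target_diameter if non-NULL, isotropically rescale the finished
#'   model so its maximum bead-bead distance equals this value (Angstrom).
#' @param label model label.
#' @return A [rigid_body_model()] with `3 * beads_per_lobe` beads, centred
#'   at its centre of mass.
#' @export
make_synthetic_mab <- function(lobe_radii = c(23, 23, 26),
                               arm_length = 30,
                               hinge_angle = 115,
                               beads_per_lobe = 100,
                               seed = 1,
                               target_diameter = NULL,
                               label = "synthetic mAb") {
  if (beads_per_lobe < 10) stop("beads_per_lobe must be at least 10")
  if (any(lobe_radii <= 0) || arm_length <= 0 || hinge_angle <= 0) {
    stop("lobe radii, arm length and hinge angle must be positive")
  }
  half <- hinge_angle / 2 * pi / 180
  centres <- rbind(
    c(+arm_length * sin(half), arm_length * cos(half), 0),  # Fab 1
    c(-arm_length * sin(half), arm_length * cos(half), 0),  # Fab 2
    c(0, -arm_length, 0))                                   # Fc
  with_seed(seed, {
    pos <- do.call(rbind, lapply(1:3, function(l) {
      u <- matrix(rnorm(3 * beads_per_lobe), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      r <- lobe_radii[l] * runif(beads_per_lobe)^(1 / 3)
      sweep(u * r, 2, centres[l, ], "+")
    }))
    model <- rigid_body_model(pos, label = label)
    if (!is.null(target_diameter)) {
      if (target_diameter <= 0) stop("target_diameter must be positive")
      model$positions <- model$positions *
        (target_diameter / model_diameter(model))
    }
    model
  })
}

#' Quasi-uniform spherical-shell rigid model
#'
#' Places `n` beads on a sphere with a Fibonacci lattice, giving a dense,
#' deterministic, quasi-uniform shell. A spherically symmetric rigid body is
#' the null case of the decoupling analysis: its coherent rotational ISF does
#' not decay and translation and rotation contribute independently.
#'
#' @param n number of beads (>= 4).
#' @param radius shell radius, Angstrom.
#' @param label model label.
#' @return A [rigid_body_model()].
#' @export
make_spherical_shell <- function(n = 1000, radius = 25,
                                 label = "spherical shell") {
  if (n < 4) stop("need at least 4 beads")
  if (radius <= 0) stop("radius must be positive")
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(0, 1 - z^2))
  rigid_body_model(radius * cbind(rho * cos(phi), rho * sin(phi), z),
                   label = label)
}

#' Orientationally averaged form factor P(Q)
#'
#' Debye double sum over bead pairs,
#' `P(Q) = sum_{m,n} b_m b_n sinc(Q r_mn) / (sum_m b_m)^2`,
#' normalized so that `P(0) = 1`.
#'
#' @param model a [rigid_body_model()].
#' @param Q numeric vector of wavevector magnitudes (inverse Angstrom),
#'   all >= 0.
#' @return numeric vector of P(Q) values.
#' @export
form_factor <- function(model, Q) {
  if (any(Q < 0)) stop("Q must be non-negative")
  b <- model$scattering_lengths
  n <- n_beads(model)
  btot2 <- sum(b)^2
  if (n == 1) return(rep(1, length(Q)))
  d <- as.matrix(stats::dist(model$positions))
  iu <- which(upper.tri(d))
  dv <- d[iu]
  bw <- (b %o% b)[iu]
  self <- sum(b^2)
  vapply(Q, function(q) {
    x <- q * dv
    s <- sum(bw * ifelse(x < 1e-12, 1, sin(x) / x))
    (self + 2 * s) / btot2
  }, numeric(1))
}
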