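test_that("PDB coarse graining gives one centred bead per residue", {
  # single residue -> one bead at the origin
  one <- toy_pdb(ca_residue("A", 1, "GLY", 3.2, -1.5, 7.0))
  m1 <- coarse_grain_pdb(one, scheme = "CA")
  expect_equal(n_beads(m1), 1)
  expect_equal(m1$positions, matrix(0, 1, 3))

  # three collinear equal-mass residues at x = 0, 1, 2 -> centred at -1, 0, 1
  three <- toy_pdb(do.call(rbind, lapply(0:2, function(i)
    ca_residue("A", i + 1, "ALA", i, 0, 0))))
  m3 <- coarse_grain_pdb(three, scheme = "CA")
  expect_equal(sort(m3$positions[, 1]), c(-1, 0, 1))
  expect_equal(m3$positions[, 2:3], matrix(0, 3, 2))
  expect_equal(m3$scattering_lengths, rep(1, 3))
  expect_equal(m3$masses, rep(1, 3))

  # mixed fixture: R residues across two chains, plus waters and a ligand
  # that must be ignored; oracle = independent text scan for unique
  # (chain, resno) among amino-acid ATOM records
  set.seed(21)
  res <- do.call(rbind, c(
    lapply(1:7, function(i) ca_residue("A", i, sample(c("ALA", "LYS", "TRP"), 1),
                                       rnorm(1), rnorm(1), rnorm(1))),
    lapply(1:5, function(i) ca_residue("B", i, "SER",
                                       rnorm(1), rnorm(1), rnorm(1)))))
  hetero <- paste(
    "HETATM 9001  O   HOH A 501       0.000   0.000   0.000  1.00  0.00           O",
    "HETATM 9002  C1  LIG A 502       1.000   1.000   1.000  1.00  0.00           C",
    sep = "\n")
  txt <- paste(sub("\nEND$", "", toy_pdb(res)), hetero, "END", sep = "\n")
  scan_count <- length(unique(vapply(
    grep("^ATOM", strsplit(txt, "\n")[[1]], value = TRUE),
    function(l) paste(substr(l, 22, 22), substr(l, 23, 26)), character(1))))
  m <- coarse_grain_pdb(txt)
  expect_equal(n_beads(m), scan_count)
  expect_equal(n_beads(m), 12)
  expect_lt(sqrt(sum(model_com(m)^2)), 1e-9)

  # recentering is idempotent
  m_again <- rigid_body_model(m$positions)
  expect_equal(m_again$positions, m$positions)
})

test_that("PDB coarse graining fails informatively on bad input", {
  waters <- paste(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END", sep = "\n")
  expect_error(coarse_grain_pdb(waters), "no.*residue")

  # residue with only a sidechain atom: centroid works, CA scheme errors
  noca <- data.frame(chain = "A", resno = 4, resname = "VAL",
                     atoms = I(list(data.frame(name = "CB", x = 1, y = 2,
                                               z = 3, element = "C"))))
  txt <- toy_pdb(rbind(ca_residue("A", 1, "GLY", 0, 0, 0), noca))
  expect_equal(n_beads(coarse_grain_pdb(txt, scheme = "centroid")), 2)
  expect_error(coarse_grain_pdb(txt, scheme = "CA"), "VAL.*A4|A4.*VAL")
})

test_that("synthetic mAb generator is deterministic with the right shape", {
  m <- make_synthetic_mab(beads_per_lobe = 100, seed = 9)
  expect_equal(n_beads(m), 300)
  expect_lt(sqrt(sum(model_com(m)^2)), 1e-9)
  # same seed -> identical; different seed -> different
  expect_identical(m$positions,
                   make_synthetic_mab(beads_per_lobe = 100, seed = 9)$positions)
  expect_false(identical(
    m$positions, make_synthetic_mab(beads_per_lobe = 100, seed = 10)$positions))

  # ~10 nm overall diameter by default, and rescaling honours the target
  expect_lt(abs(model_diameter(m) - 100) / 100, 0.1)
  m120 <- make_synthetic_mab(seed = 9, target_diameter = 120)
  expect_equal(model_diameter(m120), 120, tolerance = 1e-9)

  # equal lobes at a 120 degree hinge: threefold-symmetric Y, so the
  # in-plane gyration eigenvalues degenerate
  sym <- make_synthetic_mab(lobe_radii = c(20, 20, 20), hinge_angle = 120,
                            beads_per_lobe = 400, seed = 2)
  ev <- sort(eigen(gyration_tensor(sym), symmetric = TRUE)$values,
             decreasing = TRUE)
  expect_lt((ev[1] - ev[2]) / ev[1], 0.05)

  expect_error(make_synthetic_mab(lobe_radii = c(-1, 20, 20)), "positive")
  expect_error(make_synthetic_mab(beads_per_lobe = 5), "at least 10")
})

test_that("form factor matches closed forms and the naive Debye loop", {
  Q <- c(0, 0.02, 0.05, 0.1, 0.3)
  one <- rigid_body_model(matrix(0, 1, 3))
  expect_equal(form_factor(one, Q), rep(1, length(Q)))

  # two unit beads at separation d: P(Q) = (1 + sinc(Qd)) / 2
  d <- 8
  two <- rigid_body_model(rbind(c(0, 0, -d / 2), c(0, 0, d / 2)))
  expect_equal(form_factor(two, Q),
               (1 + ifelse(Q == 0, 1, sin(Q * d) / (Q * d))) / 2,
               tolerance = 1e-12)

  set.seed(5)
  pos <- matrix(rnorm(50 * 3, sd = 20), ncol = 3)
  b <- runif(50, 0.5, 2)
  m <- rigid_body_model(pos, scattering_lengths = b)
  expect_equal(form_factor(m, Q), debye_loop(m$positions, b, Q),
               tolerance = 1e-12)
  expect_equal(form_factor(m, 0), 1)
  expect_error(form_factor(m, -0.1), "non-negative")
})

test_that("Kirkwood tensor has the right limits, symmetry and scaling", {
  # single bead: Stokes-Einstein in both blocks
  a <- 4.5; eta <- 2; kBT <- 3
  one <- rigid_body_model(matrix(0, 1, 3))
  D1 <- estimate_diffusion_tensor(one, bead_radius = a, viscosity = eta,
                                  kBT = kBT)
  expect_equal(D1$tt, diag(3) * kBT / (6 * pi * eta * a), tolerance = 1e-12)
  expect_equal(D1$rr, diag(3) * kBT / (8 * pi * eta * a^3), tolerance = 1e-12)

  # rigid dimer along z: parallel translation faster than perpendicular
  dim2 <- rigid_body_model(rbind(c(0, 0, -10), c(0, 0, 10)))
  D2 <- estimate_diffusion_tensor(dim2, bead_radius = 2)
  expect_gt(D2$tt[3, 3], D2$tt[1, 1])
  expect_equal(D2$tt[1, 1], D2$tt[2, 2], tolerance = 1e-10)

  # 6x6 assembly symmetric, PSD; spherical shell isotropic
  sh <- make_spherical_shell(300, 20)
  Ds <- estimate_diffusion_tensor(sh)
  D6 <- assemble_tensor6(Ds)
  expect_lt(max(abs(D6 - t(D6))), 1e-10 * max(abs(D6)))
  expect_gt(min(eigen(D6, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(Ds$tt, diag(3) * mean(diag(Ds$tt)),
               tolerance = 1e-3)

  # Stokes scaling: doubling the shell radius roughly halves D0
  Dbig <- estimate_diffusion_tensor(make_spherical_shell(300, 40))
  ratio <- mean(diag(Ds$tt)) / mean(diag(Dbig$tt))
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.5)

  coincident <- rigid_body_model(matrix(0, 3, 3), recenter = FALSE)
  expect_error(estimate_diffusion_tensor(coincident), "singular")
})

test_that("diffusion tensor constructor rejects bad input and rescales", {
  expect_error(diffusion_tensor(diag(3) * -1, diag(3)), "positive semi")
  ns <- matrix(rnorm(9), 3, 3)
  expect_error(diffusion_tensor(ns, diag(3)), "symmetric|positive")
  D <- estimate_diffusion_tensor(make_spherical_shell(100, 20), D0 = 3.7)
  expect_equal(mean(diag(D$tt)), 3.7, tolerance = 1e-12)
})

test_that("model XYZ + JSON sidecar round-trips", {
  m <- make_synthetic_mab(beads_per_lobe = 20, seed = 3)
  m$scattering_lengths <- runif(n_beads(m), 0.5, 2)
  path <- file.path(tempdir(), "model.xyz")
  write_model_xyz(m, path, digits = 9)
  back <- read_model_xyz(path)
  expect_equal(back$positions, m$positions, tolerance = 1e-8)
  expect_equal(back$scattering_lengths, m$scattering_lengths,
               tolerance = 1e-12)
  expect_equal(back$label, m$label)
  unlink(c(path, paste0(path, ".json")))
})
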