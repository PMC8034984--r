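test_that("Deff extraction is exact on synthesized exponential ISFs", {
  Dstar <- 2.7
  Q <- c(0.05, 0.1, 0.2)
  lag <- seq(0, 10, by = 1)
  curve <- data.frame(component = "com",
                      Q = rep(Q, each = length(lag)),
                      lag = rep(lag, times = length(Q)))
  curve$value <- exp(-Dstar * curve$Q^2 * curve$lag)
  curve$n_origins <- 1
  de <- extract_deff(curve, c(1, 10))
  expect_equal(de$Deff, rep(Dstar, 3), tolerance = 1e-10)

  # two-exponential curve: early-window Deff matches the analytic slope at
  # the window midpoint to ~1%
  w1 <- 0.7; D1 <- 3; D2 <- 0.5
  lag_f <- seq(0, 2, by = 0.05)
  two <- data.frame(component = "com", Q = 0.1,
                    lag = lag_f, n_origins = 1)
  ifun <- function(t, q) w1 * exp(-D1 * q^2 * t) + (1 - w1) * exp(-D2 * q^2 * t)
  two$value <- ifun(two$lag, 0.1)
  det <- extract_deff(two, c(0.05, 0.6))
  tm <- 0.325 # window midpoint
  slope_true <- -(w1 * D1 * 0.1^2 * exp(-D1 * 0.01 * tm) +
                  (1 - w1) * D2 * 0.01 * exp(-D2 * 0.01 * tm)) /
    ifun(tm, 0.1)
  expect_equal(det$Deff, -slope_true / 0.01, tolerance = 0.01)
})

test_that("Deff extraction commutes with normalization and guards windows", {
  lag <- 0:10
  curve <- data.frame(component = "com", Q = 0.1, lag = lag,
                      value = exp(-2 * 0.01 * lag), n_origins = 1)
  scaled <- curve; scaled$value <- curve$value * 3 # un-normalized copy
  d1 <- extract_deff(curve, c(2, 10))
  d2 <- extract_deff(scaled, c(2, 10))
  expect_equal(d1$Deff, d2$Deff, tolerance = 1e-12)

  neg <- curve; neg$value[neg$lag > 5] <- -0.1
  expect_error(extract_deff(neg, c(2, 10)), "non-positive")
  expect_error(extract_deff(curve, c(9.5, 10)), "fewer than 3")
  expect_warning(extract_deff(curve, c(2, 10), tau_B = 5), "tau_B")
})

test_that("theoretical Dtrans: isotropy, Q -> 0 limit, and MC oracle", {
  m <- make_synthetic_mab(beads_per_lobe = 30, seed = 5)
  # isotropic tensor: weighting factors out exactly at every Q
  Diso <- diffusion_tensor(diag(3) * 3.1, diag(3) * 1e-4)
  th <- dtrans_theoretical(m, Diso, c(0.01, 0.1, 0.3))
  expect_equal(th$Dtrans, rep(3.1, 3), tolerance = 1e-12)

  # Q -> 0 with an anisotropic tensor: F flattens, average -> tr(tt)/3
  tt <- diag(c(4, 3, 2))
  Dan <- diffusion_tensor(tt, diag(3) * 1e-4)
  th0 <- dtrans_theoretical(m, Dan, 1e-4)
  expect_equal(th0$Dtrans, mean(diag(tt)), tolerance = 1e-6)

  # rigid rod with D_par = 2 D_perp against a brute-force MC average
  rod <- rigid_body_model(cbind(0, 0, seq(-25, 25, length.out = 11)))
  Drod <- diffusion_tensor(diag(c(1, 1, 2)), diag(3) * 1e-4)
  for (q in c(0.06, 0.15)) {
    mc <- dtrans_mc_oracle(rod, Drod$tt, q, n_dir = 2e5)
    th <- dtrans_theoretical(rod, Drod, q)
    expect_lt(abs(th$Dtrans - mc$value), 3 * mc$se + 1e-8)
  }
  expect_error(dtrans_theoretical(m, Diso, 0.1, quadrature_order = 2),
               "at least 4")
})

test_that("D0 normalization reads the reference Q and is idempotent", {
  de <- data.frame(component = rep(c("com", "trans"), each = 3),
                   Q = rep(c(0.01, 0.1, 0.2), 2),
                   Deff = c(3.7, 3.69, 3.71, 3.5, 3.6, 3.65))
  class(de) <- c("deff_curve", "data.frame")
  nr <- normalize_by_D0(de, Q_ref = 0.01)
  expect_equal(nr$D0, 3.5, ignore_attr = TRUE) # trans preferred
  expect_equal(nr$curves$Deff_norm, de$Deff / 3.5)
  # idempotent: re-normalizing already-normalized curves reads D0 = 1
  renorm <- nr$curves
  renorm$Deff <- renorm$Deff_norm
  nr2 <- normalize_by_D0(renorm, Q_ref = 0.01)
  expect_equal(nr2$D0, 1, ignore_attr = TRUE)
  expect_equal(nr2$curves$Deff_norm, nr$curves$Deff_norm)
  expect_error(normalize_by_D0(de, Q_ref = 0.05), "0.05.*available|available")
})

test_that("decoupling comparison: spherical null and input guards", {
  # spherical model under isotropic BD: both decoupling errors vanish
  D0 <- 3.7
  sh <- make_spherical_shell(200, 25)
  D <- estimate_diffusion_tensor(sh, D0 = D0)
  deffs <- list()
  for (s in 1:2) {
    tr <- run_bd(sh, D, dt = 1, n_steps = 20000, seed = 40 + s)
    ia <- isf_all(tr, sh, c(0.05, 0.15), lags = c(0, 2, 4, 6, 8, 10),
                  origin_stride = 20, components = c("total", "com", "rot"))
    de <- extract_deff(ia, c(2, 10)); de$seed <- s
    deffs[[s]] <- de
  }
  dl <- do.call(rbind, deffs)
  rep <- compare_decoupling(dl)
  expect_lt(max(abs(rep$table$err_com)), 0.05)
  # Drot of a sphere: coherent rotational ISF barely decays
  expect_lt(max(abs(rep$table$Drot)) / D0, 0.02)
  expect_equal(rep$n_seeds, 2)

  # shared-grid guard
  bad <- dl
  bad$Q[bad$component == "rot" & bad$seed == 1][1] <- 0.07
  expect_error(compare_decoupling(bad), "grid")
  expect_error(compare_decoupling(dl[dl$component != "rot", ]),
               "total, com and rot")
})

test_that("reproducibility onset: replicate ISFs agree early, diverge late", {
  m <- make_spherical_shell(30, 25)
  D <- estimate_diffusion_tensor(m, D0 = 3.7)
  # short runs on purpose: ~0.5 tau_c each, the finite-sampling regime
  tau_c <- characteristic_time(50, 3.7) # ~113 ns
  dt <- 0.05
  n_steps <- round(0.5 * tau_c / dt)
  isfs <- list()
  for (s in 1:3) {
    tr <- run_bd(m, D, dt = dt, n_steps = n_steps, seed = 70 + s)
    ic <- isf_com(tr, 0.1,
                  lags = round(seq(0, n_steps / 3, length.out = 14)),
                  origin_stride = 2)
    ic$seed <- s
    isfs[[s]] <- ic
  }
  long <- do.call(rbind, isfs)
  rw <- reproducibility_onset(long, threshold = 0.02, tau_c = tau_c)
  early <- rw$spread$spread[rw$spread$lag <= 0.01 * tau_c]
  late <- rw$spread$spread[rw$spread$lag >= 0.1 * tau_c]
  expect_lt(max(early), 0.02)
  expect_gt(max(late), max(early))
  expect_true(is.finite(rw$onset$onset) || max(late) <= 0.02)
})
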