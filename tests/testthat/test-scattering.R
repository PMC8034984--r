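test_that("ISF normalization and degenerate-model identities hold", {
  m1 <- rigid_body_model(matrix(0, 1, 3))
  D <- diffusion_tensor(diag(3) * 2, diag(3) * 1e-4)
  tr <- run_bd(m1, D, dt = 1, n_steps = 400, seed = 3)
  Q <- c(0.05, 0.1)
  itot <- isf_total(tr, m1, Q, lags = c(0, 5, 20), origin_stride = 10)
  icom <- isf_com(tr, Q, lags = c(0, 5, 20), origin_stride = 10)
  # lag 0 exactly 1; single bead: total has no internal structure
  expect_equal(itot$value[itot$lag == 0], rep(1, 2))
  expect_equal(itot$value, icom$value, tolerance = 1e-12)
  expect_true(all(is.finite(itot$value)))
  expect_true(all(abs(itot$value) <= 1 + 1e-9))
})

test_that("the pair-sum ISF matches the random-direction oracle", {
  # small fixture: 5 beads, 20 frames of coupled translation + rotation
  set.seed(14)
  model <- rigid_body_model(matrix(rnorm(15, sd = 6), 5, 3),
                            scattering_lengths = runif(5, 0.5, 2))
  # anisotropic tensor with a translation-rotation coupling block, so the
  # oracle also exercises the coupled propagator
  D <- diffusion_tensor(diag(c(2, 1.5, 1)), diag(3) * 0.005,
                        matrix(0.002, 3, 3))
  tr <- run_bd(model, D, dt = 1, n_steps = 19, seed = 14)
  lag <- 12L
  beads <- reconstruct_beads(tr, model, frames = c(1, 1 + lag))
  for (Q in c(0.08, 0.3)) {
    mc <- isf_mc_oracle(beads[1, , ], beads[2, , ], Q,
                        b = model$scattering_lengths, n_dir = 40000)
    ours <- rigidISF:::isf_pairsum_cpp(
      model$positions, model$scattering_lengths, tr$com, tr$quat,
      origins = 0L, lags = lag, Q = Q, mode = 0L)[1, 1]
    expect_lt(abs(ours - mc$mean), 3 * mc$se + 1e-10)
  }
})

test_that("COM ISF matches its closed forms", {
  Q <- c(0.05, 0.15)
  # static trajectory: no decay
  trs <- rb_trajectory(0:49, matrix(1.5, 50, 3))
  ist <- isf_com(trs, Q, lags = c(0, 10, 40), origin_stride = 1)
  expect_equal(ist$value, rep(1, 6))

  # uniform drift v: angular average gives sinc(Q v t) exactly
  v <- 0.8
  trd <- rb_trajectory(0:49, outer(0:49, c(v, 0, 0)))
  isd <- isf_com(trd, Q, lags = c(0, 5, 10), origin_stride = 1)
  expected <- vapply(seq_len(nrow(isd)), function(i) {
    x <- isd$Q[i] * v * isd$lag[i]
    if (x == 0) 1 else sin(x) / x
  }, numeric(1))
  expect_equal(isd$value, expected, tolerance = 1e-12)

  # free isotropic diffusion: ln Icom slope = -D0 Q^2
  D0 <- 3
  m <- make_spherical_shell(10, 5)
  tr <- run_bd(m, diffusion_tensor(diag(3) * D0, diag(3) * 1e-6),
               dt = 1, n_steps = 50000, seed = 19)
  ic <- isf_com(tr, Q, lags = 0:10, origin_stride = 5)
  for (q in Q) {
    d <- ic[ic$Q == q & ic$lag > 0, ]
    slope <- coef(lm(log(d$value) ~ d$lag))[2]
    expect_equal(unname(-slope / q^2), D0, tolerance = 0.1)
  }
})

test_that("rotational ISF: shell constancy and rod l-expansion", {
  # dense quasi-uniform shell: coherent rotational ISF stays at 1
  sh <- make_spherical_shell(1000, 25)
  Dr <- 2e-3
  tr <- run_bd(sh, diffusion_tensor(matrix(0, 3, 3), diag(3) * Dr),
               dt = 1, n_steps = 1500, seed = 4)
  Q <- c(0.8, 1.6, 2.4, 4.0) / 25 # Q * diameter <= 8, away from P(Q) zeros
  ir <- isf_rot(tr, sh, Q, lags = c(0, 150, 600, 1400), origin_stride = 50)
  expect_lt(max(abs(ir$value - 1)), 0.01)

  # two-bead rod: matches the even-l spherical Bessel expansion
  L <- 20
  rod <- rigid_body_model(rbind(c(0, 0, -L / 2), c(0, 0, L / 2)))
  Drr <- 1e-3
  trr <- run_bd(rod, diffusion_tensor(matrix(0, 3, 3), diag(3) * Drr),
                dt = 1, n_steps = 150000, seed = 6)
  Qr <- c(0.1, 0.25)
  lags <- c(0, 100, 300, 700)
  irr <- isf_rot(trr, rod, Qr, lags = lags, origin_stride = 10)
  for (q in Qr) {
    got <- irr$value[irr$Q == q]
    want <- rod_rot_isf(q, L, Drr, lags)
    # ~2 x the empirical across-origin standard error at the longest lag
    expect_equal(got, want, tolerance = 0.04)
  }
})

test_that("structure-weighted translational ISF brackets its limits", {
  Q <- c(0.02, 0.1, 0.2)
  lags <- c(0, 2, 4, 6, 8, 10)
  # spherical model: no orientational weighting possible -> equals com ISF
  sh <- make_spherical_shell(200, 20)
  Dsh <- estimate_diffusion_tensor(sh, D0 = 3)
  tr <- run_bd(sh, Dsh, dt = 1, n_steps = 20000, seed = 8)
  itr <- isf_trans_weighted(tr, sh, Q, lags = lags, origin_stride = 20)
  ico <- isf_com(tr, Q, lags = lags, origin_stride = 20)
  expect_equal(itr$value, ico$value, tolerance = 0.01)

  # anisotropic rod: short-time decay rate matches the Eq-20 quadrature
  # (dt halved: the rod rotates fast and the exponential-map step is capped)
  rod <- rigid_body_model(cbind(0, 0, seq(-30, 30, length.out = 13)))
  Drod <- estimate_diffusion_tensor(rod, bead_radius = 5, D0 = 3.7)
  trr <- run_bd(rod, Drod, dt = 0.5, n_steps = 60000, seed = 9)
  Qa <- c(0.05, 0.12)
  lag_f <- c(0, 4, 8, 12, 16, 20) # frame lags; times 0..10 ns at dt 0.5
  ita <- isf_trans_weighted(trr, rod, Qa, lags = lag_f, origin_stride = 10)
  de <- extract_deff(ita, c(2, 10))
  th <- dtrans_theoretical(rod, Drod, Qa)
  expect_equal(de$Deff[order(de$Q)], th$Dtrans[order(th$Q)],
               tolerance = 0.06)
  # at the smallest Q the weighting washes out: approaches the com value
  icoa <- isf_com(trr, Qa, lags = lag_f, origin_stride = 10)
  dco <- extract_deff(icoa, c(2, 10))
  expect_equal(de$Deff[de$Q == 0.05], dco$Deff[dco$Q == 0.05],
               tolerance = 0.05)
})

test_that("spherical model: ISFs collapse on the D0 Q^2 t master curve", {
  D0 <- 3.7
  sh <- make_spherical_shell(300, 25)
  D <- estimate_diffusion_tensor(sh, D0 = D0)
  tr <- run_bd(sh, D, dt = 1, n_steps = 30000, seed = 13)
  Q <- c(0.05, 0.1, 0.15, 0.2)
  lags <- c(0, 1, 2, 4, 8, 16)
  ia <- isf_all(tr, sh, Q, lags = lags, origin_stride = 20,
                components = c("total", "com", "rot"))
  ia <- add_reduced_time(ia, D0)
  # total and com decay as exp(-D0 Q^2 t); rot stays flat
  core <- ia[ia$component %in% c("total", "com"), ]
  expect_lt(max(abs(core$value - exp(-core$reduced_time))), 0.05)
  expect_lt(max(abs(ia$value[ia$component == "rot"] - 1)), 0.02)
  # product consistency: I_total = I_com * I_rot for the sphere
  rep <- compare_decoupling(
    extract_deff(ia, c(2, 10)), isf = ia)
  expect_lt(max(rep$residuals$resid_com), 0.03)
})

test_that("lag handling: out-of-range lags are dropped with a warning", {
  m <- make_spherical_shell(10, 5)
  tr <- run_bd(m, diffusion_tensor(diag(3), diag(3) * 1e-5),
               dt = 1, n_steps = 50, seed = 1)
  expect_warning(ic <- isf_com(tr, 0.1, lags = c(0, 10, 500)), "dropped")
  expect_equal(sort(unique(ic$lag)), c(0, 10))
})
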