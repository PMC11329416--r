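test_that("passive energy: reference state, direct evaluation, fibre terms", {
  expect_equal(passive_energy(1, 1, 1, pp_fib), 0)
  # mu = 2, no fibres: Psi = (mu/2)(I1 - 3) with I1 = 0.25 + 4 + 1
  expect_equal(passive_energy(0.5, 2, 1, passive_params(mu = 2)), 2.25)
  # identity stretches make every fibre invariant I4 = 1
  pp1 <- passive_params(mu = 0, families = data.frame(
    k1 = 5, k2 = 2, alpha_deg = 30))
  expect_equal(passive_energy(1, 1, 1, pp1), 0)
})

test_that("passive extra stress matches closed forms and an energy push-forward oracle", {
  st <- passive_extra_stress(1, 1, 1, pp_fib)
  expect_equal(st$trr, pp_fib$mu)
  expect_equal(st$ttt, pp_fib$mu)
  expect_equal(st$tzz, pp_fib$mu)
  # single circumferential fibre, I4 = 2: t_tt = k1 (I4-1) e^{k2 (I4-1)^2} lt^2 = 2e
  # (push-forward of the k1/(4 k2) exponential energy; frozen against the
  # finite-difference oracle below)
  pp90 <- passive_params(mu = 0, families = data.frame(
    k1 = 1, k2 = 1, alpha_deg = 90))
  expect_equal(passive_extra_stress(1, sqrt(2), 1, pp90)$ttt, 2 * exp(1),
               tolerance = 1e-12)
  # axial fibre contributes nothing circumferentially
  pp0 <- passive_params(mu = 0, families = data.frame(
    k1 = 3, k2 = 1, alpha_deg = 0))
  expect_equal(passive_extra_stress(0.9, 1.3, 1.2, pp0)$ttt, 0)

  # oracle: t_ii = 2 lambda_i^2 dPsi/dC_ii by central differences on C
  push_fd <- function(lr, lt, lz, params) {
    h <- 1e-6
    dC <- function(f, x) (f(x + h) - f(x - h)) / (2 * h)
    list(
      trr = 2 * lr^2 * dC(function(C) passive_energy(sqrt(C), lt, lz, params), lr^2),
      ttt = 2 * lt^2 * dC(function(C) passive_energy(lr, sqrt(C), lz, params), lt^2),
      tzz = 2 * lz^2 * dC(function(C) passive_energy(lr, lt, sqrt(C), params), lz^2))
  }
  set.seed(42)
  for (k in 1:12) {
    lt <- runif(1, 0.7, 1.9); lz <- runif(1, 1.0, 1.8); lr <- 1 / (lt * lz)
    an <- passive_extra_stress(lr, lt, lz, pp_fib)
    or <- push_fd(lr, lt, lz, pp_fib)
    for (cc in c("trr", "ttt", "tzz")) {
      expect_equal(an[[cc]], or[[cc]], tolerance = 1e-6)
    }
  }
})

test_that("passive pressure: degenerate cases and a fine-grid trapezoid oracle", {
  st <- deformation_state(1.2, 1.6)
  expect_equal(passive_pressure(g_std, st, passive_params(mu = 0)), 0)
  # identity deformation: integrand vanishes pointwise
  expect_equal(passive_pressure(g_std, deformation_state(g_std$A, 1), pp_fib),
               0, tolerance = 1e-12)
  # neo-Hookean vs independent trapezoid quadrature
  b <- deformed_outer_radius(g_std, st)
  oracle <- trapz_oracle(function(r) {
    R <- sqrt((r^2 - st$a^2) * st$lambda_z + g_std$A^2)
    lt <- r / R; lr <- 1 / (lt * st$lambda_z)
    pp_neo$mu * (lt^2 - lr^2) / r
  }, st$a, b)
  expect_equal(passive_pressure(g_std, st, pp_neo), oracle, tolerance = 1e-7)
})

test_that("passive pressure is increasing in a and its derivative matches a secant oracle", {
  a_seq <- seq(0.75, 1.5, length.out = 12)
  G <- vapply(a_seq, function(a)
    passive_pressure(g_std, deformation_state(a, 1.4), pp_fib), numeric(1))
  expect_true(all(diff(G) > 0))
  expect_equal(passive_pressure_derivative(g_std, deformation_state(0.7, 1.4),
                                           passive_params(mu = 0)), 0)
  for (a0 in c(0.9, 1.2)) {
    sec <- fd_central(function(a)
      passive_pressure(g_std, deformation_state(a, 1.4), pp_fib), a0, 1e-5)
    expect_equal(passive_pressure_derivative(g_std, deformation_state(a0, 1.4),
                                             pp_fib),
                 sec, tolerance = 1e-6)
  }
  # convex response at identity: derivative positive
  expect_gt(passive_pressure_derivative(g_std, deformation_state(g_std$A, 1),
                                        pp_fib), 0)
})

test_that("transmural stress field: boundary conditions, equilibrium, active-only structure", {
  # unloaded identity state: everything ~ 0
  f0 <- transmural_stress_field(g_std, deformation_state(g_std$A, 1), pp_fib,
                                NULL, P = 0)
  expect_lt(max(abs(f0$trr), abs(f0$ttt), abs(f0$tzz)), 1e-10)

  st <- deformation_state(1.15, 1.5)
  m <- models_all$constant_1pk
  P <- total_pressure(g_std, st, pp_fib, m)
  fld <- transmural_stress_field(g_std, st, pp_fib, m, P = P, n = 801L)
  expect_equal(fld$trr[1], -P, tolerance = 1e-8)
  expect_equal(fld$trr[length(fld$trr)], 0, tolerance = 1e-8)
  expect_equal(fld$trr[1] - fld$trr[length(fld$trr)], -P, tolerance = 1e-8)
  # radial equilibrium: d trr/dr + (trr - ttt)/r = 0
  r <- fld$r; n <- length(r)
  dtrr <- (fld$trr[3:n] - fld$trr[1:(n - 2)]) / (r[3:n] - r[1:(n - 2)])
  resid <- dtrr + (fld$trr[2:(n - 1)] - fld$ttt[2:(n - 1)]) / r[2:(n - 1)]
  expect_lt(max(abs(resid)), 1e-6 * max(abs(fld$ttt)))
  # inconsistent P rejected
  expect_error(transmural_stress_field(g_std, st, pp_fib, m, P = P + 1),
               "inconsistent")

  # active-only wall: ttt - trr is exactly the active stress profile
  pp0 <- passive_params(mu = 0)
  P_act <- total_pressure(g_std, st, pp0, m)
  fa <- transmural_stress_field(g_std, st, pp0, m, P = P_act)
  lt <- fa$r / reference_radius(fa$r, g_std, st)
  expect_equal(fa$ttt - fa$trr, active_cauchy_stress(m, lt), tolerance = 1e-9)
})
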