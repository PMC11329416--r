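# lambda_theta ranges used below keep Rachev inside its bell support and
# Zulliger inside its (default, infinite) gate so closed forms apply.

test_that("active Cauchy stress: per-family structure", {
  expect_equal(active_cauchy_stress(models_all$constant_cauchy, c(0.5, 1, 2)),
               rep(20, 3))
  expect_equal(active_cauchy_stress(models_all$constant_1pk, 1.5), 18 * 1.5)
  expect_equal(active_cauchy_stress(models_all$constant_2pk, 1.5), 16 * 1.5^2)
  # Rachev peaks at lambda_m with f = 1, vanishes outside the support
  m <- models_all$rachev
  expect_equal(active_cauchy_stress(m, m$lambda_m), m$TRv * m$lambda_m)
  expect_equal(active_cauchy_stress(m, m$lambda_0), 0)
  expect_equal(active_cauchy_stress(m, 2 * m$lambda_m - m$lambda_0), 0)
  expect_equal(active_cauchy_stress(m, 0.1), 0)
  # Zulliger vanishes where muscle stretch is 1, gates to zero outside bounds
  z <- models_all$zulliger
  expect_equal(active_cauchy_stress(z, 1 / z$lambda_pre), 0)
  zg <- active_model("zulliger", TZr = 30, lambda_pre = 1.3,
                     lambda_hat_lb = 1.2, lambda_hat_ub = 2)
  expect_equal(active_cauchy_stress(zg, 0.5), 0)  # lambda_hat = 0.65 < lb
  expect_gt(active_cauchy_stress(zg, 1.2), 0)
  # Franchini at lambda_theta = 1: bracket collapses to 1
  fr <- models_all$franchini
  expect_equal(active_cauchy_stress(fr, 1), 2 * fr$TFr1)
  frS <- active_model("franchini", TFr1 = 10, alpha1 = 1.2, beta1 = 0.4,
                      m1 = 2, S1 = 0.5)
  expect_equal(active_cauchy_stress(frS, 1), fr$TFr1)
})

test_that("active energy: anchors and the stress push-forward oracle", {
  expect_equal(active_energy(active_model("constant_cauchy", Tc = 2), exp(1)), 2)
  z1 <- active_model("zulliger", TZr = 30, lambda_pre = 1)
  for (m in c(models_all[c("constant_cauchy", "constant_1pk", "constant_2pk",
                           "rachev", "franchini")], list(z1))) {
    expect_equal(active_energy(m, 1), 0, tolerance = 1e-12)
  }
  # t = lambda_theta * dPsi/dlambda_theta (equivalent to 2 F dPsi/dC F)
  lt_grid <- seq(0.9, 1.9, length.out = 8)  # inside rachev support
  for (m in models_all) {
    fd <- vapply(lt_grid, function(lt)
      lt * fd_central(function(x) active_energy(m, x), lt, 1e-6), numeric(1))
    expect_equal(active_cauchy_stress(m, lt_grid), fd, tolerance = 1e-6,
                 info = m$family)
  }
})

test_that("closed-form active pressure equals adaptive quadrature on an (a, lz) grid", {
  gs <- grid_states()
  for (m in models_all) {
    for (k in seq_len(nrow(gs))) {
      st <- deformation_state(gs$a[k], gs$lambda_z[k])
      cf <- active_pressure_closed_form(m, g_std, st)
      q <- active_pressure_quadrature(m, g_std, st)
      expect_equal(cf, q, tolerance = 1e-8, info = sprintf(
        "%s a=%.3f lz=%.2f", m$family, gs$a[k], gs$lambda_z[k]))
    }
  }
})

test_that("quadrature handles gated models with the wall partially outside support", {
  # narrow Rachev bell: support [1.2, 1.6]; wall straddles its lower edge
  m <- active_model("rachev", TRv = 40, lambda_m = 1.4, lambda_0 = 1.2)
  st <- deformation_state(0.9, 1.3)          # inner stretch 1.125, outer ~1.07
  expect_equal(active_pressure_quadrature(m, g_std, st), 0)  # fully below
  st2 <- deformation_state(1.0, 1.3)  # inner stretch 1.25 inside, outer 1.13 below
  q <- active_pressure_quadrature(m, g_std, st2)
  # oracle: integrate only over the in-support radius interval, densely
  b <- deformed_outer_radius(g_std, st2)
  oracle <- trapz_oracle(function(r) {
    lt <- r / sqrt((r^2 - st2$a^2) * st2$lambda_z + g_std$A^2)
    active_cauchy_stress(m, lt) / r
  }, st2$a, b, n = 200001L)
  expect_equal(q, oracle, tolerance = 1e-6)
  expect_error(active_pressure_closed_form(m, g_std, st2),
               class = "vasotone_no_closed_form")
  expect_error(active_pressure_closed_form(
    active_model("franchini", TFr1 = 5, alpha1 = 0.3, beta1 = 0.1, m1 = 3),
    g_std, st2), class = "vasotone_no_closed_form")
})

test_that("analytic radius derivatives match finite differences; printed signs hold", {
  # frozen example: Tc = 1, a = 1, b = 2 (A = 1, B = 2, lz = 1)
  gg <- vessel_geometry(1, 2)
  expect_equal(active_pressure_derivative(active_model("constant_cauchy", Tc = 1),
                                          gg, deformation_state(1, 1)),
               -0.75)
  gs <- grid_states(4, 3)
  for (m in models_all) {
    for (k in seq_len(nrow(gs))) {
      st <- deformation_state(gs$a[k], gs$lambda_z[k])
      an <- active_pressure_derivative(m, g_std, st)
      fd <- fd_central(function(a) active_pressure_closed_form(
        m, g_std, deformation_state(a, st$lambda_z)), st$a, 1e-6)
      expect_equal(an, fd, tolerance = 1e-5, info = m$family)
    }
  }
  # provably signed families
  for (k in seq_len(nrow(gs))) {
    st <- deformation_state(gs$a[k], gs$lambda_z[k])
    expect_lt(active_pressure_derivative(models_all$constant_cauchy, g_std, st), 0)
    expect_lt(active_pressure_derivative(models_all$constant_1pk, g_std, st), 0)
    expect_identical(active_pressure_derivative(models_all$constant_2pk, g_std, st), 0)
  }
})

test_that("stability conditions agree with the derivative sign; constants are fixed", {
  st <- deformation_state(1.1, 1.5)
  expect_false(stability_condition(models_all$constant_cauchy, g_std, st)$is_stabilising)
  expect_false(stability_condition(models_all$constant_1pk, g_std, st)$is_stabilising)
  s2 <- stability_condition(models_all$constant_2pk, g_std, st)
  expect_true(s2$neutral)
  for (m in models_all[c("rachev", "zulliger", "franchini")]) {
    for (a in seq(0.75, 1.5, length.out = 8)) {
      stt <- deformation_state(a, 1.5)
      sc <- stability_condition(m, g_std, stt)
      d <- active_pressure_derivative(m, g_std, stt)
      if (abs(d) > 1e-10) {
        expect_equal(sc$is_stabilising, d > 0,
                     info = sprintf("%s a=%.3f", m$family, a))
      }
    }
  }
})

test_that("degenerate-case identities across stress measures", {
  # identity deformation: the three constant-stress measures coincide
  st_id <- deformation_state(g_std$A, 1)
  Tval <- 7
  expect_equal(active_pressure_closed_form(
    active_model("constant_cauchy", Tc = Tval), g_std, st_id),
    Tval * log(g_std$B / g_std$A), tolerance = 1e-12)
  expect_equal(active_pressure_closed_form(
    active_model("constant_1pk", Ti = Tval), g_std, st_id),
    Tval * log(g_std$B / g_std$A), tolerance = 1e-12)
  expect_equal(active_pressure_closed_form(
    active_model("constant_2pk", Tr = Tval), g_std, st_id),
    Tval * log(g_std$B / g_std$A), tolerance = 1e-12)

  # Zulliger stress decomposes into lambda_pre-weighted 1st PK minus Cauchy
  z <- models_all$zulliger
  m1pk <- active_model("constant_1pk", Ti = z$TZr * z$lambda_pre)
  mcau <- active_model("constant_cauchy", Tc = z$TZr)
  lt <- seq(0.8, 2, length.out = 9)
  expect_equal(active_cauchy_stress(z, lt),
               active_cauchy_stress(m1pk, lt) - active_cauchy_stress(mcau, lt),
               tolerance = 1e-12)
  st <- deformation_state(1.15, 1.4)
  expect_equal(active_pressure_closed_form(z, g_std, st),
               active_pressure_closed_form(m1pk, g_std, st) -
                 active_pressure_closed_form(mcau, g_std, st),
               tolerance = 1e-12)
  expect_equal(active_pressure_derivative(z, g_std, st),
               active_pressure_derivative(m1pk, g_std, st) -
                 active_pressure_derivative(mcau, g_std, st),
               tolerance = 1e-12)

  # Franchini with alpha1 = beta1 = 0 is a constant 2nd PK with Tr = 2 TFr1
  fr0 <- active_model("franchini", TFr1 = 9, alpha1 = 0, beta1 = 0, m1 = 2)
  m2pk <- active_model("constant_2pk", Tr = 18)
  expect_equal(active_cauchy_stress(fr0, lt), active_cauchy_stress(m2pk, lt))
  expect_equal(active_pressure_closed_form(fr0, g_std, st),
               active_pressure_closed_form(m2pk, g_std, st), tolerance = 1e-12)
})

test_that("Rachev force-length function is a unit-peak bell on its support", {
  m <- models_all$rachev
  f_of <- function(lt) active_cauchy_stress(m, lt) / (m$TRv * lt)
  expect_equal(f_of(m$lambda_0 + 1e-12), 0, tolerance = 1e-9)
  expect_equal(f_of(m$lambda_m), 1)
  expect_equal(f_of(2 * m$lambda_m - m$lambda_0 - 1e-12), 0, tolerance = 1e-9)
  lt <- seq(m$lambda_0 + 1e-6, 2 * m$lambda_m - m$lambda_0 - 1e-6,
            length.out = 50)
  f <- f_of(lt)
  expect_true(all(f >= 0 & f <= 1 + 1e-12))
})

test_that("model constructor validates the tagged union", {
  expect_error(active_model("constant_cauchy"), "missing parameter")
  expect_error(active_model("rachev", TRv = 10, lambda_m = 1, lambda_0 = 1.5),
               "lambda_0 < lambda_m")
  expect_error(active_model("zulliger", TZr = 10, lambda_pre = 1.3, S1 = 1.4),
               "S1")
  expect_error(active_model("franchini", TFr1 = 1, alpha1 = 0, beta1 = 0,
                            m1 = 2.5), "integer")
})
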