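# Six active circumferential stress formulations for vascular smooth muscle.
# Smooth muscle is taken as purely circumferentially oriented, so the active
# Cauchy extra stress is t_theta_theta^act* only. Each model provides:
#   * the active Cauchy stress as a function of lambda_theta,
#   * the active stored energy Psi_act (t = 2 F dPsi/dC F in the theta-theta
#     component, i.e. t = lambda_theta * dPsi/dlambda_theta),
#   * the closed-form active load bearing Gamma_act = int_a^b t/r dr where a
#     printed closed form exists, with an adaptive-quadrature fallback,
#   * the analytic derivative dGamma_act/da and the stability inequality.
#
# Stress measures and Cauchy-stress equivalents:
#   constant Cauchy   t = Tc
#   constant 1st PK   t = Ti * lambda_theta
#   constant 2nd PK   t = Tr * lambda_theta^2
#   Rachev-Hayashi    t = TRv * lambda_theta * f(lambda_theta), bell-shaped f
#   Zulliger          t = S1 S2 TZr (lambda_theta * lambda_pre - 1)
#   Franchini         t = S1 2 TFr1 lt^2 [1 + a1(lt^2-1) - b1(lt^2-1)^m1]

#' Supported active stress model families
#'
#' Character vector of the six constitutive family names accepted by
#' [active_model()] and the fitting functions.
#' @export
ACTIVE_FAMILIES <- c("constant_cauchy", "constant_1pk", "constant_2pk",
                     "rachev", "zulliger", "franchini")

#' Construct an active smooth muscle stress model
#'
#' Tagged-union constructor for the six supported constitutive families.
#' Stress-like parameters are in kPa; shape parameters are dimensionless.
#'
#' @param family one of `"constant_cauchy"` (parameter `Tc`),
#'   `"constant_1pk"` (`Ti`), `"constant_2pk"` (`Tr`),
#'   `"rachev"` (`TRv`, `lambda_m`, `lambda_0`),
#'   `"zulliger"` (`TZr`, `S1`, `lambda_pre`, `lambda_hat_lb`,
#'   `lambda_hat_ub`), or `"franchini"` (`TFr1`, `alpha1`, `beta1`, `m1`,
#'   `S1`).
#' @param ... named parameters of the chosen family (see Details).
#' @details
#' Rachev's force-length function is
#' `f(lt) = 1 - ((lambda_m - lt)/(lambda_m - lambda_0))^2` on the support
#' `[lambda_0, 2 lambda_m - lambda_0]` and zero outside, with maximum
#' `f(lambda_m) = 1`. Zulliger's gate `S2` is 1 when the muscle-level
#' stretch `lambda_hat = lambda_theta * lambda_pre` lies within
#' `[lambda_hat_lb, lambda_hat_ub]` and 0 otherwise; gates default to
#' `c(-Inf, Inf)` (always on). Activation `S1` defaults to 1 (maximal
#' contraction). Franchini's exponent `m1` must be a positive integer; the
#' axial muscle family and in-plane dispersion are fixed at zero (purely
#' circumferential muscle).
#' @return an object of classes `c("am_<family>", "active_model")`.
#' @examples
#' active_model("constant_2pk", Tr = 37.8)
#' active_model("rachev", TRv = 67.2, lambda_m = 1.6, lambda_0 = 0.8)
#' @export
active_model <- function(family = ACTIVE_FAMILIES, ...) {
  family <- match.arg(family)
  p <- list(...)
  num1 <- function(x, nm, lo = -Inf, strict_lo = FALSE) {
    if (is.null(x)) stop(sprintf("missing parameter '%s' for family '%s'", nm, family))
    stopifnot(is.numeric(x), length(x) == 1L, is.finite(x) || abs(x) == Inf)
    if (strict_lo) { if (x <= lo) stop(sprintf("'%s' must be > %g", nm, lo)) }
    else if (x < lo) stop(sprintf("'%s' must be >= %g", nm, lo))
    x
  }
  params <- switch(family,
    constant_cauchy = list(Tc = num1(p$Tc, "Tc", 0)),
    constant_1pk    = list(Ti = num1(p$Ti, "Ti", 0)),
    constant_2pk    = list(Tr = num1(p$Tr, "Tr", 0)),
    rachev = {
      lm <- num1(p$lambda_m, "lambda_m", 0, TRUE)
      l0 <- num1(p$lambda_0, "lambda_0", 0)
      if (l0 >= lm) stop("rachev requires lambda_0 < lambda_m")
      list(TRv = num1(p$TRv, "TRv", 0), lambda_m = lm, lambda_0 = l0)
    },
    zulliger = {
      S1 <- if (is.null(p$S1)) 1 else num1(p$S1, "S1", 0)
      if (S1 > 1) stop("S1 must lie in [0, 1]")
      lb <- if (is.null(p$lambda_hat_lb)) -Inf else p$lambda_hat_lb
      ub <- if (is.null(p$lambda_hat_ub)) Inf else p$lambda_hat_ub
      if (lb > ub) stop("lambda_hat_lb must be <= lambda_hat_ub")
      list(TZr = num1(p$TZr, "TZr", 0), S1 = S1,
           lambda_pre = num1(p$lambda_pre, "lambda_pre", 0, TRUE),
           lambda_hat_lb = lb, lambda_hat_ub = ub)
    },
    franchini = {
      S1 <- if (is.null(p$S1)) 1 else num1(p$S1, "S1", 0)
      if (S1 > 1) stop("S1 must lie in [0, 1]")
      m1 <- num1(p$m1, "m1", 1)
      if (m1 != round(m1)) stop("m1 must be a positive integer")
      list(TFr1 = num1(p$TFr1, "TFr1", 0),
           alpha1 = num1(p$alpha1, "alpha1"),
           beta1 = num1(p$beta1, "beta1"),
           m1 = as.integer(m1), S1 = S1)
    })
  structure(c(list(family = family), params),
            class = c(paste0("am_", family), "active_model"))
}

#' @export
print.active_model <- function(x, ...) {
  ps <- x[setdiff(names(x), "family")]
  cat(sprintf("<active_model: %s> %s\n", x$family,
              paste(sprintf("%s = %g", names(ps), unlist(ps)), collapse = ", ")))
  invisible(x)
}

# Rachev bell f(lt) with support [lambda_0, 2*lambda_m - lambda_0].
.rachev_f <- function(model, lt) {
  lm <- model$lambda_m; l0 <- model$lambda_0
  f <- 1 - ((lm - lt) / (lm - l0))^2
  f[lt < l0 | lt > 2 * lm - l0] <- 0
  f
}

# Zulliger gate S2(lambda_hat).
.zulliger_s2 <- function(model, lt) {
  lh <- lt * model$lambda_pre
  as.numeric(lh >= model$lambda_hat_lb & lh <= model$lambda_hat_ub)
}

#' Active circumferential Cauchy stress
#'
#' @param model an [active_model()].
#' @param lambda_theta circumferential stretch(es), `> 0`.
#' @return active Cauchy stress `t_theta_theta^act*` (kPa), vectorised over
#'   `lambda_theta`.
#' @export
active_cauchy_stress <- function(model, lambda_theta) {
  UseMethod("active_cauchy_stress")
}

#' @export
active_cauchy_stress.am_constant_cauchy <- function(model, lambda_theta) {
  rep(model$Tc, length(lambda_theta))
}
#' @export
active_cauchy_stress.am_constant_1pk <- function(model, lambda_theta) {
  model$Ti * lambda_theta
}
#' @export
active_cauchy_stress.am_constant_2pk <- function(model, lambda_theta) {
  model$Tr * lambda_theta^2
}
#' @export
active_cauchy_stress.am_rachev <- function(model, lambda_theta) {
  model$TRv * lambda_theta * .rachev_f(model, lambda_theta)
}
#' @export
active_cauchy_stress.am_zulliger <- function(model, lambda_theta) {
  model$S1 * .zulliger_s2(model, lambda_theta) * model$TZr *
    (lambda_theta * model$lambda_pre - 1)
}
#' @export
active_cauchy_stress.am_franchini <- function(model, lambda_theta) {
  e <- lambda_theta^2 - 1
  model$S1 * 2 * model$TFr1 * lambda_theta^2 *
    (1 + model$alpha1 * e - model$beta1 * e^model$m1)
}

#' Active stored energy density
#'
#' Closed-form active energy whose circumferential push-forward
#' `lambda_theta * dPsi/dlambda_theta` recovers [active_cauchy_stress()].
#' For the gated models (Rachev support, Zulliger gate) the energy is the
#' antiderivative on the active branch; outside the support/gate the stress
#' is zero and the energy is held constant (continuous).
#'
#' @inheritParams active_cauchy_stress
#' @return active energy density (kPa), zero at `lambda_theta = 1` when the
#'   active branch covers it.
#' @export
active_energy <- function(model, lambda_theta) UseMethod("active_energy")

#' @export
active_energy.am_constant_cauchy <- function(model, lambda_theta) {
  model$Tc / 2 * log(lambda_theta^2)
}
#' @export
active_energy.am_constant_1pk <- function(model, lambda_theta) {
  model$Ti * (lambda_theta - 1)
}
#' @export
active_energy.am_constant_2pk <- function(model, lambda_theta) {
  model$Tr / 2 * (lambda_theta^2 - 1)
}
#' @export
active_energy.am_rachev <- function(model, lambda_theta) {
  # Psi = TRv/2 int f(lt)/lt d(lt^2) = TRv int f(lt) dlt on the support,
  # anchored so Psi = 0 at lt = 1 (clamped into the support).
  lm <- model$lambda_m; l0 <- model$lambda_0; d <- lm - l0
  antider <- function(lt) {
    lt <- pmin(pmax(lt, l0), 2 * lm - l0)
    lt - (lt * (lm^2 - lm * lt + lt^2 / 3)) / d^2
  }
  model$TRv * (antider(lambda_theta) - antider(1))
}
#' @export
active_energy.am_zulliger <- function(model, lambda_theta) {
  lh <- lambda_theta * model$lambda_pre
  lo <- model$lambda_hat_lb; hi <- model$lambda_hat_ub
  g <- function(x) x - log(x) - 1
  # on-gate branch, continuously extended outside the gate
  val <- g(pmin(pmax(lh, lo), hi))
  model$S1 * model$TZr * val
}
#' @export
active_energy.am_franchini <- function(model, lambda_theta) {
  e <- lambda_theta^2 - 1
  model$S1 * model$TFr1 *
    (e + model$alpha1 / 2 * e^2 - model$beta1 / (model$m1 + 1) * e^(model$m1 + 1))
}

# ---------------------------------------------------------------------------
# Active load bearing Gamma_act = int_a^b t_theta_theta^act*(lambda_theta)/r dr

# Elementary integrals over the loaded wall (a -> b, R: A -> B):
#   int dr/R      = ln((B + sqrt(lz) b)/(A + sqrt(lz) a)) / sqrt(lz)
#   int r/R^2 dr  = ln(B^2/A^2) / (2 lz)
.I_1overR <- function(geom, state, b) {
  lz <- state$lambda_z
  log((geom$B + sqrt(lz) * b) / (geom$A + sqrt(lz) * state$a)) / sqrt(lz)
}

.no_closed_form <- function(model, why) {
  stop(structure(class = c("vasotone_no_closed_form", "error", "condition"),
                 list(message = sprintf(
                   "no closed-form active pressure for '%s': %s; use active_pressure_quadrature()",
                   model$family, why), call = sys.call(-1))))
}

# Whole-wall lambda_theta range.
.wall_lt_range <- function(geom, state) {
  b <- deformed_outer_radius(geom, state)
  range(state$a / geom$A, b / geom$B)
}

#' Closed-form active load bearing
#'
#' Exact printed closed forms of the active pressure contribution
#' `Gamma_act = int_a^b t^act/r dr`:
#' constant Cauchy `Tc ln(b/a)`; constant 1st PK
#' `Ti/sqrt(lz) ln((B + sqrt(lz) b)/(A + sqrt(lz) a))`; constant 2nd PK
#' `Tr/(2 lz) ln(B^2/A^2)` (deformation-independent); Rachev and
#' Franchini (`m1 = 2`) polynomial-in-`lambda_theta^2` forms; Zulliger as
#' the `lambda_pre`-weighted difference of the 1st-PK and Cauchy forms.
#' For Rachev the whole wall must lie inside the bell support, and for
#' Zulliger inside the gate; otherwise a condition of class
#' `vasotone_no_closed_form` is signalled, naming the quadrature fallback.
#'
#' @param model an [active_model()].
#' @param geom a [vessel_geometry()].
#' @param state a [deformation_state()].
#' @return `Gamma_act` (kPa).
#' @seealso [active_pressure_quadrature()]
#' @export
active_pressure_closed_form <- function(model, geom, state) {
  UseMethod("active_pressure_closed_form")
}

#' @export
active_pressure_closed_form.am_constant_cauchy <- function(model, geom, state) {
  b <- deformed_outer_radius(geom, state)
  model$Tc * log(b / state$a)
}
#' @export
active_pressure_closed_form.am_constant_1pk <- function(model, geom, state) {
  b <- deformed_outer_radius(geom, state)
  model$Ti * .I_1overR(geom, state, b)
}
#' @export
active_pressure_closed_form.am_constant_2pk <- function(model, geom, state) {
  model$Tr / (2 * state$lambda_z) * log(geom$B^2 / geom$A^2)
}
#' @export
active_pressure_closed_form.am_rachev <- function(model, geom, state) {
  lt <- .wall_lt_range(geom, state)
  lm <- model$lambda_m; l0 <- model$lambda_0
  if (lt[1] < l0 || lt[2] > 2 * lm - l0) {
    .no_closed_form(model, sprintf(
      "wall stretch range [%.4g, %.4g] leaves the force-length support [%.4g, %.4g]",
      lt[1], lt[2], l0, 2 * lm - l0))
  }
  b <- deformed_outer_radius(geom, state)
  lz <- state$lambda_z
  d2 <- (lm - l0)^2
  model$TRv / (sqrt(lz) * d2) * (d2 - lm^2 - 1 / lz) * sqrt(lz) * .I_1overR(geom, state, b) +
    model$TRv / (lz * d2) *
      (lm * log(geom$B^2 / geom$A^2) + b / geom$B - state$a / geom$A)
}
#' @export
active_pressure_closed_form.am_zulliger <- function(model, geom, state) {
  lt <- .wall_lt_range(geom, state)
  lh <- lt * model$lambda_pre
  if (lh[1] < model$lambda_hat_lb || lh[2] > model$lambda_hat_ub) {
    .no_closed_form(model, sprintf(
      "muscle stretch range [%.4g, %.4g] leaves the gate [%.4g, %.4g]",
      lh[1], lh[2], model$lambda_hat_lb, model$lambda_hat_ub))
  }
  b <- deformed_outer_radius(geom, state)
  model$S1 * model$TZr *
    (model$lambda_pre * .I_1overR(geom, state, b) - log(b / state$a))
}
#' @export
active_pressure_closed_form.am_franchini <- function(model, geom, state) {
  if (model$m1 != 2L) {
    .no_closed_form(model, sprintf("m1 = %d (closed form printed for m1 = 2)", model$m1))
  }
  b <- deformed_outer_radius(geom, state)
  A <- geom$A; B <- geom$B; a <- state$a; lz <- state$lambda_z
  T1 <- model$S1 * model$TFr1; a1 <- model$alpha1; b1 <- model$beta1
  L <- log(B^2 / A^2)
  K <- A^2 - a^2 * lz
  T1 * (1 - a1 - b1) / lz * L +
    T1 * (a1 + 2 * b1) / lz^2 * (L + K * (A^2 - B^2) / (A^2 * B^2)) -
    T1 * b1 / lz^3 *
      (L + K / 2 * ((3 * B^2 + b^2 * lz) / B^4 - (3 * A^2 + a^2 * lz) / A^4))
}

#' Active load bearing by adaptive quadrature
#'
#' Integrates `t_theta_theta^act*(lambda_theta(r))/r` over the loaded wall
#' with adaptive quadrature, splitting the interval at radii where the
#' Rachev support or Zulliger gate switches on/off so each piece is smooth.
#' Valid for every family and parameter set (including Franchini with
#' `m1 != 2`).
#'
#' @inheritParams active_pressure_closed_form
#' @return `Gamma_act` (kPa).
#' @export
active_pressure_quadrature <- function(model, geom, state) {
  stopifnot(inherits(model, "active_model"))
  b <- deformed_outer_radius(geom, state)
  breaks <- switch(model$family,
    rachev = .lambda_theta_crossings(
      c(model$lambda_0, 2 * model$lambda_m - model$lambda_0), geom, state),
    zulliger = .lambda_theta_crossings(
      c(model$lambda_hat_lb, model$lambda_hat_ub) / model$lambda_pre, geom, state),
    numeric(0))
  pts <- sort(unique(c(state$a, breaks, b)))
  f <- function(r) {
    lt <- .lambda_theta_at(r, geom, state)
    active_cauchy_stress(model, lt) / r
  }
  total <- 0
  for (j in seq_len(length(pts) - 1L)) {
    q <- stats::integrate(f, pts[j], pts[j + 1L], rel.tol = 1e-11,
                          abs.tol = 1e-13, subdivisions = 400L)
    total <- total + q$value
  }
  total
}

# ---------------------------------------------------------------------------
# dGamma_act/da

# shorthand used by the 1st PK / Rachev / Zulliger derivatives
.D_1pk_unit <- function(geom, state, b) {
  lz <- state$lambda_z
  sA <- geom$A + sqrt(lz) * state$a
  sB <- geom$B + sqrt(lz) * b
  (state$a * sA - b * sB) / (b * sA * sB)
}
.D_cauchy_unit <- function(state, b) {
  (state$a^2 - b^2) / (state$a * b^2)
}

#' Radius derivative of the active load bearing
#'
#' Exact printed derivatives `dGamma_act/da` per family: constant Cauchy
#' `Tc (a^2 - b^2)/(a b^2)` (negative for all deformations); constant 1st PK
#' (negative for all deformations); constant 2nd PK exactly 0; Rachev,
#' Zulliger (within its gate) and Franchini (`m1 = 2`) analytic forms. Where
#' a closed form does not apply (Rachev support or Zulliger gate partially
#' inside the wall, Franchini `m1 != 2`), a central finite difference of
#' [active_pressure_quadrature()] is used.
#'
#' @inheritParams active_pressure_closed_form
#' @return `dGamma_act/da` (kPa/mm).
#' @export
active_pressure_derivative <- function(model, geom, state) {
  UseMethod("active_pressure_derivative")
}

#' @export
active_pressure_derivative.am_constant_cauchy <- function(model, geom, state) {
  b <- deformed_outer_radius(geom, state)
  model$Tc * .D_cauchy_unit(state, b)
}
#' @export
active_pressure_derivative.am_constant_1pk <- function(model, geom, state) {
  b <- deformed_outer_radius(geom, state)
  model$Ti * .D_1pk_unit(geom, state, b)
}
#' @export
active_pressure_derivative.am_constant_2pk <- function(model, geom, state) {
  0
}
#' @export
active_pressure_derivative.am_rachev <- function(model, geom, state) {
  lt <- .wall_lt_range(geom, state)
  lm <- model$lambda_m; l0 <- model$lambda_0
  if (lt[1] < l0 || lt[2] > 2 * lm - l0) {
    return(.fd_active_derivative(model, geom, state))
  }
  b <- deformed_outer_radius(geom, state)
  A <- geom$A; B <- geom$B; a <- state$a; lz <- state$lambda_z
  d2 <- (lm - l0)^2
  model$TRv / d2 * (.D_1pk_unit(geom, state, b) * (d2 - lm^2 - 1 / lz) +
                      (A * a - B * b) / (A * B * b * lz))
}
#' @export
active_pressure_derivative.am_zulliger <- function(model, geom, state) {
  lt <- .wall_lt_range(geom, state)
  lh <- lt * model$lambda_pre
  if (lh[1] < model$lambda_hat_lb || lh[2] > model$lambda_hat_ub) {
    return(.fd_active_derivative(model, geom, state))
  }
  b <- deformed_outer_radius(geom, state)
  model$S1 * model$TZr *
    (model$lambda_pre * .D_1pk_unit(geom, state, b) - .D_cauchy_unit(state, b))
}
#' @export
active_pressure_derivative.am_franchini <- function(model, geom, state) {
  if (model$m1 != 2L) return(.fd_active_derivative(model, geom, state))
  b <- deformed_outer_radius(geom, state)
  A <- geom$A; B <- geom$B; a <- state$a; lz <- state$lambda_z
  T1 <- model$S1 * model$TFr1; a1 <- model$alpha1; b1 <- model$beta1
  2 * T1 * (a1 + 2 * b1) * a * (B^2 - A^2) / (A^2 * B^2 * lz) -
    2 * T1 * b1 * a *
      (B^4 * (A^2 + a^2 * lz) - A^4 * (B^2 + b^2 * lz)) / (A^4 * B^4 * lz^2)
}

# Central finite-difference fallback on the quadrature form.
.fd_active_derivative <- function(model, geom, state, h = NULL) {
  if (is.null(h)) h <- 1e-5 * max(state$a, geom$A)
  g <- function(a) active_pressure_quadrature(
    model, geom, deformation_state(a, state$lambda_z))
  (g(state$a + h) - g(state$a - h)) / (2 * h)
}

#' Analytic stability condition of the active contribution
#'
#' Evaluates, per family, the printed inequality deciding the sign of
#' `dGamma_act/da` at the given state:
#' * Rachev: `lambda_m^2 - (lambda_m - lambda_0)^2 > rhs(geometry, state)`
#'   stabilises (`dGamma_act/da > 0`);
#' * Zulliger (within its gate): `lambda_pre < rhs(geometry, state)`;
#' * Franchini (`m1 = 2`): `alpha1 > beta1 * (rhs - 2)` written as
#'   `alpha1 > rhs'`;
#' * constant Cauchy / 1st PK: destabilising for every admissible state
#'   (derivative provably negative);
#' * constant 2nd PK: neutral (derivative identically zero).
#'
#' For unsupported cases (Franchini `m1 != 2`, Rachev/Zulliger with the wall
#' partially outside support/gate) the sign of the finite-difference
#' derivative is reported with `analytic = FALSE`.
#'
#' @inheritParams active_pressure_closed_form
#' @return list with fields `is_stabilising` (logical: `dGamma_act/da > 0`),
#'   `neutral` (logical: derivative identically zero), `lhs`, `rhs`
#'   (numeric sides of the inequality, `NA` where not applicable), and
#'   `analytic` (logical).
#' @export
stability_condition <- function(model, geom, state) {
  stopifnot(inherits(model, "active_model"))
  b <- deformed_outer_radius(geom, state)
  A <- geom$A; B <- geom$B; a <- state$a; lz <- state$lambda_z
  sA <- A + sqrt(lz) * a
  sB <- B + sqrt(lz) * b
  res <- switch(model$family,
    constant_cauchy = list(is_stabilising = FALSE, neutral = FALSE,
                           lhs = NA_real_, rhs = NA_real_, analytic = TRUE),
    constant_1pk = list(is_stabilising = FALSE, neutral = FALSE,
                        lhs = NA_real_, rhs = NA_real_, analytic = TRUE),
    constant_2pk = list(is_stabilising = FALSE, neutral = TRUE,
                        lhs = 0, rhs = 0, analytic = TRUE),
    rachev = {
      lt <- .wall_lt_range(geom, state)
      if (lt[1] < model$lambda_0 || lt[2] > 2 * model$lambda_m - model$lambda_0) {
        d <- .fd_active_derivative(model, geom, state)
        list(is_stabilising = d > 0, neutral = FALSE,
             lhs = NA_real_, rhs = NA_real_, analytic = FALSE)
      } else {
        lhs <- model$lambda_m^2 - (model$lambda_m - model$lambda_0)^2
        rhs <- a * b * (B * sB - A * sA) /
          (sqrt(lz) * A * B * (b * sB - a * sA))
        list(is_stabilising = lhs > rhs, neutral = FALSE,
             lhs = lhs, rhs = rhs, analytic = TRUE)
      }
    },
    zulliger = {
      lt <- .wall_lt_range(geom, state)
      lh <- lt * model$lambda_pre
      if (lh[1] < model$lambda_hat_lb || lh[2] > model$lambda_hat_ub) {
        d <- .fd_active_derivative(model, geom, state)
        list(is_stabilising = d > 0, neutral = FALSE,
             lhs = NA_real_, rhs = NA_real_, analytic = FALSE)
      } else {
        lhs <- model$lambda_pre
        rhs <- (b^2 - a^2) * sA * sB / (a * b * (b * sB - a * sA))
        list(is_stabilising = lhs < rhs, neutral = FALSE,
             lhs = lhs, rhs = rhs, analytic = TRUE)
      }
    },
    franchini = {
      if (model$m1 != 2L) {
        d <- .fd_active_derivative(model, geom, state)
        list(is_stabilising = d > 0, neutral = FALSE,
             lhs = NA_real_, rhs = NA_real_, analytic = FALSE)
      } else {
        lhs <- model$alpha1
        rhs <- model$beta1 *
          ((B^4 * (A^2 + a^2 * lz) - A^4 * (B^2 + b^2 * lz)) /
             (A^2 * B^2 * (B^2 - A^2) * lz) - 2)
        list(is_stabilising = lhs > rhs, neutral = FALSE,
             lhs = lhs, rhs = rhs, analytic = TRUE)
      }
    })
  res
}

# Gamma_act preferring the closed form, quadrature as fallback.
.active_pressure <- function(model, geom, state) {
  if (is.null(model)) return(0)
  tryCatch(active_pressure_closed_form(model, geom, state),
           vasotone_no_closed_form = function(e)
             active_pressure_quadrature(model, geom, state))
}
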