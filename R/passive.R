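# Four-fibre family passive hyperelasticity. The wall is a constrained
# mixture of an isotropic (elastin-like) neo-Hookean matrix and four
# exponential collagen fibre families (axial 0 deg, circumferential 90 deg,
# and a symmetric +/- diagonal pair), all sharing the tissue deformation.
#
# Psi = mu/2 (I1 - 3) + sum_i k1_i/(4 k2_i) [exp(k2_i (I4_i - 1)^2) - 1]
# with I4_i = lambda_theta^2 sin^2(alpha_i) + lambda_z^2 cos^2(alpha_i),
# alpha measured from the axial direction.

#' Passive four-fibre family wall parameters
#'
#' @param mu isotropic (elastin-like) stiffness parameter (kPa), `>= 0`.
#' @param families data.frame with one row per fibre family and columns
#'   `k1` (kPa, `>= 0`), `k2` (dimensionless, `> 0`), `alpha_deg` (fibre
#'   angle from the axial direction, degrees). The canonical four-family
#'   arrangement is 0, 90, `+alpha`, `-alpha`; any non-negative number of
#'   families is accepted (zero families gives a neo-Hookean wall).
#' @param tension_only if `TRUE`, fibre families contribute only when
#'   extended (`I4 > 1`). Off by default: the energy is evaluated literally,
#'   with compressed fibres storing energy through the same exponential.
#' @return an object of class `passive_params`.
#' @examples
#' passive_params(mu = 30, families = data.frame(
#'   k1 = c(15, 10, 8, 8), k2 = c(0.8, 0.6, 1.2, 1.2),
#'   alpha_deg = c(0, 90, 45, -45)))
#' @export
passive_params <- function(mu, families = NULL, tension_only = FALSE) {
  stopifnot(is.numeric(mu), length(mu) == 1L, mu >= 0)
  if (is.null(families)) {
    families <- data.frame(k1 = numeric(0), k2 = numeric(0), alpha_deg = numeric(0))
  }
  stopifnot(is.data.frame(families),
            all(c("k1", "k2", "alpha_deg") %in% names(families)))
  if (nrow(families) > 0) {
    stopifnot(all(families$k1 >= 0), all(families$k2 > 0))
  }
  structure(list(mu = mu, families = families,
                 tension_only = isTRUE(tension_only)),
            class = "passive_params")
}

#' @export
print.passive_params <- function(x, ...) {
  cat(sprintf("<passive_params> mu = %g kPa, %d fibre families\n",
              x$mu, nrow(x$families)))
  if (nrow(x$families)) print(x$families)
  invisible(x)
}

# I4 and the common per-family factors of the fibre response. The Cauchy
# extra stress of a fibre family is the push-forward of the energy above:
#   2 lambda^2 dPsi/dI4 * (dI4/dC component) = k1 (I4-1) e^{k2 (I4-1)^2} ...
.fibre_terms <- function(lambda_theta, lambda_z, params) {
  fam <- params$families
  if (nrow(fam) == 0) return(NULL)
  al <- fam$alpha_deg * pi / 180
  s2 <- sin(al)^2
  c2 <- cos(al)^2
  I4 <- outer(lambda_theta^2, s2) + matrix(rep(lambda_z^2 * c2,
                                               each = length(lambda_theta)),
                                           nrow = length(lambda_theta))
  e <- I4 - 1
  if (params$tension_only) e[e < 0] <- 0
  list(I4 = I4, e = e, s2 = s2, c2 = c2,
       k1 = fam$k1, k2 = fam$k2)
}

#' Passive stored energy density
#'
#' Evaluates the four-fibre family strain energy (kPa) at the given
#' principal stretches. Vectorised over equal-length stretch vectors.
#'
#' @param lambda_r,lambda_theta,lambda_z principal stretches (`> 0`).
#' @param params a [passive_params()].
#' @return strain energy density (kPa).
#' @export
passive_energy <- function(lambda_r, lambda_theta, lambda_z, params) {
  stopifnot(inherits(params, "passive_params"))
  I1 <- lambda_r^2 + lambda_theta^2 + lambda_z^2
  psi <- params$mu / 2 * (I1 - 3)
  ft <- .fibre_terms(lambda_theta, lambda_z, params)
  if (!is.null(ft)) {
    fib <- sweep(expm1(sweep(ft$e^2, 2, ft$k2, `*`)), 2,
                 ft$k1 / (4 * ft$k2), `*`)
    psi <- psi + rowSums(fib)
  }
  psi
}

#' Passive Cauchy extra stress components
#'
#' Push-forward `2 F (dPsi/dC) F^T` of the passive energy for the diagonal
#' deformation gradient, returning the radial, circumferential and axial
#' components of the passive extra stress (kPa, before the Lagrange
#' multiplier is applied). With the `k1/(4 k2)` exponential fibre energy the
#' circumferential fibre contribution is
#' `k1 (I4 - 1) exp(k2 (I4 - 1)^2) lambda_theta^2 sin^2(alpha)` (and the
#' axial analogue with `cos^2`), consistent with the energy by construction
#' (verified against a finite-difference push-forward in the tests).
#'
#' @inheritParams passive_energy
#' @return list with numeric fields `trr`, `ttt`, `tzz` (kPa).
#' @export
passive_extra_stress <- function(lambda_r, lambda_theta, lambda_z, params) {
  stopifnot(inherits(params, "passive_params"))
  n <- length(lambda_theta)
  trr <- params$mu * lambda_r^2
  ttt <- params$mu * lambda_theta^2
  tzz <- rep(params$mu * lambda_z^2, length.out = n)
  ft <- .fibre_terms(lambda_theta, lambda_z, params)
  if (!is.null(ft)) {
    g <- sweep(ft$e * exp(sweep(ft$e^2, 2, ft$k2, `*`)), 2, ft$k1, `*`)
    ttt <- ttt + rowSums(sweep(g, 2, ft$s2, `*`) * lambda_theta^2)
    tzz <- tzz + rowSums(sweep(g, 2, ft$c2, `*`)) * lambda_z^2
  }
  list(trr = trr, ttt = ttt, tzz = tzz)
}

# Integrand (ttt* - trr*)/r of the passive load-bearing integral,
# vectorised over loaded radius r.
.passive_integrand <- function(r, geom, state, params) {
  R <- reference_radius(r, geom, state)
  lt <- r / R
  lr <- 1 / (lt * state$lambda_z)
  st <- passive_extra_stress(lr, lt, state$lambda_z, params)
  (st$ttt - st$trr) / r
}

#' Passive contribution to transmural pressure
#'
#' Adaptive quadrature of `(t_theta_theta^pas* - t_rr^pas*)/r` across the
#' loaded wall, giving the passive load-bearing term of the pressure split
#' `P = Gamma_pas + Gamma_act`.
#'
#' @param geom a [vessel_geometry()].
#' @param state a [deformation_state()].
#' @param params a [passive_params()].
#' @return passive pressure contribution (kPa).
#' @export
passive_pressure <- function(geom, state, params) {
  b <- deformed_outer_radius(geom, state)
  if (params$mu == 0 && (nrow(params$families) == 0 || all(params$families$k1 == 0))) {
    return(0)
  }
  q <- stats::integrate(.passive_integrand, state$a, b,
                        geom = geom, state = state, params = params,
                        rel.tol = 1e-10, abs.tol = 1e-12,
                        subdivisions = 400L, stop.on.error = FALSE)
  if (q$message != "OK" && abs(q$abs.error) > 1e-6 * max(1, abs(q$value))) {
    stop(sprintf("passive pressure quadrature failed: %s (value %g, abs.err %g)",
                 q$message, q$value, q$abs.error))
  }
  q$value
}

#' Radius derivative of the passive pressure
#'
#' Central finite difference of [passive_pressure()] with respect to the
#' loaded inner radius, with one step of Richardson extrapolation
#' (step-halving) as an internal consistency check.
#'
#' @inheritParams passive_pressure
#' @param h optional finite-difference step (mm); default scales with `a`.
#' @return `d Gamma_pas / d a` (kPa/mm).
#' @export
passive_pressure_derivative <- function(geom, state, params, h = NULL) {
  if (is.null(h)) h <- 1e-4 * max(state$a, geom$A)
  g <- function(a) passive_pressure(geom, deformation_state(a, state$lambda_z), params)
  d1 <- (g(state$a + h) - g(state$a - h)) / (2 * h)
  d2 <- (g(state$a + h / 2) - g(state$a - h / 2)) / h
  (4 * d2 - d1) / 3
}

#' Transmural stress field
#'
#' Total Cauchy stress components through the wall at equilibrium with
#' luminal pressure `P` (kPa). The Lagrange multiplier is recovered from the
#' radial equilibrium integral, enforcing `t_rr(a) = -P` and `t_rr(b) = 0`.
#' `P` must equal the total pressure implied by the configuration and
#' constitutive laws (validated to `tol`).
#'
#' @inheritParams passive_pressure
#' @param active_model an [active_model()] or `NULL` for the fully relaxed
#'   wall.
#' @param P luminal transmural pressure (kPa).
#' @param n number of radial grid points.
#' @param tol consistency tolerance on `P` (kPa).
#' @return an object of class `wall_stress_field`: list with radial grid `r`
#'   and stress components `trr`, `ttt`, `tzz` and Lagrange multiplier `p`
#'   (kPa) at each grid point.
#' @export
transmural_stress_field <- function(geom, state, params, active_model = NULL,
                                    P, n = 101L, tol = 1e-6) {
  b <- deformed_outer_radius(geom, state)
  P_model <- total_pressure(geom, state, params, active_model)
  if (abs(P - P_model) > max(tol, 1e-8 * abs(P_model))) {
    stop(sprintf("P = %g kPa inconsistent with equilibrium pressure %g kPa",
                 P, P_model))
  }
  r <- seq(state$a, b, length.out = n)
  R <- reference_radius(r, geom, state)
  lt <- r / R
  lr <- 1 / (lt * state$lambda_z)
  st <- passive_extra_stress(lr, lt, state$lambda_z, params)
  ttt_act <- if (is.null(active_model)) 0 else active_cauchy_stress(active_model, lt)
  integrand <- function(rr) {
    RR <- reference_radius(rr, geom, state)
    ltr <- rr / RR
    lrr <- 1 / (ltr * state$lambda_z)
    s <- passive_extra_stress(lrr, ltr, state$lambda_z, params)
    act <- if (is.null(active_model)) 0 else active_cauchy_stress(active_model, ltr)
    (s$ttt - s$trr + act) / rr
  }
  seg <- vapply(seq_len(n - 1L), function(j)
    stats::integrate(integrand, r[j], r[j + 1L], rel.tol = 1e-10,
                     abs.tol = 1e-13, subdivisions = 200L)$value,
    numeric(1))
  cum <- c(0, cumsum(seg))
  trr <- -P + cum
  structure(list(r = r,
                 trr = trr,
                 ttt = trr + (st$ttt - st$trr) + ttt_act,
                 tzz = trr + (st$tzz - st$trr),
                 p = st$trr - trr),
            class = "wall_stress_field")
}
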