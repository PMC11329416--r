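# Incompressible axisymmetric kinematics of a pressurised cylinder at fixed
# axial stretch. The reference configuration is the unloaded, traction-free,
# residual-stress-free tube (no opening angle). Lengths are in mm; radii are
# used internally, diameters only at the I/O boundary.

#' Unloaded vessel geometry
#'
#' Reference (unloaded) configuration of the arterial segment, described by
#' its inner radius `A` and outer radius `B` (mm). The reference state is
#' assumed traction-free and residual-stress-free.
#'
#' @param A unloaded inner radius (mm), `0 < A < B`.
#' @param B unloaded outer radius (mm).
#' @return an object of class `vessel_geometry` with fields `A`, `B`.
#' @examples
#' vessel_geometry(A = 0.8, B = 1.0)
#' @export
vessel_geometry <- function(A, B) {
  stopifnot(is.numeric(A), is.numeric(B), length(A) == 1L, length(B) == 1L)
  if (!is.finite(A) || !is.finite(B) || A <= 0 || B <= A) {
    stop("vessel_geometry requires 0 < A < B (mm)")
  }
  structure(list(A = A, B = B), class = "vessel_geometry")
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf("<vessel_geometry> A = %g mm, B = %g mm (wall %g mm)\n",
              x$A, x$B, x$B - x$A))
  invisible(x)
}

#' Loaded deformation state
#'
#' A loaded configuration at fixed axial stretch: the loaded inner radius `a`
#' (mm) together with the prescribed axial stretch `lambda_z`. The axial
#' stretch is held constant during pressurisation, consistent with ex vivo
#' inflation protocols at in vivo axial length.
#'
#' @param a loaded inner radius (mm), `a > 0`.
#' @param lambda_z axial stretch (dimensionless), `> 0`.
#' @return an object of class `deformation_state` with fields `a`, `lambda_z`.
#' @examples
#' deformation_state(a = 1.2, lambda_z = 1.6)
#' @export
deformation_state <- function(a, lambda_z) {
  stopifnot(is.numeric(a), is.numeric(lambda_z),
            length(a) == 1L, length(lambda_z) == 1L)
  if (!is.finite(a) || a <= 0) stop("loaded inner radius a must be > 0")
  if (!is.finite(lambda_z) || lambda_z <= 0) stop("lambda_z must be > 0")
  structure(list(a = a, lambda_z = lambda_z), class = "deformation_state")
}

#' Loaded outer radius from incompressibility
#'
#' Volume conservation of the incompressible wall gives the loaded outer
#' radius `b = sqrt((B^2 - A^2)/lambda_z + a^2)`.
#'
#' @param geom a [vessel_geometry()].
#' @param state a [deformation_state()].
#' @return loaded outer radius `b` (mm), `b > a`.
#' @examples
#' g <- vessel_geometry(1, 2)
#' deformed_outer_radius(g, deformation_state(1, 1)) # == 2
#' @export
deformed_outer_radius <- function(geom, state) {
  stopifnot(inherits(geom, "vessel_geometry"), inherits(state, "deformation_state"))
  sqrt((geom$B^2 - geom$A^2) / state$lambda_z + state$a^2)
}

#' Reference radial coordinate of a loaded material point
#'
#' Inverts the incompressible deformation map:
#' `R = sqrt((r^2 - a^2) * lambda_z + A^2)` for `r` in `[a, b]`.
#'
#' @param r loaded radial coordinate(s) (mm), each within `[a, b]`.
#' @inheritParams deformed_outer_radius
#' @return reference radius `R` (mm), within `[A, B]`.
#' @export
reference_radius <- function(r, geom, state) {
  stopifnot(inherits(geom, "vessel_geometry"), inherits(state, "deformation_state"))
  b <- deformed_outer_radius(geom, state)
  tol <- 1e-10 * max(1, b)
  if (any(r < state$a - tol) || any(r > b + tol)) {
    stop(sprintf("r outside the loaded wall [a, b] = [%g, %g]", state$a, b))
  }
  r <- pmin(pmax(r, state$a), b)
  sqrt((r^2 - state$a^2) * state$lambda_z + geom$A^2)
}

#' Principal stretches of the diagonal deformation gradient
#'
#' For inflation plus axial extension without torsion,
#' `F = diag(lambda_r, lambda_theta, lambda_z)` with
#' `lambda_theta = r / R` and `lambda_r = R / (r * lambda_z)` by
#' incompressibility, so `lambda_r * lambda_theta * lambda_z = 1` exactly.
#'
#' @param r loaded radial coordinate(s) (mm).
#' @param R reference radial coordinate(s) (mm).
#' @param lambda_z axial stretch.
#' @return list with numeric fields `lambda_r`, `lambda_theta`, `lambda_z`.
#' @export
stretches <- function(r, R, lambda_z) {
  stopifnot(all(r > 0), all(R > 0), lambda_z > 0)
  lt <- r / R
  list(lambda_r = 1 / (lt * lambda_z), lambda_theta = lt, lambda_z = lambda_z)
}

# Circumferential stretch profile at loaded radius r (vectorised).
.lambda_theta_at <- function(r, geom, state) {
  r / reference_radius(r, geom, state)
}

# Radii in (a, b) at which lambda_theta(r) crosses `target`. lambda_theta is
# monotone in r (sign of A^2 - a^2*lambda_z), so at most one crossing per
# target. Used to split quadrature at Rachev support / Zulliger gate edges.
.lambda_theta_crossings <- function(targets, geom, state) {
  b <- deformed_outer_radius(geom, state)
  lt_a <- state$a / geom$A
  lt_b <- b / geom$B
  lo <- min(lt_a, lt_b); hi <- max(lt_a, lt_b)
  out <- numeric(0)
  for (t in targets) {
    if (is.finite(t) && t > lo && t < hi) {
      f <- function(r) .lambda_theta_at(r, geom, state) - t
      out <- c(out, stats::uniroot(f, c(state$a, b), tol = 1e-12)$root)
    }
  }
  sort(out)
}
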