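# Thin-walled (membrane) approximation. When only the radius-to-thickness
# ratio b0/h0 at zero pressure is known (canine protocol), the modelled
# active pressure is
#   Gamma_act_mod = t_theta_theta^act*(lambda_theta) * (h0/b0) / (lambda_theta^2 * lambda_z)
# with the average wall stretch approximated by the normalised outer
# diameter b/b0. The experimental counterpart is the pressure difference
# between maximally contracted and fully relaxed curves resampled at common
# normalised diameters.

#' Thin-walled vessel description
#'
#' @param radius_to_thickness `b0/h0`, outer radius over wall thickness in
#'   the zero-pressure configuration (`> 1`).
#' @param lambda_z axial stretch during inflation (1 for the canine
#'   protocol: vessels pre-stretched to in vivo length, no further stretch).
#' @return an object of class `thinwall_vessel`.
#' @export
thin_wall_vessel <- function(radius_to_thickness, lambda_z = 1) {
  stopifnot(is.numeric(radius_to_thickness), length(radius_to_thickness) == 1L,
            radius_to_thickness > 1, lambda_z > 0)
  structure(list(radius_to_thickness = radius_to_thickness,
                 lambda_z = lambda_z),
            class = "thinwall_vessel")
}

#' Modelled thin-wall active pressure
#'
#' @param active_model an [active_model()].
#' @param vessel a [thin_wall_vessel()].
#' @param lambda_theta circumferential stretch(es), approximated by the
#'   normalised outer diameter `b/b0`.
#' @return `Gamma_act_mod` (kPa), vectorised over `lambda_theta`.
#' @export
thinwall_active_pressure <- function(active_model, vessel, lambda_theta) {
  stopifnot(inherits(vessel, "thinwall_vessel"), all(lambda_theta > 0))
  active_cauchy_stress(active_model, lambda_theta) /
    (vessel$radius_to_thickness * lambda_theta^2 * vessel$lambda_z)
}

# Normalised-diameter representation of a pd_curve: d = outer diameter /
# reference diameter d0. When d0 is NULL it is taken as this curve's
# diameter at zero pressure (interpolated if 0 not sampled). Both states of
# a contraction pair share the relaxed zero-pressure diameter so that the
# normalised diameter approximates one common wall stretch axis.
.normalised_curve <- function(curve, name = "curve", d0 = NULL) {
  stopifnot(inherits(curve, "pd_curve"))
  P <- curve$pressure_kPa
  D <- curve$outer_diameter_mm
  if (any(diff(D) <= 0)) stop(sprintf("%s: outer diameter not strictly increasing", name))
  if (is.null(d0)) {
    if (min(P) > 1e-9) stop(sprintf("%s: curve does not reach 0 pressure; cannot normalise", name))
    d0 <- stats::approx(P, D, xout = 0, rule = 1)$y
  }
  list(P = P, d = D / d0, d0 = d0)
}

#' Experimental active pressure from paired curves
#'
#' Resamples the fully relaxed and maximally contracted pressure-normalised
#' diameter relationships at `n_samples` common normalised diameters
#' (uniform over the overlap of the two diameter ranges) and returns
#' `Gamma_act_exp = P_contracted - P_relaxed` at each sample. Pressure is
#' interpolated as a function of normalised diameter with a monotone
#' piecewise-cubic (Fritsch-Carlson) scheme; `method = "linear"` falls back
#' to linear interpolation.
#'
#' @param relaxed,contracted `pd_curve` objects (see
#'   [pressure_diameter_curve()] or [read_pd_csv()]), each monotone in
#'   diameter; the relaxed curve must reach 0 pressure, and both are
#'   normalised by the relaxed zero-pressure diameter (one common stretch
#'   axis). Curves already carrying normalised diameters are handled
#'   identically (the reference is then ~1).
#' @param n_samples number of common normalised-diameter samples.
#' @param method interpolation scheme, `"monotone_cubic"` (default) or
#'   `"linear"`.
#' @return an object of class `active_pressure_samples`: data.frame with
#'   columns `normalised_diameter`, `gamma_act_kPa`; attribute `lambda_z`
#'   from the relaxed curve.
#' @export
experimental_active_pressure <- function(relaxed, contracted, n_samples = 13L,
                                         method = c("monotone_cubic", "linear")) {
  method <- match.arg(method)
  rel <- .normalised_curve(relaxed, "relaxed")
  con <- .normalised_curve(contracted, "contracted", d0 = rel$d0)
  lo <- max(min(rel$d), min(con$d))
  hi <- min(max(rel$d), max(con$d))
  if (lo >= hi) stop("relaxed and contracted curves have no normalised-diameter overlap")
  d <- seq(lo, hi, length.out = n_samples)
  interp <- function(x, y, xout) {
    if (method == "monotone_cubic") {
      stats::splinefun(x, y, method = "monoH.FC")(xout)
    } else {
      stats::approx(x, y, xout = xout, rule = 2)$y
    }
  }
  gamma <- interp(con$d, con$P, d) - interp(rel$d, rel$P, d)
  structure(data.frame(normalised_diameter = d, gamma_act_kPa = gamma),
            lambda_z = attr(relaxed, "lambda_z"),
            class = c("active_pressure_samples", "data.frame"))
}
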