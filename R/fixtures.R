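# Deterministic synthetic-data generators emulating the two experimental
# protocols: a murine descending-thoracic-aorta-like vessel contracted at a
# held pressure (single-point regime), and canine-artery-like paired
# relaxed/contracted pressure-normalised-diameter curves sampled every
# 20 mmHg over 0-240 mmHg (dense regime).
#
# The murine passive parameters below are documented stand-ins, frozen in
# version control: they emulate a compliant-then-stiffening aortic response
# at axial stretch 1.60 but are NOT the published supplementary values for
# any specific animal.

#' Mouse-aorta-like synthetic vessel fixture
#'
#' Returns a stand-in unloaded geometry, four-fibre passive parameter set,
#' and in vivo axial stretch (1.60) producing a physiologically shaped
#' relaxed pressure-diameter curve: compliant below ~60 mmHg, stiffening
#' above ~120 mmHg. Values are frozen synthetic stand-ins, not measured
#' parameters.
#'
#' @return list with fields `geom` ([vessel_geometry()]), `passive`
#'   ([passive_params()]), `lambda_z` (1.60).
#' @export
make_mouse_like_vessel <- function() {
  geom <- vessel_geometry(A = 0.55, B = 0.70)
  passive <- passive_params(
    mu = 20,
    families = data.frame(
      k1 = c(12, 8, 6, 6),
      k2 = c(0.25, 0.6, 0.9, 0.9),
      alpha_deg = c(0, 90, 45, -45)))
  list(geom = geom, passive = passive, lambda_z = 1.60)
}

#' Forward-simulate a single-point contraction datum
#'
#' Solves the relaxed and contracted configurations of a vessel fixture at a
#' held pressure and returns the exact (noise-free) fractional reduction in
#' outer diameter, for parameter-recovery round trips.
#'
#' @param vessel list with `geom`, `passive`, `lambda_z` (see
#'   [make_mouse_like_vessel()]).
#' @param true_model an [active_model()] generating the contraction, or
#'   `NULL` (zero reduction).
#' @param P_hold_mmHg held pressure (mmHg).
#' @param allow_unstable if `FALSE` (default), an error is raised when the
#'   contracted pressure-radius relation has multiple roots at the held
#'   pressure; if `TRUE` the smallest-radius root is used.
#' @return a [contraction_datum()].
#' @export
generate_contraction_datum <- function(vessel, true_model, P_hold_mmHg = 90,
                                       allow_unstable = FALSE) {
  P <- mmHg_to_kPa(P_hold_mmHg)
  lz <- vessel$lambda_z
  b_of <- function(a) deformed_outer_radius(vessel$geom,
                                            deformation_state(a, lz))
  a_rel <- solve_radius(P, vessel$geom, lz, vessel$passive, NULL)
  if (length(a_rel) > 1L) stop("relaxed fixture curve is not monotone")
  if (is.null(true_model)) {
    return(contraction_datum(P_hold_mmHg, lz, 0))
  }
  a_con <- solve_radius(P, vessel$geom, lz, vessel$passive, true_model)
  if (length(a_con) > 1L) {
    if (!allow_unstable) {
      stop("contracted state at the held pressure is inside a fold; set allow_unstable = TRUE to take the smallest-radius branch")
    }
    a_con <- min(a_con)
  }
  reduction <- 1 - b_of(a_con) / b_of(a_rel)
  contraction_datum(P_hold_mmHg, lz, reduction)
}

# Thin-wall fixture passive law: pressure (kPa) as a function of normalised
# outer diameter x = b/b0. Linear + exponential extension stiffening +
# exponential compression stiffening; P(1) = 0 and dP/dx > 0 everywhere, so
# contracted equilibria below x = 1 (active tone at zero pressure) exist.
.coxlike_passive_P <- function(x, k_lin = 2, k_exp = 0.8, c_exp = 6,
                               k_cmp = 1, c_cmp = 6) {
  k_lin * (x - 1) + k_exp * expm1(c_exp * (x - 1)) -
    k_cmp * expm1(-c_cmp * (x - 1))
}

#' Canine-like paired relaxed/contracted curve fixture
#'
#' Generates a relaxed pressure-normalised-diameter curve from a frozen
#' thin-wall fixture passive law and a contracted curve obtained by adding
#' the modelled thin-wall active pressure of `true_model`, both inverted
#' onto the canonical pressure grid 0-240 mmHg in steps of 20 mmHg
#' (13 points). Optional seeded Gaussian noise is added to the pressures
#' (the measurement axis in inflation protocols), not the diameters.
#'
#' @param vessel a [thin_wall_vessel()].
#' @param true_model an [active_model()], or `NULL` for no contraction.
#' @param noise_sd Gaussian pressure noise standard deviation (kPa).
#' @param seed RNG seed used when `noise_sd > 0`; generation is
#'   deterministic given the seed.
#' @param pressure_grid_mmHg pressure sampling grid (mmHg).
#' @return list with `relaxed` and `contracted` `pd_curve` objects whose
#'   `outer_diameter_mm` column holds the normalised diameter `b/b0`
#'   (dimensionless; `b0` = 1 by construction).
#' @export
generate_cox_like_curves <- function(vessel, true_model = NULL, noise_sd = 0,
                                     seed = 1L,
                                     pressure_grid_mmHg = seq(0, 240, by = 20)) {
  stopifnot(inherits(vessel, "thinwall_vessel"), noise_sd >= 0)
  P_grid <- mmHg_to_kPa(pressure_grid_mmHg)
  x_lo <- 0.3; x_hi <- 2.5
  invert <- function(Pfun, P) {
    vapply(P, function(p) {
      stats::uniroot(function(x) Pfun(x) - p, c(x_lo, x_hi), tol = 1e-12)$root
    }, numeric(1))
  }
  P_rel <- .coxlike_passive_P
  P_con <- function(x) P_rel(x) +
    (if (is.null(true_model)) 0
     else thinwall_active_pressure(true_model, vessel, x))
  x_rel <- invert(P_rel, P_grid)
  x_con <- invert(P_con, P_grid)
  noise <- function(n) {
    if (noise_sd == 0) return(rep(0, n))
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    stats::rnorm(2 * n, sd = noise_sd)
  }
  eps <- noise(length(P_grid))
  n <- length(P_grid)
  mk <- function(P, x, label, model) {
    structure(data.frame(pressure_kPa = P, outer_diameter_mm = x),
              lambda_z = vessel$lambda_z, label = label, model = model,
              class = c("pd_curve", "data.frame"))
  }
  if (noise_sd > 0) {
    P_rel_out <- P_grid + eps[seq_len(n)]
    P_con_out <- P_grid + eps[n + seq_len(n)]
    # keep the zero-pressure anchor exact so normalisation stays defined
    P_rel_out[1] <- 0; P_con_out[1] <- 0
  } else {
    P_rel_out <- P_con_out <- P_grid
  }
  list(relaxed = mk(P_rel_out, x_rel, "relaxed", "none"),
       contracted = mk(P_con_out, x_con, "contracted",
                       if (is.null(true_model)) "none" else true_model$family))
}
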