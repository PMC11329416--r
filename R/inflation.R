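# Total pressure-radius relation at fixed axial stretch, curve generation,
# limit-point (fold) detection, and multi-root inversion P(a) = P_target.

#' Total transmural pressure
#'
#' Additive split `P = Gamma_pas + Gamma_act`. The active term uses the
#' closed form where its preconditions hold and adaptive quadrature
#' otherwise.
#'
#' @param geom a [vessel_geometry()].
#' @param state a [deformation_state()].
#' @param passive_params a [passive_params()].
#' @param active_model an [active_model()], or `NULL` for the fully relaxed
#'   wall.
#' @return transmural pressure `P` (kPa).
#' @export
total_pressure <- function(geom, state, passive_params, active_model = NULL) {
  passive_pressure(geom, state, passive_params) +
    .active_pressure(active_model, geom, state)
}

#' Default inner-radius scan range
#'
#' Maps the inner-wall circumferential stretch `a/A` to `[0.5, 2.2]`,
#' covering compliant low-pressure states through the stiff collagen-
#' dominated regime.
#'
#' @param geom a [vessel_geometry()].
#' @param lt_range inner-wall stretch range.
#' @return numeric length-2 vector of inner radii (mm).
#' @export
default_a_range <- function(geom, lt_range = c(0.5, 2.2)) {
  geom$A * lt_range
}

#' Simulate a pressure-diameter curve
#'
#' Evaluates the total pressure on a grid of loaded inner radii at fixed
#' axial stretch and reports the loaded outer diameter `2 b`.
#'
#' @inheritParams total_pressure
#' @param lambda_z axial stretch held during pressurisation.
#' @param a_grid increasing grid of loaded inner radii (mm); default 200
#'   points over [default_a_range()].
#' @param label state label, conventionally `"relaxed"` or `"contracted"`.
#' @return an object of class `pd_curve`: data.frame with columns
#'   `pressure_kPa`, `outer_diameter_mm`, and attributes `lambda_z`,
#'   `label`, `model` (family string or `"none"`).
#' @export
pressure_diameter_curve <- function(geom, lambda_z, passive_params,
                                    active_model = NULL, a_grid = NULL,
                                    label = if (is.null(active_model))
                                      "relaxed" else "contracted") {
  if (is.null(a_grid)) {
    a_grid <- seq(default_a_range(geom)[1], default_a_range(geom)[2],
                  length.out = 200L)
  }
  stopifnot(all(diff(a_grid) > 0))
  P <- vapply(a_grid, function(a)
    total_pressure(geom, deformation_state(a, lambda_z),
                   passive_params, active_model), numeric(1))
  b <- vapply(a_grid, function(a)
    deformed_outer_radius(geom, deformation_state(a, lambda_z)), numeric(1))
  structure(data.frame(pressure_kPa = P, outer_diameter_mm = 2 * b),
            lambda_z = lambda_z, label = label,
            model = if (is.null(active_model)) "none" else active_model$family,
            class = c("pd_curve", "data.frame"))
}

# dP/da at a point: analytic active derivative + finite-difference passive.
.dP_da <- function(a, geom, lambda_z, passive_params, active_model) {
  st <- deformation_state(a, lambda_z)
  passive_pressure_derivative(geom, st, passive_params) +
    (if (is.null(active_model)) 0
     else active_pressure_derivative(active_model, geom, st))
}

#' Detect limit-point instability regions
#'
#' Scans `dP/da` on a dense grid of inner radii, brackets its sign changes
#' by bisection, and reports the intervals where the pressure-radius
#' relation is decreasing (non-unique diameter solutions: a fold).
#'
#' @inheritParams pressure_diameter_curve
#' @param a_range inner-radius scan range (mm); default [default_a_range()].
#' @param n_scan number of scan grid points.
#' @param tol bisection tolerance on the fold edges (mm).
#' @return an object of class `stability_report`: list with
#'   `unstable_intervals` (matrix with columns `a_lo`, `a_hi`, possibly
#'   0 rows), `a_grid` and `dP_da` scan samples, and `monotone` (no
#'   unstable interval found).
#' @export
find_instability_regions <- function(geom, lambda_z, passive_params,
                                     active_model = NULL, a_range = NULL,
                                     n_scan = 400L, tol = 1e-6) {
  if (is.null(a_range)) a_range <- default_a_range(geom)
  grid <- seq(a_range[1], a_range[2], length.out = n_scan)
  d <- vapply(grid, .dP_da, numeric(1), geom = geom, lambda_z = lambda_z,
              passive_params = passive_params, active_model = active_model)
  f <- function(a) .dP_da(a, geom, lambda_z, passive_params, active_model)
  crossings <- numeric(0)
  for (j in seq_len(n_scan - 1L)) {
    if (d[j] == 0) next
    if (sign(d[j]) * sign(d[j + 1L]) < 0) {
      crossings <- c(crossings,
                     stats::uniroot(f, c(grid[j], grid[j + 1L]), tol = tol)$root)
    }
  }
  # assemble negative-derivative intervals from the signed scan + crossings
  edges <- sort(unique(c(a_range[1], crossings, a_range[2])))
  lo <- hi <- numeric(0)
  for (j in seq_len(length(edges) - 1L)) {
    mid <- (edges[j] + edges[j + 1L]) / 2
    if (f(mid) < 0) { lo <- c(lo, edges[j]); hi <- c(hi, edges[j + 1L]) }
  }
  # merge adjacent intervals sharing an edge
  if (length(lo) > 1L) {
    keep <- c(TRUE, lo[-1L] > hi[-length(hi)] + tol)
    grp <- cumsum(keep)
    lo <- tapply(lo, grp, min)
    hi <- tapply(hi, grp, max)
  }
  ints <- cbind(a_lo = as.numeric(lo), a_hi = as.numeric(hi))
  structure(list(unstable_intervals = ints, a_grid = grid, dP_da = d,
                 monotone = nrow(ints) == 0L),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  if (x$monotone) {
    cat("<stability_report> monotone pressure-radius relation (no folds)\n")
  } else {
    cat(sprintf("<stability_report> %d unstable interval(s):\n",
                nrow(x$unstable_intervals)))
    for (j in seq_len(nrow(x$unstable_intervals))) {
      cat(sprintf("  a in [%.6g, %.6g] mm\n",
                  x$unstable_intervals[j, 1], x$unstable_intervals[j, 2]))
    }
  }
  invisible(x)
}

#' Invert the pressure-radius relation
#'
#' Finds all loaded inner radii solving `P(a) = P_target` within `a_range`
#' by sign-bracketing on a scan grid followed by bisection. On a fold
#' (limit-point instability) up to three roots are returned, sorted
#' ascending; no silent branch selection is made.
#'
#' @inheritParams find_instability_regions
#' @param P_target target transmural pressure (kPa).
#' @param pressure_fn optional precomputed function `P(a)` (kPa); when
#'   supplied it replaces the exact evaluation (used internally to cache the
#'   passive quadrature during fitting).
#' @return numeric vector of roots `a` (mm), length `>= 1`.
#' @export
solve_radius <- function(P_target, geom, lambda_z, passive_params,
                         active_model = NULL, a_range = NULL,
                         n_scan = 400L, pressure_fn = NULL) {
  if (is.null(a_range)) a_range <- default_a_range(geom)
  Pfun <- if (!is.null(pressure_fn)) pressure_fn else function(a)
    total_pressure(geom, deformation_state(a, lambda_z),
                   passive_params, active_model)
  grid <- seq(a_range[1], a_range[2], length.out = n_scan)
  vals <- vapply(grid, Pfun, numeric(1)) - P_target
  roots <- numeric(0)
  for (j in seq_len(n_scan - 1L)) {
    if (vals[j] == 0) { roots <- c(roots, grid[j]); next }
    if (sign(vals[j]) * sign(vals[j + 1L]) < 0) {
      roots <- c(roots, stats::uniroot(function(a) Pfun(a) - P_target,
                                       c(grid[j], grid[j + 1L]),
                                       tol = 1e-12)$root)
    }
  }
  if (vals[n_scan] == 0) roots <- c(roots, grid[n_scan])
  roots <- sort(unique(roots))
  if (length(roots) == 0L) {
    stop(sprintf("no radius in [%g, %g] mm attains P = %g kPa (P range [%g, %g] kPa)",
                 a_range[1], a_range[2], P_target,
                 min(vals) + P_target, max(vals) + P_target))
  }
  roots
}
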