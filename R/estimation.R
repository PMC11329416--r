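# Parameter estimation in two regimes:
#  * single-contraction-point fitting (murine protocol): one free
#    stress-like parameter, matched on outer diameter at a held pressure;
#  * active-pressure-curve fitting (canine protocol): bounded nonlinear
#    least squares of sum (Gamma_exp - Gamma_mod)^2 in the thin-wall
#    approximation, multi-start for multi-parameter families.

#' Single-point contraction datum
#'
#' One mapping point between the fully relaxed and contracted states: the
#' held pressure, the axial stretch, and the fractional reduction of the
#' outer diameter induced by contraction.
#'
#' @param P_mmHg held intraluminal pressure (mmHg, `> 0`).
#' @param lambda_z axial stretch during the experiment.
#' @param reduction fractional outer-diameter reduction in `[0, 1)`
#'   (e.g. 0.29 for a 29% reduction).
#' @return an object of class `contraction_datum`.
#' @export
contraction_datum <- function(P_mmHg, lambda_z, reduction) {
  stopifnot(is.numeric(P_mmHg), P_mmHg > 0, lambda_z > 0,
            is.numeric(reduction), reduction >= 0, reduction < 1)
  structure(list(P_mmHg = P_mmHg, lambda_z = lambda_z, reduction = reduction),
            class = "contraction_datum")
}

# The stress-like (free) parameter name of each family.
.stress_param <- c(constant_cauchy = "Tc", constant_1pk = "Ti",
                   constant_2pk = "Tr", rachev = "TRv",
                   zulliger = "TZr", franchini = "TFr1")

#' Imposed-parameter preset for the murine single-point protocol
#'
#' The shape parameters held fixed while the stress-like parameter is
#' estimated from a single contraction point: Rachev `lambda_m = 1.60`,
#' `lambda_0 = 0.80`; Zulliger `lambda_pre = 1.83` with gates
#' `lambda_hat_lb = 1.20`, `lambda_hat_ub = 3.83`; Franchini
#' `alpha1 = 2.3`, `beta1 = 0.95`, `m1 = 2`. The three constant-stress
#' families need no imposed parameters.
#'
#' @param family an active model family name.
#' @return named list of imposed parameters (possibly empty).
#' @export
preset_table1_mouse <- function(family = ACTIVE_FAMILIES) {
  family <- match.arg(family)
  switch(family,
         rachev = list(lambda_m = 1.60, lambda_0 = 0.80),
         zulliger = list(lambda_pre = 1.83, lambda_hat_lb = 1.20,
                         lambda_hat_ub = 3.83, S1 = 1),
         franchini = list(alpha1 = 2.3, beta1 = 0.95, m1 = 2, S1 = 1),
         list())
}

# Build a family model from imposed params + the free stress parameter.
.make_model <- function(family, imposed, T_value) {
  args <- imposed
  args[[.stress_param[[family]]]] <- T_value
  do.call(active_model, c(list(family = family), args))
}

#' Fit the stress-like parameter to a single contraction point
#'
#' Solves the relaxed configuration at the held pressure, forms the target
#' contracted outer diameter `b_measured = (1 - reduction) * b_relaxed`, and
#' estimates the single free stress-like parameter `T >= 0` by driving the
#' mismatch `Pi = b_measured - b_modelled` to zero, where each evaluation
#' solves the contracted configuration at the held pressure. When the
#' contracted pressure-radius relation folds (multiple roots), the root
#' branch closest to the target is used, `instability_flag` is set, and the
#' fit reports non-convergence if no parameter value attains the target.
#'
#' @param geom a [vessel_geometry()].
#' @param passive_params a [passive_params()].
#' @param datum a [contraction_datum()].
#' @param model_family active family name.
#' @param imposed named list of imposed (fixed) shape parameters; default
#'   [preset_table1_mouse()] for the family.
#' @param T_max upper bound of the stress-like parameter search (kPa);
#'   extended automatically up to 10x if the bracket does not close.
#' @param a_range inner-radius search range (mm); default
#'   [default_a_range()].
#' @param n_scan scan resolution for root bracketing and the cached passive
#'   pressure interpolant.
#' @param tol convergence tolerance on the diameter mismatch (mm).
#' @return an object of class `fit_result`: list with `parameters` (named;
#'   the estimated stress parameter plus imposed values), `residual`
#'   (`|Pi|`, mm), `converged`, `instability_flag`, `branch` (root index
#'   used at the optimum), and `diagnostics`.
#' @export
fit_single_point <- function(geom, passive_params, datum,
                             model_family = ACTIVE_FAMILIES,
                             imposed = preset_table1_mouse(model_family),
                             T_max = 500, a_range = NULL, n_scan = 400L,
                             tol = 1e-6) {
  model_family <- match.arg(model_family)
  stopifnot(inherits(datum, "contraction_datum"))
  if (is.null(a_range)) a_range <- default_a_range(geom)
  P <- mmHg_to_kPa(datum$P_mmHg)
  lz <- datum$lambda_z

  # cache the passive pressure on the scan grid (model-independent)
  agrid <- seq(a_range[1], a_range[2], length.out = n_scan)
  Gpas <- vapply(agrid, function(a)
    passive_pressure(geom, deformation_state(a, lz), passive_params),
    numeric(1))
  Gpas_fun <- stats::splinefun(agrid, Gpas, method = "natural")

  b_of <- function(a) deformed_outer_radius(geom, deformation_state(a, lz))
  a_rel <- solve_radius(P, geom, lz, passive_params, NULL, a_range,
                        n_scan, pressure_fn = Gpas_fun)
  if (length(a_rel) > 1L) stop("relaxed pressure-radius relation is not monotone at the held pressure")
  b_rel <- b_of(a_rel)
  b_target <- (1 - datum$reduction) * b_rel

  if (datum$reduction == 0) {
    pars <- stats::setNames(list(0), .stress_param[[model_family]])
    return(structure(list(parameters = c(pars, imposed), residual = 0,
                          converged = TRUE, instability_flag = FALSE,
                          branch = 1L,
                          diagnostics = list(b_relaxed = b_rel,
                                             b_target = b_target,
                                             evaluations = 0L)),
                     class = "fit_result"))
  }

  n_eval <- 0L
  unstable_seen <- FALSE
  last_branch <- 1L
  # signed mismatch Pi(T) = b_target - b_model(T); also used as |Pi| objective
  b_model <- function(T_value) {
    n_eval <<- n_eval + 1L
    model <- .make_model(model_family, imposed, T_value)
    Pfun <- function(a) Gpas_fun(a) +
      .active_pressure(model, geom, deformation_state(a, lz))
    roots <- tryCatch(
      solve_radius(P, geom, lz, passive_params, model, a_range, n_scan,
                   pressure_fn = Pfun),
      error = function(e) numeric(0))
    if (length(roots) == 0L) return(NA_real_)
    if (length(roots) > 1L) unstable_seen <<- TRUE
    bs <- vapply(roots, b_of, numeric(1))
    k <- which.min(abs(bs - b_target))
    last_branch <<- k
    bs[k]
  }
  Pi_fun <- function(T_value) {
    b <- b_model(T_value)
    if (is.na(b)) return(NA_real_)
    b_target - b
  }

  # bracket by geometric march: Pi(0) < 0 (relaxed diameter above target);
  # increase T until Pi >= 0 (bracket closes), Pi turns NA (contracted root
  # left the search range), or the cap T_max is hit
  lo <- 0; Pi_lo <- Pi_fun(0)
  T_try <- max(1, T_max / 512)
  hi <- NA_real_; Pi_hi <- NA_real_
  last_ok <- 0
  T_na <- NA_real_
  while (T_try <= T_max) {
    v <- Pi_fun(T_try)
    if (is.na(v)) { T_na <- T_try; break }
    last_ok <- T_try
    if (v >= 0) { hi <- T_try; Pi_hi <- v; break }
    T_try <- T_try * 2
  }
  if (is.na(hi) && !is.na(T_na)) {
    # the march left the feasible region (contracted root escaped a_range):
    # bisect to the feasibility boundary, where Pi may still cross zero
    blo <- last_ok; bhi <- T_na
    for (k in 1:50) {
      mid <- (blo + bhi) / 2
      v <- Pi_fun(mid)
      if (is.na(v)) bhi <- mid
      else {
        blo <- mid; last_ok <- mid
        if (v >= 0) { hi <- mid; Pi_hi <- v; break }
      }
      if (bhi - blo < 1e-9 * max(1, bhi)) break
    }
  }
  if (!is.na(hi) && sign(Pi_lo) * sign(Pi_hi) <= 0) {
    # uniroot on a possibly discontinuous Pi(T): on a fold, T converges to
    # the branch-jump point and the residual there exposes the gap
    root <- stats::uniroot(Pi_fun, c(lo, hi), tol = 1e-10,
                           f.lower = Pi_lo, f.upper = Pi_hi)
    T_hat <- root$root
    resid <- abs(Pi_fun(T_hat))
    if (resid > tol) {
      # polish inside the finite region in case uniroot stopped at a jump
      opt <- stats::optimize(function(T_value) {
        v <- Pi_fun(T_value); if (is.na(v)) Inf else abs(v)
      }, c(max(lo, T_hat - (hi - lo) * 1e-3), min(hi, T_hat + (hi - lo) * 1e-3)),
      tol = 1e-10)
      if (opt$objective < resid) { T_hat <- opt$minimum; resid <- opt$objective }
    }
  } else {
    # no sign change in the finite region: minimise |Pi| over it
    opt <- stats::optimize(function(T_value) {
      v <- Pi_fun(T_value); if (is.na(v)) Inf else abs(v)
    }, c(lo, if (last_ok > 0) last_ok else T_max), tol = 1e-8)
    T_hat <- opt$minimum
    resid <- opt$objective
  }
  # classify the optimum: does the matched root sit on a rising (stable)
  # branch of the contracted pressure-radius curve?
  Pi_hat <- Pi_fun(T_hat)
  converged <- is.finite(resid) && resid < tol
  model_hat <- .make_model(model_family, imposed, T_hat)
  Pfun_hat <- function(a) Gpas_fun(a) +
    .active_pressure(model_hat, geom, deformation_state(a, lz))
  roots_hat <- tryCatch(
    solve_radius(P, geom, lz, passive_params, model_hat, a_range, n_scan,
                 pressure_fn = Pfun_hat),
    error = function(e) numeric(0))
  stable_match <- NA
  if (length(roots_hat)) {
    bs <- vapply(roots_hat, b_of, numeric(1))
    k <- which.min(abs(bs - b_target))
    ha <- 1e-6 * roots_hat[k]
    stable_match <- (Pfun_hat(roots_hat[k] + ha) -
                       Pfun_hat(roots_hat[k] - ha)) / (2 * ha) > 0
  }
  pars <- stats::setNames(list(T_hat), .stress_param[[model_family]])
  structure(list(parameters = c(pars, imposed),
                 residual = resid,
                 converged = converged,
                 instability_flag = unstable_seen,
                 branch = last_branch,
                 diagnostics = list(b_relaxed = b_rel, b_target = b_target,
                                    Pi = Pi_hat, evaluations = n_eval,
                                    T_upper = hi, n_roots = length(roots_hat),
                                    stable_match = stable_match)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>\n  parameters:",
      paste(sprintf("%s = %.6g", names(x$parameters),
                    unlist(x$parameters)), collapse = ", "),
      sprintf("\n  residual = %.3g, converged = %s, instability_flag = %s\n",
              x$residual, x$converged, x$instability_flag))
  invisible(x)
}

# Default box bounds for curve fitting. Stress-like parameters are
# non-negative; shape parameter boxes cover published fits with margin.
.curve_bounds <- function(family) {
  switch(family,
    constant_cauchy = list(lower = c(Tc = 0), upper = c(Tc = 1000)),
    constant_1pk    = list(lower = c(Ti = 0), upper = c(Ti = 1000)),
    constant_2pk    = list(lower = c(Tr = 0), upper = c(Tr = 1000)),
    rachev = list(lower = c(TRv = 0, lambda_m = 1, lambda_0 = 0),
                  upper = c(TRv = 1000, lambda_m = 3, lambda_0 = 3)),
    zulliger = list(lower = c(TZr = 0, lambda_pre = 0.5),
                    upper = c(TZr = 1000, lambda_pre = 3)),
    franchini = list(lower = c(TFr1 = 0, alpha1 = 0, beta1 = 0),
                     upper = c(TFr1 = 1000, alpha1 = 5, beta1 = 2)))
}

# Latin-hypercube starts within [lower, upper], deterministic in `seed`.
# RNG state of the session is left untouched.
.lhs_starts <- function(n, lower, upper, seed) {
  k <- length(lower)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  m <- sapply(seq_len(k), function(j) {
    (sample.int(n) - stats::runif(n)) / n
  })
  m <- matrix(m, nrow = n)
  sweep(sweep(m, 2, upper - lower, `*`), 2, lower, `+`)
}

#' Fit an active stress model to thin-wall active pressure samples
#'
#' Bounded nonlinear least squares of the cost
#' `Pi = sum_i (Gamma_exp_i - Gamma_mod_i)^2`, with the modelled active
#' pressure from [thinwall_active_pressure()]. Multi-parameter families use
#' seeded Latin-hypercube multi-start (non-convex cost); Franchini's integer
#' exponent `m1` is handled by a discrete grid `{1, 2, 3, 4}` with a
#' continuous inner solve per value.
#'
#' @param samples an `active_pressure_samples` object (see
#'   [experimental_active_pressure()]), or a data.frame with columns
#'   `normalised_diameter`, `gamma_act_kPa`.
#' @param vessel a [thin_wall_vessel()].
#' @param model_family active family name.
#' @param fixed named list of parameters to hold fixed (e.g. Zulliger gate
#'   bounds, which default to +/-Inf, or `S1 = 1`).
#' @param n_starts number of multi-start points for multi-parameter
#'   families.
#' @param seed seed for the Latin-hypercube start generation (the fit is
#'   deterministic given this seed).
#' @param bounds optional list with named vectors `lower`, `upper`
#'   overriding the default boxes.
#' @return an object of class `fit_result` with the estimated free
#'   parameters, the cost at the optimum (`residual`), convergence and
#'   diagnostics (starts, best start index, bound activity).
#' @export
fit_active_curve <- function(samples, vessel, model_family = ACTIVE_FAMILIES,
                             fixed = list(), n_starts = 8L, seed = 1234L,
                             bounds = NULL) {
  model_family <- match.arg(model_family)
  stopifnot(inherits(vessel, "thinwall_vessel"),
            all(c("normalised_diameter", "gamma_act_kPa") %in% names(samples)))
  d <- samples$normalised_diameter
  g <- samples$gamma_act_kPa
  if (diff(range(d)) < 1e-12) stop("degenerate samples: all normalised diameters equal")
  bb <- if (is.null(bounds)) .curve_bounds(model_family) else bounds
  free <- setdiff(names(bb$lower), names(fixed))
  if (length(d) < length(free)) stop("fewer samples than free parameters")
  lower <- bb$lower[free]; upper <- bb$upper[free]

  sse_for <- function(theta, m1 = NULL) {
    args <- c(as.list(theta), fixed)
    if (!is.null(m1)) args$m1 <- m1
    # enforce rachev ordering constraint by penalty (box bounds cannot)
    if (model_family == "rachev") {
      lm <- if ("lambda_m" %in% names(args)) args$lambda_m else fixed$lambda_m
      l0 <- if ("lambda_0" %in% names(args)) args$lambda_0 else fixed$lambda_0
      if (l0 >= lm) return(1e8 * (1 + (l0 - lm)^2))
    }
    model <- tryCatch(do.call(active_model, c(list(model_family), args)),
                      error = function(e) NULL)
    if (is.null(model)) return(1e8)
    sum((g - thinwall_active_pressure(model, vessel, d))^2)
  }

  run_ls <- function(m1 = NULL) {
    if (length(free) == 1L) {
      opt <- stats::optimize(function(x) sse_for(stats::setNames(x, free), m1),
                             c(lower, upper), tol = 1e-12)
      # polish with a local bounded quasi-Newton step
      pol <- stats::nlminb(opt$minimum,
                           function(x) sse_for(stats::setNames(x, free), m1),
                           lower = lower, upper = upper,
                           control = list(abs.tol = 0, rel.tol = 1e-14))
      list(par = stats::setNames(pol$par, free), value = pol$objective,
           start = NA_integer_, convergence = pol$convergence)
    } else {
      starts <- .lhs_starts(n_starts, lower, upper, seed)
      best <- NULL
      for (s in seq_len(nrow(starts))) {
        fit <- stats::nlminb(stats::setNames(starts[s, ], free),
                             function(x) sse_for(stats::setNames(x, free), m1),
                             lower = lower, upper = upper,
                             control = list(abs.tol = 0, rel.tol = 1e-14,
                                            iter.max = 500, eval.max = 1000))
        if (is.null(best) || fit$objective < best$value) {
          best <- list(par = stats::setNames(fit$par, free),
                       value = fit$objective, start = s,
                       convergence = fit$convergence)
        }
      }
      best
    }
  }

  if (model_family == "franchini" && !("m1" %in% names(fixed))) {
    cand <- lapply(1:4, run_ls)
    k <- which.min(vapply(cand, `[[`, numeric(1), "value"))
    best <- cand[[k]]
    pars <- c(as.list(best$par), list(m1 = k), fixed)
  } else {
    best <- run_ls(if (model_family == "franchini") fixed$m1 else NULL)
    pars <- c(as.list(best$par), fixed)
  }
  at_bounds <- names(best$par)[best$par <= lower + 1e-10 * pmax(1, abs(lower)) |
                                 best$par >= upper - 1e-10 * pmax(1, abs(upper))]
  structure(list(parameters = pars,
                 residual = best$value,
                 converged = is.finite(best$value),
                 instability_flag = FALSE,
                 diagnostics = list(n_samples = length(d),
                                    free = free, best_start = best$start,
                                    bounds_hit = at_bounds, seed = seed)),
            class = "fit_result")
}
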