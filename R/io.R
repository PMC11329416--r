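# CSV / JSON I/O. CSV dialects:
#   curves:  pressure_mmHg (or pressure_kPa), outer_diameter_mm and/or
#            normalised_outer_diameter
#   samples: normalised_outer_diameter, gamma_act_kPa
# JSON: passive parameters {mu_kPa, families:[{k1_kPa, k2, alpha_deg}]},
# active models as tagged unions {family, params}, fit results with
# provenance (inputs hash, seed, bounds).

#' Read a pressure-diameter curve from CSV
#'
#' Expects a `pressure_mmHg` or `pressure_kPa` column (by declared `unit`)
#' plus `outer_diameter_mm` and/or `normalised_outer_diameter`. Pressures
#' are normalised to kPa on read.
#'
#' @param path CSV file path.
#' @param unit pressure unit of the file, `"mmHg"` (default) or `"kPa"`.
#' @param lambda_z axial stretch annotation carried on the curve.
#' @param label state label annotation (`"relaxed"`/`"contracted"`).
#' @return a `pd_curve` data.frame (`pressure_kPa`, `outer_diameter_mm`;
#'   the diameter column holds the normalised diameter when only
#'   `normalised_outer_diameter` is present).
#' @export
read_pd_csv <- function(path, unit = c("mmHg", "kPa"), lambda_z = NA_real_,
                        label = "unknown") {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  pcol <- paste0("pressure_", unit)
  if (!pcol %in% names(df)) {
    stop(sprintf("missing required column '%s' in %s (found: %s)",
                 pcol, path, paste(names(df), collapse = ", ")))
  }
  dcol <- intersect(c("outer_diameter_mm", "normalised_outer_diameter"),
                    names(df))
  if (length(dcol) == 0L) {
    stop(sprintf("missing diameter column in %s: need outer_diameter_mm or normalised_outer_diameter", path))
  }
  if (nrow(df) == 0L) stop(sprintf("no data rows in %s", path))
  for (cc in c(pcol, dcol[1])) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' of %s at data row %d",
                   cc, path, bad[1]))
    }
    df[[cc]] <- v
  }
  structure(data.frame(pressure_kPa = .pressure_to_kPa(df[[pcol]], unit),
                       outer_diameter_mm = df[[dcol[1]]]),
            lambda_z = lambda_z, label = label, model = "file",
            source = path,
            class = c("pd_curve", "data.frame"))
}

#' Write a pressure-diameter curve to CSV
#'
#' Columns: `pressure_mmHg`, `outer_diameter_mm`,
#' `normalised_outer_diameter` (diameter over its value at the lowest
#' pressure).
#'
#' @param curve a `pd_curve`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_pd_csv <- function(curve, path) {
  stopifnot(inherits(curve, "pd_curve"))
  d0 <- curve$outer_diameter_mm[which.min(curve$pressure_kPa)]
  df <- data.frame(pressure_mmHg = kPa_to_mmHg(curve$pressure_kPa),
                   outer_diameter_mm = curve$outer_diameter_mm,
                   normalised_outer_diameter = curve$outer_diameter_mm / d0)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialise / deserialise passive parameters as JSON
#'
#' Keys: `mu_kPa`, `families` (array of `{k1_kPa, k2, alpha_deg}`).
#'
#' @param params a [passive_params()].
#' @param path JSON file path.
#' @return `read_passive_json` returns a [passive_params()];
#'   `write_passive_json` returns `path` invisibly.
#' @export
write_passive_json <- function(params, path) {
  stopifnot(inherits(params, "passive_params"))
  obj <- list(mu_kPa = params$mu,
              families = lapply(seq_len(nrow(params$families)), function(i)
                list(k1_kPa = params$families$k1[i],
                     k2 = params$families$k2[i],
                     alpha_deg = params$families$alpha_deg[i])),
              tension_only = params$tension_only)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_passive_json
#' @export
read_passive_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  fam <- if (length(obj$families)) {
    do.call(rbind, lapply(obj$families, function(f)
      data.frame(k1 = f$k1_kPa, k2 = f$k2, alpha_deg = f$alpha_deg)))
  } else NULL
  passive_params(mu = obj$mu_kPa, families = fam,
                 tension_only = isTRUE(obj$tension_only))
}

#' Serialise / deserialise an active model as tagged-union JSON
#'
#' Format: `{"family": "<name>", "params": {...}}`, stresses in kPa.
#'
#' @param model an [active_model()].
#' @param path JSON file path.
#' @return `read_active_model_json` returns an [active_model()];
#'   `write_active_model_json` returns `path` invisibly.
#' @export
write_active_model_json <- function(model, path) {
  stopifnot(inherits(model, "active_model"))
  params <- model[setdiff(names(model), "family")]
  jsonlite::write_json(list(family = model$family, params = params),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_active_model_json
#' @export
read_active_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- as.list(obj$params)
  # JSON has no Inf: gate bounds may arrive as NULL or string
  for (nm in c("lambda_hat_lb", "lambda_hat_ub")) {
    if (!is.null(params[[nm]]) && is.character(params[[nm]])) {
      params[[nm]] <- as.numeric(params[[nm]])
    }
  }
  do.call(active_model, c(list(family = obj$family), params))
}

#' Write a fit result with provenance
#'
#' @param fit a `fit_result`.
#' @param path JSON output path.
#' @param inputs optional list of inputs to hash into the provenance block.
#' @param seed seed recorded in the provenance block.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, inputs = NULL, seed = NULL) {
  stopifnot(inherits(fit, "fit_result"))
  prov <- list(inputs_hash = .digest_light(inputs), seed = seed,
               package_version = as.character(utils::packageVersion("vasotone")))
  out <- list(parameters = fit$parameters, residual = fit$residual,
              converged = fit$converged,
              instability_flag = fit$instability_flag,
              diagnostics = fit$diagnostics, provenance = prov)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, null = "null")
  invisible(path)
}

# Small dependency-free content hash (serialisation -> 31-bit polynomial
# rolling hash; all intermediates exact in double precision).
.digest_light <- function(x) {
  if (is.null(x)) return(NA_character_)
  raw <- as.integer(serialize(x, NULL, version = 2))
  h <- 17
  for (b in raw) h <- (h * 31 + b) %% 2147483647
  sprintf("h31:%08x", as.integer(h))
}
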