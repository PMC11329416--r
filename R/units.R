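# Pressure units. All internal computation is in kPa; mmHg only at I/O
# boundaries. 1 mmHg = 0.133322 kPa (fixed conversion, not user-tunable).

MMHG_TO_KPA <- 0.133322

#' Convert pressures between mmHg and kPa
#'
#' All internal computation in the package uses kPa; experimental protocols
#' are commonly stated in mmHg. The fixed factor 1 mmHg = 0.133322 kPa is
#' used in both directions.
#'
#' @param x numeric vector of pressures.
#' @return numeric vector of converted pressures.
#' @examples
#' mmHg_to_kPa(90)   # ~12.0 kPa
#' kPa_to_mmHg(mmHg_to_kPa(90))
#' @export
mmHg_to_kPa <- function(x) x * MMHG_TO_KPA

#' @rdname mmHg_to_kPa
#' @export
kPa_to_mmHg <- function(x) x / MMHG_TO_KPA

# Normalise a pressure vector declared in `unit` to kPa.
.pressure_to_kPa <- function(x, unit) {
  unit <- match.arg(unit, c("mmHg", "kPa"))
  if (unit == "mmHg") mmHg_to_kPa(x) else x
}
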