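# Centralized unit conversions. The public interface uses clinical units
# (mL, h, mbar, mm, mPa.s); hydraulic formulas are evaluated in SI and
# converted once, here.

# 1 mbar = 100 Pa; 1 mL/h = 1e-6 m^3 / 3600 s.
# R [mbar.h/mL] = R_SI [Pa.s/m^3] * (1/100) / (3600/1e-6)^-1 ... collapsed:
.SI_RESISTANCE_TO_MBAR_H_ML <- 1e-2 * 1e-6 / 3600  # = 2.7778e-12

.MM_TO_M <- 1e-3
.MPAS_TO_PAS <- 1e-3

#' Convert hydraulic resistance from SI to clinical units
#'
#' @param r_si resistance in Pa·s/m³
#' @return resistance in mbar·h/mL
#' @keywords internal
#' @noRd
si_resistance_to_clinical <- function(r_si) r_si * .SI_RESISTANCE_TO_MBAR_H_ML

stopifnot_positive <- function(..., .what = "parameter") {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(
        sprintf("`%s` must be a single positive finite number, got %s.",
                nms[i], deparse(v)),
        class = "infusim_invalid_parameter"
      )
    }
  }
  invisible(TRUE)
}

stopifnot_nonnegative <- function(...) {
  vals <- list(...)
  nms <- names(vals)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      abort(
        sprintf("`%s` must be a single non-negative finite number, got %s.",
                nms[i], deparse(v)),
        class = "infusim_invalid_parameter"
      )
    }
  }
  invisible(TRUE)
}
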