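# Absorbed dose to blood from the activity concentration, the S-value and
# the incubation time, with radioactive decay integrated over the
# incubation, and the inverse operation used to plan experiments.

#' Decay-weighted effective exposure time
#'
#' `(1 - exp(-lambda T)) / lambda`: the integral of the decaying activity
#' over the incubation, in "effective seconds" at the initial activity.
#' For I-131 and Lu-177 a 3600 s incubation shrinks to about 3593 s.
#'
#' @param lambda decay constant, s^-1 (> 0).
#' @param duration_s incubation time, s (>= 0).
#' @return effective seconds; monotone in `duration_s`, never exceeding it.
#' @export
decay_integral <- function(lambda, duration_s) {
  if (any(lambda <= 0)) stop("lambda must be positive")
  if (any(duration_s < 0)) stop("duration must be non-negative")
  -expm1(-lambda * duration_s) / lambda
}

svalue_total <- function(svalue) {
  if (inherits(svalue, "svalue")) svalue$total
  else if (is.numeric(svalue) && length(svalue) == 1) svalue
  else stop("svalue must be an 'svalue' object or a single number")
}

#' Absorbed dose to blood after incubation
#'
#' `D = c0 * S_total * (1 - exp(-lambda T)) / lambda`, where `c0` is the
#' activity concentration at the start of the incubation.  Decay during
#' pre-incubation handling is the caller's responsibility: in the assay
#' the concentration of every sample is measured directly.
#'
#' @param concentration_bq_ml activity concentration at incubation start,
#'   Bq/ml.
#' @param duration_s incubation time, s.
#' @param svalue total S-value in Gy s^-1 Bq^-1 ml, or an `svalue` object.
#' @param nuclide a `nuclide` object (for the decay constant), or a
#'   nuclide name resolvable by [load_nuclide()].
#' @return object of class `dose_result`: `absorbed_dose_mGy` and
#'   `initial_dose_rate_mGy_h`.
#' @examples
#' lu <- load_nuclide("Lu-177")
#' absorbed_dose(1e6, 3600, 2.32e-11, lu)  # ~83.34 mGy
#' @export
absorbed_dose <- function(concentration_bq_ml, duration_s, svalue, nuclide) {
  if (any(concentration_bq_ml < 0)) stop("concentration must be non-negative")
  if (any(duration_s < 0)) stop("duration must be non-negative")
  if (is.character(nuclide)) nuclide <- load_nuclide(nuclide)
  s <- svalue_total(svalue)
  lam <- decay_constant(nuclide)
  dose_gy <- concentration_bq_ml * s * decay_integral(lam, duration_s)
  structure(list(absorbed_dose_mGy = dose_gy * 1e3,
                 initial_dose_rate_mGy_h = concentration_bq_ml * s * 3.6e6),
            class = "dose_result")
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("absorbed dose %.4g mGy (initial rate %.4g mGy/h)\n",
              x$absorbed_dose_mGy, x$initial_dose_rate_mGy_h))
  invisible(x)
}

#' Activity needed for a target initial dose rate
#'
#' Inverse of the initial-rate formula: `A = rate / (S_total * 3.6e6) *
#' volume`, the activity to pipette into `total_volume_ml` of liquid so
#' that the uniformly mixed sample starts at `target_rate_mGy_h`.
#'
#' @param target_rate_mGy_h desired initial dose rate to blood, mGy/h.
#' @param svalue total S-value (Gy s^-1 Bq^-1 ml) or an `svalue` object.
#' @param total_volume_ml total liquid volume the activity is mixed into.
#' @return activity in MBq.
#' @examples
#' required_activity(100, 3.05e-11, 4.5)  # ~4.1 MBq of I-131
#' @export
required_activity <- function(target_rate_mGy_h, svalue, total_volume_ml) {
  if (any(target_rate_mGy_h <= 0)) stop("target rate must be positive")
  if (any(total_volume_ml <= 0)) stop("volume must be positive")
  s <- svalue_total(svalue)
  if (s <= 0) stop("S-value must be positive")
  target_rate_mGy_h / (s * 3.6e6) * total_volume_ml / 1e6
}
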