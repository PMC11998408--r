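#' Temperature-humidity index parameters
#'
#' Constants of the Finocchiaro-type THI, which corrects air temperature by a
#' humidity-dependent term pivoting at a reference temperature:
#' `THI = T - (slope_const - slope_const * rh / 100) * (T - pivot_temp)`.
#' Below the pivot, dry air pushes the index below the air temperature
#' (wind-chill-like); above it, humid air pushes it above (heat-load-like).
#'
#' @param slope_const Dimensionless humidity weight (default 0.31).
#' @param pivot_temp Pivot temperature in degrees Celsius (default 14.4).
#'   Must lie in a plausible 0--30 degree range.
#' @return An object of class `"thi_params"`.
#' @export
#' @examples
#' compute_thi(20, 50, thi_params())
thi_params <- function(slope_const = 0.31, pivot_temp = 14.4) {
  stopifnot(is.numeric(slope_const), length(slope_const) == 1L, is.finite(slope_const))
  if (!is.numeric(pivot_temp) || length(pivot_temp) != 1L ||
      pivot_temp < 0 || pivot_temp > 30) {
    stop("`pivot_temp` must be a single temperature in [0, 30] degrees C", call. = FALSE)
  }
  structure(list(slope_const = slope_const, pivot_temp = pivot_temp),
            class = "thi_params")
}

#' Compute a temperature-humidity index
#'
#' Daily THI from average air temperature and relative humidity. THI is
#' computed per day, before any weekly aggregation.
#'
#' @param tavg Average air temperature, degrees Celsius (vectorised).
#' @param rh Relative humidity in percent, in `[0, 100]`.
#' @param params A [thi_params()] object.
#' @return Numeric vector of THI values (index units, same scale as degrees C).
#' @export
#' @examples
#' compute_thi(14.4, 30)   # at the pivot the humidity correction vanishes
#' compute_thi(20, 100)    # saturation humidity also cancels the correction
compute_thi <- function(tavg, rh, params = thi_params()) {
  stopifnot(inherits(params, "thi_params"))
  if (any(!is.na(rh) & (rh < 0 | rh > 100))) {
    stop("relative humidity must be within [0, 100] percent", call. = FALSE)
  }
  tavg - (params$slope_const - params$slope_const * rh / 100) *
    (tavg - params$pivot_temp)
}
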