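#' Convert between millimetres of mercury and kilopascals
#'
#' Clinical pressure gradients are reported in mm Hg while the landmark
#' pressures handled by this package are in kPa. The conversion factor
#' 0.133322 kPa/mmHg reproduces the conventional surgical threshold
#' equivalence 20 mm Hg = 2.67 kPa at two decimal places.
#'
#' @param x numeric vector of pressures.
#' @return `mmhg_to_kpa()` returns `x` in kPa; `kpa_to_mmhg()` returns `x`
#'   in mm Hg. Round-tripping is exact to well below 1e-12 relative error.
#' @examples
#' mmhg_to_kpa(20)   # 2.67 kPa (2 d.p.)
#' kpa_to_mmhg(2.67) # ~20 mm Hg
#' @export
mmhg_to_kpa <- function(x) {
  stopifnot(is.numeric(x))
  x * KPA_PER_MMHG
}

#' @rdname mmhg_to_kpa
#' @export
kpa_to_mmhg <- function(x) {
  stopifnot(is.numeric(x))
  x / KPA_PER_MMHG
}

KPA_PER_MMHG <- 0.133322
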