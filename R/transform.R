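#' Transform SpO2 percentages to the modelling scale
#'
#' Maps oxygen saturation in percent to `p = 1 - exp((spo2 - 100) / 10)`.
#' The transform magnifies differences between saturation values close to
#' 100% (where most ICU observations sit) and maps 100% to 0. It is strictly
#' decreasing, so low saturation corresponds to large `p`.
#'
#' @param spo2 Numeric vector of SpO2 values in percent, each in \[0, 100\].
#'   `NA` values pass through unchanged.
#' @return Numeric vector of transformed values in \[0, 1 - exp(-10)\].
#' @seealso [inverse_transform_spo2()], [hypoxemia_threshold_p()]
#' @examples
#' transform_spo2(c(100, 92, 75))
#' @export
transform_spo2 <- function(spo2) {
  if (!is.numeric(spo2)) {
    stop("`spo2` must be numeric", call. = FALSE)
  }
  bad <- !is.na(spo2) & (spo2 < 0 | spo2 > 100)
  if (any(bad)) {
    stop("SpO2 values must lie in [0, 100]; offending value(s): ",
         paste(utils::head(spo2[bad], 3L), collapse = ", "), call. = FALSE)
  }
  1 - exp((spo2 - 100) / 10)
}

#' Invert the saturation transform
#'
#' Recovers SpO2 in percent from transformed values: `100 + 10 * log(1 - p)`.
#' Round-tripping `transform_spo2()` then `inverse_transform_spo2()` is the
#' identity to floating-point precision.
#'
#' @param p Numeric vector in \[0, 1 - exp(-10)\]. `NA` passes through.
#' @return SpO2 in percent.
#' @export
inverse_transform_spo2 <- function(p) {
  if (!is.numeric(p)) {
    stop("`p` must be numeric", call. = FALSE)
  }
  p_hi <- 1 - exp(-10)
  bad <- !is.na(p) & (p < 0 | p > p_hi + 1e-12)
  if (any(bad)) {
    stop("transformed values must lie in [0, 1 - exp(-10)]", call. = FALSE)
  }
  100 + 10 * log(1 - p)
}

#' Hypoxemia decision threshold on the transformed scale
#'
#' Hypoxemia is operationalized as SpO2 below 92%. On the transformed scale
#' this is `p > 1 - exp(-0.8)`; the full-precision constant is used internally
#' (0.55067 is its five-decimal rounding).
#'
#' @return The scalar `1 - exp(-0.8)`.
#' @export
hypoxemia_threshold_p <- function() 1 - exp(-0.8)

#' Hypoxemia threshold in percent
#' @return 92.
#' @export
hypoxemia_threshold_spo2 <- function() 92

# Upper bound of the transform's image (SpO2 = 0 maps here).
p_range_max <- function() 1 - exp(-10)
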