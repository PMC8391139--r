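#' Erisman index
#'
#' Chest circumference minus half the body length, in centimetres. Positive
#' values indicate a broad, harmoniously developed chest; negative values
#' indicate the narrow-chested (gracile) build typical of artistic-swimming
#' athletes.
#'
#' @param chest_circumference chest circumference at rest, cm.
#' @param body_length standing body length, cm.
#' @return The index in cm: `chest_circumference - 0.5 * body_length`.
#' @examples
#' erisman_index(78.5, 151)  # 3.0
#' erisman_index(70, 150)    # -5.0
#' @export
erisman_index <- function(chest_circumference, body_length) {
  check_positive(chest_circumference, "chest_circumference")
  check_positive(body_length, "body_length")
  chest_circumference - 0.5 * body_length
}

#' Proper (predicted) vital lung capacity
#'
#' Predicted vital lung capacity in litres from a linear function of body
#' length and age: `0.041 * length - 0.018 * age - 3.7`. The linear form
#' goes non-positive for very short or very young subjects, where the
#' prediction is meaningless; such inputs raise an error.
#'
#' @param body_length body length, cm.
#' @param age age, years.
#' @return Predicted VLC in litres (always positive).
#' @examples
#' proper_vlc(150, 12)  # 2.234
#' @export
proper_vlc <- function(body_length, age) {
  check_positive(body_length, "body_length")
  check_positive(age, "age")
  pvlc <- body_length * 0.041 - age * 0.018 - 3.7
  if (!is.na(pvlc) && pvlc <= 0)
    stop(sprintf(paste0("proper VLC is non-positive (%.3f L) for body_length ",
                        "= %s cm, age = %s y: formula out of domain"),
         pvlc, body_length, age), call. = FALSE)
  pvlc
}

#' Ratio of actual to proper vital lung capacity
#'
#' Actual over predicted VLC. Values above 1 indicate respiratory function
#' above the anthropometric expectation, the direction in which trained
#' athletes exceed untrained peers.
#'
#' @param vlc_actual measured vital lung capacity, litres.
#' @param pvlc proper (predicted) VLC, litres, e.g. from [proper_vlc()].
#' @return Dimensionless ratio `vlc_actual / pvlc`.
#' @examples
#' vlc_ratio(2.5, proper_vlc(150, 12))
#' @export
vlc_ratio <- function(vlc_actual, pvlc) {
  check_positive(vlc_actual, "vlc_actual")
  check_positive(pvlc, "pvlc")
  vlc_actual / pvlc
}

#' Biceps index
#'
#' Relative increase of the biceps circumference under tension,
#' `(tense - rest) / rest`, a dimensionless fraction. The screening
#' criterion compares `100 *` the unrounded fraction against 6.7 percent
#' (strictly); comparison on the unrounded value avoids rounding-order
#' ambiguity at the boundary (6.67% is below 6.7%).
#'
#' @param biceps_tense biceps circumference, tense, cm.
#' @param biceps_rest biceps circumference, at rest, cm.
#' @return Fraction (multiply by 100 for percent).
#' @examples
#' biceps_index(27, 25)  # 0.08, i.e. 8%
#' @export
biceps_index <- function(biceps_tense, biceps_rest) {
  check_positive(biceps_rest, "biceps_rest")
  check_positive(biceps_tense, "biceps_tense")
  if (!is.na(biceps_tense) && !is.na(biceps_rest) &&
      biceps_tense < biceps_rest)
    warning("biceps_tense < biceps_rest: tension decreased the circumference",
            call. = FALSE)
  (biceps_tense - biceps_rest) / biceps_rest
}

#' Body-weight deficit against height-interval norms
#'
#' Regression-scale harmony assessment for the weight branch: the subject's
#' height selects a norm interval `(M, delta_R)`, and a deficit is present
#' when `body_weight < M - delta_R` (strictly). Weight at exactly
#' `M - delta_R` is not a deficit.
#'
#' @param body_weight kg.
#' @param body_length cm; must fall in an interval covered by `norms`.
#' @param norms a norm table, see [norm_table()].
#' @return `TRUE` (deficit present) or `FALSE`; `NA` if either measurement
#'   is missing.
#' @examples
#' weight_deficit(30, 150, default_norms())
#' @export
weight_deficit <- function(body_weight, body_length, norms) {
  if (is.na(body_weight) || is.na(body_length)) return(NA)
  check_positive(body_weight, "body_weight")
  nm <- lookup_weight_norm(norms, body_length)
  body_weight < nm$M - nm$delta_R
}
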