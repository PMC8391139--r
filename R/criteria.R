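#' The nine screening criteria
#'
#' Returns the fixed, ordered metadata for the nine binary criteria the
#' prognostic method evaluates. The order is the canonical instrument order
#' (it is also the order of descending informativeness in the reference
#' cohorts) and is used for deterministic tie-breaking when assembling a
#' table.
#'
#' @return A data frame with one row per criterion: `id`, a human-readable
#'   `label`, the comparison `direction` (`"gt"` or `"lt"`), the numeric
#'   `threshold` where fixed (NA for norm-dependent criteria), and the
#'   subject fields the criterion `depends_on` (comma-separated).
#' @examples
#' criteria()$id
#' @export
criteria <- function() {
  data.frame(
    id = c("vlc_ratio_gt1", "biceps_gt_6_7pct", "weight_deficit",
           "forward_bend_gt10s", "splits_lt0", "stange_gt_norm",
           "genchi_gt_norm", "erisman_lt0", "crab_lt60"),
    label = c(
      "Ratio of VLC to proper VLC more than 1",
      "Biceps index more than 6.7%",
      "Body-weight deficit relative to age norms",
      "\"Forward bend\" test more than 10 s",
      "Splits less than 0 cm",
      "Stange test higher than the age norm",
      "Genchi test higher than the age norm",
      "Erisman index less than 0 cm",
      "\"Crab position\" test less than 60 cm"),
    direction = c("gt", "gt", "lt", "gt", "lt", "gt", "gt", "lt", "lt"),
    threshold = c(1, 0.067, NA, 10, 0, NA, NA, 0, 60),
    depends_on = c(
      "vlc_actual,body_length,age",
      "biceps_tense,biceps_rest",
      "body_weight,body_length",
      "forward_bend", "splits", "stange,age", "genchi,age",
      "chest_circumference,body_length", "crab"),
    stringsAsFactors = FALSE
  )
}

criterion_ids <- function() criteria()$id

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, the convention of published prognostic
#' tables: halves round away from zero, unlike [base::round()]'s
#' round-half-to-even. A small guard absorbs binary representation error so
#' that values printed as exact halves round as such.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded to `digits` places, halves away from zero.
#' @examples
#' round_half_up(2.5)        # 3, where round(2.5) gives 2
#' round_half_up(-6.75, 1)   # -6.8
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-8) / f
}

# stop() with the offending field named, for validation errors
check_positive <- function(value, field) {
  if (is.na(value)) return(invisible(TRUE))
  if (!is.numeric(value) || value <= 0)
    stop(sprintf("'%s' must be positive (got %s)", field, value), call. = FALSE)
  invisible(TRUE)
}

check_nonnegative <- function(value, field) {
  if (is.na(value)) return(invisible(TRUE))
  if (!is.numeric(value) || value < 0)
    stop(sprintf("'%s' must be non-negative (got %s)", field, value),
         call. = FALSE)
  invisible(TRUE)
}
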