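#' Deciban threshold from an allowable error probability
#'
#' The symmetric stopping threshold of the sequential procedure, in whole
#' deciban points: `10 * log10((1 - alpha) / alpha)` rounded half-up to an
#' integer. An allowable error of 5% gives 13 points; 0.1% gives 30.
#'
#' @param alpha allowable error probability, in (0, 0.5).
#' @return Integer points.
#' @examples
#' threshold_from_error(0.05)   # 13
#' threshold_from_error(0.001)  # 30
#' @export
threshold_from_error <- function(alpha) {
  if (!is.numeric(alpha) || is.na(alpha) || alpha <= 0 || alpha >= 0.5)
    stop("'alpha' must be in (0, 0.5)", call. = FALSE)
  as.integer(round_half_up(10 * log10((1 - alpha) / alpha)))
}

# Sequential summation of one profile down the table. `statuses` is the
# named 1/0/NA vector; coefficients are taken rounded (1 decimal) or not.
classify_profile <- function(statuses, table, threshold, rounded = TRUE) {
  r <- table$rows
  pc_p <- if (rounded) round_half_up(r$pc_presence, 1) else r$pc_presence
  pc_a <- if (rounded) round_half_up(r$pc_absence, 1) else r$pc_absence
  steps <- data.frame(criterion_id = character(), status = character(),
                      coefficient = numeric(), cumulative = numeric(),
                      stringsAsFactors = FALSE)
  total <- 0; outcome <- "uncertain"; stopping_step <- NA_integer_
  for (i in seq_len(nrow(r))) {
    st <- statuses[[r$criterion_id[i]]]
    if (is.null(st) || is.na(st)) next  # missing: skipped, not absence
    coefficient <- if (st == 1) pc_p[i] else pc_a[i]
    total <- total + coefficient
    steps <- rbind(steps, data.frame(
      criterion_id = r$criterion_id[i],
      status = if (st == 1) "present" else "absent",
      coefficient = coefficient, cumulative = total,
      stringsAsFactors = FALSE))
    if (total >= threshold) {
      outcome <- "success"; stopping_step <- nrow(steps); break
    }
    if (total <= -threshold) {
      outcome <- "low_probability"; stopping_step <- nrow(steps); break
    }
  }
  list(steps = steps, outcome = outcome, stopping_step = stopping_step,
       final_sum = total)
}

#' Sequential classification of subjects with a prognostic table
#'
#' Applies the individual prediction: walk the table rows from the top,
#' adding the presence coefficient when the criterion is present and the
#' absence coefficient when it is absent (missing criteria are skipped,
#' never treated as absent), stopping at the first step where the
#' cumulative sum reaches `+T` (outcome `success`: high probability of
#' success in the sport) or `-T` (outcome `low_probability`). Crossing
#' exactly at the threshold counts as reached. If the table is exhausted
#' without crossing, the outcome is `uncertain` and additional examination
#' is indicated.
#'
#' By default the summation uses the 1-decimal display coefficients,
#' matching how a practitioner applies the printed instrument; set
#' `rounded = FALSE` for full-precision sums.
#'
#' @param object a [prognostic_table()].
#' @param newdata data frame of criterion profiles (columns as produced by
#'   [binarize_subjects()]), or of raw subject measurements if `norms` is
#'   supplied, in which case profiles are computed first.
#' @param alpha allowable error probability; sets the threshold via
#'   [threshold_from_error()] unless `threshold` is given. Default 0.05
#'   (threshold 13).
#' @param threshold explicit deciban threshold overriding `alpha`.
#' @param norms a [norm_table()] for binarizing raw measurements.
#' @param rounded use display-rounded coefficients (default `TRUE`).
#' @param ... unused.
#' @return An object of class `wg_predictions`: data frame `outcomes`
#'   (`subject_id`, `outcome`, `stopping_step`, `final_sum`), list
#'   `traces` of per-subject step tables, and the `threshold` used.
#' @examples
#' tab <- reference_table()
#' prof <- generate_binary_cohort(n1 = 3, n2 = 3,
#'   p1 = rep(0.8, 9), p2 = rep(0.1, 9), seed = 7)
#' predict(tab, prof)
#' @export
predict.prognostic_table <- function(object, newdata, alpha = 0.05,
                                     threshold = NULL, norms = NULL,
                                     rounded = TRUE, ...) {
  stopifnot(is.data.frame(newdata), nrow(newdata) >= 1L)
  if (is.null(threshold)) threshold <- threshold_from_error(alpha)
  stopifnot(threshold > 0)
  if (!is.null(norms)) newdata <- binarize_subjects(newdata, norms)
  if (!any(criterion_ids() %in% names(newdata)))
    stop(paste0("'newdata' has no criterion columns; pass profiles, or raw ",
                "measurements together with 'norms'"), call. = FALSE)
  ids <- if ("subject_id" %in% names(newdata))
    as.character(newdata$subject_id) else as.character(seq_len(nrow(newdata)))
  traces <- lapply(seq_len(nrow(newdata)), function(i) {
    classify_profile(as.list(newdata[i, , drop = FALSE]), object,
                     threshold, rounded)
  })
  outcomes <- data.frame(
    subject_id = ids,
    outcome = vapply(traces, `[[`, "", "outcome"),
    stopping_step = vapply(traces, `[[`, NA_integer_, "stopping_step"),
    final_sum = vapply(traces, `[[`, 0, "final_sum"),
    stringsAsFactors = FALSE)
  names(traces) <- ids
  structure(list(outcomes = outcomes, traces = traces,
                 threshold = threshold, rounded = rounded),
            class = "wg_predictions")
}

#' @export
print.wg_predictions <- function(x, ...) {
  n <- nrow(x$outcomes)
  tab <- table(factor(x$outcomes$outcome,
                      levels = c("success", "low_probability", "uncertain")))
  cat(sprintf("Sequential predictions for %d subject(s), threshold %s%d\n",
              n, "±", x$threshold))
  cat(sprintf("  success: %d   low_probability: %d   uncertain: %d\n",
              tab["success"], tab["low_probability"], tab["uncertain"]))
  print(utils::head(x$outcomes, 10), row.names = FALSE)
  if (n > 10) cat(sprintf("  ... %d more\n", n - 10))
  invisible(x)
}

#' @export
as.data.frame.wg_predictions <- function(x, ...) x$outcomes

#' Write prediction traces and a run summary
#'
#' Emits a JSON-lines file (one object per subject: id, outcome, stopping
#' step, final sum, and the full step trace) and a plain-text summary with
#' outcome counts. Field order is fixed, so identical inputs give
#' byte-identical files.
#'
#' @param predictions a `wg_predictions` object from
#'   [predict.prognostic_table()].
#' @param path path of the JSONL output; the summary goes to
#'   `<path>.summary.txt`.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_report <- function(predictions, path) {
  stopifnot(inherits(predictions, "wg_predictions"))
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  for (i in seq_len(nrow(predictions$outcomes))) {
    o <- predictions$outcomes[i, ]
    tr <- predictions$traces[[i]]
    line <- jsonlite::toJSON(list(
      subject_id = o$subject_id, outcome = o$outcome,
      stopping_step = if (is.na(o$stopping_step)) NULL else o$stopping_step,
      final_sum = o$final_sum,
      steps = tr$steps), auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(line, con, sep = "\n", useBytes = TRUE)
  }
  spath <- paste0(path, ".summary.txt")
  tab <- table(factor(predictions$outcomes$outcome,
                      levels = c("success", "low_probability", "uncertain")))
  lines <- c(
    sprintf("subjects: %d", nrow(predictions$outcomes)),
    sprintf("threshold: %d decibans", predictions$threshold),
    sprintf("success: %d", tab["success"]),
    sprintf("low_probability: %d", tab["low_probability"]),
    sprintf("uncertain: %d", tab["uncertain"]))
  writeLines(lines, spath, useBytes = TRUE)
  invisible(c(path, spath))
}
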