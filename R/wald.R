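#' Gradation counts for one criterion
#'
#' The 2x2 summary a criterion contributes: `d1` of `s1` group-1 (athlete)
#' subjects with the criterion present, `d2` of `s2` group-2 (control)
#' subjects.
#'
#' @param d1,s1,d2,s2 non-negative integers, `0 <= d <= s`, `s >= 1`.
#' @return A list of class `gradation_counts`.
#' @export
gradation_counts <- function(d1, s1, d2, s2) {
  stopifnot(s1 >= 1, s2 >= 1, d1 >= 0, d2 >= 0, d1 <= s1, d2 <= s2,
            d1 == round(d1), d2 == round(d2))
  structure(list(d1 = as.integer(d1), s1 = as.integer(s1),
                 d2 = as.integer(d2), s2 = as.integer(s2)),
            class = "gradation_counts")
}

# Presence/absence proportions, with conditional Haldane-Anscombe
# smoothing: `smoothing` (default 0.5) is added to every cell of the 2x2
# table, but only when some cell is zero; non-degenerate counts are used
# as-is, so smoothing never perturbs an estimable table.
smoothed_props <- function(counts, smoothing) {
  stopifnot(inherits(counts, "gradation_counts"))
  d1 <- counts$d1; s1 <- counts$s1; d2 <- counts$d2; s2 <- counts$s2
  degenerate <- d1 == 0 || d2 == 0 || d1 == s1 || d2 == s2
  if (degenerate) {
    if (smoothing <= 0)
      stop(sprintf(paste0("degenerate counts (d1=%d/%d, d2=%d/%d): a zero ",
                          "cell makes the coefficient undefined; set ",
                          "smoothing > 0"), d1, s1, d2, s2), call. = FALSE)
    d1 <- d1 + smoothing; d2 <- d2 + smoothing
    s1 <- s1 + 2 * smoothing; s2 <- s2 + 2 * smoothing
  }
  list(p1 = d1 / s1, p2 = d2 / s2, q1 = (s1 - d1) / s1, q2 = (s2 - d2) / s2)
}

#' Predictive coefficient (decibans)
#'
#' The deciban log-likelihood-ratio weight of one gradation of a binary
#' criterion: `10 * log10(P1 / P2)`, where for the presence gradation
#' `P = d/s` is the per-group presence proportion and for the absence
#' gradation `P = (s - d)/s`. Positive values are evidence for group 1
#' (athletes). The value is returned unrounded; published tables display
#' it half-up to 1 decimal ([round_half_up()]).
#'
#' When a count is degenerate (a zero cell), the ratio is undefined;
#' `smoothing` adds that amount to every cell of the 2x2 table
#' (Haldane-Anscombe style) before forming proportions, and is applied
#' only in that case. `smoothing = 0` makes degenerate counts an error.
#'
#' @param counts a [gradation_counts()].
#' @param gradation `"presence"` or `"absence"`.
#' @param smoothing continuity correction added to all four cells when a
#'   cell is zero; default 0.5.
#' @return Unrounded decibans.
#' @examples
#' pc <- predictive_coefficient(gradation_counts(12, 15, 1, 15), "presence")
#' round_half_up(pc, 1)  # 10.8
#' @export
predictive_coefficient <- function(counts,
                                   gradation = c("presence", "absence"),
                                   smoothing = 0.5) {
  gradation <- match.arg(gradation)
  p <- smoothed_props(counts, smoothing)
  if (gradation == "presence") 10 * log10(p$p1 / p$p2)
  else 10 * log10(p$q1 / p$q2)
}

#' Kullback informativeness of a criterion
#'
#' The weight by which a criterion separates the two groups:
#' `0.5 * pc * (P1% - P2%)`, the product of the unrounded presence
#' coefficient and the presence-proportion difference in percentage
#' points. Non-negative for all valid counts (the coefficient and the
#' proportion difference always share sign), zero exactly when the group
#' proportions are equal. Published tables display it half-up to 2
#' decimals.
#'
#' The classical Kullback divergence sums the analogous term over both
#' gradations; the presence-gradation term alone is the convention of the
#' prognostic-table literature this package follows, and is the default.
#' Set `both_gradations = TRUE` for the full two-term sum.
#'
#' @inheritParams predictive_coefficient
#' @param both_gradations add the absence-gradation term as well (default
#'   `FALSE`).
#' @return Unrounded informativeness (dimensionless).
#' @examples
#' informativeness(gradation_counts(12, 15, 1, 15))  # 395.70 after rounding
#' @export
informativeness <- function(counts, smoothing = 0.5,
                            both_gradations = FALSE) {
  p <- smoothed_props(counts, smoothing)
  i <- 0.5 * 10 * log10(p$p1 / p$p2) * (100 * p$p1 - 100 * p$p2)
  if (both_gradations)
    i <- i + 0.5 * 10 * log10(p$q1 / p$q2) * (100 * p$q1 - 100 * p$q2)
  i
}

#' Invert a printed coefficient pair to integer counts
#'
#' Exhaustive-search reconstruction oracle: given a presence/absence
#' coefficient pair as printed (rounded half-up to 1 decimal) and the two
#' group sizes, searches every `(d1, d2)` in `[0, s1] x [0, s2]` for the
#' count pairs whose unrounded coefficients display as the printed pair.
#' A printed pair usually over-determines the counts, so the solution is
#' typically unique for small cohorts.
#'
#' @param pc_presence_printed,pc_absence_printed printed decibans,
#'   1 decimal.
#' @param s1,s2 group sizes (at most 100 each).
#' @param smoothing passed to [predictive_coefficient()]; default 0 so
#'   that only non-degenerate counts can match, as in published tables.
#' @return A list of class `pc_inversion`: `candidates` (data frame of
#'   matching `d1`, `d2`), `unique` flag, and the search inputs. Errors
#'   if no pair matches, reporting the nearest candidates.
#' @examples
#' inv <- invert_pc_pair(10.8, -6.7, 15, 15)
#' inv$candidates  # d1 = 12, d2 = 1
#' @export
invert_pc_pair <- function(pc_presence_printed, pc_absence_printed,
                           s1 = 15, s2 = 15, smoothing = 0) {
  stopifnot(s1 >= 1, s2 >= 1, s1 <= 100, s2 <= 100)
  grid <- expand.grid(d1 = 0:s1, d2 = 0:s2)
  # vectorised forward map over the whole grid; degenerate cells (zero
  # numerator or denominator) are unmatchable at smoothing = 0
  degen <- grid$d1 == 0 | grid$d1 == s1 | grid$d2 == 0 | grid$d2 == s2
  a1 <- grid$d1 + ifelse(degen, smoothing, 0)
  a2 <- grid$d2 + ifelse(degen, smoothing, 0)
  b1 <- s1 + ifelse(degen, 2 * smoothing, 0)
  b2 <- s2 + ifelse(degen, 2 * smoothing, 0)
  pres <- 10 * log10((a1 / b1) / (a2 / b2))
  abse <- 10 * log10(((b1 - a1) / b1) / ((b2 - a2) / b2))
  pres[!is.finite(pres) | !is.finite(abse)] <- NA_real_
  abse[is.na(pres)] <- NA_real_
  hit <- !is.na(pres) & !is.na(abse) &
    round_half_up(pres, 1) == pc_presence_printed &
    round_half_up(abse, 1) == pc_absence_printed
  if (!any(hit)) {
    dist <- abs(pres - pc_presence_printed) + abs(abse - pc_absence_printed)
    near <- grid[order(dist)[1:3], , drop = FALSE]
    stop(sprintf(paste0("no (d1, d2) in [0,%d]x[0,%d] reproduces the pair ",
                        "(%.1f, %.1f); nearest candidates: %s"),
                 s1, s2, pc_presence_printed, pc_absence_printed,
                 paste(sprintf("(%d,%d)", near$d1, near$d2), collapse = " ")),
         call. = FALSE)
  }
  cand <- grid[hit, , drop = FALSE]
  rownames(cand) <- NULL
  structure(list(candidates = cand, unique = nrow(cand) == 1L,
                 pc_presence = pc_presence_printed,
                 pc_absence = pc_absence_printed, s1 = s1, s2 = s2),
            class = "pc_inversion")
}

#' @export
print.pc_inversion <- function(x, ...) {
  cat(sprintf("Inversion of printed pair (%.1f, %.1f), sizes %d vs %d: %s\n",
              x$pc_presence, x$pc_absence, x$s1, x$s2,
              if (x$unique) "unique" else
                sprintf("%d candidates", nrow(x$candidates))))
  print(x$candidates)
  invisible(x)
}

#' Count per-criterion exceedances in a two-group cohort
#'
#' Tallies, for each criterion, how many subjects in each group have the
#' criterion present. Missing statuses are excluded from both the
#' numerator and the effective group size for that criterion. A criterion
#' missing in an entire group cannot be estimated and is dropped with a
#' warning.
#'
#' @param profiles data frame from [binarize_subjects()] or
#'   [generate_binary_cohort()]: a `group` column valued
#'   `"athlete"`/`"control"` plus the nine criterion columns.
#' @return Named list of [gradation_counts()], one per retained criterion,
#'   in canonical criterion order.
#' @export
count_exceedances <- function(profiles) {
  stopifnot(is.data.frame(profiles), "group" %in% names(profiles))
  ids <- intersect(criterion_ids(), names(profiles))
  if (!length(ids)) stop("no criterion columns found", call. = FALSE)
  g <- as.character(profiles$group)
  if (!all(g %in% c("athlete", "control")))
    stop("group labels must be 'athlete' or 'control'", call. = FALSE)
  if (!any(g == "athlete") || !any(g == "control"))
    stop("both groups must be non-empty", call. = FALSE)
  out <- list()
  for (id in ids) {
    x1 <- profiles[[id]][g == "athlete"]
    x2 <- profiles[[id]][g == "control"]
    s1 <- sum(!is.na(x1)); s2 <- sum(!is.na(x2))
    if (s1 == 0L || s2 == 0L) {
      warning(sprintf("criterion '%s' missing in an entire group; dropped",
                      id), call. = FALSE)
      next
    }
    out[[id]] <- gradation_counts(sum(x1, na.rm = TRUE), s1,
                                  sum(x2, na.rm = TRUE), s2)
  }
  out
}
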