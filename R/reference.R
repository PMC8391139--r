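#' The published reference instrument (printed values)
#'
#' The nine-criterion prognostic table published for artistic-swimming
#' talent screening, as printed: presence/absence predictive coefficients
#' to 1 decimal and informativeness to 2 decimals, estimated from two
#' cohorts of 15 twelve-year-old girls (athletes with 4-5 years of
#' training vs untrained schoolgirls). These display values are the input
#' of the reconstruction oracle ([invert_pc_pair()]); the underlying raw
#' data were never published.
#'
#' @return Data frame: `criterion_id`, `pc_presence`, `pc_absence`,
#'   `informativeness` (all printed display values).
#' @seealso [reference_table()], [reproduce_reference()]
#' @export
reference_instrument <- function() {
  data.frame(
    criterion_id = criterion_ids(),
    pc_presence = c(10.8, 10.0, 9.5, 6.7, 6.7, 3.8, 3.0, 2.4, 1.9),
    pc_absence = c(-6.7, -4.5, -3.7, -10.8, -10.8, -5.2, -4.8, -8.5, -7.8),
    informativeness = c(395.70, 300.00, 254.46, 245.30, 245.30, 88.72,
                        60.21, 48.61, 31.98),
    stringsAsFactors = FALSE)
}

#' Reconstruct the reference prognostic table from its printed coefficients
#'
#' Runs the inversion oracle on every printed coefficient pair of
#' [reference_instrument()] (group sizes 15 vs 15), recovering the unique
#' integer exceedance counts, then refits the table from those counts.
#' The result carries full-precision coefficients and informativeness
#' whose display roundings reproduce the printed instrument exactly.
#'
#' @param min_informativeness exclusion cutoff passed through; default 30.
#' @return A [prognostic_table()].
#' @examples
#' reference_table()
#' @export
reference_table <- function(min_informativeness = 30) {
  ref <- reference_instrument()
  counts <- stats::setNames(lapply(seq_len(nrow(ref)), function(i) {
    inv <- invert_pc_pair(ref$pc_presence[i], ref$pc_absence[i], 15, 15)
    if (!inv$unique)
      stop(sprintf("printed pair for '%s' does not invert uniquely",
                   ref$criterion_id[i]), call. = FALSE)
    gradation_counts(inv$candidates$d1[1], 15, inv$candidates$d2[1], 15)
  }), ref$criterion_id)
  prognostic_table_from_counts(counts, min_informativeness)
}

#' Verify the reconstruction against the printed instrument
#'
#' Compares, value by value, the display rounding of the reconstructed
#' table ([reference_table()]) with the printed instrument
#' ([reference_instrument()]): 9 presence coefficients, 9 absence
#' coefficients, 9 informativeness values, and the row order.
#'
#' @return Data frame with one row per criterion: recovered counts, the
#'   three reconstructed display values, the three printed values, and a
#'   logical `match` per row; attribute `all_match` summarises.
#' @examples
#' rep <- reproduce_reference()
#' attr(rep, "all_match")
#' @export
reproduce_reference <- function() {
  ref <- reference_instrument()
  tab <- reference_table()
  r <- tab$rows[match(ref$criterion_id, tab$rows$criterion_id), ]
  out <- data.frame(
    criterion_id = ref$criterion_id,
    d1 = r$d1, d2 = r$d2,
    pc_presence = round_half_up(r$pc_presence, 1),
    pc_absence = round_half_up(r$pc_absence, 1),
    informativeness = round_half_up(r$informativeness, 2),
    printed_presence = ref$pc_presence,
    printed_absence = ref$pc_absence,
    printed_informativeness = ref$informativeness,
    stringsAsFactors = FALSE)
  out$match <- out$pc_presence == out$printed_presence &
    out$pc_absence == out$printed_absence &
    out$informativeness == out$printed_informativeness
  order_match <- identical(tab$rows$criterion_id, ref$criterion_id)
  attr(out, "all_match") <- all(out$match) && order_match
  attr(out, "order_match") <- order_match
  out
}
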