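#' Fit a Wald-Genkin prognostic table
#'
#' Estimates, from a two-group cohort of binary criterion profiles, the
#' published instrument of the sequential screening method: one row per
#' criterion with its presence and absence predictive coefficients
#' (decibans) and Kullback informativeness, sorted in descending
#' informativeness, with uninformative criteria excluded.
#'
#' Criteria with informativeness strictly below `min_informativeness` are
#' dropped (a value exactly at the cutoff is retained). Ties in
#' informativeness are broken by the canonical criterion order, so the fit
#' is deterministic. A warning is emitted when the retained row count
#' falls outside 7-10, the range the method's practitioners consider
#' sufficient for a reliable table.
#'
#' @param profiles data frame of binary criterion profiles with a `group`
#'   column (`"athlete"` / `"control"`), e.g. from [binarize_subjects()]
#'   or [generate_binary_cohort()].
#' @param min_informativeness exclusion cutoff; default 30.
#' @param smoothing continuity correction for zero cells, see
#'   [predictive_coefficient()]; default 0.5.
#' @return An object of class `prognostic_table`: list with `rows` (data
#'   frame of criterion_id, label, unrounded pc_presence / pc_absence /
#'   informativeness, and the provenance counts d1, s1, d2, s2),
#'   `excluded` (the dropped rows), `min_informativeness`, `smoothing`.
#' @seealso [prognostic_table_from_counts()], [predict.prognostic_table()],
#'   [simulate.prognostic_table()]
#' @examples
#' cohort <- generate_binary_cohort(d1 = c(vlc_ratio_gt1 = 12),
#'                                  d2 = c(vlc_ratio_gt1 = 1), seed = 1)
#' prognostic_table(cohort, min_informativeness = 0)
#' @export
prognostic_table <- function(profiles, min_informativeness = 30,
                             smoothing = 0.5) {
  counts <- count_exceedances(profiles)
  prognostic_table_from_counts(counts, min_informativeness, smoothing)
}

#' Assemble a prognostic table directly from gradation counts
#'
#' The count-level entry point of [prognostic_table()]: takes per-criterion
#' [gradation_counts()] (e.g. recovered by [invert_pc_pair()]) and builds
#' the sorted, filtered table.
#'
#' @param counts named list of [gradation_counts()]; names are criterion
#'   ids (unknown ids are allowed and carried through with their name as
#'   label).
#' @inheritParams prognostic_table
#' @return A `prognostic_table`.
#' @export
prognostic_table_from_counts <- function(counts, min_informativeness = 30,
                                         smoothing = 0.5) {
  stopifnot(is.list(counts), length(counts) >= 1L,
            !is.null(names(counts)), all(nzchar(names(counts))))
  meta <- criteria()
  # canonical order first so that informativeness ties break deterministically
  ord <- order(match(names(counts), meta$id, nomatch = length(meta$id) + 1L))
  counts <- counts[ord]
  rows <- do.call(rbind, lapply(names(counts), function(id) {
    ct <- counts[[id]]
    stopifnot(inherits(ct, "gradation_counts"))
    data.frame(
      criterion_id = id,
      label = if (id %in% meta$id) meta$label[meta$id == id] else id,
      pc_presence = predictive_coefficient(ct, "presence", smoothing),
      pc_absence = predictive_coefficient(ct, "absence", smoothing),
      informativeness = informativeness(ct, smoothing),
      d1 = ct$d1, s1 = ct$s1, d2 = ct$d2, s2 = ct$s2,
      stringsAsFactors = FALSE)
  }))
  keep <- rows$informativeness >= min_informativeness
  excluded <- rows[!keep, , drop = FALSE]
  rows <- rows[keep, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop(sprintf("no criterion reaches informativeness %s: empty table",
                 min_informativeness), call. = FALSE)
  rows <- rows[order(-rows$informativeness), , drop = FALSE]  # stable sort
  rownames(rows) <- rownames(excluded) <- NULL
  if (nrow(rows) < 7L || nrow(rows) > 10L)
    warning(sprintf(paste0("%d criteria retained; 7-10 are usually ",
                           "considered sufficient for a reliable table"),
                    nrow(rows)), call. = FALSE)
  structure(list(rows = rows, excluded = excluded,
                 min_informativeness = min_informativeness,
                 smoothing = smoothing),
            class = "prognostic_table")
}

#' @export
print.prognostic_table <- function(x, ...) {
  r <- x$rows
  cat(sprintf("Wald-Genkin prognostic table (%d criteria, cutoff %.1f)\n\n",
              nrow(r), x$min_informativeness))
  disp <- data.frame(
    indicator = substr(r$label, 1, 44),
    presence = sprintf("%+.1f", round_half_up(r$pc_presence, 1)),
    absence = sprintf("%+.1f", round_half_up(r$pc_absence, 1)),
    informativeness = sprintf("%.2f", round_half_up(r$informativeness, 2)))
  print(disp, right = FALSE, row.names = FALSE)
  if (nrow(x$excluded))
    cat(sprintf("\n%d criterion(s) excluded below the cutoff: %s\n",
                nrow(x$excluded),
                paste(x$excluded$criterion_id, collapse = ", ")))
  invisible(x)
}

#' @export
summary.prognostic_table <- function(object, ...) {
  structure(list(table = object,
                 n_retained = nrow(object$rows),
                 n_excluded = nrow(object$excluded),
                 informativeness_range = range(object$rows$informativeness),
                 sizes = c(s1 = object$rows$s1[1], s2 = object$rows$s2[1])),
            class = "summary.prognostic_table")
}

#' @export
print.summary.prognostic_table <- function(x, ...) {
  print(x$table)
  cat(sprintf("\nInformativeness range: %.2f - %.2f\n",
              x$informativeness_range[1], x$informativeness_range[2]))
  cat(sprintf("Group sizes (first row): %d athletes vs %d controls\n",
              x$sizes["s1"], x$sizes["s2"]))
  invisible(x)
}

#' Extract the deciban coefficients of a prognostic table
#'
#' @param object a `prognostic_table`.
#' @param rounded return the 1-decimal display values used by the printed
#'   instrument (default `FALSE`: unrounded).
#' @param ... unused.
#' @return Numeric matrix, one row per criterion, columns `presence` and
#'   `absence`.
#' @export
coef.prognostic_table <- function(object, rounded = FALSE, ...) {
  m <- cbind(presence = object$rows$pc_presence,
             absence = object$rows$pc_absence)
  rownames(m) <- object$rows$criterion_id
  if (rounded) round_half_up(m, 1) else m
}

#' @export
as.data.frame.prognostic_table <- function(x, ...) x$rows

#' Plot criterion informativeness
#'
#' Horizontal bar chart of informativeness per retained criterion (table
#' order, most informative at the top) with the exclusion cutoff marked.
#'
#' @param x a `prognostic_table`.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.prognostic_table <- function(x, ...) {
  r <- x$rows[nrow(x$rows):1, ]
  op <- graphics::par(mar = c(4, 11, 2, 1))
  on.exit(graphics::par(op))
  mid <- graphics::barplot(r$informativeness, names.arg = r$criterion_id,
                           horiz = TRUE, las = 1, col = "steelblue",
                           xlab = "Informativeness",
                           main = "Prognostic table", ...)
  graphics::abline(v = x$min_informativeness, lty = 2, col = "red3")
  invisible(mid)
}

#' Write / read a prognostic table as CSV
#'
#' The CSV carries the unrounded coefficients and informativeness at full
#' precision (15 significant digits) together with the 1- and 2-decimal
#' display columns and the provenance counts, so a round trip through disk
#' is lossless.
#'
#' @param table a `prognostic_table`.
#' @param path file path.
#' @return `write_prognostic_table()`: `path`, invisibly.
#' @export
write_prognostic_table <- function(table, path) {
  stopifnot(inherits(table, "prognostic_table"))
  r <- table$rows
  out <- data.frame(
    criterion_id = r$criterion_id,
    pc_presence = sprintf("%.15g", r$pc_presence),
    pc_absence = sprintf("%.15g", r$pc_absence),
    informativeness = sprintf("%.15g", r$informativeness),
    pc_presence_display = sprintf("%.1f", round_half_up(r$pc_presence, 1)),
    pc_absence_display = sprintf("%.1f", round_half_up(r$pc_absence, 1)),
    informativeness_display = sprintf("%.2f",
                                      round_half_up(r$informativeness, 2)),
    d1 = r$d1, s1 = r$s1, d2 = r$d2, s2 = r$s2,
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_prognostic_table
#' @return `read_prognostic_table()`: the reconstructed `prognostic_table`.
#' @export
read_prognostic_table <- function(path) {
  if (!file.exists(path)) stop("table file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("criterion_id", "d1", "s1", "d2", "s2")
  if (!all(need %in% names(df)))
    stop("table CSV lacks required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  counts <- stats::setNames(
    lapply(seq_len(nrow(df)),
           function(i) gradation_counts(df$d1[i], df$s1[i],
                                        df$d2[i], df$s2[i])),
    df$criterion_id)
  # rebuild from counts (exact); min_informativeness not stored in the CSV,
  # so keep every row that was written
  suppressWarnings(prognostic_table_from_counts(counts,
                                                min_informativeness = -Inf))
}
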