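#' Read subject records from CSV
#'
#' One row per subject; the header must be exactly:
#' `subject_id,group,age,body_length,body_weight,chest_circumference,`
#' `vlc_actual,biceps_tense,biceps_rest,stange,genchi,splits,crab,forward_bend`.
#' Units are fixed (cm, kg, L, s, years); empty cells are missing values.
#' Decimal commas are rejected with a pointed message — source data from
#' regions using them must be converted first, silent coercion would
#' corrupt every value.
#'
#' Per-row validation failures (non-positive lengths, ages outside
#' (5, 25), unknown group labels, comma decimals) do not abort the read:
#' offending rows are dropped and reported in the `errors` attribute and
#' a warning.
#'
#' @param path CSV file path.
#' @return Data frame of valid subject records; attribute `errors` is a
#'   character vector of per-row messages (empty when the file is clean).
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("subjects file not found: ", path,
                               call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  if (!identical(names(raw), subject_fields()))
    stop("malformed header: expected exactly\n  ",
         paste(subject_fields(), collapse = ","), call. = FALSE)
  if (nrow(raw) == 0L) stop("subjects file has no data rows", call. = FALSE)

  numeric_fields <- setdiff(subject_fields(), c("subject_id", "group"))
  errors <- character(); keep <- logical(nrow(raw))
  recs <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    row <- as.list(raw[i, ])
    line <- i + 1L  # header is line 1
    msg <- NULL
    for (f in numeric_fields) {
      cell <- row[[f]]
      if (is.na(cell) || cell == "") { row[[f]] <- NA_real_; next }
      if (grepl(",", cell, fixed = TRUE)) {
        msg <- c(msg, sprintf("'%s' uses a decimal comma ('%s'); use a point",
                              f, cell))
        next
      }
      v <- suppressWarnings(as.numeric(cell))
      if (is.na(v)) msg <- c(msg, sprintf("'%s' is not numeric ('%s')",
                                          f, cell))
      row[[f]] <- v
    }
    if (is.na(row$group) || row$group == "") row$group <- NA_character_
    if (is.null(msg)) msg <- validate_subject(row)
    else msg <- paste(msg, collapse = "; ")
    if (!is.null(msg)) {
      errors <- c(errors, sprintf("line %d (subject %s): %s",
                                  line, row$subject_id, msg))
    } else {
      keep[i] <- TRUE
      recs[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
    }
  }
  if (!any(keep))
    stop("no valid subject rows; first problem: ", errors[1], call. = FALSE)
  out <- do.call(rbind, recs[keep])
  rownames(out) <- NULL
  if (length(errors))
    warning(sprintf("%d row(s) dropped during validation; see attr(, 'errors')",
                    length(errors)), call. = FALSE)
  attr(out, "errors") <- errors
  out
}

#' Write subject records to CSV
#'
#' Inverse of [read_subjects()]: fixed column order, point decimals,
#' empty cells for missing values. Numeric values are written with
#' full precision, so a round trip is lossless.
#'
#' @param subjects data frame of subject records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  stopifnot(is.data.frame(subjects))
  out <- subjects[, subject_fields()]
  num <- setdiff(subject_fields(), c("subject_id", "group"))
  for (f in num) out[[f]] <- ifelse(is.na(out[[f]]), "",
                                    sprintf("%.15g", out[[f]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
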