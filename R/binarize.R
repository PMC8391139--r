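subject_fields <- function() {
  c("subject_id", "group", "age", "body_length", "body_weight",
    "chest_circumference", "vlc_actual", "biceps_tense", "biceps_rest",
    "stange", "genchi", "splits", "crab", "forward_bend")
}

# Validate one subject record (a named list or one-row data frame).
# Returns NULL when valid, otherwise a character message; missing (NA)
# values are permitted everywhere except subject_id.
validate_subject <- function(rec) {
  msgs <- character()
  num <- function(f) suppressWarnings(as.numeric(rec[[f]]))
  pos_fields <- c("body_length", "body_weight", "chest_circumference",
                  "vlc_actual", "biceps_tense", "biceps_rest")
  for (f in pos_fields) {
    v <- num(f)
    if (!is.na(v) && v <= 0) msgs <- c(msgs, sprintf("'%s' must be positive", f))
  }
  for (f in c("stange", "genchi", "forward_bend")) {
    v <- num(f)
    if (!is.na(v) && v < 0) msgs <- c(msgs, sprintf("'%s' must be non-negative", f))
  }
  a <- num("age")
  if (!is.na(a) && (a <= 5 || a >= 25))
    msgs <- c(msgs, "'age' must be in (5, 25) years")
  g <- rec[["group"]]
  if (!is.null(g) && !is.na(g) && g != "" && !g %in% c("athlete", "control"))
    msgs <- c(msgs, "'group' must be 'athlete' or 'control'")
  if (length(msgs)) paste(msgs, collapse = "; ") else NULL
}

#' Binarize a subject into the nine screening criteria
#'
#' Evaluates the nine criteria of the prognostic instrument on one subject
#' record, against a configurable norm table. Every comparison is strict in
#' the published direction ("more than" / "less than"): a value exactly at
#' a threshold yields absent. Any criterion whose input fields are missing
#' is marked missing (`NA`), never imputed.
#'
#' @param record named list or one-row data frame with the measurement
#'   fields (see [read_subjects()] for the full schema).
#' @param norms a [norm_table()].
#' @return Named integer vector over [criteria()] ids, in the canonical
#'   order: 1 = present, 0 = absent, `NA` = missing.
#' @examples
#' rec <- list(subject_id = "a1", age = 12, body_length = 152,
#'   body_weight = 34, chest_circumference = 70, vlc_actual = 2.6,
#'   biceps_tense = 24, biceps_rest = 22, stange = 55, genchi = 30,
#'   splits = -2, crab = 50, forward_bend = 14)
#' binarize(rec, default_norms())
#' @export
binarize <- function(record, norms) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record <- as.list(record)
  }
  msg <- validate_subject(record)
  if (!is.null(msg))
    stop("invalid subject record: ", msg, call. = FALSE)
  num <- function(f) {
    v <- record[[f]]
    if (is.null(v)) NA_real_ else suppressWarnings(as.numeric(v))
  }
  age <- num("age"); bl <- num("body_length")

  strict <- function(value, direction, threshold) {
    if (is.na(value)) return(NA_integer_)
    as.integer(if (direction == "gt") value > threshold else value < threshold)
  }

  ratio <- if (is.na(num("vlc_actual")) || is.na(bl) || is.na(age)) NA_real_
           else vlc_ratio(num("vlc_actual"), proper_vlc(bl, age))
  bic <- if (is.na(num("biceps_tense")) || is.na(num("biceps_rest"))) NA_real_
         else suppressWarnings(biceps_index(num("biceps_tense"),
                                            num("biceps_rest")))
  wd <- weight_deficit(num("body_weight"), bl, norms)
  eri <- if (is.na(num("chest_circumference")) || is.na(bl)) NA_real_
         else erisman_index(num("chest_circumference"), bl)
  st_norm <- if (is.na(age)) NA_real_ else lookup_age_norm(norms, age, "stange")
  ge_norm <- if (is.na(age)) NA_real_ else lookup_age_norm(norms, age, "genchi")
  st <- num("stange"); ge <- num("genchi")

  out <- c(
    vlc_ratio_gt1      = strict(ratio, "gt", 1),
    biceps_gt_6_7pct   = strict(bic, "gt", 0.067),
    weight_deficit     = if (is.na(wd)) NA_integer_ else as.integer(wd),
    forward_bend_gt10s = strict(num("forward_bend"), "gt", 10),
    splits_lt0         = strict(num("splits"), "lt", 0),
    stange_gt_norm     = if (is.na(st) || is.na(st_norm)) NA_integer_
                         else as.integer(st > st_norm),
    genchi_gt_norm     = if (is.na(ge) || is.na(ge_norm)) NA_integer_
                         else as.integer(ge > ge_norm),
    erisman_lt0        = strict(eri, "lt", 0),
    crab_lt60          = strict(num("crab"), "lt", 60)
  )
  stopifnot(identical(names(out), criterion_ids()))
  out
}

#' Binarize a cohort of subjects
#'
#' Applies [binarize()] to every row of a subject data frame, carrying the
#' subject id and group label through.
#'
#' @param subjects data frame of subject records (one row each), e.g. from
#'   [read_subjects()] or [generate_measurement_cohort()].
#' @param norms a [norm_table()].
#' @return Data frame: `subject_id`, `group`, then the nine criterion
#'   columns valued 1/0/`NA`.
#' @export
binarize_subjects <- function(subjects, norms) {
  stopifnot(is.data.frame(subjects), nrow(subjects) >= 1L)
  prof <- t(vapply(seq_len(nrow(subjects)),
                   function(i) binarize(subjects[i, ], norms),
                   integer(9)))
  out <- data.frame(subject_id = as.character(subjects$subject_id),
                    group = if ("group" %in% names(subjects))
                      as.character(subjects$group) else NA_character_,
                    prof, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write criterion profiles to CSV
#'
#' @param profiles data frame from [binarize_subjects()] or
#'   [generate_binary_cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE, quote = FALSE,
                   na = "NA")
  invisible(path)
}
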