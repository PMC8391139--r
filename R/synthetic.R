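normalize_crit_vec <- function(x, what, default = NULL) {
  ids <- criterion_ids()
  if (is.null(x)) return(default)
  if (is.null(names(x))) {
    if (length(x) == 1L) x <- rep(x, length(ids))
    stopifnot(length(x) == length(ids))
    names(x) <- ids
  }
  bad <- setdiff(names(x), ids)
  if (length(bad))
    stop(sprintf("unknown criterion id(s) in %s: %s", what,
                 paste(bad, collapse = ", ")), call. = FALSE)
  x[ids[ids %in% names(x)]]
}

#' Generate a two-group cohort of binary criterion profiles
#'
#' The binary tier of the synthetic-cohort generator: draws
#' presence/absence profiles for two groups (athletes and controls)
#' directly, without the measurement layer, so the estimation arithmetic
#' can be exercised in isolation.
#'
#' Two modes per criterion. With fixed counts (`d1`, `d2`), exactly that
#' many subjects per group — a seeded random subset — have the criterion
#' present, so [count_exceedances()] recovers the counts exactly. With
#' probabilities (`p1`, `p2`), each subject's status is an independent
#' Bernoulli draw. Criteria not named in either argument are omitted from
#' the output.
#'
#' The default emulates the reference study design: 15 athletes vs 15
#' controls.
#'
#' @param n1,n2 group sizes (default 15 and 15).
#' @param p1,p2 named vectors of per-criterion presence probabilities
#'   (athlete / control groups), or a single value recycled over all nine
#'   criteria.
#' @param d1,d2 named vectors of fixed per-criterion presence counts;
#'   override `p1`/`p2` for the criteria they name.
#' @param seed integer seed; identical inputs and seed give identical
#'   output.
#' @return Data frame: `subject_id`, `group`, one 0/1 column per
#'   criterion.
#' @examples
#' generate_binary_cohort(p1 = 0.8, p2 = 0.1, seed = 1)
#' @export
generate_binary_cohort <- function(n1 = 15, n2 = 15, p1 = NULL, p2 = NULL,
                                   d1 = NULL, d2 = NULL, seed = NULL) {
  stopifnot(n1 >= 1, n2 >= 1)
  if (!is.null(seed)) set.seed(seed)
  p1 <- normalize_crit_vec(p1, "p1"); p2 <- normalize_crit_vec(p2, "p2")
  d1 <- normalize_crit_vec(d1, "d1"); d2 <- normalize_crit_vec(d2, "d2")
  ids <- intersect(criterion_ids(),
                   unique(c(names(p1), names(d1), names(p2), names(d2))))
  if (!length(ids))
    stop("supply p1/p2 or d1/d2 for at least one criterion", call. = FALSE)
  draw_group <- function(n, p, d, group, prefix) {
    out <- data.frame(subject_id = sprintf("%s%02d", prefix, seq_len(n)),
                      group = group, stringsAsFactors = FALSE)
    for (id in ids) {
      if (!is.null(d) && id %in% names(d)) {
        k <- d[[id]]
        stopifnot(k >= 0, k <= n, k == round(k))
        v <- integer(n); v[sample.int(n, k)] <- 1L
      } else {
        pr <- p[[id]]
        stopifnot(!is.null(pr), pr >= 0, pr <= 1)
        v <- stats::rbinom(n, 1L, pr)
      }
      out[[id]] <- v
    }
    out
  }
  rbind(draw_group(n1, p1, d1, "athlete", "a"),
        draw_group(n2, p2, d2, "control", "c"))
}

# Plausible measurement distributions for ~12-year-old girls; fixture
# choices for the generator, not empirical claims. Each field is drawn
# from its base distribution, then nudged across or away from its
# criterion threshold so that binarize() reproduces the target profile.
draw_record <- function(target, norms, subject_id, group) {
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  age <- clamp(stats::rnorm(1, 12, 0.85), 10.5, 13.5)
  w <- norms$weight_norms
  bl <- clamp(stats::rnorm(1, 152, 6),
              min(w$min_height) + 2, max(w$max_height) - 2)
  rec <- list(subject_id = subject_id, group = group, age = age,
              body_length = bl)
  side <- function(id) target[[id]]  # 1 / 0 / NA

  s <- side("vlc_ratio_gt1")
  rec$vlc_actual <- if (is.na(s)) NA_real_ else
    proper_vlc(bl, age) * (if (s == 1) stats::runif(1, 1.03, 1.3)
                           else stats::runif(1, 0.7, 0.97))

  s <- side("biceps_gt_6_7pct")
  rec$biceps_rest <- clamp(stats::rnorm(1, 21, 1.5), 16, 27)
  rec$biceps_tense <- if (is.na(s)) NA_real_ else
    rec$biceps_rest * (1 + (if (s == 1) stats::runif(1, 0.08, 0.14)
                            else stats::runif(1, 0, 0.055)))

  s <- side("weight_deficit")
  nm <- lookup_weight_norm(norms, bl)
  rec$body_weight <- if (is.na(s)) NA_real_ else if (s == 1)
    max(nm$M - nm$delta_R - stats::runif(1, 0.5, 4), 16) else
    stats::runif(1, nm$M - nm$delta_R + 0.3, nm$M + nm$delta_R)

  s <- side("forward_bend_gt10s")
  rec$forward_bend <- if (is.na(s)) NA_real_ else
    if (s == 1) stats::runif(1, 10.5, 25) else stats::runif(1, 1, 9.5)

  s <- side("splits_lt0")
  rec$splits <- if (is.na(s)) NA_real_ else
    if (s == 1) stats::runif(1, -7, -0.5) else stats::runif(1, 0.5, 12)

  for (test in c("stange", "genchi")) {
    s <- side(paste0(test, "_gt_norm"))
    nv <- lookup_age_norm(norms, age, test)
    rec[[test]] <- if (is.na(s)) NA_real_ else
      if (s == 1) nv + stats::runif(1, 2, 15) else
      max(nv - stats::runif(1, 2, 15), 1)
  }

  s <- side("erisman_lt0")
  rec$chest_circumference <- if (is.na(s)) NA_real_ else
    0.5 * bl + (if (s == 1) stats::runif(1, -6, -0.5)
                else stats::runif(1, 0.5, 6))

  s <- side("crab_lt60")
  rec$crab <- if (is.na(s)) NA_real_ else
    if (s == 1) stats::runif(1, 38, 58) else stats::runif(1, 61, 82)

  rec[c(subject_fields())]
}

#' Generate full measurement records matching target binary profiles
#'
#' The measurement tier of the synthetic-cohort generator: for each target
#' criterion profile it draws a plausible raw measurement record
#' (documented normal/uniform fixture distributions for 12-year-old
#' girls) and places each field on the side of its criterion threshold
#' that the target demands, so that `binarize(record, norms)` is
#' guaranteed to reproduce the target profile; a missing target status
#' yields a missing measurement. Records whose binarization fails to
#' match (numerically impossible nudges) are redrawn, up to
#' `max_attempts` each.
#'
#' @param profiles data frame of target profiles (e.g. from
#'   [generate_binary_cohort()]); criteria absent from it are treated as
#'   missing.
#' @param norms a [norm_table()]; default [default_norms()].
#' @param seed integer seed.
#' @param max_attempts redraw budget per subject (default 20).
#' @return Data frame of subject records with the full measurement schema
#'   (see [read_subjects()]).
#' @examples
#' prof <- generate_binary_cohort(p1 = 0.9, p2 = 0.1, seed = 2)
#' rec <- generate_measurement_cohort(prof, seed = 2)
#' identical(binarize_subjects(rec, default_norms())[-(1:2)], prof[-(1:2)])
#' @export
generate_measurement_cohort <- function(profiles, norms = default_norms(),
                                        seed = NULL, max_attempts = 20) {
  stopifnot(is.data.frame(profiles), nrow(profiles) >= 1L)
  if (!is.null(seed)) set.seed(seed)
  ids <- criterion_ids()
  rows <- lapply(seq_len(nrow(profiles)), function(i) {
    target <- stats::setNames(rep(NA_integer_, length(ids)), ids)
    for (id in intersect(ids, names(profiles)))
      target[[id]] <- profiles[[id]][i]
    for (k in seq_len(max_attempts)) {
      rec <- draw_record(target, norms,
                         as.character(profiles$subject_id[i]),
                         as.character(profiles$group[i]))
      got <- suppressWarnings(binarize(rec, norms))
      if (identical(unname(got), unname(target))) return(as.data.frame(rec))
    }
    stop(sprintf("could not realise target profile for subject %s in %d attempts",
                 profiles$subject_id[i], max_attempts), call. = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Monte-Carlo validation of the sequential threshold semantics
#'
#' Draws fresh binary subjects from each group's per-criterion presence
#' probabilities, classifies them against a fitted table, and reports the
#' outcome rates per group with Monte-Carlo standard errors. The
#' misclassification rates — a control subject reaching `+T` (false
#' success) and an athlete reaching `-T` (false low-probability) — are
#' the quantities the threshold's allowable-error calibration bounds.
#'
#' @param table a [prognostic_table()].
#' @param p1,p2 per-criterion presence probabilities for the two groups;
#'   default: the table's own estimated proportions `d/s`, i.e. the
#'   generating model the table was fitted to.
#' @param n_subjects subjects per group (default 1000).
#' @param alpha,threshold stopping threshold, as in
#'   [predict.prognostic_table()].
#' @param seed integer seed.
#' @return Object of class `wg_error_rates`: data frame `rates` (group,
#'   outcome, rate, mc_se), scalars `false_success_rate` (controls
#'   classified success) and `false_low_rate` (athletes classified
#'   low_probability), `n_subjects`, `threshold`.
#' @examples
#' sim <- simulate_error_rates(reference_table(), n_subjects = 200, seed = 3)
#' sim$false_success_rate
#' @export
simulate_error_rates <- function(table, p1 = NULL, p2 = NULL,
                                 n_subjects = 1000, alpha = 0.05,
                                 threshold = NULL, seed = NULL) {
  stopifnot(inherits(table, "prognostic_table"), n_subjects >= 1)
  r <- table$rows
  if (is.null(p1)) p1 <- stats::setNames(r$d1 / r$s1, r$criterion_id)
  if (is.null(p2)) p2 <- stats::setNames(r$d2 / r$s2, r$criterion_id)
  cohort <- generate_binary_cohort(n1 = n_subjects, n2 = n_subjects,
                                   p1 = p1, p2 = p2, seed = seed)
  pred <- predict(table, cohort, alpha = alpha, threshold = threshold)
  g <- cohort$group  # prediction rows align with cohort rows
  lv <- c("success", "low_probability", "uncertain")
  rates <- do.call(rbind, lapply(c("athlete", "control"), function(gr) {
    oc <- factor(pred$outcomes$outcome[g == gr], levels = lv)
    p <- as.numeric(table(oc)) / n_subjects
    data.frame(group = gr, outcome = lv, rate = p,
               mc_se = sqrt(p * (1 - p) / n_subjects),
               stringsAsFactors = FALSE)
  }))
  structure(list(
    rates = rates,
    false_success_rate = rates$rate[rates$group == "control" &
                                      rates$outcome == "success"],
    false_low_rate = rates$rate[rates$group == "athlete" &
                                  rates$outcome == "low_probability"],
    n_subjects = n_subjects, threshold = pred$threshold),
    class = "wg_error_rates")
}

#' @export
print.wg_error_rates <- function(x, ...) {
  cat(sprintf("Monte-Carlo error rates (%d subjects/group, threshold %d):\n",
              x$n_subjects, x$threshold))
  print(transform(x$rates, rate = sprintf("%.4f", rate),
                  mc_se = sprintf("%.4f", mc_se)), row.names = FALSE)
  cat(sprintf("false success (control -> +T): %.4f\n", x$false_success_rate))
  cat(sprintf("false low (athlete -> -T):     %.4f\n", x$false_low_rate))
  invisible(x)
}

#' Simulate cohorts from a fitted prognostic table
#'
#' Draws binary criterion cohorts from the generating model the table
#' encodes (per-group presence probabilities `d/s`), one data frame per
#' simulation.
#'
#' @param object a [prognostic_table()].
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param n1,n2 group sizes; default the table's fitted sizes.
#' @param ... unused.
#' @return A data frame (`nsim = 1`) or list of data frames.
#' @export
simulate.prognostic_table <- function(object, nsim = 1, seed = NULL,
                                      n1 = NULL, n2 = NULL, ...) {
  r <- object$rows
  if (is.null(n1)) n1 <- r$s1[1]
  if (is.null(n2)) n2 <- r$s2[1]
  if (!is.null(seed)) set.seed(seed)
  p1 <- stats::setNames(r$d1 / r$s1, r$criterion_id)
  p2 <- stats::setNames(r$d2 / r$s2, r$criterion_id)
  out <- lapply(seq_len(nsim), function(k)
    generate_binary_cohort(n1 = n1, n2 = n2, p1 = p1, p2 = p2))
  if (nsim == 1) out[[1]] else out
}
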