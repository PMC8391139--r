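make_profile <- function(statuses) {
  df <- data.frame(subject_id = "p1", stringsAsFactors = FALSE)
  for (i in seq_along(criterion_ids())) df[[criterion_ids()[i]]] <- statuses[i]
  df
}

test_that("allowable error maps to whole-deciban thresholds", {
  expect_identical(threshold_from_error(0.05), 13L)
  expect_identical(threshold_from_error(0.001), 30L)
  expect_identical(threshold_from_error(0.4999), 0L)
  expect_identical(threshold_from_error(0.2), 6L)  # 10*log10(4) = 6.02
  expect_error(threshold_from_error(0), "alpha")
  expect_error(threshold_from_error(0.6), "alpha")
})

test_that("sequential summation stops at first crossing of +/-13", {
  tab <- reference_table()
  # all nine present: +10.8, +20.8 -> stops at step 2
  p <- predict(tab, make_profile(rep(1L, 9)))
  expect_equal(p$outcomes$outcome, "success")
  expect_equal(p$outcomes$stopping_step, 2L)
  expect_equal(p$traces[[1]]$steps$cumulative, c(10.8, 20.8))
  # all nine absent: -6.7, -11.2, -14.9 -> stops at step 3
  p <- predict(tab, make_profile(rep(0L, 9)))
  expect_equal(p$outcomes$outcome, "low_probability")
  expect_equal(p$outcomes$stopping_step, 3L)
  expect_equal(p$traces[[1]]$steps$cumulative, c(-6.7, -11.2, -14.9))
})

test_that("a profile that never crosses is uncertain after the whole table", {
  tab <- reference_table()
  p <- predict(tab, make_profile(c(1L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 1L)))
  expect_equal(p$outcomes$outcome, "uncertain")
  expect_true(is.na(p$outcomes$stopping_step))
  expect_equal(p$traces[[1]]$steps$cumulative,
               c(10.8, 6.3, 2.6, -8.2, -1.5, 2.3, 5.3, 7.7, 9.6))
  # empty profile: nothing to sum
  p0 <- predict(tab, make_profile(rep(NA_integer_, 9)))
  expect_equal(p0$outcomes$outcome, "uncertain")
  expect_equal(nrow(p0$traces[[1]]$steps), 0L)
})

test_that("missing rows are skipped, not scored as absence", {
  tab <- reference_table()
  with_na <- make_profile(c(NA, 1L, 1L, rep(0L, 6)))
  p <- predict(tab, with_na)
  expect_equal(p$traces[[1]]$steps$criterion_id[1], "biceps_gt_6_7pct")
  expect_equal(p$traces[[1]]$steps$cumulative[1:2], c(10.0, 19.5))
  expect_equal(p$outcomes$outcome, "success")
})

test_that("truncating at the stopping step re-yields the same outcome", {
  tab <- reference_table()
  set.seed(21)
  for (k in 1:25) {
    prof <- make_profile(sample(c(0L, 1L), 9, replace = TRUE))
    p <- predict(tab, prof)
    step <- p$outcomes$stopping_step
    if (is.na(step)) next
    # blank out everything after the stopping step; outcome must not change
    used <- p$traces[[1]]$steps$criterion_id
    trunc <- prof
    for (id in setdiff(criterion_ids(), used)) trunc[[id]] <- NA_integer_
    p2 <- predict(tab, trunc)
    expect_equal(p2$outcomes$outcome, p$outcomes$outcome)
    expect_equal(p2$outcomes$stopping_step, step)
  }
})

test_that("flipping absent to present never lowers later cumulative sums", {
  tab <- reference_table()
  expect_true(all(tab$rows$pc_presence > tab$rows$pc_absence))
  set.seed(22)
  for (k in 1:15) {
    st <- sample(c(0L, 1L), 9, replace = TRUE)
    j <- sample(which(st == 0L), 1)
    up <- st; up[j] <- 1L
    s1 <- predict(tab, make_profile(st), threshold = Inf)
    s2 <- predict(tab, make_profile(up), threshold = Inf)
    c1 <- s1$traces[[1]]$steps$cumulative
    c2 <- s2$traces[[1]]$steps$cumulative
    expect_true(all(c2[j:9] >= c1[j:9]))
  }
})

test_that("swapping the groups mirrors outcomes at the symmetric threshold", {
  prof <- generate_binary_cohort(d1 = sapply(reference_counts(), `[`, 1),
                                 d2 = sapply(reference_counts(), `[`, 2),
                                 seed = 9)
  tab <- prognostic_table(prof)
  swapped <- prof
  swapped$group <- ifelse(prof$group == "athlete", "control", "athlete")
  tab_sw <- prognostic_table(swapped)
  # coefficients negate and informativeness (hence row order) is preserved
  expect_equal(tab_sw$rows$pc_presence, -tab$rows$pc_presence)
  expect_equal(tab_sw$rows$informativeness, tab$rows$informativeness)
  test_profiles <- generate_binary_cohort(n1 = 10, n2 = 10, p1 = 0.7,
                                          p2 = 0.3, seed = 10)
  p1 <- predict(tab, test_profiles)$outcomes$outcome
  p2 <- predict(tab_sw, test_profiles)$outcomes$outcome
  map <- c(success = "low_probability", low_probability = "success",
           uncertain = "uncertain")
  expect_equal(p2, unname(map[p1]))
})

test_that("unrounded summation is available for sensitivity analysis", {
  tab <- reference_table()
  p <- predict(tab, make_profile(rep(1L, 9)), rounded = FALSE)
  expect_equal(p$traces[[1]]$steps$cumulative[2],
               10 * log10(12) + 10, tolerance = 1e-12)
})

test_that("reports carry one JSONL line per subject and are deterministic", {
  tab <- reference_table()
  prof <- generate_binary_cohort(n1 = 8, n2 = 7, p1 = 0.8, p2 = 0.2,
                                 seed = 30)
  pred <- predict(tab, prof)
  path1 <- withr::local_tempfile(fileext = ".jsonl")
  path2 <- withr::local_tempfile(fileext = ".jsonl")
  write_report(pred, path1)
  write_report(pred, path2)
  lines <- readLines(path1)
  expect_length(lines, 15)
  expect_identical(readLines(path2), lines)
  first <- jsonlite::fromJSON(lines[1])
  expect_named(first, c("subject_id", "outcome", "stopping_step",
                        "final_sum", "steps"), ignore.order = FALSE)
  # summary outcome counts conserve the subject count
  summary_lines <- readLines(paste0(path1, ".summary.txt"))
  counts <- as.numeric(sub(".*: ", "", summary_lines[3:5]))
  expect_equal(sum(counts), 15)
})
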