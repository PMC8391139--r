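test_that("predictive coefficients reproduce printed reference values", {
  ct <- gradation_counts(12, 15, 1, 15)
  expect_equal(round_half_up(predictive_coefficient(ct, "presence"), 1), 10.8)
  expect_equal(round_half_up(predictive_coefficient(ct, "absence"), 1), -6.7)
  expect_equal(predictive_coefficient(ct, "absence"),
               10 * log10((3 / 15) / (14 / 15)))
  # exact decade ratio gives exactly 10 decibans
  expect_equal(predictive_coefficient(gradation_counts(10, 15, 1, 15),
                                      "presence"), 10)
  # equal proportions carry no evidence
  expect_equal(predictive_coefficient(gradation_counts(7, 15, 7, 15),
                                      "presence"), 0)
})

test_that("degenerate counts error without smoothing and shrink with it", {
  ct <- gradation_counts(15, 15, 0, 15)
  expect_error(predictive_coefficient(ct, "presence", smoothing = 0),
               "degenerate")
  pc <- predictive_coefficient(ct, "presence", smoothing = 0.5)
  expect_equal(pc, 10 * log10((15.5 / 16) / (0.5 / 16)))
  # smoothing never perturbs non-degenerate counts
  ct2 <- gradation_counts(12, 15, 1, 15)
  expect_equal(predictive_coefficient(ct2, "presence", smoothing = 0.5),
               predictive_coefficient(ct2, "presence", smoothing = 0))
})

test_that("coefficients are antisymmetric under group swap and complement", {
  for (d1 in c(1, 5, 9, 14)) for (d2 in c(2, 7, 13)) {
    a <- gradation_counts(d1, 15, d2, 15)
    b <- gradation_counts(d2, 15, d1, 15)
    expect_equal(predictive_coefficient(a, "presence"),
                 -predictive_coefficient(b, "presence"))
    # absence gradation = presence gradation of the complemented counts
    comp <- gradation_counts(15 - d1, 15, 15 - d2, 15)
    expect_equal(predictive_coefficient(a, "absence"),
                 predictive_coefficient(comp, "presence"))
  }
})

test_that("informativeness uses the unrounded coefficient and matches print", {
  # 0.5 * 9.5424 * 53.3333 = 254.46; the printed-rounded pc would give 253.33
  expect_equal(round_half_up(informativeness(gradation_counts(9, 15, 1, 15)),
                             2), 254.46)
  expect_equal(round_half_up(informativeness(gradation_counts(12, 15, 1, 15)),
                             2), 395.70)
  expect_equal(round_half_up(informativeness(gradation_counts(14, 15, 9, 15)),
                             2), 31.98)
  expect_equal(informativeness(gradation_counts(6, 15, 6, 15)), 0)
})

test_that("informativeness is non-negative, zero only at equal proportions", {
  for (d1 in 1:14) for (d2 in 1:14) {
    i <- informativeness(gradation_counts(d1, 15, d2, 15))
    if (d1 == d2) expect_equal(i, 0) else expect_gt(i, 0)
  }
  # both-gradation option adds a non-negative term
  ct <- gradation_counts(12, 15, 4, 15)
  expect_gte(informativeness(ct, both_gradations = TRUE),
             informativeness(ct))
})

test_that("inversion oracle recovers counts from printed pairs", {
  inv <- invert_pc_pair(10.8, -6.7, 15, 15)
  expect_true(inv$unique)
  expect_equal(unlist(inv$candidates), c(d1 = 12, d2 = 1))
  inv2 <- invert_pc_pair(6.7, -10.8, 15, 15)
  expect_equal(unlist(inv2$candidates), c(d1 = 14, d2 = 3))
  # equal-proportion pair is maximally ambiguous: every d1 = d2
  inv0 <- invert_pc_pair(0.0, 0.0, 15, 15)
  expect_false(inv0$unique)
  expect_equal(nrow(inv0$candidates), 14)  # d = 1..14 (0 and 15 degenerate)
  expect_true(all(inv0$candidates$d1 == inv0$candidates$d2))
  expect_error(invert_pc_pair(99.9, -99.9, 15, 15), "nearest candidates")
})

test_that("oracle round-trips every interior count pair", {
  for (d1 in 1:14) for (d2 in 1:14) {
    ct <- gradation_counts(d1, 15, d2, 15)
    pp <- round_half_up(predictive_coefficient(ct, "presence"), 1)
    pa <- round_half_up(predictive_coefficient(ct, "absence"), 1)
    inv <- invert_pc_pair(pp, pa, 15, 15)
    hit <- any(inv$candidates$d1 == d1 & inv$candidates$d2 == d2)
    expect_true(hit, label = sprintf("(%d, %d) recovered", d1, d2))
  }
})

test_that("count_exceedances tallies groups and handles missing statuses", {
  prof <- generate_binary_cohort(d1 = c(vlc_ratio_gt1 = 12, crab_lt60 = 14),
                                 d2 = c(vlc_ratio_gt1 = 1, crab_lt60 = 9),
                                 seed = 4)
  ct <- count_exceedances(prof)
  expect_equal(ct$vlc_ratio_gt1[c("d1", "s1", "d2", "s2")],
               list(d1 = 12L, s1 = 15L, d2 = 1L, s2 = 15L))
  expect_equal(ct$crab_lt60$d1, 14L)
  # a missing status shrinks the effective group size
  prof$vlc_ratio_gt1[prof$group == "athlete"][1] <- NA
  ct2 <- count_exceedances(prof)
  expect_equal(ct2$vlc_ratio_gt1$s1, 14L)
  # all-present saturates
  prof$crab_lt60 <- 1L
  expect_equal(count_exceedances(prof)$crab_lt60[c("d1", "d2")],
               list(d1 = 15L, d2 = 15L))
  # entirely-missing criterion in one group is dropped with a warning
  prof$vlc_ratio_gt1[prof$group == "control"] <- NA
  expect_warning(ct3 <- count_exceedances(prof), "entire group")
  expect_false("vlc_ratio_gt1" %in% names(ct3))
})

test_that("table assembly sorts, filters at the cutoff, and breaks ties stably", {
  tab <- prognostic_table_from_counts(reference_counts_list())
  expect_s3_class(tab, "prognostic_table")
  expect_equal(nrow(tab$rows), 9)
  expect_true(all(diff(tab$rows$informativeness) <= 0))
  # the two tied rows (identical counts 14 vs 3) keep canonical adjacency
  expect_equal(tab$rows$criterion_id[4:5],
               c("forward_bend_gt10s", "splits_lt0"))
  # informativeness below the cutoff is excluded, at the cutoff retained
  counts <- reference_counts_list()
  counts$weak <- gradation_counts(8, 15, 5, 15)  # i = 20.4 < 30
  tab2 <- prognostic_table_from_counts(counts)
  expect_false("weak" %in% tab2$rows$criterion_id)
  expect_true("weak" %in% tab2$excluded$criterion_id)
  expect_true("crab_lt60" %in% tab2$rows$criterion_id)  # 31.98 >= 30
  expect_error(
    suppressWarnings(prognostic_table_from_counts(
      list(weak = gradation_counts(8, 15, 5, 15)))), "empty table")
})

test_that("the full reference instrument is reconstructed exactly", {
  # flagship check: inversion oracle -> counts -> forward formulas
  # reproduces all 27 printed numbers and the printed row order
  rep <- reproduce_reference()
  expect_true(all(rep$match))
  expect_true(attr(rep, "all_match"))
  expect_true(attr(rep, "order_match"))
  expected <- reference_counts()
  for (id in names(expected)) {
    expect_equal(c(rep$d1[rep$criterion_id == id],
                   rep$d2[rep$criterion_id == id]),
                 expected[[id]], label = id)
  }
})

test_that("prognostic tables round-trip through CSV losslessly", {
  tab <- reference_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_prognostic_table(tab, path)
  tab2 <- read_prognostic_table(path)
  expect_equal(tab2$rows$criterion_id, tab$rows$criterion_id)
  expect_equal(tab2$rows$pc_presence, tab$rows$pc_presence)
  expect_equal(tab2$rows$informativeness, tab$rows$informativeness)
})
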