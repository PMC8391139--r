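# Norm table with integer-exact boundaries, used where tests probe strict
# inequalities at the threshold itself.
test_norms <- function() {
  norm_table(
    weight_norms = data.frame(min_height = c(130, 150), max_height = c(150, 170),
                              M = c(38, 44), delta_R = c(5, 5)),
    stange_norm = data.frame(min_age = 5, max_age = 25, value = 48),
    genchi_norm = data.frame(min_age = 5, max_age = 25, value = 24))
}

# A record on which every one of the nine criteria is absent (test_norms):
# height 140 -> M = 38, delta_R = 5; pvlc(140, 12) = 1.824.
neutral_record <- function(...) {
  rec <- list(subject_id = "s1", group = "control", age = 12,
              body_length = 140, body_weight = 38, chest_circumference = 75,
              vlc_actual = 1.6, biceps_tense = 23, biceps_rest = 22.5,
              stange = 30, genchi = 15, splits = 5, crab = 70,
              forward_bend = 5)
  utils::modifyList(rec, list(...))
}

# The exceedance counts recovered from the printed reference instrument
# (athletes d1 vs controls d2, both out of 15), frozen from the inversion
# oracle and used as the known ground truth in construction-based tests.
reference_counts <- function() {
  list(vlc_ratio_gt1 = c(12, 1), biceps_gt_6_7pct = c(10, 1),
       weight_deficit = c(9, 1), forward_bend_gt10s = c(14, 3),
       splits_lt0 = c(14, 3), stange_gt_norm = c(12, 5),
       genchi_gt_norm = c(12, 6), erisman_lt0 = c(14, 8),
       crab_lt60 = c(14, 9))
}

reference_counts_list <- function() {
  lapply(reference_counts(), function(d) gradation_counts(d[1], 15, d[2], 15))
}
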