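test_that("p-activity transform matches hand-computed values", {
  expect_equal(to_p_activity(1000), 6.0)
  expect_equal(to_p_activity(1), 9.0)
  # 9 - log10(1110) by hand calculator
  expect_equal(to_p_activity(1110), 5.9547, tolerance = 1e-4)
  expect_error(to_p_activity(0), class = "seltrend_data_error")
  expect_error(to_p_activity(-10), class = "seltrend_data_error")
})

test_that("cutoffs anchor to the least potent recognized-active drug", {
  drugs <- make_records(c("d1", "d2", "d3", "x"), "SERT",
                        c(1110, 25, 380, 5000), endpoint = "Ki",
                        drug_name = c("sibutramine", "drugB", "drugC", NA),
                        pharm_action_known = c(TRUE, TRUE, TRUE, NA))
  cut <- derive_cutoff(drugs, "SERT", "Ki")
  expect_equal(cut$cutoff_nM, 1110)
  expect_equal(cut$reference_drug, "sibutramine")
  # permutation invariance
  perm <- drugs[sample(nrow(drugs)), ]
  expect_equal(derive_cutoff(perm, "SERT", "Ki"), cut)
})

test_that("cutoff derivation respects endpoint, relation and annotation gates", {
  recs <- rbind(
    make_records("d1", "DAT", 1830, endpoint = "IC50",
                 drug_name = "modafinil", pharm_action_known = TRUE),
    make_records("d2", "DAT", 9000, endpoint = "IC50",
                 drug_name = "censored_drug", pharm_action_known = TRUE,
                 relation = ">"),
    make_records("d3", "DAT", 7000, endpoint = "IC50",
                 drug_name = "inactive_drug", pharm_action_known = FALSE))
  cut <- derive_cutoff(recs, "DAT", "IC50")
  expect_equal(cut$cutoff_nM, 1830)
  expect_equal(cut$reference_drug, "modafinil")
  # single qualifying drug anchors to itself
  single <- make_records("d9", "DAT", 444, endpoint = "Ki",
                         drug_name = "solo", pharm_action_known = TRUE)
  expect_equal(derive_cutoff(single, "DAT", "Ki")$cutoff_nM, 444)
  expect_error(derive_cutoff(recs, "DAT", "Ki"), "explicit cutoff",
               class = "seltrend_config_error")
})

test_that("cutoff table covers every pair and honours explicit overrides", {
  recs <- rbind(
    make_records("d1", "A", 1110, endpoint = "Ki", drug_name = "ra",
                 pharm_action_known = TRUE),
    make_records("d1", "A", 2090, endpoint = "IC50", drug_name = "ra",
                 pharm_action_known = TRUE),
    make_records("d2", "B", 1460, endpoint = "Ki", drug_name = "rb",
                 pharm_action_known = TRUE),
    make_records("d2", "B", 1830, endpoint = "IC50", drug_name = "rb",
                 pharm_action_known = TRUE))
  tab <- cutoff_table(recs, c("A", "B"))
  expect_equal(nrow(tab), 4L)
  expect_setequal(tab$cutoff_nM, c(1110, 2090, 1460, 1830))
  tab2 <- cutoff_table(recs, c("A", "B"),
                       explicit = list(A = list(IC50 = 500)))
  expect_equal(tab2$cutoff_nM[tab2$target_id == "A" &
                                tab2$endpoint == "IC50"], 500)
})

test_that("labels follow the inclusive cutoff with censoring overrides", {
  expect_equal(assign_label(500, "=", 1110)$label, 1L)
  expect_equal(assign_label(2000, "=", 1110)$label, 0L)
  # the reference drug itself labels active (inclusive comparison)
  at_cutoff <- assign_label(1110, "=", 1110)
  expect_equal(at_cutoff$label, 1L)
  # a ">" lower bound below the cutoff appears active but is not
  forced <- assign_label(1000, ">", 1110)
  expect_equal(forced$label, 0L)
  expect_true(forced$censored_override)
  # a "<" upper bound above the cutoff stays inactive but is flagged
  flagged <- assign_label(5000, "<", 1110)
  expect_equal(flagged$label, 0L)
  expect_true(flagged$censored_override)
  # "~" behaves like "="
  expect_equal(assign_label(500, "~", 1110), assign_label(500, "=", 1110))
  expect_error(assign_label(500, "=", -1), class = "seltrend_config_error")
})

test_that("label is non-increasing in value with one crossing at the cutoff", {
  cutoff <- 1234
  values <- sort(10^seq(0, 5, length.out = 200))
  labels <- assign_label(values, "=", cutoff)$label
  expect_true(all(diff(labels) <= 0))
  expect_equal(sum(abs(diff(labels))), 1L)
  crossing <- which(diff(labels) == -1L)
  expect_true(values[crossing] <= cutoff && values[crossing + 1L] > cutoff)
})

test_that("vectorized labelling equals the record-at-a-time loop", {
  set.seed(11)
  n <- 300
  values <- 10^runif(n, 0, 6)
  relations <- sample(c("=", ">", "<", ">=", "<=", "~"), n, replace = TRUE)
  cutoffs <- 10^runif(n, 2, 4)
  vec <- assign_label(values, relations, cutoffs)
  loop <- do.call(rbind, lapply(seq_len(n), function(i)
    assign_label(values[i], relations[i], cutoffs[i])))
  rownames(loop) <- NULL
  expect_equal(vec, loop)
})

test_that("per-record overrides force labels after the base rules", {
  recs <- make_records(c("c1", "c2"), "A", c(100, 100))
  cuts <- toy_cutoffs("A")
  over <- data.frame(compound_id = "c2", target_id = "A", endpoint = "IC50",
                     forced_label = 0)
  lab <- apply_labels(recs, cuts, overrides = over)
  expect_equal(lab$label, c(1L, 0L))
  expect_error(apply_labels(make_records("c", "Z", 1), cuts),
               class = "seltrend_config_error")
})
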