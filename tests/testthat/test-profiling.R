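test_that("median labels follow the sample median with 0.5 for ties", {
  expect_equal(aggregate_median(c(1, 1, 0)), 1)
  expect_equal(aggregate_median(c(0, 1)), 0.5)
  expect_equal(aggregate_median(1), 1)
  expect_error(aggregate_median(numeric(0)), class = "seltrend_data_error")
})

test_that("profile classification covers the four unambiguous cases", {
  expect_equal(classify_profile(1, 0), "A_selective")
  expect_equal(classify_profile(0, 1), "B_selective")
  expect_equal(classify_profile(1, 1), "both_active")
  expect_equal(classify_profile(0, 0), "both_inactive")
  expect_error(classify_profile(0.5, 1), class = "seltrend_data_error")
})

test_that("overlap matrix preserves label lists and assigns categories", {
  recs <- rbind(make_records("c1", "A", 100), make_records("c1", "B", 50000),
                make_records("c2", "A", c(100, 90, 80)),
                make_records("c3", "A", c(10, 50000)),
                make_records("c3", "B", 10))
  lab <- apply_labels(recs, toy_cutoffs())
  prof <- build_overlap_matrix(lab, c(A = "A", B = "B"))
  expect_equal(nrow(prof), 3L)
  c1 <- prof[prof$compound_id == "c1", ]
  expect_equal(c1$labels_A[[1]], 1L)
  expect_equal(c1$labels_B[[1]], 0L)
  expect_equal(c1$category, "A_selective")
  # one target only -> incomplete; contradictory labels -> ambiguous
  expect_equal(prof$category[prof$compound_id == "c2"], "incomplete")
  expect_equal(prof$median_A[prof$compound_id == "c3"], 0.5)
  expect_equal(prof$category[prof$compound_id == "c3"], "ambiguous")
  # records on unknown targets are ignored with a warning
  expect_warning(
    build_overlap_matrix(rbind(lab, transform(lab[1, ], target_id = "Z")),
                         c(A = "A", B = "B")), "ignored")
})

test_that("completeness/ambiguity filter splits and conserves profiles", {
  recs <- rbind(make_records(c("k1", "k1"), c("A", "B"), c(10, 10)),
                make_records(c("a1", "a1", "a1"), c("A", "A", "B"),
                             c(10, 50000, 10)),
                make_records("i1", "A", 10))
  prof <- build_overlap_matrix(apply_labels(recs, toy_cutoffs()),
                               c(A = "A", B = "B"))
  split <- filter_complete_unambiguous(prof)
  expect_equal(split$kept$compound_id, "k1")
  expect_setequal(split$removed$reason, c("ambiguous", "incomplete"))
  expect_equal(nrow(split$kept) + nrow(split$removed), nrow(prof))
})

test_that("incomplete-profile count matches the generator's truth record", {
  lib <- generate_library(library_config(n_scaffold_templates = 6,
                                         members_mean = 17,
                                         complete_fraction = 0.6,
                                         censor_fraction = 0, seed = 31))
  pair <- lib$records[lib$records$target_id %in% c("P31645", "Q01959"), ]
  pair <- pair[!grepl("^DRUG_ANCHOR", pair$compound_id), ]
  prof <- build_overlap_matrix(apply_labels(pair,
                                            toy_cutoffs(c("P31645",
                                                          "Q01959"))),
                               c(A = "P31645", B = "Q01959"))
  expect_equal(sum(prof$category == "incomplete"),
               lib$truth$counts$n_single_target)
})

test_that("overlap matrix equals a brute-force nested-loop oracle", {
  set.seed(5)
  for (rep in 1:3) {
    n_rec <- sample(5:12, 1)
    recs <- make_records(sample(paste0("c", 1:5), n_rec, replace = TRUE),
                         sample(c("A", "B"), n_rec, replace = TRUE),
                         10^runif(n_rec, 1, 5))
    lab <- apply_labels(recs, toy_cutoffs())
    prof <- build_overlap_matrix(lab, c(A = "A", B = "B"))
    oracle <- overlap_oracle(lab, c("A", "B"))
    expect_equal(prof$compound_id, names(oracle))
    for (i in seq_len(nrow(prof))) {
      o <- oracle[[prof$compound_id[i]]]
      expect_equal(sort(prof$labels_A[[i]]), sort(o$A$labels))
      expect_equal(sort(prof$pacts_B[[i]]), sort(o$B$pacts))
      expect_equal(prof$median_A[i], o$A$median)
      expect_equal(prof$median_B[i], o$B$median)
    }
  }
})

test_that("adding an active measurement never lowers a median label", {
  set.seed(9)
  for (i in 1:20) {
    labels <- sample(0:1, sample(1:7, 1), replace = TRUE)
    expect_gte(aggregate_median(c(labels, 1)), aggregate_median(labels))
  }
})

test_that("duplicated replicates give perfect intra correlation", {
  recs <- make_records(rep(paste0("c", 1:5), each = 2), "A",
                       rep(10^seq(1, 3, length.out = 5), each = 2))
  rep <- variability_analysis(recs)
  intra <- rep[rep$statistic == "intra_max_min_r2", ]
  expect_equal(intra$r2, 1.0)
  expect_equal(intra$n, 5L)
})

test_that("inter correlation is invariant to a constant endpoint shift", {
  p_ic50 <- c(5, 6, 7, 8)
  recs <- rbind(
    make_records(paste0("c", 1:4), "A", 10^(9 - p_ic50), endpoint = "IC50"),
    make_records(paste0("c", 1:4), "A", 10^(9 - (p_ic50 + 0.3)),
                 endpoint = "Ki"))
  rep <- suppressWarnings(variability_analysis(recs))  # no replicates here
  inter <- rep[rep$statistic == "inter_ic50_ki_r2", ]
  expect_equal(inter$r2, 1.0)
  expect_equal(inter$n, 4L)
})

test_that("variability statistics ignore record order and censored rows", {
  lib <- generate_library(library_config(n_scaffold_templates = 4,
                                         members_mean = 12, seed = 13))
  pair <- lib$records[lib$records$target_id %in% c("P31645", "Q01959"), ]
  a <- variability_analysis(pair)
  b <- variability_analysis(pair[rev(seq_len(nrow(pair))), ])
  expect_equal(a, b)
  censored <- pair[pair$relation == ">", ]
  expect_true(nrow(censored) > 0)
})

test_that("simulated max-min correlation matches the duplicate closed form", {
  # for duplicates: cor = (tau^2 + s^2/pi) / (tau^2 + s^2 (1 - 1/pi))
  tau <- 1.2; s <- 0.8
  closed <- ((tau^2 + s^2 / pi) / (tau^2 + s^2 * (1 - 1 / pi)))^2
  sim <- simulate_maxmin_r2(s, tau, n_pairs = 20000, seed = 3)
  expect_equal(sim, closed, tolerance = 0.03)
})
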