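test_that("Murcko frameworks strip side chains and keep carbonyl linkers", {
  expect_equal(murcko_scaffold("Cc1ccccc1"), "c1ccccc1")
  # N-alkyl cathinones with acyclic side chains reduce to benzene
  expect_equal(murcko_scaffold("CC(NC)C(=O)c1ccc(C)cc1"), "c1ccccc1")
  # pyrrolidinyl cathinone keeps both rings joined by the carbonyl linker,
  # including the exocyclic oxygen
  scaff <- murcko_scaffold("CCCC(N1CCCC1)C(=O)c1ccccc1")
  expect_equal(scaff, canonical_smiles("O=C(c1ccccc1)CN1CCCC1"))
  # acyclic molecules give the empty sentinel
  expect_equal(murcko_scaffold("CCCCCC"), "")
  expect_error(murcko_scaffold("xx((("), class = "seltrend_data_error")
})

test_that("framework extraction is idempotent", {
  smis <- c("Cc1ccccc1", "CCCC(N1CCCC1)C(=O)c1ccccc1",
            "COC(=O)C(c1ccccc1)C1CCCCN1", "c1ccc2c(c1)OCO2",
            "CCN(CC)CCc1ccc2c(c1)cccc2")
  once <- murcko_scaffold(smis)
  twice <- murcko_scaffold(once[nzchar(once)])
  expect_equal(twice, once[nzchar(once)])
})

test_that("scaffold clusters partition the compound set deterministically", {
  compounds <- data.frame(
    compound_id = paste0("c", 1:4),
    smiles = c("Cc1ccccc1", "CCc1ccccc1", "CCCc1ccccc1", "CCC1CCCCN1"),
    stringsAsFactors = FALSE)
  cl <- cluster_by_scaffold(compounds)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$size, c(3L, 1L))  # descending size
  expect_equal(sum(cl$size), nrow(compounds))
  expect_setequal(unlist(cl$member_ids), compounds$compound_id)
  expect_true(cl$is_singleton[2])
})

test_that("clustering recovers the generator's scaffold templates", {
  lib <- generate_library(library_config(n_scaffold_templates = 8,
                                         members_mean = 6, seed = 21))
  cmp <- unique(lib$truth$compounds[, c("compound_id", "smiles")])
  cl <- cluster_by_scaffold(cmp)
  expect_equal(nrow(cl), 8L)
  expect_equal(sum(cl$size), nrow(cmp))
  # each cluster's members share one template in the truth record
  tmpl <- lib$truth$compounds$template_id[
    match(unlist(cl$member_ids), lib$truth$compounds$compound_id)]
  groups <- rep(seq_len(nrow(cl)), cl$size)
  expect_true(all(tapply(tmpl, groups, function(x) length(unique(x))) == 1))
})

test_that("scaffold scoring applies the 0.6/0.4 trend thresholds", {
  prof <- data.frame(compound_id = paste0("c", 1:4),
                     median_A = c(1, 1, 1, 0), median_B = c(0, 0, 0, 0),
                     category = c("A_selective", "A_selective",
                                  "A_selective", "both_inactive"),
                     stringsAsFactors = FALSE)
  clusters <- data.frame(scaffold_smiles = "c1ccccc1", size = 4L,
                         stringsAsFactors = FALSE)
  clusters$member_ids <- I(list(paste0("c", 1:4)))
  scored <- score_and_classify(clusters, prof, min_size = 3)
  expect_equal(scored$mean_A, 0.75)
  expect_equal(scored$mean_B, 0)
  expect_equal(scored$classification, "A_selective")
  expect_true(scored$reported)
  # boundary cases from the trend rule
  expect_equal(seltrend:::classify_scaffold(0.6, 0.6), "promiscuous_active")
  expect_equal(seltrend:::classify_scaffold(0.5, 0.9), "no_trend")
  expect_equal(seltrend:::classify_scaffold(0.9, 0.5), "no_trend")
  expect_equal(seltrend:::classify_scaffold(0.3, 0.35), "inactive")
  expect_equal(seltrend:::classify_scaffold(0.2, 0.95), "B_selective")
})

test_that("raising the hi threshold only moves clusters out of trends", {
  set.seed(17)
  means <- data.frame(a = runif(200), b = runif(200))
  for (hi in c(0.6, 0.7, 0.8)) {
    now <- seltrend:::classify_scaffold(means$a, means$b, hi = hi, lo = 0.4)
    harder <- seltrend:::classify_scaffold(means$a, means$b, hi = hi + 0.1,
                                           lo = 0.4)
    trended <- c("A_selective", "B_selective", "promiscuous_active")
    expect_true(all(!(now %in% trended) | harder %in% c(now, "no_trend") |
                      harder == "inactive"))
    # nothing enters a selective/promiscuous class by raising hi
    expect_true(all(harder %in% trended == FALSE |
                      now %in% trended))
  }
})

test_that("members without usable profiles are skipped with adjusted counts", {
  prof <- data.frame(compound_id = c("c1", "c2"),
                     median_A = c(1, NA), median_B = c(0, NA),
                     category = c("A_selective", "incomplete"),
                     stringsAsFactors = FALSE)
  clusters <- data.frame(scaffold_smiles = "s", size = 3L,
                         stringsAsFactors = FALSE)
  clusters$member_ids <- I(list(c("c1", "c2", "c_unknown")))
  expect_warning(scored <- score_and_classify(clusters, prof, min_size = 1),
                 "skipped")
  expect_equal(scored$n_scored, 1L)
  expect_equal(scored$mean_A, 1)
})

test_that("substructure search finds cathinones and honours containment", {
  set <- cathinone_set()
  hits <- substructure_filter(set, cathinone_query())
  expect_equal(nrow(hits), nrow(set))
  expect_true(all(hits$match_count >= 1))
  # benzene hits are a superset of benzoylethanamine hits
  benzene_hits <- substructure_filter(set, "c1ccccc1")
  expect_true(all(hits$compound_id %in% benzene_hits$compound_id))
  # aliphatic molecules never match an aromatic query
  aliphatic <- data.frame(compound_id = c("a1", "a2"),
                          smiles = c("CCCCCC", "C1CCCCC1"),
                          stringsAsFactors = FALSE)
  expect_equal(nrow(substructure_filter(aliphatic, "c1ccccc1")), 0L)
  # a query always matches itself
  self <- data.frame(compound_id = "q", smiles = "O=C(c1ccccc1)C(C)N",
                     stringsAsFactors = FALSE)
  expect_equal(substructure_filter(self, cathinone_query())$compound_id, "q")
  expect_error(substructure_filter(self, ""), class = "seltrend_config_error")
})

test_that("hERG flagging uses a strict 10 uM bound and respects censoring", {
  expect_true(flag_herg(make_records("c1", "herg", 9000))[["c1"]])
  expect_false(flag_herg(make_records("c1", "herg", 10000))[["c1"]])
  expect_false(flag_herg(make_records("c1", "herg", 5000,
                                      relation = ">"))[["c1"]])
  expect_true(flag_herg(make_records("c1", "herg", 5000,
                                     relation = "<"))[["c1"]])
  # any qualifying record flags the compound; Ki and IC50 pool
  recs <- rbind(make_records("c1", "herg", 50000),
                make_records("c1", "herg", 800, endpoint = "Ki"))
  expect_true(flag_herg(recs)[["c1"]])
  expect_length(flag_herg(recs[0, ]), 0L)
})

test_that("drug distribution counts clusters, singletons and classes", {
  clusters <- data.frame(scaffold_smiles = c("s1", "s2", "s3"),
                         size = c(3L, 1L, 2L),
                         classification = c("A_selective", "no_trend",
                                            "promiscuous_active"),
                         stringsAsFactors = FALSE)
  clusters$member_ids <- I(list(c("c1", "c2", "c3"), "c4", c("c5", "c6")))
  drugs <- data.frame(compound_id = c("c2", "c4"),
                      drug_name = c("drugA", "drugB"),
                      stringsAsFactors = FALSE)
  rep <- drug_distribution(clusters, drugs)
  expect_equal(rep$summary$n_drug_clusters, 2L)
  expect_equal(rep$summary$n_drug_singletons, 1L)
  expect_equal(rep$per_cluster$n_drugs, c(1L, 1L, 0L))
  expect_equal(unname(rep$summary$drugs_by_classification[["A_selective"]]),
               1L)
  none <- drug_distribution(clusters, drugs[0, ])
  expect_equal(none$summary$n_drug_clusters, 0L)
})

test_that("planted drug placement matches the generator truth", {
  lib <- generate_library(library_config(n_scaffold_templates = 5,
                                         members_mean = 10,
                                         drug_fraction = 0.15, seed = 77))
  truth_drugs <- lib$truth$compounds[lib$truth$compounds$is_drug, ]
  drugs <- unique(lib$records[!is.na(lib$records$drug_name) &
                                !grepl("^anchor", lib$records$drug_name),
                              c("compound_id", "drug_name")])
  expect_setequal(drugs$compound_id, truth_drugs$compound_id)
})
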