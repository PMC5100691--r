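# Shared fixtures, built in code at test time.

make_records <- function(compound_id, target_id, value_nM, relation = "=",
                         endpoint = "IC50", smiles = "c1ccccc1",
                         drug_name = NA_character_,
                         pharm_action_known = NA) {
  n <- max(lengths(list(compound_id, target_id, value_nM)))
  data.frame(compound_id = rep_len(compound_id, n),
             smiles = rep_len(smiles, n),
             target_id = rep_len(target_id, n),
             endpoint = rep_len(endpoint, n),
             relation = rep_len(relation, n),
             value_nM = rep_len(value_nM, n),
             p_activity = 9 - log10(rep_len(value_nM, n)),
             document_id = NA_character_,
             drug_name = rep_len(drug_name, n),
             pharm_action_known = rep_len(pharm_action_known, n),
             stringsAsFactors = FALSE)
}

write_records_csv <- function(records, path = tempfile(fileext = ".csv")) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  path
}

# small two-target cutoff table for unit tests
toy_cutoffs <- function(targets = c("A", "B"), cutoff = 1000) {
  expand_cut <- expand.grid(target_id = targets, endpoint = c("IC50", "Ki"),
                            stringsAsFactors = FALSE)
  expand_cut$cutoff_nM <- cutoff
  expand_cut$reference_drug <- "toy"
  expand_cut
}

# independent brute-force overlap-matrix oracle: per compound and target,
# collect labels/p-activities by explicit nested loops and take the median
overlap_oracle <- function(records, targets) {
  ids <- sort(unique(records$compound_id))
  out <- lapply(ids, function(id) {
    per_target <- lapply(targets, function(tg) {
      labels <- numeric(0); pacts <- numeric(0)
      for (i in seq_len(nrow(records))) {
        if (records$compound_id[i] == id && records$target_id[i] == tg) {
          labels <- c(labels, records$label[i])
          pacts <- c(pacts, records$p_activity[i])
        }
      }
      list(labels = labels, pacts = pacts,
           median = if (length(labels)) median(labels) else NA_real_)
    })
    names(per_target) <- c("A", "B")
    per_target
  })
  names(out) <- ids
  out
}
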