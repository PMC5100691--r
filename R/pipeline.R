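# Orchestration of the two analysis strands: global scaffold profiling and
# substructure-based SAR extraction with Hansch regression.

#' Configuration for the profiling strand
#'
#' All thresholds of the profiling strand surface here, with the reference
#' defaults: per-(target, endpoint) drug-anchored cutoffs (explicit values
#' optional), scaffold trend thresholds hi = 0.6 / lo = 0.4 with at least 10
#' members for trend reporting, and the 10 uM hERG flagging threshold.
#'
#' @param bioactivities path to a bioactivity CSV, or a ready record data
#'   frame.
#' @param targets named vector `c(A = ..., B = ...)` of the profiled pair.
#' @param herg_target_id target id of hERG-channel records in the input.
#' @param cutoffs optional explicit cutoffs `list(<target> =
#'   list(IC50 = ..., Ki = ...))`; missing entries are drug-anchored.
#' @param overrides optional per-record label override data frame
#'   (compound_id, target_id, endpoint, forced_label).
#' @param hi,lo,min_size scaffold trend thresholds.
#' @param herg_threshold_nM hERG liability threshold.
#' @param strip_stereo strip stereochemistry before scaffold extraction.
#' @param inter_method inter-endpoint variability pairing, see
#'   [variability_analysis()].
#' @param out_dir output directory for report files, or `NULL` to skip
#'   writing.
#' @return a `profile_config` list.
#' @export
profile_config <- function(bioactivities,
                           targets = c(A = "P31645", B = "Q01959"),
                           herg_target_id = "Q12809", cutoffs = NULL,
                           overrides = NULL, hi = 0.6, lo = 0.4,
                           min_size = 10, herg_threshold_nM = 1e4,
                           strip_stereo = FALSE,
                           inter_method = "median", out_dir = NULL) {
  cfg <- as.list(environment())
  if (!(hi > lo)) stop_config("hi must exceed lo")
  class(cfg) <- "profile_config"
  cfg
}

stage_count <- function(name, n_in, n_out, reasons = NULL) {
  list(stage = name, n_in = n_in, n_out = n_out, n_rejected = n_in - n_out,
       reasons = as.list(reasons))
}

#' Run the profiling strand
#'
#' Executes ingest, labelling, overlap-matrix construction, completeness and
#' ambiguity filtering, selectivity classification, scaffold clustering and
#' trend scoring, hERG flagging, drug-distribution analysis and variability
#' statistics. Every filtering stage logs input, output and rejection counts
#' (input = output + rejected always holds). With `out_dir` set, writes the
#' median-label matrix, scaffold report, variability report and a JSON run
#' manifest; outputs are deterministic given identical inputs and config.
#'
#' @param config a [profile_config()].
#' @return report list (invisible when writing files): profiles, kept,
#'   clusters, herg_flags, drug report, variability, stage log, cutoff
#'   table.
#' @export
run_profile <- function(config) {
  stopifnot(inherits(config, "profile_config"))
  cfg <- config
  stages <- list()
  log_stage <- function(...) stages[[length(stages) + 1L]] <<- stage_count(...)

  if (is.character(cfg$bioactivities)) {
    ingest <- read_bioactivity_table(cfg$bioactivities)
    records <- ingest$records
    log_stage("ingest", ingest$n_read, nrow(records),
              if (nrow(ingest$rejected)) table(ingest$rejected$reason))
  } else {
    records <- cfg$bioactivities
    log_stage("ingest", nrow(records), nrow(records))
  }
  if (nrow(records) == 0L) {
    report <- list(n_compounds = 0L, profiles = NULL, kept = NULL,
                   clusters = NULL, stages = stages,
                   message = "0 compounds")
    if (!is.null(cfg$out_dir)) write_profile_reports(report, cfg)
    return(invisible(report))
  }

  pair_records <- records[records$target_id %in% cfg$targets, , drop = FALSE]
  herg_records <- records[records$target_id == cfg$herg_target_id, ,
                          drop = FALSE]
  log_stage("target_split", nrow(records),
            nrow(pair_records) + nrow(herg_records),
            c(other_targets = nrow(records) - nrow(pair_records) -
                nrow(herg_records)))

  cutoffs <- cutoff_table(pair_records, unname(unlist(cfg$targets)),
                          explicit = cfg$cutoffs)
  labelled <- apply_labels(pair_records, cutoffs, overrides = cfg$overrides)
  profiles <- build_overlap_matrix(labelled, cfg$targets)
  split <- filter_complete_unambiguous(profiles)
  log_stage("completeness_filter", nrow(profiles), nrow(split$kept),
            if (nrow(split$removed)) table(split$removed$reason))

  compounds <- unique(labelled[, c("compound_id", "smiles")])
  compounds <- compounds[compounds$compound_id %in%
                           split$kept$compound_id, , drop = FALSE]
  clusters <- cluster_by_scaffold(compounds, strip_stereo = cfg$strip_stereo)
  clusters <- score_and_classify(clusters, split$kept, hi = cfg$hi,
                                 lo = cfg$lo, min_size = cfg$min_size)
  herg_flags <- flag_herg(herg_records, threshold_nM = cfg$herg_threshold_nM)
  clusters$n_herg_flagged <- vapply(clusters$member_ids, function(ids)
    sum(herg_flags[intersect(ids, names(herg_flags))]), numeric(1))
  drugs <- unique(records[!is.na(records$drug_name) &
                            nzchar(records$drug_name),
                          c("compound_id", "drug_name")])
  drug_report <- drug_distribution(clusters, drugs)
  variability <- variability_analysis(pair_records,
                                      inter_method = cfg$inter_method)

  report <- list(
    n_compounds = nrow(profiles), profiles = profiles, kept = split$kept,
    removed = split$removed,
    category_counts = table(split$kept$category),
    clusters = clusters, herg_flags = herg_flags,
    drug_report = drug_report, variability = variability,
    cutoffs = cutoffs, stages = stages,
    params = cfg[c("hi", "lo", "min_size", "herg_threshold_nM",
                   "strip_stereo", "inter_method")])
  if (!is.null(cfg$out_dir)) write_profile_reports(report, cfg)
  invisible(report)
}

write_profile_reports <- function(report, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(cfg$out_dir, f)
  if (!is.null(report$kept) && nrow(report$kept))
    write_matrix(profile_matrix(report$kept), path("median_label_matrix.csv"))
  if (!is.null(report$clusters)) {
    flat <- report$clusters
    flat$member_ids <- vapply(flat$member_ids, toString, character(1))
    utils::write.csv(flat, path("scaffold_report.csv"), row.names = FALSE)
  }
  if (!is.null(report$variability) && nrow(report$variability))
    utils::write.csv(report$variability, path("variability_report.csv"),
                     row.names = FALSE)
  manifest <- list(params = report$params, cutoffs = report$cutoffs,
                   stages = report$stages,
                   category_counts = as.list(report$category_counts),
                   n_compounds = report$n_compounds,
                   message = report$message)
  jsonlite::write_json(manifest, path("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, null = "null")
  invisible(cfg$out_dir)
}

#' Configuration for the SAR strand
#'
#' @param input an SD file path (activity property tags expected), a series
#'   CSV path, or a ready series data frame as produced by
#'   [generate_sar_series()] / [cathinone_set()].
#' @param query substructure SMARTS defining the series, default the
#'   benzoylethanamine (cathinone) query.
#' @param targets named vector `c(A = ..., B = ...)`; the activity response
#'   is the B-target pIC50 and the selectivity response
#'   `log10(IC50_A / IC50_B)`.
#' @param alpha backward-elimination significance level.
#' @param response_aggregation how multiple B-target IC50 values per
#'   compound collapse: `"lowest"` (most potent, default) or `"median"`.
#' @param constants substituent constants table.
#' @param out_dir output directory, or `NULL`.
#' @return a `sar_config` list.
#' @export
sar_config <- function(input, query = cathinone_query(),
                       targets = c(A = "P31645", B = "Q01959"),
                       alpha = 0.05,
                       response_aggregation = c("lowest", "median"),
                       constants = NULL, out_dir = NULL) {
  cfg <- as.list(environment())
  cfg$response_aggregation <- match.arg(response_aggregation)
  class(cfg) <- "sar_config"
  cfg
}

read_sar_input <- function(cfg) {
  inp <- cfg$input
  if (is.data.frame(inp)) return(inp)
  stopifnot(is.character(inp), length(inp) == 1L)
  if (grepl("\\.sdf?$", inp, ignore.case = TRUE)) {
    sd <- read_compound_sdf(inp)
    out <- sd$compounds
    tagval <- function(tag, default = NA) {
      if (tag %in% names(sd$properties)) sd$properties[[tag]] else default
    }
    out$ic50_A_nM <- as.numeric(tagval(paste0("IC50_", cfg$targets[["A"]],
                                              "_nM")))
    out$relation_A <- as.character(tagval(paste0("RELATION_",
                                                 cfg$targets[["A"]]), "="))
    out$ic50_B_nM <- as.numeric(tagval(paste0("IC50_", cfg$targets[["B"]],
                                              "_nM")))
    out$relation_B <- as.character(tagval(paste0("RELATION_",
                                                 cfg$targets[["B"]]), "="))
    out
  } else {
    utils::read.csv(inp, stringsAsFactors = FALSE)
  }
}

# collapse multiple B-target measurements per compound
aggregate_response <- function(values, method) {
  switch(method, lowest = min(values), median = stats::median(values))
}

#' Run the SAR strand
#'
#' Substructure-filters the input series, assembles the Hansch descriptor
#' matrix, and fits two backward-eliminated regressions: B-target pIC50
#' (activity) and log selectivity. Compounds with censored responses are
#' excluded from the respective regression and listed in the exclusion
#' report; if several B-target IC50 values exist per compound the lowest
#' (most potent) one is used by default.
#'
#' @param config a [sar_config()].
#' @return report list: filtered series, descriptor matrix, the two fitted
#'   `hansch_model`s, exclusion report, stage log.
#' @export
run_sar <- function(config) {
  stopifnot(inherits(config, "sar_config"))
  cfg <- config
  stages <- list()
  log_stage <- function(...) stages[[length(stages) + 1L]] <<- stage_count(...)

  series <- read_sar_input(cfg)
  n0 <- nrow(series)
  hits <- substructure_filter(series, cfg$query)
  log_stage("substructure_filter", n0, nrow(hits),
            c(no_match = n0 - nrow(hits)))
  if (!all(c("ca_sub", "n_sub", "aryl_subs") %in% names(hits)))
    stop_data(paste0("series lacks R-group annotations (ca_sub, n_sub, ",
                     "aryl_subs) required for descriptor assembly"))
  if (cfg$response_aggregation == "lowest" &&
      anyDuplicated(hits$compound_id)) {
    keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$compound_id),
                          function(ii)
                            ii[which.min(hits$ic50_B_nM[ii])]))
    hits <- hits[sort(keep), , drop = FALSE]
  }
  constants <- cfg$constants %||% substituent_constants()
  X <- build_descriptor_matrix(hits, constants = constants)
  excluded_desc <- attr(X, "excluded")
  log_stage("descriptor_matrix", nrow(hits), nrow(X),
            if (nrow(excluded_desc)) table(excluded_desc$reason))
  hits_X <- hits[match(X$compound_id, hits$compound_id), , drop = FALSE]

  # activity response: B-target pIC50, exact values only
  act_ok <- hits_X$relation_B == "="
  y_act <- to_p_activity(hits_X$ic50_B_nM[act_ok])
  log_stage("activity_response", nrow(X), sum(act_ok),
            c(censored_B = sum(!act_ok)))
  # selectivity response: both sides exact
  log_sel <- selectivity_response(hits_X$ic50_A_nM, hits_X$ic50_B_nM,
                                  hits_X$relation_A, hits_X$relation_B)
  sel_ok <- !is.na(log_sel)
  log_stage("selectivity_response", nrow(X), sum(sel_ok),
            c(censored = sum(!sel_ok)))
  exclusions <- rbind(
    data.frame(compound_id = X$compound_id[!act_ok],
               response = rep("activity", sum(!act_ok)),
               reason = rep("censored_B_value", sum(!act_ok)),
               stringsAsFactors = FALSE),
    data.frame(compound_id = X$compound_id[!sel_ok],
               response = rep("selectivity", sum(!sel_ok)),
               reason = rep("censored_value", sum(!sel_ok)),
               stringsAsFactors = FALSE))

  desc <- X[HANSCH_DESCRIPTORS]
  # drop zero-variance and exactly collinear (aliased) descriptors before
  # elimination; they carry no independent information in the series at hand
  fit_with_guard <- function(D, y, label) {
    if (length(y) < ncol(D) + 2L)
      stop_data("%s regression: %d usable rows for %d descriptors",
                label, length(y), ncol(D))
    D <- D[, vapply(D, stats::var, numeric(1)) > 0, drop = FALSE]
    repeat {
      cf <- stats::coef(stats::lm(.y ~ ., data = cbind(D, .y = y)))
      aliased <- intersect(names(cf)[is.na(cf)], names(D))
      if (!length(aliased)) break
      message(label, " regression: dropping collinear descriptor(s) ",
              toString(aliased))
      D <- D[, setdiff(names(D), aliased), drop = FALSE]
    }
    backward_eliminate(D, y, alpha = cfg$alpha)
  }
  activity_model <- fit_with_guard(desc[act_ok, , drop = FALSE], y_act,
                                   "activity")
  selectivity_model <- fit_with_guard(desc[sel_ok, , drop = FALSE],
                                      log_sel[sel_ok], "selectivity")

  report <- list(series = hits_X, descriptors = X,
                 activity_model = activity_model,
                 selectivity_model = selectivity_model,
                 exclusions = exclusions, stages = stages,
                 params = cfg[c("query", "alpha", "response_aggregation")])
  if (!is.null(cfg$out_dir)) write_sar_reports(report, cfg)
  invisible(report)
}

model_as_list <- function(m) {
  list(coefficients = m$coefficients, n = m$n, r2 = m$r2,
       residual_sd = m$residual_sd, alpha = m$alpha,
       elimination_trace = m$elimination_trace)
}

write_sar_reports <- function(report, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(cfg$out_dir, f)
  utils::write.csv(report$descriptors, path("descriptor_matrix.csv"),
                   row.names = FALSE)
  utils::write.csv(report$exclusions, path("exclusions.csv"),
                   row.names = FALSE)
  for (which in c("activity", "selectivity")) {
    m <- report[[paste0(which, "_model")]]
    jsonlite::write_json(model_as_list(m),
                         path(paste0(which, "_model.json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    txt <- utils::capture.output(print(m))
    writeLines(txt, path(paste0(which, "_model.txt")))
  }
  manifest <- list(params = report$params, stages = report$stages)
  jsonlite::write_json(manifest, path("run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, null = "null")
  invisible(cfg$out_dir)
}

#' Generate a synthetic library and write it to disk
#'
#' Convenience wrapper for the `simulate` pipeline stage: generates a
#' library from a [library_config()] and writes the record CSV plus the
#' truth record JSON next to it.
#'
#' @param config a [library_config()].
#' @param out_dir output directory.
#' @return list with the paths written.
#' @export
run_simulate <- function(config, out_dir) {
  lib <- generate_library(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records_path <- file.path(out_dir, "bioactivities.csv")
  truth_path <- file.path(out_dir, "truth.json")
  write_bioactivity_table(lib$records, records_path)
  jsonlite::write_json(lib$truth, truth_path, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows", force = TRUE)
  list(records = records_path, truth = truth_path)
}

#' Load a YAML run configuration
#'
#' Reads a YAML file whose keys mirror the arguments of [profile_config()]
#' or [sar_config()] (notably `cutoffs.<target>.<endpoint>` overrides).
#'
#' @param path YAML file path.
#' @return named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: %s", path)
  yaml::read_yaml(path)
}
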