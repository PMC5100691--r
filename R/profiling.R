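# Compound-by-target overlap matrix, median label aggregation, completeness
# and ambiguity filtering, selectivity classification, and measurement
# variability statistics.

PROFILE_CATEGORIES <- c("both_active", "A_selective", "B_selective",
                        "both_inactive", "ambiguous", "incomplete")

#' Median activity label
#'
#' Standard sample median of a list of 0/1 labels. Even-length lists with as
#' many 0s as 1s yield exactly 0.5, marking contradictory evidence.
#'
#' @param labels non-empty numeric vector of 0/1 labels.
#' @return the median label (0, 0.5 or 1).
#' @export
aggregate_median <- function(labels) {
  if (!length(labels)) stop_data("empty label list")
  stats::median(labels)
}

#' Classify a two-target selectivity profile
#'
#' @param median_A,median_B unambiguous median labels (0 or 1) for the two
#'   targets; vectorized.
#' @return character vector: both_active, A_selective, B_selective or
#'   both_inactive.
#' @export
classify_profile <- function(median_A, median_B) {
  if (!all(median_A %in% c(0, 1)) || !all(median_B %in% c(0, 1)))
    stop_data("medians must be 0 or 1; filter ambiguous profiles first")
  lut <- c("both_inactive", "B_selective", "A_selective", "both_active")
  lut[1 + median_B + 2 * median_A]
}

#' Build the compound-by-target overlap matrix
#'
#' Pivots labelled records into one profile per compound, preserving the full
#' list of activity labels and precise p-activities per target and retaining
#' their median for classification. Records for targets outside `targets`
#' are ignored with a warning. With exactly two targets each profile gets a
#' selectivity category; compounds lacking measurements on either target are
#' `incomplete`, compounds with a median label of 0.5 on either target are
#' `ambiguous`.
#'
#' @param records bioactivity record data frame; if it lacks a `label`
#'   column, `cutoffs` must be supplied and labels are assigned first.
#' @param targets character vector of two target ids, conventionally
#'   `c(A = ..., B = ...)` (A first).
#' @param cutoffs optional cutoff table for labelling, see [cutoff_table()].
#' @return data frame of class `compound_profiles`: compound_id, per-target
#'   replicate counts `n_A`/`n_B`, `median_A`/`median_B`, list columns
#'   `labels_A`, `labels_B`, `pacts_A`, `pacts_B`, and `category`. The
#'   target ids backing A and B are kept in `attr(, "targets")`.
#' @export
build_overlap_matrix <- function(records, targets, cutoffs = NULL) {
  stopifnot(length(targets) == 2L)
  if (is.null(records$label)) {
    if (is.null(cutoffs)) stop_config("records are unlabelled; pass cutoffs")
    records <- apply_labels(records, cutoffs)
  }
  unknown <- !(records$target_id %in% targets)
  if (any(unknown)) {
    warning(sum(unknown), " record(s) for targets outside the profile pair ",
            "ignored: ", toString(unique(records$target_id[unknown])))
    records <- records[!unknown, , drop = FALSE]
  }
  ids <- sort(unique(records$compound_id))
  per_target <- function(tg) {
    sel <- records$target_id == tg
    list(labels = split(records$label[sel], records$compound_id[sel]),
         pacts = split(records$p_activity[sel], records$compound_id[sel]))
  }
  a <- per_target(targets[[1]])
  b <- per_target(targets[[2]])
  grab <- function(lst, id) if (id %in% names(lst)) lst[[id]] else numeric(0)
  labels_A <- lapply(ids, grab, lst = a$labels)
  labels_B <- lapply(ids, grab, lst = b$labels)
  pacts_A <- lapply(ids, grab, lst = a$pacts)
  pacts_B <- lapply(ids, grab, lst = b$pacts)
  med <- function(x) if (length(x)) aggregate_median(x) else NA_real_
  median_A <- vapply(labels_A, med, numeric(1))
  median_B <- vapply(labels_B, med, numeric(1))
  n_A <- lengths(labels_A)
  n_B <- lengths(labels_B)
  category <- ifelse(n_A == 0L | n_B == 0L, "incomplete",
                     ifelse(median_A == 0.5 | median_B == 0.5, "ambiguous",
                            NA_character_))
  plain <- is.na(category)
  category[plain] <- classify_profile(median_A[plain], median_B[plain])
  profiles <- data.frame(compound_id = ids, n_A = n_A, n_B = n_B,
                         median_A = median_A, median_B = median_B,
                         category = category, stringsAsFactors = FALSE)
  profiles$labels_A <- I(labels_A)
  profiles$labels_B <- I(labels_B)
  profiles$pacts_A <- I(pacts_A)
  profiles$pacts_B <- I(pacts_B)
  attr(profiles, "targets") <- stats::setNames(unname(unlist(targets)),
                                               c("A", "B"))
  class(profiles) <- c("compound_profiles", class(profiles))
  profiles
}

#' Filter profiles for completeness and unambiguity
#'
#' Keeps profiles with measurements on both targets and neither median label
#' equal to 0.5; the complement is returned with its removal reason.
#'
#' @param profiles output of [build_overlap_matrix()].
#' @return list with `kept` and `removed` (the latter with a `reason`
#'   column: incomplete or ambiguous).
#' @export
filter_complete_unambiguous <- function(profiles) {
  drop <- profiles$category %in% c("incomplete", "ambiguous")
  removed <- profiles[drop, , drop = FALSE]
  removed$reason <- removed$category
  list(kept = profiles[!drop, , drop = FALSE], removed = removed)
}

#' Intra- and inter-endpoint measurement variability
#'
#' Two reproducibility statistics computed from exact-value measurements
#' (relations "=" and "~"):
#' * intra: per (target, endpoint), the squared Pearson correlation between
#'   the maximum and minimum replicate p-activity over compounds measured at
#'   least twice — how well multiple measurements of the same compound agree;
#' * inter: per target, the squared Pearson correlation between per-compound
#'   median pIC50 and median pKi over compounds with both endpoints — how
#'   well the two endpoints agree.
#'
#' @param records bioactivity record data frame.
#' @param inter_method `"median"` pairs one median per endpoint per compound
#'   (default); `"all_pairs"` correlates every pIC50/pKi cross pair.
#' @return data frame: target_id, endpoint (`NA` for inter rows), statistic,
#'   r2, n. Statistics with fewer than 2 qualifying compounds are absent
#'   (with a warning).
#' @export
variability_analysis <- function(records,
                                 inter_method = c("median", "all_pairs")) {
  inter_method <- match.arg(inter_method)
  pts <- records[records$relation %in% c("=", "~"), , drop = FALSE]
  out <- list()
  for (tg in sort(unique(pts$target_id))) {
    for (ep in ENDPOINTS) {
      sel <- pts$target_id == tg & pts$endpoint == ep
      reps <- split(pts$p_activity[sel], pts$compound_id[sel])
      reps <- reps[lengths(reps) >= 2L]
      if (length(reps) >= 2L) {
        hi <- vapply(reps, max, numeric(1))
        lo <- vapply(reps, min, numeric(1))
        out[[length(out) + 1L]] <- data.frame(
          target_id = tg, endpoint = ep, statistic = "intra_max_min_r2",
          r2 = stats::cor(hi, lo)^2, n = length(reps),
          stringsAsFactors = FALSE)
      } else if (any(sel)) {
        warning("fewer than 2 replicated compounds for ", tg, "/", ep,
                "; intra statistic absent")
      }
    }
    sel <- pts$target_id == tg
    ic50 <- split(pts$p_activity[sel & pts$endpoint == "IC50"],
                  pts$compound_id[sel & pts$endpoint == "IC50"])
    ki <- split(pts$p_activity[sel & pts$endpoint == "Ki"],
                pts$compound_id[sel & pts$endpoint == "Ki"])
    both <- intersect(names(ic50), names(ki))
    if (inter_method == "median") {
      if (length(both) >= 2L) {
        x <- vapply(ic50[both], stats::median, numeric(1))
        y <- vapply(ki[both], stats::median, numeric(1))
        out[[length(out) + 1L]] <- data.frame(
          target_id = tg, endpoint = NA_character_,
          statistic = "inter_ic50_ki_r2", r2 = stats::cor(x, y)^2,
          n = length(both), stringsAsFactors = FALSE)
      } else if (length(both)) {
        warning("fewer than 2 dual-endpoint compounds for ", tg,
                "; inter statistic absent")
      }
    } else {
      pairs <- do.call(rbind, lapply(both, function(id)
        expand.grid(x = ic50[[id]], y = ki[[id]])))
      if (!is.null(pairs) && nrow(pairs) >= 2L) {
        out[[length(out) + 1L]] <- data.frame(
          target_id = tg, endpoint = NA_character_,
          statistic = "inter_ic50_ki_r2_all_pairs",
          r2 = stats::cor(pairs$x, pairs$y)^2, n = nrow(pairs),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(target_id = character(), endpoint = character(),
                      statistic = character(), r2 = numeric(), n = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Median-label matrix for heat-map style output
#'
#' @param profiles output of [build_overlap_matrix()].
#' @return data frame compound_id plus one median-label column per target,
#'   ready for [write_matrix()].
#' @export
profile_matrix <- function(profiles) {
  tg <- attr(profiles, "targets")
  out <- data.frame(compound_id = profiles$compound_id,
                    A = profiles$median_A, B = profiles$median_B,
                    stringsAsFactors = FALSE)
  names(out)[2:3] <- tg
  out
}
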