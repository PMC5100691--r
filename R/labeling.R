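# Potency transformation, drug-anchored activity cutoffs, and binary labels.

#' Negative log molar activity
#'
#' Converts a nanomolar potency to its negative decadic log molar value
#' (pIC50/pKi): `9 - log10(value_nM)`. 1000 nM gives 6.0.
#'
#' @param value_nM positive potency in nanomolar.
#' @return numeric p-activity.
#' @export
to_p_activity <- function(value_nM) {
  if (any(!is.finite(value_nM) | value_nM <= 0))
    stop_data("value_nM must be positive and finite")
  9 - log10(value_nM)
}

#' Derive a drug-anchored activity cutoff
#'
#' The activity cutoff for a (target, endpoint) pair is anchored to marketed
#' drugs: among records carrying a drug annotation that is recognized as
#' pharmacologically active on the target (exact-value measurements only),
#' the *least potent* drug (maximum `value_nM`) sets the cutoff, so that
#' every recognized-active drug labels active. For the transporter pair this
#' reproduces the sibutramine (hSERT) and modafinil (hDAT) anchors.
#'
#' @param records bioactivity record data frame.
#' @param target_id,endpoint the pair to anchor.
#' @return list with `cutoff_nM` and `reference_drug`.
#' @export
derive_cutoff <- function(records, target_id, endpoint) {
  q <- records$target_id == target_id & records$endpoint == endpoint &
    records$relation == "=" & !is.na(records$drug_name) &
    nzchar(records$drug_name) & records$pharm_action_known %in% TRUE
  if (!any(q))
    stop_config(paste0("no recognized-active drug record for target %s ",
                       "endpoint %s; supply an explicit cutoff"),
                target_id, endpoint)
  i <- which(q)[which.max(records$value_nM[q])]
  list(cutoff_nM = records$value_nM[i], reference_drug = records$drug_name[i])
}

#' Build the per-(target, endpoint) cutoff table
#'
#' Cutoffs are never pooled across targets or endpoints. Explicit cutoffs
#' (e.g. from a YAML config, keys `cutoffs.<target>.<endpoint>`) override the
#' drug-anchored derivation.
#'
#' @param records bioactivity record data frame.
#' @param targets character vector of target ids.
#' @param endpoints endpoints to cover, default IC50 and Ki.
#' @param explicit optional nested list `explicit[[target]][[endpoint]]` of
#'   cutoff values in nM.
#' @return data frame: target_id, endpoint, cutoff_nM, reference_drug.
#' @export
cutoff_table <- function(records, targets, endpoints = ENDPOINTS,
                         explicit = NULL) {
  grid <- expand.grid(target_id = targets, endpoint = endpoints,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    tg <- grid$target_id[i]; ep <- grid$endpoint[i]
    exp_val <- explicit[[tg]][[ep]]
    if (!is.null(exp_val)) {
      if (!is.numeric(exp_val) || exp_val <= 0)
        stop_config("explicit cutoff for %s/%s must be a positive number",
                    tg, ep)
      data.frame(target_id = tg, endpoint = ep, cutoff_nM = exp_val,
                 reference_drug = "explicit", stringsAsFactors = FALSE)
    } else {
      cut <- derive_cutoff(records, tg, ep)
      data.frame(target_id = tg, endpoint = ep, cutoff_nM = cut$cutoff_nM,
                 reference_drug = cut$reference_drug, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Assign binary activity labels with censoring rules
#'
#' Base rule: `value_nM <= cutoff_nM` labels active (1), otherwise inactive
#' (0). The comparison is cutoff-inclusive so the anchoring reference drug
#' itself labels active. Censored records override the base rule: a ">" or
#' ">=" lower bound at or below the cutoff *appears* active but only states
#' the potency is worse than the value, so it is forced inactive and flagged;
#' a "<" or "<=" upper bound above the cutoff is labelled inactive but
#' flagged for manual review (the precise bound cannot settle the call). "~"
#' is treated as "=".
#'
#' @param value_nM numeric vector of potencies (nM).
#' @param relation relation signs, same length (recycled if scalar).
#' @param cutoff_nM positive cutoff (scalar or same length).
#' @return data frame with `label` (0/1 integer) and `censored_override`
#'   (logical, `TRUE` when the relation sign forced or clouded the label).
#' @export
assign_label <- function(value_nM, relation = "=", cutoff_nM) {
  if (any(cutoff_nM <= 0)) stop_config("cutoff_nM must be positive")
  n <- length(value_nM)
  relation <- rep_len(relation, n)
  cutoff_nM <- rep_len(cutoff_nM, n)
  if (!all(relation %in% RELATIONS))
    stop_data("unknown relation sign(s): %s",
              toString(unique(relation[!(relation %in% RELATIONS)])))
  label <- as.integer(value_nM <= cutoff_nM)
  override <- rep(FALSE, n)
  lower_bound <- relation %in% c(">", ">=") & value_nM <= cutoff_nM
  label[lower_bound] <- 0L
  override[lower_bound] <- TRUE
  upper_bound <- relation %in% c("<", "<=") & value_nM > cutoff_nM
  label[upper_bound] <- 0L
  override[upper_bound] <- TRUE
  data.frame(label = label, censored_override = override)
}

#' Label a record set against a cutoff table
#'
#' Joins records with their (target, endpoint) cutoff and applies
#' [assign_label()]. Optional per-record overrides (manual review decisions)
#' force individual labels afterwards.
#'
#' @param records bioactivity record data frame.
#' @param cutoffs cutoff table from [cutoff_table()].
#' @param overrides optional data frame (compound_id, target_id, endpoint,
#'   forced_label).
#' @return `records` with `label` and `censored_override` columns appended.
#' @export
apply_labels <- function(records, cutoffs, overrides = NULL) {
  key <- paste(records$target_id, records$endpoint)
  ckey <- paste(cutoffs$target_id, cutoffs$endpoint)
  idx <- match(key, ckey)
  if (anyNA(idx))
    stop_config("no cutoff for (target, endpoint) pair(s): %s",
                toString(unique(key[is.na(idx)])))
  lab <- assign_label(records$value_nM, records$relation,
                      cutoffs$cutoff_nM[idx])
  records$label <- lab$label
  records$censored_override <- lab$censored_override
  if (!is.null(overrides) && nrow(overrides)) {
    okey <- paste(overrides$compound_id, overrides$target_id,
                  overrides$endpoint)
    rkey <- paste(records$compound_id, records$target_id, records$endpoint)
    hit <- match(rkey, okey)
    forced <- !is.na(hit)
    records$label[forced] <- as.integer(overrides$forced_label[hit[forced]])
  }
  records
}
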