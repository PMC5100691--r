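# Bemis-Murcko scaffolds, scaffold clustering and selectivity scoring,
# substructure searches, hERG liability flagging, drug distribution.

SCAFFOLD_CLASSES <- c("A_selective", "B_selective", "promiscuous_active",
                      "inactive", "no_trend")

#' Default benzoylethanamine (cathinone) substructure query
#'
#' SMARTS for the benzoyl-carbon-amine motif defining the cathinone series:
#' a benzene-bound carbonyl whose alpha carbon carries a trivalent nitrogen.
#' The exact required substitution pattern is an assumption and the query is
#' overridable wherever it is consumed.
#'
#' @return a single SMARTS string.
#' @export
cathinone_query <- function() "O=C(c1ccccc1)[#6][NX3]"

# Murcko framework atom indices of one parsed molecule: the 2-core of the
# bond graph (rings plus ring-linking paths; side chains prune away) plus
# atoms attached to it by a multiple bond (retains e.g. exocyclic carbonyl
# oxygens on linkers).
murcko_atom_indices <- function(sdf) {
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ChemmineR::atomblock(sdf))
  if (is.null(dim(bb)) || nrow(bb) == 0L) return(integer(0))
  g <- igraph::graph_from_edgelist(cbind(bb[, 1], bb[, 2]), directed = FALSE)
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  core <- which(igraph::coreness(g) >= 2)
  if (!length(core)) return(integer(0))
  multi <- bb[bb[, 3] >= 2, , drop = FALSE]
  extra <- c(multi[multi[, 1] %in% core & !(multi[, 2] %in% core), 2],
             multi[multi[, 2] %in% core & !(multi[, 1] %in% core), 1])
  sort(unique(c(core, extra)))
}

strip_stereo_smiles <- function(smiles) {
  gsub("[/\\\\]", "", gsub("@", "", smiles))
}

#' Bemis-Murcko scaffold of a molecule
#'
#' Extracts the ring-plus-linker framework: all ring systems and the linker
#' atoms connecting them, with side chains removed and atoms double-bonded
#' to the framework retained (so a carbonyl linker keeps its oxygen). The
#' framework is returned as canonical SMILES; acyclic molecules map to the
#' empty-string sentinel. Stereo descriptors present in the input are kept
#' by default — frameworks of different stereoisomers can therefore differ —
#' and `strip_stereo = TRUE` removes them for coarser clustering.
#'
#' @param smiles character vector of SMILES.
#' @param strip_stereo drop stereochemistry before framework extraction.
#' @return character vector of canonical scaffold SMILES ("" for acyclic
#'   molecules).
#' @export
murcko_scaffold <- function(smiles, strip_stereo = FALSE) {
  smiles <- as.character(smiles)
  if (strip_stereo) smiles <- strip_stereo_smiles(smiles)
  uni <- unique(smiles)
  scaff <- vapply(uni, function(smi) {
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smi, "q"))[[1]]),
      error = function(e) NULL)
    if (is.null(sdf)) stop_data("unparseable SMILES: %s", smi)
    keep <- murcko_atom_indices(sdf)
    if (!length(keep)) return("")
    sub_sdf <- ChemmineR::atomsubset(sdf, atomrows = keep)
    tf <- tempfile(fileext = ".sdf")
    on.exit(unlink(tf), add = TRUE)
    ChemmineR::write.SDF(ChemmineR::SDFset(SDFlist = list(sub_sdf),
                                           ID = "scaffold"), tf)
    can <- tryCatch(
      ChemmineOB::convertFormat("SDF", "CAN",
                                paste(readLines(tf), collapse = "\n")),
      error = function(e) NA_character_)
    if (is.na(can)) stop_data("scaffold canonicalization failed for %s", smi)
    sub("[ \t\n].*$", "", trimws(can))
  }, character(1))
  unname(scaff[match(smiles, uni)])
}

#' Cluster compounds by Murcko scaffold
#'
#' Groups a compound set by shared framework. Clusters partition the set;
#' acyclic compounds (empty scaffold) form their own cluster. Output order
#' is deterministic: descending size, then scaffold SMILES.
#'
#' @param compounds data frame with `compound_id` and `smiles` columns.
#' @param strip_stereo passed to [murcko_scaffold()].
#' @return data frame of class `scaffold_clusters`: scaffold_smiles, size,
#'   `member_ids` (list column), `is_singleton`.
#' @export
cluster_by_scaffold <- function(compounds, strip_stereo = FALSE) {
  stopifnot(all(c("compound_id", "smiles") %in% names(compounds)))
  scaff <- murcko_scaffold(compounds$smiles, strip_stereo = strip_stereo)
  groups <- split(compounds$compound_id, scaff)
  clusters <- data.frame(scaffold_smiles = names(groups),
                         size = lengths(groups), stringsAsFactors = FALSE)
  clusters$member_ids <- I(unname(groups))
  ord <- order(-clusters$size, clusters$scaffold_smiles)
  clusters <- clusters[ord, , drop = FALSE]
  rownames(clusters) <- NULL
  clusters$is_singleton <- clusters$size == 1L
  class(clusters) <- c("scaffold_clusters", class(clusters))
  clusters
}

classify_scaffold <- function(mean_A, mean_B, hi = 0.6, lo = 0.4) {
  ifelse(is.na(mean_A) | is.na(mean_B), NA_character_,
  ifelse(mean_A >= hi & mean_B <= lo, "A_selective",
  ifelse(mean_B >= hi & mean_A <= lo, "B_selective",
  ifelse(mean_A >= hi & mean_B >= hi, "promiscuous_active",
  ifelse(mean_A <= lo & mean_B <= lo, "inactive", "no_trend")))))
}

#' Score scaffold clusters and classify selectivity trends
#'
#' Each cluster gets, per target, the arithmetic mean of its members' median
#' activity labels (each compound counted once). A mean at or above `hi` on
#' one target with at most `lo` on the other marks a selective scaffold
#' trend; both at or above `hi` is promiscuous-active, both at or below `lo`
#' inactive, anything else shows no clear trend. Clusters smaller than
#' `min_size` keep their scores but are excluded from trend reporting
#' (`reported = FALSE`). Members without a usable median label (unprofiled,
#' incomplete or ambiguous) are skipped with a warning and the scored member
#' count adjusted.
#'
#' @param clusters output of [cluster_by_scaffold()].
#' @param profiles output of [build_overlap_matrix()] (or its kept subset).
#' @param hi,lo trend thresholds on the mean label, defaults 0.6 / 0.4.
#' @param min_size minimum members for trend reporting, default 10.
#' @param label_source `"median"` (default) averages member median labels;
#'   `"raw"` averages every raw label of every member instead.
#' @return `clusters` with columns mean_A, mean_B, n_scored, classification,
#'   reported.
#' @export
score_and_classify <- function(clusters, profiles, hi = 0.6, lo = 0.4,
                               min_size = 10,
                               label_source = c("median", "raw")) {
  if (!(hi > lo)) stop_config("hi must exceed lo")
  label_source <- match.arg(label_source)
  usable <- profiles$category %in% c("both_active", "A_selective",
                                     "B_selective", "both_inactive")
  n_missing <- 0L
  stats_for <- function(members) {
    i <- match(members, profiles$compound_id)
    ok <- !is.na(i)
    ok[ok] <- usable[i[ok]]
    n_missing <<- n_missing + sum(!ok)
    i <- i[ok]
    if (!length(i)) return(c(NA_real_, NA_real_, 0L))
    if (label_source == "median") {
      c(mean(profiles$median_A[i]), mean(profiles$median_B[i]), length(i))
    } else {
      c(mean(unlist(profiles$labels_A[i])),
        mean(unlist(profiles$labels_B[i])), length(i))
    }
  }
  m <- t(vapply(clusters$member_ids, stats_for, numeric(3)))
  clusters$mean_A <- m[, 1]
  clusters$mean_B <- m[, 2]
  clusters$n_scored <- as.integer(m[, 3])
  clusters$classification <- classify_scaffold(m[, 1], m[, 2], hi, lo)
  clusters$reported <- clusters$size >= min_size
  if (n_missing > 0)
    warning(n_missing, " cluster member(s) without a usable median label ",
            "skipped in scaffold scoring")
  clusters
}

#' Filter compounds by substructure
#'
#' Subgraph search with a SMARTS (or plain SMILES) pattern; compounds with
#' at least one match are returned with their match count.
#'
#' @param compounds data frame with `compound_id` and `smiles`.
#' @param query SMARTS pattern, e.g. [cathinone_query()].
#' @param name optional query name recorded on the result.
#' @return subset of `compounds` with a `match_count` column; the query name
#'   is kept in `attr(, "query")`.
#' @export
substructure_filter <- function(compounds, query = cathinone_query(),
                                name = NULL) {
  if (!is.character(query) || length(query) != 1L || !nzchar(query))
    stop_config("query must be a single non-empty SMARTS string")
  conv <- smiles_to_sdfset(compounds$smiles, compounds$compound_id)
  if (any(!conv$ok))
    stop_data("unparseable SMILES for compound(s): %s",
              toString(compounds$compound_id[!conv$ok]))
  counts <- tryCatch(
    suppressWarnings(ChemmineR::smartsSearchOB(conv$sdf, query,
                                               uniqueMatches = FALSE)),
    error = function(e) stop_config("unparseable SMARTS query: %s", query))
  hits <- which(counts > 0)
  out <- compounds[hits, , drop = FALSE]
  out$match_count <- as.integer(counts[hits])
  rownames(out) <- NULL
  attr(out, "query") <- c(name = name %||% "query", pattern = query)
  out
}

#' Flag potential hERG blockers
#'
#' A compound is flagged when any of its hERG-channel records reports a
#' potency strictly below the threshold (default 10 uM) with a relation that
#' actually bounds the potency from above ("=", "~", "<", "<="); ">"-censored
#' records never trigger the flag. IC50 and Ki records are pooled.
#'
#' @param records bioactivity records measured on the hERG channel (any
#'   number of compounds).
#' @param threshold_nM flagging threshold, default 10000 nM.
#' @return named logical vector, one entry per compound present in
#'   `records`; zero-length input gives a zero-length result.
#' @export
flag_herg <- function(records, threshold_nM = 10000) {
  if (is.null(records) || nrow(records) == 0L)
    return(stats::setNames(logical(0), character(0)))
  trig <- records$relation %in% c("=", "~", "<", "<=") &
    records$value_nM < threshold_nM
  vapply(split(trig, records$compound_id), any, logical(1))
}

#' Distribution of annotated drugs over scaffold clusters
#'
#' @param clusters output of [cluster_by_scaffold()] (optionally scored).
#' @param drugs data frame with `compound_id` and `drug_name` for annotated
#'   drugs.
#' @return list with `per_cluster` (drug count, drug names, singleton flag
#'   per cluster) and `summary` (number of drug-containing clusters, of
#'   drug-containing singletons, and drugs per classification when
#'   available).
#' @export
drug_distribution <- function(clusters, drugs) {
  drug_names_for <- function(members) {
    nm <- unique(drugs$drug_name[drugs$compound_id %in% members])
    nm[!is.na(nm) & nzchar(nm)]
  }
  names_list <- lapply(clusters$member_ids, drug_names_for)
  per_cluster <- data.frame(scaffold_smiles = clusters$scaffold_smiles,
                            size = clusters$size,
                            n_drugs = lengths(names_list),
                            drug_names = vapply(names_list, toString,
                                                character(1)),
                            is_singleton = clusters$size == 1L,
                            stringsAsFactors = FALSE)
  has_drug <- per_cluster$n_drugs > 0
  by_class <- NULL
  if (!is.null(clusters$classification)) {
    by_class <- tapply(per_cluster$n_drugs[has_drug],
                       clusters$classification[has_drug], sum)
    by_class <- by_class[!is.na(by_class)]
  }
  list(per_cluster = per_cluster,
       summary = list(n_drug_clusters = sum(has_drug),
                      n_drug_singletons = sum(has_drug &
                                                per_cluster$is_singleton),
                      drugs_by_classification = by_class))
}
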