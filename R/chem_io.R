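# Shared record model and file I/O for the selectivity-profiling pipeline.
#
# A bioactivity record is one measurement of one compound against one target:
# compound_id, smiles, target_id, endpoint (IC50/Ki), relation (=, >, <, >=,
# <=, ~), value_nM (> 0), derived p_activity = 9 - log10(value_nM), plus
# optional document_id, drug_name and pharm_action_known (whether the drug is
# recognized as pharmacologically active on that target).

ENDPOINTS <- c("IC50", "Ki")
RELATIONS <- c("=", ">", "<", ">=", "<=", "~")

#' Default column mapping for bioactivity tables
#'
#' Maps the logical record fields to the column names of a delimited input
#' file. Override individual entries to ingest files with different headers.
#'
#' @param ... named overrides, e.g. `value_nM = "standard_value"`.
#' @return named character vector of logical field -> file column.
#' @export
bioactivity_schema <- function(...) {
  schema <- c(compound_id = "compound_id", smiles = "smiles",
              target_id = "target_id", endpoint = "endpoint",
              relation = "relation", value_nM = "value_nM",
              document_id = "document_id", drug_name = "drug_name",
              pharm_action_known = "pharm_action_known", unit = "unit")
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(schema))
    if (length(bad)) stop_config("unknown schema field(s): %s", toString(bad))
    schema[names(dots)] <- dots
  }
  schema
}

REQUIRED_FIELDS <- c("compound_id", "smiles", "target_id", "endpoint",
                     "relation", "value_nM")

#' Read a ChEMBL-style bioactivity table
#'
#' Reads a delimited text table of potency measurements, validates each row,
#' and returns clean records together with a rejection report. Values are
#' fixed to nanomolar: if the file carries a unit column, rows in any other
#' unit are rejected rather than converted. Rows with missing or unparseable
#' potency or SMILES, non-positive values, values above `max_value_nM`
#' (guards against data errors), unknown endpoints/relations or empty ids are
#' dropped and counted. SMILES are canonicalized at ingestion; compound
#' identity is `compound_id`, not structure.
#'
#' @param path file path of a delimited text table.
#' @param schema column mapping, see [bioactivity_schema()].
#' @param sep field separator, default comma.
#' @param validate_smiles parse and canonicalize SMILES (set `FALSE` to skip
#'   structure validation for speed on pre-validated inputs).
#' @param max_value_nM ingestion guard; records above it are rejected.
#' @return list with `records` (data frame, one row per accepted measurement,
#'   `p_activity` populated), `rejected` (data frame of dropped rows with a
#'   `reason` column) and `n_read`.
#' @export
read_bioactivity_table <- function(path, schema = bioactivity_schema(),
                                   sep = ",", validate_smiles = TRUE,
                                   max_value_nM = 1e8) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE)
  missing_cols <- setdiff(unname(schema[REQUIRED_FIELDS]), names(df))
  if (length(missing_cols))
    stop_config("required column(s) missing from %s: %s", path,
                toString(missing_cols))
  if (nrow(df) == 0L) {
    warning("empty bioactivity table: ", path)
    return(list(records = empty_records(), rejected = empty_rejections(),
                n_read = 0L))
  }
  raw <- data.frame(
    compound_id = as.character(df[[schema[["compound_id"]]]]),
    smiles = as.character(df[[schema[["smiles"]]]]),
    target_id = as.character(df[[schema[["target_id"]]]]),
    endpoint = as.character(df[[schema[["endpoint"]]]]),
    relation = as.character(df[[schema[["relation"]]]]),
    value_raw = as.character(df[[schema[["value_nM"]]]]),
    stringsAsFactors = FALSE)
  opt <- function(field, default) {
    col <- schema[[field]]
    if (!is.null(col) && col %in% names(df)) df[[col]] else default
  }
  raw$document_id <- as.character(opt("document_id", NA_character_))
  raw$drug_name <- as.character(opt("drug_name", NA_character_))
  raw$pharm_action_known <- as.logical(opt("pharm_action_known", NA))
  raw$unit <- as.character(opt("unit", NA_character_))

  value <- suppressWarnings(as.numeric(raw$value_raw))
  reason <- rep(NA_character_, nrow(raw))
  flag <- function(cond, why) reason[is.na(reason) & cond] <<- why
  flag(!nzchar(raw$compound_id) | is.na(raw$compound_id) |
         !nzchar(raw$target_id) | is.na(raw$target_id), "missing_id")
  flag(!is.na(raw$unit) & !(raw$unit %in% c("nM", "nanomolar")),
       "non_nanomolar_unit")
  flag(!(raw$endpoint %in% ENDPOINTS), "unknown_endpoint")
  flag(!(raw$relation %in% RELATIONS), "unknown_relation")
  flag(is.na(value), "unspecified_value")
  flag(!is.na(value) & value <= 0, "nonpositive_value")
  flag(!is.na(value) & value > max_value_nM, "value_above_limit")
  flag(is.na(raw$smiles) | !nzchar(raw$smiles), "missing_smiles")
  if (validate_smiles) {
    todo <- is.na(reason)
    can <- canonical_smiles(raw$smiles[todo])
    bad <- todo
    bad[todo] <- is.na(can)
    flag(bad, "invalid_smiles")
    raw$smiles[todo & !bad] <- can[!is.na(can)]
  }

  keep <- is.na(reason)
  records <- data.frame(
    compound_id = raw$compound_id[keep], smiles = raw$smiles[keep],
    target_id = raw$target_id[keep], endpoint = raw$endpoint[keep],
    relation = raw$relation[keep], value_nM = value[keep],
    p_activity = to_p_activity(value[keep]),
    document_id = raw$document_id[keep], drug_name = raw$drug_name[keep],
    pharm_action_known = raw$pharm_action_known[keep],
    stringsAsFactors = FALSE)
  rejected <- cbind(raw[!keep, c("compound_id", "target_id", "endpoint",
                                 "value_raw")],
                    reason = reason[!keep])
  rownames(records) <- rownames(rejected) <- NULL
  list(records = records, rejected = rejected, n_read = nrow(raw))
}

empty_records <- function() {
  data.frame(compound_id = character(), smiles = character(),
             target_id = character(), endpoint = character(),
             relation = character(), value_nM = numeric(),
             p_activity = numeric(), document_id = character(),
             drug_name = character(), pharm_action_known = logical(),
             stringsAsFactors = FALSE)
}

empty_rejections <- function() {
  data.frame(compound_id = character(), target_id = character(),
             endpoint = character(), value_raw = character(),
             reason = character(), stringsAsFactors = FALSE)
}

#' Write bioactivity records to a delimited file
#'
#' @param records record data frame as returned by [read_bioactivity_table()].
#' @param path output path (CSV).
#' @return the path, invisibly.
#' @export
write_bioactivity_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an SD file of compound structures
#'
#' Reads a V2000 SD file, skipping unparseable molecule blocks with a warning,
#' and returns compound ids (molecule titles), canonical SMILES and the
#' property tags carried in the data blocks. Property tag names are preserved
#' verbatim; `tag_map` optionally renames them (logical name -> file tag) for
#' files whose activity tags follow a different convention.
#'
#' @param path SD file path.
#' @param tag_map optional named character vector renaming property tags.
#' @return list with `compounds` (data frame: compound_id, smiles),
#'   `properties` (data frame of property tags, one row per compound),
#'   `sdf` (the `SDFset`) and `n_skipped`.
#' @export
read_compound_sdf <- function(path, tag_map = NULL) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  records <- parse_sd_records(readLines(path, warn = FALSE))
  smiles <- vapply(records, function(rec) {
    tryCatch({
      out <- suppressWarnings(
        ChemmineOB::convertFormat("SDF", "CAN",
                                  paste0(paste(rec$molblock,
                                               collapse = "\n"),
                                         "\n$$$$\n")))
      out <- sub("[ \t\n].*$", "", trimws(out))
      if (!nzchar(out)) NA_character_ else out
    }, error = function(e) NA_character_)
  }, character(1))
  ok <- !is.na(smiles)
  n_skipped <- sum(!ok)
  if (n_skipped > 0)
    warning(n_skipped, " unparseable molecule block(s) skipped in ", path)
  if (!any(ok)) {
    warning("no parseable molecules in ", path)
    return(list(compounds = data.frame(compound_id = character(),
                                       smiles = character(),
                                       stringsAsFactors = FALSE),
                properties = data.frame(), sdf = NULL,
                n_skipped = n_skipped))
  }
  records <- records[ok]
  smiles <- smiles[ok]
  ids <- vapply(records, function(rec) trimws(rec$molblock[1]), character(1))
  if (any(!nzchar(ids)) || anyDuplicated(ids))
    ids <- make.unique(ifelse(nzchar(ids), ids,
                              paste0("CMP", seq_along(ids))), sep = "_")
  tags <- unique(unlist(lapply(records, function(rec) names(rec$tags))))
  properties <- as.data.frame(
    lapply(stats::setNames(tags, tags),
           function(tg) vapply(records, function(rec) {
             if (tg %in% names(rec$tags)) rec$tags[[tg]]
             else NA_character_
           }, character(1))),
    optional = TRUE, stringsAsFactors = FALSE)
  if (nrow(properties) == 0 && length(ids))
    properties <- data.frame(row.names = seq_along(ids))
  if (!is.null(tag_map)) {
    hit <- match(unname(tag_map), names(properties))
    names(properties)[hit[!is.na(hit)]] <- names(tag_map)[!is.na(hit)]
  }
  rownames(properties) <- NULL
  # molblock-only SDFset (datablocks re-parsed above; a bare ">" property
  # value would otherwise derail the stock datablock parser)
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(unlist(lapply(records, function(rec)
    c(rec$molblock, "$$$$"))), tf)
  sdf <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(tf)),
                  error = function(e) NULL)
  list(compounds = data.frame(compound_id = ids, smiles = smiles,
                              stringsAsFactors = FALSE),
       properties = properties, sdf = sdf, n_skipped = n_skipped)
}

# Split raw SD file lines into records of molblock lines plus property
# tags. Tag headers are lines of the form "> <NAME>"; values run to the
# next blank line and may legitimately start with ">" (relation signs), so
# only proper tag headers advance the parser.
parse_sd_records <- function(lines) {
  if (!length(lines)) return(list())
  ends <- which(trimws(lines) == "$$$$")
  if (!length(ends) || ends[length(ends)] < length(lines))
    ends <- c(ends, length(lines) + 1L)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  records <- list()
  for (k in seq_along(starts)) {
    block <- lines[starts[k]:min(ends[k] - 1L, length(lines))]
    if (!length(block) || all(!nzchar(trimws(block)))) next
    m_end <- which(grepl("^M\\s+END", block))
    if (length(m_end)) {
      mol <- block[1:m_end[1]]
      rest <- if (m_end[1] < length(block))
        block[(m_end[1] + 1L):length(block)] else character(0)
    } else {
      mol <- block
      rest <- character(0)
    }
    tag_idx <- grep("^>\\s*<.+>", rest)
    tags <- list()
    for (j in seq_along(tag_idx)) {
      name <- sub("^>\\s*<([^>]+)>.*$", "\\1", rest[tag_idx[j]])
      from <- tag_idx[j] + 1L
      to <- if (j < length(tag_idx)) tag_idx[j + 1L] - 1L else length(rest)
      vals <- rest[seq(from, length.out = max(to - from + 1L, 0L))]
      vals <- vals[cumsum(!nzchar(trimws(vals))) == 0]  # stop at blank
      tags[[name]] <- paste(vals, collapse = "\n")
    }
    records[[length(records) + 1L]] <- list(molblock = mol, tags = tags)
  }
  records
}

#' Write compound structures to an SD file
#'
#' @param compounds data frame with `compound_id` and `smiles` columns.
#' @param path output SD file path.
#' @param properties optional data frame (one row per compound) written as
#'   property tags.
#' @return the path, invisibly.
#' @export
write_compound_sdf <- function(compounds, path, properties = NULL) {
  conv <- smiles_to_sdfset(compounds$smiles, compounds$compound_id)
  if (any(!conv$ok))
    stop_data("unparseable SMILES for compound(s): %s",
              toString(compounds$compound_id[!conv$ok]))
  sdf <- conv$sdf
  if (!is.null(properties)) {
    stopifnot(nrow(properties) == nrow(compounds))
    ChemmineR::datablock(sdf) <- lapply(seq_len(nrow(properties)), function(i) {
      vals <- vapply(properties[i, , drop = FALSE], as.character, character(1))
      stats::setNames(vals, names(properties))
    })
  }
  ChemmineR::write.SDF(sdf, path)
  invisible(path)
}

#' Write a compound-by-target label matrix
#'
#' One row per compound (sorted by `compound_id` for deterministic output),
#' one column per target, cells holding median activity labels.
#'
#' @param matrix data frame with a `compound_id` column plus one numeric
#'   column per target.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  if (is.null(matrix) || nrow(matrix) == 0L) stop_data("empty matrix")
  matrix <- matrix[order(matrix$compound_id), , drop = FALSE]
  utils::write.csv(matrix, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a matrix written by [write_matrix()]
#' @param path CSV path.
#' @return data frame.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop_data("file not found: %s", path)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
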