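`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(msg, ...) {
  stop(structure(class = c("seltrend_config_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_data <- function(msg, ...) {
  stop(structure(class = c("seltrend_data_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so generators never leak global state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to Open Babel canonical form, one molecule at a time so a
#' single malformed string cannot silently truncate a batch. Unparseable
#' entries come back as `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
canonical_smiles <- function(smiles) {
  smiles <- as.character(smiles)
  uni <- unique(smiles[!is.na(smiles) & nzchar(smiles)])
  can <- vapply(uni, function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s)),
      error = function(e) NA_character_)
    if (is.na(out) || !nzchar(trimws(out))) return(NA_character_)
    sub("[ \t\n].*$", "", trimws(out))
  }, character(1))
  out <- can[match(smiles, uni)]
  names(out) <- NULL
  out
}

# Robust SMILES -> SDFset conversion. Returns list(sdf = SDFset, ok = logical)
# where ok marks which inputs parsed; molecule titles are set to `ids` so
# downstream property tables have stable row names.
smiles_to_sdfset <- function(smiles, ids = NULL) {
  n <- length(smiles)
  if (is.null(ids)) ids <- sprintf("M%04d", seq_len(n))
  stopifnot(length(ids) == n, !anyDuplicated(ids))
  mols <- vector("list", n)
  for (i in seq_len(n)) {
    smi <- stats::setNames(smiles[i], ids[i])
    mols[[i]] <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(smi)[[1]]),
      error = function(e) NULL)
  }
  ok <- !vapply(mols, is.null, logical(1))
  if (!any(ok)) return(list(sdf = NULL, ok = ok))
  sdf <- ChemmineR::SDFset(SDFlist = mols[ok], ID = ids[ok])
  list(sdf = sdf, ok = ok)
}

# first molblock line of each SDF record (molecule title)
sdfset_ids <- function(sdf) unname(ChemmineR::sdfid(sdf))
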