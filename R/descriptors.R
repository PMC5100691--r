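# Whole-molecule descriptor backend: group-contribution van der Waals
# volume, plus logP and molar refractivity from Open Babel.

# Atomic vdW volume contributions (A^3) for the group-contribution scheme
# V = sum(atoms) - 5.92 * N_bonds - 14.7 * N_aromatic_rings
#     - 3.8 * N_nonaromatic_rings
# (bond and ring terms absorb sphere overlap).
VDW_ATOM_CONTRIB <- c(H = 7.24, C = 20.58, N = 15.60, O = 14.71, F = 13.31,
                      Cl = 22.45, Br = 26.52, I = 32.52, P = 24.43,
                      S = 24.43, Si = 38.79, Se = 28.73, Te = 36.62,
                      As = 26.52, B = 40.48)

count_hydrogens <- function(formula) {
  m <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  h <- grep("^H[0-9]*$", m, value = TRUE)
  if (!length(h)) return(0L)
  n <- sub("^H", "", h[1])
  if (nzchar(n)) as.integer(n) else 1L
}

# Ring census from one SDF molecule: total SSSR-rank ring count via the
# cycle rank of the bond graph, aromatic count via a bond-order heuristic
# (5-6 ring whose carbons each carry a multiple bond; N/O/S pass as lone-pair
# donors). Kekulized SDF input is assumed, as Open Babel writes it.
ring_census <- function(sdf) {
  bb <- ChemmineR::bondblock(sdf)
  ab <- ChemmineR::atomblock(sdf)
  n_atoms <- nrow(ab)
  n_bonds <- if (is.null(dim(bb))) 0L else nrow(bb)
  if (n_bonds == 0L) return(list(total = 0L, aromatic = 0L, n_bonds = 0L))
  g <- igraph::graph_from_edgelist(cbind(bb[, 1], bb[, 2]), directed = FALSE)
  if (igraph::vcount(g) < n_atoms)
    g <- igraph::add_vertices(g, n_atoms - igraph::vcount(g))
  n_comp <- igraph::components(g)$no
  total <- n_bonds - n_atoms + n_comp
  if (total <= 0L) return(list(total = 0L, aromatic = 0L, n_bonds = n_bonds))
  sym <- sub("_.*$", "", rownames(ab))
  multi <- rep(FALSE, n_atoms)
  hit <- bb[, 3] >= 2
  multi[bb[hit, 1]] <- TRUE
  multi[bb[hit, 2]] <- TRUE
  ring_list <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = FALSE)),
    error = function(e) list())
  idx_of <- function(nm) match(nm, rownames(ab))
  aromatic <- 0L
  for (ring in ring_list) {
    k <- length(ring)
    if (k < 5L || k > 6L) next
    ii <- idx_of(ring)
    ok <- all(ifelse(sym[ii] == "C", multi[ii], sym[ii] %in% c("N", "O", "S")))
    if (ok) aromatic <- aromatic + 1L
  }
  aromatic <- min(aromatic, total)
  list(total = total, aromatic = aromatic, n_bonds = n_bonds)
}

#' Group-contribution van der Waals volume
#'
#' Fast approximate molecular van der Waals volume (A^3) from atomic
#' contributions with bond and ring overlap corrections:
#' `V = sum(atom contributions) - 5.92 B - 14.7 R_arom - 3.8 R_nonarom`,
#' where B counts all bonds including those to hydrogen. Benzene evaluates
#' to 81.2 A^3. Used as the open descriptor backend for the steric terms of
#' the Hansch analysis.
#'
#' @param x an `SDFset` or a character vector of SMILES.
#' @return numeric vector of volumes (A^3), `NA` for unparseable molecules.
#' @export
vdw_volume <- function(x) {
  if (is.character(x)) {
    conv <- smiles_to_sdfset(x)
    out <- rep(NA_real_, length(x))
    if (is.null(conv$sdf)) return(out)
    out[conv$ok] <- vdw_volume(conv$sdf)
    return(out)
  }
  stopifnot(methods::is(x, "SDFset"))
  props <- ob_properties(x)
  vapply(seq_along(x), function(i) {
    sdf <- x[[i]]
    ab <- ChemmineR::atomblock(sdf)
    sym <- sub("_.*$", "", rownames(ab))
    unknown <- setdiff(unique(sym), names(VDW_ATOM_CONTRIB))
    if (length(unknown)) return(NA_real_)
    n_h <- count_hydrogens(props$formula[i])
    census <- ring_census(sdf)
    sum(VDW_ATOM_CONTRIB[sym]) + n_h * VDW_ATOM_CONTRIB[["H"]] -
      5.92 * (census$n_bonds + n_h) -
      14.7 * census$aromatic - 3.8 * (census$total - census$aromatic)
  }, numeric(1))
}

# Open Babel bulk properties with rownames-safe titles.
ob_properties <- function(sdf) {
  ids <- sdfset_ids(sdf)
  if (any(!nzchar(ids)) || anyDuplicated(ids))
    ChemmineR::cid(sdf) <- make.unique(paste0("M", seq_along(sdf)))
  ChemmineR::propOB(sdf)
}

#' Whole-molecule descriptor backend
#'
#' Computes the three whole-molecule descriptors of the Hansch analysis:
#' van der Waals volume ([vdw_volume()]), octanol/water logP and molar
#' refractivity (both from Open Babel's additive models).
#'
#' @param smiles character vector of SMILES.
#' @return data frame with columns `vdw_vol`, `logP`, `mr` (rows align with
#'   `smiles`; `NA` for unparseable input).
#' @export
descriptor_backend <- function(smiles) {
  conv <- smiles_to_sdfset(smiles)
  out <- data.frame(vdw_vol = rep(NA_real_, length(smiles)),
                    logP = NA_real_, mr = NA_real_)
  if (is.null(conv$sdf)) return(out)
  props <- ob_properties(conv$sdf)
  out$vdw_vol[conv$ok] <- vdw_volume(conv$sdf)
  out$logP[conv$ok] <- props$logP
  out$mr[conv$ok] <- props$MR
  out
}

#' Incremental substituent descriptor
#'
#' The incremental approach to substituent constants: the difference between
#' the whole-molecule descriptor values of two molecules differing in a
#' single position isolates the substituent's contribution.
#'
#' @param parent_value,analog_value descriptor values computed by the same
#'   backend.
#' @return `analog_value - parent_value`, vectorized.
#' @export
incremental_descriptor <- function(parent_value, analog_value) {
  analog_value - parent_value
}
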