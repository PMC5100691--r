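# Synthetic cathinone-like SAR series with planted Hansch coefficients.
#
# Compounds are benzoyl ethanamines assembled from substituent pools at the
# three variable positions (C-alpha to the carbonyl, amine nitrogen,
# aromatic ring). Responses are generated as linear combinations of the
# package's own descriptor matrix with planted coefficients plus Gaussian
# noise, so regression machinery can be validated against known ground
# truth. The shipped 56-compound set (inst/extdata/cathinone_synthetic.csv)
# is a frozen draw from this generator and is a synthetic stand-in, not
# experimental data.

CA_FRAGMENTS <- c(H = "", CH3 = "C", C2H5 = "CC", nC3H7 = "CCC",
                  nC4H9 = "CCCC", iC4H9 = "CC(C)C")
N_FRAGMENTS <- c(H = "N", CH3 = "NC", diCH3 = "N(C)C", C2H5 = "NCC",
                 tC4H9 = "NC(C)(C)C", cC5H9 = "NC1CCCC1",
                 pyrrolidinyl = "N1CCCC1", piperidinyl = "N1CCCCC1")
ARYL_FRAGMENTS <- c(F = "F", Cl = "Cl", Br = "Br", CH3 = "C", OCH3 = "OC",
                    CF3 = "C(F)(F)F", OH = "O", NO2 = "[N+](=O)[O-]")

#' Assemble a cathinone SMILES from substituent keys
#'
#' Builds `R_Ca-CH(NR')C(=O)-aryl` SMILES for the benzoyl ethanamine series:
#' `ca_sub` keys the C-alpha substituent, `n_sub` the amine (including
#' cyclic amines where the nitrogen is part of a pyrrolidine or piperidine
#' ring), and `aryl_subs` the aromatic pattern string used by
#' [build_descriptor_matrix()] (meta/para substituents or the bridged
#' 3,4-methylenedioxy).
#'
#' @param ca_sub,n_sub,aryl_subs substituent keys; vectorized.
#' @return character vector of SMILES.
#' @export
cathinone_smiles <- function(ca_sub, n_sub, aryl_subs = "") {
  n <- max(length(ca_sub), length(n_sub), length(aryl_subs))
  ca_sub <- rep_len(ca_sub, n)
  n_sub <- rep_len(n_sub, n)
  aryl_subs <- rep_len(aryl_subs, n)
  bad_ca <- !(ca_sub %in% names(CA_FRAGMENTS))
  bad_n <- !(n_sub %in% names(N_FRAGMENTS))
  if (any(bad_ca | bad_n))
    stop_config("unknown substituent key(s): %s",
                toString(unique(c(ca_sub[bad_ca], n_sub[bad_n]))))
  aryl <- vapply(aryl_subs, aryl_smiles, character(1))
  paste0(CA_FRAGMENTS[ca_sub], "C(", N_FRAGMENTS[n_sub], ")C(=O)", aryl)
}

aryl_smiles <- function(spec) {
  subs <- parse_aryl_subs(spec)
  if (!nrow(subs)) return("c1ccccc1")
  if (any(subs$pos == "3,4")) {
    if (nrow(subs) > 1 || subs$key != "OCH2O")
      stop_config("only the lone bridged substituent 3,4-OCH2O is supported")
    return("c1ccc2c(c1)OCO2")
  }
  frag <- ARYL_FRAGMENTS[subs$key]
  if (anyNA(frag))
    stop_config("no SMILES fragment for aromatic substituent(s): %s",
                toString(subs$key[is.na(frag)]))
  meta <- frag[subs$pos == "3"]
  para <- frag[subs$pos == "4"]
  if (length(meta) > 1 || length(para) > 1 || any(subs$pos == "2"))
    stop_config("aryl builder supports at most one meta and one para group")
  if (length(meta) && length(para))
    sprintf("c1cc(%s)c(%s)cc1", meta, para)
  else if (length(para)) sprintf("c1ccc(%s)cc1", para)
  else sprintf("c1cc(%s)ccc1", meta)
}

#' Configuration for the synthetic SAR series
#'
#' Planted coefficients mirror the structure of the two reported regression
#' responses: an activity model for the B-target (hDAT-like) pIC50 with a
#' negative logP term, a positive C-alpha volume term and a positive
#' aromatic-pi term; and a log-selectivity model with a negative
#' whole-molecule mr term and positive C-alpha/N volume and aromatic-mr
#' terms. Coefficients are on the package's open descriptor scales.
#'
#' @param n_compounds series size.
#' @param coef_activity,coef_selectivity named coefficient vectors over
#'   `(Intercept)` plus any of the Hansch descriptors; unnamed descriptors
#'   are planted at zero.
#' @param noise_sd response noise sd (p-activity / log10 units).
#' @param ca_pool,n_pool,aryl_pool substituent pools sampled per position.
#' @param censor_p_limits hSERT-side censoring: true p-activities below
#'   `censor_p_limits[1]` are reported as "> 100 uM", below
#'   `censor_p_limits[2]` as "> 10 uM".
#' @param exemplar optional pinned exemplar, a list with `ca_sub`, `n_sub`,
#'   `aryl_subs`, `ic50_A_nM`, `ic50_B_nM`; it replaces the last generated
#'   compound and is exempt from censoring (the C-alpha selectivity
#'   exemplar of the shipped set).
#' @param seed integer RNG seed.
#' @return a `sar_series_config` list.
#' @export
sar_series_config <- function(n_compounds = 100,
                              coef_activity = c("(Intercept)" = 7.2,
                                                logP = -0.35,
                                                vdw_vol_Ca = 0.030,
                                                pi_arom = 0.45),
                              coef_selectivity = c("(Intercept)" = 5.65,
                                                   mr = -0.085,
                                                   vdw_vol_N = 0.020,
                                                   vdw_vol_Ca = 0.040,
                                                   mr_arom = 0.060,
                                                   sigma_p = -0.60),
                              noise_sd = 0.3,
                              ca_pool = names(CA_FRAGMENTS)[-1],
                              n_pool = names(N_FRAGMENTS),
                              aryl_pool = c("", "3-CH3", "4-CH3", "4-F",
                                            "4-Cl", "4-Br", "4-OCH3",
                                            "4-CF3", "3-CH3;4-CH3",
                                            "3,4-OCH2O"),
                              censor_p_limits = c(4, 5),
                              exemplar = NULL, seed = 1L) {
  cfg <- as.list(environment())
  if (!length(cfg$ca_pool) || !length(cfg$n_pool) || !length(cfg$aryl_pool))
    stop_config("substituent pools must be non-empty")
  if (cfg$n_compounds < 1) stop_config("n_compounds must be >= 1")
  if (cfg$noise_sd < 0) stop_config("noise_sd must be >= 0")
  class(cfg) <- "sar_series_config"
  cfg
}

# X %*% coefs for a named planted coefficient vector (absent terms are 0).
planted_response <- function(X, coefs) {
  out <- rep(unname(coefs["(Intercept)"]) %||% 0, nrow(X))
  if (is.na(out[1])) out[] <- 0
  for (term in setdiff(names(coefs), "(Intercept)")) {
    if (!term %in% names(X))
      stop_config("planted coefficient names unknown descriptor: %s", term)
    out <- out + coefs[[term]] * X[[term]]
  }
  out
}

#' Generate a synthetic SAR series with planted coefficients
#'
#' Samples substituents per position, builds SMILES and the descriptor
#' matrix, and generates two responses over it: the B-target (hDAT-like)
#' pIC50 from `coef_activity` and the log selectivity
#' `log10(IC50_A / IC50_B)` from `coef_selectivity`, each plus Gaussian
#' noise. A-target potencies follow as `p_A = p_B - logSel` and are
#' right-censored at the configured assay limits (emulating series where
#' roughly half of the A-side measurements are reported only as bounds).
#' The truth record carries the descriptor matrix, planted coefficients and
#' noise draws.
#'
#' @param config a [sar_series_config()].
#' @return list with `series` (compound_id, smiles, substituent keys,
#'   ic50_A_nM/relation_A, ic50_B_nM/relation_B, response_pActivity,
#'   response_logSel) and `truth`.
#' @export
generate_sar_series <- function(config) {
  stopifnot(inherits(config, "sar_series_config"))
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_compounds
    series <- data.frame(
      compound_id = sprintf("CATH-%02d", seq_len(n)),
      ca_sub = sample(cfg$ca_pool, n, replace = TRUE),
      n_sub = sample(cfg$n_pool, n, replace = TRUE),
      aryl_subs = sample(cfg$aryl_pool, n, replace = TRUE),
      stringsAsFactors = FALSE)
    if (!is.null(cfg$exemplar)) {
      ex <- cfg$exemplar
      series$ca_sub[n] <- ex$ca_sub
      series$n_sub[n] <- ex$n_sub
      series$aryl_subs[n] <- ex$aryl_subs %||% ""
    }
    series$smiles <- cathinone_smiles(series$ca_sub, series$n_sub,
                                      series$aryl_subs)
    X <- build_descriptor_matrix(series)
    if (nrow(X) != n)
      stop_config("descriptor matrix incomplete for generated series")
    eps_act <- rnorm(n, 0, cfg$noise_sd)
    eps_sel <- rnorm(n, 0, cfg$noise_sd)
    p_B <- planted_response(X[HANSCH_DESCRIPTORS], cfg$coef_activity) +
      eps_act
    log_sel <- planted_response(X[HANSCH_DESCRIPTORS],
                                cfg$coef_selectivity) + eps_sel
    p_A <- p_B - log_sel
    series$ic50_B_nM <- signif(10^(9 - p_B), 6)
    series$relation_B <- "="
    series$ic50_A_nM <- signif(10^(9 - p_A), 6)
    series$relation_A <- "="
    censor_hi <- p_A < cfg$censor_p_limits[1]
    censor_lo <- !censor_hi & p_A < cfg$censor_p_limits[2]
    series$ic50_A_nM[censor_hi] <- 1e5
    series$ic50_A_nM[censor_lo] <- 1e4
    series$relation_A[censor_hi | censor_lo] <- ">"
    if (!is.null(cfg$exemplar)) {
      ex <- cfg$exemplar
      series$ic50_A_nM[n] <- ex$ic50_A_nM
      series$ic50_B_nM[n] <- ex$ic50_B_nM
      series$relation_A[n] <- series$relation_B[n] <- "="
    }
    truth <- list(X = X, coef_activity = cfg$coef_activity,
                  coef_selectivity = cfg$coef_selectivity,
                  noise = data.frame(activity = eps_act,
                                     selectivity = eps_sel),
                  p_B = p_B, log_sel = log_sel,
                  exemplar_id = if (!is.null(cfg$exemplar))
                    series$compound_id[n] else NA_character_,
                  seed = cfg$seed)
    list(series = series, truth = truth)
  })
}

#' Regenerate responses for a fixed SAR descriptor matrix
#'
#' Redraws the response noise for an existing series truth record, keeping
#' structures and descriptors fixed. Used for replicate studies of
#' coefficient recovery and elimination behaviour.
#'
#' @param truth the `truth` element of [generate_sar_series()] output.
#' @param noise_sd response noise sd.
#' @param seed RNG seed for this replicate.
#' @return list with numeric vectors `activity` and `selectivity`.
#' @export
resample_sar_responses <- function(truth, noise_sd = 0.3, seed = 1L) {
  X <- truth$X
  with_seed(seed, {
    list(activity = planted_response(X[HANSCH_DESCRIPTORS],
                                     truth$coef_activity) +
           rnorm(nrow(X), 0, noise_sd),
         selectivity = planted_response(X[HANSCH_DESCRIPTORS],
                                        truth$coef_selectivity) +
           rnorm(nrow(X), 0, noise_sd))
  })
}

#' The shipped synthetic cathinone set
#'
#' Generates the 56-compound synthetic benzoyl ethanamine set emulating the
#' published cathinone use case: four scaffold types (aliphatic amines,
#' cyclopentylamine, pyrrolidine, piperidine), meta/para aromatic
#' substitution including 3,4-methylenedioxy, roughly half of the A-target
#' (hSERT-like) potencies right-censored at 10 or 100 uM, and one pinned
#' exemplar with an isobutyl C-alpha substituent showing a 345-fold
#' selectivity for the B target (hDAT-like). Entirely synthetic data with a
#' fixed seed; a frozen copy ships as
#' `inst/extdata/cathinone_synthetic.csv`.
#'
#' @param seed fixed seed of the frozen set; change it only to draw fresh
#'   variants.
#' @return list with `series` and `truth` as in [generate_sar_series()].
#' @export
generate_cathinone_set <- function(seed = 20160722) {
  cfg <- sar_series_config(
    n_compounds = 56,
    exemplar = list(ca_sub = "iC4H9", n_sub = "pyrrolidinyl",
                    aryl_subs = "", ic50_A_nM = 34500, ic50_B_nM = 100),
    seed = seed)
  generate_sar_series(cfg)
}

#' Path to the frozen synthetic cathinone CSV
#' @return file path within the installed package.
#' @export
cathinone_synthetic_file <- function() {
  system.file("extdata", "cathinone_synthetic.csv", package = "seltrend",
              mustWork = TRUE)
}

#' Load the frozen synthetic cathinone set
#'
#' @param path CSV path, defaulting to the shipped frozen set.
#' @return data frame with structures, substituent annotations and
#'   two-target IC50 columns.
#' @export
cathinone_set <- function(path = cathinone_synthetic_file()) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write the synthetic cathinone set as an SD file
#'
#' Builds an SD file with per-target activity property tags
#' (`IC50_<target>_nM`, `RELATION_<target>`) from the frozen synthetic set,
#' mimicking the layout of a supplementary activity SD file.
#'
#' @param path output SD file path.
#' @param set data frame from [cathinone_set()].
#' @param targets target ids used in the tag names.
#' @return the path, invisibly.
#' @export
write_cathinone_sdf <- function(path, set = cathinone_set(),
                                targets = c(A = "P31645", B = "Q01959")) {
  props <- data.frame(
    a_val = set$ic50_A_nM, a_rel = set$relation_A,
    b_val = set$ic50_B_nM, b_rel = set$relation_B,
    stringsAsFactors = FALSE)
  names(props) <- c(paste0("IC50_", targets[["A"]], "_nM"),
                    paste0("RELATION_", targets[["A"]]),
                    paste0("IC50_", targets[["B"]], "_nM"),
                    paste0("RELATION_", targets[["B"]]))
  write_compound_sdf(set[, c("compound_id", "smiles")], path,
                     properties = props)
}
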