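# Seeded synthetic bioactivity library generator with known ground truth.
#
# The generator emulates the statistical structure of public two-target
# transporter bioactivity data: compounds built by decorating ring-system
# templates (so Murcko clustering recovers the templates), lognormal
# potencies (Gaussian in p-activity units) with scaffold-level selectivity
# classes, replicate measurements with calibrated noise, a systematic
# Ki-vs-IC50 offset, right-censored records at an assay limit, drug
# annotations anchoring the labeling cutoffs, and hERG channel activities.

# Ring-system templates. Each starts with a ring atom so an acyclic
# decoration can be prefixed to give a valid SMILES without changing the
# Murcko framework.
SCAFFOLD_TEMPLATES <- c(
  "c1ccccc1",                     # benzene
  "C1CCCCN1",                     # piperidine
  "c1ccc2c(c1)CCCC2",             # tetralin
  "c1ccc2c(c1)OCO2",              # 1,3-benzodioxole
  "c1ccc2ccccc2c1",               # naphthalene
  "c1ccsc1",                      # thiophene
  "c1ccncc1",                     # pyridine
  "c1ccc(Cc2ccccc2)cc1",          # diphenylmethane
  "c1ccc(C2CCNCC2)cc1",           # 4-phenylpiperidine
  "c1ccc(N2CCNCC2)cc1",           # phenylpiperazine
  "c1ccc2[nH]ccc2c1",             # indole
  "c1ccc(CC2CCCCN2)cc1",          # 2-benzylpiperidine
  "c1ccc(C2CCCN2)cc1",            # 2-phenylpyrrolidine
  "c1ccc(-c2ccccc2)cc1",          # biphenyl
  "C1CCOC1",                      # tetrahydrofuran
  "c1cnc2[nH]ccc2c1")             # 7-azaindole

# Acyclic decorations, written so their last atom bonds to the template's
# first ring atom when prefixed.
DECORATIONS <- c("", "C", "CC", "CCC", "CCCC", "CC(C)C", "CC(C)(C)C",
                 "CCN", "CCNC", "CCN(C)C", "CO", "CCO", "OC", "OCC",
                 "CC(=O)", "CC(N)C(=O)", "CCC(N)C(=O)", "NC(=O)", "CN",
                 "CNC", "CCCN", "CC(C)N", "CC(O)C", "OC(F)(F)F", "CC#N",
                 "CS", "CSC", "CC(C)O", "CCCO", "CCCCN")

SELECTIVITY_CLASSES <- c("A_selective", "B_selective", "promiscuous",
                         "inactive")

#' Configuration for the synthetic bioactivity library
#'
#' Defaults describe the emulated study conditions: two transporter-like
#' targets, a scaffold selectivity mix echoing the observed preponderance of
#' dual actives and A-selectives, active potencies centred at 100 nM
#' (p = 7.0) and inactives at ~20 uM (p = 4.7), drug anchors at the four
#' reference cutoffs (A: Ki 1110 / IC50 2090 nM; B: Ki 1460 / IC50 1830 nM),
#' right-censoring at a 10 uM assay limit, and replicate noise calibrated so
#' the intra-assay max-vs-min R-squared lands at the 0.74 target.
#'
#' @param n_scaffold_templates number of distinct ring-system templates.
#' @param members_mean mean compounds per template (>= 1).
#' @param targets named character vector `c(A = ..., B = ...)`.
#' @param scaffold_selectivity_mix proportions over A_selective, B_selective,
#'   promiscuous, inactive (must sum to 1).
#' @param active_p_mean,inactive_p_mean class potency centres (p-activity).
#' @param scaffold_sd,compound_sd scaffold- and compound-level potency
#'   spread (log10 units).
#' @param complete_fraction fraction of compounds measured on both targets.
#' @param p_ic50,p_ki probability a measured compound-target pair carries
#'   each endpoint (at least one is forced).
#' @param replicate_lambda Poisson rate of extra replicates per record
#'   group (replicate count is `1 + Pois(lambda)`).
#' @param replicate_noise_sd measurement noise (log10 units); `NULL`
#'   calibrates it to `intra_r2_target` via [calibrate_replicate_noise()].
#' @param intra_r2_target target intra-assay max-vs-min R-squared.
#' @param ki_ic50_offset systematic pKi minus pIC50 offset (log10 units).
#' @param censor_limit_nM,censor_fraction right-censoring assay limit and
#'   fraction of records reported as ">" at that limit.
#' @param anchors data frame of drug anchor potencies (target key A/B,
#'   endpoint, value_nM, drug_name) defining the labeling cutoffs.
#' @param drug_fraction fraction of ordinary compounds annotated as drugs.
#' @param herg_active_fraction fraction of compounds with a hERG record.
#' @param herg_p_mean,herg_p_sd hERG potency distribution (p-activity).
#' @param seed integer RNG seed; a fixed seed makes output bit-identical.
#' @return a `library_config` list.
#' @export
library_config <- function(n_scaffold_templates = 12, members_mean = 15,
                           targets = c(A = "P31645", B = "Q01959"),
                           scaffold_selectivity_mix = c(A_selective = 0.22,
                                                        B_selective = 0.11,
                                                        promiscuous = 0.51,
                                                        inactive = 0.16),
                           active_p_mean = 7.0, inactive_p_mean = 4.7,
                           scaffold_sd = 0.3, compound_sd = 0.5,
                           complete_fraction = 0.85,
                           p_ic50 = 0.8, p_ki = 0.7,
                           replicate_lambda = 0.7,
                           replicate_noise_sd = NULL,
                           intra_r2_target = 0.74,
                           ki_ic50_offset = 0.25,
                           censor_limit_nM = 1e4, censor_fraction = 0.08,
                           anchors = default_anchors(targets),
                           drug_fraction = 0.02,
                           herg_active_fraction = 0.3,
                           herg_p_mean = 5.3, herg_p_sd = 0.5,
                           herg_target_id = "Q12809",
                           seed = 1L) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$scaffold_selectivity_mix) - 1) > 1e-8)
    stop_config("scaffold_selectivity_mix must sum to 1")
  if (!setequal(names(cfg$scaffold_selectivity_mix), SELECTIVITY_CLASSES))
    stop_config("scaffold_selectivity_mix must name the classes %s",
                toString(SELECTIVITY_CLASSES))
  if (cfg$n_scaffold_templates < 1 ||
      cfg$n_scaffold_templates > length(SCAFFOLD_TEMPLATES))
    stop_config("n_scaffold_templates must be in 1..%d",
                length(SCAFFOLD_TEMPLATES))
  sds <- c(cfg$scaffold_sd, cfg$compound_sd, cfg$herg_p_sd)
  if (any(sds < 0)) stop_config("standard deviations must be >= 0")
  if (cfg$censor_fraction < 0 || cfg$censor_fraction > 1)
    stop_config("censor_fraction must be in [0, 1]")
  if (cfg$censor_fraction > 0 &&
      cfg$censor_limit_nM <= 10^(9 - cfg$active_p_mean))
    stop_config(paste0("infeasible config: censor limit %g nM is at or ",
                       "below the active-class median potency"),
                cfg$censor_limit_nM)
  cfg$rng <- "Mersenne-Twister"  # RNG algorithm pinned for reproducibility
  class(cfg) <- "library_config"
  cfg
}

default_anchors <- function(targets) {
  data.frame(target = c("A", "A", "B", "B"),
             endpoint = c("Ki", "IC50", "Ki", "IC50"),
             value_nM = c(1110, 2090, 1460, 1830),
             drug_name = c("anchor_drug_A", "anchor_drug_A",
                           "anchor_drug_B", "anchor_drug_B"),
             stringsAsFactors = FALSE)
}

#' Simulated max-vs-min replicate correlation
#'
#' Brute-force estimate of the squared Pearson correlation between the
#' maximum and minimum of duplicate measurements, for compounds whose true
#' values spread with `between_sd` and replicates with `noise_sd`.
#'
#' @param noise_sd replicate noise sd (log10 units).
#' @param between_sd between-compound sd of the true p-activity.
#' @param n_pairs number of simulated duplicate pairs.
#' @param seed RNG seed.
#' @return the simulated R-squared.
#' @export
simulate_maxmin_r2 <- function(noise_sd, between_sd, n_pairs = 10000,
                               seed = 1L) {
  with_seed(seed, {
    mu <- rnorm(n_pairs, 0, between_sd)
    e1 <- rnorm(n_pairs)
    e2 <- rnorm(n_pairs)
    hi <- mu + noise_sd * pmax(e1, e2)
    lo <- mu + noise_sd * pmin(e1, e2)
    stats::cor(hi, lo)^2
  })
}

#' Calibrate replicate noise to a target max-vs-min R-squared
#'
#' Finds the replicate noise sd whose duplicate-measurement max-vs-min
#' correlation matches `target_r2`, by root-finding on a brute-force
#' pre-simulation with common random numbers (the same standard-normal draws
#' are rescaled at every candidate sd, making the simulated R-squared a
#' smooth, monotone function of the noise). For duplicates the closed form
#' `cor = (tau^2 + sigma^2/pi) / (tau^2 + sigma^2 (1 - 1/pi))` bounds the
#' attainable range: targets at or below `1/(pi - 1)^2` (~ 0.218) are
#' unreachable for any noise level and rejected.
#'
#' @param target_r2 target R-squared, e.g. the observed 0.74.
#' @param between_sd between-compound sd of the true p-activity.
#' @param n_pairs simulation size, default 10000.
#' @param seed RNG seed for the pre-simulation.
#' @return the calibrated noise sd (log10 units).
#' @export
calibrate_replicate_noise <- function(target_r2 = 0.74, between_sd,
                                      n_pairs = 10000, seed = 1L) {
  if (target_r2 <= 1 / (pi - 1)^2 || target_r2 >= 1)
    stop_config("target_r2 must be in (%.3f, 1)", 1 / (pi - 1)^2)
  if (between_sd <= 0) stop_config("between_sd must be positive")
  draws <- with_seed(seed, list(mu = rnorm(n_pairs, 0, between_sd),
                                e1 = rnorm(n_pairs), e2 = rnorm(n_pairs)))
  r2_at <- function(s) {
    hi <- draws$mu + s * pmax(draws$e1, draws$e2)
    lo <- draws$mu + s * pmin(draws$e1, draws$e2)
    stats::cor(hi, lo)^2 - target_r2
  }
  upper <- 10 * between_sd
  if (r2_at(upper) > 0)
    stop_config("target_r2 %.2f not reachable below noise sd %.1f",
                target_r2, upper)
  stats::uniroot(r2_at, c(1e-6, upper), tol = 1e-6)$root
}

# Analytic between-compound sd of true p-activity per target under the
# class mixture (used to feed the noise calibration).
mixture_between_sd <- function(cfg) {
  mix <- cfg$scaffold_selectivity_mix
  p_active_A <- mix[["A_selective"]] + mix[["promiscuous"]]
  within_var <- cfg$scaffold_sd^2 + cfg$compound_sd^2
  mix_var <- function(p_active) {
    mu <- c(cfg$active_p_mean, cfg$inactive_p_mean)
    w <- c(p_active, 1 - p_active)
    sum(w * (mu^2 + within_var)) - sum(w * mu)^2
  }
  sqrt(mix_var(p_active_A))
}

#' Generate a synthetic two-target bioactivity library
#'
#' Draws a compound library from ring-system templates with acyclic
#' decorations, assigns each template a selectivity class, and emits
#' replicate IC50/Ki measurements per compound and target with calibrated
#' noise, a Ki-vs-IC50 offset, right-censored records, drug-anchor records
#' that reproduce the tailored cutoffs, planted drug annotations and hERG
#' activities. All randomness flows from `config$seed`; the caller's RNG
#' state is untouched and a fixed seed yields bit-identical output.
#'
#' @param config a [library_config()].
#' @return list with `records` (bioactivity record data frame, hERG records
#'   included under target id `"herg"`) and `truth` (latent assignments:
#'   per-compound template, class, true p-activities, drug and hERG
#'   annotations, templates table, calibrated parameters, counts).
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "library_config"))
  cfg <- config
  with_seed(cfg$seed, {
    noise_sd <- cfg$replicate_noise_sd %||%
      calibrate_replicate_noise(cfg$intra_r2_target,
                                between_sd = mixture_between_sd(cfg),
                                seed = cfg$seed + 1L)
    k <- cfg$n_scaffold_templates
    templates <- data.frame(
      template_id = seq_len(k), smiles = SCAFFOLD_TEMPLATES[seq_len(k)],
      class = sample(SELECTIVITY_CLASSES, k, replace = TRUE,
                     prob = cfg$scaffold_selectivity_mix),
      effect_A = rnorm(k, 0, cfg$scaffold_sd),
      effect_B = rnorm(k, 0, cfg$scaffold_sd),
      stringsAsFactors = FALSE)
    members <- 1L + stats::rpois(k, max(cfg$members_mean - 1, 0))
    template_of <- rep(templates$template_id, members)
    n <- length(template_of)
    decor <- sample(DECORATIONS, n, replace = TRUE)
    compounds <- data.frame(
      compound_id = sprintf("CPD%05d", seq_len(n)),
      smiles = paste0(decor, SCAFFOLD_TEMPLATES[template_of]),
      template_id = template_of,
      class = templates$class[template_of],
      stringsAsFactors = FALSE)
    class_mean <- function(class, side) {
      active <- switch(side,
                       A = class %in% c("A_selective", "promiscuous"),
                       B = class %in% c("B_selective", "promiscuous"))
      ifelse(active, cfg$active_p_mean, cfg$inactive_p_mean)
    }
    compounds$p_true_A <- class_mean(compounds$class, "A") +
      templates$effect_A[template_of] + rnorm(n, 0, cfg$compound_sd)
    compounds$p_true_B <- class_mean(compounds$class, "B") +
      templates$effect_B[template_of] + rnorm(n, 0, cfg$compound_sd)
    both <- stats::runif(n) < cfg$complete_fraction
    only_A <- !both & stats::runif(n) < 0.5
    compounds$measured_A <- both | only_A
    compounds$measured_B <- both | !only_A
    compounds$is_drug <- stats::runif(n) < cfg$drug_fraction
    compounds$drug_name <- ifelse(compounds$is_drug,
                                  paste0("drug_", compounds$compound_id), NA)

    rows <- vector("list", 2L * n + 8L)
    ri <- 0L
    emit <- function(compound_id, smiles, target_key, endpoint, relation,
                     value_nM, drug_name = NA_character_,
                     pharm_action_known = NA) {
      ri <<- ri + 1L
      rows[[ri]] <<- data.frame(
        compound_id = compound_id, smiles = smiles,
        target_id = unname(cfg$targets[target_key]), endpoint = endpoint,
        relation = relation, value_nM = value_nM,
        document_id = NA_character_, drug_name = drug_name,
        pharm_action_known = pharm_action_known, stringsAsFactors = FALSE)
    }
    anchor_value <- function(target_key, endpoint) {
      a <- cfg$anchors
      a$value_nM[a$target == target_key & a$endpoint == endpoint]
    }
    for (i in seq_len(n)) {
      for (side in c("A", "B")) {
        if (!compounds[[paste0("measured_", side)]][i]) next
        p_true <- compounds[[paste0("p_true_", side)]][i]
        eps <- c(IC50 = stats::runif(1) < cfg$p_ic50,
                 Ki = stats::runif(1) < cfg$p_ki)
        if (!any(eps)) eps[sample(ENDPOINTS, 1)] <- TRUE
        for (ep in ENDPOINTS[eps]) {
          n_rep <- 1L + stats::rpois(1, cfg$replicate_lambda)
          p_obs <- p_true + (ep == "Ki") * cfg$ki_ic50_offset +
            rnorm(n_rep, 0, noise_sd)
          value <- signif(10^(9 - p_obs), 6)
          censored <- stats::runif(n_rep) < cfg$censor_fraction
          value[censored] <- cfg$censor_limit_nM
          relation <- ifelse(censored, ">", "=")
          drug <- compounds$drug_name[i]
          known <- if (compounds$is_drug[i]) {
            value < anchor_value(side, ep) & !censored
          } else rep(NA, n_rep)
          for (j in seq_len(n_rep))
            emit(compounds$compound_id[i], compounds$smiles[i], side, ep,
                 relation[j], value[j], drug, known[j])
        }
      }
    }
    # anchor drug compounds: one per target, least potent recognized-active
    anchor_templates <- sample(seq_len(k), 2, replace = TRUE)
    anchor_ids <- c(A = "DRUG_ANCHOR_A", B = "DRUG_ANCHOR_B")
    for (side in c("A", "B")) {
      tmpl <- anchor_templates[match(side, c("A", "B"))]
      smi <- paste0("CCN", SCAFFOLD_TEMPLATES[tmpl])
      for (ep in ENDPOINTS)
        emit(anchor_ids[[side]], smi, side, ep, "=",
             anchor_value(side, ep),
             drug_name = cfg$anchors$drug_name[cfg$anchors$target == side][1],
             pharm_action_known = TRUE)
      # modest activity on the other target too, below its cutoff region
      other <- setdiff(c("A", "B"), side)
      emit(anchor_ids[[side]], smi, other, "IC50", "=",
           signif(10^(9 - cfg$inactive_p_mean), 6),
           drug_name = cfg$anchors$drug_name[cfg$anchors$target == side][1],
           pharm_action_known = FALSE)
    }
    # hERG records
    herg_sel <- which(stats::runif(n) < cfg$herg_active_fraction)
    herg <- data.frame(compound_id = compounds$compound_id[herg_sel],
                       value_nM = signif(10^(9 - rnorm(length(herg_sel),
                                                       cfg$herg_p_mean,
                                                       cfg$herg_p_sd)), 6),
                       stringsAsFactors = FALSE)
    for (i in seq_along(herg_sel))
      emit(compounds$compound_id[herg_sel[i]],
           compounds$smiles[herg_sel[i]], "A", "IC50", "=",
           herg$value_nM[i])
    records <- do.call(rbind, rows[seq_len(ri)])
    n_herg <- nrow(herg)
    if (n_herg > 0) {
      herg_rows <- (ri - n_herg + 1L):ri
      records$target_id[herg_rows] <- cfg$herg_target_id
    }
    records$p_activity <- to_p_activity(records$value_nM)
    records <- records[, names(empty_records())]
    rownames(records) <- NULL
    herg$flag_expected <- herg$value_nM < 1e4
    truth <- list(compounds = compounds, templates = templates,
                  anchors = cbind(cfg$anchors,
                                  compound_id = anchor_ids[cfg$anchors$target]),
                  herg = herg,
                  params = list(replicate_noise_sd = noise_sd,
                                between_sd = mixture_between_sd(cfg),
                                seed = cfg$seed),
                  counts = list(
                    n_compounds = n,
                    n_templates = k,
                    n_both_targets = sum(both),
                    n_single_target = sum(!both),
                    n_records = nrow(records)))
    list(records = records, truth = truth)
  })
}
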