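# Hansch descriptor matrix assembly and multiple linear regression with
# backward descriptor elimination.
#
# The descriptor set follows classical Hansch practice for a benzoyl
# ethanamine series: whole-molecule steric/lipophilic terms (vdw-vol, logP,
# mr), incremental van der Waals volumes of the substituents at the
# C-alpha to the carbonyl (vdw_vol_Ca) and at the amine nitrogen
# (vdw_vol_N), additive aromatic substituent constants (pi_arom, mr_arom,
# Hammett sigma_m/sigma_p) and meta/para indicator variables (I_m, I_p).

HANSCH_DESCRIPTORS <- c("vdw_vol", "logP", "mr", "vdw_vol_Ca", "vdw_vol_N",
                        "pi_arom", "mr_arom", "sigma_m", "sigma_p",
                        "I_m", "I_p")

#' Substituent constants table
#'
#' Loads the editable substituent-constants table shipped with the package:
#' per substituent key, the incremental van der Waals volume (A^3, computed
#' with the package's own volume backend via the incremental probe approach),
#' aromatic pi (log P) and molar refractivity increments, and Hammett
#' sigma_m/sigma_p values from the standard Hansch-Leo compilation. The
#' table is data, not code: pass `path` to use an edited copy.
#'
#' @param path optional path to a CSV with columns substituent, class,
#'   fragment, vdw_vol_inc, pi_inc, mr_inc, sigma_m, sigma_p, source.
#' @return data frame of substituent constants.
#' @export
substituent_constants <- function(path = NULL) {
  path <- path %||% system.file("extdata", "substituent_constants.csv",
                                package = "seltrend", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Parse an aromatic substitution pattern string: tokens separated by ";",
# each "<pos>-<key>" with pos one of 2 (ortho), 3 (meta), 4 (para), or the
# bridged "3,4" (e.g. "3,4-OCH2O"). "" means unsubstituted.
parse_aryl_subs <- function(spec) {
  if (is.na(spec) || !nzchar(spec)) {
    return(data.frame(pos = character(), key = character(),
                      stringsAsFactors = FALSE))
  }
  tokens <- trimws(strsplit(spec, ";", fixed = TRUE)[[1]])
  m <- regmatches(tokens, regexec("^(2|3|4|3,4)-(.+)$", tokens))
  bad <- lengths(m) != 3L
  if (any(bad))
    stop_data("malformed aromatic substituent token(s): %s",
              toString(tokens[bad]))
  data.frame(pos = vapply(m, `[`, character(1), 2),
             key = vapply(m, `[`, character(1), 3),
             stringsAsFactors = FALSE)
}

#' Assemble the Hansch descriptor matrix
#'
#' Builds one descriptor row per compound of an R-group annotated series:
#' whole-molecule vdw_vol/logP/mr from the descriptor backend, substituent
#' volumes at the C-alpha and nitrogen positions from the constants table,
#' additive aromatic constants (sums over all ring substituents for
#' pi_arom/mr_arom; position-wise sums for sigma_m/sigma_p), and meta/para
#' indicators. A bridged "3,4-" substituent (e.g. methylenedioxy) counts
#' once for pi/mr and sets both indicators. Rows referencing a substituent
#' missing from the constants table are excluded and reported.
#'
#' @param series data frame with columns compound_id, smiles, ca_sub, n_sub
#'   (substituent keys into the constants table) and aryl_subs (pattern
#'   string, e.g. `"3-CH3;4-OCH3"` or `"3,4-OCH2O"`; "" if unsubstituted).
#'   Response columns, when present, are carried through.
#' @param constants substituent constants, see [substituent_constants()].
#' @param backend whole-molecule descriptor provider, a
#'   `function(smiles) -> data.frame(vdw_vol, logP, mr)`.
#' @return data frame of descriptor rows; excluded compounds are reported in
#'   `attr(, "excluded")` (compound_id, reason).
#' @export
build_descriptor_matrix <- function(series, constants = substituent_constants(),
                                    backend = descriptor_backend) {
  stopifnot(all(c("compound_id", "smiles", "ca_sub", "n_sub", "aryl_subs")
                %in% names(series)))
  const_at <- function(keys, class, col) {
    tab <- constants[constants$class == class, , drop = FALSE]
    tab[[col]][match(keys, tab$substituent)]
  }
  n <- nrow(series)
  rows <- data.frame(compound_id = series$compound_id,
                     stringsAsFactors = FALSE)
  whole <- backend(series$smiles)
  rows$vdw_vol <- whole$vdw_vol
  rows$logP <- whole$logP
  rows$mr <- whole$mr
  rows$vdw_vol_Ca <- const_at(series$ca_sub, "alpha", "vdw_vol_inc")
  rows$vdw_vol_N <- const_at(series$n_sub, "amine", "vdw_vol_inc")
  rows$pi_arom <- rows$mr_arom <- rows$sigma_m <- rows$sigma_p <- 0
  rows$I_m <- rows$I_p <- 0L
  excluded_reason <- rep(NA_character_, n)
  if (anyNA(rows$vdw_vol_Ca))
    excluded_reason[is.na(rows$vdw_vol_Ca)] <-
      paste0("unknown C-alpha substituent: ",
             series$ca_sub[is.na(rows$vdw_vol_Ca)])
  if (anyNA(rows$vdw_vol_N))
    excluded_reason[is.na(excluded_reason) & is.na(rows$vdw_vol_N)] <-
      paste0("unknown N substituent: ",
             series$n_sub[is.na(excluded_reason) & is.na(rows$vdw_vol_N)])
  for (i in seq_len(n)) {
    if (!is.na(excluded_reason[i])) next
    subs <- parse_aryl_subs(series$aryl_subs[i])
    if (!nrow(subs)) next
    pi_v <- const_at(subs$key, "aryl", "pi_inc")
    mr_v <- const_at(subs$key, "aryl", "mr_inc")
    sm_v <- const_at(subs$key, "aryl", "sigma_m")
    sp_v <- const_at(subs$key, "aryl", "sigma_p")
    if (anyNA(pi_v) || anyNA(mr_v)) {
      excluded_reason[i] <- paste0("unknown aromatic substituent: ",
                                   toString(subs$key[is.na(pi_v)]))
      next
    }
    rows$pi_arom[i] <- sum(pi_v)
    rows$mr_arom[i] <- sum(mr_v)
    meta <- subs$pos %in% c("3", "3,4")
    para <- subs$pos %in% c("4", "3,4")
    rows$sigma_m[i] <- sum(sm_v[meta])
    rows$sigma_p[i] <- sum(sp_v[para])
    rows$I_m[i] <- as.integer(any(meta))
    rows$I_p[i] <- as.integer(any(para))
  }
  bad_backend <- is.na(rows$vdw_vol) | is.na(rows$logP) | is.na(rows$mr)
  excluded_reason[is.na(excluded_reason) & bad_backend] <-
    "descriptor backend failed"
  keep <- is.na(excluded_reason)
  carry <- intersect(c("response_pActivity", "response_logSel"),
                     names(series))
  for (col in carry) rows[[col]] <- series[[col]]
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- data.frame(
    compound_id = series$compound_id[!keep],
    reason = excluded_reason[!keep], stringsAsFactors = FALSE)
  out
}

#' Ordinary least squares fit with inference statistics
#'
#' Fits `y ~ X` with an intercept and reports per-coefficient standard
#' errors, t statistics and two-sided p values on `n - p - 1` degrees of
#' freedom, plus the coefficient of determination. Zero-variance and
#' collinear descriptor columns are rejected by name rather than silently
#' dropped.
#'
#' @param X numeric matrix or data frame of descriptors (no intercept
#'   column).
#' @param y numeric response vector.
#' @return an object of class `hansch_model`: list with `coefficients`
#'   (term, estimate, std_error, t_value, p_value), `n`, `r2`,
#'   `residual_sd`, `alpha` and an empty `elimination_trace`.
#' @export
ols_fit <- function(X, y) {
  X <- as.data.frame(X)
  stopifnot(nrow(X) == length(y))
  p <- ncol(X)
  if (nrow(X) <= p + 1L)
    stop_data("need more observations (%d) than descriptors + 1 (%d)",
              nrow(X), p + 1L)
  variances <- vapply(X, stats::var, numeric(1))
  if (any(variances == 0))
    stop_data("zero-variance descriptor column(s): %s",
              toString(names(X)[variances == 0]))
  dat <- cbind(X, .y = y)
  fit <- stats::lm(.y ~ ., data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop_data("rank-deficient descriptor matrix; collinear column(s): %s",
              toString(names(cf)[is.na(cf)]))
  sm <- summary(fit)
  tab <- sm$coefficients
  model <- list(
    coefficients = data.frame(term = rownames(tab), estimate = tab[, 1],
                              std_error = tab[, 2], t_value = tab[, 3],
                              p_value = tab[, 4], stringsAsFactors = FALSE,
                              row.names = NULL),
    n = nrow(X), r2 = sm$r.squared, residual_sd = sm$sigma,
    alpha = NA_real_,
    elimination_trace = data.frame(term = character(), p_value = numeric(),
                                   stringsAsFactors = FALSE))
  class(model) <- "hansch_model"
  model
}

#' Backward descriptor elimination
#'
#' Starting from the full model, repeatedly refits after dropping the
#' descriptor with the largest p value, while that p value exceeds `alpha`;
#' the intercept is never dropped. Terminates when every retained
#' coefficient is significant at `alpha` or no descriptors remain (then an
#' intercept-only summary is returned). Equal p values break ties towards
#' the later column in matrix order, keeping elimination deterministic.
#'
#' @inheritParams ols_fit
#' @param alpha significance level retained coefficients must meet,
#'   default 0.05 (95% confidence).
#' @return a `hansch_model` whose `elimination_trace` records every dropped
#'   descriptor with its p value at the drop.
#' @export
backward_eliminate <- function(X, y, alpha = 0.05) {
  X <- as.data.frame(X)
  trace <- data.frame(term = character(), p_value = numeric(),
                      stringsAsFactors = FALSE)
  while (ncol(X) > 0L) {
    model <- ols_fit(X, y)
    coefs <- model$coefficients
    terms <- coefs[coefs$term != "(Intercept)", , drop = FALSE]
    pv <- terms$p_value
    if (all(pv <= alpha)) {
      model$alpha <- alpha
      model$elimination_trace <- trace
      return(model)
    }
    worst <- max(which(pv == max(pv)))  # tie -> later column
    trace <- rbind(trace, data.frame(term = terms$term[worst],
                                     p_value = pv[worst],
                                     stringsAsFactors = FALSE))
    X <- X[, setdiff(names(X), terms$term[worst]), drop = FALSE]
  }
  # nothing survived: intercept-only model
  model <- list(
    coefficients = data.frame(term = "(Intercept)", estimate = mean(y),
                              std_error = stats::sd(y) / sqrt(length(y)),
                              t_value = NA_real_, p_value = NA_real_,
                              stringsAsFactors = FALSE),
    n = length(y), r2 = 0, residual_sd = stats::sd(y), alpha = alpha,
    elimination_trace = trace)
  class(model) <- "hansch_model"
  model
}

#' @export
print.hansch_model <- function(x, digits = 3, ...) {
  cf <- x$coefficients
  terms <- cf[cf$term != "(Intercept)", , drop = FALSE]
  intercept <- cf$estimate[cf$term == "(Intercept)"]
  eq <- sprintf("y = %.*g", digits, intercept)
  if (nrow(terms)) {
    parts <- sprintf("%s %.*g %s", ifelse(terms$estimate >= 0, "+", "-"),
                     digits, abs(terms$estimate), terms$term)
    eq <- paste(eq, paste(parts, collapse = " "))
  }
  cat(eq, "\n")
  cat(sprintf("n = %d, r2 = %.2f\n", x$n, x$r2))
  if (nrow(cf)) {
    print(cbind(cf[1], round(cf[-1], 4)), row.names = FALSE)
  }
  if (nrow(x$elimination_trace)) {
    cat("eliminated:",
        paste(sprintf("%s (p=%.3f)", x$elimination_trace$term,
                      x$elimination_trace$p_value), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Confidence intervals for a fitted Hansch model
#'
#' @param object a `hansch_model`.
#' @param parm unused (all coefficients are returned).
#' @param level confidence level, default 0.95.
#' @param ... unused.
#' @return matrix with lower/upper bounds per coefficient.
#' @export
confint.hansch_model <- function(object, parm, level = 0.95, ...) {
  cf <- object$coefficients
  df <- object$n - nrow(cf)
  crit <- stats::qt(1 - (1 - level) / 2, df)
  out <- cbind(lower = cf$estimate - crit * cf$std_error,
               upper = cf$estimate + crit * cf$std_error)
  rownames(out) <- cf$term
  out
}

#' Log selectivity response
#'
#' `log10(ic50_A_nM / ic50_B_nM)`, the log of the potency ratio between the
#' two targets; equals `pActivity_B - pActivity_A`, so positive values mean
#' the compound is more potent on target B. Censored measurements (relation
#' other than "=") carry no exact ratio and come back `NA`; callers exclude
#' and report them.
#'
#' @param ic50_A_nM,ic50_B_nM positive potencies (nM) on targets A and B.
#' @param relation_A,relation_B relation signs (recycled).
#' @return numeric vector, `NA` where either input is censored.
#' @export
selectivity_response <- function(ic50_A_nM, ic50_B_nM,
                                 relation_A = "=", relation_B = "=") {
  if (any(c(ic50_A_nM, ic50_B_nM) <= 0, na.rm = TRUE))
    stop_data("potencies must be positive")
  n <- max(length(ic50_A_nM), length(ic50_B_nM))
  relation_A <- rep_len(relation_A, n)
  relation_B <- rep_len(relation_B, n)
  out <- log10(rep_len(ic50_A_nM, n) / rep_len(ic50_B_nM, n))
  out[relation_A != "=" | relation_B != "="] <- NA_real_
  out
}
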