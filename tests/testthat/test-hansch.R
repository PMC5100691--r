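test_that("incremental descriptors are simple differences", {
  expect_equal(incremental_descriptor(100, 125), 25)
  expect_equal(incremental_descriptor(77.7, 77.7), 0)
})

test_that("volume increments agree across probe scaffolds within 1 A^3", {
  # the H -> CH3 swap must contribute the same volume on benzene and on
  # naphthalene if the group-contribution backend is internally consistent
  inc_benzene <- incremental_descriptor(vdw_volume("c1ccccc1"),
                                        vdw_volume("Cc1ccccc1"))
  inc_naphthalene <- incremental_descriptor(
    vdw_volume("c1ccc2ccccc2c1"), vdw_volume("Cc1ccc2ccccc2c1"))
  expect_lt(abs(inc_benzene - inc_naphthalene), 1)
  # benzene reference value of the scheme
  expect_equal(vdw_volume("c1ccccc1"), 81.2, tolerance = 0.01)
})

test_that("shipped vdW increments reproduce the incremental computation", {
  constants <- substituent_constants()
  probe <- function(frag) vdw_volume(paste0(frag, "C(N)C(=O)c1ccccc1"))
  parent <- vdw_volume("NCC(=O)c1ccccc1")
  for (key in c("CH3", "nC3H7", "iC4H9")) {
    frag <- seltrend:::CA_FRAGMENTS[[key]]
    shipped <- constants$vdw_vol_inc[constants$substituent == key &
                                       constants$class == "alpha"]
    expect_equal(shipped, incremental_descriptor(parent, probe(frag)),
                 tolerance = 0.01)
  }
})

test_that("descriptor rows assemble substituent constants and indicators", {
  series <- data.frame(
    compound_id = c("p", "para", "meta_para", "bad"),
    ca_sub = c("CH3", "CH3", "C2H5", "nonesuch"),
    n_sub = c("H", "CH3", "pyrrolidinyl", "H"),
    aryl_subs = c("", "4-Cl", "3-CH3;4-OCH3", ""),
    stringsAsFactors = FALSE)
  series$smiles <- cathinone_smiles(
    ifelse(series$ca_sub == "nonesuch", "CH3", series$ca_sub),
    series$n_sub, series$aryl_subs)
  X <- build_descriptor_matrix(series)
  expect_equal(nrow(X), 3L)
  constants <- substituent_constants()
  aryl <- constants[constants$class == "aryl", ]
  p <- X[X$compound_id == "p", ]
  expect_equal(p$pi_arom + p$mr_arom + p$sigma_m + p$sigma_p, 0)
  expect_equal(p$I_m + p$I_p, 0L)
  para <- X[X$compound_id == "para", ]
  expect_equal(para$I_p, 1L)
  expect_equal(para$I_m, 0L)
  expect_equal(para$sigma_p, aryl$sigma_p[aryl$substituent == "Cl"])
  expect_equal(para$sigma_m, 0)
  mp <- X[X$compound_id == "meta_para", ]
  expect_equal(mp$I_m, 1L)
  expect_equal(mp$I_p, 1L)
  expect_equal(mp$pi_arom, sum(aryl$pi_inc[aryl$substituent %in%
                                             c("CH3", "OCH3")]))
  excluded <- attr(X, "excluded")
  expect_equal(excluded$compound_id, "bad")
  expect_match(excluded$reason, "nonesuch")
})

test_that("the bridged methylenedioxy counts once and sets both indicators", {
  series <- data.frame(compound_id = "mdx", ca_sub = "CH3",
                       n_sub = "pyrrolidinyl", aryl_subs = "3,4-OCH2O",
                       stringsAsFactors = FALSE)
  series$smiles <- cathinone_smiles("CH3", "pyrrolidinyl", "3,4-OCH2O")
  X <- build_descriptor_matrix(series)
  constants <- substituent_constants()
  row <- constants[constants$substituent == "OCH2O", ]
  expect_equal(X$pi_arom, row$pi_inc)
  expect_equal(X$mr_arom, row$mr_inc)
  expect_equal(X$sigma_m, row$sigma_m)
  expect_equal(X$sigma_p, row$sigma_p)
  expect_equal(X$I_m + X$I_p, 2L)
})

test_that("OLS recovers exact linear relations and guards its inputs", {
  x <- 1:10
  fit <- suppressWarnings(ols_fit(data.frame(x = x), 2 * x + 1))
  expect_equal(fit$coefficients$estimate,
               c(1, 2), tolerance = 1e-10)
  expect_equal(fit$r2, 1)
  expect_equal(fit$n, 10L)
  expect_error(ols_fit(data.frame(x = rep(1, 10)), rnorm(10)),
               "zero-variance", class = "seltrend_data_error")
  X <- data.frame(a = x, b = 2 * x)
  expect_error(ols_fit(X, rnorm(10)), "collinear",
               class = "seltrend_data_error")
  expect_error(ols_fit(data.frame(x = 1:2), c(2, 4)),
               class = "seltrend_data_error")  # n <= p + 1
})

test_that("OLS matches a normal-equations oracle on random instances", {
  set.seed(101)
  worst <- 0
  for (i in 1:100) {
    n <- sample(10:50, 1)
    p <- sample(1:6, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("d", seq_len(p))))
    y <- rnorm(n)
    fit <- ols_fit(as.data.frame(X), y)
    Xi <- cbind(1, X)
    beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)[, 1]
    worst <- max(worst, max(abs(fit$coefficients$estimate - beta)))
  }
  expect_lt(worst, 1e-8)
})

test_that("coefficient p values are calibrated under the null", {
  set.seed(202)
  n <- 200
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  hits <- replicate(200, {
    fit <- ols_fit(X, rnorm(n))
    any(fit$coefficients$p_value[-1] < 0.05)
  })
  # each replicate rejects with prob ~ 1 - 0.95^2 ~ 0.0975
  expect_lt(mean(hits), 0.2)
})

test_that("backward elimination keeps significant models unchanged", {
  set.seed(33)
  n <- 60
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- 2 * X$a - 3 * X$b + rnorm(n, 0, 0.1)
  full <- ols_fit(X, y)
  eliminated <- backward_eliminate(X, y)
  expect_equal(eliminated$coefficients, full$coefficients)
  expect_equal(nrow(eliminated$elimination_trace), 0L)
  # alpha = 1 can never trigger a drop
  noisy <- backward_eliminate(X, rnorm(n), alpha = 1)
  expect_equal(nrow(noisy$elimination_trace), 0L)
})

test_that("elimination isolates the planted informative descriptor", {
  set.seed(44)
  n <- 50
  X <- data.frame(signal = rnorm(n), n1 = rnorm(n), n2 = rnorm(n),
                  n3 = rnorm(n))
  y <- 1.0 * X$signal + rnorm(n, 0, 0.1)
  fit <- backward_eliminate(X, y)
  retained <- setdiff(fit$coefficients$term, "(Intercept)")
  expect_true("signal" %in% retained)
  expect_true(all(fit$coefficients$p_value[
    fit$coefficients$term != "(Intercept)"] <= 0.05))
  # exhaustive best-subset oracle on the same instance: the single-descriptor
  # model {signal} has the lowest residual sum of squares among size-1 models
  rss <- sapply(names(X), function(v)
    sum(residuals(lm(y ~ X[[v]]))^2))
  expect_equal(names(which.min(rss)), "signal")
  # trace is strictly decreasing in descriptor count
  expect_equal(anyDuplicated(fit$elimination_trace$term), 0L)
})

test_that("scaling a descriptor rescales only its coefficient", {
  set.seed(55)
  n <- 40
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- X$a - 0.5 * X$b + rnorm(n, 0, 0.2)
  f1 <- ols_fit(X, y)
  X2 <- transform(X, a = a * 10)
  f2 <- ols_fit(X2, y)
  expect_equal(f2$coefficients$estimate[f2$coefficients$term == "a"] * 10,
               f1$coefficients$estimate[f1$coefficients$term == "a"],
               tolerance = 1e-8)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-8)
  expect_equal(f1$coefficients$p_value, f2$coefficients$p_value,
               tolerance = 1e-8)
})

test_that("log selectivity is the signed log potency ratio", {
  expect_equal(selectivity_response(1000, 1000), 0)
  expect_equal(selectivity_response(34500, 100), 2.5378, tolerance = 1e-4)
  expect_equal(selectivity_response(250, 1000),
               -selectivity_response(1000, 250))
  # equals pActivity_B - pActivity_A
  expect_equal(selectivity_response(34500, 100),
               to_p_activity(100) - to_p_activity(34500))
  expect_true(is.na(selectivity_response(1000, 1000, ">", "=")))
  expect_error(selectivity_response(-1, 10), class = "seltrend_data_error")
})
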