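# Weight derivation: preprocessing, the penalized fit, truncation and
# normalization, and the additive score.

test_that("preprocessing imputes with training means and z-scores columns", {
  x <- cbind(a = c(1, 2, NA), b = c(5, 5, 5), c = c(1, 2, 3))
  prep <- cssi_preprocess(x)
  # hand arithmetic: a imputed to (1, 2, 1.5) then z-scored
  expect_equal(prep$impute_means[["a"]], 1.5)
  expect_equal(prep$x[, "a"], c(-1, 1, 0), ignore_attr = TRUE)
  expect_equal(mean(prep$x[, "a"]), 0)
  expect_equal(sd(prep$x[, "a"]), 1)
  # constant column standardized to all zeros, not NaN
  expect_equal(prep$x[, "b"], c(0, 0, 0), ignore_attr = TRUE)
  # no-missing column: imputation is the identity
  expect_equal(prep$x[, "c"], (c(1, 2, 3) - 2) / 1, ignore_attr = TRUE)
  # held-out rows reuse training parameters
  new <- cssi:::apply_preprocess(
    cbind(a = c(NA, 3), b = c(9, 9), c = c(2, 2)), prep)
  expect_equal(unname(new[1, "a"]), 0)  # imputed to training mean 1.5 -> z = 0
  expect_error(cssi_preprocess(x[1, , drop = FALSE]),
               class = "cssi_argument_error")
})

test_that("a very large penalty shrinks every predictor coefficient to zero", {
  coh <- generate_cohort(300, seed = 31)
  prof <- code_risk_factors(coh)
  y <- plant_outcome(coh, c(obesity = 2), -2, seed = 1)
  prep <- cssi_preprocess(cssi:::build_design(prof, coh))
  fit <- fit_l1_logistic(prep$x, y, lambda = 50)
  expect_true(all(fit$beta == 0))
})

test_that("a strongly planted predictor is selected while noise stays at zero", {
  hits <- 0
  reps <- 20
  for (s in seq_len(reps)) {
    coh <- generate_cohort(1000, seed = 100 + s)
    prof <- code_risk_factors(coh)
    y <- plant_outcome(coh, c(dyslipidemia = 3), intercept = -3,
                       seed = 200 + s)
    prep <- cssi_preprocess(cssi:::build_design(prof, coh))
    fit <- fit_l1_logistic(prep$x, y, lambda = 0.03)
    noise <- setdiff(risk_factor_names(), "dyslipidemia")
    if (fit$beta[["dyslipidemia"]] > 0 && all(fit$beta[noise] == 0)) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / reps, 0.95)
})

test_that("a vanishing penalty recovers the unpenalized logistic fit", {
  set.seed(77)
  n <- 400
  x <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x[, 1] - 0.4 * x[, 2]))
  prep <- cssi_preprocess(x)
  fit <- fit_l1_logistic(prep$x, y, lambda = 1e-6)
  oracle <- glm(y ~ prep$x, family = binomial())
  expect_equal(unname(fit$beta), unname(coef(oracle)[-1]), tolerance = 1e-3)
  expect_equal(fit$a0, unname(coef(oracle)[1]), tolerance = 1e-3)
})

test_that("auto lambda selection stays usable with a two-member minority class", {
  coh <- generate_cohort(200, seed = 151)
  prof <- code_risk_factors(coh)
  y <- c(1L, 1L, rep(0L, 198))
  prep <- cssi_preprocess(cssi:::build_design(prof, coh))
  fit <- fit_l1_logistic(prep$x, y, lambda = "auto", seed = 1)
  expect_true(is.finite(fit$lambda) && fit$lambda > 0)
  fit2 <- fit_l1_logistic(prep$x, y, lambda = "auto", seed = 1)
  expect_identical(fit$beta, fit2$beta)
})

test_that("fitting errors are classed and informative", {
  prep_x <- cssi_preprocess(cbind(a = rnorm(20)))$x
  expect_error(fit_l1_logistic(prep_x, rep(1, 20)), class = "cssi_fit_error")
  expect_error(fit_l1_logistic(prep_x, rep(0:1, 10), lambda = -1),
               class = "cssi_argument_error")
})

test_that("truncation and normalization follow the positive-part rule", {
  expect_equal(derive_weights(c(2, -1, 2))$weight, c(0.5, 0, 0.5))
  k <- 7
  expect_equal(derive_weights(rep(3.3, k))$weight, rep(1 / k, k))
  expect_warning(w0 <- derive_weights(c(-1, 0, -0.5)),
                 class = "cssi_degenerate_weights")
  expect_equal(w0$weight, c(0, 0, 0))
  expect_error(derive_weights(numeric(0)), class = "cssi_argument_error")
  expect_error(derive_weights(rep(1, 14)), class = "cssi_argument_error")
  expect_error(derive_weights(c(bogus = 1)), class = "cssi_argument_error")
})

test_that("weights sum to one whenever any coefficient is positive", {
  set.seed(5)
  for (i in 1:50) {
    raw <- rnorm(13)
    if (all(raw <= 0)) raw[1] <- abs(raw[1]) + 0.1
    w <- derive_weights(raw)
    expect_equal(sum(w$weight), 1, tolerance = 1e-9)
    expect_true(all(w$weight >= 0))
    expect_true(all(w$weight[w$raw <= 0] == 0))
  }
})

test_that("the additive score is bounded, missing-safe and monotone in flags", {
  wts <- derive_weights(setNames(c(6.075, 3.242, 3.063, 2.992, 2.343,
                                   1.030, 0.730, 0.586, 0.465, -1, -1, 0, 0),
                                 c("dyslipidemia", "low_fitness",
                                   "abnormal_hr", "hypertension", "ecg",
                                   "alcohol", "pulmonary", "liver_enzymes",
                                   "obesity", "smoking", "diabetes",
                                   "anemia", "hearing_loss")))
  mkprof <- function(flags) {
    p <- as.data.frame(as.list(setNames(flags, risk_factor_names())))
    p$id <- "W1"
    p$category <- assign_category(sum(flags, na.rm = TRUE))
    p
  }
  expect_equal(compute_score(mkprof(rep(0L, 13)), wts)$cssi_score, 0)
  expect_equal(compute_score(mkprof(rep(1L, 13)), wts)$cssi_score, 100)
  # two printed weights: dyslipidemia + hypertension -> 44.2 on the 0-100 scale
  fl <- setNames(rep(0L, 13), risk_factor_names())
  fl[c("dyslipidemia", "hypertension")] <- 1L
  expect_equal(round_half_up(compute_score(mkprof(fl), wts)$cssi_score, 1),
               44.2)
  # NA flags contribute zero
  flna <- fl
  flna[] <- NA_integer_
  flna <- as.integer(flna)
  expect_equal(compute_score(mkprof(flna), wts)$cssi_score, 0)
  # property: setting any flag 0 -> 1 never decreases the score
  set.seed(11)
  for (i in 1:30) {
    base <- rbinom(13, 1, 0.3)
    j <- sample(which(base == 0), 1)
    up <- base
    up[j] <- 1L
    expect_gte(compute_score(mkprof(up), wts)$cssi_score,
               compute_score(mkprof(base), wts)$cssi_score)
  }
})

test_that("cssi_fit returns a coherent model object with working methods", {
  coh <- generate_cohort(400, seed = 41)
  prof <- code_risk_factors(coh)
  fit <- cssi_fit(prof, coh, lambda = 0.01, seed = 1)
  expect_s3_class(fit, "cssi_fit")
  expect_named(weights(fit), risk_factor_names())
  expect_equal(sum(weights(fit)), 1, tolerance = 1e-9)
  expect_setequal(names(coef(fit)), c(risk_factor_names(), "age", "sex_male"))
  # covariates never enter the weight set
  expect_false(any(c("age", "sex_male") %in% fit$weights$factor))
  expect_equal(predict(fit, prof, coh, type = "score"),
               compute_score(prof, fit)$cssi_score)
  expect_equal(predict(fit, prof, coh, type = "response"), fit$fitted_prob,
               tolerance = 1e-12)
  expect_length(residuals(fit), nrow(prof))
  expect_output(print(fit), "lambda")
  expect_output(print(summary(fit)), "truncated")
  # determinism of the auto policy
  f1 <- cssi_fit(prof, coh, lambda = "auto", seed = 3)
  f2 <- cssi_fit(prof, coh, lambda = "auto", seed = 3)
  expect_equal(f1$weights, f2$weights)
})

test_that("planted effect ordering is recovered in the weight ranking", {
  coh <- generate_cohort(2000, seed = 55)
  prof <- code_risk_factors(coh)
  y <- plant_outcome(coh, c(dyslipidemia = 3, obesity = 2, alcohol = 1),
                     intercept = -4, seed = 56)
  fit <- cssi_fit(prof, coh, lambda = 0.01, outcome = y)
  w <- weights(fit)
  expect_equal(names(sort(w, decreasing = TRUE))[1:3],
               c("dyslipidemia", "obesity", "alcohol"))
})
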