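# Synthetic worker-cohort generator.
#
# Continuous variables are drawn through a Gaussian copula with per-sex
# marginal mean/SD and clipped to physiologic bounds. For variables whose
# configured normal puts non-negligible mass outside the bounds (pack-years,
# alcohol frequency, liver enzymes, triglycerides), the latent normal
# parameters are moment-matched so that the *clipped* variable reproduces the
# configured mean and SD; clipping then yields a realistic point mass at the
# floor (e.g. never-smokers at 0 pack-years) without biasing the marginals.

# variable order is the copula dimension order
.cssi_cont_vars <- c(
  "age", "bmi", "waist", "sbp", "dbp", "resting_hr", "fasting_glucose",
  "hba1c", "total_chol", "ldl", "hdl", "triglycerides", "ast", "alt",
  "ggtp", "hemoglobin", "pta_0_5_4k", "fev1_fvc", "fev1_pred", "vo2max",
  "pack_years", "alcohol_per_week"
)

.cssi_binary_vars <- c(
  "on_antihypertensive", "on_antidiabetic", "on_lipid_lowering",
  "ecg_abnormal"
)

#' Cohort generator parameters
#'
#' Returns the parameter set used by [generate_cohort()]. Defaults are the
#' sex-stratified marginal means and standard deviations of the study
#' population's baseline characteristics (age, anthropometrics, blood
#' pressure, resting heart rate, glycemic and lipid panels, liver enzymes,
#' hemoglobin, pure-tone average, spirometry, VO2max, pack-years, alcohol
#' frequency), a male fraction of 72/111, and plausible prevalences for
#' medication flags and ECG abnormality. Any element can be overridden via
#' `...` (e.g. `cohort_params(sex_fraction_male = 0.5)`).
#'
#' @param correlation either a correlation matrix over the 22 continuous
#'   variables (unit diagonal, symmetric, positive semi-definite), or one of
#'   `"identity"` (default: independent marginals) / `"realistic"` (a
#'   documented non-study preset adding BMI-waist r = 0.8, SBP-DBP r = 0.7,
#'   total-LDL cholesterol r = 0.85).
#' @param miss_rate missingness injection rate in \[0,1\] applied uniformly to
#'   continuous measurements (default 0: complete records).
#' @param ... named overrides for `means`, `sds`, `bounds`,
#'   `sex_fraction_male`, `prevalence`.
#'
#' @return A list of class `cssi_params` with elements `means` and `sds`
#'   (named lists `male`/`female` of named numeric vectors), `bounds`
#'   (2-column matrix of lower/upper physiologic limits), `sex_fraction_male`,
#'   `prevalence` (per-sex named lists for the binary flags), `correlation`,
#'   and `miss_rate`.
#' @export
#' @examples
#' p <- cohort_params()
#' p$means$male[["vo2max"]]   # 34.5
cohort_params <- function(correlation = "identity", miss_rate = 0, ...) {
  male_mean <- c(
    age = 44.5, bmi = 25.0, waist = 83.9, sbp = 123.8, dbp = 76.7,
    resting_hr = 64.6, fasting_glucose = 97.2, hba1c = 5.7,
    total_chol = 198.9, ldl = 119.4, hdl = 54.7, triglycerides = 150.0,
    ast = 27.6, alt = 35.0, ggtp = 33.4, hemoglobin = 15.6,
    pta_0_5_4k = 15.1, fev1_fvc = 84.4, fev1_pred = 88.0, vo2max = 34.5,
    pack_years = 7.8, alcohol_per_week = 1.3
  )
  male_sd <- c(
    age = 10.7, bmi = 2.9, waist = 8.1, sbp = 10.4, dbp = 9.0,
    resting_hr = 10.1, fasting_glucose = 8.7, hba1c = 0.4,
    total_chol = 36.7, ldl = 33.0, hdl = 15.6, triglycerides = 103.8,
    ast = 16.0, alt = 32.8, ggtp = 23.2, hemoglobin = 1.0,
    pta_0_5_4k = 9.1, fev1_fvc = 6.4, fev1_pred = 9.2, vo2max = 5.3,
    pack_years = 11.2, alcohol_per_week = 1.2
  )
  female_mean <- c(
    age = 44.0, bmi = 23.0, waist = 71.1, sbp = 116.7, dbp = 71.0,
    resting_hr = 67.1, fasting_glucose = 94.5, hba1c = 5.7,
    total_chol = 210.3, ldl = 127.9, hdl = 63.9, triglycerides = 109.9,
    ast = 21.7, alt = 20.7, ggtp = 15.2, hemoglobin = 13.3,
    pta_0_5_4k = 11.5, fev1_fvc = 83.3, fev1_pred = 88.2, vo2max = 28.8,
    pack_years = 0.0, alcohol_per_week = 0.3
  )
  female_sd <- c(
    age = 8.9, bmi = 3.2, waist = 8.9, sbp = 10.8, dbp = 8.8,
    resting_hr = 9.3, fasting_glucose = 14.1, hba1c = 0.5,
    total_chol = 29.5, ldl = 28.9, hdl = 14.2, triglycerides = 55.5,
    ast = 10.0, alt = 13.8, ggtp = 10.9, hemoglobin = 1.0,
    pta_0_5_4k = 4.6, fev1_fvc = 5.0, fev1_pred = 7.8, vo2max = 3.6,
    pack_years = 0.0, alcohol_per_week = 0.7
  )
  bounds <- rbind(
    age = c(18, 70), bmi = c(12, 60), waist = c(40, 200),
    sbp = c(60, 260), dbp = c(30, 160), resting_hr = c(25, 220),
    fasting_glucose = c(30, 600), hba1c = c(3, 20),
    total_chol = c(50, 600), ldl = c(10, 500), hdl = c(10, 200),
    triglycerides = c(10, 2000), ast = c(5, 2000), alt = c(3, 2000),
    ggtp = c(3, 2000), hemoglobin = c(4, 22), pta_0_5_4k = c(-10, 120),
    fev1_fvc = c(20, 100), fev1_pred = c(20, 150), vo2max = c(5, 90),
    pack_years = c(0, 150), alcohol_per_week = c(0, 30)
  )
  colnames(bounds) <- c("lower", "upper")

  prevalence <- list(
    male = c(on_antihypertensive = 0.12, on_antidiabetic = 0.03,
             on_lipid_lowering = 0.06, ecg_abnormal = 0.153),
    female = c(on_antihypertensive = 0.05, on_antidiabetic = 0.03,
               on_lipid_lowering = 0.04, ecg_abnormal = 0.103)
  )

  params <- list(
    means = list(male = male_mean, female = female_mean),
    sds = list(male = male_sd, female = female_sd),
    bounds = bounds,
    sex_fraction_male = 72 / 111,
    prevalence = prevalence,
    correlation = correlation,
    miss_rate = miss_rate
  )
  params <- modifyList(params, list(...))
  params$correlation <- resolve_correlation(params$correlation)
  class(params) <- "cssi_params"
  validate_params(params)
  params
}

#' @rdname cohort_params
#' @param name preset name, `"identity"` or `"realistic"`.
#' @export
correlation_preset <- function(name = c("identity", "realistic")) {
  name <- match.arg(name)
  k <- length(.cssi_cont_vars)
  r <- diag(k)
  dimnames(r) <- list(.cssi_cont_vars, .cssi_cont_vars)
  if (name == "realistic") {
    set_r <- function(a, b, v) {
      r[a, b] <<- v
      r[b, a] <<- v
    }
    set_r("bmi", "waist", 0.8)
    set_r("sbp", "dbp", 0.7)
    set_r("total_chol", "ldl", 0.85)
  }
  r
}

resolve_correlation <- function(correlation) {
  if (is.character(correlation) && length(correlation) == 1L) {
    return(correlation_preset(correlation))
  }
  correlation
}

validate_params <- function(params) {
  for (sex in c("male", "female")) {
    m <- params$means[[sex]]
    s <- params$sds[[sex]]
    if (!all(.cssi_cont_vars %in% names(m)) ||
        !all(.cssi_cont_vars %in% names(s))) {
      cssi_stop(sprintf("means/sds for %s must cover all continuous variables",
                        sex), "cssi_config_error")
    }
    if (any(s < 0)) {
      cssi_stop(sprintf("negative sd for %s: %s", sex,
                        paste(names(s)[s < 0], collapse = ", ")),
                "cssi_config_error")
    }
    pv <- params$prevalence[[sex]]
    if (any(pv < 0 | pv > 1)) {
      cssi_stop(sprintf("prevalence outside [0,1] for %s: %s", sex,
                        paste(names(pv)[pv < 0 | pv > 1], collapse = ", ")),
                "cssi_config_error")
    }
  }
  r <- params$correlation
  k <- length(.cssi_cont_vars)
  if (!is.matrix(r) || nrow(r) != k || ncol(r) != k) {
    cssi_stop(sprintf("correlation must be a %d x %d matrix", k, k),
              "cssi_config_error")
  }
  if (any(abs(diag(r) - 1) > 1e-10)) {
    bad <- .cssi_cont_vars[which(abs(diag(r) - 1) > 1e-10)[1]]
    cssi_stop(sprintf("correlation diagonal entry for '%s' is not 1", bad),
              "cssi_config_error")
  }
  if (any(abs(r - t(r)) > 1e-10)) {
    idx <- which(abs(r - t(r)) > 1e-10, arr.ind = TRUE)[1, ]
    cssi_stop(sprintf("correlation entry (%s, %s) is not symmetric",
                      .cssi_cont_vars[idx[1]], .cssi_cont_vars[idx[2]]),
              "cssi_config_error")
  }
  ev <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    cssi_stop("correlation matrix is not positive semi-definite",
              "cssi_config_error")
  }
  if (params$miss_rate < 0 || params$miss_rate > 1) {
    cssi_stop("miss_rate must be in [0,1]", "cssi_config_error")
  }
  invisible(params)
}

# Moments of Z ~ N(mu, sigma) clipped to [a, b].
clipped_norm_moments <- function(mu, sigma, a, b) {
  if (sigma <= 0) {
    x <- min(max(mu, a), b)
    return(c(mean = x, sd = 0))
  }
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  pa <- pnorm(al)
  pb <- 1 - pnorm(be)
  d <- pnorm(be) - pnorm(al)
  if (d < 1e-12) {
    # essentially all mass clipped to one side
    e <- a * pa + b * pb
    e2 <- a^2 * pa + b^2 * pb
    return(c(mean = e, sd = sqrt(max(e2 - e^2, 0))))
  }
  m1t <- mu + sigma * (dnorm(al) - dnorm(be)) / d
  m2t <- mu^2 + sigma^2 +
    sigma * ((a + mu) * dnorm(al) - (b + mu) * dnorm(be)) / d
  e <- a * pa + b * pb + d * m1t
  e2 <- a^2 * pa + b^2 * pb + d * m2t
  c(mean = e, sd = sqrt(max(e2 - e^2, 0)))
}

# Latent normal parameters whose clipped distribution matches target moments.
# Returns c(mu, sigma). Identity when clipping mass is negligible.
match_clipped_params <- function(target_mean, target_sd, a, b) {
  if (target_sd == 0) {
    return(c(mu = target_mean, sigma = 0))
  }
  clip_mass <- pnorm((a - target_mean) / target_sd) +
    1 - pnorm((b - target_mean) / target_sd)
  if (clip_mass < 5e-4) {
    return(c(mu = target_mean, sigma = target_sd))
  }
  obj <- function(par) {
    mom <- clipped_norm_moments(par[1], exp(par[2]), a, b)
    (mom[["mean"]] - target_mean)^2 / target_sd^2 +
      (mom[["sd"]] - target_sd)^2 / target_sd^2
  }
  fit <- optim(c(target_mean, log(target_sd)), obj,
               control = list(reltol = 1e-14, maxit = 5000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Generate a synthetic worker cohort
#'
#' Draws `n` worker records with the configured sex split, Gaussian-copula
#' continuous measurements clipped to physiologic bounds, and Bernoulli
#' medication/ECG flags. Identical `(params, n, seed)` give identical output.
#'
#' @param n number of workers (>= 0).
#' @param params a [cohort_params()] object.
#' @param seed integer RNG seed.
#' @return A data.frame with one row per worker: `id`, `sex`
#'   (`"male"`/`"female"`), the 22 continuous measurements, and the four
#'   logical flags (`on_antihypertensive`, `on_antidiabetic`,
#'   `on_lipid_lowering`, `ecg_abnormal`).
#' @export
#' @examples
#' coh <- generate_cohort(50, seed = 1)
#' mean(coh$vo2max[coh$sex == "male"])
generate_cohort <- function(n, params = cohort_params(), seed = 1) {
  if (!inherits(params, "cssi_params")) {
    params <- do.call(cohort_params, params)
  }
  validate_params(params)
  if (length(n) != 1L || is.na(n) || n < 0 || n != floor(n)) {
    cssi_stop("n must be a single non-negative integer", "cssi_argument_error")
  }
  n <- as.integer(n)
  vars <- .cssi_cont_vars
  empty <- data.frame(
    id = character(), sex = character(),
    matrix(numeric(), 0, length(vars), dimnames = list(NULL, vars)),
    on_antihypertensive = logical(), on_antidiabetic = logical(),
    on_lipid_lowering = logical(), ecg_abnormal = logical(),
    stringsAsFactors = FALSE
  )
  if (n == 0L) {
    return(empty)
  }

  set.seed(as.integer(seed))
  sex <- ifelse(runif(n) < params$sex_fraction_male, "male", "female")

  # copula draw: correlated standard normals
  ch <- chol(params$correlation + diag(1e-10, length(vars)))
  z <- matrix(rnorm(n * length(vars)), n, length(vars)) %*% ch
  colnames(z) <- vars

  x <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
  for (sx in c("male", "female")) {
    rows <- sex == sx
    if (!any(rows)) next
    for (v in vars) {
      a <- params$bounds[v, "lower"]
      b <- params$bounds[v, "upper"]
      lat <- match_clipped_params(params$means[[sx]][[v]],
                                  params$sds[[sx]][[v]], a, b)
      val <- lat[["mu"]] + lat[["sigma"]] * z[rows, v]
      x[rows, v] <- pmin(pmax(val, a), b)
    }
  }

  flags <- matrix(FALSE, n, length(.cssi_binary_vars),
                  dimnames = list(NULL, .cssi_binary_vars))
  for (sx in c("male", "female")) {
    rows <- which(sex == sx)
    if (!length(rows)) next
    for (v in .cssi_binary_vars) {
      flags[rows, v] <- runif(length(rows)) < params$prevalence[[sx]][[v]]
    }
  }

  cohort <- data.frame(
    id = sprintf("W%05d", seq_len(n)), sex = sex, x, flags,
    stringsAsFactors = FALSE
  )

  if (params$miss_rate > 0) {
    # age stays complete: it anchors the VO2max reference banding
    for (v in setdiff(vars, "age")) {
      drop <- runif(n) < params$miss_rate
      cohort[[v]][drop] <- NA_real_
    }
  }
  cohort
}

#' Plant a binary outcome on a cohort
#'
#' Draws Bernoulli labels from a logistic model on the coded risk-factor
#' flags: `P(y = 1) = plogis(intercept + sum(w_i * flag_i))`, with flags
#' computed by [code_risk_factors()] under the default cutoffs. Used for
#' parameter-recovery tests of the weighting stage.
#'
#' @param cohort a cohort data.frame from [generate_cohort()] or
#'   [read_cohort_csv()].
#' @param true_weights named numeric vector; names must be risk-factor names
#'   (see [risk_factor_names()]). Unnamed factors get weight 0.
#' @param intercept log-odds intercept.
#' @param seed integer RNG seed.
#' @param cutoffs cutoff configuration, default [cssi_cutoffs()].
#' @return Integer vector of 0/1 labels, one per worker.
#' @export
plant_outcome <- function(cohort, true_weights, intercept, seed = 1,
                          cutoffs = cssi_cutoffs()) {
  bad <- setdiff(names(true_weights), risk_factor_names())
  if (length(bad)) {
    cssi_stop(paste0("unknown risk factor name(s): ",
                     paste(bad, collapse = ", ")), "cssi_argument_error")
  }
  profiles <- code_risk_factors(cohort, cutoffs)
  w <- setNames(numeric(length(risk_factor_names())), risk_factor_names())
  w[names(true_weights)] <- true_weights
  fl <- as.matrix(profiles[, risk_factor_names()])
  fl[is.na(fl)] <- 0
  eta <- intercept + as.vector(fl %*% w)
  set.seed(as.integer(seed))
  rbinom(nrow(cohort), 1L, plogis(eta))
}
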