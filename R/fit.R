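# CSSI weight derivation: L1-penalized logistic regression of the rule-based
# unsuitable label on the 13 flags plus age and sex, coefficient truncation at
# zero, and normalization of the positive part to an additive weight set.

.cssi_design_cols <- function() c(risk_factor_names(), "age", "sex_male")

# Assemble the raw (unstandardized, NA-preserving) design matrix.
build_design <- function(profiles, cohort) {
  if (nrow(profiles) != nrow(cohort)) {
    idx <- match(profiles$id, cohort$id)
    if (any(is.na(idx))) {
      cssi_stop("profiles contain ids absent from the cohort",
                "cssi_schema_error")
    }
    cohort <- cohort[idx, , drop = FALSE]
  }
  x <- as.matrix(profiles[, risk_factor_names(), drop = FALSE])
  storage.mode(x) <- "double"
  x <- cbind(x, age = cohort$age,
             sex_male = as.numeric(cohort$sex == "male"))
  rownames(x) <- profiles$id
  x
}

#' Preprocess a design matrix (mean imputation + z-scoring)
#'
#' Column means for imputation and the z-score center/scale are computed on
#' the supplied (training) rows only and returned, so that held-out rows can
#' be transformed with the training parameters (no leakage across
#' cross-validation folds). Zero-variance columns are standardized to
#' all-zeros rather than NaN.
#'
#' @param x numeric matrix, possibly with NAs.
#' @param standardize z-score after imputation (default TRUE).
#' @return list of class `cssi_prep`: `x` (transformed matrix),
#'   `impute_means`, `center`, `scale` (named vectors), `standardize`.
#' @export
cssi_preprocess <- function(x, standardize = TRUE) {
  if (!is.matrix(x) || ncol(x) == 0) {
    cssi_stop("design matrix must have at least one column",
              "cssi_argument_error")
  }
  if (nrow(x) < 2) {
    cssi_stop("at least 2 rows are required for preprocessing",
              "cssi_argument_error")
  }
  imp <- colMeans(x, na.rm = TRUE)
  imp[!is.finite(imp)] <- 0  # all-missing column
  for (j in seq_len(ncol(x))) {
    x[is.na(x[, j]), j] <- imp[j]
  }
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, sd)
    scl[scl == 0] <- Inf  # zero-variance column -> all zeros
    x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
    scl[!is.finite(scl)] <- 0
  } else {
    ctr <- setNames(rep(0, ncol(x)), colnames(x))
    scl <- setNames(rep(1, ncol(x)), colnames(x))
  }
  structure(list(x = x, impute_means = imp, center = ctr, scale = scl,
                 standardize = standardize),
            class = "cssi_prep")
}

# Transform new rows with training imputation/standardization parameters.
apply_preprocess <- function(x, prep) {
  for (j in seq_len(ncol(x))) {
    x[is.na(x[, j]), j] <- prep$impute_means[j]
  }
  if (prep$standardize) {
    scl <- prep$scale
    scl[scl == 0] <- Inf
    x <- sweep(sweep(x, 2, prep$center), 2, scl, "/")
  }
  x
}

# Rare outcomes make glmnet's small-class advisory fire on nearly every
# leave-one-out fold and bootstrap resample; it is structural here (the
# unsuitable class is rare by design), so that one message is muffled.
quiet_glmnet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8  ?observations", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

# Deterministic stratified fold assignment (both classes spread over folds).
stratified_folds <- function(y, nfolds, seed) {
  set.seed(as.integer(seed))
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    foldid[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  foldid
}

#' L1-penalized logistic fit
#'
#' Fits `glmnet(family = "binomial")` on a pre-standardized design
#' (`standardize = FALSE`, intercept unpenalized). `lambda = "auto"` selects
#' the penalty by seeded stratified k-fold cross-validated deviance
#' (`lambda.min`); a positive numeric fixes it. When the minority class has
#' only two members (possible in bootstrap resamples of a rare outcome),
#' cross-validation is infeasible and the auto policy falls back to the
#' deterministic BIC minimum along the penalty path. Deterministic given
#' `(x, y, lambda, seed)`.
#'
#' @param x preprocessed design matrix.
#' @param y 0/1 outcome vector with both classes present.
#' @param lambda `"auto"` or a positive number.
#' @param seed integer seed for fold assignment.
#' @param nfolds folds for the auto policy (default 5; reduced if a class is
#'   smaller).
#' @return list: `a0` (intercept), `beta` (named coefficient vector on the
#'   standardized scale), `lambda` (the value used), `lambda_policy`.
#' @export
fit_l1_logistic <- function(x, y, lambda = "auto", seed = 1, nfolds = 5) {
  y <- as.integer(y)
  if (min(sum(y == 1), sum(y == 0)) < 2) {
    cssi_stop("each outcome class needs at least 2 observations; a larger or more balanced sample is required",
              "cssi_fit_error")
  }
  policy <- if (identical(lambda, "auto")) "auto" else "fixed"
  if (policy == "fixed" && (!is.numeric(lambda) || lambda <= 0)) {
    cssi_stop("lambda must be \"auto\" or a positive number",
              "cssi_argument_error")
  }
  if (policy == "auto") {
    k <- min(nfolds, sum(y == 1), sum(y == 0))
    if (k >= 3) {
      foldid <- stratified_folds(y, k, seed)
      cvfit <- quiet_glmnet(glmnet::cv.glmnet(x, y, family = "binomial",
                                              standardize = FALSE,
                                              foldid = foldid,
                                              type.measure = "deviance"))
      lambda <- cvfit$lambda.min
      cf <- as.matrix(coef(cvfit, s = "lambda.min"))
      beta <- setNames(cf[-1, 1], rownames(cf)[-1])
      return(list(a0 = cf[1, 1], beta = beta, lambda = lambda,
                  lambda_policy = policy))
    }
    # a minority class of 2 cannot be split for cross-validation (every
    # training part would hold a single member); fall back to a
    # deterministic BIC minimum along the penalty path
    path <- quiet_glmnet(glmnet::glmnet(x, y, family = "binomial",
                                        standardize = FALSE))
    dev <- (1 - path$dev.ratio) * path$nulldev
    bic <- dev + path$df * log(length(y))
    lambda <- path$lambda[which.min(bic)]
    cf <- as.matrix(coef(path, s = lambda))
  } else {
    fit <- quiet_glmnet(glmnet::glmnet(x, y, family = "binomial",
                                       standardize = FALSE))
    cf <- as.matrix(quiet_glmnet(coef(fit, s = lambda, exact = TRUE, x = x,
                                      y = y, family = "binomial",
                                      standardize = FALSE)))
  }
  beta <- setNames(cf[-1, 1], rownames(cf)[-1])
  list(a0 = cf[1, 1], beta = beta, lambda = lambda, lambda_policy = policy)
}

#' Truncate and normalize raw coefficients into additive weights
#'
#' Implements the positive-part weighting rule: negative or zero raw
#' coefficients get weight exactly 0 (so no factor is interpreted as
#' protective in the screening index), and the positive coefficients are
#' normalized to sum to 1. If no coefficient is positive a degenerate
#' all-zero weight set is returned with a warning.
#'
#' @param raw numeric vector of raw coefficients for the risk factors
#'   (covariate coefficients must be excluded beforehand). If unnamed and of
#'   length 13 the canonical factor names are assumed.
#' @return data.frame of class `cssi_weights` with columns `factor`, `raw`,
#'   `truncated`, `weight`.
#' @export
#' @examples
#' w <- derive_weights(c(dyslipidemia = 6.075, hypertension = 2.992,
#'                       obesity = 0.465, anemia = -0.2))
#' w$weight
derive_weights <- function(raw) {
  if (!is.numeric(raw) || length(raw) < 1 || length(raw) > 13) {
    cssi_stop("raw coefficients must be a numeric vector of length 1-13",
              "cssi_argument_error")
  }
  if (is.null(names(raw))) {
    if (length(raw) == length(risk_factor_names())) {
      names(raw) <- risk_factor_names()
    } else {
      names(raw) <- paste0("factor", seq_along(raw))
    }
  } else {
    bad <- setdiff(names(raw), risk_factor_names())
    if (length(bad)) {
      cssi_stop(paste0("unknown risk factor name(s): ",
                       paste(bad, collapse = ", ")), "cssi_argument_error")
    }
  }
  trunc <- pmax(raw, 0)
  total <- sum(trunc)
  if (total <= 0) {
    cssi_warn("all raw coefficients are non-positive; weight set is degenerate (all zeros)",
              "cssi_degenerate_weights")
    w <- trunc * 0
  } else {
    w <- trunc / total
  }
  out <- data.frame(factor = names(raw), raw = unname(raw),
                    truncated = unname(trunc), weight = unname(w),
                    stringsAsFactors = FALSE)
  class(out) <- c("cssi_weights", "data.frame")
  out
}

#' Compute the additive 0-100 CSSI score
#'
#' Multiplies each worker's binary risk-factor flags by the normalized
#' additive weights and sums: `raw_score = sum(flag_i * weight_i)` in
#' \[0,1\], `cssi_score = 100 * raw_score`. Missing flags contribute 0.
#'
#' @param profiles a [code_risk_factors()] result.
#' @param weights a `cssi_weights` data.frame, a fitted [cssi_fit()] object,
#'   or a named numeric vector of normalized weights.
#' @return data.frame: `id`, `raw_score`, `cssi_score`, `category`.
#' @export
compute_score <- function(profiles, weights) {
  if (inherits(weights, "cssi_fit")) weights <- weights$weights
  if (inherits(weights, "data.frame")) {
    weights <- setNames(weights$weight, weights$factor)
  }
  bad <- setdiff(names(weights), risk_factor_names())
  if (length(bad)) {
    cssi_stop(paste0("unknown risk factor name(s) in weights: ",
                     paste(bad, collapse = ", ")), "cssi_argument_error")
  }
  fl <- as.matrix(profiles[, names(weights), drop = FALSE])
  storage.mode(fl) <- "double"
  fl[is.na(fl)] <- 0
  raw <- as.vector(fl %*% weights)
  data.frame(id = profiles$id, raw_score = raw, cssi_score = 100 * raw,
             category = profiles$category, stringsAsFactors = FALSE)
}

#' Fit the Confined-Space Suitability Index weighting model
#'
#' The central fitting function. The outcome is the rule-based unsuitable
#' classification (`category == "unsuitable"`, i.e. six or more of the 13
#' risk factors); predictors are the 13 dichotomous flags with age and sex
#' as covariates. Missing predictor values are mean-imputed and the design
#' z-scored (training parameters retained for out-of-sample prediction), an
#' L1-penalized logistic model is fitted, and the 13 factor coefficients are
#' truncated at zero and normalized into the additive weight set used for
#' the 0-100 score. Covariate coefficients never enter the weights.
#'
#' @param profiles a [code_risk_factors()] result.
#' @param cohort the matching cohort data.frame (source of age and sex).
#' @param lambda `"auto"` (seeded 5-fold stratified cross-validated deviance
#'   minimum) or a positive number.
#' @param seed integer seed for fold assignment.
#' @param standardize z-score the design (default TRUE).
#' @param outcome optional explicit 0/1 outcome vector overriding the
#'   rule-based label (used for planted-outcome experiments).
#' @return An object of class `cssi_fit` with components `weights` (a
#'   `cssi_weights` data.frame), `coefficients` (all raw coefficients on the
#'   standardized scale, including covariates), `a0`, `lambda`, `prep`
#'   (preprocessing parameters), `scores` (training-set score table), `n`,
#'   `n_unsuitable`, `call`. Methods: `print`, `summary`, `coef`, `weights`,
#'   `predict`, `plot`, `residuals`.
#' @export
#' @examples
#' coh <- generate_cohort(200, seed = 2)
#' prof <- code_risk_factors(coh)
#' fit <- cssi_fit(prof, coh, lambda = 0.01)
#' weights(fit)
cssi_fit <- function(profiles, cohort, lambda = "auto", seed = 1,
                     standardize = TRUE, outcome = NULL) {
  if (is.null(outcome)) {
    outcome <- as.integer(profiles$category == "unsuitable")
  }
  if (length(outcome) != nrow(profiles)) {
    cssi_stop("outcome length must match the number of workers",
              "cssi_argument_error")
  }
  x <- build_design(profiles, cohort)
  prep <- cssi_preprocess(x, standardize = standardize)
  fit <- fit_l1_logistic(prep$x, outcome, lambda = lambda, seed = seed)
  wts <- derive_weights(fit$beta[risk_factor_names()])
  scores <- compute_score(profiles, wts)
  obj <- list(
    weights = wts,
    coefficients = fit$beta,
    a0 = fit$a0,
    lambda = fit$lambda,
    lambda_policy = fit$lambda_policy,
    seed = seed,
    prep = prep[c("impute_means", "center", "scale", "standardize")],
    outcome = outcome,
    fitted_prob = as.vector(plogis(fit$a0 + prep$x %*% fit$beta)),
    scores = scores,
    n = nrow(profiles),
    n_unsuitable = sum(outcome),
    call = match.call()
  )
  class(obj) <- "cssi_fit"
  obj
}

#' @export
print.cssi_fit <- function(x, ...) {
  cat("Confined-Space Suitability Index fit\n")
  cat(sprintf("  n = %d workers, %d unsuitable (outcome)\n",
              x$n, x$n_unsuitable))
  cat(sprintf("  lambda = %.6g (%s)\n", x$lambda, x$lambda_policy))
  pos <- x$weights[x$weights$weight > 0, ]
  pos <- pos[order(-pos$weight), ]
  if (nrow(pos)) {
    cat("  positive-weight factors:\n")
    for (i in seq_len(nrow(pos))) {
      cat(sprintf("    %-15s %.3f\n", pos$factor[i], pos$weight[i]))
    }
  } else {
    cat("  degenerate fit: all weights zero\n")
  }
  invisible(x)
}

#' @export
summary.cssi_fit <- function(object, ...) {
  s <- list(
    weights = object$weights[order(-object$weights$weight), ],
    covariates = object$coefficients[c("age", "sex_male")],
    lambda = object$lambda, lambda_policy = object$lambda_policy,
    n = object$n, n_unsuitable = object$n_unsuitable,
    score_summary = summary(object$scores$cssi_score)
  )
  class(s) <- "summary.cssi_fit"
  s
}

#' @export
print.summary.cssi_fit <- function(x, ...) {
  cat("CSSI weight set (raw L1 coefficient -> truncated -> normalized):\n")
  print(x$weights, row.names = FALSE, digits = 3)
  cat(sprintf("\nCovariate coefficients (not weighted): age %.3f, sex(male) %.3f\n",
              x$covariates[["age"]], x$covariates[["sex_male"]]))
  cat(sprintf("lambda = %.6g (%s); n = %d, unsuitable = %d\n",
              x$lambda, x$lambda_policy, x$n, x$n_unsuitable))
  cat("CSSI score distribution (0-100):\n")
  print(x$score_summary)
  invisible(x)
}

#' @export
coef.cssi_fit <- function(object, ...) object$coefficients

#' @export
weights.cssi_fit <- function(object, ...) {
  setNames(object$weights$weight, object$weights$factor)
}

#' Predict from a CSSI fit
#'
#' @param object a [cssi_fit()] object.
#' @param profiles,cohort new data (default: training data predictions).
#' @param type `"response"` (penalized-logistic probability of the
#'   unsuitable class), `"score"` (additive 0-100 CSSI score), or `"class"`
#'   (probability >= 0.5).
#' @param ... unused.
#' @return numeric (or integer for `"class"`) vector, one value per worker.
#' @export
predict.cssi_fit <- function(object, profiles = NULL, cohort = NULL,
                             type = c("response", "score", "class"), ...) {
  type <- match.arg(type)
  if (is.null(profiles)) {
    if (type == "response") return(object$fitted_prob)
    if (type == "score") return(object$scores$cssi_score)
    return(as.integer(object$fitted_prob >= 0.5))
  }
  if (type == "score") {
    return(compute_score(profiles, object)$cssi_score)
  }
  x <- build_design(profiles, cohort)
  prep <- object$prep
  class(prep) <- "cssi_prep"
  xs <- apply_preprocess(x, prep)
  p <- as.vector(plogis(object$a0 + xs %*% object$coefficients))
  if (type == "class") as.integer(p >= 0.5) else p
}

#' @export
residuals.cssi_fit <- function(object, ...) {
  object$outcome - object$fitted_prob
}

#' @export
plot.cssi_fit <- function(x, ...) {
  w <- x$weights[order(x$weights$weight), ]
  op <- par(mar = c(4, 9, 2, 1))
  on.exit(par(op))
  barplot(w$weight, names.arg = w$factor, horiz = TRUE, las = 1,
          xlab = "normalized additive CSSI weight",
          main = "CSSI factor weights", ...)
  invisible(x)
}
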