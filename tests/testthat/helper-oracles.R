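# Independent oracles used to cross-check the implementation. These are
# deliberately naive re-implementations (brute-force enumeration, direct
# per-record predicates, an explicit refit loop) kept separate from the
# package code paths they verify.

# AUROC by exhaustive pairwise comparison, ties counted one half.
bruteforce_auroc <- function(prob, y) {
  pos <- prob[y == 1]
  neg <- prob[y == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# AUPRC by direct threshold sweep: counts recomputed from scratch at every
# distinct probability, precision-weighted recall increments summed.
bruteforce_auprc <- function(prob, y) {
  npos <- sum(y == 1)
  thresholds <- sort(unique(prob), decreasing = TRUE)
  ap <- 0
  prev_recall <- 0
  for (t in thresholds) {
    tp <- sum(prob >= t & y == 1)
    fp <- sum(prob >= t & y == 0)
    recall <- tp / npos
    precision <- tp / (tp + fp)
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Independent per-record predicates for the 13 operational cutoff rules,
# written as plain disjunctions over a single row. Missing handling: TRUE
# wins, all-missing is NA, otherwise FALSE.
oracle_flags <- function(row, ref = vo2max_reference_default()) {
  male <- row$sex == "male"
  dj <- function(...) {
    v <- c(...)
    if (any(v %in% TRUE)) 1L else if (all(is.na(v))) NA_integer_ else 0L
  }
  vo2_low <- if (is.na(row$vo2max)) NA_integer_ else {
    band <- ref[ref$sex == row$sex & ref$age_min <= row$age &
                  row$age < ref$age_max, ]
    as.integer(row$vo2max < band$lower_bound[1])
  }
  c(
    obesity = dj(row$bmi >= 25, row$waist >= if (male) 90 else 85),
    hypertension = dj(row$sbp >= 140, row$dbp >= 90, row$on_antihypertensive),
    diabetes = dj(row$fasting_glucose >= 126, row$hba1c >= 6.5,
                  row$on_antidiabetic),
    dyslipidemia = dj(row$ldl >= 160, row$hdl < 40, row$total_chol >= 240,
                      row$on_lipid_lowering),
    liver_enzymes = dj(row$ast > 40, row$alt > 40, row$ggtp > 50),
    abnormal_hr = dj(row$resting_hr < 50, row$resting_hr > 100),
    anemia = dj(row$hemoglobin < if (male) 13 else 12),
    hearing_loss = dj(row$pta_0_5_4k > 25),
    pulmonary = dj(row$fev1_fvc < 70, row$fev1_pred < 80),
    ecg = dj(row$ecg_abnormal),
    low_fitness = vo2_low,
    smoking = dj(row$pack_years >= 20),
    alcohol = dj(row$alcohol_per_week >= 2)
  )
}

# Naive leave-one-out loop with its own mean imputation, z-scoring and a
# direct glmnet call per fold at a fixed penalty.
naive_loocv_probs <- function(profiles, cohort, lambda) {
  y <- as.integer(profiles$category == "unsuitable")
  x <- as.matrix(profiles[, risk_factor_names()])
  storage.mode(x) <- "double"
  x <- cbind(x, age = cohort$age, sex_male = as.numeric(cohort$sex == "male"))
  n <- nrow(x)
  probs <- numeric(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    mu <- colMeans(xtr, na.rm = TRUE)
    for (j in seq_len(ncol(xtr))) xtr[is.na(xtr[, j]), j] <- mu[j]
    ctr <- colMeans(xtr)
    scl <- apply(xtr, 2, stats::sd)
    xs <- xtr
    for (j in seq_len(ncol(xs))) {
      xs[, j] <- if (scl[j] == 0) 0 else (xtr[, j] - ctr[j]) / scl[j]
    }
    fit <- glmnet::glmnet(xs, y[-i], family = "binomial",
                          standardize = FALSE)
    cf <- as.matrix(stats::coef(fit, s = lambda, exact = TRUE, x = xs,
                                y = y[-i], family = "binomial",
                                standardize = FALSE))
    xi <- x[i, ]
    xi[is.na(xi)] <- mu[is.na(xi)]
    xi <- ifelse(scl == 0, 0, (xi - ctr) / scl)
    probs[i] <- stats::plogis(cf[1, 1] + sum(xi * cf[-1, 1]))
  }
  probs
}

# A worker record with every measurement well inside the normal range.
normal_record <- function(sex = "male") {
  data.frame(
    id = "W1", sex = sex, age = 40, bmi = 22, waist = 75, sbp = 115,
    dbp = 72, resting_hr = 65, fasting_glucose = 90, hba1c = 5.3,
    total_chol = 180, ldl = 100, hdl = 60, triglycerides = 100, ast = 20,
    alt = 20, ggtp = 20, hemoglobin = if (sex == "male") 15 else 13.5,
    pta_0_5_4k = 10, fev1_fvc = 85, fev1_pred = 95, vo2max = 45,
    pack_years = 0, alcohol_per_week = 0, on_antihypertensive = FALSE,
    on_antidiabetic = FALSE, on_lipid_lowering = FALSE,
    ecg_abnormal = FALSE, stringsAsFactors = FALSE
  )
}
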