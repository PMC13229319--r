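# Discrimination metrics, confusion arithmetic, leave-one-out validation
# and bootstrap stability.

test_that("auroc handles perfect, tied and single-class inputs", {
  expect_equal(auroc(c(0.9, 0.1), c(1, 0)), 1)
  expect_equal(auroc(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_equal(auroc(c(0.1, 0.9), c(1, 0)), 0)
  expect_true(is.na(auroc(c(0.2, 0.3), c(1, 1))))
  # constant predictions are chance-level under midrank tie handling
  expect_equal(auroc(rep(0.42, 20), rep(0:1, 10)), 0.5)
})

test_that("auroc is invariant under strictly monotone transforms", {
  set.seed(3)
  p <- runif(40)
  y <- rbinom(40, 1, p)
  a <- auroc(p, y)
  expect_equal(auroc(qnorm(p), y), a)
  expect_equal(auroc(p^3 + 2, y), a)
})

test_that("auprc matches its closed forms", {
  expect_equal(auprc(c(0.9, 0.8, 0.7, runif(7, 0, 0.5)),
                     c(1, 1, 1, rep(0, 7))), 1)
  # constant predictions: average precision equals prevalence
  expect_equal(auprc(rep(0.3, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  expect_true(is.na(auprc(c(0.1, 0.2), c(0, 0))))
})

test_that("auroc and auprc agree with brute-force oracles on random instances", {
  set.seed(19)
  for (i in 1:25) {
    prob <- round(runif(12), 2)  # rounding forces occasional ties
    y <- rbinom(12, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(auroc(prob, y), bruteforce_auroc(prob, y))
    expect_equal(auprc(prob, y), bruteforce_auprc(prob, y))
  }
})

test_that("confusion metrics honour their identities and undefined markers", {
  m <- confusion_metrics(tp = 0, fp = 0, tn = 10, fn = 0)
  expect_true(is.na(m$ppv))
  expect_true(is.na(m$sensitivity))
  expect_equal(m$specificity, 1)
  perfect <- confusion_metrics(tp = 4, fp = 0, tn = 4, fn = 0)
  for (k in c("sensitivity", "specificity", "ppv", "npv", "accuracy",
              "balanced_accuracy", "f1")) {
    expect_equal(perfect[[k]], 1)
  }
  expect_error(confusion_metrics(tp = -1, fp = 0, tn = 1, fn = 0),
               class = "cssi_argument_error")
  expect_error(confusion_metrics(tp = 0, fp = 0, tn = 0, fn = 0),
               class = "cssi_argument_error")
  set.seed(8)
  for (i in 1:20) {
    cts <- rbinom(4, 30, 0.5) + 1
    m <- confusion_metrics(tp = cts[1], fp = cts[2], tn = cts[3], fn = cts[4])
    expect_equal(m$sensitivity, cts[1] / (cts[1] + cts[4]))
    expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2)
    expect_equal(m$f1, 2 * cts[1] / (2 * cts[1] + cts[2] + cts[4]))
    expect_equal(m$n, sum(cts))
  }
})

test_that("round_half_up rounds .5 away from zero at the target digit", {
  expect_equal(round_half_up(0.8335, 3), 0.834)
  expect_equal(round_half_up(0.1235, 3), 0.124)
  expect_equal(round_half_up(-0.1235, 3), -0.124)
  expect_equal(round_half_up(2.5, 0), 3)
})

test_that("perfectly separable data give AUROC and AUPRC of 1 in LOOCV", {
  coh <- generate_cohort(60, seed = 61)
  prof <- code_risk_factors(coh)
  # outcome driven deterministically by one flag: separable
  y <- as.integer(coh$sex == "male")
  val <- cssi_loocv(prof, coh, lambda = 0.01, outcome = y)
  expect_equal(val$auroc, 1)
  expect_equal(val$auprc, 1)
})

test_that("LOOCV equals a naive hand-rolled refit loop on a toy cohort", {
  n <- 20
  coh <- generate_cohort(n, seed = 71)
  prof <- code_risk_factors(coh)
  y <- plant_outcome(coh, c(obesity = 4, alcohol = 2), intercept = -2,
                     seed = 72)
  prof$category <- assign_category(ifelse(y == 1, 6, 0))
  lam <- 0.05
  val <- cssi_loocv(prof, coh, lambda = lam, seed = 1)
  oracle_probs <- naive_loocv_probs(prof, coh, lam)
  expect_equal(unname(val$prob), oracle_probs, tolerance = 1e-7)
  expect_equal(val$auroc, auroc(oracle_probs, y))
  expect_equal(val$counts, confusion_counts(oracle_probs, y, 0.5))
})

test_that("fold preprocessing excludes the held-out row (leakage guard)", {
  coh <- generate_cohort(30, seed = 81)
  prof <- code_risk_factors(coh)
  y <- rep_len(c(0L, 1L), 30)
  coh$age[1] <- 69  # sentinel extreme within bounds
  val <- cssi_loocv(prof, coh, lambda = 0.1, outcome = y, details = TRUE)
  fold1_mean <- val$fold_details[[1]]$impute_means[["age"]]
  expect_equal(fold1_mean, mean(coh$age[-1]))
  # a fold NOT holding out the sentinel does see it
  fold2_mean <- val$fold_details[[2]]$impute_means[["age"]]
  expect_equal(fold2_mean, mean(coh$age[-2]))
  expect_false(isTRUE(all.equal(fold1_mean, fold2_mean)))
})

test_that("degenerate training folds fall back to prevalence with a warning", {
  coh <- generate_cohort(12, seed = 91)
  prof <- code_risk_factors(coh)
  y <- c(1L, 1L, rep(0L, 10))
  expect_warning(val <- cssi_loocv(prof, coh, lambda = 0.1, outcome = y),
                 class = "cssi_degenerate_fold")
  # folds holding out a positive leave one positive in training: degenerate
  expect_equal(val$degenerate_folds, c(1L, 2L))
  expect_equal(unname(val$prob[1]), 1 / 11)  # training prevalence of fold 1
  expect_true(all(!is.na(val$prob)))
})

test_that("LOOCV preconditions are enforced", {
  coh <- generate_cohort(8, seed = 95)
  prof <- code_risk_factors(coh)
  expect_error(cssi_loocv(prof, coh, outcome = rep_len(0:1, 8)),
               class = "cssi_argument_error")
  coh <- generate_cohort(15, seed = 96)
  prof <- code_risk_factors(coh)
  expect_error(cssi_loocv(prof, coh, outcome = rep(0L, 15)),
               class = "cssi_fit_error")
})

test_that("bootstrap stability is seeded, bounded and degenerate-safe", {
  coh <- generate_cohort(120, seed = 101)
  prof <- code_risk_factors(coh)
  y <- plant_outcome(coh, c(obesity = 3), intercept = -2.5, seed = 102)
  s1 <- cssi_bootstrap(prof, coh, B = 1, seed = 5, lambda = 0.05, outcome = y)
  expect_true(all(s1$table$selection_frequency %in% c(0, 1)))
  s2 <- cssi_bootstrap(prof, coh, B = 25, seed = 7, lambda = 0.05, outcome = y)
  s3 <- cssi_bootstrap(prof, coh, B = 25, seed = 7, lambda = 0.05, outcome = y)
  expect_identical(s2, s3)
  expect_true(all(s2$table$selection_frequency >= 0 &
                    s2$table$selection_frequency <= 1))
  expect_true(all(s2$table$mean_truncated >= 0))
  # too few positives for any resample: bounded retries then classed error
  y0 <- c(1L, rep(0L, 119))
  expect_error(
    cssi_bootstrap(prof, coh, B = 2, seed = 1, lambda = 0.05, outcome = y0,
                   max_retries = 3),
    class = "cssi_stability_error")
})

test_that("nonzero-selection mode counts coefficients of either sign", {
  coh <- generate_cohort(150, seed = 111)
  prof <- code_risk_factors(coh)
  y <- plant_outcome(coh, c(obesity = 3), intercept = -2, seed = 112)
  pos <- cssi_bootstrap(prof, coh, B = 10, seed = 2, lambda = 0.02,
                        outcome = y, selection = "positive")
  any_sign <- cssi_bootstrap(prof, coh, B = 10, seed = 2, lambda = 0.02,
                             outcome = y, selection = "nonzero")
  expect_true(all(any_sign$table$selection_frequency >=
                    pos$table$selection_frequency))
})
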