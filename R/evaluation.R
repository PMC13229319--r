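# Internal validation: pooled leave-one-out cross-validated discrimination,
# confusion-matrix arithmetic, and bootstrap selection-frequency stability.

#' Round half-up
#'
#' Report-display rounding (0.0005 -> 0.001), as opposed to R's banker's
#' rounding. Full precision is retained in all internal computations.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the normalized rank-sum of the positive-class
#' probabilities, with ties counted one half (midranks). Invariant under any
#' strictly monotone transform of the probabilities.
#'
#' @param probabilities numeric predictions.
#' @param labels 0/1 outcomes.
#' @return AUROC in \[0,1\]; `NA` if a class is absent.
#' @export
#' @examples
#' auroc(c(0.9, 0.1), c(1, 0))  # 1
auroc <- function(probabilities, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(probabilities)  # midranks for ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise sum of precision times recall increments over thresholds taken
#' at the distinct predicted probabilities in descending order; tied
#' probabilities are grouped as a single step.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0,1\]; `NA` if there are no positives.
#' @export
auprc <- function(probabilities, labels) {
  labels <- as.integer(labels)
  npos <- sum(labels == 1)
  if (npos == 0) return(NA_real_)
  thr <- sort(unique(probabilities), decreasing = TRUE)
  tp <- fp <- 0
  prev_recall <- 0
  ap <- 0
  for (t in thr) {
    sel <- probabilities == t
    tp <- tp + sum(labels[sel] == 1)
    fp <- fp + sum(labels[sel] == 0)
    recall <- tp / npos
    precision <- tp / (tp + fp)
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

#' Confusion counts at a probability threshold
#'
#' @inheritParams auroc
#' @param threshold predicted positive iff probability >= threshold
#'   (default 0.50).
#' @return named integer vector `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(probabilities, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  pred <- as.integer(probabilities >= threshold)
  c(tp = sum(pred == 1 & labels == 1), fp = sum(pred == 1 & labels == 0),
    tn = sum(pred == 0 & labels == 0), fn = sum(pred == 0 & labels == 1))
}

#' Confusion-matrix metrics
#'
#' Full metric set from the four counts. Any 0/0 ratio yields an explicit
#' `NA` ("undefined") rather than NaN. Values are exact; use
#' [round_half_up()] for 3-decimal report display.
#'
#' @param tp,fp,tn,fn non-negative counts. `tp` may also be a named vector
#'   as returned by [confusion_counts()].
#' @return list: `n`, `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `accuracy`, `balanced_accuracy`, `f1`.
#' @export
#' @examples
#' m <- confusion_metrics(tp = 5, fp = 7, tn = 98, fn = 1)
#' round_half_up(m$sensitivity)  # 0.833
confusion_metrics <- function(tp, fp = NULL, tn = NULL, fn = NULL) {
  if (length(tp) == 4 && !is.null(names(tp))) {
    fn <- tp[["fn"]]; tn <- tp[["tn"]]; fp <- tp[["fp"]]; tp <- tp[["tp"]]
  }
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(counts)) || any(counts < 0)) {
    cssi_stop("confusion counts must be non-negative", "cssi_argument_error")
  }
  n <- sum(counts)
  if (n == 0) {
    cssi_stop("confusion counts sum to zero", "cssi_argument_error")
  }
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  list(
    n = n, tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens,
    specificity = spec,
    ppv = safe_div(tp, tp + fp),
    npv = safe_div(tn, tn + fn),
    accuracy = (tp + tn) / n,
    balanced_accuracy = if (is.na(sens) || is.na(spec)) NA_real_ else (sens + spec) / 2,
    f1 = safe_div(2 * tp, 2 * tp + fp + fn)
  )
}

#' Leave-one-out cross-validation of the CSSI pipeline
#'
#' For each worker the full pipeline — imputation means, z-scoring, lambda
#' selection and the L1 fit — is re-run on the remaining n-1 workers and the
#' held-out predicted probability of the unsuitable class recorded
#' (`refit = TRUE`, the leakage-free default). AUROC and AUPRC are computed
#' once on the n pooled out-of-fold probabilities; confusion counts use the
#' 0.50 probability threshold on the model scale. With `refit = FALSE` a
#' single full-sample model scores every worker instead (fixed-weights
#' comparison mode).
#'
#' A fold whose training outcome is single-class (or leaves fewer than two
#' workers in a class, below the penalized solver's minimum) is marked
#' degenerate and assigned the training prevalence as its probability, with
#' a warning.
#'
#' @inheritParams cssi_fit
#' @param threshold classification threshold on the predicted probability.
#' @param refit refit the pipeline per fold (default TRUE).
#' @param details if TRUE, keep per-fold preprocessing parameters (used to
#'   audit the leakage guard).
#' @return object of class `cssi_validation`: `n`, `positives`, `auroc`,
#'   `auprc`, `counts`, `metrics` (see [confusion_metrics()]), `prob`
#'   (per-worker out-of-fold probabilities), `degenerate_folds`, `threshold`,
#'   and optionally `fold_details`.
#' @export
cssi_loocv <- function(profiles, cohort, lambda = "auto", seed = 1,
                       threshold = 0.5, refit = TRUE, details = FALSE,
                       outcome = NULL) {
  if (is.null(outcome)) {
    outcome <- as.integer(profiles$category == "unsuitable")
  }
  n <- nrow(profiles)
  if (n < 10) {
    cssi_stop("leave-one-out validation requires at least 10 workers",
              "cssi_argument_error")
  }
  if (length(unique(outcome)) < 2) {
    cssi_stop("outcome has a single class; validation is undefined",
              "cssi_fit_error")
  }
  x <- build_design(profiles, cohort)
  prob <- numeric(n)
  degenerate <- integer(0)
  fold_details <- if (details) vector("list", n) else NULL

  if (!refit) {
    fit <- cssi_fit(profiles, cohort, lambda = lambda, seed = seed,
                    outcome = outcome)
    prob <- fit$fitted_prob
  } else {
    for (i in seq_len(n)) {
      ytr <- outcome[-i]
      if (min(sum(ytr == 1), sum(ytr == 0)) < 2) {
        degenerate <- c(degenerate, i)
        prob[i] <- mean(ytr)
        next
      }
      prep <- cssi_preprocess(x[-i, , drop = FALSE])
      fit <- fit_l1_logistic(prep$x, ytr, lambda = lambda, seed = seed)
      xi <- apply_preprocess(x[i, , drop = FALSE], prep)
      prob[i] <- plogis(fit$a0 + sum(xi * fit$beta))
      if (details) {
        fold_details[[i]] <- list(impute_means = prep$impute_means,
                                  center = prep$center, scale = prep$scale,
                                  lambda = fit$lambda)
      }
    }
    if (length(degenerate)) {
      cssi_warn(sprintf(
        "%d leave-one-out fold(s) had a degenerate (near-single-class) training outcome; held-out probability set to training prevalence",
        length(degenerate)), "cssi_degenerate_fold")
    }
  }

  counts <- confusion_counts(prob, outcome, threshold)
  out <- list(
    n = n, positives = sum(outcome),
    auroc = auroc(prob, outcome), auprc = auprc(prob, outcome),
    counts = counts, metrics = confusion_metrics(counts),
    prob = setNames(prob, profiles$id), outcome = outcome,
    degenerate_folds = degenerate, threshold = threshold, refit = refit
  )
  if (details) out$fold_details <- fold_details
  class(out) <- "cssi_validation"
  out
}

#' @export
print.cssi_validation <- function(x, digits = 3, ...) {
  cat("CSSI internal validation (leave-one-out cross-validation)\n")
  cat(sprintf("  n = %d, unsuitable = %d, threshold = %.2f%s\n",
              x$n, x$positives, x$threshold,
              if (x$refit) "" else " (fixed full-sample weights)"))
  m <- x$metrics
  show <- c(AUROC = x$auroc, AUPRC = x$auprc, Accuracy = m$accuracy,
            `Balanced accuracy` = m$balanced_accuracy,
            Sensitivity = m$sensitivity, Specificity = m$specificity,
            PPV = m$ppv, NPV = m$npv, `F1-score` = m$f1)
  for (nm in names(show)) {
    cat(sprintf("  %-18s %s\n", nm,
                ifelse(is.na(show[[nm]]), "undefined",
                       format(round_half_up(show[[nm]], digits)))))
  }
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n",
              x$counts[["tp"]], x$counts[["fp"]],
              x$counts[["tn"]], x$counts[["fn"]]))
  invisible(x)
}

#' Bootstrap selection-frequency stability analysis
#'
#' Refits the weighting pipeline on `B` resamples of the cohort drawn with
#' replacement and reports, per risk factor, how often it was selected
#' (raw coefficient strictly positive by default, mirroring the
#' positive-weight rule; `selection = "nonzero"` counts either sign) and the
#' mean truncated coefficient. Resamples with fewer than two unsuitable
#' outcomes are redrawn (bounded retries, count reported). Deterministic
#' given the master seed.
#'
#' @inheritParams cssi_fit
#' @param B number of bootstrap resamples (study analysis used 1,000).
#' @param selection `"positive"` or `"nonzero"`.
#' @param max_retries redraw bound per resample.
#' @return object of class `cssi_stability`: data.frame `table` (`factor`,
#'   `selection_frequency`, `mean_truncated`), plus `B`, `redraws`, `seed`.
#' @export
cssi_bootstrap <- function(profiles, cohort, B = 1000, seed = 1,
                           lambda = "auto",
                           selection = c("positive", "nonzero"),
                           max_retries = 100, outcome = NULL) {
  selection <- match.arg(selection)
  if (B < 1) cssi_stop("B must be >= 1", "cssi_argument_error")
  if (is.null(outcome)) {
    outcome <- as.integer(profiles$category == "unsuitable")
  }
  n <- nrow(profiles)
  x <- build_design(profiles, cohort)
  factors <- risk_factor_names()
  sel <- matrix(0, B, length(factors), dimnames = list(NULL, factors))
  truncs <- matrix(0, B, length(factors), dimnames = list(NULL, factors))
  redraws <- 0L

  for (b in seq_len(B)) {
    set.seed(as.integer(seed) + b)
    idx <- sample.int(n, n, replace = TRUE)
    tries <- 0L
    while (sum(outcome[idx]) < 2) {
      tries <- tries + 1L
      if (tries > max_retries) {
        cssi_stop("bootstrap redraw bound exceeded; too few unsuitable cases for stable resampling",
                  "cssi_stability_error")
      }
      idx <- sample.int(n, n, replace = TRUE)
    }
    redraws <- redraws + tries
    prep <- cssi_preprocess(x[idx, , drop = FALSE])
    fit <- fit_l1_logistic(prep$x, outcome[idx], lambda = lambda,
                           seed = as.integer(seed) + b)
    beta <- fit$beta[factors]
    sel[b, ] <- if (selection == "positive") beta > 0 else beta != 0
    truncs[b, ] <- pmax(beta, 0)
  }

  out <- list(
    table = data.frame(
      factor = factors,
      selection_frequency = colMeans(sel),
      mean_truncated = colMeans(truncs),
      row.names = NULL, stringsAsFactors = FALSE
    ),
    B = B, redraws = redraws, seed = seed, selection = selection
  )
  class(out) <- "cssi_stability"
  out
}

#' @export
print.cssi_stability <- function(x, ...) {
  cat(sprintf("CSSI bootstrap stability (B = %d, %d redraw(s), selection = %s)\n",
              x$B, x$redraws, x$selection))
  tab <- x$table[order(-x$table$selection_frequency), ]
  print(tab, row.names = FALSE, digits = 3)
  invisible(x)
}
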