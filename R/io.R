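# Interchange formats: cohort/profile/score CSVs with fixed documented
# headers, weight sets and validation reports as JSON, cutoff configuration
# as YAML. "NA" and empty cells both parse as missing.

cohort_schema <- function() {
  c("id", "sex", .cssi_cont_vars, .cssi_binary_vars)
}

#' Read and write worker cohorts as CSV
#'
#' The cohort CSV has a fixed, case-sensitive header: `id`, `sex`, the 22
#' continuous measurements, then the four logical flags. `NA` or empty cells
#' are missing values. `read_cohort_csv(write_cohort_csv(x))` is the
#' identity for finite values and missing markers (numerics are serialized
#' at full precision).
#'
#' @param path file path.
#' @param cohort cohort data.frame.
#' @return `read_cohort_csv`: the cohort data.frame; `write_cohort_csv`:
#'   `path`, invisibly.
#' @export
read_cohort_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                  colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(cohort_schema(), names(raw))
  if (length(missing_cols)) {
    cssi_stop(paste0("cohort CSV is missing required column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "cssi_schema_error")
  }
  out <- data.frame(id = raw$id, sex = raw$sex, stringsAsFactors = FALSE)
  bad_sex <- !is.na(out$sex) & !out$sex %in% c("male", "female")
  if (any(bad_sex)) {
    cssi_stop(sprintf("unknown sex token '%s' at row %d",
                      out$sex[bad_sex][1], which(bad_sex)[1]),
              "cssi_schema_error")
  }
  for (v in .cssi_cont_vars) {
    vals <- suppressWarnings(as.numeric(raw[[v]]))
    bad <- is.na(vals) & !is.na(raw[[v]])
    if (any(bad)) {
      cssi_stop(sprintf("unparseable numeric value '%s' in column %s, row %d",
                        raw[[v]][bad][1], v, which(bad)[1]),
                "cssi_schema_error")
    }
    out[[v]] <- vals
  }
  for (v in .cssi_binary_vars) {
    vals <- toupper(raw[[v]])
    bad <- !is.na(vals) & !vals %in% c("TRUE", "FALSE")
    if (any(bad)) {
      cssi_stop(sprintf("unparseable logical value '%s' in column %s, row %d",
                        raw[[v]][bad][1], v, which(bad)[1]),
                "cssi_schema_error")
    }
    out[[v]] <- vals == "TRUE"
  }
  out
}

#' @rdname read_cohort_csv
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- cohort[, cohort_schema(), drop = FALSE]
  for (v in .cssi_cont_vars) {
    x <- out[[v]]
    out[[v]] <- ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read and write coded risk profiles as CSV
#'
#' Columns: `id`, the 13 flag columns, `tier1_sum`, `tier2_sum`,
#' `tier3_sum`, `total`, `category`.
#'
#' @param profiles a [code_risk_factors()] result.
#' @param path file path.
#' @export
write_profiles_csv <- function(profiles, path) {
  write.csv(as.data.frame(profiles), path, row.names = FALSE, quote = FALSE,
            na = "NA")
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("id", risk_factor_names(), "tier1_sum", "tier2_sum", "tier3_sum",
            "total", "category")
  missing_cols <- setdiff(need, names(out))
  if (length(missing_cols)) {
    cssi_stop(paste0("profiles CSV is missing required column(s): ",
                     paste(missing_cols, collapse = ", ")),
              "cssi_schema_error")
  }
  out$category <- factor(out$category,
                         levels = c("suitable", "caution", "unsuitable"),
                         ordered = TRUE)
  class(out) <- c("cssi_profiles", "data.frame")
  out
}

#' Serialize a weight set (with provenance) to JSON
#'
#' @param fit a [cssi_fit()] object.
#' @param path file path.
#' @export
write_weights_json <- function(fit, path) {
  payload <- list(
    weights = fit$weights,
    covariate_coefficients = as.list(fit$coefficients[c("age", "sex_male")]),
    intercept = fit$a0,
    lambda = fit$lambda,
    lambda_policy = fit$lambda_policy,
    seed = fit$seed,
    n = fit$n,
    n_unsuitable = fit$n_unsuitable
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_weights_json
#' @return `read_weights_json`: a `cssi_weights` data.frame (provenance in
#'   attributes).
#' @export
read_weights_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  w <- payload$weights
  class(w) <- c("cssi_weights", "data.frame")
  attr(w, "provenance") <- payload[setdiff(names(payload), "weights")]
  w
}

#' Read/write cutoff configuration as YAML
#'
#' Keeps the operational risk-factor definitions as data rather than code,
#' so guideline overrides (e.g. a different VO2max reference table) need no
#' code change.
#'
#' @param cutoffs a [cssi_cutoffs()] object.
#' @param path YAML file path.
#' @export
write_cutoffs_yaml <- function(cutoffs, path) {
  lst <- unclass(cutoffs)
  lst$vo2max_reference <- lapply(
    seq_len(nrow(cutoffs$vo2max_reference)),
    function(i) as.list(cutoffs$vo2max_reference[i, ])
  )
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_cutoffs_yaml
#' @export
read_cutoffs_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  ref <- do.call(rbind, lapply(lst$vo2max_reference, as.data.frame))
  lst$vo2max_reference <- NULL
  do.call(cssi_cutoffs, c(list(vo2max_reference = ref), lst))
}

#' Run the full CSSI pipeline
#'
#' End to end: simulate (or read) a cohort, code the 13 risk factors, fit
#' the weighting model, score every worker, run leave-one-out validation and
#' bootstrap stability, and write all artifacts plus a run manifest to
#' `out_dir`. Re-running with an identical configuration reproduces
#' identical artifacts; partial outputs are removed on failure.
#'
#' @param config a list (or path to a YAML file) with elements: `out_dir`
#'   (required); `cohort_csv` (path) or `n` (simulate, default 111);
#'   `seeds` (list with `simulate`, `fit`, `loocv`, `bootstrap`; default all
#'   1); `lambda` (`"auto"` or number); `B` (bootstrap resamples, default
#'   1000); `cutoffs_yaml` (optional path); `digits` (report rounding,
#'   default 3).
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) {
    cssi_stop("config must name out_dir", "cssi_config_error")
  }
  defaults <- list(n = 111, seeds = list(), lambda = "auto", B = 1000,
                   digits = 3)
  config <- modifyList(defaults, config)
  seeds <- modifyList(list(simulate = 1, fit = 1, loocv = 1, bootstrap = 1),
                      as.list(config$seeds))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    cohort = file.path(config$out_dir, "cohort.csv"),
    profiles = file.path(config$out_dir, "profiles.csv"),
    weights = file.path(config$out_dir, "weights.json"),
    scores = file.path(config$out_dir, "scores.csv"),
    report = file.path(config$out_dir, "report.json"),
    stability = file.path(config$out_dir, "stability.csv"),
    manifest = file.path(config$out_dir, "manifest.json")
  )
  written <- character(0)
  on_fail <- function(e) {
    file.remove(written[file.exists(written)])
    stop(e)
  }
  tryCatch({
    cutoffs <- if (!is.null(config$cutoffs_yaml)) {
      read_cutoffs_yaml(config$cutoffs_yaml)
    } else {
      cssi_cutoffs()
    }
    if (!is.null(config$cohort_csv)) {
      cohort <- read_cohort_csv(config$cohort_csv)
    } else {
      cohort <- generate_cohort(config$n, seed = seeds$simulate)
    }
    write_cohort_csv(cohort, paths$cohort)
    written <- c(written, paths$cohort)

    profiles <- code_risk_factors(cohort, cutoffs)
    write_profiles_csv(profiles, paths$profiles)
    written <- c(written, paths$profiles)

    fit <- cssi_fit(profiles, cohort, lambda = config$lambda,
                    seed = seeds$fit)
    write_weights_json(fit, paths$weights)
    written <- c(written, paths$weights)

    scores <- compute_score(profiles, fit)
    write.csv(scores, paths$scores, row.names = FALSE, quote = FALSE)
    written <- c(written, paths$scores)

    val <- cssi_loocv(profiles, cohort, lambda = config$lambda,
                      seed = seeds$loocv)
    d <- config$digits
    report <- list(
      n = val$n, unsuitable = val$positives, threshold = val$threshold,
      auroc = round_half_up(val$auroc, d), auroc_raw = val$auroc,
      auprc = round_half_up(val$auprc, d), auprc_raw = val$auprc,
      counts = as.list(val$counts),
      metrics = lapply(val$metrics[
        c("sensitivity", "specificity", "ppv", "npv", "accuracy",
          "balanced_accuracy", "f1")], round_half_up, digits = d),
      metrics_raw = val$metrics[
        c("sensitivity", "specificity", "ppv", "npv", "accuracy",
          "balanced_accuracy", "f1")],
      degenerate_folds = length(val$degenerate_folds)
    )
    jsonlite::write_json(report, paths$report, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    written <- c(written, paths$report)

    stab <- cssi_bootstrap(profiles, cohort, B = config$B,
                           seed = seeds$bootstrap, lambda = config$lambda)
    write.csv(stab$table, paths$stability, row.names = FALSE, quote = FALSE)
    written <- c(written, paths$stability)

    cfg_tmp <- tempfile(fileext = ".yaml")
    # fingerprint covers the scientific configuration, not the output path
    fp_cfg <- config[sort(setdiff(names(config), "out_dir"))]
    yaml::write_yaml(fp_cfg, cfg_tmp)
    manifest <- list(
      package = "cssi",
      version = as.character(utils::packageVersion("cssi")),
      seeds = seeds,
      lambda = config$lambda,
      B = config$B,
      config_md5 = unname(tools::md5sum(cfg_tmp)),
      rows = list(cohort = nrow(cohort), profiles = nrow(profiles),
                  scores = nrow(scores))
    )
    file.remove(cfg_tmp)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, paths$manifest)
  }, error = on_fail)
  invisible(paths)
}
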