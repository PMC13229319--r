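# Tiered dichotomous risk-factor coding.
#
# Boundary semantics follow the printed operational cutoffs literally:
# >= for the obesity/hypertension/diabetes/dyslipidemia/smoking/alcohol
# thresholds, strict > for liver enzymes, pure-tone average and tachycardia,
# strict < for bradycardia, anemia, the spirometry ratios and the VO2max
# reference lower bound.

.cssi_factors <- c(
  obesity = 1L, hypertension = 1L, diabetes = 1L, dyslipidemia = 1L,
  liver_enzymes = 1L, abnormal_hr = 1L, anemia = 1L,
  hearing_loss = 2L, pulmonary = 2L, ecg = 2L, low_fitness = 2L,
  smoking = 3L, alcohol = 3L
)

#' Risk-factor names and tiers
#'
#' The 13 CSSI risk factors in canonical order. Tier 1 groups the seven
#' anthropometric/metabolic factors, tier 2 the four functional/physiological
#' factors, tier 3 the two lifestyle factors.
#'
#' @return `risk_factor_names()`: character vector of length 13.
#'   `risk_factor_tiers()`: named integer vector of tiers.
#' @export
risk_factor_names <- function() names(.cssi_factors)

#' @rdname risk_factor_names
#' @export
risk_factor_tiers <- function() .cssi_factors

#' Risk-factor cutoff configuration
#'
#' Builds the cutoff set used by [code_risk_factors()]. Defaults are the
#' operational definitions of the 13 tiered risk factors: obesity (BMI >= 25
#' kg/m2 or waist >= 90 cm men / >= 85 cm women), hypertension (SBP >= 140 or
#' DBP >= 90 mmHg or medication), diabetes (fasting glucose >= 126 mg/dL or
#' HbA1c >= 6.5\% or medication), dyslipidemia (LDL >= 160, HDL < 40, total
#' cholesterol >= 240 mg/dL, or medication), elevated liver enzymes (AST > 40,
#' ALT > 40, or gamma-GTP > 50 IU/L), abnormal resting heart rate (< 50 or
#' > 100 bpm), anemia (Hb < 13 g/dL men / < 12 women), hearing loss (0.5-4 kHz
#' pure-tone average > 25 dB), abnormal pulmonary function (FEV1/FVC < 70\% or
#' FEV1 < 80\% predicted), any abnormal ECG finding, low cardiorespiratory
#' fitness (VO2max below the age- and sex-specific reference lower bound),
#' significant smoking history (>= 20 pack-years), and habitual alcohol
#' consumption (>= 2 times/week).
#'
#' The bundled VO2max reference bands are documented placeholders (see
#' [vo2max_reference_default()]); supply guideline values via
#' `vo2max_reference` to reproduce a specific guideline's coding.
#'
#' @param vo2max_reference data.frame with columns `sex`, `age_min`,
#'   `age_max` (band is `age_min <= age < age_max`) and `lower_bound`
#'   (mL/kg/min).
#' @param ... named threshold overrides (see the element names of the
#'   returned list).
#' @return A list of class `cssi_cutoffs`.
#' @export
cssi_cutoffs <- function(vo2max_reference = vo2max_reference_default(), ...) {
  cfg <- list(
    obesity = list(bmi = 25, waist_male = 90, waist_female = 85),
    hypertension = list(sbp = 140, dbp = 90),
    diabetes = list(glucose = 126, hba1c = 6.5),
    dyslipidemia = list(ldl = 160, hdl = 40, total_chol = 240),
    liver_enzymes = list(ast = 40, alt = 40, ggtp = 50),
    abnormal_hr = list(low = 50, high = 100),
    anemia = list(hb_male = 13, hb_female = 12),
    hearing_loss = list(pta = 25),
    pulmonary = list(fev1_fvc = 70, fev1_pred = 80),
    smoking = list(pack_years = 20),
    alcohol = list(per_week = 2),
    vo2max_reference = vo2max_reference
  )
  cfg <- modifyList(cfg, list(...))
  class(cfg) <- "cssi_cutoffs"
  validate_vo2max_reference(cfg$vo2max_reference)
  cfg
}

#' Placeholder VO2max reference bands
#'
#' Age- and sex-specific lower bounds of the "normal" VO2max category
#' (mL/kg/min) in roughly 10-year bands. These are synthetic placeholder
#' values in the range typical of published cardiorespiratory-fitness
#' classifications; they are NOT the KOSHA H-43-2021 or Canadian Public
#' Health Association tables, which must be supplied by the user to
#' reproduce coding under those guidelines.
#'
#' @return data.frame with columns `sex`, `age_min`, `age_max`,
#'   `lower_bound`.
#' @export
vo2max_reference_default <- function() {
  data.frame(
    sex = rep(c("male", "female"), each = 5),
    age_min = rep(c(18, 30, 40, 50, 60), 2),
    age_max = rep(c(30, 40, 50, 60, 120), 2),
    lower_bound = c(33, 31, 29, 26, 23, 28, 26, 24, 21, 18),
    stringsAsFactors = FALSE
  )
}

validate_vo2max_reference <- function(ref) {
  need <- c("sex", "age_min", "age_max", "lower_bound")
  if (!is.data.frame(ref) || !all(need %in% names(ref))) {
    cssi_stop("vo2max reference must have columns sex, age_min, age_max, lower_bound",
              "cssi_config_error")
  }
  for (sx in unique(ref$sex)) {
    b <- ref[ref$sex == sx, ]
    b <- b[order(b$age_min), ]
    if (any(b$age_max <= b$age_min)) {
      cssi_stop(sprintf("vo2max reference: empty band for sex '%s'", sx),
                "cssi_config_error")
    }
    if (nrow(b) > 1 && any(b$age_min[-1] != b$age_max[-nrow(b)])) {
      i <- which(b$age_min[-1] != b$age_max[-nrow(b)])[1]
      cssi_stop(sprintf(
        "vo2max reference: gap or overlap between bands ending %g and starting %g for sex '%s'",
        b$age_max[i], b$age_min[i + 1], sx), "cssi_config_error")
    }
  }
  invisible(ref)
}

#' Low cardiorespiratory fitness indicator
#'
#' Flags VO2max strictly below the age- and sex-specific lower bound of the
#' reference table. Vectorized over workers.
#'
#' @param vo2max maximal oxygen uptake, mL/kg/min (NA allowed).
#' @param sex `"male"`/`"female"`, recycled to length of `vo2max`.
#' @param age age in years.
#' @param reference reference band table (see [cssi_cutoffs()]).
#' @return Integer 0/1 (NA where `vo2max` is missing).
#' @export
#' @examples
#' ref <- vo2max_reference_default()
#' vo2max_is_low(c(28, 29, NA), "male", 45, ref)  # 1 0 NA
vo2max_is_low <- function(vo2max, sex, age, reference = vo2max_reference_default()) {
  validate_vo2max_reference(reference)
  k <- max(length(vo2max), length(sex), length(age))
  vo2max <- rep_len(vo2max, k)
  sex <- rep_len(sex, k)
  age <- rep_len(age, k)
  out <- integer(k)
  for (i in seq_len(k)) {
    band <- reference$sex == sex[i] &
      reference$age_min <= age[i] & age[i] < reference$age_max
    if (!any(band)) {
      cssi_stop(sprintf(
        "vo2max reference has no band covering sex '%s' at age %g",
        sex[i], age[i]), "cssi_config_error")
    }
    lb <- reference$lower_bound[which(band)[1]]
    out[i] <- if (is.na(vo2max[i])) NA_integer_ else as.integer(vo2max[i] < lb)
  }
  out
}

# Disjunction with missing-handling: 1 if any available term fires, NA if
# every constituent is missing, else 0.
or_flag <- function(...) {
  terms <- list(...)
  m <- do.call(cbind, terms)
  fired <- apply(m, 1, function(r) any(r %in% TRUE))
  all_na <- apply(m, 1, function(r) all(is.na(r)))
  out <- as.integer(fired)
  out[!fired & all_na] <- NA_integer_
  out
}

#' Code the 13 dichotomous risk factors
#'
#' Applies the tiered operational cutoffs to each worker record, producing
#' one 0/1 flag per factor, per-tier sums, the total risk count, and the
#' rule-based fitness category. A factor whose every constituent measurement
#' is missing is coded `NA` and contributes 0 to the sums (a warning is
#' emitted); a factor with at least one available constituent is 1 if any
#' available constituent fires, else 0.
#'
#' @param cohort cohort data.frame (see [generate_cohort()] /
#'   [read_cohort_csv()]).
#' @param cutoffs a [cssi_cutoffs()] configuration.
#' @return data.frame of class `cssi_profiles`: `id`, the 13 factor columns,
#'   `tier1_sum`, `tier2_sum`, `tier3_sum`, `total`, `category`.
#' @export
#' @examples
#' coh <- generate_cohort(20, seed = 1)
#' code_risk_factors(coh)[1:3, c("id", "obesity", "total", "category")]
code_risk_factors <- function(cohort, cutoffs = cssi_cutoffs()) {
  if (!all(c("sex", "age") %in% names(cohort))) {
    cssi_stop("cohort must contain sex and age columns", "cssi_schema_error")
  }
  bad_sex <- !cohort$sex %in% c("male", "female")
  if (any(bad_sex)) {
    cssi_stop(sprintf("unknown sex value '%s' at row %d",
                      cohort$sex[bad_sex][1], which(bad_sex)[1]),
              "cssi_coding_error")
  }
  if (any(is.na(cohort$age))) {
    cssi_stop("age is required for every worker", "cssi_coding_error")
  }
  ratio_scale <- !is.na(cohort$fev1_fvc) &
    cohort$fev1_fvc > 0 & cohort$fev1_fvc <= 1.5
  if (any(ratio_scale)) {
    cssi_stop(sprintf(
      "fev1_fvc looks ratio-scaled (value %.3g at row %d); supply percent (0-100)",
      cohort$fev1_fvc[ratio_scale][1], which(ratio_scale)[1]),
      "cssi_schema_error")
  }

  cf <- cutoffs
  male <- cohort$sex == "male"
  n <- nrow(cohort)
  col <- function(v) if (v %in% names(cohort)) cohort[[v]] else rep(NA_real_, n)
  lcol <- function(v) {
    if (v %in% names(cohort)) as.logical(cohort[[v]]) else rep(NA, n)
  }

  waist_cut <- ifelse(male, cf$obesity$waist_male, cf$obesity$waist_female)
  hb_cut <- ifelse(male, cf$anemia$hb_male, cf$anemia$hb_female)

  flags <- data.frame(
    obesity = or_flag(col("bmi") >= cf$obesity$bmi, col("waist") >= waist_cut),
    hypertension = or_flag(col("sbp") >= cf$hypertension$sbp,
                           col("dbp") >= cf$hypertension$dbp,
                           lcol("on_antihypertensive")),
    diabetes = or_flag(col("fasting_glucose") >= cf$diabetes$glucose,
                       col("hba1c") >= cf$diabetes$hba1c,
                       lcol("on_antidiabetic")),
    dyslipidemia = or_flag(col("ldl") >= cf$dyslipidemia$ldl,
                           col("hdl") < cf$dyslipidemia$hdl,
                           col("total_chol") >= cf$dyslipidemia$total_chol,
                           lcol("on_lipid_lowering")),
    liver_enzymes = or_flag(col("ast") > cf$liver_enzymes$ast,
                            col("alt") > cf$liver_enzymes$alt,
                            col("ggtp") > cf$liver_enzymes$ggtp),
    abnormal_hr = or_flag(col("resting_hr") < cf$abnormal_hr$low,
                          col("resting_hr") > cf$abnormal_hr$high),
    anemia = or_flag(col("hemoglobin") < hb_cut),
    hearing_loss = or_flag(col("pta_0_5_4k") > cf$hearing_loss$pta),
    pulmonary = or_flag(col("fev1_fvc") < cf$pulmonary$fev1_fvc,
                        col("fev1_pred") < cf$pulmonary$fev1_pred),
    ecg = or_flag(lcol("ecg_abnormal")),
    low_fitness = vo2max_is_low(col("vo2max"), cohort$sex, cohort$age,
                                cf$vo2max_reference),
    smoking = or_flag(col("pack_years") >= cf$smoking$pack_years),
    alcohol = or_flag(col("alcohol_per_week") >= cf$alcohol$per_week)
  )

  n_missing <- sum(is.na(as.matrix(flags)))
  if (n_missing > 0) {
    cssi_warn(sprintf(
      "%d risk-factor flag(s) could not be coded (all constituents missing); counted as 0 in risk totals",
      n_missing), "cssi_missing_flag_warning")
  }

  tiers <- risk_factor_tiers()
  fl0 <- as.matrix(flags)
  fl0[is.na(fl0)] <- 0L
  tier_sum <- function(t) as.integer(rowSums(fl0[, names(tiers)[tiers == t], drop = FALSE]))
  out <- data.frame(
    id = if ("id" %in% names(cohort)) cohort$id else sprintf("W%05d", seq_len(n)),
    flags,
    tier1_sum = tier_sum(1L), tier2_sum = tier_sum(2L), tier3_sum = tier_sum(3L),
    stringsAsFactors = FALSE
  )
  out$total <- out$tier1_sum + out$tier2_sum + out$tier3_sum
  out$category <- assign_category(out$total)
  class(out) <- c("cssi_profiles", "data.frame")
  out
}

#' Rule-based fitness category from the total risk count
#'
#' Maps the total number of coded risk factors to the three-level fitness
#' category: 0-3 suitable, 4-5 caution, 6 or more unsuitable.
#'
#' @param total integer vector of total risk counts (0-13).
#' @return Ordered factor with levels `suitable < caution < unsuitable`.
#' @export
#' @examples
#' assign_category(c(0, 3, 4, 5, 6, 13))
assign_category <- function(total) {
  if (any(is.na(total)) || any(total < 0)) {
    cssi_stop("total risk count must be non-negative", "cssi_argument_error")
  }
  lev <- c("suitable", "caution", "unsuitable")
  out <- ifelse(total <= 3, "suitable", ifelse(total <= 5, "caution", "unsuitable"))
  factor(out, levels = lev, ordered = TRUE)
}
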