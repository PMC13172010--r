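#' Metabolic-health classification thresholds
#'
#' BioSHaRE-EU Healthy Obese Project criteria: metabolic health (MH)
#' requires fasting glucose <= 100 mg/dL, triglycerides <= 150 mg/dL, HDL
#' cholesterol > 40 mg/dL (men) / > 50 mg/dL (women), systolic blood
#' pressure <= 130 mmHg and diastolic <= 85 mmHg. Obesity follows the WHO
#' definition, BMI >= 30 kg/m2 (inclusive).
#'
#' @param glucose_max,tg_max,hdl_min_male,hdl_min_female,sbp_max,dbp_max,bmi_obesity
#'   Threshold overrides.
#' @return Named list of class `phenotype_criteria`.
#' @export
phenotype_criteria <- function(glucose_max = 100, tg_max = 150,
                               hdl_min_male = 40, hdl_min_female = 50,
                               sbp_max = 130, dbp_max = 85,
                               bmi_obesity = 30) {
  structure(list(glucose_max = glucose_max, tg_max = tg_max,
                 hdl_min_male = hdl_min_male,
                 hdl_min_female = hdl_min_female,
                 sbp_max = sbp_max, dbp_max = dbp_max,
                 bmi_obesity = bmi_obesity), class = "phenotype_criteria")
}

# mmol/L -> mg/dL conversion factors
UNIT_FACTORS <- c(glucose = 18.0, triglycerides = 88.57, hdl = 38.67)

as_mgdl <- function(value, biomarker, unit) {
  if (is.null(unit) || is.na(unit) || unit %in% c("mg/dL", "mg/dl"))
    return(value)
  if (unit %in% c("mmol/L", "mmol/l"))
    return(value * UNIT_FACTORS[[biomarker]])
  stop("unknown unit '", unit, "' for ", biomarker)
}

flag_fields <- c("diagnosed_t2d", "diagnosed_hypertension",
                 "diagnosed_hypercholesterolemia", "on_medication",
                 "impaired_glucose_tolerance")

#' Classify metabolic health (MH / MU / indeterminate)
#'
#' A subject with any diagnosis, medication or impaired-glucose-tolerance
#' flag set is metabolically unhealthy (MU) regardless of biomarkers.
#' Otherwise MH requires every biomarker to satisfy its bound (the HDL
#' bound is sex-specific and strict). A subject failing any single
#' evaluable biomarker is MU; a subject whose evaluable biomarkers all pass
#' but with one or more missing is indeterminate rather than imputed.
#'
#' @param record Named list or one-row data.frame: `glucose`,
#'   `triglycerides`, `hdl` (mg/dL, or supply `units`), `sex`
#'   ("male"/"female"), `sbp`, `dbp`, and logical flags `diagnosed_t2d`,
#'   `diagnosed_hypertension`, `diagnosed_hypercholesterolemia`,
#'   `on_medication`, `impaired_glucose_tolerance`. Missing fields allowed.
#' @param criteria A [phenotype_criteria()].
#' @param units Optional named character vector (e.g.
#'   `c(glucose = "mmol/L")`).
#' @return `"MH"`, `"MU"` or `"indeterminate"`.
#' @export
classify_metabolic_health <- function(record,
                                      criteria = phenotype_criteria(),
                                      units = NULL) {
  r <- as.list(record)
  get <- function(f) if (is.null(r[[f]]) || (length(r[[f]]) == 1 &&
                                             is.na(r[[f]]))) NA else r[[f]]
  for (f in flag_fields) if (isTRUE(get(f))) return("MU")
  conv <- function(f) {
    v <- get(f)
    if (is.na(v)) return(NA_real_)
    as_mgdl(as.numeric(v), f, units[[f]])
  }
  glucose <- conv("glucose"); tg <- conv("triglycerides")
  hdl <- conv("hdl")
  sbp <- get("sbp"); dbp <- get("dbp"); sex <- get("sex")
  hdl_pass <- if (is.na(hdl)) NA else {
    if (is.na(sex) || !sex %in% c("male", "female")) {
      warning("HDL present but sex unknown; HDL bound not evaluable")
      NA
    } else hdl > (if (sex == "male") criteria$hdl_min_male
                  else criteria$hdl_min_female)
  }
  checks <- c(glucose = if (is.na(glucose)) NA else
                glucose <= criteria$glucose_max,
              triglycerides = if (is.na(tg)) NA else tg <= criteria$tg_max,
              hdl = hdl_pass,
              sbp = if (is.na(sbp)) NA else sbp <= criteria$sbp_max,
              dbp = if (is.na(dbp)) NA else dbp <= criteria$dbp_max)
  if (any(!checks, na.rm = TRUE)) return("MU")
  if (anyNA(checks)) return("indeterminate")
  "MH"
}

#' Classify the combined metabolic-health / obesity phenotype
#'
#' Crosses the MH/MU label with obesity (BMI >= 30 kg/m2, inclusive) into
#' MHNO, MHO, MUNO or MUO.
#'
#' @inheritParams classify_metabolic_health
#' @return One of `"MHNO"`, `"MHO"`, `"MUNO"`, `"MUO"`, `"indeterminate"`.
#' @export
classify_phenotype <- function(record, criteria = phenotype_criteria(),
                               units = NULL) {
  r <- as.list(record)
  bmi <- r$bmi
  if (is.null(bmi) || is.na(bmi)) return("indeterminate")
  mh <- classify_metabolic_health(record, criteria, units)
  if (mh == "indeterminate") return("indeterminate")
  obese <- bmi >= criteria$bmi_obesity
  paste0(mh, if (obese) "O" else "NO")
}

#' Classify a metadata table of subjects
#'
#' Vectorized wrapper over [classify_phenotype()]; adds `metabolic_health`
#' and `phenotype` columns.
#'
#' @param metadata data.frame with the [classify_metabolic_health()] columns
#'   plus `bmi`.
#' @param criteria A [phenotype_criteria()].
#' @param units Optional units vector.
#' @return `metadata` with the two label columns appended.
#' @export
classify_phenotype_table <- function(metadata,
                                     criteria = phenotype_criteria(),
                                     units = NULL) {
  metadata$metabolic_health <- vapply(seq_len(nrow(metadata)), function(i)
    classify_metabolic_health(metadata[i, , drop = FALSE], criteria, units),
    character(1))
  metadata$phenotype <- vapply(seq_len(nrow(metadata)), function(i)
    classify_phenotype(metadata[i, , drop = FALSE], criteria, units),
    character(1))
  metadata
}
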