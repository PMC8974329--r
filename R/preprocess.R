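#' Phenotype trait registry
#'
#' Names the traits the preprocessing rules know about and the rule class
#' each belongs to: `pressure` traits are shifted upward under
#' antihypertensive treatment, `glycemic` traits are blanked for
#' diabetics (glucose additionally when non-fasting), `lipid` traits are
#' blanked under lipid-lowering medication or non-fasting, and `other`
#' traits pass through unchanged.
#'
#' @return Named character vector mapping trait name to rule class.
#' @export
trait_registry <- function() {
  c(sbp = "pressure", dbp = "pressure",
    pulse_pressure = "other", heart_rate = "other",
    glucose = "glycemic", hba1c = "glycemic",
    total_cholesterol = "lipid", hdl = "lipid", ldl = "lipid",
    triglycerides = "lipid",
    bmi = "other", weight = "other", abdominal_circumference = "other",
    grip_strength = "other", gait_speed = "other",
    fev1 = "other", fev6 = "other", fvc = "other",
    mmse = "other", creatinine = "other", generic = "other")
}

trait_class <- function(trait) {
  reg <- trait_registry()
  if (!trait %in% names(reg))
    stop("unknown phenotype name: ", trait,
         " (see trait_registry() for known traits)")
  unname(reg[trait])
}

lgl_or_false <- function(x, n) {
  if (is.null(x)) return(rep(FALSE, n))
  x[is.na(x)] <- FALSE
  as.logical(x)
}

#' Antihypertensive medication adjustment
#'
#' Participants on antihypertensive medication have systolic blood
#' pressure adjusted by +15 and diastolic by +10; other traits are left
#' unchanged. The adjustment is recorded in a `med_adjusted` column.
#'
#' @param records data.frame of visit records with a `value` column and an
#'   optional logical `antihypertensive` column (absent treated as FALSE).
#' @param trait trait name (see [trait_registry()]).
#' @return `records` with adjusted `value` and a `med_adjusted` column.
#' @export
apply_medication_adjustment <- function(records, trait) {
  cls <- trait_class(trait)
  n <- nrow(records)
  on_med <- lgl_or_false(records$antihypertensive, n)
  shift <- if (cls == "pressure") {
    if (trait == "sbp") 15 else 10
  } else 0
  adj <- on_med & shift > 0 & !is.na(records$value)
  records$value[adj] <- records$value[adj] + shift
  records$med_adjusted <- adj
  records
}

#' Trait-specific exclusions
#'
#' Glycemic traits (glucose, HbA1c) are set to missing for diabetics,
#' defined by the four-part rule: fasting glucose >= 126 mg/dL, or
#' HbA1c >= 6.5, or reported diabetes, or diabetes medication. Glucose is
#' additionally set to missing when the participant was not fasting.
#' Lipid traits are set to missing under lipid-lowering medication or
#' non-fasting. All other traits pass through. An `excluded_reason`
#' column records why a value was blanked.
#'
#' @param records data.frame with `value` plus optional columns `fasting`,
#'   `glucose`, `hba1c`, `diabetes_dx`, `diabetes_meds`,
#'   `lipid_lowering` (missing columns are treated as FALSE; `fasting`
#'   absent is treated as fasting).
#' @param trait trait name.
#' @return `records` with excluded values set to `NA` and
#'   `excluded_reason` filled in.
#' @export
apply_exclusions <- function(records, trait) {
  cls <- trait_class(trait)
  n <- nrow(records)
  records$excluded_reason <- NA_character_
  if (!cls %in% c("glycemic", "lipid")) return(records)

  fasting <- if (is.null(records$fasting)) rep(TRUE, n) else {
    f <- records$fasting; f[is.na(f)] <- TRUE; as.logical(f)
  }
  if (cls == "glycemic") {
    glu <- if (!is.null(records$glucose)) records$glucose
           else if (trait == "glucose") records$value else rep(NA_real_, n)
    a1c <- if (!is.null(records$hba1c)) records$hba1c
           else if (trait == "hba1c") records$value else rep(NA_real_, n)
    diabetic <- (fasting & !is.na(glu) & glu >= 126) |
      (!is.na(a1c) & a1c >= 6.5) |
      lgl_or_false(records$diabetes_dx, n) |
      lgl_or_false(records$diabetes_meds, n)
    drop <- diabetic
    records$excluded_reason[drop] <- "diabetes"
    if (trait == "glucose") {
      nf <- !fasting & !drop
      records$excluded_reason[nf] <- "non-fasting"
      drop <- drop | !fasting
    }
    records$value[drop] <- NA_real_
  } else {                                   # lipid
    med <- lgl_or_false(records$lipid_lowering, n)
    records$excluded_reason[med] <- "lipid-lowering medication"
    nf <- !fasting & !med
    records$excluded_reason[nf] <- "non-fasting"
    records$value[med | !fasting] <- NA_real_
  }
  records
}

#' Residualize a phenotype on standard covariates
#'
#' Removes sex, age, age squared and field site by linear projection:
#' residuals of `lm(value ~ sex + age + I(age^2) + site)` computed on the
#' non-missing records. Visit-level values use same-visit age; slope
#' phenotypes should be passed baseline (Visit 1) age.
#'
#' @param value numeric phenotype (may contain NA).
#' @param sex,site categorical covariates.
#' @param age continuous age in years.
#' @return Residuals, NA where `value`, `age`, `sex` or `site` is missing.
#' @export
residualize <- function(value, sex, age, site) {
  keep <- !is.na(value) & !is.na(sex) & !is.na(age) & !is.na(site)
  site_f <- factor(site[keep])
  if (nlevels(site_f) > 0 && any(table(site_f) < 2))
    stop("field-site level(s) with fewer than 2 observations: ",
         paste(names(which(table(site_f) < 2)), collapse = ", "))
  df <- data.frame(value = value[keep], sex = factor(sex[keep]),
                   age = age[keep], site = site_f)
  form <- value ~ age + I(age^2)
  if (nlevels(df$sex) > 1) form <- update(form, . ~ . + sex)
  if (nlevels(df$site) > 1) form <- update(form, . ~ . + site)
  fit <- stats::lm(form, data = df)
  out <- rep(NA_real_, length(value))
  out[keep] <- stats::residuals(fit)
  out
}

#' Naive per-person OLS change slopes
#'
#' For each person with usable values at both visits, the change slope is
#' (Visit 2 value - Visit 1 value) / years passed, with years passed
#' computed as (date of Visit 2 - date of Visit 1) / 365.25. Persons
#' missing either visit keep a missing slope with the reason recorded.
#'
#' @param records data.frame with columns `person_id`, `visit` (1 or 2),
#'   `visit_date` (Date or coercible), `value`.
#' @return data.frame with person_id, ols_slope, years_between, reason.
#' @export
ols_slopes <- function(records) {
  records$visit_date <- as.Date(records$visit_date)
  ids <- unique(records$person_id)
  out <- data.frame(person_id = ids, ols_slope = NA_real_,
                    years_between = NA_real_, reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    sub <- records[records$person_id == ids[k], , drop = FALSE]
    v1 <- sub[sub$visit == 1, , drop = FALSE]
    v2 <- sub[sub$visit == 2, , drop = FALSE]
    if (nrow(v1) != 1 || nrow(v2) != 1 ||
        is.na(v1$value) || is.na(v2$value)) {
      out$reason[k] <- "incomplete pair"
      next
    }
    if (is.na(v1$visit_date) || is.na(v2$visit_date)) {
      out$reason[k] <- "missing visit date"
      next
    }
    if (v2$visit_date <= v1$visit_date)
      stop("person ", ids[k], ": Visit 2 date not after Visit 1 date")
    yrs <- as.numeric(v2$visit_date - v1$visit_date) / 365.25
    out$years_between[k] <- yrs
    out$ols_slope[k] <- (v2$value - v1$value) / yrs
  }
  out
}
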