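#' The default 20-criterion prescription assessment ruleset
#'
#' Codifies the twenty documentation-quality criteria a safe, complete and
#' actionable prescription should fulfil. Criteria #1-#5 check the presence of
#' relevant patient data (allergies, age, weight, renal function, drug
#' history); #6-#15 check formal requirements of the order itself (validity,
#' electronic creation, legibility, unabbreviated substance names, drug and
#' dosage information); #16-#20 check information needed for safe
#' administration (risky-route spelling, body site, identified risks, reason
#' for as-needed orders, overall unambiguity).
#'
#' Each rule carries an applicability predicate and a fulfilment predicate,
#' both vectorised over the prescription and patient tables; fulfilment is
#' only evaluated where the rule applies. Tri-state inputs (logical \code{NA})
#' drive applicability for criteria marked "NA allowed": a missing drug
#' history for a patient without pre-admission medication makes #5 not
#' applicable rather than unmet.
#'
#' @param vocab Route vocabulary used by criterion #16.
#' @param derived_complete If \code{TRUE}, criterion #20 (complete and
#'   unambiguous) is derived as the conjunction of the applicable criteria
#'   #10-#14, #16 and #17 instead of being read from the
#'   \code{complete_and_unambiguous} input flag.
#' @param version Version string recorded into every assessment.
#' @return A \code{ruleset} object: list of 20 rules plus metadata.
#' @export
default_ruleset <- function(vocab = route_vocabulary(),
                            derived_complete = FALSE,
                            version = "aps20-default-1.0") {
  rule <- function(id, label, applicable, met) {
    list(id = id, label = label, applicable = applicable, met = met)
  }
  always <- function(rx, pat) rep(TRUE, nrow(rx))
  rules <- list(
    rule(1L, "allergies and intolerances documented",
         always, function(rx, pat) pat$allergies_documented),
    rule(2L, "age in years documented",
         always, function(rx, pat) pat$age_documented),
    rule(3L, "weight in kilograms documented",
         always, function(rx, pat) pat$weight_documented),
    rule(4L, "organ functions documented (eGFR and creatinine)",
         always, function(rx, pat) pat$renal_function_documented),
    rule(5L, "drug history documented",
         function(rx, pat) !is.na(pat$drug_history_documented),
         function(rx, pat) pat$drug_history_documented),
    rule(6L, "prescription is valid",
         always, function(rx, pat) rx$is_valid),
    rule(7L, "prescription created with the aid of a computer",
         always, function(rx, pat) rx$source == "ELECTRONIC"),
    rule(8L, "prescription is easy to read",
         always, function(rx, pat) rx$is_legible),
    rule(9L, "no abbreviations for active substances",
         function(rx, pat) !is.na(rx$contains_substance_abbreviation),
         function(rx, pat) !rx$contains_substance_abbreviation),
    rule(10L, "full trade name or every active substance named",
         always,
         function(rx, pat) rx$trade_name_complete |
           rx$active_substances_fully_named),
    rule(11L, "dose strength and unit documented",
         function(rx, pat) !is.na(rx$dose_strength_documented),
         function(rx, pat) rx$dose_strength_documented),
    rule(12L, "dosage form and type of release documented",
         always, function(rx, pat) rx$dosage_form_and_release_documented),
    rule(13L, "single dose and unit documented",
         function(rx, pat) !is.na(rx$single_dose_unit_documented),
         function(rx, pat) !is.na(rx$single_dose_value) &
           rx$single_dose_unit_documented),
    rule(14L, "dosage interval documented",
         function(rx, pat) !is.na(rx$dosage_interval_documented),
         function(rx, pat) rx$dosage_interval_documented),
    rule(15L, "single dose is a whole number",
         function(rx, pat) !is.na(rx$single_dose_value),
         function(rx, pat) rx$single_dose_value == floor(rx$single_dose_value)),
    rule(16L, "risky administration type stated clearly, unabbreviated",
         function(rx, pat) is_risky_route(rx$route, vocab),
         function(rx, pat) rx$risky_route_stated_unabbreviated),
    rule(17L, "body part and site for administration indicated",
         function(rx, pat) rx$body_site_required,
         function(rx, pat) rx$body_site_documented),
    rule(18L, "no identifiable risks for the patient",
         always, function(rx, pat) rx$risk_flags == 0L),
    rule(19L, "reason for administration documented",
         function(rx, pat) rx$as_needed,
         function(rx, pat) rx$reason_documented),
    rule(20L, "prescription complete and unambiguous",
         always, function(rx, pat) rx$complete_and_unambiguous)
  )
  structure(list(rules = rules, version = version,
                 derived_complete = derived_complete),
            class = "ruleset")
}

#' @export
print.ruleset <- function(x, ...) {
  cat("Prescription assessment ruleset", x$version, "-",
      length(x$rules), "criteria\n")
  for (r in x$rules) cat(sprintf("  #%-2d %s\n", r$id, r$label))
  invisible(x)
}

# indices of criteria whose conjunction defines derived criterion #20
DERIVED_20_PARTS <- c(10L, 11L, 12L, 13L, 14L, 16L, 17L)

#' Assess prescriptions against the ruleset
#'
#' Evaluates every prescription against all 20 criteria. Each outcome is
#' \code{"M"} (met), \code{"N"} (not met) or \code{"X"} (not applicable).
#' A missing value in a field required by an applicable rule is an error
#' naming the criterion and prescription, never a silent \code{"N"}.
#'
#' @param patients Patients data frame.
#' @param prescriptions Prescriptions data frame.
#' @param rules Ruleset from \code{\link{default_ruleset}}.
#' @return An \code{assessment} object: character matrix
#'   (prescriptions x 20) of outcomes plus \code{prescription_id},
#'   \code{patient_id} and the ruleset version.
#' @export
assess_prescriptions <- function(patients, prescriptions,
                                 rules = default_ruleset()) {
  check_referential_integrity(patients, prescriptions)
  pat <- patients[match(prescriptions$patient_id, patients$patient_id), ,
                  drop = FALSE]
  n <- nrow(prescriptions)
  out <- matrix("X", nrow = n, ncol = 20,
                dimnames = list(NULL, paste0("c", 1:20)))
  for (r in rules$rules) {
    app <- r$applicable(prescriptions, pat)
    if (anyNA(app))
      stop("applicability of criterion #", r$id, " is undefined for ",
           "prescription(s) ",
           paste(utils::head(prescriptions$prescription_id[is.na(app)], 3),
                 collapse = ", "))
    if (rules$derived_complete && r$id == 20L) next
    met <- rep(NA, n)
    met[app] <- r$met(prescriptions, pat)[app]
    bad <- app & is.na(met)
    if (any(bad))
      stop("criterion #", r$id, " (", r$label, ") requires a field that is ",
           "missing for prescription(s): ",
           paste(utils::head(prescriptions$prescription_id[bad], 3),
                 collapse = ", "))
    out[app, r$id] <- ifelse(met[app], "M", "N")
  }
  if (rules$derived_complete) {
    parts <- out[, DERIVED_20_PARTS, drop = FALSE]
    any_unmet <- rowSums(parts == "N") > 0
    out[, 20L] <- ifelse(any_unmet, "N", "M")
  }
  structure(list(outcomes = out,
                 prescription_id = prescriptions$prescription_id,
                 patient_id = prescriptions$patient_id,
                 ruleset_version = rules$version),
            class = "assessment")
}

#' @rdname assess_prescriptions
#' @param p Single-row prescription data frame.
#' @param pat Single-row patient data frame (the prescription's patient).
#' @export
assess_prescription <- function(p, pat, rules = default_ruleset()) {
  stopifnot(nrow(p) == 1, nrow(pat) == 1)
  a <- assess_prescriptions(pat, p, rules)
  a$outcomes[1, ]
}

#' @export
print.assessment <- function(x, ...) {
  cat("Assessment of", nrow(x$outcomes), "prescriptions, ruleset",
      x$ruleset_version, "\n")
  cat("  outcomes: M", sum(x$outcomes == "M"), " N", sum(x$outcomes == "N"),
      " X", sum(x$outcomes == "X"), "\n")
  invisible(x)
}

#' Mean and SD of not-applicable criteria per prescription
#'
#' @param assessment An \code{assessment}.
#' @return List with \code{mean} and \code{sd} (sample SD) of the
#'   per-prescription count of not-applicable criteria.
#' @export
count_not_applicable <- function(assessment) {
  stopifnot(inherits(assessment, "assessment"))
  n_na <- rowSums(assessment$outcomes == "X")
  if (length(n_na) == 0) stop("empty assessment")
  list(mean = mean(n_na), sd = stats::sd(n_na))
}

#' Write assessment outcomes to CSV
#'
#' One row per prescription: \code{prescription_id} plus 20 outcome columns
#' coded M (met), N (not met), X (not applicable).
#'
#' @param assessment An \code{assessment}.
#' @param path Output CSV path.
#' @export
write_assessments <- function(assessment, path) {
  df <- data.frame(prescription_id = assessment$prescription_id,
                   assessment$outcomes, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
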