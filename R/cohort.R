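#' @name cohort-data
#' @title Patient and prescription tables
#'
#' @description
#' The package works on two plain data frames.
#'
#' \strong{patients} has one row per patient: \code{patient_id},
#' \code{ward_id} (integer 1..K), \code{time_point} (\code{"PRE"} or
#' \code{"POST"}), \code{age_years}, \code{sex}, \code{weight_kg}, the five
#' patient-level documentation flags \code{allergies_documented},
#' \code{age_documented}, \code{weight_documented},
#' \code{renal_function_documented} (requires both eGFR and creatinine on the
#' chart), \code{drug_history_documented} (tri-state: \code{NA} means no
#' pre-admission medication, so the criterion does not apply), and
#' \code{n_comedications}.
#'
#' \strong{prescriptions} has one row per drug order with the structured
#' documentation fields consumed by the criteria engine (see
#' \code{\link{default_ruleset}}). Tri-state fields use logical \code{NA} for
#' "not applicable"; they are never coerced to \code{FALSE}.
NULL

PATIENT_LOGICAL <- c("allergies_documented", "age_documented",
                     "weight_documented", "renal_function_documented",
                     "drug_history_documented")

RX_LOGICAL <- c("as_needed", "trade_name_complete",
                "active_substances_fully_named",
                "contains_substance_abbreviation", "dose_strength_documented",
                "dosage_form_and_release_documented",
                "single_dose_unit_documented", "dosage_interval_documented",
                "is_valid", "is_legible", "risky_route_stated_unabbreviated",
                "body_site_required", "body_site_documented",
                "reason_documented", "complete_and_unambiguous")

parse_bool <- function(x) {
  if (is.logical(x)) return(x)
  x <- trimws(tolower(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "1")] <- TRUE
  out[x %in% c("false", "f", "0")] <- FALSE
  bad <- !(x %in% c("true", "t", "1", "false", "f", "0", "", "na"))
  if (any(bad)) stop("cannot parse boolean value(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  out
}

#' Read a patients table from CSV
#'
#' Comma-separated, UTF-8, header mandatory; booleans written as
#' \code{true}/\code{false}; missing / not-applicable values as empty cells.
#'
#' @param path CSV file path.
#' @return Validated patients data frame.
#' @export
read_patients <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("patient_id", "ward_id", "time_point", PATIENT_LOGICAL,
            "n_comedications")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("patients file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  for (cl in PATIENT_LOGICAL) df[[cl]] <- parse_bool(df[[cl]])
  df$ward_id <- as.integer(df$ward_id)
  df$n_comedications <- as.integer(df$n_comedications)
  for (cl in intersect(c("age_years", "weight_kg"), names(df)))
    df[[cl]] <- suppressWarnings(as.numeric(df[[cl]]))
  validate_patients(df)
}

#' Read a prescriptions table from CSV
#'
#' @inheritParams read_patients
#' @param vocab Route vocabulary used to validate the \code{route} column.
#' @return Validated prescriptions data frame.
#' @export
read_prescriptions <- function(path, vocab = route_vocabulary()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("prescription_id", "patient_id", "route", "source", RX_LOGICAL,
            "single_dose_value", "risk_flags")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("prescriptions file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  for (cl in RX_LOGICAL) df[[cl]] <- parse_bool(df[[cl]])
  df$single_dose_value <- suppressWarnings(as.numeric(df$single_dose_value))
  df$risk_flags <- as.integer(df$risk_flags)
  validate_prescriptions(df, vocab)
}

#' @rdname read_patients
#' @param patients Patients data frame.
#' @export
validate_patients <- function(patients) {
  stopifnot(is.data.frame(patients))
  if (nrow(patients) == 0) stop("patients table is empty")
  if (anyDuplicated(patients$patient_id))
    stop("duplicate patient_id in patients table")
  if (!all(patients$time_point %in% c("PRE", "POST")))
    stop("time_point must be PRE or POST")
  if (anyNA(patients$ward_id)) stop("ward_id missing for some patients")
  patients
}

#' @rdname read_prescriptions
#' @param prescriptions Prescriptions data frame.
#' @export
validate_prescriptions <- function(prescriptions, vocab = route_vocabulary()) {
  stopifnot(is.data.frame(prescriptions))
  if (nrow(prescriptions) == 0) stop("prescriptions table is empty")
  if (!all(prescriptions$source %in% c("PAPER", "ELECTRONIC")))
    stop("source must be PAPER or ELECTRONIC")
  validate_route(prescriptions$route, vocab)
  if (anyNA(prescriptions$as_needed))
    stop("as_needed must be true or false for every prescription")
  neg <- !is.na(prescriptions$single_dose_value) &
    prescriptions$single_dose_value < 0
  if (any(neg)) stop("single_dose_value must be nonnegative")
  prescriptions
}

check_referential_integrity <- function(patients, prescriptions) {
  orphan <- setdiff(prescriptions$patient_id, patients$patient_id)
  if (length(orphan) > 0)
    stop("prescriptions refer to unknown patient_id(s): ",
         paste(utils::head(orphan, 5), collapse = ", "))
  invisible(TRUE)
}

#' Per-patient prescription counts by category
#'
#' @param patients Patients data frame.
#' @param prescriptions Prescriptions data frame.
#' @param vocab Route vocabulary.
#' @return Data frame with one row per patient: \code{patient_id},
#'   \code{total} and one column per category (lower-case names).
#' @export
patient_category_counts <- function(patients, prescriptions,
                                    vocab = route_vocabulary()) {
  check_referential_integrity(patients, prescriptions)
  cat <- categorize_prescription(prescriptions$route, prescriptions$as_needed,
                                 vocab)
  ids <- patients$patient_id
  tab <- table(factor(prescriptions$patient_id, levels = ids), cat)
  out <- data.frame(patient_id = ids, total = as.integer(rowSums(tab)),
                    stringsAsFactors = FALSE)
  for (cc in prescription_categories())
    out[[tolower(cc)]] <- as.integer(tab[, cc])
  out
}

#' Summarize a cohort
#'
#' Patient count, mean and sample SD of per-patient prescription totals, and
#' prescription counts per category.
#'
#' @inheritParams patient_category_counts
#' @return A \code{cohort_summary} list.
#' @export
summarize_cohort <- function(patients, prescriptions,
                             vocab = route_vocabulary()) {
  validate_patients(patients)
  counts <- patient_category_counts(patients, prescriptions, vocab)
  by_cat <- colSums(counts[, tolower(prescription_categories()), drop = FALSE])
  out <- list(
    n_patients = nrow(patients),
    mean_prescriptions_per_patient = mean(counts$total),
    sd_prescriptions_per_patient = stats::sd(counts$total),
    counts_by_category = by_cat,
    total_prescriptions = sum(counts$total)
  )
  stopifnot(sum(by_cat) == out$total_prescriptions)
  class(out) <- "cohort_summary"
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: %d patients, %d prescriptions (%.1f +/- %.1f per patient)\n",
              x$n_patients, x$total_prescriptions,
              x$mean_prescriptions_per_patient,
              x$sd_prescriptions_per_patient))
  pct <- 100 * x$counts_by_category / x$total_prescriptions
  for (i in seq_along(x$counts_by_category))
    cat(sprintf("  %-17s %5d (%s%%)\n", names(x$counts_by_category)[i],
                x$counts_by_category[i], format_percent(pct[i])))
  invisible(x)
}

MATCHING_VARS <- c("total", "standard_peroral", "risky_route", "as_needed",
                   "other")

#' Matching statistics from the pre-implementation cohort
#'
#' Means and sample SDs of the five per-patient count variables (total plus
#' the four categories) used by the cohort matching rule.
#'
#' @param counts Output of \code{\link{patient_category_counts}} on the
#'   pre-implementation cohort.
#' @return List with named numeric vectors \code{mean} and \code{sd}.
#' @export
matching_stats <- function(counts) {
  miss <- setdiff(MATCHING_VARS, names(counts))
  if (length(miss) > 0)
    stop("count table lacks variable(s): ", paste(miss, collapse = ", "))
  list(mean = vapply(counts[MATCHING_VARS], mean, 0),
       sd   = vapply(counts[MATCHING_VARS], stats::sd, 0))
}

#' Cohort matching filter
#'
#' Keeps post-implementation patients whose five per-patient prescription
#' counts (total, standard peroral, risky route, as needed, other) all lie
#' within one standard deviation of the pre-implementation means. Both
#' interval ends are included.
#'
#' @param stats Output of \code{\link{matching_stats}} for the pre cohort.
#' @param post_counts Per-patient counts for candidate post patients, as
#'   produced by \code{\link{patient_category_counts}}.
#' @return The subset of \code{post_counts} rows that pass the filter.
#' @export
matching_filter <- function(stats, post_counts) {
  miss <- setdiff(MATCHING_VARS, names(post_counts))
  if (length(miss) > 0)
    stop("count table lacks variable(s): ", paste(miss, collapse = ", "))
  keep <- rep(TRUE, nrow(post_counts))
  for (v in MATCHING_VARS) {
    lo <- stats$mean[[v]] - stats$sd[[v]]
    hi <- stats$mean[[v]] + stats$sd[[v]]
    keep <- keep & post_counts[[v]] >= lo & post_counts[[v]] <= hi
  }
  post_counts[keep, , drop = FALSE]
}
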