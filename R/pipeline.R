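#' Run the full documentation-quality analysis pipeline
#'
#' Reads the patient and prescription tables, assesses every prescription
#' against the 20 criteria, computes prescription- and criterion-level
#' fulfilment scores, compares the cohorts (Mann-Whitney overall and per
#' category, chi-squared per criterion), fits the beta GLMM with patient
#' random intercepts, derives odds ratios, net interventional effects and
#' the E-value of the intervention effect, and classifies per-criterion
#' ward change patterns.
#'
#' @param patients_path CSV path (or data frame) of patients.
#' @param prescriptions_path CSV path (or data frame) of prescriptions.
#' @param ruleset Assessment ruleset.
#' @param vocab Route vocabulary.
#' @param nodes Quadrature nodes for the model fit.
#' @param pattern_tolerance Same-start/end tolerance (percentage points).
#' @param fit_model Set \code{FALSE} to skip the (slower) GLMM stage.
#' @param out_dir Optional directory for \code{report.json} and
#'   \code{report.txt}.
#' @return A \code{pipeline_report} list.
#' @export
run_pipeline <- function(patients_path, prescriptions_path,
                         ruleset = default_ruleset(),
                         vocab = route_vocabulary(), nodes = 15,
                         pattern_tolerance = 2, fit_model = TRUE,
                         out_dir = NULL) {
  patients <- if (is.data.frame(patients_path)) {
    validate_patients(patients_path)
  } else read_patients(patients_path)
  prescriptions <- if (is.data.frame(prescriptions_path)) {
    validate_prescriptions(prescriptions_path, vocab)
  } else read_prescriptions(prescriptions_path, vocab)

  pre_pat <- patients[patients$time_point == "PRE", , drop = FALSE]
  post_pat <- patients[patients$time_point == "POST", , drop = FALSE]
  rx_of <- function(p) prescriptions[prescriptions$patient_id %in%
                                       p$patient_id, , drop = FALSE]
  summaries <- list(PRE = summarize_cohort(pre_pat, rx_of(pre_pat), vocab),
                    POST = summarize_cohort(post_pat, rx_of(post_pat),
                                            vocab))

  assessment <- assess_prescriptions(patients, prescriptions, ruleset)
  scores <- prescription_fscores(assessment)
  na_stats <- count_not_applicable(assessment)
  mdata <- prepare_model_data(patients, prescriptions, scores, vocab)

  pre_sel <- mdata$time_point == "PRE"
  comparisons <- list(all = compare_fscores(mdata$fscore[pre_sel],
                                            mdata$fscore[!pre_sel]))
  for (cc in intersect(prescription_categories(), unique(mdata$category))) {
    a <- mdata$fscore[pre_sel & mdata$category == cc]
    b <- mdata$fscore[!pre_sel & mdata$category == cc]
    if (length(a) > 0 && length(b) > 0)
      comparisons[[cc]] <- compare_fscores(a, b)
  }

  csum <- criteria_summary(assessment, patients)
  crit_tests <- list()
  for (cr in intersect(csum$criterion[csum$cohort == "PRE"],
                       csum$criterion[csum$cohort == "POST"])) {
    a <- csum[csum$criterion == cr & csum$cohort == "PRE", ]
    b <- csum[csum$criterion == cr & csum$cohort == "POST", ]
    tst <- compare_criterion(a$met, a$applicable, b$met, b$applicable)
    crit_tests[[as.character(cr)]] <- c(list(criterion = cr), tst)
  }

  fit <- NULL; or_table <- NULL; net_effects <- NULL; e_value <- NULL
  if (fit_model) {
    fit <- fit_beta_glmm(mdata, nodes = nodes)
    or_table <- odds_ratios(fit)
    net_effects <- net_interventional_effect(fit)
    e_value <- evalue(or_table$odds_ratio[or_table$term == "time_post"])
  }

  patterns <- change_pattern_table(assessment, patients,
                                   tolerance = pattern_tolerance)

  report <- list(
    cohort_summaries = summaries,
    not_applicable = na_stats,
    fscore_comparisons = comparisons,
    criteria_summary = csum,
    criteria_tests = crit_tests,
    model = if (fit_model) list(odds_ratios = or_table,
                                sigma_b = sigma_b_ci(fit),
                                phi = fit$phi, loglik = fit$loglik,
                                converged = fit$converged) else NULL,
    net_interventional_effects = net_effects,
    e_value = e_value,
    change_patterns = patterns,
    provenance = list(ruleset_version = ruleset$version,
                      quadrature_nodes = nodes,
                      pattern_tolerance = pattern_tolerance,
                      n_patients = nrow(patients),
                      n_prescriptions = nrow(prescriptions))
  )
  class(report) <- "pipeline_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(unclass_report(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::capture.output(print(report),
                          file = file.path(out_dir, "report.txt"))
  }
  report
}

unclass_report <- function(report) {
  r <- unclass(report)
  r$cohort_summaries <- lapply(r$cohort_summaries, function(s) {
    s <- unclass(s); s$counts_by_category <- as.list(s$counts_by_category); s
  })
  if (!is.null(r$net_interventional_effects))
    r$net_interventional_effects <- as.list(r$net_interventional_effects)
  if (!is.null(r$model)) r$model$sigma_b <- as.list(r$model$sigma_b)
  r
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== Prescription documentation quality report ==\n\n")
  for (arm in names(x$cohort_summaries)) {
    cat(arm, "  "); print(x$cohort_summaries[[arm]])
  }
  cat(sprintf("\nNot-applicable criteria per prescription: %.1f (+/- %.1f)\n",
              x$not_applicable$mean, x$not_applicable$sd))
  cm <- x$fscore_comparisons$all
  cat(sprintf("\nPrescription-Fscore: %s%% (+/- %s%%) pre vs %s%% (+/- %s%%) post, p = %.3g, r = %.2f\n",
              format_percent(100 * cm$mean_a), format_percent(100 * cm$sd_a),
              format_percent(100 * cm$mean_b), format_percent(100 * cm$sd_b),
              cm$p, cm$r))
  if (!is.null(x$model)) {
    cat("\nBeta GLMM odds ratios (patient random intercept):\n")
    ot <- x$model$odds_ratios
    for (i in seq_len(nrow(ot)))
      cat(sprintf("  %-18s OR %6.2f [%5.2f; %6.2f]  p %s\n", ot$term[i],
                  ot$odds_ratio[i], ot$ci_low[i], ot$ci_high[i],
                  format.pval(ot$p[i], digits = 2, eps = 1e-3)))
    cat(sprintf("  random-intercept SD %.3f [%.3f; %.3f], phi %.1f\n",
                x$model$sigma_b[["estimate"]], x$model$sigma_b[["lower"]],
                x$model$sigma_b[["upper"]], x$model$phi))
    cat(sprintf("  E-value of the time-point OR: %.1f\n", x$e_value))
    cat("\nNet interventional effects (percentage points):\n")
    for (nm in names(x$net_interventional_effects))
      cat(sprintf("  %-18s %+.1f\n", nm, x$net_interventional_effects[[nm]]))
  }
  cat("\nChange patterns:",
      paste(sprintf("#%d:%s", x$change_patterns$criterion,
                    x$change_patterns$pattern), collapse = " "), "\n")
  invisible(x)
}
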