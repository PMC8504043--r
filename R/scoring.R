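#' Prescription-level fulfilment scores
#'
#' For every assessed prescription, the fulfilment score is the number of met
#' criteria divided by the number of applicable criteria. A prescription with
#' no applicable criterion has no defined score and raises an error.
#'
#' @param assessment An \code{assessment} from
#'   \code{\link{assess_prescriptions}}.
#' @return Data frame: \code{prescription_id}, \code{patient_id}, \code{met},
#'   \code{applicable}, \code{fscore}.
#' @export
prescription_fscores <- function(assessment) {
  stopifnot(inherits(assessment, "assessment"))
  met <- rowSums(assessment$outcomes == "M")
  applicable <- met + rowSums(assessment$outcomes == "N")
  if (any(applicable == 0))
    stop("prescription(s) with no applicable criterion: ",
         paste(utils::head(assessment$prescription_id[applicable == 0], 3),
               collapse = ", "))
  data.frame(prescription_id = assessment$prescription_id,
             patient_id = assessment$patient_id,
             met = met, applicable = applicable,
             fscore = met / applicable,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Criterion-level fulfilment score
#'
#' Share of prescriptions meeting a criterion among those where it applies.
#'
#' @param met Number of prescriptions that met the criterion.
#' @param applicable Number of prescriptions where it was applicable
#'   (positive).
#' @return Proportion in \code{[0, 1]} (vectorised).
#' @examples
#' criteria_fscore(337, 1850)  # 0.1822 -> printed as 18.2%
#' @export
criteria_fscore <- function(met, applicable) {
  stopifnot(all(applicable >= 1), all(met >= 0), all(met <= applicable))
  met / applicable
}

#' Per-criterion cohort summary
#'
#' Met and applicable counts and criteria-Fscore for each criterion within
#' each time point. Criteria applicable to no prescription in a cohort are
#' omitted from that cohort's rows.
#'
#' @param assessment An \code{assessment}.
#' @param patients Patients data frame (supplies \code{time_point}).
#' @return Data frame: \code{criterion}, \code{cohort}, \code{met},
#'   \code{applicable}, \code{fscore}.
#' @export
criteria_summary <- function(assessment, patients) {
  tp <- patients$time_point[match(assessment$patient_id,
                                  patients$patient_id)]
  if (anyNA(tp)) stop("assessment refers to patients missing from the table")
  rows <- list()
  for (cohort in intersect(c("PRE", "POST"), unique(tp))) {
    oc <- assessment$outcomes[tp == cohort, , drop = FALSE]
    met <- colSums(oc == "M")
    applicable <- met + colSums(oc == "N")
    keep <- applicable >= 1
    rows[[cohort]] <- data.frame(
      criterion = seq_len(20)[keep], cohort = cohort,
      met = met[keep], applicable = applicable[keep],
      fscore = met[keep] / applicable[keep],
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Map a closed-interval proportion strictly inside (0, 1)
#'
#' The usual boundary transformation for bounded outcomes ahead of beta
#' regression: \code{(score * (N - 1) + 0.5) / N}, with \code{N} the total
#' number of observations in the analysis set. Strictly increasing, fixes
#' 0.5, and never returns 0 or 1.
#'
#' @param score Proportion(s) in \code{[0, 1]}.
#' @param n_total Total number of observations N (>= 2).
#' @return Transformed value(s) in the open interval (0, 1).
#' @export
transform_to_open_interval <- function(score, n_total) {
  stopifnot(length(n_total) == 1, n_total >= 2)
  if (any(score < 0 | score > 1)) stop("score must lie in [0, 1]")
  (score * (n_total - 1) + 0.5) / n_total
}

#' @rdname transform_to_open_interval
#' @param y Transformed value(s).
#' @export
inverse_open_interval <- function(y, n_total) {
  (y * n_total - 0.5) / (n_total - 1)
}

#' Compare fulfilment scores between two groups (Mann-Whitney U)
#'
#' Two-sided Mann-Whitney U test using the normal approximation with tie
#' correction, plus the effect size r = |z| / sqrt(n). The U statistic is
#' reported for the first group (number of pairs in which the first group's
#' value exceeds the second's, counting ties as half).
#'
#' @param group_a,group_b Numeric vectors of scores (both nonempty).
#' @return List: \code{U}, \code{z}, \code{p}, \code{r}, and
#'   \code{mean_a}, \code{sd_a}, \code{n_a} (likewise for b).
#' @export
compare_fscores <- function(group_a, group_b) {
  n1 <- length(group_a); n2 <- length(group_b)
  if (n1 == 0 || n2 == 0) stop("both groups must be nonempty")
  x <- c(group_a, group_b)
  rk <- rank(x)
  U <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(x)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- if (sigma2 > 0) (U - mu) / sqrt(sigma2) else 0
  p <- if (sigma2 > 0) 2 * stats::pnorm(-abs(z)) else 1
  list(U = U, z = z, p = p, r = abs(z) / sqrt(n),
       mean_a = mean(group_a), sd_a = stats::sd(group_a), n_a = n1,
       mean_b = mean(group_b), sd_b = stats::sd(group_b), n_b = n2)
}

#' Compare one criterion's fulfilment between two cohorts (chi-squared)
#'
#' Pearson chi-squared on the 2x2 table of met / not-met counts, without
#' continuity correction by default. A degenerate table (a zero margin, e.g.
#' the criterion met by all or by none in both cohorts combined) yields
#' statistic 0, p = 1 and \code{degenerate = TRUE}.
#'
#' @param met_a,applicable_a Counts in the first cohort.
#' @param met_b,applicable_b Counts in the second cohort.
#' @param correct Apply the Yates continuity correction?
#' @return List: \code{statistic}, \code{p}, \code{degenerate}.
#' @export
compare_criterion <- function(met_a, applicable_a, met_b, applicable_b,
                              correct = FALSE) {
  stopifnot(applicable_a >= 1, applicable_b >= 1,
            met_a >= 0, met_b >= 0,
            met_a <= applicable_a, met_b <= applicable_b)
  tab <- matrix(c(met_a, applicable_a - met_a,
                  met_b, applicable_b - met_b), nrow = 2, byrow = TRUE)
  if (any(colSums(tab) == 0))
    return(list(statistic = 0, p = 1, degenerate = TRUE))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), p = unname(ct$p.value),
       degenerate = FALSE)
}

#' Write per-prescription scores to CSV
#'
#' @param scores Output of \code{\link{prescription_fscores}}.
#' @param n_total Total observation count used by the boundary
#'   transformation.
#' @param path Output CSV path.
#' @export
write_scores <- function(scores, n_total, path) {
  scores$transformed_fscore <- transform_to_open_interval(scores$fscore,
                                                          n_total)
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
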