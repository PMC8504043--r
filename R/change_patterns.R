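#' Ward-level pre/post trajectories for one criterion
#'
#' Criteria-Fscores per ward at each time point. A ward enters only when the
#' criterion is applicable to at least one prescription on that ward at both
#' time points (wards where a rare criterion never applies are excluded, as
#' is standard when plotting per-ward trajectories).
#'
#' @param assessment An \code{assessment}.
#' @param patients Patients data frame.
#' @param criterion Criterion id (1..20).
#' @return Data frame: \code{ward_id}, \code{criterion}, \code{fscore_pre},
#'   \code{fscore_post} (proportions). Empty, with a warning, when the
#'   criterion is applicable nowhere.
#' @export
ward_criteria_fscores <- function(assessment, patients, criterion) {
  stopifnot(criterion %in% 1:20)
  idx <- match(assessment$patient_id, patients$patient_id)
  tp <- patients$time_point[idx]
  ward <- patients$ward_id[idx]
  oc <- assessment$outcomes[, criterion]
  rows <- list()
  for (w in sort(unique(ward))) {
    fs <- c(PRE = NA_real_, POST = NA_real_)
    for (cohort in c("PRE", "POST")) {
      sel <- ward == w & tp == cohort
      applicable <- sum(oc[sel] != "X")
      if (applicable >= 1) fs[cohort] <- sum(oc[sel] == "M") / applicable
    }
    if (!anyNA(fs))
      rows[[length(rows) + 1]] <- data.frame(
        ward_id = w, criterion = criterion,
        fscore_pre = fs[["PRE"]], fscore_post = fs[["POST"]])
  }
  if (length(rows) == 0) {
    warning("criterion #", criterion,
            " applicable on no ward at both time points")
    return(data.frame(ward_id = integer(), criterion = integer(),
                      fscore_pre = numeric(), fscore_post = numeric()))
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Classify ward trajectories into a change pattern
#'
#' Four qualitative patterns describe how a criterion's ward-level scores
#' moved from pre to post:
#' \describe{
#'   \item{A}{different starting points, end points, and gradient direction}
#'   \item{B}{different starting and end points but same gradient direction}
#'   \item{C}{different starting points but same end points and direction}
#'   \item{D}{same starting points, end points, and gradient direction}
#' }
#' Starts (ends) count as "same" when their pairwise spread is at most
#' \code{tolerance} percentage points. A trajectory is flat when its change
#' is within \code{flat_tolerance} percentage points; flat trajectories are
#' direction-compatible with a single shared direction, but flat mixed with
#' both rising and falling counts as differing directions.
#'
#' @param trajectories Data frame from \code{\link{ward_criteria_fscores}}.
#' @param tolerance Same-start / same-end tolerance in percentage points.
#' @param flat_tolerance Flat-direction tolerance in percentage points.
#' @return Single character: \code{"A"}, \code{"B"}, \code{"C"} or
#'   \code{"D"}.
#' @export
classify_change_pattern <- function(trajectories, tolerance = 2,
                                    flat_tolerance = 1) {
  if (nrow(trajectories) == 0) stop("no trajectories to classify")
  pre <- 100 * trajectories$fscore_pre
  post <- 100 * trajectories$fscore_post
  same_start <- diff(range(pre)) <= tolerance
  same_end <- diff(range(post)) <= tolerance
  d <- post - pre
  dir <- ifelse(d > flat_tolerance, 1L, ifelse(d < -flat_tolerance, -1L, 0L))
  nonflat <- unique(dir[dir != 0L])
  same_dir <- length(nonflat) <= 1
  if (!same_dir) "A"
  else if (same_start && same_end) "D"
  else if (same_end) "C"
  else "B"
}

#' Change-pattern table across all criteria
#'
#' @param assessment An \code{assessment}.
#' @param patients Patients data frame.
#' @param tolerance,flat_tolerance See
#'   \code{\link{classify_change_pattern}}.
#' @return Data frame: \code{criterion}, \code{pattern}, \code{n_wards},
#'   \code{tolerance}; criteria applicable on no ward are skipped.
#' @export
change_pattern_table <- function(assessment, patients, tolerance = 2,
                                 flat_tolerance = 1) {
  rows <- list()
  for (cr in 1:20) {
    traj <- suppressWarnings(ward_criteria_fscores(assessment, patients, cr))
    if (nrow(traj) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      criterion = cr,
      pattern = classify_change_pattern(traj, tolerance, flat_tolerance),
      n_wards = nrow(traj), tolerance = tolerance,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
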