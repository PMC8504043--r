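#' Build the fixed- and random-effect design for the prescription-score model
#'
#' Constructs the observation-level fixed-effects matrix: intercept,
#' post-implementation indicator, three prescription-category indicators
#' (reference: standard peroral), the comedication count, and K-1 weighted
#' effect-coded ward columns. With weights w equal to each ward's share of
#' prescriptions, an observation on ward k (k != reference) scores 1 in
#' column k, an observation on the reference ward scores -w_k / w_ref, and
#' all other entries are 0. Each ward column then has mean exactly zero, so
#' ward coefficients are deviations from the prescription-weighted grand
#' mean. The random-effect design is the patient indicator.
#'
#' @param data Observation-level data frame with columns \code{time_point},
#'   \code{category}, \code{n_comedications}, \code{ward_id},
#'   \code{patient_id} (see \code{\link{prepare_model_data}}).
#' @param ref_ward Ward used as the weighted-effect-coding reference; by
#'   default the highest ward id present.
#' @return List: \code{X} (fixed design), \code{patient} (factor),
#'   \code{ward_weights} (named shares), \code{ref_ward}, \code{wards}.
#' @export
build_design <- function(data, ref_ward = NULL) {
  need <- c("time_point", "category", "n_comedications", "ward_id",
            "patient_id")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    stop("model data lacks column(s): ", paste(miss, collapse = ", "))
  if (anyNA(data$n_comedications) || anyNA(data$ward_id) ||
      anyNA(data$time_point) || anyNA(data$category))
    stop("missing covariate values in model data")
  wards <- sort(unique(data$ward_id))
  if (is.null(ref_ward)) ref_ward <- wards[length(wards)]
  if (!(ref_ward %in% wards)) stop("reference ward ", ref_ward,
                                   " has no prescriptions")
  n <- nrow(data)
  w <- as.numeric(table(factor(data$ward_id, levels = wards))) / n
  names(w) <- wards
  if (any(w == 0)) stop("ward(s) with zero prescriptions: ",
                        paste(wards[w == 0], collapse = ", "))

  cat <- factor(data$category, levels = prescription_categories())
  if (anyNA(cat)) stop("unknown prescription category in model data")
  X <- cbind(
    `(Intercept)` = 1,
    time_post = as.numeric(data$time_point == "POST"),
    cat_risky_route = as.numeric(cat == "RISKY_ROUTE"),
    cat_as_needed = as.numeric(cat == "AS_NEEDED"),
    cat_other = as.numeric(cat == "OTHER"),
    n_comedications = as.numeric(data$n_comedications)
  )
  for (k in setdiff(wards, ref_ward)) {
    col <- numeric(n)
    col[data$ward_id == k] <- 1
    col[data$ward_id == ref_ward] <- -w[[as.character(k)]] /
      w[[as.character(ref_ward)]]
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- paste0("ward_", k)
  }
  list(X = X, patient = factor(data$patient_id),
       ward_weights = w, ref_ward = ref_ward, wards = wards)
}

#' Assemble the observation-level model data
#'
#' Joins per-prescription fulfilment scores with patient covariates and
#' applies the open-interval boundary transformation with N equal to the
#' total number of observations.
#'
#' @param patients Patients data frame.
#' @param prescriptions Prescriptions data frame.
#' @param scores Output of \code{\link{prescription_fscores}}.
#' @param vocab Route vocabulary (for categorization).
#' @return Data frame with \code{y} (transformed score in (0,1)),
#'   \code{fscore}, \code{time_point}, \code{category},
#'   \code{n_comedications}, \code{ward_id}, \code{patient_id}.
#' @export
prepare_model_data <- function(patients, prescriptions, scores,
                               vocab = route_vocabulary()) {
  stopifnot(nrow(scores) == nrow(prescriptions))
  idx <- match(prescriptions$patient_id, patients$patient_id)
  if (anyNA(idx)) stop("prescriptions refer to unknown patients")
  n <- nrow(prescriptions)
  data.frame(
    y = transform_to_open_interval(scores$fscore, n),
    fscore = scores$fscore,
    time_point = patients$time_point[idx],
    category = as.character(categorize_prescription(prescriptions$route,
                                                    prescriptions$as_needed,
                                                    vocab)),
    n_comedications = patients$n_comedications[idx],
    ward_id = patients$ward_id[idx],
    patient_id = prescriptions$patient_id,
    stringsAsFactors = FALSE
  )
}
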