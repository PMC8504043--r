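#' Simulation configuration for synthetic cohorts
#'
#' Builds the configuration consumed by the generators. Defaults emulate a
#' two-cohort (pre/post CPOE) hospital study: 160 patients per time point
#' over 7 wards (the largest ward contributing twice as many patients),
#' per-patient prescription counts of 11.6 +/- 5.6 (pre) and 10.0 +/- 3.3
#' (post), the observed category mixtures, per-criterion fulfilment
#' probabilities equal to the observed criteria-Fscores of each cohort, and
#' a patient-level latent shift on the logit scale inducing within-patient
#' correlation of scores.
#'
#' @param seed Integer seed; fully determines generator output.
#' @param n_patients_per_ward Named integer vector, patients per ward per
#'   time point.
#' @param rx_per_patient List with \code{PRE}/\code{POST} elements
#'   \code{c(mean, sd)} of the per-patient prescription count (truncated at
#'   1).
#' @param category_mix List with \code{PRE}/\code{POST} probability vectors
#'   over the four categories (standard peroral, risky route, as needed,
#'   other).
#' @param model_params Score-level truth: \code{beta} (named fixed effects),
#'   \code{ward_effects} (per-ward log-odds shifts), \code{sigma_b},
#'   \code{phi}.
#' @param criterion_probs 20 x 2 matrix (\code{PRE}, \code{POST} columns) of
#'   fulfilment probabilities among applicable prescriptions.
#' @param applicability_probs Named list of tri-state applicability rates
#'   (see defaults).
#' @param p_risky_within_as_needed Share of as-needed orders carrying a
#'   risky route, per time point.
#' @param p_body_site_required Rate of orders requiring a body site.
#' @param latent_sd SD of the shared patient-level logit shift applied to
#'   fulfilment probabilities (record-level mode).
#' @param matching_max_attempts Oversampling cap for the matched post
#'   cohort.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L,
                       n_patients_per_ward = c(`1` = 20L, `2` = 20L,
                                               `3` = 20L, `4` = 20L,
                                               `5` = 20L, `6` = 20L,
                                               `7` = 40L),
                       rx_per_patient = list(PRE = c(mean = 11.6, sd = 5.6),
                                             POST = c(mean = 10.0, sd = 3.3)),
                       category_mix = list(
                         PRE = c(0.568, 0.143, 0.244, 0.044) /
                           sum(c(0.568, 0.143, 0.244, 0.044)),
                         POST = c(0.622, 0.126, 0.227, 0.025)),
                       model_params = default_model_params(),
                       criterion_probs = default_criterion_probs(),
                       applicability_probs = default_applicability_probs(),
                       p_risky_within_as_needed = c(PRE = 0.177,
                                                    POST = 0.119),
                       p_body_site_required = 0.005,
                       latent_sd = 0.76,
                       matching_max_attempts = 50L) {
  for (arm in c("PRE", "POST")) {
    mix <- category_mix[[arm]]
    if (length(mix) != 4 || any(mix < 0))
      stop("category_mix$", arm, " must be 4 nonnegative probabilities")
    category_mix[[arm]] <- mix / sum(mix)
  }
  if (!all(dim(criterion_probs) == c(20, 2)))
    stop("criterion_probs must be a 20 x 2 matrix")
  if (any(criterion_probs < 0 | criterion_probs > 1))
    stop("criterion probabilities must lie in [0, 1]")
  cfg <- list(seed = as.integer(seed),
              n_patients_per_ward = n_patients_per_ward,
              rx_per_patient = rx_per_patient,
              category_mix = category_mix,
              model_params = model_params,
              criterion_probs = criterion_probs,
              applicability_probs = applicability_probs,
              p_risky_within_as_needed = p_risky_within_as_needed,
              p_body_site_required = p_body_site_required,
              latent_sd = latent_sd,
              matching_max_attempts = matching_max_attempts)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_model_params <- function() {
  list(beta = c(`(Intercept)` = log(1.71), time_post = log(10.11),
                cat_risky_route = log(0.76), cat_as_needed = log(0.59),
                cat_other = log(0.87), n_comedications = log(0.99)),
       ward_effects = log(c(`1` = 0.80, `2` = 1.04, `3` = 0.53, `4` = 0.82,
                            `5` = 1.29, `6` = 1.44, `7` = 1.21)),
       sigma_b = 0.762, phi = 30)
}

#' @rdname sim_config
#' @export
default_criterion_probs <- function() {
  m <- matrix(c(
    0.819, 0.540,   # 1 allergies
    0.182, 1.000,   # 2 age
    0.552, 0.870,   # 3 weight
    0.889, 0.880,   # 4 organ functions
    0.431, 0.619,   # 5 drug history
    0.575, 1.000,   # 6 valid
    0.000, 1.000,   # 7 computer-aided
    0.898, 1.000,   # 8 legible
    0.788, 0.734,   # 9 no substance abbreviations
    0.962, 0.997,   # 10 trade name / active substances
    0.571, 0.800,   # 11 dose strength and unit
    0.126, 0.964,   # 12 dosage form and release
    0.149, 0.944,   # 13 single dose and unit
    0.744, 1.000,   # 14 dosage interval
    0.969, 0.977,   # 15 whole-number single dose
    0.084, 1.000,   # 16 risky route unabbreviated
    0.273, 0.600,   # 17 body site
    0.930, 0.941,   # 18 no identified risks
    0.013, 0.798,   # 19 reason for as-needed
    0.619, 0.914),  # 20 complete and unambiguous
    ncol = 2, byrow = TRUE, dimnames = list(1:20, c("PRE", "POST")))
  m
}

#' @rdname sim_config
#' @export
default_applicability_probs <- function() {
  list(drug_history = c(PRE = 0.942, POST = 0.935),        # criterion 5
       substance_abbrev = c(PRE = 0.443, POST = 0.486),    # criterion 9
       dose_strength = c(PRE = 0.996, POST = 0.996),       # criterion 11
       dose_unit_interval = c(PRE = 0.991, POST = 1.0),    # criteria 13/14
       single_dose_present = c(PRE = 0.760, POST = 0.945)) # criterion 15
}

# solve E[plogis(a + sd * Z)] = p for the logit intercept a, so that the
# patient latent shift leaves the marginal fulfilment rate at p
calibrate_logit <- function(p, sd) {
  if (p <= 0) return(-Inf)
  if (p >= 1) return(Inf)
  if (sd == 0) return(stats::qlogis(p))
  gh <- pracma::gaussHermite(21)
  marg <- function(a) sum(gh$w / sqrt(pi) *
                            stats::plogis(a + sd * sqrt(2) * gh$x)) - p
  stats::uniroot(marg, c(-40, 40), tol = 1e-10)$root
}

# memoized calibration over the probabilities used in one run
make_calibrator <- function(sd) {
  cache <- new.env(parent = emptyenv())
  function(p) {
    key <- sprintf("%.12g", p)
    if (is.null(cache[[key]])) cache[[key]] <- calibrate_logit(p, sd)
    cache[[key]]
  }
}

# Bernoulli draw with patient-level logit shift u, marginal rate p
rbern_shift <- function(p_logit, u) {
  stats::runif(length(u)) < stats::plogis(p_logit + u)
}

# per-patient prescription counts: discretized gamma matched to (mean, sd),
# truncated at 1
draw_rx_counts <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  rate <- mean / sd^2
  pmax(1L, as.integer(round(stats::rgamma(n, shape = shape, rate = rate))))
}

RISKY_ROUTE_POOL <- c("subcutaneous", "intravenous", "intramuscular",
                      "epidural", "via-probe", "intraarterial")
OTHER_ROUTE_POOL <- c("transdermal", "ocular", "nasal", "rectal",
                      "inhalative")

# one synthetic arm of patients + structured prescriptions
simulate_arm <- function(config, arm, n_per_ward, id_prefix) {
  stopifnot(arm %in% c("PRE", "POST"))
  cal <- make_calibrator(config$latent_sd)
  cp <- config$criterion_probs[, arm]
  ap <- lapply(config$applicability_probs, function(x) x[[arm]])
  wards <- as.integer(names(n_per_ward))
  n_pat <- sum(n_per_ward)
  pid <- sprintf("%s%04d", id_prefix, seq_len(n_pat))
  ward_id <- rep(wards, n_per_ward)
  u <- stats::rnorm(n_pat, 0, config$latent_sd)

  rx_mean <- config$rx_per_patient[[arm]][["mean"]]
  rx_sd <- config$rx_per_patient[[arm]][["sd"]]
  n_rx <- draw_rx_counts(n_pat, rx_mean, rx_sd)

  hist_app <- stats::runif(n_pat) < ap$drug_history
  patients <- data.frame(
    patient_id = pid, ward_id = ward_id, time_point = arm,
    age_years = pmin(pmax(round(stats::rnorm(n_pat, 59, 20)), 18), 99),
    sex = sample(c("F", "M"), n_pat, replace = TRUE, prob = c(0.52, 0.48)),
    weight_kg = round(stats::rnorm(n_pat, 75, 15), 1),
    allergies_documented = rbern_shift(cal(cp[1]), u),
    age_documented = rbern_shift(cal(cp[2]), u),
    weight_documented = rbern_shift(cal(cp[3]), u),
    renal_function_documented = rbern_shift(cal(cp[4]), u),
    drug_history_documented = ifelse(hist_app,
                                     rbern_shift(cal(cp[5]), u), NA),
    n_comedications = n_rx - 1L,
    stringsAsFactors = FALSE)

  m <- sum(n_rx)
  rx_pat <- rep(seq_len(n_pat), n_rx)
  uo <- u[rx_pat]

  cat <- sample(prescription_categories(), m, replace = TRUE,
                prob = config$category_mix[[arm]])
  route <- character(m)
  route[cat == "STANDARD_PERORAL"] <- "peroral"
  nr <- sum(cat == "RISKY_ROUTE")
  route[cat == "RISKY_ROUTE"] <- sample(RISKY_ROUTE_POOL, nr, replace = TRUE)
  no <- sum(cat == "OTHER")
  route[cat == "OTHER"] <- sample(OTHER_ROUTE_POOL, no, replace = TRUE)
  ian <- which(cat == "AS_NEEDED")
  if (length(ian) > 0) {
    p_risky <- config$p_risky_within_as_needed[[arm]]
    risky_an <- stats::runif(length(ian)) < p_risky
    route[ian[risky_an]] <- sample(RISKY_ROUTE_POOL, sum(risky_an),
                                   replace = TRUE)
    rest <- ian[!risky_an]
    peroral_an <- stats::runif(length(rest)) < 0.75
    route[rest[peroral_an]] <- "peroral"
    route[rest[!peroral_an]] <- sample(OTHER_ROUTE_POOL, sum(!peroral_an),
                                       replace = TRUE)
  }
  as_needed <- cat == "AS_NEEDED"
  risky <- route %in% RISKY_ROUTE_POOL | startsWith(route, "intra")

  # tri-state applicabilities (unshifted), then fulfilment fields with the
  # patient shift, calibrated so marginal met-rates equal criterion_probs
  app9 <- stats::runif(m) < ap$substance_abbrev
  app11 <- stats::runif(m) < ap$dose_strength
  app1314 <- stats::runif(m) < ap$dose_unit_interval
  value_present <- stats::runif(m) < ap$single_dose_present
  p13_cond <- min(1, cp[13] / ap$single_dose_present)
  body_req <- stats::runif(m) < config$p_body_site_required

  source_elec <- rbern_shift(cal(cp[7]), rep(0, m))
  dose_int <- sample(c(1, 2, 5, 10, 50, 100, 250, 500), m, replace = TRUE)
  whole <- rbern_shift(cal(cp[15]), uo)
  sdv <- ifelse(value_present, ifelse(whole, dose_int, dose_int + 0.5), NA)

  unit_doc <- rbern_shift(cal(p13_cond), uo)
  rx <- data.frame(
    prescription_id = sprintf("%s-rx%05d", id_prefix, seq_len(m)),
    patient_id = pid[rx_pat],
    route = route, as_needed = as_needed,
    source = ifelse(source_elec, "ELECTRONIC", "PAPER"),
    drug_display_name = sprintf("drug%03d", sample.int(150, m,
                                                       replace = TRUE)),
    trade_name_complete = rbern_shift(cal(cp[10]), uo),
    active_substances_fully_named = FALSE,
    contains_substance_abbreviation =
      ifelse(app9, !rbern_shift(cal(cp[9]), uo), NA),
    dose_strength_documented = ifelse(app11, rbern_shift(cal(cp[11]), uo),
                                      NA),
    dosage_form_and_release_documented = rbern_shift(cal(cp[12]), uo),
    single_dose_value = sdv,
    single_dose_unit_documented = ifelse(app1314, unit_doc, NA),
    dosage_interval_documented = ifelse(app1314,
                                        rbern_shift(cal(cp[14]), uo), NA),
    is_valid = rbern_shift(cal(cp[6]), uo),
    is_legible = rbern_shift(cal(cp[8]), uo),
    risky_route_stated_unabbreviated =
      ifelse(risky, rbern_shift(cal(cp[16]), uo), NA),
    body_site_required = body_req,
    body_site_documented = ifelse(body_req, rbern_shift(cal(cp[17]), uo),
                                  NA),
    reason_documented = ifelse(as_needed, rbern_shift(cal(cp[19]), uo), NA),
    risk_flags = ifelse(rbern_shift(cal(cp[18]), uo), 0L,
                        1L + stats::rpois(m, 0.5)),
    complete_and_unambiguous = rbern_shift(cal(cp[20]), uo),
    stringsAsFactors = FALSE)
  list(patients = patients, prescriptions = rx)
}

#' Generate a record-level synthetic study (both cohorts, no matching)
#'
#' Draws structured patient and prescription tables for the pre and post
#' cohorts whose field-level rates, shifted per patient by a shared latent
#' logit effect, induce criterion outcomes matching
#' \code{config$criterion_probs} in expectation when pushed through the
#' criteria engine.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{patients} and \code{prescriptions} data frames
#'   covering both cohorts.
#' @export
simulate_record_level <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pre <- simulate_arm(config, "PRE", config$n_patients_per_ward, "pre")
  post <- simulate_arm(config, "POST", config$n_patients_per_ward, "post")
  list(patients = rbind(pre$patients, post$patients),
       prescriptions = rbind(pre$prescriptions, post$prescriptions))
}

#' Generate score-level data directly from the beta GLMM
#'
#' Draws covariates (cohort, ward, category, comedication count), patient
#' random intercepts b_i ~ N(0, sigma_b^2), and transformed fulfilment
#' scores y ~ Beta(mu * phi, (1 - mu) * phi) with
#' logit(mu) = x' beta + ward effect + b_i. Emits exactly the table
#' \code{\link{fit_beta_glmm}} consumes.
#'
#' @param config A \code{\link{sim_config}}; truth taken from
#'   \code{config$model_params}.
#' @return List: \code{data} (observation-level model data frame),
#'   \code{patients}, and \code{truth} (the generating parameters).
#' @export
simulate_score_level <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mp <- config$model_params
  stopifnot(mp$sigma_b >= 0, mp$phi > 0)
  rows <- list()
  pats <- list()
  for (arm in c("PRE", "POST")) {
    npw <- config$n_patients_per_ward
    n_pat <- sum(npw)
    pid <- sprintf("%s%04d", tolower(arm), seq_len(n_pat))
    ward <- rep(as.integer(names(npw)), npw)
    nrx <- draw_rx_counts(n_pat, config$rx_per_patient[[arm]][["mean"]],
                          config$rx_per_patient[[arm]][["sd"]])
    b <- stats::rnorm(n_pat, 0, mp$sigma_b)
    m <- sum(nrx)
    idx <- rep(seq_len(n_pat), nrx)
    cat <- sample(prescription_categories(), m, replace = TRUE,
                  prob = config$category_mix[[arm]])
    ncom <- (nrx - 1L)[idx]
    eta <- mp$beta[["(Intercept)"]] +
      mp$beta[["time_post"]] * (arm == "POST") +
      mp$beta[["cat_risky_route"]] * (cat == "RISKY_ROUTE") +
      mp$beta[["cat_as_needed"]] * (cat == "AS_NEEDED") +
      mp$beta[["cat_other"]] * (cat == "OTHER") +
      mp$beta[["n_comedications"]] * ncom +
      mp$ward_effects[as.character(ward[idx])] +
      b[idx]
    mu <- stats::plogis(eta)
    y <- stats::rbeta(m, mu * mp$phi, (1 - mu) * mp$phi)
    y <- pmin(pmax(y, 1e-6), 1 - 1e-6)
    rows[[arm]] <- data.frame(
      y = y, fscore = y, time_point = arm, category = cat,
      n_comedications = ncom, ward_id = ward[idx], patient_id = pid[idx],
      stringsAsFactors = FALSE)
    pats[[arm]] <- data.frame(patient_id = pid, ward_id = ward,
                              time_point = arm, stringsAsFactors = FALSE)
  }
  list(data = rbind(rows$PRE, rows$POST),
       patients = rbind(pats$PRE, pats$POST),
       truth = mp)
}

#' Generate a complete matched pre/post study bundle
#'
#' Generates the pre cohort, computes the five per-patient count statistics,
#' then oversamples post-cohort candidates ward by ward, keeping only
#' patients passing \code{\link{matching_filter}}, until each ward reaches
#' its target size (or a configurable attempt cap is hit).
#'
#' @param config A \code{\link{sim_config}}.
#' @param out_dir Optional directory; when given, writes
#'   \code{patients.csv}, \code{prescriptions.csv} and
#'   \code{manifest.json}.
#' @return List: \code{patients}, \code{prescriptions},
#'   \code{pre_matching_stats}, \code{manifest}.
#' @export
simulate_pre_post_study <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pre <- simulate_arm(config, "PRE", config$n_patients_per_ward, "pre")
  stats <- matching_stats(patient_category_counts(pre$patients,
                                                  pre$prescriptions))
  target <- config$n_patients_per_ward
  kept_pat <- list(); kept_rx <- list()
  got <- stats::setNames(integer(length(target)), names(target))
  for (attempt in seq_len(config$matching_max_attempts)) {
    cand <- simulate_arm(config, "POST", target,
                         sprintf("post_b%02d_", attempt))
    counts <- patient_category_counts(cand$patients, cand$prescriptions)
    ok <- matching_filter(stats, counts)$patient_id
    keep_ids <- character(0)
    for (w in names(target)) {
      need <- target[[w]] - got[[w]]
      if (need <= 0) next
      ids <- cand$patients$patient_id[cand$patients$ward_id ==
                                        as.integer(w) &
                                        cand$patients$patient_id %in% ok]
      take <- utils::head(ids, need)
      got[[w]] <- got[[w]] + length(take)
      keep_ids <- c(keep_ids, take)
    }
    kept_pat[[attempt]] <- cand$patients[cand$patients$patient_id %in%
                                           keep_ids, , drop = FALSE]
    kept_rx[[attempt]] <- cand$prescriptions[
      cand$prescriptions$patient_id %in% keep_ids, , drop = FALSE]
    if (all(got >= target)) break
  }
  if (!all(got >= target))
    stop("matched post cohort infeasible after ",
         config$matching_max_attempts, " oversampling rounds; filled ",
         sum(got), "/", sum(target), " patients")
  patients <- rbind(pre$patients, do.call(rbind, kept_pat))
  prescriptions <- rbind(pre$prescriptions, do.call(rbind, kept_rx))
  manifest <- list(seed = config$seed,
                   config_hash = config_hash(config),
                   n_patients = nrow(patients),
                   n_prescriptions = nrow(prescriptions),
                   n_pre = nrow(pre$patients),
                   n_post = nrow(patients) - nrow(pre$patients),
                   oversampling_rounds = attempt)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_patients(patients, file.path(out_dir, "patients.csv"))
    write_prescriptions(prescriptions,
                        file.path(out_dir, "prescriptions.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(patients = patients, prescriptions = prescriptions,
       pre_matching_stats = stats, manifest = manifest)
}

# stable content hash of a config (polynomial rolling hash over its
# canonical JSON; provenance fingerprint, not cryptographic)
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = 12)
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

format_bool <- function(x) ifelse(is.na(x), "", ifelse(x, "true", "false"))

#' Write patient / prescription tables in the package CSV dialect
#'
#' Booleans as \code{true}/\code{false}, missing and not-applicable values
#' as empty cells.
#'
#' @param patients,prescriptions Data frames.
#' @param path Output CSV path.
#' @export
write_patients <- function(patients, path) {
  df <- patients
  for (cl in intersect(PATIENT_LOGICAL, names(df)))
    df[[cl]] <- format_bool(df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_patients
#' @export
write_prescriptions <- function(prescriptions, path) {
  df <- prescriptions
  for (cl in intersect(RX_LOGICAL, names(df)))
    df[[cl]] <- format_bool(df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
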