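# in-code fixtures: a fully documented electronic prescription and its
# patient, plus knobs to break individual fields

make_patient <- function(patient_id = "p1", ward_id = 1L,
                         time_point = "POST", drug_history = TRUE,
                         n_comedications = 3L, ...) {
  args <- list(...)
  df <- data.frame(
    patient_id = patient_id, ward_id = ward_id, time_point = time_point,
    age_years = 60, sex = "F", weight_kg = 70,
    allergies_documented = TRUE, age_documented = TRUE,
    weight_documented = TRUE, renal_function_documented = TRUE,
    drug_history_documented = drug_history,
    n_comedications = n_comedications,
    stringsAsFactors = FALSE)
  for (nm in names(args)) df[[nm]] <- args[[nm]]
  df
}

make_prescription <- function(prescription_id = "rx1", patient_id = "p1",
                              route = "peroral", as_needed = FALSE,
                              source = "ELECTRONIC", ...) {
  args <- list(...)
  df <- data.frame(
    prescription_id = prescription_id, patient_id = patient_id,
    route = route, as_needed = as_needed, source = source,
    drug_display_name = "drug001", trade_name_complete = TRUE,
    active_substances_fully_named = FALSE,
    contains_substance_abbreviation = FALSE,
    dose_strength_documented = TRUE,
    dosage_form_and_release_documented = TRUE,
    single_dose_value = 100,
    single_dose_unit_documented = TRUE,
    dosage_interval_documented = TRUE,
    is_valid = TRUE, is_legible = TRUE,
    risky_route_stated_unabbreviated = NA,
    body_site_required = FALSE, body_site_documented = NA,
    reason_documented = NA, risk_flags = 0L,
    complete_and_unambiguous = TRUE,
    stringsAsFactors = FALSE)
  for (nm in names(args)) df[[nm]] <- args[[nm]]
  df
}

# small simulation config for fast tests
small_config <- function(seed = 1, ...) {
  sim_config(seed = seed,
             n_patients_per_ward = c(`1` = 4L, `2` = 4L, `3` = 8L),
             ...)
}

# independent oracle: dense-grid integration of the marginal likelihood.
# The window spans 10 sigma around zero AND around each patient's
# likelihood centre, so no posterior mass is truncated even when the
# evaluation point is far from the data-generating parameters.
brute_loglik <- function(beta, sigma, phi, y, X, pid, npts = 10001,
                         width = 10) {
  eta <- drop(X %*% beta)
  total <- 0
  for (i in unique(pid)) {
    sel <- pid == i
    centre <- mean(qlogis(y[sel]) - eta[sel])
    grid <- seq(min(0, centre) - width * sigma,
                max(0, centre) + width * sigma, length.out = npts)
    h <- grid[2] - grid[1]
    lf <- vapply(grid, function(b) {
      mu <- plogis(eta[sel] + b)
      sum(dbeta(y[sel], mu * phi, (1 - mu) * phi, log = TRUE)) +
        dnorm(b, 0, sigma, log = TRUE)
    }, 0)
    mx <- max(lf)
    total <- total + mx + log(sum(exp(lf - mx)) * h)
  }
  total
}

# tiny clustered beta outcome fixture for likelihood tests
make_beta_fixture <- function(seed = 42, n_pat = 4, n_obs = 3,
                              sigma = 0.5, phi = 20) {
  set.seed(seed)
  pid <- rep(seq_len(n_pat), each = n_obs)
  x <- rnorm(n_pat * n_obs)
  b <- rnorm(n_pat, 0, sigma)
  mu <- plogis(0.3 + 0.8 * x + b[pid])
  y <- rbeta(n_pat * n_obs, mu * phi, (1 - mu) * phi)
  y <- pmin(pmax(y, 1e-4), 1 - 1e-4)
  list(y = y, X = cbind(`(Intercept)` = 1, x = x), pid = pid)
}
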