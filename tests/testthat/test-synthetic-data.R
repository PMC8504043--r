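test_that("generation is fully determined by the seed", {
  s1 <- simulate_record_level(small_config(seed = 4))
  s2 <- simulate_record_level(small_config(seed = 4))
  expect_identical(s1, s2)
  s3 <- simulate_record_level(small_config(seed = 5))
  expect_false(identical(s1$prescriptions, s3$prescriptions))
  sc1 <- simulate_score_level(small_config(seed = 4))
  sc2 <- simulate_score_level(small_config(seed = 4))
  expect_identical(sc1$data, sc2$data)
})

test_that("configs are validated", {
  expect_error(sim_config(category_mix = list(PRE = c(1, 2), POST = 1:4)),
               "category_mix")
  bad <- default_criterion_probs(); bad[3, 1] <- 1.4
  expect_error(sim_config(criterion_probs = bad), "0, 1")
  expect_error(sim_config(criterion_probs = matrix(0.5, 10, 2)),
               "20 x 2")
})

test_that("perfect documentation probabilities give perfect scores", {
  cfg <- small_config(
    seed = 8,
    criterion_probs = matrix(1, 20, 2,
                             dimnames = list(1:20, c("PRE", "POST"))),
    applicability_probs = list(
      drug_history = c(PRE = 1, POST = 1),
      substance_abbrev = c(PRE = 1, POST = 1),
      dose_strength = c(PRE = 1, POST = 1),
      dose_unit_interval = c(PRE = 1, POST = 1),
      single_dose_present = c(PRE = 1, POST = 1)))
  sim <- simulate_record_level(cfg)
  a <- assess_prescriptions(sim$patients, sim$prescriptions)
  s <- prescription_fscores(a)
  expect_true(all(s$fscore == 1))
})

test_that("tables round-trip through the CSV dialect without loss", {
  sim <- simulate_record_level(small_config(seed = 6))
  pf <- tempfile(fileext = ".csv"); rf <- tempfile(fileext = ".csv")
  write_patients(sim$patients, pf)
  write_prescriptions(sim$prescriptions, rf)
  pats <- read_patients(pf)
  rx <- read_prescriptions(rf)
  for (cl in names(sim$patients))
    expect_equal(pats[[cl]], sim$patients[[cl]], ignore_attr = TRUE,
                 label = paste("patients column", cl))
  for (cl in names(sim$prescriptions))
    expect_equal(rx[[cl]], sim$prescriptions[[cl]], ignore_attr = TRUE,
                 label = paste("prescriptions column", cl))
})

test_that("score-level mode with sigma_b = 0 has no between-patient excess variance", {
  mp <- default_model_params(); mp$sigma_b <- 0
  sim <- simulate_score_level(sim_config(seed = 12, model_params = mp))
  d <- sim$data[sim$data$time_point == "PRE" &
                  sim$data$category == "STANDARD_PERORAL", ]
  # variance of patient means should match what within-patient sampling
  # alone predicts (no random intercept): compare via one-way ANOVA F
  d$patient_id <- factor(d$patient_id)
  d <- d[d$patient_id %in% names(which(table(d$patient_id) >= 3)), ]
  f <- anova(lm(qlogis(y) ~ n_comedications + factor(ward_id) + patient_id,
                data = d))
  expect_gt(f["patient_id", "Pr(>F)"], 0.001)
})

test_that("the matched study bundle honours ward quotas and the filter", {
  cfg <- sim_config(seed = 14)
  study <- simulate_pre_post_study(cfg)
  expect_equal(nrow(study$patients), 320)
  tab <- table(study$patients$ward_id, study$patients$time_point)
  expect_equal(unname(tab[, "PRE"]), c(20L, 20L, 20L, 20L, 20L, 20L, 40L))
  expect_equal(unname(tab[, "POST"]), c(20L, 20L, 20L, 20L, 20L, 20L, 40L))
  # every kept post patient passes the matching filter
  post <- study$patients[study$patients$time_point == "POST", ]
  counts <- patient_category_counts(
    post, study$prescriptions[study$prescriptions$patient_id %in%
                                post$patient_id, ])
  kept <- matching_filter(study$pre_matching_stats, counts)
  expect_equal(nrow(kept), nrow(post))
  expect_true(is.character(study$manifest$config_hash))
})

test_that("matching acceptance rate agrees with a resampling oracle", {
  cfg <- sim_config(seed = 15)
  set.seed(cfg$seed)
  pre <- rxaudit:::simulate_arm(cfg, "PRE", cfg$n_patients_per_ward, "pre")
  stats <- matching_stats(patient_category_counts(pre$patients,
                                                  pre$prescriptions))
  # oracle: empirical pass rate of fresh PRE-distributed patients
  hits <- integer(0)
  for (r in 1:12) {
    cand <- rxaudit:::simulate_arm(cfg, "PRE", cfg$n_patients_per_ward,
                                   sprintf("c%02d", r))
    counts <- patient_category_counts(cand$patients, cand$prescriptions)
    hits <- c(hits, nrow(matching_filter(stats, counts)))
  }
  rate <- mean(hits) / sum(cfg$n_patients_per_ward)
  # the five-way within-one-SD box keeps an appreciable but partial share
  expect_gt(rate, 0.15); expect_lt(rate, 0.95)
  # binomial agreement between two halves of the resampling oracle
  r1 <- mean(hits[1:6]); r2 <- mean(hits[7:12])
  n <- sum(cfg$n_patients_per_ward)
  se <- sqrt(2 * rate * (1 - rate) / (6 * n))
  expect_lt(abs(r1 - r2) / n, 4 * se + 0.05)
})
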