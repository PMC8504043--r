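vocab <- route_vocabulary()

test_that("risky-route classification follows the list and the intra- prefix", {
  expect_true(is_risky_route("subcutaneous", vocab))
  expect_false(is_risky_route("peroral", vocab))
  expect_false(is_risky_route("transdermal", vocab))
  # every intra-* token in the vocabulary is risky by the prefix rule
  intra <- grep("^intra", vocab$vocabulary, value = TRUE)
  expect_gt(length(intra), 5)
  expect_true(all(is_risky_route(intra, vocab)))
  # normalisation: hyphens, case, spaces
  expect_true(is_risky_route("Sub-Tenon", vocab))
  expect_true(is_risky_route("via probe", vocab))
  expect_error(is_risky_route("oralperos", vocab), "unknown")
})

test_that("categorization puts as-needed first, then splits by route", {
  expect_equal(as.character(categorize_prescription("subcutaneous", TRUE,
                                                    vocab)), "AS_NEEDED")
  expect_equal(as.character(categorize_prescription("peroral", FALSE,
                                                    vocab)),
               "STANDARD_PERORAL")
  expect_equal(as.character(categorize_prescription("transdermal", FALSE,
                                                    vocab)), "OTHER")
  expect_equal(as.character(categorize_prescription("epidural", FALSE,
                                                    vocab)), "RISKY_ROUTE")
})

test_that("categories partition any generated prescription set", {
  sim <- simulate_record_level(small_config(seed = 5))
  cat <- categorize_prescription(sim$prescriptions$route,
                                 sim$prescriptions$as_needed, vocab)
  expect_equal(sum(table(cat)), nrow(sim$prescriptions))
  expect_false(anyNA(cat))
  # order independence
  perm <- sample(nrow(sim$prescriptions))
  cat2 <- categorize_prescription(sim$prescriptions$route[perm],
                                  sim$prescriptions$as_needed[perm], vocab)
  expect_equal(as.character(cat2), as.character(cat)[perm])
})

test_that("cohort summary reports counts and sample SD", {
  pats <- rbind(make_patient("a"), make_patient("b"))
  rx <- do.call(rbind, c(
    lapply(1:3, function(i) make_prescription(paste0("a", i), "a")),
    lapply(1:5, function(i) make_prescription(paste0("b", i), "b"))))
  s <- summarize_cohort(pats, rx)
  expect_equal(s$mean_prescriptions_per_patient, 4)
  expect_equal(s$sd_prescriptions_per_patient, sd(c(3, 5)))
  expect_equal(s$total_prescriptions, 8)
  expect_equal(sum(s$counts_by_category), 8)
  expect_error(summarize_cohort(pats[0, ], rx), "empty")
  orphan <- make_prescription("z1", "nobody")
  expect_error(summarize_cohort(pats, rbind(rx, orphan)), "unknown patient")
})

test_that("synthetic cohorts reproduce the configured category mixture", {
  sim <- simulate_record_level(sim_config(seed = 2))
  pre <- sim$patients$time_point == "PRE"
  s <- summarize_cohort(sim$patients[pre, ],
                        sim$prescriptions[sim$prescriptions$patient_id %in%
                                            sim$patients$patient_id[pre], ])
  props <- s$counts_by_category / s$total_prescriptions
  target <- c(0.568, 0.143, 0.244, 0.044) / sum(c(0.568, 0.143, 0.244,
                                                  0.044))
  # multinomial Monte-Carlo tolerance at ~1850 draws
  expect_true(all(abs(props - target) < 0.03))
})

test_that("matching filter keeps the closed one-SD box and is idempotent", {
  counts <- data.frame(patient_id = c("x", "y", "z", "w"),
                       total = c(10, 10, 16, 10),
                       standard_peroral = c(6, 6, 6, 6),
                       risky_route = c(2, 2, 2, 2),
                       as_needed = c(1, 1, 1, 1),
                       other = c(1, 13, 1, 1),
                       stringsAsFactors = FALSE)
  stats <- list(mean = c(total = 10, standard_peroral = 6, risky_route = 2,
                         as_needed = 1, other = 1),
                sd = c(total = 3, standard_peroral = 2, risky_route = 1,
                       as_needed = 1, other = 2))
  kept <- matching_filter(stats, counts)
  # x at all means: in; y one count at mean + 6 SD: out;
  # z total exactly at mean + 2 SD: out; w at means: in
  expect_setequal(kept$patient_id, c("x", "w"))
  # boundary: exactly mean + SD is included
  boundary <- counts[1, ]; boundary$total <- 13
  expect_equal(nrow(matching_filter(stats, boundary)), 1)
  # idempotent and a subset
  expect_identical(matching_filter(stats, kept), kept)
  expect_true(all(kept$patient_id %in% counts$patient_id))
  expect_error(matching_filter(stats, kept[, -2]), "lacks")
})
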