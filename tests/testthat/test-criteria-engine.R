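rules <- default_ruleset()

test_that("the default ruleset has 20 stable criteria", {
  expect_length(rules$rules, 20)
  expect_equal(vapply(rules$rules, `[[`, 0L, "id"), 1:20)
})

test_that("a fully documented electronic prescription meets all applicable criteria", {
  out <- assess_prescription(make_prescription(), make_patient(), rules)
  expect_length(out, 20)
  expect_true(all(out %in% c("M", "X")))
  # regular peroral order: #16 (risky route), #17 (body site), #19
  # (as-needed reason) do not apply
  expect_equal(unname(out[c(16, 17, 19)]), c("X", "X", "X"))
  expect_equal(sum(out != "X") + sum(out == "X"), 20)
})

test_that("paper-based orders always fail the computer-aided criterion", {
  out <- assess_prescription(make_prescription(source = "PAPER"),
                             make_patient(), rules)
  expect_equal(unname(out[7]), "N")
})

test_that("applicability gates follow the prescription type", {
  # as-needed without reason: #19 not met; same order regular: #19 NA
  prn <- make_prescription(as_needed = TRUE, reason_documented = FALSE)
  expect_equal(unname(assess_prescription(prn, make_patient(), rules)[19]),
               "N")
  reg <- make_prescription(as_needed = FALSE, reason_documented = FALSE)
  expect_equal(unname(assess_prescription(reg, make_patient(), rules)[19]),
               "X")
  # risky route applies to #16 regardless of schedule
  prn_sc <- make_prescription(route = "subcutaneous", as_needed = TRUE,
                              reason_documented = TRUE,
                              risky_route_stated_unabbreviated = TRUE)
  expect_equal(unname(assess_prescription(prn_sc, make_patient(),
                                          rules)[16]), "M")
  # body site only when required
  bs <- make_prescription(body_site_required = TRUE,
                          body_site_documented = FALSE)
  expect_equal(unname(assess_prescription(bs, make_patient(), rules)[17]),
               "N")
  # tri-state drug history: NA means the criterion does not apply
  out <- assess_prescription(make_prescription(),
                             make_patient(drug_history = NA), rules)
  expect_equal(unname(out[5]), "X")
  # risk flags drive #18
  risky18 <- make_prescription(risk_flags = 2L)
  expect_equal(unname(assess_prescription(risky18, make_patient(),
                                          rules)[18]), "N")
})

test_that("missing required fields raise a named error, never silent NOT_MET", {
  p <- make_prescription(is_valid = NA)
  expect_error(assess_prescription(p, make_patient(), rules),
               "criterion #6")
  p2 <- make_prescription(as_needed = TRUE, reason_documented = NA)
  expect_error(assess_prescription(p2, make_patient(), rules),
               "criterion #19")
})

test_that("derived completeness mode conjugates the content criteria", {
  drules <- default_ruleset(derived_complete = TRUE)
  good <- make_prescription(complete_and_unambiguous = FALSE)  # flag ignored
  expect_equal(unname(assess_prescription(good, make_patient(),
                                          drules)[20]), "M")
  bad <- make_prescription(dosage_form_and_release_documented = FALSE)
  expect_equal(unname(assess_prescription(bad, make_patient(),
                                          drules)[20]), "N")
})

test_that("NA counts + applicable counts always total 20 on generated cohorts", {
  sim <- simulate_record_level(small_config(seed = 9))
  a <- assess_prescriptions(sim$patients, sim$prescriptions, rules)
  n_na <- rowSums(a$outcomes == "X")
  n_app <- rowSums(a$outcomes != "X")
  expect_true(all(n_na + n_app == 20))
  # criterion #19 applicable exactly on as-needed orders, #16 exactly on
  # risky routes, #17 exactly when a body site is required
  expect_equal(a$outcomes[, 19] != "X", sim$prescriptions$as_needed)
  expect_equal(a$outcomes[, 16] != "X",
               is_risky_route(sim$prescriptions$route))
  expect_equal(a$outcomes[, 17] != "X",
               sim$prescriptions$body_site_required)
  # purity: same inputs give identical assessments
  a2 <- assess_prescriptions(sim$patients, sim$prescriptions, rules)
  expect_identical(a$outcomes, a2$outcomes)
})

test_that("not-applicable summary uses mean and sample SD", {
  sim <- simulate_record_level(small_config(seed = 9))
  a <- assess_prescriptions(sim$patients, sim$prescriptions, rules)
  cn <- count_not_applicable(a)
  expect_equal(cn$mean, mean(rowSums(a$outcomes == "X")))
  # record-level defaults leave roughly 3-4 criteria inapplicable
  expect_gt(cn$mean, 2); expect_lt(cn$mean, 5)
  one <- a; one$outcomes <- a$outcomes[1, , drop = FALSE]
  expect_equal(count_not_applicable(one)$mean,
               sum(a$outcomes[1, ] == "X"))
})
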