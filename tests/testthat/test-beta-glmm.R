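test_that("weighted effect coding has the defining zero-mean property", {
  d <- data.frame(time_point = rep(c("PRE", "POST"), 30),
                  category = "STANDARD_PERORAL", n_comedications = 2,
                  ward_id = rep(c(1L, 2L, 3L), each = 20),
                  patient_id = rep(sprintf("p%02d", 1:12), each = 5))
  des <- build_design(d, ref_ward = 3)
  wc <- grep("^ward_", colnames(des$X))
  # equal ward sizes: classical effect coding, reference rows carry -1
  expect_equal(unique(des$X[d$ward_id == 3, wc]), matrix(-1, 1, 2),
               ignore_attr = TRUE)
  expect_equal(colMeans(des$X[, wc]), c(ward_1 = 0, ward_2 = 0))
  # unequal weights 0.75 / 0.25, reference second
  d2 <- d[1:40, ]; d2$ward_id <- rep(c(1L, 2L), c(30, 10))
  des2 <- build_design(d2, ref_ward = 2)
  expect_equal(unique(des2$X[d2$ward_id == 1, "ward_1"]), 1)
  expect_equal(unique(des2$X[d2$ward_id == 2, "ward_1"]), -3)
  expect_equal(mean(des2$X[, "ward_1"]), 0)
  expect_error(build_design(d, ref_ward = 9), "no prescriptions")
})

test_that("quadrature log-likelihood matches dense brute-force integration", {
  fx <- make_beta_fixture()
  gh <- pracma::gaussHermite(15)
  grid_params <- expand.grid(b0 = c(-0.5, 0.3), b1 = c(0, 0.8),
                             sigma = c(0.2, 0.5, 1.2), phi = c(5, 20))
  for (i in seq_len(nrow(grid_params))) {
    g <- grid_params[i, ]
    agq <- rxaudit:::marginal_loglik_core(c(g$b0, g$b1), g$sigma, g$phi,
                                          fx$y, fx$X, fx$pid, gh)
    brute <- brute_loglik(c(g$b0, g$b1), g$sigma, g$phi, fx$y, fx$X,
                          fx$pid)
    expect_lt(abs(agq - brute), 1e-4)
  }
})

test_that("degenerate and structural likelihood identities hold", {
  fx <- make_beta_fixture()
  gh <- pracma::gaussHermite(15)
  # sigma_b = 0 collapses to the fixed-effects beta log-likelihood
  eta <- drop(fx$X %*% c(0.3, 0.8))
  mu <- plogis(eta)
  direct <- sum(dbeta(fx$y, mu * 20, (1 - mu) * 20, log = TRUE))
  expect_equal(rxaudit:::marginal_loglik_core(c(0.3, 0.8), 0, 20, fx$y,
                                              fx$X, fx$pid, gh), direct)
  # duplicating every patient doubles the log-likelihood
  ll1 <- rxaudit:::marginal_loglik_core(c(0.3, 0.8), 0.5, 20, fx$y, fx$X,
                                        fx$pid, gh)
  ll2 <- rxaudit:::marginal_loglik_core(c(0.3, 0.8), 0.5, 20,
                                        rep(fx$y, 2), rbind(fx$X, fx$X),
                                        c(fx$pid, fx$pid + 4), gh)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
  # node refinement stabilises: 15 -> 31 changes less than 5 -> 15
  lls <- vapply(c(5, 15, 31), function(q)
    rxaudit:::marginal_loglik_core(c(0.3, 0.8), 0.5, 20, fx$y, fx$X,
                                   fx$pid, pracma::gaussHermite(q)), 0)
  expect_lt(abs(lls[3] - lls[2]), abs(lls[2] - lls[1]) + 1e-12)
  expect_lt(abs(lls[3] - lls[2]), 1e-5)
})

test_that("sigma_b = 0 fit agrees with an independent beta regression", {
  sim <- simulate_score_level(small_config(seed = 21))
  fit0 <- fit_beta_glmm(sim$data, fix_sigma_b = 0)
  des <- build_design(sim$data)
  dd <- cbind(data.frame(y = sim$data$y), as.data.frame(des$X[, -1]))
  fml <- reformulate(colnames(des$X)[-1], response = "y")
  tmb <- glmmTMB::glmmTMB(fml, family = glmmTMB::beta_family(), data = dd)
  expect_lt(max(abs(glmmTMB::fixef(tmb)$cond - fit0$coefficients)), 1e-4)
  expect_equal(fit0$phi, glmmTMB::sigma(tmb), tolerance = 1e-4)
})

test_that("the mixed fit recovers generating parameters and is deterministic", {
  sim <- simulate_score_level(small_config(seed = 31))
  fit <- fit_beta_glmm(sim$data, nodes = 7)
  expect_true(fit$converged)
  truth <- sim$truth$beta
  # small-sample check: time-point log-OR within 3 SE of the truth
  se <- sqrt(diag(fit$vcov)["time_post"])
  expect_lt(abs(fit$coefficients["time_post"] - truth["time_post"]),
            3 * se)
  expect_gt(fit$sigma_b, 0.2); expect_lt(fit$sigma_b, 2)
  # refit on identical data reproduces estimates bitwise
  fit2 <- fit_beta_glmm(sim$data, nodes = 7)
  expect_identical(fit$coefficients, fit2$coefficients)
  expect_identical(fit$loglik, fit2$loglik)
})

test_that("odds ratios include the derived reference ward with weighted-sum-zero", {
  sim <- simulate_score_level(small_config(seed = 31))
  fit <- fit_beta_glmm(sim$data, nodes = 7)
  ot <- odds_ratios(fit)
  expect_true(all(ot$ci_low <= ot$odds_ratio + 1e-12 &
                    ot$odds_ratio <= ot$ci_high + 1e-12))
  expect_true(all(ot$odds_ratio > 0))
  # all wards reported; their weighted log-OR sum vanishes
  wt <- fit$ward_weights
  iw <- grepl("^ward_", ot$term)
  expect_equal(sum(iw), length(fit$wards))
  lo <- ot$estimate[iw][order(as.integer(sub("ward_", "", ot$term[iw])))]
  expect_equal(sum(wt * lo), 0, tolerance = 1e-10)
})

test_that("adjusted predictions are population-level and reference-invariant", {
  sim <- simulate_score_level(small_config(seed = 31))
  fit <- fit_beta_glmm(sim$data, nodes = 7)
  pred <- predict_adjusted(fit)
  expect_true(all(pred > 0 & pred < 1))
  # refitting with a rotated ward reference leaves predictions unchanged
  fit_alt <- fit_beta_glmm(sim$data, nodes = 7, ref_ward = fit$wards[1])
  expect_equal(predict_adjusted(fit_alt), pred, tolerance = 1e-6)
  # conditional predictions differ once patients have own intercepts
  cond <- predict_adjusted(fit, conditional = TRUE)
  expect_gt(sd(cond - pred), 0)
  # net effects bounded and positive under a strong intervention
  ne <- net_interventional_effect(fit)
  expect_true(all(ne > -100 & ne < 100))
  expect_true(all(ne > 0))
})

test_that("E-value formula matches its closed form and monotonicity", {
  expect_equal(round_half_up(evalue(10.11), 1), 19.7)
  expect_equal(evalue(1), 1)
  expect_equal(evalue(4), 4 + sqrt(12))
  # protective odds ratios are inverted first
  expect_equal(evalue(0.25), evalue(4))
  ors <- seq(1, 20, by = 0.25)
  expect_true(all(diff(evalue(ors)) > 0))
  expect_error(evalue(-2), "positive")
})
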