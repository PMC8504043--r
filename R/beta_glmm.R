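#' Beta-distributed GLMM for prescription fulfilment scores
#'
#' The multivariable model for the (boundary-transformed) prescription
#' fulfilment score y_ij of prescription j in patient i:
#'
#'   logit(mu_ij) = x_ij' beta + b_i,   b_i ~ N(0, sigma_b^2),
#'   y_ij | b_i ~ Beta(mu_ij * phi, (1 - mu_ij) * phi)
#'
#' i.e. a beta regression in mean-precision parameterization with a patient
#' random intercept capturing within-patient correlation of scores. The
#' marginal likelihood integrates the random intercept out per patient; the
#' integral is approximated by adaptive Gauss-Hermite quadrature centered at
#' the per-patient posterior mode and scaled by its curvature (Laplace
#' approximation is the 1-node special case). Estimation maximizes the
#' marginal log-likelihood over (beta, log sigma_b, log phi) with a
#' quasi-Newton optimizer (analytic score via the Fisher identity) from a
#' deterministic start; the covariance of the estimates is the inverse
#' numerical Hessian.
#'
#' @name beta_glmm
NULL

# beta density, mean-precision form
dbeta_mu_phi <- function(y, mu, phi, log = TRUE) {
  eps <- 1e-12
  mu <- pmin(pmax(mu, eps), 1 - eps)
  stats::dbeta(y, mu * phi, (1 - mu) * phi, log = log)
}

# per-patient joint log-density of (observations, b) at intercepts bvec;
# pid is an integer patient index 1..m aligned with y/eta
joint_logdens <- function(bvec, y, eta, pid, sigma, phi) {
  ll <- dbeta_mu_phi(y, stats::plogis(eta + bvec[pid]), phi)
  drop(rowsum(ll, pid, reorder = TRUE)) +
    stats::dnorm(bvec, 0, sigma, log = TRUE)
}

# analytic first/second derivatives of the joint log-density wrt b,
# per patient. For the mean-precision beta density,
#   d l / d mu = phi * (logit(y) - digamma(mu phi) + digamma((1-mu) phi))
# and d mu / d b = mu (1 - mu).
joint_derivs <- function(bvec, y, eta, pid, sigma, phi, ylogit) {
  eps <- 1e-12
  mu <- pmin(pmax(stats::plogis(eta + bvec[pid]), eps), 1 - eps)
  dmu <- mu * (1 - mu)
  Tj <- ylogit - digamma(mu * phi) + digamma((1 - mu) * phi)
  d1 <- phi * dmu * Tj
  d2 <- phi * (dmu * (1 - 2 * mu) * Tj -
                 phi * dmu^2 * (trigamma(mu * phi) +
                                  trigamma((1 - mu) * phi)))
  list(g1 = drop(rowsum(d1, pid, reorder = TRUE)) - bvec / sigma^2,
       g2 = drop(rowsum(d2, pid, reorder = TRUE)) - 1 / sigma^2)
}

# safeguarded Newton ascent to the per-patient posterior modes of b.
# Steps that fail to increase the joint log-density are halved patient-wise,
# which keeps the search stable on sharp or skewed posteriors; returns the
# modes and the curvature-based scale tau used by the adaptive quadrature.
find_modes <- function(b, y, eta, pid, sigma, phi, ylogit) {
  g0 <- joint_logdens(b, y, eta, pid, sigma, phi)
  for (iter in 1:100) {
    d <- joint_derivs(b, y, eta, pid, sigma, phi, ylogit)
    g2 <- d$g2
    g2[!is.finite(g2) | g2 > -1e-8] <- -1 / sigma^2
    delta <- -d$g1 / g2
    cap <- 1 + 3 * sigma
    delta <- pmin(pmax(delta, -cap), cap)
    bt <- b; gt <- g0
    for (half in 1:30) {
      bt <- b + delta
      gt <- joint_logdens(bt, y, eta, pid, sigma, phi)
      worse <- !is.finite(gt) | gt < g0 - 1e-12
      if (!any(worse)) break
      delta[worse] <- delta[worse] / 2
    }
    keep <- is.finite(gt) & gt >= g0 - 1e-12
    b[keep] <- bt[keep]
    g0[keep] <- gt[keep]
    if (max(abs(delta)) < 1e-10) break
  }
  d <- joint_derivs(b, y, eta, pid, sigma, phi, ylogit)
  g2 <- d$g2
  g2[!is.finite(g2) | g2 > -1e-8] <- -1 / sigma^2
  list(b = b, tau = sqrt(-1 / g2), g = g0)
}

# the joint density can be bimodal when a sharp likelihood sits far from a
# tight prior; search from both the supplied start and the per-patient
# likelihood centre and keep the better mode
best_modes <- function(b0, y, eta, pid, sigma, phi, ylogit) {
  m1 <- find_modes(b0, y, eta, pid, sigma, phi, ylogit)
  centre <- drop(rowsum(ylogit - eta, pid, reorder = TRUE)) /
    tabulate(pid, nbins = max(pid))
  m2 <- find_modes(centre, y, eta, pid, sigma, phi, ylogit)
  take2 <- is.finite(m2$g) & (!is.finite(m1$g) | m2$g > m1$g)
  list(b = ifelse(take2, m2$b, m1$b),
       tau = ifelse(take2, m2$tau, m1$tau))
}

# adaptive GH marginal log-likelihood given a prepared design; `warm` is an
# optional environment caching the per-patient modes between calls (a mode
# off by delta changes the log-likelihood only at order delta^2, so warm
# starts do not perturb the optimizer)
marginal_loglik_core <- function(beta, sigma, phi, y, X, pid, gh,
                                 warm = NULL) {
  eta <- drop(X %*% beta)
  if (sigma == 0)
    return(sum(dbeta_mu_phi(y, stats::plogis(eta), phi)))
  m <- max(pid)
  b0 <- if (!is.null(warm) && !is.null(warm$b) && length(warm$b) == m)
    warm$b else numeric(m)
  ylogit <- stats::qlogis(y)
  md <- best_modes(b0, y, eta, pid, sigma, phi, ylogit)
  b <- md$b; tau <- md$tau
  if (!is.null(warm)) warm$b <- b
  # sum_k w_k exp(x_k^2) f(bhat + sqrt(2) tau x_k) * sqrt(2) tau
  lw <- matrix(NA_real_, m, length(gh$x))
  for (k in seq_along(gh$x)) {
    bk <- b + sqrt(2) * tau * gh$x[k]
    lw[, k] <- log(gh$w[k]) + gh$x[k]^2 +
      joint_logdens(bk, y, eta, pid, sigma, phi)
  }
  mx <- apply(lw, 1, max)
  sum(mx + log(rowSums(exp(lw - mx))) + log(sqrt(2) * tau))
}

# log-likelihood and its analytic gradient wrt (beta, log sigma, log phi).
# The gradient uses the Fisher identity: d/dtheta log L_i equals the
# posterior expectation of d/dtheta log f(y_i, b; theta), evaluated with the
# same adaptive quadrature nodes and their normalised posterior weights.
marginal_ll_grad_core <- function(beta, sigma, phi, y, X, pid, gh,
                                  warm = NULL) {
  eta <- drop(X %*% beta)
  eps <- 1e-12
  if (sigma == 0) {
    mu <- pmin(pmax(stats::plogis(eta), eps), 1 - eps)
    dmu <- mu * (1 - mu)
    Tj <- stats::qlogis(y) - digamma(mu * phi) + digamma((1 - mu) * phi)
    ll <- sum(dbeta_mu_phi(y, mu, phi))
    gbeta <- drop(crossprod(X, phi * dmu * Tj))
    dlphi <- digamma(phi) - mu * digamma(mu * phi) -
      (1 - mu) * digamma((1 - mu) * phi) + mu * log(y) +
      (1 - mu) * log1p(-y)
    return(list(ll = ll, gbeta = gbeta, glogsigma = NA_real_,
                glogphi = phi * sum(dlphi)))
  }
  m <- max(pid)
  b0 <- if (!is.null(warm) && !is.null(warm$b) && length(warm$b) == m)
    warm$b else numeric(m)
  ylogit <- stats::qlogis(y)
  md <- best_modes(b0, y, eta, pid, sigma, phi, ylogit)
  b <- md$b; tau <- md$tau
  if (!is.null(warm)) warm$b <- b
  Q <- length(gh$x)
  lw <- matrix(NA_real_, m, Q)
  bk_all <- matrix(NA_real_, m, Q)
  for (k in seq_len(Q)) {
    bk <- b + sqrt(2) * tau * gh$x[k]
    bk_all[, k] <- bk
    lw[, k] <- log(gh$w[k]) + gh$x[k]^2 +
      joint_logdens(bk, y, eta, pid, sigma, phi)
  }
  mx <- apply(lw, 1, max)
  wsum <- rowSums(exp(lw - mx))
  ll <- sum(mx + log(wsum) + log(sqrt(2) * tau))
  pw <- exp(lw - mx) / wsum   # posterior node weights, rows sum to 1
  logy <- log(y); log1my <- log1p(-y)
  wrow <- numeric(length(y))  # accumulates per-row beta-gradient weights
  glphi <- 0; glsig <- 0
  for (k in seq_len(Q)) {
    bvec <- bk_all[, k]
    mu <- pmin(pmax(stats::plogis(eta + bvec[pid]), eps), 1 - eps)
    dmu <- mu * (1 - mu)
    dig1 <- digamma(mu * phi); dig2 <- digamma((1 - mu) * phi)
    Tj <- ylogit - dig1 + dig2
    wrow <- wrow + pw[pid, k] * phi * dmu * Tj
    dlphi <- digamma(phi) - mu * dig1 - (1 - mu) * dig2 + mu * logy +
      (1 - mu) * log1my
    glphi <- glphi + sum(pw[pid, k] * phi * dlphi)
    glsig <- glsig + sum(pw[, k] * (bvec^2 / sigma^2 - 1))
  }
  list(ll = ll, gbeta = drop(crossprod(X, wrow)), glogsigma = glsig,
       glogphi = glphi)
}

#' Marginal log-likelihood of the beta GLMM
#'
#' Evaluates the adaptive Gauss-Hermite approximation to the marginal
#' log-likelihood at given parameter values. With \code{sigma_b = 0} this is
#' exactly the fixed-effects beta-regression log-likelihood.
#'
#' @param beta Fixed-effect coefficient vector, ordered as the columns of
#'   \code{\link{build_design}}'s \code{X}.
#' @param sigma_b Random-intercept SD (>= 0).
#' @param phi Beta precision parameter (> 0).
#' @param data Observation-level model data
#'   (\code{\link{prepare_model_data}}).
#' @param nodes Number of quadrature nodes (1 = Laplace).
#' @param ref_ward Reference ward for the effect coding.
#' @return Scalar log-likelihood.
#' @export
marginal_loglikelihood <- function(beta, sigma_b, phi, data, nodes = 15,
                                   ref_ward = NULL) {
  stopifnot(sigma_b >= 0, phi > 0)
  if (any(data$y <= 0 | data$y >= 1))
    stop("outcome must lie strictly inside (0, 1); apply ",
         "transform_to_open_interval() first")
  des <- build_design(data, ref_ward)
  if (length(beta) != ncol(des$X))
    stop("beta has length ", length(beta), ", design has ", ncol(des$X),
         " columns")
  gh <- pracma::gaussHermite(nodes)
  marginal_loglik_core(beta, sigma_b, phi, data$y, des$X,
                       as.integer(des$patient), gh)
}

#' Fit the beta GLMM by marginal maximum likelihood
#'
#' @param data Observation-level model data with outcome \code{y} strictly
#'   in (0, 1) (see \code{\link{prepare_model_data}}).
#' @param nodes Adaptive Gauss-Hermite nodes (default 15).
#' @param ref_ward Reference ward for weighted effect coding (default: the
#'   highest ward id).
#' @param fix_sigma_b Optionally fix the random-intercept SD (e.g. 0 for a
#'   pure fixed-effects beta regression) instead of estimating it.
#' @param control List: \code{maxit} (default 500) and \code{reltol}
#'   (default 1e-10) for the quasi-Newton (PORT) optimizer.
#' @return A \code{beta_glmm_fit}: \code{coefficients}, \code{sigma_b},
#'   \code{phi}, \code{vcov} (all estimated parameters, log scale for
#'   sigma_b/phi), \code{loglik}, \code{converged}, design metadata and the
#'   model data.
#' @export
fit_beta_glmm <- function(data, nodes = 15, ref_ward = NULL,
                          fix_sigma_b = NULL,
                          control = list(maxit = 500, reltol = 1e-12)) {
  if (any(data$y <= 0 | data$y >= 1))
    stop("outcome must lie strictly inside (0, 1)")
  if (length(unique(data$patient_id)) < 2) stop("need at least 2 patients")
  des <- build_design(data, ref_ward)
  X <- des$X
  if (qr(X)$rank < ncol(X)) stop("fixed-effects design is rank deficient")
  y <- data$y
  pid <- as.integer(des$patient)
  gh <- pracma::gaussHermite(nodes)
  p <- ncol(X)

  # deterministic start: logit-scale least squares, sigma_b 0.1, phi 10
  beta0 <- qr.coef(qr(X), stats::qlogis(y))
  est_sigma <- is.null(fix_sigma_b)
  theta0 <- c(beta0, if (est_sigma) log(0.1), log(10))
  nm <- c(colnames(X), if (est_sigma) "log_sigma_b", "log_phi")
  names(theta0) <- nm

  warm <- new.env(parent = emptyenv())
  negll <- function(theta) {
    beta <- theta[1:p]
    sigma <- if (est_sigma) exp(theta[p + 1]) else fix_sigma_b
    phi <- exp(theta[length(theta)])
    ll <- tryCatch(marginal_loglik_core(beta, sigma, phi, y, X, pid, gh,
                                        warm),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  negll_grad <- function(theta) {
    beta <- theta[1:p]
    sigma <- if (est_sigma) exp(theta[p + 1]) else fix_sigma_b
    phi <- exp(theta[length(theta)])
    g <- tryCatch(marginal_ll_grad_core(beta, sigma, phi, y, X, pid, gh,
                                        warm),
                  error = function(e) NULL)
    if (is.null(g) || !all(is.finite(unlist(g[c("gbeta", "glogphi")]))))
      return(rep(0, length(theta)))
    -c(g$gbeta, if (est_sigma) g$glogsigma, g$glogphi)
  }
  opt <- stats::nlminb(theta0, negll, gradient = negll_grad,
                       control = list(iter.max = control$maxit %||% 500,
                                      eval.max = 2 * (control$maxit %||%
                                                        500),
                                      rel.tol = control$reltol %||% 1e-10))
  opt$par <- stats::setNames(opt$par, nm)
  hess <- stats::optimHess(opt$par, negll, gr = negll_grad)
  vcov <- tryCatch(solve(hess), error = function(e) {
    warning("singular Hessian; covariance unavailable")
    matrix(NA_real_, length(opt$par), length(opt$par))
  })
  dimnames(vcov) <- list(nm, nm)
  # PORT sometimes reports "singular convergence" at a genuine optimum;
  # accept when the score has vanished relative to the log-likelihood scale
  gfinal <- max(abs(negll_grad(opt$par)))
  converged <- opt$convergence == 0 ||
    (is.finite(gfinal) && gfinal < 1e-4 * max(1, abs(opt$objective)))
  if (!converged) warning("optimizer did not converge (code ",
                          opt$convergence, ": ", opt$message, ")")
  beta <- opt$par[1:p]
  fit <- list(
    coefficients = beta,
    sigma_b = if (est_sigma) unname(exp(opt$par[p + 1])) else fix_sigma_b,
    phi = unname(exp(opt$par[length(opt$par)])),
    sigma_b_fixed = !est_sigma,
    vcov = vcov,
    loglik = -opt$objective,
    converged = converged,
    n_obs = length(y),
    n_patients = max(pid),
    nodes = nodes,
    ward_weights = des$ward_weights,
    ref_ward = des$ref_ward,
    wards = des$wards,
    data = data
  )
  class(fit) <- "beta_glmm_fit"
  fit
}

#' @export
print.beta_glmm_fit <- function(x, ...) {
  cat(sprintf(
    "Beta GLMM (logit link, patient random intercept), %d obs / %d patients\n",
    x$n_obs, x$n_patients))
  cat(sprintf("  logLik %.2f | sigma_b %.3f | phi %.2f | %s\n", x$loglik,
              x$sigma_b, x$phi,
              if (x$converged) "converged" else "NOT converged"))
  print(odds_ratios(x), digits = 3)
  invisible(x)
}

#' Random-intercept SD with Wald CI on the log scale
#'
#' @param fit A \code{beta_glmm_fit}.
#' @param conf_level Confidence level.
#' @return Named vector: estimate, lower, upper.
#' @export
sigma_b_ci <- function(fit, conf_level = 0.95) {
  if (fit$sigma_b_fixed) return(c(estimate = fit$sigma_b, lower = NA,
                                  upper = NA))
  se <- sqrt(unname(fit$vcov["log_sigma_b", "log_sigma_b"]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  c(estimate = unname(fit$sigma_b),
    lower = unname(fit$sigma_b) * exp(-z * se),
    upper = unname(fit$sigma_b) * exp(z * se))
}

#' Odds ratios with Wald confidence intervals
#'
#' Exponentiates the fixed-effect coefficients. The reference ward, omitted
#' from the design, is reported too: its coefficient is the negative
#' weighted sum of the other ward coefficients (the defining constraint of
#' weighted effect coding) with a delta-method standard error, the ward
#' weights treated as fixed.
#'
#' @param fit A \code{beta_glmm_fit}.
#' @param conf_level Confidence level for the Wald intervals.
#' @return Data frame: \code{term}, \code{estimate} (log-odds), \code{se},
#'   \code{odds_ratio}, \code{ci_low}, \code{ci_high}, \code{p}.
#' @export
odds_ratios <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "beta_glmm_fit"))
  if (anyNA(fit$vcov)) stop("covariance matrix unavailable")
  beta <- fit$coefficients
  terms <- names(beta)
  se <- sqrt(diag(fit$vcov)[terms])
  # derived reference-ward effect
  ward_terms <- grep("^ward_", terms, value = TRUE)
  if (length(ward_terms) > 0) {
    w <- fit$ward_weights
    wr <- w[[as.character(fit$ref_ward)]]
    a <- -w[sub("^ward_", "", ward_terms)] / wr
    b_ref <- sum(a * beta[ward_terms])
    se_ref <- sqrt(drop(t(a) %*% fit$vcov[ward_terms, ward_terms] %*% a))
    beta <- c(beta, b_ref)
    se <- c(se, se_ref)
    terms <- c(terms, paste0("ward_", fit$ref_ward))
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(
    term = terms, estimate = unname(beta), se = unname(se),
    odds_ratio = exp(unname(beta)),
    ci_low = exp(unname(beta) - z * unname(se)),
    ci_high = exp(unname(beta) + z * unname(se)),
    p = 2 * stats::pnorm(-abs(unname(beta) / unname(se))),
    stringsAsFactors = FALSE, row.names = NULL)
  # wards in id order at the end
  iw <- grepl("^ward_", out$term)
  rbind(out[!iw, ], out[iw, ][order(as.integer(sub("^ward_", "",
                                                   out$term[iw]))), ])
}

# design matrix for new data using the stored coding (training weights)
design_for <- function(fit, data) {
  if (!all(data$ward_id %in% fit$wards))
    stop("new data contains ward(s) absent from the fitted design")
  des <- build_design(data, fit$ref_ward)
  # replace recomputed ward columns with training-weight coding
  n <- nrow(data)
  X <- des$X[, !grepl("^ward_", colnames(des$X)), drop = FALSE]
  w <- fit$ward_weights
  wr <- w[[as.character(fit$ref_ward)]]
  for (k in setdiff(fit$wards, fit$ref_ward)) {
    col <- numeric(n)
    col[data$ward_id == k] <- 1
    col[data$ward_id == fit$ref_ward] <- -w[[as.character(k)]] / wr
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- paste0("ward_", k)
  }
  X[, names(fit$coefficients), drop = FALSE]
}

#' Covariate-adjusted predicted fulfilment scores
#'
#' Population-level predictions logistic(x' beta) with the random intercept
#' at zero; set \code{conditional = TRUE} for empirical-Bayes conditional
#' predictions using each patient's posterior modal intercept.
#'
#' @param fit A \code{beta_glmm_fit}.
#' @param data Observation-level data (default: the training data).
#' @param conditional Use empirical-Bayes patient intercepts?
#' @return Numeric vector of predicted scores in (0, 1).
#' @export
predict_adjusted <- function(fit, data = fit$data, conditional = FALSE) {
  X <- design_for(fit, data)
  eta <- drop(X %*% fit$coefficients)
  if (conditional) {
    pid <- as.integer(factor(data$patient_id))
    b <- posterior_modes(fit, data, eta, pid)
    eta <- eta + b[pid]
  }
  stats::plogis(eta)
}

posterior_modes <- function(fit, data, eta, pid) {
  find_modes(numeric(max(pid)), data$y, eta, pid, fit$sigma_b, fit$phi,
             stats::qlogis(data$y))$b
}

#' Net interventional effect per prescription category
#'
#' Difference in mean covariate-adjusted predicted scores, post minus pre,
#' within each prescription category, in percentage points. Categories
#' missing a time point are omitted with a warning.
#'
#' @param fit A \code{beta_glmm_fit}.
#' @param data Observation-level data (default: training data).
#' @return Named numeric vector of differences in percentage points.
#' @export
net_interventional_effect <- function(fit, data = fit$data) {
  pred <- predict_adjusted(fit, data)
  out <- c()
  for (cc in intersect(prescription_categories(), unique(data$category))) {
    sel <- data$category == cc
    pre <- pred[sel & data$time_point == "PRE"]
    post <- pred[sel & data$time_point == "POST"]
    if (length(pre) == 0 || length(post) == 0) {
      warning("category ", cc, " missing a time point; omitted")
      next
    }
    out[cc] <- 100 * (mean(post) - mean(pre))
  }
  out
}

#' E-value for unmeasured confounding
#'
#' Minimum strength of association, on the risk-ratio scale, that an
#' unmeasured confounder would need with both intervention and outcome to
#' explain away an observed effect: E = OR + sqrt(OR * (OR - 1)) for
#' OR >= 1; for protective effects the formula is applied to 1 / OR.
#'
#' @param odds_ratio Positive effect estimate(s).
#' @return E-value(s), >= 1.
#' @examples
#' evalue(10.11)  # 19.7
#' @export
evalue <- function(odds_ratio) {
  if (any(!is.finite(odds_ratio)) || any(odds_ratio <= 0))
    stop("odds_ratio must be positive")
  or <- ifelse(odds_ratio < 1, 1 / odds_ratio, odds_ratio)
  or + sqrt(or * (or - 1))
}

#' Write model results to JSON
#'
#' Coefficients as odds ratios with CIs and p-values, the random-intercept
#' SD with its CI, precision parameter, log-likelihood and convergence.
#'
#' @param fit A \code{beta_glmm_fit}.
#' @param path Output path.
#' @export
write_fit_results <- function(fit, path) {
  res <- list(
    odds_ratios = odds_ratios(fit),
    random_intercept_sd = as.list(sigma_b_ci(fit)),
    precision = fit$phi,
    loglik = fit$loglik,
    converged = fit$converged,
    n_obs = fit$n_obs,
    n_patients = fit$n_patients,
    quadrature_nodes = fit$nodes,
    ref_ward = fit$ref_ward
  )
  jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
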