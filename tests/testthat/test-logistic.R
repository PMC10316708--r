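test_that("IRLS matches the reference fitter on a generic design", {
  set.seed(21)
  n <- 500
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.4), x3 = runif(n))
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * X[, 1] - 1.2 * X[, 2]))
  fit <- fit_logistic(y, X)
  # tight epsilon: glm's default stops earlier, leaving its Wald SEs
  # computed from the penultimate iterate's weights
  ref <- glm(y ~ X, family = binomial(),
             control = glm.control(epsilon = 1e-12, maxit = 100))
  expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(fit$se),
               unname(summary(ref)$coefficients[, "Std. Error"]),
               tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(fit$aic, AIC(ref), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("the MLE satisfies the score equations and calibration", {
  set.seed(22)
  n <- 800
  X <- cbind(a = rbinom(n, 1, 0.3), b = rnorm(n))
  y <- rbinom(n, 1, plogis(-1 + X[, 1] + 0.5 * X[, 2]))
  fit <- fit_logistic(y, X)
  Xd <- cbind(1, X)
  expect_lt(max(abs(crossprod(Xd, y - fit$fitted))), 1e-8)
  # fitted probabilities average to the observed prevalence
  expect_equal(mean(fit$fitted), mean(y), tolerance = 1e-10)
  # AIC identity with k coefficients including the intercept
  expect_equal(fit$aic, 2 * 3 - 2 * fit$loglik)
  # OR table is exp(beta) with Wald limits bracketing it
  expect_equal(fit$or_ci$or, unname(exp(fit$beta)))
  expect_true(all(fit$or_ci$low <= fit$or_ci$or &
                    fit$or_ci$or <= fit$or_ci$high))
})

test_that("degenerate designs raise explicit errors", {
  set.seed(23)
  n <- 200
  x <- rnorm(n)
  y_sep <- as.numeric(x > 0)
  expect_error(fit_logistic(y_sep, cbind(x = x)), "separation")
  y <- rbinom(n, 1, 0.5)
  expect_error(fit_logistic(y, cbind(c1 = rep(1, n), x = x)), "c1")
  expect_error(fit_logistic(y, cbind(x = x, x2 = 2 * x)), "collinear")
  expect_error(fit_logistic(rep(1, n), cbind(x = x)), "both classes")
  expect_error(fit_logistic(y[1:3], cbind(x = x[1:3], z = x[1:3]^2)),
               "more observations")
})

test_that("forward stepwise from nothing recovers the closed-form null", {
  set.seed(24)
  y <- rbinom(300, 1, 0.3)
  X <- matrix(rnorm(300 * 3), ncol = 3,
              dimnames = list(NULL, c("n1", "n2", "n3")))
  m <- stepwise_aic(y, X, direction = "forward")
  if (length(m$selected) == 0) {
    expect_equal(unname(m$beta[1]), qlogis(mean(y)))
    expect_equal(m$aic, 2 - 2 * m$loglik)
  }
  # forced-in dominant predictor is never dropped
  signal <- rbinom(300, 1, 0.5)
  y2 <- rbinom(300, 1, plogis(-2 + 3 * signal))
  X2 <- cbind(sig = signal, X)
  m2 <- stepwise_aic(y2, X2, forced = "sig")
  expect_true("sig" %in% m2$selected)
})

test_that("stepwise recovers a planted four-question model", {
  # only the reduced items separate the conditions; the other four
  # questions share identical rates across groups
  pd <- c(0.75, 0.65, 0.57, 0.49, 0.64, 0.37, 0.41, 0.33)
  pt <- pd; pt[c(1, 2, 5, 8)] <- c(0.37, 0.19, 0.19, 0.09)
  # uniform prevalence keeps the condition-given-risks model exactly
  # logistic, so the population ORs are the marginal-rate odds ratios
  pars <- cohort_params(n_per_age = c(34000, 33000, 33000),
                        prevalence_per_age = rep(0.26, 3),
                        p_risk_dld = pd, p_risk_tld = pt, rho = 0,
                        seed = 11)
  coded <- code_records(generate_cohort(pars))
  m <- stepwise_aic(coded$condition, coded[, paste0("risk", 1:8)])
  # all planted questions are selected; AIC may additionally admit a
  # noise term (each enters with probability ~P(chisq_1 > 2) ~ 0.157
  # regardless of n), but any such term is identifiable by an odds
  # ratio indistinguishable from 1
  planted <- paste0("risk", c(1, 2, 5, 8))
  expect_true(all(planted %in% m$selected))
  extras <- setdiff(m$selected, planted)
  expect_lte(length(extras), 2)
  for (tm in extras) {
    expect_lt(abs(log(m$or_ci$or[m$or_ci$term == tm])), log(1.15))
  }
  # fitted ORs of planted terms within 3 SEs of the population ORs
  # implied by the generator's marginal rates
  pop_or <- (pd / (1 - pd)) / (pt / (1 - pt))
  for (q in c(1, 2, 5, 8)) {
    i <- which(m$or_ci$term == paste0("risk", q))
    expect_lt(abs(log(m$or_ci$or[i]) - log(pop_or[q])),
              3 * unname(m$se[paste0("risk", q)]))
  }
})

test_that("with no signal AIC keeps few questions, at the chi-square rate", {
  # each independent noise term survives stepwise AIC when its deviance
  # contribution exceeds 2, i.e. with probability P(chisq_1 > 2) ~ 0.157
  p_null <- c(0.37, 0.19, 0.36, 0.20, 0.19, 0.30, 0.16, 0.09)
  n_sel <- integer(20)
  for (s in seq_len(20)) {
    pars <- cohort_params(n_per_age = c(1700, 1700, 1600),
                          p_risk_dld = p_null, p_risk_tld = p_null,
                          rho = 0, seed = 500 + s)
    coded <- code_records(generate_cohort(pars))
    m <- stepwise_aic(coded$condition, coded[, paste0("risk", 1:8)])
    n_sel[s] <- length(m$selected)
  }
  retention <- mean(n_sel) / 8
  expect_lt(abs(retention - pchisq(2, 1, lower.tail = FALSE)),
            3 * sqrt(0.157 * 0.843 / (20 * 8)))
  expect_true(any(n_sel == 0))
  expect_true(all(n_sel <= 5))
})

test_that("stepwise is deterministic and reports its move sequence", {
  set.seed(26)
  x <- matrix(rbinom(2000 * 4, 1, 0.5), ncol = 4,
              dimnames = list(NULL, paste0("q", 1:4)))
  y <- rbinom(2000, 1, plogis(-1 + x[, 1] + 0.7 * x[, 3]))
  m1 <- stepwise_aic(y, x)
  m2 <- stepwise_aic(y, x)
  expect_identical(m1$selected, m2$selected)
  expect_identical(m1$steps, m2$steps)
  expect_true(all(diff(m1$steps$aic) < 0))  # every move lowered AIC
})
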