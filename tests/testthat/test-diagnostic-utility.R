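test_that("SSLRs reproduce the published score strata", {
  s <- sslr(overall_strata())
  expect_equal(round(s$sslr, 3), c(8.792, 4.014, 1.055, 0.695, 0.270))
  expect_equal(s$band, c("moderate", "small", "none", "none", "small"))
  s5 <- sslr(subgroup_strata())
  expect_equal(round(s5$sslr, 3), c(4.367, 1.108, 0.527, 0.124))
  # equal stratum proportions give an uninformative ratio
  eq <- sslr(stratum_table(c("1", "0"), c(10, 30), c(20, 60)))
  expect_equal(eq$sslr, c(1, 1))
})

test_that("SSLR intervals use the log-method standard error", {
  tab <- overall_strata()
  s <- sslr(tab)
  se <- sqrt(1 / s$dld - 1 / tab$d_total + 1 / s$tld - 1 / tab$t_total)
  expect_equal(s$ci_low, exp(log(s$sslr) - qnorm(0.975) * se))
  expect_equal(s$ci_high, exp(log(s$sslr) + qnorm(0.975) * se))
  expect_true(all(s$ci_low <= s$sslr & s$sslr <= s$ci_high))
})

test_that("SSLRs conserve unit mass against each group's distribution", {
  set.seed(41)
  for (i in 1:1000) {
    tab <- random_stratum_table()
    s <- sslr(tab)
    expect_equal(sum(s$sslr * tab$t_counts / tab$t_total), 1,
                 tolerance = 1e-12)
    expect_equal(sum((1 / s$sslr) * tab$d_counts / tab$d_total), 1,
                 tolerance = 1e-12)
  }
})

test_that("zero cells yield sentinels unless the correction is requested", {
  tab <- stratum_table(c("2", "1", "0"), c(5, 0, 10), c(0, 8, 20))
  s <- sslr(tab)
  expect_identical(s$sslr[1], Inf)
  expect_identical(s$sslr[2], 0)
  sc <- sslr(tab, correction = TRUE)
  expect_true(all(is.finite(sc$sslr) & sc$sslr > 0))
  expect_equal(sc$corrected, c(TRUE, TRUE, FALSE))
  expect_error(sslr(stratum_table(c("1", "0"), c(0, 5), c(0, 5))),
               "both groups")
})

test_that("sparse strata merge inward with exact count conservation", {
  # the published subgroup situation: a top score stratum of 2 DLD / 3 TLD
  raw <- stratum_table(c("4", "3", "2", "1", "0"),
                       d_counts = c(2, 10, 5, 3, 1),
                       t_counts = c(3, 11, 23, 29, 41))
  merged <- collapse_sparse(raw, min_count = 3)
  expect_equal(merged$strata[1], "3-4")
  expect_equal(merged$d_counts[1], 12)
  expect_equal(merged$t_counts[1], 14)
  expect_equal(merged$d_total, raw$d_total)
  expect_equal(merged$t_total, raw$t_total)
  # a table already satisfying the rule is returned unchanged
  tab <- overall_strata()
  expect_equal(collapse_sparse(tab, min_count = 5), tab)
  # impossible demands fail loudly
  expect_error(collapse_sparse(raw, min_count = 1000), "cannot reach")
  # conservation invariant survives merging
  set.seed(42)
  for (i in 1:50) {
    tab <- random_stratum_table()
    m <- collapse_sparse(tab, min_count = 15)
    expect_equal(sum(m$d_counts), tab$d_total)
    expect_equal(sum(m$t_counts), tab$t_total)
    s <- sslr(m)
    expect_equal(sum(s$sslr * m$t_counts / m$t_total), 1, tolerance = 1e-12)
  }
})

test_that("probability updating follows Bayes on the odds scale", {
  u <- update_probability(0.12, 8.792)
  expect_equal(round(u$pretest_odds, 3), 0.136)
  expect_equal(round(u$posttest_odds, 3), 1.199)
  expect_equal(round(u$posttest_prob, 2), 0.55)
  # chaining a concern score of 3-4 with the preschool likelihood ratio
  u2 <- update_probability(0.12, c(4.367, 1.829))
  expect_equal(round(u2$posttest_prob, 2), 0.52)
  # an uninformative ratio leaves the probability untouched
  expect_equal(update_probability(0.3, 1)$posttest_prob, 0.3)
  expect_error(update_probability(0, 2), "inside")
  expect_error(update_probability(0.5, c(2, -1)), "positive")
})

test_that("chained updates equal the single product update, in any order", {
  set.seed(43)
  for (i in 1:100) {
    pre <- runif(1, 0.01, 0.99)
    lrs <- exp(rnorm(3, 0, 1))
    chained <- update_probability(pre, lrs)
    prod1 <- update_probability(pre, prod(lrs))
    shuffled <- update_probability(pre, sample(lrs))
    expect_equal(chained$posttest_prob, prod1$posttest_prob)
    expect_equal(chained$posttest_prob, shuffled$posttest_prob)
    # odds-probability inverses hold to machine precision
    expect_equal(chained$pretest_odds, pre / (1 - pre), tolerance = 1e-12)
    expect_equal(chained$posttest_prob /
                   (1 - chained$posttest_prob),
                 chained$posttest_odds, tolerance = 1e-12)
  }
})

test_that("the posttest probability is monotone in the LR and the pretest", {
  lrs <- c(0.2, 0.5, 1, 2, 5, 10)
  post <- sapply(lrs, function(l) update_probability(0.12, l)$posttest_prob)
  expect_true(all(diff(post) > 0))
  pres <- seq(0.05, 0.9, by = 0.05)
  post2 <- sapply(pres, function(p) update_probability(p, 3)$posttest_prob)
  expect_true(all(diff(post2) > 0))
})

test_that("LR interpretation bands are symmetric under inversion", {
  expect_equal(interpret_lr(8.792), "moderate")
  expect_equal(interpret_lr(0.27), "small")
  expect_equal(interpret_lr(1), "none")
  expect_equal(interpret_lr(c(10, 0.1, 5, 0.2, 2, 0.5, 1.9)),
               c("large", "large", "moderate", "moderate", "small",
                 "small", "none"))
  set.seed(44)
  lr <- exp(rnorm(100, 0, 2))
  expect_equal(interpret_lr(lr), interpret_lr(1 / lr))
  expect_error(interpret_lr(0), "positive")
})

test_that("binary likelihood ratios satisfy the mixture identity", {
  # identical level distributions: both ratios 1
  ind <- rep(c(0, 1), 50)
  lab <- rep(c("DLD", "TLD"), each = 50)
  b <- binary_lr(ind, lab)
  expect_equal(b$lr, c(1, 1))
  set.seed(45)
  ind2 <- rbinom(400, 1, 0.4)
  lab2 <- ifelse(rbinom(400, 1, plogis(ind2 - 0.5)) == 1, "DLD", "TLD")
  b2 <- binary_lr(ind2, lab2)
  expect_equal(sum(b2$lr * b2$p_tld), 1, tolerance = 1e-12)
  # polarity swap exchanges the two ratios
  b3 <- binary_lr(1 - ind2, lab2)
  expect_equal(b3$lr, rev(b2$lr))
  expect_error(binary_lr(rep(1, 10), rep(c("DLD", "TLD"), 5)),
               "two observed levels")
})

test_that("a planted below-median rate reproduces the preschool LR", {
  # configured below-median probabilities imply LR = 0.60/0.328 = 1.829
  set.seed(46)
  n_d <- 20000; n_t <- 80000
  below <- c(rbinom(n_d, 1, 0.60), rbinom(n_t, 1, 0.328))
  lab <- rep(c("DLD", "TLD"), c(n_d, n_t))
  b <- binary_lr(below, lab)
  est <- b$lr[b$level == "1"]
  se_log <- sqrt((1 - 0.60) / (0.60 * n_d) + (1 - 0.328) / (0.328 * n_t))
  expect_lt(abs(log(est) - log(0.60 / 0.328)), 3 * se_log)
})

test_that("the utility report chains counts, SSLRs and updates", {
  rep4 <- utility_report(overall_strata(), pretest = 0.12)
  expect_equal(round(rep4$posttest_prob, 2), c(0.55, 0.35, 0.13, 0.09, 0.04))
  expect_equal(round(rep4$pretest_odds[1], 3), 0.136)
  rep5 <- utility_report(subgroup_strata(), pretest = 0.12, extra_lr = 1.829)
  expect_equal(round(rep5$posttest2_prob, 2), c(0.52, 0.22, 0.12, 0.03))
  expect_equal(round(rep5$posttest_prob, 2), c(0.37, 0.13, 0.07, 0.02))
})

test_that("stratum tables validate their invariants", {
  expect_error(stratum_table(c("1", "1"), c(1, 2), c(3, 4)), "unique")
  expect_error(stratum_table(c("1", "0"), c(1, -2), c(3, 4)), "nonnegative")
  expect_error(stratum_table(c("1", "0"), c(0, 0), c(3, 4)), "positive total")
  expect_error(stratum_table(character(), numeric(), numeric()),
               "positive length")
  tab <- stratum_table_from_scores(c(4, 4, 0, NA, 2),
                                   c("DLD", "TLD", "TLD", "DLD", NA))
  expect_equal(tab$d_total, 1)
  expect_equal(tab$t_total, 2)
  expect_equal(attr(tab, "n_excluded"), 2)
  expect_error(expand_strata(subgroup_strata()), "merged")
})

test_that("end-to-end SSLR recovery matches the pattern-enumeration oracle", {
  # generate from the published marginals with independent questions,
  # score, stratify, and compare with the closed-form SSLR from the 2^4
  # enumeration oracle: every stratum CI must cover the oracle value
  p_dld4 <- c(0.75, 0.65, 0.64, 0.33)   # items 1, 2, 5, 8
  p_tld4 <- c(0.37, 0.19, 0.19, 0.09)
  pars <- cohort_params(n_per_age = c(34000, 33000, 33000), rho = 0,
                        seed = 47)
  coded <- code_records(generate_cohort(pars))
  tab <- stratum_table_from_scores(coded$score4, coded$condition)
  s <- sslr(tab)
  oracle <- rev(sslr_oracle(p_dld4, p_tld4))   # strata ordered 4..0
  # 3-SE band on the log scale: five strata are checked simultaneously,
  # so per-stratum 95% intervals would fail a quarter of honest runs
  se_log <- sqrt(1 / s$dld - 1 / tab$d_total + 1 / s$tld - 1 / tab$t_total)
  for (i in seq_len(5)) {
    expect_lt(abs(log(s$sslr[i]) - log(oracle[i])), 3 * se_log[i],
              label = paste("stratum", s$stratum[i], "log deviation"))
  }
})
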