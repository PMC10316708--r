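# Shared fixtures and independent oracles for the test suite.

# Published condition-by-score count tables used throughout: the overall
# four-item concern-score distribution (185 DLD / 495 TLD) and the
# 128-child subgroup with the top strata already merged (21 DLD / 107 TLD).
overall_strata <- function() {
  stratum_table(c("4", "3", "2", "1", "0"),
                d_counts = c(46, 57, 28, 27, 27),
                t_counts = c(14, 38, 71, 104, 268))
}

subgroup_strata <- function() {
  stratum_table(c("3-4", "2", "1", "0"),
                d_counts = c(12, 5, 3, 1),
                t_counts = c(14, 23, 29, 41))
}

# Independent brute-force oracle: score distribution over the four
# score-4 items with independent Bernoulli risks, by enumerating all
# 2^4 response patterns. Returns P(score = 0..4).
score4_pattern_oracle <- function(p_risk) {
  stopifnot(length(p_risk) == 4)
  patterns <- as.matrix(expand.grid(rep(list(0:1), 4)))
  probs <- apply(patterns, 1, function(pat) {
    prod(ifelse(pat == 1, p_risk, 1 - p_risk))
  })
  tapply(probs, rowSums(patterns), sum)
}

# Closed-form SSLR per score from per-condition item risk rates.
sslr_oracle <- function(p_dld4, p_tld4) {
  score4_pattern_oracle(p_dld4) / score4_pattern_oracle(p_tld4)
}

# Random valid 2x2 table with all margins positive.
random_two_by_two <- function() {
  repeat {
    cells <- rpois(4, lambda = sample(3:40, 1)) + 1L
    t <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    if (all(rowSums(t) > 0) && all(colSums(t) > 0)) return(t)
  }
}

# Random stratum table with no empty strata.
random_stratum_table <- function(n_strata = sample(3:6, 1)) {
  stratum_table(as.character(seq_len(n_strata)),
                d_counts = rpois(n_strata, 20) + 1L,
                t_counts = rpois(n_strata, 30) + 1L)
}

# Small deterministic cohort data.frame built in code.
tiny_cohort <- function(n = 40, seed = 42) {
  generate_cohort(cohort_params(
    n_per_age = c(ceiling(n / 3), ceiling(n / 3), n - 2 * ceiling(n / 3)),
    seed = seed))
}
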