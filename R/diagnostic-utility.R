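#' Condition-by-score stratum table
#'
#' Holds DLD and TLD counts for each ordinal score stratum, the input for
#' stratum-specific likelihood ratios.
#'
#' @param strata Ordered stratum labels (e.g. `c("4","3","2","1","0")` or a
#'   merged label such as `"3-4"`).
#' @param d_counts,t_counts DLD and TLD counts per stratum.
#' @return An object of class `stratum_table`.
#' @export
stratum_table <- function(strata, d_counts, t_counts) {
  strata <- as.character(strata)
  if (length(strata) == 0L ||
      length(d_counts) != length(strata) ||
      length(t_counts) != length(strata)) {
    stop("strata, d_counts and t_counts must have equal positive length",
         call. = FALSE)
  }
  if (anyDuplicated(strata)) stop("stratum labels must be unique",
                                  call. = FALSE)
  if (any(d_counts < 0) || any(t_counts < 0)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  if (sum(d_counts) == 0 || sum(t_counts) == 0) {
    stop("both condition groups must have a positive total", call. = FALSE)
  }
  out <- list(strata = strata,
              d_counts = as.numeric(d_counts),
              t_counts = as.numeric(t_counts),
              d_total = sum(d_counts), t_total = sum(t_counts))
  class(out) <- "stratum_table"
  out
}

#' @export
print.stratum_table <- function(x, ...) {
  df <- data.frame(stratum = x$strata, DLD = x$d_counts, TLD = x$t_counts)
  print(df, row.names = FALSE)
  cat("totals: DLD", x$d_total, "| TLD", x$t_total, "\n")
  invisible(x)
}

#' Read a stratum table from delimited text
#'
#' Expects a header `stratum,dld,tld` (comma or tab separated).
#'
#' @param path Path to the file.
#' @return A [stratum_table()].
#' @export
read_stratum_table <- function(path) {
  if (!file.exists(path)) stop("cannot read: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "numeric"))
  names(df) <- tolower(names(df))
  if (!all(c("stratum", "dld", "tld") %in% names(df))) {
    stop("stratum file needs columns stratum, dld, tld", call. = FALSE)
  }
  stratum_table(df$stratum, df$dld, df$tld)
}

#' Stratum table from per-child scores
#'
#' Tabulates a concern score by condition, ordered from the highest score
#' down (the presentation order of SSLR tables). Children with a missing
#' score or condition are excluded; their number is attached as an
#' attribute.
#'
#' @param score Integer concern score per child (`NA` excluded).
#' @param condition "DLD"/"TLD" per child.
#' @param levels Score levels to tabulate (default `4:0`); strata absent
#'   from the data keep a zero count.
#' @return A [stratum_table()] with attribute `n_excluded`.
#' @export
stratum_table_from_scores <- function(score, condition, levels = 4:0) {
  keep <- !is.na(score) & !is.na(condition)
  score <- factor(score[keep], levels = levels)
  condition <- condition[keep]
  out <- stratum_table(as.character(levels),
                       d_counts = as.vector(table(score[condition == "DLD"])),
                       t_counts = as.vector(table(score[condition == "TLD"])))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Interpretation band for a likelihood ratio
#'
#' An LR of 10 or more (or 0.1 or less) indicates a large change between
#' pretest and posttest probability; 5-10 (or 0.1-0.2) moderate; 2-5 (or
#' 0.2-0.5) small; between 0.5 and 2 essentially none. An LR and its
#' reciprocal always fall in the same band.
#'
#' @param lr Positive likelihood ratio(s).
#' @return Character vector in `{"large","moderate","small","none"}`.
#' @export
interpret_lr <- function(lr) {
  if (!is.numeric(lr) || anyNA(lr) || any(lr <= 0)) {
    stop("likelihood ratios must be positive", call. = FALSE)
  }
  m <- pmax(lr, 1 / lr)  # fold change; band is symmetric in lr vs 1/lr
  ifelse(m >= 10, "large",
         ifelse(m >= 5, "moderate",
                ifelse(m >= 2, "small", "none")))
}

#' Stratum-specific likelihood ratios
#'
#' For each stratum s, `SSLR_s = (d_s/d_total) / (t_s/t_total)`: the ratio
#' of the probability of landing in that score stratum among children with
#' the condition to the same probability among children without it. The
#' 95% CI uses the log method with
#' `SE = sqrt(1/d_s - 1/d_total + 1/t_s - 1/t_total)` (an extension; the
#' source tables print no SSLR CIs). A zero cell yields an infinite or
#' zero SSLR sentinel unless `correction = TRUE`, which adds 0.5 to both
#' cells of the affected stratum (totals adjusted accordingly) and flags
#' the row.
#'
#' @param table A [stratum_table()].
#' @param correction Apply the Haldane +0.5 correction to zero-cell strata.
#' @return An `sslr_result`: a data.frame with per-stratum counts, `sslr`,
#'   `ci_low`, `ci_high`, `band` and `corrected`.
#' @export
sslr <- function(table, correction = FALSE) {
  stopifnot(inherits(table, "stratum_table"))
  if (any(table$d_counts == 0 & table$t_counts == 0)) {
    stop("a stratum with zero counts in both groups is not estimable; ",
         "merge it first (collapse_sparse)", call. = FALSE)
  }
  d <- table$d_counts; t <- table$t_counts
  dn <- rep(table$d_total, length(d)); tn <- rep(table$t_total, length(t))
  corrected <- (d == 0 | t == 0) & correction
  d2 <- d + 0.5 * corrected; t2 <- t + 0.5 * corrected
  dn2 <- dn + 0.5 * corrected; tn2 <- tn + 0.5 * corrected
  est <- (d2 / dn2) / (t2 / tn2)
  se <- sqrt(pmax(1 / d2 - 1 / dn2 + 1 / t2 - 1 / tn2, 0))
  ci_low <- exp(log(est) - stats::qnorm(0.975) * se)
  ci_high <- exp(log(est) + stats::qnorm(0.975) * se)
  ci_low[!is.finite(est) | est == 0] <- NA_real_
  ci_high[!is.finite(est) | est == 0] <- NA_real_
  band <- rep(NA_character_, length(est))
  ok <- est > 0 & is.finite(est)
  band[ok] <- interpret_lr(est[ok])
  out <- data.frame(stratum = table$strata, dld = d, tld = t,
                    sslr = est, ci_low = ci_low, ci_high = ci_high,
                    band = band, corrected = corrected,
                    stringsAsFactors = FALSE)
  attr(out, "d_total") <- table$d_total
  attr(out, "t_total") <- table$t_total
  class(out) <- c("sslr_result", "data.frame")
  out
}

#' Merge sparse score strata with their neighbors
#'
#' Adjacent strata are merged until every stratum holds at least
#' `min_count` children in each condition group (the rule used when a
#' top score stratum holds only a handful of children). The stratum
#' furthest below the threshold is merged into whichever adjacent
#' neighbor lies closer to the count-weighted center of the distribution,
#' so sparse tails fold inward; merged labels are concatenated with "-".
#' Group totals are preserved exactly.
#'
#' @param table A [stratum_table()] with strata in score order.
#' @param min_count Minimum per-group count per stratum (default 5).
#' @return A [stratum_table()]; unchanged if already satisfying the rule.
#' @export
collapse_sparse <- function(table, min_count = 5L) {
  stopifnot(inherits(table, "stratum_table"), min_count >= 0)
  groups <- as.list(table$strata)  # original labels folded into each stratum
  d <- table$d_counts; t <- table$t_counts
  repeat {
    bad <- which(d < min_count | t < min_count)
    if (length(bad) == 0L) break
    if (length(d) == 1L) {
      stop("cannot reach min_count ", min_count,
           " even after merging all strata", call. = FALSE)
    }
    # most deficient stratum first
    k <- bad[which.min(pmin(d, t)[bad])]
    center <- sum(seq_along(d) * (d + t)) / sum(d + t)
    if (k == 1L) j <- 2L
    else if (k == length(d)) j <- length(d) - 1L
    else j <- if (abs(k - 1L - center) <= abs(k + 1L - center)) k - 1L
              else k + 1L
    lo <- min(k, j); hi <- max(k, j)
    groups[[lo]] <- c(groups[[lo]], groups[[hi]])
    d[lo] <- d[lo] + d[hi]; t[lo] <- t[lo] + t[hi]
    groups <- groups[-hi]; d <- d[-hi]; t <- t[-hi]
  }
  strata <- vapply(groups, function(g) {
    if (length(g) == 1L) return(g)
    num <- suppressWarnings(as.numeric(g))
    if (anyNA(num)) paste(g, collapse = "-")
    else paste0(min(num), "-", max(num))  # conventional "3-4" range label
  }, character(1))
  stratum_table(strata, d, t)
}

#' Update a pretest probability through one or more likelihood ratios
#'
#' Bayes' theorem on the odds scale: the pretest probability is converted
#' to odds, multiplied by each likelihood ratio in turn, and converted
#' back. Chaining several LRs assumes the tests are conditionally
#' independent given condition status; the result does not depend on the
#' order of the LRs.
#'
#' @param pretest Pretest probability in (0, 1).
#' @param lrs Positive likelihood ratio(s) to apply in sequence.
#' @return A `probability_update`: list with `pretest_prob`,
#'   `pretest_odds`, `applied_lrs`, `posttest_odds`, `posttest_prob`
#'   (full precision; the print method rounds odds to 3 dp and
#'   probabilities to 2 dp).
#' @examples
#' update_probability(0.12, 8.792)   # posttest ~ 0.55
#' @export
update_probability <- function(pretest, lrs) {
  if (!is.numeric(pretest) || length(pretest) != 1L ||
      !is.finite(pretest) || pretest <= 0 || pretest >= 1) {
    stop("pretest must be a probability strictly inside (0, 1)",
         call. = FALSE)
  }
  if (length(lrs) == 0L || any(!(lrs > 0))) {
    stop("all likelihood ratios must be positive", call. = FALSE)
  }
  pre_odds <- pretest / (1 - pretest)
  post_odds <- pre_odds * prod(lrs)
  out <- list(pretest_prob = pretest, pretest_odds = pre_odds,
              applied_lrs = as.numeric(lrs),
              posttest_odds = post_odds,
              posttest_prob = post_odds / (1 + post_odds))
  class(out) <- "probability_update"
  out
}

#' @export
print.probability_update <- function(x, ...) {
  cat(sprintf("pretest %.2f (odds %.3f) x LR %s -> odds %.3f, posttest %.2f\n",
              x$pretest_prob, x$pretest_odds,
              paste(sprintf("%.3f", x$applied_lrs), collapse = " x "),
              x$posttest_odds, x$posttest_prob))
  invisible(x)
}

#' Likelihood ratios of a dichotomous indicator
#'
#' For each level of a binary indicator, `LR_level =
#' P(level | DLD) / P(level | TLD)`. The two LRs satisfy the mixture
#' identity `sum_level LR_level * P(level | TLD) = 1`. An indicator level
#' empty in the TLD group yields an infinite sentinel unless
#' `correction = TRUE` (Haldane +0.5 on the level's two cells).
#'
#' @param indicator Binary per-child value (logical, 0/1 or a two-level
#'   factor); `NA` excluded with its child.
#' @param labels Condition per child, "DLD"/"TLD" (or logical with `TRUE`
#'   = DLD).
#' @param correction Apply +0.5 to the cells of an empty level.
#' @return A data.frame with one row per indicator level: `level`, counts,
#'   conditional proportions, `lr` and its interpretation `band`.
#' @export
binary_lr <- function(indicator, labels, correction = FALSE) {
  if (is.logical(labels)) labels <- ifelse(labels, "DLD", "TLD")
  keep <- !is.na(indicator) & !is.na(labels)
  indicator <- factor(indicator[keep])
  labels <- labels[keep]
  if (nlevels(indicator) != 2L) {
    stop("indicator must take exactly two observed levels", call. = FALSE)
  }
  if (!all(c("DLD", "TLD") %in% labels)) {
    stop("both condition classes must be present", call. = FALSE)
  }
  d <- as.vector(table(indicator[labels == "DLD"]))
  t <- as.vector(table(indicator[labels == "TLD"]))
  dn <- sum(d); tn <- sum(t)
  corrected <- (d == 0 | t == 0) & correction
  d2 <- d + 0.5 * corrected; t2 <- t + 0.5 * corrected
  dn2 <- dn + 0.5 * corrected; tn2 <- tn + 0.5 * corrected
  lr <- (d2 / dn2) / (t2 / tn2)
  band <- rep(NA_character_, length(lr))
  ok <- lr > 0 & is.finite(lr)
  band[ok] <- interpret_lr(lr[ok])
  data.frame(level = levels(indicator), dld = d, tld = t,
             p_dld = d / dn, p_tld = t / tn, lr = lr, band = band,
             corrected = corrected, stringsAsFactors = FALSE)
}

#' Screening-utility report: SSLRs with probability updates
#'
#' Produces the canonical utility table: per score stratum, counts, the
#' SSLR, and the pretest-to-posttest probability update from the given
#' pretest probability (default 0.12, an estimate of DLD prevalence among
#' Mexican 4-6 year olds). With `extra_lr` set (e.g. the likelihood ratio
#' of a dichotomized preschool-attendance indicator), a second, chained
#' posttest column is added under a conditional-independence assumption.
#'
#' @param table A [stratum_table()].
#' @param pretest Pretest probability (default 0.12).
#' @param extra_lr Optional single positive LR to chain after each SSLR.
#' @param correction Passed to [sslr()].
#' @return A `utility_report` data.frame: stratum, counts, sslr, band,
#'   pretest/posttest odds and probabilities (and `posttest2_odds`/
#'   `posttest2_prob` when `extra_lr` is given).
#' @export
utility_report <- function(table, pretest = 0.12, extra_lr = NULL,
                           correction = FALSE) {
  s <- sslr(table, correction = correction)
  upd <- lapply(s$sslr, function(l) update_probability(pretest, l))
  out <- data.frame(
    stratum = s$stratum, dld = s$dld, tld = s$tld,
    sslr = s$sslr, band = s$band,
    pretest_prob = pretest,
    pretest_odds = pretest / (1 - pretest),
    posttest_odds = vapply(upd, `[[`, numeric(1), "posttest_odds"),
    posttest_prob = vapply(upd, `[[`, numeric(1), "posttest_prob"),
    stringsAsFactors = FALSE
  )
  if (!is.null(extra_lr)) {
    stopifnot(length(extra_lr) == 1L, extra_lr > 0)
    upd2 <- lapply(s$sslr, function(l) update_probability(pretest,
                                                          c(l, extra_lr)))
    out$extra_lr <- extra_lr
    out$posttest2_odds <- vapply(upd2, `[[`, numeric(1), "posttest_odds")
    out$posttest2_prob <- vapply(upd2, `[[`, numeric(1), "posttest_prob")
  }
  class(out) <- c("utility_report", "data.frame")
  out
}

#' @export
print.utility_report <- function(x, ...) {
  y <- as.data.frame(x)
  y$sslr <- sprintf("%.3f", y$sslr)
  for (cc in grep("odds", names(y), value = TRUE)) {
    y[[cc]] <- sprintf("%.3f", y[[cc]])
  }
  for (cc in grep("prob", names(y), value = TRUE)) {
    y[[cc]] <- sprintf("%.2f", as.numeric(y[[cc]]))
  }
  print(y, row.names = FALSE)
  invisible(x)
}
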