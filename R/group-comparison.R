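#' Build a 2x2 condition-by-risk table
#'
#' Rows are conditions (DLD, TLD), columns are risk / no-risk. Cell `a` is
#' DLD-with-risk, `b` DLD-without, `c` TLD-with-risk, `d` TLD-without.
#'
#' @param a,b,c,d Nonnegative integer counts.
#' @return A 2x2 integer matrix of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(!is.finite(counts)) || any(counts < 0) || sum(counts) == 0) {
    stop("counts must be nonnegative with a positive total", call. = FALSE)
  }
  m <- matrix(counts, 2, 2, byrow = TRUE,
              dimnames = list(condition = c("DLD", "TLD"),
                              risk = c("risk", "no_risk")))
  class(m) <- c("two_by_two", class(m))
  m
}

.check_margins <- function(t) {
  if (any(rowSums(t) == 0) || any(colSums(t) == 0)) {
    stop("2x2 table has a zero margin; the effect is undefined",
         call. = FALSE)
  }
}

#' Interpretation band for an effect size
#'
#' Magnitude thresholds: for categorical effects (phi) null < 0.1 <= small
#' < 0.3 <= medium < 0.5 <= large; for continuous effects (Cohen's d)
#' null < 0.2 <= small < 0.5 <= medium < 0.8 <= large.
#'
#' @param value Effect-size value (sign ignored).
#' @param kind `"categorical"` (phi) or `"continuous"` (Cohen's d).
#' @return One of `"null"`, `"small"`, `"medium"`, `"large"`.
#' @export
effect_band <- function(value, kind = c("categorical", "continuous")) {
  kind <- match.arg(kind)
  cuts <- if (kind == "categorical") c(0.1, 0.3, 0.5) else c(0.2, 0.5, 0.8)
  bands <- c("null", "small", "medium", "large")
  bands[findInterval(abs(value), cuts) + 1L]
}

.effect_size <- function(kind, value, ci95 = NULL, band = NA_character_,
                         corrected = FALSE) {
  out <- list(kind = kind, value = value, ci95 = ci95, band = band,
              corrected = corrected)
  class(out) <- "effect_size"
  out
}

#' @export
print.effect_size <- function(x, digits = 3, ...) {
  cat(x$kind, "=", round(x$value, digits))
  if (!is.null(x$ci95)) {
    cat(sprintf(" (95%% CI %.*f, %.*f)", digits, x$ci95[1], digits, x$ci95[2]))
  }
  if (!is.na(x$band)) cat(" [", x$band, "]", sep = "")
  if (isTRUE(x$corrected)) cat(" (0.5 correction applied)")
  cat("\n")
  invisible(x)
}

#' Phi coefficient of a 2x2 table
#'
#' `phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`, the Pearson correlation
#' of the two binary variables. The sign follows the DLD-minus-TLD
#' convention of [two_by_two()]; the interpretation band uses the
#' magnitude with the categorical thresholds.
#'
#' @param t A [two_by_two()] table.
#' @return An `effect_size` with `kind = "phi"`.
#' @export
phi_coefficient <- function(t) {
  .check_margins(t)
  a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
  phi <- (a * d - b * c) /
    sqrt(prod(c(a + b, c + d, a + c, b + d)))
  .effect_size("phi", phi, band = effect_band(phi, "categorical"))
}

#' Pearson chi-square test of a 2x2 table
#'
#' No continuity correction is applied, so the identity
#' `statistic = n * phi^2` holds exactly and the test matches the
#' uncorrected chi-square convention of the screening analysis.
#'
#' @param t A [two_by_two()] table.
#' @return List with `statistic`, `df` (1) and `p_value`.
#' @export
pearson_chi2 <- function(t) {
  .check_margins(t)
  ht <- stats::chisq.test(unclass(t), correct = FALSE)
  list(statistic = unname(ht$statistic), df = 1L,
       p_value = unname(ht$p.value))
}

#' Odds ratio of a 2x2 table with a Woolf 95% CI
#'
#' `OR = ad / bc`; the confidence interval is
#' `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. A zero cell
#' triggers the Haldane-Anscombe correction (+0.5 to every cell), flagged
#' in the result.
#'
#' @param t A [two_by_two()] table.
#' @return An `effect_size` with `kind = "odds_ratio"` and `ci95`.
#' @export
odds_ratio <- function(t) {
  .check_margins(t)
  cells <- c(t[1, 1], t[1, 2], t[2, 1], t[2, 2])
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  .effect_size("odds_ratio", or, ci95 = ci, corrected = corrected)
}

#' Welch's unequal-variance t test
#'
#' Two-sided t test with the Welch-Satterthwaite degrees of freedom.
#'
#' @param x,y Numeric samples of size >= 2 with nonzero variance.
#' @return List with `statistic` (sign = mean(x) - mean(y)), `df` and
#'   `p_value`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2 ||
      stats::var(x) == 0 && stats::var(y) == 0) {
    stop("welch_t needs two samples of size >= 2 with nonzero variance",
         call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(ht$statistic),
       df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Cohen's d for two samples
#'
#' `d = (mean(x) - mean(y)) / s_pooled` with the (n-1)-weighted pooled
#' standard deviation by default; `pooled = FALSE` uses the
#' unpooled (Welch-style) `sqrt((s_x^2 + s_y^2)/2)` denominator. The
#' interpretation band uses the continuous thresholds on the magnitude.
#'
#' @param x,y Numeric samples.
#' @param pooled Use the pooled-SD denominator (default).
#' @return An `effect_size` with `kind = "cohens_d"` (sign = x minus y).
#' @export
cohens_d <- function(x, y, pooled = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("samples must have size >= 2", call. = FALSE)
  s <- if (pooled) {
    sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
           (nx + ny - 2))
  } else {
    sqrt((stats::var(x) + stats::var(y)) / 2)
  }
  if (s == 0) stop("zero pooled standard deviation", call. = FALSE)
  d <- (mean(x) - mean(y)) / s
  .effect_size("cohens_d", d, band = effect_band(d, "continuous"))
}

#' Question-wise DLD vs TLD comparison report
#'
#' For each PLCQ question, tabulates risk perceptions by condition and
#' reports counts (percent), the phi coefficient with its band, the
#' uncorrected Pearson chi-square p value, and the odds ratio with a 95%
#' CI — the layout of a question-screening table. Children with a missing
#' answer on a question are excluded from that question's table only; the
#' number of tests performed (no multiplicity adjustment is applied) and
#' per-question exclusion counts are attached as attributes.
#'
#' @param children A coded cohort (see [code_records()]); the `condition`
#'   column must be complete.
#' @return A data.frame with one row per question, attributes `n_tests`
#'   and `n_excluded`.
#' @export
compare_questions <- function(children) {
  if (!all(paste0("risk", 1:8) %in% names(children))) {
    children <- code_records(children)
  }
  if (anyNA(children$condition)) {
    stop("condition must be known (DLD/TLD) for every child", call. = FALSE)
  }
  sch <- plcq_schema()
  is_dld <- children$condition == "DLD"
  rows <- lapply(1:8, function(q) {
    r <- children[[paste0("risk", q)]]
    keep <- !is.na(r)
    a <- sum(r[keep] & is_dld[keep]); b <- sum(!r[keep] & is_dld[keep])
    cc <- sum(r[keep] & !is_dld[keep]); d <- sum(!r[keep] & !is_dld[keep])
    t <- two_by_two(a, b, cc, d)
    phi <- phi_coefficient(t)
    or <- odds_ratio(t)
    chi <- pearson_chi2(t)
    data.frame(
      question = q, text = sch$text[q],
      dld_risk = a, dld_n = a + b, dld_pct = 100 * a / (a + b),
      tld_risk = cc, tld_n = cc + d, tld_pct = 100 * cc / (cc + d),
      phi = phi$value, band = phi$band, p_value = chi$p_value,
      odds_ratio = or$value, or_low = or$ci95[1], or_high = or$ci95[2],
      n_excluded = sum(!keep),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "n_tests") <- 8L
  attr(out, "n_excluded") <- stats::setNames(out$n_excluded,
                                             paste0("q", out$question))
  out
}

#' Write a comparison (or any report) table
#'
#' @param report A data.frame report.
#' @param path Output path; `.json` selects JSON, otherwise CSV.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(report, path, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(report, path, row.names = FALSE, na = "NA")
  }
  invisible(path)
}
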