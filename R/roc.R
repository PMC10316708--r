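#' Empirical ROC curve and AUC with a DeLong confidence interval
#'
#' Computes the empirical ROC over all distinct score thresholds
#' (higher score = more indicative of the condition), the trapezoidal
#' AUC — identical to the tie-corrected Mann-Whitney probability that a
#' child with the condition outscores one without, ties counted half —
#' and a 95% CI for the AUC by DeLong's method (placement-value
#' variance, deterministic).
#'
#' @param scores Numeric or ordinal score per child.
#' @param labels Condition per child: "DLD"/"TLD", logical or 0/1
#'   (1/TRUE/DLD = positive class).
#' @return A `roc_curve`: list with `thresholds`, `sensitivity`, `fpr`
#'   (1 - specificity), `auc`, `auc_se`, `auc_ci95`, `n_pos`, `n_neg`.
#' @examples
#' roc_auc(c(3, 2, 1, 0), c(1, 1, 0, 0))
#' @export
roc_auc <- function(scores, labels) {
  labels <- .as_binary_label(labels)
  keep <- !is.na(scores)
  scores <- as.numeric(scores[keep]); labels <- labels[keep]
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  if (m == 0L || n == 0L) {
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  }
  # curve: classify positive when score >= threshold, thresholds from
  # above the maximum down through every distinct score
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  # placement values: psi(x, y) = 1[x > y] + 0.5 * 1[x == y]
  # V10[i] = mean_j psi(pos_i, neg_j); V01[j] = mean_i psi(pos_i, neg_j)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  auc <- mean(v10)
  s10 <- if (m > 1) stats::var(v10) else 0
  s01 <- if (n > 1) stats::var(v01) else 0
  se <- sqrt(s10 / m + s01 / n)
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  out <- list(thresholds = thr, sensitivity = sens, fpr = fpr,
              auc = auc, auc_se = se, auc_ci95 = ci,
              n_pos = m, n_neg = n)
  class(out) <- "roc_curve"
  out
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (95%% CI %.4f, %.4f; DeLong), %d vs %d\n",
              x$auc, x$auc_ci95[1], x$auc_ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' ROC coordinates as a data.frame (for export/plotting)
#'
#' @param roc A `roc_curve`.
#' @return data.frame with `threshold`, `sensitivity`, `specificity`,
#'   `fpr`.
#' @export
roc_coordinates <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  data.frame(threshold = roc$thresholds, sensitivity = roc$sensitivity,
             specificity = 1 - roc$fpr, fpr = roc$fpr)
}

#' Expand a stratum table to per-child scores and labels
#'
#' Convenience inverse of [stratum_table_from_scores()]: turns a
#' condition-by-score count table back into per-child `(score, label)`
#' pairs, e.g. for score-based ROC analysis of a published count table.
#' Stratum labels must be single numeric scores (merged strata cannot be
#' expanded).
#'
#' @param table A [stratum_table()].
#' @return A data.frame with `score` and `condition`.
#' @export
expand_strata <- function(table) {
  stopifnot(inherits(table, "stratum_table"))
  sc <- suppressWarnings(as.numeric(table$strata))
  if (anyNA(sc)) {
    stop("cannot expand merged stratum labels to scores", call. = FALSE)
  }
  data.frame(
    score = c(rep(sc, table$d_counts), rep(sc, table$t_counts)),
    condition = c(rep("DLD", sum(table$d_counts)),
                  rep("TLD", sum(table$t_counts))),
    stringsAsFactors = FALSE
  )
}
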