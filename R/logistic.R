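#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Newton-Raphson / IRLS for the binomial-logit likelihood. Iterates until
#' the log-likelihood improves by less than `tol` (default 1e-10) or
#' `max_iter` steps. Standard errors are Wald, from the inverse of the
#' final weighted information matrix; per-term Wald chi-square statistics
#' and odds ratios with 95% CIs are reported alongside, the layout of a
#' question-selection model table.
#'
#' @param y Binary response: logical, 0/1, or "DLD"/"TLD" labels (DLD = 1).
#' @param X Predictor matrix or data.frame (no intercept column; one is
#'   added). Column names become term names.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum IRLS iterations (default 50).
#' @return A `logistic_model`: list with `terms`, `beta`, `se`, `vcov`,
#'   `loglik`, `aic` (`2k - 2 loglik`), `wald_chi2`, `p_value`, `or_ci`
#'   (data.frame of exp(beta) with 95% Wald CI), `fitted`, `n_iter`,
#'   `converged`.
#' @export
fit_logistic <- function(y, X, tol = 1e-10, max_iter = 50L) {
  y <- .as_binary_label(y)
  X <- .as_design(X)
  n <- length(y)
  if (nrow(X) != n) stop("y and X disagree on n", call. = FALSE)
  Xd <- cbind(`(Intercept)` = 1, X)
  k <- ncol(Xd)
  if (n <= k) stop("need more observations than coefficients", call. = FALSE)
  const <- apply(X, 2, function(col) length(unique(col)) == 1L)
  if (any(const)) {
    stop("constant (degenerate) column(s): ",
         paste(colnames(X)[const], collapse = ", "), call. = FALSE)
  }
  qrX <- qr(Xd)
  if (qrX$rank < k) {
    bad <- colnames(Xd)[qrX$pivot[(qrX$rank + 1):k]]
    stop("singular design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- numeric(k)
  beta[1] <- stats::qlogis(max(min(mean(y), 1 - 0.5 / n), 0.5 / n))
  loglik <- sum(y * beta[1] - log1p(exp(beta[1])))
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    eta <- drop(Xd %*% beta)
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    info <- crossprod(Xd, Xd * w)
    score <- crossprod(Xd, y - p)
    step <- tryCatch(solve(info, score),
                     error = function(e) stop("information matrix singular ",
                                              "during IRLS", call. = FALSE))
    beta <- beta + drop(step)
    eta <- drop(Xd %*% beta)
    if (max(abs(eta)) > 30 && iter > 3L) {
      stop("diverging coefficients: perfect or quasi-perfect separation",
           call. = FALSE)
    }
    ll <- sum(y * eta - log1p(exp(eta)))
    if (abs(ll - loglik) < tol) {
      loglik <- ll
      converged <- TRUE
      break
    }
    loglik <- ll
  }
  eta <- drop(Xd %*% beta)
  p <- stats::plogis(eta)
  info <- crossprod(Xd, Xd * (p * (1 - p)))
  vcov <- solve(info)
  se <- sqrt(diag(vcov))
  wald <- (beta / se)^2
  zq <- stats::qnorm(0.975)
  or_ci <- data.frame(term = colnames(Xd), or = exp(beta),
                      low = exp(beta - zq * se), high = exp(beta + zq * se),
                      row.names = NULL, stringsAsFactors = FALSE)
  out <- list(terms = colnames(X), beta = stats::setNames(beta, colnames(Xd)),
              se = stats::setNames(se, colnames(Xd)), vcov = vcov,
              loglik = loglik, aic = 2 * k - 2 * loglik,
              wald_chi2 = stats::setNames(wald, colnames(Xd)),
              p_value = stats::setNames(stats::pchisq(wald, 1,
                                                      lower.tail = FALSE),
                                        colnames(Xd)),
              or_ci = or_ci, fitted = p, n = n,
              n_iter = iter, converged = converged)
  class(out) <- "logistic_model"
  out
}

.as_binary_label <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- toupper(as.character(y))
    if (!all(y %in% c("DLD", "TLD"))) {
      stop("character response must be DLD/TLD", call. = FALSE)
    }
    y <- as.numeric(y == "DLD")
  }
  y <- as.numeric(y)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("response must be binary with no missing values", call. = FALSE)
  }
  if (length(unique(y)) < 2L) {
    stop("response must contain both classes", call. = FALSE)
  }
  y
}

.as_design <- function(X) {
  if (is.data.frame(X)) {
    X <- vapply(X, function(col) {
      if (is.logical(col)) as.numeric(col)
      else if (is.character(col)) as.numeric(.normalize_answers(col) == "yes")
      else as.numeric(col)
    }, numeric(nrow(X)))
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (anyNA(X)) stop("design matrix contains missing values", call. = FALSE)
  X
}

#' @export
print.logistic_model <- function(x, digits = 3, ...) {
  cat("Logistic model (IRLS,", x$n_iter, "iterations",
      if (!x$converged) ", NOT converged", ")\n", sep = "")
  df <- data.frame(term = names(x$beta),
                   beta = round(x$beta, digits),
                   se = round(x$se, digits),
                   wald_chi2 = round(x$wald_chi2, 2),
                   p = signif(x$p_value, 2),
                   or = round(x$or_ci$or, 2),
                   or_low = round(x$or_ci$low, 2),
                   or_high = round(x$or_ci$high, 2))
  print(df, row.names = FALSE)
  cat(sprintf("logLik %.3f | AIC %.2f | n %d\n", x$loglik, x$aic, x$n))
  invisible(x)
}

#' Model report as a data.frame
#'
#' @param model A `logistic_model`.
#' @return A data.frame with one row per coefficient (term, beta, se,
#'   Wald chi-square, p, OR with 95% CI).
#' @export
model_report <- function(model) {
  stopifnot(inherits(model, "logistic_model"))
  data.frame(term = names(model$beta), beta = unname(model$beta),
             se = unname(model$se), wald_chi2 = unname(model$wald_chi2),
             p_value = unname(model$p_value), or = model$or_ci$or,
             or_low = model$or_ci$low, or_high = model$or_ci$high,
             stringsAsFactors = FALSE)
}

#' Stepwise question selection by AIC
#'
#' Bidirectional stepwise search (the default; pure forward or backward
#' are options): starting from the full model, every single-term deletion
#' and addition is evaluated, the move with the lowest AIC is applied, and
#' the search stops when no move improves on the current AIC. Ties break
#' deterministically by term order in `X_full`. Candidates whose fit fails
#' (e.g. separation) are skipped with a warning.
#'
#' @param y Binary response as in [fit_logistic()].
#' @param X_full Full design matrix/data.frame of candidate terms.
#' @param direction "both" (default), "backward" or "forward".
#' @param forced Character vector of term names never dropped.
#' @param trace Print the move sequence.
#' @return The selected `logistic_model`, with the visited terms and AICs
#'   in `$steps`. An empty selection returns the intercept-only model.
#' @export
stepwise_aic <- function(y, X_full, direction = c("both", "backward",
                                                  "forward"),
                         forced = character(), trace = FALSE) {
  direction <- match.arg(direction)
  X_full <- .as_design(X_full)
  all_terms <- colnames(X_full)
  stopifnot(all(forced %in% all_terms))
  y <- .as_binary_label(y)

  fit_terms <- function(terms) {
    if (length(terms) == 0L) {
      # intercept-only model in closed form
      n <- length(y); p <- mean(y)
      ll <- sum(y * log(p) + (1 - y) * log(1 - p))
      se0 <- sqrt(1 / (n * p * (1 - p)))
      out <- list(terms = character(),
                  beta = c(`(Intercept)` = stats::qlogis(p)),
                  se = c(`(Intercept)` = se0),
                  loglik = ll, aic = 2 - 2 * ll,
                  fitted = rep(p, n), n = n, n_iter = 0L, converged = TRUE)
      class(out) <- "logistic_model"
      return(out)
    }
    tryCatch(fit_logistic(y, X_full[, terms, drop = FALSE]),
             error = function(e) {
               warning("skipping candidate {", paste(terms, collapse = ","),
                       "}: ", conditionMessage(e), call. = FALSE)
               NULL
             })
  }

  current <- switch(direction, forward = forced,
                    both = , backward = all_terms)
  cur_fit <- fit_terms(current)
  if (is.null(cur_fit)) stop("initial model failed to fit", call. = FALSE)
  steps <- data.frame(move = "<start>", aic = cur_fit$aic,
                      stringsAsFactors = FALSE)
  repeat {
    candidates <- list()
    if (direction %in% c("both", "backward")) {
      for (tm in setdiff(current, forced)) {
        candidates[[paste0("- ", tm)]] <- setdiff(current, tm)
      }
    }
    if (direction %in% c("both", "forward")) {
      for (tm in setdiff(all_terms, current)) {
        candidates[[paste0("+ ", tm)]] <- c(current, tm)
      }
    }
    if (length(candidates) == 0L) break
    aics <- vapply(candidates, function(tm) {
      f <- fit_terms(tm)
      if (is.null(f)) Inf else f$aic
    }, numeric(1))
    best <- which.min(aics)  # which.min takes the first minimum: the
                             # documented tie-break by candidate order
    if (aics[best] >= cur_fit$aic) break
    current <- candidates[[best]]
    # keep original term order for determinism of the reported model
    current <- all_terms[all_terms %in% current]
    cur_fit <- fit_terms(current)
    steps <- rbind(steps, data.frame(move = names(candidates)[best],
                                     aic = cur_fit$aic))
    if (trace) message(names(candidates)[best], "  AIC = ",
                       round(cur_fit$aic, 2))
  }
  out <- cur_fit
  out$selected <- current
  out$steps <- steps
  out
}
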