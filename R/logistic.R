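# Logistic risk-factor screening.
#
# The maximum-likelihood fit is iteratively reweighted least squares with
# step-halving, which guarantees a non-decreasing log-likelihood across
# iterations. Confidence intervals are Wald: exp(b +/- z * se).

logistic_loglik <- function(eta, y) {
  # numerically safe Bernoulli log-likelihood
  sum(y * eta - log1p(exp(-abs(eta))) - pmax(eta, 0))
}

irls_logistic <- function(X, y, max_iter = 100L, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  eta <- drop(X %*% beta)
  ll <- logistic_loglik(eta, y)
  ll_trace <- ll
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    fit <- tryCatch(
      solve(crossprod(X, w * X), crossprod(X, w * z)),
      error = function(e) NULL)
    if (is.null(fit)) break
    beta_new <- drop(fit)
    step <- beta_new - beta
    # step-halving: never decrease the log-likelihood
    for (h in 0:30) {
      cand <- beta + step / 2^h
      eta_c <- drop(X %*% cand)
      ll_c <- logistic_loglik(eta_c, y)
      if (is.finite(ll_c) && ll_c >= ll - 1e-12) break
    }
    moved <- max(abs(cand - beta))
    beta <- cand; eta <- eta_c
    ll_trace <- c(ll_trace, ll_c)
    ll <- ll_c
    if (moved < tol * (1 + max(abs(beta)))) {
      converged <- TRUE
      break
    }
  }
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  vcov <- tryCatch(solve(crossprod(X, w * X)), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  separated <- any(mu > 1 - 1e-8 | mu < 1e-8) && max(abs(beta)) > 10
  list(coefficients = beta, vcov = vcov, loglik = ll, loglik_trace = ll_trace,
       iterations = length(ll_trace) - 1L, converged = converged,
       separated = separated, fitted = mu)
}

#' Fit a logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with Wald confidence intervals on the
#' odds-ratio scale. Rank-deficient designs (e.g. constant covariates) are
#' rejected; separation or non-convergence is flagged on the result rather
#' than silently reported.
#'
#' @param x Numeric design matrix or data.frame of covariates (no intercept
#'   column; one is added).
#' @param y Binary response (0/1, logical, or two-level factor).
#' @param conf_level Confidence level for the Wald intervals (default 0.95).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @return Object of class `lcshift_logistic`: data.frame `coefficients`
#'   with columns `term`, `estimate`, `se`, `or`, `ci_lower`, `ci_upper`,
#'   `p_value`, plus `converged`, `separated`, `loglik`, `loglik_trace`,
#'   `n`.
#' @export
logistic_fit <- function(x, y, conf_level = 0.95, max_iter = 100L) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L, dimnames = list(NULL, "x"))
  storage.mode(x) <- "double"
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_lcshift("response must be binary (0/1)")
  keep <- stats::complete.cases(x) & !is.na(y)
  x <- x[keep, , drop = FALSE]; y <- y[keep]
  n <- length(y)
  X <- cbind(`(Intercept)` = 1, x)
  if (n <= ncol(X))
    stop_lcshift("need more observations (", n, ") than parameters (", ncol(X), ")")
  if (qr(X)$rank < ncol(X))
    stop_lcshift("design matrix is rank-deficient (constant or collinear covariate)")
  fit <- irls_logistic(X, y, max_iter = max_iter)
  if (!fit$converged)
    warning("IRLS did not converge in ", max_iter, " iterations", call. = FALSE)
  if (fit$separated)
    warning("(quasi-)separation detected; estimates are unstable", call. = FALSE)
  se <- sqrt(diag(fit$vcov))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- fit$coefficients
  coefs <- data.frame(
    term = colnames(X), estimate = est, se = se,
    or = exp(est), ci_lower = exp(est - z * se), ci_upper = exp(est + z * se),
    p_value = 2 * stats::pnorm(-abs(est / se)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, converged = fit$converged,
                 separated = fit$separated, loglik = fit$loglik,
                 loglik_trace = fit$loglik_trace, n = n,
                 conf_level = conf_level),
            class = "lcshift_logistic")
}

#' @export
print.lcshift_logistic <- function(x, digits = 3, ...) {
  cat("Logistic regression (IRLS), n =", x$n,
      if (!x$converged) "[NOT CONVERGED]" else "",
      if (x$separated) "[SEPARATION]" else "", "\n")
  co <- x$coefficients
  co$or <- signif(co$or, digits)
  co$ci <- sprintf("(%s to %s)", signif(co$ci_lower, digits),
                   signif(co$ci_upper, digits))
  co$p <- format.pval(co$p_value, digits = digits, eps = 1e-3)
  print(co[, c("term", "or", "ci", "p")], row.names = FALSE)
  invisible(x)
}

#' Univariate screen followed by multivariate logistic fit
#'
#' Fits one univariate logistic model per candidate covariate, keeps
#' candidates with Wald p below `threshold` (default 0.20) and fits the
#' joint multivariate model on the survivors. Rows with missing values are
#' dropped per model. If no candidate passes, only the univariate stage is
#' returned, with a note.
#'
#' @param data data.frame holding the candidate covariates.
#' @param response Binary response vector aligned with `data`.
#' @param candidates Character vector of column names to screen (defaults
#'   to every column of `data`).
#' @param threshold Univariate screening p-value threshold (default 0.20).
#' @param conf_level Confidence level passed to [logistic_fit()].
#' @return Object of class `lcshift_screen`: `univariate` (data.frame of
#'   per-candidate rows), `selected`, `multivariate`
#'   (`lcshift_logistic` or `NULL`), `note`.
#' @export
screen_and_fit <- function(data, response, candidates = names(data),
                           threshold = 0.20, conf_level = 0.95) {
  stopifnot(is.data.frame(data), all(candidates %in% names(data)))
  uni <- do.call(rbind, lapply(candidates, function(v) {
    fit <- tryCatch(logistic_fit(data[[v]], response, conf_level = conf_level),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(term = v, estimate = NA_real_, se = NA_real_,
                        or = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, p_value = NA_real_, n = NA_integer_,
                        stringsAsFactors = FALSE))
    row <- fit$coefficients[fit$coefficients$term != "(Intercept)", , drop = FALSE]
    row$term <- v
    row$n <- fit$n
    row
  }))
  selected <- uni$term[!is.na(uni$p_value) & uni$p_value < threshold]
  multi <- NULL
  note <- NULL
  if (length(selected) >= 1L) {
    multi <- tryCatch(
      logistic_fit(data[, selected, drop = FALSE], response,
                   conf_level = conf_level),
      error = function(e) {
        note <<- conditionMessage(e)
        NULL
      })
  } else {
    note <- paste0("no candidate passed the univariate screen at p < ",
                   threshold)
  }
  structure(list(univariate = uni, selected = selected, multivariate = multi,
                 threshold = threshold, note = note),
            class = "lcshift_screen")
}

#' @export
print.lcshift_screen <- function(x, digits = 3, ...) {
  cat("Univariate logistic screen (threshold p <", x$threshold, ")\n")
  u <- x$univariate
  u$or <- signif(u$or, digits)
  u$p <- format.pval(u$p_value, digits = digits, eps = 1e-3)
  print(u[, c("term", "or", "p", "n")], row.names = FALSE)
  cat("Selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  if (!is.null(x$multivariate)) {
    cat("\nMultivariate model:\n")
    print(x$multivariate, digits = digits)
  }
  if (!is.null(x$note)) cat("Note:", x$note, "\n")
  invisible(x)
}
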