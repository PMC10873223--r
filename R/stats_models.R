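#' Firth penalized logistic regression
#'
#' Maximizes the Jeffreys-prior penalized log-likelihood
#' `l(beta) + 0.5 * log det(X'WX)` by Newton iterations on the
#' hat-value-corrected score `X'(y - p + h * (0.5 - p))`, with
#' step-halving when a step does not improve the penalized likelihood.
#' Estimates remain finite under complete or quasi-complete separation,
#' the situation that motivates the correction when one covariate group
#' contains no events.
#'
#' @param x design matrix including an intercept column (full rank).
#' @param y binary outcome (logical or 0/1).
#' @param max_iter maximum Newton iterations.
#' @param tol convergence tolerance on the score norm.
#' @param conf confidence level for Wald intervals.
#' @return object of class `firth_fit`: coefficients, standard errors,
#'   odds ratios with Wald confidence intervals, Wald p-values, the
#'   penalized log-likelihood, `converged` and `iterations`.
#' @export
firth_logistic <- function(x, y, max_iter = 100L, tol = 1e-8,
                           conf = 0.95) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary")
  if (nrow(x) != length(y)) stop("design/outcome length mismatch")
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("x", seq_len(ncol(x)) - 1L)
  p <- ncol(x)
  beta <- rep(0, p)
  penll <- function(beta) {
    eta <- drop(x %*% beta)
    pr <- stats::plogis(eta)
    w <- pmax(pr * (1 - pr), .Machine$double.eps)
    info <- crossprod(x * sqrt(w))
    sum(y * eta - log1p(exp(eta))) +
      0.5 * determinant(info, logarithm = TRUE)$modulus
  }
  ll_old <- penll(beta)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    pr <- stats::plogis(eta)
    w <- pmax(pr * (1 - pr), .Machine$double.eps)
    xw <- x * sqrt(w)
    info <- crossprod(xw)
    hat <- rowSums((xw %*% solve(info)) * xw)
    score <- drop(crossprod(x, y - pr + hat * (0.5 - pr)))
    if (sqrt(sum(score^2)) < tol) { converged <- TRUE; break }
    delta <- solve(info, score)
    step <- 1
    repeat {
      ll_new <- penll(beta + step * delta)
      if (ll_new >= ll_old - 1e-12 || step < 1e-6) break
      step <- step / 2
    }
    beta <- beta + step * delta
    ll_old <- penll(beta)
  }
  eta <- drop(x %*% beta)
  pr <- stats::plogis(eta)
  w <- pmax(pr * (1 - pr), .Machine$double.eps)
  vcov <- solve(crossprod(x * sqrt(w)))
  se <- sqrt(diag(vcov))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  pvals <- 2 * stats::pnorm(-abs(beta / se))
  structure(list(coefficients = stats::setNames(beta, colnames(x)),
                 se = stats::setNames(se, colnames(x)),
                 odds_ratio = exp(beta),
                 or_lower = exp(beta - z * se),
                 or_upper = exp(beta + z * se),
                 p_value = pvals,
                 log_penalized_likelihood = as.numeric(ll_old),
                 vcov = vcov,
                 converged = converged, iterations = iter),
            class = "firth_fit")
}

#' @export
print.firth_fit <- function(x, ...) {
  tab <- data.frame(coef = x$coefficients, se = x$se, OR = x$odds_ratio,
                    lower = x$or_lower, upper = x$or_upper,
                    p = x$p_value)
  print(round(tab, 4))
  cat("penalized logLik", round(x$log_penalized_likelihood, 3),
      if (x$converged) "(converged," else "(NOT converged,",
      x$iterations, "iterations)\n")
  invisible(x)
}

#' Univariable screen for multivariable candidates
#'
#' Fits one Firth logistic regression per predictor column and keeps
#' those with a Wald p-value below `alpha`, the conventional screen
#' before a multivariable model.
#'
#' @param data data frame of predictors.
#' @param outcome binary outcome vector.
#' @param alpha retention threshold (default 0.05).
#' @return character vector of retained predictor names.
#' @export
screen_predictors <- function(data, outcome, alpha = 0.05) {
  keep <- vapply(names(data), function(nm) {
    x <- cbind(intercept = 1, as.numeric(data[[nm]]))
    fit <- firth_logistic(x, outcome)
    fit$p_value[2] < alpha
  }, logical(1))
  names(data)[keep]
}

#' McNemar's test on paired classifier correctness
#'
#' Converts two classifiers' predictions into paired correct/incorrect
#' indicators against the observed outcome and tests the discordant
#' counts: `chi^2 = (b - c)^2 / (b + c)`, with an exact binomial test
#' when fewer than 25 discordant pairs are available.
#'
#' @param flags_a,flags_b logical predictions of the two classifiers.
#' @param actual logical observed outcome.
#' @return list with `statistic`, `p_value`, discordant counts `b` and
#'   `c`, and `method`.
#' @export
mcnemar_paired <- function(flags_a, flags_b, actual) {
  n <- length(actual)
  if (length(flags_a) != n || length(flags_b) != n)
    stop("inputs must be paired")
  ca <- flags_a == actual
  cb <- flags_b == actual
  b <- sum(ca & !cb)
  cc <- sum(!ca & cb)
  if (b + cc == 0)
    return(list(statistic = 0, p_value = 1, b = b, c = cc,
                method = "degenerate"))
  stat <- (b - cc)^2 / (b + cc)
  if (b + cc < 25) {
    p <- stats::binom.test(b, b + cc, 0.5)$p.value
    method <- "exact_binomial"
  } else {
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    method <- "chi_squared"
  }
  list(statistic = stat, p_value = p, b = b, c = cc, method = method)
}

#' DeLong comparison of two paired AUCs
#'
#' AUCs are Mann-Whitney estimates (ties count one half); the paired
#' difference is tested with DeLong's placement-value covariance and a
#' two-sided normal p-value.
#'
#' @param scores_a,scores_b paired continuous classifier scores.
#' @param actual logical outcome; both classes must be present.
#' @return list with `auc_a`, `auc_b`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, actual) {
  actual <- as.logical(actual)
  if (length(unique(actual)) < 2)
    stop("both outcome classes must be present")
  if (length(scores_a) != length(actual) ||
      length(scores_b) != length(actual))
    stop("scores must be paired with the outcome")
  ra <- pROC::roc(response = actual, predictor = scores_a,
                  direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)
  rb <- pROC::roc(response = actual, predictor = scores_b,
                  direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)
  auc_a <- as.numeric(pROC::auc(ra))
  auc_b <- as.numeric(pROC::auc(rb))
  if (isTRUE(all.equal(scores_a, scores_b))) {
    p <- 1
  } else {
    tst <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    p <- tst$p.value
    if (!is.finite(p)) p <- 1  # zero-variance difference
  }
  list(auc_a = auc_a, auc_b = auc_b, p_value = p)
}
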