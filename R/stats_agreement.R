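#' Lin's concordance correlation coefficient
#'
#' Agreement of paired measurements with the identity line:
#' `2 * s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with population
#' (1/n) moments.  The confidence interval uses the Fisher z-transform
#' of the CCC with Lin's asymptotic variance.
#'
#' @param x,y numeric vectors of equal length (n >= 3); at least one of
#'   the two must have nonzero variance.
#' @param conf confidence level.
#' @return object of class `ccc_result`: `estimate`, `lower`, `upper`,
#'   `n`.
#' @export
ccc <- function(x, y, conf = 0.95) {
  n <- length(x)
  if (n != length(y) || n < 3) stop("ccc: need paired vectors, n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("ccc: non-finite values")
  mx <- mean(x); my <- mean(y)
  sx2 <- mean((x - mx)^2); sy2 <- mean((y - my)^2)
  sxy <- mean((x - mx) * (y - my))
  if (sx2 == 0 && sy2 == 0) stop("ccc: both variances are zero")
  est <- 2 * sxy / (sx2 + sy2 + (mx - my)^2)
  lo <- hi <- NA_real_
  if (abs(est) < 1 && sx2 > 0 && sy2 > 0) {
    r <- sxy / sqrt(sx2 * sy2)
    u <- (mx - my) / (sx2 * sy2)^0.25
    z <- atanh(est)
    sz2 <- ((1 - r^2) * est^2 / ((1 - est^2) * r^2) +
              2 * est^3 * (1 - est) * u^2 / (r * (1 - est^2)^2) -
              est^4 * u^4 / (2 * r^2 * (1 - est^2)^2)) / (n - 2)
    if (is.finite(sz2) && sz2 > 0) {
      q <- stats::qnorm(1 - (1 - conf) / 2) * sqrt(sz2)
      lo <- tanh(z - q); hi <- tanh(z + q)
    }
  } else if (abs(est) == 1) {
    lo <- hi <- est
  }
  structure(list(estimate = est, lower = lo, upper = hi, n = n),
            class = "ccc_result")
}

#' @export
print.ccc_result <- function(x, ...) {
  cat(sprintf("CCC %.3f (95%% CI %.3f-%.3f), n = %d\n", x$estimate,
              x$lower, x$upper, x$n))
  invisible(x)
}

# BCa interval from a boot() object (handles NA replicates, which
# boot.ci() does not)
bca_interval <- function(b, conf = 0.95) {
  t0 <- b$t0
  t <- b$t[, 1]
  t <- t[is.finite(t)]
  if (length(t) < 50) stop("too few valid bootstrap replicates")
  z0 <- stats::qnorm((sum(t < t0) + sum(t == t0) / 2) / length(t))
  jack <- vapply(seq_len(nrow(b$data)), function(i)
    b$statistic(b$data[-i, , drop = FALSE],
                seq_len(nrow(b$data) - 1L)), numeric(1))
  jm <- mean(jack, na.rm = TRUE)
  num <- sum((jm - jack)^3, na.rm = TRUE)
  den <- 6 * (sum((jm - jack)^2, na.rm = TRUE))^1.5
  a <- if (den == 0) 0 else num / den
  al <- (1 - conf) / 2
  adj <- function(alpha) {
    zal <- stats::qnorm(alpha)
    stats::pnorm(z0 + (z0 + zal) / (1 - a * (z0 + zal)))
  }
  stats::quantile(t, probs = c(adj(al), adj(1 - al)), names = FALSE,
                  type = 6)
}

#' Difference of concordance correlation coefficients with BCa bootstrap
#'
#' `CCC(pred_a, outcome) - CCC(pred_b, outcome)` with a paired
#' case-resampling bootstrap and a bias-corrected and accelerated (BCa)
#' confidence interval.  Resamples in which a CCC is undefined (zero
#' variance) are dropped and counted.  The difference is significant
#' when the interval excludes 0.
#'
#' @param pred_a,pred_b,outcome aligned numeric vectors (n >= 10).
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed RNG seed (required for reproducibility).
#' @param conf confidence level.
#' @return object of class `ccc_difference`: `delta`, `lower`, `upper`,
#'   `ccc_a`, `ccc_b`, `n_boot`, `n_dropped`.
#' @export
ccc_difference <- function(pred_a, pred_b, outcome, n_boot = 2000,
                           seed = 1L, conf = 0.95) {
  n <- length(outcome)
  if (length(pred_a) != n || length(pred_b) != n)
    stop("vectors must be aligned")
  if (n < 10) stop("need n >= 10 for a stable bootstrap")
  dat <- data.frame(a = pred_a, b = pred_b, y = outcome)
  stat <- function(d, i) {
    di <- d[i, , drop = FALSE]
    ca <- tryCatch(ccc(di$a, di$y)$estimate, error = function(e) NA_real_)
    cb <- tryCatch(ccc(di$b, di$y)$estimate, error = function(e) NA_real_)
    ca - cb
  }
  set.seed(seed)
  b <- boot::boot(dat, stat, R = n_boot)
  n_dropped <- sum(!is.finite(b$t[, 1]))
  if (n_dropped > 0)
    warning(sprintf("%d degenerate bootstrap resamples dropped",
                    n_dropped))
  ci <- bca_interval(b, conf)
  structure(list(delta = b$t0, lower = ci[1], upper = ci[2],
                 ccc_a = ccc(pred_a, outcome)$estimate,
                 ccc_b = ccc(pred_b, outcome)$estimate,
                 n_boot = n_boot, n_dropped = n_dropped),
            class = "ccc_difference")
}

#' @export
print.ccc_difference <- function(x, ...) {
  cat(sprintf("dCCC %.3f (BCa 95%% CI %.3f-%.3f), B = %d\n", x$delta,
              x$lower, x$upper, x$n_boot))
  invisible(x)
}

#' Cohen's weighted kappa
#'
#' Chance-corrected agreement of two ordinal raters,
#' `1 - sum(w * observed) / sum(w * expected)` with linear or quadratic
#' disagreement weights.
#'
#' @param ratings_a,ratings_b vectors of equal length (n >= 2) over the
#'   same ordered categories.
#' @param weights `"quadratic"` (default) or `"linear"`.
#' @param categories optional explicit ordered category levels.
#' @return the weighted kappa.
#' @export
weighted_kappa <- function(ratings_a, ratings_b,
                           weights = c("quadratic", "linear"),
                           categories = NULL) {
  weights <- match.arg(weights)
  n <- length(ratings_a)
  if (n != length(ratings_b) || n < 2)
    stop("need paired ratings, n >= 2")
  if (is.null(categories))
    categories <- sort(unique(c(ratings_a, ratings_b)))
  fa <- factor(ratings_a, levels = categories)
  fb <- factor(ratings_b, levels = categories)
  if (any(is.na(fa)) || any(is.na(fb)))
    stop("ratings outside the category set")
  k <- length(categories)
  obs <- table(fa, fb) / n
  expc <- outer(rowSums(obs), colSums(obs))
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  w <- if (weights == "quadratic") d^2 else d
  if (sum(w * expc) == 0) return(1)
  1 - sum(w * obs) / sum(w * expc)
}
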