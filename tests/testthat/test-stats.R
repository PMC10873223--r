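test_that("confusion counts follow the standard layout", {
  cm <- confusion(rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(unlist(cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 5L, fp = 0L, fn = 0L, tn = 0L))
  a <- c(TRUE, TRUE, FALSE, FALSE)
  cm2 <- confusion(!a, a)
  expect_equal(cm2$tp + cm2$tn, 0L)
  expect_error(confusion(TRUE, logical(0)), "equal length")
})

test_that("diagnostic metrics reproduce arithmetic on reconstructed counts", {
  cm <- structure(list(tp = 34, fp = 6, fn = 2, tn = 10),
                  class = "confusion_matrix")
  m <- diagnostic_metrics(cm)
  est <- setNames(round(m$estimate, 1), m$metric)
  expect_equal(est[["accuracy"]], 84.6)
  expect_equal(est[["ppv"]], 85.0)
  expect_equal(est[["npv"]], 83.3)
  cm2 <- structure(list(tp = 35, fp = 0, fn = 1, tn = 16),
                   class = "confusion_matrix")
  est2 <- setNames(round(diagnostic_metrics(cm2)$estimate, 1),
                   m$metric)
  expect_equal(est2[["accuracy"]], 98.1)
  expect_equal(est2[["ppv"]], 100.0)
  expect_equal(est2[["npv"]], 94.1)
  # zero denominator: undefined, not zero
  cm3 <- structure(list(tp = 1, fp = 0, fn = 0, tn = 0),
                   class = "confusion_matrix")
  m3 <- diagnostic_metrics(cm3)
  expect_equal(m3$estimate[m3$metric == "sensitivity"], 100)
  expect_true(is.na(m3$estimate[m3$metric == "specificity"]))
})

test_that("confusion matrices are reconstructed from printed rates", {
  r <- metrics_from_rates(94.4, 62.5, 36, 16)
  expect_equal(unlist(r$cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 34, fp = 6, fn = 2, tn = 10))
  r2 <- metrics_from_rates(97.2, 100.0, 36, 16)
  expect_equal(unlist(r2$cm[c("tp", "fp", "fn", "tn")]),
               c(tp = 35, fp = 0, fn = 1, tn = 16))
  r3 <- metrics_from_rates(100, 100, 10, 10)
  expect_equal(r3$metrics$estimate[r3$metrics$metric == "accuracy"], 100)
})

test_that("rates round-trip through reconstruction to one decimal place", {
  set.seed(7)
  for (k in 1:20) {
    np <- sample(5:60, 1); nn <- sample(5:60, 1)
    tp <- sample(0:np, 1); tn <- sample(0:nn, 1)
    sens <- round(100 * tp / np, 1); spec <- round(100 * tn / nn, 1)
    r <- metrics_from_rates(sens, spec, np, nn)
    expect_equal(r$cm$tp, tp)
    expect_equal(r$cm$tn, tn)
    est <- setNames(r$metrics$estimate, r$metrics$metric)
    expect_equal(round(est[["sensitivity"]], 1), sens)
    expect_equal(round(est[["specificity"]], 1), spec)
  }
})

test_that("Lin's concordance matches hand evaluation and its bounds", {
  expect_equal(ccc(1:10, 1:10)$estimate, 1.0)
  expect_equal(ccc(c(1, 2, 3), c(2, 3, 4))$estimate, 4 / 7)
  expect_equal(ccc(c(1, 2, 3, 4), c(2, 2, 2, 2))$estimate, 0)
  expect_error(ccc(rep(1, 5), rep(2, 5)), "variance")
  # |CCC| <= |r| and symmetry, over random pairs
  set.seed(12)
  for (k in 1:25) {
    x <- rnorm(20); y <- rnorm(20) + 0.5 * x
    ci <- ccc(x, y)
    expect_lte(abs(ci$estimate), abs(cor(x, y)) + 1e-12)
    expect_equal(ci$estimate, ccc(y, x)$estimate)
    expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
  }
})

test_that("BCa bootstrap CCC differences behave at the identities", {
  set.seed(3)
  out <- rnorm(40) + 5
  noise <- rnorm(40)
  d0 <- ccc_difference(out, out, out + rnorm(40, 0, 0.2),
                       n_boot = 400, seed = 11)
  expect_equal(d0$delta, 0)
  expect_true(d0$lower <= 0 && 0 <= d0$upper)
  d1 <- ccc_difference(out, out, out + rnorm(40, 0, 0.2),
                       n_boot = 400, seed = 11)
  expect_identical(c(d0$lower, d0$upper), c(d1$lower, d1$upper))
})

test_that("Firth fit equals the add-half closed form on a 2x2 table", {
  x1 <- rep(c(1, 1, 0, 0), c(4, 6, 2, 8))
  y <- rep(c(1, 0, 1, 0), c(4, 6, 2, 8))
  X <- cbind(intercept = 1, exposure = x1)
  fit <- firth_logistic(X, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$odds_ratio[2]), (4.5 * 8.5) / (6.5 * 2.5),
               tolerance = 1e-4)
  # independent penalized-likelihood maximizer (Nelder-Mead on a
  # separately coded objective)
  penll <- function(b) {
    eta <- X %*% b
    p <- 1 / (1 + exp(-eta))
    W <- diag(as.vector(p * (1 - p)))
    sum(y * log(p) + (1 - y) * log(1 - p)) +
      0.5 * log(det(t(X) %*% W %*% X))
  }
  opt <- optim(c(0, 0), function(b) -penll(b),
               control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(unname(fit$coefficients), opt$par, tolerance = 1e-4)
  # symmetric table: odds ratio exactly 1
  xs <- rep(c(1, 1, 0, 0), each = 5)
  ys <- rep(c(1, 0, 1, 0), each = 5)
  fs <- firth_logistic(cbind(1, xs), ys)
  expect_equal(unname(fs$odds_ratio[2]), 1.0, tolerance = 1e-8)
})

test_that("Firth estimates stay finite under complete separation", {
  x <- rep(c(0, 1), each = 10)
  y <- x  # all events in the exposed group
  fit <- firth_logistic(cbind(intercept = 1, x = x), y)
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(all(is.finite(fit$se)))
  # interior maximum confirmed by an independent optimizer
  X <- cbind(1, x)
  penll <- function(b) {
    p <- 1 / (1 + exp(-(X %*% b)))
    W <- diag(as.vector(p * (1 - p)))
    sum(y * log(p) + (1 - y) * log(1 - p)) +
      0.5 * log(det(t(X) %*% W %*% X))
  }
  opt <- optim(c(0, 0), function(b) -penll(b),
               control = list(reltol = 1e-14, maxit = 5000))
  expect_equal(unname(fit$coefficients), opt$par, tolerance = 1e-3)
})

test_that("Firth estimates approach the MLE as counts scale up", {
  x1 <- rep(c(1, 1, 0, 0), 100 * c(4, 6, 2, 8))
  y <- rep(c(1, 0, 1, 0), 100 * c(4, 6, 2, 8))
  fit <- firth_logistic(cbind(intercept = 1, exposure = x1), y)
  ml <- glm(y ~ x1, family = binomial())
  expect_equal(unname(fit$coefficients[2]), unname(coef(ml)[2]),
               tolerance = 0.01)
})

test_that("Firth rejects rank-deficient designs and non-binary outcomes", {
  expect_error(firth_logistic(cbind(1, c(1, 2, 3), c(2, 4, 6)),
                              c(0, 1, 0)), "rank deficient")
  expect_error(firth_logistic(cbind(1, 1:4), c(0, 1, 2, 1)), "binary")
})

test_that("McNemar test handles discordance and the exact small-sample path", {
  actual <- rep(TRUE, 30)
  fa <- rep(TRUE, 30); fb <- rep(TRUE, 30)
  expect_equal(mcnemar_paired(fa, fb, actual)$p_value, 1)
  # b = 10 (a right, b wrong), c = 2
  fb[1:10] <- FALSE; fa[11:12] <- FALSE
  res <- mcnemar_paired(fa, fb, actual)
  expect_equal(res$statistic, 16 / 3)
  expect_equal(res$method, "exact_binomial")  # 12 discordant < 25
  # large-sample chi-squared path agrees with stats::mcnemar.test
  set.seed(5)
  a2 <- rbinom(200, 1, 0.5) == 1
  b2 <- rbinom(200, 1, 0.5) == 1
  act <- rbinom(200, 1, 0.5) == 1
  res2 <- mcnemar_paired(a2, b2, act)
  ref <- mcnemar.test(table(a2 == act, b2 == act), correct = FALSE)
  expect_equal(res2$p_value, ref$p.value, tolerance = 1e-12)
  # tiny discordance: exact branch
  fa3 <- rep(TRUE, 30); fb3 <- rep(TRUE, 30); fb3[1:4] <- FALSE
  expect_equal(mcnemar_paired(fa3, fb3, actual)$method,
               "exact_binomial")
})

test_that("DeLong AUCs equal the brute-force pairwise count", {
  set.seed(9)
  actual <- c(rep(TRUE, 10), rep(FALSE, 10))
  sa <- rnorm(20) + actual
  sb <- round(rnorm(20), 0)  # ties exercised
  res <- delong_test(sa, sb, actual)
  expect_equal(res$auc_a, auc_bruteforce(sa, actual))
  expect_equal(res$auc_b, auc_bruteforce(sb, actual))
  expect_equal(delong_test(sa, sa, actual)$p_value, 1)
  perfect <- as.numeric(actual)
  expect_equal(delong_test(perfect, sb, actual)$auc_a, 1.0)
  expect_error(delong_test(sa, sb, rep(TRUE, 20)), "both outcome")
})

test_that("weighted kappa matches direct formula evaluation", {
  expect_equal(weighted_kappa(c(1, 2, 3, 1), c(1, 2, 3, 1)), 1.0)
  # 10 paired ratings over 3 categories, one off-by-one disagreement
  a <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 3)
  b <- c(1, 1, 1, 2, 2, 2, 3, 3, 3, 2)
  direct <- function(w_fun) {
    obs <- table(factor(a, 1:3), factor(b, 1:3)) / 10
    expc <- outer(rowSums(obs), colSums(obs))
    w <- w_fun(abs(outer(1:3, 1:3, "-")) / 2)
    1 - sum(w * obs) / sum(w * expc)
  }
  expect_equal(weighted_kappa(a, b, "quadratic"),
               direct(function(d) d^2))
  expect_equal(weighted_kappa(a, b, "linear"), direct(identity))
  # independent uniform ratings: kappa near zero
  set.seed(2)
  ra <- sample(1:4, 20000, TRUE); rb <- sample(1:4, 20000, TRUE)
  expect_lt(abs(weighted_kappa(ra, rb)), 0.05)
  expect_error(weighted_kappa(integer(0), integer(0)), "n >= 2")
})

test_that("exact binomial intervals achieve nominal coverage", {
  set.seed(123)
  x <- rbinom(10000, 16, 0.6)
  lo <- 100 * qbeta(0.025, x, 16 - x + 1)
  hi <- 100 * ifelse(x == 16, 1, qbeta(0.975, x + 1, 16 - x))
  lo[x == 0] <- 0
  covered <- mean(lo <= 60 & 60 <= hi)
  expect_gte(covered, 0.95)
})

test_that("univariable screening keeps only significant predictors", {
  set.seed(44)
  n <- 120
  good <- rnorm(n)
  y <- rbinom(n, 1, plogis(2 * good))
  noise <- rnorm(n)
  kept <- screen_predictors(data.frame(good = good, noise = noise), y)
  expect_true("good" %in% kept)
  expect_false("noise" %in% kept)
})
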