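# Independent oracles used by several test files.

# Clause-by-clause transcription of the collateral perfusion grading
# table: every clause is evaluated independently and the highest
# matching score wins (the documented precedence of the score-3 clause
# over score 2 falls out of taking the maximum).
score_oracle <- function(cap, ev, lv, small_max = 0) {
  small <- function(k) k <= small_max
  matches <- c(
    `5` = small(cap),
    `4` = cap <= 4 && small(ev),
    `3` = (cap <= 4 && ev <= 4) || (cap >= 5 && small(ev)),
    `2` = cap >= 5 && ev <= 4,
    `1` = ev >= 5 && lv <= 4,
    `0` = lv >= 5)
  if (!any(matches)) stop("no clause matched")
  max(as.integer(names(matches)[matches]))
}

# O(n^2) Mann-Whitney AUC with ties counting one half
auc_bruteforce <- function(scores, actual) {
  pos <- scores[actual]; neg <- scores[!actual]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# independent scalar transcription of the bolus curve formula
gamma_oracle <- function(t, t0, alpha, beta, amplitude) {
  if (t <= t0) return(0)
  tp <- alpha * beta
  amplitude * ((t - t0) / tp)^alpha * exp(alpha * (1 - (t - t0) / tp))
}

# small fast phantom grid used throughout the tests
test_grid <- c(32L, 32L, 16L)
test_phantom_config <- function(...) {
  phantom_config(grid_shape = test_grid, ...)
}
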