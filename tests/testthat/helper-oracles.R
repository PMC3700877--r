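# Brute-force oracles: exhaustive enumeration over all multinomial library
# outcomes (feasible for n <= 6, L <= 8).  These stay independent of the
# package's class-based computations.

# all compositions of L over n+1 cells (variants + stop class)
all_libraries <- function(L, ncells) {
  satmut:::compositions_capped(L, rep(L, ncells))
}

# exhaustive expected coverage, full-coverage probability and expected best
oracle_library_metrics <- function(p, p_stp, L, F = NULL) {
  n <- length(p)
  libs <- all_libraries(L, n + 1L)
  prob <- apply(libs, 1L, function(x) dmultinom(x, prob = c(p, p_stp)))
  present <- libs[, seq_len(n), drop = FALSE] > 0
  ncov <- rowSums(present)
  out <- list(
    expected_coverage = sum(prob * ncov) / n,
    full_coverage = sum(prob[ncov == n])
  )
  if (!is.null(F)) {
    any_fun <- ncov > 0
    best <- apply(present, 1L, function(pr) if (any(pr)) max(F[pr]) else NA_real_)
    out$expected_best_cond <- sum(prob[any_fun] * best[any_fun]) / sum(prob[any_fun])
  }
  out
}

# top-k probability by direct averaging over raw k-subsets (not classes)
oracle_top_k <- function(p, p_stp, k, L) {
  n <- length(p)
  subs <- utils::combn(n, k)
  vals <- apply(subs, 2L, function(K) (1 - sum(p[K]))^L)
  1 - mean(vals)
}

# naive Monte-Carlo estimate of E[F_v* | >= 1 functional] for one landscape
naive_best_mc <- function(p, p_stp, F, L, draws) {
  acc <- numeric(0)
  for (i in seq_len(draws)) {
    x <- rmultinom(1L, L, c(p, p_stp))[, 1]
    pres <- which(x[seq_along(p)] > 0)
    if (length(pres)) acc <- c(acc, max(F[pres]))
  }
  acc
}
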