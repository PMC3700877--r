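#' Expected library coverage
#'
#' Expected fraction of variant space represented in a library of `L` clones
#' drawn multinomially (stop-codon clones occupy library slots):
#' `E(|V|/n) = (1/n) * sum_v (1 - (1 - p_v)^L)`.
#'
#' @param space A `variant_space`.
#' @param L Library size (vector of nonnegative integers allowed).
#' @return Expected coverage in `[0, 1]`, one value per element of `L`.
#' @examples
#' expected_coverage(build_variant_space("NNK", M = 2), L = 1000)
#' @export
expected_coverage <- function(space, L) {
  stopifnot(inherits(space, "variant_space"), all(L >= 0))
  q <- space$classes$p
  nc <- space$classes$count
  vapply(L, function(l) sum(nc * (1 - (1 - q)^l)) / space$n, numeric(1))
}

## Bonferroni level sum B_j over equal-probability classes:
## B_j = sum over (k_c), sum k_c = j, of prod(choose(n_c, k_c)) * (1 - sum k_c q_c)^L
.bonferroni_level <- function(j, q, nc, L) {
  comp <- compositions_capped(j, nc)
  if (!nrow(comp)) return(0)
  lw <- numeric(nrow(comp))
  for (c in seq_along(nc)) lw <- lw + lchoose(nc[c], comp[, c])
  miss <- pmax(0, 1 - as.numeric(comp %*% q))
  sum(ifelse(miss > 0, exp(lw + L * log(miss)), ifelse(L == 0, exp(lw), 0)))
}

#' Probability of full coverage
#'
#' Probability that every variant in variant space appears at least once in a
#' multinomial library of `L` clones, computed by inclusion-exclusion over
#' the "variant v missing" events, organized by equal-probability classes:
#' `P(miss) = sum_j (-1)^(j+1) B_j` with
#' `B_j = sum_{(k_c): sum k_c = j} prod_c C(n_c, k_c) (1 - sum_c k_c q_c)^L`.
#'
#' Three evaluation methods are available.  `"exact"` enumerates every term
#' (feasible only when `prod(n_c + 1)` is below `term_cap`).  `"truncated"`
#' sums Bonferroni levels `j = 1, 2, ...` until the level falls below `tol`;
#' the alternating partial sums bracket the exact value, so the returned
#' `error_bound` is rigorous.  `"independent"` uses the independence
#' approximation `prod_v (1 - (1 - p_v)^L)`, which is smooth, monotone and
#' accurate to well under a percent at the library sizes where full coverage
#' becomes likely.  `"auto"` picks `exact` for small spaces and `truncated`
#' otherwise.
#'
#' @param space A `variant_space`.
#' @param L Library size (single nonnegative integer).
#' @param method One of `"auto"`, `"exact"`, `"truncated"`, `"independent"`.
#' @param term_cap Maximum number of enumerated terms for `"exact"`.
#' @param tol Truncation tolerance for `"truncated"` (absolute, on the
#'   missing-probability scale).
#' @param max_level Maximum Bonferroni depth for `"truncated"`.
#' @return A list of class `coverage_prob`: `probability`, `method`,
#'   `error_bound` (half-width of the bracketing interval; 0 for exact),
#'   `converged`.
#' @examples
#' vs <- build_variant_space("NNK", M = 2)
#' full_coverage_probability(vs, 8128)$probability  # about 0.95
#' @export
full_coverage_probability <- function(space, L,
                                      method = c("auto", "exact", "truncated", "independent"),
                                      term_cap = 2e6, tol = 1e-12, max_level = 120L) {
  method <- match.arg(method)
  stopifnot(inherits(space, "variant_space"), length(L) == 1L, L >= 0)
  q <- space$classes$p
  nc <- space$classes$count
  n <- space$n

  mk <- function(prob, meth, bound = 0, conv = TRUE) {
    structure(list(probability = prob, method = meth,
                   error_bound = bound, converged = conv),
              class = "coverage_prob")
  }
  if (method == "independent") {
    val <- exp(sum(nc * log1p(-pmin(1, (1 - q)^L))))
    return(mk(val, "independent"))
  }
  if (method == "auto")
    method <- if (prod(nc + 1) <= term_cap) "exact" else "truncated"
  if (L < n) return(mk(0, method))  # fewer clones than variants

  if (method == "exact") {
    if (prod(nc + 1) > term_cap)
      stopf("exact inclusion-exclusion needs %.3g terms, above term_cap = %.3g; use method 'truncated'",
            prod(nc + 1), term_cap)
    grid <- as.matrix(do.call(expand.grid, lapply(nc, function(m) 0:m)))
    k <- rowSums(grid)
    lw <- numeric(nrow(grid))
    for (c in seq_along(nc)) lw <- lw + lchoose(nc[c], grid[, c])
    miss <- pmax(0, 1 - as.numeric(grid %*% q))
    term <- ifelse(miss > 0, exp(lw + L * log(miss)), ifelse(k == 0, 1, 0))
    return(mk(max(0, min(1, sum((-1)^k * term))), "exact"))
  }

  ## truncated Bonferroni on P(at least one variant missing)
  s_odd <- Inf; s_even <- 0   # upper/lower partial sums of P(miss)
  s <- 0; sign <- 1; bound <- Inf; conv <- FALSE
  for (j in seq_len(max_level)) {
    Bj <- .bonferroni_level(j, q, nc, L)
    s <- s + sign * Bj
    if (sign > 0) s_odd <- s else s_even <- s
    sign <- -sign
    if (Bj <= tol) { bound <- Bj; conv <- TRUE; break }
    if (is.finite(s_odd) && s_odd - max(s_even, 0) <= tol) {
      bound <- (s_odd - max(s_even, 0)) / 2; conv <- TRUE; break
    }
  }
  lo_miss <- max(s_even, 0)
  hi_miss <- min(if (is.finite(s_odd)) s_odd else 1, 1)
  pm <- (lo_miss + hi_miss) / 2
  if (!conv) bound <- (hi_miss - lo_miss) / 2
  mk(max(0, min(1, 1 - pm)), "truncated", bound = bound, conv = conv)
}

#' @export
print.coverage_prob <- function(x, ...) {
  cat(sprintf("P(full coverage) = %.8g  [method %s, error bound %.3g%s]\n",
              x$probability, x$method, x$error_bound,
              if (!x$converged) ", NOT converged" else ""))
  invisible(x)
}

#' Probability of discovering a top-k variant
#'
#' Probability of the event `T_k` that the library contains at least one of
#' the `k` highest-fitness variants of variant space, under the assumption
#' that the fitness ranking is uniform over all `n!` orderings (no variant is
#' a priori better than another):
#' `P(T_k) = 1 - mean over k-subsets K of (1 - sum_{v in K} p_v)^L`.
#' The subset average is computed exactly by enumerating per-class selection
#' counts with hypergeometric weights; for `k` above `max_exact_k` the
#' average falls back to Monte-Carlo subset sampling (reported standard
#' error in attribute `"se"`).
#'
#' @param space A `variant_space`.
#' @param k Number of top variants considered a success (1 <= k <= n).
#' @param L Library size.
#' @param max_exact_k Largest `k` handled by exact class enumeration.
#' @param mc_subsets Number of Monte-Carlo subsets beyond that.
#' @param seed Seed for the Monte-Carlo fallback.
#' @return `P(T_k)` as a numeric scalar (attributes `method`, and `se` when
#'   Monte Carlo is used).
#' @examples
#' vs <- build_variant_space("NNK", M = 2)
#' top_k_probability(vs, k = 2, L = 500)
#' @export
top_k_probability <- function(space, k, L, max_exact_k = 5L,
                              mc_subsets = 20000L, seed = 1L) {
  stopifnot(inherits(space, "variant_space"))
  n <- space$n
  if (k < 1 || k > n) stopf("k must lie in 1..n = %d", n)
  q <- space$classes$p
  nc <- space$classes$count
  if (k <= max_exact_k || length(q) == 1L) {
    comp <- compositions_capped(k, nc)
    lw <- numeric(nrow(comp))
    for (c in seq_along(nc)) lw <- lw + lchoose(nc[c], comp[, c])
    lw <- lw - lchoose(n, k)
    miss <- pmax(0, 1 - as.numeric(comp %*% q))
    val <- 1 - sum(exp(lw) * miss^L)
    return(structure(max(0, min(1, val)), method = "exact"))
  }
  set.seed(seed)
  s <- vapply(seq_len(mc_subsets), function(i)
    sum(space$p[sample.int(n, k)]), numeric(1))
  x <- pmax(0, 1 - s)^L
  structure(max(0, min(1, 1 - mean(x))), method = "monte-carlo",
            se = sd(x) / sqrt(mc_subsets))
}

#' Minimal library size reaching a coverage target
#'
#' Smallest integer `L` for which the chosen metric reaches `alpha`:
#' the probability of full coverage (`"full"`), the expected coverage
#' (`"expected"`), or the top-k discovery probability `P(T_k)` (`"topk"`).
#' All three metrics are nondecreasing in `L`, so the crossing is located by
#' exponential bracketing followed by integer bisection.  For the full-
#' coverage metric on large spaces the bracketing runs on the independence
#' approximation and the crossing is then refined with the truncated
#' inclusion-exclusion (rigorous near the crossing, where the Bonferroni
#' series converges fast).
#'
#' @param space A `variant_space`.
#' @param metric `"full"`, `"expected"`, or `"topk"`.
#' @param alpha Target level in (0, 1).
#' @param k Top-k parameter (metric `"topk"` only).
#' @param term_cap Passed to [full_coverage_probability()].
#' @return A list of class `libsize`: `L`, `metric_at_L`,
#'   `metric_at_L_minus_1`, `metric`, `alpha`, `method`.
#' @examples
#' min_library_size(manual_variant_space(c(0.5, 0.5)),
#'                  metric = "expected", alpha = 0.74)$L  # 2
#' @export
min_library_size <- function(space, metric = c("full", "expected", "topk"),
                             alpha, k = 1L, term_cap = 2e6) {
  metric <- match.arg(metric)
  stopifnot(inherits(space, "variant_space"))
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must lie strictly in (0, 1)")

  f_cheap <- switch(metric,
    expected = function(L) expected_coverage(space, L),
    topk = function(L) as.numeric(top_k_probability(space, k, L)),
    full = {
      exact_ok <- prod(space$classes$count + 1) <= term_cap
      if (exact_ok)
        function(L) full_coverage_probability(space, L, method = "exact",
                                              term_cap = term_cap)$probability
      else
        function(L) full_coverage_probability(space, L,
                                              method = "independent")$probability
    })

  bisect <- function(f) {
    hi <- 1L
    while (f(hi) < alpha) {
      hi <- hi * 2L
      if (hi > 2^40) stopf("library size bracketing exceeded 2^40; metric cannot reach alpha")
    }
    lo <- hi %/% 2L
    if (hi == 1L) return(1L)
    while (hi - lo > 1L) {
      mid <- lo + (hi - lo) %/% 2L
      if (f(mid) >= alpha) hi <- mid else lo <- mid
    }
    hi
  }

  L0 <- bisect(f_cheap)
  method <- if (metric == "full") {
    if (prod(space$classes$count + 1) <= term_cap) "exact" else "independent"
  } else "exact"

  if (metric == "full" && method == "independent") {
    ## refine the independence-approximation crossing with the rigorous
    ## truncated inclusion-exclusion in a +/-5% window
    f_tr <- function(L) full_coverage_probability(space, L,
                                                  method = "truncated")$probability
    lo <- max(space$n, floor(0.95 * L0)); hi <- ceiling(1.05 * L0)
    while (f_tr(hi) < alpha) { lo <- hi; hi <- ceiling(1.05 * hi) }
    while (f_tr(lo) >= alpha && lo > space$n) { hi <- lo; lo <- max(space$n, floor(0.95 * lo)) }
    while (hi - lo > 1L) {
      mid <- lo + (hi - lo) %/% 2L
      if (f_tr(mid) >= alpha) hi <- mid else lo <- mid
    }
    L0 <- hi
    method <- "truncated"
    f_cheap <- f_tr
  }

  out <- list(L = L0, metric_at_L = f_cheap(L0),
              metric_at_L_minus_1 = if (L0 > 1) f_cheap(L0 - 1L) else 0,
              metric = metric, alpha = alpha, method = method, k = k)
  class(out) <- "libsize"
  out
}

#' @export
print.libsize <- function(x, ...) {
  cat(sprintf("Minimal library size for %s >= %.4g: L = %d (metric %.6g at L, %.6g at L-1; method %s)\n",
              x$metric, x$alpha, x$L, x$metric_at_L, x$metric_at_L_minus_1, x$method))
  invisible(x)
}
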