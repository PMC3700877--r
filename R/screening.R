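#' Expected best discovered fitness, given a landscape
#'
#' For a fixed landscape, the library is a multinomial draw of `L` clones
#' over the variants and the stop class, and the quantity of interest is the
#' fitness of the best variant represented.  Sorting variants by fitness
#' (descending, stable index tie-break) and writing `S_j` for the cumulative
#' sampling probability of the top `j` variants, the distribution of the
#' best-present rank telescopes:
#' `P(best present has rank j) = (1 - S_{j-1})^L - (1 - S_j)^L`, so the
#' expectation needs only one pass over the sorted variants.  Because a
#' library may consist entirely of nonsense clones (probability
#' `p_stp^L`), the expectation is reported conditional on at least one
#' functional clone, with the conditioning probability returned alongside.
#'
#' @param landscape A `fitness_landscape` (or a list with elements `space`
#'   and `F`).
#' @param L Library size(s), each >= 1.
#' @return A list: `e_best` (conditional expectation per `L`),
#'   `p_all_stop` (`p_stp^L`), and `e_best_unconditional` (the
#'   contribution-weighted sum without conditioning, i.e. treating an
#'   all-stop library as contributing 0).
#' @examples
#' toy <- manual_variant_space(c(0.5, 0.5))
#' ls <- sample_landscape(toy, fixed_model(c(0, 1)))
#' expected_best_given_landscape(ls, L = 2)$e_best  # 0.75
#' @export
expected_best_given_landscape <- function(landscape, L) {
  space <- landscape$space
  F <- landscape$F
  stopifnot(length(F) == space$n)
  if (any(L < 1)) stopf("L must be >= 1")
  o <- order(F, decreasing = TRUE, method = "radix")
  Fs <- F[o]
  Tl <- 1 - cumsum(space$p[o])
  Tl <- pmax(Tl, 0)
  Tl[space$n] <- space$p_stp
  Tprev <- c(1, Tl[-space$n])
  ev <- function(l) {
    w <- Tprev^l - Tl^l
    tot <- sum(Fs * w)
    list(u = tot, c = tot / (1 - space$p_stp^l), s = space$p_stp^l)
  }
  res <- lapply(L, ev)
  list(e_best = vapply(res, `[[`, numeric(1), "c"),
       p_all_stop = vapply(res, `[[`, numeric(1), "s"),
       e_best_unconditional = vapply(res, `[[`, numeric(1), "u"))
}

## Precomputed per-replication order statistics for fast curve evaluation.
## sF: n x R fitness values sorted descending per replication;
## Tl: n x R tail probabilities 1 - S_j (last row = p_stp).
.curve_engine <- function(Fmat, p, p_stp) {
  n <- nrow(Fmat); R <- ncol(Fmat)
  sF <- matrix(0, n, R); Tl <- matrix(0, n, R)
  for (r in seq_len(R)) {
    o <- order(Fmat[, r], decreasing = TRUE, method = "radix")
    sF[, r] <- Fmat[o, r]
    Tl[, r] <- 1 - cumsum(p[o])
  }
  Tl <- pmax(Tl, 0)
  Tl[n, ] <- p_stp
  e_single <- colSums(Fmat * p) / (1 - p_stp)
  list(sF = sF, Tl = Tl, p_stp = p_stp, n = n, R = R,
       e_single_r = e_single, e_global_r = sF[1, ])
}

## per-replication conditional expectation of the best discovered fitness at L
.engine_eval <- function(eng, L, cols = NULL) {
  sF <- eng$sF; Tl <- eng$Tl
  if (!is.null(cols)) { sF <- sF[, cols, drop = FALSE]; Tl <- Tl[, cols, drop = FALSE] }
  P <- Tl^L
  W <- rbind(rep(1, ncol(P)), P[-nrow(P), , drop = FALSE]) - P
  colSums(sF * W) / (1 - eng$p_stp^L)
}

.default_grid <- function(Lmax) {
  g <- unique(c(1L, round(10^(seq(0, log10(Lmax), by = 0.04)))))
  as.integer(g[g >= 1])
}

#' Monte-Carlo screening curve
#'
#' Estimates the expected fitness of the best variant discovered,
#' `E[F_v*]`, as a function of the library size `L`, under a generative
#' landscape model: an outer Monte Carlo over landscape replications
#' combined with the exact inner expectation over multinomial library
#' sampling ([expected_best_given_landscape()]).  The exact inner
#' expectation removes one simulation layer, so thousands of replications
#' evaluate in seconds and the only standard error reported is the
#' between-landscape one.  Expectations are conditional on the library
#' containing at least one functional (stop-free) clone; the conditioning
#' probability is reported per `L` as `cond_prob`.
#'
#' The default grid is geometric (25 points per decade, starting at
#' `L = 1`) and is extended automatically until the curve brackets the
#' 95-percent-of-gap threshold used by [find_lstar95()].
#'
#' @param space A `variant_space`.
#' @param model A `landscape_model`.
#' @param L_grid Increasing integer grid (default: auto).
#' @param reps Number of landscape replications (>= 2).
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `screening_curve`: `L_grid`, `e_best`, `se`,
#'   `cond_prob`, `e_single`, `e_best_global` (with standard errors),
#'   `reps`, `seed`, `model`, plus internal per-replication state reused by
#'   [find_lstar95()].
#' @examples
#' vs <- build_variant_space("NNK", M = 2)
#' sc <- screening_curve(vs, nk_model(24, 6, overlap = 6), reps = 200, seed = 1)
#' @export
screening_curve <- function(space, model, L_grid = NULL, reps = 5000L, seed = 1L) {
  stopifnot(inherits(space, "variant_space"), inherits(model, "landscape_model"))
  if (reps < 2) stopf("need at least 2 landscape replications")
  set.seed(seed)
  Fmat <- .sample_F_matrix(space, model, reps)
  eng <- .curve_engine(Fmat, space$p, space$p_stp)

  e_single <- mean(eng$e_single_r)
  e_global <- mean(eng$e_global_r)
  threshold <- e_single + 0.95 * (e_global - e_single)

  if (is.null(L_grid)) {
    Lmax <- 1e4
    repeat {
      L_grid <- .default_grid(Lmax)
      top <- mean(.engine_eval(eng, max(L_grid)))
      if (top >= threshold || Lmax >= 1e9) break
      Lmax <- Lmax * 10
    }
  } else {
    L_grid <- as.integer(sort(unique(L_grid)))
    if (any(L_grid < 1)) stopf("L_grid must contain integers >= 1")
  }

  per <- vapply(L_grid, function(l) .engine_eval(eng, l), numeric(reps))
  per <- matrix(per, nrow = reps)
  e_best <- colMeans(per)
  se <- apply(per, 2L, sd) / sqrt(reps)

  out <- list(L_grid = L_grid, e_best = e_best, se = se,
              cond_prob = 1 - space$p_stp^L_grid,
              e_single = e_single, e_single_se = sd(eng$e_single_r) / sqrt(reps),
              e_best_global = e_global,
              e_best_global_se = sd(eng$e_global_r) / sqrt(reps),
              reps = reps, seed = seed, model = model,
              n = space$n, p_stp = space$p_stp,
              percurve = per, engine = eng)
  class(out) <- "screening_curve"
  out
}

#' @export
print.screening_curve <- function(x, ...) {
  cat(sprintf("Screening curve (%s model, %d reps, seed %d): %d grid points in [%d, %d]\n",
              x$model$name, x$reps, x$seed, length(x$L_grid),
              min(x$L_grid), max(x$L_grid)))
  cat(sprintf("  E[F at L=1] = %.5g (se %.2g); E[global best] = %.5g (se %.2g)\n",
              x$e_single, x$e_single_se, x$e_best_global, x$e_best_global_se))
  invisible(x)
}

#' @method as.data.frame screening_curve
#' @export
as.data.frame.screening_curve <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(L = x$L_grid, e_best = x$e_best, se = x$se,
             cond_prob = x$cond_prob)
}

## crossing of a monotone grid curve with a threshold, log-linear in L
.interp_crossing <- function(L, y, th) {
  i <- which(y >= th)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1) return(L[1])
  x0 <- log(L[i - 1]); x1 <- log(L[i])
  exp(x0 + (x1 - x0) * (th - y[i - 1]) / (y[i] - y[i - 1]))
}

#' 95-percent-of-gap library size
#'
#' The library size at which the expected best discovered fitness reaches
#' `level` (default 95 percent) of the gap between its value at `L = 1`
#' (a single randomized clone, the lowest point of the curve) and the
#' expected fitness of the global optimum of variant space.  The crossing is
#' bracketed on the curve's grid and then refined to the exact minimal
#' integer by re-evaluating the per-landscape inner expectation (integer
#' bisection), so the result does not depend on grid resolution.  A bootstrap
#' confidence interval over landscape replications is attached (grid-based,
#' log-linear interpolation).
#'
#' Because the threshold is defined through a gap, the result is invariant
#' to adding a constant to all fitness values.
#'
#' @param curve A `screening_curve`.
#' @param level Fraction of the gap to reach (default 0.95).
#' @param boot Number of bootstrap resamples (0 to skip).
#' @param boot_seed Seed for the bootstrap resampling.
#' @return A list of class `lstar`: `l_star`, `threshold`, `level`, `ci`
#'   (2.5/97.5 percent bootstrap interval), `boot`, `e_single`,
#'   `e_best_global`.
#' @export
find_lstar95 <- function(curve, level = 0.95, boot = 200L, boot_seed = 1L) {
  stopifnot(inherits(curve, "screening_curve"))
  eng <- curve$engine
  threshold <- curve$e_single + level * (curve$e_best_global - curve$e_single)
  L <- curve$L_grid
  y <- curve$e_best
  if (max(y) < threshold)
    stopf("curve does not reach the %.0f%%-of-gap threshold at L = %d; extend L_grid",
          100 * level, max(L))
  i <- which(y >= threshold)[1]
  hi <- L[i]
  lo <- if (i == 1) 1L else L[i - 1]
  f <- function(l) mean(.engine_eval(eng, l))
  if (lo == hi || f(1) >= threshold) {
    l_star <- if (f(1) >= threshold) 1L else hi
  } else {
    while (hi - lo > 1L) {
      mid <- lo + (hi - lo) %/% 2L
      if (f(mid) >= threshold) hi <- mid else lo <- mid
    }
    l_star <- hi
  }

  ci <- c(NA_real_, NA_real_)
  if (boot > 0) {
    set.seed(boot_seed)
    bs <- numeric(boot)
    for (b in seq_len(boot)) {
      idx <- sample.int(curve$reps, replace = TRUE)
      es <- mean(eng$e_single_r[idx])
      eg <- mean(eng$e_global_r[idx])
      th_b <- es + level * (eg - es)
      yb <- colMeans(curve$percurve[idx, , drop = FALSE])
      bs[b] <- .interp_crossing(L, yb, th_b)
    }
    ci <- unname(quantile(bs, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(l_star = l_star, threshold = threshold, level = level,
                 ci = ci, boot = boot, e_single = curve$e_single,
                 e_best_global = curve$e_best_global),
            class = "lstar")
}

#' @export
print.lstar <- function(x, ...) {
  cat(sprintf("L*%d = %d (threshold %.5g between E[F at L=1] = %.5g and E[global best] = %.5g)\n",
              round(100 * x$level), x$l_star, x$threshold, x$e_single, x$e_best_global))
  if (x$boot > 0)
    cat(sprintf("  %d-resample bootstrap 95%% CI: [%.1f, %.1f]\n",
                x$boot, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Distribution of percent fitness loss
#'
#' The percent fitness loss of an experiment is
#' `Lambda = 100 * (1 - raw_best_discovered / raw_global_best)`, the
#' shortfall of the best discovered variant relative to the best variant in
#' variant space, on the raw fitness scale (for models on a log scale the
#' ratio is `exp(F_best_discovered - F_global_best)`); it lies in
#' `[0, 100]`, with 0 meaning the global best was found.  Unlike the
#' expected-best curve, `Lambda` is a distribution over both landscape and
#' library randomness, so each replication samples one landscape and one
#' multinomial library of size `L`.  Replications whose library contains no
#' functional clone are flagged (`functional_found = FALSE`, `lambda = NA`)
#' rather than dropped.
#'
#' With `scale = "transformed"` the loss is computed on the model's
#' transformed scale as `100 * (F** - F*) / F**`; this variant is only
#' meaningful when `F** > 0` and may leave `[0, 100]` (replications with
#' `F** <= 0` are flagged `NA`).
#'
#' @param space A `variant_space`.
#' @param model A `landscape_model`.
#' @param L Library size (>= 1).
#' @param reps Replications.
#' @param seed Integer seed.
#' @param scale `"raw"` (default) or `"transformed"`.
#' @return An object of class `loss_sample`: a data frame `samples`
#'   (`replication`, `lambda`, `functional_found`) plus `L`, `scale`,
#'   `seed`, `model`.
#' @examples
#' toy <- manual_variant_space(c(0.5, 0.5))
#' ld <- loss_distribution(toy, fixed_model(c(1, 2)), L = 1, reps = 500, seed = 1)
#' @export
loss_distribution <- function(space, model, L, reps = 5000L, seed = 1L,
                              scale = c("raw", "transformed")) {
  scale <- match.arg(scale)
  stopifnot(inherits(space, "variant_space"), L >= 1)
  set.seed(seed)
  Fmat <- .sample_F_matrix(space, model, reps)
  prob <- c(space$p, space$p_stp)
  lambda <- rep(NA_real_, reps)
  found <- logical(reps)
  warn_neg <- FALSE
  for (r in seq_len(reps)) {
    x <- rmultinom(1L, L, prob)[, 1]
    present <- which(x[seq_len(space$n)] > 0)
    if (!length(present)) next
    found[r] <- TRUE
    Fv <- Fmat[, r]
    fstar <- max(Fv[present])
    fss <- max(Fv)
    if (scale == "raw") {
      if (identical(model$fitness_scale, "log")) {
        lambda[r] <- 100 * (1 - exp(fstar - fss))
      } else if (fss > 0 && fstar >= 0) {
        lambda[r] <- 100 * (1 - fstar / fss)
      } else warn_neg <- TRUE
    } else {
      if (fss > 0) lambda[r] <- 100 * (fss - fstar) / fss
      else warn_neg <- TRUE
    }
  }
  if (warn_neg)
    warning("some replications had nonpositive fitness values; their loss is NA")
  structure(list(samples = data.frame(replication = seq_len(reps),
                                      lambda = lambda,
                                      functional_found = found),
                 L = L, scale = scale, seed = seed, model = model,
                 reps = reps),
            class = "loss_sample")
}

#' @export
print.loss_sample <- function(x, ...) {
  ok <- x$samples$functional_found & !is.na(x$samples$lambda)
  cat(sprintf("Fitness-loss sample at L = %d (%s scale, %d reps): median loss %.3g%%, P(loss = 0) = %.3g\n",
              x$L, x$scale, x$reps, stats::median(x$samples$lambda[ok]),
              mean(x$samples$lambda[ok] == 0)))
  if (any(!x$samples$functional_found))
    cat(sprintf("  %d replications without a functional clone\n",
                sum(!x$samples$functional_found)))
  invisible(x)
}

#' Tail probabilities of the fitness loss
#'
#' Empirical probabilities `P(Lambda >= t)` for a set of loss thresholds,
#' with binomial standard errors, computed over the replications in which a
#' functional clone was found.
#'
#' @param loss A `loss_sample`.
#' @param thresholds Loss thresholds in percent (default 5, 10, 20).
#' @return Data frame with columns `threshold`, `prob`, `se`, `n`.
#' @export
exceedance_probabilities <- function(loss, thresholds = c(5, 10, 20)) {
  stopifnot(inherits(loss, "loss_sample"))
  lam <- loss$samples$lambda[loss$samples$functional_found]
  lam <- lam[!is.na(lam)]
  if (!length(lam)) stopf("no functional replications in the loss sample")
  n <- length(lam)
  p <- vapply(thresholds, function(t) mean(lam >= t), numeric(1))
  data.frame(threshold = thresholds, prob = p,
             se = sqrt(p * (1 - p) / n), n = n)
}
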