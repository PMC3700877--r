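#' Bundle variant fitness observations for model fitting
#'
#' Container for a table of variants (amino-acid tuples over the randomized
#' positions, relative to a declared wild type) with their fitness on the
#' model's transformed scale.  Used by [novwein_loglik()] and
#' [fit_novwein_mle()].
#'
#' @param variants Character matrix (one row per variant, one column per
#'   randomized position) of amino acids.
#' @param fitness Transformed fitness per variant (the wild type, if
#'   present, should have fitness 0).
#' @param wt Wild-type amino-acid tuple (character vector, one per
#'   position).
#' @param transform Record of the transformation applied to the raw data:
#'   a list with elements `kind` (`"log"` or `"boxcox"`), optional
#'   `lambda`, and `wt_raw`.
#' @return An object of class `fitness_observations`.
#' @export
fitness_observations <- function(variants, fitness, wt,
                                 transform = list(kind = "log", wt_raw = 1)) {
  variants <- as.matrix(variants)
  mode(variants) <- "character"
  fitness <- as.numeric(fitness)
  if (nrow(variants) != length(fitness))
    stopf("variants (%d rows) and fitness (%d values) disagree",
          nrow(variants), length(fitness))
  if (length(wt) != ncol(variants))
    stopf("wild type must have %d amino acids", ncol(variants))
  key <- apply(variants, 1L, paste, collapse = "")
  if (anyDuplicated(key)) stopf("duplicate variant entries in observations")
  structure(list(variants = variants, fitness = fitness,
                 wt = as.character(wt), transform = transform),
            class = "fitness_observations")
}

#' @export
print.fitness_observations <- function(x, ...) {
  cat(sprintf("%d fitness observations over %d positions (wild type %s, %s transform)\n",
              nrow(x$variants), ncol(x$variants), paste(x$wt, collapse = ""),
              x$transform$kind %||% "?"))
  invisible(x)
}

## mean vector and covariance matrix of the observations under the model,
## excluding wild-type rows (their fitness is identically 0)
.novwein_obs_moments <- function(model, obs, var_floor = 1e-8) {
  s <- .novwein_dbc(obs$variants, obs$wt)
  keep <- s$d > 0
  vp <- max(model$var_pos, var_floor)
  va <- max(model$var_aa, var_floor)
  vn <- max(model$var_nonadd, var_floor)
  Sigma <- vp * s$B[keep, keep, drop = FALSE] +
    va * s$C[keep, keep, drop = FALSE] +
    vn * diag(sum(keep))
  list(mu = model$m * s$d[keep], Sigma = Sigma, keep = keep)
}

#' Log-likelihood of the Gaussian landscape model
#'
#' Exact multivariate-normal log-density of the observed transformed fitness
#' vector under the Gaussian random-effects landscape model, with mean and
#' covariance given by [novwein_moments()].  Wild-type rows (zero mean and
#' variance by construction) are excluded from the density with a warning.
#' Variances are floored at `var_floor` to keep the density finite in
#' degenerate corners; if the covariance Cholesky fails, a 1e-9 diagonal
#' jitter is added (with a warning) before giving up.
#'
#' @param model A `novwein_model()`.
#' @param obs A `fitness_observations`.
#' @param var_floor Lower bound applied to each variance component.
#' @return Log-likelihood (numeric scalar).
#' @export
novwein_loglik <- function(model, obs, var_floor = 1e-8) {
  stopifnot(inherits(model, "landscape_model"), model$name == "novwein",
            inherits(obs, "fitness_observations"))
  mm <- .novwein_obs_moments(model, obs, var_floor)
  if (any(!mm$keep))
    warning("wild-type observation(s) excluded from the likelihood")
  y <- obs$fitness[mm$keep] - mm$mu
  N <- length(y)
  ch <- tryCatch(chol(mm$Sigma), error = function(e) NULL)
  if (is.null(ch)) {
    warning("covariance not positive definite; adding 1e-9 jitter")
    ch <- tryCatch(chol(mm$Sigma + 1e-9 * diag(N)), error = function(e) NULL)
    if (is.null(ch)) stopf("covariance matrix not positive definite even after jitter")
  }
  z <- backsolve(ch, y, transpose = TRUE)
  -0.5 * N * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z^2)
}

#' Maximum-likelihood fit of the Gaussian landscape model
#'
#' Estimates the four parameters (drift and the three variance components)
#' by maximizing the exact Gaussian log-likelihood.  Variances are
#' log-parameterized so the optimization is unconstrained; a small
#' variance floor replaces the paper-thin boundary at zero.  The surface can
#' be multimodal, so the optimizer (Nelder-Mead, with a BFGS polish of the
#' best solution) is restarted from `n_starts` dispersed initial points
#' derived from data moments: the drift from a least-squares regression of
#' fitness on mutation count, the total variance from the residuals, split
#' randomly across the three components.
#'
#' @param obs A `fitness_observations` with at least 5 non-wild-type rows.
#' @param n_starts Number of multistart initial points.
#' @param seed Seed controlling the start dispersion (the fit is
#'   deterministic given data and seed).
#' @param fixed Optional named list pinning parameters during optimization,
#'   e.g. `list(var_pos = 0)` for a constrained fit.
#' @param var_floor Variance floor (see [novwein_loglik()]).
#' @return An object of class `novwein_fit`: `model` (the fitted
#'   `novwein_model`), `loglik`, `converged`, `n_starts`,
#'   `start_logliks`.
#' @examples
#' \donttest{
#' tab <- simulate_fitness_table(novwein_model(-0.3, 0.1, 0.1, 0.05),
#'                               wt = c("A", "A"), n_obs = 120, seed = 1)
#' obs <- fitness_observations(as.matrix(tab[, c("pos1_aa", "pos2_aa")]),
#'                             transform_fitness(tab$raw_fitness, "log"),
#'                             wt = c("A", "A"))
#' fit_novwein_mle(obs, n_starts = 4, seed = 1)
#' }
#' @export
fit_novwein_mle <- function(obs, n_starts = 8L, seed = 1L, fixed = list(),
                            var_floor = 1e-8) {
  stopifnot(inherits(obs, "fitness_observations"))
  s <- .novwein_dbc(obs$variants, obs$wt)
  keep <- s$d > 0
  if (sum(keep) < 5) stopf("need at least 5 non-wild-type observations to fit 4 parameters")
  d <- s$d[keep]
  B <- s$B[keep, keep, drop = FALSE]
  C <- s$C[keep, keep, drop = FALSE]
  F <- obs$fitness[keep]
  N <- length(F)
  I <- diag(N)

  par_names <- c("m", "var_pos", "var_aa", "var_nonadd")
  free <- setdiff(par_names, names(fixed))
  to_model <- function(theta) {
    full <- setNames(numeric(4), par_names)
    for (nm in names(fixed)) full[nm] <- fixed[[nm]]
    j <- 1L
    for (nm in free) {
      full[nm] <- if (nm == "m") theta[j] else exp(theta[j])
      j <- j + 1L
    }
    full
  }
  negll <- function(theta) {
    p <- to_model(theta)
    vp <- max(p["var_pos"], var_floor)
    va <- max(p["var_aa"], var_floor)
    vn <- max(p["var_nonadd"], var_floor)
    Sigma <- vp * B + va * C + vn * I
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    y <- F - p["m"] * d
    z <- backsolve(ch, y, transpose = TRUE)
    val <- 0.5 * N * log(2 * pi) + sum(log(diag(ch))) + 0.5 * sum(z^2)
    if (!is.finite(val)) 1e10 else val
  }

  ## data-driven dispersed starts
  set.seed(seed)
  m0 <- sum(F * d) / sum(d^2)
  s2 <- max(var(F - m0 * d), 1e-3)
  starts <- vector("list", n_starts)
  for (b in seq_len(n_starts)) {
    w <- rexp(3); w <- w / sum(w)
    full <- c(m = m0 * runif(1, 0.5, 1.5) + rnorm(1, sd = 0.05 * abs(m0) + 1e-3),
              var_pos = s2 * w[1], var_aa = s2 * w[2], var_nonadd = s2 * w[3])
    theta <- vapply(free, function(nm)
      if (nm == "m") unname(full["m"]) else log(max(full[nm], var_floor)),
      numeric(1))
    starts[[b]] <- theta
  }

  best <- NULL
  start_ll <- numeric(n_starts)
  any_conv <- FALSE
  for (b in seq_len(n_starts)) {
    o <- optim(starts[[b]], negll, method = "Nelder-Mead",
               control = list(maxit = 800, reltol = 1e-10))
    start_ll[b] <- -o$value
    if (o$convergence == 0) any_conv <- TRUE
    if (is.null(best) || o$value < best$value) best <- o
  }
  pol <- tryCatch(optim(best$par, negll, method = "BFGS",
                        control = list(maxit = 200)),
                  error = function(e) NULL)
  if (!is.null(pol) && pol$value <= best$value) {
    best <- pol
    if (pol$convergence == 0) any_conv <- TRUE
  }

  p <- to_model(best$par)
  model <- novwein_model(p[["m"]], p[["var_pos"]], p[["var_aa"]], p[["var_nonadd"]])
  structure(list(model = model, loglik = -best$value, converged = any_conv,
                 n_starts = n_starts, start_logliks = start_ll),
            class = "novwein_fit")
}

#' @export
print.novwein_fit <- function(x, ...) {
  m <- x$model
  cat(sprintf("Gaussian landscape MLE (%d starts%s): logLik = %.4f\n",
              x$n_starts, if (!x$converged) ", NOT converged" else "",
              x$loglik))
  cat(sprintf("  m = %.4g, var_pos = %.4g, var_aa = %.4g, var_nonadd = %.4g\n",
              m$m, m$var_pos, m$var_aa, m$var_nonadd))
  invisible(x)
}
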