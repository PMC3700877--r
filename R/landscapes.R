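#' Gaussian random-effects landscape model
#'
#' Four-parameter Gaussian model of the sequence-fitness relationship on a
#' transformed scale on which the wild type has fitness 0.  Each mutation
#' replacing the wild-type amino acid at position `i` by amino acid `a`
#' contributes `f[i,a] ~ Normal(mu_i, var_aa)`, where the position means
#' `mu_i` are themselves `Normal(m, var_pos)` random effects; a variant's
#' fitness is the sum of its mutation contributions plus an independent
#' `Normal(0, var_nonadd)` non-additive residual.  A negative drift `m`
#' encodes wild-type dominance (mutations hurt on average), the shared
#' position means encode clustering of favorable mutations at hotspot
#' positions, and the additive sum structure encodes (approximate)
#' additivity of mutational effects on the transformed scale.
#'
#' @param m Drift: mean per-mutation fitness effect (transformed units;
#'   typically negative).
#' @param var_pos Position variance (variance of the position means).
#' @param var_aa Amino-acid variance (spread of mutations around their
#'   position mean).
#' @param var_nonadd Non-additivity variance (per-variant residual).
#' @return A `landscape_model` of name `"novwein"`; its `fitness_scale` is
#'   `"log"` (raw fitness is recovered as `exp(F)` times the wild-type raw
#'   fitness).
#' @examples
#' novwein_model(m = -0.3, var_pos = 0.3, var_aa = 0.3, var_nonadd = 0.04)
#' @export
novwein_model <- function(m, var_pos, var_aa, var_nonadd) {
  if (any(c(var_pos, var_aa, var_nonadd) < 0)) stopf("variances must be >= 0")
  if (var_pos + var_aa + var_nonadd <= 0) stopf("at least one variance must be positive")
  structure(list(name = "novwein", m = m, var_pos = var_pos, var_aa = var_aa,
                 var_nonadd = var_nonadd, fitness_scale = "log"),
            class = "landscape_model")
}

#' NK landscape model restricted to two randomized sites
#'
#' Kauffman's NK model: a protein of `N` positions where the fitness
#' contribution of each position is a fresh `Uniform(0, 1)` value that
#' depends on the amino acids at that position and at its `K` nearest
#' flanking positions; total fitness is the average of the `N`
#' contributions.  `K` tunes ruggedness (`K = 0`: smooth and additive;
#' `K = N - 1`: all variants independent).  Here exactly two sites are
#' randomized and the remaining `N - 2` background positions are held fixed,
#' so only positions whose influence set contains a randomized site vary
#' across the variant space; the rest contribute a per-landscape constant.
#' With symmetric flanking neighborhoods on a circular sequence the number
#' of positions influenced by both sites is `max(0, K + 1 - separation)`,
#' so the `overlap` argument fixes the site separation.
#'
#' @param N Sequence length.
#' @param K Epistatic neighborhood size, `0 <= K < N`.
#' @param overlap Number of positions influenced by both randomized sites
#'   (0..K); mutually exclusive with `separation`.
#' @param separation Distance between the two randomized sites (>= 1).
#' @param topology `"circular"` (default; overlap is a pure function of
#'   separation) or `"linear"` (edge windows shifted inward to keep size
#'   `K + 1`).
#' @return A `landscape_model` of name `"nk"`; `fitness_scale` `"linear"`
#'   (fitness is already on its natural scale, in (0, 1)).
#' @examples
#' nk_model(N = 24, K = 6, overlap = 6)  # adjacent sites
#' @export
nk_model <- function(N = 24L, K = 6L, overlap = NULL, separation = NULL,
                     topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (K >= N) stopf("K must be smaller than N")
  if (is.null(separation)) {
    if (is.null(overlap)) stopf("give either 'overlap' or 'separation'")
    if (overlap < 0 || overlap > K) stopf("overlap must lie in 0..K")
    separation <- K + 1L - as.integer(overlap)
  }
  if (separation < 1) stopf("randomized sites must be distinct (separation >= 1)")
  if (topology == "circular" && N - separation < K + 1)
    stopf("N too small: the sites' influence ranges also overlap around the circle")
  structure(list(name = "nk", N = as.integer(N), K = as.integer(K),
                 separation = as.integer(separation), topology = topology,
                 fitness_scale = "linear"),
            class = "landscape_model")
}

#' Rough Mount Fuji landscape model
#'
#' Additive-plus-noise landscape: the fitness of a sequence is
#' `W_P + omega_P`, where the additive part `W_P` sums per-position
#' contributions `w_j(a) = eps * i/10` for `i = 0, 1, ..., 19` (the rank of
#' amino acid `a` at position `j`, assigned by a fresh uniform random
#' permutation per position per landscape), and `omega_P ~ Normal(0, rho^2)`
#' is an independent non-additive term per variant.  `eps < 0` is the mean
#' contribution of an "incorrect" (rank > 0) amino acid; the ratio
#' `|eps|/rho` indexes landscape smoothness.  Non-randomized positions are
#' taken to carry their rank-0 amino acid, so they contribute 0 to the
#' additive part (any other fixed background only shifts all fitness values
#' by a per-landscape constant).
#'
#' @param nu Sequence length (>= number of randomized positions).
#' @param eps Mean incorrect-amino-acid contribution (negative).
#' @param rho Standard deviation of the non-additive term (>= 0).
#' @return A `landscape_model` of name `"rmf"`; `fitness_scale` `"linear"`.
#' @examples
#' rmf_model(nu = 60, eps = -1, rho = 1)
#' @export
rmf_model <- function(nu = 60L, eps = -1, rho = 1) {
  if (nu < 2) stopf("nu must be at least 2")
  if (eps >= 0) stopf("eps must be negative")
  if (rho < 0) stopf("rho must be >= 0")
  structure(list(name = "rmf", nu = as.integer(nu), eps = eps, rho = rho,
                 fitness_scale = "linear"),
            class = "landscape_model")
}

#' Fixed (deterministic) landscape
#'
#' Wraps an explicit fitness vector as a degenerate landscape model; every
#' replication returns the same values.  Useful for closed-form checks.
#'
#' @param F Fitness value per variant (length n of the target space).
#' @param fitness_scale `"linear"` or `"log"`.
#' @return A `landscape_model` of name `"fixed"`.
#' @export
fixed_model <- function(F, fitness_scale = c("linear", "log")) {
  structure(list(name = "fixed", F = as.numeric(F),
                 fitness_scale = match.arg(fitness_scale)),
            class = "landscape_model")
}

#' @export
print.landscape_model <- function(x, ...) {
  ps <- x[setdiff(names(x), c("name", "fitness_scale", "F"))]
  cat(sprintf("Landscape model '%s' (%s scale): %s\n", x$name, x$fitness_scale,
              paste(names(ps), unlist(ps), sep = " = ", collapse = ", ")))
  invisible(x)
}

## ---- vectorized samplers: n x reps fitness matrices -----------------------

.sample_F_novwein <- function(space, model, reps) {
  if (is.null(space$wt_index))
    stopf("the Gaussian landscape model needs a variant space with a wild type")
  M <- space$M
  n <- space$n
  wt <- space$wt
  ## mutation dictionary: one entry per (position, non-wt amino acid)
  mut_pos <- integer(0); mut_aa <- character(0)
  for (i in seq_len(M)) {
    sup <- if (is.null(space$per_position)) unique(space$variants[, i])
           else names(space$per_position[[i]]$q)
    aas <- setdiff(sup, wt[i])
    mut_pos <- c(mut_pos, rep(i, length(aas)))
    mut_aa <- c(mut_aa, aas)
  }
  K0 <- length(mut_pos)
  ## design matrix: variant v uses mutation j iff its aa at mut_pos[j] is mut_aa[j]
  D <- matrix(0, n, K0)
  for (j in seq_len(K0))
    D[space$variants[, mut_pos[j]] == mut_aa[j], j] <- 1
  mu <- matrix(rnorm(M * reps, mean = model$m, sd = sqrt(model$var_pos)), M, reps)
  f <- mu[mut_pos, , drop = FALSE] +
    matrix(rnorm(K0 * reps, sd = sqrt(model$var_aa)), K0, reps)
  F <- D %*% f
  eps <- matrix(rnorm(n * reps, sd = sqrt(model$var_nonadd)), n, reps)
  eps[space$wt_index, ] <- 0
  F <- F + eps
  F[space$wt_index, ] <- 0   # exact, not just in expectation
  F
}

## which of the two randomized sites influence each sequence position
.nk_layout <- function(model) {
  N <- model$N; K <- model$K
  left <- ceiling(K / 2); right <- floor(K / 2)
  site <- c(1L, 1L + model$separation)
  infl <- function(i) {
    if (model$topology == "circular") {
      ((i - left - 1L):(i + right - 1L)) %% N + 1L
    } else {
      lo <- i - left; hi <- i + right
      if (lo < 1) { hi <- hi + (1 - lo); lo <- 1 }
      if (hi > N) { lo <- lo - (hi - N); hi <- N }
      lo:hi
    }
  }
  dep <- t(vapply(seq_len(N), function(i) site %in% infl(i), logical(2)))
  list(n_both = sum(dep[, 1] & dep[, 2]),
       n_only1 = sum(dep[, 1] & !dep[, 2]),
       n_only2 = sum(dep[, 2] & !dep[, 1]),
       n_bg = sum(!dep[, 1] & !dep[, 2]))
}

.sample_F_nk <- function(space, model, reps) {
  if (space$M != 2L) stopf("the NK sampler randomizes exactly two sites")
  lay <- .nk_layout(model)
  n <- space$n
  sup1 <- unique(space$variants[, 1]); sup2 <- unique(space$variants[, 2])
  i1 <- match(space$variants[, 1], sup1)
  i2 <- match(space$variants[, 2], sup2)
  acc <- function(nrow_, count) {
    S <- matrix(0, nrow_, reps)
    for (t in seq_len(count)) S <- S + matrix(runif(nrow_ * reps), nrow_, reps)
    S
  }
  F <- matrix(0, n, reps)
  if (lay$n_only1 > 0) F <- F + acc(length(sup1), lay$n_only1)[i1, , drop = FALSE]
  if (lay$n_only2 > 0) F <- F + acc(length(sup2), lay$n_only2)[i2, , drop = FALSE]
  if (lay$n_both > 0)  F <- F + acc(n, lay$n_both)
  if (lay$n_bg > 0) {
    bg <- colSums(matrix(runif(lay$n_bg * reps), lay$n_bg, reps))
    F <- sweep(F, 2L, bg, "+")
  }
  F / model$N
}

.sample_F_rmf <- function(space, model, reps) {
  if (space$M > model$nu) stopf("more randomized positions than sequence length nu")
  n <- space$n
  F <- matrix(0, n, reps)
  for (i in seq_len(space$M)) {
    sup <- unique(space$variants[, i])
    A <- length(sup)
    if (A > 20) stopf("the contribution ladder has 20 levels; position %d has %d amino acids", i, A)
    ## fresh random rank assignment (injection into 0..19) per replication
    ranks <- vapply(seq_len(reps), function(r) sample.int(20, A) - 1L,
                    integer(A))
    ranks <- matrix(ranks, A, reps)
    w <- model$eps * ranks / 10
    F <- F + w[match(space$variants[, i], sup), , drop = FALSE]
  }
  F + matrix(rnorm(n * reps, sd = model$rho), n, reps)
}

.sample_F_matrix <- function(space, model, reps) {
  stopifnot(inherits(space, "variant_space"), inherits(model, "landscape_model"))
  switch(model$name,
    novwein = .sample_F_novwein(space, model, reps),
    nk = .sample_F_nk(space, model, reps),
    rmf = .sample_F_rmf(space, model, reps),
    fixed = {
      if (length(model$F) != space$n)
        stopf("fixed landscape has %d values but the space has %d variants",
              length(model$F), space$n)
      matrix(model$F, space$n, reps)
    },
    stopf("unknown landscape model '%s'", model$name))
}

#' Sample one fitness-landscape realization
#'
#' Draws a single realization of the sequence-fitness map over a variant
#' space under the given model.  [sample_novwein()], [sample_nk()] and
#' [sample_rmf()] are thin wrappers fixing the model family.
#'
#' @param space A `variant_space`.
#' @param model A `landscape_model` ([novwein_model()], [nk_model()],
#'   [rmf_model()], [fixed_model()]).
#' @param seed Optional integer seed (recorded in the result); the sampler is
#'   fully reproducible given the seed.
#' @return An object of class `fitness_landscape`: `space`, `F` (fitness per
#'   variant, in variant order), `model`, `seed`.
#' @examples
#' vs <- build_variant_space("NNK", M = 2, wt = c("A", "A"))
#' ls <- sample_landscape(vs, novwein_model(-0.3, 0.3, 0.3, 0.04), seed = 1)
#' @export
sample_landscape <- function(space, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  F <- as.numeric(.sample_F_matrix(space, model, 1L))
  structure(list(space = space, F = F, model = model, seed = seed),
            class = "fitness_landscape")
}

#' @rdname sample_landscape
#' @param m,var_pos,var_aa,var_nonadd See [novwein_model()].
#' @export
sample_novwein <- function(space, m, var_pos, var_aa, var_nonadd, seed = NULL)
  sample_landscape(space, novwein_model(m, var_pos, var_aa, var_nonadd), seed)

#' @rdname sample_landscape
#' @param N,K,overlap,separation,topology See [nk_model()].
#' @export
sample_nk <- function(space, N = 24L, K = 6L, overlap = NULL, separation = NULL,
                      topology = "circular", seed = NULL)
  sample_landscape(space, nk_model(N, K, overlap, separation, topology), seed)

#' @rdname sample_landscape
#' @param nu,eps,rho See [rmf_model()].
#' @export
sample_rmf <- function(space, nu = 60L, eps = -1, rho = 1, seed = NULL)
  sample_landscape(space, rmf_model(nu, eps, rho), seed)

#' @export
print.fitness_landscape <- function(x, ...) {
  cat(sprintf("Fitness landscape (%s model) over %d variants: best %.4g at index %d\n",
              x$model$name, length(x$F), max(x$F), which.max(x$F)))
  invisible(x)
}

#' Export a landscape as a data frame
#'
#' @param x A `fitness_landscape`.
#' @param row.names,optional,... Standard [as.data.frame()] arguments (unused).
#' @return Data frame with columns `variant_id`, `aa_tuple`, `p`, `fitness`.
#' @method as.data.frame fitness_landscape
#' @export
as.data.frame.fitness_landscape <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(variant_id = seq_along(x$F),
             aa_tuple = apply(x$space$variants, 1, paste, collapse = ""),
             p = x$space$p, fitness = x$F)
}

## pairwise structure counts relative to the wild type:
## d  = Hamming distance of each variant to wt
## B[v,v'] = number of positions where both differ from wt
## C[v,v'] = number of positions where both carry the identical mutation
.novwein_dbc <- function(variants, wt) {
  N <- nrow(variants); M <- ncol(variants)
  D <- variants != matrix(wt, N, M, byrow = TRUE)
  d <- rowSums(D)
  B <- tcrossprod(D * 1)
  C <- matrix(0, N, N)
  for (i in seq_len(M)) {
    z <- ifelse(D[, i], variants[, i], NA_character_)
    eq <- outer(z, z, "==")
    eq[is.na(eq)] <- FALSE
    C <- C + eq
  }
  list(d = d, B = B, C = C)
}

#' Mean and covariance of the Gaussian landscape model
#'
#' Closed-form first and second moments of the fitness vector under the
#' Gaussian random-effects model: `E F_v = m * d(v)` and, for `v != v'`,
#' `Cov(F_v, F_v') = b * var_pos + c * var_aa`, with
#' `Var F_v = d * (var_pos + var_aa) + var_nonadd`, where `d` is the Hamming
#' distance of `v` to the wild type, `b` the number of positions at which
#' both variants differ from the wild type, and `c` the number of positions
#' at which they carry the identical mutation.  The wild type has mean and
#' variance 0.
#'
#' @param space A `variant_space` with a defined wild type.
#' @param model A `novwein_model()`.
#' @return A list of class `novwein_moments`: `mean` (length n), `cov`
#'   (n-by-n), and the structure counts `d`, `b`, `c`.
#' @export
novwein_moments <- function(space, model) {
  stopifnot(inherits(space, "variant_space"),
            inherits(model, "landscape_model"), model$name == "novwein")
  if (is.null(space$wt_index)) stopf("variant space has no wild type")
  s <- .novwein_dbc(space$variants, space$wt)
  Sigma <- model$var_pos * s$B + model$var_aa * s$C +
    model$var_nonadd * diag(as.numeric(s$d > 0))
  structure(list(mean = model$m * s$d, cov = Sigma,
                 d = s$d, b = s$B, c = s$C),
            class = "novwein_moments")
}

#' Fitness scale transformations
#'
#' Transforms raw (assay-scale) fitness values to the model's transformed
#' scale, relative to the wild type's raw fitness `wt_raw` so that the wild
#' type maps to 0.  `kind = "log"` applies `x -> log(x / wt_raw)`;
#' `kind = "boxcox"` applies the Box-Cox power transformation
#' `x -> ((x / wt_raw)^lambda - 1) / lambda` with `lambda` in (0, 1]
#' (`lambda = 1` is affine, and the log transform is the `lambda -> 0`
#' limit).  Set `inverse = TRUE` to map transformed values back to the raw
#' scale.
#'
#' @param x Values to transform (raw scale, or transformed scale when
#'   `inverse = TRUE`).
#' @param kind `"log"` or `"boxcox"`.
#' @param lambda Box-Cox power in (0, 1].
#' @param wt_raw Wild-type raw fitness (> 0).
#' @param inverse Apply the inverse transformation.
#' @return Transformed (or back-transformed) numeric vector.
#' @examples
#' transform_fitness(exp(1), "log", wt_raw = 1)        # 1
#' transform_fitness(2, "boxcox", lambda = 1, wt_raw = 1)  # 1
#' @export
transform_fitness <- function(x, kind = c("log", "boxcox"), lambda = NULL,
                              wt_raw = 1, inverse = FALSE) {
  kind <- match.arg(kind)
  if (wt_raw <= 0) stopf("wt_raw must be positive")
  if (kind == "log") {
    if (inverse) return(wt_raw * exp(x))
    if (any(x <= 0)) stopf("log transform needs positive raw fitness values")
    return(log(x / wt_raw))
  }
  if (is.null(lambda) || lambda <= 0 || lambda > 1)
    stopf("Box-Cox lambda must lie in (0, 1]")
  if (inverse) return(wt_raw * (1 + lambda * x)^(1 / lambda))
  if (any(x < 0)) stopf("Box-Cox transform needs nonnegative raw fitness values")
  ((x / wt_raw)^lambda - 1) / lambda
}
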