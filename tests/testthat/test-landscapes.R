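# small 2-position space with 4 amino acids per position (A, C, D, E)
four_aa_space <- function() {
  sch <- build_scheme(data.frame(codon = c("GCT", "TGT", "GAT", "GAA"),
                                 weight = rep(0.25, 4)))
  build_variant_space(sch, M = 2, wt = c("A", "A"))
}

test_that("degenerate Gaussian landscapes reduce to their closed forms", {
  vs <- four_aa_space()
  d <- rowSums(vs$variants != matrix(c("A", "A"), vs$n, 2, byrow = TRUE))
  ## all variances zero: F = m * d exactly
  ls <- sample_landscape(vs, novwein_model(-0.3, 0, 0, 1e-300), seed = 1)
  expect_equal(ls$F, -0.3 * d, tolerance = 1e-12)
  expect_equal(ls$F[vs$wt_index], 0)
  ## var_aa = var_nonadd = 0: single mutants at one position share their mean
  ls2 <- sample_landscape(vs, novwein_model(-0.3, 0.5, 0, 0), seed = 2)
  singles_p1 <- which(d == 1 & vs$variants[, 2] == "A")
  expect_equal(length(unique(round(ls2$F[singles_p1], 12))), 1L)
})

test_that("sampled Gaussian landscapes match the closed-form moment structure", {
  vs <- four_aa_space()
  mom_reps <- 20000L
  params <- list(novwein_model(-0.3, 0.4, 0.2, 0.1),
                 novwein_model(-0.5, 1e-12, 1e-12, 0.6),  # extreme non-additivity
                 novwein_model(-0.2, 0.3, 0.3, 1e-12))
  for (ip in seq_along(params)) {
    pm <- params[[ip]]
    mom <- novwein_moments(vs, pm)
    set.seed(100 + ip)
    F <- satmut:::.sample_F_matrix(vs, pm, mom_reps)
    emp_mean <- rowMeans(F)
    se_mean <- apply(F, 1L, sd) / sqrt(mom_reps)
    expect_true(all(abs(emp_mean - mom$mean) <= 4 * se_mean + 1e-9))
    emp_var <- apply(F, 1L, var)
    se_var <- mom$cov[cbind(1:vs$n, 1:vs$n)] * sqrt(2 / (mom_reps - 1))
    expect_true(all(abs(emp_var - diag(mom$cov)) <= 4 * se_var + 1e-9))
    ## a spread of off-diagonal pairs
    set.seed(1)
    pairs <- cbind(sample(vs$n, 12, replace = TRUE), sample(vs$n, 12, replace = TRUE))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      emp_cov <- cov(F[i, ], F[j, ])
      se_cov <- sqrt((mom$cov[i, i] * mom$cov[j, j] + mom$cov[i, j]^2) / mom_reps)
      expect_lte(abs(emp_cov - mom$cov[i, j]), 4 * se_cov + 1e-9)
    }
  }
})

test_that("moment structure has its pairwise special cases and is PSD", {
  vs <- four_aa_space()
  pm <- novwein_model(-0.4, 0.3, 0.2, 0.1)
  mom <- novwein_moments(vs, pm)
  d <- mom$d
  s1 <- which(d == 1)[1:2]
  ## single mutant: mean m, variance vp + va + vn
  expect_equal(mom$mean[s1[1]], -0.4)
  expect_equal(mom$cov[s1[1], s1[1]], 0.3 + 0.2 + 0.1)
  ## two distinct single mutants at the same position: covariance vp
  p1_singles <- which(d == 1 & vs$variants[, 2] == "A")
  expect_equal(mom$cov[p1_singles[1], p1_singles[2]], 0.3)
  ## wild type row: all zero
  expect_true(all(mom$cov[vs$wt_index, ] == 0))
  expect_equal(mom$mean[vs$wt_index], 0)
  expect_gte(min(eigen(mom$cov, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("exponentiating then log-transforming recovers the simulated landscape", {
  vs <- four_aa_space()
  ls <- sample_landscape(vs, novwein_model(-0.3, 0.2, 0.2, 0.1), seed = 5)
  raw <- exp(ls$F)
  expect_equal(transform_fitness(raw, "log", wt_raw = raw[vs$wt_index]), ls$F,
               tolerance = 1e-12)
})

test_that("NK influence-set layout follows the overlap arithmetic", {
  lay6 <- satmut:::.nk_layout(nk_model(24, 6, overlap = 6))
  expect_equal(lay6$n_both, 6L)
  expect_equal(lay6$n_only1 + lay6$n_only2 + lay6$n_both, 8L)  # union of two 7-sets
  lay0 <- satmut:::.nk_layout(nk_model(24, 6, separation = 7))
  expect_equal(lay0$n_both, 0L)
  expect_equal(lay0$n_only1 + lay0$n_only2, 14L)
  lay3 <- satmut:::.nk_layout(nk_model(24, 6, overlap = 3))
  expect_equal(lay3$n_both, 3L)
  expect_error(nk_model(24, 24, overlap = 0), "smaller")
  expect_error(nk_model(24, 6, separation = 0), "distinct")
})

test_that("NK with K = 0 is exactly additive across the two sites", {
  vs <- build_variant_space("NNK", M = 2)
  ls <- sample_nk(vs, N = 24, K = 0, separation = 5, seed = 3)
  Fm <- matrix(ls$F, nrow = 20, byrow = TRUE)  # rows: pos1 aa, cols: pos2 aa
  ## two-way additive decomposition leaves zero interaction residual
  res <- Fm - outer(rowMeans(Fm), colMeans(Fm), "+") + mean(Fm)
  expect_lt(max(abs(res)), 1e-12)
})

test_that("rough Mount Fuji landscapes follow the contribution ladder", {
  vs1 <- build_variant_space("NNK", M = 1)
  ls <- sample_rmf(vs1, nu = 60, eps = -1, rho = 0, seed = 4)
  ## additive optimum at rank 0 is fitness 0; one-site range is 1.9
  expect_equal(max(ls$F), 0)
  expect_equal(max(ls$F) - min(ls$F), 1.9)
  ## mean contribution of an incorrect amino acid equals eps
  expect_equal(mean(ls$F[ls$F < 0]), -1, tolerance = 1e-12)

  vs <- build_variant_space("NNK", M = 2)
  ls0 <- sample_rmf(vs, rho = 0, seed = 6)
  expect_equal(max(ls0$F), 0)  # correct amino acids at both sites
})

test_that("rho adds pure noise variance on top of a rho-independent additive part", {
  vs <- build_variant_space("NNK", M = 2)
  reps <- 300L
  vartot <- function(rho, seed) {
    set.seed(seed)
    F <- satmut:::.sample_F_matrix(vs, rmf_model(60, -1, rho), reps)
    mean(apply(F, 2L, var))
  }
  v0 <- vartot(0, 9)
  v2 <- vartot(2, 9)
  expect_equal(v2 - v0, 4, tolerance = 0.15 * 4)
  ## additive-part variance itself is stable across seeds
  expect_equal(v0, vartot(0, 10), tolerance = 0.05)
})

test_that("samplers are reproducible given a seed", {
  vs <- build_variant_space("NNK", M = 2, wt = c("A", "A"))
  for (m in list(novwein_model(-0.3, 0.2, 0.2, 0.1),
                 nk_model(24, 6, overlap = 3), rmf_model(60, -1, 1))) {
    a <- sample_landscape(vs, m, seed = 77)
    b <- sample_landscape(vs, m, seed = 77)
    expect_identical(a$F, b$F)
  }
})

test_that("fitness transformations round-trip and validate their domain", {
  x <- c(0.5, 1, 2, 7)
  y <- transform_fitness(x, "log", wt_raw = 2)
  expect_equal(y[2], log(0.5))
  expect_equal(transform_fitness(y, "log", wt_raw = 2, inverse = TRUE), x)
  expect_equal(transform_fitness(2, "boxcox", lambda = 1, wt_raw = 1), 1)
  b <- transform_fitness(x, "boxcox", lambda = 0.4, wt_raw = 2)
  expect_equal(transform_fitness(b, "boxcox", lambda = 0.4, wt_raw = 2,
                                 inverse = TRUE), x)
  expect_equal(transform_fitness(2, "log", wt_raw = 2), 0)
  expect_equal(transform_fitness(exp(1), "log", wt_raw = 1), 1)
  expect_error(transform_fitness(-1, "log"), "positive")
  expect_error(transform_fitness(2, "boxcox", lambda = 1.5), "lambda")
})
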