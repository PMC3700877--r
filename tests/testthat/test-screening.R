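test_that("expected best discovered fitness matches small closed forms", {
  toy <- manual_variant_space(c(0.5, 0.5))
  ls <- sample_landscape(toy, fixed_model(c(0, 1)))
  expect_equal(expected_best_given_landscape(ls, 2)$e_best, 0.75)
  ## L = 1 with equal probabilities: arithmetic mean
  sp3 <- manual_variant_space(rep(1 / 3, 3))
  ls3 <- sample_landscape(sp3, fixed_model(c(0.1, 0.7, 0.4)))
  expect_equal(expected_best_given_landscape(ls3, 1)$e_best, 0.4)
  ## enormous L: the global maximum
  expect_equal(expected_best_given_landscape(ls3, 1e9)$e_best, 0.7,
               tolerance = 1e-9)
  ## all-stop probability reported separately
  spst <- manual_variant_space(c(0.4, 0.4), p_stp = 0.2)
  lst <- sample_landscape(spst, fixed_model(c(1, 2)))
  eb <- expected_best_given_landscape(lst, 3)
  expect_equal(eb$p_all_stop, 0.2^3)
  expect_equal(eb$e_best_unconditional, eb$e_best * (1 - 0.2^3))
  expect_error(expected_best_given_landscape(ls, 0), ">= 1")
})

test_that("expected best matches exhaustive library enumeration", {
  cases <- list(
    list(p = c(0.5, 0.3), p_stp = 0.2, F = c(2, 5)),
    list(p = c(0.4, 0.3, 0.3), p_stp = 0, F = c(-1, 0.5, 0.2)),
    list(p = c(0.3, 0.3, 0.2, 0.1), p_stp = 0.1, F = c(4, 1, 3, 2))
  )
  for (cs in cases) {
    sp <- manual_variant_space(cs$p, cs$p_stp)
    ls <- sample_landscape(sp, fixed_model(cs$F))
    for (L in c(1L, 3L, 6L)) {
      or <- oracle_library_metrics(cs$p, cs$p_stp, L, F = cs$F)
      expect_equal(expected_best_given_landscape(ls, L)$e_best,
                   or$expected_best_cond, tolerance = 1e-10)
    }
  }
})

test_that("screening curve matches naive library-sampling Monte Carlo", {
  sp <- manual_variant_space(c(0.5, 0.3, 0.2), wt_index = 1)
  model <- novwein_model(-0.5, 0.2, 0.2, 0.1)
  L <- 3L
  sc <- screening_curve(sp, model, L_grid = c(1L, L), reps = 2000L, seed = 21)
  ## naive: fresh landscapes, sampled libraries, observed best
  set.seed(22)
  reps_n <- 2000L; draws_per <- 50L
  Fm <- satmut:::.sample_F_matrix(sp, model, reps_n)
  obs <- unlist(lapply(seq_len(reps_n), function(r)
    naive_best_mc(sp$p, sp$p_stp, Fm[, r], L, draws_per)))
  i <- match(L, sc$L_grid)
  comb_se <- sqrt(sc$se[i]^2 + var(obs) / length(obs))
  expect_lt(abs(sc$e_best[i] - mean(obs)), 3 * comb_se)
})

test_that("deterministic landscapes give a zero-error closed-form curve", {
  toy <- manual_variant_space(c(0.5, 0.5))
  sc <- screening_curve(toy, fixed_model(c(0, 1)), L_grid = c(1, 2, 4, 8),
                        reps = 50, seed = 1)
  expect_equal(sc$e_best, 1 - 0.5^c(1, 2, 4, 8))
  expect_equal(sc$se, rep(0, 4))
  expect_equal(sc$e_single, 0.5)
  expect_equal(sc$e_best_global, 1)
  ## reproducibility: identical seeds give identical curves
  vs <- build_variant_space("NNK", M = 2)
  a <- screening_curve(vs, rmf_model(60, -1, 1), L_grid = c(10, 100),
                       reps = 50, seed = 5)
  b <- screening_curve(vs, rmf_model(60, -1, 1), L_grid = c(10, 100),
                       reps = 50, seed = 5)
  expect_identical(a$e_best, b$e_best)
})

test_that("curves are monotone in L and bounded by their limits", {
  vs <- build_variant_space("NNK", M = 2)
  for (model in list(nk_model(24, 6, overlap = 3), rmf_model(60, -1, 1))) {
    sc <- screening_curve(vs, model, reps = 300, seed = 8)
    expect_true(all(diff(sc$e_best) >= -2 * max(sc$se)))
    expect_true(all(sc$e_best >= sc$e_single - 2 * (sc$se + sc$e_single_se)))
    expect_true(all(sc$e_best <= sc$e_best_global +
                      2 * (sc$se + sc$e_best_global_se)))
    expect_equal(sc$cond_prob, 1 - vs$p_stp^sc$L_grid)
  }
})

test_that("the 95%-of-gap size is exact on a closed-form curve", {
  ## two variants p = 1/2 each, fitness 0 and 1: E(L) = 1 - 0.5^L,
  ## threshold 0.975 crossed first at L = 6
  toy <- manual_variant_space(c(0.5, 0.5))
  sc <- screening_curve(toy, fixed_model(c(0, 1)), L_grid = c(1, 2, 16),
                        reps = 20, seed = 1)
  l <- find_lstar95(sc, boot = 50)
  expect_equal(l$l_star, 6L)
  expect_equal(l$threshold, 0.975)
  ## affine shift leaves the crossing unchanged
  sc2 <- screening_curve(toy, fixed_model(c(0, 1) + 7), L_grid = c(1, 2, 16),
                         reps = 20, seed = 1)
  expect_equal(find_lstar95(sc2, boot = 0)$l_star, 6L)
  ## grid that stops short of the threshold errors out
  sc3 <- screening_curve(toy, fixed_model(c(0, 1)), L_grid = c(1, 2, 3),
                         reps = 20, seed = 1)
  expect_error(find_lstar95(sc3, boot = 0), "extend")
})

test_that("fitness-loss distribution enumerates the toy case", {
  toy <- manual_variant_space(c(0.5, 0.5))
  ld <- loss_distribution(toy, fixed_model(c(1, 2)), L = 1, reps = 2000, seed = 3)
  lam <- ld$samples$lambda
  expect_true(all(lam %in% c(0, 50)))
  expect_equal(mean(lam == 50), 0.5, tolerance = 0.05)
  ## huge L: full coverage almost surely, all losses zero
  ld2 <- loss_distribution(toy, fixed_model(c(1, 2)), L = 200, reps = 200, seed = 3)
  expect_true(all(ld2$samples$lambda == 0))
  ## raw-scale losses stay within [0, 100] for a log-scale model
  vs <- build_variant_space("NNK", M = 2, wt = c("A", "A"))
  ld3 <- loss_distribution(vs, novwein_model(-0.3, 0.2, 0.2, 0.1), L = 50,
                           reps = 200, seed = 4)
  ok <- ld3$samples$functional_found
  expect_true(all(ld3$samples$lambda[ok] >= 0 & ld3$samples$lambda[ok] <= 100))
  expect_true(all(is.na(ld3$samples$lambda[!ok])))
})

test_that("loss exceedance probabilities behave like tail frequencies", {
  toy <- manual_variant_space(c(0.5, 0.5))
  ld <- loss_distribution(toy, fixed_model(c(1, 2)), L = 1, reps = 2000, seed = 3)
  ex <- exceedance_probabilities(ld, thresholds = c(0, 20, 100))
  expect_equal(ex$prob[1], 1)
  expect_equal(ex$prob[2], 0.5, tolerance = 3 * ex$se[2] + 0.01)
  expect_equal(ex$prob[3], 0)
  expect_true(all(diff(ex$prob) <= 0))
  ## exceedance is nonincreasing in L as well
  ld_big <- loss_distribution(toy, fixed_model(c(1, 2)), L = 10, reps = 2000, seed = 3)
  ex_big <- exceedance_probabilities(ld_big, thresholds = c(0, 20, 100))
  expect_lte(ex_big$prob[2], ex$prob[2])
})
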