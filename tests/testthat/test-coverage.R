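test_that("expected coverage matches closed forms on toy spaces", {
  toy <- manual_variant_space(c(0.5, 0.5))
  expect_equal(expected_coverage(toy, 0), 0)
  expect_equal(expected_coverage(toy, 2), 0.75)
  one <- manual_variant_space(1)
  expect_equal(expected_coverage(one, 1), 1)
  ## nondecreasing in L, approaching 1
  vs <- build_variant_space("NNK", M = 1)
  ec <- expected_coverage(vs, c(1, 10, 100, 1000, 1e6))
  expect_true(all(diff(ec) > 0))
  expect_equal(ec[5], 1, tolerance = 1e-8)
})

test_that("full-coverage probability agrees across methods on small spaces", {
  toy <- manual_variant_space(c(0.5, 0.5))
  expect_equal(full_coverage_probability(toy, 2, method = "exact")$probability, 0.5)
  expect_equal(full_coverage_probability(manual_variant_space(1), 5)$probability, 1)
  ## truncated brackets exact within its reported bound
  sp <- manual_variant_space(c(0.3, 0.3, 0.2, 0.1, 0.05), p_stp = 0.05)
  for (L in c(5, 10, 25, 60)) {
    ex <- full_coverage_probability(sp, L, method = "exact")
    tr <- full_coverage_probability(sp, L, method = "truncated")
    expect_lte(abs(tr$probability - ex$probability), tr$error_bound + 1e-12)
  }
  ## L below n cannot cover
  expect_equal(full_coverage_probability(sp, 3)$probability, 0)
})

test_that("coverage metrics match exhaustive multinomial enumeration", {
  cases <- list(
    list(p = c(0.5, 0.5), p_stp = 0),
    list(p = c(0.6, 0.3), p_stp = 0.1),
    list(p = c(0.25, 0.25, 0.2, 0.15, 0.1), p_stp = 0.05),
    list(p = rep(1 / 6, 6), p_stp = 0)
  )
  for (cs in cases) {
    sp <- manual_variant_space(cs$p, cs$p_stp)
    for (L in c(2L, 5L, 8L)) {
      or <- oracle_library_metrics(cs$p, cs$p_stp, L)
      expect_equal(expected_coverage(sp, L), or$expected_coverage,
                   tolerance = 1e-10)
      expect_equal(full_coverage_probability(sp, L, method = "exact")$probability,
                   or$full_coverage, tolerance = 1e-10)
      for (k in c(1L, 2L, length(cs$p)))
        expect_equal(as.numeric(top_k_probability(sp, k, L)),
                     oracle_top_k(cs$p, cs$p_stp, k, L), tolerance = 1e-10)
    }
  }
})

test_that("top-k probability has its closed-form special cases", {
  ## equal probabilities, k = 1
  sp <- manual_variant_space(rep(0.9 / 3, 3), p_stp = 0.1)
  for (L in c(1, 4, 9))
    expect_equal(as.numeric(top_k_probability(sp, 1, L)),
                 1 - (1 - 0.3)^L, tolerance = 1e-12)
  ## k = n: some functional variant present
  vs <- build_variant_space("NNK", M = 1)
  for (L in c(1, 3, 10))
    expect_equal(as.numeric(top_k_probability(vs, vs$n, L)),
                 1 - vs$p_stp^L, tolerance = 1e-12)
  ## two variants p = (0.6, 0.4), k = 1, L = 1
  expect_equal(as.numeric(top_k_probability(manual_variant_space(c(0.6, 0.4)), 1, 1)),
               0.5)
  expect_error(top_k_probability(vs, 0, 5), "1..n")
})

test_that("coverage metrics are monotone and correctly ordered", {
  vs <- build_variant_space("NNK", M = 1)
  Ls <- c(10, 30, 100, 300)
  pk <- sapply(1:3, function(k) sapply(Ls, function(L)
    as.numeric(top_k_probability(vs, k, L))))
  fc <- sapply(Ls, function(L) full_coverage_probability(vs, L)$probability)
  expect_true(all(diff(fc) >= 0))
  for (k in 1:3) expect_true(all(diff(pk[, k]) >= 0))
  ## P(full) <= P(T_k) <= P(T_{k+1})
  expect_true(all(fc <= pk[, 1] + 1e-12))
  expect_true(all(pk[, 1] <= pk[, 2] & pk[, 2] <= pk[, 3]))
})

test_that("minimal library size brackets the target level exactly", {
  toy <- manual_variant_space(c(0.5, 0.5))
  r <- min_library_size(toy, metric = "expected", alpha = 0.74)
  expect_equal(r$L, 2L)
  expect_gte(r$metric_at_L, 0.74)
  expect_lt(r$metric_at_L_minus_1, 0.74)
  expect_equal(min_library_size(manual_variant_space(1), "topk", alpha = 0.95)$L, 1L)
  expect_error(min_library_size(toy, "expected", alpha = 1), "alpha")
})
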