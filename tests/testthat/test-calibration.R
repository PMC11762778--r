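mk_curves <- function(nta, sen_A, sen_B, prop_B = NULL) {
  cv <- list(nta = nta, sen_A = sen_A, sen_B = sen_B,
             sen = sort(c(sen_A, sen_B)))
  if (!is.null(prop_B)) attr(cv, "prop_B") <- prop_B
  cv
}

test_that("the curve cost is a symmetric nonnegative quadratic distance", {
  a <- mk_curves(1:5, 3:10, 5:12)
  expect_equal(curve_cost(a, a), 0)
  b <- mk_curves(2:6, 4:11, 6:13)
  expect_gt(curve_cost(a, b), 0)
  expect_equal(curve_cost(a, b), curve_cost(b, a))
  # doubling every generation difference quadruples the quadratic term
  b2 <- mk_curves(3:7, 5:12, 7:14)
  expect_equal(curve_cost(a, b2), 4 * curve_cost(a, b))
})

test_that("empty categories are skipped (target) or penalized (simulation)", {
  tgt <- mk_curves(integer(0), 3:10, 5:12)
  sim <- mk_curves(1:5, 3:10, 5:12)
  expect_warning(c0 <- curve_cost(sim, tgt), "nta.*empty")
  expect_equal(c0, 0)
  sim_empty <- mk_curves(1:5, 3:10, integer(0))
  full <- mk_curves(1:5, 3:10, 5:12)
  expect_gt(suppressWarnings(curve_cost(sim_empty, full)), 0)
  # the type-B-proportion penalty enters quadratically
  x <- mk_curves(1:5, 3:10, 5:12, prop_B = 0.6)
  y <- mk_curves(1:5, 3:10, 5:12, prop_B = 0.8)
  expect_equal(curve_cost(x, y), 1000 * 0.2^2)
})

test_that("the CMA-ES minimizer solves a bounded quadratic and tracks its incumbent", {
  set.seed(1)
  target <- c(0.3, 0.7, 0.5, 0.2)
  res <- cma_es(function(x) sum((x - target)^2), x0 = rep(0.5, 4),
                sigma0 = 0.3, lower = 0, upper = 1, budget = 600)
  expect_lt(res$value, 1e-4)
  expect_equal(res$par, target, tolerance = 0.02)
  expect_true(all(diff(res$trace) <= 0))
  # bounded optimum on the box edge
  res2 <- cma_es(function(x) sum((x + 1)^2), x0 = rep(0.5, 3),
                 sigma0 = 0.3, lower = 0, upper = 1, budget = 400)
  expect_equal(res2$par, rep(0, 3), tolerance = 0.02)
})

test_that("fitting is reproducible and returns the ten named parameters", {
  set.seed(2)
  bank <- test_bank()
  target <- arrest_generation_curves(
    simulate_lineages(300, law_params(), initial_distribution(), bank))
  spec <- fit_spec(n_lineages = 30, n_repeats = 1, budget = 60, seed = 5)
  f1 <- fit_parameters(target, spec, bank = bank)
  f2 <- fit_parameters(target, spec, bank = bank)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$value, f2$value)
  expect_named(f1$par, c("a_nta", "b_nta", "a_sen_A", "b_sen_A",
                         "a_sen_B", "b_sen_B", "l_min_A", "l_min_B",
                         "l_0", "l_1"))
  expect_true(all(diff(f1$trace) <= 0))
  expect_equal(f1$par[["l_min_A"]], round(f1$par[["l_min_A"]]))
})
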