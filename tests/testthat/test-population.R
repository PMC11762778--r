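test_that("immortal populations double every cycle until the saturation cap", {
  # constant 90-min cycles, no arrests: count = N_init * 2^(t/90) until N_sat
  set.seed(1)
  cfg <- experiment_config(n_init = 4, r_sat = 1000, n_days = 1)
  run <- run_population_experiment(cfg, immortal_params(), point_dist(5000),
                                   constant_bank(nor = 90))
  # saturation needs ceil(log2(1000)) = 10 doublings: reached at 900 min = 15 h
  hh <- run$hourly
  expect_true(all(hh$count <= cfg$n_sat))
  expect_equal(run$end_counts, 4000)
  # closed-form doubling: hourly counts reflect the division rounds completed
  # strictly before each mark, capped at N_sat
  expect_equal(hh$count,
               pmin(4 * 2^floor((hh$time_h * 60 - 1) / 90), 4000))
  expect_equal(hh$count[hh$time_h > 15], rep(4000L, sum(hh$time_h > 15)))
})

test_that("mean telomere loss per generation is exactly h/2 without clamping", {
  set.seed(2)
  cfg <- experiment_config(n_init = 8, r_sat = 100, n_days = 2)
  run <- run_population_experiment(cfg, immortal_params(), point_dist(5000),
                                   constant_bank(nor = 90))
  sn <- run$snapshots
  # each division removes h from one end of each chromosome: 16 h per cell,
  # i.e. h/2 per telomere on average, deterministically
  expect_equal(sn$telo_mean, 5000 - 3.5 * sn$gen_mean)
})

test_that("the population cap is never exceeded and frozen cells resume after dilution", {
  set.seed(3)
  cfg <- experiment_config(n_init = 50, r_sat = 10, n_days = 3)
  run <- run_population_experiment(cfg, immortal_params(), point_dist(5000),
                                   constant_bank(nor = 90))
  expect_true(all(run$hourly$count <= cfg$n_sat))
  expect_true(all(run$end_counts == cfg$n_sat))
  expect_identical(run$snapshots$count, rep(500L, 3))
})

test_that("dilution keeps a uniform without-replacement sample of cells", {
  # founders split into ancestry halves; with synchronous immortal growth the
  # pre-dilution composition is exactly half marked, so the day-2 composition
  # reflects the dilution draw: mean marked fraction 1/2, hypergeometric SE
  set.seed(4)
  cfg <- experiment_config(n_init = 50, r_sat = 4, n_days = 2,
                           ancestry_bins = 2)
  fr <- replicate(150, {
    run <- run_population_experiment(cfg, immortal_params(), point_dist(5000),
                                     constant_bank(nor = 90))
    run$ancestry[2, 1]
  })
  # keep 50 of 200; variance of the kept-marked count is hypergeometric
  v_hyper <- 50 * 0.5 * 0.5 * (200 - 50) / (200 - 1)
  se_mean <- sqrt(v_hyper) / 50 / sqrt(150)
  expect_lt(abs(mean(fr) - 0.5), 3 * se_mean)
  expect_gt(sd(fr), 0)   # dilution is genuinely random
})

test_that("population summaries compute composition, mode and shortest statistics", {
  telo <- matrix(200L, 32, 3)
  telo[1:8, 1] <- 100L   # length 100 appears 8 times; per-cell minima 100/30/50
  telo[1, 2] <- 30L
  telo[1, 3] <- 50L
  cells <- list(telo = telo, type = c(1L, 2L, 2L), cyc = c(1L, 3L, 2L),
                gen = c(0L, 4L, 8L), anc = 1:3)
  s <- summarize_population(cells, time_h = 10)
  expect_identical(s$count, 3L)
  expect_equal(s$frac_B, 2 / 3)
  expect_equal(s$frac_sen, 1 / 3)
  expect_equal(s$telo_mode, 200)
  expect_equal(s$shortest_mean, 60)
  expect_equal(s$shortest_min, 30)
  expect_equal(s$shortest_max, 100)
  # tie in the pooled telomere counts: the smallest length wins
  telo2 <- matrix(c(rep(10L, 16), rep(20L, 16)), 32, 1)
  s2 <- summarize_population(list(telo = telo2, type = 1L, cyc = 1L,
                                  gen = 0L, anc = 1L), 0)
  expect_equal(s2$telo_mode, 10)
  s0 <- summarize_population(list(telo = matrix(0L, 32, 0), type = integer(),
                                  cyc = integer(), gen = integer(),
                                  anc = integer()), 5)
  expect_identical(s0$count, 0L)
})

test_that("half-saturation time interpolates end-of-day counts", {
  expect_equal(compute_hsl(c(1, 1, 1, 0.8, 0.3) * 1000, n_sat = 1000), 110.4)
  censored <- compute_hsl(rep(1000, 5), n_sat = 1000)
  expect_true(is.na(censored))
  expect_identical(attr(censored, "censored"), "right")
  # halving every count moves HSL earlier (or leaves it equal)
  counts <- c(1000, 900, 700, 420, 100)
  expect_lte(compute_hsl(counts / 2, 1000), compute_hsl(counts, 1000))
  left <- compute_hsl(c(100, 50), 1000)
  expect_identical(attr(left, "censored"), "left")
})

test_that("generational age and its heterogeneity grow over the first days", {
  set.seed(6)
  cfg <- experiment_config(n_init = 60, r_sat = 50, n_days = 4)
  run <- run_population_experiment(cfg, law_params(), initial_distribution(),
                                   test_bank())
  expect_true(all(diff(run$snapshots$gen_mean) > 0))
  expect_gt(run$snapshots$gen_var[4], run$snapshots$gen_var[1])
  # telomere mode and mean decline day over day
  expect_true(all(diff(run$snapshots$telo_mode) <= 0))
  expect_true(all(diff(run$snapshots$telo_mean) < 0))
})

test_that("count-to-OD conversion is the linear display map", {
  expect_equal(count_to_od600(3e5, n_init = 300), 12.5)
  expect_equal(count_to_od600(c(300, 600), 300), c(0.0125, 0.025))
})
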