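p_tab <- law_params()

test_that("arrest laws evaluate to their closed-form values", {
  # nta law has no hard threshold
  expect_equal(arrest_probability(p_tab$a_nta, p_tab$b_nta, -Inf, 0), 0.44)
  expect_equal(arrest_probability(p_tab$a_nta, p_tab$b_nta, -Inf, 50),
               0.44 * exp(-1))
  # type-A senescence: certain at or below 27 bp
  expect_equal(arrest_probability(p_tab$a_sen_A, p_tab$b_sen_A, p_tab$l_min_A, 27), 1)
  expect_equal(arrest_probability(p_tab$a_sen_A, p_tab$b_sen_A, p_tab$l_min_A, 10), 1)
  expect_equal(arrest_probability(p_tab$a_sen_A, p_tab$b_sen_A, p_tab$l_min_A, 40),
               0.73 * exp(-0.19 * 40))
  # type-B senescence is flat in telomere length
  expect_equal(arrest_probability(p_tab$a_sen_B, p_tab$b_sen_B, p_tab$l_min_B,
                                  c(1, 50, 500)), rep(0.12, 3))
  expect_error(arrest_probability(-0.1, 1, 0, 10), "non-negative")
})

test_that("default parameters carry the fitted constants", {
  expect_equal(p_tab$a_nta, 0.02); expect_equal(p_tab$b_nta, 0.44)
  expect_equal(p_tab$a_sen_A, 0.19); expect_equal(p_tab$b_sen_A, 0.73)
  expect_equal(p_tab$a_sen_B, 0); expect_equal(p_tab$b_sen_B, 0.12)
  expect_equal(p_tab$l_min_A, 27); expect_equal(p_tab$l_min_B, 0)
  expect_equal(p_tab$p_accident, 4.3e-3)
  expect_equal(p_tab$p_repair, 0.65); expect_equal(p_tab$p_death, 0.58)
  expect_equal(p_tab$h, 7); expect_equal(p_tab$D, 180)
  expect_error(law_params(p_accident = 1.5), "\\[0, 1\\]")
})

test_that("short daughters of normally cycling type-A mothers always senesce", {
  p <- law_params(p_accident = 0)
  set.seed(1)
  for (rep in 1:50) {
    f <- next_cell_fate("A", "nor", params = p, l = 25)
    expect_true(f$alive)
    expect_identical(f$cycle, "sen")
    expect_identical(f$type, "A")
    expect_true(f$onset)
  }
  # long telomeres, all stochastic channels effectively never firing
  p0 <- immortal_params()
  f <- next_cell_fate("A", "nor", params = p0, l = 300)
  expect_identical(f[c("alive", "type", "cycle")],
                   list(alive = TRUE, type = "A", cycle = "nor"))
})

test_that("senescent-sequence death frequency matches p_death", {
  p <- law_params(p_accident = 0)
  set.seed(2)
  n <- 3e4
  dead <- logical(n)
  for (i in seq_len(n)) dead[i] <- !next_cell_fate("B", "sen", params = p, l = 50)$alive
  se <- sqrt(0.58 * 0.42 / n)
  expect_lt(abs(mean(dead) - 0.58), 3 * se)
})

test_that("accidental-death frequency matches p_accident", {
  p <- law_params()
  set.seed(3)
  n <- 2e5
  # vectorized oracle path: accident is the first check, so the frequency of
  # dead-with-cause-accident among long-telomere normal cells is p_accident
  dead <- vapply(seq_len(n), function(i) {
    f <- next_cell_fate("A", "nor", params = p, l = 300)
    !f$alive && f$death_cause == "accident"
  }, logical(1))
  se <- sqrt(4.3e-3 * (1 - 4.3e-3) / n)
  expect_lt(abs(mean(dead) - 4.3e-3), 3 * se)
})

test_that("arrest-sequence lengths are geometric with the exit probabilities", {
  p <- law_params(p_accident = 0)
  set.seed(4)
  # senescent sequences: count cycles until the death draw succeeds
  n <- 1e4
  sen_len <- vapply(seq_len(n), function(i) {
    k <- 1L
    repeat {
      if (!next_cell_fate("A", "sen", params = p, l = 20)$alive) return(k)
      k <- k + 1L
    }
  }, integer(1))
  mean_sen <- 1 / 0.58
  se_sen <- sqrt((1 - 0.58) / 0.58^2 / n)
  expect_lt(abs(mean(sen_len) - mean_sen), 3 * se_sen)

  # nta sequences: cycles until repair fires; senescence onset through the
  # flat type-B law is disabled here to isolate the repair geometry
  p2 <- law_params(p_accident = 0, b_sen_B = 0, b_nta = 0)
  nta_len <- vapply(seq_len(n), function(i) {
    k <- 1L
    repeat {
      f <- next_cell_fate("B", "nta", params = p2, l = 100)
      if (f$cycle != "nta") return(k)
      k <- k + 1L
    }
  }, integer(1))
  mean_nta <- 1 / 0.65
  se_nta <- sqrt((1 - 0.65) / 0.65^2 / n)
  expect_lt(abs(mean(nta_len) - mean_nta), 3 * se_nta)
})

test_that("a first nta converts type A to type B and repair can run into senescence", {
  p <- law_params(p_accident = 0, b_nta = 1, a_nta = 0)   # nta certain
  set.seed(5)
  f <- next_cell_fate("A", "nor", params = p, l = 200)
  expect_identical(f$type, "B")
  expect_identical(f$cycle, "nta")
  # repaired daughters face the type-B onset checks at once: with certain
  # repair and certain type-B senescence, an nta mother yields a sen daughter
  p3 <- law_params(p_accident = 0, p_repair = 1, b_sen_B = 1, a_sen_B = 0)
  f3 <- next_cell_fate("B", "nta", params = p3, l = 200)
  expect_identical(f3$cycle, "sen")
  expect_true(f3$onset)
  expect_error(next_cell_fate("A", "nta", params = p, l = 10), "type B")
})

test_that("cell-state invariants are enforced", {
  L <- matrix(100L, 2, 16)
  expect_error(cell_state(L, type = "A", ever_nta = TRUE), "type-A")
  expect_error(cell_state(L, type = "A", cycle = "nta"), "type B")
  s <- cell_state(L, type = "B", cycle = "sen", generation = 5L)
  expect_identical(s$generation, 5L)
})
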