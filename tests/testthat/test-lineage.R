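test_that("a founder at the threshold senesces at generation 1 and dies at once when p_death = 1", {
  p <- law_params(p_accident = 0, p_death = 1)
  set.seed(1)
  for (rep in 1:10) {
    rec <- simulate_lineage(p, point_dist(27), constant_bank())
    expect_identical(rec$gen_sen, 1L)
    expect_identical(rec$gen_death, 1L)
    expect_identical(rec$death_cause, "senescence")
    expect_identical(sum(rec$cycles$cycle_type == "sen"), 1L)
  }
})

test_that("immortal parameters truncate at the generation cap", {
  set.seed(2)
  rec <- simulate_lineage(immortal_params(), point_dist(5000), constant_bank(),
                          max_generations = 40L)
  expect_true(rec$truncated)
  expect_identical(rec$gen_death, 40L)
  expect_true(all(rec$cycles$cycle_type == "nor"))
  # shortest telomere is non-increasing along the recorded lineage
  expect_true(all(diff(rec$cycles$shortest_bp) <= 0))
})

test_that("duration-only classification separates visible from hidden arrests", {
  mk <- function(durs, types) {
    list(cycles = data.frame(duration_min = durs, cycle_type = types))
  }
  # long cycle later followed by a normal one: observed B
  r1 <- mk(c(90, 95, 250, 92, 300, 310), c("nor", "nor", "nta", "nor", "sen", "sen"))
  expect_identical(classify_lineage(r1)$observed_type, "B")
  # terminal-only arrests: observed A
  r2 <- mk(c(90, 95, 200, 250), c("nor", "nor", "sen", "sen"))
  cl2 <- classify_lineage(r2)
  expect_identical(cl2$observed_type, "A")
  expect_false(cl2$is_M)
  # an nta sequence running directly into senescence and death: observed A
  # but ground-truth type B, i.e. the misclassified type M
  r3 <- mk(c(90, 95, 250, 300, 310), c("nor", "nor", "nta", "nta", "sen"))
  cl3 <- classify_lineage(r3)
  expect_identical(cl3$observed_type, "A")
  expect_true(cl3$is_M)
})

test_that("without the nta channel every lineage stays pure type A", {
  p <- law_params(b_nta = 0, p_accident = 0)
  set.seed(3)
  recs <- simulate_lineages(300, p, initial_distribution(), test_bank())
  expect_true(all(is.na(recs$gen_first_nta)))
  expect_true(all(recs$observed_type == "A"))
  expect_true(all(!recs$is_M))
  expect_true(all(recs$death_cause == "senescence"))
})

test_that("arrest-generation curves are sorted and partition consistently", {
  recs <- data.frame(
    gen_first_nta = c(2L, NA, 4L),
    gen_sen = c(5L, 3L, 8L),
    observed_type = c("B", "A", "B"))
  cv <- arrest_generation_curves(recs)
  expect_identical(cv$sen, c(3L, 5L, 8L))
  expect_identical(cv$nta, c(2L, 4L))
  expect_identical(cv$sen_A, 3L)
  expect_identical(cv$sen_B, c(5L, 8L))

  set.seed(4)
  sim <- simulate_lineages(400, law_params(), initial_distribution(), test_bank())
  cv2 <- arrest_generation_curves(sim)
  # union identity: sen is the multiset union of sen_A and sen_B
  expect_identical(sort(c(cv2$sen_A, cv2$sen_B)), cv2$sen)
  expect_true(all(diff(cv2$nta) >= 0))
  expect_equal(attr(cv2, "prop_B"), mean(sim$observed_type == "B"))
})

test_that("first non-terminal arrests precede type-A senescence onsets", {
  set.seed(5)
  recs <- simulate_lineages(600, law_params(), initial_distribution(), test_bank())
  senA <- recs$gen_sen[recs$observed_type == "A" & !is.na(recs$gen_sen)]
  expect_lt(median(recs$gen_first_nta, na.rm = TRUE), median(senA))
})

test_that("the compiled batch path agrees with the pure-R reference path", {
  p <- law_params()
  d <- initial_distribution()
  b <- test_bank()
  set.seed(6)
  batch <- simulate_lineages(600, p, d, b)
  set.seed(7)
  ref <- replicate(250, {
    r <- simulate_lineage(p, d, b)
    c(B = r$observed_type == "B", death = r$gen_death,
      sen = if (is.na(r$gen_sen)) NA_real_ else r$gen_sen)
  })
  pB_batch <- mean(batch$observed_type == "B")
  pB_ref <- mean(ref["B", ])
  se <- sqrt(pB_ref * (1 - pB_ref) * (1 / 600 + 1 / 250))
  expect_lt(abs(pB_batch - pB_ref), 4 * se)
  expect_lt(abs(median(batch$gen_death) - median(ref["death", ])), 4)
})

test_that("raising accidental mortality shortens lineages monotonically", {
  set.seed(8)
  scan <- run_mortality_scan(c(5, 20), mode = "lineage",
                             dist = initial_distribution(),
                             bank = test_bank(),
                             n_lineages = 11, n_experiments = 40, seed = 80)
  expect_identical(scan$multiplier, c(1, 5, 20))
  expect_true(all(diff(scan$median_onset_gen) <= 0))
})
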