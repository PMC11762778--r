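test_that("division shortens exactly one end per chromosome, coupled between daughters", {
  set.seed(1)
  parent <- matrix(sample(100:400, 32, replace = TRUE), 2, 16)
  h <- 7
  for (rep in 1:20) {
    d <- divide_telomeres(parent, h)
    # conservation: per chromosome, total shortening across daughters is 2h
    expect_equal(colSums(d$daughter1) + colSums(d$daughter2),
                 2 * colSums(parent) - 2 * h)
    # per daughter, each chromosome loses exactly h, from one end only
    cut1 <- parent - d$daughter1
    cut2 <- parent - d$daughter2
    expect_true(all(colSums(cut1) == h))
    expect_true(all(colSums(cut2) == h))
    expect_true(all(cut1 %in% c(0, h)))
    # coupling: the end shortened in daughter 1 is intact in daughter 2
    expect_true(all(cut1 + cut2 == h))
  }
})

test_that("forced update equations hold for each Bernoulli outcome", {
  # brute force over B in {0, 1}: chromosome (100, 200), h = 7 must yield
  # the complementary pair {(93,200),(100,193)} in one order or the other
  parent <- matrix(c(100L, 200L), 2, 16)
  set.seed(2)
  for (rep in 1:10) {
    d <- divide_telomeres(parent, 7)
    for (j in 1:16) {
      pair <- list(d$daughter1[, j], d$daughter2[, j])
      expect_true(
        (identical(pair[[1]], c(93L, 200L)) && identical(pair[[2]], c(100L, 193L))) ||
        (identical(pair[[1]], c(100L, 193L)) && identical(pair[[2]], c(93L, 200L))))
    }
  }
})

test_that("zero overhang is the identity and lengths clamp at zero", {
  parent <- matrix(sample(0:50, 32, replace = TRUE), 2, 16)
  d0 <- divide_telomeres(parent, 0)
  expect_identical(d0$daughter1, as_telomere_matrix(parent))
  expect_identical(d0$daughter2, as_telomere_matrix(parent))
  short <- matrix(c(3L, 200L), 2, 16)
  set.seed(3)
  for (rep in 1:10) {
    d <- divide_telomeres(short, 7)
    expect_true(all(d$daughter1 >= 0) && all(d$daughter2 >= 0))
    # the short end is either kept at 3 or clamped at 0 (3 - 7 -> 0)
    expect_true(all(d$daughter1 %in% c(0L, 3L, 193L, 200L)))
  }
})

test_that("telomere lengths are non-increasing along a lineage and shorten by h/2 on average", {
  set.seed(4)
  L <- matrix(10000L, 2, 16)
  n_gen <- 400
  track <- numeric(n_gen)
  for (g in seq_len(n_gen)) {
    d <- divide_telomeres(L, 7)
    new_L <- if (runif(1) < 0.5) d$daughter1 else d$daughter2
    expect_true(all(new_L <= L))
    L <- new_L
    track[g] <- L[1, 1]
  }
  # fixed telomere: loses h with prob 1/2 each division
  loss <- 10000 - track[n_gen]
  se <- 7 * sqrt(n_gen * 0.25)
  expect_lt(abs(loss - n_gen * 3.5), 3 * se)
})

test_that("invalid division inputs are rejected", {
  expect_error(divide_telomeres(matrix(1L, 3, 16), 7), "2 x 16")
  expect_error(divide_telomeres(matrix(-1L, 2, 16), 7), "non-negative")
  expect_error(divide_telomeres(matrix(1L, 2, 16), -1), "non-negative")
})

test_that("dilation maps support endpoints and preserves the mode", {
  d <- initial_distribution(l_inf = 100, l_mode = 300, l_sup = 500,
                            l_0 = 40, l_1 = 58, l_trans = 0)
  expect_identical(transform_length(c(100, 300, 500), d), c(140L, 300L, 358L))
  # identity map
  id <- initial_distribution(l_0 = 0, l_1 = 200, l_trans = 0)
  x <- seq(100, 500, by = 25)
  expect_identical(transform_length(x, id), as.integer(x))
  # the mode maps to l_mode + l_trans for any dilation
  for (l0 in c(-50, 0, 80)) for (l1 in c(20, 58, 300)) {
    dd <- initial_distribution(l_0 = l0, l_1 = l1, l_trans = -12)
    expect_identical(transform_length(300, dd), 288L)
  }
})

test_that("degenerate dilation parameters and out-of-support inputs error", {
  expect_error(initial_distribution(l_0 = 200), "collapses")
  expect_error(initial_distribution(l_0 = 250), "collapses")
  d <- initial_distribution()
  expect_error(transform_length(90, d), "within")
  expect_error(initial_distribution(l_inf = 400, l_mode = 300), "l_inf <= l_mode")
})

test_that("initial matrices are 2 x 16, translation-coupled under a shared seed", {
  d <- point_dist(300)
  L <- sample_initial_matrix(d)
  expect_identical(dim(L), c(2L, 16L))
  expect_true(all(L == 300L))

  d0 <- initial_distribution(l_trans = 0)
  dm <- initial_distribution(l_trans = -20)
  set.seed(7); a <- sample_initial_matrix(d0)
  set.seed(7); b <- sample_initial_matrix(dm)
  expect_identical(a - b, matrix(20L, 2, 16))
})

test_that("sampled lengths follow the transformed distribution (two-sample test)", {
  d <- initial_distribution()
  set.seed(8)
  drawn <- sample_initial_lengths(32000, d)
  # independent oracle: push beta quantiles through the piecewise map directly
  u <- runif(32000)
  base <- d$l_inf + (d$l_sup - d$l_inf) * qbeta(u, d$shape1, d$shape2)
  left <- base <= d$l_mode
  oracle <- ifelse(left,
                   d$l_inf + d$l_0 + (base - d$l_inf) * (200 - d$l_0) / 200,
                   d$l_mode + (base - d$l_mode) * d$l_1 / 200)
  ks <- suppressWarnings(ks.test(drawn, round(oracle)))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(drawn >= 140 & drawn <= 358))
})
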