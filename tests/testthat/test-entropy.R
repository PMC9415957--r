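test_that("min-subtraction yields a nonnegative series and records the offset", {
  cases <- list(
    list(input = c(-2, 0, 3), values = c(0, 2, 5), offset = -2),
    list(input = c(0, 1, 2), values = c(0, 1, 2), offset = 0),
    list(input = c(5, 5, 5), values = c(0, 0, 0), offset = 5)
  )
  for (cs in cases) {
    out <- to_positive_series(cs$input)
    expect_equal(out$values, cs$values)
    expect_equal(out$offset, cs$offset)
    expect_equal(min(out$values), 0)
  }
  expect_error(to_positive_series(c(1, NA, 2)), "non-finite")
  expect_error(to_positive_series(c(1, Inf, 2)), "non-finite")
  expect_error(to_positive_series(3), "at least 2")
})

test_that("Poincare points pair each sample with its lagged successor", {
  pts <- poincare_points(c(0, 2, 5), delay = 1)
  expect_equal(unname(pts), cbind(c(0, 2), c(2, 5)))
  expect_equal(nrow(poincare_points(c(1, 2), 1)), 1L)
  expect_equal(nrow(poincare_points(1:10, 3)), 7L)
  expect_equal(unname(poincare_points(1:10, 3)[, 2]), 4:10)
  expect_error(poincare_points(c(1, 2), 2), "exceed")
})

test_that("sector-ring binning uses half-open rings with a closed outer ring", {
  # all points on the outer boundary fall in the closed last ring
  pts <- cbind(rep(3, 4), rep(4, 4))
  part <- ring_partition(pts, 5)
  expect_equal(part$l_max, 5)
  expect_equal(part$counts, c(0, 0, 0, 0, 4))
  expect_equal(part$p, c(0, 0, 0, 0, 1))

  # boundary point 0.5 goes to ring 2 (half-open), max-distance point to ring 5
  d <- c(0.4, 0.5, 1.2, 2.5)
  part <- ring_partition(cbind(d, 0), 5)
  expect_equal(part$l_max, 2.5)
  expect_equal(part$counts, c(1, 1, 1, 0, 1)) # frozen from the per-point loop oracle
  expect_equal(sum(part$p), 1)
  expect_error(ring_partition(cbind(d, 0), 0), "rings")
})

test_that("occupancy probabilities are a distribution on random inputs", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(10:300, 1)
    w <- sample(1:60, 1)
    x <- to_positive_series(rnorm(n))$values
    part <- ring_partition(poincare_points(x, 1), w)
    expect_equal(sum(part$counts), n - 1L)
    expect_equal(sum(part$p), 1)
    expect_true(all(part$p >= 0 & part$p <= 1))
    expect_equal(part$radii[w], part$l_max)
    expect_true(all(diff(part$radii) > 0) || w == 1)
  }
})

test_that("distribution entropy matches direct summation and its bounds", {
  p <- c(1 / 15, 2 / 15, 1 / 5, 4 / 15, 1 / 3)
  part <- ring_partition(points_for_p(p, l_max = 10, n_points = 15), 5)
  expect_equal(part$p, p)
  expect_equal(distribution_entropy(part), 1.4897503, tolerance = 1e-6)

  # uniform occupancy attains log(W)
  part_u <- ring_partition(points_for_p(rep(1 / 8, 8), 4, 8), 8)
  expect_equal(distribution_entropy(part_u), log(8))

  # concentrated occupancy scores 0
  part_c <- ring_partition(points_for_p(c(0, 0, 0, 0, 1), 5, 10), 5)
  expect_equal(distribution_entropy(part_c), 0)

  # degenerate partition (constant series) scores 0
  part_d <- ring_partition(cbind(c(0, 0), c(0, 0)), 5)
  expect_true(part_d$degenerate)
  expect_equal(distribution_entropy(part_d), 0)
})

test_that("Tsallis entropy evaluates its closed form and rejects q = 1", {
  expect_equal(tsallis_entropy(c(0.5, 0.5), 2), 0.5)
  expect_equal(tsallis_entropy(1, 3), 0)
  expect_equal(tsallis_entropy(rep(0.25, 4), 3), 0.46875)
  expect_error(tsallis_entropy(c(0.5, 0.5), 1), "Shannon")
  expect_error(tsallis_entropy(c(0.7, 0.7), 2), "sum to 1")
})

test_that("nonextensive parameters are reverse-subtracted ring-center distances", {
  part <- ring_partition(points_for_p(rep(0.2, 5), 10, 10), 5)
  expect_equal(nonextensive_params(part), c(10, 8, 6, 4, 2))

  part1 <- ring_partition(points_for_p(1, 2, 4), 1)
  expect_equal(nonextensive_params(part1), 2)

  set.seed(7)
  for (i in 1:20) {
    w <- sample(2:80, 1)
    x <- to_positive_series(rnorm(50))$values
    part <- ring_partition(poincare_points(x, 1), w)
    q <- nonextensive_params(part)
    expect_true(all(diff(q) < 0))
    expect_equal(min(q), 1 + part$dl / 2)
    expect_true(all(q > 1))
  }

  degen <- ring_partition(cbind(0, 0), 5)
  expect_error(nonextensive_params(degen), "degenerate")
})

test_that("NNE evaluates per-ring terms and recovers Shannon in the q -> 1 limit", {
  expect_equal(nne(c(0.5, 0.5), c(2, 3)), 0.4375) # 0.25 + 0.1875, by hand
  expect_equal(nne(c(1, 0, 0), c(5, 3, 2)), 0)
  p <- c(0.1, 0.2, 0.3, 0.4)
  expect_equal(nne(p, rep(1 + 1e-6, 4)), -sum(p * log(p)), tolerance = 1e-4)
  # within 1e-8 of 1 the limit form takes over without blowing up
  expect_equal(nne(p, rep(1 + 1e-12, 4)), -sum(p * log(p)), tolerance = 1e-8)
  expect_error(nne(c(0.5, 0.5), 2), "equal length")
  expect_error(nne(c(0.5, 0.5), c(0.5, 2)), ">= 1")
})

test_that("NDE separates distributions that DE cannot", {
  p_fwd <- c(1 / 15, 2 / 15, 1 / 5, 4 / 15, 1 / 3)
  p_rev <- rev(p_fwd)
  part_fwd <- ring_partition(points_for_p(p_fwd, 10, 15), 5)
  part_rev <- ring_partition(points_for_p(p_rev, 10, 15), 5)
  q <- nonextensive_params(part_fwd)
  expect_equal(q, c(10, 8, 6, 4, 2))

  # identical DE, different NDE (expected values from term-by-term evaluation)
  expect_equal(distribution_entropy(part_fwd), distribution_entropy(part_rev))
  expect_equal(nne(part_fwd$p, q), 0.3758677, tolerance = 1e-6)
  expect_equal(nne(part_rev$p, q), 0.2216753, tolerance = 1e-6)

  # permuting a non-uniform occupancy never changes DE, generally changes NNE
  set.seed(33)
  for (i in 1:10) {
    p <- as.numeric(rmultinom(1, 60, runif(5))) / 60
    perm <- sample(5)
    expect_equal(shannon <- -sum(p[p > 0] * log(p[p > 0])),
                 -sum(p[perm][p[perm] > 0] * log(p[perm][p[perm] > 0])))
    if (!identical(p[perm], p)) {
      expect_false(isTRUE(all.equal(nne(p, q), nne(p[perm], q))))
    }
  }
})

test_that("NDE is shift-invariant, amplitude-sensitive, and 0 for constants", {
  set.seed(9)
  s <- cumsum(rnorm(400))
  expect_identical(poincare_nde(s + 17.3, 30), poincare_nde(s, 30))
  expect_identical(poincare_nde(s - 5, 30), poincare_nde(s, 30))
  # DE is exactly scale-invariant (rings scale with l_max), NDE is not
  expect_equal(poincare_de(3 * s, 40), poincare_de(s, 40))
  expect_false(isTRUE(all.equal(poincare_nde(3 * s, 30), poincare_nde(s, 30))))
  expect_equal(poincare_nde(rep(4.2, 100), 50), 0)
  expect_true(poincare_nde(s, 30) >= 0)

  det <- poincare_nde(s, 30, details = TRUE)
  expect_equal(det$method, "NDE")
  expect_equal(det$value, poincare_nde(s, 30))
  expect_equal(det$offset, min(s))
})

test_that("NDE equals the brute-force reference on random series", {
  set.seed(21)
  for (i in 1:20) {
    s <- rnorm(sample(50:250, 1), sd = runif(1, 0.5, 20))
    w <- sample(2:40, 1)
    expect_equal(poincare_nde(s, w), nde_bruteforce(s, w), tolerance = 1e-12)
  }
})

test_that("DE stays within [0, log W] on random series", {
  set.seed(57)
  for (i in 1:20) {
    s <- cumsum(rnorm(200))
    w <- sample(2:60, 1)
    de <- poincare_de(s, w)
    expect_true(de >= 0 && de <= log(w) + 1e-12)
  }
})
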