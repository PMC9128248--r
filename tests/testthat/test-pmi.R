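# Part mutual information core: discretization, joint estimation, partially
# conditioned marginals, extended KL, and the assembled PMI estimator.

test_that("discretization maps samples to the expected bins", {
  expect_equal(discretize(c(1, 2, 3, 4), n_bins = 2)$bins, c(1L, 1L, 2L, 2L))
  expect_equal(discretize(c(0, 0.1, 0.9, 1.0), n_bins = 2,
                          scheme = "equal_width")$bins, c(1L, 1L, 2L, 2L))
  set.seed(42)
  b <- discretize(rnorm(1000), n_bins = 4)$bins
  expect_true(all(abs(tabulate(b, 4) - 250) <= 1))
  expect_error(discretize(rep(1, 10)), "degenerate")
  expect_error(discretize(1:4, n_bins = 1), "n_bins")
})

test_that("joint estimation yields empirical relative frequencies", {
  j <- estimate_joint(c(0, 0, 1, 1), c(0, 0, 1, 1), n_bins = 2,
                      scheme = "equal_width")
  expect_equal(j$p_xyz[, , 1], matrix(c(0.5, 0, 0, 0.5), 2))
  j2 <- estimate_joint(c(0, 1, 0, 1), c(0, 0, 1, 1), n_bins = 2,
                       scheme = "equal_width")
  expect_equal(c(j2$p_xyz), rep(0.25, 4))
  set.seed(1)
  j3 <- estimate_joint(rnorm(100), rnorm(100), rnorm(100), n_bins = 3)
  expect_equal(sum(j3$p_xyz), 1, tolerance = 1e-9)
  expect_true(all(j3$p_xyz >= 0))
  # marginals over each axis are probability vectors
  for (ax in 1:3) expect_equal(sum(apply(j3$p_xyz, ax, sum)), 1,
                               tolerance = 1e-9)
  expect_error(estimate_joint(1:4, 1:3), "length mismatch")
})

test_that("partially conditioned marginals match direct summation", {
  # independent X, Y with constant Z: p*(x|z) = p(x)
  set.seed(2)
  x <- rnorm(400); y <- rnorm(400)
  j <- estimate_joint(x, y, n_bins = 3)
  px <- apply(j$p_xyz, 1, sum)
  expect_equal(drop(star_conditional(j, "x")$table), px, tolerance = 1e-12)
  # perfectly dependent binary uniform pair, constant z
  j2 <- estimate_joint(c(0, 0, 1, 1), c(0, 0, 1, 1), n_bins = 2,
                       scheme = "equal_width")
  expect_equal(drop(star_conditional(j2, "x")$table), c(0.5, 0.5))
  # deterministic Z = X, Y independent: p*(x|z) = 1 iff x = z
  x <- rep(c(0, 1), each = 8)
  y <- rep(c(0, 1, 0, 1), 4)
  j3 <- estimate_joint(x, y, z = x, n_bins = 2, scheme = "equal_width")
  expect_equal(star_conditional(j3, "x")$table, diag(2))
  # random joints: modular vs brute-force direct summation
  set.seed(3)
  for (rep in 1:5) {
    p <- array(runif(12), dim = c(2, 3, 2)); p <- p / sum(p)
    j4 <- list(p_xyz = p)
    class(j4) <- "discrete_joint"
    expect_equal(star_conditional(j4, "x")$table, star_brute_force(p, "x"),
                 tolerance = 1e-12)
    expect_equal(star_conditional(j4, "y")$table, star_brute_force(p, "y"),
                 tolerance = 1e-12)
  }
})

test_that("extended KL divergence follows its closed forms", {
  expect_equal(extended_kl(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(extended_kl(c(1, 0), c(0.5, 0.5)), log(2))
  # unnormalized q is allowed
  expect_equal(extended_kl(c(0.5, 0.5), c(0.25, 0.25)), log(2))
  expect_identical(extended_kl(c(0.5, 0.5), c(0.5, 0)), Inf)
  expect_error(extended_kl(c(1, 0), c(0.5, 0.5, 0)), "shape")
})

test_that("PMI reproduces closed-form and null cases", {
  x <- rep(c(0, 1), each = 10)
  expect_equal(pmi(x, x, n_bins = 2), log(2), tolerance = 1e-12)
  set.seed(4)
  a <- rnorm(2000); b <- rnorm(2000); c0 <- rnorm(2000)
  expect_lt(abs(pmi(a, b, c0)), 0.05)
  expect_error(pmi(rep(1, 20), rnorm(20)), "degenerate")
})

test_that("PMI is symmetric in its first two arguments", {
  set.seed(5)
  for (rep in 1:10) {
    x <- rnorm(150); y <- x * runif(1, -1, 1) + rnorm(150)
    z <- y + rnorm(150)
    expect_equal(pmi(x, y, z), pmi(y, x, z), tolerance = 1e-12)
    expect_equal(pmi(x, y, z, scheme = "gaussian"),
                 pmi(y, x, z, scheme = "gaussian"), tolerance = 1e-9)
  }
})

test_that("modular pipeline equals brute-force summation on 2x2x2 joints", {
  # small version of the exhaustive acceptance grid
  set.seed(6)
  for (rep in 1:25) {
    counts <- array(sample(0:4, 8, replace = TRUE), dim = c(2, 2, 2))
    if (sum(counts) == 0) next
    p <- counts / sum(counts)
    samples <- expand_joint_to_samples(p, n = sum(counts))
    if (length(unique(samples$x)) < 2 || length(unique(samples$y)) < 2 ||
        length(unique(samples$z)) < 2) next
    modular <- pmi(samples$x, samples$y, samples$z, n_bins = 2,
                   scheme = "equal_width")
    expect_equal(modular, pmi_brute_force(p), tolerance = 1e-9)
  }
})

test_that("independence null shrinks with sample size", {
  est <- function(n, seeds) {
    vapply(seeds, function(s) {
      set.seed(s)
      pmi(rnorm(n), rnorm(n), rnorm(n))
    }, numeric(1))
  }
  expect_lt(median(est(5000, 1:50)), median(est(200, 1:50)))
})

test_that("conditioning on the mediator suppresses an indirect pair", {
  ratios <- vapply(1:20, function(s) {
    expr <- make_chain(2000, noise_sd = 0.5, seed = s)
    pmi(expr["g1", ], expr["g3", ], expr["g2", ], scheme = "gaussian") /
      pmi(expr["g1", ], expr["g3", ], scheme = "gaussian")
  }, numeric(1))
  expect_gte(mean(ratios < 0.2), 0.9)
})

test_that("gaussian scheme matches Gaussian MI and vanishes under CI", {
  set.seed(7)
  x <- rnorm(500); y <- 0.7 * x + rnorm(500)
  expect_equal(pmi(x, y, scheme = "gaussian"),
               -0.5 * log(1 - cor(x, y)^2), tolerance = 1e-12)
  # exact conditional independence given z
  z <- rnorm(5000)
  x2 <- z + rnorm(5000); y2 <- -z + rnorm(5000)
  expect_lt(pmi(x2, y2, z, scheme = "gaussian"), 0.01)
  # +Inf sentinel on a singular pair
  expect_identical(pmi(x, 2 * x + 1, scheme = "gaussian"), Inf)
})

test_that("Laplace pseudocounts smooth empty cells", {
  j <- estimate_joint(c(0, 0, 1, 1), c(0, 0, 1, 1), n_bins = 2,
                      scheme = "equal_width", alpha = 1)
  expect_true(all(j$p_xyz > 0))
  expect_equal(sum(j$p_xyz), 1, tolerance = 1e-12)
})
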