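test_that("density-to-density TV matches the equal-variance normal closed form", {
  f <- std_normal()
  for (mu in c(0, 0.5, 2)) {
    g <- parametric_model("normal", c(mu, 1))
    expect_equal(dist_value(tv_density_density(f, g, nq_grid(-9, 9 + mu, 16384))),
                 2 * pnorm(mu / 2) - 1, tolerance = 1e-6)
  }
})

test_that("density-to-density TV of the half-half far mixture reduces analytically", {
  mix <- mixture_two(0.5, 5)
  v <- dist_value(tv_density_density(mix, std_normal()))
  expect_equal(v, 0.5 * (2 * pnorm(2.5) - 1), tolerance = 1e-6)
})

test_that("a grid missing mass is flagged in the diagnostics", {
  res <- tv_density_density(std_normal(), parametric_model("normal", c(0, 2)),
                            nq_grid(-2, 2, 512))
  expect_false(is.null(res$meta$coverage_warning))
})

test_that("sample-vs-model TV shrinks on nested samples from the model", {
  set.seed(61)
  x <- rnorm(5000)
  m <- std_normal()
  vals <- sapply(c(200, 1000, 5000), function(n)
    dist_value(tv_sample_model(x[1:n], m)))
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[3], 0.06)
})

test_that("sample-vs-model TV ignores sample order and honours a numeric bandwidth", {
  set.seed(62)
  x <- rnorm(400)
  m <- std_normal()
  expect_equal(dist_value(tv_sample_model(x, m)),
               dist_value(tv_sample_model(rev(x), m)))
  res <- tv_sample_model(x, m, bandwidth = 0.25)
  expect_equal(res$meta$bandwidth, 0.25)
  expect_error(tv_sample_model(rep(2, 50), m), "spread")
})

test_that("two-sample KL is zero at identity, nonnegative, and finite on disjoint samples", {
  set.seed(63)
  x <- rnorm(300)
  expect_equal(dist_value(kl_sample_sample(x, x)), 0, tolerance = 1e-12)
  for (i in 1:20) {
    a <- rnorm(100); b <- rnorm(100, runif(1, -2, 2))
    expect_gte(dist_value(kl_sample_sample(a, b)), 0)
  }
  # two-bin toy with disjoint samples: value is large but bounded by the
  # smoothing scale log(1 + n/alpha)
  a <- rep(0, 50); b <- rep(1, 50)
  v <- dist_value(kl_sample_sample(a, b, n_bins = 2, alpha = 0.5))
  q <- c(0.5, 50.5) / 51; p <- c(50.5, 0.5) / 51
  expect_equal(v, sum(q * log(q / p)))
  expect_lt(v, log(1 + 50 / 0.5))
  expect_error(kl_sample_sample(a, b, n_bins = 1), "bins")
  expect_error(kl_sample_sample(numeric(0), b), "nonempty")
})

test_that("total variation is invariant under monotone transformations of densities", {
  f <- std_normal(); g <- parametric_model("normal", c(1, 1))
  affine <- nq_transform(function(x) 2 * x + 1, function(y) (y - 1) / 2,
                         function(y) 0.5, "affine")
  res <- tv_invariance_check(f, g, affine)
  expect_equal(dist_value(res$original), dist_value(res$transformed),
               tolerance = 1e-6)
  expmap <- nq_transform(exp, log, function(y) 1 / y, "exp",
                         check_range = c(-5, 5))
  res2 <- tv_invariance_check(f, g, expmap, grid = nq_grid(-5.5, 5.5, 16384))
  expect_lt(abs(dist_value(res2$original) - dist_value(res2$transformed)), 1e-4)
  ident <- nq_transform(identity, identity, function(y) 1, "identity")
  res3 <- tv_invariance_check(f, g, ident)
  expect_identical(dist_value(res3$original), dist_value(res3$transformed))
  expect_error(nq_transform(function(x) x^2, sqrt, function(y) 0.5 / sqrt(y)),
               "monotone")
})

test_that("sample-based invariance holds approximately after re-smoothing", {
  set.seed(64)
  x <- rnorm(2000, 1, 1)
  affine <- nq_transform(function(x) 2 * x + 1, function(y) (y - 1) / 2,
                         function(y) 0.5, "affine")
  res <- tv_invariance_check(x, std_normal(), affine)
  expect_equal(dist_value(res$original), dist_value(res$transformed),
               tolerance = 0.02)
})

test_that("without smoothing, discrete-vs-continuous TV is maximal", {
  # empirical measure on two atoms vs N(0,1), compared on an ever finer
  # common discretisation: the distance climbs to 1
  atoms <- c(0, 1)
  tv_at_width <- function(w) {
    breaks <- seq(-6, 6, by = w)
    mids <- head(breaks, -1) + w / 2
    emp <- sapply(atoms, function(a) findInterval(a, breaks))
    d <- rep(0, length(mids)); d[emp] <- 0.5
    model_mass <- diff(pnorm(breaks)) / (pnorm(6) - pnorm(-6))
    dist_value(total_variation(prob_vector(d), prob_vector(model_mass)))
  }
  coarse <- tv_at_width(0.5)
  fine <- tv_at_width(1e-4)
  expect_gt(fine, coarse)
  expect_gt(fine, 0.999)
})

test_that("scaled product-measure TV is zero at equality and tracks the Fisher limit locally", {
  expect_identical(fisher_local_tv("poisson", 1, 1, n = 100)$value, 0)
  res <- fisher_local_tv("poisson", 1, 1.003, n = 1e4, reps = 1500, seed = 65)
  expect_lt(abs(res$value - res$limit), 3 * res$se)
  resn <- fisher_local_tv("normal", 0, 0.003, n = 1e4, reps = 1500, seed = 66)
  expect_lt(abs(resn$value - resn$limit), 3 * resn$se)
  expect_equal(resn$limit, 0.003 * sqrt(1 / (2 * pi)))
})
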