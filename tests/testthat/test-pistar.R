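test_that("fixed-model pi* matches the sup formula and reconstructs tau", {
  res <- pistar_fixed_discrete(c(0.7, 0.3), c(0.5, 0.5))
  expect_equal(res$pi_star, 0.4)
  expect_equal(res$achieving_point, 1)
  recon <- (1 - res$pi_star) * c(0.5, 0.5) +
    res$pi_star * as.numeric(res$residual)
  expect_equal(recon, c(0.7, 0.3), tolerance = 1e-10)
  expect_equal(pistar_fixed_discrete(c(0.5, 0.5), c(0.5, 0.5))$pi_star, 0)
})

test_that("a zero-tau cell under positive model mass forces pi* = 1", {
  expect_equal(pistar_fixed_discrete(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5))$pi_star, 1)
  set.seed(31)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    tau <- as.numeric(rprob_vector(k)); tau[sample(k, 1)] <- 0
    tau <- tau / sum(tau)
    m <- as.numeric(rprob_vector(k, concentration = 5))  # strictly positive
    expect_equal(pistar_fixed_discrete(tau, m)$pi_star, 1)
  }
})

test_that("pi* reconstruction yields a valid residual touching zero", {
  set.seed(32)
  for (i in 1:50) {
    k <- sample(2:10, 1)
    tau <- rprob_vector(k); m <- rprob_vector(k)
    res <- pistar_fixed_discrete(tau, m)
    if (res$pi_star > 0 && res$pi_star < 1) {
      e <- as.numeric(res$residual)
      expect_true(all(e >= 0))
      expect_equal(sum(e), 1, tolerance = 1e-10)
      recon <- (1 - res$pi_star) * as.numeric(m) + res$pi_star * e
      expect_equal(recon, as.numeric(tau), tolerance = 1e-10)
      expect_lt(min(e), 1e-10)  # binds at the achieving cell
    }
  }
})

test_that("feasibility-scan oracle agrees with the closed form", {
  expect_equal(pistar_oracle(c(0.7, 0.3), c(0.5, 0.5)), 0.4, tolerance = 1e-6)
  expect_equal(pistar_oracle(c(0.5, 0.5), c(0.5, 0.5)), 0)
  set.seed(33)
  for (i in 1:40) {
    k <- sample(2:12, 1)
    tau <- rprob_vector(k); m <- rprob_vector(k)
    expect_equal(pistar_oracle(tau, m),
                 pistar_fixed_discrete(tau, m)$pi_star, tolerance = 2e-6)
  }
})

test_that("total variation is bounded by pi*", {
  set.seed(34)
  for (i in 1:200) {
    k <- sample(2:10, 1)
    tau <- rprob_vector(k); m <- rprob_vector(k)
    expect_lte(dist_value(total_variation(tau, m)),
               pistar_fixed_discrete(tau, m)$pi_star + 1e-12)
  }
})

test_that("pi* recovers the contamination fraction when outliers sit on model-free cells", {
  set.seed(35)
  for (eps in c(0.05, 0.2, 0.5)) {
    m <- c(as.numeric(rprob_vector(4, 3)), 0, 0)
    e <- c(0, 0, 0, 0, 0.6, 0.4)
    tau <- (1 - eps) * m + eps * e
    expect_equal(pistar_fixed_discrete(tau, m)$pi_star, eps, tolerance = 1e-12)
    expect_equal(pistar_oracle(tau, m), eps, tolerance = 2e-6)
  }
})

test_that("pi* is not robust: removing a sliver of mass jumps it to 1", {
  delta <- 1e-3
  m <- c(delta, (1 - delta) / 2, (1 - delta) / 2)
  tau_before <- m
  tau_after <- c(0, m[2] + delta / 2, m[3] + delta / 2)
  expect_equal(pistar_fixed_discrete(tau_before, m)$pi_star, 0)
  expect_equal(pistar_fixed_discrete(tau_after, m)$pi_star, 1)
  expect_equal(dist_value(total_variation(tau_after, m)), delta,
               tolerance = 1e-12)  # TV hardly moved
})

test_that("W index equals V/(1+V) and agrees with V to first order", {
  expect_equal(w_index(c(0.7, 0.3), c(0.5, 0.5)), 1 / 6)
  expect_equal(w_index(c(1, 0), c(0, 1)), 1 / 2)
  set.seed(36)
  for (i in 1:100) {
    pr <- random_pair()
    v <- dist_value(total_variation(pr$tau, pr$m))
    w <- w_index(pr$tau, pr$m)
    expect_gte(w, 0); expect_lte(w, 0.5)
    expect_lte(abs(w - v), v^2 + 1e-12)
  }
})

test_that("continuous pi* against the true model shrinks with sample size", {
  m <- std_normal()
  set.seed(37)
  x <- rnorm(4000)
  p_small <- pistar_fixed_continuous(x[1:300], m)$pi_star
  p_large <- pistar_fixed_continuous(x, m)$pi_star
  expect_lt(p_large, p_small)
  expect_lt(p_large, 0.15)
})

test_that("continuous pi* tracks epsilon from above for a far-separated contaminant", {
  # the grid supremum over a noisy density ratio overestimates the
  # contamination fraction: cells near the density floor carry ~30% relative
  # kernel noise at this n, inflating the supremum by up to ~0.2
  set.seed(38)
  eps <- 0.3
  x <- c(rnorm(2800), rnorm(1200, 10))
  res <- pistar_fixed_continuous(x, std_normal())
  expect_gte(res$pi_star, eps - 0.02)
  expect_lte(res$pi_star, eps + 0.2)
})

test_that("light tails give pi* = 1 without the data-range/floor restriction", {
  set.seed(39)
  x <- rnorm(2000)                      # lighter-tailed than N(0, 3^2)
  m <- parametric_model("normal", c(0, 3))
  k <- kde(x)
  far <- seq(6, 12, length.out = 50)    # far outside the data
  unrestricted_sup <- max(1 - predict(k, far) / model_pdf(m, far))
  expect_gt(unrestricted_sup, 0.999)
  restricted <- pistar_fixed_continuous(x, m)$pi_star
  expect_lt(restricted, unrestricted_sup)
  expect_lt(restricted, 0.97)
})

test_that("family minimisation beats the initial model and finds the main component", {
  set.seed(40)
  x <- c(rnorm(1500, 0.3, 1.1), rnorm(1500, 10))
  fixed <- pistar_fixed_continuous(x, std_normal())$pi_star
  fam <- pistar_family(x, seed = 1)
  expect_lte(fam$pi_star, fixed + 1e-10)
  expect_lt(abs(unname(fam$theta_hat["mean"]) - 0.3), 0.3)
  expect_lt(abs(fam$pi_star - 0.5), 0.08)
  expect_true(fam$meta$converged)
})
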