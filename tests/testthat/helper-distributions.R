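# shared generators for property-style tests

random_pair <- function(k = sample(2:10, 1), concentration = 1) {
  list(tau = rprob_vector(k, concentration), m = rprob_vector(k, concentration))
}

# strictly positive pair (needed for the log/chi-squared inequality chains)
random_positive_pair <- function(k = sample(2:10, 1)) {
  jitter <- function(p) prob_vector((as.numeric(p) + 1e-3) / (1 + k * 1e-3))
  pr <- random_pair(k)
  list(tau = jitter(pr$tau), m = jitter(pr$m))
}

std_normal <- function() parametric_model("normal", c(0, 1))

mixture_two <- function(eps, mu, sd = 1) {
  parametric_model("normal_mixture",
                   list(w = c(1 - eps, eps), mean = c(0, mu), sd = c(1, sd)))
}

expect_dist_equal <- function(res, value, tol = 1e-12) {
  expect_s3_class(res, "distance_result")
  expect_equal(dist_value(res), value, tolerance = tol)
}
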