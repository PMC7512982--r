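test_that("contaminated samples have exactly round(n*eps) contaminant draws", {
  spec <- contamination_spec(0.2, 1000, parametric_model("normal", c(10, 1)))
  x <- sample_contaminated(spec, seed = 71)
  expect_length(x, 1000)
  # components are 10 sd apart; count draws above the midpoint
  expect_equal(sum(x > 5), 200)
  expect_identical(x, sample_contaminated(spec, seed = 71))
})

test_that("edge contamination fractions use a single component", {
  base_only <- sample_contaminated(
    contamination_spec(0, 500, parametric_model("normal", c(10, 1))), seed = 72)
  expect_equal(mean(base_only), 0, tolerance = 0.2)
  contam_only <- sample_contaminated(
    contamination_spec(1, 500, parametric_model("normal", c(10, 1))), seed = 73)
  expect_equal(mean(contam_only), 10, tolerance = 0.2)
  expect_error(contamination_spec(1.2, 100, std_normal()))
})

test_that("summaries reproduce hand-computed means and are order invariant", {
  raw <- data.frame(contaminant = "c", epsilon = 0.1, n = 100, measure = "tv",
                    value = c(0.1, 0.3), rep = 1:2)
  s <- summarize_reps(raw)
  expect_equal(s$mean, 0.2)
  expect_equal(s$sd, sqrt(0.02), tolerance = 1e-12)  # ~0.1414, reps-1 denominator
  const <- within(raw, value <- 0.25)
  expect_equal(summarize_reps(const)$sd, 0)
  big <- do.call(rbind, lapply(1:3, function(i)
    data.frame(contaminant = c("a", "b"), epsilon = 0.1, n = 100,
               measure = "tv", value = runif(2), rep = i)))
  expect_identical(summarize_reps(big), summarize_reps(big[sample(nrow(big)), ]))
})

test_that("failed replications are counted, not dropped silently", {
  raw <- data.frame(contaminant = "c", epsilon = 0.1, n = 100, measure = "tv",
                    value = c(0.2, NA, 0.4), rep = 1:3)
  s <- summarize_reps(raw)
  expect_equal(s$failed, 1)
  expect_equal(s$reps, 2)
  expect_equal(s$mean, 0.3)
  one <- summarize_reps(raw[1:2, ])
  expect_true(is.na(one$sd))  # below two successes, SD is missing
})

test_that("a tiny study populates every requested cell deterministically", {
  config <- mc_config(
    contaminants = list("N(5,1)" = parametric_model("normal", c(5, 1)),
                        "N(0,9)" = parametric_model("normal", c(0, 3))),
    epsilon_grid = 0.1, n_grid = 200, reps = 2, seed = 5)
  tab <- run_study(config)
  expect_s3_class(tab, "nq_summary")
  # pistar only for the asymmetric contaminant
  expect_setequal(tab$measure[tab$contaminant == "N(5,1)"],
                  c("tv", "kld", "pistar"))
  expect_setequal(tab$measure[tab$contaminant == "N(0,9)"], c("tv", "kld"))
  expect_true(all(tab$reps == 2 & tab$failed == 0))
  expect_true(all(is.finite(tab$mean) & tab$sd >= 0))
  expect_identical(tab, run_study(config))
})

test_that("cell seeds derive stably from the master seed", {
  config1 <- mc_config(list(c1 = parametric_model("normal", c(5, 1))),
                       epsilon_grid = c(0.1, 0.3), n_grid = 200, reps = 2,
                       measures = "tv", seed = 9)
  tab1 <- run_study(config1)
  # reordering the epsilon grid must not change any cell's result
  config2 <- config1; config2$epsilon_grid <- c(0.3, 0.1)
  tab2 <- run_study(config2)
  expect_identical(tab1, tab2[order(tab2$contaminant, tab2$epsilon, tab2$n), ],
                   ignore_attr = TRUE)
})

test_that("summary tables round-trip through CSV", {
  config <- mc_config(list(c1 = parametric_model("normal", c(5, 1))),
                      epsilon_grid = 0.2, n_grid = 100, reps = 2,
                      measures = "tv", seed = 3)
  tab <- run_study(config)
  path <- withr::local_tempfile(fileext = ".csv")
  write_summary_csv(tab, path)
  back <- utils::read.csv(path)
  expect_equal(back$mean, tab$mean)
  expect_equal(names(back), names(tab))
})
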