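#' Contamination model specification
#'
#' The two-component mixture `(1 - epsilon) * base + epsilon * contaminant`
#' used as the true data-generating distribution in the Monte Carlo study.
#' Composition is deterministic: exactly `round(n * epsilon)` draws come from
#' the contaminant and the rest from the base (the study's epsilon and n
#' grids make `n * epsilon` an integer), then the sample is shuffled.
#'
#' @param epsilon Contamination fraction in `[0, 1]`.
#' @param n Sample size.
#' @param contaminant A [parametric_model()] (e.g. `N(mu, sigma^2)`).
#' @param base A [parametric_model()]; defaults to `N(0, 1)`.
#' @return An object of class `contamination_spec`.
#' @export
contamination_spec <- function(epsilon, n,
                               contaminant,
                               base = parametric_model("normal", c(0, 1))) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L,
            epsilon >= 0, epsilon <= 1, n >= 1,
            inherits(contaminant, "parametric_model"),
            inherits(base, "parametric_model"))
  structure(list(epsilon = epsilon, n = as.integer(n),
                 contaminant = contaminant, base = base),
            class = "contamination_spec")
}

#' @export
print.contamination_spec <- function(x, ...) {
  cat(sprintf("<contamination_spec> (1 - %g)*base + %g*contaminant, n = %d\n",
              x$epsilon, x$epsilon, x$n))
  invisible(x)
}

#' Draw one contaminated sample
#'
#' @param spec A [contamination_spec()].
#' @param seed Optional integer seed; fixed seed gives a reproducible sample.
#' @return Numeric vector of length `spec$n`.
#' @export
sample_contaminated <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "contamination_spec"))
  if (!is.null(seed)) set.seed(seed)
  k <- round(spec$n * spec$epsilon)
  x <- c(model_sample(spec$base, spec$n - k),
         model_sample(spec$contaminant, k))
  sample(x)
}

#' Monte Carlo study configuration
#'
#' @param contaminants Named list of [parametric_model()] contaminants.
#' @param epsilon_grid Contamination fractions.
#' @param n_grid Sample sizes.
#' @param reps Replications per cell.
#' @param measures Subset of `c("tv", "kld", "pistar")`.
#' @param seed Master seed; every cell derives its own stream from it.
#' @param base Base model (default `N(0, 1)`), which is also the reference
#'   model the distances are computed against.
#' @param pistar_contaminants Names of contaminants for which the mixture
#'   index of fit is estimated; by default those whose mean differs from the
#'   base mean (the index presumes an asymmetric, heterogeneous population).
#' @param bandwidth,grid_points,density_floor,kl_bins Tuning passed through
#'   to the distance estimators.
#' @return An object of class `mc_config`.
#' @export
mc_config <- function(contaminants, epsilon_grid, n_grid, reps = 500L,
                      measures = c("tv", "kld", "pistar"), seed = 1L,
                      base = parametric_model("normal", c(0, 1)),
                      pistar_contaminants = NULL,
                      bandwidth = "sj", grid_points = 512L,
                      density_floor = 0.01, kl_bins = 100L) {
  stopifnot(is.list(contaminants), length(contaminants) >= 1L,
            !is.null(names(contaminants)), all(nzchar(names(contaminants))),
            all(vapply(contaminants, inherits, TRUE, "parametric_model")),
            reps >= 1L, all(n_grid >= 2), all(epsilon_grid >= 0 & epsilon_grid <= 1))
  measures <- match.arg(measures, c("tv", "kld", "pistar"), several.ok = TRUE)
  if (is.null(pistar_contaminants)) {
    base_mean <- mean_of(base)
    pistar_contaminants <- names(contaminants)[
      vapply(contaminants, function(m) !isTRUE(all.equal(mean_of(m), base_mean)),
             TRUE)]
  }
  structure(list(contaminants = contaminants, epsilon_grid = epsilon_grid,
                 n_grid = as.integer(n_grid), reps = as.integer(reps),
                 measures = measures, seed = as.integer(seed), base = base,
                 pistar_contaminants = pistar_contaminants,
                 bandwidth = bandwidth, grid_points = as.integer(grid_points),
                 density_floor = density_floor, kl_bins = as.integer(kl_bins)),
            class = "mc_config")
}

mean_of <- function(m) {
  switch(m$family,
         normal = m$theta[1],
         poisson = m$theta,
         normal_mixture = sum(m$theta$w * m$theta$mean))
}

# deterministic 31-bit seed from the master seed and a cell key string
derive_seed <- function(master, key) {
  h <- as.double(master %% 2147483647L)
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

#' Run the contamination Monte Carlo study
#'
#' For every cell `(contaminant, epsilon, n)` and each replication: draw a
#' contaminated sample; compute the total variation between its
#' kernel-smoothed density and the base model ([tv_sample_model()]); compute
#' the Kullback-Leibler distance between the sample and a freshly drawn base
#' sample of the same size ([kl_sample_sample()]); and, for asymmetric
#' contaminants, the family-minimised mixture index of fit
#' ([pistar_family()]). Results are aggregated to means and sample standard
#' deviations (denominator `reps - 1`).
#'
#' Each cell derives its own random stream from the master seed by stable
#' hashing of the cell coordinates, so the study is fully deterministic and
#' cells are independent of evaluation order. A failing measure within a
#' replication is recorded (column `failed`) rather than aborting the study.
#'
#' @param config An [mc_config()].
#' @param progress Print one line per cell.
#' @return A `data.frame` (class `nq_summary`) with columns `contaminant`,
#'   `epsilon`, `n`, `measure`, `mean`, `sd`, `reps`, `failed`.
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "mc_config"))
  raw <- list(); ri <- 0L
  for (cname in names(config$contaminants)) {
    contaminant <- config$contaminants[[cname]]
    cell_measures <- config$measures
    if (!(cname %in% config$pistar_contaminants)) {
      cell_measures <- setdiff(cell_measures, "pistar")
    }
    for (eps in config$epsilon_grid) {
      for (n in config$n_grid) {
        key <- sprintf("%s|%.10g|%d", cname, eps, n)
        set.seed(derive_seed(config$seed, key))
        spec <- contamination_spec(eps, n, contaminant, config$base)
        vals <- matrix(NA_real_, config$reps, length(cell_measures),
                       dimnames = list(NULL, cell_measures))
        for (r in seq_len(config$reps)) {
          x <- sample_contaminated(spec)
          for (ms in cell_measures) {
            vals[r, ms] <- tryCatch(switch(ms,
              tv = dist_value(tv_sample_model(x, config$base,
                                              bandwidth = config$bandwidth)),
              kld = dist_value(kl_sample_sample(x, model_sample(config$base, n),
                                                n_bins = config$kl_bins)),
              pistar = pistar_family(x, grid_points = config$grid_points,
                                     density_floor = config$density_floor,
                                     bandwidth = config$bandwidth)$pi_star),
              error = function(e) NA_real_)
          }
        }
        for (ms in cell_measures) {
          ri <- ri + 1L
          v <- vals[, ms]
          raw[[ri]] <- data.frame(contaminant = cname, epsilon = eps, n = n,
                                  measure = ms, value = v,
                                  rep = seq_len(config$reps))
        }
        if (progress) {
          message(sprintf("cell %s done (%d reps)", key, config$reps))
        }
      }
    }
  }
  summarize_reps(do.call(rbind, raw))
}

#' Aggregate raw replication values into a summary table
#'
#' @param raw Data frame with columns `contaminant`, `epsilon`, `n`,
#'   `measure`, `value` (one row per replication; row order is irrelevant).
#' @return A `data.frame` of class `nq_summary`, one row per cell, ordered by
#'   `(contaminant, epsilon, n, measure)`, with the replication mean, sample
#'   standard deviation (`NA` below two successful replications), the number
#'   of successful replications and the number of failed ones.
#' @export
summarize_reps <- function(raw) {
  needed <- c("contaminant", "epsilon", "n", "measure", "value")
  stopifnot(all(needed %in% names(raw)))
  key <- interaction(raw$contaminant, raw$epsilon, raw$n, raw$measure,
                     drop = TRUE, lex.order = TRUE)
  pieces <- lapply(split(raw, key), function(d) {
    ok <- d$value[!is.na(d$value)]
    data.frame(contaminant = d$contaminant[1], epsilon = d$epsilon[1],
               n = d$n[1], measure = d$measure[1],
               mean = if (length(ok)) mean(ok) else NA_real_,
               sd = if (length(ok) >= 2L) stats::sd(ok) else NA_real_,
               reps = length(ok), failed = sum(is.na(d$value)))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$contaminant, out$epsilon, out$n, out$measure), ]
  rownames(out) <- NULL
  class(out) <- c("nq_summary", "data.frame")
  out
}

#' @export
print.nq_summary <- function(x, ...) {
  cat("<nq_summary> Monte Carlo cell summaries\n")
  print.data.frame(x, digits = 4, row.names = FALSE, ...)
  invisible(x)
}

#' Write a study summary as tidy CSV
#'
#' @param x An `nq_summary`.
#' @param path Output path.
#' @export
write_summary_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
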