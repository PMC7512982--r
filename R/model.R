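#' Univariate parametric model
#'
#' A lightweight container for a parametric density family `m_theta`, carrying
#' the operations the continuous distances need: density, log-density,
#' sampling, the score in the first parameter and the Fisher information.
#'
#' Supported families:
#' * `"normal"` — `theta = c(mean, sd)`, `sd > 0`.
#' * `"normal_mixture"` — `theta = list(w, mean, sd)` with weights summing to
#'   one; the two-component case is the contamination model of the Monte Carlo
#'   study.
#' * `"poisson"` — `theta = lambda > 0` (discrete; used by the Fisher
#'   local-equivalence check).
#'
#' @param family Family name.
#' @param theta Parameter vector (or list for `"normal_mixture"`).
#' @return An object of class `parametric_model`.
#' @examples
#' m <- parametric_model("normal", c(0, 1))
#' model_pdf(m, 0)
#' mix <- parametric_model("normal_mixture",
#'                         list(w = c(0.5, 0.5), mean = c(0, 5), sd = c(1, 1)))
#' model_sample(mix, 5, seed = 1)
#' @export
parametric_model <- function(family, theta) {
  family <- match.arg(family, c("normal", "normal_mixture", "poisson"))
  if (family == "normal") {
    theta <- as.numeric(theta)
    stopifnot(length(theta) == 2L, is.finite(theta[2]), theta[2] > 0)
  } else if (family == "poisson") {
    theta <- as.numeric(theta)
    stopifnot(length(theta) == 1L, theta > 0)
  } else {
    stopifnot(is.list(theta), all(c("w", "mean", "sd") %in% names(theta)))
    theta$w <- as.numeric(theta$w)
    theta$mean <- as.numeric(theta$mean)
    theta$sd <- as.numeric(theta$sd)
    k <- length(theta$w)
    stopifnot(k >= 1, length(theta$mean) == k, length(theta$sd) == k,
              all(theta$w >= 0), abs(sum(theta$w) - 1) < 1e-12,
              all(theta$sd > 0))
  }
  structure(list(family = family, theta = theta), class = "parametric_model")
}

#' @export
print.parametric_model <- function(x, ...) {
  th <- if (is.list(x$theta)) {
    paste(sprintf("%.3g*N(%.3g, %.3g^2)", x$theta$w, x$theta$mean, x$theta$sd),
          collapse = " + ")
  } else paste(format(x$theta, digits = 4), collapse = ", ")
  cat(sprintf("<parametric_model> %s(%s)\n", x$family, th))
  invisible(x)
}

#' Model operations
#'
#' Density, log-density, reproducible sampling, quantiles, the score
#' `u(x) = d/d theta log m_theta(x)` in the family's first (location/rate)
#' parameter, and the Fisher information for that parameter.
#'
#' @param m A [parametric_model()].
#' @param x Numeric vector of evaluation points.
#' @param n Number of draws.
#' @param seed Optional integer seed; sampling with a fixed seed is
#'   reproducible and does not disturb the caller's RNG state.
#' @param p Probabilities for the quantile function.
#' @name model_ops
NULL

#' @rdname model_ops
#' @export
model_pdf <- function(m, x) {
  stopifnot(inherits(m, "parametric_model"))
  switch(m$family,
    normal = stats::dnorm(x, m$theta[1], m$theta[2]),
    poisson = stats::dpois(round(x), m$theta),
    normal_mixture = {
      out <- 0
      for (i in seq_along(m$theta$w)) {
        out <- out + m$theta$w[i] * stats::dnorm(x, m$theta$mean[i], m$theta$sd[i])
      }
      out
    })
}

#' @rdname model_ops
#' @export
model_logpdf <- function(m, x) {
  stopifnot(inherits(m, "parametric_model"))
  switch(m$family,
    normal = stats::dnorm(x, m$theta[1], m$theta[2], log = TRUE),
    poisson = stats::dpois(round(x), m$theta, log = TRUE),
    normal_mixture = log(model_pdf(m, x)))
}

#' @rdname model_ops
#' @export
model_sample <- function(m, n, seed = NULL) {
  stopifnot(inherits(m, "parametric_model"), n >= 0)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  switch(m$family,
    normal = stats::rnorm(n, m$theta[1], m$theta[2]),
    poisson = stats::rpois(n, m$theta),
    normal_mixture = {
      comp <- sample.int(length(m$theta$w), n, replace = TRUE, prob = m$theta$w)
      stats::rnorm(n, m$theta$mean[comp], m$theta$sd[comp])
    })
}

#' @rdname model_ops
#' @export
model_quantile <- function(m, p) {
  stopifnot(inherits(m, "parametric_model"))
  switch(m$family,
    normal = stats::qnorm(p, m$theta[1], m$theta[2]),
    poisson = stats::qpois(p, m$theta),
    normal_mixture = {
      # bracket the mixture quantile between component quantiles
      vapply(p, function(pp) {
        lo <- min(stats::qnorm(pp, m$theta$mean, m$theta$sd))
        hi <- max(stats::qnorm(pp, m$theta$mean, m$theta$sd))
        if (lo == hi) return(lo)
        cdf <- function(x) {
          s <- 0
          for (i in seq_along(m$theta$w)) {
            s <- s + m$theta$w[i] * stats::pnorm(x, m$theta$mean[i], m$theta$sd[i])
          }
          s - pp
        }
        stats::uniroot(cdf, c(lo, hi), extendInt = "upX", tol = 1e-10)$root
      }, numeric(1))
    })
}

#' @rdname model_ops
#' @export
model_score <- function(m, x) {
  stopifnot(inherits(m, "parametric_model"))
  switch(m$family,
    normal = (x - m$theta[1]) / m$theta[2]^2,
    poisson = round(x) / m$theta - 1,
    stop("score not available for family '", m$family, "'", call. = FALSE))
}

#' @rdname model_ops
#' @export
model_fisher_info <- function(m) {
  stopifnot(inherits(m, "parametric_model"))
  switch(m$family,
    normal = 1 / m$theta[2]^2,  # information for the mean
    poisson = 1 / m$theta,
    stop("Fisher information not available for family '", m$family, "'",
         call. = FALSE))
}

#' Read a model specification from JSON
#'
#' Accepts `{"family": "normal", "theta": [0, 1]}` or, for mixtures,
#' `{"family": "normal_mixture", "theta": {"w": [...], "mean": [...],
#' "sd": [...]}}`.
#'
#' @param path Path to a JSON file (or a literal JSON string).
#' @return A [parametric_model()].
#' @export
model_from_json <- function(path) {
  spec <- jsonlite::fromJSON(path)
  if (is.null(spec$family) || is.null(spec$theta)) {
    stop("model JSON must contain `family` and `theta`", call. = FALSE)
  }
  parametric_model(spec$family, spec$theta)
}
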