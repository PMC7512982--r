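#' Total variation between two continuous densities
#'
#' Computes `V(f, g) = (1/2) * integral |f - g|` by composite trapezoid
#' quadrature on a dense equispaced grid. The integrand has kinks where the
#' densities cross, so a dense fixed grid is more robust than low-order
#' adaptive schemes; quadrature resolution is controlled by the grid.
#'
#' @param f,g [parametric_model()] objects (or [kde()] objects).
#' @param grid An [nq_grid()]; when `NULL`, a grid spanning the 1e-8 tail
#'   quantiles of both densities with 4096 points is used.
#' @return A [distance_result()]; `meta$mass_f`/`meta$mass_g` record how much
#'   of each density the grid captured, with a `coverage_warning` flag if
#'   either misses more than 1e-6.
#' @examples
#' f <- parametric_model("normal", c(0, 1))
#' g <- parametric_model("normal", c(1, 1))
#' dist_value(tv_density_density(f, g))  # 2*pnorm(0.5) - 1
#' @export
tv_density_density <- function(f, g, grid = NULL) {
  df <- density_closure(f)
  dg <- density_closure(g)
  if (is.null(grid)) {
    models <- Filter(function(o) inherits(o, "parametric_model"), list(f, g))
    xs <- unlist(lapply(list(f, g), function(o) if (inherits(o, "kde")) range(o$data)))
    h <- max(unlist(lapply(list(f, g), function(o) if (inherits(o, "kde")) o$bw)), 0)
    if (is.null(xs)) xs <- numeric(0)
    lo <- suppressWarnings(min(xs)); hi <- suppressWarnings(max(xs))
    for (m in models) {
      lo <- min(lo, model_quantile(m, 1e-8)); hi <- max(hi, model_quantile(m, 1 - 1e-8))
    }
    grid <- nq_grid(lo - 5 * h - 1e-9, hi + 5 * h + 1e-9, 4096L)
  }
  pts <- grid_points(grid)
  yf <- df(pts); yg <- dg(pts)
  if (any(!is.finite(yf)) || any(!is.finite(yg))) {
    stop("non-finite density values on the quadrature grid", call. = FALSE)
  }
  mass_f <- trapezoid(yf, grid$spacing)
  mass_g <- trapezoid(yg, grid$spacing)
  meta <- list(mass_f = mass_f, mass_g = mass_g)
  if (abs(1 - mass_f) > 1e-6 || abs(1 - mass_g) > 1e-6) {
    meta$coverage_warning <- "quadrature grid misses more than 1e-6 of mass"
  }
  distance_result("tv_density_density",
                  min(1, 0.5 * trapezoid(abs(yf - yg), grid$spacing)),
                  meta = meta)
}

density_closure <- function(o) {
  if (inherits(o, "parametric_model")) return(function(x) model_pdf(o, x))
  if (inherits(o, "kde")) return(function(x) predict(o, x))
  if (is.function(o)) return(o)
  stop("expected a parametric_model, kde or density function", call. = FALSE)
}

#' Total variation between a sample and a continuous model
#'
#' Smooths the sample with a normal kernel, then computes the total variation
#' distance between the smoothed empirical density and the model density by
#' trapezoid quadrature. Comparing the raw empirical measure to a continuous
#' density would always give distance 1 (discrete versus continuous measures
#' are mutually singular); the smoothing step is what makes this comparison
#' meaningful ("discretization robustness").
#'
#' @param x Numeric sample (n >= 2, finite, non-constant).
#' @param m A [parametric_model()].
#' @param bandwidth Bandwidth rule or value, see [kde()].
#' @param grid Optional [nq_grid()]; defaults to the sample/model range padded
#'   by five bandwidths, 4096 points.
#' @return A [distance_result()]; `meta$bandwidth` records the bandwidth used.
#' @export
tv_sample_model <- function(x, m, bandwidth = "sj", grid = NULL) {
  stopifnot(inherits(m, "parametric_model"))
  k <- kde(x, bandwidth)
  if (is.null(grid)) grid <- default_grid(k$data, list(m), k$bw)
  pts <- grid_points(grid)
  yf <- kde_on_grid(k, grid)
  yg <- model_pdf(m, pts)
  res <- distance_result("tv_sample_model",
                         min(1, 0.5 * trapezoid(abs(yf - yg), grid$spacing)),
                         meta = list(bandwidth = k$bw,
                                     grid = c(grid$lo, grid$hi, grid$n_points)))
  res
}

#' Kullback-Leibler distance between two samples
#'
#' Bins both samples on a common equal-width grid spanning their pooled
#' range, converts counts to smoothed relative frequencies (additive
#' smoothing `alpha` per bin, so the estimate is always finite) and returns
#' `sum q * log(q / p)` with the second (model-side) sample `y` in front of
#' the logarithm, matching the package's Kullback-Leibler argument
#' convention.
#'
#' @param x Sample playing the data role.
#' @param y Sample playing the model role.
#' @param n_bins Number of equal-width bins (>= 2, default 100).
#' @param alpha Additive smoothing constant per bin (default 1/2).
#' @return A [distance_result()].
#' @export
kl_sample_sample <- function(x, y, n_bins = 100L, alpha = 0.5) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("samples must be nonempty", call. = FALSE)
  if (n_bins < 2L) stop("need at least 2 bins", call. = FALSE)
  lo <- min(x, y); hi <- max(x, y)
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  cx <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = n_bins)
  cy <- tabulate(findInterval(y, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), nbins = n_bins)
  p <- (cx + alpha) / (length(x) + alpha * n_bins)
  q <- (cy + alpha) / (length(y) + alpha * n_bins)
  distance_result("kl_sample_sample", sum(q * log(q / p)),
                  meta = list(n_bins = n_bins, alpha = alpha,
                              range = c(lo, hi)))
}

#' Strictly monotone transformation of the real line
#'
#' Bundle of a forward map `a`, its inverse `b` and the derivative of the
#' inverse, used by [tv_invariance_check()]. Monotonicity of the forward map
#' is spot-checked numerically on construction.
#'
#' @param fun Forward map `a(x)`.
#' @param inverse Inverse map `b(y)` with `b(a(x)) = x`.
#' @param inverse_deriv Derivative `b'(y)`.
#' @param name Label.
#' @param check_range Interval on which monotonicity is spot-checked.
#' @return An object of class `nq_transform`.
#' @export
nq_transform <- function(fun, inverse, inverse_deriv, name = "transform",
                         check_range = c(-10, 10)) {
  stopifnot(is.function(fun), is.function(inverse), is.function(inverse_deriv))
  xs <- seq(check_range[1], check_range[2], length.out = 201)
  d <- diff(fun(xs))
  if (!(all(d > 0) || all(d < 0))) {
    stop("`fun` is not strictly monotone on the check range", call. = FALSE)
  }
  structure(list(fun = fun, inverse = inverse, inverse_deriv = inverse_deriv,
                 name = name, increasing = all(d > 0)),
            class = "nq_transform")
}

#' Invariance of total variation under monotone transformations
#'
#' Total variation between two distributions is unchanged by a one-to-one
#' transformation of the underlying variable. This check computes the
#' distance on the original scale and on the transformed scale, where the
#' transformed density is `f(b(y)) * |b'(y)|` with `b` the inverse map, and
#' returns both. With two parametric densities the values agree within
#' quadrature tolerance; with a sample as the first argument the sample is
#' transformed pointwise and re-smoothed, so agreement is only approximate
#' (smoothing is not transformation-equivariant).
#'
#' @param x A [parametric_model()] (density-to-density check) or numeric
#'   sample (sample-to-model check).
#' @param m A [parametric_model()].
#' @param transform An [nq_transform()].
#' @param grid Optional [nq_grid()] on the original scale; the transformed
#'   grid is its image under the forward map.
#' @param bandwidth Bandwidth rule when `x` is a sample.
#' @return List with elements `original` and `transformed`, both
#'   [distance_result()]s.
#' @export
tv_invariance_check <- function(x, m, transform, grid = NULL, bandwidth = "sj") {
  stopifnot(inherits(m, "parametric_model"), inherits(transform, "nq_transform"))
  b <- transform$inverse; bp <- transform$inverse_deriv
  transformed_density <- function(dens) {
    function(y) dens(b(y)) * abs(bp(y))
  }
  if (inherits(x, "parametric_model")) {
    if (is.null(grid)) {
      lo <- min(model_quantile(x, 1e-8), model_quantile(m, 1e-8))
      hi <- max(model_quantile(x, 1 - 1e-8), model_quantile(m, 1 - 1e-8))
      grid <- nq_grid(lo, hi, 8192L)
    }
    ends <- sort(transform$fun(c(grid$lo, grid$hi)))
    tgrid <- nq_grid(ends[1], ends[2], grid$n_points)
    orig <- tv_density_density(x, m, grid)
    trans <- tv_density_density(transformed_density(density_closure(x)),
                                transformed_density(density_closure(m)), tgrid)
  } else {
    x <- as.numeric(x)
    orig <- tv_sample_model(x, m, bandwidth = bandwidth, grid = grid)
    y <- transform$fun(x)
    k <- kde(y, bandwidth)
    tgrid <- nq_grid(min(y) - 5 * k$bw, max(y) + 5 * k$bw, 4096L)
    pts <- grid_points(tgrid)
    ym <- transformed_density(function(z) model_pdf(m, z))(pts)
    trans <- distance_result("tv_sample_model_transformed",
                             min(1, 0.5 * trapezoid(abs(kde_on_grid(k, tgrid) - ym),
                                                    tgrid$spacing)),
                             meta = list(bandwidth = k$bw))
  }
  list(original = orig, transformed = trans)
}

#' Local equivalence of total variation and Fisher information
#'
#' For an i.i.d. model with `n` observations, the total variation between the
#' product measures at nearby parameter values behaves, after scaling by
#' `n^(-1/2)`, like `|theta - theta0| * sqrt(I(theta0) / (2*pi))` where `I` is
#' the Fisher information. The product-measure distance is estimated by Monte
#' Carlo through the representation `V(P, Q) = (1/2) * E_P |1 - q(X)/p(X)|`
#' (exact integration over n-dimensional blocks is infeasible).
#'
#' The equivalence is *local*: the Taylor expansion behind it is accurate only
#' while `sqrt(n) * |theta - theta0| * sqrt(I)` stays small (below about 0.5
#' the limit formula is accurate to under 1 percent). At fixed separation and
#' growing `n` the scaled distance must eventually decay to zero because
#' total variation is bounded by 1.
#'
#' @param family `"poisson"` (theta = rate) or `"normal"` (theta = mean,
#'   unit variance).
#' @param theta0,theta Parameter values; `theta = theta0` returns exactly 0.
#' @param n Block size (number of i.i.d. observations per replicate).
#' @param reps Monte Carlo replicates.
#' @param seed Optional integer seed.
#' @return List of class `fisher_local_tv` with `value` (the scaled distance
#'   `n^(-1/2) * V_hat`), `se` (its Monte Carlo standard error), `tv` (the
#'   unscaled estimate), and `limit` (the closed-form local limit).
#' @export
fisher_local_tv <- function(family = c("poisson", "normal"), theta0, theta,
                            n, reps = 2000L, seed = NULL) {
  family <- match.arg(family)
  make <- function(th) switch(family,
                              poisson = parametric_model("poisson", th),
                              normal = parametric_model("normal", c(th, 1)))
  p_model <- make(theta)
  q_model <- make(theta0)
  info <- model_fisher_info(q_model)
  limit <- abs(theta - theta0) * sqrt(info / (2 * pi))
  out <- list(family = family, theta0 = theta0, theta = theta, n = n,
              reps = as.integer(reps), limit = limit)
  if (theta == theta0) {
    out$value <- 0; out$se <- 0; out$tv <- 0
    class(out) <- "fisher_local_tv"
    return(out)
  }
  if (!is.null(seed)) set.seed(seed)
  vals <- numeric(reps)
  chunk <- max(1L, floor(2e6 / n))
  done <- 0L
  while (done < reps) {
    k <- min(chunk, reps - done)
    draws <- matrix(model_sample(p_model, n * k), nrow = n)
    logratio <- colSums(matrix(model_logpdf(q_model, draws) -
                                 model_logpdf(p_model, draws), nrow = n))
    vals[done + seq_len(k)] <- 0.5 * abs(1 - exp(logratio))
    done <- done + k
  }
  out$tv <- mean(vals)
  out$value <- out$tv / sqrt(n)
  out$se <- stats::sd(vals) / sqrt(reps) / sqrt(n)
  class(out) <- "fisher_local_tv"
  out
}

#' @export
print.fisher_local_tv <- function(x, ...) {
  cat(sprintf("<fisher_local_tv> %s: theta %g vs %g, n = %d\n",
              x$family, x$theta, x$theta0, x$n))
  cat(sprintf("  scaled TV = %.5g (MC se %.2g), local limit = %.5g\n",
              x$value, x$se, x$limit))
  invisible(x)
}
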