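#' Mixture index of fit against a fixed discrete distribution
#'
#' The mixture index of fit `pi*` is the smallest contamination fraction
#' `pi` such that the truth can be written `tau = (1 - pi) * m + pi * e` with
#' `e` an arbitrary distribution: the fraction of the population
#' intrinsically outside the model. Against a fixed discrete `m` it has the
#' closed form `pi* = sup_t [1 - tau(t) / m(t)]` over cells with `m(t) > 0`,
#' and equals 1 as soon as some cell has `tau = 0 < m` — a one-sided
#' sensitivity that [total_variation()] does not share.
#'
#' @param tau,m Probability vectors on a common support.
#' @return An object of class `pistar_result` with fields `pi_star`,
#'   `achieving_point` (smallest support point attaining the supremum) and,
#'   for `0 < pi* < 1`, the residual distribution `residual` with
#'   `tau = (1 - pi*) * m + pi* * residual`.
#' @examples
#' pistar_fixed_discrete(c(0.7, 0.3), c(0.5, 0.5))$pi_star  # 0.4
#' @export
pistar_fixed_discrete <- function(tau, m) {
  tau <- as_prob(tau, "tau"); m <- as_prob(m, "m")
  check_same_support(tau, m)
  tt <- as.numeric(tau); mm <- as.numeric(m)
  support <- attr(tau, "support")
  pos <- which(mm > 0)
  ratios <- 1 - tt[pos] / mm[pos]
  i <- pos[which.max(ratios)]  # which.max returns the first (smallest) tie
  pi_star <- min(1, max(0, max(ratios)))
  residual <- NULL
  if (pi_star > 0 && pi_star < 1) {
    residual <- (tt - (1 - pi_star) * mm) / pi_star
    residual[abs(residual) < 1e-14] <- 0
    residual <- prob_vector(residual / sum(residual), support = support)
  }
  new_pistar_result(pi_star, achieving_point = support[i], residual = residual)
}

new_pistar_result <- function(pi_star, theta_hat = NULL, achieving_point = NULL,
                              residual = NULL, meta = list()) {
  structure(list(pi_star = pi_star, theta_hat = theta_hat,
                 achieving_point = achieving_point, residual = residual,
                 meta = meta),
            class = "pistar_result")
}

#' @export
print.pistar_result <- function(x, ...) {
  cat(sprintf("<pistar_result> pi* = %.5g", x$pi_star))
  if (!is.null(x$achieving_point)) cat(sprintf("  (achieved at %g)", x$achieving_point))
  cat("\n")
  if (!is.null(x$theta_hat)) {
    cat("  theta_hat: ", paste(format(x$theta_hat, digits = 5), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Brute-force oracle for the discrete mixture index of fit
#'
#' Scans a grid of candidate `pi` values and returns the smallest one for
#' which `tau(t) - (1 - pi) * m(t) >= 0` at every cell, i.e. for which a
#' valid residual distribution exists. Agrees with the closed form of
#' [pistar_fixed_discrete()] within one grid step; kept as an independent
#' check (supports of at most 50 points).
#'
#' @inheritParams pistar_fixed_discrete
#' @param grid_size Total resolution of the candidate `pi` grid on `[0, 1]`;
#'   the scan refines coarse-to-fine (each stage rescans the bracketing
#'   interval), so resolution `1/grid_size` is reached without evaluating
#'   every candidate.
#' @return The smallest feasible `pi` on the grid (a bare number).
#' @export
pistar_oracle <- function(tau, m, grid_size = 1e6L) {
  tau <- as_prob(tau, "tau"); m <- as_prob(m, "m")
  check_same_support(tau, m)
  if (length(tau) > 50L) stop("oracle restricted to support size <= 50", call. = FALSE)
  tt <- as.numeric(tau); mm <- as.numeric(m)
  feasible <- function(pi) all(tt - (1 - pi) * mm >= -1e-15)
  lo <- 0; hi <- 1
  step <- 1 / grid_size
  repeat {
    pis <- seq(lo, hi, length.out = 1001L)
    ok <- vapply(pis, feasible, logical(1))
    if (!any(ok)) return(1)
    i <- which(ok)[1L]
    if (i == 1L) return(pis[1L])
    lo <- pis[i - 1L]; hi <- pis[i]
    if (hi - lo <= step) return(hi)
  }
}

#' Mixture index of fit of a sample against a fixed continuous model
#'
#' Builds a normal-kernel density estimate of the sample and evaluates
#' `sup [1 - kde(t) / m(t)]` over an equispaced grid restricted to the
#' sample range `[min(x), max(x)]` and to points where the estimated density
#' is at least `density_floor` times its maximum. The restriction is
#' essential: the unrestricted supremum equals 1 whenever the estimate has
#' lighter tails than the model (light-tailed data are read as "100 percent
#' outliers"), so some truncation is implicit in any usable continuous
#' version of the index.
#'
#' @param x Numeric sample.
#' @param m A [parametric_model()].
#' @param grid_points Number of grid points over the sample range.
#' @param density_floor Fraction of the maximum estimated density below which
#'   grid points are dropped (default 0.01).
#' @param bandwidth Bandwidth rule or value, see [kde()].
#' @return A `pistar_result` (no `theta_hat`).
#' @export
pistar_fixed_continuous <- function(x, m, grid_points = 512L,
                                    density_floor = 0.01, bandwidth = "sj") {
  stopifnot(inherits(m, "parametric_model"))
  k <- kde(x, bandwidth)
  pts <- seq(k$data[1], k$data[k$n], length.out = grid_points)
  tau_hat <- predict(k, pts)
  keep <- tau_hat >= density_floor * max(tau_hat)
  if (!any(keep)) stop("density floor leaves no grid points", call. = FALSE)
  res <- pistar_profile(tau_hat, pts, keep, m)
  new_pistar_result(res$pi_star, achieving_point = res$achieving_point,
                    meta = list(bandwidth = k$bw, kept_points = sum(keep)))
}

# sup_t [1 - tau_hat/m] over kept grid points, clipped to [0,1]
pistar_profile <- function(tau_hat, pts, keep, m) {
  ratio <- 1 - tau_hat[keep] / model_pdf(m, pts[keep])
  i <- which.max(ratio)
  list(pi_star = min(1, max(0, ratio[i])), achieving_point = pts[keep][i])
}

#' Family-minimised mixture index of fit
#'
#' Estimates `pi*(tau, M) = inf over theta of pi*(tau, m_theta)` for the
#' normal location-scale family by derivative-free simplex search over
#' `(mean, log sd)`. The objective — a supremum of density ratios over a
#' grid — is non-smooth and multimodal, so the search starts from
#' `theta_init` (mean 0, sd 1 by default, the conventional starting model
#' for the contamination study) plus a handful of mildly jittered restarts,
#' and reports the best local solution found from those starts.
#'
#' @param x Numeric sample.
#' @param family Model family; only `"normal"` is supported.
#' @param theta_init Starting parameters `c(mean, sd)`.
#' @param grid_points,density_floor,bandwidth Passed to the fixed-model
#'   evaluation, see [pistar_fixed_continuous()].
#' @param restarts Total number of simplex starts (the first is exactly
#'   `theta_init`; the rest jitter it).
#' @param jitter_sd Standard deviation of the restart jitter on `(mean,
#'   log sd)`.
#' @param seed Optional seed controlling the restart jitter.
#' @return A `pistar_result` with `theta_hat = c(mean, sd)` of the minimising
#'   model; `meta$converged` is `FALSE` if no simplex run converged.
#' @examples
#' x <- c(rnorm(300), rnorm(300, 10))
#' pistar_family(x, seed = 1)  # pi* close to 0.5
#' @export
pistar_family <- function(x, family = "normal", theta_init = c(0, 1),
                          grid_points = 512L, density_floor = 0.01,
                          bandwidth = "sj", restarts = 5L, jitter_sd = 0.25,
                          seed = NULL) {
  family <- match.arg(family)
  stopifnot(length(theta_init) == 2L, theta_init[2] > 0)
  k <- kde(x, bandwidth)
  pts <- seq(k$data[1], k$data[k$n], length.out = grid_points)
  tau_hat <- predict(k, pts)
  keep <- tau_hat >= density_floor * max(tau_hat)
  if (!any(keep)) stop("density floor leaves no grid points", call. = FALSE)
  th <- tau_hat[keep]; pk <- pts[keep]
  objective <- function(par) {
    mdl <- stats::dnorm(pk, par[1], exp(par[2]))
    min(1, max(0, max(1 - th / mdl)))
  }
  if (!is.null(seed)) set.seed(seed)
  starts <- rbind(c(theta_init[1], log(theta_init[2])))
  if (restarts > 1L) {
    starts <- rbind(starts,
                    cbind(theta_init[1] + stats::rnorm(restarts - 1L, 0, jitter_sd),
                          log(theta_init[2]) + stats::rnorm(restarts - 1L, 0, jitter_sd)))
  }
  best <- NULL; any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                        control = list(maxit = 500))
    any_conv <- any_conv || fit$convergence == 0L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  theta_hat <- c(mean = unname(best$par[1]), sd = unname(exp(best$par[2])))
  prof <- pistar_profile(tau_hat, pts, keep,
                         parametric_model("normal", theta_hat))
  new_pistar_result(prof$pi_star, theta_hat = theta_hat,
                    achieving_point = prof$achieving_point,
                    meta = list(bandwidth = k$bw, converged = any_conv,
                                starts = nrow(starts)))
}

#' W index: the common-mixture contamination level
#'
#' `W(tau, m)` is the smallest `pi` at which `tau` and `m` admit a common
#' two-component mixture representation `(1 - pi) * tau + pi * e1 =
#' (1 - pi) * m + pi * e2`. It relates to total variation through
#' `W = V / (1 + V)`, so `W` lives in `[0, 1/2]` and agrees with `V` to first
#' order when the distance is small.
#'
#' @inheritParams discrete_distances
#' @return A bare numeric value in `[0, 1/2]`.
#' @export
w_index <- function(tau, m) {
  v <- dist_value(total_variation(tau, m))
  v / (1 + v)
}
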