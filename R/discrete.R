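#' Distances between finite discrete distributions
#'
#' @description
#' Closed-form statistical distances between two probability mass functions
#' `tau` (the true / data distribution) and `m` (the model) on a common finite
#' support:
#'
#' * `total_variation()`: `V = (1/2) * sum |tau - m|`, the worst error in
#'   probability committed over any event; a metric with values in `[0, 1]`.
#' * `hellinger_sq()`: `H^2 = (1/2) * sum (sqrt(tau) - sqrt(m))^2`.
#' * `affinity()`: `rho = sum sqrt(tau * m) = 1 - H^2`; Matusita's distance is
#'   `sqrt(2 * H^2)` (see [matusita()]).
#' * `kl_divergence()`: `K2 = sum m * log(m / tau)`, the Kullback-Leibler
#'   distance with the model in front of the logarithm (the convention used
#'   throughout this package; note it is the reverse of the most common one).
#' * `likelihood_distance()`: `lambda2 = sum tau * log(tau / m)`, the KL
#'   distance with the arguments exchanged.
#' * `j_divergence()`: `K2 + lambda2`, the symmetric Kullback-Leibler or
#'   J-divergence.
#' * `pearson_chisq()`: `P2 = sum m * (tau/m - 1)^2`.
#' * `symmetric_chisq()`: `S2 = sum (tau - m)^2 / ((tau + m)/2)`.
#'
#' Log- and chi-squared-type distances use the measure-theoretic conventions
#' `0 * log(0/x) = 0` and `x * log(x/0) = +Inf` for `x > 0`; `Inf` is returned
#' as a value, never raised as an error. `0/0` cells of `S2` contribute 0.
#'
#' @param tau,m Probability vectors ([prob_vector()], [count_vector()] or
#'   plain numerics summing to one) on the same support.
#' @return A [distance_result()]; extract the number with [dist_value()].
#' @examples
#' tau <- prob_vector(c(0.7, 0.3)); m <- prob_vector(c(0.5, 0.5))
#' dist_value(total_variation(tau, m))   # 0.2
#' dist_value(pearson_chisq(tau, m))     # 0.16
#' @name discrete_distances
NULL

#' @rdname discrete_distances
#' @export
total_variation <- function(tau, m) {
  tau <- as_prob(tau, "tau"); m <- as_prob(m, "m")
  check_same_support(tau, m)
  diffs <- abs(as.numeric(tau) - as.numeric(m))
  distance_result("total_variation", 0.5 * sum(diffs),
                  meta = list(argmax_cell = attr(tau, "support")[which.max(diffs)]))
}

#' Total variation as a supremum over events (brute-force oracle)
#'
#' Enumerates every subset `A` of the support and returns
#' `max_A |P_tau(A) - P_m(A)|`. Equal to [total_variation()] exactly; kept as
#' an independent oracle and therefore restricted to supports of at most 20
#' points (2^20 subsets).
#'
#' @inheritParams discrete_distances
#' @return A [distance_result()] whose `meta$achieving_set` holds the support
#'   points of a maximising subset.
#' @export
tv_set_supremum <- function(tau, m) {
  tau <- as_prob(tau, "tau"); m <- as_prob(m, "m")
  check_same_support(tau, m)
  k <- length(tau)
  if (k > 20L) stop("oracle restricted to support size <= 20", call. = FALSE)
  diff <- as.numeric(tau) - as.numeric(m)
  best <- 0; best_code <- 0L
  bits <- bitwShiftL(1L, 0:(k - 1L))
  # enumerate subsets in chunks; each chunk is a membership matrix
  for (start in seq(0L, 2^k - 1L, by = 65536L)) {
    codes <- start:min(start + 65535L, 2^k - 1L)
    membership <- outer(codes, bits, function(code, b) bitwAnd(code, b) != 0L)
    sums <- abs(as.vector(membership %*% diff))
    i <- which.max(sums)
    if (sums[i] > best) { best <- sums[i]; best_code <- codes[i] }
  }
  members <- which(bitwAnd(best_code, bits) != 0L)
  distance_result("tv_set_supremum", best,
                  meta = list(achieving_set = attr(tau, "support")[members]))
}

#' @rdname discrete_distances
#' @export
hellinger_sq <- function(tau, m) {
  tau <- as_prob(tau, "tau"); m <- as_prob(m, "m")
  check_same_support(tau, m)
  distance_result("hellinger_sq",
                  0.5 * sum((sqrt(as.numeric(tau)) - sqrt(as.numeric(m)))^2))
}

#' @rdname discrete_distances
#' @export
affinity <- function(tau, m) {
  tau <- as_prob(tau, "tau"); m <- as_prob(m, "m")
  check_same_support(tau, m)
  distance_result("affinity", sum(sqrt(as.numeric(tau) * as.numeric(m))))
}

#' Matusita's distance
#'
#' `sqrt(sum (sqrt(tau) - sqrt(m))^2)`, i.e. `sqrt(2 * H^2)` where `H^2` is
#' the squared Hellinger distance.
#'
#' @inheritParams discrete_distances
#' @return A [distance_result()].
#' @export
matusita <- function(tau, m) {
  distance_result("matusita", sqrt(2 * dist_value(hellinger_sq(tau, m))))
}

# sum of a*log(a/b) with 0*log(0/b) = 0 and a*log(a/0) = Inf for a > 0
xlogx_over <- function(a, b) {
  if (any(a > 0 & b == 0)) return(Inf)
  pos <- a > 0
  sum(a[pos] * log(a[pos] / b[pos]))
}

#' @rdname discrete_distances
#' @export
kl_divergence <- function(tau, m) {
  tau <- as_prob(tau, "tau"); m <- as_prob(m, "m")
  check_same_support(tau, m)
  distance_result("kl_divergence", xlogx_over(as.numeric(m), as.numeric(tau)))
}

#' @rdname discrete_distances
#' @export
likelihood_distance <- function(tau, m) {
  tau <- as_prob(tau, "tau"); m <- as_prob(m, "m")
  check_same_support(tau, m)
  distance_result("likelihood_distance", xlogx_over(as.numeric(tau), as.numeric(m)))
}

#' @rdname discrete_distances
#' @export
j_divergence <- function(tau, m) {
  distance_result("j_divergence",
                  dist_value(kl_divergence(tau, m)) +
                    dist_value(likelihood_distance(tau, m)))
}

#' @rdname discrete_distances
#' @export
pearson_chisq <- function(tau, m) {
  tau <- as_prob(tau, "tau"); m <- as_prob(m, "m")
  check_same_support(tau, m)
  tt <- as.numeric(tau); mm <- as.numeric(m)
  if (any(tt > 0 & mm == 0)) {
    return(distance_result("pearson_chisq", Inf))
  }
  pos <- mm > 0
  distance_result("pearson_chisq", sum((tt[pos] - mm[pos])^2 / mm[pos]))
}

#' @rdname discrete_distances
#' @export
symmetric_chisq <- function(tau, m) {
  tau <- as_prob(tau, "tau"); m <- as_prob(m, "m")
  check_same_support(tau, m)
  tt <- as.numeric(tau); mm <- as.numeric(m)
  denom <- (tt + mm) / 2
  pos <- denom > 0  # 0/0 cells (both zero) contribute nothing
  distance_result("symmetric_chisq", sum((tt[pos] - mm[pos])^2 / denom[pos]))
}

# registry used by the CLI `dist` subcommand
discrete_measures <- function() {
  list(tv = total_variation, hellinger = hellinger_sq, affinity = affinity,
       matusita = matusita, kl = kl_divergence, lik = likelihood_distance,
       j = j_divergence, pearson = pearson_chisq, s2 = symmetric_chisq)
}

#' Compute a named discrete distance
#'
#' Dispatcher over the discrete measures, keyed by the short names used by the
#' command-line interface: `tv`, `hellinger`, `affinity`, `matusita`, `kl`,
#' `lik`, `j`, `pearson`, `s2`.
#'
#' @param measure Measure name.
#' @inheritParams discrete_distances
#' @return A [distance_result()].
#' @export
discrete_distance <- function(measure, tau, m) {
  reg <- discrete_measures()
  if (!measure %in% names(reg)) {
    stop("unknown measure '", measure, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  }
  reg[[measure]](tau, m)
}
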