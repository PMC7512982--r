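#' Finite discrete probability vector
#'
#' Constructs a probability vector on the sample space `{0, 1, ..., T}`, the
#' basic discrete object the distance functions operate on. Entries must be
#' nonnegative and sum to one; validation is strict because a silently
#' renormalised vector would mask upstream data errors.
#'
#' @param p Numeric vector of probabilities, one per support point.
#' @param support Optional numeric vector of support points; defaults to
#'   `0:(length(p) - 1)`.
#' @param normalize If `TRUE`, divide `p` by its sum before validating.
#'   Renormalisation never happens implicitly.
#'
#' @return An object of class `prob_vector`: a numeric vector with a
#'   `support` attribute.
#' @examples
#' prob_vector(c(0.7, 0.3))
#' prob_vector(c(2, 1, 1), normalize = TRUE)
#' @export
prob_vector <- function(p, support = NULL, normalize = FALSE) {
  if (!is.numeric(p) || length(p) < 1L) {
    stop("`p` must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(p) || any(!is.finite(p))) {
    stop("probabilities must be finite and non-missing", call. = FALSE)
  }
  if (any(p < 0)) {
    stop("probabilities must be nonnegative", call. = FALSE)
  }
  if (normalize) {
    s <- sum(p)
    if (s <= 0) stop("cannot normalize a zero vector", call. = FALSE)
    p <- p / s
  }
  if (abs(sum(p) - 1) > 1e-12) {
    stop("probabilities must sum to 1 within 1e-12 (use `normalize = TRUE` to rescale)",
         call. = FALSE)
  }
  if (is.null(support)) support <- seq_along(p) - 1
  if (length(support) != length(p)) {
    stop("`support` must have one point per probability", call. = FALSE)
  }
  structure(as.numeric(p), support = as.numeric(support), class = "prob_vector")
}

#' Vector of counts over a discrete sample space
#'
#' @param n Nonnegative integer counts, one per support point.
#' @param support Optional support points (defaults to `0:(T)`).
#' @return An object of class `count_vector`.
#' @examples
#' normalize_counts(count_vector(c(3, 1)))
#' @export
count_vector <- function(n, support = NULL) {
  if (!is.numeric(n) || length(n) < 1L || anyNA(n)) {
    stop("`n` must be a non-empty numeric vector of counts", call. = FALSE)
  }
  if (any(n < 0) || any(n != round(n))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(n) <= 0) stop("total count must be positive", call. = FALSE)
  if (is.null(support)) support <- seq_along(n) - 1
  if (length(support) != length(n)) {
    stop("`support` must have one point per count", call. = FALSE)
  }
  structure(as.numeric(n), support = as.numeric(support), class = "count_vector")
}

#' Turn counts into relative frequencies
#'
#' Returns the data estimate `d(t) = n(t) / n` of the generating distribution.
#'
#' @param x A [count_vector()].
#' @return A [prob_vector()].
#' @export
normalize_counts <- function(x) {
  stopifnot(inherits(x, "count_vector"))
  prob_vector(unclass(x) / sum(x), support = attr(x, "support"))
}

#' @export
print.prob_vector <- function(x, ...) {
  cat("<prob_vector> on", length(x), "support points\n")
  print(stats::setNames(as.numeric(x), format(attr(x, "support"))), ...)
  invisible(x)
}

#' @export
print.count_vector <- function(x, ...) {
  cat("<count_vector> total =", sum(x), "\n")
  print(stats::setNames(as.numeric(x), format(attr(x, "support"))), ...)
  invisible(x)
}

# Coerce numeric input to a validated probability vector; used at every
# distance entry point so plain numeric vectors work too.
as_prob <- function(x, arg = "x") {
  if (inherits(x, "prob_vector")) return(x)
  if (inherits(x, "count_vector")) return(normalize_counts(x))
  tryCatch(prob_vector(x), error = function(e) {
    stop(sprintf("`%s` is not a valid probability vector: %s", arg,
                 conditionMessage(e)), call. = FALSE)
  })
}

check_same_support <- function(tau, m) {
  if (length(tau) != length(m)) {
    stop("distributions must share the same support size (got ",
         length(tau), " and ", length(m), ")", call. = FALSE)
  }
}

#' Draw a random probability vector
#'
#' Samples from a symmetric Dirichlet distribution; used throughout the test
#' suite to generate random discrete distributions.
#'
#' @param k Support size.
#' @param concentration Dirichlet concentration parameter (1 = uniform on the
#'   simplex).
#' @return A [prob_vector()].
#' @export
rprob_vector <- function(k, concentration = 1) {
  g <- stats::rgamma(k, shape = concentration)
  while (sum(g) == 0) g <- stats::rgamma(k, shape = concentration)
  prob_vector(g / sum(g))
}

#' Read / write a probability or count vector as two-column CSV
#'
#' The on-disk format is `support,value` with a header row.
#'
#' @param path File path.
#' @param normalize Passed to [prob_vector()]; set `TRUE` to accept
#'   unnormalised weights.
#' @return `read_prob_csv()` returns a [prob_vector()]; `write_prob_csv()`
#'   returns `path` invisibly.
#' @export
read_prob_csv <- function(path, normalize = FALSE) {
  d <- utils::read.csv(path)
  if (ncol(d) < 2L) stop("expected a two-column CSV (support, value)", call. = FALSE)
  prob_vector(d[[2L]], support = d[[1L]], normalize = normalize)
}

#' @rdname read_prob_csv
#' @param x A `prob_vector` or `count_vector`.
#' @export
write_prob_csv <- function(x, path) {
  utils::write.csv(
    data.frame(support = attr(x, "support"), value = as.numeric(x)),
    path, row.names = FALSE)
  invisible(path)
}
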