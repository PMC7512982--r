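#' Distance computation result
#'
#' Every distance in the package returns a `distance_result` rather than a
#' bare number, so diagnostics (achieving set, argmax cell, quadrature
#' warnings) travel with the value.
#'
#' @param name Identifier of the distance.
#' @param value Nonnegative numeric value; `Inf` is legitimate for the
#'   Kullback-Leibler family.
#' @param meta Optional named list of diagnostics.
#' @return An object of class `distance_result` with fields `name`, `value`
#'   and `meta`.
#' @export
distance_result <- function(name, value, meta = list()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(value), length(value) == 1L)
  if (is.nan(value) || (!is.infinite(value) && value < -1e-12)) {
    stop("distance value must be nonnegative", call. = FALSE)
  }
  structure(list(name = name, value = max(0, value), meta = meta),
            class = "distance_result")
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("<distance_result> %s = %s\n", x$name,
              format(x$value, digits = 7)))
  if (length(x$meta)) {
    for (nm in names(x$meta)) {
      v <- x$meta[[nm]]
      if (is.numeric(v) && length(v) <= 4) {
        cat("  ", nm, ": ", paste(format(v, digits = 4), collapse = ", "),
            "\n", sep = "")
      }
    }
  }
  invisible(x)
}

#' Extract the numeric value of a distance result
#'
#' @param x A [distance_result()] (plain numerics pass through).
#' @return A single numeric value.
#' @export
dist_value <- function(x) {
  if (inherits(x, "distance_result")) x$value else as.numeric(x)
}
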