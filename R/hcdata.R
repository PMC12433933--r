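#' Clustered historical control data
#'
#' Container for dichotomous historical control data (HCD): one record per
#' historical control group, holding the number of experimental units with
#' an event \code{y} (e.g., mice with a tumour, cells with a micronucleus)
#' out of the group's total number of experimental units \code{n}.
#'
#' Counts are stored as doubles, not integers, solely so that the half-unit
#' all-zero adjustment (see [adjust_all_zero()]) remains representable; all
#' sampling functions in the package produce integer counts.
#'
#' @param y numeric vector of event counts per historical control group
#'   (non-negative, \code{y[h] <= n[h]}).
#' @param n numeric vector of cluster sizes (positive), same length as
#'   \code{y}.
#'
#' @return An object of class \code{"hcd"}: a data frame with columns
#'   \code{y} and \code{n} and \code{H = nrow} historical groups.
#'
#' @examples
#' hcd(y = c(10, 21, 14), n = c(50, 50, 50))
#' @export
hcd <- function(y, n) {
  y <- as.numeric(y)
  n <- as.numeric(n)
  if (anyNA(y) || anyNA(n)) {
    stop("historical control data must not contain missing values")
  }
  if (length(y) != length(n)) {
    stop("'y' and 'n' must have the same length")
  }
  if (length(y) < 2L) {
    stop("at least 2 historical groups required")
  }
  if (any(n <= 0)) {
    stop("cluster sizes must be positive")
  }
  if (any(y < 0)) {
    stop("event counts must be non-negative")
  }
  if (any(y > n)) {
    stop("event count exceeds cluster size")
  }
  structure(data.frame(y = y, n = n),
            class = c("hcd", "data.frame"))
}

#' @export
print.hcd <- function(x, ...) {
  cat(sprintf("Historical control data: %d groups, pooled proportion %.4g\n",
              nrow(x), sum(x$y) / sum(x$n)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read historical control data from CSV
#'
#' Reads a CSV file with one row per historical control group and returns a
#' validated [hcd] object. Row order is preserved.
#'
#' @param path path to a CSV file with a header row.
#' @param y_column,n_column names of the event-count and cluster-size
#'   columns (defaults \code{"y"} and \code{"n"}).
#'
#' @return An object of class \code{"hcd"}.
#' @seealso [write_hcd()]
#' @export
read_hcd <- function(path, y_column = "y", n_column = "n") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c(y_column, n_column)) {
    if (!col %in% names(df)) {
      stop(sprintf("column '%s' not found in '%s'", col, path))
    }
  }
  yv <- df[[y_column]]
  nv <- df[[n_column]]
  if (!is.numeric(yv) || !is.numeric(nv)) {
    stop("event counts and cluster sizes must be numeric")
  }
  hcd(y = yv, n = nv)
}

#' Write historical control data to CSV
#'
#' @param data an [hcd] object.
#' @param path output file path.
#' @param y_column,n_column column names to use in the header.
#' @return \code{path}, invisibly.
#' @export
write_hcd <- function(data, path, y_column = "y", n_column = "n") {
  stopifnot(inherits(data, "hcd"))
  out <- data.frame(data$y, data$n)
  names(out) <- c(y_column, n_column)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' All-zero (and all-event) half-unit adjustment
#'
#' If every historical group has zero events, the pooled proportion and all
#' dispersion estimates degenerate to zero and no frequentist interval can
#' be computed. In that case the first observation is set to
#' \code{y[1] = 0.5} and its cluster size is reduced by half a unit
#' (\code{n[1] - 0.5}), which keeps the estimation problem well posed while
#' adding the smallest representable signal. The mirrored rule
#' (\code{y[1] = n[1] - 0.5}) is applied when every group shows events in
#' all units. Any other data set is returned unchanged; the adjustment is
#' idempotent.
#'
#' The frequentist estimators ([fit_quasibinomial()], [fit_betabinomial()])
#' apply this adjustment automatically; the Bayesian models do not need it
#' and never use it.
#'
#' @param data an [hcd] object.
#' @return An [hcd] object, adjusted if necessary.
#' @examples
#' adjust_all_zero(hcd(y = c(0, 0, 0), n = c(50, 50, 50)))
#' @export
adjust_all_zero <- function(data) {
  stopifnot(inherits(data, "hcd"))
  if (all(data$y == 0)) {
    data$y[1L] <- 0.5
    data$n[1L] <- data$n[1L] - 0.5
  } else if (all(data$y == data$n)) {
    data$y[1L] <- data$n[1L] - 0.5
  }
  data
}
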