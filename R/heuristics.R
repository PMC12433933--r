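# Heuristic historical control limits used in daily toxicological routine.
# They are comparators, not recommended methods: none of them targets the
# central 1-alpha region of an overdispersed distribution. Limits are
# reported raw (not truncated to [0, n*]); the integer "covered counts"
# (ceiling(l), floor(u)) are a separate presentation step, see
# covered_counts().

.warn_unequal <- function(n, method) {
  if (length(unique(n)) > 1L) {
    warning(sprintf(
      "%s limits assume constant cluster size; the historical cluster sizes differ",
      method), call. = FALSE)
  }
}

.heuristic <- function(l, u, method, k = NA_real_) {
  structure(list(l = l, u = u, method = method, k = k),
            class = "heuristic_limits")
}

#' @export
print.heuristic_limits <- function(x, ...) {
  cat(sprintf("%s limits: [%.2f, %.2f]\n", x$method, x$l, x$u))
  invisible(x)
}

#' Historical range
#'
#' The minimum and maximum observed event counts. Aims to cover all
#' realisations rather than the central \eqn{1-\alpha} region, and is only
#' interpretable under constant cluster size (a warning is issued
#' otherwise).
#'
#' @param data an [hcd] object.
#' @return A \code{"heuristic_limits"} object with elements \code{l},
#'   \code{u}, \code{method}, \code{k}.
#' @export
historical_range <- function(data) {
  stopifnot(inherits(data, "hcd"))
  .warn_unequal(data$n, "historical range")
  .heuristic(min(data$y), max(data$y), "range")
}

#' Shewhart np-chart limits from a pooled proportion
#'
#' Core computation \eqn{n^*\bar\pi \pm k\sqrt{n^*\bar\pi(1-\bar\pi)}};
#' useful when only the pooled proportion (not the raw counts) is
#' available.
#'
#' @param pi_bar pooled event proportion in (0, 1).
#' @param n_star future cluster size.
#' @param k multiplier (2 for "warning", 3 for "action" limits).
#' @return A \code{"heuristic_limits"} object.
#' @examples
#' np_chart_limits(0.276, n_star = 50)  # upper limit 20.12
#' @export
np_chart_limits <- function(pi_bar, n_star, k = 2) {
  if (pi_bar <= 0 || pi_bar >= 1) stop("degenerate pooled proportion")
  centre <- n_star * pi_bar
  half <- k * sqrt(n_star * pi_bar * (1 - pi_bar))
  .heuristic(centre - half, centre + half, "np_chart", k)
}

#' Shewhart np-chart limits for historical control data
#'
#' Limits \eqn{n^*\bar\pi \pm k\sqrt{n^*\bar\pi(1-\bar\pi)}} with the
#' pooled proportion \eqn{\bar\pi = \sum_h y_h/\sum_h n_h}. Assumes
#' independent identically binomial groups: it ignores both the estimation
#' uncertainty in \eqn{\bar\pi} and any overdispersion.
#'
#' @inheritParams historical_range
#' @inheritParams np_chart_limits
#' @return A \code{"heuristic_limits"} object.
#' @export
np_chart <- function(data, n_star, k = 2) {
  stopifnot(inherits(data, "hcd"))
  np_chart_limits(sum(data$y) / sum(data$n), n_star, k)
}

#' Mean plus/minus k standard deviations
#'
#' \eqn{\bar y \pm k \cdot SD} with the sample standard deviation over the
#' \eqn{H} historical counts (divisor \eqn{H-1}). Allows heuristically for
#' overdispersion but assumes symmetry and constant cluster size (warning
#' issued otherwise).
#'
#' @inheritParams historical_range
#' @param k multiplier.
#' @return A \code{"heuristic_limits"} object.
#' @export
mean_k_sd <- function(data, k = 2) {
  stopifnot(inherits(data, "hcd"))
  .warn_unequal(data$n, "mean +/- k SD")
  m <- mean(data$y)
  s <- stats::sd(data$y)
  .heuristic(m - k * s, m + k * s, "mean_sd", k)
}

#' Integer covered-count range of an interval
#'
#' Presentation helper: the lowest and highest integer event counts covered
#' by real-valued limits, \code{(ceiling(l), floor(u))}, clipped to
#' \code{[0, n_star]}.
#'
#' @param x a \code{"heuristic_limits"} or \code{"prediction_interval"}
#'   object, or a numeric vector \code{c(l, u)}.
#' @param n_star future cluster size used for clipping.
#' @return Integer vector \code{c(lower, upper)}.
#' @examples
#' covered_counts(np_chart_limits(0.276, 50), n_star = 50)  # 8, 20
#' @export
covered_counts <- function(x, n_star) {
  lu <- if (is.numeric(x)) x else c(x$l, x$u)
  c(max(0, ceiling(lu[1])), min(n_star, floor(lu[2])))
}
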