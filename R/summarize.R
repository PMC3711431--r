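#' Summary statistics of counts or a piecewise-constant trajectory
#'
#' Computes mean, standard deviation, squared coefficient of variation and
#' the probability of zero. With `time` supplied, values are treated as a
#' piecewise-constant trajectory (each value holds from its time until the
#' next, the last until `t_end`) and all statistics are time-weighted --
#' the correct estimator for a jump process, where holding times carry the
#' information. Without `time`, plain ensemble statistics are returned.
#'
#' @param x Numeric values (counts or levels).
#' @param time Optional event times (min), same length as `x`,
#'   non-decreasing.
#' @param t_end End of the observation window (min); required with `time`.
#' @return A one-row tibble with `mean`, `sd`, `cv2`, `p_zero` and `weight`
#'   (total time, or the number of samples). `cv2` is `NA` when the mean is
#'   zero.
#' @export
#' @examples
#' # value 0 for 1 min then 10 for 3 min: time-weighted mean 7.5
#' summarize_counts(c(0, 10), time = c(0, 1), t_end = 4)
summarize_counts <- function(x, time = NULL, t_end = NULL) {
  stopifnot("x must be non-empty" = length(x) > 0)
  if (is.null(time)) {
    m <- mean(x)
    v <- stats::var(x) * (length(x) - 1) / length(x)
    if (length(x) == 1) v <- 0
    w <- length(x)
    p0 <- mean(x == 0)
  } else {
    stopifnot(
      "time must match x in length" = length(time) == length(x),
      "time must be non-decreasing" = !is.unsorted(time),
      "t_end is required with time and must cover the last event" =
        !is.null(t_end) && t_end >= time[length(time)]
    )
    dt <- diff(c(time, t_end))
    w <- sum(dt)
    stopifnot("observation window has zero length" = w > 0)
    m <- sum(dt * x) / w
    v <- sum(dt * x^2) / w - m^2
    v <- max(v, 0)
    p0 <- sum(dt[x == 0]) / w
  }
  tibble::tibble(
    mean = m, sd = sqrt(v),
    cv2 = if (m > 0) v / m^2 else NA_real_,
    p_zero = p0, weight = w
  )
}
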