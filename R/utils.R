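# Classed error helpers so callers can distinguish validation failures
# from I/O problems programmatically.

stop_invalid <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("pavotrain_invalid_parameter", "error")))
}

stop_empty <- function(msg) {
  stop(errorCondition(msg, class = c("pavotrain_empty_input", "error")))
}

stop_insufficient <- function(msg) {
  stop(errorCondition(msg, class = c("pavotrain_insufficient_points", "error")))
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    stop_invalid(sprintf("`%s` must be > 0 (got %g)", name, x))
  if (nonneg && x < 0)
    stop_invalid(sprintf("`%s` must be >= 0 (got %g)", name, x))
  if (integer && x != round(x))
    stop_invalid(sprintf("`%s` must be an integer (got %g)", name, x))
  invisible(x)
}

# points argument normalizer: accepts a two-column matrix/data.frame or a
# train_pattern; returns a data.frame with x, y.
as_points <- function(points) {
  if (inherits(points, "train_pattern")) {
    return(data.frame(x = points$points$x, y = points$points$y))
  }
  if (is.matrix(points)) points <- as.data.frame(points)
  if (is.data.frame(points)) {
    if (all(c("x", "y") %in% names(points)))
      return(data.frame(x = as.numeric(points$x), y = as.numeric(points$y)))
    if (ncol(points) >= 2L)
      return(data.frame(x = as.numeric(points[[1L]]),
                        y = as.numeric(points[[2L]])))
  }
  stop_invalid("`points` must be a two-column matrix/data.frame or a train_pattern")
}
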