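# Small shared helpers.

#' @keywords internal
sg_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "sitargrowth_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Central 68% interval (16th and 84th percentile, linear interpolation)
#' @keywords internal
ci68 <- function(x) {
  stats::quantile(x, probs = c(0.16, 0.84), type = 7, names = FALSE, na.rm = TRUE)
}

#' Trapezoid-rule integral on a regular grid
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
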