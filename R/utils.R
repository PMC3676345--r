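# Internal condition helpers: every user-facing error carries a condition
# class so callers (and the CLI) can map failures to behaviour.

abort <- function(msg, class, call. = FALSE, ...) {
  stop(errorCondition(msg, class = c(class, "amylocld_error"), ...))
}

abort_validation <- function(msg, ...) {
  abort(msg, class = "amylocld_validation_error", ...)
}

abort_no_steady_state <- function(msg, ...) {
  abort(msg, class = "amylocld_no_steady_state_error", ...)
}

abort_numerical <- function(msg, ...) {
  abort(msg, class = "amylocld_numerical_error", ...)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_scalar_num <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# total-variation distance between two non-negative vectors, compared as
# probability distributions
tv_distance <- function(p, q) {
  stopifnot(length(p) == length(q))
  p <- p / sum(p)
  q <- q / sum(q)
  0.5 * sum(abs(p - q))
}
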