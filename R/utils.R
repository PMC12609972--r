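#' @importFrom rlang abort warn inform .data
#' @importFrom dplyr %>%
NULL

# Derive a per-component seed from a master seed so that, e.g., adding arrays
# to a simulation never perturbs the random stream of earlier arrays.
# Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 7919) %% 2147483647L)
}

stop_if_not_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != round(x)) {
    abort(sprintf("configuration error: `%s` must be a single integer >= 1", name))
  }
  invisible(as.integer(x))
}

stop_if_not_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    abort(sprintf("configuration error: `%s` must be a single positive number", name))
  }
  invisible(x)
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
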