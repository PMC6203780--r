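#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats quantile sd median rbinom runif rexp rnorm optim optimHess
#'   pnorm qnorm cor setNames
#' @importFrom utils head
NULL

# shared argument checks ------------------------------------------------------

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok) {
    abort(sprintf(
      "`%s` must lie in %s%s, %s%s (got %g).",
      name, if (strict) "(" else "[", format(lower), format(upper),
      if (strict) ")" else "]", x
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  as.integer(x)
}

assert_column <- function(data, col) {
  if (!is.character(col) || length(col) != 1L) {
    abort("Column selectors must be single column names (character).")
  }
  if (!col %in% names(data)) {
    abort(sprintf("Column `%s` not found in `data`.", col))
  }
  data[[col]]
}

assert_probability_vector <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be numeric with no missing values.", name))
  }
  bad <- if (strict) x <= 0 | x >= 1 else x < 0 | x > 1
  if (any(bad)) {
    abort(sprintf(
      "`%s` must lie strictly in (0, 1); offending entries: %s.",
      name, paste(utils::head(which(bad), 5L), collapse = ", ")
    ))
  }
  invisible(x)
}

assert_event_vector <- function(event, name = "event") {
  if (!is.numeric(event) || anyNA(event) || !all(event %in% c(0, 1))) {
    abort(sprintf("`%s` must be a 0/1 indicator with no missing values.", name))
  }
  invisible(as.numeric(event))
}

assert_positive_times <- function(time, name = "time") {
  if (!is.numeric(time) || anyNA(time) || any(time <= 0)) {
    abort(sprintf("`%s` must be strictly positive with no missing values.", name))
  }
  invisible(as.numeric(time))
}

# Run an expression under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream seed from a base seed, staying inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483629L) + 1L
}
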