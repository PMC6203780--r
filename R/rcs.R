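#' Knot specification for a restricted cubic spline on log time
#'
#' Royston-Parmar convention: boundary knots at the extremes of the
#' uncensored log event times, interior knots at their quantiles (df = 2
#' puts one interior knot at the median). `df` counts basis terms beyond
#' the intercept, so df = 1 is linear in log time (Weibull family) and a
#' df-term basis carries df - 1 interior knots.
#'
#' @param log_times Log event times of the *uncensored* observations.
#' @param df Degrees of freedom (>= 1).
#' @return A list of class `"rcs_knots"` with `boundary` (length 2) and
#'   `interior` (length df - 1, possibly empty), on the log-time scale.
#' @export
rcs_knots <- function(log_times, df = 2L) {
  df <- assert_count(df, "df")
  if (length(log_times) < df + 1L) {
    abort("Too few event times to place the requested knots.")
  }
  boundary <- range(log_times)
  if (diff(boundary) <= 0) abort("Event times are all identical; cannot place knots.")
  interior <- if (df > 1L) {
    as.numeric(quantile(log_times, probs = seq_len(df - 1L) / df, type = 7))
  } else {
    numeric()
  }
  new_rcs_knots(boundary, interior)
}

new_rcs_knots <- function(boundary, interior) {
  if (length(boundary) != 2L || boundary[1] >= boundary[2]) {
    abort("Boundary knots must be two increasing values.")
  }
  interior <- as.numeric(interior)
  if (is.unsorted(interior, strictly = TRUE) && length(interior) > 1L) {
    abort("Interior knots must be strictly increasing.")
  }
  if (length(interior) > 0 &&
      (min(interior) <= boundary[1] || max(interior) >= boundary[2])) {
    abort("Interior knots must lie strictly inside the boundary knots.")
  }
  structure(list(boundary = boundary, interior = interior,
                 df = length(interior) + 1L),
            class = "rcs_knots")
}

#' Restricted cubic spline basis (Durrleman-Simon)
#'
#' First column is `x` itself; each interior knot contributes one restricted
#' cubic term constrained so the function is linear beyond the boundary
#' knots, with continuous value, first and second derivatives everywhere.
#' For interior knot `k_j` with boundary knots `(k_min, k_max)` and
#' `lambda_j = (k_max - k_j) / (k_max - k_min)`:
#' `v_j(x) = (x - k_j)_+^3 - lambda_j (x - k_min)_+^3 - (1 - lambda_j) (x - k_max)_+^3`.
#'
#' @param x Numeric vector (here: log time).
#' @param knots An `"rcs_knots"` object (or list with `boundary`,
#'   `interior`).
#' @param deriv 0 for the basis, 1 for its derivative in `x`.
#' @return Matrix with `length(interior) + 1` columns.
#' @export
rcs_basis <- function(x, knots, deriv = 0L) {
  if (!inherits(knots, "rcs_knots")) {
    knots <- new_rcs_knots(knots$boundary, knots$interior)
  }
  kmin <- knots$boundary[1]
  kmax <- knots$boundary[2]
  m <- length(knots$interior)
  out <- matrix(0, nrow = length(x), ncol = m + 1L)
  colnames(out) <- paste0("rcs", seq_len(m + 1L))
  if (deriv == 0L) {
    out[, 1L] <- x
  } else {
    out[, 1L] <- 1
  }
  if (m == 0L) return(out)
  cube <- function(u) pmax(u, 0)^3
  dcube <- function(u) 3 * pmax(u, 0)^2
  for (j in seq_len(m)) {
    kj <- knots$interior[j]
    lam <- (kmax - kj) / (kmax - kmin)
    if (deriv == 0L) {
      out[, j + 1L] <- cube(x - kj) - lam * cube(x - kmin) -
        (1 - lam) * cube(x - kmax)
    } else {
      out[, j + 1L] <- dcube(x - kj) - lam * dcube(x - kmin) -
        (1 - lam) * dcube(x - kmax)
    }
  }
  out
}
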