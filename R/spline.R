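#' Restricted cubic spline basis with three knots
#'
#' Harrell's truncated-power restricted cubic spline with three knots yields a
#' two-column basis: the linear term and one restricted nonlinear term
#'
#' \deqn{[(x-k_1)_+^3 - (x-k_2)_+^3 (k_3-k_1)/(k_3-k_2)
#'        + (x-k_3)_+^3 (k_2-k_1)/(k_3-k_2)] / (k_3-k_1)^2.}
#'
#' The fitted curve is linear beyond the boundary knots and has continuous
#' first and second derivatives everywhere. Used for the time-dependent
#' intercept (month since study entry) and for continuous baseline covariates
#' in the pooled logistic weight models.
#'
#' @param x numeric vector of evaluation points.
#' @param knots three strictly increasing knots; by default the 10th, 50th and
#'   90th percentiles of `x`.
#' @return Numeric matrix with columns `lin` and `nonlin`, one row per element
#'   of `x`.
#' @examples
#' rcs_basis(6, knots = c(2, 5, 9))
#' @export
rcs_basis <- function(x, knots = NULL) {
  if (is.null(knots)) knots <- rcs_knots(x)
  if (length(knots) != 3 || any(diff(knots) <= 0)) {
    stop("`knots` must be three strictly increasing values", call. = FALSE)
  }
  k1 <- knots[1]; k2 <- knots[2]; k3 <- knots[3]
  cube <- function(u) pmax(u, 0)^3
  nonlin <- (cube(x - k1) -
               cube(x - k2) * (k3 - k1) / (k3 - k2) +
               cube(x - k3) * (k2 - k1) / (k3 - k2)) / (k3 - k1)^2
  cbind(lin = x, nonlin = nonlin)
}

#' @rdname rcs_basis
#' @export
rcs_knots <- function(x) {
  k <- unname(quantile(x, c(0.1, 0.5, 0.9), na.rm = TRUE, type = 7))
  if (any(diff(k) <= 0)) {
    # degenerate percentile spread (e.g. heavily tied variable): fall back to
    # evenly spaced interior knots over the observed range
    r <- range(x, na.rm = TRUE)
    if (diff(r) <= 0) r <- r + c(-0.5, 0.5)
    k <- r[1] + diff(r) * c(0.1, 0.5, 0.9)
  }
  k
}
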