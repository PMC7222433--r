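#' Local polynomial regression with tricube weights
#'
#' Loess-style smoother used for expression-versus-length curves. At each
#' target point the `ceil(span * n)` nearest observations (by |x - xi|)
#' receive tricube weights `(1 - (d/dmax)^3)^3` and a weighted
#' least-squares polynomial of the requested degree is fitted; the
#' smoothed value is the fit evaluated at the target. With `span = 1` and
#' a polynomial degree d the smoother reproduces any degree-<=d polynomial
#' exactly. Degenerate neighborhoods (all neighbors at the same x, or all
#' weights zero) fall back to a weighted/plain mean with a message.
#'
#' @param x,y numeric vectors of equal length
#' @param span neighborhood size as a proportion of points, in (0, 1]
#'   (default 0.1)
#' @param degree local polynomial degree (default 2)
#' @return fitted values at each `x`, in input order
#' @export
loess_smooth <- function(x, y, span = 0.1, degree = 2) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (degree < 0) stop("degree must be >= 0")
  if (n < degree + 2) stop("need at least degree + 2 points")
  m <- max(ceiling(span * n), degree + 1L)
  m <- min(m, n)
  fitted <- numeric(n)
  fell_back <- 0L
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    idx <- order(d)[seq_len(m)]
    dmax <- max(d[idx])
    if (dmax == 0) {           # all neighbors at the target x
      fitted[i] <- mean(y[idx])
      next
    }
    w <- (1 - (d[idx] / dmax)^3)^3
    if (sum(w) == 0) {         # all neighbors exactly at dmax
      fitted[i] <- mean(y[idx])
      next
    }
    xc <- x[idx] - x[i]        # center so the intercept is the fit at x[i]
    if (length(unique(x[idx])) < degree + 1L) {
      fitted[i] <- sum(w * y[idx]) / sum(w)
      fell_back <- fell_back + 1L
      next
    }
    X <- outer(xc, 0:degree, `^`)
    fit <- stats::lm.wfit(X, y[idx], w)
    co <- fit$coefficients
    co[is.na(co)] <- 0
    fitted[i] <- co[1]
  }
  if (fell_back > 0) {
    message(fell_back, " degenerate neighborhood(s) fell back to a weighted mean")
  }
  fitted
}
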