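# Polynomial saturation regression on build curves, derivative-based plateau
# estimation, predicted total peak count and fraction discovered.

#' Construct a polynomial model from known coefficients
#'
#' Wraps published or otherwise externally obtained coefficients in a
#' [PolynomialModel] so the derivative/plateau machinery can be applied to
#' them directly.
#'
#' @param coefficients numeric coefficients in ascending degree (intercept
#'   first).
#' @param fitDomain optional numeric(2) x-range the model describes.
#' @param rSquared optional goodness of fit.
#' @return a [PolynomialModel].
#' @export
polynomialModel <- function(coefficients, fitDomain = c(NA_real_, NA_real_),
                            rSquared = NA_real_) {
  assertThat(length(coefficients) >= 1L, "need at least one coefficient")
  new("PolynomialModel", coefficients = as.numeric(coefficients),
      order = length(coefficients) - 1L, rSquared = as.numeric(rSquared),
      fitDomain = as.numeric(fitDomain))
}

#' Evaluate a polynomial model
#'
#' @param model a [PolynomialModel].
#' @param x numeric vector of evaluation points.
#' @return numeric vector of `y(x)`.
#' @export
evalPolynomial <- function(model, x) {
  co <- coef(model)
  y <- numeric(length(x))
  for (d in seq_along(co)) y <- y + co[d] * x^(d - 1)
  y
}

#' Fit polynomial saturation models of increasing order
#'
#' Least-squares polynomial fits of orders 1..`max_order` to build-curve
#' points. Because R-squared of nested polynomial fits is non-decreasing in
#' order, "pick the highest R-squared" degenerates to the largest order; the
#' default criterion instead selects the lowest order whose R-squared is
#' within `delta_r2` of the order-`max_order` fit. Alternatives: adjusted
#' R-squared (`"adj_r2"`) or a fixed order (`select = 3` etc.).
#'
#' @param points `data.frame` with numeric columns `x` and `y` (e.g. a build
#'   curve's `replicates_added`/`peak_count`).
#' @param max_order maximum polynomial order (default 5).
#' @param select `"delta_r2"`, `"adj_r2"`, or an integer fixed order.
#' @param delta_r2 tolerance for the default criterion.
#' @return list with `model` (the selected [PolynomialModel]) and
#'   `candidates` (all fitted models, indexed by order).
#' @export
fitPolynomials <- function(points, max_order = 5L, select = "delta_r2",
                           delta_r2 = 1e-3) {
  x <- points$x
  y <- points$y
  assertThat(!is.null(x) && !is.null(y), "points must have columns x and y")
  assertThat(length(unique(x)) >= 2L, "need at least two distinct x values")
  fitOne <- function(ord) {
    if (length(unique(x)) < ord + 2L) {
      warning("order ", ord, " skipped: needs at least ", ord + 2L,
              " distinct x values", call. = FALSE)
      return(NULL)
    }
    fit <- lm(y ~ poly(x, degree = ord, raw = TRUE))
    ssRes <- sum((y - fitted(fit))^2)
    ssTot <- sum((y - mean(y))^2)
    r2 <- if (ssTot == 0) 1 else 1 - ssRes / ssTot
    co <- unname(coef(fit))
    co[is.na(co)] <- 0 # rank-deficient tail terms contribute nothing
    polynomialModel(co, fitDomain = range(x), rSquared = r2)
  }
  candidates <- lapply(seq_len(max_order), fitOne)
  names(candidates) <- paste0("order", seq_len(max_order))
  avail <- which(!vapply(candidates, is.null, logical(1)))
  assertThat(length(avail) > 0, "no polynomial order could be fitted")
  r2 <- vapply(candidates[avail], function(m) m@rSquared, numeric(1))
  chosen <- if (is.numeric(select)) {
    assertThat(as.integer(select) %in% avail, "requested order was not fittable")
    as.integer(select)
  } else if (select == "adj_r2") {
    nObs <- length(x)
    adj <- 1 - (1 - r2) * (nObs - 1) / (nObs - avail - 1)
    avail[which.max(adj)]
  } else {
    best <- max(r2)
    avail[which(r2 >= best - delta_r2)[1]]
  }
  list(model = candidates[[chosen]], candidates = candidates)
}

#' First derivative of a polynomial model
#'
#' Exact term-wise differentiation; the derivative of a constant is the zero
#' polynomial (order 0, coefficient 0).
#'
#' @param model a [PolynomialModel].
#' @return a [PolynomialModel] of order `max(order - 1, 0)`.
#' @export
polyDerivative <- function(model) {
  co <- coef(model)
  if (length(co) <= 1L) return(polynomialModel(0, fitDomain = model@fitDomain))
  dco <- co[-1] * seq_len(length(co) - 1L)
  polynomialModel(dco, fitDomain = model@fitDomain)
}

#' Smallest positive root of a polynomial
#'
#' Dense sign-scan over `(0, horizon]` followed by bisection to an interval
#' width below `tol`. Grid points where the polynomial vanishes exactly are
#' accepted as roots. Returns `NA` when no sign change occurs in the window.
#'
#' @param model a [PolynomialModel] (must not be the zero polynomial).
#' @param horizon upper end of the search interval (> 0).
#' @param tol bisection convergence tolerance on x (default 1e-9).
#' @param grid number of sign-scan points (default 20000).
#' @return numeric(1) root, or `NA_real_`.
#' @export
smallestPositiveRoot <- function(model, horizon, tol = 1e-9, grid = 20000L) {
  co <- coef(model)
  if (all(co == 0)) stop("zero polynomial has no well-defined roots", call. = FALSE)
  assertThat(horizon > 0, "horizon must be positive")
  xs <- seq(0, horizon, length.out = grid + 1L)[-1]
  ys <- evalPolynomial(model, xs)
  exact <- which(ys == 0)
  if (length(exact)) return(xs[exact[1]])
  flips <- which(ys[-1] * ys[-length(ys)] < 0)
  if (!length(flips)) return(NA_real_)
  lo <- xs[flips[1]]
  hi <- xs[flips[1] + 1L]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (evalPolynomial(model, lo) * evalPolynomial(model, mid) <= 0) hi <- mid
    else lo <- mid
  }
  (lo + hi) / 2
}

#' Plateau of a saturation model
#'
#' The plateau is the smallest positive x at which the model's first
#' derivative reaches zero within the extrapolation horizon (default three
#' times the largest fitted x); the predicted total peak count is the model
#' evaluated there. An unreached plateau is reported explicitly with `NA`s.
#'
#' @param model a fitted [PolynomialModel].
#' @param horizon maximum extrapolation x; defaults to `3 * max(fitDomain)`.
#' @return list with `x_star` (replicates), `y_star` (predicted total
#'   peaks), `horizon`, and `reached` (logical).
#' @export
plateauEstimate <- function(model, horizon = NULL) {
  if (is.null(horizon)) {
    assertThat(!is.na(model@fitDomain[2]),
               "model has no fit domain; supply horizon explicitly")
    horizon <- 3 * model@fitDomain[2]
  }
  xStar <- smallestPositiveRoot(polyDerivative(model), horizon)
  if (is.na(xStar)) {
    return(list(x_star = NA_real_, y_star = NA_real_, horizon = horizon,
                reached = FALSE))
  }
  list(x_star = xStar, y_star = evalPolynomial(model, xStar),
       horizon = horizon, reached = TRUE)
}

#' Fraction of the predicted total already discovered
#'
#' `100 * observed / predicted_total`, in percent.
#'
#' @param observed_count observed number of peaks.
#' @param predicted_total model-predicted total at the plateau (> 0).
#' @return numeric percentage.
#' @examples
#' fractionDiscovered(50, 100) # 50
#' @export
fractionDiscovered <- function(observed_count, predicted_total) {
  assertThat(is.finite(predicted_total) && predicted_total > 0,
             "predicted total must be positive")
  100 * observed_count / predicted_total
}
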