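# The published regression coefficients used as oracle inputs throughout:
# a cubic for the low-concordance factor and a quintic for the histone mark,
# both in ascending degree.
cubicAsc <- c(-812.39289, 1036.53907, -20.94564, 0.08184)
quinticAsc <- c(14700.3867, 370.7989, 176.2564, -74.7615, 10.3849, -0.4687)

test_that("exact polynomial data is recovered with R^2 = 1", {
  x <- 1:12
  y <- evalPolynomial(polynomialModel(cubicAsc), x)
  fit <- fitPolynomials(data.frame(x = x, y = y), max_order = 5, select = 3)
  expect_equal(fit$model@order, 3L)
  expect_equal(coef(fit$model), cubicAsc, tolerance = 1e-6)
  expect_equal(fit$model@rSquared, 1, tolerance = 1e-12)
  # the parsimonious default criterion never selects a higher order
  expect_lte(fitPolynomials(data.frame(x = x, y = y))$model@order, 3L)

  # quadratic with tiny noise selects a low order under the default criterion
  y2 <- withr::with_seed(7, 3 + 2 * x - 0.5 * x^2 + rnorm(12, sd = 1e-6))
  fit2 <- fitPolynomials(data.frame(x = x, y = y2), max_order = 5)
  expect_lte(fit2$model@order, 3L)
  # nested R^2 is non-decreasing with order
  r2 <- vapply(fit2$candidates, function(m) m@rSquared, numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
})

test_that("differentiation is exact term-wise and invertible", {
  expect_equal(coef(polyDerivative(polynomialModel(c(0, 0, 1)))), c(0, 2))
  expect_equal(coef(polyDerivative(polynomialModel(5))), 0)
  d <- polyDerivative(polynomialModel(cubicAsc))
  expect_equal(coef(d), c(1036.53907, -41.89128, 0.24552))
  # integrate back with the matching constant
  integ <- c(cubicAsc[1], coef(d) / seq_along(coef(d)))
  expect_equal(integ, cubicAsc)
})

test_that("the root finder matches closed forms", {
  expect_equal(smallestPositiveRoot(polynomialModel(c(-1, 0, 3)), 10),
               1 / sqrt(3), tolerance = 1e-8)
  expect_error(smallestPositiveRoot(polynomialModel(0), 10), "zero polynomial")
  expect_true(is.na(smallestPositiveRoot(polynomialModel(c(1, 0, 1)), 10)))
  withr::with_seed(21, {
    for (i in 1:100) {
      r1 <- runif(1, 0.05, 50)
      r2 <- runif(1, 0.05, 50)
      a <- runif(1, -5, 5)
      if (abs(a) < 1e-3) a <- 1
      # a (x - r1)(x - r2): roots known exactly
      co <- c(a * r1 * r2, -a * (r1 + r2), a)
      got <- smallestPositiveRoot(polynomialModel(co), 60)
      expect_equal(got, min(r1, r2), tolerance = 1e-6)
    }
  })
})

test_that("published models plateau where the text says they do", {
  quintic <- polynomialModel(quinticAsc, fitDomain = c(1, 10))
  rootQ <- smallestPositiveRoot(polyDerivative(quintic), 50)
  expect_gt(rootQ, 9)
  expect_lt(rootQ, 10)
  plat <- plateauEstimate(quintic, horizon = 50)
  expect_true(plat$reached)
  expect_equal(plat$x_star, rootQ)

  cubic <- polynomialModel(cubicAsc, fitDomain = c(1, 25))
  d <- coef(polyDerivative(cubic))
  disc <- d[2]^2 - 4 * d[3] * d[1]
  closedForm <- (-d[2] - sqrt(disc)) / (2 * d[3])
  plat2 <- plateauEstimate(cubic, horizon = 75)
  expect_equal(plat2$x_star, closedForm, tolerance = 1e-6)
  expect_gte(plat2$x_star, 27)
  expect_equal(plat2$y_star, evalPolynomial(cubic, plat2$x_star))

  # strictly increasing model: derivative root at 0, no positive plateau
  none <- plateauEstimate(polynomialModel(c(0, 0, 1)), horizon = 10)
  expect_false(none$reached)
})

test_that("fraction discovered reproduces the published arithmetic", {
  expect_equal(fractionDiscovered(100, 100), 100)
  expect_equal(fractionDiscovered(50, 100), 50)
  cubic <- polynomialModel(cubicAsc)
  expect_gte(fractionDiscovered(12672, evalPolynomial(cubic, 27)), 93)
  expect_error(fractionDiscovered(10, 0), "positive")
})

test_that("a noisy saturating curve recovers the known plateau", {
  # noisy observations of the published cubic over 25 replicates, 3 repeats
  truthModel <- polynomialModel(cubicAsc)
  truthPlat <- plateauEstimate(truthModel, horizon = 75)
  x <- rep(1:25, 3)
  y <- withr::with_seed(5,
    evalPolynomial(truthModel, x) + rnorm(length(x), sd = 100))
  fit <- fitPolynomials(data.frame(x = x, y = y), max_order = 5, select = 3)
  plat <- plateauEstimate(fit$model, horizon = 75)
  expect_true(plat$reached)
  expect_lt(abs(plat$x_star - truthPlat$x_star) / truthPlat$x_star, 0.15)
  expect_lt(abs(plat$y_star - truthPlat$y_star) / truthPlat$y_star, 0.15)
})
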