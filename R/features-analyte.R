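#' @title Analyte-level features: rates and growth-model fits
#' @description
#' Features computable from a single analyte time course: numerically
#' determined rates (second-order finite-difference gradients on possibly
#' nonuniform grids) and least-squares fits of microbial growth models.
#' Exponential growth dX/dt = mu*X, i.e. X = X0*exp(mu*t), covers the log
#' phase; lag and stationary phases call for sigmoids, here the
#' biologically-parameterized generalized logistic and the 5-parameter
#' Richards curve, whose parameters are the asymptote A, the maximum specific
#' growth rate mu_max (1/h) and the lag time lam (h).
#' @name features-analyte
NULL

finite_points <- function(course) {
  keep <- is.finite(course$values)
  list(times = course$times[keep], values = course$values[keep])
}

#' Numerical rate (gradient) of an analyte course
#'
#' Missing values are dropped first. Interior points use the second-order
#' three-point formula for nonuniform spacing (exact for quadratics); the two
#' endpoints use first-order one-sided differences.
#'
#' @param course an `analyte_course` with at least 2 finite points
#' @return a `rate_series`: list with `times`, `rates`
#'   (course unit per hour) and `kind = "gradient"`
#' @export
gradient <- function(course) {
  fp <- finite_points(course)
  t <- fp$times; y <- fp$values
  n <- length(t)
  if (n < 2L) stop("insufficient data: need >= 2 finite points", call. = FALSE)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (t[2] - t[1])
  g[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
  if (n > 2L) {
    for (i in 2:(n - 1)) {
      h1 <- t[i] - t[i - 1]; h2 <- t[i + 1] - t[i]
      g[i] <- -y[i - 1] * h2 / (h1 * (h1 + h2)) +
        y[i] * (h2 - h1) / (h1 * h2) +
        y[i + 1] * h1 / (h2 * (h1 + h2))
    }
  }
  rate_series(t, g, "gradient")
}

rate_series <- function(times, rates, kind) {
  structure(list(times = times, rates = rates,
                 kind = match.arg(kind, c("gradient", "specific", "normalized"))),
            class = "rate_series")
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf("<rate_series> kind=%s, %d points\n", x$kind, length(x$times)))
  invisible(x)
}

#' Generalized logistic growth curve
#'
#' `X(t) = A / (1 + exp(4 * mu_max / A * (lam - t) + 2))`, the
#' Zwietering-style reparameterization in which A is the asymptote, mu_max
#' the maximum specific growth rate (slope of the inflection tangent) and lam
#' the lag time (intercept of that tangent with the t axis).
#'
#' @param t time, hours
#' @param A asymptote (same unit as the data)
#' @param mu_max maximum specific growth rate, 1/h
#' @param lam lag time, h
#' @return biomass value(s)
#' @export
growth_gen_logistic <- function(t, A, mu_max, lam) {
  A / (1 + exp(4 * mu_max / A * (lam - t) + 2))
}

#' Five-parameter Richards growth curve
#'
#' `X(t) = X0 + (A - X0) * [1 + nu * exp(1 + nu) *
#'   exp((mu_max / A) * (1 + nu)^(1 + 1/nu) * (lam - t))]^(-1/nu)`
#' with shape parameter nu > 0 controlling inflection asymmetry (nu = 1
#' recovers a logistic-type curve) and X0 a baseline offset.
#'
#' @param t time, hours
#' @param A asymptote
#' @param mu_max maximum specific growth rate, 1/h
#' @param lam lag time, h
#' @param nu shape parameter, > 0
#' @param X0 baseline offset
#' @return biomass value(s)
#' @export
growth_richards5 <- function(t, A, mu_max, lam, nu, X0) {
  X0 + (A - X0) * (1 + nu * exp(1 + nu) *
    exp((mu_max / A) * (1 + nu)^(1 + 1 / nu) * (lam - t)))^(-1 / nu)
}

min_points_for <- c(exponential = 3L, gen_logistic = 5L, richards5 = 6L)

#' Fit a growth model to an analyte course
#'
#' Missing values are dropped; the remaining points (optionally restricted to
#' a time `window`) are fit by least squares. The exponential model is solved
#' exactly by ordinary least squares on log-transformed values; the sigmoid
#' models use bounded Levenberg-Marquardt nonlinear least squares with a
#' deterministic initializer (A = max(y), X0 = min(y), mu_max = the largest
#' finite-difference slope, lam = time of that slope minus A/(2*slope),
#' nu = 1), so repeated fits of the same data give identical results.
#'
#' @param course an `analyte_course`
#' @param model `"exponential"`, `"gen_logistic"` or `"richards5"`
#' @param window optional `c(t_min, t_max)` restricting the fit
#' @return a `growth_fit` with elements `model`, `params` (named list),
#'   `rss`, `n_points`, `fitted_fn`
#' @examples
#' id <- parse_identifier("strain:A|media:M9|analyte:OD600")
#' tt <- seq(0, 5, by = 0.5)
#' co <- analyte_course(id, tt, 0.05 * exp(0.6 * tt), unit = "OD")
#' coef(fit_growth_model(co, "exponential"))
#' @export
fit_growth_model <- function(course,
                             model = c("exponential", "gen_logistic", "richards5"),
                             window = NULL) {
  model <- match.arg(model)
  fp <- finite_points(course)
  t <- fp$times; y <- fp$values
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; y <- y[keep]
  }
  n <- length(t)
  if (n < min_points_for[[model]])
    stop(sprintf("insufficient data: %s fit needs >= %d finite points, got %d",
                 model, min_points_for[[model]], n), call. = FALSE)

  if (model == "exponential") {
    if (any(y <= 0))
      stop("exponential fit requires strictly positive values", call. = FALSE)
    fit <- stats::lm.fit(cbind(1, t), log(y))
    X0 <- exp(fit$coefficients[[1]]); mu <- fit$coefficients[[2]]
    pred <- function(tt) X0 * exp(mu * tt)
    params <- list(X0 = X0, mu = mu)
  } else {
    slopes <- diff(y) / diff(t)
    imax <- which.max(slopes)
    s0 <- max(slopes[imax], 1e-6)
    A0 <- max(y)
    lam0 <- max(t[imax] - A0 / (2 * s0), 0)
    start <- if (model == "gen_logistic") {
      list(A = A0, mu_max = s0, lam = lam0)
    } else {
      list(A = A0, mu_max = s0, lam = lam0, nu = 1, X0 = min(y))
    }
    lower <- if (model == "gen_logistic") c(A = 1e-8, mu_max = 1e-8, lam = -Inf)
             else c(A = 1e-8, mu_max = 1e-8, lam = -Inf, nu = 1e-3, X0 = -Inf)
    fn <- if (model == "gen_logistic") {
      function(p, tt) growth_gen_logistic(tt, p[["A"]], p[["mu_max"]], p[["lam"]])
    } else {
      function(p, tt) growth_richards5(tt, p[["A"]], p[["mu_max"]], p[["lam"]],
                                       p[["nu"]], p[["X0"]])
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = unlist(start),
                         fn = function(p) fn(p, t) - y,
                         lower = lower,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e)
        stop(sprintf("growth-model fit failed to converge: %s",
                     conditionMessage(e)), call. = FALSE))
    if (fit$info == 0L || fit$info == 9L)
      stop(sprintf("growth-model fit did not converge (info=%d); last iterate: %s",
                   fit$info, paste(signif(fit$par, 6), collapse = ", ")),
           call. = FALSE)
    p <- fit$par
    pred <- function(tt) fn(p, tt)
    params <- as.list(p)
  }
  rss <- sum((pred(t) - y)^2)
  structure(list(model = model, params = params, rss = rss, n_points = n,
                 fitted_fn = pred, times = t, values = y),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> model=%s, n=%d, rss=%.4g\n", x$model, x$n_points,
              x$rss))
  print(unlist(x$params))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) unlist(object$params)

#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$times
        else if (is.list(newdata)) newdata$times else newdata
  object$fitted_fn(tt)
}

#' @export
residuals.growth_fit <- function(object, ...) {
  object$values - object$fitted_fn(object$times)
}
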