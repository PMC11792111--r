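#' Fit a low-dimensional smooth dose-response curve
#'
#' Fits response against log dose with a cubic-regression-spline smooth
#' capped at `max_basis` basis functions (plus intercept), the small-basis
#' GAM idiom used to characterize herbivore dose-response ladders. The hard
#' cap on basis dimension is the overfitting guard; by default no ridge
#' penalty is applied on top of it, because data-driven penalization at
#' ladder-scale noise shrinks the fitted curvature (and hence every
#' Jensen-type functional of the curve) without that shrinkage being
#' reflected in the coefficient covariance. Set `penalize = TRUE` for a
#' conventional REML-penalized fit.
#'
#' Proportions supplied under the logit link are shrunk away from 0/1 with
#' the usual `(p * (n - 1) + 0.5) / n` adjustment before transformation,
#' and the model is Gaussian on the link scale. The basis spans all
#' functions linear in log dose, so data lying exactly on such a line are
#' reproduced exactly.
#'
#' @param dose vector of strictly positive doses (nmol/mg).
#' @param response vector of responses; raw proportions when
#'   `link = "logit"`, link-scale (raw) values otherwise.
#' @param max_basis maximum number of spline coefficients beyond the
#'   intercept (default 4).
#' @param link `"identity"` or `"logit"`.
#' @param penalize add a REML-selected ridge penalty (default `FALSE`).
#' @return An object of class `c("smooth_curve", "dose_response")` wrapping
#'   the fitted [mgcv::gam()] model, with elements `coefficients`,
#'   `coefficient_covariance` (Bayesian posterior covariance of the
#'   coefficients), `dose_range`, `link`, `max_basis` and `sigma` (residual
#'   SD on the link scale).
#' @examples
#' d <- exp(seq(log(0.031), log(16.1), length.out = 10))
#' y <- predict(hill_curve(1, 0, 1, 2), rep(d, 3))
#' fit <- fit_dose_response(rep(d, 3), y)
#' predict(fit, d)
#' @export
fit_dose_response <- function(dose, response, max_basis = 4,
                              link = c("identity", "logit"),
                              penalize = FALSE) {
  link <- match.arg(link)
  if (length(dose) != length(response))
    stop("`dose` and `response` must have the same length", call. = FALSE)
  keep <- is.finite(dose) & is.finite(response)
  dose <- dose[keep]; response <- response[keep]
  if (any(dose <= 0))
    stop("doses must be strictly positive (smooth is fitted on log dose)",
         call. = FALSE)
  if (length(dose) < max_basis + 2)
    stop("need at least max_basis + 2 observations to fit the smooth",
         call. = FALSE)
  if (length(unique(dose)) < 2)
    stop("all doses identical: dose effect is not identifiable", call. = FALSE)
  y <- if (link == "logit") adjusted_logit(response) else response
  dat <- data.frame(log_dose = log(dose), y = y)
  # mgcv's centering constraint absorbs one dimension: k = max_basis + 1
  # yields max_basis spline coefficients plus the model intercept
  k <- min(max_basis + 1L, length(unique(dose)) - 1L)
  model <- if (penalize)
    mgcv::gam(y ~ s(log_dose, k = k, bs = "cr"), data = dat, method = "REML")
  else
    mgcv::gam(y ~ s(log_dose, k = k, bs = "cr"), data = dat, sp = 0)
  structure(
    list(form = "smooth", model = model,
         coefficients = stats::coef(model),
         coefficient_covariance = stats::vcov(model),
         sigma = sqrt(model$sig2),
         dose_range = range(dose), link = link, max_basis = max_basis),
    class = c("smooth_curve", "dose_response")
  )
}

#' Logit transform with boundary shrinkage
#'
#' `(p * (n - 1) + 0.5) / n` pulls exact 0s and 1s off the boundary before
#' the logit, with `n` the number of observations contributing.
#'
#' @param p proportions in \[0, 1\].
#' @param n shrinkage sample size; defaults to `length(p)`.
#' @return `qlogis` of the shrunk proportions.
#' @export
adjusted_logit <- function(p, n = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  stats::qlogis((p * (n - 1) + 0.5) / n)
}

#' @rdname predict.hill_curve
#' @param warn_extrapolation warn when any dose falls outside the fitted
#'   range (the cubic spline continues linearly beyond its boundary knots).
#' @return For smooth curves the result carries a logical attribute
#'   `"extrapolated"` marking doses outside `dose_range`.
#' @export
predict.smooth_curve <- function(object, x, warn_extrapolation = TRUE, ...) {
  .check_dose(x)
  outside <- x < object$dose_range[1] | x > object$dose_range[2]
  if (warn_extrapolation && any(outside))
    warning(sum(outside), " dose(s) outside the fitted range [",
            signif(object$dose_range[1], 3), ", ",
            signif(object$dose_range[2], 3),
            "] nmol/mg; spline extrapolation used", call. = FALSE)
  xx <- pmax(x, .Machine$double.xmin)  # log(0) guard; dose 0 is extrapolated anyway
  out <- as.numeric(stats::predict(object$model,
                                   newdata = data.frame(log_dose = log(xx))))
  attr(out, "extrapolated") <- outside
  out
}

#' Finite-difference curvature of a smooth curve
#'
#' @inheritParams curvature
#' @param step_frac central-difference step as a fraction of the fitted dose
#'   range width (default 1e-4).
#' @export
curvature.smooth_curve <- function(curve, x, step_frac = 1e-4, ...) {
  .check_dose(x)
  h <- step_frac * diff(curve$dose_range)
  pos <- x[x > 0]
  if (length(pos)) h <- min(h, min(pos) / 2)  # keep x - h on the dose domain
  f <- function(z) as.numeric(predict(curve, z, warn_extrapolation = FALSE))
  (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

#' Draw curve realizations from a fitted smooth
#'
#' Samples coefficient vectors from the multivariate normal approximation at
#' the penalized optimum (mean = fitted coefficients, covariance = Bayesian
#' posterior covariance of the GAM), giving a set of plausible dose-response
#' curves that propagate fit uncertainty into downstream simulations.
#'
#' @param fit a `smooth_curve` from [fit_dose_response()].
#' @param n_draws number of curves to draw (>= 1).
#' @param seed integer seed; identical seeds give identical draw sets.
#' @return An object of class `curve_draws`: the fit plus an
#'   `n_draws x p` coefficient matrix. Evaluate all draws at once with
#'   [eval_draws()].
#' @export
sample_curve_draws <- function(fit, n_draws, seed = 1L) {
  stopifnot(inherits(fit, "smooth_curve"))
  if (!is.numeric(n_draws) || n_draws < 1)
    stop("`n_draws` must be >= 1", call. = FALSE)
  V <- fit$coefficient_covariance
  V <- (V + t(V)) / 2
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("coefficient covariance is not positive semi-definite", call. = FALSE)
  mu <- fit$coefficients
  set.seed(as.integer(seed))
  coefs <- MASS::mvrnorm(as.integer(n_draws), mu, V, tol = 1e-6)
  if (is.null(dim(coefs))) coefs <- matrix(coefs, nrow = 1,
                                           dimnames = list(NULL, names(mu)))
  structure(list(fit = fit, coefs = coefs, link = fit$link,
                 dose_range = fit$dose_range, seed = as.integer(seed)),
            class = "curve_draws")
}

#' Evaluate a set of curve draws on a dose grid
#'
#' @param draws a `curve_draws` object, a list of `dose_response` curves, or
#'   a single `dose_response` (treated as one draw).
#' @param x vector of doses.
#' @param ... passed to the evaluation of each draw.
#' @return a `length(x) x n_draws` numeric matrix.
#' @export
eval_draws <- function(draws, x, ...) UseMethod("eval_draws")

#' @export
eval_draws.curve_draws <- function(draws, x, ...) {
  .check_dose(x)
  xx <- pmax(x, .Machine$double.xmin)
  Xp <- stats::predict(draws$fit$model,
                       newdata = data.frame(log_dose = log(xx)),
                       type = "lpmatrix")
  Xp %*% t(draws$coefs)
}

#' @export
eval_draws.dose_response <- function(draws, x, ...) {
  matrix(predict(draws, x, ...), ncol = 1)
}

#' @export
eval_draws.list <- function(draws, x, ...) {
  stopifnot(length(draws) >= 1, all(vapply(draws, inherits, TRUE, "dose_response")))
  out <- vapply(draws, function(cv) as.numeric(predict(cv, x, ...)),
                numeric(length(x)))
  matrix(out, nrow = length(x))
}

#' @export
print.smooth_curve <- function(x, ...) {
  cat("Penalized smooth dose-response curve (cubic spline on log dose)\n")
  cat(sprintf("  link = %s, basis dim <= %d, dose range [%.3g, %.3g] nmol/mg\n",
              x$link, x$max_basis, x$dose_range[1], x$dose_range[2]))
  cat(sprintf("  residual SD (link scale) = %.4g\n", x$sigma))
  invisible(x)
}

#' @export
length.curve_draws <- function(x) nrow(x$coefs)
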