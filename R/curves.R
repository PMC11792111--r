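#' Hill dose-response curve
#'
#' Constructs a four-parameter Hill (log-logistic) dose-response curve
#' \deqn{f(x) = e_0 + (e_{max} - e_0) \frac{x^n}{x^n + ec_{50}^n},}
#' the toxicology workhorse for saturating responses to a toxin dose.
#' Responses are expressed on the declared link scale (identity for growth
#' rates, logit for proportion herbivory), so the curve itself is always
#' evaluated as an unconstrained real function of dose.
#'
#' @param e0 response at zero dose (link scale).
#' @param emax asymptotic response at infinite dose (link scale).
#' @param ec50 dose of half-maximal effect, in nmol/mg fresh weight; must be
#'   positive.
#' @param n Hill coefficient (steepness), positive and dimensionless.
#' @param link link-scale label, one of `"identity"`, `"logit"`, `"log"`.
#'   Purely an annotation carried through to downstream summaries.
#' @return An object of class `c("hill_curve", "dose_response")`.
#' @examples
#' f <- hill_curve(e0 = 1, emax = 0, ec50 = 1, n = 2)
#' predict(f, c(0, 1, 10))
#' @seealso [linear_curve()], [fit_dose_response()], [curvature()]
#' @export
hill_curve <- function(e0, emax, ec50, n, link = "identity") {
  stopifnot(is.finite(e0), is.finite(emax))
  if (!is.numeric(ec50) || length(ec50) != 1L || !is.finite(ec50) || ec50 <= 0)
    stop("`ec50` must be a positive finite number", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("`n` (Hill coefficient) must be a positive finite number", call. = FALSE)
  link <- match.arg(link, c("identity", "logit", "log"))
  structure(
    list(form = "hill", e0 = e0, emax = emax, ec50 = ec50, n = n, link = link),
    class = c("hill_curve", "dose_response")
  )
}

#' Linear dose-response curve
#'
#' A straight-line response `intercept + slope * x` on the link scale. Its
#' second derivative is identically zero, which makes it the canonical
#' degenerate case of the decomposition: nonlinear-averaging terms vanish and
#' only the mean-shift (selective feeding) term survives.
#'
#' @param intercept,slope real coefficients (link scale).
#' @inheritParams hill_curve
#' @return An object of class `c("linear_curve", "dose_response")`.
#' @export
linear_curve <- function(intercept, slope, link = "identity") {
  stopifnot(is.finite(intercept), is.finite(slope))
  link <- match.arg(link, c("identity", "logit", "log"))
  structure(
    list(form = "linear", intercept = intercept, slope = slope, link = link),
    class = c("linear_curve", "dose_response")
  )
}

.check_dose <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("doses must be finite numbers", call. = FALSE)
  if (any(x < 0))
    stop("negative dose: dose-response curves are defined for x >= 0",
         call. = FALSE)
  invisible(x)
}

#' Evaluate a dose-response curve
#'
#' @param object a `dose_response` curve.
#' @param x vector of doses (nmol/mg); must be non-negative.
#' @param ... passed to methods.
#' @return Numeric vector of responses on the curve's link scale. For Hill
#'   curves the value is bounded between `e0` and `emax`.
#' @export
predict.hill_curve <- function(object, x, ...) {
  .check_dose(x)
  w <- x^object$n / (x^object$n + object$ec50^object$n)
  w[x == 0] <- 0  # 0^n / (0 + c^n), also when n < 1 where 0^n/0^n would NaN
  object$e0 + (object$emax - object$e0) * w
}

#' @rdname predict.hill_curve
#' @export
predict.linear_curve <- function(object, x, ...) {
  .check_dose(x)
  object$intercept + object$slope * x
}

#' Jensen's effect potential (local convexity) of a dose-response curve
#'
#' Returns the second derivative of the curve at `x`. Its sign gives the
#' local direction of nonlinear averaging: positive (convex) means dose
#' variation raises the expected response, negative (concave) means it lowers
#' it; for a small symmetric perturbation of variance \eqn{\sigma^2} the
#' Jensen effect is approximately \eqn{\sigma^2 f''(\mu) / 2}.
#'
#' Hill and linear curves use the analytic derivative; penalized smooth fits
#' use central finite differences (see [curvature.smooth_curve()]).
#'
#' @param curve a `dose_response` object.
#' @param x dose(s) at which to evaluate the second derivative.
#' @param ... method arguments.
#' @return numeric vector of second derivatives (link-scale response per
#'   squared dose unit).
#' @export
curvature <- function(curve, x, ...) UseMethod("curvature")

#' @export
curvature.linear_curve <- function(curve, x, ...) {
  .check_dose(x)
  rep(0, length(x))
}

#' @export
curvature.hill_curve <- function(curve, x, ...) {
  .check_dose(x)
  n <- curve$n
  cc <- curve$ec50
  amp <- curve$emax - curve$e0
  out <- amp * n * cc^n * x^(n - 2) * ((n - 1) * cc^n - (n + 1) * x^n) /
    (x^n + cc^n)^3
  at0 <- which(x == 0)
  if (length(at0)) {
    lim0 <- if (n > 2) 0
    else if (n == 2) 2 * amp / cc^2
    else if (n == 1) -2 * amp / cc^2
    else sign(amp) * sign(n - 1) * Inf  # x^(n-2) blows up for 0 < n < 2, n != 1
    out[at0] <- lim0
  }
  out
}

#' @export
curvature.default <- function(curve, x, ...) {
  stop("curvature is not supported for objects of class ",
       paste(class(curve), collapse = "/"), call. = FALSE)
}

#' Critical leaf-consumption threshold
#'
#' An herbivore feeding on tissue with toxin concentration `x` (nmol/mg) is
#' poisoned once its cumulative intake reaches a critical accumulation
#' `k_crit` (nmol). The leaf mass it can consume before that point is
#' \eqn{m^*(x) = k_{crit} / x} (mg fresh weight), an inverse relationship:
#' the marginal cost of extra toxin shrinks as the concentration rises, so
#' unexpected dose increments matter less on already-toxic diets.
#'
#' @param k_crit critical toxin accumulation (nmol); positive.
#' @param x toxin concentration(s) (nmol/mg); strictly positive.
#' @return critical consumable leaf mass m* in mg, strictly decreasing in x.
#' @examples
#' critical_consumption(10, 2)  # 5 mg
#' @export
critical_consumption <- function(k_crit, x) {
  if (!is.numeric(k_crit) || length(k_crit) != 1L || !is.finite(k_crit) ||
      k_crit <= 0)
    stop("`k_crit` must be a positive finite number", call. = FALSE)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop("toxin concentration must be strictly positive", call. = FALSE)
  k_crit / x
}

#' @export
print.dose_response <- function(x, ...) {
  cat("Dose-response curve [", x$form, "], link =", x$link, "\n")
  if (x$form == "hill")
    cat(sprintf("  e0 = %.4g, emax = %.4g, ec50 = %.4g nmol/mg, n = %.4g\n",
                x$e0, x$emax, x$ec50, x$n))
  if (x$form == "linear")
    cat(sprintf("  intercept = %.4g, slope = %.4g\n", x$intercept, x$slope))
  invisible(x)
}
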