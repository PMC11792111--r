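#' Discrete dietary toxin-dose distribution
#'
#' A finite-support probability distribution over ingested toxin doses. The
#' decomposition contrasts two of these: the observed diet Xo (selective
#' feeding shifts weight toward less-defended tissue) and the counterfactual
#' reference diet Xr in which selectivity is switched off.
#'
#' @param support distinct, non-negative dose values (nmol/mg).
#' @param probs non-negative weights; normalized to sum to 1.
#' @return An object of class `dose_distribution` with elements `support`
#'   and `probs` (probabilities summing to 1 within 1e-12).
#' @seealso [reference_distribution()], [observed_distribution()],
#'   [distribution_moments()]
#' @export
dose_distribution <- function(support, probs) {
  if (length(support) != length(probs))
    stop("`support` and `probs` must have the same length", call. = FALSE)
  if (any(!is.finite(support)) || any(support < 0))
    stop("support doses must be finite and >= 0", call. = FALSE)
  if (anyDuplicated(support))
    stop("support doses must be distinct", call. = FALSE)
  if (any(!is.finite(probs)) || any(probs < 0))
    stop("probabilities must be finite and >= 0", call. = FALSE)
  tot <- sum(probs)
  if (tot <= 0)
    stop("probabilities must not all be zero", call. = FALSE)
  o <- order(support)
  structure(list(support = as.numeric(support[o]),
                 probs = as.numeric(probs[o] / tot)),
            class = "dose_distribution")
}

#' Reference (no-selectivity) dietary distribution
#'
#' The counterfactual diet Xr for the within-plant variation treatment:
#' leaves at `mu - delta` and `mu + delta` are consumed with equal weight, so
#' the mean dietary dose equals the cage mean `mu` exactly and the SD equals
#' `delta`.
#'
#' @param mu cage-mean dose (nmol/mg).
#' @param delta within-plant dose offset (nmol/mg); `mu > delta >= 0`.
#'   `delta = 0` gives a point mass at `mu` (the constant treatment).
#' @return a two-point (or degenerate) `dose_distribution`.
#' @examples
#' reference_distribution(1.89, 0.61)  # support {1.28, 2.50}, weights 1/2
#' @export
reference_distribution <- function(mu, delta) {
  .check_mu_delta(mu, delta)
  if (delta == 0) return(dose_distribution(mu, 1))
  dose_distribution(c(mu - delta, mu + delta), c(0.5, 0.5))
}

#' Observed (selectivity-weighted) dietary distribution
#'
#' The diet Xo actually experienced by a selective herbivore: the two
#' within-plant doses weighted by its estimated feeding preference (mean
#' proportion herbivory per dose level, unnormalized). With a preference for
#' the less-defended leaf, E\[Xo\] falls below the cage mean.
#'
#' @inheritParams reference_distribution
#' @param weights length-2 non-negative vector `(weight_low_dose,
#'   weight_high_dose)`, or a [preference_estimate] whose point weights are
#'   used.
#' @return a `dose_distribution` on `{mu - delta, mu + delta}`.
#' @examples
#' observed_distribution(1.89, 0.61, c(0.2, 0.1))  # probs (2/3, 1/3)
#' @export
observed_distribution <- function(mu, delta, weights) {
  .check_mu_delta(mu, delta)
  if (inherits(weights, "preference_estimate"))
    weights <- c(weights$weight_low_dose, weights$weight_high_dose)
  if (length(weights) != 2 || any(!is.finite(weights)) || any(weights < 0))
    stop("`weights` must be two finite non-negative numbers", call. = FALSE)
  if (sum(weights) == 0)
    stop("both preference weights are zero: diet undefined", call. = FALSE)
  if (delta == 0) return(dose_distribution(mu, 1))
  dose_distribution(c(mu - delta, mu + delta), weights)
}

.check_mu_delta <- function(mu, delta) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.numeric(delta),
            length(delta) == 1L, is.finite(mu), is.finite(delta))
  if (delta < 0) stop("`delta` must be >= 0", call. = FALSE)
  if (mu <= delta)
    stop("`mu` must exceed `delta` (low dose mu - delta must stay positive)",
         call. = FALSE)
  invisible(NULL)
}

#' Moments of a discrete dose distribution
#'
#' @param d a `dose_distribution`.
#' @return named list with exact probability-weighted `mean`, `variance` and
#'   `sd`.
#' @export
distribution_moments <- function(d) {
  stopifnot(inherits(d, "dose_distribution"))
  m <- sum(d$support * d$probs)
  v <- sum((d$support - m)^2 * d$probs)
  list(mean = m, variance = v, sd = sqrt(v))
}

#' @export
mean.dose_distribution <- function(x, ...) sum(x$support * x$probs)

#' @export
print.dose_distribution <- function(x, ...) {
  cat("Discrete dietary dose distribution (nmol/mg)\n")
  print(data.frame(dose = x$support, prob = x$probs), row.names = FALSE)
  mo <- distribution_moments(x)
  cat(sprintf("  mean %.4g, sd %.4g\n", mo$mean, mo$sd))
  invisible(x)
}
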