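#' Expected response over a dietary dose distribution
#'
#' The exact probability-weighted mean \eqn{E[f(X)]} of a dose-response
#' curve over a finite dietary distribution.
#'
#' @param curve a `dose_response` curve.
#' @param d a [dose_distribution].
#' @param allow_extrapolation permit support values outside a smooth curve's
#'   fitted dose range (default `FALSE`: refuse with an error).
#' @return scalar link-scale expected response.
#' @export
expected_response <- function(curve, d, allow_extrapolation = FALSE) {
  stopifnot(inherits(curve, "dose_response"), inherits(d, "dose_distribution"))
  .check_support(curve, d$support, allow_extrapolation)
  sum(d$probs * as.numeric(predict(curve, d$support,
                                   warn_extrapolation = FALSE)))
}

.check_support <- function(curve, support, allow_extrapolation) {
  if (inherits(curve, c("smooth_curve", "tabulated_curve")) &&
      !allow_extrapolation) {
    rng <- curve$dose_range
    if (any(support < rng[1] | support > rng[2]))
      stop("dietary support [", signif(min(support), 3), ", ",
           signif(max(support), 3), "] lies outside the fitted dose range [",
           signif(rng[1], 3), ", ", signif(rng[2], 3),
           "]; set allow_extrapolation = TRUE to override", call. = FALSE)
  }
  invisible(NULL)
}

#' Jensen (nonlinear-averaging) effect of dose variation
#'
#' \eqn{E[f(X)] - f(E[X])}: the gap between the average response to a
#' varying dose and the response to the average dose. Zero for linear
#' curves; negative where the curve is concave over the support, positive
#' where convex.
#'
#' @inheritParams expected_response
#' @export
jensen_effect <- function(curve, d, allow_extrapolation = FALSE) {
  expected_response(curve, d, allow_extrapolation) -
    as.numeric(predict(curve, mean(d), warn_extrapolation = FALSE))
}

#' Partition the effect of dose variability into its mechanisms
#'
#' Given a dose-response curve `f`, the observed (selectivity-weighted) diet
#' `xo` and the counterfactual no-selectivity diet `xr`, computes the
#' counterfactual partition
#' \deqn{J_r = E[f(X_r)] - f(E[X_r])}
#' \deqn{S = f(E[X_o]) - f(E[X_r])}
#' \deqn{J_S = \{E[f(X_o)] - f(E[X_o])\} - J_r}
#' \deqn{\hat T = J_r + S + J_S = E[f(X_o)] - f(E[X_r]).}
#' `jr` is pure nonlinear averaging (what variation would do to a
#' non-selective feeder), `s` the pure mean-shift benefit of selective
#' feeding, and `js` their interaction (selectivity relocating the diet to a
#' differently curved region of `f`).
#'
#' @param curve a `dose_response` curve.
#' @param xo,xr observed and reference [dose_distribution]s.
#' @inheritParams expected_response
#' @return named list `jr`, `s`, `js`, `t_hat` (link scale), satisfying
#'   `t_hat == jr + s + js` to machine precision.
#' @export
decompose_effects <- function(curve, xo, xr, allow_extrapolation = FALSE) {
  stopifnot(inherits(xo, "dose_distribution"), inherits(xr, "dose_distribution"))
  f <- function(x) as.numeric(predict(curve, x, warn_extrapolation = FALSE))
  .check_support(curve, c(xo$support, xr$support), allow_extrapolation)
  e_f_xr <- expected_response(curve, xr, allow_extrapolation = TRUE)
  e_f_xo <- expected_response(curve, xo, allow_extrapolation = TRUE)
  f_e_xr <- f(mean(xr))
  f_e_xo <- f(mean(xo))
  jr <- e_f_xr - f_e_xr
  s <- f_e_xo - f_e_xr
  js <- (e_f_xo - f_e_xo) - jr
  list(jr = jr, s = s, js = js, t_hat = jr + s + js)
}

#' Observed total effect of the variability treatment
#'
#' The empirical contrast the counterfactual prediction is compared with:
#' mean link-scale response in the variable-dose arm minus the constant-dose
#' arm at the same cage-mean treatment, optionally standardized by the
#' pooled SD of the link-scale response. Uncertainty by a cage-level
#' bootstrap within each arm.
#'
#' RGR is analyzed on the identity link; proportion herbivory on the logit
#' link after the boundary shrink of [adjusted_logit()].
#'
#' @param cages cage-level data frame with columns `mean_treatment`,
#'   `variation_treatment` (`"constant"` vs. `variation`), and the response
#'   column (`rgr_per_h` or `herbivory_prop`).
#' @param response `"rgr"` or `"herbivory"`.
#' @param mean_treatment `"low"` or `"high"`.
#' @param variation label of the variable arm (default `"intra"`,
#'   within-plant variation).
#' @param n_draws bootstrap draws.
#' @param seed integer seed.
#' @return An object of class `observed_effect`: `estimate_link` (raw
#'   link-scale difference), `sd_link` (pooled SD), `estimate`
#'   (standardized difference, `NA` if `sd_link` is 0), bootstrap
#'   `draws_link`, and arm sizes.
#' @export
observed_total_effect <- function(cages, response = c("rgr", "herbivory"),
                                  mean_treatment = c("low", "high"),
                                  variation = "intra",
                                  n_draws = 500, seed = 1L) {
  response <- match.arg(response)
  mean_treatment <- match.arg(mean_treatment)
  col <- switch(response, rgr = "rgr_per_h", herbivory = "herbivory_prop")
  req <- c("mean_treatment", "variation_treatment", col)
  miss <- setdiff(req, names(cages))
  if (length(miss))
    stop("cage table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  sub <- cages[cages$mean_treatment == mean_treatment &
                 cages$variation_treatment %in% c("constant", variation) &
                 !is.na(cages[[col]]), , drop = FALSE]
  arm <- sub$variation_treatment
  if (!any(arm == "constant") || !any(arm == variation))
    stop("both a 'constant' and a '", variation,
         "' arm are required at mean treatment '", mean_treatment, "'",
         call. = FALSE)
  y <- if (response == "herbivory")
    adjusted_logit(sub[[col]], nrow(sub)) else sub[[col]]
  yc <- y[arm == "constant"]; yv <- y[arm == variation]
  diff_fun <- function(a, b) mean(b) - mean(a)
  est <- diff_fun(yc, yv)
  n1 <- length(yc); n2 <- length(yv)
  pooled <- sqrt(((n1 - 1) * stats::var(yc) + (n2 - 1) * stats::var(yv)) /
                   (n1 + n2 - 2))
  set.seed(as.integer(seed))
  draws <- replicate(n_draws, diff_fun(
    yc[sample.int(n1, replace = TRUE)],
    yv[sample.int(n2, replace = TRUE)]))
  structure(
    list(estimate_link = est, sd_link = pooled,
         estimate = if (pooled > 0) est / pooled else NA_real_,
         draws_link = draws, n_constant = n1, n_variable = n2,
         response = response, mean_treatment = mean_treatment,
         seed = as.integer(seed)),
    class = "observed_effect"
  )
}

#' @export
print.observed_effect <- function(x, ...) {
  cat("Observed total effect of variability (To):", x$response, "at",
      x$mean_treatment, "mean dose\n")
  cat(sprintf("  link-scale difference %.4g (pooled link SD %.4g)\n",
              x$estimate_link, x$sd_link))
  if (is.finite(x$estimate))
    cat(sprintf("  standardized: %.3f SD\n", x$estimate))
  invisible(x)
}

#' Crossed Monte-Carlo decomposition of the variability effect
#'
#' Propagates curve and preference uncertainty through the counterfactual
#' partition by the full Cartesian cross of curve draws with preference
#' draws: each of the `n_curve x n_pref` simulations rebuilds the dietary
#' pair (Xo from the drawn preference weights, Xr with preference switched
#' off) on the treatment doses `mu - delta` / `mu + delta` and evaluates the
#' drawn curve. With 500 draws of each, this is the 250,000-simulation
#' ensemble summarized by its mean and equal-tailed 89% intervals.
#'
#' When an [observed_total_effect()] is supplied, its bootstrap draws are
#' recycled across the cross and the residual `eps = t_obs - t_hat`
#' (unmodelled mechanisms such as physiological-tracking constraints) is
#' reported per draw.
#'
#' @param curve_draws a `curve_draws` object from [sample_curve_draws()], a
#'   list of `dose_response` curves, or a single curve.
#' @param pref_draws a [preference_estimate] (its bootstrap draws are used)
#'   or a 2-column matrix of `(weight_low, weight_high)` draws.
#' @param mu cage-mean dose (nmol/mg).
#' @param delta within-plant dose offset (nmol/mg).
#' @param t_obs optional [observed_total_effect()].
#' @param ci_level equal-tailed interval level (default 0.89).
#' @param allow_extrapolation pass doses outside a smooth curve's fitted
#'   range (default `FALSE`).
#' @param keep_draws retain the full per-draw table (default `TRUE`).
#' @return An object of class `variability_decomposition` holding the
#'   per-draw table (`jr`, `s`, `js`, `t_hat` and, with `t_obs`, `t_obs`
#'   and `eps`, all on the raw link scale), a tidy `summary` data frame
#'   (quantity, mean, lower, upper), and metadata. See
#'   [standardize_effects()] and [mechanism_shares()].
#' @export
monte_carlo_decompose <- function(curve_draws, pref_draws, mu, delta,
                                  t_obs = NULL, ci_level = 0.89,
                                  allow_extrapolation = FALSE,
                                  keep_draws = TRUE) {
  .check_mu_delta(mu, delta)
  if (inherits(pref_draws, "preference_estimate"))
    pref_draws <- pref_draws$draws
  pref_draws <- as.matrix(pref_draws)
  if (ncol(pref_draws) != 2 || nrow(pref_draws) < 1)
    stop("preference draws must be a non-empty 2-column matrix", call. = FALSE)
  if (any(pref_draws < 0) || any(rowSums(pref_draws) <= 0))
    stop("preference weights must be non-negative and not both zero",
         call. = FALSE)
  if (inherits(curve_draws, "dose_response"))
    curve_draws <- list(curve_draws)
  n_curve <- if (inherits(curve_draws, "curve_draws")) length(curve_draws)
  else length(curve_draws)
  if (n_curve < 1) stop("need at least one curve draw", call. = FALSE)

  x_lo <- mu - delta; x_hi <- mu + delta
  if (inherits(curve_draws, "curve_draws") && !allow_extrapolation) {
    rng <- curve_draws$dose_range
    if (x_lo < rng[1] || x_hi > rng[2])
      stop("treatment doses [", signif(x_lo, 3), ", ", signif(x_hi, 3),
           "] fall outside the fitted dose range [", signif(rng[1], 3), ", ",
           signif(rng[2], 3), "]; set allow_extrapolation = TRUE", call. = FALSE)
  }

  p_lo <- pref_draws[, 1] / rowSums(pref_draws)  # P(Xo = mu - delta) per draw
  m <- length(p_lo)
  e_xo <- p_lo * x_lo + (1 - p_lo) * x_hi
  # evaluate every curve draw once on the pooled dose grid
  FF <- eval_draws(curve_draws, c(x_lo, x_hi, mu, e_xo),
                   warn_extrapolation = FALSE)        # (3 + m) x n_curve
  jr_c <- 0.5 * FF[1, ] + 0.5 * FF[2, ] - FF[3, ]     # per curve draw
  e_f_xo <- outer(p_lo, FF[1, ]) + outer(1 - p_lo, FF[2, ])   # m x n_curve
  f_e_xo <- FF[-(1:3), , drop = FALSE]                        # m x n_curve
  f_e_xr <- matrix(FF[3, ], m, n_curve, byrow = TRUE)
  jr <- matrix(jr_c, m, n_curve, byrow = TRUE)
  s <- f_e_xo - f_e_xr
  js <- (e_f_xo - f_e_xo) - jr
  t_hat <- jr + s + js

  draws <- data.frame(jr = as.vector(jr), s = as.vector(s),
                      js = as.vector(js), t_hat = as.vector(t_hat))
  if (!is.null(t_obs)) {
    stopifnot(inherits(t_obs, "observed_effect"))
    draws$t_obs <- rep_len(t_obs$draws_link, nrow(draws))
    draws$eps <- draws$t_obs - draws$t_hat
  }

  out <- structure(
    list(draws = draws,
         summary = .summarize_draws(draws, ci_level),
         ci_level = ci_level, n_curve_draws = n_curve, n_pref_draws = m,
         mu = mu, delta = delta, t_obs = t_obs,
         sd_link = if (!is.null(t_obs)) t_obs$sd_link else NA_real_,
         standardized = FALSE),
    class = "variability_decomposition"
  )
  if (!keep_draws) out$draws <- NULL
  out
}

.summarize_draws <- function(draws, ci_level) {
  a <- (1 - ci_level) / 2
  do.call(rbind, lapply(names(draws), function(q) {
    v <- draws[[q]]
    qs <- stats::quantile(v, c(a, 1 - a), names = FALSE, na.rm = TRUE)
    data.frame(quantity = q, mean = mean(v), lower = qs[1], upper = qs[2])
  }))
}

#' Standardize a decomposition by the link-scale response SD
#'
#' Divides every quantity (and all draws) by `sd_link`, expressing effects
#' in units of the SD of the link-transformed response, the scale on which
#' effect sizes across responses are comparable.
#'
#' @param result a `variability_decomposition`.
#' @param sd_link positive scalar; defaults to the pooled SD stored from the
#'   observed-effect stage.
#' @return the rescaled `variability_decomposition` (identities such as
#'   `t_hat = jr + s + js` are preserved exactly under the rescaling).
#' @export
standardize_effects <- function(result, sd_link = result$sd_link) {
  stopifnot(inherits(result, "variability_decomposition"))
  if (!is.numeric(sd_link) || length(sd_link) != 1L || !is.finite(sd_link) ||
      sd_link <= 0)
    stop("`sd_link` must be a positive number", call. = FALSE)
  if (!is.null(result$draws))
    result$draws[] <- lapply(result$draws, `/`, sd_link)
  result$summary[c("mean", "lower", "upper")] <-
    result$summary[c("mean", "lower", "upper")] / sd_link
  result$standardized <- TRUE
  result$sd_link <- sd_link
  result
}

#' Mechanism shares of the predicted total effect
#'
#' Per draw, the fractions `jr / t_hat`, `s / t_hat`, `js / t_hat` (in
#' percent; they sum to 100 for every retained draw). Draws with
#' `|t_hat|` below `tol` are excluded and counted.
#'
#' @param result a `variability_decomposition` with draws.
#' @param tol exclusion threshold on `|t_hat|` (default 1e-12).
#' @return list with a `summary` data frame (mechanism, mean, lower, upper,
#'   in percent), `n_excluded`, and the retained per-draw share matrix.
#' @export
mechanism_shares <- function(result, tol = 1e-12) {
  stopifnot(inherits(result, "variability_decomposition"))
  if (is.null(result$draws))
    stop("per-draw table was not kept; rerun with keep_draws = TRUE",
         call. = FALSE)
  d <- result$draws
  keep <- abs(d$t_hat) >= tol
  if (!any(keep))
    stop("all draws have |t_hat| below tolerance; shares undefined",
         call. = FALSE)
  shares <- 100 * cbind(jr = d$jr, s = d$s, js = d$js)[keep, , drop = FALSE] /
    d$t_hat[keep]
  sm <- .summarize_draws(as.data.frame(shares), result$ci_level)
  names(sm)[1] <- "mechanism"
  list(summary = sm, n_excluded = sum(!keep), draws = shares)
}

#' @export
print.variability_decomposition <- function(x, digits = 4, ...) {
  cat("Counterfactual decomposition of the defense-variability effect\n")
  if (!is.null(x$response))
    cat("  response:", x$response, "|  mean treatment:", x$mean_treatment, "\n")
  cat(sprintf("  doses %.3g +/- %.3g nmol/mg;  %d curve x %d preference draws%s\n",
              x$mu, x$delta, x$n_curve_draws, x$n_pref_draws,
              if (isTRUE(x$standardized)) ";  standardized (link-SD units)" else ""))
  sm <- x$summary
  sm[-1] <- lapply(sm[-1], signif, digits)
  print(sm, row.names = FALSE)
  invisible(x)
}

#' @export
summary.variability_decomposition <- function(object, ...) {
  ci <- object$ci_level
  sm <- object$summary
  a <- (1 - ci) / 2
  names(sm)[names(sm) == "lower"] <- sprintf("q%.3g", a)
  names(sm)[names(sm) == "upper"] <- sprintf("q%.3g", 1 - a)
  sm$excludes_zero <- sm[[3]] > 0 | sm[[4]] < 0
  sm
}

#' Dot-and-interval plot of a decomposition
#'
#' Forest-style panel: one point per quantity with its equal-tailed
#' interval, a dashed reference line at zero, and an asterisk where the
#' interval excludes zero ("ns" otherwise).
#'
#' @param x a `variability_decomposition`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.variability_decomposition <- function(x, ...) {
  sm <- x$summary
  k <- nrow(sm)
  ylim <- c(0.5, k + 0.5)
  xlim <- range(0, sm$lower, sm$upper)
  graphics::plot(NA, xlim = xlim, ylim = ylim, yaxt = "n",
                 xlab = if (isTRUE(x$standardized))
                   "effect (SD of link-scale response)" else
                     "effect (link scale)",
                 ylab = "", ...)
  graphics::abline(v = 0, lty = 2)
  ys <- rev(seq_len(k))
  graphics::segments(sm$lower, ys, sm$upper, ys, lwd = 2)
  graphics::points(sm$mean, ys, pch = 19)
  lab <- ifelse(sm$lower > 0 | sm$upper < 0, "*", "ns")
  graphics::axis(2, at = ys, labels = sm$quantity, las = 1)
  graphics::mtext(lab, side = 4, at = ys, las = 1, line = 0.5)
  invisible(x)
}
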