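#' Estimate herbivore leaf-choice preference from leaf-level herbivory
#'
#' Within the within-plant variation treatment every plant carries leaves
#' painted at a low and a high dose. The herbivore's selectivity is
#' summarized as a pair of weights: the mean proportion herbivory on
#' low-dose and on high-dose leaves. Uncertainty comes from a nonparametric
#' cluster bootstrap that resamples whole plants with replacement, which
#' respects the dependence of leaves on their plant.
#'
#' The default `"logit"` method averages logit-transformed herbivory (after
#' the boundary shrink of [adjusted_logit()]) and back-transforms; `"raw"`
#' averages the proportions directly.
#'
#' @param leaves data frame of leaf records with columns `plant_id`,
#'   `mean_treatment` (`"low"`/`"high"`), `leaf_dose_level`
#'   (`"low_dose"`/`"high_dose"`) and `herbivory_prop` in \[0, 1\].
#' @param mean_treatment which cage-mean treatment to estimate for.
#' @param n_draws number of bootstrap draws (default 500).
#' @param seed integer seed for the bootstrap.
#' @param method `"logit"` (default) or `"raw"` averaging.
#' @return An object of class `preference_estimate`: point weights
#'   `weight_low_dose` / `weight_high_dose` (unnormalized, on the herbivory
#'   proportion scale), an `n_draws x 2` bootstrap `draws` matrix,
#'   `n_plants`, and the call metadata.
#' @seealso [preference_ratio()], [observed_distribution()]
#' @export
estimate_preference <- function(leaves, mean_treatment = c("low", "high"),
                                n_draws = 500, seed = 1L,
                                method = c("logit", "raw")) {
  mean_treatment <- match.arg(mean_treatment)
  method <- match.arg(method)
  req <- c("plant_id", "mean_treatment", "leaf_dose_level", "herbivory_prop")
  miss <- setdiff(req, names(leaves))
  if (length(miss))
    stop("leaf table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(leaves$herbivory_prop < 0 | leaves$herbivory_prop > 1, na.rm = TRUE))
    stop("herbivory_prop must lie in [0, 1]", call. = FALSE)
  sub <- leaves[leaves$mean_treatment == mean_treatment &
                  !is.na(leaves$herbivory_prop), , drop = FALSE]
  if (!all(c("low_dose", "high_dose") %in% sub$leaf_dose_level))
    stop("both leaf dose levels must be present for treatment '",
         mean_treatment, "'", call. = FALSE)
  plants <- unique(sub$plant_id)
  if (length(plants) < 2)
    stop("need >= 2 plants for the cluster bootstrap; got ",
         length(plants), call. = FALSE)

  point <- .pref_weights(sub, method)
  degenerate <- FALSE
  if (all(sub$herbivory_prop == 0)) {
    warning("no herbivory recorded on either dose level; ",
            "falling back to equal preference weights", call. = FALSE)
    point <- c(weight_low_dose = 0.5, weight_high_dose = 0.5)
    degenerate <- TRUE
  }

  set.seed(as.integer(seed))
  by_plant <- split(seq_len(nrow(sub)), sub$plant_id)
  draws <- matrix(NA_real_, nrow = n_draws, ncol = 2,
                  dimnames = list(NULL, c("weight_low_dose", "weight_high_dose")))
  for (b in seq_len(n_draws)) {
    if (degenerate) { draws[b, ] <- point; next }
    idx <- unlist(by_plant[sample.int(length(by_plant), replace = TRUE)],
                  use.names = FALSE)
    draws[b, ] <- .pref_weights(sub[idx, , drop = FALSE], method)
  }

  structure(
    list(mean_treatment = mean_treatment,
         weight_low_dose = unname(point[1]),
         weight_high_dose = unname(point[2]),
         draws = draws, n_plants = length(plants),
         method = method, seed = as.integer(seed), degenerate = degenerate),
    class = "preference_estimate"
  )
}

# mean herbivory weight per leaf dose level; logit method averages on the
# log-odds scale with boundary shrinkage, raw method on the proportion scale
.pref_weights <- function(sub, method) {
  one <- function(level) {
    p <- sub$herbivory_prop[sub$leaf_dose_level == level]
    if (method == "logit") stats::plogis(mean(adjusted_logit(p, length(p))))
    else mean(p)
  }
  c(weight_low_dose = one("low_dose"), weight_high_dose = one("high_dose"))
}

#' Relative preference for less-defended leaves
#'
#' Percent excess herbivory on low-dose relative to high-dose leaves,
#' `100 * (w_low - w_high) / w_high`; 0 means no selectivity, 100 means the
#' herbivore ate low-dose leaves twice as much.
#'
#' @param est a [preference_estimate], or a length-2 numeric
#'   `(weight_low, weight_high)`.
#' @param ci_level equal-tailed interval level for the bootstrap draws
#'   (default 0.89); used only when draws are available.
#' @return list with `estimate` (percent), `lower`/`upper` (if draws), and
#'   the per-draw ratios `draws`.
#' @export
preference_ratio <- function(est, ci_level = 0.89) {
  if (is.numeric(est) && length(est) == 2)
    est <- list(weight_low_dose = est[1], weight_high_dose = est[2],
                draws = NULL)
  if (est$weight_high_dose <= 0)
    stop("high-dose weight is zero: relative preference undefined",
         call. = FALSE)
  ratio <- function(wl, wh) 100 * (wl - wh) / wh
  out <- list(estimate = ratio(est$weight_low_dose, est$weight_high_dose))
  if (!is.null(est$draws)) {
    rd <- ratio(est$draws[, 1], est$draws[, 2])
    a <- (1 - ci_level) / 2
    qs <- stats::quantile(rd, c(a, 1 - a), names = FALSE, na.rm = TRUE)
    out$lower <- qs[1]; out$upper <- qs[2]; out$draws <- rd
  }
  out
}

#' @export
print.preference_estimate <- function(x, ...) {
  cat("Herbivore preference estimate (", x$mean_treatment,
      " mean treatment, ", x$n_plants, " plants)\n", sep = "")
  cat(sprintf("  mean herbivory: low-dose leaves %.4f, high-dose leaves %.4f\n",
              x$weight_low_dose, x$weight_high_dose))
  pr <- preference_ratio(x)
  cat(sprintf("  relative preference for low dose: %.1f%% [%.1f%%, %.1f%%]\n",
              pr$estimate, pr$lower, pr$upper))
  invisible(x)
}
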