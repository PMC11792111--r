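# Independent oracles used to freeze expected values. These deliberately do
# not share code with the package internals: Hill evaluation uses a
# different algebraic arrangement and the decomposition oracle assembles
# every term by brute-force enumeration over the support.

oracle_hill <- function(e0, emax, ec50, n) {
  function(x) ifelse(x == 0, e0, e0 + (emax - e0) / (1 + (ec50 / x)^n))
}

# brute-force counterfactual partition on finite supports
oracle_decompose <- function(f, xo_support, xo_probs, xr_support, xr_probs) {
  xo_probs <- xo_probs / sum(xo_probs)
  xr_probs <- xr_probs / sum(xr_probs)
  e_f_xr <- sum(xr_probs * vapply(xr_support, f, 0))
  e_f_xo <- sum(xo_probs * vapply(xo_support, f, 0))
  f_e_xr <- f(sum(xr_probs * xr_support))
  f_e_xo <- f(sum(xo_probs * xo_support))
  jr <- e_f_xr - f_e_xr
  s <- f_e_xo - f_e_xr
  js <- (e_f_xo - f_e_xo) - jr
  list(jr = jr, s = s, js = js, t_hat = jr + s + js)
}

# central finite-difference second derivative of an arbitrary function
oracle_fd2 <- function(f, x, h = 1e-5 * pmax(abs(x), 1)) {
  (f(x + h) - 2 * f(x) + f(x - h)) / h^2
}

# toy leaf table: n_plants plants, each with one low- and one high-dose leaf
toy_leaves <- function(herb_low, herb_high, n_plants = 4,
                       mean_treatment = "high", mu = 1.89, delta = 0.61) {
  data.frame(
    plant_id = rep(sprintf("P%02d", seq_len(n_plants)), each = 2),
    cage_id = rep(sprintf("P%02d", seq_len(n_plants)), each = 2),
    mean_treatment = mean_treatment,
    leaf_dose_level = rep(c("low_dose", "high_dose"), n_plants),
    dose_nmol_mg = rep(c(mu - delta, mu + delta), n_plants),
    herbivory_prop = rep(c(herb_low, herb_high), length.out = 2 * n_plants)
  )
}

# toy cage table with explicit responses in the two arms
toy_cages <- function(const, vari, mean_treatment = "high",
                      response = "rgr") {
  col <- if (response == "rgr") "rgr_per_h" else "herbivory_prop"
  out <- data.frame(
    cage_id = sprintf("C%02d", seq_len(length(const) + length(vari))),
    mean_treatment = mean_treatment,
    variation_treatment = rep(c("constant", "intra"),
                              c(length(const), length(vari))))
  out[[col]] <- c(const, vari)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
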