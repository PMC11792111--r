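#' Full counterfactual partition of a defense-variability experiment
#'
#' The one-stop fitting function: from the three experiment tables it (1)
#' fits the penalized smooth dose-response curve on the ladder data, (2)
#' estimates herbivore preference weights from the leaf table with a
#' plant-cluster bootstrap, (3) estimates the observed total effect of the
#' variability treatment from the cage table with a cage bootstrap, and (4)
#' crosses curve draws with preference draws through the counterfactual
#' partition, standardizing everything by the pooled SD of the
#' link-transformed response.
#'
#' @param ladder dose-response ladder table (`dose_nmol_mg`, `response`,
#'   `response_type`).
#' @param leaves leaf-level herbivory table (see [estimate_preference()]).
#' @param cages cage-level table (see [observed_total_effect()]).
#' @param response `"rgr"` (identity link) or `"herbivory"` (logit link).
#' @param mean_treatment `"low"` or `"high"` cage-mean dose treatment.
#' @param mu cage-mean dose in nmol/mg; defaults to the design constants
#'   0.66 (low) / 1.89 (high).
#' @param delta within-plant dose offset (default 0.61 nmol/mg).
#' @param n_curve_draws,n_pref_draws,n_obs_draws draw counts for the curve,
#'   preference, and observed-effect stages (defaults 500, 500, 500; the
#'   decomposition crosses the first two in full).
#' @param ci_level equal-tailed interval level (default 0.89).
#' @param max_basis basis-dimension cap of the dose smooth (default 4).
#' @param preference_method `"logit"` or `"raw"`, see [estimate_preference()].
#' @param standardize divide all effects by the pooled link-scale SD
#'   (default `TRUE`).
#' @param seed integer seed; stage seeds are derived from it.
#' @return a `variability_decomposition` (see [monte_carlo_decompose()])
#'   with the fitted stages attached as `curve_fit`, `preference`, `t_obs`.
#' @examples
#' cfg <- sim_config(seed = 42)
#' expt <- generate_variation_experiment(cfg)
#' ladder <- generate_dose_ladder_experiment(cfg)
#' fit <- partition_variability(ladder, expt$leaves, expt$cages,
#'                              response = "rgr", mean_treatment = "high",
#'                              n_curve_draws = 100, n_pref_draws = 100)
#' fit
#' @export
partition_variability <- function(ladder, leaves, cages,
                                  response = c("rgr", "herbivory"),
                                  mean_treatment = c("low", "high"),
                                  mu = NULL, delta = 0.61,
                                  n_curve_draws = 500, n_pref_draws = 500,
                                  n_obs_draws = 500, ci_level = 0.89,
                                  max_basis = 4,
                                  preference_method = c("logit", "raw"),
                                  standardize = TRUE, seed = 1L) {
  response <- match.arg(response)
  mean_treatment <- match.arg(mean_treatment)
  preference_method <- match.arg(preference_method)
  if (is.null(mu)) mu <- c(low = 0.66, high = 1.89)[[mean_treatment]]
  seed <- as.integer(seed)

  lad <- ladder[ladder$response_type == response, , drop = FALSE]
  if (!nrow(lad))
    stop("ladder table has no rows for response '", response, "'",
         call. = FALSE)
  link <- if (response == "herbivory") "logit" else "identity"
  fit <- fit_dose_response(lad$dose_nmol_mg, lad$response,
                           max_basis = max_basis, link = link)
  cdraws <- sample_curve_draws(fit, n_curve_draws, seed = seed + 101L)
  pref <- estimate_preference(leaves, mean_treatment,
                              n_draws = n_pref_draws, seed = seed + 202L,
                              method = preference_method)
  t_obs <- observed_total_effect(cages, response, mean_treatment,
                                 n_draws = n_obs_draws, seed = seed + 303L)
  res <- monte_carlo_decompose(cdraws, pref, mu = mu, delta = delta,
                               t_obs = t_obs, ci_level = ci_level)
  if (standardize) res <- standardize_effects(res)
  res$response <- response
  res$mean_treatment <- mean_treatment
  res$curve_fit <- fit
  res$preference <- pref
  res
}

#' Write a synthetic dataset to disk
#'
#' Materializes one simulated experiment as the CSV schemas the analysis
#' stages consume (`cages.csv`, `leaves.csv`, `ladder.csv`), the analytic
#' ground truth (`truth.csv`), and a JSON run manifest recording the seed,
#' configuration and files, sufficient to regenerate the directory.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expt <- generate_variation_experiment(cfg)
  ladder <- generate_dose_ladder_experiment(cfg)
  utils::write.csv(expt$cages, file.path(dir, "cages.csv"), row.names = FALSE)
  utils::write.csv(expt$leaves, file.path(dir, "leaves.csv"), row.names = FALSE)
  utils::write.csv(ladder, file.path(dir, "ladder.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(expt$truth), file.path(dir, "truth.csv"),
                   row.names = FALSE)
  manifest <- list(
    subcommand = "simulate",
    package = "defvar",
    version = as.character(utils::packageVersion("defvar")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config = .config_as_list(cfg),
    files = c("cages.csv", "leaves.csv", "ladder.csv", "truth.csv"))
  # I(17) significant digits so that config floats round-trip exactly and a
  # manifest regenerates the dataset bit for bit
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  invisible(manifest)
}

.config_as_list <- function(cfg) {
  list(rgr_curve = cfg$rgr_curve[c("e0", "emax", "ec50", "n", "link")],
       herbivory_curve = cfg$herbivory_curve[c("e0", "emax", "ec50", "n",
                                               "link")],
       lambda = cfg$lambda, mu_low = cfg$mu_low, mu_high = cfg$mu_high,
       delta = cfg$delta, n_cages_per_arm = cfg$n_cages_per_arm,
       leaves_per_plant = cfg$leaves_per_plant,
       noise_sd = as.list(cfg$noise_sd), leaf_noise_sd = cfg$leaf_noise_sd,
       dose_ladder = cfg$dose_ladder, ladder_reps = cfg$ladder_reps,
       seed = cfg$seed)
}

#' Build a simulation configuration from a YAML/JSON config file
#'
#' Keys follow [sim_config()] arguments; Hill truth curves are given as
#' mappings with `e0`, `emax`, `ec50`, `n` (and optional `link`). Unknown
#' keys are an error so that typos do not silently fall back to defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` config file.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (cv in c("rgr_curve", "herbivory_curve")) {
    if (!is.null(raw[[cv]])) {
      p <- raw[[cv]]
      # YAML 1.1 reads a bare key `n` as boolean FALSE; restore it
      names(p)[names(p) %in% c("FALSE", "F")] <- "n"
      raw[[cv]] <- hill_curve(p$e0, p$emax, p$ec50, p$n,
                              link = p$link %||%
                                if (cv == "rgr_curve") "identity" else "logit")
    }
  }
  if (!is.null(raw$noise_sd)) raw$noise_sd <- unlist(raw$noise_sd)
  do.call(sim_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return list with `cages`, `leaves`, `ladder`, `truth` data frames and
#'   the parsed `manifest`.
#' @export
read_dataset <- function(dir) {
  need <- c("cages.csv", "leaves.csv", "ladder.csv")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("dataset directory ", dir, " is missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  rd <- function(f) utils::read.csv(file.path(dir, f))
  out <- list(cages = rd("cages.csv"), leaves = rd("leaves.csv"),
              ladder = rd("ladder.csv"))
  if (file.exists(file.path(dir, "truth.csv"))) out$truth <- rd("truth.csv")
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) out$manifest <- jsonlite::read_json(mf,
                                                           simplifyVector = TRUE)
  out
}

#' Run the decomposition on a dataset directory and write its outputs
#'
#' Convenience wrapper around [partition_variability()]: reads the dataset,
#' runs one response x mean-treatment decomposition, and (optionally)
#' writes a tidy summary CSV — columns `quantity`, `mean`, and the
#' equal-tailed interval bounds labelled by their quantiles (`q0.055` /
#' `q0.945` at the default 89% level) — plus the full draw table and a run
#' manifest.
#'
#' @param dataset dataset directory path or a list as from [read_dataset()].
#' @param out_dir optional output directory for `summary_<...>.csv`,
#'   `draws_<...>.csv` (when `write_draws`) and `manifest.json`.
#' @param write_draws also write the per-draw table (default `FALSE`).
#' @inheritParams partition_variability
#' @param ... further arguments to [partition_variability()].
#' @return the `variability_decomposition`, invisibly when writing.
#' @export
run_decomposition <- function(dataset, response = "rgr",
                              mean_treatment = "high", out_dir = NULL,
                              write_draws = FALSE, seed = 1L, ...) {
  if (is.character(dataset)) dataset <- read_dataset(dataset)
  res <- partition_variability(dataset$ladder, dataset$leaves, dataset$cages,
                               response = response,
                               mean_treatment = mean_treatment,
                               seed = seed, ...)
  if (is.null(out_dir)) return(res)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tag <- paste0(response, "_", mean_treatment)
  sm <- summary(res)
  sm_path <- file.path(out_dir, paste0("summary_", tag, ".csv"))
  utils::write.csv(sm, sm_path, row.names = FALSE)
  files <- basename(sm_path)
  if (write_draws) {
    dr_path <- file.path(out_dir, paste0("draws_", tag, ".csv"))
    utils::write.csv(res$draws, dr_path, row.names = FALSE)
    files <- c(files, basename(dr_path))
  }
  manifest <- list(subcommand = "decompose", package = "defvar",
                   version = as.character(utils::packageVersion("defvar")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   seed = as.integer(seed), response = response,
                   mean_treatment = mean_treatment,
                   n_curve_draws = res$n_curve_draws,
                   n_pref_draws = res$n_pref_draws,
                   ci_level = res$ci_level, files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Plain-text report of one or more decomposition summaries
#'
#' Renders each summary as a panel listing every quantity with its mean and
#' interval, the mechanism shares of the predicted total effect when draws
#' are available, and the significance marker convention: `*` where the
#' interval excludes zero, `ns` otherwise.
#'
#' @param results a `variability_decomposition`, a summary data frame, a
#'   path to a summary CSV, or a list mixing these. Must be non-empty.
#' @param file optional path; the report is also written there.
#' @return the report lines, invisibly; printed to the console.
#' @export
report_decomposition <- function(results, file = NULL) {
  if (inherits(results, "variability_decomposition") ||
      is.data.frame(results) || is.character(results))
    results <- if (is.character(results)) as.list(results) else list(results)
  if (!length(results)) stop("no summaries to report", call. = FALSE)
  lines <- character()
  for (res in results) {
    if (is.character(res)) {
      sm <- utils::read.csv(res)
      header <- basename(res)
      shares <- NULL
    } else if (is.data.frame(res)) {
      sm <- res; header <- "decomposition summary"; shares <- NULL
    } else {
      sm <- summary(res)
      header <- paste0(res$response %||% "response", ", ",
                       res$mean_treatment %||% "?", " mean treatment",
                       if (isTRUE(res$standardized)) " (link-SD units)")
      shares <- if (!is.null(res$draws)) mechanism_shares(res)
    }
    lines <- c(lines, header, strrep("-", nchar(header)))
    lo <- sm[[3]]; hi <- sm[[4]]
    mark <- ifelse(lo > 0 | hi < 0, "*", "ns")
    lines <- c(lines, sprintf("  %-6s %10.4g  [%10.4g, %10.4g]  %s",
                              sm$quantity, sm$mean, lo, hi, mark))
    if (!is.null(shares)) {
      lines <- c(lines, "  shares of predicted total effect (T-hat):")
      ssm <- shares$summary
      lines <- c(lines, sprintf("    %-4s %6.1f%%  [%6.1f%%, %6.1f%%]",
                                ssm$mechanism, ssm$mean, ssm$lower, ssm$upper))
      if (shares$n_excluded > 0)
        lines <- c(lines, sprintf("    (%d draws with |T-hat| ~ 0 excluded)",
                                  shares$n_excluded))
    }
    lines <- c(lines, "")
  }
  cat(lines, sep = "\n")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
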