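# Pipeline drivers tying the stages together: simulate datasets to disk,
# evaluate the ten indices from a morphometrics CSV, and run the cortisol
# quantification/modelling chain. Every run writes a JSON manifest (also
# on failure) recording command, seed, config hash, inputs and outputs.

#' Read / write a generator configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_synth_config`, a validated [synth_config()].
#' @export
read_synth_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$derived <- NULL
  # yaml reads vectors back as lists; restore the fields that are atomic
  unl <- function(x) if (is.list(x)) unlist(x) else x
  raw$acute_prop <- unl(raw$acute_prop)
  raw$ages$proportions <- unl(raw$ages$proportions)
  for (nm in c("site_means", "layer_means", "sex_means", "shape"))
    raw$cortisol[[nm]] <- unl(raw$cortisol[[nm]])
  for (nm in c("standards", "sample_range"))
    raw$assay[[nm]] <- unl(raw$assay[[nm]])
  do.call(synth_config, raw)
}

#' @rdname read_synth_config
#' @param config A [synth_config()].
#' @export
write_synth_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$derived <- NULL
  # yaml serializes named atomic vectors as nameless sequences; write
  # them as maps so the names round-trip
  namify <- function(x) {
    if (is.list(x)) lapply(x, namify)
    else if (is.atomic(x) && !is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(namify(cfg), path)
  invisible(path)
}

write_manifest <- function(out_dir, command, seed, config, inputs,
                          outputs, status = "ok", error = NULL) {
  manifest <- list(
    command = command,
    package_version = as.character(utils::packageVersion("cetacond")),
    seed = seed,
    config_hash = if (is.null(config)) NA else config_hash(config),
    inputs = inputs, outputs = outputs,
    status = status, error = error,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Simulate all synthetic datasets to a directory
#'
#' Writes `morphometrics.csv`, the three cortisol designs
#' (`cortisol_site.csv`, `cortisol_layer.csv`, `cortisol_covariate.csv`),
#' `n_plates` assay plate CSVs under `plates/`, and a `manifest.json`.
#'
#' @param config A [synth_config()].
#' @param out_dir Output directory (created if missing).
#' @param n_plates Number of assay plates to simulate.
#' @return Invisible character vector of output paths.
#' @export
run_simulate <- function(config, out_dir, n_plates = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  status <- "ok"; err <- NULL
  on.exit(write_manifest(out_dir, "simulate", config$seed, config,
                         inputs = list(), outputs = outputs,
                         status = status, error = err))
  tryCatch({
    p <- file.path(out_dir, "morphometrics.csv")
    write_morphometrics(generate_morphometrics(config), p)
    outputs <- c(outputs, p)
    for (design in c("site", "layer", "covariate")) {
      p <- file.path(out_dir, paste0("cortisol_", design, ".csv"))
      utils::write.csv(generate_cortisol(config, design = design), p,
                       row.names = FALSE, quote = FALSE)
      outputs <- c(outputs, p)
    }
    dir.create(file.path(out_dir, "plates"), showWarnings = FALSE)
    for (k in seq_len(n_plates)) {
      p <- file.path(out_dir, "plates", sprintf("plate_%03d.csv", k))
      plate <- generate_assay_plate(config,
                                    plate_id = sprintf("plate-%03d", k),
                                    seed = (config$seed + k) %% .Machine$integer.max)
      utils::write.csv(plate, p, row.names = FALSE, quote = FALSE)
      outputs <- c(outputs, p)
    }
  }, error = function(e) {
    status <<- "failed"; err <<- conditionMessage(e)
    stop(e)
  })
  invisible(outputs)
}

#' Evaluate the ten condition indices from a morphometrics CSV
#'
#' Runs [evaluate_indices()] and writes the ground-truth report
#' (`report.csv`, one row per index with retained-variable flags,
#' assumption verdicts, partial eta-squared values, adjusted R-squared and
#' size-independence r), per-index selection tables
#' (`selection_<index>.csv`), an allometry report (`allometry.csv`) and a
#' JSON audit trail of the ranking (`ranking.json`).
#'
#' @param morph_csv Path to a morphometrics CSV.
#' @param out_dir Output directory.
#' @param criterion `"AIC"` or `"AICc"`.
#' @return The [evaluate_indices()] result, invisibly.
#' @export
run_evaluate <- function(morph_csv, out_dir, criterion = "AIC") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  status <- "ok"; err <- NULL
  on.exit(write_manifest(out_dir, "evaluate", NA, NULL,
                         inputs = list(morph_csv = morph_csv),
                         outputs = outputs, status = status, error = err))
  ev <- tryCatch({
    records <- read_morphometrics(morph_csv)
    evaluate_indices(records, criterion = criterion)
  }, error = function(e) {
    status <<- "failed"; err <<- conditionMessage(e)
    stop(e)
  })
  p <- file.path(out_dir, "report.csv")
  utils::write.csv(ev$report, p, row.names = FALSE)
  outputs <- c(outputs, p)
  for (ix in names(ev$selections)) {
    p <- file.path(out_dir, paste0("selection_", ix, ".csv"))
    utils::write.csv(as.data.frame(ev$selections[[ix]]), p,
                     row.names = FALSE)
    outputs <- c(outputs, p)
  }
  allo <- ev$allometry
  p <- file.path(out_dir, "allometry.csv")
  utils::write.csv(data.frame(parameter = c("delta", "alpha", "beta"),
                              estimate = c(allo$delta, allo$alpha,
                                           allo$beta),
                              ci_low = if (is.null(allo$ci)) NA else
                                allo$ci[, "low"],
                              ci_high = if (is.null(allo$ci)) NA else
                                allo$ci[, "high"]),
                   p, row.names = FALSE)
  outputs <- c(outputs, p)
  p <- file.path(out_dir, "ranking.json")
  jsonlite::write_json(list(recommended = ev$ranking$recommended,
                            trace = ev$ranking$trace),
                       p, auto_unbox = TRUE, pretty = TRUE)
  outputs <- c(outputs, p)
  invisible(ev)
}

#' Run the cortisol quantification and modelling chain
#'
#' Quantifies each plate CSV through its own 4PL standard curve, applies
#' the CV quality gates (flagging, not dropping), corrects assay
#' concentrations to ng/g where tissue masses are supplied, and fits the
#' site, layer and covariate models on the sample CSV as the available
#' designs allow. Plates without standards are skipped with a warning.
#'
#' @param plate_csvs Character vector of plate CSV paths (may be empty).
#' @param sample_csv Path to a cortisol sample CSV (schema of
#'   [generate_cortisol()]).
#' @param out_dir Output directory.
#' @return Invisible list with `quantified` (per-well concentrations),
#'   `cv` (the [assay_cv()] gates) and the fitted `site`, `layer`,
#'   `covariate` results (those whose design was present).
#' @export
run_cortisol <- function(plate_csvs = character(0), sample_csv, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  status <- "ok"; err <- NULL
  on.exit(write_manifest(out_dir, "cortisol", NA, NULL,
                         inputs = list(plate_csvs = plate_csvs,
                                       sample_csv = sample_csv),
                         outputs = outputs, status = status, error = err))
  res <- list()
  tryCatch({
    quantified <- NULL
    for (p in plate_csvs) {
      plate <- utils::read.csv(p, stringsAsFactors = FALSE)
      q <- tryCatch(quantify_plate(plate), error = function(e) {
        cc_warn(paste0("plate ", p, " skipped: ", conditionMessage(e)),
                "cetacond_plate_skipped")
        NULL
      })
      if (!is.null(q)) quantified <- rbind(quantified, q)
    }
    if (!is.null(quantified)) {
      res$quantified <- quantified
      res$cv <- assay_cv(quantified)
      pq <- file.path(out_dir, "quantified.csv")
      utils::write.csv(quantified, pq, row.names = FALSE)
      outputs <- c(outputs, pq)
      pcv <- file.path(out_dir, "cv_gates.json")
      jsonlite::write_json(res$cv, pcv, auto_unbox = TRUE, pretty = TRUE)
      outputs <- c(outputs, pcv)
    }
    samples <- utils::read.csv(sample_csv, stringsAsFactors = FALSE)
    full <- samples[samples$layer == "full", ]
    if (length(unique(full$site)) >= 2 && nrow(full) > 0) {
      res$site <- fit_site_glmm(full)
      outputs <- c(outputs, write_gamma_result(res$site, out_dir, "site"))
    }
    if (length(unique(samples$layer)) >= 2) {
      res$layer <- fit_layer_glmm(samples)
      outputs <- c(outputs, write_gamma_result(res$layer, out_dir,
                                               "layer"))
    }
    od <- samples[samples$site == "dorsal" & samples$layer == "outer", ]
    if (nrow(od) >= 8) {
      res$covariate <- fit_covariate_glm(od)
      outputs <- c(outputs, write_gamma_result(res$covariate, out_dir,
                                               "covariate"))
    }
  }, error = function(e) {
    status <<- "failed"; err <<- conditionMessage(e)
    stop(e)
  })
  invisible(res)
}

write_gamma_result <- function(res, out_dir, label) {
  paths <- character(0)
  p <- file.path(out_dir, paste0("selection_", label, ".csv"))
  utils::write.csv(as.data.frame(res$selection), p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(res$marginal_means)) {
    p <- file.path(out_dir, paste0("marginal_means_", label, ".csv"))
    utils::write.csv(res$marginal_means, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(res$contrasts)) {
    p <- file.path(out_dir, paste0("contrasts_", label, ".csv"))
    utils::write.csv(res$contrasts, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  paths
}
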