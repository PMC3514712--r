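#' Read and validate an analysis configuration
#'
#' The pipeline is driven by one declarative YAML file. Exactly one of
#' `simulation` (a [simulation_spec()]-like block) or `input` (paths to a
#' landmark file and a metadata CSV) must be present. A `seed` is mandatory
#' and `n_perm` must be at least 99.
#'
#' Recognized keys: `seed`, `n_perm`, `predictor` (metadata column regressed
#' on), `strata` (pooling column, e.g. `sex`; optional), `groups` (`ref`,
#' `alt`; optional — enables the contrast and funneling stages), `output`
#' (directory), `plane` (`xy`/`xz`/`yz`), `magnify`, `grid_n`, and either
#' `simulation` (`n`, `n_mutant`, `predictor_shift`, `noise_sd`, `slope`,
#' `predictor_mean`, `predictor_sd`, `sex_ratio`) or `input` (`landmarks`:
#' TPS or wide CSV; `metadata`: CSV keyed by `specimen_id`).
#'
#' @param path Path to a YAML configuration file, or a pre-parsed list.
#' @return A validated config list of class `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  config <- if (is.list(path)) path else fix_yaml_keys(yaml::read_yaml(path))
  has_sim <- !is.null(config$simulation)
  has_input <- !is.null(config$input)
  if (has_sim == has_input)
    stop("config must contain exactly one of 'simulation' or 'input'",
         call. = FALSE)
  if (is.null(config$seed))
    stop("config requires a 'seed' (every stochastic step is seeded)",
         call. = FALSE)
  if (is.null(config$n_perm)) config$n_perm <- 5000L
  if (config$n_perm < 99L)
    stop("'n_perm' must be at least 99", call. = FALSE)
  if (is.null(config$predictor))
    stop("config requires a 'predictor' column name", call. = FALSE)
  if (has_input &&
      (is.null(config$input$landmarks) || is.null(config$input$metadata)))
    stop("'input' needs 'landmarks' and 'metadata' paths", call. = FALSE)
  if (!is.null(config$groups) &&
      (is.null(config$groups$ref) || is.null(config$groups$alt)))
    stop("'groups' needs 'ref' and 'alt'", call. = FALSE)
  if (is.null(config$plane)) config$plane <- "xy"
  if (is.null(config$magnify)) config$magnify <- 3
  if (is.null(config$grid_n)) config$grid_n <- 20L
  structure(config, class = c("analysis_config", "list"))
}

# Internal: YAML 1.1 resolves a bare `n` (or `y`, `no`, ...) key to a
# boolean, which R then deparses to the name "FALSE"/"TRUE". The only such
# key in the config schema is the sample size `n`, so restore it.
fix_yaml_keys <- function(x) {
  if (!is.list(x)) return(x)
  nm <- names(x)
  if (!is.null(nm)) {
    nm[nm == "FALSE"] <- "n"
    names(x) <- nm
  }
  lapply(x, fix_yaml_keys)
}

# Internal: build a simulation_spec from a config's simulation block.
# Exact [[ ]] indexing throughout: `$` partial matching would silently read
# `n_mutant` for a missing `n`.
config_spec <- function(config) {
  sim <- config[["simulation"]]
  eff <- list(name = config[["predictor"]], slope = 0.017, mean = 7.7,
              sd = 0.37)
  if (!is.null(sim[["slope"]])) eff$slope <- sim[["slope"]]
  if (!is.null(sim[["predictor_mean"]])) eff$mean <- sim[["predictor_mean"]]
  if (!is.null(sim[["predictor_sd"]])) eff$sd <- sim[["predictor_sd"]]
  args <- list(effects = list(eff), seed = config[["seed"]])
  if (!is.null(sim[["n"]])) args$n <- sim[["n"]]
  if (!is.null(sim[["noise_sd"]])) args$noise_sd <- sim[["noise_sd"]]
  if (!is.null(sim[["sex_ratio"]])) args$sex_ratio <- sim[["sex_ratio"]]
  do.call(simulation_spec, args)
}

# Internal: obtain the configured dataset (simulated or read from disk).
config_dataset <- function(config) {
  if (!is.null(config$simulation)) {
    spec <- config_spec(config)
    sim <- config[["simulation"]]
    if (!is.null(sim[["predictor_shift"]])) {
      n_mut <- if (is.null(sim[["n_mutant"]])) spec$n else sim[["n_mutant"]]
      simulate_mutant_pair(spec, predictor_shift = sim[["predictor_shift"]],
                           n_mutant = n_mut)
    } else simulate_population(spec)
  } else {
    lm_path <- config$input$landmarks
    dataset <- if (grepl("\\.tps$", lm_path, ignore.case = TRUE))
      read_tps(lm_path) else read_landmark_csv(lm_path, layout = "wide")
    md <- read.csv(config$input$metadata, stringsAsFactors = FALSE)
    attach_metadata(dataset, md)
  }
}

#' Simulate a dataset and write it to disk
#'
#' Writes `landmarks.tps` and `metadata.csv` into the configured output
#' directory. Byte-identical across runs with the same configuration.
#'
#' @param config Path to a YAML config, or a config list
#'   (see [read_analysis_config()]); must contain a `simulation` block.
#' @param output Optional override of the config's output directory.
#' @return Named character vector of the written paths, invisibly.
#' @export
cmd_simulate <- function(config, output = NULL) {
  config <- read_analysis_config(config)
  if (is.null(config$simulation))
    stop("cmd_simulate requires a 'simulation' block", call. = FALSE)
  out_dir <- if (!is.null(output)) output else config$output
  if (is.null(out_dir)) stop("no output directory configured", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dataset <- config_dataset(config)
  paths <- c(landmarks = file.path(out_dir, "landmarks.tps"),
             metadata = file.path(out_dir, "metadata.csv"))
  write_tps(dataset, paths[["landmarks"]])
  md <- dataset$metadata
  num <- vapply(md, is.numeric, logical(1))
  md[num] <- lapply(md[num], function(v) sprintf("%.10g", v))
  write.csv(md, paths[["metadata"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' Reproduces the analysis design end-to-end on configured (or simulated)
#' data: GPA of the normal population, pooled within-strata regression of
#' shape on the configured predictor, and — when `groups` is configured — a
#' joint-superimposition mean-shape contrast, its permutation test, and the
#' funneling comparison of predicted versus observed Procrustes distance.
#' Writes `report.json` (all statistics, seeds and conventions),
#' `aligned_coordinates.csv`, and deformation-grid PNG figures into the
#' output directory. Outputs are staged and moved only on success, so a
#' failing run leaves no partial outputs.
#'
#' @inheritParams cmd_simulate
#' @return The report, invisibly (a nested list mirroring `report.json`).
#' @export
cmd_analyze <- function(config, output = NULL) {
  config <- read_analysis_config(config)
  out_dir <- if (!is.null(output)) output else config$output
  if (is.null(out_dir)) stop("no output directory configured", call. = FALSE)
  stage <- file.path(tempfile("funnelmorph_stage"))
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  dataset <- config_dataset(config)
  if (all(c("hormion", "opisthocranion") %in% landmark_names(dataset)))
    dataset <- measure_predictors(dataset)
  md <- dataset$metadata
  if (!config$predictor %in% names(md))
    stop("predictor column '", config$predictor, "' not in metadata",
         call. = FALSE)
  strata_col <- config$strata
  get_strata <- function(meta) {
    if (is.null(strata_col)) NULL else {
      if (!strata_col %in% names(meta))
        stop("strata column '", strata_col, "' not in metadata", call. = FALSE)
      meta[[strata_col]]
    }
  }
  ref_group <- if (!is.null(config$groups)) config$groups$ref else NULL
  normal_idx <- if (!is.null(ref_group) && "group" %in% names(md))
    which(md$group == ref_group) else seq_len(nrow(md))
  if (length(normal_idx) < 3L)
    stop("fewer than 3 normal-population specimens", call. = FALSE)

  normal <- landmark_dataset(dataset$coords[, , normal_idx, drop = FALSE],
                             md[normal_idx, , drop = FALSE])
  fit_normal <- gpa(normal)
  model <- pooled_within_regression(
    fit_normal, normal$metadata[[config$predictor]],
    strata = get_strata(normal$metadata),
    predictor_name = config$predictor,
    n_perm = config$n_perm, seed = config$seed)

  report <- list(
    settings = list(seed = config$seed, n_perm = config$n_perm,
                    predictor = config$predictor, strata = strata_col,
                    plane = config$plane, magnify = config$magnify,
                    conventions = list(
                      log_base = "natural",
                      scaling = "unit centroid size",
                      tangent_projection = "orthogonal at consensus",
                      permutation = "within strata; add-one p-value",
                      reflections = "disallowed")),
    versions = list(funnelmorph = as.character(
      utils::packageVersion("funnelmorph")),
      r = paste(R.version$major, R.version$minor, sep = ".")),
    gpa = list(n = n_specimens(normal), iterations = fit_normal$iterations,
               converged = fit_normal$converged),
    regression = list(predictor = config$predictor,
                      n = n_specimens(normal),
                      percent_var = model$percent_var,
                      p_value = model$p_value,
                      beta_norm = sqrt(sum(model$beta^2)),
                      predictor_cv = coefficient_of_variation(
                        normal$metadata[[config$predictor]])))

  figures <- character(0)
  draw_grid <- function(ref2, def2, fname, main) {
    path <- file.path(stage, fname)
    grDevices::png(path, width = 700, height = 700)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot_deformation_grid(
      deformation_grid(ref2, def2, grid_n = config$grid_n,
                       magnify = config$magnify),
      main = sprintf("%s (x%g)", main, config$magnify))
    fname
  }
  lo <- predict_shape(model, model$x_mean - 2 * sd(model$x))
  hi <- predict_shape(model, model$x_mean + 2 * sd(model$x))
  figures <- c(figures, draw_grid(
    project_to_plane(lo, config$plane), project_to_plane(hi, config$plane),
    paste0("regression_", config$predictor, ".png"),
    sprintf("shape change, low to high %s", config$predictor)))

  fit_out <- fit_normal
  if (!is.null(config$groups)) {
    alt_group <- config$groups$alt
    pair_idx <- which(md$group %in% c(ref_group, alt_group))
    pair <- landmark_dataset(dataset$coords[, , pair_idx, drop = FALSE],
                             md[pair_idx, , drop = FALSE])
    fit_joint <- gpa(pair)
    contrast <- group_contrast(fit_joint, pair$metadata$group,
                               ref = ref_group, alt = alt_group,
                               n_perm = config$n_perm, seed = config$seed,
                               predictor = pair$metadata[[config$predictor]])
    funnel <- funneling_comparison(contrast, model)
    report$contrast <- list(ref = ref_group, alt = alt_group,
                            n_ref = contrast$n_ref, n_alt = contrast$n_alt,
                            distance = contrast$distance,
                            p_value = contrast$p_value,
                            predictor_shift = contrast$predictor_shift)
    report$funneling <- list(observed = funnel$observed,
                             predicted = funnel$predicted,
                             ratio = funnel$ratio,
                             angle_deg = funnel$angle_deg)
    g <- pair$metadata$group
    ref_mean <- mean_shape(fit_joint$aligned[, , g == ref_group, drop = FALSE])
    alt_mean <- mean_shape(fit_joint$aligned[, , g == alt_group, drop = FALSE])
    figures <- c(figures, draw_grid(
      project_to_plane(ref_mean, config$plane),
      project_to_plane(alt_mean, config$plane),
      paste0("contrast_", alt_group, ".png"),
      sprintf("%s vs %s mean shape", alt_group, ref_group)))
    fit_out <- fit_joint
  }
  report$figures <- figures

  aligned_ds <- landmark_dataset(fit_out$aligned, fit_out$metadata)
  write_landmark_csv(aligned_ds, file.path(stage, "aligned_coordinates.csv"),
                     layout = "wide")
  jsonlite::write_json(report, file.path(stage, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(stage))
    file.copy(file.path(stage, f), file.path(out_dir, f), overwrite = TRUE)
  invisible(report)
}
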