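# One-call orchestration: simulate (or read) -> measures -> reduce ->
# cluster -> compare, with every stage output written to disk alongside a
# run manifest, so a run is reproducible from its config and seed alone.

#' Build a pipeline run configuration
#'
#' @param epoch_csv path to an epoch CSV to analyse; `NULL` simulates a
#'   cohort instead.
#' @param covariates_csv optional covariate CSV (required for the
#'   comparison stage when `epoch_csv` is given).
#' @param simulate list of [cohort_config()] arguments used when
#'   `epoch_csv` is `NULL`.
#' @param cutpoints a [cutpoint_config()].
#' @param dayparts a [daypart_definition()].
#' @param min_valid_days,min_wear_min wear-validity thresholds.
#' @param outlier_threshold |z| outlier threshold.
#' @param rotation PCA rotation.
#' @param keys `"auto"` or explicit key-measure names.
#' @param k fixed subtype count or `NULL`.
#' @param k_max,linkage clustering options.
#' @param alpha comparison significance level.
#' @param seed global seed; per-stage seeds derive from it via
#'   [derive_seed()].
#' @return list of class `run_config`.
#' @export
run_config <- function(epoch_csv = NULL, covariates_csv = NULL,
                       simulate = list(), cutpoints = cutpoint_config(),
                       dayparts = daypart_definition(),
                       min_valid_days = 5, min_wear_min = 660,
                       outlier_threshold = 4.0, rotation = "oblimin",
                       keys = "auto", k = NULL, k_max = 10,
                       linkage = "ward", alpha = 0.05, seed = 1L) {
  if (!is.null(epoch_csv) && !file.exists(epoch_csv))
    stop("epoch_csv not found: ", epoch_csv)
  if (!is.null(covariates_csv) && !file.exists(covariates_csv))
    stop("covariates_csv not found: ", covariates_csv)
  structure(list(epoch_csv = epoch_csv, covariates_csv = covariates_csv,
                 simulate = simulate, cutpoints = cutpoints,
                 dayparts = dayparts, min_valid_days = min_valid_days,
                 min_wear_min = min_wear_min,
                 outlier_threshold = outlier_threshold,
                 rotation = rotation, keys = keys, k = k, k_max = k_max,
                 linkage = linkage, alpha = alpha, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys mirror [run_config()] arguments; `simulate:` holds
#' [cohort_config()] fields; `cutpoints:` and `dayparts:` their respective
#' fields.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("epoch_csv", "covariates_csv", "min_valid_days",
               "min_wear_min", "outlier_threshold", "rotation", "keys",
               "k", "k_max", "linkage", "alpha", "seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$simulate)) args$simulate <- y$simulate
  if (!is.null(y$cutpoints))
    args$cutpoints <- do.call(cutpoint_config, y$cutpoints)
  if (!is.null(y$dayparts))
    args$dayparts <- do.call(daypart_definition,
                             lapply(y$dayparts, as.numeric))
  do.call(run_config, args)
}

#' Run the full subtyping pipeline
#'
#' Executes simulate/read, measure computation, reduction + clustering
#' (via [pb_subtype()]) and group comparison, writing each stage's output
#' and a JSON manifest into `out_dir`. Re-running with an identical config
#' yields identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with the fitted `pb_subtype` object, the
#'   measure table, the comparison and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[pbsubtype] ", sprintf(...))

  # stage 1: cohort
  truth <- NULL
  if (is.null(config$epoch_csv)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% derive_seed(config$seed, "simulate")
    cc <- do.call(cohort_config, sim_args)
    log_msg("simulating cohort: n = %d, seed = %d", cc$n_participants,
            cc$seed)
    cohort <- simulate_cohort(cc, cutpoints = config$cutpoints,
                              dayparts = config$dayparts)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    epochs <- cohort$epochs
    covariates <- cohort$covariates
    truth <- cohort$labels
  } else {
    log_msg("reading epochs from %s", config$epoch_csv)
    epochs <- read_epoch_csv(config$epoch_csv,
                             config$cutpoints$epoch_length)
    covariates <- if (!is.null(config$covariates_csv))
      read.csv(config$covariates_csv, stringsAsFactors = FALSE) else NULL
  }

  # stage 2: measures
  mt <- measures_table(epochs, cutpoints = config$cutpoints,
                       dayparts = config$dayparts,
                       min_valid_days = config$min_valid_days,
                       min_wear_min = config$min_wear_min)
  log_msg("measures: %d included, %d excluded", nrow(mt$measures),
          nrow(mt$exclusions))
  write_measures_csv(mt$measures, file.path(out_dir, "measures.csv"))
  write.csv(mt$exclusions, file.path(out_dir, "exclusions.csv"),
            row.names = FALSE)

  # stage 3+4: reduction and clustering
  fit <- pb_subtype(mt$measures, keys = config$keys,
                    outlier_threshold = config$outlier_threshold,
                    k = config$k, k_max = config$k_max,
                    linkage = config$linkage, rotation = config$rotation,
                    seed = derive_seed(config$seed, "cluster"))
  log_msg("clustering: k = %d, Cramer's V = %.2f", fit$k,
          fit$validation$v)
  if (!is.null(fit$pca)) {
    lo <- rbind(fit$pca$pattern,
                eigenvalue = fit$pca$eigenvalues[seq_len(fit$pca$n_retained)],
                pct_variance = fit$pca$pct_variance[seq_len(fit$pca$n_retained)])
    write.csv(lo, file.path(out_dir, "loadings.csv"))
    jsonlite::write_json(
      list(kmo = fit$kmo$kmo, n_retained = fit$pca$n_retained,
           total_explained_variance = fit$pca$total_explained_variance,
           keys = fit$keys),
      file.path(out_dir, "reduction.json"), auto_unbox = TRUE, digits = NA)
  }
  labels <- cluster_labels(fit)
  write.csv(data.frame(participant_id = names(labels), cluster = labels),
            file.path(out_dir, "labels.csv"), row.names = FALSE)
  write.csv(fit$profile, file.path(out_dir, "centroids_z.csv"))
  write.csv(fit$centers_raw, file.path(out_dir, "centroids_raw.csv"))
  write.csv(fit$elbow$elbow, file.path(out_dir, "elbow.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(k = fit$k, v_a = fit$validation$v_a, v_b = fit$validation$v_b,
         v = fit$validation$v, removed_outliers = fit$removed),
    file.path(out_dir, "validation.json"), auto_unbox = TRUE, digits = NA)
  writeLines(dendrogram_newick(fit$hierarchical),
             file.path(out_dir, "dendrogram.nwk"))
  grDevices::pdf(file.path(out_dir, "profiles.pdf"), width = 8, height = 5)
  plot(fit, type = "profile")
  if (all(c("sb_morning", "sb_afternoon", "sb_evening") %in%
          names(mt$measures)))
    plot(fit, type = "dayparts")
  plot(fit, type = "elbow")
  dev.off()

  # stage 5: comparison
  comparison <- NULL
  if (!is.null(covariates)) {
    cmp_data <- merge(covariates, mt$measures, by = "participant_id")
    comparison <- compare_groups(cmp_data, labels, alpha = config$alpha)
    write.csv(as.data.frame(comparison),
              file.path(out_dir, "comparison.csv"), row.names = FALSE)
    log_msg("comparison: %d variables", length(comparison$rows))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("pbsubtype")),
    r_version = R.version.string,
    seed = config$seed,
    stage_seeds = list(simulate = derive_seed(config$seed, "simulate"),
                       cluster = derive_seed(config$seed, "cluster")),
    n_included = nrow(mt$measures), n_excluded = nrow(mt$exclusions),
    n_clustered = length(labels), k = fit$k,
    cluster_sizes = as.vector(table(labels)),
    cramers_v = fit$validation$v,
    keys = fit$keys, timestamp_utc = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fit = fit, measures = mt, comparison = comparison,
                 truth = truth, manifest = manifest))
}
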