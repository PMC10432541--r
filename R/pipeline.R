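#' Full pipeline configuration
#'
#' Bundles every stage's parameters with one master seed that is propagated
#' to each stochastic stage (cohort simulation, fold assignment).
#'
#' @param synth a `fos_synth_config`.
#' @param cluster a `fos_cluster_params`.
#' @param shared a `fos_shared_params`.
#' @param detection a `fos_detection_params`.
#' @param classifier_folds,classifier_grouping cross-validation settings.
#' @param out_dir output directory for the report bundle.
#' @param seed master seed; overrides `synth$seed`.
#' @return list of class `fos_pipeline_config`.
#' @export
pipeline_config <- function(synth = synthetic_config(),
                            cluster = cluster_params(),
                            shared = shared_pattern_params(),
                            detection = detection_params(),
                            classifier_folds = 10L,
                            classifier_grouping = "record",
                            out_dir = tempfile("fostopo_run_"),
                            seed = 1L) {
  synth$seed <- as.integer(seed)
  structure(list(synth = synth, cluster = cluster, shared = shared,
                 detection = detection, classifier_folds = classifier_folds,
                 classifier_grouping = classifier_grouping,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "fos_pipeline_config")
}

#' Write a pipeline configuration to YAML (and read it back)
#'
#' @param config a `fos_pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  # named atomic vectors become maps (yaml sequences would drop the names)
  to_plain <- function(x) {
    if (is.list(x)) lapply(x, to_plain)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(to_plain(unclass(config)), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  synth <- do.call(synthetic_config,
                   c(list(n_per_group = unlist(raw$synth$n_per_group)),
                     raw$synth[setdiff(names(raw$synth),
                                       c("n_per_group", "effect_field"))],
                     list(effect_field = lapply(raw$synth$effect_field,
                                                unlist))))
  pipeline_config(synth = synth,
                  cluster = do.call(cluster_params, raw$cluster),
                  shared = do.call(shared_pattern_params, raw$shared),
                  detection = do.call(detection_params, raw$detection),
                  classifier_folds = raw$classifier_folds,
                  classifier_grouping = raw$classifier_grouping,
                  out_dir = raw$out_dir, seed = raw$seed)
}

#' Run the end-to-end analysis pipeline on a simulated cohort
#'
#' simulate -> heat maps -> subregion ANOVA -> frequency bins -> clustering
#' -> shared pattern -> classification, writing a report bundle (CSV + JSON)
#' and a run manifest to `config$out_dir`. Identical config and seed produce
#' an identical bundle.
#'
#' @param config a `fos_pipeline_config`.
#' @param cohort optionally, an existing `fos_cohort` to analyze instead of
#'   simulating one.
#' @return list of class `fos_report` with all stage results and the paths
#'   of the written artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  wpath <- function(name) file.path(config$out_dir, name)

  if (is.null(cohort)) cohort <- generate_cohort(config$synth)
  write_count_table(cohort, paths$cohort <- wpath("cohort.csv"))

  groups_present <- intersect(GROUP_LEVELS, unique(cohort$counts$group))
  heatmaps <- lapply(groups_present, function(g) mean_count_matrix(cohort, g))
  names(heatmaps) <- groups_present
  for (g in groups_present) {
    p <- wpath(paste0("heatmap_", g, ".csv"))
    utils::write.csv(heatmaps[[g]]$mean, p, row.names = TRUE, na = "NA")
    paths[[paste0("heatmap_", g)]] <- p
  }

  sm <- subregion_means(cohort)
  labels <- setdiff(names(sm), c("animal_id", "group"))
  anova_tab <- do.call(rbind, lapply(labels, function(l) {
    a <- subregion_anova(cohort, l)
    data.frame(subregion = l, F = a$F, df1 = a$df[1], df2 = a$df[2], p = a$p,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(anova_tab, paths$anova <- wpath("subregion_anova.csv"),
                   row.names = FALSE)

  freq <- frequency_profiles(cohort)
  utils::write.csv(freq, paths$frequency <- wpath("frequency_profiles.csv"),
                   row.names = FALSE)
  bin_tests <- if (all(c("massed", "distributed") %in% groups_present)) {
    compare_bins(cohort, "distributed", "control")
  } else NULL
  if (!is.null(bin_tests)) {
    utils::write.csv(bin_tests, paths$bins <- wpath("bin_tests.csv"),
                     row.names = FALSE)
  }

  clus <- cluster_counts_by_group(cohort, config$cluster)
  utils::write.csv(clus$per_animal,
                   paths$cluster <- wpath("clustered_counts.csv"),
                   row.names = FALSE)

  shared <- shared_pattern_report(cohort, config$shared)
  jsonlite::write_json(
    list(threshold = shared$threshold,
         n_shared = as.list(shared$n_shared),
         shared = shared$shared),
    paths$shared <- wpath("shared_pattern.json"), auto_unbox = TRUE,
    digits = NA)

  ft <- build_feature_table(cohort, threshold = shared$threshold)
  two <- ft[ft$group %in% c("massed", "distributed"), ]
  cv2 <- cross_validated_accuracy(two, k = config$classifier_folds,
                                  seed = config$seed,
                                  grouping = config$classifier_grouping)
  cv3 <- cross_validated_accuracy(ft, k = config$classifier_folds,
                                  seed = config$seed,
                                  grouping = config$classifier_grouping)
  imp <- feature_importance(ft)
  jsonlite::write_json(
    list(accuracy_2class = cv2$accuracy, accuracy_3class = cv3$accuracy,
         per_fold_2class = cv2$per_fold, per_fold_3class = cv3$per_fold,
         importance = imp),
    paths$classification <- wpath("classification.json"), auto_unbox = TRUE,
    digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("fostopo")),
    seed = config$seed,
    config_hash = config_hash(config),
    artifacts = lapply(paths, basename))
  jsonlite::write_json(manifest, wpath("manifest.json"), auto_unbox = TRUE)
  paths$manifest <- wpath("manifest.json")

  structure(list(cohort = cohort, heatmaps = heatmaps, anova = anova_tab,
                 frequency = freq, bin_tests = bin_tests, clustering = clus,
                 shared = shared,
                 classification = list(cv_2class = cv2, cv_3class = cv3,
                                       importance = imp),
                 paths = paths),
            class = "fos_report")
}

# internal: stable hash of the configuration (serialized canonical text);
# the output directory is not part of the scientific configuration
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  txt <- paste(utils::capture.output(utils::str(cfg, digits.d = 15)),
               collapse = "\n")
  # small polynomial rolling hash; stability matters, cryptography does not
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.fos_report <- function(x, ...) {
  cat("fostopo pipeline report\n")
  print(x$cohort)
  cat("Subregion ANOVA (smallest p):\n")
  print(utils::head(x$anova[order(x$anova$p), ], 3), row.names = FALSE)
  cat("Clustered high-count ROIs per group:\n")
  print(x$clustering$group_stats, row.names = FALSE)
  print(x$shared)
  cat(sprintf("CV accuracy: 2-class %.3f, 3-class %.3f; top feature: %s\n",
              x$classification$cv_2class$accuracy,
              x$classification$cv_3class$accuracy,
              x$classification$importance$feature[1]))
  invisible(x)
}
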