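#' Shared-pattern parameters
#'
#' @param threshold activation cutoff (cells per ROI, inclusive), or `NULL`
#'   to derive it from the control animals via [control_threshold()].
#' @param min_animals integer number of animals that must share a position,
#'   or the rule `"n-1"` (all but one animal of the group, the default).
#' @param pool_hemispheres if `TRUE` (default) a position counts as above
#'   threshold for an animal when either hemisphere is; if `FALSE`,
#'   hemispheres are treated as separate positions.
#' @return list of class `fos_shared_params`.
#' @export
shared_pattern_params <- function(threshold = NULL, min_animals = "n-1",
                                  pool_hemispheres = TRUE) {
  if (!is.null(threshold)) stopifnot(threshold >= 0)
  if (!(identical(min_animals, "n-1") ||
        (is.numeric(min_animals) && min_animals >= 1))) {
    stop("`min_animals` must be a positive integer or \"n-1\"")
  }
  structure(list(threshold = threshold, min_animals = min_animals,
                 pool_hemispheres = isTRUE(pool_hemispheres)),
            class = "fos_shared_params")
}

#' Control-derived activation threshold
#'
#' Pooled mean of all sampled per-ROI counts over the control animals,
#' rounded half-up to an integer.
#'
#' @param cohort a `fos_cohort` containing control animals.
#' @return integer threshold.
#' @export
control_threshold <- function(cohort) {
  x <- cohort$counts$count[cohort$counts$group == "control"]
  if (!length(x)) stop("no control animals in cohort")
  as.integer(floor(mean(x) + 0.5))
}

# internal: resolve params against a group size
resolve_min_animals <- function(params, n) {
  m <- if (identical(params$min_animals, "n-1")) max(n - 1L, 1L)
       else as.integer(params$min_animals)
  if (m > n) stop("min_animals (", m, ") exceeds group size (", n, ")")
  m
}

# internal: per-animal above-threshold position keys
above_threshold_keys <- function(animal, threshold, pool_hemispheres) {
  hit <- animal[animal$count >= threshold, , drop = FALSE]
  if (pool_hemispheres) {
    unique(paste(hit$section, hit$roi, sep = ":"))
  } else {
    unique(paste(hit$hemisphere, hit$section, hit$roi, sep = ":"))
  }
}

#' Grid positions activated above threshold in nearly all of a group
#'
#' Finds (section, roi) positions whose count reaches the threshold in at
#' least `min_animals` animals of the group. By default a position is
#' "above" for an animal if either hemisphere reaches the threshold; a
#' missing ROI counts as below threshold.
#'
#' @param group_animals list of per-animal data frames (count rows), e.g.
#'   from splitting a cohort by animal.
#' @param params a `fos_shared_params` with `threshold` resolved (integer).
#' @param grid,scheme grid and scheme used to annotate subregions.
#' @return data frame of shared positions: `section`, `roi` (and
#'   `hemisphere` when `pool_hemispheres = FALSE`), `n_above` (animals above
#'   threshold there) and `subregion`.
#' @export
shared_rois <- function(group_animals, params,
                        grid = build_canonical_grid(),
                        scheme = default_subregion_scheme()) {
  if (!length(group_animals)) stop("empty group")
  if (is.null(params$threshold)) {
    stop("`params$threshold` must be resolved (see control_threshold)")
  }
  m <- resolve_min_animals(params, length(group_animals))
  keys <- unlist(lapply(group_animals, above_threshold_keys,
                        threshold = params$threshold,
                        pool_hemispheres = params$pool_hemispheres))
  tab <- table(keys)
  hit <- names(tab)[tab >= m]
  if (is.null(hit)) hit <- character(0)
  parts <- strsplit(hit, ":", fixed = TRUE)
  if (params$pool_hemispheres) {
    out <- data.frame(
      section = as.integer(vapply(parts, `[`, "", 1)),
      roi = as.integer(vapply(parts, `[`, "", 2)),
      n_above = as.integer(tab[hit]))
    coords <- data.frame(hemisphere = rep(grid$hemispheres[1], nrow(out)),
                         section = out$section, roi = out$roi)
  } else {
    out <- data.frame(
      hemisphere = vapply(parts, `[`, "", 1),
      section = as.integer(vapply(parts, `[`, "", 2)),
      roi = as.integer(vapply(parts, `[`, "", 3)),
      n_above = as.integer(tab[hit]))
    coords <- out
  }
  out$subregion <- if (nrow(out)) assign_subregion(coords, grid, scheme)
                   else character(0)
  out <- out[order(out$section, out$roi), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Shared-position report over all three groups
#'
#' Runs [shared_rois()] per group (resolving the `"n-1"` rule against each
#' group's size, and the threshold from the controls when not given) and
#' tallies shared positions per antero-posterior band and per subregion.
#'
#' @param cohort a `fos_cohort` with all three groups.
#' @param params a `fos_shared_params`.
#' @return list of class `fos_shared_report`: `threshold`, per-group
#'   `shared` data frames, `n_shared` counts, and `by_band` / `by_subregion`
#'   tally tables.
#' @export
shared_pattern_report <- function(cohort, params = shared_pattern_params()) {
  if (is.null(params$threshold)) {
    params$threshold <- control_threshold(cohort)
  }
  groups <- animal_groups(cohort)
  animals <- split_animals(cohort)
  band_of <- function(sections) {
    cohort$grid$sections$ap_band[match(sections, cohort$grid$sections$section)]
  }
  shared <- list(); n_shared <- integer(0)
  by_band <- list(); by_sub <- list()
  for (g in intersect(GROUP_LEVELS, unique(groups))) {
    ga <- animals[names(groups)[groups == g]]
    sr <- shared_rois(ga, params, cohort$grid, cohort$scheme)
    shared[[g]] <- sr
    n_shared[g] <- nrow(sr)
    by_band[[g]] <- table(factor(band_of(sr$section),
                                 levels = unique(cohort$grid$sections$ap_band)))
    by_sub[[g]] <- table(sr$subregion)
  }
  structure(list(threshold = params$threshold, min_animals = params$min_animals,
                 shared = shared, n_shared = n_shared,
                 by_band = by_band, by_subregion = by_sub),
            class = "fos_shared_report")
}

#' @export
print.fos_shared_report <- function(x, ...) {
  cat("Shared above-threshold positions (threshold =", x$threshold,
      ", rule =", x$min_animals, "):\n")
  for (g in names(x$n_shared)) {
    cat(sprintf("  %-12s %d position(s)", g, x$n_shared[[g]]))
    if (x$n_shared[[g]] > 0) {
      cat(" [", paste(names(x$by_band[[g]]), x$by_band[[g]], sep = "=",
                      collapse = ", "), "]")
    }
    cat("\n")
  }
  invisible(x)
}

#' Sweep the minimum-animals rule
#'
#' Robustness check: shared-set size for one group across a range of
#' `min_animals` values.
#'
#' @param cohort a `fos_cohort`.
#' @param group group label.
#' @param min_range integer vector of `min_animals` values (default 2 up to
#'   the group size).
#' @param params a `fos_shared_params` (threshold resolved from controls if
#'   `NULL`).
#' @return data frame `min_animals`, `n_shared`.
#' @export
shared_sweep <- function(cohort, group, min_range = NULL,
                         params = shared_pattern_params()) {
  if (is.null(params$threshold)) params$threshold <- control_threshold(cohort)
  groups <- animal_groups(cohort)
  ga <- split_animals(cohort)[names(groups)[groups == group]]
  if (is.null(min_range)) min_range <- seq(2L, length(ga))
  n <- vapply(min_range, function(m) {
    p <- params; p$min_animals <- m
    nrow(shared_rois(ga, p, cohort$grid, cohort$scheme))
  }, integer(1))
  data.frame(min_animals = as.integer(min_range), n_shared = n)
}
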