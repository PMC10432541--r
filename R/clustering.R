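#' High-count neighbor clustering parameters
#'
#' The clustering rule of the topographic analysis: among ROIs with a high
#' c-Fos count (at or above `count_threshold`), keep only those with at
#' least `min_neighbors` *other* high-count ROIs within `radius` (Euclidean,
#' grid-index units, boundary inclusive), per hemisphere.
#'
#' @param count_threshold high-count cutoff (cells per ROI; inclusive).
#' @param radius neighborhood radius in grid-index units.
#' @param min_neighbors required number of other high-count ROIs in the
#'   neighborhood.
#' @param inclusive if `FALSE`, use a strict (`<`) radius instead of the
#'   default closed (`<=`) one.
#' @return list of class `fos_cluster_params`.
#' @export
cluster_params <- function(count_threshold = 40L, radius = 5,
                           min_neighbors = 5L, inclusive = TRUE) {
  stopifnot(count_threshold >= 0, radius > 0, is.finite(radius),
            min_neighbors >= 0)
  structure(list(count_threshold = as.integer(count_threshold),
                 radius = radius, min_neighbors = as.integer(min_neighbors),
                 inclusive = isTRUE(inclusive)),
            class = "fos_cluster_params")
}

#' High-count ROI mask for one animal
#'
#' @param animal data frame of one animal's count rows.
#' @param params a `fos_cluster_params`.
#' @return data frame (`hemisphere`, `section`, `roi`) of sampled ROIs with
#'   `count >= count_threshold`; missing ROIs never qualify.
#' @export
high_count_mask <- function(animal, params = cluster_params()) {
  hit <- animal$count >= params$count_threshold
  out <- animal[hit, c("hemisphere", "section", "roi"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spatially clustered high-count ROIs for one animal
#'
#' Applies the neighbor rule: a high-count ROI is retained iff at least
#' `min_neighbors` other high-count ROIs of the same hemisphere lie within
#' `radius` of it (self excluded, boundary inclusive by default).
#'
#' @inheritParams high_count_mask
#' @return data frame (`hemisphere`, `section`, `roi`) of retained ROIs.
#' @export
clustered_rois <- function(animal, params = cluster_params()) {
  mask <- high_count_mask(animal, params)
  if (!nrow(mask)) return(mask)
  keep <- logical(nrow(mask))
  for (h in unique(mask$hemisphere)) {
    i <- which(mask$hemisphere == h)
    if (length(i) <= params$min_neighbors) next
    dm <- pairwise_grid_distance(mask[i, ])
    within <- if (params$inclusive) dm <= params$radius else dm < params$radius
    keep[i] <- (rowSums(within) - 1L) >= params$min_neighbors
  }
  out <- mask[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clustered-ROI counts per animal with pairwise group comparisons
#'
#' Counts each animal's clustered high-count ROIs (both hemispheres) and
#' compares the three groups pairwise with two-sided two-sample t tests.
#' A pairwise comparison whose pooled variance is zero is flagged degenerate
#' and reported without a p-value.
#'
#' @param cohort a `fos_cohort`.
#' @param params a `fos_cluster_params`.
#' @return list: `per_animal` (data frame `animal_id`, `group`,
#'   `n_clustered`), `group_stats` (mean, sd, sem, n per group), `tests`
#'   (data frame `contrast`, `t`, `df`, `p`, `degenerate`).
#' @export
cluster_counts_by_group <- function(cohort, params = cluster_params()) {
  groups <- animal_groups(cohort)
  n_clustered <- vapply(split_animals(cohort),
                        function(a) nrow(clustered_rois(a, params)),
                        integer(1))
  per_animal <- data.frame(animal_id = names(n_clustered),
                           group = unname(groups[names(n_clustered)]),
                           n_clustered = unname(n_clustered),
                           stringsAsFactors = FALSE)
  gs <- do.call(rbind, lapply(split(per_animal$n_clustered, per_animal$group),
                              function(x) data.frame(n = length(x),
                                                     mean = mean(x),
                                                     sd = stats::sd(x),
                                                     sem = stats::sd(x) /
                                                       sqrt(length(x)))))
  gs <- cbind(group = rownames(gs), gs, stringsAsFactors = FALSE)
  rownames(gs) <- NULL
  present <- intersect(GROUP_LEVELS, unique(per_animal$group))
  pairs <- if (length(present) >= 2) {
    utils::combn(present, 2, simplify = FALSE)
  } else list()
  tests <- if (!length(pairs)) {
    data.frame(contrast = character(0), t = numeric(0), df = numeric(0),
               p = numeric(0), degenerate = logical(0))
  } else do.call(rbind, lapply(pairs, function(p) {
    x <- per_animal$n_clustered[per_animal$group == p[1]]
    y <- per_animal$n_clustered[per_animal$group == p[2]]
    if (length(x) < 2 || length(y) < 2 ||
        (stats::sd(x) == 0 && stats::sd(y) == 0)) {
      return(data.frame(contrast = paste(p, collapse = " vs "), t = NA_real_,
                        df = NA_real_, p = NA_real_, degenerate = TRUE))
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
    data.frame(contrast = paste(p, collapse = " vs "),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, degenerate = FALSE)
  }))
  list(per_animal = per_animal, group_stats = gs, tests = tests)
}
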