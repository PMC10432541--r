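# internal: per-animal counts with hemispheres pooled at each (section, roi):
# average of the two hemispheres when both sampled, else the sampled one.
pooled_positions <- function(animal_rows) {
  key <- interaction(animal_rows$section, animal_rows$roi, drop = TRUE)
  agg <- tapply(animal_rows$count, key, mean)
  first <- !duplicated(key)
  out <- data.frame(section = animal_rows$section[first],
                    roi = animal_rows$roi[first])
  out$count <- as.numeric(agg[as.character(key[first])])
  out
}

#' Group mean count matrix (heat-map matrix)
#'
#' Arithmetic mean of per-ROI c-Fos counts across a group's animals, laid out
#' as a section x ROI matrix (the numeric core of a 3-D heat map). Within an
#' animal the two hemispheres are averaged where both are sampled; missing
#' ROIs are excluded from the cross-animal mean (cells sampled by no animal
#' are `NA`).
#'
#' @param cohort a `fos_cohort`.
#' @param group group label.
#' @return object of class `fos_heatmap`: list with `group`, `mean` (matrix,
#'   `NA` off-grid or unsampled) and `n` (per-cell number of contributing
#'   animals).
#' @export
mean_count_matrix <- function(cohort, group) {
  rows <- cohort$counts[cohort$counts$group == group, ]
  if (!nrow(rows)) stop("no animals in group '", group, "'")
  ns <- nrow(cohort$grid$sections)
  nr <- max(cohort$grid$sections$n_roi)
  acc <- matrix(0, ns, nr); nmat <- matrix(0L, ns, nr)
  for (a in split(rows, rows$animal_id)) {
    p <- pooled_positions(a)
    ij <- cbind(p$section, p$roi)
    acc[ij] <- acc[ij] + p$count
    nmat[ij] <- nmat[ij] + 1L
  }
  m <- acc / ifelse(nmat == 0L, NA_integer_, nmat)
  dimnames(m) <- dimnames(nmat) <-
    list(section = seq_len(ns), roi = seq_len(nr))
  structure(list(group = group, mean = m, n = nmat), class = "fos_heatmap")
}

#' @export
print.fos_heatmap <- function(x, digits = 1, ...) {
  cat("Mean c-Fos count matrix, group:", x$group, "\n")
  print(round(x$mean, digits))
  invisible(x)
}

#' @export
plot.fos_heatmap <- function(x, ...) {
  m <- x$mean
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "section (antero-posterior)",
                  ylab = "ROI (distal to proximal)",
                  main = paste("mean c-Fos+ cells per ROI,", x$group), ...)
  invisible(x)
}

#' Per-animal subregion mean counts
#'
#' Mean of sampled ROI counts within each of the eight subregions, per
#' animal, over both hemispheres; missing ROIs are excluded from the
#' denominator, and a subregion with no sampled ROI for an animal is `NA`
#' (absent), never zero.
#'
#' @param cohort a `fos_cohort`.
#' @return data frame: `animal_id`, `group`, then one column per subregion
#'   label.
#' @export
subregion_means <- function(cohort) {
  lab <- assign_subregion(cohort$counts, cohort$grid, cohort$scheme)
  labels <- sort(unique(assign_subregion(grid_coordinates(cohort$grid),
                                         cohort$grid, cohort$scheme)))
  groups <- animal_groups(cohort)
  ids <- names(groups)
  out <- data.frame(animal_id = ids, group = unname(groups),
                    stringsAsFactors = FALSE)
  for (l in labels) out[[l]] <- NA_real_
  means <- tapply(cohort$counts$count,
                  list(cohort$counts$animal_id, lab), mean)
  for (l in intersect(labels, colnames(means))) {
    out[[l]] <- as.numeric(means[ids, l])
  }
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey HSD on one subregion's per-animal means
#'
#' Fixed-effects one-way ANOVA of per-animal subregion mean counts across the
#' three training groups, followed by Tukey's HSD (Tukey-Kramer for the
#' unequal group sizes) on the three pairwise contrasts.
#'
#' @param cohort a `fos_cohort`.
#' @param subregion subregion label, e.g. `"PD"`.
#' @return list: `subregion`, `F`, `df`, `p`, and `tukey` (data frame of
#'   pairwise contrasts with adjusted p-values).
#' @export
subregion_anova <- function(cohort, subregion) {
  sm <- subregion_means(cohort)
  if (!subregion %in% names(sm)) stop("unknown subregion '", subregion, "'")
  d <- data.frame(y = sm[[subregion]], group = factor(sm$group))
  d <- d[!is.na(d$y), ]
  sizes <- table(droplevels(d$group))
  if (length(sizes) < 2) stop("need at least two groups with data")
  if (any(sizes < 2)) {
    stop("group(s) with fewer than 2 animals: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  d$group <- droplevels(d$group)
  fit <- stats::aov(y ~ group, data = d)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(subregion = subregion,
       F = an[["F value"]][1],
       df = c(an[["Df"]][1], an[["Df"]][2]),
       p = an[["Pr(>F)"]][1],
       tukey = data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL))
}

FREQ_BREAKS <- seq(0, 100, by = 10)

#' Frequency profile of per-ROI counts for one animal
#'
#' Classifies an animal's sampled ROIs by c-Fos count into the intervals
#' 0-10, 11-20, ..., 91-100 (upper edge inclusive) plus an overflow bin for
#' counts above 100, and reports each bin as a percentage of that animal's
#' sampled ROIs.
#'
#' @param animal data frame of one animal's count rows (both hemispheres).
#' @return named numeric vector of percentages over the 11 bins; sums to 100.
#' @export
frequency_histogram <- function(animal) {
  counts <- animal$count
  if (!length(counts)) stop("animal has no sampled ROIs")
  bin <- findInterval(counts, seq(11, 101, by = 10))  # 0: 0-10 ... 10: >100
  if (any(bin == 10L)) {
    warning(sum(bin == 10L), " ROI count(s) above 100 placed in overflow bin")
  }
  labels <- c("0-10", paste(FREQ_BREAKS[-c(1, 11)] + 1,
                            FREQ_BREAKS[-c(1, 2)], sep = "-"), ">100")
  pct <- 100 * tabulate(bin + 1L, nbins = 11L) / length(counts)
  stats::setNames(pct, labels)
}

#' Per-bin frequency profiles for every animal of a cohort
#'
#' @param cohort a `fos_cohort`.
#' @return data frame: `animal_id`, `group`, one column per bin (percent).
#' @export
frequency_profiles <- function(cohort) {
  groups <- animal_groups(cohort)
  # overflow is visible in the ">100" column; per-animal warnings silenced
  prof <- t(vapply(split_animals(cohort),
                   function(a) suppressWarnings(frequency_histogram(a)),
                   numeric(11L)))
  out <- data.frame(animal_id = rownames(prof),
                    group = unname(groups[rownames(prof)]),
                    stringsAsFactors = FALSE, check.names = FALSE)
  cbind(out, as.data.frame(prof, check.names = FALSE))
}

#' Mann-Whitney comparison of frequency bins between two groups
#'
#' Two-sided Mann-Whitney U test per count-frequency bin, on per-animal bin
#' percentages. `U` is the statistic for the first group (0..nA*nB). Bins in
#' which every value is tied across both groups are flagged `degenerate` and
#' get `p = NA`.
#'
#' @param cohort a `fos_cohort`.
#' @param group_a,group_b the two group labels to compare.
#' @return data frame: `bin`, `U`, `p`, `degenerate`.
#' @export
compare_bins <- function(cohort, group_a, group_b) {
  prof <- frequency_profiles(cohort)
  a <- prof[prof$group == group_a, , drop = FALSE]
  b <- prof[prof$group == group_b, , drop = FALSE]
  if (nrow(a) < 1 || nrow(b) < 1) stop("both groups need >= 1 animal")
  bins <- setdiff(names(prof), c("animal_id", "group"))
  res <- lapply(bins, function(bn) {
    x <- a[[bn]]; y <- b[[bn]]
    if (length(unique(c(x, y))) == 1L) {
      return(data.frame(bin = bn, U = length(x) * length(y) / 2, p = NA_real_,
                        degenerate = TRUE))
    }
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = FALSE))
    data.frame(bin = bn, U = unname(wt$statistic), p = wt$p.value,
               degenerate = FALSE)
  })
  do.call(rbind, res)
}
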