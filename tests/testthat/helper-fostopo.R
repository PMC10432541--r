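# shared fixtures and independent brute-force oracles

# quick animal data frame from explicit coordinates
toy_animal <- function(section, roi, count, hemisphere = "H1",
                       animal_id = "a1", group = "control") {
  data.frame(animal_id = animal_id, group = group,
             hemisphere = rep_len(hemisphere, length(section)),
             section = as.integer(section), roi = as.integer(roi),
             count = as.integer(count), stringsAsFactors = FALSE)
}

# a small fully-valid cohort: 3 animals, a handful of ROIs each
toy_cohort <- function() {
  rows <- rbind(
    toy_animal(c(1, 1, 2), c(1, 2, 3), c(10, 20, 30), animal_id = "c1",
               group = "control"),
    toy_animal(c(1, 9, 9), c(1, 1, 2), c(5, 50, 45), animal_id = "m1",
               group = "massed"),
    toy_animal(c(9, 10, 11), c(1, 2, 3), c(60, 55, 40), animal_id = "d1",
               group = "distributed"))
  fos_cohort(rows)
}

# brute-force neighbor-rule oracle: plain double loop over the mask
oracle_clustered <- function(animal, params) {
  mask <- animal[animal$count >= params$count_threshold, , drop = FALSE]
  if (!nrow(mask)) return(mask[, c("hemisphere", "section", "roi")])
  keep <- logical(nrow(mask))
  for (i in seq_len(nrow(mask))) {
    n_nb <- 0L
    for (j in seq_len(nrow(mask))) {
      if (i == j) next
      if (mask$hemisphere[i] != mask$hemisphere[j]) next
      d <- sqrt((mask$section[i] - mask$section[j])^2 +
                  (mask$roi[i] - mask$roi[j])^2)
      if (d <= params$radius) n_nb <- n_nb + 1L
    }
    keep[i] <- n_nb >= params$min_neighbors
  }
  out <- mask[keep, c("hemisphere", "section", "roi"), drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force shared-position oracle: per-position tally over animals
oracle_shared <- function(group_animals, threshold, min_animals) {
  tally <- new.env()
  for (a in group_animals) {
    pos <- unique(paste(a$section[a$count >= threshold],
                        a$roi[a$count >= threshold]))
    for (p in pos) assign(p, (if (exists(p, tally)) get(p, tally) else 0) + 1,
                          tally)
  }
  hits <- Filter(function(p) get(p, tally) >= min_animals, ls(tally))
  out <- do.call(rbind, lapply(hits, function(p) {
    v <- as.integer(strsplit(p, " ")[[1]])
    data.frame(section = v[1], roi = v[2])
  }))
  if (is.null(out)) data.frame(section = integer(0), roi = integer(0))
  else out[order(out$section, out$roi), , drop = FALSE]
}

# exhaustive Mann-Whitney U: count pairs where x beats y (ties half)
oracle_U <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# longhand one-way ANOVA from sums of squares
oracle_anova_F <- function(groups) {
  all <- unlist(groups)
  gm <- mean(all)
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2,
                     numeric(1)))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_b <- length(groups) - 1
  df_w <- length(all) - length(groups)
  (ss_b / df_b) / (ss_w / df_w)
}

# independent per-point Gaussian log-density QDA scorer
oracle_qda_scores <- function(x, mus, sigmas, priors) {
  t(apply(x, 1, function(p) {
    vapply(seq_along(mus), function(k) {
      d <- p - mus[[k]]
      -0.5 * determinant(sigmas[[k]], logarithm = TRUE)$modulus[1] -
        0.5 * drop(d %*% solve(sigmas[[k]]) %*% d) + log(priors[k])
    }, numeric(1))
  }))
}

# small synthetic cohort config for fast tests
fast_config <- function(seed, ...) {
  synthetic_config(n_per_group = c(control = 4L, massed = 3L,
                                   distributed = 3L), seed = seed, ...)
}
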