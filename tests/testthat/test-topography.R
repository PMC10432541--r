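test_that("mean count matrix averages animals and hemispheres", {
  grid <- build_canonical_grid()
  all1 <- grid_coordinates(grid)
  rows <- cbind(data.frame(animal_id = "a1", group = "control"), all1,
                count = 7L)
  coh <- fos_cohort(rows)
  m <- mean_count_matrix(coh, "control")
  expect_true(all(m$mean[!is.na(m$mean)] == 7))
  expect_true(is.na(m$mean[1, 9]))      # off-grid cell (anterior, roi 9)

  # two animals, counts 4 and 10 at one cell -> 7
  rows2 <- rbind(toy_animal(1, 1, 4, animal_id = "a1"),
                 toy_animal(1, 1, 10, animal_id = "a2"))
  m2 <- mean_count_matrix(fos_cohort(rows2), "control")
  expect_equal(m2$mean[1, 1], 7)
  expect_equal(m2$n[1, 1], 2L)
  # hemispheres averaged within animal before the cross-animal mean
  rows3 <- rbind(toy_animal(1, 1, 10, hemisphere = "H1"),
                 toy_animal(1, 1, 20, hemisphere = "H2"))
  expect_equal(mean_count_matrix(fos_cohort(rows3), "control")$mean[1, 1], 15)
  expect_error(mean_count_matrix(fos_cohort(rows2), "massed"), "no animals")
})

test_that("subregion means exclude missing ROIs from the denominator", {
  grid <- build_canonical_grid(); scheme <- default_subregion_scheme()
  coords <- grid_coordinates(grid, "H1")
  pd <- coords[assign_subregion(coords, grid, scheme) == "PD", ]
  rows <- cbind(data.frame(animal_id = "a1", group = "control"), pd,
                count = 30L)
  sm <- subregion_means(fos_cohort(rows))
  expect_equal(sm$PD, 30)
  expect_true(is.na(sm$AD))             # unsampled subregion absent, not 0
  # half the PD ROIs missing: mean still 30
  sm2 <- subregion_means(fos_cohort(rows[1:8, ]))
  expect_equal(sm2$PD, 30)
})

test_that("subregion ANOVA matches a longhand sum-of-squares oracle", {
  build <- function(vals_by_group) {
    rows <- do.call(rbind, lapply(seq_along(vals_by_group), function(gi) {
      g <- names(vals_by_group)[gi]
      do.call(rbind, lapply(seq_along(vals_by_group[[gi]]), function(ai) {
        toy_animal(9, 1, vals_by_group[[gi]][ai],
                   animal_id = sprintf("%s_%d", g, ai), group = g)
      }))
    }))
    fos_cohort(rows)
  }
  groups <- list(control = c(2, 3, 4), massed = c(6, 7, 8),
                 distributed = c(2, 3, 4))
  a <- subregion_anova(build(groups), "PD")
  expect_equal(a$F, oracle_anova_F(groups), tolerance = 1e-10)
  expect_equal(a$df, c(2, 6))
  expect_equal(a$p, pf(oracle_anova_F(groups), 2, 6, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(nrow(a$tukey), 3L)
  expect_true(all(a$tukey$p_adj >= 0 & a$tukey$p_adj <= 1))

  # identical groups: F = 0, p = 1
  same <- list(control = c(10, 10.5, 11), massed = c(10, 10.5, 11),
               distributed = c(10, 10.5, 11))
  a0 <- subregion_anova(build(same), "PD")
  expect_equal(a0$F, 0, tolerance = 1e-12)
  expect_equal(a0$p, 1)
  expect_error(subregion_anova(build(list(control = c(1, 2), massed = 3)),
                               "PD"), "fewer than 2")
})

test_that("ANOVA F equals the longhand oracle on random small datasets", {
  set.seed(99)
  for (rep in 1:50) {
    groups <- list(control = rnorm(sample(3:6, 1), 10, 2),
                   massed = rnorm(sample(3:6, 1), 11, 2),
                   distributed = rnorm(sample(3:6, 1), 12, 2))
    rows <- do.call(rbind, lapply(names(groups), function(g) {
      do.call(rbind, lapply(seq_along(groups[[g]]), function(ai) {
        toy_animal(9, 1, round(groups[[g]][ai] * 10),
                   animal_id = sprintf("%s%d", g, ai), group = g)
      }))
    }))
    coh <- fos_cohort(rows)
    grp_counts <- lapply(split(coh$counts$count, coh$counts$group), identity)
    expect_equal(subregion_anova(coh, "PD")$F, oracle_anova_F(grp_counts),
                 tolerance = 1e-10)
  }
})

test_that("frequency histogram uses upper-inclusive bins and an overflow bin", {
  h <- frequency_histogram(toy_animal(rep(9, 4), 1:4, c(0, 10, 11, 100)))
  expect_equal(unname(h[c("0-10", "11-20", "91-100")]), c(50, 25, 25))
  expect_equal(sum(h), 100)
  h2 <- frequency_histogram(toy_animal(rep(9, 3), 1:3, c(45, 45, 45)))
  expect_equal(unname(h2["41-50"]), 100)
  expect_warning(h3 <- frequency_histogram(toy_animal(9, 1, 101)), "overflow")
  expect_equal(unname(h3[">100"]), 100)
})

test_that("frequency profiles sum to 100 for every simulated animal", {
  prof <- frequency_profiles(generate_cohort(fast_config(seed = 2)))
  sums <- rowSums(prof[, !(names(prof) %in% c("animal_id", "group"))])
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("bin comparison reproduces the exhaustive Mann-Whitney U", {
  mk <- function(vals, g, id0) {
    do.call(rbind, lapply(seq_along(vals), function(i) {
      # one animal with vals[i]% of ROIs in the 41-50 bin: vals[i] of 100
      n_hi <- vals[i]
      counts <- c(rep(45L, n_hi), rep(5L, 100 - n_hi))
      coords <- grid_coordinates(build_canonical_grid())[1:100, ]
      cbind(data.frame(animal_id = paste0(id0, i), group = g), coords,
            count = counts)
    }))
  }
  coh <- fos_cohort(rbind(mk(c(1, 2, 3), "control", "c"),
                          mk(c(4, 5, 6), "distributed", "d")))
  res <- compare_bins(coh, "control", "distributed")
  row <- res[res$bin == "41-50", ]
  expect_equal(row$U, oracle_U(c(1, 2, 3), c(4, 5, 6)))  # 0: separation
  expect_equal(row$U, 0)
  # identical groups: U = nA*nB/2, flagged degenerate
  coh2 <- fos_cohort(rbind(mk(c(5, 5), "control", "c"),
                           mk(c(5, 5), "massed", "m")))
  res2 <- compare_bins(coh2, "control", "massed")
  expect_true(all(res2$U == 2))
  expect_true(all(res2$degenerate))
  # random case against the brute-force pair-counting oracle
  coh3 <- fos_cohort(rbind(mk(c(10, 20), "control", "c"),
                           mk(15, "massed", "m")))
  res3 <- compare_bins(coh3, "control", "massed")
  expect_equal(res3[res3$bin == "41-50", "U"], oracle_U(c(10, 20), 15))
})
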