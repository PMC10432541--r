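test_that("feature table flags, section tallies and neighbors are correct", {
  # all below threshold: every derived feature zero
  a <- toy_animal(c(5, 5), c(3, 4), c(10, 12))
  ft <- build_feature_table(fos_cohort(a), threshold = 23)
  expect_equal(nrow(ft), 2L)
  expect_true(all(ft$roi_above == 0 & ft$n_above_in_section == 0 &
                    ft$neighboring_above_both == 0))
  # one position with both hemispheres at 30: flag 1, count_both 30
  b <- rbind(toy_animal(5, 3, 30, hemisphere = "H1"),
             toy_animal(5, 3, 30, hemisphere = "H2"))
  ftb <- build_feature_table(fos_cohort(b), threshold = 23)
  expect_equal(ftb$roi_above, 1L)
  expect_equal(ftb$cell_count_both, 30)
  expect_equal(ftb$n_above_in_section, 1)
  # 3x3 above-threshold block: center has 8 adjacent above-threshold ROIs
  blk <- expand.grid(section = 5:7, roi = 3:5)
  cc <- toy_animal(blk$section, blk$roi, rep(40, 9))
  ftc <- build_feature_table(fos_cohort(cc), threshold = 23)
  center <- ftc[ftc$section_number == 6 & ftc$roi_number == 4, ]
  expect_equal(center$neighboring_above_h1, 8)
  corner <- ftc[ftc$section_number == 5 & ftc$roi_number == 3, ]
  expect_equal(corner$neighboring_above_h1, 3)
  expect_error(build_feature_table(fos_cohort(a[0, ])), "empty")
})

test_that("single-hemisphere records are completed or dropped per config", {
  rows <- rbind(toy_animal(5, 3, 30, hemisphere = "H1"),
                toy_animal(5, 4, 10, hemisphere = "H1"),
                toy_animal(5, 4, 20, hemisphere = "H2"))
  comp <- build_feature_table(fos_cohort(rows), threshold = 23)
  expect_equal(nrow(comp), 2L)
  expect_equal(comp$cell_count_h2[comp$roi_number == 3], 30)  # copied
  expect_false(any(is.na(as.matrix(comp[, -(1:2)]))))
  drop <- build_feature_table(fos_cohort(rows), threshold = 23,
                              incomplete = "drop")
  expect_equal(nrow(drop), 1L)
  expect_equal(drop$roi_number, 4L)
})

test_that("1-D two-class QDA puts the boundary midway between symmetric classes", {
  set.seed(61)
  x <- matrix(c(rnorm(400, -1), rnorm(400, 1)))
  y <- rep(c("a", "b"), each = 400)
  m <- qda_fit(x, y, lambda = 0, standardize = FALSE)
  s <- predict(m, matrix(seq(-3, 3, 0.25)), type = "score")
  crossing <- approx(s[, 1] - s[, 2], seq(-3, 3, 0.25), xout = 0)$y
  expect_lt(abs(crossing), 0.15)
  # perfectly separated data with tiny variance: training accuracy 1
  x2 <- matrix(c(rnorm(50, -5, 0.01), rnorm(50, 5, 0.01)))
  m2 <- qda_fit(x2, rep(c("a", "b"), each = 50), standardize = FALSE)
  expect_equal(mean(predict(m2, x2) == rep(c("a", "b"), each = 50)), 1)
})

test_that("QDA scores agree with an independent log-density oracle", {
  set.seed(62)
  for (rep in 1:10) {
    d <- sample(2:4, 1)
    n <- 60
    cls <- c("a", "b", "c")
    x <- do.call(rbind, lapply(1:3, function(k) {
      matrix(rnorm(n * d, mean = k), n, d) %*%
        (diag(d) + matrix(runif(d * d, -0.2, 0.2), d, d))
    }))
    y <- rep(cls, each = n)
    m <- qda_fit(x, y, lambda = 0, standardize = FALSE)
    mus <- lapply(cls, function(k) colMeans(x[y == k, , drop = FALSE]))
    sigmas <- lapply(cls, function(k) cov(x[y == k, , drop = FALSE]))
    xt <- matrix(rnorm(20 * d, 2), 20, d)
    want <- oracle_qda_scores(xt, mus, sigmas, priors = rep(1 / 3, 3))
    got <- predict(m, xt, type = "score")
    expect_equal(unname(got), unname(want), tolerance = 1e-10)
    expect_equal(as.character(predict(m, xt)),
                 cls[apply(want, 1, which.max)])
  }
})

test_that("equal class covariances reduce QDA to the closed-form LDA rule", {
  set.seed(63)
  d <- 3; n <- 80
  xa <- matrix(rnorm(n * d), n, d)
  shift <- c(1.5, -0.5, 2)
  xb <- xa + matrix(shift, n, d, byrow = TRUE)  # identical sample covariance
  x <- rbind(xa, xb); y <- rep(c("a", "b"), each = n)
  m <- qda_fit(x, y, lambda = 0, standardize = FALSE)
  xt <- matrix(rnorm(50 * d, 0.5), 50, d)
  s <- predict(m, xt, type = "score")
  mu_a <- colMeans(xa); mu_b <- colMeans(xb); sig <- cov(xa)
  w <- solve(sig, mu_b - mu_a)
  b0 <- -0.5 * drop((mu_b + mu_a) %*% w)
  lda_diff <- drop(xt %*% w) + b0       # log-odds of class b under shared cov
  expect_equal(unname(s[, 2] - s[, 1]), lda_diff, tolerance = 1e-8)
})

test_that("QDA matches MASS::qda posteriors on a Gaussian toy", {
  skip_if_not_installed("MASS")
  set.seed(64)
  x <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 2), 100, 2))
  y <- rep(c("a", "b"), each = 100)
  m <- qda_fit(x, y, lambda = 0, standardize = FALSE)
  ref <- MASS::qda(x, grouping = y)
  xt <- matrix(rnorm(60, 1), 30, 2)
  expect_equal(as.character(predict(m, xt)),
               as.character(predict(ref, xt)$class))
})

test_that("singular covariance without regularization is diagnosed", {
  x <- cbind(1:20, (1:20) * 2)          # exactly collinear
  y <- rep(c("a", "b"), 10)
  expect_error(qda_fit(x, y, lambda = 0, standardize = FALSE), "lambda")
  expect_silent(qda_fit(x, y, lambda = 1e-4, standardize = FALSE))
})

test_that("cross-validation is chance-level on permuted balanced labels", {
  set.seed(65)
  x <- matrix(rnorm(600), 200, 3)
  table <- data.frame(animal_id = sprintf("a%03d", 1:200),
                      section_number = 1L, roi_number = 1L,
                      group = rep(c("a", "b"), 100), x1 = x[, 1],
                      x2 = x[, 2], x3 = x[, 3])
  accs <- sapply(1:30, function(s) {
    t2 <- table; t2$group <- sample(t2$group)
    cross_validated_accuracy(t2, k = 10, seed = s,
                             features = c("x1", "x2", "x3"))$accuracy
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 0.5), 3 * se)
})

test_that("cross-validation is perfect on separable data and stable to row order", {
  tab <- data.frame(animal_id = sprintf("a%03d", 1:100),
                    section_number = 1L, roi_number = 1L,
                    group = rep(c("a", "b"), each = 50),
                    x1 = c(rnorm(50, -8, 0.1), rnorm(50, 8, 0.1)))
  cv <- cross_validated_accuracy(tab, k = 10, seed = 2, features = "x1")
  expect_equal(cv$accuracy, 1)
  shuf <- tab[sample(nrow(tab)), ]
  cv2 <- cross_validated_accuracy(shuf, k = 10, seed = 2, features = "x1")
  expect_identical(cv$per_fold, cv2$per_fold)
})

test_that("animal-grouped folds keep an animal's records together", {
  coh <- generate_cohort(synthetic_config(
    n_per_group = c(control = 4L, massed = 4L, distributed = 4L), seed = 66))
  ft <- build_feature_table(coh, threshold = 23)
  cv <- cross_validated_accuracy(ft, k = 4, seed = 1, grouping = "animal")
  expect_true(cv$accuracy >= 0 && cv$accuracy <= 1)
  expect_equal(cv$n_folds_used + length(cv$skipped), 4L)
})

test_that("Kruskal-Wallis importances are normalized and rank signal first", {
  set.seed(67)
  n <- 60
  tab <- data.frame(group = rep(c("a", "b", "c"), each = n),
                    signal = rep(c(0, 5, 10), each = n) + rnorm(3 * n, 0, 0.5),
                    noise1 = rnorm(3 * n), noise2 = rnorm(3 * n),
                    flat = 1)
  imp <- feature_importance(tab, features = c("signal", "noise1", "noise2",
                                              "flat"))
  expect_equal(sum(imp$importance), 1, tolerance = 1e-12)
  expect_true(all(imp$importance >= 0))
  expect_equal(imp$feature[1], "signal")
  expect_equal(imp$importance[imp$feature == "flat"], 0)
  # H agrees with stats::kruskal.test called directly
  expect_equal(imp$H[imp$feature == "signal"],
               unname(kruskal.test(tab$signal, factor(tab$group))$statistic))
})
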