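FEATURE_COLS <- c("section_number", "roi_number", "cell_count_h1",
                  "cell_count_h2", "cell_count_both", "roi_above",
                  "n_above_in_section", "neighboring_above_h1",
                  "neighboring_above_h2", "neighboring_above_both")

#' Build the per-ROI feature table for protocol classification
#'
#' One record per (animal, section, roi) position sampled in at least one
#' hemisphere, with ten features: the two grid coordinates
#' (`section_number`, `roi_number`); the per-hemisphere counts
#' (`cell_count_h1`, `cell_count_h2`) and their mean (`cell_count_both`);
#' the above-threshold flag of the pooled count (`roi_above`); the number of
#' above-threshold positions in the record's section (`n_above_in_section`);
#' and the number of above-threshold positions 8-adjacent (grid distance at
#' most sqrt(2)) to the record's position in each hemisphere
#' (`neighboring_above_h1`, `neighboring_above_h2`) and their mean
#' (`neighboring_above_both`).
#'
#' A position sampled in only one hemisphere is either completed by copying
#' the sampled hemisphere's count (`incomplete = "complete"`, default) or
#' dropped (`incomplete = "drop"`), so the table never contains missing
#' values.
#'
#' @param cohort a `fos_cohort`.
#' @param threshold activation threshold in cells per ROI (inclusive).
#' @param incomplete how to handle positions sampled in one hemisphere only.
#' @return data frame: `animal_id`, `group`, then the ten feature columns.
#' @export
build_feature_table <- function(cohort, threshold = 23L,
                                incomplete = c("complete", "drop")) {
  incomplete <- match.arg(incomplete)
  if (!nrow(cohort$counts)) stop("empty cohort")
  ns <- nrow(cohort$grid$sections)
  nr <- max(cohort$grid$sections$n_roi)
  recs <- lapply(split_animals(cohort), function(a) {
    h1 <- matrix(NA_real_, ns, nr); h2 <- matrix(NA_real_, ns, nr)
    a1 <- a[a$hemisphere == "H1", ]; a2 <- a[a$hemisphere == "H2", ]
    h1[cbind(a1$section, a1$roi)] <- a1$count
    h2[cbind(a2$section, a2$roi)] <- a2$count
    sampled <- !is.na(h1) | !is.na(h2)
    if (incomplete == "drop") {
      sampled <- !is.na(h1) & !is.na(h2)
    } else {
      fill1 <- is.na(h1) & sampled; h1[fill1] <- h2[fill1]
      fill2 <- is.na(h2) & sampled; h2[fill2] <- h1[fill2]
    }
    if (!any(sampled)) return(NULL)
    both <- (h1 + h2) / 2
    above <- sampled & !is.na(both) & both >= threshold
    above1 <- sampled & !is.na(h1) & h1 >= threshold
    above2 <- sampled & !is.na(h2) & h2 >= threshold
    # 8-neighborhood sums of the above-threshold indicators, self excluded
    nb_sum <- function(m) {
      z <- matrix(0, ns + 2L, nr + 2L)
      z[2:(ns + 1L), 2:(nr + 1L)] <- m
      acc <- matrix(0, ns, nr)
      for (ds in -1:1) for (dr in -1:1) {
        if (ds == 0 && dr == 0) next
        acc <- acc + z[(2:(ns + 1L)) + ds, (2:(nr + 1L)) + dr]
      }
      acc
    }
    nb1 <- nb_sum(above1 + 0); nb2 <- nb_sum(above2 + 0)
    idx <- which(sampled, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    data.frame(
      animal_id = a$animal_id[1], group = a$group[1],
      section_number = idx[, 1], roi_number = idx[, 2],
      cell_count_h1 = h1[idx], cell_count_h2 = h2[idx],
      cell_count_both = both[idx],
      roi_above = as.integer(above[idx]),
      n_above_in_section = rowSums(above)[idx[, 1]],
      neighboring_above_h1 = nb1[idx], neighboring_above_h2 = nb2[idx],
      neighboring_above_both = (nb1[idx] + nb2[idx]) / 2,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Fit a regularized quadratic discriminant classifier
#'
#' Gaussian class-conditional model with class-specific covariance matrices.
#' Class k is scored by the quadratic discriminant
#' `delta_k(x) = -log(det(S_k))/2 - (x-m_k)' S_k^{-1} (x-m_k)/2 + log(pi_k)`
#' with `S_k = Sigma_k + lambda * (tr(Sigma_k)/d) * I`; prediction is the
#' argmax, ties resolved in class-level order.
#'
#' @param x numeric matrix or data frame of features (records x features).
#' @param y class labels (coerced to factor).
#' @param lambda non-negative ridge regularization of the class covariances,
#'   scaled by the mean class variance.
#' @param standardize z-score each feature (using training mean and SD;
#'   constant features get SD 1) before fitting.
#' @param priors class prior probabilities (default: training proportions).
#' @return object of class `fos_qda`.
#' @export
qda_fit <- function(x, y, lambda = 1e-6, standardize = TRUE, priors = NULL) {
  x <- as.matrix(x); storage.mode(x) <- "double"
  y <- factor(y)
  if (nlevels(y) < 2) stop("need at least two classes")
  if (is.null(priors)) priors <- as.numeric(table(y)) / length(y)
  stopifnot(length(priors) == nlevels(y), abs(sum(priors) - 1) < 1e-8)
  center <- scl <- NULL
  if (standardize) {
    center <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0 | is.na(scl)] <- 1
    x <- scale(x, center = center, scale = scl)
  }
  d <- ncol(x)
  classes <- levels(y)
  fit <- lapply(classes, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    if (nrow(xc) < 2) stop("class '", cl, "' has fewer than 2 records")
    mu <- colMeans(xc)
    sigma <- stats::cov(xc)
    sigma <- sigma + lambda * (sum(diag(sigma)) / d) * diag(d)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (!is.null(ch) &&
        any(diag(ch) < sqrt(.Machine$double.eps) *
              sqrt(max(diag(sigma), 1e-300)))) {
      ch <- NULL                        # numerically singular
    }
    if (is.null(ch)) {
      stop("singular class covariance for '", cl,
           "'; increase `lambda` above 0")
    }
    list(mu = mu, chol = ch, logdet = 2 * sum(log(diag(ch))))
  })
  names(fit) <- classes
  structure(list(classes = classes, priors = stats::setNames(priors, classes),
                 fit = fit, lambda = lambda, center = center, scale = scl,
                 d = d, feature_names = colnames(x)),
            class = "fos_qda")
}

#' @export
print.fos_qda <- function(x, ...) {
  cat("Quadratic discriminant classifier:", length(x$classes), "classes (",
      paste(x$classes, collapse = ", "), "),", x$d, "features, lambda =",
      x$lambda, "\n")
  invisible(x)
}

#' Predict from a fitted quadratic discriminant classifier
#'
#' @param object a `fos_qda`.
#' @param newdata numeric matrix or data frame with the training features.
#' @param type `"class"` for labels, `"score"` for the matrix of
#'   per-class discriminant scores.
#' @param ... unused.
#' @return factor of predicted labels, or the score matrix.
#' @export
predict.fos_qda <- function(object, newdata, type = c("class", "score"),
                            ...) {
  type <- match.arg(type)
  x <- as.matrix(newdata); storage.mode(x) <- "double"
  if (!is.null(object$center)) {
    x <- scale(x, center = object$center, scale = object$scale)
  }
  scores <- vapply(object$classes, function(cl) {
    f <- object$fit[[cl]]
    z <- backsolve(f$chol, t(x) - f$mu, transpose = TRUE)
    -0.5 * f$logdet - 0.5 * colSums(z^2) + log(object$priors[[cl]])
  }, numeric(nrow(x)))
  scores <- matrix(scores, nrow = nrow(x),
                   dimnames = list(NULL, object$classes))
  if (type == "score") return(scores)
  pick <- apply(scores, 1, which.max)
  n_tied <- sum(apply(scores, 1, function(s) sum(s == max(s))) > 1)
  if (n_tied > 0) {
    message(n_tied, " tied record(s) resolved in class-level order")
  }
  factor(object$classes[pick], levels = object$classes)
}

#' Cross-validated classification accuracy
#'
#' k-fold cross-validation of the quadratic discriminant classifier on a
#' feature table. Folds are assigned deterministically from `seed` after
#' sorting records by their stable key (animal, section, roi), so the result
#' is invariant to the order of the input rows. With `grouping = "animal"`
#' all of an animal's records share a fold (no animal-level leakage).
#'
#' @param table feature table from [build_feature_table()] (or any data
#'   frame with `group`, `animal_id` and feature columns).
#' @param k number of folds.
#' @param seed integer seed for the fold assignment.
#' @param grouping `"record"` (default) or `"animal"`.
#' @param lambda,standardize passed to [qda_fit()].
#' @param features feature column names.
#' @return list: `accuracy` (mean of per-fold held-out accuracies),
#'   `per_fold`, `n_folds_used`, `skipped` (folds lacking a class in
#'   training).
#' @export
cross_validated_accuracy <- function(table, k = 10L, seed = 1L,
                                     grouping = c("record", "animal"),
                                     lambda = 1e-6, standardize = TRUE,
                                     features = intersect(FEATURE_COLS,
                                                          names(table))) {
  grouping <- match.arg(grouping)
  ord <- order(table$animal_id, table$section_number, table$roi_number)
  table <- table[ord, , drop = FALSE]
  n <- nrow(table)
  if (grouping == "record") {
    if (n < k) stop("fewer records than folds")
    fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  } else {
    ids <- sort(unique(table$animal_id))
    if (length(ids) < k) stop("fewer animals than folds")
    af <- with_seed(seed, sample(rep_len(seq_len(k), length(ids))))
    fold <- af[match(table$animal_id, ids)]
  }
  y <- factor(table$group)
  x <- as.matrix(table[, features, drop = FALSE])
  per_fold <- rep(NA_real_, k); skipped <- integer(0)
  for (f in seq_len(k)) {
    tr <- fold != f
    if (length(unique(y[tr])) < nlevels(droplevels(y))) {
      warning("fold ", f, " skipped: a class is absent from training")
      skipped <- c(skipped, f)
      next
    }
    m <- qda_fit(x[tr, , drop = FALSE], droplevels(y[tr]), lambda = lambda,
                 standardize = standardize)
    pred <- suppressMessages(predict(m, x[!tr, , drop = FALSE]))
    per_fold[f] <- mean(as.character(pred) == as.character(y[!tr]))
  }
  list(accuracy = mean(per_fold, na.rm = TRUE), per_fold = per_fold,
       n_folds_used = sum(!is.na(per_fold)), skipped = skipped)
}

#' Kruskal-Wallis feature importance
#'
#' Per-feature Kruskal-Wallis H statistic across the class labels,
#' normalized to fractions of the total (scores are non-negative and sum to
#' one; a feature constant across records scores zero).
#'
#' @param table feature table with a `group` column.
#' @param features feature column names.
#' @return data frame `feature`, `H`, `importance`, sorted by descending
#'   importance.
#' @export
feature_importance <- function(table,
                               features = intersect(FEATURE_COLS,
                                                    names(table))) {
  y <- factor(table$group)
  if (nlevels(y) < 2) stop("need at least two classes")
  H <- vapply(features, function(f) {
    v <- table[[f]]
    if (length(unique(v)) == 1L) return(0)
    unname(stats::kruskal.test(v, y)$statistic)
  }, numeric(1))
  H[!is.finite(H)] <- 0
  total <- sum(H)
  imp <- if (total > 0) H / total else rep(0, length(H))
  out <- data.frame(feature = features, H = unname(H),
                    importance = unname(imp))
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  out
}
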