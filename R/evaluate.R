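#' Repeated stratified k-fold cross-validation
#'
#' Reproduces the offline evaluation protocol: the samples are randomly
#' partitioned into `k` folds (stratified by class, so the default 240-trial
#' dataset keeps 6 test trials per class in every fold), each fold is tested
#' on a classifier fitted to the other `k - 1` folds, and the whole
#' partitioning is repeated `repeats` times with fresh random splits --
#' 40 folds in total at the defaults (k = 10, 4 repeats). Standardization
#' statistics are fitted inside each training split only, so no information
#' leaks from the test fold.
#'
#' @param features Numeric matrix, samples x features.
#' @param labels Character vector of action labels.
#' @param k Number of folds (default 10).
#' @param repeats Number of independent re-partitions (default 4).
#' @param optimizer Passed to [fit_classifier()].
#' @param config `training_config` for every fold's fit.
#' @param hidden Hidden-layer width.
#' @param seed Integer seed controlling the partitions and every fold's
#'   weight initialization.
#' @return Object of class `facemyo_cv`: `folds` (data frame: repeat, fold,
#'   accuracy %, n_test, train mean of the first feature -- kept so
#'   leakage-freedom is checkable), `mean`/`sd` accuracy in percent,
#'   `confusion` (true x predicted counts over all folds), `per_class`
#'   accuracy %, and `assignments` (samples x repeats fold ids).
#' @export
repeated_kfold <- function(features, labels, k = 10, repeats = 4,
                           optimizer = c("lmbp", "adam"),
                           config = training_config(max_epochs = 100),
                           hidden = 16, seed = 1) {
  optimizer <- match.arg(optimizer)
  n <- nrow(features)
  stopifnot(n == length(labels))
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))
  classes <- sort(unique(labels))
  acts <- action_classes()
  cm_levels <- if (all(classes %in% acts)) acts else classes
  confusion <- matrix(0L, length(cm_levels), length(cm_levels),
                      dimnames = list(true = cm_levels, predicted = cm_levels))
  folds <- list()
  assignments <- matrix(NA_integer_, n, repeats)
  for (r in seq_len(repeats)) {
    fold_id <- integer(n)
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      fold_id[idx] <- rep_len(seq_len(k), length(idx))
    }
    assignments[, r] <- fold_id
    for (f in seq_len(k)) {
      test <- which(fold_id == f)
      train <- which(fold_id != f)
      clf <- fit_classifier(features[train, , drop = FALSE], labels[train],
                            optimizer = optimizer, hidden = hidden,
                            config = config,
                            seed = sample.int(.Machine$integer.max, 1))
      pred <- predict(clf, features[test, , drop = FALSE])
      acc <- 100 * mean(pred == labels[test])
      for (i in seq_along(test)) {
        confusion[labels[test[i]], pred[i]] <-
          confusion[labels[test[i]], pred[i]] + 1L
      }
      folds[[length(folds) + 1L]] <- data.frame(
        repeat_id = r, fold = f, accuracy = acc, n_test = length(test),
        train_mean_f1 = clf$standardizer$mean[[1]])
    }
  }
  folds <- do.call(rbind, folds)
  per_class <- 100 * diag(confusion) / pmax(rowSums(confusion), 1)
  structure(
    list(folds = folds, mean = mean(folds$accuracy),
         sd = stats::sd(folds$accuracy), confusion = confusion,
         per_class = per_class, assignments = assignments,
         k = k, repeats = repeats, optimizer = optimizer, seed = seed),
    class = "facemyo_cv"
  )
}

#' @export
print.facemyo_cv <- function(x, ...) {
  cat(sprintf("<facemyo_cv> %s: %.2f +/- %.2f%% over %d folds (k = %d x %d repeats)\n",
              x$optimizer, x$mean, x$sd, nrow(x$folds), x$k, x$repeats))
  invisible(x)
}

#' Regression performance of a trained model
#'
#' Pearson correlation between the concatenated continuous network outputs
#' and the encoded targets, the scalar summary used to report training/test
#' regression quality.
#'
#' @param outputs Numeric matrix or vector of network outputs.
#' @param targets Targets of the same shape.
#' @return Correlation coefficient R.
#' @export
regression_performance <- function(outputs, targets) {
  o <- as.vector(as.matrix(outputs))
  t <- as.vector(as.matrix(targets))
  if (length(o) != length(t)) stop("lengths differ", call. = FALSE)
  if (stats::sd(o) == 0 || stats::sd(t) == 0) {
    stop("regression performance undefined: zero variance", call. = FALSE)
  }
  stats::cor(o, t)
}

#' Paired t test on matched accuracy vectors
#'
#' Classical two-sided paired Student t test, used to compare two methods
#' (e.g. FFT vs WT features) across matched units such as subjects or folds.
#' Degenerate inputs are handled explicitly: identical vectors give
#' `t = 0, p = 1`; a constant nonzero difference gives `t = +/-Inf, p = 0`.
#'
#' @param acc_a,acc_b Equal-length numeric vectors, paired by position.
#' @return List with `t`, `p`, `df` and the mean difference.
#' @export
paired_t_test <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) stop("unequal lengths", call. = FALSE)
  if (length(acc_a) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- acc_a - acc_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, df = length(d) - 1, mean_diff = 0))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, df = length(d) - 1,
                mean_diff = mean(d)))
  }
  ht <- stats::t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_diff = mean(d))
}

#' One-way ANOVA across groups
#'
#' Standard one-way fixed-effects F test (equal-variance), used e.g. to test
#' whether session accuracies drift over the experiment. When every
#' observation is identical the F statistic is undefined (0/0); by
#' convention this returns `F = 0, p = 1` (no evidence of any difference).
#'
#' @param groups List of numeric vectors, one per group (>= 2 groups, each
#'   with >= 2 observations).
#' @return List with `F`, `p`, and the degrees of freedom `df1`, `df2`.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of at least two groups", call. = FALSE)
  }
  if (any(vapply(groups, length, 0L) < 2)) {
    stop("every group needs at least 2 observations", call. = FALSE)
  }
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  df1 <- length(groups) - 1
  df2 <- length(y) - length(groups)
  if (stats::sd(y) == 0) {
    return(list(F = 0, p = 1, df1 = df1, df2 = df2))
  }
  ht <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic), p = ht$p.value,
       df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]))
}
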