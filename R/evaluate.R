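# Train/test splitting, centroid readout on the selected sensors'
# non-standardized first-spike features, and replicate accuracy statistics.

#' Stratified train/test split
#'
#' Splits observations into disjoint train and test sets, stratified by
#' class, deterministic given the seed. With the default 1,500 observations
#' and 90% training fraction this gives 1,350 training and 150 test points.
#'
#' @param features A labelled `spike_features`.
#' @param train_frac Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test`, both `spike_features`.
#' @export
split_data <- function(features, train_frac = 0.9, seed = 1) {
  if (is.null(features$label)) abort("features must carry class labels")
  if (!(train_frac > 0 && train_frac < 1)) {
    abort("train_frac must be strictly between 0 and 1 (both splits must be non-empty)")
  }
  y <- features$label
  test_idx <- with_seed(seed, {
    unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      n_test <- round((1 - train_frac) * length(idx))
      if (n_test < 1 || n_test >= length(idx)) {
        abort(sprintf("class '%s' would be absent from one of the splits", cl))
      }
      sample(idx, n_test)
    }))
  })
  test_idx <- sort(test_idx)
  list(train = subset_features(features, setdiff(seq_along(y), test_idx)),
       test = subset_features(features, test_idx))
}

subset_features <- function(sf, rows) {
  out <- sf
  out$features <- sf$features[rows, , drop = FALSE]
  if (!is.null(sf$label)) out$label <- droplevels(sf$label[rows])
  out$wingbeat <- sf$wingbeat[rows]
  out$rep <- sf$rep[rows]
  out
}

#' Fit the spike-timing readout and score held-out accuracy
#'
#' Fits an LDA projection on the training split restricted to the selected
#' sensors, using the original (non-standardized) first-spike features. For
#' two classes the decision boundary is the midpoint of the two projected
#' class centroids; for more classes, points are assigned to the nearest
#' projected centroid. Returns accuracy on the test split.
#'
#' @param train,test `spike_features` from [split_data()].
#' @param sensors Integer indices of the selected sensor locations.
#' @param rule `"midpoint"` (two-class) or `"nearest_centroid"`; chosen
#'   automatically by default.
#' @return An `accuracy_result`: accuracy, test size, confusion matrix,
#'   fitted projection.
#' @export
fit_and_score <- function(train, test, sensors,
                          rule = c("auto", "midpoint", "nearest_centroid")) {
  rule <- match.arg(rule)
  stopifnot(length(sensors) >= 1)
  ytr <- droplevels(train$label); yte <- test$label
  classes <- levels(ytr)
  if (rule == "auto") rule <- if (length(classes) == 2) "midpoint" else "nearest_centroid"
  Xtr <- train$features[, sensors, drop = FALSE]
  Xte <- test$features[, sensors, drop = FALSE]

  ld <- lda_directions(Xtr, ytr, ridge = 1e-6)
  W <- ld$W
  Ztr <- Xtr %*% W; Zte <- Xte %*% W
  centroids <- t(sapply(classes, function(cl) colMeans(Ztr[ytr == cl, , drop = FALSE])))
  if (ncol(W) == 1) centroids <- matrix(centroids, ncol = 1)

  if (rule == "midpoint") {
    thr <- mean(centroids[, 1])
    sgn <- if (centroids[1, 1] >= thr) 1 else -1
    pred <- ifelse(sgn * (Zte[, 1] - thr) >= 0, classes[1], classes[2])
  } else {
    d2 <- sapply(seq_along(classes), function(i) {
      rowSums(sweep(Zte, 2, centroids[i, ])^2)
    })
    if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
    pred <- classes[max.col(-d2, ties.method = "first")]
  }
  pred <- factor(pred, levels = levels(yte))
  structure(
    list(accuracy = mean(pred == yte), n_test = length(yte),
         confusion = table(truth = yte, predicted = pred),
         rule = rule, sensors = sensors, projection = W,
         centroids = centroids),
    class = "accuracy_result")
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("<accuracy_result> %.1f%% on %d held-out observations (%s rule, %d sensors)\n",
              100 * x$accuracy, x$n_test, x$rule, length(x$sensors)))
  invisible(x)
}

#' @export
glance.accuracy_result <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, n_test = x$n_test,
                 n_sensors = length(x$sensors), rule = x$rule)
}

#' @export
tidy.accuracy_result <- function(x, ...) {
  as.data.frame(x$confusion) |>
    tibble::as_tibble() |>
    dplyr::rename(n = "Freq")
}

#' Replicate the full pipeline and summarize accuracy
#'
#' Repeats simulation, encoding, sensor selection and evaluation with fresh
#' seeds and reports per-replicate accuracies with their mean and standard
#' deviation (the replicate statistics shown as error bands on accuracy
#' curves).
#'
#' @param task A [detection_task()].
#' @param n_replicates Number of independent replicate data sets (>= 2).
#' @param seed Integer seed; replicate seeds are derived from it.
#' @return An `accuracy_replicates` tibble (one row per replicate) with
#'   `mean`/`sd` accessible via [glance()].
#' @export
replicate_accuracy <- function(task, n_replicates = 20, seed = 1) {
  if (n_replicates < 2) abort("n_replicates must be at least 2")
  seeds <- derive_seeds(seed, n_replicates)
  rows <- purrr::map2_dfr(seeds, seq_len(n_replicates), function(s, i) {
    r <- run_detection(task, seed = s)
    tibble::tibble(replicate = i, seed = s, accuracy = r$score$accuracy,
                   n_test = r$score$n_test,
                   mean_span_frac = r$mean_span_frac)
  })
  class(rows) <- c("accuracy_replicates", class(rows))
  rows
}

#' @export
glance.accuracy_replicates <- function(x, ...) {
  tibble::tibble(mean_accuracy = mean(x$accuracy), sd_accuracy = sd(x$accuracy),
                 n_replicates = nrow(x))
}

# Derive independent sub-seeds from one base seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
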