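#' @include AllClasses.R AllGenerics.R cnn.R
NULL

# Flatten a FeatureTensorSet (or epochs x 7 x 4 x L array) to n x (28 * L),
# cell-major within layer; this is the vector the KNN and SVM see and the
# cell layout the CNN indexes.
.flattenTensors <- function(tensors) {
  arr <- if (is(tensors, "FeatureTensorSet")) tensorData(tensors) else
    tensors
  stopIfNot(length(dim(arr)) == 4L, "expected an epochs x 7 x 4 x L array")
  matrix(arr, nrow = dim(arr)[1])
}

.tensorLabels <- function(tensors, labels) {
  if (is.null(labels)) {
    stopIfNot(is(tensors, "FeatureTensorSet"),
              "labels are required when tensors is a plain array")
    labels <- epochMeta(tensors)$group
  }
  factor(as.character(labels), levels = GROUP_LEVELS)
}

.checkTrainSet <- function(X, y) {
  stopIfNot(nrow(X) == length(y), "one label per tensor required")
  stopIfNot(!anyNA(y), "labels must be MDD or HC")
  if (length(unique(y)) < 2L) stop("training set contains a single class")
}

.fitScaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

.applyScaler <- function(X, center, scale) {
  sweep(sweep(X, 2, center), 2, scale, `/`)
}

.tensorLayerNames <- function(tensors) {
  if (is(tensors, "FeatureTensorSet")) layerNames(tensors) else
    as.character(seq_len(dim(tensors)[4]))
}

#' @describeIn fitClassifier KNN stores the (z-scored) training matrix and
#'   classifies by majority vote among the k nearest Euclidean neighbours.
setMethod("fitClassifier", "KNNConfig",
  function(config, tensors, labels = NULL, seed = 1L) {
    validObject(config)
    X <- .flattenTensors(tensors)
    y <- .tensorLabels(tensors, labels)
    .checkTrainSet(X, y)
    sc <- .fitScaler(X)
    new("KNNModel", x = .applyScaler(X, sc$center, sc$scale), y = y,
        k = config@k, center = sc$center, scale = sc$scale,
        layerNames = .tensorLayerNames(tensors),
        classLevels = levels(y))
  })

#' @describeIn fitClassifier SVM with polynomial kernel
#'   `(gamma * <u, v>)^degree` on z-scored flattened tensors (via e1071 /
#'   libsvm).
setMethod("fitClassifier", "SVMConfig",
  function(config, tensors, labels = NULL, seed = 1L) {
    validObject(config)
    X <- .flattenTensors(tensors)
    y <- .tensorLabels(tensors, labels)
    .checkTrainSet(X, y)
    sc <- .fitScaler(X)
    fit <- e1071::svm(.applyScaler(X, sc$center, sc$scale), y,
                      kernel = "polynomial", degree = config@degree,
                      gamma = config@gamma, coef0 = 0,
                      cost = config@cost, scale = FALSE)
    new("SVMModel", fit = fit, center = sc$center, scale = sc$scale,
        layerNames = .tensorLayerNames(tensors), classLevels = levels(y))
  })

#' @describeIn fitClassifier trains the small convolutional network on the
#'   raw (unstandardized) 7 x 4 x L tensors; deterministic given `seed`.
setMethod("fitClassifier", "CNNConfig",
  function(config, tensors, labels = NULL, seed = 1L) {
    validObject(config)
    X <- .flattenTensors(tensors)
    y <- .tensorLabels(tensors, labels)
    .checkTrainSet(X, y)
    trained <- .cnnTrain(X, y, config, seed)
    new("CNNModel", weights = trained$weights, config = config,
        flattenLength = as.integer(trained$flattenLength),
        inputDepth = as.integer(trained$inputDepth),
        layerNames = .tensorLayerNames(tensors),
        classLevels = trained$classLevels)
  })

.checkPredictShape <- function(model, X) {
  p <- length(model@layerNames) * 28L
  stopIfNot(ncol(X) == p,
            "tensor shape does not match the training tensors")
}

#' @describeIn predictLabels majority vote of the k nearest training
#'   exemplars.
setMethod("predictLabels", "KNNModel", function(model, tensors) {
  X <- .applyScaler(.flattenTensors(tensors), model@center, model@scale)
  .checkPredictShape(model, X)
  class::knn(model@x, X, model@y, k = model@k)
})

#' @describeIn predictLabels decision-function sign of the polynomial SVM.
setMethod("predictLabels", "SVMModel", function(model, tensors) {
  X <- .applyScaler(.flattenTensors(tensors), model@center, model@scale)
  .checkPredictShape(model, X)
  stats::predict(model@fit, X)
})

#' @describeIn predictLabels softmax argmax with dropout disabled.
setMethod("predictLabels", "CNNModel", function(model, tensors) {
  X <- .flattenTensors(tensors)
  .checkPredictShape(model, X)
  .cnnPredict(model, X)
})

#' Classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/(TP+FN+TN+FP)`, sensitivity `TP/(TP+FN)` (the MDD
#' recall), specificity `TN/(TN+FP)` (the HC recall) and F1
#' `2TP/(2TP+FP+FN)`. A metric whose denominator is zero is undefined and
#' returned as `NA` with a warning rather than silently 0.
#'
#' @param tp,tn,fp,fn non-negative confusion counts with MDD as the
#'   positive class.
#' @param warn warn on undefined metrics (default TRUE).
#' @return named numeric: `accuracy`, `sensitivity`, `specificity`, `f1`.
#' @examples
#' computeMetrics(tp = 3, tn = 2, fp = 1, fn = 1)
#' @export
computeMetrics <- function(tp, tn, fp, fn, warn = TRUE) {
  stopIfNot(all(c(tp, tn, fp, fn) >= 0), "counts must be non-negative")
  safe <- function(num, den, what) {
    if (den == 0) {
      if (warn) warning(what, " undefined: zero denominator")
      return(NA_real_)
    }
    num / den
  }
  c(accuracy = safe(tp + tn, tp + fn + tn + fp, "accuracy"),
    sensitivity = safe(tp, tp + fn, "sensitivity"),
    specificity = safe(tn, tn + fp, "specificity"),
    f1 = safe(2 * tp, 2 * tp + fp + fn, "f1"))
}

.confusion <- function(truth, pred) {
  c(tp = sum(truth == "MDD" & pred == "MDD"),
    tn = sum(truth == "HC" & pred == "HC"),
    fp = sum(truth == "HC" & pred == "MDD"),
    fn = sum(truth == "MDD" & pred == "HC"))
}

.subsetTensorSet <- function(tensors, idx) {
  if (is(tensors, "FeatureTensorSet")) {
    new("FeatureTensorSet",
        data = tensors@data[idx, , , , drop = FALSE],
        layerNames = tensors@layerNames,
        meta = tensors@meta[idx, , drop = FALSE],
        kind = tensors@kind)
  } else {
    tensors[idx, , , , drop = FALSE]
  }
}

# Shuffled fold assignment; sizes differ by at most one. For subject-level
# splits, subjects are shuffled within each group and dealt round-robin so
# every fold sees both classes where possible.
.foldAssignment <- function(labels, meta, folds, splitUnit) {
  n <- length(labels)
  if (splitUnit == "epoch") {
    return(sample(rep(seq_len(folds), length.out = n)))
  }
  sub <- meta$subjectId
  fold <- integer(n)
  counter <- 0L
  for (g in unique(as.character(labels))) {
    subs <- sample(unique(sub[labels == g]))
    for (s in subs) {
      counter <- counter + 1L
      fold[sub == s] <- (counter - 1L) %% folds + 1L
    }
  }
  fold
}

#' Repeated shuffled k-fold cross-validation
#'
#' Shuffles the epochs, partitions them into `folds` groups (sizes
#' differing by at most one), trains on `folds - 1` groups and evaluates
#' confusion counts on the held-out group, rotating over all folds; the
#' whole scheme is repeated `repeats` times with fresh shuffles. Seeds
#' for shuffling and model initialization are derived deterministically
#' from `seed`, so identical inputs give identical results.
#'
#' `splitUnit = "epoch"` splits at the epoch level, so epochs of one
#' subject can appear in both training and test folds — this mirrors how
#' pooled-epoch classification studies are usually evaluated, but it is
#' optimistic about generalization to new subjects. `"subject"` keeps all
#' epochs of a subject in one fold and is the recommended hygiene mode.
#'
#' @param tensors a [FeatureTensorSet-class].
#' @param config a classifier configuration ([knnConfig()], [svmConfig()]
#'   or [cnnConfig()]).
#' @param labels optional factor of labels (defaults to tensor metadata).
#' @param folds fold count (default 10).
#' @param repeats repetitions of the whole scheme (default 10).
#' @param seed integer pipeline seed.
#' @param splitUnit `"epoch"` or `"subject"`.
#' @return a [CVResult-class].
#' @export
crossValidate <- function(tensors, config, labels = NULL, folds = 10L,
                          repeats = 10L, seed = 1L,
                          splitUnit = c("epoch", "subject")) {
  splitUnit <- match.arg(splitUnit)
  y <- .tensorLabels(tensors, labels)
  n <- length(y)
  stopIfNot(n >= folds, "fewer samples than folds")
  meta <- if (is(tensors, "FeatureTensorSet")) epochMeta(tensors) else
    data.frame(subjectId = as.character(seq_len(n)))

  rows <- vector("list", repeats * folds)
  k <- 0L
  for (r in seq_len(repeats)) {
    repSeed <- as.integer(seed) + 1009L * r
    fold <- withSeed(repSeed, .foldAssignment(y, meta, folds, splitUnit))
    for (f in seq_len(folds)) {
      test <- which(fold == f)
      train <- which(fold != f)
      if (length(unique(y[train])) < 2L) {
        stop("training portion of a fold lacks one class; ",
             "use more data or fewer folds")
      }
      model <- fitClassifier(config, .subsetTensorSet(tensors, train),
                             labels = y[train], seed = repSeed + f)
      pred <- predictLabels(model, .subsetTensorSet(tensors, test))
      cf <- .confusion(y[test], pred)
      met <- computeMetrics(cf[["tp"]], cf[["tn"]], cf[["fp"]], cf[["fn"]],
                            warn = FALSE)
      k <- k + 1L
      rows[[k]] <- data.frame(repeat. = r, fold = f, tp = cf[["tp"]],
                              tn = cf[["tn"]], fp = cf[["fp"]],
                              fn = cf[["fn"]],
                              accuracy = met[["accuracy"]],
                              sensitivity = met[["sensitivity"]],
                              specificity = met[["specificity"]],
                              f1 = met[["f1"]])
    }
  }
  new("CVResult", table = do.call(rbind, rows), folds = as.integer(folds),
      repeats = as.integer(repeats), splitUnit = splitUnit)
}

#' @rdname accessors
setMethod("cvSummary", "CVResult", function(object) {
  t <- object@table
  mets <- c("accuracy", "sensitivity", "specificity", "f1")
  data.frame(
    metric = mets,
    mean = vapply(mets, function(m) mean(t[[m]], na.rm = TRUE), numeric(1)),
    se = vapply(mets, function(m) {
      v <- t[[m]][!is.na(t[[m]])]
      stats::sd(v) / sqrt(length(v))
    }, numeric(1)),
    row.names = NULL
  )
})

#' Export a cross-validation result as tab-separated text
#'
#' One row per metric with its mean and standard error, prefixed by the
#' classifier, feature kind and epoch window so several runs can be
#' concatenated into one results table.
#'
#' @param result a [CVResult-class].
#' @param classifier,feature,window descriptive columns.
#' @return data.frame (also usable without writing).
#' @param path optional output path; appends when the file exists.
#' @export
cvResultRow <- function(result, classifier = "", feature = "",
                        window = NA_real_, path = NULL) {
  s <- cvSummary(result)
  row <- data.frame(classifier = classifier, feature = feature,
                    window_s = window,
                    acc = s$mean[s$metric == "accuracy"],
                    sen = s$mean[s$metric == "sensitivity"],
                    spe = s$mean[s$metric == "specificity"],
                    f1 = s$mean[s$metric == "f1"],
                    acc_se = s$se[s$metric == "accuracy"])
  if (!is.null(path)) {
    utils::write.table(row, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = !file.exists(path),
                       append = file.exists(path))
  }
  row
}
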