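#' @import methods
NULL

GROUP_LEVELS <- c("HC", "MDD")

#' Multi-channel EEG recording
#'
#' Container for one subject's continuous EEG: a channels-by-samples matrix
#' in microvolts, the sampling rate, ordered 10-20 channel labels, and
#' subject metadata (identifier, diagnostic group, reference scheme).
#'
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot sampleRate sampling rate in Hz.
#' @slot channelLabels character vector, one unique 10-20 label per row of
#'   `data`.
#' @slot subjectId subject identifier.
#' @slot group diagnostic group, one of `"MDD"`, `"HC"`, `"unknown"`.
#' @slot reference free-text description of the reference scheme.
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    sampleRate = "numeric",
    channelLabels = "character",
    subjectId = "character",
    group = "character",
    reference = "character"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) {
    msg <- c(msg, "data must be a numeric matrix")
  }
  if (anyDuplicated(object@channelLabels)) {
    msg <- c(msg, "channel labels must be unique")
  }
  if (nrow(object@data) != length(object@channelLabels)) {
    msg <- c(msg, "data row count must equal number of channel labels")
  }
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0) {
    msg <- c(msg, "sampleRate must be a single positive number")
  }
  if (length(object@data) && !all(is.finite(object@data))) {
    msg <- c(msg, "all samples must be finite")
  }
  if (!object@group %in% c(GROUP_LEVELS, "unknown")) {
    msg <- c(msg, "group must be one of MDD, HC, unknown")
  }
  if (length(msg)) msg else TRUE
})

#' Constructor for [EEGRecording-class]
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param sampleRate sampling rate, Hz.
#' @param channelLabels character vector of 10-20 channel names.
#' @param subjectId subject identifier.
#' @param group `"MDD"`, `"HC"` or `"unknown"`.
#' @param reference description of the reference scheme.
#' @return An [EEGRecording-class] object.
#' @export
EEGRecording <- function(data, sampleRate, channelLabels,
                         subjectId = "anonymous", group = "unknown",
                         reference = "unknown") {
  rownames(data) <- channelLabels
  new("EEGRecording",
    data = data, sampleRate = as.numeric(sampleRate),
    channelLabels = as.character(channelLabels),
    subjectId = as.character(subjectId), group = as.character(group),
    reference = as.character(reference)
  )
}

#' Registry of symmetric electrode pairs
#'
#' The ordered list of 28 left/right mirror electrode pairs, each tagged
#' with a scalp region and its cell in the 7 x 4 spatial grid used for the
#' feature tensors. The (row, col) assignments are a bijection onto the
#' grid, so every pair owns exactly one tensor cell.
#'
#' @slot entries data.frame with columns `left`, `right`, `region`, `row`
#'   (0-6), `col` (0-3).
#' @export
setClass("PairRegistry", representation(entries = "data.frame"))

setValidity("PairRegistry", function(object) {
  e <- object@entries
  msg <- character()
  need <- c("left", "right", "region", "row", "col")
  if (!all(need %in% names(e))) {
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(e) != 28L) msg <- c(msg, "registry must have exactly 28 pairs")
  if (any(e$row < 0 | e$row > 6 | e$col < 0 | e$col > 3)) {
    msg <- c(msg, "row must be in 0..6 and col in 0..3")
  }
  cell <- e$row * 4 + e$col
  if (anyDuplicated(cell)) {
    msg <- c(msg, "(row, col) cells must be a bijection onto the 7x4 grid")
  }
  labs <- c(e$left, e$right)
  if (anyDuplicated(labs)) {
    msg <- c(msg, "each electrode may appear in at most one pair")
  }
  if (any(e$left == e$right)) {
    msg <- c(msg, "left and right labels must differ")
  }
  regions <- c("frontal", "temporal", "central", "parietal", "occipital")
  if (!all(e$region %in% regions)) {
    msg <- c(msg, "unknown region tag")
  }
  if (nrow(e) == 28L && !all(regions %in% e$region)) {
    msg <- c(msg, "all five scalp regions must be represented")
  }
  if (length(msg)) msg else TRUE
})

#' A frequency band
#'
#' @slot name band name ("theta", "alpha", "beta").
#' @slot low lower edge, Hz (inclusive).
#' @slot high upper edge, Hz (exclusive unless `closedUpper`).
#' @slot closedUpper whether the upper edge is included; TRUE only for the
#'   default beta band so its 40 Hz edge is kept.
#' @export
setClass("Band",
  representation(name = "character", low = "numeric", high = "numeric",
                 closedUpper = "logical")
)

setValidity("Band", function(object) {
  if (object@low >= object@high) "low must be < high" else TRUE
})

#' Construct a [Band-class]
#' @param name band name.
#' @param low,high band edges in Hz; the interval is `[low, high)` unless
#'   `closedUpper = TRUE`, in which case it is `[low, high]`.
#' @param closedUpper include the upper edge?
#' @return A [Band-class] object.
#' @export
band <- function(name, low, high, closedUpper = FALSE) {
  new("Band", name = name, low = low, high = high, closedUpper = closedUpper)
}

#' Set of non-overlapping fixed-length epochs
#'
#' Epochs cut from one or more recordings. Each epoch is a channels x
#' samples matrix carrying its subject id, group label and a per-subject
#' epoch index that is contiguous from 0.
#'
#' @slot epochs list of channels x samples matrices.
#' @slot subjectId,group,epochIndex per-epoch metadata vectors.
#' @slot durationS epoch duration in seconds.
#' @slot sampleRate sampling rate, Hz.
#' @slot channelLabels channel labels shared by all epochs.
#' @export
setClass("EpochSet",
  representation(
    epochs = "list",
    subjectId = "character",
    group = "character",
    epochIndex = "integer",
    durationS = "numeric",
    sampleRate = "numeric",
    channelLabels = "character"
  )
)

setValidity("EpochSet", function(object) {
  n <- length(object@epochs)
  msg <- character()
  if (length(object@subjectId) != n || length(object@group) != n ||
      length(object@epochIndex) != n) {
    msg <- c(msg, "metadata vectors must match the number of epochs")
  }
  len <- round(object@durationS * object@sampleRate)
  ok <- vapply(object@epochs, function(m) {
    is.matrix(m) && ncol(m) == len && nrow(m) == length(object@channelLabels)
  }, logical(1))
  if (n && !all(ok)) {
    msg <- c(msg, "every epoch must be channels x (durationS * sampleRate)")
  }
  # per-subject indices contiguous from 0
  if (n) {
    bySub <- split(object@epochIndex, object@subjectId)
    contig <- vapply(bySub, function(ix) {
      identical(sort(ix), seq_along(ix) - 1L)
    }, logical(1))
    if (!all(contig)) {
      msg <- c(msg, "epoch indices must be contiguous from 0 per subject")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic two-cohort EEG study
#'
#' Defines the generative model for synthetic resting-state EEG: per-band
#' narrowband oscillations shared (to a controllable degree) between
#' symmetric electrode pairs, a controllable left-right log-power asymmetry
#' per band, and a 1/f background. Two cohorts (MDD and HC) of configurable
#' size are produced.
#'
#' @slot nMdd,nHc cohort sizes (subjects).
#' @slot durationS recording length per subject, seconds.
#' @slot sampleRate sampling rate, Hz; must exceed twice the upper beta
#'   edge (40 Hz).
#' @slot bandAmp named numeric (theta/alpha/beta): per-band oscillation RMS
#'   amplitude, microvolts.
#' @slot asymDeltaMdd,asymDeltaHc named numeric per band: target left-right
#'   log-power difference (natural-log units) per group.
#' @slot couplingRhoMdd,couplingRhoHc named numeric per band in [0, 1]:
#'   fraction of source variance shared between the two electrodes of a
#'   symmetric pair.
#' @slot noiseSigma 1/f background RMS, microvolts.
#' @slot artifactRate blink-like transients per minute (0 disables them).
#' @slot seed integer base seed; per-subject seeds are `seed + subject index`.
#' @export
setClass("CohortSpec",
  representation(
    nMdd = "integer", nHc = "integer",
    durationS = "numeric", sampleRate = "numeric",
    bandAmp = "numeric",
    asymDeltaMdd = "numeric", asymDeltaHc = "numeric",
    couplingRhoMdd = "numeric", couplingRhoHc = "numeric",
    noiseSigma = "numeric", artifactRate = "numeric",
    seed = "integer"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  bn <- c("theta", "alpha", "beta")
  if (object@nMdd < 1L || object@nHc < 1L) {
    msg <- c(msg, "cohort sizes must be >= 1")
  }
  if (object@durationS <= 0) msg <- c(msg, "durationS must be positive")
  if (object@sampleRate <= 2 * 40) {
    msg <- c(msg, "sampleRate must exceed twice the beta upper edge (40 Hz)")
  }
  for (s in c("bandAmp", "asymDeltaMdd", "asymDeltaHc",
              "couplingRhoMdd", "couplingRhoHc")) {
    v <- slot(object, s)
    if (!all(bn %in% names(v))) {
      msg <- c(msg, paste(s, "must be named with theta, alpha, beta"))
    }
  }
  if (any(object@bandAmp <= 0)) msg <- c(msg, "bandAmp must be positive")
  if (any(object@couplingRhoMdd < 0 | object@couplingRhoMdd > 1) ||
      any(object@couplingRhoHc < 0 | object@couplingRhoHc > 1)) {
    msg <- c(msg, "coupling rho must lie in [0, 1]")
  }
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (object@artifactRate < 0) msg <- c(msg, "artifactRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' K-nearest-neighbour classifier configuration
#'
#' Euclidean-distance KNN with an odd neighbour count so binary votes
#' cannot tie (default k = 7). Inputs are flattened feature tensors,
#' z-scored with statistics fitted on the training fold only.
#'
#' @slot k neighbour count, odd, >= 1.
#' @export
setClass("KNNConfig", representation(k = "integer"))

setValidity("KNNConfig", function(object) {
  if (object@k < 1L || object@k %% 2L == 0L) "k must be odd and >= 1" else TRUE
})

#' Polynomial-kernel SVM configuration
#'
#' Kernel (gamma * <u, v>)^degree with degree 3 and gamma 2 by default.
#' `maxIterations` records the declared optimizer budget (30,000); the
#' underlying libsvm solver terminates on its convergence tolerance and
#' does not expose an iteration cap, so the value is configuration
#' metadata. Inputs are flattened tensors, z-scored on training folds.
#'
#' @slot degree polynomial degree.
#' @slot gamma kernel scale.
#' @slot maxIterations declared iteration budget.
#' @slot cost soft-margin constant C.
#' @export
setClass("SVMConfig",
  representation(degree = "integer", gamma = "numeric",
                 maxIterations = "integer", cost = "numeric")
)

setValidity("SVMConfig", function(object) {
  msg <- character()
  if (object@degree < 1L) msg <- c(msg, "degree must be >= 1")
  if (object@gamma <= 0) msg <- c(msg, "gamma must be positive")
  if (object@maxIterations < 1L) msg <- c(msg, "maxIterations must be positive")
  if (object@cost <= 0) msg <- c(msg, "cost must be positive")
  if (length(msg)) msg else TRUE
})

#' Small convolutional network configuration
#'
#' Architecture over a 7 x 4 x L input tensor: `nFilters` 2 x 2 x L
#' convolution kernels with shape-preserving padding and ReLU, 2 x 2 max
#' pooling at stride 1 (also shape-preserving), a flatten to
#' 7 * 4 * nFilters units (56 with the default two filters), dropout on
#' the flattened layer during training, and a dense softmax output over
#' the two classes. Trained with cross-entropy loss and Adam.
#'
#' @slot nFilters convolution filter count (default 2).
#' @slot dropoutRate probability of dropping a flattened unit in training.
#' @slot epochs training passes over the data.
#' @slot learningRate Adam step size.
#' @slot batchSize minibatch size.
#' @export
setClass("CNNConfig",
  representation(nFilters = "integer", dropoutRate = "numeric",
                 epochs = "integer", learningRate = "numeric",
                 batchSize = "integer")
)

setValidity("CNNConfig", function(object) {
  msg <- character()
  if (object@nFilters < 1L) msg <- c(msg, "nFilters must be >= 1")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1) {
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  }
  if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be positive")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname KNNConfig-class
#' @param k neighbour count (odd).
#' @return a [KNNConfig-class].
#' @export
knnConfig <- function(k = 7L) new("KNNConfig", k = as.integer(k))

#' @rdname SVMConfig-class
#' @param degree,gamma,maxIterations,cost see slots.
#' @return a [SVMConfig-class].
#' @export
svmConfig <- function(degree = 3L, gamma = 2, maxIterations = 30000L,
                      cost = 1) {
  new("SVMConfig", degree = as.integer(degree), gamma = gamma,
      maxIterations = as.integer(maxIterations), cost = cost)
}

#' @rdname CNNConfig-class
#' @param nFilters,dropoutRate,epochs,learningRate,batchSize see slots.
#' @return a [CNNConfig-class].
#' @export
cnnConfig <- function(nFilters = 2L, dropoutRate = 0.5, epochs = 30L,
                      learningRate = 1e-2, batchSize = 32L) {
  new("CNNConfig", nFilters = as.integer(nFilters),
      dropoutRate = dropoutRate, epochs = as.integer(epochs),
      learningRate = learningRate, batchSize = as.integer(batchSize))
}

#' Set of spatial feature tensors
#'
#' Stacked 7 x 4 x L feature tensors for a set of epochs, with layer names
#' and per-epoch provenance. L = 3 for single-feature tensors (layer order
#' alpha, beta, theta) and L = 6 for mixed tensors (alpha-MIX1, alpha-MIX2,
#' beta-MIX1, beta-MIX2, theta-MIX1, theta-MIX2).
#'
#' @slot data 4-d numeric array, epochs x 7 x 4 x L.
#' @slot layerNames names of the L layers.
#' @slot meta data.frame with columns subjectId, epochIndex, group.
#' @slot kind tensor kind: "single_asymmetry", "single_crosscorr" or "mixed".
#' @export
setClass("FeatureTensorSet",
  representation(data = "array", layerNames = "character",
                 meta = "data.frame", kind = "character")
)

setValidity("FeatureTensorSet", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 4L || d[2] != 7L || d[3] != 4L) {
    msg <- c(msg, "data must be an epochs x 7 x 4 x L array")
  }
  if (length(d) == 4L && d[4] != length(object@layerNames)) {
    msg <- c(msg, "layerNames must match the tensor depth")
  }
  if (nrow(object@meta) != d[1]) {
    msg <- c(msg, "meta must have one row per epoch")
  }
  if (length(msg)) msg else TRUE
})

#' Virtual parent of trained classifiers
#' @export
setClass("TrainedModel", representation("VIRTUAL",
  layerNames = "character", classLevels = "character"))

#' @rdname TrainedModel-class
#' @slot x,y stored training matrix and labels (KNN is lazy).
#' @slot k neighbour count.
#' @slot center,scale z-scoring statistics fitted on the training data.
#' @export
setClass("KNNModel", contains = "TrainedModel",
  representation(x = "matrix", y = "factor", k = "integer",
                 center = "numeric", scale = "numeric"))

#' @rdname TrainedModel-class
#' @slot fit the underlying e1071 svm fit.
#' @export
setClass("SVMModel", contains = "TrainedModel",
  representation(fit = "ANY", center = "numeric", scale = "numeric"))

#' @rdname TrainedModel-class
#' @slot weights list of network parameters.
#' @slot config the [CNNConfig-class] used.
#' @slot flattenLength length of the flattened layer (56 by default).
#' @export
setClass("CNNModel", contains = "TrainedModel",
  representation(weights = "list", config = "CNNConfig",
                 flattenLength = "integer", inputDepth = "integer"))

#' Repeated k-fold cross-validation result
#'
#' Per (repeat, fold) confusion counts (MDD positive) with derived
#' accuracy, sensitivity, specificity and F1; [cvSummary()] aggregates
#' means and standard errors over all repeat x fold cells.
#'
#' @slot table data.frame: repeat, fold, tp, tn, fp, fn plus the four
#'   metrics.
#' @slot folds,repeats the scheme.
#' @slot splitUnit "epoch" or "subject".
#' @export
setClass("CVResult",
  representation(table = "data.frame", folds = "integer",
                 repeats = "integer", splitUnit = "character")
)

setValidity("CVResult", function(object) {
  t <- object@table
  msg <- character()
  if (!all(c("repeat.", "fold", "tp", "tn", "fp", "fn") %in% names(t))) {
    msg <- c(msg, "table missing confusion columns")
  } else if (any(t$tp < 0 | t$tn < 0 | t$fp < 0 | t$fn < 0)) {
    msg <- c(msg, "confusion counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})
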