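#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param object an object of one of the package's classes.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(object) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("recordingData", function(object) standardGeneric("recordingData"))

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("groupLabel", function(object) standardGeneric("groupLabel"))

#' @rdname accessors
#' @export
setGeneric("registryEntries", function(object)
  standardGeneric("registryEntries"))

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(object) standardGeneric("nEpochs"))

#' @rdname accessors
#' @export
setGeneric("epochMeta", function(object) standardGeneric("epochMeta"))

#' @rdname accessors
#' @export
setGeneric("tensorData", function(object) standardGeneric("tensorData"))

#' @rdname accessors
#' @export
setGeneric("layerNames", function(object) standardGeneric("layerNames"))

#' Fit a classifier on feature tensors
#'
#' @param config a [KNNConfig-class], [SVMConfig-class] or
#'   [CNNConfig-class].
#' @param tensors a [FeatureTensorSet-class] (or an epochs x 7 x 4 x L
#'   array).
#' @param labels factor of group labels ("MDD"/"HC"), one per epoch;
#'   defaults to the tensor set's metadata.
#' @param seed integer seed controlling any stochastic part of training.
#' @return a [TrainedModel-class].
#' @export
setGeneric("fitClassifier", function(config, tensors, labels = NULL,
                                     seed = 1L)
  standardGeneric("fitClassifier"))

#' Predict group labels for feature tensors
#'
#' Deterministic at prediction time (dropout disabled for the CNN).
#'
#' @param model a [TrainedModel-class].
#' @param tensors a [FeatureTensorSet-class] or tensor array with the same
#'   shape as the training tensors.
#' @return factor of predicted labels.
#' @export
setGeneric("predictLabels", function(model, tensors)
  standardGeneric("predictLabels"))

#' @rdname accessors
#' @export
setGeneric("cvSummary", function(object) standardGeneric("cvSummary"))

## ---- accessor methods ----

#' @rdname accessors
setMethod("sampleRate", "EEGRecording", function(object) object@sampleRate)
#' @rdname accessors
setMethod("sampleRate", "EpochSet", function(object) object@sampleRate)
#' @rdname accessors
setMethod("channelLabels", "EEGRecording", function(object)
  object@channelLabels)
#' @rdname accessors
setMethod("channelLabels", "EpochSet", function(object) object@channelLabels)
#' @rdname accessors
setMethod("recordingData", "EEGRecording", function(object) object@data)
#' @rdname accessors
setMethod("subjectId", "EEGRecording", function(object) object@subjectId)
#' @rdname accessors
setMethod("groupLabel", "EEGRecording", function(object) object@group)
#' @rdname accessors
setMethod("registryEntries", "PairRegistry", function(object) object@entries)
#' @rdname accessors
setMethod("nEpochs", "EpochSet", function(object) length(object@epochs))
#' @rdname accessors
setMethod("nEpochs", "FeatureTensorSet", function(object)
  dim(object@data)[1])
#' @rdname accessors
setMethod("epochMeta", "EpochSet", function(object)
  data.frame(subjectId = object@subjectId, group = object@group,
             epochIndex = object@epochIndex, stringsAsFactors = FALSE))
#' @rdname accessors
setMethod("epochMeta", "FeatureTensorSet", function(object) object@meta)
#' @rdname accessors
setMethod("tensorData", "FeatureTensorSet", function(object) object@data)
#' @rdname accessors
setMethod("layerNames", "FeatureTensorSet", function(object)
  object@layerNames)

## ---- show methods ----

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf(
    "EEGRecording '%s' (%s): %d channels x %d samples @ %g Hz, ref %s\n",
    object@subjectId, object@group, nrow(object@data), ncol(object@data),
    object@sampleRate, object@reference))
})

setMethod("show", "PairRegistry", function(object) {
  cat(sprintf("PairRegistry: %d symmetric pairs on a 7x4 grid\n",
              nrow(object@entries)))
  tab <- table(object@entries$region)
  cat("  regions:", paste(sprintf("%s=%d", names(tab), tab),
                          collapse = ", "), "\n")
})

setMethod("show", "EpochSet", function(object) {
  cat(sprintf(
    "EpochSet: %d epochs of %gs (%d channels @ %g Hz), %d subject(s)\n",
    length(object@epochs), object@durationS, length(object@channelLabels),
    object@sampleRate, length(unique(object@subjectId))))
})

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf(
    "CohortSpec: %d MDD + %d HC, %gs @ %g Hz, seed %d\n",
    object@nMdd, object@nHc, object@durationS, object@sampleRate,
    object@seed))
  cat(sprintf("  asym delta (MDD): %s\n",
              paste(sprintf("%s=%g", names(object@asymDeltaMdd),
                            object@asymDeltaMdd), collapse = " ")))
})

setMethod("show", "FeatureTensorSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("FeatureTensorSet (%s): %d tensors of %d x %d x %d\n",
              object@kind, d[1], d[2], d[3], d[4]))
  cat("  layers:", paste(object@layerNames, collapse = ", "), "\n")
})

setMethod("show", "CVResult", function(object) {
  s <- cvSummary(object)
  cat(sprintf("CVResult: %d-fold x %d repeats (%s-level splits)\n",
              object@folds, object@repeats, object@splitUnit))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-11s %.4f (se %.4f)\n", s$metric[i], s$mean[i], s$se[i]))
  }
})
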