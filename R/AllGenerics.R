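#' @name accessors
#' @title Accessors for examEEG classes
#' @description Accessor generics for [Recording-class], [EpochSet-class],
#'   [FeatureTable-class] and [ModelFit-class] objects.
#' @param x an examEEG object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))
#' @rdname accessors
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))
#' @rdname accessors
#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))
#' @rdname accessors
#' @export
setGeneric("epochs", function(x) standardGeneric("epochs"))
#' @rdname accessors
#' @export
setGeneric("artifactMask", function(x) standardGeneric("artifactMask"))
#' @rdname accessors
#' @export
setGeneric("taskLabel", function(x) standardGeneric("taskLabel"))
#' @rdname accessors
#' @export
setGeneric("retainedEpochs", function(x) standardGeneric("retainedEpochs"))
#' @rdname accessors
#' @export
setGeneric("featureStage", function(x) standardGeneric("featureStage"))
#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @rdname accessors
#' @export
setMethod("channelLabels", "Recording", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("samplingRate", "Recording", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("signalData", "Recording", function(x) x@signal)
#' @rdname accessors
#' @export
setMethod("markers", "Recording", function(x) x@markers)
#' @rdname accessors
#' @export
setMethod("recordingDuration", "Recording",
          function(x) ncol(x@signal) / x@samplingRate)

#' @rdname accessors
#' @export
setMethod("channelLabels", "EpochSet", function(x) x@channelLabels)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@samplingRate)
#' @rdname accessors
#' @export
setMethod("epochs", "EpochSet", function(x) x@epochs)
#' @rdname accessors
#' @export
setMethod("artifactMask", "EpochSet", function(x) x@artifactMask)
#' @rdname accessors
#' @export
setMethod("taskLabel", "EpochSet", function(x) x@task)
#' @rdname accessors
#' @export
setMethod("retainedEpochs", "EpochSet",
          function(x) x@epochs[!x@artifactMask, , , drop = FALSE])

#' @rdname accessors
#' @export
setMethod("featureStage", "FeatureTable", function(x) metadata(x)$stage)

#' @rdname accessors
#' @export
setMethod("selectedFeatures", "ModelFit", function(x) x@selected)
#' @rdname accessors
#' @export
setMethod("rSquared", "ModelFit", function(x) x@r2)
#' @rdname accessors
#' @export
setMethod("coef", "ModelFit", function(object, ...) object@coefficients)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples (%.1f s @ %g Hz)\n",
              nrow(object@signal), ncol(object@signal),
              recordingDuration(object), object@samplingRate))
  cat("  channels:", paste(object@channelLabels, collapse = " "), "\n")
  if (nrow(object@markers))
    cat("  markers:",
        paste(sprintf("'%s'@%gs", object@markers$label, object@markers$onset),
              collapse = ", "), "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochSet '%s': %d epochs x %d channels x %d samples, %d masked\n",
              object@task, d[1], d[2], d[3], sum(object@artifactMask)))
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit for '%s': %d selected features, R^2 = %.3f, lambda = %.4g\n",
              object@outcome, length(object@selected), object@r2, object@lambda))
  if (nrow(object@coefficients)) print(object@coefficients, digits = 3)
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf("CohortConfig: %d per group @ %g Hz, %d segments (%g s total), %d designed effects, artifact rate %.2f, seed %d\n",
              object@nPerGroup, object@samplingRate, nrow(object@segmentPlan),
              sum(object@segmentPlan$duration), nrow(object@effectTable),
              object@artifactRate, object@seed))
})
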