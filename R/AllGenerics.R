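# Accessor generics and show() methods for the package's S4 classes.

#' Number of sensor channels
#' @param x a SensorRecording, WindowBatch or ModelSpec.
#' @return integer channel count D.
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' Number of time steps in a recording
#' @param x a SensorRecording.
#' @return integer sample count N.
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' Sample matrix of a recording
#' @param x a SensorRecording.
#' @return numeric matrix N x D.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' Sampling rate in Hz
#' @param x a SensorRecording.
#' @return numeric sample rate.
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' Per-channel modality tags
#' @param x a SensorRecording.
#' @return character vector of length D.
#' @export
setGeneric("modalityTags", function(x) standardGeneric("modalityTags"))

#' Channel names
#' @param x a SensorRecording.
#' @return character vector of length D.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' Number of windows in a batch
#' @param x a WindowBatch.
#' @return integer window count M.
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' Window length in samples
#' @param x a WindowBatch or ModelSpec.
#' @return integer S1.
#' @export
setGeneric("windowLength", function(x) standardGeneric("windowLength"))

#' Window sequences
#' @param x a WindowBatch.
#' @return numeric array D x S1 x M.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' Window start indices
#' @param x a WindowBatch.
#' @return integer vector of 1-based start indices.
#' @export
setGeneric("windowStarts", function(x) standardGeneric("windowStarts"))

#' Architecture specification of a model
#' @param x a HARModel.
#' @return the \linkS4class{ModelSpec}.
#' @export
setGeneric("spec", function(x) standardGeneric("spec"))

#' Layer parameter list of a model
#' @param x a HARModel.
#' @return list of per-layer parameter sets.
#' @export
setGeneric("modelLayers", function(x) standardGeneric("modelLayers"))

#' Shorthand architecture string
#'
#' E.g. "C(64)-C(64)-C(64)-C(64)-R(128)-R(128)-Sm" for the recurrent
#' variant and "...-D(128)-D(128)-Sm" for the baseline CNN.
#' @param x a ModelSpec or HARModel.
#' @return character shorthand.
#' @export
setGeneric("shorthand", function(x) standardGeneric("shorthand"))

#' Sample-weighted F1 of an evaluation
#' @param x an EvaluationReport.
#' @return numeric in [0, 1].
#' @export
setGeneric("weightedF1Score", function(x) standardGeneric("weightedF1Score"))

#' Confusion matrix of an evaluation
#' @param x an EvaluationReport.
#' @return integer matrix, rows = actual, columns = predicted.
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))

#' Per-class metric table of an evaluation
#' @param x an EvaluationReport.
#' @return data.frame with support, weight, precision, recall, F1 per class.
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))

## ---- SensorRecording ----

#' @describeIn SensorRecording channel count.
#' @param x a SensorRecording.
#' @export
setMethod("nChannels", "SensorRecording", function(x) ncol(x@samples))

#' @describeIn SensorRecording time-step count.
#' @export
setMethod("nSamples", "SensorRecording", function(x) nrow(x@samples))

#' @describeIn SensorRecording sample matrix (N x D).
#' @export
setMethod("samples", "SensorRecording", function(x) x@samples)

#' @describeIn SensorRecording sampling rate in Hz.
#' @export
setMethod("sampleRate", "SensorRecording", function(x) x@sampleRate)

#' @describeIn SensorRecording per-channel modality tags.
#' @export
setMethod("modalityTags", "SensorRecording", function(x) x@modalityTags)

#' @describeIn SensorRecording channel names.
#' @export
setMethod("channelNames", "SensorRecording", function(x) x@channelNames)

#' @describeIn SensorRecording per-sample labels (0 = Null).
#' @param object a SensorRecording.
#' @param ... unused.
#' @export
setMethod("labels", "SensorRecording", function(object, ...) object@labels)

setMethod("show", "SensorRecording", function(object) {
  n <- nSamples(object)
  cat(sprintf("SensorRecording: %d samples x %d channels @ %g Hz (%.1f s)\n",
              n, nChannels(object), object@sampleRate,
              n / object@sampleRate))
  tags <- unique(object@modalityTags[object@modalityTags != ""])
  if (length(tags))
    cat("  modalities:", paste(tags, collapse = ", "), "\n")
  nmiss <- sum(is.na(object@samples))
  if (nmiss > 0)
    cat(sprintf("  missing values: %d (%.2f%%)\n", nmiss,
                100 * nmiss / length(object@samples)))
  tab <- table(object@labels)
  cat("  label counts:",
      paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
})

## ---- WindowBatch ----

#' @describeIn WindowBatch number of windows M.
#' @param x a WindowBatch.
#' @export
setMethod("nWindows", "WindowBatch", function(x) dim(x@sequences)[3L])

#' @describeIn WindowBatch window length S1.
#' @export
setMethod("windowLength", "WindowBatch", function(x) dim(x@sequences)[2L])

#' @describeIn WindowBatch channel count D.
#' @export
setMethod("nChannels", "WindowBatch", function(x) dim(x@sequences)[1L])

#' @describeIn WindowBatch the D x S1 x M sequence array.
#' @export
setMethod("sequences", "WindowBatch", function(x) x@sequences)

#' @describeIn WindowBatch window start indices.
#' @export
setMethod("windowStarts", "WindowBatch", function(x) x@starts)

#' @describeIn WindowBatch per-window labels (last-sample policy).
#' @param object a WindowBatch.
#' @param ... unused.
#' @export
setMethod("labels", "WindowBatch", function(object, ...) object@labels)

setMethod("show", "WindowBatch", function(object) {
  d <- dim(object@sequences)
  cat(sprintf("WindowBatch: %d windows of %d channels x %d samples (step %d)\n",
              d[3L], d[1L], d[2L], object@step))
  tab <- table(object@labels)
  cat("  window labels:",
      paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
})

## ---- ModelSpec / HARModel ----

#' @describeIn ModelSpec channel count D.
#' @param x a ModelSpec.
#' @export
setMethod("nChannels", "ModelSpec", function(x) x@nChannels)

#' @describeIn ModelSpec input window length S1.
#' @export
setMethod("windowLength", "ModelSpec", function(x) x@windowLen)

#' @describeIn ModelSpec shorthand architecture string.
#' @export
setMethod("shorthand", "ModelSpec", function(x) {
  conv <- paste(rep(sprintf("C(%d)", x@nFilters), x@nConvLayers),
                collapse = "-")
  dense <- if (x@variant == "convlstm")
    sprintf("R(%d)-R(%d)", x@nUnits, x@nUnits)
  else sprintf("D(%d)-D(%d)", x@nUnits, x@nUnits)
  paste(conv, dense, "Sm", sep = "-")
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec [%s]: %s\n", object@variant, shorthand(object)))
  cat(sprintf("  D=%d channels, S1=%d samples, P=%d, %d classes\n",
              object@nChannels, object@windowLen, object@kernelLen,
              object@nClasses))
})

#' @describeIn HARModel architecture specification.
#' @param x a HARModel.
#' @export
setMethod("spec", "HARModel", function(x) x@spec)

#' @describeIn HARModel list of layer parameters.
#' @export
setMethod("modelLayers", "HARModel", function(x) x@layers)

#' @describeIn HARModel shorthand architecture string.
#' @export
setMethod("shorthand", "HARModel", function(x) shorthand(x@spec))

setMethod("show", "HARModel", function(object) {
  cat(sprintf("HARModel [%s] %s\n", object@spec@variant, shorthand(object)))
  pt <- countParameters(object)
  cat(sprintf("  %d trainable parameters in %d layers (seed %d)\n",
              sum(pt$parameters), nrow(pt), object@seed))
})

## ---- EvaluationReport ----

#' @describeIn EvaluationReport sample-weighted F1.
#' @param x an EvaluationReport.
#' @export
setMethod("weightedF1Score", "EvaluationReport", function(x) x@weightedF1)

#' @describeIn EvaluationReport confusion matrix.
#' @export
setMethod("confusion", "EvaluationReport", function(x) x@confusion)

#' @describeIn EvaluationReport per-class metric table.
#' @export
setMethod("perClassMetrics", "EvaluationReport", function(x) x@perClass)

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport (Null class %s): weighted F1 = %.4f over %d windows\n",
              object@nullMode, object@weightedF1, sum(object@confusion)))
  print(object@perClass, digits = 4)
})
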