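#' @import methods
NULL

#' SensorRecording: a labelled multichannel sensor stream
#'
#' Container for a continuous recording from body-worn sensors: an N x D
#' matrix of samples (N time steps, D channels, possibly containing missing
#' values as NA/NaN), one integer activity label per time step (0 is the
#' Null class by convention), the nominal sample rate, and optional channel
#' names and per-channel modality tags (e.g. "acc", "gyro", "mag").
#'
#' @slot samples numeric matrix, N time steps x D channels.
#' @slot labels integer vector of length N; class 0 is the Null class.
#' @slot sampleRate sampling rate in Hz (nominal 30 for the datasets this
#'   dialect mirrors).
#' @slot channelNames character vector of length D.
#' @slot modalityTags character vector of length D (may be empty strings).
#'
#' @exportClass SensorRecording
setClass("SensorRecording",
  representation(
    samples      = "matrix",
    labels       = "integer",
    sampleRate   = "numeric",
    channelNames = "character",
    modalityTags = "character"
  )
)

setValidity("SensorRecording", function(object) {
  msg <- NULL
  if (!is.numeric(object@samples)) msg <- c(msg, "samples must be numeric")
  if (ncol(object@samples) < 1L) msg <- c(msg, "need at least one channel")
  if (nrow(object@samples) != length(object@labels))
    msg <- c(msg, "labels length must equal the number of time steps")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "sampleRate must be a single positive number")
  if (any(object@labels < 0L, na.rm = TRUE))
    msg <- c(msg, "labels must be non-negative integers (0 = Null)")
  if (length(object@channelNames) != ncol(object@samples))
    msg <- c(msg, "channelNames length must equal the number of channels")
  if (length(object@modalityTags) != ncol(object@samples))
    msg <- c(msg, "modalityTags length must equal the number of channels")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SensorRecording
#'
#' @param samples numeric matrix, N time steps x D channels; missing values
#'   as NA/NaN.
#' @param labels integer vector of per-sample class labels (0 = Null).
#' @param sampleRate sampling rate in Hz.
#' @param channelNames optional channel names (default "ch1".."chD").
#' @param modalityTags optional per-channel modality tags.
#' @return A \linkS4class{SensorRecording} object.
#' @examples
#' rec <- SensorRecording(matrix(rnorm(60), 30, 2), rep(0L, 30))
#' nChannels(rec)
#' @export
SensorRecording <- function(samples, labels, sampleRate = 30,
                            channelNames = NULL, modalityTags = NULL) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(ncol(samples)))
  if (is.null(modalityTags))
    modalityTags <- rep("", ncol(samples))
  new("SensorRecording",
      samples = samples, labels = as.integer(labels),
      sampleRate = as.numeric(sampleRate),
      channelNames = as.character(channelNames),
      modalityTags = as.character(modalityTags))
}

#' WindowConfig: sliding-window segmentation settings
#'
#' @slot windowLen window length S1 in samples.
#' @slot step step between consecutive window starts, in samples.
#'
#' @exportClass WindowConfig
setClass("WindowConfig",
  representation(windowLen = "integer", step = "integer"))

setValidity("WindowConfig", function(object) {
  msg <- NULL
  if (object@windowLen < 1L) msg <- c(msg, "windowLen must be >= 1")
  if (object@step < 1L || object@step > object@windowLen)
    msg <- c(msg, "step must satisfy 1 <= step <= windowLen")
  if (is.null(msg)) TRUE else msg
})

#' Construct a WindowConfig
#'
#' Defaults follow the 24-sample window with 50% overlap used throughout
#' the package (a 0.8 s window at 30 Hz, the shortest window for which four
#' valid length-5 convolutions leave a sequence for the recurrent layers;
#' see the methods vignette). Windows are labelled with the class of their
#' last sample.
#'
#' @param windowLen window length in samples (default 24).
#' @param step step size in samples (default 12).
#' @return A \linkS4class{WindowConfig} object.
#' @export
windowConfig <- function(windowLen = 24L, step = 12L) {
  new("WindowConfig", windowLen = as.integer(windowLen),
      step = as.integer(step))
}

#' WindowBatch: segmented fixed-length sequences
#'
#' The result of sliding-window segmentation: M windows of shape D x S1,
#' each carrying the label of its final sample and the (1-based) start
#' index of the window in its source recording.
#'
#' @slot sequences numeric array D x S1 x M.
#' @slot labels integer vector of M window labels (last-sample policy).
#' @slot starts integer vector of M start indices, strictly increasing.
#' @slot step step size used during segmentation.
#'
#' @exportClass WindowBatch
setClass("WindowBatch",
  representation(sequences = "array", labels = "integer",
                 starts = "integer", step = "integer"))

setValidity("WindowBatch", function(object) {
  msg <- NULL
  d <- dim(object@sequences)
  if (length(d) != 3L) msg <- c(msg, "sequences must be a D x S1 x M array")
  else {
    if (d[3L] != length(object@labels))
      msg <- c(msg, "labels length must equal the number of windows")
    if (d[3L] != length(object@starts))
      msg <- c(msg, "starts length must equal the number of windows")
  }
  if (length(object@starts) > 1L && any(diff(object@starts) <= 0L))
    msg <- c(msg, "window starts must be strictly increasing")
  if (is.null(msg)) TRUE else msg
})

#' ModelSpec: architecture description
#'
#' Describes either the hybrid convolutional-LSTM network
#' (\code{variant = "convlstm"}, shorthand
#' C(F)-C(F)-C(F)-C(F)-R(U)-R(U)-Sm) or the equally sized baseline CNN
#' (\code{variant = "cnn"}, C(F)-C(F)-C(F)-C(F)-D(U)-D(U)-Sm). Both share
#' four valid temporal convolution layers (F kernels of length P per layer,
#' applied to every sensor channel independently, ReLU); they differ only
#' in whether the two 128-unit layers are peephole-LSTM cells or plain
#' ReLU dense units.
#'
#' @slot variant "convlstm" or "cnn".
#' @slot nChannels number of sensor channels D.
#' @slot nClasses number of output classes (including Null if present).
#' @slot windowLen input sequence length S1 in samples.
#' @slot kernelLen temporal kernel length P (default 5).
#' @slot nFilters feature maps per convolutional layer F (default 64).
#' @slot nUnits units/cells per dense or recurrent layer (default 128).
#' @slot nConvLayers number of convolutional layers (default 4).
#'
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(variant = "character", nChannels = "integer",
                 nClasses = "integer", windowLen = "integer",
                 kernelLen = "integer", nFilters = "integer",
                 nUnits = "integer", nConvLayers = "integer"))

setValidity("ModelSpec", function(object) {
  msg <- NULL
  if (!object@variant %in% c("convlstm", "cnn"))
    msg <- c(msg, "variant must be 'convlstm' or 'cnn'")
  if (object@nChannels < 1L) msg <- c(msg, "nChannels must be >= 1")
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (object@kernelLen < 1L) msg <- c(msg, "kernelLen must be >= 1")
  if (object@nConvLayers < 1L) msg <- c(msg, "need at least 1 conv layer")
  minLen <- object@nConvLayers * (object@kernelLen - 1L) + 1L
  if (object@windowLen < minLen)
    msg <- c(msg, sprintf(
      "windowLen %d too small: %d valid convolutions with kernel length %d need at least %d samples (each layer shortens the sequence by P-1)",
      object@windowLen, object@nConvLayers, object@kernelLen, minLen))
  if (is.null(msg)) TRUE else msg
})

#' Construct a ModelSpec
#'
#' @param variant "convlstm" (recurrent dense layers) or "cnn" (baseline
#'   fully-connected dense layers).
#' @param nChannels number of sensor channels D.
#' @param nClasses number of classes (including Null if modelled).
#' @param windowLen input window length S1 in samples (default 24).
#' @param kernelLen kernel length P (default 5).
#' @param nFilters feature maps per conv layer (default 64).
#' @param nUnits units or LSTM cells per dense layer (default 128).
#' @param nConvLayers number of convolutional layers (default 4; exposed so
#'   the depth sweep of 2--7 conv layers can be run).
#' @return A \linkS4class{ModelSpec}.
#' @examples
#' spec <- modelSpec("convlstm", nChannels = 113, nClasses = 18)
#' shorthand(spec)
#' @export
modelSpec <- function(variant = c("convlstm", "cnn"), nChannels, nClasses,
                      windowLen = 24L, kernelLen = 5L, nFilters = 64L,
                      nUnits = 128L, nConvLayers = 4L) {
  variant <- match.arg(variant)
  new("ModelSpec", variant = variant, nChannels = as.integer(nChannels),
      nClasses = as.integer(nClasses), windowLen = as.integer(windowLen),
      kernelLen = as.integer(kernelLen), nFilters = as.integer(nFilters),
      nUnits = as.integer(nUnits), nConvLayers = as.integer(nConvLayers))
}

#' HARModel: an architecture plus all trainable parameters
#'
#' @slot spec the \linkS4class{ModelSpec} the parameters realise.
#' @slot layers ordered list of layer parameter sets: nConvLayers
#'   convolutional layers (kernels K of dim F_out x F_in x P shared across
#'   channels, biases b), then two LSTM or two dense layers, then the
#'   softmax output layer.
#' @slot seed integer seed the parameters were initialised from.
#'
#' @exportClass HARModel
setClass("HARModel",
  representation(spec = "ModelSpec", layers = "list", seed = "integer"))

#' TrainingConfig: optimisation settings
#'
#' Mini-batch RMSProp with inverted dropout on the inputs of every dense
#' (or recurrent) layer, orthogonal weight initialisation, and early
#' stopping on validation weighted F1.
#'
#' @slot learningRate RMSProp learning rate (default 1e-3).
#' @slot rho RMSProp decay factor for the squared-gradient cache
#'   (default 0.9).
#' @slot batchSize mini-batch size in windows (default 100).
#' @slot dropoutP dropout probability on dense-layer inputs (default 0.5).
#' @slot maxEpochs maximum number of epochs (default 100).
#' @slot patience epochs without validation improvement before stopping
#'   (default 10).
#' @slot seed RNG seed controlling shuffling and dropout.
#' @slot epsilon RMSProp denominator stabiliser (default 1e-6).
#'
#' @exportClass TrainingConfig
setClass("TrainingConfig",
  representation(learningRate = "numeric", rho = "numeric",
                 batchSize = "integer", dropoutP = "numeric",
                 maxEpochs = "integer", patience = "integer",
                 seed = "integer", epsilon = "numeric"))

setValidity("TrainingConfig", function(object) {
  msg <- NULL
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@rho <= 0 || object@rho >= 1) msg <- c(msg, "rho must be in (0,1)")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@dropoutP < 0 || object@dropoutP >= 1)
    msg <- c(msg, "dropoutP must be in [0,1)")
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
  if (object@patience < 0L) msg <- c(msg, "patience must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TrainingConfig
#'
#' @param learningRate learning rate (default 1e-3).
#' @param rho squared-gradient decay factor (default 0.9).
#' @param batchSize windows per mini-batch (default 100).
#' @param dropoutP dropout probability on dense-layer inputs (default 0.5).
#' @param maxEpochs epoch cap (default 100).
#' @param patience early-stopping patience in epochs (default 10).
#' @param seed RNG seed (default 1).
#' @param epsilon RMSProp stabiliser (default 1e-6).
#' @return A \linkS4class{TrainingConfig}.
#' @export
trainingConfig <- function(learningRate = 1e-3, rho = 0.9, batchSize = 100L,
                           dropoutP = 0.5, maxEpochs = 100L, patience = 10L,
                           seed = 1L, epsilon = 1e-6) {
  new("TrainingConfig", learningRate = learningRate, rho = rho,
      batchSize = as.integer(batchSize), dropoutP = dropoutP,
      maxEpochs = as.integer(maxEpochs), patience = as.integer(patience),
      seed = as.integer(seed), epsilon = epsilon)
}

#' EvaluationReport: confusion matrix and imbalance-aware scores
#'
#' @slot confusion integer matrix, rows = actual class, columns = predicted
#'   class.
#' @slot perClass data.frame with one row per class: support n, weight
#'   n/N, precision, recall, F1.
#' @slot weightedF1 sample-weighted F1 over the evaluated classes.
#' @slot nullMode "included" or "excluded".
#'
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(confusion = "matrix", perClass = "data.frame",
                 weightedF1 = "numeric", nullMode = "character"))

#' SyntheticConfig: settings for the wearable-stream simulator
#'
#' The generator emulates the statistical structure of naturalistic
#' activity recordings: modality groups of channels with a ladder of
#' informativeness (accelerometer-like channels strongest, magnetometer-like
#' weakest), sporadic smooth gesture motifs embedded in a dominant Null
#' background (target fraction 0.75), amplitude jitter and +/-20 percent
#' time warping per instance, and optional time-mirrored gesture pairs
#' whose only distinguishing cue is sample order.
#'
#' @slot channelsPerModality named integer vector of channels per modality
#'   group.
#' @slot nClasses number of classes including Null (class 0).
#' @slot templateLenRange integer length-2 range for motif lengths in
#'   samples.
#' @slot gesturesPerClass gesture instances inserted per non-Null class.
#' @slot nullFraction target fraction of Null-labelled samples.
#' @slot noiseSd named numeric vector: background/observation noise sd per
#'   modality group.
#' @slot amplitude named numeric vector: motif amplitude scale per modality
#'   group.
#' @slot mirroredPairs list of integer class pairs c(a, b) where class b's
#'   motif is class a's motif reversed in time.
#' @slot modalityOverlap fraction (0..1) of each non-final modality
#'   group's motif variance that is shared between classes the group's
#'   nested sub-motif assignment merges. 0 (the default reference task)
#'   gives every class fully distinct motifs in every group; 1 makes
#'   merged classes identical within a single modality, so only adding
#'   further modality groups can separate them — the setting used for
#'   sensor-fusion studies.
#' @slot ampJitter half-width of the per-instance amplitude jitter (0.2
#'   means multipliers drawn from [0.8, 1.2]; 0 disables).
#' @slot timeWarp half-width of the per-instance time warp (0.2 means
#'   lengths rescaled by [0.8, 1.2]; 0 disables).
#' @slot driftAmplitude scale of the slow background drift relative to
#'   the modality amplitude (0 disables).
#' @slot corCap maximum absolute correlation allowed between motifs of
#'   non-paired classes.
#' @slot sampleRate sample rate in Hz.
#' @slot missingRate expected fraction of samples replaced by short missing
#'   runs (0 disables).
#' @slot seed RNG seed.
#'
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(channelsPerModality = "integer", nClasses = "integer",
                 templateLenRange = "integer", gesturesPerClass = "integer",
                 nullFraction = "numeric", noiseSd = "numeric",
                 amplitude = "numeric", mirroredPairs = "list",
                 modalityOverlap = "numeric",
                 ampJitter = "numeric", timeWarp = "numeric",
                 driftAmplitude = "numeric",
                 corCap = "numeric", sampleRate = "numeric",
                 missingRate = "numeric", seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- NULL
  if (object@nullFraction < 0 || object@nullFraction >= 1)
    msg <- c(msg, "nullFraction must be in [0,1)")
  if (object@nClasses < 2L) msg <- c(msg, "need at least Null plus one class")
  if (any(object@channelsPerModality < 1L))
    msg <- c(msg, "each modality group needs at least one channel")
  if (!setequal(names(object@noiseSd), names(object@channelsPerModality)) ||
      !setequal(names(object@amplitude), names(object@channelsPerModality)))
    msg <- c(msg, "noiseSd and amplitude must be named per modality group")
  for (pr in object@mirroredPairs)
    if (length(pr) != 2L || any(pr < 1L) || any(pr >= object@nClasses))
      msg <- c(msg, "mirroredPairs must be pairs of gesture class ids in 1..nClasses-1")
  if (object@modalityOverlap < 0 || object@modalityOverlap > 1)
    msg <- c(msg, "modalityOverlap must be in [0,1]")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SyntheticConfig
#'
#' Defaults define the package's reference synthetic task: three modality
#' groups of five channels each (15 channels total) at 30 Hz, five classes
#' (Null plus four gestures, one time-mirrored pair), 75 percent Null, and
#' a modality informativeness ladder (acc strongest, mag weakest).
#'
#' @param channelsPerModality named integer vector (default
#'   c(acc = 5, gyro = 5, mag = 5)).
#' @param nClasses classes including Null (default 5).
#' @param templateLenRange motif length range in samples (default
#'   c(36, 72), i.e. 1.2-2.4 s at 30 Hz, the scale of real sporadic
#'   gestures; motifs well below one window length would make windows
#'   that end just inside a gesture — labelled with the gesture class
#'   by the last-sample convention — nearly indistinguishable from
#'   Null, capping achievable F1 regardless of the model).
#' @param gesturesPerClass instances per gesture class (default 25).
#' @param nullFraction target Null fraction (default 0.75).
#' @param noiseSd per-modality noise sd
#'   (default c(acc = 0.15, gyro = 0.20, mag = 0.25)).
#' @param amplitude per-modality motif amplitude
#'   (default c(acc = 1.0, gyro = 0.8, mag = 0.6)).
#' @param mirroredPairs list of mirrored class pairs (default list(c(3, 4))).
#' @param modalityOverlap shared fraction of non-final-group motif
#'   variance between classes merged by the nested sub-motif assignment
#'   (default 0: fully distinct motifs; 1: single modalities cannot
#'   separate merged classes, for fusion studies).
#' @param ampJitter amplitude jitter half-width (default 0.2).
#' @param timeWarp time-warp half-width (default 0.2).
#' @param driftAmplitude background drift scale (default 0.3).
#' @param corCap max motif correlation between non-paired classes
#'   (default 0.6).
#' @param sampleRate Hz (default 30).
#' @param missingRate fraction of samples hidden in missing runs
#'   (default 0).
#' @param seed RNG seed (default 1).
#' @return A \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(channelsPerModality = c(acc = 5L, gyro = 5L, mag = 5L),
                            nClasses = 5L,
                            templateLenRange = c(36L, 72L),
                            gesturesPerClass = 25L,
                            nullFraction = 0.75,
                            noiseSd = c(acc = 0.15, gyro = 0.20, mag = 0.25),
                            amplitude = c(acc = 1.0, gyro = 0.8, mag = 0.6),
                            mirroredPairs = list(c(3L, 4L)),
                            modalityOverlap = 0,
                            ampJitter = 0.2,
                            timeWarp = 0.2,
                            driftAmplitude = 0.3,
                            corCap = 0.6,
                            sampleRate = 30,
                            missingRate = 0,
                            seed = 1L) {
  cpm <- as.integer(channelsPerModality)
  names(cpm) <- names(channelsPerModality)
  new("SyntheticConfig",
      channelsPerModality = cpm, nClasses = as.integer(nClasses),
      templateLenRange = as.integer(templateLenRange),
      gesturesPerClass = as.integer(gesturesPerClass),
      nullFraction = nullFraction, noiseSd = noiseSd, amplitude = amplitude,
      mirroredPairs = lapply(mirroredPairs, as.integer),
      modalityOverlap = modalityOverlap,
      ampJitter = ampJitter, timeWarp = timeWarp,
      driftAmplitude = driftAmplitude, corCap = corCap,
      sampleRate = sampleRate, missingRate = missingRate,
      seed = as.integer(seed))
}
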