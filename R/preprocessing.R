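# Preprocessing: missing-value interpolation, [0,1] normalisation and
# sliding-window segmentation with last-sample labelling.

#' Fill missing samples by per-channel linear interpolation
#'
#' Every NA/NaN run is replaced by linear interpolation between the nearest
#' observed neighbours in time; gaps at the start or end of the recording
#' are filled with the nearest observed value (constant extension, so no
#' extrapolation artifacts). Observed values are returned unchanged.
#'
#' @param recording a \linkS4class{SensorRecording}.
#' @return a \linkS4class{SensorRecording} with no missing values.
#' @examples
#' rec <- SensorRecording(cbind(c(1, NA, 3)), rep(0L, 3))
#' samples(interpolateMissing(rec))[, 1]  # 1 2 3
#' @export
interpolateMissing <- function(recording) {
  stopifnot(is(recording, "SensorRecording"))
  x <- recording@samples
  n <- nrow(x)
  for (d in seq_len(ncol(x))) {
    col <- x[, d]
    miss <- is.na(col)
    if (!any(miss)) next
    if (all(miss))
      stop(sprintf("channel %d ('%s') has no observed values",
                   d, recording@channelNames[d]))
    obs <- which(!miss)
    x[miss, d] <- if (length(obs) == 1L) col[obs] else
      approx(x = obs, y = col[obs], xout = which(miss),
             method = "linear", rule = 2)$y
  }
  initialize(recording, samples = x)
}

#' Normalise each channel to the interval [0, 1]
#'
#' Affine per-channel map x -> (x - min) / (max - min). Bounds are either
#' computed from the data or supplied (so validation/test recordings reuse
#' the bounds of the training data and no information leaks); values
#' outside supplied bounds are clipped into [0, 1]. A channel with
#' max == min is set to all zeros with a warning.
#'
#' @param recording a \linkS4class{SensorRecording} without missing values
#'   (run \code{\link{interpolateMissing}} first).
#' @param bounds optional D x 2 matrix (columns min, max) of per-channel
#'   bounds to reuse; default NULL computes them from the data.
#' @return list with elements \code{recording} (normalised) and
#'   \code{bounds} (the D x 2 matrix used).
#' @examples
#' rec <- SensorRecording(cbind(c(2, 4, 6)), rep(0L, 3))
#' normalizeChannels(rec)$recording |> samples()  # 0 0.5 1
#' @export
normalizeChannels <- function(recording, bounds = NULL) {
  stopifnot(is(recording, "SensorRecording"))
  x <- recording@samples
  if (anyNA(x))
    stop("recording contains missing values; run interpolateMissing() first")
  D <- ncol(x)
  if (is.null(bounds)) {
    bounds <- cbind(min = apply(x, 2, min), max = apply(x, 2, max))
  } else {
    bounds <- as.matrix(bounds)
    if (nrow(bounds) != D || ncol(bounds) != 2L)
      stop("bounds must be a D x 2 (min, max) matrix")
  }
  for (d in seq_len(D)) {
    lo <- bounds[d, 1L]; hi <- bounds[d, 2L]
    if (hi == lo) {
      warning(sprintf("channel %d ('%s') has constant value %g; set to 0",
                      d, recording@channelNames[d], lo))
      x[, d] <- 0
    } else {
      x[, d] <- pmin(pmax((x[, d] - lo) / (hi - lo), 0), 1)
    }
  }
  list(recording = initialize(recording, samples = x), bounds = bounds)
}

#' Segment a recording into fixed-length windows
#'
#' Sliding (jumping) windows of length S1 starting at indices 1, 1+step,
#' 1+2*step, ... while fully inside the recording, so the window count is
#' floor((N - S1) / step) + 1. Each window carries the ground-truth label
#' of its final sample (last-sample labelling), matching how the network
#' is scored: the prediction made after observing a full window is
#' compared against the label at that instant. Windows never span
#' recording boundaries; segment each session independently.
#'
#' @param recording a preprocessed \linkS4class{SensorRecording}.
#' @param cfg a \linkS4class{WindowConfig}.
#' @return a \linkS4class{WindowBatch} whose sequences array is
#'   D x S1 x M.
#' @examples
#' rec <- SensorRecording(matrix(0, 100, 2), rep(0L, 100))
#' nWindows(slidingWindows(rec, windowConfig(24, 12)))  # 7
#' @export
slidingWindows <- function(recording, cfg = windowConfig()) {
  stopifnot(is(recording, "SensorRecording"), is(cfg, "WindowConfig"))
  N <- nSamples(recording); S1 <- cfg@windowLen; step <- cfg@step
  if (N < S1)
    stop(sprintf("recording shorter than window (%d < %d samples)", N, S1))
  starts <- seq.int(1L, N - S1 + 1L, by = step)
  M <- length(starts)
  D <- nChannels(recording)
  xt <- t(recording@samples)            # D x N, so windows slice columns
  seqs <- array(0, dim = c(D, S1, M))
  for (m in seq_len(M))
    seqs[, , m] <- xt[, starts[m]:(starts[m] + S1 - 1L), drop = FALSE]
  new("WindowBatch", sequences = seqs,
      labels = recording@labels[starts + S1 - 1L],
      starts = starts, step = step)
}

#' Drop Null-labelled windows and relabel gesture classes
#'
#' For the evaluation mode that ignores the Null class, models are trained
#' and scored on the gesture classes only. This helper removes windows
#' labelled 0 and shifts the remaining labels down by one so the gesture
#' classes form a contiguous 0-based set.
#'
#' @param batch a \linkS4class{WindowBatch} with 0 = Null labels.
#' @return a \linkS4class{WindowBatch} containing only gesture windows.
#' @export
dropNullWindows <- function(batch) {
  stopifnot(is(batch, "WindowBatch"))
  keep <- which(batch@labels != 0L)
  if (!length(keep)) stop("no non-Null windows in batch")
  new("WindowBatch",
      sequences = batch@sequences[, , keep, drop = FALSE],
      labels = batch@labels[keep] - 1L,
      starts = batch@starts[keep], step = batch@step)
}

#' Subset a batch of windows by index
#'
#' @param batch a \linkS4class{WindowBatch}.
#' @param idx integer indices of windows to keep (in increasing order).
#' @return a \linkS4class{WindowBatch}.
#' @export
subsetWindows <- function(batch, idx) {
  stopifnot(is(batch, "WindowBatch"))
  idx <- sort(as.integer(idx))
  new("WindowBatch",
      sequences = batch@sequences[, , idx, drop = FALSE],
      labels = batch@labels[idx],
      starts = batch@starts[idx], step = batch@step)
}
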