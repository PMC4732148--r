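# Seeded generator of wearable-like labelled sensor streams: smooth
# gesture motifs embedded in a dominant Null background, modality groups
# with a ladder of informativeness, and optional time-mirrored gesture
# pairs whose only distinguishing cue is sample order.

.modalityOfChannel <- function(cfg) {
  rep(names(cfg@channelsPerModality), cfg@channelsPerModality)
}

# Smooth band-limited motif on a set of channels: per channel a sum of
# three sinusoids under a raised-cosine onset/offset envelope.
.drawMotif <- function(len, nCh, amplitude, fs) {
  tt <- seq_len(len) / fs
  env <- 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))
  tpl <- matrix(0, nCh, len)
  for (d in seq_len(nCh)) {
    w <- numeric(len)
    for (k in 1:3) {
      f <- runif(1, 0.8, 5)       # Hz, well under Nyquist at 30 Hz
      a <- runif(1, 0.4, 1)
      ph <- runif(1, 0, 2 * pi)
      w <- w + a * sin(2 * pi * f * tt + ph)
    }
    tpl[d, ] <- amplitude * env * w / 1.5
  }
  tpl
}

.resampleRows <- function(tpl, L) {
  if (ncol(tpl) == L) return(tpl)
  out <- matrix(0, nrow(tpl), L)
  for (d in seq_len(nrow(tpl)))
    out[d, ] <- approx(seq_len(ncol(tpl)), tpl[d, ], n = L)$y
  out
}

# Which shared base does class k use in modality group g? The bases
# form a nested refinement: the first group merges consecutive class
# pairs, each further group resolves one remaining merged pair (from
# the last pair backwards), and the final group is distinct per class.
# At modalityOverlap = 1 a class's group motif IS its base, so every
# prefix of groups leaves some classes identical that only a later
# group separates — each added modality group is then strictly
# informative, never merely redundant, which is what makes the
# sensor-fusion trend testable.
.poolAssignment <- function(nGest, nGroups) {
  A <- matrix(0L, nGroups, nGest)
  pair <- (seq_len(nGest) + 1L) %/% 2L
  nPairs <- max(pair)
  for (g in seq_len(nGroups)) {
    A[g, ] <- if (g == nGroups) seq_len(nGest)
    else if (g == 1L) pair
    else {
      cut <- max(nPairs - (g - 1L), 0L)
      ifelse(pair <= cut, pair, cut + (seq_len(nGest) - 2L * cut))
    }
  }
  A
}

#' Generate the per-class motif bank
#'
#' One smooth multichannel motif per gesture class, deterministic given
#' the config seed. Motifs are composed per modality group from small
#' sub-motif pools arranged as a nested refinement: the first group's
#' shared bases merge consecutive class pairs, each further group
#' resolves one more merged pair, and the last group carries a fully
#' distinct per-class signature. \code{modalityOverlap} sets how much
#' of each non-final group's motif variance is the shared base rather
#' than a class-specific overlay: at 0 (the default reference task)
#' every class is distinct in every group, while at 1 merged classes
#' are identical within a single modality, so only adding further
#' modality groups can separate them — the structure that makes
#' sensor fusion pay off in real multimodal recordings. Within each
#' pool, distinct sub-motifs are redrawn until their pairwise correlation
#' stays below \code{corCap}.
#'
#' For every mirrored pair (a, b), class b's motif is exactly class a's
#' motif reversed in time on every channel, so the two share the same
#' per-channel sample multiset and differ only in temporal order.
#'
#' @param cfg a \linkS4class{SyntheticConfig}.
#' @return list of D x L_k matrices, one per gesture class 1..nClasses-1.
#' @export
makeTemplates <- function(cfg) {
  stopifnot(is(cfg, "SyntheticConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  nGest <- cfg@nClasses - 1L
  groups <- names(cfg@channelsPerModality)
  nGroups <- length(groups)
  mirrorOf <- integer(nGest)           # 0 = independent motif
  for (pr in cfg@mirroredPairs) mirrorOf[pr[2L]] <- pr[1L]
  lens <- sample(cfg@templateLenRange[1L]:cfg@templateLenRange[2L],
                 nGest, replace = TRUE)
  for (pr in cfg@mirroredPairs) lens[pr[2L]] <- lens[pr[1L]]
  assign <- .poolAssignment(nGest, nGroups)
  # canonical pool length: the middle of the motif length range, so
  # resampling to class lengths only mildly rescales frequency content
  L0 <- as.integer(round(mean(cfg@templateLenRange)))
  pools <- vector("list", nGroups)
  for (g in seq_len(nGroups)) {
    nItems <- max(assign[g, ])
    nCh <- cfg@channelsPerModality[g]
    amp <- cfg@amplitude[groups[g]]
    items <- vector("list", nItems)
    for (it in seq_len(nItems)) {
      for (attempt in 1:100) {
        cand <- .drawMotif(L0, nCh, amp, cfg@sampleRate)
        ok <- TRUE
        for (j in seq_len(it - 1L)) {
          r <- cor(as.vector(cand), as.vector(items[[j]]))
          if (abs(r) >= cfg@corCap) { ok <- FALSE; break }
        }
        if (ok) break
        if (attempt == 100) stop("could not draw sub-motifs under corCap")
      }
      items[[it]] <- cand
    }
    pools[[g]] <- items
  }
  overlays <- vector("list", nGroups)
  for (g in seq_len(nGroups)) {
    if (g == nGroups) next             # final group: distinct items already
    overlays[[g]] <- lapply(seq_len(nGest), function(k)
      .drawMotif(L0, cfg@channelsPerModality[g],
                 cfg@amplitude[groups[g]], cfg@sampleRate))
  }
  ov <- cfg@modalityOverlap
  templates <- vector("list", nGest)
  for (k in seq_len(nGest)) {
    if (mirrorOf[k] > 0L) next
    templates[[k]] <- do.call(rbind, lapply(seq_len(nGroups), function(g) {
      block <- if (g == nGroups) pools[[g]][[assign[g, k]]]
      else sqrt(ov) * pools[[g]][[assign[g, k]]] +
        sqrt(1 - ov) * overlays[[g]][[k]]
      .resampleRows(block, lens[k])
    }))
  }
  for (k in which(mirrorOf > 0L))
    templates[[k]] <- templates[[mirrorOf[k]]][, lens[k]:1, drop = FALSE]
  templates
}

#' Generate a labelled synthetic sensor recording
#'
#' Builds a Null background (per-channel noise at the modality's noise
#' level plus a slow sinusoidal drift) and inserts, at non-overlapping
#' random positions separated by at least one window length of Null,
#' \code{gesturesPerClass} instances of every gesture motif, each
#' amplitude-jittered and time-warped by up to +/-20 percent. The stream
#' length is chosen so the realised Null fraction matches the target;
#' per-sample labels mark the gesture spans (0 elsewhere). Optionally
#' hides short runs of samples as missing values to exercise
#' interpolation. Deterministic given the config seed.
#'
#' @param cfg a \linkS4class{SyntheticConfig}.
#' @param templates optional motif bank from \code{\link{makeTemplates}}
#'   (so several recordings can share one bank); default regenerates it
#'   from the config.
#' @param seedOffset added to the config seed for the placement/noise RNG,
#'   letting one config produce independent train/validation/test streams
#'   that share templates.
#' @return a \linkS4class{SensorRecording}.
#' @export
generateRecording <- function(cfg, templates = NULL, seedOffset = 0L) {
  stopifnot(is(cfg, "SyntheticConfig"))
  if (is.null(templates)) templates <- makeTemplates(cfg)
  set.seed((cfg@seed + 7919 * (as.integer(seedOffset) + 1)) %%
             .Machine$integer.max)
  nGest <- cfg@nClasses - 1L
  mods <- .modalityOfChannel(cfg)
  D <- length(mods)
  fs <- cfg@sampleRate
  gapMin <- 24L                      # >= one window of Null between gestures
  # draw instance realisations (class, warp, jitter) first, so stream
  # length can match the target Null fraction
  inst <- do.call(rbind, lapply(seq_len(nGest), function(k) {
    L0 <- ncol(templates[[k]])
    warp <- runif(cfg@gesturesPerClass, 1 - cfg@timeWarp, 1 + cfg@timeWarp)
    data.frame(class = k,
               len = pmax(8L, round(L0 * warp)),
               amp = runif(cfg@gesturesPerClass, 1 - cfg@ampJitter,
                           1 + cfg@ampJitter))
  }))
  inst <- inst[sample.int(nrow(inst)), , drop = FALSE]
  nInst <- nrow(inst)
  G <- sum(inst$len)
  N <- as.integer(round(G / (1 - cfg@nullFraction)))
  slack <- N - G - gapMin * (nInst + 1L)
  if (slack < 0L)
    stop(sprintf(
      "requested gesture mass (%d samples) exceeds stream capacity at Null fraction %.2f",
      G, cfg@nullFraction))
  extra <- as.vector(rmultinom(1L, slack, rep(1, nInst + 1L)))
  gaps <- gapMin + extra
  starts <- integer(nInst)
  pos <- 0L
  for (i in seq_len(nInst)) {
    pos <- pos + gaps[i]
    starts[i] <- pos + 1L
    pos <- pos + inst$len[i]
  }
  # background: slow drift + modality-level noise
  x <- matrix(0, N, D)
  tt <- seq_len(N) / fs
  for (d in seq_len(D)) {
    f <- runif(1, 0.02, 0.1)
    a <- cfg@driftAmplitude * cfg@amplitude[mods[d]]
    drift <- a * sin(2 * pi * f * tt + runif(1, 0, 2 * pi))
    x[, d] <- drift + rnorm(N, 0, cfg@noiseSd[mods[d]])
  }
  labelsVec <- integer(N)
  for (i in seq_len(nInst)) {
    k <- inst$class[i]; L <- inst$len[i]
    tpl <- templates[[k]]
    warped <- t(apply(tpl, 1L, function(ch)
      if (L == ncol(tpl)) ch else approx(seq_along(ch), ch, n = L)$y))
    span <- starts[i]:(starts[i] + L - 1L)
    x[span, ] <- x[span, ] + inst$amp[i] * t(warped)
    labelsVec[span] <- k
  }
  if (cfg@missingRate > 0) {
    target <- cfg@missingRate * N * D
    hidden <- 0
    while (hidden < target) {
      d <- sample.int(D, 1L)
      runLen <- sample(3:8, 1L)
      s <- sample.int(N - runLen, 1L)
      x[s:(s + runLen - 1L), d] <- NA_real_
      hidden <- hidden + runLen
    }
  }
  SensorRecording(x, labelsVec, sampleRate = fs,
                  channelNames = paste0(mods, "_", ave(seq_len(D), mods,
                                                       FUN = seq_along)),
                  modalityTags = mods)
}

#' Select the channels of given modality groups
#'
#' Returns the recording restricted to channels whose modality tag is in
#' \code{tags}, preserving channel order and labels. Used to reproduce
#' the sensor-fusion ladder (accelerometers alone, plus gyroscopes, plus
#' magnetometers).
#'
#' @param recording a \linkS4class{SensorRecording} with modality tags.
#' @param tags character vector of tags to keep.
#' @return a \linkS4class{SensorRecording} with the selected channels.
#' @export
modalitySubset <- function(recording, tags) {
  stopifnot(is(recording, "SensorRecording"))
  keep <- which(recording@modalityTags %in% tags)
  if (!length(keep))
    stop(sprintf("no channels match tags: %s", paste(tags, collapse = ", ")))
  SensorRecording(recording@samples[, keep, drop = FALSE],
                  recording@labels, recording@sampleRate,
                  channelNames = recording@channelNames[keep],
                  modalityTags = recording@modalityTags[keep])
}
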