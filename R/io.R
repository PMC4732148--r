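# File I/O: the whitespace-delimited sensor dialect (one row per time
# step, numeric channels plus an integer label column, "NaN" for missing
# samples), dataset manifests, key-value config files and the plain-text
# checkpoint archive.

#' Write a recording in the delimited sensor dialect
#'
#' One row per time step: the D channel values followed by the integer
#' label column, whitespace-separated, missing values as NaN. Values are
#' printed with 17 significant digits so a write/read round trip is
#' value-identical.
#'
#' @param recording a \linkS4class{SensorRecording}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeRecording <- function(recording, path) {
  stopifnot(is(recording, "SensorRecording"))
  x <- recording@samples
  lines <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(sprintf("%.17g", x[i, ]), sprintf("%d", recording@labels[i])),
          collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a recording from the delimited sensor dialect
#'
#' Reads a whitespace-delimited numeric table, selects the channel and
#' label columns, and maps the label values to contiguous 0-based class
#' ids. The mapping can be supplied (persisted from the training data, so
#' train and test agree) or computed; label value 0 always maps to class
#' 0 (Null). NaN tokens are kept as missing values for
#' \code{\link{interpolateMissing}}.
#'
#' @param path input file.
#' @param labelColumn 1-based index of the label column; default NULL
#'   means the last column.
#' @param channelColumns 1-based indices of the channel columns; default
#'   NULL means all columns except the label column.
#' @param labelMap optional named integer vector mapping original label
#'   values (names) to 0-based class ids, as returned by a previous call.
#' @param sampleRate sampling rate in Hz (default 30).
#' @param channelNames,modalityTags optional per-channel metadata.
#' @return list with \code{recording} (a \linkS4class{SensorRecording})
#'   and \code{labelMap} (the named integer vector used).
#' @export
readRecording <- function(path, labelColumn = NULL, channelColumns = NULL,
                          labelMap = NULL, sampleRate = 30,
                          channelNames = NULL, modalityTags = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- tryCatch(
    as.matrix(utils::read.table(path, header = FALSE,
                                colClasses = "numeric")),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e)))
  dimnames(tab) <- NULL
  if (is.null(labelColumn)) labelColumn <- ncol(tab)
  if (labelColumn < 1L || labelColumn > ncol(tab))
    stop(sprintf("label column %d outside the %d columns of %s",
                 labelColumn, ncol(tab), path))
  if (is.null(channelColumns))
    channelColumns <- setdiff(seq_len(ncol(tab)), labelColumn)
  if (any(channelColumns > ncol(tab)))
    stop("channel columns outside the file's columns")
  rawLabels <- tab[, labelColumn]
  if (anyNA(rawLabels)) stop("label column contains missing values")
  if (is.null(labelMap)) {
    vals <- sort(unique(rawLabels))
    vals <- c(0, setdiff(vals, 0))   # 0 (Null) always maps to class 0
    labelMap <- stats::setNames(seq_along(vals) - 1L, format(vals,
                                                             trim = TRUE))
  }
  idx <- match(format(rawLabels, trim = TRUE), names(labelMap))
  if (anyNA(idx))
    stop("unknown label values (not in the persisted label map): ",
         paste(unique(rawLabels[is.na(idx)]), collapse = ", "))
  rec <- SensorRecording(tab[, channelColumns, drop = FALSE],
                         unname(labelMap[idx]), sampleRate,
                         channelNames = channelNames,
                         modalityTags = modalityTags)
  list(recording = rec, labelMap = labelMap)
}

#' Persist or load a label map
#'
#' Two-column text sidecar (original value, 0-based class id) so training
#' and test runs agree on the class encoding.
#'
#' @param labelMap named integer vector (names = original label values).
#' @param path file path.
#' @return \code{writeLabelMap} returns the path invisibly;
#'   \code{readLabelMap} returns the named integer vector.
#' @export
writeLabelMap <- function(labelMap, path) {
  writeLines(sprintf("%s %d", names(labelMap), labelMap), path)
  invisible(path)
}

#' @rdname writeLabelMap
#' @export
readLabelMap <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           colClasses = c("character", "integer"))
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Read a dataset manifest
#'
#' Flat key-value text (\code{key = value} lines, \code{#} comments).
#' Recognised keys: \code{train}, \code{validation}, \code{test}
#' (recording files, repeatable, paths relative to the manifest),
#' \code{label_column}, \code{channels} (comma-separated indices or
#' \code{a:b} ranges), \code{sample_rate}, \code{modality_tags}
#' (comma-separated, one per channel). The same channel selection applies
#' to every file. An example mirroring a public 113-channel benchmark
#' layout ships in \code{inst/extdata}.
#'
#' @param path manifest file.
#' @return list with \code{files} (data.frame path, role),
#'   \code{labelColumn}, \code{channels}, \code{sampleRate},
#'   \code{modalityTags}.
#' @export
readManifest <- function(path) {
  kv <- readConfigFile(path)
  dir <- dirname(path)
  files <- data.frame(path = character(), role = character())
  for (role in c("train", "validation", "test")) {
    for (f in kv[names(kv) == role])
      files <- rbind(files,
                     data.frame(path = file.path(dir, f), role = role))
  }
  if (!any(files$role == "train") || !any(files$role == "test"))
    stop("manifest needs at least one train and one test recording")
  parseChannels <- function(s) {
    unlist(lapply(strsplit(s, ",")[[1L]], function(part) {
      part <- trimws(part)
      if (grepl(":", part)) {
        ab <- as.integer(strsplit(part, ":")[[1L]])
        ab[1L]:ab[2L]
      } else as.integer(part)
    }))
  }
  list(files = files,
       labelColumn = if ("label_column" %in% names(kv))
         as.integer(kv[["label_column"]]) else NULL,
       channels = if ("channels" %in% names(kv))
         parseChannels(kv[["channels"]]) else NULL,
       sampleRate = if ("sample_rate" %in% names(kv))
         as.numeric(kv[["sample_rate"]]) else 30,
       modalityTags = if ("modality_tags" %in% names(kv))
         trimws(strsplit(kv[["modality_tags"]], ",")[[1L]]) else NULL)
}

#' Read a flat key-value config file
#'
#' Lines of the form \code{key = value}; \code{#} starts a comment; keys
#' may repeat (all values are kept, in order).
#'
#' @param path file path.
#' @return named character vector.
#' @export
readConfigFile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  bad <- !grepl("=", lines, fixed = TRUE)
  if (any(bad)) stop("malformed config line: ", lines[bad][1L])
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  stats::setNames(vals, keys)
}

## ---- checkpoint archive ----

.writeArray <- function(con, name, x) {
  d <- if (is.null(dim(x))) length(x) else dim(x)
  writeLines(paste("param", name, length(d), paste(d, collapse = " ")), con)
  writeLines(paste(sprintf("%.17g", as.vector(x)), collapse = " "), con)
}

#' Save a model checkpoint as a plain-text archive
#'
#' Documented single-file format: a header with the spec fields and seed,
#' then one \code{param <layer>.<name> <ndim> <dims>} line plus one line
#' of whitespace-separated values per trainable array. Values use 17
#' significant digits, which round-trips IEEE doubles exactly, so
#' \code{loadModel(saveModel(m))} is bit-identical.
#'
#' @param model a \linkS4class{HARModel}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "HARModel"))
  sp <- model@spec
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("deepHAR-checkpoint 1",
               paste("variant", sp@variant),
               paste("nChannels", sp@nChannels),
               paste("nClasses", sp@nClasses),
               paste("windowLen", sp@windowLen),
               paste("kernelLen", sp@kernelLen),
               paste("nFilters", sp@nFilters),
               paste("nUnits", sp@nUnits),
               paste("nConvLayers", sp@nConvLayers),
               paste("seed", model@seed)), con)
  for (l in seq_along(model@layers)) {
    lay <- model@layers[[l]]
    for (nm in names(lay)) {
      if (!is.numeric(lay[[nm]])) next
      .writeArray(con, sprintf("%d.%s", l, nm), lay[[nm]])
    }
  }
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path a checkpoint written by \code{\link{saveModel}}.
#' @return a \linkS4class{HARModel}.
#' @export
loadModel <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1L], "deepHAR-checkpoint"))
    stop("not a deepHAR checkpoint: ", path)
  hdr <- list()
  i <- 2L
  while (!startsWith(lines[i], "param")) {
    kv <- strsplit(lines[i], " ", fixed = TRUE)[[1L]]
    hdr[[kv[1L]]] <- kv[2L]
    i <- i + 1L
  }
  sp <- modelSpec(hdr$variant, as.integer(hdr$nChannels),
                  as.integer(hdr$nClasses), as.integer(hdr$windowLen),
                  as.integer(hdr$kernelLen), as.integer(hdr$nFilters),
                  as.integer(hdr$nUnits), as.integer(hdr$nConvLayers))
  model <- buildModel(sp, as.integer(hdr$seed))
  while (i <= length(lines)) {
    parts <- strsplit(lines[i], " ", fixed = TRUE)[[1L]]
    stopifnot(parts[1L] == "param")
    name <- strsplit(parts[2L], ".", fixed = TRUE)[[1L]]
    l <- as.integer(name[1L]); nm <- name[2L]
    nd <- as.integer(parts[3L])
    d <- as.integer(parts[4L:(3L + nd)])
    vals <- as.numeric(strsplit(lines[i + 1L], " ", fixed = TRUE)[[1L]])
    if (length(vals) != prod(d))
      stop("corrupt checkpoint: wrong value count for ", parts[2L])
    if (nd > 1L) dim(vals) <- d
    model@layers[[l]][[nm]] <- vals
    i <- i + 2L
  }
  model
}
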