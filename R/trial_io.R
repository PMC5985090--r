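#' Construct an EEG trial
#'
#' An `eeg_trial` is the unit of acquisition: a labelled channels-by-samples
#' matrix in microvolts recorded at a fixed sampling rate. The channel set is
#' the fixed 14-electrode montage in [emotiv_channels]; a trial supplied in a
#' different channel order is re-ordered to it so downstream feature indices
#' are stable.
#'
#' @param data numeric matrix, channels x samples (microvolts). Rows may be
#'   named by channel; unnamed rows are taken to already be in canonical
#'   order.
#' @param fs sampling rate in Hz (default 128).
#' @param channels character vector of 14 channel names giving the row order
#'   of `data`; defaults to rownames or the canonical order.
#' @param label movement class, one of `"thumb"`, `"index"`, `"fist"`.
#' @param subject_category `"I"` (high-blink-rate subject), `"II"`, or
#'   `"unknown"`.
#' @return An object of class `eeg_trial`: list with elements `data`
#'   (canonically ordered 14 x N matrix), `fs`, `channels`, `label`,
#'   `subject_category`.
#' @examples
#' x <- matrix(rnorm(14 * 64), nrow = 14, dimnames = list(emotiv_channels))
#' tr <- eeg_trial(x, label = "thumb")
#' n_samples(tr)
#' @export
eeg_trial <- function(data, fs = default_fs, channels = NULL, label,
                      subject_category = "unknown") {
  data <- as.matrix(data)
  if (is.null(channels)) {
    channels <- if (!is.null(rownames(data))) rownames(data) else emotiv_channels
  }
  if (nrow(data) != length(emotiv_channels)) {
    stop("trial must have exactly ", length(emotiv_channels),
         " channels, got ", nrow(data), call. = FALSE)
  }
  if (!setequal(channels, emotiv_channels) || anyDuplicated(channels)) {
    stop("channel names must be a permutation of the Emotiv montage: ",
         paste(emotiv_channels, collapse = ","), call. = FALSE)
  }
  if (ncol(data) < chunk_samples) {
    stop("trial must contain at least ", chunk_samples,
         " samples per channel (one 250 ms chunk), got ", ncol(data),
         call. = FALSE)
  }
  if (!all(is.finite(data))) stop("trial contains non-finite samples", call. = FALSE)
  label <- match.arg(label, movement_classes)
  subject_category <- match.arg(subject_category, c("unknown", "I", "II"))
  data <- data[match(emotiv_channels, channels), , drop = FALSE]
  rownames(data) <- emotiv_channels
  structure(
    list(data = data, fs = fs, channels = emotiv_channels, label = label,
         subject_category = subject_category),
    class = "eeg_trial"
  )
}

#' @rdname eeg_trial
#' @param trial an `eeg_trial`.
#' @export
n_samples <- function(trial) ncol(trial$data)

#' @export
print.eeg_trial <- function(x, ...) {
  cat(sprintf("<eeg_trial> %d channels x %d samples @ %g Hz (%.2f s), label=%s, category=%s\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              x$label, x$subject_category))
  invisible(x)
}

#' Read an EEG trial from its text dialect
#'
#' Trial files are UTF-8 CSV with one self-describing header line
#' `#fs=128,label=thumb,category=II,channels=AF3;F7;...` followed by one row
#' of 14 comma-separated samples (microvolts) per time point, columns in the
#' header's channel order. Channel order is normalised to the canonical
#' montage on read.
#'
#' @param path path to a trial file.
#' @return An [eeg_trial].
#' @seealso [write_trial()]
#' @export
read_trial <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("malformed trial file (line 1): need a header and at least one sample row",
         call. = FALSE)
  }
  header <- lines[[1L]]
  if (!startsWith(header, "#")) {
    stop("malformed header (line 1): expected a line starting with '#'", call. = FALSE)
  }
  fields <- strsplit(sub("^#", "", header), ",", fixed = TRUE)[[1L]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed header (line 1): expected key=value fields", call. = FALSE)
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, `[[`, "", 2L)
  need <- c("fs", "label", "category", "channels")
  if (!all(need %in% keys)) {
    stop("malformed header (line 1): missing field(s) ",
         paste(setdiff(need, keys), collapse = ", "), call. = FALSE)
  }
  fs <- suppressWarnings(as.numeric(vals[keys == "fs"][1L]))
  if (!is.finite(fs) || fs <= 0) stop("malformed header (line 1): bad fs", call. = FALSE)
  channels <- strsplit(vals[keys == "channels"][1L], ";", fixed = TRUE)[[1L]]
  if (length(channels) != length(emotiv_channels)) {
    stop("wrong channel count (line 1): header declares ", length(channels),
         " channels, expected ", length(emotiv_channels), call. = FALSE)
  }
  body <- lines[-1L]
  rows <- strsplit(body, ",", fixed = TRUE)
  nfield <- vapply(rows, length, 1L)
  if (any(nfield != length(channels))) {
    i <- which(nfield != length(channels))[1L]
    stop(sprintf("wrong channel count (line %d): %d values, expected %d",
                 i + 1L, nfield[i], length(channels)), call. = FALSE)
  }
  vals_num <- suppressWarnings(vapply(rows, as.numeric, numeric(length(channels))))
  if (anyNA(vals_num)) {
    i <- which(apply(is.na(vals_num), 2L, any))[1L]
    stop(sprintf("non-numeric sample (line %d)", i + 1L), call. = FALSE)
  }
  # vals_num is channels x samples already (vapply binds row vectors as columns)
  eeg_trial(vals_num, fs = fs, channels = channels,
            label = vals[keys == "label"][1L],
            subject_category = vals[keys == "category"][1L])
}

#' Write an EEG trial in the text dialect
#'
#' Values are written with `digits` significant digits (default 6); a
#' written-then-read trial reproduces the in-memory matrix exactly at that
#' precision.
#'
#' @param trial an [eeg_trial].
#' @param path destination file path.
#' @param digits significant digits for samples (default 6).
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, digits = 6L) {
  stopifnot(inherits(trial, "eeg_trial"))
  header <- sprintf("#fs=%s,label=%s,category=%s,channels=%s",
                    format(trial$fs), trial$label, trial$subject_category,
                    paste(trial$channels, collapse = ";"))
  body <- apply(trial$data, 2L, function(col) {
    paste(formatC(col, digits = digits, format = "g"), collapse = ",")
  })
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write trial file: ", path, call. = FALSE))
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Replay a trial as the embedded 250 ms chunk loop
#'
#' The embedded decoder consumes one full 250 ms read (32 samples at 128 Hz)
#' at a time; `stream_chunks()` reproduces that loop, yielding consecutive
#' non-overlapping chunks. A trailing remainder shorter than one chunk is
#' discarded, never zero-padded.
#'
#' @param trial an [eeg_trial] (or any list with a channels x samples `data`
#'   matrix).
#' @param trial_id identifier stamped on each chunk (default `"trial"`).
#' @param samples_per_chunk chunk length in samples (default 32 = 250 ms at
#'   128 Hz).
#' @return List of chunks; each is a list with `data` (14 x 32 matrix),
#'   `trial_id`, `index` (1-based ordinal), and `label` when the trial
#'   carries one.
#' @examples
#' tr <- eeg_trial(matrix(rnorm(14 * 1280), 14,
#'                        dimnames = list(emotiv_channels)), label = "fist")
#' length(stream_chunks(tr))  # 40
#' @export
stream_chunks <- function(trial, trial_id = "trial",
                          samples_per_chunk = chunk_samples) {
  n <- ncol(trial$data)
  if (n < samples_per_chunk) {
    stop("empty stream: trial has ", n, " samples, shorter than one chunk (",
         samples_per_chunk, ")", call. = FALSE)
  }
  k <- n %/% samples_per_chunk
  lapply(seq_len(k), function(i) {
    idx <- ((i - 1L) * samples_per_chunk + 1L):(i * samples_per_chunk)
    list(data = trial$data[, idx, drop = FALSE], trial_id = trial_id,
         index = i, label = trial$label)
  })
}

#' Dataset sample bookkeeping
#'
#' Total sample count of a recorded dataset: trials x samples-per-movement x
#' movements. Used to validate manifests against the acquisition protocol
#' (e.g. 47 retained trials x 1280 samples x 3 movements = 180480 samples per
#' subject).
#'
#' @param n_trials number of retained trials.
#' @param samples_per_movement samples per movement segment (1280 for 10 s at
#'   128 Hz).
#' @param n_movements number of movement classes.
#' @return Integer-valued count.
#' @export
count_dataset_samples <- function(n_trials, samples_per_movement, n_movements) {
  args <- c(n_trials, samples_per_movement, n_movements)
  if (length(args) != 3L || !all(is.finite(args)) || any(args <= 0) ||
      any(args != round(args))) {
    stop("all counts must be positive integers", call. = FALSE)
  }
  n_trials * samples_per_movement * n_movements
}

#' Read and write dataset manifests
#'
#' A manifest lists one trial per line as `path,label`. Paths are stored
#' relative to the manifest's directory.
#'
#' @param paths character vector of trial file paths.
#' @param labels movement class per trial.
#' @param manifest_path manifest file location.
#' @return `write_manifest()` returns `manifest_path` invisibly;
#'   `read_manifest()` a data.frame with columns `path` (absolute) and
#'   `label`.
#' @export
write_manifest <- function(paths, labels, manifest_path) {
  stopifnot(length(paths) == length(labels))
  base <- normalizePath(dirname(manifest_path), mustWork = FALSE)
  rel <- vapply(paths, function(p) {
    p <- normalizePath(p, mustWork = FALSE)
    if (startsWith(p, paste0(base, "/"))) substring(p, nchar(base) + 2L) else p
  }, "")
  writeLines(paste(rel, labels, sep = ","), manifest_path)
  invisible(manifest_path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(manifest_path) {
  lines <- readLines(manifest_path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ",", fixed = TRUE)
  if (any(vapply(parts, length, 1L) != 2L)) {
    stop("malformed manifest: expected 'path,label' per line", call. = FALSE)
  }
  path <- vapply(parts, `[[`, "", 1L)
  abs <- ifelse(startsWith(path, "/"), path,
                file.path(normalizePath(dirname(manifest_path)), path))
  data.frame(path = abs, label = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}
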