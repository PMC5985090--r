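#' Map a decoded movement class to prosthesis motor states
#'
#' The prosthesis has two motors: one driving the thumb (the embedded
#' board's output pins 4/6) and one driving the fingers (pins 2/3). The
#' decoded class maps to their on/off states as: thumb -> (On, Off),
#' index -> (Off, On), fist -> (On, On).
#'
#' @param label movement class, one of `"thumb"`, `"index"`, `"fist"`.
#' @return A `motor_command`: list with `motor_thumb`, `motor_finger`
#'   (each `"On"`/`"Off"`) and `source_label`.
#' @export
to_motor_command <- function(label) {
  label <- match.arg(label, movement_classes)
  states <- switch(label,
                   thumb = c("On", "Off"),
                   index = c("Off", "On"),
                   fist  = c("On", "On"))
  structure(list(motor_thumb = states[1L], motor_finger = states[2L],
                 source_label = label),
            class = "motor_command")
}

#' @export
print.motor_command <- function(x, ...) {
  cat(sprintf("<motor_command> %s: thumb motor %s, finger motor %s\n",
              x$source_label, x$motor_thumb, x$motor_finger))
  invisible(x)
}

#' Command trace for a sequence of decoded chunks
#'
#' The desktop stand-in for the embedded system's motor-drive output: one
#' structured record per chunk instead of GPIO writes.
#'
#' @param chunk_ids identifiers, one per decoded chunk.
#' @param labels decoded movement class per chunk.
#' @return data.frame with columns `chunk_id`, `label`, `motor_thumb`,
#'   `motor_finger`.
#' @export
command_trace <- function(chunk_ids, labels) {
  stopifnot(length(chunk_ids) == length(labels))
  cmds <- lapply(as.character(labels), to_motor_command)
  data.frame(chunk_id = chunk_ids,
             label = as.character(labels),
             motor_thumb = vapply(cmds, `[[`, "", "motor_thumb"),
             motor_finger = vapply(cmds, `[[`, "", "motor_finger"),
             stringsAsFactors = FALSE)
}

#' @rdname command_trace
#' @param trace a command trace data.frame.
#' @param path CSV destination.
#' @export
write_command_trace <- function(trace, path) {
  write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Confusion matrix over the three movement classes
#'
#' Rows are true classes, columns predicted classes, both in the canonical
#' order thumb, index, fist; entry (i, j) counts chunks of true class i
#' predicted as class j.
#'
#' @param true_labels,predicted_labels equal-length label vectors.
#' @return 3 x 3 integer matrix of class `confusion_matrix` with dimnames
#'   `true` x `predicted`.
#' @export
confusion <- function(true_labels, predicted_labels) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels)) {
    stop("label sequences differ in length", call. = FALSE)
  }
  bad <- setdiff(unique(c(true_labels, predicted_labels)), movement_classes)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  tf <- factor(true_labels, levels = movement_classes)
  pf <- factor(predicted_labels, levels = movement_classes)
  cm <- unclass(table(true = tf, predicted = pf))
  storage.mode(cm) <- "integer"
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' @rdname confusion
#' @param counts 3 x 3 numeric matrix of counts, rows = true class in the
#'   order thumb, index, fist.
#' @export
as_confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3L, 3L)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("counts must be a 3 x 3 matrix of non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(true = movement_classes, predicted = movement_classes)
  structure(counts, class = c("confusion_matrix", "matrix"))
}

# nearest-integer rounding, halves away from zero (matches the reported
# percent tables, where R's round-half-even does not)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Per-class accuracy (recall) from a confusion matrix
#'
#' Recall per class: diagonal count over row sum, as a percentage. By
#' default each percentage is rounded to the nearest integer with halves
#' away from zero — the convention of the study's accuracy tables.
#'
#' @param cm a `confusion_matrix` (or 3 x 3 count matrix).
#' @param rounded round to integer percent (default TRUE); FALSE returns
#'   the exact percentages.
#' @return Named numeric vector of three percentages (thumb, index, fist).
#' @export
per_class_accuracy <- function(cm, rounded = TRUE) {
  if (!inherits(cm, "confusion_matrix")) cm <- as_confusion_matrix(cm)
  rs <- rowSums(cm)
  if (any(rs == 0)) {
    stop("empty row: every true class needs at least one test chunk", call. = FALSE)
  }
  acc <- diag(cm) / rs * 100
  names(acc) <- movement_classes
  if (rounded) round_half_away(acc) else acc
}

#' Macro mean accuracy from a confusion matrix
#'
#' Unweighted mean of the three un-rounded per-class recalls, then rounded
#' to the nearest integer percent (halves away from zero). Being a macro
#' average, it is invariant to per-class test-set size imbalance.
#'
#' @inheritParams per_class_accuracy
#' @return Single percentage.
#' @export
mean_accuracy <- function(cm, rounded = TRUE) {
  m <- mean(per_class_accuracy(cm, rounded = FALSE))
  if (rounded) round_half_away(m) else m
}

#' Evaluation report: confusion matrix plus accuracies
#'
#' Bundles the evaluation artifacts of a decoding run and renders them as
#' human-readable text or a JSON document.
#'
#' @param cm a `confusion_matrix`.
#' @return An `eval_report`: list with `confusion`, `per_class` (rounded
#'   integer percents) and `mean` (rounded macro mean percent).
#' @export
evaluation_report <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) cm <- as_confusion_matrix(cm)
  structure(list(confusion = cm,
                 per_class = per_class_accuracy(cm),
                 mean = mean_accuracy(cm)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Confusion matrix (rows = true, cols = predicted):\n")
  print(unclass(x$confusion))
  cat("\nPer-class accuracy: ",
      paste(sprintf("%s %d%%", names(x$per_class), as.integer(x$per_class)),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("Mean accuracy: %d%%\n", as.integer(x$mean)))
  invisible(x)
}

#' @rdname evaluation_report
#' @param report an `eval_report`.
#' @param path JSON destination.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(
    list(confusion = unclass(report$confusion),
         classes = movement_classes,
         per_class_percent = as.list(report$per_class),
         mean_percent = unname(report$mean)),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}
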