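#' Multichannel recording container
#'
#' A `recording` bundles a channels-by-samples matrix with its sampling
#' rate, channel labels, event annotations and subject metadata. It is the
#' raw unit of analysis: everything downstream (segment selection, source
#' estimation, spectra, connectivity) consumes recordings or windows cut
#' from them.
#'
#' @param data numeric matrix, channels x samples.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_labels character vector, one label per row of `data`.
#' @param annotations data frame with columns `onset` (s), `duration` (s)
#'   and `label` (e.g. `"SWD"`, `"artifact"`); may have zero rows.
#' @param subject_id subject identifier.
#' @param group `"patient"` or `"control"`.
#'
#' @return An object of class `recording`.
#' @export
recording <- function(data, sampling_rate, channel_labels = rownames(data),
                      annotations = empty_annotations(),
                      subject_id = "s01", group = c("patient", "control")) {
  group <- match.arg(group)
  data <- as.matrix(data)
  assert_that(is.numeric(data), "data must be numeric")
  assert_that(all(is.finite(data)), "data contains non-finite samples")
  assert_that(is.numeric(sampling_rate) && length(sampling_rate) == 1L &&
                sampling_rate > 0, "sampling_rate must be a positive scalar")
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(nrow(data)))
  }
  assert_that(length(channel_labels) == nrow(data),
              "channel count must equal label count")
  annotations <- validate_annotations(annotations,
                                      total = ncol(data) / sampling_rate)
  rownames(data) <- channel_labels
  structure(
    list(data = data, sampling_rate = sampling_rate,
         channel_labels = channel_labels, annotations = annotations,
         subject_id = subject_id, group = group),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s (%s): %d channels x %d samples @ %g Hz, %d events\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data),
              x$sampling_rate, nrow(x$annotations)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param x a `recording`.
#' @return length in seconds.
#' @export
duration <- function(x) ncol(x$data) / x$sampling_rate

empty_annotations <- function() {
  data.frame(onset = numeric(0), duration = numeric(0),
             label = character(0), stringsAsFactors = FALSE)
}

# Annotation contract: onset >= 0, duration > 0, sorted by onset, spans of
# the same label non-overlapping and inside [0, total] when total is known.
validate_annotations <- function(ann, total = NULL) {
  assert_that(is.data.frame(ann) &&
                all(c("onset", "duration", "label") %in% names(ann)),
              "annotations need columns onset, duration, label")
  if (nrow(ann) == 0L) return(empty_annotations())
  assert_that(all(ann$onset >= 0), "annotation onsets must be >= 0")
  assert_that(all(ann$duration > 0), "annotation durations must be > 0")
  ann <- ann[order(ann$onset), , drop = FALSE]
  rownames(ann) <- NULL
  for (lab in unique(ann$label)) {
    a <- ann[ann$label == lab, , drop = FALSE]
    if (nrow(a) > 1L) {
      ends <- a$onset + a$duration
      assert_that(all(a$onset[-1L] >= ends[-nrow(a)] - 1e-9),
                  sprintf("overlapping '%s' annotations", lab))
    }
  }
  if (!is.null(total)) {
    assert_that(all(ann$onset + ann$duration <= total + 1e-9),
                "annotation spans exceed recording length")
  }
  ann
}

annotation_spans <- function(rec, label) {
  a <- rec$annotations
  a <- a[a$label == label, , drop = FALSE]
  merge_intervals(a$onset, a$onset + a$duration)
}

#' Write a recording to a plain-text container
#'
#' The container is a TSV sample matrix (`<prefix>_data.tsv`, one column
#' per channel), a JSON sidecar (`<prefix>.json`) with the sampling rate
#' and subject metadata, and a BIDS-style events table
#' (`<prefix>_events.tsv` with columns `onset`, `duration`, `trial_type`,
#' in seconds from recording start).
#'
#' @param rec a `recording`.
#' @param prefix path prefix (no extension).
#' @return `prefix`, invisibly.
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "recording"))
  d <- as.data.frame(t(rec$data))
  names(d) <- rec$channel_labels
  utils::write.table(d, paste0(prefix, "_data.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  meta <- list(sampling_rate = rec$sampling_rate,
               channel_labels = rec$channel_labels,
               subject_id = rec$subject_id, group = rec$group)
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  ev <- rec$annotations
  ev <- data.frame(onset = ev$onset, duration = ev$duration,
                   trial_type = ev$label)
  utils::write.table(ev, paste0(prefix, "_events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' Read a recording written by [write_recording()]
#' @param prefix path prefix used when writing.
#' @return a `recording`.
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  d <- utils::read.table(paste0(prefix, "_data.tsv"), header = TRUE,
                         sep = "\t", check.names = FALSE)
  ev <- utils::read.table(paste0(prefix, "_events.tsv"), header = TRUE,
                          sep = "\t",
                          colClasses = c("numeric", "numeric", "character"))
  ann <- data.frame(onset = ev$onset, duration = ev$duration,
                    label = ev$trial_type)
  recording(t(as.matrix(d)), meta$sampling_rate,
            channel_labels = meta$channel_labels, annotations = ann,
            subject_id = meta$subject_id, group = meta$group)
}
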