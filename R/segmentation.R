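#' Segment-selection rules
#'
#' The selection rules for cutting condition-labelled windows out of an
#' annotated recording: seizures strictly longer than
#' `min_seizure_duration` contribute one centered `ictal_window`; maximal
#' SWD-free, artifact-free spans of at least
#' `min_clean_span + 2 * guard_interval` contribute one centered
#' `interictal_window` (so the window sits more than `guard_interval`
#' from the nearest seizure on each side); control recordings contribute
#' `control_segments_per_subject` non-overlapping `control_window`s,
#' earliest first. Duration thresholds are read strictly ("longer than").
#'
#' @param min_seizure_duration s, default 10.
#' @param ictal_window s, default 5 (centered in the seizure).
#' @param min_clean_span s, default 30.
#' @param guard_interval s, default 30 (before and after).
#' @param interictal_window s, default 30 (centered in the clean span).
#' @param control_window s, default 30.
#' @param control_segments_per_subject count, default 2.
#'
#' @return An object of class `segment_rules`.
#' @export
segment_rules <- function(min_seizure_duration = 10, ictal_window = 5,
                          min_clean_span = 30, guard_interval = 30,
                          interictal_window = 30, control_window = 30,
                          control_segments_per_subject = 2) {
  vals <- c(min_seizure_duration, ictal_window, min_clean_span,
            guard_interval, interictal_window, control_window)
  assert_that(all(vals > 0), "all rule durations must be > 0")
  assert_that(ictal_window <= min_seizure_duration,
              "ictal_window must not exceed min_seizure_duration")
  assert_that(interictal_window <= min_clean_span,
              "interictal_window must not exceed min_clean_span")
  assert_that(control_segments_per_subject >= 1,
              "control_segments_per_subject must be >= 1")
  structure(list(min_seizure_duration = min_seizure_duration,
                 ictal_window = ictal_window,
                 min_clean_span = min_clean_span,
                 guard_interval = guard_interval,
                 interictal_window = interictal_window,
                 control_window = control_window,
                 control_segments_per_subject = control_segments_per_subject),
            class = "segment_rules")
}

new_data_segment <- function(data, sampling_rate, condition, subject,
                             group, span) {
  structure(list(data = data, sampling_rate = sampling_rate,
                 condition = condition, subject = subject, group = group,
                 span = span),
            class = "data_segment")
}

#' @export
print.data_segment <- function(x, ...) {
  cat(sprintf("<data_segment> %s %s [%.2f, %.2f) s, %d ch @ %g Hz\n",
              x$subject, x$condition, x$span[1], x$span[2],
              nrow(x$data), x$sampling_rate))
  invisible(x)
}

# Cut [start, start + width) seconds as an exact number of samples.
cut_span <- function(rec, start, width, condition) {
  fs <- rec$sampling_rate
  i0 <- round(start * fs) + 1L
  nsmp <- round(width * fs)
  new_data_segment(rec$data[, i0:(i0 + nsmp - 1L), drop = FALSE], fs,
                   condition, rec$subject_id, rec$group,
                   span = c(start, start + width))
}

#' Notch powerline frequencies out of a recording
#'
#' Zero-phase (forward–backward) second-order Butterworth band-stop
#' sections at `base` Hz and, optionally, each harmonic below Nyquist.
#' The default 2 Hz stop width attenuates the line frequency by well over
#' 20 dB while leaving passband power essentially untouched.
#'
#' @param rec a `recording`.
#' @param base line frequency in Hz (default 50).
#' @param include_harmonics filter harmonics of `base` below Nyquist too.
#' @param width stopband width in Hz (default 2).
#' @return The filtered `recording`.
#' @export
notch_filter <- function(rec, base = 50, include_harmonics = TRUE,
                         width = 2) {
  stopifnot(inherits(rec, "recording"))
  nyq <- rec$sampling_rate / 2
  assert_that(base < nyq, sprintf("notch base %g Hz is not below Nyquist (%g Hz)",
                                  base, nyq))
  freqs <- if (include_harmonics) {
    seq(base, nyq - width, by = base)
  } else base
  data <- rec$data
  for (f in freqs) {
    bf <- signal::butter(2, c(f - width / 2, f + width / 2) / nyq,
                         type = "stop")
    for (ch in seq_len(nrow(data))) {
      data[ch, ] <- signal::filtfilt(bf, data[ch, ])
    }
  }
  rec$data <- data
  rec
}

#' Maximal artifact-free spans of a recording
#'
#' Returns the complement of the `artifact` annotations within the
#' recording: the maximal set of spans not intersecting any artifact,
#' sorted and non-overlapping. A recording without artifacts yields one
#' full-length span.
#'
#' @param rec a `recording`.
#' @return Data frame with columns `start`, `end` (seconds).
#' @export
discard_artifacts <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  spans <- complement_intervals(annotation_spans(rec, "artifact"),
                                duration(rec))
  data.frame(start = unname(spans[, "start"]),
             end = unname(spans[, "end"]))
}

# Spans free of both artifacts and SWDs.
clean_spans <- function(rec) {
  bad <- rbind(annotation_spans(rec, "artifact"),
               annotation_spans(rec, "SWD"))
  bad <- merge_intervals(bad[, 1], bad[, 2])
  spans <- complement_intervals(bad, duration(rec))
  data.frame(start = unname(spans[, "start"]),
             end = unname(spans[, "end"]))
}

span_intersects <- function(start, end, spans) {
  if (nrow(spans) == 0L) return(FALSE)
  any(start < spans[, "end"] & end > spans[, "start"])
}

#' Select ictal segments
#'
#' Each seizure (SWD annotation) strictly longer than
#' `min_seizure_duration` yields the `ictal_window` centered at the
#' seizure midpoint — the middle of the discharge, where the
#' electrographic seizure is unambiguous. Seizures at the rule threshold
#' or shorter yield nothing; windows that would cross a recording edge or
#' an artifact are skipped with a warning.
#'
#' @param rec a `recording` with SWD annotations.
#' @param rules a [segment_rules()].
#' @return List of `data_segment`s (possibly empty).
#' @export
select_ictal <- function(rec, rules = segment_rules()) {
  stopifnot(inherits(rec, "recording"))
  sw <- rec$annotations[rec$annotations$label == "SWD", , drop = FALSE]
  art <- annotation_spans(rec, "artifact")
  out <- list()
  for (i in seq_len(nrow(sw))) {
    if (!(sw$duration[i] > rules$min_seizure_duration)) next
    mid <- sw$onset[i] + sw$duration[i] / 2
    start <- mid - rules$ictal_window / 2
    end <- start + rules$ictal_window
    if (start < 0 || end > duration(rec)) {
      warning(sprintf("ictal window [%.1f, %.1f) crosses recording edge; seizure skipped",
                      start, end))
      next
    }
    if (span_intersects(start, end, art)) {
      warning(sprintf("ictal window [%.1f, %.1f) intersects an artifact; seizure skipped",
                      start, end))
      next
    }
    out[[length(out) + 1L]] <- cut_span(rec, start, rules$ictal_window,
                                        "ictal")
  }
  out
}

#' Select interictal segments
#'
#' For each maximal SWD-free, artifact-free span whose length is at least
#' `min_clean_span + 2 * guard_interval` (90 s at the defaults), the
#' centered `interictal_window` is emitted; centering places the window
#' more than `guard_interval` from the nearest seizure on both sides.
#' Recording edges count as valid guards.
#'
#' @inheritParams select_ictal
#' @return List of `data_segment`s (possibly empty).
#' @export
select_interictal <- function(rec, rules = segment_rules()) {
  stopifnot(inherits(rec, "recording"))
  need <- rules$min_clean_span + 2 * rules$guard_interval
  spans <- clean_spans(rec)
  out <- list()
  for (i in seq_len(nrow(spans))) {
    len <- spans$end[i] - spans$start[i]
    if (len < need) next
    start <- spans$start[i] + (len - rules$interictal_window) / 2
    out[[length(out) + 1L]] <- cut_span(rec, start,
                                        rules$interictal_window,
                                        "interictal")
  }
  out
}

#' Select control segments
#'
#' `control_segments_per_subject` non-overlapping, artifact-free
#' `control_window`s, tiled earliest-first across the artifact-free
#' spans. If fewer windows fit, all available are returned with a
#' warning.
#'
#' @inheritParams select_ictal
#' @return List of `data_segment`s.
#' @export
select_control <- function(rec, rules = segment_rules()) {
  stopifnot(inherits(rec, "recording"))
  spans <- discard_artifacts(rec)
  out <- list()
  for (i in seq_len(nrow(spans))) {
    start <- spans$start[i]
    while (start + rules$control_window <= spans$end[i] + 1e-9 &&
           length(out) < rules$control_segments_per_subject) {
      out[[length(out) + 1L]] <- cut_span(rec, start,
                                          rules$control_window, "control")
      start <- start + rules$control_window
    }
    if (length(out) >= rules$control_segments_per_subject) break
  }
  if (length(out) < rules$control_segments_per_subject) {
    warning(sprintf("only %d of %d control windows available for %s",
                    length(out), rules$control_segments_per_subject,
                    rec$subject_id))
  }
  out
}

#' Segment a recording according to its group
#'
#' Control recordings yield control segments; patient recordings yield
#' ictal and interictal segments.
#'
#' @inheritParams select_ictal
#' @return List of `data_segment`s.
#' @export
segment_recording <- function(rec, rules = segment_rules()) {
  if (rec$group == "control") {
    select_control(rec, rules)
  } else {
    c(select_ictal(rec, rules), select_interictal(rec, rules))
  }
}

#' Tabulate a list of segments
#'
#' @param segments list of `data_segment`s.
#' @return Data frame with `subject`, `group`, `condition`, `start`,
#'   `end` (seconds).
#' @export
segment_manifest <- function(segments) {
  if (length(segments) == 0L) {
    return(data.frame(subject = character(0), group = character(0),
                      condition = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  do.call(rbind, lapply(segments, function(s)
    data.frame(subject = s$subject, group = s$group,
               condition = s$condition, start = s$span[1],
               end = s$span[2])))
}
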