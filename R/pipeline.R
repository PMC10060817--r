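#' End-to-end pipeline configuration
#'
#' Bundles the stage settings: the synthetic cohort generator, the
#' segment-selection rules, the band table, Welch settings, the
#' connectivity options and the statistics options. All defaults mirror
#' the analysis conventions used throughout the package: 50 Hz notch,
#' 5 s / 50% Welch windows, 1–90 Hz normalization, six canonical bands,
#' 1 s transient trim, alpha 0.05.
#'
#' @param synthetic a [synthetic_config()].
#' @param rules a [segment_rules()].
#' @param bands band table (default [canonical_bands()]).
#' @param welch_window,welch_overlap Welch settings (5 s, 0.5).
#' @param norm_range relative-PSD normalization range, Hz.
#' @param notch_base powerline base frequency, Hz.
#' @param conn_trim transient trim for connectivity, s.
#' @param rectify report absolute AEC-c values (default FALSE).
#' @param alpha significance level after FDR.
#' @param per_subject average observations within subject before testing.
#' @param seed master seed; overrides `synthetic$seed` when given.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = synthetic_config(),
                            rules = segment_rules(),
                            bands = canonical_bands(),
                            welch_window = 5, welch_overlap = 0.5,
                            norm_range = c(1, 90), notch_base = 50,
                            conn_trim = 1, rectify = FALSE, alpha = 0.05,
                            per_subject = FALSE, seed = NULL) {
  if (!is.null(seed)) synthetic$seed <- as.integer(seed)
  validate_bands(bands)
  structure(list(synthetic = synthetic, rules = rules, bands = bands,
                 welch_window = welch_window, welch_overlap = welch_overlap,
                 norm_range = norm_range, notch_base = notch_base,
                 conn_trim = conn_trim, rectify = rectify, alpha = alpha,
                 per_subject = per_subject, seed = synthetic$seed),
            class = "pipeline_config")
}

pipeline_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[dmnmeg] %s", sprintf(fmt, ...)))
}

#' Run the full pipeline on a synthetic cohort
#'
#' Simulate each subject, notch-filter, cut condition-labelled segments,
#' compute relative band power per segment, compute per-band AEC-c
#' adjacencies with node strengths, and compare conditions with
#' Kruskal–Wallis + FDR. Subjects are processed one at a time, so memory
#' stays proportional to a single recording. All randomness derives from
#' the configuration seed: identical configuration and seed give
#' bit-identical output tables.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory; created if missing. `NULL` skips all
#'   file output.
#' @param verbose log stage progress and timings (default TRUE).
#' @return (Invisibly) a list with `manifest`, `segments`, `band_power`,
#'   `node_strength`, `measures`, `stats`, `difference_maps` and
#'   `mean_adjacency` (per condition and band).
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  syn <- config$synthetic
  rois <- make_roi_set()
  man <- cohort_manifest(syn)
  pipeline_log(verbose, "cohort: %d patients, %d controls, seed %d",
               syn$n_patients, syn$n_controls, syn$seed)

  seg_rows <- list(); pow_rows <- list(); conn_rows <- list()
  adj_acc <- list()   # running sums of adjacencies per condition x band
  adj_n <- list()
  for (i in seq_len(nrow(man))) {
    rec <- simulate_subject(syn, i, rois = rois)
    rec <- notch_filter(rec, base = config$notch_base)
    segs <- segment_recording(rec, config$rules)
    if (length(segs) == 0L) next
    seg_rows[[length(seg_rows) + 1L]] <- segment_manifest(segs)
    for (s in segs) {
      sp <- welch_psd(s, window_s = config$welch_window,
                      overlap = config$welch_overlap)
      sp <- relative_psd(sp, config$norm_range)
      bp <- band_power(sp, config$bands)
      bp$condition <- s$condition; bp$subject <- s$subject
      bp$start <- s$span[1]
      pow_rows[[length(pow_rows) + 1L]] <- bp
      for (b in seq_len(nrow(config$bands))) {
        cm <- adjacency(s, config$bands[b, ], n_roi = nrow(rois),
                        trim = config$conn_trim, rectify = config$rectify)
        key <- paste(s$condition, config$bands$name[b], sep = ".")
        if (is.null(adj_acc[[key]])) {
          adj_acc[[key]] <- cm$aecc; adj_n[[key]] <- 1L
        } else {
          adj_acc[[key]] <- adj_acc[[key]] + cm$aecc
          adj_n[[key]] <- adj_n[[key]] + 1L
        }
        conn_rows[[length(conn_rows) + 1L]] <- data.frame(
          condition = s$condition, subject = s$subject,
          start = s$span[1], roi = cm$labels,
          band = config$bands$name[b],
          node_strength = unname(cm$node_strength),
          relative_node_strength = unname(cm$relative_node_strength))
      }
    }
    pipeline_log(verbose, "subject %s: %d segments", man$subject_id[i],
                 length(segs))
  }
  segments <- do.call(rbind, seg_rows)
  power_tbl <- do.call(rbind, pow_rows)
  conn_tbl <- do.call(rbind, conn_rows)
  pipeline_log(verbose, "segments total: %d (%s)", nrow(segments),
               paste(sprintf("%s=%d", names(table(segments$condition)),
                             table(segments$condition)), collapse = ", "))

  measures <- rbind(
    data.frame(condition = power_tbl$condition, subject = power_tbl$subject,
               roi = power_tbl$roi, band = power_tbl$band,
               measure = "rel_power", value = power_tbl$power),
    data.frame(condition = conn_tbl$condition, subject = conn_tbl$subject,
               roi = conn_tbl$roi, band = conn_tbl$band,
               measure = "node_strength", value = conn_tbl$node_strength),
    data.frame(condition = conn_tbl$condition, subject = conn_tbl$subject,
               roi = conn_tbl$roi, band = conn_tbl$band,
               measure = "relative_node_strength",
               value = conn_tbl$relative_node_strength))

  conds <- unique(measures$condition)
  want <- list(c("ictal", "interictal"), c("interictal", "control"))
  contrasts <- Filter(function(p) all(p %in% conds), want)
  stat_res <- NULL
  if (length(conds) >= 2L) {
    stat_res <- compare_conditions(measures, contrasts = contrasts,
                                   alpha = config$alpha,
                                   per_subject = config$per_subject)
    pipeline_log(verbose, "stats: %d cells tested, %d significant",
                 sum(!is.na(stat_res$stats$p_raw)),
                 sum(stat_res$stats$significant, na.rm = TRUE))
  } else {
    pipeline_log(verbose, "stats skipped: single condition")
  }

  mean_adj <- lapply(names(adj_acc), function(k)
    adj_acc[[k]] / adj_n[[k]])
  names(mean_adj) <- names(adj_acc)

  result <- list(manifest = man, segments = segments,
                 band_power = power_tbl, node_strength = conn_tbl,
                 measures = measures,
                 stats = if (!is.null(stat_res)) stat_res$stats else NULL,
                 difference_maps = if (!is.null(stat_res))
                   stat_res$difference_maps else NULL,
                 mean_adjacency = mean_adj, config = config)

  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  pipeline_log(verbose, "done in %.1f s",
               as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(result)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(result$manifest, file.path(out_dir, "manifest.tsv"))
  write_tsv(result$segments, file.path(out_dir, "segments.tsv"))
  write_tsv(result$band_power, file.path(out_dir, "band_power.tsv"))
  write_tsv(result$node_strength, file.path(out_dir, "node_strength.tsv"))
  if (!is.null(result$stats)) {
    write_tsv(result$stats, file.path(out_dir, "stats.tsv"))
    for (nm in names(result$difference_maps)) {
      m <- result$difference_maps[[nm]]
      write_tsv(data.frame(roi = rownames(m), as.data.frame(m),
                           check.names = FALSE),
                file.path(out_dir, sprintf("diffmap_%s.tsv", nm)))
    }
  }
  for (nm in names(result$mean_adjacency)) {
    m <- result$mean_adjacency[[nm]]
    write_tsv(data.frame(roi = rownames(m), as.data.frame(m),
                         check.names = FALSE),
              file.path(out_dir, sprintf("adjacency_%s.tsv", nm)))
  }
  cfg <- result$config
  snapshot <- list(seed = cfg$seed,
                   notch_base = cfg$notch_base,
                   welch_window = cfg$welch_window,
                   welch_overlap = cfg$welch_overlap,
                   norm_range = cfg$norm_range,
                   conn_trim = cfg$conn_trim, rectify = cfg$rectify,
                   alpha = cfg$alpha, per_subject = cfg$per_subject,
                   bands = as.list(stats::setNames(
                     paste(cfg$bands$low, cfg$bands$high, sep = "-"),
                     cfg$bands$name)),
                   synthetic = list(
                     sampling_rate = cfg$synthetic$sampling_rate,
                     epoch_length = cfg$synthetic$epoch_length,
                     n_epochs_per_subject = cfg$synthetic$n_epochs_per_subject,
                     n_patients = cfg$synthetic$n_patients,
                     n_controls = cfg$synthetic$n_controls,
                     swd_rate = cfg$synthetic$swd_rate,
                     swd_fundamental = cfg$synthetic$swd_fundamental,
                     seed = cfg$synthetic$seed))
  yaml::write_yaml(snapshot, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
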