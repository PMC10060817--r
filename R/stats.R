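#' Kruskal–Wallis rank test
#'
#' Thin wrapper around [stats::kruskal.test()] (midranks, standard tie
#' correction, chi-square approximation with k-1 degrees of freedom)
#' that enforces the module contract: every group non-empty, and the
#' fully tied degenerate case (no rank variation) reported as H = 0 with
#' p = 1 instead of an error.
#'
#' @param groups list of two or more numeric vectors.
#' @return List with `statistic` (H) and `p`.
#' @export
kruskal_wallis <- function(groups) {
  assert_that(is.list(groups) && length(groups) >= 2L,
              "need at least two groups")
  assert_that(all(vapply(groups, length, integer(1)) > 0L),
              "every group must be non-empty")
  pooled <- unlist(groups)
  assert_that(all(is.finite(pooled)), "groups contain non-finite values")
  if (length(unique(pooled)) == 1L) {
    return(list(statistic = 0, p = 1))
  }
  kt <- stats::kruskal.test(groups)
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Benjamini–Hochberg false-discovery-rate correction
#'
#' Step-up BH adjustment via [stats::p.adjust()]; rejection at
#' `q < alpha`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return List with `q` (adjusted values) and `reject` (logical flags).
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  assert_that(is.numeric(p) && all(p >= 0 & p <= 1),
              "p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  list(q = q, reject = q < alpha)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson statistic without continuity correction, one degree of
#' freedom — the variant appropriate for comparing a sex-by-group
#' contingency table between cohorts.
#'
#' @param table 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @return List with `statistic` and `p`.
#' @export
chi_square_2x2 <- function(table) {
  table <- as.matrix(table)
  assert_that(all(dim(table) == c(2L, 2L)), "table must be 2x2")
  assert_that(all(table >= 0) && all(table == round(table)),
              "counts must be non-negative integers")
  assert_that(all(rowSums(table) > 0) && all(colSums(table) > 0),
              "all margins must be positive")
  ct <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(ct$statistic), p = ct$p.value)
}

#' Compare measures across recording conditions
#'
#' For every (measure, ROI, band) cell, runs the omnibus Kruskal–Wallis
#' test across all conditions plus a two-group Kruskal–Wallis test for
#' each requested contrast, then applies Benjamini–Hochberg FDR within
#' each (measure, contrast) family across the ROI-by-band cells.
#' Difference maps hold the difference of condition medians (first
#' condition minus second) per cell.
#'
#' @param measures data frame with columns `condition`, `subject`,
#'   `roi`, `band`, `measure`, `value` (one row per observation, e.g.
#'   per segment).
#' @param contrasts list of length-2 character vectors naming condition
#'   pairs; the default tests ictal vs. interictal and interictal vs.
#'   control.
#' @param alpha significance level after FDR (default 0.05).
#' @param per_subject average observations within subject before testing
#'   (default FALSE: observations are per dataset/segment).
#' @return List with `stats` (tidy table: `measure`, `contrast`, `roi`,
#'   `band`, group medians, `median_diff`, `statistic`, `p_raw`,
#'   `q_fdr`, `significant`) and `difference_maps` (per measure and
#'   contrast, an ROI-by-band matrix of median differences).
#' @export
compare_conditions <- function(measures,
                               contrasts = list(c("ictal", "interictal"),
                                                c("interictal", "control")),
                               alpha = 0.05, per_subject = FALSE) {
  need <- c("condition", "subject", "roi", "band", "measure", "value")
  assert_that(all(need %in% names(measures)),
              paste("measures needs columns:", paste(need, collapse = ", ")))
  if (per_subject) {
    measures <- stats::aggregate(
      value ~ condition + subject + roi + band + measure, data = measures,
      FUN = mean)
  }
  conditions <- unique(measures$condition)
  rois <- unique(measures$roi)
  bands <- unique(measures$band)
  rows <- list()
  maps <- list()
  for (m in unique(measures$measure)) {
    dm <- measures[measures$measure == m, , drop = FALSE]
    fams <- c(list(conditions), contrasts)
    names(fams) <- c("omnibus",
                     vapply(contrasts, paste, character(1), collapse = "_vs_"))
    for (fam in names(fams)) {
      conds <- fams[[fam]]
      fam_rows <- list()
      for (r in rois) for (b in bands) {
        cell <- dm[dm$roi == r & dm$band == b, , drop = FALSE]
        gr <- lapply(conds, function(cc) cell$value[cell$condition == cc])
        sizes <- vapply(gr, length, integer(1))
        med <- vapply(gr, function(v)
          if (length(v)) stats::median(v) else NA_real_, numeric(1))
        names(med) <- conds
        if (any(sizes < 2L)) {
          warning(sprintf("cell (%s, %s, %s, %s) has a condition with < 2 observations; excluded from FDR family",
                          m, fam, r, b))
          kw <- list(statistic = NA_real_, p = NA_real_)
        } else {
          kw <- kruskal_wallis(gr)
        }
        fam_rows[[length(fam_rows) + 1L]] <- data.frame(
          measure = m, contrast = fam, roi = r, band = b,
          median_1 = med[[1L]],
          median_2 = if (length(med) >= 2L) med[[2L]] else NA_real_,
          median_3 = if (length(med) >= 3L) med[[3L]] else NA_real_,
          median_diff = if (length(med) == 2L) med[[1L]] - med[[2L]]
            else NA_real_,
          statistic = kw$statistic, p_raw = kw$p)
      }
      fr <- do.call(rbind, fam_rows)
      ok <- !is.na(fr$p_raw)
      fr$q_fdr <- NA_real_
      if (any(ok)) {
        adj <- fdr_bh(fr$p_raw[ok], alpha)
        fr$q_fdr[ok] <- adj$q
      }
      fr$significant <- !is.na(fr$q_fdr) & fr$q_fdr < alpha
      rows[[length(rows) + 1L]] <- fr
      if (fam != "omnibus") {
        mp <- matrix(NA_real_, length(rois), length(bands),
                     dimnames = list(rois, bands))
        st <- matrix("", length(rois), length(bands),
                     dimnames = list(rois, bands))
        for (k in seq_len(nrow(fr))) {
          mp[fr$roi[k], fr$band[k]] <- fr$median_diff[k]
          st[fr$roi[k], fr$band[k]] <-
            if (isTRUE(fr$significant[k])) "*" else ""
        }
        attr(mp, "stars") <- st
        maps[[paste(m, fam, sep = ".")]] <- mp
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(stats = out, difference_maps = maps)
}
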