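#' The 12-region default-mode-network ROI set
#'
#' The default mode network is summarized by six bilateral regions: medial
#' frontal cortex (MFC), posterior cingulate cortex (PCC), precuneus (PCu),
#' lateral temporal lobe (LTL), medial temporal lobe (MTL) and inferior
#' parietal lobe (IPL) — twelve regions of interest in total, six per
#' hemisphere.
#'
#' Without a table, the packaged defaults are returned. Their MNI
#' coordinates are *synthetic placeholders* (plausible centroids, shipped
#' in `inst/extdata/dmn_rois_synthetic.tsv`), intended only to give the
#' ROI set a concrete geometry; supply your own table to use study
#' coordinates. A user table is tab-separated with columns `label`,
#' `region`, `hemisphere`, `x`, `y`, `z` (MNI mm).
#'
#' @param coordinate_table optional path to a TSV file as described above.
#'
#' @return A data frame of class `roi_set` with 12 rows and columns
#'   `label`, `region`, `hemisphere`, `x`, `y`, `z`.
#' @export
make_roi_set <- function(coordinate_table = NULL) {
  path <- coordinate_table %||%
    system.file("extdata", "dmn_rois_synthetic.tsv", package = "dmnmeg",
                mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  validate_roi_set(tab)
}

validate_roi_set <- function(tab) {
  need <- c("label", "region", "hemisphere", "x", "y", "z")
  assert_that(all(need %in% names(tab)),
              paste("ROI table needs columns:", paste(need, collapse = ", ")))
  assert_that(nrow(tab) == 12L,
              sprintf("ROI table must have 12 rows, found %d", nrow(tab)))
  assert_that(!anyDuplicated(tab$label), "ROI labels must be unique")
  assert_that(all(tab$hemisphere %in% c("left", "right")),
              "hemisphere must be 'left' or 'right'")
  assert_that(sum(tab$hemisphere == "left") == 6L &&
                sum(tab$hemisphere == "right") == 6L,
              "ROI set must have 6 left and 6 right regions")
  key <- paste(tab$region, tab$hemisphere)
  assert_that(!anyDuplicated(key),
              "each region must appear exactly once per hemisphere")
  assert_that(all(is.finite(tab$x)) && all(is.finite(tab$y)) &&
                all(is.finite(tab$z)), "ROI coordinates must be finite")
  tab <- tab[order(match(tab$region, unique(tab$region)),
                   tab$hemisphere), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("roi_set", "data.frame")
  tab
}
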