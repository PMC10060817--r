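#' Forward model for toy-scale source estimation
#'
#' Wraps an explicit sensors-by-sources gain matrix and a
#' symmetric-positive-definite sensor noise covariance. Orientation is
#' handled upstream: each source is a single signed scalar amplitude.
#'
#' @param gain numeric matrix, sensors x sources.
#' @param noise_cov sensors x sensors SPD matrix; `NULL` means identity.
#' @param source_labels optional labels for the source columns.
#' @return An object of class `forward_model`.
#' @export
forward_model <- function(gain, noise_cov = NULL, source_labels = NULL) {
  gain <- as.matrix(gain)
  assert_that(all(is.finite(gain)), "gain must be finite")
  if (is.null(noise_cov)) noise_cov <- diag(nrow(gain))
  noise_cov <- as.matrix(noise_cov)
  assert_that(nrow(noise_cov) == nrow(gain) &&
                ncol(noise_cov) == nrow(gain),
              "noise_cov must be sensors x sensors")
  assert_that(max(abs(noise_cov - t(noise_cov))) < 1e-8 * max(1, max(abs(noise_cov))),
              "noise_cov must be symmetric")
  ev <- eigen((noise_cov + t(noise_cov)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  assert_that(min(ev) > 0, "noise_cov must be positive-definite")
  if (is.null(source_labels)) {
    source_labels <- colnames(gain) %||% sprintf("src%03d", seq_len(ncol(gain)))
  }
  structure(list(gain = gain, noise_cov = noise_cov,
                 source_labels = source_labels),
            class = "forward_model")
}

#' Depth-weighted minimum-norm inverse operator
#'
#' The classic regularized minimum-norm estimator with a depth-weighting
#' source prior. With gain `G`, noise covariance `C` and depth exponent
#' `gamma`, the prior is `R = diag(||g_i||^(-2 gamma))`, normalized to
#' unit mean so the exponent does not change the overall scale, and the
#' weights are
#'
#' \deqn{W = R G^T (G R G^T + \lambda^2 C)^{-1}.}
#'
#' Depth weighting compensates for the inhomogeneous sensitivity of the
#' sensor array to deep versus superficial sources: columns with small
#' gain norms receive proportionally larger prior variance. The default
#' regularization `lambda2 = 0.33` corresponds to an assumed
#' signal-to-noise ratio of 3 under the 1/SNR convention.
#'
#' @param forward a [forward_model()].
#' @param lambda2 regularization parameter (> 0), default 0.33.
#' @param depth_exponent depth-weighting exponent `gamma` (>= 0),
#'   default 0.8; 0 disables depth weighting.
#' @return An object of class `inverse_operator` with elements `weights`
#'   (sources x sensors), `lambda2`, `depth_exponent` and `source_prior`
#'   (the diagonal of `R`).
#' @export
compute_inverse <- function(forward, lambda2 = 0.33, depth_exponent = 0.8) {
  stopifnot(inherits(forward, "forward_model"))
  assert_that(lambda2 > 0, "lambda2 must be > 0")
  assert_that(depth_exponent >= 0, "depth_exponent must be >= 0")
  g <- forward$gain
  norms <- sqrt(colSums(g^2))
  assert_that(all(norms > 0), "every source must have a non-zero gain column")
  r <- norms^(-2 * depth_exponent)
  r <- r / mean(r)
  grg <- g %*% (r * t(g)) + lambda2 * forward$noise_cov
  w <- (r * t(g)) %*% solve(grg)
  rownames(w) <- forward$source_labels
  structure(list(weights = w, lambda2 = lambda2,
                 depth_exponent = depth_exponent, source_prior = r,
                 source_labels = forward$source_labels),
            class = "inverse_operator")
}

#' Apply an inverse operator to sensor data
#'
#' @param sensor a sensor-level `recording`.
#' @param inv an [compute_inverse()] result.
#' @return A source-level `recording` (annotations copied through).
#' @export
apply_inverse <- function(sensor, inv) {
  stopifnot(inherits(sensor, "recording"), inherits(inv, "inverse_operator"))
  assert_that(ncol(inv$weights) == nrow(sensor$data),
              "sensor channel count does not match inverse weights")
  recording(inv$weights %*% sensor$data, sensor$sampling_rate,
            channel_labels = inv$source_labels,
            annotations = sensor$annotations,
            subject_id = sensor$subject_id, group = sensor$group)
}

#' Average source time courses within ROIs
#'
#' Each ROI channel is the unweighted mean of its member source signals
#' (the average current density across the ROI's vertices).
#'
#' @param sources a source-level `recording`.
#' @param membership data frame with columns `source_label`,
#'   `roi_label`, or a named character vector mapping source label to
#'   ROI label.
#' @return A `recording` with one channel per ROI, in first-appearance
#'   order of `roi_label`.
#' @export
roi_timecourse <- function(sources, membership) {
  stopifnot(inherits(sources, "recording"))
  if (!is.data.frame(membership)) {
    membership <- data.frame(source_label = names(membership),
                             roi_label = unname(membership))
  }
  assert_that(all(c("source_label", "roi_label") %in% names(membership)),
              "membership needs columns source_label, roi_label")
  rois <- unique(membership$roi_label)
  out <- matrix(0, nrow = length(rois), ncol = ncol(sources$data))
  for (i in seq_along(rois)) {
    members <- membership$source_label[membership$roi_label == rois[i]]
    idx <- match(members, sources$channel_labels)
    assert_that(length(idx) > 0L && !anyNA(idx),
                sprintf("ROI '%s' has no member sources in the recording",
                        rois[i]))
    out[i, ] <- colMeans(sources$data[idx, , drop = FALSE])
  }
  recording(out, sources$sampling_rate, channel_labels = rois,
            annotations = sources$annotations,
            subject_id = sources$subject_id, group = sources$group)
}
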