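#' Gate low-confidence keypoints and fill by interpolation
#'
#' Coordinates whose tracking likelihood falls below `likelihood_threshold`
#' are replaced by linear interpolation between the nearest confident frames
#' of the same body part; leading/trailing gaps take the nearest confident
#' value. Likelihoods of filled frames are set to the threshold so the gating
#' is recorded in the output.
#'
#' @param rec A [keypoint_recording()].
#' @param likelihood_threshold Real in 0..1.
#' @return A gated `keypoint_recording`.
#' @export
gate_and_interpolate <- function(rec, likelihood_threshold = 0.5) {
  stopifnot(inherits(rec, "keypoint_recording"))
  check_scalar_num(likelihood_threshold, "likelihood_threshold", 0, 1)
  T_ <- n_frames(rec)
  coords <- rec$coords
  lik <- rec$likelihood
  for (j in seq_along(rec$body_parts)) {
    ok <- lik[, j] >= likelihood_threshold
    if (!any(ok))
      stopf("body part '%s' has no frame with likelihood >= %g",
            rec$body_parts[j], likelihood_threshold)
    if (all(ok)) next
    idx <- seq_len(T_)
    for (c_ in 1:2) {
      coords[!ok, j, c_] <- approx(idx[ok], coords[ok, j, c_], xout = idx[!ok],
                                   method = "linear", rule = 2)$y
    }
    lik[!ok, j] <- likelihood_threshold
  }
  keypoint_recording(coords, lik, rec$body_parts, rec$fps, rec$arena_size)
}

#' Egocentric alignment of a keypoint recording
#'
#' Per frame: the centroid (unweighted mean of all tracked parts) is
#' translated to the origin and the pose is rotated so the tail_base-to-nose
#' axis points along +x, leaving only postural information. The centroid
#' track (arena frame) and heading are retained so location and orientation
#' are recoverable.
#'
#' @param rec A [keypoint_recording()]; body parts must include `nose` and
#'   `tail_base`.
#' @param centroid_parts Optional character vector of parts to average for the
#'   centroid (default: all parts).
#' @return Object of class `pose_series`: `aligned` (frames x parts x 2, mm,
#'   centroid at origin), `centroid` (frames x 2, mm, arena frame), `heading`
#'   (rad), `fps`, `body_parts`.
#' @export
egocentric_align <- function(rec, centroid_parts = NULL) {
  stopifnot(inherits(rec, "keypoint_recording"))
  bp <- rec$body_parts
  if (!all(c("nose", "tail_base") %in% bp))
    stopf("body parts must include 'nose' and 'tail_base'")
  T_ <- n_frames(rec)
  cp <- if (is.null(centroid_parts)) seq_along(bp) else match(centroid_parts, bp)
  if (anyNA(cp)) stopf("unknown centroid part(s)")

  cx <- rowMeans(rec$coords[, cp, 1, drop = FALSE])
  cy <- rowMeans(rec$coords[, cp, 2, drop = FALSE])
  i_nose <- match("nose", bp); i_tail <- match("tail_base", bp)
  vx <- rec$coords[, i_nose, 1] - rec$coords[, i_tail, 1]
  vy <- rec$coords[, i_nose, 2] - rec$coords[, i_tail, 2]
  degenerate <- (vx == 0 & vy == 0)
  heading <- atan2(vy, vx)
  if (any(degenerate)) {
    warnf("%d frame(s) with coincident nose/tail_base; reusing previous heading",
          sum(degenerate))
    heading[degenerate] <- NA_real_
    if (is.na(heading[1])) heading[1] <- 0
    for (t in which(is.na(heading))) heading[t] <- heading[t - 1L]
  }

  ch <- cos(-heading); sh <- sin(-heading)
  aligned <- array(0, dim = dim(rec$coords))
  for (j in seq_along(bp)) {
    dx <- rec$coords[, j, 1] - cx
    dy <- rec$coords[, j, 2] - cy
    aligned[, j, 1] <- dx * ch - dy * sh
    aligned[, j, 2] <- dx * sh + dy * ch
  }
  structure(list(aligned = aligned, centroid = cbind(cx, cy),
                 heading = heading, fps = rec$fps, body_parts = bp),
            class = "pose_series")
}

#' @export
print.pose_series <- function(x, ...) {
  cat(sprintf("<pose_series> %d frames x %d parts @ %g fps\n",
              dim(x$aligned)[1], dim(x$aligned)[2], x$fps))
  invisible(x)
}

flatten_pose <- function(pose) {
  a <- pose$aligned
  T_ <- dim(a)[1]; P <- dim(a)[2]
  X <- matrix(0, T_, 2L * P)
  X[, seq(1, 2 * P, 2)] <- a[, , 1]
  X[, seq(2, 2 * P, 2)] <- a[, , 2]
  X
}

#' Fit PCA on pooled egocentric poses
#'
#' Flattened aligned coordinates (x, y of every part) of all sessions are
#' pooled, per-feature centered, and decomposed; the leading `n_components`
#' directions (5 by default, the usual choice for 8-part mouse skeletons)
#' define the latent space the AR-HMM is fit in.
#'
#' @param pose_batches A `pose_series` or list of them.
#' @param n_components Number of retained components.
#' @return Object of class `pca_model`: `mean` (length n_features),
#'   `components` (n_components x n_features, orthonormal rows),
#'   `explained_variance` (fractions, all features, non-increasing),
#'   `n_components`.
#' @export
fit_pca <- function(pose_batches, n_components = 5L) {
  if (inherits(pose_batches, "pose_series")) pose_batches <- list(pose_batches)
  X <- do.call(rbind, lapply(pose_batches, flatten_pose))
  n_feat <- ncol(X)
  if (n_components > n_feat)
    stopf("n_components (%d) exceeds number of features (%d)",
          n_components, n_feat)
  if (nrow(X) <= n_feat)
    stopf("need more pooled frames (%d) than features (%d)", nrow(X), n_feat)
  p <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  structure(list(mean = p$center,
                 components = t(p$rotation[, seq_len(n_components), drop = FALSE]),
                 explained_variance = ev / sum(ev),
                 n_components = as.integer(n_components)),
            class = "pca_model")
}

#' Project a pose series into the PCA latent space
#'
#' @param model A `pca_model` from [fit_pca()].
#' @param pose A `pose_series` with the same skeleton.
#' @return A `latent_series`: frames x n_components matrix with `fps`
#'   attribute; frames map one-to-one to the input.
#' @export
transform_pca <- function(model, pose) {
  stopifnot(inherits(model, "pca_model"), inherits(pose, "pose_series"))
  X <- flatten_pose(pose)
  if (ncol(X) != length(model$mean))
    stopf("feature dimension %d does not match model (%d)",
          ncol(X), length(model$mean))
  Z <- sweep(X, 2, model$mean) %*% t(model$components)
  structure(Z, fps = pose$fps, class = c("latent_series", class(Z)))
}

#' Reconstruct flattened poses from latents (projection onto the subspace)
#' @param model A `pca_model`.
#' @param latents frames x n_components matrix.
#' @return frames x n_features matrix.
#' @export
reconstruct_pca <- function(model, latents) {
  sweep(unclass(latents) %*% model$components, 2, model$mean, `+`)
}
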