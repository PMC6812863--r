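#' Otsu threshold of a 3D intensity array
#'
#' Histogram-based Otsu threshold (maximum between-class variance) computed on
#' the full 3D volume. Used as the default automatic threshold. Two known
#' limitations, inherent to the method: (1) do not use it on negative controls
#' that contain no foreground mode: it will split the background noise (see
#' [estimate_artifact_cutoff()]); (2) when the foreground occupies well under
#' ~1% of all voxels and the background is noisy, the class-probability
#' weighting makes splitting the dominant background mode score higher than
#' the true valley, and the threshold collapses into the noise. For such
#' sparse channels (e.g. a few nuclei in a large stack) prefer an absolute
#' threshold; the threshold actually applied is always logged so the failure
#' is visible in run logs.
#'
#' @param x Numeric array of intensities (not constant).
#' @param n_bins Number of histogram bins.
#' @return The threshold intensity (a value strictly between the minimum and
#'   maximum of `x`).
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  rng <- range(x)
  if (rng[1] == rng[2]) stop("otsu threshold undefined for a constant image")
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                nbins = n_bins)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  w <- h / sum(h)
  cw <- cumsum(w)
  cm <- cumsum(w * mids)
  mu <- cm[n_bins]
  # between-class variance for threshold after bin k
  valid <- cw > 0 & cw < 1
  bcv <- rep(-Inf, n_bins)
  bcv[valid] <- (mu * cw[valid] - cm[valid])^2 / (cw[valid] * (1 - cw[valid]))
  k <- which.max(bcv)
  breaks[k + 1L]
}

threshold_channel <- function(channel, method = c("otsu", "absolute"),
                              absolute_value = NULL) {
  method <- match.arg(method)
  if (method == "absolute") {
    if (is.null(absolute_value))
      stop("method 'absolute' requires absolute_value")
    thr <- absolute_value
    rng <- range(channel)
    if (thr < rng[1] || thr > rng[2]) {
      warning(sprintf("absolute threshold %.4g outside intensity range [%.4g, %.4g]",
                      thr, rng[1], rng[2]))
    }
  } else {
    thr <- otsu_threshold(channel)
  }
  mask <- channel >= thr
  attr(mask, "threshold") <- thr
  mask
}

#' Threshold the marker channel
#'
#' Produces the binary marker mask (`TRUE` where intensity >= threshold). The
#' threshold actually applied is attached as attribute `"threshold"` so every
#' run log can record it.
#'
#' @param stack An [image_stack()].
#' @param method `"otsu"` (default, automatic) or `"absolute"`.
#' @param absolute_value Intensity threshold, required for
#'   `method = "absolute"`. A value outside the intensity range triggers a
#'   warning and yields the implied empty or full mask.
#' @return Logical 3D array with attribute `threshold`.
#' @export
threshold_marker <- function(stack, method = c("otsu", "absolute"),
                             absolute_value = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  threshold_channel(stack$marker_channel, method, absolute_value)
}

#' Label connected components of a binary 3D mask
#'
#' Maximal connected components under 6-, 18- or 26-connectivity, labeled
#' `1..K` in scan order. The default 26 merges any voxel contact, the closest
#' analogue of surface-reconstruction tools that fuse touching voxels;
#' connectivity is configurable because the network statistic is sensitive to
#' it.
#'
#' @param mask Logical 3D array (Z, Y, X).
#' @param connectivity 6, 18 or 26.
#' @param spacing [voxel_spacing()] to carry on the result.
#' @return A [label_mask()].
#' @export
label_components <- function(mask, connectivity = 26L, spacing) {
  if (!is.array(mask) || length(dim(mask)) != 3)
    stop("mask must be a 3D array")
  lab <- label_components_cpp(as.logical(mask), dim(mask),
                              as.integer(connectivity))
  dim(lab) <- dim(mask)
  label_mask(lab, spacing)
}

#' Components of a label mask with physical volumes
#'
#' One row per label with `voxel_count`, `volume_um3 = voxel_count *
#' voxel_volume` (exact), and `border_touching` (`TRUE` iff at least one voxel
#' lies on any of the six array faces — lateral and axial truncation are
#' treated alike, since a cell cut by the top or bottom optical section is as
#' incomplete as one cut laterally). `nuclei_count` and `cls` are filled later
#' by [assign_nuclei()] and [classify_components()].
#'
#' @param labels A [label_mask()].
#' @return A data frame with columns `label`, `voxel_count`, `volume_um3`,
#'   `border_touching`, `nuclei_count`, `cls`.
#' @export
component_volumes <- function(labels) {
  stopifnot(inherits(labels, "label_mask"))
  lab <- labels$labels
  k <- max(lab)
  vv <- voxel_volume(labels$spacing)
  if (k == 0) {
    return(data.frame(label = integer(0), voxel_count = integer(0),
                      volume_um3 = numeric(0), border_touching = logical(0),
                      nuclei_count = NA_integer_[0], cls = character(0),
                      stringsAsFactors = FALSE))
  }
  counts <- tabulate(lab[lab > 0L], nbins = k)
  d <- dim(lab)
  face_labels <- unique(c(lab[1, , ], lab[d[1], , ],
                          lab[, 1, ], lab[, d[2], ],
                          lab[, , 1], lab[, , d[3]]))
  face_labels <- face_labels[face_labels > 0L]
  data.frame(label = seq_len(k),
             voxel_count = counts,
             volume_um3 = counts * vv,
             border_touching = seq_len(k) %in% face_labels,
             nuclei_count = NA_integer_,
             cls = NA_character_,
             stringsAsFactors = FALSE)
}

#' Calibrate the artifact-size cutoff from a negative control
#'
#' Negative controls carry no specific staining, so any supra-threshold object
#' in them is an artifact (antibody precipitate, nonspecific binding). The
#' cutoff is `(1 + margin)` times the largest control component volume — a
#' control-calibrated size rather than a fixed constant — and 0 when the
#' control contains no components. Apply the *sample-derived* threshold as an
#' absolute value here: an automatic (Otsu) threshold computed on a control
#' with no foreground mode would split the background noise and return a
#' meaningless, huge cutoff.
#'
#' @param control An [image_stack()] scanned like the samples.
#' @param method,absolute_value Passed to [threshold_marker()];
#'   `method = "absolute"` with the sample threshold is the intended use.
#' @param connectivity Component connectivity, as for [label_components()].
#' @param margin Safety margin on the largest control object (default 0.10).
#' @return Cutoff volume in cubic micrometres.
#' @export
estimate_artifact_cutoff <- function(control, method = "absolute",
                                     absolute_value = NULL,
                                     connectivity = 26L, margin = 0.10) {
  stopifnot(inherits(control, "image_stack"), margin >= 0)
  mask <- threshold_marker(control, method = method,
                           absolute_value = absolute_value)
  if (!any(mask)) return(0)
  labs <- label_components(mask, connectivity, control$spacing)
  comps <- component_volumes(labs)
  if (nrow(comps) == 0) return(0)
  (1 + margin) * max(comps$volume_um3)
}

#' Remove components smaller than a volume cutoff
#'
#' Components with `volume_um3 < cutoff` are set to background and reported
#' with class `REMOVED`; survivors are relabeled `1..K'` preserving scan
#' order.
#'
#' @param labels A [label_mask()].
#' @param cutoff Volume cutoff in cubic micrometres (>= 0). `cutoff = 0` is
#'   the identity.
#' @return A list with elements `labels` (relabeled [label_mask()]) and
#'   `removed` (data frame of removed components, `cls = "REMOVED"`).
#' @export
remove_small_objects <- function(labels, cutoff) {
  stopifnot(inherits(labels, "label_mask"), cutoff >= 0)
  comps <- component_volumes(labels)
  drop <- comps$volume_um3 < cutoff
  removed <- comps[drop, , drop = FALSE]
  if (nrow(removed) > 0) removed$cls <- "REMOVED"
  if (!any(drop)) {
    return(list(labels = labels, removed = removed))
  }
  k <- nrow(comps)
  map <- integer(k)
  map[!drop] <- seq_len(sum(!drop))
  lab <- labels$labels
  pos <- lab > 0L
  lab[pos] <- map[lab[pos]]
  list(labels = label_mask(lab, labels$spacing), removed = removed)
}

#' Exclude nucleus voxels from the marker mask
#'
#' The nuclear stain is not part of the quantified cytoplasm volume; this
#' guarantees cytoplasm volumes never count nuclear voxels even when channels
#' bleed into each other. Logical `marker_mask AND NOT nucleus_mask`.
#'
#' @param marker_mask,nucleus_mask Logical 3D arrays of identical shape.
#' @return Logical 3D array.
#' @export
exclude_nucleus_voxels <- function(marker_mask, nucleus_mask) {
  if (!identical(dim(marker_mask), dim(nucleus_mask)))
    stop("marker and nucleus masks must have identical shape")
  out <- marker_mask & !nucleus_mask
  attr(out, "threshold") <- attr(marker_mask, "threshold")
  out
}
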