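#' Detect nuclei in the nuclear-stain channel
#'
#' Threshold + 26-connected labeling + removal of components below
#' `min_volume_um3` (DAPI debris and noise specks). Centroids are
#' volume-weighted centers in micrometres (voxel centers at
#' `(index - 0.5) * spacing`). Two nuclei closer than the resolution of the
#' threshold merge into one component; the resulting undercount is a known,
#' logged limitation of threshold-based counting.
#'
#' @param stack An [image_stack()] with a nucleus channel.
#' @param method,absolute_value Thresholding, as in [threshold_marker()].
#' @param min_volume_um3 Minimum nucleus volume kept (default 30 um^3, well
#'   below any real nucleus at this resolution but above noise specks).
#' @param connectivity Component connectivity.
#' @return An object of class `nucleus_set`: list with `centroids` (n x 3
#'   matrix, columns z/y/x in um), `labels` (a [label_mask()] over the nucleus
#'   channel) and `count`.
#' @export
detect_nuclei <- function(stack, method = c("otsu", "absolute"),
                          absolute_value = NULL, min_volume_um3 = 30,
                          connectivity = 26L) {
  stopifnot(inherits(stack, "image_stack"))
  if (max(stack$nucleus_channel) == min(stack$nucleus_channel) &&
      match.arg(method) == "otsu") {
    # empty channel: no nuclei rather than an Otsu error
    labs <- label_mask(array(0L, dim(stack$nucleus_channel)), stack$spacing)
    return(structure(list(centroids = matrix(numeric(0), 0, 3,
                                             dimnames = list(NULL, c("z", "y", "x"))),
                          labels = labs, count = 0L),
                     class = "nucleus_set"))
  }
  mask <- threshold_channel(stack$nucleus_channel, method, absolute_value)
  labs <- label_components(mask, connectivity, stack$spacing)
  filt <- remove_small_objects(labs, min_volume_um3)
  labs <- filt$labels
  lab <- labs$labels
  k <- max(lab)
  sp <- stack$spacing
  if (k == 0) {
    centroids <- matrix(numeric(0), 0, 3)
  } else {
    idx <- which(lab > 0L)
    li <- lab[idx]
    d <- dim(lab)
    z <- ((idx - 1L) %% d[1]) + 1L
    y <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
    x <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
    coords <- cbind(z = (z - 0.5) * sp$dz, y = (y - 0.5) * sp$dy,
                    x = (x - 0.5) * sp$dx)
    sums <- rowsum(coords, li)
    counts <- tabulate(li, nbins = k)
    centroids <- sums / counts
  }
  colnames(centroids) <- c("z", "y", "x")
  structure(list(centroids = centroids, labels = labs, count = k),
            class = "nucleus_set")
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("nucleus_set: %d nuclei\n", x$count))
  invisible(x)
}

#' Assign nuclei to marker components
#'
#' Each nucleus is assigned to the marker component nearest to the nucleus
#' region if that distance is at most `max_distance_um`. Distance is measured
#' from the nucleus's labeled voxels (not its centroid): cytoplasm shells
#' surround rather than contain nuclei, so a nucleus enclosed by a shell sits
#' at distance ~0 from it while its centroid is a whole nucleus radius away.
#' The default 2 um tolerates small stain gaps between nucleus and cytoplasm;
#' 0 would demand strict voxel adjacency. Unassigned nuclei are counted in
#' attribute `"unassigned"`. No nucleus is ever assigned twice, so the
#' assigned counts plus the unassigned count equal the nucleus count.
#'
#' @param components Data frame from [component_volumes()].
#' @param nuclei A `nucleus_set` from [detect_nuclei()].
#' @param marker_labels The [label_mask()] the components came from.
#' @param max_distance_um Maximum nucleus-to-component distance in um.
#' @return `components` with `nuclei_count` filled; attribute `unassigned`
#'   holds the number of nuclei matched to no component.
#' @export
assign_nuclei <- function(components, nuclei, marker_labels,
                          max_distance_um = 2.0) {
  stopifnot(inherits(nuclei, "nucleus_set"),
            inherits(marker_labels, "label_mask"))
  if (!identical(dim(nuclei$labels$labels), dim(marker_labels$labels)))
    stop("nucleus and marker label masks must share geometry")
  components$nuclei_count <- 0L
  if (nuclei$count == 0L || nrow(components) == 0L) {
    attr(components, "unassigned") <- nuclei$count
    return(components)
  }
  sp <- marker_labels$spacing
  d <- dim(marker_labels$labels)
  nl <- nuclei$labels$labels
  idx <- which(nl > 0L)
  ni <- nl[idx]
  z <- ((idx - 1L) %% d[1]) + 1L
  y <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  x <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  # per-axis padding that covers every marker voxel within max_distance_um
  pad <- c(ceiling(max_distance_um / sp$dz), ceiling(max_distance_um / sp$dy),
           ceiling(max_distance_um / sp$dx)) + 1L
  unassigned <- 0L
  for (n in seq_len(nuclei$count)) {
    sel <- ni == n
    if (!any(sel)) { unassigned <- unassigned + 1L; next }
    zr <- range(z[sel]); yr <- range(y[sel]); xr <- range(x[sel])
    zi <- max(1L, zr[1] - pad[1]):min(d[1], zr[2] + pad[1])
    yi <- max(1L, yr[1] - pad[2]):min(d[2], yr[2] + pad[2])
    xi <- max(1L, xr[1] - pad[3]):min(d[3], xr[2] + pad[3])
    crop <- marker_labels$labels[zi, yi, xi, drop = FALSE]
    near <- nearest_label_cpp(crop, dim(crop), c(sp$dz, sp$dy, sp$dx),
                              max_distance_um)
    # nucleus voxels in crop-local coordinates
    cz <- z[sel] - zi[1] + 1L
    cy <- y[sel] - yi[1] + 1L
    cx <- x[sel] - xi[1] + 1L
    cl <- cz + length(zi) * (cy - 1L) + length(zi) * length(yi) * (cx - 1L)
    dist <- near$dist[cl]
    dmin <- min(dist)
    if (!is.finite(dmin) || dmin > max_distance_um) {
      unassigned <- unassigned + 1L
      next
    }
    target <- near$label[cl][which.min(dist)]
    row <- match(target, components$label)
    if (is.na(row)) { unassigned <- unassigned + 1L; next }
    components$nuclei_count[row] <- components$nuclei_count[row] + 1L
  }
  attr(components, "unassigned") <- unassigned
  components
}

#' Classify components into single cells, networks and undefined fragments
#'
#' Fixed rule order: (1) any component touching a stack face is `UD` — an
#' edge fragment is not a definable cell regardless of its size; (2) interior
#' components with at least 3 (effective) nuclei are networks `NW` (cell
#' aggregates of at least three cells); (3) 1 or 2 nuclei give `SC` — pairs
#' are solitary cells, not networks, since networks require at least three
#' cells and no third class exists for doublets (pairs are counted in
#' attribute `"n_pairs"` so the choice is auditable); (4) interior components
#' with 0 nuclei that survived the artifact cutoff are `UD`, not silently
#' dropped: marker-positive mass with no countable cell.
#'
#' Multinucleated cells inflate nucleus counts; `nuclei_per_cell` divides
#' counts (rounding up) before the rules are applied.
#'
#' @param components Data frame with `nuclei_count` and `border_touching`
#'   populated.
#' @param nuclei_per_cell Expected nuclei per cell (default 1).
#' @return `components` with `cls` set to one of `"SC"`, `"NW"`, `"UD"`.
#' @export
classify_components <- function(components, nuclei_per_cell = 1L) {
  stopifnot(nuclei_per_cell >= 1)
  if (nrow(components) == 0) return(components)
  if (anyNA(components$nuclei_count) || anyNA(components$border_touching))
    stop("nuclei_count and border_touching must be populated before classification")
  eff <- ceiling(components$nuclei_count / nuclei_per_cell)
  cls <- ifelse(components$border_touching, "UD",
         ifelse(eff >= 3L, "NW",
         ifelse(eff >= 1L, "SC", "UD")))
  components$cls <- cls
  attr(components, "n_pairs") <- sum(!components$border_touching & eff == 2L)
  components
}
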