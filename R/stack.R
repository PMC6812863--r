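#' Two-channel 3D image stack
#'
#' Container for a confocal z-stack with a nuclear-stain channel (e.g. DAPI)
#' and a membrane/cytoplasm marker channel (e.g. CD30). Both channels are 3D
#' arrays in (Z, Y, X) axis order; this order is fixed throughout the package
#' and enforced on disk (see [write_stack()]) because TIFF dialects disagree.
#'
#' @param nucleus_channel 3D numeric array (Z, Y, X) of non-negative, finite
#'   intensities: the nuclear stain.
#' @param marker_channel 3D numeric array with the same shape: the cytoplasm
#'   marker.
#' @param spacing A [voxel_spacing()] object.
#' @param name Identifier string used in result tables.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(nucleus_channel, marker_channel, spacing,
                        name = "stack") {
  if (!is.array(nucleus_channel) || length(dim(nucleus_channel)) != 3)
    stop("nucleus_channel must be a 3D array (Z, Y, X)")
  if (!is.array(marker_channel) || length(dim(marker_channel)) != 3)
    stop("marker_channel must be a 3D array (Z, Y, X)")
  if (!identical(dim(nucleus_channel), dim(marker_channel)))
    stop("channels must have identical shape")
  if (any(dim(nucleus_channel) < 1)) stop("all dimensions must be >= 1")
  if (anyNA(nucleus_channel) || anyNA(marker_channel) ||
      any(!is.finite(range(nucleus_channel))) ||
      any(!is.finite(range(marker_channel))))
    stop("intensities must be finite")
  if (min(nucleus_channel) < 0 || min(marker_channel) < 0)
    stop("intensities must be >= 0")
  stopifnot(inherits(spacing, "voxel_spacing"))
  structure(list(nucleus_channel = nucleus_channel,
                 marker_channel = marker_channel,
                 spacing = spacing,
                 name = as.character(name)),
            class = "image_stack")
}

#' Physical volume of an image stack
#'
#' @param stack An [image_stack()].
#' @return Total imaged volume in cubic micrometres, `Z * Y * X * dx * dy * dz`.
#' @export
stack_volume_um3 <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  prod(dim(stack$marker_channel)) * voxel_volume(stack$spacing)
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$marker_channel)
  cat(sprintf("image_stack '%s': %d x %d x %d (Z,Y,X), %.4g um^3 total\n",
              x$name, d[1], d[2], d[3], stack_volume_um3(x)))
  print(x$spacing)
  invisible(x)
}

#' Integer-labeled 3D component map
#'
#' @param labels 3D integer array (Z, Y, X); 0 is background, components are
#'   labeled with positive integers.
#' @param spacing A [voxel_spacing()] shared with the source stack.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, spacing) {
  if (!is.array(labels) || length(dim(labels)) != 3)
    stop("labels must be a 3D array (Z, Y, X)")
  stopifnot(inherits(spacing, "voxel_spacing"))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, spacing = spacing), class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$labels)
  k <- max(x$labels)
  cat(sprintf("label_mask: %d x %d x %d (Z,Y,X), %d component(s)\n",
              d[1], d[2], d[3], k))
  invisible(x)
}
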