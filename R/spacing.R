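#' Voxel spacing in micrometres
#'
#' Physical size of one voxel along each axis. All volumes in the package are
#' physical volumes in cubic micrometres computed as
#' `voxel_count * dx * dy * dz`, so anisotropic stacks (the usual confocal
#' case, with a z-step much finer or coarser than the lateral pixel size)
#' need no resampling.
#'
#' @param dx,dy,dz Voxel edge length along x, y and z in micrometres. All
#'   three must be strictly positive and finite.
#' @return An object of class `voxel_spacing`: a named list with elements
#'   `dx`, `dy`, `dz`.
#' @examples
#' sp <- voxel_spacing(0.36, 0.37, 0.13)
#' voxel_volume(sp)
#' @export
voxel_spacing <- function(dx, dy, dz) {
  v <- c(dx = dx, dy = dy, dz = dz)
  if (length(dx) != 1 || length(dy) != 1 || length(dz) != 1 ||
      !all(is.finite(v)) || any(v <= 0)) {
    stop("voxel spacing must be three strictly positive, finite lengths (um)")
  }
  structure(list(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz)),
            class = "voxel_spacing")
}

#' Physical volume of one voxel
#'
#' @param spacing A [voxel_spacing()] object.
#' @return Voxel volume in cubic micrometres (`dx * dy * dz`).
#' @export
voxel_volume <- function(spacing) {
  stopifnot(inherits(spacing, "voxel_spacing"))
  spacing$dx * spacing$dy * spacing$dz
}

#' Default confocal acquisition spacing
#'
#' Spacing of a 63x confocal acquisition scanning 365 x 375 um at
#' 1024 x 1024 px with a 0.13 um z-step: dx = 365/1024, dy = 375/1024,
#' dz = 0.13. These are configuration values, not constants; override them
#' whenever the acquisition differs.
#'
#' @return A [voxel_spacing()] object.
#' @export
default_spacing <- function() {
  voxel_spacing(dx = 365 / 1024, dy = 375 / 1024, dz = 0.13)
}

#' @export
print.voxel_spacing <- function(x, ...) {
  cat(sprintf("voxel spacing (um): dx=%.4g dy=%.4g dz=%.4g (voxel volume %.6g um^3)\n",
              x$dx, x$dy, x$dz, voxel_volume(x)))
  invisible(x)
}
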