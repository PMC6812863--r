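#' Write a two-channel stack to a multi-page TIFF with spacing metadata
#'
#' Pages are written channel-first: all Z slices of the nucleus channel, then
#' all Z slices of the marker channel, each slice a (Y, X) 16-bit grayscale
#' page. Voxel spacing, shape, channel order and stack name are persisted in a
#' JSON sidecar at `<path>.json` (the plain TIFF container carried by the
#' `tiff` package has no reliable slot for 3D spacing). [read_stack()] inverts
#' the pair bit-exactly for integer-valued stacks.
#'
#' @param stack An [image_stack()] with integer intensities in 0..65535.
#'   Non-integer intensities are rounded with a warning.
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$marker_channel)
  mx <- max(stack$nucleus_channel, stack$marker_channel)
  if (mx > 65535) stop("intensities exceed the 16-bit range (0..65535)")
  nuc <- stack$nucleus_channel
  mrk <- stack$marker_channel
  if (any(nuc != round(nuc)) || any(mrk != round(mrk))) {
    warning("non-integer intensities rounded to the nearest integer for 16-bit storage")
    nuc <- round(nuc)
    mrk <- round(mrk)
  }
  pages <- vector("list", 2L * d[1])
  for (z in seq_len(d[1])) {
    pages[[z]] <- matrix(nuc[z, , ], d[2], d[3]) / 65535
    pages[[d[1] + z]] <- matrix(mrk[z, , ], d[2], d[3]) / 65535
  }
  ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L),
                 error = function(e) stop("cannot write TIFF at '", path, "': ",
                                          conditionMessage(e)))
  meta <- list(format = "cytovol3d-stack",
               axis_order = "ZYX",
               channel_order = c("nucleus", "marker"),
               shape_zyx = as.integer(d),
               spacing_um = list(dx = stack$spacing$dx, dy = stack$spacing$dy,
                                 dz = stack$spacing$dz),
               name = stack$name,
               bits_per_sample = 16L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a two-channel stack from a multi-page TIFF
#'
#' Reads a TIFF written by [write_stack()] (or any channel-first multi-page
#' TIFF) and assigns channels according to `channel_map`. Spacing comes from
#' the JSON sidecar; a `spacing` override always wins over file metadata
#' (microscope metadata is frequently wrong) and a warning is issued when the
#' two disagree by more than 1%. The function fails rather than silently
#' defaulting spacing when neither source provides it.
#'
#' @param path TIFF path.
#' @param channel_map Named integer vector mapping roles to 1-based channel
#'   indices, e.g. `c(nucleus = 1, marker = 2)`. Both roles are required.
#' @param spacing Optional [voxel_spacing()] override.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, channel_map = c(nucleus = 1, marker = 2),
                       spacing = NULL) {
  if (!file.exists(path)) stop("no such file: '", path, "'")
  if (!all(c("nucleus", "marker") %in% names(channel_map)))
    stop("channel_map must name both 'nucleus' and 'marker' channels")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL

  file_spacing <- NULL
  if (!is.null(meta) && !is.null(meta$spacing_um)) {
    file_spacing <- voxel_spacing(meta$spacing_um$dx, meta$spacing_um$dy,
                                  meta$spacing_um$dz)
  }
  if (is.null(spacing) && is.null(file_spacing)) {
    stop("voxel spacing metadata missing for '", path,
         "': no sidecar '", basename(sidecar),
         "' and no spacing override supplied")
  }
  if (!is.null(spacing) && !is.null(file_spacing)) {
    rel <- abs(c(spacing$dx, spacing$dy, spacing$dz) -
               c(file_spacing$dx, file_spacing$dy, file_spacing$dz)) /
      c(file_spacing$dx, file_spacing$dy, file_spacing$dz)
    if (any(rel > 0.01)) {
      warning("spacing override disagrees with file metadata by >1%; using the override")
    }
  }
  sp <- if (!is.null(spacing)) spacing else file_spacing

  n_chan <- if (!is.null(meta)) length(meta$channel_order) else max(channel_map)
  if (length(pages) %% n_chan != 0)
    stop("page count (", length(pages), ") is not a multiple of the channel count (",
         n_chan, ")")
  Z <- length(pages) %/% n_chan
  if (max(channel_map) > n_chan)
    stop("channel_map requires channel ", max(channel_map),
         " but the file has only ", n_chan, " channel(s)")
  d2 <- dim(pages[[1]])
  get_channel <- function(ci) {
    arr <- array(0, c(Z, d2[1], d2[2]))
    for (z in seq_len(Z)) arr[z, , ] <- pages[[(ci - 1L) * Z + z]]
    round(arr * 65535)
  }
  nm <- if (!is.null(meta) && !is.null(meta$name)) meta$name
        else sub("\\.tiff?$", "", basename(path))
  image_stack(nucleus_channel = get_channel(channel_map[["nucleus"]]),
              marker_channel = get_channel(channel_map[["marker"]]),
              spacing = sp, name = nm)
}

#' Write a label mask as a 16-bit TIFF (with JSON sidecar)
#'
#' @param mask A [label_mask()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  d <- dim(mask$labels)
  if (max(mask$labels) > 65535) stop("more than 65535 labels cannot be stored as 16-bit TIFF")
  pages <- lapply(seq_len(d[1]),
                  function(z) matrix(mask$labels[z, , ], d[2], d[3]) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(format = "cytovol3d-labels", axis_order = "ZYX",
               shape_zyx = as.integer(d),
               spacing_um = list(dx = mask$spacing$dx, dy = mask$spacing$dy,
                                 dz = mask$spacing$dz))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write per-stack quantification results as a flat CSV
#'
#' One row per stack with the columns: `stack`, `entity`,
#' `total_fraction_pct`, `nw_share_pct`, `sc_share_pct`, `ud_share_pct`,
#' `n_single_cells`, `single_cell_mean_um3`, `single_cell_sd_um3`,
#' `n_networks`, `artifact_cutoff_um3`.
#'
#' @param result A `quant_result` (see [quantify_stack()]) or a non-empty list
#'   of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  if (inherits(result, "quant_result")) result <- list(result)
  if (!is.list(result) || length(result) == 0)
    stop("results must be a non-empty quant_result or list of quant_results")
  rows <- lapply(result, function(r) {
    stopifnot(inherits(r, "quant_result"))
    as.data.frame(r)
  })
  df <- do.call(rbind, rows)
  ok <- tryCatch(write.csv(df, path, row.names = FALSE),
                 error = function(e) stop("cannot write results to '", path,
                                          "': ", conditionMessage(e)))
  invisible(path)
}

#' Serialize generator ground truth to JSON
#'
#' @param truth The `cells` data frame (and optionally `artifacts`) from
#'   [generate_stack()], or the full generation result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  if (inherits(truth, "synthetic_stack")) {
    truth <- list(cells = truth$cells, artifacts = truth$artifacts)
  }
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Read generator ground truth from JSON
#'
#' @param path JSON path written by [write_ground_truth()].
#' @return A list with data frames `cells` and `artifacts`.
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
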