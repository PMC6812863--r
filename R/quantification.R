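#' Marker-positive volume fraction of a stack
#'
#' `100 * sum(retained component volumes) / total stack volume`. The
#' denominator is the imaged stack volume (Z*Y*X*voxel volume); removed
#' (artifact) components must not be in `components`. Scaling all three voxel
#' edges by a common factor leaves the percentage unchanged.
#'
#' @param components Classified component table for this stack (artifacts
#'   already removed).
#' @param stack The source [image_stack()].
#' @return Percentage in `[0, 100]`.
#' @export
volume_fraction <- function(components, stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (nrow(components) == 0) return(0)
  100 * sum(components$volume_um3) / stack_volume_um3(stack)
}

#' Volume shares of the three component classes
#'
#' Each share is `100 * class volume / total marker-positive volume`, over the
#' classes network (NW), single cell (SC) and undefined (UD). Undefined
#' volume stays in the denominator (it is marker-positive mass), it just never
#' enters single-cell statistics. When the total is 0 all shares are 0 and
#' attribute `"empty"` is `TRUE`.
#'
#' @param components Classified component table.
#' @return Named numeric vector `c(nw, sc, ud)` summing to 100 (or 0 when
#'   empty, flagged via attribute `empty`).
#' @export
class_shares <- function(components) {
  if (nrow(components) > 0 && anyNA(components$cls))
    stop("all components must be classified before computing shares")
  total <- sum(components$volume_um3)
  if (nrow(components) == 0 || total == 0) {
    out <- c(nw = 0, sc = 0, ud = 0)
    attr(out, "empty") <- TRUE
    return(out)
  }
  vol_of <- function(cl) sum(components$volume_um3[components$cls == cl])
  out <- 100 * c(nw = vol_of("NW"), sc = vol_of("SC"), ud = vol_of("UD")) / total
  attr(out, "empty") <- FALSE
  out
}

#' Single-cell volume statistics
#'
#' Sample mean and sample standard deviation (n-1 denominator) of
#' `volume_um3` over components classified `SC` only. With no single cell the
#' mean and SD are `NA`; with one, the SD is `NA`.
#'
#' @param components Classified component table.
#' @return List with `n`, `mean_um3`, `sd_um3`.
#' @export
single_cell_stats <- function(components) {
  v <- components$volume_um3[!is.na(components$cls) & components$cls == "SC"]
  list(n = length(v),
       mean_um3 = if (length(v) >= 1) mean(v) else NA_real_,
       sd_um3 = if (length(v) >= 2) sd(v) else NA_real_)
}

#' Assemble the per-stack quantification result
#'
#' @param components Classified component table (artifacts removed).
#' @param stack The source [image_stack()].
#' @param entity Entity label for result tables.
#' @param artifact_cutoff_um3 The cutoff that was applied.
#' @return An object of class `quant_result` with the stack's volume fraction,
#'   class shares, counts and single-cell statistics.
#' @export
quantify_stack <- function(components, stack, entity = NA_character_,
                           artifact_cutoff_um3 = 0) {
  shares <- class_shares(components)
  scs <- single_cell_stats(components)
  structure(list(stack_name = stack$name,
                 entity = as.character(entity),
                 total_fraction_pct = volume_fraction(components, stack),
                 nw_share_pct = unname(shares["nw"]),
                 sc_share_pct = unname(shares["sc"]),
                 ud_share_pct = unname(shares["ud"]),
                 n_single_cells = scs$n,
                 single_cell_mean_um3 = scs$mean_um3,
                 single_cell_sd_um3 = scs$sd_um3,
                 n_networks = sum(components$cls == "NW"),
                 artifact_cutoff_um3 = artifact_cutoff_um3,
                 marker_volume_um3 = sum(components$volume_um3)),
            class = "quant_result")
}

#' @export
as.data.frame.quant_result <- function(x, ...) {
  data.frame(stack = x$stack_name, entity = x$entity,
             total_fraction_pct = x$total_fraction_pct,
             nw_share_pct = x$nw_share_pct, sc_share_pct = x$sc_share_pct,
             ud_share_pct = x$ud_share_pct,
             n_single_cells = x$n_single_cells,
             single_cell_mean_um3 = x$single_cell_mean_um3,
             single_cell_sd_um3 = x$single_cell_sd_um3,
             n_networks = x$n_networks,
             artifact_cutoff_um3 = x$artifact_cutoff_um3,
             stringsAsFactors = FALSE)
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf("quant_result '%s' (%s): fraction %.3f%%, shares NW %.1f / SC %.1f / UD %.1f,\n  %d single cells (mean %.1f um^3, sd %s), %d networks, cutoff %.3g um^3\n",
              x$stack_name, x$entity, x$total_fraction_pct, x$nw_share_pct,
              x$sc_share_pct, x$ud_share_pct, x$n_single_cells,
              x$single_cell_mean_um3,
              ifelse(is.na(x$single_cell_sd_um3), "NA",
                     sprintf("%.1f", x$single_cell_sd_um3)),
              x$n_networks, x$artifact_cutoff_um3))
  invisible(x)
}

#' Summarize quantification results across the stacks of one entity
#'
#' Across-stack mean and sample SD of the volume fraction and of the per-stack
#' single-cell mean volume (SDs are `NA` with fewer than two stacks), plus
#' class shares pooled by per-stack marker-positive volume (so a large stack
#' weighs more than a sparse one).
#'
#' @param results Non-empty list of `quant_result`s sharing one entity label.
#' @return An object of class `entity_summary`.
#' @export
summarize_entity <- function(results) {
  if (inherits(results, "quant_result")) results <- list(results)
  stopifnot(is.list(results), length(results) >= 1)
  ent <- unique(vapply(results, function(r) r$entity, character(1)))
  if (length(ent) != 1) stop("all results must share one entity label, got: ",
                             paste(ent, collapse = ", "))
  fr <- vapply(results, function(r) r$total_fraction_pct, numeric(1))
  scm <- vapply(results, function(r) r$single_cell_mean_um3, numeric(1))
  w <- vapply(results, function(r) r$marker_volume_um3, numeric(1))
  pool <- function(field) {
    x <- vapply(results, function(r) r[[field]], numeric(1))
    if (sum(w) == 0) 0 else sum(x * w) / sum(w)
  }
  n <- length(results)
  structure(list(entity = ent, n_stacks = n,
                 fraction_mean_pct = mean(fr),
                 fraction_sd_pct = if (n >= 2) sd(fr) else NA_real_,
                 single_cell_mean_um3 = mean(scm, na.rm = TRUE),
                 single_cell_mean_sd_um3 = if (n >= 2) sd(scm) else NA_real_,
                 nw_share_pct = pool("nw_share_pct"),
                 sc_share_pct = pool("sc_share_pct"),
                 ud_share_pct = pool("ud_share_pct")),
            class = "entity_summary")
}

#' @export
as.data.frame.entity_summary <- function(x, ...) {
  data.frame(entity = x$entity, n_stacks = x$n_stacks,
             fraction_mean_pct = x$fraction_mean_pct,
             fraction_sd_pct = x$fraction_sd_pct,
             single_cell_mean_um3 = x$single_cell_mean_um3,
             single_cell_mean_sd_um3 = x$single_cell_mean_sd_um3,
             nw_share_pct = x$nw_share_pct, sc_share_pct = x$sc_share_pct,
             ud_share_pct = x$ud_share_pct, stringsAsFactors = FALSE)
}

#' @export
print.entity_summary <- function(x, ...) {
  cat(sprintf("entity_summary %s (n=%d): fraction %.2f%% (sd %s), SC mean %.0f um^3, shares NW %.1f / SC %.1f / UD %.1f\n",
              x$entity, x$n_stacks, x$fraction_mean_pct,
              ifelse(is.na(x$fraction_sd_pct), "NA",
                     sprintf("%.2f", x$fraction_sd_pct)),
              x$single_cell_mean_um3, x$nw_share_pct, x$sc_share_pct,
              x$ud_share_pct))
  invisible(x)
}
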