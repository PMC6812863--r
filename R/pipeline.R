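#' Pipeline run configuration
#'
#' Every parameter has a recorded default; the effective configuration is
#' serialized next to the outputs by [run_pipeline()] so that every number in
#' every CSV is reproducible from the output directory alone.
#'
#' @param input Path to the sample stack TIFF (or `NULL` when a stack object
#'   is passed to [run_pipeline()] directly).
#' @param control Path to the negative-control TIFF (or `NULL`).
#' @param out_dir Output directory (created if missing); `NULL` suppresses
#'   file output.
#' @param spacing Optional [voxel_spacing()] override; always wins over file
#'   metadata.
#' @param threshold_method,threshold_value Marker threshold: `"otsu"`
#'   (default) or `"absolute"` with `threshold_value`.
#' @param nucleus_threshold_method,nucleus_threshold_value Same for the
#'   nucleus channel.
#' @param connectivity Component connectivity (6, 18 or 26).
#' @param artifact_margin Safety margin on the control-derived cutoff.
#' @param artifact_cutoff Fixed cutoff in um^3, used when no control is given
#'   (default 0: nothing removed).
#' @param nucleus_min_volume_um3 Minimum nucleus volume kept.
#' @param nucleus_max_distance_um Maximum nucleus-to-component assignment
#'   distance.
#' @param nuclei_per_cell Expected nuclei per cell for classification.
#' @param entity Entity label for result tables.
#' @param seed Seed recorded with the run (the pipeline itself is
#'   deterministic; the seed matters when the config drives generation).
#' @return An object of class `run_config`.
#' @export
run_config <- function(input = NULL, control = NULL, out_dir = NULL,
                       spacing = NULL,
                       threshold_method = "otsu", threshold_value = NULL,
                       nucleus_threshold_method = "otsu",
                       nucleus_threshold_value = NULL,
                       connectivity = 26L,
                       artifact_margin = 0.10, artifact_cutoff = 0,
                       nucleus_min_volume_um3 = 30,
                       nucleus_max_distance_um = 2.0,
                       nuclei_per_cell = 1L,
                       entity = NA_character_, seed = 1L) {
  stopifnot(connectivity %in% c(6L, 18L, 26L), artifact_margin >= 0,
            artifact_cutoff >= 0, nucleus_min_volume_um3 >= 0,
            nucleus_max_distance_um >= 0, nuclei_per_cell >= 1)
  structure(list(input = input, control = control, out_dir = out_dir,
                 spacing = spacing,
                 threshold_method = threshold_method,
                 threshold_value = threshold_value,
                 nucleus_threshold_method = nucleus_threshold_method,
                 nucleus_threshold_value = nucleus_threshold_value,
                 connectivity = as.integer(connectivity),
                 artifact_margin = artifact_margin,
                 artifact_cutoff = artifact_cutoff,
                 nucleus_min_volume_um3 = nucleus_min_volume_um3,
                 nucleus_max_distance_um = nucleus_max_distance_um,
                 nuclei_per_cell = as.integer(nuclei_per_cell),
                 entity = entity, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Unknown keys are rejected; values override [run_config()] defaults
#' (file overrides defaults; function arguments to [run_pipeline()] override
#' both).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: '", path, "'")
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), c(known, "spacing_um"))
  if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(vals$spacing_um)) {
    vals$spacing <- voxel_spacing(vals$spacing_um$dx, vals$spacing_um$dy,
                                  vals$spacing_um$dz)
    vals$spacing_um <- NULL
  }
  do.call(run_config, vals)
}

config_as_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$spacing)) out$spacing <- unclass(out$spacing)
  out
}

#' Run the full quantification pipeline on one stack
#'
#' Stages: threshold the marker channel; threshold the nucleus channel and
#' exclude nucleus voxels from the marker mask; label components; calibrate
#' the artifact cutoff from the control (applying the sample-derived threshold
#' as an absolute value — see [estimate_artifact_cutoff()]) and remove
#' sub-cutoff objects; detect and assign nuclei; classify components; compute
#' the quantification result. The applied threshold, cutoff, component counts
#' before/after removal, and the unassigned-nucleus count are reported via
#' `message()` and attached as attributes.
#'
#' When `out_dir` is set, writes `components_<name>.csv`,
#' `result_<name>.csv`, `labels_<name>.tif` (classified label mask) and
#' `config_<name>.json` (the effective configuration).
#'
#' @param config A [run_config()].
#' @param stack An [image_stack()]; read from `config$input` when `NULL`.
#' @param control An [image_stack()]; read from `config$control` when `NULL`.
#' @return A `quant_result` with attributes `components` (classified table),
#'   `threshold`, `cutoff_um3`, `unassigned_nuclei`.
#' @export
run_pipeline <- function(config = run_config(), stack = NULL, control = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(stack)) {
    if (is.null(config$input)) stop("no stack given and config$input is NULL")
    stack <- read_stack(config$input, spacing = config$spacing)
  }
  if (is.null(control) && !is.null(config$control)) {
    control <- read_stack(config$control, spacing = config$spacing)
  }

  marker_mask <- tryCatch(
    threshold_marker(stack, method = config$threshold_method,
                     absolute_value = config$threshold_value),
    error = function(e) stop("stage threshold_marker: ", conditionMessage(e)))
  thr <- attr(marker_mask, "threshold")
  message(sprintf("[%s] marker threshold: %.4g (%s)", stack$name, thr,
                  config$threshold_method))

  nuclei <- tryCatch(
    detect_nuclei(stack, method = config$nucleus_threshold_method,
                  absolute_value = config$nucleus_threshold_value,
                  min_volume_um3 = config$nucleus_min_volume_um3,
                  connectivity = config$connectivity),
    error = function(e) stop("stage detect_nuclei: ", conditionMessage(e)))
  message(sprintf("[%s] nuclei detected: %d", stack$name, nuclei$count))

  nucleus_mask <- nuclei$labels$labels > 0L
  marker_mask <- exclude_nucleus_voxels(marker_mask, nucleus_mask)

  labs <- label_components(marker_mask, config$connectivity, stack$spacing)
  n_before <- max(labs$labels)

  cutoff <- if (!is.null(control)) {
    estimate_artifact_cutoff(control, method = "absolute",
                             absolute_value = thr,
                             connectivity = config$connectivity,
                             margin = config$artifact_margin)
  } else {
    config$artifact_cutoff
  }
  filt <- remove_small_objects(labs, cutoff)
  labs <- filt$labels
  comps <- component_volumes(labs)
  message(sprintf("[%s] artifact cutoff %.4g um^3: %d component(s) -> %d retained, %d removed",
                  stack$name, cutoff, n_before, nrow(comps),
                  nrow(filt$removed)))

  comps <- assign_nuclei(comps, nuclei, labs,
                         max_distance_um = config$nucleus_max_distance_um)
  message(sprintf("[%s] unassigned nuclei: %d", stack$name,
                  attr(comps, "unassigned")))
  comps <- classify_components(comps, nuclei_per_cell = config$nuclei_per_cell)

  result <- quantify_stack(comps, stack, entity = config$entity,
                           artifact_cutoff_um3 = cutoff)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    nm <- stack$name
    write.csv(comps, file.path(config$out_dir,
                               sprintf("components_%s.csv", nm)),
              row.names = FALSE)
    write_results(result, file.path(config$out_dir,
                                    sprintf("result_%s.csv", nm)))
    write_label_mask(labs, file.path(config$out_dir,
                                     sprintf("labels_%s.tif", nm)))
    eff <- config_as_list(config)
    eff$applied_threshold <- thr
    eff$applied_cutoff_um3 <- cutoff
    jsonlite::write_json(eff, file.path(config$out_dir,
                                        sprintf("config_%s.json", nm)),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  attr(result, "components") <- comps
  attr(result, "threshold") <- thr
  attr(result, "cutoff_um3") <- cutoff
  attr(result, "unassigned_nuclei") <- attr(comps, "unassigned")
  result
}

#' Run a cohort of stacks and summarize per entity
#'
#' Accepts either a list of `quant_result`s (e.g. from repeated
#' [run_pipeline()] calls) or a list of run descriptors
#' `list(config =, stack =, control =)` to execute. Results are grouped by
#' entity label and summarized with [summarize_entity()]; summaries are
#' independent of the order in which stacks are supplied.
#'
#' @param runs List of `quant_result`s or of run descriptors.
#' @return A list with `summaries` (one `entity_summary` per entity, sorted by
#'   label) and `comparison` (one data frame row per entity).
#' @export
run_cohort <- function(runs) {
  stopifnot(is.list(runs), length(runs) >= 1)
  results <- lapply(runs, function(r) {
    if (inherits(r, "quant_result")) return(r)
    run_pipeline(config = r$config, stack = r$stack, control = r$control)
  })
  ents <- vapply(results, function(r) r$entity, character(1))
  if (anyNA(ents)) stop("every result needs an entity label for cohort summaries")
  groups <- split(results, ents)
  groups <- groups[order(names(groups))]
  summaries <- lapply(groups, summarize_entity)
  comparison <- do.call(rbind, lapply(summaries, as.data.frame))
  rownames(comparison) <- NULL
  list(summaries = summaries, comparison = comparison)
}
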