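#' Pipeline configuration and end-to-end stage runners
#'
#' A single configuration object carries every tunable parameter of the
#' analyses; the pre-set defaults are the values the method prescribes
#' (50 nm bins, 6 rings, miR positivity threshold 5, significance level
#' 0.05), the remaining parameters are documented package decisions. The
#' `run_*` functions chain the per-module operations over batches of
#' inputs, log progress, optionally write the per-module output files,
#' and record a manifest (configuration, seed, input digests) sufficient
#' to reproduce the outputs.
#'
#' @name cli_pipeline
NULL

#' Build a pipeline configuration
#'
#' @param bin_size_nm occupancy-grid bin size in nm (default 50).
#' @param n_rings number of equal-area radial rings (default 6).
#' @param mir_threshold miR positivity cut-off on the 0-255 scale
#'   (default 5, boundary inclusive).
#' @param alpha significance level for the rank-sum comparison
#'   (default 0.05).
#' @param smoothing_sigma_px,min_separation_px,prominence_fraction,level_fraction
#'   chromatin-compaction parameters, see [analyze_chromatin_compaction()].
#' @param cytoplasm_width_px cytoplasm band width, see [detect_cells()].
#' @param min_nucleus_area_um2 minimum nucleus area kept in cell detection.
#' @param pixel_size_um pixel pitch of confocal inputs.
#' @param seed top-level RNG seed from which all randomness flows
#'   (`NULL` leaves the RNG state untouched).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(bin_size_nm = 50, n_rings = 6L, mir_threshold = 5,
                            alpha = 0.05, smoothing_sigma_px = 1.0,
                            min_separation_px = 3L, prominence_fraction = 0.10,
                            level_fraction = 0.5, cytoplasm_width_px = 5L,
                            min_nucleus_area_um2 = 2, pixel_size_um = 0.1,
                            seed = NULL) {
  cfg <- list(bin_size_nm = bin_size_nm, n_rings = as.integer(n_rings),
              mir_threshold = mir_threshold, alpha = alpha,
              smoothing_sigma_px = smoothing_sigma_px,
              min_separation_px = as.integer(min_separation_px),
              prominence_fraction = prominence_fraction,
              level_fraction = level_fraction,
              cytoplasm_width_px = as.integer(cytoplasm_width_px),
              min_nucleus_area_um2 = min_nucleus_area_um2,
              pixel_size_um = pixel_size_um,
              seed = if (is.null(seed)) NULL else as.integer(seed))
  stopifnot(cfg$bin_size_nm > 0, cfg$n_rings >= 2L, cfg$mir_threshold >= 0,
            cfg$alpha > 0, cfg$alpha < 1)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys absent from the file keep their defaults; unknown keys are an
#' error so that typos do not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj)) obj <- list()
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(obj), known)
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, obj)
}

.log_msg <- function(...) message("[chromnano] ", ...)

.write_manifest <- function(out_dir, config, inputs) {
  digests <- vapply(inputs, function(p) {
    if (is.character(p) && file.exists(p)) unname(tools::md5sum(p))
    else "in-memory"
  }, character(1L))
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("chromnano")),
         config = unclass(config),
         inputs = as.list(stats::setNames(digests, names(inputs)))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(NULL)
}

#' Run the occupancy-binning stage over a batch of nuclei
#'
#' For each nucleus: read localisations, restrict to the ROI, bin on the
#' configured grid, summarise. Grids are pooled per group with
#' [merge_distributions()].
#'
#' @param loc_paths character vector of localisation CSV paths.
#' @param roi_paths character vector of ROI JSON paths (same length).
#' @param config a [pipeline_config()].
#' @param groups optional character vector of group labels per nucleus
#'   (default: one pooled group `"all"`).
#' @param out_dir optional output directory (per-nucleus bin CSVs, a JSON
#'   distribution summary and a manifest are written when given).
#' @return List with `grids`, `per_nucleus` (distributions) and `pooled`
#'   (named list of distributions per group).
#' @export
run_density <- function(loc_paths, roi_paths, config = pipeline_config(),
                        groups = NULL, out_dir = NULL) {
  stopifnot(length(loc_paths) == length(roi_paths))
  n <- length(loc_paths)
  if (is.null(groups)) groups <- rep("all", n)
  stopifnot(length(groups) == n)
  ids <- .nucleus_ids(loc_paths, n)
  grids <- vector("list", n)
  for (k in seq_len(n)) {
    tab <- read_localisations(loc_paths[k])
    roi <- read_roi(roi_paths[k])
    inside <- filter_by_roi(tab, roi)
    .log_msg("nucleus ", ids[k], ": ", nrow(tab), " localisations, ",
             nrow(inside), " inside ROI")
    if (nrow(inside) == 0L)
      stop("empty-grid error: nucleus ", ids[k],
           ": ROI excludes every localisation")
    grids[[k]] <- bin_localisations(inside, config$bin_size_nm)
  }
  names(grids) <- ids
  per_nucleus <- lapply(grids, bin_count_distribution)
  pooled <- lapply(split(grids, groups), merge_distributions)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_len(n))
      write_bin_table(grids[[k]], file.path(out_dir, paste0("bins_", ids[k], ".csv")))
    jsonlite::write_json(
      lapply(pooled, function(d) d[c("n_bins", "median", "q1", "q3",
                                     "whisker_low", "whisker_high", "outliers")]),
      file.path(out_dir, "distributions.json"), auto_unbox = TRUE, digits = NA)
    .write_manifest(out_dir, config,
                    stats::setNames(as.list(c(loc_paths, roi_paths)),
                                    c(paste0("loc_", ids), paste0("roi_", ids))))
  }
  list(grids = grids, per_nucleus = per_nucleus, pooled = pooled)
}

.nucleus_ids <- function(paths, n) {
  ids <- make.unique(tools::file_path_sans_ext(basename(paths)))
  if (length(ids) != n) as.character(seq_len(n)) else ids
}

#' Run the radial-ring stage over a batch of nuclei
#'
#' @inheritParams run_density
#' @return List with `rings` (per-nucleus `ring_set`s), `profiles`
#'   (per-nucleus `ring_profile`s) and `table` (one row per nucleus).
#' @export
run_rings <- function(loc_paths, roi_paths, config = pipeline_config(),
                      out_dir = NULL) {
  stopifnot(length(loc_paths) == length(roi_paths))
  n <- length(loc_paths)
  ids <- .nucleus_ids(loc_paths, n)
  rings <- profiles <- vector("list", n)
  for (k in seq_len(n)) {
    tab <- read_localisations(loc_paths[k])
    roi <- read_roi(roi_paths[k])
    rings[[k]] <- build_rings(roi, config$n_rings)
    profiles[[k]] <- ring_profile(tab, rings[[k]])
    .log_msg("nucleus ", ids[k], ": ", profiles[[k]]$n_inside,
             " localisations across ", config$n_rings, " rings")
  }
  names(rings) <- names(profiles) <- ids
  tab_out <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tab_out <- write_ring_table(profiles, file.path(out_dir, "ring_profiles.csv"))
    .write_manifest(out_dir, config,
                    stats::setNames(as.list(c(loc_paths, roi_paths)),
                                    c(paste0("loc_", ids), paste0("roi_", ids))))
  } else {
    tmp <- tempfile(fileext = ".csv")
    tab_out <- write_ring_table(profiles, tmp)
    unlink(tmp)
  }
  list(rings = rings, profiles = profiles, table = tab_out)
}

#' Run the chromatin-compaction stage over a batch of nucleus images
#'
#' @param images list of [nucleus_image()] objects, or a character vector
#'   of single-channel TIFF paths (read at `config$pixel_size_um`).
#' @param config a [pipeline_config()].
#' @param groups optional group labels; a mode +/- SD cohort summary of
#'   compact percentage and nuclear area is computed per group.
#' @param out_dir optional output directory (per-nucleus CSV, cohort JSON,
#'   manifest).
#' @return List with `segmentations`, `table` (per-nucleus data.frame) and
#'   `cohort` (per-group [mode_sd_summary()] of `compact_percent` and
#'   `nucleus_area_um2`).
#' @export
run_compaction <- function(images, config = pipeline_config(), groups = NULL,
                           out_dir = NULL) {
  paths <- NULL
  if (is.character(images)) {
    paths <- images
    images <- lapply(images, read_nucleus_image,
                     pixel_size_um = config$pixel_size_um)
  }
  n <- length(images)
  if (is.null(groups)) groups <- rep("all", n)
  segs <- lapply(seq_len(n), function(k) {
    s <- analyze_chromatin_compaction(
      images[[k]],
      smoothing_sigma_px = config$smoothing_sigma_px,
      min_separation_px = config$min_separation_px,
      prominence_fraction = config$prominence_fraction,
      level_fraction = config$level_fraction)
    .log_msg("nucleus ", k, ": ", sprintf("%.1f", s$compact_percent),
             "% compact, ", s$n_domains, " domains")
    s
  })
  tab <- data.frame(
    nucleus_id = seq_len(n),
    group = groups,
    nucleus_area_um2 = vapply(segs, `[[`, numeric(1L), "nucleus_area_um2"),
    n_domains = vapply(segs, `[[`, numeric(1L), "n_domains"),
    compact_percent = vapply(segs, `[[`, numeric(1L), "compact_percent"),
    dark_area_um2 = vapply(segs, `[[`, numeric(1L), "dark_area_um2"))
  cohort <- lapply(split(tab, tab$group), function(d)
    list(compact_percent = mode_sd_summary(d$compact_percent),
         nucleus_area_um2 = mode_sd_summary(d$nucleus_area_um2)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tab, file.path(out_dir, "compaction.csv"), row.names = FALSE)
    jsonlite::write_json(lapply(cohort, function(g) lapply(g, unclass)),
                         file.path(out_dir, "cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    ins <- if (!is.null(paths)) stats::setNames(as.list(paths), basename(paths))
           else list()
    .write_manifest(out_dir, config, ins)
  }
  list(segmentations = segs, table = tab, cohort = cohort)
}

#' Run the miR-FISH quantification stage over a batch of tissue fields
#'
#' Each field is segmented into cells, classified at the configured
#' threshold, and summarised as the percentage of miR+ cells. When
#' `groups` has exactly two levels the field percentages are compared
#' with the one-sided rank-sum test (first level tested as greater).
#' Fields with zero detected cells are skipped with a warning.
#'
#' @param fields list of [tissue_field()] objects.
#' @param config a [pipeline_config()].
#' @param groups optional character vector of group labels per field.
#' @param alternative sidedness of the comparison (default `"greater"`:
#'   the first group level tends to larger percentages).
#' @param out_dir optional output directory (per-field cell CSVs, summary
#'   JSON, manifest).
#' @return List with `cells` (per-field records), `summaries` (data.frame
#'   of field percentages) and `comparison` (a `rank_sum_result` with a
#'   `significant` flag, or `NULL`).
#' @export
run_mir <- function(fields, config = pipeline_config(), groups = NULL,
                    alternative = "greater", out_dir = NULL) {
  n <- length(fields)
  if (is.null(groups)) groups <- rep("all", n)
  stopifnot(length(groups) == n)
  cells <- vector("list", n)
  rows <- list()
  for (k in seq_len(n)) {
    cl <- detect_cells(fields[[k]],
                       min_nucleus_area_um2 = config$min_nucleus_area_um2,
                       cytoplasm_width_px = config$cytoplasm_width_px)
    cl <- classify_mir_positive(cl, threshold = config$mir_threshold)
    cells[[k]] <- cl
    if (nrow(cl) == 0L) {
      warning("field ", k, ": no cells detected, skipped")
      next
    }
    fs <- field_summary(cl)
    .log_msg("field ", k, ": ", fs$n_cells, " cells, ",
             sprintf("%.1f", fs$percent_positive), "% miR+")
    rows[[length(rows) + 1L]] <- data.frame(
      field = k, group = groups[k], n_cells = fs$n_cells,
      n_positive = fs$n_positive, percent_positive = fs$percent_positive)
  }
  summaries <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(field = integer(), group = character(), n_cells = integer(),
               n_positive = integer(), percent_positive = numeric())
  comparison <- NULL
  lv <- unique(summaries$group)
  if (length(lv) == 2L) {
    comparison <- rank_sum_one_sided(
      summaries$percent_positive[summaries$group == lv[1L]],
      summaries$percent_positive[summaries$group == lv[2L]],
      alternative = alternative)
    comparison$groups <- lv
    comparison$significant <- comparison$p_value <= config$alpha
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_len(n))
      if (nrow(cells[[k]]) > 0L)
        write_cell_table(cells[[k]], file.path(out_dir, paste0("cells_field", k, ".csv")))
    out <- list(fields = summaries)
    if (!is.null(comparison)) out$comparison <- unclass(comparison)
    jsonlite::write_json(out, file.path(out_dir, "mir_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    .write_manifest(out_dir, config, list())
  }
  list(cells = cells, summaries = summaries, comparison = comparison)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("chromnano pipeline configuration:\n")
  for (nm in names(x))
    cat(sprintf("  %-22s %s\n", nm,
                if (is.null(x[[nm]])) "NULL" else format(x[[nm]])))
  invisible(x)
}
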