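#' Pipeline configuration
#'
#' All tunables of the batch analysis in one validated list. The config
#' round-trips losslessly through JSON via [write_config()] /
#' [read_config()].
#'
#' @param foci_threshold Intensity threshold for the damage mask, applied
#'   to the background-subtracted damage channel. This is an
#'   experiment-level constant chosen by the user (`"auto"` falls back to
#'   the isodata threshold of each image, for exploration only).
#' @param rolling_radius_px Rolling-ball radius (default 10 px; match the
#'   largest chromatin feature to preserve).
#' @param min_area_px,max_area_px Nucleus area filter in pixels (defaults
#'   5000 and `Inf`).
#' @param exclude_border Drop border-touching nuclei (default `TRUE`).
#' @param min_focus_px Minimum focus area (default 4 px).
#' @param max_quantile Normalizer quantile for [normalize_dna()] (default
#'   1, the strict in-nucleus maximum).
#' @param segment_on_subtracted Segment nuclei on the background-subtracted
#'   DNA channel instead of the raw one (default `FALSE`: count masks are
#'   generated from raw counterstain intensity).
#' @param channel_order Page order of two-page input TIFFs.
#' @param iccs [iccs_params()] list.
#' @param seed Seed for any randomized diagnostics (the core estimators
#'   are deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(foci_threshold, rolling_radius_px = 10,
                       min_area_px = 5000L, max_area_px = Inf,
                       exclude_border = TRUE, min_focus_px = 4L,
                       max_quantile = 1, segment_on_subtracted = FALSE,
                       channel_order = c("damage", "dna"),
                       iccs = iccs_params(), seed = 1L) {
  stopifnot(rolling_radius_px >= 1, min_area_px >= 0,
            max_area_px >= min_area_px, min_focus_px >= 1,
            max_quantile > 0, max_quantile <= 1)
  if (!(identical(foci_threshold, "auto") ||
        (is.numeric(foci_threshold) && length(foci_threshold) == 1L))) {
    stop("foci_threshold must be a number or 'auto'")
  }
  structure(list(foci_threshold = foci_threshold,
                 rolling_radius_px = rolling_radius_px,
                 min_area_px = min_area_px, max_area_px = max_area_px,
                 exclude_border = isTRUE(exclude_border),
                 min_focus_px = as.integer(min_focus_px),
                 max_quantile = max_quantile,
                 segment_on_subtracted = isTRUE(segment_on_subtracted),
                 channel_order = channel_order, iccs = iccs,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (is.infinite(x$max_area_px)) x$max_area_px <- NULL # JSON has no Inf
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$max_area_px <- x$max_area_px %||% Inf
  ic <- x$iccs
  x$iccs <- NULL
  cfg <- do.call(run_config, x)
  cfg$iccs <- do.call(iccs_params, as.list(ic))
  cfg
}

#' Analyse one two-channel field in memory
#'
#' Runs the full per-image chain: rolling-ball background subtraction of
#' both channels, nucleus segmentation into a count mask (from the raw DNA
#' channel by default), damage-mask generation, then per nucleus the focus
#' count, the normalized DNA density over the damage regions, and the ICCS
#' colocalization fractions. Deterministic for fixed inputs and config.
#'
#' @param ch1 Damage `channel_image` (raw).
#' @param ch2 DNA `channel_image` (raw).
#' @param config A [run_config()].
#' @param image_id Identifier recorded in the results.
#' @return List: `cells` (data frame, one row per segmented nucleus),
#'   `nuclei` (`count_mask`), `damage_mask`, `foci_threshold` (the value
#'   actually used).
#' @export
analyze_field <- function(ch1, ch2, config, image_id = "image") {
  stopifnot(inherits(config, "run_config"))
  A <- as_pixels(ch1, role = if (inherits(ch1, "channel_image")) "damage")
  B <- as_pixels(ch2, role = if (inherits(ch2, "channel_image")) "dna")
  if (!identical(dim(A), dim(B))) stop("channel shapes differ")
  sub1 <- rolling_ball_subtract(A, config$rolling_radius_px)
  sub2 <- rolling_ball_subtract(B, config$rolling_radius_px)
  seg_src <- if (config$segment_on_subtracted) sub2 else B
  nuclei <- segment_nuclei(seg_src, config$min_area_px,
                           config$exclude_border, config$max_area_px)
  thr <- if (identical(config$foci_threshold, "auto")) {
    isodata_threshold(sub1)
  } else config$foci_threshold
  dmask <- damage_mask(sub1, thr)

  empty_cells <- data.frame(
    image_id = character(), cell_id = integer(), area_px = integer(),
    n_foci = integer(), roi_area_px = integer(), dna_density = numeric(),
    f1 = numeric(), f2 = numeric(), w_cross_px = numeric(),
    w_auto1_px = numeric(), w_auto2_px = numeric(), G0_cross = numeric(),
    G0_auto1 = numeric(), G0_auto2 = numeric(), valid = logical(),
    reason = character())
  if (nuclei$n_objects == 0L) {
    warning(sprintf("image '%s': no nuclei segmented", image_id))
    return(list(cells = empty_cells, nuclei = nuclei, damage_mask = dmask,
                foci_threshold = thr))
  }

  iccs_res <- per_cell_iccs(sub1, sub2, nuclei, config$iccs)
  dens <- lapply(seq_len(nuclei$n_objects), function(id) {
    region <- nuclei$labels == id
    area <- sum(region)
    nf <- count_foci(dmask, region, config$min_focus_px)
    d <- tryCatch({
      nrm <- normalize_dna(sub2, region, config$max_quantile)
      dna_density(nrm, region, dmask)
    }, error = function(e) list(dna_density = NA_real_, roi_area_px = 0L,
                                flag = conditionMessage(e)))
    data.frame(cell_id = id, area_px = area, n_foci = nf,
               roi_area_px = d$roi_area_px, dna_density = d$dna_density,
               density_flag = d$flag)
  })
  dens <- do.call(rbind, dens)
  cells <- merge(dens, iccs_res, by = "cell_id", sort = TRUE)
  cells$reason <- ifelse(
    cells$density_flag == "" & cells$reason == "", "",
    trimws(paste(cells$reason, cells$density_flag, sep = " "), "both"))
  cells$density_flag <- NULL
  # undefined fractions iff flagged invalid
  cells$f1[!cells$valid] <- NA_real_
  cells$f2[!cells$valid] <- NA_real_
  cells <- cbind(data.frame(image_id = image_id), cells)
  cells <- cells[, names(empty_cells)]
  list(cells = cells, nuclei = nuclei, damage_mask = dmask,
       foci_threshold = thr)
}

#' Batch analysis over TIFF files
#'
#' Reads each input (one two-page TIFF or a pair of single-channel TIFFs),
#' analyses it with [analyze_field()], and writes `results.csv` (one row
#' per nucleus), `summary.csv` (per-image group summaries) and
#' `errors.csv` under `out_dir`. Per-image failures are recorded and the
#' batch continues. Running twice on identical inputs and config yields
#' byte-identical CSVs.
#'
#' @param inputs Data frame with columns `image_id`, `path_ch1` and
#'   optionally `path_ch2` (NA/missing for two-page files).
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param save_masks Also write per-image count masks (16-bit TIFF) and
#'   damage masks (8-bit TIFF).
#' @return Invisibly, list with `cells`, `summary`, `errors`.
#' @export
run_batch <- function(inputs, config, out_dir, save_masks = FALSE) {
  stopifnot(is.data.frame(inputs), all(c("image_id", "path_ch1") %in%
                                       names(inputs)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_cells <- list(); errors <- list()
  for (i in seq_len(nrow(inputs))) {
    id <- as.character(inputs$image_id[i])
    res <- tryCatch({
      p2 <- if ("path_ch2" %in% names(inputs)) inputs$path_ch2[i] else NA
      chs <- read_channels(inputs$path_ch1[i],
                           if (!is.na(p2) && nzchar(p2)) p2,
                           channel_order = config$channel_order)
      out <- analyze_field(chs$ch1, chs$ch2, config, image_id = id)
      if (save_masks) {
        write_tiff(matrix(as.numeric(out$nuclei$labels),
                          nrow(out$nuclei$labels)),
                   file.path(out_dir, paste0(id, "_count_mask.tif")),
                   bits = 16)
        write_tiff(out$damage_mask * 255,
                   file.path(out_dir, paste0(id, "_damage_mask.tif")),
                   bits = 8)
      }
      out$cells
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<-
        data.frame(image_id = id, error = conditionMessage(e))
      NULL
    })
    if (!is.null(res)) all_cells[[length(all_cells) + 1L]] <- res
  }
  cells <- if (length(all_cells)) do.call(rbind, all_cells) else
    analyze_empty_cells()
  errs <- if (length(errors)) do.call(rbind, errors) else
    data.frame(image_id = character(), error = character())
  summ <- if (nrow(cells)) summarize_cells(cells, "image_id") else
    data.frame()
  write.csv(cells, file.path(out_dir, "results.csv"), row.names = FALSE,
            na = "NA")
  write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE,
            na = "NA")
  write.csv(errs, file.path(out_dir, "errors.csv"), row.names = FALSE,
            na = "NA")
  invisible(list(cells = cells, summary = summ, errors = errs))
}

analyze_empty_cells <- function() {
  data.frame(image_id = character(), cell_id = integer(),
             area_px = integer(), n_foci = integer(),
             roi_area_px = integer(), dna_density = numeric(),
             f1 = numeric(), f2 = numeric(), w_cross_px = numeric(),
             w_auto1_px = numeric(), w_auto2_px = numeric(),
             G0_cross = numeric(), G0_auto1 = numeric(),
             G0_auto2 = numeric(), valid = logical(),
             reason = character())
}

#' Group summaries of per-cell results
#'
#' Mean and standard deviation of DNA density and of f1 per group, over
#' cells where the quantity is defined; `n_cells` counts cells with a
#' valid ICCS result. Exclusions are tallied by reason.
#'
#' @param cells Per-cell results data frame (from [analyze_field()] or
#'   read back from `results.csv`).
#' @param group_by Name of the grouping column (default `"image_id"`).
#' @return Data frame, one row per group: `group`, `n_cells`,
#'   `mean_dna_density`, `sd_dna_density`, `mean_f1`, `sd_f1`,
#'   `n_excluded`, `exclusion_reasons`.
#' @export
summarize_cells <- function(cells, group_by = "image_id") {
  if (nrow(cells) == 0L) stop("results table is empty")
  if (!group_by %in% names(cells)) {
    stop(sprintf("unknown grouping key '%s'", group_by))
  }
  groups <- unique(as.character(cells[[group_by]]))
  rows <- lapply(groups, function(g) {
    sub <- cells[as.character(cells[[group_by]]) == g, ]
    ok <- sub$valid & !is.na(sub$f1)
    dd <- sub$dna_density[!is.na(sub$dna_density)]
    excl <- sub$reason[!ok | is.na(sub$dna_density)]
    excl <- excl[nzchar(excl)]
    tally <- if (length(excl)) {
      tb <- sort(table(excl), decreasing = TRUE)
      paste(sprintf("%s (%d)", names(tb), as.integer(tb)), collapse = "; ")
    } else ""
    data.frame(group = g, n_cells = sum(ok),
               mean_dna_density = if (length(dd)) mean(dd) else NA_real_,
               sd_dna_density = if (length(dd) > 1) sd(dd) else NA_real_,
               mean_f1 = if (any(ok)) mean(sub$f1[ok]) else NA_real_,
               sd_f1 = if (sum(ok) > 1) sd(sub$f1[ok]) else NA_real_,
               n_excluded = sum(!ok),
               exclusion_reasons = tally)
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- group_by
  out
}
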