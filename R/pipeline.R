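# Batch pipeline: per-image processing (io -> preprocess -> segment ->
# skeleton -> quantify), zone/group roll-up, config snapshotting and
# logging. The analysis path is fully deterministic; randomness lives only
# in the synthetic generator.

#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis chain. A run's
#' effective configuration is always written as JSON next to its outputs,
#' and re-running from that snapshot reproduces the outputs exactly.
#'
#' @param um_per_px global spatial calibration (um/pixel); see
#'   [calibrate_from_scale_bar()].
#' @param preprocess a [preprocess_params()] object.
#' @param cleanup a [cleanup_params()] object.
#' @param dark_foreground stained structures are darker than background.
#' @param junction_merge_px passed to [build_branch_table()].
#' @param bin_edges_um branch-length histogram edges, micrometers.
#' @param gray_weights `"mean"` or `"luminance"` for RGB collapse.
#' @param save_intermediates write mask and skeleton PNGs per image.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(um_per_px = 1,
                            preprocess = preprocess_params(),
                            cleanup = cleanup_params(),
                            dark_foreground = TRUE,
                            junction_merge_px = 8,
                            bin_edges_um = default_bin_edges_um(),
                            gray_weights = "mean",
                            save_intermediates = FALSE) {
  if (um_per_px <= 0) stop_input("'um_per_px' must be positive")
  if (junction_merge_px < 0) stop_input("'junction_merge_px' must be >= 0")
  structure(list(um_per_px = um_per_px, preprocess = preprocess,
                 cleanup = cleanup,
                 dark_foreground = isTRUE(dark_foreground),
                 junction_merge_px = junction_merge_px,
                 bin_edges_um = bin_edges_um,
                 gray_weights = gray_weights,
                 save_intermediates = isTRUE(save_intermediates),
                 threshold_method = "max_entropy"),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as JSON
#'
#' Open-ended bin edges (`Inf`) survive the round trip (encoded as the
#' string `"Inf"`).
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @return `read_config` returns a `pipeline_config`; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$preprocess <- unclass(x$preprocess)
  x$cleanup <- unclass(x$cleanup)
  x$bin_edges_um <- as.character(x$bin_edges_um)
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    um_per_px = x$um_per_px,
    preprocess = do.call(preprocess_params, x$preprocess),
    cleanup = do.call(cleanup_params, x$cleanup),
    dark_foreground = x$dark_foreground,
    junction_merge_px = if (is.null(x$junction_merge_px)) 8
                        else x$junction_merge_px,
    bin_edges_um = as.numeric(x$bin_edges_um),
    gray_weights = x$gray_weights,
    save_intermediates = x$save_intermediates)
}

#' Process one calibrated image through the full chain
#'
#' FFT bandpass, unsharp mask, despeckle; maximum-entropy threshold with
#' mask cleanup; skeletonization; branch-table extraction; singleton
#' filtering and per-cell/per-image summaries.
#'
#' @param image a [calibrated_image()] (already 8-bit grayscale).
#' @param config a [pipeline_config()].
#' @param image_id identifier used in outputs.
#' @param area_um2 analysed area; defaults to the full field
#'   (`width * height * um_per_px^2`).
#' @return List: `threshold`, `preprocessed`, `mask`, `skeleton`,
#'   `branches` (raw branch table), `filtered`, `cells` (per-skeleton
#'   summaries), `scatter`, `summary` (an `image_summary`).
#' @export
process_image <- function(image, config = pipeline_config(),
                          image_id = "image", area_um2 = NULL) {
  stopifnot(inherits(image, "calibrated_image"))
  pp <- config$preprocess
  pre <- fft_bandpass(image, pp)
  pre <- unsharp_mask(pre, pp$unsharp_radius_px, pp$unsharp_weight)
  pre <- despeckle(pre)
  seg <- segment_image(pre, config$cleanup, config$dark_foreground)
  skel <- skeletonize(seg$mask)
  branches <- build_branch_table(skel, config$junction_merge_px)
  filtered <- filter_singletons(branches)
  cells <- summarize_skeletons(filtered)
  if (is.null(area_um2))
    area_um2 <- image$width_px * image$height_px * image$um_per_px^2
  summ <- summarize_image(cells, filtered$branch_length_um,
                          config$bin_edges_um, area_um2, image_id)
  list(threshold = seg$threshold, preprocessed = pre, mask = seg$mask,
       skeleton = skel, branches = branches, filtered = filtered,
       cells = cells, scatter = virtual_cell_points(cells), summary = summ)
}

image_summary_row <- function(s) {
  edges <- s$bin_edges_um
  k <- length(edges) - 1
  lab <- sprintf("mode_%s_%s", edges[-length(edges)], edges[-1])
  row <- data.frame(n_cells = s$n_cells, n_branches = s$n_branches,
                    total_length_um = s$total_length_um,
                    area_um2 = s$area_um2,
                    modal_bin = if (is.na(s$modal_bin)) NA_integer_
                                else s$modal_bin)
  for (i in seq_len(k)) row[[lab[i]]] <- s$binned_mode[i]
  row
}

#' Run the batch pipeline over a manifest
#'
#' The manifest CSV maps images to animals, zones and treatment groups
#' (columns `image`, `animal`, `zone`, `group`, optional `area_um2`).
#' Every image is processed independently; failures are logged and skipped
#' without aborting the batch, and the returned `exit_status` is nonzero
#' if any image failed. Outputs written to `outdir`: per-image
#' `<stem>_branches.csv` and `<stem>_cells.csv`, `image_summaries.csv`,
#' `zones.csv` (per animal x zone pooled), `groups.csv` (ratio metrics),
#' `scatter.csv` (virtual cell sizes), `config.json` (effective config
#' snapshot), `run.log`, and with `save_intermediates` the mask/skeleton
#' PNGs.
#'
#' @param manifest path to a manifest CSV, or an equivalent `data.frame`.
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if missing).
#' @return Invisibly, a list with `summaries`, `zones`, `groups`,
#'   `failures` (character vector of failed image paths) and
#'   `exit_status` (0 = all processed, 1 = partial failure).
#' @export
run_pipeline <- function(manifest, config = pipeline_config(), outdir) {
  man <- if (is.character(manifest)) {
    if (!file.exists(manifest)) stop_input("manifest not found: ", manifest)
    utils::read.csv(manifest, stringsAsFactors = FALSE)
  } else as.data.frame(manifest)
  req <- c("image", "animal", "zone", "group")
  if (!all(req %in% names(man)))
    stop_input("manifest needs columns: ", paste(req, collapse = ", "))
  if (nrow(man) == 0) stop_input("empty manifest")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop_input("cannot create output directory: ", outdir)

  logfile <- file.path(outdir, "run.log")
  cat(sprintf("astromorph run: %d image(s)\n", nrow(man)), file = logfile)
  logmsg <- function(...) {
    msg <- paste0(...)
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
    message(msg)
  }

  write_config(config, file.path(outdir, "config.json"))

  summaries <- list(); meta <- list(); failures <- character(0)
  scatter_all <- list()
  for (r in seq_len(nrow(man))) {
    path <- man$image[r]
    stem <- tools::file_path_sans_ext(basename(path))
    res <- tryCatch({
      img <- read_calibrated(path, um_per_px = config$um_per_px,
                             weights = config$gray_weights)
      area <- if ("area_um2" %in% names(man) && !is.na(man$area_um2[r]))
        man$area_um2[r] else NULL
      process_image(img, config, image_id = stem, area_um2 = area)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, path)
      logmsg("FAILED ", path, ": ", conditionMessage(res))
      next
    }
    br <- res$branches
    utils::write.csv(
      data.frame(image = stem, skeleton_id = br$skeleton_id,
                 branch_length_um = br$branch_length_um),
      file.path(outdir, paste0(stem, "_branches.csv")), row.names = FALSE)
    utils::write.csv(res$cells,
      file.path(outdir, paste0(stem, "_cells.csv")), row.names = FALSE)
    if (config$save_intermediates) {
      write_png(res$mask, file.path(outdir, paste0(stem, "_mask.png")))
      write_png(res$skeleton, file.path(outdir, paste0(stem, "_skeleton.png")))
    }
    summaries[[stem]] <- res$summary
    meta[[stem]] <- man[r, , drop = FALSE]
    if (nrow(res$scatter) > 0)
      scatter_all[[stem]] <- data.frame(image = stem,
                                        animal = man$animal[r],
                                        zone = man$zone[r],
                                        group = man$group[r], res$scatter)
    logmsg("processed ", path, ": threshold ", res$threshold, ", ",
           res$summary$n_cells, " cells, ", res$summary$n_branches,
           " branches")
  }

  if (length(summaries) == 0) {
    logmsg("no image processed successfully")
    out <- list(summaries = list(), zones = NULL, groups = NULL,
                failures = failures, exit_status = 1L)
    return(invisible(out))
  }

  metadf <- do.call(rbind, meta)
  metadf$stem <- names(summaries)
  img_rows <- do.call(rbind, lapply(names(summaries), function(s)
    cbind(data.frame(image = s, animal = metadf$animal[metadf$stem == s],
                     zone = metadf$zone[metadf$stem == s],
                     group = metadf$group[metadf$stem == s]),
          image_summary_row(summaries[[s]]))))
  utils::write.csv(img_rows, file.path(outdir, "image_summaries.csv"),
                   row.names = FALSE)

  zone_key <- paste(metadf$animal, metadf$zone, sep = "/")
  zones <- list(); group_rows <- list()
  for (zk in unique(zone_key)) {
    stems <- metadf$stem[zone_key == zk]
    zs <- summarize_zone(summaries[stems], zone_id = zk)
    zones[[zk]] <- zs
    gid <- metadf$group[zone_key == zk][1]
    aid <- metadf$animal[zone_key == zk][1]
    zid <- metadf$zone[zone_key == zk][1]
    group_rows[[zk]] <- suppressWarnings(
      group_metrics(zs, group_id = gid, animal_id = aid, zone_id = zid))
  }
  zone_rows <- do.call(rbind, lapply(names(zones), function(zk)
    cbind(data.frame(zone_key = zk), image_summary_row(zones[[zk]]))))
  utils::write.csv(zone_rows, file.path(outdir, "zones.csv"),
                   row.names = FALSE)
  groups <- do.call(rbind, group_rows)
  rownames(groups) <- NULL
  utils::write.csv(groups, file.path(outdir, "groups.csv"),
                   row.names = FALSE)
  scatter <- if (length(scatter_all) > 0) do.call(rbind, scatter_all)
             else data.frame(image = character(0), animal = character(0),
                             zone = character(0), group = character(0),
                             branch_count = integer(0),
                             total_branch_length_um = numeric(0))
  rownames(scatter) <- NULL
  utils::write.csv(scatter, file.path(outdir, "scatter.csv"),
                   row.names = FALSE)

  status <- if (length(failures) > 0) 1L else 0L
  logmsg("done: ", length(summaries), " processed, ", length(failures),
         " failed")
  invisible(list(summaries = summaries, zones = zones, groups = groups,
                 failures = failures, exit_status = status))
}
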