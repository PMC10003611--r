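# Data trimming and aggregation, reproducing the spreadsheet workflow:
# remove one-branch skeletons (not astrocytes), per-skeleton COUNTIF/SUMIF
# summaries, per-image "Key" tables, zone pooling, group ratios and the
# per-cell virtual-size scatter table.

#' Remove one-branch skeletons
#'
#' A skeleton with exactly one branch is not considered an astrocyte: every
#' record whose `skeleton_id` occurs exactly once in the raw branch table
#' is removed (the spreadsheet's duplicate filter on the Skeleton ID
#' column). All other records are preserved in order. Idempotent.
#'
#' @param records `data.frame` with columns `skeleton_id`,
#'   `branch_length_um` (one image's branch table).
#' @return The filtered `data.frame`.
#' @export
filter_singletons <- function(records) {
  check_branch_records(records)
  if (nrow(records) == 0) return(records)
  tab <- table(records$skeleton_id)
  keep <- tab[as.character(records$skeleton_id)] > 1L
  out <- records[as.vector(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

check_branch_records <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("skeleton_id", "branch_length_um") %in% names(records)))
    stop_input("branch records need columns 'skeleton_id', 'branch_length_um'")
  if (nrow(records) > 0 && any(records$branch_length_um < 0))
    stop_input("branch lengths must be non-negative")
  invisible(records)
}

#' Per-skeleton summaries (branch count and total branch length)
#'
#' One row per distinct `skeleton_id`: the number of branches (COUNTIF
#' analog) and the sum of their lengths (SUMIF analog). The input must
#' already be singleton-filtered; an id with a single record violates that
#' contract and raises an error.
#'
#' @param records singleton-filtered branch records.
#' @return `data.frame` with columns `skeleton_id`, `branch_count`,
#'   `total_branch_length_um`, ordered by `skeleton_id`.
#' @export
summarize_skeletons <- function(records) {
  check_branch_records(records)
  if (nrow(records) == 0)
    return(data.frame(skeleton_id = integer(0), branch_count = integer(0),
                      total_branch_length_um = numeric(0)))
  ids <- sort(unique(records$skeleton_id))
  f <- factor(records$skeleton_id, levels = ids)
  cnt <- as.integer(table(f))
  if (any(cnt < 2))
    stop_input("singleton skeleton_id present: input was not filtered")
  tot <- as.numeric(tapply(records$branch_length_um, f, sum))
  data.frame(skeleton_id = as.integer(ids), branch_count = cnt,
             total_branch_length_um = tot)
}

#' Per-image summary ("Key" table)
#'
#' Counts cells (filtered skeletons), totals branch length, and bins all
#' branch lengths into the configured intervals, each count divided by the
#' number of cells - the cell-normalized branch-length distribution (the
#' workflow's "mode" distribution). The final bin is closed on the right.
#'
#' @param summaries output of [summarize_skeletons()].
#' @param branch_lengths_um numeric vector of all (filtered) branch
#'   lengths in the image.
#' @param bin_edges_um strictly ascending bin edges; may end in `Inf`.
#' @param area_um2 analysed area of the image, square micrometers.
#' @param image_id identifier for the image.
#' @return List of class `image_summary`: `image_id`, `n_cells`,
#'   `n_branches`, `total_length_um`, `bin_edges_um`, `bin_counts`,
#'   `binned_mode` (counts / n_cells), `modal_bin` (index of the fullest
#'   bin), `area_um2`, `zero_cells` flag.
#' @export
summarize_image <- function(summaries, branch_lengths_um, bin_edges_um,
                            area_um2, image_id = "image") {
  if (any(diff(bin_edges_um) <= 0) || length(bin_edges_um) < 2)
    stop_input("'bin_edges_um' must be strictly ascending")
  if (!is.numeric(area_um2) || area_um2 <= 0)
    stop_input("'area_um2' must be positive")
  n_cells <- nrow(summaries)
  n_branches <- length(branch_lengths_um)
  counts <- bin_counts(branch_lengths_um, bin_edges_um)
  zero <- n_cells == 0
  mode <- if (zero) counts * 0 else counts / n_cells
  structure(list(
    image_id = as.character(image_id),
    n_cells = n_cells,
    n_branches = n_branches,
    total_length_um = if (zero) 0 else sum(summaries$total_branch_length_um),
    bin_edges_um = bin_edges_um,
    bin_counts = counts,
    binned_mode = mode,
    modal_bin = if (all(counts == 0)) NA_integer_ else which.max(counts),
    area_um2 = area_um2,
    zero_cells = zero), class = "image_summary")
}

# histogram counts with the last bin closed on the right
bin_counts <- function(x, edges) {
  k <- length(edges) - 1
  if (length(x) == 0) return(integer(k))
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  tabulate(idx[idx >= 1 & idx <= k], nbins = k)
}

#' @export
print.image_summary <- function(x, ...) {
  cat(sprintf("<image_summary> %s: %d cells, %d branches, %.2f um total\n",
              x$image_id, x$n_cells, x$n_branches, x$total_length_um))
  invisible(x)
}

#' Pool image summaries into a zone summary
#'
#' Zone-level information is the sum of its images: cell counts, branch
#' counts, total lengths, areas and raw bin counts are added, and the
#' normalized distribution is recomputed from the pooled counts over the
#' pooled cell number (never averaged across images).
#'
#' @param images list of `image_summary` objects sharing bin edges.
#' @param zone_id identifier for the pooled zone.
#' @return An `image_summary` describing the zone.
#' @export
summarize_zone <- function(images, zone_id = "zone") {
  if (length(images) < 1) stop_input("need at least one image summary")
  edges <- images[[1]]$bin_edges_um
  for (im in images)
    if (!isTRUE(all.equal(im$bin_edges_um, edges)))
      stop_input("images have mismatched bin edges")
  n_cells <- as.integer(sum(vapply(images, `[[`, 0, "n_cells")))
  counts <- Reduce(`+`, lapply(images, `[[`, "bin_counts"))
  zero <- n_cells == 0L
  structure(list(
    image_id = as.character(zone_id),
    n_cells = n_cells,
    n_branches = as.integer(sum(vapply(images, `[[`, 0, "n_branches"))),
    total_length_um = sum(vapply(images, `[[`, 0, "total_length_um")),
    bin_edges_um = edges,
    bin_counts = counts,
    binned_mode = if (zero) counts * 0 else counts / n_cells,
    modal_bin = if (all(counts == 0)) NA_integer_ else which.max(counts),
    area_um2 = sum(vapply(images, `[[`, 0, "area_um2")),
    zero_cells = zero), class = "image_summary")
}

#' Group metrics for one zone
#'
#' The three normalized group statistics: branches per cell (total branch
#' number over astrocyte number), cells per area (astrocyte number over
#' analysed area) and branch length per cell (total branch length over
#' astrocyte number). Zones without cells yield `NA` ratios with a warning
#' rather than a division error.
#'
#' @param zone an `image_summary` (typically from [summarize_zone()]).
#' @param group_id,animal_id,zone_id identifiers carried into the row.
#' @return One-row `data.frame` with columns `group_id`, `animal_id`,
#'   `zone_id`, `area_um2`, `n_cells`, `n_branches`, `total_length_um`,
#'   `branches_per_cell`, `cells_per_area`, `length_per_cell_um`.
#' @export
group_metrics <- function(zone, group_id = "group", animal_id = "animal",
                          zone_id = zone$image_id) {
  if (zone$area_um2 <= 0) stop_input("zone area must be positive")
  if (zone$n_cells == 0) {
    warning("zone has no cells; group ratios are undefined (NA)",
            call. = FALSE)
    bpc <- lpc <- NA_real_
  } else {
    bpc <- zone$n_branches / zone$n_cells
    lpc <- zone$total_length_um / zone$n_cells
  }
  data.frame(
    group_id = as.character(group_id),
    animal_id = as.character(animal_id),
    zone_id = as.character(zone_id),
    area_um2 = zone$area_um2,
    n_cells = zone$n_cells,
    n_branches = zone$n_branches,
    total_length_um = zone$total_length_um,
    branches_per_cell = bpc,
    cells_per_area = zone$n_cells / zone$area_um2,
    length_per_cell_um = lpc)
}

#' Virtual cell size scatter points
#'
#' One point per cell, pairing its branch count with its total branch
#' length - a scatter proxy for astrocyte size/activation.
#'
#' @param summaries output of [summarize_skeletons()].
#' @return `data.frame` with columns `branch_count`,
#'   `total_branch_length_um` (one row per cell).
#' @export
virtual_cell_points <- function(summaries) {
  data.frame(branch_count = summaries$branch_count,
             total_branch_length_um = summaries$total_branch_length_um)
}

#' Default branch-length bin edges
#'
#' The length intervals of the branch-size distribution are not canonical;
#' these defaults (in micrometers, final bin open-ended) are a deliberate,
#' fully configurable choice.
#'
#' @export
default_bin_edges_um <- function() c(0, 5, 10, 15, 20, 30, 50, Inf)
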