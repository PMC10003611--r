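# Synthetic DAB-like photomicrographs with exact ground truth: star-shaped
# dark cells (disk soma + straight arms) on a bright noisy background, plus
# isolated one-branch fragments that the downstream singleton filter must
# discard. Deterministic given the seed; the analysis path itself contains
# no randomness.

#' Specification for a synthetic photomicrograph
#'
#' Defaults describe the stated test world: a 1024 x 1024 field at
#' 0.5 um/px with well-separated cells bearing 3-6 straight arms of
#' 10-30 um drawn 3 px thick, dark staining (level ~60) on a bright
#' background (~200) with Gaussian noise (sd 8), and 5 singleton
#' fragments. The default soma is compact (radius 3 px = 3 um apparent
#' diameter, the dense perinuclear GFAP core): ground truth records each
#' arm from the soma boundary to its tip, and that truth is only
#' recoverable by skeletonization when the soma stays comparable to the
#' process thickness. Arms are straight - enough for contract testing,
#' and it keeps length ground truth exact.
#'
#' @param width_px,height_px canvas size in pixels.
#' @param um_per_px spatial calibration.
#' @param n_cells number of star-shaped cells.
#' @param branches_per_cell integer range `c(min, max)` of arms per cell.
#' @param branch_length_um range `c(min, max)` of arm lengths, soma
#'   boundary to tip, micrometers.
#' @param branch_thickness_px arm stroke thickness, pixels (>= 2).
#' @param soma_radius_px soma disk radius, pixels.
#' @param background_level,foreground_level 8-bit gray levels; staining is
#'   dark, so `foreground_level < background_level`.
#' @param noise_sd Gaussian noise standard deviation (gray levels).
#' @param n_singleton_fragments number of isolated short bars (one branch
#'   each) that must be discarded by the singleton filter.
#' @param min_arm_separation_rad minimum angular gap between arms of one
#'   cell, radians.
#' @param seed integer seed; generation is deterministic given it.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(width_px = 1024, height_px = 1024, um_per_px = 0.5,
                       n_cells = 10, branches_per_cell = c(3L, 6L),
                       branch_length_um = c(10, 30),
                       branch_thickness_px = 3L, soma_radius_px = 3L,
                       background_level = 200L, foreground_level = 60L,
                       noise_sd = 8, n_singleton_fragments = 5L,
                       min_arm_separation_rad = 0.5, seed = 1L) {
  if (foreground_level >= background_level)
    stop_input("foreground_level must be darker than background_level")
  if (branch_thickness_px < 2) stop_input("branch_thickness_px must be >= 2")
  if (n_cells < 0 || n_singleton_fragments < 0)
    stop_input("counts must be non-negative")
  if (branches_per_cell[1] < 1 || branches_per_cell[2] < branches_per_cell[1])
    stop_input("invalid branches_per_cell range")
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 um_per_px = um_per_px, n_cells = as.integer(n_cells),
                 branches_per_cell = as.integer(branches_per_cell),
                 branch_length_um = branch_length_um,
                 branch_thickness_px = as.integer(branch_thickness_px),
                 soma_radius_px = as.integer(soma_radius_px),
                 background_level = as.integer(background_level),
                 foreground_level = as.integer(foreground_level),
                 noise_sd = noise_sd,
                 n_singleton_fragments = as.integer(n_singleton_fragments),
                 min_arm_separation_rad = min_arm_separation_rad,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# paint a disk of given radius at (ci, cj) into canvas (dark level)
paint_disk <- function(canvas, ci, cj, radius, level) {
  h <- nrow(canvas); w <- ncol(canvas)
  r <- ceiling(radius)
  ii <- max(1, ci - r):min(h, ci + r)
  jj <- max(1, cj - r):min(w, cj + r)
  d2 <- outer((ii - ci)^2, (jj - cj)^2, "+")
  sub <- canvas[ii, jj, drop = FALSE]
  sub[d2 <= radius^2] <- level
  canvas[ii, jj] <- sub
  canvas
}

# paint a straight stroke from (i0,j0) to (i1,j1) of given thickness:
# pixels within thickness/2 of the segment (distance to segment computed
# vectorized over the stroke's bounding box)
paint_stroke <- function(canvas, i0, j0, i1, j1, thickness, level) {
  h <- nrow(canvas); w <- ncol(canvas)
  r <- thickness / 2
  ii <- max(1, floor(min(i0, i1) - r - 1)):min(h, ceiling(max(i0, i1) + r + 1))
  jj <- max(1, floor(min(j0, j1) - r - 1)):min(w, ceiling(max(j0, j1) + r + 1))
  di <- i1 - i0; dj <- j1 - j0
  L2 <- di^2 + dj^2
  pi_ <- matrix(ii, length(ii), length(jj))
  pj_ <- matrix(jj, length(ii), length(jj), byrow = TRUE)
  t <- if (L2 == 0) 0 else pmin(pmax(((pi_ - i0) * di + (pj_ - j0) * dj) / L2, 0), 1)
  d2 <- (pi_ - (i0 + t * di))^2 + (pj_ - (j0 + t * dj))^2
  sub <- canvas[ii, jj, drop = FALSE]
  sub[d2 <= r^2] <- level
  canvas[ii, jj] <- sub
  canvas
}

# rejection-sample k angles with a minimum circular separation
draw_angles <- function(k, min_sep) {
  for (attempt in 1:200) {
    a <- sort(runif(k, 0, 2 * pi))
    gaps <- c(diff(a), 2 * pi - (a[k] - a[1]))
    if (k == 1 || min(gaps) >= min_sep) return(a)
  }
  stop_input("cannot place ", k, " arms with the requested angular separation")
}

#' Generate a synthetic photomicrograph with ground truth
#'
#' Places `n_cells` star-shaped cells (dark soma disk plus straight dark
#' arms of recorded length at random angles) and
#' `n_singleton_fragments` isolated short bars, enforcing a minimum
#' centre-to-centre distance of twice the maximum arm length so cells
#' never overlap, then adds Gaussian noise and clips to 0..255. Ground
#' truth lengths are measured from the soma boundary to the arm tip - what
#' skeletonization can in principle recover.
#'
#' @param spec a [synth_spec()].
#' @return List with elements `image` (a [calibrated_image()]) and
#'   `truth`: `cells` (`data.frame`: `cell_id`, `center_x_px`,
#'   `center_y_px`, `branch_count`), `branches` (`data.frame`: `cell_id`,
#'   `branch_length_um`), `n_singletons`, `fragments` (centres), `seed`.
#' @export
synth_generate <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, synth_generate_impl(spec))
}

synth_generate_impl <- function(spec) {
  h <- spec$height_px; w <- spec$width_px
  max_len_px <- spec$branch_length_um[2] / spec$um_per_px
  frag_len_um <- c(4, 8)  # short bars: one skeleton branch each
  margin <- ceiling(spec$soma_radius_px + max_len_px +
                    spec$branch_thickness_px + 2)
  min_dist <- 2 * max_len_px
  n_objects <- spec$n_cells + spec$n_singleton_fragments

  if (n_objects > 0 && (w - 2 * margin < 1 || h - 2 * margin < 1))
    stop_input("canvas too small for the requested cell geometry")

  centers <- matrix(numeric(0), 0, 2)
  for (k in seq_len(n_objects)) {
    placed <- FALSE
    for (attempt in 1:2000) {
      ci <- runif(1, margin, h - margin)
      cj <- runif(1, margin, w - margin)
      if (nrow(centers) == 0 ||
          min(sqrt((centers[, 1] - ci)^2 + (centers[, 2] - cj)^2)) >= min_dist) {
        centers <- rbind(centers, c(ci, cj))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop_input("canvas too small: cannot place ", n_objects,
                 " objects at the required separation")
  }

  canvas <- matrix(as.numeric(spec$background_level), h, w)
  fg <- spec$foreground_level

  cells <- data.frame(cell_id = integer(0), center_x_px = numeric(0),
                      center_y_px = numeric(0), branch_count = integer(0))
  branches <- data.frame(cell_id = integer(0), branch_length_um = numeric(0))

  for (k in seq_len(spec$n_cells)) {
    ci <- centers[k, 1]; cj <- centers[k, 2]
    nb <- if (spec$branches_per_cell[1] == spec$branches_per_cell[2])
      spec$branches_per_cell[1]
    else sample(spec$branches_per_cell[1]:spec$branches_per_cell[2], 1)
    angles <- draw_angles(nb, spec$min_arm_separation_rad)
    lens_um <- runif(nb, spec$branch_length_um[1], spec$branch_length_um[2])
    canvas <- paint_disk(canvas, ci, cj, spec$soma_radius_px, fg)
    for (a in seq_len(nb)) {
      len_px <- lens_um[a] / spec$um_per_px
      r0 <- spec$soma_radius_px
      di <- sin(angles[a]); dj <- cos(angles[a])
      canvas <- paint_stroke(canvas,
                             ci + r0 * di, cj + r0 * dj,
                             ci + (r0 + len_px) * di, cj + (r0 + len_px) * dj,
                             spec$branch_thickness_px, fg)
    }
    cells <- rbind(cells, data.frame(cell_id = k, center_x_px = cj,
                                     center_y_px = ci, branch_count = nb))
    branches <- rbind(branches, data.frame(cell_id = k,
                                           branch_length_um = lens_um))
  }

  frag_centers <- matrix(numeric(0), 0, 2)
  for (k in seq_len(spec$n_singleton_fragments)) {
    idx <- spec$n_cells + k
    ci <- centers[idx, 1]; cj <- centers[idx, 2]
    ang <- runif(1, 0, pi)
    len_px <- runif(1, frag_len_um[1], frag_len_um[2]) / spec$um_per_px
    canvas <- paint_stroke(canvas,
                           ci - len_px / 2 * sin(ang), cj - len_px / 2 * cos(ang),
                           ci + len_px / 2 * sin(ang), cj + len_px / 2 * cos(ang),
                           spec$branch_thickness_px, fg)
    frag_centers <- rbind(frag_centers, c(cj, ci))
  }

  if (spec$noise_sd > 0)
    canvas <- canvas + rnorm(length(canvas), 0, spec$noise_sd)
  canvas <- matrix(iround(canvas), h, w)
  canvas[canvas < 0L] <- 0L; canvas[canvas > 255L] <- 255L

  list(image = calibrated_image(canvas, spec$um_per_px),
       truth = list(cells = cells, branches = branches,
                    n_singletons = spec$n_singleton_fragments,
                    fragments = frag_centers, seed = spec$seed))
}
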