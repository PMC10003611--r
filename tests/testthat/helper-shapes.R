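# Programmatic fixtures: masks and images built in code at test time.

# random blob mask: thresholded smoothed noise, guaranteed non-trivial
random_blob_mask <- function(n = 64, p = 0.35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(rnorm(n * n), n, n)
  sm <- astromorph:::cpp_gaussian_blur(z, 1.5)
  matrix(as.integer(sm > quantile(sm, 1 - p)), n, n)
}

# horizontal 1-px line of given length inside a field
line_mask <- function(len, n = len + 4, diagonal = FALSE) {
  m <- matrix(0L, n, n)
  if (diagonal) for (k in seq_len(len)) m[1 + k, 1 + k] <- 1L
  else m[3, 2 + seq_len(len)] <- 1L
  m
}

# Y: three straight 1-px arms meeting at one junction pixel
y_mask <- function(arm = 5) {
  n <- 2 * arm + 5
  m <- matrix(0L, n, n)
  cx <- arm + 3
  for (k in 0:arm) {
    m[cx - k, cx] <- 1L        # arm up
    m[cx + k, cx - k] <- 1L    # arm down-left (diagonal)
    m[cx + k, cx + k] <- 1L    # arm down-right (diagonal)
  }
  m
}

as_skel <- function(m, um = 1) {
  structure(list(pixels = m, um_per_px = um),
            class = c("skeleton_mask", "binary_mask"))
}

# tiny synthetic scene used by pipeline/CLI tests (fast to process)
small_scene_spec <- function(seed, n_cells = 3, n_frag = 2) {
  synth_spec(width_px = 256, height_px = 256, um_per_px = 0.5,
             n_cells = n_cells, branch_length_um = c(8, 15),
             n_singleton_fragments = n_frag, seed = seed)
}
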