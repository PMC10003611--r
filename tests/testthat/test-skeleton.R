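# skeleton: thinning and branch-table extraction

test_that("skeletonize leaves 1-px lines unchanged and empties empty masks", {
  m <- line_mask(9)
  expect_identical(skeletonize(binary_mask(m, 1))$pixels, m)
  em <- matrix(0L, 6, 6)
  sk <- skeletonize(binary_mask(em, 1))
  expect_identical(sum(sk$pixels), 0L)
  expect_identical(nrow(build_branch_table(sk)), 0L)
})

test_that("a filled 9x3 rectangle thins to a spanning 1-px path", {
  m <- matrix(0L, 9, 15); m[4:6, 4:12] <- 1L
  sk <- skeletonize(binary_mask(m, 1))
  expect_true(all(sk$pixels[m == 0L] == 0L))                # subset
  expect_false(astromorph:::has_2x2_block(sk$pixels == 1L)) # thin
  expect_identical(max(astromorph:::cpp_label8(sk$pixels)), 1L)
  # spans the long axis; the thinner erodes at most ceil(thickness/2) + 1
  # pixels per end (tip rounding, documented)
  cols <- range(which(sk$pixels == 1L, arr.ind = TRUE)[, 2])
  expect_gte(diff(cols) + 1, 9 - 3)
})

test_that("skeleton invariants hold on random blob masks", {
  for (s in 1:20) {
    m <- random_blob_mask(64, seed = 400 + s)
    sk <- skeletonize(binary_mask(m, 1))
    expect_true(all(sk$pixels[m == 0L] == 0L))
    expect_false(astromorph:::has_2x2_block(sk$pixels == 1L))
    expect_identical(max(astromorph:::cpp_label8(sk$pixels)),
                     max(astromorph:::cpp_label8(m)))
  }
})

test_that("branch lengths are exact chain lengths times calibration", {
  # straight horizontal 11 px at 0.5 um/px -> one 5.0 um branch
  bt <- build_branch_table(as_skel(line_mask(11), um = 0.5))
  expect_identical(nrow(bt), 1L)
  expect_equal(bt$branch_length_um, 5.0, tolerance = 1e-12)
  # diagonal 5 px at 1 um/px -> 4 sqrt(2)
  btd <- build_branch_table(as_skel(line_mask(5, diagonal = TRUE)))
  expect_equal(btd$branch_length_um, 4 * sqrt(2), tolerance = 1e-12)
  # doubling um_per_px doubles every length
  bt2 <- build_branch_table(as_skel(line_mask(11), um = 1.0))
  expect_equal(bt2$branch_length_um, 2 * bt$branch_length_um)
})

test_that("a Y-shape yields exactly 3 branches in one component", {
  bt <- build_branch_table(as_skel(y_mask(5)))
  expect_identical(nrow(bt), 3L)
  expect_identical(unique(bt$skeleton_id), 1L)
  # arms: one straight (5 steps), two diagonal (5 steps each)
  expect_equal(sort(bt$branch_length_um), sort(c(5, 5 * sqrt(2), 5 * sqrt(2))),
               tolerance = 1e-12)
})

test_that("degenerate components still appear in the table", {
  m <- matrix(0L, 7, 7); m[4, 4] <- 1L        # isolated pixel
  bt <- build_branch_table(as_skel(m))
  expect_identical(nrow(bt), 1L)
  expect_identical(bt$branch_length_um, 0)
  m2 <- matrix(0L, 7, 7); m2[4, 4:5] <- 1L    # two-pixel component
  bt2 <- build_branch_table(as_skel(m2))
  expect_identical(nrow(bt2), 1L)
  expect_equal(bt2$branch_length_um, 1)
})

test_that("isolated cycles measure the full closed path", {
  # diamond ring: |i-c| + |j-c| == 3; every pixel has exactly two
  # (diagonal) neighbours, so the component is a pure 12-step cycle
  m <- matrix(0L, 9, 9)
  for (i in 1:9) for (j in 1:9) if (abs(i - 5) + abs(j - 5) == 3) m[i, j] <- 1L
  bt <- build_branch_table(as_skel(m))
  expect_identical(nrow(bt), 1L)
  expect_equal(bt$branch_length_um, 12 * sqrt(2), tolerance = 1e-12)
})

test_that("total branch length is invariant to translation and rotation", {
  for (s in 1:5) {
    m <- skeletonize(binary_mask(random_blob_mask(48, seed = 90 + s), 1))$pixels
    tot <- function(mm) sum(build_branch_table(as_skel(mm))$branch_length_um)
    base <- tot(m)
    shifted <- matrix(0L, 58, 58); shifted[6:53, 6:53] <- m
    expect_equal(tot(shifted), base, tolerance = 1e-9)
    rotated <- t(m)[ncol(m):1, ]  # 90 degrees
    expect_equal(tot(rotated), base, tolerance = 1e-9)
  }
})

test_that("skeleton_id set covers every 8-connected component", {
  for (s in 1:8) {
    m <- skeletonize(binary_mask(random_blob_mask(48, seed = 700 + s), 1))$pixels
    bt <- build_branch_table(as_skel(m))
    expect_identical(sort(unique(bt$skeleton_id)),
                     seq_len(max(astromorph:::cpp_label8(m))))
  }
})

test_that("non-thin input raises a contract error", {
  m <- matrix(0L, 6, 6); m[2:3, 2:3] <- 1L
  expect_error(build_branch_table(as_skel(m)), "thin")
})

test_that("short junction-junction connectors merge into one node region", {
  # H-shape: two 3-way junctions joined by a 6-px bridge
  m <- matrix(0L, 11, 13)
  m[2:10, 3] <- 1L                    # left bar
  m[2:10, 11] <- 1L                   # right bar
  m[6, 4:10] <- 1L                    # bridge between the two junctions
  bt_raw <- build_branch_table(as_skel(m), junction_merge_px = 0)
  expect_identical(nrow(bt_raw), 5L)  # 4 arms + the bridge
  expect_equal(sort(bt_raw$branch_length_um), c(3, 3, 3, 3, 6))
  bt <- build_branch_table(as_skel(m), junction_merge_px = 8)
  expect_identical(nrow(bt), 4L)      # bridge absorbed into the node region
  expect_equal(sort(bt$branch_length_um), rep(3, 4))
})
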