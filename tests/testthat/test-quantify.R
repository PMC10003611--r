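# quantify: singleton filter, per-skeleton/image/zone summaries, group
# ratios, virtual cell points

rec <- function(ids, lens) data.frame(skeleton_id = ids, branch_length_um = lens)

test_that("filter_singletons drops one-branch skeletons and is idempotent", {
  r <- rec(c(1, 1, 2, 3, 3, 3), c(1, 2, 3, 4, 5, 6))
  out <- filter_singletons(r)
  expect_identical(out$skeleton_id, c(1, 1, 3, 3, 3))
  expect_identical(out$branch_length_um, c(1, 2, 4, 5, 6))
  expect_identical(filter_singletons(out), out)
  expect_identical(nrow(filter_singletons(rec(1:5, 1:5))), 0L)
  empty <- rec(integer(0), numeric(0))
  expect_identical(nrow(filter_singletons(empty)), 0L)
})

test_that("summarize_skeletons reproduces COUNTIF/SUMIF semantics", {
  r <- rec(c(1, 1, 3, 3, 3), c(2, 3, 1.5, 2.5, 4))
  s <- summarize_skeletons(r)
  expect_identical(s$skeleton_id, c(1L, 3L))
  expect_identical(s$branch_count, c(2L, 3L))
  expect_equal(s$total_branch_length_um, c(5, 8))
  # ids with identical lengths stay independent
  r2 <- rec(c(4, 4, 9, 9), c(1, 2, 1, 2))
  s2 <- summarize_skeletons(r2)
  expect_equal(s2$total_branch_length_um, c(3, 3))
  # contract: unfiltered input is rejected
  expect_error(summarize_skeletons(rec(c(1, 1, 2), c(1, 2, 3))), "singleton")
})

test_that("filter + summarize equals the spreadsheet oracle on random data", {
  set.seed(101)
  ids <- sample(1:120, 1000, replace = TRUE)
  lens <- round(runif(1000, 0.1, 40), 3)
  got <- summarize_skeletons(filter_singletons(rec(ids, lens)))
  ref <- oracle_spreadsheet(ids, lens)
  expect_identical(got$skeleton_id, ref$skeleton_id)
  expect_identical(got$branch_count, ref$branch_count)
  expect_equal(got$total_branch_length_um, ref$total_branch_length_um,
               tolerance = 1e-9)
  # conservation
  filt <- filter_singletons(rec(ids, lens))
  expect_identical(sum(got$branch_count), nrow(filt))
  expect_equal(sum(got$total_branch_length_um), sum(filt$branch_length_um),
               tolerance = 1e-9 * nrow(filt))
})

test_that("summarize_image bins lengths normalized by cell count", {
  s <- summarize_skeletons(rec(c(1, 1, 3, 3, 3), c(2.1, 2.3, 7.5, 1, 1)))
  # worked example: lengths [2.1, 2.3, 7.5], edges [0,5,10], 2 cells
  im <- summarize_image(s[1:2, ], c(2.1, 2.3, 7.5), c(0, 5, 10), 100, "im")
  expect_identical(im$n_cells, 2L)
  expect_equal(im$binned_mode, c(1.0, 0.5))
  expect_identical(im$modal_bin, 1L)
  # single [0, Inf) bin equals branches per cell
  im2 <- summarize_image(s, c(2.1, 2.3, 7.5, 1, 1), c(0, Inf), 100)
  expect_equal(im2$binned_mode, 5 / 2)
  # conservation: sum(binned_mode) * n_cells = n_branches
  expect_equal(sum(im2$binned_mode) * im2$n_cells, im2$n_branches)
  # zero cells flagged, all-zero distribution
  im0 <- summarize_image(s[0, ], numeric(0), c(0, 5, 10), 100)
  expect_true(im0$zero_cells)
  expect_identical(im0$n_cells, 0L)
  expect_equal(im0$total_length_um, 0)
  expect_true(all(im0$binned_mode == 0))
  expect_error(summarize_image(s[1:2, ], 1:3, c(5, 0), 100), "ascending")
})

test_that("final bin is closed on the right", {
  s <- summarize_skeletons(rec(c(1, 1), c(5, 10)))
  im <- summarize_image(s, c(5, 10), c(0, 5, 10), 100)
  expect_identical(sum(im$bin_counts), 2L)  # the 10 falls in the last bin
  expect_equal(im$bin_counts, c(0L, 2L))    # bins [0,5), [5,10]
})

test_that("summarize_zone pools rather than averages", {
  mk <- function(ids, lens, area) {
    f <- filter_singletons(rec(ids, lens))
    summarize_image(summarize_skeletons(f), f$branch_length_um,
                    c(0, 5, 10, Inf), area)
  }
  a <- mk(c(1, 1, 1, 2), c(1, 2, 3, 9), 100)        # id 2 filtered out
  b <- mk(c(1, 1, 5, 5, 5, 5, 9), c(6, 7, 1, 2, 3, 4, 2), 250)
  z <- summarize_zone(list(a, b), "z")
  expect_identical(z$n_cells, a$n_cells + b$n_cells)
  expect_equal(z$total_length_um, a$total_length_um + b$total_length_um)
  expect_equal(z$area_um2, 350)
  # pooled recompute oracle: bin all branches together, divide by all cells
  pooled <- mk(c(1, 1, 1, 11, 11, 15, 15, 15, 15), c(1, 2, 3, 6, 7, 1, 2, 3, 4), 1)
  expect_equal(z$bin_counts, pooled$bin_counts)
  expect_equal(z$binned_mode, pooled$bin_counts / z$n_cells)
  # identity on one image
  z1 <- summarize_zone(list(a), "z1")
  expect_equal(z1$binned_mode, a$binned_mode)
  # mismatched bin edges rejected
  bad <- mk(c(1, 1), c(1, 2), 10); bad$bin_edges_um <- c(0, 1, Inf)
  expect_error(summarize_zone(list(a, bad)), "bin edges")
})

test_that("group_metrics computes the three ratios exactly", {
  z <- structure(list(image_id = "z", n_cells = 50L, n_branches = 150L,
                      total_length_um = 1200, bin_edges_um = c(0, Inf),
                      bin_counts = 150L, binned_mode = 3, modal_bin = 1L,
                      area_um2 = 250000, zero_cells = FALSE),
                 class = "image_summary")
  g <- group_metrics(z, "ctrl", "rat1", "CA3")
  expect_equal(g$branches_per_cell, 3.0)
  expect_equal(g$cells_per_area, 2e-4)
  expect_equal(g$length_per_cell_um, 24)
  expect_identical(g$group_id, "ctrl")
  # zero cells: NA ratios with a warning, no crash
  z0 <- z; z0$n_cells <- 0L; z0$n_branches <- 0L; z0$total_length_um <- 0
  expect_warning(g0 <- group_metrics(z0), "no cells")
  expect_true(is.na(g0$branches_per_cell))
  expect_true(is.na(g0$length_per_cell_um))
  expect_equal(g0$cells_per_area, 0)
})

test_that("group ratios are scale-consistent", {
  mk <- function(k) {
    ids <- rep(seq_len(10 * k), each = 3)
    f <- rec(ids, rep(c(5, 7, 9), 10 * k))
    s <- summarize_skeletons(f)
    summarize_image(s, f$branch_length_um, c(0, Inf), 1000 * k)
  }
  g1 <- group_metrics(mk(1)); g2 <- group_metrics(mk(2))
  expect_identical(g2$n_cells, 2L * g1$n_cells)
  expect_identical(g2$n_branches, 2L * g1$n_branches)
  expect_equal(g2$total_length_um, 2 * g1$total_length_um)
  expect_equal(g2$branches_per_cell, g1$branches_per_cell)
  expect_equal(g2$length_per_cell_um, g1$length_per_cell_um)
  expect_equal(g2$cells_per_area, g1$cells_per_area)
})

test_that("virtual_cell_points is a per-cell bijection", {
  s <- summarize_skeletons(rec(c(1, 1, 3, 3, 3), c(2, 3, 1.5, 2.5, 4)))
  pts <- virtual_cell_points(s)
  expect_identical(nrow(pts), nrow(s))
  expect_identical(pts$branch_count, c(2L, 3L))
  expect_equal(pts$total_branch_length_um, c(5, 8))
  expect_identical(nrow(virtual_cell_points(s[0, ])), 0L)
})
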