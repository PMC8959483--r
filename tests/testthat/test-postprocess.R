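fake_map <- function(p, dens_window = c(0, nrow(p) / 10),
                     dose_window = c(0, ncol(p) / 10)) {
  structure(
    list(p_values = p,
         n_used = matrix(10L, nrow(p), ncol(p)),
         metric_pair = c("mean", "dose_sd"),
         density_distances = (dens_window[1] * 10 + seq_len(nrow(p)) - 0.5) / 10,
         dose_distances = (dose_window[1] * 10 + seq_len(ncol(p)) - 0.5) / 10,
         min_events = 10L),
    class = "interaction_map")
}

region_from_cells <- function(cells) {
  new_map_region <- getFromNamespace("new_map_region", "coxradius")
  new_map_region(cells, fake_map(matrix(1, nrow(cells), ncol(cells))))
}

test_that("significant cells threshold p < alpha and exclude missing", {
  p <- matrix(1, 4, 4)
  m <- fake_map(p)
  expect_false(any(significant_cells(m)))
  m$p_values[] <- 0.01
  expect_true(all(significant_cells(m)))
  m$p_values <- matrix(c(0.04, 0.05, NA, 0.0499, 0.2, 0.049,
                         rep(1, 10)), 4, 4)
  s <- significant_cells(m)
  expect_identical(sum(s), 3L)                    # hand tally
  expect_false(s[3, 1])                           # missing cell
})

test_that("connected components use 8-connectivity", {
  b <- matrix(FALSE, 5, 5)
  b[1, 1] <- TRUE
  b[2, 2] <- TRUE                                  # diagonal touch
  b[5, 5] <- TRUE                                  # isolated island
  regs <- connected_regions(b, fake_map(matrix(1, 5, 5)))
  expect_length(regs, 2L)
  expect_identical(sum(regs[[1]]$cells), 2L)
  # L-shape plus island matches manual labelling
  b2 <- matrix(FALSE, 6, 6)
  b2[1:4, 2] <- TRUE
  b2[4, 2:5] <- TRUE
  b2[1, 5:6] <- TRUE
  regs2 <- connected_regions(b2, fake_map(matrix(1, 6, 6)))
  expect_length(regs2, 2L)
  sizes <- sort(vapply(regs2, function(r) sum(r$cells), integer(1)))
  expect_identical(sizes, c(2L, 7L))
})

test_that("thin-run pruning removes tails, keeps blocks, empties 2x2", {
  solid <- matrix(FALSE, 9, 9)
  solid[3:7, 3:7] <- TRUE
  r <- prune_thin(region_from_cells(solid))
  expect_identical(r$cells, solid)                 # 5x5 block unchanged

  tail1 <- solid
  tail1[8:9, 5] <- TRUE                            # 1-wide tail below block
  r2 <- prune_thin(region_from_cells(tail1))
  expect_identical(r2$cells, solid)                # tail rows removed

  two <- matrix(FALSE, 4, 4)
  two[2:3, 2:3] <- TRUE
  r3 <- prune_thin(region_from_cells(two))
  expect_false(any(r3$cells))                      # all runs < 3: emptied

  # idempotent once stable; never adds cells
  r4 <- prune_thin(r2)
  expect_identical(r4$cells, r2$cells)
  expect_true(all(r2$cells <= tail1))
})

test_that("box averaging reproduces hand-computed extents and screens", {
  solid <- matrix(FALSE, 9, 9)
  solid[3:7, 3:7] <- TRUE
  b <- box_and_screen(region_from_cells(solid))
  expect_identical(b$status, "boxed")
  expect_equal(b$box$width_mm, 5)
  expect_equal(b$box$height_mm, 5)
  expect_equal(b$box$centre, c(0.45, 0.45))        # centroid of rows/cols 3..7
  expect_equal(diff(b$box$density), 0.5)           # 5 mm in cm

  rect <- matrix(FALSE, 12, 6)
  rect[2:11, 2:4] <- TRUE                          # 10 wide x 3 tall
  b2 <- box_and_screen(region_from_cells(rect))
  expect_identical(b2$status, "boxed")
  expect_equal(b2$box$width_mm, 10)
  expect_equal(b2$box$height_mm, 3)

  # staircase with mean density extent 2.4 mm -> rejected
  stair <- matrix(FALSE, 8, 5)
  stair[1:2, 1] <- TRUE
  stair[2:3, 2] <- TRUE
  stair[3:5, 3] <- TRUE
  stair[5:7, 4] <- TRUE
  stair[7:8, 5] <- TRUE
  extents <- c(2, 2, 3, 3, 2)                      # hand mean = 2.4
  b3 <- box_and_screen(region_from_cells(stair))
  expect_equal(b3$box$width_mm, mean(extents))
  expect_identical(b3$status, "rejected_size")

  empty <- box_and_screen(region_from_cells(matrix(FALSE, 4, 4)))
  expect_identical(empty$status, "rejected_size")
})

test_that("boxes of accepted regions stay inside the map windows", {
  edge <- matrix(FALSE, 6, 6)
  edge[1:4, 1:4] <- TRUE
  b <- box_and_screen(region_from_cells(edge))
  expect_gte(b$box$density[1], 0)
  expect_gte(b$box$dose[1], 0)
  expect_lte(b$box$density[2], 0.6)
  expect_lte(b$box$dose[2], 0.6)
})

test_that("near-zero variance matches the hand tallies", {
  expect_true(near_zero_variance(rep(5, 10), 0.1))         # constant
  expect_false(near_zero_variance(seq(1, 5, length.out = 50), 0.1))
  v <- c(rep(0, 95), 1, 2, 3, 4, 5)
  expect_true(near_zero_variance(v, 0.1))    # unique 6% < 10%, ratio 95 > 19
  # unique fraction low but balanced frequencies: not flagged
  v2 <- rep(c(0, 1), 50)
  expect_false(near_zero_variance(v2, 0.1))
  # granularity merges near-equal values before tallying
  v3 <- c(rep(0, 95), 0.01, 0.02, 10, 20, 30)
  expect_true(near_zero_variance(v3, 0.1))
  expect_identical(nzv_granularity("gen_mean"), 0.1)
  expect_identical(nzv_granularity("fraction_below"), 0.01)
  expect_identical(nzv_granularity("p90"), 1)
})
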