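# BPI grid with rectangular blocks of a given value on a low background
block_bpi <- function(nr = 30L, nc = 30L, cs = 2, blocks = list(), bg = 0) {
  m <- matrix(bg, nr, nc)
  for (b in blocks) m[b$rows, b$cols] <- b$value
  grid_create(m, cs)
}

test_that("label_regions matches an independent flood fill", {
  set.seed(5)
  mask <- matrix(runif(25 * 30) < 0.4, 25, 30)
  expect_identical(moundr:::label_regions(mask), oracle_regions(mask))
  # empty mask
  expect_identical(moundr:::label_regions(matrix(FALSE, 3, 3)),
                   matrix(0L, 3, 3))
  # diagonal contact joins regions (8-connectivity)
  d <- matrix(FALSE, 3, 3); d[1, 1] <- d[2, 2] <- TRUE
  expect_equal(max(moundr:::label_regions(d)), 1L)
})

test_that("minimum bounding rectangle recovers width, length, orientation", {
  rect <- cbind(c(0, 10, 10, 0), c(0, 0, 4, 4))
  m <- min_bounding_rectangle(rect)
  expect_equal(m$width, 4)
  expect_equal(m$length, 10)
  expect_equal(m$w_l, 0.4)
  expect_equal(m$orient, 90)  # long axis east-west = azimuth 90
  # north-south long axis
  m2 <- min_bounding_rectangle(cbind(c(0, 4, 4, 0), c(0, 0, 10, 10)))
  expect_equal(m2$orient, 0)
  # rotated rectangle: long-axis azimuth 30 degrees clockwise from north
  th <- 30 * pi / 180
  d <- c(sin(th), cos(th)); p <- c(cos(th), -sin(th))
  ctr <- c(50, 50)
  corners <- rbind(ctr + 10 * d + 3 * p, ctr + 10 * d - 3 * p,
                   ctr - 10 * d + 3 * p, ctr - 10 * d - 3 * p)
  m3 <- min_bounding_rectangle(corners)
  expect_equal(m3$length, 20, tolerance = 1e-9)
  expect_equal(m3$width, 6, tolerance = 1e-9)
  expect_equal(m3$orient, 30, tolerance = 1e-6)
  # a square's orientation is the 0 tie value
  expect_equal(min_bounding_rectangle(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))$orient, 0)
  expect_error(min_bounding_rectangle(cbind(1, 1)), "two distinct points")
})

test_that("polygon area and perimeter on simple rings", {
  sq <- cbind(c(0, 2, 2, 0, 0), c(0, 0, 2, 2, 0))  # CCW unit-ish square
  expect_equal(polygon_area(sq), 4)
  expect_equal(polygon_perimeter(sq), 8)
  expect_equal(polygon_area(sq[5:1, ]), -4)  # CW is negative
})

test_that("delineate keeps a qualifying block and traces its outline", {
  g <- block_bpi(blocks = list(list(rows = 5:9, cols = 5:9, value = 10)))
  f <- delineate(g, delineation_config())
  expect_s3_class(f, "mound_features")
  expect_length(f, 1L)
  ft <- f$features[[1]]
  expect_equal(length(ft$raw_cells), 25L)
  expect_equal(polygon_area(ft$raw_ring), 25 * 4)          # CCW, cs = 2
  expect_equal(polygon_perimeter(ft$raw_ring), 4 * 10)
  # buffering by 4 m (2 cells) strictly grows the feature
  expect_gt(length(ft$cells), length(ft$raw_cells))
  expect_gt(polygon_area(ft$ring), polygon_area(ft$raw_ring))
  expect_true(all(ft$raw_cells %in% ft$cells))
  expect_false(ft$merged_flag)
  expect_false(ft$edited_flag)
})

test_that("buffer distance zero leaves the raw outline untouched", {
  g <- block_bpi(blocks = list(list(rows = 5:9, cols = 5:9, value = 10)))
  f <- delineate(g, delineation_config(buffer_distance = 0))
  expect_identical(f$features[[1]]$ring, f$features[[1]]$raw_ring)
  expect_identical(f$features[[1]]$cells, f$features[[1]]$raw_cells)
})

test_that("filters are applied to the raw region, before buffering", {
  # 3x3 block at 2 m cells = 36 m^2 < 50 m^2: dropped even though its
  # buffered outline would pass the area threshold
  small <- block_bpi(blocks = list(list(rows = 5:7, cols = 5:7, value = 10)))
  expect_length(delineate(small), 0L)
  # max BPI below min_bpi: seeded by the cutline but dropped
  weak <- block_bpi(blocks = list(list(rows = 5:9, cols = 5:9, value = 3.2)))
  expect_length(delineate(weak), 0L)
  expect_length(delineate(block_bpi(blocks = list(
    list(rows = 5:9, cols = 5:9, value = 3.6)))), 1L)
  # elongated one-cell line: W/L far below 0.2
  line <- block_bpi(blocks = list(list(rows = 1:28, cols = 20, value = 10)))
  expect_length(delineate(line), 0L)
})

test_that("touching buffered outlines are flagged, not dissolved", {
  g <- block_bpi(blocks = list(list(rows = 5:9, cols = 5:9, value = 10),
                               list(rows = 5:9, cols = 12:16, value = 10)))
  f <- delineate(g)
  expect_length(f, 2L)
  expect_true(all(vapply(f$features, function(x) x$merged_flag, logical(1))))
  # far-apart blocks stay unflagged
  g2 <- block_bpi(blocks = list(list(rows = 5:9, cols = 3:7, value = 10),
                                list(rows = 5:9, cols = 20:24, value = 10)))
  f2 <- delineate(g2)
  expect_length(f2, 2L)
  expect_false(any(vapply(f2$features, function(x) x$merged_flag, logical(1))))
})

test_that("feature ids are deterministic (west-then-south region order)", {
  g <- block_bpi(blocks = list(list(rows = 15:19, cols = 20:24, value = 10),
                               list(rows = 5:9, cols = 3:7, value = 10)))
  f <- delineate(g)
  cols_of <- vapply(f$features, function(x)
    min(((x$raw_cells - 1L) %/% 30L) + 1L), numeric(1))
  expect_equal(cols_of, c(3, 20))  # smallest linear (column-major) index first
  expect_equal(vapply(f$features, function(x) x$feature_id, numeric(1)), c(1, 2))
})

test_that("degenerate inputs are handled", {
  expect_warning(f <- delineate(grid_create(matrix(NA_real_, 5, 5), 2)),
                 "entirely nodata")
  expect_length(f, 0L)
  expect_length(delineate(block_bpi(blocks = list())), 0L)  # nothing above cutline
  expect_error(delineate(matrix(0, 5, 5)), "moundr_grid")
  expect_error(delineation_config(min_bpi = 2), "min_bpi")
  expect_error(delineation_config(min_area = 0), "min_area")
  expect_error(delineation_config(min_wl_ratio = 1.5), "min_wl_ratio")
  expect_error(delineation_config(buffer_distance = -1), "buffer_distance")
})
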