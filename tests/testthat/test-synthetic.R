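test_that("scene_config enforces its invariants", {
  expect_error(scene_config(mounds = data.frame(
    x = 10, y = 10, height = -1, sd_long = 5, sd_short = 5, azimuth = 0)),
    "heights")
  expect_error(scene_config(noise_sd = -0.1), "noise_sd")
  expect_error(scene_config(grid_shape = c(50L, 50L), mounds = data.frame(
    x = 500, y = 10, height = 5, sd_long = 5, sd_short = 5, azimuth = 0)),
    "inside the grid")
  expect_error(generate_dem(list()), "scene_config")
})

test_that("zero mounds, zero noise yields the exact plane", {
  cfg <- scene_config(grid_shape = c(40L, 40L), base_depth = -150,
                      plane_slope_deg = 3, plane_azimuth_deg = 180)
  dem <- generate_dem(cfg)$dem
  s <- slope(dem)$values
  expect_equal(s[20, 20], 3, tolerance = 1e-9)
  expect_equal(max(s, na.rm = TRUE) - min(s, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(dem$values[20, 20] + dem$values[21, 20], 2 * -150,
               tolerance = 1e-6)  # plane is anchored at the grid centre
})

test_that("a planted mound adds exactly its height at the centre", {
  # mound centred on a cell centre (odd coordinates at 2 m cells)
  gen <- mound_dem(depth = -100, height = 8, sd_short = 6, sd_long = 6,
                   cx = 101, cy = 101)
  rc <- cell_at(gen$dem, 101, 101)
  expect_equal(gen$dem$values[rc], -100 + 8)
  expect_equal(max(gen$dem$values), -92)
})

test_that("footprints are the cells where the mound term reaches 0.2 m", {
  gen <- mound_dem(depth = -120, height = 5, sd_short = 5, sd_long = 9,
                   azimuth = 40)
  fp <- gen$registry$footprint[[1]]
  expect_gt(length(fp), 0L)
  dem <- gen$dem
  nr <- nrow(dem$values)
  all_cells <- seq_along(dem$values)
  xy <- cell_center(dem, ((all_cells - 1L) %% nr) + 1L,
                    ((all_cells - 1L) %/% nr) + 1L)
  m <- gen$registry[1, ]
  term <- moundr:::mound_term(m, xy[, "x"], xy[, "y"])
  expect_setequal(fp, all_cells[term >= 0.2])
})

test_that("seeded scenes are bit-identical and noise is seed-controlled", {
  cfg <- reference_scene_config(n_mounds = 6L, noise_sd = 0.3, seed = 5L,
                                grid_shape = c(120L, 150L))
  g1 <- generate_dem(cfg); g2 <- generate_dem(cfg)
  expect_identical(g1$dem$values, g2$dem$values)
  expect_identical(g1$registry$footprint, g2$registry$footprint)
  cfg2 <- reference_scene_config(n_mounds = 6L, noise_sd = 0.3, seed = 6L,
                                 grid_shape = c(120L, 150L))
  expect_false(identical(generate_dem(cfg2)$dem$values, g1$dem$values))
  # realised noise magnitude matches the configured sd
  quiet <- reference_scene_config(n_mounds = 6L, noise_sd = 0, seed = 5L,
                                  grid_shape = c(120L, 150L))
  resid <- g1$dem$values - generate_dem(quiet)$dem$values
  expect_equal(stats::sd(resid), 0.3, tolerance = 0.02)
})

test_that("random_mound_field respects the margin and published scales", {
  mf <- random_mound_field(30, c(1000, 800), seed = 2)
  expect_equal(nrow(mf), 30L)
  expect_true(all(mf$x >= 80 & mf$x <= 920 & mf$y >= 80 & mf$y <= 720))
  expect_true(all(mf$height >= 4.5 & mf$height <= 9))
  expect_true(all(mf$sd_long >= mf$sd_short - 1e-9))
  expect_error(random_mound_field(5, c(100, 100)), "margin")
})

test_that("generate_current builds the coarse gradient field", {
  cur <- generate_current(c(1000, 600))
  expect_equal(dim(cur$values), c(6L, 10L))
  expect_equal(cur$cell_size, 100)
  expect_true(all(diff(t(cur$values)[, 1]) > 0))  # increases eastward
})

test_that("generate_labels saturates with the intercept and is seeded", {
  gen <- mound_dem(height = 6, sd_short = 7, sd_long = 7)
  feats <- features_from_cells(gen$dem, gen$registry$footprint)
  attrs <- describe_features(gen$dem, compute_bpi(gen$dem), feats,
                             with_initial_slope = FALSE)
  attrs$MaxCurrent <- 0.4
  base <- scene_config(grid_shape = c(120L, 120L), seed = 3L)
  hi <- base; hi$label_model$intercept <- 50
  lo <- base; lo$label_model$intercept <- -50
  expect_equal(generate_labels(attrs, hi)$labels$presence, 1L)
  expect_equal(generate_labels(attrs, lo)$labels$presence, 0L)
  expect_length(generate_labels(attrs, lo)$coral_polygons, 0L)
  l1 <- generate_labels(attrs, base); l2 <- generate_labels(attrs, base)
  expect_identical(l1$labels, l2$labels)
  # empty feature set -> empty outputs
  e <- generate_labels(attrs[0, ], base)
  expect_equal(nrow(e$labels), 0L)
  expect_length(e$coral_polygons, 0L)
})

test_that("coral discs carry the configured cover fraction of the feature", {
  gen <- mound_dem(height = 6, sd_short = 7, sd_long = 7)
  feats <- features_from_cells(gen$dem, gen$registry$footprint)
  attrs <- describe_features(gen$dem, compute_bpi(gen$dem), feats,
                             with_initial_slope = FALSE)
  cfg <- scene_config(grid_shape = c(120L, 120L), seed = 3L)
  cfg$label_model$intercept <- 50   # force presence
  lab <- generate_labels(attrs, cfg)
  expect_length(lab$coral_polygons, 1L)
  disc <- lab$coral_polygons[[1]]
  expect_identical(disc[1, ], disc[nrow(disc), ])  # closed ring
  expect_equal(abs(polygon_area(disc)), cfg$coral_cover_rule * attrs$Area,
               tolerance = 0.005)
})

test_that("strong depth coefficient makes presence monotone in MaxWD deciles", {
  set.seed(31)
  attrs <- data.frame(feature_id = 1:500,
                      MaxWD = runif(500, 100, 200),
                      Max_Rug = runif(500, 0, 3),
                      Index = runif(500, 3, 8),
                      MaxCurrent = runif(500, 0.2, 0.6),
                      Area = runif(500, 100, 1000),
                      centroid_x = runif(500, 0, 200),
                      centroid_y = runif(500, 0, 200))
  cfg <- scene_config(seed = 9L,
                      label_model = list(intercept = 0, coef = c(MaxWD = 4)))
  lab <- generate_labels(attrs, cfg)
  dec <- cut(attrs$MaxWD, quantile(attrs$MaxWD, 0:10 / 10),
             include.lowest = TRUE)
  rate <- tapply(lab$labels$presence, dec, mean)
  expect_lt(mean(rate[1:3]), 0.25)
  expect_gt(mean(rate[8:10]), 0.75)
  expect_true(all(diff(stats::filter(rate, rep(1 / 3, 3))[2:9]) > -0.15))
})

test_that("score_recovery attributes features to footprints", {
  g <- grid_create(matrix(0, 20, 20), 2)
  fpA <- as.integer(outer(3:8, (3:8 - 1) * 20, `+`))
  fpB <- as.integer(outer(12:17, (12:17 - 1) * 20, `+`))
  registry <- data.frame(mound_id = 1:2)
  registry$footprint <- list(fpA, fpB)
  inner_A <- as.integer(outer(4:7, (4:7 - 1) * 20, `+`))   # inside A
  stray <- as.integer(outer(12:15, (2:5 - 1) * 20, `+`))   # overlaps nothing
  feats <- features_from_cells(g, list(inner_A, stray))
  sc <- score_recovery(registry, feats)
  expect_equal(sc$n_mounds, 2L)
  expect_equal(sc$n_features, 2L)
  expect_equal(sc$recovered, c(TRUE, FALSE))
  expect_equal(sc$recovery_rate, 0.5)
  expect_equal(sc$one_to_one, c(TRUE, FALSE))
  expect_equal(sc$n_spurious, 1L)
  # two features over one mound: recovered but not one-to-one
  feats2 <- features_from_cells(g, list(
    as.integer(outer(4:5, (4:5 - 1) * 20, `+`)),
    as.integer(outer(6:7, (6:7 - 1) * 20, `+`))))
  sc2 <- score_recovery(registry, feats2)
  expect_true(sc2$recovered[1])
  expect_false(sc2$one_to_one[1])
})
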