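test_that("rendering is deterministic and loom geometry is monotone", {
  spec <- stimulus_spec("loom", background = 0, object_luminance = 1,
                        width = 80, height = 60, n_frames = 40,
                        radius0 = 5, collision_frame = 60, noise_sd = 0.02,
                        seed = 7)
  a <- render_scene(spec)
  b <- render_scene(spec)
  expect_identical(a$seq$frames, b$seq$frames)
  expect_identical(a$gt$relative_area, b$gt$relative_area)
  # relative area strictly increasing up to the (off-clip) collision
  expect_true(all(diff(a$gt$relative_area) > 0))
})

test_that("translation keeps the relative area constant within 1%", {
  spec <- stimulus_spec("translate", background = 0, object_luminance = 1,
                        width = 100, height = 60, n_frames = 30, radius0 = 10,
                        center0 = c(30, 30), lateral_velocity = c(1.3, 0.4))
  sc <- render_scene(spec)
  rel <- sc$gt$relative_area
  expect_lt(max(abs(rel / rel[1] - 1)), 0.01)
  # anti-aliased pixel-counted area also stays near-constant
  px <- sc$gt$pixel_area
  expect_lt(max(abs(px / px[1] - 1)), 0.01)
})

test_that("analytic and pixel-counted areas agree within 3% once rho >= 5 px", {
  spec <- stimulus_spec("loom", background = 0, object_luminance = 1,
                        width = 120, height = 90, n_frames = 50,
                        radius0 = 5, collision_frame = 70)
  sc <- render_scene(spec)
  sel <- which(sc$gt$radius >= 5 & sc$gt$radius <= 40)
  expect_lt(max(abs(sc$gt$pixel_area[sel] / sc$gt$area[sel] - 1)), 0.03)
})

test_that("contrast variants share kinematics and follow Weber arithmetic", {
  base <- stimulus_spec("loom", background = 0.5, object_luminance = 0.9,
                        width = 60, height = 40, n_frames = 20,
                        radius0 = 4, collision_frame = 30)
  vs <- contrast_variants(base, c(0.8, 0.4, -0.4))
  expect_equal(vapply(vs, function(s) s$object_luminance, numeric(1)),
               c(0.9, 0.7, 0.3))
  # identical ground-truth kinematics (bit-for-bit)
  g1 <- render_scene(vs[[1]])$gt
  g3 <- render_scene(vs[[3]])$gt
  expect_identical(g1$area, g3$area)
  expect_identical(g1$collision_frame, g3$collision_frame)
  expect_identical(g1$masks, g3$masks)
  # edge cases
  expect_identical(contrast_variants(base, numeric(0)), list())
  expect_error(contrast_variants(base, 2.0), "outside")
  nobg <- stimulus_spec("loom", background = 0, object_luminance = 1)
  expect_error(contrast_variants(nobg, 0.5), "positive")
})

test_that("speed classification implements the 8% minimum-span rule", {
  # construct relative-area series with known Delta_f: area grows by exactly
  # 8% over df frames (piecewise-linear), so the minimum span is df
  series_with_df <- function(df, total = 200) {
    steps <- floor(total / df)
    rel <- 0.01 * cumprod(c(1, rep(1.08^(1 / df), total - 1)))
    rel
  }
  expect_identical(classify_speed(series_with_df(25)), "fast")
  expect_identical(classify_speed(series_with_df(60, 400)), "slow")
  expect_identical(classify_speed(series_with_df(40)), "unclassified")
  # area that never changes by 8%
  expect_identical(classify_speed(rep(0.05, 100)), "unclassified")
  expect_identical(classify_speed(seq(0.05, 0.052, length.out = 100)),
                   "unclassified")
})

test_that("image-sequence IO round-trips within quantisation", {
  spec <- stimulus_spec("loom", background = 0.2, object_luminance = 0.8,
                        width = 40, height = 30, n_frames = 10,
                        radius0 = 4, collision_frame = 15)
  sc <- render_scene(spec, keep_masks = FALSE)
  d8 <- tempfile("seq8_")
  write_sequence(sc$seq, d8, format = "png")
  back <- read_sequence(d8)
  expect_equal(dim(back$frames), dim(sc$seq$frames))
  expect_lte(max(abs(back$frames - sc$seq$frames)), 1 / 255)
  d16 <- tempfile("seq16_")
  write_sequence(sc$seq, d16, format = "tiff")
  back16 <- read_sequence(d16)
  expect_lte(max(abs(back16$frames - sc$seq$frames)), 1 / 65535)
  unlink(c(d8, d16), recursive = TRUE)
})

test_that("sequence reading errors are informative", {
  empty <- tempfile("empty_")
  dir.create(empty)
  expect_error(read_sequence(empty), "no PNG/TIFF")
  # mixed frame sizes
  mixed <- tempfile("mixed_")
  dir.create(mixed)
  png::writePNG(matrix(0.5, 10, 10), file.path(mixed, "a.png"))
  png::writePNG(matrix(0.5, 12, 10), file.path(mixed, "b.png"))
  expect_error(read_sequence(mixed), "mixed frame sizes")
  # grey RGB pixel maps to the same luminance
  rgbdir <- tempfile("rgb_")
  dir.create(rgbdir)
  img <- array(0.5, c(6, 6, 3))
  png::writePNG(img, file.path(rgbdir, "a.png"))
  grey <- read_sequence(rgbdir)
  expect_equal(max(abs(grey$frames - 0.5)), 0, tolerance = 1 / 255)
  unlink(c(empty, mixed, rgbdir), recursive = TRUE)
})

test_that("spec validation rejects impossible stimuli", {
  expect_error(stimulus_spec(background = 1.2), "luminances")
  expect_error(stimulus_spec(n_frames = 1), "frame count")
  expect_error(frame_sequence(array(0, c(4, 4, 0))), "at least one frame")
})
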