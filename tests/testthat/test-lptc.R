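# drifting-edge helper shared by correlation/decoding tests
edge_channels <- function(speed, n_frames = 110, height = 12) {
  stim <- loomcontour:::drifting_edge_sequence(speed, n_frames, height = height)
  list(ch = run_frontend(stim$frames), edge_at = stim$edge_at)
}

test_that("correlator is silent on static scenes and validates beta", {
  ch <- run_frontend(array(0.4, c(10, 12, 40)))
  R <- correlate_lptc(ch, 30, beta = 4, theta = 0)
  expect_lt(max(abs(R)), 1e-20)
  expect_error(correlate_lptc(ch, 30, beta = 0, theta = 0), "positive")
})

test_that("correlator output is zero where the neighbour channels are zero", {
  # channels nonzero only at one isolated pixel: the product with the
  # (zero-valued) shifted neighbour vanishes there
  ch <- list(tm3 = array(0, c(8, 8, 3)), tm2 = array(0, c(8, 8, 3)),
             mi1 = array(0, c(8, 8, 3)), tm1 = array(0, c(8, 8, 3)))
  ch$tm3[4, 4, 2] <- 1   # instantaneous only; delayed channels all zero
  R <- correlate_lptc(ch, 2, beta = 2, theta = 0)
  expect_identical(max(abs(R)), 0)
})

test_that("a drifting edge drives the aligned direction and motion-convention angle", {
  ec <- edge_channels(0.3)
  t <- 100
  lf <- lptc_frame(ec$ch, t)
  xe <- round(ec$edge_at(t))
  # direction selectivity: response along the motion axis beats orthogonal
  r_aligned <- correlate_lptc(ec$ch, t, beta = 8, theta = pi)      # offset left
  r_ortho <- correlate_lptc(ec$ch, t, beta = 8, theta = pi / 2)
  expect_gt(r_aligned[6, xe], 5 * max(r_ortho[6, xe], 1e-12))
  # decoded motion direction within one direction bin of 0 (rightward)
  ang <- lf$theta_motion[6, xe]
  expect_lt(abs(atan2(sin(ang), cos(ang))), 2 * pi / 8)
})

test_that("rotating the stimulus by 90 degrees rotates the decoded direction", {
  # same edge drifting downward instead of rightward: transpose the frames
  stim <- loomcontour:::drifting_edge_sequence(0.3, 110, height = 12)
  frames_dn <- array(0, c(dim(stim$frames)[2], dim(stim$frames)[1], 110))
  for (t in 1:110) frames_dn[, , t] <- t(stim$frames[, , t])
  ch <- run_frontend(frames_dn)
  lf <- lptc_frame(ch, 100)
  ye <- round(stim$edge_at(100))
  ang <- lf$theta_motion[ye, 6]
  expect_lt(abs(ang - pi / 2), 2 * pi / 8)   # downward = +pi/2 image convention
})

test_that("circular-mean direction follows its defining identities", {
  ch <- list(tm3 = array(0, c(6, 6, 2)), tm2 = array(0, c(6, 6, 2)),
             mi1 = array(0, c(6, 6, 2)), tm1 = array(0, c(6, 6, 2)))
  # all-zero responses: theta_star ties resolve to the lowest index (theta=0)
  lf <- lptc_frame(ch, 1)
  expect_true(all(lf$theta_star == 1L))
  expect_true(all(lf$theta_bar == 0))
  # identical angles average to themselves; +/-45 average to 0
  th <- lptc_params()$thetas
  expect_equal(atan2(sum(sin(th[c(2, 2, 2)])), sum(cos(th[c(2, 2, 2)]))), th[2])
  expect_equal(atan2(sin(th[2]) + sin(th[8]), cos(th[2]) + cos(th[8])), 0)
})

test_that("tuning calibration is deterministic with distinct rows and rejects bad grids", {
  tab <- test_tuning_table()
  tab2 <- calibrate_tuning()
  expect_identical(tab$resp, tab2$resp)
  # no two unit-norm rows identical within floor tolerance
  d <- as.matrix(stats::dist(tab$resp_unit))
  diag(d) <- Inf
  expect_gt(min(d), 1e-4)
  expect_error(calibrate_tuning(speeds = c(0.2, 0.1)), "increasing")
  expect_error(calibrate_tuning(speeds = c(0, 0.1)), "static scene")
})

test_that("tuning table round-trips through JSON", {
  tab <- test_tuning_table()
  f <- tempfile(fileext = ".json")
  write_tuning_table(tab, f)
  back <- read_tuning_table(f)
  expect_equal(back$speeds, tab$speeds)
  expect_equal(back$resp, tab$resp, ignore_attr = TRUE)
  expect_equal(back$floor, tab$floor)
  unlink(f)
})

test_that("decoding recovers exact rows, floors weak vectors, and checks sizes", {
  tab <- test_tuning_table()
  k <- 7
  expect_identical(decode_velocity(tab$resp[k, ], tab), tab$speeds[k])
  expect_identical(decode_velocity(rep(0, 9), tab), 0)
  expect_identical(decode_velocity(tab$resp[k, ] * 1e-6, tab), 0)  # below floor
  expect_error(decode_velocity(rep(1, 5), tab), "does not match")
  # contrast scaling leaves the normalised decode unchanged
  expect_identical(decode_velocity(tab$resp[k, ] * 0.05, tab,
                                   floor = tab$floor * 0.05),
                   tab$speeds[k])
})

test_that("drifting edges decode to their true speed across the calibrated range", {
  tab <- test_tuning_table()
  # off-grid speeds; median error must be within one grid step
  speeds <- c(0.08, 0.22, 0.52, 0.72)
  err <- vapply(speeds, function(v) {
    ec <- edge_channels(v)
    acc <- 0
    for (t in 103:108) {
      lf <- lptc_frame(ec$ch, t)
      acc <- acc + lf$r[6, round(ec$edge_at(t)), ]
    }
    decode_velocity(acc / 6, tab) - v
  }, numeric(1))
  expect_lte(stats::median(abs(err)), max(diff(tab$speeds)))
})

test_that("motion mask applies the dynamic threshold and picks the dominant region", {
  # threshold arithmetic: global max 10, factor 0.1 -> delta = 1
  r <- array(0, c(10, 12, 2))
  r[2, 2, 1] <- 10
  r[5, 5, 1] <- 0.5     # below delta = 1
  r[8, 8, 1] <- 2
  mm <- motion_mask(r, factor = 0.1)
  expect_equal(mm$delta, 1)
  expect_true(mm$mask[2, 2])
  expect_false(mm$mask[5, 5])
  expect_true(mm$mask[8, 8])
  # dominant region: the larger 8-connected component wins
  r2 <- array(0, c(12, 20, 1))
  r2[2:6, 2:9, 1] <- 5          # 40 px
  r2[10:11, 15:17, 1] <- 5      # 6 px (diagonal-adjacent pixels join it)
  r2[9, 14, 1] <- 5             # 8-connectivity glue -> 7 px
  mm2 <- motion_mask(r2, 0.1)
  expect_equal(mm2$region_size, 40L)
  expect_equal(mm2$centroid, c(mean(2:9), mean(2:6)))
  # all-zero responses: empty mask, distinct signal
  mm3 <- motion_mask(array(0, c(5, 5, 3)))
  expect_true(mm3$empty)
  expect_null(mm3$centroid)
})

test_that("accumulated displacement follows frame-step quadrature", {
  v <- array(1, c(3, 4, 5))
  th0 <- array(0, c(3, 4, 5))
  d <- accumulate_displacement(v, th0, 1, 5)
  expect_true(all(d$phi == 5) && all(d$psi == 0))
  th90 <- array(pi / 2, c(3, 4, 5))
  d90 <- accumulate_displacement(v, th90, 1, 5)
  expect_equal(max(abs(d90$phi)), 0, tolerance = 1e-12)
  expect_true(all(abs(d90$psi - 5) < 1e-12))
  # alternating opposite directions cancel
  tha <- array(rep(c(0, pi), each = 12, length.out = 3 * 4 * 4), c(3, 4, 4))
  da <- accumulate_displacement(array(1, c(3, 4, 4)), tha, 1, 4)
  expect_lt(max(abs(da$phi)), 1e-12)
  # empty window -> zero grids
  d0 <- accumulate_displacement(v, th0, 3, 2)
  expect_true(all(d0$phi == 0) && all(d0$psi == 0))
})
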