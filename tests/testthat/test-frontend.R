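test_that("retina smoothing conserves mass and matches the Gaussian peak", {
  # constant frame is a fixed point
  cfr <- matrix(0.37, 20, 25)
  expect_equal(smooth_retina(cfr, 1), cfr, tolerance = 1e-12)
  # unit impulse: centre value 1/(2*pi) within truncation error
  m <- matrix(0, 21, 21); m[11, 11] <- 1
  s <- smooth_retina(m, 1)
  expect_lt(abs(s[11, 11] - 1 / (2 * pi)), 1e-3)
  # total luminance conserved for interior impulses
  expect_lt(abs(sum(s) - 1), 1e-3)
  expect_error(smooth_retina(m, 0), "positive")
})

test_that("Gamma kernels are normalised and peak at lag tau", {
  # brute-force oracle: evaluate the continuous kernel on a fine grid and
  # confirm the maximiser is t = tau, then check the discrete arg-max tap
  for (p in list(c(2, 3), c(6, 9), c(25, 30))) {
    n <- p[1]; tau <- p[2]
    tt <- seq(0.01, 8 * tau, by = 0.01)
    dens <- exp(n * log(n * tt) - n * tt / tau - lgamma(n) - (n + 1) * log(tau))
    expect_equal(tt[which.max(dens)], tau, tolerance = 0.02)
    k <- gamma_kernel(n, tau)
    expect_equal(sum(k$taps), 1, tolerance = 1e-9)
    expect_identical(which.max(k$taps) - 1L, as.integer(tau))
    expect_true(all(k$taps >= 0))
  }
  expect_error(gamma_kernel(0, 3), "integer")
  expect_error(gamma_kernel(2.5, 3), "integer")
  expect_error(gamma_kernel(2, 0), "positive")
})

test_that("lamina band-pass rejects DC and responds to steps with sign symmetry", {
  params <- frontend_params()
  tn <- 100
  # constant stream -> identically zero output
  const <- array(0.6, c(4, 5, tn))
  expect_lt(max(abs(lamina_bandpass(const, params))), 1e-9)
  # numeric step-response oracle: convolve a step with H directly
  k1 <- gamma_kernel(params$n1, params$tau1)$taps
  k2 <- gamma_kernel(params$n2, params$tau2)$taps
  h <- numeric(max(length(k1), length(k2)))
  h[seq_along(k1)] <- k1; h[seq_along(k2)] <- h[seq_along(k2)] - k2
  t_step <- 40
  step <- c(rep(0, t_step - 1), rep(1, tn - t_step + 1))
  oracle <- vapply(seq_len(tn), function(t) {
    lags <- seq_along(h) - 1L
    src <- t - lags
    sum(h[src >= 1] * step[src[src >= 1]])
  }, numeric(1))
  a <- array(rep(step, each = 6), c(2, 3, tn))
  L <- lamina_bandpass(a, params)
  expect_equal(L[1, 1, ], oracle, tolerance = 1e-12)
  # transient positive lobe, then sign-reversing decay back to zero
  expect_gt(max(oracle), 0.1)
  expect_lt(min(oracle[t_step:(t_step + 30)]), 0)
  expect_lt(abs(oracle[tn]), 1e-6)
  # step decrease mirrors the transient (linearity)
  a_dn <- array(rep(1 - step, each = 6), c(2, 3, tn))
  expect_equal(lamina_bandpass(a_dn, params)[1, 1, ], -oracle,
               tolerance = 1e-12)
})

test_that("retina + lamina cascade is linear", {
  params <- frontend_params()
  set.seed(11)
  tn <- 60
  i1 <- array(runif(6 * 7 * tn), c(6, 7, tn))
  i2 <- array(runif(6 * 7 * tn), c(6, 7, tn))
  run_lin <- function(a) {
    p <- array(0, dim(a))
    for (t in seq_len(tn)) p[, , t] <- smooth_retina(a[, , t], params$sigma1)
    lamina_bandpass(p, params)
  }
  lhs <- run_lin(2.5 * i1 - 0.7 * i2)
  rhs <- 2.5 * run_lin(i1) - 0.7 * run_lin(i2)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("medulla channels rectify, stay complementary, and delay by tau3", {
  params <- frontend_params()
  tn <- 120
  # signed L stream with known values
  l <- array(0, c(3, 3, tn))
  l[1, 1, ] <- 0.4           # constant positive
  l[2, 2, ] <- -0.25         # constant negative
  ch <- medulla_split_delay(l, params)
  expect_equal(ch$tm3[1, 1, 10], 0.4)
  expect_equal(ch$tm2[1, 1, 10], 0)
  expect_equal(ch$tm2[2, 2, 10], 0.25)
  expect_equal(ch$tm3[2, 2, 10], 0)
  expect_true(all(ch$tm3 * ch$tm2 == 0))
  expect_true(all(ch$mi1 >= 0) && all(ch$tm1 >= 0))
  # ON impulse at t0: delayed channel peaks at t0 + tau3
  t0 <- 20L
  imp <- array(0, c(2, 2, tn)); imp[1, 1, t0] <- 1
  chi <- medulla_split_delay(imp, params)
  expect_identical(which.max(chi$mi1[1, 1, ]), t0 + as.integer(params$tau3))
})

test_that("a static scene yields an identically zero channel set", {
  spec <- stimulus_spec("translate", background = 0.3, object_luminance = 0.9,
                        width = 40, height = 30, n_frames = 50, radius0 = 8,
                        lateral_velocity = c(0, 0))
  sc <- render_scene(spec, keep_masks = FALSE)
  ch <- run_frontend(sc$seq)
  expect_lt(max(abs(ch$l)), 1e-9)
  expect_lt(max(ch$tm3), 1e-12)
  expect_lt(max(ch$tm2), 1e-12)
  expect_lt(max(ch$mi1), 1e-12)
  expect_lt(max(ch$tm1), 1e-12)
})
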