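#' Frontend (retina, lamina, medulla) parameters
#'
#' Spatial and temporal filter constants of the early visual layers. One
#' discrete time step equals one frame, so all time constants are in frames.
#' Defaults are the published operating point: retina Gaussian `sigma1 = 1`
#' px; lamina band-pass as the difference of Gamma kernels with
#' `(n1, tau1) = (2, 3)` and `(n2, tau2) = (6, 9)`; medulla delay Gamma
#' `(n3, tau3) = (25, 30)`.
#'
#' @param sigma1 retina Gaussian standard deviation, px.
#' @param n1,tau1,n2,tau2 orders and time constants (frames) of the two
#'   lamina Gamma kernels.
#' @param n3,tau3 order and time constant (frames) of the medulla delay
#'   Gamma kernel.
#' @param tol kernel truncation tolerance: taps below `tol` times the peak
#'   tap are dropped (then the kernel is renormalised to unit sum).
#' @return an object of class `frontend_params`.
#' @export
frontend_params <- function(sigma1 = 1, n1 = 2, tau1 = 3, n2 = 6, tau2 = 9,
                            n3 = 25, tau3 = 30, tol = 1e-3) {
  for (n in c(n1, n2, n3)) {
    if (n < 1 || n != round(n)) stop("Gamma orders must be integers >= 1")
  }
  if (any(c(tau1, tau2, tau3) <= 0)) stop("time constants must be positive")
  if (sigma1 <= 0) stop("sigma1 must be positive")
  structure(list(sigma1 = sigma1, n1 = n1, tau1 = tau1, n2 = n2, tau2 = tau2,
                 n3 = n3, tau3 = tau3, tol = tol),
            class = "frontend_params")
}

#' Discrete Gamma kernel
#'
#' Samples the continuous Gamma kernel
#' `(n t)^n exp(-n t / tau) / ((n - 1)! tau^(n + 1))`
#' at unit frame steps `t = 0, 1, 2, ...`, truncates the tail where taps fall
#' below `tol` times the peak tap, and renormalises to unit discrete sum (so
#' a static input passes through with unit gain and the lamina difference
#' kernel has exactly zero DC). The continuous kernel peaks at `t = tau`, so
#' the arg-max tap sits at lag `tau` for integer `tau`.
#'
#' @param n integer order (>= 1).
#' @param tau time constant, frames.
#' @param tol truncation tolerance relative to the peak tap.
#' @return object of class `temporal_kernel`: numeric `taps` (index 1 = lag
#'   0), and fields `n`, `tau`.
#' @export
gamma_kernel <- function(n, tau, tol = 1e-3) {
  if (n < 1 || n != round(n)) stop("n must be an integer >= 1")
  if (tau <= 0) stop("tau must be positive")
  # generous upper bound for the support, then truncate by tolerance
  tmax <- ceiling(tau + 12 * tau / sqrt(n) + 10)
  t <- 0:tmax
  logtap <- ifelse(t == 0, -Inf,
                   n * log(n * t) - n * t / tau - lgamma(n) - (n + 1) * log(tau))
  taps <- exp(logtap - max(logtap))  # peak = 1
  keep <- max(which(taps >= tol))
  taps <- taps[seq_len(keep)]
  taps <- taps / sum(taps)
  structure(list(taps = taps, n = n, tau = tau), class = "temporal_kernel")
}

#' @export
print.temporal_kernel <- function(x, ...) {
  cat(sprintf("<temporal_kernel> Gamma(n=%g, tau=%g), %d taps, peak lag %d\n",
              x$n, x$tau, length(x$taps), which.max(x$taps) - 1L))
  invisible(x)
}

#' Retina layer: ommatidium Gaussian smoothing
#'
#' Convolves a luminance frame with a 2-D Gaussian of standard deviation
#' `sigma1` (the ommatidium acceptance profile), kernel truncated at
#' `ceiling(3 sigma1)` taps each side, borders replicate-padded.
#'
#' @param frame numeric matrix.
#' @param sigma1 Gaussian standard deviation, px.
#' @return smoothed matrix `P`, same shape.
#' @export
smooth_retina <- function(frame, sigma1 = 1) {
  if (!all(is.finite(frame))) stop("frame must be finite")
  gauss_smooth(frame, sigma1)
}

#' Lamina layer: LMC temporal band-pass
#'
#' Filters the retina output stream per pixel with the causal impulse
#' response `H = Gamma(n1, tau1) - Gamma(n2, tau2)`. Both kernels are
#' renormalised to unit discrete sum before subtraction, so `H` has exactly
#' zero DC and any static scene is rejected. The stream is replicate-padded
#' into the past (frames before the clip are treated as the first frame), so
#' a temporally constant input yields an identically zero output.
#'
#' @param p array `[H, W, T]` of retina outputs.
#' @param params a [frontend_params()].
#' @return array `[H, W, T]` of LMC outputs `L` (signed).
#' @export
lamina_bandpass <- function(p, params = frontend_params()) {
  k1 <- gamma_kernel(params$n1, params$tau1, params$tol)$taps
  k2 <- gamma_kernel(params$n2, params$tau2, params$tol)$taps
  len <- max(length(k1), length(k2))
  h <- numeric(len)
  h[seq_along(k1)] <- k1
  h[seq_along(k2)] <- h[seq_along(k2)] - k2
  temporal_filter(p, h)
}

#' Medulla layer: ON/OFF split and Gamma delay
#'
#' Half-wave rectifies the LMC output into instantaneous ON (`Tm3 = [L]+`)
#' and OFF (`Tm2 = [-L]+`) channels and produces their Gamma-delayed
#' counterparts (`Mi1`, `Tm1`) by causal temporal convolution with
#' `Gamma(n3, tau3)`. All four output grids are non-negative and the
#' instantaneous channels are complementary (`Tm3 * Tm2 = 0` pixelwise).
#'
#' @param l array `[H, W, T]` of LMC outputs.
#' @param params a [frontend_params()].
#' @return object of class `channel_set`: arrays `tm3`, `tm2`, `mi1`, `tm1`
#'   (all `[H, W, T]`), plus the delay kernel and parameters.
#' @export
medulla_split_delay <- function(l, params = frontend_params()) {
  tm3 <- pmax(l, 0)
  tm2 <- pmax(-l, 0)
  k3 <- gamma_kernel(params$n3, params$tau3, params$tol)
  mi1 <- temporal_filter(tm3, k3$taps)
  tm1 <- temporal_filter(tm2, k3$taps)
  structure(list(tm3 = tm3, tm2 = tm2, mi1 = mi1, tm1 = tm1,
                 delay_kernel = k3, params = params),
            class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  d <- dim(x$tm3)
  cat(sprintf("<channel_set> %d x %d px, %d frames (Tm3/Tm2 instantaneous, Mi1/Tm1 delayed)\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Run the full frontend on a frame sequence
#'
#' Applies retina smoothing, lamina band-pass and the medulla ON/OFF split
#' with delay, retaining the intermediate `P` and `L` streams (the retina
#' output also feeds the contour pathway's edge indicator).
#'
#' @param seq a [frame_sequence()] or `[H, W, T]` array.
#' @param params a [frontend_params()].
#' @return a `channel_set` with extra elements `p` and `l` (arrays
#'   `[H, W, T]`) and `warmup` (frames until the temporal filters are full:
#'   combined support of the lamina and delay kernels).
#' @export
run_frontend <- function(seq, params = frontend_params()) {
  a <- if (inherits(seq, "frame_sequence")) seq$frames else seq
  d <- dim(a)
  p <- array(0, d)
  for (t in seq_len(d[3])) p[, , t] <- smooth_retina(a[, , t], params$sigma1)
  l <- lamina_bandpass(p, params)
  ch <- medulla_split_delay(l, params)
  ch$p <- p
  ch$l <- l
  k1 <- gamma_kernel(params$n1, params$tau1, params$tol)$taps
  k2 <- gamma_kernel(params$n2, params$tau2, params$tol)$taps
  ch$warmup <- max(length(k1), length(k2)) + length(ch$delay_kernel$taps)
  ch$kernel_max <- max(length(k1), length(k2), length(ch$delay_kernel$taps))
  ch
}
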