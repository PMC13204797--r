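#' LPTC sub-network parameters
#'
#' The lobula-plate tangential cell bank correlates each pixel's
#' instantaneous channel with the delayed channel of a neighbour at distance
#' `beta` along direction `theta` (a Hassenstein-Reichardt correlator per
#' `(beta, theta)` pair). Velocity is represented by the population of
#' responses across the distance set.
#'
#' @param betas spatial correlation distances, px (default
#'   `{2, 4, ..., 18}`).
#' @param n_dirs number of equally spaced preferred directions (default 8,
#'   i.e. 45 degree steps; must be >= 4).
#' @param mask_factor detection-threshold factor: the per-frame motion mask
#'   threshold is `mask_factor * max r` (default 0.1).
#' @param floor_frac response floor as a fraction of the calibration table's
#'   global maximum (default 0.01): pixels whose peak response falls below
#'   the floor decode to speed 0.
#' @return object of class `lptc_params`.
#' @export
lptc_params <- function(betas = seq(2, 18, by = 2), n_dirs = 8L,
                        mask_factor = 0.1, floor_frac = 0.01) {
  if (length(betas) == 0 || any(betas <= 0)) stop("betas must be positive")
  if (n_dirs < 4L) stop("need at least 4 directions")
  structure(list(betas = betas, n_dirs = as.integer(n_dirs),
                 thetas = 2 * pi * (seq_len(n_dirs) - 1L) / n_dirs,
                 mask_factor = mask_factor, floor_frac = floor_frac),
            class = "lptc_params")
}

#' Single correlator response grid
#'
#' Computes, for one frame, the LPTC output
#' `R(x, y) = Tm3(x, y) * Mi1(x', y') + Tm2(x, y) * Tm1(x', y')`
#' with the neighbour at `(x', y') = (x + beta cos(theta), y + beta
#' sin(theta))`. Non-integer offsets are sampled bilinearly; out-of-frame
#' neighbours contribute zero. Note the preferred *motion* direction of this
#' correlator is opposite to the offset direction `theta`: the delayed
#' neighbour signal matches the instantaneous centre signal when the pattern
#' moved from the neighbour towards the centre.
#'
#' @param channels a `channel_set` (see [medulla_split_delay()]).
#' @param t frame index.
#' @param beta correlation distance, px (> 0).
#' @param theta offset direction, radians (image convention: x = column,
#'   y = row increasing downward).
#' @return response matrix `R`, non-negative.
#' @export
correlate_lptc <- function(channels, t, beta, theta) {
  if (beta <= 0) stop("beta must be positive")
  dx <- beta * cos(theta)
  dy <- beta * sin(theta)
  channels$tm3[, , t] * shift_bilinear(channels$mi1[, , t], dx, dy) +
    channels$tm2[, , t] * shift_bilinear(channels$tm1[, , t], dx, dy)
}

#' Per-frame LPTC population response
#'
#' Evaluates the correlator bank over all `(beta, theta)` pairs for one
#' frame, selects per pixel and per distance the direction maximising the
#' response (`theta_i*`, ties to the lowest index), forms the circular-mean
#' direction `theta_bar = atan2(sum sin theta_i*, sum cos theta_i*)`, and
#' reads the firing-rate vector `r(beta_i) = R(beta_i, theta_bar)` by linear
#' interpolation between the two sampled directions adjacent to `theta_bar`.
#' When the circular mean vector has zero length, `theta_bar` falls back to
#' the direction of the single largest response at that pixel.
#'
#' @param channels a `channel_set`.
#' @param t frame index.
#' @param params an [lptc_params()].
#' @return list with `r` (array `[H, W, N]`, N = number of distances),
#'   `theta_bar` (offset-convention direction grid, radians in `(-pi, pi]`),
#'   `theta_motion` (motion-convention direction, `theta_bar + pi` wrapped),
#'   `rmax` (max response over distances), and `theta_star` (`[H, W, N]`
#'   per-distance arg-max direction indices).
#' @export
lptc_frame <- function(channels, t, params = lptc_params()) {
  d <- dim(channels$tm3)
  nr <- d[1]; nc <- d[2]; npx <- nr * nc
  nb <- length(params$betas); nd <- params$n_dirs
  thetas <- params$thetas
  tm3 <- channels$tm3[, , t]; tm2 <- channels$tm2[, , t]
  mi1 <- channels$mi1[, , t]; tm1 <- channels$tm1[, , t]
  R <- array(0, c(npx, nb, nd))
  for (j in seq_len(nd)) {
    dxu <- cos(thetas[j]); dyu <- sin(thetas[j])
    for (i in seq_len(nb)) {
      b <- params$betas[i]
      R[, i, j] <- tm3 * shift_bilinear(mi1, b * dxu, b * dyu) +
                   tm2 * shift_bilinear(tm1, b * dxu, b * dyu)
    }
  }
  # arg-max direction per distance (ties -> lowest index)
  theta_star <- matrix(1L, npx, nb)
  star_val <- matrix(0, npx, nb)
  for (i in seq_len(nb)) {
    Ri <- R[, i, ]
    theta_star[, i] <- max.col(Ri, ties.method = "first")
    star_val[, i] <- Ri[cbind(seq_len(npx), theta_star[, i])]
  }
  sv <- rowSums(matrix(sin(thetas[theta_star]), npx, nb))
  cv <- rowSums(matrix(cos(thetas[theta_star]), npx, nb))
  theta_bar <- atan2(sv, cv)
  # zero-length circular mean: fall back to direction of the largest response
  degen <- (sv^2 + cv^2) < 1e-12
  if (any(degen)) {
    best_b <- max.col(star_val, ties.method = "first")
    theta_bar[degen] <- thetas[theta_star[cbind(which(degen), best_b[degen])]]
  }
  # interpolate R between the two directions adjacent to theta_bar
  step <- 2 * pi / nd
  pos <- (theta_bar %% (2 * pi)) / step
  j0 <- floor(pos)
  w <- pos - j0
  j0 <- (as.integer(j0) %% nd) + 1L
  j1 <- (j0 %% nd) + 1L
  r <- matrix(0, npx, nb)
  for (i in seq_len(nb)) {
    Ri <- R[, i, ]
    r[, i] <- (1 - w) * Ri[cbind(seq_len(npx), j0)] +
              w * Ri[cbind(seq_len(npx), j1)]
  }
  tb <- matrix(theta_bar, nr, nc)
  tm <- matrix(atan2(-sin(theta_bar), -cos(theta_bar)), nr, nc)
  rmax <- r[, 1L]
  if (nb > 1L) for (i in 2:nb) rmax <- pmax(rmax, r[, i])
  list(r = array(r, c(nr, nc, nb)),
       theta_bar = tb,
       theta_motion = tm,
       rmax = matrix(rmax, nr, nc),
       theta_star = array(theta_star, c(nr, nc, nb)))
}

#' Motion mask and dominant region
#'
#' Thresholds the per-pixel peak firing rate with the dynamic detection
#' threshold `delta = factor * max_(x,y,i) r` (the maximum is taken per
#' frame), labels 8-connected components of the resulting binary mask, and
#' returns the dominant region: the component containing the greatest number
#' of motion-responsive pixels, with its pixel-coordinate centroid.
#'
#' @param r array `[H, W, N]` of firing rates for one frame (or the list
#'   returned by [lptc_frame()]).
#' @param factor threshold factor (default 0.1).
#' @return list with `mask` (logical `[H, W]`), `delta`, `empty` (TRUE when
#'   no pixel responds), `region` (logical `[H, W]` dominant region),
#'   `centroid` (`c(x, y)` px or `NULL`), `region_size`.
#' @export
motion_mask <- function(r, factor = 0.1) {
  if (is.list(r) && !is.null(r$r)) r <- r$r
  nr <- dim(r)[1]; nc <- dim(r)[2]
  nb <- dim(r)[3]
  rmax <- r[, , 1L]
  if (nb > 1L) for (i in 2:nb) rmax <- pmax(rmax, r[, , i])
  gmax <- max(rmax)
  if (gmax <= 0) {
    return(list(mask = matrix(FALSE, nr, nc), delta = 0, empty = TRUE,
                region = NULL, centroid = NULL, region_size = 0L))
  }
  delta <- factor * gmax
  mask <- rmax > delta
  lab <- label_components8(mask)
  region <- lab$labels == 1L
  px <- which(region)
  centroid <- c(mean(((px - 1L) %/% nr) + 1L),  # x = col
                mean(((px - 1L) %% nr) + 1L))   # y = row
  list(mask = mask, delta = delta, empty = FALSE,
       region = region, centroid = centroid,
       region_size = length(px))
}

# canonical calibration stimulus: a high-contrast vertical edge drifting in
# +x; luminance 1 behind the edge, 0 ahead, anti-aliased by pixel coverage
drifting_edge_sequence <- function(speed, n_frames, height = 12L,
                                   margin = 30L, x0 = NULL) {
  x0 <- x0 %||% margin
  width <- as.integer(ceiling(x0 + speed * n_frames + margin))
  frames <- array(0, c(height, width, n_frames))
  cols <- seq_len(width)
  for (t in seq_len(n_frames)) {
    xe <- x0 + speed * (t - 1)
    frames[, , t] <- matrix(clamp(xe - cols + 0.5, 0, 1), height, width,
                            byrow = TRUE)
  }
  list(frames = frames, edge_at = function(t) x0 + speed * (t - 1))
}

#' Calibrate the LPTC tuning table
#'
#' Builds the population-decoding lookup `f(v, beta_i)`: for every candidate
#' speed the canonical high-contrast drifting edge is rendered, run through
#' the frontend and correlator bank, and the firing-rate vector is sampled at
#' the moving edge (centre row, current edge column) over a steady-state
#' window after the temporal filters have filled, then averaged. The default
#' speed grid spans 0.05-0.8 px/frame with finer steps at the slow end, the
#' range over which the distance set `{2..18}` px and the 30-frame delay make
#' the response-vector shape vary with speed (preferred speeds are near
#' `beta / tau3`).
#'
#' @param fparams a [frontend_params()].
#' @param lparams an [lptc_params()].
#' @param speeds candidate speed grid, px/frame, strictly increasing.
#' @param steady_window number of steady-state frames averaged.
#' @return object of class `tuning_table`: `speeds`, response matrix `resp`
#'   (`V x N`), unit-norm rows `resp_unit`, `floor` (response floor), and
#'   calibration metadata. Degenerate (all-zero) calibration rows raise an
#'   error: the speed lies outside the sensitive range.
#' @export
calibrate_tuning <- function(fparams = frontend_params(),
                             lparams = lptc_params(),
                             speeds = default_speed_grid(),
                             steady_window = 16L) {
  if (any(diff(speeds) <= 0)) stop("speeds must be strictly increasing")
  if (any(speeds <= 0)) stop("calibration speeds must be positive (a static scene gives zero response)")
  # warm-up: support of lamina + delay kernels
  k1 <- gamma_kernel(fparams$n1, fparams$tau1, fparams$tol)$taps
  k2 <- gamma_kernel(fparams$n2, fparams$tau2, fparams$tol)$taps
  k3 <- gamma_kernel(fparams$n3, fparams$tau3, fparams$tol)$taps
  warm <- max(length(k1), length(k2)) + length(k3)
  tn <- warm + steady_window + 2L
  nb <- length(lparams$betas)
  resp <- matrix(0, length(speeds), nb)
  height <- 12L
  mid <- as.integer(height / 2)
  for (k in seq_along(speeds)) {
    v <- speeds[k]
    stim <- drifting_edge_sequence(v, tn, height = height)
    ch <- run_frontend(stim$frames, fparams)
    acc <- numeric(nb)
    frames <- seq.int(warm + 1L, tn)
    for (t in frames) {
      lf <- lptc_frame(ch, t, lparams)
      xe <- as.integer(round(stim$edge_at(t)))
      acc <- acc + lf$r[mid, xe, ]
    }
    resp[k, ] <- acc / length(frames)
    if (max(resp[k, ]) <= 0) {
      stop(sprintf("degenerate calibration row at speed %g px/frame (outside sensitive range)", v))
    }
  }
  norms <- sqrt(rowSums(resp^2))
  structure(list(speeds = speeds, resp = resp,
                 resp_unit = resp / norms,
                 floor = max(resp) * lparams$floor_frac,
                 meta = list(betas = lparams$betas, n_dirs = lparams$n_dirs,
                             frontend = unclass(fparams),
                             steady_window = steady_window,
                             key = paste(c(unlist(fparams),
                                           lparams$betas, lparams$n_dirs),
                                         collapse = "|"))),
            class = "tuning_table")
}

#' Default candidate speed grid
#'
#' 0.05-0.8 px/frame: 0.025 steps up to 0.3, 0.05 steps to 0.6, then 0.7 and
#' 0.8. The published distance set and delay constant place the correlators'
#' preferred speeds at `beta / tau3` in [0.067, 0.6] px/frame; beyond
#' ~0.8 px/frame the population response falls below the decoding floor
#' (the delay kernel has no mass at sub-frame lags), so faster candidates
#' would be degenerate. See the package vignette.
#' @return numeric vector of speeds, px/frame.
#' @export
default_speed_grid <- function() {
  c(seq(0.05, 0.3, by = 0.025), seq(0.35, 0.6, by = 0.05), 0.7, 0.8)
}

#' @export
print.tuning_table <- function(x, ...) {
  cat(sprintf("<tuning_table> %d speeds in [%.3g, %.3g] px/frame, %d distances, floor %.3g\n",
              length(x$speeds), min(x$speeds), max(x$speeds),
              ncol(x$resp), x$floor))
  invisible(x)
}

#' Save / load a tuning table
#'
#' JSON persistence for the calibration artifact, including the parameter
#' key used to detect stale tables.
#' @param table a `tuning_table`.
#' @param path file path.
#' @return `write_tuning_table` returns `path` invisibly;
#'   `read_tuning_table` returns the `tuning_table`.
#' @export
write_tuning_table <- function(table, path) {
  obj <- list(speeds = table$speeds, resp = table$resp, floor = table$floor,
              meta = table$meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_tuning_table
#' @export
read_tuning_table <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  resp <- as.matrix(obj$resp)
  norms <- sqrt(rowSums(resp^2))
  structure(list(speeds = as.numeric(obj$speeds), resp = resp,
                 resp_unit = resp / norms, floor = obj$floor,
                 meta = obj$meta),
            class = "tuning_table")
}

#' Decode speed from firing-rate vectors
#'
#' Population decoding against the tuning table: the decoded speed maximises
#' `prod_i exp(-||r_i - f(v, beta_i)||^2)`, i.e. minimises the summed squared
#' distance over the lookup grid. By default both the measured vector and the
#' tuning rows are normalised to unit length first, so the match is on the
#' response *shape* across correlation distances; correlator amplitudes scale
#' with the square of stimulus contrast, and shape matching removes that
#' dependence (raw Euclidean matching is available with
#' `normalize = FALSE`). Vectors whose peak response falls below the table's
#' response floor decode to 0.
#'
#' @param r numeric vector of length N, or a matrix `[n, N]` of vectors.
#' @param table a `tuning_table`.
#' @param normalize match unit-norm shapes (default `TRUE`).
#' @param floor response floor; defaults to the table's absolute floor (1% of
#'   the calibration maximum). The pipeline passes a per-frame *relative*
#'   floor so decode validity does not depend on stimulus contrast.
#' @return decoded speed(s), px/frame (0 where below floor).
#' @export
decode_velocity <- function(r, table, normalize = TRUE, floor = NULL) {
  if (is.null(dim(r))) r <- matrix(r, 1L)
  if (ncol(r) != ncol(table$resp)) {
    stop("response vector length does not match the tuning table")
  }
  floor <- floor %||% table$floor
  v <- numeric(nrow(r))
  peak <- apply(r, 1, max)
  live <- peak >= floor & peak > 0
  if (any(live)) {
    rl <- r[live, , drop = FALSE]
    if (normalize) {
      rl <- rl / sqrt(rowSums(rl^2))
      # cosine similarity; argmax == argmin distance for unit vectors
      sim <- rl %*% t(table$resp_unit)
      v[live] <- table$speeds[max.col(sim, ties.method = "first")]
    } else {
      d2 <- outer(rowSums(rl^2), rep(1, length(table$speeds))) -
        2 * rl %*% t(table$resp) +
        outer(rep(1, nrow(rl)), rowSums(table$resp^2))
      v[live] <- table$speeds[max.col(-d2, ties.method = "first")]
    }
  }
  v
}

#' Accumulated displacement fields
#'
#' Integrates the decoded velocity field over a frame window:
#' `phi = sum v cos(theta)`, `psi = sum v sin(theta)` (frame-step
#' quadrature). An empty window yields zero grids.
#'
#' @param v array `[H, W, T]` of decoded speeds.
#' @param theta array `[H, W, T]` of motion directions, radians.
#' @param from,to window limits (frame indices, inclusive).
#' @return list with matrices `phi` and `psi` (px).
#' @export
accumulate_displacement <- function(v, theta, from, to) {
  d <- dim(v)
  phi <- matrix(0, d[1], d[2])
  psi <- matrix(0, d[1], d[2])
  if (to >= from) {
    for (t in seq.int(from, to)) {
      phi <- phi + v[, , t] * cos(theta[, , t])
      psi <- psi + v[, , t] * sin(theta[, , t])
    }
  }
  list(phi = phi, psi = psi)
}
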