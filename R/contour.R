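#' Contour-pathway parameters
#'
#' Settings of the geodesic-active-contour stage: the Gaussian inverse
#' gradient edge indicator and the narrow-band level-set solver. Defaults are
#' the published operating point: `sigma2 = 7` (gradient-magnitude units on a
#' 0-255 intensity scale), time step `dt = 0.1`, window radius 2 px and at
#' most 300 iterations.
#'
#' @param sigma2 edge-indicator standard deviation in gradient-magnitude
#'   units of the 0-255 intensity scale.
#' @param dt evolution time step.
#' @param window_radius local update window radius, px (retained for the
#'   solver contract; the narrow-band sweep updates the whole band).
#' @param max_iter maximum number of evolution iterations.
#' @param tol convergence tolerance: mean front displacement over 10 sweeps
#'   below `tol` px stops the evolution.
#' @param band_width half-width of the narrow band, px.
#' @param reinit_every iterations between signed-distance redistancing.
#' @param intensity_scale factor mapping `[0, 1]` luminance to the intensity
#'   scale on which `sigma2` is expressed (default 255).
#' @param warm_start seed each frame's level set from the previous frame's
#'   converged front when the dominant region moved little (default `FALSE`:
#'   re-initialise from the motion band every frame, which tracks
#'   accelerating boundaries more robustly; see the vignette).
#' @param warm_start_dist px; with `warm_start = TRUE`, the previous level
#'   set seeds the next frame only when the dominant-region centroid moved
#'   less than this.
#' @return object of class `contour_params`.
#' @export
contour_params <- function(sigma2 = 7, dt = 0.1, window_radius = 2,
                           max_iter = 300L, tol = 0.10, band_width = 5,
                           reinit_every = 25L, intensity_scale = 255,
                           warm_start = FALSE, warm_start_dist = 10) {
  if (dt <= 0) stop("dt must be positive")
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  structure(list(sigma2 = sigma2, dt = dt, window_radius = window_radius,
                 max_iter = as.integer(max_iter), tol = tol,
                 band_width = band_width,
                 reinit_every = as.integer(reinit_every),
                 intensity_scale = intensity_scale,
                 warm_start = isTRUE(warm_start),
                 warm_start_dist = warm_start_dist),
            class = "contour_params")
}

#' Gaussian inverse-gradient edge indicator
#'
#' Computes `g = exp(-|grad P|^2 / (2 sigma2^2))` from the retina-smoothed
#' frame `P` (central differences, luminance mapped to a 0-255 intensity
#' scale so the published `sigma2` applies as printed), then rescales so the
#' maximum is 1. `g` is strictly decreasing in the gradient magnitude, equals
#' 1 in homogeneous regions and drops towards 0 at strong boundaries, where
#' it arrests the evolving contour.
#'
#' Before the gradient, the frame's luminance range is normalised to `[0, 1]`
#' (the Amacrine stage: average luminance is suppressed and structural
#' boundaries are accentuated), which makes the edge map — and therefore the
#' extracted contour — independent of the object's contrast against the
#' background. Set `normalize = FALSE` for the raw-luminance form.
#'
#' @param p retina-smoothed luminance matrix (values in `[0, 1]`).
#' @param sigma2 standard deviation, 0-255 intensity units.
#' @param intensity_scale luminance-to-intensity factor (default 255).
#' @param normalize normalise the frame's luminance range first (default
#'   `TRUE`).
#' @return matrix `g` with values in `(0, 1]`.
#' @export
edge_indicator <- function(p, sigma2 = 7, intensity_scale = 255,
                           normalize = TRUE) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (normalize) {
    rng <- max(p) - min(p)
    if (rng > 1e-12) p <- (p - min(p)) / rng
  }
  gr <- grad_central(p * intensity_scale)
  gm2 <- gr$gx^2 + gr$gy^2
  g <- exp(-gm2 / (2 * sigma2^2))
  g / max(g)
}

# outermost region pixel per angular bin around (cx, cy)
band_outer_rim <- function(x, y, cx, cy, nbins = 48L) {
  d <- sqrt((x - cx)^2 + (y - cy)^2)
  bin <- floor((atan2(y - cy, x - cx) + pi) / (2 * pi) * nbins) %% nbins
  keep <- vapply(split(seq_along(d), bin),
                 function(i) i[which.max(d[i])], integer(1))
  list(x = x[keep], y = y[keep], r = d[keep])
}

# least-squares (Kasa) circle fit to pixel coordinates; returns c(cx, cy, R)
# or NULL when degenerate
kasa_circle_fit <- function(x, y) {
  n <- length(x)
  if (n < 3L) return(NULL)
  A <- cbind(x, y, 1)
  b <- x^2 + y^2
  fit <- tryCatch(unname(qr.solve(A, b)), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  cx <- fit[1] / 2; cy <- fit[2] / 2
  r2 <- fit[3] + cx^2 + cy^2
  if (!is.finite(r2) || r2 <= 0) return(NULL)
  c(cx, cy, sqrt(r2))
}

#' Initialise the level set from the dominant motion region
#'
#' Seeds the evolution from the dominant motion region. A least-squares
#' (Kasa) circle fit to the region's pixel coordinates — refined by a second
#' fit to the band's angular outer rim — provides the centre and a reference
#' radius. The motion-responsive band lies along the moving boundary but
#' trails it in proportion to the local boundary speed, and a balloon-free
#' geodesic evolution can only capture a front within the short attraction
#' range of the edge indicator (see the package vignette). With `g` supplied
#' (the default in the pipeline) the initial front is therefore refined
#' per direction: along each of 48 rays from the centre, the front is placed
#' at the deepest edge-indicator valley near the band's outer rim; directions
#' the motion band does not cover (e.g. the optical-stasis side of a diagonal
#' loom) are bridged by circular interpolation, completing the gap. Without
#' `g`, the seed is the fitted circle. The level set is negative inside.
#'
#' @param region logical matrix (dominant region) or a 2-column matrix of
#'   pixel coordinates `(x = col, y = row)`.
#' @param shape frame dimensions `c(H, W)` (taken from `region` when it is a
#'   matrix mask).
#' @param params a [contour_params()].
#' @param g optional edge-indicator matrix used to refine the initial front.
#' @return list of class `level_set`: `phi` (signed distance grid, negative
#'   inside), `center`, `radius`, `iterations = 0`, `converged = FALSE`.
#' @export
initialize_levelset <- function(region, shape = NULL,
                                params = contour_params(), g = NULL) {
  if (is.logical(region) || (is.matrix(region) && is.null(shape))) {
    if (!any(region)) stop("empty dominant region")
    shape <- dim(region)
    nr <- shape[1]
    px <- which(region)
    x <- ((px - 1L) %/% nr) + 1
    y <- ((px - 1L) %% nr) + 1
  } else {
    if (is.null(shape)) stop("shape required with coordinate input")
    x <- region[, 1]; y <- region[, 2]
    if (length(x) == 0L) stop("empty dominant region")
  }
  cx0 <- mean(x); cy0 <- mean(y)
  dists <- sqrt((x - cx0)^2 + (y - cy0)^2)
  rq <- stats::quantile(dists, 0.9, names = FALSE)
  fit <- kasa_circle_fit(x, y)
  if (is.null(fit) || fit[3] > 2.5 * max(rq, 5) ||
      fit[1] < 1 || fit[1] > shape[2] || fit[2] < 1 || fit[2] > shape[1]) {
    fit <- c(cx0, cy0, rq)
  }
  cx <- fit[1]; cy <- fit[2]
  # the motion-responsive band trails the moving boundary; its angular outer
  # rim is the best available boundary estimate (the band's thickness varies
  # with local boundary speed, which biases a fit through all band pixels),
  # and the balloon-free evolution needs the seed within the edge map's
  # short attraction range. Second pass: re-fit the circle to the rim.
  rim <- band_outer_rim(x, y, cx, cy)
  fit2 <- kasa_circle_fit(rim$x, rim$y)
  if (!is.null(fit2) && fit2[3] > 0.5 * fit[3] && fit2[3] < 2 * fit[3] &&
      fit2[1] >= 1 && fit2[1] <= shape[2] &&
      fit2[2] >= 1 && fit2[2] <= shape[1]) {
    cx <- fit2[1]; cy <- fit2[2]
    rim <- band_outer_rim(x, y, cx, cy)
  }
  radius <- max(5, stats::quantile(rim$r, 0.80, names = FALSE))
  X <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  Y <- matrix(seq_len(shape[1]), shape[1], shape[2])
  D <- sqrt((X - cx)^2 + (Y - cy)^2)
  if (is.null(g)) {
    phi <- D - radius
  } else {
    rad <- ray_refined_radii(rim, cx, cy, radius, g)
    # signed radial distance to the star-shaped front; the first redistance
    # inside evolve_contour() turns it into a true signed distance
    A <- (atan2(Y - cy, X - cx) + pi) / (2 * pi) * length(rad)
    r_of_a <- stats::approx(x = 0:length(rad),
                            y = c(rad[length(rad)], rad), xout = A,
                            rule = 2)$y
    phi <- D - matrix(r_of_a, shape[1], shape[2])
  }
  structure(list(phi = phi, center = c(cx, cy), radius = radius,
                 iterations = 0L, converged = FALSE, status = "initialized"),
            class = "level_set")
}

# per-direction front radius: the deepest edge-indicator valley near the
# band's outer rim, with uncovered directions bridged by circular
# interpolation and a light circular smoothing
ray_refined_radii <- function(rim, cx, cy, radius, g, nbins = 48L,
                              g_valley = 0.6) {
  rad <- rep(NA_real_, nbins)
  bin <- (floor((atan2(rim$y - cy, rim$x - cx) + pi) / (2 * pi) * nbins) %%
            nbins) + 1L
  for (k in seq_along(bin)) {
    b <- bin[k]
    a <- (b - 0.5) / nbins * 2 * pi - pi
    rr <- seq(max(2, rim$r[k] - 3), rim$r[k] + 10, by = 0.5)
    gx <- cx + rr * cos(a); gy <- cy + rr * sin(a)
    inside <- gx >= 1 & gx <= ncol(g) & gy >= 1 & gy <= nrow(g)
    if (!any(inside)) { rad[b] <- rim$r[k]; next }
    gv <- sample_bilinear(g, gx[inside], gy[inside])
    if (min(gv) < g_valley) {
      rad[b] <- rr[inside][which.min(gv)]
    } else {
      rad[b] <- rim$r[k]
    }
  }
  if (anyNA(rad)) {
    if (all(is.na(rad))) return(rep(radius, nbins))
    # circular linear interpolation across uncovered bins
    idx <- which(!is.na(rad))
    ext_x <- c(idx - nbins, idx, idx + nbins)
    ext_y <- rep(rad[idx], 3)
    rad <- stats::approx(ext_x, ext_y, xout = seq_len(nbins), rule = 2)$y
  }
  # light circular smoothing (3-bin mean)
  (rad + rad[c(nbins, 1:(nbins - 1))] + rad[c(2:nbins, 1)]) / 3
}

#' @export
print.level_set <- function(x, ...) {
  cat(sprintf("<level_set> %d x %d grid, %d iterations, %s\n",
              nrow(x$phi), ncol(x$phi), x$iterations,
              if (isTRUE(x$converged)) "converged" else x$status))
  invisible(x)
}

# zero-level polyline vertices of phi as an (x, y) matrix (all components)
zero_front_points <- function(phi) {
  cl <- suppressWarnings(
    grDevices::contourLines(x = seq_len(nrow(phi)), y = seq_len(ncol(phi)),
                            phi, levels = 0))
  if (length(cl) == 0L) return(NULL)
  do.call(rbind, lapply(cl, function(c1) cbind(c1$y, c1$x)))  # (x=col, y=row)
}

# redistance phi to a signed distance function from its current zero level
# set; values outside the band are clamped to +-clamp_at
redistance <- function(phi, band = 5, clamp_at = band + 1) {
  pts <- zero_front_points(phi)
  if (is.null(pts)) return(NULL)
  nr <- nrow(phi); nc <- ncol(phi)
  newphi <- matrix(clamp_at, nr, nc)
  newphi[phi < 0] <- -clamp_at
  # candidate pixels near the front: bounding boxes around front points
  cand <- matrix(FALSE, nr, nc)
  ix <- pmin(pmax(round(pts[, 1]), 1L), nc)
  iy <- pmin(pmax(round(pts[, 2]), 1L), nr)
  r <- ceiling(band) + 1L
  for (dx in -r:r) {
    cx <- pmin(pmax(ix + dx, 1L), nc)
    for (dy in -r:r) {
      cand[cbind(pmin(pmax(iy + dy, 1L), nr), cx)] <- TRUE
    }
  }
  ci <- which(cand)
  px <- ((ci - 1L) %/% nr) + 1
  py <- ((ci - 1L) %% nr) + 1
  # min distance to front vertices (vertices are ~1 px apart along the front)
  dmin <- rep(Inf, length(ci))
  chunk <- 512L
  for (s in seq(1L, nrow(pts), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(pts))
    dd <- outer(px, pts[s:e, 1], "-")^2 + outer(py, pts[s:e, 2], "-")^2
    dmin <- pmin(dmin, sqrt(do.call(pmin, asplit(dd, 2))))
  }
  newphi[ci] <- sign(phi[ci]) * pmin(dmin, clamp_at)
  newphi
}

#' Evolve the level set under the geodesic active contour flow
#'
#' Integrates `phi_t = g K |grad phi| + grad g . grad phi` (curvature-driven
#' smoothing weighted by the edge indicator plus gradient-guided advection;
#' no balloon term) with upwind differencing for the advection term and
#' central differences for curvature. Updates are restricted to a narrow
#' band around the zero level set; the field is redistanced to a signed
#' distance every `reinit_every` iterations; evolution stops at `max_iter`
#' or when the mean front displacement over 10 sweeps falls below `tol`.
#'
#' @param levelset a `level_set` (see [initialize_levelset()]).
#' @param g edge indicator matrix from [edge_indicator()], same shape.
#' @param params a [contour_params()].
#' @return the evolved `level_set`; `status` is `"collapsed"` (no zero
#'   crossing remains), `"converged"` or `"max_iter"`.
#' @export
evolve_contour <- function(levelset, g, params = contour_params()) {
  phi <- levelset$phi
  if (!all(dim(phi) == dim(g))) stop("g and phi must have the same shape")
  nr <- nrow(phi); nc <- ncol(phi)
  gg <- grad_central(g)
  gx <- gg$gx; gy <- gg$gy
  band_w <- params$band_width
  clamp_at <- band_w + 1
  phi <- redistance(phi, band_w, clamp_at)
  if (is.null(phi)) {
    levelset$status <- "collapsed"; levelset$phi[] <- clamp_at
    return(levelset)
  }
  # offsets in column-major indexing
  oN <- -1L; oS <- 1L; oW <- -nr; oE <- nr
  interior <- function(idx) {
    py <- ((idx - 1L) %% nr) + 1L
    px <- ((idx - 1L) %/% nr) + 1L
    idx[py > 1L & py < nr & px > 1L & px < nc]
  }
  band <- interior(which(abs(phi) < band_w))
  prev_front <- zero_front_points(phi)
  it <- 0L
  converged <- FALSE
  while (it < params$max_iter) {
    it <- it + 1L
    if (length(band) == 0L) break
    pc <- phi[band]
    pE <- phi[band + oE]; pW <- phi[band + oW]
    pN <- phi[band + oN]; pS <- phi[band + oS]
    pNE <- phi[band + oN + oE]; pNW <- phi[band + oN + oW]
    pSE <- phi[band + oS + oE]; pSW <- phi[band + oS + oW]
    dx <- (pE - pW) / 2; dy <- (pS - pN) / 2
    dxx <- pE - 2 * pc + pW
    dyy <- pS - 2 * pc + pN
    dxy <- (pSE - pNE - pSW + pNW) / 4
    g2 <- dx^2 + dy^2
    K <- (dxx * dy^2 - 2 * dx * dy * dxy + dyy * dx^2) / (g2^1.5 + 1e-9)
    K <- clamp(K, -1, 1)
    curvature_term <- g[band] * K * sqrt(g2)
    # upwind advection grad g . grad phi
    a <- gx[band]; b <- gy[band]
    Dxm <- pc - pW; Dxp <- pE - pc
    Dym <- pc - pN; Dyp <- pS - pc
    advection <- pmax(a, 0) * Dxm + pmin(a, 0) * Dxp +
                 pmax(b, 0) * Dym + pmin(b, 0) * Dyp
    phi[band] <- pc + params$dt * (curvature_term + advection)
    redistanced <- FALSE
    if (it %% params$reinit_every == 0L) {
      nphi <- redistance(phi, band_w, clamp_at)
      if (is.null(nphi)) { levelset$status <- "collapsed"; break }
      phi <- nphi
      band <- interior(which(abs(phi) < band_w))
      redistanced <- TRUE
    }
    if (it %% 10L == 0L) {
      # mean front displacement over the last 10 sweeps: |phi| sampled at the
      # previous front (|grad phi| ~ 1 near the front)
      if (!is.null(prev_front)) {
        disp <- abs(sample_bilinear(phi, prev_front[, 1], prev_front[, 2]))
        if (mean(disp) < params$tol) { converged <- TRUE }
      }
      prev_front <- zero_front_points(phi)
      if (is.null(prev_front)) { levelset$status <- "collapsed"; break }
      if (converged) break
      if (!redistanced) {
        band <- interior(which(abs(phi) < band_w))
      }
    }
  }
  levelset$phi <- phi
  levelset$iterations <- levelset$iterations + it
  levelset$converged <- converged
  if (is.null(zero_front_points(phi))) {
    levelset$status <- "collapsed"
  } else if (!identical(levelset$status, "collapsed")) {
    levelset$status <- if (converged) "converged" else "max_iter"
  }
  levelset
}

#' Extract the final contour polyline
#'
#' Marching-squares extraction (linear interpolation) of the zero level set
#' as an ordered closed polyline with sub-pixel vertices. When several closed
#' components exist, the one enclosing `center` (default: the level set's
#' initialisation centre) is kept, falling back to the largest-area
#' component. Vertices are reordered so the signed area is positive, and
#' per-vertex outward unit normals and arc lengths are attached.
#'
#' @param levelset a `level_set` (or a bare `phi` matrix).
#' @param center optional `c(x, y)` the target contour must enclose.
#' @return object of class `target_contour`: `xy` (n x 2 vertex matrix, open
#'   representation of a closed polyline), `normal` (n x 2 outward unit
#'   normals), `dl` (per-vertex arc length), `area` (enclosed area, px^2),
#'   `status` (`"ok"` or `"empty"`).
#' @export
extract_polyline <- function(levelset, center = NULL) {
  phi <- if (inherits(levelset, "level_set")) levelset$phi else levelset
  if (is.null(center) && inherits(levelset, "level_set")) {
    center <- levelset$center
  }
  cl <- suppressWarnings(
    grDevices::contourLines(x = seq_len(nrow(phi)),
                            y = seq_len(ncol(phi)), phi, levels = 0))
  if (length(cl) == 0L) {
    return(structure(list(xy = NULL, normal = NULL, dl = NULL, area = 0,
                          status = "empty"), class = "target_contour"))
  }
  polys <- lapply(cl, function(c1) {
    vx <- c1$y; vy <- c1$x  # contourLines x runs along rows
    n <- length(vx)
    if (vx[1] == vx[n] && vy[1] == vy[n]) { vx <- vx[-n]; vy <- vy[-n] }
    list(x = vx, y = vy, area = polygon_area(vx, vy))
  })
  polys <- Filter(function(p) length(p$x) >= 3L, polys)
  if (length(polys) == 0L) {
    return(structure(list(xy = NULL, normal = NULL, dl = NULL, area = 0,
                          status = "empty"), class = "target_contour"))
  }
  pick <- NULL
  if (!is.null(center)) {
    enclosing <- which(vapply(polys, function(p)
      point_in_polygon(center[1], center[2], p$x, p$y), logical(1)))
    if (length(enclosing)) {
      pick <- enclosing[which.max(vapply(polys[enclosing],
                                         function(p) abs(p$area), numeric(1)))]
    }
  }
  if (is.null(pick)) {
    pick <- which.max(vapply(polys, function(p) abs(p$area), numeric(1)))
  }
  p <- polys[[pick]]
  if (p$area < 0) { p$x <- rev(p$x); p$y <- rev(p$y); p$area <- -p$area }
  n <- length(p$x)
  nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1L))
  tx <- (p$x[nxt] - p$x[prv]) / 2
  ty <- (p$y[nxt] - p$y[prv]) / 2
  tl <- sqrt(tx^2 + ty^2); tl[tl == 0] <- 1
  # for a positively oriented polygon the outward normal is the tangent
  # rotated by -90 degrees: (ty, -tx)
  nx <- ty / tl; ny <- -tx / tl
  seg_prev <- sqrt((p$x - p$x[prv])^2 + (p$y - p$y[prv])^2)
  dl <- (seg_prev + seg_prev[nxt]) / 2
  structure(list(xy = cbind(x = p$x, y = p$y),
                 normal = cbind(nx = nx, ny = ny),
                 dl = dl, area = p$area, status = "ok"),
            class = "target_contour")
}

#' @export
print.target_contour <- function(x, ...) {
  if (identical(x$status, "empty")) {
    cat("<target_contour> empty\n")
  } else {
    cat(sprintf("<target_contour> %d vertices, perimeter %.1f px, area %.1f px^2\n",
                nrow(x$xy), sum(x$dl), x$area))
  }
  invisible(x)
}

#' Discrete geodesic energy of a contour
#'
#' Quadrature of the edge-weighted arc length `integral g dl` along a
#' polyline; the quantity the geodesic active contour minimises.
#'
#' @param contour a `target_contour`.
#' @param g edge indicator matrix.
#' @return scalar energy.
#' @export
contour_energy <- function(contour, g) {
  if (identical(contour$status, "empty")) return(NA_real_)
  gv <- sample_bilinear(g, contour$xy[, 1], contour$xy[, 2])
  sum(gv * contour$dl)
}
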