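# Internal numerical helpers shared across modules.
#
# Image convention used throughout the package: a frame is a numeric matrix
# indexed [row, col]; positions are (x, y) with x = column, y = row, origin at
# the top-left pixel (1, 1). Angles are measured from the +x axis with +y
# pointing down the rows (image convention), so theta = pi/2 points towards
# increasing row index.

#' @keywords internal
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Integer shift of a matrix by (dx columns, dy rows), zero-filled: the result
# at (row r, col c) is m[r + dy, c + dx] where that index exists, else 0.
#' @noRd
shift_int <- function(m, dx, dy) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  src_r <- seq_len(nr) + dy
  src_c <- seq_len(nc) + dx
  keep_r <- src_r >= 1L & src_r <= nr
  keep_c <- src_c >= 1L & src_c <= nc
  if (any(keep_r) && any(keep_c)) {
    out[which(keep_r), which(keep_c)] <- m[src_r[keep_r], src_c[keep_c], drop = FALSE]
  }
  out
}

# Bilinear sample of m at the displaced grid (x + dx, y + dy); out-of-frame
# samples are zero. dx, dy may be fractional.
#' @noRd
shift_bilinear <- function(m, dx, dy) {
  ix <- floor(dx); fx <- dx - ix
  iy <- floor(dy); fy <- dy - iy
  if (fx == 0 && fy == 0) return(shift_int(m, ix, iy))
  (1 - fx) * (1 - fy) * shift_int(m, ix,      iy) +
  fx       * (1 - fy) * shift_int(m, ix + 1L, iy) +
  (1 - fx) * fy       * shift_int(m, ix,      iy + 1L) +
  fx       * fy       * shift_int(m, ix + 1L, iy + 1L)
}

# Bilinear interpolation of matrix m at arbitrary points (x = col, y = row).
# Points outside the grid are clamped to the border when `rule = "clamp"`,
# or return `fill` when `rule = "fill"`.
#' @noRd
sample_bilinear <- function(m, x, y, rule = c("clamp", "fill"), fill = 0) {
  rule <- match.arg(rule)
  nr <- nrow(m); nc <- ncol(m)
  out_of <- x < 1 | x > nc | y < 1 | y > nr
  xx <- clamp(x, 1, nc); yy <- clamp(y, 1, nr)
  x0 <- clamp(floor(xx), 1, nc - 1L); y0 <- clamp(floor(yy), 1, nr - 1L)
  fx <- xx - x0; fy <- yy - y0
  idx <- function(r, c) m[cbind(r, c)]
  val <- (1 - fx) * (1 - fy) * idx(y0,      x0) +
         fx       * (1 - fy) * idx(y0,      x0 + 1L) +
         (1 - fx) * fy       * idx(y0 + 1L, x0) +
         fx       * fy       * idx(y0 + 1L, x0 + 1L)
  if (rule == "fill") val[out_of] <- fill
  val
}

# Separable Gaussian convolution with replicate-padded borders.
# Kernel truncated at ceiling(3 * sigma) taps each side and normalised.
#' @noRd
gauss_smooth <- function(m, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  r <- ceiling(3 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  conv_sep(m, k)
}

# 1-D kernel applied along rows then columns with replicate padding.
#' @noRd
conv_sep <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  # pad by index clamping
  ri <- clamp(seq.int(1L - r, nr + r), 1L, nr)
  ci <- clamp(seq.int(1L - r, nc + r), 1L, nc)
  mp <- m[ri, ci, drop = FALSE]
  # convolve along rows (dimension 1)
  tmp <- matrix(0, nr, nc + 2L * r)
  for (j in seq_along(k)) {
    tmp <- tmp + k[j] * mp[seq.int(j, j + nr - 1L), , drop = FALSE]
  }
  out <- matrix(0, nr, nc)
  for (j in seq_along(k)) {
    out <- out + k[j] * tmp[, seq.int(j, j + nc - 1L), drop = FALSE]
  }
  out
}

# Causal temporal convolution matrix for a frame stream of length tlen.
# Returns B (tlen x tlen) such that, for X of shape [npix, tlen],
# X %*% B yields the stream filtered by taps h (h[1] = lag 0), with the
# stream replicate-padded into the past (frames before the clip equal the
# first frame).
#' @noRd
temporal_conv_matrix <- function(h, tlen, pad = c("replicate", "zero")) {
  pad <- match.arg(pad)
  B <- matrix(0, tlen, tlen)
  for (t in seq_len(tlen)) {
    lags <- seq_along(h) - 1L
    src <- t - lags
    inside <- src >= 1L
    for (j in which(inside)) B[src[j], t] <- B[src[j], t] + h[j]
    if (pad == "replicate" && any(!inside)) {
      B[1L, t] <- B[1L, t] + sum(h[!inside])
    }
  }
  B
}

# Apply taps h causally along the 3rd dimension of array a [H, W, T].
#' @noRd
temporal_filter <- function(a, h, pad = "replicate") {
  d <- dim(a)
  B <- temporal_conv_matrix(h, d[3], pad)
  x <- matrix(a, d[1] * d[2], d[3]) %*% B
  array(x, d)
}

# Central-difference gradients with replicated borders. Returns list(gx, gy)
# where gx is d/dcol and gy is d/drow.
#' @noRd
grad_central <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  xm <- m[, clamp(seq_len(nc) - 1L, 1L, nc), drop = FALSE]
  xp <- m[, clamp(seq_len(nc) + 1L, 1L, nc), drop = FALSE]
  ym <- m[clamp(seq_len(nr) - 1L, 1L, nr), , drop = FALSE]
  yp <- m[clamp(seq_len(nr) + 1L, 1L, nr), , drop = FALSE]
  list(gx = (xp - xm) / 2, gy = (yp - ym) / 2)
}

# Label 8-connected components of a logical matrix. Returns an integer matrix
# (0 = background) and the component sizes, largest first relabelled as 1.
#' @noRd
label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (length(idx) == 0L) return(list(labels = lab, sizes = integer(0)))
  row <- ((idx - 1L) %% nr) + 1L
  col <- ((idx - 1L) %/% nr) + 1L
  # edges to 4 forward neighbours (E, S, SE, SW) cover 8-connectivity
  nb <- function(dr, dc) {
    ok <- which(row + dr >= 1L & row + dr <= nr & col + dc >= 1L & col + dc <= nc)
    tgt <- idx[ok] + dr + dc * nr
    sel <- mask[tgt]
    cbind(ok[sel], match(tgt[sel], idx))
  }
  e <- rbind(nb(0L, 1L), nb(1L, 0L), nb(1L, 1L), nb(-1L, 1L))
  e <- e[!is.na(e[, 2]), , drop = FALSE]
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (nrow(e) > 0) g <- igraph::add_edges(g, t(e))
  comp <- igraph::components(g)
  # relabel by decreasing size
  ord <- order(comp$csize, decreasing = TRUE)
  newlab <- match(comp$membership, ord)
  lab[idx] <- newlab
  list(labels = lab, sizes = comp$csize[ord])
}

# Even-odd (ray crossing) point-in-polygon test for a single point.
#' @noRd
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if (((vy[i] > py) != (vy[j] > py)) &&
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

# Shoelace signed area of polygon given open vertex lists.
#' @noRd
polygon_area <- function(vx, vy) {
  n <- length(vx)
  j <- c(n, seq_len(n - 1L))
  sum(vx[j] * vy - vx * vy[j]) / 2
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
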