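#' Frame sequence container
#'
#' A time-ordered stack of 2-D luminance grids with frame-rate metadata; the
#' universal carrier between processing stages. Frames are numeric matrices
#' in `[0, 1]`, indexed `[row, col]`.
#'
#' @param frames numeric array `[H, W, T]` (or a list of equally sized
#'   matrices) with values in `[0, 1]`; values are clipped.
#' @param fps frames per second.
#' @param source optional source path.
#' @return an object of class `frame_sequence` with elements `frames`
#'   (array `[H, W, T]`), `fps` and `source`.
#' @export
frame_sequence <- function(frames, fps = 30, source = NULL) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1L) stop("all frames must have the same size")
    frames <- array(unlist(frames), c(dims[[1]], length(frames)))
  }
  if (length(dim(frames)) != 3L) stop("frames must be an [H, W, T] array")
  if (dim(frames)[3] < 1L) stop("at least one frame required")
  frames[] <- clamp(frames, 0, 1)
  structure(list(frames = frames, fps = fps, source = source),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_sequence> %d x %d px, %d frames @ %g fps\n",
              d[1], d[2], d[3], x$fps))
  invisible(x)
}

#' @export
dim.frame_sequence <- function(x) dim(x$frames)

#' Synthetic stimulus specification
#'
#' Describes one synthetic scene: the object's shape and photometry, its
#' trajectory, and rendering parameters. Looming follows a perspective
#' (constant approach speed) law: the apparent radius is
#' `rho(t) = rho0 * sqrt(tc^2 + th^2) / sqrt((tc - t)^2 + th^2)`
#' where `tc` is the collision frame (physical contact, `Z = 0`) and `th` is
#' an optional closest-approach offset in frame units (`th = 0` gives the
#' classic head-on hyperbolic growth `rho0 * tc / (tc - t)`).
#'
#' @param kind scene kind: `"loom"`, `"translate"`, `"recede"`,
#'   `"diagonal_loom"`, `"deform_loom"` or `"multi_object"`.
#' @param shape object shape: `"disc"`, `"rectangle"` or `"polygon"`.
#' @param background,object_luminance luminances in `[0, 1]`.
#' @param width,height frame size in px.
#' @param n_frames number of frames (>= 2).
#' @param fps frame rate.
#' @param radius0 initial apparent radius, px (for rectangles the
#'   half-diagonal; for polygons the circumradius).
#' @param collision_frame frame of physical contact for looming kinds
#'   (may exceed `n_frames`; `NA` for non-looming kinds).
#' @param approach_offset closest-approach offset `th` in frame units
#'   (0 = head-on).
#' @param center0 object centre at t = 0, `c(x, y)` px.
#' @param lateral_velocity lateral drift of the centre, `c(vx, vy)` px/frame.
#' @param recede_rate for `"recede"`: apparent radius follows
#'   `rho0 * t0 / (t0 + t)` with `t0 = recede_rate` frames.
#' @param noise_sd additive Gaussian luminance noise (applied after
#'   rasterisation, clipped to `[0, 1]`).
#' @param seed integer random seed (drives noise and distractors).
#' @param deform_schedule for `"deform_loom"`: list with fractional clip
#'   positions `square_at`, `polygon_at` and `morph_frac` (morph duration as a
#'   fraction of the clip); defaults follow the circle-to-square-to-polygon
#'   script with switches at 54% and 75% of the clip.
#' @param distractors for `"multi_object"`: list of lists, each with fields
#'   `radius`, `center0`, `velocity`, `luminance` describing a translating
#'   distractor.
#' @param n_polygon number of vertices of the polygon shape (default 5).
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind = c("loom", "translate", "recede",
                                   "diagonal_loom", "deform_loom",
                                   "multi_object"),
                          shape = c("disc", "rectangle", "polygon"),
                          background = 0.0, object_luminance = 1.0,
                          width = 160, height = 120,
                          n_frames = 120, fps = 30,
                          radius0 = 8, collision_frame = NA,
                          approach_offset = 0,
                          center0 = c(width / 2, height / 2),
                          lateral_velocity = c(0, 0),
                          recede_rate = 40,
                          noise_sd = 0, seed = 1L,
                          deform_schedule = NULL,
                          distractors = NULL,
                          n_polygon = 5L) {
  kind <- match.arg(kind)
  shape <- match.arg(shape)
  if (background < 0 || background > 1 || object_luminance < 0 ||
      object_luminance > 1) {
    stop("luminances must lie in [0, 1]")
  }
  if (n_frames < 2) stop("frame count must be >= 2")
  looming <- kind %in% c("loom", "diagonal_loom", "deform_loom", "multi_object")
  if (looming && is.na(collision_frame)) {
    collision_frame <- round(0.92 * n_frames)
  }
  if (kind == "deform_loom" && is.null(deform_schedule)) {
    deform_schedule <- list(square_at = 0.55, polygon_at = 0.75,
                            morph_frac = 0.15)
  }
  structure(list(kind = kind, shape = shape,
                 background = background,
                 object_luminance = object_luminance,
                 weber_contrast = if (background > 0)
                   (object_luminance - background) / background else NA_real_,
                 width = width, height = height,
                 n_frames = n_frames, fps = fps,
                 radius0 = radius0, collision_frame = collision_frame,
                 approach_offset = approach_offset,
                 center0 = center0, lateral_velocity = lateral_velocity,
                 recede_rate = recede_rate,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 deform_schedule = deform_schedule,
                 distractors = distractors,
                 n_polygon = as.integer(n_polygon)),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec> %s %s, %dx%d px, %d frames @ %g fps\n",
              x$kind, x$shape, x$height, x$width, x$n_frames, x$fps))
  cat(sprintf("  luminance obj %.3g on bg %.3g (Weber %s), radius0 %.3g px\n",
              x$object_luminance, x$background,
              ifelse(is.na(x$weber_contrast), "n/a",
                     sprintf("%+.3g", x$weber_contrast)), x$radius0))
  invisible(x)
}

# apparent radius trajectory, possibly exceeding the frame
spec_radius <- function(spec, t) {
  tc <- spec$collision_frame
  th <- spec$approach_offset
  if (spec$kind == "deform_loom") {
    # size increase stalls during the deformation phases: the perspective law
    # runs on effective time that excludes the morph windows
    t <- deform_effective_time(spec, t)
  }
  switch(spec$kind,
    translate = rep(spec$radius0, length(t)),
    recede = spec$radius0 * spec$recede_rate / (spec$recede_rate + t),
    # all looming kinds share the perspective law
    {
      denom <- sqrt(pmax((tc - t), 0)^2 + th^2)
      denom[denom < 1e-9] <- 1e-9
      spec$radius0 * sqrt(tc^2 + th^2) / denom
    })
}

# frames elapsed excluding the deform-loom morph windows
deform_effective_time <- function(spec, t) {
  sch <- spec$deform_schedule
  w <- max(1, sch$morph_frac * spec$n_frames)
  starts <- c(sch$square_at, sch$polygon_at) * spec$n_frames
  teff <- t
  for (s in starts) {
    teff <- teff - pmin(pmax(t - s, 0), w)
  }
  teff
}

spec_center <- function(spec, t) {
  cbind(spec$center0[1] + spec$lateral_velocity[1] * t,
        spec$center0[2] + spec$lateral_velocity[2] * t)
}

# radial profile r(angle) of the shape at unit scale (area pi for rho = 1),
# used for star-shaped rasterisation and analytic areas
shape_radius_fun <- function(shape, n_polygon = 5L) {
  switch(shape,
    disc = function(a) rep(1, length(a)),
    rectangle = {
      # square of equal area pi: half-side s with (2 s)^2 = pi
      s <- sqrt(pi) / 2
      function(a) s / pmax(abs(cos(a)), abs(sin(a)))
    },
    polygon = {
      k <- n_polygon
      # regular k-gon of area pi: circumradius Rc
      Rc <- sqrt(2 * pi / (k * sin(2 * pi / k)))
      apo <- Rc * cos(pi / k)
      function(a) {
        am <- (a %% (2 * pi / k)) - pi / k
        apo / cos(am)
      }
    })
}

# blended radial profile for the deform-loom schedule; returns function(angle)
# and the area factor (area of unit-scale shape / pi, = 1 for area-preserving
# morphs by construction)
deform_profile <- function(spec, t) {
  sch <- spec$deform_schedule
  tsq <- sch$square_at * spec$n_frames
  tpg <- sch$polygon_at * spec$n_frames
  w <- max(1, sch$morph_frac * spec$n_frames)
  f_circle <- shape_radius_fun("disc")
  f_square <- shape_radius_fun("rectangle")
  f_poly <- shape_radius_fun("polygon", spec$n_polygon)
  # area-preserving blend: corners push out while edges pull in, with the
  # enclosed area held at pi * rho^2 (the morph itself adds no expansion)
  blend <- function(f1, f2, a) {
    fb <- function(ang) (1 - a) * f1(ang) + a * f2(ang)
    sc <- sqrt(pi / analytic_area(fb, 1))
    function(ang) sc * fb(ang)
  }
  if (t < tsq) return(f_circle)
  if (t < tsq + w) return(blend(f_circle, f_square, (t - tsq) / w))
  if (t < tpg) return(f_square)
  if (t < tpg + w) return(blend(f_square, f_poly, (t - tpg) / w))
  f_poly
}

# analytic area of a star-shaped region with radius function rho * f(angle)
analytic_area <- function(f, rho, nq = 2048L) {
  a <- (seq_len(nq) - 0.5) / nq * 2 * pi
  sum((rho * f(a))^2) / 2 * (2 * pi / nq)
}

# rasterise a star-shaped region (4x4 supersampling) into a coverage matrix
rasterise_star <- function(h, w, cx, cy, rho, f, ss = 4L) {
  # supersample grid centred on pixel centres
  off <- (seq_len(ss) - 0.5) / ss - 0.5
  xs <- rep(seq_len(w), each = ss) + rep(off, times = w)
  ys <- rep(seq_len(h), each = ss) + rep(off, times = h)
  dx <- matrix(xs - cx, nrow = h * ss, ncol = w * ss, byrow = TRUE)
  dy <- matrix(ys - cy, nrow = h * ss, ncol = w * ss)
  rr <- sqrt(dx * dx + dy * dy)
  aa <- atan2(dy, dx)
  inside <- (rr <= rho * f(aa)) + 0
  # average ss x ss blocks
  m <- matrix(inside, nrow = h * ss)
  m <- rowsum(m, rep(seq_len(h), each = ss)) / ss
  m <- t(rowsum(t(m), rep(seq_len(w), each = ss)) / ss)
  m
}

#' Render a synthetic scene
#'
#' Rasterises the scene described by a [stimulus_spec()] with 4x anti-aliasing
#' supersampling and returns both the frame sequence and its ground truth.
#' Rendering is deterministic given the spec (including its seed). Ground
#' truth areas are computed from the analytic shape, not from pixels; objects
#' may exceed or leave the frame, in which case the per-frame *visible*
#' relative area is additionally reported.
#'
#' @param spec a [stimulus_spec()].
#' @param keep_masks logical; store per-frame object masks (coverage > 0.5)
#'   in the ground truth (default `TRUE`).
#' @return list with elements `seq` (a [frame_sequence()]) and `gt` (class
#'   `ground_truth`: per-frame analytic `area` px^2, anti-aliased
#'   `pixel_area`, `relative_area` (clipped to the field of view),
#'   `collision_frame`, `delta_f`, `speed_class`, `center` and `radius`
#'   trajectories, and optional `masks`).
#' @export
render_scene <- function(spec, keep_masks = TRUE) {
  stopifnot(inherits(spec, "stimulus_spec"))
  h <- spec$height; w <- spec$width; tn <- spec$n_frames
  frames <- array(spec$background, c(h, w, tn))
  masks <- if (keep_masks) array(FALSE, c(h, w, tn)) else NULL
  rho <- spec_radius(spec, seq_len(tn) - 1)
  ctr <- spec_center(spec, seq_len(tn) - 1)
  area <- numeric(tn)
  pixel_area <- numeric(tn)
  fov <- h * w
  set.seed(spec$seed)
  for (t in seq_len(tn)) {
    f <- if (spec$kind == "deform_loom") deform_profile(spec, t - 1)
         else shape_radius_fun(spec$shape, spec$n_polygon)
    rmax <- min(rho[t], 2 * sqrt(h^2 + w^2))  # cap far beyond the frame
    cov <- rasterise_star(h, w, ctr[t, 1], ctr[t, 2], rmax, f)
    frame <- spec$background + (spec$object_luminance - spec$background) * cov
    if (!is.null(spec$distractors)) {
      for (d in spec$distractors) {
        dc <- c(d$center0[1] + d$velocity[1] * (t - 1),
                d$center0[2] + d$velocity[2] * (t - 1))
        dcov <- rasterise_star(h, w, dc[1], dc[2], d$radius,
                               shape_radius_fun("disc"))
        frame <- frame + (d$luminance - spec$background) * dcov * (cov < 0.5)
      }
    }
    if (spec$noise_sd > 0) {
      frame <- frame + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    }
    frames[, , t] <- clamp(frame, 0, 1)
    if (keep_masks) masks[, , t] <- cov > 0.5
    pixel_area[t] <- sum(cov)   # anti-aliased pixel count of the target
    area[t] <- analytic_area(f, rho[t])
  }
  rel <- pmin(area / fov, 1)
  df <- delta_f_8pct(rel)
  gt <- structure(list(area = area, pixel_area = pixel_area,
                       relative_area = rel,
                       collision_frame = if (is.na(spec$collision_frame)) NA
                                         else ceiling(spec$collision_frame),
                       delta_f = df,
                       speed_class = speed_class_from_delta_f(df),
                       center = ctr, radius = rho,
                       masks = masks, fov = fov),
                  class = "ground_truth")
  list(seq = frame_sequence(frames, spec$fps), gt = gt)
}

# minimum frame span over which the relative area changes by 8% (relative)
delta_f_8pct <- function(rel, frac = 0.08) {
  tn <- length(rel)
  best <- Inf
  for (t in seq_len(tn - 1L)) {
    if (rel[t] <= 0) next
    ratio <- abs(rel[(t + 1L):tn] / rel[t] - 1)
    hit <- which(ratio >= frac)
    if (length(hit)) best <- min(best, hit[1])
    if (best == 1) break
  }
  if (is.infinite(best)) NA_integer_ else as.integer(best)
}

speed_class_from_delta_f <- function(df) {
  if (is.na(df)) return("unclassified")
  if (df <= 30) return("fast")
  if (df > 50) return("slow")
  "unclassified"
}

#' Classify approach speed from ground truth
#'
#' Computes `Delta_f`, the minimum frame span over which the relative area
#' changes by 8% (relative), and assigns the speed class: `Delta_f <= 30`
#' frames is `"fast"`, `Delta_f > 50` frames is `"slow"`, and the unassigned
#' gap (30, 50] — or an area series that never changes by 8% — yields
#' `"unclassified"`.
#'
#' @param gt a `ground_truth` object from [render_scene()], or a numeric
#'   vector of per-frame relative areas.
#' @return `"fast"`, `"slow"` or `"unclassified"`.
#' @export
classify_speed <- function(gt) {
  rel <- if (inherits(gt, "ground_truth")) gt$relative_area else as.numeric(gt)
  speed_class_from_delta_f(delta_f_8pct(rel))
}

#' Contrast-matched variants of a stimulus
#'
#' Returns specs that differ only in object luminance, computed from the
#' requested Weber contrasts `(I_obj - I_bg) / I_bg`; kinematics, seed and all
#' other fields are identical, so ground truth is shared bit-for-bit.
#'
#' @param spec a [stimulus_spec()] with positive background luminance.
#' @param weber_values numeric vector of Weber contrasts.
#' @return list of `stimulus_spec`, one per contrast.
#' @export
contrast_variants <- function(spec, weber_values) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (spec$background <= 0) stop("background luminance must be positive")
  lapply(weber_values, function(wb) {
    lum <- spec$background * (1 + wb)
    if (lum < 0 || lum > 1) {
      stop(sprintf("Weber contrast %+g implies object luminance %.3g outside [0, 1]",
                   wb, lum))
    }
    out <- spec
    out$object_luminance <- lum
    out$weber_contrast <- wb
    out
  })
}

#' Read an image-sequence directory
#'
#' Reads a directory of PNG or TIFF frames (sorted by file name) into a
#' [frame_sequence()]. Colour frames are converted to luminance with Rec. 601
#' weights (0.299 R + 0.587 G + 0.114 B). Video containers are not supported;
#' decode them to an image sequence first.
#'
#' @param path directory containing `.png` or `.tif/.tiff` files.
#' @param fps frame rate to record (default 30).
#' @return a [frame_sequence()].
#' @export
read_sequence <- function(path, fps = 30) {
  if (!dir.exists(path)) {
    if (file.exists(path)) {
      stop("video containers are not supported; provide a PNG/TIFF image-sequence directory")
    }
    stop("no such directory: ", path)
  }
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) stop("no PNG/TIFF frames found in ", path)
  frames <- lapply(files, function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
           else tiff::readTIFF(f)
    to_luminance(img)
  })
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1L) stop("mixed frame sizes in ", path)
  frame_sequence(frames, fps = fps, source = path)
}

to_luminance <- function(img) {
  if (length(dim(img)) == 2L) return(img)
  ch <- dim(img)[3]
  if (ch >= 3L) {
    0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  } else {
    img[, , 1]
  }
}

#' Write a frame sequence to an image-sequence directory
#'
#' @param seq a [frame_sequence()].
#' @param path output directory (created if needed).
#' @param format `"png"` (8-bit) or `"tiff"` (16-bit).
#' @return invisibly, the written file names.
#' @export
write_sequence <- function(seq, path, format = c("png", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(seq, "frame_sequence"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  tn <- dim(seq$frames)[3]
  files <- file.path(path, sprintf("frame_%05d.%s", seq_len(tn),
                                   ifelse(format == "png", "png", "tif")))
  for (t in seq_len(tn)) {
    if (format == "png") {
      png::writePNG(seq$frames[, , t], files[t])
    } else {
      tiff::writeTIFF(seq$frames[, , t], files[t], bits.per.sample = 16L)
    }
  }
  invisible(files)
}
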