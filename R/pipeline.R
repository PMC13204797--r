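#' Full pipeline configuration
#'
#' Bundles the per-stage parameter objects; every knob of the system lives in
#' exactly one of them.
#'
#' @param frontend a [frontend_params()].
#' @param lptc an [lptc_params()].
#' @param contour a [contour_params()].
#' @param decision a [decision_params()].
#' @return object of class `loom_config`.
#' @export
loom_config <- function(frontend = frontend_params(), lptc = lptc_params(),
                        contour = contour_params(),
                        decision = decision_params()) {
  structure(list(frontend = frontend, lptc = lptc, contour = contour,
                 decision = decision), class = "loom_config")
}

#' Detect looming collisions in a frame sequence
#'
#' Runs the full motion-contour-guided cascade: frontend filtering (retina,
#' lamina, medulla), LPTC population responses, motion mask and dominant
#' region, geodesic-active-contour boundary extraction (warm-started from the
#' previous frame when the dominant region moved less than
#' `contour$warm_start_dist` px), population decoding of speed along the
#' masked field, the motion-flux line integral, and the windowed alarm rule.
#'
#' @param seq a [frame_sequence()] (or `[H, W, T]` array).
#' @param table a calibrated `tuning_table` (see [calibrate_tuning()]).
#' @param config a [loom_config()].
#' @param gt optional `ground_truth` from [render_scene()]; enables the
#'   event-level outcome.
#' @param keep_contours store per-frame contours (default `TRUE`).
#' @param verbose print per-frame progress to stderr.
#' @return object of class `loom_detect` with elements
#'   \describe{
#'     \item{flux}{per-frame motion flux `Phi(t)` (`NA` where no contour)}
#'     \item{dphi}{flux increments `DeltaPhi(t)`}
#'     \item{alarm}{an `alarm_trace`; `warning_frame` is its first warning}
#'     \item{contours}{list of `target_contour` (when kept)}
#'     \item{frame_info}{data frame of per-frame status}
#'     \item{event}{event-level result when `gt` supplied}
#'   }
#' @seealso [warning_metrics()], [sensitivity_sweep()]
#' @export
loom_detect <- function(seq, table, config = loom_config(), gt = NULL,
                        keep_contours = TRUE, verbose = FALSE) {
  a <- if (inherits(seq, "frame_sequence")) seq$frames else seq
  d <- dim(a)
  tn <- d[3]
  ch <- run_frontend(a, config$frontend)
  lp <- config$lptc; cp <- config$contour
  flux <- rep(NA_real_, tn)
  status <- character(tn)
  region_size <- integer(tn)
  cx <- rep(NA_real_, tn); cy <- rep(NA_real_, tn)
  contours <- if (keep_contours) vector("list", tn) else NULL
  prev_ls <- NULL
  prev_centroid <- NULL
  t0 <- Sys.time()
  prev_radius <- NULL
  for (t in seq_len(tn)) {
    lf <- lptc_frame(ch, t, lp)
    # response-floor gate: sub-floor frames carry no decodable motion and
    # must not seed the contour stage
    if (max(lf$rmax) < table$floor) {
      status[t] <- "no_motion"
      prev_ls <- NULL; prev_centroid <- NULL; prev_radius <- NULL
      next
    }
    mm <- motion_mask(lf$r, lp$mask_factor)
    if (mm$empty) {
      status[t] <- "no_motion"
      prev_ls <- NULL; prev_centroid <- NULL; prev_radius <- NULL
      next
    }
    region_size[t] <- mm$region_size
    cx[t] <- mm$centroid[1]; cy[t] <- mm$centroid[2]
    g <- edge_indicator(ch$p[, , t], cp$sigma2, cp$intensity_scale)
    fresh <- tryCatch(initialize_levelset(mm$region, params = cp, g = g),
                      error = function(e) NULL)
    if (is.null(fresh)) {
      status[t] <- "init_failed"
      prev_ls <- NULL; prev_centroid <- NULL; prev_radius <- NULL
      next
    }
    # optional warm start, only while the previous front stays within the
    # edge indicator's capture range of the current motion band
    ls <- fresh
    if (isTRUE(cp$warm_start) && !is.null(prev_ls) && !is.null(prev_centroid) &&
        sqrt(sum((mm$centroid - prev_centroid)^2)) < cp$warm_start_dist &&
        !is.null(prev_radius) && abs(fresh$radius - prev_radius) < 4) {
      ls <- prev_ls
    }
    ev <- evolve_contour(ls, g, cp)
    if (identical(ev$status, "collapsed")) {
      status[t] <- "collapsed"
      prev_ls <- NULL; prev_centroid <- NULL; prev_radius <- NULL
      next
    }
    con <- extract_polyline(ev, center = mm$centroid)
    if (identical(con$status, "empty")) {
      status[t] <- "empty_contour"
      prev_ls <- NULL; prev_centroid <- NULL; prev_radius <- NULL
      next
    }
    # decode the velocity field wherever the population response clears the
    # per-frame relative floor (scale-free, so decode validity does not
    # depend on stimulus contrast; the absolute calibration floor gates the
    # whole frame above). Eq.-18's relative mask drives segregation and
    # initialisation; the floor drives decode validity — see vignette.
    nr <- d[1]
    rel_floor <- lp$floor_frac * max(lf$rmax)
    valid <- lf$rmax >= rel_floor
    ridx <- which(valid)
    rmat <- matrix(lf$r, nr * d[2], dim(lf$r)[3])[ridx, , drop = FALSE]
    vdec <- decode_velocity(rmat, table, floor = rel_floor)
    vgrid <- matrix(0, nr, d[2])
    vgrid[ridx] <- vdec
    vx <- vgrid * cos(lf$theta_motion)
    vy <- vgrid * sin(lf$theta_motion)
    flux[t] <- motion_flux(con, vx, vy, valid)
    status[t] <- "ok"
    if (keep_contours) contours[[t]] <- con
    ev$status <- "warm_start"
    prev_ls <- ev
    prev_centroid <- mm$centroid
    prev_radius <- sqrt(max(con$area, 0) / pi)
    if (verbose) {
      message(sprintf("frame %3d: %s region=%d flux=%.2f", t, status[t],
                      region_size[t], flux[t]))
    }
  }
  dphi <- flux_dynamics(flux)
  dp <- config$decision
  # alarms suppressed for the longest temporal-kernel length + Ncon frames
  if (is.na(dp$warmup)) dp$warmup <- ch$kernel_max + dp$n_con
  at <- alarm_trace(dphi, dp)
  event <- NULL
  if (!is.null(gt)) event <- event_result(at$first_warning, gt)
  structure(list(flux = flux, dphi = dphi, alarm = at,
                 warning_frame = at$first_warning,
                 contours = contours,
                 frame_info = data.frame(frame = seq_len(tn), status = status,
                                         region_size = region_size,
                                         centroid_x = cx, centroid_y = cy,
                                         flux = flux, dphi = dphi,
                                         alarm = at$alarm),
                 event = event, config = config, warmup = dp$warmup,
                 n_frames = tn,
                 elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
            class = "loom_detect")
}

# event-level outcome against ground truth
event_result <- function(warning_frame, gt, id = NA_character_) {
  col <- gt$collision_frame %||% NA_integer_
  if (length(col) != 1) col <- NA_integer_
  looming <- !is.na(col)
  outcome <- if (looming) {
    if (!is.na(warning_frame) && warning_frame < col) "hit" else "missed"
  } else {
    if (!is.na(warning_frame)) "false-alarm" else "correct-reject"
  }
  lead <- if (looming && !is.na(warning_frame)) col - warning_frame else NA_real_
  area_at_warning <- if (!is.na(warning_frame) &&
                         warning_frame <= length(gt$relative_area)) {
    100 * gt$relative_area[warning_frame]
  } else NA_real_
  list(id = id, collision_frame = col, warning_frame = warning_frame,
       lead_time = lead, area_at_warning = area_at_warning,
       speed_class = gt$speed_class, outcome = outcome)
}

#' @export
print.loom_detect <- function(x, ...) {
  ok <- sum(x$frame_info$status == "ok")
  cat(sprintf("<loom_detect> %d frames (%d with contour); warm-up %d frames\n",
              x$n_frames, ok, x$warmup))
  if (is.na(x$warning_frame)) {
    cat("  no collision warning issued\n")
  } else {
    cat(sprintf("  first collision warning at frame %d\n", x$warning_frame))
  }
  if (!is.null(x$event)) {
    cat(sprintf("  outcome: %s (collision frame %s, lead %s frames)\n",
                x$event$outcome,
                ifelse(is.na(x$event$collision_frame), "n/a",
                       x$event$collision_frame),
                ifelse(is.na(x$event$lead_time), "n/a", x$event$lead_time)))
  }
  invisible(x)
}

#' @export
summary.loom_detect <- function(object, ...) {
  fi <- object$frame_info
  cat(sprintf("Frames: %d  contour ok: %d  no-motion: %d  collapsed/empty: %d\n",
              nrow(fi), sum(fi$status == "ok"), sum(fi$status == "no_motion"),
              sum(fi$status %in% c("collapsed", "empty_contour", "init_failed"))))
  v <- fi$flux[!is.na(fi$flux)]
  if (length(v)) {
    cat(sprintf("Flux: mean %.2f sd %.2f range [%.2f, %.2f] px^2/frame\n",
                mean(v), stats::sd(v), min(v), max(v)))
  }
  print(object)
  invisible(object)
}

#' @export
plot.loom_detect <- function(x, gt = NULL, ...) {
  t <- seq_len(x$n_frames)
  plot(t, x$flux, type = "l", lwd = 2, xlab = "frame",
       ylab = expression(Phi(t) ~ (px^2 / frame)),
       main = "Motion flux along the target contour", ...)
  graphics::abline(h = 0, col = "grey70")
  if (!is.na(x$warning_frame)) {
    graphics::abline(v = x$warning_frame, col = "blue", lwd = 2)
  }
  col <- if (!is.null(gt)) gt$collision_frame else
    if (!is.null(x$event)) x$event$collision_frame else NA
  if (!is.na(col %||% NA)) graphics::abline(v = col, col = "darkgreen", lwd = 2)
  invisible(x)
}

#' Write per-frame and summary outputs
#'
#' Emits the per-frame trace as CSV (frame, flux, increments, windowed
#' statistic, alarm state, contour area) and a JSON summary (warning frame,
#' collision frame, lead time, resolved configuration).
#'
#' @param x a `loom_detect` result.
#' @param dir output directory.
#' @param id stimulus identifier used in file names.
#' @return invisibly, the file paths.
#' @export
write_results <- function(x, dir, id = "run") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fi <- x$frame_info
  fi$contour_area <- vapply(seq_len(nrow(fi)), function(t) {
    if (!is.null(x$contours) && !is.null(x$contours[[t]])) {
      x$contours[[t]]$area
    } else NA_real_
  }, numeric(1))
  csv <- file.path(dir, paste0(id, "_frames.csv"))
  utils::write.csv(fi, csv, row.names = FALSE)
  js <- file.path(dir, paste0(id, "_summary.json"))
  jsonlite::write_json(list(
    id = id,
    warning_frame = x$warning_frame,
    event = x$event,
    warmup = x$warmup,
    config = unclass_config(x$config)
  ), js, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(c(csv, js))
}

unclass_config <- function(cfg) {
  lapply(unclass(cfg), function(p) {
    p <- unclass(p)
    p[!vapply(p, is.function, logical(1))]
  })
}

#' Evaluation metrics over a set of events
#'
#' Computes the four headline metrics: mean Area at Warning (% of the field
#' of view occupied at the warning frame), mean Warning Lead Time (frames),
#' Coefficient of Variation of warning times across contrast-matched events
#' (100 x population standard deviation / mean, computed within each contrast
#' group then averaged), and Error Rate (missed + false alarms as a
#' percentage of all events).
#'
#' @param events list of event results (from `loom_detect()$event`).
#' @param groups optional character/factor vector assigning contrast-matched
#'   events to groups; CV is computed within groups with >= 2 warnings.
#' @return object of class `metric_summary`.
#' @export
warning_metrics <- function(events, groups = NULL) {
  keep <- !vapply(events, is.null, logical(1))
  if (!all(keep)) {
    message(sum(!keep), " event(s) without ground truth excluded")
    events <- events[keep]
    if (!is.null(groups)) groups <- groups[keep]
  }
  if (length(events) == 0L) stop("no events with ground truth to summarise")
  num1 <- function(x) if (is.null(x) || length(x) != 1 || !is.finite(as.numeric(x))) NA_real_ else as.numeric(x)
  lead <- vapply(events, function(e) num1(e$lead_time), numeric(1))
  area <- vapply(events, function(e) num1(e$area_at_warning), numeric(1))
  outc <- vapply(events, function(e) as.character(e$outcome %||% NA), character(1))
  warn <- vapply(events, function(e) num1(e$warning_frame), numeric(1))
  err <- 100 * sum(outc %in% c("missed", "false-alarm")) / length(events)
  cv <- NA_real_
  rng <- NA_real_
  if (!is.null(groups)) {
    cvs <- c(); rngs <- c()
    for (gname in unique(groups)) {
      wt <- warn[groups == gname]
      wt <- wt[!is.na(wt)]
      if (length(wt) >= 2) {
        sd_pop <- sqrt(mean((wt - mean(wt))^2))
        cvs <- c(cvs, 100 * sd_pop / mean(wt))
        rngs <- c(rngs, max(wt) - min(wt))
      } else {
        message("CV undefined for group '", gname, "' (fewer than 2 warnings); excluded")
      }
    }
    if (length(cvs)) { cv <- mean(cvs); rng <- mean(rngs) }
  }
  structure(list(mean_area_at_warning = mean(area, na.rm = TRUE),
                 mean_lead_time = mean(lead, na.rm = TRUE),
                 cv_warning_times = cv,
                 consistency_range = rng,
                 error_rate = err,
                 n_events = length(events),
                 outcomes = table(outc),
                 cv_definition = "population standard deviation"),
            class = "metric_summary")
}

#' @export
print.metric_summary <- function(x, ...) {
  cat("<metric_summary>\n")
  cat(sprintf("  events: %d (%s)\n", x$n_events,
              paste(names(x$outcomes), x$outcomes, sep = "=", collapse = ", ")))
  cat(sprintf("  mean area at warning: %.3f %%\n", x$mean_area_at_warning))
  cat(sprintf("  mean warning lead time: %.3f frames\n", x$mean_lead_time))
  cat(sprintf("  CV of warning times: %s %%\n",
              ifelse(is.na(x$cv_warning_times), "n/a",
                     sprintf("%.3f", x$cv_warning_times))))
  cat(sprintf("  warning-time range: %s frames\n",
              ifelse(is.na(x$consistency_range), "n/a",
                     sprintf("%.1f", x$consistency_range))))
  cat(sprintf("  error rate: %.3f %%\n", x$error_rate))
  invisible(x)
}

#' Decision-parameter sensitivity sweep
#'
#' Re-evaluates the alarm rule over a grid of `(Ncon, xi_th)` settings on a
#' set of already-processed runs (the flux pipeline does not depend on the
#' decision parameters, so each run is processed once and the decision rule
#' is re-applied per grid cell). Reports, per cell, the mean safety margin
#' (frames between warning and collision; a missed looming event counts 0)
#' per speed class, and the warning-time fluctuation (max - min, frames)
#' across contrast-matched groups.
#'
#' @param runs list of `loom_detect` results, each with ground truth attached.
#' @param gts list of matching `ground_truth` objects.
#' @param n_con_values,xi_values grids of decision parameters.
#' @param speed_class character vector labelling each run's speed class
#'   (defaults to the ground-truth class).
#' @param groups optional contrast-group labels for the fluctuation metric.
#' @param rule decision rule (see [decision_params()]).
#' @return data frame with one row per grid cell and speed class:
#'   `n_con`, `xi_th`, `speed_class`, `mean_margin`, `n_warned`, `n_events`,
#'   `fluctuation`.
#' @export
sensitivity_sweep <- function(runs, gts,
                              n_con_values = c(2L, 4L, 6L),
                              xi_values = c(2.5, 3.5, 4.5),
                              speed_class = NULL, groups = NULL,
                              rule = c("persistence", "windowed_sum")) {
  rule <- match.arg(rule)
  stopifnot(length(runs) == length(gts))
  if (is.null(speed_class)) {
    speed_class <- vapply(gts, function(g) g$speed_class, character(1))
  }
  rows <- list()
  for (nc in n_con_values) {
    for (xi in xi_values) {
      warn <- vapply(seq_along(runs), function(i) {
        dp <- decision_params(n_con = nc, xi_th = xi, rule = rule,
                              warmup = runs[[i]]$warmup)
        as.numeric(alarm_trace(runs[[i]]$dphi, dp)$first_warning)
      }, numeric(1))
      margin <- vapply(seq_along(runs), function(i) {
        col <- gts[[i]]$collision_frame
        if (is.na(col)) return(NA_real_)
        if (is.na(warn[i]) || warn[i] >= col) return(0)  # miss: zero margin
        col - warn[i]
      }, numeric(1))
      fluct <- NA_real_
      if (!is.null(groups)) {
        f <- c()
        for (gname in unique(groups)) {
          wt <- warn[groups == gname]
          wt <- wt[!is.na(wt)]
          if (length(wt) >= 2) f <- c(f, max(wt) - min(wt))
        }
        if (length(f)) fluct <- mean(f)
      }
      for (scl in unique(speed_class)) {
        sel <- speed_class == scl & !is.na(margin)
        rows[[length(rows) + 1L]] <- data.frame(
          n_con = nc, xi_th = xi, speed_class = scl,
          mean_margin = if (any(sel)) mean(margin[sel]) else NA_real_,
          n_warned = sum(!is.na(warn[sel]) & warn[sel] > 0),
          n_events = sum(sel), fluctuation = fluct)
      }
    }
  }
  do.call(rbind, rows)
}
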