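#' Collision-decision parameters
#'
#' The alarm fires when the temporal dynamics of the motion flux exceed the
#' critical expansion threshold persistently. Defaults are the published
#' operating point `Ncon = 4`, `xi_th = 3.5`.
#'
#' Two decision rules are provided. `"persistence"` (default) requires every
#' flux increment in the window `t - Ncon .. t` to exceed `xi_th`
#' individually — the "continuously exceed for a persistent window" reading,
#' which is robust to transient flux swings. `"windowed_sum"` requires the
#' summed increments over the window to exceed `xi_th`; the sum telescopes to
#' `Phi(t) - Phi(t - Ncon - 1)`, so any transient flux jump can fire it, and
#' on an accelerating flux a *larger* window fires *earlier*. See the package
#' vignette for why persistence is the default.
#'
#' @param n_con consecutive-frame window (the window holds `n_con + 1`
#'   increments, `t - n_con .. t`).
#' @param xi_th critical expansion threshold, px^2/frame.
#' @param rule `"persistence"` or `"windowed_sum"`.
#' @param warmup frames at the start of the clip during which alarms are
#'   suppressed (`NA` = filter latency + `n_con`, resolved by the pipeline).
#' @return object of class `decision_params`.
#' @export
decision_params <- function(n_con = 4L, xi_th = 3.5,
                            rule = c("persistence", "windowed_sum"),
                            warmup = NA_integer_) {
  if (n_con < 1) stop("n_con must be >= 1")
  structure(list(n_con = as.integer(n_con), xi_th = xi_th,
                 rule = match.arg(rule), warmup = warmup),
            class = "decision_params")
}

#' Motion flux along the target contour
#'
#' The line integral of the outward-normal velocity component along the
#' extracted contour: `Phi = sum_k (U_k . n_k) dl_k`, with the local velocity
#' `U = v (cos theta, sin theta)` sampled bilinearly from the decoded field
#' at each vertex. Vertices where the motion mask is 0 (nearest-neighbour
#' sample) contribute 0. A positive flux signifies net outward boundary
#' motion (expansion); contraction yields negative flux; a uniform
#' translational field integrates to ~0 around a closed contour (divergence
#' theorem).
#'
#' @param contour a `target_contour` (see [extract_polyline()]).
#' @param vx,vy decoded velocity component grids (px/frame), e.g.
#'   `v * cos(theta_motion)` and `v * sin(theta_motion)`.
#' @param mask logical motion-mask matrix (optional; omitted = all valid).
#' @return scalar flux, px^2/frame, or `NA` for an empty contour.
#' @export
motion_flux <- function(contour, vx, vy, mask = NULL) {
  if (identical(contour$status, "empty") || is.null(contour$xy)) {
    return(NA_real_)
  }
  x <- contour$xy[, 1]; y <- contour$xy[, 2]
  ux <- sample_bilinear(vx, x, y, rule = "fill", fill = 0)
  uy <- sample_bilinear(vy, x, y, rule = "fill", fill = 0)
  w <- rep(1, length(x))
  if (!is.null(mask)) {
    mi <- cbind(pmin(pmax(round(y), 1L), nrow(mask)),
                pmin(pmax(round(x), 1L), ncol(mask)))
    w <- as.numeric(mask[mi])
  }
  sum(w * (ux * contour$normal[, 1] + uy * contour$normal[, 2]) * contour$dl)
}

#' Temporal dynamics of the motion flux
#'
#' First differences `DeltaPhi(t) = Phi(t) - Phi(t-1)` over consecutive valid
#' frames. Invalid frames (no contour) break the difference chain: both
#' differences adjacent to a gap are undefined (`NA`), never spanned.
#'
#' @param phi numeric vector of per-frame flux values (`NA` = invalid frame).
#' @return numeric vector of the same length; element `t` is
#'   `Phi(t) - Phi(t-1)` where both are valid, else `NA` (element 1 is
#'   always `NA`).
#' @export
flux_dynamics <- function(phi) {
  n <- length(phi)
  d <- rep(NA_real_, n)
  if (n >= 2) {
    d[2:n] <- phi[2:n] - phi[1:(n - 1)]
  }
  d
}

#' Collision alarm trace
#'
#' Evaluates the windowed decision rule on the flux-increment stream. With
#' the `"persistence"` rule, `A_col(t)` is true iff every increment in
#' `t - Ncon .. t` exceeds `xi_th`; with `"windowed_sum"`, iff the increments
#' sum above `xi_th`. In both rules every window entry must be valid (a
#' window containing an invalid frame yields false), and alarms are
#' suppressed during the warm-up.
#'
#' @param dphi numeric vector of flux increments (`NA` = invalid).
#' @param params a [decision_params()]; its `warmup` must be resolved (use
#'   `warmup = 0` for a bare stream).
#' @return object of class `alarm_trace`: logical vector `alarm`,
#'   `first_warning` (frame index or `NA`), `params`.
#' @export
alarm_trace <- function(dphi, params = decision_params(warmup = 0L)) {
  n <- length(dphi)
  warm <- params$warmup
  if (is.na(warm)) warm <- 0L
  alarm <- rep(FALSE, n)
  span <- params$n_con  # window t - n_con .. t
  for (t in seq_len(n)) {
    if (t <= warm + span) next
    w <- dphi[(t - span):t]
    if (anyNA(w)) next
    alarm[t] <- if (params$rule == "windowed_sum") sum(w) > params$xi_th
                else all(w > params$xi_th)
  }
  first <- if (any(alarm)) which(alarm)[1] else NA_integer_
  structure(list(alarm = alarm, first_warning = first, params = params),
            class = "alarm_trace")
}

#' @export
print.alarm_trace <- function(x, ...) {
  cat(sprintf("<alarm_trace> %d frames, rule=%s Ncon=%d xi=%.3g; first warning: %s\n",
              length(x$alarm), x$params$rule, x$params$n_con, x$params$xi_th,
              ifelse(is.na(x$first_warning), "none", x$first_warning)))
  invisible(x)
}
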