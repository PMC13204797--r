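# Shared fixtures, computed lazily and cached for the whole test run.
# Everything is generated in code; no data files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small tuning table shared across LPTC/pipeline tests (full default grid)
test_tuning_table <- function() {
  fixture("tuning_table", function() calibrate_tuning())
}

# canonical looming-disc scene used by several end-to-end tests
test_loom_scene <- function() {
  fixture("loom_scene", function() {
    spec <- stimulus_spec("loom", background = 0.5, object_luminance = 0.9,
                          width = 160, height = 120, n_frames = 120,
                          radius0 = 8, collision_frame = 110)
    render_scene(spec, keep_masks = TRUE)
  })
}

test_loom_result <- function() {
  fixture("loom_result", function() {
    sc <- test_loom_scene()
    loom_detect(sc$seq, test_tuning_table(), gt = sc$gt,
                keep_contours = FALSE)
  })
}

# rasterised disc frame (luminance 1 on 0) plus geometry
disc_frame <- function(h = 100, w = 120, cx = 60, cy = 50, R = 20) {
  f <- loomcontour:::rasterise_star(h, w, cx, cy, R,
                                    function(a) rep(1, length(a)))
  list(frame = f, cx = cx, cy = cy, R = R, h = h, w = w)
}

# analytic signed-distance level set of a circle
circle_levelset <- function(h, w, cx, cy, R) {
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  Y <- matrix(seq_len(h), h, w)
  phi <- sqrt((X - cx)^2 + (Y - cy)^2) - R
  structure(list(phi = phi, center = c(cx, cy), radius = R,
                 iterations = 0L, converged = FALSE, status = "initialized"),
            class = "level_set")
}

# radial / uniform velocity fields around a centre
radial_field <- function(h, w, cx, cy, speed = 1, outward = TRUE) {
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  Y <- matrix(seq_len(h), h, w)
  dx <- X - cx; dy <- Y - cy
  d <- sqrt(dx^2 + dy^2); d[d == 0] <- 1
  s <- if (outward) speed else -speed
  list(vx = s * dx / d, vy = s * dy / d)
}
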