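# Shared fixture builders (all fixtures are generated in code).

PITCH <- 3 / 304

semicircle_spec <- function(r_mm, theta0 = pi / 6, width_mm = 0.05,
                            class = "artery", n = 300) {
  centerline_spec("circular_arc", center = c(0, 0), radius = r_mm,
                  theta0 = theta0, theta1 = theta0 + pi,
                  width_mm = width_mm, vessel_class = class, n_samples = n)
}

# Rasterize one spec and return its longest extracted track.
longest_track <- function(spec, shape = c(304L, 304L), pitch = PITCH) {
  ras <- rasterize_specs(list(spec), shape = shape, pixel_pitch_mm = pitch)
  sk <- skeletonize(binary_mask(ras$map, "all"))
  tks <- extract_tracks(skeleton_graph(sk), min_length = 11, map = ras$map)
  tks[[which.max(vapply(tks, function(t) t$n, numeric(1)))]]
}

# A small random phantom (1-3 curves) for property sweeps.
random_phantom <- function(shape = c(160L, 160L), pitch = 3 / 160) {
  n_curves <- sample(1:3, 1)
  specs <- lapply(seq_len(n_curves), function(i) {
    cls <- sample(c("artery", "vein"), 1)
    kind <- sample(c("line", "circular_arc", "sinusoid"), 1)
    w <- runif(1, 0.04, 0.08)
    if (kind == "line") {
      ang <- runif(1, 0, 2 * pi)
      u <- c(cos(ang), sin(ang))
      mid <- runif(2, -0.3, 0.3)
      l <- runif(1, 0.8, 1.2)
      centerline_spec("line", p0 = mid - u * l / 2, p1 = mid + u * l / 2,
                      width_mm = w, vessel_class = cls, n_samples = 150)
    } else if (kind == "circular_arc") {
      r <- runif(1, 0.4, 0.9)
      th0 <- runif(1, 0, 2 * pi)
      centerline_spec("circular_arc", center = runif(2, -0.2, 0.2),
                      radius = r, theta0 = th0,
                      theta1 = th0 + runif(1, 1.5, 3),
                      width_mm = w, vessel_class = cls, n_samples = 250)
    } else {
      ang <- runif(1, 0, 2 * pi)
      u <- c(cos(ang), sin(ang))
      mid <- runif(2, -0.2, 0.2)
      l <- runif(1, 0.8, 1.2)
      centerline_spec("sinusoid", p0 = mid - u * l / 2, p1 = mid + u * l / 2,
                      amplitude = runif(1, 0, 0.08),
                      frequency = runif(1, 0.5, 2.5),
                      phase = runif(1, 0, 2 * pi),
                      width_mm = w, vessel_class = cls, n_samples = 150)
    }
  })
  rasterize_specs(specs, shape = shape, pixel_pitch_mm = pitch)
}

gauss_smooth_pts <- function(v, sigma) vesselmetrics:::gauss_smooth(v, sigma)
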