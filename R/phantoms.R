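#' Specify a parametric vessel centerline
#'
#' Centerlines are smooth planar curves in mm coordinates (origin at the
#' field center, x to image-right, y to image-up/superior). Four families
#' are supported:
#' \describe{
#'   \item{line}{segment `p0` to `p1`.}
#'   \item{circular_arc}{`center`, `radius`, angles `theta0` to `theta1`
#'     (radians, counterclockwise from +x).}
#'   \item{sinusoid}{baseline `p0` to `p1` displaced along its normal by
#'     `amplitude * sin(2*pi*frequency*s + phase)`, `s` = distance along
#'     the baseline (mm), `frequency` in cycles/mm.}
#'   \item{cubic_bezier}{`control`, a 4x2 matrix of control points.}
#' }
#'
#' @param kind One of `"line"`, `"circular_arc"`, `"sinusoid"`,
#'   `"cubic_bezier"`.
#' @param width_mm Vessel caliber (full width), mm; must be positive.
#' @param vessel_class `"artery"` or `"vein"`.
#' @param n_samples Number of discretization points (>= 2).
#' @param p0,p1,center,radius,theta0,theta1,amplitude,frequency,phase,control
#'   Per-kind geometry parameters (see Description).
#' @return A `centerline_spec` object.
#' @export
centerline_spec <- function(kind = c("line", "circular_arc", "sinusoid",
                                     "cubic_bezier"),
                            width_mm, vessel_class = c("artery", "vein"),
                            n_samples = 200,
                            p0 = NULL, p1 = NULL,
                            center = NULL, radius = NULL,
                            theta0 = NULL, theta1 = NULL,
                            amplitude = NULL, frequency = NULL, phase = 0,
                            control = NULL) {
  kind <- match.arg(kind)
  vessel_class <- match.arg(vessel_class)
  if (!is.numeric(width_mm) || width_mm <= 0)
    stop("width_mm must be positive")
  if (n_samples < 2) stop("n_samples must be at least 2")
  params <- switch(kind,
    line = {
      if (length(p0) != 2 || length(p1) != 2)
        stop("line needs 2-vectors p0, p1")
      if (sqrt(sum((p1 - p0)^2)) <= 0) stop("degenerate line: p0 == p1")
      list(p0 = p0, p1 = p1)
    },
    circular_arc = {
      if (length(center) != 2 || !is.numeric(radius) || radius <= 0 ||
          !is.numeric(theta0) || !is.numeric(theta1))
        stop("circular_arc needs center, radius > 0, theta0, theta1")
      if (abs(theta1 - theta0) <= 0) stop("degenerate arc: zero span")
      list(center = center, radius = radius, theta0 = theta0, theta1 = theta1)
    },
    sinusoid = {
      if (length(p0) != 2 || length(p1) != 2 || amplitude < 0 ||
          frequency < 0)
        stop("sinusoid needs p0, p1, amplitude >= 0, frequency >= 0")
      if (sqrt(sum((p1 - p0)^2)) <= 0) stop("degenerate sinusoid baseline")
      list(p0 = p0, p1 = p1, amplitude = amplitude, frequency = frequency,
           phase = phase)
    },
    cubic_bezier = {
      if (!is.matrix(control) || nrow(control) != 4 || ncol(control) != 2)
        stop("cubic_bezier needs a 4 x 2 control matrix")
      list(control = control)
    })
  structure(list(kind = kind, params = params, width_mm = width_mm,
                 vessel_class = vessel_class,
                 n_samples = as.integer(n_samples)),
            class = "centerline_spec")
}

# Evaluate position and first/second parametric derivatives at t in [0, 1].
# Returns a list of vectors x, y, dx, dy, ddx, ddy (length(t) each).
curve_eval <- function(spec, t) {
  p <- spec$params
  switch(spec$kind,
    line = {
      d <- p$p1 - p$p0
      list(x = p$p0[1] + t * d[1], y = p$p0[2] + t * d[2],
           dx = rep(d[1], length(t)), dy = rep(d[2], length(t)),
           ddx = rep(0, length(t)), ddy = rep(0, length(t)))
    },
    circular_arc = {
      span <- p$theta1 - p$theta0
      th <- p$theta0 + t * span
      r <- p$radius
      list(x = p$center[1] + r * cos(th), y = p$center[2] + r * sin(th),
           dx = -r * sin(th) * span, dy = r * cos(th) * span,
           ddx = -r * cos(th) * span^2, ddy = -r * sin(th) * span^2)
    },
    sinusoid = {
      d <- p$p1 - p$p0
      B <- sqrt(sum(d^2))
      u <- d / B
      nrm <- c(-u[2], u[1])
      w <- 2 * pi * p$frequency * B          # angular rate in t
      ph <- w * t + p$phase
      a <- p$amplitude
      list(x = p$p0[1] + t * B * u[1] + a * sin(ph) * nrm[1],
           y = p$p0[2] + t * B * u[2] + a * sin(ph) * nrm[2],
           dx = B * u[1] + a * w * cos(ph) * nrm[1],
           dy = B * u[2] + a * w * cos(ph) * nrm[2],
           ddx = -a * w^2 * sin(ph) * nrm[1],
           ddy = -a * w^2 * sin(ph) * nrm[2])
    },
    cubic_bezier = {
      P <- p$control
      b0 <- (1 - t)^3; b1 <- 3 * (1 - t)^2 * t
      b2 <- 3 * (1 - t) * t^2; b3 <- t^3
      d0 <- 3 * (1 - t)^2; d1 <- 6 * (1 - t) * t; d2 <- 3 * t^2
      e0 <- 6 * (1 - t); e1 <- 6 * t
      list(
        x = b0 * P[1, 1] + b1 * P[2, 1] + b2 * P[3, 1] + b3 * P[4, 1],
        y = b0 * P[1, 2] + b1 * P[2, 2] + b2 * P[3, 2] + b3 * P[4, 2],
        dx = d0 * (P[2, 1] - P[1, 1]) + d1 * (P[3, 1] - P[2, 1]) +
          d2 * (P[4, 1] - P[3, 1]),
        dy = d0 * (P[2, 2] - P[1, 2]) + d1 * (P[3, 2] - P[2, 2]) +
          d2 * (P[4, 2] - P[3, 2]),
        ddx = e0 * (P[3, 1] - 2 * P[2, 1] + P[1, 1]) +
          e1 * (P[4, 1] - 2 * P[3, 1] + P[2, 1]),
        ddy = e0 * (P[3, 2] - 2 * P[2, 2] + P[1, 2]) +
          e1 * (P[4, 2] - 2 * P[3, 2] + P[2, 2])
      )
    })
}

# Map t -> arc length via a fine grid; returns list(t_grid, s_grid, total).
arc_length_table <- function(spec, m = 4001) {
  tg <- seq(0, 1, length.out = m)
  ev <- curve_eval(spec, tg)
  sp <- sqrt(ev$dx^2 + ev$dy^2)
  # trapezoid cumulative integral of speed
  ds <- (sp[-1] + sp[-m]) / 2 * diff(tg)
  s <- c(0, cumsum(ds))
  list(t = tg, s = s, total = s[m])
}

#' Sample a centerline at uniform arc-length spacing
#'
#' @param spec A `centerline_spec`.
#' @param n_samples Override of the spec's sample count.
#' @return An `n x 2` matrix of (x, y) mm coordinates.
#' @export
sample_centerline <- function(spec, n_samples = spec$n_samples) {
  stopifnot(inherits(spec, "centerline_spec"), n_samples >= 2)
  if (spec$kind == "line") {
    t <- seq(0, 1, length.out = n_samples)
  } else if (spec$kind == "circular_arc") {
    t <- seq(0, 1, length.out = n_samples)  # uniform angle == uniform arc
  } else {
    tab <- arc_length_table(spec, m = max(4001, 20L * n_samples))
    if (tab$total <= 1e-12) stop("degenerate curve: zero arc length")
    s_tgt <- seq(0, tab$total, length.out = n_samples)
    t <- stats::approx(tab$s, tab$t, xout = s_tgt, ties = "ordered")$y
  }
  ev <- curve_eval(spec, t)
  cbind(x = ev$x, y = ev$y)
}

#' Analytic ground truth for a centerline
#'
#' Computes arc length, chord length, the curvature profile, the total
#' squared curvature family, and the mean direction angle change directly
#' from the parametric form (by quadrature on the exact derivatives, and
#' for MDAC from exactly-sampled points) — never from a raster. These are
#' the reference values the raster pipeline is validated against.
#'
#' @param spec A `centerline_spec`.
#' @param mdac_step Index step for the MDAC ground truth (applied to the
#'   spec's `n_samples` uniform arc-length samples).
#' @param m Quadrature grid size.
#' @return A `phantom_truth` list: `arc_length_mm`, `chord_length_mm`,
#'   `curvature` (profile at the quadrature grid, 1/mm), `tsc`, `tsc_lx`,
#'   `tsc_lc`, `mdac`, `mdac_step`, `closed` (logical: chord-normalized
#'   values undefined).
#' @export
analytic_truth <- function(spec, mdac_step = 5, m = 4001) {
  stopifnot(inherits(spec, "centerline_spec"))
  tg <- seq(0, 1, length.out = m)
  ev <- curve_eval(spec, tg)
  sp2 <- ev$dx^2 + ev$dy^2
  sp <- sqrt(sp2)
  if (max(sp) <= 1e-12) stop("degenerate curve: zero arc length")
  kappa <- (ev$dx * ev$ddy - ev$dy * ev$ddx) / pmax(sp2^1.5, 1e-300)
  trap <- function(f) sum((f[-1] + f[-m]) / 2 * diff(tg))
  lc <- trap(sp)
  lx <- sqrt((ev$x[m] - ev$x[1])^2 + (ev$y[m] - ev$y[1])^2)
  tsc <- trap(kappa^2 * sp)
  closed <- lx < 1e-9
  pts <- sample_centerline(spec)
  md <- mdac_points(pts, step = mdac_step)
  structure(list(arc_length_mm = lc, chord_length_mm = lx,
                 curvature = kappa, tsc = tsc,
                 tsc_lx = if (closed) NA_real_ else tsc / lx,
                 tsc_lc = tsc / lc,
                 mdac = md, mdac_step = mdac_step, closed = closed),
            class = "phantom_truth")
}

# Convert mm coordinates to continuous pixel coordinates (row, col) where
# pixel (i, j), 1-based, has center (i - 0.5, j - 0.5).
mm_to_px <- function(xy, shape, pixel_pitch_mm) {
  cbind(r = shape[1] / 2 - xy[, 2] / pixel_pitch_mm,
        c = shape[2] / 2 + xy[, 1] / pixel_pitch_mm)
}

#' Rasterize centerline specs into an artery/vein label map
#'
#' Each centerline is painted as a ribbon: every pixel whose center lies
#' within `width_mm / 2` of the polyline (sampled at >= 2 points per pixel
#' of arc) is marked with the vessel class. Pixels painted by both an
#' artery and a vein become arteriovenous junctions (code 3). Optional
#' pixel dropout turns each painted pixel off independently, emulating
#' segmentation gaps.
#'
#' @param specs List of `centerline_spec`s.
#' @param shape Image shape `c(nrow, ncol)` (default 304 x 304).
#' @param pixel_pitch_mm Pixel pitch (default 3 mm / 304 px).
#' @param dropout Per-pixel dropout probability in \[0, 1).
#' @param seed Optional integer; if given, dropout is locally seeded so the
#'   call is reproducible in isolation.
#' @param laterality,eye_id Metadata for the resulting map.
#' @param mdac_step Step used for the per-curve MDAC truth.
#' @param compute_truth If `FALSE`, skip the analytic truth table (faster
#'   for large simulations).
#' @return List with `map` (a `vessel_label_map`) and `truth` (data.frame,
#'   one row per spec: class, width, analytic lengths/tortuosity, painted
#'   pixel count).
#' @export
rasterize_specs <- function(specs, shape = c(304L, 304L),
                            pixel_pitch_mm = 3 / 304, dropout = 0,
                            seed = NULL, laterality = "OS",
                            eye_id = "phantom", mdac_step = 5,
                            compute_truth = TRUE) {
  stopifnot(is.list(specs), pixel_pitch_mm > 0, dropout >= 0, dropout < 1)
  if (!all(vapply(specs, inherits, logical(1), "centerline_spec")))
    stop("specs must be a list of centerline_spec objects")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  art <- matrix(0L, nr, nc); vei <- matrix(0L, nr, nc)
  n_specs <- length(specs)
  painted_v <- integer(n_specs)
  truth <- if (compute_truth) vector("list", n_specs) else NULL
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    w_px <- sp$width_mm / pixel_pitch_mm
    if (w_px < 1)
      stop("vessel width ", sp$width_mm, " mm is below one pixel (",
           signif(w_px, 3), " px); increase width_mm or use a finer pitch")
    # polyline density: at least ~3 points per pixel of arc length.
    # Painting needs dense, not arc-length-uniform, sampling, so the
    # cheap parameter-uniform evaluation suffices (local spacing varies
    # by at most the ripple factor, which the 3x margin covers).
    lc_mm <- arc_length_table(sp, m = 201)$total
    n_pts <- max(sp$n_samples, ceiling(3 * lc_mm / pixel_pitch_mm) + 1)
    ev <- curve_eval(sp, seq(0, 1, length.out = n_pts))
    xy <- cbind(ev$x, ev$y)
    pc <- mm_to_px(xy, c(nr, nc), pixel_pitch_mm)
    if (any(pc < 0) || any(pc[, 1] > nr) || any(pc[, 2] > nc))
      stop("centerline ", i, " leaves the field of view")
    tgt <- if (sp$vessel_class == "artery") art else vei
    painted_v[i] <- cpp_paint_ribbon(tgt, pc[, 1], pc[, 2], w_px / 2, 1L)
    if (compute_truth) {
      tr <- analytic_truth(sp, mdac_step = mdac_step)
      truth[[i]] <- data.frame(
        curve = i, kind = sp$kind, vessel_class = sp$vessel_class,
        width_mm = sp$width_mm, arc_length_mm = tr$arc_length_mm,
        chord_length_mm = tr$chord_length_mm, tsc = tr$tsc,
        tsc_lx = tr$tsc_lx, tsc_lc = tr$tsc_lc, mdac = tr$mdac,
        painted_px = painted_v[i])
    }
  }
  if (!compute_truth) {
    truth_df <- data.frame(
      curve = seq_len(n_specs),
      kind = vapply(specs, function(s) s$kind, character(1)),
      vessel_class = vapply(specs, function(s) s$vessel_class, character(1)),
      width_mm = vapply(specs, function(s) s$width_mm, numeric(1)),
      arc_length_mm = NA_real_, chord_length_mm = NA_real_, tsc = NA_real_,
      tsc_lx = NA_real_, tsc_lc = NA_real_, mdac = NA_real_,
      painted_px = painted_v)
  }
  cl <- matrix(0L, nr, nc)
  cl[art == 1L] <- 1L
  cl[vei == 1L] <- 2L
  cl[art == 1L & vei == 1L] <- 3L
  if (dropout > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(seed)
    }
    idx <- which(cl > 0L)
    drop <- idx[stats::runif(length(idx)) < dropout]
    cl[drop] <- 0L
  }
  map <- structure(
    list(classes = cl, pixel_pitch_mm = pixel_pitch_mm,
         laterality = laterality, eye_id = as.character(eye_id)),
    class = "vessel_label_map")  # codes valid by construction
  list(map = map,
       truth = if (compute_truth) do.call(rbind, truth) else truth_df)
}

#' Cohort simulation parameters
#'
#' Describes a synthetic study: groups of eyes whose label maps are drawn
#' from the phantom generator with per-zone vessel-density targets and
#' optional injected group effects (the known "disease" signal).
#'
#' Per-zone density is realized by laying vessels in non-overlapping
#' concentric lanes inside each parafoveal quadrant (gently wavy arc-chord
#' chains, alternating artery/vein), short chords through the fovea, and
#' one artery plus one vein radial crosser that generates arteriovenous
#' junctions. Between-eye biological variability enters as a relative
#' Gaussian perturbation (`cv_eye`) of each zone-by-class density target,
#' so the within-group SD of vessel density is approximately
#' `target * cv_eye`.
#'
#' @param groups Character vector of group names.
#' @param eyes_per_group Integer (>= 2), or vector per group.
#' @param vd_fovea,vd_parafovea All-vessel density targets (fractions in
#'   (0, 1)); parafovea may be a named vector over
#'   `c("para_S","para_I","para_N","para_T")`.
#' @param cv_eye Relative between-eye SD of the density targets.
#' @param width_mm Vessel caliber.
#' @param amplitude_mm,freq_per_mm Sinusoidal tortuosity of the lanes.
#' @param dropout Pixel dropout probability.
#' @param shape,fov_mm Raster geometry (pitch = `fov_mm / shape`).
#' @param effects Optional data.frame with columns `group`, `zone`,
#'   `class` (`"artery"`, `"vein"` or `"all"`), and `delta_vd` (absolute
#'   density offset) and/or `delta_amplitude` (mm, added to the lane
#'   amplitude in that zone).
#' @param include_crossers Add the junction-forming radial vessels.
#' @param seed Integer; fixes all randomness of [generate_cohort()].
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(groups = c("control", "NDR", "NPDR"),
                        eyes_per_group = 10,
                        vd_fovea = 0.04, vd_parafovea = 0.12,
                        cv_eye = 0.10, width_mm = 0.05,
                        amplitude_mm = 0.02, freq_per_mm = 2,
                        dropout = 0.02, shape = c(304L, 304L), fov_mm = 3,
                        effects = NULL, include_crossers = TRUE, seed = 1) {
  if (length(eyes_per_group) == 1)
    eyes_per_group <- rep(eyes_per_group, length(groups))
  if (any(eyes_per_group < 2))
    stop("eyes_per_group must be at least 2 for every group")
  quad <- c("para_S", "para_I", "para_N", "para_T")
  if (length(vd_parafovea) == 1) {
    vd_parafovea <- stats::setNames(rep(vd_parafovea, 4), quad)
  } else {
    stopifnot(all(quad %in% names(vd_parafovea)))
    vd_parafovea <- vd_parafovea[quad]
  }
  dens <- c(vd_fovea, vd_parafovea)
  if (any(dens <= 0 | dens >= 1))
    stop("density targets must lie strictly in (0, 1)")
  if (!is.null(effects)) {
    stopifnot(is.data.frame(effects),
              all(c("group", "zone") %in% names(effects)))
    if (is.null(effects$class)) effects$class <- "all"
    if (is.null(effects$delta_vd)) effects$delta_vd <- 0
    if (is.null(effects$delta_amplitude)) effects$delta_amplitude <- 0
    stopifnot(all(effects$group %in% groups),
              all(effects$zone %in% c("fovea", quad)),
              all(effects$class %in% c("artery", "vein", "all")))
  }
  structure(list(groups = groups,
                 eyes_per_group = as.integer(eyes_per_group),
                 vd_fovea = vd_fovea, vd_parafovea = vd_parafovea,
                 cv_eye = cv_eye, width_mm = width_mm,
                 amplitude_mm = amplitude_mm, freq_per_mm = freq_per_mm,
                 dropout = dropout, shape = as.integer(shape),
                 fov_mm = fov_mm, effects = effects,
                 include_crossers = include_crossers,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Arc-length inflation factor of a sinusoid relative to its baseline.
sinusoid_ripple <- function(amplitude, freq_per_mm) {
  if (amplitude <= 0 || freq_per_mm <= 0) return(1)
  u <- seq(0, 2 * pi, length.out = 721)
  k <- 2 * pi * freq_per_mm * amplitude
  mean(sqrt(1 + (k * cos(u))^2))
}

# Point on the circle of radius rho at clockwise-from-up angle theta_deg
# (mm coordinates, y up).
ring_point <- function(rho, theta_deg) {
  th <- theta_deg * pi / 180
  c(rho * sin(th), rho * cos(th))
}

# Build the centerline specs for one synthetic eye. `vd` is a named list
# zone -> c(artery=, vein=) of density targets already including effects
# and eye-level jitter; `amp` a named list zone -> amplitude (mm).
build_eye_specs <- function(vd, amp, cspec, laterality, zinfo) {
  pitch <- cspec$fov_mm / cspec$shape[1]
  w_px <- cspec$width_mm / pitch
  cap_px <- pi * (w_px / 2)^2   # two half-disc end caps per curve, px
  infl <- 1 / (1 - cspec$dropout)         # paint more to survive dropout
  # sector (clockwise from up: 0=up,1=right,2=down,3=left) -> zone name
  sector_zone <- c("para_S",
                   if (laterality == "OS") "para_N" else "para_T",
                   "para_I",
                   if (laterality == "OS") "para_T" else "para_N")
  specs <- list()
  budget_px <- list()  # zone -> c(artery=, vein=) painted-pixel budget
  for (z in c("fovea", "para_S", "para_I", "para_N", "para_T"))
    budget_px[[z]] <- vd[[z]] * zinfo[[z]] * infl
  # radial crossers: one artery (superior sector), one vein (inferior)
  if (cspec$include_crossers) {
    for (k in 1:2) {
      cls <- if (k == 1) "artery" else "vein"
      zone <- sector_zone[if (k == 1) 1 else 3]
      th <- (if (k == 1) 0 else 180) + stats::runif(1, -25, 25)
      r0 <- 0.55; r1 <- 1.45
      specs[[length(specs) + 1]] <- centerline_spec(
        "line", p0 = ring_point(r0, th), p1 = ring_point(r1, th),
        width_mm = cspec$width_mm, vessel_class = cls, n_samples = 200)
      budget_px[[zone]][cls] <-
        max(0, budget_px[[zone]][cls] - ((r1 - r0) / pitch * w_px + cap_px))
    }
  }
  # parafoveal lanes: 5 concentric lanes per sector, alternating class
  rho_lanes <- c(0.648, 0.824, 1.000, 1.176, 1.352)
  for (sec in 0:3) {
    zone <- sector_zone[sec + 1]
    a <- amp[[zone]]
    ripple <- sinusoid_ripple(a, cspec$freq_per_mm)
    cls_lane <- rep(c("artery", "vein"), length.out = 5)
    if (sec %% 2 == 1) cls_lane <- rev(cls_lane)
    for (cls in c("artery", "vein")) {
      lanes <- which(cls_lane == cls)
      need_px <- budget_px[[zone]][cls]
      if (need_px <= 0) next
      # chained segments merge into one ribbon: one cap pair per lane
      len_px <- max(0, (need_px - length(lanes) * cap_px) / w_px)
      len_mm <- len_px * pitch / ripple    # baseline (chord) length total
      rho_sum <- sum(rho_lanes[lanes])
      for (li in lanes) {
        rho <- rho_lanes[li] * (1 + stats::runif(1, -0.02, 0.02))
        chord_tot <- len_mm * rho_lanes[li] / rho_sum
        seg_chord <- chord_tot / 3
        phi_seg <- 2 * asin(min(0.45, seg_chord / (2 * rho))) * 180 / pi
        phi_seg <- min(phi_seg, 28)        # stay inside the sector
        th_c <- sec * 90 + stats::runif(1, -3, 3)
        th_edges <- th_c + (seq(-1.5, 1.5, by = 1)) * phi_seg
        ph <- stats::runif(1, 0, 2 * pi)   # chained across segments
        for (sgi in 1:3) {
          pA <- ring_point(rho, th_edges[sgi])
          pB <- ring_point(rho, th_edges[sgi + 1])
          seg_len <- sqrt(sum((pB - pA)^2))
          if (seg_len < 4 * pitch) next
          specs[[length(specs) + 1]] <- centerline_spec(
            "sinusoid", p0 = pA, p1 = pB,
            amplitude = a, frequency = cspec$freq_per_mm, phase = ph,
            width_mm = cspec$width_mm, vessel_class = cls, n_samples = 120)
          ph <- ph + 2 * pi * cspec$freq_per_mm * seg_len
        }
      }
    }
  }
  # foveal chords: one per class, parallel (non-crossing), confined to
  # the central disk
  a_fov <- amp[["fovea"]]
  fov_ang <- stats::runif(1, 0, 180)
  for (cls in c("artery", "vein")) {
    need_px <- budget_px[["fovea"]][cls]
    len_mm <- max(0, (need_px - cap_px) / w_px) * pitch /
      sinusoid_ripple(min(a_fov, 0.015), cspec$freq_per_mm)
    len_mm <- min(len_mm, 0.72)
    if (len_mm < 6 * pitch) next
    ang <- fov_ang
    off <- 0.18 * (if (cls == "artery") 1 else -1)
    u <- c(cos(ang * pi / 180), sin(ang * pi / 180))
    nrm <- c(-u[2], u[1])
    mid <- nrm * off
    specs[[length(specs) + 1]] <- centerline_spec(
      "sinusoid", p0 = mid - u * len_mm / 2, p1 = mid + u * len_mm / 2,
      amplitude = min(a_fov, 0.015), frequency = cspec$freq_per_mm,
      phase = stats::runif(1, 0, 2 * pi),
      width_mm = cspec$width_mm, vessel_class = cls, n_samples = 80)
  }
  specs
}

#' Generate a synthetic cohort of artery/vein label maps
#'
#' Draws `eyes_per_group` label maps per group from the phantom generator
#' under the density/tortuosity targets of the `cohort_spec`, applying any
#' injected group effects. All randomness is governed by `spec$seed`:
#' identical specs produce byte-identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Optional directory; if given, label-map PNGs, the
#'   manifest CSV, the truth CSV, and the target table are written there.
#' @param compute_truth Compute per-curve analytic truth tables (slower).
#' @return List with `manifest` (data.frame: eye_id, subject_id, group,
#'   laterality, path, pixel_pitch_mm), `maps` (named list of
#'   `vessel_label_map`s), `truth` (per-curve analytic truth rows), and
#'   `targets` (the effective per-eye zone-by-class density targets).
#' @export
generate_cohort <- function(spec, out_dir = NULL, compute_truth = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  pitch <- spec$fov_mm / spec$shape[1]
  zones <- c("fovea", "para_S", "para_I", "para_N", "para_T")
  # zone pixel areas (laterality only permutes N/T labels, areas equal)
  zp <- build_zones(spec$shape, pitch, "OS")
  za <- zone_areas(zp)
  zinfo <- stats::setNames(as.list(za$n_px[match(zones, za$zone)]), zones)
  base_vd <- c(list(fovea = spec$vd_fovea), as.list(spec$vd_parafovea))

  manifest <- list(); maps <- list(); truth <- list(); targets <- list()
  eye_n <- 0L
  for (gi in seq_along(spec$groups)) {
    g <- spec$groups[gi]
    for (e in seq_len(spec$eyes_per_group[gi])) {
      eye_n <- eye_n + 1L
      eye_id <- sprintf("%s_%02d", g, e)
      lat <- if (eye_n %% 2 == 1) "OS" else "OD"
      vd <- list(); amp <- list()
      for (z in zones) {
        tgt <- base_vd[[z]]
        d_art <- tgt / 2; d_vei <- tgt / 2; a <- spec$amplitude_mm
        if (!is.null(spec$effects)) {
          ef <- spec$effects[spec$effects$group == g & spec$effects$zone == z, ]
          for (r in seq_len(nrow(ef))) {
            dl <- ef$delta_vd[r]; da <- ef$delta_amplitude[r]
            if (ef$class[r] %in% c("artery", "all"))
              d_art <- d_art + dl / (if (ef$class[r] == "all") 2 else 1)
            if (ef$class[r] %in% c("vein", "all"))
              d_vei <- d_vei + dl / (if (ef$class[r] == "all") 2 else 1)
            a <- a + da
          }
        }
        jit <- 1 + stats::rnorm(2, 0, spec$cv_eye)
        vd[[z]] <- c(artery = max(0.002, d_art * jit[1]),
                     vein = max(0.002, d_vei * jit[2]))
        amp[[z]] <- max(0.003, a * (1 + stats::rnorm(1, 0, 0.1)))
      }
      eye_specs <- build_eye_specs(vd, amp, spec, lat, zinfo)
      ras <- rasterize_specs(eye_specs, shape = spec$shape,
                             pixel_pitch_mm = pitch,
                             dropout = spec$dropout, seed = NULL,
                             laterality = lat, eye_id = eye_id,
                             compute_truth = compute_truth)
      maps[[eye_id]] <- ras$map
      tr <- ras$truth; tr$eye_id <- eye_id; tr$group <- g
      truth[[eye_id]] <- tr
      tg <- do.call(rbind, lapply(zones, function(z)
        data.frame(eye_id = eye_id, group = g, zone = z,
                   target_vd_artery = vd[[z]][["artery"]],
                   target_vd_vein = vd[[z]][["vein"]],
                   amplitude_mm = amp[[z]])))
      targets[[eye_id]] <- tg
      manifest[[eye_id]] <- data.frame(
        eye_id = eye_id, subject_id = eye_id, group = g, laterality = lat,
        path = NA_character_, pixel_pitch_mm = pitch)
    }
  }
  manifest <- do.call(rbind, manifest); rownames(manifest) <- NULL
  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  targets <- do.call(rbind, targets); rownames(targets) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(nrow(manifest))) {
      p <- file.path(out_dir, paste0(manifest$eye_id[i], ".png"))
      write_label_map(maps[[manifest$eye_id[i]]], p)
      manifest$path[i] <- p
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    utils::write.csv(targets, file.path(out_dir, "targets.csv"),
                     row.names = FALSE)
  }
  list(manifest = manifest, maps = maps, truth = truth, targets = targets)
}
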