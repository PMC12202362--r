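#' Vessel density (VD)
#'
#' Fraction of zone pixels occupied by vessels: `sum(V) / N`, where `V`
#' is the vessel mask restricted to the zone and `N` the number of zone
#' pixels. An empty zone yields `NA` (undefined), never 0.
#'
#' @param mask Logical vessel mask.
#' @param zone_mask Logical matrix selecting the zone.
#' @return Fraction in \[0, 1\], or `NA` if the zone is empty.
#' @export
vessel_density <- function(mask, zone_mask) {
  if (!all(dim(mask) == dim(zone_mask))) stop("shape mismatch")
  n <- sum(zone_mask)
  if (n == 0) return(NA_real_)
  sum(mask & zone_mask) / n
}

#' Vessel diameter index (VDI)
#'
#' Mean vessel caliber: vessel-area pixels per skeleton pixel within the
#' zone, `sum(V) / sum(S)`. Undefined (`NA`) when the zone holds no
#' skeleton pixels.
#'
#' @param mask Logical vessel mask.
#' @param skeleton Logical skeleton raster (subset of `mask`).
#' @param zone_mask Logical zone selector.
#' @return Caliber in pixels, or `NA`.
#' @export
vessel_diameter_index <- function(mask, skeleton, zone_mask) {
  if (!all(dim(mask) == dim(zone_mask)) ||
      !all(dim(skeleton) == dim(zone_mask))) stop("shape mismatch")
  s <- sum(skeleton & zone_mask)
  if (s == 0) return(NA_real_)
  sum(mask & zone_mask) / s
}

#' Vessel length fraction (VLF)
#'
#' Normalized total vessel length: skeleton pixels per zone pixel,
#' `sum(S) / N`. Always `<=` VD on the same input since the skeleton is a
#' subset of the mask.
#'
#' @inheritParams vessel_diameter_index
#' @return Fraction, or `NA` for an empty zone.
#' @export
vessel_length_fraction <- function(skeleton, zone_mask) {
  if (!all(dim(skeleton) == dim(zone_mask))) stop("shape mismatch")
  n <- sum(zone_mask)
  if (n == 0) return(NA_real_)
  sum(skeleton & zone_mask) / n
}

#' Box-counting fractal dimension (FD)
#'
#' Counts occupied boxes `N(eps)` of the skeleton over a dyadic scale
#' ladder (`eps = 2, 4, 8, ...` up to a quarter of the smaller image
#' side), with the grid anchored at the zone bounding-box origin, and
#' returns minus the ordinary least-squares slope of `log N(eps)` vs
#' `log eps` over all scales with `N(eps) >= 2`. Returns `NA` when fewer
#' than two scales qualify.
#'
#' @param skeleton Logical skeleton raster.
#' @param zone_mask Optional logical zone selector; the skeleton is
#'   clipped to it and the box grid anchored at its bounding box. `NULL`
#'   uses the whole image.
#' @param eps Optional explicit vector of box sizes (pixels).
#' @return Dimension estimate in \[0, 2\], or `NA`.
#' @export
fractal_dimension <- function(skeleton, zone_mask = NULL, eps = NULL) {
  stopifnot(is.matrix(skeleton))
  sk <- skeleton != 0
  if (!is.null(zone_mask)) {
    if (!all(dim(zone_mask) == dim(sk))) stop("shape mismatch")
    sk <- sk & zone_mask
    anchor_px <- which(zone_mask, arr.ind = TRUE)
  } else {
    anchor_px <- NULL
  }
  pts <- which(sk, arr.ind = TRUE)
  if (nrow(pts) == 0) return(NA_real_)
  # grid anchored at the zone bounding box, or at the occupied bounding
  # box for whole-field calls (misaligned anchors inflate large-box
  # counts and bias the slope down)
  org <- if (is.null(anchor_px) || nrow(anchor_px) == 0)
    c(min(pts[, 1]), min(pts[, 2]))
  else c(min(anchor_px[, 1]), min(anchor_px[, 2]))
  if (is.null(eps)) {
    emax <- min(dim(sk)) / 4
    eps <- 2^(1:30)
    eps <- eps[eps <= emax]
  }
  if (length(eps) < 2) return(NA_real_)
  counts <- vapply(eps, function(e) {
    bi <- (pts[, 1] - org[1]) %/% e
    bj <- (pts[, 2] - org[2]) %/% e
    length(unique(bi * 1e6 + bj))
  }, numeric(1))
  keep <- counts >= 2
  if (sum(keep) < 2) return(NA_real_)
  lx <- log(eps[keep]); ly <- log(counts[keep])
  -(sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2))
}

track_points <- function(track) {
  if (inherits(track, "vessel_track")) track$points
  else if (is.matrix(track)) track
  else stop("track must be a vessel_track or an n x 2 matrix")
}

#' Curve (arc) length of a track
#'
#' Sum of consecutive point-to-point Euclidean distances.
#'
#' @param track A `vessel_track` or n x 2 coordinate matrix.
#' @return Length in the track's coordinate units (pixels for skeleton
#'   tracks).
#' @export
curve_length <- function(track) {
  p <- track_points(track)
  if (nrow(p) < 2) stop("a track needs at least 2 points")
  d <- diff(p)
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

#' Chord length of a track
#'
#' Euclidean distance between the first and last point. Closed tracks
#' (chord ~ 0) make chord-normalized tortuosity undefined downstream.
#'
#' @inheritParams curve_length
#' @return Chord length.
#' @export
chord_length <- function(track) {
  p <- track_points(track)
  if (nrow(p) < 2) stop("a track needs at least 2 points")
  sqrt(sum((p[nrow(p), ] - p[1, ])^2))
}

# Gaussian smoothing of a numeric sequence with reflected ends.
gauss_smooth <- function(v, sigma) {
  if (sigma <= 0) return(v)
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  n <- length(v)
  pad <- c(v[pmin(n, (h + 1):2)], v, v[pmax(1, (n - 1):(n - h))])
  stats::filter(pad, k, sides = 2)[(h + 1):(h + n)]
}

# First/second derivatives by central differences (one-sided at ends).
diff12 <- function(v) {
  n <- length(v)
  d1 <- c(v[2] - v[1], (v[3:n] - v[1:(n - 2)]) / 2, v[n] - v[n - 1])
  d2 <- c(v[3] - 2 * v[2] + v[1],
          v[3:n] - 2 * v[2:(n - 1)] + v[1:(n - 2)],
          v[n] - 2 * v[n - 1] + v[n - 2])
  list(d1 = d1, d2 = d2)
}

#' Pointwise curvature profile of a track
#'
#' Signed curvature `C(t) = (x'y'' - y'x'') / (x'^2 + y'^2)^(3/2)` from
#' Gaussian-smoothed coordinates (raw pixel chains alias curvature badly),
#' with central differences in the interior and one-sided differences at
#' the ends.
#'
#' @inheritParams curve_length
#' @param sigma Gaussian smoothing SD in points (default 2).
#' @return List with `curvature` (per point), the smoothed coordinates,
#'   and the derivative estimates.
#' @export
curvature_profile <- function(track, sigma = 2) {
  p <- track_points(track)
  if (nrow(p) < 5) stop("curvature needs at least 5 points")
  if (any(rowSums(abs(diff(p))) == 0)) stop("coincident consecutive points")
  xs <- gauss_smooth(p[, 1], sigma)
  ys <- gauss_smooth(p[, 2], sigma)
  dx <- diff12(xs); dy <- diff12(ys)
  sp2 <- dx$d1^2 + dy$d1^2
  kappa <- (dx$d1 * dy$d2 - dy$d1 * dx$d2) / pmax(sp2, 1e-300)^1.5
  list(curvature = kappa, x = xs, y = ys,
       x1 = dx$d1, y1 = dy$d1, x2 = dx$d2, y2 = dy$d2)
}

# Moving average that ignores NAs and renormalizes at the edges.
ma_na <- function(v, w) {
  w <- max(1L, as.integer(w))
  n <- length(v)
  val <- ifelse(is.na(v), 0, v)
  ind <- as.numeric(!is.na(v))
  k <- rep(1, w)
  padv <- c(rep(0, w), val, rep(0, w))
  padi <- c(rep(0, w), ind, rep(0, w))
  sv <- stats::filter(padv, k, sides = 2)[(w + 1):(w + n)]
  si <- stats::filter(padi, k, sides = 2)[(w + 1):(w + n)]
  out <- sv / si
  out[si == 0] <- NA
  as.numeric(out)
}

sinc <- function(z) ifelse(abs(z) < 1e-8, 1, sin(z) / z)

# Curvature from width-h central differences of pre-smoothed coordinates,
# with the finite-step circle bias (kappa_hat = kappa *
# sinc(z/2)^2 / sinc(z)^2, z = h * ds * kappa) divided back out.
kappa_wide <- function(xs, ys, h) {
  n <- length(xs)
  idx <- (h + 1):(n - h)
  x1 <- (xs[idx + h] - xs[idx - h]) / (2 * h)
  y1 <- (ys[idx + h] - ys[idx - h]) / (2 * h)
  x2 <- (xs[idx + h] - 2 * xs[idx] + xs[idx - h]) / h^2
  y2 <- (ys[idx + h] - 2 * ys[idx] + ys[idx - h]) / h^2
  sp2 <- x1^2 + y1^2
  k <- (x1 * y2 - y1 * x2) / pmax(sp2, 1e-300)^1.5
  ds <- sqrt(sp2)
  for (it in 1:2) {
    z <- h * ds * abs(k)
    k <- k * (sinc(z)^2 / sinc(z / 2)^2)
  }
  full <- rep(NA_real_, n)
  full[idx] <- k
  full
}

# Quantization-robust TSC for pixel tracks: two curvature estimates at
# different difference steps are locally averaged and multiplied, so
# their (largely independent) digitization noise cancels in expectation
# instead of inflating the squared-curvature integral. Returns the
# integral scaled to the full smoothed arc length, plus that length.
tsc_denoised_raw <- function(p, sigma = 2, steps = c(5, 9), window = 31) {
  xs <- gauss_smooth(p[, 1], sigma)
  ys <- gauss_smooth(p[, 2], sigma)
  n <- length(xs)
  h1 <- min(steps[1], max(1, floor((n - 1) / 4)))
  h2 <- min(steps[2], max(1, floor((n - 1) / 4)))
  kA <- ma_na(kappa_wide(xs, ys, h1), window)
  kB <- ma_na(kappa_wide(xs, ys, h2), window)
  prod <- kA * kB
  ds <- sqrt(diff(xs)^2 + diff(ys)^2)
  lc <- sum(ds)
  okl <- !is.na(prod[-n])
  if (!any(okl) || lc <= 0) return(list(tsc = NA_real_, lc_smooth = lc))
  tsc_cov <- sum(prod[-n][okl] * ds[okl])
  cov_len <- sum(ds[okl])
  list(tsc = max(0, tsc_cov) * lc / cov_len, lc_smooth = lc)
}

#' Total squared curvature (TSC) and normalized variants
#'
#' `TSC = sum C_i^2 * ds_i`, the discrete arc-length integral of squared
#' curvature (`ds_i` = distance between consecutive smoothed points).
#' Two estimators are provided. `method = "profile"` applies the
#' definition directly to the [curvature_profile()] — accurate for
#' densely and exactly sampled curves. `method = "denoised"` is built
#' for quantized pixel tracks, where squaring the pointwise curvature
#' inflates TSC by the digitization noise variance: it multiplies two
#' locally-averaged curvature estimates taken at different difference
#' steps, whose independent noise cancels in expectation. `tsc_lx()` and
#' `tsc_lc()` divide by the chord and arc length respectively; a closed
#' track (chord ~ 0) makes `tsc_lx()` `NA`.
#'
#' @inheritParams curvature_profile
#' @param profile Optional precomputed [curvature_profile()]
#'   (`method = "profile"` only).
#' @param method `"profile"` (definitional) or `"denoised"` (for raster
#'   pixel tracks).
#' @param steps,window Difference steps and curvature averaging window of
#'   the denoised estimator, points.
#' @return Scalar tortuosity value (units: 1/length^2 times length, i.e.
#'   1/length for TSC; 1/length^2 for the normalized variants).
#' @export
total_squared_curvature <- function(track, sigma = 2, profile = NULL,
                                    method = c("profile", "denoised"),
                                    steps = c(5, 9), window = 31) {
  method <- match.arg(method)
  if (method == "denoised")
    return(tsc_denoised_raw(track_points(track), sigma, steps, window)$tsc)
  if (is.null(profile)) profile <- curvature_profile(track, sigma)
  xs <- profile$x; ys <- profile$y
  ds <- sqrt(diff(xs)^2 + diff(ys)^2)
  n <- length(xs)
  sum(profile$curvature[-n]^2 * ds)
}

#' @rdname total_squared_curvature
#' @export
tsc_lx <- function(track, sigma = 2, profile = NULL,
                   method = c("profile", "denoised"),
                   steps = c(5, 9), window = 31) {
  method <- match.arg(method)
  lx <- chord_length(track)
  if (lx < 1e-9) return(NA_real_)
  total_squared_curvature(track, sigma, profile, method, steps, window) / lx
}

#' @rdname total_squared_curvature
#' @export
tsc_lc <- function(track, sigma = 2, profile = NULL,
                   method = c("profile", "denoised"),
                   steps = c(5, 9), window = 31) {
  method <- match.arg(method)
  if (method == "denoised") {
    res <- tsc_denoised_raw(track_points(track), sigma, steps, window)
    return(res$tsc / res$lc_smooth)
  }
  total_squared_curvature(track, sigma, profile) / curve_length(track)
}

# MDAC on a coordinate matrix; shared by the raster and analytic paths.
mdac_points <- function(p, step = 5) {
  n <- nrow(p)
  if (n < 2 * step + 1) return(NA_real_)
  idx <- (step + 1):(n - step)           # centers (1-based)
  v1 <- p[idx, , drop = FALSE] - p[idx - step, , drop = FALSE]
  v2 <- p[idx + step, , drop = FALSE] - p[idx, , drop = FALSE]
  n1 <- sqrt(rowSums(v1^2)); n2 <- sqrt(rowSums(v2^2))
  dots <- rowSums(v1 * v2) / pmax(n1 * n2, 1e-300)
  sum(acos(pmin(1, pmax(-1, dots)))) / (n - 2 * step)
}

#' Mean direction angle change (MDAC)
#'
#' Averages the turning angle between consecutive unit direction vectors
#' taken at a fixed index step along the track:
#' `mean over n of arccos( UV(P[n-step], P[n]) . UV(P[n], P[n+step]) )`,
#' with the arccos argument clamped to \[-1, 1\]. Tracks shorter than
#' `2 * step + 1` points return `NA` (excluded from aggregates).
#'
#' @inheritParams curve_length
#' @param step Index step (default 5 points).
#' @param sigma Optional Gaussian coordinate smoothing (points) applied
#'   before the angle computation; 0 (default) uses the raw points.
#'   Pixel tracks need smoothing, otherwise staircase quantization
#'   inflates the mean angle.
#' @return Mean turning angle in radians, or `NA`.
#' @export
mdac <- function(track, step = 5, sigma = 0) {
  p <- track_points(track)
  if (sigma > 0 && nrow(p) >= 3)
    p <- cbind(gauss_smooth(p[, 1], sigma), gauss_smooth(p[, 2], sigma))
  mdac_points(p, step = step)
}

#' Metric computation parameters
#'
#' @param mdac_step MDAC index step, points.
#' @param sigma Curvature smoothing SD, points.
#' @param mdac_sigma Coordinate smoothing for the MDAC estimator, points
#'   (slightly wider than the curvature smoothing: the mean absolute
#'   turning angle is noise-dominated on nearly straight pixel tracks).
#' @param min_track_length Minimum track length for tortuosity (default
#'   `2 * mdac_step + 1`, the shortest track on which MDAC is defined).
#' @param track_weight `"unweighted"` (default) or `"length"`: how
#'   per-track tortuosity values are averaged into zone records.
#' @param include_junction_in_class Count junction pixels in per-class
#'   masks (double counting); default `FALSE`.
#' @param fd_eps Optional explicit box-size ladder.
#' @param metrics Which metric families to compute: any of `"density"`
#'   (VD), `"skeleton"` (VDI, VLF, FD), `"tortuosity"` (MDAC, LC, TSC
#'   family).
#' @return A `metric_config` list.
#' @export
metric_config <- function(mdac_step = 5, sigma = 2, mdac_sigma = 3,
                          min_track_length = 2 * mdac_step + 1,
                          track_weight = c("unweighted", "length"),
                          include_junction_in_class = FALSE,
                          fd_eps = NULL,
                          metrics = c("density", "skeleton", "tortuosity")) {
  track_weight <- match.arg(track_weight)
  metrics <- match.arg(metrics, several.ok = TRUE)
  structure(list(mdac_step = mdac_step, sigma = sigma,
                 mdac_sigma = mdac_sigma,
                 min_track_length = min_track_length,
                 track_weight = track_weight,
                 include_junction_in_class = include_junction_in_class,
                 fd_eps = fd_eps, metrics = metrics),
            class = "metric_config")
}

#' All metrics for one eye, per zone and vessel class
#'
#' Computes the full metric family on a label map: vessel density, vessel
#' diameter index (pixels and micrometres), vessel length fraction,
#' box-counting fractal dimension, and the track-based tortuosity family
#' (MDAC, arc length, TSC, TSC/LX, TSC/LC), for every analysis zone
#' (fovea, four parafoveal quadrants, plus a whole-`image` row) crossed
#' with vessel class (`artery`, `vein`, `all`). Junction pixels count only
#' in `all`. The skeleton is computed once on the all-vessel mask; class
#' membership of skeleton pixels and tracks follows the underlying labels.
#' Zones without vessels yield `NA` metrics, never silent zeros.
#'
#' @param map A `vessel_label_map`.
#' @param zones Optional `zone_partition` (built from the map's geometry
#'   by default).
#' @param config A [metric_config()].
#' @return data.frame, one row per zone x class.
#' @export
metrics_by_zone <- function(map, zones = NULL, config = metric_config()) {
  stopifnot(inherits(map, "vessel_label_map"))
  if (is.null(zones))
    zones <- build_zones(dim(map$classes), map$pixel_pitch_mm,
                         laterality = map$laterality)
  stopifnot(all(dim(zones$zones) == dim(map$classes)))
  pitch <- map$pixel_pitch_mm
  cl <- map$classes
  # one pass over the raster gives all zone x class pixel counts
  comb <- zones$zones * 4L + cl
  ct <- matrix(tabulate(comb + 1L, nbins = 24L), nrow = 4L)
  # ct[class_code + 1, zone_code + 1]; append whole-image column
  ct <- cbind(ct, rowSums(ct))
  count_px <- function(zcode, cls) {
    col <- zcode + 1L
    switch(cls,
           artery = ct[2, col] +
             if (config$include_junction_in_class) ct[4, col] else 0,
           vein = ct[3, col] +
             if (config$include_junction_in_class) ct[4, col] else 0,
           all = ct[2, col] + ct[3, col] + ct[4, col])
  }
  do_skel <- any(c("skeleton", "tortuosity") %in% config$metrics)
  masks <- if (do_skel)
    list(artery = binary_mask(map, "artery",
                              config$include_junction_in_class),
         vein = binary_mask(map, "vein",
                            config$include_junction_in_class),
         all = binary_mask(map, "all"))
  else NULL
  skels <- NULL; tracks <- NULL
  if (do_skel) {
    skel_all <- skeletonize(masks$all)
    skels <- list(artery = skel_all & masks$artery,
                  vein = skel_all & masks$vein,
                  all = skel_all)
    if ("tortuosity" %in% config$metrics) {
      g <- skeleton_graph(skel_all)
      tracks <- extract_tracks(g, min_length = config$min_track_length,
                               map = map, zones = zones)
    }
  }
  zlist <- c(zone_names(), "image")
  rows <- list()
  for (zn in zlist) {
    zcode <- if (zn == "image") 6L else ZONE_CODES[[zn]]
    n_zone <- sum(ct[, zcode + 1L])
    zmask <- NULL
    if (do_skel)
      zmask <- if (zn == "image") matrix(TRUE, nrow(cl), ncol(cl))
               else zones$zones == ZONE_CODES[[zn]]
    for (cls in c("artery", "vein", "all")) {
      rec <- list(eye_id = map$eye_id, zone = zn, vessel_class = cls,
                  n_zone_px = n_zone,
                  vd = NA_real_, vdi_px = NA_real_, vdi_um = NA_real_,
                  vlf = NA_real_, fd = NA_real_, mdac = NA_real_,
                  lc_px = NA_real_, lc_mm = NA_real_, tsc = NA_real_,
                  tsc_lx = NA_real_, tsc_lc = NA_real_,
                  n_tracks = NA_integer_)
      if ("density" %in% config$metrics)
        rec$vd <- if (n_zone == 0) NA_real_ else count_px(zcode, cls) / n_zone
      if ("skeleton" %in% config$metrics) {
        rec$vdi_px <- vessel_diameter_index(masks[[cls]], skels[[cls]], zmask)
        rec$vdi_um <- rec$vdi_px * pitch * 1000
        rec$vlf <- vessel_length_fraction(skels[[cls]], zmask)
        rec$fd <- fractal_dimension(skels[[cls]],
                                    zone_mask = if (zn == "image") NULL
                                                else zmask,
                                    eps = config$fd_eps)
      }
      if ("tortuosity" %in% config$metrics) {
        sel <- vapply(tracks, function(tr) {
          (cls == "all" || identical(tr$vessel_class, cls)) &&
            (zn == "image" || identical(tr$zone, zn))
        }, logical(1))
        trs <- tracks[sel]
        rec$n_tracks <- length(trs)
        if (length(trs) > 0) {
          vals <- lapply(trs, function(tr) {
            den <- tsc_denoised_raw(tr$points, sigma = config$sigma)
            # arc length of the smoothed centerline: the raw 8-connected
            # pixel chain overestimates length by up to ~10%
            c(mdac = mdac(tr, config$mdac_step, sigma = config$mdac_sigma),
              lc = den$lc_smooth, tsc = den$tsc,
              tsc_lx = if (tr$is_loop) NA_real_ else
                den$tsc / max(chord_length(tr), 1e-9),
              tsc_lc = den$tsc / den$lc_smooth)
          })
          vm <- do.call(rbind, vals)
          w <- if (config$track_weight == "length")
            vapply(trs, function(tr) tr$n, numeric(1)) else
              rep(1, length(trs))
          wmean <- function(v) {
            ok <- !is.na(v)
            if (!any(ok)) return(NA_real_)
            sum(v[ok] * w[ok]) / sum(w[ok])
          }
          rec$mdac <- wmean(vm[, "mdac"])
          rec$lc_px <- wmean(vm[, "lc"])
          rec$lc_mm <- rec$lc_px * pitch
          rec$tsc <- wmean(vm[, "tsc"])
          rec$tsc_lx <- wmean(vm[, "tsc_lx"])
          rec$tsc_lc <- wmean(vm[, "tsc_lc"])
        }
      }
      rows[[length(rows) + 1]] <- as.data.frame(rec)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
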