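ZONE_CODES <- c(outside = 0L, fovea = 1L, para_S = 2L, para_I = 3L,
                para_N = 4L, para_T = 5L)

#' Partition the en-face field into macular analysis zones
#'
#' Builds the standard macular grid used for zone-wise OCTA metrics: a
#' foveal disk of radius 0.5 mm centered on the fovea, surrounded by a
#' parafoveal annulus out to 1.5 mm split into four equal 90-degree
#' quadrants (superior, inferior, nasal, temporal). Everything beyond the
#' outer circle is `outside`.
#'
#' Geometry conventions: distances are measured from pixel centers; the
#' fovea is the half-open disk `dist < r_fovea_mm` and the annulus
#' `r_fovea_mm <= dist < r_outer_mm`, so zones are disjoint and cover the
#' field. With the default `"diagonal"` split the quadrants are sectors
#' centered on the up/down/left/right axes with boundaries on the 45-degree
#' diagonals; a pixel whose angle falls exactly on a boundary joins the
#' clockwise sector. Row 1 is the superior edge; the nasal quadrant is
#' image-right for OS (left eye) and image-left for OD.
#'
#' @param shape `c(nrow, ncol)` in pixels.
#' @param pixel_pitch_mm Pixel size, mm.
#' @param laterality `"OS"` or `"OD"`.
#' @param center Fovea center as `c(row, col)` in continuous pixel
#'   coordinates (pixel (i, j) has center (i - 0.5, j - 0.5)); default is
#'   the geometric image center.
#' @param r_fovea_mm,r_outer_mm Zone radii, mm.
#' @param quadrant_split `"diagonal"` (sectors centered on the axes,
#'   default) or `"axis"` (sectors between the axes).
#' @return A `zone_partition`: list with the integer `zones` raster
#'   (codes: 0 outside, 1 fovea, 2 para_S, 3 para_I, 4 para_N, 5 para_T)
#'   and the parameters used.
#' @export
build_zones <- function(shape, pixel_pitch_mm, laterality = c("OS", "OD"),
                        center = NULL, r_fovea_mm = 0.5, r_outer_mm = 1.5,
                        quadrant_split = c("diagonal", "axis")) {
  laterality <- match.arg(laterality)
  quadrant_split <- match.arg(quadrant_split)
  stopifnot(length(shape) == 2, all(shape >= 1), pixel_pitch_mm > 0,
            r_fovea_mm > 0, r_outer_mm > r_fovea_mm)
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  if (is.null(center)) center <- c(nr / 2, nc / 2)
  half_w <- min(center[1], nr - center[1], center[2], nc - center[2]) *
    pixel_pitch_mm
  if (r_outer_mm > half_w + 1e-9)
    stop(sprintf(
      "outer radius %.3f mm exceeds the distance from the center to the nearest image edge (%.3f mm)",
      r_outer_mm, half_w))

  # pixel-center coordinates, mm, y up (superior), x right
  rr <- matrix(seq_len(nr) - 0.5, nr, nc)
  cc <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
  x <- (cc - center[2]) * pixel_pitch_mm
  y <- (center[1] - rr) * pixel_pitch_mm
  d <- sqrt(x^2 + y^2)

  # angle clockwise from the image-up (superior) axis, degrees in [0, 360)
  theta <- (atan2(x, y) * 180 / pi) %% 360
  offset <- if (quadrant_split == "diagonal") 45 else 0
  sector <- floor(((theta + offset) %% 360) / 90)  # 0=up,1=right,2=down,3=left
  right_zone <- if (laterality == "OS") ZONE_CODES[["para_N"]]
                else ZONE_CODES[["para_T"]]
  left_zone <- if (laterality == "OS") ZONE_CODES[["para_T"]]
               else ZONE_CODES[["para_N"]]
  quad <- matrix(ZONE_CODES[["outside"]], nr, nc)
  quad[sector == 0] <- ZONE_CODES[["para_S"]]
  quad[sector == 1] <- right_zone
  quad[sector == 2] <- ZONE_CODES[["para_I"]]
  quad[sector == 3] <- left_zone

  z <- matrix(ZONE_CODES[["outside"]], nr, nc)
  annulus <- d >= r_fovea_mm & d < r_outer_mm
  z[annulus] <- quad[annulus]
  z[d < r_fovea_mm] <- ZONE_CODES[["fovea"]]
  storage.mode(z) <- "integer"
  structure(
    list(zones = z, center = center, pixel_pitch_mm = pixel_pitch_mm,
         laterality = laterality, r_fovea_mm = r_fovea_mm,
         r_outer_mm = r_outer_mm, quadrant_split = quadrant_split),
    class = "zone_partition"
  )
}

#' @export
print.zone_partition <- function(x, ...) {
  tab <- table(factor(x$zones, levels = ZONE_CODES, labels = names(ZONE_CODES)))
  cat(sprintf("<zone_partition> %d x %d px, %s, fovea %.2f mm / outer %.2f mm\n",
              nrow(x$zones), ncol(x$zones), x$laterality,
              x$r_fovea_mm, x$r_outer_mm))
  print(tab)
  invisible(x)
}

#' Zone names in canonical order
#' @return Character vector of the five analysis zones.
#' @export
zone_names <- function() names(ZONE_CODES)[-1]

#' Restrict a raster to one zone
#'
#' Clears every pixel outside the named zone; idempotent.
#'
#' @param mask Logical or numeric matrix.
#' @param partition A `zone_partition`.
#' @param zone One of `"fovea"`, `"para_S"`, `"para_I"`, `"para_N"`,
#'   `"para_T"`, `"outside"`.
#' @return Matrix of the same type with off-zone pixels zeroed.
#' @export
restrict_zone <- function(mask, partition, zone) {
  stopifnot(inherits(partition, "zone_partition"))
  if (!zone %in% names(ZONE_CODES)) stop("unknown zone: ", zone)
  if (!all(dim(mask) == dim(partition$zones)))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match zone raster ",
         paste(dim(partition$zones), collapse = "x"))
  out <- mask
  out[partition$zones != ZONE_CODES[[zone]]] <- if (is.logical(mask)) FALSE else 0
  out
}

#' Zone pixel counts and areas
#'
#' @param partition A `zone_partition`.
#' @return data.frame with `zone`, `n_px`, `area_mm2`.
#' @export
zone_areas <- function(partition) {
  stopifnot(inherits(partition, "zone_partition"))
  tab <- table(factor(partition$zones, levels = ZONE_CODES,
                      labels = names(ZONE_CODES)))
  data.frame(zone = names(tab), n_px = as.integer(tab),
             area_mm2 = as.integer(tab) * partition$pixel_pitch_mm^2,
             row.names = NULL)
}
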