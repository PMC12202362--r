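#' @useDynLib vesselmetrics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Class codes shared across the package.
CLASS_CODES <- c(background = 0L, artery = 1L, vein = 2L, junction = 3L)

# Default palette (RGB in 0..255) for label-map PNGs:
# black background, red arteries, blue veins, green arteriovenous junctions.
DEFAULT_PALETTE <- matrix(
  c(0, 0, 0,
    255, 0, 0,
    0, 0, 255,
    0, 255, 0),
  nrow = 4, byrow = TRUE,
  dimnames = list(c("background", "artery", "vein", "junction"),
                  c("r", "g", "b"))
)

#' Construct a vessel label map
#'
#' A vessel label map is the per-pixel artery/vein classification of one
#' en-face OCTA angiogram: an integer raster with codes 0 (background),
#' 1 (artery), 2 (vein), 3 (arteriovenous junction), plus the metadata
#' needed to interpret it physically (pixel pitch in mm) and anatomically
#' (laterality, which decides the nasal/temporal side).
#'
#' Orientation convention used throughout the package: matrix row 1 is the
#' superior (top) edge of the scan, column 1 the image-left edge; the mm
#' origin sits at the field center.
#'
#' @param classes Integer matrix with values in \{0, 1, 2, 3\}.
#' @param pixel_pitch_mm Physical size of one pixel, mm (> 0).
#' @param laterality `"OS"` (left eye) or `"OD"` (right eye).
#' @param eye_id Identifier string.
#' @return An object of class `vessel_label_map`.
#' @export
label_map <- function(classes, pixel_pitch_mm, laterality = c("OS", "OD"),
                      eye_id = "eye") {
  laterality <- match.arg(laterality)
  if (!is.matrix(classes)) stop("`classes` must be a matrix")
  storage.mode(classes) <- "integer"
  bad <- setdiff(unique(as.vector(classes)), unname(CLASS_CODES))
  if (length(bad) > 0)
    stop("unknown class codes in raster: ", paste(bad, collapse = ", "))
  if (!is.numeric(pixel_pitch_mm) || length(pixel_pitch_mm) != 1 ||
      pixel_pitch_mm <= 0)
    stop("`pixel_pitch_mm` must be a single positive number")
  structure(
    list(classes = classes, pixel_pitch_mm = pixel_pitch_mm,
         laterality = laterality, eye_id = as.character(eye_id)),
    class = "vessel_label_map"
  )
}

#' @export
print.vessel_label_map <- function(x, ...) {
  d <- dim(x$classes)
  tab <- table(factor(x$classes, levels = CLASS_CODES,
                      labels = names(CLASS_CODES)))
  cat(sprintf("<vessel_label_map> %s (%s), %d x %d px, %.4f mm/px\n",
              x$eye_id, x$laterality, d[1], d[2], x$pixel_pitch_mm))
  cat("  pixels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a label map as an RGB PNG
#'
#' Encodes the class raster with the artery/vein palette (red = artery,
#' blue = vein, green = junction, black = background).
#'
#' @param map A `vessel_label_map`.
#' @param path Output PNG path.
#' @param palette 4x3 RGB matrix (0..255), rows in class-code order.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(map, path, palette = DEFAULT_PALETTE) {
  stopifnot(inherits(map, "vessel_label_map"))
  cl <- map$classes
  arr <- array(0, dim = c(nrow(cl), ncol(cl), 3))
  for (k in seq_len(4)) {
    sel <- cl == (k - 1L)
    for (ch in 1:3) {
      plane <- arr[, , ch]
      plane[sel] <- palette[k, ch] / 255
      arr[, , ch] <- plane
    }
  }
  png::writePNG(arr, target = path)
  invisible(path)
}

#' Read a label map from a PNG
#'
#' Maps image colors back to class codes via the palette. Matching is exact
#' by default; `tolerance` (max per-channel distance, 0..255 scale) admits
#' anti-aliased or re-encoded exports by snapping to the nearest palette
#' entry. A grayscale 0/255 mask is accepted as a binary "all vessels"
#' image: foreground (> 0.5) is stored under the artery code, so the `"all"`
#' mask is faithful while per-class splits are degenerate for such input.
#'
#' @param path PNG path.
#' @param pixel_pitch_mm,laterality,eye_id Metadata (see [label_map()]).
#' @param palette 4x3 RGB matrix (0..255).
#' @param tolerance Max per-channel distance (0..255) for nearest-palette
#'   matching; 0 requires exact colors.
#' @return A `vessel_label_map`.
#' @export
read_label_map <- function(path, pixel_pitch_mm, laterality = c("OS", "OD"),
                           eye_id = basename(path),
                           palette = DEFAULT_PALETTE, tolerance = 0) {
  laterality <- match.arg(laterality)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) {
    # grayscale binary mask: foreground = undifferentiated vessel (artery
    # code, no veins/junctions present; per-class metrics will be trivial)
    cl <- matrix(ifelse(img > 0.5, CLASS_CODES[["artery"]], 0L),
                 nrow(img), ncol(img))
    return(label_map(cl, pixel_pitch_mm, laterality, eye_id))
  }
  rgb255 <- round(img[, , 1:3] * 255)
  n <- nrow(rgb255) * ncol(rgb255)
  px <- matrix(rgb255, nrow = n)           # n x 3
  cl <- rep(NA_integer_, n)
  dist_chan <- matrix(Inf, n, 4)
  for (k in 1:4) {
    d <- pmax(abs(px[, 1] - palette[k, 1]),
              abs(px[, 2] - palette[k, 2]),
              abs(px[, 3] - palette[k, 3]))
    dist_chan[, k] <- d
  }
  best <- max.col(-dist_chan, ties.method = "first")
  bestd <- dist_chan[cbind(seq_len(n), best)]
  ok <- bestd <= tolerance
  if (!all(ok)) {
    off <- unique(px[!ok, , drop = FALSE])
    off <- off[seq_len(min(5, nrow(off))), , drop = FALSE]
    stop("unmappable colors in ", path, " (max channel distance > ",
         tolerance, "): ",
         paste(apply(off, 1, function(v)
           sprintf("rgb(%d,%d,%d)", v[1], v[2], v[3])), collapse = ", "))
  }
  cl[ok] <- best[ok] - 1L
  label_map(matrix(cl, nrow(rgb255), ncol(rgb255)),
            pixel_pitch_mm, laterality, eye_id)
}

#' Binary vessel mask from a label map
#'
#' `"artery"` selects artery pixels only and `"vein"` vein pixels only;
#' junction pixels belong to neither single-class mask (they cannot be
#' attributed without double counting) but are included in `"all"`.
#'
#' @param map A `vessel_label_map`.
#' @param class `"all"`, `"artery"`, or `"vein"`.
#' @param include_junction_in_class If `TRUE`, junction pixels are also
#'   included in the single-class masks (double counting them).
#' @return Logical matrix.
#' @export
binary_mask <- function(map, class = c("all", "artery", "vein"),
                        include_junction_in_class = FALSE) {
  stopifnot(inherits(map, "vessel_label_map"))
  class <- match.arg(class)
  cl <- map$classes
  switch(class,
         all = matrix(cl %in% c(1L, 2L, 3L), nrow(cl), ncol(cl)),
         artery = matrix(cl == 1L |
                           (include_junction_in_class & cl == 3L),
                         nrow(cl), ncol(cl)),
         vein = matrix(cl == 2L |
                         (include_junction_in_class & cl == 3L),
                       nrow(cl), ncol(cl)))
}

#' Load and validate a cohort manifest
#'
#' The manifest lists one row per eye: `eye_id`, `group`, `laterality`,
#' `path` (label-map image), `pixel_pitch_mm`, plus optional covariates
#' (e.g. `subject_id`, `age`, `duration_years`, `sex`).
#'
#' @param path CSV path.
#' @param groups Optional character vector of allowed group labels.
#' @return A validated data.frame.
#' @export
load_cohort_manifest <- function(path, groups = NULL) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("eye_id", "group", "laterality", "path", "pixel_pitch_mm")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("manifest is missing required column(s): ",
         paste(miss, collapse = ", "))
  dup <- tab$eye_id[duplicated(tab$eye_id)]
  if (length(dup) > 0)
    stop("duplicate eye_id in manifest: ", paste(unique(dup), collapse = ", "))
  bad_lat <- !tab$laterality %in% c("OS", "OD")
  if (any(bad_lat))
    stop("unknown laterality in manifest row(s) ",
         paste(which(bad_lat), collapse = ", "), ": ",
         paste(unique(tab$laterality[bad_lat]), collapse = ", "))
  if (!is.null(groups)) {
    bad_g <- !tab$group %in% groups
    if (any(bad_g))
      stop("unknown group label in manifest row(s) ",
           paste(which(bad_g), collapse = ", "), ": ",
           paste(unique(tab$group[bad_g]), collapse = ", "))
  }
  if (any(tab$pixel_pitch_mm <= 0))
    stop("pixel_pitch_mm must be positive for every row")
  tab
}
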