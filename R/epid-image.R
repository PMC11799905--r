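#' EPID image container
#'
#' An `epid_image` holds a 2D integrated (or cine-frame) portal image
#' together with the geometry metadata the analysis needs: pixel spacing
#' projected to the isocenter plane, source-detector distance, and the
#' gantry and collimator angles of the acquisition.
#'
#' Coordinate convention: pixels are addressed with 0-based indices and
#' the *center* of pixel (0,0) is the mm-origin of the raw image frame.
#' The x axis (crossplane, leaf-travel direction) increases with column
#' index, the y axis (inplane, leaf-stacking direction) with row index.
#' All analysis distances are mm at the isocenter plane; `pixel_spacing`
#' is already projected there, so detector positions and isocenter
#' positions agree by construction.
#'
#' @param pixels numeric matrix of non-negative signal values; rows are
#'   inplane (y), columns crossplane (x).  At least 64 x 64.
#' @param pixel_spacing mm per pixel at the isocenter plane (square pixels).
#' @param sdd source-detector distance in cm.
#' @param gantry_angle,collimator_angle degrees (IEC 61217); normalized
#'   to `[0, 360)`.
#' @param acquisition_mode `"integrated"` or `"cine_frame"`.
#' @return An object of class `epid_image`.
#' @export
epid_image <- function(pixels, pixel_spacing, sdd = 100,
                       gantry_angle = 0, collimator_angle = 0,
                       acquisition_mode = c("integrated", "cine_frame")) {
  acquisition_mode <- match.arg(acquisition_mode)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 64 || ncol(pixels) < 64)
    stop("epid_image: pixel grid must be at least 64 x 64")
  if (!all(is.finite(pixels)))
    stop("epid_image: all pixel values must be finite")
  if (any(pixels < 0))
    stop("epid_image: pixel values must be non-negative")
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1 || pixel_spacing <= 0)
    stop("epid_image: pixel_spacing must be a positive scalar (mm at iso)")
  if (!is.numeric(sdd) || length(sdd) != 1 || sdd <= 0)
    stop("epid_image: sdd must be a positive scalar (cm)")
  structure(
    list(
      pixels = pixels,
      pixel_spacing = as.numeric(pixel_spacing),
      sdd = as.numeric(sdd),
      gantry_angle = normalize_angle(gantry_angle),
      collimator_angle = normalize_angle(collimator_angle),
      acquisition_mode = acquisition_mode
    ),
    class = "epid_image"
  )
}

#' @export
print.epid_image <- function(x, ...) {
  cat(sprintf(
    "<epid_image> %d x %d px, %.4f mm/px at iso, SDD %.1f cm, G%.1f C%.1f, %s\n",
    nrow(x$pixels), ncol(x$pixels), x$pixel_spacing, x$sdd,
    x$gantry_angle, x$collimator_angle, x$acquisition_mode))
  invisible(x)
}

normalize_angle <- function(a) {
  a <- as.numeric(a) %% 360
  a[a < 0] <- a[a < 0] + 360
  a
}

#' Image point
#'
#' A 2D point in mm with an explicit origin tag, so that positions in the
#' raw image frame (origin at the center of pixel (0,0)) are never mixed
#' up with positions relative to the beam central axis.
#'
#' @param x,y mm crossplane / inplane.
#' @param origin `"pixel0"` (raw image frame) or `"cax"`.
#' @export
image_point <- function(x, y, origin = c("pixel0", "cax")) {
  origin <- match.arg(origin)
  stopifnot(is.finite(x), is.finite(y))
  structure(list(x = as.numeric(x), y = as.numeric(y), origin = origin),
            class = "image_point")
}

#' @export
print.image_point <- function(x, ...) {
  cat(sprintf("<image_point> (%.4f, %.4f) mm [origin: %s]\n", x$x, x$y, x$origin))
  invisible(x)
}

# pixel (0-based) <-> mm converters for the raw frame; bijective on the grid
px_to_mm <- function(idx0, spacing) idx0 * spacing
mm_to_px <- function(mm, spacing) mm / spacing

image_extent_mm <- function(img) {
  c(xmax = px_to_mm(ncol(img$pixels) - 1, img$pixel_spacing),
    ymax = px_to_mm(nrow(img$pixels) - 1, img$pixel_spacing))
}

image_center_mm <- function(img) {
  image_point(px_to_mm((ncol(img$pixels) - 1) / 2, img$pixel_spacing),
              px_to_mm((nrow(img$pixels) - 1) / 2, img$pixel_spacing))
}

#' Cubic-convolution interpolation of an image at arbitrary positions
#'
#' Samples the pixel grid at fractional (column, row) positions with the
#' Catmull-Rom cubic convolution kernel (the standard "cubic" image
#' interpolant).  Exact at integer pixel centers.  Positions must stay a
#' pixel inside the outer border so the 4x4 support is available.
#'
#' @param pixels numeric matrix.
#' @param col0,row0 0-based fractional pixel coordinates (vectors).
#' @return numeric vector of interpolated values.
#' @keywords internal
interp_bicubic <- function(pixels, col0, row0) {
  nr <- nrow(pixels); nc <- ncol(pixels)
  if (any(col0 < 0) || any(col0 > nc - 1) || any(row0 < 0) || any(row0 > nr - 1))
    stop("interp_bicubic: position outside image bounds")
  # clamp base index so the 4x4 neighbourhood exists (replicate border)
  jc <- floor(col0); jr <- floor(row0)
  tx <- col0 - jc;   ty <- row0 - jr
  wx <- catmull_weights(tx)   # n x 4
  wy <- catmull_weights(ty)
  out <- numeric(length(col0))
  for (a in 1:4) {
    r <- pmin(pmax(jr + a - 2L, 0L), nr - 1L)
    acc <- numeric(length(col0))
    for (b in 1:4) {
      cc <- pmin(pmax(jc + b - 2L, 0L), nc - 1L)
      acc <- acc + wx[, b] * pixels[cbind(r + 1L, cc + 1L)]
    }
    out <- out + wy[, a] * acc
  }
  out
}

catmull_weights <- function(t) {
  # weights for samples at offsets -1, 0, +1, +2 (Catmull-Rom, a = -1/2)
  t2 <- t * t; t3 <- t2 * t
  cbind(
    -0.5 * t3 + t2 - 0.5 * t,
     1.5 * t3 - 2.5 * t2 + 1,
    -1.5 * t3 + 2 * t2 + 0.5 * t,
     0.5 * t3 - 0.5 * t2
  )
}

#' Sample an interpolated line profile through an image
#'
#' Values are interpolated at sub-pixel positions along the straight
#' segment from `start` to `end`, at `step` mm spacing; the first sample
#' lies on `start` and distances increase monotonically from 0.  Used for
#' the comb-pattern leaf localization profiles, the leaf-travel profiles,
#' and the central field-edge profiles.
#'
#' @param img an [epid_image].
#' @param start,end [image_point]s in the raw image frame (`origin = "pixel0"`).
#' @param step sampling step in mm (> 0); default 0.01 mm for sub-pixel work.
#' @return data.frame with columns `distance_mm`, `value`, `x_mm`, `y_mm`.
#' @export
sample_profile <- function(img, start, end, step = 0.01) {
  stopifnot(inherits(img, "epid_image"))
  if (inherits(start, "image_point")) {
    if (start$origin != "pixel0") stop("sample_profile: start must be in the raw image frame")
  } else start <- image_point(start[1], start[2])
  if (inherits(end, "image_point")) {
    if (end$origin != "pixel0") stop("sample_profile: end must be in the raw image frame")
  } else end <- image_point(end[1], end[2])
  if (step <= 0) stop("sample_profile: step must be > 0")
  len <- sqrt((end$x - start$x)^2 + (end$y - start$y)^2)
  if (len == 0) stop("sample_profile: start and end coincide")
  ext <- image_extent_mm(img)
  for (p in list(start = start, end = end)) {
    if (p$x < 0 || p$x > ext["xmax"] || p$y < 0 || p$y > ext["ymax"])
      stop(sprintf("sample_profile: endpoint (%.3f, %.3f) mm outside image bounds", p$x, p$y))
  }
  d <- seq(0, len, by = step)
  fx <- (end$x - start$x) / len
  fy <- (end$y - start$y) / len
  xs <- start$x + d * fx
  ys <- start$y + d * fy
  vals <- interp_bicubic(img$pixels,
                         mm_to_px(xs, img$pixel_spacing),
                         mm_to_px(ys, img$pixel_spacing))
  data.frame(distance_mm = d, value = vals, x_mm = xs, y_mm = ys)
}
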