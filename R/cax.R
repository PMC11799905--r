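#' Locate the center of a single field on an EPID image
#'
#' Finds the midpoint between the two 50% penumbra crossings on a central
#' crossplane profile (x) and a central inplane profile (y), both
#' interpolated to sub-pixel precision.  Works for rectangular and
#' circular fields that roughly cover the image center.  The 50% level on
#' each profile is the midpoint of the in-field maximum and the
#' out-of-field minimum of that same profile, which makes the estimate
#' robust to a mild lack of beam flatness and to a signal pedestal.
#'
#' @param img an [epid_image] containing one roughly centered field.
#' @param step profile sampling step, mm.
#' @param smooth_sigma Gaussian low-pass sigma applied to the sampled
#'   profiles, mm; symmetric, so erf-edge 50% crossings are unshifted.
#' @return [image_point] of the field center in the raw image frame.
#' @export
field_center <- function(img, step = 0.01, smooth_sigma = 0.3) {
  stopifnot(inherits(img, "epid_image"))
  ext <- image_extent_mm(img)
  cy <- ext["ymax"] / 2; cx <- ext["xmax"] / 2
  px <- sample_profile(img, image_point(0, cy), image_point(ext["xmax"], cy), step)
  py <- sample_profile(img, image_point(cx, 0), image_point(cx, ext["ymax"]), step)
  x <- profile_midpoint(px$distance_mm, smooth_profile(px$value, smooth_sigma / step))
  y <- profile_midpoint(py$distance_mm, smooth_profile(py$value, smooth_sigma / step))
  image_point(x, y)
}

# midpoint of the two 50% crossings of a single-field profile
profile_midpoint <- function(d, v) {
  lo <- min(v); hi <- max(v)
  level <- lo + 0.5 * (hi - lo)
  cr <- profile_crossings(d, v, level)
  if (length(cr) != 2)
    stop("field_center: ambiguous field edges (", length(cr),
         " crossings of the 50% level)")
  mean(cr)
}

# all crossings of `level`, by inverse linear interpolation between samples
profile_crossings <- function(d, v, level) {
  s <- v - level
  idx <- which(s[-length(s)] * s[-1] < 0)
  if (any(s == 0)) idx <- sort(unique(c(idx, which(s == 0))))
  vapply(idx, function(i) {
    if (s[i] == 0) return(d[i])
    d[i] + (d[i + 1] - d[i]) * s[i] / (s[i] - s[i + 1])
  }, numeric(1))
}

#' Determine the beam central axis from a C90/C270 field pair
#'
#' The collimator-rotation-axis projection onto the panel is the
#' component-wise average of the field centers of two 10 x 10 cm
#' jaw-defined fields imaged at collimator 90 and 270 degrees: the 180
#' degree rotation flips any jaw asymmetry, so it cancels in the mean.
#'
#' @param img_c90,img_c270 [epid_image]s at collimator angles 90 and 270,
#'   gantry 0, same SDD.
#' @return An object of class `beam_cax` with field `position`
#'   (an [image_point], raw frame, valid at gantry 0).
#' @export
compute_cax <- function(img_c90, img_c270) {
  stopifnot(inherits(img_c90, "epid_image"), inherits(img_c270, "epid_image"))
  if (abs(img_c90$collimator_angle - 90) > 0.5 ||
      abs(img_c270$collimator_angle - 270) > 0.5)
    stop("compute_cax: expected collimator angles 90 and 270 (got ",
         img_c90$collimator_angle, " and ", img_c270$collimator_angle, ")")
  if (img_c90$sdd != img_c270$sdd)
    warning("compute_cax: SDD differs between the two images; ",
            "the panel must not move between acquisitions")
  p90 <- field_center(img_c90)
  p270 <- field_center(img_c270)
  structure(
    list(position = image_point((p90$x + p270$x) / 2, (p90$y + p270$y) / 2),
         centers = list(c90 = p90, c270 = p270)),
    class = "beam_cax"
  )
}

#' @export
print.beam_cax <- function(x, ...) {
  cat(sprintf("<beam_cax> (%.4f, %.4f) mm (raw frame, G0)\n",
              x$position$x, x$position$y))
  invisible(x)
}

#' Build a gantry-sag map from cone-arc cine frames
#'
#' Each frame's cone center is located with [field_center()]; offsets are
#' normalized to the frame nearest gantry 0, so the map value at G0 is
#' exactly (0, 0).  The map captures the gantry-angle dependence of the
#' CAX projection caused by panel and gantry sag.
#'
#' @param frames list of [epid_image] cine frames with gantry tags
#'   spanning 360 degrees (>= 8 frames; one within 5 degrees of G0).
#' @return A `sag_map`: data.frame with columns `gantry_angle`, `dx`, `dy`
#'   (mm relative to G0), sorted by angle.
#' @export
build_sag_map <- function(frames) {
  if (length(frames) < 8)
    stop("build_sag_map: need at least 8 frames spanning 360 degrees")
  angles <- vapply(frames, function(f) f$gantry_angle, numeric(1))
  centers <- lapply(frames, field_center)
  wrap_dist <- pmin(angles, 360 - angles)
  if (min(wrap_dist) > 5)
    stop("build_sag_map: no frame within 5 degrees of gantry 0")
  ref <- which.min(wrap_dist)
  dx <- vapply(centers, `[[`, numeric(1), "x") - centers[[ref]]$x
  dy <- vapply(centers, `[[`, numeric(1), "y") - centers[[ref]]$y
  m <- data.frame(gantry_angle = angles, dx = dx, dy = dy)
  m <- m[order(m$gantry_angle), ]
  rownames(m) <- NULL
  class(m) <- c("sag_map", "data.frame")
  m
}

#' Persist / load a sag map as CSV
#' @param sag a `sag_map` (see [build_sag_map()]).
#' @param path CSV path (columns `gantry_angle`, `dx`, `dy`).
#' @return `write_sag_map` returns `path` invisibly; `read_sag_map` the map.
#' @export
write_sag_map <- function(sag, path) {
  utils::write.csv(as.data.frame(sag), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sag_map
#' @export
read_sag_map <- function(path) {
  if (!file.exists(path)) stop("read_sag_map: file not found: ", path)
  m <- utils::read.csv(path)
  for (f in c("gantry_angle", "dx", "dy"))
    if (is.null(m[[f]])) stop("read_sag_map: CSV missing column ", f)
  m <- m[order(m$gantry_angle), ]
  rownames(m) <- NULL
  class(m) <- c("sag_map", "data.frame")
  m
}

#' Sag-corrected CAX position at a gantry angle
#'
#' Adds the sag-map offset (linearly interpolated in gantry angle, with
#' 360 degree wrap-around when the map covers the full circle) to the
#' session's G0 CAX position.
#'
#' @param cax a [beam_cax][compute_cax].
#' @param sag a `sag_map`, or `NULL` (allowed only at gantry 0).
#' @param gantry gantry angle, degrees.
#' @return [image_point] in the raw image frame.
#' @export
cax_at_gantry <- function(cax, sag, gantry = 0) {
  stopifnot(inherits(cax, "beam_cax"))
  g <- normalize_angle(gantry)
  if (is.null(sag)) {
    if (g != 0)
      stop("cax_at_gantry: no sag map supplied for gantry ", g,
           "; build one from a cone arc (build_sag_map) first")
    return(cax$position)
  }
  a <- sag$gantry_angle
  # full-circle map: the gap across 360/0 is no larger than the tabulated
  # spacing, so interpolation may wrap around
  wrap_gap <- min(a) + 360 - max(a)
  full_circle <- length(a) > 2 && wrap_gap <= 1.5 * max(diff(sort(a)))
  if (full_circle) {
    a <- c(a, min(a) + 360)
    dxs <- c(sag$dx, sag$dx[which.min(sag$gantry_angle)])
    dys <- c(sag$dy, sag$dy[which.min(sag$gantry_angle)])
    if (g < min(a)) g <- g + 360
  } else {
    dxs <- sag$dx; dys <- sag$dy
    if (g < min(a) || g > max(a))
      stop("cax_at_gantry: gantry ", g, " outside sag-map coverage [",
           min(a), ", ", max(a), "]")
  }
  dx <- stats::approx(a, dxs, xout = g)$y
  dy <- stats::approx(a, dys, xout = g)$y
  image_point(cax$position$x + dx, cax$position$y + dy)
}
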