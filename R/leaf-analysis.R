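#' Sub-pixel extremum center within a window of a sampled profile
#'
#' Finds the discrete extremum of the sampled profile inside the window,
#' then refines it by a parabolic fit through the extremum and its two
#' neighbours.  An extremum sitting on the window boundary (a monotone
#' profile in the window) is rejected as "not located".
#'
#' @param d,v sampled profile: positions (mm) and values.
#' @param window `c(lo, hi)` mm.
#' @param type `"peak"` or `"trough"`.
#' @return the refined extremum position (mm), or `NA_real_` if not
#'   located.
#' @export
extremum_center <- function(d, v, window, type = c("peak", "trough")) {
  type <- match.arg(type)
  if (window[1] < min(d) || window[2] > max(d)) return(NA_real_)
  sel <- which(d >= window[1] & d <= window[2])
  if (length(sel) < 3) return(NA_real_)
  vv <- if (type == "peak") v[sel] else -v[sel]
  i <- which.max(vv)
  if (i == 1 || i == length(sel)) return(NA_real_)  # boundary: monotone
  j <- sel[i]
  denom <- v[j - 1] - 2 * v[j] + v[j + 1]
  offset <- if (abs(denom) < .Machine$double.eps * 100) 0 else
    0.5 * (v[j - 1] - v[j + 1]) / denom
  offset <- max(min(offset, 1), -1)
  d[j] + offset * (d[j + 1] - d[j])
}

# Sub-pixel leaf center from the comb profile: the midpoint of the leaf's
# two inplane boundary transitions (50% crossings between the adjacent
# peak/trough plateaus).  The comb extrema themselves are flat-topped, so
# an extremum position is ill-conditioned under pixel noise; the boundary
# edges are steep and localize to a few hundredths of a millimetre.  When
# only one boundary shows a transition (outermost leaves), the center is
# recovered from that edge and the nominal leaf width.
comb_leaf_center <- function(ys, v, mlc, l) {
  locate_edge <- function(b, halfwin) {
    # iterate: the 50% level from window min/max is biased when the edge
    # sits off-center (e.g. under collimator rotation); re-centering the
    # window on the current estimate converges in a few steps
    est <- b
    for (it in 1:4) {
      win <- which(ys >= est - halfwin & ys <= est + halfwin)
      if (length(win) < 5) return(NA_real_)
      lo <- min(v[win]); hi <- max(v[win])
      if (hi - lo < 0.2 * max(v)) return(NA_real_)  # no real transition here
      cr <- profile_crossings(ys[win], v[win], lo + 0.5 * (hi - lo))
      if (length(cr) == 0) return(NA_real_)
      est <- cr[which.min(abs(cr - est))]
    }
    est
  }
  w <- mlc$leaf_widths[l]
  hw1 <- 0.4 * if (l > 1) min(w, mlc$leaf_widths[l - 1]) else w
  hw2 <- 0.4 * if (l < mlc$n_leaf_pairs) min(w, mlc$leaf_widths[l + 1]) else w
  e1 <- locate_edge(mlc$leaf_edges[l], hw1)
  e2 <- locate_edge(mlc$leaf_edges[l + 1], hw2)
  if (is.finite(e1) && is.finite(e2)) (e1 + e2) / 2
  else if (is.finite(e1)) e1 + w / 2
  else if (is.finite(e2)) e2 - w / 2
  else NA_real_
}

#' Locate individual leaves from the comb patterns
#'
#' Samples a sub-pixel vertical profile at the comb measurement column on
#' each side of the image.  Protruding comb leaves appear as troughs and
#' retracted leaves as peaks, each sought within a window centered on the
#' leaf's nominal inplane interval (window half-width = 40% of the leaf
#' width); the center is then refined to the midpoint of the leaf's two
#' 50% boundary transitions, which is far better conditioned under pixel
#' noise than the flat-topped extremum itself.  Matched left/right centers
#' define each leaf's trajectory, which corrects for collimator-vs-panel
#' rotation.
#'
#' @param img an [epid_image] of a stakitt delivery.
#' @param plan the [stakitt_plan][build_default_plan].
#' @param mlc the [mlc_model].
#' @param cax [image_point] (raw frame): the sag-corrected CAX for this
#'   image's gantry angle.
#' @param step profile sampling step, mm.
#' @return data.frame of trajectories: `leaf`, `x_left`, `y_left`,
#'   `x_right`, `y_right` (raw-frame mm), `located` (logical).  Leaves
#'   whose comb window falls off the panel or whose extremum is absent are
#'   flagged `located = FALSE` and excluded from measurement.  More than
#'   20% unlocated leaves is a hard error.
#' @export
locate_leaves <- function(img, plan, mlc, cax, step = 0.01) {
  stopifnot(inherits(img, "epid_image"), inherits(plan, "stakitt_plan"),
            inherits(mlc, "mlc_model"), inherits(cax, "image_point"))
  ext <- image_extent_mm(img)
  side_centers <- function(side) {
    comb <- plan$comb[[side]]
    x <- cax$x + comb$column
    if (x < 0 || x > ext["xmax"])
      stop("locate_leaves: comb column for side '", side, "' is off the panel")
    y0 <- max(0, cax$y + min(mlc$leaf_edges) - 5)
    y1 <- min(ext["ymax"], cax$y + max(mlc$leaf_edges) + 5)
    pr <- sample_profile(img, image_point(x, y0), image_point(x, y1), step)
    ys <- pr$y_mm - cax$y   # pattern-frame inplane coordinate
    vapply(seq_len(mlc$n_leaf_pairs), function(l) {
      # a leaf is only measurable if its full inplane band is on the panel
      if (cax$y + mlc$leaf_edges[l] < 2 ||
          cax$y + mlc$leaf_edges[l + 1] > ext["ymax"] - 2)
        return(NA_real_)
      w <- 0.4 * mlc$leaf_widths[l]
      win <- mlc$leaf_centers[l] + c(-w, w)
      type <- if (l %% 2 == comb$protrude_parity) "trough" else "peak"
      if (!is.finite(extremum_center(ys, pr$value, win, type)))
        return(NA_real_)   # expected extremum absent -> not located
      comb_leaf_center(ys, pr$value, mlc, l)
    }, numeric(1))
  }
  yl <- side_centers("left")
  yr <- side_centers("right")
  located <- is.finite(yl) & is.finite(yr)
  if (mean(!located) > 0.2)
    stop("locate_leaves: ", sum(!located), " of ", length(located),
         " leaves could not be located (> 20%)")
  data.frame(
    leaf = seq_len(mlc$n_leaf_pairs),
    x_left = cax$x + plan$comb$left$column,
    y_left = cax$y + yl,
    x_right = cax$x + plan$comb$right$column,
    y_right = cax$y + yr,
    located = located
  )
}

# Gaussian low-pass along a profile (sigma in samples).  The kernel is
# symmetric, so the 50% crossing of an erf-shaped edge is preserved
# exactly; only pixel noise is suppressed.  Ends are pad-replicated.
smooth_profile <- function(v, sigma_samples) {
  if (sigma_samples <= 0) return(v)
  hw <- as.integer(ceiling(4 * sigma_samples))
  k <- stats::dnorm(seq(-hw, hw), sd = sigma_samples)
  k <- k / sum(k)
  vp <- c(rep(v[1], hw), v, rep(v[length(v)], hw))
  stats::convolve(vp, rev(k), type = "filter")
}

#' Measure leaf-tip positions along the leaf trajectories
#'
#' For every located leaf, a profile is sampled along its trajectory.
#' Per stakitt and per bank, the local maximum is taken in the stakitt's
#' nominal open window and the local minimum in the adjacent shielded
#' window (8 mm wide); the 50% level is `min + 0.5 * (max - min)` per
#' edge, and the crossing is found by inverse linear interpolation of the
#' densely sampled profile, within +/- 3 mm of the nominal tip.  The
#' per-bank radiation field offset (RFO) is then removed, and the result
#' expressed as crossplane mm from the CAX.
#'
#' The signed deviation uses the retraction-positive convention: positive
#' values mean the leaf is retracted away from the gap (gap expansion),
#' negative values mean it extends into the gap.
#'
#' @param img an [epid_image].
#' @param trajectories output of [locate_leaves()].
#' @param plan,mlc plan and MLC model.
#' @param cax [image_point]: sag-corrected CAX (raw frame).
#' @param rfo radiation field offset per bank, mm: scalar or
#'   `c(A = , B = )`.  Positive = radiation edge beyond the light-field
#'   edge, away from the gap.
#' @param step profile sampling step, mm.
#' @param search_halfwidth tip search half-window around nominal, mm.
#' @param smooth_sigma Gaussian low-pass sigma applied to the sampled
#'   profile, mm (0 disables).  A symmetric kernel leaves the 50%
#'   crossing of an erf edge unshifted while suppressing pixel noise.
#' @return data.frame with one row per leaf x bank x stakitt: `leaf`,
#'   `bank`, `stakitt`, `nominal_tip`, `measured_tip` (mm from CAX,
#'   light-field equivalent after RFO correction), `deviation` (mm,
#'   retraction-positive), `flag` (`"ok"`, `"edge_not_found"`,
#'   `"low_contrast"`, `"out_of_range"`).
#' @export
measure_tips <- function(img, trajectories, plan, mlc, cax,
                         rfo = c(A = 0, B = 0), step = 0.01,
                         search_halfwidth = 3, smooth_sigma = 0.3) {
  stopifnot(inherits(img, "epid_image"), inherits(cax, "image_point"))
  rfo <- rfo_pair(rfo)
  ns <- length(plan$stakitt_centers)
  half <- plan$stakitt_width / 2
  ext <- image_extent_mm(img)
  reach <- max(abs(c(plan$nominal_tips$A, plan$nominal_tips$B))) + 8
  res <- vector("list", nrow(trajectories))

  for (k in seq_len(nrow(trajectories))) {
    tr <- trajectories[k, ]
    if (!tr$located) next
    dirv <- c(tr$x_right - tr$x_left, tr$y_right - tr$y_left)
    dirv <- dirv / sqrt(sum(dirv^2))
    # foot of the CAX on the trajectory line: profile coordinate t is the
    # collimator-frame crossplane position relative to the CAX
    p0 <- c(tr$x_left, tr$y_left)
    t0 <- sum((c(cax$x, cax$y) - p0) * dirv)
    foot <- p0 + t0 * dirv
    tmin <- -reach; tmax <- reach
    a <- foot + tmin * dirv; b <- foot + tmax * dirv
    if (a[1] < 0 || b[1] > ext["xmax"] ||
        min(a[2], b[2]) < 0 || max(a[2], b[2]) > ext["ymax"]) next
    pr <- sample_profile(img, image_point(a[1], a[2]), image_point(b[1], b[2]),
                         step)
    tt <- tmin + pr$distance_mm
    v <- smooth_profile(pr$value, smooth_sigma / step)

    for (s in seq_len(ns)) {
      cs <- plan$stakitt_centers[s]
      vmax <- max(v[tt >= cs - half + 4 & tt <= cs + half - 4])
      for (bank in c("A", "B")) {
        nom <- plan$nominal_tips[[bank]][tr$leaf, s]
        shield <- if (bank == "A") {
          if (s == 1) c(nom - 8, nom) else
            c((plan$stakitt_centers[s - 1] + cs) / 2 - 4,
              (plan$stakitt_centers[s - 1] + cs) / 2 + 4)
        } else {
          if (s == ns) c(nom, nom + 8) else
            c((cs + plan$stakitt_centers[s + 1]) / 2 - 4,
              (cs + plan$stakitt_centers[s + 1]) / 2 + 4)
        }
        vmin <- min(v[tt >= shield[1] & tt <= shield[2]])
        level <- vmin + 0.5 * (vmax - vmin)
        win <- tt >= nom - search_halfwidth & tt <= nom + search_halfwidth
        cr <- profile_crossings(tt[win], v[win], level)
        flag <- "ok"
        if (vmax - vmin < 0.1 * vmax) flag <- "low_contrast"
        if (length(cr) == 0) {
          meas_raw <- NA_real_
          flag <- "edge_not_found"
        } else {
          meas_raw <- cr[which.min(abs(cr - nom))]
        }
        # RFO correction back to the light-field convention
        meas <- if (bank == "A") meas_raw + rfo[["A"]] else meas_raw - rfo[["B"]]
        dev <- if (bank == "A") -(meas - nom) else (meas - nom)
        if (is.finite(dev) && abs(dev) > 5 && flag == "ok") flag <- "out_of_range"
        res[[length(res) + 1]] <- data.frame(
          leaf = tr$leaf, bank = bank, stakitt = s,
          nominal_tip = nom, measured_tip = meas, deviation = dev,
          flag = flag
        )
      }
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop("measure_tips: no leaves could be measured")
  rownames(out) <- NULL
  out
}

#' Full stakitt image analysis
#'
#' Convenience orchestrator: locates the leaves from the comb patterns,
#' applies the sag-corrected CAX for the image's gantry angle, measures
#' all leaf tips, and returns the per-leaf measurement table.
#'
#' @param img an [epid_image] of a stakitt delivery.
#' @param plan,mlc plan and MLC model.
#' @param cax a [beam_cax][compute_cax] (session G0 reference) or a plain
#'   [image_point] already valid for this image.
#' @param sag optional `sag_map` (required when the image's gantry angle
#'   is not 0 and `cax` is a `beam_cax`).
#' @param rfo per-bank radiation field offset, mm.
#' @return An object of class `stakitt_analysis`: list with
#'   `measurements`, `trajectories`, `cax_used`, `gantry_angle`.
#' @export
analyze_stakitt <- function(img, plan, mlc, cax, sag = NULL,
                            rfo = c(A = 0, B = 0)) {
  cax_pt <- if (inherits(cax, "beam_cax"))
    cax_at_gantry(cax, sag, img$gantry_angle)
  else if (inherits(cax, "image_point")) cax
  else stop("analyze_stakitt: cax must be a beam_cax or an image_point")
  traj <- locate_leaves(img, plan, mlc, cax_pt)
  meas <- measure_tips(img, traj, plan, mlc, cax_pt, rfo = rfo)
  structure(
    list(measurements = meas, trajectories = traj, cax_used = cax_pt,
         gantry_angle = img$gantry_angle),
    class = "stakitt_analysis"
  )
}

#' @export
print.stakitt_analysis <- function(x, ...) {
  ok <- x$measurements$flag == "ok"
  cat(sprintf(
    "<stakitt_analysis> G%.0f: %d leaf-tip measurements (%d ok), %d/%d leaves located\n",
    x$gantry_angle, nrow(x$measurements), sum(ok),
    sum(x$trajectories$located), nrow(x$trajectories)))
  invisible(x)
}
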