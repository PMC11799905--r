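#' Simulator configuration
#'
#' Parameters of the synthetic EPID image generator.  Defaults emulate an
#' integrated 480 MU 6 MV acquisition on a 1024 x 1024 panel with 0.39 mm
#' pixels at the isocenter plane: an erf-shaped penumbra of sigma 1.2 mm
#' (typical for a 6 MV beam imaged on an amorphous-silicon panel) and
#' additive Gaussian pixel noise of 0.5% of the open-field signal (an
#' integrated 480 MU image is low-noise).
#'
#' @param penumbra_sigma erf edge width (Gaussian sigma), mm.
#' @param noise_sd additive Gaussian noise, as a fraction of the
#'   open-field signal.
#' @param rotation_deg collimator-vs-panel rotation, degrees (applied
#'   about the true CAX).
#' @param rfo_true true radiation field offset per bank, mm; positive
#'   means the 50% radiation edge lies beyond the light-field edge, away
#'   from the gap.
#' @param leaf_error list with numeric vectors `A` and `B` (one entry per
#'   leaf pair) of introduced tip errors in mm, positive = retracted away
#'   from the gap; `NULL` means no errors.
#' @param backlash list with vectors `A`, `B` of per-leaf mechanical play
#'   in mm; under gravity at lateral gantry angles the tip is displaced by
#'   half the play (see Details); `NULL` means none.
#' @param sag_true function `gantry_degrees -> c(dx, dy)` mm giving the
#'   true panel sag relative to gantry 0; default no sag.
#' @param narrowing_slope apparent radiological leaf-width change, mm per
#'   100 mm of tip travel, applied to leaves carrying a tip error (models
#'   the tongue-and-groove width modulation seen on narrow leaves).
#' @param jaw_asym jaw asymmetry `c(x1, x2, y1, y2)` mm for the square
#'   reference fields (positions added to the -/+ jaw edges in the
#'   collimator frame).
#' @param seed integer; the same seed yields byte-identical images.
#' @param panel_n panel size in pixels (square).
#' @param pixel_spacing mm per pixel at the isocenter plane.
#' @param open_signal open-field signal level (arbitrary units).
#' @param pedestal baseline signal added everywhere (keeps noisy shielded
#'   pixels non-negative, as a real panel's dark baseline does).
#'
#' @details
#' Backlash model: gravity displaces a leaf by `(g.u) * backlash / 2`
#' where the gravity projection `g.u` onto the leaf-travel axis is +1
#' (toward retraction) for bank A at gantry 90 and for bank B at gantry
#' 270, -1 in the mirrored cases, and 0 at gantry 0 and 180.  The
#' gantry-90-minus-gantry-270 position difference therefore equals the
#' full backlash value.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(penumbra_sigma = 1.2,
                       noise_sd = 0.005,
                       rotation_deg = 0,
                       rfo_true = c(A = 0, B = 0),
                       leaf_error = NULL,
                       backlash = NULL,
                       sag_true = NULL,
                       narrowing_slope = 0,
                       jaw_asym = c(x1 = 0, x2 = 0, y1 = 0, y2 = 0),
                       seed = 1L,
                       panel_n = 1024L,
                       pixel_spacing = 0.39,
                       open_signal = 1000,
                       pedestal = 50) {
  if (penumbra_sigma <= 0) stop("sim_config: penumbra_sigma must be > 0")
  if (noise_sd < 0) stop("sim_config: noise_sd must be >= 0")
  if (is.null(sag_true)) sag_true <- function(gantry) c(0, 0)
  structure(
    list(penumbra_sigma = penumbra_sigma, noise_sd = noise_sd,
         rotation_deg = rotation_deg, rfo_true = rfo_true,
         leaf_error = leaf_error, backlash = backlash, sag_true = sag_true,
         narrowing_slope = narrowing_slope, jaw_asym = jaw_asym,
         seed = as.integer(seed), panel_n = as.integer(panel_n),
         pixel_spacing = pixel_spacing, open_signal = open_signal,
         pedestal = pedestal),
    class = "sim_config"
  )
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

per_leaf_vec <- function(x, n, what) {
  if (is.null(x)) return(numeric(n))
  if (length(x) == 1) return(rep(as.numeric(x), n))
  if (length(x) != n) stop("sim_config: ", what, " must have one entry per leaf pair")
  as.numeric(x)
}

# coerce an RFO spec (scalar or named/unnamed pair) to c(A=, B=)
rfo_pair <- function(x) {
  if (is.null(x)) return(c(A = 0, B = 0))
  if (length(x) == 1) return(c(A = as.numeric(x), B = as.numeric(x)))
  if (!is.null(names(x)) && all(c("A", "B") %in% names(x)))
    return(c(A = as.numeric(x[["A"]]), B = as.numeric(x[["B"]])))
  c(A = as.numeric(x[[1]]), B = as.numeric(x[[2]]))
}

gravity_sign <- function(gantry, bank) {
  g <- normalize_angle(gantry)
  if (abs(g - 90) < 1e-9) return(if (bank == "A") 1 else -1)
  if (abs(g - 270) < 1e-9) return(if (bank == "A") -1 else 1)
  0
}

# erf-edge open fraction for an interval [lo, hi] evaluated at u
edge_open <- function(u, lo, hi, sigma) {
  stats::pnorm((u - lo) / sigma) - stats::pnorm((u - hi) / sigma)
}

#' Render a synthetic stakitt delivery image with ground truth
#'
#' Builds the integrated EPID image of the six-stakitt + comb delivery.
#' Each leaf edge is rendered as an erf transition of width
#' `penumbra_sigma` centered on the true radiation edge:
#' nominal light-field tip, displaced by the introduced leaf error, the
#' true RFO, and the gravity-projected half-backlash for the given gantry
#' angle.  A collimator-vs-panel rotation is applied about the true CAX,
#' then Gaussian noise is added.
#'
#' @param plan a [stakitt_plan][build_default_plan].
#' @param mlc the matching [mlc_model].
#' @param cfg a [sim_config].
#' @param gantry gantry angle, degrees.
#' @param cax_offset optional `c(dx, dy)` mm displacement of the true CAX
#'   from the panel center (on top of the sag model).
#' @return list with `image` (an [epid_image]), `truth` (data.frame with
#'   one row per leaf x bank x stakitt: `leaf`, `bank`, `stakitt`,
#'   `nominal_tip`, `true_tip` mm relative to the true CAX (radiation
#'   edge), and `true_dev`, the introduced deviation in the
#'   retraction-positive convention, RFO excluded), and `cax_true`
#'   (an [image_point] in the raw frame).
#' @export
render_stakitt_image <- function(plan, mlc, cfg = sim_config(), gantry = 0,
                                 cax_offset = c(0, 0)) {
  stopifnot(inherits(plan, "stakitt_plan"), inherits(mlc, "mlc_model"),
            inherits(cfg, "sim_config"))
  if (plan$mlc_name != mlc$name)
    stop("render_stakitt_image: plan was built for MLC '", plan$mlc_name, "'")
  n <- cfg$panel_n; ps <- cfg$pixel_spacing; sg <- cfg$penumbra_sigma
  nl <- mlc$n_leaf_pairs
  ns <- length(plan$stakitt_centers)
  err_a <- per_leaf_vec(cfg$leaf_error$A, nl, "leaf_error$A")
  err_b <- per_leaf_vec(cfg$leaf_error$B, nl, "leaf_error$B")
  bkl_a <- per_leaf_vec(cfg$backlash$A, nl, "backlash$A")
  bkl_b <- per_leaf_vec(cfg$backlash$B, nl, "backlash$B")
  rfo <- rfo_pair(cfg$rfo_true)
  rfo_a <- rfo[["A"]]; rfo_b <- rfo[["B"]]
  ga <- gravity_sign(gantry, "A"); gb <- gravity_sign(gantry, "B")

  dev_a <- err_a + ga * bkl_a / 2           # retraction-positive, per leaf
  dev_b <- err_b + gb * bkl_b / 2
  # radiation-edge x per leaf x stakitt (pattern frame, CAX origin)
  tip_a <- plan$nominal_tips$A - (dev_a + rfo_a)   # bank A retracts toward -x
  tip_b <- plan$nominal_tips$B + (dev_b + rfo_b)

  sag <- cfg$sag_true(gantry)
  center <- (n - 1) / 2 * ps
  cax <- c(center + cax_offset[1] + sag[1], center + cax_offset[2] + sag[2])
  u <- px_to_mm(0:(n - 1), ps) - cax[1]     # crossplane, pattern frame
  v <- px_to_mm(0:(n - 1), ps) - cax[2]     # inplane

  # the pattern must fit on the panel crossplane; off-panel *outer leaves*
  # (inplane) are tolerated -- they are simply not visible on the image
  reach <- max(abs(c(tip_a, tip_b, plan$comb$left$retract_tip,
                     plan$comb$right$retract_tip))) + 3 * sg
  if (reach > min(abs(min(u)), max(u)))
    stop("render_stakitt_image: leaf pattern extends beyond the panel")

  img <- matrix(0, n, n)
  for (l in seq_len(nl)) {
    wl <- stats::pnorm((v - mlc$leaf_edges[l]) / sg) -
          stats::pnorm((v - mlc$leaf_edges[l + 1]) / sg)
    if (max(wl) < 1e-12) next
    ol <- numeric(n)
    for (s in seq_len(ns))
      ol <- ol + edge_open(u, tip_a[l, s], tip_b[l, s], sg)
    # comb sub-fields
    cl <- plan$comb$left; cr <- plan$comb$right
    tip_l <- if (l %% 2 == cl$protrude_parity) cl$protrude_tip else cl$retract_tip
    tip_r <- if (l %% 2 == cr$protrude_parity) cr$protrude_tip else cr$retract_tip
    ol <- ol + edge_open(u, tip_l, cl$park_tip, sg)
    ol <- ol + edge_open(u, cr$park_tip, tip_r, sg)
    img <- img + outer(wl, ol)

  }

  # radiological width modulation of error-carrying (protruding) leaves:
  # the leaf's two inplane boundaries move inward by delta(u) =
  # narrowing_slope * u / 200 per side (a linear apparent-width change
  # along the travel direction), and the adjacent leaves' boundaries move
  # with them so the bank still tiles -- which is what makes the
  # protruding tongue render narrower, exactly as seen on the image.
  if (cfg$narrowing_slope != 0) {
    for (l in which(err_a != 0 | err_b != 0)) {
      jj <- max(1, l - 1):min(nl, l + 1)
      band <- c(mlc$leaf_edges[max(1, l - 1)] - 4 * sg,
                mlc$leaf_edges[min(nl, l + 1) + 1] + 4 * sg)
      rows <- which(v >= band[1] & v <= band[2])
      if (length(rows) == 0) next
      for (s in seq_len(ns)) {
        cols <- which(abs(u - plan$stakitt_centers[s]) <
                        plan$stakitt_width / 2 + 6 * sg)
        delta <- cfg$narrowing_slope * u[cols] / 200  # per-side shift, mm
        for (j in jj) {
          lo_base <- mlc$leaf_edges[j]; hi_base <- mlc$leaf_edges[j + 1]
          lo <- rep(lo_base, length(cols)); hi <- rep(hi_base, length(cols))
          if (j == l) { lo <- lo + delta; hi <- hi - delta }
          if (j == l - 1) hi <- hi + delta   # neighbour follows the boundary
          if (j == l + 1) lo <- lo - delta
          os <- edge_open(u[cols], tip_a[j, s], tip_b[j, s], sg)
          wb <- stats::pnorm((v[rows] - lo_base) / sg) -
                stats::pnorm((v[rows] - hi_base) / sg)
          wn <- stats::pnorm(outer(v[rows], lo, `-`) / sg) -
                stats::pnorm(outer(v[rows], hi, `-`) / sg)
          img[rows, cols] <- img[rows, cols] +
            sweep(wn, 2, os, `*`) - outer(wb, os)
        }
      }
    }
  }
  img <- pmin(pmax(img, 0), 1)

  if (cfg$rotation_deg != 0)
    img <- rotate_about(img, cfg$rotation_deg, ps, cax)

  img <- cfg$open_signal * img + cfg$pedestal
  if (cfg$noise_sd > 0) {
    img <- with_seed(cfg$seed, {
      img + stats::rnorm(length(img), sd = cfg$noise_sd * cfg$open_signal)
    })
    img <- pmax(img, 0)
  }

  truth <- data.frame(
    leaf = rep(rep(seq_len(nl), ns), 2),
    bank = rep(c("A", "B"), each = nl * ns),
    stakitt = rep(rep(seq_len(ns), each = nl), 2),
    nominal_tip = c(as.vector(plan$nominal_tips$A), as.vector(plan$nominal_tips$B)),
    true_tip = c(as.vector(tip_a), as.vector(tip_b)),
    true_dev = c(rep(dev_a, ns), rep(dev_b, ns))
  )
  list(
    image = epid_image(img, ps, 100, gantry, cfg$rotation_deg %% 360, "integrated"),
    truth = truth,
    cax_true = image_point(cax[1], cax[2])
  )
}

# resample an image rotated by theta degrees about a fixed point (mm)
rotate_about <- function(px, theta, spacing, center_mm) {
  n_r <- nrow(px); n_c <- ncol(px)
  th <- theta * pi / 180
  x <- px_to_mm(0:(n_c - 1), spacing) - center_mm[1]
  y <- px_to_mm(0:(n_r - 1), spacing) - center_mm[2]
  X <- matrix(x, n_r, n_c, byrow = TRUE)
  Y <- matrix(y, n_r, n_c)
  xs <- cos(th) * X + sin(th) * Y + center_mm[1]   # inverse rotation
  ys <- -sin(th) * X + cos(th) * Y + center_mm[2]
  cs <- pmin(pmax(mm_to_px(xs, spacing), 0), n_c - 1)
  rs <- pmin(pmax(mm_to_px(ys, spacing), 0), n_r - 1)
  matrix(interp_bicubic(px, as.vector(cs), as.vector(rs)), n_r, n_c)
}

#' Render the collimator 90/270 reference field pair
#'
#' Two jaw-defined 10 x 10 cm erf-edged fields at gantry 0, collimator 90
#' and 270, whose collimator-rotation-axis projection sits at the
#' requested offset from the panel center.  A jaw asymmetry displaces the
#' individual field centers, but the 180 degree collimator rotation flips
#' its sign between the two images, so the C90/C270 average recovers the
#' axis.
#'
#' @param cfg a [sim_config] (uses `jaw_asym`, noise, penumbra, panel).
#' @param offset `c(dx, dy)` mm of the collimator axis from panel center.
#' @param field_size field side length at iso, mm.
#' @return list with `c90`, `c270` ([epid_image]s) and `axis_true`
#'   (an [image_point], raw frame).
#' @export
render_cax_pair <- function(cfg = sim_config(), offset = c(0, 0),
                            field_size = 100) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$panel_n; ps <- cfg$pixel_spacing
  center <- (n - 1) / 2 * ps
  axis <- c(center + offset[1], center + offset[2])
  ext <- (n - 1) * ps
  if (any(axis < 0) || any(axis > ext))
    stop("render_cax_pair: requested axis offset is outside the panel")
  a <- cfg$jaw_asym
  # field box in the collimator frame
  half <- field_size / 2
  cx <- (a[["x1"]] + a[["x2"]]) / 2; wx <- half + (a[["x2"]] - a[["x1"]]) / 2
  cy <- (a[["y1"]] + a[["y2"]]) / 2; wy <- half + (a[["y2"]] - a[["y1"]]) / 2
  one <- function(coll, seed_shift) {
    th <- coll * pi / 180
    cc <- c(cos(th) * cx - sin(th) * cy, sin(th) * cx + cos(th) * cy)
    # square stays axis-aligned at 90/270; x/y half-widths swap
    w <- c(wy, wx)
    u <- px_to_mm(0:(n - 1), ps) - (axis[1] + cc[1])
    v <- px_to_mm(0:(n - 1), ps) - (axis[2] + cc[2])
    fx <- edge_open(u, -w[1], w[1], cfg$penumbra_sigma)
    fy <- edge_open(v, -w[2], w[2], cfg$penumbra_sigma)
    img <- cfg$open_signal * outer(fy, fx) + cfg$pedestal
    if (cfg$noise_sd > 0) {
      img <- with_seed(cfg$seed + seed_shift, {
        img + stats::rnorm(length(img), sd = cfg$noise_sd * cfg$open_signal)
      })
      img <- pmax(img, 0)
    }
    epid_image(img, ps, 100, 0, coll, "integrated")
  }
  list(c90 = one(90, 101L), c270 = one(270, 202L),
       axis_true = image_point(axis[1], axis[2]))
}

#' Render cone-arc cine frames for sag-map construction
#'
#' A circular erf-edged field (stereotactic cone) whose center follows the
#' true sag model as the gantry sweeps a full 360 degree arc; each frame
#' is tagged with its gantry angle.
#'
#' @param cfg a [sim_config] (`sag_true` drives the motion).
#' @param n_frames number of cine frames (>= 8) spanning 360 degrees.
#' @param radius cone field radius at iso, mm.
#' @return list of [epid_image] cine frames.
#' @export
render_cone_arc <- function(cfg = sim_config(), n_frames = 48, radius = 15) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_frames < 8) stop("render_cone_arc: need at least 8 frames")
  n <- cfg$panel_n; ps <- cfg$pixel_spacing
  center <- (n - 1) / 2 * ps
  angles <- seq(0, 360, length.out = n_frames + 1)[seq_len(n_frames)]
  lapply(seq_along(angles), function(i) {
    g <- angles[i]
    sag <- cfg$sag_true(g)
    u <- px_to_mm(0:(n - 1), ps) - (center + sag[1])
    v <- px_to_mm(0:(n - 1), ps) - (center + sag[2])
    r <- sqrt(outer(v^2, u^2, `+`))
    img <- cfg$open_signal *
      stats::pnorm((radius - r) / cfg$penumbra_sigma) + cfg$pedestal
    if (cfg$noise_sd > 0) {
      img <- with_seed(cfg$seed + 1000L + i, {
        img + stats::rnorm(length(img), sd = cfg$noise_sd * cfg$open_signal)
      })
      img <- pmax(img, 0)
    }
    epid_image(img, ps, 100, g, 0, "cine_frame")
  })
}
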