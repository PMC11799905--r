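#' Build the default stakitt test plan
#'
#' The test pattern consists of six evenly distributed 2 cm wide
#' MLC-defined sub-fields ("stakitts") with 4 cm center-to-center spacing,
#' delivered step-and-shoot with 480 MU at 6 MV, plus comb patterns on
#' both sides of the field formed by alternating protruding and retracted
#' leaves (used to locate individual leaves in the image).  A carriage
#' shift is flagged between the two central stakitts.
#'
#' Nominal tip positions use the light-field convention (what a DICOM plan
#' encodes); the light/radiation field discrepancy is carried entirely by
#' the per-bank radiation field offset (RFO) applied at measurement time.
#'
#' Comb geometry (the published pattern gives no dimensions; these are this
#' package's declared defaults): protruding tips at ±124 mm, retracted tips
#' at ±154 mm, opposing bank parked at ±118 mm, and the comb measurement
#' column at ±134 mm.  They clear the outermost stakitt edge (±110 mm) by
#' 8 mm, which keeps the shielded valley between stakitt and comb deep
#' enough for stable local minima.
#'
#' @param mlc an [mlc_model].
#' @param stakitt_centers crossplane stakitt centers, mm (default six at
#'   -100, -60, -20, +20, +60, +100).
#' @param stakitt_width open gap width per stakitt, mm (default 20).
#' @param mu monitor units (default 480).
#' @param energy nominal beam (default `"6MV"`).
#' @return An object of class `stakitt_plan` with fields
#'   `stakitt_centers`, `stakitt_width`, `nominal_tips` (list with `A` and
#'   `B`, each an `n_leaf_pairs x n_stakitts` matrix of light-field tip
#'   positions in mm), `comb` (per-side protrude/retract/park tips, the
#'   measurement column, and the protruding leaf parity),
#'   `carriage_shift_after`, `mu`, `energy`, `mlc_name`.
#' @export
build_default_plan <- function(mlc,
                               stakitt_centers = c(-100, -60, -20, 20, 60, 100),
                               stakitt_width = 20,
                               mu = 480,
                               energy = "6MV") {
  stopifnot(inherits(mlc, "mlc_model"))
  ns <- length(stakitt_centers)
  half <- stakitt_width / 2
  tips_a <- matrix(rep(stakitt_centers - half, each = mlc$n_leaf_pairs),
                   nrow = mlc$n_leaf_pairs)
  tips_b <- matrix(rep(stakitt_centers + half, each = mlc$n_leaf_pairs),
                   nrow = mlc$n_leaf_pairs)
  plan <- structure(
    list(
      mlc_name = mlc$name,
      stakitt_centers = as.numeric(stakitt_centers),
      stakitt_width = stakitt_width,
      nominal_tips = list(A = tips_a, B = tips_b),
      comb = list(
        left = list(protrude_tip = -124, retract_tip = -154, park_tip = -118,
                    column = -134, protrude_parity = 1L),
        right = list(protrude_tip = 124, retract_tip = 154, park_tip = 118,
                     column = 134, protrude_parity = 0L)
      ),
      carriage_shift_after = as.integer(ceiling(ns / 2)),
      mu = mu,
      energy = energy
    ),
    class = "stakitt_plan"
  )
  validate_plan(plan, warn = FALSE)
  plan
}

#' @export
print.stakitt_plan <- function(x, ...) {
  cat(sprintf(
    "<stakitt_plan> %s: %d stakitts at {%s} mm, width %.0f mm, %g MU %s, carriage shift after stakitt %d\n",
    x$mlc_name, length(x$stakitt_centers),
    paste(x$stakitt_centers, collapse = ", "),
    x$stakitt_width, x$mu, x$energy, x$carriage_shift_after))
  invisible(x)
}

#' Validate a stakitt plan
#'
#' Hard-errors on structural defects (missing fields, closed gaps); emits
#' warnings for departures from the canonical six-stakitt layout so that
#' hand-edited plans can still be analyzed.
#'
#' @param plan a [stakitt_plan][build_default_plan].
#' @param warn warn (TRUE) or stay silent (FALSE) on non-fatal departures.
#' @return `plan`, invisibly.
#' @export
validate_plan <- function(plan, warn = TRUE) {
  req <- c("mlc_name", "stakitt_centers", "stakitt_width", "nominal_tips",
           "comb", "carriage_shift_after", "mu")
  for (f in req) {
    if (is.null(plan[[f]])) stop("stakitt_plan: missing field '", f, "'")
  }
  if (!all(plan$nominal_tips$A < plan$nominal_tips$B))
    stop("stakitt_plan: every bank-A tip must sit below its bank-B tip (open gap)")
  if (warn) {
    ns <- length(plan$stakitt_centers)
    if (ns != 6)
      warning("stakitt_plan: ", ns, " stakitts (canonical layout has 6)")
    sp <- diff(sort(plan$stakitt_centers))
    if (ns > 1 && any(abs(sp - 40) > 1e-9))
      warning("stakitt_plan: stakitt spacing differs from the canonical 40 mm")
  }
  invisible(plan)
}

#' Write / read a stakitt plan as JSON
#'
#' Lossless round trip through a flat JSON schema (matrices stored
#' row-per-leaf).  Reading validates the plan and warns on non-canonical
#' layouts without refusing to proceed.
#'
#' @param plan a [stakitt_plan][build_default_plan].
#' @param path file path.
#' @return `write_plan` returns `path` invisibly; `read_plan` the plan.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "stakitt_plan"))
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  if (!file.exists(path)) stop("read_plan: file not found: ", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("stakitt_centers", "stakitt_width", "nominal_tips", "comb",
              "carriage_shift_after", "mu", "mlc_name")) {
    if (is.null(p[[f]])) stop("read_plan: plan file missing field '", f, "'")
  }
  p$nominal_tips$A <- as.matrix(p$nominal_tips$A)
  p$nominal_tips$B <- as.matrix(p$nominal_tips$B)
  p$carriage_shift_after <- as.integer(p$carriage_shift_after)
  p$comb$left$protrude_parity <- as.integer(p$comb$left$protrude_parity)
  p$comb$right$protrude_parity <- as.integer(p$comb$right$protrude_parity)
  plan <- structure(p, class = "stakitt_plan")
  validate_plan(plan, warn = TRUE)
  plan
}

#' Human-readable plan summary table
#'
#' @param plan a [stakitt_plan][build_default_plan].
#' @return data.frame with one row per stakitt.
#' @export
plan_summary <- function(plan) {
  data.frame(
    stakitt = seq_along(plan$stakitt_centers),
    center_mm = plan$stakitt_centers,
    tip_a_mm = plan$stakitt_centers - plan$stakitt_width / 2,
    tip_b_mm = plan$stakitt_centers + plan$stakitt_width / 2,
    width_mm = plan$stakitt_width,
    after_carriage_shift = seq_along(plan$stakitt_centers) > plan$carriage_shift_after
  )
}
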