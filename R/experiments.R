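# Experiment harnesses: simulated counterparts of the bench evaluation --
# algorithm consistency, MLC repeatability, sensitivity to introduced
# errors, and the gantry-angle backlash use case.  All run entirely on the
# synthetic image generator, so the injected truth is known exactly.

#' Algorithm consistency check
#'
#' Runs the full analysis `n_runs` times on one fixed image and reports
#' the maximum absolute difference in measured leaf positions across runs
#' (the algorithm is deterministic, so this should be exactly zero).
#'
#' @param img,plan,mlc,cax,rfo as for [analyze_stakitt()].
#' @param n_runs number of repeated analyses.
#' @return list with `max_abs_diff` (mm), `decimal_places` (agreement in
#'   decimal places, capped at 15), and `runs` (list of measurement
#'   tables).
#' @export
consistency_experiment <- function(img, plan, mlc, cax, rfo = c(A = 0, B = 0),
                                   n_runs = 5) {
  runs <- lapply(seq_len(n_runs), function(i)
    analyze_stakitt(img, plan, mlc, cax, rfo = rfo)$measurements)
  ref <- runs[[1]]$measured_tip
  mad <- max(vapply(runs[-1], function(m)
    max(abs(m$measured_tip - ref), na.rm = TRUE), numeric(1)), 0)
  dp <- if (mad == 0) 15 else max(0, floor(-log10(mad)))
  list(max_abs_diff = mad, decimal_places = min(dp, 15), runs = runs)
}

#' MLC repeatability experiment
#'
#' Renders `n_runs` images of the same (error-free) truth with
#' independent noise realizations, analyzes each, and reports the
#' per-leaf-position 3 SD of the measured positions averaged over all
#' leaf x bank x stakitt samples -- the repeatability metric.
#'
#' @param cfg a [sim_config]; run `i` uses seed `cfg$seed + i`.
#' @param plan,mlc plan and MLC model (defaults: canonical Millennium120).
#' @param n_runs number of consecutive simulated acquisitions.
#' @return list with `mean_3sd` (mm), `per_position` data.frame (leaf,
#'   bank, stakitt, sd, three_sd).
#' @export
repeatability_experiment <- function(cfg = sim_config(),
                                     plan = NULL, mlc = NULL, n_runs = 5) {
  if (is.null(mlc)) mlc <- mlc_model("millennium120")
  if (is.null(plan)) plan <- build_default_plan(mlc)
  tabs <- lapply(seq_len(n_runs), function(i) {
    ci <- cfg; ci$seed <- cfg$seed + i
    sim <- render_stakitt_image(plan, mlc, ci, gantry = 0)
    analyze_stakitt(sim$image, plan, mlc, sim$cax_true)$measurements
  })
  key <- function(m) paste(m$leaf, m$bank, m$stakitt)
  ref <- tabs[[1]]
  mat <- vapply(tabs, function(m)
    m$measured_tip[match(key(ref), key(m))], numeric(nrow(ref)))
  ok <- Reduce(`&`, lapply(tabs, function(m) m$flag == "ok"))
  sds <- apply(mat[ok, , drop = FALSE], 1, stats::sd)
  per <- data.frame(leaf = ref$leaf[ok], bank = ref$bank[ok],
                    stakitt = ref$stakitt[ok], sd = sds, three_sd = 3 * sds)
  list(mean_3sd = mean(per$three_sd), per_position = per)
}

# default error-leaf choices: 5 non-adjacent inner leaves / 5 adjacent pairs
default_error_leaves <- function(mlc) {
  il <- inner_leaves(mlc)
  mid <- il[ceiling(length(il) / 2)]
  mid + c(-8, -4, 0, 4, 8)
}

default_gap_leaves <- function(mlc) {
  il <- inner_leaves(mlc)
  mid <- il[ceiling(length(il) / 2)]
  mid + (-2:2)
}

#' Sensitivity experiment: recovery of introduced leaf and gap errors
#'
#' For each error magnitude, renders a stakitt image with the error
#' injected -- on 5 non-adjacent inner leaves of one bank for position
#' errors (mimicking random leaf errors), or split across both leaves of
#' 5 adjacent pairs for gap-width errors (mimicking systematic errors) --
#' analyzes it, and reports the measured-minus-injected statistics pooled
#' over the errored leaves and all stakitts.
#'
#' @param magnitudes injected error magnitudes, mm (sign follows the
#'   retraction-positive convention for position errors; positive gap
#'   errors widen the gap).
#' @param cfg a [sim_config] (its `leaf_error` field is overwritten).
#' @param plan,mlc plan and MLC model (defaults: canonical Millennium120).
#' @param mode `"position"` or `"gap"`.
#' @param leaves leaf indices to error; defaults as above.
#' @return data.frame with one row per magnitude: `injected`,
#'   `mean_measured_dev`, `mean_error` (measured - injected), `sd_error`,
#'   `worst_abs_error`, `n`.
#' @export
sensitivity_experiment <- function(magnitudes = c(-1.5, -1, -0.5, -0.1,
                                                  0.1, 0.5, 1, 1.5),
                                   cfg = sim_config(),
                                   plan = NULL, mlc = NULL,
                                   mode = c("position", "gap"),
                                   leaves = NULL) {
  mode <- match.arg(mode)
  if (is.null(mlc)) mlc <- mlc_model("millennium120")
  if (is.null(plan)) plan <- build_default_plan(mlc)
  if (is.null(leaves))
    leaves <- if (mode == "position") default_error_leaves(mlc)
              else default_gap_leaves(mlc)
  rows <- lapply(seq_along(magnitudes), function(i) {
    mag <- magnitudes[i]
    err_a <- numeric(mlc$n_leaf_pairs); err_b <- numeric(mlc$n_leaf_pairs)
    if (mode == "position") {
      err_a[leaves] <- mag
    } else {
      err_a[leaves] <- mag / 2
      err_b[leaves] <- mag / 2
    }
    ci <- cfg
    ci$leaf_error <- list(A = err_a, B = err_b)
    ci$seed <- cfg$seed + 10L * i
    sim <- render_stakitt_image(plan, mlc, ci, gantry = 0)
    an <- analyze_stakitt(sim$image, plan, mlc, sim$cax_true)
    if (mode == "position") {
      m <- an$measurements
      m <- m[m$bank == "A" & m$leaf %in% leaves & m$flag == "ok", ]
      err <- m$deviation - mag
      mean_meas <- mean(m$deviation)
    } else {
      g <- summarize_stakitt(an)$gaps
      g <- g[g$leaf %in% leaves, ]
      err <- g$gap_deviation - mag
      mean_meas <- mean(g$gap_deviation)
    }
    data.frame(injected = mag, mean_measured_dev = mean_meas,
               mean_error = mean(err), sd_error = stats::sd(err),
               worst_abs_error = max(abs(err)), n = length(err))
  })
  do.call(rbind, rows)
}

#' Backlash experiment: bank offsets at the lateral gantry angles
#'
#' Injects per-bank mechanical backlash, renders stakitt images at
#' gantry 90, 0 and 270 (with the sag model applied and the analysis
#' using the sag-corrected CAX), and reports the per-bank mean deviation
#' at each angle together with the G90 - G270 mean differences.  With the
#' gravity model, the per-bank G90 - G270 difference equals the injected
#' backlash while the gap deviation stays constant across angles.
#'
#' @param backlash_per_bank `c(A = , B = )` mm of mechanical play.
#' @param cfg a [sim_config] (its `backlash` field is overwritten).
#' @param plan,mlc plan and MLC model (defaults: canonical Millennium120).
#' @param use_sag_map build the sag map from a simulated cone arc and use
#'   the sag-corrected CAX (TRUE), or use the known true CAX per angle.
#' @return list with `per_angle` (data.frame: gantry, bank mean/SD, gap
#'   mean), `mean_diff_g90_g270` (named vector, banks A and B),
#'   `gap_diff_g90_g270`.
#' @export
backlash_experiment <- function(backlash_per_bank = c(A = 0.27, B = 0.28),
                                cfg = sim_config(),
                                plan = NULL, mlc = NULL,
                                use_sag_map = TRUE) {
  if (is.null(mlc)) mlc <- mlc_model("millennium120")
  if (is.null(plan)) plan <- build_default_plan(mlc)
  ci <- cfg
  ci$backlash <- list(A = rep(backlash_per_bank[["A"]], mlc$n_leaf_pairs),
                      B = rep(backlash_per_bank[["B"]], mlc$n_leaf_pairs))

  cax_for <- if (use_sag_map) {
    pair <- render_cax_pair(ci)
    cax0 <- compute_cax(pair$c90, pair$c270)
    sag <- build_sag_map(render_cone_arc(ci, n_frames = 12))
    function(g) cax_at_gantry(cax0, sag, g)
  } else NULL

  angles <- c(90, 0, 270)
  per <- lapply(seq_along(angles), function(i) {
    g <- angles[i]
    cg <- ci; cg$seed <- ci$seed + 100L * i
    sim <- render_stakitt_image(plan, mlc, cg, gantry = g)
    cax_pt <- if (use_sag_map) cax_for(g) else sim$cax_true
    res <- summarize_stakitt(analyze_stakitt(sim$image, plan, mlc, cax_pt))
    data.frame(
      gantry = g,
      mean_a = res$bank_stats$mean[res$bank_stats$bank == "A"],
      sd_a = res$bank_stats$sd[res$bank_stats$bank == "A"],
      mean_b = res$bank_stats$mean[res$bank_stats$bank == "B"],
      sd_b = res$bank_stats$sd[res$bank_stats$bank == "B"],
      gap_mean = res$gap_mean
    )
  })
  per <- do.call(rbind, per)
  g90 <- per[per$gantry == 90, ]; g270 <- per[per$gantry == 270, ]
  list(
    per_angle = per,
    mean_diff_g90_g270 = c(A = g90$mean_a - g270$mean_a,
                           B = g90$mean_b - g270$mean_b),
    gap_diff_g90_g270 = g90$gap_mean - g270$gap_mean
  )
}
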