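test_that("extremum_center refines analytic extrema to sub-step accuracy", {
  # symmetric triangular trough centered at 12.7
  d <- seq(0, 25, by = 0.05)
  v <- abs(d - 12.7) * 3 + 10
  expect_lt(abs(extremum_center(d, v, c(9, 16), "trough") - 12.7), 0.05)

  # analytic Gaussian dip centered at 3.456 mm (dense-scan oracle)
  d2 <- seq(0, 8, by = 0.01)
  v2 <- 100 - 80 * exp(-(d2 - 3.456)^2 / (2 * 0.8^2))
  dd <- seq(2, 5, by = 1e-4)
  oracle <- dd[which.min(100 - 80 * exp(-(dd - 3.456)^2 / (2 * 0.8^2)))]
  got <- extremum_center(d2, v2, c(2, 5), "trough")
  expect_lt(abs(got - oracle), 0.01)

  # Gaussian peak
  expect_lt(abs(extremum_center(d2, -v2, c(2, 5), "peak") - 3.456), 0.01)

  # monotone profile in the window -> not located
  expect_true(is.na(extremum_center(d2, d2 * 2, c(2, 5), "trough")))
  # window outside the profile span -> not located
  expect_true(is.na(extremum_center(d2, v2, c(7, 9.5), "trough")))
})

test_that("comb localization reproduces leaf centers and rotations", {
  mlc <- fix_mlc(); plan <- fix_plan()
  sim <- fix_sim0()
  tr <- locate_leaves(sim$image, plan, mlc, sim$cax_true)
  loc <- tr[tr$located, ]
  # the two outermost Millennium leaves hang off the panel
  expect_equal(nrow(loc), 58)
  expect_false(any(tr$located[c(1, 60)]))
  exp_y <- sim$cax_true$y + mlc$leaf_centers[loc$leaf]
  expect_lt(max(abs(loc$y_left - exp_y)), 0.05)
  expect_lt(max(abs(loc$y_right - exp_y)), 0.05)

  # 0.5 degree collimator-vs-panel rotation: trajectory slopes match
  simr <- fix_get("simr", function()
    render_stakitt_image(plan, mlc, sim_config(noise_sd = 0,
                                               rotation_deg = 0.5)))
  trr <- locate_leaves(simr$image, plan, mlc, simr$cax_true)
  sl <- (trr$y_right - trr$y_left) / (trr$x_right - trr$x_left)
  expect_lt(max(abs(sl[trr$located] / tan(0.5 * pi / 180) - 1)), 0.05)
})

test_that("null-case tips measure exactly nominal at zero noise", {
  m <- ok_meas(fix_an0())
  expect_gte(nrow(m), 690)
  expect_lt(max(abs(m$deviation)), 0.01)
})

test_that("an injected single-leaf error is recovered, others unaffected", {
  plan <- fix_plan(); mlc <- fix_mlc()
  err <- list(A = replace(numeric(60), 25, -0.5), B = numeric(60))
  sim <- render_stakitt_image(plan, mlc,
                              sim_config(noise_sd = 0, leaf_error = err))
  m <- ok_meas(analyze_stakitt(sim$image, plan, mlc, sim$cax_true))
  hit <- m[m$leaf == 25 & m$bank == "A", ]
  expect_equal(nrow(hit), 6)
  expect_true(all(abs(hit$deviation - (-0.5)) < 0.03))
  rest <- m[!(m$leaf == 25 & m$bank == "A"), ]
  expect_lt(max(abs(rest$deviation)), 0.03)
})

test_that("RFO is corrected symmetrically for both banks", {
  plan <- fix_plan(); mlc <- fix_mlc()
  cfg <- sim_config(noise_sd = 0, rfo_true = c(A = 0.4, B = 0.25))
  sim <- render_stakitt_image(plan, mlc, cfg)
  # analyzing with the matching RFO recovers zero deviations
  an <- analyze_stakitt(sim$image, plan, mlc, sim$cax_true,
                        rfo = c(A = 0.4, B = 0.25))
  expect_lt(max(abs(ok_meas(an)$deviation)), 0.01)
  # ignoring the RFO biases each bank by its offset, in the retraction sense
  an0 <- analyze_stakitt(sim$image, plan, mlc, sim$cax_true)
  m0 <- ok_meas(an0)
  expect_equal(mean(m0$deviation[m0$bank == "A"]), 0.4, tolerance = 0.01)
  expect_equal(mean(m0$deviation[m0$bank == "B"]), 0.25, tolerance = 0.01)
})

test_that("measured deviations are invariant to rotation and CAX shifts", {
  plan <- fix_plan(); mlc <- fix_mlc()
  m0 <- ok_meas(fix_an0())
  simr <- fix_get("simr", function()
    render_stakitt_image(plan, mlc, sim_config(noise_sd = 0,
                                               rotation_deg = 0.5)))
  mr <- ok_meas(analyze_stakitt(simr$image, plan, mlc, simr$cax_true))
  common <- intersect(meas_key(m0), meas_key(mr))
  expect_gt(length(common), 650)
  d <- m0$deviation[match(common, meas_key(m0))] -
       mr$deviation[match(common, meas_key(mr))]
  expect_lt(max(abs(d)), 0.02)

  # shifting the panel (and hence the CAX) by 2 mm moves absolute tips by
  # 2 mm but leaves deviations untouched
  sims <- render_stakitt_image(plan, mlc, sim_config(noise_sd = 0),
                               cax_offset = c(2, 0))
  ms <- ok_meas(analyze_stakitt(sims$image, plan, mlc, sims$cax_true))
  common <- intersect(meas_key(m0), meas_key(ms))
  dd <- m0$deviation[match(common, meas_key(m0))] -
        ms$deviation[match(common, meas_key(ms))]
  expect_lt(max(abs(dd)), 0.01)
})

test_that("missing edges and bad CAX inputs are reported", {
  plan <- fix_plan(); mlc <- fix_mlc()
  sim <- fix_sim0()
  # a grossly wrong nominal tip puts the 50% crossing outside the search
  # window: flagged, not silently mismeasured
  bad_plan <- plan
  bad_plan$nominal_tips$A[30, 2] <- bad_plan$nominal_tips$A[30, 2] - 5
  tr <- locate_leaves(sim$image, bad_plan, mlc, sim$cax_true)
  m <- measure_tips(sim$image, tr, bad_plan, mlc, sim$cax_true)
  expect_equal(m$flag[m$leaf == 30 & m$bank == "A" & m$stakitt == 2],
               "edge_not_found")
  expect_error(analyze_stakitt(sim$image, plan, mlc, cax = 42),
               "beam_cax or an image_point")
})
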