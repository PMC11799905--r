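test_that("same seed renders byte-identical images; truth bookkeeping holds", {
  plan <- fix_plan(); mlc <- fix_mlc()
  cfg <- sim_config(seed = 5)
  s1 <- render_stakitt_image(plan, mlc, cfg)
  s2 <- render_stakitt_image(plan, mlc, cfg)
  expect_identical(s1$image$pixels, s2$image$pixels)

  s3 <- render_stakitt_image(plan, mlc, sim_config(seed = 6))
  expect_false(identical(s1$image$pixels, s3$image$pixels))
  # different seeds: same noise statistics within Monte-Carlo error
  d <- s1$image$pixels - s3$image$pixels
  expect_equal(sd(d) / sqrt(2), 0.005 * 1000, tolerance = 0.05)

  # null config: ground-truth deviations identically zero
  expect_true(all(fix_sim0()$truth$true_dev == 0))

  # +1 mm error on one bank-A leaf retracts that leaf's true tip by 1 mm
  err <- list(A = replace(numeric(60), 31, 1), B = numeric(60))
  se <- render_stakitt_image(plan, mlc, sim_config(noise_sd = 0,
                                                   leaf_error = err))
  tr <- se$truth
  moved <- tr[tr$leaf == 31 & tr$bank == "A", ]
  expect_true(all(moved$true_dev == 1))
  expect_equal(moved$true_tip, moved$nominal_tip - 1)
  expect_true(all(tr$true_dev[!(tr$leaf == 31 & tr$bank == "A")] == 0))
})

test_that("rendered 50% edge crossing matches a dense analytic scan", {
  # oracle: 1e-4 mm scan of the analytic erf edge model
  sim <- fix_sim0()
  img <- sim$image; cax <- sim$cax_true
  tip_true <- -110  # stakitt 1, bank A nominal (no errors injected)
  y <- cax$y + 2.5  # center of leaf 31 (5 mm leaf at pattern y = 2.5)
  pr <- sample_profile(img, image_point(cax$x - 118, y),
                       image_point(cax$x - 95, y), step = 0.01)
  x <- pr$x_mm - cax$x
  lo <- min(pr$value[x < -112]); hi <- max(pr$value[x > -105])
  cr <- profile_crossings(x, pr$value, lo + 0.5 * (hi - lo))
  meas <- cr[which.min(abs(cr - tip_true))]

  xs <- seq(tip_true - 5, tip_true + 5, by = 1e-4)
  oracle <- xs[which.min(abs(pnorm((xs - tip_true) / 1.2) - 0.5))]
  expect_lt(abs(meas - oracle), 0.005)
})

test_that("backlash shifts true tips between G90 and G270 by its value", {
  plan <- fix_plan(); mlc <- fix_mlc()
  cfg <- sim_config(noise_sd = 0,
                    backlash = list(A = rep(0.27, 60), B = numeric(60)))
  t90 <- render_stakitt_image(plan, mlc, cfg, gantry = 90)$truth
  t270 <- render_stakitt_image(plan, mlc, cfg, gantry = 270)$truth
  dA <- t90$true_dev[t90$bank == "A"] - t270$true_dev[t270$bank == "A"]
  expect_true(all(abs(dA - 0.27) < 1e-12))
  expect_true(all(t90$true_dev[t90$bank == "B"] == 0))
  # zero at gantry 0
  t0 <- render_stakitt_image(plan, mlc, cfg, gantry = 0)$truth
  expect_true(all(t0$true_dev == 0))
})

test_that("narrowing shrinks the protruding error-leaf monotonically with x", {
  mlc <- mlc_model("hdmlc")
  plan <- build_default_plan(mlc)
  err <- list(A = replace(numeric(60), 30, -1), B = numeric(60))
  cfg <- sim_config(noise_sd = 0, leaf_error = err, narrowing_slope = 0.8)
  sim <- render_stakitt_image(plan, mlc, cfg)
  img <- sim$image; cax <- sim$cax_true
  yc <- mlc$leaf_centers[30]
  # apparent inplane width of the protruding tongue, per stakitt: distance
  # between the two 50% crossings of a vertical profile through the tongue
  widths <- vapply(seq_along(plan$stakitt_centers), function(s) {
    xq <- cax$x + plan$nominal_tips$A[30, s] + 0.5  # just inside the tongue
    pr <- sample_profile(img, image_point(xq, cax$y + yc - 6),
                         image_point(xq, cax$y + yc + 6), step = 0.01)
    v <- pr$value
    lev <- min(v) + 0.5 * (max(v) - min(v))
    cr <- profile_crossings(pr$distance_mm, v, lev)
    if (length(cr) < 2) return(NA_real_)
    max(cr) - min(cr)
  }, numeric(1))
  expect_true(all(is.finite(widths)))
  expect_true(all(diff(widths) < 0))
})

test_that("patterns that leave the panel are rejected", {
  mlc <- fix_mlc()
  plan <- build_default_plan(mlc, stakitt_centers = c(-190, -60, -20, 20, 60, 190))
  expect_error(render_stakitt_image(plan, mlc, sim_config(noise_sd = 0)),
               "beyond the panel")
})
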