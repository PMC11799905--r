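fake_measurements <- function(dev_a, dev_b) {
  n <- length(dev_a)
  data.frame(
    leaf = rep(seq_len(n), 2),
    bank = rep(c("A", "B"), each = n),
    stakitt = 1L,
    nominal_tip = rep(c(-110, -90), each = n),
    measured_tip = c(-110 - dev_a, -90 + dev_b),
    deviation = c(dev_a, dev_b),
    flag = "ok"
  )
}

test_that("gap deviation is the exact sum of the two leaf deviations", {
  m <- fake_measurements(dev_a = c(-0.40, -0.44, -0.42),
                         dev_b = c(0.30, 0.34, 0.32))
  res <- summarize_stakitt(m, gantry_angle = 0)
  expect_equal(res$gaps$gap_deviation, c(-0.10, -0.10, -0.10))
  # bank means combine into the gap mean by plain addition
  expect_equal(res$bank_stats$mean, c(-0.42, 0.32))
  expect_equal(res$gap_mean, -0.42 + 0.32)

  # and on a full synthetic analysis the identity holds per pair, exactly
  res2 <- summarize_stakitt(fix_ann())
  m2 <- ok_meas(fix_ann())
  for (i in sample(nrow(res2$gaps), 25)) {
    g <- res2$gaps[i, ]
    da <- m2$deviation[m2$leaf == g$leaf & m2$stakitt == g$stakitt & m2$bank == "A"]
    db <- m2$deviation[m2$leaf == g$leaf & m2$stakitt == g$stakitt & m2$bank == "B"]
    expect_identical(g$gap_deviation, da + db)
  }
})

test_that("tolerance flags and gantry-dependent action limits", {
  m <- fake_measurements(dev_a = c(0.6, 0.1, -0.2), dev_b = c(0, 0, 0))
  res <- summarize_stakitt(m, gantry_angle = 0)
  expect_equal(res$action_limit, 0.5)
  expect_equal(nrow(res$out_of_tolerance), 1)
  expect_equal(res$out_of_tolerance$deviation, 0.6)

  # at a lateral gantry angle the default limit opens up to 1.0 mm
  res90 <- summarize_stakitt(m, gantry_angle = 90)
  expect_equal(res90$action_limit, 1.0)
  expect_equal(nrow(res90$out_of_tolerance), 0)

  # explicit limit overrides
  res_tight <- summarize_stakitt(m, action_limit = 0.15, gantry_angle = 0)
  expect_equal(nrow(res_tight$out_of_tolerance), 2)

  # all-zero deviations: clean bill
  res0 <- summarize_stakitt(fake_measurements(numeric(3), numeric(3)),
                            gantry_angle = 0)
  expect_equal(res0$bank_stats$mean, c(0, 0))
  expect_equal(nrow(res0$out_of_tolerance), 0)

  expect_error(summarize_stakitt(m[0, ]), "no valid measurements")
})

test_that("deviation histogram builds a three-panel ggplot", {
  res <- summarize_stakitt(fix_ann())
  p <- plot_stakitt(res)
  expect_s3_class(p, "ggplot")
  b <- ggplot2::ggplot_build(p)
  expect_equal(length(unique(b$layout$layout$PANEL)), 3)
})
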