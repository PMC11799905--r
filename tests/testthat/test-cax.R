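test_that("field_center recovers injected shifts to sub-pixel accuracy", {
  img0 <- square_field_image()
  c0 <- field_center(img0)
  mid <- (256 - 1) / 2 * 0.39
  expect_lt(abs(c0$x - mid), 0.01)
  expect_lt(abs(c0$y - mid), 0.01)

  for (off in list(c(2, -1.5), c(-7.25, 4.1), c(15, 18))) {
    ci <- field_center(square_field_image(center_off = off))
    expect_lt(abs(ci$x - (mid + off[1])), 0.01)
    expect_lt(abs(ci$y - (mid + off[2])), 0.01)
  }
})

test_that("field_center noise floor is a few microns", {
  mid <- (256 - 1) / 2 * 0.39
  centers <- vapply(1:12, function(s) {
    ci <- field_center(square_field_image(noise_sd = 0.005, seed = s))
    c(ci$x, ci$y)
  }, numeric(2))
  expect_lt(sd(centers[1, ]), 0.02)
  expect_lt(sd(centers[2, ]), 0.02)
})

test_that("field_center rejects ambiguous multi-field profiles", {
  img <- fix_sim0()$image  # six stakitts: many 50% crossings
  expect_error(field_center(img), "ambiguous field edges")
})

test_that("C90/C270 averaging cancels jaw asymmetry and finds the axis", {
  cfg <- sim_config(noise_sd = 0, jaw_asym = c(x1 = 0.5, x2 = 0, y1 = 0, y2 = 0))
  pair <- render_cax_pair(cfg, offset = c(1.3, -0.7))
  # the individual field centers are displaced by the asymmetry...
  c90 <- field_center(pair$c90)
  expect_gt(abs(c90$x - pair$axis_true$x) + abs(c90$y - pair$axis_true$y), 0.1)
  # ...but their average recovers the axis to 0.01 mm
  cax <- compute_cax(pair$c90, pair$c270)
  expect_lt(abs(cax$position$x - pair$axis_true$x), 0.01)
  expect_lt(abs(cax$position$y - pair$axis_true$y), 0.01)

  expect_error(compute_cax(pair$c90, pair$c90), "collimator angles")
})

test_that("sag map closed loop: injected sinusoid recovered, G0 normalized", {
  sagf <- function(g) c(0.8 * sin(g * pi / 180),
                        0.5 * (1 - cos(g * pi / 180)))
  cfg <- sim_config(noise_sd = 0.005, sag_true = sagf, panel_n = 512)
  frames <- render_cone_arc(cfg, n_frames = 12)
  expect_length(frames, 12)
  expect_equal(vapply(frames, function(f) f$gantry_angle, numeric(1)),
               seq(0, 330, by = 30))
  sag <- build_sag_map(frames)
  expect_equal(unlist(sag[sag$gantry_angle == 0, c("dx", "dy")]),
               c(dx = 0, dy = 0))
  truth <- t(vapply(sag$gantry_angle, sagf, numeric(2)))
  rms <- sqrt(mean((sag$dx - truth[, 1])^2 + (sag$dy - truth[, 2])^2))
  expect_lt(rms, 0.02)

  # zero injected sag: all offsets within 0.02 mm
  cfg0 <- sim_config(noise_sd = 0.005, panel_n = 512)
  sag0 <- build_sag_map(render_cone_arc(cfg0, n_frames = 8))
  expect_lt(max(abs(c(sag0$dx, sag0$dy))), 0.02)

  # CSV round trip
  path <- file.path(tempdir(), "sag_test.csv")
  write_sag_map(sag, path)
  back <- read_sag_map(path)
  expect_equal(back$dx, sag$dx)
  expect_equal(back$gantry_angle, sag$gantry_angle)

  # no frame near G0 -> error
  shifted <- lapply(frames, function(f) { f$gantry_angle <- f$gantry_angle + 10; f })
  expect_error(build_sag_map(shifted[-1]), "within 5 degrees")
  expect_error(build_sag_map(frames[1:3]), "at least 8")
})

test_that("cax_at_gantry interpolates the sag map linearly", {
  cax <- structure(list(position = image_point(100, 100)), class = "beam_cax")
  sag <- data.frame(gantry_angle = c(0, 90, 180, 270),
                    dx = c(0, 0.3, 0.1, -0.3), dy = c(0, -0.2, 0.4, 0.2))
  class(sag) <- c("sag_map", "data.frame")

  p0 <- cax_at_gantry(cax, sag, 0)
  expect_equal(c(p0$x, p0$y), c(100, 100))
  p270 <- cax_at_gantry(cax, sag, 270)
  expect_equal(c(p270$x, p270$y), c(100 - 0.3, 100 + 0.2))
  # hand-computed midpoint between tabulated angles
  p45 <- cax_at_gantry(cax, sag, 45)
  expect_equal(c(p45$x, p45$y), c(100 + 0.15, 100 - 0.1))
  # full-circle wrap: 315 interpolates between 270 and 0+360
  p315 <- cax_at_gantry(cax, sag, 315)
  expect_equal(p315$x, 100 - 0.15)

  # no sag map: only gantry 0 is allowed
  expect_equal(cax_at_gantry(cax, NULL, 0)$x, 100)
  expect_error(cax_at_gantry(cax, NULL, 90), "sag map")

  # partial map: extrapolation is refused
  part <- sag[1:2, ]
  class(part) <- c("sag_map", "data.frame")
  expect_error(cax_at_gantry(cax, part, 180), "coverage")
})
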