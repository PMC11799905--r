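test_that("MLC models have the vendor leaf layouts", {
  m <- mlc_model("millennium120")
  expect_equal(m$n_leaf_pairs, 60)
  expect_setequal(unique(m$leaf_widths), c(10, 5))
  expect_equal(sum(m$leaf_widths == 5), 40)
  expect_equal(range(m$leaf_edges), c(-200, 200))
  expect_true(all(diff(m$leaf_edges) > 0))

  h <- mlc_model("hdmlc")
  expect_equal(h$n_leaf_pairs, 60)
  expect_equal(sum(h$leaf_widths == 2.5), 32)
  expect_equal(sum(h$leaf_widths == 5), 28)
  expect_equal(range(h$leaf_edges), c(-110, 110))
  expect_true(all(inner_leaves(h) %in% 15:46))
})

test_that("default plan encodes the canonical stakitt geometry", {
  plan <- fix_plan()
  expect_equal(plan$stakitt_centers, c(-100, -60, -20, 20, 60, 100))
  expect_equal(unique(diff(plan$stakitt_centers)), 40)
  expect_equal(plan$stakitt_width, 20)
  expect_equal(plan$mu, 480)
  # stakitt 1: tips at center -/+ half-width
  expect_equal(plan$nominal_tips$A[1, 1], -110)
  expect_equal(plan$nominal_tips$B[1, 1], -90)
  # every leaf pair's nominal gap equals the stakitt width, everywhere
  expect_true(all(plan$nominal_tips$B - plan$nominal_tips$A ==
                    plan$stakitt_width))
  # carriage shift between the two central stakitts
  expect_equal(plan$carriage_shift_after, 3L)
  # comb parity alternates strictly: each side protrudes every second leaf,
  # and the two sides protrude opposite parities
  expect_equal(abs(plan$comb$left$protrude_parity -
                     plan$comb$right$protrude_parity), 1L)
})

test_that("plan JSON round trip is lossless and validates", {
  plan <- fix_plan()
  path <- file.path(tempdir(), "plan_test.json")
  write_plan(plan, path)
  back <- read_plan(path)
  expect_equal(back$stakitt_centers, plan$stakitt_centers)
  expect_equal(back$nominal_tips$A, plan$nominal_tips$A,
               ignore_attr = TRUE)
  expect_equal(back$nominal_tips$B, plan$nominal_tips$B,
               ignore_attr = TRUE)
  expect_equal(back$comb$left$protrude_tip, plan$comb$left$protrude_tip)
  expect_equal(back$carriage_shift_after, plan$carriage_shift_after)
  expect_equal(back$mu, plan$mu)

  # missing required field -> schema error naming it
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$stakitt_centers <- NULL
  path2 <- file.path(tempdir(), "plan_bad.json")
  jsonlite::write_json(p, path2, auto_unbox = TRUE)
  expect_error(read_plan(path2), "stakitt_centers")

  # a hand-edited 5-stakitt plan warns but still loads
  p5 <- build_default_plan(fix_mlc(),
                           stakitt_centers = c(-80, -40, 0, 40, 80))
  write_plan(p5, path2)
  expect_warning(back5 <- read_plan(path2), "5 stakitts")
  expect_s3_class(back5, "stakitt_plan")

  # a closed gap is a hard error
  bad <- plan
  bad$nominal_tips$A[3, 2] <- bad$nominal_tips$B[3, 2] + 1
  expect_error(validate_plan(bad), "open gap")
})
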