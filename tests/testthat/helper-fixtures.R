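# Shared fixtures, rendered lazily and cached for the whole test run.
# All synthetic: nothing is read from disk except what a test writes.

.fix <- new.env(parent = emptyenv())

fix_get <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

fix_mlc <- function() fix_get("mlc", function() mlc_model("millennium120"))
fix_plan <- function() fix_get("plan", function() build_default_plan(fix_mlc()))

# error-free, zero-noise render + analysis (the workhorse null case)
fix_sim0 <- function() fix_get("sim0", function()
  render_stakitt_image(fix_plan(), fix_mlc(), sim_config(noise_sd = 0)))

fix_an0 <- function() fix_get("an0", function()
  analyze_stakitt(fix_sim0()$image, fix_plan(), fix_mlc(), fix_sim0()$cax_true))

# error-free render at the default 0.5% noise
fix_simn <- function() fix_get("simn", function()
  render_stakitt_image(fix_plan(), fix_mlc(), sim_config(seed = 11)))

fix_ann <- function() fix_get("ann", function()
  analyze_stakitt(fix_simn()$image, fix_plan(), fix_mlc(), fix_simn()$cax_true))

meas_key <- function(m) paste(m$leaf, m$bank, m$stakitt)

ok_meas <- function(an) {
  m <- an$measurements
  m[m$flag == "ok" & is.finite(m$deviation), ]
}

# small synthetic single-field image for field_center tests
square_field_image <- function(center_off = c(0, 0), noise_sd = 0, seed = 1,
                               n = 256, ps = 0.39, sigma = 1.2, half = 30) {
  cx <- (n - 1) / 2 * ps + center_off[1]
  cy <- (n - 1) / 2 * ps + center_off[2]
  u <- (0:(n - 1)) * ps - cx
  v <- (0:(n - 1)) * ps - cy
  fx <- pnorm((u + half) / sigma) - pnorm((u - half) / sigma)
  fy <- pnorm((v + half) / sigma) - pnorm((v - half) / sigma)
  px <- 1000 * outer(fy, fx) + 50
  if (noise_sd > 0) {
    set.seed(seed)
    px <- pmax(px + rnorm(length(px), sd = noise_sd * 1000), 0)
  }
  epid_image(px, ps)
}
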