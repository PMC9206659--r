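test_that("measurement scheme enumerates all 16 PSG x PSA combinations", {
  sch <- measurement_scheme()
  expect_equal(nrow(sch), 16)
  expect_equal(unlist(sch[1, ], use.names = FALSE), c("lcp", "lcp"))
  expect_equal(length(unique(sch$psg)), 4)
  expect_equal(length(unique(sch$psa)), 4)
  expect_false(any(duplicated(paste(sch$psg, sch$psa))))
  # label <-> retardance bijection
  ps <- pol_states()
  expect_equal(ps$retardance[match(c("lcp", "hlp", "rcp", "vlp"), ps$label)],
    c(1, 2, 3, 4) / 4)
})

test_that("stack construction validates keys, dimensions and positivity", {
  sch <- measurement_scheme()
  imgs <- setNames(
    replicate(16, matrix(1, 2, 2), simplify = FALSE),
    paste(sch$psg, sch$psa, sep = "_")
  )
  expect_s3_class(measurement_stack(imgs), "measurement_stack")
  expect_error(measurement_stack(imgs[-1]), "missing polarization states")
  bad <- imgs
  bad[[3]] <- matrix(1, 3, 2)
  expect_error(measurement_stack(bad), "identical dimensions")
  bad2 <- imgs
  bad2[[1]][1, 1] <- -1
  expect_error(measurement_stack(bad2), "negative")
})

test_that("Stokes reconstruction implements the four-state combination rules", {
  sch <- measurement_scheme()
  mk <- function(f) {
    imgs <- setNames(
      lapply(seq_len(16), function(i) matrix(f(sch$psg[i], sch$psa[i]))),
      paste(sch$psg, sch$psa, sep = "_")
    )
    measurement_stack(imgs)
  }
  # equal analyzed intensities 0.5 -> s0 = 1, s1 = s3 = 0
  st <- reconstruct_stokes(mk(function(g, a) 0.5))
  expect_equal(st$psg$hlp$s0[1, 1], 1)
  expect_equal(st$psg$hlp$s1[1, 1], 0)
  expect_equal(st$psg$hlp$s3[1, 1], 0)
  # I_R = 1, I_L = 0, I_H = I_V = 0.5 -> s0 = 1, s1 = 0, s3 = 1
  st2 <- reconstruct_stokes(mk(function(g, a) {
    switch(a, rcp = 1, lcp = 0, 0.5)
  }))
  expect_equal(st2$psg$lcp$s0[1, 1], 1)
  expect_equal(st2$psg$lcp$s1[1, 1], 0)
  expect_equal(st2$psg$lcp$s3[1, 1], 1)
  # sign conventions flip the difference elements only
  st3 <- reconstruct_stokes(mk(function(g, a) switch(a, rcp = 1, lcp = 0, 0.5)),
    sign_s3 = -1
  )
  expect_equal(st3$psg$lcp$s3[1, 1], -1)
  expect_equal(st3$psg$lcp$s0[1, 1], 1)
})

test_that("noise-free reconstruction matches the simulator's analytic Stokes maps", {
  field <- single_fiber(6, delta = 25, alpha = 10, r = 2.2, c = 0.15i,
    amplitude = 3)
  st <- reconstruct_stokes(simulate_stack(field))
  for (p in pol_states()$label) {
    truth <- forward_stokes(field, p)
    expect_lt(max(abs(st$psg[[p]]$s0 - truth$s0)) / max(truth$s0), 1e-9)
    expect_lt(max(abs(st$psg[[p]]$s1 - truth$s1)) / max(truth$s0), 1e-9)
    expect_lt(max(abs(st$psg[[p]]$s3 - truth$s3)) / max(truth$s0), 1e-9)
    expect_lt(max(st$psg[[p]]$residual) / max(truth$s0), 1e-9)
  }
})

test_that("parameter formulas give the stated arithmetic values", {
  st <- stokes_pixel(
    rcp = c(s0 = 2, s1 = 0, s3 = 0),
    lcp = c(s0 = 4, s1 = 0, s3 = 0)
  )
  expect_equal(compute_icp(st)[1, 1], 3)
  # DCP forced arithmetic: 0.8 and 0.6 average to 0.7
  st2 <- stokes_pixel(
    rcp = c(s0 = 1, s1 = 0, s3 = 0.8),
    lcp = c(s0 = 1, s1 = 0, s3 = -0.6)
  )
  expect_equal(compute_dcp(st2)[1, 1], 0.7)
  # fully circular -> DCP 1; zero s3 -> 0
  st3 <- stokes_pixel(
    rcp = c(s0 = 2, s1 = 0, s3 = -2),
    lcp = c(s0 = 3, s1 = 0, s3 = 3)
  )
  expect_equal(compute_dcp(st3)[1, 1], 1)
  st4 <- stokes_pixel(
    rcp = c(s0 = 2, s1 = 0, s3 = 0),
    lcp = c(s0 = 3, s1 = 0, s3 = 0)
  )
  expect_equal(compute_dcp(st4)[1, 1], 0)
  # SHG-CD: symmetry, boundary, forced arithmetic
  expect_equal(compute_shg_cd(st3)[1, 1], 2 * (2 - 3) / 5)
  st5 <- stokes_pixel(
    rcp = c(s0 = 5, s1 = 0, s3 = 0),
    lcp = c(s0 = 5, s1 = 0, s3 = 0)
  )
  expect_equal(compute_shg_cd(st5)[1, 1], 0)
  st6 <- stokes_pixel(
    rcp = c(s0 = 3, s1 = 0, s3 = 0),
    lcp = c(s0 = 1, s1 = 0, s3 = 0)
  )
  expect_equal(compute_shg_cd(st6)[1, 1], 1)
  st7 <- stokes_pixel(
    rcp = c(s0 = 7, s1 = 0, s3 = 0),
    lcp = c(s0 = 0, s1 = 0, s3 = 0)
  )
  expect_equal(compute_shg_cd(st7)[1, 1], 2)
  # SHG-LD endpoints and arithmetic
  st8 <- stokes_pixel(
    vlp = c(s0 = 1, s1 = 0, s3 = 0),
    hlp = c(s0 = 3, s1 = 0, s3 = 0)
  )
  expect_equal(compute_shg_ld(st8)[1, 1], -1)
  st9 <- stokes_pixel(
    vlp = c(s0 = 2, s1 = 0, s3 = 0),
    hlp = c(s0 = 0, s1 = 0, s3 = 0)
  )
  expect_equal(compute_shg_ld(st9)[1, 1], 2)
})

test_that("R-ratio roots, domain masking and branch calibration behave", {
  # A = 1: both roots coincide at R = 3; constructed via the inverse map
  # A(R) = ((R-1)^2 + 4) / (4 (R-1)), which equals 1 at R = 3
  st <- stokes_pixel(
    rcp = c(s0 = 1, s1 = 0, s3 = 1),
    lcp = c(s0 = 1, s1 = 0, s3 = -1)
  )
  expect_equal(compute_r_ratio(st, branch = "minus")[1, 1], 3)
  expect_equal(compute_r_ratio(st, branch = "plus")[1, 1], 3)
  # |A| < 1 -> no real root -> invalid pixel
  st2 <- stokes_pixel(
    rcp = c(s0 = 0.5, s1 = 0, s3 = 1),
    lcp = c(s0 = 0.5, s1 = 0, s3 = -1)
  )
  expect_warning(r2 <- compute_r_ratio(st2, branch = "minus"), "no pixel")
  expect_true(is.nan(r2[1, 1]))
  # round trip at R0 = 2 with auto branch
  field <- single_fiber(4, delta = 0, alpha = 0, r = 2)
  stf <- reconstruct_stokes(simulate_stack(field))
  rf <- compute_r_ratio(stf, branch = "auto")
  expect_equal(attr(rf, "branch"), "minus")
  expect_lt(abs(rf[1, 1] - 2), 1e-6)
  # the conjugate root pair multiplies to 4 around R - 1
  rp <- compute_r_ratio(stf, branch = "plus")
  expect_equal((rp[1, 1] - 1) * (rf[1, 1] - 1), 4, tolerance = 1e-9)
})

test_that("DCP, SHG-CD and SHG-LD stay in their physical ranges on random states", {
  st <- random_stokes_maps(10000, seed = 42)
  dcp <- compute_dcp(st)
  cd <- compute_shg_cd(st)
  ld <- compute_shg_ld(st)
  expect_true(all(dcp >= 0 & dcp <= 1))
  expect_true(all(abs(cd) <= 2))
  expect_true(all(abs(ld) <= 2))
})

test_that("DCP clamps noise-driven excursions above 1 and counts them", {
  st <- stokes_pixel(
    rcp = c(s0 = 1, s1 = 0, s3 = 1.2), # unphysical, as from noise
    lcp = c(s0 = 1, s1 = 0, s3 = 1)
  )
  d <- compute_dcp(st)
  expect_equal(d[1, 1], 1)
  expect_equal(attr(d, "n_clamped"), 1)
})

test_that("SNR mask applies the background-referenced z-score rule", {
  img <- matrix(10, 4, 4)
  img[1, 1] <- 10 + 5 * 2 # 5 sigma above background
  m <- snr_mask(img, background = c(10, 2), threshold = 3)
  expect_true(m[1, 1])
  expect_false(any(m[-1]))
  expect_error(snr_mask(img, background = c(10, 0)), "positive")
  # background from a designated region
  img2 <- matrix(rnorm(100 * 100, 10, 2), 100, 100)
  img2[1:10, 1:10] <- 100
  m2 <- snr_mask(img2, background = list(region = c(50, 100, 50, 100)),
    threshold = 3)
  expect_true(all(m2[1:10, 1:10]))
  # retained fraction tracks the ground-truth fiber fraction
  set.seed(11)
  preset <- group_preset("normal")
  field <- generate_fiber_field(128, preset, seed = 11)
  stack <- simulate_stack(field,
    noise = list(background_mean = 10, background_sd = 2, shot_noise = FALSE),
    seed = 12
  )
  icp <- compute_icp(reconstruct_stokes(stack))
  m3 <- snr_mask(icp, background = c(20, 2 / sqrt(2)), threshold = 3)
  expect_lt(abs(mean(m3) - mean(field$fiber_mask)), 0.01)
})

test_that("parameter-map assembly masks background and reports QC counters", {
  field <- generate_fiber_field(64, group_preset("tumor"), seed = 3)
  st <- reconstruct_stokes(simulate_stack(field))
  pm <- compute_parameter_maps(st, mask = field$fiber_mask)
  expect_s3_class(pm, "parameter_maps")
  expect_true(all(is.nan(pm$icp[!field$fiber_mask])))
  expect_true(all(is.finite(pm$icp[field$fiber_mask])))
  expect_equal(pm$qc$n_valid, sum(field$fiber_mask))
  expect_equal(pm$qc$r_branch, "minus")
  expect_true(all(pm$dcp[pm$valid] >= 0 & pm$dcp[pm$valid] <= 1))
})
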