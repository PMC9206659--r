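test_that("tiling splits images exactly and rejects non-divisible dimensions", {
  m <- matrix(seq_len(2048), 64, 32)
  tiles <- tile_image(m, 4)
  expect_length(tiles, 16)
  expect_equal(dim(tiles[[1]]$values), c(16, 8))
  expect_equal(tiles[[1]]$values, m[1:16, 1:8])
  expect_equal(tiles[[16]]$values, m[49:64, 25:32])
  expect_equal(tile_image(m, 1)[[1]]$values, m) # identity
  expect_error(tile_image(matrix(0, 512, 512), 3), "not divisible")
  expect_error(tile_image(matrix(0, 12, 10), 4), "width")
})

test_that("quantization bins valid pixels and preserves the missing marker", {
  m <- matrix(c(0, 1, NaN, 0.5), 2, 2)
  q <- quantize(m, n_g = 2, range_spec = c(0, 1))
  expect_equal(q[1, 1], 0L)
  expect_equal(q[2, 1], 1L)
  expect_true(is.na(q[1, 2]))
  # constant image maps to a single level
  qc <- quantize(matrix(7, 3, 3), n_g = 16)
  expect_equal(unique(as.vector(qc)), 0L)
  # clipping at range ends
  q2 <- quantize(matrix(c(-5, 0.5, 99, NA), 2, 2), n_g = 4,
    range_spec = c(0, 1))
  expect_equal(q2[1, 1], 0L)
  expect_equal(q2[1, 2], 3L)
  expect_error(quantize(m, 4, range_spec = c(1, 0)), "lo > hi")
  # uniform random map fills levels uniformly (3-sigma multinomial bound)
  set.seed(8)
  n <- 64 * 64
  qr <- quantize(matrix(runif(n), 64, 64), n_g = 8, range_spec = c(0, 1))
  counts <- tabulate(qr + 1L, nbins = 8)
  expect_true(all(abs(counts - n / 8) < 3 * sqrt(n * (1 / 8) * (7 / 8))))
})

test_that("masked GLCM matches the stated small examples", {
  # rows (0,0) and (1,1): horizontal pairs within rows
  q <- matrix(c(0, 1, 0, 1), 2, 2)
  g <- masked_glcm(q, n_g = 2, d = 1, angles = 0)
  expect_equal(g$p, matrix(c(0.5, 0, 0, 0.5), 2, 2))
  # masking the top-left pixel leaves only the (1,1) pair
  q2 <- q
  q2[1, 1] <- NA
  g2 <- masked_glcm(q2, n_g = 2, d = 1, angles = 0)
  expect_equal(g2$p, matrix(c(0, 0, 0, 1), 2, 2))
  # all-missing tile
  g3 <- masked_glcm(matrix(NA_integer_, 3, 3), n_g = 2)
  expect_equal(g3$n_pairs, 0)
  expect_true(all(is.na(texture_features(g3))))
})

test_that("masked GLCM equals the brute-force pair-enumeration oracle", {
  set.seed(101)
  for (i in 1:250) {
    nr <- sample(2:16, 1)
    nc <- sample(2:16, 1)
    n_g <- sample(2:6, 1)
    q <- matrix(sample(0:(n_g - 1), nr * nc, replace = TRUE), nr, nc)
    q[runif(nr * nc) < 0.3] <- NA # random mask
    d <- sample(1:2, 1)
    angles <- sample(c(0, 45, 90, 135), sample(1:4, 1))
    sym <- sample(c(TRUE, FALSE), 1)
    g <- masked_glcm(q, n_g = n_g, d = d, angles = angles, symmetric = sym)
    expect_equal(g$p, oracle_glcm(q, n_g, d, angles, sym),
      tolerance = 1e-14
    )
    if (sym && g$n_pairs > 0) expect_equal(g$p, t(g$p))
    if (g$n_pairs > 0) expect_equal(sum(g$p), 1, tolerance = 1e-12)
    expect_true(all(g$p >= 0))
  }
})

test_that("texture features hit their analytic endpoints", {
  # uniform image: ASM = IDM = 1, contrast = entropy = 0, correlation NA
  gq <- masked_glcm(quantize(matrix(3.7, 64, 64), n_g = 32), d = 1)
  f <- texture_features(gq)
  expect_equal(f[["asm"]], 1)
  expect_equal(f[["idm"]], 1)
  expect_equal(f[["contrast"]], 0)
  expect_equal(f[["entropy"]], 0)
  expect_true(is.na(f[["correlation"]]))
  # vertical stripes at d = 1, angle 0: perfect negative correlation
  stripes <- matrix(rep(c(0L, 1L), 8), 16, 16, byrow = TRUE)
  gs <- masked_glcm(stripes, n_g = 2, d = 1, angles = 0)
  fs <- texture_features(gs)
  expect_equal(fs[["correlation"]], -1)
  expect_equal(fs[["contrast"]], 1)
  expect_equal(fs[["asm"]], 0.5)
  expect_equal(fs[["idm"]], 0.5)
  expect_equal(fs[["entropy"]], 1)
  # blocks: perfect positive correlation
  gp <- masked_glcm(matrix(c(0, 1, 0, 1), 2, 2), n_g = 2, d = 1, angles = 0)
  fp <- texture_features(gp)
  expect_equal(fp[["correlation"]], 1)
  expect_equal(fp[["idm"]], 1)
  # legacy sign flag negates the correlation only
  expect_equal(
    texture_features(gs, legacy_sign = TRUE)[["correlation"]], 1
  )
})

test_that("texture feature bounds hold on random masked tiles", {
  set.seed(55)
  for (i in 1:200) {
    n_g <- sample(2:8, 1)
    q <- matrix(sample(0:(n_g - 1), 100, replace = TRUE), 10, 10)
    q[runif(100) < 0.2] <- NA
    f <- texture_features(masked_glcm(q, n_g = n_g))
    if (all(is.na(f))) next
    expect_lte(f[["asm"]], 1)
    expect_lte(f[["idm"]], 1)
    expect_gte(f[["contrast"]], 0)
    expect_lte(f[["entropy"]], 2 * log2(n_g))
    if (!is.na(f[["correlation"]])) {
      expect_lte(abs(f[["correlation"]]), 1 + 1e-12)
    }
  }
})

test_that("four-angle averaged features are invariant under tile rotation", {
  set.seed(7)
  q <- matrix(sample(0:3, 144, replace = TRUE), 12, 12)
  q[runif(144) < 0.2] <- NA
  f1 <- texture_features(masked_glcm(q, n_g = 4, d = 1))
  f2 <- texture_features(masked_glcm(t(q[nrow(q):1, ]), n_g = 4, d = 1))
  expect_equal(f1, f2, tolerance = 1e-12)
})

test_that("sub-image statistics follow their definitions", {
  s <- subimage_stats(matrix(c(1, 2, 3, NaN), 2, 2))
  expect_equal(s[["mean"]], 2)
  expect_equal(s[["mad"]], 2 / 3)
  expect_equal(s[["pixel_density"]], 3)
  expect_equal(subimage_stats(matrix(5, 3, 3))[["mad"]], 0)
  expect_true(is.na(subimage_stats(matrix(NaN, 2, 2))[["mean"]]))
  # shift invariance of MAD, equivariance of the mean
  set.seed(2)
  x <- matrix(rnorm(64), 8, 8)
  s0 <- subimage_stats(x)
  s1 <- subimage_stats(x + 10)
  expect_equal(s1[["mad"]], s0[["mad"]])
  expect_equal(s1[["mean"]], s0[["mean"]] + 10)
})

test_that("feature table has 36 features per retained sub-image", {
  field <- generate_fiber_field(64, group_preset("normal"), seed = 31)
  pm <- compute_parameter_maps(
    reconstruct_stokes(simulate_stack(field)),
    mask = field$fiber_mask
  )
  ft <- build_feature_table(pm,
    core_id = "c1", label = "normal",
    tiles_per_side = 4, n_g = 16
  )
  feats <- intersect(feature_names(), names(ft))
  expect_length(feature_names(), 36)
  expect_length(feats, 36)
  expect_equal(
    setdiff(names(ft), feats),
    c("core_id", "label", "tile_row", "tile_col")
  )
  expect_lte(nrow(ft), 16)
  # an empty tile is dropped
  roi <- matrix(TRUE, 64, 64)
  roi[1:16, 1:16] <- FALSE # kill tile (1,1)
  ft2 <- build_feature_table(pm,
    core_id = "c1", label = "normal",
    tiles_per_side = 4, n_g = 16, roi = roi
  )
  expect_false(any(ft2$tile_row == 1 & ft2$tile_col == 1))
  # fully valid synthetic map: all tiles retained
  pm_full <- pm
  for (nm in c("icp", "r_ratio", "dcp", "shg_cd", "shg_ld")) {
    m <- matrix(as.vector(pm[[nm]]), 64, 64)
    m[!is.finite(m)] <- 1
    pm_full[[nm]] <- m
  }
  pm_full$valid <- matrix(TRUE, 64, 64)
  ft3 <- build_feature_table(pm_full,
    core_id = "c", label = "x",
    tiles_per_side = 8, n_g = 8
  )
  expect_equal(nrow(ft3), 64)
})
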