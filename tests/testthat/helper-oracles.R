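# Brute-force pair-enumeration GLCM oracle: loops over every pixel and
# angle, skipping masked pairs; independent of the vectorized
# implementation in masked_glcm().
oracle_glcm <- function(q, n_g, d = 1, angles = c(0, 45, 90, 135),
                        symmetric = TRUE) {
  offs <- list(
    "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d)
  )
  counts <- matrix(0, n_g, n_g)
  for (ang in angles) {
    off <- offs[[as.character(ang)]]
    tab <- matrix(0, n_g, n_g)
    for (r in seq_len(nrow(q))) {
      for (cc in seq_len(ncol(q))) {
        r2 <- r + off[1]
        c2 <- cc + off[2]
        if (r2 < 1 || r2 > nrow(q) || c2 < 1 || c2 > ncol(q)) next
        a <- q[r, cc]
        b <- q[r2, c2]
        if (is.na(a) || is.na(b)) next
        tab[a + 1, b + 1] <- tab[a + 1, b + 1] + 1
        if (symmetric) tab[b + 1, a + 1] <- tab[b + 1, a + 1] + 1
      }
    }
    counts <- counts + tab / length(angles)
  }
  if (sum(counts) > 0) counts / sum(counts) else counts
}

# Random physically valid reduced Stokes maps (|s1| <= s0, |s3| <= s0,
# s1^2 + s3^2 <= s0^2) for all four PSG states, as 1 x n pixel rows.
random_stokes_maps <- function(n, seed = 1) {
  set.seed(seed)
  psg <- lapply(pshg::pol_states()$label, function(p) {
    s0 <- matrix(runif(n, 0.1, 10), 1)
    frac <- matrix(runif(n), 1) # degree of polarization
    ang <- matrix(runif(n, 0, 2 * pi), 1)
    list(
      s0 = s0,
      s1 = s0 * frac * cos(ang),
      s3 = s0 * frac * sin(ang),
      residual = matrix(0, 1, n)
    )
  })
  names(psg) <- pshg::pol_states()$label
  structure(
    list(psg = psg, height = 1L, width = n, pixel_size = 0.3),
    class = "stokes_maps"
  )
}

# Stokes maps holding one pixel with prescribed elements per PSG state.
stokes_pixel <- function(...) {
  vals <- list(...)
  psg <- lapply(pshg::pol_states()$label, function(p) {
    v <- vals[[p]]
    if (is.null(v)) v <- c(s0 = 0, s1 = 0, s3 = 0)
    list(
      s0 = matrix(v[["s0"]]), s1 = matrix(v[["s1"]]),
      s3 = matrix(v[["s3"]]), residual = matrix(0)
    )
  })
  names(psg) <- pshg::pol_states()$label
  structure(
    list(psg = psg, height = 1L, width = 1L, pixel_size = 0.3),
    class = "stokes_maps"
  )
}

single_fiber <- pshg:::single_fiber_field
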