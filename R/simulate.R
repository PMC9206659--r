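#' Group presets for the synthetic tissue simulator
#'
#' Qualitative normal-vs-tumor presets for the synthetic collagen-fiber
#' simulator. The direction of every contrast follows the reported tissue
#' phenotype: tumor stroma carries less ordered collagen (lower fiber
#' density and SHG amplitude), a larger susceptibility ratio R, and
#' straighter fibers (smaller orientation dispersion, hence narrower
#' dichroism spreads). The magnitudes are simulator choices, not fits to
#' tissue data.
#'
#' @param label `"normal"` or `"tumor"`.
#' @return A list of class `"group_preset"` with fields `label`, `r_mean`,
#'   `r_sd`, `fiber_density_target`, `orientation_dispersion` (degrees),
#'   `alpha_sd` (degrees), `amplitude_mean`, `chirality` and
#'   `chirality_phase` (degrees; the phase retardance between the chiral
#'   and achiral susceptibility components, without which the circular
#'   dichroism of tilted fibers vanishes), and noise parameters
#'   `background_mean`, `background_sd`, `shot_noise`.
#' @export
group_preset <- function(label = c("normal", "tumor")) {
  label <- match.arg(label)
  p <- switch(label,
    normal = list(
      label = "normal",
      r_mean = 1.6, r_sd = 0.10,
      fiber_density_target = 0.35,
      orientation_dispersion = 30,
      alpha_sd = 12,
      amplitude_mean = 100,
      chirality = 0.1, chirality_phase = 90,
      background_mean = 10, background_sd = 2,
      shot_noise = TRUE
    ),
    tumor = list(
      label = "tumor",
      r_mean = 2.1, r_sd = 0.12,
      fiber_density_target = 0.15,
      orientation_dispersion = 10,
      alpha_sd = 12,
      amplitude_mean = 40,
      chirality = 0.1, chirality_phase = 90,
      background_mean = 10, background_sd = 2,
      shot_noise = TRUE
    )
  )
  structure(p, class = "group_preset")
}

# Minimal uniform single-fiber field covering the whole frame; used for
# branch calibration and analytic round-trip tests. `c` may be complex
# (magnitude = chiral ratio, phase = chiral-achiral retardance).
single_fiber_field <- function(size, delta = 0, alpha = 0, r = 2, c = 0,
                               amplitude = 1) {
  m <- function(v) matrix(v, size, size)
  structure(
    list(
      fiber_mask = m(TRUE),
      delta = m(delta), alpha = m(alpha),
      r_true = m(r), c_true = m(c),
      amplitude = m(amplitude),
      size = size
    ),
    class = "fiber_field"
  )
}

#' Generate a synthetic collagen fiber field
#'
#' Draws smooth curvilinear fibers as random-walk polylines (per-step
#' heading increments scaled so the heading spread over a fiber's length
#' matches `orientation_dispersion`), dilates them to a random 2-6 pixel
#' width, and paints pixels until the target fiber density is reached
#' (within 10%). Each painted pixel records the local fiber tangent as its
#' in-plane orientation `delta`; out-of-plane tilt `alpha`, susceptibility
#' ratio `r` and emission amplitude are drawn per fiber from the preset
#' distributions. Overlap pixels keep the first fiber drawn.
#'
#' @param size Image side in pixels (>= 64 for realistic fields; smaller
#'   values are accepted for testing).
#' @param preset A [group_preset()] (or a list with the same fields).
#' @param seed Integer seed; the field is deterministic given
#'   `(size, preset, seed)`.
#' @return An object of class `"fiber_field"` with per-pixel matrices
#'   `fiber_mask`, `delta` (degrees, counter-clockwise from the image
#'   horizontal), `alpha` (degrees), `r_true`, `c_true`, `amplitude`.
#' @export
generate_fiber_field <- function(size, preset, seed) {
  stopifnot(size >= 8)
  target <- preset$fiber_density_target
  with_seed(seed, {
    mask <- matrix(FALSE, size, size)
    delta <- matrix(NaN, size, size)
    alpha <- matrix(NaN, size, size)
    r_true <- matrix(NaN, size, size)
    c_true <- matrix(NaN, size, size)
    amplitude <- matrix(0, size, size)
    if (target > 0) {
      n_px <- size * size
      fiber_len <- max(8L, as.integer(size))
      turn_sd <- preset$orientation_dispersion / sqrt(fiber_len)
      max_fibers <- 50000L
      n_fibers <- 0L
      while (sum(mask) < target * n_px && n_fibers < max_fibers) {
        n_fibers <- n_fibers + 1L
        w <- sample(2:6, 1)
        rad <- (w - 1) / 2
        f_alpha <- max(-80, min(80, stats::rnorm(1, 0, preset$alpha_sd)))
        f_r <- max(1.05, stats::rnorm(1, preset$r_mean, preset$r_sd))
        phase <- if (is.null(preset$chirality_phase)) 90 else preset$chirality_phase
        f_c <- preset$chirality * exp(1i * deg2rad(phase))
        f_amp <- preset$amplitude_mean * exp(stats::rnorm(1, 0, 0.25))
        # random-walk polyline
        pos <- stats::runif(2, 1, size)
        heading <- stats::runif(1, 0, 180)
        turns <- stats::rnorm(fiber_len, 0, turn_sd)
        for (s in seq_len(fiber_len)) {
          heading <- heading + turns[s]
          pos <- pos + c(
            -sin(deg2rad(heading)), # row decreases as delta increases (CCW)
            cos(deg2rad(heading))
          )
          if (any(pos < 1 - rad) || any(pos > size + rad)) break
          rows <- max(1, floor(pos[1] - rad)):min(size, ceiling(pos[1] + rad))
          cols <- max(1, floor(pos[2] - rad)):min(size, ceiling(pos[2] + rad))
          for (ri in rows) {
            for (ci in cols) {
              if ((ri - pos[1])^2 + (ci - pos[2])^2 <= rad^2 + 0.25 &&
                !mask[ri, ci]) {
                mask[ri, ci] <- TRUE
                delta[ri, ci] <- heading %% 180
                alpha[ri, ci] <- f_alpha
                r_true[ri, ci] <- f_r
                c_true[ri, ci] <- f_c
                amplitude[ri, ci] <- f_amp
              }
            }
          }
        }
        if (sum(mask) >= (target + 0.1 * target) * n_px) break
      }
      if (sum(mask) < (target - 0.1 * target) * n_px &&
        n_fibers >= max_fibers) {
        stop("fiber density target unreachable within attempt budget")
      }
    }
    structure(
      list(
        fiber_mask = mask, delta = delta, alpha = alpha,
        r_true = r_true, c_true = c_true, amplitude = amplitude,
        size = size, label = preset$label
      ),
      class = "fiber_field"
    )
  })
}

#' @export
print.fiber_field <- function(x, ...) {
  cat(sprintf(
    "Synthetic fiber field %d x %d px: %.1f%% fiber pixels",
    x$size, x$size, 100 * mean(x$fiber_mask)
  ))
  if (!is.null(x$label)) cat(sprintf(" (preset: %s)", x$label))
  cat("\n")
  invisible(x)
}

#' Exact outgoing SHG Stokes maps from the fiber model
#'
#' Evaluates the coherent single-fiber SHG emission model per pixel. The
#' fiber axis is \eqn{\hat z_f = (\cos\alpha\cos\delta,
#' \cos\alpha\sin\delta, \sin\alpha)}; the incident Jones field (which has
#' no component along the propagation axis) is projected onto the fiber
#' frame, the second-order polarization is formed under a cylindrically
#' symmetric, Kleinman-restricted susceptibility with \eqn{\chi_{zxx} = 1},
#' ratio \eqn{r = \chi_{zzz}/\chi_{zxx}} and one antisymmetric chiral
#' element \eqn{c = \chi_{xyz}/\chi_{zxx}}:
#' \deqn{P_z = (E_x^2 + E_y^2) + r E_z^2,\quad
#'       P_x = 2 E_x E_z + 2 c E_y E_z,\quad
#'       P_y = 2 E_y E_z - 2 c E_x E_z,}
#' where `c` may be complex: its phase is the retardance between the
#' chiral and achiral susceptibility components, and with a purely real
#' `c` the circular dichroism of tilted fibers vanishes identically
#' (the chiral term then enters in quadrature). The polarization is
#' then rotated back to the lab frame; only the transverse (image-plane)
#' components radiate into the detection path. The outgoing Stokes vector
#' is formed from the transverse polarization amplitudes, scaled by the
#' per-pixel emission amplitude. Non-fiber pixels emit nothing. The model
#' omits birefringence, scattering and focal-volume averaging, so each
#' fiber pixel emits fully polarized light.
#'
#' @param field A `"fiber_field"`.
#' @param psg Incident PSG state label (`"lcp"`, `"hlp"`, `"rcp"`, `"vlp"`).
#' @return A list of matrices `s0`, `s1`, `s2`, `s3`.
#' @export
forward_stokes <- function(field, psg) {
  stopifnot(inherits(field, "fiber_field"))
  jon <- jones_vector(psg)
  n <- field$size
  zero <- matrix(0, n, n)
  out <- list(s0 = zero, s1 = zero, s2 = zero, s3 = zero)
  idx <- which(field$fiber_mask)
  if (!length(idx)) {
    return(out)
  }
  d <- deg2rad(field$delta[idx])
  a <- deg2rad(field$alpha[idx])
  r <- field$r_true[idx]
  cc <- field$c_true[idx]
  amp <- field$amplitude[idx]
  # fiber frame: zf = fiber axis; xf in-plane, perpendicular to the in-plane
  # projection of zf; yf = zf x xf (contains the propagation direction at
  # alpha = 0)
  zf <- cbind(cos(a) * cos(d), cos(a) * sin(d), sin(a))
  xf <- cbind(-sin(d), cos(d), 0)
  yf <- cbind(
    zf[, 2] * xf[, 3] - zf[, 3] * xf[, 2],
    zf[, 3] * xf[, 1] - zf[, 1] * xf[, 3],
    zf[, 1] * xf[, 2] - zf[, 2] * xf[, 1]
  )
  # incident field in the lab frame (no longitudinal component)
  ex_l <- jon[1]
  ey_l <- jon[2]
  ez_f <- ex_l * zf[, 1] + ey_l * zf[, 2]
  ex_f <- ex_l * xf[, 1] + ey_l * xf[, 2]
  ey_f <- ex_l * yf[, 1] + ey_l * yf[, 2]
  pz <- (ex_f^2 + ey_f^2) + r * ez_f^2
  px <- 2 * ex_f * ez_f + 2 * cc * ey_f * ez_f
  py <- 2 * ey_f * ez_f - 2 * cc * ex_f * ez_f
  # back to lab frame, keep transverse components
  pX <- px * xf[, 1] + py * yf[, 1] + pz * zf[, 1]
  pY <- px * xf[, 2] + py * yf[, 2] + pz * zf[, 2]
  s0 <- amp * (Mod(pX)^2 + Mod(pY)^2)
  s1 <- amp * (Mod(pX)^2 - Mod(pY)^2)
  s2 <- amp * 2 * Re(pX * Conj(pY))
  s3 <- amp * -2 * Im(pX * Conj(pY))
  out$s0[idx] <- s0
  out$s1[idx] <- s1
  out$s2[idx] <- s2
  out$s3[idx] <- s3
  out
}

# Sum Stokes maps from several fields (incoherent superposition, e.g.
# crossing fibers); partially depolarizes the combined emission.
combine_stokes <- function(stokes_list) {
  Reduce(function(a, b) Map(`+`, a, b), stokes_list)
}

#' Render one analyzed intensity image
#'
#' Projects the exact outgoing Stokes maps onto a perfect analyzer in state
#' `psa` (`I = (s0 + shat . (s1, s2, s3)) / 2`) and optionally corrupts the
#' image with Poisson shot noise on the signal plus a Gaussian dark
#' background.
#'
#' @param field A `"fiber_field"`.
#' @param psg,psa PSG and PSA state labels.
#' @param noise `NULL` for a noise-free image, or a list with
#'   `background_mean`, `background_sd`, and logical `shot_noise`.
#' @param seed Seed for the noise draws (required when `noise` is given).
#' @return A numeric intensity matrix (non-negative).
#' @export
render_measurement <- function(field, psg, psa, noise = NULL, seed = NULL) {
  st <- forward_stokes(field, psg)
  shat <- analyzer_stokes(psa)
  img <- (st$s0 + shat[1] * st$s1 + shat[2] * st$s2 + shat[3] * st$s3) / 2
  img[img < 0 & img > -1e-12] <- 0 # numerical jitter only
  if (!is.null(noise)) {
    img <- with_seed(seed, {
      out <- img
      if (isTRUE(noise$shot_noise)) {
        out <- stats::rpois(length(out), lambda = out)
      }
      out <- out + stats::rnorm(
        length(out),
        mean = noise$background_mean, sd = noise$background_sd
      )
      matrix(pmax(out, 0), nrow(img), ncol(img))
    })
  }
  img
}

#' Simulate a full 16-state measurement stack
#'
#' Renders all 16 PSG x PSA combinations of [measurement_scheme()] for one
#' fiber field.
#'
#' @param field A `"fiber_field"`.
#' @param noise,seed Passed to [render_measurement()]; each state gets a
#'   sub-seed derived from `seed`.
#' @param pixel_size Metadata for the stack.
#' @return A [measurement_stack()].
#' @export
simulate_stack <- function(field, noise = NULL, seed = NULL, pixel_size = 0.3) {
  sch <- measurement_scheme()
  imgs <- vector("list", nrow(sch))
  names(imgs) <- state_key(sch$psg, sch$psa)
  for (i in seq_len(nrow(sch))) {
    s_i <- if (is.null(seed)) NULL else derive_seed(seed, i)
    imgs[[i]] <- render_measurement(
      field, sch$psg[i], sch$psa[i],
      noise = noise, seed = s_i
    )
  }
  measurement_stack(imgs, pixel_size = pixel_size)
}

#' Simulate a labelled multi-core dataset
#'
#' Generates `n_per_group` synthetic tissue cores per group, each with a
#' fresh fiber field drawn from its group preset and a full 16-image
#' measurement stack. Core-level seeds are derived from the master seed, so
#' the dataset (including its manifest) is reproducible.
#'
#' @param n_per_group Cores per group (>= 1).
#' @param presets Named list of [group_preset()]s (default: normal + tumor).
#' @param core_size Core image side in pixels.
#' @param seed Master seed.
#' @param noise `TRUE` to use each preset's noise parameters, `FALSE` for
#'   noise-free stacks.
#' @return A list of class `"pshg_dataset"`: `cores` (each with `core_id`,
#'   `label`, `field`, `stack`) and `manifest` (data frame core_id, label,
#'   seed, fiber_fraction).
#' @export
generate_dataset <- function(n_per_group, presets = NULL, core_size = 256,
                             seed = 1, noise = TRUE) {
  stopifnot(n_per_group >= 1)
  if (is.null(presets)) {
    presets <- list(normal = group_preset("normal"), tumor = group_preset("tumor"))
  }
  cores <- list()
  man <- list()
  i <- 0L
  for (g in names(presets)) {
    for (k in seq_len(n_per_group)) {
      i <- i + 1L
      core_seed <- derive_seed(seed, i)
      field <- generate_fiber_field(core_size, presets[[g]], seed = core_seed)
      nz <- if (isTRUE(noise)) {
        list(
          background_mean = presets[[g]]$background_mean,
          background_sd = presets[[g]]$background_sd,
          shot_noise = presets[[g]]$shot_noise
        )
      }
      stack <- simulate_stack(field, noise = nz, seed = core_seed + 1)
      core_id <- sprintf("%s_%02d", g, k)
      cores[[core_id]] <- list(
        core_id = core_id, label = g, field = field, stack = stack
      )
      man[[core_id]] <- data.frame(
        core_id = core_id, label = g, seed = core_seed,
        fiber_fraction = mean(field$fiber_mask),
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(cores = cores, manifest = do.call(rbind, c(man, make.row.names = FALSE))),
    class = "pshg_dataset"
  )
}

#' @export
print.pshg_dataset <- function(x, ...) {
  cat(sprintf("Synthetic P-SHG dataset: %d cores\n", length(x$cores)))
  print(table(x$manifest$label))
  invisible(x)
}
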