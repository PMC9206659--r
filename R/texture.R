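#' Tile an image into non-overlapping sub-images
#'
#' Subdivides a parameter map into `tiles_per_side^2` equal tiles in
#' row-major order (the analysis default of 8 turns a 2048 x 2048 core into
#' 64 sub-images of 256 x 256).
#'
#' @param map A matrix whose dimensions are divisible by `tiles_per_side`.
#' @param tiles_per_side Number of tiles along each axis.
#' @return A list of tiles; each element has `tile_row`, `tile_col`
#'   (1-based) and the sub-matrix `values`.
#' @export
tile_image <- function(map, tiles_per_side) {
  stopifnot(is.matrix(map), tiles_per_side >= 1)
  if (nrow(map) %% tiles_per_side != 0) {
    stop("image height ", nrow(map), " not divisible by ", tiles_per_side)
  }
  if (ncol(map) %% tiles_per_side != 0) {
    stop("image width ", ncol(map), " not divisible by ", tiles_per_side)
  }
  th <- nrow(map) / tiles_per_side
  tw <- ncol(map) / tiles_per_side
  out <- vector("list", tiles_per_side^2)
  k <- 0L
  for (i in seq_len(tiles_per_side)) {
    for (j in seq_len(tiles_per_side)) {
      k <- k + 1L
      out[[k]] <- list(
        tile_row = i, tile_col = j,
        values = map[
          ((i - 1) * th + 1):(i * th),
          ((j - 1) * tw + 1):(j * tw),
          drop = FALSE
        ]
      )
    }
  }
  out
}

#' Quantize a parameter map to discrete grey levels
#'
#' Linearly bins valid (finite) pixels into `n_g` grey levels
#' `0 .. n_g - 1`, clipping at the range ends; `NaN`/`NA` (background)
#' pixels stay missing. By default the range is the robust 1st-99th
#' percentile of the valid pixels, which makes levels comparable across the
#' tiles of a core.
#'
#' @param map Numeric matrix with `NaN` marking background.
#' @param n_g Number of grey levels (>= 2).
#' @param range_spec `NULL` for the robust per-map range, or `c(lo, hi)`.
#' @return An integer matrix of levels with `NA` preserved for background.
#' @export
quantize <- function(map, n_g = 64, range_spec = NULL) {
  stopifnot(n_g >= 2)
  valid <- is.finite(map)
  if (is.null(range_spec)) {
    if (!any(valid)) {
      return(matrix(NA_integer_, nrow(map), ncol(map)))
    }
    range_spec <- stats::quantile(map[valid], c(0.01, 0.99), names = FALSE)
  }
  lo <- range_spec[1]
  hi <- range_spec[2]
  if (lo > hi) stop("quantization range has lo > hi")
  out <- matrix(NA_integer_, nrow(map), ncol(map))
  if (hi == lo) {
    out[valid] <- 0L # degenerate range: single level
    return(out)
  }
  lv <- floor((map[valid] - lo) / (hi - lo) * n_g)
  lv[lv < 0] <- 0L
  lv[lv > n_g - 1] <- n_g - 1L
  out[valid] <- as.integer(lv)
  out
}

# (row, col) pixel offset for a GLCM angle at distance d; angles follow the
# standard image convention (0 = east, 45 = north-east, ...).
glcm_offset <- function(angle, d) {
  switch(as.character(angle),
    "0" = c(0L, d),
    "45" = c(-d, d),
    "90" = c(-d, 0L),
    "135" = c(-d, -d),
    stop("unsupported GLCM angle: ", angle)
  )
}

#' Masked grey-level co-occurrence matrix
#'
#' Counts co-occurrences of grey levels at pixel offset `d` along each
#' requested angle, skipping every pair in which either pixel is missing
#' (`NA`), so background never contributes. In symmetric mode each pair is
#' counted in both orders, making the matrix symmetric. The per-angle count
#' matrices are averaged and then normalized into the pair-probability
#' matrix, yielding a direction-independent GLCM.
#'
#' @param q Integer matrix of grey levels in `0 .. n_g - 1` with `NA` for
#'   background (from [quantize()]).
#' @param n_g Number of grey levels (defaults to `max(q) + 1`).
#' @param d Offset distance in pixels.
#' @param angles Subset of `c(0, 45, 90, 135)` in degrees.
#' @param symmetric Count each pair in both orders (default `TRUE`).
#' @return An object of class `"glcm"`: probability matrix `p` (all zeros
#'   when no pair contributes), `n_g`, `d`, `angles`, `symmetric`, and
#'   `n_pairs`, the total number of counted (ordered) pairs.
#' @export
masked_glcm <- function(q, n_g = NULL, d = 1, angles = c(0, 45, 90, 135),
                        symmetric = TRUE) {
  stopifnot(d >= 1, all(angles %in% c(0, 45, 90, 135)))
  if (is.null(n_g)) {
    n_g <- if (all(is.na(q))) 1L else max(q, na.rm = TRUE) + 1L
  }
  counts <- matrix(0, n_g, n_g)
  n_pairs <- 0
  for (ang in angles) {
    off <- glcm_offset(ang, d)
    nr <- nrow(q)
    nc <- ncol(q)
    r_lo <- max(1L, 1L - off[1])
    r_hi <- min(nr, nr - off[1])
    c_lo <- max(1L, 1L - off[2])
    c_hi <- min(nc, nc - off[2])
    if (r_lo > r_hi || c_lo > c_hi) next # offset exceeds tile extent
    r1 <- r_lo:r_hi
    c1 <- c_lo:c_hi
    a <- q[r1, c1, drop = FALSE]
    b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    i <- a[ok]
    j <- b[ok]
    tab <- matrix(
      tabulate(i * n_g + j + 1L, nbins = n_g * n_g),
      n_g, n_g,
      byrow = TRUE
    )
    if (symmetric) tab <- tab + t(tab)
    counts <- counts + tab / length(angles)
    n_pairs <- n_pairs + sum(tab)
  }
  p <- if (n_pairs > 0) counts / sum(counts) else counts
  structure(
    list(
      p = p, n_g = n_g, d = d, angles = angles,
      symmetric = symmetric, n_pairs = n_pairs
    ),
    class = "glcm"
  )
}

#' Haralick texture features of a GLCM
#'
#' Computes the five texture statistics used throughout the analysis from a
#' pair-probability matrix \eqn{P(i,j)}:
#' contrast \eqn{\sum (i-j)^2 P(i,j)};
#' correlation \eqn{\sum P(i,j)(i-\mu)(j-\mu)/\sigma^2} with \eqn{\mu},
#' \eqn{\sigma} the mean and standard deviation of the GLCM marginal
#' distribution (for a symmetric GLCM the row and column marginals agree);
#' entropy \eqn{-\sum P \log_2 P} (with \eqn{0 \log 0 = 0}), in bits;
#' angular second moment \eqn{\sum P^2}; and inverse difference moment
#' \eqn{\sum P / (1 + (i-j)^2)}. A completely uniform image gives ASM and
#' IDM of 1 and contrast and entropy of 0; its correlation is undefined
#' (zero marginal variance) and reported as `NA`.
#'
#' @param g A `"glcm"` object.
#' @param legacy_sign If `TRUE`, negate the correlation, reproducing a
#'   sign-flipped variant of the formula found in some references; the
#'   default keeps the standard orientation in which +1 means perfectly
#'   positively correlated neighbours.
#' @return Named numeric vector `contrast`, `correlation`, `entropy`,
#'   `asm`, `idm` (all `NA` when the GLCM has no contributing pairs).
#' @export
texture_features <- function(g, legacy_sign = FALSE) {
  stopifnot(inherits(g, "glcm"))
  if (g$n_pairs == 0) {
    return(c(
      contrast = NA_real_, correlation = NA_real_,
      entropy = NA_real_, asm = NA_real_, idm = NA_real_
    ))
  }
  p <- g$p
  n_g <- g$n_g
  lev <- 0:(n_g - 1)
  i <- matrix(lev, n_g, n_g)
  j <- t(i)
  contrast <- sum((i - j)^2 * p)
  marg <- rowSums(p)
  mu <- sum(lev * marg)
  sig2 <- sum((lev - mu)^2 * marg)
  correlation <- if (sig2 > 0) {
    sum(p * (i - mu) * (j - mu)) / sig2
  } else {
    NA_real_
  }
  if (legacy_sign && !is.na(correlation)) correlation <- -correlation
  nz <- p > 0
  entropy <- -sum(p[nz] * log2(p[nz]))
  asm <- sum(p^2)
  idm <- sum(p / (1 + (i - j)^2))
  c(
    contrast = contrast, correlation = correlation,
    entropy = entropy, asm = asm, idm = idm
  )
}

#' Mean, MAD and pixel density of a sub-image
#'
#' Summary statistics over the valid (finite) pixels of one tile of a
#' parameter map: the mean, the mean absolute deviation about the mean, and
#' the pixel density (count of valid pixels, a measure of how much
#' SHG-producing collagen the tile contains). All are `NA` when the tile
#' has no valid pixel.
#'
#' @param values Numeric matrix (or vector) with `NaN` background.
#' @return Named vector `mean`, `mad`, `pixel_density`.
#' @export
subimage_stats <- function(values) {
  v <- values[is.finite(values)]
  n <- length(v)
  if (n == 0) {
    return(c(mean = NA_real_, mad = NA_real_, pixel_density = 0))
  }
  m <- mean(v)
  c(mean = m, mad = mean(abs(v - m)), pixel_density = n)
}

#' Assemble the per-sub-image feature table
#'
#' Tiles the five parameter maps of one core, computes for each tile and
#' each parameter the mean, MAD and the five GLCM texture features, plus
#' the tile's pixel density, and stacks them into the 36-feature table (5
#' parameters x 7 statistics + pixel density). Quantization uses a robust
#' per-core range (1st-99th percentile of the valid pixels of the whole
#' map) so grey levels are comparable across tiles. Tiles whose pixel
#' density falls below `min_density` (fraction of tile pixels) are deemed
#' non-viable and dropped; an optional ROI mask excludes regions (e.g.
#' empty corners) up front.
#'
#' @param pm A `"parameter_maps"` object.
#' @param core_id Core identifier carried into the table.
#' @param label Group label carried into the table.
#' @param tiles_per_side Tiles per image side (default 8 = 64 sub-images).
#' @param n_g Grey levels for the GLCM quantization.
#' @param d GLCM offset distance.
#' @param min_density Minimum fraction of valid pixels for a viable tile.
#' @param roi Optional logical matrix; pixels outside are invalidated.
#' @param legacy_correlation_sign Passed to [texture_features()].
#' @return A data frame with columns `core_id`, `label`, `tile_row`,
#'   `tile_col`, `pd`, and `<param>_<stat>` for each of the five parameters
#'   (`icp`, `r`, `dcp`, `shgcd`, `shgld`) and seven statistics (`mean`,
#'   `mad`, `contrast`, `correlation`, `entropy`, `asm`, `idm`).
#' @export
build_feature_table <- function(pm, core_id = "core", label = NA_character_,
                                tiles_per_side = 8, n_g = 64, d = 1,
                                min_density = 0.01, roi = NULL,
                                legacy_correlation_sign = FALSE) {
  stopifnot(inherits(pm, "parameter_maps"))
  params <- c(
    icp = "icp", r = "r_ratio", dcp = "dcp",
    shgcd = "shg_cd", shgld = "shg_ld"
  )
  maps <- lapply(pm[params], function(m) {
    m <- matrix(as.vector(m), nrow(m), ncol(m)) # strip qc attributes
    if (!is.null(roi)) m[!roi] <- NaN
    m
  })
  names(maps) <- names(params)
  # per-core robust quantization range, then tile
  qmaps <- lapply(maps, quantize, n_g = n_g)
  vtiles <- lapply(maps, tile_image, tiles_per_side = tiles_per_side)
  qtiles <- lapply(qmaps, tile_image, tiles_per_side = tiles_per_side)
  n_tiles <- tiles_per_side^2
  tile_px <- prod(dim(maps[[1]])) / n_tiles
  rows <- vector("list", n_tiles)
  for (t in seq_len(n_tiles)) {
    # pixel density from the shared validity mask via the ICP tile
    pd <- sum(is.finite(vtiles$icp[[t]]$values))
    if (pd < min_density * tile_px) next
    feats <- list()
    for (pn in names(params)) {
      vt <- vtiles[[pn]][[t]]$values
      st <- subimage_stats(vt)
      g <- masked_glcm(qtiles[[pn]][[t]]$values, n_g = n_g, d = d)
      tx <- texture_features(g, legacy_sign = legacy_correlation_sign)
      feats[[pn]] <- c(st["mean"], st["mad"], tx)
    }
    fv <- unlist(feats)
    names(fv) <- sub("\\.", "_", names(fv))
    rows[[t]] <- data.frame(
      core_id = core_id, label = label,
      tile_row = vtiles$icp[[t]]$tile_row,
      tile_col = vtiles$icp[[t]]$tile_col,
      pd = pd,
      as.list(fv),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame()
  }
  rownames(out) <- NULL
  out
}

#' Names of the 36 sub-image features
#'
#' @return Character vector: `pd` plus `<param>_<stat>` for the five
#'   parameters and seven statistics.
#' @export
feature_names <- function() {
  params <- c("icp", "r", "dcp", "shgcd", "shgld")
  stats <- c("mean", "mad", "contrast", "correlation", "entropy", "asm", "idm")
  c("pd", as.vector(t(outer(params, stats, paste, sep = "_"))))
}
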