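#' Write a measurement stack to TIFF
#'
#' Stores the 16 intensity images either as one multi-page 16-bit TIFF
#' (page order = [measurement_scheme()] order) or as 16 single-page files
#' named `{stem}_{psg}_{psa}.tif`. Counts are rounded to integers; a JSON
#' sidecar (`{stem}.json`) records the intensity scale (counts per
#' grey-level unit), the pixel size and the page order so the stack reads
#' back in the original units.
#'
#' @param stack A [measurement_stack()].
#' @param stem Output path stem (without extension).
#' @param layout `"multipage"` or `"files"`.
#' @return Invisibly, the paths written.
#' @export
write_stack <- function(stack, stem, layout = c("multipage", "files")) {
  layout <- match.arg(layout)
  sch <- measurement_scheme()
  keys <- state_key(sch$psg, sch$psa)
  max_i <- max(1, max(unlist(lapply(stack$images, max))))
  # integer counts per 16-bit grey level; 1 whenever counts fit in 16 bits,
  # which makes the round trip exact for camera-count images
  scale <- ceiling(max_i / 65535)
  imgs <- lapply(stack$images[keys], function(m) round(m / scale) / 65535)
  paths <- character(0)
  if (layout == "multipage") {
    path <- paste0(stem, ".tif")
    tiff::writeTIFF(imgs, path, bits.per.sample = 16L, reduce = FALSE)
    paths <- path
  } else {
    for (k in keys) {
      path <- paste0(stem, "_", k, ".tif")
      tiff::writeTIFF(imgs[[k]], path, bits.per.sample = 16L, reduce = FALSE)
      paths <- c(paths, path)
    }
  }
  meta <- list(
    scale = scale, # counts per grey level
    pixel_size = stack$pixel_size,
    page_order = keys, layout = layout
  )
  jsonlite::write_json(
    meta, paste0(stem, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(c(paths, paste0(stem, ".json")))
}

#' Read a measurement stack from TIFF
#'
#' Accepts either a multi-page 16-page TIFF (pages in
#' [measurement_scheme()] order) or a directory/stem holding 16 files
#' named `{stem}_{psg}_{psa}.tif`. If a `{stem}.json` sidecar exists its
#' intensity scale and pixel size are applied; otherwise raw grey levels
#' are returned. Missing or duplicate states are reported by name.
#'
#' @param path Path to the multi-page TIFF, or the stem used by
#'   [write_stack()].
#' @return A [measurement_stack()].
#' @export
read_stack <- function(path) {
  sch <- measurement_scheme()
  keys <- state_key(sch$psg, sch$psa)
  stem <- sub("\\.tif$", "", path)
  meta_path <- paste0(stem, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(scale = 1, pixel_size = NA_real_)
  }
  to_counts <- function(m) {
    # 16-bit TIFF reads back as grey levels in [0,1] * 65535ths
    round(m * 65535) * meta$scale
  }
  if (file.exists(path) && grepl("\\.tif$", path)) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (length(pages) != 16) {
      stop("expected 16 TIFF pages, found ", length(pages))
    }
    imgs <- lapply(pages, to_counts)
    names(imgs) <- keys
  } else {
    files <- paste0(stem, "_", keys, ".tif")
    missing_f <- keys[!file.exists(files)]
    if (length(missing_f)) {
      stop(
        "missing polarization state files: ",
        paste(missing_f, collapse = ", ")
      )
    }
    imgs <- lapply(files, function(f) to_counts(tiff::readTIFF(f)))
    names(imgs) <- keys
  }
  ps <- if (is.null(meta$pixel_size) || is.na(meta$pixel_size)) 0.3 else meta$pixel_size
  measurement_stack(imgs, pixel_size = ps)
}

#' Write parameter maps to disk
#'
#' Persists the five parameter maps of a core. Each map is affinely scaled
#' into grey levels and written as a 32-bit integer TIFF; the shared
#' validity mask is an 8-bit TIFF; a JSON sidecar (`maps.json`) stores the
#' per-map scaling (lo/hi), the QC counters and the pixel size, so
#' [read_parameter_maps()] restores values (to 2^-32 relative
#' quantization) and the NaN background exactly.
#'
#' @param pm A `"parameter_maps"` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_parameter_maps <- function(pm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ranges <- list()
  for (nm in c("icp", "r_ratio", "dcp", "shg_cd", "shg_ld")) {
    m <- pm[[nm]]
    m <- matrix(as.vector(m), nrow(m), ncol(m))
    fin <- is.finite(m)
    lo <- if (any(fin)) min(m[fin]) else 0
    hi <- if (any(fin)) max(m[fin]) else 1
    if (hi == lo) hi <- lo + 1
    # grey level 0 is reserved for NaN; finite values occupy [eps, 1]
    eps <- 1e-6
    scaled <- matrix(0, nrow(m), ncol(m))
    scaled[fin] <- eps + (1 - eps) * (m[fin] - lo) / (hi - lo)
    tiff::writeTIFF(
      scaled, file.path(dir, paste0(nm, ".tif")),
      bits.per.sample = 32L, reduce = FALSE
    )
    ranges[[nm]] <- c(lo, hi)
  }
  tiff::writeTIFF(
    matrix(as.numeric(pm$valid), nrow(pm$valid)),
    file.path(dir, "valid.tif"),
    bits.per.sample = 8L, reduce = FALSE
  )
  meta <- list(
    ranges = ranges, qc = pm$qc, pixel_size = pm$pixel_size
  )
  jsonlite::write_json(
    meta, file.path(dir, "maps.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read parameter maps written by [write_parameter_maps()]
#'
#' @param dir Directory holding the map TIFFs and `maps.json`.
#' @return A `"parameter_maps"` object.
#' @export
read_parameter_maps <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "maps.json"),
    simplifyVector = TRUE
  )
  valid <- tiff::readTIFF(file.path(dir, "valid.tif")) > 0.5
  maps <- list()
  eps <- 1e-6
  for (nm in c("icp", "r_ratio", "dcp", "shg_cd", "shg_ld")) {
    s <- tiff::readTIFF(file.path(dir, paste0(nm, ".tif")))
    rg <- meta$ranges[[nm]]
    m <- (s - eps) / (1 - eps) * (rg[2] - rg[1]) + rg[1]
    m[s < eps / 2] <- NaN # grey level 0 encodes NaN
    m[!valid] <- NaN
    maps[[nm]] <- m
  }
  structure(
    c(maps, list(
      valid = valid, qc = meta$qc,
      pixel_size = meta$pixel_size
    )),
    class = "parameter_maps"
  )
}

#' Write a feature table to CSV
#'
#' @param features Feature table from [build_feature_table()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_feature_table <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table CSV
#'
#' @param path CSV path written by [write_feature_table()].
#' @return Data frame.
#' @export
read_feature_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
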