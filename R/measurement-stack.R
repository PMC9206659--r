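#' Construct a 16-state P-SHG measurement stack
#'
#' Bundles the 16 co-registered intensity images (one per PSG x PSA
#' polarization-state combination) into a validated container.
#'
#' @param images Named list of 16 numeric matrices; names are
#'   `"<psg>_<psa>"` with states in `{lcp, hlp, rcp, vlp}` (see
#'   [measurement_scheme()]).
#' @param pixel_size Pixel size in micrometres (metadata only).
#' @return An object of class `"measurement_stack"`.
#' @export
measurement_stack <- function(images, pixel_size = 0.3) {
  sch <- measurement_scheme()
  keys <- state_key(sch$psg, sch$psa)
  if (is.null(names(images))) {
    stop("`images` must be a named list keyed by '<psg>_<psa>'")
  }
  missing_keys <- setdiff(keys, names(images))
  if (length(missing_keys)) {
    stop("missing polarization states: ", paste(missing_keys, collapse = ", "))
  }
  extra <- setdiff(names(images), keys)
  if (length(extra)) {
    stop("unexpected state keys: ", paste(extra, collapse = ", "))
  }
  images <- images[keys]
  dims <- vapply(images, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all 16 images must share identical dimensions")
  }
  for (k in keys) {
    if (!is.numeric(images[[k]])) stop("image ", k, " is not numeric")
    if (any(images[[k]] < 0, na.rm = TRUE)) {
      stop("negative intensities in image ", k)
    }
  }
  structure(
    list(
      images = images,
      width = dims[2, 1], height = dims[1, 1],
      pixel_size = pixel_size
    ),
    class = "measurement_stack"
  )
}

#' @export
print.measurement_stack <- function(x, ...) {
  cat(sprintf(
    "P-SHG measurement stack: 16 states, %d x %d px (%.2f um/px)\n",
    x$height, x$width, x$pixel_size
  ))
  rng <- range(unlist(lapply(x$images, range)))
  cat(sprintf("intensity range: [%.4g, %.4g]\n", rng[1], rng[2]))
  invisible(x)
}

# fetch one image by (psg, psa)
stack_image <- function(stack, psg, psa) stack$images[[state_key(psg, psa)]]
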