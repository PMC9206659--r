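#' Build a validated pipeline configuration
#'
#' Flat, typed configuration for [run_pipeline()]. Unknown keys are
#' rejected; thresholds are bound-checked. Defaults reproduce the standard
#' analysis settings at desk scale.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A list of class `"pshg_config"`.
#' @section Keys:
#' \describe{
#'   \item{seed}{master seed (integer).}
#'   \item{n_per_group}{simulated cores per group.}
#'   \item{core_size}{core image side in pixels.}
#'   \item{noise}{logical; simulate detector noise.}
#'   \item{snr_threshold}{analysis SNR threshold (default 3).}
#'   \item{sign_s1, sign_s3}{Stokes sign conventions (+1/-1).}
#'   \item{r_branch}{"auto", "minus" or "plus".}
#'   \item{tiles_per_side}{subdivision level (default 8).}
#'   \item{n_g}{GLCM grey levels.}
#'   \item{glcm_d}{GLCM offset distance.}
#'   \item{min_density}{tile viability threshold (fraction of pixels).}
#'   \item{trim_lo, trim_hi}{trimming percentiles for the stats stage.}
#'   \item{k_folds, repeats, threshold, ridge}{CV protocol.}
#'   \item{held_out_per_group}{cores per group reserved for prediction.}
#' }
#' @export
pshg_config <- function(...) {
  defaults <- list(
    seed = 1L,
    n_per_group = 4L,
    core_size = 256L,
    noise = TRUE,
    snr_threshold = 3,
    sign_s1 = 1, sign_s3 = 1,
    r_branch = "auto",
    tiles_per_side = 8L,
    n_g = 32L,
    glcm_d = 1L,
    min_density = 0.01,
    trim_lo = 1, trim_hi = 99,
    k_folds = 5L, repeats = 20L, threshold = 0.5, ridge = 0,
    held_out_per_group = 1L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, over)
  stopifnot(
    cfg$snr_threshold >= 0, cfg$min_density >= 0, cfg$min_density <= 1,
    cfg$trim_lo < cfg$trim_hi, cfg$n_g >= 2, cfg$glcm_d >= 1,
    cfg$k_folds >= 2, cfg$repeats >= 1,
    cfg$threshold > 0, cfg$threshold < 1,
    cfg$r_branch %in% c("auto", "minus", "plus"),
    cfg$sign_s1 %in% c(-1, 1), cfg$sign_s3 %in% c(-1, 1),
    cfg$held_out_per_group >= 0, cfg$held_out_per_group < cfg$n_per_group
  )
  structure(cfg, class = "pshg_config")
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic-data pipeline
#'
#' Orchestrates the stages end to end on a simulated dataset: simulate
#' cores, reconstruct Stokes maps, derive parameter maps with SNR masking,
#' build the sub-image feature table, screen features by significance, and
#' train/evaluate the classifier (CV panel on training cores plus a
#' held-out core prediction). Artifacts (parameter maps, feature CSV,
#' significance CSV, exclusion JSON, metrics JSON, run log) are written
#' under `out_dir`; all CSV/JSON outputs embed the configuration hash and
#' master seed, so equal configurations give identical outputs.
#'
#' @param config A [pshg_config()].
#' @param out_dir Output directory (created).
#' @param write_maps Write per-core parameter-map TIFFs (default `FALSE`;
#'   the maps can be large).
#' @return Invisibly, a list of class `"pshg_run"` with the in-memory
#'   results of each stage (`dataset`, `cores`, `features`, `screen`,
#'   `cv`, `held_out`, `log`).
#' @export
run_pipeline <- function(config = pshg_config(), out_dir = tempfile("pshg_run_"),
                         write_maps = FALSE) {
  stopifnot(inherits(config, "pshg_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  log <- list(
    config = unclass(config), config_hash = hash, seed = config$seed,
    counters = list()
  )

  # --- simulate ---
  ds <- generate_dataset(
    config$n_per_group,
    core_size = config$core_size,
    seed = config$seed, noise = config$noise
  )

  # --- reconstruct + parameter maps ---
  cores <- lapply(ds$cores, function(co) {
    st <- reconstruct_stokes(
      co$stack,
      sign_s1 = config$sign_s1, sign_s3 = config$sign_s3
    )
    icp <- compute_icp(st)
    preset <- group_preset(co$label)
    mask <- if (config$noise) {
      snr_mask(
        icp,
        # ICP background: each s0 sums 4 images / 2 -> N(2*mu, sd); the
        # average over the two circular PSG states divides sd by sqrt(2)
        background = c(
          2 * preset$background_mean,
          preset$background_sd / sqrt(2)
        ),
        threshold = config$snr_threshold
      )
    } else {
      icp > 0
    }
    pm <- compute_parameter_maps(st, mask = mask, branch = config$r_branch)
    list(core_id = co$core_id, label = co$label, pm = pm, field = co$field)
  })
  log$counters$r_branch <- cores[[1]]$pm$qc$r_branch
  log$counters$valid_fraction <- vapply(
    cores, function(co) co$pm$qc$n_valid / co$pm$qc$n_pixels, numeric(1)
  )
  if (write_maps) {
    for (co in cores) {
      write_parameter_maps(co$pm, file.path(out_dir, "maps", co$core_id))
    }
  }

  # --- features ---
  features <- do.call(rbind, lapply(cores, function(co) {
    build_feature_table(
      co$pm,
      core_id = co$core_id, label = co$label,
      tiles_per_side = config$tiles_per_side,
      n_g = config$n_g, d = config$glcm_d,
      min_density = config$min_density
    )
  }))
  rownames(features) <- NULL
  log$counters$n_tiles <- nrow(features)
  write_feature_table(features, file.path(out_dir, "features.csv"))

  # --- stats ---
  screen <- significance_matrix(
    features,
    lo_pct = config$trim_lo, hi_pct = config$trim_hi
  )
  utils::write.csv(
    screen$records, file.path(out_dir, "significance.csv"),
    row.names = FALSE
  )
  jsonlite::write_json(
    list(
      excluded = screen$excluded, config_hash = hash, seed = config$seed
    ),
    file.path(out_dir, "exclusion.json"),
    auto_unbox = TRUE, digits = NA
  )

  # --- classify ---
  man <- ds$manifest
  held_out_ids <- unlist(lapply(split(man$core_id, man$label), function(ids) {
    utils::tail(ids, config$held_out_per_group)
  }))
  train <- features[!features$core_id %in% held_out_ids, , drop = FALSE]
  predictors <- setdiff(
    intersect(feature_names(), names(features)), screen$excluded
  )
  cv <- fit_logistic_cv(
    train[, predictors, drop = FALSE],
    factor(train$label, levels = c("normal", "tumor")),
    k = config$k_folds, repeats = config$repeats,
    threshold = config$threshold, seed = config$seed, ridge = config$ridge
  )
  held_out <- if (length(held_out_ids)) {
    features$.y <- as.integer(features$label == "tumor")
    predict_held_out(
      features, held_out_ids,
      predictors = predictors,
      label_col = ".y", threshold = config$threshold, ridge = config$ridge
    )
  }
  metrics_out <- list(
    config_hash = hash, seed = config$seed,
    predictors = predictors,
    cv_summary = cv$summary,
    held_out_cores = as.list(held_out_ids),
    held_out_metrics = if (!is.null(held_out)) as.list(held_out$metrics)
  )
  jsonlite::write_json(
    metrics_out, file.path(out_dir, "metrics.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  jsonlite::write_json(
    log, file.path(out_dir, "run_log.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(structure(
    list(
      dataset = ds, cores = cores, features = features, screen = screen,
      cv = cv, held_out = held_out, log = log, out_dir = out_dir
    ),
    class = "pshg_run"
  ))
}

#' @export
print.pshg_run <- function(x, ...) {
  cat("P-SHG pipeline run\n")
  cat(sprintf(
    "  cores: %d, feature rows: %d, predictors: %d (excluded: %d)\n",
    length(x$cores), nrow(x$features),
    length(setdiff(
      intersect(feature_names(), names(x$features)), x$screen$excluded
    )),
    length(x$screen$excluded)
  ))
  print(x$cv)
  if (!is.null(x$held_out)) print(x$held_out)
  invisible(x)
}
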