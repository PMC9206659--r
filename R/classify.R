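#' Classification metric panel for one evaluation
#'
#' Confusion-matrix metrics at a posterior-probability threshold plus two
#' threshold-independent scores: the AUROC by the midrank (Mann-Whitney)
#' statistic, ties counted one half, and the Brier score (mean squared
#' error of the probabilities against the 0/1 labels). Metrics with an
#' empty denominator, and the AUROC when only one class is present, are
#' `NA`. The complementary pairs satisfy `tpr + fnr = 1`, `tnr + fpr = 1`,
#' `ppv + fdr = 1`, `npv + fom = 1` whenever defined.
#'
#' @param truth Binary labels (0/1, logical, or a 2-level factor or
#'   character vector whose second sorted level is the positive class).
#' @param prob Predicted probabilities of the positive class, in `[0, 1]`.
#' @param threshold Classification threshold (default 0.5).
#' @return Named numeric vector: `accuracy`, `f1`, `tpr`, `tnr`, `ppv`,
#'   `npv`, `fpr`, `fnr`, `fom`, `fdr`, `auroc`, `brier`.
#' @export
compute_metrics <- function(truth, prob, threshold = 0.5) {
  y <- as_binary(truth)
  stopifnot(length(y) == length(prob), all(prob >= 0 & prob <= 1))
  pred <- as.integer(prob >= threshold)
  tp <- sum(pred == 1 & y == 1)
  tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0)
  fn <- sum(pred == 0 & y == 1)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  tpr <- rate(tp, tp + fn)
  tnr <- rate(tn, tn + fp)
  ppv <- rate(tp, tp + fp)
  npv <- rate(tn, tn + fn)
  f1 <- if (!is.na(ppv) && !is.na(tpr) && (ppv + tpr) > 0) {
    2 * ppv * tpr / (ppv + tpr)
  } else {
    NA_real_
  }
  auroc <- if (n1 > 0 && n0 > 0) {
    r <- rank(prob) # midranks handle ties as half-counts
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else {
    NA_real_
  }
  c(
    accuracy = (tp + tn) / length(y),
    f1 = f1,
    tpr = tpr, tnr = tnr, ppv = ppv, npv = npv,
    fpr = if (is.na(tnr)) NA_real_ else 1 - tnr,
    fnr = if (is.na(tpr)) NA_real_ else 1 - tpr,
    fom = if (is.na(npv)) NA_real_ else 1 - npv,
    fdr = if (is.na(ppv)) NA_real_ else 1 - ppv,
    auroc = auroc,
    brier = mean((prob - y)^2)
  )
}

as_binary <- function(truth) {
  if (is.logical(truth)) {
    return(as.integer(truth))
  }
  if (is.character(truth)) truth <- factor(truth)
  if (is.factor(truth)) {
    if (nlevels(truth) != 2) stop("truth factor must have 2 levels")
    return(as.integer(truth == levels(truth)[2]))
  }
  u <- sort(unique(truth))
  if (!all(u %in% c(0, 1))) stop("truth must be binary (0/1)")
  as.integer(truth)
}

# Unpenalized logistic fit returning a linear predictor function of the
# (already standardized) feature matrix. Falls back to ridge (glmnet) when
# requested for separable data.
fit_logistic <- function(x, y, ridge = 0) {
  if (ridge > 0) {
    if (!requireNamespace("glmnet", quietly = TRUE)) {
      stop("ridge > 0 requires the glmnet package")
    }
    fit <- glmnet::glmnet(x, y,
      family = "binomial", alpha = 0,
      lambda = ridge, standardize = FALSE
    )
    beta <- c(as.numeric(fit$a0), as.numeric(fit$beta))
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, x), y, family = stats::binomial())
    )
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0 # aliased columns carry no signal
  }
  beta
}

logistic_prob <- function(beta, x) {
  eta <- beta[1] + as.matrix(x) %*% beta[-1]
  as.numeric(1 / (1 + exp(-eta)))
}

# Stratified k-fold assignment; returns an integer fold id per row.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Repeated stratified cross-validated logistic regression
#'
#' The classification protocol of the pipeline: per repeat, a fresh
#' stratified k-fold partition is drawn; per fold, features are
#' standardized with training-fold statistics only and an unpenalized
#' binary logistic regression is fitted; out-of-fold posterior
#' probabilities are pooled within the repeat and the full metric panel is
#' evaluated at the threshold. The panel summary is the mean and standard
#' deviation of each metric across repeats; the SD measures classifier
#' stability. Deterministic given the master seed.
#'
#' @param x Numeric feature matrix or data frame (rows = sub-images).
#' @param y Binary labels (see [compute_metrics()]).
#' @param k Number of folds (default 5).
#' @param repeats Number of repeated partitions (the full protocol uses
#'   1000; smaller values are appropriate for exploratory runs).
#' @param threshold Posterior-probability threshold (default 0.5).
#' @param seed Master seed.
#' @param ridge Optional ridge penalty (0 = plain maximum likelihood).
#' @return An object of class `"pshg_cv"`: `per_repeat` (data frame of
#'   metrics, one row per repeat), `summary` (mean and sd per metric),
#'   `beta` (coefficients of a final fit on all rows, on standardized
#'   scale), `scaling` (feature means/sds of the final fit), plus the
#'   protocol settings.
#' @export
fit_logistic_cv <- function(x, y, k = 5, repeats = 100, threshold = 0.5,
                            seed = 1, ridge = 0) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- as_binary(y)
  keep <- stats::complete.cases(x)
  n_dropped <- sum(!keep)
  x <- x[keep, , drop = FALSE]
  y <- y[keep]
  stopifnot(k >= 2, repeats >= 1)
  if (min(table(y)) < k) stop("need at least k samples in each class")
  metric_names <- names(compute_metrics(c(0, 1), c(0.2, 0.8)))
  per_repeat <- matrix(
    NA_real_, repeats, length(metric_names),
    dimnames = list(NULL, metric_names)
  )
  n_redrawn <- 0L
  with_seed(seed, {
    for (rep_i in seq_len(repeats)) {
      for (attempt in 1:100) {
        fold <- stratified_folds(y, k)
        ok <- all(vapply(
          seq_len(k),
          function(f) length(unique(y[fold != f])) == 2,
          logical(1)
        ))
        if (ok) break
        n_redrawn <- n_redrawn + 1L
      }
      prob <- numeric(length(y))
      for (f in seq_len(k)) {
        tr <- fold != f
        mu <- colMeans(x[tr, , drop = FALSE])
        sg <- apply(x[tr, , drop = FALSE], 2, stats::sd)
        sg[sg == 0 | !is.finite(sg)] <- 1
        xs_tr <- scale(x[tr, , drop = FALSE], center = mu, scale = sg)
        xs_te <- scale(x[!tr, , drop = FALSE], center = mu, scale = sg)
        beta <- fit_logistic(xs_tr, y[tr], ridge = ridge)
        prob[!tr] <- logistic_prob(beta, xs_te)
      }
      per_repeat[rep_i, ] <- compute_metrics(y, prob, threshold)
    }
  })
  # final refit on all rows for downstream prediction
  mu <- colMeans(x)
  sg <- apply(x, 2, stats::sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  beta <- fit_logistic(scale(x, mu, sg), y, ridge = ridge)
  per_repeat <- as.data.frame(per_repeat)
  summ <- data.frame(
    metric = metric_names,
    mean = vapply(per_repeat, mean, numeric(1)),
    sd = vapply(per_repeat, stats::sd, numeric(1)),
    row.names = NULL
  )
  structure(
    list(
      per_repeat = per_repeat, summary = summ,
      beta = beta, scaling = list(mean = mu, sd = sg),
      features = colnames(x),
      k = k, repeats = repeats, threshold = threshold, seed = seed,
      ridge = ridge, n_dropped = n_dropped, n_redrawn = n_redrawn
    ),
    class = "pshg_cv"
  )
}

#' @export
print.pshg_cv <- function(x, ...) {
  cat(sprintf(
    "Logistic regression, %d-fold stratified CV x %d repeats (threshold %.2f)\n",
    x$k, x$repeats, x$threshold
  ))
  s <- x$summary
  key <- s[s$metric %in% c("accuracy", "f1", "auroc", "brier"), ]
  for (i in seq_len(nrow(key))) {
    cat(sprintf(
      "  %-8s %.3f +/- %.3f\n", key$metric[i], key$mean[i], key$sd[i]
    ))
  }
  invisible(x)
}

#' @export
summary.pshg_cv <- function(object, ...) {
  cat(sprintf(
    "Logistic regression CV panel (%d features, %d repeats):\n",
    length(object$features), object$repeats
  ))
  print(object$summary, digits = 3)
  if (object$n_dropped > 0) {
    cat(sprintf("rows dropped for missing features: %d\n", object$n_dropped))
  }
  invisible(object$summary)
}

#' @export
coef.pshg_cv <- function(object, ...) {
  stats::setNames(object$beta, c("(Intercept)", object$features))
}

#' Predict posterior probabilities from a CV-trained classifier
#'
#' Uses the final all-rows refit (standardized with its training
#' statistics) stored in the `"pshg_cv"` object.
#'
#' @param object A `"pshg_cv"` object.
#' @param newdata Data frame or matrix containing the model's feature
#'   columns.
#' @param type `"prob"` for posterior probabilities, `"label"` for
#'   thresholded 0/1 labels.
#' @param ... Unused.
#' @return Numeric vector of probabilities or integer labels.
#' @export
predict.pshg_cv <- function(object, newdata, type = c("prob", "label"), ...) {
  type <- match.arg(type)
  nd <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  xs <- scale(nd, object$scaling$mean, object$scaling$sd)
  p <- logistic_prob(object$beta, xs)
  if (type == "label") as.integer(p >= object$threshold) else p
}

#' @export
plot.pshg_cv <- function(x, ...) {
  graphics::boxplot(
    x$per_repeat[, c("accuracy", "f1", "tpr", "tnr", "auroc")],
    ylab = "metric value", main = "CV metric stability across repeats", ...
  )
  invisible(x)
}

#' Feature-subset comparison experiment
#'
#' Re-runs the CV protocol on four nested predictor subsets: (1) SHG
#' intensity statistics (mean + MAD) and pixel density; (2) subset 1 plus
#' the intensity texture features; (3) mean + MAD of all five polarimetric
#' parameters and pixel density; (4) all predictors surviving the
#' significance screen (the complete dataset). Mirrors the standard
#' ablation that shows texture and polarimetric parameters each add
#' discriminative power.
#'
#' @param features Feature table (data frame) with label column.
#' @param label_col Name of the binary label column.
#' @param excluded Character vector of feature names to drop from subset 4
#'   (from [significance_matrix()]).
#' @param ... Passed to [fit_logistic_cv()] (k, repeats, seed, ...).
#' @return A list of class `"subset_experiment"` with one `"pshg_cv"` per
#'   subset (named `intensity_pd`, `intensity_tx_pd`, `polarimetry_pd`,
#'   `all`), plus `columns`, the per-subset predictor lists.
#' @export
subset_experiment <- function(features, label_col = "label",
                              excluded = character(0), ...) {
  all_feats <- intersect(feature_names(), names(features))
  tx <- c("contrast", "correlation", "entropy", "asm", "idm")
  params <- c("icp", "r", "dcp", "shgcd", "shgld")
  subsets <- list(
    intensity_pd = c("icp_mean", "icp_mad", "pd"),
    intensity_tx_pd = c("icp_mean", "icp_mad", paste0("icp_", tx), "pd"),
    polarimetry_pd = c(
      paste0(rep(params, each = 2), "_", c("mean", "mad")), "pd"
    ),
    all = setdiff(all_feats, excluded)
  )
  subsets <- lapply(subsets, intersect, y = names(features))
  y <- features[[label_col]]
  fits <- lapply(subsets, function(cols) {
    fit_logistic_cv(features[, cols, drop = FALSE], y, ...)
  })
  structure(
    list(fits = fits, columns = subsets),
    class = "subset_experiment"
  )
}

#' @export
print.subset_experiment <- function(x, ...) {
  cat("Feature-subset experiment:\n")
  for (nm in names(x$fits)) {
    s <- x$fits[[nm]]$summary
    acc <- s[s$metric == "accuracy", ]
    auc <- s[s$metric == "auroc", ]
    cat(sprintf(
      "  %-16s (%2d predictors): accuracy %.3f +/- %.3f, AUROC %.3f\n",
      nm, length(x$columns[[nm]]), acc$mean, acc$sd, auc$mean
    ))
  }
  invisible(x)
}

#' Train on training cores, predict held-out cores
#'
#' Removes the held-out cores from the table, refits the logistic model on
#' every remaining row (standardization from the training rows only), and
#' predicts the held-out sub-images. A leakage guard errors if a held-out
#' core id also appears among the training rows.
#'
#' @param features Feature table with `core_id` and label columns.
#' @param held_out Character vector of core ids to hold out.
#' @param predictors Character vector of predictor columns (default: all
#'   feature columns present).
#' @param label_col Binary label column name.
#' @param threshold Posterior threshold.
#' @param ridge Optional ridge penalty.
#' @return A list of class `"held_out_prediction"`: `tiles` (data frame of
#'   held-out rows with `prob` and `pred`), `metrics` (metric panel on the
#'   held-out rows), and `model` (the refit `"pshg_cv"`-style parameters).
#' @export
predict_held_out <- function(features, held_out, predictors = NULL,
                             label_col = "label", threshold = 0.5,
                             ridge = 0) {
  stopifnot("core_id" %in% names(features))
  if (is.null(predictors)) {
    predictors <- intersect(feature_names(), names(features))
  }
  missing_cores <- setdiff(held_out, features$core_id)
  if (length(missing_cores)) {
    stop("held-out cores not in table: ", paste(missing_cores, collapse = ", "))
  }
  test <- features[features$core_id %in% held_out, , drop = FALSE]
  train <- features[!features$core_id %in% held_out, , drop = FALSE]
  if (any(train$core_id %in% held_out)) {
    stop("leakage: held-out core id present in training rows")
  }
  xtr <- as.matrix(train[, predictors, drop = FALSE])
  ytr <- as_binary(train[[label_col]])
  keep <- stats::complete.cases(xtr)
  xtr <- xtr[keep, , drop = FALSE]
  ytr <- ytr[keep]
  mu <- colMeans(xtr)
  sg <- apply(xtr, 2, stats::sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  beta <- fit_logistic(scale(xtr, mu, sg), ytr, ridge = ridge)
  xte <- as.matrix(test[, predictors, drop = FALSE])
  ok_te <- stats::complete.cases(xte)
  prob <- rep(NA_real_, nrow(test))
  prob[ok_te] <- logistic_prob(
    beta, scale(xte[ok_te, , drop = FALSE], mu, sg)
  )
  tiles <- cbind(
    test[, intersect(c("core_id", "label", "tile_row", "tile_col"), names(test))],
    prob = prob, pred = as.integer(prob >= threshold)
  )
  yte <- as_binary(test[[label_col]])
  metrics <- compute_metrics(yte[ok_te], prob[ok_te], threshold)
  structure(
    list(
      tiles = tiles, metrics = metrics,
      model = list(
        beta = beta, scaling = list(mean = mu, sd = sg),
        predictors = predictors, threshold = threshold
      )
    ),
    class = "held_out_prediction"
  )
}

#' @export
print.held_out_prediction <- function(x, ...) {
  cat(sprintf(
    "Held-out prediction: %d tiles from %d cores\n",
    nrow(x$tiles), length(unique(x$tiles$core_id))
  ))
  m <- x$metrics
  cat(sprintf(
    "  accuracy %.3f, F1 %.3f, AUROC %.3f, Brier %.3f\n",
    m["accuracy"], m["f1"], m["auroc"], m["brier"]
  ))
  invisible(x)
}

#' Tile-grid label map of a held-out prediction
#'
#' @param pred A `"held_out_prediction"`.
#' @param core_id Which core to map.
#' @return An integer matrix over the tile grid (NA = tile dropped,
#'   0 = predicted normal, 1 = predicted tumor).
#' @export
prediction_label_map <- function(pred, core_id) {
  t <- pred$tiles[pred$tiles$core_id == core_id, ]
  if (!nrow(t)) stop("no tiles for core ", core_id)
  n <- max(t$tile_row, t$tile_col)
  m <- matrix(NA_integer_, n, n)
  m[cbind(t$tile_row, t$tile_col)] <- t$pred
  m
}

#' Subdivision-level sweep
#'
#' Rebuilds the feature table at several subdivision levels (tiles per
#' image side) and reruns the CV protocol at each, reporting the metric
#' panel and the stability (SD across repeats) per level. Coarser levels
#' give fewer, larger sub-images: often slightly higher point accuracy but
#' less stable estimates.
#'
#' @param cores List of cores, each a list with `pm` (a
#'   `"parameter_maps"`), `core_id` and `label`.
#' @param levels Integer vector of tiles-per-side values; each must divide
#'   the image side.
#' @param n_g,d,min_density Passed to [build_feature_table()].
#' @param ... Passed to [fit_logistic_cv()] (k, repeats, seed, ...).
#' @return A list of class `"subdivision_sweep"`: `panels` (one
#'   `"pshg_cv"` per level) and `stability` (data frame `level`, `n_rows`,
#'   `accuracy_mean`, `accuracy_sd`, `auroc_mean`, `brier_mean`).
#' @export
subdivision_sweep <- function(cores, levels = c(1, 2, 4, 8), n_g = 32,
                              d = 1, min_density = 0.01, ...) {
  side <- nrow(cores[[1]]$pm$icp)
  bad <- levels[side %% levels != 0]
  if (length(bad)) {
    stop("levels not dividing image side ", side, ": ", paste(bad, collapse = ", "))
  }
  panels <- list()
  rows <- list()
  for (lv in levels) {
    ft <- do.call(rbind, lapply(cores, function(co) {
      build_feature_table(
        co$pm,
        core_id = co$core_id, label = co$label,
        tiles_per_side = lv, n_g = n_g, d = d, min_density = min_density
      )
    }))
    feats <- intersect(feature_names(), names(ft))
    fit <- fit_logistic_cv(ft[, feats], ft$label, ...)
    panels[[as.character(lv)]] <- fit
    s <- fit$summary
    rows[[as.character(lv)]] <- data.frame(
      level = lv, n_rows = nrow(ft),
      accuracy_mean = s$mean[s$metric == "accuracy"],
      accuracy_sd = s$sd[s$metric == "accuracy"],
      auroc_mean = s$mean[s$metric == "auroc"],
      brier_mean = s$mean[s$metric == "brier"]
    )
  }
  structure(
    list(
      panels = panels,
      stability = do.call(rbind, c(rows, make.row.names = FALSE))
    ),
    class = "subdivision_sweep"
  )
}

#' @export
print.subdivision_sweep <- function(x, ...) {
  cat("Subdivision-level sweep:\n")
  print(x$stability, digits = 3)
  invisible(x)
}
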