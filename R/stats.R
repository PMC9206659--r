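#' Trim extreme percentiles from a value vector
#'
#' Removes values strictly below the `lo_pct` percentile and strictly
#' above the `hi_pct` percentile (percentiles by linear interpolation,
#' `quantile` type 7). Applied per group and per parameter before
#' significance testing to blunt extreme outliers. Vectors with fewer than
#' 10 values are returned unchanged with a warning. Because the
#' percentiles are recomputed from the data they are applied to, repeated
#' trimming can shave a little further; trim once, on the raw values.
#'
#' @param x Numeric vector.
#' @param lo_pct,hi_pct Percentile bounds in `[0, 100]`.
#' @return The trimmed vector.
#' @export
trim_percentiles <- function(x, lo_pct = 1, hi_pct = 99) {
  if (lo_pct >= hi_pct) stop("lo_pct must be < hi_pct")
  x <- x[is.finite(x)]
  if (length(x) < 10) {
    warning("fewer than 10 values; returned untrimmed")
    return(x)
  }
  q <- stats::quantile(x, c(lo_pct, hi_pct) / 100, names = FALSE, type = 7)
  x[x >= q[1] & x <= q[2]]
}

#' Kruskal-Wallis omnibus test with Dunn-Bonferroni post hoc comparisons
#'
#' Runs the rank-based Kruskal-Wallis H test (with tie correction, via
#' [stats::kruskal.test()]) across the groups of one parameter, then Dunn's
#' pairwise z-tests on the mean ranks with the usual tie-corrected
#' variance,
#' \deqn{z_{ab} = \frac{\bar R_a - \bar R_b}{\sqrt{\left(\frac{N(N+1)}{12}
#'   - \frac{\sum (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_a} +
#'   \frac{1}{n_b}\right)}},}
#' Bonferroni-adjusting the two-sided p-values over the pairwise
#' comparisons within the parameter. Each adjusted p is categorized as
#' `highly_significant` (p < 0.001), `significant` (0.001 <= p < 0.05) or
#' `ns`.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor (or coercible) of group membership, same length.
#' @return A list of class `"kruskal_dunn"`: `h`, `df`, `p_omnibus` from
#'   the omnibus test, and `pairs`, a data frame with columns `group1`,
#'   `group2`, `z`, `p_raw`, `p_adj`, `category`.
#' @export
kruskal_dunn <- function(values, groups) {
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 groups")
  n_by <- table(groups)
  if (any(n_by < 2)) stop("each group needs at least 2 values")
  lv <- levels(groups)
  pairs_idx <- utils::combn(k, 2)
  m <- ncol(pairs_idx)
  n <- length(values)
  if (length(unique(values)) == 1) {
    # fully tied data carries no ordering information
    pairs <- data.frame(
      group1 = lv[pairs_idx[1, ]], group2 = lv[pairs_idx[2, ]],
      z = 0, p_raw = 1, p_adj = 1, category = "ns",
      stringsAsFactors = FALSE
    )
    return(structure(
      list(h = 0, df = k - 1, p_omnibus = 1, pairs = pairs),
      class = "kruskal_dunn"
    ))
  }
  kw <- stats::kruskal.test(values, groups)
  r <- rank(values)
  mean_rank <- tapply(r, groups, mean)
  tie_tab <- table(values)
  tie_term <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  var_base <- n * (n + 1) / 12 - tie_term
  z <- p_raw <- numeric(m)
  for (q in seq_len(m)) {
    a <- pairs_idx[1, q]
    b <- pairs_idx[2, q]
    se <- sqrt(var_base * (1 / n_by[a] + 1 / n_by[b]))
    z[q] <- (mean_rank[a] - mean_rank[b]) / se
    p_raw[q] <- 2 * stats::pnorm(-abs(z[q]))
  }
  p_adj <- pmin(p_raw * m, 1)
  category <- ifelse(p_adj < 0.001, "highly_significant",
    ifelse(p_adj < 0.05, "significant", "ns")
  )
  pairs <- data.frame(
    group1 = lv[pairs_idx[1, ]], group2 = lv[pairs_idx[2, ]],
    z = z, p_raw = p_raw, p_adj = p_adj, category = category,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      h = unname(kw$statistic), df = unname(kw$parameter),
      p_omnibus = kw$p.value, pairs = pairs
    ),
    class = "kruskal_dunn"
  )
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf(
    "Kruskal-Wallis H = %.3f, df = %g, p = %.3g\n", x$h, x$df, x$p_omnibus
  ))
  print(x$pairs, digits = 3)
  invisible(x)
}

#' Significance screen across all features
#'
#' For each feature column, trims each group's values at the configured
#' percentiles and runs [kruskal_dunn()] across the groups, collecting
#' every pairwise record (the data behind a circular significance plot).
#' Features for which no comparison between the reference (normal) group
#' and any other group is significant are put on the exclusion list and
#' are dropped from classification.
#'
#' @param features Data frame containing the feature columns and a group
#'   column.
#' @param feature_cols Character vector of feature column names (default
#'   [feature_names()] intersected with the table).
#' @param group_col Name of the group column (default `"label"`).
#' @param normal_label Reference group label (default `"normal"`).
#' @param trim `TRUE` to apply percentile trimming per group.
#' @param lo_pct,hi_pct Trimming percentiles.
#' @return A list of class `"significance_screen"`: `records` (data frame
#'   `parameter`, `group1`, `group2`, `z`, `p_raw`, `p_adj`, `category`)
#'   and `excluded` (character vector of never-significant features).
#' @export
significance_matrix <- function(features, feature_cols = NULL,
                                group_col = "label",
                                normal_label = "normal",
                                trim = TRUE, lo_pct = 1, hi_pct = 99) {
  if (is.null(feature_cols)) {
    feature_cols <- intersect(feature_names(), names(features))
  }
  stopifnot(length(feature_cols) >= 1, group_col %in% names(features))
  groups <- factor(features[[group_col]])
  records <- list()
  excluded <- character(0)
  for (fc in feature_cols) {
    vals <- split(features[[fc]], groups)
    if (trim) {
      vals <- lapply(vals, function(v) {
        suppressWarnings(trim_percentiles(v, lo_pct, hi_pct))
      })
    }
    v <- unlist(vals, use.names = FALSE)
    g <- rep(names(vals), lengths(vals))
    kd <- kruskal_dunn(v, g)
    rec <- cbind(parameter = fc, kd$pairs, stringsAsFactors = FALSE)
    records[[fc]] <- rec
    vs_normal <- rec[rec$group1 == normal_label | rec$group2 == normal_label, ]
    if (nrow(vs_normal) > 0 && all(vs_normal$category == "ns")) {
      excluded <- c(excluded, fc)
    }
  }
  structure(
    list(
      records = do.call(rbind, c(records, make.row.names = FALSE)),
      excluded = excluded,
      normal_label = normal_label
    ),
    class = "significance_screen"
  )
}

#' @export
print.significance_screen <- function(x, ...) {
  n_par <- length(unique(x$records$parameter))
  cat(sprintf(
    "Significance screen: %d parameters, %d pairwise records\n",
    n_par, nrow(x$records)
  ))
  cat(sprintf(
    "excluded (no significant pair vs %s): %s\n", x$normal_label,
    if (length(x$excluded)) paste(x$excluded, collapse = ", ") else "none"
  ))
  invisible(x)
}

#' Normality report for feature columns
#'
#' Shapiro-Wilk p-values per feature and group (subsampled to at most 5000
#' values, the test's limit). Purely descriptive: the pipeline's tests are
#' rank-based regardless; this report documents why.
#'
#' @inheritParams significance_matrix
#' @param seed Seed for the subsampling.
#' @return Data frame `parameter`, `group`, `n`, `shapiro_p`.
#' @export
normality_report <- function(features, feature_cols = NULL,
                             group_col = "label", seed = 1) {
  if (is.null(feature_cols)) {
    feature_cols <- intersect(feature_names(), names(features))
  }
  groups <- factor(features[[group_col]])
  out <- list()
  for (fc in feature_cols) {
    for (g in levels(groups)) {
      v <- features[[fc]][groups == g]
      v <- v[is.finite(v)]
      p <- if (length(v) >= 3 && length(unique(v)) > 1) {
        if (length(v) > 5000) {
          v <- with_seed(seed, sample(v, 5000))
        }
        stats::shapiro.test(v)$p.value
      } else {
        NA_real_
      }
      out[[paste(fc, g)]] <- data.frame(
        parameter = fc, group = g, n = length(v), shapiro_p = p,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
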