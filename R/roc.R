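#' All-pairs window correlation matrix
#'
#' Pearson correlation between the feature vectors of every pair of windows
#' at one timescale: symmetric, unit diagonal, entries in `[-1, 1]`.
#' Windows whose feature vector is constant get `NA` rows/columns (sentinel;
#' excluded from ROC evaluation downstream).
#'
#' @param features A `feature_matrix` (windows x channels) or plain matrix.
#' @return A W x W numeric matrix.
#' @export
pairwise_r_matrix <- function(features) {
  x <- if (inherits(features, "feature_matrix")) unclass_matrix(features) else as.matrix(features)
  stopifnot(nrow(x) >= 2)
  r <- clip_unit(suppressWarnings(stats::cor(t(x))))
  const <- apply(x, 1, stats::sd) == 0
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  diag(r)[!const] <- 1
  r
}

default_thresholds <- function() seq(-1, 1, by = 0.01)

#' Threshold sweep for one query window
#'
#' The query window's correlations with every other window are thresholded
#' at each value of a common grid: windows with `r >= threshold` are
#' predicted positive; windows sharing the query's ground-truth label are
#' the actual positives. The query itself is excluded from the candidates.
#' Queries whose label has no other member, or with no negative candidates,
#' are skipped (their rates are undefined).
#'
#' @param r_row Numeric vector of correlations of the query against all W
#'   windows (including itself; `NA` entries are dropped from candidates).
#' @param labels Character vector of per-window ground-truth labels.
#' @param query Index of the query window in `r_row`/`labels`.
#' @param thresholds Correlation thresholds to sweep (default
#'   `seq(-1, 1, 0.01)`).
#' @return A tibble with one row per threshold: `threshold`, `tp`, `fp`,
#'   `tn`, `fn`, `tpr`, `fpr`; zero rows when the query is skipped.
#' @export
#' @examples
#' roc_per_query(c(NA, 0.9, 0.1, -0.2), c("A", "A", "B", "B"), 1,
#'               thresholds = c(0.5, 0))
roc_per_query <- function(r_row, labels, query, thresholds = default_thresholds()) {
  stopifnot(length(r_row) == length(labels), query >= 1, query <= length(r_row))
  cand <- setdiff(seq_along(r_row), query)
  cand <- cand[!is.na(r_row[cand]) & !is.na(labels[cand])]
  pos <- cand[labels[cand] == labels[query]]
  neg <- setdiff(cand, pos)
  if (length(pos) == 0 || length(neg) == 0) {
    warn(sprintf("query %d skipped: no %s candidates share the evaluation", query,
                 if (length(pos) == 0) "positive" else "negative"))
    return(tibble(threshold = numeric(), tp = integer(), fp = integer(),
                  tn = integer(), fn = integer(), tpr = numeric(), fpr = numeric()))
  }
  tp <- colSums(outer(r_row[pos], thresholds, ">="))
  fp <- colSums(outer(r_row[neg], thresholds, ">="))
  tibble(
    threshold = thresholds,
    tp = as.integer(tp),
    fp = as.integer(fp),
    tn = as.integer(length(neg) - fp),
    fn = as.integer(length(pos) - tp),
    tpr = tp / length(pos),
    fpr = fp / length(neg)
  )
}

#' Averaged retrieval ROC over all query windows
#'
#' Implements the unsupervised-search validation: every window is used in
#' turn as the query, its correlation row is swept over a fixed common
#' threshold grid, and the true/false positive rates are averaged across
#' queries at each threshold. The area under the averaged curve is computed
#' by the trapezoid rule with (0,0) and (1,1) appended.
#'
#' @param r_matrix W x W correlation matrix from [pairwise_r_matrix()].
#' @param labels Character vector of per-window ground-truth labels
#'   (windows with `NA` labels are never queries and never candidates).
#' @param thresholds Common threshold grid.
#' @return An object of class `avg_roc`: list with `points` (tibble of
#'   `threshold`, `fpr`, `tpr`), `auc`, `n_queries`, `n_skipped`.
#' @export
averaged_roc <- function(r_matrix, labels, thresholds = default_thresholds()) {
  w <- nrow(r_matrix)
  stopifnot(w == ncol(r_matrix), length(labels) == w,
            length(unique(stats::na.omit(labels))) >= 2)
  tpr_sum <- numeric(length(thresholds))
  fpr_sum <- numeric(length(thresholds))
  n_used <- 0L
  n_skipped <- 0L
  for (q in seq_len(w)) {
    if (is.na(labels[q]) || all(is.na(r_matrix[q, ]))) {
      n_skipped <- n_skipped + 1L
      next
    }
    pts <- suppressWarnings(roc_per_query(r_matrix[q, ], labels, q, thresholds))
    if (nrow(pts) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    tpr_sum <- tpr_sum + pts$tpr
    fpr_sum <- fpr_sum + pts$fpr
    n_used <- n_used + 1L
  }
  if (n_used == 0) abort("every query was skipped; cannot average a ROC")
  points <- tibble(threshold = thresholds,
                   fpr = fpr_sum / n_used,
                   tpr = tpr_sum / n_used)
  structure(list(points = points, auc = trapezoid_auc(points$fpr, points$tpr),
                 n_queries = n_used, n_skipped = n_skipped,
                 thresholds = thresholds),
            class = "avg_roc")
}

trapezoid_auc <- function(fpr, tpr) {
  x <- c(fpr, 0, 1)
  y <- c(tpr, 0, 1)
  o <- order(x, y)
  x <- x[o]
  y <- y[o]
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' @export
print.avg_roc <- function(x, ...) {
  cat(sprintf("<avg_roc> AUC = %.4f over %d queries (%d skipped), %d thresholds\n",
              x$auc, x$n_queries, x$n_skipped, length(x$thresholds)))
  invisible(x)
}

#' @rdname averaged_roc
#' @param x An `avg_roc` object.
#' @param ... Unused.
#' @method tidy avg_roc
#' @export
tidy.avg_roc <- function(x, ...) x$points

#' @rdname averaged_roc
#' @method glance avg_roc
#' @export
glance.avg_roc <- function(x, ...) {
  tibble(auc = x$auc, n_queries = x$n_queries, n_skipped = x$n_skipped,
         n_thresholds = length(x$thresholds))
}

#' ROC curve plot
#'
#' @param object An `avg_roc` object.
#' @param ... Unused.
#' @return A ggplot of the averaged ROC curve with the chance diagonal.
#' @method autoplot avg_roc
#' @export
autoplot.avg_roc <- function(object, ...) {
  pts <- dplyr::arrange(object$points, .data$fpr, .data$tpr)
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_path(colour = "firebrick") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("averaged retrieval ROC (AUC = %.3f)", object$auc))
}

#' End-to-end retrieval evaluation of a recording
#'
#' Convenience wrapper: extract band-power features at one timescale from a
#' data group, label each window by the stimulus block containing its
#' midpoint, and compute the averaged retrieval ROC.
#'
#' @param x A [bb_file()] model, a path to an HDF5 data file, or a
#'   `bb_simulation`.
#' @param group Name of the ECoG/EEG data group.
#' @param labels_group Name of the annotation group holding labelled
#'   timespans.
#' @param duration Window duration in seconds.
#' @param band Band edges in Hz.
#' @param thresholds Threshold grid.
#' @return An `avg_roc`.
#' @export
evaluate_retrieval <- function(x, group = "ecog", labels_group = "stimulus",
                               duration = 1.5, band = c(60, 100),
                               thresholds = default_thresholds()) {
  if (inherits(x, "bb_simulation")) x <- x$file
  if (is.character(x)) x <- read_bbfile(x, strict = FALSE)
  stopifnot(inherits(x, "bb_file"))
  nms <- group_names(x)
  gi <- match(group, nms)
  li <- match(labels_group, nms)
  if (is.na(gi)) abort(sprintf("no group '%s' in file", group))
  if (is.na(li)) abort(sprintf("no group '%s' in file", labels_group))
  g <- x$groups[[gi]]
  lg <- x$groups[[li]]
  if (is.null(lg$timespans) || !"label" %in% names(lg$timespans)) {
    abort(sprintf("group '%s' has no labelled timespans", labels_group))
  }
  feats <- extract_features(g, spectral_config(band = band, durations = duration))
  fm <- feats[[1]]
  labels <- label_windows(lg$timespans, attr(fm, "grid"))
  averaged_roc(pairwise_r_matrix(fm), labels, thresholds)
}
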