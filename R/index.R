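#' Pearson correlation between two feature vectors
#'
#' Product-moment correlation, clipped to `[-1, 1]` against rounding. When
#' either vector is constant the correlation is undefined and `NA` is
#' returned as a "no similarity" sentinel; downstream code treats it as not
#' significant.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A scalar in `[-1, 1]`, or `NA`.
#' @export
#' @examples
#' pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))  # 0.6
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  r <- stats::cor(x, y)
  max(-1, min(1, r))
}

#' Two-tailed p-value for a Pearson correlation
#'
#' Uses the exact null distribution of r for bivariate-normal data via the
#' t transform `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of
#' freedom, where `n` is the number of paired observations (here: the
#' channel count of the feature vectors). `r = +/-1` maps to `p = 0`;
#' `NA` correlations map to `p = NA`.
#'
#' @param r Correlation value(s) in `[-1, 1]` (vectorised).
#' @param n Sample size per vector; must be >= 3.
#' @return Two-tailed p-value(s) in `[0, 1]`.
#' @export
#' @examples
#' r_pvalue(0, 10)   # 1
#' r_pvalue(1, 64)   # 0
r_pvalue <- function(r, n) {
  if (n < 3) abort("need n >= 3 for a correlation p-value (df = n - 2)")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) abort("|r| must be <= 1")
  r <- pmax(-1, pmin(1, r))
  p <- rep(NA_real_, length(r))
  ext <- !is.na(r) & abs(r) == 1
  p[ext] <- 0
  ok <- !is.na(r) & !ext
  tstat <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  if (length(r) == 1) p[1] else p
}

#' Build a sparse significance-span index
#'
#' For every ordered (query window, target window) pair at each timescale the
#' Pearson correlation between the two feature vectors is computed across
#' channels; a pair is stored iff `r > 0` and its two-tailed p-value is at
#' most `alpha`. Stored pairs are run-length encoded per query row as maximal
#' runs of consecutive significant target windows, each run carrying its
#' p-values — so index size grows linearly in the number of significant
#' pairs, and far slower when related activity clusters in time. Only
#' positive correlations are stored.
#'
#' @param features A `feature_set` from [extract_features()], or a single
#'   `feature_matrix` / plain windows-x-channels matrix.
#' @param alpha Two-tailed significance threshold (default 0.05). No
#'   multiple-testing correction is applied.
#' @param include_self Keep the self pair (r = 1) in each query row?
#' @param keep_r_max When the window count W is at most this cap, the dense
#'   W x W correlation matrix is retained per timescale (for programmatic
#'   access); set to 0 to never keep it.
#' @return An object of class `span_index`.
#' @export
build_index <- function(features, alpha = 0.05, include_self = TRUE,
                        keep_r_max = 2000) {
  if (is.matrix(features) || inherits(features, "feature_matrix")) {
    d <- attr(features, "duration") %||% NA_real_
    features <- structure(stats::setNames(list(features),
                                          format(if (is.na(d)) 1 else d)),
                          class = "feature_set")
  }
  stopifnot(inherits(features, "feature_set"), alpha > 0, alpha <= 1)
  scales <- list()
  for (nm in names(features)) {
    fm <- features[[nm]]
    w <- nrow(fm)
    n_ch <- ncol(fm)
    if (w < 2 || n_ch < 3) {
      warn(sprintf("timescale %s: need >= 2 windows and >= 3 channels; empty index", nm))
      scales[[nm]] <- empty_scale(fm, nm, alpha)
      next
    }
    r <- clip_unit(suppressWarnings(stats::cor(t(unclass_matrix(fm)))))
    p <- matrix(r_pvalue(as.vector(r), n_ch), w, w)
    mask <- !is.na(r) & r > 0 & p <= alpha
    # constant-vector windows have undefined correlation, even with themselves
    const_win <- apply(unclass_matrix(fm), 1, stats::sd) == 0
    mask[const_win, ] <- FALSE
    mask[, const_win] <- FALSE
    if (!include_self) diag(mask) <- FALSE
    runs <- encode_runs(mask, p)
    scales[[nm]] <- list(
      duration = attr(fm, "duration") %||% as.numeric(nm),
      n_windows = w,
      n_channels = n_ch,
      alpha = alpha,
      grid = attr(fm, "grid"),
      runs = runs,
      r = if (w <= keep_r_max) r else NULL
    )
  }
  structure(list(scales = scales, alpha = alpha, include_self = include_self),
            class = "span_index")
}

# clip to [-1, 1] while keeping dims (pmin/pmax with a scalar drop them)
clip_unit <- function(r) {
  r[] <- pmax(-1, pmin(1, as.vector(r)))
  r
}

empty_scale <- function(fm, nm, alpha) {
  list(duration = attr(fm, "duration") %||% as.numeric(nm),
       n_windows = nrow(fm), n_channels = ncol(fm), alpha = alpha,
       grid = attr(fm, "grid"),
       runs = tibble(query = integer(), start = integer(), p = list()),
       r = NULL)
}

encode_runs <- function(mask, p) {
  rows <- which(rowSums(mask) > 0)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    q <- rows[i]
    rl <- rle(mask[q, ])
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1
    keep <- which(rl$values)
    out[[i]] <- tibble(
      query = q,
      start = as.integer(starts[keep]),
      p = lapply(keep, function(k) p[q, starts[k]:ends[k]])
    )
  }
  if (length(out) == 0) {
    tibble(query = integer(), start = integer(), p = list())
  } else {
    dplyr::bind_rows(out)
  }
}

#' @export
print.span_index <- function(x, ...) {
  cat(sprintf("<span_index> alpha = %g, %d timescale(s)\n", x$alpha,
              length(x$scales)))
  for (nm in names(x$scales)) {
    sc <- x$scales[[nm]]
    n_pairs <- sum(vapply(sc$runs$p, length, integer(1)))
    cat(sprintf("  %s s: %d windows, %d runs, %d stored pairs\n",
                nm, sc$n_windows, nrow(sc$runs), n_pairs))
  }
  invisible(x)
}

#' Densify one timescale of a span index
#'
#' Reconstructs the full boolean significance mask from the run encoding;
#' used for testing and programmatic access.
#'
#' @param index A `span_index`.
#' @param duration Which timescale (seconds or name); defaults to the only
#'   one when unambiguous.
#' @return A logical W x W matrix: entry (q, t) is `TRUE` iff the pair is
#'   stored.
#' @export
densify_index <- function(index, duration = NULL) {
  sc <- pick_scale(index, duration)
  w <- sc$n_windows
  m <- matrix(FALSE, w, w)
  for (i in seq_len(nrow(sc$runs))) {
    len <- length(sc$runs$p[[i]])
    m[sc$runs$query[i], sc$runs$start[i] + seq_len(len) - 1] <- TRUE
  }
  m
}

pick_scale <- function(index, duration = NULL) {
  stopifnot(inherits(index, "span_index"))
  if (is.null(duration)) {
    if (length(index$scales) != 1) {
      abort("index holds several timescales; pass `duration`")
    }
    return(index$scales[[1]])
  }
  nm <- if (is.character(duration)) duration else format(as.double(duration))
  sc <- index$scales[[nm]]
  if (is.null(sc)) abort(sprintf("no timescale '%s' in index", nm))
  sc
}

#' Resolve the timescale for a query length
#'
#' Picks the largest indexed duration that is still less than or equal to
#' the query length (a 600 ms query resolves to the 500 ms timescale under
#' the defaults). Queries shorter than the smallest duration clamp to the
#' smallest.
#'
#' @param length Query length in seconds.
#' @param durations Available durations in seconds.
#' @return The selected duration (seconds).
#' @export
#' @examples
#' select_timescale(0.6)   # 0.5
#' select_timescale(1.5)   # 1.5
select_timescale <- function(length, durations = c(0.5, 1, 1.5, 5)) {
  stopifnot(length(durations) >= 1, is.numeric(length), length > 0)
  durations <- sort(as.double(durations))
  eligible <- durations[durations <= length + 1e-9]
  if (length(eligible) == 0) durations[1] else max(eligible)
}

#' Query a span index for similar time windows
#'
#' The query is an interval (start time + length). Its length resolves the
#' timescale via [select_timescale()]; the grid window containing the start
#' time becomes the query window (boundaries belong to the window starting
#' there). That window's runs decode into time intervals with their
#' p-values.
#'
#' @param index A `span_index`.
#' @param start Query start time in seconds (>= 0).
#' @param length Query length in seconds (> 0).
#' @return A tibble of class `search_result` with columns `start`, `end`
#'   (seconds, half-open, grid-aligned) and `p`, sorted by `start`;
#'   attributes `duration` and `query_window`. Empty (with a warning) when
#'   the query lies beyond the indexed recording.
#' @export
query_index <- function(index, start, length) {
  stopifnot(inherits(index, "span_index"), start >= 0, length > 0)
  d <- select_timescale(length, vapply(index$scales, `[[`, numeric(1), "duration"))
  sc <- pick_scale(index, d)
  qwin <- floor(start / d + 1e-9) + 1
  hits <- tibble(start = numeric(), end = numeric(), p = numeric())
  if (qwin > sc$n_windows) {
    warn(sprintf("query start %g s is beyond the indexed recording (%d windows of %g s)",
                 start, sc$n_windows, d))
  } else {
    rows <- sc$runs[sc$runs$query == qwin, ]
    if (nrow(rows) > 0) {
      hits <- purrr::map_dfr(seq_len(nrow(rows)), function(i) {
        wins <- rows$start[i] + seq_along(rows$p[[i]]) - 1
        tibble(start = (wins - 1) * d, end = wins * d, p = rows$p[[i]])
      }) |> dplyr::arrange(.data$start)
    }
  }
  structure(hits, duration = d, query_window = as.integer(qwin),
            class = c("search_result", class(hits)))
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search_result> %d hit(s) at the %g s timescale (query window %d)\n",
              nrow(x), attr(x, "duration"), attr(x, "query_window")))
  NextMethod()
}

#' Plot search hits along the recording
#'
#' @param object A `search_result` from [query_index()].
#' @param ... Unused.
#' @return A ggplot of hit intervals vs -log10(p).
#' @method autoplot search_result
#' @export
autoplot.search_result <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(xmin = .data$start, xmax = .data$end,
                                   ymin = 0, ymax = -log10(pmax(.data$p, 1e-300)))) +
    ggplot2::geom_rect(fill = "seagreen", alpha = 0.7) +
    ggplot2::labs(x = "time (s)", y = expression(-log[10](p)),
                  title = sprintf("similar windows at the %g s timescale",
                                  attr(object, "duration")))
}

#' Persist a span index as an HDF5 sidecar
#'
#' Mirrors the two-list layout of the in-memory encoding: per timescale,
#' aligned datasets of run queries, run starts, run lengths and the
#' concatenated p-values.
#'
#' @param index A `span_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "span_index"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(index$alpha, path, "alpha")
  rhdf5::h5write(as.integer(index$include_self), path, "includeSelf")
  for (nm in names(index$scales)) {
    sc <- index$scales[[nm]]
    base <- paste0("d", nm)
    rhdf5::h5createGroup(path, base)
    rhdf5::h5write(sc$duration, path, paste0(base, "/duration"))
    rhdf5::h5write(as.integer(sc$n_windows), path, paste0(base, "/nWindows"))
    rhdf5::h5write(as.integer(sc$n_channels), path, paste0(base, "/nChannels"))
    rhdf5::h5write(as.integer(sc$runs$query), path, paste0(base, "/runQueries"))
    rhdf5::h5write(as.integer(sc$runs$start), path, paste0(base, "/runStarts"))
    rhdf5::h5write(vapply(sc$runs$p, length, integer(1)), path,
                   paste0(base, "/runLengths"))
    rhdf5::h5write(unlist(sc$runs$p) %||% numeric(0), path, paste0(base, "/pValues"))
  }
  invisible(path)
}

#' Read a span index written by [write_index()]
#'
#' @param path Path to the sidecar file.
#' @return A `span_index` (without the dense correlation sidecar).
#' @export
read_index <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  bases <- ls$name[ls$group == "/" & ls$otype == "H5I_GROUP"]
  scales <- list()
  alpha <- as.double(rhdf5::h5read(path, "alpha"))
  for (base in bases) {
    rd <- function(nm) rhdf5::h5read(path, paste0(base, "/", nm))
    d <- as.double(rd("duration"))
    lens <- as.integer(rd("runLengths"))
    pv <- as.double(rd("pValues"))
    ends <- cumsum(lens)
    p <- lapply(seq_along(lens), function(i) pv[(ends[i] - lens[i] + 1):ends[i]])
    if (length(lens) == 0) p <- list()
    nm <- format(d)
    scales[[nm]] <- list(
      duration = d,
      n_windows = as.integer(rd("nWindows")),
      n_channels = as.integer(rd("nChannels")),
      alpha = alpha,
      grid = NULL,
      runs = tibble(query = as.integer(rd("runQueries")),
                    start = as.integer(rd("runStarts")), p = p),
      r = NULL
    )
  }
  scales <- scales[order(as.numeric(names(scales)))]
  structure(list(scales = scales, alpha = alpha,
                 include_self = as.logical(as.integer(rhdf5::h5read(path, "includeSelf")))),
            class = "span_index")
}
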