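#' Spectral feature configuration
#'
#' Defaults follow the search method's design point: high-gamma band power
#' summed over 60-100 Hz, computed independently at four window durations
#' (0.5, 1, 1.5 and 5 s), z-scored per channel across the windows of each
#' duration.
#'
#' @param band Numeric length-2, band edges in Hz (inclusive on bin centers).
#' @param durations Window durations in seconds; positive, unique, ascending.
#' @param zscore Denominator convention for the z-score: `"population"`
#'   (divide by n) or `"sample"` (n - 1).
#' @return An object of class `spectral_config`.
#' @export
#' @examples
#' spectral_config()$durations
spectral_config <- function(band = c(60, 100),
                            durations = c(0.5, 1, 1.5, 5),
                            zscore = c("population", "sample")) {
  zscore <- match.arg(zscore)
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2])
  durations <- sort(unique(as.double(durations)))
  stopifnot(length(durations) >= 1, all(durations > 0))
  structure(list(band = as.double(band), durations = durations, zscore = zscore),
            class = "spectral_config")
}

#' Multichannel time series container
#'
#' @param values Numeric matrix, samples x channels.
#' @param sampling_rate Sampling rate in Hz.
#' @param channel_labels Optional character vector of channel names.
#' @return An object of class `channel_series`.
#' @export
channel_series <- function(values, sampling_rate, channel_labels = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.finite(sampling_rate), sampling_rate > 0, ncol(values) >= 1)
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("ch%02d", seq_len(ncol(values)))
  }
  stopifnot(length(channel_labels) == ncol(values))
  structure(list(values = values, sampling_rate = as.double(sampling_rate),
                 channel_labels = as.character(channel_labels)),
            class = "channel_series")
}

#' Coerce to a channel series
#'
#' @param x A `channel_series`, a [bb_group()] carrying a data matrix and
#'   sampling rate, or a plain matrix (then `sampling_rate` is required).
#' @param sampling_rate Sampling rate in Hz for matrix input.
#' @param ... Unused.
#' @return A [channel_series()].
#' @export
as_channel_series <- function(x, ...) UseMethod("as_channel_series")

#' @rdname as_channel_series
#' @export
as_channel_series.channel_series <- function(x, ...) x

#' @rdname as_channel_series
#' @export
as_channel_series.bb_group <- function(x, ...) {
  if (is.null(x$data)) abort(sprintf("group '%s' has no data matrix", x$name))
  if (is.null(x$sampling_rate)) abort(sprintf("group '%s' has no samplingRate", x$name))
  channel_series(x$data, x$sampling_rate, x$channel_labels)
}

#' @rdname as_channel_series
#' @export
as_channel_series.matrix <- function(x, sampling_rate, ...) {
  channel_series(x, sampling_rate)
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<channel_series> %d samples x %d channels @ %g Hz (%.3f s)\n",
              nrow(x$values), ncol(x$values), x$sampling_rate,
              nrow(x$values) / x$sampling_rate))
  invisible(x)
}

#' Segment a recording into non-overlapping windows
#'
#' Windows tile the recording from t = 0 at a fixed duration; a trailing
#' partial window is discarded. Intervals are half-open `[start, end)`.
#'
#' @param series A [channel_series()] (or coercible).
#' @param duration Window duration in seconds.
#' @return A tibble with one row per window (`window`, `start`, `end`) and
#'   attributes `samples_per_window` and `duration`. Zero rows (with a
#'   warning) when the recording is shorter than one window.
#' @export
#' @examples
#' s <- channel_series(matrix(rnorm(10000), ncol = 1), 1000)
#' nrow(segment_windows(s, 1.5))  # floor(10 / 1.5) = 6
segment_windows <- function(series, duration) {
  series <- as_channel_series(series)
  stopifnot(is.numeric(duration), duration > 0)
  spw <- round(duration * series$sampling_rate)
  n_win <- floor(nrow(series$values) / spw)
  if (n_win == 0) {
    warn(sprintf("recording (%.3f s) shorter than one %g s window; empty grid",
                 nrow(series$values) / series$sampling_rate, duration))
  }
  grid <- tibble(
    window = seq_len(n_win),
    start = (seq_len(n_win) - 1) * duration,
    end = seq_len(n_win) * duration
  )
  attr(grid, "samples_per_window") <- as.integer(spw)
  attr(grid, "duration") <- as.double(duration)
  grid
}

#' Band power of one window
#'
#' Per channel: discrete Fourier transform of the raw samples (rectangular
#' window, no detrending, unnormalised transform), then the sum of
#' magnitude-squared coefficients over all bins whose center frequency f
#' satisfies `low <= f <= high` (inclusive), considering bins up to the
#' Nyquist frequency only.
#'
#' @param window Numeric matrix, samples x channels (a vector is treated as
#'   one channel).
#' @param sampling_rate Sampling rate in Hz.
#' @param low,high Band edges in Hz; must satisfy `low < high` and
#'   `low < sampling_rate / 2`.
#' @return Numeric vector of non-negative band powers, one per channel.
#' @export
#' @examples
#' t <- seq(0, 1 - 1e-3, by = 1e-3)
#' band_power(cbind(sin(2 * pi * 80 * t)), 1000)  # energy inside 60-100 Hz
band_power <- function(window, sampling_rate, low = 60, high = 100) {
  if (!is.matrix(window)) window <- as.matrix(window)
  n <- nrow(window)
  stopifnot(n >= 2, low < high)
  nyquist <- sampling_rate / 2
  if (low >= nyquist) {
    abort(sprintf("band [%g, %g] Hz lies above the Nyquist frequency (%g Hz)",
                  low, high, nyquist))
  }
  freqs <- (seq_len(n) - 1) * sampling_rate / n
  sel <- freqs >= low & freqs <= high & freqs <= nyquist
  co <- stats::mvfft(window)
  colSums(abs(co[sel, , drop = FALSE])^2)
}

#' Extract multi-timescale band-power features
#'
#' For each configured duration: segment the recording, compute per-window
#' per-channel band power, then z-score each channel across that duration's
#' windows. Every window is thereby compressed to a feature vector of length
#' equal to the channel count, independent of sampling rate and duration.
#' Channels whose band power is identical in every window are set to zero and
#' flagged constant (so correlations downstream stay defined). Durations
#' yielding fewer than two windows are skipped with a warning.
#'
#' @param series A [channel_series()], [bb_group()] of type ECoG/EEG, or
#'   matrix (+ `sampling_rate`).
#' @param config A [spectral_config()].
#' @param sampling_rate Passed through when `series` is a plain matrix.
#' @return An object of class `feature_set`: a named list (one element per
#'   retained duration, names like `"1.5"`) of `feature_matrix` objects.
#' @export
#' @examples
#' s <- channel_series(matrix(rnorm(8 * 4000), ncol = 8), 1000)
#' fs <- extract_features(s, spectral_config(durations = c(0.5, 1)))
#' dim(fs[["1"]])  # windows x channels
extract_features <- function(series, config = spectral_config(),
                             sampling_rate = NULL) {
  series <- if (is.matrix(series) && !is.null(sampling_rate)) {
    channel_series(series, sampling_rate)
  } else {
    as_channel_series(series)
  }
  stopifnot(inherits(config, "spectral_config"))
  nyq <- series$sampling_rate / 2
  if (config$band[1] >= nyq) {
    abort(sprintf("band [%g, %g] Hz above Nyquist (%g Hz)",
                  config$band[1], config$band[2], nyq))
  }
  out <- list()
  for (d in config$durations) {
    grid <- suppressWarnings(segment_windows(series, d))
    n_win <- nrow(grid)
    if (n_win < 2) {
      warn(sprintf("duration %g s yields %d window(s); skipped (need >= 2 for z-scoring)",
                   d, n_win))
      next
    }
    spw <- attr(grid, "samples_per_window")
    bp <- matrix(NA_real_, n_win, ncol(series$values))
    for (w in seq_len(n_win)) {
      idx <- ((w - 1) * spw + 1):(w * spw)
      bp[w, ] <- band_power(series$values[idx, , drop = FALSE],
                            series$sampling_rate,
                            config$band[1], config$band[2])
    }
    z <- zscore_columns(bp, config$zscore)
    fm <- structure(z$values,
                    duration = as.double(d),
                    grid = grid,
                    constant = z$constant,
                    band = config$band,
                    sampling_rate = series$sampling_rate,
                    channel_labels = series$channel_labels,
                    class = c("feature_matrix", "matrix", "array"))
    out[[format(d)]] <- fm
  }
  if (length(out) == 0) warn("no duration produced at least two windows; empty feature set")
  structure(out, class = "feature_set")
}

zscore_columns <- function(x, convention = "population") {
  mu <- colMeans(x)
  centered <- sweep(x, 2, mu)
  denom <- if (convention == "population") nrow(x) else nrow(x) - 1
  s <- sqrt(colSums(centered^2) / denom)
  constant <- s == 0
  s[constant] <- 1
  z <- sweep(centered, 2, s, "/")
  z[, constant] <- 0
  list(values = z, constant = constant)
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d timescale(s)\n", length(x)))
  for (nm in names(x)) {
    fm <- x[[nm]]
    cat(sprintf("  %s s: %d windows x %d channels (%d constant)\n",
                nm, nrow(fm), ncol(fm), sum(attr(fm, "constant"))))
  }
  invisible(x)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %g s windows: %d x %d (z-scored band power)\n",
              attr(x, "duration"), nrow(x), ncol(x)))
  invisible(x)
}

#' Tidy a feature matrix into long form
#'
#' @param x A `feature_matrix` from [extract_features()].
#' @param ... Unused.
#' @return A tibble with columns `window`, `start`, `end`, `channel`,
#'   `feature`.
#' @method tidy feature_matrix
#' @export
tidy.feature_matrix <- function(x, ...) {
  grid <- attr(x, "grid")
  labels <- attr(x, "channel_labels") %||% sprintf("ch%02d", seq_len(ncol(x)))
  tibble(
    window = rep(grid$window, each = ncol(x)),
    start = rep(grid$start, each = ncol(x)),
    end = rep(grid$end, each = ncol(x)),
    channel = rep(labels, nrow(x)),
    feature = as.vector(t(unclass_matrix(x)))
  )
}

#' Heatmap of a feature matrix
#'
#' @param object A `feature_matrix`.
#' @param ... Unused.
#' @return A ggplot: time (window start) on x, channel on y, z-scored band
#'   power as fill.
#' @method autoplot feature_matrix
#' @export
autoplot.feature_matrix <- function(object, ...) {
  df <- tidy.feature_matrix(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, y = .data$channel,
                                   fill = .data$feature)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    ggplot2::labs(x = "time (s)", y = NULL, fill = "z(band power)",
                  title = sprintf("%g s windows, %g-%g Hz band power",
                                  attr(object, "duration"),
                                  attr(object, "band")[1], attr(object, "band")[2]))
}

#' Write a feature set to an HDF5 sidecar
#'
#' One HDF5 group per duration (named `d<duration>`), holding the feature
#' matrix, the window grid and the constant-channel flags.
#'
#' @param features A `feature_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(inherits(features, "feature_set"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  for (nm in names(features)) {
    fm <- features[[nm]]
    base <- paste0("d", nm)
    rhdf5::h5createGroup(path, base)
    suppressMessages(rhdf5::h5write(unclass_matrix(fm), path, paste0(base, "/features")))
    rhdf5::h5write(attr(fm, "duration"), path, paste0(base, "/duration"))
    rhdf5::h5write(attr(fm, "grid")$start, path, paste0(base, "/windowStarts"))
    rhdf5::h5write(as.integer(attr(fm, "constant")), path, paste0(base, "/constantChannels"))
    rhdf5::h5write(attr(fm, "band"), path, paste0(base, "/band"))
    rhdf5::h5write(attr(fm, "sampling_rate"), path, paste0(base, "/samplingRate"))
    rhdf5::h5write(attr(fm, "channel_labels"), path, paste0(base, "/channelLabels"))
  }
  invisible(path)
}

unclass_matrix <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(y))
  y
}

#' Read a feature set written by [write_features()]
#'
#' @param path Path to the sidecar file.
#' @return A `feature_set`.
#' @export
read_features <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  bases <- ls$name[ls$group == "/" & ls$otype == "H5I_GROUP"]
  out <- list()
  for (base in bases) {
    rd <- function(nm) rhdf5::h5read(path, paste0(base, "/", nm))
    d <- as.double(rd("duration"))
    feats <- rd("features")
    starts <- as.double(rd("windowStarts"))
    grid <- tibble(window = seq_along(starts), start = starts, end = starts + d)
    attr(grid, "samples_per_window") <- as.integer(round(d * as.double(rd("samplingRate"))))
    attr(grid, "duration") <- d
    out[[format(d)]] <- structure(
      feats,
      duration = d, grid = grid,
      constant = as.logical(as.integer(rd("constantChannels"))),
      band = as.double(rd("band")),
      sampling_rate = as.double(rd("samplingRate")),
      channel_labels = as.character(rd("channelLabels")),
      class = c("feature_matrix", "matrix", "array")
    )
  }
  out <- out[order(as.numeric(names(out)))]
  structure(out, class = "feature_set")
}
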