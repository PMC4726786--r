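#' Configuration for a synthetic block-design ECoG recording
#'
#' Emulates a block-design visual-stimulation experiment recorded with a
#' multichannel ECoG array: a 1/f-shaped Gaussian background on every
#' channel, plus a condition-dependent narrowband high-gamma component on a
#' condition-specific subset of channels during that condition's blocks.
#' Defaults: 32 channels at 1000 Hz, 1.5 s blocks alternating two stimulus
#' conditions (48 blocks, 72 s), gamma band centered at 80 Hz with 20 Hz
#' width, gamma amplitude 2 against unit-SD background noise, and
#' overlapping channel subsets (half the channels per condition) so that
#' retrieval is non-trivial.
#'
#' @param channels Number of channels (>= 3).
#' @param sampling_rate Sampling rate in Hz; must exceed twice the top of
#'   the gamma band.
#' @param block_duration Length of one task block in seconds; should be at
#'   least the largest feature window used downstream.
#' @param conditions Character vector of per-block condition labels in
#'   presentation order; the label `"rest"` carries no gamma component.
#' @param condition_channels Named list label -> integer vector of modulated
#'   channels. `NULL` assigns each non-rest condition a contiguous block of
#'   `channels / 2` channels, staggered so neighbouring conditions overlap.
#' @param condition_amplitude Named numeric vector label -> gamma amplitude.
#'   `NULL` gives every non-rest condition amplitude 2.
#' @param gamma_center,gamma_width Center and full width of the narrowband
#'   component, in Hz (defaults cover 60-100 Hz).
#' @param noise_amplitude Standard deviation of the 1/f background; 0
#'   disables noise.
#' @param seed Integer seed fixing the entire stream.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(channels = 32,
                       sampling_rate = 1000,
                       block_duration = 1.5,
                       conditions = rep(c("A", "B"), 24),
                       condition_channels = NULL,
                       condition_amplitude = NULL,
                       gamma_center = 80,
                       gamma_width = 20,
                       noise_amplitude = 1,
                       seed = 1) {
  stopifnot(channels >= 3, sampling_rate > 2 * (gamma_center + gamma_width / 2),
            block_duration > 0, length(conditions) >= 2,
            gamma_width > 0, gamma_center - gamma_width / 2 > 0,
            noise_amplitude >= 0)
  active <- setdiff(unique(conditions), "rest")
  if (is.null(condition_channels)) {
    half <- max(3, floor(channels / 2))
    step <- if (length(active) > 1) {
      max(1, floor((channels - half) / (length(active) - 1) / 2))
    } else 0
    condition_channels <- stats::setNames(lapply(seq_along(active), function(i) {
      offset <- (i - 1) * step
      seq.int(offset + 1, min(channels, offset + half))
    }), active)
  }
  if (is.null(condition_amplitude)) {
    condition_amplitude <- stats::setNames(rep(2, length(active)), active)
  }
  stopifnot(all(active %in% names(condition_channels)),
            all(active %in% names(condition_amplitude)))
  structure(list(
    channels = as.integer(channels),
    sampling_rate = as.double(sampling_rate),
    block_duration = as.double(block_duration),
    conditions = as.character(conditions),
    condition_channels = condition_channels,
    condition_amplitude = condition_amplitude,
    gamma_center = as.double(gamma_center),
    gamma_width = as.double(gamma_width),
    noise_amplitude = as.double(noise_amplitude),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate a synthetic block-design ECoG recording
#'
#' Generates the multichannel signal, the ground-truth block labels, and a
#' fully valid time-aligned brain-behavior file model holding one ECoG data
#' group plus one stimulus annotation group (labelled timespans, one per
#' block). The same seed reproduces the output bit for bit.
#'
#' Signal model per channel: 1/f-shaped Gaussian background (white noise
#' whose Fourier amplitudes are scaled by 1/sqrt(f), rescaled to the
#' configured SD) plus, on each condition's channel subset during its
#' blocks, a sinusoid with per-block frequency jitter inside the gamma band,
#' per-channel random phase and a fixed per-channel random gain — so feature
#' vectors differ across channels and conditions rather than being rank-1.
#'
#' @param config A [sim_config()].
#' @return A list of class `bb_simulation` with elements `series`
#'   ([channel_series()]), `truth` (tibble of blocks: `start`, `end`,
#'   `label`) and `file` ([bb_file()]).
#' @export
#' @examples
#' sim <- simulate_recording(sim_config(channels = 4, conditions = c("A", "B", "A", "B")))
#' sim$truth
simulate_recording <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fs <- config$sampling_rate
  spb <- round(config$block_duration * fs)
  n_blocks <- length(config$conditions)
  n <- spb * n_blocks
  ch <- config$channels

  values <- matrix(0, n, ch)
  if (config$noise_amplitude > 0) {
    for (c_i in seq_len(ch)) {
      values[, c_i] <- pink_noise(n, fs) * config$noise_amplitude
    }
  }

  # fixed per-channel gamma gain, drawn once per recording
  gain <- matrix(stats::runif(ch * length(config$condition_channels), 0.75, 1.25),
                 nrow = ch)
  colnames(gain) <- names(config$condition_channels)

  half_w <- config$gamma_width / 2
  t_block <- (seq_len(spb) - 1) / fs
  for (b in seq_len(n_blocks)) {
    lab <- config$conditions[b]
    if (!lab %in% names(config$condition_channels)) next
    chans <- config$condition_channels[[lab]]
    amp <- config$condition_amplitude[[lab]]
    f_b <- stats::runif(1, config$gamma_center - half_w + 1,
                        config$gamma_center + half_w - 1)
    phase <- stats::runif(length(chans), 0, 2 * pi)
    rows <- ((b - 1) * spb + 1):(b * spb)
    burst <- outer(t_block, phase, function(tt, ph) sin(2 * pi * f_b * tt + ph))
    values[rows, chans] <- values[rows, chans] +
      amp * sweep(burst, 2, gain[chans, lab], "*")
  }

  series <- channel_series(values, fs)
  truth <- tibble(
    start = (seq_len(n_blocks) - 1) * config$block_duration,
    end = seq_len(n_blocks) * config$block_duration,
    label = config$conditions
  )
  file <- bb_file(
    groups = list(
      bb_group("ecog", title = "synthetic ECoG array", type = "ECoG",
               data = values, sampling_rate = fs,
               channel_labels = series$channel_labels,
               preprocessing = "synthetic signal: 1/f background plus condition-dependent narrowband gamma"),
      bb_group("stimulus", title = "stimulus blocks", type = "stimulus",
               timespans = truth)
    ),
    header = list(
      experimentDescription = "synthetic block-design recording for search validation",
      species = "synthetic",
      subjectId = sprintf("sim-seed-%d", config$seed)
    )
  )
  structure(list(series = series, truth = truth, file = file, config = config),
            class = "bb_simulation")
}

# 1/f ("pink") background: shape white-noise Fourier amplitudes by 1/sqrt(f)
# (power ~ 1/f), zero DC, then rescale to unit SD.
pink_noise <- function(n, fs) {
  z <- stats::rnorm(n)
  zf <- stats::fft(z)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs[freqs > fs / 2] <- fs - freqs[freqs > fs / 2]  # fold to |f|
  h <- c(0, 1 / sqrt(freqs[-1]))
  x <- Re(stats::fft(zf * h, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' @export
print.bb_simulation <- function(x, ...) {
  cat(sprintf("<bb_simulation> %d channels @ %g Hz, %d blocks of %g s (seed %d)\n",
              x$config$channels, x$config$sampling_rate,
              length(x$config$conditions), x$config$block_duration,
              x$config$seed))
  invisible(x)
}

#' Label windows by the block containing their midpoint
#'
#' @param truth Block tibble with columns `start`, `end`, `label` (as from
#'   [simulate_recording()], or any labelled timespans).
#' @param grid Window grid tibble (from [segment_windows()] or a
#'   `feature_matrix`'s `grid` attribute).
#' @return Character vector of labels, one per window; `NA` where the
#'   midpoint falls outside every block.
#' @export
label_windows <- function(truth, grid) {
  mid <- (grid$start + grid$end) / 2
  vapply(mid, function(m) {
    hit <- which(truth$start <= m & m < truth$end)
    if (length(hit) == 0) NA_character_ else truth$label[hit[1]]
  }, character(1))
}
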