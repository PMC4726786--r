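# Programmatic fixtures; all randomness is driven by the caller's RNG state.

# A random valid file model exercising every optional field combination.
random_bbfile <- function() {
  n_groups <- sample(1:4, 1)
  groups <- lapply(seq_len(n_groups), function(i) {
    name <- sprintf("grp%02d", i)
    kind <- sample(c("data", "spans", "events", "mixed"), 1)
    data <- NULL
    sampling_rate <- NULL
    channel_labels <- NULL
    roi <- list()
    statl <- list()
    if (kind %in% c("data", "mixed")) {
      n_samp <- sample(20:60, 1)
      n_ch <- sample(1:4, 1)
      data <- matrix(rnorm(n_samp * n_ch), n_samp, n_ch)
      sampling_rate <- sample(c(100, 250, 1000), 1)
      if (runif(1) < 0.5) channel_labels <- sprintf("e%d", seq_len(n_ch))
      if (runif(1) < 0.3) roi <- list(mask = matrix(rbinom(n_samp * n_ch, 1, 0.5), n_samp, n_ch))
      if (runif(1) < 0.3) statl <- list(zvals = matrix(rnorm(n_samp * n_ch), n_samp, n_ch))
    }
    timespans <- NULL
    if (kind %in% c("spans", "mixed")) {
      k <- sample(1:5, 1)
      start <- sort(runif(k, 0, 10))
      timespans <- tibble::tibble(start = start, end = start + runif(k, 0.1, 1))
      if (runif(1) < 0.7) timespans$label <- sample(LETTERS[1:3], k, replace = TRUE)
    }
    timestamps <- if (kind == "events") sort(runif(sample(1:8, 1), 0, 10)) else NULL
    bb_group(
      name = name,
      title = paste("group", i),
      type = sample(c("ECoG", "EEG", "stimulus", "physicalMovement"), 1),
      data = data, timespans = timespans, timestamps = timestamps,
      sampling_rate = sampling_rate, channel_labels = channel_labels,
      roi = roi, stats = statl,
      preprocessing = if (runif(1) < 0.4) "bandpassed 0.5-200 Hz" else NULL,
      props = if (runif(1) < 0.4) list(unit = "microvolts") else list()
    )
  })
  header <- list(experimentDescription = "randomly generated test file")
  if (runif(1) < 0.5) header$species <- sample(c("rat", "human", "macaque"), 1)
  bb_file(groups = groups, header = header)
}

# Drop the violations attribute so models compare field-for-field.
strip_violations <- function(f) {
  attr(f, "violations") <- NULL
  f
}

# Small, fast simulation for unit tests (full default config is exercised in
# the acceptance suite).
quick_sim_config <- function(seed = 7, conditions = rep(c("A", "B"), 8), ...) {
  sim_config(channels = 8, sampling_rate = 500, block_duration = 1,
             conditions = conditions, gamma_center = 80,
             gamma_width = 20, seed = seed, ...)
}

# A pure sinusoid window, samples x 1.
sinusoid <- function(freq, sampling_rate, duration, amplitude = 1, phase = 0) {
  t <- seq(0, duration - 1 / sampling_rate, by = 1 / sampling_rate)
  cbind(amplitude * sin(2 * pi * freq * t + phase))
}
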