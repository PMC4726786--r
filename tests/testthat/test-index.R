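test_that("pearson_r matches hand computation and handles degenerate input", {
  x <- c(1, 5, 2, 8, 3)
  expect_identical(pearson_r(x, x), 1)
  expect_identical(pearson_r(x, -x), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6)
  expect_true(is.na(pearson_r(c(1, 1, 1), c(1, 2, 3))))
  set.seed(21)
  for (i in 1:10) {
    a <- rnorm(8)
    b <- rnorm(8)
    expect_equal(pearson_r(a, b), pearson_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("correlation p-values match a quadrature oracle of the t density", {
  expect_identical(r_pvalue(0, 10), 1)
  expect_identical(r_pvalue(1, 64), 0)
  expect_identical(r_pvalue(-1, 64), 0)
  expect_equal(r_pvalue(0.5, 16), t_pvalue_quadrature(0.5, 16), tolerance = 1e-8)
  for (r in c(-0.9, -0.3, 0.1, 0.45, 0.8)) {
    for (n in c(5, 16, 64)) {
      expect_equal(r_pvalue(r, n), t_pvalue_quadrature(r, n), tolerance = 1e-8)
    }
  }
  # monotone decreasing in |r| at fixed df
  rs <- seq(0, 0.99, by = 0.01)
  expect_true(all(diff(r_pvalue(rs, 32)) < 0))
  expect_error(r_pvalue(0.5, 2), "n >= 3")
})

test_that("densified index equals the brute-force significant-pair mask exactly", {
  set.seed(22)
  for (i in 1:6) {
    w <- sample(5:50, 1)
    n_ch <- sample(c(4, 8, 16), 1)
    x <- matrix(rnorm(w * n_ch), w, n_ch)
    # plant some structure so masks are not near-empty
    x[seq(1, w, by = 3), ] <- x[seq(1, w, by = 3), ] +
      matrix(rep(rnorm(n_ch), each = length(seq(1, w, by = 3))), ncol = n_ch)
    idx <- build_index(x, alpha = 0.05)
    expect_identical(densify_index(idx), brute_force_mask(x, 0.05))
  }
})

test_that("identical windows correlate perfectly and encode as one run per query", {
  x <- matrix(rep(c(1, 3, 2, 5), each = 6), 6, 4)  # 6 identical non-constant windows
  idx <- build_index(x)
  sc <- idx$scales[[1]]
  expect_identical(nrow(sc$runs), 6L)           # one maximal run per query row
  expect_true(all(sc$runs$start == 1L))
  expect_true(all(vapply(sc$runs$p, length, integer(1)) == 6L))
  expect_true(all(densify_index(idx)))
})

test_that("only positive correlations are stored", {
  set.seed(23)
  x <- matrix(rnorm(30 * 8), 30, 8)
  idx <- build_index(x)
  r <- idx$scales[[1]]$r
  mask <- densify_index(idx)
  expect_true(all(r[mask] > 0))
})

test_that("shrinking alpha never adds index entries", {
  set.seed(24)
  x <- matrix(rnorm(40 * 8), 40, 8)
  x[1:20, ] <- x[1:20, ] + matrix(rep(rnorm(8), each = 20), ncol = 8)
  m05 <- densify_index(build_index(x, alpha = 0.05))
  m01 <- densify_index(build_index(x, alpha = 0.01))
  expect_true(all(m05[m01]))  # entries at 0.01 are a subset of those at 0.05
  expect_lte(sum(m01), sum(m05))
})

test_that("stored pairs are symmetric as unordered pairs and runs are maximal", {
  set.seed(25)
  x <- matrix(rnorm(25 * 6), 25, 6)
  x[1:12, ] <- x[1:12, ] + matrix(rep(rnorm(6), each = 12), ncol = 6)
  idx <- build_index(x)
  m <- densify_index(idx)
  expect_identical(m, t(m))
  runs <- idx$scales[[1]]$runs
  # maximality: the window before a run start and the one after its end are off
  for (i in seq_len(nrow(runs))) {
    q <- runs$query[i]
    s <- runs$start[i]
    e <- s + length(runs$p[[i]]) - 1
    if (s > 1) expect_false(m[q, s - 1])
    if (e < ncol(m)) expect_false(m[q, e + 1])
  }
  # sorted, non-overlapping within each query row
  by_q <- split(runs, runs$query)
  for (rq in by_q) {
    if (nrow(rq) > 1) {
      ends <- rq$start + vapply(rq$p, length, integer(1)) - 1
      expect_true(all(rq$start[-1] > ends[-nrow(rq)] + 1))
    }
  }
})

test_that("run encoding is linear in significant pairs even when they alternate", {
  # adversarial worst case: every other target significant -> singleton runs
  w <- 20
  base <- c(2, 7, 1, 9, 4, 6)
  x <- matrix(NA_real_, w, 6)
  for (i in seq_len(w)) {
    x[i, ] <- if (i %% 2 == 1) base + rnorm(6, sd = 1e-3) else -base + rnorm(6, sd = 1e-3)
  }
  idx <- build_index(x)
  m <- densify_index(idx)
  runs <- idx$scales[[1]]$runs
  expect_identical(sum(vapply(runs$p, length, integer(1))), sum(m))
  # each run is a significant singleton: storage grows linearly with the pairs
  expect_identical(nrow(runs), sum(m))
  expect_true(all(vapply(runs$p, length, integer(1)) == 1L))
})

test_that("degenerate feature input yields an empty index with a warning", {
  x <- matrix(0, 10, 8)  # all-constant windows: correlation undefined everywhere
  idx <- build_index(x, alpha = 0.05)
  expect_identical(sum(densify_index(idx)), 0L)
  expect_warning(build_index(matrix(1, 5, 2)), "3 channels")
})

test_that("timescale selection takes the largest duration not exceeding the query", {
  expect_identical(select_timescale(0.6), 0.5)
  expect_identical(select_timescale(1.5), 1.5)
  expect_identical(select_timescale(0.3), 0.5)   # clamp below the smallest
  expect_identical(select_timescale(4.99), 1.5)
  expect_identical(select_timescale(60), 5)
})

test_that("queries decode the stored runs into grid-aligned intervals", {
  set.seed(26)
  x <- matrix(rnorm(30 * 8), 30, 8)
  x[11:20, ] <- x[11:20, ] + matrix(rep(rnorm(8), each = 10), ncol = 8)
  fm <- structure(x, duration = 1, grid = NULL,
                  class = c("feature_matrix", "matrix", "array"))
  idx <- build_index(fm)
  m <- densify_index(idx)
  hits <- query_index(idx, start = 14.2, length = 1)  # window 15
  expect_s3_class(hits, "search_result")
  expect_identical(attr(hits, "query_window"), 15L)
  expect_identical(sort(hits$start / 1 + 1), as.numeric(which(m[15, ])))
  expect_equal(hits$end - hits$start, rep(1, nrow(hits)))
  # hits carry the p-values of their pairs
  r <- idx$scales[[1]]$r
  expect_true(all(hits$p <= 0.05))
  # a query past the recording end is empty with a warning
  expect_warning(far <- query_index(idx, start = 99, length = 1), "beyond")
  expect_identical(nrow(far), 0L)
})

test_that("a query window with no significant partners returns no hits", {
  set.seed(27)
  x <- matrix(rnorm(12 * 6), 12, 6)
  idx <- build_index(x, include_self = FALSE)
  m <- densify_index(idx)
  lonely <- which(rowSums(m) == 0)
  skip_if(length(lonely) == 0)  # extremely unlikely under 6 channels
  hits <- query_index(idx, start = lonely[1] - 1 + 0.5, length = 1)
  expect_identical(nrow(hits), 0L)
})

test_that("span indices survive the HDF5 sidecar round trip", {
  set.seed(28)
  s <- channel_series(matrix(rnorm(6000 * 4), ncol = 4), 1000)
  idx <- build_index(extract_features(s, spectral_config(durations = c(0.5, 1))))
  path <- withr::local_tempfile(fileext = ".h5")
  write_index(idx, path)
  idx2 <- read_index(path)
  expect_identical(names(idx2$scales), names(idx$scales))
  for (nm in names(idx$scales)) {
    expect_equal(idx2$scales[[nm]]$runs, idx$scales[[nm]]$runs)
    expect_identical(densify_index(idx2, nm), densify_index(idx, nm))
  }
  expect_identical(idx2$alpha, idx$alpha)
})
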