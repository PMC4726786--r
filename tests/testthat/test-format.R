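test_that("written files use the documented HDF5 layout", {
  f <- bb_file(
    bb_group("ecog", title = "ecog", type = "ECoG",
             data = matrix(rnorm(200), 100, 2), sampling_rate = 1000),
    header = list(experimentDescription = "layout check")
  )
  path <- withr::local_tempfile(fileext = ".h5")
  write_bbfile(f, path, quiet = TRUE)
  ls <- rhdf5::h5ls(path)
  entries <- file.path(gsub("^/$", "", ls$group), ls$name)
  expect_true(all(c("/ecog/data", "/ecog/props/title", "/ecog/props/type",
                    "/ecog/props/samplingRate",
                    "/fileHeader/experimentDescription") %in% entries))
})

test_that("write -> read round trips randomly generated valid files exactly", {
  set.seed(101)
  for (i in 1:25) {
    f <- random_bbfile()
    path <- withr::local_tempfile(fileext = ".h5")
    suppressMessages(write_bbfile(f, path, quiet = TRUE))
    f2 <- strip_violations(read_bbfile(path))
    expect_equal(f2, f, tolerance = 0)
    # float payloads must be bit-identical
    for (g in seq_along(f$groups)) {
      expect_identical(f2$groups[[g]]$data, f$groups[[g]]$data)
    }
  }
})

test_that("an empty file is written with a header only, and flagged", {
  f <- bb_file(header = list(experimentDescription = "nothing yet"))
  v <- validate_bbfile(f)
  expect_identical(v$severity, "warning")
  expect_match(v$message, "no groups")
  path <- withr::local_tempfile(fileext = ".h5")
  expect_message(write_bbfile(f, path), "warnings")
  ls <- rhdf5::h5ls(path)
  expect_identical(ls$name[ls$group == "/"], "fileHeader")
})

test_that("reading a group without a title fails naming group and field", {
  f <- bb_file(bb_group("ecog", title = "t", type = "ECoG", timestamps = 1:3))
  path <- withr::local_tempfile(fileext = ".h5")
  write_bbfile(f, path, quiet = TRUE)
  rhdf5::h5delete(path, "ecog/props/title")
  expect_error(read_bbfile(path), "ecog.*title")
  # best-effort mode still returns the model plus the violation
  f2 <- read_bbfile(path, strict = FALSE)
  v <- attr(f2, "violations")
  expect_true(any(v$severity == "error" & v$group == "ecog" &
                    grepl("title", v$message)))
  expect_length(f2$groups, 1)
})

test_that("unknown custom properties survive the round trip verbatim", {
  g <- bb_group("ecog", title = "t", type = "ECoG", timestamps = c(1, 2),
                props = list(myCustomNote = "keep me"))
  path <- withr::local_tempfile(fileext = ".h5")
  suppressMessages(write_bbfile(bb_file(g), path, quiet = TRUE))
  f2 <- read_bbfile(path, strict = FALSE)
  expect_identical(f2$groups[[1]]$props$myCustomNote, "keep me")
})

test_that("non-HDF5 input is rejected as a format error", {
  path <- withr::local_tempfile(fileext = ".h5")
  writeLines("this is not hdf5", path)
  expect_error(read_bbfile(path), "not an HDF5 file")
})

test_that("validator separates errors from warnings", {
  ok <- bb_file(bb_group("g", title = "t", type = "ECoG",
                         data = matrix(rnorm(50), 50, 1), sampling_rate = 100))
  expect_identical(nrow(validate_bbfile(ok)), 0L)

  bad_roi <- bb_file(bb_group("g", title = "t", type = "ECoG",
                              data = matrix(rnorm(50), 50, 1), sampling_rate = 100,
                              roi = list(mask = matrix(0, 5, 1))))
  v <- validate_bbfile(bad_roi)
  expect_true(any(v$severity == "error" & grepl("roi dataset 'mask'", v$message)))

  wrong_case <- bb_file(bb_group("g", title = "t", type = "ECoG",
                                 data = matrix(rnorm(50), 50, 1), sampling_rate = 100,
                                 props = list(SamplingRate = 100)))
  v <- validate_bbfile(wrong_case)
  expect_true(any(v$severity == "warning" &
                    grepl("did you mean 'samplingRate'", v$message)))

  inverted <- bb_file(bb_group("g", title = "t", type = "stimulus",
                               timespans = data.frame(start = 2, end = 1)))
  v <- validate_bbfile(inverted)
  expect_true(any(v$severity == "error" & grepl("start >= end", v$message)))

  odd_type <- bb_file(bb_group("g", title = "t", type = "calciumImaging",
                               timestamps = 1))
  v <- validate_bbfile(odd_type)
  expect_identical(unique(v$severity), "warning")

  empty_group <- bb_file(bb_group("g", title = "t", type = "ECoG"))
  v <- validate_bbfile(empty_group)
  expect_true(any(v$severity == "error" &
                    grepl("none of data/timespans/timestamps", v$message)))
})

test_that("writing refuses a model with validation errors", {
  bad <- bb_file(bb_group("g", type = "ECoG", timestamps = 1))  # no title
  path <- withr::local_tempfile(fileext = ".h5")
  expect_error(write_bbfile(bad, path), "title")
  expect_false(file.exists(path))
})

test_that("grouping advice follows the span/rate/kind heuristic and is symmetric", {
  a <- grouping_descriptor(0, 60, 1000, "ECoG")
  expect_identical(suggest_grouping(a, a), "same_group")  # reflexive

  b <- grouping_descriptor(0, 60, 1000, "ECoG")
  expect_identical(suggest_grouping(a, b), "same_group")

  cases <- list(
    grouping_descriptor(0, 60, 1000, "fMRI"),      # other modality
    grouping_descriptor(0, 30, 1000, "ECoG"),      # other span
    grouping_descriptor(0, 60, 500, "ECoG")        # other rate
  )
  for (other in cases) {
    expect_identical(suggest_grouping(a, other), "separate_groups")
    expect_identical(suggest_grouping(other, a), suggest_grouping(a, other))
  }
  # unsampled annotations compare on span and kind alone
  s1 <- grouping_descriptor(0, 60, NA, "stimulus")
  s2 <- grouping_descriptor(0, 60, NA, "stimulus")
  expect_identical(suggest_grouping(s1, s2), "same_group")
})

test_that("bb_info summarises groups with derived durations", {
  f <- bb_file(list(
    bb_group("ecog", title = "t", type = "ECoG",
             data = matrix(0, 1000, 2), sampling_rate = 500),
    bb_group("stim", title = "s", type = "stimulus",
             timespans = data.frame(start = 0, end = 1, label = "A"))
  ))
  info <- bb_info(f)
  expect_identical(nrow(info), 2L)
  expect_identical(info$duration[info$name == "ecog"], 2)
  expect_identical(info$n_timespans[info$name == "stim"], 1L)
})
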