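#' Load a property schema
#'
#' The schema is a small YAML document listing the controlled vocabulary for
#' the `type` property and the recognised group / file-header property names.
#' A bundled default ships with the package; users may point to their own file
#' with the same layout to extend the vocabulary. Unknown names found in a
#' file are downgraded to validation warnings, never errors.
#'
#' @param path Path to a YAML schema file; `NULL` loads the bundled default.
#' @return A list with elements `types`, `group_properties` and
#'   `file_header_properties`, each a character vector.
#' @export
#' @examples
#' sch <- bb_schema()
#' "ECoG" %in% sch$types
bb_schema <- function(path = NULL) {
  path <- path %||% system.file("extdata", "schema.yaml", package = "neurospan")
  sch <- yaml::read_yaml(path)
  needed <- c("types", "group_properties", "file_header_properties")
  missing <- setdiff(needed, names(sch))
  if (length(missing) > 0) {
    abort(paste0("schema file lacks section(s): ", paste(missing, collapse = ", ")))
  }
  lapply(sch[needed], as.character)
}

#' Construct a data group
#'
#' A group is the central unit of organisation in a time-aligned
#' brain-behavior file: a named bundle of a time-series matrix (`data`),
#' interval annotations (`timespans`, optionally labelled) and/or point events
#' (`timestamps`), plus descriptive properties. At least one of the three
#' payloads must be present for the group to validate. All times are seconds
#' on the file's common axis with 0 = recording start; intervals are half-open
#' `[start, end)`.
#'
#' @param name Group name (HDF5 group under the file root).
#' @param title Human-readable title (required property).
#' @param type Modality or annotation kind, e.g. `"ECoG"`, `"EEG"`,
#'   `"stimulus"` (required property; controlled but extensible vocabulary).
#' @param data Optional numeric matrix, samples x channels (time runs down
#'   the rows).
#' @param timespans Optional data frame with numeric columns `start`, `end`
#'   (seconds) and an optional character column `label`.
#' @param timestamps Optional numeric vector of event times in seconds.
#' @param sampling_rate Sampling rate in Hz (recommended whenever `data` is
#'   present).
#' @param channel_labels Optional character vector, one label per data column.
#' @param roi,stats Optional named lists of numeric arrays, each
#'   dimension-matched to `data`.
#' @param preprocessing Optional free-text provenance note.
#' @param props Named list of additional properties (camel-case names);
#'   values must be character or numeric vectors. Unknown names are preserved
#'   verbatim on write/read.
#' @return An object of class `bb_group`.
#' @export
#' @examples
#' g <- bb_group("ecog", title = "ecog", type = "ECoG",
#'               data = matrix(rnorm(200), 100, 2), sampling_rate = 100)
bb_group <- function(name, title = NULL, type = NULL, data = NULL,
                     timespans = NULL, timestamps = NULL,
                     sampling_rate = NULL, channel_labels = NULL,
                     roi = list(), stats = list(), preprocessing = NULL,
                     props = list()) {
  if (!is.null(data)) {
    if (!is.matrix(data)) data <- as.matrix(data)
    storage.mode(data) <- "double"
  }
  if (!is.null(timespans)) {
    timespans <- as_tibble(as.data.frame(timespans))
    if (!all(c("start", "end") %in% names(timespans))) {
      abort("`timespans` needs columns `start` and `end`")
    }
    timespans$start <- as.double(timespans$start)
    timespans$end <- as.double(timespans$end)
    if ("label" %in% names(timespans)) timespans$label <- as.character(timespans$label)
    timespans <- timespans[intersect(c("start", "end", "label"), names(timespans))]
  }
  if (!is.null(timestamps)) timestamps <- as.double(timestamps)
  if (!is.null(sampling_rate)) sampling_rate <- as.double(sampling_rate)[1]
  if (!is.null(channel_labels)) channel_labels <- as.character(channel_labels)
  if (!is.null(preprocessing)) preprocessing <- as.character(preprocessing)[1]
  roi <- if (length(roi) > 0) roi[order(names(roi))] else list()
  stats <- if (length(stats) > 0) stats[order(names(stats))] else list()
  props <- if (length(props) > 0) props[order(names(props))] else list()
  structure(
    list(
      name = as.character(name)[1],
      title = if (is.null(title)) NULL else as.character(title)[1],
      type = if (is.null(type)) NULL else as.character(type)[1],
      data = data,
      timespans = timespans,
      timestamps = timestamps,
      sampling_rate = sampling_rate,
      channel_labels = channel_labels,
      roi = roi,
      stats = stats,
      preprocessing = preprocessing,
      props = props
    ),
    class = "bb_group"
  )
}

#' Construct a time-aligned brain-behavior file model
#'
#' In-memory model of one HDF5 data file: a file header (free-form
#' experiment / subject properties stored under the root `fileHeader` group)
#' plus an ordered list of uniquely named data groups.
#'
#' @param groups List of [bb_group()] objects.
#' @param header Named list of scalar header properties (camel-case names,
#'   e.g. `experimentDescription`, `species`).
#' @return An object of class `bb_file`.
#' @seealso [write_bbfile()], [read_bbfile()], [validate_bbfile()]
#' @export
bb_file <- function(groups = list(), header = list()) {
  if (inherits(groups, "bb_group")) groups <- list(groups)
  # canonical order: sort by name so the model is invariant under HDF5
  # round trips (HDF5 enumerates links alphabetically)
  nms <- vapply(groups, function(g) g$name %||% "", character(1))
  groups <- groups[order(nms)]
  if (length(header) > 0) header <- header[order(names(header))]
  structure(list(header = header, groups = groups), class = "bb_file")
}

#' @export
print.bb_group <- function(x, ...) {
  cat(sprintf("<bb_group> %s (title=%s, type=%s)\n", x$name,
              x$title %||% "<missing>", x$type %||% "<missing>"))
  if (!is.null(x$data)) {
    cat(sprintf("  data: %d samples x %d channels", nrow(x$data), ncol(x$data)))
    if (!is.null(x$sampling_rate)) cat(sprintf(" @ %g Hz", x$sampling_rate))
    cat("\n")
  }
  if (!is.null(x$timespans)) cat(sprintf("  timespans: %d\n", nrow(x$timespans)))
  if (!is.null(x$timestamps)) cat(sprintf("  timestamps: %d\n", length(x$timestamps)))
  invisible(x)
}

#' @export
print.bb_file <- function(x, ...) {
  cat(sprintf("<bb_file> %d group(s), %d header propert%s\n",
              length(x$groups), length(x$header),
              if (length(x$header) == 1) "y" else "ies"))
  for (g in x$groups) print(g)
  invisible(x)
}

group_names <- function(file) vapply(file$groups, function(g) g$name, character(1))

violation <- function(severity, group, message) {
  tibble(severity = severity, group = group, message = message)
}

camel_case_ok <- function(x) grepl("^[a-z][a-zA-Z0-9]*$", x)

#' Validate a file model
#'
#' Checks every structural invariant of the format and returns all findings
#' as a tibble rather than throwing: errors are violations that make a file
#' unwritable (missing `title`/`type`, dimension-mismatched `roi`/`stats`
#' arrays, inverted timespans, no payload in a group), warnings are advisory
#' (unknown property names or types, missing sampling rate on a data group,
#' an empty file, suspicious data orientation).
#'
#' @param file A [bb_file()] model.
#' @param schema A schema as returned by [bb_schema()].
#' @return A tibble with columns `severity` (`"error"`/`"warning"`), `group`
#'   and `message`; zero rows iff the file is fully valid.
#' @export
#' @examples
#' f <- bb_file(bb_group("x", title = "t", type = "ECoG", timestamps = 1:3))
#' validate_bbfile(f)
validate_bbfile <- function(file, schema = bb_schema()) {
  stopifnot(inherits(file, "bb_file"))
  v <- list()
  add <- function(sev, grp, msg) v[[length(v) + 1]] <<- violation(sev, grp, msg)

  nms <- group_names(file)
  if (length(nms) == 0) add("warning", NA_character_, "file has no groups")
  if (any(!nzchar(nms))) add("error", NA_character_, "group with empty name")
  dup <- unique(nms[duplicated(nms)])
  for (d in dup) add("error", d, "duplicate group name")

  for (hn in names(file$header)) {
    if (!camel_case_ok(hn)) {
      add("warning", "fileHeader", sprintf(
        "property '%s' does not follow camel-case naming%s", hn,
        suggest_name(hn, schema$file_header_properties)))
    } else if (!hn %in% schema$file_header_properties) {
      add("warning", "fileHeader", sprintf("unknown header property '%s'", hn))
    }
  }

  for (g in file$groups) v <- c(v, list(validate_group(g, schema)))
  out <- dplyr::bind_rows(v)
  if (nrow(out) == 0) {
    out <- tibble(severity = character(), group = character(), message = character())
  }
  out
}

suggest_name <- function(name, known) {
  hit <- known[tolower(known) == tolower(name)]
  if (length(hit) == 1) sprintf(" (did you mean '%s'?)", hit) else ""
}

validate_group <- function(g, schema) {
  v <- list()
  add <- function(sev, msg) v[[length(v) + 1]] <<- violation(sev, g$name, msg)

  if (is.null(g$title) || !nzchar(g$title)) add("error", "missing required property 'title'")
  if (is.null(g$type) || !nzchar(g$type)) {
    add("error", "missing required property 'type'")
  } else if (!g$type %in% schema$types) {
    add("warning", sprintf("type '%s' is not in the schema vocabulary%s",
                           g$type, suggest_name(g$type, schema$types)))
  }

  if (is.null(g$data) && is.null(g$timespans) && is.null(g$timestamps)) {
    add("error", "group has none of data/timespans/timestamps")
  }

  if (!is.null(g$data)) {
    if (!is.numeric(g$data)) add("error", "'data' is not numeric")
    if (anyNA(g$data) || any(!is.finite(g$data))) {
      add("warning", "'data' contains non-finite values")
    }
    if (is.null(g$sampling_rate)) {
      add("warning", "data group lacks 'samplingRate'")
    } else if (!is.finite(g$sampling_rate) || g$sampling_rate <= 0) {
      add("error", "'samplingRate' must be a positive finite number")
    }
    if (nrow(g$data) < ncol(g$data)) {
      add("warning", "fewer samples than channels; data may be transposed (expected samples x channels)")
    }
    if (!is.null(g$channel_labels) && length(g$channel_labels) != ncol(g$data)) {
      add("error", sprintf("channelLabels length %d != %d channels",
                           length(g$channel_labels), ncol(g$data)))
    }
    for (kind in c("roi", "stats")) {
      arrs <- g[[kind]]
      for (an in names(arrs)) {
        if (!identical(dim_of(arrs[[an]]), dim_of(g$data))) {
          add("error", sprintf("%s dataset '%s' does not match data dimensions", kind, an))
        }
      }
    }
  } else if (length(g$roi) > 0 || length(g$stats) > 0) {
    add("error", "roi/stats present without a data matrix")
  }

  if (!is.null(g$timespans)) {
    bad <- which(!(g$timespans$start < g$timespans$end))
    for (i in bad) add("error", sprintf("timespan %d has start >= end", i))
    if (anyNA(g$timespans$start) || anyNA(g$timespans$end)) {
      add("error", "timespans contain missing times")
    }
  }
  if (!is.null(g$timestamps) && any(!is.finite(g$timestamps))) {
    add("error", "timestamps contain non-finite values")
  }

  for (pn in names(g$props)) {
    if (!camel_case_ok(pn)) {
      add("warning", sprintf("property '%s' does not follow camel-case naming%s",
                             pn, suggest_name(pn, schema$group_properties)))
    } else if (!pn %in% schema$group_properties) {
      add("warning", sprintf("unknown property '%s'", pn))
    }
  }
  dplyr::bind_rows(v)
}

dim_of <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Write a file model to HDF5
#'
#' Lays the model out on disk as one root-level HDF5 group per data group,
#' each holding `data` / `timespans` (+ parallel `labels`) / `timestamps`
#' datasets and a `props` subgroup with one dataset per property (including
#' the `roi`, `stats` subgroups and `preprocessing`), plus a root
#' `fileHeader` group. Writing refuses files with validation *errors*;
#' warnings are reported with [message()] and do not block.
#'
#' @param file A [bb_file()] model.
#' @param path Output path (`.h5`); an existing file is replaced.
#' @param schema Schema used for validation.
#' @param quiet Suppress warning chatter.
#' @return `path`, invisibly.
#' @export
write_bbfile <- function(file, path, schema = bb_schema(), quiet = FALSE) {
  viol <- validate_bbfile(file, schema)
  errs <- viol[viol$severity == "error", ]
  if (nrow(errs) > 0) {
    abort(c("file model has validation errors; not writing",
            stats::setNames(paste0("[", ifelse(is.na(errs$group), "<file>", errs$group),
                                   "] ", errs$message),
                            rep("x", nrow(errs)))))
  }
  if (!quiet && nrow(viol) > 0) {
    inform(paste0("validation warnings: ",
                  paste(unique(viol$message), collapse = "; ")))
  }
  if (file.exists(path)) unlink(path)
  ok <- rhdf5::h5createFile(path)
  if (!isTRUE(ok)) abort(sprintf("cannot create HDF5 file at '%s'", path))
  on.exit(rhdf5::h5closeAll(), add = TRUE)

  rhdf5::h5createGroup(path, "fileHeader")
  for (hn in names(file$header)) {
    h5_write_value(file$header[[hn]], path, paste0("fileHeader/", hn))
  }

  for (g in file$groups) {
    base <- g$name
    rhdf5::h5createGroup(path, base)
    if (!is.null(g$data)) {
      # suppress rhdf5's chunk-size advisory for large datasets
      suppressMessages(rhdf5::h5write(g$data, path, paste0(base, "/data")))
    }
    if (!is.null(g$timespans)) {
      rhdf5::h5write(cbind(g$timespans$start, g$timespans$end), path,
                     paste0(base, "/timespans"))
      if ("label" %in% names(g$timespans)) {
        rhdf5::h5write(g$timespans$label, path, paste0(base, "/labels"))
      }
    }
    if (!is.null(g$timestamps)) {
      rhdf5::h5write(g$timestamps, path, paste0(base, "/timestamps"))
    }
    pbase <- paste0(base, "/props")
    rhdf5::h5createGroup(path, pbase)
    h5_write_value(g$title, path, paste0(pbase, "/title"))
    h5_write_value(g$type, path, paste0(pbase, "/type"))
    if (!is.null(g$sampling_rate)) {
      h5_write_value(g$sampling_rate, path, paste0(pbase, "/samplingRate"))
    }
    if (!is.null(g$channel_labels)) {
      rhdf5::h5write(g$channel_labels, path, paste0(pbase, "/channelLabels"))
    }
    if (!is.null(g$preprocessing)) {
      h5_write_value(g$preprocessing, path, paste0(pbase, "/preprocessing"))
    }
    for (kind in c("roi", "stats")) {
      arrs <- g[[kind]]
      if (length(arrs) > 0) {
        rhdf5::h5createGroup(path, paste0(pbase, "/", kind))
        for (an in names(arrs)) {
          arr <- arrs[[an]]
          storage.mode(arr) <- "double"
          rhdf5::h5write(arr, path, paste0(pbase, "/", kind, "/", an))
        }
      }
    }
    for (pn in names(g$props)) {
      h5_write_value(g$props[[pn]], path, paste0(pbase, "/", pn))
    }
  }
  invisible(path)
}

h5_write_value <- function(value, path, name) {
  if (is.numeric(value)) value <- as.double(value)
  rhdf5::h5write(value, path, name)
}

#' Read an HDF5 file into the file model
#'
#' Reconstructs a [bb_file()] from disk. Properties not named in the schema
#' are preserved verbatim in each group's `props` list (forward
#' compatibility). With `strict = TRUE` (default) a group missing a required
#' property raises an error that names the group and the field; with
#' `strict = FALSE` reading is best-effort and the violations are attached as
#' the `"violations"` attribute, so downstream tools can still operate on
#' imperfect files.
#'
#' @param path Path to an HDF5 file.
#' @param strict Abort on validation errors?
#' @param schema Schema used for validation.
#' @return A [bb_file()]; attribute `"violations"` holds the validation
#'   tibble.
#' @export
read_bbfile <- function(path, strict = TRUE, schema = bb_schema()) {
  if (!file.exists(path)) abort(sprintf("no such file: '%s'", path))
  if (!isTRUE(rhdf5::H5Fis_hdf5(path))) {
    abort(sprintf("'%s' is not an HDF5 file", path))
  }
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)

  header <- list()
  for (hn in ls$name[ls$group == "/fileHeader" & ls$otype == "H5I_DATASET"]) {
    header[[hn]] <- h5_read_value(path, paste0("fileHeader/", hn))
  }

  root_groups <- setdiff(ls$name[ls$group == "/" & ls$otype == "H5I_GROUP"], "fileHeader")
  groups <- lapply(root_groups, function(gname) read_bbgroup(path, gname, ls, schema))

  file <- bb_file(groups = groups, header = header)
  viol <- validate_bbfile(file, schema)
  errs <- viol[viol$severity == "error", ]
  if (strict && nrow(errs) > 0) {
    abort(c(sprintf("'%s' violates the format", path),
            stats::setNames(paste0("[", ifelse(is.na(errs$group), "<file>", errs$group),
                                   "] ", errs$message),
                            rep("x", nrow(errs)))))
  }
  attr(file, "violations") <- viol
  file
}

h5_read_value <- function(path, name) {
  x <- rhdf5::h5read(path, name)
  if (is.array(x) && length(dim(x)) == 1) x <- as.vector(x)
  if (length(x) == 1) x <- x[[1]]
  x
}

read_bbgroup <- function(path, gname, ls, schema) {
  in_group <- function(sub) ls$name[ls$group == sub & ls$otype == "H5I_DATASET"]
  top <- in_group(paste0("/", gname))

  data <- NULL
  if ("data" %in% top) {
    data <- rhdf5::h5read(path, paste0(gname, "/data"))
    if (is.null(dim(data))) data <- matrix(data, ncol = 1)
  }
  timespans <- NULL
  if ("timespans" %in% top) {
    ts <- rhdf5::h5read(path, paste0(gname, "/timespans"))
    timespans <- tibble(start = as.double(ts[, 1]), end = as.double(ts[, 2]))
    if ("labels" %in% top) {
      timespans$label <- as.character(rhdf5::h5read(path, paste0(gname, "/labels")))
    }
  }
  timestamps <- NULL
  if ("timestamps" %in% top) {
    timestamps <- as.double(rhdf5::h5read(path, paste0(gname, "/timestamps")))
  }

  pbase <- paste0("/", gname, "/props")
  pnames <- in_group(pbase)
  getp <- function(nm) {
    if (nm %in% pnames) h5_read_value(path, paste0(gname, "/props/", nm)) else NULL
  }
  known <- c("title", "type", "samplingRate", "channelLabels", "preprocessing")
  extra <- setdiff(pnames, known)
  props <- stats::setNames(
    lapply(extra, function(nm) h5_read_value(path, paste0(gname, "/props/", nm))),
    extra
  )
  read_arrays <- function(kind) {
    sub <- paste0(pbase, "/", kind)
    nms <- in_group(sub)
    stats::setNames(
      lapply(nms, function(an) rhdf5::h5read(path, paste0(gname, "/props/", kind, "/", an))),
      nms
    )
  }
  chl <- getp("channelLabels")
  bb_group(
    name = gname,
    title = getp("title"),
    type = getp("type"),
    data = data,
    timespans = timespans,
    timestamps = timestamps,
    sampling_rate = getp("samplingRate"),
    channel_labels = if (is.null(chl)) NULL else as.character(chl),
    roi = read_arrays("roi"),
    stats = read_arrays("stats"),
    preprocessing = getp("preprocessing"),
    props = props
  )
}

#' Summarise the groups of a file
#'
#' @param x A [bb_file()] model or a path to an HDF5 file.
#' @return A tibble with one row per group: name, title, type, payload sizes,
#'   sampling rate and duration where derivable.
#' @export
bb_info <- function(x) {
  if (is.character(x)) x <- read_bbfile(x, strict = FALSE)
  stopifnot(inherits(x, "bb_file"))
  purrr::map_dfr(x$groups, function(g) {
    tibble(
      name = g$name,
      title = g$title %||% NA_character_,
      type = g$type %||% NA_character_,
      samples = if (is.null(g$data)) NA_integer_ else nrow(g$data),
      channels = if (is.null(g$data)) NA_integer_ else ncol(g$data),
      sampling_rate = g$sampling_rate %||% NA_real_,
      duration = if (!is.null(g$data) && !is.null(g$sampling_rate)) {
        nrow(g$data) / g$sampling_rate
      } else NA_real_,
      n_timespans = if (is.null(g$timespans)) NA_integer_ else nrow(g$timespans),
      n_timestamps = if (is.null(g$timestamps)) NA_integer_ else length(g$timestamps)
    )
  })
}

#' Describe a candidate set of data for grouping advice
#'
#' @param start,end Time span covered, in seconds.
#' @param sampling_rate Sampling rate in Hz, or `NA` for unsampled
#'   annotation data.
#' @param kind Recording modality (for brain data) or behavior/stimulus type.
#' @return An object of class `grouping_descriptor`.
#' @export
grouping_descriptor <- function(start, end, sampling_rate = NA_real_, kind) {
  stopifnot(is.numeric(start), is.numeric(end), start < end)
  if (!is.na(sampling_rate)) stopifnot(sampling_rate > 0)
  structure(list(start = as.double(start), end = as.double(end),
                 sampling_rate = as.double(sampling_rate),
                 kind = as.character(kind)),
            class = "grouping_descriptor")
}

#' Advise whether two datasets belong in the same group
#'
#' Encodes the format's grouping heuristic: data belong together iff they
#' cover the same time span, share a sampling rate, and are the same
#' recording modality (for brain data) or the same behavior/stimulus type.
#' The relation is symmetric and reflexive.
#'
#' @param a,b [grouping_descriptor()] objects.
#' @return `"same_group"` or `"separate_groups"`.
#' @export
#' @examples
#' a <- grouping_descriptor(0, 60, 1000, "ECoG")
#' b <- grouping_descriptor(0, 60, 1000, "fMRI")
#' suggest_grouping(a, b)
suggest_grouping <- function(a, b) {
  stopifnot(inherits(a, "grouping_descriptor"), inherits(b, "grouping_descriptor"))
  same_rate <- (is.na(a$sampling_rate) && is.na(b$sampling_rate)) ||
    (!is.na(a$sampling_rate) && !is.na(b$sampling_rate) &&
       a$sampling_rate == b$sampling_rate)
  same <- identical(a$start, b$start) && identical(a$end, b$end) &&
    same_rate && identical(a$kind, b$kind)
  if (same) "same_group" else "separate_groups"
}
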