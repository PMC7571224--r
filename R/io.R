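STREAM_COLS <- c("time_s", "gyro_x_dps", "gyro_y_dps", "gyro_z_dps")

#' Construct a sensor stream
#'
#' A sensor stream is a tibble of one sensor's tri-axial angular velocity
#' with columns `time_s`, `gyro_x_dps`, `gyro_y_dps`, `gyro_z_dps`, carrying
#' the body site and sampling rate as attributes. Axis convention: `x` =
#' proximal-distal (transverse-plane rotation), `y` = sagittal-plane
#' rotation, `z` = coronal-plane rotation; units are degrees/s and seconds.
#'
#' @param data Data frame with the four stream columns.
#' @param site One of `"T6"`, `"S1"`, `"thigh_R"`, `"shank_R"`.
#' @param fs Sampling rate in Hz; if `NULL`, inferred from the median time
#'   step.
#' @return A `sensor_stream` tibble.
#' @export
sensor_stream <- function(data, site, fs = NULL) {
  site <- match.arg(site, SITES)
  missing_cols <- setdiff(STREAM_COLS, names(data))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::as_tibble(data[STREAM_COLS])
  t <- out$time_s
  if (nrow(out) < 2 || any(diff(t) <= 0)) {
    stop("non-monotonic time", call. = FALSE)
  }
  if (is.null(fs)) fs <- 1 / median(diff(t))
  stopifnot(fs > 0)
  structure(out,
    site = site, fs = fs,
    class = c("sensor_stream", class(tibble::tibble()))
  )
}

#' @export
print.sensor_stream <- function(x, ...) {
  cat(
    "<sensor_stream> site=", attr(x, "site"),
    " fs=", format(attr(x, "fs")), " Hz, ",
    nrow(x), " samples (", format(round(max(x$time_s) - min(x$time_s), 2)),
    " s)\n",
    sep = ""
  )
  NextMethod()
}

#' Read a sensor stream from delimited text
#'
#' Reads a comma-separated file with header columns `time_s`, `gyro_x_dps`,
#' `gyro_y_dps`, `gyro_z_dps`, validates monotonic time, and checks the
#' sampling rate inferred from the median time step against the expected
#' rate.
#'
#' @param path File path.
#' @param site Body site label (see [sensor_stream()]).
#' @param expected_fs Expected sampling rate in Hz (default 80).
#' @param fs_tolerance Maximum relative deviation of the inferred rate from
#'   `expected_fs` (default 1%).
#' @return A `sensor_stream` tibble.
#' @export
read_sensor_stream <- function(path, site, expected_fs = 80,
                               fs_tolerance = 0.01) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, sep = ",", data.table = FALSE)
  missing_cols <- setdiff(STREAM_COLS, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing columns in ", path, ": ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  s <- sensor_stream(raw, site = site)
  fs_inferred <- attr(s, "fs")
  if (!is.null(expected_fs) &&
    abs(fs_inferred - expected_fs) / expected_fs > fs_tolerance) {
    stop(
      "sampling-rate mismatch in ", path, ": inferred ",
      format(round(fs_inferred, 3)), " Hz vs expected ", expected_fs,
      " Hz (> ", fs_tolerance * 100, "% off)",
      call. = FALSE
    )
  }
  attr(s, "fs") <- expected_fs %||% fs_inferred
  s
}

#' Write a sensor stream to delimited text
#'
#' @param stream A `sensor_stream` (or data frame with the stream columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sensor_stream <- function(stream, path) {
  data.table::fwrite(as.data.frame(stream)[STREAM_COLS], path)
  invisible(path)
}

parse_load <- function(load) {
  if (is.numeric(load)) {
    idx <- match(round(load, 1), round(unname(LOAD_LEVELS), 1))
  } else {
    lab <- toupper(as.character(load))
    idx <- match(lab, names(LOAD_LEVELS))
    if (anyNA(idx)) {
      num <- suppressWarnings(as.numeric(lab))
      idx2 <- match(round(num, 1), round(unname(LOAD_LEVELS), 1))
      idx[is.na(idx)] <- idx2[is.na(idx)]
    }
  }
  if (anyNA(idx)) {
    stop(
      "unknown load level: ",
      paste(unique(load[is.na(idx)]), collapse = ", "),
      " (expected one of NL/L/M/H or 0/4.5/9.1/13.6 kg)",
      call. = FALSE
    )
  }
  factor(names(LOAD_LEVELS)[idx], levels = names(LOAD_LEVELS))
}

#' Read a trial manifest
#'
#' A manifest is a delimited table with one row per walk trial and columns
#' `participant`, `carry_mode` (`side`, `anterior` or `none` for the shared
#' empty-handed reference), `load` (`NL`/`L`/`M`/`H` or 0/4.5/9.1/13.6 kg),
#' `trial`, and per-site file-path columns `t6_file`, `s1_file`,
#' `thigh_r_file`, `shank_r_file`.
#'
#' @param path Manifest file path.
#' @return A tibble of trial records (streams not yet loaded), with
#'   `carry_mode` and `load` as factors and `load_kg` numeric.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- tibble::as_tibble(data.table::fread(path, sep = ",", data.table = FALSE))
  if (nrow(m) == 0) {
    warning("empty manifest: ", path, call. = FALSE)
    return(m)
  }
  required <- c("participant", "carry_mode", "load", "trial")
  missing_cols <- setdiff(required, names(m))
  if (length(missing_cols) > 0) {
    stop("manifest missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  bad_mode <- setdiff(unique(m$carry_mode), c(MODES, "none"))
  if (length(bad_mode) > 0) {
    stop("unknown carry_mode: ", paste(bad_mode, collapse = ", "),
      call. = FALSE
    )
  }
  m$carry_mode <- factor(m$carry_mode, levels = c(MODES, "none"))
  m$load <- parse_load(m$load)
  m$load_kg <- unname(LOAD_LEVELS[as.character(m$load)])
  key <- paste(m$participant, m$carry_mode, m$load, m$trial)
  if (anyDuplicated(key)) {
    stop("duplicate (participant, carry_mode, load, trial) rows in manifest",
      call. = FALSE
    )
  }
  if (any(m$carry_mode == "none" & m$load != "NL")) {
    stop("carry_mode 'none' is only valid for the no-load level",
      call. = FALSE
    )
  }
  m
}

#' Write a trial manifest
#' @param manifest Manifest tibble as returned by [read_manifest()] or
#'   [generate_design()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  data.table::fwrite(as.data.frame(manifest), path)
  invisible(path)
}

#' Expand shared no-load trials across carrying modes
#'
#' Empty-handed reference trials recorded once per participant (manifest
#' `carry_mode = "none"`) are shared between the two carrying modes. For the
#' crossed mode-by-load analysis each such trial is listed under both modes,
#' which reproduces the bookkeeping of a full 2 x 4 design. Rows gain a
#' `shared_ref` flag marking duplicated references.
#'
#' @param manifest Manifest tibble.
#' @return Manifest tibble with no `"none"` rows and a `shared_ref` column.
#' @export
expand_shared_noload <- function(manifest) {
  if (!"shared_ref" %in% names(manifest)) manifest$shared_ref <- FALSE
  if (nrow(manifest) == 0 || !any(manifest$carry_mode == "none")) {
    return(manifest)
  }
  none <- dplyr::filter(manifest, .data$carry_mode == "none")
  rest <- dplyr::filter(manifest, .data$carry_mode != "none")
  rest$shared_ref <- FALSE
  dup <- purrr::map_dfr(MODES, function(md) {
    out <- none
    out$carry_mode <- factor(md, levels = levels(manifest$carry_mode))
    out$shared_ref <- TRUE
    out
  })
  out <- dplyr::bind_rows(rest, dup)
  out$carry_mode <- droplevels(out$carry_mode)
  dplyr::arrange(out, .data$participant, .data$carry_mode, .data$load,
    .data$trial
  )
}

#' Read participant anthropometry
#'
#' Delimited table with columns `participant`, `stature_m`, `leg_length_m`,
#' `thigh_length_m`, `shank_length_m` (all metres).
#'
#' @param path File path.
#' @return Tibble of anthropometry, validated (positive lengths, leg length
#'   shorter than stature).
#' @export
read_anthropometry <- function(path) {
  if (!file.exists(path)) stop("anthropometry file not found: ", path,
      call. = FALSE
    )
  a <- tibble::as_tibble(data.table::fread(path, sep = ",", data.table = FALSE))
  required <- c(
    "participant", "stature_m", "leg_length_m",
    "thigh_length_m", "shank_length_m"
  )
  missing_cols <- setdiff(required, names(a))
  if (length(missing_cols) > 0) {
    stop("anthropometry missing columns: ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  validate_anthropometry(a)
}

validate_anthropometry <- function(a) {
  lengths <- c("stature_m", "leg_length_m", "thigh_length_m", "shank_length_m")
  if (any(as.matrix(a[lengths]) <= 0)) {
    stop("anthropometry lengths must be positive", call. = FALSE)
  }
  if (any(a$leg_length_m >= a$stature_m)) {
    stop("leg_length_m must be smaller than stature_m", call. = FALSE)
  }
  tibble::as_tibble(a)
}

#' Write / read a per-cycle feature table
#'
#' The tidy feature table has one row per gait cycle with the trial keys,
#' the 11 gait parameters (cycle duration, stride length, six ROMs, three
#' mean relative phase angles) and the relative-speed covariate columns.
#'
#' @param features Feature tibble from [process_manifest()] or
#'   [process_design()].
#' @param path Output (input) file path.
#' @return `path` invisibly for the writer; a tibble for the reader.
#' @export
write_features <- function(features, path) {
  data.table::fwrite(as.data.frame(features), path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path, call. = FALSE)
  f <- tibble::as_tibble(data.table::fread(path, sep = ",", data.table = FALSE))
  if ("carry_mode" %in% names(f)) {
    f$carry_mode <- factor(f$carry_mode, levels = MODES)
  }
  if ("load" %in% names(f)) f$load <- parse_load(f$load)
  f
}

`%||%` <- function(x, y) if (is.null(x)) y else x
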