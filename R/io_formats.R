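#' Construct a marker trajectory set
#'
#' A `trajectory_set` holds time-indexed 3D positions of named markers at a
#' fixed sampling rate. Coordinates are in meters in the canonical axes
#' (AP = x forward, ML = y leftward, vertical = z up). Missing samples are
#' `NA`, never silently zero.
#'
#' @param positions named list, one element per marker, each an `n x 3`
#'   numeric matrix of positions in meters (`NA` marks missing samples).
#'   All markers must share the same frame count.
#' @param sample_rate sampling frequency in Hz (positive).
#' @return An object of class `trajectory_set` with fields `marker_names`,
#'   `positions`, `sample_rate` and `frame_count`.
#' @export
trajectory_set <- function(positions, sample_rate) {
  if (!is.list(positions)) stop("`positions` must be a named list of matrices")
  nm <- names(positions)
  if (length(positions) > 0 && (is.null(nm) || any(!nzchar(nm))))
    stop("every marker must be named")
  positions <- lapply(positions, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    if (ncol(p) != 3L) stop("marker positions need exactly 3 columns (x, y, z)")
    colnames(p) <- c("x", "y", "z")
    p
  })
  fc <- if (length(positions)) vapply(positions, nrow, integer(1)) else 0L
  if (length(unique(fc)) > 1L)
    stop("all markers must have identical frame counts")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("`sample_rate` must be a single positive number")
  structure(
    list(marker_names = nm %||% character(0), positions = positions,
         sample_rate = as.numeric(sample_rate),
         frame_count = as.integer(unique(fc)[1])),
    class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> %d markers, %d frames @ %g Hz\n",
              length(x$marker_names), x$frame_count, x$sample_rate))
  invisible(x)
}

#' Extract one marker's positions
#'
#' @param ts a [trajectory_set()].
#' @param marker marker name.
#' @return `n x 3` matrix in meters.
#' @export
marker_positions <- function(ts, marker) {
  stopifnot(inherits(ts, "trajectory_set"))
  if (!marker %in% ts$marker_names)
    stop(sprintf("marker '%s' not present in trajectory set", marker))
  ts$positions[[marker]]
}

#' Frame timestamps of a trajectory set
#' @param ts a [trajectory_set()].
#' @return numeric vector of times in seconds, starting at 0.
#' @export
trajectory_time <- function(ts) {
  stopifnot(inherits(ts, "trajectory_set"))
  (seq_len(ts$frame_count) - 1) / ts$sample_rate
}

#' Read marker trajectories from file
#'
#' Supported dialects: `"csv"` (one row per frame, columns
#' `time, <marker>_x, <marker>_y, <marker>_z`) and `"trc"` (OpenSim-style
#' tab-separated marker file). TRC files declaring `Units mm` are converted to
#' meters on load. Missing samples come back as `NA`.
#'
#' @param path file path.
#' @param format `"csv"` or `"trc"`; default guessed from the extension.
#' @return a [trajectory_set()] in meters.
#' @export
read_trajectories <- function(path, format = c("auto", "csv", "trc")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.trc$", path, ignore.case = TRUE)) "trc" else "csv"
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "csv") read_trajectories_csv(path) else read_trajectories_trc(path)
}

read_trajectories_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 1L || names(df)[1] != "time")
    stop(sprintf("malformed CSV trajectory header in %s: first column must be 'time'", path))
  cols <- names(df)[-1]
  bad <- cols[!grepl("_[xyz]$", cols)]
  if (length(bad))
    stop(sprintf("malformed CSV trajectory header: columns without _x/_y/_z suffix: %s",
                 paste(bad, collapse = ", ")))
  markers <- unique(sub("_[xyz]$", "", cols))
  sr_attr <- attr(df, "sample_rate")
  tvec <- df$time
  sr <- if (length(tvec) >= 2L) 1 / stats::median(diff(tvec)) else sr_attr %||% 100
  pos <- lapply(markers, function(m) {
    need <- paste0(m, "_", c("x", "y", "z"))
    if (!all(need %in% names(df)))
      stop(sprintf("marker '%s' is missing one of its x/y/z columns", m))
    as.matrix(df[, need])
  })
  names(pos) <- markers
  trajectory_set(pos, sr)
}

read_trajectories_trc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 5L) stop(sprintf("malformed TRC file (too short): %s", path))
  hdr_keys <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  hdr_vals <- strsplit(lines[3], "\t", fixed = TRUE)[[1]]
  hdr <- setNames(as.list(hdr_vals), hdr_keys[seq_along(hdr_vals)])
  sr <- as.numeric(hdr[["DataRate"]] %||% NA)
  n_markers <- as.integer(hdr[["NumMarkers"]] %||% NA)
  units <- hdr[["Units"]] %||% "m"
  if (is.na(sr) || is.na(n_markers))
    stop(sprintf("malformed TRC header (DataRate/NumMarkers) in %s", path))
  name_row <- strsplit(lines[4], "\t", fixed = TRUE)[[1]]
  markers <- name_row[-(1:2)]
  markers <- markers[nzchar(markers)]
  if (length(markers) != n_markers)
    stop(sprintf("TRC header declares %d markers but names %d", n_markers, length(markers)))
  data_lines <- lines[-(1:5)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  n <- length(data_lines)
  scale <- switch(tolower(units), mm = 1e-3, cm = 1e-2, m = 1, 1)
  vals <- matrix(NA_real_, nrow = n, ncol = 2 + 3 * n_markers)
  for (i in seq_len(n)) {
    fields <- strsplit(data_lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) > ncol(vals))
      stop(sprintf("TRC parse error at data line %d: %d columns, expected at most %d",
                   i, length(fields), ncol(vals)))
    v <- suppressWarnings(as.numeric(fields))
    vals[i, seq_along(v)] <- v
  }
  pos <- lapply(seq_len(n_markers), function(k) {
    vals[, 2 + (3 * (k - 1) + 1):(3 * k), drop = FALSE] * scale
  })
  names(pos) <- markers
  trajectory_set(pos, sr)
}

#' Write marker trajectories to file
#'
#' Inverse of [read_trajectories()]; round-trips are lossless to better than
#' 1e-9 m in both dialects.
#'
#' @param ts a [trajectory_set()].
#' @param path output file path.
#' @param format `"csv"` or `"trc"`.
#' @param units output length unit for TRC (`"m"` or `"mm"`); CSV is always
#'   meters.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(ts, path, format = c("auto", "csv", "trc"),
                               units = "m") {
  stopifnot(inherits(ts, "trajectory_set"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.trc$", path, ignore.case = TRUE)) "trc" else "csv"
  if (format == "csv") {
    df <- data.frame(time = trajectory_time(ts), check.names = FALSE)
    for (m in ts$marker_names) {
      p <- ts$positions[[m]]
      df[[paste0(m, "_x")]] <- p[, 1]
      df[[paste0(m, "_y")]] <- p[, 2]
      df[[paste0(m, "_z")]] <- p[, 3]
    }
    ok <- tryCatch({ write.csv(df, path, row.names = FALSE); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop(sprintf("cannot write trajectory file: %s", path))
  } else {
    scale <- switch(tolower(units), mm = 1e3, cm = 1e2, m = 1,
                    stop("unsupported TRC unit"))
    n <- ts$frame_count
    nm <- length(ts$marker_names)
    l1 <- sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path))
    l2 <- paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
                "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t")
    l3 <- paste(fmt_num(ts$sample_rate), fmt_num(ts$sample_rate), n, nm, units,
                fmt_num(ts$sample_rate), 1, n, sep = "\t")
    l4 <- paste(c("Frame#", "Time",
                  unlist(lapply(ts$marker_names, function(m) c(m, "", "")))),
                collapse = "\t")
    l5 <- paste(c("", "", unlist(lapply(seq_len(nm), function(k)
      paste0(c("X", "Y", "Z"), k)))), collapse = "\t")
    tvec <- trajectory_time(ts)
    body <- vapply(seq_len(n), function(i) {
      row <- unlist(lapply(ts$positions, function(p) p[i, ] * scale))
      paste(c(i, fmt_num(tvec[i]), fmt_num(row)), collapse = "\t")
    }, character(1))
    ok <- tryCatch({
      writeLines(c(l1, l2, l3, l4, l5, body), path); TRUE
    }, error = function(e) FALSE)
    if (!ok) stop(sprintf("cannot write trajectory file: %s", path))
  }
  invisible(path)
}

fmt_num <- function(x) {
  out <- formatC(x, digits = 15, format = "g")
  out[is.na(x)] <- ""
  trimws(out)
}

#' Interpolate short marker dropouts
#'
#' Linearly interpolates `NA` runs of at most `max_gap` frames per marker and
#' coordinate. Longer gaps (and gaps touching the series boundary) are left
#' missing and reported, so downstream code can reject the affected trials.
#'
#' @param ts a [trajectory_set()].
#' @param max_gap longest gap (frames) eligible for interpolation; default 5.
#' @return a `trajectory_set`; attribute `"long_gaps"` is a data.frame of
#'   markers/frames still missing (zero rows when fully repaired).
#' @export
interpolate_gaps <- function(ts, max_gap = 5L) {
  stopifnot(inherits(ts, "trajectory_set"))
  remaining <- list()
  pos <- ts$positions
  for (m in ts$marker_names) {
    p <- pos[[m]]
    for (j in 1:3) {
      x <- p[, j]
      if (!anyNA(x)) next
      r <- rle(is.na(x))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        gap <- r$lengths[k]
        a <- starts[k]; b <- ends[k]
        interior <- a > 1L && b < length(x)
        if (gap <= max_gap && interior) {
          x[a:b] <- approx(c(a - 1L, b + 1L), x[c(a - 1L, b + 1L)], xout = a:b)$y
        } else {
          remaining[[length(remaining) + 1L]] <-
            data.frame(marker = m, from = a, to = b)
        }
      }
      p[, j] <- x
    }
    pos[[m]] <- p
  }
  out <- trajectory_set(pos, ts$sample_rate)
  attr(out, "long_gaps") <- if (length(remaining)) {
    unique(do.call(rbind, remaining))
  } else data.frame(marker = character(0), from = integer(0), to = integer(0))
  out
}

#' Read / write YAML-style configuration
#'
#' Thin wrappers over the `yaml` package used for acquisition, model and game
#' configuration files.
#'
#' @param path file path.
#' @return `read_config`: a named list.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param cfg a named list to serialize.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Acquisition configuration
#'
#' Declares the sampling rate and the roles of the coordinate axes. The
#' canonical convention is AP = x (forward), ML = y (leftward),
#' vertical = z (up); lengths are meters after loading.
#'
#' @param sample_rate Hz.
#' @param axes named character vector mapping roles `ap`, `ml`, `vertical` to
#'   distinct axis letters.
#' @param units length unit; only `"m"` is canonical internally.
#' @return list of class `acquisition_config`.
#' @export
acquisition_config <- function(sample_rate = 100,
                               axes = c(ap = "x", ml = "y", vertical = "z"),
                               units = "m") {
  stopifnot(sample_rate > 0)
  if (!setequal(names(axes), c("ap", "ml", "vertical")) ||
      anyDuplicated(axes) > 0)
    stop("axes must assign distinct letters to ap, ml and vertical")
  structure(list(sample_rate = sample_rate, axes = axes, units = units),
            class = "acquisition_config")
}
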