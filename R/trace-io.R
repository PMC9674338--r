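# ROI fluorescence containers and file I/O.
#
# A recording is a set of regions of interest (ROIs) tiled over starburst
# dendrites, each carrying one fluorescence time series plus the stimulus
# window and (optionally) the ROI's radial distance from the soma.  Two
# on-disk representations are supported: a diffable CSV table (one time
# column, one column per ROI, metadata in a commented JSON header) and a
# lossless single-file container (RDS).

#' Construct a single-ROI fluorescence trace
#'
#' @param roi_id Identifier for the region of interest.
#' @param time_s Sample times in seconds, strictly increasing.
#' @param f_raw Raw fluorescence samples (arbitrary units), same length as
#'   `time_s`.
#' @param dff Optional \eqn{\Delta F/F} samples; normally left `NULL` and
#'   filled in by [compute_dff()].
#' @param fov_id Identifier of the field of view the ROI belongs to.
#' @param stim_onset_s,stim_offset_s Stimulus window in seconds; must lie
#'   within the trace extent.
#' @param radial_distance_um Distance of the ROI centre from the soma
#'   (micrometres), or `NA` if unknown.
#' @param group ROI group label: `"proximal"`, `"distal"` or
#'   `"unassigned"`.
#' @param truth Optional list of generator ground truth (used by the
#'   synthetic-data module); passed through untouched.
#'
#' @return An object of class `roi_trace`.
#' @export
roi_trace <- function(roi_id, time_s, f_raw, dff = NULL, fov_id = "fov1",
                      stim_onset_s = NA_real_, stim_offset_s = NA_real_,
                      radial_distance_um = NA_real_,
                      group = c("unassigned", "proximal", "distal"),
                      truth = NULL) {
  group <- match.arg(group)
  time_s <- as.numeric(time_s)
  f_raw <- as.numeric(f_raw)
  if (length(time_s) != length(f_raw))
    stop("time_s and f_raw must have equal length")
  if (length(time_s) < 2L || any(diff(time_s) <= 0))
    stop("non-monotonic time", call. = FALSE)
  if (all(is.na(f_raw)))
    stop(sprintf("trace '%s' is NaN-only", roi_id), call. = FALSE)
  if (!is.na(stim_onset_s) && !is.na(stim_offset_s)) {
    if (stim_offset_s <= stim_onset_s)
      stop("stimulus window must have positive duration")
    if (stim_onset_s < time_s[1L] || stim_offset_s > time_s[length(time_s)])
      stop("stimulus window outside trace extent")
  }
  structure(list(
    roi_id = as.character(roi_id), fov_id = as.character(fov_id),
    time_s = time_s, f_raw = f_raw, dff = dff,
    stim_onset_s = stim_onset_s, stim_offset_s = stim_offset_s,
    radial_distance_um = radial_distance_um, group = group,
    truth = truth
  ), class = "roi_trace")
}

#' @export
print.roi_trace <- function(x, ...) {
  cat(sprintf("<roi_trace '%s' (%s), %d samples over %.2f s, dff %s>\n",
              x$roi_id, x$group, length(x$time_s),
              diff(range(x$time_s)),
              if (is.null(x$dff)) "absent" else "computed"))
  invisible(x)
}

#' Construct a recording set
#'
#' Bundles the ROI traces of one or more fields of view with the
#' acquisition frame rate and free-text provenance.
#'
#' @param traces List of [roi_trace()] objects.
#' @param frame_rate_hz Acquisition frame rate in Hz.
#' @param provenance Free-text metadata carried through file round trips.
#'
#' @return An object of class `recording_set`.
#' @export
recording_set <- function(traces, frame_rate_hz = NA_real_, provenance = "") {
  stopifnot(is.list(traces))
  ok <- vapply(traces, inherits, logical(1), what = "roi_trace")
  if (length(traces) && !all(ok)) stop("all elements must be roi_trace objects")
  names(traces) <- vapply(traces, `[[`, character(1), "roi_id")
  structure(list(traces = traces, frame_rate_hz = frame_rate_hz,
                 provenance = provenance),
            class = "recording_set")
}

#' @export
print.recording_set <- function(x, ...) {
  cat(sprintf("<recording_set: %d ROIs, frame rate %s Hz>\n",
              length(x$traces),
              format(x$frame_rate_hz)))
  invisible(x)
}

#' @export
length.recording_set <- function(x) length(x$traces)

trace_meta <- function(tr) {
  list(fov_id = tr$fov_id, stim_onset_s = tr$stim_onset_s,
       stim_offset_s = tr$stim_offset_s,
       radial_distance_um = tr$radial_distance_um, group = tr$group)
}

#' Read ROI traces from file
#'
#' @param path Path to a file written by [write_traces()] (or any CSV with
#'   a `time_s` column plus one column per ROI).
#' @param format `"table"` for the CSV dialect, `"container"` for the
#'   lossless RDS container.
#'
#' @return A [recording_set()].
#' @export
read_traces <- function(path, format = c("table", "container")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "container") {
    set <- readRDS(path)
    if (!inherits(set, "recording_set"))
      stop("container does not hold a recording_set")
    return(set)
  }
  first <- readLines(path, n = 50L)
  meta_line <- grep("^#sacglu-meta:", first, value = TRUE)
  meta <- if (length(meta_line)) {
    jsonlite::fromJSON(sub("^#sacglu-meta:\\s*", "", meta_line[1L]),
                       simplifyVector = FALSE)
  } else list()
  tab <- read.csv(path, comment.char = "#", check.names = FALSE)
  if (!"time_s" %in% names(tab)) stop("missing time column 'time_s'")
  time_s <- tab$time_s
  if (any(diff(time_s) <= 0)) stop("non-monotonic time", call. = FALSE)
  roi_cols <- setdiff(names(tab), "time_s")
  if (!length(roi_cols)) stop("no ROI columns found")
  traces <- lapply(roi_cols, function(id) {
    y <- tab[[id]]
    if (all(is.na(y)))
      stop(sprintf("trace '%s' is NaN-only", id), call. = FALSE)
    m <- meta$roi[[id]]
    do.call(roi_trace, c(list(roi_id = id, time_s = time_s, f_raw = y),
                         if (!is.null(m)) lapply(m, function(v) {
                           if (is.null(v)) NA_real_ else v
                         })))
  })
  recording_set(traces,
                frame_rate_hz = if (!is.null(meta$frame_rate_hz))
                  meta$frame_rate_hz else 1 / median(diff(time_s)),
                provenance = if (!is.null(meta$provenance))
                  meta$provenance else "")
}

#' Write ROI traces to file
#'
#' The table format requires all traces to share one time base (true of any
#' single field of view).  Values survive a write/read round trip to at
#' least 1e-9 relative tolerance; the container format is lossless and also
#' preserves computed \eqn{\Delta F/F} and ground-truth side data.
#'
#' @param set A [recording_set()]; must be non-empty.
#' @param path Output path.
#' @inheritParams read_traces
#' @return `path`, invisibly.
#' @export
write_traces <- function(set, path, format = c("table", "container")) {
  format <- match.arg(format)
  stopifnot(inherits(set, "recording_set"))
  if (!length(set$traces)) stop("empty recording set")
  if (format == "container") {
    saveRDS(set, path)
    return(invisible(path))
  }
  t0 <- set$traces[[1L]]$time_s
  same <- vapply(set$traces, function(tr) {
    length(tr$time_s) == length(t0) && max(abs(tr$time_s - t0)) < 1e-12
  }, logical(1))
  if (!all(same)) stop("table format requires a common time base")
  tab <- data.frame(time_s = t0, check.names = FALSE)
  for (tr in set$traces) tab[[tr$roi_id]] <- tr$f_raw
  meta <- list(frame_rate_hz = set$frame_rate_hz,
               provenance = set$provenance,
               roi = lapply(set$traces, trace_meta))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#sacglu-meta: ",
                    jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                     na = "null")), con)
  write.csv(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compute \eqn{\Delta F/F} relative to a pre-stimulus baseline
#'
#' Baseline fluorescence F0 is the mean of `f_raw` over the baseline
#' window, by default the 1 s immediately preceding stimulus onset; then
#' \eqn{\Delta F/F = (F - F_0)/F_0}.
#'
#' @param x A [roi_trace()] or [recording_set()].
#' @param baseline_window_s Length-2 numeric `c(start, end)` in seconds;
#'   must precede the stimulus onset and lie within the trace.  `NULL`
#'   selects the default window.
#' @return Object of the same class with `dff` filled in.
#' @export
compute_dff <- function(x, baseline_window_s = NULL) UseMethod("compute_dff")

baseline_window_for <- function(trace, baseline_window_s) {
  if (!is.null(baseline_window_s)) {
    stopifnot(length(baseline_window_s) == 2L,
              baseline_window_s[2L] > baseline_window_s[1L])
    return(baseline_window_s)
  }
  if (is.na(trace$stim_onset_s))
    stop("no stimulus onset: give baseline_window_s explicitly")
  c(max(trace$time_s[1L], trace$stim_onset_s - 1), trace$stim_onset_s)
}

window_idx <- function(time_s, window) {
  idx <- which(time_s >= window[1L] & time_s <= window[2L])
  if (!length(idx)) stop("window contains no samples")
  idx
}

#' @export
compute_dff.roi_trace <- function(x, baseline_window_s = NULL) {
  win <- baseline_window_for(x, baseline_window_s)
  if (!is.na(x$stim_onset_s) && win[2L] > x$stim_onset_s + 1e-12)
    stop("baseline window must precede stimulus onset")
  f0 <- mean(x$f_raw[window_idx(x$time_s, win)], na.rm = TRUE)
  if (!is.finite(f0) || f0 <= 0) stop("non-positive baseline", call. = FALSE)
  x$dff <- (x$f_raw - f0) / f0
  x
}

#' @export
compute_dff.recording_set <- function(x, baseline_window_s = NULL) {
  x$traces <- lapply(x$traces, compute_dff, baseline_window_s = baseline_window_s)
  x
}

#' Extract ROI traces from an image stack over a square grid
#'
#' Tiles the field of view with non-overlapping square ROIs (row-major
#' order, 0-based indices; partial edge tiles are dropped) and reports the
#' mean pixel intensity of each tile in each frame.
#'
#' @param stack Either a 3-D numeric array `[y, x, frame]` or the path to a
#'   multi-frame TIFF file.
#' @param grid_um ROI edge length in micrometres.
#' @param pixel_size_um Pixel pitch in micrometres.
#' @param frame_rate_hz Acquisition frame rate used to build the time axis.
#' @param stim_onset_s,stim_offset_s Optional stimulus window attached to
#'   every extracted trace.
#' @return A [recording_set()] with ROI ids `"roi_<row>_<col>"`.
#' @export
extract_rois <- function(stack, grid_um, pixel_size_um, frame_rate_hz = 58.25,
                         stim_onset_s = NA_real_, stim_offset_s = NA_real_) {
  stopifnot(grid_um > 0, pixel_size_um > 0, frame_rate_hz > 0)
  if (is.character(stack)) {
    frames <- tiff::readTIFF(stack, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    stack <- array(unlist(frames),
                   dim = c(nrow(frames[[1L]]), ncol(frames[[1L]]),
                           length(frames)))
  }
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  if (dim(stack)[3L] < 2L) stop("stack must have at least 2 frames")
  px <- max(1L, round(grid_um / pixel_size_um))
  ny <- dim(stack)[1L] %/% px
  nx <- dim(stack)[2L] %/% px
  if (ny < 1L || nx < 1L) stop("ROI grid larger than the field")
  nf <- dim(stack)[3L]
  time_s <- (seq_len(nf) - 0.5) / frame_rate_hz
  traces <- vector("list", ny * nx)
  k <- 0L
  for (r in seq_len(ny) - 1L) {
    for (cc in seq_len(nx) - 1L) {
      k <- k + 1L
      ys <- r * px + seq_len(px)
      xs <- cc * px + seq_len(px)
      traces[[k]] <- roi_trace(
        roi_id = sprintf("roi_%d_%d", r, cc),
        time_s = time_s,
        f_raw = apply(stack[ys, xs, , drop = FALSE], 3L, mean),
        stim_onset_s = stim_onset_s, stim_offset_s = stim_offset_s)
    }
  }
  recording_set(traces, frame_rate_hz = frame_rate_hz,
                provenance = "extract_rois")
}
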