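#' In-memory model of a diaPASEF run
#'
#' A `RunFixture` bundles everything one acquisition contributes to the
#' deconvolution: the frame table (one TIMS ramp per retention-time point),
#' the DIA isolation windows (bounded in both m/z and ion mobility), the
#' per-frame ion-mobility segmentation of MS2 frames, and the sparse point
#' cloud of (m/z, 1/K0, intensity) detector events.
#'
#' Conventions: m/z in Thomson, ion mobility as inverse reduced mobility
#' 1/K0 (Vs/cm^2), retention time in seconds. All intervals are half-open
#' `[low, high)` so boundary points have an unambiguous owner.
#'
#' @param meta named list of run-level constants. Required keys:
#'   `mz_step`, `im_step` (the smallest m/z and 1/K0 difference between two
#'   signals, i.e. the digitizer grid), `ms1_mz_min`, `ms1_mz_max`,
#'   `frag_mz_min`, `frag_mz_max`, `im_min`, `im_max`, `run_label`.
#' @param windows data.frame with columns `window_id`, `mz_low`, `mz_high`,
#'   `im_low`, `im_high`, `cycle_position`.
#' @param frames data.frame with columns `frame_id`, `rt_seconds`, `ms_level`.
#' @param segments data.frame with columns `frame_id`, `window_id`, `im_low`,
#'   `im_high`; one row per isolation-window scan range of each MS2 frame.
#' @param points data.frame with columns `frame_id`, `mz`, `inv_k0`,
#'   `intensity`; sorted by (`inv_k0`, `mz`) within each frame.
#' @param validate check all invariants (default `TRUE`).
#' @return an object of class `RunFixture`.
#' @export
run_fixture <- function(meta, windows, frames, segments, points, validate = TRUE) {
  run <- structure(list(
    meta = meta,
    windows = as.data.table(windows),
    frames = as.data.table(frames),
    segments = as.data.table(segments),
    points = as.data.table(points)
  ), class = "RunFixture")
  setkey(run$points, frame_id)
  if (validate) validate_fixture(run)
  run
}

#' @export
print.RunFixture <- function(x, ...) {
  cat(sprintf(
    "RunFixture '%s': %d frames (%d MS1 / %d MS2), %d windows, %d points\n",
    x$meta$run_label, nrow(x$frames), sum(x$frames$ms_level == 1L),
    sum(x$frames$ms_level == 2L), nrow(x$windows), nrow(x$points)))
  invisible(x)
}

.req_meta <- c("mz_step", "im_step", "ms1_mz_min", "ms1_mz_max",
               "frag_mz_min", "frag_mz_max", "im_min", "im_max", "run_label")

#' Validate a RunFixture against all structural invariants
#'
#' Checks the invariants documented in [run_fixture()]; the error message of
#' the first violation names the offending frame where one is identifiable.
#'
#' @param run a `RunFixture`.
#' @return `TRUE` invisibly; stops with a validation error otherwise.
#' @export
validate_fixture <- function(run) {
  fail <- function(...) stop("fixture validation: ", sprintf(...), call. = FALSE)
  m <- run$meta
  missing_keys <- setdiff(.req_meta, names(m))
  if (length(missing_keys))
    fail("missing meta keys: %s", paste(missing_keys, collapse = ", "))
  for (k in c("mz_step", "im_step"))
    if (!is.finite(m[[k]]) || m[[k]] <= 0) fail("meta %s must be positive", k)
  if (m$ms1_mz_min >= m$ms1_mz_max || m$frag_mz_min >= m$frag_mz_max ||
      m$im_min >= m$im_max)
    fail("meta axis ranges must have low < high")

  w <- run$windows
  if (nrow(w)) {
    if (anyDuplicated(w$window_id)) fail("duplicate window_id")
    if (any(w$mz_low >= w$mz_high)) fail("window with mz_low >= mz_high")
    if (any(w$im_low >= w$im_high)) fail("window with im_low >= im_high")
  }

  fr <- run$frames
  if (nrow(fr)) {
    if (any(fr$frame_id <= 0) || anyDuplicated(fr$frame_id))
      fail("frame_ids must be unique positive integers")
    if (is.unsorted(fr$frame_id, strictly = TRUE))
      fail("frames must be ordered by frame_id")
    if (is.unsorted(fr$rt_seconds, strictly = TRUE))
      fail("rt_seconds must strictly increase with frame_id (first violation near frame %d)",
           fr$frame_id[which(diff(fr$rt_seconds) <= 0)[1] + 1L])
    if (!all(fr$ms_level %in% c(1L, 2L))) fail("ms_level must be 1 or 2")
  }

  seg <- run$segments
  if (nrow(seg)) {
    bad <- setdiff(seg$frame_id, fr$frame_id[fr$ms_level == 2L])
    if (length(bad)) fail("segments attached to non-MS2 frame %d", bad[1])
    if (length(setdiff(seg$window_id, w$window_id)))
      fail("segment references unknown window (frame %d)",
           seg$frame_id[!seg$window_id %in% w$window_id][1])
    if (any(seg$im_low >= seg$im_high)) fail("segment with im_low >= im_high")
    ov <- seg[order(frame_id, im_low),
              .(bad = any(head(im_high, -1) > tail(im_low, -1))), by = frame_id]
    if (any(ov$bad)) fail("overlapping segments in frame %d", ov$frame_id[ov$bad][1])
  }
  ms2_frames <- fr$frame_id[fr$ms_level == 2L]
  no_seg <- setdiff(ms2_frames, unique(seg$frame_id))
  if (length(no_seg)) fail("MS2 frame %d has no window segments", no_seg[1])

  # cyclic structure: the per-frame stream label sequence must repeat
  if (nrow(fr)) {
    sig <- vapply(seq_len(nrow(fr)), function(k) {
      if (fr$ms_level[k] == 1L) return("MS1")
      s <- seg[frame_id == fr$frame_id[k]][order(im_low)]
      paste(s$window_id, s$im_low, s$im_high, collapse = ";")
    }, character(1))
    p <- length(unique(sig))
    if (anyDuplicated(sig[seq_len(min(p, length(sig)))]))
      fail("frame cycle is not a repetition of distinct streams")
    expect_sig <- sig[((seq_along(sig) - 1L) %% p) + 1L]
    if (!identical(sig, expect_sig))
      fail("frame sequence is not cyclic (first break at frame %d)",
           fr$frame_id[which(sig != expect_sig)[1]])
  }

  pts <- run$points
  if (nrow(pts)) {
    if (length(setdiff(unique(pts$frame_id), fr$frame_id)))
      fail("points reference unknown frame %d",
           setdiff(unique(pts$frame_id), fr$frame_id)[1])
    if (any(!is.finite(pts$intensity)) || any(pts$intensity <= 0))
      fail("intensities must be finite and > 0 (frame %d)",
           pts$frame_id[!is.finite(pts$intensity) | pts$intensity <= 0][1])
    if (any(!is.finite(pts$mz)) || any(!is.finite(pts$inv_k0)))
      fail("non-finite point coordinates (frame %d)",
           pts$frame_id[!is.finite(pts$mz) | !is.finite(pts$inv_k0)][1])
    srt <- pts[, .(ok = identical(order(inv_k0, mz), seq_len(.N))), by = frame_id]
    if (any(!srt$ok))
      fail("points not sorted by (inv_k0, mz) in frame %d", srt$frame_id[!srt$ok][1])
    # every MS2 point inside exactly one segment of its frame
    lev <- fr$ms_level[match(pts$frame_id, fr$frame_id)]
    p2 <- pts[lev == 2L]
    if (nrow(p2)) {
      p2 <- p2[, .(frame_id, inv_k0)]
      p2[, idx := .I]
      hit <- seg[p2, on = .(frame_id, im_low <= inv_k0, im_high > inv_k0),
                 .(idx = i.idx, window_id = x.window_id), nomatch = NULL]
      nhit <- hit[, .N, by = idx]
      if (nrow(nhit) < nrow(p2) || any(nhit$N != 1L)) {
        off <- if (nrow(nhit) < nrow(p2))
          setdiff(p2$idx, nhit$idx)[1] else nhit$idx[nhit$N != 1L][1]
        fail("MS2 point outside exactly one window segment in frame %d",
             p2$frame_id[off])
      }
    }
    p1 <- pts[lev == 1L]
    if (nrow(p1) && (any(p1$mz < m$ms1_mz_min | p1$mz >= m$ms1_mz_max) ||
                     any(p1$inv_k0 < m$im_min | p1$inv_k0 >= m$im_max)))
      fail("MS1 point outside the declared scan ranges (frame %d)",
           p1$frame_id[(p1$mz < m$ms1_mz_min | p1$mz >= m$ms1_mz_max |
                        p1$inv_k0 < m$im_min | p1$inv_k0 >= m$im_max)][1])
    if (nrow(p2) && any(pts[lev == 2L]$mz < m$frag_mz_min |
                        pts[lev == 2L]$mz >= m$frag_mz_max))
      fail("MS2 point outside the fragment scan range (frame %d)",
           pts[lev == 2L]$frame_id[(pts[lev == 2L]$mz < m$frag_mz_min |
                                    pts[lev == 2L]$mz >= m$frag_mz_max)][1])
  }
  invisible(TRUE)
}

.write_table <- function(con, name, dt, num_cols) {
  writeLines(sprintf("TABLE\t%s\t%d", name, nrow(dt)), con)
  writeLines(paste(names(dt), collapse = "\t"), con)
  if (nrow(dt)) {
    cols <- lapply(names(dt), function(nm) {
      v <- dt[[nm]]
      if (nm %in% num_cols) sprintf("%.17g", v) else as.character(v)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
}

#' Write a RunFixture to the open single-file run-fixture format
#'
#' The format is a plain-text, tab-separated, single-file columnar layout:
#' a versioned header of `#key<TAB>value` meta lines, followed by four
#' `TABLE <name> <nrow>` sections (windows, frames, segments, points), each
#' with a header row. Numeric values are written with `%.17g` so the
#' read/write round trip is bit-identical.
#'
#' @param run a valid `RunFixture` (validated before any byte is written).
#' @param path output file path.
#' @return `path` invisibly.
#' @export
write_fixture <- function(run, path) {
  validate_fixture(run)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("#diadeconv_fixture\t1", con)
  for (k in names(run$meta)) {
    v <- run$meta[[k]]
    writeLines(sprintf("#%s\t%s", k,
                       if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)),
               con)
  }
  .write_table(con, "windows", run$windows,
               c("mz_low", "mz_high", "im_low", "im_high"))
  .write_table(con, "frames", run$frames, "rt_seconds")
  .write_table(con, "segments", run$segments, c("im_low", "im_high"))
  .write_table(con, "points", run$points, c("mz", "inv_k0", "intensity"))
  invisible(path)
}

.meta_numeric <- c("mz_step", "im_step", "ms1_mz_min", "ms1_mz_max",
                   "frag_mz_min", "frag_mz_max", "im_min", "im_max", "seed")

#' Read a run fixture file
#'
#' Parses the format written by [write_fixture()] and validates every
#' structural invariant before returning.
#'
#' @param path fixture file path.
#' @return a validated `RunFixture`.
#' @export
read_fixture <- function(path) {
  if (!file.exists(path)) stop("fixture file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#diadeconv_fixture"))
    stop("not a diadeconv fixture file: ", path, call. = FALSE)
  k <- 2L
  meta <- list()
  while (k <= length(lines) && startsWith(lines[k], "#")) {
    kv <- strsplit(sub("^#", "", lines[k]), "\t", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- if (kv[1] %in% .meta_numeric) as.numeric(kv[2]) else kv[2]
    k <- k + 1L
  }
  tabs <- list()
  int_cols <- c("window_id", "cycle_position", "frame_id", "ms_level")
  while (k <= length(lines)) {
    hdr <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (hdr[1] != "TABLE") stop("malformed fixture near line ", k, call. = FALSE)
    n <- as.integer(hdr[3])
    dt <- fread(text = paste(lines[(k + 1L):(k + 1L + n)], collapse = "\n"),
                sep = "\t", header = TRUE, colClasses = NULL)
    if (n == 0L) {
      cols <- strsplit(lines[k + 1L], "\t", fixed = TRUE)[[1]]
      dt <- setnames(as.data.table(rep(list(numeric(0)), length(cols))), cols)
    }
    for (nm in intersect(names(dt), int_cols)) set(dt, j = nm, value = as.integer(dt[[nm]]))
    for (nm in setdiff(names(dt), int_cols)) set(dt, j = nm, value = as.numeric(dt[[nm]]))
    tabs[[hdr[2]]] <- dt
    k <- k + 2L + n
  }
  need <- c("windows", "frames", "segments", "points")
  if (length(setdiff(need, names(tabs))))
    stop("fixture missing table(s): ",
         paste(setdiff(need, names(tabs)), collapse = ", "), call. = FALSE)
  run_fixture(meta, tabs$windows, tabs$frames, tabs$segments, tabs$points)
}

#' Look up the isolation window owning a mobility coordinate of a frame
#'
#' For an MS2 frame, returns the unique window whose ion-mobility segment
#' contains `inv_k0` under the half-open `[low, high)` convention; `NULL` for
#' MS1 frames or mobilities outside every segment.
#'
#' @param run a `RunFixture`.
#' @param frame_id frame identifier (must exist).
#' @param inv_k0 inverse reduced ion mobility to locate.
#' @return a one-row list with the window fields, or `NULL`.
#' @export
window_of <- function(run, frame_id, inv_k0) {
  row <- match(frame_id, run$frames$frame_id)
  if (is.na(row)) stop("unknown frame_id: ", frame_id, call. = FALSE)
  if (run$frames$ms_level[row] == 1L) return(NULL)
  seg <- run$segments
  hit <- which(seg$frame_id == frame_id & seg$im_low <= inv_k0 &
                 seg$im_high > inv_k0)
  if (!length(hit)) return(NULL)
  as.list(run$windows[run$windows$window_id == seg$window_id[hit[1]]][1])
}

#' Extract one frame as a MobilityFrame list
#'
#' @param run a `RunFixture`.
#' @param frame_id frame identifier.
#' @return list with `frame_id`, `rt_seconds`, `ms_level`, `points`
#'   (data.table) and `window_segments` (data.table, empty for MS1).
#' @export
get_frame <- function(run, frame_id) {
  row <- match(frame_id, run$frames$frame_id)
  if (is.na(row)) stop("unknown frame_id: ", frame_id, call. = FALSE)
  fid <- frame_id
  seg <- run$segments[run$segments$frame_id == fid]
  list(frame_id = run$frames$frame_id[row],
       rt_seconds = run$frames$rt_seconds[row],
       ms_level = run$frames$ms_level[row],
       points = run$points[run$points$frame_id == fid],
       window_segments = seg[order(seg$im_low)])
}

#' Frame-source backend interface
#'
#' Minimal adapter contract so a vendor reader (e.g. a Bruker TDF backend:
#' SQLite frame metadata plus binary scan decoding) can be plugged in without
#' touching the algorithm: a `frame_source` is a list with
#' `enumerate_frames()` returning the frame table and
#' `fetch_points(frame_id)` returning that frame's point table. This
#' constructor wraps an in-memory `RunFixture` in the same interface.
#'
#' @param run a `RunFixture`.
#' @return a list of class `frame_source`.
#' @export
fixture_frame_source <- function(run) {
  structure(list(
    enumerate_frames = function() copy(run$frames),
    fetch_points = function(frame_id) {
      fid <- frame_id
      run$points[run$points$frame_id == fid]
    }
  ), class = "frame_source")
}
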