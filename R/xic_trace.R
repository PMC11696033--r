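#' @name xic_trace
#' @title XIC tracing across retention time
#' @description
#' Links per-merged-frame 2D peaks into extracted-ion-chromatogram features,
#' locates the apex of every trace (attributes are frozen at the apex frame),
#' determines bell-shape boundaries by walking outward from the apex, and
#' segments elongated traces with Savitzky-Golay smoothing plus the
#' rolling-statistics Z-score peak detector.
NULL

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing. Interior points use the central
#' convolution weights; the first and last half-windows are evaluated from
#' the polynomial fitted to the first/last full window, so no samples are
#' lost. Inputs shorter than the window are returned unchanged.
#'
#' @param y numeric vector.
#' @param window odd window length.
#' @param order polynomial order (< window).
#' @return smoothed numeric vector of the same length.
#' @export
savitzky_golay <- function(y, window = 5L, order = 2L) {
  n <- length(y)
  if (window %% 2 == 0) stop("window must be odd", call. = FALSE)
  if (order >= window) stop("order must be < window", call. = FALSE)
  if (n < window) return(y)
  m <- (window - 1L) %/% 2L
  A <- outer(-m:m, 0:order, `^`)
  H <- A %*% solve(crossprod(A), t(A))  # projection onto local polynomials
  out <- numeric(n)
  for (k in seq_len(n)) {
    if (k <= m) {
      out[k] <- H[k, ] %*% y[1:window]
    } else if (k > n - m) {
      out[k] <- H[window - (n - k), ] %*% y[(n - window + 1L):n]
    } else {
      out[k] <- H[m + 1L, ] %*% y[(k - m):(k + m)]
    }
  }
  out
}

#' Rolling Z-score peak detection
#'
#' The lag/threshold/influence peak detector based on rolling mean and
#' standard deviation: a sample deviating more than `threshold` standard
#' deviations from the rolling statistics of the preceding `lag` (filtered)
#' samples is flagged +1/-1, and flagged samples enter the rolling window
#' damped by `influence`.
#'
#' @param y numeric vector.
#' @param lag rolling-window length.
#' @param threshold deviation threshold in standard deviations.
#' @param influence weight of flagged samples in the rolling statistics.
#' @return integer vector of signals in \{-1, 0, 1\}, same length as `y`.
#' @export
zscore_peaks <- function(y, lag = 5L, threshold = 3, influence = 0.5) {
  n <- length(y)
  signals <- integer(n)
  if (n <= lag + 1L) return(signals)
  filt <- y
  avg <- std <- numeric(n)
  avg[lag] <- mean(y[1:lag])
  std[lag] <- stats::sd(y[1:lag])
  for (k in (lag + 1L):n) {
    if (is.finite(std[k - 1L]) && std[k - 1L] > 0 &&
        abs(y[k] - avg[k - 1L]) > threshold * std[k - 1L]) {
      signals[k] <- if (y[k] > avg[k - 1L]) 1L else -1L
      filt[k] <- influence * y[k] + (1 - influence) * filt[k - 1L]
    } else {
      signals[k] <- 0L
      filt[k] <- y[k]
    }
    avg[k] <- mean(filt[(k - lag + 1L):k])
    std[k] <- stats::sd(filt[(k - lag + 1L):k])
  }
  signals
}

.new_xic <- function(mz, im, mz_range, im_range, frames, rt, intensity,
                     ms_level, window_id) {
  apex <- which.max(intensity)  # ties broken toward the earlier frame
  structure(list(
    mz = mz, im = im, mz_range = mz_range, im_range = im_range,
    frames = frames, rt = rt, intensity = intensity,
    apex = apex, apex_intensity = intensity[apex],
    ms_level = ms_level, window_id = window_id,
    bounds = c(1L, length(frames)), rt_start = rt[1], rt_end = rt[length(rt)],
    extended = FALSE, extended_left = FALSE, extended_right = FALSE,
    area = 0
  ), class = "XICFeature")
}

#' @export
print.XICFeature <- function(x, ...) {
  cat(sprintf(
    "XICFeature %s m/z %.4f 1/K0 %.4f: %d frames, apex %.2f s, intensity %.3g%s\n",
    if (x$ms_level == 1L) "MS1" else paste0("W", x$window_id),
    x$mz, x$im, length(x$frames), x$rt[x$apex], x$apex_intensity,
    if (x$extended) " (extended)" else ""))
  invisible(x)
}

#' Link per-frame 2D peaks into XIC features
#'
#' Greedy frame-to-frame linking: while traversing merged frames along
#' retention time, each active trace is matched to the peak within the m/z
#' and IM tolerances with the smallest relative m/z residual (ties broken by
#' trace then peak m/z, so the result is invariant to the input order of
#' peaks within a frame). The reference coordinates of a trace are those of
#' its apex-so-far peak, and the final attributes (m/z, IM, signal ranges)
#' are frozen at the apex frame. A trace terminates after `gap_max`
#' consecutive unmatched frames; single-frame gaps are filled by linear
#' interpolation so trace frames are consecutive.
#'
#' @param peaks data.table as returned by [detect_peaks()] (needs columns
#'   `frame_index`, `rt`, `mz`, `im`, `mz_lo`, `mz_hi`, `im_lo`, `im_hi`,
#'   `intensity`).
#' @param mz_tol linking tolerance in ppm.
#' @param im_tol linking tolerance in 1/K0.
#' @param gap_max consecutive unmatched frames before a trace closes.
#' @param ms_level,window_id stream labels stamped onto the features.
#' @return list of `XICFeature`.
#' @export
trace_xics <- function(peaks, mz_tol = 10, im_tol = 0.01, gap_max = 1L,
                       ms_level = 1L, window_id = NA_integer_) {
  if (is.null(peaks) || !nrow(peaks)) return(list())
  peaks <- as.data.table(peaks)
  setorder(peaks, frame_index, mz, im)
  p_fidx <- peaks$frame_index; p_mz <- peaks$mz; p_im <- peaks$im
  p_int <- peaks$intensity
  by_frame <- split(seq_len(nrow(peaks)), p_fidx)
  active <- list()   # each: list(rows, last_frame, ref_mz, ref_im, apex_int)
  closed <- list()
  for (f in seq(min(p_fidx), max(p_fidx))) {
    pidx <- by_frame[[as.character(f)]]
    matched_peak <- rep(FALSE, length(pidx))
    if (length(active) && length(pidx)) {
      ref_mz <- vapply(active, `[[`, numeric(1), "ref_mz")
      ref_im <- vapply(active, `[[`, numeric(1), "ref_im")
      dm <- abs(outer(ref_mz, p_mz[pidx], `-`))
      di <- abs(outer(ref_im, p_im[pidx], `-`))
      hit <- which(dm <= mz_tol * 1e-6 * ref_mz & di <= im_tol, arr.ind = TRUE)
      if (nrow(hit)) {
        ord <- order(dm[hit], hit[, 1], hit[, 2])
        used_t <- rep(FALSE, length(active))
        for (r in ord) {
          t <- hit[r, 1]; p <- hit[r, 2]
          if (used_t[t] || matched_peak[p]) next
          used_t[t] <- TRUE; matched_peak[p] <- TRUE
          tr <- active[[t]]
          tr$rows <- c(tr$rows, pidx[p])
          tr$last_frame <- f
          if (p_int[pidx[p]] > tr$apex_int) {
            tr$apex_int <- p_int[pidx[p]]
            tr$ref_mz <- p_mz[pidx[p]]; tr$ref_im <- p_im[pidx[p]]
          }
          active[[t]] <- tr
        }
      }
    }
    # close traces that exceeded the gap
    if (length(active)) {
      gone <- vapply(active, function(tr) f - tr$last_frame > gap_max, logical(1))
      closed <- c(closed, active[gone])
      active <- active[!gone]
    }
    # unmatched peaks start new traces
    for (p in which(!matched_peak)) {
      active[[length(active) + 1L]] <- list(
        rows = pidx[p], last_frame = f,
        ref_mz = p_mz[pidx[p]], ref_im = p_im[pidx[p]],
        apex_int = p_int[pidx[p]])
    }
  }
  closed <- c(closed, active)

  lapply(closed, function(tr) {
    rows <- tr$rows[order(p_fidx[tr$rows])]
    fr <- seq(p_fidx[rows[1]], p_fidx[rows[length(rows)]])
    if (length(rows) > 1) {
      inten <- approx(p_fidx[rows], p_int[rows], xout = fr)$y
      rt <- approx(p_fidx[rows], peaks$rt[rows], xout = fr)$y
    } else {
      inten <- p_int[rows]; rt <- peaks$rt[rows]
    }
    apex_row <- rows[which.max(p_int[rows])]
    .new_xic(p_mz[apex_row], p_im[apex_row],
             c(peaks$mz_lo[apex_row], peaks$mz_hi[apex_row]),
             c(peaks$im_lo[apex_row], peaks$im_hi[apex_row]),
             fr, rt, inten, ms_level, window_id)
  })
}

#' Determine bell-shape boundaries of an XIC feature
#'
#' Walks outward from the apex on each side until the intensity falls below
#' `valley_frac` times the apex intensity (that sample becomes the boundary)
#' or rises again (the valley becomes the boundary), whichever occurs first.
#' If neither occurs before the trace end, the end becomes the boundary and
#' the extended flag is set for that side.
#'
#' @param xic an `XICFeature` with a nonempty trace.
#' @param valley_frac boundary intensity fraction of the apex.
#' @return the feature with `bounds`, `rt_start`, `rt_end`, `extended_*` and
#'   `area` (trapezoid-free sum of bounded intensities times the frame
#'   spacing) filled in.
#' @export
bound_xic <- function(xic, valley_frac = 0.1) {
  v <- xic$intensity
  n <- length(v)
  a <- xic$apex
  thr <- valley_frac * v[a]
  walk <- function(dir) {
    pos <- a
    repeat {
      nxt <- pos + dir
      if (nxt < 1L || nxt > n) return(list(b = pos, ext = TRUE))
      if (v[nxt] < thr) return(list(b = nxt, ext = FALSE))
      if (v[nxt] > v[pos]) return(list(b = pos, ext = FALSE))
      pos <- nxt
    }
  }
  L <- walk(-1L); R <- walk(1L)
  xic$bounds <- c(L$b, R$b)
  xic$extended_left <- L$ext
  xic$extended_right <- R$ext
  xic$extended <- L$ext || R$ext
  xic$rt_start <- xic$rt[L$b]
  xic$rt_end <- xic$rt[R$b]
  dt <- if (length(xic$rt) > 1) stats::median(diff(xic$rt)) else 1
  xic$area <- sum(xic$intensity[L$b:R$b]) * dt
  xic
}

.slice_xic <- function(xic, lo, hi) {
  sub <- xic
  sub$frames <- xic$frames[lo:hi]
  sub$rt <- xic$rt[lo:hi]
  sub$intensity <- xic$intensity[lo:hi]
  sub$apex <- which.max(sub$intensity)
  sub$apex_intensity <- sub$intensity[sub$apex]
  sub$bounds <- c(1L, hi - lo + 1L)
  sub$rt_start <- sub$rt[1]; sub$rt_end <- sub$rt[length(sub$rt)]
  sub
}

#' Segment an elongated XIC feature
#'
#' Applies Savitzky-Golay smoothing and the rolling Z-score peak detector to
#' the trace of a feature whose boundary search ran off an end; each
#' contiguous above-threshold region becomes a sub-feature, re-bounded with
#' [bound_xic()]. Sub-feature RT ranges are disjoint and lie inside the
#' parent's range; the parent is replaced. Traces too short for the smoother
#' or the detector are returned unchanged.
#'
#' @param xic an `XICFeature`.
#' @param sg_window,sg_order Savitzky-Golay parameters.
#' @param lag,z_threshold,influence Z-score detector parameters.
#' @param valley_frac re-bounding parameter, see [bound_xic()].
#' @return list of `XICFeature` (length >= 1).
#' @export
zscore_segment <- function(xic, sg_window = 5L, sg_order = 2L, lag = 5L,
                           z_threshold = 3, influence = 0.5,
                           valley_frac = 0.1) {
  n <- length(xic$intensity)
  if (n <= sg_window || n <= lag + 1L) return(list(xic))
  sm <- savitzky_golay(xic$intensity, sg_window, sg_order)
  sig <- zscore_peaks(sm, lag, z_threshold, influence)
  r <- rle(sig == 1L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  reg <- which(r$values)
  if (!length(reg)) return(list(bound_xic(xic, valley_frac)))
  # each above-threshold region anchors one sub-feature; slice boundaries sit
  # at the smoothed-trace minima between consecutive regions (and the trace
  # ends outside), so every slice contains its own apex
  nr <- length(reg)
  cuts <- integer(nr - 1L)
  for (k in seq_len(nr - 1L)) {
    lo <- ends[reg[k]]; hi <- starts[reg[k + 1L]]
    cuts[k] <- lo + which.min(sm[lo:hi]) - 1L
  }
  lo_all <- c(1L, cuts + 1L)
  hi_all <- c(cuts, n)
  lapply(seq_len(nr), function(k) bound_xic(.slice_xic(xic, lo_all[k], hi_all[k]),
                                            valley_frac))
}

#' Detect and trace all XIC features of one stream
#'
#' Convenience driver: [detect_peaks()], [trace_xics()], [bound_xic()], and
#' [zscore_segment()] for traces flagged as extended.
#'
#' @param run a `RunFixture`.
#' @param window `"MS1"` or a window id.
#' @param params named list overriding the defaults of
#'   [default_detect_params()] and the tracing/bounding parameters
#'   (`mz_tol`, `im_tol`, `gap_max`, `valley_frac`, `sg_window`, `sg_order`,
#'   `lag`, `z_threshold`, `influence`).
#' @return list of `XICFeature`.
#' @export
stream_features <- function(run, window = "MS1", params = NULL) {
  ms_level <- if (identical(window, "MS1")) 1L else 2L
  p <- modifyList(c(default_detect_params(ms_level),
                    list(mz_tol = 10, im_tol = 0.01, gap_max = 1L,
                         valley_frac = 0.1, sg_window = 5L, sg_order = 2L,
                         lag = 5L, z_threshold = 3, influence = 0.5)),
                  params %||% list())
  peaks <- detect_peaks(run, window, p)
  xics <- trace_xics(peaks, p$mz_tol, p$im_tol, p$gap_max, ms_level,
                     if (identical(window, "MS1")) NA_integer_ else as.integer(window))
  out <- list()
  for (x in xics) {
    x <- bound_xic(x, p$valley_frac)
    if (x$extended) {
      out <- c(out, zscore_segment(x, p$sg_window, p$sg_order, p$lag,
                                   p$z_threshold, p$influence, p$valley_frac))
    } else {
      out <- c(out, list(x))
    }
  }
  out
}
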