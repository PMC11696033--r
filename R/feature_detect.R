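#' @name feature_detect
#' @title Sparse 2D (m/z x 1/K0) feature detection
#' @description
#' One isolation window (or the MS1 stream) of each retention-time frame is
#' binned into a sparse N x W matrix, where N is the m/z range divided by the
#' smallest m/z difference between two signals and W the ion-mobility range
#' divided by the smallest 1/K0 difference (both carried in the fixture
#' meta). Adjacent RT frames are aggregated by summing cell intensities,
#' isolated cells are removed, the matrix is smoothed with a 2D Gaussian
#' filter, local maxima seed separable Gaussian fits, and the fitted centres
#' become the m/z / IM coordinates of 2D peaks.
NULL

#' Default feature-detection parameters
#'
#' MS2 streams use the relaxed neighbour requirement (`min_neighbors` 1
#' instead of 2); everything else is shared between MS levels.
#'
#' @param ms_level 1 or 2.
#' @return named list of detection parameters.
#' @export
default_detect_params <- function(ms_level = 1L) {
  list(
    half_width = 2L,            # RT frames aggregated each side
    radius_bins = c(1L, 1L),    # denoise neighbourhood half-sizes (m/z, IM)
    min_neighbors = if (ms_level == 1L) 2L else 1L,  # relaxed for MS2
    sigma_bins = c(1, 1),       # Gaussian filter sigmas in bins
    truncate = 4,               # kernel truncation in sigmas
    min_intensity = 0,          # seed acceptance floor
    k_sigma = 2,                # signal range half-width in fitted sigmas
    patch_half = c(4L, 4L)      # fitting patch half-sizes in bins
  )
}

.stream_axes <- function(run, window) {
  m <- run$meta
  if (identical(window, "MS1")) {
    list(ms_level = 1L, window_id = NA_integer_,
         mz0 = m$ms1_mz_min, n_mz = as.integer(ceiling((m$ms1_mz_max - m$ms1_mz_min) / m$mz_step)) + 1L,
         im0 = m$im_min, n_im = as.integer(ceiling((m$im_max - m$im_min) / m$im_step)) + 1L,
         mz_step = m$mz_step, im_step = m$im_step)
  } else {
    w <- run$windows[J(as.integer(window)), on = "window_id", nomatch = NULL]
    if (!nrow(w)) stop("unknown window: ", window, call. = FALSE)
    list(ms_level = 2L, window_id = w$window_id,
         mz0 = m$frag_mz_min, n_mz = as.integer(ceiling((m$frag_mz_max - m$frag_mz_min) / m$mz_step)) + 1L,
         im0 = w$im_low, n_im = as.integer(ceiling((w$im_high - w$im_low) / m$im_step)) + 1L,
         mz_step = m$mz_step, im_step = m$im_step)
  }
}

.stream_frames <- function(run, window) {
  if (identical(window, "MS1")) {
    run$frames[ms_level == 1L][order(frame_id)]
  } else {
    fid <- sort(run$segments[window_id == as.integer(window), unique(frame_id)])
    run$frames[J(fid), on = "frame_id"]
  }
}

.new_binned <- function(cells, ax, frame_index, frame_lo, frame_hi,
                        central_frame_id, rt) {
  setorder(cells, i, j)
  structure(list(cells = cells, n_mz = ax$n_mz, n_im = ax$n_im,
                 mz0 = ax$mz0, im0 = ax$im0,
                 mz_step = ax$mz_step, im_step = ax$im_step,
                 ms_level = ax$ms_level, window_id = ax$window_id,
                 frame_index = frame_index, frame_lo = frame_lo,
                 frame_hi = frame_hi, central_frame_id = central_frame_id,
                 rt = rt),
            class = "BinnedMatrix")
}

#' @export
print.BinnedMatrix <- function(x, ...) {
  cat(sprintf("BinnedMatrix %s #%d: %d x %d bins, %d nonzero, rt %.2f s\n",
              if (x$ms_level == 1L) "MS1" else paste0("W", x$window_id),
              x$frame_index, x$n_mz, x$n_im, nrow(x$cells), x$rt))
  invisible(x)
}

#' Convert a BinnedMatrix to a dense base matrix (tests / small inputs only)
#' @param bm a `BinnedMatrix`.
#' @return dense numeric matrix of dimension `n_mz x n_im`.
#' @export
as_dense <- function(bm) {
  m <- matrix(0, bm$n_mz, bm$n_im)
  if (nrow(bm$cells)) m[cbind(bm$cells$i, bm$cells$j)] <- bm$cells$x
  m
}

#' Aggregate adjacent RT frames of one stream into binned matrices
#'
#' Produces one sparse binned matrix per central frame of the stream (the
#' MS1 frames, or the MS2 frames carrying the given window); each cell is
#' the summed intensity of that cell over frames
#' `[c - half_width, c + half_width]`, clipped to the run, so edge frames
#' aggregate the neighbours that exist.
#'
#' @param run a `RunFixture`.
#' @param window `"MS1"` or a window id.
#' @param half_width number of neighbour frames merged on each side (>= 0).
#' @return list of `BinnedMatrix`, one per central frame, in RT order.
#' @export
aggregate_frames <- function(run, window = "MS1", half_width = 2L) {
  stopifnot(half_width >= 0)
  ax <- .stream_axes(run, window)
  fr <- .stream_frames(run, window)
  n <- nrow(fr)
  if (!n) return(list())
  stride <- ax$n_im + 3
  keys <- vals <- vector("list", n)
  for (k in seq_len(n)) {
    fid <- fr$frame_id[k]
    pts <- run$points[J(fid), on = "frame_id", nomatch = NULL]
    if (ax$ms_level == 2L && nrow(pts)) {
      seg <- run$segments[frame_id == fid & window_id == ax$window_id]
      pts <- pts[inv_k0 >= seg$im_low[1] & inv_k0 < seg$im_high[1]]
    }
    if (nrow(pts)) {
      key <- as.numeric(.bin_index(pts$mz, ax$mz0, ax$mz_step)) * stride +
        .bin_index(pts$inv_k0, ax$im0, ax$im_step)
      cc <- key_collapse(key, pts$intensity)
      keys[[k]] <- cc$key; vals[[k]] <- cc$x
    } else {
      keys[[k]] <- numeric(0); vals[[k]] <- numeric(0)
    }
  }
  lapply(seq_len(n), function(c) {
    lo <- max(1L, c - half_width); hi <- min(n, c + half_width)
    cc <- key_collapse(unlist(keys[lo:hi], use.names = FALSE),
                       unlist(vals[lo:hi], use.names = FALSE))
    cells <- data.table(i = as.integer(cc$key %/% stride),
                        j = as.integer(cc$key %% stride), x = cc$x)
    .new_binned(cells, ax, c, fr$frame_id[lo], fr$frame_id[hi],
                fr$frame_id[c], fr$rt_seconds[c])
  })
}

#' Remove cells lacking proximate neighbours
#'
#' Zeroes every cell with fewer than `min_neighbors` nonzero cells in its
#' `(2*dmz+1) x (2*dim+1)` neighbourhood (the cell itself excluded); all
#' other cells are unchanged. Counts are taken on the input matrix in a
#' single pass.
#'
#' @param bm a `BinnedMatrix`.
#' @param radius_bins integer pair `(dmz, dim)`, each >= 1.
#' @param min_neighbors required nonzero neighbours.
#' @return the denoised `BinnedMatrix`.
#' @export
denoise <- function(bm, radius_bins = c(1L, 1L), min_neighbors = 2L) {
  stopifnot(all(radius_bins >= 1))
  if (!nrow(bm$cells)) return(bm)
  cnt <- sparse_neighbor_count(bm$cells$i, bm$cells$j,
                               as.integer(radius_bins[1]),
                               as.integer(radius_bins[2]), bm$n_im)
  bm$cells <- bm$cells[cnt >= min_neighbors]
  bm
}

.gauss_kernel <- function(sigma_bins, truncate) {
  r1 <- max(1L, as.integer(ceiling(truncate * sigma_bins[1])))
  r2 <- max(1L, as.integer(ceiling(truncate * sigma_bins[2])))
  k1 <- dnorm(-r1:r1, sd = sigma_bins[1]); k1 <- k1 / sum(k1)
  k2 <- dnorm(-r2:r2, sd = sigma_bins[2]); k2 <- k2 / sum(k2)
  outer(k1, k2)
}

#' Smooth a binned matrix with a normalized 2D Gaussian kernel
#'
#' Discrete convolution with a separable Gaussian kernel truncated at
#' `truncate` sigmas and normalized to unit mass; out-of-grid kernel mass is
#' reflected back at the edges, so total intensity is conserved.
#'
#' @param bm a `BinnedMatrix`.
#' @param sigma_bins Gaussian sigmas in bins, `(mz, im)`, each > 0.
#' @param truncate kernel truncation radius in sigmas.
#' @return the smoothed `BinnedMatrix`.
#' @export
smooth2d <- function(bm, sigma_bins = c(1, 1), truncate = 4) {
  stopifnot(all(sigma_bins > 0))
  if (!nrow(bm$cells)) return(bm)
  kern <- .gauss_kernel(sigma_bins, truncate)
  out <- sparse_convolve(bm$cells$i, bm$cells$j, bm$cells$x, kern,
                         bm$n_mz, bm$n_im)
  bm$cells <- setorder(as.data.table(out), i, j)
  bm
}

#' Find local-maximum seed cells
#'
#' Cells strictly greater than all 8 neighbours (absent neighbours count as
#' zero) and at least `min_intensity`, ordered by descending value; plateau
#' ties are broken toward the lower (m/z bin, IM bin) cell.
#'
#' @param bm a (smoothed) `BinnedMatrix`.
#' @param min_intensity seed acceptance floor.
#' @return data.table with columns `i`, `j`, `value`, `mz`, `im`.
#' @export
find_seeds <- function(bm, min_intensity = 0) {
  if (!nrow(bm$cells))
    return(data.table(i = integer(), j = integer(), value = numeric(),
                      mz = numeric(), im = numeric()))
  is_max <- sparse_local_maxima(bm$cells$i, bm$cells$j, bm$cells$x, bm$n_im)
  s <- bm$cells[is_max & bm$cells$x >= min_intensity]
  setnames(s, "x", "value")
  s[, mz := .bin_center(i, bm$mz0, bm$mz_step)]
  s[, im := .bin_center(j, bm$im0, bm$im_step)]
  setorder(s, -value, i, j)
  s[]
}

# O(log nnz) sparse cell value lookup on the (i,j)-sorted triplets
.cell_lookup <- function(cells, n_im) {
  stride <- n_im + 3
  key <- cells$i * stride + cells$j  # ascending because cells sorted by (i,j)
  x <- cells$x
  function(qi, qj) {
    qkey <- qi * stride + qj
    pos <- findInterval(qkey, key)
    v <- numeric(length(qkey))
    ok <- pos > 0L
    ok[ok] <- key[pos[ok]] == qkey[ok]
    v[ok] <- x[pos[ok]]
    v
  }
}

# Vectorized separable Gaussian fits along one axis for all seeds at once.
# The profile through the seed row/column is fitted with a weighted
# log-parabola (exact for noiseless Gaussian samples); non-concave or
# under-determined fits fall back to the intensity-weighted centroid.
.fit_axis <- function(lookup, si, sj, ph, along_i) {
  ns <- length(si)
  offs <- -ph:ph
  L <- length(offs)
  QI <- if (along_i) outer(si, offs, `+`) else matrix(si, ns, L)
  QJ <- if (along_i) matrix(sj, ns, L) else outer(sj, offs, `+`)
  V <- matrix(lookup(as.numeric(QI), as.numeric(QJ)), ns, L)
  D <- matrix(offs, ns, L, byrow = TRUE)
  W <- V * V
  Y <- matrix(0, ns, L)
  pos <- V > 0
  Y[pos] <- log(V[pos])
  WD <- W * D; WD2 <- WD * D
  S0 <- rowSums(W); S1 <- rowSums(WD); S2 <- rowSums(WD2)
  S3 <- rowSums(WD2 * D); S4 <- rowSums(WD2 * D * D)
  T0 <- rowSums(W * Y); T1 <- rowSums(WD * Y); T2 <- rowSums(WD2 * Y)
  # Cramer's rule for [S4 S3 S2; S3 S2 S1; S2 S1 S0] (a b c)' = (T2 T1 T0)'
  det3 <- function(a1, a2, a3, b1, b2, b3, c1, c2, c3)
    a1 * (b2 * c3 - b3 * c2) - a2 * (b1 * c3 - b3 * c1) + a3 * (b1 * c2 - b2 * c1)
  Dd <- det3(S4, S3, S2, S3, S2, S1, S2, S1, S0)
  a <- det3(T2, S3, S2, T1, S2, S1, T0, S1, S0) / Dd
  b <- det3(S4, T2, S2, S3, T1, S1, S2, T0, S0) / Dd
  mu_g <- -b / (2 * a)
  sigma_g <- sqrt(pmax(-1 / (2 * a), 1e-12))
  npos <- rowSums(pos)
  ok <- npos >= 3 & is.finite(a) & a < -1e-12 &
    is.finite(mu_g) & abs(mu_g) <= ph + 1
  C0 <- rowSums(V); C1 <- rowSums(V * D); C2 <- rowSums(V * D * D)
  mu_c <- ifelse(C0 > 0, C1 / C0, 0)
  sigma_c <- sqrt(pmax(C2 / pmax(C0, 1e-300) - mu_c^2, 0))
  list(mu = ifelse(ok, mu_g, mu_c),
       sigma = pmin(pmax(ifelse(ok, sigma_g, sigma_c), 0.5), ph),
       ok = ok, V = V)
}

# half-max contiguous region bounds (bin offsets) for fallback ranges
.halfmax_range <- function(v, center_pos) {
  vmax <- v[center_pos]
  lo <- center_pos
  while (lo > 1 && v[lo - 1] >= vmax / 2 && v[lo - 1] > 0) lo <- lo - 1
  hi <- center_pos
  while (hi < length(v) && v[hi + 1] >= vmax / 2 && v[hi + 1] > 0) hi <- hi + 1
  c(lo, hi) - center_pos
}

fit_peaks_batch <- function(bm, seeds, k_sigma = 2, patch_half = c(4L, 4L),
                            min_intensity = 0) {
  if (!nrow(seeds))
    return(data.table(mz = numeric(), im = numeric(), mz_lo = numeric(),
                      mz_hi = numeric(), im_lo = numeric(), im_hi = numeric(),
                      sigma_mz = numeric(), sigma_im = numeric(),
                      amplitude = numeric(), intensity = numeric(),
                      i = integer(), j = integer()))
  lookup <- .cell_lookup(bm$cells, bm$n_im)
  ph1 <- as.integer(patch_half[1]); ph2 <- as.integer(patch_half[2])
  si <- seeds$i; sj <- seeds$j
  ns <- length(si)
  fi <- .fit_axis(lookup, si, sj, ph1, TRUE)
  fj <- .fit_axis(lookup, si, sj, ph2, FALSE)
  mu_i <- si + fi$mu; mu_j <- sj + fj$mu
  lo_i <- pmax(mu_i - k_sigma * fi$sigma, si - ph1)
  hi_i <- pmin(mu_i + k_sigma * fi$sigma, si + ph1)
  lo_j <- pmax(mu_j - k_sigma * fj$sigma, sj - ph2)
  hi_j <- pmin(mu_j + k_sigma * fj$sigma, sj + ph2)
  # fallback ranges from the contiguous above-half-max region
  for (k in which(!fi$ok)) {
    r <- .halfmax_range(fi$V[k, ], ph1 + 1L)
    lo_i[k] <- si[k] + r[1]; hi_i[k] <- si[k] + r[2]
  }
  for (k in which(!fj$ok)) {
    r <- .halfmax_range(fj$V[k, ], ph2 + 1L)
    lo_j[k] <- sj[k] + r[1]; hi_j[k] <- sj[k] + r[2]
  }
  # summed intensity over the integer bin box of each signal range
  bi_lo <- as.integer(floor(lo_i)); bi_hi <- as.integer(ceiling(hi_i))
  bj_lo <- as.integer(floor(lo_j)); bj_hi <- as.integer(ceiling(hi_j))
  doi <- rep(-ph1:ph1, times = 2 * ph2 + 1)
  doj <- rep(-ph2:ph2, each = 2 * ph1 + 1)
  nb <- length(doi)
  BI <- outer(si, rep(1, nb)) + outer(rep(1, ns), doi)
  BJ <- outer(sj, rep(1, nb)) + outer(rep(1, ns), doj)
  VB <- matrix(lookup(as.numeric(BI), as.numeric(BJ)), ns, nb)
  mask <- BI >= bi_lo & BI <= bi_hi & BJ >= bj_lo & BJ <= bj_hi
  intensity <- pmax(rowSums(VB * mask), seeds$value)
  data.table(
    mz = .bin_center(mu_i, bm$mz0, bm$mz_step),
    im = .bin_center(mu_j, bm$im0, bm$im_step),
    mz_lo = .bin_center(lo_i, bm$mz0, bm$mz_step),
    mz_hi = .bin_center(hi_i, bm$mz0, bm$mz_step),
    im_lo = .bin_center(lo_j, bm$im0, bm$im_step),
    im_hi = .bin_center(hi_j, bm$im0, bm$im_step),
    sigma_mz = fi$sigma * bm$mz_step,
    sigma_im = fj$sigma * bm$im_step,
    amplitude = seeds$value, intensity = intensity,
    i = si, j = sj
  )
}

#' Fit a 2D Gaussian peak around one seed
#'
#' Separable 1D Gaussian fits along the seed row and column (weighted
#' log-parabola with moments initialisation; exact on noiseless Gaussian
#' samples). On fit failure the peak falls back to the intensity-weighted
#' centroid of the patch with ranges from the contiguous above-half-max
#' region. The fitted centre is converted to physical m/z and 1/K0 and the
#' signal range set to centre +/- `k_sigma` fitted sigmas, clipped to the
#' patch; the summed intensity of all cells inside the range box is the
#' peak's per-frame intensity.
#'
#' @param bm a (smoothed) `BinnedMatrix`.
#' @param seed a one-row subset of [find_seeds()] output (or a list with
#'   `i`, `j`).
#' @param k_sigma range half-width in fitted sigmas.
#' @param patch_half fitting patch half-sizes in bins.
#' @param min_intensity the patch must contain a cell at or above this value.
#' @return one-row data.table: `mz`, `im`, `mz_lo`, `mz_hi`, `im_lo`,
#'   `im_hi`, `sigma_mz`, `sigma_im`, `amplitude`, `intensity`.
#' @export
fit_peak <- function(bm, seed, k_sigma = 2, patch_half = c(4L, 4L),
                     min_intensity = 0) {
  seed <- as.list(seed)
  cells <- bm$cells
  patch <- cells[i >= seed$i - patch_half[1] & i <= seed$i + patch_half[1] &
                   j >= seed$j - patch_half[2] & j <= seed$j + patch_half[2]]
  if (!nrow(patch) || max(patch$x) < min_intensity)
    stop("degenerate peak: fitting patch entirely below min_intensity",
         call. = FALSE)
  sv <- cells[J(seed$i, seed$j), on = .(i, j), x]
  fit_peaks_batch(bm, data.table(i = seed$i, j = seed$j,
                                 value = if (is.na(sv)) 0 else sv),
                  k_sigma, patch_half, min_intensity)
}

#' Detect 2D peaks for every merged frame of one stream
#'
#' Runs the full per-stream chain: [aggregate_frames()], [denoise()],
#' [smooth2d()], [find_seeds()] and batch Gaussian fitting.
#'
#' @param run a `RunFixture`.
#' @param window `"MS1"` or a window id.
#' @param params parameter list as from [default_detect_params()]; MS2
#'   streams default to the relaxed neighbour requirement.
#' @return data.table of peaks with merged-frame index, RT and the
#'   [fit_peak()] columns.
#' @export
detect_peaks <- function(run, window = "MS1", params = NULL) {
  ms_level <- if (identical(window, "MS1")) 1L else 2L
  p <- modifyList(default_detect_params(ms_level), params %||% list())
  mats <- aggregate_frames(run, window, p$half_width)
  rbindlist(lapply(mats, function(bm) {
    bm <- denoise(bm, p$radius_bins, p$min_neighbors)
    bm <- smooth2d(bm, p$sigma_bins, p$truncate)
    seeds <- find_seeds(bm, p$min_intensity)
    if (!nrow(seeds)) return(NULL)
    pk <- fit_peaks_batch(bm, seeds, p$k_sigma, p$patch_half, p$min_intensity)
    pk[, `:=`(frame_index = bm$frame_index, frame_id = bm$central_frame_id,
              rt = bm$rt)]
    pk
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
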