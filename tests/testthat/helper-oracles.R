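# Independent brute-force oracles for the dual-route acceptance checks.
# These deliberately share no code with the package implementations: dense
# double loops instead of sparse hash maps, textbook formulas instead of
# stats shortcuts.

# dense scatter convolution with edge reflection (same edge semantics as the
# sparse path, but dense, loop-based and gather-free)
oracle_convolve <- function(M, kernel) {
  ni <- nrow(M); nj <- ncol(M)
  ri <- (nrow(kernel) - 1) / 2; rj <- (ncol(kernel) - 1) / 2
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, ni, nj)
  for (i in seq_len(ni)) for (j in seq_len(nj)) {
    if (M[i, j] == 0) next
    for (a in -ri:ri) for (b in -rj:rj) {
      ii <- reflect(i + a, ni); jj <- reflect(j + b, nj)
      out[ii, jj] <- out[ii, jj] + M[i, j] * kernel[a + ri + 1, b + rj + 1]
    }
  }
  out
}

# exhaustive neighbourhood count of nonzero cells, excluding self
oracle_neighbor_count <- function(M, di, dj) {
  ni <- nrow(M); nj <- ncol(M)
  out <- matrix(0L, ni, nj)
  for (i in seq_len(ni)) for (j in seq_len(nj)) {
    cnt <- 0L
    for (a in max(1, i - di):min(ni, i + di))
      for (b in max(1, j - dj):min(nj, j + dj))
        if (!(a == i && b == j) && M[a, b] != 0) cnt <- cnt + 1L
    out[i, j] <- cnt
  }
  out
}

# exhaustive 8-neighbourhood local-maxima scan with the lower-(i,j) plateau rule
oracle_local_maxima <- function(M) {
  ni <- nrow(M); nj <- ncol(M)
  res <- NULL
  for (i in seq_len(ni)) for (j in seq_len(nj)) {
    if (M[i, j] <= 0) next
    is_max <- TRUE
    for (a in -1:1) for (b in -1:1) {
      if (a == 0 && b == 0) next
      ii <- i + a; jj <- j + b
      if (ii < 1 || ii > ni || jj < 1 || jj > nj) next
      if (M[i, j] < M[ii, jj] ||
          (M[i, j] == M[ii, jj] && (a < 0 || (a == 0 && b < 0))))
        is_max <- FALSE
    }
    if (is_max) res <- rbind(res, c(i, j, M[i, j]))
  }
  res
}

# textbook Pearson correlation, sum formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# step-by-step transliteration of the published rolling Z-score detector
oracle_zscore <- function(y, lag, threshold, influence) {
  n <- length(y)
  signals <- integer(n)
  filteredY <- y
  avgFilter <- stdFilter <- rep(NA_real_, n)
  avgFilter[lag] <- mean(y[1:lag])
  stdFilter[lag] <- sqrt(sum((y[1:lag] - mean(y[1:lag]))^2) / (lag - 1))
  if (n <= lag + 1) return(signals)
  for (i in (lag + 1):n) {
    if (!is.na(stdFilter[i - 1]) && stdFilter[i - 1] > 0 &&
        abs(y[i] - avgFilter[i - 1]) > threshold * stdFilter[i - 1]) {
      signals[i] <- if (y[i] > avgFilter[i - 1]) 1L else -1L
      filteredY[i] <- influence * y[i] + (1 - influence) * filteredY[i - 1]
    } else {
      signals[i] <- 0L
      filteredY[i] <- y[i]
    }
    w <- filteredY[(i - lag + 1):i]
    avgFilter[i] <- mean(w)
    stdFilter[i] <- sqrt(sum((w - mean(w))^2) / (lag - 1))
  }
  signals
}

# naive atom-by-atom isotope-distribution convolution (polynomial expansion
# one atom at a time; the package uses truncated exponentiation-by-squaring)
oracle_envelope <- function(mono_mass, n) {
  iso <- list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0.0001)
  )
  mono_elem <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                 O = 15.9949146221, S = 31.97207069)
  avg <- c(C = 4.9384, H = 7.7583, N = 1.3577, O = 1.4773, S = 0.0417)
  counts <- round(avg * mono_mass / 111.1254)
  counts["H"] <- 0
  counts["H"] <- max(0, round((mono_mass - sum(counts * mono_elem)) /
                                mono_elem["H"]))
  dist <- 1
  for (el in names(iso)) {
    for (k in seq_len(counts[el])) {
      d <- iso[[el]]
      new <- numeric(length(dist) + length(d) - 1)
      for (a in seq_along(dist)) for (b in seq_along(d))
        new[a + b - 1] <- new[a + b - 1] + dist[a] * d[b]
      dist <- new[seq_len(min(length(new), n + 6))]  # keep tails bounded
    }
  }
  env <- dist[seq_len(n)]
  env / max(env)
}

# brute-force pseudo-MS/MS assembly: plain O(P x F) double loop over every
# precursor/fragment pair with its own window lookup and textbook Pearson
oracle_assemble <- function(precursors, ms2_features, windows, cfg) {
  out <- list()
  for (pid in seq_along(precursors)) {
    pre <- precursors[[pid]]
    if (cfg$mass_defect_filter &&
        !mass_defect_pass((pre$mono_mz - 1.00727646688) * pre$charges[1])) next
    wid <- NA_integer_
    for (k in seq_len(nrow(windows))) {
      if (windows$mz_low[k] <= pre$mono_mz && windows$mz_high[k] > pre$mono_mz &&
          windows$im_low[k] <= pre$apex_im && windows$im_high[k] > pre$apex_im) {
        wid <- windows$window_id[k]
        break
      }
    }
    if (is.na(wid)) next
    frags <- ms2_features[[as.character(wid)]]
    if (is.null(frags)) next
    mono <- pre$members[[1]]
    grid <- mono$frames[mono$bounds[1]:mono$bounds[2]]
    pv <- savitzky_golay(mono$intensity[mono$bounds[1]:mono$bounds[2]])
    keep <- NULL
    for (k in seq_along(frags)) {
      fg <- frags[[k]]
      if (abs(fg$rt[fg$apex] - pre$apex_rt) > cfg$delta_apex_rt) next
      if (abs(fg$im - pre$apex_im) > cfg$delta_apex_im) next
      if (length(grid) < 3 || length(intersect(grid, fg$frames)) < 3) {
        r <- 0
      } else {
        fv <- numeric(length(grid))
        for (q in seq_along(fg$frames)) {
          w <- which(grid == fg$frames[q])
          if (length(w)) fv[w] <- fg$intensity[q]
        }
        r <- if (length(unique(pv)) == 1 || length(unique(fv)) == 1) 0 else
          oracle_pearson(pv, fv)
      }
      if (r >= cfg$corr_threshold)
        keep <- rbind(keep, data.frame(mz = fg$mz, intensity = fg$apex_intensity,
                                       corr = r))
    }
    if (is.null(keep)) next
    if (nrow(keep) > cfg$rf_max)
      keep <- keep[order(-keep$intensity, keep$mz), ][seq_len(cfg$rf_max), ]
    if (nrow(keep) < cfg$min_fragments) next
    keep <- keep[order(keep$mz), ]
    for (z in pre$charges)
      out[[length(out) + 1L]] <- list(precursor_id = pid, charge = z,
                                      fragments = keep)
  }
  out
}

# handmade XICFeature constructor for synthetic-trace tests
make_xic <- function(intensity, rt = seq_along(intensity) * 1.0,
                     frames = seq_along(intensity), mz = 500, im = 1.0,
                     ms_level = 1L, window_id = NA_integer_) {
  x <- structure(list(
    mz = mz, im = im, mz_range = c(mz - 0.01, mz + 0.01),
    im_range = c(im - 0.005, im + 0.005),
    frames = frames, rt = rt, intensity = intensity,
    apex = which.max(intensity), apex_intensity = max(intensity),
    ms_level = ms_level, window_id = window_id,
    bounds = c(1L, length(intensity)), rt_start = rt[1],
    rt_end = rt[length(rt)], extended = FALSE, extended_left = FALSE,
    extended_right = FALSE, area = 0), class = "XICFeature")
  x
}

# small dense BinnedMatrix for oracle comparisons
make_bm <- function(M, mz0 = 400, im0 = 1.0, mz_step = 0.01, im_step = 0.001) {
  nz <- which(M != 0, arr.ind = TRUE)
  cells <- data.table::data.table(i = as.integer(nz[, 1]),
                                  j = as.integer(nz[, 2]),
                                  x = M[nz])
  data.table::setorder(cells, i, j)
  structure(list(cells = cells, n_mz = nrow(M), n_im = ncol(M),
                 mz0 = mz0, im0 = im0, mz_step = mz_step, im_step = im_step,
                 ms_level = 1L, window_id = NA_integer_, frame_index = 1L,
                 frame_lo = 1L, frame_hi = 1L, central_frame_id = 1L, rt = 0),
            class = "BinnedMatrix")
}

# small, fast simulator configuration for module-level tests
small_sim <- function(seed, n_species = 5L, ...) {
  args <- utils::modifyList(
    list(n_species = n_species, seed = seed, gradient_s = 50,
         noise_ms1 = 40L, noise_ms2 = 30L),
    list(...))
  do.call(sim_config, args)
}
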