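test_that("Savitzky-Golay smoothing reproduces the classic weights", {
  # classic window-5 order-2 interior weights: (-3, 12, 17, 12, -3)/35
  y <- c(0, 0, 1, 0, 0, 0, 0)
  sm <- savitzky_golay(y, 5L, 2L)
  expect_equal(sm[3:5] * 35, c(17, 12, -3) * c(1, 1, 1), tolerance = 1e-12)
  # quadratic signals are reproduced exactly everywhere, including edges
  x <- 1:20
  q <- 3 + 0.5 * x - 0.25 * x^2
  expect_equal(savitzky_golay(q, 5L, 2L), q, tolerance = 1e-10)
  expect_equal(savitzky_golay(q, 7L, 3L), q, tolerance = 1e-9)
  # shorter than the window: unchanged
  expect_identical(savitzky_golay(c(1, 2, 3), 5L, 2L), c(1, 2, 3))
  expect_error(savitzky_golay(1:10, 4L, 2L), "odd")
})

test_that("zscore detector equals the reference transliteration", {
  set.seed(12)
  for (rep in 1:5) {
    y <- cumsum(rnorm(80)) + 10 * (runif(80) < 0.05)
    for (lag in c(5L, 10L)) for (thr in c(2.5, 3.5)) {
      expect_identical(zscore_peaks(y, lag, thr, 0.5),
                       oracle_zscore(y, lag, thr, 0.5))
    }
  }
  # fixed numeric trace: frozen expectation from the reference algorithm
  y <- c(1, 1, 1.1, 1, 0.9, 1, 1, 1.1, 1, 0.9, 1, 1.1, 1, 1, 0.9, 1, 1, 1.1,
         1, 1, 9, 10, 9, 1, 1, 1, 1, 1, 1)
  expect_identical(zscore_peaks(y, 5L, 3, 0.5), oracle_zscore(y, 5L, 3, 0.5))
  # the third burst sample is absorbed by the influence-damped statistics
  expect_equal(which(zscore_peaks(y, 5L, 3, 0.5) == 1L), 21:22)
})

test_that("trace linking follows tolerances, gaps and permutation invariance", {
  mkpeaks <- function(fidx, mz, im, inten) data.table::data.table(
    frame_index = fidx, rt = fidx * 1.0, mz = mz, im = im,
    mz_lo = mz - 0.01, mz_hi = mz + 0.01, im_lo = im - 0.005,
    im_hi = im + 0.005, intensity = inten, amplitude = inten,
    sigma_mz = 0.005, sigma_im = 0.002)
  expect_identical(trace_xics(NULL), list())
  # one species over 7 frames
  p <- mkpeaks(1:7, rep(500.0, 7), rep(1.0, 7), c(1, 4, 9, 20, 8, 3, 1))
  xs <- trace_xics(p)
  expect_length(xs, 1L)
  expect_equal(xs[[1]]$frames, 1:7)
  expect_equal(xs[[1]]$apex, 4L)
  expect_equal(xs[[1]]$apex_intensity, 20)
  expect_equal(xs[[1]]$mz, 500.0)
  # two species 10 ppm apart with a 5 ppm tolerance stay disjoint
  p2 <- rbind(mkpeaks(1:5, rep(600, 5), rep(1, 5), rep(10, 5)),
              mkpeaks(1:5, rep(600 * (1 + 10e-6), 5), rep(1, 5), rep(20, 5)))
  xs2 <- trace_xics(p2, mz_tol = 5)
  expect_length(xs2, 2L)
  expect_setequal(vapply(xs2, function(x) length(x$frames), integer(1)), c(5L, 5L))
  # at 20 ppm both pairs are within tolerance, but one-to-one assignment by
  # smallest m/z residual still keeps the co-eluting ions separate
  expect_length(trace_xics(p2, mz_tol = 20), 2L)
  # a single-frame gap is bridged (gap_max 1), a 2-frame gap terminates
  p3 <- mkpeaks(c(1, 2, 4, 5), rep(700, 4), rep(1, 4), c(5, 9, 8, 4))
  xs3 <- trace_xics(p3, gap_max = 1L)
  expect_length(xs3, 1L)
  expect_equal(xs3[[1]]$frames, 1:5)  # gap interpolated, frames consecutive
  expect_equal(xs3[[1]]$intensity[3], (9 + 8) / 2)
  p4 <- mkpeaks(c(1, 2, 5, 6), rep(700, 4), rep(1, 4), c(5, 9, 8, 4))
  expect_length(trace_xics(p4, gap_max = 1L), 2L)
  # permutation of peaks within frames does not change the result
  set.seed(3)
  p5 <- rbind(mkpeaks(1:6, 500 + 0.0001 * (1:6), rep(1, 6), c(2, 6, 9, 7, 3, 1)),
              mkpeaks(1:6, rep(500.3, 6), rep(1.02, 6), c(1, 5, 11, 6, 2, 1)),
              mkpeaks(2:5, rep(810.5, 4), rep(0.9, 4), c(3, 8, 6, 2)))
  perm <- p5[sample(nrow(p5)), ]
  key <- function(xs) sort(vapply(xs, function(x)
    sprintf("%.6f|%.4f|%d|%d", x$mz, x$im, x$frames[1], length(x$frames)),
    character(1)))
  expect_identical(key(trace_xics(p5)), key(trace_xics(perm)))
})

test_that("boundary walk implements the valley rule", {
  b <- bound_xic(make_xic(c(1, 5, 20, 5, 1)), 0.1)
  expect_equal(b$bounds, c(1L, 5L))
  expect_false(b$extended)
  b2 <- bound_xic(make_xic(c(1, 2, 3, 4)), 0.1)
  expect_true(b2$extended_right)
  b3 <- bound_xic(make_xic(c(1, 10, 2, 9, 1)), 0.1)
  expect_equal(b3$bounds[2], 3L)  # the valley next to the apex
  # area covers only the bounded region
  expect_equal(b$area, sum(c(1, 5, 20, 5, 1)) * 1.0)
})

test_that("zscore segmentation splits elongated peaks and preserves area", {
  # flat trace: no segmentation
  flat <- bound_xic(make_xic(rep(5, 30) + 0.01 * sin(1:30)))
  segs <- zscore_segment(flat)
  expect_length(segs, 1L)
  # two planted Gaussians 30 s apart
  rt <- (1:70) * 1.05
  y <- 200 * exp(-(rt - 20)^2 / 18) + 150 * exp(-(rt - 50)^2 / 18) + 20
  parent <- make_xic(y, rt = rt)
  parent$extended <- TRUE
  subs <- zscore_segment(parent)
  expect_length(subs, 2L)
  apexes <- vapply(subs, function(s) s$rt[s$apex], numeric(1))
  expect_lt(abs(apexes[1] - 20), 1.05 + 1e-9)
  expect_lt(abs(apexes[2] - 50), 1.05 + 1e-9)
  # disjoint sub-ranges within the parent, areas bounded by the full parent
  # trace integral (the extended parent spans the whole elongated region)
  expect_true(subs[[1]]$frames[length(subs[[1]]$frames)] < subs[[2]]$frames[1])
  expect_lte(sum(vapply(subs, `[[`, numeric(1), "area")),
             sum(parent$intensity) * 1.05 + 1e-9)
  # too-short traces are returned unchanged
  short <- make_xic(c(1, 2, 3))
  expect_length(zscore_segment(short), 1L)
})

test_that("planted species yield XIC features at the true apex (5 seeds, mini runs)", {
  # scaled-down version of the 20-seed recall property; the full-size run
  # is exercised in the acceptance suite
  found <- 0L; total <- 0L
  for (seed in 1:5) {
    cfg <- sim_config(n_species = 5L, seed = 100 + seed, gradient_s = 40,
                      noise_ms1 = 40L, noise_ms2 = 0L,
                      n_frag_range = c(0L, 0L), decoy_frac = 0)
    sim <- simulate_run(cfg)
    xs <- stream_features(sim$run, "MS1")
    rts <- vapply(xs, function(x) x$rt[x$apex], numeric(1))
    mzs <- vapply(xs, function(x) x$mz, numeric(1))
    for (k in seq_len(nrow(sim$species))) {
      s <- sim$species[k, ]
      total <- total + 1L
      if (any(abs(mzs - s$mz) <= 10e-6 * s$mz & abs(rts - s$rt_apex) <= 1.05 * 1.5))
        found <- found + 1L
    }
  }
  expect_gte(found / total, 0.95)
})
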