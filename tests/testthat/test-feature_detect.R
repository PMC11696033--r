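test_that("frame aggregation sums exactly the contributing raw points", {
  sim <- simulate_run(small_sim(17, n_species = 3L))
  run <- sim$run
  hw <- 2L
  mats <- aggregate_frames(run, "MS1", hw)
  ms1 <- run$frames[run$frames$ms_level == 1L, ]
  # binning conserves intensity: whole-stream sum equals raw point sum
  pts1 <- run$points[run$points$frame_id %in% ms1$frame_id, ]
  expect_equal(sum(aggregate_frames(run, "MS1", 0L)[[10]]$cells$x),
               sum(pts1$intensity[pts1$frame_id == ms1$frame_id[10]]))
  # brute-force re-summation for a few central frames
  m <- run$meta
  for (c in c(1L, 2L, 10L, nrow(ms1))) {
    lo <- max(1L, c - hw); hi <- min(nrow(ms1), c + hw)
    pts <- run$points[run$points$frame_id %in% ms1$frame_id[lo:hi], ]
    i <- floor((pts$mz - m$ms1_mz_min) / m$mz_step + 0.5) + 1
    j <- floor((pts$inv_k0 - m$im_min) / m$im_step + 0.5) + 1
    agg <- rowsum(pts$intensity, paste(i, j, sep = "_"))
    got <- mats[[c]]$cells
    expect_equal(nrow(got), nrow(agg))
    expect_equal(got$x, unname(agg[paste(got$i, got$j, sep = "_"), 1]))
  }
  # half_width = 1 on constant frames: middle equals 3x the single frame
  pts_c <- data.table::data.table(
    frame_id = rep(c(1L, 4L, 7L), each = 2),
    mz = rep(c(500.00, 500.50), 3), inv_k0 = rep(c(1.0, 1.0), 3),
    intensity = rep(c(10, 20), 3))
  data.table::setorder(pts_c, frame_id, inv_k0, mz)
  runc <- run_fixture(
    meta = list(run_label = "c", mz_step = 0.01, im_step = 0.001,
                ms1_mz_min = 400, ms1_mz_max = 1200, frag_mz_min = 200,
                frag_mz_max = 1700, im_min = 0.6, im_max = 1.5),
    windows = run$windows,
    frames = data.table::data.table(frame_id = 1:9,
                                    rt_seconds = (1:9) * 0.35,
                                    ms_level = rep(c(1L, 2L, 2L), 3)),
    segments = run$segments[run$segments$frame_id %in%
                              run$frames$frame_id[run$frames$ms_level == 2L][1:6], ][
                                , frame_id := rep(c(2L, 3L, 5L, 6L, 8L, 9L),
                                                  each = 2)],
    points = pts_c)
  mid <- aggregate_frames(runc, "MS1", 1L)[[2]]
  one <- aggregate_frames(runc, "MS1", 0L)[[1]]
  expect_equal(mid$cells$x, 3 * one$cells$x)
  expect_error(aggregate_frames(run, 99L), "unknown window")
})

test_that("denoise equals the exhaustive neighbourhood-count oracle", {
  set.seed(5)
  for (rep in 1:5) {
    M <- matrix(0, 50, 50)
    nz <- sample(2500, 150)
    M[nz] <- runif(150, 1, 100)
    bm <- make_bm(M)
    for (min_nb in c(1L, 2L, 4L)) {
      got <- as_dense(denoise(bm, c(1L, 1L), min_nb))
      cnt <- oracle_neighbor_count(M, 1L, 1L)
      expected <- M
      expected[M != 0 & cnt < min_nb] <- 0
      expect_identical(got, expected)
    }
  }
  # isolated cell is removed; fully dense block is unchanged
  M1 <- matrix(0, 10, 10); M1[5, 5] <- 7
  expect_equal(sum(as_dense(denoise(make_bm(M1), c(1L, 1L), 1L))), 0)
  M2 <- matrix(1, 10, 10)
  expect_identical(as_dense(denoise(make_bm(M2), c(1L, 1L), 2L)), M2)
  # idempotence at the MS2 default (min_neighbors = 1): mutual neighbours
  # always survive a second pass
  set.seed(6)
  M <- matrix(0, 40, 40); M[sample(1600, 200)] <- 1
  d1 <- denoise(make_bm(M), c(1L, 1L), 1L)
  d2 <- denoise(d1, c(1L, 1L), 1L)
  expect_identical(as_dense(d1), as_dense(d2))
})

test_that("smooth2d equals the dense double-loop convolution oracle", {
  set.seed(7)
  for (rep in 1:3) {
    M <- matrix(0, 40, 30)
    M[sample(1200, 80)] <- runif(80, 1, 50)
    bm <- make_bm(M)
    sm <- smooth2d(bm, c(1, 1), truncate = 4)
    kern <- diadeconv:::.gauss_kernel(c(1, 1), 4)
    expect_equal(as_dense(sm), oracle_convolve(M, kern), tolerance = 1e-10)
    # total intensity is conserved
    expect_equal(sum(sm$cells$x), sum(M), tolerance = 1e-9)
  }
  # unit impulse at an interior cell reproduces the kernel
  M <- matrix(0, 21, 21); M[11, 11] <- 1
  sm <- as_dense(smooth2d(make_bm(M), c(1, 1), 4))
  kern <- diadeconv:::.gauss_kernel(c(1, 1), 4)
  expect_equal(sm[7:15, 7:15], kern, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  # constant matrix unchanged in the interior
  M <- matrix(5, 15, 15)
  sm <- as_dense(smooth2d(make_bm(M), c(1, 1), 4))
  expect_equal(sm[8, 8], 5, tolerance = 1e-12)
})

test_that("find_seeds equals the exhaustive 8-neighbourhood scan", {
  set.seed(8)
  for (rep in 1:5) {
    M <- matrix(0, 30, 30)
    M[sample(900, 120)] <- sample(c(1, 2, 2, 5, 10), 120, replace = TRUE)
    bm <- make_bm(M)
    got <- find_seeds(bm)
    expected <- oracle_local_maxima(M)
    expect_equal(nrow(got), NROW(expected))
    if (NROW(expected)) {
      eo <- expected[order(-expected[, 3], expected[, 1], expected[, 2]), ,
                     drop = FALSE]
      expect_equal(got$i, as.integer(eo[, 1]))
      expect_equal(got$j, as.integer(eo[, 2]))
      expect_equal(got$value, eo[, 3])
    }
  }
  expect_equal(nrow(find_seeds(make_bm(matrix(0, 5, 5)))), 0L)
  # planted Gaussian yields exactly one seed at its apex cell
  g <- outer(dnorm(-10:10, sd = 2), dnorm(-8:8, sd = 1.5))
  s <- find_seeds(make_bm(g))
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$i, s$j), c(11L, 9L))
})

test_that("fit_peak recovers planted Gaussian centres and falls back cleanly", {
  # noiseless sampled Gaussian at off-centre physical coordinates
  mz0 <- 500; im0 <- 1.0; mz_step <- 0.01; im_step <- 0.001
  true_mz <- 500.250; true_im <- 1.020
  i_axis <- mz0 + (0:60) * mz_step
  j_axis <- im0 + (0:40) * im_step
  M <- outer(exp(-(i_axis - true_mz)^2 / (2 * 0.02^2)),
             exp(-(j_axis - true_im)^2 / (2 * 0.003^2))) * 1000
  M[M < 1e-6] <- 0
  bm <- make_bm(M, mz0 = mz0, im0 = im0, mz_step = mz_step, im_step = im_step)
  seed <- find_seeds(bm)[1]
  pk <- fit_peak(bm, seed)
  expect_lt(abs(pk$mz - true_mz), 1e-3)
  expect_lt(abs(pk$im - true_im), 1e-4)
  expect_true(pk$mz_lo <= pk$mz && pk$mz < pk$mz_hi)
  expect_true(pk$im_lo <= pk$im && pk$im < pk$im_hi)
  expect_gte(pk$intensity, pk$amplitude)
  expect_gt(pk$sigma_mz, 0); expect_gt(pk$sigma_im, 0)
  # perfectly symmetric peak centred on a bin centre
  g <- outer(dnorm(-5:5, sd = 1.2), dnorm(-5:5, sd = 1.2)) * 100
  bm2 <- make_bm(g, mz0 = 600, im0 = 1.1)
  pk2 <- fit_peak(bm2, list(i = 6L, j = 6L))
  expect_equal(pk2$mz, 600 + 5 * 0.01, tolerance = 1e-9)
  expect_equal(pk2$im, 1.1 + 5 * 0.001, tolerance = 1e-9)
  # single nonzero cell: centroid fallback returns the cell's coordinates
  M1 <- matrix(0, 11, 11); M1[6, 6] <- 42
  pk3 <- fit_peak(make_bm(M1), list(i = 6L, j = 6L))
  expect_equal(pk3$mz, 400 + 5 * 0.01)
  expect_equal(pk3$im, 1.0 + 5 * 0.001)
  # degenerate patch
  expect_error(fit_peak(make_bm(M1), list(i = 6L, j = 6L),
                        min_intensity = 100), "degenerate")
})

test_that("one seed per planted species per merged frame within its RT range", {
  # scaled to MS1-only mini-runs; 20 simulator seeds as stated
  bad <- 0L; total <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(n_species = 4L, seed = seed, gradient_s = 30,
                      noise_ms1 = 40L, noise_ms2 = 0L,
                      n_frag_range = c(0L, 0L), decoy_frac = 0)
    sim <- simulate_run(cfg)
    mats <- aggregate_frames(sim$run, "MS1", 2L)
    ms1_rt <- sim$run$frames$rt_seconds[sim$run$frames$ms_level == 1L]
    for (k in seq_len(nrow(sim$species))) {
      s <- sim$species[k, ]
      mid_frames <- which(abs(ms1_rt - s$rt_apex) <= 1.5 * s$rt_sigma)
      for (c in mid_frames) {
        bm <- smooth2d(denoise(mats[[c]], c(1L, 1L), 2L), c(1, 1), 4)
        seeds <- find_seeds(bm)
        near <- seeds[abs(seeds$mz - s$mz) < 0.02 & abs(seeds$im - s$im_apex) < 0.005, ]
        total <- total + 1L
        if (nrow(near) != 1L) bad <- bad + 1L
      }
    }
  }
  expect_lte(bad / total, 0.001)
})
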