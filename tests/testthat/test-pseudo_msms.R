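test_that("mass defect band accepts tryptic-like and rejects off-band masses", {
  expect_true(all(mass_defect_pass(c(500.1, 1500.01), enabled = FALSE)))
  expect_true(mass_defect_pass(1500.786))   # tryptic-like fractional mass
  expect_false(mass_defect_pass(1500.010))  # far below the band
  # band evaluated numerically: centre 0.000507*m mod 1, widening half-width
  m <- 2000
  centre <- (0.000507 * m) %% 1
  hw <- 0.15 + 0.001 * m / 100
  expect_true(mass_defect_pass(floor(m) + centre + hw - 1e-6))
  expect_false(mass_defect_pass(floor(m) + centre + hw + 0.02))
  # circular distance: fractional parts wrap around 1
  expect_true(mass_defect_pass(3000 + ((0.000507 * 3000) %% 1)))
})

test_that("xic_pearson matches the textbook formula and sentinels", {
  # the precursor trace is smoothed before correlating; a quadratic bell is
  # invariant under Savitzky-Golay order 2, so identity/negation are exact
  q <- 25 - (seq(1, 5) - 3)^2
  p <- bound_xic(make_xic(q), 0.0)
  expect_equal(xic_pearson(p, make_xic(q)), 1.0, tolerance = 1e-12)
  expect_equal(xic_pearson(p, make_xic(2 * mean(q) - q)), -1.0,
               tolerance = 1e-12)
  p <- bound_xic(make_xic(c(1, 4, 9, 4, 1)), 0.0)
  # fixed vectors: equal to the oracle on the smoothed/raw pair
  f <- make_xic(c(0, 2, 10, 3, 0) + 1e-12)
  got <- xic_pearson(p, f)
  pv <- savitzky_golay(p$intensity[p$bounds[1]:p$bounds[2]], 5L, 2L)
  expect_equal(got, oracle_pearson(pv, f$intensity), tolerance = 1e-12)
  # insufficient overlap and zero variance give the 0 sentinel
  short <- make_xic(c(5, 6), frames = 1:2)
  expect_equal(xic_pearson(bound_xic(short, 0), make_xic(c(1, 2, 3))), 0)
  far <- make_xic(c(1, 5, 1), frames = 101:103)
  expect_equal(xic_pearson(p, far), 0)
  expect_equal(xic_pearson(p, make_xic(rep(3, 5))), 0)
})

test_that("correlation threshold is a sharp boundary at the default 0.3", {
  fx <- .assembly_fixture()
  f29 <- .frag_with_corr(fx$pre$members[[1]], 0.29, mz = 300)
  f31 <- .frag_with_corr(fx$pre$members[[1]], 0.31, mz = 310)
  fill <- lapply(1:4, function(k)
    .frag_with_corr(fx$pre$members[[1]], 0.95, mz = 400 + 10 * k))
  cfg <- assembly_config(min_fragments = 1L)
  sp <- assemble_spectra(list(fx$pre), list("1" = c(list(f29, f31), fill)),
                         fx$windows, cfg)
  expect_length(sp, 1L)
  expect_false(300 %in% sp[[1]]$fragments$mz)  # r = 0.29 excluded
  expect_true(310 %in% sp[[1]]$fragments$mz)   # r = 0.31 included
  # fragments are sorted by ascending m/z and all pass the threshold
  expect_identical(sp[[1]]$fragments$mz, sort(sp[[1]]$fragments$mz))
  expect_true(all(sp[[1]]$fragments$corr >= 0.3))
})

test_that("600 passing candidates are cut to the 500 most intense", {
  fx <- .assembly_fixture()
  frags <- lapply(1:600, function(k)
    .frag_with_corr(fx$pre$members[[1]], 0.9, mz = 200 + k * 0.5,
                    intensity = 1000 + k))
  sp <- assemble_spectra(list(fx$pre), list("1" = frags), fx$windows,
                         assembly_config())
  expect_length(sp, 1L)
  expect_equal(nrow(sp[[1]]$fragments), 500L)
  # exactly the 500 largest by apex intensity survive (k = 101..600)
  expect_setequal(sp[[1]]$fragments$intensity, 1000 + 101:600)
})

test_that("tolerances, min_fragments, charge duplication and window routing", {
  fx <- .assembly_fixture()
  mk <- function(mz, drt = 0, dim = 0)
    make_xic(fx$pre$members[[1]]$intensity, rt = fx$grid_rt + drt,
             frames = 1:11, mz = mz, im = 0.8 + dim, ms_level = 2L)
  good <- lapply(1:5, function(k) mk(250 + k))
  off_rt <- mk(300, drt = 4)    # apex outside delta_apex_rt = 3
  off_im <- mk(310, dim = 0.05) # outside delta_apex_im = 0.02
  sp <- assemble_spectra(list(fx$pre),
                         list("1" = c(good, list(off_rt, off_im))),
                         fx$windows, assembly_config())
  expect_length(sp, 1L)
  expect_setequal(sp[[1]]$fragments$mz, 250 + 1:5)
  # min_fragments drops sparse spectra
  sp2 <- assemble_spectra(list(fx$pre), list("1" = good[1:3]), fx$windows,
                          assembly_config(min_fragments = 4L))
  expect_length(sp2, 0L)
  # ambiguous charges: one spectrum per charge with a shared fragment list
  pre2 <- fx$pre
  pre2$charges <- c(2L, 3L)
  sp3 <- assemble_spectra(list(pre2), list("1" = good), fx$windows,
                          assembly_config())
  expect_length(sp3, 2L)
  expect_identical(sp3[[1]]$fragments, sp3[[2]]$fragments)
  expect_setequal(vapply(sp3, `[[`, integer(1), "charge"), c(2L, 3L))
  # a precursor outside every window is skipped, not an error
  pre3 <- fx$pre
  pre3$mono_mz <- 900
  expect_length(assemble_spectra(list(pre3), list("1" = good), fx$windows,
                                 assembly_config()), 0L)
})

test_that("assembly equals the brute-force pair loop on a simulated run", {
  sim <- simulate_run(small_sim(55, n_species = 8L))
  res <- deconvolute_run(sim$run)
  cfg <- assembly_config()
  oracle <- oracle_assemble(res$precursors, res$ms2_features,
                            sim$run$windows, cfg)
  got <- assemble_spectra(res$precursors, res$ms2_features, sim$run$windows, cfg)
  expect_equal(length(got), length(oracle))
  okey <- function(s) sprintf("%d|%d", s$precursor_id, s$charge)
  o_by <- setNames(oracle, vapply(oracle, okey, character(1)))
  for (s in got) {
    o <- o_by[[okey(s)]]
    expect_false(is.null(o))
    expect_equal(s$fragments$mz, o$fragments$mz)
    expect_equal(s$fragments$intensity, o$fragments$intensity)
    expect_equal(s$fragments$corr, o$fragments$corr, tolerance = 1e-10)
  }
})

test_that("threshold and RF-max changes are monotone", {
  sim <- simulate_run(small_sim(66, n_species = 6L))
  res <- deconvolute_run(sim$run)
  frag_sets <- function(thr, rfmax) {
    sp <- assemble_spectra(res$precursors, res$ms2_features, sim$run$windows,
                           assembly_config(corr_threshold = thr, rf_max = rfmax,
                                           min_fragments = 1L))
    setNames(lapply(sp, function(s) sprintf("%.5f", s$fragments$mz)),
             vapply(sp, function(s) sprintf("%d|%d", s$precursor_id, s$charge),
                    character(1)))
  }
  base <- frag_sets(0.3, 500L)
  higher <- frag_sets(0.6, 500L)
  for (k in names(higher)) expect_true(all(higher[[k]] %in% base[[k]]))
  smaller <- frag_sets(0.3, 3L)
  for (k in names(smaller)) expect_true(all(smaller[[k]] %in% base[[k]]))
})
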