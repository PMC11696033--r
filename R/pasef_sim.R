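#' Theoretical peptide isotope envelope from the averagine model
#'
#' Computes the aggregated (nominal-mass) isotope intensity distribution of a
#' peptide-like molecule of the given monoisotopic mass using the averagine
#' average amino-acid composition (C 4.9384, H 7.7583, N 1.3577, O 1.4773,
#' S 0.0417 per 111.1254 Da; Senko-style rounding with hydrogen filling the
#' mass remainder). Element isotope distributions are convolved over the
#' number of extra neutrons, so envelope members are spaced by one C13 mass
#' difference, 1.0033548 / z in m/z space.
#'
#' The simulator plants envelopes with this model and the isotope-grouping
#' scorer compares against it, so the two share one definition.
#'
#' @param mono_mass monoisotopic neutral mass in Da (> 0).
#' @param n number of envelope members to return (>= 1).
#' @return numeric vector of `n` relative intensities, max-normalized.
#' @export
isotope_envelope <- function(mono_mass, n) {
  if (!is.finite(mono_mass) || mono_mass <= 0)
    stop("mono_mass must be > 0", call. = FALSE)
  if (!is.finite(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  n <- as.integer(n)
  # isotope abundances over extra-neutron count (IUPAC 2013 representative)
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
  scale <- mono_mass / 111.1254
  counts <- round(avg * scale)
  counts["H"] <- 0
  counts["H"] <- max(0, round((mono_mass - sum(counts * mono_elem)) /
                                mono_elem["H"]))
  len <- n + 3L
  # n-fold self-convolution by exponentiation-by-squaring, truncated to len
  conv_trunc <- function(a, b) {
    out <- numeric(len)
    for (k in seq_along(a)) {
      if (a[k] == 0) next
      upto <- min(length(b), len - k + 1L)
      if (upto >= 1)
        out[k:(k + upto - 1L)] <- out[k:(k + upto - 1L)] + a[k] * b[seq_len(upto)]
    }
    out
  }
  pow_conv <- function(d, m) {
    res <- c(1, numeric(len - 1L))
    base <- c(d, numeric(max(0L, len - length(d))))[seq_len(len)]
    while (m > 0) {
      if (m %% 2 == 1) res <- conv_trunc(res, base)
      base <- conv_trunc(base, base)
      m <- m %/% 2
    }
    res
  }
  dist <- c(1, numeric(len - 1L))
  for (el in names(iso)) {
    if (counts[el] > 0) dist <- conv_trunc(dist, pow_conv(iso[[el]], counts[el]))
  }
  env <- dist[seq_len(n)]
  env / max(env)
}

#' Configuration of the synthetic diaPASEF simulator
#'
#' Default values define the simulator's "stated world": a 110 s gradient
#' sampled with a ~1.05 s frame cycle of one MS1 frame followed by two MS2
#' frames; four DIA windows tiling MS1 m/z 400-1200 Th, two IM-stacked
#' windows per MS2 frame with the low-m/z window at low 1/K0 (the diaPASEF
#' diagonal); digitizer grid 0.002 Th x 0.001 1/K0; 50 peptide-like species
#' with abundances 4e3-4e4 counts (>= 5x the mean chemical-noise intensity at
#' the weakest planted cell), charge 1-4, RT sigma 2.5-4 s; 8-14 fragments
#' per species of which `decoy_frac` are planted as uncorrelated interference
#' (RT apex displaced by 5-15 s, or IM apex by 0.04-0.1 when the window band
#' allows); multiplicative lognormal intensity jitter and uniform dropout
#' emulate detector noise and sparsity.
#'
#' @param n_species number of planted peptide-like species.
#' @param seed mandatory RNG seed recorded in the fixture header.
#' @param n_windows,windows_per_frame DIA window scheme.
#' @param gradient_s,cycle_s gradient length and frame-cycle time (seconds).
#' @param ms1_mz_range,frag_mz_range,im_range scan ranges.
#' @param mz_step,im_step digitizer grid (smallest difference between two
#'   signals); these become the fixture's binning resolution constants.
#' @param noise_ms1,noise_ms2 chemical-noise points per MS1 frame and per
#'   window segment of each MS2 frame.
#' @param noise_mean mean of the exponential noise intensity distribution.
#' @param intensity_sdlog sdlog of the multiplicative lognormal jitter on
#'   planted intensities (0 disables).
#' @param dropout probability that a planted detector point is lost.
#' @param abundance_range species abundance range (log-uniform), counts.
#' @param rt_sigma_range chromatographic peak sigma range, seconds.
#' @param charge_probs sampling weights for charges 1..4.
#' @param n_frag_range fragments per species (uniform integer range).
#' @param frag_rel_range relative fragment intensity range.
#' @param decoy_frac fraction of fragments planted as decoys.
#' @param frag_rt_jitter,frag_im_jitter s.d. of the RT (s) / IM (1/K0) apex
#'   jitter of non-decoy fragments around their precursor.
#' @param max_isotopes,min_isotope_rel envelope truncation: members up to
#'   `max_isotopes` with relative intensity >= `min_isotope_rel`.
#' @param run_label label stored in the fixture meta.
#' @return a list of class `SimConfig`.
#' @export
sim_config <- function(n_species = 50L, seed,
                       n_windows = 4L, windows_per_frame = 2L,
                       gradient_s = 110, cycle_s = 1.05,
                       ms1_mz_range = c(400, 1200),
                       frag_mz_range = c(200, 1700),
                       im_range = c(0.6, 1.5),
                       mz_step = 0.002, im_step = 0.001,
                       noise_ms1 = 150L, noise_ms2 = 100L, noise_mean = 30,
                       intensity_sdlog = 0.15, dropout = 0.05,
                       abundance_range = c(4e3, 4e4),
                       rt_sigma_range = c(2.5, 4),
                       charge_probs = c(0.10, 0.45, 0.30, 0.15),
                       n_frag_range = c(8L, 14L),
                       frag_rel_range = c(0.3, 1),
                       decoy_frac = 0.25,
                       frag_rt_jitter = 0.25, frag_im_jitter = 0.002,
                       max_isotopes = 6L, min_isotope_rel = 0.05,
                       run_label = "sim") {
  if (missing(seed) || is.null(seed)) stop("sim_config: seed is mandatory", call. = FALSE)
  cfg <- as.list(environment())
  stopifnot(cfg$n_species >= 0, cfg$n_windows >= 1,
            cfg$n_windows %% cfg$windows_per_frame == 0,
            cfg$noise_ms1 >= 0, cfg$noise_ms2 >= 0, cfg$dropout >= 0,
            cfg$dropout < 1, cfg$mz_step > 0, cfg$im_step > 0)
  structure(cfg, class = "SimConfig")
}

# window scheme: windows tile MS1 m/z; window w sits in MS2 frame
# position ceil(w / wpf), IM band index ((w-1) %% wpf) + 1 (low m/z -> low IM)
.sim_windows <- function(cfg) {
  w <- seq_len(cfg$n_windows)
  wslice <- diff(cfg$ms1_mz_range) / cfg$n_windows
  band <- diff(cfg$im_range) / cfg$windows_per_frame
  data.table(
    window_id = as.integer(w),
    mz_low = cfg$ms1_mz_range[1] + (w - 1) * wslice,
    mz_high = cfg$ms1_mz_range[1] + w * wslice,
    im_low = cfg$im_range[1] + ((w - 1) %% cfg$windows_per_frame) * band,
    im_high = cfg$im_range[1] + (((w - 1) %% cfg$windows_per_frame) + 1) * band,
    cycle_position = as.integer((w - 1) %/% cfg$windows_per_frame + 1L)
  )
}

#' Simulate a diaPASEF run with ground truth
#'
#' Plants `n_species` peptide-like species: each contributes a 3D Gaussian
#' profile (RT x IM x isotope envelope in m/z) to the MS1 frames and fragment
#' profiles to the MS2 frames of the isolation window containing its
#' precursor. Deposits are laid on the digitizer grid as a 3x3 (m/z x IM)
#' Gaussian stencil per isotope/fragment per frame, jittered by the
#' multiplicative lognormal noise model and thinned by the dropout rate.
#' Uniform chemical noise is added over each stream's (m/z, IM) rectangle.
#'
#' @param cfg a [sim_config()].
#' @return list with `run` (a validated `RunFixture`), `species` (manifest
#'   data.table, one row per planted species incl. the deposited MS1/MS2
#'   intensity totals) and `fragments` (one row per planted fragment with its
#'   decoy flag and apex coordinates).
#' @export
simulate_run <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  windows <- .sim_windows(cfg)
  fpc <- 1L + cfg$n_windows %/% cfg$windows_per_frame  # frames per cycle
  n_cycles <- max(1L, as.integer(floor(cfg$gradient_s / cfg$cycle_s)))
  n_frames <- n_cycles * fpc
  pos <- rep(seq_len(fpc), n_cycles)
  frames <- data.table(
    frame_id = seq_len(n_frames),
    rt_seconds = (rep(seq_len(n_cycles), each = fpc) - 1) * cfg$cycle_s +
      (pos - 1) * (cfg$cycle_s / fpc),
    ms_level = ifelse(pos == 1L, 1L, 2L)
  )
  segments <- rbindlist(lapply(which(frames$ms_level == 2L), function(k) {
    cyc_pos <- pos[k] - 1L  # MS2 position 1..n_ms2
    ww <- windows[cycle_position == cyc_pos]
    data.table(frame_id = frames$frame_id[k], window_id = ww$window_id,
               im_low = ww$im_low, im_high = ww$im_high)
  }))
  if (is.null(segments) || !nrow(segments))
    segments <- data.table(frame_id = integer(), window_id = integer(),
                           im_low = numeric(), im_high = numeric())

  mz0 <- cfg$ms1_mz_range[1]; fmz0 <- cfg$frag_mz_range[1]; im0 <- cfg$im_range[1]
  # 3x3 grid stencil, sigma 0.9 grid steps, normalized to sum 1
  w1 <- dnorm(-1:1, sd = 0.9); w1 <- w1 / sum(w1)
  stencil <- as.vector(outer(w1, w1))
  st_dmz <- rep(-1:1, times = 3); st_dim <- rep(-1:1, each = 3)

  species <- fragments <- NULL
  deposits <- list()
  if (cfg$n_species > 0) {
    wsel <- sample(windows$window_id, cfg$n_species, replace = TRUE)
    ww <- windows[J(wsel), on = "window_id"]
    charge <- sample(1:4, cfg$n_species, replace = TRUE, prob = cfg$charge_probs)
    mz <- .quantize(runif(cfg$n_species, ww$mz_low + 2, ww$mz_high - 8),
                    mz0, cfg$mz_step)
    im <- .quantize(runif(cfg$n_species, ww$im_low + 0.05, ww$im_high - 0.05),
                    im0, cfg$im_step)
    mass <- (mz - PROTON_MASS) * charge
    species <- data.table(
      species_id = seq_len(cfg$n_species), window_id = wsel,
      mass = mass, mz = mz, charge = charge,
      rt_apex = runif(cfg$n_species, min(12, cfg$gradient_s / 4),
                      cfg$gradient_s - min(12, cfg$gradient_s / 4)),
      rt_sigma = runif(cfg$n_species, cfg$rt_sigma_range[1], cfg$rt_sigma_range[2]),
      im_apex = im,
      abundance = exp(runif(cfg$n_species, log(cfg$abundance_range[1]),
                            log(cfg$abundance_range[2])))
    )
    species[, in_window := mz >= ww$mz_low & mz < ww$mz_high &
              im >= ww$im_low & im < ww$im_high]
    if (any(!species$in_window))
      warning("simulated species outside every window: ",
              paste(species$species_id[!species$in_window], collapse = ","))
    envs <- lapply(seq_len(cfg$n_species), function(s) {
      e <- isotope_envelope(species$mass[s], cfg$max_isotopes)
      e[seq_len(max(1L, max(which(e >= cfg$min_isotope_rel))))]
    })
    species[, n_isotopes := vapply(envs, length, integer(1))]

    n_frag <- sample(cfg$n_frag_range[1]:cfg$n_frag_range[2],
                     cfg$n_species, replace = TRUE)
    fragments <- rbindlist(lapply(seq_len(cfg$n_species), function(s) {
      nf <- n_frag[s]
      dec <- runif(nf) < cfg$decoy_frac
      wrow <- windows[J(species$window_id[s]), on = "window_id"]
      f_im <- species$im_apex[s] + rnorm(nf, 0, cfg$frag_im_jitter)
      f_rt <- species$rt_apex[s] + rnorm(nf, 0, cfg$frag_rt_jitter)
      for (k in which(dec)) {
        # decoy: displaced beyond the assembly tolerances, in IM if the band
        # allows, otherwise in RT
        lo <- wrow$im_low + 0.01; hi <- wrow$im_high - 0.01
        im_try <- runif(1, lo, hi)
        if (runif(1) < 0.5 && abs(im_try - species$im_apex[s]) >= 0.04) {
          f_im[k] <- im_try
        } else {
          f_rt[k] <- species$rt_apex[s] +
            sample(c(-1, 1), 1) * runif(1, 5, 15)
        }
      }
      data.table(
        species_id = s, frag_id = seq_len(nf),
        mz = .quantize(runif(nf, cfg$frag_mz_range[1] + 2,
                             cfg$frag_mz_range[2] - 2), fmz0, cfg$mz_step),
        rel_intensity = runif(nf, cfg$frag_rel_range[1], cfg$frag_rel_range[2]),
        decoy = dec,
        rt_apex = f_rt,
        im_apex = pmin(pmax(.quantize(f_im, im0, cfg$im_step),
                            wrow$im_low + 2 * cfg$im_step),
                       wrow$im_high - 2 * cfg$im_step)
      )
    }))

    # --- MS1 deposits ---
    ms1 <- frames[ms_level == 1L]
    for (s in seq_len(cfg$n_species)) {
      g <- exp(-(ms1$rt_seconds - species$rt_apex[s])^2 /
                 (2 * species$rt_sigma[s]^2))
      keep <- which(g >= 0.01)
      if (!length(keep)) next
      env <- envs[[s]]
      iso_mz <- .quantize(species$mz[s] +
                            (seq_along(env) - 1) * C13_DELTA / species$charge[s],
                          mz0, cfg$mz_step)
      grid <- CJ(fk = keep, iso = seq_along(env), st = seq_along(stencil))
      base <- species$abundance[s] * g[grid$fk] * env[grid$iso] * stencil[grid$st]
      deposits[[length(deposits) + 1L]] <- data.table(
        frame_id = ms1$frame_id[grid$fk],
        mz = iso_mz[grid$iso] + st_dmz[grid$st] * cfg$mz_step,
        inv_k0 = species$im_apex[s] + st_dim[grid$st] * cfg$im_step,
        intensity = base, species_id = s, ms_level = 1L)
    }
    # --- MS2 deposits (fragments in the precursor's window frames) ---
    for (s in seq_len(cfg$n_species)) {
      wfr <- segments[window_id == species$window_id[s], frame_id]
      frt <- frames[J(wfr), on = "frame_id", rt_seconds]
      fr_s <- fragments[species_id == s]
      for (k in seq_len(nrow(fr_s))) {
        g <- exp(-(frt - fr_s$rt_apex[k])^2 / (2 * species$rt_sigma[s]^2))
        keep <- which(g >= 0.01)
        if (!length(keep)) next
        grid <- CJ(fk = keep, st = seq_along(stencil))
        base <- species$abundance[s] * fr_s$rel_intensity[k] *
          g[grid$fk] * stencil[grid$st]
        deposits[[length(deposits) + 1L]] <- data.table(
          frame_id = wfr[grid$fk],
          mz = fr_s$mz[k] + st_dmz[grid$st] * cfg$mz_step,
          inv_k0 = fr_s$im_apex[k] + st_dim[grid$st] * cfg$im_step,
          intensity = base, species_id = s, ms_level = 2L)
      }
    }
  }

  planted <- if (length(deposits)) rbindlist(deposits) else
    data.table(frame_id = integer(), mz = numeric(), inv_k0 = numeric(),
               intensity = numeric(), species_id = integer(), ms_level = integer())
  if (nrow(planted)) {
    if (cfg$intensity_sdlog > 0)
      planted[, intensity := intensity *
                rlnorm(.N, meanlog = -cfg$intensity_sdlog^2 / 2,
                       sdlog = cfg$intensity_sdlog)]
    if (cfg$dropout > 0) planted <- planted[runif(.N) >= cfg$dropout]
    # clamp IM stencil spill to the valid ranges (margins make this a no-op
    # for species; defensive for fragments near segment edges)
    planted <- planted[inv_k0 >= im0 & inv_k0 < cfg$im_range[2]]
  }

  # --- chemical noise, uniform over each stream's (m/z, IM) rectangle ---
  noise <- list()
  if (cfg$noise_ms1 > 0) {
    ms1 <- frames[ms_level == 1L]
    n <- cfg$noise_ms1 * nrow(ms1)
    noise[[length(noise) + 1L]] <- data.table(
      frame_id = rep(ms1$frame_id, each = cfg$noise_ms1),
      mz = .quantize(runif(n, cfg$ms1_mz_range[1] + cfg$mz_step,
                           cfg$ms1_mz_range[2] - cfg$mz_step), mz0, cfg$mz_step),
      inv_k0 = .quantize(runif(n, im0 + cfg$im_step,
                               cfg$im_range[2] - cfg$im_step), im0, cfg$im_step),
      intensity = rexp(n, 1 / cfg$noise_mean))
  }
  if (cfg$noise_ms2 > 0 && nrow(segments)) {
    n <- cfg$noise_ms2 * nrow(segments)
    idx <- rep(seq_len(nrow(segments)), each = cfg$noise_ms2)
    noise[[length(noise) + 1L]] <- data.table(
      frame_id = segments$frame_id[idx],
      mz = .quantize(runif(n, cfg$frag_mz_range[1] + cfg$mz_step,
                           cfg$frag_mz_range[2] - cfg$mz_step), fmz0, cfg$mz_step),
      inv_k0 = .quantize(runif(n, segments$im_low[idx] + cfg$im_step,
                               segments$im_high[idx] - cfg$im_step),
                         im0, cfg$im_step),
      intensity = rexp(n, 1 / cfg$noise_mean))
  }
  pts <- rbindlist(c(list(planted[, .(frame_id, mz, inv_k0, intensity)]), noise))
  # merge co-located detector events and order points per the frame contract
  pts <- pts[intensity > 0,
             .(intensity = sum(intensity)), by = .(frame_id, mz, inv_k0)]
  setorder(pts, frame_id, inv_k0, mz)

  meta <- list(run_label = cfg$run_label, mz_step = cfg$mz_step,
               im_step = cfg$im_step,
               ms1_mz_min = cfg$ms1_mz_range[1], ms1_mz_max = cfg$ms1_mz_range[2],
               frag_mz_min = cfg$frag_mz_range[1], frag_mz_max = cfg$frag_mz_range[2],
               im_min = cfg$im_range[1], im_max = cfg$im_range[2],
               seed = cfg$seed)
  run <- run_fixture(meta, windows, frames, segments,
                     pts[, .(frame_id, mz, inv_k0, intensity)])

  if (!is.null(species)) {
    tot <- planted[, .(tot = sum(intensity)), by = .(species_id, ms_level)]
    species[, planted_ms1 := 0.0]; species[, planted_ms2 := 0.0]
    t1 <- tot[ms_level == 1L]; t2 <- tot[ms_level == 2L]
    species[t1, planted_ms1 := i.tot, on = "species_id"]
    species[t2, planted_ms2 := i.tot, on = "species_id"]
    species[, n_fragments := fragments[, .N, by = species_id][J(species$species_id), on = "species_id", N]]
    species[, n_decoys := fragments[, sum(decoy), by = species_id][J(species$species_id), on = "species_id", V1]]
  } else {
    species <- data.table(species_id = integer())
    fragments <- data.table(species_id = integer())
  }
  list(run = run, species = species, fragments = fragments)
}
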