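#' @name pseudo_msms
#' @title Pseudo-MS/MS spectrum assembly
#' @description
#' Clustering begins with the precursor peaks: all fragment features in the
#' precursor's isolation window within the apex RT and IM tolerances
#' ("Delta Apex RT" default 3 s, "Delta Apex IM" default 0.02 1/K0) are
#' candidates; the Pearson correlation between the smoothed monoisotopic
#' precursor XIC and each raw fragment XIC gates them ("Corr threshold"
#' default 0.3); at most "RF max" (default 500) of the highest-intensity
#' fragments are kept. Fragment intensities in the pseudo-MS/MS spectrum are
#' the apex intensities of the fragment XICs. An optional fractional-mass
#' (mass defect) filter removes precursors outside the tryptic-peptide band.
NULL

#' Assembly configuration with the field-standard defaults
#'
#' @param delta_apex_im "Delta Apex IM": fragment-precursor apex IM
#'   tolerance, 1/K0.
#' @param delta_apex_rt "Delta Apex RT": fragment-precursor apex RT
#'   tolerance, seconds.
#' @param corr_threshold "Corr threshold": minimum precursor-fragment XIC
#'   Pearson correlation.
#' @param rf_max "RF max": maximum fragments per spectrum.
#' @param mass_defect_filter enable the fractional-mass precursor filter
#'   (not recommended for PTM or nonspecific workflows).
#' @param min_fragments spectra with fewer fragments are dropped.
#' @return a list of class `AssemblyConfig`.
#' @export
assembly_config <- function(delta_apex_im = 0.02, delta_apex_rt = 3,
                            corr_threshold = 0.3, rf_max = 500L,
                            mass_defect_filter = FALSE, min_fragments = 4L) {
  stopifnot(delta_apex_im > 0, delta_apex_rt > 0, rf_max >= 1)
  structure(list(delta_apex_im = delta_apex_im, delta_apex_rt = delta_apex_rt,
                 corr_threshold = corr_threshold, rf_max = as.integer(rf_max),
                 mass_defect_filter = isTRUE(mass_defect_filter),
                 min_fragments = as.integer(min_fragments)),
            class = "AssemblyConfig")
}

#' Fractional-mass (mass defect) filter for tryptic peptides
#'
#' Peptide monoisotopic masses concentrate along a line of slope ~0.000507
#' fractional mass per Da ("peptide mass rule"). The filter accepts a
#' neutral mass iff its fractional part lies within a band centred at
#' `0.000507 * mass (mod 1)` with half-width `half_width + widen_per_100da *
#' mass / 100`, measured circularly.
#'
#' @param neutral_mass neutral monoisotopic mass in Da (> 0). Vectorized.
#' @param enabled when `FALSE` the filter always passes.
#' @param slope band centre slope per Da.
#' @param half_width base band half-width.
#' @param widen_per_100da extra half-width per 100 Da.
#' @return logical vector.
#' @export
mass_defect_pass <- function(neutral_mass, enabled = TRUE, slope = 0.000507,
                             half_width = 0.15, widen_per_100da = 0.001) {
  if (!enabled) return(rep(TRUE, length(neutral_mass)))
  stopifnot(all(neutral_mass > 0))
  centre <- (slope * neutral_mass) %% 1
  frac <- neutral_mass %% 1
  d <- abs(frac - centre)
  d <- pmin(d, 1 - d)  # circular distance on the unit fractional-mass ring
  d <= half_width + widen_per_100da * neutral_mass / 100
}

#' Pearson correlation of a precursor and a fragment XIC
#'
#' Both traces are resampled to the precursor's merged-frame grid over its
#' bounded RT range (frames outside a trace read as 0); the precursor trace
#' is Savitzky-Golay smoothed, the fragment trace is used raw. Fewer than 3
#' shared trace frames, or zero variance on either side, yield the sentinel
#' value 0.
#'
#' @param precursor an MS1 `XICFeature` (typically the monoisotopic member).
#' @param fragment an MS2 `XICFeature`.
#' @param sg_window,sg_order smoothing parameters for the precursor trace.
#' @return Pearson r in `[-1, 1]`, or 0.
#' @export
xic_pearson <- function(precursor, fragment, sg_window = 5L, sg_order = 2L) {
  grid <- precursor$frames[precursor$bounds[1]:precursor$bounds[2]]
  if (length(grid) < 3L) return(0)
  if (length(intersect(grid, fragment$frames)) < 3L) return(0)
  pv <- precursor$intensity[precursor$bounds[1]:precursor$bounds[2]]
  pv <- savitzky_golay(pv, sg_window, sg_order)
  fv <- numeric(length(grid))
  hit <- match(fragment$frames, grid)
  fv[hit[!is.na(hit)]] <- fragment$intensity[!is.na(hit)]
  if (stats::sd(pv) == 0 || stats::sd(fv) == 0) return(0)
  cor(pv, fv)
}

.locate_window <- function(windows, mz, im) {
  w <- windows[mz_low <= mz & mz_high > mz & im_low <= im & im_high > im]
  if (!nrow(w)) return(NA_integer_)
  w$window_id[order(w$window_id)][1]
}

#' Assemble pseudo-MS/MS spectra from precursors and fragment features
#'
#' For each precursor (optionally pre-filtered by [mass_defect_pass()] on
#' the neutral mass of its first charge), candidate fragments are the MS2
#' XIC features of the precursor's isolation window with apex distances
#' within the RT and IM tolerances; those with [xic_pearson()] at or above
#' the correlation threshold are kept; if more than `rf_max` remain, the
#' `rf_max` highest by apex intensity (ties toward lower m/z) are kept.
#' Spectra with fewer than `min_fragments` fragments are dropped. A
#' precursor with k ambiguous charges emits one spectrum per charge sharing
#' the fragment list. Fragments may be shared between precursors.
#'
#' @param precursors list of `PrecursorFeature`.
#' @param ms2_features named list (by window id) of MS2 `XICFeature` lists.
#' @param windows the run's window table (`RunFixture$windows`).
#' @param cfg an [assembly_config()].
#' @return list of `PseudoSpectrum`: `precursor_id`, `precursor_mz`,
#'   `charge`, `charges`, `rt`, `im`, `window_id`, `fragments` (data.table
#'   `mz`, `intensity`, `corr`, ascending m/z).
#' @export
assemble_spectra <- function(precursors, ms2_features, windows,
                             cfg = assembly_config()) {
  out <- list()
  for (pid in seq_along(precursors)) {
    pre <- precursors[[pid]]
    if (cfg$mass_defect_filter) {
      nm <- (pre$mono_mz - PROTON_MASS) * pre$charges[1]
      if (!mass_defect_pass(nm)) next
    }
    wid <- .locate_window(windows, pre$mono_mz, pre$apex_im)
    if (is.na(wid)) next  # logged by the pipeline driver, not a failure
    frags <- ms2_features[[as.character(wid)]]
    if (is.null(frags) || !length(frags)) next
    mono <- pre$members[[1]]
    cand <- data.table(
      k = seq_along(frags),
      mz = vapply(frags, `[[`, numeric(1), "mz"),
      im = vapply(frags, `[[`, numeric(1), "im"),
      rt = vapply(frags, function(f) f$rt[f$apex], numeric(1)),
      inten = vapply(frags, `[[`, numeric(1), "apex_intensity")
    )
    cand <- cand[abs(rt - pre$apex_rt) <= cfg$delta_apex_rt &
                   abs(im - pre$apex_im) <= cfg$delta_apex_im]
    if (!nrow(cand)) next
    cand[, corr := vapply(k, function(kk) xic_pearson(mono, frags[[kk]]),
                          numeric(1))]
    cand <- cand[corr >= cfg$corr_threshold]
    if (nrow(cand) > cfg$rf_max) {
      setorder(cand, -inten, mz)
      cand <- cand[seq_len(cfg$rf_max)]
    }
    if (nrow(cand) < cfg$min_fragments) next
    setorder(cand, mz)
    for (z in pre$charges) {
      out[[length(out) + 1L]] <- structure(list(
        precursor_id = pid, precursor_mz = pre$mono_mz, charge = z,
        charges = pre$charges, rt = pre$apex_rt, im = pre$apex_im,
        window_id = wid,
        fragments = cand[, .(mz, intensity = inten, corr)]
      ), class = "PseudoSpectrum")
    }
  }
  out
}

#' @export
print.PseudoSpectrum <- function(x, ...) {
  cat(sprintf(
    "PseudoSpectrum prec %d m/z %.4f z%d rt %.2f s 1/K0 %.4f: %d fragments\n",
    x$precursor_id, x$precursor_mz, x$charge, x$rt, x$im, nrow(x$fragments)))
  invisible(x)
}
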