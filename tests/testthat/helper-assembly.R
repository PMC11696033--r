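# Engineered assembly fixtures: a precursor in window 1 of the standard
# scheme and fragments constructed to have an exact target Pearson
# correlation with its smoothed XIC.

.assembly_fixture <- function() {
  # precursor in window 1 of the standard scheme, plus engineered fragments
  rt <- (1:11) * 1.0
  y <- 100 * exp(-((1:11) - 6)^2 / 4) + 2
  prec_member <- make_xic(y, rt = rt, frames = 1:11, mz = 450.0, im = 0.8)
  prec_member <- bound_xic(prec_member, 0.0)
  pre <- structure(list(
    mono_mz = 450.0, charges = 2L, members = list(prec_member),
    envelope_corr = 1, xic_corr = 1, apex_rt = 6.0, apex_im = 0.8,
    intensity = 100, n_isotopes = 1L), class = "PrecursorFeature")
  windows <- data.table::data.table(
    window_id = 1:2, mz_low = c(400, 600), mz_high = c(600, 800),
    im_low = c(0.6, 1.05), im_high = c(1.05, 1.5), cycle_position = c(1L, 1L))
  list(pre = pre, windows = windows, grid_rt = rt)
}

# fragment with an exact target correlation r against the smoothed precursor
.frag_with_corr <- function(pre_member, r, mz, intensity = 50, im = 0.8) {
  pv <- savitzky_golay(pre_member$intensity, 5L, 2L)
  u <- pv - mean(pv)
  u <- u / sqrt(sum(u^2))
  # centre-peaked orthogonal component (a sharper bell) so the constructed
  # fragment keeps its apex at the precursor apex and passes the RT gate
  w <- u^3
  w <- w - mean(w)
  w <- w - sum(w * u) * u
  w <- w / sqrt(sum(w^2))
  if (w[which.max(u)] < 0) w <- -w
  v <- r * u + sqrt(1 - r^2) * w
  y <- v - min(v) + 0.01          # shift positive; Pearson is shift-invariant
  y <- y / max(y) * intensity
  stopifnot(which.max(y) == which.max(pre_member$intensity))
  make_xic(y, rt = pre_member$rt, frames = pre_member$frames, mz = mz,
           im = im, ms_level = 2L, window_id = 1L)
}

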