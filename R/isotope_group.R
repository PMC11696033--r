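#' @name isotope_group
#' @title MS1 isotope grouping and charge assignment
#' @description
#' Traced MS1 peaks are organised into isotopic clusters based on RT and IM
#' tolerances; member spacing follows the C13 mass difference (1.0033548/z).
#' The correlation of theoretical and experimental isotope intensity
#' distributions and the correlation of the member XICs control cluster
#' quality; highly confident clusters claim their members exclusively. The
#' minimum number of isotopes is one: unclaimed singletons are retained as
#' charge-unknown precursors with a configurable default charge list.
NULL

#' Pearson correlation between observed and theoretical isotope envelopes
#'
#' @param members member apex intensities, ordered by isotope index.
#' @param mono_mass monoisotopic neutral mass in Da (selects the averagine
#'   envelope, truncated to the member count).
#' @return Pearson r; `1.0` sentinel for singletons, `0` sentinel when a
#'   zero-variance input makes the correlation undefined.
#' @export
envelope_corr <- function(members, mono_mass) {
  n <- length(members)
  if (n < 2L) return(1.0)
  theo <- isotope_envelope(mono_mass, n)
  if (stats::sd(members) == 0 || stats::sd(theo) == 0) return(0)
  cor(members, theo)
}

#' Charge states consistent with observed isotope spacings
#'
#' All charges z in `1..max_charge` whose theoretical spacing 1.0033548/z is
#' within `iso_ppm` (relative to the observed m/z) of the mean observed
#' spacing, ranked by spacing residual. Singletons (no spacing) receive the
#' configured default charge list.
#'
#' @param spacings observed consecutive member m/z differences (Th); may be
#'   empty.
#' @param mz observed (monoisotopic) m/z, setting the ppm scale.
#' @param iso_ppm spacing tolerance in ppm of `mz`.
#' @param max_charge largest charge considered.
#' @param default_charges returned for singletons.
#' @return integer vector of charges (possibly length > 1).
#' @export
assign_charge <- function(spacings, mz, iso_ppm = 20, max_charge = 4L,
                          default_charges = c(2L, 3L)) {
  if (!length(spacings)) return(as.integer(default_charges))
  sp <- mean(spacings)
  z <- seq_len(max_charge)
  resid <- abs(sp - C13_DELTA / z)
  keep <- resid <= iso_ppm * 1e-6 * mz
  if (!any(keep)) return(integer(0))
  z[keep][order(resid[keep])]
}

# mean pairwise Pearson r of member XIC traces on the shared merged-frame
# grid (union of member frame ranges; frames outside a trace read as 0)
.member_xic_corr <- function(members) {
  if (length(members) < 2L) return(1.0)
  fr_lo <- min(vapply(members, function(m) m$frames[1], numeric(1)))
  fr_hi <- max(vapply(members, function(m) m$frames[length(m$frames)], numeric(1)))
  grid <- fr_lo:fr_hi
  mat <- vapply(members, function(m) {
    v <- numeric(length(grid))
    v[match(m$frames, grid)] <- m$intensity
    v
  }, numeric(length(grid)))
  cc <- suppressWarnings(cor(mat))
  cc[!is.finite(cc)] <- 0
  mean(cc[upper.tri(cc)])
}

#' Group MS1 XIC features into isotopic clusters and assign charges
#'
#' Greedy seeding from the most intense unclaimed feature. For each
#' candidate charge (from `max_charge` down) the cluster is extended with
#' features at the expected C13 spacing within `iso_ppm`, `rt_tol` and
#' `im_tol` — leftward first, so the reported monoisotopic member is the
#' cluster head even when a heavier isotope is the most intense, then
#' rightward. The best-scoring charge (most members, then highest envelope
#' correlation) defines the cluster; clusters passing both confidence
#' thresholds claim their members, which are removed from subsequent
#' seeding. Unclaimed singletons are retained as charge-unknown precursors
#' with `default_charges`.
#'
#' @param ms1_features list of MS1 `XICFeature`.
#' @param rt_tol apex RT tolerance in seconds.
#' @param im_tol apex IM tolerance in 1/K0.
#' @param max_charge largest charge considered.
#' @param iso_ppm isotope spacing tolerance in ppm.
#' @param conf_envelope,conf_xic confidence thresholds on the envelope and
#'   XIC correlations for claim-and-remove.
#' @param default_charges charge list for singleton precursors.
#' @return list of `PrecursorFeature`: `mono_mz`, `charges`, `members`,
#'   `envelope_corr`, `xic_corr`, `apex_rt`, `apex_im`, `intensity`,
#'   `n_isotopes`.
#' @export
group_isotopes <- function(ms1_features, rt_tol = 1.05, im_tol = 0.01,
                           max_charge = 4L, iso_ppm = 20,
                           conf_envelope = 0.6, conf_xic = 0.6,
                           default_charges = c(2L, 3L)) {
  n <- length(ms1_features)
  if (!n) return(list())
  feat <- data.table(
    idx = seq_len(n),
    mz = vapply(ms1_features, `[[`, numeric(1), "mz"),
    im = vapply(ms1_features, `[[`, numeric(1), "im"),
    rt = vapply(ms1_features, function(f) f$rt[f$apex], numeric(1)),
    inten = vapply(ms1_features, `[[`, numeric(1), "apex_intensity")
  )
  # deterministic seeding order: intensity desc, then m/z
  seed_order <- feat[order(-inten, mz, im), idx]
  claimed <- rep(FALSE, n)
  out <- list()
  eps <- 1e-9  # tolerances are inclusive up to floating-point noise
  find_next <- function(from_row, target_mz, tol_th) {
    cand <- feat[!claimed[idx] &
                   abs(mz - target_mz) <= tol_th &
                   abs(rt - from_row$rt) <= rt_tol * (1 + eps) + eps &
                   abs(im - from_row$im) <= im_tol + eps]
    if (!nrow(cand)) return(NULL)
    cand[order(abs(mz - target_mz), -inten)][1]
  }
  for (s in seed_order) {
    if (claimed[s]) next
    seed_row <- feat[idx == s]
    best <- NULL
    for (z in seq(max_charge, 1L)) {
      dmz <- C13_DELTA / z
      tol_th <- iso_ppm * 1e-6 * seed_row$mz
      chain <- list(seed_row)
      cur <- seed_row  # leftward: walk to the cluster head
      repeat {
        nxt <- find_next(cur, cur$mz - dmz, tol_th)
        if (is.null(nxt)) break
        chain <- c(list(nxt), chain)
        cur <- nxt
      }
      cur <- seed_row  # rightward
      repeat {
        nxt <- find_next(cur, cur$mz + dmz, tol_th)
        if (is.null(nxt)) break
        chain <- c(chain, list(nxt))
        cur <- nxt
      }
      ch <- rbindlist(chain)
      mono_mass <- (ch$mz[1] - PROTON_MASS) * z
      ecorr <- if (mono_mass > 0) envelope_corr(ch$inten, mono_mass) else 0
      score <- c(nrow(ch), ecorr)
      if (is.null(best) || score[1] > best$score[1] ||
          (score[1] == best$score[1] && score[2] > best$score[2])) {
        best <- list(z = z, rows = ch, score = score, ecorr = ecorr)
      }
    }
    ch <- best$rows
    members <- ms1_features[ch$idx]
    if (nrow(ch) >= 2L) {
      spac <- diff(ch$mz)
      charges <- assign_charge(spac, ch$mz[1], iso_ppm, max_charge,
                               default_charges)
      if (!length(charges)) charges <- best$z
      xcorr <- .member_xic_corr(members)
      ecorr <- best$ecorr
      if (ecorr >= conf_envelope && xcorr >= conf_xic)
        claimed[ch$idx] <- TRUE
      else
        claimed[s] <- TRUE  # the seed itself never re-seeds
    } else {
      charges <- as.integer(default_charges)
      xcorr <- 1.0
      ecorr <- 1.0
      claimed[s] <- TRUE
    }
    mono <- members[[1]]
    out[[length(out) + 1L]] <- structure(list(
      mono_mz = mono$mz,
      charges = as.integer(charges),
      members = members,
      envelope_corr = ecorr,
      xic_corr = xcorr,
      apex_rt = mono$rt[mono$apex],
      apex_im = mono$im,
      intensity = sum(ch$inten),
      n_isotopes = nrow(ch)
    ), class = "PrecursorFeature")
  }
  out
}

#' @export
print.PrecursorFeature <- function(x, ...) {
  cat(sprintf(
    "PrecursorFeature m/z %.4f z [%s]: %d isotopes, rt %.2f s, 1/K0 %.4f, env r %.3f, xic r %.3f\n",
    x$mono_mz, paste(x$charges, collapse = ","), x$n_isotopes, x$apex_rt,
    x$apex_im, x$envelope_corr, x$xic_corr))
  invisible(x)
}
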