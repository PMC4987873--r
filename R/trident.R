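# Y1-ion triplet-pattern (Trident) detection of the deglycosylated peptide
# ion (Y0), dynamic-programming extension of the Y-ion ladder, and emission
# of in silico peptide spectra with the precursor reassigned to the Y0 mass.
#
# Pattern A: [Y0, Y0 + GlcNAc/z, Y0 + 2*GlcNAc/z]
# Pattern B: [Y0 - NH3/z, Y0, Y0 + GlcNAc/z]

#' Detect Y1-ion triplet patterns (Y0 candidates)
#'
#' For each charge state z in 1..precursor_charge, every peak p with
#' companion peaks at p + GlcNAc/z and p + 2*GlcNAc/z (pattern A) or at
#' p - NH3/z and p + GlcNAc/z (pattern B), within the fragment tolerance,
#' yields a Y0 candidate. Candidates are deduplicated on the implied peptide
#' neutral mass (rounded to the tolerance grid); a Y0 found by both patterns
#' is recorded once with pattern `"A+B"`. The Y0 neutral mass must lie below
#' the intact precursor neutral mass.
#'
#' @param spectrum A `glyco_spectrum`.
#' @param config A [glyco_config()]; uses `fragment_tolerance`.
#' @return List of `trident_match` objects, sorted by Y0 m/z. Each has
#'   `y0_mz`, `charge`, `pattern`, `evidence_mz` (the matched triplet peak
#'   m/z values; four peaks when both patterns fire),
#'   `peptide_neutral_mass`, `y0_peak_index`.
#' @export
detect_y1_patterns <- function(spectrum, config = glyco_config()) {
  tol <- config$fragment_tolerance
  peaks <- spectrum$peaks
  if (!nrow(peaks)) return(list())
  prec_neutral <- mass_from_mz(spectrum$precursor_mz, spectrum$precursor_charge)
  found <- list()
  for (z in seq_len(spectrum$precursor_charge)) {
    g <- .GLCNAC / z
    nh3 <- NH3_MASS / z
    mz <- peaks[, "mz"]
    up1 <- .nearest_peak(peaks, mz + g, tol)
    up2 <- .nearest_peak(peaks, mz + 2 * g, tol)
    dn <- .nearest_peak(peaks, mz - nh3, tol)
    pat_a <- !is.na(up1) & !is.na(up2)
    pat_b <- !is.na(dn) & !is.na(up1)
    for (i in which(pat_a | pat_b)) {
      neutral <- mass_from_mz(mz[i], z)
      if (neutral >= prec_neutral - tol) next
      pattern <- if (pat_a[i] && pat_b[i]) "A+B" else if (pat_a[i]) "A" else "B"
      # evidence union: both triplets' peaks when both patterns fire
      ev <- c(if (pat_b[i]) mz[dn[i]], mz[i], mz[up1[i]],
              if (pat_a[i]) mz[up2[i]])
      found[[length(found) + 1L]] <- structure(
        list(y0_mz = mz[i], charge = z, pattern = pattern,
             evidence_mz = ev, peptide_neutral_mass = neutral,
             y0_peak_index = i),
        class = "trident_match")
    }
  }
  if (!length(found)) return(list())
  # dedup on neutral mass rounded to the tolerance grid, merging patterns
  keys <- vapply(found, function(m) round(m$peptide_neutral_mass / tol), 0)
  out <- list()
  for (k in unique(keys)) {
    grp <- found[keys == k]
    m <- grp[[1L]]
    pats <- sort(unique(unlist(strsplit(vapply(grp, `[[`, "", "pattern"), "+",
                                        fixed = TRUE))))
    m$pattern <- paste(pats, collapse = "+")
    out[[length(out) + 1L]] <- m
  }
  out[order(vapply(out, `[[`, 0, "y0_mz"))]
}

#' @export
print.trident_match <- function(x, ...) {
  cat(sprintf("<trident_match> Y0 %.4f Th (%d+), pattern %s, peptide mass %.4f Da\n",
              x$y0_mz, x$charge, x$pattern, x$peptide_neutral_mass))
  invisible(x)
}

# Longest monosaccharide-spaced path starting at `start` over `mz` (sorted),
# edges i -> j when mz[j] - mz[i] matches any residue mass / z within tol.
# Ties broken by larger summed intensity. Returns indices of the path
# (excluding start) and the residue labels of its steps.
.ladder_dp <- function(mz, intensity, start, z, tol,
                       mono = monosaccharide_masses()) {
  n <- length(mz)
  len <- rep(-Inf, n); len[start] <- 0
  isum <- rep(-Inf, n); isum[start] <- intensity[start]
  prev <- rep(NA_integer_, n)
  step <- rep(NA_character_, n)
  steps <- mono / z
  for (i in seq_len(n)) {
    if (!is.finite(len[i])) next
    for (r in seq_along(steps)) {
      target <- mz[i] + steps[r]
      lo <- findInterval(target - tol, mz) + 1L
      hi <- findInterval(target + tol, mz)
      if (hi < lo) next
      for (j in lo:hi) {
        cand_len <- len[i] + 1
        cand_int <- isum[i] + intensity[j]
        if (cand_len > len[j] || (cand_len == len[j] && cand_int > isum[j])) {
          len[j] <- cand_len; isum[j] <- cand_int
          prev[j] <- i; step[j] <- names(mono)[r]
        }
      }
    }
  }
  best <- which(len == max(len))
  if (length(best) > 1L) best <- best[which.max(isum[best])]
  path <- integer(); labels <- character()
  j <- best
  while (!is.na(prev[j])) {
    path <- c(j, path); labels <- c(step[j], labels)
    j <- prev[j]
  }
  list(indices = path, residues = labels)
}

#' Extend the Y-ion ladder above a Y0 candidate
#'
#' Builds the directed acyclic graph whose nodes are the peaks at m/z >= Y0
#' and whose edges connect peaks differing by any monosaccharide residue mass
#' divided by the match's charge (within the fragment tolerance), then returns
#' the maximum-length path starting at Y0 by dynamic programming over the
#' m/z order. Ties are broken by the larger summed peak intensity.
#'
#' @param spectrum The source `glyco_spectrum`.
#' @param match A `trident_match` from [detect_y1_patterns()] on this spectrum.
#' @param config A [glyco_config()].
#' @return A `y_ladder`: list with `y0` (the match) and `steps` (data.frame
#'   `residue`, `mz`, `intensity`; zero rows when no peak extends Y0).
#' @export
extend_y_ladder <- function(spectrum, match, config = glyco_config()) {
  peaks <- spectrum$peaks
  keep <- which(peaks[, "mz"] >= match$y0_mz - 1e-9)
  mz <- peaks[keep, "mz"]; it <- peaks[keep, "intensity"]
  start <- which.min(abs(mz - match$y0_mz))
  dp <- .ladder_dp(mz, it, start, match$charge, config$fragment_tolerance)
  steps <- data.frame(residue = dp$residues,
                      mz = mz[dp$indices],
                      intensity = it[dp$indices])
  structure(list(y0 = match, steps = steps), class = "y_ladder")
}

#' @export
print.y_ladder <- function(x, ...) {
  cat(sprintf("<y_ladder> Y0 %.4f Th (%d+), %d step(s): %s\n",
              x$y0$y0_mz, x$y0$charge, nrow(x$steps),
              paste(x$steps$residue, collapse = " > ")))
  invisible(x)
}

#' Strip glycan ions and emit an in silico peptide spectrum
#'
#' Removes (a) every peak matching a built-in oxonium B-ion, (b) the Y-ladder
#' peaks including the Y0 peak and the triplet evidence peaks, and (c) peaks
#' matching the ladder ions at other charge states, then reassigns the
#' precursor to the Y0-derived peptide mass. The emission charge is
#' `precursor_charge - 1` for multiply charged precursors (the departing
#' glycan is assumed to carry at most one charge), else 1.
#'
#' @param spectrum Source `glyco_spectrum`.
#' @param match The `trident_match` being emitted.
#' @param ladder Its [extend_y_ladder()] result.
#' @param filter_result The spectrum's [is_glycopeptide_spectrum()] result.
#' @param config A [glyco_config()].
#' @param variant_index Index of this Y0 candidate within the spectrum, used
#'   to suffix the title (`"::Y0_<k>"`) when one spectrum yields several
#'   in silico versions.
#' @return An `insilico_spectrum` (a `glyco_spectrum` with `source_title`,
#'   `y0`, `removed_count`), or `NULL` with a warning when stripping removes
#'   every peak.
#' @export
build_insilico_spectrum <- function(spectrum, match, ladder, filter_result,
                                    config = glyco_config(), variant_index = 1L) {
  tol <- config$fragment_tolerance
  peaks <- spectrum$peaks
  drop <- logical(nrow(peaks))
  # (a) oxonium-region B-ions
  ox <- oxonium_ions()
  ox <- ox[ox$mz < config$low_mz_bound, , drop = FALSE]
  for (m in ox$mz)
    drop[.peaks_within(peaks, m, config$oxonium_tolerance)] <- TRUE
  # (b) ladder + Y0 + triplet evidence peaks
  glyco_mz <- c(match$evidence_mz, match$y0_mz, ladder$steps$mz)
  glyco_mz <- glyco_mz[!is.na(glyco_mz)]
  for (m in glyco_mz)
    drop[.peaks_within(peaks, m, tol)] <- TRUE
  # (c) ladder ions at other charge states
  neutrals <- mass_from_mz(c(match$y0_mz, ladder$steps$mz), match$charge)
  for (z in seq_len(spectrum$precursor_charge)) {
    if (z == match$charge) next
    for (m in mz_from_mass(neutrals, z))
      drop[.peaks_within(peaks, m, tol)] <- TRUE
  }
  if (all(drop)) {
    warning("stripping removed every peak of '", spectrum$title,
            "'; spectrum dropped", call. = FALSE)
    return(NULL)
  }
  emission_charge <- if (spectrum$precursor_charge >= 2L)
    spectrum$precursor_charge - 1L else 1L
  out <- new_spectrum(
    title = paste0(spectrum$title, "::Y0_", variant_index),
    precursor_mz = mz_from_mass(match$peptide_neutral_mass, emission_charge),
    precursor_charge = emission_charge,
    peaks = peaks[!drop, , drop = FALSE],
    rt = spectrum$rt
  )
  out$source_title <- spectrum$title
  out$y0 <- match
  out$removed_count <- sum(drop)
  class(out) <- c("insilico_spectrum", class(out))
  out
}

#' Neutral glycan mass implied by a Y0 candidate
#'
#' The intact glycopeptide neutral mass minus the Y0-derived peptide neutral
#' mass.
#'
#' @param spectrum Source `glyco_spectrum` (intact precursor).
#' @param match A `trident_match`.
#' @return Glycan neutral mass in Da (> 0).
#' @export
glycan_neutral_mass <- function(spectrum, match) {
  g <- mass_from_mz(spectrum$precursor_mz, spectrum$precursor_charge) -
    match$peptide_neutral_mass
  if (g <= 0)
    stop("Y0 candidate at ", format(match$y0_mz), " Th implies a non-positive ",
         "glycan mass; inconsistent Y0", call. = FALSE)
  unname(g)
}
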