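# Targeted search of in silico peptide spectra against the target-decoy
# database: precursor match at 0.6 Da, top-40-peak b/y fragment matching,
# acceptance rules, PepScore, multi-Y0 resolution, target-decoy diagnostics.

#' Most intense peaks of a spectrum
#'
#' The `n` most intense peaks (all peaks when fewer), intensity ties broken
#' by the lower m/z; the result is returned sorted by m/z.
#'
#' @param spectrum A spectrum object.
#' @param n Number of peaks to keep (default 40).
#' @return Two-column peak matrix.
#' @export
top_peaks <- function(spectrum, n = 40L) {
  stopifnot(n >= 1L)
  pk <- spectrum$peaks
  if (!nrow(pk)) return(pk)
  ord <- order(-pk[, "intensity"], pk[, "mz"])
  keep <- sort(ord[seq_len(min(n, nrow(pk)))])
  pk[keep, , drop = FALSE]
}

#' Retrieve database entries matching a peptide neutral mass
#'
#' Binary search on the mass-sorted database; both targets and decoys are
#' returned.
#'
#' @param peptide_neutral_mass Query mass in Da.
#' @param db A [build_database()] result.
#' @param tolerance Match tolerance in Da (default 0.6).
#' @return Subset of `db$entries`.
#' @export
find_precursor_candidates <- function(peptide_neutral_mass, db,
                                      tolerance = 0.6) {
  m <- db$entries$mass
  lo <- findInterval(peptide_neutral_mass - tolerance, m) + 1L
  hi <- findInterval(peptide_neutral_mass + tolerance, m)
  if (hi < lo) return(db$entries[0L, , drop = FALSE])
  db$entries[lo:hi, , drop = FALSE]
}

#' Match theoretical b/y ions against the top peaks
#'
#' Theoretical fragments are computed at charges 1+ and 2+. Pairs within
#' tolerance are assigned greedily by smallest absolute m/z deviation (ties
#' to the lower fragment index); each peak satisfies at most one ion and
#' each ion at most one peak.
#'
#' @param top40 Peak matrix from [top_peaks()].
#' @param entry One database entry (row of `db$entries`).
#' @param tolerance Fragment m/z tolerance in Da.
#' @return data.frame (`series`, `index`, `charge`, `frag_mz`, `peak_mz`,
#'   `intensity`); zero rows when nothing matches.
#' @export
match_fragment_ions <- function(top40, entry, tolerance = 0.05) {
  empty <- data.frame(series = character(), index = integer(),
                      charge = integer(), frag_mz = numeric(),
                      peak_mz = numeric(), intensity = numeric())
  if (!nrow(top40)) return(empty)
  frags <- theoretical_fragments(entry$sequence, parse_mods(entry$mods),
                                 max_charge = 2L)
  if (!nrow(frags)) return(empty)
  pairs <- list()
  for (f in seq_len(nrow(frags))) {
    idx <- .peaks_within(top40, frags$mz[f], tolerance)
    for (p in idx)
      pairs[[length(pairs) + 1L]] <- c(f, p, abs(top40[p, "mz"] - frags$mz[f]))
  }
  if (!length(pairs)) return(empty)
  pairs <- do.call(rbind, pairs)
  pairs <- pairs[order(pairs[, 3L], frags$index[pairs[, 1L]]), , drop = FALSE]
  used_f <- logical(nrow(frags)); used_p <- logical(nrow(top40))
  keep <- logical(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    f <- pairs[r, 1L]; p <- pairs[r, 2L]
    if (!used_f[f] && !used_p[p]) {
      keep[r] <- TRUE; used_f[f] <- TRUE; used_p[p] <- TRUE
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  out <- data.frame(series = frags$series[pairs[, 1L]],
                    index = frags$index[pairs[, 1L]],
                    charge = frags$charge[pairs[, 1L]],
                    frag_mz = frags$mz[pairs[, 1L]],
                    peak_mz = top40[pairs[, 2L], "mz"],
                    intensity = top40[pairs[, 2L], "intensity"])
  out <- out[order(out$series, out$index, out$charge), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate acceptance rule
#'
#' A decoy is always acceptable (it may match zero ions). A target is
#' acceptable only with at least three matched b/y ions regardless of charge,
#' and, when exactly three are matched, at least two of them must be
#' consecutive ions of the same series at charge 1+.
#'
#' @param matches Result of [match_fragment_ions()].
#' @param entry The database entry matched.
#' @return Logical.
#' @export
is_acceptable_candidate <- function(matches, entry) {
  if (isTRUE(entry$is_decoy)) return(TRUE)
  n <- nrow(matches)
  if (n < 3L) return(FALSE)
  if (n > 3L) return(TRUE)
  m1 <- matches[matches$charge == 1L, , drop = FALSE]
  for (s in unique(m1$series)) {
    idx <- sort(m1$index[m1$series == s])
    if (any(diff(idx) == 1L)) return(TRUE)
  }
  FALSE
}

#' PepScore of a candidate
#'
#' 100 times the ratio of the summed intensity of top-40 peaks matched to
#' charge-1+ b/y ions over the summed intensity of all top-40 peaks.
#' Charge-2+ matches count toward acceptance but contribute nothing here.
#'
#' @param matches Result of [match_fragment_ions()].
#' @param top40 The peak matrix the matches were computed from.
#' @return Score in [0, 100].
#' @export
pep_score <- function(matches, top40) {
  total <- sum(top40[, "intensity"])
  if (total <= 0) {
    warning("zero total top-40 intensity; PepScore 0", call. = FALSE)
    return(0)
  }
  100 * sum(matches$intensity[matches$charge == 1L]) / total
}

#' Search the in silico variants of one source spectrum
#'
#' Per variant, the best candidate is the acceptable database entry with the
#' highest PepScore. Across variants the winner has the most matched b/y
#' ions, ties broken by the higher PepScore, remaining ties by the lower Y0
#' m/z.
#'
#' @param variants List of `insilico_spectrum` objects sharing one source
#'   title, each optionally carrying ranked `glycan_candidates`.
#' @param db A `target_decoy_db`.
#' @param config A [glyco_config()].
#' @return A `glyco_psm` (list) or `NULL` when no variant yields an
#'   acceptable candidate.
#' @export
search_spectrum <- function(variants, db, config = glyco_config()) {
  best <- NULL
  for (v in variants) {
    t40 <- top_peaks(v, 40L)
    cands <- find_precursor_candidates(v$y0$peptide_neutral_mass, db,
                                       config$precursor_match_tolerance)
    if (!nrow(cands)) next
    v_best <- NULL
    for (i in seq_len(nrow(cands))) {
      entry <- cands[i, ]
      matches <- match_fragment_ions(t40, entry, config$fragment_tolerance)
      if (!is_acceptable_candidate(matches, entry)) next
      ps <- pep_score(matches, t40)
      cand <- list(entry = entry, matches = matches, pep_score = ps,
                   n_matched = nrow(matches))
      if (is.null(v_best) ||
          ps > v_best$pep_score ||
          (ps == v_best$pep_score && cand$n_matched > v_best$n_matched) ||
          (ps == v_best$pep_score && cand$n_matched == v_best$n_matched &&
           !entry$is_decoy && v_best$entry$is_decoy))
        v_best <- cand
    }
    if (is.null(v_best)) next
    v_best$y0 <- v$y0
    v_best$glycan_candidates <- v$glycan_candidates
    if (is.null(best) ||
        v_best$n_matched > best$n_matched ||
        (v_best$n_matched == best$n_matched &&
         v_best$pep_score > best$pep_score) ||
        (v_best$n_matched == best$n_matched &&
         v_best$pep_score == best$pep_score && v_best$y0$y0_mz < best$y0$y0_mz))
      best <- v_best
  }
  if (is.null(best)) return(NULL)
  structure(
    list(spectrum_title = variants[[1L]]$source_title,
         y0 = best$y0,
         peptide = best$entry$sequence,
         mods = best$entry$mods,
         protein = best$entry$source_protein,
         ion_matches = best$matches,
         n_matched = best$n_matched,
         pep_score = best$pep_score,
         is_decoy_hit = isTRUE(best$entry$is_decoy),
         glycan_candidates = best$glycan_candidates),
    class = "glyco_psm")
}

#' @export
print.glyco_psm <- function(x, ...) {
  cat(sprintf("<glyco_psm> %s -> %s (%s), %d ions, PepScore %.1f%s\n",
              x$spectrum_title, x$peptide, x$protein, x$n_matched, x$pep_score,
              if (x$is_decoy_hit) " [decoy]" else ""))
  invisible(x)
}

# Exact two-sided Mann-Whitney p by enumeration of all choose(n1+n2, n1)
# assignments of the pooled observations (handles ties by construction).
.mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x); n <- length(pooled)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  combos <- utils::combn(n, n1)
  u_all <- apply(combos, 2L, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

#' Target-decoy PepScore summary
#'
#' Bins target and decoy PepScores into equal-width bins over [0, 100] (the
#' machine-readable twin of the target-decoy score diagram) and tests whether
#' the two score samples come from one distribution with a two-sided
#' Mann-Whitney U-test: exact enumeration when both groups have at most 8
#' scores, the tie-corrected normal approximation otherwise.
#'
#' @param psms List of `glyco_psm` objects.
#' @param n_bins Number of score bins.
#' @return A `td_summary`: list with `bins` (data.frame `bin_lo`, `bin_hi`,
#'   `n_target`, `n_decoy`), `U` (target-based statistic), `p_value`,
#'   `n_target`, `n_decoy`, `note`.
#' @export
target_decoy_summary <- function(psms, n_bins = 20L) {
  scores <- vapply(psms, `[[`, 0, "pep_score")
  decoy <- vapply(psms, `[[`, TRUE, "is_decoy_hit")
  ts <- scores[!decoy]; ds <- scores[decoy]
  breaks <- seq(0, 100, length.out = n_bins + 1L)
  bin <- function(v) {
    idx <- pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1L), n_bins)
    tabulate(idx, nbins = n_bins)
  }
  bins <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
                     n_target = bin(ts), n_decoy = bin(ds))
  U <- NA_real_; p <- NA_real_; note <- ""
  if (length(ts) >= 1L && length(ds) >= 1L) {
    r <- rank(c(ts, ds))
    U <- sum(r[seq_along(ts)]) - length(ts) * (length(ts) + 1) / 2
    if (length(unique(c(ts, ds))) == 1L) {
      p <- 1; note <- "degenerate: all scores identical"
    } else if (length(ts) <= 8L && length(ds) <= 8L) {
      p <- .mw_exact(ts, ds)
    } else {
      p <- suppressWarnings(stats::wilcox.test(ts, ds, exact = FALSE)$p.value)
    }
  } else {
    note <- "test skipped: need at least one target and one decoy hit"
  }
  structure(list(bins = bins, U = U, p_value = p,
                 n_target = length(ts), n_decoy = length(ds), note = note),
            class = "td_summary")
}

#' @export
print.td_summary <- function(x, ...) {
  cat(sprintf("<td_summary> %d target vs %d decoy hits; U = %s, p = %s%s\n",
              x$n_target, x$n_decoy, format(x$U), format(x$p_value),
              if (nzchar(x$note)) paste0(" (", x$note, ")") else ""))
  invisible(x)
}

#' Decoy-based FDR estimate at a score threshold
#'
#' Optional diagnostic (an extension beyond the score diagram and U-test):
#' the ratio of decoy to target hits at or above each PSM's score.
#'
#' @param psms List of `glyco_psm` objects.
#' @return Numeric vector of estimated FDRs, one per PSM.
#' @export
estimate_fdr <- function(psms) {
  scores <- vapply(psms, `[[`, 0, "pep_score")
  decoy <- vapply(psms, `[[`, TRUE, "is_decoy_hit")
  vapply(scores, function(s) {
    nt <- sum(scores >= s & !decoy)
    nd <- sum(scores >= s & decoy)
    if (nt == 0L) ifelse(nd > 0L, Inf, 0) else nd / nt
  }, 0)
}
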