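# Summary tables and the report integrator: join peptide-level PSMs from an
# external engine with glycan-level results into a site-specific report.

# Strip the "::Y0_<k>" suffix the in silico writer appends.
.strip_y0_suffix <- function(title) sub("::Y0_\\d+$", "", title)
.y0_index <- function(title) {
  m <- regmatches(title, regexpr("::Y0_(\\d+)$", title))
  ifelse(lengths(regmatches(title, gregexpr("::Y0_(\\d+)$", title))) > 0,
         suppressWarnings(as.integer(sub("^.*::Y0_", "", title))), NA_integer_)
}

#' Write the untargeted pipeline summary
#'
#' One row per (spectrum, Y0 candidate) for spectra that passed the oxonium
#' filter and contain at least one Y-ion triplet pattern; all other spectra
#' go to a rejected-spectra audit table with the failure reason.
#'
#' @param results A [run_untargeted()] result.
#' @param path Summary TSV path; the audit table goes to
#'   `<path>.rejected.tsv`. `NULL` writes nothing.
#' @return List with `summary` and `rejected` data.frames, invisibly.
#' @export
write_untargeted_summary <- function(results, path = NULL) {
  summary <- results$summary
  rejected <- results$rejected
  if (!is.null(path)) {
    utils::write.table(summary, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(rejected, paste0(path, ".rejected.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(list(summary = summary, rejected = rejected))
}

#' Integrate external PSMs with glycan-level results
#'
#' Joins a PSM table (titles following the in silico `::Y0_<k>` suffix
#' convention, or raw source titles) with the per-Y0 rows of a pipeline run.
#' When several PSMs share a title, the best search score is kept and the
#' rest go to the unmatched table. Rows are sorted by protein, then peptide,
#' then retention time.
#'
#' @param psms data.frame from [read_psm_table()].
#' @param glyco_results A [run_untargeted()] (or [run_targeted()]) result
#'   whose `summary` has per-Y0 rows.
#' @param spectra The source spectra list (for retention times).
#' @param proteins Optional named protein sequences; when given, sequon sites
#'   are reported as 1-based protein coordinates, otherwise as 1-based
#'   positions within the peptide.
#' @return List with `rows` (the site-specific report), `unmatched_psms`,
#'   `unmatched_glyco`.
#' @export
integrate_reports <- function(psms, glyco_results, spectra, proteins = NULL) {
  summary <- glyco_results$summary
  stopifnot(is.data.frame(psms))
  rts <- stats::setNames(
    vapply(spectra, function(s) if (is.na(s$rt)) NA_real_ else s$rt, 0),
    vapply(spectra, `[[`, "", "title"))
  psms$source <- .strip_y0_suffix(psms$title)
  psms$variant <- .y0_index(psms$title)
  # best score per title; the rest are unmatched duplicates
  ord <- order(psms$title, -psms$score)
  psms <- psms[ord, , drop = FALSE]
  dup <- duplicated(psms$title)
  dup_rows <- psms[dup, , drop = FALSE]
  psms_best <- psms[!dup, , drop = FALSE]
  key_glyco <- paste(summary$title, summary$y0_index, sep = "#")
  rows <- list(); unmatched <- list()
  for (i in seq_len(nrow(psms_best))) {
    p <- psms_best[i, ]
    k <- if (is.na(p$variant)) {
      w <- which(summary$title == p$source)
      if (length(w)) w[1L] else NA_integer_
    } else {
      match(paste(p$source, p$variant, sep = "#"), key_glyco)
    }
    if (is.na(k)) {
      unmatched[[length(unmatched) + 1L]] <- p
      next
    }
    g <- summary[k, ]
    sites <- .report_sites(p$peptide, proteins)
    z <- g$y0_charge
    rows[[length(rows) + 1L]] <- data.frame(
      protein = p$protein, peptide = p$peptide, sites = sites,
      rt = unname(rts[p$source]), score = p$score, evalue = p$evalue,
      glycan_composition = g$top_composition,
      glycan_alternatives = g$alt_compositions,
      y0_mz = g$y0_mz,
      y1_mz = g$y0_mz + .GLCNAC / z,
      y2_mz = g$y0_mz + 2 * .GLCNAC / z,
      spectrum_title = p$title)
  }
  if (!length(rows) && nrow(psms_best))
    stop("no PSM title joined any glycan result; check the '::Y0_<k>' title ",
         "suffix convention", call. = FALSE)
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein = character(), peptide = character())
  if (nrow(rows)) {
    rows <- rows[order(rows$protein, rows$peptide, rows$rt), , drop = FALSE]
    rownames(rows) <- NULL
  }
  unmatched_psms <- rbind(
    if (length(unmatched)) do.call(rbind, unmatched) else NULL,
    dup_rows)
  matched_keys <- paste(psms_best$source, psms_best$variant, sep = "#")
  unmatched_glyco <- summary[!(key_glyco %in% matched_keys) &
                               !(summary$title %in% psms_best$source[
                                 is.na(psms_best$variant)]), , drop = FALSE]
  list(rows = rows,
       unmatched_psms = if (is.null(unmatched_psms))
         psms[0L, , drop = FALSE] else unmatched_psms,
       unmatched_glyco = unmatched_glyco)
}

# 1-based sequon site positions: protein coordinates when the protein list
# is available, in-peptide positions otherwise.
.report_sites <- function(peptide, proteins) {
  in_pep <- .sequons_in_peptide(peptide) + 1L
  if (!is.null(proteins)) {
    for (acc in names(proteins)) {
      off <- regexpr(peptide, proteins[[acc]], fixed = TRUE)
      if (off > 0L) {
        glob <- find_sequons(proteins[[acc]], off - 1L, nchar(peptide))
        return(paste(off + glob, collapse = ","))
      }
    }
  }
  paste(in_pep, collapse = ",")
}
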