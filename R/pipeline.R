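# End-to-end drivers: the untargeted path (filter -> Y0 detection -> in
# silico spectra -> glycan inference) and the targeted path (additionally
# database build -> search -> target-decoy diagnostics).

.log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# Per-spectrum untargeted processing; returns NULL for rejected spectra.
.process_spectrum <- function(sp, config, table) {
  fr <- is_glycopeptide_spectrum(sp, config)
  if (!fr$passed)
    return(list(rejected = data.frame(title = sp$title,
                                      reason = "failed oxonium filter")))
  matches <- detect_y1_patterns(sp, config)
  if (!length(matches))
    return(list(rejected = data.frame(title = sp$title,
                                      reason = "no Y1-ion triplet pattern")))
  variants <- list(); rows <- list()
  for (k in seq_along(matches)) {
    m <- matches[[k]]
    ladder <- extend_y_ladder(sp, m, config)
    gm <- tryCatch(glycan_neutral_mass(sp, m), error = function(e) NA_real_)
    if (is.na(gm)) next
    cands <- match_compositions(gm, table)
    ranked <- score_and_rank_compositions(cands, ladder, fr,
                                          config$glycan_score_weights)
    ins <- build_insilico_spectrum(sp, m, ladder, fr, config,
                                   variant_index = k)
    if (is.null(ins)) next
    ins$glycan_candidates <- ranked
    variants[[length(variants) + 1L]] <- ins
    top <- if (nrow(ranked)) composition_string(ranked[1L, ]) else ""
    alts <- if (nrow(ranked) > 1L)
      paste(vapply(2:min(nrow(ranked), 4L), function(r)
        composition_string(ranked[r, ]), ""), collapse = "|") else ""
    rows[[length(rows) + 1L]] <- data.frame(
      title = sp$title, y0_index = k, y0_mz = m$y0_mz,
      y0_charge = m$charge, pattern = m$pattern,
      ladder_length = nrow(ladder$steps), glycan_mass = gm,
      top_composition = top, alt_compositions = alts)
  }
  if (!length(variants))
    return(list(rejected = data.frame(title = sp$title,
                                      reason = "no usable Y0 candidate")))
  list(variants = variants, rows = do.call(rbind, rows))
}

#' Run the untargeted identification pipeline
#'
#' Filters each spectrum by oxonium evidence, detects Y0 candidates, builds
#' in silico peptide spectra and infers glycan compositions. The in silico
#' spectra are ready for an external database search engine.
#'
#' @param spectra List of `glyco_spectrum` objects, or an MGF path.
#' @param config A [glyco_config()].
#' @param out_dir Optional output directory: writes `insilico.mgf`,
#'   `summary.tsv` (+ rejected audit) and `manifest.json`.
#' @return List with `insilico` (list of in silico spectra, grouped order),
#'   `summary`, `rejected`, `manifest`.
#' @export
run_untargeted <- function(spectra, config = glyco_config(), out_dir = NULL) {
  if (is.character(spectra)) spectra <- read_mgf(spectra)
  table <- default_composition_table(config)
  insilico <- list(); srows <- list(); rrows <- list()
  n_pass <- 0L; n_pattern <- 0L
  for (sp in spectra) {
    res <- .process_spectrum(sp, config, table)
    if (!is.null(res$rejected)) {
      rrows[[length(rrows) + 1L]] <- res$rejected
      if (res$rejected$reason != "failed oxonium filter") n_pass <- n_pass + 1L
      next
    }
    n_pass <- n_pass + 1L; n_pattern <- n_pattern + 1L
    insilico <- c(insilico, res$variants)
    srows[[length(srows) + 1L]] <- res$rows
  }
  summary <- if (length(srows)) do.call(rbind, srows) else
    data.frame(title = character(), y0_index = integer(), y0_mz = numeric(),
               y0_charge = integer(), pattern = character(),
               ladder_length = integer(), glycan_mass = numeric(),
               top_composition = character(), alt_compositions = character())
  rejected <- if (length(rrows)) do.call(rbind, rrows) else
    data.frame(title = character(), reason = character())
  rownames(summary) <- rownames(rejected) <- NULL
  manifest <- list(
    subcommand = "untargeted", seed = config$random_seed,
    config_digest = config_digest(config), timestamp = format(Sys.time()),
    counts = list(spectra_read = length(spectra), passed_filter = n_pass,
                  with_pattern = n_pattern, insilico = length(insilico)))
  .log_stage("untargeted", "%d spectra read, %d passed filter, %d with >=1 pattern",
             length(spectra), n_pass, n_pattern)
  out <- list(insilico = insilico, summary = summary, rejected = rejected,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (length(insilico))
      write_mgf(insilico, file.path(out_dir, "insilico.mgf"))
    write_untargeted_summary(out, file.path(out_dir, "summary.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Run the targeted identification pipeline
#'
#' The untargeted stages followed by target-decoy database construction from
#' the user's proteins, in silico spectrum search, PepScore-based candidate
#' selection, and the target-decoy Mann-Whitney diagnostic.
#'
#' @param spectra List of `glyco_spectrum` objects, or an MGF path.
#' @param proteins Named character vector (at most 10 sequences) or a
#'   FASTA/plain-text path.
#' @param config A [glyco_config()].
#' @param out_dir Optional output directory: `psms.tsv`, `td_summary.tsv`,
#'   `manifest.json`.
#' @return List with `psms` (list of `glyco_psm`), `psm_table` (data.frame
#'   incl. an `est_fdr` diagnostic column), `td_summary`, `db`, `untargeted`,
#'   `manifest`.
#' @export
run_targeted <- function(spectra, proteins, config = glyco_config(),
                         out_dir = NULL) {
  if (is.character(proteins) && length(proteins) == 1L && file.exists(proteins))
    proteins <- read_protein_sequences(proteins)
  if (length(proteins) > 10L)
    stop("at most 10 protein sequences are allowed", call. = FALSE)
  un <- run_untargeted(spectra, config)
  db <- build_database(proteins, config)
  .log_stage("targeted", "database: %d targets, %d decoys", db$n_targets,
             db$n_decoys)
  groups <- split(un$insilico,
                  vapply(un$insilico, `[[`, "", "source_title"))
  psms <- Filter(Negate(is.null),
                 lapply(groups, search_spectrum, db = db, config = config))
  psms <- unname(psms)
  td <- if (length(psms)) target_decoy_summary(psms) else NULL
  psm_table <- if (length(psms)) {
    data.frame(
      title = vapply(psms, `[[`, "", "spectrum_title"),
      peptide = vapply(psms, `[[`, "", "peptide"),
      mods = vapply(psms, `[[`, "", "mods"),
      protein = vapply(psms, `[[`, "", "protein"),
      is_decoy = vapply(psms, `[[`, TRUE, "is_decoy_hit"),
      n_matched = vapply(psms, `[[`, 0L, "n_matched"),
      pep_score = vapply(psms, `[[`, 0, "pep_score"),
      y0_mz = vapply(psms, function(p) p$y0$y0_mz, 0),
      glycan_composition = vapply(psms, function(p) {
        gc <- p$glycan_candidates
        if (!is.null(gc) && nrow(gc)) composition_string(gc[1L, ]) else ""
      }, ""),
      est_fdr = estimate_fdr(psms))  # optional decoy-based FDR diagnostic
  } else {
    data.frame(title = character(), peptide = character(), mods = character(),
               protein = character(), is_decoy = logical(),
               n_matched = integer(), pep_score = numeric(),
               y0_mz = numeric(), glycan_composition = character(),
               est_fdr = numeric())
  }
  manifest <- c(un$manifest[setdiff(names(un$manifest), "subcommand")],
                list(subcommand = "targeted",
                     counts_targeted = list(
                       n_targets = db$n_targets, n_decoys = db$n_decoys,
                       psms = length(psms),
                       target_hits = sum(psm_table$is_decoy == FALSE),
                       decoy_hits = sum(psm_table$is_decoy == TRUE))))
  .log_stage("targeted", "%d PSM(s): %d target, %d decoy", length(psms),
             sum(!psm_table$is_decoy), sum(psm_table$is_decoy))
  out <- list(psms = psms, psm_table = psm_table, td_summary = td, db = db,
              untargeted = un, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(psm_table, file.path(out_dir, "psms.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (!is.null(td))
      utils::write.table(td$bins, file.path(out_dir, "td_summary.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Bundled reference sequence: horseradish peroxidase C1A
#'
#' The canonical HRP C1A precursor (UniProt P00433: 30-residue signal
#' peptide, mature chain, C-terminal propeptide), bundled for the targeted
#' worked example. Returned untrimmed; the reference analysis digests the
#' precursor as-is.
#'
#' @return Named character vector of length 1.
#' @export
hrp_sequence <- function() {
  path <- system.file("extdata", "P00433_HRP_C1A.fasta",
                      package = "glycotrident")
  read_protein_sequences(path, max_count = 1L)
}
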