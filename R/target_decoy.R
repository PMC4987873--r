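# Customized target-decoy glycopeptide sequence database.
#
# Targets: tryptic sequon-bearing peptides of the input proteins, with
# missed cleavages and modification variants. Decoys: sequence-permuted
# counterparts (reversal and even-odd switching) with the sequon block
# re-placed at the original and at four random locations, realized as
# mass-preserving block swaps so every decoy is exactly isobaric with its
# source target and genuinely competes at the precursor-match stage.

# ---- mods string helpers ("name@pos;name@pos", 1-based positions) ----

format_mods <- function(mods) {
  if (is.null(mods) || !nrow(mods)) return("")
  mods <- mods[order(mods$pos, mods$name), , drop = FALSE]
  paste(sprintf("%s@%d", mods$name, mods$pos), collapse = ";")
}

parse_mods <- function(s, mod_table = default_modifications()) {
  if (is.na(s) || !nzchar(s))
    return(data.frame(name = character(), pos = integer(), delta = numeric()))
  parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1L]], "@", fixed = TRUE)
  name <- vapply(parts, `[`, "", 1L)
  pos <- as.integer(vapply(parts, `[`, "", 2L))
  delta <- vapply(name, function(n) mod_table[[n]]$delta_mass, 0)
  data.frame(name = name, pos = pos, delta = unname(delta))
}

# ---- digestion and sequon detection ----

#' In silico enzymatic digestion
#'
#' Trypsin rule: cleave after K or R except before P. Returns every fully
#' specific peptide with 0..`max_missed` internal missed cleavage sites
#' (semi-specific peptides are not generated).
#'
#' @param protein_sequence Uppercase protein string.
#' @param enzyme Enzyme name; only `"trypsin"` is supported.
#' @param max_missed Maximum missed cleavages.
#' @return data.frame with columns `peptide`, `start` (0-based offset in the
#'   protein) and `missed`.
#' @export
digest <- function(protein_sequence, enzyme = "trypsin", max_missed = 2L) {
  if (!identical(enzyme, "trypsin"))
    stop("unknown enzyme: ", enzyme, call. = FALSE)
  stopifnot(max_missed >= 0L)
  aa <- strsplit(protein_sequence, "", fixed = TRUE)[[1L]]
  L <- length(aa)
  after <- which(aa %in% c("K", "R"))
  after <- after[after == L | aa[pmin(after + 1L, L)] != "P"]
  cuts <- unique(c(0L, after, L))          # cut positions (0-based boundaries)
  out <- list()
  for (a in seq_len(length(cuts) - 1L)) {
    for (m in 0:max_missed) {
      b <- a + 1L + m
      if (b > length(cuts)) break
      out[[length(out) + 1L]] <- data.frame(
        peptide = substr(protein_sequence, cuts[a] + 1L, cuts[b]),
        start = cuts[a], missed = m)
    }
  }
  do.call(rbind, out)
}

#' Locate N-glycosylation sequons within a peptide
#'
#' A sequon is N-X-S/T with X any residue except proline. The +1/+2 context
#' is taken from the **protein**, so a sequon truncated at the peptide
#' C-terminus (its S/T lying in the next tryptic peptide) still counts.
#'
#' @param protein_sequence The protein the peptide was digested from.
#' @param peptide_start 0-based offset of the peptide in the protein.
#' @param peptide_length Peptide length.
#' @return Integer vector of 0-based in-peptide indices of sequon asparagines.
#' @export
find_sequons <- function(protein_sequence, peptide_start, peptide_length) {
  L <- nchar(protein_sequence)
  if (peptide_start < 0L || peptide_start + peptide_length > L)
    stop("peptide span outside protein", call. = FALSE)
  aa <- strsplit(protein_sequence, "", fixed = TRUE)[[1L]]
  out <- integer()
  for (i in seq_len(peptide_length) - 1L) {
    g <- peptide_start + i + 1L            # 1-based global position of N
    if (aa[g] != "N") next
    if (g + 2L > L) next
    if (aa[g + 1L] == "P") next
    if (aa[g + 2L] %in% c("S", "T")) out <- c(out, i)
  }
  out
}

# In-peptide sequon detection for standalone sequences (decoys).
.sequons_in_peptide <- function(sequence) {
  find_sequons(sequence, 0L, nchar(sequence))
}

# ---- target enumeration ----

#' Enumerate target glycopeptide entries
#'
#' Digests each protein, keeps sequon-bearing peptides within the configured
#' length range, applies fixed modifications everywhere applicable, expands
#' variable-modification combinations up to `max_var_mods` per peptide
#' (deamidation is never placed on a sequon asparagine, which carries the
#' glycan), and deduplicates on (sequence, modifications).
#'
#' @param proteins Named character vector of protein sequences (at most 10).
#' @param config A [glyco_config()].
#' @return data.frame of target entries: `sequence`, `mods`, `sequons`
#'   (comma-separated 0-based indices), `missed`, `is_decoy`, `transform`,
#'   `source_protein`, `source_target`, `mass`.
#' @export
enumerate_target_peptides <- function(proteins, config = glyco_config()) {
  if (length(proteins) > 10L)
    stop("at most 10 protein sequences are allowed", call. = FALSE)
  if (is.null(names(proteins)))
    names(proteins) <- sprintf("seq%02d", seq_along(proteins))
  mod_table <- default_modifications()
  fixed <- Filter(function(m) m$mode == "fixed", mod_table)
  variable <- Filter(function(m) m$mode == "variable", mod_table)
  lr <- config$peptide_length_range
  rows <- list()
  for (acc in names(proteins)) {
    prot <- proteins[[acc]]
    dg <- digest(prot, config$enzyme, config$max_missed_cleavages)
    any_sequon <- FALSE
    for (r in seq_len(nrow(dg))) {
      pep <- dg$peptide[r]
      sq <- find_sequons(prot, dg$start[r], nchar(pep))
      if (!length(sq)) next
      any_sequon <- TRUE
      if (nchar(pep) < lr[1] || nchar(pep) > lr[2]) next
      aa <- strsplit(pep, "", fixed = TRUE)[[1L]]
      fixed_mods <- do.call(rbind, lapply(fixed, function(m) {
        pos <- which(aa %in% m$target_residues)
        if (!length(pos)) return(NULL)
        data.frame(name = m$name, pos = pos, delta = m$delta_mass)
      }))
      # variable sites; deamidation barred on sequon N
      sites <- do.call(rbind, lapply(variable, function(m) {
        pos <- which(aa %in% m$target_residues)
        if (m$name == "deam") pos <- setdiff(pos, sq + 1L)
        if (!length(pos)) return(NULL)
        data.frame(name = m$name, pos = pos, delta = m$delta_mass)
      }))
      n_sites <- if (is.null(sites)) 0L else nrow(sites)
      combos <- list(integer())
      if (n_sites > 0L) {
        for (k in seq_len(min(config$max_var_mods, n_sites)))
          combos <- c(combos, utils::combn(n_sites, k, simplify = FALSE))
      }
      for (cb in combos) {
        mods <- rbind(fixed_mods, if (length(cb)) sites[cb, , drop = FALSE])
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = pep,
          mods = format_mods(mods),
          sequons = paste(sq, collapse = ","),
          missed = dg$missed[r],
          is_decoy = FALSE, transform = "none",
          source_protein = acc, source_target = NA_character_,
          mass = peptide_neutral_mass(pep, mods))
      }
    }
    if (!any_sequon)
      warning("protein '", acc, "' has no sequon-bearing peptide", call. = FALSE)
  }
  if (!length(rows))
    return(data.frame(sequence = character(), mods = character(),
                      sequons = character(), missed = integer(),
                      is_decoy = logical(), transform = character(),
                      source_protein = character(),
                      source_target = character(), mass = numeric()))
  out <- do.call(rbind, rows)
  out <- out[!duplicated(paste(out$sequence, out$mods, sep = "|")), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- decoy transforms ----

# Reverse and even-odd-switch sequence transforms.
.transform_sequence <- function(sequence, transform) {
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(aa)
  if (transform == "reverse") {
    aa <- rev(aa)
  } else if (transform == "evenodd") {
    for (i in seq(1L, L - L %% 2L, by = 2L)) {
      tmp <- aa[i]; aa[i] <- aa[i + 1L]; aa[i + 1L] <- tmp
    }
  } else stop("unknown transform: ", transform, call. = FALSE)
  paste(aa, collapse = "")
}

# Swap the equal-length disjoint blocks starting at 1-based i and j.
.swap_blocks <- function(aa, i, j, bl) {
  ri <- i:(i + bl - 1L); rj <- j:(j + bl - 1L)
  tmp <- aa[rj]; aa[rj] <- aa[ri]; aa[ri] <- tmp
  aa
}

# Restore the residue block `block` at 1-based position p of `aa` by swapping
# each needed residue into place from an unplaced position. Pure permutation:
# the residue multiset is untouched.
.place_block <- function(aa, block, p, placed) {
  for (k in seq_along(block)) {
    tgt <- p + k - 1L
    if (aa[tgt] != block[k]) {
      q <- which(aa == block[k] & !placed & seq_along(aa) != tgt)[1L]
      if (is.na(q)) stop("internal: block residue not available", call. = FALSE)
      tmp <- aa[tgt]; aa[tgt] <- aa[q]; aa[q] <- tmp
    }
    placed[tgt] <- TRUE
  }
  list(aa = aa, placed = placed)
}

#' Generate decoy entries for one target peptide
#'
#' For each transform (sequence reversal; even-odd position switching), the
#' sequon tri-residue block is first restored at its original location, then
#' relocated to four randomly drawn other positions by mass-preserving block
#' swaps. Multi-sequon targets iterate the relocation one sequon at a time
#' with the others held at their original positions. The expected yield is
#' 2 x 5 decoys per sequon before deduplication (~10 for a single-sequon
#' target); duplicates of the target and of each other are then removed.
#'
#' @param target One row of [enumerate_target_peptides()] output (data.frame
#'   or list with `sequence`, `mods`, `sequons`, `mass`, `source_protein`).
#' @param config A [glyco_config()]; decoy placement draws from the current
#'   RNG state (seed it once per database build).
#' @param dedup Remove duplicate decoys (default). When `FALSE`, every raw
#'   variant is returned.
#' @return data.frame of decoy entries (same columns as targets) with
#'   attribute `n_raw`, the pre-deduplication count.
#' @export
generate_decoys <- function(target, config = glyco_config(), dedup = TRUE) {
  seq0 <- target$sequence
  L <- nchar(seq0)
  sq <- as.integer(strsplit(target$sequons, ",", fixed = TRUE)[[1L]])
  stopifnot(length(sq) >= 1L)
  aa0 <- strsplit(seq0, "", fixed = TRUE)[[1L]]
  p_all <- sq + 1L                               # 1-based block starts
  bl_all <- pmin(3L, L - p_all + 1L)             # truncated C-terminal blocks
  mod_counts <- table(parse_mods(target$mods)$name)
  out <- list(); n_raw <- 0L
  for (tr in c("reverse", "evenodd")) {
    d0 <- strsplit(.transform_sequence(seq0, tr), "", fixed = TRUE)[[1L]]
    placed <- logical(L)
    for (s in seq_along(p_all)) {
      block <- aa0[p_all[s]:(p_all[s] + bl_all[s] - 1L)]
      res <- .place_block(d0, block, p_all[s], placed)
      d0 <- res$aa; placed <- res$placed
    }
    block_rng <- function(p, bl) p:(p + bl - 1L)
    for (s in seq_along(p_all)) {
      p <- p_all[s]; bl <- bl_all[s]
      other_rng <- unlist(lapply(setdiff(seq_along(p_all), s),
                                 function(m) block_rng(p_all[m], bl_all[m])))
      valid <- Filter(function(j) {
        rng <- block_rng(j, bl)
        !any(rng %in% other_rng) && !any(rng %in% block_rng(p, bl))
      }, setdiff(seq_len(L - bl + 1L), p))
      picks <- if (length(valid) >= 4L) sample(valid, 4L) else {
        warning("target '", seq0, "': only ", length(valid),
                " alternative sequon placements available", call. = FALSE)
        if (length(valid)) sample(valid, length(valid)) else integer()
      }
      variants <- c(list(d0),
                    lapply(picks, function(j) .swap_blocks(d0, p, j, bl)))
      n_raw <- n_raw + 1L + length(picks)        # variant 0 + relocations
      sequon_sets <- c(list(p_all - 1L),
                       lapply(picks, function(j) sort(c(setdiff(p_all, p), j)) - 1L))
      for (v in seq_along(variants)) {
        dseq <- paste(variants[[v]], collapse = "")
        out[[length(out) + 1L]] <- data.frame(
          sequence = dseq,
          mods = .assign_decoy_mods(variants[[v]], sequon_sets[[v]] + 1L,
                                    mod_counts),
          sequons = paste(sequon_sets[[v]], collapse = ","),
          missed = target$missed,
          is_decoy = TRUE, transform = tr,
          source_protein = target$source_protein,
          source_target = seq0,
          mass = target$mass)
      }
    }
  }
  res <- do.call(rbind, out)
  if (dedup) {
    res <- res[res$sequence != seq0, , drop = FALSE]
    res <- res[!duplicated(paste(res$sequence, res$mods, sep = "|")), , drop = FALSE]
  }
  rownames(res) <- NULL
  attr(res, "n_raw") <- n_raw
  res
}

# Re-place a target's modification multiset onto a decoy sequence: fixed
# carbamidomethyl goes on every cysteine; deamidation on the first non-sequon
# N/Q positions; oxidation on the first methionines. Only the multiset
# matters for mass, which stays exactly equal to the target's.
.assign_decoy_mods <- function(aa, sequon_starts, mod_counts) {
  mods <- list()
  if (!is.na(mod_counts["cam"]) || any(aa == "C")) {
    pos <- which(aa == "C")
    if (length(pos))
      mods[[length(mods) + 1L]] <- data.frame(name = "cam", pos = pos,
                                              delta = 57.02146372)
  }
  n_deam <- if (is.na(mod_counts["deam"])) 0L else mod_counts[["deam"]]
  if (n_deam > 0L) {
    pos <- which(aa %in% c("N", "Q"))
    pos <- setdiff(pos, sequon_starts)          # sequon N carries the glycan
    pos <- utils::head(pos, n_deam)
    mods[[length(mods) + 1L]] <- data.frame(name = "deam", pos = pos,
                                            delta = 0.98401587)
  }
  n_ox <- if (is.na(mod_counts["ox"])) 0L else mod_counts[["ox"]]
  if (n_ox > 0L) {
    pos <- utils::head(which(aa == "M"), n_ox)
    mods[[length(mods) + 1L]] <- data.frame(name = "ox", pos = pos,
                                            delta = 15.99491462)
  }
  format_mods(if (length(mods)) do.call(rbind, mods) else NULL)
}

#' Build the concatenated target-decoy database
#'
#' Deterministic given (sequences, config, seed): the seed is set once and
#' decoy positions are drawn in target entry order. Decoys equal to any
#' target sequence are removed, as are duplicate (sequence, mods) pairs.
#' Entries are sorted ascending by neutral mass.
#'
#' @param proteins Named character vector of protein sequences.
#' @param config A [glyco_config()]; `random_seed` governs decoy placement.
#' @return A `target_decoy_db`: list with `entries` (mass-sorted data.frame),
#'   `n_targets`, `n_decoys`, `seed`, `config_digest`.
#' @export
build_database <- function(proteins, config = glyco_config()) {
  targets <- enumerate_target_peptides(proteins, config)
  if (!nrow(targets)) stop("no target peptides; empty database", call. = FALSE)
  set.seed(config$random_seed)
  decoys <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i)
    generate_decoys(targets[i, ], config)))
  decoys <- decoys[!(decoys$sequence %in% targets$sequence), , drop = FALSE]
  decoys <- decoys[!duplicated(paste(decoys$sequence, decoys$mods, sep = "|")), ,
                   drop = FALSE]
  entries <- rbind(targets, decoys)
  entries <- entries[order(entries$mass, entries$sequence, entries$mods), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  structure(
    list(entries = entries, n_targets = nrow(targets), n_decoys = nrow(decoys),
         seed = config$random_seed, config_digest = config_digest(config)),
    class = "target_decoy_db")
}

#' @export
print.target_decoy_db <- function(x, ...) {
  cat(sprintf("<target_decoy_db> %d targets + %d decoys (ratio 1:%.1f), seed %d\n",
              x$n_targets, x$n_decoys, x$n_decoys / x$n_targets, x$seed))
  invisible(x)
}
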