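# Glycan composition inference: enumerate compositions under N-glycan
# biosynthesis constraints into a mass-indexed table, match observed glycan
# masses, and rank candidates by B-/Y-ion evidence.
#
# Constraint set (the trimannosyl core plus standard antenna rules):
#   HexNAc >= 2; Hex >= 3; dHex <= HexNAc; NeuAc + NeuGc <= max(1, HexNAc - 2);
#   total residues <= glycan_max_residues.

#' Build the glycan composition look-up table
#'
#' Deterministically enumerates every composition over
#' {Hex, HexNAc, dHex, NeuAc, NeuGc} satisfying the biosynthesis constraints,
#' sorted ascending by mass (ties by composition counts for a stable order).
#'
#' @param config A [glyco_config()]; uses `glycan_max_residues`.
#' @return data.frame of class `glycan_table` with one count column per
#'   monosaccharide plus `mass` (Da).
#' @export
build_composition_table <- function(config = glyco_config()) {
  max_res <- config$glycan_max_residues
  stopifnot(max_res >= 5L)
  mono <- monosaccharide_masses()
  chunks <- list()
  for (hn in 2:(max_res - 3L)) {
    for (hex in 3:(max_res - hn)) {
      rem <- max_res - hn - hex
      s_cap <- max(1L, hn - 2L)
      g <- expand.grid(dHex = 0:min(hn, rem),
                       NeuAc = 0:min(s_cap, rem),
                       NeuGc = 0:min(s_cap, rem),
                       KEEP.OUT.ATTRS = FALSE)
      g <- g[g$NeuAc + g$NeuGc <= pmin(s_cap, rem - g$dHex), , drop = FALSE]
      if (!nrow(g)) next
      g$Hex <- hex; g$HexNAc <- hn
      chunks[[length(chunks) + 1L]] <- g
    }
  }
  tab <- do.call(rbind, chunks)
  tab <- tab[, c("Hex", "HexNAc", "dHex", "NeuAc", "NeuGc")]
  tab$mass <- as.numeric(as.matrix(tab) %*% mono[colnames(tab)])
  tab <- tab[order(tab$mass, tab$Hex, tab$HexNAc, tab$dHex, tab$NeuAc, tab$NeuGc), ]
  rownames(tab) <- NULL
  class(tab) <- c("glycan_table", "data.frame")
  tab
}

# Cached default table (built on first use; deterministic).
.glycan_cache <- new.env(parent = emptyenv())

default_composition_table <- function(config = glyco_config()) {
  key <- as.character(config$glycan_max_residues)
  if (is.null(.glycan_cache[[key]]))
    .glycan_cache[[key]] <- build_composition_table(config)
  .glycan_cache[[key]]
}

#' Default composition match tolerance
#'
#' Scales with the glycan mass to absorb ladder-accumulated error:
#' `0.02 * (1 + glycan_mass / 2000)` Da.
#'
#' @param glycan_mass Observed glycan neutral mass (Da).
#' @return Tolerance in Da.
#' @export
composition_tolerance <- function(glycan_mass) 0.02 * (1 + glycan_mass / 2000)

#' Match an observed glycan mass against the composition table
#'
#' Binary search on the mass-sorted table; results ordered by increasing
#' absolute mass deviation.
#'
#' @param glycan_mass Observed glycan neutral mass (Da, > 0).
#' @param table A `glycan_table` from [build_composition_table()].
#' @param tolerance Match tolerance (Da); defaults to
#'   [composition_tolerance()] of the query mass.
#' @return Subset of `table` with an extra `delta` column (entry mass minus
#'   query); zero rows when nothing matches.
#' @export
match_compositions <- function(glycan_mass, table,
                               tolerance = composition_tolerance(glycan_mass)) {
  stopifnot(glycan_mass > 0, tolerance > 0)
  m <- table$mass
  lo <- findInterval(glycan_mass - tolerance, m) + 1L
  hi <- findInterval(glycan_mass + tolerance, m)
  if (hi < lo) {
    out <- table[0L, , drop = FALSE]
    out$delta <- numeric()
    return(out)
  }
  out <- table[lo:hi, , drop = FALSE]
  out$delta <- out$mass - glycan_mass
  out <- out[order(abs(out$delta)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# "Hex:5;HexNAc:2" style composition strings.
composition_string <- function(row) {
  types <- c("Hex", "HexNAc", "dHex", "NeuAc", "NeuGc")
  counts <- unlist(row[types])
  nz <- counts > 0
  paste(sprintf("%s:%d", types[nz], counts[nz]), collapse = ";")
}

#' Score and rank candidate glycan compositions
#'
#' Two-term evidence score in [0, 1]:
#' `w_ladder * coverage + w_oxonium * type_evidence`, where `coverage` is the
#' fraction of the candidate's residue multiset coverable by the observed
#' Y-ladder step multiset and `type_evidence` the fraction of the candidate's
#' distinct monosaccharide types seen among the matched oxonium-ion
#' compositions. Ties are broken by smaller absolute mass deviation, then by
#' lexicographic composition string. Ranks are assigned 1..n.
#'
#' @param candidates Result of [match_compositions()].
#' @param ladder A `y_ladder` (or `NULL` for no ladder evidence).
#' @param oxonium A `filter_result` (or `NULL`).
#' @param weights Two weights (`ladder`, `oxonium`) summing to 1.
#' @return `candidates` with `score` and `rank` columns, ordered by rank.
#' @export
score_and_rank_compositions <- function(candidates, ladder = NULL,
                                        oxonium = NULL,
                                        weights = c(ladder = 0.7, oxonium = 0.3)) {
  if (!nrow(candidates)) {
    candidates$score <- numeric(); candidates$rank <- integer()
    return(candidates)
  }
  types <- c("Hex", "HexNAc", "dHex", "NeuAc", "NeuGc")
  ladder_counts <- stats::setNames(integer(length(types)), types)
  if (!is.null(ladder) && nrow(ladder$steps)) {
    tb <- table(ladder$steps$residue)
    ladder_counts[names(tb)] <- as.integer(tb)
  }
  ox_types <- character()
  if (!is.null(oxonium) && nrow(oxonium$matched)) {
    comps <- unlist(strsplit(oxonium$matched$composition, ";", fixed = TRUE))
    ox_types <- unique(sub(":.*$", "", comps))
  }
  score <- vapply(seq_len(nrow(candidates)), function(i) {
    counts <- unlist(candidates[i, types])
    total <- sum(counts)
    coverage <- sum(pmin(counts, ladder_counts)) / total
    present <- types[counts > 0]
    type_ev <- mean(present %in% ox_types)
    unname(weights[["ladder"]] * coverage + weights[["oxonium"]] * type_ev)
  }, 0)
  candidates$score <- score
  cs <- vapply(seq_len(nrow(candidates)), function(i)
    composition_string(candidates[i, ]), "")
  ord <- order(-score, abs(candidates$delta), cs)
  candidates <- candidates[ord, , drop = FALSE]
  candidates$rank <- seq_len(nrow(candidates))
  rownames(candidates) <- NULL
  candidates
}
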