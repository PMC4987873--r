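# Monoisotopic mass model shared by every stage of the pipeline.
# All masses are monoisotopic Da; average masses are deliberately unsupported
# (beam-type CID data come from high-resolution instruments).

# Atomic monoisotopic masses used to derive residue and monosaccharide masses.
.ATOM <- c(C = 12.000000, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
           S = 31.97207069)

#' Physical constants of the mass model
#'
#' `PROTON_MASS` is the mass of a proton (charge carrier), `WATER_MASS` the
#' monoisotopic mass of H2O (peptide termini), `NH3_MASS` the monoisotopic mass
#' of ammonia (the neutral loss used by the second Y-ion triplet pattern).
#'
#' @format Numeric scalars in Da.
#' @name mass-constants
NULL

#' @rdname mass-constants
#' @export
PROTON_MASS <- 1.007276

#' @rdname mass-constants
#' @export
WATER_MASS <- 2 * .ATOM[["H"]] + .ATOM[["O"]]

#' @rdname mass-constants
#' @export
NH3_MASS <- .ATOM[["N"]] + 3 * .ATOM[["H"]]

# Standard 20 amino-acid residue monoisotopic masses.
.AA_MASS <- c(
  G = 57.02146372,  A = 71.03711379,  S = 87.03202841,  P = 97.05276385,
  V = 99.06841392,  T = 101.04767847, C = 103.00918448, L = 113.08406398,
  I = 113.08406398, N = 114.04292744, D = 115.02694302, Q = 128.05857751,
  K = 128.09496302, E = 129.04259309, M = 131.04048509, H = 137.05891186,
  F = 147.06841392, R = 156.10111102, Y = 163.06332853, W = 186.07931295
)

#' Amino-acid residue monoisotopic masses
#'
#' @return Named numeric vector over the standard 20 residues (Da).
#' @export
amino_acid_masses <- function() .AA_MASS

#' Monosaccharide residue monoisotopic masses
#'
#' Residue masses (glycosidic-bond residues, i.e. the free monosaccharide minus
#' water) for the standard mammalian N-glycan alphabet, derived from elemental
#' composition: Hex C6H10O5, HexNAc C8H13NO5, dHex (fucose) C6H10O4,
#' NeuAc C11H17NO8, NeuGc C11H17NO9.
#'
#' @return Named numeric vector (Da).
#' @export
monosaccharide_masses <- function() {
  el <- function(C, H, N = 0, O = 0)
    C * .ATOM[["C"]] + H * .ATOM[["H"]] + N * .ATOM[["N"]] + O * .ATOM[["O"]]
  c(Hex    = el(6, 10, 0, 5),
    HexNAc = el(8, 13, 1, 5),
    dHex   = el(6, 10, 0, 4),
    NeuAc  = el(11, 17, 1, 8),
    NeuGc  = el(11, 17, 1, 9))
}

# HexNAc (GlcNAc) residue mass, the spacing of the Y-ion triplet patterns.
.GLCNAC <- 8 * 12 + 13 * .ATOM[["H"]] + .ATOM[["N"]] + 5 * .ATOM[["O"]]

#' Modification specification
#'
#' @param name Short modification name (e.g. `"cam"`).
#' @param target_residues Character vector of single-letter residues the
#'   modification may be placed on.
#' @param delta_mass Mass shift in Da.
#' @param mode `"fixed"` (applied to every target residue) or `"variable"`.
#' @return A `mod_spec` object.
#' @export
mod_spec <- function(name, target_residues, delta_mass, mode = c("variable", "fixed")) {
  mode <- match.arg(mode)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            length(target_residues) >= 1L, is.finite(delta_mass))
  structure(list(name = name, target_residues = target_residues,
                 delta_mass = delta_mass, mode = mode),
            class = "mod_spec")
}

#' Default modification set
#'
#' Carbamidomethylation of cysteine as a fixed modification; deamidation of
#' asparagine/glutamine and oxidation of methionine as variable modifications.
#'
#' @return Named list of [mod_spec()] objects.
#' @export
default_modifications <- function() {
  list(
    cam  = mod_spec("cam",  "C",        57.02146372, "fixed"),
    deam = mod_spec("deam", c("N", "Q"), 0.98401587,  "variable"),
    ox   = mod_spec("ox",   "M",        15.99491462,  "variable")
  )
}

# Split a peptide into residue letters, with validation.
.residues <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("peptide sequence must be a non-empty string", call. = FALSE)
  aa <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(aa, names(.AA_MASS))
  if (length(bad))
    stop("invalid residue letter(s) in sequence: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  aa
}

# Validate applied modifications against a sequence. `mods` is a data.frame
# with columns name, pos (1-based), delta; NULL means unmodified.
.check_mods <- function(aa, mods, mod_table = default_modifications()) {
  if (is.null(mods) || nrow(mods) == 0L) return(invisible(NULL))
  stopifnot(all(c("name", "pos", "delta") %in% names(mods)))
  if (any(mods$pos < 1L | mods$pos > length(aa)))
    stop("modification position outside peptide", call. = FALSE)
  for (i in seq_len(nrow(mods))) {
    spec <- mod_table[[mods$name[i]]]
    if (!is.null(spec) && !(aa[mods$pos[i]] %in% spec$target_residues))
      stop("modification '", mods$name[i], "' placed on non-target residue ",
           aa[mods$pos[i]], " at position ", mods$pos[i], call. = FALSE)
  }
  invisible(NULL)
}

#' Neutral monoisotopic mass of a (modified) peptide
#'
#' Sum of residue masses plus one water plus the mass shifts of all applied
#' modifications.
#'
#' @param sequence Uppercase peptide string over the standard 20 amino acids.
#' @param mods Applied modifications: a data.frame with columns `name`, `pos`
#'   (1-based residue position) and `delta` (Da), or `NULL` for none.
#' @return Neutral mass in Da.
#' @examples
#' peptide_neutral_mass("GK")   # 203.12698
#' @export
peptide_neutral_mass <- function(sequence, mods = NULL) {
  aa <- .residues(sequence)
  .check_mods(aa, mods)
  m <- sum(.AA_MASS[aa]) + WATER_MASS
  if (!is.null(mods) && nrow(mods)) m <- m + sum(mods$delta)
  unname(m)
}

#' Convert a neutral mass to m/z at a given charge
#'
#' @param neutral_mass Neutral mass in Da (> 0).
#' @param charge Positive integer charge state.
#' @return m/z in Th.
#' @export
mz_from_mass <- function(neutral_mass, charge) {
  if (any(charge < 1)) stop("charge must be >= 1", call. = FALSE)
  (neutral_mass + charge * PROTON_MASS) / charge
}

#' Convert an observed m/z back to a neutral mass
#'
#' Exact inverse of [mz_from_mass()].
#'
#' @inheritParams mz_from_mass
#' @param mz m/z in Th.
#' @return Neutral mass in Da.
#' @export
mass_from_mz <- function(mz, charge) {
  if (any(charge < 1)) stop("charge must be >= 1", call. = FALSE)
  charge * mz - charge * PROTON_MASS
}

#' Theoretical b- and y-ion m/z values of a peptide
#'
#' Enumerates b_i and y_i for i = 1..L-1 at charge states 1..`max_charge`,
#' with modification mass shifts included at their residue positions.
#'
#' @inheritParams peptide_neutral_mass
#' @param max_charge Highest fragment charge state to emit.
#' @return data.frame with columns `series` ("b"/"y"), `index`, `charge`, `mz`,
#'   ordered by series, index, charge. A length-1 peptide yields zero rows.
#' @export
theoretical_fragments <- function(sequence, mods = NULL, max_charge = 1L) {
  aa <- .residues(sequence)
  .check_mods(aa, mods)
  stopifnot(max_charge >= 1L)
  L <- length(aa)
  empty <- data.frame(series = character(), index = integer(),
                      charge = integer(), mz = numeric())
  if (L < 2L) return(empty)
  res <- unname(.AA_MASS[aa])
  if (!is.null(mods) && nrow(mods))
    res[mods$pos] <- res[mods$pos] + mods$delta
  prefix <- cumsum(res)[seq_len(L - 1L)]            # neutral b fragment masses
  suffix <- rev(cumsum(rev(res)))[2:L] + WATER_MASS # neutral y_i, i = L-1..1
  suffix <- rev(suffix)                             # y_1..y_{L-1}
  out <- lapply(seq_len(max_charge), function(z) {
    data.frame(
      series = rep(c("b", "y"), each = L - 1L),
      index = rep(seq_len(L - 1L), 2L),
      charge = z,
      mz = c((prefix + z * PROTON_MASS) / z, (suffix + z * PROTON_MASS) / z)
    )
  })
  out <- do.call(rbind, out)
  out[order(out$series, out$index, out$charge), , drop = FALSE]
}
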