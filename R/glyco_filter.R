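# Oxonium-ion (B-ion) spectrum filter: glycopeptide spectra carry intense
# glycan fragment ions in the low m/z region; spectra lacking them are
# rejected before any Y-ion work.

#' Built-in oxonium ion list
#'
#' The canonical glyco-oxonium series: singly protonated intact
#' monosaccharide/disaccharide oxocarbenium ions (m/z computed from residue
#' masses + proton) plus the well-known low-mass HexNAc fragment series
#' (water/formaldehyde losses, fixed m/z). The `composition` column records
#' which monosaccharide types an ion evidences.
#'
#' @return data.frame with columns `name`, `mz`, `composition` (e.g.
#'   `"HexNAc:1"`), `is_fragment` (TRUE for sub-monosaccharide fragments whose
#'   m/z is not a residue-sum).
#' @export
oxonium_ions <- function() {
  mono <- monosaccharide_masses()
  comp_mz <- function(...) {
    counts <- c(...)
    sum(mono[names(counts)] * counts) + PROTON_MASS
  }
  intact <- data.frame(
    name = c("Hex+", "HexNAc+", "NeuAc+", "dHexHexNAc+", "HexHexNAc+",
             "Hex2HexNAc+", "NeuAcHexHexNAc+"),
    mz = c(comp_mz(Hex = 1), comp_mz(HexNAc = 1), comp_mz(NeuAc = 1),
           comp_mz(dHex = 1, HexNAc = 1), comp_mz(Hex = 1, HexNAc = 1),
           comp_mz(Hex = 2, HexNAc = 1), comp_mz(NeuAc = 1, Hex = 1, HexNAc = 1)),
    composition = c("Hex:1", "HexNAc:1", "NeuAc:1", "dHex:1;HexNAc:1",
                    "Hex:1;HexNAc:1", "Hex:2;HexNAc:1", "NeuAc:1;Hex:1;HexNAc:1"),
    is_fragment = FALSE
  )
  frag <- data.frame(
    name = c("HexNAc-2H2O-CH2O", "HexNAc-2H2O-CO", "HexNAc-CH6O3",
             "HexNAc-2H2O", "HexNAc-H2O", "NeuAc-H2O"),
    mz = c(126.0550, 138.0550, 144.0655, 168.0655, 186.0761, 274.0921),
    composition = c(rep("HexNAc:1", 5L), "NeuAc:1"),
    is_fragment = TRUE
  )
  out <- rbind(intact, frag)
  out[order(out$mz), , drop = FALSE]
}

#' Match a spectrum's peaks against the built-in oxonium list
#'
#' Each oxonium ion with at least one peak within `tolerance` is paired with
#' the most intense such peak. Only the low m/z region (below the configured
#' bound) is scanned.
#'
#' @param spectrum A `glyco_spectrum`.
#' @param tolerance m/z tolerance in Da.
#' @param ions Oxonium table; defaults to [oxonium_ions()].
#' @param low_mz_bound Upper bound of the scanned region (Th).
#' @return data.frame (`name`, `ion_mz`, `peak_mz`, `intensity`,
#'   `composition`), sorted by ion m/z; zero rows when nothing matches.
#' @export
oxonium_matches <- function(spectrum, tolerance = 0.02, ions = oxonium_ions(),
                            low_mz_bound = 700) {
  stopifnot(tolerance > 0)
  ions <- ions[ions$mz < low_mz_bound, , drop = FALSE]
  rows <- lapply(seq_len(nrow(ions)), function(i) {
    idx <- .peaks_within(spectrum$peaks, ions$mz[i], tolerance)
    if (!length(idx)) return(NULL)
    best <- idx[which.max(spectrum$peaks[idx, "intensity"])]
    data.frame(name = ions$name[i], ion_mz = ions$mz[i],
               peak_mz = spectrum$peaks[best, "mz"],
               intensity = spectrum$peaks[best, "intensity"],
               composition = ions$composition[i])
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(name = character(), ion_mz = numeric(),
                      peak_mz = numeric(), intensity = numeric(),
                      composition = character()))
  out <- do.call(rbind, rows)
  out <- out[order(out$ion_mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a spectrum as a glycopeptide candidate
#'
#' In `"default_pair"` mode the spectrum passes iff both the HexNAc+
#' (m/z 204.087) and HexHexNAc+ (m/z 366.139) diagnostic ions are matched.
#' In `"min_count"` mode it passes iff at least `min_oxonium_count` distinct
#' built-in oxonium ions are matched.
#'
#' @param spectrum A `glyco_spectrum`.
#' @param config A [glyco_config()].
#' @return A `filter_result`: list with `passed`, `matched` (the
#'   [oxonium_matches()] table), `mode`.
#' @export
is_glycopeptide_spectrum <- function(spectrum, config = glyco_config()) {
  matched <- oxonium_matches(spectrum, config$oxonium_tolerance,
                             low_mz_bound = config$low_mz_bound)
  passed <- if (config$filter_mode == "default_pair") {
    all(c("HexNAc+", "HexHexNAc+") %in% matched$name)
  } else {
    if (config$min_oxonium_count < 1L)
      stop("min_oxonium_count must be >= 1", call. = FALSE)
    length(unique(matched$name)) >= config$min_oxonium_count
  }
  structure(list(passed = passed, matched = matched, mode = config$filter_mode),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat(sprintf("<filter_result> %s (%s mode, %d oxonium ion(s) matched)\n",
              if (x$passed) "PASSED" else "failed", x$mode, nrow(x$matched)))
  invisible(x)
}
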