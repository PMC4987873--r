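# Deterministic generator of intact-glycopeptide MS2 spectra and negative
# controls with the phenomenology the pipeline assumes: dominant glycan B-
# and Y-ions, sparse low-abundance peptide b/y ions, and noise.

#' Synthetic spectrum generator parameters
#'
#' @param by_fraction Fraction of theoretical 1+ b/y ions included (default
#'   0.7).
#' @param by_rel_intensity Peptide backbone ion intensity relative to the
#'   base peak (default 0.05; B/Y ions dominate beam-type CID spectra).
#' @param base_intensity Base peak intensity (arbitrary units).
#' @param n_noise Number of noise peaks per spectrum (uniform m/z in
#'   [100, precursor m/z], exponential intensity).
#' @param noise_mean Mean of the exponential noise intensity.
#' @param mz_jitter_sd Gaussian m/z jitter (Da) applied to signal peaks;
#'   must stay below half the fragment tolerance.
#' @param ladder_depth Maximum Y-ladder steps emitted (`Inf` = the full
#'   glycan).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `synth_params` list.
#' @export
synth_params <- function(by_fraction = 0.7, by_rel_intensity = 0.05,
                         base_intensity = 100, n_noise = 30L,
                         noise_mean = 2, mz_jitter_sd = 0.005,
                         ladder_depth = Inf, seed = 1L) {
  stopifnot(by_fraction >= 0, by_fraction <= 1, by_rel_intensity >= 0,
            by_rel_intensity <= 1, n_noise >= 0L, mz_jitter_sd >= 0)
  structure(list(by_fraction = by_fraction,
                 by_rel_intensity = by_rel_intensity,
                 base_intensity = base_intensity,
                 n_noise = as.integer(n_noise), noise_mean = noise_mean,
                 mz_jitter_sd = mz_jitter_sd, ladder_depth = ladder_depth,
                 seed = as.integer(seed)),
            class = "synth_params")
}

#' Zero-noise generator parameters
#'
#' Convenience preset: no noise peaks, no m/z jitter, every b/y ion included.
#'
#' @param seed Integer seed.
#' @return A [synth_params()] object.
#' @export
synth_params_clean <- function(seed = 1L) {
  synth_params(by_fraction = 1, n_noise = 0L, mz_jitter_sd = 0, seed = seed)
}

# Expand a composition (named counts) into a biosynthesis-consistent residue
# addition order from Y0 upward: chitobiose core first, then the mannose
# core, then antenna residues, with sialic acids last (terminal positions).
.glycan_order <- function(composition) {
  counts <- composition
  core <- c(rep("HexNAc", 2L), rep("Hex", 3L))
  counts["HexNAc"] <- counts["HexNAc"] - 2L
  counts["Hex"] <- counts["Hex"] - 3L
  antenna <- c(rep("HexNAc", counts["HexNAc"]), rep("Hex", counts["Hex"]),
               rep("dHex", counts["dHex"]))
  antenna <- sample(antenna)
  terminal <- c(rep("NeuAc", counts["NeuAc"]), rep("NeuGc", counts["NeuGc"]))
  c(core, antenna, terminal)
}

#' Generate one synthetic intact-glycopeptide spectrum
#'
#' Emits the oxonium B-ion series (including the 204.087/366.139 diagnostic
#' pair), the full Y-ion ladder from Y0 upward at 1+, a Y0-NH3 peak, a
#' sampled subset of 1+ peptide b/y ions at low intensity, and noise peaks.
#' The precursor is the intact glycopeptide (peptide + glycan) at the given
#' charge.
#'
#' @param peptide Peptide sequence (with at least one sequon for realism;
#'   not enforced).
#' @param composition Named integer vector of monosaccharide counts
#'   satisfying the biosynthesis constraints (HexNAc >= 2, Hex >= 3).
#' @param params A [synth_params()]; the RNG is advanced, seed it upstream.
#' @param charge Precursor charge.
#' @param title Spectrum title.
#' @return List with `spectrum` (a `glyco_spectrum`) and `truth` (peptide,
#'   composition string, peptide mass, glycan mass, Y0 m/z at 1+).
#' @export
synth_glycopeptide_spectrum <- function(peptide, composition, params,
                                        charge = 2L, title = "synth") {
  types <- c("Hex", "HexNAc", "dHex", "NeuAc", "NeuGc")
  comp <- stats::setNames(integer(length(types)), types)
  comp[names(composition)] <- as.integer(composition)
  if (comp["HexNAc"] < 2L || comp["Hex"] < 3L)
    stop("composition must contain the HexNAc2Hex3 core", call. = FALSE)
  mono <- monosaccharide_masses()
  pep_mass <- peptide_neutral_mass(peptide)
  glycan_mass <- sum(comp * mono[names(comp)])
  order <- .glycan_order(comp)
  # Y ladder at 1+ (dominant): Y0, Y1, ..., up to ladder_depth steps
  depth <- min(length(order), params$ladder_depth)
  y_neutral <- pep_mass + cumsum(c(0, unname(mono[order[seq_len(depth)]])))
  y_mz <- mz_from_mass(y_neutral, 1L)
  y_int <- stats::runif(length(y_mz), 0.3, 1) * params$base_intensity
  # Y0 - NH3 companion (pattern B evidence)
  y0nh3 <- c(y_mz[1L] - NH3_MASS, 0.4 * params$base_intensity)
  # oxonium B ions: diagnostic pair always; type-dependent extras
  ox <- c(204.0866485, 366.1394719)
  if (comp["NeuAc"] > 0) ox <- c(ox, 274.0921, 292.1026935)
  if (comp["dHex"] > 0) ox <- c(ox, 350.1445573)
  ox <- c(ox, 163.0601007)
  ox_int <- stats::runif(length(ox), 0.3, 1) * params$base_intensity
  # sparse low-abundance peptide backbone ions at 1+
  frags <- theoretical_fragments(peptide, max_charge = 1L)
  keep <- stats::runif(nrow(frags)) < params$by_fraction
  by_mz <- frags$mz[keep]
  by_int <- stats::runif(length(by_mz), 0.2, 1) *
    params$by_rel_intensity * params$base_intensity
  precursor_mz <- mz_from_mass(pep_mass + glycan_mass, charge)
  signal_mz <- c(y_mz, y0nh3[1L], ox, by_mz)
  signal_int <- c(y_int, y0nh3[2L], ox_int, by_int)
  if (params$mz_jitter_sd > 0)
    signal_mz <- signal_mz + stats::rnorm(length(signal_mz), 0,
                                          params$mz_jitter_sd)
  if (params$n_noise > 0L) {
    noise_mz <- stats::runif(params$n_noise, 100, precursor_mz)
    noise_int <- stats::rexp(params$n_noise, 1 / params$noise_mean)
    signal_mz <- c(signal_mz, noise_mz)
    signal_int <- c(signal_int, noise_int)
  }
  sp <- new_spectrum(title, precursor_mz, charge,
                     cbind(mz = signal_mz, intensity = signal_int))
  list(spectrum = sp,
       truth = data.frame(title = title, peptide = peptide,
                          composition = paste(
                            sprintf("%s:%d", names(comp)[comp > 0],
                                    comp[comp > 0]), collapse = ";"),
                          pep_mass = pep_mass, glycan_mass = glycan_mass,
                          y0_mz = y_mz[1L], charge = charge,
                          is_glyco = TRUE))
}

# A negative-control (non-glycopeptide) spectrum: backbone b/y ions + noise,
# no oxonium-region diagnostic ions. `hard` mode adds a lone HexNAc+ peak to
# exercise the pair rule.
.synth_negative_spectrum <- function(peptide, params, charge = 2L,
                                     title = "neg", hard = FALSE) {
  pep_mass <- peptide_neutral_mass(peptide)
  frags <- theoretical_fragments(peptide, max_charge = 1L)
  mzs <- frags$mz
  ints <- stats::runif(length(mzs), 0.2, 1) * params$base_intensity
  if (hard) {
    mzs <- c(mzs, 204.0866485)
    ints <- c(ints, 0.5 * params$base_intensity)
  }
  if (params$mz_jitter_sd > 0)
    mzs <- mzs + stats::rnorm(length(mzs), 0, params$mz_jitter_sd)
  precursor_mz <- mz_from_mass(pep_mass, charge)
  if (params$n_noise > 0L) {
    keep_clear <- function(x) {
      # keep noise out of the diagnostic oxonium windows so negatives are
      # negatives by construction
      ok <- abs(x - 204.0866) > 0.5 & abs(x - 366.1395) > 0.5
      x[ok]
    }
    noise_mz <- keep_clear(stats::runif(params$n_noise, 100, precursor_mz))
    mzs <- c(mzs, noise_mz)
    ints <- c(ints, stats::rexp(length(noise_mz), 1 / params$noise_mean))
  }
  sp <- new_spectrum(title, precursor_mz, charge,
                     cbind(mz = mzs, intensity = ints))
  list(spectrum = sp,
       truth = data.frame(title = title, peptide = peptide,
                          composition = "", pep_mass = pep_mass,
                          glycan_mass = NA_real_, y0_mz = NA_real_,
                          charge = charge, is_glyco = FALSE))
}

# Default glycoprotein-like peptide/composition pools used when the caller
# supplies none.
.default_glyco_peptides <- c(
  "NVTAGLLK", "LLNDSVTR", "AGNFTELK", "VVNGTSLLK", "TNLSEVAK",
  "GGLNWTVER", "FENSTLAAK", "IVDNSTLPR"
)
.default_neg_peptides <- c(
  "AGVLDEK", "TLLEDGAVR", "GGFVDEAK", "LLTEDGVR", "AVDLGEEK", "TGGLVEDR"
)
.default_compositions <- list(
  c(HexNAc = 2L, Hex = 3L),
  c(HexNAc = 2L, Hex = 5L),
  c(HexNAc = 2L, Hex = 3L, dHex = 1L),
  c(HexNAc = 4L, Hex = 5L),
  c(HexNAc = 4L, Hex = 5L, NeuAc = 1L),
  c(HexNAc = 2L, Hex = 9L)
)

#' Generate a synthetic benchmark dataset
#'
#' `n_glyco` glycopeptide spectra plus `n_nonglyco` negative controls,
#' deterministically shuffled by the seed. Peptides and compositions cycle
#' through the supplied pools.
#'
#' @param n_glyco Number of glycopeptide spectra.
#' @param n_nonglyco Number of negative-control spectra.
#' @param params A [synth_params()]; `params$seed` seeds the whole dataset.
#' @param peptides Glycopeptide pool (default: built-in sequon peptides).
#' @param neg_peptides Negative-control pool.
#' @param compositions List of named count vectors.
#' @param charges Precursor charges cycled over the glyco spectra.
#' @param mgf_path,truth_path Optional output paths (MGF and ground-truth
#'   TSV).
#' @param hard_negatives If `TRUE`, negatives carry a lone HexNAc+ peak.
#' @return List with `spectra` (list) and `truth` (data.frame).
#' @export
synth_dataset <- function(n_glyco, n_nonglyco, params = synth_params(),
                          peptides = .default_glyco_peptides,
                          neg_peptides = .default_neg_peptides,
                          compositions = .default_compositions,
                          charges = c(2L, 3L),
                          mgf_path = NULL, truth_path = NULL,
                          hard_negatives = FALSE) {
  stopifnot(n_glyco >= 0L, n_nonglyco >= 0L)
  set.seed(params$seed)
  spectra <- list(); truth <- list()
  for (i in seq_len(n_glyco)) {
    pep <- peptides[[(i - 1L) %% length(peptides) + 1L]]
    comp <- compositions[[(i - 1L) %% length(compositions) + 1L]]
    z <- charges[[(i - 1L) %% length(charges) + 1L]]
    g <- synth_glycopeptide_spectrum(pep, comp, params, charge = z,
                                     title = sprintf("synth_glyco_%04d", i))
    spectra[[length(spectra) + 1L]] <- g$spectrum
    truth[[length(truth) + 1L]] <- g$truth
  }
  for (i in seq_len(n_nonglyco)) {
    pep <- neg_peptides[[(i - 1L) %% length(neg_peptides) + 1L]]
    g <- .synth_negative_spectrum(pep, params, charge = 2L,
                                  title = sprintf("synth_neg_%04d", i),
                                  hard = hard_negatives)
    spectra[[length(spectra) + 1L]] <- g$spectrum
    truth[[length(truth) + 1L]] <- g$truth
  }
  if (length(spectra)) {
    ord <- sample(length(spectra))
    spectra <- spectra[ord]
    truth <- do.call(rbind, truth)[ord, , drop = FALSE]
    rownames(truth) <- NULL
  } else {
    truth <- data.frame()
  }
  if (!is.null(mgf_path) && length(spectra)) write_mgf(spectra, mgf_path)
  if (!is.null(truth_path) && nrow(truth))
    utils::write.table(truth, truth_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  list(spectra = spectra, truth = truth)
}
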