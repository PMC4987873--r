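# Run configuration: every tunable parameter of the pipeline in one place,
# serializable to YAML so a run can be reproduced from its config file alone.

#' Pipeline run configuration
#'
#' @param filter_mode `"default_pair"` (require the HexNAc+ 204.087 and
#'   HexHexNAc+ 366.139 diagnostic ions) or `"min_count"` (require at least
#'   `min_oxonium_count` distinct built-in oxonium ions).
#' @param min_oxonium_count Minimum distinct oxonium ions for `"min_count"` mode.
#' @param fragment_tolerance m/z tolerance (Da) for Y-ion pattern/ladder and
#'   b/y fragment matching.
#' @param precursor_match_tolerance Tolerance (Da) for matching the Y0-derived
#'   peptide mass against the target-decoy database. Default 0.6.
#' @param oxonium_tolerance Tolerance (Da) for oxonium-ion matching.
#' @param enzyme Digestion enzyme; only `"trypsin"` is implemented.
#' @param max_missed_cleavages Maximum internal missed cleavage sites.
#' @param peptide_length_range Inclusive `[min, max]` target peptide length.
#' @param max_var_mods Maximum variable modifications per peptide.
#' @param random_seed Integer seed governing decoy placement (and recorded in
#'   every output).
#' @param glycan_max_residues Maximum total monosaccharide count in the glycan
#'   composition table.
#' @param glycan_score_weights Two weights (`ladder`, `oxonium`) of the
#'   composition evidence score; must sum to 1.
#' @param low_mz_bound Upper bound (Th) of the "low m/z region" scanned for
#'   oxonium ions.
#' @param trim_signal_peptide If `TRUE`, [enumerate_target_peptides()] callers
#'   are expected to pass mature chains; kept as a documented flag only (the
#'   reference configuration digests sequences as provided, untrimmed).
#' @return A `glyco_config` object (named list).
#' @export
glyco_config <- function(filter_mode = c("default_pair", "min_count"),
                         min_oxonium_count = 2L,
                         fragment_tolerance = 0.05,
                         precursor_match_tolerance = 0.6,
                         oxonium_tolerance = 0.02,
                         enzyme = "trypsin",
                         max_missed_cleavages = 2L,
                         peptide_length_range = c(6L, 40L),
                         max_var_mods = 2L,
                         random_seed = 1L,
                         glycan_max_residues = 29L,
                         glycan_score_weights = c(ladder = 0.7, oxonium = 0.3),
                         low_mz_bound = 700,
                         trim_signal_peptide = FALSE) {
  filter_mode <- match.arg(filter_mode)
  stopifnot(fragment_tolerance > 0, precursor_match_tolerance > 0,
            oxonium_tolerance > 0,
            length(peptide_length_range) == 2L,
            peptide_length_range[1] <= peptide_length_range[2],
            max_missed_cleavages >= 0L, max_var_mods >= 0L,
            glycan_max_residues >= 5L,
            abs(sum(glycan_score_weights) - 1) < 1e-9)
  if (filter_mode == "min_count" && min_oxonium_count < 1L)
    stop("min_oxonium_count must be >= 1 in min_count mode", call. = FALSE)
  structure(
    list(filter_mode = filter_mode,
         min_oxonium_count = as.integer(min_oxonium_count),
         fragment_tolerance = fragment_tolerance,
         precursor_match_tolerance = precursor_match_tolerance,
         oxonium_tolerance = oxonium_tolerance,
         enzyme = enzyme,
         max_missed_cleavages = as.integer(max_missed_cleavages),
         peptide_length_range = as.integer(peptide_length_range),
         max_var_mods = as.integer(max_var_mods),
         random_seed = as.integer(random_seed),
         glycan_max_residues = as.integer(glycan_max_residues),
         glycan_score_weights = glycan_score_weights,
         low_mz_bound = low_mz_bound,
         trim_signal_peptide = isTRUE(trim_signal_peptide)),
    class = "glyco_config"
  )
}

#' Write / read a run configuration
#'
#' The YAML round trip is bit-exact: numeric parameters are serialized at full
#' double precision.
#'
#' @param config A `glyco_config` object.
#' @param path File path.
#' @return `read_config()` returns the `glyco_config`; `write_config()` its
#'   path, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "glyco_config"))
  x <- unclass(config)
  x$glycan_score_weights <- as.list(x$glycan_score_weights)
  writeLines(yaml::as.yaml(x, precision = 17L), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  w <- unlist(x$glycan_score_weights)
  do.call(glyco_config, c(
    x[setdiff(names(x), "glycan_score_weights")],
    list(glycan_score_weights = w)
  ))
}

#' MD5 digest of a configuration
#'
#' Embedded in every output artifact so results can be traced to the exact
#' parameter set that produced them.
#'
#' @param config A `glyco_config` object.
#' @return Character MD5 digest.
#' @export
config_digest <- function(config) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  write_config(config, tf)
  unname(tools::md5sum(tf))
}

#' @export
print.glyco_config <- function(x, ...) {
  cat("<glyco_config>\n")
  for (k in names(x))
    cat(sprintf("  %-26s %s\n", k, paste(format(x[[k]]), collapse = ", ")))
  invisible(x)
}
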