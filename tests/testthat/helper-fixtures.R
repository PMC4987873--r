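# Shared fixtures: small peptide pools and a spectrum builder used across
# the suite. All randomness is seeded inside the tests that use it.

glyco_pool <- c("NVTAGLLK", "LLNDSVTR", "AGNFTELK", "VVNGTSLLK", "TNLSEVAK",
                "GGLNWTVER", "FENSTLAAK", "IVDNSTLPR")
neg_pool <- c("AGVLDEK", "TLLEDGAVR", "GGFVDEAK", "LLTEDGVR")

# one protein whose tryptic digest is exactly the pool
pool_protein <- c(poolA = paste(glyco_pool, collapse = ""))

# quick spectrum from bare peak vectors
mk_spectrum <- function(mz, intensity = rep(1, length(mz)),
                        precursor_mz = 1500, charge = 2L, title = "t") {
  new_spectrum(title, precursor_mz, charge, cbind(mz = mz, intensity = intensity))
}

GLCNAC <- monosaccharide_masses()[["HexNAc"]]
HEX <- monosaccharide_masses()[["Hex"]]
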