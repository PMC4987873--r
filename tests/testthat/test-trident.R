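NH3 <- 17.02655

test_that("triplet patterns find Y0 and merge pattern A and B evidence", {
  cfg <- glyco_config(fragment_tolerance = 0.02)
  # constructed so Y0 = 1000.5 satisfies both patterns at 1+
  sp <- mk_spectrum(c(1000.5 - NH3, 1000.5, 1000.5 + GLCNAC,
                      1000.5 + 2 * GLCNAC),
                    precursor_mz = 1500, charge = 2L)
  m <- detect_y1_patterns(sp, cfg)
  y0 <- Filter(function(x) abs(x$y0_mz - 1000.5) < 1e-6, m)
  expect_length(y0, 1L)
  expect_equal(y0[[1]]$pattern, "A+B")
  expect_equal(y0[[1]]$peptide_neutral_mass, 1000.5 - 1.007276,
               tolerance = 1e-5)
})

test_that("Hex spacings do not trigger the GlcNAc triplet patterns", {
  cfg <- glyco_config(fragment_tolerance = 0.02)
  sp <- mk_spectrum(c(1000.5, 1000.5 + HEX, 1000.5 + 2 * HEX),
                    precursor_mz = 1500, charge = 2L)
  expect_length(detect_y1_patterns(sp, cfg), 0L)
  expect_length(detect_y1_patterns(mk_spectrum(numeric(0)), cfg), 0L)
})

test_that("Y0 candidates above the precursor neutral mass are rejected", {
  cfg <- glyco_config(fragment_tolerance = 0.02)
  sp <- mk_spectrum(c(1000.5, 1000.5 + GLCNAC, 1000.5 + 2 * GLCNAC),
                    precursor_mz = 600, charge = 1L)  # precursor below Y0
  expect_length(detect_y1_patterns(sp, cfg), 0L)
})

test_that("Y-ladder extension follows monosaccharide spacings", {
  cfg <- glyco_config(fragment_tolerance = 0.02)
  mz <- c(1000.5, 1000.5 + GLCNAC, 1000.5 + 2 * GLCNAC,
          1000.5 + 2 * GLCNAC + HEX)
  sp <- mk_spectrum(mz, precursor_mz = 1800, charge = 2L)
  m <- detect_y1_patterns(sp, cfg)[[1]]
  lad <- extend_y_ladder(sp, m, cfg)
  expect_equal(lad$steps$residue, c("HexNAc", "HexNAc", "Hex"))
  expect_equal(nrow(lad$steps), 3L)
  # no peaks above Y0 -> zero steps
  sp0 <- mk_spectrum(c(900, 1000.5, 1000.5 + GLCNAC, 1000.5 + 2 * GLCNAC),
                     precursor_mz = 1800, charge = 2L)
  m0 <- detect_y1_patterns(sp0, cfg)[[1]]
  top <- mk_spectrum(1000.5 + 2 * GLCNAC, precursor_mz = 1800, charge = 2L)
  lad_top <- extend_y_ladder(
    top, structure(list(y0_mz = 1000.5 + 2 * GLCNAC, charge = 1L,
                        pattern = "A", evidence_mz = rep(NA_real_, 3),
                        peptide_neutral_mass =
                          mass_from_mz(1000.5 + 2 * GLCNAC, 1L),
                        y0_peak_index = 1L), class = "trident_match"), cfg)
  expect_equal(nrow(lad_top$steps), 0L)
})

# exhaustive enumeration oracle for the DP ladder: longest monosaccharide-
# spaced path from the start peak, ties by summed intensity
brute_ladder <- function(mz, intensity, start, z, tol) {
  mono <- monosaccharide_masses() / z
  best <- list(len = 0, int = intensity[start])
  recurse <- function(i, len, int) {
    if (len > best$len || (len == best$len && int > best$int))
      best <<- list(len = len, int = int)
    for (j in seq_along(mz)) {
      if (mz[j] <= mz[i]) next
      if (any(abs(mz[j] - mz[i] - mono) <= tol))
        recurse(j, len + 1, int + intensity[j])
    }
  }
  recurse(start, 0, intensity[start])
  best
}

test_that("DP ladder equals exhaustive path enumeration on small spectra", {
  cfg <- glyco_config(fragment_tolerance = 0.02)
  mono <- monosaccharide_masses()
  set.seed(17)
  for (rep in 1:25) {
    # random walk peaks: some monosaccharide steps, some junk steps
    mz <- 800
    for (k in 1:10) {
      step <- if (runif(1) < 0.6) sample(mono, 1) else runif(1, 50, 250)
      mz <- c(mz, mz[length(mz)] + step)
    }
    mz <- sort(unique(round(mz, 4)))[1:min(12, length(mz))]
    it <- runif(length(mz), 1, 100)
    start <- 1L
    oracle <- brute_ladder(mz, it, start, 1L, cfg$fragment_tolerance)
    sp <- mk_spectrum(mz, it, precursor_mz = 3000, charge = 1L)
    match <- structure(list(y0_mz = mz[start], charge = 1L, pattern = "A",
                            evidence_mz = rep(NA_real_, 3),
                            peptide_neutral_mass = mass_from_mz(mz[start], 1L),
                            y0_peak_index = start), class = "trident_match")
    lad <- extend_y_ladder(sp, match, cfg)
    expect_equal(nrow(lad$steps), oracle$len)
    expect_equal(sum(lad$steps$intensity) + it[start], oracle$int,
                 tolerance = 1e-9)
  }
})

test_that("in silico spectra strip glyco ions and reassign the precursor", {
  cfg <- glyco_config(fragment_tolerance = 0.02)
  pep_mass <- 999.49272
  y0 <- mz_from_mass(pep_mass, 1L)
  glyco_mz <- c(204.0866, 366.1395, y0 - NH3, y0, y0 + GLCNAC, y0 + 2 * GLCNAC)
  by_mz <- c(458.2, 640.9, 712.31, 825.4)
  sp <- mk_spectrum(c(glyco_mz, by_mz), rep(10, 10),
                    precursor_mz = mz_from_mass(pep_mass + 892.317, 2L),
                    charge = 2L, title = "src")
  fr <- is_glycopeptide_spectrum(sp, cfg)
  m <- detect_y1_patterns(sp, cfg)
  m <- Filter(function(x) abs(x$y0_mz - y0) < 1e-3, m)[[1]]
  lad <- extend_y_ladder(sp, m, cfg)
  ins <- build_insilico_spectrum(sp, m, lad, fr, cfg, variant_index = 1L)
  expect_s3_class(ins, "insilico_spectrum")
  expect_equal(nrow(ins$peaks), 4L)
  expect_equal(ins$removed_count, 6L)
  expect_equal(ins$title, "src::Y0_1")
  # emission at precursor_charge - 1 = 1+
  expect_equal(ins$precursor_charge, 1L)
  expect_equal(ins$precursor_mz, mz_from_mass(pep_mass, 1L), tolerance = 1e-5)
  # stripping idempotence: re-stripping the output removes nothing
  ins2 <- build_insilico_spectrum(ins, m, lad, fr, cfg, variant_index = 1L)
  expect_equal(ins2$removed_count, 0L)
  expect_equal(nrow(ins2$peaks), nrow(ins$peaks))
})

test_that("a spectrum that is all glyco ions is dropped with a warning", {
  cfg <- glyco_config(fragment_tolerance = 0.02)
  y0 <- 1000.5
  sp <- mk_spectrum(c(y0, y0 + GLCNAC, y0 + 2 * GLCNAC),
                    precursor_mz = 1500, charge = 2L)
  m <- detect_y1_patterns(sp, cfg)[[1]]
  lad <- extend_y_ladder(sp, m, cfg)
  fr <- is_glycopeptide_spectrum(sp, cfg)
  expect_warning(out <- build_insilico_spectrum(sp, m, lad, fr, cfg), "dropped")
  expect_null(out)
})

test_that("precursor reassignment and glycan mass subtraction are exact", {
  cfg <- glyco_config(fragment_tolerance = 0.02)
  # 2+ precursor at 1500, Y0 at 1000.5 (1+) -> glycan 1998.49272
  sp <- mk_spectrum(c(1000.5, 1000.5 + GLCNAC, 1000.5 + 2 * GLCNAC),
                    precursor_mz = 1500, charge = 2L)
  m <- detect_y1_patterns(sp, cfg)[[1]]
  expect_equal(glycan_neutral_mass(sp, m), 1998.49272, tolerance = 1e-4)
  # N-glycan core mass difference
  core <- 2 * GLCNAC + 3 * HEX
  sp2 <- mk_spectrum(c(1000.5, 1000.5 + GLCNAC, 1000.5 + 2 * GLCNAC),
                     precursor_mz = mz_from_mass(999.49272 + core, 2L),
                     charge = 2L)
  m2 <- detect_y1_patterns(sp2, cfg)[[1]]
  expect_equal(glycan_neutral_mass(sp2, m2), core, tolerance = 1e-4)
  # zero glycan -> error
  sp3 <- mk_spectrum(c(1000.5, 1000.5 + GLCNAC, 1000.5 + 2 * GLCNAC),
                     precursor_mz = 1000.5, charge = 1L)
  fake <- structure(list(y0_mz = 1000.5, charge = 1L, pattern = "A",
                         evidence_mz = rep(NA_real_, 3),
                         peptide_neutral_mass = mass_from_mz(1000.5, 1L),
                         y0_peak_index = 1L), class = "trident_match")
  expect_error(glycan_neutral_mass(sp3, fake), "glycan")
})
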