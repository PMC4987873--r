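test_that("top_peaks keeps the most intense peaks with a lower-m/z tie rule", {
  set.seed(9)
  mz <- sort(runif(100, 100, 2000))
  sp <- mk_spectrum(mz, runif(100, 1, 1000))
  t40 <- top_peaks(sp, 40L)
  expect_equal(nrow(t40), 40L)
  expect_gte(min(t40[, "intensity"]),
             sort(sp$peaks[, "intensity"], decreasing = TRUE)[41])
  expect_false(is.unsorted(t40[, "mz"]))
  sp12 <- mk_spectrum(sort(runif(12, 100, 900)))
  expect_equal(nrow(top_peaks(sp12, 40L)), 12L)
  # tie at the cutoff: lower m/z retained
  tie <- mk_spectrum(c(100, 200, 300), c(5, 1, 1))
  t2 <- top_peaks(tie, 2L)
  expect_equal(t2[, "mz"], c(100, 200), ignore_attr = TRUE)
})

test_that("precursor candidate retrieval equals a linear scan", {
  db <- suppressWarnings(build_database(hrp_sequence(), glyco_config()))
  set.seed(13)
  queries <- c(sample(db$entries$mass, 5), runif(5, 600, 4500))
  for (q in queries) {
    got <- find_precursor_candidates(q, db, tolerance = 0.6)
    oracle <- db$entries[abs(db$entries$mass - q) <= 0.6, ]  # linear scan
    expect_equal(nrow(got), nrow(oracle))
    expect_setequal(got$sequence, oracle$sequence)
  }
  # exact boundary behavior
  m0 <- db$entries$mass[1]
  expect_true(db$entries$sequence[1] %in%
                find_precursor_candidates(m0, db, 0.6)$sequence)
  lone <- list(entries = db$entries[1, , drop = FALSE])
  expect_equal(nrow(find_precursor_candidates(m0 + 0.61, lone, 0.6)), 0L)
})

test_that("fragment matching is one-to-one and tolerance-bounded", {
  entry <- data.frame(sequence = "NVTAGLLK", mods = "", is_decoy = FALSE)
  fr <- theoretical_fragments("NVTAGLLK", max_charge = 1L)
  pick <- fr[fr$series == "b" & fr$index %in% 2:3 |
               fr$series == "y" & fr$index == 4, ]
  sp <- mk_spectrum(c(pick$mz, 500.77, 901.3), rep(10, 5))
  m <- match_fragment_ions(top_peaks(sp), entry, tolerance = 0.05)
  expect_equal(nrow(m), 3L)
  expect_setequal(paste0(m$series, m$index), c("b2", "b3", "y4"))
  empty <- mk_spectrum(numeric(0))
  expect_equal(nrow(match_fragment_ions(top_peaks(empty), entry, 0.05)), 0L)
  # one peak within a loose tolerance of two ions goes to the closer ion only:
  # for LNK, b1 at 1+ (114.091) and b2 at 2+ (114.575) straddle 114.3
  entry2 <- data.frame(sequence = "LNK", mods = "", is_decoy = FALSE)
  sp2 <- mk_spectrum(114.3, 10)
  m2 <- match_fragment_ions(top_peaks(sp2), entry2, tolerance = 0.3)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$index, 1L)
  expect_equal(m2$charge, 1L)
})

test_that("acceptance rules distinguish targets and decoys", {
  mk_matches <- function(...) {
    rows <- list(...)
    data.frame(series = vapply(rows, `[[`, "", 1),
               index = as.integer(vapply(rows, `[[`, "", 2)),
               charge = as.integer(vapply(rows, `[[`, "", 3)),
               frag_mz = 0, peak_mz = 0, intensity = 1)
  }
  target <- data.frame(is_decoy = FALSE)
  decoy <- data.frame(is_decoy = TRUE)
  two <- mk_matches(c("b", "2", "1"), c("b", "3", "1"))
  expect_false(is_acceptable_candidate(two, target))
  three_ok <- mk_matches(c("b", "2", "1"), c("b", "3", "1"), c("y", "5", "2"))
  expect_true(is_acceptable_candidate(three_ok, target))
  three_bad <- mk_matches(c("b", "2", "1"), c("b", "5", "1"), c("y", "3", "2"))
  expect_false(is_acceptable_candidate(three_bad, target))
  # consecutive pair only at 2+ does not satisfy the 1+ requirement
  three_2plus <- mk_matches(c("b", "2", "2"), c("b", "3", "2"), c("y", "5", "1"))
  expect_false(is_acceptable_candidate(three_2plus, target))
  four <- mk_matches(c("b", "2", "1"), c("b", "5", "1"), c("y", "3", "2"),
                     c("y", "7", "2"))
  expect_true(is_acceptable_candidate(four, target))
  none <- three_ok[0, ]
  expect_true(is_acceptable_candidate(none, decoy))
  expect_false(is_acceptable_candidate(none, target))
})

test_that("PepScore is the 1+ matched intensity fraction of the top 40", {
  t40 <- cbind(mz = c(100, 200, 300, 400), intensity = c(250, 250, 250, 250))
  m1 <- data.frame(series = "b", index = 2L, charge = 1L, frag_mz = 100,
                   peak_mz = 100, intensity = 250)
  expect_equal(pep_score(m1, t40), 25.0)
  m2 <- m1; m2$charge <- 2L
  expect_equal(pep_score(m2, t40), 0.0)
  all4 <- data.frame(series = "b", index = 1:4, charge = 1L, frag_mz = 1,
                     peak_mz = 1, intensity = 250)
  expect_equal(pep_score(all4, t40), 100.0)
  expect_warning(z <- pep_score(m1, cbind(mz = 1, intensity = 0)), "zero")
  expect_equal(z, 0)
})

test_that("the winner across Y0 variants has the most matched ions", {
  cfg <- glyco_config()
  peps <- glyco_pool
  p <- synth_params_clean(seed = 19)
  ds <- synth_dataset(6, 0, p, peptides = peps)
  db <- suppressWarnings(build_database(pool_protein, cfg))
  un <- run_untargeted(ds$spectra, cfg)
  groups <- split(un$insilico, vapply(un$insilico, `[[`, "", "source_title"))
  psms <- Filter(Negate(is.null), lapply(groups, search_spectrum, db = db,
                                         config = cfg))
  expect_length(psms, 6L)
  truth <- ds$truth
  for (psm in psms) {
    want <- truth$peptide[truth$title == psm$spectrum_title]
    expect_equal(psm$peptide, want)
    expect_false(psm$is_decoy_hit)
    # winner re-derivation: no variant of this spectrum matches more ions
    g <- groups[[psm$spectrum_title]]
    for (v in g) {
      t40 <- top_peaks(v)
      cands <- find_precursor_candidates(v$y0$peptide_neutral_mass, db,
                                         cfg$precursor_match_tolerance)
      if (!nrow(cands)) next
      for (i in seq_len(nrow(cands))) {
        mm <- match_fragment_ions(t40, cands[i, ], cfg$fragment_tolerance)
        if (is_acceptable_candidate(mm, cands[i, ]))
          expect_lte(nrow(mm), psm$n_matched)
      }
    }
  }
})

test_that("Mann-Whitney summary: exact enumeration, ties, bin conservation", {
  mk_psm <- function(score, decoy)
    structure(list(pep_score = score, is_decoy_hit = decoy,
                   spectrum_title = "x"), class = "glyco_psm")
  psms <- c(lapply(c(3, 4, 5), mk_psm, decoy = FALSE),
            lapply(c(1, 2), mk_psm, decoy = TRUE))
  td <- target_decoy_summary(psms)
  expect_equal(td$U, 6)
  expect_equal(td$p_value, 0.2)
  # brute-force oracle over all rank arrangements for random small samples
  enum_oracle <- function(x, y) {
    pooled <- c(x, y); n1 <- length(x)
    r <- rank(pooled); mu <- n1 * length(y) / 2
    u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    us <- apply(utils::combn(length(pooled), n1), 2,
                function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
    mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
  }
  set.seed(29)
  for (rep in 1:8) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(0:20, n1, replace = TRUE); y <- sample(0:20, n2, replace = TRUE)
    if (length(unique(c(x, y))) == 1L) next
    psms <- c(lapply(x, mk_psm, decoy = FALSE), lapply(y, mk_psm, decoy = TRUE))
    td <- target_decoy_summary(psms)
    expect_equal(td$p_value, enum_oracle(x, y), tolerance = 1e-12)
    # tie-free cases also agree with the standard exact test
    if (!anyDuplicated(c(x, y)))
      expect_equal(td$p_value, stats::wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    expect_equal(sum(td$bins$n_target), length(x))
    expect_equal(sum(td$bins$n_decoy), length(y))
  }
  # identical multisets give the null U and a degenerate flag when constant
  same <- c(lapply(c(10, 20), mk_psm, decoy = FALSE),
            lapply(c(10, 20), mk_psm, decoy = TRUE))
  expect_equal(target_decoy_summary(same)$U, 2 * 2 / 2)
  const <- c(lapply(c(7, 7), mk_psm, decoy = FALSE),
             lapply(c(7, 7), mk_psm, decoy = TRUE))
  tdc <- target_decoy_summary(const)
  expect_equal(tdc$p_value, 1)
  expect_match(tdc$note, "degenerate")
})
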