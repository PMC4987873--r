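test_that("tryptic digestion cleaves after K/R (not before P) with missed sites", {
  d0 <- digest("AAKCCRDDKEE", max_missed = 0L)
  expect_setequal(d0$peptide, c("AAK", "CCR", "DDK", "EE"))
  d2 <- digest("AAKCCRDDKEE", max_missed = 2L)
  expect_setequal(d2$peptide,
                  c("AAK", "CCR", "DDK", "EE", "AAKCCR", "CCRDDK", "DDKEE",
                    "AAKCCRDDK", "CCRDDKEE"))
  dkp <- digest("AAKPGGR", max_missed = 0L)
  expect_setequal(dkp$peptide, c("AAKPGGR"))
  expect_error(digest("AAK", enzyme = "lysC"), "unknown enzyme")
})

test_that("sequon detection uses protein context across peptide boundaries", {
  hrp <- hrp_sequence()[[1]]
  # NVGLNR: its second N is a sequon whose S/T lies in the next peptide
  start <- regexpr("NVGLNR", hrp, fixed = TRUE) - 1L
  expect_equal(find_sequons(hrp, start, 6L), 4L)
  # MGNITPLTGTQGQIR: one sequon at the N of N-I-T
  start <- regexpr("MGNITPLTGTQGQIR", hrp, fixed = TRUE) - 1L
  expect_equal(find_sequons(hrp, start, 15L), 2L)
  # double sequons
  start <- regexpr("LYNFSNTGLPDPTLNTTYLQTLR", hrp, fixed = TRUE) - 1L
  expect_equal(find_sequons(hrp, start, 23L), c(2L, 14L))
  # X = P excluded
  expect_equal(find_sequons("AANPTAA", 0L, 7L), integer())
  expect_error(find_sequons("AAA", 1L, 5L), "outside")
})

test_that("HRP enumeration reproduces missed-cleavage and length behavior", {
  hrp <- hrp_sequence()
  t <- suppressWarnings(enumerate_target_peptides(hrp, glyco_config()))
  # DSFRNVGLNR arises with one missed cleavage alongside NVGLNR
  expect_true("DSFRNVGLNR" %in% t$sequence[t$missed == 1])
  expect_true("NVGLNR" %in% t$sequence[t$missed == 0])
  # length window respected
  expect_true(all(nchar(t$sequence) >= 6 & nchar(t$sequence) <= 40))
  # the 49-residue N-terminal sequon peptide is excluded by length
  expect_false(any(grepl("QLTPTFYDNSCPNVSNIVR", t$sequence, fixed = TRUE) &
                     t$missed == 0))
  # no-sequon protein contributes nothing, with a warning
  expect_warning(none <- enumerate_target_peptides(c(x = "AAAKGGGR"),
                                                   glyco_config()),
                 "no sequon")
  expect_equal(nrow(none), 0L)
})

test_that("deamidation is never placed on a sequon asparagine", {
  t <- suppressWarnings(enumerate_target_peptides(hrp_sequence(),
                                                  glyco_config()))
  for (i in which(t$sequence == "NVGLNR")) {
    mods <- t$mods[i]
    if (!nzchar(mods)) next
    # sequon N is position 5 (1-based)
    expect_false(grepl("deam@5", mods, fixed = TRUE))
  }
})

test_that("the even-odd transform switches position pairs", {
  expect_equal(glycotrident:::.transform_sequence("GLCP", "evenodd"), "LGPC")
  expect_equal(glycotrident:::.transform_sequence("GLCPA", "evenodd"), "LGPCA")
  expect_equal(glycotrident:::.transform_sequence("GLCP", "reverse"), "PCLG")
})

test_that("block-swap relocation preserves the residue multiset", {
  target <- data.frame(sequence = "AAANSTAAAK", mods = "", sequons = "3",
                       missed = 0L, is_decoy = FALSE, transform = "none",
                       source_protein = "x", source_target = NA,
                       mass = peptide_neutral_mass("AAANSTAAAK"))
  set.seed(2)
  d <- suppressWarnings(generate_decoys(target, glyco_config(), dedup = FALSE))
  # every decoy is an anagram of the target
  canon <- function(s) paste(sort(strsplit(s, "")[[1]]), collapse = "")
  expect_true(all(vapply(d$sequence, canon, "") == canon(target$sequence)))
  # relocated sequons carry the NST block verbatim
  for (i in seq_len(nrow(d))) {
    sq <- as.integer(strsplit(d$sequons[i], ",")[[1]])
    expect_equal(substr(d$sequence[i], sq + 1L, sq + 3L), "NST")
  }
  # the relocation primitive: swapping the sequon block (0-based 3-5) with
  # positions 0-2 of AAANSTAAAK gives NSTAAAAAAK
  aa <- strsplit("AAANSTAAAK", "")[[1]]
  expect_equal(paste(glycotrident:::.swap_blocks(aa, 4L, 1L, 3L),
                     collapse = ""), "NSTAAAAAAK")
})

test_that("a single-sequon target yields 10 decoys before deduplication", {
  target <- data.frame(sequence = "ACDNFSGHIKLR", mods = "", sequons = "3",
                       missed = 0L, is_decoy = FALSE, transform = "none",
                       source_protein = "x", source_target = NA,
                       mass = peptide_neutral_mass("ACDNFSGHIKLR"))
  set.seed(4)
  d <- generate_decoys(target, glyco_config(), dedup = FALSE)
  expect_equal(attr(d, "n_raw"), 10L)
  expect_equal(nrow(d), 10L)
  expect_true(all(d$mass == target$mass))  # exact isobarity
})

test_that("database build is deterministic, isobaric and target-clean", {
  hrp <- hrp_sequence()
  cfg <- glyco_config(random_seed = 123L)
  db1 <- suppressWarnings(build_database(hrp, cfg))
  db2 <- suppressWarnings(build_database(hrp, cfg))
  expect_identical(db1$entries, db2$entries)
  expect_false(is.unsorted(db1$entries$mass))
  # whole-DB scan: every decoy's stored mass equals the mass recomputed from
  # its own sequence and modifications, and matches a target entry of its
  # source sequence exactly
  dec <- db1$entries[db1$entries$is_decoy, ]
  tgt <- db1$entries[!db1$entries$is_decoy, ]
  recomputed <- vapply(seq_len(nrow(dec)), function(i)
    peptide_neutral_mass(dec$sequence[i],
                         glycotrident:::parse_mods(dec$mods[i])), 0)
  expect_equal(recomputed, dec$mass, tolerance = 1e-9)
  has_src <- vapply(seq_len(nrow(dec)), function(i)
    any(tgt$sequence == dec$source_target[i] & tgt$mass == dec$mass[i]), TRUE)
  expect_true(all(has_src))
  # no decoy sequence equals any target sequence
  expect_length(intersect(dec$sequence, tgt$sequence), 0L)
  # decoy:target ratio in the expected band
  expect_gte(db1$n_decoys / db1$n_targets, 5)
  expect_lte(db1$n_decoys / db1$n_targets, 13)
  # duplicated input proteins collapse to the same database
  db3 <- suppressWarnings(build_database(c(hrp, dup = unname(hrp)), cfg))
  expect_identical(db3$entries, db1$entries)
  suppressWarnings(expect_error(build_database(c(x = "AAAKGGGR"), cfg)))
})
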