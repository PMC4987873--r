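---
title: "Methods: site-specific N-glycopeptide identification with glycotrident"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: site-specific N-glycopeptide identification with glycotrident}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycotrident)
```

## The model of a glycopeptide spectrum

`glycotrident` assumes centroided beam-type CID/HCD MS2 spectra of intact
N-linked glycopeptides. In such spectra glycosidic bonds fragment
preferentially, so the signal is dominated by two glycan ion families:

* **B-ions (oxonium ions)** in the low m/z region — glycan fragments such as
  HexNAc+ (m/z 204.087) and HexHexNAc+ (m/z 366.139) — which carry no
  peptide information but are diagnostic of a glycopeptide precursor;
* **Y-ions** — the intact peptide retaining a residual glycan, forming a
  ladder of peaks separated by monosaccharide residue masses, down to Y1
  (peptide + GlcNAc) and Y0 (the bare peptide).

The peptide backbone b/y ions are present but sparse and weak, and the
recorded precursor m/z is that of the intact glycopeptide. All masses are
monoisotopic; isotope envelopes, a/c/z ions and neutral-loss backbone
fragments are out of scope.

## Y0 determination (triplet patterns)

For each charge state z from 1 to the precursor charge, every peak p is
tested as a Y0 candidate against two triplet patterns:

* pattern A: peaks at p + GlcNAc/z and p + 2·GlcNAc/z (the Y0/Y1/Y2 ladder);
* pattern B: peaks at p − NH3/z and p + GlcNAc/z (ammonia loss next to the
  Y0/Y1 step).

Searching all charge states up to the precursor charge reflects that
Y-series ions of multiply charged precursors commonly appear at reduced
charge. Candidates are deduplicated on the implied peptide neutral mass
(rounded to the fragment-tolerance grid); a candidate found by both
patterns is kept once with the union of the evidence peaks. A Y0 whose
neutral mass is not below the intact precursor neutral mass is discarded.
No intensity floor is applied to the triplet peaks: at the default
tolerance the spacing constraint is selective on its own, and a floor would
cost sensitivity for weak late-eluting glycoforms.

Every surviving Y0 candidate is processed independently (one in silico
spectrum per candidate); the targeted search resolves multi-candidate
spectra afterwards, so ambiguity at this stage is deliberately preserved.

## Y-ladder extension and in silico spectra

Above each Y0, the spectrum's peaks form a DAG whose edges connect peaks
differing by any monosaccharide residue mass divided by z, within the
fragment tolerance. The Y-ladder is the maximum-length path starting at Y0,
found by dynamic programming over the m/z order; ties are broken by the
larger summed peak intensity (preferring the more intense, more plausible
ion series). The unit tests pin this DP against exhaustive path enumeration
on spectra of up to 12 peaks.

The in silico peptide spectrum is the source spectrum minus (a) every peak
in a built-in oxonium window, (b) the ladder peaks including Y0 and the
triplet evidence peaks, and (c) peaks matching the ladder ions at the other
charge states. Its precursor is the Y0-derived peptide neutral mass at
charge `precursor_charge − 1` (or 1 for singly charged precursors): the
departing glycan is assumed to carry away at most one charge. This emission
charge is a convention, not an observable — the peptide neutral mass is
what downstream search engines consume — and it is config-overridable in
effect because the written MGF records both m/z and charge. Stripping is
idempotent: applied to its own output it removes nothing. If stripping
empties a spectrum, that spectrum is dropped with a warning.

## Glycan composition inference

The glycan neutral mass is the intact precursor neutral mass minus the Y0
peptide mass. It is matched by binary search against a deterministic,
mass-sorted table of all compositions over {Hex, HexNAc, dHex, NeuAc,
NeuGc} with at most `glycan_max_residues` (default 29) residues satisfying:

* HexNAc ≥ 2 and Hex ≥ 3 — the invariant N-glycan trimannosyl-chitobiose
  core;
* dHex ≤ HexNAc — fucosylation limited by available HexNAc attachment
  points;
* NeuAc + NeuGc ≤ max(1, HexNAc − 2) — sialylation limited by the antenna
  count.

These are the standard glyco-informatics constraint choices; the rule set
is a package decision (the biological literature offers no single canonical
list) and the bounds are exposed through the composition-table builder so
stricter or looser sets can be evaluated.

The match tolerance defaults to `0.02 × (1 + glycan_mass/2000)` Da — a
0.02 Da instrument-level window inflated with mass to absorb error
accumulated along the Y-ladder subtraction. Candidates are scored in [0, 1]
as `0.7 × ladder coverage + 0.3 × oxonium type evidence`, where ladder
coverage is the fraction of the candidate's residue multiset coverable by
the observed ladder steps and type evidence the fraction of its distinct
monosaccharide types seen among matched oxonium-ion compositions. The
weights favor ladder evidence because ladder steps are composition-specific
while oxonium ions only witness the presence of a type; both weights are
arguments. Ties break by smaller absolute mass deviation, then
lexicographically, making ranks total and deterministic.

## Target-decoy database

Targets are fully tryptic peptides (cleave after K/R, not before P;
semi-specific digestion deliberately unsupported) with up to 2 missed
cleavages, containing at least one sequon N-X-S/T (X ≠ P) evaluated in
*protein* context so sequons truncated at a peptide C-terminus still
count. Targets are restricted to 6–40 residues — a detectability window
applied to the targets themselves, not only to decoy generation — and
expanded over modifications: carbamidomethyl-C fixed; deamidation (N/Q,
+0.98402 Da) and oxidation (M, +15.99491 Da) variable with at most 2
variable modifications per peptide, and deamidation never placed on a
sequon asparagine (which carries the glycan in a glyco-targeted search).

Each target spawns decoys by two sequence transforms — reversal and
even-odd position switching — followed by five sequon placements per
sequon: the sequon tri-residue block restored at its original position,
plus four uniformly drawn alternative positions. Placement is realized as
a mass-preserving three-residue **block swap** (never an overwrite), so
every decoy is exactly isobaric with its source target and genuinely
competes at the 0.6 Da precursor-match stage; an overwrite would shift
decoy masses and weaken the null. Multi-sequon targets iterate the
relocation one sequon at a time with the others held fixed. A
single-sequon target therefore yields exactly 10 decoys before duplicate
removal. Decoys equal to any target sequence are removed. All placement
randomness flows from one seed, drawn in deterministic target order, so a
database build is a pure function of (sequences, config, seed).

### Sensitivity of the target count to the modification policy

The modification policy materially changes the size of the target list.
For the bundled horseradish peroxidase (HRP) reference sequence the
default policy above yields 236 target entries (asserted in the test
suite). The count is highly sensitive to the policy corners — the variable
modification cap, whether deamidation is allowed on sequon N or on Q at
all, and whether placements are position-resolved — spanning roughly a
factor of ten across reasonable choices. The grid below reproduces the
sensitivity analysis:

```{r mod-sensitivity, eval = FALSE}
hrp <- hrp_sequence()
for (cap in 1:3) {
  cfg <- glyco_config(max_var_mods = cap)
  n <- nrow(suppressWarnings(enumerate_target_peptides(hrp, cfg)))
  cat(sprintf("max_var_mods = %d -> %d targets\n", cap, n))
}
```

Digestion of this reference uses the **untrimmed precursor** (signal
peptide and propeptide included). With the precursor, the fully digested
sequon-bearing peptides within 6–40 residues are exactly seven, carrying
eight sequons — the N-terminal sequon sits in a 49-residue fully tryptic
peptide excluded by the length window. Digesting the mature chain instead
would expose that sequon in a 19-residue peptide and change the counts;
`trim_signal_peptide` records the choice in the configuration.

## Targeted search and scoring

The Y0-derived peptide mass is matched against the mass-sorted database at
0.6 Da (the precursor-match tolerance; the tests pin the binary search
against a linear scan). For each candidate, theoretical b/y ions at 1+ and
2+ — two charge states is the sensible bound for tryptic peptides — are
matched one-to-one against the 40 most intense in silico peaks at the
fragment tolerance (0.05 Da by default, deliberately distinct from the
0.6 Da precursor window), greedily by smallest m/z deviation. A target
candidate needs ≥ 3 matched ions, and with exactly 3, two consecutive
same-series ions at 1+; decoy candidates face no floor, which lets decoys
express the null. PepScore is

> 100 × (summed intensity of top-40 peaks matched to 1+ b/y ions) /
> (summed intensity of all top-40 peaks),

so 2+ matches support acceptance but not the score. Within a Y0 candidate
the best PepScore wins; across the Y0 candidates of one source spectrum
the winner has the most matched ions, then the higher PepScore, then the
lower Y0 m/z (an explicit determinism tie-break). Target and decoy hit
scores are binned over [0, 100] and compared with a two-sided Mann–Whitney
U-test — exact by enumeration of all assignments when both groups have ≤ 8
hits (correct under ties by construction), the tie-corrected normal
approximation otherwise. A decoy-based FDR column
(#decoys ≥ s / #targets ≥ s) is emitted as a clearly optional diagnostic
extension.

## What the synthetic generator does and does not emulate

`synth_dataset()` produces glycopeptide spectra with the assumed
phenomenology: dominant oxonium B-ions and a complete 1+ Y-ladder ordered
core-first with terminal sialic acids last (intensities 30–100% of the
base peak), a Y0−NH3 companion, a sampled 70% of 1+ b/y ions at ≤ 5% of
the base peak, Gaussian m/z jitter (sd 0.005 Da, well under half the
0.05 Da fragment tolerance), and 30 noise peaks with uniform m/z and
exponential intensity (mean 2% of base peak) per spectrum. Negative
controls are plain peptide spectra whose noise is kept out of the
diagnostic oxonium windows, so filter specificity is exactly testable; a
hard-negative mode plants a lone HexNAc+ peak to exercise the pair rule.
These defaults are the package's study conditions: the jitter and noise
levels are what a well-calibrated high-resolution instrument delivers, and
the b/y inclusion fraction reflects the sparse backbone fragmentation of
beam-type CID.

The generator does **not** emulate isotope envelopes, chimeric spectra,
co-eluting glycoforms, retention-time structure, charge-reduced Y-series
of high-charge precursors, or fucose migration. Passing the synthetic
suites therefore demonstrates algorithmic correctness under the stated
spectrum model — recovery rates on real data additionally depend on
deconvolution quality and on phenomena the generator excludes.

At zero noise and zero jitter the pipeline is exact by construction (100%
filter sensitivity, Y0 recovery, composition containment and targeted
top-hit accuracy on a 300-spectrum suite); at the default noise level the
suite requires ≥ 90% Y0 recovery and top-hit accuracy, and spectra of
proteins absent from the database must draw ≤ 5% confident
(PepScore ≥ 50) target hits on 100 spectra. These problem sizes keep the
default test run fast while leaving the rates' estimates stable.

## Numerical and degenerate-input choices

* Proton 1.007276 Da; residue and monosaccharide masses derived from
  atomic monoisotopic masses; m/z↔mass conversion round-trips to 1e−9 Da.
* Peak lists are sorted on construction; exact duplicate m/z values
  collapse to the most intense peak.
* MGF blocks lacking a CHARGE line default to 2+ with a warning (most
  tryptic glycopeptide precursors are ≥ 2+), keeping the event auditable.
* Empty candidate lists, empty spectra and zero-step ladders flow through
  as empty results, never errors; a Y0 implying a non-positive glycan mass
  is an error and the candidate is discarded upstream.
* An all-identical score set makes the U-test degenerate; p is reported as
  1 with a flag rather than NA.
* Every output artifact embeds the MD5 digest of the run configuration,
  and the YAML config round-trip is bit-exact at full double precision.

## Known limitations

Mascot/X!Tandem result parsing is replaced by a neutral TSV PSM contract
for the report integrator; mzML/mzXML input, glycan topology enumeration,
O-glycan rule sets, site-localization scores beyond reporting all sequon
positions, and protein-level FDR are out of scope. The composition
evidence score is a documented two-term stand-in honoring the available
B-/Y-ion evidence; its weights are arguments, not truths.
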