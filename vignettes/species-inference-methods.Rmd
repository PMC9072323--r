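---
title: "Site-level species inference from bone proteomes: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Site-level species inference from bone proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protaxa)
```

## The inference problem

Protein databases are wildly uneven across mammalian species: missing
genes, alignment gaps and prediction errors bias any assignment based on
raw counts of identified peptides or protein groups toward well-annotated
species. `protaxa` therefore works at the level of individual alignment
columns. A gene-wise multiple sequence alignment over the 20 most abundant
bone protein-coding genes is concatenated in alphabetical gene order and
every column receives a *global site* number in `1..L`. Two species are
compared only at sites where both have a known (non-gap) residue and the
residues differ — the *site difference matrix*. This makes the comparison
symmetric in database quality: a species cannot win or lose at sites it
has no sequence for.

### From peptides to sites

Evidence tables (MaxQuant `evidence.txt` or a Spectronaut report; the two
dialects differ only in column names) are filtered at 1% precursor FDR
where a q-value column exists — MaxQuant evidence tables are already
engine-filtered and carry none. Isoleucine is indistinguishable from
leucine in standard MS/MS, so every sequence on both sides is projected
I→L before matching. Each stripped peptide is matched as an exact
substring of every species' gapless gene sequences and its residues are
lifted to global sites through per-species residue maps. We deliberately
re-match rather than trust the search engine's protein-id column: the
result is identical across dialects and independent of how the engine
groups proteins. No missed-cleavage or terminus model is applied at
matching time; enzymatic specificity already lives in the upstream search.

Per (raw file, global site, amino acid) four metrics are aggregated:
distinct precursor count (unique modified sequence + charge), distinct
peptide count (unique stripped sequence), summed intensity and maximum
search score. A precursor matching several species contributes once per
covered site, not once per species.

### The joint score

Within each (file, site), summed intensities above 1 are log10
transformed (0 otherwise), each of the four metrics is divided by its
maximum over the amino acids observed at that site, and the four ratios
are multiplied and rescaled by the site maximum. The resulting J-score
lies in [0, 1], equals 1 for the best-supported amino acid at a site, and
intentionally mixes independent notions of evidence strength; it is not a
posterior probability of the amino acid and is never interpreted as one.

Two degenerate situations need a rule the formula does not give:

* a metric whose per-site maximum is 0 (all intensities ≤ 1, or all
  scores ≤ 0 after negative scores are clamped to 0) would produce 0/0;
  it is treated as *neutral* — factor 1 for every amino acid — so the
  remaining metrics still rank the candidates;
* if every amino acid at a site ends with a zero product (different rows
  zeroed by different metrics), all J-scores at that site are 0 and the
  site is effectively uninformative.

### Competition and indistinguishable sets

For each file and each species pair, the J-scores of each species'
variants over the pair's discriminating sites are summed; the larger sum
wins, and equal sums — including the common case where none of the pair's
sites were observed — are a tie in which *both* species win. Counting a
tie as a win for both means "no data" never penalizes either side, and it
is what allows the method to output honest indistinguishable sets: the
best match is the set of species with the maximal number of wins. An
optional fine-grouping step rescores a best match that intersects a
curated marker-peptide group (e.g. sheep vs. goat) by the summed precursor
intensity of each candidate's markers, returning the argmax set; summing
(rather than taking the maximum) uses all marker evidence and is robust to
a single spuriously intense precursor. Fine-grouping never widens the
taxonomy beyond the marker group(s) involved.

### Two FDR mechanisms

**Decoy species.** The filtered target database is extended with an equal
number of chimeric decoys: the global alignment is cut into 500-column
slices (the last slice may be shorter) and each slice is copied verbatim,
gaps included, from a target species drawn uniformly *with replacement*;
sampling with replacement and keeping the terminal partial slice are
genuinely free design choices, fixed here once and recorded. A decoy
identical to a target is regenerated;
if the slice length spans the whole alignment every candidate would be
such a copy, which is reported as an error rather than looped on. Decoys
enter the difference matrix and the competition exactly like targets.
Ranking all files by *site count* — the number of distinct global sites
whose observed amino acid matches the assigned species (any member of an
indistinguishable set, since the set is one taxonomic claim) — the q-value
at a rank is the fraction of decoy-only assignments above it. Tied site
counts share the q of the worst rank of their tie group, and q-values are
monotonized by a cumulative minimum from the lowest-coverage rank upward,
so the 1% flag corresponds to a single site-count cutoff. A set mixing
targets and decoys counts as a target assignment: a decoy that merely ties
should not inflate the FDR.

**Protease spike-in.** Trypsin and Lys-C autolysis peptides are present in
every run at roughly constant absolute intensity, so the *relative
protease intensity* — protease intensity over total intensity — is an
inverse proxy for endogenous signal. The cutoff is the 75th percentile
(linear-interpolation quantile, the common default among the several
"upper quartile" conventions) of the blank files' ratios; files at or above it
are flagged `signal_too_low`. With no blanks in the cohort the package
refuses to guess and demands a manual cutoff.

All files of a study are processed jointly: the q-value is a cohort
quantity, and an incremental mode is deliberately absent.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `max_missing` | 5 (of the populated genes) | species lacking more genes are removed before inference |
| `slice_len` | 500 columns | decoy slice width |
| `n_decoys` | = targets | decoy roster size |
| `fdr_alpha` | 0.01 | precursor q-value threshold |
| `q_threshold` | 0.01 | species-level decoy q-value threshold |
| blank quantile | 0.75, type 7 | protease-intensity cutoff calibration |

The gene-count filter counts missing genes against the genes actually
populated in the database at hand, so the same `max_missing = 5` semantics
apply to a 20-gene production database and to a 6-gene desk-scale one.

## Open points resolved in this implementation

* **Isoform collapse.** The difference matrix needs one sequence per
  (species, gene); when several aligned isoforms exist they are collapsed
  to a per-column majority consensus (ties alphabetical; a column with
  more than half gaps becomes a gap).
* **Ambiguous residues.** X/B/Z/U cannot carry site information and are
  converted to gaps on ingest (counted and reported).
* **Pair counting.** Competition is over all unordered pairs of the
  combined target+decoy roster, i.e. `(2n choose 2)` pairs for `n`
  targets (an `n` x `n` target-vs-decoy square would count comparisons
  differently and is not used).
* **Precursor vs. peptide.** A precursor is a unique (modified sequence,
  charge) within a raw file; a peptide is a unique stripped sequence —
  the standard convention. Duplicate precursor rows are merged (intensity
  summed, score maximum) *before* site aggregation.

## What the simulator emulates — and what it does not

`simulate_database()` draws a random coalescent tree (`ape::rcoal`),
rescales it so the root-to-tip path equals `divergence` expected
substitutions per site (default 0.08, giving roughly 10–15% pairwise
differences — the order of divergence seen between mammalian families in
collagen), and evolves uniformly random root sequences with per-site
uniform replacement over the other 19 amino acids. There is no rate
heterogeneity, no indel process (gaps enter as missing genes and random
gap runs), and no biased amino-acid composition; the model's only job is
to create discriminating sites with controllable density, and the
two-species expectation `P(diff) = 2p(1-p) + p²·18/19`, `p = 1-exp(-b)`,
is checked against it.

`simulate_evidence()` draws peptides from an in-silico semi-tryptic
digest (cleavage after K/R, not before P, ≤ 2 missed cleavages, lengths
7–30, 30% of peptides truncated on one side — degraded bone is rich in
semi-tryptic peptides) until a target number of distinct residues of the
true species is covered; intensities are log-normal (median 1e6,
`sdlog` 1.2), scores normal around 100 floored at 40, charges 2:3 at
70:30, and N/Q residues carry deamidation annotations with probability
0.2. Protease autolysis peptides are added and rescaled so the file's
relative protease intensity equals the configured value (default 5%)
exactly. Blank files contain protease peptides as their only quantified
signal plus unquantified noise identifications that are rejection-sampled
to match nothing in the database; their relative protease intensity is
therefore exactly 1, which makes the blank-calibrated cutoff flag every
blank — in real data blanks scatter slightly below 1 and a blank cleaner
than 75% of its peers could escape the flag. The simulator produces no
spectra, no retention times, no chromatographic effects, no shared
contamination between files, and its intensity noise is independent per
precursor; passing tests on synthetic data therefore validate the
*inference logic and its FDR bookkeeping*, not robustness to real
instrument artefacts.

## Problem sizes used in the test suite

Desk-scale databases use 6 genes (~3,800 alignment columns) and 30
species plus one held-out species; the FDR cohort is 200 files (150 from
database species, 30 from the held-out species, 20 blanks) over 30
targets + 30 decoys. Species-recovery runs use a coverage target of 1,000
sites; the near-identical-sister scenario (a species differing from the
truth at 12 sites) requires ≥ 3,000 covered sites, which is only
realizable with complete sequences and a larger proteome, so that
scenario uses complete collagen-scale gene lengths (~5,100 columns).
Oracle-equivalence checks run on 50 random toy databases of ≤ 6 species
against naive brute-force reimplementations of the difference matrix,
substring annotation and pairwise competition.

## Known limitations

* Exact substring matching cannot place peptides spanning residues the
  database itself got wrong; a single bad residue in the database splits
  real peptide evidence.
* The J-score is uncalibrated; downstream consumers should treat the
  consensus sequences (`write_consensus_fasta()`) as evidence summaries,
  not genotype calls.
* Mixtures (hybrids, contamination across species) are out of scope: the
  competition assumes one dominant species per file, and marker-peptide
  intensities for hybrid candidates are reported but not called.
* With few blanks the protease cutoff is a quantile of a tiny sample;
  three blanks per plate is a practical minimum.
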