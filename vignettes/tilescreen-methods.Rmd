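---
title: "Methods: tiled spacer screens, from oligo design to phenotype statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tiled spacer screens, from oligo design to phenotype statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilescreen)
library(dplyr)
```

This vignette is the package's own account of what it computes and why:
the model behind each stage, the tunable parameters with their defaults,
what the synthetic-data generator does and does not emulate, and the
numerical and design choices made where more than one convention was
defensible.

## 1. The screen in one paragraph

A type III-A CRISPR-Cas system targets phage transcripts: a spacer
protects only if its crRNA is complementary to RNA actually made during
infection, so protection depends on the targeted strand and on the timing
of the targeted operon. The screen tiles spacers densely across *both*
strands of a phage genome, clones them as a pooled library, infects, and
sequences the spacer cassettes before and after infection. The central
statistic is the per-spacer **enrichment ratio**

$$E_s = \frac{f_s(t)}{f_s(t_0)}, \qquad f_s = \frac{c_s}{\sum_{s'} c_{s'}},$$

the post-infection frequency of spacer $s$ over its frequency in the
uninfected library. Plotted against genome position, split by matched
strand, $E$ forms a landscape whose structure (early operon vs late
operon, plus vs minus strand) is the screen's readout.

## 2. Library design

`design_tiled_spacers(genome, k, stride)` enumerates every interval
$[start, start+k)$ with $start = 0, stride, 2\,stride, \dots$ and
$start + k \le L$, once per strand. The count is
$2\,(\lfloor (L-k)/stride \rfloor + 1)$; at the default $k = 35$,
$stride = 2$ a 42,000-nt genome yields 41,966 spacers.

Choices:

* **Spacer length `k = 35` nt.** A typical processed spacer length for
  type III-A systems; exposed as an argument since any (genome, k) pair
  can be designed.
* **Coordinates are 0-based, half-open**, on the plus strand for both
  strands' spacers — the BED convention, so positions join cleanly with
  region annotations and coverage tracks downstream. Minus-strand spacers
  carry the reverse complement of the interval as their sequence.
* **Ambiguous bases.** Genomes may contain `N`; affected spacers are
  emitted but flagged `ambiguous` (with `strict = TRUE` they are an
  error). Flagged spacers are excluded from mapping-based tests.
* **Oligos.** `build_oligos()` concatenates constant flanks around each
  spacer and checks the total length (default 90 nt, the standard pool
  oligo size: 30-nt upstream flank + 35-nt spacer + 25-nt downstream
  flank). The default flanks are documented placeholders — real cloning
  schemes supply their own priming/cloning/repeat-homology sequences via
  `oligo_layout()`.

## 3. Spacer extraction from amplicon reads

A sequenced cassette read contains the spacer between two copies of the
direct repeat (DR). `find_repeat_flanked_inserts()`:

1. finds all DR occurrences in the read within a **Hamming** mismatch
   budget (default `max_mismatches = 1`);
2. chains occurrences greedily left-to-right so that kept occurrences
   never overlap (leftmost-match-first);
3. emits every gap between two consecutive kept occurrences whose length
   lies in `[min_len, max_len]` (default `[30, 45]` nt, bracketing
   type III-A spacer lengths and excluding repeat–repeat artifacts);
4. repeats the scan on the reverse complement of the read (default on),
   reporting those inserts in the orientation that places the DR 5'→3'.

Hamming rather than edit distance keeps the scan $O(\text{read} \times
\text{repeat})$ and matches the biology: substitution errors dominate in
short amplicons, and an indel inside a DR would shift the insert frame
anyway. Occurrence search is delegated to Biostrings
(`vmatchPattern`), with the chaining and windowing logic implemented
here; the test suite checks the whole operation against an independent
all-substring brute-force scan.

`extract_spacer_counts()` applies this to every read of a FASTQ file
(plain or gzipped) and tallies inserts **verbatim**: no error correction
or clustering, so an insert with an internal sequencing error becomes a
distinct key. This mirrors a direct counting script; downstream mapping
tolerates such keys through its own mismatch budget. Quality scores are
read but ignored — the counting model makes no use of them. Malformed
records are reported with their record index.

## 4. Enrichment landscapes

* `spacer_frequencies()` computes $f_s$ over the spacers counted in the
  sample; frequencies sum to 1 by construction.
* `enrichment_ratios(ft, f0, min_t0_count = 5)` computes $E$ for every
  spacer with at least `min_t0_count` reads at $t_0$. **No pseudocounts
  are used**: spacers below the threshold are excluded
  (status `absent_t0`) rather than inflated, because pseudocounts would
  bias region means; spacers undetected post-infection keep $f_t = 0$,
  $E = 0$ (status `absent_t`). The default threshold of 5 reads keeps the
  relative error of $f_0$ below ~45% for retained spacers while
  discarding little of a well-covered library.
* `locate_spacers()` / `align_spacers()` match sequences to the genome on
  both strands within a Hamming budget (exact matching via a PDict,
  mismatch matching per query). Gapped alignment is deliberately out of
  scope: designed and acquired spacers are genome substrings up to
  substitution errors. Queries with several equally good positions are
  `ambiguous` and excluded from profiles (never double-counted), with a
  QC tally.
* `position_profile()` places one point per designed spacer at the
  **start of its plus-strand interval** for both strands — a single
  consistent x-axis for the two tracks.
* `region_summary()` reports n, mean and **sample SD (n−1 denominator)**
  of $E$ per region × matched strand — the conventional reading of
  "mean ± SD" — plus the number of detected spacers.
  `unique_detection_by_region()` counts distinct spacers with positive
  counts per region/strand, the statistic used to compare genotypes'
  survivor sets.
* Region defaults place the early operon (PE) at `[1000, 15000)` and the
  late operon (PL) at `[15000, 42000)` on a 42-kb genome, both
  transcribed from the plus strand. The boundary splitting PE into a
  Csm6-independent upstream and a Csm6-dependent downstream part is not a
  sharply defined coordinate; it defaults to the PE midpoint and is
  configurable everywhere it is used (`split_pe`, `pe_split`).

## 5. Acquisition mapping and RPM

`strand_coverage()` increments every genome position under each uniquely
mapped hit, per strand, at single-nucleotide resolution;
`rpm_normalize()` converts counts to reads per million:

$$\mathrm{RPM}[i] = 10^6 \cdot \frac{\text{count}[i]}{\text{total aligned reads}}.$$

The denominator — all reads aligned anywhere, phage plus host — is an
**explicit argument**, not inferred, because "total aligned" is exactly
the kind of quantity that silently drifts between pipelines; making it an
input keeps the normalization auditable. Multi-hit queries are dropped
from coverage (and tallied) rather than counted once or at all loci;
on low-repeat phage genomes this discards almost nothing and never
inflates repeats. Tracks round-trip exactly through run-length-encoded
bedGraph files.

## 6. Expression normalization and correlation

RNA-seq coverage tracks from different timepoints differ in sequencing
depth. `normalize_timepoints()` scales each track by
`reference_size / library_size` with the **reference set to the smallest
library**: down-scaling only, which never extrapolates counts that were
not observed. Per-spacer target expression is the **mean** (not sum)
normalized coverage over the spacer interval — length-invariant for fixed
k — and is defined only for minus-strand spacers, whose crRNA has a
plus-strand transcript to pair with; plus-strand spacers are flagged
`no_target`.

`pearson_r()` is implemented from the centered product-moment definition
(the package's own statistic, cross-checked against `stats::cor` in the
tests) and errors on degenerate (zero-variance) input. Correlation is
computed on untransformed values by default; a log10 option exists since
enrichment ratios are naturally multiplicative.

## 7. Phenotype statistics

* `time_to_threshold()` interpolates linearly between the two
  observations bracketing the first crossing of the OD threshold
  (default OD600 = 0.5); a series starting above threshold returns 0.
  Interpolation is linear in OD — growth is locally smooth at 30-min
  sampling, and any monotone interpolation preserves the ordering used
  downstream.
* `regrowth_fraction()` calls a well regrown if it crosses the threshold
  within the horizon (default: last timepoint common to all wells).
  Whether one pools wells or averages per-replicate fractions is a real
  convention choice, so **both are reported** (attributes
  `pooled_fraction` and `mean_fraction` ± `sd_fraction`), along with the
  per-replicate binomial SD.
* `welch_t()` implements the unequal-variance t statistic with
  Welch–Satterthwaite degrees of freedom. Welch is the safe default for
  an "unpaired t-test" when equal variances were never asserted; with
  equal variances it loses almost nothing. Both-groups-constant corner
  cases are defined explicitly (equal means: t = 0, p = 1; unequal:
  p = 0, flagged degenerate).
* `escape_fraction()` is the paired-titer ratio
  targeting-host PFU / naive-host PFU; the naive titer must be positive.
* Blank subtraction is out of scope — input OD is assumed
  blank-corrected.

## 8. The synthetic-data generator

The generator produces every input the pipeline consumes, with ground
truth returned alongside each artifact, so tests assert recovery of known
structure rather than plausibility.

**Genome** (`simulate_genome`): a seeded random sequence (default
42,000 nt) with PE = `[1000, 15000)`, PL = `[15000, 42000)`, both
transcribed from the plus strand. Any 20-mer occurring twice — counting
both strands, so neither duplications nor reverse-complement palindromic
collisions survive — is rejection-resampled; consequently every spacer of
length ≥ 20 maps uniquely and sequence-keyed count tables are in
bijection with designed spacers.

**Amplicon reads** (`simulate_library_fastq`,
`simulate_selection_fastq`): spacers drawn multinomially from weights,
embedded as DR + spacer + DR plus random padding in constant-length reads
(default 100 nt), half the reads reverse-complemented, substitution
errors applied uniformly at the configured rate. Selection classifies
each spacer as `plus_strand`, `minus_PE_up`, `minus_PE_down` or
`minus_PL`; a lineage survives with probability `1 − dropout(class)` and
surviving lineages are re-weighted by `f0 × fitness(class)`. The default
fitness/dropout tables per genotype (`selection_model()`):

| genotype  | fitness (plus, PEup, PEdown, PL) | dropout (plus, PEup, PEdown, PL) |
|-----------|----------------------------------|----------------------------------|
| `wt`      | 0.3, 10, 8, 0.3                  | 0, 0, 0, 0                       |
| `dcsm6`   | 0.3, 10, 0.1, 0.05               | 0.8, 0, 0.5, 0.9                 |
| `cas10hd` | 0.3, 0.8, 0.8, 2.0               | 0, 0, 0, 0                       |

These numbers are **simulator conventions, not measurements**; they are
chosen only to reproduce the qualitative orderings a type III-A screen
shows (wild type: early-operon minus-strand spacers dominate; dCsm6: the
Csm6-dependent downstream class and the late operon collapse and drop
out; Cas10-HD: late-operon spacers modestly outgrow early-operon ones).
Tests and the acceptance script assert orderings and calibrations
against these generators, never real-data magnitudes.

**RNA-seq** (`simulate_rnaseq_coverage`): PE covered from 5 min with a
linear 5'→3' decay (so downstream PE targets see less RNA — the
structure that makes the expression–enrichment correlation positive); PL
silent at 5 min and switching on linearly between 5 and 15 min;
per-timepoint depth factors emulate library-size variability; Poisson
noise per position.

**Acquisition** (`simulate_acquisition_spacers`): wild type draws 90%
minus-strand PE / 5% minus-strand PL / 5% plus-strand; dCsm6 draws 90%
from the upstream half of PE (minus strand) with the remaining 10% split
as in wild type; Cas10-HD yields a uniform both-strand background at 1%
of the wild-type yield. Emitted sequences are exact genome substrings or
reverse complements of length k.

**Wells** (`simulate_wells`): regrowth is Bernoulli(`p_regrow`,
default 0.44); regrowers follow a logistic OD curve with lag drawn
uniformly from 10–15 h; non-regrowers stay at baseline with small
measurement noise; initial GFP is drawn from two normals with the
non-regrower mean shifted upward (default +30 units at SD 15),
reflecting a higher phage burden in arrested cells.

**Randomness**: every generator takes a mandatory seed and derives
deterministic substream seeds from it, so the full pipeline — genome →
FASTQ → extraction → enrichment → summaries — is byte-reproducible for a
fixed seed and independent of the caller's RNG state.

What the generator does **not** emulate: realistic Illumina error
profiles (errors are uniform substitutions), PCR duplicates and
amplification bias, quality-score structure, indels, partial-cassette or
chimeric reads, and phage escaper evolution. Passing tests therefore
demonstrate correctness of the computations on data with the assumed
statistical structure, not robustness to every artifact of real
sequencing runs.

## 9. Validation design and problem sizes

The test suite exercises each operation against independent oracles
(brute-force enumeration, all-substring scans, `stats::t.test`,
`stats::cor`) on small inputs, and runs the full pipeline at sizes where
the statistics it checks are sharp: million-read extractions over a
2,000-spacer library (exact recovery at zero error; ≥95% read recovery at
1% error with budget 2), a million-read neutral-selection run whose mean
enrichment over spacers with ≥5 t₀ reads must fall in [0.9, 1.1],
three-genotype rank-order runs at 3×10⁵ reads on an 8-kb genome,
10,000 acquisition reads for the strand-bias check, n = 2,000 correlation
recovery within ±0.05 for ρ ∈ {0, 0.5, 0.9}, and 5×96 simulated wells at
p = 0.44 checked against the exact binomial interval. The acceptance
script (`scripts/acceptance.R`) re-runs the same computations at
2×10⁵-read depth and reports every quantity it computes as JSON.

## 10. Known limitations

* Extraction counts sequence keys, so sequencing errors inflate the tail
  of singleton keys; analyses that need error-aware counts should
  aggregate keys upstream (out of scope here).
* Enrichment ratios carry no per-spacer significance model — the screen's
  readout is the landscape and its region summaries, and none is
  computed.
* On natural genomes, a spacer sequence may occur at several loci (or on
  both strands); such spacers are flagged and excluded from profiles
  rather than resolved.
* Ungapped matching cannot place spacers across indel differences between
  the sequenced phage and the reference genome.
* The well model assumes blank-corrected OD and a single threshold
  crossing; oscillating series report their first crossing.
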