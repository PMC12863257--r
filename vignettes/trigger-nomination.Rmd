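---
title: "Nominating TDMD trigger sites from AGO-CLASH chimeras"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nominating TDMD trigger sites from AGO-CLASH chimeras}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most miRNA:target interactions end with repression of the target. A small
class of sites inverts this: when a transcript pairs extensively with both
the seed and the 3' end of a miRNA, the ZSWIM8 ubiquitin-ligase complex
recognizes the resulting AGO conformation and destroys the miRNA instead.
Transcripts bearing such sites are called TDMD (target-directed miRNA
degradation) triggers, and they are rare — a handful of validated examples
against hundreds of thousands of ordinary target sites.

AGO-CLASH (chimeric eCLIP) reads out miRNA:target pairs directly: an
intermolecular ligation inside AGO fuses the miRNA to a fragment of its
bound target, so a single chimeric read names both partners. Probe
enrichment concentrates chimeras of chosen miRNAs. The catch is that
almost every chimera reflects ordinary target binding; trigger sites must
be separated from that background by their pairing architecture. This
package implements that separation as a deterministic, desk-scale
pipeline, operating in transcript space against a provided transcriptome
(the genome-alignment and statistical peak-calling stages of a production
CLIP workflow are deliberately replaced by transcriptome mapping and
interval merging, which keeps every stage exact and reproducible).

## From raw reads to mapped chimeras

Reads follow the library layout `[UMI][miRNA][target fragment][adapter]`.
`process_reads()` applies, in order: UMI extraction (`umi_length` = 10 nt),
adapter trimming, contaminant removal, miRNA-segment calling, ungapped
target mapping, and UMI-based deduplication. Every read receives exactly
one fate, and fate counts always sum to the input count — this
conservation property is tested, and it is the reason each stage is a
total function with an explicit drop reason rather than a filter.

Decisions worth knowing about:

* **Adapter rule.** The longest read suffix matching a prefix of the
  adapter with ≥ 3 bases and a mismatch rate ≤ 0.1 is removed; a full
  internal occurrence truncates at its start. The implementation is exact
  (pigeonhole seeding plus verification), not heuristic, and is
  property-tested against a literal scalar scan.
* **miRNA calling.** The miRNA must be a read prefix (after the UMI) —
  this matches the ligation chemistry, where the 3' linker sits after the
  target fragment. The best catalog match is chosen by longest matched
  length, then fewest mismatches (≤ 1); exact ties are dropped as
  ambiguous rather than assigned arbitrarily.
* **Mapping.** Sense-strand, ungapped, ≤ 2 mismatches, unique best hit
  required; AGO-bound targets are sense transcripts, and indels in a
  20–40 nt fragment are better treated as losses than modeled. snoRNA-like
  contaminants (gene ids matching `^Snord` by convention) are screened
  before miRNA calling and excluded from the mapping index.
* **Deduplication.** One representative per
  (UMI, miRNA, transcript, target start), the lexicographically smallest
  read id, output sorted by key — deterministic regardless of input order.

## Site assembly

Deduplicated chimeras are merged per transcript into clusters (touching or
overlapping intervals; `merge_gap = 0` by default — a statistical peak
model is intentionally out of scope), and each cluster core is extended by
10 nt at its 5' end. The extension exists for a structural reason: the
3'-supplementary pairing of a trigger lies 5' of the seed match on the
target, so seed-anchored fragments systematically under-cover the pairing
region. Clusters are annotated with the transcript segment of largest
overlap; exact ties resolve by the priority 3UTR > 5UTR > ncRNA_exon >
CDS, i.e. toward the regions where a trigger is biologically plausible.

## The pairing model

Candidate evaluation rests on two sequence-analysis primitives.

**Seed classification** (`classify_seed()`): an 8-nt target window is
classified as 8mer / 7mer-m8 / 7mer-A1 / 6mer / none from Watson–Crick
complementarity of target positions t2–t8 to miRNA positions 2–8 and the
identity of t1. G:U wobbles count as mismatches in the seed — the filter
demands a perfect seed. The class definitions force exact combinatorics
(1 / 3 / 3 / 9 / 65,520 over all 4^8 windows), which the test suite
verifies by enumeration.

**Duplex prediction** (`predict_duplex()`): the minimum-free-energy
antiparallel intermolecular alignment under a nearest-neighbor model —
Watson–Crick and G:U pairs, dinucleotide stack energies, bulge and
internal-loop penalties by loop length, a duplex-initiation term, and a
terminal penalty at each duplex end closed by A:U or G:U. No
intramolecular structure, no pseudoknots, no dangling-end terms, and no
temperature dependence: the parameters are a 37 °C set. Loop penalties are
taken at total loop length with no asymmetry term. The DP tracks partial
alignments with and without a stack so that the "at least one stack"
requirement for a reportable duplex is exact; its optimality is tested
against brute-force enumeration of every non-crossing pairing on short
sequences. Energies live in a plain-text parameter file
(`inst/extdata/nn_params_turner2004.txt`): Watson–Crick stacks from the
Xia et al. measurement set, wobble stacks and loop penalties from the
Turner 2004 compilation. Swapping the file swaps the model; the tests that
assert specific energies derive them from the shipped table rather than
hard-coding an independent copy.

Two statistics are read off the MFE alignment of miRNA positions 9..L
against the 20-nt flank immediately 5' of the seed window:

* `max_unpaired_run_after_seed()` — the longest run of consecutive
  unpaired **miRNA** positions at or after position 9 (the central
  bulge). Target-side bulges do not contribute: the criterion describes
  unpaired miRNA sequence.
* `max_pair_run()` — the longest run of consecutive paired miRNA
  positions with consecutive target partners, restricted to the miRNA 3'
  region. A target-side bulge breaks a pair run even though it adds no
  unpaired miRNA position.

The miRNA "3' region" is defined once, as the final 13 nt, and used both
for the consecutive-pair criterion and for the ranking energy. The
ranking metric, the **3' MFE** (`three_prime_mfe()`), is the duplex
energy of that 13-nt region against the same 20-nt flank; when no duplex
with a stack exists the energy is `+Inf`, which sorts the candidate last.

## The filter cascade and ranking

`evaluate_candidate()` emits one row per (miRNA, seed hit) in a cluster's
extended window, with five boolean criteria:

| | criterion | default | rationale |
|---|---|---|---|
| C1 | seed class ∈ {8mer, 7mer-m8, 7mer-A1, 6mer} | — | perfect seed pairing; wobbles/mismatches excluded |
| C2 | region ∈ {5UTR, 3UTR, ncRNA_exon} | — | translating ribosomes suppress TDMD at ORF sites |
| C3 | central unpaired run ≤ 7 nt | 7 | large central bulges disqualify |
| C4 | 3'-region pair run ≥ 6 bp | 6 | all validated triggers pair the miRNA 3' end |
| C5 | mean conservation > 0 over seed-binding bases **and** over 3'-paired bases | strict 0 | functional sites are conserved |

Conservation is aggregated as the arithmetic mean per region with a
strict positivity threshold; per-base positivity was the alternative and
is stricter than the data warrant at phyloP-like noise levels. A missing
conservation track fails C5 with a warning rather than crashing.

Survivors are ranked per miRNA by 3' MFE ascending; ties break by higher
chimera support, then by (transcript, site start) for determinism. The
top `top_k = 3` are flagged selected. Chimera abundance deliberately does
**not** enter the ranking beyond tie-breaking: abundance is a poor
predictor of trigger validation, so the thermodynamic metric leads.

The criteria are pure predicates: applying them in any order yields the
same survivor set, which is tested by permutation.

## What the generator emulates — and what it does not

`run_simulate()` builds the study conditions used throughout the tests:
10 miRNAs (half probe-enriched, 8× chimera boost), 60 transcripts of
500–1500 nt (about 65% coding with 5'UTR/CDS/3'UTR segmentation), four
snoRNA-like contaminant transcripts, 200,000 reads with 2% chimeras, 5%
contaminants, 0.1% per-base substitution error, and a conservation track
of N(0, 0.5) background with mean ±1 over embedded site pairing
positions (magnitude chosen so sign tests are unambiguous). The 2%
chimera rate is a free parameter — chimeric reads are a small minority in
such libraries, but no canonical per-sample figure exists.

Eight sites are embedded by default: three true triggers (13/10/8 bp 3'
runs with 1/4/6 nt bulges, 8mer/7mer-m8/7mer-A1 seeds, in 3'UTRs and a
noncoding exon) and five decoys, each violating exactly one criterion —
CDS location, 8-nt central bulge, 5-bp 3' run, negative conservation,
mismatched seed. This one-decoy-per-failure-mode design means every
criterion is exercised end-to-end: a pipeline bug that silently disables
one criterion makes a specific decoy survive, and the recovery report
names it.

Site realization is verified, not assumed: after embedding, the window is
re-classified and the flank re-folded with the package's own engine, and
the realized statistics must equal the requested ones exactly, else the
sequence context is resampled. One subtlety deserves a note: where a
fixed miRNA base adjacent to a designed helix could pair with the fixed
seed-window boundary, the MFE alignment would extend the helix on every
resampling attempt; the designer therefore inserts 1-nt target "guard"
bulges whose base pairs with nothing adjacent, and can place the central
bulge either against the seed or between the two helices.

The generator does **not** model crosslink-induced mutations, quality
scores beyond a constant, paired-end layouts, genomic coordinates,
introns, expression-level variation between transcripts, or position
effects within 3'UTRs. Passing tests therefore demonstrate the pipeline's
correctness on its own terms — exact recovery of architectures it defines
— not performance on tissue libraries, where mapping ambiguity,
incomplete annotation and peak-model choices dominate.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere in tables and files;
  conversion to R's 1-based indexing happens only at sequence extraction.
* All randomness derives from one integer seed; each generator stage
  offsets it (+0 catalog, +1 transcriptome, +2 reads), so stages are
  individually reproducible and fixture files are byte-identical across
  reruns.
* Energies are reported to 2 decimals, conservation means to 4; ranking
  uses the reported (rounded) energy so that a re-read table ranks
  identically.
* Reads shorter than the UMI are dropped as `too_short`; empty FASTQs,
  empty site lists, empty candidate tables and miRNAs without chimeras
  all produce empty-but-well-formed outputs rather than errors.
* Problem sizes in the test suite: duplex-DP oracle checks run on ≤ 8-nt
  pairs (where exhaustive enumeration is cheap); end-to-end recovery runs
  the full 200,000-read condition across 20 seeds; round-trip and
  property tests use 3,000–10,000 reads. These sizes make the whole suite
  complete in minutes on one CPU while still exercising the full-scale
  study condition.

## Known limitations

* The duplex model omits dangling ends, loop-asymmetry penalties,
  coaxial stacking and special-case loop energies; it is a deliberately
  transparent nearest-neighbor core, adequate for ranking by 3'
  complementarity, not a replacement for a full folding engine.
* Transcript-space mapping cannot produce intron or intergenic
  annotations, and multimapping is resolved by dropping rather than
  rescue.
* The stringent criteria are known to exclude real triggers with
  unusual architectures (seed-only or minimal-3'-pairing TDMD exists);
  the filter trades sensitivity for a short, high-confidence candidate
  list.
* Conservation positivity is a proxy; it assumes the supplied track is
  on a scale where 0 separates conserved from neutral.
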