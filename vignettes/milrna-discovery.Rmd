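---
title: "Discovering fungal milRNAs and their cross-kingdom targets: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering fungal milRNAs and their cross-kingdom targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Filamentous fungi express microRNA-like RNAs (milRNAs): ~18–25 nt small
RNAs excised from genome-encoded fold-back (hairpin) precursors. When a
fungus colonises a plant, some of its milRNAs may act across the species
boundary, silencing host transcripts through plant-style, near-perfect
complementarity. Identifying such candidates from a small-RNA sequencing
library is a chain of small, well-defined computational steps — read
filtering, tag collapsing, genome mapping, non-coding-RNA triage, hairpin
calling, duplex scoring, and a consensus across several target predictors —
each with thresholds that materially change the outcome. `milkit`
implements that chain end to end, with every threshold explicit, and ships
a synthetic-data generator so the whole pipeline can be exercised against a
known ground truth.

## Pipeline model and assumptions

**Read cleansing.** Reads are assumed to be single-end, Phred+33,
adapter-ligated inserts of structure `[insert][3' adapter]`. Six filters
run in a fixed order — (1) more than one base at Q ≤ 20, or any N; (2) no
3' adapter; (3) empty insert; (4) 5' adapter inside the insert; (5) poly-A
insert (≥ 80% A); (6) insert < 18 nt — and a read is charged to the *first*
filter it fails, which makes the accounting well defined: category counts
always sum to the input. Inserts longer than 30 nt (outside the
gel-purified size range) go to a separate overflow bucket rather than being
silently kept. Percentages follow the mixed-denominator convention of
published accounting tables: the high-quality count and the adapter/poly-A
classes are fractions of all reads, while the short-read and final
clean-tag counts are fractions of high-quality reads.

Adapter detection is a semi-global overlap of the adapter prefix with the
read suffix (≥ 8 nt, ≤ 1 mismatch per 10 nt); the 5'-adapter scan applies
the same allowance anywhere in the insert. These are deliberate, simple
choices: at 18–30 nt insert lengths, fancier trimming buys nothing
reproducible.

**Tag atlas.** Clean inserts collapse to unique tags with aggregated
counts. Mapping is exact-match, full-length, on both strands — at tag
lengths of 18–30 nt, exact matching is the reproducible choice and doubles
as its own alignment-score policy. Classification resolves each tag to a
*single* category by precedence (rRNA > tRNA > snRNA > snoRNA > repeat >
exon sense > exon antisense > intron sense > intron antisense >
unannotated), so category totals obey conservation. Structural-RNA matching
is an exact full-length substring test against the reference sets, standing
in for a live BLASTN/Rfam search; this is a documented divergence — it
cannot find diverged homologues, which only matters if your reference sets
are from a distant species.

**Hairpin calling.** A novel milRNA requires a precursor in which the
sequenced tag (the mature arm) base-pairs with a star region on the
opposite arm. The acceptance criteria, all exposed in `hairpin_params()`:

| parameter | default | meaning |
|---|---|---|
| `min_mature` / `max_mature` | 18 / 25 nt | mature arm length band |
| `min_reference` / `max_reference` | 20 / 23 nt | duplex register band |
| `max_copies` | 20 | genomic loci allowed per tag |
| `max_precursor_energy` | −18 kcal/mol | precursor MFE ceiling |
| `min_space` / `max_space` | 16 / 300 nt | mature–star loop spacing |
| `max_bulge` | 4 nt | bulged nucleotides in the duplex |
| `max_asymmetry` | 4 nt | arm unpaired-length difference |
| `flank` | 20 nt | reported precursor flank |

The energy ceiling is read as MFE ≤ −18 kcal/mol: fold-backs have negative
energies, and every credible precursor in practice sits well below that
bar. The duplex register band (20–23 nt) is applied when the mature is
extended or trimmed to nominate the star window. Bulges are counted as
unpaired positions inside either duplex arm of the *realised* fold;
asymmetry is the absolute difference of the two arms' unpaired counts.
Note that with both caps at their defaults the asymmetry rule can never
fire on its own (|a − b| > 4 forces a + b > 4); it becomes independent
only when `max_bulge` is raised, which is how its unit tests isolate it.

**Folding.** All thermodynamics are delegated to ViennaRNA (`RNAfold` /
`RNAduplex`) through the `vienna_engine()` contract — deterministic,
batched, and injectable, so tests can count on bit-identical re-runs. The
package deliberately does not reimplement a folding algorithm.

**Expression.** TPM is `count / total_clean_tags × 10^6`, the standard
definition implied by the name; it sums to one million over all clean tags
by construction.

**Self-target verification.** Six rules applied to gap-free duplexes:
≤ 4 mismatch equivalents (G:U counts 0.5); no run of > 2 mismatches; no
adjacent mismatches within positions 2–12; perfect pairing at positions
10–11; ≤ 2.5 mismatch equivalents over positions 1–12; and duplex MFE at
least 60% of the perfect-complement duplex MFE. Wobbles base-pair, so the
adjacency and positional rules (2–4) count full mismatches only; the 0.5
weighting enters the two numeric budgets (rules 1 and 5). Energies for
rule 6 are computed only for sites already passing rules 1–5.

**Transboundary screen.** A milRNA is *host-encoded* if it matches the
host genome exactly (full length, either strand) and the matched region
± 100 bp folds at or below −85 kcal/mol; such milRNAs are excluded from
cross-kingdom prediction, since a host hairpin could produce the same
small RNA. "Stable secondary structure" is operationalised purely as that
MFE cutoff on the whole ±100 bp window — no shape criterion is added, and
eligibility is the disjunction: no perfect match, *or* no stable flank
fold (a bare match in structureless sequence does not disqualify). Windows
truncated at contig edges are folded as-is and flagged.

**Host target prediction and consensus.** Three rulesets mirror the three
families of plant-miRNA target predictors, all with a weighted-score
cutoff of 4.0 under Allen-style penalties (mismatch 1, G:U 0.5, gap 2,
doubled in the seed band): *expectation* (gap-free, seed 2–13, position 10
must pair, ≤ 1 mismatch or ≤ 2 wobbles in seed 2–12, ≤ 2 continuous
mismatches), *seed17* (seed 2–17, no gaps through position 17, ≤ 1 gap
after), and *allen* (seed 2–13, one gap allowed anywhere). The penalty
constants are the shared Allen-scheme convention; published descriptions
of such screens print thresholds, not constants, so the constants here are
the normative interpretation and are exposed in `pairing_model()`. The
seed-region budget ("one mismatch or two wobbles") is read as an inclusive
conjunction: accept if mismatches ≤ 1 AND wobbles ≤ 2 — the most
permissive reading of the sentence. The expectation seed band is 2–13 (the
classical expectation-score band); 2–12 can be configured where a stricter
reading is wanted. A (milRNA, transcript) pair is a *consensus* target
when every ruleset accepts at least one site in that transcript; Venn
counts are reported over target-gene sets (transcript = gene unless a
transcript→gene map is supplied).

## Numerical choices

*Window enumeration.* Candidate precursor windows place the tag on either
arm and scan the loop spacing over a grid: every 4 nt up to 60 nt, then
every 16 nt to 300 nt. A full 1-nt scan would cost hundreds of folds per
locus for no benefit — any window that covers the true duplex folds back
to the same hairpin, and the winner is subsequently *trimmed to the duplex
extent plus the flank and refolded*, so the reported precursor does not
depend on which covering window found it. The grid is a parameter
(`space_grid`) for callers who want it denser.

*Selection and tie-breaks.* Among accepted windows per locus the lowest
MFE wins, ties to the shortest window; among overlapping matures on the
same arm the most abundant tag wins, ties lexicographic; two matures from
*different* arms of one precursor are both kept (5p/3p pairs). One record
is reported per distinct (precursor, mature) pair. Multiple sites tying on
score within one transcript are all reported; consensus only asks whether
at least one site exists.

*Degenerate inputs.* Zero denominators in percentage tables yield NA, not
errors. Empty candidate lists render header-only tables. Folding an empty
sequence, mapping against an empty genome, and malformed FASTQ records
(sequence/quality length mismatch, reported with the record index) are
hard errors.

*Determinism.* Every stochastic step takes an explicit seed and restores
the caller's RNG state; the folding engine is deterministic; re-running
the pipeline on identical inputs is bit-identical.

## The synthetic generator: what it emulates, and what it does not

`build_genome()` plants hairpins built to satisfy the acceptance criteria
by construction — mature 18–25 nt starting with U (mirroring the strong
5'-U bias of fungal milRNAs), star = reverse complement with 0–2 planted
G:U wobbles and ≤ 1 bulge nucleotide (always at least one imperfection, so
the mature cannot map onto its own star arm), loop 16–40 nt, 20 nt flanks
— then *refolds each one and requires it to pass the caller's own
assessment* before planting. Decoy loci for seven annotation classes carry
their reference sequences or interval tracks. `simulate_reads()` draws
per-milRNA abundances log-uniformly over 5–25,000 (the dynamic range seen
in real libraries), injects the six contamination classes at specified
rates with class labels recorded in read names, and uses two-level
qualities (clean Q38, injected Q10) so the Q ≤ 20 threshold is
unambiguous. Every planted milRNA is guaranteed at least one clean read.
`build_host()` places designed target sites whose mismatch/wobble
positions decide each ruleset's verdict deterministically, and can embed a
milRNA inside a synthetic perfect inverted repeat (a deeply stable
fold-back) or in plain sequence for the two arms of the eligibility test.

The default study (`synthetic_study()`) is a 60 kb genome, 6 hairpins, 2
decoys per class, 10,000 reads at contamination rates 5/5/2/1/1/5%, 8 host
transcripts with 6 designed sites, and one host-embedded milRNA. These
sizes keep a complete run in tens of seconds while leaving every stage
non-trivially populated.

What the generator does *not* emulate: sequencing error inside inserts,
quality-score decay along the read, host transcript expression levels,
diverged (non-identical) structural-RNA families, and multi-contig
genomes with scaffold gaps. Passing tests therefore demonstrate the
*logic* of the pipeline — filters charge the right reads, criteria accept
and reject the right structures, rulesets disagree exactly where their
constraints differ — not robustness to noisy real-world base calls, which
should be assessed on real libraries.

## Known limitations

- Exact-match mapping and ncRNA matching miss diverged copies; on real
  genomes a user may want to pre-mask with a proper aligner/Rfam scan and
  feed the results in as tracks.
- The hairpin caller reports the best precursor per locus; it does not
  attempt to split tandem or overlapping hairpins at a single locus.
- Published accounting of this pipeline family contains internal
  inconsistencies (duplicate table rows; a removal count never printed);
  the reporting here keeps both raw counts and explicit denominators so
  its own arithmetic is always checkable, and reports one record per
  distinct (precursor, mature) pair.
- The energy-ratio rule uses `RNAduplex` hybridisation energies; these
  ignore target-site accessibility (unpaired-region energetics), which is
  out of scope.
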