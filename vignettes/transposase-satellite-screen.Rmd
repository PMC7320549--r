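---
title: "Screening for transposase-derived satellite DNA junctions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for transposase-derived satellite DNA junctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satjunction)
```

## The biological question and the screen's model

Satellite DNA (satDNA) consists of long arrays of tandemly repeated
monomers. In *Chenopodium* genomes the dominant family (CficCl-61-40) has a
~39–40 bp monomer, and its monomers closely resemble a ~41 bp fragment at
the 3′ end of truncated *tnp2* transposase domains of a CACTA-like DNA
transposon. The screening procedure implemented here formalizes that
observation as a set of testable sequence signatures:

* **tnp2A** — a complete transposase domain of ~630 bp, recognized by the
  diagnostic motif `TATAACTTGCCTCCTT` (≤ 1 mismatch) at position 159 of the
  domain, with *no* derivative motif in its extent.
* **tnp2B** — a deletion derivative copied from the domain's internal
  region, recognized by the diagnostic motif `GGCTGGGTTACC` (≤ 2
  mismatches). Its 3′-terminal ~41 bp (the *parental fragment*) begins with
  the anchor motif `TTTCATTTGA`, and the diagnostic motif starts 20 bp
  upstream of the fragment.
* **junction** — a satellite array whose start monomer is simultaneously
  the parental fragment: the array must begin within
  `[fragment_end − period, fragment_end + max_gap]`, be oriented like the
  derivative, and its first monomer must align to the fragment at ≥ 80%
  identity.

A sample passes through four stages: mismatch-tolerant motif scanning on
both strands, tandem-array detection with consensus calling, transposase
classification against a packaged reference domain, and junction
validation. Downstream, anchored monomer alignment feeds a p-distance
matrix, a neighbor-joining tree and a position frequency matrix; ultralong
reads get a self-dot-plot tandem analysis; and an in silico PCR step
predicts the outward-facing junction amplicon.

## Percent identity: one convention throughout

All reported identities come from a single primitive: Needleman–Wunsch
global alignment with match +1, mismatch −1, gap −2, and a deterministic
traceback preference (diagonal, then up, then left). Identity is
`100 × matches / columns` where *every* alignment column counts in the
denominator (gap columns are non-matches) and `N` matches nothing. Values
are rounded half-up to one decimal, so printed numbers like 89.7 are exact
outputs, not display artifacts.

The junction's headline number — the fragment-to-consensus identity —
compares the fragment's **first period bp** (the part that is the start
monomer) with the array consensus. The two sequences then have equal
length and the optimal alignment is gap-free, so the value is a pure
substitution fraction: e.g. 4 substitutions on a 39 bp monomer give
35/39 = 89.7%. Comparing the full 41 bp fragment against a 39 bp consensus
would charge the two overhanging bases as gap columns and report 85.4% for
the same divergence — a bookkeeping artifact the monomer-scale convention
avoids.

## The tandem-array detector

The detector is built for short monomers (default period range 20–60 bp)
in assemblies and long reads:

1. **Period seeding.** Exact 10-mer recurrence distances are histogrammed;
   a spacing supported by a positional cluster seeds a candidate array
   with that period. A ~39 bp monomer retaining ≥ 80% identity between
   neighbours shares intact 10-mers with high probability.
2. **Boundary refinement.** From the seed, the lag-*p* match profile
   (+1 for `seq[i] == seq[i+p]`, −2 otherwise) is walked outwards with an
   X-drop stop and an argmax boundary. Array interior climbs at ~+0.9 per
   base; random background drifts at −1.25 per base, so the score maximum
   sits at the boundary.
3. **Phasing and consensus.** Full monomers are phased from the array
   start; the consensus is a per-column majority vote with lexicographic
   tie-breaking (`A < C < G < T`). The fractional copy number is
   `round(length / period, 1)`, so the trailing partial monomer is
   included through the length.

**Boundary ambiguity.** A flanking background base that happens to equal
the base one period away extends the periodic pattern *genuinely*; no
detector can exclude it, so boundaries carry an irreducible ~25%-per-base
chance of one-base slop (occasionally a short run). Because a start slop
would rotate the whole monomer frame, the detector snaps the phase to the
anchor motif whenever the consensus carries it: the anchor is the
biological definition of the monomer start, and it pins the frame exactly.
For anchor-free repeats the consensus is recovered up to that small
rotation; the tests assert exactly this, not more.

## Transposase classification

Candidate regions are anchored on diagnostic motif hits and extended
against the packaged 630 bp reference domain along the modal shared-12-mer
diagonal (X-drop 80, match +1 / mismatch −2). Two asymmetries matter:

* For **tnp2A**, the motif's known position (159) fixes the diagonal
  directly; the extent converges on the full domain.
* For **tnp2B**, the diagnostic motif has no counterpart in complete
  domains, so the diagonal comes from shared 12-mers around the hit and
  the extension starts from the outermost seeds. The derivative's
  diagnostic block (motif + 8 bp spacer + anchor, ~30 bp with no domain
  homology) can exceed what the short fragment tail can repay in alignment
  score, so the 3′ end of a derivative is *defined* structurally: when the
  anchor motif follows the diagnostic motif (≤ 80 bp), the call ends at
  `anchor_start + fragment_length − 1`. The alignment extent is the
  fallback. Calls shorter than 60 bp are discarded, which suppresses
  chance motif hits in non-homologous sequence.

The packaged reference domain is a synthetic stand-in (generated once,
deterministically): 630 bp with the tnp2A motif at 159–174 and free of the
anchor/derivative motifs at their scan tolerances on both strands. Real
transposase domains are not redistributed with the package; identities
against this reference are internally consistent but are not comparable to
identities against a biological pfam02992 consensus.

## The synthetic-genome generator

The generator is the package's ground-truth substrate, and its defaults
are the study conditions: an 8300 bp element with `CACTA`/`TAGTG` terminal
stubs and one 630 bp domain; derivatives of 100–600 bp (default 295)
copied from the domain's internal region (source window anchored at
position 63); a 41 bp fragment whose first 10 bp are the anchor; the
diagnostic motif planted 20 bp upstream of the fragment together with the
8 bp `GACTTACA` spacer (making the published 20-mer forward primer a
genuine substring); arrays of 39 bp monomers at 94.4 copies; consensus
divergence 0.103; 2% per-monomer noise; background GC 0.37 (typical plant
intergenic value; cosmetic).

Deliberate modelling choices:

* **Exact divergence counts.** The consensus differs from the fragment at
  exactly `round(divergence × period)` positions (never in the anchor), so
  planted identities are deterministic — `round(0.103 × 39) = 4`
  substitutions give exactly 89.7%. Per-monomer noise is Bernoulli.
* **Element divergence is pairwise.** Each element copy receives
  `round(d/2 × 630)` substitutions from the reference (never in the
  diagnostic motif), so two copies diverge by ~`d` from each other; with
  the default 0.071 the expected pairwise domain identity is ~93%,
  slightly above `(1 − d)` because independent mutations occasionally
  collide.
* **Junction geometry.** The array is planted immediately after the
  derivative and its first monomer repeats the fragment's first period bp
  verbatim — the start monomer *is* a transposase fragment, while the
  geometry stays compatible with the screen's junction window.
* **Motif exclusivity.** Elements are resampled (≤ 100 times) until they
  contain no anchor or derivative-motif occurrence at scan tolerance on
  either strand, so every generated element classifies as exactly one
  tnp2A and zero tnp2B.

What the generator does **not** emulate: real monomer-length variation and
higher-order repeats, indel mutations, nanopore homopolymer error
profiles, assembly artifacts, and biological domain sequence. Passing
tests therefore demonstrate the pipeline's correctness on
substitution-divergent tandem structure, not robustness to indel-rich or
structurally heterogeneous real data.

## Monomer phylogeny

Monomers and fragments are aligned by the anchor motif (left-padding with
gaps so anchor starts share a column; no internal gaps — near-equal-length
~40 bp monomers do not need a full progressive MSA). Sequences lacking the
anchor at ≤ 1 mismatch are excluded and listed as rejects. p-distances
ignore columns where either sequence is gapped; they may violate the
triangle inequality, which is expected for p-distances and not asserted.

The tree is canonical neighbor joining — the standard greedy heuristic for
the minimum-evolution criterion — with deterministic tie-breaking by the
lexicographically smallest label pair and negative branch lengths clamped
to zero. The implementation is native; `ape::nj` serves as an independent
oracle in the tests (topological agreement on additive matrices up to
n = 8), and trees are returned as `ape` `phylo` objects.

The position frequency matrix reports per-column base frequencies among
non-gap symbols, the gap fraction, and information content `2 − H` bits
for logo rendering.

## Ultralong-read dot plots

`self_match_map()` indexes exact 12-mers and enumerates all identical word
pairs; `detect_tandem_regions()` groups matches by offset `j − i`. A
diagonal must be *densely* supported: span ≥ 200 bp and at least
`max(10, 0.1 × span)` collinear matches, with isolated chance pairs
trimmed by keeping each offset's longest run (matches ≤ 200 bp apart).
Stacks of ≥ 3 diagonals at near-multiples (±10%) of a base spacing form a
tandem region; the period estimate is the modal spacing between
neighbouring diagonals, and the copy estimate is region length / period.
Exact word matching is adequate for ≤ 5% divergence at word size 12; both
parameters are configurable.

## In silico PCR

Primers anneal with ≤ 1 total mismatch and an exact 3′-terminal 5 bases
(an approximation of the primer-extension requirement; both configurable).
All products up to 5 kb are reported — satellite templates give ladders —
and the shortest is the headline value.

The outward-facing forward primer (diagnostic motif + spacer,
`GGCTGGGTTACCGACTTACA`) matches any generated derivative by construction.
A reverse primer for a *synthetic* array cannot be a fixed published
sequence, because the array consensus is seeded randomly; instead
`design_reverse_primer()` reproduces the design procedure: it selects an
array-internal 21-mer whose product is as close as possible to the ~400 bp
target and verifies specificity by running the amplicon prediction,
accepting only candidates whose shortest product is the intended one. On a
near-homogeneous array this favours sites whose 3′ terminus covers a
monomer-variant position — the same logic as allele-specific primer
placement.

## Numerical choices and degenerate inputs

* Rounding is half-up (`round_half_up()`), never banker's rounding.
* `N` is never a match — in alignment, motif scanning, consensus voting
  (no vote) and primer annealing.
* Ties: consensus voting `A < C < G < T`; NJ smallest label pair;
  alignment traceback diagonal > up > left; overlapping arrays keep the
  longer, then the shorter period (harmonic duplicates).
* Empty results are empty tables/lists, not errors; malformed FASTA,
  non-symmetric distance matrices, unequal monomer lengths and
  unbuildable generator plans raise errors naming the problem.
* Every pipeline run is reproducible from its seed; TSV/GFF3 outputs embed
  the configuration hash.

## Problem sizes and runtime

The shipped tests and the acceptance script use desk-scale constructs
chosen to exercise every code path: a 4.5 kb junction contig (94.4 × 39 bp
array), a 49 kb read with a 5 kb array, 8.3 kb elements, 20-seed screens
of 2.5 kb contigs, and 200 randomized motif-scan cases up to 2 kb. The
full suite runs in well under a minute on one CPU; the acceptance script
in a few seconds per construct.

## Known limitations

* Extent boundaries abutting random background carry ~±1 bp slop
  (occasionally a few bp) for the reasons above; lengths are estimates,
  not annotations.
* The screen assumes substitution-only divergence; indel-rich satellites
  would break monomer phasing and the Hamming-based motif scan.
* Minimum-evolution tree search is approximated by NJ, as is standard.
* The dot-plot detector reports a single period per region; nested or
  higher-order periodicities are summarized by their base spacing.
* PCR prediction models annealing combinatorics only — no melting
  temperatures, dimers or efficiency.
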