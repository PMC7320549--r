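# satjunction

Detection of junctions between CACTA-like transposase deletion derivatives
and the satellite DNA arrays they seed.

In *Chenopodium* genomes, the most abundant satellite family
(CficCl-61-40, ~39–40 bp monomer) shows striking sequence similarity to a
~41 bp fragment at the 3′ end of truncated *tnp2* transposase domains:
satellite arrays can start with a monomer that is simultaneously a
transposase fragment, which points to the transposon as the source of new
satellite monomers. `satjunction` is for researchers studying
transposon–satellite interactions who want to run that screen on assembled
contigs or ultralong reads — and to test it, end to end, against synthetic
genomes with known ground truth.

## What it computes

The screen classifies transposase regions by diagnostic motifs
(`TATAACTTGCCTCCTT` for complete ~630 bp domains, "tnp2A";
`GGCTGGGTTACC` for deletion derivatives, "tnp2B"), detects tandem arrays
natively (k-mer period seeding, X-drop boundary refinement, majority-rule
consensus, fractional copy number = length/period), and calls a junction
when an array of the same orientation starts at the derivative's parental
fragment (the terminal ~41 bp beginning with `TTTCATTTGA`). Percent
identities are Needleman–Wunsch global alignment identities
(match +1, mismatch −1, gap −2; identity = 100·matches/columns, half-up to
one decimal). Around the core screen sit anchored monomer phylogeny
(p-distances + neighbor joining), self-dot-plot tandem detection for
ultralong reads, in silico PCR with outward-facing primers, and a
synthetic-genome generator that plants elements, derivatives and arrays
with GFF3 ground truth.

## Worked example

Simulate a contig carrying one derivative–array junction (the default plan
replicates the reported D-genome junction locus: 115 bp derivative, 41 bp
fragment, 94.4 copies of a 39 bp monomer at 10.3% consensus divergence)
and screen it:

```r
library(satjunction)

sim <- simulate_sample(junction_locus_plan(), seed = 42)
res <- screen_genome(sim$sequences[[1]], sample_id = "demo")
print(res)
#> screen result: 1 report row(s), 1 junction(s), 1 array(s)
#>   sample tnp2b_present tnp2b_with_array   contig tnp2b_length array_copy_number identity_pct
#> 1   demo          TRUE             TRUE contig_1          115              94.4         89.7

print(res$junctions[[1]])
#> junction contig_1:374-4096 (+): tnp2B 115 bp + array 94.4 x 39 bp, identity 89.7%

print(res$arrays[[1]])
#> tandem array contig_1:415-4096 (+): period 39 bp, 94.4 copies, tail 16 bp
#>   consensus: TTTCATTTGATACCTTAGATGCTATAACATGCCCCCTTC
```

Reading the output: the screen found one derivative of 115 bp whose
terminal 41 bp fragment is immediately followed by a satellite array of
94.4 monomers (39 bp period, 3682 bp/39); the fragment's monomer-length
prefix aligns to the array consensus at 89.7% identity (4 substitutions on
39 bp), and the consensus itself begins with the `TTTCATTTGA` anchor — the
signature of a transposase-seeded array.

The full pipeline (screen + phylogeny + dot plots + PCR, with TSV/GFF3/
FASTA/Newick outputs) runs via `run_end_to_end()` or the thin CLI:

```sh
Rscript inst/scripts/satjunction.R --demo --seed 42 --out results/
Rscript inst/scripts/satjunction.R --fasta contigs.fasta --out results/
```

## Package layout

* `R/` — sequence core and alignment, motif scanning, tandem-array
  detection, transposase classification and junction screen, synthetic
  genome generator, monomer phylogeny, long-read dot plots, in silico PCR,
  pipeline orchestration.
* `src/` — the Needleman–Wunsch primitive (Rcpp).
* `inst/extdata/` — the packaged synthetic reference *tnp2* domain.
* `vignettes/transposase-satellite-screen.Rmd` — the methods vignette:
  model, parameters, numerical conventions, generator scope, limitations.
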