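# primarytx

Primary-transcriptome reannotation of bacterial genomes from 5′-enriched
RNA-seq, for microbial genomicists working on high-GC organisms
(actinomycetes and relatives) whose automated gene calls are notoriously
unreliable at the 5′ end.

Gene callers over-extend ORFs in GC-rich genomes because AT-rich stop
codons are scarce; promoter, 5′-UTR and operon structure are invisible to
sequence-only annotation. A library enriched for native transcript 5′
ends turns all of this into data: a transcription start site (TSS)
appears as a sharp stack of read starts, and the whole-transcriptome
track ties genes into operons. `primarytx` implements the full analysis
chain on top of two per-base, strand-specific tracks:

1. **TSS detection** — position *i* is called when
   `starts[i] ≥ 10` and the increase over the strand-aware upstream
   neighbour is ≥ 1000% (`100·(s_i − s_{i−1})/max(s_{i−1}, 1)`; a
   low-coverage mode uses 100%). Adjacent stacks within ±2 nt collapse
   to the strongest position.
2. **Genomic-context classification** — each TSS is assigned to the
   nearest same-strand translation start (TLS) within 500 nt
   (strongest TSS per gene = *primary*, others *secondary*), else
   called *antisense* (inside an opposite-strand gene or its UTR),
   *intragenic*, or *intergenic*. 5′-UTR length is the TSS–TLS
   distance; 0–3 nt means *leaderless*.
3. **Translation-start correction** — an intragenic TSS in the first
   25% of a CDS, with no reads at the annotated TLS and no upstream
   TSS, proposes the first in-frame ATG/GTG/TTG downstream of it as
   the corrected start.
4. **Motif discovery** — a fixed-width (6 nt) ZOOPS EM search over
   anchor-constrained placements recovers the −10 box (TAnnnT-like,
   4–9 nt upstream of the TSS), the −35 element (15–19 nt upstream of
   the −10) and the ribosome-binding site (AGGAGG-like, searched in
   20 nt windows above the TLS for genes with 10–150 nt UTRs), with
   spacer statistics and consensus-match fractions
   (`rpkm`-style transcription strength per gene:
   `reads·10⁹ / (total_mapped · length)`).
5. **Operon inference** — adjacent same-strand genes join one
   transcription unit when ≥ 5 whole-transcriptome reads bridge the
   entire intergenic gap; internal TSS split suffix sub-operons.
6. **Attenuator scan** — small leader ORFs (8–35 aa) upstream of
   target genes, scored by residue enrichment (≥ 3× over background,
   ≥ 2 copies), with a Rho-independent terminator heuristic (perfect
   inverted-repeat stem ≥ 6 bp, loop 3–9 nt, ≥ 3 U within 10 nt).

A first-class synthetic-genome generator plants all of these signals
with known ground truth, so every stage is testable end to end with no
external data.

## Worked example

```r
library(primarytx)

sim    <- simulate_genome(sim_config(seed = 42, background_rate = 0))
report <- run_pipeline(sim$annotation, sim$profile, reads = sim$reads)
print(report)
```

```
ReannotationReport
  TSS: 72 (primary 72, secondary 0, antisense 0, intragenic 0, intergenic 0)
  leaderless fraction: 15.3%
  TLS corrections proposed: 0
  operons: 10 (10 validated, 9 sub-operons), 27 genes in operons, 53 monocistronic
  attenuator leader-peptide hits: 37
  RBS: consensus AGGAGG, placed in 88.2% of 51 sequences
```

The simulated 100 kb chromosome carries 80 genes in 10 operons plus 8
attenuator-regulated genes and monocistronic fillers; every planted TSS
(72 here: one per transcription unit, plus sub-operon internal starts)
is recovered at its exact coordinate, so all TSS come out `primary`.
The leaderless fraction fluctuates around the configured 17%; the RBS
consensus is the planted Shine-Dalgarno element, placed in the subset of
UTRs long enough to hold one. Scoring against the generator's truth:

```r
ev <- evaluate_against_truth(sim$truth, tss = report$tss,
                             operon_map = report$operon_map,
                             attenuator_hits = report$attenuators)
```

gives TSS precision 1.00, recall 1.00, operon exact-match 1.00 and
attenuator-peptide recovery 1.00 in this noiseless regime; with the
default Poisson background (0.02 starts/base) precision and recall stay
above 0.95. Among the recovered leader peptides:

```
 upstream_of                       peptide length_aa enriched_residue enriched_count
   gene_0016 MSTTSDRTPATEATTTPGARCMCRRMCAF        29                T              7
   gene_0020            MFAHSTRNWWWTAHPAAH        18                A              4
```

## File formats and CLI

FASTA + GFF3 for genome and features (internally 0-based half-open;
converted at I/O), 4-column bedGraph per strand for the 5′-start and
coverage tracks, BED-like intervals for bridging reads, TSV/JSON for all
stage outputs. A CLI driver ships in `inst/scripts/primarytx-cli.R`:

```sh
Rscript inst/scripts/primarytx-cli.R simulate --seed 1 --out-prefix sim
Rscript inst/scripts/primarytx-cli.R run --fasta sim.fa --gff sim.gff3 \
    --starts-fwd sim.starts_fwd.bedgraph --starts-rev sim.starts_rev.bedgraph \
    --cov-fwd sim.cov_fwd.bedgraph --cov-rev sim.cov_rev.bedgraph \
    --reads sim.reads.bed --out-prefix out
```

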