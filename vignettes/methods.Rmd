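---
title: "Methods: primary-transcriptome reannotation from 5'-end profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: primary-transcriptome reannotation from 5'-end profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primarytx)
```

# The problem and the data model

Automated annotation of high-GC bacterial genomes (GC ≈ 70%+) is
systematically wrong in two ways that transcriptome data can fix. First,
stop codons (TAA/TAG/TGA) are AT-rich and therefore rare, so gene
callers over-extend open reading frames at the 5′ end and pick wrong
start codons. Second, sequence alone says nothing about where
transcription actually starts, which genes share a promoter, and which
5′ leaders carry regulatory elements.

The package consumes two strand-specific per-base tracks over one
replicon:

* a **5′-read-start track** from a library enriched for native
  transcript 5′ ends — the first base of each read marks a candidate
  TSS and read stacks pile up at real ones;
* a **whole-transcriptome coverage track** (plus, optionally, the raw
  read intervals) — used for operon bridging and as negative evidence
  at silent translation starts.

All internal coordinates are 0-based half-open; GFF3's 1-based inclusive
convention is converted exactly once at I/O. On the reverse strand
"upstream" means larger coordinate, and a single pair of helpers owns
that arithmetic so no stage re-derives ±1 offsets.

# TSS detection and classification

A position is a TSS candidate when it carries at least
`min_read_starts` (default 10) read starts **and** the percent increase
from the strand-aware upstream neighbour,
$100\,(s_i - s_{i-1})/\max(s_{i-1}, 1)$, reaches `percent_increase`
(default 1000%, i.e. at least a tenfold jump; a low-coverage mode uses
100%). The $\max(\cdot,1)$ floor defines the otherwise-undefined
zero-background case: a stack of 10 over nothing scores exactly 1000%
and is called. Chromosome edges treat the missing neighbour as zero.
Real 5′ libraries smear stacks over a base or two, and the
published analyses resolved such cases by manual review; we replace
that with an explicit rule — within a ±2 nt window only the strongest
position survives, ties going to the most upstream — because a
reproducible pipeline cannot contain a curation step.

Classification follows a two-pass precedence. Pass 1: a TSS whose
strand-aware distance to the nearest same-strand TLS is 0–500 nt is
assigned to that gene; per gene, the highest-count TSS is *primary*
(count ties break towards the TLS), the rest *secondary*. Pass 2, for
the remainder: *antisense* when inside an opposite-strand gene **or**
inside a 5′-UTR established by an opposite-strand primary TSS in pass 1
(so the UTR context exists before it is used); *intragenic* when inside
a same-strand gene body; otherwise *intergenic*. The 500 nt assignment
window applies to secondary TSS as well — the sources state no separate
rule, and one window keeps the partition property trivial to verify.
UTR length is the TSS–TLS distance (0 at the start codon); 0–3 nt is
*leaderless*, because a ribosome-binding site cannot fit in such a
leader.

# Translation-start correction

A CDS is a correction candidate when a same-strand TSS lies inside its
first `tls_scan_fraction` (default 25%) and the gene has no assigned
primary/secondary TSS of its own. The reading frame is scanned strictly
downstream of that TSS, within the same 25% bound, for the first
ATG/GTG/TTG; "no reads at the annotated start" is hardened to
whole-transcriptome coverage ≤ `old_tls_coverage_max` (default 0) at
the TLS base. Both the supporting TSS and the proposed start must fall
inside the 25% bound — the narrower of the readings of an ambiguous
prose criterion — and the first qualifying codon is chosen rather than
the one with the best RBS, as the simplest deterministic rule.
Applying a proposal shrinks the CDS, keeps stop codon and frame (both
checked), and is a fixed point: a second scan proposes nothing because
the supporting TSS now lies upstream of the corrected gene.

# Motif discovery

Promoter and RBS motifs are found with a fixed-width (6 nt)
zero-or-one-occurrence-per-sequence (ZOOPS) EM over placement offsets,
re-implementing the class of tool the field uses for this job.
Windows end immediately upstream of their anchor (TSS for promoters,
TLS for the RBS) and allowed placements are those whose 3′-end-to-anchor
distance lies in a spacer range: 4–9 nt for the −10 box, 15–19 nt
between −35 and −10 (the −35 search is anchored on each −10 placement,
not on the TSS), 4–9 nt for the RBS. The background is a 0-order model
estimated from the input; windows containing `N` are excluded from
placement.

Numerical choices worth knowing:

* The objective EM ascends is the pseudocount-penalised (MAP)
  log-likelihood; it is asserted non-decreasing at every iteration
  with a $10^{-8}$ relative tolerance. The raw likelihood alone can
  dip by O(pseudocount) near convergence, which is expected behaviour,
  not a bug.
* Restarts (default 8 in analysis code, 4 in the constructor)
  alternate random initialisations with substring seeding — a
  placement window drawn from the data with its letters up-weighted —
  because in GC-rich background the register-shifted local optimum of
  a planted motif can otherwise capture every random restart.
* A sequence is "placed" when its best posterior placement probability
  is ≥ 0.5; the consensus letter of a column is the residue with
  frequency ≥ 0.5, else `n`. Under this rule a position that is 43%
  T prints as `n`, matching how weakly conserved first positions of
  −10 hexamers are reported in practice.
* The EM seed comes from the configuration, never from the data, so
  results are invariant under input order permutation.

The exact-consensus match fraction (e.g. `TAnnnT` within spacer 4–9) is
computed independently of the EM as a plain pattern scan, so the two
notions of "sequences containing the motif" — EM placement vs literal
match — are reported side by side rather than conflated.
Anti-Shine-Dalgarno complementarity is quantified as the longest
contiguous reverse-complement match between the RBS consensus and the
16S rRNA 3′ tail, via longest-common-substring dynamic programming
against the reverse complement.

# Operons and attenuators

Two genomically adjacent same-strand genes join one transcription unit
when at least `bridging_reads_min` (default 5) whole-transcriptome read
intervals span the entire intergenic gap — both the last base of the
upstream gene and the first base of the downstream one; for overlapping
genes every read covering the downstream gene's first base counts. An
interleaved opposite-strand gene breaks the chain. Maximal chains of
≥ 2 genes are primary operons, *validated* when the first transcribed
gene carries an assigned TSS; every internal gene with an assigned TSS
spawns a suffix sub-operon (nested suffixes are all emitted — the
sources leave nesting unstated). Fragment-level (paired-end insert)
bridging is deliberately not the default: the stated evidence is reads,
not fragments.

The attenuator scan looks for the classic transcription-attenuation
architecture: a small leader ORF (8–35 aa) in the 5′ leader of an
amino-acid-pathway gene, enriched in codons of the regulated amino
acid, followed by a Rho-independent terminator. Leaders are `[TSS, TLS)`
when a TSS is assigned, else a fixed 250 nt window (the sources do not
state their window; 250 nt comfortably holds every known leader-ORF +
terminator arrangement and the value is config-exposed, not asserted).
Enrichment is observed frequency over a background (uniform 1/20 by
default, swappable for a proteome table); a hit needs ≥ 3-fold
enrichment with ≥ 2 copies. The terminator heuristic accepts only
perfect inverted-repeat stems (≥ 6 bp, loop 3–9 nt) with ≥ 3 T in the
10 nt after the stem — no G·U wobble, no bulges, no thermodynamics —
because expert inspection had to become a rule with an exact,
enumerable oracle, and known U-less attenuator terminators motivate
reporting hairpin-only hits flagged non-canonical rather than dropping
them.

# The synthetic world

The generator states one fixed world rather than a tuning surface: a
100 kb chromosome at GC 0.72, ~80 genes of 300–750 nt, ten operons
(sizes 2–4, 30 nt junction gaps), eight attenuator-regulated genes
carrying the classic leader peptides re-encoded with random synonymous
codons, and monocistronic fillers. Each transcription unit gets a
promoter (−10 `TATAAT` mutated at 10% per position at spacers 4–9
weighted to mean ≈ 6.3; −35 `TTGACA` at 15–19 nt), leadered units an
`AGGAGG` RBS at spacer 5–8 where the UTR is long enough, and a 5′ read
stack at the TSS. UTR lengths are `4 + NB(mu = 50, size = 3)` truncated
to [4, 300] — a geometric-like law chosen once so the modal 5 nt bin
falls in the 26–40 nt range typical of bacterial leaders. The
leaderless fraction is Bernoulli 0.17 per unit.

Stack heights are `10 + NB(mu = 40, size = 2)` — an overdispersed law
whose lower truncation at the detection floor makes "every planted TSS
is detectable" a property of the stated world rather than a lucky
draw; background read starts are Poisson 0.02 per base per strand.
Operon junctions receive `5 + Poisson(5)` bridging reads of 75 nt, so
every planted junction meets the threshold by construction. Intergenic
pads keep each TSS's nearest downstream TLS unambiguous, which is what
makes closed-loop equality a meaningful test of the *pipeline* rather
than of layout accidents.

What a green closed loop does establish: exact recovery of planted TSS
positions, classes, UTR lengths, operon membership, sub-operons and
leader peptides under the stated noise. What it does not: robustness to
features the generator omits — overlapping transcription units,
condition-dependent expression, 5′-end degradation artefacts, mapping
ambiguity, and TSS closer than 4 nt apart. The published genome-scale
counts from real organisms are not reproducible from synthetic data
and are not targeted.

# Degenerate inputs and determinism

Empty 5′ profiles yield an empty TSS table and a report whose motif and
RBS sections carry explicit insufficient-data markers; fewer than 10
sequences refuse an EM run for the same reason. `spacer_stats` returns
a no-placements marker instead of NaN. All randomness (generator, EM
restarts) is seeded from configuration, and rerunning any stage with
identical inputs reproduces identical output, byte-for-byte for the
serialised report.

# Known limitations

* TSS within ~2 nt of each other merge under the collapse rule.
* The intragenic class competes with rule-1 assignment: a TSS inside a
  short gene that is also within 500 nt of the next gene's start is
  assigned to the next gene, as the precedence demands.
* The terminator heuristic's perfect-stem requirement under-calls
  hairpins with single mismatches or wobble pairs; its purpose is a
  reproducible signature, not folding accuracy.
* rpkm uses strand-matched 5′ read starts (config-switchable to
  coverage); no TPM or size-factor normalisation is offered.
* Manual-curation steps of the motivating studies (false-positive TSS
  review, conservation checks of corrected starts) are out of scope;
  correction proposals are logged for external review instead.
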