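---
title: "Paralog-aware assembly and characterization of gastropod hemocyanins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paralog-aware assembly and characterization of gastropod hemocyanins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemocyanr)
```

## The problem

Gastropod hemocyanins are enormous extracellular oxygen carriers. One
polypeptide subunit of the typical form is about 400 kDa and consists of
eight paralogous ~420-aa domains — functional units (FUs), labelled
FU-a..FU-h — each carrying one binuclear copper oxygen-binding site; FU-h
ends in an extra ~100-aa tail. Ten subunits form a cylindrical decamer,
and decamers stack into didecamers and multidecamers. Muricid snails carry
two paralogous subunit genes (H1 and H2) that arose by duplication before
the species split, so H1 of one species is orthologous to H1 of the other.
The H2-type subunits additionally carry a strongly hydrophilic,
histidine/aspartate-rich insertion in the N-terminal region of FU-g
(on the order of 118–340 aa, i.e. roughly 14–41 kDa per subunit, or
~272–828 kDa summed over a 20-subunit didecamer).

Reconstructing these coding sequences from short-read data is hard for a
specific reason: the two paralogs are similar to each other, and each gene
is internally repetitive (eight paralogous FUs). A reference-guided
assembler can therefore stitch reads from different paralogs or different
FUs into a *chimeric* ("hybrid") consensus that looks locally clean.
`hemocyanr` implements the full computational pipeline for this setting:

1. **`synth`** — a ground-truthed generator of paralogous multi-FU genes
   and paired-end reads;
2. **`mapasm`** — iterative reference-guided, paralog-separating mapping
   assembly;
3. **`verify`** — a three-part audit against chimeric consensi;
4. **`protchar`** — translation, mass, FU annotation, insertion calls,
   hydropathy, cysteine census;
5. **`phylo`** — neighbor-joining orthology trees with bootstrap support;
6. **`quatmass`** — oligomer mass and oxygen-binding-site accounting.

## The assembler

The assembler follows the classical iterative read-mapping strategy with
two stringency regimes:

* **Seeding.** Reads are mapped to a heterologous reference CDS at a
  permissive nucleotide identity (default `seed_identity = 0.70`, ungapped,
  both strands, exact 13-mer candidate placement). The initial contigs are
  built *from the accepted reads*, not from reference bases.
* **Extension.** Unplaced reads are recruited against the current consensi
  under the high-stringency acceptance rule: overlap ≥ 60 nt, overlap
  identity ≥ 99 %, and mismatches ≤ floor(0.01 × overlap). The identity and
  mismatch caps are evaluated independently; at short overlaps the floored
  count is the stricter of the two, which is the conservative reading of
  thresholds quoted as both a percentage and a fraction. Iteration stops
  when no contig grew, no read was recruited and no merge happened.

Several design points are this package's own and deserve justification:

* **Paralog separation at the seed stage.** Accepted seed reads are
  processed in decreasing order of reference identity and greedily grouped:
  a read joins the group whose current majority consensus it matches, and
  *founds a new group* when its best identity is ≤ 0.90 — strong evidence
  of a distinct paralog. Group joining uses an error-tolerant identity
  (0.96) because an early group consensus is supported by one or two
  error-carrying reads; all later recruitment against mature consensi uses
  the strict 99 % rule. 0.96 sits far above between-paralog identity at any
  divergence where 99 %-stringency separation is possible at all.
* **Best-hit tie rule.** A read contributes to the consensus only of the
  contig(s) where it places best — most matching bases, then fewest
  mismatches. Equidistant reads are flagged *ambiguous*: they add coverage
  to every tied contig but never extend any contig end. Comparing matching
  bases (not raw mismatch counts) matters because raw counts are biased
  toward short overlaps.
* **End extension** requires ≥ 3 unambiguous reads and ≥ 80 % agreement per
  extended base; a tie stops extension. This prevents single-read runaway
  extension through repeats.
* **Contig merging** is a consensus-level operation: candidate overlaps are
  detected down to 20 nt at the group-join identity, and every merge must
  be confirmed by at least 3 unambiguous reads spanning the junction by
  ≥ 20 nt on both sides at the strict acceptance identity. Read spanning is
  what distinguishes a genuine within-gene junction from a coincidental
  identical stretch between paralog contig tips. Without the short-overlap
  merge, two same-gene contigs whose ends meet split the local read
  coverage between them, and a single column where two sequencing errors
  coincide can stall both ends permanently.
* **Consensus calls** are majority votes; ties resolve to the
  alphabetically smallest base and are flagged low-confidence. Ambiguous
  bases (non-ACGT) always count as mismatches.

## The verification protocol

Three independent checks audit a finished assembly:

1. **Low-stringency remapping** (`remap_low_stringency`). Every read is
   anchored at its best ungapped placement by its longest perfect-match
   run, requiring only ≥ 25 nt of anchor, and up to 60 % of the read length
   may mismatch beyond the anchor. On a chimeric contig, reads that cross
   the breakpoint anchor on their own parent's side and disagree sharply on
   the other; their anchor boundaries pile up at one coordinate. The
   package's concrete statistic: a read emits a *clip event* when one
   off-anchor side (≥ 10 informative nt) disagrees at ≥ 10 % **and** by
   ≥ 3 bases, and only when its anchor is ≥ 50 nt (a read anchored merely
   on a short conserved block shared by both paralogs is not confidently
   placed, and such blocks otherwise generate artifact clusters at their
   edges). Clip events within 50 nt cluster; a cluster is *suspect* when
   supported by at least `max(3, 20% of local anchored depth)` reads, and
   the breakpoint is reported as the median clip position. The two
   absolute thresholds (≥ 3 mismatching bases, ≥ 50 nt anchor) keep one or
   two sequencing errors in a short tail, and opportunistic anchors of
   reads without a true home, from counting as evidence.
2. **Identity-window scan** (`scan_identity_windows`). After a global
   alignment of two contigs, gapless identity is computed in 100-nt windows
   at 50-nt steps; windows ≥ 95 % identity are flagged as hybrid-risk
   regions where reads cannot distinguish the sequences.
3. **Pair spanning** (`check_pair_spanning`). Each flagged window must be
   bridged by read pairs whose mates lie wholly in unique sequence on
   opposite sides with a consistent implied fragment length (mean ± 4 sd).
   Geometrically this requires fragments of at least the window length plus
   two read lengths.

## The synthetic-data generator

The generator emulates the gene family the pipeline assumes. An ancestral
eight-FU gene (each FU derived from one prototype at a configurable
intra-gene identity, default 0.5) duplicates into H1 and H2; H2 acquires
the His/Asp-rich insertion (motif-periodic with per-copy variation, exact
global His+Asp count, default fraction 0.7, no cysteines); both paralogs
are then inherited by two species, and a heterologous seed reference and an
outgroup branch off the ancestor.

* **Divergence calibration.** Substitutions are applied per site with
  branch probabilities derived from a Jukes–Cantor-style composition
  formula, so the *realized* pairwise divergences match the requested
  values (paralog 0.30, species 0.15, seed reference 0.25 by default)
  within ±0.02 at these gene lengths, double substitutions included.
  Replacement bases are weighted 2:1 synonymous:nonsynonymous, start and
  stop codons are immutable, and stop codons are never created.
* **Insert composition under purifying selection.** Within the insert,
  post-insertion substitutions are restricted to synonymous changes, so the
  realized His+Asp fraction of the final sequences equals the configured
  value exactly; this mirrors the compositional conservation the insertion
  is defined by, and keeps the ground truth sharp for recovery tests.
* **Reads.** Substitution-only errors (uniform replacement), constant Q30
  qualities, forward–reverse mates, normal fragment lengths. Fragments are
  placed with *ragged ends*: the fragment window may overhang the
  transcript and is truncated to it, as after random fragmentation of
  full-length molecules, so transcript termini receive coverage — without
  this no read-based assembler could recover the exact CDS ends. Per-gene
  pair count is `round(coverage × length / (2 × read_length))`.

What the generator does **not** model: indels (sequencing or evolutionary,
apart from the insertion itself), quality-score error profiles, expression
differences between paralogs, sequence-composition biases of real
transcriptomes, or the true homology structure of real FU domains. Passing
tests on this generator therefore demonstrate the *algorithmic* properties
(paralog separation, exact consensus recovery, breakpoint localization)
under the stated divergence and coverage regime, not performance on any
particular real library.

## Protein characterization

* **Masses** use average (not monoisotopic) residue masses plus one water,
  the appropriate convention for ~400-kDa subunits quoted in kDa;
  monoisotopic masses sit behind a flag. The mass of an insertion segment
  is the sum of its residue masses without water (it is part of a chain).
* **Hydropathy** uses the Kyte–Doolittle scale (window 9, centered,
  truncated ends). His (−3.2) and Asp (−3.5) are both strongly
  hydrophilic, so any His/Asp-dominated insert has negative mean
  hydropathy.
* **Alignments** for FU projection, insertion calling, cysteine census and
  distances are global with affine gaps (open 10, extend 0.5) over
  BLOSUM62. Insertion calls are maximal runs of query residues aligned to
  counterpart gaps, with gap runs separated by ≤ 10 aligned columns merged
  first — in a long divergent insertion the aligner occasionally pairs a
  couple of insert residues with the counterpart by chance. For short
  (~50 aa) inserts the maximum-score gap placement can sit a few residues
  away from the generative truth at equal biological plausibility, so
  recovery is assessed as a mean over replicates rather than per replicate.
* **ORFs**: longest ATG-initiated frame on either strand, standard code;
  an ORF may end at a stop codon or at the sequence end; internal Ns
  translate to X and are flagged. For a stop-terminated ORF the protein
  length is `nt/3 − 1` counting the stop codon.
* **Cysteine census** partitions query cysteines into canonical (aligned
  to a reference cysteine — the conserved intra-FU disulfide partners) and
  additional, reported in protein-local coordinates.

## Phylogeny

The orthology question — do the subunits group by gene (H1 with H1) rather
than by species? — only needs a topology with support, so the package uses
distance methods rather than maximum likelihood: star alignment to the
longest sequence (a documented approximation; each sequence is aligned to
the center and gap patterns are merged), Poisson-corrected distances
`d = −ln(1 − p)` over shared columns, and canonical Saitou–Nei neighbor
joining written for deterministic behavior: Q-matrix ties break by
lexicographic taxon-pair order, and negative branch estimates are clamped
to zero with the deficit moved to the sister branch. Bootstrap support
resamples alignment columns (default 100 replicates, seeded) and counts
bipartition recovery. Trees are `ape` `phylo` objects, so newick I/O and
rooting on the outgroup come from `ape`. On near-additive data this
recovers the generating topology exactly; on strongly non-additive
matrices NJ's usual pathologies (including separating zero-distance taxa)
apply to this implementation exactly as they do to the reference one.

## Oligomer accounting

Mass and site bookkeeping is linear arithmetic made explicit: one oxygen
site per FU, ten subunits per decamer. A typical 8-FU tridecamer carries
240 sites; replacing the central decamer with 12-FU subunits adds 40. A
didecamer of insert-bearing subunits aggregates 20 × the per-subunit insert
mass — e.g. 20 × 41.4 kDa = 828 kDa of extra hydrophilic mass inside one
didecamer, versus 20 × 13.6 kDa = 272 kDa for the smaller insert. Reports
round to one decimal in kDa; internals keep full precision.

## Problem sizes and reproducibility

The packaged benchmarks (`benchmark_assembly_recovery`,
`benchmark_chimera_detection`, `benchmark_insertion_recovery`,
`benchmark_orthology`) run the full conditions above: 10 assembly
replicates at 50× / 1 % error on full eight-FU genes, 50 seeded chimeras
plus 20 clean assemblies, 50 insertion replicates over lengths
{50, 118, 150, 340} aa, and 10 bootstrap runs of 100 replicates. The
insertion and phylogeny benchmarks use a reduced four-FU architecture
(a, b, g, h), which leaves the insertion geometry and the orthology signal
unchanged while keeping each replicate light. All randomness flows from
explicit integer seeds; identical seeds give byte-identical sequences,
reads and supports.

## Known limitations

* Mapping is ungapped end to end; an indel in real data would break a
  contig rather than shift it. This matches the substitution-only error
  model and the stated acceptance thresholds, but real libraries need
  indel-aware preprocessing.
* The star alignment is a center-anchored approximation; residues inside
  insertions are not aligned *to each other* across non-center sequences.
* Molecular weights are computed on the full deduced ORF; any
  post-translational processing (e.g. signal peptide removal) would shift
  reported masses by a small offset.
* Distance trees answer topology/orthology questions; branch lengths are
  Poisson-corrected protein distances, not ML estimates, and are not
  comparable to likelihood branch lengths.
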