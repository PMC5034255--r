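---
title: "Consensus-annotation splicing analysis: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-annotation splicing analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consplice)
```

# The problem

Fungal genomes are gene-dense: intergenic distances of a few hundred base
pairs mean that transcript UTRs routinely overlap neighboring genes, and
genome-wide transcript assemblers respond by fusing transcripts of adjacent
genes. `consplice` implements an analysis built around that constraint:
transcript discovery is restricted to annotated gene regions (per-gene
genome fragments, assembled externally, projected back), and alternative
splicing is then classified per gene against a *consensus annotation*
rather than the raw reference annotation.

The package covers the full downstream analysis: transcript filtering,
consensus construction, primitive and composite splice-event classification
with three-level counting and coding/UTR/frame context, splice-junction
cluster analysis, time-course isoform-switch detection across developmental
stages, and functional-impact assessment from domain and localization
predictor tables. A deterministic generator with planted ground truth
stands in for sequencing data, so every stage is testable end to end.

# Region restriction

`fragmentGenome()` cuts the genome at annotated gene boundaries — one
fragment per gene, exactly the annotated span, never reverse-complemented.
Reads must align entirely within a fragment
(`alignmentWithinFragment()` validates externally produced alignments
against this contract), and assembled transcripts are shifted back with
`projectToGenome()`. Fragments carry no flanking padding: the method by
construction cannot see events in UTRs extending beyond the annotated gene
span; those regions are covered instead by the junction-cluster analysis
below.

`filterTranscripts()` applies three noise rules in order, reporting the
first failure per transcript: (1) a predicted transcript must lie on its
gene's strand (without strand-specific reads an antisense model cannot be
called); (2) it must have nonzero estimated abundance in at least one
sample and every splice junction must have read support — a junction
missing from the support table is an error, never a silent pass; (3) its
longest ORF must reach `min_orf_nt` (default 40 nt). "No expression" means
zero in every sample; any positive abundance passes, as no threshold is
imposed.

# ORF and CDS conventions

`longestOrf()` scans all three forward frames of the spliced sense-strand
sequence for complete ATG..stop ORFs and keeps the longest, measured from
the A of ATG through the stop codon inclusive. Ties break to the 5'-most
start; codons containing `N` match neither start nor stop; only ATG starts
are considered (non-AUG initiation is real but rare and unpredictable
without translation evidence). Because ORF lengths are codon multiples,
the 40 nt floor admits 42 nt as the smallest passing ORF; the threshold is
read inclusively (`length >= 40`), counting the stop codon.

Coordinates are 0-based half-open everywhere inside the package; GFF3/GTF
I/O converts at the file boundary only. This removes the usual off-by-one
hazards from interval arithmetic.

# The consensus annotation and event calling

For each gene, `buildConsensus()` collects all observed exons of the
gene's transcripts and removes *retained-intron exons*: an exon is one iff
a splice junction of another transcript of the same gene lies strictly
inside it (removal iterates to a fixpoint to resolve nested retentions).
The remaining exons are clustered by genomic overlap (single linkage) into
exon groups. Each group's representative boundary pair is the variant
observed in the most transcripts; ties go to the longest variant, then the
5'-most. The consensus is a reference for describing variation — it need
not equal any transcript and need not contain a valid ORF.

The representative is a design choice the underlying boundary-event
definitions require ("extension or contraction" is relative to
*something*); a majority vote across transcripts is the least surprising
anchor and degrades gracefully to the single observed variant.

`callPrimitiveEvents()` aligns a transcript's exons to the groups:

* an internal group absent from the transcript is exon skipping (ES);
* an exon covering two or more groups plus the gap(s) between them is
  intron retention (IR), one event per retained intron;
* a junction-adjacent exon boundary differing from the representative is
  an alternative splice site, labeled at the exon end where it occurs in
  transcript orientation: A5SS at the exon's 5' end, A3SS at the 3' end.
  Note this is the exon-relative convention, not the donor/acceptor
  convention of rMATS-style tools — the labels invert relative to those
  tools.

Outer boundaries of transcript-terminal exons are transcription start/end
variation, not splicing, and are never called; a missing terminal group is
reported as an anomaly rather than ES.

`callCompositeEvents()` classifies across transcripts: a mutually
exclusive exon (MXE) pair is two exon groups each observed in some
transcript but never together in any; a group whose variants show three or
more distinct 5' (3') boundaries is a multiple alternative 5' (3') splice
site event. `delta_nt` is 0 for composite events as no single length
change is defined.

## Context and counting

`classifyEventContext()` labels an event *coding* iff its genomic interval
overlaps the bearing transcript's genomic CDS span, else *utr*; frame
neutrality is `overlap %% 3 == 0`. The intersection uses the genomic CDS
span rather than the exonic CDS union: a retained intron sits inside that
span and its full length shifts the reading frame, while a skipped exon is
exonic anyway. Transcripts without a CDS place all their events in the
UTR. Composite events take the any-member rule: coding if coding in any
member transcript.

`countEvents()` reports all three levels. Event level counts every event;
transcript level counts each transcript once per event type; gene level
counts each gene once per type. Composite events are keyed at transcript
level by their whole member set — expanding them per member would let
transcript-level counts exceed event-level counts, breaking the
event >= transcript >= gene hierarchy that holds for every other type.
Counts are kept per (type, region) cell, so coding and UTR columns always
sum to the totals.

`selectIsolatedGenes()` implements the neighbor-interference control:
genes whose two flanking intergenic intervals have strictly zero coverage
at every base (a chromosome-terminal gene qualifies on its single flank).

# Junction clusters

Junction analysis sees splicing wherever reads do, including outside
modeled regions. `loadJunctions()` merges aligner junction tables across
samples, then removes junctions whose total support is a single read —
observed-once junctions are treated as splicing or sequencing noise.
Merging precedes filtering so a junction seen once in each of two samples
survives. `clusterJunctions()` groups junctions by genomic overlap
(single linkage, per chromosome and strand; unknown-strand records are
clustered with the forward track and take an overlapping gene's strand at
classification). Within a cluster, `classifyJunctionEvents()` calls one
alternative-splice-site event per distinct alternative boundary (k
junctions sharing a donor give k−1 events, not C(k,2) pairs), labeled at
the varying exon end in transcript orientation, and flags a junction as
exon skipping when two cluster mates subdivide it with room for an exon
between. Events are coding if they overlap any CDS, else UTR if inside a
gene span, else intergenic. These rules are a documented reconstruction of
junction-cluster practice and are isolated behind this module's interface
so they can be swapped.

# Time-course switches

The primary transcript of a gene is the one with the highest mean
expression across the ordered stages (ties break to the smallest id). For
an alternative with profile $a$ against primary $p$, the score is the
dominance range of the relative expression

$$ r_t = \frac{a_t}{a_t + p_t}, \qquad
   S = \max_t r_t - \min_t r_t \in [0, 1], $$

with $r_t = 0.5$ when both profiles are zero at a stage (neutral, keeping
the stage axis intact). Shape-identical profiles give $S = 0$; a complete
dominance flip approaches 1; a gene is a switch when any alternative
scores strictly above the threshold (default 0.5). The score is one
exported function (`tcsScore()`) so an alternative formulation can be
substituted without touching the caller; this dominance-range form
satisfies the properties the method requires — it measures relative
expression, grows with shape dissimilarity, lives in $[0,1]$, and makes
0.5 a meaningful switching threshold. `stageDominanceCounts()` gives the
per-stage census of alternatives exceeding their primary above an
expression threshold; it is monotone non-increasing in that threshold by
construction.

# Functional impact

Domain hits are re-indexed by location before isoforms are compared: the
same accession at two gene-disjoint locations is two distinct functional
elements. Hits are projected through each isoform's CDS to genomic
coordinates and clustered per accession by overlap across all isoforms
jointly (`reindexDomains()`); any 1-aa overlap after projection merges
hits into one located identifier, so fragmented hits of one biological
domain may split into separate identifiers — a documented limitation.
`classifyDomainChange()` is then a set comparison of located identifiers:
*identical* (all sets equal), *exchange* (some isoform pair each has a
located domain the other lacks), *gain_loss* (a strict subset relation
somewhere), *unannotated* (all sets empty). Exchange is checked before
gain/loss, making the outcomes mutually exclusive.

Localization predictions are score-filtered (kept at score >= 17, the
`psort_keep_ge` constant) and genes classified as *no_prediction*,
*uniform*, or *changed* with one edge per distinct unordered location
pair. Functional groups: transcription factor (any accession from a
configurable DNA-binding/regulatory list — the list is data, not code),
metabolic (GO:0008152), cytochrome P450 (IPR001128), cazyme (external
predictor flag), and secreted (signal peptide or secretory targeting, at
most one transmembrane domain, extracellular score strictly greater than
17, the `psort_secreted_gt` constant). The two 17-thresholds are
deliberately separate configuration values: the secretion rule is strict
(`> 17`) while localization filtering keeps ties (`>= 17`), and each rule
is applied literally where it belongs. `groupEnrichment()` is a one-sided
hypergeometric tail with Benjamini–Hochberg correction across groups.

# The synthetic-data generator

`simulationConfig()` fixes the study conditions; its defaults are the
conditions the analysis is tested under, not tuning knobs. The primitive
event mix is IR 0.33 / A5SS 0.25 / A3SS 0.21 / ES 0.21; 18% of genes are
alternatively spliced; five developmental stages (vegetative, induced
vegetative, aggregates, primordia, mushroom); 19% of AS genes are planted
switches; 29% of emitted junctions are spurious singletons; domain-change
categories are planted at identical 0.18 / gain_loss 0.70 / exchange
0.12, and localization outcomes at no_prediction 0.41 / uniform 0.56 /
changed 0.03. Where the emulated conditions leave a free choice we fixed
realistic values once: exons of 60–240 nt, introns of 48–90 nt (typical
compact fungal gene geometry), 4–8 exons per gene, intergenic spacing of
300–800 nt, lognormal expression noise of sdlog 0.1, and one third of
planted coding deltas frame-neutral (the unconstrained expectation for a
random length).

Each gene's reference transcript is a single ORF spanning the whole
spliced sequence, so CDS context is well defined; alternatives realize one
sampled event each. MXE genes are necessarily realized as two transcripts
each skipping one exon of the pair — the pairwise-absence definition
forbids a transcript containing both — so the ground truth records the
MXE *and* the two implied ES primitives. Multiple-alternative-site genes
likewise record the two implied boundary primitives. The generator emits
assembler-style transcript models and junction tables directly; it does
not simulate reads, fragment coverage, alignment artifacts, partial
transcripts, or overlapping-UTR read bleed. Passing closure tests
therefore demonstrate the correctness of the classification logic under
clean inputs, not robustness to assembler noise on real data.

Determinism is part of the contract: the same `SimulationConfig`
(including seed) produces byte-identical files.

# Numerical and degenerate-input choices

* Exon-group clustering, junction clustering and domain clustering merge
  on true overlap only (touching intervals stay separate).
* Strict containment defines a retained-intron exon (`s < a`, `b < e`):
  an exon merely sharing a boundary with an intron is boundary variation,
  not retention.
* A transcript exon overlapping no group representative falls back to the
  group's variant span; overlapping neither is an anomaly that is
  reported, never dropped.
* Zero-expression stage pairs score a neutral r of 0.5 rather than being
  dropped.
* An empty annotation file parses to an empty gene list; empty event
  tables count to all-zero tables with every event type present.

# Problem sizes

The shipped tests and the acceptance script run the full closure at 500
genes (about 90 planted events), switch recovery at 400 genes, the
junction filter at 1,500 genes (over 10,000 junctions) and impact closure
at 150 genes — sizes chosen so the whole suite completes in about two
minutes on a single core while every code path is exercised at
non-trivial scale.

# Known limitations

* Boundary events are called against the majority representative; calling
  against the annotated reference exon instead would shift labels for
  genes where the annotation is the minority variant.
* The A5SS/A3SS labels follow the exon-relative convention and invert
  relative to donor/acceptor-convention tools.
* Junction-cluster event rules are a reconstruction, isolated for
  replacement.
* Domain re-indexing merges on any overlap; adjacent same-accession hits
  split.
* No PSI quantification and no per-event significance testing — the
  analysis is categorical by design.

# A worked example

```{r example}
cfg <- simulationConfig(seed = 7, n_genes = 40, noise_sd = 0)
gm <- simulateGeneModels(cfg)
events <- do.call(rbind, lapply(gm$genes, callGeneEvents, genome = gm$genome))
head(events[, c("gene_id", "transcript_ids", "etype", "start", "end",
                "region", "frame_neutral", "delta_nt")])
countEvents(events, "event")
evaluateEventRecovery(events, gm$truth)
```
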