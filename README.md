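# consplice

Consensus-annotation alternative-splicing analysis for gene-dense
(fungal) genomes.

## The problem

In compact fungal genomes, intergenic distances of a few hundred base
pairs make genome-wide transcript assembly unreliable: overlapping UTRs
cause assemblers to fuse transcripts of neighboring genes. `consplice`
supports a region-restricted workflow — the genome is split into one
fragment per annotated gene, transcripts are assembled per fragment
externally and projected back — and then classifies alternative splicing
per gene against a **consensus annotation**: all distinctly observed
exons of the gene, with retained-intron exons removed, clustered into
exon groups with majority-vote representative boundaries.

Against that reference the package calls:

* **primitive events** per transcript — intron retention (IR), exon
  skipping (ES), and alternative 5'/3' splice sites (A5SS/A3SS, labeled
  at the exon end that varies, in transcript orientation);
* **composite events** per gene — mutually exclusive exons (MXE: two
  exon groups each observed but never together in one transcript) and
  multiple alternative 5'/3' splice sites (three or more distinct
  boundaries on one exon group);
* **context** — coding vs UTR by overlap with the bearing transcript's
  CDS (longest-ORF rule, minimum 40 nt), and reading-frame neutrality
  (`coding overlap %% 3 == 0`);
* **three-level counts** — per event, per transcript, per gene.

Around the core sit: splice-junction cluster analysis with
singleton-junction removal (for splicing outside modeled regions),
time-course isoform-switch detection over developmental stages (dominance
range of `r_t = alt/(alt+primary)`, switch when the range exceeds 0.5),
domain gain/loss/exchange classification after location re-indexing,
subcellular-localization change edges, functional-group rules and
hypergeometric group enrichment. A deterministic synthetic-data generator
with planted ground truth makes the whole pipeline testable without
sequencing data.

## A worked example

```r
library(consplice)

cfg <- simulationConfig(seed = 7, n_genes = 40, noise_sd = 0)
gm  <- simulateGeneModels(cfg)
events <- do.call(rbind, lapply(gm$genes, callGeneEvents, genome = gm$genome))
head(events[, c("gene_id", "transcript_ids", "etype", "start", "end",
                "region", "frame_neutral", "delta_nt")])
#>   gene_id transcript_ids etype start   end region frame_neutral delta_nt
#> 1  g00002      g00002.t2    IR  3637  3687 coding          TRUE       50
#> 2  g00008      g00008.t2    IR 13903 13957 coding          TRUE       54
#> 3  g00015      g00015.t2  A3SS 26473 26491 coding          TRUE      -18
#> 4  g00019      g00019.t2    IR 32188 32272 coding          TRUE       84
#> 5  g00026      g00026.t2  A5SS 43986 44009 coding         FALSE      -23
#> 6  g00028      g00028.t2    IR 49322 49408    utr          TRUE       86
```

Each row is one classified event: `g00002.t2` retains a 50-nt intron at
scaffold positions [3637, 3687) inside its coding region; `g00015.t2`
contracts an exon 3' boundary by 18 nt (negative `delta_nt` = shorter
than the consensus representative), a frame-neutral change.

```r
countEvents(events, "event")
#>   etype coding utr total
#> 1    IR      3   1     4
#> 2    ES      0   0     0
#> 3  A5SS      2   0     2
#> 4  A3SS      1   0     1
#> 5   MXE      0   0     0
#> 6 MA5SS      0   0     0
#> 7 MA3SS      0   0     0

evaluateEventRecovery(events, gm$truth)
#> $precision  [1] 1
#> $recall     [1] 1
#> $n_called   [1] 7
#> $n_truth    [1] 7
```

All seven planted events are recovered with no false calls. The full
pipeline (`runPipeline()` over a YAML/`pipelineConfig()` configuration, or
`inst/scripts/run-pipeline.R` from a shell) additionally produces junction
events, time-course switch calls, domain/localization impact tables and a
JSON summary report.

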