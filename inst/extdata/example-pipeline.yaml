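# Example pipeline configuration; paths are relative to where you run it.
annotation: synthetic/annotation.gff3
genome: synthetic/genome.fa
expression: synthetic/expression.tsv
junctions: synthetic/junctions.tsv
domains: synthetic/domains.tsv
localization: synthetic/localization.tsv
annotation_dialect: gff3
outdir: results
min_orf_nt: 40
tcs_threshold: 0.5
psort_secreted_gt: 17
psort_keep_ge: 17
junction_min_count: 2
seed: 1
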