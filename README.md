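# circchar

Downstream characterization of circular RNAs (circRNAs) from back-spliced
junction calls.

CircRNAs are covalently closed transcripts detected in RNA-seq as
*back-spliced junctions* — reads in which a downstream splice donor joins an
upstream acceptor. Junction callers (CIRCexplorer2, circRNA_finder, CIRI2,
...) stop at per-sample junction tables; everything biological comes after:
which junctions are exonic circRNAs and which are intronic, which genes
parent them, how reproducible the calls are across replicates and
developmental stages, what distinguishes circularized exons (position in
the gene, flanking-intron length, repeats, inverted repeats), which parent
genes are functionally enriched, which circRNAs are differentially
expressed, and how circRNA abundance tracks parent-gene expression.
`circchar` implements that entire downstream analysis as a tested R
package, for transcriptomics researchers working with multi-stage or
multi-condition circRNA catalogs — the defaults target a 3-stage x
2-replicate fungal developmental design, but every threshold is exposed.

## What it computes

* **Catalog** — junctions merged by exact coordinates
  (`circ_id = scaffold_start_end`), classified against union-merged gene
  models (exonic / intronic / other), per-sample counts and CPM
  (count / total back-spliced reads x 10^6), read-count filters
  (per-sample count >= 1; summed count >= 5 for characterization).
* **Set comparisons** — replicate consensus by intersection; 7-region
  three-stage Venn tallies per class.
* **Genomic features** — back-spliced exon position (first / middle /
  last / ambiguous, transcriptional orientation), spanned exon count and
  length, flanking vs control intron lengths with a one-sided Wilcoxon
  rank-sum test (exact for small untied samples), merged repeat coverage
  per intron, and exact inverted repeats between flanking introns
  (seed-and-extend, default >= 20 nt).
* **Statistics** — hypergeometric upper-tail term enrichment computed in
  log space; Pearson correlation significance via
  `t = r / sqrt((1 - r^2)/(N - 2))` with `N - 2` degrees of freedom and
  classification at `r >= 0.9` / `r <= -0.9`, `q < 0.01`; stage-wise
  differential expression by pairwise equal-variance t-tests
  (pair-corrected minimum p, `q < 0.05`); Benjamini–Hochberg q-values
  throughout.
* **Alternative circularization** — multi-isoform parent genes, event
  counts, 2 / 3 / >=4 histogram.
* **Synthetic data** — a seeded generator emitting a complete input bundle
  (annotation, genome, repeats, junction tables, expression tables, term
  map) with planted ground truth (classes, positions, intron inflation,
  correlated pairs, enriched terms, DE circRNAs, replicate concordance)
  and a truth manifest for recovery scoring.

## Worked example

```r
library(circchar)

sim   <- simulate_dataset(sim_config(seed = 42))   # planted ground truth
paths <- write_sim_dataset(sim, "bundle")

run <- run_pipeline(pipeline_config(
  annotation = paths$annotation, junctions = paths$junctions,
  sample_stage = paths$sample_map, out_dir = "results",
  genome = paths$genome, repeats = paths$repeats,
  term_map = paths$term_map, gene_expr = paths$gene_expr,
  circ_expr = paths$circ_expr))
print(run)
```

```
circRNA characterization run
  junctions: 144 (exonic 122, intronic 22, other 0)
  filtered (total count): 131
  flank vs control introns: 169.6 vs 82.2 nt, p = 6.74e-30
  DE circRNAs (q<0.05): 17
  correlations: 17 positive, 17 negative
  alt-circ: 64 events from 31 loci
```

Reading the output: of 150 planted circRNAs, 144 were detected in at least
one sample (per-sample detection is deliberately sparse, emulating ~25%
replicate concordance) and 131 survive the summed-count filter. Flanking
introns average twice the control-intron length — the planted inflation
factor — with an overwhelming one-sided Wilcoxon p. The differential
expression and correlation counts recover the planted 8-fold DE circRNAs
and the planted positive/negative circRNA–parent-gene pairs that survived
detection. Per-record tables (`catalog.tsv`, `features.tsv`,
`enrichment.tsv`, `de.tsv`, `correlation.tsv`, ...) and a `report.json`
whose tallies are re-derivable from them land in `results/`.

A thin command-line wrapper is installed at `inst/cli/circchar.R`
(`simulate` and `run` subcommands, YAML config).

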