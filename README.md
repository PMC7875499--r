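# genetrapr

Analysis of gene-trap insertional-mutagenesis libraries in mouse embryonic
stem cells.

Gene-trap vectors mutate a gene, report its expression and leave a genomic
sequence tag marking the insertion site; international consortia have built
libraries of hundreds of thousands of ES cell lines this way. `genetrapr`
is for computational biologists mining such a library — in particular for
asking which non-coding RNA genes it mutates. It provides the full analysis
path from raw sequence tags to publishable census and enrichment tables:

* **Tag filtering** — reduce the tag set to one representative, uniquely
  and confidently mapped tag per vector integration (unmapped /
  non-unique → multi-mapping → non-representative, in that order, with a
  conservation-checked discard report).
* **Insertion-site annotation** — map each integration against GTF gene
  models (Ensembl dialect; biotypes via `gene_biotype` or `gene_type`),
  classified into GENCODE biotypes: protein-coding, lncRNA subclasses
  (lincRNA, antisense, sense overlapping, sense intronic, bidirectional
  promoter, processed transcript, TEC, …), sncRNA and pseudogene. Each hit
  carries the relative position from the TSS, decile, exon/intron context,
  strand relation, spliced-host flag and an activation-mechanism call
  (sense splice fusion, polyA exon capture, antisense insertion, …).
* **Positional statistics** — decile profiles per vector class × gene
  class, tested for uniformity with the G-test of goodness-of-fit,
  `G = 2 Σ Oᵢ ln(Oᵢ/Eᵢ)` against χ²₉. Splice-acceptor promoter traps are
  5′-biased; polyA traps are 3′-biased (upstream insertions are lost to
  nonsense-mediated decay).
* **Biotype enrichment** — per (vector, biotype) cell a 2×2 table tested
  with one-sided Fisher's exact test (over-representation), all cells
  adjusted jointly by Benjamini–Hochberg with FDR 0.01, exported as a
  −log₁₀(adjusted p) matrix ready for any heatmap plotter.
* **Simulator** — a seeded generator of annotation sets and tag libraries
  with known ground truth (biotype census, positional models, vector
  biotype preferences, expression dependence, mapping noise), so the whole
  pipeline is testable offline.

See `vignettes/genetrap-methods.Rmd` for the model, conventions and design
choices.

## Worked example

Simulate a two-vector study (a 5′-biased splice-acceptor promoter trap and
a 3′-biased polyA trap, 5000 integrations each over a ~280-gene genome) and
run the full pipeline:

```r
library(genetrapr)

cfg <- synthetic_config(seed = 1)
sim <- simulate_study(cfg, "demo")
res <- run_pipeline(list(gtf = "demo/genes.gtf",
                         tags = "demo/tags.tsv",
                         out_dir = "demo/out"))
#> genome_model: 278 genes loaded
#> gtst_filter: n_input = 14496 = n_retained 10000 + unmapped 1003 + no_unique_hq 490 + multi_hq 1006 + nonrepresentative 1997
#> annotate: 5996 in genes, 4004 intergenic of 10000 integrations
#> positional: 4 strata
#> enrichment: 3 significant cell(s) at FDR 0.01
#> reports: census, ncrna_subclasses, spliced written

res$positional
#> positional_profiles: 4 strata
#>      vector_class     gene_class    n        G       p_value
#>  promoter_trap_SA protein_coding 1716 3121.972  0.000000e+00
#>        polyA_trap protein_coding 1500 2730.242  0.000000e+00
#>  promoter_trap_SA         lncRNA  576 1067.297 5.271376e-224
#>        polyA_trap         lncRNA  665 1281.303 3.377431e-270

res$enrichment
#> enrichment_matrix (major_class level): 2 vectors x 4 biotypes; 3 significant at FDR 0.01
#>       protein_coding lncRNA sncRNA pseudogene
#> PTSA1           6.12   0.00   0.11       0.00
#> PAT1            0.00   2.41   0.00       4.98
```

Reading the output: the filter's counters sum exactly to the input tag
count and all 10,000 planted integrations survive; ~40% of integrations are
intergenic, matching the generator's setting. Every positional G-test
rejects uniformity decisively because both vectors were generated with
geometric decile bias. In the enrichment matrix the expression-dependent
promoter trap (PTSA1) is over-represented in protein-coding genes, while
the polyA trap (PAT1), which inserts regardless of host expression, is
relatively enriched in the weakly expressed lncRNA and pseudogene classes —
the vector-design effect the analysis is built to detect.

`run_pipeline()` writes the integration table, annotation TSV + BED,
positional profiles, enrichment tables and the census reports to the output
directory; all outputs are byte-deterministic for a given seed and config.
A thin CLI wrapper lives at `inst/cli/genetrap.R`
(`Rscript genetrap.R run config.yaml` / `simulate <seed> <dir>`).

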