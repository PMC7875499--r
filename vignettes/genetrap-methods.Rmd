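---
title: "Methods: annotating and testing gene-trap insertion libraries"
author: "genetrapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: annotating and testing gene-trap insertion libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genetrapr)
```

## The problem

Gene trapping mutagenises mouse embryonic stem (ES) cells with generic
vectors that simultaneously disrupt a gene, report its expression, and leave
a genomic sequence tag identifying the insertion site. Large international
libraries hold hundreds of thousands of such ES cell lines. `genetrapr`
implements the downstream computational analysis of such a library:

1. **filter** raw gene-trap sequence tags down to one representative,
   uniquely and confidently mapped tag per vector integration;
2. **annotate** each integration against gene models (hit gene or
   intergenic, position along the gene, exon/intron, strand relation,
   activation mechanism), with genes classified into GENCODE biotypes —
   protein-coding, lncRNA with its positional subclasses, short ncRNA and
   pseudogene;
3. **test** positional bias along genes (decile profiles, G-test of
   goodness-of-fit) and vector-specific biotype preference (one-sided
   Fisher's exact tests under Benjamini–Hochberg FDR control);
4. **report** the census tables a library analysis publishes.

A seeded simulator generates annotation sets and tag libraries with known
ground truth, so every stage is testable without any external download.

## Tag filtering

Three rules are applied in a fixed order, each discarded tag being
attributed to the first rule that removed it: (i) drop tags that are
unmapped or lack a unique high-quality alignment; (ii) drop tags with
multiple high-quality alignments; (iii) among a cell line's surviving tags
keep only those flagged representative. The mapping-quality and
representativeness flags are taken as given input columns — re-alignment is
out of scope. Each surviving cell line contributes exactly one integration
(the library is built from lines with single integrations); if several
representative tags survive for one line, the lexicographically smallest
`tag_id` wins deterministically and a warning is raised when the survivors
disagree on coordinates. The tie losers are counted together with the
non-representative discards so that the filter report's counters always sum
to the input size.

## Annotation conventions

* **Coordinates** are 0-based half-open internally; GTF I/O converts at the
  boundary. This makes the decile arithmetic exact and unambiguous.
* **Gene extent** is the annotated gene record's span (TSS to transcription
  end), not the exon union, because positional profiles measure distance
  from the transcription start site over the whole gene. Whether the
  original analyses used gene spans or transcript unions is not documented;
  the gene span is the simpler, reproducible choice.
* **Relative position** of an insertion at `p` in a gene `[s, e)` is
  `(p - s)/(e - s)` on the plus strand and `(e - 1 - p)/(e - s)` on the
  minus strand, so 0 is always the TSS; the decile is
  `floor(10 * rel) + 1`.
* **Intergenic** means contained in no gene span. Whether "intergenic"
  should instead mean outside transcripts is unstated in the source
  analyses; span containment is used, and since hits report the containing
  gene either convention can be recovered from the output.
* **Overlapping genes**: all containing genes are reported as hits. A
  primary hit is chosen per integration — sense-strand hits first (gene-trap
  selection acts on the sense strand), then the smallest gene span (the most
  specific locus), then lexicographic `gene_id`. Statistics (positional
  profiles, enrichment) use primary hits only so each integration counts
  once; census tables count every hit gene, deduplicated per (gene, cell
  line) pair, because an insertion inside two overlapping genes is evidence
  for both loci.
* **Strandless tags** are treated as sense by convention and flagged in a
  `strand_imputed` column, keeping the pipeline deterministic.
* **Exon membership** is tested against the union of exons over all of a
  gene's transcripts: any isoform's exon can carry a reporter fusion.
* A gene counts as **spliced** iff some single transcript has at least two
  exons; two single-exon isoforms at different positions do not splice.

### Activation mechanisms

The mechanism classifier is a total rule table with precedence
`intergenic > antisense > structural subclass > vector class`:
intergenic insertions activate from non-annotated regions; antisense
insertions transcribe opposite to the host; sense insertions into
bidirectional-promoter lncRNAs are driven by the shared divergent promoter
and those into sense-overlapping lncRNAs truncate the host read-through
transcript. Below those, a sense insertion into a single-exon host is
classified `unspliced_insertion` *before* the vector-class rules: both
splice-acceptor and polyA-trap activation require a splicing partner, so a
non-spliced host overrides vector design. Otherwise polyA traps incorporate
themselves as a portable exon (`polyA_exon_capture`) and every
splice-acceptor-bearing class forms an upstream fusion
(`sense_splice_fusion`).

## Biotype taxonomy

The shipped table maps GENCODE vM8 biotype strings (plus common aliases) to
the four major classes, keeping TEC inside the lncRNA class as the
enrichment analyses group it there. Unmatched `*_pseudogene` strings fall
back to pseudogene and `IG_*`/`TR_*` segment genes to protein-coding;
anything else is retained as `unclassified` — excluded from biotype tables
but visible in diagnostics, so the pipeline does not hard-fail on other
annotation releases. The table is overridable from a two-column TSV. The
bundled annotated-gene census carries the mouse Ensembl 83 / GENCODE vM8
lncRNA counts (9072 lncRNA genes; lincRNA 3579, antisense 2189, sense
overlapping 23, sense intronic 253, bidirectional promoter 12), used for
the percent-of-annotated column of the census report.

## Statistics

**Positional profiles.** Counts over ten equal-length gene segments from
the TSS, per (vector class, gene class) stratum, tested for uniformity with
the G-test `G = 2 Σ O_i ln(O_i / E_i)`, `E_i = n/10`, compared to a
chi-square with 9 degrees of freedom. Zero cells contribute 0 (the
`0·ln 0` limit); no Williams or continuity correction is applied — at
library-scale counts a correction changes nothing, but the convention must
be fixed. Both raw counts and frequencies are emitted because the published
figures use an unspecified "relative units" normalisation.

**Enrichment.** For each (vector, biotype) cell a 2×2 table `[[a, b],
[c, d]]` contrasts this vector's integrations in the biotype against all
other vectors, over primary non-intergenic hits. The test is the one-sided
(`greater`) exact hypergeometric tail — the question asked is
over-representation, not any difference. At the `lnc_subclass` level, cells
are formed for the lncRNA subclasses (TEC included) while the universe
remains *all* annotated integrations; restricting the universe to lncRNA
hits would let one vector's strong subclass preference masquerade as
relative enrichment of every other vector in the remaining subclasses.
Adjusted p-values are Benjamini–Hochberg step-up, computed jointly over all
cells of the matrix (the conservative reading when one matrix of adjusted
values is reported; a per-vector family is available by subsetting), with
significance at adjusted `p ≤ 0.01` by default. For display,
`-log10(p_adjusted)` is capped at 300 where the adjusted p underflows.

## The simulator

`synthetic_config()` defaults define the emulated study:

* **Genome**: the mouse GENCODE vM8 census scaled by roughly 1/150
  (140 protein-coding, 60 lncRNA across all subclasses, 38 sncRNA, 40
  pseudogene genes), placed with random intergenic gaps on synthetic
  chromosomes. Four overlap arrangements are planted deliberately —
  antisense-in-PCG, sense-intronic guest, bidirectional-promoter pair,
  sense-overlapping host with an intronic PCG — mirroring the structural
  contexts the mechanism classifier must resolve. Gene lengths are rounded
  to multiples of 10 so decile boundaries are exact.
* **Positional bias** is a truncated geometric distribution over deciles,
  mass `∝ (1-ρ)^(d-1)` from the favoured end with `ρ = 0.5` by default:
  the published profiles give shapes (5′-biased splice-acceptor promoter
  traps, 3′-biased polyA traps) but no functional form, so a one-parameter
  family was chosen for testability against an analytic mass function.
* **Expression** is a per-gene Bernoulli flag (0.75 for protein-coding,
  0.6 for lncRNA/sncRNA, 0.3 for pseudogenes — a minimal model of ES-cell
  expression breadth). Promoter-trap vectors sample only expressed genes;
  polyA traps, which carry their own promoter, ignore the flag. This is the
  minimal model of expression-independent polyA-trap activation, and it
  alone reproduces the qualitative vector-class preference differences in
  the default run.
* **Noise**: per clean integration a Poisson(0.2) number of redundant
  non-representative tags; plus unmapped (10%), low-quality (5%) and
  multi-mapping (10%) tags for separate noise cell lines, all of which the
  filter must remove exactly.
* **Intergenic fraction** defaults to 0.4, the genic/intergenic split
  observed in the real library.
* All randomness flows from `config$seed` (the annotation uses `seed`, the
  tag library `seed + 1`), and identical configs give byte-identical output
  files.

The simulator does **not** emulate sequence-level effects (no nucleotides,
no cryptic splice sites), insertion hotspots, chromatin accessibility,
NMD kinetics beyond the 3′ decile bias, multi-integration cell lines, or
real GENCODE gene-structure complexity (one transcript per gene, equal-block
exon layout). Passing tests therefore demonstrate correctness of the
pipeline's logic and calibration of its statistics under a clean generative
model — not robustness to every artefact of real MGI data.

## Validation study designs

The test suite fixes these problem sizes as its study conditions:

* G-test type-I calibration: 2000 uniform replicates of n = 1000, rejection
  rate at α = 0.05 required in [0.04, 0.06].
* Null enrichment: two identically distributed vectors of 1000 integrations,
  100 seeded runs; at least 95 runs must flag nothing at FDR 0.01.
* Planted recovery: one vector with a 10× lincRNA multiplier among four
  unbiased vectors, 5000 integrations each, 100 seeded runs; the planted
  cell must be flagged in at least 95 runs with false flags in at most 5.
  The genome for this experiment keeps the preferred subclass rare (6
  lincRNA genes of ~300): a strong preference for a common biotype
  necessarily depletes the biased vector's share of every other biotype,
  making the unbiased vectors *genuinely* relatively enriched elsewhere —
  a composition effect, not a false positive, but one that would confound
  the false-flag count. Keeping the planted class rare keeps that
  distortion below the detection limit while leaving the planted signal
  overwhelming.
* Exact oracles: the Fisher tail is checked against explicit
  binomial-coefficient enumeration over every 2×2 table with grand total
  ≤ 60; BH against a naive double loop; the interval index against an
  all-pairs containment scan on a 500-gene × 5000-integration fixture.

## Known limitations

* One integration per cell line is assumed; violations are resolved
  deterministically, not modelled.
* The "high-quality alignment" judgement is an input flag; the pipeline
  never recomputes alignment quality.
* Biotype taxonomies that collapse lncRNA subclasses (e.g. releases that
  use a bare `lncRNA` biotype) classify as `unclassified` unless an
  override table is supplied, because a subclass cannot be invented.
* The enrichment test conditions on margins per cell; it does not model
  correlation between cells induced by the shared universe beyond the BH
  adjustment.
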