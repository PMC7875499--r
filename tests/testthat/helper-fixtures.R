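# fixture builders shared across test files

# write a GTF from a compact gene spec; coordinates are 1-based closed as in
# the file format. exons defaults to one exon spanning the gene.
write_fixture_gtf <- function(genes, path = tempfile(fileext = ".gtf"),
                              biotype_key = "gene_biotype") {
  lines <- character(0)
  for (g in genes) {
    exons <- g$exons %||% list(c(g$start, g$end))
    attrs <- sprintf('gene_id "%s"; gene_name "%s"; %s "%s";',
                     g$gene_id, g$symbol %||% g$gene_id, biotype_key, g$biotype)
    lines <- c(lines, sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\t%s",
                              g$chrom, g$start, g$end, g$strand, attrs))
    tx <- sprintf('%s transcript_id "%s";', attrs, paste0(g$gene_id, ".t1"))
    lines <- c(lines, sprintf("%s\ttest\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              g$chrom, min(vapply(exons, `[`, 0, 1)),
                              max(vapply(exons, `[`, 0, 2)), g$strand, tx))
    for (e in exons) {
      lines <- c(lines, sprintf("%s\ttest\texon\t%d\t%d\t.\t%s\t.\t%s",
                                g$chrom, e[1], e[2], g$strand, tx))
    }
  }
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one sequence tag row with sensible defaults, overridable per field
make_tag <- function(tag_id, cell_line_id = tag_id, vector_id = "V1",
                     vector_class = "promoter_trap_SA", chrom = "chr1",
                     position = 100L, tag_strand = "+", mapped = TRUE,
                     alignment_quality = "high",
                     n_high_quality_alignments = 1L, representative = TRUE) {
  data.frame(tag_id = tag_id, cell_line_id = cell_line_id,
             vector_id = vector_id, vector_class = vector_class,
             chrom = chrom, position = position, tag_strand = tag_strand,
             mapped = mapped, alignment_quality = alignment_quality,
             n_high_quality_alignments = n_high_quality_alignments,
             representative = representative, stringsAsFactors = FALSE)
}

# minimal annotation table (genetrap_annotation) built directly, for report
# and statistics tests that do not need a genome
make_annot <- function(vector_id, major_class, lnc_subclass = "none",
                       gene_id = NULL, decile = 1L,
                       vector_class = "promoter_trap_SA",
                       host_spliced = TRUE, strand_relation = "sense",
                       relative_position = (decile - 0.5) / 10) {
  n <- max(lengths(list(vector_id, major_class, lnc_subclass, gene_id, decile)))
  if (is.null(gene_id)) gene_id <- sprintf("G%04d", seq_len(n))
  df <- data.frame(
    cell_line_id = sprintf("CL%05d", seq_len(n)),
    vector_id = rep_len(vector_id, n),
    vector_class = rep_len(vector_class, n),
    chrom = "chr1", position = seq_len(n),
    tag_strand = "+", strand_imputed = FALSE, intergenic = FALSE,
    gene_id = rep_len(gene_id, n), symbol = rep_len(gene_id, n),
    raw_biotype = rep_len(major_class, n),
    major_class = rep_len(major_class, n),
    lnc_subclass = rep_len(lnc_subclass, n),
    relative_position = rep_len(relative_position, n),
    decile = rep_len(as.integer(decile), n),
    strand_relation = rep_len(strand_relation, n),
    host_spliced = rep_len(host_spliced, n),
    region = "intron", primary = TRUE,
    stringsAsFactors = FALSE
  )
  df$mechanism <- classify_mechanism(df$strand_relation, df$host_spliced,
                                     df$lnc_subclass, df$vector_class,
                                     df$intergenic)
  attr(df, "n_integrations") <- n
  class(df) <- c("genetrap_annotation", "data.frame")
  df
}

# brute-force one-sided Fisher p by explicit hypergeometric enumeration
fisher_enum <- function(a, b, c, d) {
  N <- a + b + c + d
  K <- a + c
  n1 <- a + b
  kmax <- min(K, n1)
  if (a > kmax) return(0)
  k <- a:kmax
  sum(exp(lchoose(K, k) + lchoose(N - K, n1 - k) - lchoose(N, n1)))
}

# naive O(m^2) Benjamini-Hochberg step-up
bh_naive <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m / j * ps[j])
    adj[i] <- min(1, best)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}
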