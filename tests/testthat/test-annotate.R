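fixture_ann <- function() {
  read_gtf(write_fixture_gtf(list(
    # 2-exon plus-strand PCG on [0,1000): exons [0,100) and [800,1000)
    list(gene_id = "PCG1", chrom = "chr1", start = 1, end = 1000, strand = "+",
         biotype = "protein_coding", exons = list(c(1, 100), c(801, 1000))),
    # single-exon lincRNA
    list(gene_id = "LNC1", chrom = "chr1", start = 5001, end = 6000,
         strand = "+", biotype = "lincRNA"),
    # minus-strand spliced antisense gene overlapping nothing
    list(gene_id = "AS1", chrom = "chr1", start = 8001, end = 10000,
         strand = "-", biotype = "antisense",
         exons = list(c(8001, 8500), c(9501, 10000)))
  )))
}

test_that("relative position measures distance from the TSS on either strand", {
  expect_equal(relative_position(0L, 0L, 1000L, "+"), 0)
  expect_equal(relative_position(999L, 0L, 1000L, "-"), 0)
  expect_equal(relative_position(950L, 0L, 1000L, "+"), 0.95)
  expect_equal(relative_position(0L, 0L, 1000L, "-"), 0.999)
  expect_error(relative_position(1000L, 0L, 1000L, "+"), "outside")
})

test_that("integrations map to hits with region, strand relation and decile", {
  ann <- fixture_ann()
  ints <- data.frame(
    cell_line_id = c("c1", "c2", "c3", "c4"),
    vector_id = "V1", vector_class = "promoter_trap_SA",
    chrom = "chr1",
    position = c(3000L, 500L, 5500L, 9000L),
    tag_strand = c("+", "+", "+", "+"),
    stringsAsFactors = FALSE
  )
  annot <- annotate_integrations(ints, ann)

  # c1 outside every span -> intergenic
  r1 <- annot[annot$cell_line_id == "c1", ]
  expect_true(r1$intergenic)
  expect_equal(r1$mechanism, "intergenic_activation")

  # c2 in intron 1 of PCG1, sense
  r2 <- annot[annot$cell_line_id == "c2", ]
  expect_equal(r2$gene_id, "PCG1")
  expect_equal(r2$region, "intron")
  expect_equal(r2$strand_relation, "sense")
  expect_equal(r2$decile, 6L)
  expect_equal(r2$mechanism, "sense_splice_fusion")

  # c3 inside single-exon lincRNA -> exon, unspliced host
  r3 <- annot[annot$cell_line_id == "c3", ]
  expect_equal(r3$gene_id, "LNC1")
  expect_equal(r3$region, "exon")
  expect_false(r3$host_spliced)
  expect_equal(r3$mechanism, "unspliced_insertion")

  # c4 on + strand inside minus-strand gene -> antisense
  r4 <- annot[annot$cell_line_id == "c4", ]
  expect_equal(r4$strand_relation, "antisense")
  expect_equal(r4$mechanism, "antisense_insertion")

  # counts conserve and stored deciles recompute from relative position
  s <- summary(annot)
  expect_equal(s$n_annotated + s$n_intergenic, s$n_integrations)
  hits <- annot[!annot$intergenic, ]
  expect_equal(hits$decile, floor(hits$relative_position * 10) + 1)
})

test_that("tags without strand are annotated sense by convention and flagged", {
  ann <- fixture_ann()
  ints <- data.frame(cell_line_id = "c1", vector_id = "V1",
                     vector_class = "promoter_trap_SA", chrom = "chr1",
                     position = 9000L, tag_strand = NA_character_,
                     stringsAsFactors = FALSE)
  annot <- annotate_integrations(ints, ann)
  expect_true(annot$strand_imputed)
  expect_equal(annot$strand_relation, "sense")
})

test_that("integrations on unknown chromosomes become intergenic with a warning", {
  ann <- fixture_ann()
  ints <- data.frame(cell_line_id = "c1", vector_id = "V1",
                     vector_class = "promoter_trap_SA", chrom = "chrUn",
                     position = 100L, tag_strand = "+",
                     stringsAsFactors = FALSE)
  expect_warning(annot <- annotate_integrations(ints, ann), "absent")
  expect_true(annot$intergenic)
})

test_that("the mechanism rule table is total and respects precedence", {
  # antisense beats every structural subclass
  expect_equal(classify_mechanism("antisense", TRUE, "bidirectional_promoter",
                                  "promoter_trap_SA", FALSE),
               "antisense_insertion")
  # bidirectional promoter beats vector-class rules
  expect_equal(classify_mechanism("sense", TRUE, "bidirectional_promoter",
                                  "polyA_trap", FALSE),
               "bidirectional_promoter_capture")
  expect_equal(classify_mechanism("sense", TRUE, "sense_overlapping",
                                  "promoter_trap_SA", FALSE),
               "host_readthrough_truncation")
  # splice-acceptor classes in spliced hosts fuse; polyA traps exon-capture
  for (vc in c("promoter_trap_SA", "exon_trap", "combined", "secretory_trap")) {
    expect_equal(classify_mechanism("sense", TRUE, "lincRNA", vc, FALSE),
                 "sense_splice_fusion")
  }
  expect_equal(classify_mechanism("sense", TRUE, "processed_transcript",
                                  "polyA_trap", FALSE),
               "polyA_exon_capture")
  # no splicing partner in a single-exon host, whatever the vector
  expect_equal(classify_mechanism("sense", FALSE, "lincRNA", "polyA_trap", FALSE),
               "unspliced_insertion")
  expect_equal(classify_mechanism(NA, NA, NA, "polyA_trap", TRUE),
               "intergenic_activation")
})

test_that("primary hits prefer sense strand, then the smallest gene span", {
  ann <- read_gtf(write_fixture_gtf(list(
    list(gene_id = "BIG", chrom = "chr1", start = 1, end = 20000, strand = "-",
         biotype = "protein_coding", exons = list(c(1, 500), c(19001, 20000))),
    list(gene_id = "SMALL", chrom = "chr1", start = 5001, end = 8000,
         strand = "+", biotype = "lincRNA"),
    list(gene_id = "MID", chrom = "chr1", start = 4001, end = 9000,
         strand = "+", biotype = "antisense",
         exons = list(c(4001, 4500), c(8501, 9000)))
  )))
  ints <- data.frame(cell_line_id = "c1", vector_id = "V1",
                     vector_class = "promoter_trap_SA", chrom = "chr1",
                     position = 6000L, tag_strand = "+",
                     stringsAsFactors = FALSE)
  annot <- annotate_integrations(ints, ann)
  expect_equal(nrow(annot), 3)  # all containing genes are reported
  expect_equal(annot$gene_id[annot$primary], "SMALL")
})

test_that("interval-index hits agree with an all-pairs containment scan", {
  cfg <- synthetic_config(seed = 31, n_integrations_per_vector = 2500,
                          genes_per_biotype = c(protein_coding = 250,
                                                lincRNA = 100, antisense = 80,
                                                miRNA = 40,
                                                processed_pseudogene = 30),
                          noise = list(p_unmapped = 0, p_low_quality = 0,
                                       p_multi_hit = 0,
                                       extra_nonrepresentative_tags_per_integration = 0))
  ann <- generate_annotation(cfg)
  sim <- generate_tags(ann, cfg)
  ints <- filter_tags(sim$tags)$integrations
  annot <- annotate_integrations(ints, ann)
  got <- as.data.frame(annot)[!annot$intergenic, c("cell_line_id", "gene_id")]
  got <- got[order(got$cell_line_id, got$gene_id), ]
  g <- ann$genes
  want <- do.call(rbind, lapply(seq_len(nrow(ints)), function(i) {
    hit <- which(g$chrom == ints$chrom[i] & g$start <= ints$position[i] &
                   ints$position[i] < g$end)
    if (length(hit) == 0) return(NULL)
    data.frame(cell_line_id = ints$cell_line_id[i], gene_id = g$gene_id[hit],
               stringsAsFactors = FALSE)
  }))
  want <- want[order(want$cell_line_id, want$gene_id), ]
  rownames(got) <- rownames(want) <- NULL
  expect_identical(got, want)
})

test_that("relative positions are invariant under genome reflection", {
  cfg <- synthetic_config(seed = 32, n_integrations_per_vector = 500,
                          noise = list(p_unmapped = 0, p_low_quality = 0,
                                       p_multi_hit = 0,
                                       extra_nonrepresentative_tags_per_integration = 0))
  ann <- generate_annotation(cfg)
  sim <- generate_tags(ann, cfg)
  ints <- filter_tags(sim$tags)$integrations
  annot <- annotate_integrations(ints, ann)

  M <- max(ann$genes$end) + 10000L
  flip <- function(s) ifelse(s == "+", "-", "+")
  g2 <- ann$genes
  g2$start <- M - ann$genes$end
  g2$end <- M - ann$genes$start
  g2$strand <- flip(ann$genes$strand)
  e2 <- ann$exons
  e2$start <- M - ann$exons$end
  e2$end <- M - ann$exons$start
  ann2 <- genetrapr:::as_annotation_set(
    g2[c("gene_id", "symbol", "chrom", "start", "end", "strand", "raw_biotype")],
    e2, ann$taxonomy)
  ints2 <- ints
  ints2$position <- M - 1L - ints$position
  ints2$tag_strand <- flip(ints$tag_strand)
  annot2 <- annotate_integrations(ints2, ann2)

  key <- function(a) a[order(a$cell_line_id, a$gene_id), ]
  a1 <- key(annot[!annot$intergenic, ])
  a2 <- key(annot2[!annot2$intergenic, ])
  expect_equal(a1$gene_id, a2$gene_id)
  expect_equal(a1$relative_position, a2$relative_position)
  expect_equal(a1$strand_relation, a2$strand_relation)
})
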