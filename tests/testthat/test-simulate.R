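no_noise <- function() list(p_unmapped = 0, p_low_quality = 0, p_multi_hit = 0,
                            extra_nonrepresentative_tags_per_integration = 0)

test_that("the generator is byte-deterministic given a seed", {
  cfg <- synthetic_config(seed = 61, n_integrations_per_vector = 300)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_study(cfg, d1)
  simulate_study(cfg, d2)
  f1 <- sort(list.files(d1)); f2 <- sort(list.files(d2))
  expect_equal(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  # and a different seed actually changes the library
  d3 <- tempfile()
  simulate_study(synthetic_config(seed = 62, n_integrations_per_vector = 300), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "tags.tsv"))),
                         unname(tools::md5sum(file.path(d3, "tags.tsv")))))
})

test_that("requested biotype counts are honoured and the GTF round-trips", {
  cfg <- synthetic_config(seed = 63,
                          genes_per_biotype = c(protein_coding = 5, lincRNA = 3))
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$genes), 8)
  expect_equal(sum(ann$genes$raw_biotype == "lincRNA"), 3)
  path <- tempfile(fileext = ".gtf")
  write_gtf(ann, path)
  expect_equal(nrow(read_gtf(path)$genes), 8)
})

test_that("single-exon probability 1 makes every gene of that biotype unspliced", {
  cfg <- synthetic_config(seed = 64,
                          genes_per_biotype = c(protein_coding = 10, lincRNA = 10),
                          single_exon_prob = c(protein_coding = 0, lincRNA = 1))
  ann <- generate_annotation(cfg)
  linc <- ann$genes$gene_id[ann$genes$raw_biotype == "lincRNA"]
  expect_true(all(!is_spliced(ann, linc)))
  pcg <- ann$genes$gene_id[ann$genes$raw_biotype == "protein_coding"]
  expect_true(all(is_spliced(ann, pcg)))
})

test_that("without noise or intergenic draws the filter retains every planted event", {
  cfg <- synthetic_config(seed = 65, n_integrations_per_vector = 400,
                          intergenic_fraction = 0, noise = no_noise())
  ann <- generate_annotation(cfg)
  sim <- generate_tags(ann, cfg)
  expect_equal(nrow(sim$tags), 800)  # exactly one tag per planted integration
  res <- filter_tags(sim$tags)
  expect_equal(res$report$n_retained, 800)
  expect_true(all(!sim$truth$intergenic))
})

test_that("planted gene, decile and intergenic state are recovered by the pipeline", {
  cfg <- synthetic_config(seed = 66, n_integrations_per_vector = 3000)
  ann <- generate_annotation(cfg)
  sim <- generate_tags(ann, cfg)
  annot <- annotate_integrations(filter_tags(sim$tags)$integrations, ann)

  tr <- sim$truth
  # intergenic truth must be annotated intergenic
  inter_cl <- tr$cell_line_id[tr$intergenic]
  got_inter <- tapply(annot$intergenic, annot$cell_line_id, all)
  expect_true(all(got_inter[inter_cl]))
  # planted intergenic fraction recovered within binomial error (4 sigma)
  phat <- mean(tr$intergenic)
  expect_lt(abs(phat - 0.4), 4 * sqrt(0.4 * 0.6 / nrow(tr)))

  # every clean gene integration is found among the hits of its true gene,
  # with exactly the planted decile
  clean <- tr[!tr$intergenic, ]
  key <- paste(annot$cell_line_id, annot$gene_id)
  m <- match(paste(clean$cell_line_id, clean$gene_id), key)
  expect_false(anyNA(m))
  expect_equal(annot$decile[m], clean$decile)
})

test_that("geometric positional models reproduce their analytic decile mass", {
  pmf <- decile_pmf("five_prime_geometric", rho = 0.5)
  expect_equal(sum(pmf), 1)
  expect_equal(pmf, rev(decile_pmf("three_prime_geometric", rho = 0.5)))
  expect_equal(decile_pmf("uniform"), rep(0.1, 10))

  cfg <- synthetic_config(
    seed = 67, n_integrations_per_vector = 10000, intergenic_fraction = 0,
    vectors = list(vector_spec("V5p", "promoter_trap_SA",
                               "five_prime_geometric", rho = 0.5,
                               expression_dependent = FALSE)),
    noise = no_noise())
  ann <- generate_annotation(cfg)
  sim <- generate_tags(ann, cfg)
  cnt <- table(factor(sim$truth$decile, levels = 1:10))
  n <- sum(cnt)
  for (d in 1:10) {
    sd_d <- sqrt(n * pmf[d] * (1 - pmf[d]))
    expect_lt(abs(cnt[d] - n * pmf[d]), 4 * sd_d + 1)
  }
})

test_that("planted overlap arrangements exist and carry the right geometry", {
  cfg <- synthetic_config(seed = 68)
  ann <- generate_annotation(cfg)
  g <- ann$genes
  pick <- function(bt) g[g$raw_biotype == bt, ][1, ]
  host_of <- function(row) {
    cand <- g[g$chrom == row$chrom & g$start <= row$start & g$end >= row$end &
                g$gene_id != row$gene_id, ]
    cand[which.min(cand$end - cand$start), ]
  }
  as1 <- pick("antisense"); h <- host_of(as1)
  expect_equal(h$major_class, "protein_coding")
  expect_true(h$strand != as1$strand)

  si <- pick("sense_intronic"); h <- host_of(si)
  expect_equal(h$major_class, "protein_coding")
  expect_true(h$strand == si$strand)
  # inside an intron: no exon of the host overlaps the guest
  hex <- ann$exons[ann$exons$gene_id == h$gene_id, ]
  expect_true(all(hex$end <= si$start | hex$start >= si$end))

  so <- pick("sense_overlapping")
  guest <- g[g$chrom == so$chrom & g$start >= so$start & g$end <= so$end &
               g$gene_id != so$gene_id & g$major_class == "protein_coding", ]
  expect_equal(nrow(guest), 1)
  expect_true(guest$strand == so$strand)

  bp <- pick("bidirectional_promoter")
  partner <- g[g$chrom == bp$chrom & g$gene_id != bp$gene_id &
                 g$start < bp$end & g$end > bp$start, ]
  expect_gte(nrow(partner), 1)
  expect_true(any(partner$strand != bp$strand))
})

test_that("invalid configurations are rejected up front", {
  expect_error(synthetic_config(noise = list(p_unmapped = 1.2, p_low_quality = 0,
                                             p_multi_hit = 0,
                                             extra_nonrepresentative_tags_per_integration = 0)),
               "probabilities")
  expect_error(vector_spec("V", "not_a_class"), "vector_class")
  expect_error(vector_spec("V", "polyA_trap", rho = 1.5), "rho")

  cfg <- synthetic_config(seed = 69, vectors = list(
    vector_spec("V1", "promoter_trap_SA",
                biotype_multipliers = c(no_such_biotype = 10),
                expression_dependent = FALSE),
    vector_spec("V2", "promoter_trap_SA", expression_dependent = FALSE)))
  ann <- generate_annotation(cfg)
  expect_error(generate_tags(ann, cfg), "unknown biotype label")

  too_big <- synthetic_config(seed = 70, chrom_length = 20000,
                              gene_length_range = list(protein_coding = c(30000, 40000)),
                              genes_per_biotype = c(protein_coding = 2))
  expect_error(generate_annotation(too_big), "capacity")
})
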