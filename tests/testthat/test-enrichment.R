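test_that("2x2 tables count vector and biotype margins correctly", {
  annot <- rbind(make_annot(rep("V1", 4), c(rep("lncRNA", 3), "protein_coding"),
                            c(rep("lincRNA", 3), "none")),
                 make_annot(rep("V2", 6), c("lncRNA", rep("protein_coding", 5)),
                            c("lincRNA", rep("none", 5))))
  attr(annot, "n_integrations") <- 10
  class(annot) <- c("genetrap_annotation", "data.frame")
  cells <- build_tables(annot, "major_class")
  v1 <- cells[cells$vector_id == "V1" & cells$biotype_label == "lncRNA", ]
  expect_equal(unlist(v1[c("a", "b", "c", "d")], use.names = FALSE),
               c(3, 1, 1, 5))
  v2 <- cells[cells$vector_id == "V2" & cells$biotype_label == "lncRNA", ]
  expect_equal(unlist(v2[c("a", "b", "c", "d")], use.names = FALSE),
               c(1, 5, 3, 1))
  expect_true(all(cells$a + cells$b + cells$c + cells$d == 10))
})

test_that("degenerate enrichment inputs error or yield trivial cells", {
  single <- make_annot("V1", c("lncRNA", "protein_coding"))
  expect_error(build_tables(single, "major_class"), "two vectors")

  # a vector with zero annotated integrations still gets p = 1 cells
  annot <- rbind(make_annot(rep("V1", 4), rep(c("lncRNA", "protein_coding"), 2)),
                 make_annot("V2", "protein_coding"))
  annot$intergenic[annot$vector_id == "V2"] <- TRUE
  annot$gene_id[annot$vector_id == "V2"] <- NA
  annot$major_class[annot$vector_id == "V2"] <- NA
  attr(annot, "n_integrations") <- 5
  class(annot) <- c("genetrap_annotation", "data.frame")
  cells <- build_tables(annot, "major_class")
  v2 <- cells[cells$vector_id == "V2", ]
  expect_true(all(v2$a == 0 & v2$b == 0))
  expect_true(all(fisher_one_sided(v2$a, v2$b, v2$c, v2$d) == 1))
})

test_that("one-sided Fisher p equals hypergeometric enumeration", {
  expect_equal(fisher_one_sided(0, 10, 0, 10), 1)
  expect_equal(fisher_one_sided(10, 0, 0, 10), 1 / choose(20, 10))
  expect_equal(fisher_one_sided(5, 5, 1, 9), fisher_enum(5, 5, 1, 9),
               tolerance = 1e-14)

  set.seed(50)
  for (i in 1:200) {
    t <- as.integer(rmultinom(1, sample(4:60, 1), prob = runif(4)))
    expect_equal(fisher_one_sided(t[1], t[2], t[3], t[4]),
                 fisher_enum(t[1], t[2], t[3], t[4]), tolerance = 1e-12)
  }
})

test_that("one-sided Fisher p matches stats::fisher.test(alternative='greater')", {
  set.seed(51)
  for (i in 1:50) {
    t <- as.integer(rmultinom(1, sample(10:200, 1), prob = runif(4)))
    ref <- stats::fisher.test(matrix(t, 2, byrow = TRUE),
                              alternative = "greater")$p.value
    expect_equal(fisher_one_sided(t[1], t[2], t[3], t[4]), ref,
                 tolerance = 1e-10)
  }
})

test_that("the two one-sided tails are complementary up to the point mass", {
  set.seed(52)
  for (i in 1:50) {
    t <- as.integer(rmultinom(1, sample(8:80, 1), prob = runif(4)))
    a <- t[1]; b <- t[2]; c <- t[3]; d <- t[4]
    lhs <- fisher_one_sided(a, b, c, d) + fisher_one_sided(c, d, a, b)
    expect_equal(lhs, 1 + dhyper(a, a + c, b + d, a + b), tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up formula and a naive oracle", {
  got <- bh_adjust(c(0.001, 0.01, 0.03, 0.04))
  expect_equal(got$p_adjusted, c(0.004, 0.02, 0.04, 0.04))

  expect_equal(bh_adjust(1)$p_adjusted, 1)
  expect_false(bh_adjust(1)$significant)
  expect_equal(bh_adjust(rep(0.007, 5))$p_adjusted, rep(0.007, 5))
  expect_true(all(bh_adjust(rep(0.007, 5))$significant))

  set.seed(53)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))^2
    adj <- bh_adjust(p)$p_adjusted
    expect_equal(adj, bh_naive(p))
    # monotone non-decreasing in the raw p
    o <- order(p)
    expect_true(all(diff(adj[o]) >= 0))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the enrichment matrix is ordered, capped and jointly adjusted", {
  annot <- rbind(
    make_annot(rep("VA", 40), rep(c("lncRNA", "protein_coding"), c(30, 10)),
               rep(c("lincRNA", "none"), c(30, 10))),
    make_annot(rep("VB", 60), rep(c("lncRNA", "protein_coding"), c(5, 55)),
               rep(c("lincRNA", "none"), c(5, 55)))
  )
  attr(annot, "n_integrations") <- 100
  class(annot) <- c("genetrap_annotation", "data.frame")
  em <- enrichment_matrix(annot, "major_class", fdr = 0.01)
  expect_equal(rownames(em$neg_log10_adj), c("VB", "VA"))  # by descending total
  expect_equal(colnames(em$neg_log10_adj), c("protein_coding", "lncRNA"))
  expect_equal(em$neg_log10_adj[cbind(em$cells$vector_id, em$cells$biotype_label)],
               unname(pmin(-log10(em$cells$p_adjusted), 300)))
  expect_equal(em$cells$p_adjusted, bh_naive(em$cells$p_value))
  expect_true(em$cells$significant[em$cells$vector_id == "VA" &
                                     em$cells$biotype_label == "lncRNA"])
  # underflow cap
  expect_true(all(is.finite(em$neg_log10_adj)))

  # a single biotype label cannot form a matrix
  one <- rbind(make_annot(c("V1", "V2"), "protein_coding"))
  attr(one, "n_integrations") <- 2
  class(one) <- c("genetrap_annotation", "data.frame")
  expect_error(enrichment_matrix(one, "major_class"), "two biotype")
})

test_that("subclass-level cells keep every annotated hit in the universe", {
  annot <- rbind(
    make_annot(rep("VA", 6), rep("lncRNA", 6),
               rep(c("lincRNA", "antisense"), c(4, 2))),
    make_annot(rep("VB", 14), rep(c("lncRNA", "protein_coding"), c(4, 10)),
               rep(c("antisense", "none"), c(4, 10)))
  )
  attr(annot, "n_integrations") <- 20
  class(annot) <- c("genetrap_annotation", "data.frame")
  cells <- build_tables(annot, "lnc_subclass")
  # cells exist only for lncRNA subclasses, but protein-coding hits stay in
  # the margins: the grand total is all 20 annotated integrations
  expect_setequal(unique(cells$biotype_label), c("lincRNA", "antisense"))
  expect_true(all(cells$a + cells$b + cells$c + cells$d == 20))
  va_linc <- cells[cells$vector_id == "VA" & cells$biotype_label == "lincRNA", ]
  expect_equal(unlist(va_linc[c("a", "b", "c", "d")], use.names = FALSE),
               c(4, 2, 0, 14))
})
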