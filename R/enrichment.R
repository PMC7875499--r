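#' Build 2x2 contingency tables for vector-by-biotype enrichment
#'
#' For each (vector, biotype label) pair forms the table
#' \preformatted{  a = integrations of this vector in this biotype
#'   b = integrations of this vector in all other biotypes
#'   c = integrations of all other vectors in this biotype
#'   d = integrations of all other vectors elsewhere}
#' over primary, non-intergenic hits. The universe is always the annotated
#' integrations in classified genes; the level only chooses the cell labels:
#' the four major classes, or the lncRNA subclasses (TEC included), in which
#' case `b`/`d` still count the vector's integrations in every other biotype
#' including protein-coding genes.
#'
#' @param annot a `genetrap_annotation`.
#' @param level `"major_class"` or `"lnc_subclass"`.
#' @return data.frame of cells: `vector_id`, `biotype_label`, `a`, `b`,
#'   `c`, `d`.
#' @export
build_tables <- function(annot, level = c("major_class", "lnc_subclass")) {
  level <- match.arg(level)
  hits <- annot[!annot$intergenic & annot$primary &
                  annot$major_class %in% major_class_levels(), , drop = FALSE]
  hits$biotype_label <- if (level == "major_class") hits$major_class else
    ifelse(hits$major_class == "lncRNA", hits$lnc_subclass, hits$major_class)
  vectors <- sort(unique(annot$vector_id))
  if (length(vectors) < 2) {
    data_error("comparison group empty: enrichment needs at least two vectors")
  }
  cell_labels <- if (level == "major_class") {
    sort(unique(hits$biotype_label))
  } else {
    sort(unique(hits$lnc_subclass[hits$major_class == "lncRNA"]))
  }
  if (length(unique(hits$biotype_label)) < 2 || length(cell_labels) < 1) {
    data_error("enrichment needs at least two biotype labels among annotated integrations")
  }
  counts <- table(factor(hits$vector_id, levels = vectors),
                  factor(hits$biotype_label,
                         levels = unique(c(cell_labels,
                                           sort(unique(hits$biotype_label))))))
  grand <- sum(counts)
  vec_tot <- rowSums(counts)
  bio_tot <- colSums(counts)
  cells <- expand.grid(vector_id = vectors, biotype_label = cell_labels,
                       stringsAsFactors = FALSE)
  cells$a <- as.integer(counts[cbind(cells$vector_id, cells$biotype_label)])
  cells$b <- as.integer(vec_tot[cells$vector_id] - cells$a)
  cells$c <- as.integer(bio_tot[cells$biotype_label] - cells$a)
  cells$d <- as.integer(grand - cells$a - cells$b - cells$c)
  cells
}

#' One-sided Fisher's exact test for over-representation
#'
#' Exact upper-tail hypergeometric probability
#' `p = P(X >= a)` with margins fixed, i.e. the one-sided
#' (`alternative = "greater"`) Fisher test on the 2x2 table
#' `[[a, b], [c, d]]`. Vectorised over tables.
#'
#' @param a,b,c,d nonnegative integer cell counts (recycled).
#' @return numeric vector of p-values.
#' @export
fisher_one_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) data_error("negative cell count")
  if (any(a + b + c + d == 0)) data_error("empty 2x2 table")
  # X ~ Hypergeometric(white = a + c, black = b + d, drawn = a + b)
  stats::phyper(a - 1, a + c, b + d, a + b, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment with an FDR significance flag
#'
#' Step-up adjusted p-values `q_(i) = min_{j >= i} m * p_(j) / j`, clipped
#' to 1 and mapped back to input order; a cell is significant when its
#' adjusted p-value does not exceed the FDR constraint.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @param fdr false-discovery-rate constraint (default 0.01).
#' @return list with `p_adjusted` and logical `significant`.
#' @export
bh_adjust <- function(p, fdr = 0.01) {
  stopifnot(length(p) >= 1)
  if (any(p < 0 | p > 1)) data_error("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p, method = "BH")
  list(p_adjusted = adj, significant = adj <= fdr)
}

#' Vector-by-biotype enrichment matrix
#'
#' Runs [build_tables()], tests every cell for over-representation with
#' [fisher_one_sided()], adjusts all cells jointly with [bh_adjust()], and
#' assembles the `-log10(adjusted p)` matrix (capped at 300 where the
#' adjusted p underflows to zero). Rows (vectors) are ordered by descending
#' integration total, columns (biotypes) in the canonical class order.
#'
#' @param annot a `genetrap_annotation`.
#' @param level `"major_class"` or `"lnc_subclass"`.
#' @param fdr false-discovery-rate constraint (default 0.01).
#' @param cap cap for `-log10(adjusted p)` (default 300).
#' @return object of class `enrichment_matrix`: list with `cells` (long
#'   data.frame incl. `odds_ratio`, `p_value`, `p_adjusted`, `significant`)
#'   and `neg_log10_adj` (vectors x biotypes matrix).
#' @export
enrichment_matrix <- function(annot, level = c("major_class", "lnc_subclass"),
                              fdr = 0.01, cap = 300) {
  level <- match.arg(level)
  if (fdr <= 0 || fdr >= 1) config_error("fdr must lie in (0, 1)")
  cells <- build_tables(annot, level)
  cells$odds_ratio <- with(cells, (a * d) / (b * c))
  cells$p_value <- fisher_one_sided(cells$a, cells$b, cells$c, cells$d)
  adj <- bh_adjust(cells$p_value, fdr = fdr)
  cells$p_adjusted <- adj$p_adjusted
  cells$significant <- adj$significant

  canon <- if (level == "major_class") major_class_levels() else lnc_subclass_levels()
  labels <- c(intersect(canon, unique(cells$biotype_label)),
              setdiff(sort(unique(cells$biotype_label)), canon))
  vec_tot <- tapply(cells$a + cells$b, cells$vector_id, max)
  vectors <- names(vec_tot)[order(-vec_tot, names(vec_tot))]

  m <- matrix(NA_real_, length(vectors), length(labels),
              dimnames = list(vectors, labels))
  m[cbind(cells$vector_id, cells$biotype_label)] <-
    pmin(-log10(cells$p_adjusted), cap)

  cells <- cells[order(match(cells$vector_id, vectors),
                       match(cells$biotype_label, labels)), , drop = FALSE]
  rownames(cells) <- NULL
  structure(list(cells = cells, neg_log10_adj = m, level = level, fdr = fdr),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat("enrichment_matrix (", x$level, " level): ",
      nrow(x$neg_log10_adj), " vectors x ", ncol(x$neg_log10_adj),
      " biotypes; ", sum(x$cells$significant), " significant at FDR ",
      x$fdr, "\n", sep = "")
  print(round(x$neg_log10_adj, 2))
  invisible(x)
}

#' Write enrichment results
#'
#' @param x an `enrichment_matrix`.
#' @param long_path TSV path for the long cell table.
#' @param matrix_path optional TSV path for the wide `-log10(adjusted p)`
#'   matrix (rows = vectors).
#' @return paths written, invisibly.
#' @export
write_enrichment <- function(x, long_path, matrix_path = NULL) {
  stopifnot(inherits(x, "enrichment_matrix"))
  write_tsv(x$cells, long_path)
  if (!is.null(matrix_path)) {
    wide <- data.frame(vector_id = rownames(x$neg_log10_adj),
                       x$neg_log10_adj, check.names = FALSE)
    write_tsv(wide, matrix_path)
  }
  invisible(c(long_path, matrix_path))
}
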