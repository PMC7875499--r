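#' Biotype census table from trapped-gene counts
#'
#' Pure report layer: takes per-class counts (from [census_report()] or any
#' other source, e.g. a published table) and derives the percentage columns.
#' `pct_of_trapped` is each class's share of all trapped genes;
#' `pct_of_annotated` the trapped fraction of the annotated gene census.
#' Percentages are rounded half-up at the requested precision; inputs stay
#' untouched.
#'
#' @param trapped_genes named numeric vector: unique trapped genes per
#'   major class.
#' @param n_integrations optional named numeric vector of integration counts
#'   per class.
#' @param annotated optional named numeric vector: annotated genes per class
#'   (the reference census). Classes without a census value get `NA` with a
#'   warning.
#' @param digits decimal places for percentages (default 1).
#' @return data.frame with one row per class plus a `total` row.
#' @export
biotype_census <- function(trapped_genes, n_integrations = NULL,
                           annotated = NULL, digits = 1) {
  stopifnot(!is.null(names(trapped_genes)), all(trapped_genes >= 0))
  classes <- names(trapped_genes)
  total <- sum(trapped_genes)
  pct_tr <- if (total > 0) round_half_up(100 * trapped_genes / total, digits)
            else rep(NA_real_, length(classes))
  ann <- if (is.null(annotated)) rep(NA_real_, length(classes))
         else unname(annotated[classes])
  if (!is.null(annotated) && anyNA(ann)) {
    warning("annotated census missing for class(es): ",
            paste(classes[is.na(ann)], collapse = ", "),
            "; pct_of_annotated left NA")
  }
  pct_ann <- ifelse(is.na(ann) | ann == 0, NA_real_,
                    round_half_up(100 * trapped_genes / ann, digits))
  ints <- if (is.null(n_integrations)) rep(NA_real_, length(classes))
          else unname(n_integrations[classes])
  out <- data.frame(class = classes,
                    n_annotated = ann,
                    n_trapped_genes = unname(trapped_genes),
                    n_integrations = ints,
                    pct_of_trapped = unname(pct_tr),
                    pct_of_annotated = pct_ann,
                    stringsAsFactors = FALSE)
  rbind(out, data.frame(class = "total", n_annotated = sum(ann),
                        n_trapped_genes = total,
                        n_integrations = if (all(is.na(ints))) NA else sum(ints),
                        pct_of_trapped = if (total > 0) 100 else NA_real_,
                        pct_of_annotated = NA_real_))
}

# unique trapped genes and (gene, cell line)-deduplicated integration counts
# over ALL hits (not only primary), grouped by an arbitrary label column
trapped_counts <- function(annot, label_col, levels = NULL) {
  hits <- annot[!annot$intergenic, , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$gene_id, hits$cell_line_id)), , drop = FALSE]
  lab <- hits[[label_col]]
  if (is.null(levels)) levels <- sort(unique(lab))
  genes <- vapply(levels, function(l) length(unique(hits$gene_id[lab == l])), 0L)
  ints <- vapply(levels, function(l) sum(lab == l), 0L)
  list(genes = stats::setNames(genes, levels),
       integrations = stats::setNames(ints, levels))
}

#' Biotype census report from an annotation table
#'
#' Counts distinct trapped genes and (gene, cell line)-deduplicated
#' integrations per major biotype class over all gene hits (an insertion in
#' two overlapping genes is evidence for both loci), then formats the census
#' with [biotype_census()]. The annotated-gene column comes from the loaded
#' annotation when `ann` is given, otherwise from the taxonomy census.
#'
#' @param annot a `genetrap_annotation`.
#' @param ann optional `annotation_set`: count annotated genes per class
#'   from it.
#' @param taxonomy optional [biotype_taxonomy()] supplying the reference
#'   census when `ann` is absent.
#' @param digits decimal places for percentages.
#' @return data.frame as from [biotype_census()].
#' @export
census_report <- function(annot, ann = NULL, taxonomy = NULL, digits = 1) {
  lv <- major_class_levels()
  tc <- trapped_counts(annot, "major_class", lv)
  annotated <- if (!is.null(ann)) {
    gene_class_counts(ann)[lv]
  } else if (!is.null(taxonomy)) {
    taxonomy$census$major
  } else {
    NULL
  }
  biotype_census(tc$genes, tc$integrations, annotated, digits)
}

#' ncRNA subclass report
#'
#' Distinct trapped genes per lncRNA subclass, overall and per vector class,
#' with the combined lincRNA + antisense share of all trapped lncRNA genes
#' (the two most prevalent subclasses) attached as attributes.
#'
#' @param annot a `genetrap_annotation`.
#' @param digits decimal places for the share.
#' @return data.frame, one row per observed subclass with a column per
#'   vector class and a `total` column; attributes `linc_antisense_n`,
#'   `lnc_total` and `linc_antisense_pct`.
#' @export
ncrna_subclass_report <- function(annot, digits = 1) {
  hits <- annot[!annot$intergenic & annot$major_class %in% "lncRNA", , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$gene_id, hits$cell_line_id)), , drop = FALSE]
  subs <- intersect(lnc_subclass_levels(), unique(hits$lnc_subclass))
  if (nrow(hits) == 0 || length(subs) == 0) {
    out <- data.frame(lnc_subclass = character(), total = integer())
    attr(out, "linc_antisense_n") <- 0L
    attr(out, "lnc_total") <- 0L
    attr(out, "linc_antisense_pct") <- NA_real_
    return(out)
  }
  vcs <- sort(unique(hits$vector_class))
  out <- data.frame(lnc_subclass = subs, stringsAsFactors = FALSE)
  for (vc in vcs) {
    sel <- hits$vector_class == vc
    out[[vc]] <- vapply(subs, function(s) {
      length(unique(hits$gene_id[sel & hits$lnc_subclass == s]))
    }, 0L)
  }
  out$total <- vapply(subs, function(s) {
    length(unique(hits$gene_id[hits$lnc_subclass == s]))
  }, 0L)
  lnc_total <- length(unique(hits$gene_id))
  la <- sum(out$total[out$lnc_subclass %in% c("lincRNA", "antisense")])
  attr(out, "linc_antisense_n") <- la
  attr(out, "lnc_total") <- lnc_total
  attr(out, "linc_antisense_pct") <-
    if (lnc_total > 0) round_half_up(100 * la / lnc_total, digits) else NA_real_
  out
}

#' Spliced vs non-spliced host report
#'
#' Per vector class and major gene class: the fraction of integrations
#' (primary hits) whose host gene is non-spliced (single exon in every
#' transcript). Splice-acceptor vectors depend on host splicing for
#' activation, so this fraction is diagnostic of vector design.
#'
#' @param annot a `genetrap_annotation`.
#' @param digits decimal places for the percentage.
#' @return data.frame: `vector_class`, `gene_class`, `n`, `n_nonspliced`,
#'   `pct_nonspliced`.
#' @export
spliced_report <- function(annot, digits = 1) {
  hits <- annot[!annot$intergenic & annot$primary &
                  annot$major_class %in% major_class_levels(), , drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(vector_class = character(), gene_class = character(),
                      n = integer(), n_nonspliced = integer(),
                      pct_nonspliced = numeric()))
  }
  agg <- expand.grid(vector_class = sort(unique(hits$vector_class)),
                     gene_class = intersect(major_class_levels(),
                                            unique(hits$major_class)),
                     stringsAsFactors = FALSE)
  agg$n <- mapply(function(vc, gc) {
    sum(hits$vector_class == vc & hits$major_class == gc)
  }, agg$vector_class, agg$gene_class)
  agg$n_nonspliced <- mapply(function(vc, gc) {
    sum(hits$vector_class == vc & hits$major_class == gc & !hits$host_spliced)
  }, agg$vector_class, agg$gene_class)
  agg$pct_nonspliced <- ifelse(agg$n > 0,
                               round_half_up(100 * agg$n_nonspliced / agg$n,
                                             digits), NA_real_)
  rownames(agg) <- NULL
  agg
}
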