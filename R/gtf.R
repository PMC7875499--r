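#' Build an annotation set from gene and exon tables
#'
#' Internal constructor shared by [read_gtf()] and [generate_annotation()].
#' Coordinates are 0-based half-open throughout the package; GTF I/O converts
#' at the boundary.
#'
#' @param genes data.frame with columns `gene_id`, `symbol`, `chrom`,
#'   `start`, `end` (0-based half-open), `strand`, `raw_biotype`.
#' @param exons data.frame with columns `gene_id`, `transcript_id`,
#'   `start`, `end` (0-based half-open).
#' @param taxonomy a [biotype_taxonomy()].
#' @return object of class `annotation_set`.
#' @keywords internal
as_annotation_set <- function(genes, exons, taxonomy = biotype_taxonomy()) {
  stopifnot(is.data.frame(genes), is.data.frame(exons))
  if (anyDuplicated(genes$gene_id)) {
    data_error("duplicate gene_id in annotation: ",
               genes$gene_id[duplicated(genes$gene_id)][1])
  }
  if (nrow(genes) > 0) {
    stopifnot(all(genes$start < genes$end), all(genes$strand %in% c("+", "-")))
  }
  if (nrow(exons) > 0) {
    stopifnot(all(exons$start < exons$end),
              all(exons$gene_id %in% genes$gene_id))
    # transcripts must lie within their gene span
    tx_start <- tapply(exons$start, exons$transcript_id, min)
    tx_end <- tapply(exons$end, exons$transcript_id, max)
    tx_gene <- exons$gene_id[match(names(tx_start), exons$transcript_id)]
    gi <- match(tx_gene, genes$gene_id)
    if (any(tx_start < genes$start[gi] | tx_end > genes$end[gi])) {
      warning("transcript(s) extend beyond their gene span; expanding gene span")
      lo <- tapply(tx_start, tx_gene, min)
      hi <- tapply(tx_end, tx_gene, max)
      gj <- match(names(lo), genes$gene_id)
      genes$start[gj] <- pmin(genes$start[gj], as.integer(lo))
      genes$end[gj] <- pmax(genes$end[gj], as.integer(hi))
    }
  }

  cls <- classify_biotype(genes$raw_biotype, taxonomy)
  genes$major_class <- cls$major_class
  genes$lnc_subclass <- cls$lnc_subclass

  # spliced iff any single transcript has >= 2 exons
  if (nrow(exons) > 0) {
    ex_per_tx <- table(exons$transcript_id)
    spliced_tx <- names(ex_per_tx)[ex_per_tx >= 2]
    spliced_genes <- unique(exons$gene_id[exons$transcript_id %in% spliced_tx])
    genes$spliced <- genes$gene_id %in% spliced_genes
  } else {
    genes$spliced <- logical(nrow(genes))
  }
  rownames(genes) <- NULL
  rownames(exons) <- NULL

  obj <- list(genes = genes, exons = exons, taxonomy = taxonomy)
  obj$index <- if (nrow(genes) > 0) {
    GenomicRanges::GRanges(genes$chrom,
                           IRanges::IRanges(genes$start + 1L, genes$end),
                           gene_id = genes$gene_id)
  } else {
    GenomicRanges::GRanges()
  }
  obj$exon_index <- if (nrow(exons) > 0) {
    GenomicRanges::GRanges(genes$chrom[match(exons$gene_id, genes$gene_id)],
                           IRanges::IRanges(exons$start + 1L, exons$end),
                           gene_id = exons$gene_id)
  } else {
    GenomicRanges::GRanges()
  }
  class(obj) <- "annotation_set"
  obj
}

#' Read gene models from a GTF file
#'
#' Accepts any Ensembl-dialect GTF carrying gene, transcript and exon records
#' with `gene_id`, `transcript_id` and a biotype attribute (either
#' `gene_biotype` or `gene_type`). GTF 1-based closed coordinates are
#' converted to the package's internal 0-based half-open convention. Genes
#' whose biotype is absent from the taxonomy are retained and flagged
#' `unclassified`; genes with no exon record in any transcript are rejected
#' and listed in the `rejected` attribute.
#'
#' @param path GTF file path.
#' @param taxonomy a [biotype_taxonomy()].
#' @return an `annotation_set`: gene table, exon table, taxonomy and
#'   chromosome-keyed interval indexes for point-overlap queries.
#' @export
read_gtf <- function(path, taxonomy = biotype_taxonomy()) {
  if (!file.exists(path)) data_error("GTF file not found: ", path)
  lines <- readLines(path)
  body <- !grepl("^#", lines) & nzchar(trimws(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 9)) {
    data_error(sprintf("malformed GTF line %d: expected 9 tab-separated fields, found %d",
                       which(body)[which(nf < 9)[1]], nf[nf < 9][1]))
  }
  if (!any(body)) {
    return(as_annotation_set(
      data.frame(gene_id = character(), symbol = character(),
                 chrom = character(), start = integer(), end = integer(),
                 strand = character(), raw_biotype = character(),
                 stringsAsFactors = FALSE),
      data.frame(gene_id = character(), transcript_id = character(),
                 start = integer(), end = integer(), stringsAsFactors = FALSE),
      taxonomy))
  }

  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  bt_col <- intersect(c("gene_biotype", "gene_type"), names(mc))
  if (length(bt_col) == 0) {
    data_error("GTF lacks a biotype attribute (gene_biotype or gene_type)")
  }
  biotype <- as.character(mc[[bt_col[1]]])
  type <- as.character(mc$type)
  gene_id <- as.character(mc$gene_id)

  is_gene <- type == "gene"
  if (any(is_gene)) {
    genes <- data.frame(
      gene_id = gene_id[is_gene],
      symbol = if ("gene_name" %in% names(mc))
        as.character(mc$gene_name[is_gene]) else gene_id[is_gene],
      chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
      start = GenomicRanges::start(gr)[is_gene] - 1L,
      end = GenomicRanges::end(gr)[is_gene],
      strand = as.character(GenomicRanges::strand(gr))[is_gene],
      raw_biotype = biotype[is_gene],
      stringsAsFactors = FALSE
    )
  } else {
    # no explicit gene records: derive spans from the union of a gene's records
    sp <- split(seq_along(gr), gene_id)
    genes <- data.frame(
      gene_id = names(sp),
      symbol = names(sp),
      chrom = vapply(sp, function(i) as.character(GenomicRanges::seqnames(gr))[i[1]], ""),
      start = vapply(sp, function(i) min(GenomicRanges::start(gr)[i]), 0L) - 1L,
      end = vapply(sp, function(i) max(GenomicRanges::end(gr)[i]), 0L),
      strand = vapply(sp, function(i) as.character(GenomicRanges::strand(gr))[i[1]], ""),
      raw_biotype = vapply(sp, function(i) biotype[i[1]], ""),
      stringsAsFactors = FALSE
    )
  }
  genes$symbol[is.na(genes$symbol)] <- genes$gene_id[is.na(genes$symbol)]

  is_exon <- type == "exon"
  exons <- data.frame(
    gene_id = gene_id[is_exon],
    transcript_id = as.character(mc$transcript_id[is_exon]),
    start = GenomicRanges::start(gr)[is_exon] - 1L,
    end = GenomicRanges::end(gr)[is_exon],
    stringsAsFactors = FALSE
  )

  rejected <- character(0)
  bad_strand <- !genes$strand %in% c("+", "-")
  if (any(bad_strand)) {
    rejected <- c(rejected, genes$gene_id[bad_strand])
    message("rejected ", sum(bad_strand), " gene(s) with undefined strand")
    genes <- genes[!bad_strand, , drop = FALSE]
  }
  no_exon <- !genes$gene_id %in% exons$gene_id
  if (any(no_exon)) {
    rejected <- c(rejected, genes$gene_id[no_exon])
    message("rejected ", sum(no_exon), " gene(s) with zero exons: ",
            paste(utils::head(genes$gene_id[no_exon], 5), collapse = ", "))
    genes <- genes[!no_exon, , drop = FALSE]
  }
  exons <- exons[exons$gene_id %in% genes$gene_id, , drop = FALSE]

  ann <- as_annotation_set(genes, exons, taxonomy)
  attr(ann, "rejected") <- rejected
  ann
}

#' Write an annotation set to GTF
#'
#' Emits gene, transcript and exon records with `gene_id`, `gene_name` and
#' `gene_biotype` attributes, converting internal 0-based half-open
#' coordinates back to GTF's 1-based closed convention. Output is
#' byte-deterministic for a given annotation set.
#'
#' @param ann an `annotation_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  g <- ann$genes
  e <- ann$exons
  fmt <- function(chrom, feat, start0, end0, strand, attrs) {
    sprintf("%s\tgenetrapr\t%s\t%d\t%d\t.\t%s\t.\t%s",
            chrom, feat, start0 + 1L, end0, strand, attrs)
  }
  out <- character(0)
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    ga <- sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
                  gid, g$symbol[i], g$raw_biotype[i])
    out <- c(out, fmt(g$chrom[i], "gene", g$start[i], g$end[i], g$strand[i], ga))
    ex <- e[e$gene_id == gid, , drop = FALSE]
    for (tid in unique(ex$transcript_id)) {
      tex <- ex[ex$transcript_id == tid, , drop = FALSE]
      tex <- tex[order(tex$start), , drop = FALSE]
      ta <- sprintf('%s transcript_id "%s";', ga, tid)
      out <- c(out, fmt(g$chrom[i], "transcript", min(tex$start), max(tex$end),
                        g$strand[i], ta))
      for (j in seq_len(nrow(tex))) {
        out <- c(out, fmt(g$chrom[i], "exon", tex$start[j], tex$end[j],
                          g$strand[i], ta))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Is a gene spliced?
#'
#' A gene counts as spliced iff at least one of its transcripts has two or
#' more exons; two single-exon transcripts at different positions do not
#' make a spliced gene. Single-exon (non-spliced) hosts matter because most
#' gene-trap vectors are activated by splicing into the reporter.
#'
#' @param ann an `annotation_set`.
#' @param gene_id gene identifier(s); default all genes.
#' @return named logical vector.
#' @export
is_spliced <- function(ann, gene_id = NULL) {
  stopifnot(inherits(ann, "annotation_set"))
  g <- ann$genes
  if (is.null(gene_id)) gene_id <- g$gene_id
  idx <- match(gene_id, g$gene_id)
  if (anyNA(idx)) data_error("unknown gene_id: ", gene_id[is.na(idx)][1])
  stats::setNames(g$spliced[idx], gene_id)
}

#' Count genes per major biotype class
#'
#' @param ann an `annotation_set`.
#' @return named integer vector over the major classes plus `unclassified`.
#' @export
gene_class_counts <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  lv <- c(major_class_levels(), "unclassified")
  tab <- table(factor(ann$genes$major_class, levels = lv))
  stats::setNames(as.integer(tab), lv)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$genes), "genes on",
      length(unique(x$genes$chrom)), "chromosome(s)\n")
  cc <- gene_class_counts(x)
  cc <- cc[cc > 0]
  if (length(cc)) {
    cat(paste(sprintf("  %s: %d", names(cc), cc), collapse = "\n"), "\n")
  }
  invisible(x)
}
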