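#' Position of an insertion relative to the transcription start site
#'
#' Returns the insertion point's fractional distance from the TSS along the
#' gene span, in `[0, 1)`. For a plus-strand gene this is
#' `(position - start) / (end - start)`; for a minus-strand gene
#' `(end - 1 - position) / (end - start)`, so that 0 is always the TSS end.
#'
#' @param position 0-based insertion point(s), must satisfy
#'   `start <= position < end`.
#' @param start,end gene span, 0-based half-open.
#' @param strand `"+"` or `"-"` (recycled).
#' @return numeric vector in `[0, 1)`.
#' @export
relative_position <- function(position, start, end, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  if (any(position < start | position >= end)) {
    data_error("position outside the gene span")
  }
  len <- end - start
  ifelse(strand == "+", (position - start) / len, (end - 1 - position) / len)
}

decile_of <- function(relative_position) {
  as.integer(floor(relative_position * 10)) + 1L
}

#' Classify the gene-trap activation mechanism
#'
#' Total rule table mapping the structural context of an insertion to the
#' mechanism by which the gene-trap reporter is activated, in precedence
#' order:
#' \enumerate{
#'   \item intergenic insertions activate from non-annotated regions
#'     (`intergenic_activation`);
#'   \item antisense insertions transcribe the reporter opposite to the host
#'     (`antisense_insertion`);
#'   \item sense insertions in a bidirectional-promoter lncRNA are driven by
#'     the shared divergent promoter (`bidirectional_promoter_capture`);
#'   \item sense insertions in a sense-overlapping lncRNA truncate the host
#'     read-through transcript (`host_readthrough_truncation`);
#'   \item sense insertions in a single-exon host cannot be activated by
#'     splicing (`unspliced_insertion`) — this outranks the vector-class
#'     rules because both splice-acceptor and polyA-trap activation need a
#'     splicing partner;
#'   \item otherwise a polyA trap incorporates itself as a portable exon
#'     (`polyA_exon_capture`) and every splice-acceptor-bearing class forms
#'     an upstream fusion transcript (`sense_splice_fusion`).
#' }
#'
#' @param strand_relation `"sense"` or `"antisense"` (NA for intergenic).
#' @param host_spliced logical; does the host gene have a multi-exon
#'   transcript (NA for intergenic).
#' @param lnc_subclass host lncRNA subclass or `"none"` (NA for intergenic).
#' @param vector_class one of `r paste(vector_classes(), collapse = ", ")`.
#' @param intergenic logical; no host gene at the insertion point.
#' @return character vector of mechanism labels.
#' @export
classify_mechanism <- function(strand_relation, host_spliced, lnc_subclass,
                               vector_class, intergenic) {
  n <- max(lengths(list(strand_relation, host_spliced, lnc_subclass,
                        vector_class, intergenic)))
  strand_relation <- rep_len(strand_relation, n)
  host_spliced <- rep_len(host_spliced, n)
  lnc_subclass <- rep_len(lnc_subclass, n)
  vector_class <- rep_len(vector_class, n)
  intergenic <- rep_len(intergenic, n)

  out <- character(n)
  out[intergenic] <- "intergenic_activation"
  g <- !intergenic
  anti <- g & strand_relation == "antisense"
  out[anti] <- "antisense_insertion"
  sense <- g & strand_relation == "sense"
  bp <- sense & lnc_subclass == "bidirectional_promoter"
  out[bp] <- "bidirectional_promoter_capture"
  so <- sense & lnc_subclass == "sense_overlapping" & !bp
  out[so] <- "host_readthrough_truncation"
  rest <- sense & !bp & !so
  out[rest & !host_spliced] <- "unspliced_insertion"
  out[rest & host_spliced & vector_class == "polyA_trap"] <- "polyA_exon_capture"
  out[rest & host_spliced & vector_class != "polyA_trap"] <- "sense_splice_fusion"
  out
}

#' Annotate integrations against an annotation set
#'
#' Maps every integration to the gene(s) whose span contains its insertion
#' point. For each (integration, gene) hit the relative position from the
#' TSS, decile (1-10), exon/intron context (tested against the union of the
#' gene's exons over all transcripts), strand relation, spliced-host flag
#' and activation mechanism are computed. Integrations contained in no gene
#' span are annotated intergenic. Among several overlapping hits a primary
#' hit is chosen: sense-strand hits first, then the smallest gene span, then
#' the lexicographically smallest `gene_id`.
#'
#' Tags without a reported strand are treated as sense by convention and
#' flagged in the `strand_imputed` column. Integrations on chromosomes
#' absent from the annotation are annotated intergenic with a warning.
#'
#' @param integrations integration data.frame from [filter_tags()].
#' @param ann an `annotation_set`.
#' @return data.frame of class `genetrap_annotation`: one row per hit plus
#'   one row per intergenic integration.
#' @export
annotate_integrations <- function(integrations, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  req <- c("cell_line_id", "vector_id", "vector_class", "chrom", "position",
           "tag_strand")
  stopifnot(all(req %in% names(integrations)))
  n <- nrow(integrations)
  g <- ann$genes

  known_chroms <- unique(g$chrom)
  off <- !is.na(integrations$chrom) & !(integrations$chrom %in% known_chroms)
  if (any(off)) {
    warning(sum(off), " integration(s) on chromosome(s) absent from the ",
            "annotation; annotated intergenic")
  }

  hit_int <- integer(0)
  hit_gene <- integer(0)
  if (n > 0 && nrow(g) > 0) {
    lv <- union(known_chroms, unique(integrations$chrom[!is.na(integrations$chrom)]))
    qry <- GenomicRanges::GRanges(
      factor(integrations$chrom, levels = lv),
      IRanges::IRanges(integrations$position + 1L, integrations$position + 1L))
    subj <- GenomicRanges::GRanges(factor(g$chrom, levels = lv),
                                   IRanges::IRanges(g$start + 1L, g$end))
    ov <- GenomicRanges::findOverlaps(qry, subj, ignore.strand = TRUE)
    hit_int <- S4Vectors::queryHits(ov)
    hit_gene <- S4Vectors::subjectHits(ov)
  }

  strand_imputed <- is.na(integrations$tag_strand) | integrations$tag_strand == ""
  eff_strand <- integrations$tag_strand

  hits <- data.frame(
    cell_line_id = integrations$cell_line_id[hit_int],
    vector_id = integrations$vector_id[hit_int],
    vector_class = integrations$vector_class[hit_int],
    chrom = integrations$chrom[hit_int],
    position = integrations$position[hit_int],
    tag_strand = integrations$tag_strand[hit_int],
    strand_imputed = strand_imputed[hit_int],
    intergenic = logical(length(hit_int)),
    gene_id = g$gene_id[hit_gene],
    symbol = g$symbol[hit_gene],
    raw_biotype = g$raw_biotype[hit_gene],
    major_class = g$major_class[hit_gene],
    lnc_subclass = g$lnc_subclass[hit_gene],
    stringsAsFactors = FALSE
  )
  if (nrow(hits) > 0) {
    gs <- g$start[hit_gene]; ge <- g$end[hit_gene]; gstr <- g$strand[hit_gene]
    hits$relative_position <- relative_position(hits$position, gs, ge, gstr)
    hits$decile <- decile_of(hits$relative_position)
    hits$strand_relation <- ifelse(hits$strand_imputed, "sense",
                                   ifelse(hits$tag_strand == gstr,
                                          "sense", "antisense"))
    hits$host_spliced <- g$spliced[hit_gene]
    hits$span <- ge - gs

    # exon membership against the union of the gene's exons
    in_exon <- rep(FALSE, nrow(hits))
    if (length(ann$exon_index) > 0) {
      lv <- union(unique(g$chrom), unique(hits$chrom))
      eq <- GenomicRanges::GRanges(factor(hits$chrom, levels = lv),
                                   IRanges::IRanges(hits$position + 1L,
                                                    hits$position + 1L))
      ex <- ann$exons
      es <- GenomicRanges::GRanges(
        factor(g$chrom[match(ex$gene_id, g$gene_id)], levels = lv),
        IRanges::IRanges(ex$start + 1L, ex$end),
        gene_id = ex$gene_id)
      eov <- GenomicRanges::findOverlaps(eq, es, ignore.strand = TRUE)
      key_hit <- paste(S4Vectors::queryHits(eov),
                       S4Vectors::mcols(es)$gene_id[S4Vectors::subjectHits(eov)])
      in_exon <- paste(seq_len(nrow(hits)), hits$gene_id) %in% key_hit
    }
    hits$region <- ifelse(in_exon, "exon", "intron")

    # primary hit: sense first, then smallest span, then gene_id
    ord <- order(hits$cell_line_id, hits$strand_relation != "sense",
                 hits$span, hits$gene_id)
    hits <- hits[ord, , drop = FALSE]
    hits$primary <- !duplicated(hits$cell_line_id)
    hits$span <- NULL
  } else {
    hits$relative_position <- numeric(0)
    hits$decile <- integer(0)
    hits$strand_relation <- character(0)
    hits$host_spliced <- logical(0)
    hits$region <- character(0)
    hits$primary <- logical(0)
  }

  inter_idx <- setdiff(seq_len(n), unique(hit_int))
  k <- length(inter_idx)
  inter <- data.frame(
    cell_line_id = integrations$cell_line_id[inter_idx],
    vector_id = integrations$vector_id[inter_idx],
    vector_class = integrations$vector_class[inter_idx],
    chrom = integrations$chrom[inter_idx],
    position = integrations$position[inter_idx],
    tag_strand = integrations$tag_strand[inter_idx],
    strand_imputed = strand_imputed[inter_idx],
    intergenic = rep(TRUE, k),
    gene_id = rep(NA_character_, k), symbol = rep(NA_character_, k),
    raw_biotype = rep(NA_character_, k), major_class = rep(NA_character_, k),
    lnc_subclass = rep(NA_character_, k),
    relative_position = rep(NA_real_, k), decile = rep(NA_integer_, k),
    strand_relation = rep(NA_character_, k), host_spliced = rep(NA, k),
    region = rep(NA_character_, k), primary = rep(FALSE, k),
    stringsAsFactors = FALSE
  )

  out <- rbind(hits, inter)
  out$mechanism <- classify_mechanism(out$strand_relation, out$host_spliced,
                                      out$lnc_subclass, out$vector_class,
                                      out$intergenic)
  out <- out[order(out$cell_line_id, !out$primary, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_integrations") <- n
  class(out) <- c("genetrap_annotation", "data.frame")
  out
}

#' Summarise an annotation table
#'
#' @param object a `genetrap_annotation`.
#' @param ... unused.
#' @return list with integration, annotated and intergenic counts.
#' @export
summary.genetrap_annotation <- function(object, ...) {
  n <- attr(object, "n_integrations")
  inter <- sum(object$intergenic)
  list(n_integrations = n,
       n_annotated = n - inter,
       n_intergenic = inter,
       n_hits = sum(!object$intergenic))
}

#' @export
print.genetrap_annotation <- function(x, ...) {
  s <- summary(x)
  cat("genetrap_annotation:", s$n_integrations, "integrations —",
      s$n_annotated, "in genes (", s$n_hits, "gene hits ),",
      s$n_intergenic, "intergenic\n")
  invisible(x)
}

#' Write the annotation table and a BED6 of insertion points
#'
#' @param annot a `genetrap_annotation`.
#' @param tsv_path output TSV (one row per hit plus intergenic rows).
#' @param bed_path optional BED6 of integration points (one row per
#'   integration; name = cell line id).
#' @return paths written, invisibly.
#' @export
write_annotation <- function(annot, tsv_path, bed_path = NULL) {
  cols <- c("cell_line_id", "vector_id", "vector_class", "chrom", "position",
            "tag_strand", "strand_imputed", "intergenic", "gene_id", "symbol",
            "raw_biotype", "major_class", "lnc_subclass", "relative_position",
            "decile", "region", "strand_relation", "host_spliced", "primary",
            "mechanism")
  write_tsv(as.data.frame(annot)[cols], tsv_path)
  if (!is.null(bed_path)) {
    one <- annot[!duplicated(annot$cell_line_id), , drop = FALSE]
    one <- one[!is.na(one$chrom), , drop = FALSE]
    bed <- data.frame(one$chrom, one$position, one$position + 1L,
                      one$cell_line_id, 0L,
                      ifelse(is.na(one$tag_strand), ".", one$tag_strand))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(c(tsv_path, bed_path))
}
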