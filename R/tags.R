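tag_schema <- function() {
  c("tag_id", "cell_line_id", "vector_id", "vector_class", "chrom",
    "position", "tag_strand", "mapped", "alignment_quality",
    "n_high_quality_alignments", "representative")
}

vector_classes <- function() {
  c("promoter_trap_SA", "exon_trap", "polyA_trap", "combined", "secretory_trap")
}

# vector classes whose activation depends on splicing into the reporter's
# splice acceptor (everything except the polyA traps)
sa_vector_classes <- function() setdiff(vector_classes(), "polyA_trap")

#' Read gene-trap sequence tags from a TSV file
#'
#' The TSV must carry a header naming all tag fields: `tag_id`,
#' `cell_line_id`, `vector_id`, `vector_class`, `chrom`, `position`
#' (0-based insertion point), `tag_strand`, `mapped`, `alignment_quality`
#' (`high`/`low`), `n_high_quality_alignments`, `representative`. Boolean
#' columns accept 0/1/true/false. Unmapped tags may leave `chrom`,
#' `position` and `tag_strand` empty.
#'
#' @param path TSV file path.
#' @return data.frame of tags, one row per sequence tag.
#' @export
read_tags <- function(path) {
  if (!file.exists(path)) data_error("tag file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("", "NA"))
  missing <- setdiff(tag_schema(), names(df))
  if (length(missing) > 0) {
    data_error("tag TSV missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[tag_schema()]
  pos <- suppressWarnings(as.integer(df$position))
  bad <- which(!is.na(df$position) & is.na(pos))
  if (length(bad) > 0) {
    data_error(sprintf("bad integer in column position, line %d: '%s'",
                       bad[1] + 1L, df$position[bad[1]]))
  }
  nhq <- suppressWarnings(as.integer(df$n_high_quality_alignments))
  bad <- which(!is.na(df$n_high_quality_alignments) & is.na(nhq))
  if (length(bad) > 0) {
    data_error(sprintf("bad integer in column n_high_quality_alignments, line %d: '%s'",
                       bad[1] + 1L, df$n_high_quality_alignments[bad[1]]))
  }
  df$position <- pos
  df$n_high_quality_alignments <- ifelse(is.na(nhq), 0L, nhq)
  df$mapped <- parse_logical(df$mapped, "mapped")
  df$mapped[is.na(df$mapped)] <- FALSE
  df$representative <- parse_logical(df$representative, "representative")
  df$representative[is.na(df$representative)] <- FALSE
  # unmapped tags carry no coordinates
  df$chrom[!df$mapped] <- NA_character_
  df$position[!df$mapped] <- NA_integer_
  df$tag_strand[!df$mapped] <- NA_character_
  df
}

#' Read tags from BED6 plus a sidecar metadata TSV
#'
#' The BED6 supplies `chrom`, `position` (the 0-based start), `tag_id`
#' (name field) and `tag_strand`; the sidecar TSV, joined on `tag_id`,
#' supplies the remaining tag fields.
#'
#' @param bed_path BED6 file of mapped tag positions.
#' @param meta_path TSV with `tag_id` plus the non-coordinate tag columns.
#' @return data.frame of tags as from [read_tags()].
#' @export
read_tags_bed <- function(bed_path, meta_path) {
  if (!file.exists(bed_path)) data_error("BED file not found: ", bed_path)
  bed <- utils::read.delim(bed_path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 6) data_error("expected BED6, found ", ncol(bed), " columns")
  names(bed)[1:6] <- c("chrom", "start", "end", "tag_id", "score", "strand")
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE,
                            na.strings = c("", "NA"))
  need <- setdiff(tag_schema(), c("chrom", "position", "tag_strand"))
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0) {
    data_error("sidecar TSV missing column(s): ", paste(missing, collapse = ", "))
  }
  idx <- match(meta$tag_id, bed$tag_id)
  df <- meta[need]
  df$chrom <- bed$chrom[idx]
  df$position <- as.integer(bed$start[idx])
  df$tag_strand <- bed$strand[idx]
  df$mapped <- parse_logical(df$mapped, "mapped") & !is.na(idx)
  df$representative <- parse_logical(df$representative, "representative")
  df$n_high_quality_alignments <- as.integer(df$n_high_quality_alignments)
  df$chrom[!df$mapped] <- NA_character_
  df$position[!df$mapped] <- NA_integer_
  df$tag_strand[!df$mapped] <- NA_character_
  df[tag_schema()]
}

#' Filter sequence tags to one representative integration per cell line
#'
#' Applies, in order, the three filtering rules used to reduce the raw tag
#' set to unequivocally mapped integrations:
#' \enumerate{
#'   \item drop unmapped tags, and tags without a unique high-quality
#'     alignment (`alignment_quality = "low"` or zero high-quality
#'     alignments);
#'   \item drop tags with multiple high-quality alignments;
#'   \item among a cell line's surviving tags keep only those flagged
#'     representative.
#' }
#' Each discarded tag is attributed to the first rule that removed it. If a
#' cell line still has several surviving representative tags, the
#' lexicographically smallest `tag_id` wins (a warning is issued when the
#' survivors map to different coordinates) and the losers are counted with
#' the non-representative discards. Each surviving cell line yields exactly
#' one integration.
#'
#' @param tags data.frame of tags as from [read_tags()].
#' @return object of class `filter_result`: list with `integrations`
#'   (data.frame: `cell_line_id`, `vector_id`, `vector_class`, `chrom`,
#'   `position`, `tag_strand`, `source_tag_id`) and `report` (named counters
#'   summing to the number of input tags).
#' @export
filter_tags <- function(tags) {
  need <- setdiff(tag_schema(), "tag_id")
  stopifnot(all(c("tag_id", need) %in% names(tags)))
  n_input <- nrow(tags)

  unmapped <- !tags$mapped
  no_hq <- !unmapped & (tags$alignment_quality != "high" |
                          tags$n_high_quality_alignments == 0L)
  multi <- !unmapped & !no_hq & tags$n_high_quality_alignments > 1L
  alive <- !unmapped & !no_hq & !multi
  nonrep <- alive & !tags$representative
  alive <- alive & tags$representative

  surv <- tags[alive, , drop = FALSE]
  n_tie <- 0L
  if (nrow(surv) > 0) {
    surv <- surv[order(surv$cell_line_id, surv$tag_id), , drop = FALSE]
    dup <- duplicated(surv$cell_line_id)
    if (any(dup)) {
      n_tie <- sum(dup)
      loser_cl <- unique(surv$cell_line_id[dup])
      coords <- paste(surv$chrom, surv$position)
      differing <- vapply(loser_cl, function(cl) {
        length(unique(coords[surv$cell_line_id == cl])) > 1
      }, logical(1))
      if (any(differing)) {
        warning(sum(differing), " cell line(s) with several representative tags ",
                "at different coordinates; keeping the lexicographically ",
                "smallest tag_id")
      }
      surv <- surv[!dup, , drop = FALSE]
    }
  }

  integrations <- data.frame(
    cell_line_id = surv$cell_line_id,
    vector_id = surv$vector_id,
    vector_class = surv$vector_class,
    chrom = surv$chrom,
    position = surv$position,
    tag_strand = surv$tag_strand,
    source_tag_id = surv$tag_id,
    stringsAsFactors = FALSE
  )
  rownames(integrations) <- NULL

  report <- list(
    n_input = n_input,
    n_discarded_unmapped = sum(unmapped),
    n_discarded_no_unique_hq = sum(no_hq),
    n_discarded_multi_hq = sum(multi),
    n_discarded_nonrepresentative = sum(nonrep) + n_tie,
    n_retained = nrow(integrations)
  )
  stopifnot(report$n_input == report$n_retained +
              report$n_discarded_unmapped + report$n_discarded_no_unique_hq +
              report$n_discarded_multi_hq + report$n_discarded_nonrepresentative)

  structure(list(integrations = integrations, report = report),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  r <- x$report
  cat("filter_result:", r$n_input, "tags ->", r$n_retained, "integrations\n")
  cat("  discarded: unmapped", r$n_discarded_unmapped,
      "| no unique high-quality alignment", r$n_discarded_no_unique_hq,
      "| multiple high-quality alignments", r$n_discarded_multi_hq,
      "| non-representative", r$n_discarded_nonrepresentative, "\n")
  invisible(x)
}

#' Write integrations and the filter report
#'
#' @param x a `filter_result`.
#' @param integrations_path TSV output path for the integration table.
#' @param report_path optional JSON output path for the filter counters.
#' @return paths written, invisibly.
#' @export
write_filter_result <- function(x, integrations_path, report_path = NULL) {
  stopifnot(inherits(x, "filter_result"))
  write_tsv(x$integrations, integrations_path)
  if (!is.null(report_path)) {
    jsonlite::write_json(x$report, report_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(integrations_path, report_path))
}

#' Re-express integrations as sequence tags
#'
#' Utility mainly used to check the filter's idempotence: an integration is
#' re-expressed as a mapped, unique, high-quality, representative tag.
#'
#' @param integrations integration data.frame from [filter_tags()].
#' @return data.frame with the tag schema.
#' @export
integrations_as_tags <- function(integrations) {
  data.frame(
    tag_id = integrations$source_tag_id,
    cell_line_id = integrations$cell_line_id,
    vector_id = integrations$vector_id,
    vector_class = integrations$vector_class,
    chrom = integrations$chrom,
    position = integrations$position,
    tag_strand = integrations$tag_strand,
    mapped = TRUE,
    alignment_quality = "high",
    n_high_quality_alignments = 1L,
    representative = TRUE,
    stringsAsFactors = FALSE
  )
}
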