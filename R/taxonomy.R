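#' GENCODE biotype taxonomy
#'
#' Maps raw GTF biotype strings to the four major GENCODE gene classes
#' (protein-coding, lncRNA, sncRNA, pseudogene), and lncRNA biotypes to
#' their positional subclasses (lincRNA, antisense, sense overlapping,
#' sense intronic, bidirectional promoter, processed transcript,
#' 3'-overlapping, macro, TEC). TEC is kept inside the lncRNA class, where
#' GENCODE places these to-be-experimentally-confirmed loci.
#'
#' The default table covers GENCODE vM8 biotype strings plus common aliases
#' from neighbouring releases; any `*_pseudogene` string falls back to the
#' pseudogene class and `IG_*`/`TR_*` segment genes to protein-coding. A
#' biotype absent from the table is *not* an error: such genes are retained
#' and reported as `unclassified`.
#'
#' The bundled annotated-gene census carries the GENCODE vM8 / Ensembl 83
#' (GRCm38) mouse lncRNA counts: 9072 lncRNA genes, of which 3579 lincRNA,
#' 2189 antisense, 23 sense overlapping, 253 sense intronic and 12
#' bidirectional promoter. These feed the percent-of-annotated column of the
#' biotype census report.
#'
#' @param overrides optional `data.frame` with columns `raw_biotype` and
#'   `class_path` (`"major"` or `"major/subclass"`, e.g. `"lncRNA/lincRNA"`),
#'   or a path to a two-column TSV with those columns. Overrides replace or
#'   extend the default mapping.
#' @param census optional replacement census: a list with named numeric
#'   vectors `major` and `lnc_subclass`.
#' @return object of class `biotype_taxonomy`: list with elements `map`
#'   (data.frame `raw_biotype`, `major_class`, `lnc_subclass`) and `census`.
#' @export
biotype_taxonomy <- function(overrides = NULL, census = NULL) {
  lnc <- c(lincRNA = "lincRNA",
           antisense = "antisense",
           antisense_RNA = "antisense",
           sense_intronic = "sense_intronic",
           sense_overlapping = "sense_overlapping",
           bidirectional_promoter = "bidirectional_promoter",
           bidirectional_promoter_lncRNA = "bidirectional_promoter",
           processed_transcript = "processed_transcript",
           `3prime_overlapping_ncRNA` = "three_prime_overlapping",
           `3prime_overlapping_ncrna` = "three_prime_overlapping",
           macro_lncRNA = "macro",
           TEC = "TEC")
  snc <- c("miRNA", "snoRNA", "snRNA", "rRNA", "misc_RNA", "scaRNA",
           "sRNA", "Mt_tRNA", "Mt_rRNA", "ribozyme")
  map <- rbind(
    data.frame(raw_biotype = "protein_coding", major_class = "protein_coding",
               lnc_subclass = "none", stringsAsFactors = FALSE),
    data.frame(raw_biotype = names(lnc), major_class = "lncRNA",
               lnc_subclass = unname(lnc), stringsAsFactors = FALSE),
    data.frame(raw_biotype = snc, major_class = "sncRNA",
               lnc_subclass = "none", stringsAsFactors = FALSE)
  )

  if (!is.null(overrides)) {
    if (is.character(overrides) && length(overrides) == 1) {
      overrides <- utils::read.delim(overrides, stringsAsFactors = FALSE)
    }
    if (!all(c("raw_biotype", "class_path") %in% names(overrides))) {
      config_error("taxonomy override needs columns raw_biotype, class_path")
    }
    parts <- strsplit(overrides$class_path, "/", fixed = TRUE)
    odf <- data.frame(
      raw_biotype = overrides$raw_biotype,
      major_class = vapply(parts, `[`, "", 1),
      lnc_subclass = vapply(parts, function(p) if (length(p) > 1) p[2] else "none", ""),
      stringsAsFactors = FALSE
    )
    bad <- odf$major_class == "lncRNA" & odf$lnc_subclass == "none" |
      odf$major_class != "lncRNA" & odf$lnc_subclass != "none"
    if (any(bad)) {
      config_error("taxonomy override: lnc_subclass must be given exactly for lncRNA entries (",
                   paste(odf$raw_biotype[bad], collapse = ", "), ")")
    }
    map <- map[!map$raw_biotype %in% odf$raw_biotype, , drop = FALSE]
    map <- rbind(map, odf)
  }
  rownames(map) <- NULL

  if (is.null(census)) {
    census <- list(
      major = c(lncRNA = 9072),
      lnc_subclass = c(lincRNA = 3579, antisense = 2189,
                       sense_overlapping = 23, sense_intronic = 253,
                       bidirectional_promoter = 12)
    )
  }
  stopifnot(all(unlist(census) >= 0))

  structure(list(map = map, census = census), class = "biotype_taxonomy")
}

#' Classify raw biotype strings
#'
#' Deterministic lookup through a [biotype_taxonomy()]. Unmatched
#' `*_pseudogene` strings map to the pseudogene class and `IG_*`/`TR_*`
#' segment genes to protein-coding; anything else falls through to the
#' `unclassified` sentinel, which is excluded from biotype tables but
#' surfaced in diagnostics.
#'
#' @param raw_biotype character vector of GTF biotype attribute values.
#' @param taxonomy a [biotype_taxonomy()].
#' @return data.frame with columns `major_class` and `lnc_subclass`,
#'   one row per input.
#' @export
classify_biotype <- function(raw_biotype, taxonomy = biotype_taxonomy()) {
  stopifnot(inherits(taxonomy, "biotype_taxonomy"))
  idx <- match(raw_biotype, taxonomy$map$raw_biotype)
  major <- taxonomy$map$major_class[idx]
  sub <- taxonomy$map$lnc_subclass[idx]
  miss <- is.na(idx)
  if (any(miss)) {
    pseudo <- miss & grepl("pseudogene", raw_biotype, fixed = TRUE)
    igtr <- miss & !pseudo & grepl("^(IG|TR)_.*gene$", raw_biotype)
    major[pseudo] <- "pseudogene"
    major[igtr] <- "protein_coding"
    major[miss & !pseudo & !igtr] <- "unclassified"
    sub[miss] <- "none"
  }
  data.frame(major_class = major, lnc_subclass = sub, stringsAsFactors = FALSE)
}

# canonical category orders used by reports and the enrichment matrix
major_class_levels <- function() {
  c("protein_coding", "lncRNA", "sncRNA", "pseudogene")
}

lnc_subclass_levels <- function() {
  c("lincRNA", "antisense", "sense_overlapping", "sense_intronic",
    "bidirectional_promoter", "processed_transcript",
    "three_prime_overlapping", "macro", "TEC")
}

#' @export
print.biotype_taxonomy <- function(x, ...) {
  cat("biotype_taxonomy:", nrow(x$map), "raw biotypes ->",
      length(unique(x$map$major_class)), "major classes\n")
  tab <- table(x$map$major_class)
  cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)), collapse = "\n"), "\n")
  invisible(x)
}
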