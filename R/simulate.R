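#' Specification of one simulated gene-trap vector
#'
#' @param vector_id vector name.
#' @param vector_class one of `promoter_trap_SA`, `exon_trap`, `polyA_trap`,
#'   `combined`, `secretory_trap`.
#' @param positional_model decile distribution of insertion points along the
#'   gene: `five_prime_geometric` (splice-acceptor promoter traps favour the
#'   5' end, since long upstream fusions compromise the reporter),
#'   `three_prime_geometric` (polyA traps favour the 3' end, upstream
#'   insertions being lost to nonsense-mediated decay), or `uniform`.
#' @param rho geometric decay parameter in `(0, 1)`: decile `d` from the
#'   favoured end carries mass proportional to `(1 - rho)^(d - 1)`.
#' @param biotype_multipliers named nonnegative multipliers on a gene's
#'   sampling weight, keyed by raw biotype, lncRNA subclass or major class;
#'   unnamed biotypes default to 1.
#' @param expression_dependent if `TRUE` the vector can only insert into
#'   genes expressed in ES cells (default: `TRUE` for every class except the
#'   polyA traps, which carry their own promoter).
#' @return object of class `vector_spec`.
#' @export
vector_spec <- function(vector_id, vector_class,
                        positional_model = c("uniform", "five_prime_geometric",
                                             "three_prime_geometric"),
                        rho = 0.5, biotype_multipliers = NULL,
                        expression_dependent = vector_class %in% sa_vector_classes()) {
  positional_model <- match.arg(positional_model)
  if (!vector_class %in% vector_classes()) {
    config_error("unknown vector_class: ", vector_class)
  }
  if (rho <= 0 || rho >= 1) config_error("rho must lie in (0, 1)")
  if (!is.null(biotype_multipliers)) {
    stopifnot(!is.null(names(biotype_multipliers)),
              all(biotype_multipliers >= 0))
  }
  structure(list(vector_id = vector_id, vector_class = vector_class,
                 positional_model = positional_model, rho = rho,
                 biotype_multipliers = biotype_multipliers,
                 expression_dependent = expression_dependent),
            class = "vector_spec")
}

#' Decile mass function of a positional model
#'
#' @param positional_model model name as in [vector_spec()].
#' @param rho geometric decay parameter.
#' @return numeric vector of length 10 summing to 1 (decile 1 = TSS end).
#' @export
decile_pmf <- function(positional_model, rho = 0.5) {
  w <- switch(positional_model,
              uniform = rep(1, 10),
              five_prime_geometric = (1 - rho)^(0:9),
              three_prime_geometric = rev((1 - rho)^(0:9)),
              config_error("unknown positional_model: ", positional_model))
  w / sum(w)
}

#' Configuration of the synthetic gene-trap study
#'
#' Defaults emulate the mouse GENCODE vM8 gene census scaled down by roughly
#' 1/150 (so biotype proportions match the annotated genome), two vectors
#' representing the two dominant vector designs, 5000 integrations per
#' vector, a 40% intergenic insertion rate and MGI-like tag noise (unmapped
#' tags, low-quality and multi-mapping alignments, redundant
#' non-representative tags per integration).
#'
#' @param seed integer seed; all randomness in the generator flows from it.
#' @param genes_per_biotype named integer vector of gene counts per raw
#'   biotype.
#' @param gene_length_range named list of `c(min, max)` gene lengths (bp)
#'   per major class; drawn lengths are rounded to multiples of 10 so decile
#'   boundaries are exact.
#' @param single_exon_prob named per-biotype probability that a gene is
#'   single-exon (non-spliced); biotypes that are unspliced by definition
#'   (TEC, macro lncRNA, most sncRNAs) default to 1.
#' @param exon_count_lambda mean number of exons beyond 2 for spliced genes.
#' @param expression_fraction named per-major-class probability that a gene
#'   is expressed in ES cells.
#' @param vectors list of [vector_spec()]s.
#' @param n_integrations_per_vector clean integrations simulated per vector.
#' @param noise list with `p_unmapped`, `p_low_quality`, `p_multi_hit`
#'   (rates of discardable noise tags relative to the clean count) and
#'   `extra_nonrepresentative_tags_per_integration` (Poisson mean of
#'   redundant tags per integration).
#' @param intergenic_fraction fraction of integrations landing outside gene
#'   spans.
#' @param chrom_length synthetic chromosome capacity (bp).
#' @param intergenic_gap_range `c(min, max)` gap between adjacent genes.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             genes_per_biotype = NULL,
                             gene_length_range = NULL,
                             single_exon_prob = NULL,
                             exon_count_lambda = 3,
                             expression_fraction = NULL,
                             vectors = NULL,
                             n_integrations_per_vector = 5000L,
                             noise = NULL,
                             intergenic_fraction = 0.4,
                             chrom_length = 2e7,
                             intergenic_gap_range = c(2000, 10000)) {
  if (is.null(genes_per_biotype)) {
    genes_per_biotype <- c(
      protein_coding = 140L,
      lincRNA = 24L, antisense = 15L, sense_intronic = 2L,
      sense_overlapping = 1L, bidirectional_promoter = 1L,
      processed_transcript = 12L, TEC = 4L, macro_lncRNA = 1L,
      miRNA = 15L, snoRNA = 15L, snRNA = 8L,
      processed_pseudogene = 40L
    )
  }
  if (is.null(gene_length_range)) {
    gene_length_range <- list(protein_coding = c(5000, 40000),
                              lncRNA = c(1000, 15000),
                              sncRNA = c(100, 300),
                              pseudogene = c(1000, 8000),
                              unclassified = c(1000, 5000))
  }
  if (is.null(single_exon_prob)) {
    single_exon_prob <- c(protein_coding = 0.03,
                          lincRNA = 0.3, antisense = 0.3,
                          sense_intronic = 0.6, sense_overlapping = 0.1,
                          bidirectional_promoter = 0.3,
                          processed_transcript = 0.2,
                          TEC = 1, macro_lncRNA = 1,
                          miRNA = 1, snoRNA = 1, snRNA = 1,
                          processed_pseudogene = 0.9)
  }
  if (is.null(expression_fraction)) {
    expression_fraction <- c(protein_coding = 0.75, lncRNA = 0.6,
                             sncRNA = 0.6, pseudogene = 0.3,
                             unclassified = 0.5)
  }
  if (is.null(vectors)) {
    vectors <- list(
      vector_spec("PTSA1", "promoter_trap_SA", "five_prime_geometric",
                  rho = 0.5),
      vector_spec("PAT1", "polyA_trap", "three_prime_geometric", rho = 0.5)
    )
  }
  if (is.null(noise)) {
    noise <- list(p_unmapped = 0.1, p_low_quality = 0.05, p_multi_hit = 0.1,
                  extra_nonrepresentative_tags_per_integration = 0.2)
  }
  probs <- c(noise$p_unmapped, noise$p_low_quality, noise$p_multi_hit,
             intergenic_fraction, expression_fraction, single_exon_prob)
  if (any(probs < 0 | probs > 1)) config_error("all probabilities must lie in [0, 1]")
  if (noise$extra_nonrepresentative_tags_per_integration < 0) {
    config_error("extra_nonrepresentative_tags_per_integration must be >= 0")
  }
  stopifnot(all(genes_per_biotype >= 0), n_integrations_per_vector >= 0)
  if (!all(vapply(vectors, inherits, TRUE, "vector_spec"))) {
    config_error("vectors must be a list of vector_spec objects")
  }
  if (anyDuplicated(vapply(vectors, `[[`, "", "vector_id"))) {
    config_error("duplicate vector_id")
  }
  structure(list(seed = as.integer(seed),
                 genes_per_biotype = genes_per_biotype,
                 gene_length_range = gene_length_range,
                 single_exon_prob = single_exon_prob,
                 exon_count_lambda = exon_count_lambda,
                 expression_fraction = expression_fraction,
                 vectors = vectors,
                 n_integrations_per_vector = as.integer(n_integrations_per_vector),
                 noise = noise,
                 intergenic_fraction = intergenic_fraction,
                 chrom_length = chrom_length,
                 intergenic_gap_range = intergenic_gap_range),
            class = "synthetic_config")
}

round10 <- function(x) pmax(10L, as.integer(round(x / 10) * 10))

# equal-block exon layout: 2*n_ex - 1 alternating exon/intron blocks
make_exons <- function(start, end, n_ex) {
  L <- end - start
  n_ex <- max(1L, min(n_ex, (L %/% 40) + 1L))
  blocks <- 2L * n_ex - 1L
  w <- L %/% blocks
  s <- start + (seq_len(n_ex) - 1L) * 2L * w
  e <- s + w
  e[n_ex] <- end
  data.frame(start = s, end = e)
}

#' Generate a synthetic annotation set
#'
#' Places the configured genes on synthetic chromosomes (`chrS1`, ...)
#' separated by random intergenic gaps, draws strand, length, exon
#' structure and an ES-cell expression flag per gene, and plants four
#' deliberate overlap arrangements when the involved biotypes are
#' requested: an antisense lncRNA inside a protein-coding gene on the
#' opposite strand, a sense-intronic lncRNA inside a host intron, a
#' bidirectional-promoter lncRNA head-to-head with a protein-coding gene,
#' and a sense-overlapping lncRNA hosting a protein-coding gene in its
#' intron. Everything is deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param taxonomy a [biotype_taxonomy()].
#' @return an `annotation_set` whose gene table carries an extra
#'   `expressed` column.
#' @export
generate_annotation <- function(config, taxonomy = biotype_taxonomy()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  gpb <- config$genes_per_biotype
  gpb <- gpb[gpb > 0]
  n <- sum(gpb)
  if (n == 0) {
    return(as_annotation_set(
      data.frame(gene_id = character(), symbol = character(),
                 chrom = character(), start = integer(), end = integer(),
                 strand = character(), raw_biotype = character(),
                 stringsAsFactors = FALSE),
      data.frame(gene_id = character(), transcript_id = character(),
                 start = integer(), end = integer(), stringsAsFactors = FALSE),
      taxonomy))
  }

  raw <- rep(names(gpb), gpb)
  major <- classify_biotype(raw, taxonomy)$major_class
  ids <- sprintf("G%04d", seq_len(n))
  symbols <- paste0(raw, "-", unlist(lapply(gpb, seq_len)))

  rng <- function(cls) config$gene_length_range[[cls]] %||%
    config$gene_length_range[["unclassified"]] %||% c(1000, 5000)
  lens <- round10(vapply(major, function(cl) {
    r <- rng(cl); stats::runif(1, r[1], r[2])
  }, 0))
  p1 <- ifelse(is.na(config$single_exon_prob[raw]), 0.2,
               config$single_exon_prob[raw])
  single <- stats::runif(n) < p1
  n_ex <- ifelse(single, 1L, 2L + stats::rpois(n, config$exon_count_lambda))
  strand <- sample(c("+", "-"), n, replace = TRUE)

  # designate planted-overlap guests and their protein-coding partners
  pcg_pool <- which(raw == "protein_coding")
  guests <- integer(0)
  pick_pcg <- function() {
    avail <- setdiff(pcg_pool, guests)
    if (length(avail) == 0) return(NA_integer_)
    avail[1]
  }
  plant <- list()
  take_guest <- function(biotype) {
    i <- which(raw == biotype)[1]
    if (is.na(i)) return(NA_integer_)
    i
  }
  a1 <- take_guest("antisense")
  if (!is.na(a1) && length(pcg_pool) > 1) {
    host <- pick_pcg(); guests <- c(guests, a1)
    plant$antisense <- c(guest = a1, host = host)
  }
  si <- take_guest("sense_intronic")
  if (!is.na(si) && length(setdiff(pcg_pool, c(guests, unlist(plant)))) > 1) {
    host <- setdiff(pcg_pool, c(guests, unlist(plant)))[1]
    guests <- c(guests, si)
    lens[host] <- max(lens[host], 15000L)
    n_ex[host] <- max(n_ex[host], 2L); single[host] <- FALSE
    plant$sense_intronic <- c(guest = si, host = host)
  }
  bp <- take_guest("bidirectional_promoter")
  if (!is.na(bp) && length(setdiff(pcg_pool, c(guests, unlist(plant)))) > 1) {
    host <- setdiff(pcg_pool, c(guests, unlist(plant)))[1]
    guests <- c(guests, bp)
    plant$bidirectional_promoter <- c(guest = bp, host = host)
  }
  so <- take_guest("sense_overlapping")
  if (!is.na(so) && length(setdiff(pcg_pool, c(guests, unlist(plant)))) > 1) {
    guest_pcg <- setdiff(pcg_pool, c(guests, unlist(plant)))[1]
    guests <- c(guests, guest_pcg)
    lens[so] <- max(lens[so], 10000L)
    n_ex[so] <- max(n_ex[so], 3L); single[so] <- FALSE
    plant$sense_overlapping <- c(guest = guest_pcg, host = so)
  }

  # sequential placement of standalone genes
  standalone <- setdiff(seq_len(n), guests)
  order_sa <- sample(standalone)
  start <- integer(n); end <- integer(n); chrom <- character(n)
  cursor <- 10000; chrom_i <- 1L
  gapr <- config$intergenic_gap_range
  for (i in order_sa) {
    if (10000 + lens[i] > config$chrom_length) {
      config_error("gene length ", lens[i], " exceeds chromosome capacity ",
                   config$chrom_length)
    }
    if (cursor + lens[i] > config$chrom_length) {
      chrom_i <- chrom_i + 1L
      cursor <- 10000
    }
    chrom[i] <- paste0("chrS", chrom_i)
    start[i] <- as.integer(cursor)
    end[i] <- as.integer(cursor + lens[i])
    cursor <- end[i] + round10(stats::runif(1, gapr[1], gapr[2]))
  }

  place_guest <- function(gi, s, e, chr, str) {
    chrom[gi] <<- chr; start[gi] <<- as.integer(s); end[gi] <<- as.integer(e)
    strand[gi] <<- str
  }
  flip <- function(s) if (s == "+") "-" else "+"

  if (!is.null(plant$antisense)) {
    g <- plant$antisense["guest"]; h <- plant$antisense["host"]
    L <- end[h] - start[h]
    lg <- min(lens[g], round10(0.6 * L))
    s <- start[h] + min(round10(0.2 * L), L - lg - 10L)
    place_guest(g, s, s + lg, chrom[h], flip(strand[h]))
  }
  if (!is.null(plant$sense_intronic)) {
    g <- plant$sense_intronic["guest"]; h <- plant$sense_intronic["host"]
    ex <- make_exons(start[h], end[h], n_ex[h])
    iv <- c(ex$end[1], ex$start[2])  # first intron
    w <- iv[2] - iv[1]
    lg <- min(lens[g], round10(w - 20L))
    place_guest(g, iv[1] + 10L, iv[1] + 10L + lg, chrom[h], strand[h])
  }
  if (!is.null(plant$bidirectional_promoter)) {
    g <- plant$bidirectional_promoter["guest"]
    h <- plant$bidirectional_promoter["host"]
    lg <- min(lens[g], 2000L)
    if (strand[h] == "+") {
      e <- start[h] + 100L
      place_guest(g, max(10L, e - lg), e, chrom[h], "-")
    } else {
      s <- end[h] - 100L
      place_guest(g, s, s + lg, chrom[h], "+")
    }
  }
  if (!is.null(plant$sense_overlapping)) {
    g <- plant$sense_overlapping["guest"]; h <- plant$sense_overlapping["host"]
    ex <- make_exons(start[h], end[h], n_ex[h])
    iv <- c(ex$end[1], ex$start[2])
    w <- iv[2] - iv[1]
    lg <- min(lens[g], round10(w - 20L))
    place_guest(g, iv[1] + 10L, iv[1] + 10L + lg, chrom[h], strand[h])
  }

  genes <- data.frame(gene_id = ids, symbol = symbols, chrom = chrom,
                      start = start, end = end, strand = strand,
                      raw_biotype = raw, stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(seq_len(n), function(i) {
    ex <- make_exons(start[i], end[i], n_ex[i])
    data.frame(gene_id = ids[i], transcript_id = paste0(ids[i], ".t1"),
               start = ex$start, end = ex$end, stringsAsFactors = FALSE)
  }))

  ann <- as_annotation_set(genes, exons, taxonomy)
  ef <- config$expression_fraction
  pex <- ifelse(is.na(ef[ann$genes$major_class]), 0.5,
                ef[ann$genes$major_class])
  ann$genes$expressed <- stats::runif(nrow(ann$genes)) < pex
  ann
}

# intergenic gaps (0-based half-open) of an annotation set, with 5 kb flanks
intergenic_gaps <- function(ann) {
  red <- GenomicRanges::reduce(ann$index)
  out <- list()
  for (chr in unique(as.character(GenomicRanges::seqnames(red)))) {
    r <- red[as.character(GenomicRanges::seqnames(red)) == chr]
    s <- GenomicRanges::start(r) - 1L  # back to 0-based
    e <- GenomicRanges::end(r)
    o <- order(s)
    s <- s[o]; e <- e[o]
    gs <- c(max(0L, s[1] - 5000L), e)
    ge <- c(s, e[length(e)] + 5000L)
    keep <- ge - gs >= 100L
    out[[chr]] <- data.frame(chrom = chr, start = gs[keep], end = ge[keep],
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

vector_gene_weights <- function(ann, vs) {
  g <- ann$genes
  w <- rep(1, nrow(g))
  m <- vs$biotype_multipliers
  if (!is.null(m)) {
    known <- c(g$raw_biotype, g$lnc_subclass, g$major_class)
    bad <- setdiff(names(m), known)
    if (length(bad) > 0) {
      config_error("vector ", vs$vector_id,
                   " references unknown biotype label(s): ",
                   paste(bad, collapse = ", "))
    }
    for (key in names(m)) {
      sel <- g$raw_biotype == key | g$lnc_subclass == key | g$major_class == key
      w[sel] <- w[sel] * m[[key]]
    }
  }
  if (vs$expression_dependent) w[!g$expressed] <- 0
  w
}

#' Generate a synthetic gene-trap tag library with ground truth
#'
#' For every configured vector, draws clean integrations: intergenic with
#' probability `intergenic_fraction` (uniform over inter-gene gaps,
#' length-weighted), otherwise a target gene weighted by the vector's
#' biotype multipliers (restricted to expressed genes for
#' expression-dependent vectors), a decile from the vector's positional
#' model and a uniform position within that decile; tags inherit the host
#' gene's strand (intergenic tags a random strand). Each clean integration
#' is emitted as one representative high-quality tag plus a Poisson number
#' of redundant non-representative tags; discardable noise tags (unmapped,
#' low-quality, multi-mapping) are added for separate noise cell lines at
#' the configured rates. The ground-truth table records the planted gene
#' (or intergenic state) and realized decile of every clean integration.
#'
#' @param ann annotation set from [generate_annotation()] (same config).
#' @param config the [synthetic_config()].
#' @return list with `tags` (tag data.frame in the [read_tags()] schema)
#'   and `truth` (data.frame: `cell_line_id`, `vector_id`, `gene_id`,
#'   `chrom`, `position`, `decile`, `intergenic`).
#' @export
generate_tags <- function(ann, config) {
  stopifnot(inherits(ann, "annotation_set"), inherits(config, "synthetic_config"))
  if (!"expressed" %in% names(ann$genes)) {
    ann$genes$expressed <- TRUE
  }
  set.seed(config$seed + 1L)
  g <- ann$genes
  gaps <- if (nrow(g) > 0) intergenic_gaps(ann) else NULL
  chrom_ext <- if (nrow(g) > 0) tapply(g$end, g$chrom, max) + 5000L else NULL

  all_tags <- list(); all_truth <- list()
  for (vs in config$vectors) {
    n <- config$n_integrations_per_vector
    if (n == 0) next
    pmf <- decile_pmf(vs$positional_model, vs$rho)
    is_inter <- stats::runif(n) < config$intergenic_fraction
    n_gene <- sum(!is_inter)

    chrom <- character(n); pos <- integer(n); strand <- character(n)
    gene_id <- rep(NA_character_, n); dec <- rep(NA_integer_, n)

    if (n_gene > 0) {
      w <- vector_gene_weights(ann, vs)
      if (sum(w) == 0) {
        config_error("vector ", vs$vector_id, " has no eligible target gene")
      }
      gi <- sample.int(nrow(g), n_gene, replace = TRUE, prob = w)
      d <- sample.int(10L, n_gene, replace = TRUE, prob = pmf)
      L <- g$end[gi] - g$start[gi]
      band <- L %/% 10L
      off <- (d - 1L) * band + as.integer(floor(stats::runif(n_gene) * band))
      p <- ifelse(g$strand[gi] == "+", g$start[gi] + off, g$end[gi] - 1L - off)
      sel <- !is_inter
      chrom[sel] <- g$chrom[gi]
      pos[sel] <- as.integer(p)
      strand[sel] <- g$strand[gi]
      gene_id[sel] <- g$gene_id[gi]
      # realized decile recomputed exactly as the annotator will see it
      dec[sel] <- decile_of(off / L)
    }
    if (any(is_inter)) {
      if (is.null(gaps) || nrow(gaps) == 0) {
        config_error("intergenic_fraction > 0 but the annotation has no intergenic space")
      }
      k <- sum(is_inter)
      gwi <- sample.int(nrow(gaps), k, replace = TRUE,
                        prob = gaps$end - gaps$start)
      p <- gaps$start[gwi] +
        as.integer(floor(stats::runif(k) * (gaps$end[gwi] - gaps$start[gwi])))
      chrom[is_inter] <- gaps$chrom[gwi]
      pos[is_inter] <- as.integer(p)
      strand[is_inter] <- sample(c("+", "-"), k, replace = TRUE)
    }

    cl <- sprintf("%s.%06d", vs$vector_id, seq_len(n))
    clean <- data.frame(
      tag_id = paste0(cl, ".t01"),
      cell_line_id = cl, vector_id = vs$vector_id,
      vector_class = vs$vector_class,
      chrom = chrom, position = pos, tag_strand = strand,
      mapped = TRUE, alignment_quality = "high",
      n_high_quality_alignments = 1L, representative = TRUE,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(cell_line_id = cl, vector_id = vs$vector_id,
                        gene_id = gene_id, chrom = chrom, position = pos,
                        decile = dec, intergenic = is_inter,
                        stringsAsFactors = FALSE)

    parts <- list(clean)
    rate <- config$noise$extra_nonrepresentative_tags_per_integration
    if (rate > 0) {
      n_extra <- stats::rpois(n, rate)
      if (sum(n_extra) > 0) {
        rep_idx <- rep(seq_len(n), n_extra)
        dup <- clean[rep_idx, , drop = FALSE]
        k <- unlist(lapply(n_extra[n_extra > 0], seq_len))
        dup$tag_id <- sprintf("%s.t%02d", dup$cell_line_id, k + 1L)
        dup$representative <- FALSE
        parts <- c(parts, list(dup))
      }
    }

    noise_tag <- function(kind, count) {
      if (count == 0) return(NULL)
      ncl <- sprintf("%s.N%s%05d", vs$vector_id,
                     switch(kind, unmapped = "U", low = "L", multi = "M"),
                     seq_len(count))
      if (kind == "unmapped") {
        nchrom <- rep(NA_character_, count)
        npos <- rep(NA_integer_, count)
        nstr <- rep(NA_character_, count)
      } else {
        nchr_i <- sample(names(chrom_ext), count, replace = TRUE)
        nchrom <- nchr_i
        npos <- as.integer(floor(stats::runif(count) * chrom_ext[nchr_i]))
        nstr <- sample(c("+", "-"), count, replace = TRUE)
      }
      data.frame(
        tag_id = paste0(ncl, ".t01"),
        cell_line_id = ncl, vector_id = vs$vector_id,
        vector_class = vs$vector_class,
        chrom = nchrom, position = npos, tag_strand = nstr,
        mapped = kind != "unmapped",
        alignment_quality = if (kind == "multi") "high" else "low",
        n_high_quality_alignments = switch(kind, unmapped = 0L, low = 0L,
                                           multi = 2L),
        representative = TRUE,
        stringsAsFactors = FALSE
      )
    }
    parts <- c(parts,
               list(noise_tag("unmapped",
                              stats::rbinom(1, n, config$noise$p_unmapped)),
                    noise_tag("low",
                              stats::rbinom(1, n, config$noise$p_low_quality)),
                    noise_tag("multi",
                              stats::rbinom(1, n, config$noise$p_multi_hit))))
    all_tags[[vs$vector_id]] <- do.call(rbind, parts)
    all_truth[[vs$vector_id]] <- truth
  }

  tags <- do.call(rbind, all_tags) %||%
    data.frame(matrix(nrow = 0, ncol = length(tag_schema()),
                      dimnames = list(NULL, tag_schema())))
  truth <- do.call(rbind, all_truth) %||% data.frame()
  if (nrow(tags) > 0) {
    tags <- tags[order(tags$tag_id), , drop = FALSE]
    rownames(tags) <- NULL
    rownames(truth) <- NULL
  }
  list(tags = tags, truth = truth)
}

#' Write a tag table as TSV
#'
#' Logical columns are written as `true`/`false` and missing coordinates as
#' empty fields, matching what [read_tags()] parses. Output is
#' byte-deterministic.
#'
#' @param tags tag data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(tags, path) {
  out <- tags
  for (col in c("mapped", "representative")) {
    out[[col]] <- ifelse(out[[col]], "true", "false")
  }
  write_tsv(out, path)
}
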