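#' Read and validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or an R list. Recognised fields: `gtf`
#' (gene models), `tags` (tag TSV), `out_dir`, `taxonomy_tsv` (optional
#' biotype override table), `level` (`major_class` or `lnc_subclass`),
#' `fdr` (default 0.01), `digits` (report rounding, default 1), `strata`
#' (data.frame or list of `vector_class`/`gene_class` pairs for the
#' positional profiles).
#'
#' @param config list or path to a YAML/JSON config file.
#' @return validated config list.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) config_error("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("config must be a list or file path")
  config$fdr <- config$fdr %||% 0.01
  config$digits <- config$digits %||% 1
  config$level <- config$level %||% "major_class"
  if (config$fdr <= 0 || config$fdr >= 1) config_error("fdr must lie in (0, 1)")
  if (config$digits < 0) config_error("digits must be >= 0")
  if (!config$level %in% c("major_class", "lnc_subclass")) {
    config_error("level must be major_class or lnc_subclass")
  }
  for (f in c("gtf", "tags")) {
    if (is.null(config[[f]])) config_error("config field missing: ", f)
    if (!file.exists(config[[f]])) {
      config_error("config path does not exist: ", f, " = ", config[[f]])
    }
  }
  if (is.null(config$out_dir)) config_error("config field missing: out_dir")
  if (!is.null(config$strata)) {
    config$strata <- as.data.frame(do.call(rbind, lapply(config$strata, as.data.frame)))
  }
  config
}

#' Run the full gene-trap analysis pipeline
#'
#' Filter tags, annotate integrations, build positional profiles, compute
#' the vector-by-biotype enrichment matrix and write the summary reports.
#' Per-stage record counts are logged with [message()]. All outputs are
#' plain TSV/JSON/BED and byte-deterministic for a given input.
#'
#' Files written to `out_dir`: `integrations.tsv`, `filter_report.json`,
#' `annotation.tsv`, `integrations.bed`, `positional_profiles.tsv`,
#' `enrichment_long.tsv`, `enrichment_matrix.tsv`, `census.tsv`,
#' `ncrna_subclasses.tsv`, `spliced.tsv`.
#'
#' @param config list or config file path, see [read_pipeline_config()].
#' @return invisibly, a list with the stage results and output paths.
#' @export
run_pipeline <- function(config) {
  config <- read_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  taxonomy <- biotype_taxonomy(overrides = config$taxonomy_tsv)
  ann <- read_gtf(config$gtf, taxonomy)
  message("genome_model: ", nrow(ann$genes), " genes loaded")

  tags <- read_tags(config$tags)
  filt <- filter_tags(tags)
  r <- filt$report
  message("gtst_filter: n_input = ", r$n_input, " = n_retained ", r$n_retained,
          " + unmapped ", r$n_discarded_unmapped,
          " + no_unique_hq ", r$n_discarded_no_unique_hq,
          " + multi_hq ", r$n_discarded_multi_hq,
          " + nonrepresentative ", r$n_discarded_nonrepresentative)
  write_filter_result(filt, out("integrations.tsv"), out("filter_report.json"))

  annot <- annotate_integrations(filt$integrations, ann)
  s <- summary(annot)
  message("annotate: ", s$n_annotated, " in genes, ", s$n_intergenic,
          " intergenic of ", s$n_integrations, " integrations")
  write_annotation(annot, out("annotation.tsv"), out("integrations.bed"))

  prof <- positional_profiles(annot, config$strata)
  message("positional: ", nrow(prof), " strata")
  write_tsv(as.data.frame(prof), out("positional_profiles.tsv"))

  enr <- tryCatch(
    enrichment_matrix(annot, level = config$level, fdr = config$fdr),
    genetrapr_data_error = function(e) {
      message("enrichment: skipped (", conditionMessage(e), ")")
      NULL
    })
  if (!is.null(enr)) {
    message("enrichment: ", sum(enr$cells$significant),
            " significant cell(s) at FDR ", config$fdr)
    write_enrichment(enr, out("enrichment_long.tsv"), out("enrichment_matrix.tsv"))
  }

  census <- census_report(annot, ann = ann, digits = config$digits)
  write_tsv(census, out("census.tsv"))
  subcls <- ncrna_subclass_report(annot, digits = config$digits)
  write_tsv(subcls, out("ncrna_subclasses.tsv"))
  spl <- spliced_report(annot, digits = config$digits)
  write_tsv(spl, out("spliced.tsv"))
  message("reports: census, ncrna_subclasses, spliced written")

  invisible(list(annotation_set = ann, filter = filt, annotation = annot,
                 positional = prof, enrichment = enr, census = census,
                 ncrna_subclasses = subcls, spliced = spl,
                 out_dir = config$out_dir))
}

#' Simulate a study and write its inputs to disk
#'
#' Convenience wrapper: generates the annotation and tag library for a
#' [synthetic_config()] and writes `genes.gtf`, `tags.tsv` and
#' `ground_truth.tsv` into `out_dir`. Outputs are byte-identical across
#' runs with the same config.
#'
#' @param config a [synthetic_config()].
#' @param out_dir output directory.
#' @return invisibly, list with `ann`, `tags`, `truth` and the paths.
#' @export
simulate_study <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- generate_annotation(config)
  sim <- generate_tags(ann, config)
  gtf <- file.path(out_dir, "genes.gtf")
  tags <- file.path(out_dir, "tags.tsv")
  truth <- file.path(out_dir, "ground_truth.tsv")
  write_gtf(ann, gtf)
  write_tags(sim$tags, tags)
  write_tsv(sim$truth, truth)
  invisible(list(ann = ann, tags = sim$tags, truth = sim$truth,
                 paths = c(gtf = gtf, tags = tags, truth = truth)))
}
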