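# Single-run orchestration: simulate (optional) -> catalog -> ingest ->
# popstats -> concordance -> annotate -> report, with a machine-readable
# manifest.  Stages whose inputs are absent are skipped with a notice; a
# stage failure aborts with the stage name (partial outputs are retained).

#' Load and validate a run configuration
#'
#' The configuration is a JSON object (or an equivalent R list) with
#' optional blocks: `simulate` ([simulation_config()] fields), `fasta`,
#' `vcf`, `vcf_b`, `genes_gff3`, `panel`, `universe`, `scores` input paths,
#' `detection` / `align` parameter overrides, and `thresholds`
#' (`flank_bp = 1000`, `hi_cutoff = 40`, `pli_cutoff = 0.75`). `seed` and
#' `outdir` are required.
#'
#' @param config Path to a JSON file or a named list.
#' @return A validated list of class `cgg_run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$outdir)) stop("config needs an 'outdir'")
  if (is.null(config$seed)) config$seed <- 1L
  config$seed <- as.integer(config$seed)
  defaults <- list(flank_bp = 1000L, hi_cutoff = 40, pli_cutoff = 0.75)
  config$thresholds <- modifyList(defaults,
                                  as.list(config$thresholds %||% list()))
  if (any(unlist(config$thresholds) <= 0)) stop("thresholds must be positive")
  config$detection <- do.call(detection_params,
                              as.list(config$detection %||% list()))
  config$align <- do.call(align_params, as.list(config$align %||% list()))
  for (f in c("fasta", "vcf", "vcf_b", "genes_gff3", "panel", "universe",
              "scores"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("configured input does not exist: ", f, " = ", config[[f]])
  structure(config, class = c("cgg_run_config", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full repeat-catalogue pipeline
#'
#' Executes, in order and as inputs permit: synthetic-data generation,
#' catalogue construction, VCF ingestion with locus exclusion, population
#' statistics, two-genotyper concordance, gene annotation and panel
#' enrichment. Writes all stage tables plus `report.json` (summary counts;
#' byte-identical across reruns with the same config) and `manifest.json`
#' (package version, parameters, input checksums) into `outdir`.
#'
#' @param config A [run_config()] (or path / list accepted by it).
#' @return The report, invisibly (a named list).
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$outdir, ...)
  report <- list(seed = cfg$seed)
  inputs <- list()

  if (!is.null(cfg$simulate)) {
    message("stage simulate")
    .stage("simulate", {
      sim <- cfg$simulate
      sim$seed <- sim$seed %||% cfg$seed
      scfg <- do.call(simulation_config, sim[setdiff(names(sim), "gff3")])
      gen <- generate_genome(scfg)
      Biostrings::writeXStringSet(gen$genome, out("genome.fa"))
      write.table(gen$truth, out("truth.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      pop <- simulate_population(gen$truth, scfg)
      emit_vcf(pop, gen$truth, scfg, out("calls.vcf"))
      cfg$fasta <- out("genome.fa")
      cfg$vcf <- cfg$vcf %||% out("calls.vcf")
      report$n_planted <- nrow(gen$truth)
    })
  }

  catalog <- NULL
  if (!is.null(cfg$fasta)) {
    message("stage catalog")
    .stage("catalog", {
      catalog <- build_catalog(cfg$fasta, params = cfg$detection,
                                align = cfg$align)
      write_catalog_bed(catalog, out("catalog.bed"))
      write_catalog_json(catalog, out("catalog.json"))
      report$n_loci_catalog <- nrow(catalog)
      inputs$fasta <- cfg$fasta
    })
  } else message("no FASTA: catalog stage skipped")

  cs <- NULL
  if (!is.null(cfg$vcf)) {
    message("stage ingest")
    .stage("ingest", {
      cs0 <- read_str_vcf(cfg$vcf)
      excl <- exclude_uncovered_loci(cs0)
      cs <- excl$kept
      write_calls_tsv(cs0, out("calls.tsv"))
      if (nrow(excl$excluded))
        write.table(excl$excluded, out("excluded_loci.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
      report$n_loci_ingested <- length(unique(cs0$locus_id))
      report$n_loci_excluded <- nrow(excl$excluded)
      report$exclusion_reasons <- as.list(table(excl$excluded$reason))
      report$n_samples <- length(unique(cs0$sample))
      inputs$vcf <- cfg$vcf
    })
  } else message("no VCF: ingest and popstats stages skipped")

  summaries <- NULL
  if (!is.null(cs)) {
    message("stage popstats")
    .stage("popstats", {
      summaries <- summarize_loci(cs)
      samp <- summarize_samples(cs, summaries)
      dev <- deviation_table(cs, summaries)
      write.table(summaries, out("locus_summary.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(samp, out("sample_summary.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write.table(dev, out("deviation_table.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      ok <- !is.na(summaries$polymorphic)
      report$allele_call_rate <- round(allele_call_rate(cs), 6)
      report$n_polymorphic <- sum(summaries$polymorphic[ok])
      report$fraction_polymorphic <-
        round(mean(summaries$polymorphic[ok]), 6)
      report$median_units_range <-
        range(summaries$median_units[ok])
    })
  }

  if (!is.null(cfg$vcf_b) && !is.null(cs)) {
    message("stage concordance")
    .stage("concordance", {
      csb <- exclude_uncovered_loci(read_str_vcf(cfg$vcf_b))$kept
      conc <- concordance_summary(cs, csb)
      write.table(conc$records, out("concordance_records.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(counts = as.list(conc$counts),
             fractions = as.list(round(conc$fractions, 6)),
             consistency = round(conc$consistency, 6),
             n_pairs = conc$n_pairs),
        out("concordance.json"), auto_unbox = TRUE, pretty = TRUE)
      report$concordance <- list(consistency = round(conc$consistency, 6),
                                  n_pairs = conc$n_pairs)
      inputs$vcf_b <- cfg$vcf_b
    })
  }

  if (!is.null(cfg$genes_gff3) && !is.null(catalog)) {
    message("stage annotate")
    .stage("annotate", {
      models <- read_gene_models(cfg$genes_gff3)
      ann <- assign_region(catalog, models,
                           flank = cfg$thresholds$flank_bp)
      assoc <- gene_association_table(catalog, models,
                                      flank = cfg$thresholds$flank_bp)
      write.table(ann, out("annotated_loci.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write.table(assoc, out("gene_association.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      report$region_counts <- as.list(table(ann$region))
      inputs$genes_gff3 <- cfg$genes_gff3
      if (!is.null(cfg$panel) && !is.null(cfg$universe)) {
        panel <- readLines(cfg$panel)
        universe <- readLines(cfg$universe)
        rg <- assoc$gene[assoc$any_repeat]
        enr <- enrichment_chi2(intersect(rg, universe),
                               intersect(panel, universe), universe,
                               yates = isTRUE(cfg$yates))
        jsonlite::write_json(
          list(table = enr$table, chi2 = enr$chi2, p_value = enr$p_value,
               n_overlap = enr$n_overlap),
          out("enrichment.json"), auto_unbox = TRUE, pretty = TRUE,
          digits = 10)
        report$enrichment <- list(chi2 = round(enr$chi2, 6),
                                   p_value = signif(enr$p_value, 6))
        inputs$panel <- cfg$panel; inputs$universe <- cfg$universe
      }
      if (!is.null(cfg$scores)) {
        scores <- read.table(cfg$scores, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
        flags <- join_gene_scores(assoc$gene[assoc$any_repeat], scores,
                                  hi_cutoff = cfg$thresholds$hi_cutoff,
                                  pli_cutoff = cfg$thresholds$pli_cutoff)
        write.table(flags, out("gene_scores.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        report$n_hi_low <- sum(flags$hi_low, na.rm = TRUE)
        report$n_pli_high <- sum(flags$pli_high, na.rm = TRUE)
        inputs$scores <- cfg$scores
      }
    })
  }

  manifest <- list(
    package = "cggcat",
    version = as.character(packageVersion("cggcat")),
    seed = cfg$seed,
    detection = unclass(cfg$detection),
    align = unclass(cfg$align),
    thresholds = cfg$thresholds,
    input_md5 = lapply(inputs, function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = 10)
  invisible(report)
}
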