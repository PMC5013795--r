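#' @name pipeline_cli
#' @title End-to-end pipeline orchestration
#'
#' @description One call runs the whole flow on files or in-memory objects:
#' fragment (and, for FASTQ, quality-filter) the virome, search the host
#' proteome against six-frame translations of the fragments, aggregate to
#' candidates, triage through reference homology and domain scanning, test
#' domain-category enrichment, and predict transmembrane segments for the
#' novel class. Every output is a deterministic plain-text table; a run
#' manifest records the resolved configuration, its hash and the seed.
NULL

PIPELINE_DEFAULTS <- list(
  frag_len = 200L, min_keep = 100L,
  qc_min_len = 100L, qc_min_mean_q = 25, qc_max_n_frac = 0.10,
  evalue_virome = 1e-4, min_fragments = 5L,
  evalue_ref = 1e-5, evalue_dom = 0.01, dom_shuffles = 1000L,
  tm_window = 19L, tm_threshold = 1.6, tm_all = FALSE,
  word_size = 3L, neighbor_thresh = 11L, x_drop = 20L,
  gap_open = 11L, gap_extend = 1L, evalue_report_max = 10,
  mask_window = 12L, mask_entropy = 2.0,
  seed = 1L)

#' Pipeline configuration
#'
#' Defaults: 200 nt fragments (min 100), QC at 100 nt / mean Q 25 / 10% N,
#' virome cutoff E < 1e-4 with >= 5 unique fragments, reference cutoff
#' E < 1e-5, domain cutoff E < 0.01, TM window 19 / threshold 1.6, and the
#' BLAST-era search defaults.
#'
#' @param ... overrides of the default keys; an unknown key is an error
#'   naming the key.
#' @return full configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  bad <- setdiff(names(over), names(PIPELINE_DEFAULTS))
  if (length(bad))
    viromimic_error(sprintf("unknown config key '%s'", bad[1]),
                    "viromimic_config_error")
  cfg <- PIPELINE_DEFAULTS
  cfg[names(over)] <- over
  num <- vapply(cfg[setdiff(names(cfg), "tm_all")], as.numeric, numeric(1))
  if (any(num[setdiff(names(num), "seed")] <= 0))
    viromimic_error("all thresholds must be positive", "viromimic_config_error")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' Flat key-value text (YAML-compatible subset).
#' @param path config file.
#' @return [pipeline_config()] list.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

.write_tsv <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

.read_virome_input <- function(x) {
  if (is.data.frame(x)) return(x)
  first <- readLines(x, n = 1L)
  if (startsWith(first, "@")) read_fastq(x) else read_fasta(x, "nucleotide")
}

#' Run the full prediction pipeline
#'
#' @param virome virome input: FASTA path (genomes or reads, fragmented at
#'   `frag_len`), FASTQ path (quality-filtered first), or a [seq_set()].
#' @param proteome host proteome: FASTA path or protein [seq_set()]
#'   (required).
#' @param reference optional reference proteome (path or [seq_set()]);
#'   when absent the homology stage is skipped and logged.
#' @param models optional domain models (path to a
#'   [write_domain_models()] file or a model list); when absent the domain
#'   stages are skipped and logged.
#' @param category_map named list for enrichment (default: the model
#'   categories via [sim_category_map()] when models are given).
#' @param config [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param log function used for progress/warning lines (default
#'   [message()]).
#' @return (invisibly) list with every stage's table: qc_report, fragments,
#'   hits, summaries, ref_map, domain_hits, triage, counts, enrichment,
#'   tm, manifest.
#' @export
run_pipeline <- function(virome, proteome, reference = NULL, models = NULL,
                         category_map = NULL, config = pipeline_config(),
                         outdir, log = message) {
  if (missing(proteome) || is.null(proteome))
    viromimic_error("host proteome is required", "viromimic_param_error")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(proteome)) proteome <- read_fasta(proteome, "protein")
  if (is.character(reference)) reference <- read_fasta(reference, "protein")
  if (is.character(models)) models <- read_domain_models(models)
  reads <- .read_virome_input(virome)

  qc_report <- NULL
  has_qual <- nrow(reads) > 0 && !is.null(reads$qual) &&
    !vapply(reads$qual, is.null, logical(1))[1]
  if (has_qual) {
    qc <- qc_filter(reads, config$qc_min_len, config$qc_min_mean_q,
                    config$qc_max_n_frac)
    reads <- qc$kept
    qc_report <- qc$report
    .write_tsv(qc_report, file.path(outdir, "qc_report.tsv"))
    log(sprintf("qc: kept %d of %d reads", qc_report$n_kept,
                qc_report$n_input))
  }
  fragments <- fragment_set(reads, config$frag_len, config$min_keep)
  log(sprintf("fragmenter: %d fragments", nrow(fragments)))

  params <- search_params(word_size = config$word_size,
                          neighbor_thresh = config$neighbor_thresh,
                          x_drop = config$x_drop, gap_open = config$gap_open,
                          gap_extend = config$gap_extend,
                          evalue_report_max = config$evalue_report_max,
                          mask_window = config$mask_window,
                          mask_entropy = config$mask_entropy)
  hits <- seeded_search(proteome, fragments, params = params,
                        mode = "tblastn")
  write_hit_table(hits, file.path(outdir, "hits.m6"))
  log(sprintf("search: %d HSPs", nrow(hits)))

  summaries <- aggregate_hits(hits, config$evalue_virome,
                              config$min_fragments)
  .write_tsv(summaries, file.path(outdir, "protein_summaries.tsv"))
  log(sprintf("triage: %d qualifying proteins", nrow(summaries)))

  candidates <- proteome[proteome$id %in% summaries$protein_id, ,
                         drop = FALSE]
  ref_map <- NULL
  if (!is.null(reference) && nrow(reference) > 0) {
    if (nrow(candidates) > 0)
      ref_map <- reference_homology(candidates, reference,
                                    config$evalue_ref, params)
  } else {
    log("reference proteome absent: homology stage skipped")
  }
  domain_hits <- NULL
  if (!is.null(models)) {
    if (nrow(candidates) > 0)
      domain_hits <- scan_domains(candidates, models, config$evalue_dom,
                                  config$dom_shuffles, seed = config$seed)
  } else {
    log("domain models absent: domain stage skipped")
  }
  triage <- triage_classify(summaries, ref_map, domain_hits)
  .write_tsv(triage, file.path(outdir, "triage.tsv"))
  counts <- count_categories(triage)
  .write_tsv(data.frame(category = names(counts), n = as.integer(counts)),
             file.path(outdir, "category_counts.tsv"))

  enrichment <- NULL
  if (!is.null(models)) {
    if (is.null(category_map)) category_map <- sim_category_map(models)
    have <- unlist(category_map) %in%
      vapply(models, `[[`, character(1), "name")
    if (length(unlist(category_map)) && all(have) &&
        all(lengths(category_map) >= 2) && nrow(summaries) > 0) {
      all_hits <- scan_domains(proteome, models, config$evalue_dom,
                               config$dom_shuffles, seed = config$seed)
      enrichment <- tryCatch(
        enrichment_test(summaries$protein_id, proteome$id, all_hits,
                        category_map),
        viromimic_degenerate_error = function(e) {
          log(paste("enrichment degenerate:", conditionMessage(e)))
          NULL
        })
      if (!is.null(enrichment))
        .write_tsv(enrichment, file.path(outdir, "enrichment.tsv"))
    }
  }

  tm_targets <- if (isTRUE(config$tm_all)) candidates else
    candidates[candidates$id %in%
                 triage$protein_id[triage$category == "novel"], ,
               drop = FALSE]
  tm <- predict_tm_set(tm_targets, config$tm_window, config$tm_threshold)
  .write_tsv(tm, file.path(outdir, "tm.tsv"))

  cfg_path <- file.path(outdir, "config.yaml")
  cfg_list <- unclass(config)
  yaml::write_yaml(cfg_list, cfg_path, line.sep = "\n")
  manifest <- list(tool = "viromimic",
                   version = as.character(utils::packageVersion("viromimic")),
                   seed = config$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"),
                   line.sep = "\n")
  invisible(list(qc_report = qc_report, fragments = fragments, hits = hits,
                 summaries = summaries, ref_map = ref_map,
                 domain_hits = domain_hits, triage = triage, counts = counts,
                 enrichment = enrichment, tm = tm, manifest = manifest))
}
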