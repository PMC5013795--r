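#' @name triage
#' @title Candidate aggregation and annotation triage
#'
#' @description Host proteins matched by at least `min_fragments` unique
#' virome fragments at E below `evalue_virome` become immune-protein
#' candidates. Candidates are then classified by a strict cascade:
#' reference-proteome homology first, then non-viral domain annotation,
#' then viral-tagged domains, and finally `novel` for proteins with no
#' similarity to either database.
NULL

#' Aggregate virome hits per host protein
#'
#' HSPs at or above the E-value cutoff are discarded (the cutoff is a
#' strict "less than"); fragments are counted once per protein regardless
#' of how many HSPs they contribute.
#'
#' @param hits tblastn-mode hit table (query = host protein,
#'   subject = fragment).
#' @param evalue_virome E-value cutoff (default 1e-4, strict).
#' @param min_fragments minimum unique fragments (default 5).
#' @return data.frame of qualifying proteins with columns protein_id,
#'   n_unique_fragments, n_hsps, best_evalue, sorted by n_unique_fragments
#'   descending then protein id.
#' @export
aggregate_hits <- function(hits, evalue_virome = 1e-4, min_fragments = 5L) {
  h <- hits[hits$evalue < evalue_virome, , drop = FALSE]
  if (!nrow(h))
    return(data.frame(protein_id = character(0),
                      n_unique_fragments = integer(0), n_hsps = integer(0),
                      best_evalue = numeric(0), stringsAsFactors = FALSE))
  sp <- split(h, h$qseqid)
  out <- data.frame(
    protein_id = names(sp),
    n_unique_fragments = vapply(sp, function(d) length(unique(d$sseqid)),
                                integer(1)),
    n_hsps = vapply(sp, nrow, integer(1)),
    best_evalue = vapply(sp, function(d) min(d$evalue), numeric(1)),
    stringsAsFactors = FALSE)
  out <- out[out$n_unique_fragments >= min_fragments, , drop = FALSE]
  out <- out[order(-out$n_unique_fragments, out$protein_id, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best reference-proteome homolog per candidate
#'
#' BLASTp-mode search of candidate proteins against a reference proteome;
#' for each candidate the best hit with E-value strictly below `evalue_ref`
#' is kept. Candidates absent from the result had no hit below the cutoff.
#'
#' @param candidates protein [seq_set()] of candidates.
#' @param reference protein [seq_set()] reference proteome (must be
#'   non-empty — an empty reference is an error, distinct from "no hits").
#' @param evalue_ref cutoff (default 1e-5, strict).
#' @param params,matrix passed to [seeded_search()].
#' @return data.frame protein_id, ref_id, evalue.
#' @export
reference_homology <- function(candidates, reference, evalue_ref = 1e-5,
                               params = search_params(), matrix = blosum62()) {
  if (is.null(reference) || nrow(reference) == 0L)
    viromimic_error("reference proteome is empty", "viromimic_param_error")
  hits <- seeded_search(candidates, reference, params = params,
                        matrix = matrix, mode = "blastp")
  hits <- hits[hits$evalue < evalue_ref, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(protein_id = character(0), ref_id = character(0),
                      evalue = numeric(0), stringsAsFactors = FALSE))
  sp <- split(hits, hits$qseqid)
  data.frame(
    protein_id = names(sp),
    ref_id = vapply(sp, function(d) d$sseqid[which.min(d$evalue)], character(1)),
    evalue = vapply(sp, function(d) min(d$evalue), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Scan proteins against a PSSM domain collection
#'
#' For each (protein, model) pair the best-scoring window (sum over model
#' positions of the score for the observed residue) is compared with the
#' maxima of `n_shuffles` residue-shuffled copies of the protein; the
#' empirical p-value (1 + #shuffled >= observed) / (n_shuffles + 1) is
#' Bonferroni-multiplied by the number of models to give the reported
#' E-value. Hits with E-value strictly below `evalue_dom` are returned.
#' Pairs whose running shuffle count already rules out the cutoff stop
#' shuffling early; each pair uses its own RNG stream so results are
#' deterministic per seed.
#'
#' @param proteins protein [seq_set()] data.frame (or a single row).
#' @param models list of domain models (see [read_domain_models()]).
#' @param evalue_dom E-value cutoff (default 0.01, strict).
#' @param n_shuffles shuffled copies per pair (default 1000).
#' @param seed integer RNG seed.
#' @return data.frame protein_id, domain_name, category, start, end
#'   (0-based half-open), score, evalue.
#' @export
scan_domains <- function(proteins, models, evalue_dom = 0.01,
                         n_shuffles = 1000L, seed = 1L) {
  empty <- data.frame(protein_id = character(0), domain_name = character(0),
                      category = character(0), start = integer(0),
                      end = integer(0), score = integer(0),
                      evalue = numeric(0), stringsAsFactors = FALSE)
  if (!length(models) || is.null(proteins) || nrow(proteins) == 0L)
    return(empty)
  nm <- length(models)
  thresh <- evalue_dom * (n_shuffles + 1) / nm - 1
  c_bound <- max(0L, as.integer(ceiling(thresh)))
  res <- cpp_scan_domains(proteins$seq,
                          lapply(models, function(m) m$pssm),
                          as.integer(n_shuffles), c_bound, as.integer(seed))
  rows <- list()
  np <- nrow(proteins)
  for (i in seq_len(np)) {
    for (j in seq_len(nm)) {
      idx <- (i - 1L) * nm + j
      if (is.na(res$obs[idx]) || res$done[idx] < n_shuffles) next
      p <- (1 + res$count[idx]) / (n_shuffles + 1)
      ev <- p * nm
      if (ev < evalue_dom) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = proteins$id[i], domain_name = models[[j]]$name,
          category = models[[j]]$category, start = res$start[idx],
          end = res$start[idx] + models[[j]]$length, score = res$obs[idx],
          evalue = ev, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

TRIAGE_CATEGORIES <- c("reference_homolog", "domain_annotated", "viral_like",
                       "novel")

#' Classify qualifying proteins through the annotation cascade
#'
#' Strict order: (1) any reference homolog -> `reference_homolog`;
#' (2) else any domain hit of non-viral category -> `domain_annotated`;
#' (3) else any viral-tagged domain hit -> `viral_like`; (4) else `novel`.
#' Categories are mutually exclusive and exhaustive over the qualifying set.
#'
#' @param summaries output of [aggregate_hits()].
#' @param ref_map output of [reference_homology()] (NULL when the reference
#'   stage was skipped).
#' @param domain_hits output of [scan_domains()] (NULL when skipped).
#' @return data.frame protein_id, n_unique_fragments, category, ref_id,
#'   ref_evalue, domains (comma-separated hit names).
#' @export
triage_classify <- function(summaries, ref_map = NULL, domain_hits = NULL) {
  n <- nrow(summaries)
  cat <- character(n); refid <- rep(NA_character_, n)
  refev <- rep(NA_real_, n); doms <- character(n)
  for (i in seq_len(n)) {
    pid <- summaries$protein_id[i]
    dh <- if (is.null(domain_hits)) NULL else
      domain_hits[domain_hits$protein_id == pid, , drop = FALSE]
    if (!is.null(dh) && nrow(dh))
      doms[i] <- paste(dh$domain_name, collapse = ",")
    ri <- if (is.null(ref_map)) integer(0) else which(ref_map$protein_id == pid)
    if (length(ri)) {
      cat[i] <- "reference_homolog"
      refid[i] <- ref_map$ref_id[ri[1]]
      refev[i] <- ref_map$evalue[ri[1]]
    } else if (!is.null(dh) && any(dh$category != "viral")) {
      cat[i] <- "domain_annotated"
    } else if (!is.null(dh) && nrow(dh) && all(dh$category == "viral")) {
      cat[i] <- "viral_like"
    } else {
      cat[i] <- "novel"
    }
  }
  data.frame(protein_id = summaries$protein_id,
             n_unique_fragments = summaries$n_unique_fragments,
             category = cat, ref_id = refid, ref_evalue = refev,
             domains = doms, stringsAsFactors = FALSE)
}

#' Count triage categories
#'
#' @param records output of [triage_classify()].
#' @return named integer vector over the four categories (zeros included).
#' @export
count_categories <- function(records) {
  counts <- setNames(integer(length(TRIAGE_CATEGORIES)), TRIAGE_CATEGORIES)
  if (!is.null(records) && nrow(records)) {
    tab <- table(records$category)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Write a domain-model collection
#'
#' Plain-text blocks: a header line `>name category length` followed by
#' `length` rows of 20 tab-separated integer scores (columns in
#' alphabetical amino-acid order A,C,D,...,Y).
#'
#' @param models list of domain models.
#' @param path output path.
#' @export
write_domain_models <- function(models, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (m in models) {
    writeLines(sprintf(">%s %s %d", m$name, m$category, m$length), con, sep = "\n")
    writeLines(apply(m$pssm, 1, paste, collapse = "\t"), con, sep = "\n")
  }
  invisible(path)
}

#' Read a domain-model collection
#'
#' @param path file written by [write_domain_models()].
#' @return list of models, each list(name, category, length, pssm,
#'   consensus) where consensus is the per-position argmax residue.
#' @export
read_domain_models <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (!length(hdr))
    viromimic_error("no domain models found", "viromimic_io_error")
  models <- vector("list", length(hdr))
  bounds <- c(hdr, length(lines) + 1L)
  for (k in seq_along(hdr)) {
    parts <- strsplit(sub("^>", "", lines[hdr[k]]), "\\s+")[[1]]
    len <- as.integer(parts[3])
    body <- lines[(hdr[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(body) != len)
      viromimic_error(sprintf("model '%s': expected %d rows, found %d",
                              parts[1], len, length(body)),
                      "viromimic_io_error")
    pssm <- do.call(rbind, lapply(strsplit(body, "\t", fixed = TRUE),
                                  as.integer))
    colnames(pssm) <- AA20
    models[[k]] <- list(name = parts[1], category = parts[2], length = len,
                        pssm = pssm,
                        consensus = paste0(AA20[apply(pssm, 1, which.max)],
                                           collapse = ""))
  }
  models
}
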