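#' @name enrichment
#' @title Domain-category enrichment testing
#'
#' @description Compares the frequency of PAMP-sensing and apoptosis
#' domains between the virome-identified candidate set and the whole
#' proteome (the baseline includes the candidates). Frequencies are
#' presence/absence proportions — the fraction of proteins in a set
#' carrying at least one hit to the domain. Per category, candidate and
#' proteome frequencies are paired across domains and compared with a
#' paired two-tailed t-test.
NULL

#' Default domain category map
#'
#' PAMP-sensing: NACHT, LRR_1, Lectin_C, TIR, MASP_R. Apoptosis: TNF,
#' TNFR, DED, CARD, Pep_C14.
#' @return named list category -> character vector of domain names.
#' @export
default_category_map <- function() {
  list(PAMP = c("NACHT", "LRR_1", "Lectin_C", "TIR", "MASP_R"),
       apoptosis = c("TNF", "TNFR", "DED", "CARD", "Pep_C14"))
}

#' Per-domain presence frequencies in a protein set
#'
#' @param protein_ids non-empty character vector of protein ids.
#' @param domain_hits [scan_domains()] output.
#' @param category_map named list category -> domain names.
#' @return data.frame category, domain, freq (proportion of proteins in the
#'   set with >= 1 hit to that domain; 0 when absent).
#' @export
domain_frequencies <- function(protein_ids, domain_hits, category_map) {
  protein_ids <- unique(protein_ids)
  if (!length(protein_ids))
    viromimic_error("protein set is empty", "viromimic_param_error")
  doms <- unlist(category_map, use.names = FALSE)
  if (anyDuplicated(doms))
    viromimic_error("domain names must be unique across categories",
                    "viromimic_param_error")
  cats <- rep(names(category_map), lengths(category_map))
  dh <- domain_hits[domain_hits$protein_id %in% protein_ids, , drop = FALSE]
  freq <- vapply(doms, function(d)
    length(unique(dh$protein_id[dh$domain_name == d])) / length(protein_ids),
    numeric(1))
  data.frame(category = cats, domain = doms, freq = unname(freq),
             stringsAsFactors = FALSE)
}

#' Paired two-tailed t-test
#'
#' Differences d = x - y; t = mean(d) / (sd(d)/sqrt(n)) with the sample
#' standard deviation (n-1 denominator); df = n-1; two-tailed p from the
#' Student-t survival function. A zero-variance difference vector is an
#' error (degenerate), never a silent p-value.
#'
#' @param x,y paired numeric vectors of equal length n >= 2.
#' @return list(t, df, p).
#' @export
paired_t_test <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 2L)
    viromimic_error("paired vectors of equal length n >= 2 required",
                    "viromimic_param_error")
  d <- x - y
  s <- sd(d)
  if (s == 0)
    viromimic_error("zero variance of paired differences",
                    "viromimic_degenerate_error")
  t <- mean(d) / (s / sqrt(n))
  df <- n - 1L
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

#' Domain-category enrichment of a candidate set
#'
#' @param candidate_ids candidate protein ids (subset of
#'   `all_protein_ids`).
#' @param all_protein_ids whole-proteome ids (the baseline; includes the
#'   candidates).
#' @param domain_hits [scan_domains()] output covering the whole proteome.
#' @param category_map named list category -> domain names (each category
#'   needs >= 2 domains).
#' @return data.frame with one row per category: category, n_domains,
#'   t_stat, df, p_two_tailed, plus attribute "pairs" holding the
#'   per-domain frequency pairs.
#' @export
enrichment_test <- function(candidate_ids, all_protein_ids, domain_hits,
                            category_map = default_category_map()) {
  if (!all(candidate_ids %in% all_protein_ids))
    viromimic_error("candidate ids must be a subset of the proteome ids",
                    "viromimic_param_error")
  if (any(lengths(category_map) < 2L))
    viromimic_error("each category needs at least 2 domains",
                    "viromimic_param_error")
  fc <- domain_frequencies(candidate_ids, domain_hits, category_map)
  fa <- domain_frequencies(all_protein_ids, domain_hits, category_map)
  pairs <- data.frame(category = fc$category, domain = fc$domain,
                      freq_candidates = fc$freq, freq_proteome = fa$freq,
                      stringsAsFactors = FALSE)
  rows <- lapply(names(category_map), function(cat) {
    sel <- pairs$category == cat
    tt <- paired_t_test(pairs$freq_candidates[sel], pairs$freq_proteome[sel])
    data.frame(category = cat, n_domains = sum(sel), t_stat = tt$t,
               df = tt$df, p_two_tailed = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "pairs") <- pairs
  out
}
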