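#' @name mimicry_sim
#' @title Ground-truthed viral-mimicry simulator
#'
#' @description Generates the synthetic study system: a host proteome with
#' a designated immune subset carrying planted domain-consensus
#' subsequences, viral genomes embedding reverse-translated, point-mutated
#' copies of segments of those immune proteins at a controlled amino-acid
#' identity (on both strands), a diverged reference proteome covering only
#' part of the host proteome, and a PSSM domain collection — plus a ground
#' truth mapping planted mimic regions to their source proteins so that
#' pipeline sensitivity and precision can be scored exactly.
NULL

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation parameters
#'
#' Defaults are the standard scenario: 500 host proteins of 150-600 aa,
#' 50 immune targets mimicked at 70% amino-acid identity over 100-aa
#' segments with 4 copies per target, 10 viral genomes of 50 kb fragmented
#' at 200 bp, a reference proteome covering 60% of the host proteome at
#' 50% identity, and the >= 5-unique-fragment candidate rule.
#'
#' @param n_proteins,protein_len_range,n_immune host-proteome shape.
#' @param mimic_identity,mimic_len,copies_per_target planted mimic design.
#' @param n_genomes,genome_len,frag_len virome design (nt).
#' @param ref_coverage,ref_identity reference-proteome design.
#' @param min_fragments candidate rule used to validate the mimic design.
#' @param seed integer RNG seed.
#' @return validated parameter list of class `sim_params`.
#' @export
sim_params <- function(n_proteins = 500L, protein_len_range = c(150L, 600L),
                       n_immune = 50L, mimic_identity = 0.7, mimic_len = 100L,
                       copies_per_target = 4L, n_genomes = 10L,
                       genome_len = 50000L, frag_len = 200L,
                       ref_coverage = 0.6, ref_identity = 0.5,
                       min_fragments = 5L, seed = 1L) {
  p <- list(n_proteins = as.integer(n_proteins),
            protein_len_range = as.integer(protein_len_range),
            n_immune = as.integer(n_immune), mimic_identity = mimic_identity,
            mimic_len = as.integer(mimic_len),
            copies_per_target = as.integer(copies_per_target),
            n_genomes = as.integer(n_genomes),
            genome_len = as.integer(genome_len),
            frag_len = as.integer(frag_len), ref_coverage = ref_coverage,
            ref_identity = ref_identity,
            min_fragments = as.integer(min_fragments), seed = as.integer(seed))
  if (p$n_immune > p$n_proteins)
    viromimic_error("n_immune must not exceed n_proteins",
                    "viromimic_param_error")
  if (p$mimic_identity <= 0 || p$mimic_identity > 1)
    viromimic_error("mimic_identity must be in (0, 1]", "viromimic_param_error")
  if (p$mimic_len * 3L > p$genome_len)
    viromimic_error("mimic_len too long for genome_len", "viromimic_param_error")
  if (p$copies_per_target * p$mimic_len * 3L < p$min_fragments * p$frag_len)
    viromimic_error(
      "copies_per_target * mimic_len * 3 must cover min_fragments fragments",
      "viromimic_param_error")
  if (p$ref_coverage < 0 || p$ref_coverage > 1)
    viromimic_error("ref_coverage must be in [0, 1]", "viromimic_param_error")
  if (p$mimic_len > p$protein_len_range[1])
    viromimic_error("mimic_len must fit the shortest protein",
                    "viromimic_param_error")
  structure(p, class = "sim_params")
}

# standard genetic code as aa -> codons (bases A,C,G,T)
.codon_table <- function() {
  if (!is.null(.pkg_cache$codons)) return(.pkg_cache$codons)
  bases <- c("T", "C", "A", "G")
  aas <- strsplit("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG",
                  "")[[1]]
  codons <- character(64)
  k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  tab <- split(codons, aas)
  .pkg_cache$codons <- tab
  tab
}

#' Reverse complement of a nucleotide string
#' @param nuc nucleotide string.
#' @return reverse complement (N maps to N).
#' @export
reverse_complement <- function(nuc) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(nuc, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Reverse-translate a protein segment
#'
#' Chooses uniformly among synonymous codons; the round trip
#' `translate(result, +1)` reproduces the segment exactly.
#'
#' @param protein_segment protein string (no X).
#' @param seed RNG seed.
#' @return nucleotide string of length 3 * nchar(segment).
#' @export
reverse_translate <- function(protein_segment, seed = 1L) {
  tab <- .codon_table()
  aas <- strsplit(protein_segment, "", fixed = TRUE)[[1]]
  if (any(!aas %in% names(tab)) || any(aas == "*"))
    viromimic_error(sprintf("residue without codon: '%s'",
                            setdiff(aas, setdiff(names(tab), "*"))[1]),
                    "viromimic_param_error")
  with_seed(seed, {
    paste(vapply(aas, function(a) {
      cs <- tab[[a]]
      cs[sample.int(length(cs), 1L)]
    }, character(1)), collapse = "")
  })
}

#' Mutate a coding region to a target amino-acid identity
#'
#' Applies amino-acid-changing codon substitutions at randomly chosen
#' codons until the translated identity to the original segment equals
#' `round(target_identity * len) / len` exactly. No indels.
#'
#' @param nuc in-frame coding nucleotide string (length divisible by 3).
#' @param target_identity target amino-acid identity in (0, 1].
#' @param seed RNG seed.
#' @return mutated nucleotide string of the same length.
#' @export
mutate_to_identity <- function(nuc, target_identity, seed = 1L) {
  if (target_identity <= 0 || target_identity > 1)
    viromimic_error("target_identity must be in (0, 1]", "viromimic_param_error")
  aa <- translate(nuc, 1L)
  len <- nchar(aa)
  n_keep <- round(target_identity * len)
  if (n_keep < 1)
    viromimic_error("target identity below 1/len is unreachable",
                    "viromimic_param_error")
  n_mut <- len - n_keep
  if (n_mut == 0L) return(nuc)
  tab <- .codon_table()
  with_seed(seed, {
    posns <- sample.int(len, n_mut)
    codons <- substring(nuc, 3L * (seq_len(len) - 1L) + 1L, 3L * seq_len(len))
    orig <- strsplit(aa, "", fixed = TRUE)[[1]]
    for (p in posns) {
      alt <- setdiff(AA20, orig[p])
      new_aa <- alt[sample.int(length(alt), 1L)]
      cs <- tab[[new_aa]]
      codons[p] <- cs[sample.int(length(cs), 1L)]
    }
    paste(codons, collapse = "")
  })
}

#' Generate a PSSM domain-model collection
#'
#' Each model has a random consensus sequence and a caricature log-odds
#' PSSM scoring +4 on the consensus residue and -2 elsewhere. Categories
#' are assigned round-robin; PAMP and apoptosis models take the canonical
#' domain names (NACHT, LRR_1, ... / TNF, TNFR, ...) so the default
#' category map applies, viral/other models get generated names.
#'
#' @param n_models number of models (default 10, the largest collection
#'   for which a hit can clear the 0.01 Bonferroni-corrected cutoff at
#'   1000 shuffles).
#' @param length model length in positions (default 12).
#' @param categories category cycle (default PAMP, apoptosis, viral).
#' @param seed RNG seed.
#' @return list of domain models (name, category, length, pssm, consensus).
#' @export
generate_domain_models <- function(n_models = 10L, length = 12L,
                                   categories = c("PAMP", "apoptosis",
                                                  "viral"),
                                   seed = 1L) {
  pools <- list(PAMP = default_category_map()$PAMP,
                apoptosis = default_category_map()$apoptosis)
  used <- c(PAMP = 0L, apoptosis = 0L, viral = 0L, other = 0L)
  with_seed(seed, {
    lapply(seq_len(n_models), function(i) {
      cat <- categories[(i - 1L) %% base::length(categories) + 1L]
      used[cat] <<- used[cat] + 1L
      name <- if (cat %in% names(pools) && used[cat] <= base::length(pools[[cat]]))
        pools[[cat]][used[cat]] else paste0(toupper(substr(cat, 1, 3)), "DOM",
                                            used[cat])
      cons <- sample(AA20, length, replace = TRUE)
      pssm <- matrix(-2L, nrow = length, ncol = 20L,
                     dimnames = list(NULL, AA20))
      pssm[cbind(seq_len(length), match(cons, AA20))] <- 4L
      list(name = name, category = cat, length = as.integer(length),
           pssm = pssm, consensus = paste0(cons, collapse = ""))
    })
  })
}

#' Category map for a generated model collection
#'
#' @param models [generate_domain_models()] output.
#' @return named list restricted to PAMP and apoptosis model names.
#' @export
sim_category_map <- function(models) {
  cats <- vapply(models, `[[`, character(1), "category")
  nms <- vapply(models, `[[`, character(1), "name")
  list(PAMP = nms[cats == "PAMP"], apoptosis = nms[cats == "apoptosis"])
}

#' Generate the host proteome with a designated immune subset
#'
#' Residues are drawn i.i.d. from the substitution-matrix background
#' (Robinson-Robinson); lengths are uniform over `protein_len_range`. The
#' immune subset receives planted domain-consensus subsequences: 42% of
#' the targets carry a PAMP-sensing domain, 42% an apoptosis domain, 8% a
#' viral-tagged domain and 8% none. Within a category the allocation is
#' near-balanced but deliberately unequal (first model one extra, last one
#' fewer), so the paired enrichment differences never have exactly zero
#' variance; the triage cascade can yield all four classes and
#' PAMP/apoptosis enrichment is testable. Non-immune proteins carry a
#' uniformly chosen domain with probability `bg_domain_rate`, giving the
#' proteome a realistic domain background.
#'
#' @param params [sim_params()].
#' @param models [generate_domain_models()] output.
#' @param seed RNG seed (default from params).
#' @param bg_domain_rate probability that a non-immune protein carries a
#'   (uniformly chosen) planted domain (default 0.15).
#' @return list(proteome = [seq_set()], immune_ids, domain_assignments =
#'   named character vector protein_id -> planted domain name (NA for the
#'   no-domain slot)).
#' @export
generate_proteome <- function(params, models, seed = params$seed,
                              bg_domain_rate = 0.15) {
  p <- params
  cats <- vapply(models, `[[`, character(1), "category")
  nms <- vapply(models, `[[`, character(1), "name")
  # immune category counts: 42/42/8/8% of targets, remainder to no-domain
  n_pamp <- round(0.42 * p$n_immune)
  n_apo <- round(0.42 * p$n_immune)
  n_vir <- round(0.08 * p$n_immune)
  n_none <- p$n_immune - n_pamp - n_apo - n_vir
  fill <- function(names_in_cat, n) {
    k <- length(names_in_cat)
    if (!k || n <= 0) return(character(0))
    counts <- rep(n %/% k, k)
    r <- n %% k
    if (r > 0) counts[seq_len(r)] <- counts[seq_len(r)] + 1L
    if (k >= 2L && counts[k] >= 1L) {   # force an unequal split
      counts[1L] <- counts[1L] + 1L
      counts[k] <- counts[k] - 1L
    }
    rep(names_in_cat, counts)
  }
  plan <- c(fill(nms[cats == "PAMP"], n_pamp),
            fill(nms[cats == "apoptosis"], n_apo),
            fill(nms[cats == "viral"], n_vir),
            rep(NA_character_, n_none))
  with_seed(seed, {
    lens <- sample(p$protein_len_range[1]:p$protein_len_range[2],
                   p$n_proteins, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(names(ROBINSON_BG), L, replace = TRUE,
                   prob = ROBINSON_BG), collapse = ""), character(1))
    ids <- sprintf("prot%04d", seq_len(p$n_proteins))
    immune <- sort(sample.int(p$n_proteins, p$n_immune))
    plant <- function(i, dom) {
      m <- models[[match(dom, nms)]]
      start <- sample.int(lens[i] - m$length + 1L, 1L)
      substr(seqs[i], start, start + m$length - 1L) <<- m$consensus
    }
    assign <- setNames(plan, ids[immune])
    for (k in seq_along(immune))
      if (!is.na(plan[k])) plant(immune[k], plan[k])
    non_immune <- setdiff(seq_len(p$n_proteins), immune)
    bg <- non_immune[runif(length(non_immune)) < bg_domain_rate]
    for (i in bg) plant(i, nms[sample.int(length(nms), 1L)])
    list(proteome = seq_set(ids, seqs),
         immune_ids = ids[immune], domain_assignments = assign)
  })
}

#' Generate viral genomes carrying planted mimics, with ground truth
#'
#' Genomes are uniform random nucleotide sequences; for each immune
#' target, `copies_per_target` reverse-translated, identity-mutated copies
#' of random segments of the protein are written into the genomes at
#' non-overlapping positions, alternate copies on the minus strand.
#'
#' @param proteome [seq_set()] host proteome.
#' @param immune_ids ids of the mimic-target proteins.
#' @param params [sim_params()].
#' @param seed RNG seed (default from params).
#' @return list(genomes = [seq_set()], truth = data.frame(genome_id, start,
#'   end, protein_id, protein_start, protein_end, strand)).
#' @export
generate_virome <- function(proteome, immune_ids, params,
                            seed = params$seed) {
  p <- params
  region_len <- 3L * p$mimic_len
  n_place <- length(immune_ids) * p$copies_per_target
  if (n_place * region_len > 0.5 * p$n_genomes * p$genome_len)
    viromimic_error("insufficient genome space for mimic placements",
                    "viromimic_param_error")
  with_seed(seed + 1L, {
    genomes <- vapply(seq_len(p$n_genomes), function(i)
      paste(sample(c("A", "C", "G", "T"), p$genome_len, replace = TRUE),
            collapse = ""), character(1))
    gids <- sprintf("genome%02d", seq_len(p$n_genomes))
    occupied <- lapply(seq_len(p$n_genomes), function(i)
      data.frame(start = integer(0), end = integer(0)))
    truth <- list()
    ci <- 0L
    for (t in seq_along(immune_ids)) {
      pid <- immune_ids[t]
      prot <- proteome$seq[proteome$id == pid]
      plen <- nchar(prot)
      for (cp in seq_len(p$copies_per_target)) {
        ci <- ci + 1L
        g <- (ci - 1L) %% p$n_genomes + 1L
        seg_start <- sample.int(plen - p$mimic_len + 1L, 1L)
        seg <- substr(prot, seg_start, seg_start + p$mimic_len - 1L)
        sub_seed <- (p$seed * 1000L + ci) %% .Machine$integer.max
        nt <- reverse_translate(seg, seed = sub_seed)
        nt <- mutate_to_identity(nt, p$mimic_identity, seed = sub_seed + 1L)
        strand <- if (cp %% 2L == 1L) "+" else "-"
        ins <- if (strand == "+") nt else reverse_complement(nt)
        # non-overlapping placement by rejection sampling
        occ <- occupied[[g]]
        pos <- NA_integer_
        for (try in 1:1000) {
          cand <- sample.int(p$genome_len - region_len + 1L, 1L) - 1L
          if (!any(cand < occ$end & (cand + region_len) > occ$start)) {
            pos <- cand
            break
          }
        }
        if (is.na(pos))
          viromimic_error("insufficient genome space for mimic placements",
                          "viromimic_param_error")
        occupied[[g]] <- rbind(occ, data.frame(start = pos,
                                               end = pos + region_len))
        substr(genomes[g], pos + 1L, pos + region_len) <- ins
        truth[[ci]] <- data.frame(
          genome_id = gids[g], start = pos, end = pos + region_len,
          protein_id = pid, protein_start = seg_start - 1L,
          protein_end = seg_start - 1L + p$mimic_len, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(genome_id = character(0), start = integer(0),
                 end = integer(0), protein_id = character(0),
                 protein_start = integer(0), protein_end = integer(0),
                 strand = character(0), stringsAsFactors = FALSE)
    list(genomes = seq_set(gids, genomes), truth = truth)
  })
}

#' Generate a diverged, partial reference proteome
#'
#' A `ref_coverage` fraction of host proteins is copied with random
#' amino-acid substitutions down to `ref_identity`; the remaining host
#' proteins have no reference homolog.
#'
#' @param host_proteome [seq_set()] host proteome.
#' @param ref_coverage fraction of host proteins covered, in [0, 1].
#' @param ref_identity amino-acid identity of the copies.
#' @param seed RNG seed.
#' @param exclude_ids host protein ids guaranteed to stay uncovered (the
#'   coverage fraction still applies to the whole proteome).
#' @return [seq_set()] of reference proteins (ids `ref_<host id>`), with
#'   attribute `covered_ids` listing the covered host proteins.
#' @export
generate_reference_proteome <- function(host_proteome, ref_coverage,
                                        ref_identity, seed = 1L,
                                        exclude_ids = character(0)) {
  n <- nrow(host_proteome)
  eligible <- which(!host_proteome$id %in% exclude_ids)
  with_seed(seed + 2L, {
    n_cov <- min(round(ref_coverage * n), length(eligible))
    covered <- sort(eligible[sample.int(length(eligible), n_cov)])
    seqs <- character(n_cov)
    for (k in seq_along(covered)) {
      s <- host_proteome$seq[covered[k]]
      chars <- strsplit(s, "", fixed = TRUE)[[1]]
      len <- length(chars)
      n_sub <- len - round(ref_identity * len)
      if (n_sub > 0L) {
        posns <- sample.int(len, n_sub)
        for (p in posns) {
          alt <- setdiff(AA20, chars[p])
          chars[p] <- alt[sample.int(length(alt), 1L)]
        }
      }
      seqs[k] <- paste(chars, collapse = "")
    }
    out <- seq_set(paste0("ref_", host_proteome$id[covered]), seqs)
    attr(out, "covered_ids") <- host_proteome$id[covered]
    out
  })
}

#' Simulate the full study system
#'
#' @param params [sim_params()].
#' @return list(params, models, category_map, proteome, immune_ids,
#'   domain_assignments, genomes, truth, reference, ref_covered_ids).
#' @export
simulate_scenario <- function(params = sim_params()) {
  models <- generate_domain_models(seed = params$seed)
  pr <- generate_proteome(params, models)
  vir <- generate_virome(pr$proteome, pr$immune_ids, params)
  # keep one viral-domain target and one domain-free target out of the
  # reference so the viral_like and novel triage classes are attainable
  cats <- setNames(vapply(models, `[[`, character(1), "category"),
                   vapply(models, `[[`, character(1), "name"))
  da <- pr$domain_assignments
  hold_out <- c(names(da)[!is.na(da) & cats[da] == "viral"][1],
                names(da)[is.na(da)][1])
  ref <- generate_reference_proteome(pr$proteome, params$ref_coverage,
                                     params$ref_identity, seed = params$seed,
                                     exclude_ids = hold_out[!is.na(hold_out)])
  list(params = params, models = models,
       category_map = sim_category_map(models),
       proteome = pr$proteome, immune_ids = pr$immune_ids,
       domain_assignments = pr$domain_assignments,
       genomes = vir$genomes, truth = vir$truth,
       reference = ref, ref_covered_ids = attr(ref, "covered_ids"))
}

#' Sensitivity and precision of a recovered candidate set
#'
#' @param recovered_ids protein ids recovered by the pipeline.
#' @param target_ids planted immune target ids (the truth).
#' @return list(sensitivity, precision, n_recovered, n_targets).
#' @export
score_recovery <- function(recovered_ids, target_ids) {
  tp <- length(intersect(recovered_ids, target_ids))
  list(sensitivity = if (length(target_ids)) tp / length(target_ids) else NA_real_,
       precision = if (length(recovered_ids)) tp / length(recovered_ids) else NA_real_,
       n_recovered = length(recovered_ids), n_targets = length(target_ids))
}
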