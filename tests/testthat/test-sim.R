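test_that("sim_params validates the scenario design", {
  expect_s3_class(sim_params(), "sim_params")
  expect_error(sim_params(n_immune = 600), class = "viromimic_param_error")
  expect_error(sim_params(mimic_identity = 0), class = "viromimic_param_error")
  expect_error(sim_params(mimic_identity = 1.2), class = "viromimic_param_error")
  expect_error(sim_params(copies_per_target = 1, mimic_len = 100,
                          frag_len = 200, min_fragments = 5),
               class = "viromimic_param_error")
  expect_error(sim_params(ref_coverage = 1.5), class = "viromimic_param_error")
  expect_error(sim_params(mimic_len = 200, protein_len_range = c(150, 600)),
               class = "viromimic_param_error")
})

test_that("reverse_translate round-trips through translation", {
  set.seed(61)
  seg <- random_protein(80)
  nt <- reverse_translate(seg, seed = 9)
  expect_identical(nchar(nt), 240L)
  expect_identical(translate(nt, 1), seg)
  # deterministic per seed, varying across seeds
  expect_identical(reverse_translate(seg, seed = 9), nt)
  expect_false(identical(reverse_translate(seg, seed = 10), nt))
  expect_error(reverse_translate("AX"), class = "viromimic_param_error")
})

test_that("reverse_complement is a self-inverse base swap", {
  expect_identical(reverse_complement("ACGTN"), "NACGT")
  set.seed(62)
  s <- random_dna(101)
  expect_identical(reverse_complement(reverse_complement(s)), s)
})

test_that("mutate_to_identity hits the target amino-acid identity exactly", {
  set.seed(63)
  seg <- random_protein(100)
  nt <- reverse_translate(seg, seed = 1)
  for (target in c(0.7, 0.5, 0.93)) {
    mut <- mutate_to_identity(nt, target, seed = 2)
    expect_identical(nchar(mut), nchar(nt))
    aa <- translate(mut, 1)
    expect_equal(identity_frac(aa, seg), round(target * 100) / 100)
  }
  expect_identical(mutate_to_identity(nt, 1), nt)
  expect_error(mutate_to_identity(nt, 0), class = "viromimic_param_error")
})

test_that("generated domain models are scorable PSSM caricatures", {
  models <- generate_domain_models(seed = 2)
  expect_identical(length(models), 10L)
  cats <- vapply(models, `[[`, character(1), "category")
  expect_setequal(unique(cats), c("PAMP", "apoptosis", "viral"))
  nms <- vapply(models, `[[`, character(1), "name")
  expect_true(all(c("NACHT", "TNF") %in% nms))
  expect_identical(anyDuplicated(nms), 0L)
  for (m in models) {
    expect_identical(dim(m$pssm), c(m$length, 20L))
    # consensus is the per-position argmax
    cons <- strsplit(m$consensus, "")[[1]]
    expect_identical(colnames(m$pssm)[apply(m$pssm, 1, which.max)], cons)
  }
  cm <- sim_category_map(models)
  expect_true(all(lengths(cm) >= 2))
  expect_true(all(unlist(cm) %in% nms))
})

test_that("the generated proteome has the designed shape and composition", {
  p <- sim_params(n_proteins = 300L, n_immune = 30L, seed = 5L)
  models <- generate_domain_models(seed = 5)
  pr <- generate_proteome(p, models)
  expect_identical(nrow(pr$proteome), 300L)
  expect_identical(length(pr$immune_ids), 30L)
  expect_true(all(pr$immune_ids %in% pr$proteome$id))
  lens <- nchar(pr$proteome$seq)
  expect_true(all(lens >= 150 & lens <= 600))
  # immune proteins carry their assigned domain consensus verbatim
  nms <- vapply(models, `[[`, character(1), "name")
  for (pid in names(pr$domain_assignments)) {
    dom <- pr$domain_assignments[[pid]]
    if (is.na(dom)) next
    cons <- models[[match(dom, nms)]]$consensus
    expect_true(grepl(cons, pr$proteome$seq[pr$proteome$id == pid],
                      fixed = TRUE))
  }
  # residue composition matches the background (chi-squared GOF)
  bg <- blosum62()$background
  bg <- bg[bg > 0]
  obs <- table(factor(strsplit(paste(pr$proteome$seq, collapse = ""),
                               "")[[1]], levels = names(bg)))
  gof <- suppressWarnings(chisq.test(as.integer(obs), p = bg / sum(bg)))
  expect_gt(gof$p.value, 1e-4)
  # deterministic
  pr2 <- generate_proteome(p, models)
  expect_identical(pr2$proteome$seq, pr$proteome$seq)
})

test_that("virome placements are in-bounds, non-overlapping and truthful", {
  p <- sim_params(n_proteins = 60L, n_immune = 6L, n_genomes = 2L,
                  genome_len = 20000L, seed = 7L)
  models <- generate_domain_models(seed = 7)
  pr <- generate_proteome(p, models)
  vir <- generate_virome(pr$proteome, pr$immune_ids, p)
  expect_identical(nrow(vir$genomes), 2L)
  expect_true(all(nchar(vir$genomes$seq) == 20000L))
  tr <- vir$truth
  expect_identical(nrow(tr), 6L * 4L)
  expect_true(all(tr$start >= 0 & tr$end <= 20000))
  expect_true(all(tr$end - tr$start == 300L))
  expect_setequal(unique(tr$protein_id), pr$immune_ids)
  # per-genome placements never overlap
  for (g in unique(tr$genome_id)) {
    tg <- tr[tr$genome_id == g, ]
    tg <- tg[order(tg$start), ]
    if (nrow(tg) > 1)
      expect_true(all(tg$start[-1] >= tg$end[-nrow(tg)]))
  }
  # each placement translates back to its protein segment at the designed
  # identity, on the recorded strand
  for (k in seq_len(nrow(tr))) {
    row <- tr[k, ]
    region <- substr(vir$genomes$seq[vir$genomes$id == row$genome_id],
                     row$start + 1, row$end)
    if (row$strand == "-") region <- reverse_complement(region)
    aa <- translate(region, 1)
    seg <- substr(pr$proteome$seq[pr$proteome$id == row$protein_id],
                  row$protein_start + 1, row$protein_end)
    expect_equal(identity_frac(aa, seg), 0.7)
  }
  # both strands are used
  expect_setequal(unique(tr$strand), c("+", "-"))
})

test_that("the reference proteome is a diverged partial copy", {
  p <- sim_params(n_proteins = 100L, n_immune = 10L, seed = 9L)
  models <- generate_domain_models(seed = 9)
  pr <- generate_proteome(p, models)
  ref <- generate_reference_proteome(pr$proteome, 0.6, 0.5, seed = 9)
  covered <- attr(ref, "covered_ids")
  expect_identical(nrow(ref), 60L)
  expect_identical(ref$id, paste0("ref_", covered))
  for (k in c(1L, 30L, 60L)) {
    host <- pr$proteome$seq[pr$proteome$id == covered[k]]
    expect_identical(nchar(ref$seq[k]), nchar(host))
    expect_equal(identity_frac(ref$seq[k], host),
                 round(0.5 * nchar(host)) / nchar(host))
  }
  # exclusions are honored without changing the covered count
  excl <- pr$proteome$id[1:5]
  ref2 <- generate_reference_proteome(pr$proteome, 0.6, 0.5, seed = 9,
                                      exclude_ids = excl)
  expect_identical(nrow(ref2), 60L)
  expect_true(!any(excl %in% attr(ref2, "covered_ids")))
})

test_that("simulate_scenario guarantees material for all four triage classes", {
  p <- sim_params(seed = 13L)
  sc <- simulate_scenario(p)
  da <- sc$domain_assignments
  cats <- setNames(vapply(sc$models, `[[`, character(1), "category"),
                   vapply(sc$models, `[[`, character(1), "name"))
  uncovered <- setdiff(names(da), sc$ref_covered_ids)
  # at least one viral-domain target and one domain-free target lack a
  # reference homolog
  expect_true(any(!is.na(da[uncovered]) &
                    cats[da[uncovered]] == "viral", na.rm = TRUE))
  expect_true(any(is.na(da[uncovered])))
  # and plenty of targets do have reference homologs
  expect_gt(length(intersect(names(da), sc$ref_covered_ids)), 10)
})

test_that("score_recovery computes sensitivity and precision", {
  r <- score_recovery(c("a", "b", "c"), c("b", "c", "d", "e"))
  expect_equal(r$sensitivity, 0.5)
  expect_equal(r$precision, 2 / 3)
  expect_identical(r$n_recovered, 3L)
  r0 <- score_recovery(character(0), c("a"))
  expect_equal(r0$sensitivity, 0)
  expect_true(is.na(r0$precision))
})
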