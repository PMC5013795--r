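make_hits <- function(protein, fragments, evalues) {
  n <- length(fragments)
  data.frame(qseqid = rep(protein, n), sseqid = fragments,
             pident = 90, length = 50L, mismatch = 5L, gapopen = 0L,
             qstart = 1L, qend = 50L, sstart = 1L, send = 150L,
             evalue = evalues, bitscore = 40, stringsAsFactors = FALSE)
}

test_that("aggregate_hits applies the strict >=5-unique-fragments rule", {
  # 5 unique fragments below cutoff qualifies
  h5 <- make_hits("p1", paste0("f", 1:5), rep(1e-6, 5))
  expect_identical(aggregate_hits(h5)$protein_id, "p1")
  # 4 unique fragments (5 HSPs, one fragment twice) does not
  h4 <- make_hits("p2", c("f1", "f1", "f2", "f3", "f4"), rep(1e-6, 5))
  expect_identical(nrow(aggregate_hits(h4)), 0L)
  # the E-value cutoff is strictly less-than
  hedge <- make_hits("p3", paste0("f", 1:5), c(rep(1e-6, 4), 1e-4))
  expect_identical(nrow(aggregate_hits(hedge)), 0L)
  hin <- make_hits("p4", paste0("f", 1:5), c(rep(1e-6, 4), 0.99e-4))
  expect_identical(aggregate_hits(hin)$protein_id, "p4")
})

test_that("aggregate_hits summarises and orders qualifying proteins", {
  h <- rbind(make_hits("b", paste0("f", 1:5), rep(1e-6, 5)),
             make_hits("a", paste0("g", 1:7), rep(1e-8, 7)),
             make_hits("c", paste0("h", 1:5), rep(1e-5, 5)))
  s <- aggregate_hits(h)
  expect_identical(s$protein_id, c("a", "b", "c"))   # by count desc, then id
  expect_identical(s$n_unique_fragments, c(7L, 5L, 5L))
  expect_equal(s$best_evalue, c(1e-8, 1e-6, 1e-5))
  expect_identical(nrow(aggregate_hits(empty_hit_table())), 0L)
})

test_that("reference_homology keeps the best sub-cutoff hit per candidate", {
  set.seed(21)
  core <- random_protein(80)
  cands <- seq_set("cand", core)
  ref <- seq_set(c("ref_yes", "ref_no"),
                 c(paste0(core, random_protein(10)), random_protein(90)))
  rm <- reference_homology(cands, ref)
  expect_identical(rm$protein_id, "cand")
  expect_identical(rm$ref_id, "ref_yes")
  expect_lt(rm$evalue, 1e-5)
  expect_error(reference_homology(cands, ref[0, ]),
               class = "viromimic_param_error")
})

test_that("scan_domains detects planted consensus and respects the null", {
  models <- generate_domain_models(seed = 3)
  m1 <- models[[1]]
  set.seed(22)
  prot <- random_protein(200)
  substr(prot, 50, 49 + m1$length) <- m1$consensus
  planted <- seq_set("withdom", prot)
  hits <- scan_domains(planted, models, seed = 1)
  hit1 <- hits[hits$domain_name == m1$name, ]
  expect_identical(nrow(hit1), 1L)
  expect_identical(hit1$start, 49L)                 # 0-based
  expect_identical(hit1$end, 49L + m1$length)
  expect_identical(hit1$score, 4L * m1$length)
  # minimum attainable E-value: Bonferroni over models at 1000 shuffles
  expect_equal(hit1$evalue, length(models) / 1001)
  # a random protein of the same composition yields no hits
  set.seed(23)
  rand <- seq_set("plain", random_protein(200))
  expect_identical(nrow(scan_domains(rand, models, seed = 1)), 0L)
  # deterministic for a fixed seed
  expect_identical(scan_domains(planted, models, seed = 5),
                   scan_domains(planted, models, seed = 5))
})

test_that("the triage cascade reproduces a constructed 20/10/5/15 fixture", {
  ids <- sprintf("p%03d", 1:50)
  summaries <- data.frame(protein_id = ids, n_unique_fragments = 6L,
                          n_hsps = 8L, best_evalue = 1e-9,
                          stringsAsFactors = FALSE)
  ref_map <- data.frame(protein_id = ids[1:20],
                        ref_id = paste0("ref_", ids[1:20]), evalue = 1e-10,
                        stringsAsFactors = FALSE)
  domain_hits <- data.frame(
    protein_id = c(ids[21:30], ids[31:35], ids[15]),
    domain_name = c(rep("NACHT", 10), rep("VIRDOM1", 5), "TNF"),
    category = c(rep("PAMP", 10), rep("viral", 5), "apoptosis"),
    start = 0L, end = 12L, score = 48L, evalue = 0.005,
    stringsAsFactors = FALSE)
  tr <- triage_classify(summaries, ref_map, domain_hits)
  counts <- count_categories(tr)
  expect_identical(unname(counts),
                   c(20L, 10L, 5L, 15L))
  expect_identical(names(counts),
                   c("reference_homolog", "domain_annotated", "viral_like",
                     "novel"))
  # reference homology shadows domain evidence (p015 has a TNF hit)
  expect_identical(tr$category[tr$protein_id == "p015"], "reference_homolog")
  # mixed viral + non-viral domains classify as domain_annotated
  mixed <- rbind(domain_hits,
                 data.frame(protein_id = ids[21], domain_name = "VIRDOM1",
                            category = "viral", start = 0L, end = 12L,
                            score = 48L, evalue = 0.005,
                            stringsAsFactors = FALSE))
  tr2 <- triage_classify(summaries, ref_map, mixed)
  expect_identical(tr2$category[tr2$protein_id == "p021"], "domain_annotated")
})

test_that("triage categories always partition the qualifying set", {
  set.seed(24)
  for (rep in 1:20) {
    n <- sample(1:40, 1)
    ids <- sprintf("x%03d", seq_len(n))
    summaries <- data.frame(protein_id = ids, n_unique_fragments = 5L,
                            n_hsps = 5L, best_evalue = 1e-8,
                            stringsAsFactors = FALSE)
    refn <- sample(0:n, 1)
    ref_map <- data.frame(protein_id = sample(ids, refn),
                          ref_id = rep("r", refn), evalue = rep(1e-9, refn),
                          stringsAsFactors = FALSE)
    domn <- sample(0:n, 1)
    dh <- data.frame(protein_id = sample(ids, domn, replace = TRUE),
                     domain_name = rep("D", domn),
                     category = sample(c("PAMP", "apoptosis", "viral"), domn,
                                       replace = TRUE),
                     start = rep(0L, domn), end = rep(12L, domn),
                     score = rep(48L, domn), evalue = rep(0.005, domn),
                     stringsAsFactors = FALSE)
    tr <- triage_classify(summaries, ref_map, dh)
    counts <- count_categories(tr)
    expect_identical(sum(counts), n)                       # exhaustive
    expect_true(all(tr$category %in% names(counts)))       # exclusive labels
    expect_identical(anyDuplicated(tr$protein_id), 0L)
  }
})

test_that("domain models round-trip through their text format", {
  models <- generate_domain_models(seed = 4)
  path <- tempfile()
  write_domain_models(models, path)
  back <- read_domain_models(path)
  expect_identical(length(back), length(models))
  for (k in seq_along(models)) {
    expect_identical(back[[k]]$name, models[[k]]$name)
    expect_identical(back[[k]]$category, models[[k]]$category)
    expect_identical(unname(back[[k]]$pssm), unname(models[[k]]$pssm))
    expect_identical(back[[k]]$consensus, models[[k]]$consensus)
  }
  # malformed collection: wrong number of PSSM rows
  lines <- readLines(path)
  writeLines(lines[-2], path)
  expect_error(read_domain_models(path), class = "viromimic_io_error")
})
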