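test_that("translate implements six-frame tBLASTn semantics", {
  expect_identical(translate("ATGAAA", 1), "MK")
  expect_identical(translate("ATGAAA", 2), "*")        # TGA + trailing AA
  expect_identical(translate("ATGAAA", 3), "E")        # GAA + trailing AA
  # minus frames read the reverse complement
  rc <- reverse_complement("ATGAAA")                   # TTTCAT
  expect_identical(translate("ATGAAA", -1), translate(rc, 1))
  expect_identical(translate("ATGAAA", -2), translate(rc, 2))
  # N-containing codons become X; stops are '*'
  expect_identical(translate("ATNAAA", 1), "XK")
  expect_identical(translate("TAATAG", 1), "**")
  expect_error(translate("ATG", 4), class = "viromimic_param_error")
  expect_error(translate("ATG", 0), class = "viromimic_param_error")
})

test_that("low-complexity masking replaces only low-entropy windows", {
  homo <- strrep("A", 30)
  expect_identical(mask_low_complexity(homo), strrep("X", 30))
  set.seed(5)
  div <- random_protein(40)
  expect_identical(mask_low_complexity(div), div)
  # shorter than the window: returned untouched
  expect_identical(mask_low_complexity("AAAAA"), "AAAAA")
  # a low-complexity island inside a diverse protein is masked locally
  s <- paste0(substr(div, 1, 15), strrep("P", 14), substr(div, 16, 40))
  masked <- mask_low_complexity(s)
  expect_true(grepl("X", masked))
  expect_identical(substr(masked, 1, 8), substr(div, 1, 8))
})

test_that("smith_waterman_affine matches hand-checked alignments", {
  m <- blosum62()
  # exact 6-mer: sum of diagonal scores
  r <- smith_waterman_affine("MKWVTF", "MKWVTF", m)
  sc <- m$scores
  expect_identical(r$score,
                   sum(sc[cbind(c("M","K","W","V","T","F"),
                                c("M","K","W","V","T","F"))]))
  expect_identical(r$a_start, 1L)
  expect_identical(r$a_end, 6L)
  # single-residue deletion: gap of length 1 costs open + extend
  a <- "WWWWKWWWW"
  b <- "WWWWWWWW"
  r2 <- smith_waterman_affine(a, b, m, gap_open = 3, gap_extend = 1)
  expect_identical(r2$score, 8L * sc["W", "W"] - 3L - 1L)
  expect_identical(r2$gap_openings, 1L)
  # no positive-scoring alignment
  expect_identical(smith_waterman_affine("W", "P", m)$score, 0L)
  expect_error(smith_waterman_affine("", "A", m),
               class = "viromimic_param_error")
})

test_that("full DP agrees with the naive oracle on random pairs", {
  m <- blosum62()
  set.seed(42)
  for (i in 1:25) {
    a <- random_protein(sample(5:40, 1))
    b <- random_protein(sample(5:40, 1))
    expect_identical(smith_waterman_affine(a, b, m)$score,
                     as.integer(naive_sw_score(a, b, m$scores)))
  }
})

test_that("seeded blastp finds a planted identical segment at full identity", {
  set.seed(7)
  core <- random_protein(40)
  q <- seq_set("query", paste0(random_protein(20), core, random_protein(20)))
  s <- seq_set("subj", paste0(random_protein(10), core, random_protein(10)))
  hits <- seeded_search(q, s, mode = "blastp")
  expect_gte(nrow(hits), 1)
  h <- hits[1, ]
  # the planted core is inside the reported alignment
  expect_lte(h$qstart, 21)
  expect_gte(h$qend, 60)
  expect_lte(h$sstart, 11)
  expect_gte(h$send, 50)
  expect_lt(h$evalue, 1e-10)
})

test_that("tblastn finds a planted coding segment on both strands", {
  set.seed(8)
  prot <- random_protein(60)
  nt <- reverse_translate(prot, seed = 99)
  fwd <- seq_set("fwd", paste0(random_dna(50), nt, random_dna(49)))
  rev <- seq_set("rev", reverse_complement(fwd$seq))
  q <- seq_set("p", prot)
  hf <- seeded_search(q, fwd, mode = "tblastn")
  hr <- seeded_search(q, rev, mode = "tblastn")
  expect_gte(nrow(hf), 1)
  expect_gte(nrow(hr), 1)
  f <- hf[1, ]; r <- hr[1, ]
  # plus-strand hit: coordinates 1-based inclusive on the forward strand
  expect_gt(f$frame, 0)
  expect_lt(r$frame, 0)
  expect_identical(f$pident, 100)
  expect_identical(r$pident, 100)
  # reverse-complement symmetry: same alignment, mirrored coordinates
  L <- nchar(fwd$seq)
  expect_identical(r$sstart, L - f$sstart + 1L)
  expect_identical(r$send, L - f$send + 1L)
  expect_identical(r$score, f$score)
  # minus-strand convention: sstart > send
  expect_gt(r$sstart, r$send)
  expect_lt(f$sstart, f$send)
})

test_that("reported subject coordinates map back to the aligned residues", {
  set.seed(9)
  prot <- random_protein(50)
  nt <- reverse_translate(prot, seed = 100)
  subj <- seq_set("s", paste0(random_dna(30), nt, random_dna(30)))
  q <- seq_set("p", prot)
  h <- seeded_search(q, subj, mode = "tblastn")[1, ]
  # translating the reported subject range in the reported frame gives the
  # aligned protein segment
  region <- substr(subj$seq, h$sstart, h$send)
  expect_identical(translate(region, 1),
                   substr(prot, h$qstart, h$qend))
})

test_that("seeded search output is deterministic and sorted", {
  set.seed(10)
  qs <- seq_set(c("q1", "q2"), c(random_protein(80), random_protein(80)))
  frs <- seq_set(sprintf("f%02d", 1:30),
                 vapply(1:30, function(i) random_dna(200), character(1)))
  # plant q1 into two fragments
  nt <- reverse_translate(substr(qs$seq[1], 11, 60), seed = 3)
  substr(frs$seq[5], 20, 19 + nchar(nt)) <- nt
  substr(frs$seq[9], 1, nchar(nt)) <- nt
  h1 <- seeded_search(qs, frs, mode = "tblastn")
  h2 <- seeded_search(qs, frs, mode = "tblastn")
  expect_identical(h1, h2)
  # sorted by query input order then ascending evalue
  expect_true(!is.unsorted(match(h1$qseqid, qs$id)))
  for (qq in unique(h1$qseqid))
    expect_true(!is.unsorted(h1$evalue[h1$qseqid == qq]))
})

test_that("searches over empty inputs return empty hit tables", {
  q <- seq_set("q", "MKWVTFISLLLLFSSAYS")
  expect_identical(nrow(seeded_search(q[0, ], q, mode = "blastp")), 0L)
  expect_identical(nrow(seeded_search(q, q[0, ], mode = "blastp")), 0L)
})

test_that("search_params validates its arguments", {
  expect_error(search_params(word_size = 0), class = "viromimic_param_error")
  expect_error(search_params(gap_open = 1, gap_extend = 2),
               class = "viromimic_param_error")
})
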