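#' @name matrices
#' @title Substitution matrices and residue backgrounds
NULL

#' Construct a substitution matrix object
#'
#' @param scores square integer matrix with identical row/column dimnames
#'   (the alphabet).
#' @param background named residue background probabilities; residues absent
#'   from `background` get probability 0 (they score but never contribute to
#'   the random model, e.g. X and stop codons).
#' @return an object of class `sub_matrix`: list(scores, background).
#' @export
sub_matrix <- function(scores, background) {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores),
            identical(rownames(scores), colnames(scores)))
  ab <- rownames(scores)
  bg <- setNames(rep(0, length(ab)), ab)
  bg[names(background)] <- background
  bg <- bg / sum(bg)
  if (!isTRUE(all.equal(scores, t(scores))))
    viromimic_error("substitution matrix must be symmetric", "viromimic_matrix_error")
  act <- bg > 0
  es <- sum(outer(bg[act], bg[act]) * scores[act, act, drop = FALSE])
  if (es >= 0)
    viromimic_error("expected score must be negative", "viromimic_matrix_error")
  if (max(scores[act, act]) <= 0)
    viromimic_error("at least one positive score required", "viromimic_matrix_error")
  structure(list(scores = scores, background = bg), class = "sub_matrix")
}

#' Read a substitution matrix in NCBI text layout
#'
#' Comment lines start with '#'; the first non-comment line lists the column
#' residues, each following line a row residue and its integer scores.
#'
#' @param path matrix file.
#' @param background named background probabilities to attach (default:
#'   Robinson-Robinson over the 20 amino acids).
#' @return a [sub_matrix()] object.
#' @export
read_score_matrix <- function(path, background = ROBINSON_BG) {
  lines <- readLines(path)
  lines <- trimws(lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))])
  cols <- strsplit(lines[1], "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(l, "\\s+")[[1]])
  rn <- vapply(rows, `[`, character(1), 1)
  m <- do.call(rbind, lapply(rows, function(r) as.integer(r[-1])))
  dimnames(m) <- list(rn, cols)
  sub_matrix(m, background)
}

.pkg_cache <- new.env(parent = emptyenv())

#' The bundled BLOSUM62 matrix
#'
#' BLOSUM62 in the engine's 22-letter order (20 amino acids + X + '*'), with
#' X forced to -1 and '*' to -4 against everything, and the Robinson-Robinson
#' background attached.
#' @return a [sub_matrix()] object.
#' @export
blosum62 <- function() {
  if (!is.null(.pkg_cache$blosum62)) return(.pkg_cache$blosum62)
  path <- system.file("extdata", "BLOSUM62.txt", package = "viromimic")
  full <- read_score_matrix(path)
  m <- full$scores[AA_ORDER, AA_ORDER]
  m["X", ] <- -1L; m[, "X"] <- -1L
  m["*", ] <- -4L; m[, "*"] <- -4L
  out <- sub_matrix(m, ROBINSON_BG)
  .pkg_cache$blosum62 <- out
  out
}

#' A simple match/mismatch matrix over an arbitrary alphabet
#'
#' @param match,mismatch integer scores.
#' @param alphabet residue letters (default the 4 DNA bases).
#' @param background named background (default uniform).
#' @return a [sub_matrix()] object.
#' @export
match_mismatch_matrix <- function(match = 1L, mismatch = -1L,
                                  alphabet = c("A", "C", "G", "T"),
                                  background = NULL) {
  n <- length(alphabet)
  m <- matrix(as.integer(mismatch), n, n, dimnames = list(alphabet, alphabet))
  diag(m) <- as.integer(match)
  if (is.null(background)) background <- setNames(rep(1 / n, n), alphabet)
  sub_matrix(m, background)
}

#' Karlin-Altschul parameters of an ungapped scoring system
#'
#' Solves for lambda (the unique positive root of
#' \eqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1}), the relative entropy H
#' (nats per aligned pair), and the K prefactor via the standard
#' Karlin-Altschul series over partial-sum distributions of the score random
#' walk.
#'
#' @param matrix a [sub_matrix()] object.
#' @param tol relative tolerance on lambda.
#' @return list(lambda, K, H) of class `ka_params`.
#' @export
compute_ka_params <- function(matrix, tol = 1e-9) {
  stopifnot(inherits(matrix, "sub_matrix"))
  bg <- matrix$background
  act <- names(bg)[bg > 0]
  p2 <- outer(bg[act], bg[act])
  s <- matrix$scores[act, act, drop = FALSE]
  # score distribution
  svals <- sort(unique(as.vector(s)))
  probs <- vapply(svals, function(v) sum(p2[s == v]), numeric(1))
  if (sum(probs * svals) >= 0)
    viromimic_error("expected score is non-negative; no positive lambda exists",
                    "viromimic_matrix_error")
  d <- Reduce(.gcd, abs(svals[svals != 0]))          # score lattice span
  f <- function(l) sum(probs * exp(l * svals)) - 1
  hi <- 0.5
  while (f(hi) < 0) hi <- hi * 2
  lambda <- uniroot(f, c(1e-12, hi), tol = tol * 0.5)$root
  # refine with a few Newton steps (uniroot's tol is absolute)
  for (i in 1:8) {
    g  <- sum(probs * exp(lambda * svals)) - 1
    gp <- sum(probs * svals * exp(lambda * svals))
    lambda <- lambda - g / gp
  }
  H <- lambda * sum(probs * svals * exp(lambda * svals))
  K <- .karlin_K(svals, probs, lambda, H, d)
  structure(list(lambda = lambda, K = K, H = H), class = "ka_params")
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

# K via the sigma series: sigma = sum_k (1/k) [ E(e^{lambda S_k}; S_k < 0)
# + P(S_k >= 0) ], K = d * lambda * exp(-2 sigma) / (H * (1 - e^{-lambda d})).
.karlin_K <- function(svals, probs, lambda, H, d, term_tol = 1e-12,
                      max_iter = 400L) {
  lo <- min(svals); hi <- max(svals)
  # base distribution on integer support lo..hi
  base <- rep(0, hi - lo + 1)
  base[svals - lo + 1] <- probs
  dist <- 1               # S_0 = 0 with probability 1
  off <- 0                # dist[i] = P(S_k = off + i - 1)
  sigma <- 0
  for (k in seq_len(max_iter)) {
    # convolve dist with base
    n1 <- length(dist); n2 <- length(base)
    newd <- rep(0, n1 + n2 - 1)
    for (j in seq_len(n2)) {
      if (base[j] > 0)
        newd[j:(j + n1 - 1)] <- newd[j:(j + n1 - 1)] + dist * base[j]
    }
    dist <- newd
    off <- off + lo
    vals <- off + seq_along(dist) - 1
    neg <- vals < 0
    term <- sum(dist[neg] * exp(lambda * vals[neg])) + sum(dist[!neg])
    sigma <- sigma + term / k
    if (term / k < term_tol) break
  }
  d * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * d)))
}

#' E-value of a raw local alignment score
#'
#' \eqn{E = K m' n' e^{-\lambda S}} with the finite-size edge correction
#' \eqn{\ell = \mathrm{round}(\ln(K m n)/H)}, \eqn{m' = \max(1, m-\ell)},
#' \eqn{n' = \max(c, n - c\ell)} where c is the number of database sequences.
#'
#' @param raw_score positive raw alignment score (matrix units).
#' @param query_len query length m in residues.
#' @param db_len total database length n in residues (for translated searches,
#'   summed over all six frames of all fragments).
#' @param ka [compute_ka_params()] result.
#' @param n_seqs number of database sequences c.
#' @param edge_correct set FALSE to force the edge-correction length to 0.
#' @return numeric E-value.
#' @export
evalue <- function(raw_score, query_len, db_len, ka, n_seqs = 1L,
                   edge_correct = TRUE) {
  if (any(raw_score <= 0))
    viromimic_error("raw_score must be positive", "viromimic_param_error")
  ell <- if (edge_correct)
    max(0, round(log(ka$K * query_len * db_len) / ka$H)) else 0
  mp <- max(1, query_len - ell)
  np <- max(n_seqs, db_len - n_seqs * ell)
  ka$K * mp * np * exp(-ka$lambda * raw_score)
}

#' Convert a raw score to a bit score
#'
#' @inheritParams evalue
#' @return bit score \eqn{(\lambda S - \ln K)/\ln 2}.
#' @export
bit_score <- function(raw_score, ka) {
  (ka$lambda * raw_score - log(ka$K)) / log(2)
}
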