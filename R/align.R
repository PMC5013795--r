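#' @name align_core
#' @title Translated homology search engine
#'
#' @description A seed-and-extend local aligner with tBLASTn semantics
#' (protein queries against six-frame translations of nucleotide subjects)
#' or BLASTp semantics (protein vs protein), scored with an integer
#' substitution matrix under affine gap penalties, with E-values from
#' ungapped Karlin-Altschul statistics.
NULL

#' Translate a nucleotide sequence in one reading frame
#'
#' Frames +1..+3 read the forward strand offset by frame-1; frames -1..-3
#' read the reverse complement likewise. Trailing partial codons are
#' dropped; codons containing N translate to X; stop codons are '*'.
#'
#' @param nuc nucleotide string (A,C,G,T,N; U accepted as T).
#' @param frame one of +1,+2,+3,-1,-2,-3.
#' @return protein string.
#' @export
translate <- function(nuc, frame) {
  if (!is.numeric(frame) || length(frame) != 1L || !(frame %in% c(-3:-1, 1:3)))
    viromimic_error("frame must be one of +1,+2,+3,-1,-2,-3",
                    "viromimic_param_error")
  cpp_translate(toupper(nuc), as.integer(frame))
}

#' Mask low-complexity protein regions
#'
#' Every residue lying inside any length-`window` sliding window whose
#' Shannon entropy (base 2, over observed residue frequencies) falls below
#' `entropy_thresh` is replaced by X. Proteins shorter than the window are
#' returned unmasked.
#'
#' @param protein protein string.
#' @param window window length in residues (>= 2).
#' @param entropy_thresh entropy threshold in bits.
#' @return masked protein string.
#' @export
mask_low_complexity <- function(protein, window = 12L, entropy_thresh = 2.0) {
  if (window < 2) viromimic_error("window must be >= 2", "viromimic_param_error")
  n <- nchar(protein)
  if (n < window) return(protein)
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  codes <- match(chars, c(AA20, "X", "*"))
  nw <- n - window + 1L
  mask <- logical(n)
  counts <- integer(22L)
  for (k in 1:window) counts[codes[k]] <- counts[codes[k]] + 1L
  ent <- function(cnt) {
    p <- cnt[cnt > 0] / window
    -sum(p * log2(p))
  }
  for (w in seq_len(nw)) {
    if (w > 1L) {
      counts[codes[w - 1L]] <- counts[codes[w - 1L]] - 1L
      counts[codes[w + window - 2L]] <- counts[codes[w + window - 2L]] + 1L
    }
    if (ent(counts) < entropy_thresh) mask[w:(w + window - 1L)] <- TRUE
  }
  if (!any(mask)) return(protein)
  chars[mask] <- "X"
  paste0(chars, collapse = "")
}

#' Search parameters
#'
#' BLAST-era defaults for the seeded search: 3-residue words with a
#' neighborhood score threshold of 11, x-drop of 20 for ungapped extension,
#' affine gap costs 11 (open) / 1 (extend), hits reported up to E-value 10,
#' and low-complexity masking with a 12-residue window at 2.0 bits.
#'
#' @param word_size seed word length (aa).
#' @param neighbor_thresh minimum word-pair score to seed.
#' @param x_drop extension termination drop (score units).
#' @param gap_open,gap_extend affine gap costs.
#' @param evalue_report_max report hits with E-value at or below this.
#' @param mask_window,mask_entropy low-complexity masking parameters.
#' @return list of class `search_params`.
#' @export
search_params <- function(word_size = 3L, neighbor_thresh = 11L, x_drop = 20L,
                          gap_open = 11L, gap_extend = 1L,
                          evalue_report_max = 10, mask_window = 12L,
                          mask_entropy = 2.0) {
  p <- list(word_size = as.integer(word_size),
            neighbor_thresh = as.integer(neighbor_thresh),
            x_drop = as.integer(x_drop), gap_open = as.integer(gap_open),
            gap_extend = as.integer(gap_extend),
            evalue_report_max = evalue_report_max,
            mask_window = as.integer(mask_window),
            mask_entropy = mask_entropy)
  if (any(unlist(p) <= 0))
    viromimic_error("all search parameters must be positive",
                    "viromimic_param_error")
  if (p$gap_extend > p$gap_open)
    viromimic_error("gap_extend must not exceed gap_open",
                    "viromimic_param_error")
  structure(p, class = "search_params")
}

#' Optimal local alignment with affine gaps
#'
#' Full Smith-Waterman dynamic programming (the exact oracle the seeded
#' search approximates). A gap of length k costs gap_open + k * gap_extend.
#' Traceback ties prefer diagonal, then up (gap in `b`), then left.
#'
#' @param a,b sequences over the matrix alphabet.
#' @param matrix a [sub_matrix()].
#' @param gap_open,gap_extend affine gap costs.
#' @return list with raw `score`, 1-based inclusive coordinates
#'   (`a_start`,`a_end`,`b_start`,`b_end`), alignment statistics and the
#'   aligned strings. Score 0 means no positive-scoring local alignment.
#' @export
smith_waterman_affine <- function(a, b, matrix = blosum62(),
                                  gap_open = 11L, gap_extend = 1L) {
  if (!nzchar(a) || !nzchar(b))
    viromimic_error("both sequences must be non-empty", "viromimic_param_error")
  cpp_sw_affine(a, b, matrix$scores, paste0(rownames(matrix$scores), collapse = ""),
                as.integer(gap_open), as.integer(gap_extend))
}

.blosum62_ka <- function() {
  if (is.null(.pkg_cache$blosum62_ka))
    .pkg_cache$blosum62_ka <- compute_ka_params(blosum62())
  .pkg_cache$blosum62_ka
}

.ids_of <- function(df) {
  if (!is.null(df$fragment_id)) df$fragment_id else df$id
}

#' Seeded translated/protein homology search
#'
#' For each query (optionally low-complexity masked), word seeds scoring at
#' least `neighbor_thresh` against the database words trigger ungapped
#' x-drop extension; subject frames whose best ungapped segment reaches the
#' score corresponding to E = 100 x `evalue_report_max` are then aligned
#' with full affine-gap Smith-Waterman, giving one HSP per
#' (query, subject, frame). E-values are computed against the whole subject
#' set (in tblastn mode, the total residue count over all six translated
#' frames). The search is fully deterministic.
#'
#' @param queries protein [seq_set()] data.frame.
#' @param subjects nucleotide records (tblastn) or protein records (blastp);
#'   a [seq_set()] or [fragment_set()] data.frame.
#' @param params a [search_params()] list.
#' @param matrix a [sub_matrix()] covering the engine's 22-letter alphabet.
#' @param mode "tblastn" or "blastp".
#' @param mask apply low-complexity masking to queries (default TRUE).
#' @param ka optional precomputed [compute_ka_params()]; default computed
#'   from `matrix`.
#' @return hit-table data.frame with outfmt-6 columns plus `frame` and raw
#'   `score`, sorted by query (input order) then ascending E-value, ties by
#'   subject id.
#' @export
seeded_search <- function(queries, subjects, params = search_params(),
                          matrix = blosum62(), mode = c("tblastn", "blastp"),
                          mask = TRUE, ka = NULL) {
  mode <- match.arg(mode)
  out0 <- empty_hit_table()
  out0$frame <- integer(0); out0$score <- integer(0)
  if (is.null(queries) || nrow(queries) == 0L ||
      is.null(subjects) || nrow(subjects) == 0L) return(out0)
  if (is.null(ka)) {
    ka <- if (identical(matrix, blosum62())) .blosum62_ka()
          else compute_ka_params(matrix)
  }
  qseq <- queries$seq
  if (mask)
    qseq <- vapply(qseq, mask_low_complexity, character(1),
                   window = params$mask_window,
                   entropy_thresh = params$mask_entropy, USE.NAMES = FALSE)
  sseq <- subjects$seq
  sids <- .ids_of(subjects)
  qids <- queries$id
  slen <- nchar(sseq)
  if (mode == "tblastn") {
    db_len <- sum(vapply(0:2, function(off) sum(pmax(0L, (slen - off) %/% 3L)),
                         numeric(1))) * 2
    # each translated frame is a separate database sequence for the
    # finite-size edge correction: frames are short relative to the
    # edge-effect length, so correcting per fragment instead of per frame
    # overstates the effective search space
    n_seqs <- 6L * nrow(subjects)
  } else {
    db_len <- sum(slen)
    n_seqs <- nrow(subjects)
  }
  qlen <- nchar(queries$seq)
  e_trig <- 100 * params$evalue_report_max
  trigger <- pmax(1L, as.integer(ceiling(
    (log(ka$K * qlen * db_len) - log(e_trig)) / ka$lambda)))
  raw <- cpp_seeded_search(qseq, sseq, mode == "tblastn", matrix$scores,
                           params$word_size, params$neighbor_thresh,
                           params$x_drop, params$gap_open, params$gap_extend,
                           trigger)
  n <- length(raw$query)
  if (n == 0L) return(out0)
  qi <- raw$query + 1L; si <- raw$subject + 1L
  fr <- raw$frame
  ev <- vapply(seq_len(n), function(i)
    evalue(raw$score[i], qlen[qi[i]], db_len, ka, n_seqs), numeric(1))
  keep <- ev <= params$evalue_report_max
  if (!any(keep)) return(out0)
  qi <- qi[keep]; si <- si[keep]; fr <- fr[keep]
  sc <- raw$score[keep]; ev <- ev[keep]
  qb <- raw$q_beg[keep]; qe <- raw$q_end[keep]
  sb <- raw$s_beg[keep]; se <- raw$s_end[keep]
  L <- slen[si]
  sstart <- integer(length(qi)); send <- integer(length(qi))
  pos <- fr > 0; neg <- fr < 0; pro <- fr == 0
  sstart[pos] <- (fr[pos] - 1L) + 3L * sb[pos] + 1L
  send[pos]   <- (fr[pos] - 1L) + 3L * se[pos]
  sstart[neg] <- L[neg] - (-fr[neg] - 1L) - 3L * sb[neg]
  send[neg]   <- L[neg] - (-fr[neg] - 1L) - 3L * se[neg] + 1L
  sstart[pro] <- sb[pro] + 1L
  send[pro]   <- se[pro]
  hits <- data.frame(
    qseqid = qids[qi], sseqid = sids[si],
    pident = round(100 * raw$identities[keep] / raw$aln_len[keep], 2),
    length = raw$aln_len[keep], mismatch = raw$mismatches[keep],
    gapopen = raw$gap_openings[keep],
    qstart = qb + 1L, qend = qe, sstart = sstart, send = send,
    evalue = ev, bitscore = round(bit_score(sc, ka), 1),
    stringsAsFactors = FALSE)
  hits$frame <- fr
  hits$score <- sc
  ord <- order(match(hits$qseqid, qids), hits$evalue, hits$sseqid,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
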