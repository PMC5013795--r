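#' @name qc
#' @title Read quality control
#'
#' @description The stated virome read filters: minimum length, minimum
#' arithmetic-mean Phred quality, and maximum fraction of N calls. All
#' bounds are strict in the removal direction — a read of exactly 100 nt,
#' mean quality exactly 25, or exactly 10% N passes.
NULL

#' Quality-filter reads
#'
#' A read is removed iff its length is below `min_len`, OR its mean Phred
#' quality is below `min_mean_q`, OR its fraction of N residues exceeds
#' `max_n_frac`. Each removed read is counted against the first failing
#' rule in that order.
#'
#' @param reads [seq_set()] data.frame; every read must carry qualities.
#' @param min_len minimum length in nt (default 100).
#' @param min_mean_q minimum mean Phred score (default 25).
#' @param max_n_frac maximum N fraction (default 0.10).
#' @return list(kept = filtered seq_set, report = one-row data.frame with
#'   n_input, n_removed_length, n_removed_quality, n_removed_n_content,
#'   n_kept).
#' @export
qc_filter <- function(reads, min_len = 100L, min_mean_q = 25,
                      max_n_frac = 0.10) {
  n <- nrow(reads)
  lacks <- vapply(reads$qual, is.null, logical(1))
  if (any(lacks))
    viromimic_error(sprintf("read '%s' lacks qualities",
                            reads$id[which(lacks)[1]]),
                    "viromimic_param_error")
  len <- nchar(reads$seq)
  meanq <- vapply(reads$qual, mean, numeric(1))
  nfrac <- vapply(seq_len(n), function(i) {
    lengths(regmatches(reads$seq[i], gregexpr("N", reads$seq[i], fixed = TRUE))) /
      len[i]
  }, numeric(1))
  fail_len <- len < min_len
  fail_q <- !fail_len & meanq < min_mean_q
  fail_n <- !fail_len & !fail_q & nfrac > max_n_frac
  keep <- !(fail_len | fail_q | fail_n)
  report <- data.frame(n_input = n,
                       n_removed_length = sum(fail_len),
                       n_removed_quality = sum(fail_q),
                       n_removed_n_content = sum(fail_n),
                       n_kept = sum(keep))
  kept <- reads[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, report = report)
}
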