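#' @name fragmenter
#' @title Mock-virome construction by genome fragmentation
#'
#' @description Viral genomes are cut into fixed-length, non-overlapping
#' segments tiling from position 0, mimicking the construction of an
#' in-silico ("mock") virome from sequenced genomes. Only the forward
#' strand is stored; both strands are recovered downstream by six-frame
#' translation.
NULL

#' Fragment one genome into fixed-length segments
#'
#' Tiles the genome from position 0 in steps of `frag_len`; the trailing
#' remainder is kept as a final shorter fragment iff its length is at least
#' `min_keep`. Fragment ids are `<parent_id>_<start>` (0-based start).
#'
#' @param genome a single-row [seq_set()] data.frame (or a list/row with
#'   `id` and `seq`).
#' @param frag_len fragment length in nt (default 200).
#' @param min_keep minimum length of the trailing fragment (default 100).
#' @return data.frame with columns fragment_id, parent_id, start, end
#'   (0-based half-open) and seq.
#' @export
fragment_genome <- function(genome, frag_len = 200L, min_keep = 100L) {
  if (frag_len < 1L)
    viromimic_error("frag_len must be >= 1", "viromimic_param_error")
  if (min_keep < 1L || min_keep > frag_len)
    viromimic_error("min_keep must be in 1..frag_len", "viromimic_param_error")
  id <- genome$id[1]; s <- genome$seq[1]
  L <- nchar(s)
  empty <- data.frame(fragment_id = character(0), parent_id = character(0),
                      start = integer(0), end = integer(0), seq = character(0),
                      stringsAsFactors = FALSE)
  if (is.na(s) || L == 0L) return(empty)
  n_full <- L %/% frag_len
  rem <- L %% frag_len
  starts <- if (n_full > 0L) (0:(n_full - 1L)) * frag_len else integer(0)
  ends <- starts + frag_len
  if (rem >= min_keep && rem > 0L) {
    starts <- c(starts, n_full * frag_len)
    ends <- c(ends, L)
  }
  if (!length(starts)) return(empty)
  data.frame(fragment_id = paste0(id, "_", starts), parent_id = id,
             start = as.integer(starts), end = as.integer(ends),
             seq = substring(s, starts + 1L, ends),
             stringsAsFactors = FALSE)
}

#' Fragment a set of genomes
#'
#' @param genomes [seq_set()] data.frame of genomes with unique ids.
#' @inheritParams fragment_genome
#' @return concatenated per-genome fragmentations (genome order preserved).
#' @export
fragment_set <- function(genomes, frag_len = 200L, min_keep = 100L) {
  if (anyDuplicated(genomes$id))
    viromimic_error("duplicate genome ids", "viromimic_param_error")
  parts <- lapply(seq_len(nrow(genomes)), function(i)
    fragment_genome(genomes[i, , drop = FALSE], frag_len, min_keep))
  if (!length(parts))
    return(fragment_genome(seq_set("x", "A"), frag_len, min_keep)[0, ])
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

#' Convert fragments to sequence records
#'
#' @param fragments a [fragment_set()] data.frame.
#' @return [seq_set()] with fragment ids as record ids.
#' @export
fragments_as_records <- function(fragments) {
  seq_set(fragments$fragment_id, fragments$seq,
          desc = paste0(fragments$parent_id, ":", fragments$start, "-",
                        fragments$end))
}
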