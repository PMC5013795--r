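#' @name seqio
#' @title Sequence and hit-table input/output
#'
#' @description Sequence records are held in a plain data.frame with columns
#' `id` (token, unique within a file), `desc` (free text), `seq` (residue
#' string) and, for reads with base qualities, a list-column `qual` of
#' integer Phred scores. This keeps the whole pipeline inspectable with
#' ordinary data-frame tools.
NULL

#' Construct a sequence record set
#'
#' @param id character vector of record identifiers (no whitespace).
#' @param seq character vector of residue strings.
#' @param desc optional descriptions (default "").
#' @param qual optional list of integer Phred quality vectors.
#' @return data.frame with columns id, desc, seq and list-column qual.
#' @export
seq_set <- function(id, seq, desc = "", qual = NULL) {
  n <- length(id)
  stopifnot(length(seq) == n)
  if (is.null(qual)) qual <- rep(list(NULL), n)
  df <- data.frame(id = as.character(id), desc = rep_len(as.character(desc), n),
                   seq = as.character(seq), stringsAsFactors = FALSE)
  df$qual <- qual
  df
}

.check_alphabet <- function(df, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  allowed <- if (alphabet == "nucleotide") NUC_ALPHABET else PROT_ALPHABET
  for (i in seq_len(nrow(df))) {
    chars <- unique(strsplit(df$seq[i], "", fixed = TRUE)[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad))
      viromimic_error(
        sprintf("record '%s' contains character(s) outside the %s alphabet: %s",
                df$id[i], alphabet, paste(bad, collapse = ", ")),
        "viromimic_alphabet_error")
  }
  invisible(df)
}

#' Read a FASTA file (or literal FASTA text)
#'
#' Headers start with '>'; the first whitespace-delimited token is the id,
#' the remainder the description. Wrapped sequence lines are concatenated,
#' residues are uppercased and, for nucleotide input, 'U' is mapped to 'T'.
#'
#' @param x path to a FASTA file, or a character scalar containing FASTA text.
#' @param alphabet "nucleotide" (A,C,G,T,N) or "protein" (20 amino acids + X);
#'   residues outside the alphabet raise an error naming the record and
#'   offending character.
#' @return a [seq_set()] data.frame (qual all NULL).
#' @export
read_fasta <- function(x, alphabet = c("nucleotide", "protein")) {
  alphabet <- match.arg(alphabet)
  is_text <- length(x) == 1L && (grepl("\n", x, fixed = TRUE) || startsWith(x, ">"))
  lines <- if (is_text) strsplit(x, "\n", fixed = TRUE)[[1]] else readLines(x)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!length(lines) || !any(hdr))
    viromimic_error("no FASTA records found", "viromimic_io_error")
  if (!hdr[1])
    viromimic_error("FASTA input does not start with a '>' header", "viromimic_io_error")
  grp <- cumsum(hdr)
  ids <- character(0); descs <- character(0); seqs <- character(0)
  for (g in seq_len(max(grp))) {
    block <- lines[grp == g]
    h <- sub("^>", "", block[1])
    tok <- regmatches(h, regexpr("^\\S+", h))
    if (!length(tok))
      viromimic_error("FASTA header with empty id", "viromimic_io_error")
    ids <- c(ids, tok)
    descs <- c(descs, trimws(sub("^\\S+\\s*", "", h)))
    s <- toupper(paste0(block[-1], collapse = ""))
    if (!nzchar(s))
      viromimic_error(sprintf("record '%s' has an empty sequence", tok),
                      "viromimic_io_error")
    if (alphabet == "nucleotide") s <- gsub("U", "T", s, fixed = TRUE)
    seqs <- c(seqs, s)
  }
  if (anyDuplicated(ids))
    viromimic_error(sprintf("duplicate record id '%s'", ids[duplicated(ids)][1]),
                    "viromimic_io_error")
  df <- seq_set(ids, seqs, descs)
  .check_alphabet(df, alphabet)
  df
}

#' Write records to FASTA
#'
#' @param records a [seq_set()] data.frame.
#' @param path output file path.
#' @param width line-wrap width for residues.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "wb")  # binary mode: deterministic \n endings
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(records$desc[i]))
      paste0(">", records$id[i], " ", records$desc[i]) else paste0(">", records$id[i])
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", records$seq[i])
    writeLines(c(hdr, strsplit(body, "\n")[[1]]), con, sep = "\n")
  }
  invisible(path)
}

#' Read a FASTQ file (4-line records, Phred+33)
#'
#' @param path FASTQ file path, or a character scalar of FASTQ text.
#' @return a [seq_set()] data.frame with integer qualities populated.
#' @export
read_fastq <- function(path) {
  lines <- if (length(path) == 1L && grepl("\n", path))
    strsplit(path, "\n", fixed = TRUE)[[1]] else readLines(path)
  lines <- lines[seq_len(length(lines))]
  while (length(lines) && !nzchar(lines[length(lines)])) lines <- lines[-length(lines)]
  if (!length(lines))
    viromimic_error("no FASTQ records found", "viromimic_io_error")
  if (length(lines) %% 4L != 0L)
    viromimic_error(sprintf("truncated FASTQ record at record %d",
                            length(lines) %/% 4L + 1L), "viromimic_io_error")
  n <- length(lines) %/% 4L
  ids <- character(n); descs <- character(n); seqs <- character(n)
  quals <- vector("list", n)
  for (i in seq_len(n)) {
    off <- (i - 1L) * 4L
    h <- lines[off + 1L]
    if (!startsWith(h, "@"))
      viromimic_error(sprintf("record %d: header does not start with '@'", i),
                      "viromimic_io_error")
    h <- sub("^@", "", h)
    ids[i] <- regmatches(h, regexpr("^\\S+", h))
    descs[i] <- trimws(sub("^\\S+\\s*", "", h))
    s <- toupper(gsub("U", "T", lines[off + 2L], fixed = TRUE))
    q <- lines[off + 4L]
    if (nchar(s) != nchar(q))
      viromimic_error(sprintf("record %d ('%s'): sequence and quality lengths differ (%d vs %d)",
                              i, ids[i], nchar(s), nchar(q)), "viromimic_io_error")
    seqs[i] <- s
    quals[[i]] <- as.integer(utf8ToInt(q)) - 33L
    if (any(quals[[i]] < 0L))
      viromimic_error(sprintf("record %d ('%s'): quality character below Phred+33 range",
                              i, ids[i]), "viromimic_io_error")
  }
  df <- seq_set(ids, seqs, descs, quals)
  .check_alphabet(df, "nucleotide")
  df
}

#' Write records to FASTQ (Phred+33)
#'
#' @param records a [seq_set()] data.frame; every record must carry qualities.
#' @param path output file path.
#' @export
write_fastq <- function(records, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    q <- records$qual[[i]]
    if (is.null(q))
      viromimic_error(sprintf("record '%s' lacks qualities", records$id[i]),
                      "viromimic_io_error")
    hdr <- if (nzchar(records$desc[i]))
      paste0("@", records$id[i], " ", records$desc[i]) else paste0("@", records$id[i])
    writeLines(c(hdr, records$seq[i], "+", intToUtf8(q + 33L)), con, sep = "\n")
  }
  invisible(path)
}

HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' An empty hit table
#'
#' Hit tables are data.frames in BLAST outfmt-6 column order (plus, when
#' produced by [seeded_search()], extra `frame` and `score` columns carrying
#' the reading frame and raw alignment score).
#' @return zero-row hit-table data.frame.
#' @export
empty_hit_table <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0), mismatch = integer(0),
             gapopen = integer(0), qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

.fmt_evalue <- function(e) {
  out <- vapply(e, function(x) {
    if (x == 0) "0.0" else sprintf("%.3g", x)
  }, character(1))
  out
}

#' Write a hit table in BLAST outfmt-6 layout
#'
#' Twelve tab-separated columns: query id, subject id, percent identity
#' (2 decimals), alignment length, mismatches, gap openings, query start/end,
#' subject start/end (1-based inclusive; start > end on the minus strand),
#' E-value, bit score.
#'
#' @param hits hit-table data.frame.
#' @param path output path.
#' @export
write_hit_table <- function(hits, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(hits)) {
    lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
                     hits$qseqid, hits$sseqid, hits$pident,
                     as.integer(hits$length), as.integer(hits$mismatch),
                     as.integer(hits$gapopen),
                     as.integer(hits$qstart), as.integer(hits$qend),
                     as.integer(hits$sstart), as.integer(hits$send),
                     .fmt_evalue(hits$evalue), hits$bitscore)
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Parse a BLAST outfmt-6 hit table
#'
#' @param path tabular file path.
#' @return hit-table data.frame (empty file gives an empty table).
#' @export
parse_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_hit_table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc < 12L))
    viromimic_error(sprintf("line %d has %d columns; 12 expected",
                            which(nc < 12L)[1], nc[which(nc < 12L)[1]]),
                    "viromimic_io_error")
  m <- do.call(rbind, lapply(parts, function(p) p[1:12]))
  data.frame(qseqid = m[, 1], sseqid = m[, 2],
             pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
             mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
             qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
             sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
             evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
             stringsAsFactors = FALSE)
}
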