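#' @name tm_predict
#' @title Hydropathy-based transmembrane segment prediction
#'
#' @description A windowed Kyte-Doolittle hydropathy scan: runs of window
#' centers whose mean hydropathy reaches the threshold are called
#' transmembrane segments. Window 19 and threshold 1.6 are the scale
#' authors' recommended settings for transmembrane detection.
NULL

#' Kyte-Doolittle hydropathy scale
#' @return named numeric vector over the 20 amino acids (X scores 0).
#' @export
kyte_doolittle <- function() {
  c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9, A = 1.8,
    G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6,
    H = -3.2, E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5,
    X = 0, "*" = 0)
}

#' Windowed mean hydropathy profile
#'
#' @param protein protein string.
#' @param window window length (default 19); the profile is defined only
#'   where the full window fits, so proteins shorter than the window give
#'   an empty profile.
#' @return numeric vector of length `nchar(protein) - window + 1` (mean
#'   hydropathy of the window starting at each position), empty when the
#'   protein is shorter than the window.
#' @export
hydropathy_profile <- function(protein, window = 19L) {
  n <- nchar(protein)
  if (n < window) return(numeric(0))
  kd <- kyte_doolittle()
  v <- kd[strsplit(protein, "", fixed = TRUE)[[1]]]
  v[is.na(v)] <- 0
  cs <- c(0, cumsum(v))
  unname((cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window)
}

#' Predict transmembrane segments
#'
#' Maximal runs of consecutive window positions with profile at or above
#' the threshold are expanded to the full window extent of their first and
#' last position; overlapping expansions are merged.
#'
#' @param protein protein string.
#' @param window hydropathy window (default 19).
#' @param threshold mean-hydropathy call threshold (default 1.6).
#' @return list(segments = data.frame(start, end) 0-based half-open,
#'   n_segments).
#' @export
predict_tm_segments <- function(protein, window = 19L, threshold = 1.6) {
  prof <- hydropathy_profile(protein, window)
  segs <- data.frame(start = integer(0), end = integer(0))
  if (length(prof)) {
    hot <- prof >= threshold
    if (any(hot)) {
      r <- rle(hot)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      s0 <- starts[runs] - 1L                      # 0-based window start
      e0 <- ends[runs] - 1L + window               # end of last window
      # merge overlapping expansions
      ord <- order(s0)
      s0 <- s0[ord]; e0 <- e0[ord]
      ms <- s0[1]; me <- e0[1]; out_s <- integer(0); out_e <- integer(0)
      for (i in seq_along(s0)[-1]) {
        if (s0[i] <= me) me <- max(me, e0[i])
        else { out_s <- c(out_s, ms); out_e <- c(out_e, me); ms <- s0[i]; me <- e0[i] }
      }
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      segs <- data.frame(start = out_s, end = out_e)
    }
  }
  list(segments = segs, n_segments = nrow(segs))
}

#' Transmembrane prediction for a set of proteins
#'
#' @param proteins protein [seq_set()] data.frame.
#' @inheritParams predict_tm_segments
#' @return data.frame protein_id, n_segments, segments (semicolon-joined
#'   `start-end` 0-based half-open intervals).
#' @export
predict_tm_set <- function(proteins, window = 19L, threshold = 1.6) {
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    r <- predict_tm_segments(proteins$seq[i], window, threshold)
    data.frame(protein_id = proteins$id[i], n_segments = r$n_segments,
               segments = paste(sprintf("%d-%d", r$segments$start,
                                        r$segments$end), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(protein_id = character(0), n_segments = integer(0),
                      segments = character(0), stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
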