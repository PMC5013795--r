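# Shared alphabets and backgrounds (defined first in collation order).

NUC_ALPHABET <- c("A", "C", "G", "T", "N")

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

PROT_ALPHABET <- c(AA20, "X")

# Search-engine residue order: 20 amino acids, then X (unknown/masked), then
# '*' (stop). X scores -1 and '*' scores -4 against everything, matching
# classic translated-search behaviour (alignments may run through stops).
AA_ORDER <- c(AA20, "X", "*")

# Robinson & Robinson amino-acid background frequencies (the standard
# composition used for ungapped Karlin-Altschul parameters).
ROBINSON_BG <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
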