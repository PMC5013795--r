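// Core search engine: six-frame translation, affine-gap local alignment,
// word-seeded ungapped extension, and PSSM domain scanning with an
// empirical shuffle null. Scores are integer substitution-matrix units;
// statistics (E-values) are applied on the R side.
#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
#include <climits>
#include <algorithm>
#include <random>
using namespace Rcpp;

// Engine residue order: 20 amino acids, X (unknown/masked), '*' (stop).
static const char* AA_CHARS = "ACDEFGHIKLMNPQRSTVWYX*";
static const int N_AA = 22;

static int aa_table[256];
static bool aa_table_init = false;
static void init_aa_table() {
  if (aa_table_init) return;
  for (int i = 0; i < 256; ++i) aa_table[i] = -1;
  for (int i = 0; AA_CHARS[i]; ++i) aa_table[(unsigned char)AA_CHARS[i]] = i;
  aa_table_init = true;
}

// nucleotide codes: A0 C1 G2 T3 N4
static inline int nt_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1; case 'G': return 2;
    case 'T': return 3; case 'U': return 3; case 'N': return 4;
    default: return -1;
  }
}
static inline int nt_comp(int c) {
  switch (c) { case 0: return 3; case 1: return 2; case 2: return 1;
               case 3: return 0; default: return 4; }
}

// standard genetic code, codon index t*16+c*4+a... order T,C,A,G per base
static const char* CODON_TCAG =
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG";
// map our base codes (A0 C1 G2 T3) into TCAG indices (T0 C1 A2 G3)
static inline int tcag(int code) {
  switch (code) { case 3: return 0; case 1: return 1; case 0: return 2;
                  default: return 3; } // G
}
static inline char codon_aa(int b0, int b1, int b2) {
  if (b0 > 3 || b1 > 3 || b2 > 3) return 'X';       // any N -> X
  return CODON_TCAG[tcag(b0) * 16 + tcag(b1) * 4 + tcag(b2)];
}

static std::string translate_codes(const std::vector<int>& nc, int frame) {
  int L = (int)nc.size();
  std::string out;
  if (frame > 0) {
    int off = frame - 1;
    for (int i = off; i + 2 < L; i += 3)
      out.push_back(codon_aa(nc[i], nc[i + 1], nc[i + 2]));
  } else {
    int off = -frame - 1;
    // reverse complement, then offset
    for (int i = L - 1 - off; i - 2 >= 0; i -= 3)
      out.push_back(codon_aa(nt_comp(nc[i]), nt_comp(nc[i - 1]),
                             nt_comp(nc[i - 2])));
  }
  return out;
}

static std::vector<int> encode_nt(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = nt_code(s[i]);
    if (c < 0) stop("invalid nucleotide '%c'", s[i]);
    v[i] = c;
  }
  return v;
}

static std::vector<int8_t> encode_aa(const std::string& s) {
  init_aa_table();
  std::vector<int8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int c = aa_table[(unsigned char)s[i]];
    if (c < 0) stop("invalid amino acid '%c'", s[i]);
    v[i] = (int8_t)c;
  }
  return v;
}

// [[Rcpp::export]]
std::string cpp_translate(std::string nuc, int frame) {
  if (frame == 0 || frame < -3 || frame > 3)
    stop("frame must be one of +1,+2,+3,-1,-2,-3");
  return translate_codes(encode_nt(nuc), frame);
}

// ---------------------------------------------------------------------------
// Affine-gap local alignment (Smith-Waterman / Gotoh) with traceback.
// Gap of length k costs gap_open + k * gap_extend.
struct SWResult {
  int score = 0;
  int a_beg = 0, a_end = 0, b_beg = 0, b_end = 0; // 0-based half-open
  int identities = 0, mismatches = 0, gap_open_count = 0, aln_len = 0;
  std::string aligned_a, aligned_b;
};

static SWResult sw_affine(const std::vector<int8_t>& a,
                          const std::vector<int8_t>& b,
                          const int* S, int nS,
                          int gap_open, int gap_extend,
                          const std::string* sa = nullptr,
                          const std::string* sb = nullptr) {
  const int m = (int)a.size(), n = (int)b.size();
  const int NEG = -1000000000;
  const int go = gap_open + gap_extend;
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Eprev; // E row-local
  std::vector<int> Fcol(n + 1, NEG);
  // traceback matrices
  std::vector<uint8_t> oh((size_t)(m + 1) * (n + 1), 0); // 0 stop,1 diag,2 up(F),3 left(E)
  std::vector<uint8_t> oe((size_t)(m + 1) * (n + 1), 0); // 1 = opened from H
  std::vector<uint8_t> of((size_t)(m + 1) * (n + 1), 0);
  SWResult res;
  int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int Ecur = NEG;
    const int8_t ai = a[i - 1];
    const int* Srow = S + (size_t)ai * nS;
    for (int j = 1; j <= n; ++j) {
      size_t idx = (size_t)i * (n + 1) + j;
      // E: gap in a (moving left), F: gap in b (moving up)
      int e_open = Hcur[j - 1] - go, e_ext = Ecur - gap_extend;
      if (e_open >= e_ext) { Ecur = e_open; oe[idx] = 1; }
      else { Ecur = e_ext; oe[idx] = 0; }
      int f_open = Hprev[j] - go, f_ext = Fcol[j] - gap_extend;
      if (f_open >= f_ext) { Fcol[j] = f_open; of[idx] = 1; }
      else { Fcol[j] = f_ext; of[idx] = 0; }
      int diag = Hprev[j - 1] + Srow[b[j - 1]];
      int best = 0; uint8_t org = 0;
      if (diag >= best) { best = diag; org = 1; }
      if (Fcol[j] > best) { best = Fcol[j]; org = 2; }
      if (Ecur > best) { best = Ecur; org = 3; }
      if (best <= 0) { best = 0; org = 0; }
      Hcur[j] = best; oh[idx] = org;
      if (best > res.score) { res.score = best; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  if (res.score <= 0) return res;
  // traceback
  int i = bi, j = bj;
  res.a_end = bi; res.b_end = bj;
  std::string xa, xb;
  int state = 0; // 0 in H, 2 in F, 3 in E
  while (true) {
    size_t idx = (size_t)i * (n + 1) + j;
    if (state == 0) {
      uint8_t org = oh[idx];
      if (org == 0) break;
      if (org == 1) {
        char ca = sa ? (*sa)[i - 1] : AA_CHARS[(int)a[i - 1]];
        char cb = sb ? (*sb)[j - 1] : AA_CHARS[(int)b[j - 1]];
        xa.push_back(ca); xb.push_back(cb);
        if (a[i - 1] == b[j - 1]) res.identities++; else res.mismatches++;
        --i; --j;
      } else state = org;
    } else if (state == 2) { // F: consume a (gap in b)
      char ca = sa ? (*sa)[i - 1] : AA_CHARS[(int)a[i - 1]];
      xa.push_back(ca); xb.push_back('-');
      bool opened = of[idx];
      --i;
      if (opened) { res.gap_open_count++; state = 0; }
    } else { // E: consume b (gap in a)
      char cb = sb ? (*sb)[j - 1] : AA_CHARS[(int)b[j - 1]];
      xa.push_back('-'); xb.push_back(cb);
      bool opened = oe[idx];
      --j;
      if (opened) { res.gap_open_count++; state = 0; }
    }
  }
  res.a_beg = i; res.b_beg = j;
  std::reverse(xa.begin(), xa.end());
  std::reverse(xb.begin(), xb.end());
  res.aligned_a = xa; res.aligned_b = xb;
  res.aln_len = (int)xa.size();
  return res;
}

// Generic-alphabet affine SW exposed to R (alphabet = matrix row letters).
// [[Rcpp::export]]
List cpp_sw_affine(std::string a, std::string b, IntegerMatrix score,
                   std::string alphabet, int gap_open, int gap_extend) {
  int nS = (int)alphabet.size();
  int tbl[256]; for (int i = 0; i < 256; ++i) tbl[i] = -1;
  for (int i = 0; i < nS; ++i) tbl[(unsigned char)alphabet[i]] = i;
  std::vector<int8_t> va(a.size()), vb(b.size());
  for (size_t i = 0; i < a.size(); ++i) {
    int c = tbl[(unsigned char)a[i]];
    if (c < 0) stop("residue '%c' not in matrix alphabet", a[i]);
    va[i] = (int8_t)c;
  }
  for (size_t i = 0; i < b.size(); ++i) {
    int c = tbl[(unsigned char)b[i]];
    if (c < 0) stop("residue '%c' not in matrix alphabet", b[i]);
    vb[i] = (int8_t)c;
  }
  std::vector<int> S((size_t)nS * nS);
  for (int i = 0; i < nS; ++i)
    for (int j = 0; j < nS; ++j) S[(size_t)i * nS + j] = score(i, j);
  SWResult r = sw_affine(va, vb, S.data(), nS, gap_open, gap_extend, &a, &b);
  return List::create(_["score"] = r.score,
                      _["a_start"] = r.a_beg + 1, _["a_end"] = r.a_end,
                      _["b_start"] = r.b_beg + 1, _["b_end"] = r.b_end,
                      _["identities"] = r.identities,
                      _["mismatches"] = r.mismatches,
                      _["gap_openings"] = r.gap_open_count,
                      _["aln_len"] = r.aln_len,
                      _["aligned_a"] = r.aligned_a,
                      _["aligned_b"] = r.aligned_b);
}

// ---------------------------------------------------------------------------
// Seeded search (tblastn / blastp semantics).
// [[Rcpp::export]]
List cpp_seeded_search(CharacterVector queries, CharacterVector subjects,
                       bool tblastn, IntegerMatrix score,
                       int word_size, int neighbor_thresh, int x_drop,
                       int gap_open, int gap_extend, IntegerVector trigger) {
  init_aa_table();
  const int nS = N_AA;
  std::vector<int> S((size_t)nS * nS);
  for (int i = 0; i < nS; ++i)
    for (int j = 0; j < nS; ++j) S[(size_t)i * nS + j] = score(i, j);
  const int W = word_size;
  if (W < 2 || W > 5) stop("word_size must be in 2..5");
  int n_words = 1; for (int k = 0; k < W; ++k) n_words *= 20;

  // subject frame translations
  const int frames_pos[6] = {1, 2, 3, -1, -2, -3};
  int nsub = subjects.size();
  int nframes = tblastn ? 6 : 1;
  int nsf = nsub * nframes;
  std::vector<std::vector<int8_t> > sf_seq(nsf);
  std::vector<int> sf_subject(nsf), sf_frame(nsf);
  for (int s = 0; s < nsub; ++s) {
    std::string ss = as<std::string>(subjects[s]);
    if (tblastn) {
      std::vector<int> nc = encode_nt(ss);
      for (int f = 0; f < 6; ++f) {
        std::string tr = translate_codes(nc, frames_pos[f]);
        int k = s * 6 + f;
        sf_seq[k] = encode_aa(tr);
        sf_subject[k] = s; sf_frame[k] = frames_pos[f];
      }
    } else {
      sf_seq[s] = encode_aa(ss);
      sf_subject[s] = s; sf_frame[s] = 0;
    }
  }
  // word index over the db: bucket positions by exact word id
  std::vector<int> wcount(n_words + 1, 0);
  long long total_pos = 0;
  auto word_id_at = [&](const std::vector<int8_t>& v, int p) -> int {
    int id = 0;
    for (int k = 0; k < W; ++k) {
      int c = v[p + k];
      if (c >= 20) return -1;
      id = id * 20 + c;
    }
    return id;
  };
  for (int k = 0; k < nsf; ++k) {
    int L = (int)sf_seq[k].size();
    for (int p = 0; p + W <= L; ++p) {
      int id = word_id_at(sf_seq[k], p);
      if (id >= 0) { wcount[id]++; total_pos++; }
    }
  }
  std::vector<long long> wstart(n_words + 1, 0);
  for (int i = 0; i < n_words; ++i) wstart[i + 1] = wstart[i] + wcount[i];
  std::vector<int32_t> pos_sf(total_pos), pos_off(total_pos);
  {
    std::vector<long long> cur(wstart.begin(), wstart.end() - 1);
    for (int k = 0; k < nsf; ++k) {
      int L = (int)sf_seq[k].size();
      for (int p = 0; p + W <= L; ++p) {
        int id = word_id_at(sf_seq[k], p);
        if (id >= 0) { pos_sf[cur[id]] = k; pos_off[cur[id]] = p; cur[id]++; }
      }
    }
  }
  // neighborhood cache: query word id -> db word ids scoring >= T
  std::vector<std::vector<int> > nbr_cache(n_words);
  std::vector<char> nbr_done(n_words, 0);
  std::vector<int> maxrow(20);
  for (int c = 0; c < 20; ++c) {
    int mx = -1000;
    for (int d = 0; d < 20; ++d) mx = std::max(mx, S[(size_t)c * nS + d]);
    maxrow[c] = mx;
  }
  // enumerate all W-mers whose score vs the query word reaches the
  // neighborhood threshold, with suffix-max pruning (iterative DFS)
  auto enum_words = [&](std::vector<int>& out, const int* qw) {
    int sufmax[6]; sufmax[W] = 0;
    for (int k = W - 1; k >= 0; --k) sufmax[k] = sufmax[k + 1] + maxrow[qw[k]];
    int choice[5]; int psc[6]; int pid[6];
    psc[0] = 0; pid[0] = 0;
    int k = 0; choice[0] = -1;
    while (k >= 0) {
      int d = ++choice[k];
      if (d >= 20) { --k; continue; }
      int sc = psc[k] + S[(size_t)qw[k] * nS + d];
      if (sc + sufmax[k + 1] < neighbor_thresh) continue;
      if (k == W - 1) {
        out.push_back(pid[k] * 20 + d);
      } else {
        psc[k + 1] = sc; pid[k + 1] = pid[k] * 20 + d;
        ++k; choice[k] = -1;
      }
    }
  };

  // outputs
  std::vector<int> o_q, o_s, o_fr, o_score, o_qb, o_qe, o_sb, o_se,
                   o_id, o_mm, o_go, o_al;

  // flat per-diagonal "extension reached" array across all subject frames
  int max_m = 0;
  for (int q = 0; q < queries.size(); ++q)
    max_m = std::max(max_m, (int)LENGTH(STRING_ELT(queries, q)));
  std::vector<long long> diag_base(nsf + 1, 0);
  for (int k = 0; k < nsf; ++k)
    diag_base[k + 1] = diag_base[k] + (long long)sf_seq[k].size() + max_m + 2;
  std::vector<int32_t> diag_end((size_t)diag_base[nsf], -1);
  std::vector<long long> diag_touched;

  std::vector<int> best_ungap(nsf, 0);
  std::vector<int> touched;

  for (int q = 0; q < queries.size(); ++q) {
    std::string qs = as<std::string>(queries[q]);
    std::vector<int8_t> qv = encode_aa(qs);
    int m = (int)qv.size();
    for (long long t : diag_touched) diag_end[t] = -1;
    diag_touched.clear();
    for (int t : touched) best_ungap[t] = 0;
    touched.clear();
    int qw[5];
    for (int i = 0; i + W <= m; ++i) {
      bool ok = true;
      for (int k = 0; k < W; ++k) { qw[k] = qv[i + k]; if (qw[k] >= 20) ok = false; }
      if (!ok) continue;
      int qid = 0; for (int k = 0; k < W; ++k) qid = qid * 20 + qw[k];
      if (!nbr_done[qid]) {
        enum_words(nbr_cache[qid], qw);
        nbr_done[qid] = 1;
      }
      const std::vector<int>& nb = nbr_cache[qid];
      for (int w : nb) {
        for (long long u = wstart[w]; u < wstart[w + 1]; ++u) {
          int k = pos_sf[u], p = pos_off[u];
          const std::vector<int8_t>& sv = sf_seq[k];
          int L = (int)sv.size();
          long long dkey = diag_base[k] + (p - i) + max_m;
          if (diag_end[dkey] >= p + W) continue;
          // ungapped x-drop extension around the word
          int sc = 0;
          for (int t = 0; t < W; ++t)
            sc += S[(size_t)qv[i + t] * nS + sv[p + t]];
          int total = sc;
          // right
          int run = 0, bestg = 0, qi = i + W, sj = p + W, ext_right = 0;
          while (qi < m && sj < L) {
            run += S[(size_t)qv[qi] * nS + sv[sj]];
            if (run > bestg) { bestg = run; ext_right = qi - (i + W) + 1; }
            if (run <= bestg - x_drop) break;
            ++qi; ++sj;
          }
          total += bestg;
          // left
          run = 0; bestg = 0; qi = i - 1; sj = p - 1;
          while (qi >= 0 && sj >= 0) {
            run += S[(size_t)qv[qi] * nS + sv[sj]];
            if (run > bestg) bestg = run;
            if (run <= bestg - x_drop) break;
            --qi; --sj;
          }
          total += bestg;
          if (best_ungap[k] == 0) touched.push_back(k);
          if (total > best_ungap[k]) best_ungap[k] = total;
          if (diag_end[dkey] < 0) diag_touched.push_back(dkey);
          diag_end[dkey] = p + W + ext_right;
        }
      }
    }
    int trig = trigger[q];
    for (int k : touched) {
      if (best_ungap[k] < trig) continue;
      SWResult r = sw_affine(qv, sf_seq[k], S.data(), nS, gap_open, gap_extend);
      if (r.score <= 0) continue;
      o_q.push_back(q); o_s.push_back(sf_subject[k]); o_fr.push_back(sf_frame[k]);
      o_score.push_back(r.score);
      o_qb.push_back(r.a_beg); o_qe.push_back(r.a_end);
      o_sb.push_back(r.b_beg); o_se.push_back(r.b_end);
      o_id.push_back(r.identities); o_mm.push_back(r.mismatches);
      o_go.push_back(r.gap_open_count); o_al.push_back(r.aln_len);
    }
  }
  return List::create(
    _["query"] = o_q, _["subject"] = o_s, _["frame"] = o_fr,
    _["score"] = o_score, _["q_beg"] = o_qb, _["q_end"] = o_qe,
    _["s_beg"] = o_sb, _["s_end"] = o_se, _["identities"] = o_id,
    _["mismatches"] = o_mm, _["gap_openings"] = o_go, _["aln_len"] = o_al);
}

// ---------------------------------------------------------------------------
// PSSM domain scanning with an empirical residue-shuffle null.
// models: list of IntegerMatrix (length x 20, columns in AA order A..Y).
// Residue codes >= 20 (X) score the per-position minimum.
// Returns per (protein, model): observed max window score, best start
// (0-based), count of shuffled maxima >= observed, shuffles completed.
// Shuffling for pair (i,j) uses its own RNG stream so early exit (once
// count reaches c_bound, the hit threshold can no longer be met) does not
// perturb other pairs.
// [[Rcpp::export]]
List cpp_scan_domains(CharacterVector prots, List models,
                      int n_shuffles, int c_bound, int seed) {
  init_aa_table();
  int np = prots.size(), nm = models.size();
  std::vector<std::vector<int> > pssm(nm);
  std::vector<std::vector<int> > pssm_min(nm);
  std::vector<int> mlen(nm);
  for (int j = 0; j < nm; ++j) {
    IntegerMatrix M = models[j];
    if (M.ncol() != 20) stop("PSSM must have 20 columns");
    mlen[j] = M.nrow();
    pssm[j].resize((size_t)mlen[j] * 20);
    pssm_min[j].resize(mlen[j]);
    for (int r = 0; r < mlen[j]; ++r) {
      int mn = M(r, 0);
      for (int c = 0; c < 20; ++c) {
        pssm[j][(size_t)r * 20 + c] = M(r, c);
        mn = std::min(mn, M(r, c));
      }
      pssm_min[j][r] = mn;
    }
  }
  auto scan_max = [&](const std::vector<int8_t>& v, int j, int* best_start) -> int {
    int L = (int)v.size(), len = mlen[j];
    if (L < len) return INT_MIN;
    int best = INT_MIN, bs = 0;
    const int* P = pssm[j].data();
    const int* Pm = pssm_min[j].data();
    for (int w = 0; w + len <= L; ++w) {
      int sc = 0;
      for (int r = 0; r < len; ++r) {
        int c = v[w + r];
        sc += (c < 20) ? P[(size_t)r * 20 + c] : Pm[r];
      }
      if (sc > best) { best = sc; bs = w; }
    }
    if (best_start) *best_start = bs;
    return best;
  };
  IntegerVector out_obs(np * nm), out_start(np * nm),
                out_count(np * nm), out_done(np * nm);
  for (int i = 0; i < np; ++i) {
    std::vector<int8_t> v = encode_aa(as<std::string>(prots[i]));
    for (int j = 0; j < nm; ++j) {
      int idx = i * nm + j;
      if ((int)v.size() < mlen[j]) {
        out_obs[idx] = NA_INTEGER; out_start[idx] = NA_INTEGER;
        out_count[idx] = NA_INTEGER; out_done[idx] = 0;
        continue;
      }
      int bs = 0;
      int obs = scan_max(v, j, &bs);
      out_obs[idx] = obs; out_start[idx] = bs;
      std::mt19937 rng((uint32_t)(seed * 2654435761u) ^
                       (uint32_t)(i * 1000003 + j * 7919 + 17));
      std::vector<int8_t> sh = v;
      int count = 0, done = 0;
      for (int t = 0; t < n_shuffles; ++t) {
        for (int a = (int)sh.size() - 1; a > 0; --a) {
          std::uniform_int_distribution<int> d(0, a);
          std::swap(sh[a], sh[d(rng)]);
        }
        int mx = scan_max(sh, j, nullptr);
        if (mx >= obs) ++count;
        ++done;
        if (count >= c_bound && c_bound > 0 && done < n_shuffles) break;
      }
      out_count[idx] = count; out_done[idx] = done;
    }
  }
  return List::create(_["obs"] = out_obs, _["start"] = out_start,
                      _["count"] = out_count, _["done"] = out_done);
}
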