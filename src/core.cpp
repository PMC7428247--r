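#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default: return -1;
  }
}

// Base-pair weights for the weighted Nussinov fold: GC=3, AU=2, GU=1.
// Sequences are T-normalized (U -> T) before they reach C++.
static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 2;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(std::string seq, int min_loop = 3, bool traceback = true) {
  const int n = seq.size();
  if (n == 0) stop("empty sequence");
  // coded bases and a flat pair-weight table keep the O(n^3) loop tight
  static const int wtab[5][5] = {
    //        A  C  G  T  other
    /*A*/   { 0, 0, 0, 2, 0 },
    /*C*/   { 0, 0, 3, 0, 0 },
    /*G*/   { 0, 3, 0, 1, 0 },
    /*T*/   { 2, 0, 1, 0, 0 },
    /*oth*/ { 0, 0, 0, 0, 0 } };
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) {
    int c = base_code(seq[i]);
    code[i] = (c < 0) ? 4 : c;
  }
  std::vector<int> W((size_t)n * n, 0);
  int* Wp = W.data();
  auto M = [&](int i, int j) -> int& { return Wp[(size_t)i * n + j]; };

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      const int j = i + span;
      int best = Wp[(size_t)(i + 1) * n + j]; // i unpaired
      const int* wrow = wtab[code[i]];
      const int* rowi1 = Wp + (size_t)(i + 1) * n;
      {
        int k = i + min_loop + 1;
        for (; k < j; ++k) {
          const int w = wrow[code[k]];
          if (w == 0) continue;
          const int v = w + rowi1[k - 1] + Wp[(size_t)(k + 1) * n + j];
          if (v > best) best = v;
        }
        // k == j
        const int w = wrow[code[j]];
        if (w) {
          const int v = w + rowi1[j - 1];
          if (v > best) best = v;
        }
      }
      M(i, j) = best;
    }
  }
  int total = (n > 1) ? M(0, n - 1) : 0;

  IntegerMatrix pairs(0, 2);
  if (traceback && n > 1) {
    std::vector<std::pair<int, int> > out;
    std::vector<std::pair<int, int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
      int i = stack.back().first, j = stack.back().second;
      stack.pop_back();
      if (j - i < min_loop + 1) continue;
      bool paired = false;
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int w = pair_weight(seq[i], seq[k]);
        if (w == 0) continue;
        int v = w;
        if (k > i + 1) v += M(i + 1, k - 1);
        if (k < j) v += M(k + 1, j);
        if (v == M(i, j)) {
          out.push_back(std::make_pair(i, k));
          if (k > i + 1) stack.push_back(std::make_pair(i + 1, k - 1));
          if (k < j) stack.push_back(std::make_pair(k + 1, j));
          paired = true;
          break;
        }
      }
      if (!paired) stack.push_back(std::make_pair(i + 1, j));
    }
    IntegerMatrix pm(out.size(), 2);
    for (size_t r = 0; r < out.size(); ++r) {
      pm(r, 0) = out[r].first + 1; // 1-based for R
      pm(r, 1) = out[r].second + 1;
    }
    pairs = pm;
  }
  return List::create(_["pairs"] = pairs, _["energy"] = -(double)total);
}

// ---------------------------------------------------------------------------
// Affine-gap Smith-Waterman. Gap of length L costs gap_open + L * gap_extend
// (penalties passed as positive numbers). Identity is computed over all
// aligned columns of the local alignment, including internal gap columns.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b, double match = 2.0,
                  double mismatch = -3.0, double gap_open = 5.0,
                  double gap_extend = 2.0) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e18;
  std::vector<double> H((size_t)(n + 1) * (m + 1), 0.0);
  std::vector<double> E((size_t)(n + 1) * (m + 1), NEG);
  std::vector<double> F((size_t)(n + 1) * (m + 1), NEG);
  auto IX = [&](int i, int j) { return (size_t)i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e = std::max(H[IX(i, j - 1)] - gap_open - gap_extend,
                          E[IX(i, j - 1)] - gap_extend);
      double f = std::max(H[IX(i - 1, j)] - gap_open - gap_extend,
                          F[IX(i - 1, j)] - gap_extend);
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double h = H[IX(i - 1, j - 1)] + s;
      double v = std::max(0.0, std::max(h, std::max(e, f)));
      E[IX(i, j)] = e;
      F[IX(i, j)] = f;
      H[IX(i, j)] = v;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }

  int i = bi, j = bj, state = 0; // 0=H, 1=E (gap in a), 2=F (gap in b)
  int cols = 0, matches = 0;
  int a_end = bi, b_end = bj;
  while (i > 0 || j > 0) {
    if (state == 0) {
      double v = H[IX(i, j)];
      if (v <= 0.0) break;
      double s = (i > 0 && j > 0 && a[i - 1] == b[j - 1]) ? match : mismatch;
      if (i > 0 && j > 0 && H[IX(i - 1, j - 1)] + s == v) {
        ++cols;
        if (a[i - 1] == b[j - 1]) ++matches;
        --i; --j;
      } else if (E[IX(i, j)] == v) {
        state = 1;
      } else if (F[IX(i, j)] == v) {
        state = 2;
      } else break;
    } else if (state == 1) {
      ++cols;
      if (E[IX(i, j)] == H[IX(i, j - 1)] - gap_open - gap_extend) {
        --j; state = 0;
      } else { --j; }
    } else {
      ++cols;
      if (F[IX(i, j)] == H[IX(i - 1, j)] - gap_open - gap_extend) {
        --i; state = 0;
      } else { --i; }
    }
  }
  double ident = (cols > 0) ? 100.0 * matches / cols : 0.0;
  return List::create(_["score"] = best, _["identity_pct"] = ident,
                      _["aligned_cols"] = cols, _["matches"] = matches,
                      _["a_start"] = i + 1, _["a_end"] = a_end,
                      _["b_start"] = j + 1, _["b_end"] = b_end);
}

// Word-seeded local alignment scan of a short query against a long subject
// (blast-style seed and extend): exact word hits are clustered and each
// cluster window is aligned with affine Smith-Waterman.
// [[Rcpp::export(name = ".seeded_scan_cpp")]]
DataFrame seeded_scan_cpp(std::string query, std::string genome,
                          int word_size = 11, double match = 2.0,
                          double mismatch = -3.0, double gap_open = 5.0,
                          double gap_extend = 2.0) {
  const int qn = query.size(), gn = genome.size();
  std::vector<double> score_v; std::vector<double> ident_v;
  std::vector<int> cols_v, gs_v, ge_v;
  if (word_size > 14) stop("word_size must be <= 14");
  if (qn >= word_size && gn >= word_size) {
    // direct-addressed word table (reset between calls via the word list)
    static std::vector<uint8_t> flag;
    const size_t tab = (size_t)1 << (2 * word_size);
    if (flag.size() < tab) flag.assign(tab, 0);
    const uint32_t mask = (uint32_t)(tab - 1);
    std::vector<uint32_t> qwords;
    uint32_t code = 0; int run = 0;
    for (int p = 0; p < qn; ++p) {
      int c = base_code(query[p]);
      if (c < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)c) & mask;
      if (++run >= word_size && !flag[code]) {
        flag[code] = 1;
        qwords.push_back(code);
      }
    }
    std::vector<int> hits;
    code = 0; run = 0;
    for (int p = 0; p < gn; ++p) {
      int c = base_code(genome[p]);
      if (c < 0) { run = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t)c) & mask;
      if (++run >= word_size && flag[code])
        hits.push_back(p - word_size + 1);
    }
    for (uint32_t w : qwords) flag[w] = 0;
    size_t h = 0;
    while (h < hits.size()) {
      size_t h2 = h;
      while (h2 + 1 < hits.size() && hits[h2 + 1] - hits[h2] <= qn) ++h2;
      int ws = std::max(0, hits[h] - qn - 5);
      int we = std::min(gn, hits[h2] + word_size + qn + 5);
      List al = sw_align_cpp(query, genome.substr(ws, we - ws), match,
                             mismatch, gap_open, gap_extend);
      score_v.push_back(as<double>(al["score"]));
      ident_v.push_back(as<double>(al["identity_pct"]));
      cols_v.push_back(as<int>(al["aligned_cols"]));
      gs_v.push_back(ws + as<int>(al["b_start"]));    // 1-based genomic
      ge_v.push_back(ws + as<int>(al["b_end"]));
      h = h2 + 1;
    }
  }
  return DataFrame::create(_["score"] = score_v, _["identity_pct"] = ident_v,
                           _["aligned_cols"] = cols_v, _["g_start"] = gs_v,
                           _["g_end"] = ge_v);
}

// Maximum ungapped local segment score over all diagonals of two sequences
// (used to calibrate the Karlin-Altschul K constant by simulation).
// [[Rcpp::export(name = ".max_segment_cpp")]]
double max_segment_cpp(std::string a, std::string b, double match = 2.0,
                       double mismatch = -3.0) {
  const int n = a.size(), m = b.size();
  double best = 0.0;
  for (int d = -(n - 1); d <= m - 1; ++d) {
    double run = 0.0;
    int i0 = std::max(0, -d);
    int len = std::min(n - i0, m - (i0 + d));
    for (int k = 0; k < len; ++k) {
      double s = (a[i0 + k] == b[i0 + k + d]) ? match : mismatch;
      run = std::max(0.0, run + s);
      if (run > best) best = run;
    }
  }
  return best;
}

// ---------------------------------------------------------------------------
// miRNA:target duplex model. The duplex is anchored on an exact Watson-Crick
// seed site (miRNA positions 2-8 pairing the target 3'UTR proxy antiparallel)
// and extended 3' of the seed by a banded DP allowing pairs, symmetric
// mismatches and single-nucleotide bulges. One optimal pairing is scored
// under two linear models: an alignment score (WC +5, G:U +1, mismatch -3,
// bulge opening -9, seed pairs weighted by seed_weight) and a duplex energy
// (GC -3, AU -2, GU -1, +3 per interior loop/bulge opening).
// ---------------------------------------------------------------------------

static inline int duplex_pair_type(char m, char u) {
  // m = miRNA base, u = target (mRNA-sense) base; both T-normalized.
  if ((m == 'A' && u == 'T') || (m == 'T' && u == 'A') ||
      (m == 'G' && u == 'C') || (m == 'C' && u == 'G')) return 1; // WC
  if ((m == 'G' && u == 'T') || (m == 'T' && u == 'G')) return 2; // G:U
  return 0;
}

static inline double duplex_pair_energy(char m, char u) {
  int t = duplex_pair_type(m, u);
  if (t == 2) return -1.0;
  if (t == 1) return ((m == 'G' || m == 'C') ? -3.0 : -2.0);
  return 0.0;
}

// Core duplex evaluation; offset is 0-based position of the seed
// reverse-complement within utr.
static List duplex_eval(const std::string& mirna, const std::string& utr,
                        int offset, int band, double seed_weight) {
  const int mlen = mirna.size(), ulen = utr.size();
  if (mlen < 9) stop("mature sequence shorter than 9 nt");
  if (offset < 0 || offset + 7 > ulen) stop("seed site outside target window");
  const double WC = 5.0, GU = 1.0, MM = -3.0, BULGE = -9.0, LOOP_E = 3.0;
  double score = 0.0, energy = 0.0;
  int npairs = 0;

  // seed block: miRNA 0-based positions 1..7 pair utr offset+6 .. offset
  for (int k = 0; k < 7; ++k) {
    char cm = mirna[1 + k], cu = utr[offset + 6 - k];
    if (duplex_pair_type(cm, cu) != 1) stop("seed site is not a strict match");
    score += seed_weight * WC;
    energy += duplex_pair_energy(cm, cu);
    ++npairs;
  }
  // miRNA position 1 (5'-most) may pair the base just 3' of the site
  if (offset + 7 < ulen) {
    int t = duplex_pair_type(mirna[0], utr[offset + 7]);
    if (t == 1) { score += WC; energy += duplex_pair_energy(mirna[0], utr[offset + 7]); ++npairs; }
    else if (t == 2) { score += GU; energy += -1.0; ++npairs; }
  }
  // 3' extension: miRNA positions 8..mlen-1 against utr upstream of the site
  const int la = mlen - 8;
  const int lb = std::min(offset, la + band);
  if (la > 0 && lb > 0) {
    const double NEG = -1e18;
    std::vector<double> D((size_t)(la + 1) * (lb + 1), NEG);
    auto IX = [&](int i, int j) { return (size_t)i * (lb + 1) + j; };
    D[IX(0, 0)] = 0.0;
    double best = 0.0; int besti = 0, bestj = 0;
    for (int i = 0; i <= la; ++i) {
      for (int j = std::max(0, i - band); j <= std::min(lb, i + band); ++j) {
        if (i == 0 && j == 0) continue;
        double v = NEG;
        if (i > 0 && j > 0 && D[IX(i - 1, j - 1)] > NEG / 2) {
          int t = duplex_pair_type(mirna[8 + i - 1], utr[offset - j]);
          double add = (t == 1) ? WC : (t == 2 ? GU : MM);
          v = std::max(v, D[IX(i - 1, j - 1)] + add);
        }
        if (i > 0 && std::abs(i - 1 - j) <= band && D[IX(i - 1, j)] > NEG / 2)
          v = std::max(v, D[IX(i - 1, j)] + BULGE);
        if (j > 0 && std::abs(i - (j - 1)) <= band && D[IX(i, j - 1)] > NEG / 2)
          v = std::max(v, D[IX(i, j - 1)] + BULGE);
        D[IX(i, j)] = v;
        if (v > best) { best = v; besti = i; bestj = j; }
      }
    }
    // traceback to collect column types (from the outer end back to the seed)
    std::vector<int> colty; // 1 = pair, 0 = mismatch/bulge
    std::vector<double> colen;
    int i = besti, j = bestj;
    while (i > 0 || j > 0) {
      double v = D[IX(i, j)];
      if (i > 0 && j > 0 && D[IX(i - 1, j - 1)] > NEG / 2) {
        int t = duplex_pair_type(mirna[8 + i - 1], utr[offset - j]);
        double add = (t == 1) ? WC : (t == 2 ? GU : MM);
        if (D[IX(i - 1, j - 1)] + add == v) {
          colty.push_back(t > 0 ? 1 : 0);
          colen.push_back(t > 0 ? duplex_pair_energy(mirna[8 + i - 1], utr[offset - j]) : 0.0);
          --i; --j; continue;
        }
      }
      if (i > 0 && std::abs(i - 1 - j) <= band && D[IX(i - 1, j)] > NEG / 2 &&
          D[IX(i - 1, j)] + BULGE == v) {
        colty.push_back(0); colen.push_back(0.0); --i; continue;
      }
      colty.push_back(0); colen.push_back(0.0); --j;
    }
    // columns now run seed-edge -> outward after reversal
    std::reverse(colty.begin(), colty.end());
    std::reverse(colen.begin(), colen.end());
    // trim trailing non-pair columns (tie paths ending in mismatches)
    int last_pair = -1;
    for (int k = (int)colty.size() - 1; k >= 0; --k)
      if (colty[k] == 1) { last_pair = k; break; }
    double esum = 0.0; int openings = 0; bool in_run = false;
    for (int k = 0; k <= last_pair; ++k) {
      if (colty[k] == 1) {
        esum += colen[k]; ++npairs; in_run = false;
      } else if (!in_run) { ++openings; in_run = true; }
    }
    score += best;
    energy += esum + LOOP_E * openings;
  }
  return List::create(_["align_score"] = score, _["duplex_energy"] = energy,
                      _["n_pairs"] = npairs);
}

// [[Rcpp::export(name = ".duplex_site_cpp")]]
List duplex_site_cpp(std::string mirna, std::string utr, int offset,
                     int band = 3, double seed_weight = 3.0) {
  return duplex_eval(mirna, utr, offset, band, seed_weight);
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'T': return 'A';
    case 'G': return 'C'; case 'C': return 'G';
    default: return 'N';
  }
}

// Null duplex energies for the site permutation test: the seed complement is
// implanted into flanks drawn (without replacement) from the UTR's own letter
// pool, matching the composition-conditional distribution of a chance seed
// site, and the duplex is evaluated at the implanted site. Uses R's RNG.
// [[Rcpp::export(name = ".duplex_null_cpp")]]
NumericVector duplex_null_cpp(std::string mirna, std::string utr, int n_perm,
                              int band = 3, double seed_weight = 3.0) {
  const int mlen = mirna.size();
  if (mlen < 9) stop("mature sequence shorter than 9 nt");
  const int la = mlen - 8;
  const int up = la + band;          // flank upstream of the implanted site
  const int wlen = up + 7 + 1;       // + site + one downstream base
  std::string site(7, 'N');
  for (int k = 0; k < 7; ++k) site[k] = comp_base(mirna[1 + (6 - k)]);
  std::vector<char> pool(utr.begin(), utr.end());
  const int pn = pool.size();
  NumericVector out(n_perm);
  std::string win(wlen, 'A');
  for (int r = 0; r < n_perm; ++r) {
    if (pn >= wlen) { // partial Fisher-Yates draw without replacement
      for (int k = 0; k < wlen; ++k) {
        int j = k + (int)(unif_rand() * (pn - k));
        if (j >= pn) j = pn - 1;
        std::swap(pool[k], pool[j]);
        win[k] = pool[k];
      }
    } else {
      for (int k = 0; k < wlen; ++k) {
        int j = (int)(unif_rand() * pn);
        if (j >= pn) j = pn - 1;
        win[k] = pool[j];
      }
    }
    for (int k = 0; k < 7; ++k) win[up + k] = site[k];
    List res = duplex_eval(mirna, win, up, band, seed_weight);
    out[r] = as<double>(res["duplex_energy"]);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Altschul-Erickson dinucleotide-preserving shuffle (Eulerian path method),
// using R's RNG. First and last characters are fixed; the returned sequence
// has exactly the input's dinucleotide counts.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".dinuc_shuffle_cpp")]]
std::string dinuc_shuffle_cpp(std::string seq) {
  const int n = seq.size();
  if (n < 3) return seq;
  // map characters to vertex indices
  std::vector<int> vid(256, -1);
  std::vector<char> vchar;
  for (int i = 0; i < n; ++i) {
    if (vid[(unsigned char)seq[i]] < 0) {
      vid[(unsigned char)seq[i]] = vchar.size();
      vchar.push_back(seq[i]);
    }
  }
  const int nv = vchar.size();
  if (nv == 1) return seq;
  std::vector<std::vector<int> > adj(nv); // out-edges: target vertex ids
  for (int i = 0; i + 1 < n; ++i)
    adj[vid[(unsigned char)seq[i]]].push_back(vid[(unsigned char)seq[i + 1]]);
  const int sf = vid[(unsigned char)seq[n - 1]];

  std::vector<int> last(nv, -1); // index into adj[v] of the chosen last edge
  bool ok = false;
  for (int attempt = 0; attempt < 1000 && !ok; ++attempt) {
    for (int v = 0; v < nv; ++v) {
      if (v == sf || adj[v].empty()) { last[v] = -1; continue; }
      last[v] = (int)(unif_rand() * adj[v].size());
      if (last[v] >= (int)adj[v].size()) last[v] = adj[v].size() - 1;
    }
    ok = true;
    for (int v = 0; v < nv && ok; ++v) {
      if (v == sf || adj[v].empty()) continue;
      int cur = v;
      for (int step = 0; step <= nv; ++step) {
        if (cur == sf) break;
        if (adj[cur].empty() || last[cur] < 0) { ok = false; break; }
        cur = adj[cur][last[cur]];
        if (step == nv) ok = false; // cycle not reaching sf
      }
      if (cur != sf) ok = false;
    }
  }
  if (!ok) return seq; // fully degenerate input

  // order edges: random permutation with the chosen last edge at the end
  std::vector<std::vector<int> > order(nv);
  for (int v = 0; v < nv; ++v) {
    const int ne = adj[v].size();
    std::vector<int> idx(ne);
    for (int e = 0; e < ne; ++e) idx[e] = e;
    if (v != sf && last[v] >= 0) {
      std::swap(idx[last[v]], idx[ne - 1]);
      for (int e = ne - 2; e > 0; --e) {
        int j = (int)(unif_rand() * (e + 1));
        if (j > e) j = e;
        std::swap(idx[e], idx[j]);
      }
    } else {
      for (int e = ne - 1; e > 0; --e) {
        int j = (int)(unif_rand() * (e + 1));
        if (j > e) j = e;
        std::swap(idx[e], idx[j]);
      }
    }
    order[v] = idx;
  }
  std::string out(n, ' ');
  out[0] = seq[0];
  std::vector<int> ptr(nv, 0);
  int cur = vid[(unsigned char)seq[0]];
  for (int i = 1; i < n; ++i) {
    int e = order[cur][ptr[cur]++];
    cur = adj[cur][e];
    out[i] = vchar[cur];
  }
  return out;
}

// ---------------------------------------------------------------------------
// One-pass exact read mapping: reads are indexed by an 11-mer prefix word
// (forward and reverse-complement orientations) and the genome is scanned
// once with full-length verification at each word hit.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".map_exact_cpp")]]
DataFrame map_exact_cpp(std::vector<std::string> reads, std::string genome) {
  const int W = 11;
  const int gn = genome.size();
  struct Entry { int read; bool fwd; std::string seq; };
  std::unordered_map<uint32_t, std::vector<Entry> > index;
  const uint32_t mask = (1u << (2 * W)) - 1u;
  for (size_t r = 0; r < reads.size(); ++r) {
    for (int orient = 0; orient < 2; ++orient) {
      std::string s = reads[r];
      if (orient == 1) {
        std::string rc(s.rbegin(), s.rend());
        for (size_t k = 0; k < rc.size(); ++k) rc[k] = comp_base(rc[k]);
        s = rc;
      }
      if ((int)s.size() < W) continue;
      uint32_t code = 0; bool valid = true;
      for (int k = 0; k < W; ++k) {
        int c = base_code(s[k]);
        if (c < 0) { valid = false; break; }
        code = ((code << 2) | (uint32_t)c) & mask;
      }
      if (!valid) continue;
      Entry e; e.read = r; e.fwd = (orient == 0); e.seq = s;
      index[code].push_back(e);
    }
  }
  std::vector<int> out_read, out_start;
  std::vector<bool> out_fwd;
  uint32_t code = 0; int run = 0;
  for (int p = 0; p < gn; ++p) {
    int c = base_code(genome[p]);
    if (c < 0) { run = 0; code = 0; continue; }
    code = ((code << 2) | (uint32_t)c) & mask;
    if (++run < W) continue;
    auto it = index.find(code);
    if (it == index.end()) continue;
    const int pos = p - W + 1;
    for (const Entry& e : it->second) {
      if (pos + (int)e.seq.size() > gn) continue;
      if (genome.compare(pos, e.seq.size(), e.seq) == 0) {
        out_read.push_back(e.read + 1); // 1-based read index for R
        out_start.push_back(pos);       // 0-based genomic start
        out_fwd.push_back(e.fwd);
      }
    }
  }
  return DataFrame::create(_["read"] = out_read, _["start"] = out_start,
                           _["forward"] = out_fwd);
}
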