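#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

// miRNA:target duplex scoring. The miRNA (5'->3') is aligned against the
// REVERSED target window so that complementary pairing reads left to right.
// Column scores: Watson-Crick pair +5, G:U wobble +2, mismatch -3 (doubled
// to -6 when the miRNA base sits in the seed, positions 2-8), gap open -8,
// gap extend -2. Energy of an alignment (kcal/mol by convention):
//   -(3*#GC + 2*#AU + 1*#GU) + 4*#gap_openings + 2*#internal_mismatches
// (a gap contributes once per indel event, not per column, mirroring how
// affine scoring treats a run as one event).

static const int WC = 5, GU = 2, MM = -3, GAP_OPEN = -8, GAP_EXT = -2;

enum PairClass { P_NONE = 0, P_GC, P_AU, P_GU, P_MM };

static inline PairClass pair_class(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return P_GC;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return P_AU;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return P_GU;
  return P_MM;
}

// mirna_pos is 1-based position on the miRNA
static inline int column_score(PairClass pc, int mirna_pos) {
  switch (pc) {
    case P_GC:
    case P_AU: return WC;
    case P_GU: return GU;
    case P_MM: return (mirna_pos >= 2 && mirna_pos <= 8) ? 2 * MM : MM;
    default:   return 0;
  }
}

struct AlnCounts {
  int gc = 0, au = 0, gu = 0, mm = 0, gaps = 0, gap_runs = 0;
};

static double energy_from_counts(const AlnCounts &c) {
  if (c.gc + c.au + c.gu == 0) return 0.0;  // no duplex formed
  return -(3.0 * c.gc + 2.0 * c.au + 1.0 * c.gu) + 4.0 * c.gap_runs + 2.0 * c.mm;
}

// Smith-Waterman with affine gaps (Gotoh) and position-dependent column
// scores; full traceback so pair counts and the energy can be reported.
// [[Rcpp::export(name = ".duplex_align_cpp")]]
List duplex_align_cpp(std::string mirna, std::string window) {
  const int n = (int)mirna.size(), m = (int)window.size();
  if (n == 0 || m == 0) stop("duplex_align: empty sequence");
  std::string rwin(window.rbegin(), window.rend());
  const double NEG = -1e9;
  // H: best ending in column (pair/mismatch), E: gap in miRNA (consume
  // window base), F: gap in window (consume miRNA base)
  std::vector<std::vector<double>> H(n + 1, std::vector<double>(m + 1, 0.0)),
      E(n + 1, std::vector<double>(m + 1, NEG)),
      F(n + 1, std::vector<double>(m + 1, NEG));
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      PairClass pc = pair_class(mirna[i - 1], rwin[j - 1]);
      double diag = std::max({H[i - 1][j - 1], E[i - 1][j - 1], F[i - 1][j - 1], 0.0});
      double sc = diag + column_score(pc, i);
      E[i][j] = std::max(std::max(H[i][j - 1], F[i][j - 1]) + GAP_OPEN,
                         E[i][j - 1] + GAP_EXT);
      F[i][j] = std::max(std::max(H[i - 1][j], E[i - 1][j]) + GAP_OPEN,
                         F[i - 1][j] + GAP_EXT);
      H[i][j] = sc;
      double cell = std::max({H[i][j], E[i][j], F[i][j]});
      if (cell > best + 1e-9) { best = cell; bi = i; bj = j; }
    }
  }
  AlnCounts counts;
  std::vector<int> mir_pos, tgt_pos;
  std::vector<std::string> cls;
  if (best > 0) {
    // traceback from the best H/E/F cell
    int i = bi, j = bj;
    char state;
    if (H[i][j] >= E[i][j] && H[i][j] >= F[i][j]) state = 'H';
    else if (E[i][j] >= F[i][j]) state = 'E';
    else state = 'F';
    while (i > 0 && j > 0) {
      if (state == 'H') {
        PairClass pc = pair_class(mirna[i - 1], rwin[j - 1]);
        if (pc == P_GC) { counts.gc++; cls.push_back("WC"); }
        else if (pc == P_AU) { counts.au++; cls.push_back("WC"); }
        else if (pc == P_GU) { counts.gu++; cls.push_back("GU"); }
        else { counts.mm++; cls.push_back("mismatch"); }
        mir_pos.push_back(i);
        tgt_pos.push_back(m - j + 1);  // back to original window coordinates
        double need = H[i][j] - column_score(pc, i);
        --i; --j;
        if (i == 0 || j == 0) break;
        if (std::fabs(std::max({H[i][j], E[i][j], F[i][j], 0.0}) - need) > 1e-6) {
          // local alignment start
          break;
        }
        if (need <= 1e-9 && H[i][j] <= 1e-9 && E[i][j] < -1e-9 && F[i][j] < -1e-9)
          break;
        if (H[i][j] >= E[i][j] && H[i][j] >= F[i][j] &&
            std::fabs(H[i][j] - need) < 1e-6) state = 'H';
        else if (E[i][j] >= F[i][j] && std::fabs(E[i][j] - need) < 1e-6) state = 'E';
        else if (std::fabs(F[i][j] - need) < 1e-6) state = 'F';
        else break;  // alignment started here (diag came from 0)
      } else if (state == 'E') {
        counts.gaps++;
        cls.push_back("gap");
        mir_pos.push_back(NA_INTEGER);
        tgt_pos.push_back(m - j + 1);
        double cur = E[i][j];
        if (std::fabs(E[i][j - 1] + GAP_EXT - cur) < 1e-6) { --j; state = 'E'; }
        else if (std::fabs(H[i][j - 1] + GAP_OPEN - cur) < 1e-6) {
          counts.gap_runs++; --j; state = 'H';
        } else { counts.gap_runs++; --j; state = 'F'; }
      } else {  // F
        counts.gaps++;
        cls.push_back("gap");
        mir_pos.push_back(i);
        tgt_pos.push_back(NA_INTEGER);
        double cur = F[i][j];
        if (std::fabs(F[i - 1][j] + GAP_EXT - cur) < 1e-6) { --i; state = 'F'; }
        else if (std::fabs(H[i - 1][j] + GAP_OPEN - cur) < 1e-6) {
          counts.gap_runs++; --i; state = 'H';
        } else { counts.gap_runs++; --i; state = 'E'; }
      }
    }
    std::reverse(mir_pos.begin(), mir_pos.end());
    std::reverse(tgt_pos.begin(), tgt_pos.end());
    std::reverse(cls.begin(), cls.end());
  }
  return List::create(
      _["score"] = best > 0 ? best : 0.0,
      _["energy"] = energy_from_counts(counts),
      _["n_wc"] = counts.gc + counts.au, _["n_gu"] = counts.gu,
      _["n_mismatch"] = counts.mm, _["n_gaps"] = counts.gaps,
      _["n_gap_runs"] = counts.gap_runs,
      _["alignment"] = DataFrame::create(
          _["mirna_pos"] = wrap(mir_pos), _["target_pos"] = wrap(tgt_pos),
          _["cls"] = wrap(cls)));
}

// ---------------------------------------------------------------------------
// Brute-force reference enumerator used only by the test suite: enumerates
// every local alignment (all start cells, all monotone column sequences with
// affine gap states) and returns the maximum score. Exponential; callers
// keep sequences at <= 10 nt.

struct BruteCtx {
  const std::string *a;   // miRNA
  const std::string *b;   // reversed window
  double best;
};

// state: 0 = last column was a pair/mismatch, 1 = gap in a, 2 = gap in b
static void brute_rec(BruteCtx &ctx, int i, int j, int state, double score) {
  if (score > ctx.best) ctx.best = score;
  const int n = (int)ctx.a->size(), m = (int)ctx.b->size();
  if (i < n && j < m) {
    PairClass pc = pair_class((*ctx.a)[i], (*ctx.b)[j]);
    brute_rec(ctx, i + 1, j + 1, 0, score + column_score(pc, i + 1));
  }
  if (j < m)  // gap in miRNA, consume window base
    brute_rec(ctx, i, j + 1, 1, score + (state == 1 ? GAP_EXT : GAP_OPEN));
  if (i < n)  // gap in window, consume miRNA base
    brute_rec(ctx, i + 1, j, 2, score + (state == 2 ? GAP_EXT : GAP_OPEN));
}

// [[Rcpp::export(name = ".duplex_brute_cpp")]]
double duplex_brute_cpp(std::string mirna, std::string window) {
  const int n = (int)mirna.size(), m = (int)window.size();
  if (n == 0 || m == 0) stop("duplex_brute: empty sequence");
  if (n > 12 || m > 12) stop("duplex_brute: sequences must be <= 12 nt");
  std::string rwin(window.rbegin(), window.rend());
  BruteCtx ctx{&mirna, &rwin, 0.0};
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      brute_rec(ctx, i, j, -1, 0.0);
  return ctx.best;
}
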