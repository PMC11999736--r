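#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Bases are encoded 0=A, 1=C, 2=G, 3=U. Canonical pairs: GC, CG, AU, UA,
// GU, UG (wobble included), i.e. 6 of the 16 ordered combinations.
static const int CANONICAL[4][4] = {
  // A  C  G  U
  {0, 0, 0, 1}, // A
  {0, 0, 1, 0}, // C
  {0, 1, 0, 1}, // G
  {1, 0, 1, 0}  // U
};

struct StructSpec {
  int Lstr, Lran, M, slack;
  bool anchored;
  std::vector<int> mod_start, mod_len;        // structure coords, 0-based
  std::vector<int> cons_pos, cons_base, cons_mod;
  std::vector<int> pair_a, pair_b, pair_moda, pair_modb, pair_maxmod;
  bool has_cross;                              // any pair spanning modules
};

static int module_of(const StructSpec& sp, int pos) {
  for (int j = sp.M - 1; j >= 0; --j)
    if (pos >= sp.mod_start[j]) return j;
  return 0;
}

static StructSpec build_spec(int Lran, IntegerVector mod_start,
                             IntegerVector mod_len, IntegerVector cons_pos,
                             IntegerVector cons_base, IntegerVector pair_a,
                             IntegerVector pair_b, bool anchored) {
  StructSpec sp;
  sp.M = mod_start.size();
  sp.mod_start.assign(mod_start.begin(), mod_start.end());
  sp.mod_len.assign(mod_len.begin(), mod_len.end());
  sp.Lstr = 0;
  for (int j = 0; j < sp.M; ++j) sp.Lstr += sp.mod_len[j];
  sp.Lran = Lran;
  sp.slack = Lran - sp.Lstr;
  sp.anchored = anchored;
  sp.cons_pos.assign(cons_pos.begin(), cons_pos.end());
  sp.cons_base.assign(cons_base.begin(), cons_base.end());
  sp.cons_mod.resize(sp.cons_pos.size());
  for (size_t i = 0; i < sp.cons_pos.size(); ++i)
    sp.cons_mod[i] = module_of(sp, sp.cons_pos[i]);
  sp.pair_a.assign(pair_a.begin(), pair_a.end());
  sp.pair_b.assign(pair_b.begin(), pair_b.end());
  sp.pair_moda.resize(sp.pair_a.size());
  sp.pair_modb.resize(sp.pair_a.size());
  sp.pair_maxmod.resize(sp.pair_a.size());
  sp.has_cross = false;
  for (size_t i = 0; i < sp.pair_a.size(); ++i) {
    sp.pair_moda[i] = module_of(sp, sp.pair_a[i]);
    sp.pair_modb[i] = module_of(sp, sp.pair_b[i]);
    sp.pair_maxmod[i] = std::max(sp.pair_moda[i], sp.pair_modb[i]);
    if (sp.pair_moda[i] != sp.pair_modb[i]) sp.has_cross = true;
  }
  return sp;
}

// Per-module mismatch cost at every shift r (sequence offset of module j is
// mod_start[j] + r). Only valid when no pair spans modules.
static void module_costs(const StructSpec& sp, const int* seq,
                         std::vector<std::vector<int> >& cost) {
  cost.assign(sp.M, std::vector<int>(sp.slack + 1, 0));
  for (size_t i = 0; i < sp.cons_pos.size(); ++i) {
    int j = sp.cons_mod[i];
    for (int r = 0; r <= sp.slack; ++r)
      cost[j][r] += (seq[sp.cons_pos[i] + r] != sp.cons_base[i]);
  }
  for (size_t i = 0; i < sp.pair_a.size(); ++i) {
    int j = sp.pair_maxmod[i];
    for (int r = 0; r <= sp.slack; ++r)
      cost[j][r] += !CANONICAL[seq[sp.pair_a[i] + r]][seq[sp.pair_b[i] + r]];
  }
}

// Straightforward recursive enumeration of all placements; also counts
// them. Handles cross-module pairs. Used for toys and as the reference.
struct BruteCtx {
  const StructSpec* sp;
  const int* seq;
  std::vector<int> shift;
  long long count;
  int best;
};

static void brute_rec(BruteCtx& ctx, int j, int rmin, int acc) {
  const StructSpec& sp = *ctx.sp;
  if (j == sp.M) {
    ctx.count++;
    if (acc < ctx.best) ctx.best = acc;
    return;
  }
  int rlo = rmin, rhi = sp.slack;
  if (j == 0 && sp.anchored) rhi = 0;
  for (int r = rlo; r <= rhi; ++r) {
    ctx.shift[j] = r;
    int add = 0;
    for (size_t i = 0; i < sp.cons_pos.size(); ++i)
      if (sp.cons_mod[i] == j)
        add += (ctx.seq[sp.cons_pos[i] + r] != sp.cons_base[i]);
    for (size_t i = 0; i < sp.pair_a.size(); ++i)
      if (sp.pair_maxmod[i] == j) {
        int pa = sp.pair_a[i] + ctx.shift[sp.pair_moda[i]];
        int pb = sp.pair_b[i] + ctx.shift[sp.pair_modb[i]];
        add += !CANONICAL[ctx.seq[pa]][ctx.seq[pb]];
      }
    brute_rec(ctx, j + 1, r, acc + add);
  }
}

static void brute_scan(const StructSpec& sp, const int* seq, int& best,
                       long long& count) {
  BruteCtx ctx;
  ctx.sp = &sp;
  ctx.seq = seq;
  ctx.shift.assign(sp.M, 0);
  ctx.count = 0;
  ctx.best = std::numeric_limits<int>::max();
  brute_rec(ctx, 0, 0, 0);
  best = ctx.best;
  count = ctx.count;
}

// Anchored-aware DP driver (module 0 shift fixed to 0 when anchored).
static int scan_one(const StructSpec& sp, const int* seq,
                    std::vector<std::vector<int> >& cost,
                    std::vector<int>& suffix) {
  if (sp.has_cross) {
    int best; long long cnt;
    brute_scan(sp, seq, best, cnt);
    return best;
  }
  module_costs(sp, seq, cost);
  const int S = sp.slack;
  // backward DP: suffix[r] = min over nondecreasing shifts of modules
  // j..M-1 with shift_j >= r
  suffix.assign(S + 1, 0);
  for (int j = sp.M - 1; j >= 0; --j) {
    int run = std::numeric_limits<int>::max();
    for (int r = S; r >= 0; --r) {
      int v = cost[j][r] + ((j == sp.M - 1) ? 0 : suffix[r]);
      if (v < run) run = v;
      cost[j][r] = run;                  // temp: best for shift >= r
    }
    if (j == 0 && sp.anchored) {
      // module 0 pinned: its own cost at r = 0 plus the best of the rest
      int rest = (sp.M > 1) ? suffix[0] : 0;
      // recover module-0 raw cost at shift 0: recompute directly
      int c0 = 0;
      for (size_t i = 0; i < sp.cons_pos.size(); ++i)
        if (sp.cons_mod[i] == 0) c0 += (seq[sp.cons_pos[i]] != sp.cons_base[i]);
      for (size_t i = 0; i < sp.pair_a.size(); ++i)
        if (sp.pair_maxmod[i] == 0)
          c0 += !CANONICAL[seq[sp.pair_a[i]]][seq[sp.pair_b[i]]];
      return c0 + rest;
    }
    for (int r = 0; r <= S; ++r) suffix[r] = cost[j][r];
  }
  return suffix[0];
}

// [[Rcpp::export]]
int cpp_min_distance(IntegerVector seq, int Lran, IntegerVector mod_start,
                     IntegerVector mod_len, IntegerVector cons_pos,
                     IntegerVector cons_base, IntegerVector pair_a,
                     IntegerVector pair_b, bool anchored) {
  StructSpec sp = build_spec(Lran, mod_start, mod_len, cons_pos, cons_base,
                             pair_a, pair_b, anchored);
  if (seq.size() != Lran) stop("sequence length must equal Lran");
  std::vector<int> s(seq.begin(), seq.end());
  std::vector<std::vector<int> > cost;
  std::vector<int> suffix;
  return scan_one(sp, s.data(), cost, suffix);
}

// [[Rcpp::export]]
List cpp_scan_enumerate(IntegerVector seq, int Lran, IntegerVector mod_start,
                        IntegerVector mod_len, IntegerVector cons_pos,
                        IntegerVector cons_base, IntegerVector pair_a,
                        IntegerVector pair_b, bool anchored) {
  StructSpec sp = build_spec(Lran, mod_start, mod_len, cons_pos, cons_base,
                             pair_a, pair_b, anchored);
  if (seq.size() != Lran) stop("sequence length must equal Lran");
  std::vector<int> s(seq.begin(), seq.end());
  int best; long long cnt;
  brute_scan(sp, s.data(), best, cnt);
  return List::create(_["min_distance"] = best,
                      _["n_placements"] = (double)cnt);
}

// [[Rcpp::export]]
IntegerVector cpp_sample_min_distances(int n, int Lran,
                                       IntegerVector mod_start,
                                       IntegerVector mod_len,
                                       IntegerVector cons_pos,
                                       IntegerVector cons_base,
                                       IntegerVector pair_a,
                                       IntegerVector pair_b, bool anchored) {
  StructSpec sp = build_spec(Lran, mod_start, mod_len, cons_pos, cons_base,
                             pair_a, pair_b, anchored);
  IntegerVector out(n);
  std::vector<int> seq(Lran);
  std::vector<std::vector<int> > cost;
  std::vector<int> suffix;
  RNGScope scope;
  for (int t = 0; t < n; ++t) {
    for (int i = 0; i < Lran; ++i) {
      int b = (int)(unif_rand() * 4.0);
      seq[i] = (b > 3) ? 3 : b;
    }
    out[t] = scan_one(sp, seq.data(), cost, suffix);
    if (t % 65536 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_exhaustive_counts(int Lran, IntegerVector mod_start,
                                    IntegerVector mod_len,
                                    IntegerVector cons_pos,
                                    IntegerVector cons_base,
                                    IntegerVector pair_a,
                                    IntegerVector pair_b, bool anchored,
                                    int max_m) {
  StructSpec sp = build_spec(Lran, mod_start, mod_len, cons_pos, cons_base,
                             pair_a, pair_b, anchored);
  if (Lran > 15) stop("exhaustive enumeration guarded to Lran <= 15");
  NumericVector counts(max_m + 1);
  std::vector<int> seq(Lran, 0);
  std::vector<std::vector<int> > cost;
  std::vector<int> suffix;
  long long total = 1;
  for (int i = 0; i < Lran; ++i) total *= 4;
  for (long long code = 0; code < total; ++code) {
    long long c = code;
    for (int i = 0; i < Lran; ++i) { seq[i] = c & 3; c >>= 2; }
    int m = scan_one(sp, seq.data(), cost, suffix);
    if (m <= max_m) counts[m] += 1.0;
    if ((code & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return counts;
}
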