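#include <Rcpp.h>
using namespace Rcpp;

// Cell coding shared with R: 0 empty, 1 parasite, 2 mutualist.
//
// Rate tables are 2x3 matrices: row = focal strain (parasite, mutualist),
// column = partner state (empty, parasite, mutualist). Rp holds the
// per-neighbour colonization probability R/4 (R clamped to [0,4]); D holds
// the clamped death probability.
//
// All randomness flows through R's own uniform generator (unif_rand), so a
// single set.seed() in R makes every trajectory bit-reproducible. Draw order
// per site event is fixed: one draw per EMPTY Neumann neighbour of an
// occupied focal A cell (order up, right, down, left), then likewise for the
// B cell, then one death draw per occupied focal cell (A first, then B).
// Empty focal cells consume no draws.

struct Tables {
  double Rp[2][3];
  double D[2][3];
};

static Tables as_tables(const NumericMatrix& Rp, const NumericMatrix& D) {
  Tables t;
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 3; ++j) {
      t.Rp[i][j] = Rp(i, j);
      t.D[i][j] = D(i, j);
    }
  return t;
}

static inline int wrap(int i, int L) { return (i + L) % L; }

static const int DI[4] = {-1, 0, 1, 0};  // up, right, down, left (rows)
static const int DJ[4] = {0, 1, 0, -1};

static void reproduce(IntegerMatrix& own, int partner_state,
                      const Tables& t, int i, int j, int L) {
  int s = own(i, j);
  if (s == 0) return;
  double rp = t.Rp[s - 1][partner_state];
  for (int k = 0; k < 4; ++k) {
    int ni = wrap(i + DI[k], L), nj = wrap(j + DJ[k], L);
    if (own(ni, nj) == 0 && unif_rand() < rp) own(ni, nj) = s;
  }
}

static void site_event(IntegerMatrix& A, IntegerMatrix& B,
                       const Tables& tA, const Tables& tB,
                       int i, int j, int L) {
  // (a) A reproduces, partner = current B occupant of the same site
  reproduce(A, B(i, j), tA, i, j, L);
  // (b) B reproduces; (a) cannot have altered A(i,j) or any B cell
  reproduce(B, A(i, j), tB, i, j, L);
  // (c) A death, against current B(i,j)
  int a = A(i, j);
  if (a != 0 && unif_rand() < tA.D[a - 1][B(i, j)]) A(i, j) = 0;
  // (d) B death, against current A(i,j) -- which (c) may just have emptied
  int b = B(i, j);
  if (b != 0 && unif_rand() < tB.D[b - 1][A(i, j)]) B(i, j) = 0;
}

static void count_states(const IntegerMatrix& g, int* out) {
  out[0] = out[1] = out[2] = 0;
  for (int k = 0; k < g.size(); ++k) ++out[g[k]];
}

// [[Rcpp::export]]
List cpp_site_event(IntegerMatrix gridA, IntegerMatrix gridB,
                    NumericMatrix RpA, NumericMatrix DA,
                    NumericMatrix RpB, NumericMatrix DB,
                    int i, int j) {
  IntegerMatrix A = clone(gridA), B = clone(gridB);
  Tables tA = as_tables(RpA, DA), tB = as_tables(RpB, DB);
  site_event(A, B, tA, tB, i, j, A.nrow());
  return List::create(_["grid_A"] = A, _["grid_B"] = B);
}

// Runs `generations` full generations (L*L site events each, sites drawn
// uniformly with replacement). If record_counts, returns a generations x 6
// matrix of cell counts (A empty/parasite/mutualist, then B) taken at the
// end of each generation.
// [[Rcpp::export]]
List cpp_run(IntegerMatrix gridA, IntegerMatrix gridB,
             NumericMatrix RpA, NumericMatrix DA,
             NumericMatrix RpB, NumericMatrix DB,
             int generations, bool record_counts) {
  IntegerMatrix A = clone(gridA), B = clone(gridB);
  Tables tA = as_tables(RpA, DA), tB = as_tables(RpB, DB);
  const int L = A.nrow();
  const int n = L * L;
  IntegerMatrix counts(record_counts ? generations : 0, 6);
  int cnt[3];
  for (int g = 0; g < generations; ++g) {
    for (int e = 0; e < n; ++e) {
      int idx = (int)(unif_rand() * n);
      if (idx >= n) idx = n - 1;
      site_event(A, B, tA, tB, idx % L, idx / L, L);
    }
    if (record_counts) {
      count_states(A, cnt);
      for (int s = 0; s < 3; ++s) counts(g, s) = cnt[s];
      count_states(B, cnt);
      for (int s = 0; s < 3; ++s) counts(g, s + 3) = cnt[s];
    }
  }
  List out = List::create(_["grid_A"] = A, _["grid_B"] = B);
  if (record_counts) out["counts"] = counts;
  return out;
}
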