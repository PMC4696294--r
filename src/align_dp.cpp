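#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Glocal DP over (molecule cut, reference cut) states.
//
// Molecule fragments x[0..m-1] (m >= 2) give interior cuts 1..m-1; reference
// fragments f[0..R] give cuts 1..R. State (i, j): molecule cut i is matched
// to reference cut j. Blocks between consecutive matched cuts may merge up
// to `delta` fragments on either side; a merged reference fragment pays
// miss_pen per skipped reference cut, a merged molecule fragment pays
// false_pen per skipped molecule cut, and the block size mismatch costs
// (dx - dr)^2 / (2 (cv dr)^2). Terminal molecule fragments are partial
// (molecules start/end mid-fragment), so they are scored one-sided: free if
// they fit inside the flanking reference fragment, quadratic on the excess
// otherwise, plus false_pen per molecule cut merged into the terminal block.
//
// Returns, for every reference end cut j, the best-scoring alignment that
// consumes the whole molecule and ends with a match at j (score, start cut,
// final matched molecule cut, number of matched cuts). If path_end_i /
// path_end_j >= 0, also returns the matched (mol cut, ref cut) pairs of the
// best path ending at that state; the traceback uses the same scan order and
// strict improvement as the forward pass, so it reproduces the reported
// optimum deterministically.
// [[Rcpp::export(name = ".dp_align")]]
List dp_align(NumericVector mol, NumericVector ref_frags,
              double cv, double miss_pen, double false_pen, int delta,
              int path_end_i = -1, int path_end_j = -1) {
  const int m = mol.size();            // fragments
  const int R = ref_frags.size() - 1;  // interior reference cuts
  const double NEG = -std::numeric_limits<double>::infinity();
  if (m < 2 || R < 1)
    return List::create(_["cand"] = NumericMatrix(0, 5));

  std::vector<double> X(m + 1, 0.0), F(R + 2, 0.0);
  for (int i = 0; i < m; ++i) X[i + 1] = X[i] + mol[i];
  for (int j = 0; j <= R; ++j) F[j + 1] = F[j] + ref_frags[j];

  // block size and inverse Gaussian denominator per (reference cut j,
  // lookback dj): dr = F[j] - F[j-dj], inv = 1 / (2 (cv dr)^2)
  std::vector<double> DR((size_t)(R + 1) * delta),
                      INV((size_t)(R + 1) * delta);
  for (int j = 1; j <= R; ++j)
    for (int dj = 1; dj <= delta && dj <= j - 1; ++dj) {
      const double dr = F[j] - F[j - dj];
      DR[(size_t)(j)*delta + dj - 1] = dr;
      INV[(size_t)(j)*delta + dj - 1] = 1.0 / (2.0 * cv * dr * cv * dr);
    }

  // state layout: column-per-j, molecule cut i contiguous (stride 1)
  const int nI = m;  // i = 1..m-1 used
  std::vector<double> S((size_t)nI * (R + 1), NEG);
  std::vector<int> K((size_t)nI * (R + 1), 0);
  std::vector<int> START((size_t)nI * (R + 1), 0);
  const bool want_path = path_end_i >= 1 && path_end_j >= 1;
  std::vector<int> PI, PJ;
  if (want_path) {
    PI.assign((size_t)nI * (R + 1), 0);  // 0 = alignment starts here
    PJ.assign((size_t)nI * (R + 1), 0);
  }
  auto idx = [&](int i, int j) { return (size_t)j * nI + i; };

  const int max_i0 = std::min(delta, m - 1);
  for (int j = 1; j <= R; ++j) {
    const int djmax = std::min(delta, j - 1);
    for (int i = 1; i <= m - 1; ++i) {
      double best = NEG; int bK = 0, bS = 0, bpi = 0, bpj = 0;
      if (i <= max_i0) {
        // start terminal: molecule fragments 1..i vs reference fragment
        // ending at cut j (one-sided)
        const double s = X[i], L = ref_frags[j - 1];
        const double over = s > L ? s - L : 0.0;
        best = -(over * over) / (2.0 * cv * L * cv * L)
               - false_pen * (i - 1);
        bK = 1; bS = j;
      }
      const int dimax = std::min(delta, i - 1);
      const double Xi = X[i];
      for (int dj = 1; dj <= djmax; ++dj) {
        const double dr = DR[(size_t)j * delta + dj - 1];
        const double inv = INV[(size_t)j * delta + dj - 1];
        const double base_cost = miss_pen * (dj - 1);
        const double* Sprev = &S[idx(0, j - dj)];
        for (int di = 1; di <= dimax; ++di) {
          const double prev = Sprev[i - di];
          if (prev == NEG) continue;
          const double d = (Xi - X[i - di]) - dr;
          const double sc = prev - d * d * inv
                            - base_cost - false_pen * (di - 1);
          if (sc > best) {
            best = sc;
            bK = K[idx(i - di, j - dj)] + 1;
            bS = START[idx(i - di, j - dj)];
            bpi = i - di; bpj = j - dj;
          }
        }
      }
      S[idx(i, j)] = best;
      K[idx(i, j)] = bK;
      START[idx(i, j)] = bS;
      if (want_path) { PI[idx(i, j)] = bpi; PJ[idx(i, j)] = bpj; }
    }
  }

  // terminal candidates: one best final state per reference end cut
  std::vector<double> cj, cs, cst, cei, ck;
  const int min_if = std::max(1, m - delta);
  for (int j = 1; j <= R; ++j) {
    double best = NEG; int bi = -1;
    for (int i = min_if; i <= m - 1; ++i) {
      const double base = S[idx(i, j)];
      if (base == NEG) continue;
      const double e = X[m] - X[i], L = ref_frags[j];
      const double over = e > L ? e - L : 0.0;
      const double tot = base - (over * over) / (2.0 * cv * L * cv * L)
                         - false_pen * (m - 1 - i);
      if (tot > best) { best = tot; bi = i; }
    }
    if (bi >= 0) {
      cj.push_back(j); cs.push_back(best);
      cst.push_back(START[idx(bi, j)]);
      cei.push_back(bi); ck.push_back(K[idx(bi, j)]);
    }
  }
  NumericMatrix cand(cj.size(), 5);
  for (size_t r = 0; r < cj.size(); ++r) {
    cand(r, 0) = cj[r]; cand(r, 1) = cs[r]; cand(r, 2) = cst[r];
    cand(r, 3) = cei[r]; cand(r, 4) = ck[r];
  }
  colnames(cand) = CharacterVector::create("end_cut", "score", "start_cut",
                                           "end_mol_cut", "matched");
  if (!want_path)
    return List::create(_["cand"] = cand);

  std::vector<int> pi_out, pj_out;
  int i = path_end_i, j = path_end_j;
  while (i >= 1 && j >= 1) {
    pi_out.push_back(i); pj_out.push_back(j);
    int ni = PI[idx(i, j)], nj = PJ[idx(i, j)];
    i = ni; j = nj;
  }
  std::reverse(pi_out.begin(), pi_out.end());
  std::reverse(pj_out.begin(), pj_out.end());
  return List::create(_["cand"] = cand,
                      _["mol_cuts"] = IntegerVector(pi_out.begin(), pi_out.end()),
                      _["ref_cuts"] = IntegerVector(pj_out.begin(), pj_out.end()));
}
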