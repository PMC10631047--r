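#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dynamic-programming fill for the b-ion alignment.
//
// Rows are peptide residues (the i-th row places the boundary after residue
// i, i.e. the b_{i+1} position; the last boundary is the precursor MH+).
// Columns are peaks of the completed spectrum, sorted ascending, with the
// virtual anchor (m/z = proton) at column 0.
//
// Moves into cell (i, j):
//  - from a predecessor column m: candidate shift
//        s = (peak[j] - bt[i]) - cum(i-1, m)
//    scored as an alignment (S_A, no shift recorded) when |s| <= tol and as
//    a realignment (S_R, shift recorded) otherwise. Predecessors are
//    admissible only when the residue mass is found between peak j and some
//    peak k (aafound), with m <= k_max, the largest such witness. Row 0 may
//    additionally realign from the anchor even without a witness.
//  - non-alignment: stay in column j, add S_N; only when aafound is false.
//
// cum(i, j) tracks peak[j] - bt[i] for mapped cells and is inherited down a
// column across non-aligned residues, so shifts of later realignments
// account for the residue masses skipped in between (a realignment across
// merely-missing peaks gets shift ~ 0 and is scored as an alignment).
//
// Scores: sc[0] = align/both, sc[1] = align/single, sc[2] = realign penalty
// (both), sc[3] = realign penalty (single), sc[4] = non-align. A realign
// contributes align + penalty (e.g. 10 - 8 = +2); evid[j] = 1 when peak j
// has both b- and y-ion evidence.

static const double NEG = -1e9;

// [[Rcpp::export(name = ".dp_fill_cpp")]]
List dp_fill_cpp(NumericVector bt, NumericVector rm, NumericVector peaks,
                 IntegerVector evid, IntegerVector rank, NumericVector sc,
                 double tol) {
  const int n = bt.size();
  const int M = peaks.size();
  if (rm.size() != n) stop("bt and rm must have equal length");
  if (evid.size() != M) stop("peaks and evid must have equal length");
  if (rank.size() != M) stop("peaks and rank must have equal length");

  NumericMatrix D(n, M);      // best score
  IntegerMatrix move(n, M);   // 0 unreachable, 1 align, 2 realign, 3 non-align
  IntegerMatrix pred(n, M);   // predecessor column (0-based; -1 none)
  NumericMatrix shift(n, M);  // shift recorded by a realign move
  NumericMatrix cum(n, M);    // cumulative shift state

  for (int i = 0; i < n; ++i) {
    const double sa_b = sc[0], sa_s = sc[1], sr_b = sc[2], sr_s = sc[3], sn = sc[4];
    for (int j = 0; j < M; ++j) {
      // witnesses: peaks k with |(peak_j - peak_k) - rm_i| <= tol
      double lo = peaks[j] - rm[i] - tol, hi = peaks[j] - rm[i] + tol;
      int kmax = -1;
      // peaks sorted: binary search for upper bound of hi
      int a = 0, b = M;
      while (a < b) { int mid = (a + b) / 2; if (peaks[mid] <= hi) a = mid + 1; else b = mid; }
      if (a - 1 >= 0 && peaks[a - 1] >= lo && a - 1 < j) kmax = a - 1;

      double best = NEG;
      int bmove = 0, bpred = -1;
      double bshift = 0.0;

      int bound = kmax;
      if (kmax < 0 && i == 0 && j > 0) bound = 0;  // anchor seeding of row 0

      for (int m = 0; m <= bound; ++m) {
        double ps, pc;
        if (i == 0) {
          if (m != 0) continue;  // only the anchor is reachable before row 0
          ps = 0.0; pc = 0.0;
        } else {
          if (move(i - 1, m) == 0) continue;
          ps = D(i - 1, m); pc = cum(i - 1, m);
        }
        double s = (peaks[j] - bt[i]) - pc;
        bool is_align = std::fabs(s) <= tol;
        // a realignment scores the landing alignment decreased by the
        // realignment penalty; a null shift escapes the penalty entirely
        double cand = ps + (is_align ? (evid[j] ? sa_b : sa_s)
                                     : (evid[j] ? sa_b + sr_b : sa_s + sr_s));
        int cmove = is_align ? 1 : 2;
        bool take = false;
        if (cand > best + 1e-12) take = true;
        else if (cand > best - 1e-12 && bmove != 3 && bmove != 0) {
          // tie: prefer align over realign, then the predecessor peak with
          // stronger ion evidence (both > native > inferred), then the
          // nearer predecessor
          if (cmove < bmove) take = true;
          else if (cmove == bmove) {
            if (rank[m] > rank[bpred]) take = true;
            else if (rank[m] == rank[bpred] && m > bpred) take = true;
          }
        }
        if (take) { best = cand; bmove = cmove; bpred = m;
                    bshift = is_align ? 0.0 : s; }
      }

      if (kmax < 0) {  // aafound false: non-align keeps the column
        double ps = (i == 0) ? (j == 0 ? 0.0 : NEG)
                             : (move(i - 1, j) != 0 ? D(i - 1, j) : NEG);
        if (ps > NEG / 2) {
          double cand = ps + sn;
          if (cand > best) {
            best = cand; bmove = 3; bpred = j; bshift = 0.0;
          }
        }
      }

      if (bmove == 0) { D(i, j) = NEG; move(i, j) = 0; pred(i, j) = -1;
                        shift(i, j) = 0.0; cum(i, j) = 0.0; continue; }
      D(i, j) = best; move(i, j) = bmove; pred(i, j) = bpred; shift(i, j) = bshift;
      if (bmove == 3) {
        cum(i, j) = (i == 0) ? 0.0 : cum(i - 1, j);
      } else {
        cum(i, j) = peaks[j] - bt[i];
      }
    }
  }

  return List::create(_["score"] = D, _["move"] = move, _["pred"] = pred,
                      _["shift"] = shift, _["cum"] = cum);
}
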