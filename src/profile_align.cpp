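#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman) alignment of a protein sequence against a
// position-specific log-odds profile with affine gaps. `emis` is a
// (columns x alphabet) score matrix; `seq` holds 1-based alphabet
// indices (0 = unknown residue, scored 0). Gap penalties are negative;
// `gap_open` is charged for the first gapped position, `gap_extend`
// for each subsequent one.
//
// Returns the best local score, the aligned ranges, and for every
// profile column the 1-based sequence position aligned to it (0 =
// column deleted inside the aligned region, -1 = outside it).
// [[Rcpp::export(name = ".profile_sw")]]
List profile_sw(NumericMatrix emis, IntegerVector seq,
                double gap_open, double gap_extend) {
  const int P = emis.nrow();
  const int n = seq.size();
  const double NEG = -1e30;

  std::vector<double> M((n + 1) * (P + 1), NEG),
                      X((n + 1) * (P + 1), NEG),
                      Y((n + 1) * (P + 1), NEG);
  // traceback: 0 none/start, 1 from M, 2 from X, 3 from Y
  std::vector<signed char> tM((n + 1) * (P + 1), 0),
                           tX((n + 1) * (P + 1), 0),
                           tY((n + 1) * (P + 1), 0);
  auto at = [P](int i, int j) { return i * (P + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= P; ++j) {
      int a = seq[i - 1];
      double sub = (a >= 1 && a <= emis.ncol()) ? emis(j - 1, a - 1) : 0.0;
      // M: consume residue i at column j
      double m0 = 0.0; signed char tm = 0;
      double pm = M[at(i - 1, j - 1)], px = X[at(i - 1, j - 1)],
             py = Y[at(i - 1, j - 1)];
      if (pm > m0) { m0 = pm; tm = 1; }
      if (px > m0) { m0 = px; tm = 2; }
      if (py > m0) { m0 = py; tm = 3; }
      M[at(i, j)] = m0 + sub;
      tM[at(i, j)] = tm;
      // X: residue i inserted (no column consumed)
      double xo = M[at(i - 1, j)] + gap_open;
      double xe = X[at(i - 1, j)] + gap_extend;
      if (xo >= xe) { X[at(i, j)] = xo; tX[at(i, j)] = 1; }
      else          { X[at(i, j)] = xe; tX[at(i, j)] = 2; }
      // Y: column j deleted (no residue consumed)
      double yo = M[at(i, j - 1)] + gap_open;
      double ye = Y[at(i, j - 1)] + gap_extend;
      if (yo >= ye) { Y[at(i, j)] = yo; tY[at(i, j)] = 1; }
      else          { Y[at(i, j)] = ye; tY[at(i, j)] = 3; }
      if (M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; }
    }
  }

  IntegerVector col_to_res(P, -1);
  int seq_start = 0, seq_end = 0, prof_start = 0, prof_end = 0;
  if (best > 0.0) {
    seq_end = bi; prof_end = bj;
    int i = bi, j = bj, state = 1; // start in M at the best cell
    while (i > 0 && j > 0) {
      if (state == 1) {
        col_to_res[j - 1] = i;
        signed char tm = tM[at(i, j)];
        --i; --j;
        if (tm == 0) break;
        state = tm;
      } else if (state == 2) {
        signed char tx = tX[at(i, j)];
        --i;
        state = tx;
      } else {
        col_to_res[j - 1] = 0;
        signed char ty = tY[at(i, j)];
        --j;
        state = ty;
      }
    }
    seq_start = i + 1; prof_start = j + 1;
  }
  return List::create(_["score"] = best,
                      _["seq_start"] = seq_start, _["seq_end"] = seq_end,
                      _["prof_start"] = prof_start, _["prof_end"] = prof_end,
                      _["col_to_res"] = col_to_res);
}
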