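#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exhaustive k-way MDR scan over cross-validation folds.
//
// For each combination of k SNP columns (lexicographic order over column
// index) and each fold f, cells are the joint 0/1/2 dosage states; a cell is
// labelled high-risk when its summed training score exceeds `threshold`
// (sums at or below the threshold, and unobserved cells, are low-risk).
// Training balanced accuracy is the mean of the score-mass sensitivity
// (positive mass captured in high cells over total positive mass) and
// specificity (negative mass captured in low cells over total negative
// mass). The fold-best combination is the training-BA maximiser, ties going
// to the first (lexicographically smallest) combination; its labels are
// then applied to the held-out fold for the testing balanced accuracy.
//
// One pass per combination accumulates per-(fold, cell) positive/negative
// masses; training masses for fold f are totals minus fold f's own masses.
// [[Rcpp::export]]
List mdr_scan_cpp(const IntegerMatrix& geno, const NumericVector& scores,
                  const IntegerVector& fold, int k, int n_folds,
                  double threshold) {
  const int n = geno.nrow(), m = geno.ncol();
  if (k < 1 || k > 3) stop("k must be 1, 2 or 3");
  if (m < k) stop("fewer SNPs than k");
  if (scores.size() != n || fold.size() != n) stop("length mismatch");
  int ncell = 1;
  for (int i = 0; i < k; ++i) ncell *= 3;

  std::vector<double> foldPos(n_folds * ncell), foldNeg(n_folds * ncell);
  std::vector<double> totPos(ncell), totNeg(ncell);
  std::vector<double> sumPosF(n_folds), sumNegF(n_folds);
  std::vector<int> cells(n);
  double sumPosT = 0.0, sumNegT = 0.0;
  for (int i = 0; i < n; ++i) {
    const double s = scores[i];
    const int f = fold[i] - 1;
    if (f < 0 || f >= n_folds) stop("fold labels must be in 1..n_folds");
    if (s > 0) { sumPosT += s; sumPosF[f] += s; }
    else if (s < 0) { sumNegT -= s; sumNegF[f] -= s; }
  }
  if (sumPosT == 0.0 || sumNegT == 0.0)
    stop("uninformative scores: positive and negative score mass required");
  for (int f = 0; f < n_folds; ++f) {
    if (sumPosT - sumPosF[f] <= 0.0 || sumNegT - sumNegF[f] <= 0.0)
      stop("degenerate fold: training scores are one-sided");
  }

  IntegerMatrix bestCombo(n_folds, k);
  NumericVector bestTrain(n_folds, -1.0);

  const int kk = k;
  std::vector<int> idx(kk);
  // initialise first combo 0,1,...,k-1
  for (int i = 0; i < kk; ++i) idx[i] = i;
  bool more = true;
  while (more) {
    // --- evaluate combination idx ---
    const int* g0 = &geno[(R_xlen_t)idx[0] * n];
    const int* g1 = (kk >= 2) ? &geno[(R_xlen_t)idx[1] * n] : 0;
    const int* g2 = (kk >= 3) ? &geno[(R_xlen_t)idx[2] * n] : 0;
    std::fill(foldPos.begin(), foldPos.end(), 0.0);
    std::fill(foldNeg.begin(), foldNeg.end(), 0.0);
    std::fill(totPos.begin(), totPos.end(), 0.0);
    std::fill(totNeg.begin(), totNeg.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      int c = g0[i];
      if (kk >= 2) c += 3 * g1[i];
      if (kk >= 3) c += 9 * g2[i];
      if (c < 0 || c >= ncell) stop("dosage entries must be 0, 1 or 2");
      cells[i] = c;
      const double s = scores[i];
      const int f = fold[i] - 1;
      if (s > 0) { foldPos[f * ncell + c] += s; totPos[c] += s; }
      else if (s < 0) { foldNeg[f * ncell + c] -= s; totNeg[c] -= s; }
    }
    for (int f = 0; f < n_folds; ++f) {
      const double P = sumPosT - sumPosF[f];
      const double N = sumNegT - sumNegF[f];
      double hiPos = 0.0, loNeg = 0.0;
      for (int c = 0; c < ncell; ++c) {
        const double tp = totPos[c] - foldPos[f * ncell + c];
        const double tn = totNeg[c] - foldNeg[f * ncell + c];
        if (tp - tn > threshold) hiPos += tp; else loNeg += tn;
      }
      const double ba = 0.5 * (hiPos / P + loNeg / N);
      if (ba > bestTrain[f]) {
        bestTrain[f] = ba;
        for (int i = 0; i < kk; ++i) bestCombo(f, i) = idx[i] + 1;
      }
    }
    // --- advance combination ---
    int pos = kk - 1;
    while (pos >= 0 && idx[pos] == m - kk + pos) --pos;
    if (pos < 0) more = false;
    else {
      ++idx[pos];
      for (int i = pos + 1; i < kk; ++i) idx[i] = idx[i - 1] + 1;
    }
  }

  // re-derive labels and testing BA for each fold's best combination
  IntegerMatrix labels(n_folds, ncell);
  NumericVector testBA(n_folds);
  for (int f = 0; f < n_folds; ++f) {
    std::vector<double> trPos(ncell), trNeg(ncell), tePos(ncell), teNeg(ncell);
    for (int i = 0; i < n; ++i) {
      int c = geno(i, bestCombo(f, 0) - 1);
      if (kk >= 2) c += 3 * geno(i, bestCombo(f, 1) - 1);
      if (kk >= 3) c += 9 * geno(i, bestCombo(f, 2) - 1);
      const double s = scores[i];
      if (fold[i] - 1 == f) {
        if (s > 0) tePos[c] += s; else if (s < 0) teNeg[c] -= s;
      } else {
        if (s > 0) trPos[c] += s; else if (s < 0) trNeg[c] -= s;
      }
    }
    double P = 0.0, N = 0.0, hiPos = 0.0, loNeg = 0.0;
    for (int c = 0; c < ncell; ++c) { P += tePos[c]; N += teNeg[c]; }
    if (P == 0.0 || N == 0.0)
      stop("testing balanced accuracy undefined: held-out scores are one-sided");
    for (int c = 0; c < ncell; ++c) {
      const bool hi = (trPos[c] - trNeg[c]) > threshold;
      labels(f, c) = hi ? 1 : 0;
      if (hi) hiPos += tePos[c]; else loNeg += teNeg[c];
    }
    testBA[f] = 0.5 * (hiPos / P + loNeg / N);
  }

  return List::create(_["best_combo"] = bestCombo,
                      _["train_ba"] = bestTrain,
                      _["test_ba"] = testBA,
                      _["labels"] = labels);
}
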