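#include <Rcpp.h>
using namespace Rcpp;

// Fold one experiment's modeled-activation histogram into the running ALE
// histogram: ale_new = 1 - (1 - ale)(1 - ma), with mass products
// accumulated into bins of width bw. Each bin carries its probability
// mass and the mass-weighted mean of the exact values that landed in it;
// folding from those representative values keeps combination values
// unbiased instead of drifting toward bin left edges. Hot loop of the
// analytic ALE null.
// [[Rcpp::export(name = ".fold_null_cpp")]]
List fold_null_cpp(NumericVector pa, NumericVector pav,
                   NumericVector mvals, NumericVector mprobs,
                   double bw, int kmax) {
  NumericVector acc(kmax + 1);
  NumericVector accv(kmax + 1);
  int K = pa.size();
  std::vector<double> wa, va;
  wa.reserve(K); va.reserve(K);
  for (int i = 0; i < K; ++i) {
    if (pa[i] > 0) {
      wa.push_back(pa[i]);
      va.push_back(pav[i]);
    }
  }
  int na = (int)wa.size();
  int nm = mvals.size();
  for (int j = 0; j < nm; ++j) {
    double pm = mprobs[j];
    double mv = mvals[j];
    for (int i = 0; i < na; ++i) {
      double nv = va[i] + mv - va[i] * mv;
      int tb = (int)std::floor(nv / bw);
      if (tb > kmax) tb = kmax;
      double w = wa[i] * pm;
      acc[tb] += w;
      accv[tb] += w * nv;
    }
  }
  for (int b = 0; b <= kmax; ++b)
    if (acc[b] > 0) accv[b] /= acc[b];
  return List::create(_["probs"] = acc, _["values"] = accv);
}
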