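#include <Rcpp.h>
using namespace Rcpp;

// Self-consistent WHAM iteration on precomputed histograms, energies in kT.
//   P_j      = (sum_i n_ij) / (sum_i N_i exp(f_i - c_ij))
//   exp(-f_i) = sum_j P_j exp(-c_ij)
// with c_ij the bias energy of window i at bin center j. f is gauged to
// f_1 = 0 each sweep and P renormalised (pure gauge; keeps exp(f) bounded).
// Stops when max_i |delta f_i| <= tol. exp(-c_ij) is precomputed; entries
// that underflow to zero are bins the window cannot reach and contribute
// nothing, which is the correct limit.
// [[Rcpp::export(name = ".wham_cpp")]]
List wham_cpp(NumericMatrix counts, NumericMatrix bias, NumericVector N,
              double tol, int max_iter) {
  int nw = counts.nrow(), nb = counts.ncol();
  NumericVector Cj(nb);
  for (int j = 0; j < nb; ++j) {
    double s = 0.0;
    for (int i = 0; i < nw; ++i) s += counts(i, j);
    Cj[j] = s;
  }
  NumericMatrix emc(nw, nb); // exp(-c_ij)
  for (int i = 0; i < nw; ++i)
    for (int j = 0; j < nb; ++j) emc(i, j) = std::exp(-bias(i, j));

  NumericVector f(nw, 0.0), fnew(nw), P(nb), ef(nw);
  std::vector<double> resid_trace;
  resid_trace.reserve(256);
  double resid = R_PosInf;
  int iter = 0;
  while (iter < max_iter) {
    ++iter;
    for (int i = 0; i < nw; ++i) ef[i] = std::exp(f[i]);
    double Psum = 0.0;
    for (int j = 0; j < nb; ++j) {
      double denom = 0.0;
      for (int i = 0; i < nw; ++i) denom += N[i] * ef[i] * emc(i, j);
      P[j] = (denom > 0.0) ? Cj[j] / denom : 0.0;
      Psum += P[j];
    }
    for (int j = 0; j < nb; ++j) P[j] /= Psum;
    for (int i = 0; i < nw; ++i) {
      double Z = 0.0;
      for (int j = 0; j < nb; ++j) Z += P[j] * emc(i, j);
      fnew[i] = -std::log(Z);
    }
    double f0 = fnew[0];
    resid = 0.0;
    for (int i = 0; i < nw; ++i) {
      fnew[i] -= f0;
      double d = std::fabs(fnew[i] - f[i]);
      if (d > resid) resid = d;
      f[i] = fnew[i];
    }
    resid_trace.push_back(resid);
    if (resid <= tol) break;
  }
  NumericVector W(nb);
  for (int j = 0; j < nb; ++j)
    W[j] = (P[j] > 0.0) ? -std::log(P[j]) : R_PosInf;
  return List::create(_["f"] = f, _["W"] = W, _["P"] = P,
                      _["iterations"] = iter, _["residual"] = resid,
                      _["converged"] = (resid <= tol),
                      _["residual_trace"] = NumericVector(resid_trace.begin(),
                                                          resid_trace.end()));
}
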