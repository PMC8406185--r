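#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for the two-state (Unimported/Imported)
// per-branch recombination HMM over a binary mismatch track.
//
// obs:    0/1 mismatch indicators (missing sites already removed; the
//         transition then bridges the gap between flanking retained sites)
// e_u:    P(mismatch | Unimported) = 1 - exp(-b)
// e_i:    P(mismatch | Imported)   = nu
// t_ui:   P(U -> I) = 1 - exp(-(R/theta) * b)
// t_iu:   P(I -> U) = 1 / delta
//
// The initial distribution is fixed at (1/2, 1/2) so the EM objective
// decomposes over the remaining parameters exactly.
//
// Returns the log-likelihood, the expected transition counts, expected
// state occupancies and expected mismatch counts per state, and (optionally)
// the posterior P(Imported) per site.
// [[Rcpp::export(name = ".hmm_fb")]]
List hmm_fb(IntegerVector obs, double e_u, double e_i,
            double t_ui, double t_iu, bool want_posterior) {
  const int n = obs.size();
  if (n == 0) {
    return List::create(_["loglik"] = 0.0,
                        _["A"] = NumericVector::create(0, 0, 0, 0),
                        _["occ"] = NumericVector::create(0, 0),
                        _["mm"] = NumericVector::create(0, 0),
                        _["posterior"] = NumericVector(0));
  }
  const double a[2][2] = {{1.0 - t_ui, t_ui}, {t_iu, 1.0 - t_iu}};
  const double e[2][2] = {{1.0 - e_u, e_u}, {1.0 - e_i, e_i}};

  NumericVector fwdU(n), fwdI(n), scale(n);
  double loglik = 0.0;

  double fU = 0.5 * e[0][obs[0]];
  double fI = 0.5 * e[1][obs[0]];
  double s = fU + fI;
  fwdU[0] = fU / s; fwdI[0] = fI / s; scale[0] = s;
  loglik += std::log(s);
  for (int t = 1; t < n; ++t) {
    const int o = obs[t];
    fU = (fwdU[t - 1] * a[0][0] + fwdI[t - 1] * a[1][0]) * e[0][o];
    fI = (fwdU[t - 1] * a[0][1] + fwdI[t - 1] * a[1][1]) * e[1][o];
    s = fU + fI;
    fwdU[t] = fU / s; fwdI[t] = fI / s; scale[t] = s;
    loglik += std::log(s);
  }

  // backward pass with on-the-fly accumulation of expected counts
  double A_uu = 0, A_ui = 0, A_iu = 0, A_ii = 0;
  double occU = 0, occI = 0, mmU = 0, mmI = 0;
  NumericVector post;
  if (want_posterior) post = NumericVector(n);

  double bU = 1.0, bI = 1.0;
  {
    double gU = fwdU[n - 1] * bU, gI = fwdI[n - 1] * bI;
    double gs = gU + gI;
    gU /= gs; gI /= gs;
    occU += gU; occI += gI;
    if (obs[n - 1] == 1) { mmU += gU; mmI += gI; }
    if (want_posterior) post[n - 1] = gI;
  }
  for (int t = n - 2; t >= 0; --t) {
    const int o = obs[t + 1];
    const double eu = e[0][o], ei = e[1][o];
    // xi_{t}(p,q) proportional to fwd[t][p] * a[p][q] * e[q][o_{t+1}] * bwd[t+1][q]
    const double xuu = fwdU[t] * a[0][0] * eu * bU;
    const double xui = fwdU[t] * a[0][1] * ei * bI;
    const double xiu = fwdI[t] * a[1][0] * eu * bU;
    const double xii = fwdI[t] * a[1][1] * ei * bI;
    const double xs = xuu + xui + xiu + xii;
    A_uu += xuu / xs; A_ui += xui / xs; A_iu += xiu / xs; A_ii += xii / xs;

    double nbU = (a[0][0] * eu * bU + a[0][1] * ei * bI) / scale[t + 1];
    double nbI = (a[1][0] * eu * bU + a[1][1] * ei * bI) / scale[t + 1];
    bU = nbU; bI = nbI;

    double gU = fwdU[t] * bU, gI = fwdI[t] * bI;
    double gs = gU + gI;
    gU /= gs; gI /= gs;
    occU += gU; occI += gI;
    if (obs[t] == 1) { mmU += gU; mmI += gI; }
    if (want_posterior) post[t] = gI;
  }

  return List::create(
    _["loglik"] = loglik,
    _["A"] = NumericVector::create(A_uu, A_ui, A_iu, A_ii),
    _["occ"] = NumericVector::create(occU, occI),
    _["mm"] = NumericVector::create(mmU, mmI),
    _["posterior"] = post);
}

// Viterbi decoding of the same two-state model; returns the MAP state
// sequence (0 = Unimported, 1 = Imported).
// [[Rcpp::export(name = ".hmm_viterbi")]]
IntegerVector hmm_viterbi(IntegerVector obs, double e_u, double e_i,
                          double t_ui, double t_iu) {
  const int n = obs.size();
  IntegerVector path(n);
  if (n == 0) return path;
  const double la[2][2] = {{std::log(1.0 - t_ui), std::log(t_ui)},
                           {std::log(t_iu), std::log(1.0 - t_iu)}};
  const double le[2][2] = {{std::log(1.0 - e_u), std::log(e_u)},
                           {std::log(1.0 - e_i), std::log(e_i)}};
  std::vector<unsigned char> bpU(n), bpI(n);
  double vU = std::log(0.5) + le[0][obs[0]];
  double vI = std::log(0.5) + le[1][obs[0]];
  for (int t = 1; t < n; ++t) {
    const int o = obs[t];
    const double uu = vU + la[0][0], iu = vI + la[1][0];
    const double ui = vU + la[0][1], ii = vI + la[1][1];
    const double nU = std::max(uu, iu) + le[0][o];
    const double nI = std::max(ui, ii) + le[1][o];
    bpU[t] = iu > uu; bpI[t] = ii > ui;
    vU = nU; vI = nI;
  }
  int st = vI > vU;
  path[n - 1] = st;
  for (int t = n - 1; t > 0; --t) {
    st = st ? bpI[t] : bpU[t];
    path[t - 1] = st;
  }
  return path;
}
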