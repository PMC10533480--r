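#include <Rcpp.h>
using namespace Rcpp;

// Forward-algorithm log-likelihood for the multivariate-state CJS model.
//
// The hidden chain runs over 9 states (4 reproductive states x 2 location
// strata + Dead).  Each animal is conditioned on its release: the filter is
// initialised as a point mass on state `init` at occasion `release[a]` with
// no emission term there, then propagated through per-interval transition
// matrices and per-occasion emission columns selected by index maps.
//
// E: 9 x 4 x nE array (column-major; one 9x4 emission matrix per stratum,
// stored contiguously).  T: 9 x 9 x nT array, one transition matrix per
// stratum.  obs: n x T integer codes 0..3 (entries at or before release are
// ignored).  eidx / tidx: 1-based stratum ids per animal-occasion /
// animal-interval.
//
// Returns per-animal log-likelihood contributions; -Inf marks an observation
// sequence with probability zero under the supplied parameters.
// [[Rcpp::export]]
NumericVector forward_loglik(NumericVector E, int nE,
                             NumericVector T, int nT,
                             IntegerMatrix obs,
                             IntegerMatrix eidx,
                             IntegerMatrix tidx,
                             IntegerVector release,
                             int init) {
  const int S = 9;
  const int n = obs.nrow();
  const int Tocc = obs.ncol();
  NumericVector ll(n);
  std::vector<double> alpha(S), anew(S);
  const double *Ep = &E[0];
  const double *Tp = &T[0];

  for (int a = 0; a < n; ++a) {
    int rel = release[a] - 1;
    std::fill(alpha.begin(), alpha.end(), 0.0);
    alpha[init - 1] = 1.0;
    double logl = 0.0;
    bool dead_end = false;

    for (int t = rel + 1; t < Tocc; ++t) {
      const double *Tm = Tp + (std::size_t)81 * (tidx(a, t - 1) - 1);
      for (int j = 0; j < S; ++j) {
        double s = 0.0;
        const double *col = Tm + S * j;
        for (int i = 0; i < S; ++i) s += alpha[i] * col[i];
        anew[j] = s;
      }
      const double *Em = Ep + (std::size_t)36 * (eidx(a, t) - 1) +
        S * obs(a, t);
      double tot = 0.0;
      for (int j = 0; j < S; ++j) {
        anew[j] *= Em[j];
        tot += anew[j];
      }
      if (tot <= 0.0) { dead_end = true; break; }
      for (int j = 0; j < S; ++j) alpha[j] = anew[j] / tot;
      logl += std::log(tot);
    }
    ll[a] = dead_end ? R_NegInf : logl;
  }
  return ll;
}

// Forward pass plus reverse-mode (adjoint) accumulation of the gradient of
// the total log-likelihood with respect to every emission and transition
// matrix entry.  Writing b_t = (alpha_{t-1} T_t) o e_t, c_t = sum(b_t),
// alpha_t = b_t / c_t and logL = sum_t log c_t, the adjoint recursion for
// g_t = dlogL/dalpha_t is
//   h_t[j]   = (1 + g_t[j] - g_t . alpha_t) / c_t          (= dlogL/db_t[j])
//   dE[j]   += h_t[j] * u_t[j],  u_t = alpha_{t-1} T_t
//   dT[i,j] += alpha_{t-1}[i] * h_t[j] * e_t[j]
//   g_{t-1}[i] = sum_j T_t[i,j] * h_t[j] * e_t[j].
// Returns the per-animal log-likelihoods plus dlogL/dE and dlogL/dT summed
// over animals (same layouts as the inputs).
// [[Rcpp::export]]
List forward_backward(NumericVector E, int nE,
                      NumericVector T, int nT,
                      IntegerMatrix obs,
                      IntegerMatrix eidx,
                      IntegerMatrix tidx,
                      IntegerVector release,
                      int init) {
  const int S = 9;
  const int n = obs.nrow();
  const int Tocc = obs.ncol();
  NumericVector ll(n);
  NumericVector Ebar((std::size_t)36 * nE);
  NumericVector Tbar((std::size_t)81 * nT);
  const double *Ep = &E[0];
  const double *Tp = &T[0];
  double *Ebp = &Ebar[0];
  double *Tbp = &Tbar[0];
  std::vector<double> A((std::size_t)S * Tocc);   // alpha_t per occasion
  std::vector<double> U((std::size_t)S * Tocc);   // u_t (pre-emission)
  std::vector<double> C(Tocc);                    // scaling sums
  std::vector<double> g(S), h(S), gprev(S);

  for (int a = 0; a < n; ++a) {
    int rel = release[a] - 1;
    double *A0 = &A[(std::size_t)S * rel];
    std::fill(A0, A0 + S, 0.0);
    A0[init - 1] = 1.0;
    double logl = 0.0;
    bool dead_end = false;

    for (int t = rel + 1; t < Tocc; ++t) {
      const double *Tm = Tp + (std::size_t)81 * (tidx(a, t - 1) - 1);
      const double *ap = &A[(std::size_t)S * (t - 1)];
      double *up = &U[(std::size_t)S * t];
      double *vp = &A[(std::size_t)S * t];
      for (int j = 0; j < S; ++j) {
        double s = 0.0;
        const double *col = Tm + S * j;
        for (int i = 0; i < S; ++i) s += ap[i] * col[i];
        up[j] = s;
      }
      const double *Em = Ep + (std::size_t)36 * (eidx(a, t) - 1) +
        S * obs(a, t);
      double tot = 0.0;
      for (int j = 0; j < S; ++j) {
        vp[j] = up[j] * Em[j];
        tot += vp[j];
      }
      if (tot <= 0.0) { dead_end = true; break; }
      for (int j = 0; j < S; ++j) vp[j] /= tot;
      C[t] = tot;
      logl += std::log(tot);
    }
    if (dead_end) { ll[a] = R_NegInf; continue; }
    ll[a] = logl;

    std::fill(g.begin(), g.end(), 0.0);
    for (int t = Tocc - 1; t > rel; --t) {
      const double *vp = &A[(std::size_t)S * t];
      const double *up = &U[(std::size_t)S * t];
      const double *ap = &A[(std::size_t)S * (t - 1)];
      const double *Em = Ep + (std::size_t)36 * (eidx(a, t) - 1) +
        S * obs(a, t);
      double *Eb = Ebp + (std::size_t)36 * (eidx(a, t) - 1) + S * obs(a, t);
      const double *Tm = Tp + (std::size_t)81 * (tidx(a, t - 1) - 1);
      double *Tb = Tbp + (std::size_t)81 * (tidx(a, t - 1) - 1);
      double gv = 0.0;
      for (int j = 0; j < S; ++j) gv += g[j] * vp[j];
      for (int j = 0; j < S; ++j) {
        h[j] = (1.0 + g[j] - gv) / C[t];
        Eb[j] += h[j] * up[j];
        h[j] *= Em[j];                    // now h = dlogL/du_t
      }
      for (int j = 0; j < S; ++j) {
        double *Tbc = Tb + S * j;
        const double *Tc = Tm + S * j;
        const double hj = h[j];
        for (int i = 0; i < S; ++i) Tbc[i] += ap[i] * hj;
        (void)Tc;
      }
      for (int i = 0; i < S; ++i) {
        double s = 0.0;
        for (int j = 0; j < S; ++j) s += Tm[S * j + i] * h[j];
        gprev[i] = s;
      }
      g = gprev;
    }
  }
  return List::create(Named("loglik") = ll, Named("Ebar") = Ebar,
                      Named("Tbar") = Tbar);
}

// Simulate one hidden-state / observation pair per animal given the same
// matrix stacks (used by the population simulator; kept in C++ so large
// scenarios stay cheap).  Uniform draws are supplied from R so that all
// randomness flows through R's RNG and is seed-reproducible.
// [[Rcpp::export]]
IntegerVector sample_categorical(NumericMatrix prob, NumericVector u) {
  const int n = prob.nrow();
  const int k = prob.ncol();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    int pick = k;
    for (int j = 0; j < k; ++j) {
      acc += prob(i, j);
      if (u[i] <= acc) { pick = j + 1; break; }
    }
    out[i] = pick > k ? k : pick;
  }
  return out;
}
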