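#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Adaptive tau-leaping for mass-action-style reaction systems with
// integer-valued species counts.
//
// Propensities are c_j * prod_i x_i^e_ij with small integer exponents
// (the logistic crowding term uses e = 2, i.e. a rate proportional to
// T^2, matching the deterministic a*b*T^2 decomposition).
//
// Leap control follows the species-based bound of Cao, Gillespie &
// Petzold (2006): the leap tau limits the expected relative change of
// every species to eps (with an absolute floor of one unit), using
// g_i = 2 uniformly (bimolecular worst case). When the resulting tau is
// smaller than ssa_factor expected reaction times, a burst of exact SSA
// steps is taken instead. Leaps that would drive any species negative
// are rejected and retried with tau halved.
//
// All randomness comes from the R RNG (RNGScope via Rcpp attributes),
// so set.seed() on the R side makes runs bit-reproducible.

static inline double propensity(const NumericVector& x,
                                const NumericVector& coef,
                                const IntegerMatrix& expo,
                                int j) {
  double a = coef[j];
  for (int i = 0; i < expo.ncol(); ++i) {
    int e = expo(j, i);
    if (e == 1) a *= x[i];
    else if (e == 2) a *= x[i] * x[i];
    else if (e > 2) a *= std::pow(x[i], e);
  }
  return a;
}

// [[Rcpp::export(name = ".tauleap_run")]]
List tauleap_run(NumericVector init,
                 IntegerMatrix change,   // n_react x n_spec
                 NumericVector coef0,    // coefficient per reaction
                 IntegerMatrix expo,     // n_react x n_spec
                 NumericVector record_times, // increasing, first = t0
                 NumericVector ev_times, // sorted, may repeat
                 IntegerVector ev_type,  // 0 = set coefficient, 1 = bolus
                 IntegerVector ev_index, // reaction (type 0) / species (1)
                 NumericVector ev_value, // new coefficient / bolus size
                 double eps,
                 double ssa_factor,
                 int ssa_burst) {
  const int nr = change.nrow(), ns = change.ncol();
  const int nrec = record_times.size(), nev = ev_times.size();
  NumericVector x = clone(init);
  NumericVector coef = clone(coef0);
  NumericMatrix out(nrec, ns);
  NumericVector a(nr), mu(ns), var(ns), xtry(ns);

  double t = record_times[0];
  for (int i = 0; i < ns; ++i) out(0, i) = x[i];
  int irec = 1, iev = 0;
  const double lambda_cap = 5e8; // keep Poisson means inside rpois range

  while (irec < nrec || iev < nev) {
    // next stop: earliest of next record or next event time
    double t_stop = R_PosInf;
    bool stop_is_rec = false;
    if (irec < nrec) { t_stop = record_times[irec]; stop_is_rec = true; }
    if (iev < nev && ev_times[iev] < t_stop - 1e-12) {
      t_stop = ev_times[iev];
      stop_is_rec = false;
    } else if (iev < nev && std::abs(ev_times[iev] - t_stop) <= 1e-12) {
      // coincident event and record: record first, then apply event
      stop_is_rec = true;
    }

    // advance from t to t_stop
    while (t < t_stop - 1e-12) {
      double a0 = 0.0;
      for (int j = 0; j < nr; ++j) {
        a[j] = propensity(x, coef, expo, j);
        if (!R_finite(a[j]) || a[j] < 0 || a[j] > 1e25)
          stop("propensity overflow or invalid propensity");
        a0 += a[j];
      }
      if (a0 <= 0.0) { t = t_stop; break; } // frozen state

      // species-level drift and noise
      for (int i = 0; i < ns; ++i) { mu[i] = 0.0; var[i] = 0.0; }
      for (int j = 0; j < nr; ++j) {
        for (int i = 0; i < ns; ++i) {
          int v = change(j, i);
          if (v != 0) { mu[i] += v * a[j]; var[i] += (double)v * v * a[j]; }
        }
      }
      double tau = R_PosInf;
      for (int i = 0; i < ns; ++i) {
        double bound = std::max(eps * x[i] / 2.0, 1.0);
        if (std::abs(mu[i]) > 0)
          tau = std::min(tau, bound / std::abs(mu[i]));
        if (var[i] > 0)
          tau = std::min(tau, bound * bound / var[i]);
      }
      double amax = 0.0;
      for (int j = 0; j < nr; ++j) amax = std::max(amax, a[j]);
      if (amax > 0) tau = std::min(tau, lambda_cap / amax);

      if (tau < ssa_factor / a0) {
        // exact SSA burst
        for (int s = 0; s < ssa_burst; ++s) {
          double dt = R::exp_rand() / a0;
          if (t + dt > t_stop) { t = t_stop; break; }
          t += dt;
          double u = R::unif_rand() * a0, acc = 0.0;
          int jfire = nr - 1;
          for (int j = 0; j < nr; ++j) {
            acc += a[j];
            if (u <= acc) { jfire = j; break; }
          }
          for (int i = 0; i < ns; ++i) x[i] += change(jfire, i);
          // propensities change after each firing
          a0 = 0.0;
          for (int j = 0; j < nr; ++j) {
            a[j] = propensity(x, coef, expo, j);
            a0 += a[j];
          }
          if (a0 <= 0.0) { t = t_stop; break; }
        }
        continue;
      }

      tau = std::min(tau, t_stop - t);
      // Poisson leap with rejection on negative counts
      bool ok = false;
      for (int attempt = 0; attempt < 60 && !ok; ++attempt) {
        ok = true;
        for (int i = 0; i < ns; ++i) xtry[i] = x[i];
        for (int j = 0; j < nr; ++j) {
          double lam = a[j] * tau;
          double nj = (lam > 0) ? R::rpois(lam) : 0.0;
          if (nj > 0)
            for (int i = 0; i < ns; ++i) xtry[i] += change(j, i) * nj;
        }
        for (int i = 0; i < ns; ++i)
          if (xtry[i] < 0) { ok = false; break; }
        if (!ok) tau *= 0.5;
      }
      if (!ok) stop("tau-leap failed to find a nonnegative step");
      for (int i = 0; i < ns; ++i) x[i] = xtry[i];
      t += tau;
    }

    if (stop_is_rec) {
      for (int i = 0; i < ns; ++i) out(irec, i) = x[i];
      ++irec;
    }
    // apply every event scheduled at this stop
    while (iev < nev && ev_times[iev] <= t + 1e-12) {
      if (ev_type[iev] == 0) {
        coef[ev_index[iev]] = ev_value[iev];
      } else {
        x[ev_index[iev]] += ev_value[iev];
      }
      ++iev;
    }
  }
  return List::create(_["times"] = record_times, _["states"] = out);
}
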