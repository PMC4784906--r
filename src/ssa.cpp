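#include <Rcpp.h>
using namespace Rcpp;

// Direct-method Gillespie for the N-site autorepressive circuit.
// Reactions (2N+2): for s=1..N binding (occ s-1 -> s, consumes one repressor)
// and unbinding (occ s -> s-1, releases one); synthesis (occ==0 only); degradation.
// kon[s-1] is the per-molecule binding rate constant for the s-1 -> s step,
// koff[s-1] the unbinding rate for s -> s-1. a_counts in molecules/min.

// [[Rcpp::export]]
List ssa_events_cpp(NumericVector kon, NumericVector koff,
                    double a_counts, double g, int occ0, int n0,
                    double t_end, double burn_in, int max_events) {
  int N = kon.size();
  std::vector<double> times; std::vector<int> occs, ns, rxn;
  times.reserve(4096); occs.reserve(4096); ns.reserve(4096); rxn.reserve(4096);
  int occ = occ0; long n = n0; double t = 0.0;
  int ev = 0;
  while (t < t_end && ev < max_events) {
    double ab = (occ < N) ? kon[occ] * n : 0.0;
    double au = (occ > 0) ? koff[occ - 1] : 0.0;
    double as = (occ == 0) ? a_counts : 0.0;
    double ad = g * n;
    double atot = ab + au + as + ad;
    if (atot <= 0.0) break;
    t += R::exp_rand() / atot;
    if (t >= t_end) break;
    double u = unif_rand() * atot;
    int r;
    if (u < ab) { occ += 1; n -= 1; r = 2 * occ - 1; }           // binding to state occ
    else if (u < ab + au) { occ -= 1; n += 1; r = 2 * (occ + 1); } // unbinding from occ+1
    else if (u < ab + au + as) { n += 1; r = 2 * N + 1; }
    else { n -= 1; r = 2 * N + 2; }
    ++ev;
    if (t >= burn_in) {
      times.push_back(t); occs.push_back(occ); ns.push_back((int)n); rxn.push_back(r);
    }
  }
  return List::create(_["time"] = times, _["occupancy"] = occs,
                      _["n"] = ns, _["reaction"] = rxn,
                      _["final_time"] = t, _["final_occ"] = occ, _["final_n"] = (int)n);
}

// Zero-order-hold sampling of repressor counts on a uniform grid, batched over
// realizations; avoids storing event-resolved paths when only spectra are needed.
// Returns an n_grid x n_real matrix.
// [[Rcpp::export]]
NumericMatrix ssa_grid_cpp(NumericVector kon, NumericVector koff,
                           double a_counts, double g, int occ0, int n0,
                           double dt, int n_grid, double burn_in, int n_real) {
  int N = kon.size();
  NumericMatrix out(n_grid, n_real);
  for (int r = 0; r < n_real; ++r) {
    int occ = occ0; long n = n0; double t = 0.0;
    double t_end = burn_in + dt * n_grid;
    int gi = 0;
    while (gi < n_grid) {
      double ab = (occ < N) ? kon[occ] * n : 0.0;
      double au = (occ > 0) ? koff[occ - 1] : 0.0;
      double as = (occ == 0) ? a_counts : 0.0;
      double ad = g * n;
      double atot = ab + au + as + ad;
      double tnew = (atot > 0.0) ? t + R::exp_rand() / atot : t_end;
      while (gi < n_grid && burn_in + gi * dt < tnew) { out(gi, r) = n; ++gi; }
      if (tnew >= t_end) break;
      t = tnew;
      if (atot <= 0.0) break;
      double u = unif_rand() * atot;
      if (u < ab) { occ += 1; n -= 1; }
      else if (u < ab + au) { occ -= 1; n += 1; }
      else if (u < ab + au + as) { n += 1; }
      else { n -= 1; }
    }
  }
  return out;
}

// Frozen-repressor ladder: binding/unbinding only at fixed repressor count,
// sampling promoter occupancy on a uniform grid (for QSS validation).
// [[Rcpp::export]]
IntegerVector ssa_frozen_cpp(NumericVector kon, NumericVector koff,
                             int n_frozen, int occ0, double dt, int n_grid,
                             double burn_in) {
  int N = kon.size();
  IntegerVector out(n_grid);
  int occ = occ0; double t = 0.0; int gi = 0;
  double t_end = burn_in + dt * n_grid;
  while (gi < n_grid) {
    double ab = (occ < N) ? kon[occ] * n_frozen : 0.0;
    double au = (occ > 0) ? koff[occ - 1] : 0.0;
    double atot = ab + au;
    double tnew = (atot > 0.0) ? t + R::exp_rand() / atot : t_end;
    while (gi < n_grid && burn_in + gi * dt < tnew) { out[gi] = occ; ++gi; }
    if (tnew >= t_end) break;
    t = tnew;
    double u = unif_rand() * atot;
    if (u < ab) occ += 1; else occ -= 1;
  }
  return out;
}
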