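#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Exact stochastic simulation of one clone on its own periodic 1D lattice.
//
// State: a set of GFRa1+ syncytial units (length k >= 1, one per lattice
// site) plus an off-lattice count m of GFRa1- cells. Event channels:
//   - incomplete division: per unit, rate lambda; k -> 2k in place
//   - fragmentation: per unit, rate (k-1)*eta; each of the k-1 bridges
//     breaks independently with prob 1/2; one random fragment keeps the
//     origin site, the others are displaced uniformly among the 2r sites
//     within +/- r of the origin (origin excluded, random placement order);
//     a displaced fragment landing on an occupied site differentiates the
//     occupant (its k nuclei join m)
//   - death: per unit, rate gamma, active only while t < t0
//   - progenitor birth: total rate mu*m (stochastic mode only)
//
// The death switch-off at t0 is handled exactly for piecewise-constant
// rates: a sampled waiting time that would cross t0 is discarded, the clock
// advances to t0, and a fresh time is drawn from the post-t0 propensities.
//
// In deterministic-m mode the GFRa1- pool carries its expectation,
// m(t + dt) = m(t) * exp(mu * dt), with jumps of +k at differentiation
// events; it contributes no event propensity.
//
// Uses R's RNG (unif_rand / exp_rand), so set.seed() on the R side gives
// full reproducibility.

// [[Rcpp::export(name = ".simulate_clone_cpp")]]
List simulate_clone_cpp(IntegerVector init_lengths,
                        IntegerVector init_sites,
                        double init_m,
                        double lambda, double eta, double gamma, double t0,
                        double mu, int r_range, int lattice_sites,
                        double t_start,
                        NumericVector record_times,
                        bool stochastic_m) {
  std::vector<int> len(init_lengths.begin(), init_lengths.end());
  std::vector<int> site(init_sites.begin(), init_sites.end());
  std::unordered_map<int, int> occ;  // lattice site -> index into len/site
  long long sum_bridges = 0;
  for (size_t i = 0; i < len.size(); ++i) {
    if (len[i] < 1) stop("unit length must be >= 1");
    if (occ.count(site[i])) stop("two units share a lattice site");
    occ[site[i]] = (int)i;
    sum_bridges += len[i] - 1;
  }
  double m = init_m;
  double t = t_start;

  const int nrec = record_times.size();
  List out_lengths(nrec);
  NumericVector out_m(nrec);
  IntegerVector out_n(nrec);
  int ri = 0;

  auto remove_unit = [&](int idx) {
    sum_bridges -= len[idx] - 1;
    occ.erase(site[idx]);
    int last = (int)len.size() - 1;
    if (idx != last) {
      len[idx] = len[last];
      site[idx] = site[last];
      occ[site[idx]] = idx;
    }
    len.pop_back();
    site.pop_back();
  };

  auto snapshot = [&](double tr) {
    out_m[ri] = stochastic_m ? m : m * std::exp(mu * (tr - t));
    IntegerVector lv(len.begin(), len.end());
    out_lengths[ri] = lv;
    long long n = 0;
    for (int k : len) n += k;
    out_n[ri] = (int)n;
    ++ri;
  };

  while (ri < nrec) {
    const bool death_on = (t < t0);
    const int U = (int)len.size();
    const double a_div = lambda * U;
    const double a_frag = eta * (double)sum_bridges;
    const double a_death = death_on ? gamma * U : 0.0;
    const double a_m = stochastic_m ? mu * m : 0.0;
    const double total = a_div + a_frag + a_death + a_m;

    if (total <= 0.0) {
      // absorbing (no event channel active); m may still grow deterministically
      while (ri < nrec) snapshot(record_times[ri]);
      break;
    }

    const double dt = exp_rand() / total;
    const double t_ev = t + dt;

    if (death_on && t_ev > t0) {
      // waiting time crosses the loss-phase boundary: advance to t0 without
      // an event and redraw with the death channel off
      while (ri < nrec && record_times[ri] <= t0) snapshot(record_times[ri]);
      if (!stochastic_m) m *= std::exp(mu * (t0 - t));
      t = t0;
      continue;
    }

    while (ri < nrec && record_times[ri] < t_ev) snapshot(record_times[ri]);
    if (ri >= nrec) break;

    if (!stochastic_m) m *= std::exp(mu * dt);
    t = t_ev;

    double u = unif_rand() * total;
    if (u < a_div) {
      int i = (int)(unif_rand() * U);
      if (i >= U) i = U - 1;
      sum_bridges += len[i];  // (2k-1) - (k-1) = k
      len[i] *= 2;
    } else if (u < a_div + a_frag) {
      // pick unit proportional to (k - 1)
      double target = unif_rand() * (double)sum_bridges;
      int i = U - 1;
      double acc = 0.0;
      for (int j = 0; j < U; ++j) {
        acc += len[j] - 1;
        if (target < acc) { i = j; break; }
      }
      const int k = len[i];
      const int origin = site[i];
      // each bridge breaks independently with probability 1/2
      std::vector<int> frags;
      int run = 1;
      for (int b = 0; b < k - 1; ++b) {
        if (unif_rand() < 0.5) { frags.push_back(run); run = 1; }
        else ++run;
      }
      frags.push_back(run);
      const int nf = (int)frags.size();
      if (nf > 1) {  // a zero-break draw is a real no-op event
        int stay = (int)(unif_rand() * nf);
        if (stay >= nf) stay = nf - 1;
        sum_bridges -= (k - 1);
        len[i] = frags[stay];
        sum_bridges += frags[stay] - 1;
        std::vector<int> disp;
        disp.reserve(nf - 1);
        for (int f = 0; f < nf; ++f) if (f != stay) disp.push_back(frags[f]);
        // random placement order (Fisher-Yates)
        for (int a = (int)disp.size() - 1; a > 0; --a) {
          int b = (int)(unif_rand() * (a + 1));
          if (b > a) b = a;
          std::swap(disp[a], disp[b]);
        }
        for (int fk : disp) {
          int j = (int)(unif_rand() * (2 * r_range));
          if (j >= 2 * r_range) j = 2 * r_range - 1;
          const int off = (j < r_range) ? (j + 1) : -(j - r_range + 1);
          int s = (origin + off) % lattice_sites;
          if (s < 0) s += lattice_sites;
          std::unordered_map<int, int>::iterator it = occ.find(s);
          if (it != occ.end()) {
            // former occupant differentiates: nuclei join the GFRa1- pool
            m += (double)len[it->second];
            remove_unit(it->second);
          }
          len.push_back(fk);
          site.push_back(s);
          occ[s] = (int)len.size() - 1;
          sum_bridges += fk - 1;
        }
      }
    } else if (u < a_div + a_frag + a_death) {
      int i = (int)(unif_rand() * U);
      if (i >= U) i = U - 1;
      remove_unit(i);
    } else {
      m += 1.0;
    }
  }

  return List::create(_["lengths"] = out_lengths,
                      _["m"] = out_m,
                      _["n_total"] = out_n);
}
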