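#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation of an actin filament propelled by myosins on a
// line of binding sites. Motors cycle detached -> pre-stroke -> post-stroke ->
// detached. Mechanical steps (the main power stroke, distance d_main, and the
// secondary pre-detachment step, distance d_second) shift the stepping motor's
// anchor forward; the rigid filament re-equilibrates instantly to the mean of
// the bound anchors (equal-stiffness linear crossbridges). Mechanical rates
// carry a Boltzmann factor exp(-c * dE / kT) where dE is the elastic-energy
// change of the whole motor-filament system if the step executes.
//
// With n bound motors at equilibrium (z = mean anchor, strains x_i = z - a_i,
// sum x_i = 0), shifting anchor j forward by d gives in closed form
//   dE = (kappa/2) * d^2 * (1 - 1/n) - kappa * d * x_j
// (re-derived by brute-force energy bookkeeping in the R test suite).
//
// Internal units: nm, s, pN. Positions are returned in nm.

static inline double mech_rate(double k0, double coupling, double kappa,
                               double d, double strain, double inv_n,
                               double kT) {
  double dE = 0.5 * kappa * d * d * (1.0 - inv_n) - kappa * d * strain;
  return k0 * std::exp(-coupling * dE / kT);
}

// [[Rcpp::export]]
List gillespie_core(int n_sites, double k_attach, double k_stroke,
                    double k_detach, double coupling, double d_main,
                    double d_second, double kappa, double kT,
                    double total_time, double dt, double bind_sigma = 0.0,
                    bool log_events = false) {
  if (n_sites < 1) stop("n_sites must be >= 1");
  if (total_time <= 0) stop("total_time must be > 0");
  const int n_grid = (int)std::floor(total_time / dt + 1e-9) + 1;

  std::vector<int> state(n_sites, 0);      // 0 detached, 1 pre, 2 post
  std::vector<double> anchor(n_sites, 0.0); // nm, valid when bound
  double z = 0.0;                           // filament position, nm
  double t = 0.0;
  int n_bound = 0, n_pre = 0, n_post = 0;

  NumericVector z_grid(n_grid), t_grid(n_grid);
  IntegerVector nb_grid(n_grid);
  int next_sample = 0;

  // time-weighted occupancy over motor-count compositions (n_pre, n_post)
  NumericMatrix occupancy(n_sites + 1, n_sites + 1);

  std::vector<double> ev_time;
  std::vector<int> ev_site, ev_type; // 1 attach, 2 stroke, 3 detach

  std::vector<double> rate(n_sites);
  long long n_events = 0;

  while (t < total_time) {
    // rates for current state
    double attach_total = (double)(n_sites - n_bound) * k_attach;
    double total = attach_total;
    double inv_n = n_bound > 0 ? 1.0 / (double)n_bound : 0.0;
    for (int i = 0; i < n_sites; ++i) {
      if (state[i] == 1)
        rate[i] = mech_rate(k_stroke, coupling, kappa, d_main, z - anchor[i],
                            inv_n, kT);
      else if (state[i] == 2)
        rate[i] = mech_rate(k_detach, coupling, kappa, d_second, z - anchor[i],
                            inv_n, kT);
      else
        rate[i] = 0.0;
      total += rate[i];
    }

    double t_next;
    if (total <= 0.0) {
      t_next = total_time; // frozen: nothing can happen
    } else {
      t_next = t + R::rexp(1.0 / total);
    }

    // sample the grid over [t, min(t_next, total_time)]: z constant here
    double t_stop = std::min(t_next, total_time);
    while (next_sample < n_grid && next_sample * dt <= t_stop + 1e-12) {
      t_grid[next_sample] = next_sample * dt;
      z_grid[next_sample] = z;
      nb_grid[next_sample] = n_bound;
      ++next_sample;
    }
    occupancy(n_pre, n_post) += t_stop - t;
    t = t_next;
    if (t >= total_time || total <= 0.0) break;

    // choose event
    double u = R::runif(0.0, total);
    int site = -1, type = 0;
    if (u < attach_total) {
      // attach at the (k+1)-th free site
      int k = (int)(u / k_attach);
      if (k >= n_sites - n_bound) k = n_sites - n_bound - 1;
      int seen = 0;
      for (int i = 0; i < n_sites; ++i) {
        if (state[i] == 0) {
          if (seen == k) { site = i; break; }
          ++seen;
        }
      }
      type = 1;
    } else {
      u -= attach_total;
      for (int i = 0; i < n_sites; ++i) {
        if (rate[i] > 0.0) {
          if (u < rate[i]) { site = i; type = state[i] == 1 ? 2 : 3; break; }
          u -= rate[i];
        }
      }
      if (site < 0) { // numeric edge: pick last active site
        for (int i = n_sites - 1; i >= 0; --i)
          if (rate[i] > 0.0) { site = i; type = state[i] == 1 ? 2 : 3; break; }
      }
    }
    if (site < 0) continue;

    // execute: anchors move, filament re-equilibrates to mean bound anchor
    if (type == 1) {
      state[site] = 1;
      // binding strain drawn from the thermal equilibrium of the unbound
      // crossbridge spring (sd ~ sqrt(kT/kappa) when bind_sigma is set so)
      double off = bind_sigma > 0.0 ? R::rnorm(0.0, bind_sigma) : 0.0;
      anchor[site] = z + off;
      ++n_bound; ++n_pre;
      z += off / (double)n_bound; // re-equilibrate to the new anchor mean
    } else if (type == 2) {
      anchor[site] += d_main;
      state[site] = 2;
      z += d_main / (double)n_bound;
      --n_pre; ++n_post;
    } else {
      // secondary step drags the filament, then the motor releases and the
      // remaining motors pull z back to their own equilibrium
      anchor[site] += d_second;
      z += d_second / (double)n_bound;
      state[site] = 0;
      --n_bound; --n_post;
      if (n_bound > 0) {
        double s = 0.0;
        for (int i = 0; i < n_sites; ++i)
          if (state[i] != 0) s += anchor[i];
        z = s / (double)n_bound;
      } // else: z stays where the detaching motor left it
    }
    ++n_events;
    if (log_events) {
      ev_time.push_back(t);
      ev_site.push_back(site + 1);
      ev_type.push_back(type);
    }
  }

  // fill any remaining samples (flat tail)
  while (next_sample < n_grid) {
    t_grid[next_sample] = next_sample * dt;
    z_grid[next_sample] = z;
    nb_grid[next_sample] = n_bound;
    ++next_sample;
  }

  List out = List::create(
      _["time"] = t_grid, _["z"] = z_grid, _["n_bound"] = nb_grid,
      _["occupancy"] = occupancy / total_time,
      _["n_events"] = (double)n_events);
  if (log_events)
    out["events"] = DataFrame::create(_["time"] = ev_time, _["site"] = ev_site,
                                      _["type"] = ev_type);
  return out;
}
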