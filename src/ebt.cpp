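// Escalator Boxcar Train integration of the size-structured consumer-resource
// model. Cohorts carry (number, mean mass, birth time, lineage); the resource
// follows semi-chemostat renewal minus total ingestion. Newborns produced
// within one closure interval are pooled and inserted as a fresh cohort at the
// size at birth (first-order EBT variant). Two parameter sets (lineages)
// may coexist and share the resource, which is what mutant-invasion
// experiments use.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

struct Pars {
  double Rmax, delta, Q, P, M, T, mu_c, mu_j, mu_a, sigma, H;
  double s_b, s_j, s_m, s_rI, s_rT, chi;
};

static Pars unpack(const NumericVector& v) {
  Pars p;
  p.Rmax = v["Rmax"]; p.delta = v["delta"]; p.Q = v["Q"]; p.P = v["P"];
  p.M = v["M"]; p.T = v["T"]; p.mu_c = v["mu_c"]; p.mu_j = v["mu_j"];
  p.mu_a = v["mu_a"]; p.sigma = v["sigma"]; p.H = v["H"];
  p.s_b = v["s_b"]; p.s_j = v["s_j"]; p.s_m = v["s_m"];
  p.s_rI = v["s_rI"]; p.s_rT = v["s_rT"]; p.chi = v["chi"];
  return p;
}

static inline double kappa_fun(double s, const Pars& p) {
  if (s < p.s_j) return 1.0;
  if (s >= p.s_m) return 0.0;
  double L = (s - p.s_j) / (p.s_m - p.s_j);
  return 1.0 - 3.0 * L * L + 2.0 * L * L * L;
}

// per-capita rates at (R, s): ingestion, growth, fecundity, mortality
static inline void vital_rates(double R, double s, const Pars& p,
                               double& I, double& g, double& b, double& mu) {
  I = p.M * std::pow(s / p.s_rI, p.Q) * R / (R + p.H);
  double om = p.sigma * I - p.T * std::pow(s / p.s_rT, p.P);
  double op = om > 0 ? om : 0.0;
  double on = om < 0 ? om : 0.0;
  double k = kappa_fun(s, p);
  g = k * op;
  b = (1.0 - k) * op / p.s_b;
  mu = p.mu_c + (s < p.s_j ? p.mu_j : p.mu_a) - on / s;
}

struct State {
  double R;
  std::vector<double> N, s;   // per cohort
  std::vector<int> lin;
  std::vector<double> birth;  // birth time (diagnostic only)
  double pool[2];             // newborns accumulated since last closure
};

struct Deriv {
  double dR;
  std::vector<double> dN, ds;
  double dpool[2];
};

static void derivs(const State& st, const Pars pars[2], Deriv& d) {
  size_t k = st.N.size();
  d.dN.resize(k); d.ds.resize(k);
  double cons = 0.0;
  d.dpool[0] = 0.0; d.dpool[1] = 0.0;
  for (size_t i = 0; i < k; ++i) {
    const Pars& p = pars[st.lin[i]];
    double I, g, b, mu;
    vital_rates(st.R, st.s[i], p, I, g, b, mu);
    d.dN[i] = -mu * st.N[i];
    d.ds[i] = g;
    d.dpool[st.lin[i]] += b * st.N[i];
    cons += p.chi * I * st.N[i];
  }
  d.dR = pars[0].delta * (pars[0].Rmax - st.R) - cons;
}

// classical RK4 over the coupled cohort + resource + newborn-pool system
static void rk4_step(State& st, const Pars pars[2], double h) {
  size_t k = st.N.size();
  Deriv k1, k2, k3, k4;
  State tmp = st;

  derivs(st, pars, k1);
  tmp.R = st.R + 0.5 * h * k1.dR;
  for (size_t i = 0; i < k; ++i) {
    tmp.N[i] = st.N[i] + 0.5 * h * k1.dN[i];
    tmp.s[i] = st.s[i] + 0.5 * h * k1.ds[i];
  }
  derivs(tmp, pars, k2);
  tmp.R = st.R + 0.5 * h * k2.dR;
  for (size_t i = 0; i < k; ++i) {
    tmp.N[i] = st.N[i] + 0.5 * h * k2.dN[i];
    tmp.s[i] = st.s[i] + 0.5 * h * k2.ds[i];
  }
  derivs(tmp, pars, k3);
  tmp.R = st.R + h * k3.dR;
  for (size_t i = 0; i < k; ++i) {
    tmp.N[i] = st.N[i] + h * k3.dN[i];
    tmp.s[i] = st.s[i] + h * k3.ds[i];
  }
  derivs(tmp, pars, k4);

  st.R += h / 6.0 * (k1.dR + 2 * k2.dR + 2 * k3.dR + k4.dR);
  if (st.R < 0) st.R = 0;
  for (size_t i = 0; i < k; ++i) {
    const Pars& p = pars[st.lin[i]];
    st.N[i] += h / 6.0 * (k1.dN[i] + 2 * k2.dN[i] + 2 * k3.dN[i] + k4.dN[i]);
    st.s[i] += h / 6.0 * (k1.ds[i] + 2 * k2.ds[i] + 2 * k3.ds[i] + k4.ds[i]);
    if (st.N[i] < 0) st.N[i] = 0;
    if (st.s[i] > p.s_m) st.s[i] = p.s_m;
    if (st.s[i] < p.s_b) st.s[i] = p.s_b;
  }
  for (int l = 0; l < 2; ++l)
    st.pool[l] += h / 6.0 * (k1.dpool[l] + 2 * k2.dpool[l] +
                             2 * k3.dpool[l] + k4.dpool[l]);
}

// [[Rcpp::export(name = ".ebt_run")]]
List ebt_run(NumericVector pars_resident, NumericVector pars_mutant,
             NumericMatrix init_cohorts, double init_R,
             double t0, double t_max, double dt, double dt_cohort,
             double record_every, NumericVector extinct_abs, int max_cohorts,
             double merge_tol, double merge_min_age) {
  Pars pars[2];
  pars[0] = unpack(pars_resident);
  pars[1] = pars_mutant.size() ? unpack(pars_mutant) : pars[0];

  State st;
  st.R = init_R;
  st.pool[0] = st.pool[1] = 0.0;
  for (int i = 0; i < init_cohorts.nrow(); ++i) {
    if (init_cohorts(i, 0) <= 0) continue;
    st.N.push_back(init_cohorts(i, 0));
    st.s.push_back(init_cohorts(i, 1));
    st.birth.push_back(t0 - init_cohorts(i, 2));  // column 3 is age
    st.lin.push_back((int) init_cohorts(i, 3));
  }

  int n_sub = (int) std::ceil(dt_cohort / dt);
  double h = dt_cohort / n_sub;
  int n_closures = (int) std::ceil((t_max - t0) / dt_cohort);

  std::vector<double> rec_t, rec_R, rec_jb0, rec_ab0, rec_jb1, rec_ab1,
      rec_b0, rec_b1, rec_nc;
  double next_record = t0;
  double t = t0;

  for (int step = 0; step <= n_closures; ++step) {
    // record state at closure boundaries
    if (t >= next_record - 1e-9 || step == n_closures) {
      double jb[2] = {0, 0}, ab[2] = {0, 0}, br[2] = {0, 0};
      for (size_t i = 0; i < st.N.size(); ++i) {
        const Pars& p = pars[st.lin[i]];
        double I, g, b, mu;
        vital_rates(st.R, st.s[i], p, I, g, b, mu);
        if (st.s[i] < p.s_j) jb[st.lin[i]] += st.N[i] * st.s[i];
        else ab[st.lin[i]] += st.N[i] * st.s[i];
        br[st.lin[i]] += b * st.N[i];
      }
      rec_t.push_back(t); rec_R.push_back(st.R);
      rec_jb0.push_back(jb[0]); rec_ab0.push_back(ab[0]);
      rec_jb1.push_back(jb[1]); rec_ab1.push_back(ab[1]);
      rec_b0.push_back(br[0]); rec_b1.push_back(br[1]);
      rec_nc.push_back((double) st.N.size());
      while (next_record <= t + 1e-9) next_record += record_every;
    }
    if (step == n_closures) break;

    for (int sub = 0; sub < n_sub; ++sub) rk4_step(st, pars, h);
    t = t0 + (step + 1) * dt_cohort;

    // close the boundary cohort: insert pooled newborns at s_b
    for (int l = 0; l < 2; ++l) {
      if (st.pool[l] > extinct_abs[l]) {
        st.N.push_back(st.pool[l]);
        st.s.push_back(pars[l].s_b);
        st.birth.push_back(t);
        st.lin.push_back(l);
      }
      st.pool[l] = 0.0;
    }

    // drop extinct cohorts; merge old cohorts that have converged in mass
    size_t w = 0;
    for (size_t i = 0; i < st.N.size(); ++i) {
      if (st.N[i] > extinct_abs[st.lin[i]]) {
        st.N[w] = st.N[i]; st.s[w] = st.s[i];
        st.birth[w] = st.birth[i]; st.lin[w] = st.lin[i];
        ++w;
      }
    }
    st.N.resize(w); st.s.resize(w); st.birth.resize(w); st.lin.resize(w);

    if (w > 1) {
      size_t m = 0;
      for (size_t i = 1; i < w; ++i) {
        bool old_pair = (t - st.birth[m] > merge_min_age) &&
                        (t - st.birth[i] > merge_min_age);
        if (old_pair && st.lin[i] == st.lin[m] &&
            std::fabs(st.s[i] - st.s[m]) <= merge_tol * st.s[m]) {
          double Nsum = st.N[m] + st.N[i];
          st.s[m] = (st.N[m] * st.s[m] + st.N[i] * st.s[i]) / Nsum;
          st.birth[m] = (st.N[m] * st.birth[m] + st.N[i] * st.birth[i]) / Nsum;
          st.N[m] = Nsum;
        } else {
          ++m;
          st.N[m] = st.N[i]; st.s[m] = st.s[i];
          st.birth[m] = st.birth[i]; st.lin[m] = st.lin[i];
        }
      }
      st.N.resize(m + 1); st.s.resize(m + 1);
      st.birth.resize(m + 1); st.lin.resize(m + 1);
    }

    if ((int) st.N.size() > max_cohorts)
      stop("cohort count exceeded %d; increase dt_cohort or merge_tol",
           max_cohorts);
  }

  NumericMatrix fin(st.N.size(), 4);
  for (size_t i = 0; i < st.N.size(); ++i) {
    fin(i, 0) = st.N[i]; fin(i, 1) = st.s[i];
    fin(i, 2) = t - st.birth[i]; fin(i, 3) = st.lin[i];
  }
  colnames(fin) = CharacterVector::create("density", "mass", "age", "lineage");

  return List::create(
      _["time"] = rec_t, _["resource"] = rec_R,
      _["juv_biomass"] = rec_jb0, _["adult_biomass"] = rec_ab0,
      _["juv_biomass_mutant"] = rec_jb1, _["adult_biomass_mutant"] = rec_ab1,
      _["birth_rate"] = rec_b0, _["birth_rate_mutant"] = rec_b1,
      _["n_cohorts"] = rec_nc,
      _["final_R"] = st.R, _["final_cohorts"] = fin);
}
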