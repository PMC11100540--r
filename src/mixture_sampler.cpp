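// Adaptive Metropolis-within-Gibbs sampler for the hierarchical von
// Mises mixture model of continuous colour reproduction.
//
// Observation i (participant p, design cell c, set-size index s) has
// per-degree density
//   P_M  * vM(resp; target, kappa)
// + P_Swap * mean_j vM(resp; other_j, kappa)
// + P_LTM * vM(resp; ltm, kappa)
// + P_G / 360
// with (P_M, P_Swap, P_LTM, P_G) = softmax of three free logits per
// cell (guess logit fixed at 0) plus participant deviations shared
// across cells, and kappa = exp(log_kappa[s] + participant deviation).
// Components are marginalised (no latent indicators), so the chain
// only moves group logits, log-kappas, participant deviations and the
// four between-participant SDs.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double log_i0e(double kappa) {
  // log of exp(-kappa) * I0(kappa)
  return std::log(Rf_bessel_i(kappa, 0.0, 2.0));
}

// per-degree von Mises density from cos(angular difference)
static inline double vm_pdf(double cosd, double kappa, double li0e) {
  return std::exp(kappa * (cosd - 1.0) - li0e) / 360.0;
}

static inline double dnorm_log(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - 0.9189385332046727;
}

struct MixState {
  NumericMatrix L;      // C x 3 group logits (M, Swap, LTM)
  NumericVector lk;     // K log-kappas
  NumericMatrix dev;    // S x 4 participant deviations (M, Swap, LTM, log-kappa)
  NumericVector sigma;  // 4 between-participant SDs
  NumericMatrix kap;    // S x K participant kappas
  NumericMatrix li0;    // S x K cached log I0e(kappa)
};

class MixModel {
public:
  IntegerVector cell, ssi, pid, o_start, o_len;
  NumericVector cos_t, cos_l, cos_o;
  int n, C, K, S;
  double logit_sd, lk_mean, lk_sd, sigma_scale;

  double obs_ll(int i, const MixState &st) const {
    int c = cell[i], s = ssi[i], p = pid[i];
    double lM = st.L(c, 0) + st.dev(p, 0);
    double lS = st.L(c, 1) + st.dev(p, 1);
    double lL = st.L(c, 2) + st.dev(p, 2);
    double m = std::max(std::max(lM, lS), std::max(lL, 0.0));
    double eM = std::exp(lM - m), eS = std::exp(lS - m),
           eL = std::exp(lL - m), eG = std::exp(-m);
    double tot = eM + eS + eL + eG;
    double k = st.kap(p, s), li = st.li0(p, s);
    double dS = 0.0;
    for (int j = 0; j < o_len[i]; ++j)
      dS += vm_pdf(cos_o[o_start[i] + j], k, li);
    dS /= o_len[i];
    double dens = (eM * vm_pdf(cos_t[i], k, li) + eS * dS +
                   eL * vm_pdf(cos_l[i], k, li) + eG / 360.0) / tot;
    return std::log(std::max(dens, 1e-300));
  }

  double subset_ll(const std::vector<int> &idx, const MixState &st) const {
    double s = 0.0;
    for (size_t t = 0; t < idx.size(); ++t) s += obs_ll(idx[t], st);
    return s;
  }
};

static void refresh_kappa_row(MixState &st, int p, int K) {
  for (int s = 0; s < K; ++s) {
    double k = std::exp(st.lk[s] + st.dev(p, 3));
    st.kap(p, s) = k;
    st.li0(p, s) = log_i0e(k);
  }
}

static void refresh_kappa_col(MixState &st, int s, int S) {
  for (int p = 0; p < S; ++p) {
    double k = std::exp(st.lk[s] + st.dev(p, 3));
    st.kap(p, s) = k;
    st.li0(p, s) = log_i0e(k);
  }
}

// [[Rcpp::export(name = ".mixture_mcmc")]]
List mixture_mcmc(List data, List priors, int warmup, int iter,
                  List init) {
  RNGScope scope;
  MixModel mod;
  mod.cell = data["cell"]; mod.ssi = data["ss"]; mod.pid = data["pid"];
  mod.cos_t = data["cos_t"]; mod.cos_l = data["cos_l"];
  mod.cos_o = data["cos_o"];
  mod.o_start = data["o_start"]; mod.o_len = data["o_len"];
  mod.n = mod.cell.size();
  mod.C = data["n_cell"]; mod.K = data["n_ss"]; mod.S = data["n_pid"];
  mod.logit_sd = priors["logit_sd"];
  mod.lk_mean = priors["log_kappa_mean"];
  mod.lk_sd = priors["log_kappa_sd"];
  mod.sigma_scale = priors["sigma_scale"];

  std::vector< std::vector<int> > by_cell(mod.C), by_ss(mod.K), by_pid(mod.S);
  for (int i = 0; i < mod.n; ++i) {
    by_cell[mod.cell[i]].push_back(i);
    by_ss[mod.ssi[i]].push_back(i);
    by_pid[mod.pid[i]].push_back(i);
  }

  MixState st;
  st.L = clone(as<NumericMatrix>(init["L"]));
  st.lk = clone(as<NumericVector>(init["lk"]));
  st.dev = clone(as<NumericMatrix>(init["dev"]));
  st.sigma = clone(as<NumericVector>(init["sigma"]));
  st.kap = NumericMatrix(mod.S, mod.K);
  st.li0 = NumericMatrix(mod.S, mod.K);
  for (int p = 0; p < mod.S; ++p) refresh_kappa_row(st, p, mod.K);

  std::vector<int> all_idx(mod.n);
  for (int i = 0; i < mod.n; ++i) all_idx[i] = i;

  // one adaptive proposal scale per scalar parameter, plus 4 for the
  // joint (sigma, deviations) rescaling moves
  int n_scale = mod.C * 3 + mod.K + mod.S * 4 + 4 + 4;
  std::vector<double> scale(n_scale, 0.3), acc(n_scale, 0.0), tries(n_scale, 0.0);

  int n_par = mod.C * 3 + mod.K + 4 + mod.S * 4;
  NumericMatrix out(iter, n_par);

  for (int it = 0; it < warmup + iter; ++it) {
    bool adapting = it < warmup;
    double gamma = adapting ? 1.0 / std::sqrt(1.0 + it) : 0.0;
    int sc = 0;

    // group logits, cell by cell
    for (int c = 0; c < mod.C; ++c) {
      for (int j = 0; j < 3; ++j, ++sc) {
        double old = st.L(c, j);
        double prop = old + norm_rand() * scale[sc];
        double cur_ll = mod.subset_ll(by_cell[c], st);
        st.L(c, j) = prop;
        double new_ll = mod.subset_ll(by_cell[c], st);
        double lr = new_ll - cur_ll +
          dnorm_log(prop, 0.0, mod.logit_sd) -
          dnorm_log(old, 0.0, mod.logit_sd);
        bool ok = std::log(unif_rand()) < lr;
        if (!ok) st.L(c, j) = old;
        if (adapting) {
          scale[sc] *= std::exp(gamma * ((ok ? 1.0 : 0.0) - 0.44));
          if (ok) acc[sc] += 1.0;
        }
        tries[sc] += 1.0;
      }
    }

    // log-kappas (scale index continues over parameter blocks in the
    // fixed order: cells*3, K, S*4, 4)
    int sc_lk = mod.C * 3;
    for (int s = 0; s < mod.K; ++s) {
      int id = sc_lk + s;
      double old = st.lk[s];
      double prop = old + norm_rand() * scale[id];
      double cur_ll = mod.subset_ll(by_ss[s], st);
      std::vector<double> old_kap(mod.S), old_li0(mod.S);
      for (int p = 0; p < mod.S; ++p) {
        old_kap[p] = st.kap(p, s); old_li0[p] = st.li0(p, s);
      }
      st.lk[s] = prop;
      refresh_kappa_col(st, s, mod.S);
      double new_ll = mod.subset_ll(by_ss[s], st);
      double lr = new_ll - cur_ll +
        dnorm_log(prop, mod.lk_mean, mod.lk_sd) -
        dnorm_log(old, mod.lk_mean, mod.lk_sd);
      bool ok = std::log(unif_rand()) < lr;
      if (!ok) {
        st.lk[s] = old;
        for (int p = 0; p < mod.S; ++p) {
          st.kap(p, s) = old_kap[p]; st.li0(p, s) = old_li0[p];
        }
      }
      if (adapting) {
        scale[id] *= std::exp(gamma * ((ok ? 1.0 : 0.0) - 0.44));
        if (ok) acc[id] += 1.0;
      }
      tries[id] += 1.0;
    }

    // participant deviations
    int sc_dev = mod.C * 3 + mod.K;
    for (int p = 0; p < mod.S; ++p) {
      for (int d = 0; d < 4; ++d) {
        int id = sc_dev + p * 4 + d;
        double sd_d = std::max(st.sigma[d], 1e-6);
        double old = st.dev(p, d);
        double prop = old + norm_rand() * scale[id];
        double cur_ll = mod.subset_ll(by_pid[p], st);
        std::vector<double> old_kap, old_li0;
        st.dev(p, d) = prop;
        if (d == 3) {
          old_kap.resize(mod.K); old_li0.resize(mod.K);
          for (int s = 0; s < mod.K; ++s) {
            old_kap[s] = st.kap(p, s); old_li0[s] = st.li0(p, s);
          }
          refresh_kappa_row(st, p, mod.K);
        }
        double new_ll = mod.subset_ll(by_pid[p], st);
        double lr = new_ll - cur_ll +
          dnorm_log(prop, 0.0, sd_d) - dnorm_log(old, 0.0, sd_d);
        bool ok = std::log(unif_rand()) < lr;
        if (!ok) {
          st.dev(p, d) = old;
          if (d == 3) {
            for (int s = 0; s < mod.K; ++s) {
              st.kap(p, s) = old_kap[s]; st.li0(p, s) = old_li0[s];
            }
          }
        }
        if (adapting) {
          scale[id] *= std::exp(gamma * ((ok ? 1.0 : 0.0) - 0.44));
          if (ok) acc[id] += 1.0;
        }
        tries[id] += 1.0;
      }
    }

    // between-participant SDs: random-walk on log(sigma), half-normal prior
    int sc_sig = mod.C * 3 + mod.K + mod.S * 4;
    for (int d = 0; d < 4; ++d) {
      int id = sc_sig + d;
      double old = st.sigma[d];
      double prop = old * std::exp(norm_rand() * scale[id]);
      double lr = 0.0;
      double sd_old = std::max(old, 1e-6), sd_new = std::max(prop, 1e-6);
      for (int p = 0; p < mod.S; ++p) {
        lr += dnorm_log(st.dev(p, d), 0.0, sd_new) -
              dnorm_log(st.dev(p, d), 0.0, sd_old);
      }
      // half-normal(0, sigma_scale) prior + log-scale Jacobian
      lr += -0.5 * (prop * prop - old * old) / (mod.sigma_scale * mod.sigma_scale);
      lr += std::log(prop) - std::log(old);
      bool ok = std::log(unif_rand()) < lr;
      if (ok) st.sigma[d] = prop;
      if (adapting) {
        scale[id] *= std::exp(gamma * ((ok ? 1.0 : 0.0) - 0.44));
        if (ok) acc[id] += 1.0;
      }
      tries[id] += 1.0;
    }

    // joint rescaling of (sigma_d, dev[,d]) by a common factor: a
    // funnel-traversing move whose Metropolis ratio includes the
    // transformation Jacobian (net contribution +log c)
    int sc_grp = sc_sig + 4;
    for (int d = 0; d < 4; ++d) {
      int id = sc_grp + d;
      double lc = norm_rand() * scale[id];
      double c = std::exp(lc);
      double old_sigma = st.sigma[d];
      std::vector<double> old_dev(mod.S);
      for (int p = 0; p < mod.S; ++p) old_dev[p] = st.dev(p, d);
      double cur_ll = mod.subset_ll(all_idx, st);
      st.sigma[d] = c * old_sigma;
      for (int p = 0; p < mod.S; ++p) st.dev(p, d) = c * old_dev[p];
      if (d == 3) for (int p = 0; p < mod.S; ++p) refresh_kappa_row(st, p, mod.K);
      double new_ll = mod.subset_ll(all_idx, st);
      double lr = new_ll - cur_ll + lc -
        0.5 * (st.sigma[d] * st.sigma[d] - old_sigma * old_sigma) /
          (mod.sigma_scale * mod.sigma_scale);
      bool ok = std::log(unif_rand()) < lr;
      if (!ok) {
        st.sigma[d] = old_sigma;
        for (int p = 0; p < mod.S; ++p) st.dev(p, d) = old_dev[p];
        if (d == 3) for (int p = 0; p < mod.S; ++p) refresh_kappa_row(st, p, mod.K);
      }
      if (adapting) {
        scale[id] *= std::exp(gamma * ((ok ? 1.0 : 0.0) - 0.44));
        if (ok) acc[id] += 1.0;
      }
      tries[id] += 1.0;
    }

    // likelihood-invariant translation: dev[,d] += delta with the
    // matching group parameters -= delta; accepted on the prior ratio
    // alone, decorrelating group levels from the deviation mean
    for (int d = 0; d < 4; ++d) {
      double delta = norm_rand() * 0.5 *
        std::max(st.sigma[d] / std::sqrt((double)mod.S), 0.01);
      double lr = 0.0;
      double sd_d = std::max(st.sigma[d], 1e-6);
      for (int p = 0; p < mod.S; ++p)
        lr += dnorm_log(st.dev(p, d) + delta, 0.0, sd_d) -
              dnorm_log(st.dev(p, d), 0.0, sd_d);
      if (d < 3) {
        for (int c = 0; c < mod.C; ++c)
          lr += dnorm_log(st.L(c, d) - delta, 0.0, mod.logit_sd) -
                dnorm_log(st.L(c, d), 0.0, mod.logit_sd);
      } else {
        for (int s = 0; s < mod.K; ++s)
          lr += dnorm_log(st.lk[s] - delta, mod.lk_mean, mod.lk_sd) -
                dnorm_log(st.lk[s], mod.lk_mean, mod.lk_sd);
      }
      if (std::log(unif_rand()) < lr) {
        for (int p = 0; p < mod.S; ++p) st.dev(p, d) += delta;
        if (d < 3) {
          for (int c = 0; c < mod.C; ++c) st.L(c, d) -= delta;
        } else {
          for (int s = 0; s < mod.K; ++s) st.lk[s] -= delta;
          // kappas depend on lk[s] + dev[p,3], unchanged by the shift
        }
      }
    }

    if (!adapting) {
      int col = 0, row = it - warmup;
      for (int c = 0; c < mod.C; ++c)
        for (int j = 0; j < 3; ++j) out(row, col++) = st.L(c, j);
      for (int s = 0; s < mod.K; ++s) out(row, col++) = st.lk[s];
      for (int d = 0; d < 4; ++d) out(row, col++) = st.sigma[d];
      for (int p = 0; p < mod.S; ++p)
        for (int d = 0; d < 4; ++d) out(row, col++) = st.dev(p, d);
    }
  }

  return List::create(_["draws"] = out);
}

// Direct evaluation of the marginal mixture log-likelihood for one
// parameter setting; used by tests as a cross-check of the density.
// [[Rcpp::export(name = ".mixture_loglik")]]
double mixture_loglik(List data, NumericMatrix L, NumericVector lk,
                      NumericMatrix dev, NumericVector sigma) {
  MixModel mod;
  mod.cell = data["cell"]; mod.ssi = data["ss"]; mod.pid = data["pid"];
  mod.cos_t = data["cos_t"]; mod.cos_l = data["cos_l"];
  mod.cos_o = data["cos_o"];
  mod.o_start = data["o_start"]; mod.o_len = data["o_len"];
  mod.n = mod.cell.size();
  mod.C = data["n_cell"]; mod.K = data["n_ss"]; mod.S = data["n_pid"];
  MixState st;
  st.L = L; st.lk = lk; st.dev = dev; st.sigma = sigma;
  st.kap = NumericMatrix(mod.S, mod.K);
  st.li0 = NumericMatrix(mod.S, mod.K);
  for (int p = 0; p < mod.S; ++p) refresh_kappa_row(st, p, mod.K);
  double ll = 0.0;
  for (int i = 0; i < mod.n; ++i) ll += mod.obs_ll(i, st);
  return ll;
}
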