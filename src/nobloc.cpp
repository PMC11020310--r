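// Collapsed Gibbs sampler for nonparametric Bayesian local biclustering:
// proteins are allocated to biclusters (or left invariant) by a
// zero-enriched Polya urn, and each bicluster carries its own local
// partition of the samples (label 0 = inactive). Block likelihoods use a
// Normal likelihood with a conjugate Normal-Inverse-Gamma base, integrated
// analytically; new biclusters are proposed with one auxiliary sample
// partition drawn from the prior (Neal algorithm-8 style), which leaves
// the exact zero-enriched posterior invariant.
#include <Rcpp.h>
using namespace Rcpp;

struct Priors {
  double pi0, pi0_sample, alpha_p, alpha_s;
  double m0, k0, a0, b0;   // NIG base measure
  double base_sd;          // baseline model: Normal(m0, base_sd^2)
};

static Priors read_priors(const List& pr) {
  Priors p;
  p.pi0 = as<double>(pr["pi0"]);
  p.pi0_sample = as<double>(pr["pi0_sample"]);
  p.alpha_p = as<double>(pr["alpha_protein"]);
  p.alpha_s = as<double>(pr["alpha_sample"]);
  p.m0 = as<double>(pr["m0"]);
  p.k0 = as<double>(pr["k0"]);
  p.a0 = as<double>(pr["a0"]);
  p.b0 = as<double>(pr["b0"]);
  p.base_sd = as<double>(pr["baseline_sd"]);
  return p;
}

// log marginal likelihood of a block of values under Normal-NIG, from the
// sufficient statistics (count, sum, sum of squares)
static double nig_marg(double n, double s1, double s2, const Priors& pr) {
  if (n <= 0) return 0.0;
  double kn = pr.k0 + n;
  double mean = s1 / n;
  double ss = s2 - s1 * s1 / n;
  if (ss < 0) ss = 0;
  double dm = mean - pr.m0;
  double bn = pr.b0 + 0.5 * ss + 0.5 * pr.k0 * n * dm * dm / kn;
  return -0.5 * n * std::log(2.0 * M_PI)
       + 0.5 * std::log(pr.k0 / kn)
       + pr.a0 * std::log(pr.b0)
       - (pr.a0 + 0.5 * n) * std::log(bn)
       + std::lgamma(pr.a0 + 0.5 * n) - std::lgamma(pr.a0);
}

static inline double base_ll(double y, const Priors& pr) {
  return R::dnorm(y, pr.m0, pr.base_sd, 1);
}

// [[Rcpp::export]]
double nig_marg_cpp(NumericVector values, double m0, double k0, double a0,
                    double b0) {
  Priors pr; pr.m0 = m0; pr.k0 = k0; pr.a0 = a0; pr.b0 = b0;
  pr.pi0 = pr.pi0_sample = 0.5; pr.alpha_p = pr.alpha_s = 1;
  pr.base_sd = 1;
  double n = 0, s1 = 0, s2 = 0;
  for (double v : values) {
    if (ISNAN(v)) continue;
    n += 1; s1 += v; s2 += v * v;
  }
  return nig_marg(n, s1, s2, pr);
}

// log likelihood of protein g's row under a given sample-label vector
static double row_ll(const NumericMatrix& y, int g,
                     const std::vector<int>& lab, const Priors& pr) {
  int S = y.ncol();
  int J = 0;
  for (int s = 0; s < S; s++) if (lab[s] > J) J = lab[s];
  std::vector<double> n(J + 1, 0), s1(J + 1, 0), s2(J + 1, 0);
  double ll = 0;
  for (int s = 0; s < S; s++) {
    double v = y(g, s);
    if (ISNAN(v)) continue;
    int j = lab[s];
    if (j == 0) ll += base_ll(v, pr);
    else { n[j] += 1; s1[j] += v; s2[j] += v * v; }
  }
  for (int j = 1; j <= J; j++) ll += nig_marg(n[j], s1[j], s2[j], pr);
  return ll;
}

static double baseline_row_ll(const NumericMatrix& y, int g,
                              const Priors& pr) {
  double ll = 0;
  for (int s = 0; s < y.ncol(); s++) {
    double v = y(g, s);
    if (!ISNAN(v)) ll += base_ll(v, pr);
  }
  return ll;
}

// draw a sample partition from the zero-enriched urn prior
static std::vector<int> draw_sample_partition(int S, const Priors& pr) {
  std::vector<int> lab(S, 0);
  std::vector<int> cnt;
  int nact = 0;
  for (int s = 0; s < S; s++) {
    if (unif_rand() >= pr.pi0_sample) continue;  // inactive
    double u = unif_rand() * (nact + pr.alpha_s);
    double acc = 0;
    int j = 0;
    for (size_t jj = 0; jj < cnt.size(); jj++) {
      acc += cnt[jj];
      if (u < acc) { j = (int)jj + 1; break; }
    }
    if (j == 0) { cnt.push_back(0); j = (int)cnt.size(); }
    cnt[j - 1]++;
    nact++;
    lab[s] = j;
  }
  return lab;
}

static int sample_logweights(const std::vector<double>& lw) {
  double m = lw[0];
  for (double w : lw) if (w > m) m = w;
  double tot = 0;
  for (double w : lw) tot += std::exp(w - m);
  double u = unif_rand() * tot, acc = 0;
  for (size_t i = 0; i < lw.size(); i++) {
    acc += std::exp(lw[i] - m);
    if (u <= acc) return (int)i;
  }
  return (int)lw.size() - 1;
}

struct State {
  std::vector<int> omega;                 // 0..K per protein
  std::vector<std::vector<int>> slab;     // per bicluster: S labels 0..J
  std::vector<int> csize;                 // proteins per bicluster
};

static void remove_cluster(State& st, int k) {  // k is 1-based label
  st.slab.erase(st.slab.begin() + (k - 1));
  st.csize.erase(st.csize.begin() + (k - 1));
  for (int& o : st.omega) if (o > k) o--;
}

static void update_protein(int g, State& st, const NumericMatrix& y,
                           const Priors& pr) {
  int cur = st.omega[g];
  std::vector<int> aux;
  bool have_aux = false;
  if (cur > 0) {
    st.csize[cur - 1]--;
    if (st.csize[cur - 1] == 0) {
      aux = st.slab[cur - 1];  // reuse the emptied cluster's partition
      have_aux = true;
      remove_cluster(st, cur);
    }
    st.omega[g] = 0;
  }
  if (!have_aux) aux = draw_sample_partition((int)y.ncol(), pr);
  int K = (int)st.csize.size();
  int nv = 0;
  for (size_t i = 0; i < st.omega.size(); i++)
    if ((int)i != g && st.omega[i] > 0) nv++;
  std::vector<double> lw(K + 2);
  lw[0] = std::log1p(-pr.pi0) + baseline_row_ll(y, g, pr);
  double lden = std::log(nv + pr.alpha_p);
  for (int k = 1; k <= K; k++)
    lw[k] = std::log(pr.pi0) + std::log((double)st.csize[k - 1]) - lden
          + row_ll(y, g, st.slab[k - 1], pr);
  lw[K + 1] = std::log(pr.pi0) + std::log(pr.alpha_p) - lden
            + row_ll(y, g, aux, pr);
  int pick = sample_logweights(lw);
  if (pick == 0) {
    st.omega[g] = 0;
  } else if (pick <= K) {
    st.omega[g] = pick;
    st.csize[pick - 1]++;
  } else {
    st.slab.push_back(aux);
    st.csize.push_back(1);
    st.omega[g] = K + 1;
  }
}

static void update_samples(int k, State& st, const NumericMatrix& y,
                           const Priors& pr) {
  int S = y.ncol();
  std::vector<int> members;
  for (size_t g = 0; g < st.omega.size(); g++)
    if (st.omega[g] == k) members.push_back((int)g);
  int M = (int)members.size();
  if (M == 0) return;
  std::vector<int>& lab = st.slab[k - 1];
  int J = 0;
  for (int s = 0; s < S; s++) if (lab[s] > J) J = lab[s];
  // per-subcluster, per-member sufficient statistics (NA-aware)
  std::vector<std::vector<double>> N(J), S1(J), S2(J);
  std::vector<int> scount(J, 0);
  for (int j = 0; j < J; j++) {
    N[j].assign(M, 0); S1[j].assign(M, 0); S2[j].assign(M, 0);
  }
  for (int s = 0; s < S; s++) {
    int j = lab[s];
    if (j == 0) continue;
    scount[j - 1]++;
    for (int i = 0; i < M; i++) {
      double v = y(members[i], s);
      if (ISNAN(v)) continue;
      N[j - 1][i] += 1; S1[j - 1][i] += v; S2[j - 1][i] += v * v;
    }
  }
  for (int s = 0; s < S; s++) {
    int jcur = lab[s];
    if (jcur > 0) {  // detach s
      scount[jcur - 1]--;
      for (int i = 0; i < M; i++) {
        double v = y(members[i], s);
        if (ISNAN(v)) continue;
        N[jcur - 1][i] -= 1; S1[jcur - 1][i] -= v; S2[jcur - 1][i] -= v * v;
      }
      if (scount[jcur - 1] == 0) {
        scount.erase(scount.begin() + (jcur - 1));
        N.erase(N.begin() + (jcur - 1));
        S1.erase(S1.begin() + (jcur - 1));
        S2.erase(S2.begin() + (jcur - 1));
        for (int t = 0; t < S; t++) if (lab[t] > jcur) lab[t]--;
        J--;
      }
      lab[s] = 0;
    }
    int na = 0;
    for (int j = 0; j < J; j++) na += scount[j];
    std::vector<double> lw(J + 2);
    double ll0 = 0;
    for (int i = 0; i < M; i++) {
      double v = y(members[i], s);
      if (!ISNAN(v)) ll0 += base_ll(v, pr);
    }
    lw[0] = std::log1p(-pr.pi0_sample) + ll0;
    double lden = std::log(na + pr.alpha_s);
    for (int j = 1; j <= J; j++) {
      double ll = 0;
      for (int i = 0; i < M; i++) {
        double v = y(members[i], s);
        if (ISNAN(v)) continue;
        ll += nig_marg(N[j - 1][i] + 1, S1[j - 1][i] + v,
                       S2[j - 1][i] + v * v, pr)
            - nig_marg(N[j - 1][i], S1[j - 1][i], S2[j - 1][i], pr);
      }
      lw[j] = std::log(pr.pi0_sample) + std::log((double)scount[j - 1])
            - lden + ll;
    }
    double llnew = 0;
    for (int i = 0; i < M; i++) {
      double v = y(members[i], s);
      if (!ISNAN(v)) llnew += nig_marg(1, v, v * v, pr);
    }
    lw[J + 1] = std::log(pr.pi0_sample) + std::log(pr.alpha_s) - lden + llnew;
    int pick = sample_logweights(lw);
    if (pick == 0) continue;  // stays inactive
    if (pick <= J) {
      lab[s] = pick;
      scount[pick - 1]++;
      for (int i = 0; i < M; i++) {
        double v = y(members[i], s);
        if (ISNAN(v)) continue;
        N[pick - 1][i] += 1; S1[pick - 1][i] += v; S2[pick - 1][i] += v * v;
      }
    } else {
      J++;
      lab[s] = J;
      scount.push_back(1);
      N.push_back(std::vector<double>(M, 0));
      S1.push_back(std::vector<double>(M, 0));
      S2.push_back(std::vector<double>(M, 0));
      for (int i = 0; i < M; i++) {
        double v = y(members[i], s);
        if (ISNAN(v)) continue;
        N[J - 1][i] += 1; S1[J - 1][i] += v; S2[J - 1][i] += v * v;
      }
    }
  }
}

static double state_loglik(const State& st, const NumericMatrix& y,
                           const Priors& pr) {
  double ll = 0;
  for (size_t g = 0; g < st.omega.size(); g++) {
    if (st.omega[g] == 0) ll += baseline_row_ll(y, (int)g, pr);
    else ll += row_ll(y, (int)g, st.slab[st.omega[g] - 1], pr);
  }
  return ll;
}

// [[Rcpp::export]]
List nobloc_mcmc_cpp(NumericMatrix y, IntegerVector omega_init,
                     IntegerMatrix slab_init, List priors, int n_iter,
                     int burn_in, int thin) {
  Priors pr = read_priors(priors);
  int G = y.nrow(), S = y.ncol();
  State st;
  st.omega.assign(omega_init.begin(), omega_init.end());
  int K0 = slab_init.nrow();
  for (int k = 0; k < K0; k++) {
    std::vector<int> lab(S);
    for (int s = 0; s < S; s++) lab[s] = slab_init(k, s);
    st.slab.push_back(lab);
  }
  st.csize.assign(K0, 0);
  for (int g = 0; g < G; g++)
    if (st.omega[g] > 0) st.csize[st.omega[g] - 1]++;
  int n_keep = (n_iter - burn_in) / thin;
  IntegerMatrix omega_trace(n_keep, G);
  List slab_trace(n_keep);
  NumericVector loglik(n_iter);
  int kept = 0;
  for (int it = 0; it < n_iter; it++) {
    // samples first: lets freshly initialized (or newly opened) biclusters
    // adapt their local sample partitions before memberships are judged
    for (int k = 1; k <= (int)st.csize.size(); k++)
      update_samples(k, st, y, pr);
    for (int g = 0; g < G; g++) update_protein(g, st, y, pr);
    loglik[it] = state_loglik(st, y, pr);
    if (it >= burn_in && (it - burn_in) % thin == 0 && kept < n_keep) {
      for (int g = 0; g < G; g++) omega_trace(kept, g) = st.omega[g];
      IntegerMatrix sm((int)st.slab.size(), S);
      for (size_t k = 0; k < st.slab.size(); k++)
        for (int s = 0; s < S; s++) sm((int)k, s) = st.slab[k][s];
      slab_trace[kept] = sm;
      kept++;
    }
    if (it % 500 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["omega"] = omega_trace,
                      _["sample_partitions"] = slab_trace,
                      _["loglik"] = loglik);
}
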