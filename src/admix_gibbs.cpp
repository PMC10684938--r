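#include <Rcpp.h>
using namespace Rcpp;

// Data log-likelihood of dosage matrix G under ancestry Q (N x K) and
// cluster alt-allele frequencies P (K x L); theta_il = sum_k Q_ik P_kl.
static double data_loglik(const IntegerMatrix &G, const NumericMatrix &Q,
                          const NumericMatrix &P) {
  const int N = G.nrow(), L = G.ncol(), K = Q.ncol();
  const double eps = 1e-9, log2_ = std::log(2.0);
  double ll = 0.0;
  for (int l = 0; l < L; ++l) {
    for (int i = 0; i < N; ++i) {
      int g = G(i, l);
      if (g == NA_INTEGER) continue;
      double theta = 0.0;
      for (int k = 0; k < K; ++k) theta += Q(i, k) * P(k, l);
      if (theta < eps) theta = eps;
      if (theta > 1.0 - eps) theta = 1.0 - eps;
      ll += g * std::log(theta) + (2 - g) * std::log1p(-theta);
      if (g == 1) ll += log2_;
    }
  }
  return ll;
}

// [[Rcpp::export]]
double admix_loglik_cpp(IntegerMatrix G, NumericMatrix Q, NumericMatrix P) {
  return data_loglik(G, Q, P);
}

static inline double clamp01(double x) {
  const double eps = 1e-9;
  if (x < eps) return eps;
  if (x > 1.0 - eps) return 1.0 - eps;
  return x;
}

// Latent-allele-origin Gibbs sampler for the admixture model.
//   fixed_pop: -1 for free individuals, else 0-based cluster index whose
//              indicator the Q row is pinned to (zero-migration prior).
//   freq_source: whether the individual's sampled allele origins update P
//              (frequencies-from-flagged-only semantics).
//   ll_thin:   evaluate the data log-likelihood every ll_thin-th sweep
//              (other sweeps carry NA in the trace).
// Returns posterior-mean Q and P over post-burn-in sweeps, the per-sweep
// log-likelihood trace and the alpha trace.
// [[Rcpp::export]]
List admix_gibbs_cpp(IntegerMatrix G, int K, int burnin, int reps,
                     double lambda, bool infer_alpha, double alpha_init,
                     IntegerVector fixed_pop, LogicalVector freq_source,
                     double alpha_prop_sd, double alpha_max,
                     int ll_thin = 1) {
  const int N = G.nrow(), L = G.ncol();
  const int sweeps = burnin + reps;
  const double eps = 1e-9, log2_ = std::log(2.0);
  NumericMatrix Q(N, K), P(K, L);
  NumericMatrix Qsum(N, K), Psum(K, L);
  NumericVector lnl_trace(sweeps), alpha_trace(sweeps);
  double alpha = alpha_init;

  NumericMatrix n_ik(N, K);
  NumericMatrix alt_kl(K, L), ref_kl(K, L);
  std::vector<double> walt(K), wref(K);

  for (int i = 0; i < N; ++i) {
    if (fixed_pop[i] >= 0) {
      for (int k = 0; k < K; ++k) Q(i, k) = (k == fixed_pop[i]) ? 1.0 : 0.0;
    } else {
      double s = 0.0;
      for (int k = 0; k < K; ++k) { Q(i, k) = R::rgamma(1.0, 1.0); s += Q(i, k); }
      for (int k = 0; k < K; ++k) Q(i, k) /= s;
    }
  }
  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) P(k, l) = clamp01(R::rbeta(lambda, lambda));

  int n_free = 0;
  for (int i = 0; i < N; ++i) if (fixed_pop[i] < 0) ++n_free;

  double *Qp = Q.begin(), *Pp = P.begin(), *nikp = n_ik.begin();
  double *altp = alt_kl.begin(), *refp = ref_kl.begin();
  int *Gp = G.begin();

  for (int s = 0; s < sweeps; ++s) {
    std::fill(n_ik.begin(), n_ik.end(), 0.0);
    std::fill(alt_kl.begin(), alt_kl.end(), 0.0);
    std::fill(ref_kl.begin(), ref_kl.end(), 0.0);
    bool do_ll = (s % ll_thin == 0) || s == sweeps - 1;
    double ll = 0.0;

    for (int l = 0; l < L; ++l) {
      const double *pcol = Pp + (size_t)l * K;
      double *acol = altp + (size_t)l * K;
      double *rcol = refp + (size_t)l * K;
      const int *gcol = Gp + (size_t)l * N;
      for (int i = 0; i < N; ++i) {
        int g = gcol[i];
        if (g == NA_INTEGER) continue;
        // w_alt = Q * P, w_ref = Q - w_alt; theta = sum(w_alt)
        double theta = 0.0;
        for (int k = 0; k < K; ++k) {
          double q = Qp[(size_t)k * N + i];
          double wa = q * pcol[k];
          walt[k] = wa;
          wref[k] = q - wa;
          theta += wa;
        }
        if (do_ll) {
          double th = theta < eps ? eps : (theta > 1.0 - eps ? 1.0 - eps : theta);
          ll += g * std::log(th) + (2 - g) * std::log1p(-th);
          if (g == 1) ll += log2_;
        }
        bool src = freq_source[i];
        for (int rep = 0; rep < g; ++rep) {
          double u = unif_rand() * theta, acc = 0.0;
          int z = K - 1;
          for (int k = 0; k < K; ++k) { acc += walt[k]; if (u <= acc) { z = k; break; } }
          nikp[(size_t)z * N + i] += 1.0;
          if (src) acol[z] += 1.0;
        }
        if (g < 2) {
          double wrs = 1.0 - theta;  // rows of Q sum to 1
          for (int rep = 0; rep < 2 - g; ++rep) {
            double u = unif_rand() * wrs, acc = 0.0;
            int z = K - 1;
            for (int k = 0; k < K; ++k) { acc += wref[k]; if (u <= acc) { z = k; break; } }
            nikp[(size_t)z * N + i] += 1.0;
            if (src) rcol[z] += 1.0;
          }
        }
      }
    }

    // P | origins ~ Beta(lambda + alt, lambda + ref)
    for (int k = 0; k < K; ++k)
      for (int l = 0; l < L; ++l)
        P(k, l) = clamp01(R::rbeta(lambda + alt_kl(k, l), lambda + ref_kl(k, l)));

    // Q | origins ~ Dirichlet(alpha + n_ik) for free individuals
    for (int i = 0; i < N; ++i) {
      if (fixed_pop[i] >= 0) continue;
      double s2 = 0.0;
      for (int k = 0; k < K; ++k) {
        double v = R::rgamma(alpha + n_ik(i, k), 1.0);
        if (v < 1e-300) v = 1e-300;
        Qp[(size_t)k * N + i] = v;
        s2 += v;
      }
      for (int k = 0; k < K; ++k) Qp[(size_t)k * N + i] /= s2;
    }

    // Metropolis step on the shared Dirichlet concentration
    if (infer_alpha && K > 1 && n_free > 0) {
      double prop = alpha + norm_rand() * alpha_prop_sd;
      if (prop > 0.0 && prop < alpha_max) {
        double logr = n_free * (R::lgammafn(K * prop) - K * R::lgammafn(prop)
                    - R::lgammafn(K * alpha) + K * R::lgammafn(alpha));
        double slogq = 0.0;
        for (int i = 0; i < N; ++i) {
          if (fixed_pop[i] >= 0) continue;
          for (int k = 0; k < K; ++k) slogq += std::log(Qp[(size_t)k * N + i]);
        }
        logr += (prop - alpha) * slogq;
        if (std::log(unif_rand()) < logr) alpha = prop;
      }
    }
    alpha_trace[s] = alpha;
    lnl_trace[s] = do_ll ? ll : NA_REAL;

    if (s >= burnin) {
      for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) += Q(i, k);
      for (int k = 0; k < K; ++k)
        for (int l = 0; l < L; ++l) Psum(k, l) += P(k, l);
    }
  }

  for (int k = 0; k < K; ++k)
    for (int l = 0; l < L; ++l) Psum(k, l) = clamp01(Psum(k, l) / reps);
  for (int i = 0; i < N; ++i) {
    double s2 = 0.0;
    for (int k = 0; k < K; ++k) s2 += Qsum(i, k);
    for (int k = 0; k < K; ++k) Qsum(i, k) /= s2;
  }

  return List::create(_["Q"] = Qsum, _["P"] = Psum,
                      _["lnL_trace"] = lnl_trace,
                      _["alpha_trace"] = alpha_trace);
}
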