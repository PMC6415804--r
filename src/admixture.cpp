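// Gibbs sampler for the admixture model of population structure:
// each individual i has admixture proportions q_i ~ Dirichlet(alpha), each
// cluster k carries allele frequencies p_kl ~ Dirichlet(lambda = 1) at each
// locus, and every gene copy is assigned to a cluster z ~ q_i with its
// allele drawn from p_z. Cluster assignments, Q, P and (optionally) alpha
// are updated by Gibbs / Metropolis steps; posterior means and the per-sweep
// log-likelihood after burn-in are returned. Uses R's RNG.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static void rdirichlet(std::vector<double> &x, const std::vector<double> &shape) {
  double s = 0.0;
  for (size_t j = 0; j < shape.size(); ++j) {
    x[j] = R::rgamma(shape[j], 1.0);
    if (x[j] < 1e-300) x[j] = 1e-300;
    s += x[j];
  }
  for (size_t j = 0; j < shape.size(); ++j) x[j] /= s;
}

// [[Rcpp::export]]
List cpp_admixture_gibbs(IntegerMatrix g1, IntegerMatrix g2,
                         IntegerVector nAlleles, int K, int sweeps, int burnin,
                         double alphaInit, bool updateAlpha,
                         double lambda, double alphaMax, double alphaPropSd) {
  const int n = g1.nrow(), L = g1.ncol();
  if (K < 1) stop("K must be >= 1");
  if (K > n) stop("K exceeds the number of individuals");
  if (sweeps <= burnin) stop("sweeps must exceed burn_in");

  // P[l] is a K x J_l matrix stored row-major per cluster
  std::vector< std::vector<double> > P(L), Pacc(L);
  for (int l = 0; l < L; ++l) {
    P[l].assign((size_t) K * nAlleles[l], 1.0 / nAlleles[l]);
    Pacc[l].assign((size_t) K * nAlleles[l], 0.0);
  }
  NumericMatrix Q(n, K), Qacc(n, K);
  std::fill(Q.begin(), Q.end(), 1.0 / K);
  double alpha = alphaInit;

  std::vector<double> cntQ((size_t) n * K), prob(K), tmp(K), shape;
  std::vector< std::vector<double> > cntP(L);
  for (int l = 0; l < L; ++l) cntP[l].resize((size_t) K * nAlleles[l]);
  NumericVector llTrace(sweeps - burnin);
  double alphaAcc = 0.0;
  int kept = 0;

  for (int sw = 0; sw < sweeps; ++sw) {
    std::fill(cntQ.begin(), cntQ.end(), 0.0);
    for (int l = 0; l < L; ++l)
      std::fill(cntP[l].begin(), cntP[l].end(), 0.0);
    double ll = 0.0;

    // z-step: assign every observed gene copy, accumulating counts and the
    // marginal log-likelihood sum_k q_ik p_kla of each copy
    for (int i = 0; i < n; ++i) {
      for (int l = 0; l < L; ++l) {
        for (int copy = 0; copy < 2; ++copy) {
          int a = copy == 0 ? g1(i, l) : g2(i, l);
          if (a == NA_INTEGER || a < 0) continue;
          double s = 0.0;
          for (int k = 0; k < K; ++k) {
            prob[k] = Q(i, k) * P[l][(size_t) k * nAlleles[l] + a];
            s += prob[k];
          }
          ll += std::log(s);
          double u = unif_rand() * s;
          int z = K - 1;
          double acc = 0.0;
          for (int k = 0; k < K; ++k) { acc += prob[k]; if (u <= acc) { z = k; break; } }
          cntQ[(size_t) i * K + z] += 1.0;
          cntP[l][(size_t) z * nAlleles[l] + a] += 1.0;
        }
      }
    }

    // P-step
    for (int l = 0; l < L; ++l) {
      int J = nAlleles[l];
      std::vector<double> x(J);
      shape.resize(J);
      for (int k = 0; k < K; ++k) {
        for (int j = 0; j < J; ++j)
          shape[j] = lambda + cntP[l][(size_t) k * J + j];
        rdirichlet(x, shape);
        for (int j = 0; j < J; ++j) P[l][(size_t) k * J + j] = x[j];
      }
    }

    // Q-step, tracking sum log q for the alpha update
    double sumLogQ = 0.0;
    shape.resize(K);
    for (int i = 0; i < n; ++i) {
      for (int k = 0; k < K; ++k) shape[k] = alpha + cntQ[(size_t) i * K + k];
      rdirichlet(tmp, shape);
      for (int k = 0; k < K; ++k) {
        Q(i, k) = tmp[k];
        sumLogQ += std::log(tmp[k]);
      }
    }

    // alpha: Metropolis random walk, uniform prior on (0, alphaMax]
    if (updateAlpha && K > 1) {
      double aNew = alpha + norm_rand() * alphaPropSd;
      if (aNew > 0 && aNew <= alphaMax) {
        double logR = n * (R::lgammafn(K * aNew) - K * R::lgammafn(aNew)
                           - R::lgammafn(K * alpha) + K * R::lgammafn(alpha))
                      + (aNew - alpha) * sumLogQ;
        if (std::log(unif_rand()) < logR) alpha = aNew;
      }
    }

    if (sw >= burnin) {
      llTrace[kept++] = ll;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < K; ++k) Qacc(i, k) += Q(i, k);
      for (int l = 0; l < L; ++l)
        for (size_t j = 0; j < P[l].size(); ++j) Pacc[l][j] += P[l][j];
      alphaAcc += alpha;
    }
  }

  int m = sweeps - burnin;
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < K; ++k) Qacc(i, k) /= m;
  List Pout(L);
  for (int l = 0; l < L; ++l) {
    NumericMatrix M(K, nAlleles[l]);
    for (int k = 0; k < K; ++k)
      for (int j = 0; j < nAlleles[l]; ++j)
        M(k, j) = Pacc[l][(size_t) k * nAlleles[l] + j] / m;
    Pout[l] = M;
  }
  return List::create(_["Q"] = Qacc, _["P"] = Pout, _["loglik"] = llTrace,
                      _["alpha"] = alphaAcc / m);
}
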