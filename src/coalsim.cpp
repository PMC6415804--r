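// Backward-time structured coalescent for unlinked microsatellite loci.
//
// Populations have piecewise-constant diploid sizes; "move" events send all
// lineages of a target population into one source (split) or into one of two
// sources with probability rA / 1-rA (admixture). Within an epoch, pairs in
// a population of size N coalesce at rate k(k-1)/2 / (2N) per generation.
// Mutations are Poisson on branch lengths and change the repeat count by +-1
// (SMM) or by a geometric number of steps (TPM). Uses R's RNG throughout so
// a single set.seed() governs everything.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Lineage {
  double birth;                 // time its branch started (towards the past)
  std::vector<int> samples;     // descendant sample copies (0-based)
};

int mut_steps(double pSingle, double meanMulti) {
  int size = 1;
  if (pSingle < 1.0 && unif_rand() > pSingle)
    size = 1 + (int) R::rgeom(1.0 / meanMulti);
  return (unif_rand() < 0.5) ? -size : size;
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_sim_loci(IntegerVector sampleSizes, NumericMatrix sizeEpochs,
                           NumericMatrix moves, int nLoci, NumericVector mu,
                           double pSingle, double meanMulti,
                           int ancestralState) {
  const int npop = sampleSizes.size();
  int total = 0;
  for (int p = 0; p < npop; ++p) total += sampleSizes[p];
  IntegerMatrix out(total, nLoci);

  // per-pop size schedule, sorted by start time
  std::vector< std::vector<std::pair<double,double> > > sched(npop);
  for (int r = 0; r < sizeEpochs.nrow(); ++r) {
    int p = (int) sizeEpochs(r, 0) - 1;
    if (p < 0 || p >= npop) stop("size epoch references unknown population");
    if (sizeEpochs(r, 2) <= 0) stop("non-positive population size in epoch schedule");
    sched[p].push_back(std::make_pair(sizeEpochs(r, 1), sizeEpochs(r, 2)));
  }
  for (int p = 0; p < npop; ++p) {
    if (sched[p].empty()) stop("population without a size epoch");
    std::sort(sched[p].begin(), sched[p].end());
  }
  auto pop_size = [&](int p, double t) {
    double N = sched[p][0].second;
    for (size_t e = 0; e < sched[p].size(); ++e)
      if (sched[p][e].first <= t + 1e-12) N = sched[p][e].second; else break;
    return N;
  };

  // boundaries where rates change or lineages move
  std::vector<double> bounds;
  for (int p = 0; p < npop; ++p)
    for (size_t e = 1; e < sched[p].size(); ++e) bounds.push_back(sched[p][e].first);
  for (int r = 0; r < moves.nrow(); ++r) bounds.push_back(moves(r, 0));
  std::sort(bounds.begin(), bounds.end());
  bounds.erase(std::unique(bounds.begin(), bounds.end()), bounds.end());

  std::vector<Lineage> lin;
  std::vector< std::vector<int> > byPop(npop);

  for (int l = 0; l < nLoci; ++l) {
    lin.clear();
    lin.reserve(2 * total);
    for (int p = 0; p < npop; ++p) byPop[p].clear();
    int s = 0;
    for (int p = 0; p < npop; ++p)
      for (int i = 0; i < sampleSizes[p]; ++i) {
        Lineage L; L.birth = 0.0; L.samples.assign(1, s++);
        byPop[p].push_back((int) lin.size());
        lin.push_back(L);
      }

    auto end_branch = [&](Lineage &L, double t) {
      double len = t - L.birth;
      if (len <= 0) return;
      int m = (int) R::rpois(mu[l] * len);
      if (m == 0) return;
      int net = 0;
      for (int j = 0; j < m; ++j) net += mut_steps(pSingle, meanMulti);
      if (net != 0)
        for (size_t j = 0; j < L.samples.size(); ++j) out(L.samples[j], l) += net;
    };

    double t = 0.0;
    size_t nb = 0;
    int active = total;
    std::vector<double> rate(npop);
    while (active > 1) {
      double tNext = (nb < bounds.size()) ? bounds[nb] : R_PosInf;
      double R = 0.0;
      for (int p = 0; p < npop; ++p) {
        size_t k = byPop[p].size();
        rate[p] = (k > 1) ? k * (k - 1) / 2.0 / (2.0 * pop_size(p, t)) : 0.0;
        R += rate[p];
      }
      if (R <= 0 && !R_FINITE(tNext))
        stop("coalescent cannot complete: isolated lineages remain");
      double dt = (R > 0) ? R::exp_rand() / R : R_PosInf;
      if (t + dt < tNext) {
        t += dt;
        double u = unif_rand() * R;
        int p = -1;
        double acc = 0.0;
        for (int q = 0; q < npop; ++q) {
          acc += rate[q];
          if (rate[q] > 0 && u <= acc) { p = q; break; }
        }
        if (p < 0)
          for (int q = npop - 1; q >= 0; --q) if (rate[q] > 0) { p = q; break; }
        std::vector<int> &pool = byPop[p];
        int j1 = (int) (unif_rand() * pool.size());
        int j2 = (int) (unif_rand() * (pool.size() - 1));
        if (j2 >= j1) ++j2;
        int a = pool[j1], b = pool[j2];
        end_branch(lin[a], t);
        end_branch(lin[b], t);
        if (lin[b].samples.size() > lin[a].samples.size()) {
          std::swap(lin[a], lin[b]);        // merge small into large
        }
        lin[a].samples.insert(lin[a].samples.end(), lin[b].samples.begin(),
                              lin[b].samples.end());
        lin[a].birth = t;
        lin[b].samples.clear();
        pool[j2] = pool.back();
        pool.pop_back();
        if (j1 == (int) pool.size()) pool[j2] = a;  // a sat in the popped slot
        --active;
      } else {
        t = tNext; ++nb;
        for (int r = 0; r < moves.nrow(); ++r) {
          if (std::abs(moves(r, 0) - t) > 1e-9) continue;
          int target = (int) moves(r, 1) - 1;
          int srcA = (int) moves(r, 2) - 1;
          int srcB = (int) moves(r, 3) - 1;  // -1 encodes a plain split
          double rA = moves(r, 4);
          for (size_t i = 0; i < byPop[target].size(); ++i) {
            int dest = (srcB < 0 || unif_rand() < rA) ? srcA : srcB;
            byPop[dest].push_back(byPop[target][i]);
          }
          byPop[target].clear();
        }
      }
    }
    for (int i = 0; i < total; ++i) out(i, l) += ancestralState;
  }
  return out;
}
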