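// Event-driven single-site coalescent under a multi-population demography:
// constant diploid Ne per population branch, dated sampling, backward pulse
// reassignment, forced mergers at splits. One independent genealogy per
// unlinked site; mutations by branch-length-weighted placement.
#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

namespace {

// xoshiro256++ with splitmix64 seeding: cheap to reseed, which matters
// because every genealogy gets its own stream (common random numbers
// across parameter values of a profile).
struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  void seed(uint64_t v) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(v);
  }
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double expdraw(double rate) { return -std::log(unif()) / rate; }
};

struct Lineage {
  int pop;
  int cfg;           // flattened joint-SFS cell index of the descendant set
  double t_in;       // time (generations ago) the branch segment started
  uint64_t mask;     // descendant leaves as a bitmask (<= 64 leaves)
};

struct Branch {
  double len;
  int cfg;
  uint64_t mask;
};

// Event encoding (pre-sorted by caller: time ascending; at equal times
// samples, then pulses, then splits):
//   type 0 sample: a = pop, b = n leaves, frac = stride of this sample axis
//   type 1 pulse:  a = dest, b = source, frac = alpha (backward move prob)
//   type 2 split:  a = child, b = parent
class SiteCoalescent {
public:
  int n_pops;
  const double *ne;
  int n_ev;
  const int *ev_type, *ev_a, *ev_b;
  const double *ev_time, *ev_frac;
  Xoshiro rng;
  std::vector<Lineage> lin;
  std::vector<Branch> branches;
  std::vector<double> rate;
  std::vector<int> count;
  std::vector<int> idx;

  SiteCoalescent(int n_pops_, const double *ne_, int n_ev_, const int *t_,
                 const double *tm_, const int *a_, const int *b_,
                 const double *f_, uint64_t seed)
      : n_pops(n_pops_), ne(ne_), n_ev(n_ev_), ev_type(t_), ev_a(a_),
        ev_b(b_), ev_time(tm_), ev_frac(f_),
        rate(n_pops_), count(n_pops_) {
    rng.seed(seed);
  }

  double runif01() { return rng.unif(); }

  // One independent, reproducible stream per genealogy: replicate r of a
  // run is coupled across parameter values (common random numbers), so
  // profile likelihoods are smooth in the parameter.
  void reseed(uint64_t base, uint64_t rep) {
    rng.seed(base * 0x2545F4914F6CDD1DULL + rep + 1);
  }

  // Simulate one genealogy; fills `branches` (every branch below the MRCA).
  void simulate() {
    lin.clear();
    branches.clear();
    double t = 0.0;
    int e = 0;
    int next_leaf = 0;
    for (;;) {
      // per-population pair-coalescence rates
      std::fill(count.begin(), count.end(), 0);
      for (const Lineage &l : lin) count[l.pop]++;
      double total_rate = 0.0;
      for (int p = 0; p < n_pops; ++p) {
        rate[p] = count[p] >= 2
                      ? (count[p] * (count[p] - 1) / 2.0) / (2.0 * ne[p])
                      : 0.0;
        total_rate += rate[p];
      }
      double t_ev = (e < n_ev) ? ev_time[e] : R_PosInf;
      if (total_rate > 0.0) {
        double dt = rng.expdraw(total_rate);
        if (t + dt < t_ev) {
          t += dt;
          coalesce_one(rate, total_rate, t);
          continue;
        }
      }
      if (e >= n_ev) {
        if ((int)lin.size() <= 1) break;
        Rcpp::stop("lineages cannot coalesce: disconnected demography");
      }
      // advance to the next event time, apply every event scheduled there
      t = t_ev;
      while (e < n_ev && ev_time[e] == t_ev) {
        apply_event(e, next_leaf);
        ++e;
      }
    }
  }

private:
  void coalesce_one(const std::vector<double> &rate, double total, double t) {
    double u = runif01() * total;
    int p = 0;
    for (; p < n_pops - 1; ++p) {
      if (u < rate[p]) break;
      u -= rate[p];
    }
    // collect indices of lineages in pop p
    idx.clear();
    for (int i = 0; i < (int)lin.size(); ++i)
      if (lin[i].pop == p) idx.push_back(i);
    int k = (int)idx.size();
    int i1 = (int)(runif01() * k);
    if (i1 >= k) i1 = k - 1;
    int i2 = (int)(runif01() * (k - 1));
    if (i2 >= k - 1) i2 = k - 2;
    if (i2 >= i1) ++i2;
    int a = idx[i1], b = idx[i2];
    branches.push_back({t - lin[a].t_in, lin[a].cfg, lin[a].mask});
    branches.push_back({t - lin[b].t_in, lin[b].cfg, lin[b].mask});
    Lineage parent{p, lin[a].cfg + lin[b].cfg, t, lin[a].mask | lin[b].mask};
    // O(1) removal: overwrite with the parent, back-fill the second slot
    lin[a] = parent;
    lin[b] = lin.back();
    if (&lin[b] != &lin.back()) lin.pop_back();
    else lin.pop_back();
  }

  void apply_event(int e, int &next_leaf) {
    int type = ev_type[e];
    if (type == 0) { // sample: b leaves in pop a, SFS stride ev_frac[e]
      int stride = (int)ev_frac[e];
      for (int i = 0; i < ev_b[e]; ++i) {
        lin.push_back(
            {ev_a[e], stride, ev_time[e], (uint64_t)1 << next_leaf});
        ++next_leaf;
      }
    } else if (type == 1) { // pulse dest -> source with prob alpha
      for (Lineage &l : lin)
        if (l.pop == ev_a[e] && runif01() < ev_frac[e]) l.pop = ev_b[e];
    } else { // split: child merges into parent
      for (Lineage &l : lin)
        if (l.pop == ev_a[e]) l.pop = ev_b[e];
    }
  }
};

} // namespace

// Accumulated branch length per joint-SFS cell over n_reps independent
// genealogies; Monte-Carlo expected (unnormalized) SFS.
// [[Rcpp::export]]
NumericVector coal_expected_sfs_cpp(int n_pops, NumericVector ne,
                                    IntegerVector ev_type,
                                    NumericVector ev_time, IntegerVector ev_a,
                                    IntegerVector ev_b, NumericVector ev_frac,
                                    int n_cells, int n_reps, double seed) {
  SiteCoalescent sim(n_pops, ne.begin(), ev_type.size(), ev_type.begin(),
                     ev_time.begin(), ev_a.begin(), ev_b.begin(),
                     ev_frac.begin(), (uint64_t)seed);
  NumericVector sfs(n_cells);
  for (int r = 0; r < n_reps; ++r) {
    sim.reseed((uint64_t)seed, (uint64_t)r);
    sim.simulate();
    for (const Branch &br : sim.branches) sfs[br.cfg] += br.len;
    if ((r & 0x3ff) == 0) Rcpp::checkUserInterrupt();
  }
  return sfs;
}

// n_sites unlinked segregating sites under infinite sites: mutations are
// rare and uniform on the genome, so a segregating site falls on a branch
// with probability proportional to branch length pooled across independent
// genealogies (a genealogy with more total length hosts more segregating
// sites). Simulates n_sites genealogies, pools every branch, then draws
// n_sites branches length-weighted with replacement. Returns the haploid
// 0/1 allele matrix (sites x leaves) and each site's joint-SFS cell index.
// [[Rcpp::export]]
List coal_sites_cpp(int n_pops, NumericVector ne, IntegerVector ev_type,
                    NumericVector ev_time, IntegerVector ev_a,
                    IntegerVector ev_b, NumericVector ev_frac, int n_leaves,
                    int n_sites, double seed) {
  SiteCoalescent sim(n_pops, ne.begin(), ev_type.size(), ev_type.begin(),
                     ev_time.begin(), ev_a.begin(), ev_b.begin(),
                     ev_frac.begin(), (uint64_t)seed);
  std::vector<Branch> pool;
  std::vector<double> cum;
  pool.reserve((size_t)n_sites * 2 * n_leaves);
  double total = 0.0;
  for (int s = 0; s < n_sites; ++s) {
    sim.reseed((uint64_t)seed, (uint64_t)s);
    sim.simulate();
    for (const Branch &br : sim.branches) {
      total += br.len;
      pool.push_back(br);
      cum.push_back(total);
    }
    if ((s & 0xff) == 0) Rcpp::checkUserInterrupt();
  }
  IntegerMatrix haps(n_sites, n_leaves);
  IntegerVector cfg(n_sites);
  sim.reseed((uint64_t)seed, (uint64_t)n_sites + 1);
  for (int s = 0; s < n_sites; ++s) {
    double u = sim.runif01() * total;
    size_t lo = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
    if (lo >= pool.size()) lo = pool.size() - 1;
    const Branch &hit = pool[lo];
    for (int j = 0; j < n_leaves; ++j)
      haps(s, j) = (int)((hit.mask >> j) & 1);
    cfg[s] = hit.cfg;
  }
  return List::create(_["haps"] = haps, _["cfg"] = cfg);
}
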