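#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Structured-coalescent genealogy engine shared by the genotype simulator
// and the Monte-Carlo expected-SFS approximation.  Time runs backward in
// generations; splits pool the derived deme's lineages into the ancestral
// deme; partial selfing is the equilibrium identity-by-descent shortcut
// (an individual's two haploid lineages coalesce at sampling with
// probability F = s / (2 - s)).  All randomness comes from R's RNG so a
// set.seed() call on the R side makes every run bit-reproducible.

namespace {

struct Split {
  double time;
  int derived;
  int anc;
};

struct Lineage {
  uint64_t mask;  // haploid leaves below this branch (<= 64 leaves)
  int pop;
  double birth;
};

struct Demography {
  int n_pops;
  std::vector<double> N;        // diploid effective sizes
  std::vector<double> selfing;  // selfing rate per population
  std::vector<int> n_dip;       // diploid samples per population
  std::vector<Split> splits;    // ascending time order
  std::vector<double> mig;      // row-major [from * n_pops + to], backward
};

Demography unpack(const List& dem) {
  Demography M;
  NumericVector N = dem["N"];
  NumericVector s = dem["selfing"];
  IntegerVector nd = dem["n_dip"];
  NumericVector st = dem["split_time"];
  IntegerVector sd = dem["split_derived"];
  IntegerVector sa = dem["split_anc"];
  NumericMatrix mig = dem["mig"];
  M.n_pops = N.size();
  M.N.assign(N.begin(), N.end());
  M.selfing.assign(s.begin(), s.end());
  M.n_dip.assign(nd.begin(), nd.end());
  for (int i = 0; i < st.size(); ++i)
    M.splits.push_back({st[i], sd[i], sa[i]});
  M.mig.resize(M.n_pops * M.n_pops, 0.0);
  for (int i = 0; i < M.n_pops; ++i)
    for (int j = 0; j < M.n_pops; ++j) M.mig[i * M.n_pops + j] = mig(i, j);
  int tot = 0;
  for (int p = 0; p < M.n_pops; ++p) tot += 2 * M.n_dip[p];
  if (tot > 64) stop("at most 64 haploid samples are supported");
  if (tot < 2) stop("at least one diploid sample is required");
  return M;
}

// Simulate one genealogy, calling record(mask, branch_length) for every
// non-root branch.
template <typename F>
void genealogy(const Demography& M, F&& record) {
  std::vector<Lineage> lin;
  lin.reserve(64);
  int leaf = 0;
  for (int p = 0; p < M.n_pops; ++p) {
    double Fibd = M.selfing[p] / (2.0 - M.selfing[p]);
    for (int i = 0; i < M.n_dip[p]; ++i) {
      uint64_t a = 1ULL << leaf, b = 1ULL << (leaf + 1);
      if (unif_rand() < Fibd)
        lin.push_back({a | b, p, 0.0});
      else {
        lin.push_back({a, p, 0.0});
        lin.push_back({b, p, 0.0});
      }
      leaf += 2;
    }
  }
  std::vector<bool> active(M.n_pops, true);
  std::vector<int> k(M.n_pops);
  std::vector<double> coal(M.n_pops), mig_out(M.n_pops);
  double t = 0.0;
  size_t si = 0;
  long guard = 0;
  while (lin.size() > 1) {
    if (++guard > 100000000L) stop("genealogy simulation did not terminate");
    std::fill(k.begin(), k.end(), 0);
    for (const auto& l : lin) k[l.pop]++;
    double coal_tot = 0.0, mig_tot = 0.0;
    for (int p = 0; p < M.n_pops; ++p) {
      coal[p] = k[p] > 1 ? k[p] * (k[p] - 1) / 2.0 / (2.0 * M.N[p]) : 0.0;
      coal_tot += coal[p];
      double r = 0.0;
      if (k[p] > 0)
        for (int q = 0; q < M.n_pops; ++q)
          if (q != p && active[q]) r += M.mig[p * M.n_pops + q];
      mig_out[p] = r;
      mig_tot += k[p] * r;
    }
    double tot = coal_tot + mig_tot;
    double next_split = si < M.splits.size() ? M.splits[si].time : R_PosInf;
    double dt = tot > 0.0 ? exp_rand() / tot : R_PosInf;
    if (t + dt >= next_split) {
      if (!R_FINITE(next_split))
        stop("lineages can never coalesce under this model");
      t = next_split;
      const Split& s = M.splits[si];
      for (auto& l : lin)
        if (l.pop == s.derived) l.pop = s.anc;
      active[s.derived] = false;
      ++si;
      continue;
    }
    t += dt;
    double u = unif_rand() * tot;
    if (u < coal_tot) {
      int p = 0;
      double acc = 0.0;
      for (; p < M.n_pops - 1; ++p) {
        acc += coal[p];
        if (u < acc) break;
      }
      // pick two distinct lineages within pop p
      int i1 = -1, i2 = -1;
      int pick1 = (int)(unif_rand() * k[p]);
      int pick2 = (int)(unif_rand() * (k[p] - 1));
      if (pick2 >= pick1) pick2++;
      int seen = 0;
      for (size_t i = 0; i < lin.size(); ++i) {
        if (lin[i].pop != p) continue;
        if (seen == pick1) i1 = (int)i;
        if (seen == pick2) i2 = (int)i;
        ++seen;
      }
      record(lin[i1].mask, t - lin[i1].birth);
      record(lin[i2].mask, t - lin[i2].birth);
      lin[i1].mask |= lin[i2].mask;
      lin[i1].birth = t;
      lin.erase(lin.begin() + i2);
    } else {
      double v = u - coal_tot;
      int idx = -1;
      double acc = 0.0;
      for (size_t i = 0; i < lin.size(); ++i) {
        acc += mig_out[lin[i].pop];
        if (v < acc) {
          idx = (int)i;
          break;
        }
      }
      if (idx < 0) idx = (int)lin.size() - 1;
      int p = lin[idx].pop;
      double w = unif_rand() * mig_out[p];
      double a2 = 0.0;
      int dest = -1;
      for (int q = 0; q < M.n_pops; ++q) {
        if (q == p || !active[q]) continue;
        a2 += M.mig[p * M.n_pops + q];
        if (w < a2) {
          dest = q;
          break;
        }
      }
      if (dest >= 0) lin[idx].pop = dest;
    }
  }
}

}  // namespace

// Monte-Carlo branch-length weights over joint-SFS cells.  leaf_group maps
// each haploid leaf to a 0-based group (super-population); the returned
// vector has length prod(group_sizes + 1) in column-major cell order and
// holds the accumulated branch length subtending each derived-count tuple.
// [[Rcpp::export(name = ".sim_sfs_weights")]]
NumericVector sim_sfs_weights(List dem, IntegerVector leaf_group,
                              IntegerVector group_sizes, int n_sims) {
  Demography M = unpack(dem);
  int n_groups = group_sizes.size();
  int n_leaves = leaf_group.size();
  std::vector<int> stride(n_groups, 1);
  long n_cells = 1;
  for (int g = 0; g < n_groups; ++g) {
    stride[g] = (int)n_cells;
    n_cells *= group_sizes[g] + 1;
  }
  NumericVector W(n_cells, 0.0);
  std::vector<int> cnt(n_groups);
  for (int s = 0; s < n_sims; ++s) {
    genealogy(M, [&](uint64_t mask, double len) {
      if (len <= 0.0) return;
      std::fill(cnt.begin(), cnt.end(), 0);
      for (int i = 0; i < n_leaves; ++i)
        if (mask >> i & 1ULL) cnt[leaf_group[i]]++;
      long idx = 0;
      for (int g = 0; g < n_groups; ++g) idx += (long)cnt[g] * stride[g];
      W[idx] += len;
    });
  }
  return W;
}

// Simulate independent non-recombining loci and place infinite-sites
// mutations as Poisson(mu * L * branch length).  Returns one integer
// genotype matrix (mutations x diploid individuals, values 0/1/2) per
// locus; positions are assigned on the R side.
// [[Rcpp::export(name = ".sim_genotype_loci")]]
List sim_genotype_loci(List dem, int n_loci, double mut_rate_per_locus) {
  Demography M = unpack(dem);
  int n_dip_tot = 0;
  for (int p = 0; p < M.n_pops; ++p) n_dip_tot += M.n_dip[p];
  List out(n_loci);
  std::vector<uint64_t> muts;
  for (int l = 0; l < n_loci; ++l) {
    muts.clear();
    genealogy(M, [&](uint64_t mask, double len) {
      if (len <= 0.0) return;
      int nm = (int)R::rpois(mut_rate_per_locus * len);
      for (int m = 0; m < nm; ++m) muts.push_back(mask);
    });
    IntegerMatrix G((int)muts.size(), n_dip_tot);
    for (size_t m = 0; m < muts.size(); ++m)
      for (int j = 0; j < n_dip_tot; ++j)
        G(m, j) = (int)(muts[m] >> (2 * j) & 1ULL) +
                  (int)(muts[m] >> (2 * j + 1) & 1ULL);
    out[l] = G;
  }
  return out;
}

// Stationary two-state Markov chain over {hom = 0, het = 1} with stationary
// het probability theta and lag-1 autocorrelation rho.
// [[Rcpp::export(name = ".sim_zygosity_chain")]]
IntegerVector sim_zygosity_chain(double theta, double rho, int len) {
  IntegerVector z(len);
  double p11 = theta + rho * (1.0 - theta);  // het -> het
  double p01 = theta * (1.0 - rho);          // hom -> het
  z[0] = unif_rand() < theta ? 1 : 0;
  for (int i = 1; i < len; ++i)
    z[i] = unif_rand() < (z[i - 1] ? p11 : p01) ? 1 : 0;
  return z;
}

// Pooled pair statistics for the correlation of zygosity.  For each
// distance bin [lo, hi) accumulates, over ordered within-region site pairs
// (i, j) with pos[j] - pos[i] in the bin: pair count, sum of z_i, sum of
// z_j, sum of z_i * z_j, and sum of pair distances.  positions must be
// sorted within region; z is the 0/1 heterozygosity indicator.
// [[Rcpp::export(name = ".zygosity_pair_stats")]]
List zygosity_pair_stats(NumericVector pos, IntegerVector z,
                         IntegerVector region, NumericVector lo,
                         NumericVector hi) {
  int n = pos.size(), nb = lo.size();
  NumericVector npairs(nb), Sx(nb), Sy(nb), Sxy(nb), Sd(nb);
  for (int b = 0; b < nb; ++b) {
    // sliding window [jl, jr) of partners j > i with
    // pos[i] + lo <= pos[j] < pos[i] + hi; both ends move monotonically
    // forward as i advances, so maintenance is O(n) amortized per bin.
    int jl = 1, jr = 1;
    double wy = 0.0, wpos = 0.0, wn = 0.0;
    for (int i = 0; i < n; ++i) {
      if (i > 0 && region[i] != region[i - 1]) {
        jl = jr = i + 1;
        wy = wpos = wn = 0.0;
      }
      // drop window members now invalid (index <= i or below lower bound);
      // everything inside [jl, jr) was added, so always subtract
      while (jl < jr && (jl <= i || pos[jl] < pos[i] + lo[b])) {
        wy -= z[jl];
        wpos -= pos[jl];
        wn -= 1.0;
        ++jl;
      }
      if (jl == jr && jr < i + 1) jl = jr = i + 1;
      // extend to the right while inside the bin and region
      while (jr < n && region[jr] == region[i] && pos[jr] < pos[i] + hi[b]) {
        if (jr <= i || pos[jr] < pos[i] + lo[b]) {
          // element can never re-enter this window; skip it entirely
          if (jl == jr) jl = jr + 1;
          ++jr;
        } else {
          wy += z[jr];
          wpos += pos[jr];
          wn += 1.0;
          ++jr;
        }
      }
      if (wn > 0.0) {
        npairs[b] += wn;
        Sx[b] += z[i] * wn;
        Sy[b] += wy;
        Sxy[b] += z[i] * wy;
        Sd[b] += wpos - wn * pos[i];
      }
    }
  }
  return List::create(_["n"] = npairs, _["Sx"] = Sx, _["Sy"] = Sy,
                      _["Sxy"] = Sxy, _["Sd"] = Sd);
}
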