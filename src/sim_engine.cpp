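// Core Wright-Fisher machinery for TE copy-number evolution.
//
// A haplotype is a sorted vector of occupied insertion-site indices
// (0-based, in [0, T)).  A population of N diploids is a vector of 2N
// haplotypes; individual i owns haplotypes 2i and 2i+1.  All randomness
// comes from R's RNG (R::unif_rand etc.), so set.seed() on the R side
// makes every entry point reproducible.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

typedef std::vector<int> Hap;

// Recombination map in site-index space.  Arms are contiguous blocks of
// sites and independent linkage groups; windows subdivide arms and carry
// genetic length in Morgans.
struct CppMap {
  int T;
  std::vector<int> arm_start, arm_len;
  std::vector<double> arm_M;                       // Morgans per arm
  std::vector<int> win_start, win_len;             // windows, arm-sorted
  std::vector<double> win_M;                       // Morgans per window
  std::vector<int> arm_win_begin, arm_win_end;     // window slice per arm
};

CppMap build_map(const List& m) {
  CppMap mp;
  mp.T = as<int>(m["T"]);
  mp.arm_start = as<std::vector<int> >(m["arm_start"]);
  mp.arm_len = as<std::vector<int> >(m["arm_len"]);
  mp.arm_M = as<std::vector<double> >(m["arm_M"]);
  mp.win_start = as<std::vector<int> >(m["win_start"]);
  mp.win_len = as<std::vector<int> >(m["win_len"]);
  mp.win_M = as<std::vector<double> >(m["win_M"]);
  mp.arm_win_begin = as<std::vector<int> >(m["arm_win_begin"]);
  mp.arm_win_end = as<std::vector<int> >(m["arm_win_end"]);
  return mp;
}

inline double fitness_w(double g, double x, double t) {
  if (g <= 0.0) return 1.0;
  double w = 1.0 - x * std::pow(g, t);
  return w > 0.0 ? w : 0.0;
}

// One recombinant gamete from a parent's haplotype pair.  Crossover count
// per arm is Poisson(arm genetic length); breakpoint positions have density
// proportional to per-window rate; phase alternates between breakpoints
// (no interference); arms assort freely.
void make_gamete(const Hap& hA, const Hap& hB, const CppMap& mp, Hap& out) {
  out.clear();
  std::vector<int> bps;
  const size_t n_arm = mp.arm_start.size();
  for (size_t a = 0; a < n_arm; ++a) {
    bps.clear();
    const double M = mp.arm_M[a];
    const int k = (M > 0.0) ? (int)R::rpois(M) : 0;
    for (int j = 0; j < k; ++j) {
      double u = R::unif_rand() * M;
      double acc = 0.0;
      int site = mp.arm_start[a];
      for (int wi = mp.arm_win_begin[a]; wi < mp.arm_win_end[a]; ++wi) {
        const bool last = (wi == mp.arm_win_end[a] - 1);
        if (u <= acc + mp.win_M[wi] || last) {
          double frac = (mp.win_M[wi] > 0.0) ? (u - acc) / mp.win_M[wi] : 0.0;
          if (frac < 0.0) frac = 0.0;
          if (frac > 1.0) frac = 1.0;
          site = mp.win_start[wi] + (int)(frac * mp.win_len[wi]);
          if (site >= mp.win_start[wi] + mp.win_len[wi])
            site = mp.win_start[wi] + mp.win_len[wi] - 1;
          break;
        }
        acc += mp.win_M[wi];
      }
      bps.push_back(site);
    }
    std::sort(bps.begin(), bps.end());
    bool useA = (R::unif_rand() < 0.5);
    int lo = mp.arm_start[a];
    const int arm_end = lo + mp.arm_len[a];
    size_t bi = 0;
    while (lo < arm_end) {
      int hi = (bi < bps.size()) ? bps[bi] : arm_end;
      if (hi > arm_end) hi = arm_end;
      if (hi > lo) {
        const Hap& src = useA ? hA : hB;
        Hap::const_iterator it1 =
            std::lower_bound(src.begin(), src.end(), lo);
        Hap::const_iterator it2 = std::lower_bound(it1, src.end(), hi);
        out.insert(out.end(), it1, it2);
      }
      lo = hi;
      useA = !useA;
      ++bi;
    }
  }
}

// Transposition: Binomial(g, v) attempted insertions from the diploid copy
// count g; each lands uniformly on one of T sites of a uniformly chosen
// haplotype; attempts hitting an occupied site of that haplotype are
// discarded.  No excision (u = 0).
void transpose_pair(Hap& h1, Hap& h2, double v, int T) {
  const int g = (int)(h1.size() + h2.size());
  if (g == 0 || v <= 0.0) return;
  const int n = (int)R::rbinom((double)g, v);
  for (int j = 0; j < n; ++j) {
    int site = (int)(R::unif_rand() * T);
    if (site >= T) site = T - 1;
    Hap& h = (R::unif_rand() < 0.5) ? h1 : h2;
    Hap::iterator it = std::lower_bound(h.begin(), h.end(), site);
    if (it == h.end() || *it != site) h.insert(it, site);
  }
}

inline int pick_parent(const std::vector<double>& cum, double tot) {
  double u = R::unif_rand() * tot;
  return (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
}

// One non-overlapping generation: N offspring, parents drawn with
// probability proportional to stored fitness (selfing excluded by
// redrawing the second parent), one gamete per parent, offspring fitness
// evaluated pre-transposition and stored for the next round of mating,
// then transposition applied.  Returns false on the all-zero-fitness /
// single-survivor extinction condition.
bool step_pop(const std::vector<Hap>& pop, const std::vector<double>& w,
              const CppMap& mp, double v, double x, double t,
              std::vector<Hap>& newpop, std::vector<double>& neww) {
  const int N = (int)w.size();
  std::vector<double> cum(N);
  double tot = 0.0;
  int npos = 0;
  for (int i = 0; i < N; ++i) {
    tot += w[i];
    if (w[i] > 0.0) ++npos;
    cum[i] = tot;
  }
  if (npos < 2) return false;
  newpop.resize(2 * (size_t)N);
  neww.resize(N);
  for (int i = 0; i < N; ++i) {
    const int p1 = pick_parent(cum, tot);
    int p2;
    do {
      p2 = pick_parent(cum, tot);
    } while (p2 == p1);
    Hap& c1 = newpop[2 * (size_t)i];
    Hap& c2 = newpop[2 * (size_t)i + 1];
    make_gamete(pop[2 * (size_t)p1], pop[2 * (size_t)p1 + 1], mp, c1);
    make_gamete(pop[2 * (size_t)p2], pop[2 * (size_t)p2 + 1], mp, c2);
    neww[i] = fitness_w((double)(c1.size() + c2.size()), x, t);
    transpose_pair(c1, c2, v, mp.T);
  }
  return true;
}

void init_population(std::vector<Hap>& pop, int N, int m0, int T) {
  pop.assign(2 * (size_t)N, Hap());
  const int m = std::min(m0, T);
  for (size_t h = 0; h < pop.size(); ++h) {
    Hap& hp = pop[h];
    while ((int)hp.size() < m) {
      int site = (int)(R::unif_rand() * T);
      if (site >= T) site = T - 1;
      Hap::iterator it = std::lower_bound(hp.begin(), hp.end(), site);
      if (it == hp.end() || *it != site) hp.insert(it, site);
    }
  }
}

std::vector<Hap> list_to_pop(const List& haps) {
  std::vector<Hap> pop(haps.size());
  for (R_xlen_t i = 0; i < haps.size(); ++i)
    pop[i] = as<Hap>(haps[i]);
  return pop;
}

List pop_to_list(const std::vector<Hap>& pop) {
  List out(pop.size());
  for (size_t i = 0; i < pop.size(); ++i)
    out[i] = IntegerVector(pop[i].begin(), pop[i].end());
  return out;
}

}  // namespace

// [[Rcpp::export]]
IntegerVector cpp_make_gamete(IntegerVector hapA, IntegerVector hapB,
                              List map) {
  CppMap mp = build_map(map);
  Hap hA = as<Hap>(hapA), hB = as<Hap>(hapB), out;
  make_gamete(hA, hB, mp, out);
  return IntegerVector(out.begin(), out.end());
}

// [[Rcpp::export]]
List cpp_transpose(IntegerVector h1, IntegerVector h2, double v, int T) {
  Hap a = as<Hap>(h1), b = as<Hap>(h2);
  transpose_pair(a, b, v, T);
  return List::create(_["h1"] = IntegerVector(a.begin(), a.end()),
                      _["h2"] = IntegerVector(b.begin(), b.end()));
}

// [[Rcpp::export]]
List cpp_step_generation(List haps, NumericVector w, List map, double v,
                         double x, double t) {
  CppMap mp = build_map(map);
  std::vector<Hap> pop = list_to_pop(haps), newpop;
  std::vector<double> wv = as<std::vector<double> >(w), neww;
  bool ok = step_pop(pop, wv, mp, v, x, t, newpop, neww);
  if (!ok)
    return List::create(_["extinct"] = true);
  return List::create(_["extinct"] = false,
                      _["haplotypes"] = pop_to_list(newpop),
                      _["fitness"] = NumericVector(neww.begin(), neww.end()));
}

// [[Rcpp::export]]
List cpp_run_simulation(List map, int N, double v, double x, double t,
                        int generations, int m0, bool track_sites) {
  CppMap mp = build_map(map);
  std::vector<Hap> pop, tmp;
  std::vector<double> w(N), neww;
  init_population(pop, N, m0, mp.T);
  for (int i = 0; i < N; ++i)
    w[i] = fitness_w((double)(pop[2 * (size_t)i].size() +
                              pop[2 * (size_t)i + 1].size()),
                     x, t);

  NumericVector mean_copy(generations + 1, NA_REAL);
  IntegerVector n_fixed(generations + 1, NA_INTEGER);
  IntegerVector n_seg(generations + 1, NA_INTEGER);

  std::vector<int> stamp, cnt, distinct;
  if (track_sites) {
    stamp.assign(mp.T, -1);
    cnt.assign(mp.T, 0);
  }

  bool extinct = false;
  int extinct_gen = -1;
  const int two_n = 2 * N;

  for (int gen = 0; gen <= generations; ++gen) {
    double total = 0.0;
    for (size_t h = 0; h < pop.size(); ++h) total += (double)pop[h].size();
    mean_copy[gen] = total / N;
    if (track_sites) {
      distinct.clear();
      for (size_t h = 0; h < pop.size(); ++h) {
        const Hap& hp = pop[h];
        for (size_t j = 0; j < hp.size(); ++j) {
          const int s = hp[j];
          if (stamp[s] != gen) {
            stamp[s] = gen;
            cnt[s] = 0;
            distinct.push_back(s);
          }
          ++cnt[s];
        }
      }
      int nf = 0;
      for (size_t j = 0; j < distinct.size(); ++j)
        if (cnt[distinct[j]] == two_n) ++nf;
      n_fixed[gen] = nf;
      n_seg[gen] = (int)distinct.size() - nf;
    }
    if (gen == generations) break;
    if (!step_pop(pop, w, mp, v, x, t, tmp, neww)) {
      extinct = true;
      extinct_gen = gen + 1;
      break;
    }
    pop.swap(tmp);
    w.swap(neww);
    if ((gen + 1) % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  // flatten the final population
  size_t total_sites = 0;
  for (size_t h = 0; h < pop.size(); ++h) total_sites += pop[h].size();
  IntegerVector hap_len(pop.size());
  IntegerVector hap_sites(total_sites);
  size_t pos = 0;
  for (size_t h = 0; h < pop.size(); ++h) {
    hap_len[h] = (int)pop[h].size();
    for (size_t j = 0; j < pop[h].size(); ++j) hap_sites[pos++] = pop[h][j];
  }

  return List::create(
      _["mean_copy"] = mean_copy, _["n_fixed"] = n_fixed, _["n_seg"] = n_seg,
      _["extinct"] = extinct, _["extinct_generation"] = extinct_gen,
      _["hap_sites"] = hap_sites, _["hap_len"] = hap_len);
}
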