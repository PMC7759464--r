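// Forward-in-time Wright-Fisher engine with recombination and
// infinite-sites mutation on a continuous locus [0, 1).
//
// Demography: a source population at mutation-drift equilibrium (burn-in),
// a founder event (colonization) t_col generations before sampling, a
// sustained colony bottleneck, a split into two daughter populations
// t_split generations before sampling, and symmetric migration between
// the daughters until the present.
//
// Selection: genic, per-copy coefficient s (haplotype fitness 1 + s),
// restricted to the population(s) in which the allele is beneficial
// (shared sweeps: everywhere; divergent sweeps: one daughter only).
// Conditioning: the post-colonization segment is re-run from a snapshot
// until every selected allele reaches frequency >= f_end in its target
// population(s) at sampling time.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

typedef std::vector<int> Hap;  // mutation ids, sorted by position

struct Sel {
  int id;        // registry id once injected, -1 before
  double pos;    // position in [0, 1)
  double s;      // per-copy selection coefficient
  int copies;    // initial copies at onset
  int onset;     // 0 = colonization, 1 = split
  int daughter;  // 0 = beneficial everywhere, 1 or 2 = that daughter only
};

struct Pop {
  std::vector<Hap> h;
  std::vector<double> w;  // cached fitness weights
  double wmax = 1.0;
};

struct Engine {
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> runif{0.0, 1.0};
  std::vector<double> mpos;  // position per mutation id
  double u, r;               // per-locus per-generation rates
  std::vector<Sel> sels;
  std::vector<Pop> buf;      // reusable next-generation buffer

  explicit Engine(double u_, double r_, std::uint64_t seed)
      : rng(seed), u(u_), r(r_) {}

  bool carries(const Hap& h, int id) const {
    double p = mpos[id];
    const std::vector<double>& mp = mpos;
    auto it = std::lower_bound(h.begin(), h.end(), p,
                               [&mp](int a, double v) { return mp[a] < v; });
    for (; it != h.end() && mpos[*it] == p; ++it)
      if (*it == id) return true;
    return false;
  }

  // fitness of a haplotype living in population `popcode`
  // popcode: 0 = source/colony, 1 = daughter A, 2 = daughter B
  double fitness(const Hap& h, int popcode) const {
    double w = 1.0;
    for (const Sel& s : sels) {
      if (s.id < 0) continue;
      bool applies = (s.daughter == 0) || (popcode > 0 && s.daughter == popcode);
      if (applies && carries(h, s.id)) w *= (1.0 + s.s);
    }
    return w;
  }

  bool any_selection_active() const {
    for (const Sel& s : sels)
      if (s.id >= 0) return true;
    return false;
  }

  void refresh_weights(Pop& p, int popcode) {
    size_t n = p.h.size();
    p.w.assign(n, 1.0);
    p.wmax = 1.0;
    if (!any_selection_active()) return;
    for (size_t i = 0; i < n; ++i) {
      p.w[i] = fitness(p.h[i], popcode);
      if (p.w[i] > p.wmax) p.wmax = p.w[i];
    }
  }

  int pick_parent(const Pop& p) {
    std::uniform_int_distribution<int> d(0, (int)p.h.size() - 1);
    if (p.wmax <= 1.0) return d(rng);
    for (;;) {
      int i = d(rng);
      if (runif(rng) * p.wmax <= p.w[i]) return i;
    }
  }

  void recombine(const Hap& h1, const Hap& h2,
                 const std::vector<double>& bps, Hap& out) {
    out.clear();
    size_t i1 = 0, i2 = 0;
    bool use1 = true;
    for (double b : bps) {  // last element is a sentinel > 1
      if (use1) {
        while (i1 < h1.size() && mpos[h1[i1]] < b) out.push_back(h1[i1++]);
        while (i2 < h2.size() && mpos[h2[i2]] < b) ++i2;
      } else {
        while (i2 < h2.size() && mpos[h2[i2]] < b) out.push_back(h2[i2++]);
        while (i1 < h1.size() && mpos[h1[i1]] < b) ++i1;
      }
      use1 = !use1;
    }
  }

  void mutate(Hap& h) {
    std::poisson_distribution<int> pk(u);
    int k = pk(rng);
    const std::vector<double>& mp = mpos;
    for (int j = 0; j < k; ++j) {
      double p = runif(rng);
      int id = (int)mpos.size();
      mpos.push_back(p);
      auto it = std::lower_bound(h.begin(), h.end(), p,
                                 [&mp](int a, double v) { return mp[a] < v; });
      h.insert(it, id);
    }
  }

  // one generation: fill `child` populations from `par` pools
  // par.size() == sizes.size(); migration only meaningful for two pops
  void step(std::vector<Pop>& pops, const std::vector<int>& sizes,
            const std::vector<int>& popcodes, double mig) {
    std::poisson_distribution<int> pr(r);
    size_t np = sizes.size();
    if (buf.size() != np) buf.assign(np, Pop());
    std::vector<Pop>& next = buf;
    std::vector<double> bps;
    for (size_t p = 0; p < np; ++p) {
      next[p].h.resize(sizes[p]);
      for (int i = 0; i < sizes[p]; ++i) {
        size_t q = p;
        if (np == 2 && mig > 0 && runif(rng) < mig) q = 1 - p;
        const Pop& pool = pops[q];
        int i1 = pick_parent(pool);
        int k = pr(rng);
        Hap& child = next[p].h[i];
        if (k == 0) {
          child = pool.h[i1];
        } else {
          int i2 = pick_parent(pool);
          bps.clear();
          for (int j = 0; j < k; ++j) bps.push_back(runif(rng));
          std::sort(bps.begin(), bps.end());
          bps.push_back(2.0);
          recombine(pool.h[i1], pool.h[i2], bps, child);
        }
        mutate(child);
      }
    }
    pops.swap(next);
    for (size_t p = 0; p < np; ++p) refresh_weights(pops[p], popcodes[p]);
  }

  // split reproduction: two children sets drawn from one parent pool
  void split_step(Pop& colony, std::vector<Pop>& daughters, int n_a,
                  int n_b) {
    std::poisson_distribution<int> pr(r);
    daughters.assign(2, Pop());
    daughters[0].h.resize(n_a);
    daughters[1].h.resize(n_b);
    std::vector<double> bps;
    for (int p = 0; p < 2; ++p) {
      int n = p == 0 ? n_a : n_b;
      for (int i = 0; i < n; ++i) {
        int i1 = pick_parent(colony);
        int k = pr(rng);
        Hap& child = daughters[p].h[i];
        if (k == 0) {
          child = colony.h[i1];
        } else {
          int i2 = pick_parent(colony);
          bps.clear();
          for (int j = 0; j < k; ++j) bps.push_back(runif(rng));
          std::sort(bps.begin(), bps.end());
          bps.push_back(2.0);
          recombine(colony.h[i1], colony.h[i2], bps, child);
        }
        mutate(child);
      }
    }
    refresh_weights(daughters[0], 1);
    refresh_weights(daughters[1], 2);
  }

  void inject(Pop& pop, Sel& sel, int popcode) {
    int n = (int)pop.h.size();
    int copies = std::min(sel.copies, n);
    sel.id = (int)mpos.size();
    mpos.push_back(sel.pos);
    // choose `copies` distinct haplotypes
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int j = 0; j < copies; ++j) {
      std::uniform_int_distribution<int> d(j, n - 1);
      std::swap(idx[j], idx[d(rng)]);
      Hap& h = pop.h[idx[j]];
      const std::vector<double>& mp = mpos;
      auto it = std::lower_bound(h.begin(), h.end(), sel.pos,
                                 [&mp](int a, double v) { return mp[a] < v; });
      h.insert(it, sel.id);
    }
    refresh_weights(pop, popcode);
  }

  // total copies of a selected allele across all populations
  int copies_total(const std::vector<Pop>& pops, int id) const {
    int c = 0;
    for (const Pop& p : pops)
      for (const Hap& h : p.h)
        if (carries(h, id)) ++c;
    return c;
  }

  bool any_sel_lost(const std::vector<Pop>& pops) const {
    for (const Sel& s : sels)
      if (s.id >= 0 && copies_total(pops, s.id) == 0) return true;
    return false;
  }

  double freq_in(const Pop& p, int id) const {
    if (p.h.empty()) return 0.0;
    int c = 0;
    for (const Hap& h : p.h)
      if (carries(h, id)) ++c;
    return (double)c / (double)p.h.size();
  }

  // remove mutations fixed in every current haplotype (selected ids kept)
  void cleanup(std::vector<Pop>& pops) {
    size_t total = 0;
    for (const Pop& p : pops) total += p.h.size();
    if (total == 0) return;
    std::vector<int> cnt(mpos.size(), 0);
    for (const Pop& p : pops)
      for (const Hap& h : p.h)
        for (int id : h) ++cnt[id];
    std::vector<char> drop(mpos.size(), 0);
    bool any = false;
    for (size_t id = 0; id < cnt.size(); ++id) {
      if (cnt[id] == (int)total) {
        bool is_sel = false;
        for (const Sel& s : sels)
          if (s.id == (int)id) is_sel = true;
        if (!is_sel) { drop[id] = 1; any = true; }
      }
    }
    if (!any) return;
    for (Pop& p : pops)
      for (Hap& h : p.h)
        h.erase(std::remove_if(h.begin(), h.end(),
                               [&drop](int id) { return drop[id] != 0; }),
                h.end());
  }
};

// [[Rcpp::export]]
List sim_forward_cpp(double locus_bp, double u, double r, int n_src,
                     int n_founder, int n_a, int n_b, int t_col,
                     int t_split, double mig, int burnin,
                     NumericVector sel_pos, NumericVector sel_s,
                     IntegerVector sel_copies, IntegerVector sel_onset,
                     IntegerVector sel_daughter, double f_end,
                     int max_tries, int sample_a, int sample_b,
                     double seed) {
  Engine eng(u, r, (std::uint64_t)seed);
  for (int i = 0; i < sel_pos.size(); ++i) {
    Sel s;
    s.id = -1;
    s.pos = sel_pos[i];
    s.s = sel_s[i];
    s.copies = sel_copies[i];
    s.onset = sel_onset[i];
    s.daughter = sel_daughter[i];
    eng.sels.push_back(s);
  }
  bool two_pop = (n_b > 0 && t_col > 0);
  if (!two_pop && !eng.sels.empty())
    stop("selection requires the two-population colonization history");
  if (two_pop && t_split >= t_col)
    stop("split_time must be strictly smaller than colonization_time");

  // ---- burn-in: single source population -----------------------------
  std::vector<Pop> pops(1);
  pops[0].h.assign(n_src, Hap());
  pops[0].w.assign(n_src, 1.0);
  std::vector<int> size1{n_src}, code1{0};
  int cleanup_every = 64, since = 0;
  for (int g = 0; g < burnin; ++g) {
    eng.step(pops, size1, code1, 0.0);
    if (++since >= cleanup_every) { eng.cleanup(pops); since = 0; }
  }

  int tries = 0;
  if (!two_pop) {
    // constant-size single population: sample directly below
  } else {
    // ---- colonization ------------------------------------------------
    std::vector<int> sizef{n_founder};
    eng.step(pops, sizef, code1, 0.0);  // founder generation
    eng.cleanup(pops);

    // snapshot for conditioning
    bool need_cond = !eng.sels.empty();
    std::vector<Pop> snap;
    size_t snap_nmut = 0;
    if (need_cond) {
      snap = pops;
      snap_nmut = eng.mpos.size();
    }

    bool success = false;
    for (tries = 1; tries <= std::max(max_tries, 1); ++tries) {
      if (need_cond && tries > 1) {
        pops = snap;
        eng.mpos.resize(snap_nmut);
        for (Sel& s : eng.sels) s.id = -1;
      }
      for (Sel& s : eng.sels)
        if (s.onset == 0) eng.inject(pops[0], s, 0);
      // colony period (colonization generation already consumed)
      since = 0;
      bool lost = false;
      for (int g = 0; g < t_col - t_split - 1; ++g) {
        eng.step(pops, sizef, code1, 0.0);
        if (++since >= cleanup_every) { eng.cleanup(pops); since = 0; }
        if (need_cond && (g & 15) == 15 && eng.any_sel_lost(pops)) {
          lost = true;
          break;
        }
      }
      if (lost) continue;  // fail fast: retry from the snapshot
      // split
      std::vector<Pop> daughters;
      eng.split_step(pops[0], daughters, n_a, n_b);
      pops = daughters;
      for (Sel& s : eng.sels)
        if (s.onset == 1)
          eng.inject(pops[s.daughter == 2 ? 1 : 0], s,
                     s.daughter == 2 ? 2 : 1);
      std::vector<int> size2{n_a, n_b}, code2{1, 2};
      since = 0;
      for (int g = 0; g < t_split - 1; ++g) {
        eng.step(pops, size2, code2, mig);
        if (++since >= cleanup_every) { eng.cleanup(pops); since = 0; }
        if (need_cond && (g & 15) == 15 && eng.any_sel_lost(pops)) {
          lost = true;
          break;
        }
      }
      if (lost) continue;
      // conditioning
      bool ok = true;
      for (const Sel& s : eng.sels) {
        if (s.id < 0) { ok = false; break; }
        double f;
        if (s.daughter == 0)
          f = std::min(eng.freq_in(pops[0], s.id),
                       eng.freq_in(pops[1], s.id));
        else
          f = eng.freq_in(pops[s.daughter - 1], s.id);
        if (f < f_end) { ok = false; break; }
      }
      if (ok || !need_cond) { success = true; break; }
    }
    if (need_cond && !success)
      stop("selected allele failed to reach f_end within max_tries; "
           "increase s, f0 or max_tries");
  }

  // ---- sampling ------------------------------------------------------
  int ns_a = sample_a, ns_b = two_pop ? sample_b : 0;
  std::vector<const Hap*> sample;
  {
    std::vector<int> idx((int)pops[0].h.size());
    for (size_t i = 0; i < idx.size(); ++i) idx[i] = (int)i;
    for (int j = 0; j < ns_a; ++j) {
      std::uniform_int_distribution<int> d(j, (int)idx.size() - 1);
      std::swap(idx[j], idx[d(eng.rng)]);
      sample.push_back(&pops[0].h[idx[j]]);
    }
    if (two_pop) {
      std::vector<int> idx2((int)pops[1].h.size());
      for (size_t i = 0; i < idx2.size(); ++i) idx2[i] = (int)i;
      for (int j = 0; j < ns_b; ++j) {
        std::uniform_int_distribution<int> d(j, (int)idx2.size() - 1);
        std::swap(idx2[j], idx2[d(eng.rng)]);
        sample.push_back(&pops[1].h[idx2[j]]);
      }
    }
  }
  int ns = ns_a + ns_b;
  std::vector<int> cnt(eng.mpos.size(), 0);
  for (const Hap* h : sample)
    for (int id : *h) ++cnt[id];
  // segregating sites in the sample, ordered by position
  std::vector<int> segids;
  for (size_t id = 0; id < cnt.size(); ++id)
    if (cnt[id] > 0 && cnt[id] < ns) segids.push_back((int)id);
  std::sort(segids.begin(), segids.end(), [&eng](int a, int b) {
    return eng.mpos[a] < eng.mpos[b];
  });
  // map to strictly increasing integer bp
  std::vector<double> bp(segids.size());
  std::vector<char> keep(segids.size(), 1);
  double prev = -1;
  for (size_t j = 0; j < segids.size(); ++j) {
    double p = std::floor(eng.mpos[segids[j]] * locus_bp);
    if (p <= prev) p = prev + 1;
    if (p >= locus_bp) { keep[j] = 0; continue; }
    bp[j] = p;
    prev = p;
  }
  std::vector<int> colid;
  std::vector<double> colbp;
  for (size_t j = 0; j < segids.size(); ++j)
    if (keep[j]) { colid.push_back(segids[j]); colbp.push_back(bp[j]); }
  int S = (int)colid.size();
  IntegerMatrix geno(ns, S);
  std::vector<int> col_of(eng.mpos.size(), -1);
  for (int j = 0; j < S; ++j) col_of[colid[j]] = j;
  for (int i = 0; i < ns; ++i)
    for (int id : *sample[i]) {
      int j = col_of[id];
      if (j >= 0) geno(i, j) = 1;
    }
  NumericVector positions(colbp.begin(), colbp.end());

  // selected-allele bookkeeping
  int nsel = (int)eng.sels.size();
  NumericVector sfreq_a(nsel), sfreq_b(nsel), sbp(nsel);
  for (int i = 0; i < nsel; ++i) {
    const Sel& s = eng.sels[i];
    sfreq_a[i] = s.id >= 0 ? eng.freq_in(pops[0], s.id) : 0.0;
    sfreq_b[i] = (s.id >= 0 && two_pop) ? eng.freq_in(pops[1], s.id) : NA_REAL;
    sbp[i] = std::floor(s.pos * locus_bp);
  }
  return List::create(_["positions"] = positions, _["genotypes"] = geno,
                      _["sel_freq_a"] = sfreq_a, _["sel_freq_b"] = sfreq_b,
                      _["sel_bp"] = sbp, _["tries"] = tries,
                      _["n_a"] = ns_a, _["n_b"] = ns_b);
}
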