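// Forward Wright-Fisher simulation of a single diploid population with
// partial self-fertilization, crossover recombination, and recessive (or
// partially dominant) deleterious mutations restricted to an exon mask.
//
// Haplotypes are sparse lists of mutation ids sorted by genomic position;
// deleterious ids are mirrored in a small side list so fitness evaluation
// never walks the (mostly neutral) full list. All randomness goes through
// R's RNG, so runs are reproducible under set.seed().

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct MutTable {
  std::vector<double> pos;
  std::vector<double> s;
  int n_fixed = 0;
  int n_fixed_del = 0;
};

struct Hap {
  std::vector<int> ids;  // all mutations, sorted by (position, id)
  std::vector<int> del;  // subset with s < 0, same order
};

// compare mutation ids by (position, id)
struct ByPos {
  const MutTable& mt;
  explicit ByPos(const MutTable& m) : mt(m) {}
  bool operator()(int a, int b) const {
    if (mt.pos[a] != mt.pos[b]) return mt.pos[a] < mt.pos[b];
    return a < b;
  }
};

bool in_mask(double p, const NumericVector& starts, const NumericVector& ends) {
  if (starts.size() == 0) return false;
  int lo = std::upper_bound(starts.begin(), starts.end(), p) - starts.begin();
  if (lo == 0) return false;
  return p < ends[lo - 1];
}

// meiosis: recombine the parent's two haplotypes and add new mutations
void make_gamete(const Hap& h1, const Hap& h2, MutTable& mt, double L,
                 double mu, double rrate, bool deleterious,
                 const NumericVector& ex_s, const NumericVector& ex_e,
                 double p_del, double g_shape, double g_scale, Hap& g) {
  g.ids.clear();
  g.del.clear();
  int ncx = (int)R::rpois(rrate * L);
  int nmut = (int)R::rpois(mu * L);
  if (ncx == 0 && nmut == 0) {  // fast path: transmit one chromatid intact
    const Hap& v = unif_rand() < 0.5 ? h1 : h2;
    g = v;
    return;
  }
  std::vector<double> cx(ncx);
  for (int i = 0; i < ncx; i++) cx[i] = unif_rand() * L;
  std::sort(cx.begin(), cx.end());
  const Hap* src[2] = {&h1, &h2};
  int cur = unif_rand() < 0.5 ? 0 : 1;
  g.ids.reserve(h1.ids.size() + h2.ids.size());
  size_t ip[2] = {0, 0};
  double lo = 0.0;
  for (int k = 0; k <= ncx; k++) {
    double hi = (k < ncx) ? cx[k] : L + 1.0;
    const std::vector<int>& v = src[cur]->ids;
    size_t& ii = ip[cur];
    size_t& jj = ip[1 - cur];
    const std::vector<int>& w = src[1 - cur]->ids;
    while (ii < v.size() && mt.pos[v[ii]] < hi) {
      if (mt.pos[v[ii]] >= lo) g.ids.push_back(v[ii]);
      ii++;
    }
    while (jj < w.size() && mt.pos[w[jj]] < hi) jj++;
    cur = 1 - cur;
    lo = hi;
  }
  ByPos cmp(mt);
  for (int m = 0; m < nmut; m++) {
    double p = unif_rand() * L;
    double s = 0.0;
    if (deleterious && in_mask(p, ex_s, ex_e) && unif_rand() < p_del)
      s = -R::rgamma(g_shape, g_scale);
    int id = (int)mt.pos.size();
    mt.pos.push_back(p);
    mt.s.push_back(s);
    g.ids.insert(std::upper_bound(g.ids.begin(), g.ids.end(), id, cmp), id);
  }
  if (deleterious) {
    for (int id : g.ids)
      if (mt.s[id] < 0) g.del.push_back(id);
  }
}

// multiplicative fitness over the deleterious side lists:
// (1+s) per homozygous, (1+h s) per heterozygous mutation
double fitness(const Hap& a, const Hap& b, const MutTable& mt, double h) {
  if (a.del.empty() && b.del.empty()) return 1.0;
  double w = 1.0;
  size_t i = 0, j = 0;
  ByPos cmp(mt);
  while (i < a.del.size() || j < b.del.size()) {
    if (i < a.del.size() && j < b.del.size() && a.del[i] == b.del[j]) {
      w *= 1.0 + mt.s[a.del[i]];
      i++; j++;
    } else if (j >= b.del.size() ||
               (i < a.del.size() && cmp(a.del[i], b.del[j]))) {
      if (h != 0) w *= 1.0 + h * mt.s[a.del[i]];
      i++;
    } else {
      if (h != 0) w *= 1.0 + h * mt.s[b.del[j]];
      j++;
    }
    if (w <= 0) return 0.0;
  }
  return w;
}

// drop lost mutations, strip fixed ones out of every haplotype
void cleanup(std::vector<Hap>& pop, MutTable& mt) {
  int M = (int)mt.pos.size();
  std::vector<int> cnt(M, 0);
  for (const Hap& hp : pop)
    for (int id : hp.ids) cnt[id]++;
  int n2 = (int)pop.size();
  std::vector<int> remap(M, -1);
  MutTable nt;
  nt.n_fixed = mt.n_fixed;
  nt.n_fixed_del = mt.n_fixed_del;
  for (int id = 0; id < M; id++) {
    if (cnt[id] == 0) continue;
    if (cnt[id] == n2) {
      nt.n_fixed++;
      if (mt.s[id] < 0) nt.n_fixed_del++;
      continue;
    }
    remap[id] = (int)nt.pos.size();
    nt.pos.push_back(mt.pos[id]);
    nt.s.push_back(mt.s[id]);
  }
  for (Hap& hp : pop) {
    std::vector<int> ids, del;
    ids.reserve(hp.ids.size());
    for (int id : hp.ids)
      if (remap[id] >= 0) ids.push_back(remap[id]);
    for (int id : hp.del)
      if (remap[id] >= 0) del.push_back(remap[id]);
    hp.ids.swap(ids);
    hp.del.swap(del);
  }
  mt = nt;
}

}  // namespace

// [[Rcpp::export]]
List wf_simulate(IntegerVector epoch_gens, IntegerVector epoch_N,
                 NumericVector epoch_selfing, double L, double mu,
                 double rrate, NumericVector exon_start,
                 NumericVector exon_end, bool deleterious, double p_del,
                 double gamma_shape, double gamma_mean, double h,
                 int n_sample, int max_tries) {
  MutTable mt;
  double g_scale = gamma_shape > 0 ? gamma_mean / gamma_shape : 0.0;
  std::vector<Hap> pop(2 * epoch_N[0]);
  Hap g1, g2;
  bool failed = false;
  int gen_count = 0;
  for (int e = 0; e < epoch_gens.size() && !failed; e++) {
    int Nn = epoch_N[e];
    double selfing = epoch_selfing[e];
    for (int g = 0; g < epoch_gens[e] && !failed; g++) {
      int Ncur = (int)pop.size() / 2;
      std::vector<Hap> next(2 * Nn);
      for (int o = 0; o < Nn; o++) {
        int tries = 0;
        while (true) {
          if (++tries > max_tries) { failed = true; break; }
          int p1 = (int)(unif_rand() * Ncur);
          if (p1 >= Ncur) p1 = Ncur - 1;
          int p2;
          if (selfing > 0 && unif_rand() < selfing) {
            p2 = p1;
          } else {
            do {
              p2 = (int)(unif_rand() * Ncur);
              if (p2 >= Ncur) p2 = Ncur - 1;
            } while (Ncur > 1 && p2 == p1);
          }
          make_gamete(pop[2 * p1], pop[2 * p1 + 1], mt, L, mu, rrate,
                      deleterious, exon_start, exon_end, p_del, gamma_shape,
                      g_scale, g1);
          make_gamete(pop[2 * p2], pop[2 * p2 + 1], mt, L, mu, rrate,
                      deleterious, exon_start, exon_end, p_del, gamma_shape,
                      g_scale, g2);
          if (deleterious) {
            double w = fitness(g1, g2, mt, h);
            if (w < 1.0 && unif_rand() >= w) continue;
          }
          next[2 * o].ids.swap(g1.ids);
          next[2 * o].del.swap(g1.del);
          next[2 * o + 1].ids.swap(g2.ids);
          next[2 * o + 1].del.swap(g2.del);
          break;
        }
        if (failed) break;
      }
      if (failed) break;
      pop.swap(next);
      if (++gen_count % 25 == 0) cleanup(pop, mt);
    }
  }
  if (failed)
    return List::create(_["failed"] = true);
  cleanup(pop, mt);

  // sample n_sample diploids without replacement
  int Nfin = (int)pop.size() / 2;
  if (n_sample > Nfin) n_sample = Nfin;
  std::vector<int> idx(Nfin);
  for (int i = 0; i < Nfin; i++) idx[i] = i;
  for (int i = 0; i < n_sample; i++) {
    int j = i + (int)(unif_rand() * (Nfin - i));
    if (j >= Nfin) j = Nfin - 1;
    std::swap(idx[i], idx[j]);
  }
  int nh = 2 * n_sample;
  std::vector<int> cnt(mt.pos.size(), 0);
  for (int i = 0; i < n_sample; i++) {
    for (int id : pop[2 * idx[i]].ids) cnt[id]++;
    for (int id : pop[2 * idx[i] + 1].ids) cnt[id]++;
  }
  double pi_sum = 0.0;
  int n_seg = 0;
  for (size_t id = 0; id < cnt.size(); id++) {
    int k = cnt[id];
    if (k > 0 && k < nh) {
      pi_sum += 2.0 * k * (nh - k) / ((double)nh * (nh - 1));
      n_seg++;
    }
  }
  double het_sum = 0.0, hd_sum = 0.0, dd_sum = 0.0;
  ByPos cmp(mt);
  for (int i = 0; i < n_sample; i++) {
    const std::vector<int>& a = pop[2 * idx[i]].ids;
    const std::vector<int>& b = pop[2 * idx[i] + 1].ids;
    size_t x = 0, y = 0;
    int het = 0, het_del = 0, hom_del = 0;
    while (x < a.size() || y < b.size()) {
      if (x < a.size() && y < b.size() && a[x] == b[y]) {
        if (mt.s[a[x]] < 0) hom_del++;
        x++; y++;
      } else if (y >= b.size() || (x < a.size() && cmp(a[x], b[y]))) {
        het++;
        if (mt.s[a[x]] < 0) het_del++;
        x++;
      } else {
        het++;
        if (mt.s[b[y]] < 0) het_del++;
        y++;
      }
    }
    het_sum += (double)het / L;
    hd_sum += het_del;
    dd_sum += hom_del + mt.n_fixed_del;  // fixed deleterious are homozygous
  }
  return List::create(
      _["failed"] = false, _["pi"] = pi_sum / L,
      _["het"] = het_sum / n_sample, _["n_segregating"] = n_seg,
      _["n_het_del"] = hd_sum / n_sample, _["n_hom_del"] = dd_sum / n_sample,
      _["n_fixed"] = mt.n_fixed, _["n_fixed_del"] = mt.n_fixed_del);
}
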