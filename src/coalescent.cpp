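#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Structured coalescent without migration: within each deme lineage pairs
// coalesce at rate k(k-1)/(4*Ne) per generation (diploid Ne); MERGE events
// move all lineages of the source deme into the target, SIZE_CHANGE events
// switch a deme's Ne. Times in generations, measured backward from sampling.
//
// Returns parent / node_time vectors for 2n-1 nodes; tips are nodes
// 0..n-1 ordered by deme block, root has parent -1.

// [[Rcpp::export(name = ".sim_genealogy_cpp")]]
List sim_genealogy_cpp(IntegerVector n_per_deme,
                       NumericVector ne,
                       NumericVector ev_time,
                       IntegerVector ev_type,   // 0 = merge, 1 = size change
                       IntegerVector ev_deme,   // source deme (0-based)
                       IntegerVector ev_target, // target deme for merges
                       NumericVector ev_size) { // new Ne for size changes
  const int ndeme = n_per_deme.size();
  int n = 0;
  for (int d = 0; d < ndeme; ++d) n += n_per_deme[d];
  if (n < 2) stop("need at least two gene copies");

  const int n_nodes = 2 * n - 1;
  IntegerVector parent(n_nodes, -1);
  NumericVector node_time(n_nodes, 0.0);

  std::vector<double> Ne(ne.begin(), ne.end());
  std::vector< std::vector<int> > active(ndeme);
  int tip = 0;
  for (int d = 0; d < ndeme; ++d)
    for (int i = 0; i < n_per_deme[d]; ++i) active[d].push_back(tip++);

  double t = 0.0;
  int iev = 0, next_node = n, total = n;
  const int nev = ev_time.size();

  while (total > 1) {
    double rate = 0.0;
    for (int d = 0; d < ndeme; ++d) {
      const double k = (double) active[d].size();
      if (k >= 2.0) rate += k * (k - 1.0) / (4.0 * Ne[d]);
    }
    double t_next;
    if (rate > 0.0) {
      t_next = t + R::exp_rand() / rate;
    } else {
      if (iev >= nev)
        stop("lineages cannot coalesce: isolated demes with no remaining events");
      t_next = R_PosInf;
    }
    if (iev < nev && t_next >= ev_time[iev]) {
      t = ev_time[iev];
      if (ev_type[iev] == 0) {
        std::vector<int> &src = active[ev_deme[iev]];
        std::vector<int> &dst = active[ev_target[iev]];
        dst.insert(dst.end(), src.begin(), src.end());
        src.clear();
      } else {
        Ne[ev_deme[iev]] = ev_size[iev];
      }
      ++iev;
      continue;
    }
    t = t_next;
    // choose deme proportional to its pair-coalescence rate
    double u = unif_rand() * rate, acc = 0.0;
    int cd = -1;
    for (int d = 0; d < ndeme; ++d) {
      const double k = (double) active[d].size();
      if (k >= 2.0) {
        acc += k * (k - 1.0) / (4.0 * Ne[d]);
        if (u <= acc) { cd = d; break; }
      }
    }
    if (cd < 0) cd = ndeme - 1;
    std::vector<int> &lin = active[cd];
    const int k = (int) lin.size();
    int i = (int) (unif_rand() * k); if (i >= k) i = k - 1;
    int j = (int) (unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
    if (j >= i) ++j;
    const int a = lin[i], b = lin[j];
    parent[a] = next_node; parent[b] = next_node;
    node_time[next_node] = t;
    if (i > j) std::swap(i, j);
    lin[i] = next_node;
    lin.erase(lin.begin() + j);
    ++next_node;
    --total;
  }

  return List::create(_["parent"] = parent, _["node_time"] = node_time,
                      _["n_tips"] = n);
}

static inline double reflect_fold(double x, double lo, double hi) {
  // fold into [lo, hi] (may need several passes for large excursions)
  while (x < lo || x > hi) {
    if (x > hi) x = 2.0 * hi - x;
    if (x < lo) x = 2.0 * lo - x;
  }
  return x;
}

static inline int gsm_step(double P) {
  if (P <= 0.0) return 1;
  // geometric step size: P(k) = (1-P) P^(k-1), k >= 1
  double u = unif_rand();
  int k = 1 + (int) std::floor(std::log(u) / std::log(P));
  return k < 1 ? 1 : k;
}

// Drop mutations on each branch (Poisson with mean mu * length), each a
// +/- geometric(P) step on the repeat-number ladder with reflecting
// boundaries.  For branches whose mutation count far exceeds the reflected
// walk's mixing time the end state is drawn from the walk's stationary law,
// which is uniform on the ladder (the reflected kernel is doubly stochastic).
// [[Rcpp::export(name = ".mutate_gsm_cpp")]]
IntegerVector mutate_gsm_cpp(IntegerVector parent, NumericVector node_time,
                             int n_tips, double mu, double P,
                             double lo, double hi, double ancestral) {
  const int n_nodes = parent.size();
  std::vector<double> state(n_nodes);
  state[n_nodes - 1] = ancestral;
  const bool bounded = R_finite(lo) && R_finite(hi);
  const double width = bounded ? (hi - lo) : R_PosInf;
  const double mix_cap = bounded ? 50.0 * width * width : R_PosInf;

  for (int i = n_nodes - 2; i >= 0; --i) {
    const double len = node_time[parent[i]] - node_time[i];
    const double lam = mu * len;
    double nm = R::rpois(lam);
    double x;
    if (bounded && nm > mix_cap) {
      x = lo + std::floor(unif_rand() * (width + 1.0));
      if (x > hi) x = hi;
    } else {
      x = state[parent[i]];
      for (long m = 0; m < (long) nm; ++m) {
        const int k = gsm_step(P);
        x += (unif_rand() < 0.5) ? -k : k;
        if (bounded) x = reflect_fold(x, lo, hi);
      }
    }
    state[i] = x;
  }
  IntegerVector out(n_tips);
  for (int i = 0; i < n_tips; ++i) out[i] = (int) std::lround(state[i]);
  return out;
}

// ---- fast summary statistics on simulated gene-copy matrices -------------

// Weir & Cockerham (1984) variance components for one locus, two or more
// populations, summed over alleles.  Input: per gene copy the allele state
// (NA = missing) and the population of its carrier individual; copies 2i and
// 2i+1 belong to individual i.  Returns (a, b, c); NaN triple when the locus
// is uninformative (monomorphic or <2 populations with data).
static bool wc_components_copies(const std::vector<int> &allele,
                                 const std::vector<int> &ind_pop,
                                 int npop, double out[3]) {
  const int n_ind = (int) ind_pop.size();
  std::map<int, int> amap; // allele value -> index
  for (size_t i = 0; i < allele.size(); ++i)
    if (allele[i] != NA_INTEGER) amap.insert(std::make_pair(allele[i], 0));
  int na = 0;
  for (std::map<int,int>::iterator it = amap.begin(); it != amap.end(); ++it)
    it->second = na++;
  if (na < 2) return false;

  std::vector<double> nvec(npop, 0.0); // individuals with data per pop
  std::vector< std::vector<double> > cnt(npop, std::vector<double>(na, 0.0));
  std::vector< std::vector<double> > het(npop, std::vector<double>(na, 0.0));
  for (int i = 0; i < n_ind; ++i) {
    const int a1 = allele[2 * i], a2 = allele[2 * i + 1];
    if (a1 == NA_INTEGER || a2 == NA_INTEGER) continue;
    const int p = ind_pop[i];
    nvec[p] += 1.0;
    const int k1 = amap[a1], k2 = amap[a2];
    cnt[p][k1] += 1.0; cnt[p][k2] += 1.0;
    if (k1 != k2) { het[p][k1] += 1.0; het[p][k2] += 1.0; }
  }
  int r = 0; double nsum = 0.0, nsq = 0.0;
  for (int p = 0; p < npop; ++p)
    if (nvec[p] >= 1.0) { ++r; nsum += nvec[p]; nsq += nvec[p] * nvec[p]; }
  if (r < 2) return false;
  const double nbar = nsum / r;
  if (nbar <= 1.0) return false;
  const double nc = (nsum - nsq / nsum) / (r - 1.0);
  if (nc <= 0.0) return false;

  double A = 0.0, B = 0.0, C = 0.0;
  for (int al = 0; al < na; ++al) {
    double pbar = 0.0, hbar = 0.0;
    for (int p = 0; p < npop; ++p) {
      if (nvec[p] < 1.0) continue;
      pbar += cnt[p][al] / 2.0;
      hbar += het[p][al];
    }
    pbar /= (r * nbar); hbar /= (r * nbar);
    double s2 = 0.0;
    for (int p = 0; p < npop; ++p) {
      if (nvec[p] < 1.0) continue;
      const double pi = cnt[p][al] / (2.0 * nvec[p]);
      s2 += nvec[p] * (pi - pbar) * (pi - pbar);
    }
    s2 /= ((r - 1.0) * nbar);
    const double pq = pbar * (1.0 - pbar);
    A += (nbar / nc) *
         (s2 - (pq - s2 * (r - 1.0) / r - hbar / 4.0) / (nbar - 1.0));
    B += (nbar / (nbar - 1.0)) *
         (pq - s2 * (r - 1.0) / r - hbar * (2.0 * nbar - 1.0) / (4.0 * nbar));
    C += hbar / 2.0;
  }
  out[0] = A; out[1] = B; out[2] = C;
  return true;
}

// Summary statistic vector for a simulated gene-copy matrix: per deme the
// mean number of alleles per locus and mean unbiased gene diversity, then
// multilocus Weir-Cockerham theta for every deme pair (ratio of sums over
// loci).  states: n_copies x L; copy i belongs to individual i/2.
// [[Rcpp::export(name = ".summary_stats_cpp")]]
NumericVector summary_stats_cpp(IntegerMatrix states, IntegerVector ind_pop,
                                int npop) {
  const int ncop = states.nrow(), L = states.ncol();
  const int n_ind = ncop / 2;
  const int npair = npop * (npop - 1) / 2;
  NumericVector out(2 * npop + npair);

  // per-deme allele counts and gene diversity
  for (int p = 0; p < npop; ++p) {
    double mean_na = 0.0, mean_gd = 0.0;
    for (int l = 0; l < L; ++l) {
      std::map<int, double> cnt;
      double ncop_p = 0.0;
      for (int i = 0; i < n_ind; ++i) {
        if (ind_pop[i] != p) continue;
        const int a1 = states(2 * i, l), a2 = states(2 * i + 1, l);
        if (a1 == NA_INTEGER || a2 == NA_INTEGER) continue;
        cnt[a1] += 1.0; cnt[a2] += 1.0; ncop_p += 2.0;
      }
      mean_na += (double) cnt.size();
      if (ncop_p >= 2.0) {
        double sump2 = 0.0;
        for (std::map<int,double>::iterator it = cnt.begin();
             it != cnt.end(); ++it) {
          const double pa = it->second / ncop_p;
          sump2 += pa * pa;
        }
        mean_gd += (ncop_p / (ncop_p - 1.0)) * (1.0 - sump2);
      }
    }
    out[p] = mean_na / L;
    out[npop + p] = mean_gd / L;
  }

  // pairwise multilocus theta
  int q = 2 * npop;
  for (int p1 = 0; p1 < npop - 1; ++p1) {
    for (int p2 = p1 + 1; p2 < npop; ++p2) {
      double sa = 0.0, sabc = 0.0;
      bool any = false;
      for (int l = 0; l < L; ++l) {
        std::vector<int> al; al.reserve(ncop);
        std::vector<int> ip; ip.reserve(n_ind);
        for (int i = 0; i < n_ind; ++i) {
          if (ind_pop[i] == p1 || ind_pop[i] == p2) {
            al.push_back(states(2 * i, l));
            al.push_back(states(2 * i + 1, l));
            ip.push_back(ind_pop[i] == p1 ? 0 : 1);
          }
        }
        double comp[3];
        if (wc_components_copies(al, ip, 2, comp)) {
          sa += comp[0]; sabc += comp[0] + comp[1] + comp[2];
          any = true;
        }
      }
      out[q++] = (any && sabc != 0.0) ? sa / sabc : NA_REAL;
    }
  }
  return out;
}

// ---- permutation engines -------------------------------------------------

static void wc_from_geno(const IntegerMatrix &geno, const std::vector<int> &pop,
                         int npop, double comp[3], bool &ok) {
  const int n = geno.nrow();
  std::vector<int> al(2 * n);
  for (int i = 0; i < n; ++i) { al[2 * i] = geno(i, 0); al[2 * i + 1] = geno(i, 1); }
  ok = wc_components_copies(al, pop, npop, comp);
}

// Multilocus theta (ratio of summed components over informative loci) for a
// list of per-locus n x 2 genotype matrices and a population vector.
// [[Rcpp::export(name = ".theta_multilocus_cpp")]]
double theta_multilocus_cpp(List geno_list, IntegerVector pop, int npop) {
  std::vector<int> popv(pop.begin(), pop.end());
  double sa = 0.0, sabc = 0.0; bool any = false;
  for (int l = 0; l < geno_list.size(); ++l) {
    IntegerMatrix g = geno_list[l];
    double comp[3]; bool ok;
    wc_from_geno(g, popv, npop, comp, ok);
    if (ok) { sa += comp[0]; sabc += comp[0] + comp[1] + comp[2]; any = true; }
  }
  if (!any || sabc == 0.0) return NA_REAL;
  return sa / sabc;
}

// B multilocus theta values under random permutation of population labels
// across individuals (the genotypes-between-populations scheme).
// [[Rcpp::export(name = ".theta_perm_cpp")]]
NumericVector theta_perm_cpp(List geno_list, IntegerVector pop, int npop,
                             int B) {
  const int n = pop.size();
  std::vector<int> perm(pop.begin(), pop.end());
  NumericVector out(B);
  for (int b = 0; b < B; ++b) {
    for (int i = n - 1; i > 0; --i) { // Fisher-Yates via R RNG
      int j = (int) (unif_rand() * (i + 1)); if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double sa = 0.0, sabc = 0.0; bool any = false;
    for (int l = 0; l < geno_list.size(); ++l) {
      IntegerMatrix g = geno_list[l];
      double comp[3]; bool ok;
      wc_from_geno(g, perm, npop, comp, ok);
      if (ok) { sa += comp[0]; sabc += comp[0] + comp[1] + comp[2]; any = true; }
    }
    out[b] = (any && sabc != 0.0) ? sa / sabc : NA_REAL;
  }
  return out;
}

// Single-population Weir-Cockerham f = 1 - sum(c)/sum(b+c) over loci.
static double fis_from_loci(const std::vector< std::vector<int> > &loci_alleles,
                            int n_ind) {
  double sb = 0.0, sc = 0.0; bool any = false;
  for (size_t l = 0; l < loci_alleles.size(); ++l) {
    const std::vector<int> &al = loci_alleles[l];
    std::map<int, double> cnt;
    double nl = 0.0;
    for (int i = 0; i < n_ind; ++i) {
      const int a1 = al[2 * i], a2 = al[2 * i + 1];
      if (a1 == NA_INTEGER || a2 == NA_INTEGER) continue;
      cnt[a1] += 1.0; cnt[a2] += 1.0; nl += 1.0;
    }
    if (nl < 2.0 || cnt.size() < 2) continue;
    std::map<int, double> hets;
    for (int i = 0; i < n_ind; ++i) {
      const int a1 = al[2 * i], a2 = al[2 * i + 1];
      if (a1 == NA_INTEGER || a2 == NA_INTEGER || a1 == a2) continue;
      hets[a1] += 1.0; hets[a2] += 1.0;
    }
    for (std::map<int,double>::iterator it = cnt.begin(); it != cnt.end();
         ++it) {
      const double p = it->second / (2.0 * nl);
      const double h = (hets.count(it->first) ? hets[it->first] : 0.0) / nl;
      sb += (nl / (nl - 1.0)) * (p * (1.0 - p) - (2.0 * nl - 1.0) / (4.0 * nl) * h);
      sc += h / 2.0;
    }
    any = true;
  }
  if (!any || sb + sc == 0.0) return NA_REAL;
  return 1.0 - sc / (sb + sc);
}

// [[Rcpp::export(name = ".fis_multilocus_cpp")]]
double fis_multilocus_cpp(List geno_list) {
  const int L = geno_list.size();
  int n_ind = 0;
  std::vector< std::vector<int> > loci(L);
  for (int l = 0; l < L; ++l) {
    IntegerMatrix g = geno_list[l];
    n_ind = g.nrow();
    loci[l].resize(2 * n_ind);
    for (int i = 0; i < n_ind; ++i) {
      loci[l][2 * i] = g(i, 0); loci[l][2 * i + 1] = g(i, 1);
    }
  }
  return fis_from_loci(loci, n_ind);
}

// B values of f under permutation of gene copies among individuals within
// the population, independently per locus (the alleles-within-population
// scheme); missing copies stay in place.
// [[Rcpp::export(name = ".fis_perm_cpp")]]
NumericVector fis_perm_cpp(List geno_list, int B) {
  const int L = geno_list.size();
  int n_ind = 0;
  std::vector< std::vector<int> > base(L);
  std::vector< std::vector<int> > slots(L); // indices of non-missing copies
  for (int l = 0; l < L; ++l) {
    IntegerMatrix g = geno_list[l];
    n_ind = g.nrow();
    base[l].resize(2 * n_ind);
    for (int i = 0; i < n_ind; ++i) {
      base[l][2 * i] = g(i, 0); base[l][2 * i + 1] = g(i, 1);
      if (g(i, 0) != NA_INTEGER && g(i, 1) != NA_INTEGER) {
        slots[l].push_back(2 * i); slots[l].push_back(2 * i + 1);
      }
    }
  }
  NumericVector out(B);
  std::vector< std::vector<int> > cur = base;
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < L; ++l) {
      std::vector<int> &sl = slots[l];
      const int m = (int) sl.size();
      std::vector<int> vals(m);
      for (int i = 0; i < m; ++i) vals[i] = base[l][sl[i]];
      for (int i = m - 1; i > 0; --i) {
        int j = (int) (unif_rand() * (i + 1)); if (j > i) j = i;
        std::swap(vals[i], vals[j]);
      }
      for (int i = 0; i < m; ++i) cur[l][sl[i]] = vals[i];
    }
    out[b] = fis_from_loci(cur, n_ind);
  }
  return out;
}
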