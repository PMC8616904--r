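#include <Rcpp.h>
using namespace Rcpp;

// Forward-time spatial inversion-polymorphism models.
//
// Individuals live in the unit square (model 2: two unit squares, one
// per population, both spanning the same selection gradient along the
// y-axis). Each individual carries two haplotypes: an inversion
// allele (0 = A, 1 = B) plus a vector of biallelic neutral loci at
// fixed positions along the chromosome. Phenotype is additive on the
// B dosage g: phi = g / 2, matched against the position along the
// selection gradient.
//
// All randomness comes from R's RNG so seeded runs are reproducible.

static inline double reflect01(double v) {
  // fold into [0, 1]; bounded number of folds for any finite input
  while (v < 0.0 || v > 1.0) {
    if (v < 0.0) v = -v;
    if (v > 1.0) v = 2.0 - v;
  }
  return v;
}

static inline double grad_pos(double y, int pop, int model) {
  (void)pop; (void)model;  // both habitats span the same gradient
  return y;
}

// weighted draw: returns index in [0, n) or -1 if total weight is 0
static int draw_weighted(const std::vector<double>& w) {
  double tot = 0.0;
  for (double v : w) tot += v;
  if (tot <= 0.0) return -1;
  double u = unif_rand() * tot, acc = 0.0;
  for (int i = 0; i < (int)w.size(); ++i) {
    acc += w[i];
    if (u <= acc) return i;
  }
  return (int)w.size() - 1;
}

// [[Rcpp::export]]
IntegerVector cpp_count_neighbors(NumericVector x, NumericVector y,
                                  IntegerVector pop, double radius) {
  // grid-bucketed neighbour counting: only the 3x3 block of cells of
  // side `radius` around an individual can hold its neighbours
  int n = x.size();
  IntegerVector out(n);
  double r2 = radius * radius;
  int ncell = (int)(1.0 / radius);
  if (ncell < 1) ncell = 1;
  double cell = 1.0 / ncell;
  std::vector<std::vector<int> > bucket(ncell * ncell);
  std::vector<int> cx(n), cy(n);
  for (int i = 0; i < n; ++i) {
    int a = (int)(x[i] / cell); if (a >= ncell) a = ncell - 1;
    int b = (int)(y[i] / cell); if (b >= ncell) b = ncell - 1;
    cx[i] = a; cy[i] = b;
    bucket[a * ncell + b].push_back(i);
  }
  for (int i = 0; i < n; ++i) {
    int cnt = 0;
    for (int a = std::max(0, cx[i] - 1);
         a <= std::min(ncell - 1, cx[i] + 1); ++a)
      for (int b = std::max(0, cy[i] - 1);
           b <= std::min(ncell - 1, cy[i] + 1); ++b)
        for (int j : bucket[a * ncell + b]) {
          if (j == i || pop[j] != pop[i]) continue;
          double dx = x[i] - x[j], dy = y[i] - y[j];
          if (dx * dx + dy * dy <= r2) ++cnt;
        }
    out[i] = cnt;
  }
  return out;
}

// binary search on a cumulative-weight vector; returns index in
// [0, size) or -1 when the total weight is 0
static int draw_cumulative(const std::vector<double>& cum) {
  double tot = cum.empty() ? 0.0 : cum.back();
  if (tot <= 0.0) return -1;
  double u = unif_rand() * tot;
  int idx = (int)(std::lower_bound(cum.begin(), cum.end(), u) -
                  cum.begin());
  if (idx >= (int)cum.size()) idx = (int)cum.size() - 1;
  return idx;
}

// [[Rcpp::export]]
NumericVector cpp_fitness(NumericVector y, IntegerVector pop,
                          IntegerVector g, IntegerVector n_neighbors,
                          double s, double comp_strength, int model) {
  int n = y.size();
  NumericVector w(n);
  for (int i = 0; i < n; ++i) {
    double mism = std::fabs(grad_pos(y[i], pop[i], model) - g[i] / 2.0);
    double v = 1.0 - s * mism;
    if (v < 0.0) v = 0.0;
    if (model == 1)
      v /= 1.0 + comp_strength * n_neighbors[i];
    w[i] = v;
  }
  return w;
}

// [[Rcpp::export]]
int cpp_choose_mate(IntegerVector candidate_g, NumericVector candidate_w,
                    int g_focal, double a) {
  int n = candidate_g.size();
  std::vector<double> w(n);
  for (int i = 0; i < n; ++i)
    w[i] = candidate_w[i] *
      std::pow(1.0 - a, std::abs(candidate_g[i] - g_focal));
  int idx = draw_weighted(w);
  return idx + 1;  // 1-based; 0 = no viable candidate
}

struct Gamete {
  int inv;
  std::vector<int> neut;
};

static Gamete make_gamete(int inv1, int inv2,
                          const int* n1, const int* n2, int L,
                          const std::vector<double>& loci_pos,
                          double inv_mid, double inv_start, double inv_end,
                          double chrom_length, double rr, double mu) {
  double lambda = rr * chrom_length;
  int ncross = lambda > 0 ? (int)R::rpois(lambda) : 0;
  std::vector<double> cross;
  cross.reserve(ncross);
  bool het = inv1 != inv2;
  for (int c = 0; c < ncross; ++c) {
    double p = unif_rand() * chrom_length;
    // crossovers inside the inversion are rejected in inversion
    // heterozygotes (suppressed recombination)
    if (het && p >= inv_start && p < inv_end) continue;
    cross.push_back(p);
  }
  int start = unif_rand() < 0.5 ? 0 : 1;
  Gamete gam;
  gam.neut.resize(L);
  auto hap_at = [&](double pos) {
    int k = 0;
    for (double c : cross) if (c < pos) ++k;
    return (start + k) % 2;
  };
  gam.inv = hap_at(inv_mid) == 0 ? inv1 : inv2;
  for (int l = 0; l < L; ++l) {
    int al = hap_at(loci_pos[l]) == 0 ? n1[l] : n2[l];
    if (mu > 0 && unif_rand() < mu) al = 1 - al;
    gam.neut[l] = al;
  }
  return gam;
}

// [[Rcpp::export]]
List cpp_recombine(IntegerVector inv, IntegerMatrix neut,
                   NumericVector loci_pos, double inv_start,
                   double inv_end, double chrom_length, double rr,
                   double mu) {
  // inv: length-2 inversion alleles; neut: 2 x L neutral haplotypes
  int L = neut.ncol();
  std::vector<int> h1(L), h2(L);
  for (int l = 0; l < L; ++l) { h1[l] = neut(0, l); h2[l] = neut(1, l); }
  std::vector<double> lp(loci_pos.begin(), loci_pos.end());
  Gamete g = make_gamete(inv[0], inv[1], h1.data(), h2.data(), L, lp,
                         (inv_start + inv_end) / 2.0, inv_start, inv_end,
                         chrom_length, rr, mu);
  return List::create(_["inv"] = g.inv,
                      _["neutral"] = IntegerVector(g.neut.begin(),
                                                   g.neut.end()));
}

// [[Rcpp::export]]
List cpp_step_generation(List state, List cfg) {
  NumericVector x = state["x"], y = state["y"];
  IntegerVector pop = state["pop"];
  IntegerVector inv1 = state["inv1"], inv2 = state["inv2"];
  IntegerMatrix neut1 = state["neut1"], neut2 = state["neut2"];
  int n = x.size(), L = neut1.ncol();

  int model = as<int>(cfg["model"]);
  double s = as<double>(cfg["s"]);
  double a = model == 1 ? as<double>(cfg["a"]) : 0.0;
  double m = model == 2 ? as<double>(cfg["m"]) : 0.0;
  double comp_radius = as<double>(cfg["competition_radius"]);
  double comp_strength = as<double>(cfg["competition_strength"]);
  double mate_radius = as<double>(cfg["mate_search_radius"]);
  double disp = as<double>(cfg["dispersal_sd"]);
  double chrom_length = as<double>(cfg["chromosome_length"]);
  NumericVector inv_iv = cfg["inversion_interval"];
  double rr = as<double>(cfg["recombination_rate"]);
  double mu = as<double>(cfg["mutation_rate"]);
  NumericVector loci_pos_r = cfg["loci_positions"];
  std::vector<double> loci_pos(loci_pos_r.begin(), loci_pos_r.end());
  double inv_mid = (inv_iv[0] + inv_iv[1]) / 2.0;

  IntegerVector g(n);
  for (int i = 0; i < n; ++i) g[i] = inv1[i] + inv2[i];

  IntegerVector nb(n);
  if (model == 1 && comp_strength > 0)
    nb = cpp_count_neighbors(x, y, pop, comp_radius);
  NumericVector w = cpp_fitness(y, pop, g, nb, s, comp_strength, model);

  double mr2 = mate_radius * mate_radius;

  NumericVector nx(n), ny(n);
  IntegerVector npop(n), ninv1(n), ninv2(n);
  IntegerMatrix nneut1(n, L), nneut2(n, L);

  // population-wide mating (the default: search radius covers the
  // habitat) takes a fast path with precomputed per-genotype
  // cumulative mate weights; a restricted radius uses adjacency lists
  bool global_mating = mr2 >= 2.0;
  std::vector<std::vector<int> > nbrs;
  if (!global_mating) {
    nbrs.resize(n);
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (pop[j] != pop[i]) continue;
        double dx = x[i] - x[j], dy = y[i] - y[j];
        if (dx * dx + dy * dy <= mr2) {
          nbrs[i].push_back(j);
          nbrs[j].push_back(i);
        }
      }
    }
  }
  // assortative-mating kernel lookup over |dosage difference|
  double akern[3] = {1.0, 1.0 - a, (1.0 - a) * (1.0 - a)};

  // model 2 regulates each population to its current quota; model 1 is
  // a single global pool
  int npops = model == 2 ? 2 : 1;
  std::vector<int> quota(npops, 0);
  if (model == 2) { quota[0] = n / 2; quota[1] = n - n / 2; }
  else quota[0] = n;

  int k = 0;
  for (int p = 0; p < npops; ++p) {
    std::vector<int> members;
    for (int i = 0; i < n; ++i)
      if (model != 2 || pop[i] == p) members.push_back(i);
    // cumulative fitness over members for binary-search mother draws
    size_t nm = members.size();
    std::vector<double> cumw(nm);
    double tot = 0.0;
    for (size_t i = 0; i < nm; ++i) {
      tot += w[members[i]];
      cumw[i] = tot;
    }
    // per-focal-genotype cumulative mate weights (global mating only)
    std::vector<double> cumg[3];
    if (global_mating) {
      for (int gf = 0; gf < 3; ++gf) {
        cumg[gf].resize(nm);
        double t2 = 0.0;
        for (size_t i = 0; i < nm; ++i) {
          t2 += w[members[i]] * akern[std::abs(g[members[i]] - gf)];
          cumg[gf][i] = t2;
        }
      }
    }

    std::vector<int> cand;
    std::vector<double> cw;
    for (int q = 0; q < quota[p]; ++q) {
      int mother = -1, father = -1;
      for (int tries = 0; tries < 200 && father < 0; ++tries) {
        int mi = draw_cumulative(cumw);
        if (mi < 0) break;
        int mo = members[mi];
        if (global_mating) {
          const std::vector<double>& cg = cumg[g[mo]];
          // exclude self-mating: rejection with a mass check
          if (cg.back() - w[mo] <= 0.0) continue;  // no other candidate
          for (int rt = 0; rt < 100 && father < 0; ++rt) {
            int ci = draw_cumulative(cg);
            if (ci < 0) break;
            if (members[ci] != mo) {
              mother = mo;
              father = members[ci];
            }
          }
        } else {
          cand.clear();
          cw.clear();
          for (int j : nbrs[mo]) {
            if (w[j] <= 0.0) continue;
            cand.push_back(j);
            cw.push_back(w[j] * akern[std::abs(g[j] - g[mo])]);
          }
          if (cand.empty()) continue;  // mother skips; resample
          int ci = draw_weighted(cw);
          if (ci < 0) continue;
          mother = mo;
          father = cand[ci];
        }
      }
      if (father < 0)
        return List::create(_["extinct"] = true);

      // Rcpp matrices are column-major: copy haplotype rows out first
      std::vector<int> mh1(L), mh2(L), fh1(L), fh2(L);
      for (int l = 0; l < L; ++l) {
        mh1[l] = neut1(mother, l); mh2[l] = neut2(mother, l);
        fh1[l] = neut1(father, l); fh2[l] = neut2(father, l);
      }
      Gamete gm = make_gamete(inv1[mother], inv2[mother],
                              mh1.data(), mh2.data(), L,
                              loci_pos, inv_mid, inv_iv[0], inv_iv[1],
                              chrom_length, rr, mu);
      Gamete gf = make_gamete(inv1[father], inv2[father],
                              fh1.data(), fh2.data(), L,
                              loci_pos, inv_mid, inv_iv[0], inv_iv[1],
                              chrom_length, rr, mu);

      nx[k] = reflect01(x[mother] + (disp > 0 ? norm_rand() * disp : 0));
      ny[k] = reflect01(y[mother] + (disp > 0 ? norm_rand() * disp : 0));
      npop[k] = model == 2 ? p : 0;
      // migrants keep their coordinates and only switch squares: the
      // gradient position jumps by half the gradient, so migration
      // exposes genotypes to the other population's selective regime
      if (model == 2 && m > 0 && unif_rand() < m)
        npop[k] = 1 - npop[k];
      ninv1[k] = gm.inv;
      ninv2[k] = gf.inv;
      for (int l = 0; l < L; ++l) {
        nneut1(k, l) = gm.neut[l];
        nneut2(k, l) = gf.neut[l];
      }
      ++k;
    }
  }

  return List::create(_["x"] = nx, _["y"] = ny, _["pop"] = npop,
                      _["inv1"] = ninv1, _["inv2"] = ninv2,
                      _["neut1"] = nneut1, _["neut2"] = nneut2,
                      _["extinct"] = false);
}
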