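// Lattice Monte-Carlo engine for the three-gene repression ring, plus a
// fixed-step RK4 integrator for the mass-action ODE system and a free-tracer
// random-walk helper. All randomness flows through R's RNG so that
// set.seed() on the R side makes every run bit-reproducible.

#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

static inline int wrap(int c, int R) {
  if (c < 0) return c + R;
  if (c >= R) return c - R;
  return c;
}

// Move a site index one lattice step along direction `dir` with periodic
// wrap. dir in [0, 2*dim): axis = dir >> 1, sign from low bit.
static inline int move_site(int s, int dir, int dim, int R) {
  const int axis = dir >> 1;
  const int sign = (dir & 1) ? 1 : -1;
  if (axis == 0) {
    const int x = s % R;
    return (s - x) + wrap(x + sign, R);
  } else if (axis == 1) {
    const int x = s % R;
    const int y = (s / R) % R;
    return (s - x - y * R) + x + wrap(y + sign, R) * R;
  } else {
    const int RR = R * R;
    const int z = s / RR;
    return (s % RR) + wrap(z + sign, R) * RR;
  }
}

static inline int rand_int(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// [[Rcpp::export]]
List sim_run_cpp(IntegerMatrix gene_pos, IntegerVector gene_type,
                 int dim, int R,
                 double alpha, double beta, double tau_m, double tau_p,
                 double k_on, double k_off, double k_off2,
                 double p_move,
                 double n_steps_d, double burn_in_d, int stride,
                 int init_mrna, int init_protein, int init_occupancy,
                 bool record_mrna, bool record_genes) {
  RNGScope scope;

  const long long n_steps = (long long)n_steps_d;
  const long long burn_in = (long long)burn_in_d;
  const int n_genes = gene_pos.nrow();
  const double p_deg_m = 1.0 / tau_m;
  const double p_deg_p = 1.0 / tau_p;
  long long n_sites_ll = 1;
  for (int d = 0; d < dim; ++d) n_sites_ll *= R;
  const int n_sites = (int)n_sites_ll;

  // genes: immobile; occupancy in {0,1,2}; new_bonds counts bindings made in
  // the current step (those complexes are exempt from unbinding this step).
  std::vector<int> g_site(n_genes), g_type(n_genes), g_occ(n_genes),
      g_new(n_genes, 0);
  for (int g = 0; g < n_genes; ++g) {
    int s = 0, mult = 1;
    for (int d = 0; d < dim; ++d) {
      s += gene_pos(g, d) * mult;
      mult *= R;
    }
    g_site[g] = s;
    g_type[g] = gene_type[g];
    g_occ[g] = init_occupancy;
  }

  // site -> chained list of gene ids (genes are sparse and immobile)
  std::vector<int> site_head(n_sites, -1), gene_next(n_genes, -1);
  for (int g = 0; g < n_genes; ++g) {
    gene_next[g] = site_head[g_site[g]];
    site_head[g_site[g]] = g;
  }

  // free particles; stable (creation-order) storage
  std::vector<int> m_site, m_type, p_site, p_type;
  m_site.reserve(1024); p_site.reserve(8192);
  for (int ty = 0; ty < 3; ++ty) {
    for (int k = 0; k < init_mrna; ++k) {
      m_site.push_back(rand_int(n_sites));
      m_type.push_back(ty);
    }
  }
  for (int ty = 0; ty < 3; ++ty) {
    for (int k = 0; k < init_protein; ++k) {
      p_site.push_back(rand_int(n_sites));
      p_type.push_back(ty);
    }
  }

  // occupancy totals per *gene* type (bound protein of type i sits on a gene
  // of type (i+1) mod 3)
  int occ_by_gtype[3] = {0, 0, 0};
  for (int g = 0; g < n_genes; ++g) occ_by_gtype[g_type[g]] += g_occ[g];

  const long long n_rec = n_steps / stride;
  NumericVector rec_t(n_rec);
  IntegerMatrix rec_p(n_rec, 3);
  IntegerMatrix rec_m(record_mrna ? n_rec : 0, 3);
  IntegerMatrix rec_g(record_genes ? n_rec : 0, 9); // free/single/double x type

  std::vector<int> new_m_site, new_m_type, new_p_site, new_p_type;
  std::vector<int> cand; // binding candidates (indices into protein arrays)
  std::vector<char> p_dead;

  const long long total = burn_in + n_steps;
  long long irec = 0;

  for (long long t = 1; t <= total; ++t) {
    // (1) transcription: each free gene emits one mRNA with prob alpha,
    // placed at the gene's site; new molecules are inert until next step
    new_m_site.clear(); new_m_type.clear();
    for (int g = 0; g < n_genes; ++g) {
      if (g_occ[g] == 0 && unif_rand() < alpha) {
        new_m_site.push_back(g_site[g]);
        new_m_type.push_back(g_type[g]);
      }
    }

    // (2) pre-existing mRNA: degrade (prob 1/tau_m) XOR attempt translation
    // (prob beta, protein left at the pre-move site), survivors then move
    new_p_site.clear(); new_p_type.clear();
    {
      const size_t n_old = m_site.size();
      size_t w = 0;
      for (size_t k = 0; k < n_old; ++k) {
        if (unif_rand() < p_deg_m) continue; // degraded
        if (unif_rand() < beta) {
          new_p_site.push_back(m_site[k]);
          new_p_type.push_back(m_type[k]);
        }
        int s = m_site[k];
        if (p_move >= 1.0 || unif_rand() < p_move)
          s = move_site(s, rand_int(2 * dim), dim, R);
        m_site[w] = s; m_type[w] = m_type[k]; ++w;
      }
      m_site.resize(w); m_type.resize(w);
    }

    // (3) pre-existing free proteins: degrade (prob 1/tau_p) else move
    {
      const size_t n_old = p_site.size();
      size_t w = 0;
      for (size_t k = 0; k < n_old; ++k) {
        if (unif_rand() < p_deg_p) continue;
        int s = p_site[k];
        if (p_move >= 1.0 || unif_rand() < p_move)
          s = move_site(s, rand_int(2 * dim), dim, R);
        p_site[w] = s; p_type[w] = p_type[k]; ++w;
      }
      p_site.resize(w); p_type.resize(w);
    }

    // (4) binding: protein of type i binds a co-located free or singly-bound
    // gene of type (i+1) mod 3 with prob k_on; candidates processed in
    // uniformly random order; a gene accepts at most 2 proteins
    for (int g = 0; g < n_genes; ++g) g_new[g] = 0;
    cand.clear();
    if (k_on > 0.0)
    for (size_t k = 0; k < p_site.size(); ++k) {
      const int target = (p_type[k] + 1) % 3;
      for (int g = site_head[p_site[k]]; g != -1; g = gene_next[g]) {
        if (g_type[g] == target && g_occ[g] < 2) { cand.push_back((int)k); break; }
      }
    }
    if (!cand.empty()) {
      // Fisher-Yates shuffle
      for (int k = (int)cand.size() - 1; k > 0; --k) {
        int j = rand_int(k + 1);
        std::swap(cand[k], cand[j]);
      }
      p_dead.assign(p_site.size(), 0);
      bool any_bound = false;
      for (size_t c = 0; c < cand.size(); ++c) {
        const int k = cand[c];
        const int target = (p_type[k] + 1) % 3;
        for (int g = site_head[p_site[k]]; g != -1; g = gene_next[g]) {
          if (g_type[g] != target || g_occ[g] >= 2) continue;
          if (k_on >= 1.0 || unif_rand() < k_on) {
            g_occ[g] += 1; g_new[g] += 1;
            occ_by_gtype[g_type[g]] += 1;
            p_dead[k] = 1; any_bound = true;
            break;
          }
        }
      }
      if (any_bound) {
        size_t w = 0;
        for (size_t k = 0; k < p_site.size(); ++k) {
          if (p_dead[k]) continue;
          p_site[w] = p_site[k]; p_type[w] = p_type[k]; ++w;
        }
        p_site.resize(w); p_type.resize(w);
      }
    }

    // (5) unbinding: only complexes whose bound state predates this step;
    // singly-bound release with prob k_off, doubly-bound with prob k_off2
    // (one protein released at the gene's site, inert until next step)
    for (int g = 0; g < n_genes; ++g) {
      if (g_occ[g] == 0 || g_new[g] > 0) continue;
      const double p_off = (g_occ[g] == 1) ? k_off : k_off2;
      if (unif_rand() < p_off) {
        g_occ[g] -= 1;
        occ_by_gtype[g_type[g]] -= 1;
        new_p_site.push_back(g_site[g]);
        new_p_type.push_back((g_type[g] + 2) % 3);
      }
    }

    // merge newborn molecules
    for (size_t k = 0; k < new_m_site.size(); ++k) {
      m_site.push_back(new_m_site[k]); m_type.push_back(new_m_type[k]);
    }
    for (size_t k = 0; k < new_p_site.size(); ++k) {
      p_site.push_back(new_p_site[k]); p_type.push_back(new_p_type[k]);
    }

    // record totals (free + bound) after the full step
    if (t > burn_in && (t - burn_in) % stride == 0 && irec < n_rec) {
      int pf[3] = {0, 0, 0}, mf[3] = {0, 0, 0};
      for (size_t k = 0; k < p_site.size(); ++k) pf[p_type[k]]++;
      for (size_t k = 0; k < m_site.size(); ++k) mf[m_type[k]]++;
      rec_t[irec] = (double)t;
      for (int ty = 0; ty < 3; ++ty)
        rec_p(irec, ty) = pf[ty] + occ_by_gtype[(ty + 1) % 3];
      if (record_mrna)
        for (int ty = 0; ty < 3; ++ty) rec_m(irec, ty) = mf[ty];
      if (record_genes) {
        int cnt[3][3] = {{0}};
        for (int g = 0; g < n_genes; ++g) cnt[g_type[g]][g_occ[g]]++;
        for (int ty = 0; ty < 3; ++ty)
          for (int o = 0; o < 3; ++o) rec_g(irec, 3 * ty + o) = cnt[ty][o];
      }
      ++irec;
    }

    if ((t & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  // final per-type gene occupancy tally (invariant check happens R-side)
  IntegerMatrix gene_state(3, 3);
  for (int g = 0; g < n_genes; ++g) gene_state(g_type[g], g_occ[g])++;

  return List::create(_["t"] = rec_t, _["P"] = rec_p, _["M"] = rec_m,
                      _["genes"] = rec_g, _["final_gene_state"] = gene_state,
                      _["final_free_mrna"] = (int)m_site.size(),
                      _["final_free_protein"] = (int)p_site.size());
}

// Mean squared displacement of non-interacting random walkers on an
// unbounded lattice (no wrap, so displacement is exact).
// [[Rcpp::export]]
NumericVector tracer_msd_cpp(int n_walkers, int n_steps, int dim,
                             double p_move) {
  RNGScope scope;
  std::vector<int> x(n_walkers * dim, 0);
  NumericVector msd(n_steps);
  for (int t = 0; t < n_steps; ++t) {
    double acc = 0.0;
    for (int w = 0; w < n_walkers; ++w) {
      if (p_move >= 1.0 || unif_rand() < p_move) {
        const int dir = rand_int(2 * dim);
        x[w * dim + (dir >> 1)] += (dir & 1) ? 1 : -1;
      }
      double r2 = 0.0;
      for (int d = 0; d < dim; ++d) {
        const double c = x[w * dim + d];
        r2 += c * c;
      }
      acc += r2;
    }
    msd[t] = acc / n_walkers;
  }
  return msd;
}

// ---- mass-action ODE system --------------------------------------------
// State layout: 4 components per gene i in {0,1,2}: (G_i, M_i, P_i, Gs_i),
// flattened as y[4*i + c]. The doubly-bound fraction is eliminated by
// conservation: Gss_i = G_T - G_i - Gs_i.

static inline void ma_rhs(const double *y, double *dy, double alpha,
                          double beta, double tau_m, double tau_p,
                          double k_on, double k_off, double k_off2,
                          double g_t) {
  for (int i = 0; i < 3; ++i) {
    const int ib = (i + 2) % 3; // protein repressing gene i
    const int j = (i + 1) % 3;  // gene repressed by protein i
    const double G = y[4 * i], M = y[4 * i + 1], P = y[4 * i + 2],
                 Gs = y[4 * i + 3];
    const double Pib = y[4 * ib + 2];
    const double Gj = y[4 * j], Gsj = y[4 * j + 3];
    dy[4 * i] = -k_on * G * Pib + k_off * Gs;
    dy[4 * i + 1] = alpha * G - M / tau_m;
    dy[4 * i + 2] = beta * M - P / tau_p - k_on * P * (Gj + Gsj) +
                    k_off * Gsj + k_off2 * (g_t - Gj - Gsj);
    dy[4 * i + 3] = k_on * Pib * (G - Gs) - k_off * Gs +
                    k_off2 * (g_t - G - Gs);
  }
}

// [[Rcpp::export]]
List ode_rk4_cpp(NumericVector y0, double alpha, double beta, double tau_m,
                 double tau_p, double k_on, double k_off, double k_off2,
                 double g_t, double t_end, double dt, int record_every) {
  const long long n_steps = (long long)(t_end / dt + 0.5);
  const long long n_rec = n_steps / record_every + 1;
  NumericMatrix Y(n_rec, 12);
  NumericVector tt(n_rec);
  double y[12], k1[12], k2[12], k3[12], k4[12], tmp[12];
  for (int c = 0; c < 12; ++c) y[c] = y0[c];
  long long irec = 0;
  tt[0] = 0.0;
  for (int c = 0; c < 12; ++c) Y(0, c) = y[c];
  irec = 1;
  for (long long s = 1; s <= n_steps; ++s) {
    ma_rhs(y, k1, alpha, beta, tau_m, tau_p, k_on, k_off, k_off2, g_t);
    for (int c = 0; c < 12; ++c) tmp[c] = y[c] + 0.5 * dt * k1[c];
    ma_rhs(tmp, k2, alpha, beta, tau_m, tau_p, k_on, k_off, k_off2, g_t);
    for (int c = 0; c < 12; ++c) tmp[c] = y[c] + 0.5 * dt * k2[c];
    ma_rhs(tmp, k3, alpha, beta, tau_m, tau_p, k_on, k_off, k_off2, g_t);
    for (int c = 0; c < 12; ++c) tmp[c] = y[c] + dt * k3[c];
    ma_rhs(tmp, k4, alpha, beta, tau_m, tau_p, k_on, k_off, k_off2, g_t);
    for (int c = 0; c < 12; ++c)
      y[c] += dt / 6.0 * (k1[c] + 2.0 * k2[c] + 2.0 * k3[c] + k4[c]);
    if (s % record_every == 0 && irec < n_rec) {
      tt[irec] = s * dt;
      for (int c = 0; c < 12; ++c) Y(irec, c) = y[c];
      ++irec;
    }
    if ((s & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["t"] = tt, _["y"] = Y);
}
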