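// Pattern-compressed Felsenstein pruning for the K2P + I + discrete-Gamma
// mixture, and a Newton-Raphson branch-length sweep. State codes 0..3 =
// A,C,G,T (XOR 2 = transition partner), 4 = missing. Trees arrive as ape
// postorder edge matrices with 1-based node ids; tips are 1..ntip.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double SCALE_THRESH = 1e-240;
static const double SCALE_FACTOR = 1e240;
static const double LOG_SCALE = std::log(1e-240);  // added per rescue

// K2P transition probabilities (and derivatives in the distance d) under
// the mean-rate-1 scaling beta = 1/(kappa+2).
struct PK {
  double ps, pi, pv;
  double dps, dpi, dpv;
  double d2ps, d2pi, d2pv;
};

static inline PK pk_at(double d, double kappa, bool deriv) {
  PK o;
  double beta = 1.0 / (kappa + 2.0);
  double c1 = 4.0 * beta;
  double c2 = 2.0 * (kappa + 1.0) * beta;
  double e1 = std::exp(-c1 * d);
  double e2 = std::exp(-c2 * d);
  o.ps = 0.25 + 0.25 * e1 + 0.5 * e2;
  o.pi = 0.25 + 0.25 * e1 - 0.5 * e2;
  o.pv = 0.25 - 0.25 * e1;
  if (deriv) {
    o.dps = -0.25 * c1 * e1 - 0.5 * c2 * e2;
    o.dpi = -0.25 * c1 * e1 + 0.5 * c2 * e2;
    o.dpv = 0.25 * c1 * e1;
    o.d2ps = 0.25 * c1 * c1 * e1 + 0.5 * c2 * c2 * e2;
    o.d2pi = 0.25 * c1 * c1 * e1 - 0.5 * c2 * c2 * e2;
    o.d2pv = -0.25 * c1 * c1 * e1;
  } else {
    o.dps = o.dpi = o.dpv = o.d2ps = o.d2pi = o.d2pv = 0.0;
  }
  return o;
}

// 5 x 4 lookup of the tip contribution P(t)[., s] (row s = 4: missing,
// contribution 1 for every parent state).
static inline void tip_table(const PK& k, double tab[5][4]) {
  for (int s = 0; s < 4; ++s) {
    int st = s ^ 2;
    for (int a = 0; a < 4; ++a)
      tab[s][a] = (a == s) ? k.ps : ((a == st) ? k.pi : k.pv);
  }
  for (int a = 0; a < 4; ++a) tab[4][a] = 1.0;
}

typedef std::vector<std::vector<double> > NodeArr;

// Post-order pass for one rate category over a pattern range [i0, i1):
// fills down[node] and dscale[node] for that range only (arrays sized to
// the range). Working on blocks of a few hundred patterns keeps the
// per-node partials cache-resident, which matters for trees with many
// nodes. Returns whether any rescaling happened.
static bool down_pass_range(const IntegerMatrix& edge, const NumericVector& blen,
                            const IntegerMatrix& tips, double rate, double kappa,
                            int i0, int i1,
                            NodeArr& down, NodeArr& dscale, int& root_out) {
  const int ntip = tips.ncol();
  const int nedge = edge.nrow();
  const int B = i1 - i0;
  std::vector<char> seen(down.size(), 0);
  bool scaled = false;

  for (int e = 0; e < nedge; ++e) {
    int p = edge(e, 0) - 1;
    int c = edge(e, 1) - 1;
    PK k = pk_at(blen[e] * rate, kappa, false);
    bool first = !seen[p];
    if (first) {
      if ((int)down[p].size() < B * 4) down[p].resize((size_t)B * 4);
      if ((int)dscale[p].size() < B) dscale[p].resize(B);
      std::fill(dscale[p].begin(), dscale[p].begin() + B, 0.0);
      seen[p] = 1;
    }
    double* up = &down[p][0];
    double* us = &dscale[p][0];
    if (c < ntip) {
      double tab[5][4];
      tip_table(k, tab);
      const int* col = &tips(0, c);
      if (first) {
        for (int i = 0; i < B; ++i) {
          const double* v = tab[col[i0 + i]];
          double* d = up + (size_t)i * 4;
          d[0] = v[0]; d[1] = v[1]; d[2] = v[2]; d[3] = v[3];
        }
      } else {
        for (int i = 0; i < B; ++i) {
          const double* v = tab[col[i0 + i]];
          double* d = up + (size_t)i * 4;
          d[0] *= v[0]; d[1] *= v[1]; d[2] *= v[2]; d[3] *= v[3];
        }
      }
    } else {
      const double* cd = &down[c][0];
      const double* cs = &dscale[c][0];
      for (int i = 0; i < B; ++i) {
        const double* D = cd + (size_t)i * 4;
        double T = D[0] + D[1] + D[2] + D[3];
        double* d = up + (size_t)i * 4;
        for (int a = 0; a < 4; ++a) {
          double ctr = k.ps * D[a] + k.pi * D[a ^ 2] + k.pv * (T - D[a] - D[a ^ 2]);
          if (first) d[a] = ctr; else d[a] *= ctr;
        }
        us[i] += cs[i];
        double m = std::max(std::max(d[0], d[1]), std::max(d[2], d[3]));
        if (m < SCALE_THRESH && m > 0.0) {
          for (int a = 0; a < 4; ++a) d[a] *= SCALE_FACTOR;
          us[i] += LOG_SCALE;
          scaled = true;
        }
      }
    }
  }
  root_out = edge(nedge - 1, 0) - 1;
  return scaled;
}

static const int EVAL_BLOCK = 256;

// Post-order pass for one rate category; fills down[node] (P x 4 partials)
// and dscale[node] (per-pattern log rescue corrections) for internal
// nodes. Returns the root and whether any rescaling happened.
static bool down_pass(const IntegerMatrix& edge, const NumericVector& blen,
                      const IntegerMatrix& tips, double rate, double kappa,
                      NodeArr& down, NodeArr& dscale, int& root_out) {
  const int P = tips.nrow();
  const int ntip = tips.ncol();
  const int nedge = edge.nrow();
  std::vector<char> seen(down.size(), 0);
  bool scaled = false;

  for (int e = 0; e < nedge; ++e) {
    int p = edge(e, 0) - 1;
    int c = edge(e, 1) - 1;
    PK k = pk_at(blen[e] * rate, kappa, false);
    bool first = !seen[p];
    if (first) {
      if (down[p].empty()) down[p].resize((size_t)P * 4);
      if (dscale[p].empty()) dscale[p].resize(P);
      std::fill(dscale[p].begin(), dscale[p].end(), 0.0);
      seen[p] = 1;
    }
    double* up = &down[p][0];
    double* us = &dscale[p][0];
    if (c < ntip) {
      double tab[5][4];
      tip_table(k, tab);
      const int* col = &tips(0, c);
      if (first) {
        for (int i = 0; i < P; ++i) {
          const double* v = tab[col[i]];
          double* d = up + (size_t)i * 4;
          d[0] = v[0]; d[1] = v[1]; d[2] = v[2]; d[3] = v[3];
        }
      } else {
        for (int i = 0; i < P; ++i) {
          const double* v = tab[col[i]];
          double* d = up + (size_t)i * 4;
          d[0] *= v[0]; d[1] *= v[1]; d[2] *= v[2]; d[3] *= v[3];
        }
      }
    } else {
      const double* cd = &down[c][0];
      const double* cs = &dscale[c][0];
      for (int i = 0; i < P; ++i) {
        const double* D = cd + (size_t)i * 4;
        double T = D[0] + D[1] + D[2] + D[3];
        double* d = up + (size_t)i * 4;
        for (int a = 0; a < 4; ++a) {
          double ctr = k.ps * D[a] + k.pi * D[a ^ 2] + k.pv * (T - D[a] - D[a ^ 2]);
          if (first) d[a] = ctr; else d[a] *= ctr;
        }
        us[i] += cs[i];
        double m = std::max(std::max(d[0], d[1]), std::max(d[2], d[3]));
        if (m < SCALE_THRESH && m > 0.0) {
          for (int a = 0; a < 4; ++a) d[a] *= SCALE_FACTOR;
          us[i] += LOG_SCALE;
          scaled = true;
        }
      }
    }
  }
  root_out = edge(nedge - 1, 0) - 1;
  return scaled;
}

// Per-pattern log-likelihoods for the variable rate categories.
// Returns a P x length(rates) matrix of log P(D_i | r_j).
// [[Rcpp::export]]
NumericMatrix ig_cat_loglik_cpp(IntegerMatrix edge, NumericVector blen,
                                IntegerMatrix tips, NumericVector rates,
                                double kappa) {
  const int P = tips.nrow();
  const int ntip = tips.ncol();
  const int k = rates.size();
  int nnode = ntip;
  for (int e = 0; e < edge.nrow(); ++e)
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));

  NumericMatrix out(P, k);
  NodeArr down(nnode), dscale(nnode);
  for (int i0 = 0; i0 < P; i0 += EVAL_BLOCK) {
    int i1 = std::min(P, i0 + EVAL_BLOCK);
    for (int j = 0; j < k; ++j) {
      int root;
      down_pass_range(edge, blen, tips, rates[j], kappa, i0, i1,
                      down, dscale, root);
      const double* rd = &down[root][0];
      const double* rs = &dscale[root][0];
      for (int i = 0; i < i1 - i0; ++i) {
        const double* D = rd + (size_t)i * 4;
        double s = 0.25 * (D[0] + D[1] + D[2] + D[3]);
        out(i0 + i, j) = (s > 0.0) ? std::log(s) + rs[i] : R_NegInf;
      }
    }
  }
  return out;
}

// Total mixture log-likelihood sum_i c_i log(sum_j w_j L_ij). Fast path
// without logs per category when no rescaling was needed anywhere.
// weights has k+1 entries (invariable category first); l0 is the plain
// (not log) invariable-category likelihood per pattern (0, 1/4 or 1).
// [[Rcpp::export]]
double ig_mix_loglik_cpp(IntegerMatrix edge, NumericVector blen,
                         IntegerMatrix tips, NumericVector counts,
                         NumericVector l0, NumericVector rates,
                         NumericVector weights, double kappa) {
  const int P = tips.nrow();
  const int ntip = tips.ncol();
  const int k = rates.size();
  int nnode = ntip;
  for (int e = 0; e < edge.nrow(); ++e)
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));

  const double w0 = weights[0];
  NodeArr down(nnode), dscale(nnode);
  double ll = 0.0;

  for (int i0 = 0; i0 < P; i0 += EVAL_BLOCK) {
    int i1 = std::min(P, i0 + EVAL_BLOCK);
    int B = i1 - i0;
    std::vector<double> site(B), lsite;
    bool any_scaled = false;
    for (int i = 0; i < B; ++i) site[i] = w0 * l0[i0 + i];
    for (int j = 0; j < k; ++j) {
      int root;
      bool scaled = down_pass_range(edge, blen, tips, rates[j], kappa, i0, i1,
                                    down, dscale, root);
      const double* rd = &down[root][0];
      const double* rs = &dscale[root][0];
      double wj = weights[j + 1];
      if (!scaled && !any_scaled) {
        for (int i = 0; i < B; ++i) {
          const double* D = rd + (size_t)i * 4;
          site[i] += wj * 0.25 * (D[0] + D[1] + D[2] + D[3]);
        }
      } else {
        // switch (once) to log-space accumulation within the block
        if (!any_scaled) {
          lsite.resize(B);
          for (int i = 0; i < B; ++i)
            lsite[i] = (site[i] > 0.0) ? std::log(site[i]) : R_NegInf;
          any_scaled = true;
        }
        for (int i = 0; i < B; ++i) {
          const double* D = rd + (size_t)i * 4;
          double s = 0.25 * (D[0] + D[1] + D[2] + D[3]);
          double a = (s > 0.0) ? std::log(wj * s) + rs[i] : R_NegInf;
          double m = std::max(lsite[i], a);
          if (R_FINITE(m))
            lsite[i] = m + std::log(std::exp(lsite[i] - m) + std::exp(a - m));
        }
      }
    }
    if (!any_scaled) {
      for (int i = 0; i < B; ++i) {
        if (!(site[i] > 0.0)) return R_NegInf;
        ll += counts[i0 + i] * std::log(site[i]);
      }
    } else {
      for (int i = 0; i < B; ++i) {
        if (!R_FINITE(lsite[i])) return R_NegInf;
        ll += counts[i0 + i] * lsite[i];
      }
    }
  }
  return ll;
}

// Mixture log-likelihood (up to per-pattern constants) as a function of
// one branch length, from precomputed coefficients:
// f(t) = sum_i c_i * log(b0_i + sum_j XB ps_j + YB pi_j + ZB pv_j)
struct BranchObj {
  int P, k;
  double kappa;
  const double* counts;
  std::vector<double> XB, YB, ZB, b0;  // XB etc are k*P, category-major
  const double* rates;

  double eval(double t, double* g, double* h) const {
    std::vector<PK> pk(k);
    for (int j = 0; j < k; ++j) pk[j] = pk_at(t * rates[j], kappa, g != 0);
    double f = 0.0, fg = 0.0, fh = 0.0;
    for (int i = 0; i < P; ++i) {
      double S = b0[i], S1 = 0.0, S2 = 0.0;
      for (int j = 0; j < k; ++j) {
        size_t o = (size_t)j * P + i;
        S += XB[o] * pk[j].ps + YB[o] * pk[j].pi + ZB[o] * pk[j].pv;
        if (g) {
          double r = rates[j];
          S1 += r * (XB[o] * pk[j].dps + YB[o] * pk[j].dpi + ZB[o] * pk[j].dpv);
          S2 += r * r * (XB[o] * pk[j].d2ps + YB[o] * pk[j].d2pi + ZB[o] * pk[j].d2pv);
        }
      }
      if (!(S > 0.0)) return R_NegInf;
      f += counts[i] * std::log(S);
      if (g) {
        double u = S1 / S;
        fg += counts[i] * u;
        fh += counts[i] * (S2 / S - u * u);
      }
    }
    if (g) { *g = fg; *h = fh; }
    return f;
  }
};

// Safeguarded Newton-Raphson on one branch length within [tmin, tmax];
// guarantees no decrease of the objective.
static double nr_branch(const BranchObj& obj, double t0, double tmin, double tmax) {
  double t = std::min(std::max(t0, tmin), tmax);
  const double t_init = t;
  const double f_init = obj.eval(t, 0, 0);
  double f = f_init;
  for (int iter = 0; iter < 30; ++iter) {
    double g, h;
    obj.eval(t, &g, &h);
    double step;
    if (R_FINITE(h) && h < 0.0 && R_FINITE(g)) {
      step = -g / h;
    } else if (R_FINITE(g)) {
      // no usable curvature: damped gradient-sign step (halved by the
      // backtracking below when it overshoots)
      step = (g > 0.0 ? 1.0 : -1.0) * std::max(0.5 * t, 1e-3);
    } else {
      break;
    }
    double tn = std::min(std::max(t + step, tmin), tmax);
    double fn = obj.eval(tn, 0, 0);
    int tries = 0;
    while (!(fn >= f - 1e-12) && tries < 30) {
      tn = t + 0.5 * (tn - t);
      fn = obj.eval(tn, 0, 0);
      ++tries;
    }
    if (!(fn >= f - 1e-12)) break;      // no improving point found
    double dt = std::fabs(tn - t);
    t = tn;
    f = std::max(f, fn);
    if (dt < 1e-10 * (1.0 + t)) break;
  }
  // final guard against any numerical slip
  if (!(f >= f_init - 1e-9)) t = t_init;
  return t;
}

// contribution of child c (seen from its parent) for one category:
// ctr[a] = sum_b P(t)[a,b] * down_c[b]; tips use their delta/ones vector.
static void child_contrib(const IntegerMatrix& tips, const NodeArr& down,
                          const NodeArr& dscale, int c, int ntip, int P,
                          double t, double rate, double kappa,
                          std::vector<double>& ctr, std::vector<double>& csc) {
  PK k = pk_at(t * rate, kappa, false);
  ctr.resize((size_t)P * 4);
  csc.assign(P, 0.0);
  if (c < ntip) {
    double tab[5][4];
    tip_table(k, tab);
    const int* col = &tips(0, c);
    for (int i = 0; i < P; ++i) {
      const double* v = tab[col[i]];
      double* d = &ctr[(size_t)i * 4];
      d[0] = v[0]; d[1] = v[1]; d[2] = v[2]; d[3] = v[3];
    }
  } else {
    const double* cd = &down[c][0];
    const double* cs = &dscale[c][0];
    for (int i = 0; i < P; ++i) {
      const double* D = cd + (size_t)i * 4;
      double T = D[0] + D[1] + D[2] + D[3];
      double* d = &ctr[(size_t)i * 4];
      for (int a = 0; a < 4; ++a)
        d[a] = k.ps * D[a] + k.pi * D[a ^ 2] + k.pv * (T - D[a] - D[a ^ 2]);
      csc[i] = cs[i];
    }
  }
}

// Full Newton-Raphson branch-length sweep(s): conditional optimization of
// each branch given the current values of all others (Gauss-Seidel in
// pre-order), using outside partials G maintained from the root. Returns
// the updated branch lengths and the final mixture log-likelihood.
// weights has k+1 entries (invariable category first); l0 is the plain
// invariable-category likelihood per pattern.
// [[Rcpp::export]]
List ig_branch_sweep_cpp(IntegerMatrix edge, NumericVector blen,
                         IntegerMatrix tips, NumericVector counts,
                         NumericVector l0, NumericVector rates,
                         NumericVector weights, double kappa,
                         double tmin, double tmax, int nsweep) {
  const int P = tips.nrow();
  const int ntip = tips.ncol();
  const int k = rates.size();
  const int nedge = edge.nrow();
  int nnode = ntip;
  for (int e = 0; e < nedge; ++e)
    nnode = std::max(nnode, std::max(edge(e, 0), edge(e, 1)));

  NumericVector t(clone(blen));
  const double w0 = weights[0];

  // child edges per node, and pre-order node sequence (root first)
  std::vector<std::vector<int> > childEdges(nnode);
  for (int e = 0; e < nedge; ++e) childEdges[edge(e, 0) - 1].push_back(e);
  int root = edge(nedge - 1, 0) - 1;
  std::vector<int> order;
  order.push_back(root);
  for (int e = nedge - 1; e >= 0; --e) {
    int c = edge(e, 1) - 1;
    if (c >= ntip) order.push_back(c);
  }

  std::vector<NodeArr> down(k, NodeArr(nnode)), dscale(k, NodeArr(nnode));
  std::vector<NodeArr> G(k, NodeArr(nnode)), gscale(k, NodeArr(nnode));

  for (int sweep = 0; sweep < nsweep; ++sweep) {
    for (int j = 0; j < k; ++j) {
      int r;
      down_pass(edge, t, tips, rates[j], kappa, down[j], dscale[j], r);
      G[j][root].assign((size_t)P * 4, 0.25);
      gscale[j][root].assign(P, 0.0);
    }

    std::vector<std::vector<double> > F(k), fsc(k);
    BranchObj obj;
    obj.P = P; obj.k = k; obj.kappa = kappa;
    obj.counts = &counts[0];
    obj.rates = &rates[0];
    obj.XB.resize((size_t)k * P);
    obj.YB.resize((size_t)k * P);
    obj.ZB.resize((size_t)k * P);
    obj.b0.resize(P);
    std::vector<double> Xr((size_t)k * P), Yr((size_t)k * P), Zr((size_t)k * P),
      sc((size_t)k * P);

    for (size_t oi = 0; oi < order.size(); ++oi) {
      int u = order[oi];
      std::vector<int>& ce = childEdges[u];
      int m = (int)ce.size();
      if (m == 0) continue;

      std::vector<std::vector<std::vector<double> > >
        cctr(k, std::vector<std::vector<double> >(m)),
        ccsc(k, std::vector<std::vector<double> >(m));
      for (int j = 0; j < k; ++j)
        for (int q = 0; q < m; ++q) {
          int e = ce[q];
          child_contrib(tips, down[j], dscale[j], edge(e, 1) - 1, ntip, P,
                        t[e], rates[j], kappa, cctr[j][q], ccsc[j][q]);
        }

      for (int q = 0; q < m; ++q) {
        int e = ce[q];
        int v = edge(e, 1) - 1;

        // outside partial F for edge e: G[u] times contributions of the
        // other children of u
        for (int j = 0; j < k; ++j) {
          F[j] = G[j][u];
          fsc[j] = gscale[j][u];
          for (int q2 = 0; q2 < m; ++q2) {
            if (q2 == q) continue;
            const double* cc = &cctr[j][q2][0];
            const double* cs = &ccsc[j][q2][0];
            for (int i = 0; i < P; ++i) {
              double* f = &F[j][(size_t)i * 4];
              const double* c4 = cc + (size_t)i * 4;
              f[0] *= c4[0]; f[1] *= c4[1]; f[2] *= c4[2]; f[3] *= c4[3];
              fsc[j][i] += cs[i];
              double mx = std::max(std::max(f[0], f[1]), std::max(f[2], f[3]));
              if (mx < SCALE_THRESH && mx > 0.0) {
                f[0] *= SCALE_FACTOR; f[1] *= SCALE_FACTOR;
                f[2] *= SCALE_FACTOR; f[3] *= SCALE_FACTOR;
                fsc[j][i] += LOG_SCALE;
              }
            }
          }
        }

        // per-pattern coefficients A_ij(t) = X ps + Y pi + Z pv against
        // the subtree partial D of v
        for (int j = 0; j < k; ++j) {
          const double* fj = &F[j][0];
          const double* fscj = &fsc[j][0];
          const double* dv = (v < ntip) ? 0 : &down[j][v][0];
          const double* dsv = (v < ntip) ? 0 : &dscale[j][v][0];
          const int* col = (v < ntip) ? &tips(0, v) : 0;
          for (int i = 0; i < P; ++i) {
            const double* f = fj + (size_t)i * 4;
            double SF = f[0] + f[1] + f[2] + f[3];
            double X, Y, SD, extra = 0.0;
            if (v < ntip) {
              int s = col[i];
              if (s == 4) { X = SF; Y = SF; SD = 4.0; }
              else { X = f[s]; Y = f[s ^ 2]; SD = 1.0; }
            } else {
              const double* D = dv + (size_t)i * 4;
              X = f[0] * D[0] + f[1] * D[1] + f[2] * D[2] + f[3] * D[3];
              Y = f[0] * D[2] + f[1] * D[3] + f[2] * D[0] + f[3] * D[1];
              SD = D[0] + D[1] + D[2] + D[3];
              extra = dsv[i];
            }
            size_t o = (size_t)j * P + i;
            Xr[o] = X; Yr[o] = Y;
            Zr[o] = SF * SD - X - Y;
            sc[o] = fscj[i] + extra;
          }
        }
        // reference scale m_i at the current t, then scaled coefficients
        std::vector<PK> pk0(k);
        for (int j = 0; j < k; ++j) pk0[j] = pk_at(t[e] * rates[j], kappa, false);
        for (int i = 0; i < P; ++i) {
          double a0 = (w0 > 0.0 && l0[i] > 0.0) ? std::log(w0 * l0[i]) : R_NegInf;
          double mi = a0;
          for (int j = 0; j < k; ++j) {
            size_t o = (size_t)j * P + i;
            double A = pk0[j].ps * Xr[o] + pk0[j].pi * Yr[o] + pk0[j].pv * Zr[o];
            double a = (A > 0.0) ? std::log(weights[j + 1] * A) + sc[o] : R_NegInf;
            if (a > mi) mi = a;
          }
          if (!R_FINITE(mi)) {
            // zero total likelihood at this pattern; freeze its contribution
            obj.b0[i] = 1.0;
            for (int j = 0; j < k; ++j) {
              size_t o = (size_t)j * P + i;
              obj.XB[o] = obj.YB[o] = obj.ZB[o] = 0.0;
            }
            continue;
          }
          obj.b0[i] = R_FINITE(a0) ? std::exp(a0 - mi) : 0.0;
          for (int j = 0; j < k; ++j) {
            size_t o = (size_t)j * P + i;
            double wsc = weights[j + 1] * std::exp(sc[o] - mi);
            obj.XB[o] = wsc * Xr[o];
            obj.YB[o] = wsc * Yr[o];
            obj.ZB[o] = wsc * Zr[o];
          }
        }

        t[e] = nr_branch(obj, t[e], tmin, tmax);

        // refresh this child's contribution with its new length
        for (int j = 0; j < k; ++j)
          child_contrib(tips, down[j], dscale[j], v, ntip, P,
                        t[e], rates[j], kappa, cctr[j][q], ccsc[j][q]);
      }

      // outside partials for the internal children, with all sibling
      // lengths final
      for (int q = 0; q < m; ++q) {
        int e = ce[q];
        int v = edge(e, 1) - 1;
        if (v < ntip) continue;
        for (int j = 0; j < k; ++j) {
          std::vector<double> fv = G[j][u];
          std::vector<double> fs = gscale[j][u];
          for (int q2 = 0; q2 < m; ++q2) {
            if (q2 == q) continue;
            const double* cc = &cctr[j][q2][0];
            const double* cs = &ccsc[j][q2][0];
            for (int i = 0; i < P; ++i) {
              double* f = &fv[(size_t)i * 4];
              const double* c4 = cc + (size_t)i * 4;
              f[0] *= c4[0]; f[1] *= c4[1]; f[2] *= c4[2]; f[3] *= c4[3];
              fs[i] += cs[i];
              double mx = std::max(std::max(f[0], f[1]), std::max(f[2], f[3]));
              if (mx < SCALE_THRESH && mx > 0.0) {
                f[0] *= SCALE_FACTOR; f[1] *= SCALE_FACTOR;
                f[2] *= SCALE_FACTOR; f[3] *= SCALE_FACTOR;
                fs[i] += LOG_SCALE;
              }
            }
          }
          // push through the branch: G_v = P(t_e r_j) F_v (P is symmetric)
          PK kk = pk_at(t[e] * rates[j], kappa, false);
          G[j][v].resize((size_t)P * 4);
          gscale[j][v].resize(P);
          double* gv = &G[j][v][0];
          for (int i = 0; i < P; ++i) {
            const double* f = &fv[(size_t)i * 4];
            double T = f[0] + f[1] + f[2] + f[3];
            double* g = gv + (size_t)i * 4;
            for (int a = 0; a < 4; ++a)
              g[a] = kk.ps * f[a] + kk.pi * f[a ^ 2] + kk.pv * (T - f[a] - f[a ^ 2]);
            gscale[j][v][i] = fs[i];
            double mx = std::max(std::max(g[0], g[1]), std::max(g[2], g[3]));
            if (mx < SCALE_THRESH && mx > 0.0) {
              for (int a = 0; a < 4; ++a) g[a] *= SCALE_FACTOR;
              gscale[j][v][i] += LOG_SCALE;
            }
          }
        }
      }
    }
  }

  double ll = ig_mix_loglik_cpp(edge, t, tips, counts, l0, rates, weights, kappa);
  return List::create(_["blen"] = t, _["loglik"] = ll);
}
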