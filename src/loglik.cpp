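// Dimension-reduced marginal likelihood kernel.
//
// Model structure: units (subjects, or subject-occasions in the block
// parameterization) nested in clusters (trivial singleton clusters, sites,
// or subjects in the block parameterization). Each observed response sits in
// a row (item x occasion) with a fixed banked slope and one specific factor
// shared within its group. The marginal likelihood per cluster integrates
// the cluster factors on an outer grid, the unit general factors jointly on
// an inner grid, and each specific factor one dimension at a time (two-tier
// reduction): the maximal joint integral has dimension n_general + 1 (+1
// more at cluster level when present).
//
// Grids live on the standardized latent metric; the caller supplies, per
// occasion, the vector of distinct occasion-composite values (w_vals,
// including covariate-pattern offsets and cluster-node contributions) and an
// index array w_idx of extent (Ncl * n_patterns) x Ng mapping (cluster node,
// offset pattern, general node) to a distinct value. Response probabilities
// are then precomputed once per distinct composite value.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double plogis_c(double x) {
  if (x >= 0.0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// category probability for row r at linear predictor lp
static inline double cat_prob(const NumericMatrix &row_int, int r, int c,
                              int ncat, double lp) {
  double lo = (c == 0) ? 1.0 : plogis_c(row_int(r, c - 1) + lp);
  double hi = (c == ncat - 1) ? 0.0 : plogis_c(row_int(r, c) + lp);
  double p = lo - hi;
  return (p > 1e-300) ? p : 1e-300;
}

// [[Rcpp::export]]
List eng_estep(IntegerVector obs_row, IntegerVector obs_cat,
               IntegerVector unit_ptr, IntegerVector cluster_ptr,
               IntegerVector unit_pattern, int n_patterns,
               NumericVector row_a, NumericVector row_sload,
               IntegerVector row_group, IntegerVector row_occ,
               NumericMatrix row_int, IntegerVector row_ncat,
               int n_groups,
               NumericMatrix Theta, NumericMatrix pw_unit,
               List w_idx, List w_vals,
               NumericMatrix pw_cluster, NumericMatrix Thc,
               NumericVector xq, NumericVector wq,
               bool want_post, bool want_tables, bool want_cluster_post) {
  const int n_units = unit_ptr.size() - 1;
  const int nC = cluster_ptr.size() - 1;
  const int Ng = pw_unit.ncol();
  const int Ncl = pw_cluster.ncol();
  const int Gu = Theta.ncol();
  const int Gc = Thc.ncol();
  const int Q = xq.size();
  const int T = w_idx.size();
  const int R = row_a.size();
  const size_t stride = (size_t)Ncl * n_patterns;  // rows of each w_idx matrix
  const bool pwu_shared = pw_unit.nrow() == 1;
  const bool pwc_shared = pw_cluster.nrow() == 1;

  std::vector<const int *> Wp(T);
  std::vector<const double *> Vp(T);
  std::vector<int> Dt(T);
  std::vector<IntegerMatrix> Wm(T);
  std::vector<NumericVector> Vv(T);
  for (int t = 0; t < T; ++t) {
    Wm[t] = as<IntegerMatrix>(w_idx[t]);
    Vv[t] = as<NumericVector>(w_vals[t]);
    Wp[t] = Wm[t].begin();
    Vp[t] = Vv[t].begin();
    Dt[t] = Vv[t].size();
  }

  NumericVector ll(nC);
  NumericMatrix Egen(want_post ? n_units : 0, Gu);
  NumericMatrix Egen2(want_post ? n_units : 0, Gu * Gu);
  NumericMatrix Ecl(want_cluster_post ? nC : 0, Gc);
  NumericMatrix Ecl2(want_cluster_post ? nC : 0, Gc * Gc);

  List tables(want_tables ? R : 0);
  std::vector<double *> tabp(R, (double *)0);
  if (want_tables) {
    for (int r = 0; r < R; ++r) {
      NumericVector tb(Dt[row_occ[r]] * Q * row_ncat[r]);
      tables[r] = tb;
      tabp[r] = tb.begin();
    }
  }

  std::vector<double> ptab;
  std::vector<int> ooff, oD, oT, oR;
  std::vector<double> Lum, Sm(Ncl), postm(Ncl);
  std::vector<int> gstart, gend;

  for (int cl = 0; cl < nC; ++cl) {
    const int u0 = cluster_ptr[cl], u1 = cluster_ptr[cl + 1];
    const int nu = u1 - u0;
    const int ob0 = unit_ptr[u0], ob1 = unit_ptr[u1];
    const int nobs = ob1 - ob0;

    // --- response-probability tables over distinct composite values --------
    ooff.assign(nobs, 0); oD.assign(nobs, 0); oT.assign(nobs, 0); oR.assign(nobs, 0);
    int tot = 0;
    for (int o = 0; o < nobs; ++o) {
      int r = obs_row[ob0 + o];
      oR[o] = r; oT[o] = row_occ[r]; oD[o] = Dt[oT[o]];
      ooff[o] = tot; tot += oD[o] * Q;
    }
    ptab.assign(tot, 0.0);
    for (int o = 0; o < nobs; ++o) {
      int r = oR[o], c = obs_cat[ob0 + o], ncat = row_ncat[r], t = oT[o];
      double a = row_a[r], sl = row_sload[r];
      double *tb = &ptab[ooff[o]];
      for (int q = 0; q < Q; ++q) {
        double sx = sl * xq[q];
        for (int d = 0; d < oD[o]; ++d)
          tb[d + oD[o] * q] = cat_prob(row_int, r, c, ncat, a * Vp[t][d] + sx);
      }
    }

    // --- pass 1: unit likelihoods per cluster node --------------------------
    Lum.assign((size_t)nu * Ncl, 0.0);
    for (int uu = 0; uu < nu; ++uu) {
      const int u = u0 + uu;
      const int pu = unit_pattern[u];
      const int os = unit_ptr[u] - ob0, oe = unit_ptr[u + 1] - ob0;
      for (int m = 0; m < Ncl; ++m) {
        const size_t base = m + (size_t)Ncl * pu;
        double L = 0.0;
        for (int i = 0; i < Ng; ++i) {
          double totw = pw_unit(pwu_shared ? 0 : u, i);
          if (totw <= 0.0) continue;
          int o = os;
          while (o < oe) {
            const int g = row_group[oR[o]];
            int o2 = o;
            while (o2 < oe && row_group[oR[o2]] == g) ++o2;
            double inner = 0.0;
            for (int q = 0; q < Q; ++q) {
              double prod = wq[q];
              for (int oo = o; oo < o2; ++oo) {
                const int d = Wp[oT[oo]][base + stride * i];
                prod *= ptab[ooff[oo] + d + oD[oo] * q];
              }
              inner += prod;
            }
            totw *= inner;
            o = o2;
          }
          L += totw;
        }
        Lum[uu + (size_t)nu * m] = (L > 1e-300) ? L : 1e-300;
      }
    }

    // --- cluster-level integration ------------------------------------------
    double smax = R_NegInf;
    for (int m = 0; m < Ncl; ++m) {
      double pc = pw_cluster(pwc_shared ? 0 : cl, m);
      if (pc <= 0.0) { Sm[m] = R_NegInf; continue; }
      double s = std::log(pc);
      for (int uu = 0; uu < nu; ++uu) s += std::log(Lum[uu + (size_t)nu * m]);
      Sm[m] = s;
      if (s > smax) smax = s;
    }
    double sum = 0.0;
    for (int m = 0; m < Ncl; ++m)
      if (Sm[m] > R_NegInf) sum += std::exp(Sm[m] - smax);
    ll[cl] = smax + std::log(sum);
    for (int m = 0; m < Ncl; ++m)
      postm[m] = (Sm[m] > R_NegInf) ? std::exp(Sm[m] - ll[cl]) : 0.0;

    if (want_cluster_post && Gc > 0) {
      for (int m = 0; m < Ncl; ++m) {
        if (postm[m] <= 0.0) continue;
        for (int g = 0; g < Gc; ++g) {
          Ecl(cl, g) += postm[m] * Thc(m, g);
          for (int h = 0; h < Gc; ++h)
            Ecl2(cl, g + Gc * h) += postm[m] * Thc(m, g) * Thc(m, h);
        }
      }
    }

    // --- pass 2: unit posteriors and expected count tables -------------------
    if (want_post || want_tables) {
      for (int uu = 0; uu < nu; ++uu) {
        const int u = u0 + uu;
        const int pu = unit_pattern[u];
        const int os = unit_ptr[u] - ob0, oe = unit_ptr[u + 1] - ob0;
        gstart.clear(); gend.clear();
        {
          int o = os;
          while (o < oe) {
            const int g = row_group[oR[o]];
            int o2 = o;
            while (o2 < oe && row_group[oR[o2]] == g) ++o2;
            gstart.push_back(o); gend.push_back(o2);
            o = o2;
          }
        }
        const int nruns = gstart.size();
        std::vector<double> runinner(nruns);
        for (int m = 0; m < Ncl; ++m) {
          if (postm[m] <= 1e-14) continue;
          const size_t base = m + (size_t)Ncl * pu;
          const double wfac = postm[m] / Lum[uu + (size_t)nu * m];
          for (int i = 0; i < Ng; ++i) {
            double totw = pw_unit(pwu_shared ? 0 : u, i);
            if (totw <= 0.0) continue;
            for (int rr = 0; rr < nruns; ++rr) {
              double inner = 0.0;
              for (int q = 0; q < Q; ++q) {
                double prod = wq[q];
                for (int oo = gstart[rr]; oo < gend[rr]; ++oo) {
                  const int d = Wp[oT[oo]][base + stride * i];
                  prod *= ptab[ooff[oo] + d + oD[oo] * q];
                }
                inner += prod;
              }
              runinner[rr] = inner;
              totw *= inner;
            }
            if (totw <= 0.0) continue;
            const double wpost = wfac * totw;
            if (want_post && Gu > 0) {
              for (int g = 0; g < Gu; ++g) {
                Egen(u, g) += wpost * Theta(i, g);
                for (int h = 0; h <= g; ++h)
                  Egen2(u, g + Gu * h) += wpost * Theta(i, g) * Theta(i, h);
              }
            }
            if (want_tables) {
              for (int rr = 0; rr < nruns; ++rr) {
                if (runinner[rr] <= 1e-300) continue;
                const double wl = wpost / runinner[rr];
                for (int q = 0; q < Q; ++q) {
                  double prod = wq[q];
                  for (int oo = gstart[rr]; oo < gend[rr]; ++oo) {
                    const int d = Wp[oT[oo]][base + stride * i];
                    prod *= ptab[ooff[oo] + d + oD[oo] * q];
                  }
                  const double mass = wl * prod;
                  if (mass <= 0.0) continue;
                  for (int oo = gstart[rr]; oo < gend[rr]; ++oo) {
                    const int r = oR[oo];
                    const int d = Wp[oT[oo]][base + stride * i];
                    tabp[r][d + oD[oo] * (q + Q * obs_cat[ob0 + oo])] += mass;
                  }
                }
              }
            }
          }
        }
      }
      if (want_post && Gu > 0) {
        for (int uu = 0; uu < nu; ++uu) {
          const int u = u0 + uu;
          for (int g = 0; g < Gu; ++g)
            for (int h = g + 1; h < Gu; ++h)
              Egen2(u, g + Gu * h) = Egen2(u, h + Gu * g);
        }
      }
    }
  }

  return List::create(_["ll"] = ll, _["Egen"] = Egen, _["Egen2"] = Egen2,
                      _["Ecl"] = Ecl, _["Ecl2"] = Ecl2,
                      _["tables"] = tables);
}
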