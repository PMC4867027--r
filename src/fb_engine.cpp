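// Forward-backward likelihood engine for the stochastic TM quantal model.
//
// Hidden state: number of release-competent sites S in 0..N, tracked just
// before (S-) and just after (S+) each spike.  Release upon spike k is
// Binomial(S-, u_k) (sites releasing independently); docking over interval k
// is Binomial(N - S+, l_k).  Emission for m = S- - S+ released vesicles is
// inverse-Gaussian (mean m q, variance m sq^2), convolved with Gaussian
// baseline noise of SD sn when sn > 0.
//
// Underflow control: per-spike scaling constants plus a per-spike max-shift of
// the log-emission row; the log-likelihood is accumulated from the scalers.

#include <Rcpp.h>
using namespace Rcpp;

static inline double ig_logpdf(double y, int m, double q, double sq) {
  // mean m*q, variance m*sq^2  (y > 0)
  return 0.5 * (2.0 * std::log((double)m) + 3.0 * std::log(q)
                - std::log(2.0 * M_PI * sq * sq))
         - 1.5 * std::log(y)
         - q * (y - m * q) * (y - m * q) / (2.0 * sq * sq * y);
}

// Emission log-density and posterior moments of the latent noiseless response
// y for one (R, m) pair, by Gauss-Legendre quadrature on an interval centred
// on the Gaussian-product approximation of IG x Gaussian.
struct EmisOut {
  double logdens;
  double Ey;     // E[y | R, m]
  double Einvy;  // E[1/y | R, m]
  double dlq;    // d log dens / d q
  double dlsq;   // d log dens / d sigma_q
};

// log of the (unnormalized by neither factor) integrand
// IG(y; m q, m sq^2) * N(R - y; 0, sn)
static inline double integrand_log(double y, double R, int m, double q,
                                   double sq, double sn) {
  return ig_logpdf(y, m, q, sq)
    - 0.5 * std::log(2.0 * M_PI) - std::log(sn)
    - (R - y) * (R - y) / (2.0 * sn * sn);
}

// Laplace localization: mode and curvature width of the log-integrand by
// safeguarded Newton iterations; lpeak is the Laplace estimate of the log
// emission density.
static void laplace_mode(double R, int m, double q, double sq, double sn,
                         double& y_out, double& w_out, double& lpeak) {
  double mu = m * q;
  double v_ig = m * sq * sq;
  double v_n = sn * sn;
  double w2 = 1.0 / (1.0 / v_ig + 1.0 / v_n);
  double ctr = w2 * (mu / v_ig + R / v_n);
  double a2 = q / (2.0 * sq * sq);
  double b2 = a2 * mu * mu;
  double y = ctr > 1e-10 ? ctr : std::min(mu, 1e-3);
  double curv = -1.0 / w2;
  for (int it = 0; it < 30; ++it) {
    double y2 = y * y;
    double g = -1.5 / y - a2 + b2 / y2 + (R - y) / v_n;
    double h = 1.5 / y2 - 2.0 * b2 / (y2 * y) - 1.0 / v_n;
    double step;
    if (h < 0) step = -g / h; else step = (g > 0 ? y : -0.5 * y);
    if (step < -0.9 * y) step = -0.9 * y;   // keep y > 0
    if (std::fabs(step) > 5.0 * y) step = (step > 0 ? 5.0 : -5.0) * y;
    y += step;
    if (h < 0) curv = h;
    if (std::fabs(step) < 1e-10 * y) break;
  }
  y_out = y;
  w_out = (curv < 0) ? 1.0 / std::sqrt(-curv) : std::sqrt(w2);
  lpeak = integrand_log(y, R, m, q, sq, sn)
    + 0.5 * std::log(2.0 * M_PI) + std::log(w_out);
}

static EmisOut emission_node(double R, int m, double q, double sq, double sn,
                             const std::vector<double>& glx,
                             const std::vector<double>& glw,
                             bool want_moments, bool want_derivs) {
  EmisOut out = {R_NegInf, 0.0, 0.0, 0.0, 0.0};
  if (m == 0) {
    if (sn > 0) {
      out.logdens = R::dnorm(R, 0.0, sn, 1);
    } else {
      out.logdens = (std::fabs(R) < 1e-12) ? 0.0 : R_NegInf;
    }
    return out;  // no dependence on q, sigma_q; no latent y
  }
  if (sn <= 0) {
    if (R <= 0) return out;
    out.logdens = ig_logpdf(R, m, q, sq);
    out.Ey = R;
    out.Einvy = 1.0 / R;
    if (want_derivs) {
      double y = R;
      out.dlq = 1.5 / q
        - (y * y - 4.0 * m * q * y + 3.0 * m * m * q * q) / (2.0 * sq * sq * y);
      out.dlsq = -1.0 / sq + q * (y - m * q) * (y - m * q) / (sq * sq * sq * y);
    }
    return out;
  }
  double ym, wL, lpeak;
  laplace_mode(R, m, q, sq, sn, ym, wL, lpeak);
  // Composite Gauss-Legendre segments: a Laplace window around the mode,
  // extended (as extra segments) to cover the Gaussian noise window when the
  // quantal distribution is heavy-tailed and mass extends beyond it.
  // core panel around the mode, a separate panel for the long right tail of
  // the skewed quantal density, and extensions to the Gaussian noise window
  double s1lo = std::max(1e-12, ym - 12.0 * wL);
  double smid = ym + 6.0 * wL;
  double s1hi = std::max(ym + 30.0 * wL, s1lo * (1.0 + 1e-8) + 1e-12);
  double glo = std::max(1e-12, R - 13.0 * sn);
  double ghi = R + 13.0 * sn;
  double brk[5];
  int nbrk = 0;
  if (glo < s1lo) brk[nbrk++] = glo;
  brk[nbrk++] = s1lo;
  if (smid > s1lo && smid < s1hi) brk[nbrk++] = smid;
  brk[nbrk++] = s1hi;
  if (ghi > s1hi) brk[nbrk++] = ghi;
  int n = glx.size();
  int nv = 0;
  double yv[512], wv[512], lf[512];
  double mx = R_NegInf;
  for (int s = 0; s + 1 < nbrk; ++s) {
    double half = 0.5 * (brk[s + 1] - brk[s]);
    double mid = 0.5 * (brk[s + 1] + brk[s]);
    if (half <= 0) continue;
    for (int j = 0; j < n && nv < 512; ++j) {
      yv[nv] = mid + half * glx[j];
      wv[nv] = half * glw[j];
      ++nv;
    }
  }
  for (int j = 0; j < nv; ++j) {
    lf[j] = integrand_log(yv[j], R, m, q, sq, sn);
    if (lf[j] > mx) mx = lf[j];
  }
  if (!R_finite(mx)) return out;
  double Z = 0.0, Sy = 0.0, Siy = 0.0, Sdq = 0.0, Sdsq = 0.0;
  for (int j = 0; j < nv; ++j) {
    double e = std::exp(lf[j] - mx) * wv[j];
    Z += e;
    if (want_moments) { Sy += e * yv[j]; Siy += e / yv[j]; }
    if (want_derivs) {
      double y = yv[j];
      double dq = 1.5 / q
        - (y * y - 4.0 * m * q * y + 3.0 * m * m * q * q) / (2.0 * sq * sq * y);
      double dsq = -1.0 / sq + q * (y - m * q) * (y - m * q) / (sq * sq * sq * y);
      Sdq += e * dq;
      Sdsq += e * dsq;
    }
  }
  if (Z <= 0) return out;
  out.logdens = mx + std::log(Z);
  if (want_moments) { out.Ey = Sy / Z; out.Einvy = Siy / Z; }
  if (want_derivs) { out.dlq = Sdq / Z; out.dlsq = Sdsq / Z; }
  return out;
}

// binomial pmf row P(j | n, p), j = 0..n, by the multiplicative recurrence
// (falls back to R::dbinom when the first term underflows)
static void binom_row(double* row, int n, double p) {
  if (n == 0) { row[0] = 1.0; return; }
  if (p <= 0.0) { for (int j = 0; j <= n; ++j) row[j] = 0.0; row[0] = 1.0; return; }
  if (p >= 1.0) { for (int j = 0; j <= n; ++j) row[j] = 0.0; row[n] = 1.0; return; }
  double p0 = std::pow(1.0 - p, n);
  if (p0 > 0.0 && R_finite(p0)) {
    double r = p / (1.0 - p);
    row[0] = p0;
    for (int j = 1; j <= n; ++j)
      row[j] = row[j - 1] * r * (double)(n - j + 1) / (double)j;
  } else {
    for (int j = 0; j <= n; ++j) row[j] = R::dbinom(j, n, p, 0);
  }
}

// release transition matrix for one spike: rel(s-, s+) = P(S+ = s+ | S- = s-)
static void fill_release(std::vector<double>& rel, int N, double u) {
  int K = N + 1;
  std::fill(rel.begin(), rel.end(), 0.0);
  std::vector<double> row(K);
  for (int sm = 0; sm <= N; ++sm) {
    binom_row(row.data(), sm, u);       // row[j] = P(j released | sm)
    for (int sp = 0; sp <= sm; ++sp)
      rel[sm * K + sp] = row[sm - sp];
  }
}

// docking transition: dock(s+, s-') = P(S-' | S+), s-' >= s+
static void fill_dock(std::vector<double>& dock, int N, double l) {
  int K = N + 1;
  std::fill(dock.begin(), dock.end(), 0.0);
  std::vector<double> row(K);
  for (int sp = 0; sp <= N; ++sp) {
    binom_row(row.data(), N - sp, l);   // row[j] = P(j dockings | N - sp empty)
    for (int sm = sp; sm <= N; ++sm)
      dock[sp * K + sm] = row[sm - sp];
  }
}

// [[Rcpp::export(name = ".cpp_fb_trial")]]
List cpp_fb_trial(NumericVector R, NumericVector u, NumericVector l,
                  int N, double q, double sq, double sn,
                  NumericVector gl_x, NumericVector gl_w,
                  bool want_tables, bool want_pairs, bool want_stats) {
  int M = R.size();
  int K = N + 1;
  std::vector<double> glx(gl_x.begin(), gl_x.end());
  std::vector<double> glw(gl_w.begin(), gl_w.end());

  // emissions (shifted per spike) and latent-response moments
  NumericMatrix logE(M, K);
  NumericMatrix Ey(want_stats ? M : 1, want_stats ? K : 1);
  NumericMatrix Einvy(want_stats ? M : 1, want_stats ? K : 1);
  for (int k = 0; k < M; ++k)
    for (int m = 0; m < K; ++m) {
      EmisOut e = emission_node(R[k], m, q, sq, sn, glx, glw, want_stats, false);
      logE(k, m) = e.logdens;
      if (want_stats) { Ey(k, m) = e.Ey; Einvy(k, m) = e.Einvy; }
    }

  std::vector<double> rel(K * K), dock(K * K);
  NumericMatrix am(M, K), ap(M, K);  // scaled alpha-, alpha+
  NumericVector logc(M);             // per-spike log scaling (incl. shift)
  std::vector<double> Es(K);

  // forward
  for (int s = 0; s < K; ++s) am(0, s) = 0.0;
  am(0, N) = 1.0;
  double loglik = 0.0;
  for (int k = 0; k < M; ++k) {
    double shift = R_NegInf;
    for (int m = 0; m < K; ++m) if (logE(k, m) > shift) shift = logE(k, m);
    if (!R_finite(shift))
      stop("all emission densities vanished at spike %d (response %g mV)",
           k + 1, R[k]);
    for (int m = 0; m < K; ++m) Es[m] = std::exp(logE(k, m) - shift);
    fill_release(rel, N, u[k]);
    double c = 0.0;
    for (int sp = 0; sp < K; ++sp) {
      double acc = 0.0;
      for (int sm = sp; sm < K; ++sm)
        acc += am(k, sm) * rel[sm * K + sp] * Es[sm - sp];
      ap(k, sp) = acc;
      c += acc;
    }
    if (!(c > 0) || !R_finite(c))
      stop("forward scaling failed at spike %d", k + 1);
    for (int sp = 0; sp < K; ++sp) ap(k, sp) /= c;
    logc[k] = std::log(c) + shift;
    loglik += logc[k];
    if (k + 1 < M) {
      fill_dock(dock, N, l[k]);
      for (int sm = 0; sm < K; ++sm) {
        double acc = 0.0;
        for (int sp = 0; sp <= sm; ++sp)
          acc += ap(k, sp) * dock[sp * K + sm];
        am(k + 1, sm) = acc;
      }
    }
  }

  // backward (scaled with the same per-spike constants)
  NumericMatrix bm(M, K), bp(M, K);
  for (int s = 0; s < K; ++s) bp(M - 1, s) = 1.0;
  for (int k = M - 1; k >= 0; --k) {
    double shift = R_NegInf;
    for (int m = 0; m < K; ++m) if (logE(k, m) > shift) shift = logE(k, m);
    for (int m = 0; m < K; ++m) Es[m] = std::exp(logE(k, m) - shift);
    fill_release(rel, N, u[k]);
    double cinv = std::exp(std::log(1.0) - (logc[k] - shift));
    for (int sm = 0; sm < K; ++sm) {
      double acc = 0.0;
      for (int sp = 0; sp <= sm; ++sp)
        acc += rel[sm * K + sp] * Es[sm - sp] * bp(k, sp);
      bm(k, sm) = acc * cinv;
    }
    if (k > 0) {
      fill_dock(dock, N, l[k - 1]);
      for (int sp = 0; sp < K; ++sp) {
        double acc = 0.0;
        for (int sm = sp; sm < K; ++sm)
          acc += dock[sp * K + sm] * bm(k, sm);
        bp(k - 1, sp) = acc;
      }
    }
  }

  // pair posteriors and E-step statistics
  NumericMatrix w_m;      // posterior of released count, M x K
  NumericVector ESm(M), ESp(M);
  double Sa = 0.0, Smm = 0.0, Sb2 = 0.0, W = 0.0;
  NumericVector pairs;
  if (want_pairs) { pairs = NumericVector(Dimension(M, K, K)); }
  if (want_stats || want_pairs) {
    w_m = NumericMatrix(M, K);
    for (int k = 0; k < M; ++k) {
      double shift = R_NegInf;
      for (int m = 0; m < K; ++m) if (logE(k, m) > shift) shift = logE(k, m);
      for (int m = 0; m < K; ++m) Es[m] = std::exp(logE(k, m) - shift);
      fill_release(rel, N, u[k]);
      double cinv = std::exp(-(logc[k] - shift));
      double tot = 0.0;
      for (int sm = 0; sm < K; ++sm)
        for (int sp = 0; sp <= sm; ++sp) {
          double p = am(k, sm) * rel[sm * K + sp] * Es[sm - sp]
                     * bp(k, sp) * cinv;
          tot += p;
          if (want_pairs) pairs[k + M * (sm + K * sp)] = p;
          w_m(k, sm - sp) += p;
          ESm[k] += p * sm;
          ESp[k] += p * sp;
        }
      // tot == 1 up to roundoff; renormalize defensively
      if (tot > 0 && std::fabs(tot - 1.0) > 1e-12) {
        for (int m = 0; m < K; ++m) w_m(k, m) /= tot;
        ESm[k] /= tot; ESp[k] /= tot;
        if (want_pairs)
          for (int sm = 0; sm < K; ++sm)
            for (int sp = 0; sp < K; ++sp)
              pairs[k + M * (sm + K * sp)] /= tot;
      }
      if (want_stats)
        for (int m = 1; m < K; ++m) {
          double wm = w_m(k, m);
          if (wm <= 0) continue;
          Sa += wm * Ey(k, m);
          Smm += wm * m;
          Sb2 += wm * m * m * Einvy(k, m);
          W += wm;
        }
    }
  }

  List out = List::create(
    _["log_likelihood"] = loglik,
    _["log_scalers"] = logc);
  if (want_tables) {
    out["alpha_minus"] = am; out["alpha_plus"] = ap;
    out["beta_minus"] = bm; out["beta_plus"] = bp;
    out["log_emission"] = logE;
  }
  if (want_pairs) out["pairs"] = pairs;
  if (want_stats || want_pairs) {
    out["w_released"] = w_m;
    out["E_s_minus"] = ESm;
    out["E_s_plus"] = ESp;
  }
  if (want_stats) {
    out["Sa"] = Sa; out["Sm"] = Smm; out["Sb2"] = Sb2; out["W"] = W;
  }
  return out;
}

// Batched E step for a group of trials sharing one spike-train skeleton:
// the release/docking transition matrices are built once per spike and the
// per-trial forward-backward passes accumulate the aggregated sufficient
// statistics.  Emissions in the deep mutual tail (peak more than ~45 log
// units below the per-spike maximum) are replaced by their Laplace
// approximation: their posterior weight is < 1e-19.
// [[Rcpp::export(name = ".cpp_em_group")]]
List cpp_em_group(NumericMatrix Rm, NumericVector u, NumericVector l,
                  int N, double q, double sq, double sn,
                  NumericVector gl_x, NumericVector gl_w) {
  int n_tr = Rm.nrow();
  int M = Rm.ncol();
  int K = N + 1;
  std::vector<double> glx(gl_x.begin(), gl_x.end());
  std::vector<double> glw(gl_w.begin(), gl_w.end());

  std::vector< std::vector<double> > rel(M, std::vector<double>(K * K));
  std::vector< std::vector<double> > dock(std::max(M - 1, 0),
                                          std::vector<double>(K * K));
  for (int k = 0; k < M; ++k) fill_release(rel[k], N, u[k]);
  for (int k = 0; k < M - 1; ++k) fill_dock(dock[k], N, l[k]);

  NumericVector E_released(M), E_s_plus(M), E_s_minus(M);
  double Sa = 0.0, Smm = 0.0, Sb2 = 0.0, W = 0.0, loglik = 0.0;

  std::vector<double> logE(K), Ey(K), Einvy(K), bm(K);
  std::vector<double> am(M * K), ap(M * K), bp(M * K), logc(M), shift(M);
  std::vector<double> EyStore(M * K), EiStore(M * K);
  std::vector< std::vector<double> > EsAll(M, std::vector<double>(K));
  std::vector<double> ypk(K), wpk(K), lpk(K);

  for (int t = 0; t < n_tr; ++t) {
    // forward
    std::fill(am.begin(), am.end(), 0.0);
    am[0 * K + N] = 1.0;
    for (int k = 0; k < M; ++k) {
      double R = Rm(t, k);
      double mx = R_NegInf;
      for (int m = 0; m < K; ++m) {
        if (m == 0) {
          lpk[0] = (sn > 0) ? R::dnorm(R, 0.0, sn, 1)
                            : ((std::fabs(R) < 1e-12) ? 0.0 : R_NegInf);
          ypk[0] = 0.0; wpk[0] = 0.0;
        } else if (sn <= 0) {
          lpk[m] = (R > 0) ? ig_logpdf(R, m, q, sq) : R_NegInf;
          ypk[m] = R; wpk[m] = 0.0;
        } else {
          laplace_mode(R, m, q, sq, sn, ypk[m], wpk[m], lpk[m]);
        }
        if (lpk[m] > mx) mx = lpk[m];
      }
      if (!R_finite(mx))
        stop("all emission densities vanished at spike %d (response %g mV)",
             k + 1, R);
      for (int m = 0; m < K; ++m) {
        if (m == 0 || sn <= 0 || lpk[m] < mx - 30.0) {
          logE[m] = lpk[m];
          Ey[m] = ypk[m];
          Einvy[m] = (ypk[m] > 0) ? 1.0 / ypk[m] : 0.0;
          if (sn <= 0 && m > 0 && R > 0) { Ey[m] = R; Einvy[m] = 1.0 / R; }
        } else {
          EmisOut e = emission_node(R, m, q, sq, sn, glx, glw, true, false);
          logE[m] = e.logdens;
          Ey[m] = e.Ey;
          Einvy[m] = e.Einvy;
        }
      }
      double sh = R_NegInf;
      for (int m = 0; m < K; ++m) if (logE[m] > sh) sh = logE[m];
      shift[k] = sh;
      for (int m = 0; m < K; ++m) EsAll[k][m] = std::exp(logE[m] - sh);
      double c = 0.0;
      for (int sp = 0; sp < K; ++sp) {
        double acc = 0.0;
        for (int sm = sp; sm < K; ++sm)
          acc += am[k * K + sm] * rel[k][sm * K + sp] * EsAll[k][sm - sp];
        ap[k * K + sp] = acc;
        c += acc;
      }
      if (!(c > 0) || !R_finite(c))
        stop("forward scaling failed at spike %d", k + 1);
      for (int sp = 0; sp < K; ++sp) ap[k * K + sp] /= c;
      logc[k] = std::log(c) + sh;
      loglik += logc[k];
      if (k + 1 < M)
        for (int sm = 0; sm < K; ++sm) {
          double acc = 0.0;
          for (int sp = 0; sp <= sm; ++sp)
            acc += ap[k * K + sp] * dock[k][sp * K + sm];
          am[(k + 1) * K + sm] = acc;
        }
      // stash the latent-response moments for the stats pass
      std::copy(Ey.begin(), Ey.end(), EyStore.begin() + k * K);
      std::copy(Einvy.begin(), Einvy.end(), EiStore.begin() + k * K);
    }
    // backward + pair stats
    for (int s = 0; s < K; ++s) bp[(M - 1) * K + s] = 1.0;
    for (int k = M - 1; k >= 0; --k) {
      double cinv = std::exp(-(logc[k] - shift[k]));
      // pair stats at spike k (normalized per spike against roundoff)
      double tot = 0.0, e_rel = 0.0, e_sp = 0.0, e_sm = 0.0;
      double sa = 0.0, smm = 0.0, sb2 = 0.0, ww = 0.0;
      for (int sm = 0; sm < K; ++sm) {
        double a_k = am[k * K + sm];
        if (a_k == 0.0) continue;
        for (int sp = 0; sp <= sm; ++sp) {
          double p = a_k * rel[k][sm * K + sp] * EsAll[k][sm - sp]
                     * bp[k * K + sp] * cinv;
          if (p <= 0) continue;
          int m = sm - sp;
          tot += p;
          e_rel += p * m;
          e_sp += p * sp;
          e_sm += p * sm;
          if (m > 0) {
            sa += p * EyStore[k * K + m];
            smm += p * m;
            sb2 += p * m * m * EiStore[k * K + m];
            ww += p;
          }
        }
      }
      if (tot > 0) {
        E_released[k] += e_rel / tot;
        E_s_plus[k] += e_sp / tot;
        E_s_minus[k] += e_sm / tot;
        Sa += sa / tot;
        Smm += smm / tot;
        Sb2 += sb2 / tot;
        W += ww / tot;
      }
      if (k > 0) {
        for (int sm = 0; sm < K; ++sm) {
          double acc = 0.0;
          for (int sp2 = 0; sp2 <= sm; ++sp2)
            acc += rel[k][sm * K + sp2] * EsAll[k][sm - sp2]
                   * bp[k * K + sp2];
          bm[sm] = acc * cinv;
        }
        for (int sp = 0; sp < K; ++sp) {
          double acc = 0.0;
          for (int sm = sp; sm < K; ++sm)
            acc += dock[k - 1][sp * K + sm] * bm[sm];
          bp[(k - 1) * K + sp] = acc;
        }
      }
    }
  }
  return List::create(_["log_likelihood"] = loglik,
                      _["E_released"] = E_released,
                      _["E_s_plus"] = E_s_plus,
                      _["E_s_minus"] = E_s_minus,
                      _["Sa"] = Sa, _["Sm"] = Smm, _["Sb2"] = Sb2,
                      _["W"] = W, _["n_trials"] = n_tr);
}

// Score (gradient of the log-likelihood) over the continuous parameters
// (q, sigma_q, U, tau_D, tau_F), by forward-derivative recursions: the
// derivative arrays are propagated alongside the scaled forward variables.
// [[Rcpp::export(name = ".cpp_score_trial")]]
NumericVector cpp_score_trial(NumericVector R, NumericVector u, NumericVector l,
                              NumericVector du_dU, NumericVector du_dtF,
                              NumericVector dl_dtD,
                              int N, double q, double sq, double sn,
                              NumericVector gl_x, NumericVector gl_w) {
  const int P = 5;  // q, sq, U, tD, tF
  int M = R.size();
  int K = N + 1;
  std::vector<double> glx(gl_x.begin(), gl_x.end());
  std::vector<double> glw(gl_w.begin(), gl_w.end());

  std::vector<double> a(K, 0.0), a_new(K), Es(K), dq(K), dsq(K);
  std::vector< std::vector<double> > G(P, std::vector<double>(K, 0.0));
  std::vector< std::vector<double> > Gn(P, std::vector<double>(K, 0.0));
  std::vector<double> rel(K * K), dock(K * K);
  a[N] = 1.0;

  std::vector<double> lE(K), lpk(K), ypk(K), wpk(K);
  for (int k = 0; k < M; ++k) {
    double shift = R_NegInf;
    double pkmax = R_NegInf;
    for (int m = 0; m < K; ++m) {
      if (m == 0 || sn <= 0) {
        lpk[m] = R_NegInf;  // handled exactly below
      } else {
        laplace_mode(R[k], m, q, sq, sn, ypk[m], wpk[m], lpk[m]);
        if (lpk[m] > pkmax) pkmax = lpk[m];
      }
    }
    for (int m = 0; m < K; ++m) {
      if (m > 0 && sn > 0 && lpk[m] < pkmax - 35.0) {
        // deep mutual tail: Laplace value, negligible derivative weight
        lE[m] = lpk[m];
        dq[m] = 0.0;
        dsq[m] = 0.0;
      } else {
        EmisOut e = emission_node(R[k], m, q, sq, sn, glx, glw, false, true);
        lE[m] = e.logdens;
        dq[m] = e.dlq;
        dsq[m] = e.dlsq;
      }
      if (lE[m] > shift) shift = lE[m];
    }
    if (!R_finite(shift)) stop("emission vanished at spike %d", k + 1);
    for (int m = 0; m < K; ++m) Es[m] = std::exp(lE[m] - shift);
    fill_release(rel, N, u[k]);
    double uk = u[k];
    double c = 0.0;
    for (int p = 0; p < P; ++p) std::fill(Gn[p].begin(), Gn[p].end(), 0.0);
    for (int sp = 0; sp < K; ++sp) {
      double acc = 0.0;
      double accG[P] = {0, 0, 0, 0, 0};
      for (int sm = sp; sm < K; ++sm) {
        int m = sm - sp;
        double T = rel[sm * K + sp] * Es[m];
        if (T == 0.0 && a[sm] == 0.0) {
          // still propagate derivative flow through G terms
        }
        acc += a[sm] * T;
        // emission derivatives (q, sigma_q)
        accG[0] += a[sm] * T * dq[m];
        accG[1] += a[sm] * T * dsq[m];
        // release derivative wrt u, chained to U and tau_F
        double dlrel = 0.0;
        if (m > 0) dlrel += m / uk;
        if (sp > 0 && uk < 1.0) dlrel -= sp / (1.0 - uk);
        accG[2] += a[sm] * T * dlrel * du_dU[k];
        accG[4] += a[sm] * T * dlrel * du_dtF[k];
        for (int p = 0; p < P; ++p) accG[p] += G[p][sm] * T;
      }
      a_new[sp] = acc;
      c += acc;
      for (int p = 0; p < P; ++p) Gn[p][sp] = accG[p];
    }
    for (int sp = 0; sp < K; ++sp) {
      a[sp] = a_new[sp] / c;
      for (int p = 0; p < P; ++p) G[p][sp] = Gn[p][sp] / c;
    }
    if (k + 1 < M) {
      fill_dock(dock, N, l[k]);
      double lk = l[k];
      for (int p = 0; p < P; ++p) std::fill(Gn[p].begin(), Gn[p].end(), 0.0);
      for (int sm = 0; sm < K; ++sm) {
        double acc = 0.0;
        double accG[P] = {0, 0, 0, 0, 0};
        for (int sp = 0; sp <= sm; ++sp) {
          double T = dock[sp * K + sm];
          acc += a[sp] * T;
          int d = sm - sp;
          double dldock = 0.0;
          if (d > 0) dldock += d / lk;
          if (sm < N && lk < 1.0) dldock -= (N - sm) / (1.0 - lk);
          accG[3] += a[sp] * T * dldock * dl_dtD[k];
          for (int p = 0; p < P; ++p) accG[p] += G[p][sp] * T;
        }
        a_new[sm] = acc;
        for (int p = 0; p < P; ++p) Gn[p][sm] = accG[p];
      }
      for (int sm = 0; sm < K; ++sm) {
        a[sm] = a_new[sm];
        for (int p = 0; p < P; ++p) G[p][sm] = Gn[p][sm];
      }
    }
  }
  double atot = 0.0;
  for (int s = 0; s < K; ++s) atot += a[s];
  NumericVector score(P);
  for (int p = 0; p < P; ++p) {
    double g = 0.0;
    for (int s = 0; s < K; ++s) g += G[p][s];
    score[p] = g / atot;
  }
  score.names() = CharacterVector::create("q", "sigma_q", "U", "tau_D", "tau_F");
  return score;
}
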