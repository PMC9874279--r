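// Compiled tendency of the coupled transport-reaction-isotope system.
// Mirrors the reference R implementation (model_tendency / network_rates)
// exactly; a parity test in the test suite asserts agreement.

#include <Rcpp.h>
using namespace Rcpp;

static inline double pos(double x) { return x > 0 ? x : 0.0; }

// Monod fraction, C1-regularized at zero: exactly zero for empty
// pools, quadratic onset over ~K/10, Monod beyond
static inline double mon(double x, double K) {
  if (x <= 0) return 0.0;
  double q = x * x / (x + 0.1 * K);
  return q / (q + K);
}

// smooth positive part used for the mineral saturation switch
static inline double spl(double x) {
  const double pw2 = 1e-4;
  return 0.5 * (x + std::sqrt(x * x + pw2));
}

// fraction 56R/R drawn from a source pool (fractionation-limited)
static inline double hrf(double bulk, double heavy, double alpha,
                         double clim) {
  if (bulk < 0) bulk = 0;
  if (heavy < 0) heavy = 0;
  if (heavy > bulk) heavy = bulk;
  double light = bulk - heavy;
  if (bulk >= clim && light > 0) {
    double ar = alpha * heavy / light;
    return ar / (1.0 + ar);
  }
  return bulk > 0 ? heavy / bulk : 0.0;
}

// multiplier on k_ads for the heavy isotope
static inline double k56f(double bulk, double heavy, double alpha) {
  if (bulk < 0) bulk = 0;
  if (heavy < 0) heavy = 0;
  if (heavy > bulk) heavy = bulk;
  double light = bulk - heavy;
  if (light > 0) {
    double r = heavy / light;
    return alpha * (1.0 + r) / (1.0 + alpha * r);
  }
  return 1.0;
}

// [[Rcpp::export]]
NumericVector tendency_cpp(NumericVector y, List P) {
  const int n = as<int>(P["n"]);
  const int ns = as<int>(P["ns"]);
  NumericMatrix GD = P["GD"], GA = P["GA"], ALPHA = P["ALPHA"], CAP = P["CAP"];
  NumericVector bc = P["bc"], dz = P["dz"], sv = P["sv"];
  IntegerVector is_sol = P["is_solute"];
  NumericVector sgd = P["solid_gd"], sga = P["solid_ga"];
  IntegerVector idx = P["idx"];           // 0-based, -1 when absent
  NumericVector kin = P["kin"];
  NumericVector pock = P["poc_k"], ksul = P["ksul"];
  NumericVector al = P["alphas"];         // red, ox, sorp, pre, dis, pyr
  const bool site = as<bool>(P["site"]);

  // species column offsets
  enum {iO2, iNO3, iNH4, iMn, iSO4, iHS, iCH4, iDFe, iPOC1, iPOC2, iPOC3,
        iMnO2, iFeHR, iFeMR, iFePR, iFeU, iFeS, iFeS2, iS0,
        iDFe56, iFeHR56, iFeMR56, iFePR56, iFeU56, iFeS56, iFeS256, NIDX};
  int off[NIDX];
  for (int k = 0; k < NIDX; ++k)
    off[k] = idx[k] >= 0 ? idx[k] * n : -1;
  const double *Y = y.begin();
  NumericVector out(n * ns);
  double *D = out.begin();

  // kinetic constants (order fixed by the R wrapper)
  const double K_O2 = kin[0], K_NO3 = kin[1], K_MnO2 = kin[2],
    K_FeHR = kin[3], K_SO4 = kin[4], k_nit = kin[5], k_mnox = kin[6],
    k_feox = kin[7], k_sox = kin[8], k_ch4ox = kin[9], k_aom = kin[10],
    k_s0ox = kin[11], p_s0 = kin[12], K_FeS = kin[13], k_fes_pre = kin[14],
    k_fes_dis = kin[15], k_pyr_hs = kin[16], k_pyr_s0 = kin[17],
    k_fes_ox = kin[18], k_pyr_ox = kin[19], k_age = kin[20],
    k_ads = kin[21], rNC = kin[22], c_lim = kin[23],
    k_femnox = kin[24], wa_dir = kin[25];
  const double a_red = al[0], a_ox = al[1], a_sorp = al[2], a_pre = al[3],
    a_dis = al[4], a_pyr = al[5];

  // ---- transport: interface fluxes per species column ----------------
  std::vector<double> F(n + 1);
  for (int j = 0; j < ns; ++j) {
    const double *C = Y + j * n;
    const double b = bc[j];
    if (is_sol[j]) {
      F[0] = GD(0, j) * (b - C[0]) + GA(0, j) * b;
    } else {
      F[0] = b;                      // imposed deposition flux
    }
    for (int i = 1; i < n; ++i)
      F[i] = GD(i, j) * (C[i - 1] - C[i]) + GA(i, j) * C[i - 1];
    F[n] = GA(n, j) * C[n - 1];
    double *d = D + j * n;
    for (int i = 0; i < n; ++i) {
      d[i] = (F[i] - F[i + 1]) / dz[i];
      if (is_sol[j]) d[i] -= ALPHA(i, j) * (C[i] - b);
    }
  }

  // ---- solid-phase transport of the adsorbed ferrous pools -----------
  {
    const double *dfe = Y + off[iDFe], *dfe56 = Y + off[iDFe56];
    std::vector<double> ads(n), ads56(n);
    for (int i = 0; i < n; ++i) {
      double c = pos(dfe[i]);
      double c56 = pos(dfe56[i]); if (c56 > c) c56 = c;
      ads[i] = k_ads * c;
      ads56[i] = k_ads * k56f(c, c56, a_sorp) * c56;
    }
    double *d1 = D + off[iDFe], *d2 = D + off[iDFe56];
    for (int rep = 0; rep < 2; ++rep) {
      const std::vector<double> &a = rep == 0 ? ads : ads56;
      double *d = rep == 0 ? d1 : d2;
      F[0] = 0.0;
      for (int i = 1; i < n; ++i)
        F[i] = sgd[i] * (a[i - 1] - a[i]) + sga[i] * a[i - 1];
      F[n] = sga[n] * a[n - 1];
      for (int i = 0; i < n; ++i) d[i] += (F[i] - F[i + 1]) / dz[i];
    }
  }

  // ---- reaction network, cell by cell --------------------------------
  for (int i = 0; i < n; ++i) {
    const double s = sv[i];          // 1 - porosity
    const double phi = 1.0 - s;
    #define GET(K) (off[K] >= 0 ? Y[off[K] + i] : 0.0)
    #define ADD(K, V) if (off[K] >= 0) D[off[K] + i] += (V)
    const double O2 = GET(iO2), NO3 = GET(iNO3), NH4 = GET(iNH4),
      Mn = GET(iMn), SO4 = GET(iSO4), HS = GET(iHS), CH4 = GET(iCH4),
      DFe = GET(iDFe), MnO2 = GET(iMnO2), FeHR = GET(iFeHR),
      FeMR = GET(iFeMR), FePR = GET(iFePR), FeS = GET(iFeS),
      FeS2 = GET(iFeS2), S0 = GET(iS0);

    // multi-G decay and the oxidant cascade
    const double dP1 = pock[0] * GET(iPOC1), dP2 = pock[1] * GET(iPOC2),
      dP3 = pock[2] * GET(iPOC3);
    const double Cdec = s * (dP1 + dP2 + dP3);
    double fO2 = mon(O2, K_O2);
    double rem = 1.0 - fO2, fNO3 = 0.0, fMnO2 = 0.0;
    if (!site) {
      fNO3 = mon(NO3, K_NO3) * rem; rem -= fNO3;
      fMnO2 = mon(MnO2, K_MnO2) * rem; rem -= fMnO2;
    }
    const double dirpool = pos(FeHR) + wa_dir * pos(FeMR);
    double fFe = mon(dirpool, K_FeHR) * rem; rem -= fFe;
    double fSO4 = mon(SO4, K_SO4) * rem;
    double fCH4 = rem - fSO4;
    const double R_dir = 4.0 * fFe * Cdec;
    const double sh_f = dirpool > 1e-300 ? pos(FeHR) / dirpool : 1.0;
    const double R_dir_f = R_dir * sh_f;
    const double R_dir_a = R_dir - R_dir_f;

    // secondary redox
    const double R_nit = site ? 0.0 : k_nit * O2 * NH4 * phi;
    const double R_mnox = site ? 0.0 : k_mnox * O2 * Mn * phi;
    const double R_feox = k_feox * O2 * DFe * phi;
    const double R_femnox = site ? 0.0 : k_femnox * DFe * MnO2 * s;
    const double R_sox = k_sox * O2 * HS * phi;
    const double R_ch4ox = k_ch4ox * O2 * CH4 * phi;
    const double R_aom = k_aom * SO4 * CH4 * phi;
    const double R_s0ox = k_s0ox * S0 * O2 * s;

    // sulfide-mediated oxide reduction
    const double R_sul_HR = ksul[0] * FeHR * HS * s;
    const double R_sul_MR = ksul[1] * FeMR * HS * s;
    const double R_sul_PR = (!site && ksul.size() > 2)
      ? ksul[2] * FePR * HS * s : 0.0;
    const double R_sul = R_sul_HR + R_sul_MR + R_sul_PR;

    // iron-sulfide system
    const double omega = DFe * HS / K_FeS;
    const double sat = spl(1.0 - 1.0 / (omega > 1e-12 ? omega : 1e-12));
    const double R_pre = k_fes_pre * DFe * HS * sat * phi;
    const double R_dis = k_fes_dis * FeS * spl(1.0 - omega) * s;
    const double R_pyr1 = k_pyr_hs * FeS * HS * s;
    const double R_pyr2 = k_pyr_s0 * FeS * S0 * s;
    const double R_fesox = k_fes_ox * FeS * O2 * s;
    const double R_pyrox = k_pyr_ox * FeS2 * O2 * s;
    const double R_age = k_age * FeHR * s;

    ADD(iO2, -fO2 * Cdec - 2.0 * R_nit - 0.5 * R_mnox - 0.25 * R_feox -
        (2.0 * (1.0 - p_s0) + 0.5 * p_s0) * R_sox - 2.0 * R_ch4ox -
        2.0 * R_fesox - 3.5 * R_pyrox - 1.5 * R_s0ox);
    ADD(iSO4, -0.5 * fSO4 * Cdec + (1.0 - p_s0) * R_sox + R_fesox +
        2.0 * R_pyrox + R_s0ox - R_aom);
    ADD(iHS, 0.5 * fSO4 * Cdec - R_sox - 0.5 * R_sul - R_pre + R_dis -
        R_pyr1 + R_aom);
    ADD(iCH4, 0.5 * fCH4 * Cdec - R_ch4ox - R_aom);
    ADD(iDFe, R_dir + R_sul + R_dis + R_fesox + R_pyrox - R_feox -
        R_femnox - R_pre);
    ADD(iPOC1, -s * dP1);
    ADD(iPOC2, -s * dP2);
    ADD(iPOC3, -s * dP3);
    ADD(iFeHR, -R_dir_f - R_sul_HR - R_age + R_feox + R_femnox);
    ADD(iFeMR, R_age - R_dir_a - R_sul_MR);
    ADD(iFeS, R_pre - R_dis - R_pyr1 - R_pyr2 - R_fesox);
    ADD(iFeS2, R_pyr1 + R_pyr2 - R_pyrox);
    ADD(iS0, p_s0 * R_sox + 0.5 * R_sul - R_pyr2 - R_s0ox);
    if (!site) {
      ADD(iNO3, -0.8 * fNO3 * Cdec + R_nit);
      ADD(iNH4, rNC * Cdec - R_nit);
      ADD(iMn, 2.0 * fMnO2 * Cdec - R_mnox + 0.5 * R_femnox);
      ADD(iMnO2, -2.0 * fMnO2 * Cdec + R_mnox - 0.5 * R_femnox);
      ADD(iFePR, -R_sul_PR);
    }

    // paired 56Fe tendencies
    const double DFe56 = GET(iDFe56), FeHR56 = GET(iFeHR56),
      FeMR56 = GET(iFeMR56), FeS56 = GET(iFeS56), FeS256 = GET(iFeS256);
    const double f_red_HR = hrf(FeHR, FeHR56, a_red, c_lim);
    const double f_red_MR = hrf(FeMR, FeMR56, a_red, c_lim);
    const double f_ox = hrf(DFe, DFe56, a_ox, c_lim);
    const double f_pre = hrf(DFe, DFe56, a_pre, c_lim);
    const double f_dis = hrf(FeS, FeS56, a_dis, c_lim);
    const double f_pyr = hrf(FeS, FeS56, a_pyr, c_lim);
    const double f_fesox = hrf(FeS, FeS56, a_ox, c_lim);
    const double f_pyrox = hrf(FeS2, FeS256, a_ox, c_lim);
    const double f_age = hrf(FeHR, FeHR56, 1.0, c_lim);
    const double pyr = R_pyr1 + R_pyr2;

    double dDFe56 = (R_dir_f + R_sul_HR) * f_red_HR +
      (R_dir_a + R_sul_MR) * f_red_MR +
      R_dis * f_dis + R_fesox * f_fesox + R_pyrox * f_pyrox -
      (R_feox + R_femnox) * f_ox - R_pre * f_pre;
    ADD(iFeHR56, -(R_dir_f + R_sul_HR) * f_red_HR - R_age * f_age +
        (R_feox + R_femnox) * f_ox);
    ADD(iFeMR56, R_age * f_age - (R_dir_a + R_sul_MR) * f_red_MR);
    ADD(iFeS56, R_pre * f_pre - R_dis * f_dis - pyr * f_pyr -
        R_fesox * f_fesox);
    ADD(iFeS256, pyr * f_pyr - R_pyrox * f_pyrox);
    if (!site) {
      const double FePR56 = GET(iFePR56);
      const double f_red_PR = hrf(FePR, FePR56, a_red, c_lim);
      ADD(iFePR56, -R_sul_PR * f_red_PR);
      dDFe56 += R_sul_PR * f_red_PR;
    }
    ADD(iDFe56, dDFe56);
    #undef GET
    #undef ADD
  }

  // phase capacity
  for (int j = 0; j < ns; ++j) {
    double *d = D + j * n;
    for (int i = 0; i < n; ++i) d[i] /= CAP(i, j);
  }
  return out;
}
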