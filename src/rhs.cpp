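// Compiled right-hand side of the root transport DAE.
// Mirrors assemble_residual() in R/assembly.R exactly; a test asserts
// elementwise agreement between the two implementations. The model arrays
// are parsed once into a Pack held by external pointer, so a single
// evaluation costs only the flux arithmetic.
#include <Rcpp.h>
using namespace Rcpp;

static const double F_CONST = 96485.332;
static const double R_CONST = 8.314462;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline double ghk(double P, double z, double V, double cin, double cout,
                         double RTF) {
  double u = z * V / RTF;
  if (std::fabs(u) < 1e-6)
    return P * (cin - cout + u * (cin + cout) / 2.0);
  double em = std::exp(-clampd(u, -500.0, 500.0));
  return P * u * (cin - cout * em) / (1.0 - em);
}

static inline double boltz_in(double V, double Vh, double s) {
  return 1.0 / (1.0 + std::exp(clampd((V - Vh) / s, -500.0, 500.0)));
}
static inline double boltz_out(double V, double Vh, double s) {
  return 1.0 / (1.0 + std::exp(clampd(-(V - Vh) / s, -500.0, 500.0)));
}

// four-state carrier cycle, King-Altman closed form
static inline double carrier4(double N, const double* k, double zt,
                              double dphi, double Scis, double Strans,
                              double RT) {
  double fv = std::exp(clampd(-zt * F_CONST * dphi / (2.0 * RT), -200.0, 200.0));
  double a = k[0] * Scis, b = k[1], c = k[2] * fv, d = k[3] / fv;
  double e = k[4], f = k[5] * Strans, g = k[6], h = k[7];
  double D1 = c * e * g + b * e * g + b * d * g + b * d * f;
  double D2 = e * g * a + d * g * a + d * f * a + d * f * h;
  double D3 = g * a * c + f * a * c + f * h * c + f * h * b;
  double D4 = a * c * e + h * c * e + h * b * e + h * b * d;
  double den = D1 + D2 + D3 + D4;
  if (den <= 0) return 0.0;
  return N * (a * c * e * g - b * d * f * h) / den;
}

static inline double np_flux(double D, double z, double ca, double cb,
                             double pa, double pb, double L, double v,
                             double FRT) {
  double cbar = 0.5 * (ca + cb);
  double J = -D * ((cb - ca) / L + z * FRT * cbar * (pb - pa) / L);
  double w = std::tanh(v / 1e-13);        // smoothed upwind weight
  double cup = cbar + w * (ca - cb) * 0.5;
  return J + cup * v;
}

typedef std::vector<double> dvec;
typedef std::vector<int> ivec;

struct Pack {
  int n, ground;
  ivec living, kind, vac_of;
  dvec V0, A_amt, B_amt, K_b, V0_cell;
  double T, RT, RTF, FRT, eps_cell, eps_wall, P_turgor0;
  double K_Ca, kir_Vh, kir_s, kor_off, kor_s, K_ref, P_H_pm, P_H_ton, k_chx;
  double pump_zt, khs_zt, clh_zt, vp_zt;
  double pump_k[8], khs_k[8], clh_k[8], vp_k[8];
  double P_top;
  // apoplastic edges
  ivec ap_a, ap_b; dvec ap_area, ap_L, ap_kh, ap_D;
  // plasmodesmata
  ivec pd_a, pd_b; dvec pd_area, pd_L, pd_D; double pd_Lp, pd_sig;
  // boundaries
  ivec ext_a; dvec ext_area, ext_L, ext_D; double ext_kh;
  ivec top_a; dvec top_area, top_L; double top_kh;
  // membranes
  ivec pm_c, pm_a; dvec pm_area, pm_nscc, pm_kir, pm_kor, pm_hkt, pm_anion,
    pm_pump, pm_khs, pm_clh, pm_kap; double pm_Lp, pm_sig;
  ivec tn_c, tn_v; dvec tn_area, tn_nhx;
  double tn_PNa, tn_PK, tn_PCl, tn_vpump, tn_khton, tn_Lp, tn_sig;
};

static void cp(dvec& dst, SEXP src) {
  NumericVector v(src);
  dst.assign(v.begin(), v.end());
}
static void cpi(ivec& dst, SEXP src) {
  IntegerVector v(src);
  dst.assign(v.begin(), v.end());
}

// [[Rcpp::export]]
SEXP sr_make_pack(List pack) {
  Pack* p = new Pack();
  p->n = as<int>(pack["n"]);
  p->ground = as<int>(pack["ground"]);
  cpi(p->living, pack["living"]); cpi(p->kind, pack["kind"]);
  cpi(p->vac_of, pack["vac_of"]);
  cp(p->V0, pack["V0"]); cp(p->A_amt, pack["A_amt"]);
  cp(p->B_amt, pack["B_amt"]); cp(p->K_b, pack["K_b"]);
  cp(p->V0_cell, pack["V0_cell"]);
  NumericVector prm = pack["prm"];
  p->T = prm["T"]; p->RT = R_CONST * p->T; p->RTF = p->RT / F_CONST;
  p->FRT = F_CONST / p->RT;
  p->eps_cell = prm["eps_cell"]; p->eps_wall = prm["eps_wall"];
  p->P_turgor0 = prm["P_turgor0"];
  p->K_Ca = prm["K_Ca"]; p->kir_Vh = prm["kir_Vhalf"];
  p->kir_s = prm["kir_slope"]; p->kor_off = prm["kor_offset"];
  p->kor_s = prm["kor_slope"]; p->K_ref = prm["K_cyt_ref"];
  p->P_H_pm = prm["P_H_pm"]; p->P_H_ton = prm["P_H_ton"];
  p->k_chx = prm["k_chx"];
  p->pump_zt = prm["pump_zt"]; p->khs_zt = prm["khsym_zt"];
  p->clh_zt = prm["clhsym_zt"]; p->vp_zt = prm["vpump_zt"];
  NumericVector pk = pack["pump_rates"], kk = pack["khsym_rates"],
    ck = pack["clhsym_rates"], vk = pack["vpump_rates"];
  for (int i = 0; i < 8; ++i) {
    p->pump_k[i] = pk[i]; p->khs_k[i] = kk[i];
    p->clh_k[i] = ck[i]; p->vp_k[i] = vk[i];
  }
  p->P_top = as<double>(pack["P_top"]);
  List ap = pack["ap"];
  cpi(p->ap_a, ap["a"]); cpi(p->ap_b, ap["b"]); cp(p->ap_area, ap["area"]);
  cp(p->ap_L, ap["L"]); cp(p->ap_kh, ap["kh"]); cp(p->ap_D, ap["D"]);
  List pd = pack["pd"];
  cpi(p->pd_a, pd["a"]); cpi(p->pd_b, pd["b"]); cp(p->pd_area, pd["area"]);
  cp(p->pd_L, pd["L"]); cp(p->pd_D, pd["D"]);
  p->pd_Lp = as<double>(pd["Lp"]); p->pd_sig = as<double>(pd["sigma"]);
  List ext = pack["ext"];
  cpi(p->ext_a, ext["a"]); cp(p->ext_area, ext["area"]);
  cp(p->ext_L, ext["L"]); cp(p->ext_D, ext["D"]);
  p->ext_kh = as<double>(ext["kh"]);
  List top = pack["top"];
  cpi(p->top_a, top["a"]); cp(p->top_area, top["area"]);
  cp(p->top_L, top["L"]); p->top_kh = as<double>(top["kh"]);
  List pm = pack["pm"];
  cpi(p->pm_c, pm["cyt"]); cpi(p->pm_a, pm["apo"]); cp(p->pm_area, pm["area"]);
  cp(p->pm_nscc, pm["P_nscc"]); cp(p->pm_kir, pm["P_kir"]);
  cp(p->pm_kor, pm["P_kor"]); cp(p->pm_hkt, pm["P_hkt"]);
  cp(p->pm_anion, pm["P_anion"]); cp(p->pm_pump, pm["N_pump"]);
  cp(p->pm_khs, pm["N_khsym"]); cp(p->pm_clh, pm["N_clhsym"]);
  cp(p->pm_kap, pm["k_ap"]);
  p->pm_Lp = as<double>(pm["Lp"]); p->pm_sig = as<double>(pm["sigma"]);
  List tn = pack["ton"];
  cpi(p->tn_c, tn["cyt"]); cpi(p->tn_v, tn["vac"]); cp(p->tn_area, tn["area"]);
  cp(p->tn_nhx, tn["k_nhx"]);
  p->tn_PNa = as<double>(tn["P_Na"]); p->tn_PK = as<double>(tn["P_K"]);
  p->tn_PCl = as<double>(tn["P_Cl"]); p->tn_vpump = as<double>(tn["N_vpump"]);
  p->tn_khton = as<double>(tn["k_khton"]);
  p->tn_Lp = as<double>(tn["Lp"]); p->tn_sig = as<double>(tn["sigma"]);
  XPtr<Pack> ptr(p, true);
  return ptr;
}

static void rhs_core(const Pack& P_, const double* y, const double* bc6,
                     double* dy) {
  const int n = P_.n;
  const double RT = P_.RT, RTF = P_.RTF, FRT = P_.FRT;
  const double bcNa = bc6[0], bcK = bc6[1], bcCl = bc6[2], bcH = bc6[3],
    bcCa = bc6[4], P_ext = bc6[5];

  static std::vector<double> cNa, cK, cCl, cH, phi, V, Hf, Pr, piv;
  cNa.resize(n); cK.resize(n); cCl.resize(n); cH.resize(n); phi.resize(n);
  V.resize(n); Hf.resize(n); Pr.resize(n); piv.resize(n);
  for (int i = 0; i < n; ++i) {
    cNa[i] = y[6 * i]; cK[i] = y[6 * i + 1]; cCl[i] = y[6 * i + 2];
    cH[i] = y[6 * i + 3]; V[i] = y[6 * i + 4]; phi[i] = y[6 * i + 5];
  }
  for (int i = 0; i < n; ++i) {
    if (P_.living[i]) {
      double Bt = P_.B_amt[i] / V[i], Kb = P_.K_b[i];
      double Ht = cH[i] > 0 ? cH[i] : 0;
      double b = Kb + Bt - Ht;
      double disc = std::sqrt(b * b + 4.0 * Kb * Ht);
      double hf = b >= 0 ? 2.0 * Kb * Ht / (b + disc) : (disc - b) / 2.0;
      Hf[i] = hf < Ht ? hf : Ht;
    } else Hf[i] = cH[i] > 0 ? cH[i] : 0;
    piv[i] = RT * (cNa[i] + cK[i] + cCl[i] + Hf[i] +
                   (P_.A_amt[i] + P_.B_amt[i]) / V[i]);
  }
  for (int i = 0; i < n; ++i)
    if (P_.kind[i] == 0)
      Pr[i] = P_.eps_wall * (V[i] - P_.V0[i]) / P_.V0[i];
  for (int i = 0; i < n; ++i) {
    if (P_.kind[i] == 1) {
      int vi = P_.vac_of[i];
      double Vcell = V[i] + V[vi];
      double Pc = P_.P_turgor0 +
        P_.eps_cell * (Vcell - P_.V0_cell[i]) / P_.V0_cell[i];
      Pr[i] = Pc; Pr[vi] = Pc;
    }
  }

  static std::vector<double> gNa, gK, gCl, gH, gW;
  gNa.assign(n, 0.0); gK.assign(n, 0.0); gCl.assign(n, 0.0);
  gH.assign(n, 0.0); gW.assign(n, 0.0);
  const double* conc[4] = { cNa.data(), cK.data(), cCl.data(), cH.data() };
  const double zval[4] = { 1.0, 1.0, -1.0, 1.0 };
  double* gain[4] = { gNa.data(), gK.data(), gCl.data(), gH.data() };

  // apoplastic edges
  for (size_t e = 0; e < P_.ap_a.size(); ++e) {
    int ia = P_.ap_a[e], ib = P_.ap_b[e];
    double qd = -P_.ap_kh[e] * (Pr[ib] - Pr[ia]) / P_.ap_L[e];
    double qv = qd * P_.ap_area[e];
    gW[ia] -= qv; gW[ib] += qv;
    for (int s = 0; s < 4; ++s) {
      double ca = s == 3 ? Hf[ia] : conc[s][ia];
      double cb = s == 3 ? Hf[ib] : conc[s][ib];
      double J = np_flux(P_.ap_D[s], zval[s], ca, cb, phi[ia], phi[ib],
                         P_.ap_L[e], qd, FRT) * P_.ap_area[e];
      gain[s][ia] -= J; gain[s][ib] += J;
    }
  }
  // plasmodesmata
  for (size_t e = 0; e < P_.pd_a.size(); ++e) {
    int ia = P_.pd_a[e], ib = P_.pd_b[e];
    double qd = P_.pd_Lp * ((Pr[ia] - Pr[ib]) - P_.pd_sig * (piv[ia] - piv[ib]));
    double qv = qd * P_.pd_area[e];
    gW[ia] -= qv; gW[ib] += qv;
    for (int s = 0; s < 4; ++s) {
      double ca = s == 3 ? Hf[ia] : conc[s][ia];
      double cb = s == 3 ? Hf[ib] : conc[s][ib];
      double J = np_flux(P_.pd_D[s], zval[s], ca, cb, phi[ia], phi[ib],
                         P_.pd_L[e], qd, FRT) * P_.pd_area[e];
      gain[s][ia] -= J; gain[s][ib] += J;
    }
  }
  // external boundary
  {
    double cb[4] = { bcNa, bcK, bcCl, bcH };
    for (size_t e = 0; e < P_.ext_a.size(); ++e) {
      int ia = P_.ext_a[e];
      double qd = -P_.ext_kh * (P_ext - Pr[ia]) / P_.ext_L[e];
      gW[ia] -= qd * P_.ext_area[e];
      for (int s = 0; s < 4; ++s) {
        double ca = s == 3 ? Hf[ia] : conc[s][ia];
        double J = np_flux(P_.ext_D[s], zval[s], ca, cb[s], phi[ia], 0.0,
                           P_.ext_L[e], qd, FRT) * P_.ext_area[e];
        gain[s][ia] -= J;
      }
    }
  }
  // xylem top boundary
  for (size_t e = 0; e < P_.top_a.size(); ++e) {
    int ia = P_.top_a[e];
    double qd = -P_.top_kh * (P_.P_top - Pr[ia]) / P_.top_L[e];
    double qv = qd * P_.top_area[e];
    gW[ia] -= qv;
    for (int s = 0; s < 4; ++s) {
      double ca = s == 3 ? Hf[ia] : conc[s][ia];
      gain[s][ia] -= ca * qv;
    }
  }
  // plasma membranes
  for (size_t e = 0; e < P_.pm_c.size(); ++e) {
    int ic = P_.pm_c[e], iap = P_.pm_a[e];
    double Vm = phi[ic] - phi[iap];
    double Pn = P_.pm_nscc[e] * P_.K_Ca / (P_.K_Ca + bcCa);
    double JNa = ghk(Pn, 1, Vm, cNa[ic], cNa[iap], RTF) +
      ghk(P_.pm_hkt[e], 1, Vm, cNa[ic], cNa[iap], RTF);
    double Kapo = cK[iap] > 1e-6 ? cK[iap] : 1e-6;
    double vh_kor = RTF * std::log(Kapo / P_.K_ref) + P_.kor_off;
    double JK = ghk(Pn, 1, Vm, cK[ic], cK[iap], RTF) +
      ghk(P_.pm_kir[e] * boltz_in(Vm, P_.kir_Vh, P_.kir_s), 1, Vm,
          cK[ic], cK[iap], RTF) +
      ghk(P_.pm_kor[e] * boltz_out(Vm, vh_kor, P_.kor_s), 1, Vm,
          cK[ic], cK[iap], RTF);
    double JCl = ghk(P_.pm_anion[e], -1, Vm, cCl[ic], cCl[iap], RTF);
    double Jpump = carrier4(P_.pm_pump[e], P_.pump_k, P_.pump_zt,
                            phi[iap] - phi[ic], Hf[ic], Hf[iap], RT);
    double Jkh = carrier4(P_.pm_khs[e], P_.khs_k, P_.khs_zt,
                          phi[ic] - phi[iap], cK[iap] * Hf[iap],
                          cK[ic] * Hf[ic], RT);
    double Jclh = carrier4(P_.pm_clh[e], P_.clh_k, P_.clh_zt,
                           phi[ic] - phi[iap], cCl[iap] * Hf[iap] * Hf[iap],
                           cCl[ic] * Hf[ic] * Hf[ic], RT);
    double Jap = P_.pm_kap[e] * (cNa[ic] * Hf[iap] - cNa[iap] * Hf[ic]);
    double Jchx = P_.k_chx * (cK[ic] * Hf[iap] - cK[iap] * Hf[ic]);
    double Jhleak = ghk(P_.P_H_pm, 1, Vm, Hf[ic], Hf[iap], RTF);
    JNa += Jap;
    JK += Jchx - Jkh;
    JCl -= Jclh;
    double JH = Jpump + Jhleak - Jap - Jchx - Jkh - 2.0 * Jclh;
    double qd = P_.pm_Lp * ((Pr[ic] - Pr[iap]) - P_.pm_sig * (piv[ic] - piv[iap]));
    double A = P_.pm_area[e];
    gNa[ic] -= JNa * A; gNa[iap] += JNa * A;
    gK[ic] -= JK * A; gK[iap] += JK * A;
    gCl[ic] -= JCl * A; gCl[iap] += JCl * A;
    gH[ic] -= JH * A; gH[iap] += JH * A;
    gW[ic] -= qd * A; gW[iap] += qd * A;
  }
  // tonoplasts
  for (size_t e = 0; e < P_.tn_c.size(); ++e) {
    int ic = P_.tn_c[e], iv = P_.tn_v[e];
    double Vt = phi[ic] - phi[iv];
    double JNa = ghk(P_.tn_PNa, 1, Vt, cNa[ic], cNa[iv], RTF);
    double JK = ghk(P_.tn_PK, 1, Vt, cK[ic], cK[iv], RTF);
    double JCl = ghk(P_.tn_PCl, -1, Vt, cCl[ic], cCl[iv], RTF);
    double Jvp = carrier4(P_.tn_vpump, P_.vp_k, P_.vp_zt, phi[iv] - phi[ic],
                          Hf[ic], Hf[iv], RT);
    double Jnhx = P_.tn_nhx[e] * (cNa[ic] * Hf[iv] - cNa[iv] * Hf[ic]);
    double Jkh = P_.tn_khton * (cK[ic] * Hf[iv] - cK[iv] * Hf[ic]);
    double Jhleak = ghk(P_.P_H_ton, 1, Vt, Hf[ic], Hf[iv], RTF);
    JNa += Jnhx;
    JK += Jkh;
    double JH = Jvp + Jhleak - Jnhx - Jkh;
    double qd = -P_.tn_Lp * P_.tn_sig * (piv[ic] - piv[iv]);
    double A = P_.tn_area[e];
    gNa[ic] -= JNa * A; gNa[iv] += JNa * A;
    gK[ic] -= JK * A; gK[iv] += JK * A;
    gCl[ic] -= JCl * A; gCl[iv] += JCl * A;
    gH[ic] -= JH * A; gH[iv] += JH * A;
    gW[ic] -= qd * A; gW[iv] += qd * A;
  }

  for (int i = 0; i < n; ++i) {
    double Vdot = gW[i];
    dy[6 * i]     = (gNa[i] - cNa[i] * Vdot) / V[i];
    dy[6 * i + 1] = (gK[i] - cK[i] * Vdot) / V[i];
    dy[6 * i + 2] = (gCl[i] - cCl[i] * Vdot) / V[i];
    dy[6 * i + 3] = (gH[i] - cH[i] * Vdot) / V[i];
    dy[6 * i + 4] = Vdot;
    dy[6 * i + 5] = (gNa[i] + gK[i] - gCl[i] + gH[i]) / P_.V0[i];
  }
  if (P_.ground >= 0) dy[6 * P_.ground + 5] = -phi[P_.ground];
}

// [[Rcpp::export]]
NumericVector sr_rhs_pack(double t, NumericVector y, SEXP pack_ptr,
                          NumericVector bc6) {
  XPtr<Pack> xp(pack_ptr);
  NumericVector dy(y.size());
  rhs_core(*xp, y.begin(), bc6.begin(), dy.begin());
  return dy;
}

// ---- native derivative entry point for deSolve (no R callback) ----
// The current model, boundary medium and state scaling are installed with
// sr_use_pack(); integrations are sequential, so a single slot suffices.
static Pack* g_pack = nullptr;
static std::vector<double> g_bc6(6), g_scale;
static std::vector<int> g_mask;   // 0 = freeze this slot (consistency solve)

// [[Rcpp::export]]
void sr_use_pack(SEXP pack_ptr, NumericVector bc6, NumericVector sscale,
                 IntegerVector mask = IntegerVector(0)) {
  XPtr<Pack> xp(pack_ptr);
  g_pack = xp.get();
  for (int i = 0; i < 6; ++i) g_bc6[i] = bc6[i];
  g_scale.assign(sscale.begin(), sscale.end());
  g_mask.assign(mask.begin(), mask.end());
}

extern "C" void sr_derivs(int* neq, double* t, double* y, double* ydot,
                          double* yout, int* ip) {
  static std::vector<double> ybuf;
  int m = *neq;
  ybuf.resize(m);
  for (int i = 0; i < m; ++i) ybuf[i] = y[i] * g_scale[i];
  rhs_core(*g_pack, ybuf.data(), g_bc6.data(), ydot);
  for (int i = 0; i < m; ++i) ydot[i] /= g_scale[i];
  if (!g_mask.empty())
    for (int i = 0; i < m; ++i) if (!g_mask[i]) ydot[i] = 0.0;
}
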