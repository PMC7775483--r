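/* Mouse atrial myocyte model with CaMKII activation/oxidation signaling.
 *
 * Compiled right-hand side for deSolve. State layout and parameter order
 * must match R/cell-params.R exactly (the R side builds the vectors; this
 * file only indexes them).
 *
 * Units: time ms, voltage mV, currents pA/pF, Ca uM, Na/K mM,
 * SR fluxes uM/ms referenced to the cytosolic volume.
 */

#include <R.h>
#include <math.h>

#define NPAR 117
static double p[NPAR];

/* parameter indices (0-based; R order is this + 1) */
#define P_Cm        p[0]
#define P_Vmyo      p[1]
#define P_Vjn       p[2]
#define P_Vsr       p[3]
#define P_Nao       p[4]
#define P_Ko        p[5]
#define P_Cao       p[6]
#define P_gNa       p[7]
#define P_gNaL      p[8]
#define P_hL_vshift p[9]
#define P_tau_hL    p[10]
#define P_gCaL      p[11]
#define P_Km_fCa    p[12]
#define P_gto       p[13]
#define P_kf_to     p[14]
#define P_gKur      p[15]
#define P_gss       p[16]
#define P_gK1       p[17]
#define P_vncx      p[18]
#define P_KmNa_ncx  p[19]
#define P_KmCa_ncx  p[20]
#define P_ksat_ncx  p[21]
#define P_eta_ncx   p[22]
#define P_Kd_ncxact p[23]
#define P_fjn_ncx   p[24]
#define P_ibarNaK   p[25]
#define P_KmNaip    p[26]
#define P_KmKo      p[27]
#define P_gpCa      p[28]
#define P_KmpCa     p[29]
#define P_gCab      p[30]
#define P_gNab      p[31]
#define P_ks_rel    p[32]
#define P_koCa      p[33]
#define P_kom       p[34]
#define P_kiCa      p[35]
#define P_kim       p[36]
#define P_ec50SR    p[37]
#define P_maxSR     p[38]
#define P_minSR     p[39]
#define P_Vmax_up   p[40]
#define P_Kmf_up    p[41]
#define P_Kmr_up    p[42]
#define P_hill_up   p[43]
#define P_kleak     p[44]
#define P_tau_diff  p[45]
#define P_Btn       p[46]
#define P_Ktn       p[47]
#define P_Bcd       p[48]
#define P_Kcd       p[49]
#define P_Bjn       p[50]
#define P_Kjn       p[51]
#define P_Bsr       p[52]
#define P_Ksr       p[53]
#define P_stim_amp    p[54]
#define P_stim_dur    p[55]
#define P_stim_period p[56]
#define P_stim_t0     p[57]
#define P_stim_tend   p[58]
#define P_ckii_tot_jn  p[59]
#define P_ckii_cyt_ratio p[60]
#define P_ros       p[61]
#define P_kbi       p[62]
#define P_kib       p[63]
#define P_kox       p[64]
#define P_KmROS     p[65]
#define P_kredox    p[66]
#define P_MsrA      p[67]
#define P_KmMsrA    p[68]
#define P_kauto     p[69]
#define P_kt_off    p[70]
#define P_kt2_off   p[71]
#define P_kb2i      p[72]
#define P_vpp1_jn   p[73]
#define P_vpp1_cyt  p[74]
#define P_KmPP1     p[75]
#define P_CaMtot_jn  p[76]
#define P_CaMtot_cyt p[77]
#define P_KdCaM1    p[78]
#define P_KdCaM2    p[79]
#define P_kp_L      p[80]
#define P_Km_L      p[81]
#define P_kd_L      p[82]
#define P_kp_P      p[83]
#define P_Km_P      p[84]
#define P_kd_P      p[85]
#define P_kp_R      p[86]
#define P_Km_R      p[87]
#define P_kd_R      p[88]
#define P_pL_ref    p[89]
#define P_pP_ref    p[90]
#define P_pR_ref    p[91]
#define P_cL_g      p[92]
#define P_cL_tf     p[93]
#define P_cP_km     p[94]
#define P_cR_ko     p[95]
#define P_cR_ec     p[96]
#define P_clamp_nai  p[97]
#define P_clamp_casr p[98]
#define P_clamp_pL   p[99]
#define P_clamp_pP   p[100]
#define P_clamp_pR   p[101]
#define P_probe_on   p[102]
#define P_probe_amp  p[103]
#define P_probe_t0   p[104]
#define P_probe_dur  p[105]
#define P_kinase_frozen p[106]
#define P_kib2_scale p[107]
#define P_hill_srf  p[108]
#define P_n_L       p[109]
#define P_n_P       p[110]
#define P_n_R       p[111]
#define P_hill_ryr  p[112]
#define P_k_lum     p[113]
#define P_casr_th   p[114]
#define P_w_lum     p[115]
#define P_ca_gate_km p[116]

/* state indices */
#define S_V    0
#define S_m    1
#define S_h    2
#define S_j    3
#define S_hL   4
#define S_d    5
#define S_f    6
#define S_ato  7
#define S_ito  8
#define S_aur  9
#define S_iur  10
#define S_rR   11
#define S_rO   12
#define S_rI   13
#define S_Cajn 14
#define S_Cai  15
#define S_CaSR 16
#define S_Nai  17
#define S_Ki   18
#define S_pL   19
#define S_pP   20
#define S_pR   21
#define S_KJ   22   /* kinase junctional block: Pi Pb Pt Pt2 Pa Pb2 Pot Po */
#define S_KC   30   /* kinase cytosolic block */
#define NEQ    38
#define NOUT   20

static const double FARADAY = 96485.0;
static const double RTF = 26.712;  /* RT/F at 310 K, mV */

void camk_initmod(void (*odeparms)(int *, double *))
{
  int n = NPAR;
  odeparms(&n, p);
}

/* CaM equilibrium: fraction of CaM with 2 and 4 bound Ca given free Ca */
static void cam_pools(double ca, double camtot, double *c2, double *c4)
{
  double x = (ca / P_KdCaM1) * (ca / P_KdCaM1);
  double y = (ca / P_KdCaM2) * (ca / P_KdCaM2);
  double den = 1.0 + x + x * y;
  *c2 = camtot * x / den;
  *c4 = camtot * x * y / den;
}

/* eight-state CaMKII chain; k is pointer to the 8 occupancies, dk to the
 * derivatives; rates in p are per ms */
static void kinase_rhs(const double *k, double *dk, double c2, double c4,
                       double camk_tot, double vpp1)
{
  double Pi = k[0], Pb = k[1], Pt = k[2], Pt2 = k[3], Pa = k[4],
         Pb2 = k[5], Pot = k[6], Po = k[7];
  double a_ox = P_kox * P_ros / (P_ros + P_KmROS);
  double b_red = P_kredox * P_MsrA / (P_MsrA + P_KmMsrA);
  double f_act = Pb + Pt + Pt2 + Pa + Pot + Po;
  double r_pp = vpp1 / (P_KmPP1 + camk_tot * (Pt + Pt2 + Pa));

  double v_ib  = P_kib * c4 * Pi;      /* Pi -> Pb   */
  double v_bi  = P_kbi * Pb;           /* Pb -> Pi   */
  double v_ib2 = P_kib * P_kib2_scale * c2 * Pi; /* Pi -> Pb2 */
  double v_b2i = P_kb2i * Pb2;         /* Pb2 -> Pi  */
  double v_bt  = P_kauto * f_act * Pb; /* Pb -> Pt   */
  double v_tb  = r_pp * Pt;            /* Pt -> Pb   */
  double v_ta  = P_kt_off * Pt;        /* Pt -> Pa   */
  double v_at  = P_kib * c4 * Pa;      /* Pa -> Pt   */
  double v_at2 = P_kib * P_kib2_scale * c2 * Pa; /* Pa -> Pt2 */
  double v_t2a = P_kt2_off * Pt2;      /* Pt2 -> Pa  */
  double v_ai  = r_pp * Pa;            /* Pa -> Pi   */
  double v_t2b2 = r_pp * Pt2;          /* Pt2 -> Pb2 */
  double v_ox  = a_ox * Pb;            /* Pb -> Pot  */
  double v_red = b_red * Pot;          /* Pot -> Pb  */
  double v_oto = P_kbi * Pot;          /* Pot -> Po  */
  double v_oot = P_kib * c4 * Po;      /* Po -> Pot  */
  double v_oi  = b_red * Po;           /* Po -> Pi   */

  dk[0] = -v_ib + v_bi - v_ib2 + v_b2i + v_ai + v_oi;           /* Pi  */
  dk[1] =  v_ib - v_bi - v_bt + v_tb - v_ox + v_red;            /* Pb  */
  dk[2] =  v_bt - v_tb - v_ta + v_at;                           /* Pt  */
  dk[3] =  v_at2 - v_t2a - v_t2b2;                              /* Pt2 */
  dk[4] =  v_ta - v_at - v_at2 + v_t2a - v_ai;                  /* Pa  */
  dk[5] =  v_ib2 - v_b2i + v_t2b2;                              /* Pb2 */
  dk[6] =  v_ox - v_red - v_oto + v_oot;                        /* Pot */
  dk[7] =  v_oto - v_oot - v_oi;                                /* Po  */
}

static void compute_rhs(double t, const double *y, double *ydot, double *yout)
{
  double V = y[S_V];
  double m = y[S_m], h = y[S_h], jg = y[S_j], hL = y[S_hL];
  double d = y[S_d], f = y[S_f];
  double ato = y[S_ato], ito = y[S_ito], aur = y[S_aur], iur = y[S_iur];
  double rR = y[S_rR], rO = y[S_rO], rI = y[S_rI];
  double Cajn = fmax(y[S_Cajn], 1e-5);
  double Cai  = fmax(y[S_Cai], 1e-5);
  double CaSR = fmax(y[S_CaSR], 1e-3);
  double Nai  = fmax(y[S_Nai], 1e-3);
  double Ki   = fmax(y[S_Ki], 1e-3);
  double pL = y[S_pL], pP = y[S_pP], pR = y[S_pR];

  double ENa = RTF * log(P_Nao / Nai);
  double EK  = RTF * log(P_Ko / Ki);
  double ECa = 0.5 * RTF * log(P_Cao * 1000.0 / Cai);

  /* ---- fast Na current (LR91 kinetics) ---- */
  double dv = V + 47.13;
  double am = (fabs(dv) < 1e-6) ? 3.2 : 0.32 * dv / (1.0 - exp(-0.1 * dv));
  double bm = 0.08 * exp(-V / 11.0);
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 1.0 / (0.13 * (1.0 + exp((V + 10.66) / -11.1)));
    aj = 0.0;
    bj = 0.3 * exp(-2.535e-7 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.135 * exp((80.0 + V) / -6.8);
    bh = 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V);
    aj = (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
    bj = 0.1212 * exp(-0.01052 * V) / (1.0 + exp(-0.1378 * (V + 40.14)));
  }
  double INa = P_gNa * m * m * m * h * jg * (V - ENa);

  /* ---- late Na current; OE shifts the inactivation curve ---- */
  double mL = 1.0 / (1.0 + exp(-(V + 75.0) / 5.0));
  double hL_inf = 1.0 / (1.0 + exp((V + 88.0 - P_hL_vshift) / 3.5));
  double INaL = P_gNaL * mL * hL * (V - ENa);

  /* ---- L-type Ca current with CaMKII-phosphorylation modifiers ---- */
  double d_inf = 1.0 / (1.0 + exp(-(V + 5.0) / 6.0));
  double tau_d = 0.6 + 2.2 * exp(-pow((V + 10.0) / 25.0, 2));
  double f_inf = 1.0 / (1.0 + exp((V + 27.0) / 7.0));
  double tfac = 1.0 + P_cL_tf * (pL - P_pL_ref);
  if (tfac < 0.2) tfac = 0.2;
  double tau_f = (10.0 + 40.0 * exp(-pow((V + 25.0) / 20.0, 2))) * tfac;
  double fCa = 1.0 / (1.0 + Cajn / P_Km_fCa);
  double gfac = 1.0 + P_cL_g * (pL - P_pL_ref);
  if (gfac < 0.0) gfac = 0.0;
  double ICaL = (P_probe_on > 0.5) ? 0.0
    : P_gCaL * gfac * d * f * fCa * (V - 60.0);

  /* ---- transient outward K; OE multiplies the inactivating rate ---- */
  double a_inf = 1.0 / (1.0 + exp(-V / 11.0));
  double tau_a = 0.6 + 1.8 * exp(-pow((V + 30.0) / 30.0, 2));
  double alpha_i = 0.02 / (1.0 + exp((V + 58.0) / 5.0));
  double beta_i = P_kf_to * 0.025 / (1.0 + exp(-(V + 15.0) / 6.0));
  double Ito = P_gto * ato * ito * (V - EK);

  /* ---- ultrarapid / steady-state K ---- */
  double aur_inf = 1.0 / (1.0 + exp(-(V + 25.0) / 9.0));
  double tau_aur = 0.8 + 1.5 * exp(-pow((V + 20.0) / 25.0, 2));
  double iur_inf = 1.0 / (1.0 + exp((V + 38.0) / 7.0));
  double tau_iur = 1800.0;
  double IKur = P_gKur * aur * iur * (V - EK);
  double Iss = P_gss * aur * (V - EK);

  /* ---- inward rectifier ---- */
  double IK1 = P_gK1 * (P_Ko / (P_Ko + 0.21)) * (V - EK) /
               (1.0 + exp(0.065 * (V - EK)));

  /* ---- NCX, split junctional / bulk sensing ---- */
  double e1 = exp(P_eta_ncx * V / RTF);
  double e2 = exp((P_eta_ncx - 1.0) * V / RTF);
  double den_ncx = (pow(P_KmNa_ncx, 3) + pow(P_Nao, 3)) *
                   (P_KmCa_ncx + P_Cao) * (1.0 + P_ksat_ncx * e2);
  double Nai3 = Nai * Nai * Nai;
  double Nao3 = P_Nao * P_Nao * P_Nao;
  double ka_jn = 1.0 / (1.0 + pow(P_Kd_ncxact / Cajn, 2));
  double ka_my = 1.0 / (1.0 + pow(P_Kd_ncxact / Cai, 2));
  double Incx_jn = P_fjn_ncx * P_vncx * ka_jn *
    (e1 * Nai3 * P_Cao - e2 * Nao3 * (Cajn * 1e-3)) / den_ncx;
  double Incx_my = (1.0 - P_fjn_ncx) * P_vncx * ka_my *
    (e1 * Nai3 * P_Cao - e2 * Nao3 * (Cai * 1e-3)) / den_ncx;
  double INCX = Incx_jn + Incx_my;

  /* ---- NaK pump ---- */
  double sigma = (exp(P_Nao / 67.3) - 1.0) / 7.0;
  double fNaK = 1.0 / (1.0 + 0.1245 * exp(-0.1 * V / RTF) +
                       0.0365 * sigma * exp(-V / RTF));
  double INaK = P_ibarNaK * fNaK * (P_Ko / (P_Ko + P_KmKo)) /
                (1.0 + pow(P_KmNaip / Nai, 4));

  /* ---- background and pump currents ---- */
  double IpCa = P_gpCa * Cai / (Cai + P_KmpCa);
  double ICab = P_gCab * (V - ECa);
  double INab = P_gNab * (V - ENa);

  /* ---- stimulus (charge carried by K) ---- */
  double Istim = 0.0;
  if (P_stim_amp > 0.0 && t >= P_stim_t0 && t < P_stim_tend) {
    double ph = fmod(t - P_stim_t0, P_stim_period);
    if (ph < P_stim_dur) Istim = -P_stim_amp;
  }

  /* ---- square Ca-probe current (threshold protocol) ---- */
  double Iprobe = 0.0;
  if (P_probe_on > 0.5 && t >= P_probe_t0 && t < P_probe_t0 + P_probe_dur)
    Iprobe = -P_probe_amp;

  /* ---- RyR release: luminal-sensitized Markov gating ---- */
  double ec50_eff = P_ec50SR * (1.0 - P_cR_ec * (pR - P_pR_ref));
  if (ec50_eff < 50.0) ec50_eff = 50.0;
  /* sensitization is steep above the wild-type operating point and gentle
   * below it, so the anchored feedback loop stays stable */
  double dpr = pR - P_pR_ref;
  double ko_eff = P_koCa * (1.0 + (dpr > 0.0 ? P_cR_ko : 1.0) * dpr);
  if (ko_eff < 0.01 * P_koCa) ko_eff = 0.01 * P_koCa;
  double kCaSR = P_maxSR - (P_maxSR - P_minSR) /
                 (1.0 + pow(ec50_eff / CaSR, P_hill_srf));
  double koSRCa = ko_eff / kCaSR;
  double kiSRCa = P_kiCa * kCaSR;
  double RI = 1.0 - rR - rO - rI;
  /* opening/inactivation rates capped at 20/ms: keeps the gating ODEs
   * integrable under extreme probe-driven junctional Ca */
  double r_open = fmin(koSRCa * pow(Cajn, P_hill_ryr), 20.0);
  double r_inact = fmin(kiSRCa * Cajn, 20.0);
  double drR = (P_kim * RI - r_inact * rR) -
               (r_open * rR - P_kom * rO);
  double drO = (r_open * rR - P_kom * rO) -
               (r_inact * rO - P_kim * rI);
  double drI = (r_inact * rO - P_kim * rI) -
               (P_kom * rI - r_open * RI);
  /* store-overload-induced release: a luminal-gated leak through the
   * available (rR) channels whose threshold falls with RyR
   * phosphorylation; it seeds junctional Ca and lets the regenerative
   * Ca-activation term take over (all-or-none dump) */
  double th_eff = P_casr_th * (1.0 - P_cR_ec * (pR - P_pR_ref));
  double gate = 1.0 / (1.0 + exp(-(CaSR - th_eff) / P_w_lum));
  double cg = pow(Cajn / P_ca_gate_km, 4);
  double gate_ca = cg / (1.0 + cg);
  double J_spont = P_k_lum * gate * gate_ca * rR * (CaSR - Cajn);
  double J_rel = P_ks_rel * rO * (CaSR - Cajn) + J_spont;
  double J_leak = P_kleak * (CaSR - Cai);

  /* ---- SERCA with PLB-phosphorylation-dependent affinity ---- */
  double kmf_eff = P_Kmf_up * (1.0 - P_cP_km * (pP - P_pP_ref));
  if (kmf_eff < 0.05) kmf_eff = 0.05;
  double fw = pow(Cai / kmf_eff, P_hill_up);
  double rv = pow(CaSR / P_Kmr_up, P_hill_up);
  double J_up = P_Vmax_up * (fw - rv) / (1.0 + fw + rv);

  /* ---- Ca flux conversions ---- */
  double conv2_jn = P_Cm * 1e-9 / (2.0 * FARADAY * P_Vjn);
  double conv1_jn = 2.0 * conv2_jn;
  double conv2_my = P_Cm * 1e-9 / (2.0 * FARADAY * P_Vmyo);
  double conv1_my = 2.0 * conv2_my;
  double J_CaL = -ICaL * conv2_jn;
  double J_probe = -Iprobe * conv2_jn;
  double J_ncx_jn = Incx_jn * conv1_jn;
  double J_ncx_my = Incx_my * conv1_my;
  double J_pCa = -IpCa * conv2_my;
  double J_Cab = -ICab * conv2_my;
  double J_diff = (Cajn - Cai) / P_tau_diff;  /* junction-referenced */

  /* ---- buffering (rapid approximation) ---- */
  double buf_i = 1.0 / (1.0 + P_Btn * P_Ktn / pow(P_Ktn + Cai, 2) +
                        P_Bcd * P_Kcd / pow(P_Kcd + Cai, 2));
  double buf_j = 1.0 / (1.0 + P_Bjn * P_Kjn / pow(P_Kjn + Cajn, 2));
  double buf_s = 1.0 / (1.0 + P_Bsr * P_Ksr / pow(P_Ksr + CaSR, 2));

  /* ---- membrane potential ---- */
  double Iion = INa + INaL + ICaL + Iprobe + Ito + IKur + Iss + IK1 +
                INCX + INaK + IpCa + ICab + INab;
  ydot[S_V] = -(Iion + Istim);

  ydot[S_m] = am * (1.0 - m) - bm * m;
  ydot[S_h] = ah * (1.0 - h) - bh * h;
  ydot[S_j] = aj * (1.0 - jg) - bj * jg;
  ydot[S_hL] = (hL_inf - hL) / P_tau_hL;
  ydot[S_d] = (d_inf - d) / tau_d;
  ydot[S_f] = (f_inf - f) / tau_f;
  ydot[S_ato] = (a_inf - ato) / tau_a;
  ydot[S_ito] = alpha_i * (1.0 - ito) - beta_i * ito;
  ydot[S_aur] = (aur_inf - aur) / tau_aur;
  ydot[S_iur] = (iur_inf - iur) / tau_iur;
  ydot[S_rR] = drR;
  ydot[S_rO] = drO;
  ydot[S_rI] = drI;

  ydot[S_Cajn] = buf_j * (J_CaL + J_probe + J_ncx_jn +
                           J_rel * (P_Vmyo / P_Vjn) - J_diff);
  ydot[S_Cai] = buf_i * (J_diff * (P_Vjn / P_Vmyo) - J_up + J_leak +
                          J_ncx_my + J_pCa + J_Cab);
  ydot[S_CaSR] = buf_s * ((J_up - J_leak - J_rel) * (P_Vmyo / P_Vsr));

  double conv_mM = P_Cm * 1e-12 / (FARADAY * P_Vmyo);
  ydot[S_Nai] = -(INa + INaL + INab + 3.0 * INCX + 3.0 * INaK) * conv_mM;
  ydot[S_Ki] = -(Ito + IKur + Iss + IK1 - 2.0 * INaK + Istim) * conv_mM;

  /* ---- CaMKII compartments ---- */
  double c2j, c4j, c2c, c4c;
  double ckii_tot_cyt = P_ckii_tot_jn * P_ckii_cyt_ratio;
  cam_pools(Cajn, P_CaMtot_jn, &c2j, &c4j);
  cam_pools(Cai, P_CaMtot_cyt, &c2c, &c4c);
  if (P_kinase_frozen > 0.5) {
    for (int i = 0; i < 16; i++) ydot[S_KJ + i] = 0.0;
  } else {
    kinase_rhs(y + S_KJ, ydot + S_KJ, c2j, c4j, P_ckii_tot_jn, P_vpp1_jn);
    kinase_rhs(y + S_KC, ydot + S_KC, c2c, c4c, ckii_tot_cyt, P_vpp1_cyt);
  }
  double fact_jn = y[S_KJ+1] + y[S_KJ+2] + y[S_KJ+3] + y[S_KJ+4] +
                   y[S_KJ+6] + y[S_KJ+7];
  double fact_cy = y[S_KC+1] + y[S_KC+2] + y[S_KC+3] + y[S_KC+4] +
                   y[S_KC+6] + y[S_KC+7];
  double Ajn = fact_jn * P_ckii_tot_jn;
  if (Ajn < 0.0) Ajn = 0.0;

  /* ---- CaMKII-dependent phosphorylation of LTCC / PLB / RyR ----
   * saturable Hill dependence on junctional active CaMKII */
  double hL_drv = pow(Ajn, P_n_L);
  hL_drv = hL_drv / (hL_drv + pow(P_Km_L, P_n_L));
  double hP_drv = pow(Ajn, P_n_P);
  hP_drv = hP_drv / (hP_drv + pow(P_Km_P, P_n_P));
  double hR_drv = pow(Ajn, P_n_R);
  hR_drv = hR_drv / (hR_drv + pow(P_Km_R, P_n_R));
  ydot[S_pL] = P_kp_L * hL_drv * (1.0 - pL) - P_kd_L * pL;
  ydot[S_pP] = P_kp_P * hP_drv * (1.0 - pP) - P_kd_P * pP;
  ydot[S_pR] = P_kp_R * hR_drv * (1.0 - pR) - P_kd_R * pR;

  /* ---- clamps ---- */
  if (P_clamp_nai >= 0.0) ydot[S_Nai] = 0.0;
  if (P_clamp_casr >= 0.0) ydot[S_CaSR] = 0.0;
  if (P_clamp_pL >= 0.0) ydot[S_pL] = 0.0;
  if (P_clamp_pP >= 0.0) ydot[S_pP] = 0.0;
  if (P_clamp_pR >= 0.0) ydot[S_pR] = 0.0;

  if (yout != NULL) {
    yout[0] = INa;  yout[1] = INaL; yout[2] = ICaL; yout[3] = Ito;
    yout[4] = IKur; yout[5] = Iss;  yout[6] = IK1;  yout[7] = INCX;
    yout[8] = INaK; yout[9] = IpCa; yout[10] = ICab; yout[11] = INab;
    yout[12] = Istim; yout[13] = J_rel; yout[14] = J_up; yout[15] = J_leak;
    yout[16] = Ajn; yout[17] = fact_cy * ckii_tot_cyt;
    yout[18] = c4j; yout[19] = Iprobe;
  }
}

void camk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
  if (ip[0] < NOUT) error("nout should be at least %d", NOUT);
  compute_rhs(*t, y, ydot, yout);
}

/* direct single evaluation used by R-level cell_derivatives() */
void camk_rhs_direct(double *t, double *y, double *parms, double *ydot,
                     double *yout)
{
  for (int i = 0; i < NPAR; i++) p[i] = parms[i];
  compute_rhs(*t, y, ydot, yout);
}
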