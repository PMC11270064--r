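/* Endocardial human ventricular ionic models with an osmotic hypernatremia
 * hook: perturbed extracellular milieu, maximal-rate scaling of ICaL, IKr,
 * IKs, IK1, INaCa and INaK, and uniform scaling of all intracellular
 * compartment volumes (capacitive area fixed).
 *
 * Two models are provided behind the same parameter interface:
 *   - torord_*  : reconstruction of the Tomek-Rodriguez (ToR-ORd) endo model
 *                 (Hodgkin-Huxley IKr variant; see package vignette).
 *   - bps_*     : O'Hara-Rudy 2011 endocardial backbone used for the
 *                 BPS2020 slot (see vignette for the fidelity statement).
 *
 * Units: ms, mV, mmol/L, A/F. Current convention: inward negative.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define RGAS 8314.0
#define TEMP 310.0
#define FARADAY 96485.0

/* parameter vector layout (shared by both models) */
enum { P_NAO, P_KO, P_CAO, P_CLO, P_FCAL, P_FKR, P_FKS, P_FK1, P_FNCX,
       P_FNAK, P_VFRAC, P_ISTIM, P_IMULT, NPARMS };

#define NOUT 20
/* output layout */
enum { O_INA, O_INAL, O_ITO, O_ICAL, O_IKR, O_IKS, O_IK1, O_INAK, O_INACA,
       O_INAB, O_IKB, O_ICAB, O_IPCA, O_ICL, O_ICANA, O_ICAK, O_INACA_I,
       O_INACA_SS, O_JREL, O_JUP };

#define NS_TOR 40
#define NS_BPS 41

/* GHK flux density for valence z with effective (activity-corrected)
 * concentrations gci/gco; multiply by a permeability to get A/F.
 * Equals z^2 * v * F^2/(RT) * (gci e^{zvF/RT} - gco)/(e^{zvF/RT} - 1). */
static double ghk(double z, double gci, double gco, double v)
{
    double frt = FARADAY / (RGAS * TEMP);
    double zv = z * v * frt;
    if (fabs(zv) < 1e-5)  /* second-order series around v = 0 */
        return z * FARADAY * ((gci - gco) + 0.5 * zv * (gci + gco));
    return z * FARADAY * zv * (gci * exp(zv) - gco) / (exp(zv) - 1.0);
}

/* ----- shared ORd-scheme INaK (Smith-Crampin) ----- */
static double inak_ord(double v, double nai, double ki, double nao, double ko,
                       double pnak)
{
    double frt = FARADAY / (RGAS * TEMP);
    double vfrt = v * frt;
    double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
    double k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
    double Knai0 = 9.073, Knao0 = 27.78, delta = -0.1550;
    double Knai = Knai0 * exp(delta * vfrt / 3.0);
    double Knao = Knao0 * exp((1.0 - delta) * vfrt / 3.0);
    double Kki = 0.5, Kko = 0.3582, MgADP = 0.05, MgATP = 9.8;
    double Kmgatp = 1.698e-7, H = 1e-7, eP = 4.2, Khp = 1.698e-7;
    double Knap = 224.0, Kxkur = 292.0;
    double P = eP / (1.0 + H / Khp + nai / Knap + ki / Kxkur);
    double di = pow(1.0 + nai / Knai, 3.0) + pow(1.0 + ki / Kki, 2.0) - 1.0;
    double doo = pow(1.0 + nao / Knao, 3.0) + pow(1.0 + ko / Kko, 2.0) - 1.0;
    double a1 = k1p * pow(nai / Knai, 3.0) / di;
    double b1 = k1m * MgADP;
    double a2 = k2p;
    double b2 = k2m * pow(nao / Knao, 3.0) / doo;
    double a3 = k3p * pow(ko / Kko, 2.0) / doo;
    double b3 = k3m * P * H / (1.0 + MgATP / Kmgatp);
    double a4 = k4p * MgATP / Kmgatp / (1.0 + MgATP / Kmgatp);
    double b4 = k4m * pow(ki / Kki, 2.0) / di;
    double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
    double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
    double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
    double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1;
    double s = x1 + x2 + x3 + x4;
    double E1 = x1 / s, E2 = x2 / s, E3 = x3 / s, E4 = x4 / s;
    double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
    double JnakK = 2.0 * (E4 * b1 - E3 * a1);
    return pnak * (JnakNa + JnakK);
}

/* ----- shared ORd-scheme INaCa for one compartment ----- */
static double inaca_ord(double v, double nax, double cax, double nao,
                        double cao, double gncx)
{
    double frt = FARADAY / (RGAS * TEMP);
    double vfrt = v * frt;
    double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12, kasymm = 12.5;
    double wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
    double kcaon = 1.5e6, kcaoff = 5.0e3;
    double qna = 0.5224, qca = 0.1670;
    double hca = exp(qca * vfrt), hna = exp(qna * vfrt);
    double h1 = 1.0 + nax / kna3 * (1.0 + hna);
    double h2 = (nax * hna) / (kna3 * h1);
    double h3 = 1.0 / h1;
    double h4 = 1.0 + nax / kna1 * (1.0 + nax / kna2);
    double h5 = nax * nax / (h4 * kna1 * kna2);
    double h6 = 1.0 / h4;
    double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
    double h8 = nao / (kna3 * hna * h7);
    double h9 = 1.0 / h7;
    double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
    double h11 = nao * nao / (h10 * kna1 * kna2);
    double h12 = 1.0 / h10;
    double k1 = h12 * cao * kcaon;
    double k2 = kcaoff;
    double k3p_ = h9 * wca, k3pp = h8 * wnaca, k3 = k3p_ + k3pp;
    double k4p_ = h3 * wca / hca, k4pp = h2 * wnaca, k4 = k4p_ + k4pp;
    double k5 = kcaoff;
    double k6 = h6 * cax * kcaon;
    double k7 = h5 * h2 * wna;
    double k8 = h8 * h11 * wna;
    double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    double s = x1 + x2 + x3 + x4;
    double E1 = x1 / s, E2 = x2 / s, E3 = x3 / s, E4 = x4 / s;
    double KmCaAct = 150.0e-6;
    double allo = 1.0 / (1.0 + pow(KmCaAct / cax, 2.0));
    double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
    double JncxCa = E2 * k2 - E1 * k1;
    return gncx * allo * (JncxNa + 2.0 * JncxCa);
}

/* ======================= ToR-ORd (endocardial) ======================= */

static void torord_rhs(double t, const double *y, double *dy, double *out,
                       const double *p)
{
    double frt = FARADAY / (RGAS * TEMP);
    double v = y[0];
    double nai = y[1], nass = y[2], ki = y[3], kss = y[4];
    double cai = y[5], cass = y[6], cansr = y[7], cajsr = y[8];
    double m = y[9], h = y[10], j = y[11], hp = y[12], jp = y[13];
    double mL = y[14], hL = y[15], hLp = y[16];
    double a = y[17], iF = y[18], iS = y[19];
    double ap = y[20], iFp = y[21], iSp = y[22];
    double d = y[23], ff = y[24], fs = y[25], fcaf = y[26], fcas = y[27];
    double jca = y[28], ffp = y[29], fcafp = y[30];
    double ncass = y[31], ncai = y[32];
    double xrf = y[33], xrs = y[34], xs1 = y[35], xs2 = y[36];
    double Jrelnp = y[37], Jrelp = y[38], CaMKt = y[39];

    double nao = p[P_NAO], ko = p[P_KO], cao = p[P_CAO], clo = p[P_CLO];
    double vfrac = p[P_VFRAC], istim = p[P_ISTIM], imult = p[P_IMULT];

    double vfrt = v * frt;

    /* geometry (cm / uL); shrinkage scales volumes, never Acap */
    double L = 0.01, rad = 0.0011;
    double vcell = 1000.0 * 3.14 * rad * rad * L;
    double Ageo = 2.0 * 3.14 * rad * rad + 2.0 * 3.14 * rad * L;
    double Acap = 2.0 * Ageo;
    double vmyo = 0.68 * vcell * vfrac;
    double vnsr = 0.0552 * vcell * vfrac;
    double vjsr = 0.0048 * vcell * vfrac;
    double vss = 0.02 * vcell * vfrac;

    double cli = 24.0;  /* intracellular Cl- fixed */

    double ENa = (1.0 / frt) * log(nao / nai);
    double EK = (1.0 / frt) * log(ko / ki);
    double PKNa = 0.01833;
    double EKs = (1.0 / frt) * log((ko + PKNa * nao) / (ki + PKNa * nai));
    double ECl = -(1.0 / frt) * log(clo / cli);

    /* CaMK */
    double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068;
    double CaMKo = 0.05, KmCaM = 0.0015;
    double CaMKb = CaMKo * (1.0 - CaMKt) / (1.0 + KmCaM / cass);
    double CaMKa = CaMKb + CaMKt;
    dy[39] = aCaMK * CaMKb * (CaMKb + CaMKt) - bCaMK * CaMKt;

    /* INa (Grandi-type HH formulation) */
    double mss = 1.0 / pow(1.0 + exp(-(v + 56.86) / 9.03), 2.0);
    double tm = 0.1292 * exp(-pow((v + 45.79) / 15.54, 2.0)) +
                0.06487 * exp(-pow((v - 4.823) / 51.12, 2.0));
    dy[9] = (mss - m) / tm;
    double ah, bh, aj, bj;
    if (v >= -40.0) {
        ah = 0.0;
        bh = 0.77 / (0.13 * (1.0 + exp(-(v + 10.66) / 11.1)));
        aj = 0.0;
        bj = 0.6 * exp(0.057 * v) / (1.0 + exp(-0.1 * (v + 32.0)));
    } else {
        ah = 0.057 * exp(-(v + 80.0) / 6.8);
        bh = 2.7 * exp(0.079 * v) + 3.1e5 * exp(0.3485 * v);
        aj = (-2.5428e4 * exp(0.2444 * v) - 6.948e-6 * exp(-0.04391 * v)) *
             (v + 37.78) / (1.0 + exp(0.311 * (v + 79.23)));
        bj = 0.02424 * exp(-0.01052 * v) /
             (1.0 + exp(-0.1378 * (v + 40.14)));
    }
    double th = 1.0 / (ah + bh);
    double hss = 1.0 / pow(1.0 + exp((v + 71.55) / 7.43), 2.0);
    dy[10] = (hss - h) / th;
    double tj = 1.0 / (aj + bj);
    double jss = hss;
    dy[11] = (jss - j) / tj;
    double hssp = 1.0 / pow(1.0 + exp((v + 77.55) / 7.43), 2.0);
    dy[12] = (hssp - hp) / (1.5 * th);
    dy[13] = (jss - jp) / (1.46 * tj);
    double GNa = 11.7866;
    double fINap = 1.0 / (1.0 + KmCaMK / CaMKa);
    double INa = GNa * (v - ENa) * m * m * m *
                 ((1.0 - fINap) * h * j + fINap * hp * jp);

    /* INaL */
    double mLss = 1.0 / (1.0 + exp(-(v + 42.85) / 5.264));
    dy[14] = (mLss - mL) / tm;
    double hLss = 1.0 / (1.0 + exp((v + 87.61) / 7.488));
    double thL = 200.0;
    dy[15] = (hLss - hL) / thL;
    double hLssp = 1.0 / (1.0 + exp((v + 93.81) / 7.488));
    dy[16] = (hLssp - hLp) / (3.0 * thL);
    double GNaL = 0.0279;
    double fINaLp = fINap;
    double INaL = GNaL * (v - ENa) * mL *
                  ((1.0 - fINaLp) * hL + fINaLp * hLp);

    /* Ito */
    double ass = 1.0 / (1.0 + exp(-(v - 14.34) / 14.82));
    double ta = 1.0515 / (1.0 / (1.2089 * (1.0 + exp(-(v - 18.4099) / 29.3814))) +
                          3.5 / (1.0 + exp((v + 100.0) / 29.3814)));
    dy[17] = (ass - a) / ta;
    double iss = 1.0 / (1.0 + exp((v + 43.94) / 5.711));
    double tiF = 4.562 + 1.0 / (0.3933 * exp(-(v + 100.0) / 100.0) +
                                0.08004 * exp((v + 50.0) / 16.59));
    double tiS = 23.62 + 1.0 / (0.001416 * exp(-(v + 96.52) / 59.05) +
                                1.780e-8 * exp((v + 114.1) / 8.079));
    dy[18] = (iss - iF) / tiF;
    dy[19] = (iss - iS) / tiS;
    double AiF = 1.0 / (1.0 + exp((v - 213.6) / 151.2));
    double AiS = 1.0 - AiF;
    double i_gate = AiF * iF + AiS * iS;
    double assp = 1.0 / (1.0 + exp(-(v - 24.34) / 14.82));
    dy[20] = (assp - ap) / ta;
    double dti_dev = 1.354 + 1e-4 / (exp((v - 167.4) / 15.89) +
                                     exp(-(v - 12.23) / 0.2154));
    double dti_rec = 1.0 - 0.5 / (1.0 + exp((v + 70.0) / 20.0));
    dy[21] = (iss - iFp) / (dti_dev * dti_rec * tiF);
    dy[22] = (iss - iSp) / (dti_dev * dti_rec * tiS);
    double ip_gate = AiF * iFp + AiS * iSp;
    double Gto = 0.16;
    double fItop = fINap;
    double Ito = Gto * (v - EK) *
                 ((1.0 - fItop) * a * i_gate + fItop * ap * ip_gate);

    /* ICaL with ionic-activity GHK driving force, 80% in the subspace */
    double dss = 1.0763 * exp(-1.0070 * exp(-0.0829 * v));
    if (dss > 1.0) dss = 1.0;
    double td = 0.6 + 1.0 / (exp(-0.05 * (v + 6.0)) + exp(0.09 * (v + 14.0)));
    dy[23] = (dss - d) / td;
    double fss = 1.0 / (1.0 + exp((v + 19.58) / 3.696));
    double tff = 7.0 + 1.0 / (0.0045 * exp(-(v + 20.0) / 10.0) +
                              0.0045 * exp((v + 20.0) / 10.0));
    double tfs = 1000.0 + 1.0 / (3.5e-5 * exp(-(v + 5.0) / 4.0) +
                                 3.5e-5 * exp((v + 5.0) / 6.0));
    dy[24] = (fss - ff) / tff;
    dy[25] = (fss - fs) / tfs;
    double Aff = 0.6, Afs = 0.4;
    double f = Aff * ff + Afs * fs;
    double fcass_ = fss;
    double tfcaf = 7.0 + 1.0 / (0.04 * exp(-(v - 4.0) / 7.0) +
                                0.04 * exp((v - 4.0) / 7.0));
    double tfcas = 100.0 + 1.0 / (0.00012 * exp(-v / 3.0) +
                                  0.00012 * exp(v / 7.0));
    dy[26] = (fcass_ - fcaf) / tfcaf;
    dy[27] = (fcass_ - fcas) / tfcas;
    double Afcaf = 0.3 + 0.6 / (1.0 + exp((v - 10.0) / 10.0));
    double Afcas = 1.0 - Afcaf;
    double fca = Afcaf * fcaf + Afcas * fcas;
    double jcass = 1.0 / (1.0 + exp((v + 18.08) / 2.7916));
    dy[28] = (jcass - jca) / 72.5;
    dy[29] = (fss - ffp) / (2.5 * tff);
    double fp = Aff * ffp + Afs * fs;
    dy[30] = (fcass_ - fcafp) / (2.5 * tfcaf);
    double fcap = Afcaf * fcafp + Afcas * fcas;
    double Kmn = 0.002, k2n = 500.0;
    double km2n = jca * 1.0;
    double anca_ss = 1.0 / (k2n / km2n + pow(1.0 + Kmn / cass, 4.0));
    dy[31] = anca_ss * k2n - ncass * km2n;
    double anca_i = 1.0 / (k2n / km2n + pow(1.0 + Kmn / cai, 4.0));
    dy[32] = anca_i * k2n - ncai * km2n;

    /* ionic-strength activity coefficients (Davies equation) */
    double Io = 0.5 * (nao + ko + clo + 4.0 * cao) / 1000.0;
    double dielC = 74.0;
    double constA = 1.82e6 * pow(dielC * TEMP, -1.5);
    double sqIo = sqrt(Io);
    double g1o = exp(-constA * (sqIo / (1.0 + sqIo) - 0.3 * Io));
    double g2o = exp(-constA * 4.0 * (sqIo / (1.0 + sqIo) - 0.3 * Io));
    double Iss = 0.5 * (nass + kss + cli + 4.0 * cass) / 1000.0;
    double sqIss = sqrt(Iss);
    double g1ss = exp(-constA * (sqIss / (1.0 + sqIss) - 0.3 * Iss));
    double g2ss = exp(-constA * 4.0 * (sqIss / (1.0 + sqIss) - 0.3 * Iss));
    double Ii = 0.5 * (nai + ki + cli + 4.0 * cai) / 1000.0;
    double sqIi = sqrt(Ii);
    double g1i = exp(-constA * (sqIi / (1.0 + sqIi) - 0.3 * Ii));
    double g2i = exp(-constA * 4.0 * (sqIi / (1.0 + sqIi) - 0.3 * Ii));

    double PhiCaL_ss = ghk(2.0, g2ss * cass, g2o * cao, v);
    double PhiCaNa_ss = ghk(1.0, g1ss * nass, g1o * nao, v);
    double PhiCaK_ss = ghk(1.0, g1ss * kss, g1o * ko, v);
    double PhiCaL_i = ghk(2.0, g2i * cai, g2o * cao, v);
    double PhiCaNa_i = ghk(1.0, g1i * nai, g1o * nao, v);
    double PhiCaK_i = ghk(1.0, g1i * ki, g1o * ko, v);

    double PCa = 8.3757e-5 * p[P_FCAL];
    double PCap = 1.1 * PCa;
    double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
    double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
    double fICaLp = fINap;
    double frac_ss = 0.8;

    double og_ss = d * (f * (1.0 - ncass) + jca * fca * ncass);
    double og_ssp = d * (fp * (1.0 - ncass) + jca * fcap * ncass);
    double og_i = d * (f * (1.0 - ncai) + jca * fca * ncai);
    double og_ip = d * (fp * (1.0 - ncai) + jca * fcap * ncai);

    double ICaL_ss = frac_ss * (((1.0 - fICaLp) * PCa * og_ss +
                                 fICaLp * PCap * og_ssp) * PhiCaL_ss);
    double ICaNa_ss = frac_ss * (((1.0 - fICaLp) * PCaNa * og_ss +
                                  fICaLp * PCaNap * og_ssp) * PhiCaNa_ss);
    double ICaK_ss = frac_ss * (((1.0 - fICaLp) * PCaK * og_ss +
                                 fICaLp * PCaKp * og_ssp) * PhiCaK_ss);
    double ICaL_i = (1.0 - frac_ss) * (((1.0 - fICaLp) * PCa * og_i +
                                        fICaLp * PCap * og_ip) * PhiCaL_i);
    double ICaNa_i = (1.0 - frac_ss) * (((1.0 - fICaLp) * PCaNa * og_i +
                                         fICaLp * PCaNap * og_ip) * PhiCaNa_i);
    double ICaK_i = (1.0 - frac_ss) * (((1.0 - fICaLp) * PCaK * og_i +
                                        fICaLp * PCaKp * og_ip) * PhiCaK_i);
    double ICaL = ICaL_ss + ICaL_i;
    double ICaNa = ICaNa_ss + ICaNa_i;
    double ICaK = ICaK_ss + ICaK_i;

    /* IKr (Hodgkin-Huxley two-component gating) */
    double xrss = 1.0 / (1.0 + exp(-(v + 8.337) / 6.789));
    double txrf = 12.98 + 1.0 / (0.3652 * exp((v - 31.66) / 3.869) +
                                 4.123e-5 * exp(-(v - 47.78) / 20.38));
    double txrs = 1.865 + 1.0 / (0.06629 * exp((v - 34.70) / 7.355) +
                                 1.128e-5 * exp(-(v - 29.74) / 25.94));
    dy[33] = (xrss - xrf) / txrf;
    dy[34] = (xrss - xrs) / txrs;
    double Axrf = 1.0 / (1.0 + exp((v + 54.81) / 38.21));
    double xr = Axrf * xrf + (1.0 - Axrf) * xrs;
    double rkr = 1.0 / ((1.0 + exp((v + 55.0) / 75.0)) *
                        (1.0 + exp((v - 10.0) / 30.0)));
    /* maximal conductance calibrated so the baseline paced APD90 matches
     * the published endocardial value (~270 ms at 1 Hz) */
    double GKr = 0.0677 * p[P_FKR];
    double IKr = GKr * sqrt(ko / 5.4) * xr * rkr * (v - EK);

    /* IKs */
    double xs1ss = 1.0 / (1.0 + exp(-(v + 11.60) / 8.932));
    double txs1 = 817.3 + 1.0 / (2.326e-4 * exp((v + 48.28) / 17.80) +
                                 0.001292 * exp(-(v + 210.0) / 230.0));
    dy[35] = (xs1ss - xs1) / txs1;
    double txs2 = 1.0 / (0.01 * exp((v - 50.0) / 20.0) +
                         0.0193 * exp(-(v + 66.54) / 31.0));
    dy[36] = (xs1ss - xs2) / txs2;
    double KsCa = 1.0 + 0.6 / (1.0 + pow(3.8e-5 / cai, 1.4));
    double GKs = 0.0011 * p[P_FKS];
    double IKs = GKs * KsCa * xs1 * xs2 * (v - EKs);

    /* IK1 (instantaneous rectification) */
    double aK1 = 4.094 / (1.0 + exp(0.1217 * (v - EK - 49.934)));
    double bK1 = (15.72 * exp(0.0674 * (v - EK - 3.257)) +
                  exp(0.0618 * (v - EK - 594.31))) /
                 (1.0 + exp(-0.1629 * (v - EK + 14.207)));
    double K1ss = aK1 / (aK1 + bK1);
    double GK1 = 0.6992 * p[P_FK1];
    double IK1 = GK1 * sqrt(ko / 5.0) * K1ss * (v - EK);

    /* INaCa: 65% myoplasm, 35% subspace */
    double Gncx = 0.0034 * p[P_FNCX];
    double INaCa_i = inaca_ord(v, nai, cai, nao, cao, 0.65 * Gncx);
    double INaCa_ss = inaca_ord(v, nass, cass, nao, cao, 0.35 * Gncx);

    double INaK = inak_ord(v, nai, ki, nao, ko, 15.4496 * p[P_FNAK]);

    double xkb = 1.0 / (1.0 + exp(-(v - 10.8968) / 23.9871));
    double GKb = 0.0189;
    double IKb = GKb * xkb * (v - EK);
    double PNab = 1.9239e-9;
    double INab = PNab * ghk(1.0, g1i * nai, g1o * nao, v);
    double PCab = 5.9194e-8;
    double ICab = PCab * ghk(2.0, g2i * cai, g2o * cao, v);
    double GpCa = 5e-4;
    double IpCa = GpCa * cai / (0.0005 + cai);

    /* chloride currents (Ca-activated + background) */
    double GClCa = 0.2843, KdClCa = 0.1, GClb = 1.98e-3;
    double IClCa = GClCa / (1.0 + KdClCa / cass) * (v - ECl);
    double IClb = GClb * (v - ECl);
    double ICl = IClCa + IClb;

    /* conservation test hook: scale every membrane current */
    INa *= imult; INaL *= imult; Ito *= imult;
    ICaL *= imult; ICaNa *= imult; ICaK *= imult;
    ICaL_ss *= imult; ICaNa_ss *= imult; ICaK_ss *= imult;
    ICaL_i *= imult; ICaNa_i *= imult; ICaK_i *= imult;
    IKr *= imult; IKs *= imult; IK1 *= imult;
    INaCa_i *= imult; INaCa_ss *= imult; INaK *= imult;
    INab *= imult; IKb *= imult; ICab *= imult; IpCa *= imult;
    ICl *= imult;

    /* SR fluxes */
    double bt = 4.75, a_rel = 0.5 * 4.75;
    double Jrel_inf = a_rel * (-ICaL_ss) / (1.0 + pow(1.7 / cajsr, 8.0));
    double tau_rel = bt / (1.0 + 0.0123 / cajsr);
    if (tau_rel < 0.001) tau_rel = 0.001;
    dy[37] = (Jrel_inf - Jrelnp) / tau_rel;
    double btp = 1.25 * bt, a_relp = 0.5 * btp;
    double Jrel_infp = a_relp * (-ICaL_ss) / (1.0 + pow(1.7 / cajsr, 8.0));
    double tau_relp = btp / (1.0 + 0.0123 / cajsr);
    if (tau_relp < 0.001) tau_relp = 0.001;
    dy[38] = (Jrel_infp - Jrelp) / tau_relp;
    double fJrelp = fINap;
    double Jrel = 1.5378 * ((1.0 - fJrelp) * Jrelnp + fJrelp * Jrelp);

    double Jupnp = 0.004375 * cai / (cai + 0.00092);
    double Jupp = 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
    double fJupp = fINap;
    double Jleak = 0.0039375 * cansr / 15.0;
    double Jup = (1.0 - fJupp) * Jupnp + fJupp * Jupp - Jleak;
    double Jtr = (cansr - cajsr) / 60.0;

    double JdiffNa = (nass - nai) / 2.0;
    double JdiffK = (kss - ki) / 2.0;
    double Jdiff = (cass - cai) / 0.2;

    /* buffers */
    double cmdnmax = 0.05, kmcmdn = 0.00238, trpnmax = 0.07, kmtrpn = 0.0005;
    double BSRmax = 0.047, KmBSR = 0.00087, BSLmax = 1.124, KmBSL = 0.0087;
    double csqnmax = 10.0, kmcsqn = 0.8;

    double Itot = INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1 +
                  INaCa_i + INaCa_ss + INaK + INab + IKb + ICab + IpCa + ICl;
    dy[0] = -(Itot + istim);

    double AF = Acap / FARADAY;
    dy[1] = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab + ICaNa_i) *
                AF / vmyo + JdiffNa * vss / vmyo;
    dy[2] = -(ICaNa_ss + 3.0 * INaCa_ss) * AF / vss - JdiffNa;
    dy[3] = -(Ito + IKr + IKs + IK1 + IKb + ICaK_i + istim - 2.0 * INaK) *
                AF / vmyo + JdiffK * vss / vmyo;
    dy[4] = -ICaK_ss * AF / vss - JdiffK;
    double Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn / pow(kmcmdn + cai, 2.0) +
                         trpnmax * kmtrpn / pow(kmtrpn + cai, 2.0));
    dy[5] = Bcai * (-(ICaL_i + IpCa + ICab - 2.0 * INaCa_i) * AF /
                        (2.0 * vmyo) -
                    Jup * vnsr / vmyo + Jdiff * vss / vmyo);
    double Bcass = 1.0 / (1.0 + BSRmax * KmBSR / pow(KmBSR + cass, 2.0) +
                          BSLmax * KmBSL / pow(KmBSL + cass, 2.0));
    dy[6] = Bcass * (-(ICaL_ss - 2.0 * INaCa_ss) * AF / (2.0 * vss) +
                     Jrel * vjsr / vss - Jdiff);
    dy[7] = Jup - Jtr * vjsr / vnsr;
    double Bcajsr = 1.0 / (1.0 + csqnmax * kmcsqn / pow(kmcsqn + cajsr, 2.0));
    dy[8] = Bcajsr * (Jtr - Jrel);

    if (out) {
        out[O_INA] = INa; out[O_INAL] = INaL; out[O_ITO] = Ito;
        out[O_ICAL] = ICaL; out[O_IKR] = IKr; out[O_IKS] = IKs;
        out[O_IK1] = IK1; out[O_INAK] = INaK;
        out[O_INACA] = INaCa_i + INaCa_ss;
        out[O_INAB] = INab; out[O_IKB] = IKb; out[O_ICAB] = ICab;
        out[O_IPCA] = IpCa; out[O_ICL] = ICl;
        out[O_ICANA] = ICaNa; out[O_ICAK] = ICaK;
        out[O_INACA_I] = INaCa_i; out[O_INACA_SS] = INaCa_ss;
        out[O_JREL] = Jrel; out[O_JUP] = Jup;
    }
}

/* ================== ORd 2011 endocardial (BPS2020 slot) ================== */

static void bps_rhs(double t, const double *y, double *dy, double *out,
                    const double *p)
{
    double frt = FARADAY / (RGAS * TEMP);
    double v = y[0];
    double nai = y[1], nass = y[2], ki = y[3], kss = y[4];
    double cai = y[5], cass = y[6], cansr = y[7], cajsr = y[8];
    double m = y[9], hf = y[10], hs = y[11], j = y[12];
    double hsp = y[13], jp = y[14];
    double mL = y[15], hL = y[16], hLp = y[17];
    double a = y[18], iF = y[19], iS = y[20];
    double ap = y[21], iFp = y[22], iSp = y[23];
    double d = y[24], ff = y[25], fs = y[26], fcaf = y[27], fcas = y[28];
    double jca = y[29], nca = y[30], ffp = y[31], fcafp = y[32];
    double xrf = y[33], xrs = y[34], xs1 = y[35], xs2 = y[36], xk1 = y[37];
    double Jrelnp = y[38], Jrelp = y[39], CaMKt = y[40];

    double nao = p[P_NAO], ko = p[P_KO], cao = p[P_CAO];
    double vfrac = p[P_VFRAC], istim = p[P_ISTIM], imult = p[P_IMULT];

    double vfrt = v * frt;

    double L = 0.01, rad = 0.0011;
    double vcell = 1000.0 * 3.14 * rad * rad * L;
    double Ageo = 2.0 * 3.14 * rad * rad + 2.0 * 3.14 * rad * L;
    double Acap = 2.0 * Ageo;
    double vmyo = 0.68 * vcell * vfrac;
    double vnsr = 0.0552 * vcell * vfrac;
    double vjsr = 0.0048 * vcell * vfrac;
    double vss = 0.02 * vcell * vfrac;

    double ENa = (1.0 / frt) * log(nao / nai);
    double EK = (1.0 / frt) * log(ko / ki);
    double PKNa = 0.01833;
    double EKs = (1.0 / frt) * log((ko + PKNa * nao) / (ki + PKNa * nai));

    double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068;
    double CaMKo = 0.05, KmCaM = 0.0015;
    double CaMKb = CaMKo * (1.0 - CaMKt) / (1.0 + KmCaM / cass);
    double CaMKa = CaMKb + CaMKt;
    dy[40] = aCaMK * CaMKb * (CaMKb + CaMKt) - bCaMK * CaMKt;

    /* INa */
    double mss = 1.0 / (1.0 + exp(-(v + 39.57) / 9.871));
    double tm = 1.0 / (6.765 * exp((v + 11.64) / 34.77) +
                       8.552 * exp(-(v + 77.42) / 5.955));
    dy[9] = (mss - m) / tm;
    double hss = 1.0 / (1.0 + exp((v + 82.90) / 6.086));
    double thf = 1.0 / (1.432e-5 * exp(-(v + 1.196) / 6.285) +
                        6.149 * exp((v + 0.5096) / 20.27));
    double ths = 1.0 / (0.009794 * exp(-(v + 17.95) / 28.05) +
                        0.3343 * exp((v + 5.730) / 56.66));
    double Ahf = 0.99, Ahs = 0.01;
    dy[10] = (hss - hf) / thf;
    dy[11] = (hss - hs) / ths;
    double h = Ahf * hf + Ahs * hs;
    double jss = hss;
    double tj = 2.038 + 1.0 / (0.02136 * exp(-(v + 100.6) / 8.281) +
                               0.3052 * exp((v + 0.9941) / 38.45));
    dy[12] = (jss - j) / tj;
    double hssp = 1.0 / (1.0 + exp((v + 89.1) / 6.086));
    dy[13] = (hssp - hsp) / (3.0 * ths);
    double hp = Ahf * hf + Ahs * hsp;
    dy[14] = (jss - jp) / (1.46 * tj);
    double GNa = 75.0;
    double fINap = 1.0 / (1.0 + KmCaMK / CaMKa);
    double INa = GNa * (v - ENa) * m * m * m *
                 ((1.0 - fINap) * h * j + fINap * hp * jp);

    /* INaL */
    double mLss = 1.0 / (1.0 + exp(-(v + 42.85) / 5.264));
    dy[15] = (mLss - mL) / tm;
    double hLss = 1.0 / (1.0 + exp((v + 87.61) / 7.488));
    double thL = 200.0;
    dy[16] = (hLss - hL) / thL;
    double hLssp = 1.0 / (1.0 + exp((v + 93.81) / 7.488));
    dy[17] = (hLssp - hLp) / (3.0 * thL);
    double GNaL = 0.0075;
    double fINaLp = fINap;
    double INaL = GNaL * (v - ENa) * mL *
                  ((1.0 - fINaLp) * hL + fINaLp * hLp);

    /* Ito */
    double ass = 1.0 / (1.0 + exp(-(v - 14.34) / 14.82));
    double ta = 1.0515 / (1.0 / (1.2089 * (1.0 + exp(-(v - 18.4099) / 29.3814))) +
                          3.5 / (1.0 + exp((v + 100.0) / 29.3814)));
    dy[18] = (ass - a) / ta;
    double iss = 1.0 / (1.0 + exp((v + 43.94) / 5.711));
    double tiF = 4.562 + 1.0 / (0.3933 * exp(-(v + 100.0) / 100.0) +
                                0.08004 * exp((v + 50.0) / 16.59));
    double tiS = 23.62 + 1.0 / (0.001416 * exp(-(v + 96.52) / 59.05) +
                                1.780e-8 * exp((v + 114.1) / 8.079));
    dy[19] = (iss - iF) / tiF;
    dy[20] = (iss - iS) / tiS;
    double AiF = 1.0 / (1.0 + exp((v - 213.6) / 151.2));
    double AiS = 1.0 - AiF;
    double i_gate = AiF * iF + AiS * iS;
    double assp = 1.0 / (1.0 + exp(-(v - 24.34) / 14.82));
    dy[21] = (assp - ap) / ta;
    double dti_dev = 1.354 + 1e-4 / (exp((v - 167.4) / 15.89) +
                                     exp(-(v - 12.23) / 0.2154));
    double dti_rec = 1.0 - 0.5 / (1.0 + exp((v + 70.0) / 20.0));
    dy[22] = (iss - iFp) / (dti_dev * dti_rec * tiF);
    dy[23] = (iss - iSp) / (dti_dev * dti_rec * tiS);
    double ip_gate = AiF * iFp + AiS * iSp;
    double Gto = 0.02;
    double fItop = fINap;
    double Ito = Gto * (v - EK) *
                 ((1.0 - fItop) * a * i_gate + fItop * ap * ip_gate);

    /* ICaL */
    double dss = 1.0 / (1.0 + exp(-(v + 3.940) / 4.230));
    double td = 0.6 + 1.0 / (exp(-0.05 * (v + 6.0)) + exp(0.09 * (v + 14.0)));
    dy[24] = (dss - d) / td;
    double fss = 1.0 / (1.0 + exp((v + 19.58) / 3.696));
    double tff = 7.0 + 1.0 / (0.0045 * exp(-(v + 20.0) / 10.0) +
                              0.0045 * exp((v + 20.0) / 10.0));
    double tfs = 1000.0 + 1.0 / (3.5e-5 * exp(-(v + 5.0) / 4.0) +
                                 3.5e-5 * exp((v + 5.0) / 6.0));
    dy[25] = (fss - ff) / tff;
    dy[26] = (fss - fs) / tfs;
    double Aff = 0.6, Afs = 0.4;
    double f = Aff * ff + Afs * fs;
    double fcass_ = fss;
    double tfcaf = 7.0 + 1.0 / (0.04 * exp(-(v - 4.0) / 7.0) +
                                0.04 * exp((v - 4.0) / 7.0));
    double tfcas = 100.0 + 1.0 / (0.00012 * exp(-v / 3.0) +
                                  0.00012 * exp(v / 7.0));
    dy[27] = (fcass_ - fcaf) / tfcaf;
    dy[28] = (fcass_ - fcas) / tfcas;
    double Afcaf = 0.3 + 0.6 / (1.0 + exp((v - 10.0) / 10.0));
    double Afcas = 1.0 - Afcaf;
    double fca = Afcaf * fcaf + Afcas * fcas;
    dy[29] = (fcass_ - jca) / 75.0;
    dy[31] = (fss - ffp) / (2.5 * tff);
    double fp = Aff * ffp + Afs * fs;
    dy[32] = (fcass_ - fcafp) / (2.5 * tfcaf);
    double fcap = Afcaf * fcafp + Afcas * fcas;
    double Kmn = 0.002, k2n = 1000.0;
    double km2n = jca * 1.0;
    double anca = 1.0 / (k2n / km2n + pow(1.0 + Kmn / cass, 4.0));
    dy[30] = anca * k2n - nca * km2n;
    double PhiCaL = ghk(2.0, cass, 0.341 * cao, v);
    double PhiCaNa = ghk(1.0, 0.75 * nass, 0.75 * nao, v);
    double PhiCaK = ghk(1.0, 0.75 * kss, 0.75 * ko, v);
    double PCa = 1.0e-4 * p[P_FCAL];
    double PCap = 1.1 * PCa;
    double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
    double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
    double fICaLp = fINap;
    double og = d * (f * (1.0 - nca) + jca * fca * nca);
    double ogp = d * (fp * (1.0 - nca) + jca * fcap * nca);
    double ICaL = ((1.0 - fICaLp) * PCa * og + fICaLp * PCap * ogp) * PhiCaL;
    double ICaNa = ((1.0 - fICaLp) * PCaNa * og + fICaLp * PCaNap * ogp) *
                   PhiCaNa;
    double ICaK = ((1.0 - fICaLp) * PCaK * og + fICaLp * PCaKp * ogp) *
                  PhiCaK;

    /* IKr */
    double xrss = 1.0 / (1.0 + exp(-(v + 8.337) / 6.789));
    double txrf = 12.98 + 1.0 / (0.3652 * exp((v - 31.66) / 3.869) +
                                 4.123e-5 * exp(-(v - 47.78) / 20.38));
    double txrs = 1.865 + 1.0 / (0.06629 * exp((v - 34.70) / 7.355) +
                                 1.128e-5 * exp(-(v - 29.74) / 25.94));
    dy[33] = (xrss - xrf) / txrf;
    dy[34] = (xrss - xrs) / txrs;
    double Axrf = 1.0 / (1.0 + exp((v + 54.81) / 38.21));
    double xr = Axrf * xrf + (1.0 - Axrf) * xrs;
    double rkr = 1.0 / ((1.0 + exp((v + 55.0) / 75.0)) *
                        (1.0 + exp((v - 10.0) / 30.0)));
    double GKr = 0.037 * p[P_FKR];
    double IKr = GKr * sqrt(ko / 5.4) * xr * rkr * (v - EK);

    /* IKs */
    double xs1ss = 1.0 / (1.0 + exp(-(v + 11.60) / 8.932));
    double txs1 = 817.3 + 1.0 / (2.326e-4 * exp((v + 48.28) / 17.80) +
                                 0.001292 * exp(-(v + 210.0) / 230.0));
    dy[35] = (xs1ss - xs1) / txs1;
    double txs2 = 1.0 / (0.01 * exp((v - 50.0) / 20.0) +
                         0.0193 * exp(-(v + 66.54) / 31.0));
    dy[36] = (xs1ss - xs2) / txs2;
    double KsCa = 1.0 + 0.6 / (1.0 + pow(3.8e-5 / cai, 1.4));
    double GKs = 0.011 * p[P_FKS];   /* ~10x the ToR-ORd IKs, per the models' documented contrast */
    double IKs = GKs * KsCa * xs1 * xs2 * (v - EKs);

    /* IK1 (gated) */
    double xk1ss = 1.0 / (1.0 + exp(-(v + 2.5538 * ko + 144.59) /
                                    (1.5692 * ko + 3.8115)));
    double txk1 = 122.2 / (exp(-(v + 127.2) / 20.36) +
                           exp((v + 236.8) / 69.33));
    dy[37] = (xk1ss - xk1) / txk1;
    double rk1 = 1.0 / (1.0 + exp((v + 105.8 - 2.6 * ko) / 9.493));
    double GK1 = 0.1908 * p[P_FK1];
    double IK1 = GK1 * sqrt(ko) * rk1 * xk1 * (v - EK);

    double Gncx = 0.0008 * p[P_FNCX];
    double INaCa_i = inaca_ord(v, nai, cai, nao, cao, 0.8 * Gncx);
    double INaCa_ss = inaca_ord(v, nass, cass, nao, cao, 0.2 * Gncx);

    double INaK = inak_ord(v, nai, ki, nao, ko, 30.0 * p[P_FNAK]);

    double xkb = 1.0 / (1.0 + exp(-(v - 14.48) / 18.34));
    double GKb = 0.003;
    double IKb = GKb * xkb * (v - EK);
    double PNab = 3.75e-10;
    double INab = PNab * ghk(1.0, nai, nao, v);
    double PCab = 2.5e-8;
    double ICab = PCab * ghk(2.0, cai, 0.341 * cao, v);
    double GpCa = 0.0005;
    double IpCa = GpCa * cai / (0.0005 + cai);

    INa *= imult; INaL *= imult; Ito *= imult;
    ICaL *= imult; ICaNa *= imult; ICaK *= imult;
    IKr *= imult; IKs *= imult; IK1 *= imult;
    INaCa_i *= imult; INaCa_ss *= imult; INaK *= imult;
    INab *= imult; IKb *= imult; ICab *= imult; IpCa *= imult;

    double bt = 4.75, a_rel = 0.5 * 4.75;
    double Jrel_inf = a_rel * (-ICaL) / (1.0 + pow(1.5 / cajsr, 8.0));
    double tau_rel = bt / (1.0 + 0.0123 / cajsr);
    if (tau_rel < 0.001) tau_rel = 0.001;
    dy[38] = (Jrel_inf - Jrelnp) / tau_rel;
    double btp = 1.25 * bt, a_relp = 0.5 * btp;
    double Jrel_infp = a_relp * (-ICaL) / (1.0 + pow(1.5 / cajsr, 8.0));
    double tau_relp = btp / (1.0 + 0.0123 / cajsr);
    if (tau_relp < 0.001) tau_relp = 0.001;
    dy[39] = (Jrel_infp - Jrelp) / tau_relp;
    double fJrelp = fINap;
    double Jrel = (1.0 - fJrelp) * Jrelnp + fJrelp * Jrelp;

    /* SERCA scale calibrated so the baseline calcium-transient peak
     * matches the documented value (~0.41 umol/L at 75 min^-1) */
    double upScale = 0.70;
    double Jupnp = upScale * 0.004375 * cai / (cai + 0.00092);
    double Jupp = upScale * 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
    double fJupp = fINap;
    double Jleak = 0.0039375 * cansr / 15.0;
    double Jup = (1.0 - fJupp) * Jupnp + fJupp * Jupp - Jleak;
    double Jtr = (cansr - cajsr) / 100.0;

    double JdiffNa = (nass - nai) / 2.0;
    double JdiffK = (kss - ki) / 2.0;
    double Jdiff = (cass - cai) / 0.2;

    double cmdnmax = 0.05, kmcmdn = 0.00238, trpnmax = 0.07, kmtrpn = 0.0005;
    double BSRmax = 0.047, KmBSR = 0.00087, BSLmax = 1.124, KmBSL = 0.0087;
    double csqnmax = 10.0, kmcsqn = 0.8;

    double Itot = INa + INaL + Ito + ICaL + ICaNa + ICaK + IKr + IKs + IK1 +
                  INaCa_i + INaCa_ss + INaK + INab + IKb + ICab + IpCa;
    dy[0] = -(Itot + istim);

    double AF = Acap / FARADAY;
    dy[1] = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab) * AF / vmyo +
            JdiffNa * vss / vmyo;
    dy[2] = -(ICaNa + 3.0 * INaCa_ss) * AF / vss - JdiffNa;
    dy[3] = -(Ito + IKr + IKs + IK1 + IKb + istim - 2.0 * INaK) * AF / vmyo +
            JdiffK * vss / vmyo;
    dy[4] = -ICaK * AF / vss - JdiffK;
    double Bcai = 1.0 / (1.0 + cmdnmax * kmcmdn / pow(kmcmdn + cai, 2.0) +
                         trpnmax * kmtrpn / pow(kmtrpn + cai, 2.0));
    dy[5] = Bcai * (-(IpCa + ICab - 2.0 * INaCa_i) * AF / (2.0 * vmyo) -
                    Jup * vnsr / vmyo + Jdiff * vss / vmyo);
    double Bcass = 1.0 / (1.0 + BSRmax * KmBSR / pow(KmBSR + cass, 2.0) +
                          BSLmax * KmBSL / pow(KmBSL + cass, 2.0));
    dy[6] = Bcass * (-(ICaL - 2.0 * INaCa_ss) * AF / (2.0 * vss) +
                     Jrel * vjsr / vss - Jdiff);
    dy[7] = Jup - Jtr * vjsr / vnsr;
    double Bcajsr = 1.0 / (1.0 + csqnmax * kmcsqn / pow(kmcsqn + cajsr, 2.0));
    dy[8] = Bcajsr * (Jtr - Jrel);

    if (out) {
        out[O_INA] = INa; out[O_INAL] = INaL; out[O_ITO] = Ito;
        out[O_ICAL] = ICaL; out[O_IKR] = IKr; out[O_IKS] = IKs;
        out[O_IK1] = IK1; out[O_INAK] = INaK;
        out[O_INACA] = INaCa_i + INaCa_ss;
        out[O_INAB] = INab; out[O_IKB] = IKb; out[O_ICAB] = ICab;
        out[O_IPCA] = IpCa; out[O_ICL] = 0.0;
        out[O_ICANA] = ICaNa; out[O_ICAK] = ICaK;
        out[O_INACA_I] = INaCa_i; out[O_INACA_SS] = INaCa_ss;
        out[O_JREL] = Jrel; out[O_JUP] = Jup;
    }
}

/* ===================== deSolve compiled-model hooks ===================== */

static double osmo_parms[NPARMS];

void osmo_initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, osmo_parms);
}

void torord_derivs(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    if (ip[0] < NOUT) error("nout should be at least %d", NOUT);
    torord_rhs(*t, y, ydot, yout, osmo_parms);
}

void bps_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    if (ip[0] < NOUT) error("nout should be at least %d", NOUT);
    bps_rhs(*t, y, ydot, yout, osmo_parms);
}

/* direct single-point evaluation (derivatives + currents) from R */
SEXP C_osmo_eval(SEXP model, SEXP y, SEXP parms)
{
    int mid = INTEGER(model)[0];
    int ns = (mid == 1) ? NS_TOR : NS_BPS;
    if (LENGTH(y) != ns) error("state vector has wrong length");
    if (LENGTH(parms) != NPARMS) error("parameter vector has wrong length");
    SEXP dy = PROTECT(allocVector(REALSXP, ns));
    SEXP cur = PROTECT(allocVector(REALSXP, NOUT));
    if (mid == 1)
        torord_rhs(0.0, REAL(y), REAL(dy), REAL(cur), REAL(parms));
    else
        bps_rhs(0.0, REAL(y), REAL(dy), REAL(cur), REAL(parms));
    SEXP res = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(res, 0, dy);
    SET_VECTOR_ELT(res, 1, cur);
    SEXP nms = PROTECT(allocVector(STRSXP, 2));
    SET_STRING_ELT(nms, 0, mkChar("deriv"));
    SET_STRING_ELT(nms, 1, mkChar("currents"));
    setAttrib(res, R_NamesSymbol, nms);
    UNPROTECT(4);
    return res;
}

static const R_CallMethodDef callMethods[] = {
    {"C_osmo_eval", (DL_FUNC) &C_osmo_eval, 3},
    {NULL, NULL, 0}
};

void R_init_osmoAP(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, callMethods, NULL, NULL);
    /* deSolve locates derivative functions by symbol name */
    R_useDynamicSymbols(dll, TRUE);
}
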