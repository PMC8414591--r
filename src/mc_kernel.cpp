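// Monte Carlo engine for the half-sarcomere cross-bridge model, plus the
// implicit (MusAsi) and explicit active tension kernels that re-read the
// per-interval event record.  All hot loops live here; the R layer owns
// parameter handling, orchestration and analysis.
//
// State codes: 0 N_XB, 1 P_XB, 2 N_ATP, 3 XB_PreR, 4 XB_PostR1, 5 XB_PostR2.
// T/T codes:   0 off, 1 on_Ca, 2 open.
// Units: nm, pN, ms, uM externally; rate constants in 1/s (dt converted).

#include <Rcpp.h>
#include <cfloat>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Par {
  int kind;                       // 0 DSE, 1 BSE
  double pre1, pre2, dE1, dE2, s1, s2;
  double kpos, kneg, kBT, xmax, rmax;
  double knp, kpn, gamma, ttblocked;
  double fattach, ddetach, dpost2, katp;
  double kCaOn, kCaOff, kOpen, kClose;
  double L;                       // SL0 / 2 (nm)
  int NM, NF;
  double SA0, RS;
  double ov0, ov1, ov2, ov3;      // overlap tent breakpoints (stretch)
};

Par read_par(const List& p) {
  Par q;
  q.kind = as<int>(p["kind"]);
  q.pre1 = p["pre1"]; q.pre2 = p["pre2"];
  q.dE1 = p["dE1"]; q.dE2 = p["dE2"]; q.s1 = p["s1"]; q.s2 = p["s2"];
  q.kpos = p["kpos"]; q.kneg = p["kneg"]; q.kBT = p["kBT"];
  q.xmax = p["xmax"]; q.rmax = p["rmax"];
  q.knp = p["knp"]; q.kpn = p["kpn"]; q.gamma = p["gamma"];
  q.ttblocked = p["ttblocked"];
  q.fattach = p["fattach"]; q.ddetach = p["ddetach"];
  q.dpost2 = p["dpost2"]; q.katp = p["katp"];
  q.kCaOn = p["kCaOn"]; q.kCaOff = p["kCaOff"];
  q.kOpen = p["kOpen"]; q.kClose = p["kClose"];
  q.L = p["L"]; q.NM = as<int>(p["NM"]); q.NF = as<int>(p["NF"]);
  q.SA0 = p["SA0"]; q.RS = p["RS"];
  NumericVector ov = p["ov"];
  q.ov0 = ov[0]; q.ov1 = ov[1]; q.ov2 = ov[2]; q.ov3 = ov[3];
  return q;
}

// tent-shaped thick/thin filament overlap factor in [0, 1]
inline double overlap_at(const Par& p, double lam) {
  double up = (lam - p.ov0) / std::max(p.ov1 - p.ov0, 1e-12);
  double dn = (p.ov3 - lam) / std::max(p.ov3 - p.ov2, 1e-12);
  double f = std::min(std::min(up, dn), 1.0);
  return f > 0.0 ? f : 0.0;
}

// rod strain energy, smoothly extended beyond the admissible domain
// (transitions that would overshoot the domain get vanishing rates from the
// quadratic growth; actual domain exit is handled by forced detachment).
inline double Wrod(const Par& p, double x) {
  const double k = (x >= 0.0) ? p.kpos : p.kneg;
  return 0.5 * k * x * x;
}

// Matched, capped rate pair for stroke i evaluated at pre-stroke strain x:
// hf = h_{f,i}(x), hb = h_{b,i}(x + s_i).  Capping rescales both members so
// the detailed-balance ratio is preserved exactly.
inline void stroke_pair(const Par& p, int i, double x, double& hf, double& hb) {
  const double si = (i == 1) ? p.s1 : p.s2;
  const double dE = (i == 1) ? p.dE1 : p.dE2;
  const double pre = (i == 1) ? p.pre1 : p.pre2;
  if (p.kind == 0) {            // destination strain energy
    hf = pre * std::exp(-(Wrod(p, x + si) - dE) / p.kBT);
    hb = pre * std::exp(-Wrod(p, x) / p.kBT);
  } else {                      // barrier strain energy (Kramers)
    const double Wb = Wrod(p, x + 0.5 * si);
    hf = pre * std::exp((dE + Wrod(p, x) - Wb) / p.kBT);
    hb = pre * std::exp((Wrod(p, x + si) - Wb) / p.kBT);
  }
  if (!std::isfinite(hf)) hf = DBL_MAX;
  if (!std::isfinite(hb)) hb = DBL_MAX;
  const double hi = (hf > hb) ? hf : hb;
  if (hi > p.rmax) {
    const double sc = p.rmax / hi;
    hf *= sc; hb *= sc;
  }
}

// Boltzmann attachment strain: asymmetric truncated Gaussian (uniform for a
// zero-stiffness rod).
inline double draw_attachment_strain(const Par& p) {
  if (p.kpos == 0.0 && p.kneg == 0.0)
    return R::runif(-p.xmax, p.xmax);
  const double sdp = std::sqrt(p.kBT / p.kpos);
  const double sdn = std::sqrt(p.kBT / p.kneg);
  const double mp = sdp * (R::pnorm(p.xmax / sdp, 0.0, 1.0, 1, 0) - 0.5);
  const double mn = sdn * (R::pnorm(p.xmax / sdn, 0.0, 1.0, 1, 0) - 0.5);
  const bool pos = R::unif_rand() < mp / (mp + mn);
  const double sd = pos ? sdp : sdn;
  double v;
  do { v = std::fabs(R::norm_rand()) * sd; } while (v > p.xmax);
  return pos ? v : -v;
}

}  // namespace

// [[Rcpp::export]]
List mc_interval_cpp(IntegerVector state_, NumericVector xA_, NumericVector s_,
                     NumericVector lamA_, IntegerVector tt_,
                     List par, double lambda_T, double lambda_dot_T,
                     double dt, int n, NumericVector ca) {
  const Par p = read_par(par);
  const int M = state_.size();
  if (ca.size() != n) stop("ca must have one value per micro-step");
  const double dts = dt * 1e-3;  // rates are 1/s, dt is ms

  std::vector<int> st(state_.begin(), state_.end());
  std::vector<double> xA(xA_.begin(), xA_.end());
  std::vector<double> sOf(s_.begin(), s_.end());
  std::vector<double> lamA(lamA_.begin(), lamA_.end());
  std::vector<int> tt(tt_.begin(), tt_.end());
  std::vector<int> kAify(M, 0);   // attachment micro-step within this interval

  IntegerMatrix deltaA(n, M);
  NumericMatrix xAmat(n, M), sMat(n, M), lamAcarry(n, M), xTilde(n, M);
  IntegerMatrix kAmat(n, M);

  std::vector<int> ev_k, ev_mol, ev_from, ev_to;
  std::vector<int> st_old(M), tt_old(M);
  // compressed bound-entry record (what the tension kernels iterate over)
  std::vector<int> b_k, b_kA;
  std::vector<double> b_xA, b_s, b_lamA, b_xT;

  const double g1 = p.gamma, g2 = p.gamma * p.gamma;
  const double gm1 = 1.0 / g1, gm2 = 1.0 / g2;

  for (int k = 1; k <= n; ++k) {
    const double lam_k = lambda_T + k * dt * lambda_dot_T;  // extrapolated
    const double Ca = ca[k - 1];
    std::copy(st.begin(), st.end(), st_old.begin());
    std::copy(tt.begin(), tt.end(), tt_old.begin());

    // --- T/T units first ---------------------------------------------------
    for (int m = 0; m < M; ++m) {
      double r1 = 0, r2 = 0; int t1 = -1, t2 = -1;
      switch (tt[m]) {
      case 0: r1 = p.kCaOn * Ca; t1 = 1; break;
      case 1: r1 = p.kCaOff; t1 = 0; r2 = p.kOpen; t2 = 2; break;
      case 2: r1 = p.kClose; t1 = 1; break;
      }
      const double rtot = r1 + r2;
      if (rtot <= 0.0) continue;
      const double u = R::unif_rand();
      const double ptr = -std::expm1(-rtot * dts);
      if (u < ptr) {
        const double pick = u / ptr * rtot;
        tt[m] = (pick < r1) ? t1 : t2;
      }
    }

    // --- myosin molecules (synchronous neighbour counts) -------------------
    for (int m = 0; m < M; ++m) {
      const int i = m % p.NM;  // position within filament
      int ng = 0;
      if (i > 0 && st_old[m - 1] >= 1 && st_old[m - 1] != 2) ++ng;
      if (i < p.NM - 1 && st_old[m + 1] >= 1 && st_old[m + 1] != 2) ++ng;
      const double gfac = (ng == 0) ? 1.0 : (ng == 1 ? g1 : g2);
      const double gfacInv = (ng == 0) ? 1.0 : (ng == 1 ? gm1 : gm2);

      double r[3] = {0, 0, 0};
      int tgt[3] = {-1, -1, -1};
      int ne = 0;
      double x = 0.0;

      const int s0 = st[m];
      if (s0 >= 3) {  // strong binding: evaluate strain, forced detachment
        x = xA[m] + sOf[m] + p.L * (lam_k - lamA[m]);
        if (std::fabs(x) > p.xmax) {
          ev_k.push_back(k); ev_mol.push_back(m + 1);
          ev_from.push_back(s0); ev_to.push_back(2);
          st[m] = 2;  // N_ATP
          xA[m] = NA_REAL; lamA[m] = NA_REAL; sOf[m] = 0.0; kAify[m] = 0;
          continue;
        }
      }

      switch (s0) {
      case 0: {  // N_XB -> P_XB, gated by the T/T unit, promoted by neighbours
        const double ttf = (tt[m] == 2) ? 1.0 : p.ttblocked;
        r[0] = p.knp * gfac * ttf; tgt[0] = 1; ne = 1;
        break;
      }
      case 1: {  // P_XB -> N_XB (suppressed by neighbours) | -> XB_PreR
        r[0] = p.kpn * gfacInv; tgt[0] = 0;
        r[1] = p.fattach * overlap_at(p, lam_k); tgt[1] = 3; ne = 2;
        break;
      }
      case 2: {  // N_ATP -> N_XB (ATP consuming recovery)
        r[0] = p.katp; tgt[0] = 0; ne = 1;
        break;
      }
      case 3: {  // XB_PreR: power stroke 1 | detach to P_XB
        double hf, hb;
        stroke_pair(p, 1, x, hf, hb);
        r[0] = hf; tgt[0] = 4;
        r[1] = p.ddetach; tgt[1] = 1; ne = 2;
        break;
      }
      case 4: {  // XB_PostR1: reverse stroke 1 | power stroke 2
        double hf1, hb1, hf2, hb2;
        stroke_pair(p, 1, x - p.s1, hf1, hb1);
        stroke_pair(p, 2, x, hf2, hb2);
        r[0] = hb1; tgt[0] = 3;
        r[1] = hf2; tgt[1] = 5; ne = 2;
        break;
      }
      case 5: {  // XB_PostR2: reverse stroke 2 | cycle completion (ATP)
        double hf2, hb2;
        stroke_pair(p, 2, x - p.s2, hf2, hb2);
        r[0] = hb2; tgt[0] = 4;
        r[1] = p.dpost2; tgt[1] = 0; ne = 2;
        break;
      }
      }

      double rtot = 0.0;
      for (int e = 0; e < ne; ++e) {
        if (r[e] > p.rmax) r[e] = p.rmax;  // generic cap for stable MC steps
        rtot += r[e];
      }
      if (rtot * dts > 0.6) {
        stop("total exit rate %.3g/s at state %d exceeds the one-transition"
             " bound for dt = %g ms", rtot, s0, dt);
      }
      if (rtot > 0.0) {
        const double u = R::unif_rand();
        const double ptr = -std::expm1(-rtot * dts);
        if (u < ptr) {
          const double pick = u / ptr * rtot;
          double acc = 0.0; int chosen = ne - 1;
          for (int e = 0; e < ne; ++e) {
            acc += r[e];
            if (pick < acc) { chosen = e; break; }
          }
          const int s1n = tgt[chosen];
          ev_k.push_back(k); ev_mol.push_back(m + 1);
          ev_from.push_back(s0); ev_to.push_back(s1n);
          // bookkeeping on the edges that change binding/stroke structure
          if (s0 == 1 && s1n == 3) {            // fresh attachment
            xA[m] = draw_attachment_strain(p);
            lamA[m] = lam_k;
            sOf[m] = 0.0;
            kAify[m] = k;
          } else if (s0 >= 3 && s1n < 3) {      // detachment
            xA[m] = NA_REAL; lamA[m] = NA_REAL; sOf[m] = 0.0; kAify[m] = 0;
          } else if (s0 == 3 && s1n == 4) {
            sOf[m] += p.s1;
          } else if (s0 == 4 && s1n == 3) {
            sOf[m] -= p.s1;
          } else if (s0 == 4 && s1n == 5) {
            sOf[m] += p.s2;
          } else if (s0 == 5 && s1n == 4) {
            sOf[m] -= p.s2;
          }
          st[m] = s1n;
        }
      }
    }

    // --- per-step record ---------------------------------------------------
    for (int m = 0; m < M; ++m) {
      if (st[m] >= 3) {
        deltaA(k - 1, m) = 1;
        xAmat(k - 1, m) = xA[m];
        sMat(k - 1, m) = sOf[m];
        kAmat(k - 1, m) = kAify[m];
        lamAcarry(k - 1, m) = (kAify[m] == 0) ? lamA[m] : 0.0;
        xTilde(k - 1, m) = xA[m] + sOf[m] + p.L * (lam_k - lamA[m]);
        b_k.push_back(k);
        b_xA.push_back(xA[m]);
        b_s.push_back(sOf[m]);
        b_kA.push_back(kAify[m]);
        b_lamA.push_back((kAify[m] == 0) ? lamA[m] : 0.0);
        b_xT.push_back(xTilde(k - 1, m));
      }
    }
  }

  return List::create(
    _["state"] = IntegerVector(st.begin(), st.end()),
    _["x_A"] = NumericVector(xA.begin(), xA.end()),
    _["s"] = NumericVector(sOf.begin(), sOf.end()),
    _["lambda_A"] = NumericVector(lamA.begin(), lamA.end()),
    _["tt"] = IntegerVector(tt.begin(), tt.end()),
    _["delta_A"] = deltaA,
    _["x_A_rec"] = xAmat,
    _["s_rec"] = sMat,
    _["k_A"] = kAmat,
    _["lambda_A_carry"] = lamAcarry,
    _["x_tilde"] = xTilde,
    _["ev_k"] = IntegerVector(ev_k.begin(), ev_k.end()),
    _["ev_mol"] = IntegerVector(ev_mol.begin(), ev_mol.end()),
    _["ev_from"] = IntegerVector(ev_from.begin(), ev_from.end()),
    _["ev_to"] = IntegerVector(ev_to.begin(), ev_to.end()),
    _["b_k"] = IntegerVector(b_k.begin(), b_k.end()),
    _["b_kA"] = IntegerVector(b_kA.begin(), b_kA.end()),
    _["b_xA"] = NumericVector(b_xA.begin(), b_xA.end()),
    _["b_s"] = NumericVector(b_s.begin(), b_s.end()),
    _["b_lamA"] = NumericVector(b_lamA.begin(), b_lamA.end()),
    _["b_xT"] = NumericVector(b_xT.begin(), b_xT.end()));
}

// Implicit (MusAsi) active tension and stiffness from a frozen interval
// record (compressed to its bound molecule-steps), re-evaluated at a trial
// end-of-step stretch.  Strains are clamped at the domain edge during
// trials (zero curvature beyond) to keep the residual continuous.
// [[Rcpp::export]]
List musasi_tension_cpp(IntegerVector b_k, IntegerVector b_kA,
                        NumericVector b_xA, NumericVector b_s,
                        NumericVector b_lamA, int n,
                        double lambda_T, double lambda_TdT,
                        List par, bool include_RS_in_stiffness) {
  const Par p = read_par(par);
  const double dlam = lambda_TdT - lambda_T;
  const int nb = b_k.size();
  double Tsum = 0.0, Ksum = 0.0;
  for (int e = 0; e < nb; ++e) {
    const double fk = (double)b_k[e] / n;
    const int kA = b_kA[e];
    const double fA = (kA > 0) ? (double)kA / n : 0.0;
    const double lamA = (kA > 0) ? lambda_T + fA * dlam : b_lamA[e];
    const double lam_k = lambda_T + fk * dlam;
    double x = b_xA[e] + b_s[e] + p.L * (lam_k - lamA);
    double dW, ddW;
    if (x > p.xmax) { dW = p.kpos * p.xmax; ddW = 0.0; }
    else if (x < -p.xmax) { dW = -p.kneg * p.xmax; ddW = 0.0; }
    else {
      const double kk = (x >= 0.0) ? p.kpos : p.kneg;
      dW = kk * x; ddW = kk;
    }
    Tsum += dW;
    Ksum += ddW * p.L * (fk - fA);
  }
  const double prefT = 2.0 * p.RS / (p.SA0 * p.NF * n);
  const double prefK = include_RS_in_stiffness
                         ? prefT : 2.0 / (p.SA0 * p.NF * n);
  return List::create(_["T_act"] = prefT * Tsum,
                      _["dT_dlambda"] = prefK * Ksum);
}

// Explicit active tension: Eq.-7 strains frozen at their Monte Carlo values,
// independent of the trial stretch; the associated stiffness is zero.
// [[Rcpp::export]]
double explicit_tension_cpp(NumericVector b_xT, int n, List par) {
  const Par p = read_par(par);
  double Tsum = 0.0;
  for (int e = 0; e < b_xT.size(); ++e) {
    double x = b_xT[e];
    if (x > p.xmax) x = p.xmax;
    else if (x < -p.xmax) x = -p.xmax;
    Tsum += ((x >= 0.0) ? p.kpos : p.kneg) * x;
  }
  return 2.0 * p.RS / (p.SA0 * p.NF * n) * Tsum;
}
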