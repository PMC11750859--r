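// Implicit compartmental cable integrator for a chain morphology.
//
// Scheme: backward Euler on the voltage equation with ionic conductances
// frozen at the post-update gate values (linearized ohmic currents), solved
// by the Thomas algorithm on the tridiagonal system the chain topology
// guarantees; gating variables advance first by the exact exponential
// relaxation x <- x_inf + (x - x_inf) exp(-dt/tau) evaluated at the
// pre-step voltage (staggered update).
//
// Units: mV, ms, nA, nF, uS. nA/nF = mV/ms and uS*mV = nA, so no
// conversion factors appear in the update.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Closed-form voltage-rate families. Family codes:
//   1 exponential : A * exp((V - V0)/B)
//   2 sigmoid     : A / (1 + exp((V - V0)/B))
//   3 linoid      : A * (V - V0) / (1 - exp(-(V - V0)/B)),
//                   with the removable singularity A*B at V = V0.
static inline double rate_family(int fam, double A, double V0, double B,
                                 double v) {
  switch (fam) {
  case 1:
    return A * std::exp((v - V0) / B);
  case 2:
    return A / (1.0 + std::exp((v - V0) / B));
  case 3: {
    double u = (v - V0) / B;
    if (std::fabs(u) < 1e-7) return A * B * (1.0 + u / 2.0);
    return A * (v - V0) / (1.0 - std::exp(-u));
  }
  default:
    stop("unknown rate family code %d", fam);
  }
  return NA_REAL; // not reached
}

struct GateDef {
  int exponent;
  int mode;              // 0 = alpha/beta closed form, 1 = tabulated xinf/tau
  int afam, bfam;
  double apar[3], bpar[3];
  double vmin, dv;       // tabulated grid
  std::vector<double> xinf_tab, tau_tab;

  inline void eval(double v, double &xinf, double &tau) const {
    if (mode == 0) {
      double a = rate_family(afam, apar[0], apar[1], apar[2], v);
      double b = rate_family(bfam, bpar[0], bpar[1], bpar[2], v);
      double s = a + b;
      xinf = a / s;
      tau = 1.0 / s;
    } else {
      double u = (v - vmin) / dv;
      int n = (int)xinf_tab.size();
      if (u <= 0.0) {
        xinf = xinf_tab[0]; tau = tau_tab[0];
      } else if (u >= n - 1) {
        xinf = xinf_tab[n - 1]; tau = tau_tab[n - 1];
      } else {
        int i = (int)u;
        double f = u - i;
        xinf = xinf_tab[i] * (1.0 - f) + xinf_tab[i + 1] * f;
        tau = tau_tab[i] * (1.0 - f) + tau_tab[i + 1] * f;
      }
    }
  }
};

struct ChannelDef {
  std::vector<double> g;          // max conductance per segment, uS
  double e;                       // reversal, mV
  std::vector<GateDef> gates;
  std::vector<std::vector<double> > x; // gate state [gate][segment]
};

static GateDef parse_gate(const List &gl) {
  GateDef gd;
  gd.exponent = as<int>(gl["exponent"]);
  gd.mode = as<int>(gl["mode"]);
  if (gd.mode == 0) {
    NumericVector ap = gl["apar"], bp = gl["bpar"];
    gd.afam = as<int>(gl["afam"]);
    gd.bfam = as<int>(gl["bfam"]);
    for (int k = 0; k < 3; ++k) { gd.apar[k] = ap[k]; gd.bpar[k] = bp[k]; }
  } else {
    gd.vmin = as<double>(gl["vmin"]);
    gd.dv = as<double>(gl["dv"]);
    NumericVector xi = gl["xinf"], ta = gl["tau"];
    gd.xinf_tab.assign(xi.begin(), xi.end());
    gd.tau_tab.assign(ta.begin(), ta.end());
  }
  return gd;
}

// [[Rcpp::export]]
List simulate_cpp(NumericVector cap, NumericVector gax, NumericVector gleak,
                  NumericVector eleak, List channels, NumericVector v0,
                  List gate_state, double dt, NumericVector inj, int inj_seg,
                  IntegerVector record_idx, int clamp_idx, double clamp_v) {
  const int n = cap.size();
  if (gax.size() != n - 1) stop("axial coupling vector must have length n-1");
  const int nsteps = inj.size();
  const int nch = channels.size();

  std::vector<ChannelDef> ch(nch);
  for (int c = 0; c < nch; ++c) {
    List cl = channels[c];
    NumericVector g = cl["g"];
    ch[c].g.assign(g.begin(), g.end());
    ch[c].e = as<double>(cl["e"]);
    List gl = cl["gates"];
    for (int k = 0; k < gl.size(); ++k)
      ch[c].gates.push_back(parse_gate(gl[k]));
    List st = gate_state[c];
    for (int k = 0; k < st.size(); ++k) {
      NumericVector xv = st[k];
      if (xv.size() != n) stop("gate state length mismatch");
      ch[c].x.push_back(std::vector<double>(xv.begin(), xv.end()));
    }
    if (ch[c].x.size() != ch[c].gates.size())
      stop("gate state / gate definition mismatch");
  }

  std::vector<double> v(v0.begin(), v0.end());
  const int nrec = record_idx.size();
  NumericMatrix traces(nsteps + 1, nrec);
  for (int j = 0; j < nrec; ++j) traces(0, j) = v[record_idx[j]];

  // Thomas algorithm work arrays
  std::vector<double> diag(n), rhs(n), cprime(n), dprime(n);

  for (int s = 0; s < nsteps; ++s) {
    // 1) gate update at the pre-step voltage (exact exponential relaxation)
    for (int c = 0; c < nch; ++c) {
      ChannelDef &cd = ch[c];
      for (size_t k = 0; k < cd.gates.size(); ++k) {
        const GateDef &gd = cd.gates[k];
        std::vector<double> &x = cd.x[k];
        for (int i = 0; i < n; ++i) {
          double xinf, tau;
          gd.eval(v[i], xinf, tau);
          x[i] = xinf + (x[i] - xinf) * std::exp(-dt / tau);
        }
      }
    }

    // 2) assemble the implicit voltage system
    for (int i = 0; i < n; ++i) {
      diag[i] = cap[i] / dt + gleak[i];
      rhs[i] = cap[i] / dt * v[i] + gleak[i] * eleak[i];
    }
    for (int c = 0; c < nch; ++c) {
      ChannelDef &cd = ch[c];
      for (int i = 0; i < n; ++i) {
        double open = 1.0;
        for (size_t k = 0; k < cd.gates.size(); ++k) {
          double xv = cd.x[k][i];
          int e = cd.gates[k].exponent;
          for (int p = 0; p < e; ++p) open *= xv;
        }
        double g = cd.g[i] * open;
        diag[i] += g;
        rhs[i] += g * cd.e;
      }
    }
    for (int i = 0; i < n - 1; ++i) {
      diag[i] += gax[i];
      diag[i + 1] += gax[i];
    }
    if (inj_seg >= 0) rhs[inj_seg] += inj[s];

    // off-diagonals are -gax; clamped segment becomes an identity row
    bool clamped = clamp_idx >= 0;

    // 3) Thomas solve of the tridiagonal system
    {
      double b0 = diag[0], d0 = rhs[0], c0 = (n > 1 ? -gax[0] : 0.0);
      if (clamped && clamp_idx == 0) { b0 = 1.0; d0 = clamp_v; c0 = 0.0; }
      cprime[0] = c0 / b0;
      dprime[0] = d0 / b0;
      for (int i = 1; i < n; ++i) {
        double ai = -gax[i - 1], bi = diag[i], di = rhs[i];
        double ci = (i < n - 1 ? -gax[i] : 0.0);
        if (clamped && clamp_idx == i) { ai = 0.0; bi = 1.0; ci = 0.0; di = clamp_v; }
        double m = bi - ai * cprime[i - 1];
        if (m == 0.0) stop("singular tridiagonal system at t = %.4f ms, segment %d",
                           (s + 1) * dt, i + 1);
        cprime[i] = ci / m;
        dprime[i] = (di - ai * dprime[i - 1]) / m;
      }
      v[n - 1] = dprime[n - 1];
      for (int i = n - 2; i >= 0; --i) v[i] = dprime[i] - cprime[i] * v[i + 1];
    }

    for (int i = 0; i < n; ++i) {
      if (!std::isfinite(v[i]) || std::fabs(v[i]) > 1000.0)
        stop("cable solver diverged at t = %.4f ms, segment %d (V = %g mV)",
             (s + 1) * dt, i + 1, v[i]);
    }

    for (int j = 0; j < nrec; ++j) traces(s + 1, j) = v[record_idx[j]];
  }

  NumericVector vout(v.begin(), v.end());
  List state_out(nch);
  for (int c = 0; c < nch; ++c) {
    List xs(ch[c].x.size());
    for (size_t k = 0; k < ch[c].x.size(); ++k)
      xs[k] = NumericVector(ch[c].x[k].begin(), ch[c].x[k].end());
    state_out[c] = xs;
  }
  return List::create(_["v"] = vout, _["gates"] = state_out,
                      _["traces"] = traces);
}

// [[Rcpp::export]]
double rate_family_cpp(int fam, double A, double V0, double B, double v) {
  return rate_family(fam, A, V0, B, v);
}
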