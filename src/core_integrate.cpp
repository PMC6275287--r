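// Fixed-step integration core. The R side flattens a model tree into plain
// arrays (see .compile_model); this file advances the coupled
// voltage/gating/calcium/synapse system with one of three solvers:
//   0 exponential Euler (default; supports clamp, synapses, mechanisms)
//   1 classical RK4 (single compartment, no synapses)
//   2 Crank-Nicolson cable (unbranched chain, tridiagonal implicit voltage)
//
// Gating curves arrive as lookup tables on a uniform voltage grid; linear
// interpolation keeps the loop free of R callbacks. Units: mV, ms, uM,
// uS/mm^2 (densities), mm^2, nA; synaptic/gap conductances in uS after the
// nS -> uS conversion done in R.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double FARADAY = 96485.33212;
static const double GAS_R = 8.314462618;

static inline double nernst_ca(double ca_out, double T, double ca_in) {
  double ca = ca_in > 1e-9 ? ca_in : 1e-9;
  return 1000.0 * GAS_R * (T + 273.15) / (2.0 * FARADAY) *
         std::log(ca_out / ca);
}

static inline double ipow(double x, int n) {
  double r = 1.0;
  for (int i = 0; i < n; ++i) r *= x;
  return r;
}

struct Tables {
  const double* data;  // (ntype*4) x nv, row-major by R matrix (col-major!)
  int nrow, nv;
  double vmin, dv;
  // R matrices are column-major: element (row r, col c) = data[c*nrow + r]
  inline double at(int row, double V) const {
    double u = (V - vmin) / dv;
    if (u <= 0.0) return data[row];
    if (u >= nv - 1) return data[(size_t)(nv - 1) * nrow + row];
    int i = (int)u;
    double f = u - i;
    double a = data[(size_t)i * nrow + row];
    double b = data[(size_t)(i + 1) * nrow + row];
    return a + f * (b - a);
  }
};

// [[Rcpp::export]]
List cpp_integrate(List M, List S) {
  // ---- unpack model -------------------------------------------------------
  const int nc = as<int>(M["ncomp"]);
  NumericVector A = M["A"], Cm = M["Cm"];
  std::vector<double> V = as<std::vector<double> >(M["V0"]);
  std::vector<double> Ca = as<std::vector<double> >(M["Ca0"]);

  IntegerVector ch_comp = M["ch_comp"], ch_p = M["ch_p"], ch_q = M["ch_q"],
                ch_isca = M["ch_isca"], ch_cadep = M["ch_cadep"],
                ch_tab = M["ch_tab"];
  NumericVector ch_cahalf = M["ch_cahalf"];
  std::vector<double> gbar = as<std::vector<double> >(M["ch_gbar"]);
  std::vector<double> Erev = as<std::vector<double> >(M["ch_E"]);
  std::vector<double> m = as<std::vector<double> >(M["ch_m"]);
  std::vector<double> h = as<std::vector<double> >(M["ch_h"]);
  const int nch = ch_comp.size();

  NumericMatrix tabmat = M["tab"];
  Tables tab;
  tab.data = tabmat.begin();
  tab.nrow = tabmat.nrow();
  tab.nv = as<int>(M["nv"]);
  tab.vmin = as<double>(M["vmin"]);
  tab.dv = as<double>(M["dv"]);

  IntegerVector sy_pre = M["sy_pre"], sy_post = M["sy_post"];
  NumericVector sy_g = M["sy_g"], sy_E = M["sy_E"], sy_vh = M["sy_vh"],
                sy_dl = M["sy_dl"], sy_km = M["sy_km"];
  std::vector<double> s = as<std::vector<double> >(M["sy_s"]);
  const int ns = sy_pre.size();

  IntegerVector el_a = M["el_a"], el_b = M["el_b"];
  NumericVector el_g = M["el_g"];  // uS
  const int ne = el_a.size();

  IntegerVector cam_flag = M["cam_flag"];
  NumericVector cam_tau = M["cam_tau"], cam_f = M["cam_f"],
                cam_ca0 = M["cam_ca0"], cam_caout = M["cam_caout"],
                cam_T = M["cam_T"];

  IntegerVector ct_chan = M["ct_chan"], ct_comp = M["ct_comp"];
  NumericVector ct_taum = M["ct_taum"], ct_taug = M["ct_taug"],
                ct_target = M["ct_target"];
  std::vector<double> mrna = as<std::vector<double> >(M["ct_mrna"]);
  const int nctl = ct_chan.size();

  NumericVector gax = M["gax"];  // uS, length nc-1 (cable only)

  // ---- unpack simulation --------------------------------------------------
  const double dt = as<double>(S["dt"]);
  const int nsteps = as<int>(S["nsteps"]);
  const int out_every = as<int>(S["out_every"]);
  const int solver = as<int>(S["solver"]);
  NumericVector iext_scalar = S["iext_scalar"];
  const bool use_iext_mat = as<bool>(S["use_iext_mat"]);
  NumericMatrix iext_mat = S["iext_mat"];
  IntegerVector clamp_flag = S["clamp_flag"];
  NumericVector clamp_scalar = S["clamp_scalar"];
  const bool use_clamp_mat = as<bool>(S["use_clamp_mat"]);
  NumericMatrix clamp_mat = S["clamp_mat"];
  const bool rec_curr = as<bool>(S["record_currents"]);
  const bool rec_syn = as<bool>(S["record_synapses"]);
  const bool rec_ctl = as<bool>(S["record_controllers"]);
  bool any_clamp = false;
  for (int c = 0; c < nc; ++c) if (clamp_flag[c]) any_clamp = true;

  const int nout = nsteps / out_every;
  NumericVector out_t(nout);
  NumericMatrix out_V(nout, nc), out_Ca(nout, nc);
  NumericMatrix out_Ic(any_clamp ? nout : 0, any_clamp ? nc : 0);
  NumericMatrix out_curr(rec_curr ? nout : 0, rec_curr ? nch : 0);
  NumericMatrix out_s(rec_syn ? nout : 0, rec_syn ? ns : 0);
  NumericMatrix out_cm(rec_ctl ? nout : 0, rec_ctl ? nctl : 0);
  NumericMatrix out_cg(rec_ctl ? nout : 0, rec_ctl ? nctl : 0);

  std::vector<double> Vold(nc), Gsum(nc), GEsum(nc), ica(nc), Ic(nc);
  std::vector<double> minf_j(nch), geff(nch);

  // pin clamped compartments before the first step
  for (int c = 0; c < nc; ++c)
    if (clamp_flag[c])
      V[c] = use_clamp_mat ? clamp_mat(0, c) : clamp_scalar[c];

  // RK4 scratch
  std::vector<double> y, k1, k2, k3, k4, ytmp;

  auto rk4_deriv = [&](const std::vector<double>& yy, double iext,
                       std::vector<double>& dy) {
    // y layout: [V, Ca, m(0..nch-1), h(0..nch-1)]
    double Vv = yy[0], Cav = yy[1];
    double sumG = 0.0, sumGE = 0.0, icat = 0.0;
    bool cam = cam_flag[0] != 0;
    double eca = cam ? nernst_ca(cam_caout[0], cam_T[0], Cav) : 0.0;
    for (int j = 0; j < nch; ++j) {
      int row = 4 * ch_tab[j];
      double mj = 1.0, hj = 1.0;
      if (ch_p[j] > 0) {
        double mi = tab.at(row + 0, Vv);
        if (ch_cadep[j]) mi *= Cav / (Cav + ch_cahalf[j]);
        double tm = tab.at(row + 1, Vv);
        dy[2 + j] = (mi - yy[2 + j]) / tm;
        mj = yy[2 + j];
      } else dy[2 + j] = 0.0;
      if (ch_q[j] > 0) {
        double hi = tab.at(row + 2, Vv);
        double th = tab.at(row + 3, Vv);
        dy[2 + nch + j] = (hi - yy[2 + nch + j]) / th;
        hj = yy[2 + nch + j];
      } else dy[2 + nch + j] = 0.0;
      double g = gbar[j] * ipow(mj, ch_p[j]) * ipow(hj, ch_q[j]);
      double Ej = (ch_isca[j] && cam) ? eca : Erev[j];
      sumG += g;
      sumGE += g * Ej;
      if (ch_isca[j]) icat += g * (Vv - Ej) * A[0];
    }
    dy[0] = (sumGE - sumG * Vv + iext / A[0]) / Cm[0];
    dy[1] = cam ? (-cam_f[0] * icat - Cav + cam_ca0[0]) / cam_tau[0] : 0.0;
  };

  if (solver == 1) {
    int nY = 2 + 2 * nch;
    y.assign(nY, 0.0);
    k1.assign(nY, 0.0); k2.assign(nY, 0.0);
    k3.assign(nY, 0.0); k4.assign(nY, 0.0);
    ytmp.assign(nY, 0.0);
    y[0] = V[0]; y[1] = Ca[0];
    for (int j = 0; j < nch; ++j) { y[2 + j] = m[j]; y[2 + nch + j] = h[j]; }
  }

  // Crank-Nicolson scratch
  std::vector<double> cn_a(nc), cn_b(nc), cn_c(nc), cn_d(nc), cn_cp(nc),
      cn_dp(nc);

  int out_row = 0;
  for (int step = 1; step <= nsteps; ++step) {
    int si = step - 1;  // row into input series
    if (solver == 1) {
      double iext = use_iext_mat ? iext_mat(si, 0) : iext_scalar[0];
      rk4_deriv(y, iext, k1);
      for (int i = 0; i < (int)y.size(); ++i) ytmp[i] = y[i] + 0.5 * dt * k1[i];
      rk4_deriv(ytmp, iext, k2);
      for (int i = 0; i < (int)y.size(); ++i) ytmp[i] = y[i] + 0.5 * dt * k2[i];
      rk4_deriv(ytmp, iext, k3);
      for (int i = 0; i < (int)y.size(); ++i) ytmp[i] = y[i] + dt * k3[i];
      rk4_deriv(ytmp, iext, k4);
      for (int i = 0; i < (int)y.size(); ++i)
        y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
      if (y[1] < 0.0) y[1] = 0.0;
      for (int j = 0; j < nch; ++j) {
        if (y[2 + j] < 0.0) y[2 + j] = 0.0;
        if (y[2 + j] > 1.0) y[2 + j] = 1.0;
        if (y[2 + nch + j] < 0.0) y[2 + nch + j] = 0.0;
        if (y[2 + nch + j] > 1.0) y[2 + nch + j] = 1.0;
      }
      V[0] = y[0]; Ca[0] = y[1];
      for (int j = 0; j < nch; ++j) { m[j] = y[2 + j]; h[j] = y[2 + nch + j]; }
      if (!std::isfinite(V[0]))
        stop("integration failure: non-finite voltage at step %d", step);
    } else {
      for (int c = 0; c < nc; ++c) Vold[c] = V[c];

      // calcium current at pre-update state (for the calcium mechanism)
      for (int c = 0; c < nc; ++c) ica[c] = 0.0;
      for (int j = 0; j < nch; ++j)
        if (ch_isca[j]) {
          int c = ch_comp[j];
          double g = gbar[j] * ipow(m[j], ch_p[j]) * ipow(h[j], ch_q[j]);
          ica[c] += g * (Vold[c] - Erev[j]) * A[c];
        }

      // graded synapse activations from presynaptic voltage
      for (int k = 0; k < ns; ++k) {
        double sinf =
            1.0 / (1.0 + std::exp((sy_vh[k] - Vold[sy_pre[k]]) / sy_dl[k]));
        double taus = (1.0 - sinf) / sy_km[k];
        if (taus < dt) taus = dt;
        s[k] = sinf + (s[k] - sinf) * std::exp(-dt / taus);
      }

      // gating variables (exponential Euler; exact for frozen V)
      for (int j = 0; j < nch; ++j) {
        int c = ch_comp[j], row = 4 * ch_tab[j];
        if (ch_p[j] > 0) {
          double mi = tab.at(row + 0, Vold[c]);
          if (ch_cadep[j]) mi *= Ca[c] / (Ca[c] + ch_cahalf[j]);
          double tm = tab.at(row + 1, Vold[c]);
          m[j] = mi + (m[j] - mi) * std::exp(-dt / tm);
        }
        if (ch_q[j] > 0) {
          double hi = tab.at(row + 2, Vold[c]);
          double th = tab.at(row + 3, Vold[c]);
          h[j] = hi + (h[j] - hi) * std::exp(-dt / th);
        }
      }

      // conductance/reversal sums (densities)
      for (int c = 0; c < nc; ++c) {
        double iext = use_iext_mat ? iext_mat(si, c) : iext_scalar[c];
        Gsum[c] = 0.0;
        GEsum[c] = iext / A[c];
      }
      for (int j = 0; j < nch; ++j) {
        int c = ch_comp[j];
        double g = gbar[j] * ipow(m[j], ch_p[j]) * ipow(h[j], ch_q[j]);
        geff[j] = g;
        Gsum[c] += g;
        GEsum[c] += g * Erev[j];
      }
      for (int k = 0; k < ns; ++k) {
        int c = sy_post[k];
        double gs = sy_g[k] * s[k] / A[c];  // uS -> uS/mm^2
        Gsum[c] += gs;
        GEsum[c] += gs * sy_E[k];
      }
      for (int k = 0; k < ne; ++k) {
        int a = el_a[k], b = el_b[k];
        double ga = el_g[k] / A[a], gb = el_g[k] / A[b];
        Gsum[a] += ga; GEsum[a] += ga * Vold[b];
        Gsum[b] += gb; GEsum[b] += gb * Vold[a];
      }

      if (solver == 2) {
        // Crank-Nicolson on the tridiagonal voltage system;
        // M diag = -(G_c + axial/A)/Cm, off-diagonals from g_ax.
        for (int c = 0; c < nc; ++c) {
          double gl = (c > 0) ? gax[c - 1] / A[c] : 0.0;
          double gr = (c < nc - 1) ? gax[c] / A[c] : 0.0;
          double diag = -(Gsum[c] + gl + gr) / Cm[c];
          double offl = gl / Cm[c], offr = gr / Cm[c];
          cn_a[c] = -0.5 * dt * offl;           // sub-diagonal of (I - dt/2 M)
          cn_b[c] = 1.0 - 0.5 * dt * diag;      // diagonal
          cn_c[c] = -0.5 * dt * offr;           // super-diagonal
          // rhs = (I + dt/2 M) Vold + dt * b
          double rhs = (1.0 + 0.5 * dt * diag) * Vold[c] + dt * GEsum[c] / Cm[c];
          if (c > 0) rhs += 0.5 * dt * offl * Vold[c - 1];
          if (c < nc - 1) rhs += 0.5 * dt * offr * Vold[c + 1];
          cn_d[c] = rhs;
        }
        // Thomas algorithm
        cn_cp[0] = cn_c[0] / cn_b[0];
        cn_dp[0] = cn_d[0] / cn_b[0];
        for (int c = 1; c < nc; ++c) {
          double denom = cn_b[c] - cn_a[c] * cn_cp[c - 1];
          cn_cp[c] = cn_c[c] / denom;
          cn_dp[c] = (cn_d[c] - cn_a[c] * cn_dp[c - 1]) / denom;
        }
        V[nc - 1] = cn_dp[nc - 1];
        for (int c = nc - 2; c >= 0; --c)
          V[c] = cn_dp[c] - cn_cp[c] * V[c + 1];
      } else {
        // exponential Euler toward V_inf with time constant Cm/Gsum
        for (int c = 0; c < nc; ++c) {
          if (clamp_flag[c]) {
            V[c] = use_clamp_mat ? clamp_mat(si, c) : clamp_scalar[c];
            continue;
          }
          if (Gsum[c] > 1e-12) {
            double vinf = GEsum[c] / Gsum[c];
            V[c] = vinf + (Vold[c] - vinf) * std::exp(-dt * Gsum[c] / Cm[c]);
          } else {
            V[c] = Vold[c] + dt * GEsum[c] / Cm[c];
          }
        }
      }

      // clamp current = total membrane current at the clamped voltage
      if (any_clamp)
        for (int c = 0; c < nc; ++c) Ic[c] = NA_REAL;
      if (any_clamp) {
        for (int c = 0; c < nc; ++c) if (clamp_flag[c]) Ic[c] = 0.0;
        for (int j = 0; j < nch; ++j) {
          int c = ch_comp[j];
          if (clamp_flag[c]) Ic[c] += geff[j] * (V[c] - Erev[j]) * A[c];
        }
        for (int k = 0; k < ns; ++k) {
          int c = sy_post[k];
          if (clamp_flag[c]) Ic[c] += sy_g[k] * s[k] * (V[c] - sy_E[k]);
        }
        for (int k = 0; k < ne; ++k) {
          int a = el_a[k], b = el_b[k];
          if (clamp_flag[a]) Ic[a] += el_g[k] * (V[a] - Vold[b]);
          if (clamp_flag[b]) Ic[b] += el_g[k] * (V[b] - Vold[a]);
        }
      }

      // mechanisms: calcium buffering + Nernst reversal, then controllers
      for (int c = 0; c < nc; ++c) {
        if (!cam_flag[c]) continue;
        double cainf = cam_ca0[c] - cam_f[c] * ica[c];
        double ca = cainf + (Ca[c] - cainf) * std::exp(-dt / cam_tau[c]);
        Ca[c] = ca > 0.0 ? ca : 0.0;
        double eca = nernst_ca(cam_caout[c], cam_T[c], Ca[c]);
        for (int j = 0; j < nch; ++j)
          if (ch_isca[j] && ch_comp[j] == c) Erev[j] = eca;
      }
      for (int k = 0; k < nctl; ++k) {
        int j = ct_chan[k], c = ct_comp[k];
        double mr = mrna[k];
        mrna[k] = mr + dt * (ct_target[k] - Ca[c]) / ct_taum[k];
        double g = gbar[j] + dt * (mr - gbar[j]) / ct_taug[k];
        gbar[j] = g > 0.0 ? g : 0.0;
      }

      for (int c = 0; c < nc; ++c)
        if (!std::isfinite(V[c]))
          stop("integration failure: non-finite voltage in compartment %d at step %d",
               c + 1, step);
    }

    if (step % out_every == 0) {
      out_t[out_row] = step * dt;
      for (int c = 0; c < nc; ++c) {
        out_V(out_row, c) = V[c];
        out_Ca(out_row, c) = Ca[c];
        if (any_clamp) out_Ic(out_row, c) = clamp_flag[c] ? Ic[c] : NA_REAL;
      }
      if (rec_curr)
        for (int j = 0; j < nch; ++j) {
          int c = ch_comp[j];
          double g = gbar[j] * ipow(m[j], ch_p[j]) * ipow(h[j], ch_q[j]);
          out_curr(out_row, j) = g * (V[c] - Erev[j]) * A[c];
        }
      if (rec_syn)
        for (int k = 0; k < ns; ++k) out_s(out_row, k) = s[k];
      if (rec_ctl)
        for (int k = 0; k < nctl; ++k) {
          out_cm(out_row, k) = mrna[k];
          out_cg(out_row, k) = gbar[ct_chan[k]];
        }
      ++out_row;
    }
  }

  return List::create(
      _["t"] = out_t, _["V"] = out_V, _["Ca"] = out_Ca,
      _["I_clamp"] = out_Ic, _["currents"] = out_curr, _["syn_s"] = out_s,
      _["ctl_mrna"] = out_cm, _["ctl_g"] = out_cg,
      _["final_V"] = NumericVector(V.begin(), V.end()),
      _["final_Ca"] = NumericVector(Ca.begin(), Ca.end()),
      _["final_m"] = NumericVector(m.begin(), m.end()),
      _["final_h"] = NumericVector(h.begin(), h.end()),
      _["final_s"] = NumericVector(s.begin(), s.end()),
      _["final_mrna"] = NumericVector(mrna.begin(), mrna.end()),
      _["final_E"] = NumericVector(Erev.begin(), Erev.end()),
      _["final_gbar"] = NumericVector(gbar.begin(), gbar.end()));
}
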