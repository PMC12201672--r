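// Core fixed-step network integrator.
//
// State per neuron: V (mV), h, n, z (gating), three postsynaptic drive
// traces gE, gfI, gsI (dimensionless amplitudes multiplying the driving
// force).  V/h/n/z advance by classical RK4; the traces decay analytically
// within a step (exp(-s/tau)) and jump when a presynaptic spike is
// delivered, which happens at the end of the step in which the spike was
// detected (zero synaptic delay beyond the step boundary).
//
// Units package-wide: ms, mV, uA/cm^2, mS/cm^2, uF/cm^2.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double m_inf(double v) { return 1.0 / (1.0 + std::exp(-(v + 30.0) / 9.5)); }
static inline double h_inf(double v) { return 1.0 / (1.0 + std::exp((v + 53.0) / 7.0)); }
static inline double n_inf(double v) { return 1.0 / (1.0 + std::exp(-(v + 30.0) / 10.0)); }
static inline double z_inf(double v) { return 1.0 / (1.0 + std::exp(-(v + 39.0) / 5.0)); }
static inline double tau_h(double v) { return 0.37 + 2.78 / (1.0 + std::exp((v + 40.5) / 6.0)); }
static inline double tau_n(double v) { return 0.37 + 1.85 / (1.0 + std::exp((v + 27.0) / 15.0)); }

// Gating curves are smooth sigmoids, so the integrator evaluates them
// from a fine lookup table with linear interpolation (step 0.02 mV over
// [-200, 200] mV; interpolation error < 1e-6, far below the integration
// tolerance).  The inverse time constants are tabulated so the hot loop
// multiplies instead of divides.
namespace gate_tab {
constexpr double V_LO = -200.0, V_HI = 200.0, STEP = 0.02;
constexpr int N = (int)((V_HI - V_LO) / STEP) + 1;
struct Row { double m, h, n, z, rth, rtn; };
static std::vector<Row> tab;
static void init() {
  if (!tab.empty()) return;
  tab.resize(N);
  for (int i = 0; i < N; ++i) {
    const double v = V_LO + i * STEP;
    tab[i] = {m_inf(v), h_inf(v), n_inf(v), z_inf(v),
              1.0 / tau_h(v), 1.0 / tau_n(v)};
  }
}
static inline Row at(double v) {
  if (v < V_LO || v > V_HI)   // cold path: strongly suppressed cells can
    return {m_inf(v), h_inf(v), n_inf(v), z_inf(v),   // sit far below V_LO
            1.0 / tau_h(v), 1.0 / tau_n(v)};
  double x = (v - V_LO) / STEP;
  if (x > N - 1.001) x = N - 1.001;
  const int i = (int)x;
  const double f = x - i;
  const Row &a = tab[i], &b = tab[i + 1];
  return {a.m + f * (b.m - a.m), a.h + f * (b.h - a.h),
          a.n + f * (b.n - a.n), a.z + f * (b.z - a.z),
          a.rth + f * (b.rth - a.rth), a.rtn + f * (b.rtn - a.rtn)};
}
}  // namespace gate_tab

struct CellPar {
  double C, gNa, gKdr, gL, VNa, VK, VL, tau_z;
};

// Membrane + gating derivatives.  gks varies per epoch, Iext bundles
// Idrive + stimulation + noise; syn drive traces enter through eE, eI
// (already decayed to the substep).
static inline void deriv(const CellPar &p, double gks,
                         double V, double h, double n, double z,
                         double Iext, double eE, double eI,
                         double erevE, double erevI,
                         double &dV, double &dh, double &dn, double &dz) {
  const gate_tab::Row g = gate_tab::at(V);
  const double isyn = eE * (V - erevE) + eI * (V - erevI);
  dV = (-p.gNa * g.m * g.m * g.m * h * (V - p.VNa)
        - p.gKdr * n * n * n * n * (V - p.VK)
        - p.gL * (V - p.VL)
        - gks * z * (V - p.VK)
        + Iext - isyn) / p.C;
  dh = (g.h - h) * g.rth;
  dn = (g.n - n) * g.rtn;
  dz = (g.z - z) / p.tau_z;
}

// [[Rcpp::export(name = ".sim_network")]]
List sim_network(NumericVector v0, NumericVector h0, NumericVector n0, NumericVector z0,
                 NumericVector idrive,
                 List cell,          // C, gNa, gKdr, gL, VNa, VK, VL, tau_z, v_thresh
                 IntegerVector e_pre, IntegerVector e_post,   // 0-based
                 NumericVector e_amp_fast, NumericVector e_amp_slow,
                 IntegerVector e_exc, NumericVector e_w, NumericVector e_px,
                 NumericVector seg_end,    // ms, strictly increasing, last = T
                 NumericVector seg_gks, IntegerVector seg_plastic,
                 NumericMatrix seg_drive,  // n x n_seg, added drive per neuron per segment
                 List stdp,          // a_plus, a_minus, tau_plus, tau_minus, wmax
                 List syn,           // tau_f, tau_s, erev_e, erev_i
                 double noise_p, double noise_amp, double noise_dur,
                 double dt,
                 NumericVector snap_times,
                 IntegerVector record_idx, int record_stride) {
  gate_tab::init();
  const int n = v0.size();
  const int ne = e_pre.size();
  const int nseg = seg_end.size();

  CellPar p;
  p.C = as<double>(cell["C"]);     p.gNa = as<double>(cell["gNa"]);
  p.gKdr = as<double>(cell["gKdr"]); p.gL = as<double>(cell["gL"]);
  p.VNa = as<double>(cell["VNa"]); p.VK = as<double>(cell["VK"]);
  p.VL = as<double>(cell["VL"]);   p.tau_z = as<double>(cell["tau_z"]);
  const double vth = as<double>(cell["v_thresh"]);

  const double a_plus = as<double>(stdp["a_plus"]);
  const double a_minus = as<double>(stdp["a_minus"]);
  const double tau_plus = as<double>(stdp["tau_plus"]);
  const double tau_minus = as<double>(stdp["tau_minus"]);
  const double wmax = as<double>(stdp["wmax"]);

  const double tau_f = as<double>(syn["tau_f"]);
  const double tau_s = as<double>(syn["tau_s"]);
  const double erevE = as<double>(syn["erev_e"]);
  const double erevI = as<double>(syn["erev_i"]);

  // trace decay factors for half and full step
  const double dEh = std::exp(-0.5 * dt / tau_f), dEf = dEh * dEh;
  const double dSh = std::exp(-0.5 * dt / tau_s), dSf = dSh * dSh;

  const long steps_per_ms = (long)std::llround(1.0 / dt);
  if (std::fabs(steps_per_ms * dt - 1.0) > 1e-9)
    stop("dt must divide 1 ms exactly (got dt = %f)", dt);
  const double T = seg_end[nseg - 1];
  const long n_steps = (long)std::llround(T / dt);
  const long noise_steps = (long)std::llround(noise_dur / dt);

  // CSR by presynaptic neuron (all edges), and plastic-edge CSRs by post/pre
  std::vector<int> out_ptr(n + 1, 0), pin_ptr(n + 1, 0), pout_ptr(n + 1, 0);
  for (int e = 0; e < ne; ++e) {
    out_ptr[e_pre[e] + 1]++;
    if (e_px[e] > 0.0) { pin_ptr[e_post[e] + 1]++; pout_ptr[e_pre[e] + 1]++; }
  }
  for (int i = 0; i < n; ++i) {
    out_ptr[i + 1] += out_ptr[i];
    pin_ptr[i + 1] += pin_ptr[i];
    pout_ptr[i + 1] += pout_ptr[i];
  }
  std::vector<int> out_idx(ne), pin_idx(pin_ptr[n]), pout_idx(pout_ptr[n]);
  {
    std::vector<int> c1(out_ptr.begin(), out_ptr.end() - 1),
                     c2(pin_ptr.begin(), pin_ptr.end() - 1),
                     c3(pout_ptr.begin(), pout_ptr.end() - 1);
    for (int e = 0; e < ne; ++e) {
      out_idx[c1[e_pre[e]]++] = e;
      if (e_px[e] > 0.0) {
        pin_idx[c2[e_post[e]]++] = e;
        pout_idx[c3[e_pre[e]]++] = e;
      }
    }
  }

  std::vector<double> V(v0.begin(), v0.end()), H(h0.begin(), h0.end()),
      N(n0.begin(), n0.end()), Z(z0.begin(), z0.end());
  std::vector<double> gE(n, 0.0), gF(n, 0.0), gS(n, 0.0);
  std::vector<double> w(e_w.begin(), e_w.end());
  std::vector<double> last_spike(n, -1e300);
  std::vector<long> noise_left(n, 0);
  std::vector<char> latch(n, 0);

  std::vector<long> seg_end_step(nseg);
  for (int s = 0; s < nseg; ++s) seg_end_step[s] = (long)std::llround(seg_end[s] / dt);

  std::vector<long> snap_step(snap_times.size());
  for (int s = 0; s < snap_times.size(); ++s)
    snap_step[s] = (long)std::llround(snap_times[s] / dt);
  List snaps(snap_times.size());
  int next_snap = 0;
  // snapshot requested at t = 0 (before any integration)
  while (next_snap < (int)snap_step.size() && snap_step[next_snap] == 0) {
    snaps[next_snap] = NumericVector(w.begin(), w.end());
    next_snap++;
  }

  std::vector<int> sp_id; std::vector<double> sp_t;
  sp_id.reserve(1024); sp_t.reserve(1024);
  std::vector<int> spikers; spikers.reserve(64);

  const int nrec = record_idx.size();
  long rec_rows = 0;
  if (nrec > 0 && record_stride > 0) rec_rows = n_steps / record_stride + 1;
  NumericMatrix vrec(rec_rows > 0 ? rec_rows : 0, nrec);
  NumericVector rec_t(rec_rows > 0 ? rec_rows : 0);
  long rec_row = 0;
  if (rec_rows > 0) {
    rec_t[0] = 0.0;
    for (int k = 0; k < nrec; ++k) vrec(0, k) = V[record_idx[k]];
    rec_row = 1;
  }

  int seg = 0;
  for (long step = 0; step < n_steps; ++step) {
    while (step >= seg_end_step[seg] && seg < nseg - 1) seg++;
    const double gks = seg_gks[seg];
    const bool plast = seg_plastic[seg] != 0;
    const double *dadd = &seg_drive(0, seg);

    // per-millisecond Bernoulli noise pulses
    if (noise_p > 0.0 && step % steps_per_ms == 0) {
      for (int i = 0; i < n; ++i)
        if (unif_rand() < noise_p) noise_left[i] = noise_steps;
    }

    const double t_end = (step + 1) * dt;
    spikers.clear();

    for (int i = 0; i < n; ++i) {
      const double Iext = idrive[i] + dadd[i] + (noise_left[i] > 0 ? noise_amp : 0.0);
      if (noise_left[i] > 0) noise_left[i]--;

      // traces at the start, half and full substep (fast and slow decay
      // with different time constants; keep them separate)
      const double e0 = gE[i], f0 = gF[i] + gS[i];
      const double gEh_ = gE[i] * dEh, gEf_ = gE[i] * dEf;
      const double gFh_ = gF[i] * dEh, gFf_ = gF[i] * dEf;   // fast inhibitory shares tau_f
      const double gSh_ = gS[i] * dSh, gSf_ = gS[i] * dSf;

      double k1V, k1h, k1n, k1z, k2V, k2h, k2n, k2z,
             k3V, k3h, k3n, k3z, k4V, k4h, k4n, k4z;
      const double v = V[i], hh = H[i], nn = N[i], zz = Z[i];
      deriv(p, gks, v, hh, nn, zz, Iext, e0, f0, erevE, erevI, k1V, k1h, k1n, k1z);
      deriv(p, gks, v + 0.5 * dt * k1V, hh + 0.5 * dt * k1h, nn + 0.5 * dt * k1n,
            zz + 0.5 * dt * k1z, Iext, gEh_, gFh_ + gSh_, erevE, erevI,
            k2V, k2h, k2n, k2z);
      deriv(p, gks, v + 0.5 * dt * k2V, hh + 0.5 * dt * k2h, nn + 0.5 * dt * k2n,
            zz + 0.5 * dt * k2z, Iext, gEh_, gFh_ + gSh_, erevE, erevI,
            k3V, k3h, k3n, k3z);
      deriv(p, gks, v + dt * k3V, hh + dt * k3h, nn + dt * k3n,
            zz + dt * k3z, Iext, gEf_, gFf_ + gSf_, erevE, erevI,
            k4V, k4h, k4n, k4z);

      const double Vn = v + dt / 6.0 * (k1V + 2.0 * k2V + 2.0 * k3V + k4V);
      double Hn = hh + dt / 6.0 * (k1h + 2.0 * k2h + 2.0 * k3h + k4h);
      double Nn = nn + dt / 6.0 * (k1n + 2.0 * k2n + 2.0 * k3n + k4n);
      double Zn = zz + dt / 6.0 * (k1z + 2.0 * k2z + 2.0 * k3z + k4z);
      if (Hn < 0.0) Hn = 0.0; else if (Hn > 1.0) Hn = 1.0;
      if (Nn < 0.0) Nn = 0.0; else if (Nn > 1.0) Nn = 1.0;
      if (Zn < 0.0) Zn = 0.0; else if (Zn > 1.0) Zn = 1.0;

      // Divergence guard.  The upper bound sits far above every reversal
      // potential; the lower bound is asymmetric because the leak is weak
      // (0.02 mS/cm2), so a strong suppressive drive legitimately holds
      // cells hundreds of mV below rest (V* = VL + I/gL).
      if (!std::isfinite(Vn) || Vn > 200.0 || Vn < -1000.0)
        stop("integration failure: V diverged for neuron %d at t = %.3f ms",
             i + 1, t_end);

      // upward threshold crossing with latch (HH has no reset)
      if (!latch[i] && v < vth && Vn >= vth) {
        const double tc = step * dt + dt * (vth - v) / (Vn - v);
        sp_id.push_back(i);
        sp_t.push_back(tc);
        spikers.push_back(i);
        latch[i] = 1;
      } else if (latch[i] && Vn < vth) {
        latch[i] = 0;
      }

      V[i] = Vn; H[i] = Hn; N[i] = Nn; Z[i] = Zn;
      gE[i] = gEf_; gF[i] = gFf_; gS[i] = gSf_;
    }

    // STDP first (uses partners' last spike from before this step), then
    // synaptic delivery with the updated weights, then last-spike update.
    if (!spikers.empty()) {
      if (plast) {
        for (size_t s = 0; s < spikers.size(); ++s) {
          const int i = spikers[s];
          for (int k = pin_ptr[i]; k < pin_ptr[i + 1]; ++k) {    // i postsynaptic
            const int e = pin_idx[k];
            const double tp = last_spike[e_pre[e]];
            if (tp > -1e299) {
              const double dtt = t_end - tp;
              if (dtt > 0.0) {
                double wn = w[e] + e_px[e] * a_plus * std::exp(-dtt / tau_plus);
                w[e] = wn > wmax ? wmax : wn;
              }
            }
          }
          for (int k = pout_ptr[i]; k < pout_ptr[i + 1]; ++k) {  // i presynaptic
            const int e = pout_idx[k];
            const double tq = last_spike[e_post[e]];
            if (tq > -1e299) {
              const double dtt = t_end - tq;   // post fired dtt before pre
              if (dtt > 0.0) {
                double wn = w[e] - e_px[e] * a_minus * std::exp(-dtt / tau_minus);
                w[e] = wn < 0.0 ? 0.0 : wn;
              }
            }
          }
        }
      }
      for (size_t s = 0; s < spikers.size(); ++s) {
        const int j = spikers[s];
        for (int k = out_ptr[j]; k < out_ptr[j + 1]; ++k) {
          const int e = out_idx[k];
          const int tgt = e_post[e];
          if (e_exc[e]) {
            gE[tgt] += e_amp_fast[e] * w[e];
          } else {
            gF[tgt] += e_amp_fast[e];
            gS[tgt] += e_amp_slow[e];
          }
        }
      }
      for (size_t s = 0; s < spikers.size(); ++s) last_spike[spikers[s]] = t_end;
    }

    while (next_snap < (int)snap_step.size() && snap_step[next_snap] == step + 1) {
      snaps[next_snap] = NumericVector(w.begin(), w.end());
      next_snap++;
    }
    if (rec_rows > 0 && (step + 1) % record_stride == 0 && rec_row < rec_rows) {
      rec_t[rec_row] = t_end;
      for (int k = 0; k < nrec; ++k) vrec(rec_row, k) = V[record_idx[k]];
      rec_row++;
    }
  }

  List out = List::create(
      _["spike_id"] = IntegerVector(sp_id.begin(), sp_id.end()),
      _["spike_t"] = NumericVector(sp_t.begin(), sp_t.end()),
      _["w_final"] = NumericVector(w.begin(), w.end()),
      _["snapshots"] = snaps,
      _["v_final"] = NumericVector(V.begin(), V.end()),
      _["h_final"] = NumericVector(H.begin(), H.end()),
      _["n_final"] = NumericVector(N.begin(), N.end()),
      _["z_final"] = NumericVector(Z.begin(), Z.end()));
  if (rec_rows > 0) {
    out["v_trace"] = vrec;
    out["v_trace_t"] = rec_t;
  }
  return out;
}
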