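#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include "dyk.h"

using namespace Rcpp;

// Reduced-domain hybrid simulation core.
//
// Gating: exact CTMC over the 64 subunits with driving concentrations
// frozen between refresh points; a refresh happens at every channel
// open/close transition (the macro step is split there), at macro-step
// caps, and at output-cadence marks. Open channels are driven by a fixed
// pore concentration (150 uM by default); closed channels by a baseline
// (box average corrected for the open-channel nanodomain inflation,
// floored at the bulk value) plus max(residual, superposition of
// open-channel kernels).
//
// Concentrations: two well-mixed compartments, the 500-nm cluster box and
// the remaining bulk (the domain-minimum proxy), exchanging total calcium
// with conductance g_box; rapid-buffer factor beta(c) = 1 + Btot*K/(K+c)^2
// converts total-calcium rates to free-concentration rates. SERCA/leak act
// on the membrane area share of each compartment. Per-channel residuals
// R_m decay exponentially with tau_domain and memorize the kernel
// superposition at each open-set change.

struct Compart {
  double Q, g, Vbox, Vblk, Abox, Ablk;
  double Pp, Kd, Pl, offset, cER;
  double Btot, Kbuf;
  double beta(double c) const {
    const double d = Kbuf + c;
    return 1.0 + Btot * Kbuf / (d * d);
  }
  double phi(double c) const {  // membrane flux density, nm uM / s
    return Pl * (cER - c) - offset - Pp * c * c / (Kd * Kd + c * c);
  }
  void deriv(double cb, double ck, int n_open, double* d) const {
    const double ex = g * (cb - ck);
    d[0] = (n_open * Q - ex + Abox * phi(cb) * 1e-3) / (Vbox * beta(cb));
    d[1] = (ex + Ablk * phi(ck) * 1e-3) / (Vblk * beta(ck));
  }
};

// Heun substeps; h adapted to the instantaneous box relaxation rate
static void advance_compartments(double& cb, double& ck, int n_open,
                                 double dt, double sub_h, const Compart& P) {
  while (dt > 1e-15) {
    const double rate = P.g / (P.Vbox * P.beta(cb)) + 1.0;
    double h = std::min(std::min(sub_h, 0.2 / rate), dt);
    double d0[2], d1[2];
    P.deriv(cb, ck, n_open, d0);
    double cb1 = cb + h * d0[0], ck1 = ck + h * d0[1];
    if (cb1 < 0) cb1 = 0;
    if (ck1 < 0) ck1 = 0;
    P.deriv(cb1, ck1, n_open, d1);
    cb += 0.5 * h * (d0[0] + d1[0]);
    ck += 0.5 * h * (d0[1] + d1[1]);
    if (cb < 0) cb = 0;
    if (ck < 0) ck = 0;
    dt -= h;
  }
}

// [[Rcpp::export]]
List reduced_run_cpp(IntegerMatrix sub0, double ip3,
                     NumericVector a, NumericVector b,
                     double duration, double cadence, double ca_open,
                     NumericMatrix dist, double kernA, double kernLambda,
                     double tau_domain, double g_box, double Q_red,
                     double box_excess,
                     double Vbox, double Vblk, double Abox, double Ablk,
                     double Pp, double Kd, double Pl, double offset,
                     double cER, double Btot, double Kbuf, double c_rest,
                     double dt_open, double dt_closed, double dt_elevated,
                     double c_elevated, double sub_h,
                     bool log_subunits, bool replay,
                     NumericMatrix schedule) {
  const int NCH = sub0.nrow();
  Compart P{Q_red, g_box, Vbox, Vblk, Abox, Ablk,
            Pp, Kd, Pl, offset, cER, Btot, Kbuf};

  std::vector<int> sub(NCH * 4);
  for (int c = 0; c < NCH; ++c)
    for (int u = 0; u < 4; ++u) sub[c * 4 + u] = sub0(c, u);

  std::vector<bool> open_flag(NCH, false);
  int n_open = 0;
  if (!replay)
    for (int c = 0; c < NCH; ++c)
      if (dyk_channel_open(&sub[c * 4])) { open_flag[c] = true; ++n_open; }

  // kernel matrix K[m][k]: concentration at channel m per open channel k
  std::vector<double> K(NCH * NCH, 0.0);
  for (int m = 0; m < NCH; ++m)
    for (int k = 0; k < NCH; ++k)
      if (m != k) {
        const double d = dist(m, k);
        K[m * NCH + k] = kernA * std::exp(-d / kernLambda) / d;
      }

  std::vector<double> S(NCH, 0.0), R(NCH, 0.0), drive(NCH, c_rest);
  std::vector<double> rate(NCH * 4 * 3), rtot(NCH * 4);
  std::vector<int> target(NCH * 4 * 3);
  double Rtot = 0.0;
  double c_box = c_rest, c_blk = c_rest;

  auto recompute_S = [&]() {
    for (int m = 0; m < NCH; ++m) {
      double s = 0.0;
      for (int k = 0; k < NCH; ++k)
        if (open_flag[k]) s += K[m * NCH + k];
      S[m] = s;
    }
  };
  recompute_S();

  auto sub_rates = [&](int u) {
    const int ch = u / 4;
    dyk_rates(sub[u], drive[ch], ip3, a.begin(), b.begin(),
              &rate[u * 3], &target[u * 3]);
    rtot[u] = rate[u * 3] + rate[u * 3 + 1] + rate[u * 3 + 2];
  };
  // baseline a closed channel sees: the box average corrected for the
  // nanodomain inflation contributed by currently open channels
  // (calibrated against grid replays), floored at the bulk value
  auto base = [&]() {
    return std::max(c_box - n_open * box_excess, std::min(c_blk, c_box));
  };
  auto refresh_rates = [&]() {
    Rtot = 0.0;
    const double b0 = base();
    for (int m = 0; m < NCH; ++m)
      drive[m] = open_flag[m] ? ca_open : b0 + std::max(R[m], S[m]);
    for (int u = 0; u < NCH * 4; ++u) { sub_rates(u); Rtot += rtot[u]; }
  };

  // replay schedule -> sorted toggle list
  struct Tog { double t; int ch; int on; };
  std::vector<Tog> togs;
  for (int r = 0; r < schedule.nrow(); ++r) {
    togs.push_back({schedule(r, 1), (int)schedule(r, 0) - 1, 1});
    togs.push_back({schedule(r, 2), (int)schedule(r, 0) - 1, 0});
  }
  std::sort(togs.begin(), togs.end(),
            [](const Tog& x, const Tog& y) { return x.t < y.t; });
  size_t itog = 0;

  const int nsamp = (int)std::floor(duration / cadence + 1e-9) + 1;
  NumericVector s_time(nsamp), s_nopen(nsamp), s_nact(nsamp),
      s_cbox(nsamp), s_cblk(nsamp);
  int isamp = 0;
  auto n_act = [&]() -> double {
    if (replay) return NA_REAL;
    int n = 0;
    for (int c = 0; c < NCH; ++c)
      if (dyk_channel_activatable(&sub[c * 4])) ++n;
    return n;
  };
  auto record = [&](double t) {
    s_time[isamp] = t; s_nopen[isamp] = n_open; s_nact[isamp] = n_act();
    s_cbox[isamp] = c_box; s_cblk[isamp] = c_blk; ++isamp;
  };
  record(0.0);

  std::vector<double> ol_t; std::vector<int> ol_ch, ol_on;
  std::vector<double> sl_t; std::vector<int> sl_ch, sl_su, sl_fr, sl_to;

  auto decayR = [&](double dt) {
    const double f = std::exp(-dt / tau_domain);
    for (int m = 0; m < NCH; ++m) R[m] *= f;
  };
  auto open_set_changed = [&](double t, int ch, bool now) {
    for (int m = 0; m < NCH; ++m) R[m] = std::max(R[m], S[m]);
    open_flag[ch] = now;
    n_open += now ? 1 : -1;
    ol_t.push_back(t); ol_ch.push_back(ch + 1); ol_on.push_back(now ? 1 : 0);
    recompute_S();
  };

  RNGScope scope;
  double t = 0.0;
  long n_ssa = 0, n_segments = 0;
  const double eps = 1e-12;
  while (t < duration - eps) {
    double dt_cap = dt_closed;
    if (n_open > 0) dt_cap = dt_open;
    else if (c_box > c_elevated) dt_cap = dt_elevated;
    const double next_samp = cadence * isamp;
    double t_end = std::min(duration, std::min(t + dt_cap, next_samp));
    if (replay && itog < togs.size()) t_end = std::min(t_end, togs[itog].t);
    if (t_end <= t + eps) t_end = t + eps;
    ++n_segments;
    if (!replay) refresh_rates();
    for (;;) {
      double t_next = R_PosInf;
      if (!replay && Rtot > 0) t_next = t + R::exp_rand() / Rtot;
      if (t_next >= t_end) {
        advance_compartments(c_box, c_blk, n_open, t_end - t, sub_h, P);
        decayR(t_end - t);
        t = t_end;
        break;
      }
      advance_compartments(c_box, c_blk, n_open, t_next - t, sub_h, P);
      decayR(t_next - t);
      t = t_next;
      ++n_ssa;
      // pick subunit, then site
      double pick = unif_rand() * Rtot;
      int u = 0;
      for (; u < NCH * 4 - 1; ++u) { if (pick <= rtot[u]) break; pick -= rtot[u]; }
      double ps = unif_rand() * rtot[u];
      int site = 0;
      if (ps > rate[u * 3]) { ps -= rate[u * 3]; site = (ps > rate[u * 3 + 1]) ? 2 : 1; }
      const int from = sub[u], to = target[u * 3 + site];
      if (log_subunits) {
        sl_t.push_back(t); sl_ch.push_back(u / 4 + 1); sl_su.push_back(u % 4 + 1);
        sl_fr.push_back(from); sl_to.push_back(to);
      }
      sub[u] = to;
      const int ch = u / 4;
      const bool was = open_flag[ch];
      const bool now = dyk_channel_open(&sub[ch * 4]);
      if (now != was) {
        open_set_changed(t, ch, now);
        break;  // split the macro step at the transition
      }
      Rtot -= rtot[u];
      sub_rates(u);
      Rtot += rtot[u];
    }
    // replay toggles fire exactly at segment ends
    while (replay && itog < togs.size() && togs[itog].t <= t + eps) {
      const Tog& g = togs[itog++];
      if (open_flag[g.ch] != (g.on == 1))
        open_set_changed(t, g.ch, g.on == 1);
    }
    if (isamp < nsamp && t >= cadence * isamp - eps) record(cadence * isamp);
  }
  while (isamp < nsamp) record(duration);  // guard (should not trigger)

  IntegerMatrix subf(NCH, 4);
  for (int c = 0; c < NCH; ++c)
    for (int u = 0; u < 4; ++u) subf(c, u) = sub[c * 4 + u];

  const int no = (int)ol_t.size();
  NumericMatrix olog(no, 3);
  for (int r = 0; r < no; ++r) {
    olog(r, 0) = ol_t[r]; olog(r, 1) = ol_ch[r]; olog(r, 2) = ol_on[r];
  }
  const int ns = (int)sl_t.size();
  NumericMatrix slog(ns, 5);
  for (int r = 0; r < ns; ++r) {
    slog(r, 0) = sl_t[r]; slog(r, 1) = sl_ch[r]; slog(r, 2) = sl_su[r];
    slog(r, 3) = sl_fr[r]; slog(r, 4) = sl_to[r];
  }
  return List::create(_["time"] = s_time, _["n_open"] = s_nopen,
                      _["n_activatable"] = s_nact, _["box_avg_ca"] = s_cbox,
                      _["domain_min_ca"] = s_cblk, _["open_log"] = olog,
                      _["sub_log"] = slog, _["subunits"] = subf,
                      _["n_ssa"] = (double)n_ssa,
                      _["n_segments"] = (double)n_segments);
}
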