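#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include "dyk.h"

using namespace Rcpp;

// Exact CTMC advance of independent subunits over [0, dt) with frozen
// concentrations: per subunit, draw competing exponentials, apply the
// earliest transition if < dt, recompute, repeat. Uses R's RNG.
// [[Rcpp::export]]
List advance_channels_cpp(IntegerMatrix channels, double dt,
                          NumericVector ca_per_channel,
                          NumericVector a, NumericVector b, double ip3) {
  const int nch = channels.nrow();
  IntegerMatrix out = clone(channels);
  std::vector<double> ltime;
  std::vector<int> lch, lsub, lfrom, lto;
  RNGScope scope;
  double rate[3];
  int target[3];
  for (int c = 0; c < nch; ++c) {
    const double ca = ca_per_channel[c];
    for (int u = 0; u < 4; ++u) {
      double t = 0.0;
      int s = out(c, u);
      for (;;) {
        dyk_rates(s, ca, ip3, a.begin(), b.begin(), rate, target);
        const double tot = rate[0] + rate[1] + rate[2];
        if (tot <= 0.0) break;
        t += R::exp_rand() / tot;
        if (t >= dt) break;
        double pick = unif_rand() * tot;
        int site = 0;
        if (pick > rate[0]) { pick -= rate[0]; site = (pick > rate[1]) ? 2 : 1; }
        ltime.push_back(t); lch.push_back(c + 1); lsub.push_back(u + 1);
        lfrom.push_back(s); lto.push_back(target[site]);
        s = target[site];
      }
      out(c, u) = s;
    }
  }
  // order the log globally in time (ties broken by draw order = subunit index)
  const int n = (int)ltime.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int x, int y) { return ltime[x] < ltime[y]; });
  NumericMatrix log(n, 5);
  for (int r = 0; r < n; ++r) {
    const int i = ord[r];
    log(r, 0) = ltime[i]; log(r, 1) = lch[i]; log(r, 2) = lsub[i];
    log(r, 3) = lfrom[i]; log(r, 4) = lto[i];
  }
  return List::create(_["channels"] = out, _["log"] = log);
}
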