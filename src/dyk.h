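#pragma once

// Modified DeYoung-Keizer subunit rates.
// Subunit state s = 4i + 2j + k (i IP3 site, j activating Ca2+ site,
// k inhibiting Ca2+ site). Rate arrays a, b are 0-based (a[0] = a_1).
// Site rate-index selection on the DYK cube:
//   IP3 site: i=1 (index 1) while not inhibited, i=3 while inhibited
//   inhibiting site: i=2 with IP3 bound, i=4 without
//   activating site: always i=5.
static inline void dyk_rates(int s, double ca, double ip3,
                             const double* a, const double* b,
                             double* rate, int* target) {
  const int i = (s >> 2) & 1, j = (s >> 1) & 1, k = s & 1;
  const int idx_ip3 = k ? 2 : 0;  // rate index 3 or 1 (0-based)
  const int idx_inh = i ? 1 : 3;  // rate index 2 or 4 (0-based)
  rate[0] = i ? b[idx_ip3] : a[idx_ip3] * ip3;  target[0] = s ^ 4;
  rate[1] = j ? b[4]       : a[4] * ca;         target[1] = s ^ 2;
  rate[2] = k ? b[idx_inh] : a[idx_inh] * ca;   target[2] = s ^ 1;
}

static inline bool dyk_channel_open(const int* sub) {
  int n = 0;
  for (int u = 0; u < 4; ++u) n += (sub[u] == 6);
  return n >= 3;
}

static inline bool dyk_channel_activatable(const int* sub) {
  int n = 0;
  for (int u = 0; u < 4; ++u) n += (sub[u] >= 4);
  return n >= 3;
}
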