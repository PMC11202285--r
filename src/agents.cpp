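#include <Rcpp.h>
using namespace Rcpp;

// Agent state codes shared with the R level (see AllClasses.R):
// 1 = VESSEL, 2 = NORMAL, 3 = TUMOR_NORMOXIC, 4 = TUMOR_HYPOXIC, 5 = TUMOR_NECROTIC

static inline int wrap(int i, int n) { return i < 0 ? i + n : (i >= n ? i - n : i); }

// One biological hour of cell-type determination, in the order
// survival -> oxygenation classification -> division, applied to every viable
// tumor cell in a random permutation. Uses R's RNG so set.seed() governs the
// full trajectory. Neighborhood is the Moore 8-neighborhood with periodic wrap.
//
// o2 in mmHg, glucose in mol/L. Thresholds pre-converted by the caller:
//   o2_necro  : necrosis oxygen threshold (mmHg)
//   hyp_lo/hi : hypoxia band (mmHg), closed on both ends
//   div_ref   : oxygen at which division probability saturates (mmHg)
//   atp_thr   : ATP-rate necrosis threshold (mol/min/cell)
// vmax_o2 / vmax_glu: per-class rates, index 0 = normoxic tumor, 1 = hypoxic
// tumor (mol/min/cell); km_glu in mol/L; atp = 2 f_G + atp_aerobic * f_O.
// [[Rcpp::export]]
IntegerMatrix update_agents_cpp(IntegerMatrix states, NumericMatrix o2,
                                NumericMatrix glu,
                                double o2_necro, double hyp_lo, double hyp_hi,
                                double div_ref, double p_div_max,
                                double atp_thr, double exp_atp, double exp_o2,
                                NumericVector vmax_o2, NumericVector vmax_glu,
                                double km_glu, double atp_aerobic,
                                double vessel_removal_prob) {
  const int nr = states.nrow(), nc = states.ncol();
  IntegerMatrix st = clone(states);
  // collect viable tumor cells present at the start of the hour
  std::vector<int> idx;
  idx.reserve(1024);
  for (int k = 0; k < nr * nc; ++k)
    if (st[k] == 3 || st[k] == 4) idx.push_back(k);
  const int m = (int)idx.size();
  if (m == 0) return st;
  GetRNGstate();
  // Fisher-Yates permutation driven by the same RNG stream
  for (int a = m - 1; a > 0; --a) {
    int b = (int)std::floor(unif_rand() * (a + 1));
    if (b > a) b = a;
    std::swap(idx[a], idx[b]);
  }
  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  for (int t = 0; t < m; ++t) {
    const int k = idx[t];
    int s = st[k];
    if (s != 3 && s != 4) continue;  // replaced earlier in this pass (cannot
                                     // happen: daughters only claim NORMAL or
                                     // VESSEL pixels) -- kept as a guard
    const int i = k % nr, j = k / nr;
    const double c_o = o2(i, j), c_g = glu(i, j);
    const int cls = (s == 3 ? 0 : 1);
    const double f_o = vmax_o2[cls];
    const double f_g = vmax_glu[cls] * c_g / (km_glu + c_g);
    const double f_atp = 2.0 * f_g + atp_aerobic * f_o;
    // survival: one uniform draw per criterion, oxygen first
    bool dead = false;
    if (c_o < o2_necro) {
      double p = 1.0 - std::pow(c_o / o2_necro, exp_o2);
      if (p > 1.0) p = 1.0;
      if (unif_rand() < p) dead = true;
    }
    if (!dead && f_atp < atp_thr) {
      double p = 1.0 - std::pow(f_atp / atp_thr, exp_atp);
      if (p > 1.0) p = 1.0;
      if (unif_rand() < p) dead = true;
    }
    if (dead) { st[k] = 5; continue; }
    // oxygenation state: band closed on both ends; survivors below the band
    // stay hypoxic (most oxygen-deprived viable class)
    if (c_o > hyp_hi) s = 3; else s = 4;
    st[k] = s;
    // division: requires both criteria at/above threshold, then an hourly
    // Bernoulli draw with probability scaled by local oxygen
    if (c_o < o2_necro || f_atp < atp_thr) continue;
    double p_div = p_div_max * std::min(1.0, c_o / div_ref);
    if (unif_rand() >= p_div) continue;
    int normals[8], vessels[8];
    int nn = 0, nv = 0;
    for (int q = 0; q < 8; ++q) {
      const int ii = wrap(i + dr[q], nr), jj = wrap(j + dc[q], nc);
      const int ns = st(ii, jj);
      if (ns == 2) normals[nn++] = ii + jj * nr;
      else if (ns == 1) vessels[nv++] = ii + jj * nr;
    }
    if (nn > 0) {
      int pick = (int)std::floor(unif_rand() * nn);
      if (pick >= nn) pick = nn - 1;
      st[normals[pick]] = s;
    } else if (nv > 0) {
      if (unif_rand() < vessel_removal_prob) {
        int pick = (int)std::floor(unif_rand() * nv);
        if (pick >= nv) pick = nv - 1;
        st[vessels[pick]] = s;
      }
    }
    // no NORMAL and no VESSEL neighbor: division is lost this hour
  }
  PutRNGstate();
  return st;
}
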