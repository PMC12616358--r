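#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

// Largest-remainder apportionment of `n` over `weights`, stable tie-break
// by index (matches the R implementation's order()).
static void largest_remainder(int n, const std::vector<double>& w,
                              std::vector<int>& out) {
  const int k = (int)w.size();
  double tot = std::accumulate(w.begin(), w.end(), 0.0);
  out.assign(k, 0);
  if (tot <= 0.0 || n <= 0) return;
  std::vector<double> rem(k);
  int used = 0;
  for (int i = 0; i < k; ++i) {
    double raw = n * w[i] / tot;
    out[i] = (int)std::floor(raw);
    rem[i] = raw - out[i];
    used += out[i];
  }
  int left = n - used;
  if (left > 0) {
    std::vector<int> idx(k);
    std::iota(idx.begin(), idx.end(), 0);
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) { return rem[a] > rem[b]; });
    for (int i = 0; i < left && i < k; ++i) out[idx[i]] += 1;
  }
}

// Allocation with availability caps and one redistribution pass, mirroring
// allocateAcrossMice().
static void alloc_capped(int n, const std::vector<double>& w,
                         const std::vector<int>& avail,
                         std::vector<int>& out) {
  const int k = (int)w.size();
  largest_remainder(n, w, out);
  int shortfall = 0;
  std::vector<bool> over(k, false);
  for (int i = 0; i < k; ++i) {
    if (out[i] > avail[i]) {
      shortfall += out[i] - avail[i];
      out[i] = avail[i];
      over[i] = true;
    }
  }
  if (shortfall > 0) {
    std::vector<double> wr;
    std::vector<int> pos;
    for (int i = 0; i < k; ++i)
      if (!over[i] && out[i] < avail[i]) { wr.push_back(w[i]); pos.push_back(i); }
    if (!pos.empty()) {
      std::vector<int> extra;
      largest_remainder(shortfall, wr, extra);
      for (size_t j = 0; j < pos.size(); ++j) {
        out[pos[j]] += extra[j];
        if (out[pos[j]] > avail[pos[j]]) out[pos[j]] = avail[pos[j]];
      }
    }
  }
}

static double median_of(std::vector<double>& v) {
  if (v.empty()) return NA_REAL;
  std::sort(v.begin(), v.end());
  size_t n = v.size();
  return (n % 2 == 1) ? v[n / 2] : 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

// Nested bootstrap of the per-gene relative LN mean.
//
// Rows must be sorted mouse-major, then sgRNA, then cells descending (the
// adaptive-sampling tie-break order). Per replicate: mice are resampled
// with replacement to cohort size; tumors multinomially resampled within
// each pseudo-mouse to its tumor count; per-sgRNA quotas re-allocated
// across pseudo-mice proportional to their total tumor counts (capped by
// resampled availability, one redistribution pass); the allocation-many
// largest resampled tumors per (pseudo-mouse, sgRNA) enter the per-sgRNA
// LN mean, which is normalized by the median over inert vectors and
// aggregated to genes with weights proportional to sampled tumor counts.
// With point_est = true a single deterministic pass (identity resample)
// is returned, which equals relativeStats() on the original data.
// [[Rcpp::export(name = "cq_boot_rel_lnmean")]]
NumericMatrix cq_boot_rel_lnmean(NumericVector logc, IntegerVector mouse_of,
                                 IntegerVector sg_of, int n_mice, int n_sg,
                                 IntegerVector quota, LogicalVector inert,
                                 IntegerVector gene_of_sg, int n_gene,
                                 int B, bool point_est = false) {
  const int n = logc.size();
  std::vector<int> gstart(n_mice * n_sg, -1), glen(n_mice * n_sg, 0);
  std::vector<int> mstart(n_mice + 1, 0);
  for (int i = 0; i < n; ++i) {
    int g = mouse_of[i] * n_sg + sg_of[i];
    if (glen[g] == 0) gstart[g] = i;
    glen[g] += 1;
  }
  {
    std::vector<int> mcount(n_mice, 0);
    for (int i = 0; i < n; ++i) mcount[mouse_of[i]] += 1;
    for (int m = 0; m < n_mice; ++m) mstart[m + 1] = mstart[m] + mcount[m];
  }

  const int nB = point_est ? 1 : B;
  NumericMatrix out(nB, n_gene);
  RNGScope scope;

  std::vector<int> ms(n_mice), off(n_mice + 1);
  std::vector<int> cntbuf;
  std::vector<int> kmat(n_mice * n_sg), amat(n_mice * n_sg);
  std::vector<double> prob;
  std::vector<int> rn;
  std::vector<double> s1(n_sg), s2(n_sg);
  std::vector<int> kk(n_sg);
  std::vector<double> wts(n_mice);
  std::vector<int> avail(n_mice), alloc(n_mice);
  std::vector<double> lnm(n_sg), ratio(n_sg), inert_vals;

  for (int b = 0; b < nB; ++b) {
    // 1. resample mice (identity in point mode)
    for (int m = 0; m < n_mice; ++m)
      ms[m] = point_est ? m : (int)std::floor(unif_rand() * n_mice);
    off[0] = 0;
    for (int m = 0; m < n_mice; ++m)
      off[m + 1] = off[m] + (mstart[ms[m] + 1] - mstart[ms[m]]);
    cntbuf.assign(off[n_mice], 1);

    // 2. multinomial tumor resampling within each pseudo-mouse
    for (int m = 0; m < n_mice; ++m) {
      int src = ms[m];
      int nm = mstart[src + 1] - mstart[src];
      if (nm == 0) continue;
      if (!point_est) {
        // nm uniform draws with replacement, tallied in place (equivalent
        // to an equal-probability multinomial, much cheaper)
        std::fill(cntbuf.begin() + off[m], cntbuf.begin() + off[m] + nm, 0);
        for (int i = 0; i < nm; ++i) {
          int j = (int)std::floor(unif_rand() * nm);
          if (j >= nm) j = nm - 1;
          cntbuf[off[m] + j] += 1;
        }
      }
      for (int v = 0; v < n_sg; ++v) {
        int g = src * n_sg + v;
        int tot = 0;
        for (int i = 0; i < glen[g]; ++i)
          tot += cntbuf[off[m] + (gstart[g] - mstart[src]) + i];
        kmat[m * n_sg + v] = tot;
      }
    }

    // 3. allocate quotas across pseudo-mice (weights: total tumors)
    for (int m = 0; m < n_mice; ++m)
      wts[m] = (double)(mstart[ms[m] + 1] - mstart[ms[m]]);
    for (int v = 0; v < n_sg; ++v) {
      for (int m = 0; m < n_mice; ++m) avail[m] = kmat[m * n_sg + v];
      alloc_capped(quota[v], wts, avail, alloc);
      for (int m = 0; m < n_mice; ++m) amat[m * n_sg + v] = alloc[m];
    }

    // 4. select the allocation-many largest resampled tumors per group
    std::fill(s1.begin(), s1.end(), 0.0);
    std::fill(s2.begin(), s2.end(), 0.0);
    std::fill(kk.begin(), kk.end(), 0);
    for (int m = 0; m < n_mice; ++m) {
      int src = ms[m];
      for (int v = 0; v < n_sg; ++v) {
        int want = amat[m * n_sg + v];
        if (want <= 0) continue;
        int g = src * n_sg + v;
        for (int i = 0; i < glen[g] && want > 0; ++i) {
          int row = gstart[g] + i;
          int c = cntbuf[off[m] + (row - mstart[src])];
          if (c <= 0) continue;
          int take = c < want ? c : want;
          double lx = logc[row];
          s1[v] += take * lx;
          s2[v] += take * lx * lx;
          kk[v] += take;
          want -= take;
        }
      }
    }

    // 5. per-sgRNA LN means, inert baseline, gene aggregation
    inert_vals.clear();
    for (int v = 0; v < n_sg; ++v) {
      if (kk[v] > 0) {
        double mean = s1[v] / kk[v];
        double var = s2[v] / kk[v] - mean * mean;
        if (var < 0) var = 0;
        lnm[v] = std::exp(mean + var / 2.0);
        if (inert[v]) inert_vals.push_back(lnm[v]);
      } else {
        lnm[v] = NA_REAL;
      }
    }
    double base = median_of(inert_vals);
    for (int v = 0; v < n_sg; ++v)
      ratio[v] = (kk[v] > 0 && R_finite(base) && base > 0)
                     ? lnm[v] / base : NA_REAL;
    for (int gn = 0; gn < n_gene; ++gn) {
      double num = 0.0, den = 0.0;
      for (int v = 0; v < n_sg; ++v) {
        if (gene_of_sg[v] == gn && kk[v] > 0 && R_finite(ratio[v])) {
          num += ratio[v] * kk[v];
          den += kk[v];
        }
      }
      out(b, gn) = den > 0 ? num / den : NA_REAL;
    }
  }
  return out;
}
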