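#include <Rcpp.h>
using namespace Rcpp;

// One generation of the spatial life cycle, the O(n^2) part:
// kernel-estimated local density -> Beverton-Holt expected offspring ->
// Poisson offspring numbers, and Gaussian-weighted mate choice. Both the
// competition (density) kernel and the mate-search kernel are Gaussian at
// scale sigma_f truncated at 3*sigma_f; a mother with no candidate in range
// produces no offspring. Uses R's RNG throughout, so results are reproducible
// under set.seed().
// [[Rcpp::export]]
List sim_step_core(NumericVector x, NumericVector y, double sigma_f,
                   double habitat_width, double k_capacity, double growth_rate) {
  const int n = x.size();
  const double two_sf2 = 2.0 * sigma_f * sigma_f;
  const double trunc2 = 9.0 * sigma_f * sigma_f;
  // truncated-Gaussian normalization: 2*pi*sf^2 * (1 - exp(-9/2))
  const double norm = 2.0 * M_PI * sigma_f * sigma_f * (1.0 - std::exp(-4.5));

  NumericMatrix kern(n, n); // zero-initialized; only in-range entries filled
  std::vector<double> ksum(n, 0.0);
  double *pk = kern.begin();
  for (int i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - x[j];
      const double dy = yi - y[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 > trunc2) continue;
      const double k = std::exp(-d2 / two_sf2);
      pk[(size_t)i * n + j] = k; // kern(j, i)
      pk[(size_t)j * n + i] = k; // kern(i, j)
      ksum[i] += k;
      ksum[j] += k;
    }
  }

  IntegerVector n_off(n);
  IntegerVector father(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    if (ksum[i] <= 0.0) { n_off[i] = 0; continue; } // no mate in range
    const double mass_x = R::pnorm((habitat_width - x[i]) / sigma_f, 0, 1, 1, 0) -
                          R::pnorm(-x[i] / sigma_f, 0, 1, 1, 0);
    const double mass_y = R::pnorm((habitat_width - y[i]) / sigma_f, 0, 1, 1, 0) -
                          R::pnorm(-y[i] / sigma_f, 0, 1, 1, 0);
    const double dens = ksum[i] / (norm * mass_x * mass_y);
    const double lambda = growth_rate / (1.0 + (growth_rate - 1.0) * dens / k_capacity);
    n_off[i] = (int) R::rpois(lambda);
    if (n_off[i] == 0) continue;

    // weighted pick along column i (contiguous); weights are the kernel values
    const double t = unif_rand() * ksum[i];
    const double *col = pk + (size_t)i * n;
    double acc = 0.0;
    int pick = -1;
    for (int j = 0; j < n; ++j) {
      const double k = col[j];
      if (k <= 0.0) continue;
      acc += k;
      pick = j;
      if (acc >= t) break;
    }
    father[i] = pick + 1; // 1-based
  }
  return List::create(_["n_off"] = n_off, _["father"] = father);
}

// one recombinant gamete written into dst (contiguous column of length s)
static void one_gamete(const int *ph, size_t col_a, size_t col_b, int *dst,
                       const double *pp, int s, double genome_length,
                       double recomb_rate, std::vector<double> &breaks) {
  int phase = unif_rand() < 0.5 ? 0 : 1;
  const int k = (int) R::rpois(recomb_rate * genome_length);
  if (k == 0) {
    std::memcpy(dst, ph + (phase ? col_b : col_a), s * sizeof(int));
    return;
  }
  breaks.resize(k);
  for (int b = 0; b < k; ++b) breaks[b] = unif_rand() * genome_length;
  std::sort(breaks.begin(), breaks.end());
  int c = 0;
  for (int b = 0; b <= k; ++b) {
    const double upto = (b < k) ? breaks[b] : R_PosInf;
    int c0 = c;
    while (c < s && pp[c] < upto) ++c;
    if (c > c0) {
      std::memcpy(dst + c0, ph + (phase ? col_b : col_a) + c0,
                  (c - c0) * sizeof(int));
    }
    phase ^= 1;
  }
}

// Whole-genome generation update. H is sites x haplotypes (two columns per
// individual, 1-based parent indices). Produces the offspring haplotype matrix
// (maternal gamete in column 2o-1, paternal in 2o), adds
// Poisson(2 * n_off * mut_rate * genome_length) new singleton mutations at
// uniform continuous bp positions, and drops sites fixed or lost among the
// offspring. Returns the pruned sites x (2 * n_off) matrix and the sorted site
// positions. Crossovers are Poisson(recomb_rate * genome_length) per gamete.
// [[Rcpp::export]]
List genome_step_core(IntegerMatrix H, IntegerVector mothers,
                      IntegerVector fathers, NumericVector positions,
                      double genome_length, double recomb_rate,
                      double mut_rate) {
  const int n_off = mothers.size();
  const int nh = 2 * n_off;
  const int s = positions.size();
  const int *ph = H.begin();
  const double *pp = positions.begin();

  IntegerMatrix tmp(s, nh);
  int *pt = tmp.begin();
  std::vector<double> breaks;
  for (int o = 0; o < n_off; ++o) {
    const size_t ma = (size_t)(2 * (mothers[o] - 1)) * s;
    const size_t fa = (size_t)(2 * (fathers[o] - 1)) * s;
    one_gamete(ph, ma, ma + s, pt + (size_t)(2 * o) * s, pp, s,
               genome_length, recomb_rate, breaks);
    one_gamete(ph, fa, fa + s, pt + (size_t)(2 * o + 1) * s, pp, s,
               genome_length, recomb_rate, breaks);
  }

  // new mutations: position + carrier haplotype, sorted by position
  const int n_mut = (int) R::rpois(2.0 * n_off * mut_rate * genome_length);
  std::vector<std::pair<double, int>> muts(n_mut);
  for (int u = 0; u < n_mut; ++u) {
    muts[u] = {unif_rand() * genome_length,
               (int)(unif_rand() * nh)};
  }
  std::sort(muts.begin(), muts.end());

  // prune monomorphic sites among offspring
  std::vector<int> rowsum(s, 0);
  for (int c = 0; c < nh; ++c) {
    const int *col = pt + (size_t)c * s;
    for (int r = 0; r < s; ++r) rowsum[r] += col[r];
  }
  std::vector<int> newrow(s, -1);
  int n_keep = 0;
  // destination rows after merging kept old sites with sorted new mutations
  std::vector<double> out_pos;
  out_pos.reserve(s + n_mut);
  std::vector<std::pair<int, int>> mut_cells; // (out row, haplotype column)
  {
    int u = 0;
    for (int r = 0; r < s; ++r) {
      const bool keep = rowsum[r] >= 1 && rowsum[r] <= nh - 1;
      while (u < n_mut && muts[u].first < pp[r]) {
        mut_cells.push_back({(int)out_pos.size(), muts[u].second});
        out_pos.push_back(muts[u].first);
        ++u;
      }
      if (keep) {
        newrow[r] = (int)out_pos.size();
        out_pos.push_back(pp[r]);
        ++n_keep;
      }
    }
    while (u < n_mut) {
      mut_cells.push_back({(int)out_pos.size(), muts[u].second});
      out_pos.push_back(muts[u].first);
      ++u;
    }
  }

  const int s_out = (int)out_pos.size();
  IntegerMatrix out(s_out, nh);
  int *po = out.begin();
  for (int c = 0; c < nh; ++c) {
    const int *src = pt + (size_t)c * s;
    int *dst = po + (size_t)c * s_out;
    for (int r = 0; r < s; ++r) {
      if (newrow[r] >= 0) dst[newrow[r]] = src[r];
    }
  }
  for (auto &mc : mut_cells) {
    po[(size_t)mc.second * s_out + mc.first] = 1;
  }
  return List::create(_["haplotypes"] = out,
                      _["positions"] = NumericVector(out_pos.begin(), out_pos.end()));
}
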