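#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Six-state copy-number HMM over SNP-array LRR/BAF signals.
// State order: 0=CN0, 1=CN1, 2=CN2, 3=CN2-LOH, 4=CN3, 5=CN4.
// CN2 is the neutral state; ties are broken toward it.

static const int N_STATE = 6;
static const int CN2 = 2;
// preference order used when breaking score ties
static const int TIE_ORDER[N_STATE] = {2, 0, 1, 3, 4, 5};

// unique BAF band centres shared across states
static const int N_BAND = 7;
static const double BANDS[N_BAND] = {0.0, 0.25, 1.0 / 3.0, 0.5,
                                     2.0 / 3.0, 0.75, 1.0};
// band indices per state (into BANDS); CN0 has no bands (uniform BAF)
static const int S_CN1[2] = {0, 6};
static const int S_CN2[3] = {0, 3, 6};
static const int S_CN3[4] = {0, 2, 4, 6};
static const int S_CN4[5] = {0, 1, 3, 5, 6};

static inline double norm_logpdf(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -0.5 * z * z - std::log(sd) - 0.918938533204672742; // log(sqrt(2pi))
}

struct EmissionModel {
  double lmu[N_STATE], lsd[N_STATE];
  double baf_sd, out_w;
  // boundary masses of the clipped BAF distribution per band
  double mass0[N_BAND], mass1[N_BAND];
  double inv_sd, norm_c;
  // per-marker state band weights, computed from pfb (markers x weights)
  std::vector<double> w1, w2, w3, w4; // CN1:2, CN2:3, CN3:4, CN4:5 weights

  EmissionModel(NumericVector lrr_means, NumericVector lrr_sds,
                double baf_sd_, double out_w_, NumericVector pfb)
      : baf_sd(baf_sd_), out_w(out_w_) {
    for (int s = 0; s < N_STATE; ++s) {
      lmu[s] = lrr_means[s];
      lsd[s] = lrr_sds[s];
    }
    for (int b = 0; b < N_BAND; ++b) {
      mass0[b] = R::pnorm(0.0, BANDS[b], baf_sd, 1, 0);
      mass1[b] = R::pnorm(1.0, BANDS[b], baf_sd, 0, 0);
    }
    inv_sd = 1.0 / baf_sd;
    norm_c = 0.398942280401432678 * inv_sd;
    int n = pfb.size();
    w1.resize(2 * n); w2.resize(3 * n); w3.resize(4 * n); w4.resize(5 * n);
    for (int i = 0; i < n; ++i) {
      double p = pfb[i], q = 1.0 - p;
      w1[2 * i] = q; w1[2 * i + 1] = p;
      w2[3 * i] = q * q; w2[3 * i + 1] = 2 * p * q; w2[3 * i + 2] = p * p;
      w3[4 * i] = q * q * q; w3[4 * i + 1] = 3 * q * q * p;
      w3[4 * i + 2] = 3 * q * p * p; w3[4 * i + 3] = p * p * p;
      w4[5 * i] = q * q * q * q; w4[5 * i + 1] = 4 * q * q * q * p;
      w4[5 * i + 2] = 6 * q * q * p * p; w4[5 * i + 3] = 4 * q * p * p * p;
      w4[5 * i + 4] = p * p * p * p;
    }
  }

  // log emission densities of all 6 states at marker i
  void marker(int i, double lrr, double baf, double *out) const {
    // densities of the 7 bands at this BAF value (clipped normal)
    double bd[N_BAND];
    const double eps = 1e-6;
    if (baf < eps) {
      for (int b = 0; b < N_BAND; ++b) bd[b] = mass0[b];
    } else if (baf > 1.0 - eps) {
      for (int b = 0; b < N_BAND; ++b) bd[b] = mass1[b];
    } else {
      for (int b = 0; b < N_BAND; ++b) {
        double z = (baf - BANDS[b]) * inv_sd;
        bd[b] = (z > 7.0 || z < -7.0) ? 0.0 : norm_c * std::exp(-0.5 * z * z);
      }
    }
    double dens[N_STATE];
    dens[0] = 1.0; // CN0: uniform BAF
    const double *v1 = &w1[2 * i], *v2 = &w2[3 * i], *v3 = &w3[4 * i],
                 *v4 = &w4[5 * i];
    dens[1] = v1[0] * bd[S_CN1[0]] + v1[1] * bd[S_CN1[1]];
    dens[2] = v2[0] * bd[S_CN2[0]] + v2[1] * bd[S_CN2[1]] + v2[2] * bd[S_CN2[2]];
    dens[3] = dens[1]; // CN2-LOH: homozygous bands with CN1 weights
    dens[4] = v3[0] * bd[S_CN3[0]] + v3[1] * bd[S_CN3[1]] +
              v3[2] * bd[S_CN3[2]] + v3[3] * bd[S_CN3[3]];
    dens[5] = v4[0] * bd[S_CN4[0]] + v4[1] * bd[S_CN4[1]] +
              v4[2] * bd[S_CN4[2]] + v4[3] * bd[S_CN4[3]] +
              v4[4] * bd[S_CN4[4]];
    for (int s = 0; s < N_STATE; ++s) {
      double d = (1.0 - out_w) * dens[s] + out_w; // uniform outlier component
      out[s] = std::log(d) + norm_logpdf(lrr, lmu[s], lsd[s]);
    }
  }
};

// [[Rcpp::export]]
NumericMatrix emission_logdens_cpp(NumericVector lrr, NumericVector baf,
                                   NumericVector pfb, NumericVector lrr_means,
                                   NumericVector lrr_sds, double baf_sd,
                                   double outlier_w) {
  int n = lrr.size();
  EmissionModel em(lrr_means, lrr_sds, baf_sd, outlier_w, pfb);
  NumericMatrix out(n, N_STATE);
  double row[N_STATE];
  for (int i = 0; i < n; ++i) {
    em.marker(i, lrr[i], baf[i], row);
    for (int s = 0; s < N_STATE; ++s) out(i, s) = row[s];
  }
  return out;
}

static inline void trans_logprobs(double d, double eps, double scale,
                                  double *log_stay, double *log_switch) {
  double pc = eps * (1.0 - std::exp(-d / scale));
  if (pc < 1e-300) pc = 1e-300;
  *log_stay = std::log1p(-pc);
  *log_switch = std::log(pc / (N_STATE - 1));
}

// Viterbi decoding with distance-dependent transitions; returns the
// maximum-a-posteriori state path (1-based state indices)
static void viterbi_core(const std::vector<double> &logem, int n,
                         const std::vector<double> &lstay,
                         const std::vector<double> &lsw,
                         const NumericVector &log_init, int *path) {
  std::vector<double> score(n * N_STATE);
  std::vector<int> back(n * N_STATE);
  for (int s = 0; s < N_STATE; ++s)
    score[s] = log_init[s] + logem[s];
  for (int i = 1; i < n; ++i) {
    const double *prev = &score[(i - 1) * N_STATE];
    double *cur = &score[i * N_STATE];
    int *bk = &back[i * N_STATE];
    for (int s = 0; s < N_STATE; ++s) {
      double best = R_NegInf;
      int argbest = CN2;
      for (int t = 0; t < N_STATE; ++t) {
        int pv = TIE_ORDER[t];
        double cand = prev[pv] + (pv == s ? lstay[i] : lsw[i]);
        if (cand > best) { best = cand; argbest = pv; }
      }
      cur[s] = best + logem[i * N_STATE + s];
      bk[s] = argbest;
    }
  }
  double best = R_NegInf;
  int last = CN2;
  const double *fin = &score[(n - 1) * N_STATE];
  for (int t = 0; t < N_STATE; ++t) {
    int s = TIE_ORDER[t];
    if (fin[s] > best) { best = fin[s]; last = s; }
  }
  path[n - 1] = last;
  for (int i = n - 1; i > 0; --i) path[i - 1] = back[i * N_STATE + path[i]];
}

static void fill_trans(const NumericVector &pos, double eps, double scale,
                       std::vector<double> &lstay, std::vector<double> &lsw) {
  int n = pos.size();
  lstay.resize(n); lsw.resize(n);
  for (int i = 1; i < n; ++i)
    trans_logprobs(pos[i] - pos[i - 1], eps, scale, &lstay[i], &lsw[i]);
}

// [[Rcpp::export]]
IntegerVector viterbi_decode_cpp(NumericMatrix logem, NumericVector pos,
                                 double eps, double scale,
                                 NumericVector log_init) {
  int n = logem.nrow();
  if (n == 0) stop("empty signal");
  std::vector<double> em(n * N_STATE);
  for (int i = 0; i < n; ++i)
    for (int s = 0; s < N_STATE; ++s) em[i * N_STATE + s] = logem(i, s);
  std::vector<double> lstay, lsw;
  fill_trans(pos, eps, scale, lstay, lsw);
  std::vector<int> path(n);
  viterbi_core(em, n, lstay, lsw, log_init, path.data());
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = path[i] + 1;
  return out;
}

// [[Rcpp::export]]
double path_loglik_cpp(IntegerVector path, NumericMatrix logem,
                       NumericVector pos, double eps, double scale,
                       NumericVector log_init) {
  int n = logem.nrow();
  std::vector<double> lstay, lsw;
  fill_trans(pos, eps, scale, lstay, lsw);
  double ll = log_init[path[0] - 1] + logem(0, path[0] - 1);
  for (int i = 1; i < n; ++i)
    ll += (path[i] == path[i - 1] ? lstay[i] : lsw[i]) + logem(i, path[i] - 1);
  return ll;
}

// exhaustive enumeration over all 6^n paths; independent oracle for the
// Viterbi decoder on small instances
// [[Rcpp::export]]
IntegerVector best_path_enum_cpp(NumericMatrix logem, NumericVector pos,
                                 double eps, double scale,
                                 NumericVector log_init) {
  int n = logem.nrow();
  if (n > 12) stop("enumeration limited to <= 12 markers");
  std::vector<double> lstay, lsw;
  fill_trans(pos, eps, scale, lstay, lsw);
  long total = 1;
  for (int i = 0; i < n; ++i) total *= N_STATE;
  std::vector<int> path(n), best_path(n);
  double best = R_NegInf;
  for (long code = 0; code < total; ++code) {
    long c = code;
    for (int i = 0; i < n; ++i) { path[i] = c % N_STATE; c /= N_STATE; }
    double ll = log_init[path[0]] + logem(0, path[0]);
    for (int i = 1; i < n; ++i)
      ll += (path[i] == path[i - 1] ? lstay[i] : lsw[i]) + logem(i, path[i]);
    if (ll > best) { best = ll; best_path = path; }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = best_path[i] + 1;
  return out;
}

// Decode every sample (column) of an LRR/BAF matrix pair over one
// chromosome and emit maximal non-CN2 runs.
// [[Rcpp::export]]
List segment_samples_cpp(NumericMatrix lrr, NumericMatrix baf,
                         NumericVector pos, NumericVector pfb,
                         NumericVector lrr_means, NumericVector lrr_sds,
                         double baf_sd, double outlier_w, double eps,
                         double scale, NumericVector log_init) {
  int n = lrr.nrow(), m = lrr.ncol();
  EmissionModel em(lrr_means, lrr_sds, baf_sd, outlier_w, pfb);
  std::vector<double> lstay, lsw;
  fill_trans(pos, eps, scale, lstay, lsw);
  std::vector<int> r_sample, r_start, r_end, r_state, r_nm;
  std::vector<double> r_mlrr;
  std::vector<double> logem(n * N_STATE);
  std::vector<int> path(n);
  for (int j = 0; j < m; ++j) {
    const double *lcol = &lrr(0, j), *bcol = &baf(0, j);
    for (int i = 0; i < n; ++i)
      em.marker(i, lcol[i], bcol[i], &logem[i * N_STATE]);
    viterbi_core(logem, n, lstay, lsw, log_init, path.data());
    int i = 0;
    while (i < n) {
      if (path[i] != CN2) {
        int st = i;
        while (i + 1 < n && path[i + 1] == path[st]) ++i;
        double s = 0.0;
        for (int k = st; k <= i; ++k) s += lcol[k];
        r_sample.push_back(j + 1);
        r_start.push_back(st + 1);
        r_end.push_back(i + 1);
        r_state.push_back(path[st] + 1);
        r_nm.push_back(i - st + 1);
        r_mlrr.push_back(s / (i - st + 1));
      }
      ++i;
    }
  }
  return List::create(_["sample_idx"] = wrap(r_sample),
                      _["start_idx"] = wrap(r_start),
                      _["end_idx"] = wrap(r_end),
                      _["state"] = wrap(r_state),
                      _["n_markers"] = wrap(r_nm),
                      _["mean_lrr"] = wrap(r_mlrr));
}
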