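#ifdef __SSE2__
#include <emmintrin.h>
#endif
// Dynamic-programming kernels for profile-HMM read search.
//
// Model contract (see build_phmm() on the R side): uni-hit local alignment
// with entry into any match state (prob 1/L) and exit from any match state
// (prob eps_k = 1/(L-k+1)); deletes may run to node L which exits with
// probability 1.  Scores are log2-odds against an i.i.d. background, over
// subpaths that emit at least one match residue (so null scores stay
// continuous); an empty sequence scores 0 (the null path) and a sequence
// with no positive-probability alignment scores -Inf.  The MSV filter is
// the same model restricted to match states only, with multi-segment
// re-entry at no cost.  Forward runs in scaled linear space (no per-cell
// log-sum-exp).

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct Profile {
  int L, K;
  // log2-odds, L x (K+1), column per residue code (code K = unknown, 0 bits)
  const double *mlo, *ilo;
  // transitions log2, L x 7: MM MI MD IM II DM DD (from node k = row k-1)
  const double *tlo;
  const double *entry_lo, *exit_lo;
  // linear-space mirrors for Forward
  const double *mpr, *ipr, *tpr, *entry_pr, *exit_pr;
};

static Profile unpack_profile(const List& prof) {
  Profile p;
  p.L = as<int>(prof["L"]);
  p.K = as<int>(prof["K"]);
  p.mlo = REAL(as<NumericMatrix>(prof["mlo"]));
  p.ilo = REAL(as<NumericMatrix>(prof["ilo"]));
  p.tlo = REAL(as<NumericMatrix>(prof["tlo"]));
  p.entry_lo = REAL(as<NumericVector>(prof["entry_lo"]));
  p.exit_lo = REAL(as<NumericVector>(prof["exit_lo"]));
  p.mpr = REAL(as<NumericMatrix>(prof["mpr"]));
  p.ipr = REAL(as<NumericMatrix>(prof["ipr"]));
  p.tpr = REAL(as<NumericMatrix>(prof["tpr"]));
  p.entry_pr = REAL(as<NumericVector>(prof["entry_pr"]));
  p.exit_pr = REAL(as<NumericVector>(prof["exit_pr"]));
  return p;
}

// residue encoding -------------------------------------------------------

static inline int dna_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': case 'U': case 'u': return 3;
    default: return 4;
  }
}

static int prot_code_tab[256];
static bool prot_tab_ready = false;
static void init_prot_tab() {
  const char* aa = "ACDEFGHIKLMNPQRSTVWY";
  for (int i = 0; i < 256; ++i) prot_code_tab[i] = 20;
  for (int i = 0; i < 20; ++i) {
    prot_code_tab[(unsigned char)aa[i]] = i;
    prot_code_tab[(unsigned char)std::tolower(aa[i])] = i;
  }
  prot_tab_ready = true;
}

static void encode_seq(const char* s, int n, int alphabet, std::vector<int>& out) {
  out.resize(n);
  if (alphabet == 0) {
    for (int i = 0; i < n; ++i) out[i] = dna_code(s[i]);
  } else {
    if (!prot_tab_ready) init_prot_tab();
    for (int i = 0; i < n; ++i) out[i] = prot_code_tab[(unsigned char)s[i]];
  }
}

static void revcomp_codes(const std::vector<int>& x, std::vector<int>& out) {
  int n = (int)x.size();
  out.resize(n);
  for (int i = 0; i < n; ++i) {
    int c = x[n - 1 - i];
    out[i] = (c < 4) ? 3 - c : 4;
  }
}

// [[Rcpp::export]]
IntegerVector cpp_encode(std::string seq, int alphabet) {
  std::vector<int> x;
  encode_seq(seq.c_str(), (int)seq.size(), alphabet, x);
  return wrap(x);
}

// MSV --------------------------------------------------------------------

static double msv_kernel(const int* x, int n, const Profile& p) {
  const int L = p.L;
  std::vector<double> rowA(L, NEG_INF), rowB(L, NEG_INF), exitbuf(L);
  const double* __restrict tMM = p.tlo;  // col 0
  const double* __restrict entry = p.entry_lo;
  const double* __restrict exitl = p.exit_lo;
  double* prev = rowA.data();
  double* cur = rowB.data();
  double* __restrict cb = exitbuf.data();
  double B = 0.0, best = NEG_INF;
  for (int i = 0; i < n; ++i) {
    const double* __restrict msc = p.mlo + (size_t)x[i] * L;
    const double* __restrict pv = prev;
    double* __restrict cr = cur;
    const double eB = entry[0] + B;  // entry is uniform over nodes
    cr[0] = msc[0] + eB;
    for (int k = 1; k < L; ++k) {
      double v = pv[k - 1] + tMM[k - 1];
      cr[k] = (eB > v ? eB : v) + msc[k];
    }
    for (int k = 0; k < L; ++k) cb[k] = cr[k] + exitl[k];
    double completed = cb[0];
    for (int k = 1; k < L; ++k) completed = (cb[k] > completed ? cb[k] : completed);
    if (completed > best) best = completed;
    if (completed > B) B = completed;
    std::swap(prev, cur);
  }
  return n == 0 ? 0.0 : best;
}

// single-precision MSV used as a pre-screen inside the cascade: scores
// within 0.5 bits of the stage threshold (or above it) are recomputed in
// double precision, so filter decisions are exact while the bulk scan
// vectorizes 4-wide
struct MsvFloat {
  int L;
  std::vector<float> mlo, tMM, exitl;
  float entry0;
  explicit MsvFloat(const Profile& p) : L(p.L), mlo((size_t)p.L * (p.K + 1)),
                                        tMM(p.L), exitl(p.L) {
    for (size_t i = 0; i < mlo.size(); ++i) {
      double v = p.mlo[i];
      mlo[i] = std::isfinite(v) ? (float)v : -1e30f;
    }
    for (int k = 0; k < L; ++k) {
      double v = p.tlo[k];
      tMM[k] = std::isfinite(v) ? (float)v : -1e30f;
      exitl[k] = (float)p.exit_lo[k];
    }
    entry0 = (float)p.entry_lo[0];
  }
};

static float msv_kernel_float(const int* x, int n, const MsvFloat& m) {
  const int L = m.L;
  std::vector<float> rowA(L, -1e30f), rowB(L, -1e30f);
  const float* __restrict tMM = m.tMM.data();
  const float* __restrict exitl = m.exitl.data();
  float* prev = rowA.data();
  float* cur = rowB.data();
  float B = 0.0f, best = -1e30f;
  for (int i = 0; i < n; ++i) {
    const float* __restrict msc = m.mlo.data() + (size_t)x[i] * L;
    const float* __restrict pv = prev;
    float* __restrict cr = cur;
    const float eB = m.entry0 + B;
    float completed;
    cr[0] = msc[0] + eB;
    {
      float c0 = cr[0] + exitl[0];
      completed = c0;
    }
    int k = 1;
#ifdef __SSE2__
    {
      __m128 eBv = _mm_set1_ps(eB);
      __m128 cmax = _mm_set1_ps(-1e30f);
      __m128 cmax2 = _mm_set1_ps(-1e30f);
      for (; k + 7 < L; k += 8) {
        __m128 v = _mm_add_ps(_mm_loadu_ps(pv + k - 1), _mm_loadu_ps(tMM + k - 1));
        __m128 w = _mm_add_ps(_mm_loadu_ps(pv + k + 3), _mm_loadu_ps(tMM + k + 3));
        v = _mm_max_ps(v, eBv);
        w = _mm_max_ps(w, eBv);
        v = _mm_add_ps(v, _mm_loadu_ps(msc + k));
        w = _mm_add_ps(w, _mm_loadu_ps(msc + k + 4));
        _mm_storeu_ps(cr + k, v);
        _mm_storeu_ps(cr + k + 4, w);
        cmax = _mm_max_ps(cmax, _mm_add_ps(v, _mm_loadu_ps(exitl + k)));
        cmax2 = _mm_max_ps(cmax2, _mm_add_ps(w, _mm_loadu_ps(exitl + k + 4)));
      }
      for (; k + 3 < L; k += 4) {
        __m128 v = _mm_add_ps(_mm_loadu_ps(pv + k - 1), _mm_loadu_ps(tMM + k - 1));
        v = _mm_max_ps(v, eBv);
        v = _mm_add_ps(v, _mm_loadu_ps(msc + k));
        _mm_storeu_ps(cr + k, v);
        cmax = _mm_max_ps(cmax, _mm_add_ps(v, _mm_loadu_ps(exitl + k)));
      }
      cmax = _mm_max_ps(cmax, cmax2);
      float tmp[4];
      _mm_storeu_ps(tmp, cmax);
      for (int j = 0; j < 4; ++j) if (tmp[j] > completed) completed = tmp[j];
    }
#endif
    for (; k < L; ++k) {
      float v = pv[k - 1] + tMM[k - 1];
      v = (eB > v ? eB : v) + msc[k];
      cr[k] = v;
      float c = v + exitl[k];
      if (c > completed) completed = c;
    }
    if (completed > best) best = completed;
    if (completed > B) B = completed;
    std::swap(prev, cur);
  }
  return n == 0 ? 0.0f : best;
}

// 16-bit quantized MSV screen (1/256-bit units, saturating SSE2
// arithmetic, 8 lanes).  Rounding error is bounded by ~0.5 unit per add,
// i.e. well under 1 bit over a read-length path, so any score within 1
// bit of the stage threshold is re-scored in float/double before a
// decision is made.
struct MsvInt16 {
  int L;
  std::vector<int16_t> mlo, tMM, exitl;
  int16_t entry0;
  static int16_t q(double bits) {
    double v = bits * 256.0;
    if (!std::isfinite(v) || v < -32768.0) return -32768;
    if (v > 32767.0) return 32767;
    return (int16_t)std::lround(v);
  }
  explicit MsvInt16(const Profile& p) : L(p.L), mlo((size_t)p.L * (p.K + 1)),
                                        tMM(p.L), exitl(p.L) {
    for (size_t i = 0; i < mlo.size(); ++i) mlo[i] = q(p.mlo[i]);
    for (int k = 0; k < L; ++k) {
      tMM[k] = q(p.tlo[k]);
      exitl[k] = q(p.exit_lo[k]);
    }
    entry0 = q(p.entry_lo[0]);
  }
};

#ifdef __SSE2__
static double msv_kernel_int16(const int* x, int n, const MsvInt16& m) {
  const int L = m.L;
  std::vector<int16_t> rowA(L, -32768), rowB(L, -32768);
  const int16_t* __restrict tMM = m.tMM.data();
  const int16_t* __restrict exitl = m.exitl.data();
  int16_t* prev = rowA.data();
  int16_t* cur = rowB.data();
  int B = 0, best = -32768;
  for (int i = 0; i < n; ++i) {
    const int16_t* __restrict msc = m.mlo.data() + (size_t)x[i] * L;
    const int16_t* __restrict pv = prev;
    int16_t* __restrict cr = cur;
    int eBi = m.entry0 + B;
    if (eBi > 32767) eBi = 32767;
    if (eBi < -32768) eBi = -32768;
    const int16_t eB = (int16_t)eBi;
    int completed;
    {
      int c0 = (int)msc[0] + eBi;
      if (c0 > 32767) c0 = 32767;
      cr[0] = (int16_t)c0;
      completed = cr[0] + exitl[0];
    }
    int k = 1;
    {
      __m128i eBv = _mm_set1_epi16(eB);
      __m128i cmax = _mm_set1_epi16(-32768);
      for (; k + 7 < L; k += 8) {
        __m128i v = _mm_adds_epi16(_mm_loadu_si128((const __m128i*)(pv + k - 1)),
                                   _mm_loadu_si128((const __m128i*)(tMM + k - 1)));
        v = _mm_max_epi16(v, eBv);
        v = _mm_adds_epi16(v, _mm_loadu_si128((const __m128i*)(msc + k)));
        _mm_storeu_si128((__m128i*)(cr + k), v);
        cmax = _mm_max_epi16(cmax,
            _mm_adds_epi16(v, _mm_loadu_si128((const __m128i*)(exitl + k))));
      }
      int16_t tmp[8];
      _mm_storeu_si128((__m128i*)tmp, cmax);
      for (int j = 0; j < 8; ++j) if (tmp[j] > completed) completed = tmp[j];
    }
    for (; k < L; ++k) {
      int v = (int)pv[k - 1] + tMM[k - 1];
      if (eB > v) v = eB;
      v += msc[k];
      if (v > 32767) v = 32767;
      if (v < -32768) v = -32768;
      cr[k] = (int16_t)v;
      int c = v + exitl[k];
      if (c > completed) completed = c;
    }
    if (completed > best) best = completed;
    if (completed > B) B = completed;
    if (B > 32767) B = 32767;
    std::swap(prev, cur);
  }
  return n == 0 ? 0.0 : best / 256.0;
}
#endif

// single-precision mirrors of the Viterbi and Forward kernels, used for
// cascade decisions away from the stage thresholds (double recheck
// within +-0.5 bits keeps decisions exact)
struct ProfFloat {
  int L, K;
  std::vector<float> mlo, ilo, tlo;        // log2
  std::vector<float> mpr, ipr, tpr;        // linear
  std::vector<float> entry_pr, exit_pr, exit_lo;
  float entry0;
  explicit ProfFloat(const Profile& p) : L(p.L), K(p.K) {
    size_t ne = (size_t)p.L * (p.K + 1), nt = (size_t)p.L * 7;
    auto cvt = [](double v) {
      return std::isfinite(v) ? (float)v : -1e30f;
    };
    mlo.resize(ne); ilo.resize(ne); tlo.resize(nt);
    mpr.resize(ne); ipr.resize(ne); tpr.resize(nt);
    entry_pr.resize(p.L); exit_pr.resize(p.L); exit_lo.resize(p.L);
    for (size_t i = 0; i < ne; ++i) { mlo[i] = cvt(p.mlo[i]); ilo[i] = cvt(p.ilo[i]); }
    for (size_t i = 0; i < nt; ++i) { tlo[i] = cvt(p.tlo[i]); tpr[i] = (float)p.tpr[i]; }
    for (size_t i = 0; i < ne; ++i) { mpr[i] = (float)p.mpr[i]; ipr[i] = (float)p.ipr[i]; }
    for (int k = 0; k < p.L; ++k) {
      entry_pr[k] = (float)p.entry_pr[k];
      exit_pr[k] = (float)p.exit_pr[k];
      exit_lo[k] = (float)p.exit_lo[k];
    }
    entry0 = (float)p.entry_lo[0];
  }
};

static float vit_kernel_float(const int* x, int n, const ProfFloat& p) {
  const int L = p.L;
  const float *tMM = p.tlo.data(), *tMI = tMM + L, *tMD = tMM + 2 * (size_t)L,
              *tIM = tMM + 3 * (size_t)L, *tII = tMM + 4 * (size_t)L,
              *tDM = tMM + 5 * (size_t)L, *tDD = tMM + 6 * (size_t)L;
  std::vector<float> pM(L, -1e30f), pI(L, -1e30f), pD(L, -1e30f);
  std::vector<float> cM(L), cI(L), cD(L);
  const float eB = p.entry0;
  float best = -1e30f;
  for (int i = 0; i < n; ++i) {
    const float* __restrict msc = p.mlo.data() + (size_t)x[i] * L;
    const float* __restrict isc = p.ilo.data() + (size_t)x[i] * L;
    const float* __restrict exl = p.exit_lo.data();
    float* __restrict cm = cM.data();
    float* __restrict ci = cI.data();
    const float* __restrict pm = pM.data();
    const float* __restrict pi = pI.data();
    const float* __restrict pd = pD.data();
    cm[0] = eB + msc[0];
    ci[0] = std::max(pm[0] + tMI[0], pi[0] + tII[0]) + isc[0];
    int k = 1;
#ifdef __SSE2__
    {
      __m128 eBv = _mm_set1_ps(eB);
      for (; k + 3 < L; k += 4) {
        __m128 v = _mm_add_ps(_mm_loadu_ps(pm + k - 1), _mm_loadu_ps(tMM + k - 1));
        v = _mm_max_ps(v, _mm_add_ps(_mm_loadu_ps(pi + k - 1),
                                     _mm_loadu_ps(tIM + k - 1)));
        v = _mm_max_ps(v, _mm_add_ps(_mm_loadu_ps(pd + k - 1),
                                     _mm_loadu_ps(tDM + k - 1)));
        v = _mm_max_ps(v, eBv);
        _mm_storeu_ps(cm + k, _mm_add_ps(v, _mm_loadu_ps(msc + k)));
        __m128 w = _mm_max_ps(
            _mm_add_ps(_mm_loadu_ps(pm + k), _mm_loadu_ps(tMI + k)),
            _mm_add_ps(_mm_loadu_ps(pi + k), _mm_loadu_ps(tII + k)));
        _mm_storeu_ps(ci + k, _mm_add_ps(w, _mm_loadu_ps(isc + k)));
      }
    }
#endif
    for (; k < L; ++k) {
      float v = eB;
      float a = pm[k - 1] + tMM[k - 1];
      if (a > v) v = a;
      a = pi[k - 1] + tIM[k - 1];
      if (a > v) v = a;
      a = pd[k - 1] + tDM[k - 1];
      if (a > v) v = a;
      cm[k] = v + msc[k];
      ci[k] = std::max(pm[k] + tMI[k], pi[k] + tII[k]) + isc[k];
    }
    float* __restrict cd = cD.data();
    cd[0] = -1e30f;
    for (int j = 1; j < L; ++j) {
      cd[j] = std::max(cm[j - 1] + tMD[j - 1], cd[j - 1] + tDD[j - 1]);
    }
    float completed = cd[L - 1];
    for (int j = 0; j < L; ++j) {
      float c = cm[j] + exl[j];
      if (c > completed) completed = c;
    }
    if (completed > best) best = completed;
    pM.swap(cM); pI.swap(cI); pD.swap(cD);
  }
  return n == 0 ? 0.0f : best;
}

static float fwd_kernel_float(const int* x, int n, const ProfFloat& p) {
  const int L = p.L;
  const float *tMM = p.tpr.data(), *tMI = tMM + L, *tMD = tMM + 2 * (size_t)L,
              *tIM = tMM + 3 * (size_t)L, *tII = tMM + 4 * (size_t)L,
              *tDM = tMM + 5 * (size_t)L, *tDD = tMM + 6 * (size_t)L;
  std::vector<float> pM(L, 0.0f), pI(L, 0.0f), pD(L, 0.0f);
  std::vector<float> cM(L), cI(L), cD(L);
  double tot_log2 = -std::numeric_limits<double>::infinity();
  double cum = 0.0;     // log2 scale
  bool any = false;
  for (int i = 0; i < n; ++i) {
    const float* __restrict mod = p.mpr.data() + (size_t)x[i] * L;
    const float* __restrict iod = p.ipr.data() + (size_t)x[i] * L;
    const float* __restrict epr = p.entry_pr.data();
    const float* __restrict xpr = p.exit_pr.data();
    float* __restrict cm = cM.data();
    float* __restrict ci = cI.data();
    const float* __restrict pm = pM.data();
    const float* __restrict pi = pI.data();
    const float* __restrict pd = pD.data();
    cm[0] = mod[0] * epr[0];
    ci[0] = iod[0] * (pm[0] * tMI[0] + pi[0] * tII[0]);
    int k = 1;
#ifdef __SSE2__
    for (; k + 3 < L; k += 4) {
      __m128 acc = _mm_loadu_ps(epr + k);
      acc = _mm_add_ps(acc, _mm_mul_ps(_mm_loadu_ps(pm + k - 1),
                                       _mm_loadu_ps(tMM + k - 1)));
      acc = _mm_add_ps(acc, _mm_mul_ps(_mm_loadu_ps(pi + k - 1),
                                       _mm_loadu_ps(tIM + k - 1)));
      acc = _mm_add_ps(acc, _mm_mul_ps(_mm_loadu_ps(pd + k - 1),
                                       _mm_loadu_ps(tDM + k - 1)));
      _mm_storeu_ps(cm + k, _mm_mul_ps(acc, _mm_loadu_ps(mod + k)));
      __m128 ai = _mm_add_ps(_mm_mul_ps(_mm_loadu_ps(pm + k), _mm_loadu_ps(tMI + k)),
                             _mm_mul_ps(_mm_loadu_ps(pi + k), _mm_loadu_ps(tII + k)));
      _mm_storeu_ps(ci + k, _mm_mul_ps(ai, _mm_loadu_ps(iod + k)));
    }
#endif
    for (; k < L; ++k) {
      cm[k] = mod[k] * (epr[k] + pm[k - 1] * tMM[k - 1] +
                        pi[k - 1] * tIM[k - 1] + pd[k - 1] * tDM[k - 1]);
      ci[k] = iod[k] * (pm[k] * tMI[k] + pi[k] * tII[k]);
    }
    float* __restrict cd = cD.data();
    cd[0] = 0.0f;
    for (int j = 1; j < L; ++j) {
      cd[j] = cm[j - 1] * tMD[j - 1] + cd[j - 1] * tDD[j - 1];
    }
    float completed = cd[L - 1];
    float mx = 0.0f;
    for (int j = 0; j < L; ++j) {
      completed += cm[j] * xpr[j];
      float v = cm[j];
      if (ci[j] > v) v = ci[j];
      if (cd[j] > v) v = cd[j];
      if (v > mx) mx = v;
    }
    if (completed > 0.0f) {
      double v = std::log2((double)completed) + cum;
      if (!any) tot_log2 = v;
      else if (v > tot_log2) tot_log2 = v + std::log2(1.0 + std::exp2(tot_log2 - v));
      else tot_log2 = tot_log2 + std::log2(1.0 + std::exp2(v - tot_log2));
      any = true;
    }
    if (mx > 1e30f) {
      float inv = 1.0f / mx;
      for (int j = 0; j < L; ++j) { cm[j] *= inv; ci[j] *= inv; cd[j] *= inv; }
      cum += std::log2((double)mx);
    }
    pM.swap(cM); pI.swap(cI); pD.swap(cD);
  }
  if (n == 0) return 0.0f;
  if (!any) return -1e30f;
  return (float)tot_log2;
}

// Viterbi ----------------------------------------------------------------

static double vit_kernel(const int* x, int n, const Profile& p) {
  const int L = p.L;
  const double *tMM = p.tlo, *tMI = p.tlo + L, *tMD = p.tlo + 2 * (size_t)L,
               *tIM = p.tlo + 3 * (size_t)L, *tII = p.tlo + 4 * (size_t)L,
               *tDM = p.tlo + 5 * (size_t)L, *tDD = p.tlo + 6 * (size_t)L;
  std::vector<double> pM(L, NEG_INF), pI(L, NEG_INF), pD(L, NEG_INF);
  std::vector<double> cM(L), cI(L), cD(L);
  double best = NEG_INF;
  for (int i = 0; i < n; ++i) {
    const double* msc = p.mlo + (size_t)x[i] * L;
    const double* isc = p.ilo + (size_t)x[i] * L;
    for (int k = 0; k < L; ++k) {
      double v = p.entry_lo[k];
      if (k > 0) {
        double a = pM[k - 1] + tMM[k - 1];
        if (a > v) v = a;
        a = pI[k - 1] + tIM[k - 1];
        if (a > v) v = a;
        a = pD[k - 1] + tDM[k - 1];
        if (a > v) v = a;
      }
      cM[k] = v + msc[k];
      double w = pM[k] + tMI[k];
      double w2 = pI[k] + tII[k];
      cI[k] = (w > w2 ? w : w2) + isc[k];
    }
    cD[0] = NEG_INF;
    for (int k = 1; k < L; ++k) {
      double a = cM[k - 1] + tMD[k - 1];
      double b = cD[k - 1] + tDD[k - 1];
      cD[k] = a > b ? a : b;
    }
    double completed = cD[L - 1];  // delete-through to node L, exit prob 1
    for (int k = 0; k < L; ++k) {
      double c = cM[k] + p.exit_lo[k];
      if (c > completed) completed = c;
    }
    if (completed > best) best = completed;
    pM.swap(cM); pI.swap(cI); pD.swap(cD);
  }
  return n == 0 ? 0.0 : best;
}

// Viterbi with traceback: returns best path as (seq_pos, node) pairs for
// match states only (what column projection needs), plus the score.
// [[Rcpp::export]]
List cpp_viterbi_path(std::string seq, List prof, int alphabet) {
  Profile p = unpack_profile(prof);
  const int L = p.L;
  std::vector<int> x;
  encode_seq(seq.c_str(), (int)seq.size(), alphabet, x);
  int n = (int)x.size();
  const double *tMM = p.tlo, *tMI = p.tlo + L, *tMD = p.tlo + 2 * (size_t)L,
               *tIM = p.tlo + 3 * (size_t)L, *tII = p.tlo + 4 * (size_t)L,
               *tDM = p.tlo + 5 * (size_t)L, *tDD = p.tlo + 6 * (size_t)L;
  // full DP matrices with backpointers (reads are short; memory is fine)
  std::vector<double> M((size_t)n * L, NEG_INF), I((size_t)n * L, NEG_INF),
      D((size_t)n * L, NEG_INF);
  std::vector<signed char> bM((size_t)n * L), bI((size_t)n * L), bD((size_t)n * L);
  double best = NEG_INF;
  int bi = -1, bk = -1, bstate = -1;  // 0=M exit, 2=D_L exit
  for (int i = 0; i < n; ++i) {
    const double* msc = p.mlo + (size_t)x[i] * L;
    const double* isc = p.ilo + (size_t)x[i] * L;
    size_t r = (size_t)i * L, rp = (size_t)(i - 1) * L;
    for (int k = 0; k < L; ++k) {
      double v = p.entry_lo[k];
      signed char ptr = 0;  // 0 entry, 1 MM, 2 IM, 3 DM
      if (i > 0 && k > 0) {
        double a = M[rp + k - 1] + tMM[k - 1];
        if (a > v) { v = a; ptr = 1; }
        a = I[rp + k - 1] + tIM[k - 1];
        if (a > v) { v = a; ptr = 2; }
        a = D[rp + k - 1] + tDM[k - 1];
        if (a > v) { v = a; ptr = 3; }
      }
      M[r + k] = v + msc[k];
      bM[r + k] = ptr;
      if (i > 0) {
        double w = M[rp + k] + tMI[k], w2 = I[rp + k] + tII[k];
        if (w >= w2) { I[r + k] = w + isc[k]; bI[r + k] = 0; }
        else { I[r + k] = w2 + isc[k]; bI[r + k] = 1; }
      }
    }
    for (int k = 1; k < L; ++k) {
      double a = M[r + k - 1] + tMD[k - 1], b = D[r + k - 1] + tDD[k - 1];
      if (a >= b) { D[r + k] = a; bD[r + k] = 0; }
      else { D[r + k] = b; bD[r + k] = 1; }
    }
    for (int k = 0; k < L; ++k) {
      double c = M[r + k] + p.exit_lo[k];
      if (c > best) { best = c; bi = i; bk = k; bstate = 0; }
    }
    if (D[r + L - 1] > best) { best = D[r + L - 1]; bi = i; bk = L - 1; bstate = 2; }
  }
  std::vector<int> pos, node;
  if (bi >= 0) {
    int i = bi, k = bk, st = bstate;
    while (true) {
      size_t r = (size_t)i * L;
      if (st == 0) {  // match
        pos.push_back(i + 1); node.push_back(k + 1);
        signed char ptr = bM[r + k];
        if (ptr == 0) break;
        st = (ptr == 1) ? 0 : (ptr == 2 ? 1 : 2);
        --i; --k;
      } else if (st == 1) {  // insert (emits, no column)
        st = bI[r + k] == 0 ? 0 : 1;
        --i;
      } else {  // delete (silent)
        st = bD[r + k] == 0 ? 0 : 2;
        --k;
      }
    }
    std::reverse(pos.begin(), pos.end());
    std::reverse(node.begin(), node.end());
  }
  double bits = (n == 0) ? 0.0 : best;
  return List::create(_["bits"] = bits, _["pos"] = wrap(pos), _["node"] = wrap(node));
}

// Forward ----------------------------------------------------------------

static double fwd_kernel(const int* x, int n, const Profile& p) {
  const int L = p.L;
  const double *tMM = p.tpr, *tMI = p.tpr + L, *tMD = p.tpr + 2 * (size_t)L,
               *tIM = p.tpr + 3 * (size_t)L, *tII = p.tpr + 4 * (size_t)L,
               *tDM = p.tpr + 5 * (size_t)L, *tDD = p.tpr + 6 * (size_t)L;
  std::vector<double> pM(L, 0.0), pI(L, 0.0), pD(L, 0.0);
  std::vector<double> cM(L), cI(L), cD(L);
  std::vector<double> comp_log2;  // per-row completed mass, log2 with scaling
  comp_log2.reserve(n);
  double cum = 0.0;  // accumulated log2 scale
  for (int i = 0; i < n; ++i) {
    const double* mod = p.mpr + (size_t)x[i] * L;
    const double* iod = p.ipr + (size_t)x[i] * L;
    cM[0] = mod[0] * p.entry_pr[0];
    for (int k = 1; k < L; ++k) {
      cM[k] = mod[k] * (p.entry_pr[k] + pM[k - 1] * tMM[k - 1] +
                        pI[k - 1] * tIM[k - 1] + pD[k - 1] * tDM[k - 1]);
    }
    for (int k = 0; k < L; ++k)
      cI[k] = iod[k] * (pM[k] * tMI[k] + pI[k] * tII[k]);
    cD[0] = 0.0;
    for (int k = 1; k < L; ++k)
      cD[k] = cM[k - 1] * tMD[k - 1] + cD[k - 1] * tDD[k - 1];
    double completed = cD[L - 1];
    for (int k = 0; k < L; ++k) completed += cM[k] * p.exit_pr[k];
    if (completed > 0.0) comp_log2.push_back(std::log2(completed) + cum);
    double mx = 0.0;
    for (int k = 0; k < L; ++k) {
      if (cM[k] > mx) mx = cM[k];
      if (cI[k] > mx) mx = cI[k];
      if (cD[k] > mx) mx = cD[k];
    }
    if (mx > 1e100) {
      double inv = 1.0 / mx;
      for (int k = 0; k < L; ++k) { cM[k] *= inv; cI[k] *= inv; cD[k] *= inv; }
      cum += std::log2(mx);
    }
    pM.swap(cM); pI.swap(cI); pD.swap(cD);
  }
  if (n == 0) return 0.0;                    // null path
  if (comp_log2.empty()) return NEG_INF;     // no viable alignment
  double mx = NEG_INF;
  for (double v : comp_log2) if (v > mx) mx = v;
  double s = 0.0;
  for (double v : comp_log2) s += std::exp2(v - mx);
  return mx + std::log2(s);
}

// single-sequence scoring entry points (unit tests, calibration) ---------

// [[Rcpp::export]]
double cpp_score_seq(std::string seq, List prof, int alphabet, std::string what) {
  Profile p = unpack_profile(prof);
  std::vector<int> x;
  encode_seq(seq.c_str(), (int)seq.size(), alphabet, x);
  if (what == "msv") return msv_kernel(x.data(), (int)x.size(), p);
  if (what == "viterbi") return vit_kernel(x.data(), (int)x.size(), p);
  if (what == "forward") return fwd_kernel(x.data(), (int)x.size(), p);
  stop("unknown score type");
}

// staged cascade over many reads -----------------------------------------

// thresholds: raw-score cutoffs for msv, viterbi, forward (-Inf = always
// pass, i.e. compute everything).  Returns per read the better strand's
// scores and the last stage passed (0 none, 1 msv, 2 vit, 3 fwd).
// [[Rcpp::export]]
NumericMatrix cpp_cascade_search(CharacterVector seqs, List prof, int alphabet,
                                 double t_msv, double t_vit, double t_fwd,
                                 bool both_strands) {
  Profile p = unpack_profile(prof);
  // fast path: float kernels decide each stage, falling back to the exact
  // double kernel within +-0.5 bits of the stage threshold; with
  // non-finite thresholds (scoring mode) everything is computed in double
  bool screen = std::isfinite(t_msv) && std::isfinite(t_vit) &&
                std::isfinite(t_fwd);
  MsvFloat mf(p);
  ProfFloat pf(p);
#ifdef __SSE2__
  MsvInt16 mi(p);
#endif
  const double margin = 0.5;
  int n = seqs.size();
  NumericMatrix out(n, 5);
  colnames(out) = CharacterVector::create("strand", "msv", "vit", "fwd", "stage");
  std::vector<int> fw, rv;
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    encode_seq(s, (int)std::strlen(s), alphabet, fw);
    double sc[2][3] = {{NA_REAL, NA_REAL, NA_REAL}, {NA_REAL, NA_REAL, NA_REAL}};
    int stage[2] = {0, 0};
    int nstr = both_strands ? 2 : 1;
    for (int str = 0; str < nstr; ++str) {
      const std::vector<int>* xp = &fw;
      if (str == 1) { revcomp_codes(fw, rv); xp = &rv; }
      const int* x = xp->data();
      int m = (int)xp->size();
      double v;
      if (screen) {
#ifdef __SSE2__
        v = msv_kernel_int16(x, m, mi);
        if (v >= t_msv - 1.0) {  // quantized screen: rescore near/above
          v = (double)msv_kernel_float(x, m, mf);
          if (std::fabs(v - t_msv) < margin) v = msv_kernel(x, m, p);
        }
#else
        v = (double)msv_kernel_float(x, m, mf);
        if (std::fabs(v - t_msv) < margin) v = msv_kernel(x, m, p);
#endif
      } else {
        v = msv_kernel(x, m, p);
      }
      sc[str][0] = v;
      if (v < t_msv) continue;
      stage[str] = 1;
      if (screen) {
        v = (double)vit_kernel_float(x, m, pf);
        if (std::fabs(v - t_vit) < margin) v = vit_kernel(x, m, p);
      } else {
        v = vit_kernel(x, m, p);
      }
      sc[str][1] = v;
      if (v < t_vit) continue;
      stage[str] = 2;
      if (screen) {
        v = (double)fwd_kernel_float(x, m, pf);
        if (std::fabs(v - t_fwd) < margin) v = fwd_kernel(x, m, p);
      } else {
        v = fwd_kernel(x, m, p);
      }
      sc[str][2] = v;
      if (v < t_fwd) continue;
      stage[str] = 3;
    }
    int bs = 0;
    if (nstr == 2) {
      if (stage[1] > stage[0]) bs = 1;
      else if (stage[1] == stage[0]) {
        int st = stage[0];
        int col = st >= 3 ? 2 : (st >= 2 ? 1 : 0);
        double a = ISNAN(sc[0][col]) ? NEG_INF : sc[0][col];
        double b = ISNAN(sc[1][col]) ? NEG_INF : sc[1][col];
        if (b > a) bs = 1;
      }
    }
    out(i, 0) = bs == 0 ? 1.0 : -1.0;
    out(i, 1) = sc[bs][0];
    out(i, 2) = sc[bs][1];
    out(i, 3) = sc[bs][2];
    out(i, 4) = stage[bs];
  }
  return out;
}
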