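// Dynamic-programming alignment of ordered restriction maps.
//
// Scoring: per matched block, matchBonus - (x - y)^2 / (2 * varPerBp *
// max(x, sizingFloor)) - cutPenalty * interiorSites, where x is the
// reference-side and y the query-side block length (bp).  Blocks touching a
// physically broken end (molecule shear, contig boundary) pay no sizing
// penalty when the broken side is the shorter one.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double block_score(double x, double y, int interior,
                                 double matchBonus, double cutPenalty,
                                 double varPerBp, double sizingFloor,
                                 bool freeShort) {
  double s = matchBonus - cutPenalty * interior;
  if (!freeShort) {
    double v = varPerBp * std::max(x, sizingFloor);
    double d = x - y;
    s -= d * d / (2.0 * v);
  }
  return s;
}

// Fitting alignment: the whole query interior is consumed; query end
// fragments may match partially; query fragments overhanging a reference
// end are clipped without penalty (which is how consensus contigs extend).
// [[Rcpp::export]]
List cpp_fit_align(NumericVector q, NumericVector r, int delta,
                   double matchBonus, double cutPenalty, double varPerBp,
                   double sizingFloor) {
  const int m = q.size(), n = r.size();
  const double NEG = -1e30;
  std::vector<double> Q(m + 1, 0.0), R(n + 1, 0.0);
  for (int i = 0; i < m; ++i) Q[i + 1] = Q[i] + q[i];
  for (int j = 0; j < n; ++j) R[j + 1] = R[j] + r[j];

  std::vector<double> S((size_t)(m + 1) * (n + 1), NEG);
  std::vector<signed char> bq((size_t)(m + 1) * (n + 1), 0),
                           br((size_t)(m + 1) * (n + 1), 0);
  const size_t W = n + 1;

  // per-b reference block lengths / variance factors, refreshed per j
  std::vector<double> xb(delta + 1), inv2v(delta + 1);
  std::vector<double> ya(delta + 1), base(2 * delta + 1);
  for (int t = 0; t <= 2 * delta; ++t)
    base[t] = matchBonus - cutPenalty * t;

  for (int i = 1; i <= m; ++i) {
    const int amax = std::min(delta, i);
    const bool qend = (i == m);
    for (int a = 1; a <= amax; ++a) ya[a] = Q[i] - Q[i - a];
    double *Si = &S[(size_t)i * W];
    signed char *bqi = &bq[(size_t)i * W], *bri = &br[(size_t)i * W];
    for (int j = 1; j <= n; ++j) {
      const int bmax = std::min(delta, j);
      const bool rend = (j == n);
      const bool special = (i <= delta) || (j <= delta) || qend || rend;
      for (int b = 1; b <= bmax; ++b) {
        double x = R[j] - R[j - b];
        xb[b] = x;
        inv2v[b] = 0.5 / (varPerBp * std::max(x, sizingFloor));
      }
      double best = NEG; int bqa = 0, bra = 0;
      if (!special) {
        // hot path: interior cell, extension only, full sizing penalty
        for (int a = 1; a <= amax; ++a) {
          const double y = ya[a];
          const double *Sp = &S[(size_t)(i - a) * W + j];
          for (int b = 1; b <= bmax; ++b) {
            const double prev = Sp[-b];
            if (prev <= NEG / 2) continue;
            const double d = xb[b] - y;
            const double cand = prev + base[a + b - 2] - d * d * inv2v[b];
            if (cand > best + 1e-12) { best = cand; bqa = a; bra = b; }
          }
        }
      } else {
        for (int a = 1; a <= amax; ++a) {
          const double y = ya[a];
          const bool qstart1 = (i - a == 0);
          for (int b = 1; b <= bmax; ++b) {
            const double x = xb[b];
            const int interior = a + b - 2;
            const bool rstart1 = (j - b == 0);
            double init = NEG;
            // freedom only when the longer side is short (<= 2 fragments):
            // a sheared molecule end lies within one reference fragment
            // (two when a site was missed), never across a long run
            if (qstart1 || rstart1) {
              bool freeL = (qstart1 && y < x && b <= 2) ||
                           (rstart1 && x < y && a <= 2);
              bool freeR = (qend && y < x && b <= 2) ||
                           (rend && x < y && a <= 2);
              init = block_score(x, y, interior, matchBonus, cutPenalty,
                                 varPerBp, sizingFloor, freeL || freeR);
            }
            double ext = NEG;
            if (i - a >= 1 && j - b >= 1) {
              double prev = S[(size_t)(i - a) * W + (j - b)];
              if (prev > NEG / 2) {
                bool freeR = (qend && y < x && b <= 2) ||
                             (rend && x < y && a <= 2);
                ext = prev + block_score(x, y, interior, matchBonus,
                                         cutPenalty, varPerBp, sizingFloor,
                                         freeR);
              }
            }
            double cand = std::max(init, ext);
            if (cand > best + 1e-12) {
              best = cand;
              if (init >= ext) { bqa = -a; bra = b; }
              else             { bqa = a;  bra = b; }
            }
          }
        }
      }
      Si[j] = best; bqi[j] = (signed char)bqa; bri[j] = (signed char)bra;
    }
  }

  // final cell: either query fully consumed (i == m, any j), or query tail
  // clipped past the reference end (j == n, i < m)
  double best = NEG; int bi = -1, bj = -1;
  for (int j = 1; j <= n; ++j)
    if (S[(size_t)m * W + j] > best + 1e-12) {
      best = S[(size_t)m * W + j]; bi = m; bj = j;
    }
  for (int i = 1; i < m; ++i)
    if (S[(size_t)i * W + n] > best + 1e-12) {
      best = S[(size_t)i * W + n]; bi = i; bj = n;
    }
  if (bi < 0 || best <= NEG / 2)
    return List::create(_["score"] = R_NegInf);

  std::vector<int> qs, qe, rs, re;
  int i = bi, j = bj;
  while (true) {
    int a = bq[(size_t)i * W + j], b = br[(size_t)i * W + j];
    bool start = a < 0;
    if (start) a = -a;
    qs.push_back(i - a + 1); qe.push_back(i);
    rs.push_back(j - b + 1); re.push_back(j);
    if (start) break;
    i -= a; j -= b;
    if (i < 1 || j < 1) break;
  }
  int nb = qs.size();
  IntegerMatrix blocks(nb, 4);
  for (int k = 0; k < nb; ++k) {
    blocks(k, 0) = qs[nb - 1 - k]; blocks(k, 1) = qe[nb - 1 - k];
    blocks(k, 2) = rs[nb - 1 - k]; blocks(k, 3) = re[nb - 1 - k];
  }
  return List::create(_["score"] = best, _["blocks"] = blocks);
}

// Best local alignment between maps a (reference side) and b (query side)
// honouring mask vectors (masked fragments cannot be in any block).
// [[Rcpp::export]]
List cpp_local_align(NumericVector a, NumericVector b,
                     LogicalVector maskA, LogicalVector maskB, int delta,
                     double matchBonus, double cutPenalty, double varPerBp,
                     double sizingFloor) {
  const int m = a.size(), n = b.size();
  const double NEG = -1e30;
  std::vector<double> A(m + 1, 0.0), B(n + 1, 0.0);
  for (int i = 0; i < m; ++i) A[i + 1] = A[i] + a[i];
  for (int j = 0; j < n; ++j) B[j + 1] = B[j] + b[j];
  std::vector<int> runA(m + 1, 0), runB(n + 1, 0);
  for (int i = 1; i <= m; ++i) runA[i] = maskA[i - 1] ? 0 : runA[i - 1] + 1;
  for (int j = 1; j <= n; ++j) runB[j] = maskB[j - 1] ? 0 : runB[j - 1] + 1;

  std::vector<double> S((size_t)(m + 1) * (n + 1), NEG);
  std::vector<signed char> bqv((size_t)(m + 1) * (n + 1), 0),
                           brv((size_t)(m + 1) * (n + 1), 0);
  const size_t W = n + 1;

  double gbest = NEG; int gi = -1, gj = -1;
  for (int i = 1; i <= m; ++i) {
    int amax = std::min(delta, std::min(i, runA[i]));
    if (amax == 0) continue;
    const bool aend = (i == m);
    double *Si = &S[(size_t)i * W];
    signed char *bqi = &bqv[(size_t)i * W], *bri = &brv[(size_t)i * W];
    for (int j = 1; j <= n; ++j) {
      int bmax = std::min(delta, std::min(j, runB[j]));
      if (bmax == 0) continue;
      const bool bend = (j == n);
      double best = NEG; int bqa = 0, bra = 0;
      for (int p = 1; p <= amax; ++p) {
        double x = A[i] - A[i - p];
        for (int qn = 1; qn <= bmax; ++qn) {
          double y = B[j] - B[j - qn];
          int interior = (p - 1) + (qn - 1);
          bool astart = (i - p == 0), bstart = (j - qn == 0);
          bool freeR = (bend && y < x && p <= 2) ||
                       (aend && x < y && qn <= 2);
          bool freeL = (bstart && y < x && p <= 2) ||
                       (astart && x < y && qn <= 2);
          double cand = block_score(x, y, interior, matchBonus, cutPenalty,
                                    varPerBp, sizingFloor, freeL || freeR);
          int ca = -p, cb = qn;
          if (i - p >= 1 && j - qn >= 1) {
            double prev = S[(size_t)(i - p) * W + (j - qn)];
            if (prev > 0) {
              double ext = prev + block_score(x, y, interior, matchBonus,
                                              cutPenalty, varPerBp,
                                              sizingFloor, freeR);
              if (ext > cand + 1e-12) { cand = ext; ca = p; cb = qn; }
            }
          }
          if (cand > best + 1e-12) { best = cand; bqa = ca; bra = cb; }
        }
      }
      Si[j] = best; bqi[j] = (signed char)bqa; bri[j] = (signed char)bra;
      if (best > gbest + 1e-12) { gbest = best; gi = i; gj = j; }
    }
  }
  if (gi < 0 || gbest <= NEG / 2)
    return List::create(_["score"] = R_NegInf);

  std::vector<int> as_, ae_, bs_, be_;
  int i = gi, j = gj;
  while (true) {
    int p = bqv[(size_t)i * W + j], qn = brv[(size_t)i * W + j];
    bool start = p < 0;
    if (start) p = -p;
    as_.push_back(i - p + 1); ae_.push_back(i);
    bs_.push_back(j - qn + 1); be_.push_back(j);
    if (start) break;
    i -= p; j -= qn;
    if (i < 1 || j < 1) break;
  }
  int nb = as_.size();
  IntegerMatrix blocks(nb, 4);
  for (int k = 0; k < nb; ++k) {
    blocks(k, 0) = as_[nb - 1 - k]; blocks(k, 1) = ae_[nb - 1 - k];
    blocks(k, 2) = bs_[nb - 1 - k]; blocks(k, 3) = be_[nb - 1 - k];
  }
  return List::create(_["score"] = gbest, _["blocks"] = blocks);
}
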