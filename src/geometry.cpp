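#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <functional>
using namespace Rcpp;

// Minimum-image displacement component along one axis.
static inline double mic(double d, double L, bool periodic) {
  if (periodic) d -= L * std::round(d / L);
  return d;
}

static inline double pair_dist2(const double* p, int i, int j, int n,
                                const double* box, const int* pbc) {
  double s = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = mic(p[i + k * n] - p[j + k * n], box[k], pbc[k] != 0);
    s += d * d;
  }
  return s;
}

// [[Rcpp::export]]
NumericVector cpp_min_image_dist(NumericMatrix a, NumericMatrix b,
                                 NumericVector box, LogicalVector pbc) {
  int n = a.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = 0; k < 3; ++k) {
      double d = mic(a(i, k) - b(i, k), box[k], pbc[k] != 0);
      s += d * d;
    }
    out[i] = std::sqrt(s);
  }
  return out;
}

// All pairs (i < j, 1-based) within cutoff under the periodic convention.
// [[Rcpp::export]]
IntegerMatrix cpp_pair_list(NumericMatrix pos, NumericVector box,
                            LogicalVector pbc, double cutoff) {
  int n = pos.nrow();
  const double* p = REAL(pos);
  double c2 = cutoff * cutoff;
  int pb[3] = { pbc[0], pbc[1], pbc[2] };
  double bx[3] = { box[0], box[1], box[2] };
  std::vector<int> ii, jj;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      // cheap z reject first: z is usually the long, non-periodic axis
      double dz = mic(p[i + 2 * n] - p[j + 2 * n], bx[2], pb[2] != 0);
      if (std::fabs(dz) > cutoff) continue;
      if (pair_dist2(p, i, j, n, bx, pb) <= c2) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
      }
    }
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(k, 0) = ii[k];
    out(k, 1) = jj[k];
  }
  return out;
}

// Associated Legendre P_l^m(x) for l = 6, m = 0..6, without the
// Condon-Shortley phase (the phase cancels in |q6m|^2).
static void legendre6(double x, double* P) {
  double s2 = 1.0 - x * x;         // sin^2(theta)
  double s = std::sqrt(std::max(0.0, s2));
  // P_m^m by recurrence, then two-step upward recurrence in l.
  double pmm[7];
  pmm[0] = 1.0;
  for (int m = 1; m <= 6; ++m) pmm[m] = pmm[m - 1] * (2.0 * m - 1.0) * s;
  for (int m = 0; m <= 6; ++m) {
    double p0 = pmm[m];                       // l = m
    if (m == 6) { P[m] = p0; continue; }
    double p1 = x * (2.0 * m + 1.0) * p0;     // l = m + 1
    for (int l = m + 2; l <= 6; ++l) {
      double p2 = ((2.0 * l - 1.0) * x * p1 - (l + m - 1.0) * p0) / (l - m);
      p0 = p1;
      p1 = p2;
    }
    P[m] = p1;
  }
}

// Neighbour-averaged Steinhardt l=6 order parameter over O-O neighbours
// within `cutoff`. Atoms with no neighbours get 0.
// [[Rcpp::export]]
NumericVector cpp_qbar6(NumericMatrix pos, NumericVector box,
                        LogicalVector pbc, double cutoff, int stages = 1) {
  int n = pos.nrow();
  const double* p = REAL(pos);
  double c2 = cutoff * cutoff;
  int pb[3] = { pbc[0], pbc[1], pbc[2] };
  double bx[3] = { box[0], box[1], box[2] };

  // normalisation sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!) for l=6, m=0..6
  double norm[7];
  for (int m = 0; m <= 6; ++m) {
    double ratio = 1.0;                       // (l-m)!/(l+m)!
    for (int k = 6 - m + 1; k <= 6 + m; ++k) ratio /= (double)k;
    norm[m] = std::sqrt(13.0 / (4.0 * M_PI) * ratio);
  }

  std::vector<double> qre(n * 7, 0.0), qim(n * 7, 0.0);
  std::vector<int> nb(n, 0);
  std::vector<std::vector<int> > adj(n);

  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d[3];
      for (int k = 0; k < 3; ++k)
        d[k] = mic(p[j + k * n] - p[i + k * n], bx[k], pb[k] != 0);
      if (std::fabs(d[2]) > cutoff) continue;
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 > c2 || r2 <= 0.0) continue;
      double r = std::sqrt(r2);
      double ct = d[2] / r;                 // cos(theta)
      double phi = std::atan2(d[1], d[0]);
      double P[7];
      legendre6(ct, P);
      for (int m = 0; m <= 6; ++m) {
        double ylm = norm[m] * P[m];
        double cre = ylm * std::cos(m * phi);
        double cim = ylm * std::sin(m * phi);
        // Y_lm(-r) = (-1)^l Y_lm(r) with l=6 even: same value for j -> i
        qre[i * 7 + m] += cre; qim[i * 7 + m] += cim;
        qre[j * 7 + m] += cre; qim[j * 7 + m] += cim;
      }
      nb[i]++; nb[j]++;
      adj[i].push_back(j);
      adj[j].push_back(i);
    }
  }

  // per-atom q6m = bond average
  for (int i = 0; i < n; ++i) {
    if (nb[i] == 0) continue;
    for (int m = 0; m <= 6; ++m) {
      qre[i * 7 + m] /= nb[i];
      qim[i * 7 + m] /= nb[i];
    }
  }

  // `stages` rounds of averaging the complex q6m vectors over
  // {self + neighbours}: coherent (crystalline) environments survive,
  // incoherent (disordered) ones are suppressed by each round.
  for (int s = 0; s < stages; ++s) {
    std::vector<double> nre(n * 7, 0.0), nim(n * 7, 0.0);
    for (int i = 0; i < n; ++i) {
      for (int m = 0; m <= 6; ++m) {
        double re = qre[i * 7 + m], im = qim[i * 7 + m];
        for (size_t a = 0; a < adj[i].size(); ++a) {
          re += qre[adj[i][a] * 7 + m];
          im += qim[adj[i][a] * 7 + m];
        }
        nre[i * 7 + m] = re / (nb[i] + 1.0);
        nim[i * 7 + m] = im / (nb[i] + 1.0);
      }
    }
    qre.swap(nre);
    qim.swap(nim);
  }

  NumericVector out(n);
  const double pref = 4.0 * M_PI / 13.0;
  for (int i = 0; i < n; ++i) {
    if (nb[i] == 0) { out[i] = 0.0; continue; }
    double acc = 0.0;
    for (int m = 0; m <= 6; ++m) {
      double re = qre[i * 7 + m], im = qim[i * 7 + m];
      double mag2 = re * re + im * im;
      acc += (m == 0) ? mag2 : 2.0 * mag2;
    }
    out[i] = std::sqrt(pref * acc);
  }
  return out;
}

// Bond-coherence order parameter: per atom, the fraction of neighbours
// whose bond-averaged q6m vector has a normalised real inner product
// (coherence) >= cmin with the atom's own, scaled by min(nb, 4)/4 so
// that under-coordinated atoms cannot score high. In [0, 1]; 0 for
// atoms with no neighbours.
// [[Rcpp::export]]
NumericVector cpp_q6_coherence(NumericMatrix pos, NumericVector box,
                               LogicalVector pbc, double cutoff,
                               double cmin = 0.5) {
  int n = pos.nrow();
  const double* p = REAL(pos);
  double c2 = cutoff * cutoff;
  int pb[3] = { pbc[0], pbc[1], pbc[2] };
  double bx[3] = { box[0], box[1], box[2] };
  double norm[7];
  for (int m = 0; m <= 6; ++m) {
    double ratio = 1.0;
    for (int k = 6 - m + 1; k <= 6 + m; ++k) ratio /= (double)k;
    norm[m] = std::sqrt(13.0 / (4.0 * M_PI) * ratio);
  }
  std::vector<double> qre(n * 7, 0.0), qim(n * 7, 0.0);
  std::vector<int> nb(n, 0);
  std::vector<std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d[3];
      for (int k = 0; k < 3; ++k)
        d[k] = mic(p[j + k * n] - p[i + k * n], bx[k], pb[k] != 0);
      if (std::fabs(d[2]) > cutoff) continue;
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      if (r2 > c2 || r2 <= 0.0) continue;
      double r = std::sqrt(r2);
      double ct = d[2] / r;
      double phi = std::atan2(d[1], d[0]);
      double P[7];
      legendre6(ct, P);
      for (int m = 0; m <= 6; ++m) {
        double ylm = norm[m] * P[m];
        double cre = ylm * std::cos(m * phi);
        double cim = ylm * std::sin(m * phi);
        qre[i * 7 + m] += cre; qim[i * 7 + m] += cim;
        qre[j * 7 + m] += cre; qim[j * 7 + m] += cim;
      }
      nb[i]++; nb[j]++;
      adj[i].push_back(j);
      adj[j].push_back(i);
    }
  }
  std::vector<double> mag(n, 0.0);
  for (int i = 0; i < n; ++i) {
    if (nb[i] == 0) continue;
    double acc = 0.0;
    for (int m = 0; m <= 6; ++m) {
      qre[i * 7 + m] /= nb[i];
      qim[i * 7 + m] /= nb[i];
      double m2 = qre[i * 7 + m] * qre[i * 7 + m] +
                  qim[i * 7 + m] * qim[i * 7 + m];
      acc += (m == 0) ? m2 : 2.0 * m2;
    }
    mag[i] = std::sqrt(acc);
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (nb[i] == 0 || mag[i] <= 0) { out[i] = 0.0; continue; }
    int solid = 0;
    for (size_t a = 0; a < adj[i].size(); ++a) {
      int j = adj[i][a];
      if (mag[j] <= 0) continue;
      double dot = 0.0;
      for (int m = 0; m <= 6; ++m) {
        double re = qre[i * 7 + m] * qre[j * 7 + m] +
                    qim[i * 7 + m] * qim[j * 7 + m];
        dot += (m == 0) ? re : 2.0 * re;
      }
      if (dot / (mag[i] * mag[j]) >= cmin) ++solid;
    }
    double scale = std::min(nb[i], 4) / 4.0;
    out[i] = scale * (double)solid / nb[i];
  }
  return out;
}

// Connected components from an edge list (1-based), n nodes; returns
// 1-based component labels.
// [[Rcpp::export]]
IntegerVector cpp_components(IntegerMatrix pairs, int n) {
  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int k = 0; k < pairs.nrow(); ++k) {
    int a = find(pairs(k, 0) - 1), b = find(pairs(k, 1) - 1);
    if (a != b) parent[a] = b;
  }
  IntegerVector lab(n);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = find(i);
    if (remap[r] == 0) remap[r] = ++next;
    lab[i] = remap[r];
  }
  return lab;
}

// Random min-distance-constrained packing of n points in an axis-aligned
// region [lo, hi] of a periodic box. Uses R's RNG (respects set.seed).
// [[Rcpp::export]]
NumericMatrix cpp_pack_points(int n, NumericVector lo, NumericVector hi,
                              NumericVector box, LogicalVector pbc,
                              double mindist, int maxtry,
                              NumericMatrix fixed) {
  NumericMatrix out(n, 3);
  int pb[3] = { pbc[0], pbc[1], pbc[2] };
  double bx[3] = { box[0], box[1], box[2] };
  double m2 = mindist * mindist;
  int nf = fixed.nrow();
  int placed = 0, tries = 0;
  while (placed < n) {
    if (++tries > maxtry)
      stop("packing failed: could not place %d points at min distance %.2f",
           n, mindist);
    double cand[3];
    for (int k = 0; k < 3; ++k)
      cand[k] = lo[k] + unif_rand() * (hi[k] - lo[k]);
    bool ok = true;
    for (int f = 0; f < nf && ok; ++f) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = mic(cand[k] - fixed(f, k), bx[k], pb[k] != 0);
        s += d * d;
      }
      if (s < m2) ok = false;
    }
    for (int j = 0; j < placed && ok; ++j) {
      double s = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = mic(cand[k] - out(j, k), bx[k], pb[k] != 0);
        s += d * d;
      }
      if (s < m2) ok = false;
    }
    if (ok) {
      for (int k = 0; k < 3; ++k) out(placed, k) = cand[k];
      ++placed;
    }
  }
  return out;
}

// van der Waals (union-of-spheres) volume by grid counting.
// [[Rcpp::export]]
double cpp_grid_volume(NumericMatrix pos, NumericVector radii,
                       double spacing) {
  int n = pos.nrow();
  double rmax = 0.0;
  for (int i = 0; i < n; ++i) rmax = std::max(rmax, radii[i]);
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = R_PosInf; hi[k] = R_NegInf;
    for (int i = 0; i < n; ++i) {
      lo[k] = std::min(lo[k], pos(i, k));
      hi[k] = std::max(hi[k], pos(i, k));
    }
    lo[k] -= rmax + spacing;
    hi[k] += rmax + spacing;
  }
  int dims[3];
  for (int k = 0; k < 3; ++k)
    dims[k] = (int)std::ceil((hi[k] - lo[k]) / spacing) + 1;
  std::vector<unsigned char> occ((size_t)dims[0] * dims[1] * dims[2], 0);
  for (int i = 0; i < n; ++i) {
    double r = radii[i], r2 = r * r;
    int g0[3], g1[3];
    for (int k = 0; k < 3; ++k) {
      g0[k] = std::max(0, (int)std::floor((pos(i, k) - r - lo[k]) / spacing));
      g1[k] = std::min(dims[k] - 1,
                       (int)std::ceil((pos(i, k) + r - lo[k]) / spacing));
    }
    for (int ix = g0[0]; ix <= g1[0]; ++ix) {
      double dx = lo[0] + ix * spacing - pos(i, 0);
      for (int iy = g0[1]; iy <= g1[1]; ++iy) {
        double dy = lo[1] + iy * spacing - pos(i, 1);
        double dxy = dx * dx + dy * dy;
        if (dxy > r2) continue;
        for (int iz = g0[2]; iz <= g1[2]; ++iz) {
          double dz = lo[2] + iz * spacing - pos(i, 2);
          if (dxy + dz * dz <= r2)
            occ[((size_t)ix * dims[1] + iy) * dims[2] + iz] = 1;
        }
      }
    }
  }
  size_t cnt = 0;
  for (size_t i = 0; i < occ.size(); ++i) cnt += occ[i];
  return (double)cnt * spacing * spacing * spacing;
}

// Shrake-Rupley SASA with a deterministic golden-spiral point set.
// Returns the per-atom accessible area (A^2).
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix pos, NumericVector radii,
                       double probe, int npoints) {
  int n = pos.nrow();
  // golden-spiral unit sphere points
  std::vector<double> sx(npoints), sy(npoints), sz(npoints);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < npoints; ++i) {
    double z = 1.0 - 2.0 * (i + 0.5) / npoints;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = ga * i;
    sx[i] = r * std::cos(th);
    sy[i] = r * std::sin(th);
    sz[i] = z;
  }
  NumericVector area(n);
  for (int i = 0; i < n; ++i) {
    double ri = radii[i] + probe;
    int acc = 0;
    for (int k = 0; k < npoints; ++k) {
      double px = pos(i, 0) + ri * sx[k];
      double py = pos(i, 1) + ri * sy[k];
      double pz = pos(i, 2) + ri * sz[k];
      bool buried = false;
      for (int j = 0; j < n && !buried; ++j) {
        if (j == i) continue;
        double rj = radii[j] + probe;
        double dx = px - pos(j, 0), dy = py - pos(j, 1), dz = pz - pos(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) buried = true;
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double)acc / npoints;
  }
  return area;
}
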