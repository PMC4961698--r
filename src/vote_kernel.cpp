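// Block-wise non-local label voting kernel.
//
// For every masked voxel x_i of the subject, all template voxels x_{s,j}
// inside a cubic search volume are compared through their intensity
// patches. The weight of a comparison is
//     w = exp(-||c_i - c_j||^2 / (2 sigma_d^2)) * exp(-||P_i - P_sj||^2 / h^2)
// gated to zero when the structural similarity (luminance x contrast
// product of patch means/sds) does not exceed `th`. The bandwidth is
// adaptive per voxel: h^2 = lambda * min_candidates ||P_i - P_sj||^2 + eps,
// the minimum running over every candidate (gated ones included). Each
// accepted weight votes for the whole label block around x_{s,j}; votes of
// all overlapping blocks are summed (overcomplete aggregation) and the
// per-voxel label vector normalized to 1 at the end. Patches, blocks and
// search windows are cropped at the grid boundary; cropped patch distances
// are rescaled by (full/valid element count) so the bandwidth minimum stays
// comparable.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// running box sum along one axis with window radius r (cropped at ends)
static void box_pass(std::vector<double>& x, int nx, int ny, int nz,
                     int axis, int r) {
  std::vector<double> line, out;
  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  int stride = (axis == 0) ? 1 : (axis == 1) ? nx : nx * ny;
  int n_other1 = (axis == 0) ? ny : nx;
  int n_other2 = (axis == 2) ? ny : nz;
  int stride1 = (axis == 0) ? nx : 1;
  int stride2 = (axis == 2) ? nx : nx * ny;
  line.resize(n); out.resize(n);
  for (int b = 0; b < n_other2; ++b) {
    for (int a = 0; a < n_other1; ++a) {
      double* base = x.data() + (size_t)a * stride1 + (size_t)b * stride2;
      for (int i = 0; i < n; ++i) line[i] = base[(size_t)i * stride];
      double acc = 0;
      for (int i = 0; i <= std::min(r, n - 1); ++i) acc += line[i];
      for (int i = 0; i < n; ++i) {
        out[i] = acc;
        int add = i + r + 1, rem = i - r;
        if (add < n) acc += line[add];
        if (rem >= 0) acc -= line[rem];
      }
      for (int i = 0; i < n; ++i) base[(size_t)i * stride] = out[i];
    }
  }
}

// patch mean and sd volumes for radius r (population sd, cropped windows)
static void patch_stats(const double* img, int nx, int ny, int nz, int r,
                        std::vector<double>& mean, std::vector<double>& sd) {
  size_t nvox = (size_t)nx * ny * nz;
  std::vector<double> s(img, img + nvox), s2(nvox), cnt(nvox, 1.0);
  for (size_t i = 0; i < nvox; ++i) s2[i] = img[i] * img[i];
  for (int ax = 0; ax < 3; ++ax) {
    box_pass(s, nx, ny, nz, ax, r);
    box_pass(s2, nx, ny, nz, ax, r);
    box_pass(cnt, nx, ny, nz, ax, r);
  }
  mean.resize(nvox); sd.resize(nvox);
  for (size_t i = 0; i < nvox; ++i) {
    double m = s[i] / cnt[i];
    double v = s2[i] / cnt[i] - m * m;
    mean[i] = m;
    sd[i] = v > 0 ? std::sqrt(v) : 0.0;
  }
}

static inline double struct_sim(double m1, double s1, double m2, double s2) {
  const double tiny = 1e-12;
  double md = m1 * m1 + m2 * m2;
  double lum = (md < tiny) ? 1.0 : (2.0 * m1 * m2 / md);
  if (s1 < tiny && s2 < tiny) {          // both patches constant
    return (std::fabs(m1 - m2) < tiny) ? 1.0 : lum;  // sd-term treated as 1
  }
  double sdd = s1 * s1 + s2 * s2;
  double con = (sdd < tiny) ? 1.0 : (2.0 * s1 * s2 / sdd);
  return lum * con;
}

// [[Rcpp::export]]
List cpp_blockwise_vote(NumericVector subj, IntegerVector dims,
                        NumericVector vox, List tmpl_int, List tmpl_lab,
                        LogicalVector mask, IntegerVector label_values,
                        int patch_radius, int search_radius, int block_radius,
                        double lambda, double eps, double sigma_d, double th,
                        bool normalize_blocks) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t nvox = (size_t)nx * ny * nz;
  const int nT = tmpl_int.size();
  const int K = label_values.size();
  const double vx = vox[0], vy = vox[1], vz = vox[2];

  // label value -> class index
  int max_lab = 0;
  for (int k = 0; k < K; ++k) max_lab = std::max(max_lab, label_values[k]);
  std::vector<int> labmap(max_lab + 1, -1);
  for (int k = 0; k < K; ++k) labmap[label_values[k]] = k;

  std::vector<const double*> timg(nT);
  std::vector<const int*> tlab(nT);
  for (int s = 0; s < nT; ++s) {
    timg[s] = REAL(tmpl_int[s]);
    tlab[s] = INTEGER(tmpl_lab[s]);
  }
  const double* S = REAL(subj);

  // patch statistics for the ss gate
  std::vector<double> smean, ssd_;
  patch_stats(S, nx, ny, nz, patch_radius, smean, ssd_);
  std::vector<std::vector<double>> tmean(nT), tsd(nT);
  for (int s = 0; s < nT; ++s)
    patch_stats(timg[s], nx, ny, nz, patch_radius, tmean[s], tsd[s]);

  // offset tables
  const int R = search_radius, P = patch_radius, B = block_radius;
  const int nsearch = (2 * R + 1) * (2 * R + 1) * (2 * R + 1);
  std::vector<int> sdx(nsearch), sdy(nsearch), sdz(nsearch);
  std::vector<long long> sdelta(nsearch);
  std::vector<double> sdist2(nsearch);
  {
    int c = 0;
    for (int dz = -R; dz <= R; ++dz)
      for (int dy = -R; dy <= R; ++dy)
        for (int dx = -R; dx <= R; ++dx, ++c) {
          sdx[c] = dx; sdy[c] = dy; sdz[c] = dz;
          sdelta[c] = (long long)dx + (long long)nx * (dy + (long long)ny * dz);
          double ddx = dx * vx, ddy = dy * vy, ddz = dz * vz;
          sdist2[c] = ddx * ddx + ddy * ddy + ddz * ddz;
        }
  }
  const int npatch = (2 * P + 1) * (2 * P + 1) * (2 * P + 1);
  std::vector<int> pdx(npatch), pdy(npatch), pdz(npatch);
  std::vector<long long> pdelta(npatch);
  {
    int c = 0;
    for (int dz = -P; dz <= P; ++dz)
      for (int dy = -P; dy <= P; ++dy)
        for (int dx = -P; dx <= P; ++dx, ++c) {
          pdx[c] = dx; pdy[c] = dy; pdz[c] = dz;
          pdelta[c] = (long long)dx + (long long)nx * (dy + (long long)ny * dz);
        }
  }
  const int nblock = (2 * B + 1) * (2 * B + 1) * (2 * B + 1);
  std::vector<int> bdx(nblock), bdy(nblock), bdz(nblock);
  std::vector<long long> bdelta(nblock);
  {
    int c = 0;
    for (int dz = -B; dz <= B; ++dz)
      for (int dy = -B; dy <= B; ++dy)
        for (int dx = -B; dx <= B; ++dx, ++c) {
          bdx[c] = dx; bdy[c] = dy; bdz[c] = dz;
          bdelta[c] = (long long)dx + (long long)nx * (dy + (long long)ny * dz);
        }
  }

  const int margin = R + std::max(P, B);
  const double inv2sig = 1.0 / (2.0 * sigma_d * sigma_d);

  NumericVector votes((R_xlen_t)nvox * K);
  double* V = REAL(votes);
  std::memset(V, 0, sizeof(double) * nvox * K);

  // candidate buffers (reused)
  const int maxcand = nT * nsearch;
  std::vector<double> c_ssd(maxcand), c_dist2(maxcand);
  std::vector<long long> c_j(maxcand);
  std::vector<int> c_s(maxcand);
  std::vector<char> c_elig(maxcand);
  std::vector<char> seen_lab(K);

  int n_fallback = 0;
  std::vector<int> fallback_idx;

  const int* M = LOGICAL(mask);
  for (int zi = 0; zi < nz; ++zi) {
    for (int yi = 0; yi < ny; ++yi) {
      for (int xi = 0; xi < nx; ++xi) {
        size_t i = (size_t)xi + (size_t)nx * (yi + (size_t)ny * zi);
        if (!M[i]) continue;
        bool interior = xi >= margin && xi < nx - margin &&
                        yi >= margin && yi < ny - margin &&
                        zi >= margin && zi < nz - margin;
        int ncand = 0;
        double minssd = R_PosInf;
        double mi_m = smean[i], mi_s = ssd_[i];

        for (int s = 0; s < nT; ++s) {
          const double* T = timg[s];
          for (int c = 0; c < nsearch; ++c) {
            long long j;
            if (interior) {
              j = (long long)i + sdelta[c];
            } else {
              int xj = xi + sdx[c], yj = yi + sdy[c], zj = zi + sdz[c];
              if (xj < 0 || xj >= nx || yj < 0 || yj >= ny || zj < 0 || zj >= nz)
                continue;
              j = (long long)xj + (long long)nx * (yj + (long long)ny * zj);
            }
            double ssd = 0.0;
            if (interior) {
              for (int p = 0; p < npatch; ++p) {
                double d = S[i + pdelta[p]] - T[j + pdelta[p]];
                ssd += d * d;
              }
            } else {
              int nvalid = 0;
              int xj = xi + sdx[c], yj = yi + sdy[c], zj = zi + sdz[c];
              for (int p = 0; p < npatch; ++p) {
                int ax = xi + pdx[p], ay = yi + pdy[p], az = zi + pdz[p];
                int bx2 = xj + pdx[p], by2 = yj + pdy[p], bz2 = zj + pdz[p];
                if (ax < 0 || ax >= nx || ay < 0 || ay >= ny || az < 0 || az >= nz)
                  continue;
                if (bx2 < 0 || bx2 >= nx || by2 < 0 || by2 >= ny || bz2 < 0 || bz2 >= nz)
                  continue;
                double d = S[(size_t)ax + (size_t)nx * (ay + (size_t)ny * az)] -
                           T[(size_t)bx2 + (size_t)nx * (by2 + (size_t)ny * bz2)];
                ssd += d * d;
                ++nvalid;
              }
              if (nvalid == 0) continue;
              ssd *= (double)npatch / nvalid;  // keep cropped distances comparable
            }
            double ss = struct_sim(mi_m, mi_s, tmean[s][j], tsd[s][j]);
            c_ssd[ncand] = ssd;
            c_dist2[ncand] = sdist2[c];
            c_j[ncand] = j;
            c_s[ncand] = s;
            c_elig[ncand] = (ss > th) ? 1 : 0;
            if (ssd < minssd) minssd = ssd;
            ++ncand;
          }
        }
        if (ncand == 0) continue;  // search volume entirely off-grid (tiny grids)

        double h2 = lambda * minssd + eps;
        double W = 0.0;
        for (int c = 0; c < ncand; ++c) {
          if (!c_elig[c]) continue;
          W += std::exp(-c_dist2[c] * inv2sig) * std::exp(-c_ssd[c] / h2);
        }
        if (W <= 0.0) {
          // every comparison gated out: uniform vote over labels observed
          // in the search volume, cast at the center voxel
          std::fill(seen_lab.begin(), seen_lab.end(), 0);
          int nobs = 0;
          for (int c = 0; c < ncand; ++c) {
            int lv = tlab[c_s[c]][c_j[c]];
            int k = (lv >= 0 && lv <= max_lab) ? labmap[lv] : -1;
            if (k >= 0 && !seen_lab[k]) { seen_lab[k] = 1; ++nobs; }
          }
          if (nobs > 0) {
            for (int k = 0; k < K; ++k)
              if (seen_lab[k]) V[i + nvox * k] += 1.0 / nobs;
          }
          ++n_fallback;
          fallback_idx.push_back((int)(i + 1));
          continue;
        }

        double scale = normalize_blocks ? (1.0 / W) : 1.0;
        for (int c = 0; c < ncand; ++c) {
          if (!c_elig[c]) continue;
          double w = std::exp(-c_dist2[c] * inv2sig) * std::exp(-c_ssd[c] / h2);
          if (w <= 0.0) continue;
          w *= scale;
          const int* L = tlab[c_s[c]];
          long long j = c_j[c];
          if (interior) {
            for (int b = 0; b < nblock; ++b) {
              int lv = L[j + bdelta[b]];
              int k = (lv >= 0 && lv <= max_lab) ? labmap[lv] : -1;
              if (k >= 0) V[(size_t)((long long)i + bdelta[b]) + nvox * k] += w;
            }
          } else {
            int xj = (int)(j % nx), yj = (int)((j / nx) % ny), zj = (int)(j / ((long long)nx * ny));
            for (int b = 0; b < nblock; ++b) {
              int ax = xi + bdx[b], ay = yi + bdy[b], az = zi + bdz[b];
              int bx2 = xj + bdx[b], by2 = yj + bdy[b], bz2 = zj + bdz[b];
              if (ax < 0 || ax >= nx || ay < 0 || ay >= ny || az < 0 || az >= nz)
                continue;
              if (bx2 < 0 || bx2 >= nx || by2 < 0 || by2 >= ny || bz2 < 0 || bz2 >= nz)
                continue;
              int lv = L[(size_t)bx2 + (size_t)nx * (by2 + (size_t)ny * bz2)];
              int k = (lv >= 0 && lv <= max_lab) ? labmap[lv] : -1;
              if (k >= 0)
                V[(size_t)ax + (size_t)nx * (ay + (size_t)ny * az) + nvox * k] += w;
            }
          }
        }
      }
    }
  }

  // per-voxel normalization over labels
  for (size_t i = 0; i < nvox; ++i) {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) tot += V[i + nvox * k];
    if (tot > 0.0)
      for (int k = 0; k < K; ++k) V[i + nvox * k] /= tot;
  }

  return List::create(_["votes"] = votes,
                      _["n_fallback"] = n_fallback,
                      _["fallback_voxels"] = wrap(fallback_idx));
}
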