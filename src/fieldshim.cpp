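// Compiled hot paths: pull-based affine resampling and quality-guided
// region-growing phase unwrapping. Both operate on 3D arrays in R's
// column-major layout; voxel indices are 0-based here.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline int vidx(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Resample a source volume onto a target grid. `map` is the combined 4x4
// matrix taking 0-based target voxel indices to 0-based source voxel
// indices. Out-of-footprint voxels become NA.
// [[Rcpp::export(name = ".resample_affine_cpp")]]
NumericVector resample_affine_cpp(NumericVector src, IntegerVector sdim,
                                  NumericMatrix map, IntegerVector tdim,
                                  bool nearest) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  NumericVector out(static_cast<R_xlen_t>(tx) * ty * tz, NA_REAL);

  const double m00 = map(0,0), m01 = map(0,1), m02 = map(0,2), m03 = map(0,3);
  const double m10 = map(1,0), m11 = map(1,1), m12 = map(1,2), m13 = map(1,3);
  const double m20 = map(2,0), m21 = map(2,1), m22 = map(2,2), m23 = map(2,3);

  R_xlen_t t = 0;
  for (int k = 0; k < tz; ++k) {
    for (int j = 0; j < ty; ++j) {
      for (int i = 0; i < tx; ++i, ++t) {
        const double u = m00*i + m01*j + m02*k + m03;
        const double v = m10*i + m11*j + m12*k + m13;
        const double w = m20*i + m21*j + m22*k + m23;
        if (nearest) {
          const int iu = (int)std::lround(u), iv = (int)std::lround(v),
                    iw = (int)std::lround(w);
          if (iu < 0 || iv < 0 || iw < 0 || iu >= sx || iv >= sy || iw >= sz)
            continue;
          out[t] = src[vidx(iu, iv, iw, sx, sy)];
        } else {
          const double fu = std::floor(u), fv = std::floor(v),
                       fw = std::floor(w);
          const int i0 = (int)fu, j0 = (int)fv, k0 = (int)fw;
          if (i0 < 0 || j0 < 0 || k0 < 0 ||
              i0 + 1 > sx - 1 || j0 + 1 > sy - 1 || k0 + 1 > sz - 1) {
            // allow exact upper boundary
            if (u >= 0 && v >= 0 && w >= 0 &&
                u <= sx - 1 && v <= sy - 1 && w <= sz - 1) {
              const int ic = std::min(i0, sx - 2), jc = std::min(j0, sy - 2),
                        kc = std::min(k0, sz - 2);
              const double du = u - ic, dv = v - jc, dw = w - kc;
              double acc = 0.0;
              for (int dk = 0; dk < 2; ++dk)
                for (int dj = 0; dj < 2; ++dj)
                  for (int di = 0; di < 2; ++di) {
                    const double wt = (di ? du : 1 - du) *
                                      (dj ? dv : 1 - dv) *
                                      (dk ? dw : 1 - dw);
                    acc += wt * src[vidx(ic+di, jc+dj, kc+dk, sx, sy)];
                  }
              out[t] = acc;
            }
            continue;
          }
          const double du = u - fu, dv = v - fv, dw = w - fw;
          double acc = 0.0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di) {
                const double wt = (di ? du : 1 - du) *
                                  (dj ? dv : 1 - dv) *
                                  (dk ? dw : 1 - dw);
                acc += wt * src[vidx(i0+di, j0+dj, k0+dk, sx, sy)];
              }
          out[t] = acc;
        }
      }
    }
  }
  return out;
}

struct Cand {
  double quality;
  int voxel;
  int ref;
};
struct CandLess {
  bool operator()(const Cand &a, const Cand &b) const {
    if (a.quality != b.quality) return a.quality < b.quality;
    return a.voxel > b.voxel;  // deterministic tie-break
  }
};

// Quality-guided region-growing unwrapper. Within each 6-connected
// component of the mask, voxels are unwrapped in decreasing quality order
// relative to an already-unwrapped neighbour; the result is congruent to
// the input modulo 2*pi at every masked voxel.
// [[Rcpp::export(name = ".unwrap_rg_cpp")]]
List unwrap_rg_cpp(NumericVector wrapped, NumericVector quality,
                   LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = wrapped.size();
  const double TWO_PI = 2.0 * M_PI;
  NumericVector out(n, NA_REAL);
  IntegerVector label(n, 0);
  std::vector<char> done(n, 0);

  int comp = 0;
  for (R_xlen_t seed0 = 0; seed0 < n; ++seed0) {
    if (!mask[seed0] || done[seed0]) continue;
    // collect this component by BFS, find max-quality seed
    std::vector<int> members;
    std::vector<char> seen(0);
    std::queue<int> bfs;
    bfs.push((int)seed0);
    std::vector<char> incomp(n, 0);
    incomp[seed0] = 1;
    while (!bfs.empty()) {
      int c = bfs.front(); bfs.pop();
      members.push_back(c);
      int k = c / (nx * ny), r = c % (nx * ny), j = r / nx, i = r % nx;
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        int c2 = vidx(ii, jj, kk, nx, ny);
        if (mask[c2] && !incomp[c2] && !done[c2]) {
          incomp[c2] = 1;
          bfs.push(c2);
        }
      }
    }
    ++comp;
    int seed = members[0];
    for (size_t m = 1; m < members.size(); ++m)
      if (quality[members[m]] > quality[seed]) seed = members[m];

    std::priority_queue<Cand, std::vector<Cand>, CandLess> pq;
    out[seed] = wrapped[seed];
    done[seed] = 1;
    label[seed] = comp;
    pq.push(Cand{quality[seed], seed, seed});
    while (!pq.empty()) {
      Cand c = pq.top(); pq.pop();
      int cur = c.voxel;
      if (cur != c.ref) {
        if (done[cur]) continue;
        // choose 2*pi multiple bringing value closest to the reference
        out[cur] = wrapped[cur] +
          TWO_PI * std::round((out[c.ref] - wrapped[cur]) / TWO_PI);
        done[cur] = 1;
        label[cur] = comp;
      }
      int k = cur / (nx * ny), r = cur % (nx * ny), j = r / nx, i = r % nx;
      const int di[6] = {-1, 1, 0, 0, 0, 0};
      const int dj[6] = {0, 0, -1, 1, 0, 0};
      const int dk[6] = {0, 0, 0, 0, -1, 1};
      for (int q = 0; q < 6; ++q) {
        int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        int c2 = vidx(ii, jj, kk, nx, ny);
        if (mask[c2] && !done[c2]) pq.push(Cand{quality[c2], c2, cur});
      }
    }
  }
  return List::create(_["unwrapped"] = out, _["label"] = label,
                      _["n_components"] = comp);
}

// Interpolate a source volume at arbitrary target voxel positions given
// by rows of `pts` (0-based target indices), mapped through `map` into
// source index space. Trilinear; NA outside the footprint.
// [[Rcpp::export(name = ".interp_points_cpp")]]
NumericVector interp_points_cpp(NumericVector src, IntegerVector sdim,
                                NumericMatrix map, NumericMatrix pts) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const R_xlen_t n = pts.nrow();
  NumericVector out(n, NA_REAL);
  const double m00 = map(0,0), m01 = map(0,1), m02 = map(0,2), m03 = map(0,3);
  const double m10 = map(1,0), m11 = map(1,1), m12 = map(1,2), m13 = map(1,3);
  const double m20 = map(2,0), m21 = map(2,1), m22 = map(2,2), m23 = map(2,3);
  for (R_xlen_t t = 0; t < n; ++t) {
    const double i = pts(t, 0), j = pts(t, 1), k = pts(t, 2);
    const double u = m00*i + m01*j + m02*k + m03;
    const double v = m10*i + m11*j + m12*k + m13;
    const double w = m20*i + m21*j + m22*k + m23;
    if (u < 0 || v < 0 || w < 0 ||
        u > sx - 1 || v > sy - 1 || w > sz - 1) continue;
    int i0 = std::min((int)std::floor(u), sx - 2);
    int j0 = std::min((int)std::floor(v), sy - 2);
    int k0 = std::min((int)std::floor(w), sz - 2);
    const double du = u - i0, dv = v - j0, dw = w - k0;
    double acc = 0.0;
    for (int dk = 0; dk < 2; ++dk)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di) {
          const double wt = (di ? du : 1 - du) * (dj ? dv : 1 - dv) *
                            (dk ? dw : 1 - dw);
          acc += wt * src[vidx(i0+di, j0+dj, k0+dk, sx, sy)];
        }
    out[t] = acc;
  }
  return out;
}
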