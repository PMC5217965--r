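#include <Rcpp.h>
#include <functional>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 3D volumes are stored column-major (R order): idx = x + nx*(y + ny*z),
// all indices 0-based inside this file.

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// squared feature-gradient magnitude at (x,y,z): sum over channels of the
// squared central differences along the three axes (borders clamped)
static double grad_sq(const NumericVector &feat, int nx, int ny, int nz,
                      int nch, int x, int y, int z) {
  const double *f = REAL(feat);
  const R_xlen_t vol = (R_xlen_t)nx * ny * nz;
  double g = 0.0;
  for (int c = 0; c < nch; ++c) {
    const double *fc = f + c * vol;
    int xp = clampi(x + 1, 0, nx - 1), xm = clampi(x - 1, 0, nx - 1);
    int yp = clampi(y + 1, 0, ny - 1), ym = clampi(y - 1, 0, ny - 1);
    int zp = clampi(z + 1, 0, nz - 1), zm = clampi(z - 1, 0, nz - 1);
    double dx = fc[xp + nx * (y + (R_xlen_t)ny * z)] -
                fc[xm + nx * (y + (R_xlen_t)ny * z)];
    double dy = fc[x + nx * (yp + (R_xlen_t)ny * z)] -
                fc[x + nx * (ym + (R_xlen_t)ny * z)];
    double dz = fc[x + nx * (y + (R_xlen_t)ny * zp)] -
                fc[x + nx * (y + (R_xlen_t)ny * zm)];
    g += dx * dx + dy * dy + dz * dz;
  }
  return g;
}

// Seed cluster centers on a regular lattice of spacing S, then move each to
// the lowest-gradient position in its 3x3x3 neighborhood (ties keep the
// original position). Returns a k x (3 + nch) matrix: 0-based position then
// the feature vector sampled at the final position.
// [[Rcpp::export]]
NumericMatrix cpp_seed_centers(NumericVector feat, int S) {
  IntegerVector dims = feat.attr("dim");
  if (dims.size() != 4) stop("features must be a 4D array");
  int nx = dims[0], ny = dims[1], nz = dims[2], nch = dims[3];
  const R_xlen_t vol = (R_xlen_t)nx * ny * nz;
  const double *f = REAL(feat);
  std::vector<int> xs, ys, zs;
  for (int x = S / 2; x < nx; x += S) xs.push_back(x);
  for (int y = S / 2; y < ny; y += S) ys.push_back(y);
  for (int z = S / 2; z < nz; z += S) zs.push_back(z);
  int k = (int)(xs.size() * ys.size() * zs.size());
  if (k == 0) stop("grid smaller than seed interval S in some axis");
  NumericMatrix centers(k, 3 + nch);
  int ci = 0;
  for (size_t iz = 0; iz < zs.size(); ++iz)
    for (size_t iy = 0; iy < ys.size(); ++iy)
      for (size_t ix = 0; ix < xs.size(); ++ix) {
        int bx = xs[ix], by = ys[iy], bz = zs[iz];
        int best_x = bx, best_y = by, best_z = bz;
        double best_g = grad_sq(feat, nx, ny, nz, nch, bx, by, bz);
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (dx == 0 && dy == 0 && dz == 0) continue;
              int x = bx + dx, y = by + dy, z = bz + dz;
              if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
                continue;
              double g = grad_sq(feat, nx, ny, nz, nch, x, y, z);
              if (g < best_g) {
                best_g = g; best_x = x; best_y = y; best_z = z;
              }
            }
        centers(ci, 0) = best_x;
        centers(ci, 1) = best_y;
        centers(ci, 2) = best_z;
        R_xlen_t vi = best_x + nx * (best_y + (R_xlen_t)ny * best_z);
        for (int c = 0; c < nch; ++c) centers(ci, 3 + c) = f[vi + c * vol];
        ++ci;
      }
  return centers;
}

// Localized k-means iterations under the additive feature+spatial distance:
//   D = sqrt(mean_k (b_jk - b_ik)^2) / m + sqrt(sum_k (x_jk - x_ik)^2) / S.
// Each center only competes for voxels inside its (2S+1)^3 window; centers
// are updated to the member means of position and features each iteration;
// stops early when no assignment changes. Returns 1-based labels (0 would
// mean "never covered by any window", which lattice seeding precludes and
// which is reported as an error), final centers and iteration count.
// [[Rcpp::export]]
List cpp_slic_iterate(NumericVector feat, NumericMatrix centers_in,
                      int S, double m, int max_iter) {
  IntegerVector dims = feat.attr("dim");
  if (dims.size() != 4) stop("features must be a 4D array");
  int nx = dims[0], ny = dims[1], nz = dims[2], nch = dims[3];
  const R_xlen_t vol = (R_xlen_t)nx * ny * nz;
  const double *f = REAL(feat);
  int k = centers_in.nrow();
  std::vector<double> cen(centers_in.begin(), centers_in.end()); // k x (3+nch)
  IntegerVector labels(vol, 0);
  std::vector<double> bestd(vol);
  std::vector<double> acc((size_t)k * (3 + nch));
  std::vector<double> cnt(k);
  int iters = 0;
  for (int it = 0; it < max_iter; ++it) {
    ++iters;
    std::fill(bestd.begin(), bestd.end(), R_PosInf);
    R_xlen_t changed = 0;
    for (int ci = 0; ci < k; ++ci) {
      double cx = cen[ci], cy = cen[ci + k], cz = cen[ci + 2 * (size_t)k];
      int x0 = clampi((int)std::floor(cx) - S, 0, nx - 1);
      int x1 = clampi((int)std::floor(cx) + S, 0, nx - 1);
      int y0 = clampi((int)std::floor(cy) - S, 0, ny - 1);
      int y1 = clampi((int)std::floor(cy) + S, 0, ny - 1);
      int z0 = clampi((int)std::floor(cz) - S, 0, nz - 1);
      int z1 = clampi((int)std::floor(cz) + S, 0, nz - 1);
      for (int z = z0; z <= z1; ++z)
        for (int y = y0; y <= y1; ++y) {
          R_xlen_t row = nx * (y + (R_xlen_t)ny * z);
          for (int x = x0; x <= x1; ++x) {
            R_xlen_t vi = x + row;
            double fd = 0.0;
            for (int c = 0; c < nch; ++c) {
              double d = f[vi + c * vol] - cen[ci + (size_t)k * (3 + c)];
              fd += d * d;
            }
            double dx = x - cx, dy = y - cy, dz = z - cz;
            double D = std::sqrt(fd / nch) / m +
                       std::sqrt(dx * dx + dy * dy + dz * dz) / S;
            if (D < bestd[vi]) {
              bestd[vi] = D;
              if (labels[vi] != ci + 1) { labels[vi] = ci + 1; ++changed; }
            }
          }
        }
    }
    for (R_xlen_t vi = 0; vi < vol; ++vi)
      if (labels[vi] == 0) stop("internal error: voxel covered by no window");
    // update centers to member means
    std::fill(acc.begin(), acc.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0.0);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t vi = x + nx * (y + (R_xlen_t)ny * z);
          int ci = labels[vi] - 1;
          cnt[ci] += 1.0;
          acc[ci] += x;
          acc[ci + k] += y;
          acc[ci + 2 * (size_t)k] += z;
          for (int c = 0; c < nch; ++c)
            acc[ci + (size_t)k * (3 + c)] += f[vi + c * vol];
        }
    for (int ci = 0; ci < k; ++ci) {
      if (cnt[ci] == 0.0) continue; // empty cluster keeps its old center
      for (int j = 0; j < 3 + nch; ++j)
        cen[ci + (size_t)k * j] = acc[ci + (size_t)k * j] / cnt[ci];
    }
    if (changed == 0) break;
  }
  NumericMatrix centers_out(k, 3 + nch);
  std::copy(cen.begin(), cen.end(), centers_out.begin());
  labels.attr("dim") = IntegerVector::create(nx, ny, nz);
  return List::create(_["labels"] = labels, _["centers"] = centers_out,
                      _["iterations"] = iters);
}

struct NeighborOffsets {
  std::vector<int> dx, dy, dz;
  NeighborOffsets(int connectivity) {
    if (connectivity == 6) {
      int ax[6] = {-1, 1, 0, 0, 0, 0};
      int ay[6] = {0, 0, -1, 1, 0, 0};
      int az[6] = {0, 0, 0, 0, -1, 1};
      dx.assign(ax, ax + 6); dy.assign(ay, ay + 6); dz.assign(az, az + 6);
    } else if (connectivity == 26) {
      for (int z = -1; z <= 1; ++z)
        for (int y = -1; y <= 1; ++y)
          for (int x = -1; x <= 1; ++x) {
            if (x == 0 && y == 0 && z == 0) continue;
            dx.push_back(x); dy.push_back(y); dz.push_back(z);
          }
    } else {
      stop("connectivity must be 6 or 26");
    }
  }
};

// Connected components of equal nonzero value. Returns 1-based component
// ids (0 stays 0 / background).
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector vals, int connectivity) {
  IntegerVector dims = vals.attr("dim");
  if (dims.size() != 3) stop("expected a 3D array");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t vol = (R_xlen_t)nx * ny * nz;
  NeighborOffsets nb(connectivity);
  IntegerVector comp(vol, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < vol; ++s) {
    if (vals[s] == 0 || comp[s] != 0) continue;
    int v = vals[s];
    comp[s] = ++next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (size_t j = 0; j < nb.dx.size(); ++j) {
        int xx = x + nb.dx[j], yy = y + nb.dy[j], zz = z + nb.dz[j];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t ni = xx + nx * (yy + (R_xlen_t)ny * zz);
        if (vals[ni] == v && comp[ni] == 0) {
          comp[ni] = next;
          stack.push_back(ni);
        }
      }
    }
  }
  comp.attr("dim") = dims;
  return comp;
}

// Enforce 26-connectivity of every supervoxel: each label's largest
// component keeps the label; other fragments of size >= min_size become new
// supervoxels; smaller fragments are merged into their largest 26-adjacent
// neighboring component. Output labels are contiguous 1..K.
// [[Rcpp::export]]
IntegerVector cpp_enforce_connectivity(IntegerVector labels, int min_size) {
  IntegerVector dims = labels.attr("dim");
  if (dims.size() != 3) stop("expected a 3D array");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t vol = (R_xlen_t)nx * ny * nz;
  for (R_xlen_t i = 0; i < vol; ++i)
    if (labels[i] <= 0) stop("labels must be positive");
  IntegerVector comp = cpp_label_components(labels, 26);
  int ncomp = 0;
  for (R_xlen_t i = 0; i < vol; ++i) ncomp = std::max(ncomp, comp[i]);
  std::vector<R_xlen_t> size(ncomp + 1, 0);
  std::vector<int> orig(ncomp + 1, 0);
  for (R_xlen_t i = 0; i < vol; ++i) {
    ++size[comp[i]];
    orig[comp[i]] = labels[i];
  }
  // largest component per original label keeps it
  int max_lab = 0;
  for (int c = 1; c <= ncomp; ++c) max_lab = std::max(max_lab, orig[c]);
  std::vector<int> champion(max_lab + 1, 0);
  for (int c = 1; c <= ncomp; ++c) {
    int l = orig[c];
    if (champion[l] == 0 || size[c] > size[champion[l]]) champion[l] = c;
  }
  std::vector<bool> keeper(ncomp + 1, false);
  for (int l = 1; l <= max_lab; ++l)
    if (champion[l] != 0) keeper[champion[l]] = true;
  for (int c = 1; c <= ncomp; ++c)
    if (!keeper[c] && size[c] >= (R_xlen_t)min_size) keeper[c] = true;
  // union-find over components; merge each non-keeper into its largest
  // 26-adjacent other component (adjacency keeps merged regions connected)
  std::vector<int> parent(ncomp + 1);
  for (int c = 0; c <= ncomp; ++c) parent[c] = c;
  std::function<int(int)> find = [&](int a) {
    while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
    return a;
  };
  NeighborOffsets nb(26);
  std::vector<int> order;
  for (int c = 1; c <= ncomp; ++c) if (!keeper[c]) order.push_back(c);
  std::sort(order.begin(), order.end(),
            [&](int a, int b) { return size[a] < size[b]; });
  // collect voxels per small component lazily
  std::vector<std::vector<R_xlen_t> > members(ncomp + 1);
  for (R_xlen_t i = 0; i < vol; ++i)
    if (!keeper[comp[i]]) members[comp[i]].push_back(i);
  for (size_t oi = 0; oi < order.size(); ++oi) {
    int c = order[oi];
    int best = 0;
    R_xlen_t best_size = -1;
    for (size_t mi = 0; mi < members[c].size(); ++mi) {
      R_xlen_t cur = members[c][mi];
      int x = (int)(cur % nx);
      int y = (int)((cur / nx) % ny);
      int z = (int)(cur / ((R_xlen_t)nx * ny));
      for (size_t j = 0; j < nb.dx.size(); ++j) {
        int xx = x + nb.dx[j], yy = y + nb.dy[j], zz = z + nb.dz[j];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int oc = comp[xx + nx * (yy + (R_xlen_t)ny * zz)];
        if (oc != c && find(oc) != find(c) && size[oc] > best_size) {
          best_size = size[oc];
          best = oc;
        }
      }
    }
    if (best != 0) parent[find(c)] = find(best);
    // isolated fragment (whole image is this component): keep as own label
  }
  // final labels: contiguous ids over root components
  std::vector<int> newlab(ncomp + 1, 0);
  int K = 0;
  for (int c = 1; c <= ncomp; ++c) {
    int r = find(c);
    if (newlab[r] == 0) newlab[r] = ++K;
  }
  IntegerVector out(vol);
  for (R_xlen_t i = 0; i < vol; ++i) out[i] = newlab[find(comp[i])];
  out.attr("dim") = dims;
  return out;
}

// Per-label voxel count, mean position (1-based) and mean feature vector.
// [[Rcpp::export]]
List cpp_label_stats(IntegerVector labels, NumericVector feat) {
  IntegerVector dims = labels.attr("dim");
  if (dims.size() != 3) stop("expected a 3D label array");
  IntegerVector fdims = feat.attr("dim");
  if (fdims.size() != 4) stop("features must be a 4D array");
  int nx = dims[0], ny = dims[1], nz = dims[2], nch = fdims[3];
  if (fdims[0] != nx || fdims[1] != ny || fdims[2] != nz)
    stop("labels and features must share the grid");
  const R_xlen_t vol = (R_xlen_t)nx * ny * nz;
  const double *f = REAL(feat);
  int K = 0;
  for (R_xlen_t i = 0; i < vol; ++i) {
    if (labels[i] <= 0) stop("labels must be positive");
    K = std::max(K, labels[i]);
  }
  NumericVector sizes(K);
  NumericMatrix pos(K, 3);
  NumericMatrix fm(K, nch);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t vi = x + nx * (y + (R_xlen_t)ny * z);
        int l = labels[vi] - 1;
        sizes[l] += 1.0;
        pos(l, 0) += x + 1;
        pos(l, 1) += y + 1;
        pos(l, 2) += z + 1;
        for (int c = 0; c < nch; ++c) fm(l, c) += f[vi + c * vol];
      }
  for (int l = 0; l < K; ++l) {
    if (sizes[l] == 0) continue;
    for (int j = 0; j < 3; ++j) pos(l, j) /= sizes[l];
    for (int c = 0; c < nch; ++c) fm(l, c) /= sizes[l];
  }
  return List::create(_["size"] = sizes, _["center"] = pos,
                      _["features"] = fm);
}

// Binary erosion/dilation by an explicit structuring-element offset list
// (k x 3 integer matrix of voxel offsets). Outside the grid counts as
// background: erosion shrinks at the faces, dilation never reaches out.
// [[Rcpp::export]]
IntegerVector cpp_binary_morph(IntegerVector mask, IntegerMatrix offsets,
                               bool erode) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("expected a 3D array");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t vol = (R_xlen_t)nx * ny * nz;
  int k = offsets.nrow();
  IntegerVector out(vol, 0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t vi = x + nx * (y + (R_xlen_t)ny * z);
        if (erode) {
          if (!mask[vi]) continue; // quick reject: element contains origin
          bool all_in = true;
          for (int j = 0; j < k && all_in; ++j) {
            int xx = x + offsets(j, 0), yy = y + offsets(j, 1),
                zz = z + offsets(j, 2);
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 ||
                zz >= nz || !mask[xx + nx * (yy + (R_xlen_t)ny * zz)])
              all_in = false;
          }
          out[vi] = all_in ? 1 : 0;
        } else {
          bool any = false;
          for (int j = 0; j < k && !any; ++j) {
            int xx = x + offsets(j, 0), yy = y + offsets(j, 1),
                zz = z + offsets(j, 2);
            if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 &&
                zz < nz && mask[xx + nx * (yy + (R_xlen_t)ny * zz)])
              any = true;
          }
          out[vi] = any ? 1 : 0;
        }
      }
  out.attr("dim") = dims;
  return out;
}

// Fill enclosed 3D cavities: background voxels (0) not 6-connected to the
// array boundary become foreground.
// [[Rcpp::export]]
IntegerVector cpp_fill_holes(IntegerVector mask) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("expected a 3D array");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t vol = (R_xlen_t)nx * ny * nz;
  std::vector<char> outside(vol, 0);
  std::vector<R_xlen_t> stack;
  NeighborOffsets nb(6);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        if (x != 0 && x != nx - 1 && y != 0 && y != ny - 1 && z != 0 &&
            z != nz - 1)
          continue;
        R_xlen_t vi = x + nx * (y + (R_xlen_t)ny * z);
        if (!mask[vi] && !outside[vi]) {
          outside[vi] = 1;
          stack.push_back(vi);
        }
      }
  while (!stack.empty()) {
    R_xlen_t cur = stack.back(); stack.pop_back();
    int x = (int)(cur % nx);
    int y = (int)((cur / nx) % ny);
    int z = (int)(cur / ((R_xlen_t)nx * ny));
    for (size_t j = 0; j < nb.dx.size(); ++j) {
      int xx = x + nb.dx[j], yy = y + nb.dy[j], zz = z + nb.dz[j];
      if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
        continue;
      R_xlen_t ni = xx + nx * (yy + (R_xlen_t)ny * zz);
      if (!mask[ni] && !outside[ni]) {
        outside[ni] = 1;
        stack.push_back(ni);
      }
    }
  }
  IntegerVector out(vol);
  for (R_xlen_t i = 0; i < vol; ++i)
    out[i] = mask[i] ? 1 : (outside[i] ? 0 : 1);
  out.attr("dim") = dims;
  return out;
}

// Separable convolution of a 3D volume with one shared 1D kernel along all
// three axes; faces are handled by mirror reflection (edge included).
// [[Rcpp::export]]
NumericVector cpp_sep_conv3(NumericVector vol, NumericVector kernel) {
  IntegerVector dims = vol.attr("dim");
  if (dims.size() != 3) stop("expected a 3D array");
  int klen = kernel.size();
  if (klen % 2 == 0) stop("kernel length must be odd");
  int r = klen / 2;
  int n[3] = {dims[0], dims[1], dims[2]};
  R_xlen_t vtot = (R_xlen_t)n[0] * n[1] * n[2];
  std::vector<double> a(REAL(vol), REAL(vol) + vtot), b(vtot);
  R_xlen_t stride[3] = {1, (R_xlen_t)n[0], (R_xlen_t)n[0] * n[1]};
  for (int axis = 0; axis < 3; ++axis) {
    int len = n[axis];
    R_xlen_t st = stride[axis];
    int o1 = (axis == 0) ? 1 : 0, o2 = (axis == 2) ? 1 : 2;
    int n1 = n[o1], n2 = n[o2];
    R_xlen_t s1 = stride[o1], s2 = stride[o2];
    for (int i2 = 0; i2 < n2; ++i2)
      for (int i1 = 0; i1 < n1; ++i1) {
        R_xlen_t base = i1 * s1 + i2 * s2;
        for (int i = 0; i < len; ++i) {
          double acc = 0.0;
          for (int j = 0; j < klen; ++j) {
            int p = i + j - r;
            if (p < 0) p = -p - 1;          // mirror: -1 -> 0, -2 -> 1
            if (p >= len) p = 2 * len - 1 - p;
            if (p < 0) p = 0;               // guard for tiny axes
            if (p >= len) p = len - 1;
            acc += kernel[j] * a[base + (R_xlen_t)p * st];
          }
          b[base + (R_xlen_t)i * st] = acc;
        }
      }
    std::swap(a, b);
  }
  NumericVector out(vtot);
  std::copy(a.begin(), a.end(), out.begin());
  out.attr("dim") = dims;
  return out;
}
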