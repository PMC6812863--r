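#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Neighbor offsets for 6/18/26 connectivity on a (Z, Y, X) grid.
// 6: face neighbors; 18: face + edge; 26: face + edge + corner.
static std::vector<std::array<int, 3>> neighbor_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int s = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (s == 0) continue;
        if (connectivity == 6 && s > 1) continue;
        if (connectivity == 18 && s > 2) continue;
        off.push_back({dz, dy, dx});
      }
  return off;
}

// Label connected components of a 3D binary mask (dims = Z, Y, X with Z the
// fastest-varying index, i.e. an R array). Labels are 1..K in order of first
// voxel encountered in linear scan order; background stays 0.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const R_xlen_t N = (R_xlen_t)Z * Y * X;
  if (mask.size() != N) stop("mask length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  IntegerVector labels(N, 0);
  const std::vector<std::array<int, 3>> off = neighbor_offsets(connectivity);
  std::vector<R_xlen_t> queue;
  queue.reserve(1024);
  int next_label = 0;
  for (R_xlen_t i = 0; i < N; ++i) {
    if (mask[i] != TRUE || labels[i] != 0) continue;
    ++next_label;
    labels[i] = next_label;
    queue.clear();
    queue.push_back(i);
    while (!queue.empty()) {
      R_xlen_t cur = queue.back();
      queue.pop_back();
      int z = (int)(cur % Z);
      int y = (int)((cur / Z) % Y);
      int x = (int)(cur / ((R_xlen_t)Z * Y));
      for (const auto &o : off) {
        int nz = z + o[0], ny = y + o[1], nx = x + o[2];
        if (nz < 0 || nz >= Z || ny < 0 || ny >= Y || nx < 0 || nx >= X)
          continue;
        R_xlen_t ni = nz + (R_xlen_t)Z * (ny + (R_xlen_t)Y * nx);
        if (mask[ni] == TRUE && labels[ni] == 0) {
          labels[ni] = next_label;
          queue.push_back(ni);
        }
      }
    }
  }
  labels.attr("n_labels") = next_label;
  return labels;
}

// Approximate anisotropic Euclidean distance from every voxel to the nearest
// labeled voxel, carrying that voxel's label, by chamfer propagation over the
// 26-neighborhood with physical step weights. Two forward/backward sweeps.
// Distances are only accurate up to max_dist (propagation is pruned beyond
// it); voxels farther away get dist = Inf and label = 0.
// [[Rcpp::export]]
List nearest_label_cpp(IntegerVector labels, IntegerVector dims,
                       NumericVector spacing_zyx, double max_dist) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const R_xlen_t N = (R_xlen_t)Z * Y * X;
  if (labels.size() != N) stop("labels length does not match dims");
  const double sz = spacing_zyx[0], sy = spacing_zyx[1], sx = spacing_zyx[2];
  const double inf = R_PosInf;
  // propagation cap: one max step beyond max_dist so boundary values settle
  const double step_max = std::sqrt(sz * sz + sy * sy + sx * sx);
  const double cap = max_dist + 2.0 * step_max;

  NumericVector dist(N);
  IntegerVector lab(N, 0);
  for (R_xlen_t i = 0; i < N; ++i) {
    if (labels[i] > 0) {
      dist[i] = 0.0;
      lab[i] = labels[i];
    } else {
      dist[i] = inf;
    }
  }

  // offsets preceding the current voxel in linear (z fastest) scan order
  std::vector<std::array<int, 3>> back;
  std::vector<double> wback;
  for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        R_xlen_t lin = dz + (R_xlen_t)Z * (dy + (R_xlen_t)Y * dx);
        if (lin >= 0) continue;  // keep strictly-preceding neighbors
        back.push_back({dz, dy, dx});
        wback.push_back(std::sqrt(dz * dz * sz * sz + dy * dy * sy * sy +
                                  dx * dx * sx * sx));
      }

  for (int sweep = 0; sweep < 2; ++sweep) {
    // forward sweep
    for (R_xlen_t i = 0; i < N; ++i) {
      int z = (int)(i % Z);
      int y = (int)((i / Z) % Y);
      int x = (int)(i / ((R_xlen_t)Z * Y));
      double best = dist[i];
      int bl = lab[i];
      for (size_t k = 0; k < back.size(); ++k) {
        int nz = z + back[k][0], ny = y + back[k][1], nx = x + back[k][2];
        if (nz < 0 || nz >= Z || ny < 0 || ny >= Y || nx < 0 || nx >= X)
          continue;
        R_xlen_t ni = nz + (R_xlen_t)Z * (ny + (R_xlen_t)Y * nx);
        double d = dist[ni];
        if (d >= cap || d == inf) continue;
        d += wback[k];
        if (d < best) { best = d; bl = lab[ni]; }
      }
      dist[i] = best;
      lab[i] = bl;
    }
    // backward sweep (mirror offsets)
    for (R_xlen_t i = N - 1; i >= 0; --i) {
      int z = (int)(i % Z);
      int y = (int)((i / Z) % Y);
      int x = (int)(i / ((R_xlen_t)Z * Y));
      double best = dist[i];
      int bl = lab[i];
      for (size_t k = 0; k < back.size(); ++k) {
        int nz = z - back[k][0], ny = y - back[k][1], nx = x - back[k][2];
        if (nz < 0 || nz >= Z || ny < 0 || ny >= Y || nx < 0 || nx >= X)
          continue;
        R_xlen_t ni = nz + (R_xlen_t)Z * (ny + (R_xlen_t)Y * nx);
        double d = dist[ni];
        if (d >= cap || d == inf) continue;
        d += wback[k];
        if (d < best) { best = d; bl = lab[ni]; }
      }
      dist[i] = best;
      lab[i] = bl;
      if (i == 0) break;
    }
  }
  // blank out anything beyond the requested horizon
  for (R_xlen_t i = 0; i < N; ++i) {
    if (dist[i] > max_dist) { dist[i] = inf; lab[i] = 0; }
  }
  return List::create(_["dist"] = dist, _["label"] = lab);
}
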