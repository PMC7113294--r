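#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Disc mean filter on an integer image. Disc membership: center distance
// <= radius (Euclidean, on the pixel grid). Borders replicate edge values.
// Output is the arithmetic mean rounded half-up to the nearest integer,
// matching the 8-bit semantics of the raster workflow this reimplements.
// [[Rcpp::export(name = ".disc_mean_cpp")]]
IntegerMatrix disc_mean_cpp(IntegerMatrix img, int radius) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix out(H, W);
  const int* in = INTEGER(img);
  int* o = INTEGER(out);
  if (radius == 0) {
    std::copy(in, in + (size_t)H * W, o);
    return out;
  }
  std::vector<int> dys, dxs;
  for (int dy = -radius; dy <= radius; ++dy)
    for (int dx = -radius; dx <= radius; ++dx)
      if (dy * dy + dx * dx <= radius * radius) {
        dys.push_back(dy);
        dxs.push_back(dx);
      }
  const int K = static_cast<int>(dys.size());
  const double m = static_cast<double>(K);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        int y = i + dys[k];
        int x = j + dxs[k];
        if (y < 0) y = 0; else if (y >= H) y = H - 1;
        if (x < 0) x = 0; else if (x >= W) x = W - 1;
        s += in[(size_t)x * H + y];
      }
      o[(size_t)j * H + i] = static_cast<int>(std::floor(s / m + 0.5));
    }
  }
  return out;
}

// Connected-component labeling of a binary image, 8-connectivity.
// Nonzero pixels are foreground. Returns an integer matrix of labels
// 1..n_components (0 = background), labels ordered by first occurrence
// in column-major scan order.
// [[Rcpp::export(name = ".label_components8_cpp")]]
IntegerMatrix label_components8_cpp(IntegerMatrix img) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix lab(H, W);
  const int* in = INTEGER(img);
  int* lb = INTEGER(lab);
  std::vector<int> parent(1, 0);  // union-find; parent[0] unused

  auto find = [&](int a) {
    while (parent[a] != a) {
      parent[a] = parent[parent[a]];
      a = parent[a];
    }
    return a;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return;
    if (a < b) parent[b] = a; else parent[a] = b;
  };

  int next = 0;
  // first pass, column-major: neighbors already visited are
  // (i-1, j-1), (i, j-1), (i+1, j-1), (i-1, j)
  const int ndy[4] = {-1, 0, 1, -1};
  const int ndx[4] = {-1, -1, -1, 0};
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (in[(size_t)j * H + i] == 0) continue;
      int best = 0;
      for (int k = 0; k < 4; ++k) {
        int y = i + ndy[k], x = j + ndx[k];
        if (y < 0 || y >= H || x < 0 || x >= W) continue;
        int l = lb[(size_t)x * H + y];
        if (l > 0) {
          if (best == 0) best = l;
          else unite(best, l);
        }
      }
      if (best == 0) {
        best = ++next;
        parent.push_back(best);
      }
      lb[(size_t)j * H + i] = best;
    }
  }
  // relabel compactly in order of first appearance
  std::vector<int> remap(next + 1, 0);
  int n_out = 0;
  for (size_t c = 0; c < (size_t)H * W; ++c)
    if (lb[c] > 0) {
      int r = find(lb[c]);
      if (remap[r] == 0) remap[r] = ++n_out;
      lb[c] = remap[r];
    }
  return lab;
}
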