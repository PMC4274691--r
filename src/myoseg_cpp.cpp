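#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 8-connected component labelling of a logical mask.
// Labels are assigned in raster (row-major) order of first encounter,
// consecutively from 1, so the output is deterministic.
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % H, cc = idx / H;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            int nr = cr + dr, nc = cc + dc;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (mask(nr, nc) && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              stack.push_back(nr + nc * H);
            }
          }
        }
      }
    }
  }
  return lab;
}

struct QEntry {
  double value;
  unsigned long long order;
  int idx;
  int label;
};

struct QCompare {
  bool operator()(const QEntry &a, const QEntry &b) const {
    if (a.value != b.value) return a.value > b.value;   // min-heap on value
    return a.order > b.order;                           // FIFO tie-break
  }
};

// Meyer's marker-controlled watershed (8-connected flooding).
// `surface` is the topographic relief (lower floods first); `markers` holds
// positive seed labels; flooding is restricted to `mask`. Masked pixels in a
// component with no marker remain 0.
// [[Rcpp::export(name = ".marker_watershed_cpp")]]
IntegerMatrix marker_watershed_cpp(NumericMatrix surface, IntegerMatrix markers,
                                   LogicalMatrix mask) {
  const int H = surface.nrow(), W = surface.ncol();
  if (markers.nrow() != H || markers.ncol() != W ||
      mask.nrow() != H || mask.ncol() != W)
    stop("surface, markers and mask must share the same shape");
  IntegerMatrix lab(H, W);
  std::priority_queue<QEntry, std::vector<QEntry>, QCompare> pq;
  unsigned long long counter = 0;

  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (markers(r, c) > 0 && mask(r, c)) lab(r, c) = markers(r, c);

  // seed the queue with the unlabelled masked neighbours of every marker pixel
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (lab(r, c) == 0) continue;
      for (int dr = -1; dr <= 1; ++dr) {
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int nr = r + dr, nc = c + dc;
          if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
          if (mask(nr, nc) && lab(nr, nc) == 0) {
            pq.push({surface(nr, nc), counter++, nr + nc * H, lab(r, c)});
          }
        }
      }
    }
  }

  while (!pq.empty()) {
    QEntry e = pq.top();
    pq.pop();
    int r = e.idx % H, c = e.idx / H;
    if (lab(r, c) != 0) continue;
    lab(r, c) = e.label;
    for (int dr = -1; dr <= 1; ++dr) {
      for (int dc = -1; dc <= 1; ++dc) {
        if (dr == 0 && dc == 0) continue;
        int nr = r + dr, nc = c + dc;
        if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
        if (mask(nr, nc) && lab(nr, nc) == 0) {
          pq.push({surface(nr, nc), counter++, nr + nc * H, lab(r, c)});
        }
      }
    }
  }
  return lab;
}
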