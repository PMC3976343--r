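#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling by breadth-first search.
// connectivity: 8 for foreground objects, 4 for background/holes (the
// standard dual pairing that avoids topological paradoxes on the grid).
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = connectivity;
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int r2 = rr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  lab.attr("n_objects") = next;
  return lab;
}

// Fill enclosed holes: background components (4-connected) that do not
// touch the image border are converted to foreground.
// [[Rcpp::export(name = ".cc_fill_holes")]]
LogicalMatrix cc_fill_holes(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix bg(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) bg(r, c) = !mask(r, c);
  IntegerMatrix lab = cc_label(bg, 4);
  int nlab = as<int>(lab.attr("n_objects"));
  std::vector<bool> touches(nlab + 1, false);
  for (int r = 0; r < nr; ++r) {
    if (lab(r, 0) > 0) touches[lab(r, 0)] = true;
    if (lab(r, nc - 1) > 0) touches[lab(r, nc - 1)] = true;
  }
  for (int c = 0; c < nc; ++c) {
    if (lab(0, c) > 0) touches[lab(0, c)] = true;
    if (lab(nr - 1, c) > 0) touches[lab(nr - 1, c)] = true;
  }
  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = mask(r, c) || (lab(r, c) > 0 && !touches[lab(r, c)]);
  return out;
}

// Trace the outer boundary of the filled mask as a closed cycle of pixel-edge
// vertices. Vertex (vy, vx) is the lattice corner between pixel rows vy/vy+1
// and columns vx/vx+1 (0-based: pixel (i, j) [1-based] spans vertices
// (i-1..i, j-1..j)). The walk keeps the filled region on its right; at saddle
// configurations the turn keeps wrapping tightly around the foreground, which
// matches 8-connected objects (the outline pinches through the shared corner).
// Returns an (k+1) x 2 matrix of (vy, vx), closed (last row == first row).
// [[Rcpp::export(name = ".trace_outline")]]
NumericMatrix trace_outline(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  auto filled = [&](int i, int j) {  // 1-based pixel index
    return i >= 1 && i <= nr && j >= 1 && j <= nc && mask(i - 1, j - 1);
  };
  // start: topmost then leftmost filled pixel; its top-left corner
  int si = -1, sj = -1;
  for (int i = 1; i <= nr && si < 0; ++i)
    for (int j = 1; j <= nc; ++j)
      if (filled(i, j)) { si = i; sj = j; break; }
  if (si < 0) stop("empty mask: nothing to trace");
  // vertex coords; directions 0=E,1=S,2=W,3=N as (dy,dx)
  const int dy[4] = {0, 1, 0, -1};
  const int dx[4] = {1, 0, -1, 0};
  // filled-on-right test for an edge leaving vertex (vy,vx) in direction d
  // (edge E spans row boundary vy, columns vx..vx+1, and so on):
  auto right_ok = [&](int vy, int vx, int d) {
    switch (d) {
      case 0: return filled(vy + 1, vx + 1) && !filled(vy, vx + 1);
      case 1: return filled(vy + 1, vx) && !filled(vy + 1, vx + 1);
      case 2: return filled(vy, vx) && !filled(vy + 1, vx);
      default: return filled(vy, vx + 1) && !filled(vy, vx);
    }
  };
  int vy = si - 1, vx = sj - 1, d = 0;  // top-left corner heading east
  if (!right_ok(vy, vx, d)) stop("internal error: bad outline start");
  std::vector<double> ys, xs;
  const int v0y = vy, v0x = vx, d0 = d;
  const long maxsteps = 4L * (nr + 2L) * (nc + 2L) + 8L;
  long steps = 0;
  do {
    ys.push_back(vy); xs.push_back(vx);
    vy += dy[d]; vx += dx[d];
    // try left turn first (tight wrap around foreground), then straight,
    // then right turn
    int cand[3] = {(d + 3) % 4, d, (d + 1) % 4};
    int next = -1;
    for (int k = 0; k < 3; ++k)
      if (right_ok(vy, vx, cand[k])) { next = cand[k]; break; }
    if (next < 0) stop("internal error: outline walk stuck");
    d = next;
    if (++steps > maxsteps) stop("internal error: outline walk diverged");
  } while (!(vy == v0y && vx == v0x && d == d0));
  ys.push_back(v0y); xs.push_back(v0x);
  NumericMatrix out(ys.size(), 2);
  for (size_t i = 0; i < ys.size(); ++i) { out(i, 0) = ys[i]; out(i, 1) = xs[i]; }
  return out;
}
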