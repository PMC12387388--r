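#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Label connected components of TRUE pixels. connectivity is 4 or 8.
// Returns an integer matrix: 0 for FALSE pixels, 1..k component ids,
// assigned in column-major scan order (deterministic).
// [[Rcpp::export(rng = false)]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || labels(r, c) != 0) continue;
      ++next;
      labels(r, c) = next;
      stack.push_back(r + nr * c);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int pr = idx % nr, pc = idx / nr;
        for (int i = 0; i < nnb; ++i) {
          int qr = pr + dr8[i], qc = pc + dc8[i];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) && labels(qr, qc) == 0) {
            labels(qr, qc) = next;
            stack.push_back(qr + nr * qc);
          }
        }
      }
    }
  }
  return labels;
}

// Moore-neighbour boundary tracing (8-connected walk) of the TRUE region,
// starting at the leftmost pixel of the topmost occupied row and stopping by
// Jacob's criterion: the start pixel is re-entered from its initial backtrack
// cell (the cell immediately west of the start). Returns an n x 2 matrix of
// (row, col) 1-based coordinates; the polygon closes last -> first. A
// single-pixel region yields one row.
// [[Rcpp::export(rng = false)]]
IntegerMatrix cpp_trace_boundary(const LogicalMatrix& region) {
  const int nr = region.nrow(), nc = region.ncol();
  int sr = -1, sc = -1;
  for (int r = 0; r < nr && sr < 0; ++r)
    for (int c = 0; c < nc; ++c)
      if (region(r, c)) { sr = r; sc = c; break; }
  if (sr < 0) stop("region has no TRUE pixel");

  // Moore neighbourhood in clockwise screen order starting at W
  const int dr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};

  bool isolated = true;
  for (int d = 0; d < 8; ++d) {
    int qr = sr + dr[d], qc = sc + dc[d];
    if (qr >= 0 && qr < nr && qc >= 0 && qc < nc && region(qr, qc)) {
      isolated = false;
      break;
    }
  }
  if (isolated) {
    IntegerMatrix out(1, 2);
    out(0, 0) = sr + 1; out(0, 1) = sc + 1;
    return out;
  }

  std::vector<int> path_r, path_c;
  path_r.push_back(sr); path_c.push_back(sc);

  int pr = sr, pc = sc;
  int bdir = 0;                       // direction from p to its backtrack cell
  const int b0r = sr, b0c = sc - 1;   // initial backtrack cell (may be off-grid)
  const long maxsteps = 8L * (long)nr * (long)nc + 8;
  long steps = 0;

  while (steps++ < maxsteps) {
    int found = -1, prev = -1;
    for (int i = 1; i <= 8; ++i) {
      int d = (bdir + i) % 8;
      int qr = pr + dr[d], qc = pc + dc[d];
      if (qr >= 0 && qr < nr && qc >= 0 && qc < nc && region(qr, qc)) {
        found = d;
        prev = (d + 7) % 8;  // cell scanned just before the hit
        break;
      }
    }
    int npr = pr + dr[found], npc = pc + dc[found];
    int bcr = pr + dr[prev], bcc = pc + dc[prev];  // new backtrack cell
    if (npr == sr && npc == sc && bcr == b0r && bcc == b0c)
      break;  // back at start, entered from the initial backtrack: done
    path_r.push_back(npr); path_c.push_back(npc);
    // direction index from the new pixel towards its backtrack cell
    int btr = bcr - npr, btc = bcc - npc, nb = 0;
    for (int d = 0; d < 8; ++d)
      if (dr[d] == btr && dc[d] == btc) { nb = d; break; }
    pr = npr; pc = npc; bdir = nb;
  }

  IntegerMatrix out((int)path_r.size(), 2);
  for (size_t i = 0; i < path_r.size(); ++i) {
    out((int)i, 0) = path_r[i] + 1;
    out((int)i, 1) = path_c[i] + 1;
  }
  return out;
}
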