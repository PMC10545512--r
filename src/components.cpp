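#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling for a 3D mask stored as an R array with
// dims (slice, row, col), i.e. linear index = s + ns*r + ns*nr*c (0-based).
//
// Connectivity follows the screening convention for anisotropic SAX stacks:
// 8-neighbour within a slice, optional face adjacency across slices.
// Labels are assigned in order of first (linear-index) encounter, so the
// output is deterministic for a given mask.

// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims,
                           bool across_slice) {
  const int ns = dims[0], nr = dims[1], nc = dims[2];
  const R_xlen_t n = (R_xlen_t)ns * nr * nc;
  if (mask.size() != n) stop("mask length does not match dims");
  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int next_label = 0;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t i = stack.back();
      stack.pop_back();
      int s = (int)(i % ns);
      int r = (int)((i / ns) % nr);
      int c = (int)(i / ((R_xlen_t)ns * nr));
      // in-plane 8-neighbourhood
      for (int dr = -1; dr <= 1; ++dr) {
        int rr = r + dr;
        if (rr < 0 || rr >= nr) continue;
        for (int dc = -1; dc <= 1; ++dc) {
          if (dr == 0 && dc == 0) continue;
          int cc = c + dc;
          if (cc < 0 || cc >= nc) continue;
          R_xlen_t j = s + (R_xlen_t)ns * rr + (R_xlen_t)ns * nr * cc;
          if (mask[j] && labels[j] == 0) {
            labels[j] = next_label;
            stack.push_back(j);
          }
        }
      }
      if (across_slice) {
        for (int ds = -1; ds <= 1; ds += 2) {
          int ss = s + ds;
          if (ss < 0 || ss >= ns) continue;
          R_xlen_t j = ss + (R_xlen_t)ns * r + (R_xlen_t)ns * nr * c;
          if (mask[j] && labels[j] == 0) {
            labels[j] = next_label;
            stack.push_back(j);
          }
        }
      }
    }
  }
  labels.attr("dim") = dims;
  labels.attr("n_components") = next_label;
  return labels;
}

// Per-slice 2D labelling (8-connectivity), with labels unique across the
// whole stack but never joined across slices. Equivalent to calling
// cc_label_cpp slice by slice; kept separate to avoid R-level copying.

// [[Rcpp::export]]
IntegerVector cc_label_slices_cpp(LogicalVector mask, IntegerVector dims) {
  return cc_label_cpp(mask, dims, false);
}
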