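#include <Rcpp.h>
#include <deque>
#include <vector>

// Directed flag complex enumeration.
//
// A directed k-simplex is an ordered tuple (v0, ..., vk) of distinct
// vertices such that the edge vi -> vj exists for every i < j.  The
// enumeration extends ordered cliques by vertices in the intersection of
// the out-neighbourhoods of all current members, so each simplex is
// produced exactly once.  Input is the out-adjacency in CSR form with
// sorted, 0-based column indices.

static void intersect_sorted(const int *a, int na, const int *b, int nb,
                             std::vector<int> &out) {
  out.clear();
  int i = 0, j = 0;
  while (i < na && j < nb) {
    if (a[i] < b[j]) {
      ++i;
    } else if (a[i] > b[j]) {
      ++j;
    } else {
      out.push_back(a[i]);
      ++i;
      ++j;
    }
  }
}

struct FlagEnumerator {
  const int *indptr;
  const int *indices;
  int max_dim;   // largest dimension to enumerate; -1 for unbounded
  int list_dim;  // record tuples for dim <= list_dim; -1 records nothing
  std::vector<double> counts;
  std::vector<std::vector<int>> tuples;  // flattened, by dimension
  std::vector<int> cur;
  // deque: growing it must not invalidate references held by
  // shallower recursion frames
  std::deque<std::vector<int>> bufs;
  long long ticker;

  FlagEnumerator(const int *ip, const int *ix, int md, int ld)
      : indptr(ip), indices(ix), max_dim(md), list_dim(ld), ticker(0) {}

  void visit(int dim) {
    if ((int)counts.size() <= dim) counts.resize(dim + 1, 0.0);
    counts[dim] += 1.0;
    if (list_dim >= 0 && dim <= list_dim) {
      if ((int)tuples.size() <= dim) tuples.resize(dim + 1);
      tuples[dim].insert(tuples[dim].end(), cur.begin(), cur.end());
    }
    if (++ticker % 1048576 == 0) Rcpp::checkUserInterrupt();
  }

  // cand holds the common out-neighbours of the vertices in cur; cur has
  // dim + 1 vertices.
  void extend(const std::vector<int> &cand, int dim) {
    if (max_dim >= 0 && dim >= max_dim) return;
    while ((int)bufs.size() <= dim) bufs.emplace_back();
    std::vector<int> &nxt = bufs[dim];
    for (size_t t = 0; t < cand.size(); ++t) {
      int w = cand[t];
      intersect_sorted(cand.data(), (int)cand.size(), indices + indptr[w],
                       indptr[w + 1] - indptr[w], nxt);
      cur.push_back(w);
      visit(dim + 1);
      extend(nxt, dim + 1);
      cur.pop_back();
    }
  }
};

// [[Rcpp::export]]
Rcpp::List flag_complex_cpp(Rcpp::IntegerVector indptr,
                            Rcpp::IntegerVector indices, int n_vertices,
                            int max_dim, int list_dim) {
  FlagEnumerator en(indptr.begin(), indices.begin(), max_dim, list_dim);
  std::vector<int> root;
  for (int v = 0; v < n_vertices; ++v) {
    en.cur.assign(1, v);
    en.visit(0);
    root.assign(indices.begin() + indptr[v], indices.begin() + indptr[v + 1]);
    en.extend(root, 0);
  }
  Rcpp::NumericVector counts(en.counts.begin(), en.counts.end());
  Rcpp::List tuples;
  if (list_dim >= 0) {
    for (size_t d = 0; d < en.tuples.size(); ++d) {
      const std::vector<int> &flat = en.tuples[d];
      int width = (int)d + 1;
      int rows = flat.empty() ? 0 : (int)(flat.size() / width);
      Rcpp::IntegerMatrix m(rows, width);
      for (int r = 0; r < rows; ++r)
        for (int c = 0; c < width; ++c) m(r, c) = flat[(size_t)r * width + c];
      tuples.push_back(m);
    }
  }
  return Rcpp::List::create(Rcpp::Named("counts") = counts,
                            Rcpp::Named("tuples") = tuples);
}
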