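#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// FP-growth over dense discretized matrices. Every row is a transaction of
// exactly k items (one bin per metric); an item is encoded metric * n_levels
// + bin. Frequent itemsets never contain two items from the same metric by
// construction, matching the "one value per dimension" pattern definition.

struct FPNode {
  int item;
  int count;
  int parent;
};

class FPTree {
public:
  std::vector<FPNode> nodes;
  std::vector<std::unordered_map<int, int> > children;
  std::unordered_map<int, std::vector<int> > header;

  FPTree() {
    FPNode root;
    root.item = -1; root.count = 0; root.parent = -1;
    nodes.push_back(root);
    children.push_back(std::unordered_map<int, int>());
  }

  // items must already be sorted in the global frequency order
  void insert(const std::vector<int>& items, int count) {
    int cur = 0;
    for (size_t i = 0; i < items.size(); ++i) {
      int it = items[i];
      std::unordered_map<int, int>& ch = children[cur];
      std::unordered_map<int, int>::iterator f = ch.find(it);
      int nxt;
      if (f == ch.end()) {
        nxt = (int) nodes.size();
        FPNode nd; nd.item = it; nd.count = 0; nd.parent = cur;
        nodes.push_back(nd);
        children.push_back(std::unordered_map<int, int>());
        children[cur][it] = nxt;   // re-index: push_back may have moved ch
        header[it].push_back(nxt);
      } else {
        nxt = f->second;
      }
      nodes[nxt].count += count;
      cur = nxt;
    }
  }
};

static void mine_tree(const FPTree& tree,
                      std::vector<int>& suffix,
                      int min_count, int max_len,
                      std::vector<std::vector<int> >& out_items,
                      std::vector<int>& out_counts) {
  // items present in this (conditional) tree with their total counts
  std::vector<std::pair<int, int> > item_counts;
  for (std::unordered_map<int, std::vector<int> >::const_iterator kv = tree.header.begin();
       kv != tree.header.end(); ++kv) {
    int tot = 0;
    for (size_t i = 0; i < kv->second.size(); ++i) tot += tree.nodes[kv->second[i]].count;
    if (tot >= min_count) item_counts.push_back(std::make_pair(kv->first, tot));
  }
  std::sort(item_counts.begin(), item_counts.end()); // deterministic order

  for (size_t ii = 0; ii < item_counts.size(); ++ii) {
    int item = item_counts[ii].first;
    std::vector<int> pat = suffix;
    pat.push_back(item);
    out_items.push_back(pat);
    out_counts.push_back(item_counts[ii].second);
    if ((int) pat.size() >= max_len) continue;

    // conditional pattern base: prefix paths of every node carrying `item`
    std::vector<std::pair<std::vector<int>, int> > paths;
    std::unordered_map<int, int> cond_counts;
    const std::vector<int>& nids = tree.header.at(item);
    for (size_t i = 0; i < nids.size(); ++i) {
      int cnt = tree.nodes[nids[i]].count;
      std::vector<int> path;
      int p = tree.nodes[nids[i]].parent;
      while (p > 0) {
        path.push_back(tree.nodes[p].item);
        p = tree.nodes[p].parent;
      }
      if (path.empty()) continue;
      std::reverse(path.begin(), path.end()); // root -> leaf, keeps global order
      paths.push_back(std::make_pair(path, cnt));
      for (size_t j = 0; j < path.size(); ++j) cond_counts[path[j]] += cnt;
    }
    if (paths.empty()) continue;

    FPTree cond;
    for (size_t i = 0; i < paths.size(); ++i) {
      std::vector<int> filt;
      for (size_t j = 0; j < paths[i].first.size(); ++j) {
        int x = paths[i].first[j];
        if (cond_counts[x] >= min_count) filt.push_back(x);
      }
      if (!filt.empty()) cond.insert(filt, paths[i].second);
    }
    if (!cond.header.empty())
      mine_tree(cond, pat, min_count, max_len, out_items, out_counts);
  }
}

// [[Rcpp::export]]
List fpgrowth_mine_cpp(IntegerMatrix disc, int n_levels, double min_support, int max_len) {
  int n = disc.nrow(), k = disc.ncol();
  if (n < 1) stop("empty matrix");
  int min_count = (int) std::ceil(min_support * n - 1e-9);
  if (min_count < 1) min_count = 1;
  if (max_len < 1 || max_len > k) max_len = k;

  int n_items = k * n_levels;
  std::vector<int> item_count(n_items, 0);
  for (int j = 0; j < k; ++j)
    for (int i = 0; i < n; ++i)
      item_count[j * n_levels + disc(i, j)]++;

  std::vector<int> order_rank(n_items, -1);
  std::vector<int> sorted;
  for (int it = 0; it < n_items; ++it)
    if (item_count[it] >= min_count) sorted.push_back(it);
  std::sort(sorted.begin(), sorted.end(), [&](int a, int b) {
    if (item_count[a] != item_count[b]) return item_count[a] > item_count[b];
    return a < b;
  });
  for (size_t r = 0; r < sorted.size(); ++r) order_rank[sorted[r]] = (int) r;

  FPTree tree;
  std::vector<int> trans;
  trans.reserve(k);
  for (int i = 0; i < n; ++i) {
    trans.clear();
    for (int j = 0; j < k; ++j) {
      int it = j * n_levels + disc(i, j);
      if (order_rank[it] >= 0) trans.push_back(it);
    }
    std::sort(trans.begin(), trans.end(), [&](int a, int b) {
      return order_rank[a] < order_rank[b];
    });
    if (!trans.empty()) tree.insert(trans, 1);
  }

  std::vector<std::vector<int> > out_items;
  std::vector<int> out_counts;
  std::vector<int> suffix;
  mine_tree(tree, suffix, min_count, max_len, out_items, out_counts);

  // flatten: lengths + concatenated item codes
  int total = 0;
  for (size_t i = 0; i < out_items.size(); ++i) total += (int) out_items[i].size();
  IntegerVector lens(out_items.size()), flat(total), counts(out_items.size());
  int pos = 0;
  for (size_t i = 0; i < out_items.size(); ++i) {
    std::vector<int> pat = out_items[i];
    std::sort(pat.begin(), pat.end());
    lens[i] = (int) pat.size();
    counts[i] = out_counts[i];
    for (size_t j = 0; j < pat.size(); ++j) flat[pos++] = pat[j];
  }
  return List::create(_["lengths"] = lens, _["items"] = flat, _["counts"] = counts,
                      _["n"] = n);
}

// Per-group match counts for a list of patterns.
// group: 0-based group index per row; metric_idx/bin_val: per-pattern
// integer vectors (0-based metric column, bin value).
// [[Rcpp::export]]
NumericMatrix pattern_match_counts_cpp(IntegerMatrix disc, IntegerVector group,
                                       int n_groups, List metric_idx, List bin_val) {
  int P = metric_idx.size();
  int n = disc.nrow();
  NumericMatrix out(n_groups, P);
  for (int p = 0; p < P; ++p) {
    IntegerVector m = metric_idx[p];
    IntegerVector b = bin_val[p];
    int L = m.size();
    for (int i = 0; i < n; ++i) {
      bool ok = true;
      for (int l = 0; l < L; ++l) {
        if (disc(i, m[l]) != b[l]) { ok = false; break; }
      }
      if (ok) out(group[i], p) += 1.0;
    }
  }
  return out;
}
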