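#include <Rcpp.h>
using namespace Rcpp;

// SURVIVOR-style single-linkage-free greedy breakpoint clustering.
//
// Calls must arrive sorted by start (ties: end, then source). Seeds are taken
// in that order; each seed recruits, per foreign source, the nearest
// unassigned call whose start AND end both lie within max_dist of the seed's
// breakpoints (distance = max(|dstart|, |dend|); ties -> smaller start, then
// input order). A cluster therefore never holds two calls from one source,
// and the seed order makes the result invariant to the caller/individual
// ordering of the input.
//
// [[Rcpp::export]]
IntegerVector cluster_breakpoints_cpp(IntegerVector start, IntegerVector end,
                                      IntegerVector source, IntegerVector type,
                                      int max_dist, bool match_type) {
  const int n = start.size();
  IntegerVector cluster(n, NA_INTEGER);
  int next_id = 0;
  for (int i = 0; i < n; ++i) {
    if (cluster[i] != NA_INTEGER) continue;
    const int id = ++next_id;
    cluster[i] = id;
    // scan the window of candidates around the seed (sorted by start)
    int lo = i;
    while (lo > 0 && start[i] - start[lo - 1] <= max_dist) --lo;
    int hi = i;
    while (hi + 1 < n && start[hi + 1] - start[i] <= max_dist) ++hi;
    // best candidate per foreign source
    std::map<int, int> best;       // source -> index
    std::map<int, int> best_dist;  // source -> distance
    for (int j = lo; j <= hi; ++j) {
      if (j == i || cluster[j] != NA_INTEGER) continue;
      if (source[j] == source[i]) continue;
      if (match_type && type[j] != type[i]) continue;
      int ds = std::abs(start[j] - start[i]);
      int de = std::abs(end[j] - end[i]);
      if (ds > max_dist || de > max_dist) continue;
      int d = std::max(ds, de);
      std::map<int, int>::iterator it = best.find(source[j]);
      bool take = false;
      if (it == best.end()) {
        take = true;
      } else {
        int k = it->second;
        int dk = best_dist[source[j]];
        if (d < dk) take = true;
        else if (d == dk && start[j] < start[k]) take = true;
      }
      if (take) { best[source[j]] = j; best_dist[source[j]] = d; }
    }
    for (std::map<int, int>::iterator it = best.begin(); it != best.end(); ++it)
      cluster[it->second] = id;
  }
  return cluster;
}
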