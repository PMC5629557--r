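#include <Rcpp.h>
#include <algorithm>
#include <cstdlib>
#include <string>
#include <vector>

using namespace Rcpp;

// Large-but-safe sentinel: never returned, only used inside the DP.
static const int kInf = INT_MAX / 4;

// Banded global edit distance (unit costs). The band constrains the total
// number of indels along the alignment path: a path with |i - j| > band at
// any point has more than `band` unbalanced indels, so restricting the DP
// to the diagonal band |i - j| <= band enforces the indel budget exactly.
// Returns -1 (infeasible sentinel) when no alignment within the band exists,
// in particular when the length difference alone exceeds the band.
// [[Rcpp::export(name = ".C_banded_edit_distance")]]
int C_banded_edit_distance(const std::string& a, const std::string& b, int band) {
    const int m = (int)a.size();
    const int n = (int)b.size();
    if (band < 0) return -1;
    if (std::abs(m - n) > band) return -1;

    std::vector<int> prev(n + 1, kInf), cur(n + 1, kInf);
    for (int j = 0; j <= std::min(n, band); ++j) prev[j] = j;
    for (int i = 1; i <= m; ++i) {
        const int lo = std::max(0, i - band);
        const int hi = std::min(n, i + band);
        std::fill(cur.begin() + lo, cur.begin() + hi + 1, kInf);
        // poison the cells flanking the band: the swapped row buffers hold
        // stale values from two rows back there, which would let the DP
        // step through out-of-band cells
        if (lo > 0) cur[lo - 1] = kInf;
        if (hi < n) cur[hi + 1] = kInf;
        if (lo == 0) cur[0] = i;
        for (int j = std::max(1, lo); j <= hi; ++j) {
            int d = kInf;
            if (prev[j - 1] < kInf) d = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
            if (prev[j] < kInf && prev[j] + 1 < d) d = prev[j] + 1;      // delete a[i]
            if (cur[j - 1] < kInf && cur[j - 1] + 1 < d) d = cur[j - 1] + 1;  // insert b[j]
            cur[j] = d;
        }
        std::swap(prev, cur);
    }
    return prev[n] >= kInf ? -1 : prev[n];
}

// Fit a whole component string s against prefixes of t, under the same
// diagonal band. Only prefixes p with ||p| - |s|| <= band are candidates.
// Returns c(distance, consumed): the minimum banded distance over candidate
// prefixes and the length of the best prefix (ties broken toward the longer
// prefix, i.e. toward consuming the full component length).
// distance is -1 when no candidate prefix is feasible.
// [[Rcpp::export(name = ".C_fit_prefix")]]
IntegerVector C_fit_prefix(const std::string& s, const std::string& t, int band) {
    const int m = (int)s.size();
    if (m == 0) return IntegerVector::create(0, 0);
    if (band < 0) return IntegerVector::create(-1, 0);
    const int n = std::min((int)t.size(), m + band);

    std::vector<int> prev(n + 1, kInf), cur(n + 1, kInf);
    for (int j = 0; j <= std::min(n, band); ++j) prev[j] = j;
    for (int i = 1; i <= m; ++i) {
        const int lo = std::max(0, i - band);
        const int hi = std::min(n, i + band);
        if (lo > hi) return IntegerVector::create(-1, 0);
        std::fill(cur.begin() + lo, cur.begin() + hi + 1, kInf);
        if (lo > 0) cur[lo - 1] = kInf;
        if (hi < n) cur[hi + 1] = kInf;
        if (lo == 0) cur[0] = i;
        for (int j = std::max(1, lo); j <= hi; ++j) {
            int d = kInf;
            if (prev[j - 1] < kInf) d = prev[j - 1] + (s[i - 1] == t[j - 1] ? 0 : 1);
            if (prev[j] < kInf && prev[j] + 1 < d) d = prev[j] + 1;
            if (cur[j - 1] < kInf && cur[j - 1] + 1 < d) d = cur[j - 1] + 1;
            cur[j] = d;
        }
        std::swap(prev, cur);
    }

    int best = kInf, best_j = -1;
    for (int j = std::max(0, m - band); j <= std::min(n, m + band); ++j) {
        if (prev[j] < kInf && (prev[j] < best || (prev[j] == best && j > best_j))) {
            best = prev[j];
            best_j = j;
        }
    }
    if (best >= kInf) return IntegerVector::create(-1, 0);
    return IntegerVector::create(best, best_j);
}
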