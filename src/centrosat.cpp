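#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Unit-cost Levenshtein.  With cutoff >= 0 a banded DP (Ukkonen) is used:
// when the true distance exceeds the cutoff, cutoff + 1 is returned.
static int lev(const std::string& a, const std::string& b, int cutoff) {
    const int n = a.size(), m = b.size();
    const int BIG = INT_MAX / 4;
    if (cutoff < 0) {
        std::vector<int> prev(m + 1), cur(m + 1);
        for (int j = 0; j <= m; ++j) prev[j] = j;
        for (int i = 1; i <= n; ++i) {
            cur[0] = i;
            for (int j = 1; j <= m; ++j) {
                int sub = prev[j - 1] + (a[i - 1] != b[j - 1]);
                int del = prev[j] + 1;
                int ins = cur[j - 1] + 1;
                int v = sub < del ? sub : del;
                if (ins < v) v = ins;
                cur[j] = v;
            }
            std::swap(prev, cur);
        }
        return prev[m];
    }
    const int k = cutoff;
    if (std::abs(n - m) > k) return k + 1;
    std::vector<int> prev(m + 2, BIG), cur(m + 2, BIG);
    for (int j = 0; j <= std::min(m, k); ++j) prev[j] = j;
    for (int i = 1; i <= n; ++i) {
        const int lo = std::max(1, i - k), hi = std::min(m, i + k);
        if (lo > 1) cur[lo - 1] = BIG; else cur[0] = (i <= k) ? i : BIG;
        int rowmin = BIG;
        for (int j = lo; j <= hi; ++j) {
            int sub = prev[j - 1] + (a[i - 1] != b[j - 1]);
            int del = prev[j] + 1;
            int ins = cur[j - 1] + 1;
            int v = sub < del ? sub : del;
            if (ins < v) v = ins;
            cur[j] = v;
            if (v < rowmin) rowmin = v;
        }
        if (hi + 1 <= m) cur[hi + 1] = BIG;   // kill stale band edges
        if (rowmin > k) return k + 1;
        std::swap(prev, cur);
    }
    return prev[m] > k ? k + 1 : prev[m];
}

// [[Rcpp::export]]
IntegerVector cpp_edit_distance(CharacterVector a, CharacterVector b,
                                int cutoff = -1) {
    R_xlen_t n = std::max(a.size(), b.size());
    IntegerVector out(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string sa = as<std::string>(a[i % a.size()]);
        std::string sb = as<std::string>(b[i % b.size()]);
        out[i] = lev(sa, sb, cutoff);
    }
    return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_edit_distance_matrix(CharacterVector x, CharacterVector y,
                                       int cutoff = -1) {
    R_xlen_t n = x.size(), m = y.size();
    std::vector<std::string> xs(n), ys(m);
    for (R_xlen_t i = 0; i < n; ++i) xs[i] = as<std::string>(x[i]);
    for (R_xlen_t j = 0; j < m; ++j) ys[j] = as<std::string>(y[j]);
    IntegerMatrix out(n, m);
    for (R_xlen_t i = 0; i < n; ++i)
        for (R_xlen_t j = 0; j < m; ++j)
            out(i, j) = lev(xs[i], ys[j], cutoff);
    return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_self_edit_distance(CharacterVector x, int cutoff = -1) {
    R_xlen_t n = x.size();
    std::vector<std::string> xs(n);
    for (R_xlen_t i = 0; i < n; ++i) xs[i] = as<std::string>(x[i]);
    IntegerMatrix out(n, n);
    for (R_xlen_t i = 0; i < n; ++i) {
        out(i, i) = 0;
        for (R_xlen_t j = i + 1; j < n; ++j) {
            int d = lev(xs[i], xs[j], cutoff);
            out(i, j) = d;
            out(j, i) = d;
        }
    }
    return out;
}

// Chained tiling DP: partition the sequence into consecutive blocks, each
// scored as a full global alignment of the template, minimizing total edit
// cost (the StringDecomposer contract).  A[r][j] = best cost of completely
// tiling some prefix s[1..j'] (j' <= j) plus a partial alignment of the
// template prefix t[1..r] against s[j'+1..j].  Block starts are propagated
// along the arg-min so boundaries can be recovered without the full matrix.
// Returns the 1-based start position of the block ending at each sequence
// position (for positions where a block can end, i.e., all of them).
// [[Rcpp::export]]
List cpp_decompose(std::string s, std::string t) {
    const int n = s.size(), m = t.size();
    const int INF = INT_MAX / 4;
    std::vector<int> Aprev(m + 1), Acur(m + 1);
    std::vector<int> Sprev(m + 1), Scur(m + 1);   // block start of partial align
    std::vector<int> beststart(n + 1, 1);          // start of block ending at j
    std::vector<int> cost(n + 1, 0);               // C[j]
    // column 0: nothing consumed; template prefix all deleted
    for (int r = 0; r <= m; ++r) { Aprev[r] = r; Sprev[r] = 1; }
    cost[0] = 0;
    for (int j = 1; j <= n; ++j) {
        Acur[0] = INF; Scur[0] = j + 1;
        for (int r = 1; r <= m; ++r) {
            int sub = Aprev[r - 1] + (s[j - 1] != t[r - 1]);
            int ins = Aprev[r] + 1;           // extra sequence base inside block
            int del = Acur[r - 1] + 1;        // template char skipped
            int v = sub, st = Sprev[r - 1];
            if (ins < v) { v = ins; st = Sprev[r]; }
            if (del < v) { v = del; st = Scur[r - 1]; }
            Acur[r] = v; Scur[r] = st;
        }
        cost[j] = Acur[m];
        beststart[j] = Scur[m];
        // a fresh block may begin right after j (and may open with deletions)
        Acur[0] = cost[j]; Scur[0] = j + 1;
        for (int r = 1; r <= m; ++r) {
            if (Acur[r - 1] + 1 < Acur[r]) {
                Acur[r] = Acur[r - 1] + 1;
                Scur[r] = Scur[r - 1];
            }
        }
        std::swap(Aprev, Acur);
        std::swap(Sprev, Scur);
    }
    // trace back block boundaries
    std::vector<int> starts, ends;
    int pos = n;
    while (pos > 0) {
        int st = beststart[pos];
        if (st > pos) st = pos;   // degenerate guard
        starts.push_back(st);
        ends.push_back(pos);
        pos = st - 1;
    }
    std::reverse(starts.begin(), starts.end());
    std::reverse(ends.begin(), ends.end());
    return List::create(_["start"] = wrap(starts), _["end"] = wrap(ends),
                        _["cost"] = cost[n]);
}
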