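#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>

using namespace Rcpp;

// 2-bit encode A/C/G/T; anything else (N, ...) is invalid.
static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// Exact k-mer anchors between two sequences, collapsed into maximal
// same-diagonal segments and then joined across short same-diagonal gaps
// (mismatches counted from the sequences). Coordinates are 0-based
// half-open on both sequences. k must be <= 31 (2-bit packing).
//
// Returns a numeric matrix with columns:
//   start_a, end_a, start_b, end_b, matches
// where matches is the number of identical columns within the segment.
// [[Rcpp::export(name = ".kmer_anchor_segments")]]
NumericMatrix kmer_anchor_segments(const std::string& a, const std::string& b,
                                   int k, int max_occ, int join_gap) {
    if (k < 2 || k > 31) stop("k must be in [2, 31]");
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);

    // index k-mers of b
    std::unordered_map<uint64_t, std::vector<int> > idx;
    idx.reserve(b.size());
    {
        uint64_t h = 0; int valid = 0;
        for (size_t i = 0; i < b.size(); ++i) {
            int c = base_code(b[i]);
            if (c < 0) { valid = 0; h = 0; continue; }
            h = ((h << 2) | (uint64_t)c) & mask;
            if (++valid >= k) {
                std::vector<int>& v = idx[h];
                if ((int)v.size() <= max_occ) v.push_back((int)(i + 1 - k));
            }
        }
    }

    // scan a; group anchors by diagonal (i - j), collapsing consecutive
    // same-diagonal k-mer hits into segments on the fly
    struct Seg { int sa, ea, sb, mism; };  // end_b = sb + (ea - sa)
    std::unordered_map<int64_t, std::vector<Seg> > by_diag;
    {
        uint64_t h = 0; int valid = 0;
        for (size_t i = 0; i < a.size(); ++i) {
            int c = base_code(a[i]);
            if (c < 0) { valid = 0; h = 0; continue; }
            h = ((h << 2) | (uint64_t)c) & mask;
            if (++valid < k) continue;
            std::unordered_map<uint64_t, std::vector<int> >::iterator it = idx.find(h);
            if (it == idx.end()) continue;
            if ((int)it->second.size() > max_occ) continue;  // repetitive k-mer
            int pos_a = (int)(i + 1 - k);
            for (size_t m = 0; m < it->second.size(); ++m) {
                int pos_b = it->second[m];
                int64_t diag = (int64_t)pos_a - (int64_t)pos_b;
                std::vector<Seg>& segs = by_diag[diag];
                if (!segs.empty() && pos_a <= segs.back().ea) {
                    // overlaps/extends previous segment on this diagonal
                    if (pos_a + k > segs.back().ea) segs.back().ea = pos_a + k;
                } else {
                    Seg s; s.sa = pos_a; s.ea = pos_a + k; s.sb = pos_b; s.mism = 0;
                    segs.push_back(s);
                }
            }
        }
    }

    // join same-diagonal segments across gaps <= join_gap, counting mismatches
    std::vector<Seg> out;
    for (std::unordered_map<int64_t, std::vector<Seg> >::iterator it = by_diag.begin();
         it != by_diag.end(); ++it) {
        std::vector<Seg>& segs = it->second;  // already sorted by sa (scan order)
        Seg cur = segs[0];
        for (size_t s = 1; s < segs.size(); ++s) {
            int gap = segs[s].sa - cur.ea;
            if (gap <= join_gap) {
                // count mismatching columns in the gap
                int mm = 0;
                int off = (int)(cur.sb - cur.sa);  // -diag
                for (int p = cur.ea; p < segs[s].sa; ++p)
                    if (a[p] != b[p + off]) ++mm;
                cur.mism += mm;
                cur.ea = segs[s].ea > cur.ea ? segs[s].ea : cur.ea;
            } else {
                out.push_back(cur);
                cur = segs[s];
            }
        }
        out.push_back(cur);
    }

    NumericMatrix res((int)out.size(), 5);
    for (size_t r = 0; r < out.size(); ++r) {
        int len = out[r].ea - out[r].sa;
        res(r, 0) = out[r].sa;
        res(r, 1) = out[r].ea;
        res(r, 2) = out[r].sb;
        res(r, 3) = out[r].sb + len;
        res(r, 4) = len - out[r].mism;
    }
    colnames(res) = CharacterVector::create("start_a", "end_a", "start_b",
                                            "end_b", "matches");
    return res;
}

// Longest run of TRUE in a logical vector.
// [[Rcpp::export(name = ".max_true_run")]]
int max_true_run(LogicalVector x) {
    int best = 0, cur = 0;
    for (int i = 0; i < x.size(); ++i) {
        if (x[i] == TRUE) { if (++cur > best) best = cur; }
        else cur = 0;
    }
    return best;
}

// Null distribution of the max-TRUE-run statistic under random permutation
// of the vector (Fisher-Yates using R's RNG, so results are reproducible
// under set.seed()).
// [[Rcpp::export(name = ".perm_max_runs")]]
IntegerVector perm_max_runs(LogicalVector x, int n_perm) {
    int n = x.size();
    std::vector<int> v(n);
    for (int i = 0; i < n; ++i) v[i] = (x[i] == TRUE) ? 1 : 0;
    IntegerVector res(n_perm);
    GetRNGstate();
    for (int p = 0; p < n_perm; ++p) {
        for (int i = n - 1; i > 0; --i) {
            int j = (int)(unif_rand() * (i + 1));
            if (j > i) j = i;
            int tmp = v[i]; v[i] = v[j]; v[j] = tmp;
        }
        int best = 0, cur = 0;
        for (int i = 0; i < n; ++i) {
            if (v[i]) { if (++cur > best) best = cur; }
            else cur = 0;
        }
        res[p] = best;
    }
    PutRNGstate();
    return res;
}
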