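#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Unit-cost local alignment (match +1, mismatch -1, gap -1).
// Among co-optimal alignments the one with the fewest edited bases is
// returned; ties are broken deterministically by the DP sweep order.
// The lexicographic (score desc, edits asc) objective is encoded as a
// single additive integer key: score * SCORE_W - edits. This is exact as
// long as the total number of edits on any path stays below SCORE_W.
static const int SCORE_W = 8192;

// [[Rcpp::export]]
List cpp_local_align(std::string q, std::string r) {
    const int n = (int)q.size(), m = (int)r.size();
    if (n == 0 || m == 0 || (double)n * (double)m > 4e8)
        stop("sequences empty or too long for local alignment");
    std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
    // direction per cell: 0 restart, 1 diag, 2 up (read base inserted),
    // 3 left (reference base deleted)
    std::vector<uint8_t> dir((size_t)(n + 1) * (m + 1), 0);
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        cur[0] = 0;
        const char qc = q[i - 1];
        uint8_t* drow = &dir[(size_t)i * (m + 1)];
        for (int j = 1; j <= m; ++j) {
            int d = prev[j - 1] + (qc == r[j - 1] ? SCORE_W : -(SCORE_W + 1));
            int u = prev[j] - (SCORE_W + 1);
            int l = cur[j - 1] - (SCORE_W + 1);
            int v = d;
            uint8_t dd = 1;
            if (u > v) { v = u; dd = 2; }
            if (l > v) { v = l; dd = 3; }
            if (v <= 0) { v = 0; dd = 0; }
            cur[j] = v;
            drow[j] = dd;
            if (v > best) { best = v; bi = i; bj = j; }
        }
        std::swap(prev, cur);
    }
    if (best <= 0)
        return List::create(Named("score") = 0);
    int i = bi, j = bj;
    int matches = 0, mism = 0, ins = 0, del = 0;
    while (i > 0 && j > 0) {
        uint8_t dd = dir[(size_t)i * (m + 1) + j];
        if (dd == 0) break;
        if (dd == 1) {
            if (q[i - 1] == r[j - 1]) ++matches; else ++mism;
            --i; --j;
        } else if (dd == 2) { ++ins; --i; }
        else { ++del; --j; }
    }
    int score = matches - mism - ins - del;
    return List::create(
        Named("score") = score,
        Named("matches") = matches,
        Named("mismatches") = mism,
        Named("inserted_bases") = ins,
        Named("deleted_bases") = del,
        Named("query_aligned_bases") = matches + mism + ins,
        Named("q_start") = i + 1, Named("q_end") = bi,
        Named("r_start") = j + 1, Named("r_end") = bj);
}

static inline int base_code(char c) {
    switch (c) {
        case 'A': return 0; case 'C': return 1;
        case 'G': return 2; case 'T': return 3;
        default: return -1;
    }
}

// For every read, the (1-based) indices of references sharing at least one
// exact k-mer with it. One hash over all references, one scan per read.
// [[Rcpp::export]]
List cpp_seed_hits(CharacterVector reads, CharacterVector refs, int k) {
    if (k < 1 || k > 31) stop("seed length must be in [1, 31]");
    std::unordered_map<uint64_t, std::vector<int>> index;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    for (int t = 0; t < refs.size(); ++t) {
        std::string s = as<std::string>(refs[t]);
        uint64_t h = 0; int run = 0;
        for (size_t p = 0; p < s.size(); ++p) {
            int c = base_code(s[p]);
            if (c < 0) { run = 0; h = 0; continue; }
            h = ((h << 2) | (uint64_t)c) & mask;
            if (++run >= k) {
                std::vector<int>& v = index[h];
                if (v.empty() || v.back() != t + 1) v.push_back(t + 1);
            }
        }
    }
    List out(reads.size());
    for (int i = 0; i < reads.size(); ++i) {
        std::string s = as<std::string>(reads[i]);
        std::vector<char> seen(refs.size() + 1, 0);
        std::vector<int> hits;
        uint64_t h = 0; int run = 0;
        for (size_t p = 0; p < s.size(); ++p) {
            int c = base_code(s[p]);
            if (c < 0) { run = 0; h = 0; continue; }
            h = ((h << 2) | (uint64_t)c) & mask;
            if (++run >= k) {
                auto it = index.find(h);
                if (it != index.end())
                    for (int t : it->second)
                        if (!seen[t]) { seen[t] = 1; hits.push_back(t); }
            }
        }
        std::sort(hits.begin(), hits.end());
        out[i] = IntegerVector(hits.begin(), hits.end());
    }
    return out;
}

static int lcs_len(const char* a, int n, const char* b, int m,
                   std::vector<int>& prev, std::vector<int>& cur) {
    for (int j = 0; j <= m; ++j) prev[j] = 0;
    for (int i = 1; i <= n; ++i) {
        cur[0] = 0;
        const char ac = a[i - 1];
        for (int j = 1; j <= m; ++j) {
            int v = (ac == b[j - 1]) ? prev[j - 1] + 1 : 0;
            if (prev[j] > v) v = prev[j];
            if (cur[j - 1] > v) v = cur[j - 1];
            cur[j] = v;
        }
        std::swap(prev, cur);
    }
    return prev[m];
}

// Cyclic LCS: max over all rotations of b of LCS(a, rotation(b)).
// [[Rcpp::export]]
int cpp_rotation_lcs(std::string a, std::string b) {
    const int n = (int)a.size(), m = (int)b.size();
    if (n == 0 || m == 0) stop("empty sequence");
    const int cap = n < m ? n : m;
    if (n == m) {  // exact-rotation fast path
        std::string bb = b + b;
        if (bb.find(a) != std::string::npos) return n;
    }
    std::string b2 = b + b;
    std::vector<int> prev(m + 1), cur(m + 1);
    int best = 0;
    for (int r = 0; r < m; ++r) {
        int v = lcs_len(a.c_str(), n, b2.c_str() + r, m, prev, cur);
        if (v > best) best = v;
        if (best == cap) break;
    }
    return best;
}
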