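#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Symbol codes used throughout: 0 = terminator '$', 1 = separator/N,
// 2 = A, 3 = C, 4 = G, 5 = T. Patterns may only use codes 2..5; the
// separator and N classes never match, so no seed can span a record
// junction, the forward/reverse-complement boundary, or a run of Ns.

static const int N_SYM = 6;

// Suffix array by prefix doubling with radix (counting) sort, O(n log n).
static std::vector<int> suffix_array(const std::vector<int>& s) {
    int n = (int)s.size();
    std::vector<int> sa(n), r(n), nr(n), tmp(n);
    int alpha = 0;
    for (int v : s) alpha = std::max(alpha, v);
    alpha++;
    {
        std::vector<int> cnt(alpha + 1, 0);
        for (int i = 0; i < n; i++) cnt[s[i] + 1]++;
        for (int c = 0; c < alpha; c++) cnt[c + 1] += cnt[c];
        for (int i = 0; i < n; i++) sa[cnt[s[i]]++] = i;
        r[sa[0]] = 0;
        for (int i = 1; i < n; i++)
            r[sa[i]] = r[sa[i - 1]] + (s[sa[i]] != s[sa[i - 1]] ? 1 : 0);
    }
    for (int k = 1; k < n; k <<= 1) {
        int classes = r[sa[n - 1]] + 1;
        if (classes == n) break;
        int p = 0;
        for (int i = n - k; i < n; i++) tmp[p++] = i;
        for (int i = 0; i < n; i++)
            if (sa[i] >= k) tmp[p++] = sa[i] - k;
        std::vector<int> cnt(classes + 1, 0);
        for (int i = 0; i < n; i++) cnt[r[i] + 1]++;
        for (int c = 0; c < classes; c++) cnt[c + 1] += cnt[c];
        for (int i = 0; i < n; i++) sa[cnt[r[tmp[i]]]++] = tmp[i];
        nr[sa[0]] = 0;
        for (int i = 1; i < n; i++) {
            int a = sa[i - 1], b = sa[i];
            int a2 = (a + k < n) ? r[a + k] : -1;
            int b2 = (b + k < n) ? r[b + k] : -1;
            nr[b] = nr[a] + ((r[a] != r[b] || a2 != b2) ? 1 : 0);
        }
        std::swap(r, nr);
    }
    return sa;
}

// Build suffix array, BWT, cumulative counts and sampled occurrence table
// (checkpoint every 64 positions) over `text` (codes, terminator appended
// here).
// [[Rcpp::export]]
List fm_build_cpp(IntegerVector text) {
    int L = text.size();
    std::vector<int> s(L + 1);
    for (int i = 0; i < L; i++) {
        int v = text[i];
        if (v < 1 || v >= N_SYM) stop("invalid symbol code in text");
        s[i] = v;
    }
    s[L] = 0;
    int n = L + 1;
    std::vector<int> sa = suffix_array(s);

    IntegerVector sa_out(n);
    RawVector bwt(n);
    for (int i = 0; i < n; i++) {
        sa_out[i] = sa[i];
        bwt[i] = (Rbyte)(sa[i] > 0 ? s[sa[i] - 1] : 0);
    }
    IntegerVector C(N_SYM + 1, 0);
    for (int i = 0; i < n; i++) C[s[i] + 1]++;
    for (int c = 0; c < N_SYM; c++) C[c + 1] += C[c];

    int ncp = n / 64 + 1;
    IntegerVector occ(ncp * N_SYM, 0);
    std::vector<int> run(N_SYM, 0);
    for (int i = 0; i <= n; i++) {  // <= n: the rank query occ_rank(c, n)
        if (i % 64 == 0)            // must see a checkpoint when 64 | n
            for (int c = 0; c < N_SYM; c++) occ[(i / 64) * N_SYM + c] = run[c];
        if (i < n) run[bwt[i]]++;
    }
    return List::create(_["sa"] = sa_out, _["bwt"] = bwt, _["cnt"] = C,
                        _["occ"] = occ, _["n"] = n);
}

static inline int occ_rank(const Rbyte* bwt, const int* occ, int c, int i) {
    // occurrences of c in bwt[0 .. i-1]
    int cp = i >> 6;
    int cnt = occ[cp * N_SYM + c];
    for (int j = cp << 6; j < i; j++)
        if (bwt[j] == (Rbyte)c) cnt++;
    return cnt;
}

static inline void bs_extend(const Rbyte* bwt, const int* C, const int* occ,
                             int c, int lo, int hi, int* lo2, int* hi2) {
    if (c < 2 || c >= N_SYM || lo > hi) { *lo2 = 0; *hi2 = -1; return; }
    *lo2 = C[c] + occ_rank(bwt, occ, c, lo);
    *hi2 = C[c] + occ_rank(bwt, occ, c, hi + 1) - 1;
    if (*lo2 > *hi2) { *lo2 = 0; *hi2 = -1; }
}

// One backward-search step: SA range of symbol.pattern given range of pattern.
// [[Rcpp::export]]
IntegerVector fm_extend_cpp(RawVector bwt, IntegerVector cnt, IntegerVector occ,
                            int lo, int hi, int sym) {
    int lo2, hi2;
    bs_extend(RAW(bwt), INTEGER(cnt), INTEGER(occ), sym, lo, hi, &lo2, &hi2);
    return IntegerVector::create(lo2, hi2);
}

// Backward search of a full pattern (codes); empty pattern = full range.
// [[Rcpp::export]]
IntegerVector fm_search_cpp(RawVector bwt, IntegerVector cnt, IntegerVector occ,
                            int n, IntegerVector pattern) {
    int lo = 0, hi = n - 1;
    for (int i = pattern.size() - 1; i >= 0; i--) {
        bs_extend(RAW(bwt), INTEGER(cnt), INTEGER(occ), pattern[i], lo, hi,
                  &lo, &hi);
        if (lo > hi) return IntegerVector::create(0, -1);
    }
    return IntegerVector::create(lo, hi);
}

static inline int comp_code(int c) {
    switch (c) {
    case 2: return 5; case 5: return 2;
    case 3: return 4; case 4: return 3;
    default: return -1;
    }
}

// Scan a query (codes) left to right for local maximal exact matches.
// The match of Q[j1..j] is extended forward by prepending the complement of
// Q[j+1] to a backward search, i.e. by tracking the SA range of
// revcomp(Q[j1..j]) in the index over P + P'. Hits in the P' half are
// forward-strand seeds; hits in the P half are reverse-strand seeds.
//
// jbegin    : 1-based chain start
// jlimit    : last 1-based start position for regular emission
// warmup    : discard the first extension attempt (block handoff)
// extra     : after passing jlimit, emit one more LMEM then stop
// sensitive : restart at j1 + stride instead of after the LMEM
//
// Returns a matrix with columns i1 (global 0-based start of the matched
// interval on the forward concatenated reference), j1 (1-based, forward
// query frame), len, strand (0 = forward, 1 = reverse), occ (SA range width).
// [[Rcpp::export]]
IntegerMatrix lmem_scan_cpp(IntegerVector sa, RawVector bwt, IntegerVector cnt,
                            IntegerVector occ, int n, int lc,
                            IntegerVector q, int k, int f,
                            bool sensitive, int stride,
                            int jbegin, int jlimit, bool warmup, bool extra) {
    const Rbyte* B = RAW(bwt);
    const int* C = INTEGER(cnt);
    const int* O = INTEGER(occ);
    const int* SA = INTEGER(sa);
    int qlen = q.size();
    std::vector<int> out_i1, out_j1, out_len, out_strand, out_occ;
    int j1 = jbegin;
    bool first = true;
    bool past = false;
    while (j1 <= qlen) {
        if (j1 > jlimit) {
            if (!extra || sensitive) break;
            past = true;
        }
        // extend from j1
        int lo = 0, hi = n - 1;
        int j = j1 - 1;  // last matched position (1-based), none yet
        while (j < qlen) {
            int c = comp_code(q[j]);  // q is 0-based: q[j] is Q[j+1]
            if (c < 0) break;
            int lo2, hi2;
            bs_extend(B, C, O, c, lo, hi, &lo2, &hi2);
            if (lo2 > hi2) break;
            lo = lo2; hi = hi2; j++;
        }
        int m = j - j1 + 1;
        bool discard = warmup && first;
        first = false;
        if (m >= 1 && !discard) {
            int width = hi - lo + 1;
            if (m >= k && width < f) {
                for (int t = lo; t <= hi; t++) {
                    int p = SA[t];
                    if (p <= lc - m) {
                        // P half: reverse-strand seed
                        out_i1.push_back(p);
                        out_strand.push_back(1);
                    } else if (p >= lc + 1 && p + m <= 2 * lc + 1) {
                        // P' half: forward-strand seed
                        int o = p - (lc + 1);
                        out_i1.push_back(lc - o - m);
                        out_strand.push_back(0);
                    } else {
                        continue;  // cannot happen: matches never span junctions
                    }
                    out_j1.push_back(j1);
                    out_len.push_back(m);
                    out_occ.push_back(width);
                }
                if (past) break;
            }
        }
        if (sensitive) j1 = j1 + stride;
        else j1 = (m >= 1) ? j + 1 : j1 + 1;
    }
    int nr = (int)out_i1.size();
    IntegerMatrix res(nr, 5);
    for (int i = 0; i < nr; i++) {
        res(i, 0) = out_i1[i];
        res(i, 1) = out_j1[i];
        res(i, 2) = out_len[i];
        res(i, 3) = out_strand[i];
        res(i, 4) = out_occ[i];
    }
    colnames(res) = CharacterVector::create("i1", "j1", "len", "strand", "occ");
    return res;
}
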