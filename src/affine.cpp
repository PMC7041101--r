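#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
#include <cstdlib>
using namespace Rcpp;

// Global (end-to-end) pairwise alignment with an affine gap penalty:
// a gap of length L costs gap_open + L * gap_extend. Scores are integers.
// Op codes: 0 '=', 1 'X', 2 'I' (consumes b / query), 3 'D' (consumes a /
// reference). Traceback ties are broken deterministically: diagonal over
// deletion over insertion, and gap runs prefer to extend (left-most opening).
//
// When the full matrix would exceed max_cells the DP falls back to a banded
// matrix around the main diagonal (half-width |n-m| + 2048); the `banded`
// flag in the result reports this.

static const int NEG = INT_MIN / 4;

// [[Rcpp::export]]
List affine_align_cpp(std::string a, std::string b, int match, int mismatch,
                      int gap_open, int gap_extend, double max_cells) {
    int n = (int)a.size(), m = (int)b.size();

    if (n == 0 || m == 0) {
        if (n == 0 && m == 0)
            return List::create(_["score"] = 0, _["ops"] = IntegerVector(0),
                                _["lens"] = IntegerVector(0),
                                _["banded"] = false);
        int len = std::max(n, m);
        int op = (n == 0) ? 2 : 3;
        return List::create(_["score"] = -(gap_open + len * gap_extend),
                            _["ops"] = IntegerVector::create(op),
                            _["lens"] = IntegerVector::create(len),
                            _["banded"] = false);
    }

    long long cells = (long long)(n + 1) * (long long)(m + 1);
    bool banded = cells > (long long)max_cells;
    int w = banded ? (std::abs(n - m) + 2048) : (std::max(n, m) + 1);

    std::vector<int> lo(n + 1), hi(n + 1);
    for (int i = 0; i <= n; i++) {
        int center = (int)((double)i * m / (double)n);
        lo[i] = std::max(0, center - w);
        hi[i] = std::min(m, center + w);
    }
    lo[0] = 0;
    hi[n] = m;

    std::vector<size_t> rowoff(n + 2);
    rowoff[0] = 0;
    for (int i = 0; i <= n; i++) rowoff[i + 1] = rowoff[i] + (hi[i] - lo[i] + 1);
    std::vector<unsigned char> tb(rowoff[n + 1], 0);

    std::vector<int> pm(m + 1, NEG), pe(m + 1, NEG), pf(m + 1, NEG);
    std::vector<int> cm(m + 1, NEG), ce(m + 1, NEG), cf(m + 1, NEG);

    // row 0: only insertion runs along b
    for (int j = lo[0]; j <= hi[0]; j++) {
        unsigned char t = 0;
        if (j == 0) {
            cm[j] = 0; ce[j] = NEG; cf[j] = NEG;
        } else {
            cm[j] = NEG; ce[j] = NEG;
            cf[j] = -(gap_open + j * gap_extend);
            t = (unsigned char)(((j == 1 ? 1 : 0) & 3) << 4); // F from M or F
        }
        tb[rowoff[0] + (j - lo[0])] = t;
    }
    std::swap(pm, cm); std::swap(pe, ce); std::swap(pf, cf);
    int lop = lo[0], hip = hi[0];

    for (int i = 1; i <= n; i++) {
        for (int j = lo[i]; j <= hi[i]; j++) {
            cm[j] = ce[j] = cf[j] = NEG;
            unsigned char t = 0;
            bool up_ok = (j >= lop && j <= hip);
            bool diag_ok = (j - 1 >= lop && j - 1 <= hip);
            bool left_ok = (j - 1 >= lo[i]);

            // E: gap in b, consumes a (deletion), from row i-1 same column
            if (up_ok) {
                int cont = (pe[j] > NEG) ? pe[j] - gap_extend : NEG;
                int fromM = (pm[j] > NEG) ? pm[j] - gap_open - gap_extend : NEG;
                int fromF = (pf[j] > NEG) ? pf[j] - gap_open - gap_extend : NEG;
                int bestE = cont; int orig = 0;
                if (fromM > bestE) { bestE = fromM; orig = 1; }
                if (fromF > bestE) { bestE = fromF; orig = 2; }
                if (bestE > NEG) { ce[j] = bestE; t |= (unsigned char)((orig & 3) << 2); }
            }
            // F: gap in a, consumes b (insertion), from column j-1 same row
            if (left_ok) {
                int cont = (cf[j - 1] > NEG) ? cf[j - 1] - gap_extend : NEG;
                int fromM = (cm[j - 1] > NEG) ? cm[j - 1] - gap_open - gap_extend : NEG;
                int fromE = (ce[j - 1] > NEG) ? ce[j - 1] - gap_open - gap_extend : NEG;
                int bestF = cont; int orig = 0;
                if (fromM > bestF) { bestF = fromM; orig = 1; }
                if (fromE > bestF) { bestF = fromE; orig = 2; }
                if (bestF > NEG) { cf[j] = bestF; t |= (unsigned char)((orig & 3) << 4); }
            }
            // M: diagonal
            if (j >= 1 && diag_ok) {
                int bestP = pm[j - 1]; int orig = 0;
                if (pe[j - 1] > bestP) { bestP = pe[j - 1]; orig = 1; }
                if (pf[j - 1] > bestP) { bestP = pf[j - 1]; orig = 2; }
                if (bestP > NEG) {
                    int s = (a[i - 1] == b[j - 1]) ? match : -mismatch;
                    cm[j] = bestP + s;
                    t |= (unsigned char)(orig & 3);
                }
            }
            tb[rowoff[i] + (j - lo[i])] = t;
        }
        // clear stale values outside the new band in prev arrays
        std::swap(pm, cm); std::swap(pe, ce); std::swap(pf, cf);
        lop = lo[i]; hip = hi[i];
    }

    // final cell
    int sM = pm[m], sE = pe[m], sF = pf[m];
    int state = 0, score = sM;
    if (sE > score) { score = sE; state = 1; }
    if (sF > score) { score = sF; state = 2; }
    if (score <= NEG) stop("alignment band too narrow; no path found");

    // traceback
    std::vector<unsigned char> rops;
    rops.reserve(n + m);
    int i = n, j = m;
    while (i > 0 || j > 0) {
        unsigned char t = tb[rowoff[i] + (j - lo[i])];
        if (state == 0) {
            rops.push_back(a[i - 1] == b[j - 1] ? 0 : 1);
            state = t & 3;
            i--; j--;
        } else if (state == 1) {
            rops.push_back(3); // D
            int orig = (t >> 2) & 3;
            state = (orig == 0) ? 1 : (orig == 1 ? 0 : 2);
            i--;
        } else {
            rops.push_back(2); // I
            int orig = (t >> 4) & 3;
            state = (orig == 0) ? 2 : (orig == 1 ? 0 : 1);
            j--;
        }
    }

    // reverse + run-length encode
    std::vector<int> ops, lens;
    for (int p = (int)rops.size() - 1; p >= 0; p--) {
        int op = rops[p];
        if (!ops.empty() && ops.back() == op) lens.back()++;
        else { ops.push_back(op); lens.push_back(1); }
    }
    return List::create(_["score"] = score, _["ops"] = wrap(ops),
                        _["lens"] = wrap(lens), _["banded"] = banded);
}

// Positions (1-based) where two equal-length strings differ.
// [[Rcpp::export]]
IntegerVector mismatch_positions_cpp(std::string a, std::string b) {
    if (a.size() != b.size()) stop("fragments must have equal length");
    std::vector<int> pos;
    for (size_t i = 0; i < a.size(); i++)
        if (a[i] != b[i]) pos.push_back((int)i + 1);
    return wrap(pos);
}
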