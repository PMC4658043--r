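#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

// Affine-gap Smith-Waterman (Gotoh) carrying (score, matches, length)
// lexicographically: maximise score, then matches, then minimise alignment
// length. This fixes a deterministic identity among co-optimal alignments.
// A gap of length L costs gapOpen + L * gapExt.

namespace {

struct Tri {
    long long s;  // alignment score
    int m;        // identical aligned residue pairs
    int l;        // alignment length, gap columns included
};

const long long NEG = LLONG_MIN / 4;

inline bool better(const Tri& a, const Tri& b) {
    if (a.s != b.s) return a.s > b.s;
    if (a.m != b.m) return a.m > b.m;
    return a.l < b.l;
}

inline Tri best(const Tri& a, const Tri& b) { return better(a, b) ? a : b; }

} // namespace

// [[Rcpp::export(name = ".sw_identity")]]
List sw_identity(std::string a, std::string b, IntegerMatrix sub,
                 std::string alphabet, int gapOpen, int gapExt) {
    const int n = a.size(), m = b.size();
    if (n == 0 || m == 0) stop("sequences must be non-empty");

    int idx[256];
    std::fill(idx, idx + 256, -1);
    for (size_t i = 0; i < alphabet.size(); ++i)
        idx[(unsigned char)alphabet[i]] = (int)i;
    std::vector<int> ai(n), bi(m);
    for (int i = 0; i < n; ++i) {
        ai[i] = idx[(unsigned char)a[i]];
        if (ai[i] < 0) stop("residue '%s' not in scoring alphabet",
                            std::string(1, a[i]));
    }
    for (int j = 0; j < m; ++j) {
        bi[j] = idx[(unsigned char)b[j]];
        if (bi[j] < 0) stop("residue '%s' not in scoring alphabet",
                            std::string(1, b[j]));
    }

    const Tri ZERO = {0, 0, 0};
    const Tri NONE = {NEG, 0, 0};
    const long long open1 = (long long)gapOpen + gapExt;

    // rolling rows over b
    std::vector<Tri> Mp(m + 1, NONE), Xp(m + 1, NONE), Yp(m + 1, NONE);
    std::vector<Tri> Mc(m + 1, NONE), Xc(m + 1, NONE), Yc(m + 1, NONE);
    Tri bestTri = ZERO;

    for (int i = 1; i <= n; ++i) {
        Mc[0] = NONE; Xc[0] = NONE; Yc[0] = NONE;
        for (int j = 1; j <= m; ++j) {
            // M: a[i-1] aligned to b[j-1]; local restart allowed
            Tri pred = best(best(Mp[j - 1], Xp[j - 1]),
                            best(Yp[j - 1], ZERO));
            int sc = sub(ai[i - 1], bi[j - 1]);
            bool eq = a[i - 1] == b[j - 1];
            Mc[j] = {pred.s + sc, pred.m + (eq ? 1 : 0), pred.l + 1};
            if (Mc[j].s < 0) Mc[j] = NONE;  // never extend a losing local path

            // X: gap in b (consume a[i-1])
            Tri fromM = (Mp[j].s <= NEG) ? NONE
                : Tri{Mp[j].s - open1, Mp[j].m, Mp[j].l + 1};
            Tri fromX = (Xp[j].s <= NEG) ? NONE
                : Tri{Xp[j].s - gapExt, Xp[j].m, Xp[j].l + 1};
            Xc[j] = best(fromM, fromX);

            // Y: gap in a (consume b[j-1])
            Tri fromM2 = (Mc[j - 1].s <= NEG) ? NONE
                : Tri{Mc[j - 1].s - open1, Mc[j - 1].m, Mc[j - 1].l + 1};
            Tri fromY = (Yc[j - 1].s <= NEG) ? NONE
                : Tri{Yc[j - 1].s - gapExt, Yc[j - 1].m, Yc[j - 1].l + 1};
            Yc[j] = best(fromM2, fromY);

            if (Mc[j].s > NEG) bestTri = best(bestTri, Mc[j]);
        }
        std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    }

    double identity = bestTri.l > 0 ? (double)bestTri.m / bestTri.l : 0.0;
    return List::create(_["score"] = (double)bestTri.s,
                        _["matches"] = bestTri.m,
                        _["length"] = bestTri.l,
                        _["identity"] = identity);
}
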