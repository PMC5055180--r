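#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Affine-gap global (Needleman-Wunsch) alignment of one read against the
// center sequence. Scoring: match +1, mismatch -1, first gap base -2, each
// further gap base -1 (i.e. a length-L gap costs 1 + L).
//
// The result is expressed in center coordinates: for every center position
// an aligned read character ('-' if deleted in the read), plus, for every
// inter-base slot of the center (0..n), the read bases inserted there.
struct PairAln {
    std::string aligned;                 // length = center length
    std::vector<std::string> inserts;    // length = center length + 1
};

static const int NEG = -1000000000;

static PairAln nw_to_center(const std::string& center, const std::string& read,
                            int match, int mismatch, int gap_open, int gap_ext) {
    const int n = (int)center.size();   // columns
    const int m = (int)read.size();     // rows
    // M: center[i] aligned to read[j]; X: gap in read (center consumed);
    // Y: gap in center (read consumed, i.e. insertion)
    std::vector<int> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
        Y((n + 1) * (m + 1), NEG);
    std::vector<unsigned char> tbM((n + 1) * (m + 1)), tbX((n + 1) * (m + 1)),
        tbY((n + 1) * (m + 1));
#define IDX(i, j) ((i) * (m + 1) + (j))
    M[IDX(0, 0)] = 0;
    for (int i = 1; i <= n; ++i) {
        X[IDX(i, 0)] = -gap_open - (i - 1) * gap_ext;
        tbX[IDX(i, 0)] = (i == 1) ? 0 : 1; // from M / from X
    }
    for (int j = 1; j <= m; ++j) {
        Y[IDX(0, j)] = -gap_open - (j - 1) * gap_ext;
        tbY[IDX(0, j)] = (j == 1) ? 0 : 1;
    }
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            int s = (center[i - 1] == read[j - 1]) ? match : mismatch;
            // M
            int a = M[IDX(i - 1, j - 1)], b = X[IDX(i - 1, j - 1)],
                c = Y[IDX(i - 1, j - 1)];
            int best = a; unsigned char tb = 0;
            if (b > best) { best = b; tb = 1; }
            if (c > best) { best = c; tb = 2; }
            M[IDX(i, j)] = (best <= NEG / 2) ? NEG : best + s;
            tbM[IDX(i, j)] = tb;
            // X: gap in read, consume center i
            a = M[IDX(i - 1, j)] - gap_open;
            b = X[IDX(i - 1, j)] - gap_ext;
            if (a >= b) { X[IDX(i, j)] = a; tbX[IDX(i, j)] = 0; }
            else        { X[IDX(i, j)] = b; tbX[IDX(i, j)] = 1; }
            // Y: gap in center, consume read j
            a = M[IDX(i, j - 1)] - gap_open;
            b = Y[IDX(i, j - 1)] - gap_ext;
            if (a >= b) { Y[IDX(i, j)] = a; tbY[IDX(i, j)] = 0; }
            else        { Y[IDX(i, j)] = b; tbY[IDX(i, j)] = 1; }
        }
    }
    // traceback from best of the three at (n, m)
    int state = 0; // 0 M, 1 X, 2 Y
    int bm = M[IDX(n, m)], bx = X[IDX(n, m)], by = Y[IDX(n, m)];
    if (bx > bm && bx >= by) state = 1;
    else if (by > bm && by > bx) state = 2;

    PairAln out;
    out.aligned.assign(n, '-');
    out.inserts.assign(n + 1, std::string());
    int i = n, j = m;
    while (i > 0 || j > 0) {
        if (state == 0) {
            unsigned char tb = tbM[IDX(i, j)];
            out.aligned[i - 1] = read[j - 1];
            --i; --j;
            state = tb;
        } else if (state == 1) {
            unsigned char tb = tbX[IDX(i, j)];
            // center base i deleted in read: aligned[i-1] stays '-'
            --i;
            state = (tb == 0) ? 0 : 1;
        } else {
            unsigned char tb = tbY[IDX(i, j)];
            out.inserts[i] = read.substr(j - 1, 1) + out.inserts[i];
            --j;
            state = (tb == 0) ? 0 : 2;
        }
    }
#undef IDX
    return out;
}

//' @noRd
// [[Rcpp::export(name = ".C_star_align")]]
CharacterVector C_star_align(CharacterVector reads, int match = 1,
                             int mismatch = -1, int gap_open = 2,
                             int gap_ext = 1) {
    const int k = reads.size();
    if (k == 0) stop("empty read set");
    std::vector<std::string> rs(k);
    for (int i = 0; i < k; ++i) rs[i] = as<std::string>(reads[i]);
    // center = longest read, first on ties
    int ci = 0;
    for (int i = 1; i < k; ++i)
        if (rs[i].size() > rs[ci].size()) ci = i;
    const std::string& center = rs[ci];
    const int n = (int)center.size();

    std::vector<PairAln> alns(k);
    for (int i = 0; i < k; ++i) {
        if (i == ci) continue;
        alns[i] = nw_to_center(center, rs[i], match, mismatch, gap_open, gap_ext);
    }
    // master frame: max insert length per slot ("once a gap, always a gap")
    std::vector<int> slot(n + 1, 0);
    for (int i = 0; i < k; ++i) {
        if (i == ci) continue;
        for (int s = 0; s <= n; ++s)
            if ((int)alns[i].inserts[s].size() > slot[s])
                slot[s] = (int)alns[i].inserts[s].size();
    }
    CharacterVector out(k);
    for (int i = 0; i < k; ++i) {
        std::string row;
        for (int s = 0; s < n; ++s) {
            std::string ins = (i == ci) ? std::string() : alns[i].inserts[s];
            row += ins + std::string(slot[s] - ins.size(), '-');
            row += (i == ci) ? center[s] : alns[i].aligned[s];
        }
        std::string ins = (i == ci) ? std::string() : alns[i].inserts[n];
        row += ins + std::string(slot[n] - ins.size(), '-');
        out[i] = row;
    }
    return out;
}
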