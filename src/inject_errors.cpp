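#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Per-base sequencing error model: before each template base a random base is
// inserted with probability `ins`; the base itself is deleted with
// probability `del`, otherwise substituted by one of the three other bases
// with probability `sub`. Uses R's RNG (deterministic under set.seed()).

static inline char random_base() {
    static const char B[4] = {'A', 'C', 'G', 'T'};
    return B[(int)(unif_rand() * 4.0) & 3];
}

static inline char random_other(char c) {
    char b = random_base();
    while (b == c) b = random_base();
    return b;
}

//' @noRd
// [[Rcpp::export(name = ".C_inject_errors")]]
CharacterVector C_inject_errors(CharacterVector seqs, double sub, double ins,
                                double del) {
    const int n = seqs.size();
    CharacterVector out(n);
    std::string buf;
    for (int i = 0; i < n; ++i) {
        const char* s = CHAR(STRING_ELT(seqs, i));
        buf.clear();
        for (const char* p = s; *p; ++p) {
            if (ins > 0 && unif_rand() < ins) buf += random_base();
            if (del > 0 && unif_rand() < del) continue;
            if (sub > 0 && unif_rand() < sub) buf += random_other(*p);
            else buf += *p;
        }
        out[i] = buf;
    }
    return out;
}
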