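#include <Rcpp.h>
#include <unordered_set>
#include <cstring>
using namespace Rcpp;

// Hamming distance with early exit once the count exceeds cutoff.
static inline int hamming_le(const char *a, const char *b, int len, int cutoff) {
    int d = 0;
    for (int i = 0; i < len; ++i) {
        if (a[i] != b[i] && ++d > cutoff) return d;
    }
    return d;
}

// [[Rcpp::export]]
int cpp_hamming(std::string a, std::string b) {
    if (a.size() != b.size())
        stop("sequences must have equal length (%d vs %d)",
             (int)a.size(), (int)b.size());
    int d = 0;
    for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) ++d;
    return d;
}

// For each sequence, TRUE if at least one *other* sequence of the set lies
// within Hamming distance <= radius. All sequences must share one length.
// [[Rcpp::export]]
LogicalVector cpp_has_neighbor(CharacterVector seqs, int radius) {
    int n = seqs.size();
    LogicalVector out(n);
    if (n < 2) return out;
    std::vector<const char *> p(n);
    int len = (int)std::strlen(CHAR(STRING_ELT(seqs, 0)));
    for (int i = 0; i < n; ++i) {
        p[i] = CHAR(STRING_ELT(seqs, i));
        if ((int)std::strlen(p[i]) != len)
            stop("sequence %d has length %d, expected %d",
                 i + 1, (int)std::strlen(p[i]), len);
    }
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            if (out[i] && out[j]) continue;
            if (hamming_le(p[i], p[j], len, radius) <= radius) {
                out[i] = true;
                out[j] = true;
            }
        }
    }
    return out;
}

// Classify each query fragment against a target set: 1 = identical member
// exists, 2 = nearest member within max_mismatch under either strand
// alignment, 0 = none. target_rc holds the reverse complements of target,
// in the same order. Exact matches are resolved through a hash set; the
// similarity scan aborts a pair as soon as the mismatch count exceeds
// max_mismatch.
// [[Rcpp::export]]
IntegerVector cpp_match_class(CharacterVector query, CharacterVector target,
                              CharacterVector target_rc, int max_mismatch) {
    int nq = query.size(), nt = target.size();
    IntegerVector out(nq);
    if (nt == 0) return out;
    int len = (int)std::strlen(CHAR(STRING_ELT(target, 0)));
    std::unordered_set<std::string> exact;
    std::vector<const char *> t(nt), trc(nt);
    for (int j = 0; j < nt; ++j) {
        t[j] = CHAR(STRING_ELT(target, j));
        trc[j] = CHAR(STRING_ELT(target_rc, j));
        if ((int)std::strlen(t[j]) != len)
            stop("target sequence %d has length %d, expected %d",
                 j + 1, (int)std::strlen(t[j]), len);
        exact.insert(std::string(t[j]));
    }
    for (int i = 0; i < nq; ++i) {
        const char *q = CHAR(STRING_ELT(query, i));
        if ((int)std::strlen(q) != len)
            stop("query sequence %d has length %d, expected %d",
                 i + 1, (int)std::strlen(q), len);
        if (exact.count(std::string(q))) {
            out[i] = 1;
            continue;
        }
        int cls = 0;
        for (int j = 0; j < nt; ++j) {
            if (hamming_le(q, t[j], len, max_mismatch) <= max_mismatch ||
                hamming_le(q, trc[j], len, max_mismatch) <= max_mismatch) {
                cls = 2;
                break;
            }
        }
        out[i] = cls;
    }
    return out;
}
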