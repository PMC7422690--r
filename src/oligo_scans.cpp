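#include <Rcpp.h>
#include <cctype>
using namespace Rcpp;

// 4-bit encoding of IUPAC codes: A=1, C=2, G=4, T=8; degenerate codes are
// unions. Compatibility of two codes == non-empty intersection of masks.
static inline int iupac_mask(char c) {
    switch (std::toupper(static_cast<unsigned char>(c))) {
    case 'A': return 1;
    case 'C': return 2;
    case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'R': return 5;   // A/G
    case 'Y': return 10;  // C/T
    case 'S': return 6;   // C/G
    case 'W': return 9;   // A/T
    case 'K': return 12;  // G/T
    case 'M': return 3;   // A/C
    case 'B': return 14;  // C/G/T
    case 'D': return 13;  // A/G/T
    case 'H': return 11;  // A/C/T
    case 'V': return 7;   // A/C/G
    case 'N': return 15;
    default:  return 0;
    }
}

// Watson-Crick complement of a mask (A<->T, C<->G), applied bitwise.
static inline int comp_mask(int m) {
    int r = 0;
    if (m & 1) r |= 8;
    if (m & 8) r |= 1;
    if (m & 2) r |= 4;
    if (m & 4) r |= 2;
    return r;
}

// Slides `a` against revcomp(b) over all ungapped offsets and reports the
// longest contiguous complementary (IUPAC-compatible) run, the longest such
// run anchored at a 3' terminus of either oligo, and the offset of the best
// run. Offset s aligns a[i] (0-based) with revcomp(b)[i + s].
// [[Rcpp::export(name = ".duplex_scan_cpp")]]
List duplex_scan_cpp(std::string a, std::string b) {
    const int n = a.size(), m = b.size();
    std::vector<int> am(n), rbm(m);
    for (int i = 0; i < n; ++i) am[i] = iupac_mask(a[i]);
    // revcomp(b) position j corresponds to complement of b[m - 1 - j]
    for (int j = 0; j < m; ++j) rbm[j] = comp_mask(iupac_mask(b[m - 1 - j]));

    int max_run = 0, best_offset = 0, three_prime = 0;
    for (int s = -(n - 1); s <= m - 1; ++s) {
        const int i0 = std::max(0, -s), i1 = std::min(n - 1, m - 1 - s);
        if (i0 > i1) continue;
        int cur = 0, off_max = 0, last_run = 0, init_run = 0;
        for (int i = i0; i <= i1; ++i) {
            if (am[i] & rbm[i + s]) ++cur; else cur = 0;
            if (cur > off_max) off_max = cur;
            if (i == i1) last_run = cur;
            if (cur == i - i0 + 1) init_run = cur;  // run still touching first cell
        }
        if (off_max > max_run) { max_run = off_max; best_offset = s; }
        // a's 3' end is cell i = n - 1 (last overlap cell when s <= m - n);
        // b's 3' end is revcomp(b) cell 0 (first overlap cell when s <= 0).
        if (i1 == n - 1 && last_run > three_prime) three_prime = last_run;
        if (i0 == -s && s <= 0 && init_run > three_prime) three_prime = init_run;
    }
    return List::create(_["max_run"] = max_run,
                        _["three_prime_run"] = three_prime,
                        _["offset"] = best_offset);
}

// True iff the oligo can fold back on itself: two antiparallel complementary
// stretches of length >= stem_min enclosing a loop of >= loop_min unpaired
// bases. D[i][j] counts consecutive base pairs (i,j),(i+1,j-1),... inward.
// [[Rcpp::export(name = ".hairpin_scan_cpp")]]
bool hairpin_scan_cpp(std::string s, int stem_min, int loop_min) {
    const int n = s.size();
    if (n < 2 * stem_min + loop_min) return false;
    std::vector<int> msk(n), cm(n);
    for (int i = 0; i < n; ++i) {
        msk[i] = iupac_mask(s[i]);
        cm[i] = comp_mask(msk[i]);
    }
    std::vector<std::vector<int> > D(n, std::vector<int>(n, 0));
    for (int gap = 1; gap < n; ++gap) {               // inner pairs first
        for (int i = 0; i + gap < n; ++i) {
            const int j = i + gap;
            if (msk[i] & cm[j])
                D[i][j] = 1 + ((i + 1 <= j - 1) ? D[i + 1][j - 1] : 0);
            int span = j - i + 1 - loop_min;          // bases available for 2 stems
            int k = std::min(D[i][j], span / 2);
            if (k >= stem_min) return true;
        }
    }
    return false;
}

// Ungapped merge of read pairs. r2rc must already be reverse-complemented.
// The best overlap is the longest L >= min_overlap whose mismatch fraction
// is <= max_mismatch_frac; N is uninformative (never counted as mismatch).
// Disagreements resolve to the higher-quality base, or N without qualities.
// [[Rcpp::export(name = ".merge_pairs_cpp")]]
List merge_pairs_cpp(CharacterVector r1, CharacterVector r2rc,
                     int min_overlap, double max_mismatch_frac,
                     CharacterVector q1, CharacterVector q2rc) {
    const int nreads = r1.size();
    const bool has_q = q1.size() == nreads && q2rc.size() == nreads;
    CharacterVector merged(nreads);
    IntegerVector overlap(nreads);
    for (int r = 0; r < nreads; ++r) {
        std::string s1 = as<std::string>(r1[r]), s2 = as<std::string>(r2rc[r]);
        std::string u1, u2;
        if (has_q) { u1 = as<std::string>(q1[r]); u2 = as<std::string>(q2rc[r]); }
        const int n1 = s1.size(), n2 = s2.size();
        int found = -1;
        for (int L = std::min(n1, n2); L >= min_overlap && L >= 1; --L) {
            const int allowed = static_cast<int>(max_mismatch_frac * L);
            int mm = 0;
            const int off = n1 - L;
            bool ok = true;
            for (int i = 0; i < L; ++i) {
                char c1 = s1[off + i], c2 = s2[i];
                if (c1 != c2 && c1 != 'N' && c2 != 'N') {
                    if (++mm > allowed) { ok = false; break; }
                }
            }
            if (ok) { found = L; break; }
        }
        if (found < 0) {
            merged[r] = NA_STRING;
            overlap[r] = NA_INTEGER;
            continue;
        }
        const int L = found, off = n1 - L;
        std::string out = s1.substr(0, off);
        out.reserve(n1 + n2 - L);
        for (int i = 0; i < L; ++i) {
            char c1 = s1[off + i], c2 = s2[i];
            if (c1 == c2) out.push_back(c1);
            else if (c1 == 'N') out.push_back(c2);
            else if (c2 == 'N') out.push_back(c1);
            else if (has_q) out.push_back(u1[off + i] >= u2[i] ? c1 : c2);
            else out.push_back('N');
        }
        out += s2.substr(L);
        merged[r] = out;
        overlap[r] = L;
    }
    return List::create(_["sequence"] = merged, _["overlap"] = overlap);
}
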