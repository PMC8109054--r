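#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment of a read against an amplicon
// reference under unit costs (match 0, mismatch 1, gap 1), with
// deterministic tie-breaking: diagonal (match/mismatch) preferred over a
// gap, deletion (gap in the read, reference consumed) preferred over
// insertion. Indels are then canonicalized to their leftmost equivalent
// placement (homopolymer left-shift), the convention used when calling
// indels at a Cas9 cut site.

static void traceback(const std::string &q, const std::string &r,
                      std::string &qa, std::string &ra) {
    const int m = q.size(), n = r.size();
    // DP over ints; sequences are amplicon-scale (<= a few kb)
    std::vector<std::vector<int>> D(m + 1, std::vector<int>(n + 1));
    for (int i = 0; i <= m; ++i) D[i][0] = i;
    for (int j = 0; j <= n; ++j) D[0][j] = j;
    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= n; ++j) {
            int diag = D[i - 1][j - 1] + (q[i - 1] == r[j - 1] ? 0 : 1);
            int del = D[i][j - 1] + 1;   // gap in read, ref consumed
            int ins = D[i - 1][j] + 1;   // gap in ref, read consumed
            int best = diag;
            if (del < best) best = del;
            if (ins < best) best = ins;
            D[i][j] = best;
        }
    }
    int i = m, j = n;
    qa.clear(); ra.clear();
    while (i > 0 || j > 0) {
        if (i > 0 && j > 0 &&
            D[i][j] == D[i - 1][j - 1] + (q[i - 1] == r[j - 1] ? 0 : 1)) {
            qa.push_back(q[i - 1]); ra.push_back(r[j - 1]);
            --i; --j;
        } else if (j > 0 && D[i][j] == D[i][j - 1] + 1) {
            qa.push_back('-'); ra.push_back(r[j - 1]);
            --j;
        } else {
            qa.push_back(q[i - 1]); ra.push_back('-');
            --i;
        }
    }
    std::reverse(qa.begin(), qa.end());
    std::reverse(ra.begin(), ra.end());
}

// shift every gap run to its leftmost equivalent position; cost-preserving
// single-column shifts, iterated to a fixed point
static void left_align(std::string &ga, std::string &other) {
    bool moved = true;
    while (moved) {
        moved = false;
        size_t L = ga.size();
        size_t i = 0;
        while (i < L) {
            if (ga[i] != '-') { ++i; continue; }
            size_t j = i;
            while (j < L && ga[j] == '-') ++j;  // gap run [i, j)
            while (i > 0 && ga[i - 1] != '-' && other[i - 1] != '-' &&
                   ga[i - 1] == other[i - 1] &&
                   other[i - 1] == other[j - 1]) {
                // move the matched column from i-1 to j-1
                ga[j - 1] = ga[i - 1];
                ga[i - 1] = '-';
                --i; --j;
                moved = true;
            }
            i = j;
        }
    }
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string read, std::string ref) {
    std::string qa, ra;
    traceback(read, ref, qa, ra);
    left_align(qa, ra);  // deletions: gaps in the read row
    left_align(ra, qa);  // insertions: gaps in the reference row
    // walk the alignment: edit distance, indels in reference coordinates
    int dist = 0;
    int rpos = 0;  // 0-based reference coordinate of the next ref base
    std::vector<int> ipos, ilen, itype;  // type 1 = insertion, 2 = deletion
    size_t k = 0, L = qa.size();
    while (k < L) {
        if (qa[k] == '-') {            // deletion from the read
            int start = rpos, len = 0;
            while (k < L && qa[k] == '-') { ++len; ++rpos; ++k; }
            ipos.push_back(start); ilen.push_back(len); itype.push_back(2);
            dist += len;
        } else if (ra[k] == '-') {     // insertion into the read
            int start = rpos, len = 0;
            while (k < L && ra[k] == '-') { ++len; ++k; }
            ipos.push_back(start); ilen.push_back(len); itype.push_back(1);
            dist += len;
        } else {
            if (qa[k] != ra[k]) ++dist;
            ++rpos; ++k;
        }
    }
    return List::create(
        _["edit_distance"] = dist,
        _["indel_pos"] = ipos,
        _["indel_len"] = ilen,
        _["indel_type"] = itype,
        _["aligned_read"] = qa,
        _["aligned_ref"] = ra);
}
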