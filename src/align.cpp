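#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>

using namespace Rcpp;

// Wraparound alignment of a candidate sequence against an unbounded periodic
// extension of the motif (TRF-style scoring).  The candidate is consumed
// globally; the motif phase is free at both ends.  Gap cost is linear
// (indel per base); mismatches cost a flat penalty; 'N' never matches.
//
// State: score after consuming i candidate bases with the motif at phase j
// (j = index of the next motif base).  Per row, deletions (skipped motif
// bases) are relaxed cyclically; skipping a full motif period always costs
// indel * L so two passes suffice.
// [[Rcpp::export]]
List wrap_align_cpp(std::string seq, std::string motif,
                    int match, int mismatch, int indel) {
    const int n = (int) seq.size();
    const int L = (int) motif.size();
    if (L < 1) stop("empty motif");
    std::vector<int> sc(L, 0), cm(L, 0), cx(L, 0), cg(L, 0);
    std::vector<int> nsc(L), ncm(L), ncx(L), ncg(L);
    for (int i = 1; i <= n; ++i) {
        const char c = seq[i - 1];
        for (int j2 = 0; j2 < L; ++j2) {
            const int j = (j2 + L - 1) % L; // consuming motif[j] leads to phase j2
            const bool hit = (c == motif[j]) && c != 'N';
            const int diag = sc[j] + (hit ? match : -mismatch);
            const int ins = sc[j2] - indel; // candidate base against a gap
            if (diag >= ins) {
                nsc[j2] = diag;
                ncm[j2] = cm[j] + (hit ? 1 : 0);
                ncx[j2] = cx[j] + (hit ? 0 : 1);
                ncg[j2] = cg[j];
            } else {
                nsc[j2] = ins;
                ncm[j2] = cm[j2];
                ncx[j2] = cx[j2];
                ncg[j2] = cg[j2] + 1;
            }
        }
        for (int k = 0; k < 2 * L; ++k) { // deletions: skip motif bases
            const int j = k % L, j2 = (j + 1) % L;
            if (nsc[j] - indel > nsc[j2]) {
                nsc[j2] = nsc[j] - indel;
                ncm[j2] = ncm[j];
                ncx[j2] = ncx[j];
                ncg[j2] = ncg[j] + 1;
            }
        }
        sc.swap(nsc); cm.swap(ncm); cx.swap(ncx); cg.swap(ncg);
    }
    int best = 0;
    for (int j = 1; j < L; ++j)
        if (sc[j] > sc[best]) best = j;
    return List::create(_["score"] = sc[best],
                        _["matches"] = cm[best],
                        _["mismatches"] = cx[best],
                        _["indels"] = cg[best]);
}

namespace {

struct LC {
    long long score;
    int start;  // 0-based start in the region
    int len;    // region bases consumed (matches + mismatches + insertions)
    int nint;   // interruptions: mismatches + region-side insertions
};

// Lexicographic preference used for every tie: higher score, then longer
// region span (more units), then fewer interruptions, then leftmost start.
inline bool lc_better(const LC &a, const LC &b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.len != b.len) return a.len > b.len;
    if (a.nint != b.nint) return a.nint < b.nint;
    return a.start < b.start;
}

} // namespace

// Smith-Waterman local alignment of a region against a pure periodic motif
// sequence of length len(region) + len(motif), with affine gaps (first gap
// base costs gap_open, each further base gap_extend).  Carries (start, span,
// interruptions) through the DP so ties resolve deterministically.
// [[Rcpp::export]]
List local_align_cpp(std::string region, std::string motif,
                     int match, int mismatch, int gap_open, int gap_extend) {
    const int n = (int) region.size();
    const int L = (int) motif.size();
    if (L < 1) stop("empty motif");
    if (n < 1) stop("empty region");
    const int m = n + L;
    const long long NEG = LLONG_MIN / 4;
    const LC none = {NEG, 0, 0, 0};

    std::vector<LC> Mprev(m + 1, none), Xprev(m + 1, none), Yprev(m + 1, none);
    std::vector<LC> Mcur(m + 1, none), Xcur(m + 1, none), Ycur(m + 1, none);
    LC best = none;

    for (int i = 1; i <= n; ++i) {
        const char c = region[i - 1];
        std::fill(Mcur.begin(), Mcur.end(), none);
        std::fill(Xcur.begin(), Xcur.end(), none);
        std::fill(Ycur.begin(), Ycur.end(), none);
        for (int j = 1; j <= m; ++j) {
            const char s = motif[(j - 1) % L];
            const bool hit = (c == s) && c != 'N';
            const int sub = hit ? match : -mismatch;
            // M: region[i-1] aligned to subject[j-1]
            LC from = {0, i - 1, 0, 0}; // fresh local start
            if (lc_better(Mprev[j - 1], from)) from = Mprev[j - 1];
            if (lc_better(Xprev[j - 1], from)) from = Xprev[j - 1];
            if (lc_better(Yprev[j - 1], from)) from = Yprev[j - 1];
            Mcur[j].score = from.score + sub;
            Mcur[j].start = from.start;
            Mcur[j].len = from.len + 1;
            Mcur[j].nint = from.nint + (hit ? 0 : 1);
            // X: region base against a gap (insertion relative to the motif)
            LC xo = Mprev[j], xe = Xprev[j];
            if (xo.score > NEG) xo.score -= gap_open;
            if (xe.score > NEG) xe.score -= gap_extend;
            LC xf = lc_better(xo, xe) ? xo : xe;
            if (xf.score > NEG) {
                xf.len += 1;
                xf.nint += 1;
                Xcur[j] = xf;
            }
            // Y: motif base against a gap (deletion from the region)
            LC yo = Mcur[j - 1], ye = Ycur[j - 1];
            if (yo.score > NEG) yo.score -= gap_open;
            if (ye.score > NEG) ye.score -= gap_extend;
            Ycur[j] = lc_better(yo, ye) ? yo : ye;
            // local alignments end on an aligned pair
            if (Mcur[j].score > 0 && lc_better(Mcur[j], best)) best = Mcur[j];
        }
        Mprev.swap(Mcur); Xprev.swap(Xcur); Yprev.swap(Ycur);
    }

    if (best.score <= 0)
        return List::create(_["failed"] = true);
    return List::create(_["failed"] = false,
                        _["start"] = best.start,
                        _["end"] = best.start + best.len,
                        _["score"] = best.score,
                        _["aligned"] = best.len,
                        _["interruptions"] = best.nint);
}
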