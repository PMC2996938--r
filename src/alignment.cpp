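#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Local alignment and ungapped scanning primitives.
//
// All scoring here is plain match/mismatch with affine gap costs where gaps
// are allowed at all; the ungapped scanner treats every subject offset as a
// candidate diagonal and keeps the best-scoring contiguous segment on it
// (Kadane). Coordinates returned to R are 1-based.

static inline int enc(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1; // N or anything else: never matches
    }
}

// Smith-Waterman local alignment score, affine gaps: a gap of length L costs
// gap_open + L * gap_ext (the Biostrings pairwiseAlignment convention).
static double sw_local(const std::string& a, const std::string& b,
                       double match, double mismatch,
                       double gap_open, double gap_ext) {
    const int n = (int)a.size(), m = (int)b.size();
    std::vector<double> H(m + 1, 0.0), E(m + 1, R_NegInf);
    double best = 0.0;
    for (int i = 1; i <= n; ++i) {
        double diag = 0.0;        // H[i-1][0]
        double F = R_NegInf;      // gap in b (vertical)
        int ai = enc(a[i - 1]);
        for (int j = 1; j <= m; ++j) {
            double up = H[j];     // H[i-1][j]
            E[j] = std::max(E[j] - gap_ext, H[j] - gap_open - gap_ext);
            F = std::max(F - gap_ext, H[j - 1] - gap_open - gap_ext);
            int bj = enc(b[j - 1]);
            double s = (ai >= 0 && ai == bj) ? match : mismatch;
            double h = diag + s;
            if (E[j] > h) h = E[j];
            if (F > h) h = F;
            if (h < 0) h = 0;
            diag = up;
            H[j] = h;
            if (h > best) best = h;
        }
    }
    return best;
}

//' @noRd
// [[Rcpp::export(name = ".sw_score_batch")]]
NumericVector sw_score_batch(CharacterVector seqs, std::string pattern,
                             double match, double mismatch,
                             double gap_open, double gap_ext) {
    int n = seqs.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        if (CharacterVector::is_na(seqs[i])) { out[i] = NA_REAL; continue; }
        out[i] = sw_local(as<std::string>(seqs[i]), pattern,
                          match, mismatch, gap_open, gap_ext);
    }
    return out;
}

// Best ungapped local score of pattern against seq over all diagonals.
static double ungapped_best(const std::string& s, const std::string& p,
                            double match, double mismatch) {
    const int n = (int)s.size(), m = (int)p.size();
    double best = 0.0;
    for (int d = -(m - 1); d <= n - 1; ++d) {
        // diagonal: s[d + j] vs p[j]
        int j0 = std::max(0, -d), j1 = std::min(m - 1, n - 1 - d);
        double run = 0.0;
        for (int j = j0; j <= j1; ++j) {
            int sc = enc(s[d + j]), pc = enc(p[j]);
            run += (sc >= 0 && sc == pc) ? match : mismatch;
            if (run < 0) run = 0;
            if (run > best) best = run;
        }
    }
    return best;
}

//' @noRd
// [[Rcpp::export(name = ".ungapped_max_scores")]]
NumericVector ungapped_max_scores(CharacterVector seqs, CharacterVector patterns,
                                  double match, double mismatch) {
    int n = seqs.size();
    std::vector<std::string> pats(patterns.size());
    for (int k = 0; k < patterns.size(); ++k) pats[k] = as<std::string>(patterns[k]);
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        if (CharacterVector::is_na(seqs[i])) { out[i] = NA_REAL; continue; }
        std::string s = as<std::string>(seqs[i]);
        double best = 0.0;
        for (size_t k = 0; k < pats.size(); ++k) {
            double v = ungapped_best(s, pats[k], match, mismatch);
            if (v > best) best = v;
        }
        out[i] = best;
    }
    return out;
}

// Ungapped scan of a pattern along a subject. Every subject offset at which
// the full pattern footprint fits is a candidate; the best-scoring contiguous
// segment on that diagonal is reported when it reaches min_score. Mismatches
// are additionally counted over a fixed window of pattern offsets
// [win_from, win_to] (0-based, inclusive) and over the whole footprint.
//' @noRd
// [[Rcpp::export(name = ".scan_ungapped_cpp")]]
DataFrame scan_ungapped_cpp(std::string subject, std::string pattern,
                            double match, double mismatch, double min_score,
                            int win_from, int win_to) {
    const int n = (int)subject.size(), m = (int)pattern.size();
    std::vector<int> pos, seg_from, seg_to, mm_win, mm_all;
    std::vector<double> score;
    if (m == 0 || n < m) {
        return DataFrame::create(_["pos"] = IntegerVector(0),
                                 _["score"] = NumericVector(0),
                                 _["seg_from"] = IntegerVector(0),
                                 _["seg_to"] = IntegerVector(0),
                                 _["mm_window"] = IntegerVector(0),
                                 _["mm_total"] = IntegerVector(0));
    }
    std::vector<int> penc(m);
    for (int j = 0; j < m; ++j) penc[j] = enc(pattern[j]);
    for (int p = 0; p + m <= n; ++p) {
        double run = 0.0, best = 0.0;
        int run_from = 0, best_from = 0, best_to = -1;
        int mwin = 0, mall = 0;
        for (int j = 0; j < m; ++j) {
            int sc = enc(subject[p + j]);
            bool hit = (sc >= 0 && sc == penc[j]);
            if (!hit) {
                ++mall;
                if (j >= win_from && j <= win_to) ++mwin;
            }
            double v = hit ? match : mismatch;
            if (run <= 0 && v > 0) { run = v; run_from = j; }
            else run += v;
            if (run < 0) run = 0;
            if (run > best) { best = run; best_from = run_from; best_to = j; }
        }
        if (best >= min_score && best_to >= best_from) {
            pos.push_back(p + 1);
            score.push_back(best);
            seg_from.push_back(p + best_from + 1);
            seg_to.push_back(p + best_to + 1);
            mm_win.push_back(mwin);
            mm_all.push_back(mall);
        }
    }
    return DataFrame::create(_["pos"] = wrap(pos), _["score"] = wrap(score),
                             _["seg_from"] = wrap(seg_from),
                             _["seg_to"] = wrap(seg_to),
                             _["mm_window"] = wrap(mm_win),
                             _["mm_total"] = wrap(mm_all));
}
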