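#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Smith-Waterman-Gotoh local alignment of a read against a reference window.
// Affine gaps: a gap of length k costs gap_open + k * gap_extend (both are
// supplied as negative numbers). Deterministic tie-breaking: among equal-score
// end cells the leftmost window position wins (then the shortest read prefix);
// traceback prefers a diagonal step, then the shortest reference gap, then
// the shortest read gap.
//
// Only the H (match-state) matrix is stored; the E/F gap states are kept as
// a running scalar / one rolling row during the forward sweep and
// reconstructed by scanning gap chains during traceback. The H workspace is
// reused across calls in batch mode.

struct SwResult {
    double score;
    int ref_start, ref_end, read_start, read_end;
    int nmatch;
    std::string cigar;
};

static const double NEG = -1e18;
static const double EPS = 1e-9;

static SwResult sw_core(const std::string& read, const std::string& window,
                        double match, double mismatch,
                        double gap_open, double gap_extend,
                        std::vector<double>& H, std::vector<double>& F) {
    const int n = (int)read.size();
    const int m = (int)window.size();
    const size_t need = (size_t)(n + 1) * (m + 1);
    if (H.size() < need) H.resize(need);
    if (F.size() < (size_t)(m + 1)) F.resize(m + 1);
    const size_t W = (size_t)(m + 1);

    for (int j = 0; j <= m; ++j) { H[j] = 0.0; F[j] = NEG; }
    double best = 0.0;
    int bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
        double* Hi = &H[(size_t)i * W];
        const double* Hp = &H[(size_t)(i - 1) * W];
        Hi[0] = 0.0;
        double e = NEG;
        const char ri = read[i - 1];
        for (int j = 1; j <= m; ++j) {
            e = std::max(e, Hi[j - 1] + gap_open) + gap_extend;
            double f = std::max(F[j], Hp[j] + gap_open) + gap_extend;
            F[j] = f;
            double h = Hp[j - 1] + ((ri == window[j - 1]) ? match : mismatch);
            if (e > h) h = e;
            if (f > h) h = f;
            if (h < 0.0) h = 0.0;
            Hi[j] = h;
            if (h > best + EPS) { best = h; bi = i; bj = j; }
        }
    }

    SwResult res;
    res.score = best;
    if (best <= 0.0) {
        res.ref_start = res.ref_end = res.read_start = res.read_end = NA_INTEGER;
        res.nmatch = 0;
        res.cigar = "";
        return res;
    }

    // traceback over H alone: diagonal first, else reconstruct the gap
    // chain that produced this cell (shortest gap first)
    std::string ops;  // reversed op string: M, D (ref gap), I (read gap)
    int i = bi, j = bj, nmatch = 0;
    while (i > 0 && j > 0) {
        double h = H[(size_t)i * W + j];
        if (h <= EPS) break;
        double s = (read[i - 1] == window[j - 1]) ? match : mismatch;
        if (std::abs(h - (H[(size_t)(i - 1) * W + (j - 1)] + s)) < EPS &&
            H[(size_t)(i - 1) * W + (j - 1)] > -EPS) {
            ops.push_back('M');
            if (read[i - 1] == window[j - 1]) ++nmatch;
            --i; --j;
            continue;
        }
        bool moved = false;
        const double maxH = n * std::max(match, 0.0);  // upper bound on any H
        for (int k = j - 1; k >= 1; --k) {  // reference gap of length j-k
            if (maxH + gap_open + (j - k) * gap_extend < h - EPS) break;
            double cand = H[(size_t)i * W + k] + gap_open + (j - k) * gap_extend;
            if (std::abs(cand - h) < EPS) {
                for (int t = 0; t < j - k; ++t) ops.push_back('D');
                j = k;
                moved = true;
                break;
            }
        }
        if (moved) continue;
        for (int k = i - 1; k >= 1; --k) {  // read gap of length i-k
            if (maxH + gap_open + (i - k) * gap_extend < h - EPS) break;
            double cand = H[(size_t)k * W + j] + gap_open + (i - k) * gap_extend;
            if (std::abs(cand - h) < EPS) {
                for (int t = 0; t < i - k; ++t) ops.push_back('I');
                i = k;
                moved = true;
                break;
            }
        }
        if (!moved) break;  // numerically unreachable; stop defensively
    }

    res.ref_start = j + 1;
    res.ref_end = bj;
    res.read_start = i + 1;
    res.read_end = bi;
    res.nmatch = nmatch;

    // run-length encode the (reversed) op string into a CIGAR
    std::string cig;
    int pos = (int)ops.size() - 1;
    while (pos >= 0) {
        char op = ops[pos];
        int run = 0;
        while (pos >= 0 && ops[pos] == op) { ++run; --pos; }
        cig += std::to_string(run);
        cig.push_back(op);
    }
    res.cigar = cig;
    return res;
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string read, std::string window,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
    std::vector<double> H, F;
    SwResult r = sw_core(read, window, match, mismatch, gap_open, gap_extend,
                         H, F);
    return List::create(
        _["score"] = r.score,
        _["ref_start"] = r.ref_start, _["ref_end"] = r.ref_end,
        _["read_start"] = r.read_start, _["read_end"] = r.read_end,
        _["nmatch"] = r.nmatch, _["cigar"] = r.cigar);
}

// [[Rcpp::export(name = ".sw_align_batch_cpp")]]
DataFrame sw_align_batch_cpp(CharacterVector reads, CharacterVector windows,
                             double match, double mismatch,
                             double gap_open, double gap_extend) {
    int n = reads.size();
    if (windows.size() != n) stop("reads and windows must have equal length");
    NumericVector score(n);
    IntegerVector rs(n), re(n), qs(n), qe(n), nm(n);
    CharacterVector cig(n);
    std::vector<double> H, F;
    for (int k = 0; k < n; ++k) {
        SwResult r = sw_core(as<std::string>(reads[k]), as<std::string>(windows[k]),
                             match, mismatch, gap_open, gap_extend, H, F);
        score[k] = r.score;
        rs[k] = r.ref_start; re[k] = r.ref_end;
        qs[k] = r.read_start; qe[k] = r.read_end;
        nm[k] = r.nmatch; cig[k] = r.cigar;
    }
    return DataFrame::create(
        _["score"] = score, _["ref_start"] = rs, _["ref_end"] = re,
        _["read_start"] = qs, _["read_end"] = qe,
        _["nmatch"] = nm, _["cigar"] = cig,
        _["stringsAsFactors"] = false);
}
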