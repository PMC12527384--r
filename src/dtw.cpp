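#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Dependent multivariate DTW: one warping path aligns all feature
// dimensions, local cost is the Euclidean norm across dimensions.
// step_pattern: 1 = symmetric1 (all steps weight 1),
//               2 = symmetric2 (diagonal counts the local cost twice).
// window: Sakoe-Chiba band half-width; < 0 disables the band. The caller
// must guarantee window >= |nrow(a) - nrow(b)| or the end cell is
// unreachable (returns Inf).
// normalize: divide the terminal cumulative cost by (na + nb).

static inline double local_cost(const NumericMatrix& a, const NumericMatrix& b,
                                int i, int j) {
    double s = 0.0;
    const int d = a.ncol();
    for (int k = 0; k < d; ++k) {
        const double diff = a(i, k) - b(j, k);
        s += diff * diff;
    }
    return std::sqrt(s);
}

// [[Rcpp::export]]
double dtw_cost_cpp(NumericMatrix a, NumericMatrix b, int step_pattern,
                    int window, bool normalize) {
    const int na = a.nrow(), nb = b.nrow();
    const double inf = std::numeric_limits<double>::infinity();
    if (na == 0 || nb == 0) stop("empty series");
    if (a.ncol() != b.ncol()) stop("dimension mismatch");

    // two-row rolling DP to keep memory O(nb)
    std::vector<double> prev(nb, inf), cur(nb, inf);
    for (int i = 0; i < na; ++i) {
        std::fill(cur.begin(), cur.end(), inf);
        for (int j = 0; j < nb; ++j) {
            if (window >= 0 && std::abs(i - j) > window) continue;
            const double d = local_cost(a, b, i, j);
            double best;
            if (i == 0 && j == 0) {
                best = d;
            } else {
                const double up   = (i > 0) ? prev[j] : inf;
                const double left = (j > 0) ? cur[j - 1] : inf;
                const double diag = (i > 0 && j > 0) ? prev[j - 1] : inf;
                if (step_pattern == 2) {
                    best = std::min(std::min(up + d, left + d), diag + 2.0 * d);
                } else {
                    best = std::min(std::min(up, left), diag) + d;
                }
            }
            cur[j] = best;
        }
        std::swap(prev, cur);
    }
    double out = prev[nb - 1];
    if (normalize && R_finite(out)) out /= (double)(na + nb);
    return out;
}

// Pairwise DTW cross-distance over tracks sharing one grid.
// cube: numeric array n_tracks x n_time x n_feat flattened in R order.
// [[Rcpp::export]]
NumericMatrix cross_dtw_cpp(NumericVector cube, IntegerVector dims,
                            int step_pattern, int window, bool normalize) {
    const int n = dims[0], L = dims[1], f = dims[2];
    // unpack each track into an L x f matrix once
    std::vector<NumericMatrix> tracks;
    tracks.reserve(n);
    for (int t = 0; t < n; ++t) {
        NumericMatrix m(L, f);
        for (int k = 0; k < f; ++k)
            for (int i = 0; i < L; ++i)
                m(i, k) = cube[t + (R_xlen_t)n * i + (R_xlen_t)n * L * k];
        tracks.push_back(m);
    }
    NumericMatrix D(n, n);
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            const double d = dtw_cost_cpp(tracks[i], tracks[j], step_pattern,
                                          window, normalize);
            D(i, j) = d;
            D(j, i) = d;
        }
        Rcpp::checkUserInterrupt();
    }
    return D;
}
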