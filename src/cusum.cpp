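#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Two-sided CUSUM recursion over a logR target series.
//   C+_t = max(0, R_t - K + C+_{t-1}),  C-_t = min(0, R_t + K + C-_{t-1}),
// with C+_0 = C-_0 = 0. Masked monitoring points (mask[t] true, or R_t not
// finite) carry the previous statistics forward unchanged.
// [[Rcpp::export(name = ".cusum_recursion")]]
List cusum_recursion(NumericVector r, double K, LogicalVector mask) {
    const R_xlen_t m = r.size();
    if (mask.size() != m) stop("mask length must match series length");
    NumericVector cp(m), cm(m);
    double prev_p = 0.0, prev_m = 0.0;
    for (R_xlen_t t = 0; t < m; ++t) {
        if (mask[t] || !R_finite(r[t])) {
            cp[t] = prev_p;
            cm[t] = prev_m;
            continue;
        }
        prev_p = std::max(0.0, r[t] - K + prev_p);
        prev_m = std::min(0.0, r[t] + K + prev_m);
        cp[t] = prev_p;
        cm[t] = prev_m;
    }
    return List::create(_["Cplus"] = cp, _["Cminus"] = cm);
}

// Rolling window sums of x and of a validity indicator, at a given stride.
// Windows with any NA in x (masked positions must be zeroed by the caller)
// are not special-cased here; callers pass x with masked entries set to 0
// and ok = !mask.
// [[Rcpp::export(name = ".rolling_window_sums")]]
List rolling_window_sums(NumericVector x, LogicalVector ok, int n, int stride) {
    const R_xlen_t L = x.size();
    if (ok.size() != L) stop("length mismatch");
    if (n < 1 || n > L) stop("window size out of range");
    if (stride < 1) stop("stride must be >= 1");
    const R_xlen_t m = (L - n) / stride + 1;
    NumericVector sums(m);
    IntegerVector counts(m);
    // prefix sums in long double for numerical safety on long tracks
    std::vector<long double> ps(L + 1, 0.0L);
    std::vector<R_xlen_t> pc(L + 1, 0);
    for (R_xlen_t i = 0; i < L; ++i) {
        ps[i + 1] = ps[i] + (ok[i] ? (long double)x[i] : 0.0L);
        pc[i + 1] = pc[i] + (ok[i] ? 1 : 0);
    }
    for (R_xlen_t j = 0; j < m; ++j) {
        const R_xlen_t t = j * stride;
        sums[j] = (double)(ps[t + n] - ps[t]);
        counts[j] = (int)(pc[t + n] - pc[t]);
    }
    return List::create(_["sum"] = sums, _["count"] = counts);
}

// Per-row median of a numeric matrix (used by the panel-of-normals builder
// when pooling controls with the median).
// [[Rcpp::export(name = ".row_medians")]]
NumericVector row_medians(NumericMatrix x) {
    const int nr = x.nrow(), nc = x.ncol();
    NumericVector out(nr);
    std::vector<double> buf(nc);
    for (int i = 0; i < nr; ++i) {
        for (int j = 0; j < nc; ++j) buf[j] = x(i, j);
        const int h = nc / 2;
        std::nth_element(buf.begin(), buf.begin() + h, buf.end());
        double med = buf[h];
        if (nc % 2 == 0) {
            double lo = *std::max_element(buf.begin(), buf.begin() + h);
            med = (med + lo) / 2.0;
        }
        out[i] = med;
    }
    return out;
}
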