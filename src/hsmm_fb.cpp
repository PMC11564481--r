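#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Explicit-duration semi-Markov forward-backward for one contiguous
// sequence.  Segments are complete (duration pmf factor) except the last
// segment of the sequence, which is right-censored (survivor factor), so
// the duration process assigns total mass 1 to every sequence length.
// All recursions run in log space.

static inline double lse_buf(const std::vector<double>& v, int n) {
    double m = R_NegInf;
    for (int i = 0; i < n; ++i) if (v[i] > m) m = v[i];
    if (!std::isfinite(m)) return R_NegInf;
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += std::exp(v[i] - m);
    return m + std::log(s);
}

// logB: K x T per-sample log emission densities
// lpi : K log initial probabilities
// lA  : K x K log transition matrix (diagonal -Inf for K > 1, 0 for K = 1)
// lP  : K x d_max log duration pmf
// lS  : K x d_max log survivor function, lS[k][d-1] = log P(D_k >= d)
// counts: also accumulate expected sufficient statistics for EM
// [[Rcpp::export]]
List hsmm_fb_cpp(NumericMatrix logB, NumericVector lpi, NumericMatrix lA,
                 NumericMatrix lP, NumericMatrix lS, bool counts) {
    const int K = logB.nrow(), T = logB.ncol(), dmax = lP.ncol();
    if (T < 1) stop("empty sequence");

    // cumulative per-state emission log-likelihood, CB(k, t), t = 0..T
    std::vector<double> CB((size_t)K * (T + 1));
    for (int k = 0; k < K; ++k) {
        CB[k] = 0.0;
        for (int t = 1; t <= T; ++t)
            CB[(size_t)t * K + k] = CB[(size_t)(t - 1) * K + k] + logB(k, t - 1);
    }
    auto cb = [&](int k, int t) -> double { return CB[(size_t)t * K + k]; };

    // ain(k, s): log P(state k segment starts at s, obs 1..s-1), s = 1..T
    // la(k, t) : log P(complete segment of k ends at t, obs 1..t), t = 1..T
    std::vector<double> ain((size_t)K * (T + 1), R_NegInf);
    std::vector<double> la((size_t)K * (T + 1), R_NegInf);
    std::vector<double> buf(std::max(K, dmax) + 2);

    for (int t = 1; t <= T; ++t) {
        for (int k = 0; k < K; ++k) {
            if (t == 1) {
                ain[(size_t)K + k] = lpi[k];
            } else {
                int n = 0;
                for (int j = 0; j < K; ++j)
                    buf[n++] = la[(size_t)(t - 1) * K + j] + lA(j, k);
                ain[(size_t)t * K + k] = lse_buf(buf, n);
            }
        }
        for (int k = 0; k < K; ++k) {
            int n = 0, dm = std::min(dmax, t);
            for (int d = 1; d <= dm; ++d)
                buf[n++] = ain[(size_t)(t - d + 1) * K + k] + lP(k, d - 1) +
                           cb(k, t) - cb(k, t - d);
            la[(size_t)t * K + k] = lse_buf(buf, n);
        }
    }

    // eta(k, t): log P(obs t+1..T | state k starts at t+1), t = 0..T-1
    // lb(k, t) : log P(obs t+1..T | some segment ends at t),  t = 1..T-1
    std::vector<double> eta((size_t)K * (T + 1), R_NegInf);
    std::vector<double> lb((size_t)K * (T + 1), R_NegInf);
    for (int t = T - 1; t >= 0; --t) {
        for (int k = 0; k < K; ++k) {
            int n = 0;
            int rem = T - t;
            int dmC = std::min(dmax, rem - 1);  // complete segments end <= T-1
            for (int d = 1; d <= dmC; ++d)
                buf[n++] = lP(k, d - 1) + cb(k, t + d) - cb(k, t) +
                           lb[(size_t)(t + d) * K + k];
            if (rem <= dmax)                    // censored segment covers t+1..T
                buf[n++] = lS(k, rem - 1) + cb(k, T) - cb(k, t);
            eta[(size_t)t * K + k] = lse_buf(buf, n);
        }
        if (t >= 1) {
            for (int k = 0; k < K; ++k) {
                int n = 0;
                for (int j = 0; j < K; ++j)
                    buf[n++] = lA(k, j) + eta[(size_t)t * K + j];
                lb[(size_t)t * K + k] = lse_buf(buf, n);
            }
        }
    }

    double LL;
    {
        int n = 0;
        for (int k = 0; k < K; ++k) buf[n++] = lpi[k] + eta[k];
        LL = lse_buf(buf, n);
    }
    if (!std::isfinite(LL))
        stop("non-finite log-likelihood in forward pass (degenerate model)");

    // per-sample marginals via segment posteriors + difference array
    NumericMatrix gamma(K, T);
    NumericMatrix durc(K, dmax), censc(K, dmax), xi(K, K);
    NumericVector initc(K);
    {
        std::vector<double> diff((size_t)K * (T + 2), 0.0);
        for (int s = 1; s <= T; ++s) {
            for (int k = 0; k < K; ++k) {
                double a = ain[(size_t)s * K + k];
                if (!std::isfinite(a)) continue;
                int dmC = std::min(dmax, T - s);  // complete: e = s+d-1 <= T-1
                for (int d = 1; d <= dmC; ++d) {
                    int e = s + d - 1;
                    double w = std::exp(a + lP(k, d - 1) + cb(k, e) -
                                        cb(k, s - 1) + lb[(size_t)e * K + k] - LL);
                    if (!(w > 0)) continue;
                    durc(k, d - 1) += w;
                    diff[(size_t)s * K + k] += w;
                    diff[(size_t)(e + 1) * K + k] -= w;
                    if (s == 1) initc[k] += w;
                }
                int rem = T - s + 1;              // censored: covers s..T
                if (rem <= dmax) {
                    double w = std::exp(a + lS(k, rem - 1) + cb(k, T) -
                                        cb(k, s - 1) - LL);
                    if (w > 0) {
                        censc(k, rem - 1) += w;
                        diff[(size_t)s * K + k] += w;
                        if (s == 1) initc[k] += w;
                    }
                }
            }
        }
        for (int k = 0; k < K; ++k) {
            double acc = 0.0;
            for (int t = 1; t <= T; ++t) {
                acc += diff[(size_t)t * K + k];
                gamma(k, t - 1) = acc;
            }
        }
        for (int t = 0; t < T; ++t) {  // renormalize against rounding drift
            double s = 0.0;
            for (int k = 0; k < K; ++k) s += gamma(k, t);
            if (s > 0) for (int k = 0; k < K; ++k) gamma(k, t) /= s;
        }
        if (counts && K > 1) {
            for (int t = 1; t <= T - 1; ++t)
                for (int j = 0; j < K; ++j) {
                    double l = la[(size_t)t * K + j];
                    if (!std::isfinite(l)) continue;
                    for (int k = 0; k < K; ++k) {
                        if (k == j) continue;
                        double w = std::exp(l + lA(j, k) +
                                            eta[(size_t)t * K + k] - LL);
                        if (w > 0) xi(j, k) += w;
                    }
                }
        }
    }

    return List::create(_["loglik"] = LL, _["gamma"] = gamma,
                        _["dur_counts"] = durc, _["cens_counts"] = censc,
                        _["trans_counts"] = xi, _["init_counts"] = initc);
}
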