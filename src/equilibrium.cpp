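#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Piecewise linear response: anchors a0, a1, a2 at xbar = 0, 0.5, 1.
static inline double respond_pl(const double *a, double b) {
    double c = (b <= 0.5) ? a[0] + (a[1] - a[0]) * (2.0 * b)
                          : a[1] + (a[2] - a[1]) * (2.0 * b - 1.0);
    if (c < 0.0) c = 0.0;
    if (c > 1.0) c = 1.0;
    return c;
}

// Synchronous belief/response iteration for every group (column) of a
// label matrix. Beliefs are about the others' mean contribution and start
// at initial_belief for everyone. Stops per group at a fixed point
// (contribution vector change < tol), or at an exact recurrence of the
// contribution vector rounded to 12 decimals (a limit cycle, in which
// case the per-member average over one full period is returned), or after
// max_iter rounds (average over the trailing `window` rounds, flagged
// non-converged).
//
// labels:   n x g integer matrix of strategy labels (0..26)
// anchors:  27 x 3 anchor lookup (row l = anchors of label l)
// [[Rcpp::export]]
List eq_groups_cpp(IntegerMatrix labels, NumericMatrix anchors,
                   double initial_belief, int max_iter, double tol,
                   int window) {
    const int n = labels.nrow(), g = labels.ncol();
    if (n < 1) stop("empty group");
    if (max_iter < 2) stop("max_iter must be >= 2");

    NumericMatrix contrib(n, g);
    LogicalVector converged(g);
    IntegerVector cycle_len(g), iters(g);

    std::vector<double> a(3 * n);   // anchors per member of current group
    std::vector<double> belief(n), c(n), cprev(n);
    std::vector<std::vector<double> > hist;
    std::vector<double> key;        // cheap fingerprint: sum of rounded c

    for (int j = 0; j < g; ++j) {
        for (int i = 0; i < n; ++i) {
            int l = labels(i, j);
            if (l < 0 || l > 26) stop("invalid strategy label");
            a[3 * i]     = anchors(l, 0);
            a[3 * i + 1] = anchors(l, 1);
            a[3 * i + 2] = anchors(l, 2);
            belief[i] = initial_belief;
        }
        hist.clear();
        key.clear();
        bool done = false;
        int t;
        for (t = 0; t < max_iter && !done; ++t) {
            double S = 0.0, ksum = 0.0;
            for (int i = 0; i < n; ++i) {
                c[i] = respond_pl(&a[3 * i], belief[i]);
                S += c[i];
                ksum += std::floor(c[i] * 1e12 + 0.5);
            }
            // fixed point?
            if (t > 0) {
                double d = 0.0;
                for (int i = 0; i < n; ++i) {
                    double e = std::fabs(c[i] - cprev[i]);
                    if (e > d) d = e;
                }
                if (d < tol) {
                    converged[j] = true;
                    cycle_len[j] = 1;
                    for (int i = 0; i < n; ++i) contrib(i, j) = c[i];
                    done = true;
                    break;
                }
            }
            // exact recurrence (limit cycle) on the rounded orbit
            for (int t0 = (int)hist.size() - 1; t0 >= 0; --t0) {
                if (key[t0] != ksum) continue;
                bool same = true;
                const std::vector<double> &h = hist[t0];
                for (int i = 0; i < n; ++i) {
                    if (std::floor(c[i] * 1e12 + 0.5) !=
                        std::floor(h[i] * 1e12 + 0.5)) { same = false; break; }
                }
                if (!same) continue;
                int period = (int)hist.size() - t0;
                for (int i = 0; i < n; ++i) {
                    double m = 0.0;
                    for (size_t tt = t0; tt < hist.size(); ++tt) m += hist[tt][i];
                    contrib(i, j) = m / period;
                }
                converged[j] = true;
                cycle_len[j] = period;
                done = true;
                break;
            }
            if (done) break;
            hist.push_back(c);
            key.push_back(ksum);
            // synchronous belief update: others' realised mean
            if (n > 1) {
                for (int i = 0; i < n; ++i) belief[i] = (S - c[i]) / (n - 1);
            }
            cprev = c;
        }
        iters[j] = t + 1;
        if (!done) {   // trailing-window average, flagged
            int w = window < (int)hist.size() ? window : (int)hist.size();
            for (int i = 0; i < n; ++i) {
                double m = 0.0;
                for (int tt = (int)hist.size() - w; tt < (int)hist.size(); ++tt)
                    m += hist[tt][i];
                contrib(i, j) = m / w;
            }
            converged[j] = false;
            cycle_len[j] = NA_INTEGER;
        }
    }
    return List::create(_["contributions"] = contrib,
                        _["converged"] = converged,
                        _["cycle_length"] = cycle_len,
                        _["iterations"] = iters);
}
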