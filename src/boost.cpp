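#include <Rcpp.h>
#include <cstdint>
using namespace Rcpp;

// Histogram-based gradient boosting with oblivious (symmetric) trees and
// logistic loss: every node at a given tree level shares one (feature,
// threshold) split, so a depth-d tree is a lookup table with 2^d leaves.
// Deterministic: no row/column sampling; ties in the split search resolve
// to the lowest feature index, then the lowest threshold.

static inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// [[Rcpp::export]]
List cpp_oblivious_train(NumericMatrix X, NumericVector y, int nrounds,
                         int depth, double eta, double lambda, int n_bins) {
    const int n = X.nrow(), p = X.ncol();
    if (n_bins > 255) n_bins = 255;

    // quantile candidate thresholds per feature
    std::vector<std::vector<double> > edges(p);
    {
        std::vector<double> col(n);
        for (int f = 0; f < p; ++f) {
            for (int i = 0; i < n; ++i) col[i] = X(i, f);
            std::sort(col.begin(), col.end());
            std::vector<double> e;
            for (int b = 1; b < n_bins; ++b) {
                double q = col[(size_t)((double)b / n_bins * (n - 1))];
                if (e.empty() || q > e.back()) e.push_back(q);
            }
            edges[f] = e;
        }
    }
    // bin index = number of edges strictly below the value
    std::vector<uint8_t> B((size_t)n * p);
    for (int f = 0; f < p; ++f) {
        const std::vector<double> &e = edges[f];
        for (int i = 0; i < n; ++i) {
            int b = (int)(std::upper_bound(e.begin(), e.end(), X(i, f)) - e.begin());
            B[(size_t)f * n + i] = (uint8_t)b;
        }
    }

    double ybar = 0.0;
    for (int i = 0; i < n; ++i) ybar += y[i];
    ybar /= n;
    ybar = std::min(1.0 - 1e-6, std::max(1e-6, ybar));
    const double bias = std::log(ybar / (1.0 - ybar));

    const int nleaf = 1 << depth;
    IntegerMatrix feat(nrounds, depth);
    NumericMatrix thr(nrounds, depth);
    NumericMatrix leaves(nrounds, nleaf);
    NumericVector gain_total(p);

    std::vector<double> F(n, bias), g(n), h(n);
    std::vector<int> node(n);
    const int nb = n_bins;

    for (int round = 0; round < nrounds; ++round) {
        for (int i = 0; i < n; ++i) {
            double pr = sigmoid(F[i]);
            g[i] = pr - y[i];
            h[i] = pr * (1.0 - pr);
        }
        std::fill(node.begin(), node.end(), 0);

        for (int lev = 0; lev < depth; ++lev) {
            const int nnode = 1 << lev;
            double best_gain = -1.0;
            int best_f = -1, best_cut = -1;
            std::vector<double> G((size_t)nnode * nb), H((size_t)nnode * nb);

            for (int f = 0; f < p; ++f) {
                const int ncut = (int)edges[f].size();
                if (ncut == 0) continue;
                std::fill(G.begin(), G.end(), 0.0);
                std::fill(H.begin(), H.end(), 0.0);
                const uint8_t *bf = &B[(size_t)f * n];
                for (int i = 0; i < n; ++i) {
                    size_t k = (size_t)node[i] * nb + bf[i];
                    G[k] += g[i];
                    H[k] += h[i];
                }
                // running prefix per node; cut b keeps bins <= b on the left
                std::vector<double> cg(nnode, 0.0), ch(nnode, 0.0),
                    tg(nnode, 0.0), th(nnode, 0.0), base(nnode, 0.0);
                for (int nd = 0; nd < nnode; ++nd) {
                    for (int b = 0; b < nb; ++b) {
                        tg[nd] += G[(size_t)nd * nb + b];
                        th[nd] += H[(size_t)nd * nb + b];
                    }
                    base[nd] = tg[nd] * tg[nd] / (th[nd] + lambda);
                }
                for (int cut = 0; cut < ncut; ++cut) {
                    double gn = 0.0;
                    for (int nd = 0; nd < nnode; ++nd) {
                        cg[nd] += G[(size_t)nd * nb + cut];
                        ch[nd] += H[(size_t)nd * nb + cut];
                        double GR = tg[nd] - cg[nd], HR = th[nd] - ch[nd];
                        gn += cg[nd] * cg[nd] / (ch[nd] + lambda)
                              + GR * GR / (HR + lambda) - base[nd];
                    }
                    if (gn > best_gain + 1e-12) {
                        best_gain = gn;
                        best_f = f;
                        best_cut = cut;
                    }
                }
            }
            if (best_f < 0) { best_f = 0; best_cut = 0; best_gain = 0.0; }
            feat(round, lev) = best_f;
            thr(round, lev) = edges[best_f].empty() ? 0.0 : edges[best_f][best_cut];
            if (best_gain > 0) gain_total[best_f] += best_gain;
            const uint8_t *bf = &B[(size_t)best_f * n];
            for (int i = 0; i < n; ++i)
                node[i] = node[i] * 2 + (bf[i] > best_cut ? 1 : 0);
        }

        std::vector<double> GL(nleaf, 0.0), HL(nleaf, 0.0);
        for (int i = 0; i < n; ++i) {
            GL[node[i]] += g[i];
            HL[node[i]] += h[i];
        }
        for (int l = 0; l < nleaf; ++l)
            leaves(round, l) = HL[l] + lambda > 0 ? -eta * GL[l] / (HL[l] + lambda) : 0.0;
        for (int i = 0; i < n; ++i) F[i] += leaves(round, node[i]);
    }

    return List::create(_["bias"] = bias, _["feat"] = feat, _["thr"] = thr,
                        _["leaves"] = leaves, _["gain"] = gain_total,
                        _["depth"] = depth);
}

// [[Rcpp::export]]
NumericVector cpp_oblivious_predict(NumericMatrix X, double bias,
                                    IntegerMatrix feat, NumericMatrix thr,
                                    NumericMatrix leaves) {
    const int n = X.nrow(), nrounds = feat.nrow(), depth = feat.ncol();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        double F = bias;
        for (int r = 0; r < nrounds; ++r) {
            int node = 0;
            for (int lev = 0; lev < depth; ++lev)
                node = node * 2 + (X(i, feat(r, lev)) > thr(r, lev) ? 1 : 0);
            F += leaves(r, node);
        }
        out[i] = sigmoid(F);
    }
    return out;
}
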