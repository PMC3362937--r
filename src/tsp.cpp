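#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

// Open-path TSP over the pairwise recombination-fraction matrix: minimize
// the sum of d over adjacent markers with free endpoints.

namespace {

double path_len(const std::vector<int>& ord, const NumericMatrix& d) {
    double s = 0.0;
    for (size_t i = 1; i < ord.size(); ++i) s += d(ord[i - 1], ord[i]);
    return s;
}

// 2-opt for an open path: reverse segment [i, j].  Cost delta only involves
// the boundary edges (none at the path ends).
bool two_opt_pass(std::vector<int>& ord, const NumericMatrix& d) {
    int m = ord.size();
    bool improved = false;
    for (int i = 0; i < m - 1; ++i) {
        for (int j = i + 1; j < m; ++j) {
            if (i == 0 && j == m - 1) continue; // full reversal: no change
            double delta = 0.0;
            if (i > 0) delta += d(ord[i - 1], ord[j]) - d(ord[i - 1], ord[i]);
            if (j < m - 1) delta += d(ord[i], ord[j + 1]) - d(ord[j], ord[j + 1]);
            if (delta < -1e-12) {
                std::reverse(ord.begin() + i, ord.begin() + j + 1);
                improved = true;
            }
        }
    }
    return improved;
}

// Or-opt: relocate segments of length 1..3 (either orientation).
bool or_opt_pass(std::vector<int>& ord, const NumericMatrix& d) {
    int m = ord.size();
    bool improved = false;
    for (int len = 1; len <= 3 && len < m; ++len) {
        for (int i = 0; i + len <= m; ++i) {
            double base = path_len(ord, d);
            std::vector<int> seg(ord.begin() + i, ord.begin() + i + len);
            std::vector<int> rest;
            rest.reserve(m - len);
            for (int t = 0; t < m; ++t)
                if (t < i || t >= i + len) rest.push_back(ord[t]);
            double best = base;
            std::vector<int> best_ord = ord;
            for (int pos = 0; pos <= (int)rest.size(); ++pos) {
                for (int rev = 0; rev < 2; ++rev) {
                    std::vector<int> cand(rest.begin(), rest.begin() + pos);
                    if (rev == 0)
                        cand.insert(cand.end(), seg.begin(), seg.end());
                    else
                        cand.insert(cand.end(), seg.rbegin(), seg.rend());
                    cand.insert(cand.end(), rest.begin() + pos, rest.end());
                    double L = path_len(cand, d);
                    if (L < best - 1e-12) { best = L; best_ord = cand; }
                }
            }
            if (best < base - 1e-12) { ord = best_ord; improved = true; }
        }
    }
    return improved;
}

void local_search(std::vector<int>& ord, const NumericMatrix& d) {
    for (int round = 0; round < 200; ++round) {
        bool imp = false;
        while (two_opt_pass(ord, d)) imp = true;
        if (or_opt_pass(ord, d)) imp = true;
        if (!imp) break;
    }
}

std::vector<int> greedy_nn(const NumericMatrix& d, int start) {
    int m = d.nrow();
    std::vector<int> ord;
    std::vector<bool> used(m, false);
    ord.push_back(start);
    used[start] = true;
    for (int k = 1; k < m; ++k) {
        int cur = ord.back(), best = -1;
        double bd = R_PosInf;
        for (int j = 0; j < m; ++j)
            if (!used[j] && d(cur, j) < bd) { bd = d(cur, j); best = j; }
        ord.push_back(best);
        used[best] = true;
    }
    return ord;
}

} // namespace

// [[Rcpp::export]]
IntegerVector cpp_held_karp(NumericMatrix d) {
    int m = d.nrow();
    if (m > 20) stop("Held-Karp limited to 20 markers");
    if (m == 1) return IntegerVector::create(1);
    int M = 1 << m;
    std::vector<float> dp((size_t)M * m, std::numeric_limits<float>::infinity());
    std::vector<int> par((size_t)M * m, -1);
    for (int i = 0; i < m; ++i) dp[((size_t)(1 << i)) * m + i] = 0.0f;
    for (int mask = 1; mask < M; ++mask) {
        for (int last = 0; last < m; ++last) {
            if (!(mask & (1 << last))) continue;
            float cur = dp[(size_t)mask * m + last];
            if (!std::isfinite(cur)) continue;
            for (int nxt = 0; nxt < m; ++nxt) {
                if (mask & (1 << nxt)) continue;
                int nm = mask | (1 << nxt);
                float nd = cur + (float)d(last, nxt);
                if (nd < dp[(size_t)nm * m + nxt]) {
                    dp[(size_t)nm * m + nxt] = nd;
                    par[(size_t)nm * m + nxt] = last;
                }
            }
        }
    }
    int full = M - 1, best_last = 0;
    float best = std::numeric_limits<float>::infinity();
    for (int last = 0; last < m; ++last)
        if (dp[(size_t)full * m + last] < best) {
            best = dp[(size_t)full * m + last];
            best_last = last;
        }
    std::vector<int> ord;
    int mask = full, last = best_last;
    while (last >= 0) {
        ord.push_back(last);
        int p = par[(size_t)mask * m + last];
        mask &= ~(1 << last);
        last = p;
    }
    std::reverse(ord.begin(), ord.end());
    IntegerVector out(m);
    for (int i = 0; i < m; ++i) out[i] = ord[i] + 1;
    return out;
}

// Evolution-strategy heuristic: greedy construction + 2-opt/Or-opt local
// search, then iterated perturbation (segment reversal / translocation)
// keeping improvements only.
// [[Rcpp::export]]
IntegerVector cpp_tsp_heuristic(NumericMatrix d, int iters, int stall_limit,
                                int seed) {
    int m = d.nrow();
    if (m == 1) return IntegerVector::create(1);
    std::mt19937 rng(seed);
    std::vector<int> best;
    double best_len = R_PosInf;
    int nstarts = std::min(m, 4);
    std::vector<int> starts;
    for (int s = 0; s < nstarts; ++s)
        starts.push_back((int)(rng() % m));
    starts[0] = 0;
    for (int s : starts) {
        std::vector<int> ord = greedy_nn(d, s);
        local_search(ord, d);
        double L = path_len(ord, d);
        if (L < best_len) { best_len = L; best = ord; }
    }
    int stall = 0;
    std::uniform_int_distribution<int> upos(0, m - 1);
    for (int it = 0; it < iters && stall < stall_limit; ++it) {
        std::vector<int> cand = best;
        int kind = rng() % 2;
        int i = upos(rng), j = upos(rng);
        if (i > j) std::swap(i, j);
        if (i == j) j = std::min(m - 1, i + 1);
        if (kind == 0) {
            std::reverse(cand.begin() + i, cand.begin() + j + 1);
        } else {
            std::vector<int> seg(cand.begin() + i, cand.begin() + j + 1);
            cand.erase(cand.begin() + i, cand.begin() + j + 1);
            int pos = (int)(rng() % (cand.size() + 1));
            cand.insert(cand.begin() + pos, seg.begin(), seg.end());
        }
        local_search(cand, d);
        double L = path_len(cand, d);
        if (L < best_len - 1e-12) {
            best_len = L;
            best = cand;
            stall = 0;
        } else {
            ++stall;
        }
    }
    IntegerVector out(m);
    for (int i = 0; i < m; ++i) out[i] = best[i] + 1;
    return out;
}
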