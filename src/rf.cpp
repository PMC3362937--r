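#include <Rcpp.h>
using namespace Rcpp;

// Genotype codes: 0 = A (homozygote), 1 = H (heterozygote), 2 = B
// (alternative homozygote), NA = missing.  Cross types: 1 = BC, 2 = F2,
// 3 = RIL.

namespace {

// F2 two-point log-likelihood for the 3x3 joint genotype table, collapsed
// into its four sufficient classes.  r is the recombination fraction.
//   c_par : AA/AA + BB/BB                    ~ (1-r)^2 / 4
//   c_rec : AA/BB + BB/AA                    ~ r^2 / 4
//   c_mix : one homozygote, one heterozygote ~ r(1-r) / 2
//   c_het : AB/AB (phases confounded)        ~ ((1-r)^2 + r^2) / 2
double f2_loglik(double r, double c_par, double c_rec, double c_mix,
                 double c_het) {
    double lr = std::log(r), lq = std::log(1.0 - r);
    return 2.0 * c_par * lq + 2.0 * c_rec * lr + c_mix * (lr + lq) +
           c_het * std::log((1.0 - r) * (1.0 - r) + r * r);
}

// Golden-section maximization on [lo, hi]; the F2 likelihood is unimodal.
double f2_mle(double c_par, double c_rec, double c_mix, double c_het) {
    if (c_rec == 0.0 && c_mix == 0.0 && c_het == 0.0) return 0.0;
    const double gr = (std::sqrt(5.0) - 1.0) / 2.0;
    double lo = 1e-9, hi = 0.5;
    double a = hi - gr * (hi - lo), b = lo + gr * (hi - lo);
    double fa = f2_loglik(a, c_par, c_rec, c_mix, c_het);
    double fb = f2_loglik(b, c_par, c_rec, c_mix, c_het);
    for (int it = 0; it < 120; ++it) {
        if (fa < fb) {
            lo = a; a = b; fa = fb;
            b = lo + gr * (hi - lo);
            fb = f2_loglik(b, c_par, c_rec, c_mix, c_het);
        } else {
            hi = b; b = a; fb = fa;
            a = hi - gr * (hi - lo);
            fa = f2_loglik(a, c_par, c_rec, c_mix, c_het);
        }
    }
    double r = (lo + hi) / 2.0;
    if (r < 1e-8) r = 0.0;
    if (r > 0.5) r = 0.5;
    return r;
}

} // namespace

// [[Rcpp::export]]
List cpp_rf_pair(IntegerVector g1, IntegerVector g2, int cross_type) {
    int n = g1.size();
    double rf = NA_REAL;
    int ninf = 0;
    if (cross_type == 2) {
        double tab[3][3] = {{0}};
        for (int i = 0; i < n; ++i) {
            if (g1[i] == NA_INTEGER || g2[i] == NA_INTEGER) continue;
            tab[g1[i]][g2[i]] += 1.0;
            ++ninf;
        }
        double c_par = tab[0][0] + tab[2][2];
        double c_rec = tab[0][2] + tab[2][0];
        double c_mix = tab[0][1] + tab[1][0] + tab[1][2] + tab[2][1];
        double c_het = tab[1][1];
        if (ninf > 0) rf = f2_mle(c_par, c_rec, c_mix, c_het);
    } else {
        int mism = 0;
        for (int i = 0; i < n; ++i) {
            if (g1[i] == NA_INTEGER || g2[i] == NA_INTEGER) continue;
            if (g1[i] != g2[i]) ++mism;
            ++ninf;
        }
        if (ninf > 0) {
            double R = (double)mism / ninf;
            if (cross_type == 3) {
                // RIL by selfing: observed discordance R relates to the
                // meiotic fraction r through R = 2r/(1+2r).
                rf = (R >= 2.0 / 3.0) ? 0.5 : R / (2.0 * (1.0 - R));
            } else {
                rf = R;
            }
            if (rf > 0.5) rf = 0.5;
        }
    }
    return List::create(_["rf"] = rf, _["n"] = ninf);
}

// Full pairwise matrix; geno is markers x individuals.
// [[Rcpp::export]]
List cpp_rf_matrix(IntegerMatrix geno, int cross_type) {
    int m = geno.nrow();
    NumericMatrix rf(m, m);
    IntegerMatrix ninf(m, m);
    for (int a = 0; a < m; ++a) {
        for (int b = a + 1; b < m; ++b) {
            List res = cpp_rf_pair(geno(a, _), geno(b, _), cross_type);
            double r = res["rf"];
            int nn = res["n"];
            rf(a, b) = rf(b, a) = r;
            ninf(a, b) = ninf(b, a) = nn;
        }
    }
    return List::create(_["rf"] = rf, _["n"] = ninf);
}
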