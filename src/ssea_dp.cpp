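#include <Rcpp.h>
using namespace Rcpp;

// Fill the global element-alignment DP table.
// S is the n x m element-pair score matrix; gap is the per-element gap
// cost (0 in the published scheme, making skips free). Returns the
// (n+1) x (m+1) table F with F(0,0)=0 and
// F(i,j) = max(F(i-1,j) - gap, F(i,j-1) - gap, F(i-1,j-1) + S(i,j)).
// [[Rcpp::export]]
NumericMatrix ssea_dp_fill(NumericMatrix S, double gap) {
    const int n = S.nrow(), m = S.ncol();
    NumericMatrix F(n + 1, m + 1);
    for (int i = 1; i <= n; ++i) F(i, 0) = F(i - 1, 0) - gap;
    for (int j = 1; j <= m; ++j) F(0, j) = F(0, j - 1) - gap;
    for (int i = 1; i <= n; ++i) {
        for (int j = 1; j <= m; ++j) {
            double best = F(i - 1, j - 1) + S(i - 1, j - 1);
            double up = F(i - 1, j) - gap;
            double left = F(i, j - 1) - gap;
            if (up > best) best = up;
            if (left > best) best = left;
            F(i, j) = best;
        }
    }
    return F;
}
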