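// REML objective kernel for the AR(1) x AR(1) + block-components
// field-trial model. Hot path of fitSpatialReml(): called a few hundred
// times per fit by the derivative-free optimizer. The pure-R
// implementation (remlEval) is retained as the reference and the two are
// cross-checked in the test suite.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Profiled REML negative log-likelihood (up to a constant) for the
// cell-means line model with covariance
//   W = rhoRow^|r-r'| * rhoCol^|c-c'| + gC*[colset==] + gB*[batch==].
// line is 1-based group index; when full=true the GLS solution and the
// inverse information of the line means are returned as well.
// Dense O(n^3) route; remlGridCpp below exploits the Kronecker/Woodbury
// structure on complete grids and is cross-checked against this one.
// [[Rcpp::export(name = ".remlEvalCpp")]]
Rcpp::List remlEvalCpp(const arma::ivec& row, const arma::ivec& col,
                       const arma::ivec& colset, const arma::ivec& batch,
                       const arma::vec& y, const arma::ivec& line,
                       int nLev, double rhoRow, double rhoCol,
                       double gC, double gB, bool full = false) {
    const int n = y.n_elem;
    const double big = 1e10;
    Rcpp::List bad = Rcpp::List::create(Rcpp::Named("nll") = big);

    const int maxR = row.max() - row.min();
    const int maxC = col.max() - col.min();
    vec pr(maxR + 1), pc(maxC + 1);
    pr(0) = 1.0; pc(0) = 1.0;
    for (int k = 1; k <= maxR; ++k) pr(k) = pr(k - 1) * rhoRow;
    for (int k = 1; k <= maxC; ++k) pc(k) = pc(k - 1) * rhoCol;

    mat W(n, n);
    for (int j = 0; j < n; ++j) {
        for (int i = 0; i <= j; ++i) {
            double w = pr(std::abs(row(i) - row(j))) *
                       pc(std::abs(col(i) - col(j)));
            if (colset(i) == colset(j)) w += gC;
            if (batch(i) == batch(j)) w += gB;
            W(i, j) = w;
            W(j, i) = w;
        }
    }

    mat L;
    if (!chol(L, W, "lower")) return bad;
    mat Wi;
    if (!inv_sympd(Wi, W)) return bad;

    vec Wy = Wi * y;
    mat B(nLev, n, fill::zeros);
    vec b(nLev, fill::zeros);
    for (int i = 0; i < n; ++i) {
        B.row(line(i) - 1) += Wi.row(i);
        b(line(i) - 1) += Wy(i);
    }
    mat G(nLev, nLev, fill::zeros);
    for (int j = 0; j < n; ++j) G.col(line(j) - 1) += B.col(j);

    mat cG;
    if (!chol(cG, G, "lower")) return bad;
    vec tau = solve(trimatu(cG.t()), solve(trimatl(cG), b));
    double rss = dot(y, Wy) - dot(b, tau);
    if (rss <= 0) return bad;
    const int df = n - nLev;
    double sigma2 = rss / df;
    double nll = 0.5 * (df * std::log(sigma2) +
                        2.0 * accu(log(L.diag())) +
                        2.0 * accu(log(cG.diag())));
    if (!std::isfinite(nll)) return bad;
    if (!full)
        return Rcpp::List::create(Rcpp::Named("nll") = nll);
    mat Ginv;
    if (!inv_sympd(Ginv, G)) return bad;
    return Rcpp::List::create(
        Rcpp::Named("nll") = nll,
        Rcpp::Named("tau") = tau,
        Rcpp::Named("sigma2") = sigma2,
        Rcpp::Named("rss") = rss,
        Rcpp::Named("Ginv") = Ginv);
}

// Fast path for a complete nR x nC grid with no missing plots.
//
// W = S + U Gamma U' with S = R_row (x) R_col (AR(1) correlations) and
// U the column-set / batch indicator columns. S^-1 is the Kronecker
// product of tridiagonal AR(1) inverses, so S^-1 has at most 9
// nonzeros per row (grid neighbours); every quadratic form in S^-1 is
// accumulated in one pass over those nonzeros, and the block
// components enter by the Woodbury identity:
//   W^-1 = S^-1 - S^-1 U (Gamma^-1 + U'S^-1U)^-1 U'S^-1
//   log|W| = log|S| + sum(log gamma) + log|Gamma^-1 + U'S^-1U|
// with log|S| = nC (nR-1) log(1-rhoRow^2) + nR (nC-1) log(1-rhoCol^2).

// tridiagonal AR(1) inverse entry (i, j), 0-based, |i-j| <= 1
static inline double ar1inv(int i, int j, int n, double rho) {
    double d = 1.0 - rho * rho;
    if (i == j) {
        if (n == 1) return 1.0;
        return (i == 0 || i == n - 1) ? 1.0 / d : (1.0 + rho * rho) / d;
    }
    return -rho / d;
}

// [[Rcpp::export(name = ".remlGridCpp")]]
Rcpp::List remlGridCpp(const arma::ivec& row, const arma::ivec& col,
                       int nR, int nC,
                       const arma::ivec& colset, const arma::ivec& batch,
                       const arma::vec& y, const arma::ivec& line,
                       int nLev, double rhoRow, double rhoCol,
                       double gC, double gB, bool full = false) {
    const int n = y.n_elem;
    const double big = 1e10;
    Rcpp::List bad = Rcpp::List::create(Rcpp::Named("nll") = big);
    if (n != nR * nC || std::abs(rhoRow) >= 1 || std::abs(rhoCol) >= 1)
        return bad;

    // plot index by grid cell
    imat gid(nR, nC); gid.fill(-1);
    for (int i = 0; i < n; ++i) gid(row(i) - 1, col(i) - 1) = i;
    if (gid.min() < 0) return bad;

    // active Woodbury columns
    const int nCs = colset.max();
    const int nBt = batch.max();
    const bool useC = gC > 1e-8, useB = gB > 1e-8;
    const int offB = useC ? nCs : 0;
    const int nu = (useC ? nCs : 0) + (useB ? nBt : 0);

    mat XSX(nLev, nLev, fill::zeros);
    vec XSy(nLev, fill::zeros);
    mat XSU(nLev, std::max(nu, 1), fill::zeros);
    mat USU(std::max(nu, 1), std::max(nu, 1), fill::zeros);
    vec USy(std::max(nu, 1), fill::zeros);
    double ySy = 0.0;

    for (int i = 0; i < n; ++i) {
        const int ri = row(i) - 1, ci = col(i) - 1;
        const int a = line(i) - 1;
        const int uci = useC ? colset(i) - 1 : -1;
        const int ubi = useB ? offB + batch(i) - 1 : -1;
        for (int dr = -1; dr <= 1; ++dr) {
            const int rj = ri + dr;
            if (rj < 0 || rj >= nR) continue;
            const double sr = ar1inv(ri, rj, nR, rhoRow);
            for (int dc = -1; dc <= 1; ++dc) {
                const int cj = ci + dc;
                if (cj < 0 || cj >= nC) continue;
                const int j = gid(rj, cj);
                const double s = sr * ar1inv(ci, cj, nC, rhoCol);
                const int b = line(j) - 1;
                XSX(a, b) += s;
                XSy(a) += s * y(j);
                ySy += y(i) * s * y(j);
                const int ucj = useC ? colset(j) - 1 : -1;
                const int ubj = useB ? offB + batch(j) - 1 : -1;
                if (useC) {
                    XSU(a, ucj) += s;
                    USy(uci) += s * y(j);
                    USU(uci, ucj) += s;
                    if (useB) {
                        USU(uci, ubj) += s;
                        USU(ubi, ucj) += s;
                    }
                }
                if (useB) {
                    XSU(a, ubj) += s;
                    USy(ubi) += s * y(j);
                    USU(ubi, ubj) += s;
                }
            }
        }
    }

    double logdetW = nC * (nR - 1) * std::log(1.0 - rhoRow * rhoRow) +
                     nR * (nC - 1) * std::log(1.0 - rhoCol * rhoCol);
    mat G; vec b; double yWy;
    if (nu > 0) {
        mat M = USU.submat(0, 0, nu - 1, nu - 1);
        for (int u = 0; u < nu; ++u) {
            const double gam = (useC && u < nCs) ? gC : gB;
            M(u, u) += 1.0 / gam;
            logdetW += std::log(gam);
        }
        mat cM;
        if (!chol(cM, M, "lower")) return bad;
        logdetW += 2.0 * accu(log(cM.diag()));
        mat XSUa = XSU.cols(0, nu - 1);
        vec USya = USy.subvec(0, nu - 1);
        mat Mi_XSU, tmp; vec Mi_USy, tmpv;
        if (!solve(tmp, trimatl(cM), XSUa.t(),
                   solve_opts::no_approx) ||
            !solve(Mi_XSU, trimatu(cM.t()), tmp,
                   solve_opts::no_approx) ||
            !solve(tmpv, trimatl(cM), USya, solve_opts::no_approx) ||
            !solve(Mi_USy, trimatu(cM.t()), tmpv,
                   solve_opts::no_approx))
            return bad;
        G = XSX - XSUa * Mi_XSU;
        G = 0.5 * (G + G.t());
        b = XSy - XSUa * Mi_USy;
        yWy = ySy - dot(USya, Mi_USy);
    } else {
        G = XSX;
        b = XSy;
        yWy = ySy;
    }

    mat cG;
    if (!chol(cG, G, "lower")) return bad;
    vec tau, tv;
    if (!solve(tv, trimatl(cG), b, solve_opts::no_approx) ||
        !solve(tau, trimatu(cG.t()), tv, solve_opts::no_approx))
        return bad;
    double rss = yWy - dot(b, tau);
    if (rss <= 0) return bad;
    const int df = n - nLev;
    double sigma2 = rss / df;
    double nll = 0.5 * (df * std::log(sigma2) + logdetW +
                        2.0 * accu(log(cG.diag())));
    if (!std::isfinite(nll)) return bad;
    if (!full)
        return Rcpp::List::create(Rcpp::Named("nll") = nll);
    mat Ginv;
    if (!inv_sympd(Ginv, G)) return bad;
    return Rcpp::List::create(
        Rcpp::Named("nll") = nll,
        Rcpp::Named("tau") = tau,
        Rcpp::Named("sigma2") = sigma2,
        Rcpp::Named("rss") = rss,
        Rcpp::Named("Ginv") = Ginv);
}
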