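// Gibbs samplers for whole-genome regression models.
//
// Both samplers use R's RNG (RNGScope), so results are reproducible
// under set.seed() on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Wishart draw via Bartlett decomposition: W ~ Wishart(df, V)
static arma::mat rwishart(double df, const arma::mat& V) {
    const int t = V.n_rows;
    arma::mat L = arma::chol(V, "lower");
    arma::mat A(t, t, arma::fill::zeros);
    for (int i = 0; i < t; ++i) {
        A(i, i) = std::sqrt(R::rchisq(df - i));
        for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
    }
    arma::mat LA = L * A;
    return LA * LA.t();
}

// inverse-Wishart draw: Sigma ~ IW(Psi, df)
static arma::mat riwishart(double df, const arma::mat& Psi) {
    arma::mat W = rwishart(df, arma::inv_sympd(arma::symmatu(Psi)));
    return arma::inv_sympd(arma::symmatu(W));
}

// BayesB: y = X beta + W a + e.  Mixture prior per marker: point mass
// at zero with probability pi (exclusion mass, Beta(piA, piB) prior);
// slab = normal with marker-specific variance under a scaled-inverse-
// chi-square(df, S2) prior (marginally a scaled-t slab).
// [[Rcpp::export]]
List bayesb_gibbs(const arma::vec& y, const arma::mat& X, const arma::mat& W,
                  int nIter, int burnIn, double df, double S2,
                  double piA, double piB) {
    RNGScope scope;
    const int n = y.n_elem, p = X.n_cols, m = W.n_cols;
    arma::vec xtx(p), wtw(m);
    for (int j = 0; j < p; ++j) xtx(j) = arma::dot(X.col(j), X.col(j));
    for (int j = 0; j < m; ++j) wtw(j) = arma::dot(W.col(j), W.col(j));

    arma::vec beta(p, arma::fill::zeros);
    arma::vec a(m, arma::fill::zeros);
    arma::vec sig2a(m); sig2a.fill(df * S2 / (df + 2.0));
    arma::uvec delta(m, arma::fill::zeros);
    double vy = arma::var(y);
    double sig2e = 0.5 * vy;
    double piEx = piA / (piA + piB);
    const double nuE = 5.0, Se2 = 0.5 * vy;

    arma::vec e = y - X * beta;   // a starts at 0

    arma::vec sumA(m, arma::fill::zeros), sumD(m, arma::fill::zeros);
    arma::vec sumBeta(p, arma::fill::zeros);
    double sumPi = 0.0, sumSig2e = 0.0;
    int nKeep = 0;

    for (int it = 0; it < nIter; ++it) {
        // fixed effects, flat prior
        for (int j = 0; j < p; ++j) {
            double rhs = arma::dot(X.col(j), e) + xtx(j) * beta(j);
            double mean = rhs / xtx(j);
            double bNew = mean + R::norm_rand() * std::sqrt(sig2e / xtx(j));
            e += X.col(j) * (beta(j) - bNew);
            beta(j) = bNew;
        }
        // marker effects with inclusion indicator
        int nIn = 0;
        for (int j = 0; j < m; ++j) {
            double c = wtw(j);
            if (c <= 0) { a(j) = 0; delta(j) = 0; continue; }
            double rhs = arma::dot(W.col(j), e) + c * a(j);
            double v0 = c * sig2e;
            double v1 = c * c * sig2a(j) + c * sig2e;
            double logBF = 0.5 * (std::log(v0) - std::log(v1)) +
                           0.5 * rhs * rhs * (1.0 / v0 - 1.0 / v1);
            double logOdds = std::log(1.0 - piEx) - std::log(piEx) + logBF;
            double pIn = 1.0 / (1.0 + std::exp(-logOdds));
            double aNew = 0.0;
            int dNew = (R::unif_rand() < pIn) ? 1 : 0;
            if (dNew == 1) {
                double prec = c + sig2e / sig2a(j);
                double mean = rhs / prec;
                aNew = mean + R::norm_rand() * std::sqrt(sig2e / prec);
                ++nIn;
            }
            if (aNew != a(j)) e += W.col(j) * (a(j) - aNew);
            a(j) = aNew; delta(j) = dNew;
            // marker variance: scaled-inv-chi-square update
            if (dNew == 1)
                sig2a(j) = (df * S2 + aNew * aNew) / R::rchisq(df + 1.0);
            else
                sig2a(j) = df * S2 / R::rchisq(df);
        }
        // exclusion mass
        piEx = R::rbeta(piA + (m - nIn), piB + nIn);
        // residual variance
        sig2e = (arma::dot(e, e) + nuE * Se2) / R::rchisq(n + nuE);

        if (it >= burnIn) {
            sumA += a; sumD += arma::conv_to<arma::vec>::from(delta);
            sumBeta += beta; sumPi += piEx; sumSig2e += sig2e;
            ++nKeep;
        }
    }
    return List::create(
        _["effects"] = sumA / nKeep,
        _["inclusion"] = sumD / nKeep,
        _["beta"] = sumBeta / nKeep,
        _["pi"] = sumPi / nKeep,
        _["sigma2e"] = sumSig2e / nKeep);
}

// Multi-trait BayesC-pi: Y = X B + W A + E, rows of E ~ N(0, R).
// One shared inclusion indicator per marker; included markers get a
// t-variate normal effect with covariance SigmaA (inverse-Wishart
// updated); R inverse-Wishart updated; pi Beta updated.
// [[Rcpp::export]]
List bayescpi_gibbs(const arma::mat& Y, const arma::mat& X,
                    const arma::mat& W, int nIter, int burnIn,
                    double piA, double piB) {
    RNGScope scope;
    const int n = Y.n_rows, t = Y.n_cols, p = X.n_cols, m = W.n_cols;
    arma::vec xtx(p), wtw(m);
    for (int j = 0; j < p; ++j) xtx(j) = arma::dot(X.col(j), X.col(j));
    for (int j = 0; j < m; ++j) wtw(j) = arma::dot(W.col(j), W.col(j));

    arma::mat B(p, t, arma::fill::zeros);
    arma::mat A(m, t, arma::fill::zeros);
    arma::uvec delta(m, arma::fill::zeros);
    double piEx = piA / (piA + piB);

    // priors: IW for SigmaA and R, scales from phenotypic variances
    arma::vec vy(t);
    for (int k = 0; k < t; ++k) vy(k) = arma::var(Y.col(k));
    double meanWtw = arma::mean(wtw);
    double piBar = piA / (piA + piB);
    double nuA = t + 4.0, nuR = t + 4.0;
    // E[IW(Psi, nu)] = Psi / (nu - t - 1): aim slab variance at half the
    // phenotypic variance spread over the expected included markers
    arma::mat SA = arma::diagmat(
        0.5 * vy / std::max(1e-8, (1.0 - piBar) * m * meanWtw / n) *
        (nuA - t - 1.0));
    arma::mat SR = arma::diagmat(0.5 * vy * (nuR - t - 1.0));
    arma::mat SigmaA = SA / (nuA - t - 1.0);
    arma::mat Rmat = SR / (nuR - t - 1.0);

    arma::mat E = Y - X * B;

    arma::mat sumA(m, t, arma::fill::zeros);
    arma::mat sumB(p, t, arma::fill::zeros);
    arma::mat sumR(t, t, arma::fill::zeros);
    arma::vec sumD(m, arma::fill::zeros);
    double sumPi = 0.0;
    int nKeep = 0;

    for (int it = 0; it < nIter; ++it) {
        arma::mat Rinv = arma::inv_sympd(arma::symmatu(Rmat));
        arma::mat SigAinv = arma::inv_sympd(arma::symmatu(SigmaA));
        double ldSigA, sgn;
        arma::log_det(ldSigA, sgn, SigmaA);

        // fixed effects, flat prior: b_j ~ N(rhs/c, R/c)
        for (int j = 0; j < p; ++j) {
            arma::rowvec bOld = B.row(j);
            arma::rowvec rhs = X.col(j).t() * E + xtx(j) * bOld;
            arma::rowvec mean = rhs / xtx(j);
            arma::mat L = arma::chol(Rmat / xtx(j), "lower");
            arma::vec z(t);
            for (int k = 0; k < t; ++k) z(k) = R::norm_rand();
            arma::rowvec bNew = mean + (L * z).t();
            E += X.col(j) * (bOld - bNew);
            B.row(j) = bNew;
        }
        // marker effects
        int nIn = 0;
        for (int j = 0; j < m; ++j) {
            double c = wtw(j);
            if (c <= 0) { A.row(j).zeros(); delta(j) = 0; continue; }
            arma::rowvec aOld = A.row(j);
            arma::vec u = (W.col(j).t() * E).t() + c * aOld.t(); // t-vector
            arma::mat P = c * Rinv + SigAinv;
            arma::mat C = arma::inv_sympd(arma::symmatu(P));
            arma::vec mu = C * (Rinv * u);
            double ldC; arma::log_det(ldC, sgn, C);
            double logBF = 0.5 * (ldC - ldSigA) +
                           0.5 * arma::dot(mu, P * mu);
            double logOdds = std::log(1.0 - piEx) - std::log(piEx) + logBF;
            double pIn = 1.0 / (1.0 + std::exp(-logOdds));
            arma::rowvec aNew(t, arma::fill::zeros);
            int dNew = (R::unif_rand() < pIn) ? 1 : 0;
            if (dNew == 1) {
                arma::mat L = arma::chol(C, "lower");
                arma::vec z(t);
                for (int k = 0; k < t; ++k) z(k) = R::norm_rand();
                aNew = (mu + L * z).t();
                ++nIn;
            }
            E += W.col(j) * (aOld - aNew);
            A.row(j) = aNew; delta(j) = dNew;
        }
        // effect covariance from included markers
        arma::mat SS = SA;
        for (int j = 0; j < m; ++j)
            if (delta(j) == 1) SS += A.row(j).t() * A.row(j);
        SigmaA = riwishart(nuA + nIn, SS);
        // residual covariance
        Rmat = riwishart(nuR + n, SR + E.t() * E);
        // exclusion mass
        piEx = R::rbeta(piA + (m - nIn), piB + nIn);

        if (it >= burnIn) {
            sumA += A; sumB += B; sumR += Rmat;
            sumD += arma::conv_to<arma::vec>::from(delta);
            sumPi += piEx;
            ++nKeep;
        }
    }
    return List::create(
        _["effects"] = sumA / nKeep,
        _["inclusion"] = sumD / nKeep,
        _["beta"] = sumB / nKeep,
        _["R"] = sumR / nKeep,
        _["pi"] = sumPi / nKeep);
}
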