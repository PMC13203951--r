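// EM engine for the ordered-requirement DINA-type model.
//
// Works on the reduced representation: distinct response patterns (rows of
// Rp, with multiplicities w) crossed with ideal-response equivalence classes
// of profiles (rows of PIc, with prior log-mass log_prior).  Both reductions
// are exact; see the methods vignette.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Per-item success probabilities for every class, clipped away from {0,1}.
static mat item_probs(const mat& PIc, const vec& s, const vec& g, double clip) {
    mat p1 = PIc.each_row() % (1.0 - s.t());
    mat anti = 1.0 - PIc;
    p1 += anti.each_row() % g.t();
    return clamp(p1, clip, 1.0 - clip);
}

// One E-step sweep in blocks of patterns.  Fills zc (expected pattern mass
// per class) and Wm (expected correct responses, class x item); returns the
// marginal log-likelihood.
static double e_sweep(const mat& Rp, const vec& w, const mat& A,
                      const vec& off, vec& zc, mat& Wm, uword block) {
    const uword D = Rp.n_rows;
    double ll = 0.0;
    zc.zeros();
    Wm.zeros();
    for (uword start = 0; start < D; start += block) {
        const uword end = std::min<uword>(start + block, D) - 1;
        const mat Rb = Rp.rows(start, end);
        mat LL = Rb * A.t();              // B x M
        LL.each_row() += off.t();
        const vec mx = max(LL, 1);
        LL.each_col() -= mx;
        LL = exp(LL);
        const vec rs = sum(LL, 1);
        const vec wb = w.subvec(start, end);
        ll += accu(wb % (mx + log(rs)));
        LL.each_col() /= rs;              // posterior rows
        LL.each_col() %= wb;              // weighted by multiplicity
        zc += sum(LL, 0).t();
        Wm += LL.t() * Rb;
    }
    return ll;
}

// [[Rcpp::export(name = ".em_engine_cpp")]]
Rcpp::List em_engine_cpp(const arma::mat& Rp, const arma::vec& w,
                         const arma::mat& PIc, arma::vec log_prior,
                         arma::vec s, arma::vec g, bool update_prior,
                         double tol_param, double tol_loglik, int max_iter,
                         double clip, int block) {
    const uword E = Rp.n_cols, M = PIc.n_rows;
    const double U = accu(w);
    std::vector<double> trace, delta_trace;
    vec zc(M);
    mat Wm(M, E);
    int iter = 0, n_degenerate = 0;
    bool converged = false;
    double ll_old = -datum::inf;

    while (iter < max_iter) {
        ++iter;
        const mat p1 = item_probs(PIc, s, g, clip);
        const mat lp1 = log(p1), lp0 = log(1.0 - p1);
        const mat A = lp1 - lp0;
        const vec off = sum(lp0, 1) + log_prior;

        const double ll = e_sweep(Rp, w, A, off, zc, Wm, (uword)block);
        trace.push_back(ll);

        const vec colW = sum(Wm, 0).t();
        const vec F1 = sum(PIc % Wm, 0).t();
        const vec Z1 = PIc.t() * zc;
        const vec F0 = colW - F1;
        const vec Z0 = U - Z1;
        vec g_new = g, s_new = s;
        for (uword e = 0; e < E; ++e) {
            if (Z0(e) > 1e-10) g_new(e) = F0(e) / Z0(e); else ++n_degenerate;
            if (Z1(e) > 1e-10) s_new(e) = (Z1(e) - F1(e)) / Z1(e); else ++n_degenerate;
        }
        const double delta =
            std::max(abs(g_new - g).max(), abs(s_new - s).max());
        delta_trace.push_back(delta);
        g = clamp(g_new, clip, 1.0 - clip);
        s = clamp(s_new, clip, 1.0 - clip);
        if (update_prior)
            log_prior = log(clamp(zc / U, 1e-300, 1.0));

        const bool ll_flat = std::abs(ll - ll_old) < tol_loglik;
        ll_old = ll;
        if (delta < tol_param || ll_flat) {
            converged = true;
            break;
        }
    }

    return Rcpp::List::create(
        Rcpp::Named("s") = s, Rcpp::Named("g") = g,
        Rcpp::Named("log_prior") = log_prior, Rcpp::Named("zc") = zc,
        Rcpp::Named("loglik_trace") = trace,
        Rcpp::Named("delta_trace") = delta_trace,
        Rcpp::Named("n_iter") = iter,
        Rcpp::Named("converged") = converged,
        Rcpp::Named("n_degenerate") = n_degenerate);
}

// Posterior over classes for every pattern at fixed parameters, plus the
// per-pattern marginal log-likelihood.
// [[Rcpp::export(name = ".posterior_engine_cpp")]]
Rcpp::List posterior_engine_cpp(const arma::mat& Rp, const arma::mat& PIc,
                                const arma::vec& log_prior,
                                const arma::vec& s, const arma::vec& g,
                                double clip) {
    const mat p1 = item_probs(PIc, s, g, clip);
    const mat lp1 = log(p1), lp0 = log(1.0 - p1);
    const vec off = sum(lp0, 1) + log_prior;
    mat LL = Rp * (lp1 - lp0).t();
    LL.each_row() += off.t();
    const vec mx = max(LL, 1);
    LL.each_col() -= mx;
    LL = exp(LL);
    const vec rs = sum(LL, 1);
    LL.each_col() /= rs;
    return Rcpp::List::create(Rcpp::Named("post") = LL,
                              Rcpp::Named("loglik") = mx + log(rs));
}
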