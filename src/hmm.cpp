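// Scaled forward-backward (Rabiner) and log-space Viterbi for the
// Bernoulli-emission chromatin-state HMM.  Emission probabilities are
// precomputed in R as a T x K matrix per observation sequence; C++ only
// handles the sequential recursions.

#include <Rcpp.h>
using namespace Rcpp;

// Forward-backward pass for one sequence.
// em: T x K emission likelihoods P(x_t | state k) (linear scale).
// Returns log-likelihood, gamma (T x K posteriors), xi (K x K summed
// expected transition counts) and the first-row posterior.
// [[Rcpp::export(name = ".fb_scaled")]]
List fb_scaled(NumericMatrix em, NumericVector pi, NumericMatrix A) {
    const int T = em.nrow(), K = em.ncol();
    NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), xi(K, K);
    NumericVector cvec(T);

    // forward with per-step scaling
    double c = 0.0;
    for (int k = 0; k < K; ++k) {
        alpha(0, k) = pi[k] * em(0, k);
        c += alpha(0, k);
    }
    if (c <= 0.0) stop("zero forward probability at position 1");
    cvec[0] = c;
    for (int k = 0; k < K; ++k) alpha(0, k) /= c;

    for (int t = 1; t < T; ++t) {
        c = 0.0;
        for (int k = 0; k < K; ++k) {
            double s = 0.0;
            for (int j = 0; j < K; ++j) s += alpha(t - 1, j) * A(j, k);
            alpha(t, k) = s * em(t, k);
            c += alpha(t, k);
        }
        if (c <= 0.0) stop("zero forward probability at position %d", t + 1);
        cvec[t] = c;
        for (int k = 0; k < K; ++k) alpha(t, k) /= c;
    }

    // backward with the same scaling constants
    for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0 / cvec[T - 1];
    for (int t = T - 2; t >= 0; --t) {
        for (int j = 0; j < K; ++j) {
            double s = 0.0;
            for (int k = 0; k < K; ++k)
                s += A(j, k) * em(t + 1, k) * beta(t + 1, k);
            beta(t, j) = s / cvec[t];
        }
    }

    // posteriors and expected transition counts
    for (int t = 0; t < T; ++t) {
        double s = 0.0;
        for (int k = 0; k < K; ++k) {
            gamma(t, k) = alpha(t, k) * beta(t, k) * cvec[t];
            s += gamma(t, k);
        }
        for (int k = 0; k < K; ++k) gamma(t, k) /= s;
    }
    for (int t = 0; t < T - 1; ++t) {
        for (int j = 0; j < K; ++j) {
            if (alpha(t, j) == 0.0) continue;
            for (int k = 0; k < K; ++k)
                xi(j, k) += alpha(t, j) * A(j, k) * em(t + 1, k) *
                            beta(t + 1, k);
        }
    }

    double ll = 0.0;
    for (int t = 0; t < T; ++t) ll += std::log(cvec[t]);

    return List::create(_["loglik"] = ll, _["gamma"] = gamma,
                        _["xi"] = xi);
}

// Log-space Viterbi for one sequence; logem may contain -Inf.
// [[Rcpp::export(name = ".viterbi_path")]]
IntegerVector viterbi_path(NumericMatrix logem, NumericVector logpi,
                           NumericMatrix logA) {
    const int T = logem.nrow(), K = logem.ncol();
    NumericMatrix delta(T, K);
    IntegerMatrix psi(T, K);

    for (int k = 0; k < K; ++k) delta(0, k) = logpi[k] + logem(0, k);
    for (int t = 1; t < T; ++t) {
        for (int k = 0; k < K; ++k) {
            double best = R_NegInf;
            int arg = 0;
            for (int j = 0; j < K; ++j) {
                double v = delta(t - 1, j) + logA(j, k);
                if (v > best) { best = v; arg = j; }
            }
            delta(t, k) = best + logem(t, k);
            psi(t, k) = arg;
        }
    }

    IntegerVector path(T);
    double best = R_NegInf;
    int arg = 0;
    for (int k = 0; k < K; ++k)
        if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
    if (!R_finite(best)) stop("no admissible state path (all -Inf)");
    path[T - 1] = arg + 1;
    for (int t = T - 2; t >= 0; --t) {
        arg = psi(t + 1, arg);
        path[t] = arg + 1;
    }
    return path;
}
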