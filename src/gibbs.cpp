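#include <Rcpp.h>
using namespace Rcpp;

// One Dirichlet draw into out[0..m), concentration a[0..m).
static void rdirichlet(double *a, double *out, int m) {
    double s = 0.0;
    for (int i = 0; i < m; ++i) {
        out[i] = (a[i] > 0.0) ? R::rgamma(a[i], 1.0) : 0.0;
        s += out[i];
    }
    if (s <= 0.0) { out[0] = 1.0; s = 1.0; }
    for (int i = 0; i < m; ++i) out[i] /= s;
}

// Collapsed-parameter Gibbs sampler for the haploid admixture model.
// X: N x T state indices (1-based; 0 = missing). nStates: states per trait.
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
List gibbsStructure(IntegerMatrix X, IntegerVector nStates, int K,
                    double alpha, int burnin, int reps) {
    const int N = X.nrow(), T = X.ncol();
    if (K < 1) stop("K must be >= 1");
    if (alpha <= 0) stop("alpha must be positive");

    NumericMatrix q(N, K);
    std::vector<NumericMatrix> p(T);
    for (int t = 0; t < T; ++t) {
        p[t] = NumericMatrix(K, nStates[t]);
        for (int k = 0; k < K; ++k)
            for (int s = 0; s < nStates[t]; ++s)
                p[t](k, s) = 1.0 / nStates[t];
    }
    for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) q(i, k) = 1.0 / K;

    NumericMatrix Qsum(N, K);
    std::vector<NumericMatrix> Psum(T);
    for (int t = 0; t < T; ++t) Psum[t] = NumericMatrix(K, nStates[t]);
    NumericVector ll(reps);

    std::vector<double> prob(K), conc, draw;
    NumericMatrix nz(N, K);                     // z counts per genotype
    const int total = burnin + reps;

    for (int sweep = 0; sweep < total; ++sweep) {
        std::fill(nz.begin(), nz.end(), 0.0);
        std::vector<std::vector<double> > cz(T);  // z counts per trait: K x S
        for (int t = 0; t < T; ++t) cz[t].assign(K * nStates[t], 0.0);

        for (int i = 0; i < N; ++i) {
            for (int t = 0; t < T; ++t) {
                int x = X(i, t);
                if (x == 0) continue;
                double s = 0.0;
                for (int k = 0; k < K; ++k) {
                    prob[k] = q(i, k) * p[t](k, x - 1);
                    s += prob[k];
                }
                double u = unif_rand() * s, acc = 0.0;
                int z = K - 1;
                for (int k = 0; k < K; ++k) {
                    acc += prob[k];
                    if (u <= acc) { z = k; break; }
                }
                nz(i, z) += 1.0;
                cz[t][z * nStates[t] + (x - 1)] += 1.0;
            }
        }
        // q_i ~ Dirichlet(alpha + n_i.)
        conc.resize(K); draw.resize(K);
        for (int i = 0; i < N; ++i) {
            for (int k = 0; k < K; ++k) conc[k] = alpha + nz(i, k);
            rdirichlet(conc.data(), draw.data(), K);
            for (int k = 0; k < K; ++k) q(i, k) = draw[k];
        }
        // p_{k,t} ~ Dirichlet(1 + counts)
        for (int t = 0; t < T; ++t) {
            int S = nStates[t];
            conc.resize(S); draw.resize(S);
            for (int k = 0; k < K; ++k) {
                for (int s = 0; s < S; ++s) conc[s] = 1.0 + cz[t][k * S + s];
                rdirichlet(conc.data(), draw.data(), S);
                for (int s = 0; s < S; ++s) p[t](k, s) = draw[s];
            }
        }
        if (sweep >= burnin) {
            double loglik = 0.0;
            for (int i = 0; i < N; ++i)
                for (int t = 0; t < T; ++t) {
                    int x = X(i, t);
                    if (x == 0) continue;
                    double m = 0.0;
                    for (int k = 0; k < K; ++k) m += q(i, k) * p[t](k, x - 1);
                    loglik += std::log(m);
                }
            ll[sweep - burnin] = loglik;
            for (int i = 0; i < N; ++i)
                for (int k = 0; k < K; ++k) Qsum(i, k) += q(i, k);
            for (int t = 0; t < T; ++t)
                for (int k = 0; k < K; ++k)
                    for (int s = 0; s < nStates[t]; ++s)
                        Psum[t](k, s) += p[t](k, s);
        }
    }
    for (int i = 0; i < N; ++i)
        for (int k = 0; k < K; ++k) Qsum(i, k) /= reps;
    List Pout(T);
    for (int t = 0; t < T; ++t) {
        for (int k = 0; k < K; ++k)
            for (int s = 0; s < nStates[t]; ++s) Psum[t](k, s) /= reps;
        Pout[t] = Psum[t];
    }
    return List::create(_["Q"] = Qsum, _["P"] = Pout, _["ll"] = ll);
}
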