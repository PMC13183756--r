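#ifndef VOCALIB_DPO_H
#define VOCALIB_DPO_H

#include <vector>

// Renormalized Efron double-Poisson distribution with mean m and
// variance approximately m / tau.

// log of the unnormalized Efron term at y
double dpo_logterm(int y, double m, double tau);

// log normalizing constant log Z(m, tau) = log sum_y exp(dpo_logterm)
double dpo_logz(double m, double tau);

// normalized log pmf
double dpo_logpmf(int y, double m, double tau);

// normalized pmf values at y = 0..ymax (vector of length ymax + 1)
std::vector<double> dpo_pmf_vec(int ymax, double m, double tau);

// One target class j of the window likelihood below
double clip_class_loglik(int nj, const int *v, const double *lambda, int j, double tau);

// Exact log P(n | v, lambda, tau) for one 15-s window: the sum over all
// decompositions {n_ij >= 0 : sum_i n_ij = n_j} of products of DPO terms,
// computed per target class j as the 4-fold convolution of the source pmfs.
// lambda is row-major 4x4: lambda[i*4 + j].
double clip_loglik(const int *n, const int *v, const double *lambda, double tau);

// Continuous-v recording-level log likelihood: n_j ~ DPO(sum_i lambda_ij v_i, tau)
double rec_loglik(const int *n, const double *v, const double *lambda, double tau);

#endif
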