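// Adam minibatch training of the linear readout (W_out, b_out) on fixed
// granule-layer activations, over an alternating two-task curriculum.
// Activations are precomputed in R (the sparse expansion weights never
// change), so each phase is linear regression on fixed features; this loop
// only has to stream minibatches and track losses. Feature matrices arrive
// transposed (granule x sample) so a minibatch is a contiguous column
// block, and the Adam update is a single fused pass to avoid materializing
// per-step temporaries.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// one fused Adam step over a parameter block
static inline void adamStep(double* w, double* m, double* v, const double* g,
                            const uword n, const double lr,
                            const double beta1, const double beta2,
                            const double eps, const double bc1,
                            const double bc2) {
  for (uword i = 0; i < n; ++i) {
    const double gi = g[i];
    m[i] = beta1 * m[i] + (1.0 - beta1) * gi;
    v[i] = beta2 * v[i] + (1.0 - beta2) * gi * gi;
    w[i] -= lr * (m[i] / bc1) / (std::sqrt(v[i] / bc2) + eps);
  }
}

// [[Rcpp::export]]
Rcpp::List train_readout_cpp(const arma::mat& H1t, const arma::mat& Y1,
                             const arma::mat& H2t, const arma::mat& Y2,
                             arma::mat W, arma::rowvec b,
                             const arma::ivec& phases,
                             const int epochsPerPhase,
                             const arma::imat& perms,
                             const arma::uvec& prevIdx1,
                             const arma::uvec& prevIdx2,
                             const double lr, const int batchSize,
                             const double beta1, const double beta2,
                             const double eps) {
  const int nPhases = phases.n_elem;
  const int totalEpochs = nPhases * epochsPerPhase;
  if ((int) perms.n_cols != totalEpochs)
    Rcpp::stop("perms must have one column per epoch");

  // previous-task evaluation subsamples (fixed across training)
  const mat Hp1 = H1t.cols(prevIdx1), Hp2 = H2t.cols(prevIdx2);
  const mat Yp1 = Y1.rows(prevIdx1), Yp2 = Y2.rows(prevIdx2);

  mat mW(size(W), fill::zeros), vW(size(W), fill::zeros);
  rowvec mb(size(b), fill::zeros), vb(size(b), fill::zeros);

  std::vector<double> trainLoss;
  trainLoss.reserve((size_t) totalEpochs *
                    (H1t.n_cols / batchSize + 1));
  vec epochLoss(totalEpochs), prevLoss(totalEpochs);
  prevLoss.fill(datum::nan);
  long step = 0;
  int ge = 0;  // global epoch
  mat Hb, Eb, G;

  for (int p = 0; p < nPhases; ++p) {
    const int cur = phases[p];
    const mat& Ht = (cur == 1) ? H1t : H2t;
    const mat& Y = (cur == 1) ? Y1 : Y2;
    const int n = Ht.n_cols;
    const bool hasPrev = p > 0;
    const int prevTask = hasPrev ? phases[p - 1] : 0;
    const mat& Hp = (prevTask == 1) ? Hp1 : Hp2;
    const mat& Yp = (prevTask == 1) ? Yp1 : Yp2;

    for (int e = 0; e < epochsPerPhase; ++e, ++ge) {
      double lossSum = 0.0;
      int nBatches = 0;
      for (int start = 0; start < n; start += batchSize) {
        const int bsz = std::min(batchSize, n - start);
        Hb.set_size(Ht.n_rows, bsz);
        Eb.set_size(bsz, Y.n_cols);
        for (int i = 0; i < bsz; ++i) {
          const uword src = (uword) (perms(start + i, ge) - 1);
          Hb.col(i) = Ht.col(src);
          Eb.row(i) = Y.row(src);
        }
        Eb = Hb.t() * W + repmat(b, bsz, 1) - Eb;
        const double nb = (double) bsz;
        const double loss = accu(square(Eb)) / nb;
        if (!std::isfinite(loss))
          Rcpp::stop("non-finite training loss at phase %d, epoch %d",
                     p + 1, e + 1);
        trainLoss.push_back(loss);
        lossSum += loss;
        ++nBatches;

        G = Hb * Eb;                      // gradient * nb / 2
        const rowvec gb = (2.0 / nb) * sum(Eb, 0);
        G *= 2.0 / nb;

        ++step;
        const double bc1 = 1.0 - std::pow(beta1, (double) step);
        const double bc2 = 1.0 - std::pow(beta2, (double) step);
        adamStep(W.memptr(), mW.memptr(), vW.memptr(), G.memptr(),
                 W.n_elem, lr, beta1, beta2, eps, bc1, bc2);
        adamStep(b.memptr(), mb.memptr(), vb.memptr(), gb.memptr(),
                 b.n_elem, lr, beta1, beta2, eps, bc1, bc2);
      }
      epochLoss[ge] = lossSum / nBatches;
      if (hasPrev) {
        mat Ep = Hp.t() * W;
        Ep.each_row() += b;
        Ep -= Yp;
        prevLoss[ge] = accu(square(Ep)) / (double) Ep.n_rows;
      }
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("W") = W, Rcpp::Named("b") = b,
    Rcpp::Named("trainLoss") = trainLoss,
    Rcpp::Named("epochLoss") = epochLoss,
    Rcpp::Named("prevLoss") = prevLoss);
}
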