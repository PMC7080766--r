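// Mini-batch training loop of the sparse autoencoder. All randomness
// (weight init, epoch shuffles) is drawn on the R side and passed in, so
// results are reproducible from an R seed and independent of C++ RNGs.
// The arithmetic mirrors the R reference implementation in sae_cost().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".sae_train_core")]]
Rcpp::List sae_train_core(const arma::mat& x,
                          arma::mat We, arma::vec be,
                          arma::mat Wd, arma::vec bd,
                          const arma::umat& orders,  // n x epochs, 0-based
                          const int batch_size,
                          const double rho, const double gamma,
                          const double decay, const double eps,
                          const bool full_rho) {
  const uword n = x.n_rows;
  const uword epochs = orders.n_cols;
  const double clip_lo = 1e-12, clip_hi = 1.0 - 1e-12;

  mat aWe(size(We), fill::zeros), uWe(size(We), fill::zeros);
  vec abe(size(be), fill::zeros), ube(size(be), fill::zeros);
  mat aWd(size(Wd), fill::zeros), uWd(size(Wd), fill::zeros);
  vec abd(size(bd), fill::zeros), ubd(size(bd), fill::zeros);

  vec losses(epochs, fill::zeros);

  for (uword ep = 0; ep < epochs; ++ep) {
    double ep_cost = 0.0;
    uword n_batches = 0;
    for (uword start = 0; start < n; start += (uword)batch_size) {
      const uword stop = std::min(start + (uword)batch_size, n) - 1;
      const uvec rows = orders.col(ep).subvec(start, stop);
      const mat xb = x.rows(rows);
      const double nb = (double)xb.n_rows;

      mat h = xb * We.t();
      h.each_row() += be.t();
      h = 1.0 / (1.0 + exp(-h));
      mat y = h * Wd.t();
      y.each_row() += bd.t();
      y = 1.0 / (1.0 + exp(-y));

      rowvec rho_hat;
      double n_rho;
      mat hr;  // activations the sparsity term flows through (full_rho)
      if (full_rho) {
        hr = x * We.t();
        hr.each_row() += be.t();
        hr = 1.0 / (1.0 + exp(-hr));
        rho_hat = mean(hr, 0);
        n_rho = (double)n;
      } else {
        rho_hat = mean(h, 0);
        n_rho = nb;
      }
      const rowvec rh = clamp(rho_hat, clip_lo, clip_hi);
      const rowvec kl = rho * log(rho / rh) +
                        (1.0 - rho) * log((1.0 - rho) / (1.0 - rh));
      const double cost = accu(square(y - xb)) / (2.0 * nb) +
                          gamma * accu(kl);
      if (!std::isfinite(cost))
        Rcpp::stop("non-finite loss at epoch %d; reduce the step or gamma",
                   (int)ep + 1);
      ep_cost += cost;
      ++n_batches;

      // delta_y = ((y - x)/n) .* y .* (1 - y), reusing y's storage
      mat dy = std::move(y);
      dy = ((dy - xb) / nb) % dy % (1.0 - dy);
      const mat gWd = dy.t() * h;
      const vec gbd = sum(dy, 0).t();
      const rowvec klg = gamma * (-rho / rh + (1.0 - rho) / (1.0 - rh)) / n_rho;
      mat dh = dy * Wd;
      mat gWe;
      vec gbe;
      if (full_rho) {
        dh %= h % (1.0 - h);
        mat dhr = hr % (1.0 - hr);
        dhr.each_row() %= klg;
        gWe = dh.t() * xb + dhr.t() * x;
        gbe = (sum(dh, 0) + sum(dhr, 0)).t();
      } else {
        dh.each_row() += klg;
        dh %= h % (1.0 - h);
        gWe = dh.t() * xb;
        gbe = sum(dh, 0).t();
      }

      // adadelta: E[g^2] and E[du^2] running averages, per parameter
      aWe *= decay; aWe += (1.0 - decay) * square(gWe);
      mat sWe = -sqrt(uWe + eps) / sqrt(aWe + eps) % gWe;
      uWe *= decay; uWe += (1.0 - decay) * square(sWe);
      We += sWe;

      abe *= decay; abe += (1.0 - decay) * square(gbe);
      vec sbe = -sqrt(ube + eps) / sqrt(abe + eps) % gbe;
      ube *= decay; ube += (1.0 - decay) * square(sbe);
      be += sbe;

      aWd *= decay; aWd += (1.0 - decay) * square(gWd);
      mat sWd = -sqrt(uWd + eps) / sqrt(aWd + eps) % gWd;
      uWd *= decay; uWd += (1.0 - decay) * square(sWd);
      Wd += sWd;

      abd *= decay; abd += (1.0 - decay) * square(gbd);
      vec sbd = -sqrt(ubd + eps) / sqrt(abd + eps) % gbd;
      ubd *= decay; ubd += (1.0 - decay) * square(sbd);
      bd += sbd;
    }
    losses(ep) = ep_cost / (double)n_batches;
  }

  return Rcpp::List::create(
      Rcpp::Named("W_encoder") = We, Rcpp::Named("b_encoder") = be,
      Rcpp::Named("W_decoder") = Wd, Rcpp::Named("b_decoder") = bd,
      Rcpp::Named("loss_history") = losses);
}
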