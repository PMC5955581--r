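#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Coupled Poisson spiking with per-edge integer lags, run on a sub-frame
// grid so that zero-frame-lag (bidirectional) interactions can be expressed
// as a half-frame delay that rounds to lag 0 at imaging resolution.
//
// drive:      n x T external drive at frame resolution (baseline + stimulus
//             tuning + shared latent), in softplus-rate units
// w_by_lag:   list of n x n sparse coupling matrices indexed by sub-step
//             lag (element l holds edges with lag l sub-steps, l >= 1);
//             entry (j, i) is the weight of edge j -> i applied to the
//             synaptic trace of j at sub-step t - l
// dt_s:       frame duration in seconds
// substeps:   sub-steps per imaging frame
// rate_max:   rate ceiling in Hz (keeps the recurrence stable)
// syn_tau_s:  decay time of the exponential synaptic trace each spike
//             feeds (so one presynaptic spike contributes ~weight *
//             syn_tau_s expected extra spikes downstream)
//
// Returns an n x T matrix of spike counts per imaging frame. Uses R's RNG
// (R::rpois), so results are reproducible under set.seed().
// [[Rcpp::export]]
arma::mat sim_spikes_cpp(const arma::mat& drive, const Rcpp::List& w_by_lag,
                         double dt_s, int substeps, double rate_max,
                         double syn_tau_s) {
  const int n = drive.n_rows;
  const int T = drive.n_cols;
  const int L = w_by_lag.size();            // max sub-step lag
  const int Tsub = T * substeps;
  const double dt_sub = dt_s / substeps;

  std::vector<arma::sp_mat> wt(L);
  for (int l = 0; l < L; ++l) {
    arma::sp_mat w = Rcpp::as<arma::sp_mat>(w_by_lag[l]);
    wt[l] = w.t();                          // row i collects inputs to i
  }

  arma::mat spikes(n, T, arma::fill::zeros);
  // ring buffer of the last L sub-step synaptic-trace vectors
  arma::mat ring(n, std::max(L, 1), arma::fill::zeros);
  arma::vec syn(n, arma::fill::zeros);
  const double syn_decay = std::exp(-dt_sub / syn_tau_s);

  arma::vec x(n), s(n);
  for (int ts = 0; ts < Tsub; ++ts) {
    const int t = ts / substeps;
    x = drive.col(t);
    for (int l = 1; l <= L; ++l) {
      if (ts - l < 0) continue;
      const int slot = (ts - l) % std::max(L, 1);
      if (wt[l - 1].n_nonzero > 0) x += wt[l - 1] * ring.col(slot);
    }
    for (int i = 0; i < n; ++i) {
      double r = x(i) > 30.0 ? x(i) : std::log1p(std::exp(x(i)));
      if (r > rate_max) r = rate_max;
      s(i) = R::rpois(r * dt_sub);
    }
    syn = syn_decay * syn + s;
    if (L > 0) ring.col(ts % L) = syn;
    spikes.col(t) += s;
  }
  return spikes;
}
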