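// Impulsive-dose trajectory engine for the six-compartment tumor model.
//
// Between irradiation events the system is linear time-invariant (the
// growth-inhibition factor depends only on accumulated effective dose, which
// changes at events), so each segment is propagated exactly by a matrix
// exponential. Jumps move the lethally irradiated fraction from the
// proliferating compartment V1 to U1 and increment the accumulated effective
// dose IR_Tot by (1 + b*C)*D.
//
// State order: v1, v2, v3, v4, u1, u2.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat sysmat(double kg, double kk, double inhib) {
  arma::mat A(6, 6, arma::fill::zeros);
  A(0, 0) = kg * inhib - kk;          // v1' = (kg*I - kk) v1
  A(1, 0) = kk;                       // v2' = kk (v1 + u1 + u2) - kk v2
  A(1, 4) = kk;
  A(1, 5) = kk;
  A(1, 1) = -kk;
  A(2, 1) = kk;                       // v3' = kk (v2 - v3)
  A(2, 2) = -kk;
  A(3, 2) = kk;                       // v4' = kk (v3 - v4)
  A(3, 3) = -kk;
  A(4, 4) = -(kg + kk);               // u1' = -(kg + kk) u1
  A(5, 4) = 2.0 * kg;                 // u2' = 2 kg u1 - kk u2
  A(5, 5) = -kk;
  return A;
}

// events: columns (time, dose_gy, conc); times non-decreasing, all <= max(obsTimes).
// obsTimes: non-decreasing, >= 0. An observation at an event time records the
// left (pre-event) limit. Returns per-observation states and pre/post states
// at each event, each row (v1, v2, v3, v4, u1, u2, ir_tot).
// [[Rcpp::export(name = ".simulateEngine")]]
List simulateEngine(arma::vec x0, arma::mat events, arma::vec obsTimes,
                    double kg, double kk, double alpha, double beta,
                    double a, double gamma, double b) {
  const int nE = events.n_rows, nO = obsTimes.n_elem;
  arma::mat obs(nO, 7), evPre(nE, 7), evPost(nE, 7);
  arma::vec x = x0;
  double irTot = 0.0, t = 0.0;
  int ei = 0;

  auto record = [&](arma::mat& m, int row) {
    for (int k = 0; k < 6; ++k) m(row, k) = x(k);
    m(row, 6) = irTot;
  };
  auto step = [&](double dt) {
    if (dt <= 0.0) return;
    arma::mat A = sysmat(kg, kk, std::exp(-gamma * irTot));
    x = arma::expmat(A * dt) * x;
  };
  auto fire = [&](int i) {
    const double D = events(i, 1), C = events(i, 2);
    record(evPre, i);
    const double F = 1.0 - std::exp(-(1.0 + a * C) * (alpha * D + beta * D * D));
    const double moved = F * x(0);
    x(0) -= moved;
    x(4) += moved;
    irTot += (1.0 + b * C) * D;
    record(evPost, i);
  };

  for (int oi = 0; oi < nO; ++oi) {
    const double to = obsTimes(oi);
    while (ei < nE && events(ei, 0) < to) {
      step(events(ei, 0) - t);
      t = events(ei, 0);
      fire(ei);
      ++ei;
    }
    step(to - t);
    t = to;
    record(obs, oi);
  }
  // events falling exactly on the final observation time
  while (ei < nE && events(ei, 0) <= t) {
    step(events(ei, 0) - t);
    t = events(ei, 0);
    fire(ei);
    ++ei;
  }

  return List::create(_["obs"] = obs, _["eventPre"] = evPre,
                      _["eventPost"] = evPost);
}
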