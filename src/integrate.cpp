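// Euler gradient-flow integrators for the gated linear student and the
// two-layer fully-connected linear network. Hot loops live here; all
// orchestration, recording schemas and validation are on the R side.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::rowvec;
using arma::uword;
using arma::vec;

// Mean over rows of the cosine between corresponding rows; a zero row on
// either side contributes 0 (small-initialization convention).
static double row_mean_cosine(const mat &A, const mat &B) {
  double acc = 0.0;
  for (uword i = 0; i < A.n_rows; ++i) {
    const double na = arma::norm(A.row(i), 2);
    const double nb = arma::norm(B.row(i), 2);
    if (na > 0.0 && nb > 0.0) acc += arma::dot(A.row(i), B.row(i)) / (na * nb);
  }
  return acc / static_cast<double>(A.n_rows);
}

// Cosine between the concatenated student stack and the teacher stack,
// maximized over injective assignments (exhaustive; P, M are small).
static double total_alignment_cpp(const cube &W, const cube &Wstar) {
  const uword P = W.n_slices, M = Wstar.n_slices;
  double nW = 0.0, nT = 0.0;
  for (uword p = 0; p < P; ++p) nW += arma::accu(arma::square(W.slice(p)));
  for (uword m = 0; m < M; ++m) nT += arma::accu(arma::square(Wstar.slice(m)));
  nW = std::sqrt(nW);
  nT = std::sqrt(nT);
  if (nW == 0.0 || nT == 0.0) return 0.0;

  mat ip(P, M);
  for (uword p = 0; p < P; ++p)
    for (uword m = 0; m < M; ++m)
      ip(p, m) = arma::accu(W.slice(p) % Wstar.slice(m));

  double best = -arma::datum::inf;
  if (P <= M) {
    std::vector<uword> idx(M);
    for (uword m = 0; m < M; ++m) idx[m] = m;
    do {  // paths p matched to teachers idx[p], p = 0..P-1
      double num = 0.0;
      for (uword p = 0; p < P; ++p) num += ip(p, idx[p]);
      best = std::max(best, num);
    } while (std::next_permutation(idx.begin(), idx.end()));
  } else {
    std::vector<uword> idx(P);
    for (uword p = 0; p < P; ++p) idx[p] = p;
    do {  // teachers m matched to paths idx[m]
      double num = 0.0;
      for (uword m = 0; m < M; ++m) num += ip(idx[m], m);
      best = std::max(best, num);
    } while (std::next_permutation(idx.begin(), idx.end()));
  }
  return best / (nW * nT);
}

// Gradient of lambda_norm * 0.5*(||c||_k - 1)^2 + lambda_nonneg * sum(max(0,-c))
// with respect to the gate vector c (subgradient 0 at kinks).
static vec gate_reg_grad(const vec &c, double lambda_norm, double lambda_nonneg,
                         int norm_order) {
  vec g(c.n_elem, arma::fill::zeros);
  if (lambda_norm > 0.0) {
    if (norm_order == 1) {
      const double dev = arma::accu(arma::abs(c)) - 1.0;
      g += lambda_norm * dev * arma::sign(c);
    } else {
      const double nrm = arma::norm(c, 2);
      if (nrm > 0.0) g += lambda_norm * (nrm - 1.0) * (c / nrm);
    }
  }
  if (lambda_nonneg > 0.0) {
    for (uword p = 0; p < c.n_elem; ++p)
      if (c(p) < 0.0) g(p) -= lambda_nonneg;
  }
  return g;
}

// [[Rcpp::export]]
List cpp_integrate_gated(arma::cube W, arma::mat C, const arma::cube &Wstar,
                         const arma::ivec &task, double dt, double tau_w,
                         double tau_c, double lambda_norm, double lambda_nonneg,
                         int norm_order, bool per_row, int record_every,
                         int steps_per_block, bool minibatch, int batch_size) {
  const uword P = W.n_slices;
  const uword M = Wstar.n_slices;
  const uword dout = W.n_rows, din = W.n_cols;
  const uword n_steps = task.n_elem;

  const uword n_rec = (n_steps + record_every - 1) / record_every;
  vec r_time(n_rec), r_loss(n_rec), r_total(n_rec), r_dw(n_rec), r_dc(n_rec);
  arma::ivec r_block(n_rec), r_task(n_rec);
  mat r_gates(n_rec, P), r_wnorm(n_rec, P), r_align(n_rec, P * M);

  cube dW(dout, din, P);
  mat dC(arma::size(C));
  mat E(dout, din);
  cube WX;  // minibatch per-path activations
  if (minibatch) WX.set_size(dout, batch_size, P);

  uword r = 0;
  for (uword s = 0; s < n_steps; ++s) {
    const uword m = static_cast<uword>(task(s));
    const bool rec = (s % static_cast<uword>(record_every) == 0);

    // expected error matrix (always used for the recorded loss; drives the
    // updates in expectation mode)
    if (!minibatch || rec) {
      E = Wstar.slice(m);
      for (uword p = 0; p < P; ++p) {
        if (!per_row) {
          E -= C(p, 0) * W.slice(p);
        } else {
          for (uword i = 0; i < dout; ++i) E.row(i) -= C(p, i) * W.slice(p).row(i);
        }
      }
    }

    if (!minibatch) {
      // expectation-mode gradient flow
      for (uword p = 0; p < P; ++p) {
        if (!per_row) {
          dW.slice(p) = (C(p, 0) / tau_w) * E;
          dC(p, 0) = arma::accu(W.slice(p) % E);
        } else {
          for (uword i = 0; i < dout; ++i) {
            dW.slice(p).row(i) = (C(p, i) / tau_w) * E.row(i);
            dC(p, i) = arma::dot(W.slice(p).row(i), E.row(i));
          }
        }
      }
      if (!per_row) {
        const vec reg = gate_reg_grad(C.col(0), lambda_norm, lambda_nonneg, norm_order);
        dC.col(0) = (dC.col(0) - reg) / tau_c;
      } else {
        for (uword i = 0; i < dout; ++i) {
          const vec reg = gate_reg_grad(C.col(i), lambda_norm, lambda_nonneg, norm_order);
          dC.col(i) = (dC.col(i) - reg) / tau_c;
        }
      }
    } else {
      // minibatch stochastic gradients (empirical loss over batch_size samples)
      mat X(din, batch_size);
      for (uword j = 0; j < X.n_elem; ++j) X(j) = R::norm_rand();
      mat Err = Wstar.slice(m) * X;
      for (uword p = 0; p < P; ++p) {
        WX.slice(p) = W.slice(p) * X;
        if (!per_row) {
          Err -= C(p, 0) * WX.slice(p);
        } else {
          for (uword i = 0; i < dout; ++i) Err.row(i) -= C(p, i) * WX.slice(p).row(i);
        }
      }
      const double ib = 1.0 / static_cast<double>(batch_size);
      for (uword p = 0; p < P; ++p) {
        if (!per_row) {
          dW.slice(p) = (C(p, 0) * ib / tau_w) * (Err * X.t());
          dC(p, 0) = ib * arma::accu(WX.slice(p) % Err);
        } else {
          mat G = Err * X.t();  // dout x din
          for (uword i = 0; i < dout; ++i) {
            dW.slice(p).row(i) = (C(p, i) * ib / tau_w) * G.row(i);
            dC(p, i) = ib * arma::dot(WX.slice(p).row(i), Err.row(i));
          }
        }
      }
      if (!per_row) {
        const vec reg = gate_reg_grad(C.col(0), lambda_norm, lambda_nonneg, norm_order);
        dC.col(0) = (dC.col(0) - reg) / tau_c;
      } else {
        for (uword i = 0; i < dout; ++i) {
          const vec reg = gate_reg_grad(C.col(i), lambda_norm, lambda_nonneg, norm_order);
          dC.col(i) = (dC.col(i) - reg) / tau_c;
        }
      }
    }

    if (rec) {
      const double loss = 0.5 * arma::accu(E % E);
      if (!std::isfinite(loss) || loss > 1e6)
        stop("integration diverged (expected task loss %g at t = %g); decrease dt (= %g)",
             loss, s * dt, dt);
      r_time(r) = s * dt;
      r_block(r) = static_cast<int>(s / static_cast<uword>(steps_per_block)) + 1;
      r_task(r) = task(s) + 1;
      r_loss(r) = loss;
      double dwacc = 0.0;
      for (uword p = 0; p < P; ++p) {
        r_gates(r, p) = per_row ? arma::mean(C.row(p)) : C(p, 0);
        r_wnorm(r, p) = arma::norm(W.slice(p), "fro");
        dwacc += arma::accu(arma::square(dW.slice(p)));
        for (uword mm = 0; mm < M; ++mm)
          r_align(r, p * M + mm) = row_mean_cosine(W.slice(p), Wstar.slice(mm));
      }
      r_dw(r) = std::sqrt(dwacc);
      r_dc(r) = arma::norm(arma::vectorise(dC), 2);
      r_total(r) = total_alignment_cpp(W, Wstar);
      ++r;
    }

    for (uword p = 0; p < P; ++p) W.slice(p) += dt * dW.slice(p);
    C += dt * dC;
  }

  return List::create(
      _["time"] = r_time, _["block"] = r_block, _["task"] = r_task,
      _["loss"] = r_loss, _["gates"] = r_gates, _["w_norm"] = r_wnorm,
      _["align"] = r_align, _["total_align"] = r_total, _["dw_norm"] = r_dw,
      _["dc_norm"] = r_dc, _["W_final"] = W, _["C_final"] = C);
}

// [[Rcpp::export]]
List cpp_integrate_deep(arma::mat W1, arma::mat W2, const arma::cube &Wstar,
                        const arma::ivec &task, double dt, double tau_1,
                        double tau_2, double lambda_norm, double lambda_nonneg,
                        int norm_order, int record_every, int steps_per_block) {
  const uword n_steps = task.n_elem;
  const uword hidden = W1.n_rows, din = W1.n_cols, dout = W2.n_rows;
  const uword n_blocks = n_steps / static_cast<uword>(steps_per_block);

  const uword n_rec = (n_steps + record_every - 1) / record_every;
  vec r_time(n_rec), r_loss(n_rec), r_dw1(n_rec), r_dw2(n_rec);
  arma::ivec r_block(n_rec), r_task(n_rec);
  cube snap1(hidden, din, std::max<uword>(n_blocks, 1), arma::fill::zeros);
  cube snap2(dout, hidden, std::max<uword>(n_blocks, 1), arma::fill::zeros);

  mat E(dout, din), dW1(hidden, din), dW2(dout, hidden);
  uword r = 0;
  for (uword s = 0; s < n_steps; ++s) {
    const uword m = static_cast<uword>(task(s));
    E = Wstar.slice(m) - W2 * W1;
    dW1 = (W2.t() * E) / tau_1;
    dW2 = E * W1.t();
    // gate-style regularization on each output row of the fast second layer
    for (uword i = 0; i < dout; ++i) {
      const vec ci = W2.row(i).t();
      dW2.row(i) -= gate_reg_grad(ci, lambda_norm, lambda_nonneg, norm_order).t();
    }
    dW2 /= tau_2;

    if (s % static_cast<uword>(record_every) == 0) {
      const double loss = 0.5 * arma::accu(E % E);
      if (!std::isfinite(loss) || loss > 1e6)
        stop("integration diverged (expected task loss %g at t = %g); decrease dt (= %g)",
             loss, s * dt, dt);
      r_time(r) = s * dt;
      r_block(r) = static_cast<int>(s / static_cast<uword>(steps_per_block)) + 1;
      r_task(r) = task(s) + 1;
      r_loss(r) = loss;
      r_dw1(r) = arma::norm(dW1, "fro");
      r_dw2(r) = arma::norm(dW2, "fro");
      ++r;
    }

    W1 += dt * dW1;
    W2 += dt * dW2;

    if ((s + 1) % static_cast<uword>(steps_per_block) == 0) {
      const uword b = (s + 1) / static_cast<uword>(steps_per_block) - 1;
      if (b < n_blocks) {
        snap1.slice(b) = W1;
        snap2.slice(b) = W2;
      }
    }
  }

  return List::create(_["time"] = r_time, _["block"] = r_block,
                      _["task"] = r_task, _["loss"] = r_loss,
                      _["dw1_norm"] = r_dw1, _["dw2_norm"] = r_dw2,
                      _["W1_final"] = W1, _["W2_final"] = W2,
                      _["W1_block_end"] = snap1, _["W2_block_end"] = snap2);
}
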