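// Computational kernels: D-error coordinate exchange for design generation
// and the simulated log-likelihood (with analytic gradient and respondent
// scores) of the interaction mixed logit.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// log-determinant based D-error of the MNL information matrix M (K x K);
// returns +Inf when M is (numerically) singular.
static double d_error_from_M(const arma::mat& M) {
  double val, sign;
  bool ok = arma::log_det(val, sign, M);
  const double K = static_cast<double>(M.n_rows);
  if (!ok || sign <= 0.0 || !std::isfinite(val) ||
      val < std::log(arma::datum::eps) * K)
    return arma::datum::inf;
  return std::exp(-val / K);
}

// information contribution of one task (rows of X given by idx) at priors
static arma::mat task_info(const arma::mat& Xc, const arma::uvec& idx,
                           const arma::vec& priors) {
  arma::mat Xt = Xc.rows(idx);
  arma::vec v = Xt * priors;
  v -= v.max();
  arma::vec p = arma::exp(v);
  p /= arma::accu(p);
  arma::rowvec xbar = p.t() * Xt;
  Xt.each_row() -= xbar;
  Xt.each_col() %= arma::sqrt(p);
  return Xt.t() * Xt;
}

// would task t, with slot j set to candidate c, duplicate another task?
static bool duplicates_other_task(const arma::umat& tasks, arma::uword t,
                                  arma::uword j, arma::uword c) {
  const arma::uword T = tasks.n_rows, J = tasks.n_cols;
  arma::uvec mod = tasks.row(t).t();
  mod(j) = c;
  mod = arma::sort(mod);
  for (arma::uword o = 0; o < T; ++o) {
    if (o == t) continue;
    arma::uvec other = arma::sort(tasks.row(o).t());
    if (arma::all(other == mod)) return true;
  }
  return false;
}

// [[Rcpp::export]]
List cpp_coordinate_exchange(const arma::mat& Xc,
                             arma::umat tasks,  // T x J, 0-based candidates
                             const arma::vec& priors,
                             int max_passes) {
  const arma::uword T = tasks.n_rows, J = tasks.n_cols, C = Xc.n_rows,
                    K = Xc.n_cols;
  arma::mat M(K, K, arma::fill::zeros);
  for (arma::uword t = 0; t < T; ++t)
    M += task_info(Xc, tasks.row(t).t(), priors);
  double cur = d_error_from_M(M);

  for (int pass = 0; pass < max_passes; ++pass) {
    bool improved = false;
    for (arma::uword t = 0; t < T; ++t) {
      for (arma::uword j = 0; j < J; ++j) {
        arma::uvec idx = tasks.row(t).t();
        arma::mat Mbase = M - task_info(Xc, idx, priors);
        arma::uword orig = idx(j);
        double best_de = cur;
        arma::uword best_c = orig;
        for (arma::uword c = 0; c < C; ++c) {
          if (c == orig) continue;
          bool dup = false;  // no identical profiles within a task
          for (arma::uword jj = 0; jj < J; ++jj)
            if (jj != j && idx(jj) == c) { dup = true; break; }
          if (dup) continue;
          // no task may duplicate another task of the design
          if (duplicates_other_task(tasks, t, j, c)) continue;
          idx(j) = c;
          double de = d_error_from_M(Mbase + task_info(Xc, idx, priors));
          if (de < best_de * (1.0 - 1e-12)) { best_de = de; best_c = c; }
        }
        if (best_c != orig) {
          idx(j) = best_c;
          M = Mbase + task_info(Xc, idx, priors);
          tasks(t, j) = best_c;
          cur = best_de;
          improved = true;
        }
      }
    }
    if (!improved) break;
  }
  return List::create(Named("tasks") = tasks, Named("d_error") = cur);
}

// Simulated log-likelihood of the panel mixed logit whose coefficient means
// and standard deviations shift with vignette dummies.
//
//   u_row = Xm * bm  +  sum_c Xs(row, c) * bs[c] * eta(draw, sd_dim[c], resp)
//
// Per respondent the likelihood is the average over draws of the product of
// chosen-alternative logit probabilities across that respondent's tasks.
//
// task_start: row offsets per task (0-based, length n_tasks + 1);
// chosen_row: absolute row index of the chosen alternative per task;
// resp_task_start: task offsets per respondent (tasks ordered by respondent).
// [[Rcpp::export]]
List cpp_mixl_eval(const arma::vec& bm, const arma::vec& bs,
                   const arma::mat& Xm, const arma::mat& Xs,
                   const arma::uvec& sd_dim,
                   const arma::uvec& task_start,
                   const arma::uvec& chosen_row,
                   const arma::uvec& resp_task_start,
                   const arma::cube& eta,  // R x D x N
                   bool want_grad, bool want_scores) {
  const arma::uword Km = Xm.n_cols, Ks = Xs.n_cols, Kall = Km + Ks;
  const arma::uword N = resp_task_start.n_elem - 1;
  const arma::uword R = (Ks > 0) ? eta.n_rows : 1;
  const bool grads = want_grad || want_scores;

  arma::vec Vm = Xm * bm;
  arma::mat W;  // Xs scaled by the SD coefficients
  if (Ks > 0) { W = Xs; W.each_row() %= bs.t(); }

  double ll = 0.0;
  arma::vec grad(Kall, arma::fill::zeros);
  arma::mat scores;
  if (want_scores) scores.zeros(N, Kall);

  arma::vec logP(R);
  for (arma::uword i = 0; i < N; ++i) {
    const arma::uword t0 = resp_task_start(i), t1 = resp_task_start(i + 1);
    const arma::uword r0 = task_start(t0), r1 = task_start(t1);
    const arma::uword ni = r1 - r0;

    // utilities for all of respondent i's rows across all draws
    arma::mat Et;            // Ks x R: eta value per SD column and draw
    arma::mat U(ni, R);
    if (Ks > 0) {
      Et = eta.slice(i).cols(sd_dim).t();
      U = W.rows(r0, r1 - 1) * Et;
      U.each_col() += Vm.subvec(r0, r1 - 1);
    } else {
      U.each_col() = Vm.subvec(r0, r1 - 1);
    }

    // per task: column-wise softmax; U is overwritten with probabilities
    logP.zeros();
    for (arma::uword t = t0; t < t1; ++t) {
      const arma::uword a = task_start(t) - r0, b = task_start(t + 1) - r0;
      const arma::uword chj = chosen_row(t) - r0;
      for (arma::uword r = 0; r < R; ++r) {
        double umax = U(a, r);
        for (arma::uword j = a + 1; j < b; ++j)
          if (U(j, r) > umax) umax = U(j, r);
        double sump = 0.0;
        for (arma::uword j = a; j < b; ++j) {
          const double e = std::exp(U(j, r) - umax);
          U(j, r) = e;
          sump += e;
        }
        logP(r) += std::log(U(chj, r) / sump);
        if (grads)
          for (arma::uword j = a; j < b; ++j) U(j, r) /= sump;
      }
    }

    const double m0 = logP.max();
    arma::vec w = arma::exp(logP - m0);
    const double S = arma::accu(w);
    ll += m0 + std::log(S) - std::log(static_cast<double>(R));

    if (grads) {
      // score_i = sum_r w_r/S * Xaug' (c - p_r), with the SD block scaled
      // by the draw values
      const arma::vec wn = w / S;
      arma::vec si(Kall);
      arma::uvec ch = chosen_row.subvec(t0, t1 - 1) - r0;
      const arma::mat Xmi = Xm.rows(r0, r1 - 1);
      arma::vec Pw = U * wn;  // ni: draw-weighted choice probabilities
      arma::vec cm(ni, arma::fill::zeros);
      for (arma::uword t = 0; t < ch.n_elem; ++t) cm(ch(t)) = 1.0;
      si.subvec(0, Km - 1) = Xmi.t() * (cm - Pw);
      if (Ks > 0) {
        const arma::mat Xsi = Xs.rows(r0, r1 - 1);
        // A(c, r) = [Xs' (c - p_r)](c), then scale by eta and weight
        arma::mat A = Xsi.t() * U;      // Ks x R, using probabilities
        A.each_col() -= Xsi.t() * cm;   // = -(Xs'(c - p_r))
        A %= Et;
        si.subvec(Km, Kall - 1) = -(A * wn);
      }
      grad += si;
      if (want_scores) scores.row(i) = si.t();
    }
  }

  List out = List::create(Named("loglik") = ll);
  if (want_grad) out["gradient"] = grad;
  if (want_scores) out["scores"] = scores;
  return out;
}
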