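// Fast inner loop for trial-level training and classification. The R
// functions net_forward() / bptt_gradients() / sgd_update() are the
// reference implementation; this engine reproduces them trial for trial
// (tested for agreement) so condition-level experiments stay tractable.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::vec sigmoid(const arma::vec& z) {
  return 1.0 / (1.0 + arma::exp(-z));
}

// Assemble the 82-unit input for one trial row.
// Trial columns (1-based values): target, foil_form, foil_referent,
// form_slot, object_slot, prosody, gesture, distributional.
static arma::vec assemble(const IntegerMatrix& trials, int i,
                          const arma::mat& forms, const arma::mat& refs,
                          const IntegerVector& cat_a, int n_input) {
  arma::vec x(n_input, arma::fill::zeros);
  const int target = trials(i, 0) - 1;
  const int foil_f = trials(i, 1) - 1;
  const int foil_r = trials(i, 2) - 1;
  const int fslot = trials(i, 3) - 1;   // 0 or 1
  const int oslot = trials(i, 4) - 1;
  const double pro = trials(i, 5) ? 2.0 : 1.0;
  const double ges = trials(i, 6) ? 2.0 : 1.0;

  x.subvec(fslot * 20, fslot * 20 + 19) = pro * forms.row(target).t();
  x.subvec((1 - fslot) * 20, (1 - fslot) * 20 + 19) = forms.row(foil_f).t();
  x.subvec(40 + oslot * 20, 40 + oslot * 20 + 19) = ges * refs.row(target).t();
  x.subvec(40 + (1 - oslot) * 20, 40 + (1 - oslot) * 20 + 19) =
      refs.row(foil_r).t();
  if (trials(i, 7)) x(80 + (cat_a[target] ? 0 : 1)) = 1.0;
  return x;
}

// One pass over a block of trials: forward each trial, classify it from the
// final-step semantic activations (strict argmax, pre-update), and, when
// update is true, apply one online BPTT gradient step per trial.
// [[Rcpp::export]]
List cpp_run_trials(List w, IntegerMatrix trials, NumericMatrix forms_,
                    NumericMatrix referents_, IntegerVector category_a,
                    int timesteps, IntegerVector error_window, double lr,
                    bool update) {
  arma::mat W_in = as<arma::mat>(w["W_in"]);
  arma::mat W_hh = as<arma::mat>(w["W_hh"]);
  arma::mat W_hs = as<arma::mat>(w["W_hs"]);
  arma::vec b_h = as<arma::vec>(w["b_h"]);
  arma::vec b_s = as<arma::vec>(w["b_s"]);

  const arma::mat forms = as<arma::mat>(forms_);
  const arma::mat refs = as<arma::mat>(referents_);
  const int n_h = W_hh.n_rows;
  const int n_s = W_hs.n_rows;
  const int n_in = W_in.n_cols;
  const int T = timesteps;
  const int n_trials = trials.nrow();

  std::vector<bool> in_window(T + 1, false);
  for (int k = 0; k < error_window.size(); ++k)
    in_window[error_window[k]] = true;

  LogicalVector correct(n_trials);
  arma::mat H(n_h, T), S(n_s, T);

  for (int i = 0; i < n_trials; ++i) {
    const int target = trials(i, 0) - 1;
    const arma::vec x = assemble(trials, i, forms, refs, category_a, n_in);

    // forward: semantic reads the previous hidden state (one-step delay)
    arma::vec h_prev(n_h, arma::fill::zeros);
    const arma::vec in_drive = W_in * x + b_h;
    for (int t = 0; t < T; ++t) {
      S.col(t) = sigmoid(W_hs * h_prev + b_s);
      h_prev = sigmoid(in_drive + W_hh * h_prev);
      H.col(t) = h_prev;
    }

    const arma::vec out = S.col(T - 1);
    const double tmax = out(target);
    bool ok = true;
    for (int j = 0; j < n_s; ++j)
      if (j != target && out(j) >= tmax) { ok = false; break; }
    correct[i] = ok;

    if (!update) continue;

    // error injected on the semantic pre-activations in the window
    arma::mat dS(n_s, T, arma::fill::zeros);
    for (int t = 1; t <= T; ++t) {
      if (!in_window[t]) continue;
      arma::vec s = S.col(t - 1);
      s(target) -= 1.0;                        // s - y, localist target
      dS.col(t - 1) = 2.0 * s % S.col(t - 1) % (1.0 - S.col(t - 1));
    }

    arma::mat gW_hs(n_s, n_h, arma::fill::zeros);
    arma::vec gb_s(n_s, arma::fill::zeros);
    for (int t = 0; t < T; ++t) {
      if (!in_window[t + 1]) continue;
      if (t >= 1) gW_hs += dS.col(t) * H.col(t - 1).t();
      gb_s += dS.col(t);                       // h(0) = 0: no W_hs term at t=1
    }

    arma::mat gW_hh(n_h, n_h, arma::fill::zeros);
    arma::vec sum_dh(n_h, arma::fill::zeros);
    arma::vec dH(n_h, arma::fill::zeros);
    for (int t = T; t >= 1; --t) {
      arma::vec e_h(n_h, arma::fill::zeros);
      if (t < T) {
        e_h = W_hh.t() * dH;
        if (in_window[t + 1]) e_h += W_hs.t() * dS.col(t);
      }
      dH = e_h % H.col(t - 1) % (1.0 - H.col(t - 1));
      sum_dh += dH;
      if (t >= 2) gW_hh += dH * H.col(t - 2).t();
    }

    W_in -= lr * (sum_dh * x.t());             // x clamped across steps
    W_hh -= lr * gW_hh;
    W_hs -= lr * gW_hs;
    b_h -= lr * sum_dh;
    b_s -= lr * gb_s;
  }

  return List::create(
      _["W_in"] = W_in, _["W_hh"] = W_hh, _["W_hs"] = W_hs,
      _["b_h"] = b_h, _["b_s"] = b_s, _["correct"] = correct);
}
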