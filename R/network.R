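# The hub-and-spoke recurrent network. The input layer (82 units: 2 x 20
# phonological, 2 x 20 visual, 2 distributional) projects to a fully
# self-connected integrative hidden layer, which projects to a localist
# semantic output layer. Activation cycles for six synchronous time steps
# with a one-step delay per connection; error is injected on the semantic
# layer at steps 3-6 and gradients come from unrolled backpropagation
# through time.

#' Network hyperparameters
#'
#' @param n_input Input layer size (82 for the standard task: two 20-unit
#'   word slots, two 20-unit object slots, 2 distributional units).
#' @param n_hidden Integrative layer size (default 100).
#' @param n_semantic Semantic output size; equals the lexicon size under
#'   localist coding (default 100).
#' @param timesteps Number of synchronous update steps per trial (default 6).
#' @param error_window Steps at which output error is injected (default 3:6).
#' @param learning_rate Online SGD step size. The source model leaves this
#'   unstated; 0.1 is the package default, calibrated presets override it.
#' @param init_range Weights and biases start uniform in
#'   `[-init_range, init_range]`.
#' @return A `"net_hyperparameters"` list.
#' @export
net_hyperparameters <- function(n_input = 82L, n_hidden = 100L,
                                n_semantic = 100L, timesteps = 6L,
                                error_window = 3:6, learning_rate = 0.1,
                                init_range = 0.5) {
  stopifnot(length(error_window) >= 1L, timesteps >= max(error_window),
            min(error_window) >= 1L, learning_rate > 0, init_range > 0)
  structure(list(n_input = as.integer(n_input),
                 n_hidden = as.integer(n_hidden),
                 n_semantic = as.integer(n_semantic),
                 timesteps = as.integer(timesteps),
                 error_window = as.integer(error_window),
                 learning_rate = learning_rate,
                 init_range = init_range),
            class = "net_hyperparameters")
}

#' Initialize network weights
#'
#' All connection matrices and biases are drawn i.i.d. uniform on
#' `[-init_range, init_range]` from the current RNG stream.
#'
#' @param hp A `"net_hyperparameters"` object.
#' @return A `"network_weights"` list with `W_in` (hidden x input), `W_hh`
#'   (hidden x hidden), `W_hs` (semantic x hidden), `b_h`, `b_s`.
#' @export
init_weights <- function(hp) {
  r <- hp$init_range
  u <- function(nr, nc) matrix(stats::runif(nr * nc, -r, r), nr, nc)
  structure(list(W_in = u(hp$n_hidden, hp$n_input),
                 W_hh = u(hp$n_hidden, hp$n_hidden),
                 W_hs = u(hp$n_semantic, hp$n_hidden),
                 b_h = stats::runif(hp$n_hidden, -r, r),
                 b_s = stats::runif(hp$n_semantic, -r, r)),
            class = "network_weights")
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.as_input <- function(x) {
  if (inherits(x, "input_vector")) as_network_input(x) else as.numeric(x)
}

#' Run the forward dynamics
#'
#' The hidden state starts at zero and the input is clamped for all
#' `timesteps` steps. Per step `t`:
#' `hidden(t) = sigmoid(W_in x + W_hh hidden(t-1) + b_h)` and
#' `semantic(t) = sigmoid(W_hs hidden(t-1) + b_s)`, so each connection
#' carries a one-step delay and input first reaches the semantic layer at
#' step 3 -- the start of the error window.
#'
#' @param w `"network_weights"`.
#' @param x An `"input_vector"` or a numeric vector of length `n_input`.
#' @param hp `"net_hyperparameters"`.
#' @return An `"activation_trace"`: `hidden` and `semantic` matrices with
#'   one column per time step, plus the clamped `input`.
#' @export
net_forward <- function(w, x, hp) {
  x <- .as_input(x)
  if (length(x) != ncol(w$W_in)) stop("input length does not match W_in")
  T <- hp$timesteps
  H <- matrix(0, nrow(w$W_hh), T)
  S <- matrix(0, nrow(w$W_hs), T)
  h_prev <- numeric(nrow(w$W_hh))
  in_drive <- drop(w$W_in %*% x) + w$b_h
  for (t in seq_len(T)) {
    S[, t] <- .sigmoid(drop(w$W_hs %*% h_prev) + w$b_s)
    h_prev <- .sigmoid(in_drive + drop(w$W_hh %*% h_prev))
    H[, t] <- h_prev
  }
  structure(list(hidden = H, semantic = S, input = x),
            class = "activation_trace")
}

#' Sum-squared error over the error window
#'
#' Sums squared deviations between the semantic activations and the target
#' pattern over every step in `hp$error_window`.
#'
#' @param trace An `"activation_trace"` from [net_forward()].
#' @param target Binary target vector of length `n_semantic`.
#' @param hp `"net_hyperparameters"`.
#' @return Nonnegative scalar loss.
#' @export
sse_loss <- function(trace, target, hp) {
  stopifnot(length(target) == nrow(trace$semantic))
  err <- trace$semantic[, hp$error_window, drop = FALSE] - target
  sum(err * err)
}

#' Exact BPTT gradients of the sum-squared error
#'
#' Unrolls the dynamics over the trial's time steps with error injected at
#' the error-window steps only (the semantic layer is a pure output: no
#' clamping and no feedback into the hidden state).
#'
#' @inheritParams net_forward
#' @param target Binary target vector of length `n_semantic`.
#' @return List with the same shapes as the weights (`W_in`, `W_hh`,
#'   `W_hs`, `b_h`, `b_s`), each the exact partial derivative of
#'   [sse_loss()].
#' @export
bptt_gradients <- function(w, x, target, hp) {
  x <- .as_input(x)
  tr <- net_forward(w, x, hp)
  T <- hp$timesteps
  H <- tr$hidden
  S <- tr$semantic
  n_h <- nrow(H)

  # delta on the semantic pre-activation at each step (0 outside the window)
  dS <- matrix(0, nrow(S), T)
  for (t in hp$error_window)
    dS[, t] <- 2 * (S[, t] - target) * S[, t] * (1 - S[, t])

  h_at <- function(t) if (t == 0L) numeric(n_h) else H[, t]

  gW_in <- matrix(0, nrow(w$W_in), ncol(w$W_in))
  gW_hh <- matrix(0, n_h, n_h)
  gW_hs <- matrix(0, nrow(w$W_hs), n_h)
  gb_h <- numeric(n_h)
  gb_s <- numeric(nrow(w$W_hs))

  for (t in seq_len(T)) {
    gW_hs <- gW_hs + dS[, t] %o% h_at(t - 1L)
    gb_s <- gb_s + dS[, t]
  }

  # backward through the hidden chain; h(T) feeds nothing downstream
  dH <- numeric(n_h)
  for (t in seq(T, 1L)) {
    e_h <- if (t < T)
      drop(crossprod(w$W_hh, dH)) + drop(crossprod(w$W_hs, dS[, t + 1L]))
    else numeric(n_h)
    dH <- e_h * H[, t] * (1 - H[, t])
    gW_in <- gW_in + dH %o% x
    gW_hh <- gW_hh + dH %o% h_at(t - 1L)
    gb_h <- gb_h + dH
  }
  list(W_in = gW_in, W_hh = gW_hh, W_hs = gW_hs, b_h = gb_h, b_s = gb_s)
}

#' One online gradient-descent update
#'
#' @param w `"network_weights"`.
#' @param g Gradient list from [bptt_gradients()].
#' @param lr Step size (nonnegative).
#' @return Updated `"network_weights"`.
#' @export
sgd_update <- function(w, g, lr) {
  stopifnot(lr >= 0)
  for (nm in c("W_in", "W_hh", "W_hs", "b_h", "b_s"))
    w[[nm]] <- w[[nm]] - lr * g[[nm]]
  w
}

#' Compare BPTT gradients with central finite differences
#'
#' The independent numerical oracle: perturbs every weight and bias by
#' `eps` in both directions and compares `(L(+) - L(-)) / (2 eps)` with the
#' analytic gradient.
#'
#' @inheritParams bptt_gradients
#' @param eps Finite-difference step (default 1e-6).
#' @return List with `max_abs_diff`, `max_rel_diff` (relative to
#'   `max(1, |numeric|)` elementwise) and the two gradient sets.
#' @export
gradient_check <- function(w, x, target, hp, eps = 1e-6) {
  x <- .as_input(x)
  loss_at <- function(w2) sse_loss(net_forward(w2, x, hp), target, hp)
  analytic <- bptt_gradients(w, x, target, hp)
  numeric_g <- w
  max_abs <- 0
  max_rel <- 0
  for (nm in c("W_in", "W_hh", "W_hs", "b_h", "b_s")) {
    num <- w[[nm]]
    for (i in seq_along(num)) {
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num[i] <- (loss_at(wp) - loss_at(wm)) / (2 * eps)
    }
    numeric_g[[nm]] <- num
    d <- abs(num - analytic[[nm]])
    max_abs <- max(max_abs, d)
    max_rel <- max(max_rel, d / pmax(abs(num), 1))
  }
  list(max_abs_diff = max_abs, max_rel_diff = max_rel,
       analytic = analytic, numeric = numeric_g[c("W_in", "W_hh", "W_hs",
                                                  "b_h", "b_s")])
}
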