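#' Rate-based reference network trained by pure backpropagation
#'
#' A differentiable two-layer sigmoid network with the same mean-square
#' loss as the spiking decoder, used as the analytic-gradient reference
#' against which the effect of self-backpropagation is examined. Its
#' weight updates are exactly `-eta * dC/dW` by the chain rule and are
#' verifiable against central finite differences.
#'
#' @param n_in,n_hidden,n_out Layer sizes.
#' @param seed Integer seed for the random initialization.
#' @return A `rbm_weights` list with `W1` (n_in x n_hidden), `b1`,
#'   `W2` (n_hidden x n_out), `b2`.
#' @export
rbm_init <- function(n_in, n_hidden, n_out, seed = 1L) {
  with_seed(seed, {
    structure(list(
      W1 = matrix(stats::rnorm(n_in * n_hidden, sd = 0.5), n_in, n_hidden),
      b1 = stats::rnorm(n_hidden, sd = 0.1),
      W2 = matrix(stats::rnorm(n_hidden * n_out, sd = 0.5), n_hidden, n_out),
      b2 = stats::rnorm(n_out, sd = 0.1)
    ), class = "rbm_weights")
  })
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @rdname rbm_init
#' @param weights A `rbm_weights` list.
#' @param x Input matrix, n_samples x n_in.
#' @return `rbm_forward`: list with hidden activations `h` and outputs `u`.
#' @export
rbm_forward <- function(weights, x) {
  x <- matrix(x, ncol = nrow(weights$W1))
  h <- sigmoid(sweep(x %*% weights$W1, 2, weights$b1, "+"))
  u <- sigmoid(sweep(h %*% weights$W2, 2, weights$b2, "+"))
  list(h = h, u = u)
}

#' @rdname rbm_init
#' @param batch List with `x` (n_samples x n_in) and `o` (n_samples x
#'   n_out expected outputs).
#' @return `rbm_loss`: the scalar loss `C = 1/2 sum (u - o)^2` over the
#'   batch.
#' @export
rbm_loss <- function(weights, batch) {
  u <- rbm_forward(weights, batch$x)$u
  0.5 * sum((u - matrix(batch$o, ncol = ncol(u)))^2)
}

#' Backpropagation weight deltas for the reference network
#'
#' Returns `-eta` times the analytic gradient of the mean-square loss
#' with respect to each weight and bias.
#'
#' @param weights A `rbm_weights` list from [rbm_init()].
#' @param batch List with `x` and `o` as in [rbm_loss()].
#' @param eta Learning rate.
#' @return List of deltas `W1`, `b1`, `W2`, `b2` with matching shapes.
#' @export
rbm_bp_update <- function(weights, batch, eta) {
  x <- matrix(batch$x, ncol = nrow(weights$W1))
  o <- matrix(batch$o, ncol = ncol(weights$W2))
  fw <- rbm_forward(weights, x)
  h <- fw$h; u <- fw$u
  d_out <- (u - o) * u * (1 - u)             # dC/d(pre-activation out)
  d_hid <- (d_out %*% t(weights$W2)) * h * (1 - h)
  list(W1 = -eta * crossprod(x, d_hid),
       b1 = -eta * colSums(d_hid),
       W2 = -eta * crossprod(h, d_out),
       b2 = -eta * colSums(d_out))
}

#' Central finite-difference gradient of the reference-network loss
#'
#' Independent numeric oracle for [rbm_bp_update()].
#'
#' @inheritParams rbm_bp_update
#' @param h Step size.
#' @return List of numeric gradients with the shapes of `weights`.
#' @export
rbm_numeric_grad <- function(weights, batch, h = 1e-5) {
  grad_of <- function(field) {
    g <- weights[[field]]
    g[] <- vapply(seq_along(weights[[field]]), function(i) {
      wp <- weights; wp[[field]][i] <- wp[[field]][i] + h
      wm <- weights; wm[[field]][i] <- wm[[field]][i] - h
      (rbm_loss(wp, batch) - rbm_loss(wm, batch)) / (2 * h)
    }, numeric(1))
    g
  }
  list(W1 = grad_of("W1"), b1 = grad_of("b1"),
       W2 = grad_of("W2"), b2 = grad_of("b2"))
}
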