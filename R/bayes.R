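#' Closed-form KL divergence between univariate Gaussians
#'
#' `KL(N(mu_q, sd_q) || N(mu_p, sd_p)) =
#'   ln(sd_p / sd_q) + (sd_q^2 + (mu_q - mu_p)^2) / (2 sd_p^2) - 1/2`.
#' Vectorized over all arguments; summing the result over every weight of a
#' layer gives the layer's mean-field KL penalty, the regularization term of
#' the evidence lower bound.
#'
#' @param mu_q,sd_q Posterior mean and standard deviation (`sd_q > 0`).
#' @param mu_p,sd_p Prior mean and standard deviation (`sd_p > 0`).
#' @return Non-negative numeric vector; zero iff the two distributions are
#'   identical.
#' @examples
#' gaussian_kl(0, 1, 0, 1)  # 0
#' gaussian_kl(1, 1, 0, 1)  # 0.5
#' @export
gaussian_kl <- function(mu_q, sd_q, mu_p, sd_p) {
  if (any(sd_q <= 0) || any(sd_p <= 0)) {
    stop("Standard deviations must be strictly positive.", call. = FALSE)
  }
  log(sd_p / sd_q) + (sd_q^2 + (mu_q - mu_p)^2) / (2 * sd_p^2) - 0.5
}

#' Negative Gaussian log-likelihood
#'
#' The per-observation loss `0.5 log(2 pi scale^2) + (y - location)^2 /
#' (2 scale^2)`, minimized at `y == location`. The network's output heads
#' emit the location; the output scale is fixed (1.0 by default) so the loss
#' is a shifted, scaled squared error whose value is interpretable as a
#' log-density.
#'
#' @param y Observed target(s).
#' @param location Predicted location(s).
#' @param scale Output standard deviation, strictly positive (default 1).
#' @return Numeric vector of losses.
#' @examples
#' negloglik(0, 0)  # 0.5 * log(2 * pi) ~= 0.9189
#' @export
negloglik <- function(y, location, scale = 1) {
  if (any(scale <= 0)) {
    stop("`scale` must be strictly positive.", call. = FALSE)
  }
  0.5 * log(2 * pi * scale^2) + (y - location)^2 / (2 * scale^2)
}

#' Construct a mean-field Gaussian variational dense layer
#'
#' Each weight (and bias) carries an independent Gaussian posterior
#' `N(mu, sigma)` with `sigma = softplus(rho)` stored through the
#' unconstrained `rho`, and a Gaussian prior `N(prior_mu, sigma_pr)`.
#' Posterior means are initialized `N(0, 0.1)`; posterior scales are
#' initialized to `sigma_po`. When `trainable_prior` is `TRUE` the prior
#' means are optimized alongside the posterior (the prior scale `sigma_pr`
#' stays fixed); when `FALSE` the prior is bit-frozen.
#'
#' @param in_dim,out_dim Layer dimensions.
#' @param sigma_pr Prior scale (> 0), default 1.5.
#' @param sigma_po Posterior initialization scale (> 0), default 1.0.
#' @param trainable_prior Should prior means be trained? Default `TRUE`.
#' @param activation One of `"relu"`, `"sigmoid"`, `"squashing"`,
#'   `"identity"`.
#' @param beta Sharpness used when `activation = "squashing"`.
#' @return A layer object (class `balonn_vdense`).
#' @export
variational_dense <- function(in_dim, out_dim, sigma_pr = 1.5, sigma_po = 1.0,
                              trainable_prior = TRUE,
                              activation = "relu", beta = 10) {
  if (sigma_pr <= 0 || sigma_po <= 0) {
    stop("`sigma_pr` and `sigma_po` must be strictly positive.",
         call. = FALSE)
  }
  in_dim <- as.integer(in_dim); out_dim <- as.integer(out_dim)
  stopifnot(in_dim >= 1L, out_dim >= 1L)
  rho0 <- softplus_inv(sigma_po)
  structure(list(
    type = "vdense",
    in_dim = in_dim, out_dim = out_dim,
    mu_W = matrix(stats::rnorm(in_dim * out_dim, 0, 0.1), in_dim, out_dim),
    rho_W = matrix(rho0, in_dim, out_dim),
    mu_b = stats::rnorm(out_dim, 0, 0.1),
    rho_b = rep(rho0, out_dim),
    prior_mu_W = matrix(0, in_dim, out_dim),
    prior_mu_b = rep(0, out_dim),
    sigma_pr = sigma_pr, sigma_po = sigma_po,
    trainable_prior = isTRUE(trainable_prior),
    activation = activation, beta = beta
  ), class = c("balonn_vdense", "balonn_layer"))
}

#' Draw concrete weights from a variational layer's posterior
#'
#' The reparameterization draw `W = mu + softplus(rho) * eps` with
#' `eps ~ N(0, 1)`; gradients flow through `mu` and `rho`. Uses R's global
#' RNG stream, so a fixed seed gives a bit-identical draw.
#'
#' @param layer A `balonn_vdense` layer.
#' @return List with `W` (matrix), `b` (vector) and the noise draws
#'   `eps_W`, `eps_b` (kept for backpropagation).
#' @export
sample_weights <- function(layer) {
  stopifnot(inherits(layer, "balonn_vdense"))
  eps_W <- matrix(stats::rnorm(length(layer$mu_W)),
                  nrow(layer$mu_W), ncol(layer$mu_W))
  eps_b <- stats::rnorm(length(layer$mu_b))
  list(
    W = layer$mu_W + softplus(layer$rho_W) * eps_W,
    b = layer$mu_b + softplus(layer$rho_b) * eps_b,
    eps_W = eps_W, eps_b = eps_b
  )
}

#' Total KL penalty of a variational layer
#'
#' Sum of [gaussian_kl()] over every weight and bias of the layer, posterior
#' against its prior.
#'
#' @param layer A `balonn_vdense` layer.
#' @return A single non-negative number.
#' @export
layer_kl <- function(layer) {
  stopifnot(inherits(layer, "balonn_vdense"))
  sum(gaussian_kl(layer$mu_W, softplus(layer$rho_W),
                  layer$prior_mu_W, layer$sigma_pr)) +
    sum(gaussian_kl(layer$mu_b, softplus(layer$rho_b),
                    layer$prior_mu_b, layer$sigma_pr))
}

# plain dense layer; He-normal weights and small positive biases keep the
# narrow ReLU stack alive under aggressive Adam steps
dense_layer <- function(in_dim, out_dim, activation = "relu", beta = 10) {
  in_dim <- as.integer(in_dim); out_dim <- as.integer(out_dim)
  structure(list(
    type = "dense",
    in_dim = in_dim, out_dim = out_dim,
    W = matrix(stats::rnorm(in_dim * out_dim, 0, sqrt(2 / in_dim)),
               in_dim, out_dim),
    b = rep(0.1, out_dim),
    activation = activation, beta = beta
  ), class = c("balonn_dense", "balonn_layer"))
}
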