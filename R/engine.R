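# Internal feed-forward engine.
#
# Networks here are lists of layers: plain dense, mean-field variational
# dense (reparameterized Gaussian weights), and frozen logic blocks. The
# models are tiny (a few hundred scalars), so plain R matrix algebra with
# hand-written backpropagation is both adequate and fully auditable; the
# gradients are checked against finite differences in the test suite.

act_fun <- function(z, activation, beta = 10) {
  switch(activation,
    relu = pmax(z, 0),
    sigmoid = stats::plogis(z),
    squashing = squashing_mat(z, beta),
    identity = z,
    stop("Unknown activation '", activation, "'.", call. = FALSE)
  )
}

act_deriv <- function(z, activation, beta = 10) {
  switch(activation,
    relu = (z > 0) * 1,
    sigmoid = { s <- stats::plogis(z); s * (1 - s) },
    squashing = squashing_deriv_mat(z, beta),
    identity = array(1, dim = dim(z) %||% length(z)),
    stop("Unknown activation '", activation, "'.", call. = FALSE)
  )
}

# matrix-shaped variants (squashing()/squashing_deriv() validate and drop dims)
squashing_mat <- function(z, beta) {
  out <- (softplus(beta * z) - softplus(beta * (z - 1))) / beta
  dim(out) <- dim(z)
  out
}

squashing_deriv_mat <- function(z, beta) {
  out <- stats::plogis(beta * z) - stats::plogis(beta * (z - 1))
  dim(out) <- dim(z)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Forward pass. X: M x in matrix. Returns scaled outputs (M x n_tasks) and
# per-layer caches for backprop. `sample = TRUE` draws fresh posterior
# weights in variational layers; FALSE uses posterior means.
nn_forward <- function(model, X, sample = TRUE) {
  A <- as.matrix(X)
  caches <- vector("list", length(model$layers))
  for (li in seq_along(model$layers)) {
    layer <- model$layers[[li]]
    if (layer$type == "dense") {
      Z <- A %*% layer$W + rep(layer$b, each = nrow(A))
      caches[[li]] <- list(A_in = A, Z = Z, W = layer$W)
      A <- act_fun(Z, layer$activation, layer$beta)
    } else if (layer$type == "vdense") {
      if (sample) {
        d <- sample_weights(layer)
      } else {
        d <- list(W = layer$mu_W, b = layer$mu_b,
                  eps_W = layer$mu_W * 0, eps_b = layer$mu_b * 0)
      }
      Z <- A %*% d$W + rep(d$b, each = nrow(A))
      caches[[li]] <- list(A_in = A, Z = Z, W = d$W,
                           eps_W = d$eps_W, eps_b = d$eps_b)
      A <- act_fun(Z, layer$activation, layer$beta)
    } else if (layer$type == "logic") {
      blk <- layer$block
      sub <- vector("list", length(blk$compiled))
      for (si in seq_along(blk$compiled)) {
        cl <- blk$compiled[[si]]
        Z <- A %*% cl$W + rep(cl$b, each = nrow(A))
        sub[[si]] <- list(A_in = A, Z = Z)
        A <- squashing_mat(Z, blk$beta)
      }
      caches[[li]] <- list(sub = sub)
    } else {
      stop("Unknown layer type '", layer$type, "'.", call. = FALSE)
    }
  }
  out <- A * rep(model$output_scale, each = nrow(A))
  list(output = out, caches = caches)
}

# Backward pass: dY is the gradient of the loss w.r.t. the scaled output.
# Returns a list (parallel to layers) of parameter gradients.
nn_backward <- function(model, caches, dY) {
  M <- nrow(dY)
  dA <- dY * rep(model$output_scale, each = M)
  grads <- vector("list", length(model$layers))
  for (li in rev(seq_along(model$layers))) {
    layer <- model$layers[[li]]
    if (layer$type == "logic") {
      blk <- layer$block
      for (si in rev(seq_along(blk$compiled))) {
        sc <- caches[[li]]$sub[[si]]
        dZ <- dA * squashing_deriv_mat(sc$Z, blk$beta)
        dA <- dZ %*% t(blk$compiled[[si]]$W)
      }
      grads[[li]] <- list()
    } else {
      cc <- caches[[li]]
      dZ <- dA * act_deriv(cc$Z, layer$activation, layer$beta)
      gW <- crossprod(cc$A_in, dZ)
      gb <- colSums(dZ)
      dA <- dZ %*% t(cc$W)
      if (layer$type == "dense") {
        grads[[li]] <- list(W = gW, b = gb)
      } else {
        sig_W <- stats::plogis(layer$rho_W)   # d softplus / d rho
        sig_b <- stats::plogis(layer$rho_b)
        grads[[li]] <- list(
          mu_W = gW, rho_W = gW * cc$eps_W * sig_W,
          mu_b = gb, rho_b = gb * cc$eps_b * sig_b
        )
      }
    }
  }
  grads
}

# Analytic gradients of the summed layer KL w.r.t. variational parameters.
kl_grads <- function(layer) {
  sd_q_W <- softplus(layer$rho_W)
  sd_q_b <- softplus(layer$rho_b)
  v <- layer$sigma_pr^2
  g <- list(
    mu_W = (layer$mu_W - layer$prior_mu_W) / v,
    rho_W = (sd_q_W / v - 1 / sd_q_W) * stats::plogis(layer$rho_W),
    mu_b = (layer$mu_b - layer$prior_mu_b) / v,
    rho_b = (sd_q_b / v - 1 / sd_q_b) * stats::plogis(layer$rho_b)
  )
  if (layer$trainable_prior) {
    g$prior_mu_W <- (layer$prior_mu_W - layer$mu_W) / v
    g$prior_mu_b <- (layer$prior_mu_b - layer$mu_b) / v
  }
  g
}

# names of trainable parameter slots for a layer
trainable_slots <- function(layer) {
  if (layer$type == "dense") {
    c("W", "b")
  } else if (layer$type == "vdense") {
    slots <- c("mu_W", "rho_W", "mu_b", "rho_b")
    if (layer$trainable_prior) slots <- c(slots, "prior_mu_W", "prior_mu_b")
    slots
  } else {
    character(0)
  }
}

# Data-fit loss and its gradient w.r.t. the scaled predictions.
# pred, y: M x n_tasks. Multitask loss = sum over tasks of per-task means.
# MSE is computed on the unit (pre-scale) output range so the two task
# heads weigh equally; negloglik uses the fixed output sd of 1.0 on the
# class scale itself.
data_loss <- function(pred, y, loss, scale = rep(1, ncol(y))) {
  M <- nrow(y)
  if (loss == "mse") {
    diff <- (pred - y) / rep(scale, each = M)
    value <- sum(colMeans(diff^2))
    grad <- 2 * diff / rep(scale, each = M) / M
  } else if (loss == "negloglik") {
    value <- sum(colMeans(negloglik(y, pred, 1)))
    grad <- (pred - y) / M
  } else {
    stop("Unknown loss '", loss, "'.", call. = FALSE)
  }
  list(value = value, grad = grad)
}

#' One-sample evidence-lower-bound objective
#'
#' Draws one set of posterior weights, runs the forward pass, and returns the
#' two-term variational objective: the data-fit term (negative log-likelihood
#' or mean squared error, summed over tasks) plus `kl_weight` times the
#' summed Kullback-Leibler penalty of every variational layer. With
#' `kl_weight = 0`, or when the posterior equals the prior, the objective
#' reduces to the pure data-fit term.
#'
#' @param model A built model (see [build_model()]).
#' @param x Feature matrix or data frame (rows = patients).
#' @param y Target data frame/matrix with one column per task.
#' @param kl_weight Non-negative weight on the KL term. Defaults to
#'   `1 / nrow(x)`, the standard per-observation ELBO scaling.
#' @param loss `"negloglik"` or `"mse"`.
#' @param sample Draw posterior weights (`TRUE`) or use posterior means.
#' @return List with `total`, `data_loss`, `kl`.
#' @export
elbo_loss <- function(model, x, y, kl_weight = NULL, loss = "negloglik",
                      sample = TRUE) {
  x <- as.matrix(x); y <- as.matrix(y)
  kl_weight <- kl_weight %||% (1 / nrow(x))
  fw <- nn_forward(model, x, sample = sample)
  dl <- data_loss(fw$output, y, loss, model$output_scale)
  kl <- model_kl(model)
  list(total = dl$value + kl_weight * kl, data_loss = dl$value, kl = kl)
}

model_kl <- function(model) {
  sum(vapply(model$layers, function(l) {
    if (l$type == "vdense") layer_kl(l) else 0
  }, numeric(1)))
}

# Adam optimizer state and update (Kingma & Ba defaults).
adam_init <- function() list(t = 0L, m = list(), v = list())

adam_step <- function(layers, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (li in seq_along(layers)) {
    for (slot in trainable_slots(layers[[li]])) {
      key <- paste0(li, ".", slot)
      g <- grads[[li]][[slot]]
      if (is.null(state$m[[key]])) {
        state$m[[key]] <- g * 0
        state$v[[key]] <- g * 0
      }
      state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * g
      state$v[[key]] <- beta2 * state$v[[key]] + (1 - beta2) * g^2
      mhat <- state$m[[key]] / (1 - beta1^t)
      vhat <- state$v[[key]] / (1 - beta2^t)
      layers[[li]][[slot]] <- layers[[li]][[slot]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}
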