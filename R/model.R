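#' Specify a model architecture
#'
#' Three variants share one topology (feature width 10, hidden widths
#' 10-4-3, two output units):
#'
#' * `"dnn"` — deterministic dense baseline: ReLU hidden layers, sigmoid
#'   output head, trained with mean squared error;
#' * `"bnn"` — the same stack with every layer variational (mean-field
#'   Gaussian weights), trained with the negative log-likelihood plus KL;
#' * `"balonn"` — a variational input layer with squashing activation, a
#'   frozen logic block in the middle, and a variational output head; only
#'   the first and last layers are trained.
#'
#' The two output units are the task heads: a binary heart-failure class
#' (`hf`, sigmoid in (0,1)) and an ordinal therapy-length class (`tl`,
#' sigmoid rescaled to span 0-3).
#'
#' @param variant `"dnn"`, `"bnn"` or `"balonn"`.
#' @param n_features Input width (default 10).
#' @param hidden Hidden widths for the dense variants (default `c(10, 4, 3)`).
#' @param sigma_pr Prior scale for variational layers (default 1.5).
#' @param sigma_po Posterior initialization scale (default 1.0).
#' @param trainable_prior Train the prior means? Default `TRUE`.
#' @param logic_block A [logic_block()] for the balonn variant (default
#'   [default_logic_block()]); ignored otherwise.
#' @param beta Squashing sharpness for the balonn variant.
#' @param tasks Task names (output head order).
#' @param output_scale Per-task multiplier applied to the sigmoid head
#'   (default `c(1, 3)`: binary task on (0,1), ordinal task on (0,3)).
#' @param output_activation Head activation (default `"sigmoid"`).
#' @return A `balonn_model_spec`.
#' @export
model_spec <- function(variant = c("dnn", "bnn", "balonn"),
                       n_features = 10,
                       hidden = c(10, 4, 3),
                       sigma_pr = 1.5, sigma_po = 1.0,
                       trainable_prior = TRUE,
                       logic_block = NULL,
                       beta = 10,
                       tasks = c("hf", "tl"),
                       output_scale = c(1, 3),
                       output_activation = "sigmoid") {
  variant <- match.arg(variant)
  if (variant == "balonn" && is.null(logic_block)) {
    logic_block <- default_logic_block(n_inputs = hidden[1], beta = beta)
  }
  if (variant == "balonn" && !inherits(logic_block, "balonn_logic_block")) {
    stop("The balonn variant requires a `logic_block`.", call. = FALSE)
  }
  stopifnot(length(tasks) == length(output_scale))
  structure(list(
    variant = variant, n_features = as.integer(n_features),
    hidden = as.integer(hidden),
    sigma_pr = sigma_pr, sigma_po = sigma_po,
    trainable_prior = isTRUE(trainable_prior),
    logic_block = logic_block, beta = beta,
    tasks = tasks, output_scale = output_scale,
    output_activation = output_activation
  ), class = "balonn_model_spec")
}

#' Build a model from its specification
#'
#' Instantiates the layer stack (randomly initializing trainable
#' parameters). Pass a seed for reproducible initialization.
#'
#' @param spec A [model_spec()].
#' @param seed Optional integer seed for the initialization draws.
#' @return A `balonn_model`.
#' @export
build_model <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "balonn_model_spec"))
  if (!is.null(seed)) set.seed(seed)
  n_tasks <- length(spec$tasks)
  layers <- list()
  if (spec$variant == "dnn") {
    dims <- c(spec$n_features, spec$hidden)
    for (i in seq_len(length(dims) - 1)) {
      layers[[i]] <- dense_layer(dims[i], dims[i + 1], activation = "relu")
    }
    layers[[length(layers) + 1]] <-
      dense_layer(dims[length(dims)], n_tasks,
                  activation = spec$output_activation)
  } else if (spec$variant == "bnn") {
    dims <- c(spec$n_features, spec$hidden)
    for (i in seq_len(length(dims) - 1)) {
      layers[[i]] <- variational_dense(
        dims[i], dims[i + 1], sigma_pr = spec$sigma_pr,
        sigma_po = spec$sigma_po, trainable_prior = spec$trainable_prior,
        activation = "relu")
    }
    layers[[length(layers) + 1]] <- variational_dense(
      dims[length(dims)], n_tasks, sigma_pr = spec$sigma_pr,
      sigma_po = spec$sigma_po, trainable_prior = spec$trainable_prior,
      activation = spec$output_activation)
  } else { # balonn
    blk <- spec$logic_block
    layers[[1]] <- variational_dense(
      spec$n_features, blk$n_inputs, sigma_pr = spec$sigma_pr,
      sigma_po = spec$sigma_po, trainable_prior = spec$trainable_prior,
      activation = "squashing", beta = blk$beta)
    layers[[2]] <- structure(list(type = "logic", block = blk),
                             class = c("balonn_logic", "balonn_layer"))
    layers[[3]] <- variational_dense(
      blk$n_outputs, n_tasks, sigma_pr = spec$sigma_pr,
      sigma_po = spec$sigma_po, trainable_prior = spec$trainable_prior,
      activation = spec$output_activation)
  }
  structure(list(
    spec = spec, layers = layers, tasks = spec$tasks,
    output_scale = spec$output_scale,
    trained = FALSE, trace = NULL, kl_weight = NULL
  ), class = "balonn_model")
}

#' Count model parameters
#'
#' Trainable scalars per layer: a dense layer contributes
#' `in * out + out`; a variational layer twice that (means and log-scales),
#' plus the prior means again when the prior is trainable; a frozen logic
#' block contributes nothing. The dense baseline at the default topology has
#' 110 + 44 + 15 + 8 = 177 trainable scalars.
#'
#' @param model A `balonn_model`.
#' @param trainable_only Count only trainable scalars (default) or also the
#'   frozen logic-gate weights and biases.
#' @return Integer count.
#' @export
n_parameters <- function(model, trainable_only = TRUE) {
  stopifnot(inherits(model, "balonn_model"))
  n <- 0L
  for (layer in model$layers) {
    if (layer$type == "logic") {
      if (!trainable_only) {
        n <- n + sum(vapply(layer$block$compiled,
                            function(cl) length(cl$W[cl$W != 0]) + length(cl$b),
                            numeric(1)))
      }
    } else {
      for (slot in trainable_slots(layer)) {
        n <- n + length(layer[[slot]])
      }
    }
  }
  as.integer(n)
}

#' Training configuration
#'
#' Defaults follow the variant: the dense baseline trains with Adam at
#' learning rate 0.08 for 400 epochs on mean squared error; the variational
#' variants (bnn, balonn) with Adam at 0.008 for 300 epochs on the negative
#' log-likelihood plus KL. Minibatches of 32 by default (the usual
#' stochastic-gradient regime for these optimizers); pass
#' `batch_size = "full"` for one full-batch step per epoch — the regime the
#' sensitivity sweep uses so the posterior initialization scale remains the
#' experiment's control parameter.
#'
#' @param variant Model variant the defaults are drawn for.
#' @param learning_rate,epochs,loss,seed Overrides.
#' @param batch_size Rows per gradient step, or `"full"`.
#' @param kl_weight Weight of the KL term; default `1 / n_train`, resolved
#'   at fit time.
#' @return A `balonn_train_config`.
#' @export
train_config <- function(variant = c("dnn", "bnn", "balonn"),
                         learning_rate = NULL, epochs = NULL, loss = NULL,
                         batch_size = NULL, seed = NULL, kl_weight = NULL) {
  variant <- match.arg(variant)
  defaults <- if (variant == "dnn") {
    list(learning_rate = 0.08, epochs = 400L, loss = "mse")
  } else {
    list(learning_rate = 0.008, epochs = 300L, loss = "negloglik")
  }
  cfg <- list(
    optimizer = "adam",
    learning_rate = learning_rate %||% defaults$learning_rate,
    epochs = as.integer(epochs %||% defaults$epochs),
    loss = loss %||% defaults$loss,
    batch_size = batch_size %||% 32, seed = seed, kl_weight = kl_weight
  )
  stopifnot(cfg$learning_rate >= 0, cfg$epochs >= 1,
            cfg$loss %in% c("mse", "negloglik"),
            identical(cfg$batch_size, "full") || cfg$batch_size >= 1)
  structure(cfg, class = "balonn_train_config")
}

#' Fit a model with Adam
#'
#' Minimizes the multitask objective (sum of per-task data losses, plus the
#' KL penalty scaled by `kl_weight` for variational layers) by full-batch
#' (or minibatch) Adam. One posterior weight draw per gradient step
#' (reparameterization); frozen logic blocks are never updated. The
#' epoch-wise loss trace is stored on the returned model.
#'
#' @param model A built `balonn_model`.
#' @param x Feature data frame or matrix (normalized to `[0, 1]`).
#' @param y Targets: data frame/matrix with one column per task, in task
#'   order (default `hf`, `tl`).
#' @param config A [train_config()]; defaults are drawn from the model's
#'   variant.
#' @return The trained model, with `$trace` (tibble: epoch, data_loss, kl,
#'   total) and `$trained = TRUE`.
#' @export
train_model <- function(model, x, y, config = NULL) {
  stopifnot(inherits(model, "balonn_model"))
  config <- config %||% train_config(model$spec$variant)
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) stop("x and y row counts differ.", call. = FALSE)
  if (ncol(y) != length(model$tasks)) {
    stop("y must have one column per task (", length(model$tasks), ").",
         call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- nrow(x)
  klw <- config$kl_weight %||% (1 / n)
  layers <- model$layers
  state <- adam_init()
  bs <- if (identical(config$batch_size, "full")) n else
    min(config$batch_size %||% n, n)
  trace <- matrix(NA_real_, nrow = config$epochs, ncol = 3)
  tmp_model <- model
  for (epoch in seq_len(config$epochs)) {
    idx <- if (bs < n) sample.int(n) else seq_len(n)
    starts <- seq(1, n, by = bs)
    dsum <- 0; nb <- 0L
    for (s in starts) {
      rows <- idx[s:min(s + bs - 1, n)]
      tmp_model$layers <- layers
      fw <- nn_forward(tmp_model, x[rows, , drop = FALSE], sample = TRUE)
      dl <- data_loss(fw$output, y[rows, , drop = FALSE], config$loss,
                      model$output_scale)
      grads <- nn_backward(tmp_model, fw$caches, dl$grad)
      for (li in seq_along(layers)) {
        if (layers[[li]]$type == "vdense") {
          kg <- kl_grads(layers[[li]])
          for (slot in names(kg)) {
            grads[[li]][[slot]] <- (grads[[li]][[slot]] %||% 0) +
              klw * kg[[slot]]
          }
        }
      }
      st <- adam_step(layers, grads, state, config$learning_rate)
      layers <- st$layers; state <- st$state
      dsum <- dsum + dl$value; nb <- nb + 1L
    }
    tmp_model$layers <- layers
    kl <- model_kl(tmp_model)
    total <- dsum / nb + klw * kl
    if (!is.finite(total)) {
      stop("Non-finite loss at epoch ", epoch, " (data term ",
           format(dsum / nb), ", KL ", format(kl), "); stopping.",
           call. = FALSE)
    }
    trace[epoch, ] <- c(dsum / nb, kl, total)
  }
  model$layers <- layers
  model$trained <- TRUE
  model$kl_weight <- klw
  model$config <- config
  model$trace <- tibble::tibble(
    epoch = seq_len(config$epochs),
    data_loss = trace[, 1], kl = trace[, 2], total = trace[, 3]
  )
  model
}

#' Sample predictions from a (possibly stochastic) model
#'
#' Runs `n_draws` forward passes; variational layers draw fresh posterior
#' weights each pass, so the result is the patients-by-draws matrix
#' of sampled outputs per task. For a deterministic model every
#' column is identical (a degenerate sample).
#'
#' @param model A trained (or at least built) `balonn_model`.
#' @param x Feature data frame or matrix.
#' @param n_draws Number of posterior draws (default 1000).
#' @param seed Optional seed for reproducible draws.
#' @return A `balonn_sample`: named list of M x N matrices, one per task.
#' @export
predict_sample <- function(model, x, n_draws = 1000, seed = NULL) {
  stopifnot(inherits(model, "balonn_model"))
  n_draws <- as.integer(n_draws)
  if (is.na(n_draws) || n_draws < 1L) {
    stop("`n_draws` must be a positive integer.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(x)
  M <- nrow(x)
  out <- lapply(model$tasks, function(t) matrix(NA_real_, M, n_draws))
  names(out) <- model$tasks
  for (j in seq_len(n_draws)) {
    fw <- nn_forward(model, x, sample = TRUE)
    for (ti in seq_along(model$tasks)) {
      out[[ti]][, j] <- fw$output[, ti]
    }
  }
  structure(out, class = "balonn_sample", n_draws = n_draws)
}

#' @export
print.balonn_model <- function(x, ...) {
  cat("<balonn_model> variant:", x$spec$variant,
      "| trainable parameters:", n_parameters(x),
      "|", if (x$trained) "trained" else "untrained", "\n")
  invisible(x)
}

#' Tidy a sampled prediction into long format
#'
#' @param x A `balonn_sample`.
#' @param ... Unused.
#' @return Tibble with columns `patient`, `task`, `draw`, `value`.
#' @export
as_tibble.balonn_sample <- function(x, ...) {
  purrr::map_dfr(names(x), function(task) {
    m <- x[[task]]
    tibble::tibble(
      patient = rep(seq_len(nrow(m)), times = ncol(m)),
      task = task,
      draw = rep(seq_len(ncol(m)), each = nrow(m)),
      value = as.vector(m)
    )
  })
}

#' @export
tidy.balonn_model <- function(x, ...) {
  purrr::map_dfr(seq_along(x$layers), function(li) {
    l <- x$layers[[li]]
    tibble::tibble(
      layer = li,
      type = l$type,
      in_dim = if (l$type == "logic") l$block$n_inputs else l$in_dim,
      out_dim = if (l$type == "logic") l$block$n_outputs else l$out_dim,
      activation = if (l$type == "logic") "squashing" else l$activation,
      trainable = l$type != "logic",
      n_trainable = sum(vapply(trainable_slots(l),
                               function(s) length(l[[s]]), numeric(1)))
    )
  })
}

#' @export
glance.balonn_model <- function(x, ...) {
  tibble::tibble(
    variant = x$spec$variant,
    n_layers = length(x$layers),
    n_trainable = n_parameters(x),
    trained = x$trained,
    epochs = if (x$trained) nrow(x$trace) else NA_integer_,
    final_loss = if (x$trained) x$trace$total[nrow(x$trace)] else NA_real_
  )
}

#' broom-style generics
#'
#' `tidy()` returns a per-component tibble, `glance()` a one-row summary.
#' Methods are provided for models, validation reports and sensitivity
#' sweeps.
#'
#' @param x Object to tidy.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble
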