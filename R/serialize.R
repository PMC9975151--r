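# Model checkpoints as JSON: layer parameter arrays plus the architecture
# spec, at full floating-point precision so a reloaded model reproduces the
# in-memory predictions.

layer_to_list <- function(layer) {
  if (layer$type == "dense") {
    list(type = "dense", in_dim = layer$in_dim, out_dim = layer$out_dim,
         W = layer$W, b = layer$b,
         activation = layer$activation, beta = layer$beta)
  } else if (layer$type == "vdense") {
    list(type = "vdense", in_dim = layer$in_dim, out_dim = layer$out_dim,
         mu_W = layer$mu_W, rho_W = layer$rho_W,
         mu_b = layer$mu_b, rho_b = layer$rho_b,
         prior_mu_W = layer$prior_mu_W, prior_mu_b = layer$prior_mu_b,
         sigma_pr = layer$sigma_pr, sigma_po = layer$sigma_po,
         trainable_prior = layer$trainable_prior,
         activation = layer$activation, beta = layer$beta)
  } else {
    list(type = "logic", block = logic_block_to_json(layer$block))
  }
}

layer_from_list <- function(l) {
  as_mat <- function(m) {
    if (is.list(m)) m <- do.call(rbind, lapply(m, unlist))
    matrix(as.numeric(m), nrow = nrow(m), ncol = ncol(m))
  }
  if (l$type == "dense") {
    structure(list(
      type = "dense", in_dim = as.integer(l$in_dim),
      out_dim = as.integer(l$out_dim),
      W = as_mat(l$W), b = as.numeric(unlist(l$b)),
      activation = l$activation, beta = l$beta
    ), class = c("balonn_dense", "balonn_layer"))
  } else if (l$type == "vdense") {
    structure(list(
      type = "vdense", in_dim = as.integer(l$in_dim),
      out_dim = as.integer(l$out_dim),
      mu_W = as_mat(l$mu_W), rho_W = as_mat(l$rho_W),
      mu_b = as.numeric(unlist(l$mu_b)), rho_b = as.numeric(unlist(l$rho_b)),
      prior_mu_W = as_mat(l$prior_mu_W),
      prior_mu_b = as.numeric(unlist(l$prior_mu_b)),
      sigma_pr = l$sigma_pr, sigma_po = l$sigma_po,
      trainable_prior = isTRUE(l$trainable_prior),
      activation = l$activation, beta = l$beta
    ), class = c("balonn_vdense", "balonn_layer"))
  } else {
    structure(list(type = "logic",
                   block = logic_block_from_json(l$block)),
              class = c("balonn_logic", "balonn_layer"))
  }
}

#' Write / read a model checkpoint
#'
#' Serializes the full layer stack (including frozen logic blocks and, when
#' trained, the loss trace) to a JSON file. `read_model()` reconstructs a
#' model whose predictions match the in-memory model.
#'
#' @param model A `balonn_model`.
#' @param path File path for the JSON checkpoint.
#' @return `write_model()`: `path`, invisibly. `read_model()`: a
#'   `balonn_model`.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "balonn_model"))
  spec <- model$spec
  obj <- list(
    variant = spec$variant,
    n_features = spec$n_features,
    hidden = spec$hidden,
    sigma_pr = spec$sigma_pr, sigma_po = spec$sigma_po,
    trainable_prior = spec$trainable_prior,
    beta = spec$beta,
    tasks = spec$tasks,
    output_scale = spec$output_scale,
    output_activation = spec$output_activation,
    trained = model$trained,
    kl_weight = model$kl_weight,
    layers = lapply(model$layers, layer_to_list),
    trace = if (!is.null(model$trace)) as.list(model$trace)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @param path File path for the JSON checkpoint.
#' @export
read_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyMatrix = TRUE,
                            simplifyDataFrame = FALSE)
  layers <- lapply(obj$layers, layer_from_list)
  blk <- NULL
  for (l in layers) if (l$type == "logic") blk <- l$block
  spec <- model_spec(
    variant = obj$variant, n_features = obj$n_features,
    hidden = obj$hidden, sigma_pr = obj$sigma_pr, sigma_po = obj$sigma_po,
    trainable_prior = obj$trainable_prior, logic_block = blk,
    beta = obj$beta, tasks = obj$tasks, output_scale = obj$output_scale,
    output_activation = obj$output_activation
  )
  model <- structure(list(
    spec = spec, layers = layers, tasks = obj$tasks,
    output_scale = obj$output_scale,
    trained = isTRUE(obj$trained),
    kl_weight = obj$kl_weight,
    trace = if (!is.null(obj$trace)) tibble::as_tibble(obj$trace)
  ), class = "balonn_model")
  model
}
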