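#' Frozen logic-gate parameterizations
#'
#' Returns the frozen weight/bias parameterization of a continuous logical
#' operator. A gate is a perceptron `S_beta(sum(w * x) + b)` whose weights and
#' bias are fixed at the Lukasiewicz values, so that in the crisp limit
#' (`beta -> Inf`) it computes `clip(sum(w * x) + b, 0, 1)`:
#'
#' * `AND` (t-norm), arity k: weights all 1, bias `-(k - 1)`;
#' * `OR` (t-conorm), arity k: weights all 1, bias 0;
#' * `NOT` (also accepted as `NOT_X` / `NOT_Y`; which input is negated is a
#'   wiring choice): arity 1, weight -1, bias 1;
#' * `NOT_BOTH` (joint negation, NOR), arity k: weights all -1, bias 1.
#'
#' Gate parameters are immutable: a gate is data, and the network trainer
#' never touches it.
#'
#' @param kind One of `"AND"`, `"OR"`, `"NOT"`, `"NOT_X"`, `"NOT_Y"`,
#'   `"NOT_BOTH"` (case-insensitive).
#' @param arity Number of inputs (`NOT` variants require 1).
#' @return An object of class `balonn_gate`: list with `kind`, `arity`,
#'   `weights`, `bias`.
#' @examples
#' make_gate("AND", 2)  # weights (1, 1), bias -1
#' make_gate("OR", 2)   # weights (1, 1), bias 0
#' @export
make_gate <- function(kind, arity = 2L) {
  supported <- c("AND", "OR", "NOT", "NOT_X", "NOT_Y", "NOT_BOTH")
  kind <- toupper(as.character(kind)[1])
  if (!kind %in% supported) {
    stop("Unsupported gate kind '", kind, "'. Supported kinds: ",
         paste(supported, collapse = ", "), ".", call. = FALSE)
  }
  arity <- as.integer(arity)
  if (is.na(arity) || arity < 1L) {
    stop("`arity` must be a positive integer.", call. = FALSE)
  }
  if (kind %in% c("NOT", "NOT_X", "NOT_Y")) {
    if (arity != 1L) {
      stop("NOT gates are unary; negate one wired input per gate.",
           call. = FALSE)
    }
    w <- -1
    b <- 1
  } else if (kind == "AND") {
    w <- rep(1, arity)
    b <- -(arity - 1)
  } else if (kind == "OR") {
    w <- rep(1, arity)
    b <- 0
  } else { # NOT_BOTH
    w <- rep(-1, arity)
    b <- 1
  }
  structure(
    list(kind = kind, arity = arity, weights = w, bias = b),
    class = "balonn_gate"
  )
}

#' Evaluate a single logic gate
#'
#' Computes `S_beta(sum(weights * inputs) + bias)`. For `beta >= 100` this
#' agrees with the crisp Lukasiewicz operator `clip(sum(w x) + b, 0, 1)`
#' within `log(2) / beta`.
#'
#' @param gate A `balonn_gate` from [make_gate()].
#' @param inputs Numeric vector of activations in `[0, 1]`, length = arity.
#' @param beta Squashing sharpness.
#' @return A single value in `(0, 1)`.
#' @export
gate_forward <- function(gate, inputs, beta = 10) {
  stopifnot(inherits(gate, "balonn_gate"))
  if (length(inputs) != gate$arity) {
    stop("Gate of arity ", gate$arity, " got ", length(inputs), " inputs.",
         call. = FALSE)
  }
  squashing(sum(gate$weights * inputs) + gate$bias, beta)
}

#' Place a gate in a logic block
#'
#' Binds a gate kind to the indices of its inputs in the previous layer. The
#' arity is taken from the wiring fan-in.
#'
#' @param kind Gate kind, see [make_gate()].
#' @param inputs Integer indices into the previous layer's outputs.
#' @return A `balonn_gate` with a `wiring` field.
#' @export
gate_node <- function(kind, inputs) {
  inputs <- as.integer(inputs)
  if (anyNA(inputs) || length(inputs) < 1L) {
    stop("`inputs` must be one or more integer indices.", call. = FALSE)
  }
  g <- make_gate(kind, length(inputs))
  g$wiring <- inputs
  g
}

#' Construct a frozen logic block
#'
#' A logic block is an ordered list of gate layers wired feed-forward onto
#' the outputs of the preceding layer (the first layer reads the block's
#' `n_inputs` input activations). All parameters are frozen at construction;
#' wiring is validated here, never at forward time. Each layer is compiled to
#' a sparse weight matrix and bias vector so that a whole cohort can be
#' pushed through with one matrix product per layer.
#'
#' @param layers List of layers; each layer is a list of [gate_node()]s.
#' @param n_inputs Width of the input the first layer is wired onto.
#' @param beta Squashing sharpness used inside the block (default 10 for
#'   training; use 100 for crisp evaluation).
#' @return An object of class `balonn_logic_block`.
#' @examples
#' blk <- logic_block(
#'   list(
#'     list(gate_node("AND", c(1, 2)), gate_node("AND", c(3, 4))),
#'     list(gate_node("OR", c(1, 2)))
#'   ),
#'   n_inputs = 4, beta = 100
#' )
#' logic_block_forward(blk, c(1, 1, 0, 0))  # (A AND B) OR (C AND D) ~ 1
#' @export
logic_block <- function(layers, n_inputs, beta = 10) {
  check_beta(beta)
  if (!is.list(layers) || length(layers) < 1L) {
    stop("`layers` must be a non-empty list of gate layers.", call. = FALSE)
  }
  n_inputs <- as.integer(n_inputs)
  stopifnot(n_inputs >= 1L)
  prev <- n_inputs
  compiled <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    layer <- layers[[li]]
    if (!is.list(layer) || length(layer) < 1L) {
      stop("Gate layer ", li, " is empty.", call. = FALSE)
    }
    W <- matrix(0, nrow = prev, ncol = length(layer))
    b <- numeric(length(layer))
    for (gi in seq_along(layer)) {
      g <- layer[[gi]]
      if (!inherits(g, "balonn_gate") || is.null(g$wiring)) {
        stop("Layer ", li, ", gate ", gi,
             ": expected a wired gate from gate_node().", call. = FALSE)
      }
      if (any(g$wiring < 1L) || any(g$wiring > prev)) {
        stop("Layer ", li, ", gate ", gi, ": wiring index out of range ",
             "(previous width ", prev, ").", call. = FALSE)
      }
      if (length(g$wiring) != g$arity) {
        stop("Layer ", li, ", gate ", gi, ": arity ", g$arity,
             " != fan-in ", length(g$wiring), ".", call. = FALSE)
      }
      W[g$wiring, gi] <- g$weights
      b[gi] <- g$bias
    }
    compiled[[li]] <- list(W = W, b = b)
    prev <- length(layer)
  }
  structure(
    list(layers = layers, compiled = compiled, n_inputs = n_inputs,
         n_outputs = prev, beta = beta),
    class = "balonn_logic_block"
  )
}

#' Run activations through a logic block
#'
#' Applies the block layer by layer: `A <- S_beta(A %*% W + b)`. A pure
#' function of its inputs — there is no trainable state.
#'
#' @param block A `balonn_logic_block`.
#' @param activations Numeric vector (one case) or matrix (cases in rows)
#'   with `n_inputs` columns, values in `[0, 1]`.
#' @param beta Optional override of the block's sharpness.
#' @return Vector or matrix of outputs, width `block$n_outputs`.
#' @export
logic_block_forward <- function(block, activations, beta = NULL) {
  stopifnot(inherits(block, "balonn_logic_block"))
  beta <- if (is.null(beta)) block$beta else beta
  vec <- is.null(dim(activations))
  A <- if (vec) matrix(activations, nrow = 1) else as.matrix(activations)
  if (ncol(A) != block$n_inputs) {
    stop("Block expects ", block$n_inputs, " inputs, got ", ncol(A), ".",
         call. = FALSE)
  }
  for (cl in block$compiled) {
    A <- squashing(A %*% cl$W + rep(cl$b, each = nrow(A)), beta)
  }
  if (vec) drop(A) else A
}

#' Serialize / deserialize a logic block
#'
#' The JSON form records gate kinds, wiring and beta — everything needed to
#' reconstruct the block bit-for-bit, and to audit that training never
#' altered the frozen structure.
#'
#' @param block A `balonn_logic_block`.
#' @return `logic_block_to_json()`: a JSON string; `logic_block_from_json()`:
#'   a `balonn_logic_block`.
#' @export
logic_block_to_json <- function(block) {
  stopifnot(inherits(block, "balonn_logic_block"))
  spec <- list(
    n_inputs = block$n_inputs,
    beta = block$beta,
    layers = lapply(block$layers, function(layer) {
      lapply(layer, function(g) {
        list(kind = g$kind, wiring = g$wiring,
             weights = g$weights, bias = g$bias)
      })
    })
  )
  as.character(jsonlite::toJSON(spec, auto_unbox = TRUE, digits = NA))
}

#' @rdname logic_block_to_json
#' @param json A JSON string produced by `logic_block_to_json()`.
#' @export
logic_block_from_json <- function(json) {
  spec <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  layers <- lapply(spec$layers, function(layer) {
    lapply(layer, function(g) {
      gate_node(g$kind, unlist(g$wiring))
    })
  })
  logic_block(layers, n_inputs = as.integer(spec$n_inputs),
              beta = as.numeric(spec$beta))
}

#' @export
format.balonn_logic_block <- function(x, input_names = NULL, ...) {
  nm <- if (is.null(input_names)) paste0("x", seq_len(x$n_inputs)) else input_names
  sym <- c(AND = " ∧ ", OR = " ⊕ ", NOT_BOTH = " ⊕ ")
  for (layer in x$layers) {
    nm_next <- character(length(layer))
    for (gi in seq_along(layer)) {
      g <- layer[[gi]]
      args <- nm[g$wiring]
      nm_next[gi] <- switch(
        g$kind,
        NOT = , NOT_X = , NOT_Y = paste0("¬", args),
        NOT_BOTH = paste0("¬(", paste(args, collapse = sym[["OR"]]), ")"),
        paste0("(", paste(args, collapse = sym[[g$kind]]), ")")
      )
    }
    nm <- nm_next
  }
  nm
}

#' @export
print.balonn_logic_block <- function(x, ...) {
  widths <- vapply(x$layers, length, integer(1))
  cat("<balonn_logic_block> ", x$n_inputs, " inputs -> ",
      paste(widths, collapse = " -> "), " gates, beta = ", x$beta, "\n",
      sep = "")
  cat(paste0("  ", format(x)), sep = "\n")
  invisible(x)
}

#' Default logic block for the 10-feature cohort
#'
#' A two-layer block mirroring the exemplary clinical gate formulas: the
#' first gate layer forms conjunctions/disjunctions of small groups of the
#' ten weighted inputs, the second combines them. Widths 10 -> 4 -> 3 match
#' the hidden widths of the dense baseline so that the Bayesian-logic model
#' and the fully trainable models are compared at equal topology.
#'
#' @param n_inputs Input width (default 10).
#' @param beta Squashing sharpness.
#' @return A `balonn_logic_block`.
#' @export
default_logic_block <- function(n_inputs = 10, beta = 10) {
  stopifnot(n_inputs >= 10)
  logic_block(
    list(
      list(
        gate_node("AND", c(1, 2, 3)),
        gate_node("OR",  c(4, 5, 6)),
        gate_node("AND", c(7, 8)),
        gate_node("OR",  c(9, 10))
      ),
      list(
        gate_node("AND", c(1, 2)),
        gate_node("OR",  c(3, 4)),
        gate_node("AND", c(1, 4))
      )
    ),
    n_inputs = n_inputs, beta = beta
  )
}
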