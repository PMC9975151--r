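# Shared fixtures and independent oracles used across the suite.

softplus <- balonn:::softplus
softplus_inv_test <- balonn:::softplus_inv
`%||%` <- balonn:::`%||%`

# Synthesize a cohort and produce the standard train/test preparation.
make_prepared_cohort <- function(n = 400, seed = 7, split_seed = 2) {
  cohort <- synthesize_cohort(n, seed = seed)
  sp <- split_cohort(cohort, 0.8, seed = split_seed)
  scaler <- fit_scaler(sp$train)
  list(
    cohort = cohort,
    train = sp$train, test = sp$test,
    x_train = apply_scaler(sp$train, scaler),
    x_test = apply_scaler(sp$test, scaler),
    y_train = sp$train[, c("hf", "tl")],
    y_test = sp$test[, c("hf", "tl")],
    scaler = scaler
  )
}

# Brute-force reimplementations of the validation statistics (explicit
# loops, no shared code with the package internals).
brute_precision <- function(pr) {
  count <- 0
  for (v in pr) if (v == 1) count <- count + 1
  count / length(pr)
}

brute_error <- function(phi, printed = FALSE) {
  total <- 0
  for (v in phi) total <- total + v
  if (printed) 1 - total / length(phi) else total / length(phi)
}

brute_phi <- function(sample_matrix, target) {
  out <- numeric(nrow(sample_matrix))
  for (i in seq_len(nrow(sample_matrix))) {
    out[i] <- abs(sum(sample_matrix[i, ]) / ncol(sample_matrix) - target[i])
  }
  out
}

# Crisp Lukasiewicz evaluation of a logic block (the beta -> Inf limit),
# used as the truth-table oracle.
lukasiewicz_block <- function(block, inputs) {
  a <- if (is.null(dim(inputs))) matrix(inputs, nrow = 1) else inputs
  for (cl in block$compiled) {
    z <- a %*% cl$W + rep(cl$b, each = nrow(a))
    a <- pmin(pmax(z, 0), 1)
  }
  drop(a)
}
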