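test_that("trainable-parameter counts follow the layer bookkeeping", {
  dnn <- build_model(model_spec("dnn"), seed = 1)
  expect_identical(n_parameters(dnn), 177L)  # 110 + 44 + 15 + 8
  bnn_fixed <- build_model(model_spec("bnn", trainable_prior = FALSE),
                           seed = 1)
  expect_identical(n_parameters(bnn_fixed), 354L)  # means + scales
  bnn <- build_model(model_spec("bnn", trainable_prior = TRUE), seed = 1)
  expect_identical(n_parameters(bnn), 531L)  # + trainable prior means
  balonn_fixed <- build_model(model_spec("balonn", trainable_prior = FALSE),
                              seed = 1)
  # only input layer (2 x 110) and head (2 x 8) are trainable
  expect_identical(n_parameters(balonn_fixed), 236L)
  expect_lt(n_parameters(balonn_fixed), n_parameters(bnn_fixed))
  balonn <- build_model(model_spec("balonn"), seed = 1)
  expect_lt(n_parameters(balonn), n_parameters(bnn))
  # the frozen gates do carry (non-trainable) parameters
  expect_gt(n_parameters(balonn, trainable_only = FALSE),
            n_parameters(balonn))
})

test_that("model layout matches the variant", {
  m <- build_model(model_spec("balonn"), seed = 2)
  expect_identical(vapply(m$layers, `[[`, "", "type"),
                   c("vdense", "logic", "vdense"))
  expect_identical(m$layers[[1]]$activation, "squashing")
  d <- tidy(m)
  expect_identical(d$trainable, c(TRUE, FALSE, TRUE))
  expect_error(model_spec("balonn", logic_block = "nope"), "logic_block")
})

test_that("training reduces the dense baseline's loss", {
  prep <- make_prepared_cohort(250, seed = 19)
  m <- build_model(model_spec("dnn"), seed = 3)
  m <- train_model(m, prep$x_train, prep$y_train,
                   train_config("dnn", seed = 4))
  expect_identical(nrow(m$trace), 400L)
  expect_lt(m$trace$data_loss[400], m$trace$data_loss[1])
  expect_true(all(is.finite(m$trace$total)))
  g <- glance(m)
  expect_true(g$trained)
  expect_identical(g$epochs, 400L)
})

test_that("sampled predictions are degenerate for the deterministic model", {
  prep <- make_prepared_cohort(120, seed = 23)
  m <- build_model(model_spec("dnn"), seed = 5)
  m <- train_model(m, prep$x_train, prep$y_train,
                   train_config("dnn", epochs = 10, seed = 6))
  smp <- predict_sample(m, prep$x_test, n_draws = 5, seed = 7)
  expect_equal(apply(smp$hf, 1, var), rep(0, nrow(smp$hf)))
  expect_equal(apply(smp$tl, 1, var), rep(0, nrow(smp$tl)))
})

test_that("posterior draws vary per patient and reproduce under a seed", {
  prep <- make_prepared_cohort(120, seed = 29)
  m <- build_model(model_spec("bnn"), seed = 8)
  m <- train_model(m, prep$x_train, prep$y_train,
                   train_config("bnn", epochs = 20, seed = 9))
  s1 <- predict_sample(m, prep$x_test, n_draws = 50, seed = 10)
  s2 <- predict_sample(m, prep$x_test, n_draws = 50, seed = 10)
  expect_identical(s1$hf, s2$hf)
  expect_identical(s1$tl, s2$tl)
  sds <- apply(s1$hf, 1, sd)
  expect_gt(mean(sds > 0), 0.99)
  expect_error(predict_sample(m, prep$x_test, n_draws = 0), "positive")
  # tidy long export
  d <- as_tibble(s1)
  expect_identical(nrow(d), 2L * nrow(prep$x_test) * 50L)
  expect_identical(sort(unique(d$task)), c("hf", "tl"))
  # outputs live on their task scales
  expect_true(all(s1$hf >= 0 & s1$hf <= 1))
  expect_true(all(s1$tl >= 0 & s1$tl <= 3))
})

test_that("multitask gradients decompose additively across task heads", {
  set.seed(60)
  X <- matrix(runif(20), 2, 10)
  Y <- cbind(hf = c(0, 1), tl = c(3, 1))
  m <- build_model(model_spec("dnn"), seed = 61)
  fw <- balonn:::nn_forward(m, X, sample = FALSE)
  dl <- balonn:::data_loss(fw$output, Y, "mse", m$output_scale)
  mask <- function(col) {
    g <- dl$grad; g[, -col] <- 0
    balonn:::nn_backward(m, fw$caches, g)
  }
  full <- balonn:::nn_backward(m, fw$caches, dl$grad)
  hf_only <- mask(1); tl_only <- mask(2)
  for (li in seq_along(full)) {
    for (slot in names(full[[li]])) {
      expect_equal(full[[li]][[slot]],
                   hf_only[[li]][[slot]] + tl_only[[li]][[slot]],
                   tolerance = 1e-12)
    }
  }
  # the head's HF column receives no gradient from the TL term
  head <- length(full)
  expect_equal(tl_only[[head]]$W[, 1], rep(0, 3))
})

test_that("checkpoints round-trip model state and predictions", {
  prep <- make_prepared_cohort(120, seed = 37)
  m <- build_model(model_spec("balonn"), seed = 11)
  m <- train_model(m, prep$x_train, prep$y_train,
                   train_config("balonn", epochs = 15, seed = 12))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_identical(n_parameters(back), n_parameters(m))
  s1 <- predict_sample(m, prep$x_test, n_draws = 20, seed = 13)
  s2 <- predict_sample(back, prep$x_test, n_draws = 20, seed = 13)
  expect_equal(s1$hf, s2$hf, tolerance = 1e-12)
  expect_equal(s1$tl, s2$tl, tolerance = 1e-12)
  expect_equal(back$trace$total, m$trace$total, tolerance = 1e-12)
})

test_that("a trained Bayesian model learns the generator's ejection-fraction rule", {
  prep <- make_prepared_cohort(1000, seed = 7, split_seed = 2)
  m <- build_model(model_spec("bnn", sigma_po = 0.1), seed = 3)
  m <- train_model(m, prep$x_train, prep$y_train,
                   train_config("bnn", seed = 4))
  val <- validate_model(m, prep$x_test, prep$y_test, n_draws = 1000,
                        seed = 5)
  s <- val$summary
  expect_gte(s$precision[s$task == "hf"], 0.8)
  hf <- val$patients[val$patients$task == "hf", ]
  # the predictive means genuinely separate the classes
  expect_gt(cor(hf$mean, hf$target), 0.3)
  expect_gt(mean(hf$mean[hf$target == 1]), mean(hf$mean[hf$target == 0]))
})
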