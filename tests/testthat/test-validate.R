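test_that("the sampled distance is the absolute mean deviation", {
  expect_equal(phi_distance(matrix(c(1, 1, 1, 1), 1), 1), 0)
  expect_equal(phi_distance(matrix(c(1, 1, 1, 0), 1), 1), 0.25)
  expect_equal(phi_distance(matrix(0, 1, 10), 1), 1)
  expect_equal(phi_distance(c(0.2, 0.4), 0.1), 0.2)  # vector = one patient
  m <- rbind(c(0, 1), c(1, 1))
  expect_equal(phi_distance(m, c(1, 0)), c(0.5, 1))
  expect_error(phi_distance(matrix(numeric(0), 1, 0), 1), "Empty")
})

test_that("true predictions use a strict tolerance per task", {
  tol <- tolerance_spec()  # 0.7 / 1.2
  expect_identical(true_prediction(0.25, "hf", tol), 1L)
  expect_identical(true_prediction(0.7, "hf", tol), 0L)   # strict boundary
  expect_identical(true_prediction(0.69999, "hf", tol), 1L)
  expect_identical(true_prediction(1.1, "tl", tol), 1L)
  expect_identical(true_prediction(1.2, "tl", tol), 0L)
  expect_error(tolerance_spec(tr_hf = 1.4), "between 0 and 1")
  expect_error(tolerance_spec(tr_tl = 3.2), "between 0 and 3")
})

test_that("precision and error agree exactly with brute-force oracles", {
  expect_equal(precision_micro(c(1, 0, 1, 1)), 0.75)
  expect_equal(precision_micro(rep(1, 7)), 1)
  expect_equal(error_statistic(c(0.2, 0.4)), 0.3)
  expect_equal(error_statistic(c(0.2, 0.4), mode = "printed"), 0.7)
  expect_equal(error_statistic(rep(0, 5)), 0)
  expect_error(precision_micro(integer(0)), "at least one")
  expect_error(error_statistic(numeric(0)), "at least one")

  set.seed(5)
  for (rep in 1:25) {
    draws <- matrix(runif(20 * 50, 0, 3), 20, 50)
    target <- sample(0:3, 20, replace = TRUE)
    phi <- phi_distance(draws, target)
    expect_equal(phi, brute_phi(draws, target), tolerance = 1e-14)
    tol <- tolerance_spec()
    pr <- true_prediction(phi, "tl", tol)
    expect_identical(precision_micro(pr), brute_precision(pr))
    expect_lt(abs(error_statistic(phi) - brute_error(phi)), 1e-12)
    expect_lt(abs(error_statistic(phi, "printed") -
                  brute_error(phi, printed = TRUE)), 1e-12)
  }
})

test_that("precision never decreases as the tolerance rises", {
  set.seed(6)
  for (rep in 1:10) {
    phi <- runif(40, 0, 2.5)
    p <- vapply(c(0.5, 1.2, 2.0), function(tr) {
      precision_micro(true_prediction(phi, "tl", tolerance_spec(tr_tl = tr)))
    }, numeric(1))
    expect_false(is.unsorted(p))
  }
})

test_that("traffic lights separate perfect, covered and missed predictions", {
  expect_identical(as.character(traffic_light(matrix(1, 1, 10), 1, "hf")),
                   "green")
  draws <- matrix(rep(c(0, 1, 2, 3), 25), 1)
  expect_identical(as.character(traffic_light(draws, 3, "tl")), "blue")
  tight <- matrix(rnorm(100, 0, 0.01), 1)
  expect_identical(as.character(traffic_light(tight, 1, "hf")), "red")
  # vectorized over patients
  m <- rbind(matrix(1, 1, 100), matrix(rnorm(100, 0, 0.01), 1))
  expect_identical(as.character(traffic_light(m, c(1, 1), "hf")),
                   c("green", "red"))
})

test_that("tolerance-based precision dominates exact rounded matching", {
  # for any sample: a rounded match implies phi <= 0.5 < Tr, so the
  # tolerance count can only gain patients
  set.seed(7)
  tol <- tolerance_spec()
  for (rep in 1:50) {
    task <- sample(c("hf", "tl"), 1)
    hi <- if (task == "hf") 1 else 3
    draws <- matrix(runif(15 * 40, 0, hi), 15, 40)
    target <- sample(0:hi, 15, replace = TRUE)
    phi <- phi_distance(draws, target)
    p_tol <- precision_micro(true_prediction(phi, task, tol))
    expect_gte(p_tol, point_accuracy(draws, target, task))
  }
})

test_that("validation composes the chain and reduces cleanly when deterministic", {
  prep <- make_prepared_cohort(150, seed = 43)
  m <- build_model(model_spec("dnn"), seed = 44)
  m <- train_model(m, prep$x_train, prep$y_train,
                   train_config("dnn", epochs = 30, seed = 45))
  val <- validate_model(m, prep$x_test, prep$y_test, n_draws = 20, seed = 46)
  M <- nrow(prep$x_test)
  expect_identical(nrow(val$patients), 2L * M)
  expect_identical(val$summary$m_patients, c(M, M))
  # light counts partition the cohort
  expect_equal(val$summary$n_green + val$summary$n_blue + val$summary$n_red,
               c(M, M))
  # a deterministic model shows no sampling spread: no blue band
  expect_identical(sum(val$summary$n_blue), 0L)
  # degenerate sample: point accuracy equals classical thresholded accuracy
  fw <- balonn:::nn_forward(m, as.matrix(prep$x_test), sample = FALSE)
  acc_hf <- mean((fw$output[, 1] > 0.5) == prep$y_test$hf)
  got <- val$summary$point_accuracy[val$summary$task == "hf"]
  expect_equal(got, acc_hf, tolerance = 1e-12)
  # histogram tabulates every patient once per task
  h <- val$histogram
  expect_equal(sum(h$predicted[h$task == "tl"]), M)
  expect_equal(sum(h$target[h$task == "hf"]), M)
  # tidiers
  expect_identical(nrow(tidy(val)), 2L * M)
  expect_identical(nrow(glance(val)), 1L)
})

test_that("the sensitivity sweep covers the grid and records seeds", {
  co <- synthesize_cohort(150, seed = 53)
  quick <- train_config("bnn", epochs = 8, batch_size = "full")
  sw <- sensitivity_sweep(co, c(0.5, 1.5, 2.5), c(0.1, 2.0),
                          seed = 54, config = quick, n_draws = 30)
  expect_identical(nrow(sw), 6L)
  expect_identical(nrow(unique(sw[, c("sigma_pr", "sigma_po")])), 6L)
  expect_false(any(sw$failed))
  expect_true(all(sw$precision_hf >= 0 & sw$precision_hf <= 1))
  one <- sensitivity_sweep(co, 1.5, 1.0, seed = 54, config = quick,
                           n_draws = 30)
  expect_identical(nrow(one), 1L)
  expect_error(sensitivity_sweep(co, numeric(0), 1), "non-empty")
  # larger posterior init scale leaves a wider predictive spread
  agg <- tapply(sw$mean_sd, sw$sigma_po, mean)
  expect_lt(agg[["0.1"]], agg[["2"]])
})

test_that("stage seeds derive deterministically and stay within integer range", {
  s1 <- derive_seed(1, "train")
  expect_identical(s1, derive_seed(1, "train"))
  expect_false(s1 == derive_seed(2, "train"))
  expect_false(s1 == derive_seed(1, "validate"))
  seeds <- vapply(1:100, function(s) derive_seed(s, "x"), integer(1))
  expect_true(all(seeds >= 0 & seeds < 2^31))
})
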