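test_that("time discretization maps months onto therapy-length classes", {
  expect_identical(discretize_time(c(0, 1, 2, 3, 4, 5, 7, 24)),
                   c(0L, 0L, 1L, 2L, 2L, 3L, 3L, 3L))
  expect_error(discretize_time(-1), "non-negative")
  # configurable band boundary
  expect_identical(discretize_time(3, breaks = c(1, 3, 4)), 1L)
})

test_that("the synthetic generator is seeded, validated and honest about its rules", {
  co1 <- synthesize_cohort(500, seed = 7)
  co2 <- synthesize_cohort(500, seed = 7)
  expect_identical(as.data.frame(co1), as.data.frame(co2))
  expect_identical(nrow(co1), 500L)
  expect_error(synthesize_cohort(5), ">= 10")
  expect_silent(validate_cohort(co1))
  gt <- synth_ground_truth(co1)
  expect_identical(gt$mode, "de_novo")
  expect_named(gt$hf_coef, c("intercept", "ef"))
  # noise-free limit: follow-up equals its (rounded) linear predictor
  cfg <- synth_config(time_sd = 0)
  co0 <- synthesize_cohort(200, seed = 8, config = cfg)
  pred <- cfg$time_coef[[1]] + cfg$time_coef[[2]] * co0$hf +
    cfg$time_coef[[3]] * co0$sc
  expect_identical(co0$time_months, as.integer(round(pmax(0, pred))))
})

test_that("the ejection-fraction dependency has the stated direction", {
  co <- synthesize_cohort(5000, seed = 21)
  p_low <- mean(co$hf[co$ef < 30])
  p_high <- mean(co$hf[co$ef > 50])
  expect_gt(p_low, p_high)
  expect_gt(p_low, 0.8)
  expect_lt(p_high, 0.2)
})

test_that("regression on synthesized follow-up recovers the generator coefficients", {
  co <- synthesize_cohort(5000, seed = 33)
  gt <- synth_ground_truth(co)
  fit <- lm(time_months ~ hf + sc, data = co)
  est <- coef(summary(fit))
  truth <- c(gt$time_coef[["intercept"]], gt$time_coef[["hf"]],
             gt$time_coef[["sc"]])
  for (i in 1:3) {
    expect_lt(abs(est[i, "Estimate"] - truth[i]), 3 * est[i, "Std. Error"])
  }
})

test_that("fitted-mode synthesis draws from sequential regressions on the base", {
  base <- synthesize_cohort(400, seed = 41)
  expect_error(synthesize_from(base[1:10, ], 50), "at least 20")
  s1 <- synthesize_from(base, 200, seed = 42)
  s2 <- synthesize_from(base, 200, seed = 42)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_identical(nrow(s1), 200L)
  expect_true(all(s1$hf %in% 0:1))
  expect_true(all(s1$time_months >= 0))
  gt <- synth_ground_truth(s1)
  expect_identical(gt$mode, "fitted")
  expect_true("time_months" %in% names(gt$coefficients))
})

test_that("cohort CSV round-trips and accepts the long column aliases", {
  co <- synthesize_cohort(12, seed = 51)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_identical(nrow(back), 12L)
  expect_identical(back$hf, co$hf)
  expect_identical(back$tl, co$tl)

  # UCI-style headers, follow-up in days, no hf label
  uci <- data.frame(
    Age = co$age, Anaemia = co$anemia,
    Creatinine_Phosphokinase = co$cph, Ejection_Fraction = co$ef,
    High_Blood_Pressure = co$hbp, Platelets = co$platelets,
    Serum_Creatinine = co$sc, Serum_Sodium = co$ss, Sex = co$sex,
    Smoking = co$smoking, Time = co$time_months * 30
  )
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(uci, path2)
  got <- read_cohort(path2, time_unit = "days", hf_threshold = 45)
  expect_identical(got$time_months, as.numeric(co$time_months))
  expect_identical(got$hf, as.integer(co$ef < 45))
})

test_that("schema violations are reported by name and row", {
  co <- synthesize_cohort(12, seed = 52)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co[, setdiff(names(co), "ef")], path)
  expect_error(read_cohort(path), "ef")

  bad <- co
  bad$ef[3] <- 150
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(bad, path2)
  expect_error(read_cohort(path2), "'ef' at row\\(s\\) 3")
})

test_that("min-max scaling is fit on train only and never clips", {
  train <- synthesize_cohort(50, seed = 61)
  train$age <- rep(c(40, 60, 80), length.out = 50)
  sc <- fit_scaler(train)
  scaled <- apply_scaler(train, sc)
  expect_equal(sort(unique(scaled$age)), c(0, 0.5, 1))
  expect_identical(scaled$sex, train$sex)  # binaries pass through
  real <- setdiff(feature_names(), c("sex", "hbp", "smoking", "anemia"))
  expect_true(all(vapply(real, function(cl) {
    all(scaled[[cl]] >= 0 & scaled[[cl]] <= 1)
  }, logical(1))))
  # unseen value above the training maximum maps above 1
  probe <- train[1, ]
  probe$age <- 100
  expect_gt(apply_scaler(probe, sc)$age, 1)
  # constant column: range 1 with a warning
  const <- train
  const$ss <- 140
  expect_warning(fit_scaler(const), "constant")
})

test_that("SMOTE balances to the majority count by convex interpolation", {
  set.seed(70)
  d <- tibble::tibble(
    a = c(rnorm(10), rnorm(5, 4)),
    b = c(rnorm(10), rnorm(5, 4)),
    hf = rep(c(0, 1), c(10, 5))
  )
  out <- smote_balance(d, class_cols = "hf", k = 3, seed = 71)
  expect_identical(as.integer(table(out$hf)), c(10L, 10L))
  # synthetic rows lie between same-class originals
  synth <- out[16:20, ]
  expect_true(all(synth$a >= min(d$a[d$hf == 1]) &
                  synth$a <= max(d$a[d$hf == 1])))

  # two-point minority with k = 1: synthetic points on the diagonal segment
  d2 <- tibble::tibble(a = c(0, 1, rnorm(8, 5)), b = c(0, 1, rnorm(8, 5)),
                       hf = rep(c(1, 0), c(2, 8)))
  out2 <- smote_balance(d2, class_cols = "hf", k = 1, seed = 72)
  synth2 <- out2[out2$hf == 1, ][-(1:2), ]
  expect_equal(synth2$a, synth2$b, tolerance = 1e-12)
  expect_true(all(synth2$a >= 0 & synth2$a <= 1))

  # balanced input comes back unchanged
  d3 <- tibble::tibble(a = rnorm(8), hf = rep(0:1, each = 4))
  expect_identical(smote_balance(d3, class_cols = "hf", seed = 73), d3)

  # singleton class: an error advising duplication, or explicit opt-in
  d4 <- tibble::tibble(a = rnorm(5), hf = c(1, 0, 0, 0, 0))
  expect_error(smote_balance(d4, class_cols = "hf"), "duplicate")
  out4 <- smote_balance(d4, class_cols = "hf", singleton = "duplicate")
  expect_identical(as.integer(table(out4$hf)), c(4L, 4L))
})

test_that("composite-label SMOTE improves both target marginals", {
  co <- synthesize_cohort(600, seed = 81)
  out <- smote_balance(co, class_cols = c("hf", "tl"), seed = 82,
                       singleton = "duplicate")
  joint <- table(out$hf, out$tl)
  expect_true(all(joint[joint > 0] == max(joint)))
  # each marginal is no more skewed than before
  skew <- function(x) max(table(x)) / length(x)
  expect_lte(skew(out$tl), skew(co$tl))
  expect_lte(skew(out$hf), skew(co$hf))
})

test_that("the train/test split is seeded, disjoint and exhaustive", {
  co <- synthesize_cohort(100, seed = 91)
  sp <- split_cohort(co, 0.8, seed = 92)
  expect_identical(nrow(sp$train), 80L)
  expect_identical(nrow(sp$test), 20L)
  expect_identical(sort(c(sp$train$id, sp$test$id)), sort(co$id))
  expect_length(intersect(sp$train$id, sp$test$id), 0L)
  sp2 <- split_cohort(co, 0.8, seed = 92)
  expect_identical(sp$train$id, sp2$train$id)
  expect_error(split_cohort(co, 1.2), "between 0 and 1")
})
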