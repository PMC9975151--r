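#' Configuration of the synthetic cohort generator
#'
#' De-novo generation draws each feature from a marginal chosen to emulate a
#' heart-failure EHR cohort (prevalences and moments in the range reported
#' for the public heart-failure clinical-records data), then generates the
#' targets from explicit dependency rules:
#'
#' * `hf ~ Bernoulli(plogis(hf_coef[1] + hf_coef[2] * ef))` — a logistic
#'   rule with a negative ejection-fraction coefficient (reduced EF marks
#'   systolic heart failure);
#' * `time_months = round(max(0, time_coef[1] + time_coef[2] * hf +
#'   time_coef[3] * sc + N(0, time_sd)))` — follow-up shortens for systolic
#'   heart failure and elevated serum creatinine.
#'
#' The true coefficients travel with the generated table (attribute
#' `ground_truth`) so recovery tests can regress against them.
#'
#' @param hf_coef Named numeric `(intercept, ef)` of the logistic HF rule.
#' @param time_coef Named numeric `(intercept, hf, sc)` of the linear
#'   follow-up rule.
#' @param time_sd Residual standard deviation of the follow-up rule
#'   (months).
#' @param smote_k Default neighbour count carried into [smote_balance()].
#' @return A `balonn_synth_config`.
#' @export
synth_config <- function(hf_coef = c(intercept = 9.5, ef = -0.25),
                         time_coef = c(intercept = 10, hf = -3.5, sc = -1.2),
                         time_sd = 2, smote_k = 5) {
  stopifnot(length(hf_coef) == 2, length(time_coef) == 3, time_sd >= 0)
  structure(list(hf_coef = hf_coef, time_coef = time_coef,
                 time_sd = time_sd, smote_k = smote_k),
            class = "balonn_synth_config")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate a synthetic patient cohort
#'
#' Sequential synthesis: features are drawn from their marginals, then the
#' heart-failure class from its logistic rule on the ejection fraction, then
#' the follow-up time from its linear rule on `hf` and serum creatinine (see
#' [synth_config()]). The therapy-length class `tl` is derived with
#' [discretize_time()]. With `time_sd = 0` and a degenerate `hf` draw the
#' targets equal their linear predictors exactly.
#'
#' @param n Number of patients (at least 10).
#' @param seed Optional seed; the same seed reproduces the table exactly.
#' @param config A [synth_config()].
#' @return Cohort tibble (`id`, features, `time_months`, `hf`, `tl`) with
#'   attribute `ground_truth` (the coefficients actually used); read it with
#'   [synth_ground_truth()].
#' @examples
#' cohort <- synthesize_cohort(200, seed = 1)
#' synth_ground_truth(cohort)$hf_coef
#' @export
synthesize_cohort <- function(n, seed = NULL, config = synth_config()) {
  stopifnot(inherits(config, "balonn_synth_config"))
  n <- as.integer(n)
  if (is.na(n) || n < 10L) {
    stop("`n` must be an integer >= 10.", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  cohort <- tibble::tibble(
    id = sprintf("synth_%05d", seq_len(n)),
    sex = stats::rbinom(n, 1, 0.65),
    age = round(clamp(stats::rnorm(n, 61, 12), 40, 95)),
    cph = round(clamp(stats::rlnorm(n, 5.5, 1.0), 23, 7900)),
    ef = round(clamp(stats::rnorm(n, 38, 12), 14, 80)),
    hbp = stats::rbinom(n, 1, 0.35),
    platelets = round(clamp(stats::rnorm(n, 263000, 97000), 25000, 850000)),
    sc = round(clamp(stats::rlnorm(n, 0.18, 0.35), 0.5, 9.4), 2),
    ss = round(clamp(stats::rnorm(n, 136.6, 4.4), 113, 148)),
    smoking = stats::rbinom(n, 1, 0.32),
    anemia = stats::rbinom(n, 1, 0.43)
  )
  p_hf <- stats::plogis(config$hf_coef[[1]] + config$hf_coef[[2]] * cohort$ef)
  cohort$hf <- stats::rbinom(n, 1, p_hf)
  latent <- config$time_coef[[1]] +
    config$time_coef[[2]] * cohort$hf +
    config$time_coef[[3]] * cohort$sc +
    stats::rnorm(n, 0, config$time_sd)
  cohort$time_months <- as.integer(round(pmax(0, latent)))
  cohort$tl <- discretize_time(cohort$time_months)
  attr(cohort, "ground_truth") <- list(
    mode = "de_novo",
    hf_coef = config$hf_coef,
    time_coef = config$time_coef,
    time_sd = config$time_sd
  )
  cohort
}

#' Ground-truth coefficients of a synthetic cohort
#'
#' @param cohort A cohort produced by [synthesize_cohort()] or
#'   [synthesize_from()].
#' @return The `ground_truth` attribute (list), or `NULL` for real data.
#' @export
synth_ground_truth <- function(cohort) {
  attr(cohort, "ground_truth")
}

#' Synthesize patients from a fitted base cohort
#'
#' Sequential-regression synthesis in the style of population-synthesis
#' tools: variables are generated in canonical order, each drawn from a
#' model fitted on the base table given the previously generated variables —
#' linear regression with Gaussian residuals for real-valued features,
#' logistic regression for binaries. `hf` is fitted on all features and
#' `time_months` on the features plus `hf`; `tl` is derived.
#'
#' @param base A validated cohort with at least 20 rows (smaller tables give
#'   unstable fits and are refused).
#' @param n Number of synthetic patients.
#' @param seed Optional seed.
#' @return Cohort tibble with attribute `ground_truth` holding the fitted
#'   coefficients.
#' @export
synthesize_from <- function(base, n, seed = NULL) {
  if (nrow(base) < 20) {
    stop("`base` must have at least 20 rows for stable sequential fits.",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  stopifnot(n >= 1L)
  vars <- feature_names()
  bin <- binary_features()
  out <- tibble::tibble(id = sprintf("synth_%05d", seq_len(n)))
  coefs <- list()
  for (i in seq_along(vars)) {
    v <- vars[i]
    prev <- vars[seq_len(i - 1)]
    if (!length(prev)) {
      if (v %in% bin) {
        p <- mean(base[[v]])
        out[[v]] <- stats::rbinom(n, 1, p)
        coefs[[v]] <- c(p = p)
      } else {
        out[[v]] <- stats::rnorm(n, mean(base[[v]]), stats::sd(base[[v]]))
        coefs[[v]] <- c(mean = mean(base[[v]]), sd = stats::sd(base[[v]]))
      }
      next
    }
    fml <- stats::reformulate(prev, response = v)
    if (v %in% bin) {
      fit <- suppressWarnings(
        stats::glm(fml, data = base, family = stats::binomial()))
      p <- stats::predict(fit, newdata = out, type = "response")
      out[[v]] <- stats::rbinom(n, 1, p)
    } else {
      fit <- stats::lm(fml, data = base)
      mu <- stats::predict(fit, newdata = out)
      out[[v]] <- mu + stats::rnorm(n, 0, stats::sigma(fit))
    }
    coefs[[v]] <- stats::coef(fit)
  }
  hf_fit <- suppressWarnings(stats::glm(
    stats::reformulate(vars, response = "hf"),
    data = base, family = stats::binomial()))
  out$hf <- stats::rbinom(
    n, 1, stats::predict(hf_fit, newdata = out, type = "response"))
  tm_fit <- stats::lm(
    stats::reformulate(c(vars, "hf"), response = "time_months"),
    data = base)
  out$time_months <- as.integer(round(pmax(
    0, stats::predict(tm_fit, newdata = out) +
      stats::rnorm(n, 0, stats::sigma(tm_fit)))))
  out$tl <- discretize_time(out$time_months)
  coefs$hf <- stats::coef(hf_fit)
  coefs$time_months <- stats::coef(tm_fit)
  attr(out, "ground_truth") <- list(mode = "fitted", coefficients = coefs,
                                    time_sd = stats::sigma(tm_fit))
  out
}
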