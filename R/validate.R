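#' Tolerance specification for uncertainty-aware validation
#'
#' The tolerance `Tr` decides how far the sampled predictive mean may sit
#' from the target while still counting as a true prediction — i.e. how many
#' simultaneous output states are accepted. Defaults follow the validation
#' setup: `tr_hf = 0.7` on the binary (0, 1) scale (samples a majority of one
#' binary value) and `tr_tl = 1.2` on the ordinal 0-3 scale (accepts at
#' least two adjacent plausible classes). Sensitivity sweeps conventionally
#' tighten the binary tolerance to 0.6 (see [sensitivity_sweep()]).
#'
#' @param tr_hf Binary-task tolerance in (0, 1).
#' @param tr_tl Ordinal-task tolerance in (0, 3).
#' @return A `balonn_tolerance`.
#' @export
tolerance_spec <- function(tr_hf = 0.7, tr_tl = 1.2) {
  if (tr_hf <= 0 || tr_hf >= 1) {
    stop("`tr_hf` must lie strictly between 0 and 1.", call. = FALSE)
  }
  if (tr_tl <= 0 || tr_tl >= 3) {
    stop("`tr_tl` must lie strictly between 0 and 3.", call. = FALSE)
  }
  structure(list(tr_hf = tr_hf, tr_tl = tr_tl), class = "balonn_tolerance")
}

#' Distance between a sampled prediction and its target
#'
#' `phi_i = |mean_j(f_ij) - O_i|`: the absolute distance between the average
#' of the N sampled model outputs for patient i and the target. Zero iff the
#' sample mean equals the target; symmetric in the sign of the deviation.
#'
#' @param sample_matrix M x N matrix of sampled outputs (or a single row as
#'   a vector).
#' @param target Numeric target vector of length M.
#' @return Non-negative numeric vector of length M.
#' @examples
#' phi_distance(matrix(c(1, 1, 1, 0), 1), 1)  # 0.25
#' @export
phi_distance <- function(sample_matrix, target) {
  if (is.null(dim(sample_matrix))) {
    sample_matrix <- matrix(sample_matrix, nrow = 1)
  }
  if (ncol(sample_matrix) < 1L || nrow(sample_matrix) < 1L) {
    stop("Empty sample.", call. = FALSE)
  }
  stopifnot(length(target) == nrow(sample_matrix))
  abs(rowMeans(sample_matrix) - target)
}

#' Tolerance-based true-prediction indicator
#'
#' `Pr_i = 1` if `phi_i < Tr` (strict), else 0. The task selects which
#' tolerance applies.
#'
#' @param phi Non-negative distances.
#' @param task `"hf"` or `"tl"`.
#' @param tol A [tolerance_spec()].
#' @return Integer vector of 0/1 indicators.
#' @export
true_prediction <- function(phi, task = c("hf", "tl"),
                            tol = tolerance_spec()) {
  task <- match.arg(task)
  stopifnot(inherits(tol, "balonn_tolerance"), all(phi >= 0))
  tr <- if (task == "hf") tol$tr_hf else tol$tr_tl
  as.integer(phi < tr)
}

#' Micro-averaged precision
#'
#' The mean of the per-patient true-prediction indicators,
#' `P = sum(Pr_i) / M` — a micro average, weighting classes by their
#' frequency.
#'
#' @param pr Vector of 0/1 indicators (length M >= 1).
#' @return A number in `[0, 1]`.
#' @export
precision_micro <- function(pr) {
  if (length(pr) < 1L) stop("Need at least one indicator.", call. = FALSE)
  stopifnot(all(pr %in% c(0, 1)))
  sum(pr) / length(pr)
}

#' Aggregate prediction error
#'
#' Default mode: the mean sampled distance `E = sum(phi_i) / M`, which is 0
#' for perfect predictions and grows with miss distance. The alternate
#' `"printed"` mode computes `1 - sum(phi_i) / M`, the complement form some
#' reports use (note it *rewards* large distances; it is provided for
#' comparability, not as the default).
#'
#' @param phi Non-negative distances (length M >= 1).
#' @param mode `"mean_distance"` (default) or `"printed"`.
#' @return A single number.
#' @export
error_statistic <- function(phi, mode = c("mean_distance", "printed")) {
  mode <- match.arg(mode)
  if (length(phi) < 1L) stop("Need at least one distance.", call. = FALSE)
  e <- sum(phi) / length(phi)
  if (mode == "printed") 1 - e else e
}

#' Traffic-light classification of a sampled prediction
#'
#' Per patient: **green** if the sample median, rounded to the task's class
#' grid (HF: {0, 1}; TL: {0..3}), equals the target — a perfect prognosis;
#' **blue** if not green but the target lies inside the central interval of
#' the draws (default 95%) — a by-prognosis still fulfilled within the
#' prediction's uncertainty; **red** otherwise — an off-prognosis.
#'
#' @param sample_matrix M x N matrix of sampled outputs.
#' @param target Targets, length M.
#' @param task `"hf"` or `"tl"` (sets the rounding grid).
#' @param level Central-interval coverage for blue (default 0.95).
#' @return Factor vector with levels green, blue, red.
#' @export
traffic_light <- function(sample_matrix, target, task = c("hf", "tl"),
                          level = 0.95) {
  task <- match.arg(task)
  if (is.null(dim(sample_matrix))) {
    sample_matrix <- matrix(sample_matrix, nrow = 1)
  }
  if (ncol(sample_matrix) < 1L) stop("Empty sample.", call. = FALSE)
  hi_class <- if (task == "hf") 1 else 3
  med <- apply(sample_matrix, 1, stats::median)
  rounded <- clamp(round(med), 0, hi_class)
  alpha <- (1 - level) / 2
  qs <- t(apply(sample_matrix, 1, stats::quantile, probs = c(alpha, 1 - alpha)))
  light <- ifelse(rounded == target, "green",
                  ifelse(target >= qs[, 1] & target <= qs[, 2],
                         "blue", "red"))
  factor(light, levels = c("green", "blue", "red"))
}

#' Point-prediction accuracy from the same samples
#'
#' The classical deterministic yardstick: the rounded sample mean must equal
#' the target exactly. Used to quantify how much tolerance-based validation
#' gains by accepting ambiguous (blue) predictions.
#'
#' @inheritParams traffic_light
#' @return Proportion of exact rounded matches.
#' @export
point_accuracy <- function(sample_matrix, target, task = c("hf", "tl")) {
  task <- match.arg(task)
  if (is.null(dim(sample_matrix))) {
    sample_matrix <- matrix(sample_matrix, nrow = 1)
  }
  hi_class <- if (task == "hf") 1 else 3
  rounded <- clamp(round(rowMeans(sample_matrix)), 0, hi_class)
  mean(rounded == target)
}

#' Uncertainty-aware validation of a model
#'
#' Composes the whole validation chain: sample N predictions per patient and
#' task ([predict_sample()]), compute distances ([phi_distance()]),
#' tolerance indicators ([true_prediction()]), micro-averaged precision and
#' error ([precision_micro()], [error_statistic()]) and traffic lights
#' ([traffic_light()]). Also tabulates the predicted-mean class histogram
#' against the target histogram per task, the distribution comparison used
#' to check that a stochastic model reproduces the test-data dynamics.
#'
#' @param model A trained `balonn_model`.
#' @param x Test feature table (already scaled with the *training* scaler).
#' @param y Test targets (data frame with `hf` and `tl` columns).
#' @param n_draws Posterior draws per patient (default 1000).
#' @param tol A [tolerance_spec()].
#' @param seed Optional seed for the draws.
#' @return A `balonn_validation`: list with `patients` (per-patient tibble:
#'   task, target, mean, sd, phi, pr, light), `summary` (per-task tibble:
#'   precision, error_mean, error_printed, point_accuracy, light counts) and
#'   `histogram` (per-task predicted vs target class counts).
#' @export
validate_model <- function(model, x, y, n_draws = 1000,
                           tol = tolerance_spec(), seed = NULL) {
  stopifnot(inherits(model, "balonn_model"), inherits(tol, "balonn_tolerance"))
  y <- as.data.frame(y)
  smp <- predict_sample(model, x, n_draws = n_draws, seed = seed)
  patients <- purrr::map_dfr(model$tasks, function(task) {
    m <- smp[[task]]
    target <- y[[task]]
    phi <- phi_distance(m, target)
    pr <- true_prediction(phi, task, tol)
    light <- traffic_light(m, target, task)
    tibble::tibble(
      patient = seq_len(nrow(m)),
      task = task,
      target = target,
      mean = rowMeans(m),
      sd = apply(m, 1, stats::sd),
      phi = phi,
      pr = pr,
      light = light
    )
  })
  summary <- patients |>
    dplyr::group_by(.data$task) |>
    dplyr::summarise(
      m_patients = dplyr::n(),
      precision = precision_micro(.data$pr),
      error_mean = error_statistic(.data$phi),
      error_printed = error_statistic(.data$phi, mode = "printed"),
      n_green = sum(.data$light == "green"),
      n_blue = sum(.data$light == "blue"),
      n_red = sum(.data$light == "red"),
      .groups = "drop"
    )
  summary$point_accuracy <- vapply(summary$task, function(task) {
    point_accuracy(smp[[task]], y[[task]], task)
  }, numeric(1), USE.NAMES = FALSE)
  histogram <- purrr::map_dfr(model$tasks, function(task) {
    hi <- if (task == "hf") 1 else 3
    classes <- 0:hi
    pred_class <- clamp(round(rowMeans(smp[[task]])), 0, hi)
    pred_n <- vapply(classes, function(cl) sum(pred_class == cl), numeric(1))
    targ_n <- vapply(classes, function(cl) sum(y[[task]] == cl), numeric(1))
    tibble::tibble(task = task, class = classes,
                   predicted = pred_n, target = targ_n)
  })
  structure(list(patients = patients, summary = summary,
                 histogram = histogram, n_draws = n_draws, tol = tol),
            class = "balonn_validation")
}

#' @export
print.balonn_validation <- function(x, ...) {
  cat("<balonn_validation> ", x$n_draws, " draws, Tr(hf) = ", x$tol$tr_hf,
      ", Tr(tl) = ", x$tol$tr_tl, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.balonn_validation <- function(x, ...) x$patients

#' @export
glance.balonn_validation <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    precision_total = mean(s$precision),
    error_total = mean(s$error_mean),
    precision_hf = s$precision[s$task == "hf"],
    precision_tl = s$precision[s$task == "tl"],
    error_hf = s$error_mean[s$task == "hf"],
    error_tl = s$error_mean[s$task == "tl"],
    n_draws = x$n_draws
  )
}

#' Prior/posterior scale sensitivity sweep
#'
#' Trains and validates one fresh model per cell of the Cartesian grid
#' `sigma_pr x sigma_po`, recording per-task precision and error together
#' with the per-cell seed, so each cell is independently reproducible.
#' Cells that fail are recorded with their error message and the sweep
#' continues. By convention the binary tolerance tightens to 0.6 in sweeps
#' (single validations keep 0.7); pass `tol` to override.
#'
#' @param data A cohort tibble (features + `hf`, `tl`).
#' @param sigma_pr,sigma_po Numeric grids (non-empty).
#' @param variant Model variant to sweep (default `"bnn"`).
#' @param seed Base seed; cell seeds are derived from it.
#' @param config Optional [train_config()] override applied to every cell.
#' @param tol Tolerances (default `tolerance_spec(tr_hf = 0.6)`).
#' @param n_draws Draws per validation (default 1000).
#' @param train_fraction Train split per cell (default 0.8).
#' @param keep_patient_sd Keep each cell's per-patient predictive standard
#'   deviations (list-column `patient_sd`, averaged over tasks)?
#' @return A `balonn_sweep`: tibble with one row per grid cell.
#' @export
sensitivity_sweep <- function(data, sigma_pr, sigma_po,
                              variant = c("bnn", "balonn"),
                              seed = 1, config = NULL,
                              tol = tolerance_spec(tr_hf = 0.6),
                              n_draws = 1000, train_fraction = 0.8,
                              keep_patient_sd = FALSE) {
  variant <- match.arg(variant)
  if (!length(sigma_pr) || !length(sigma_po)) {
    stop("Both grids must be non-empty.", call. = FALSE)
  }
  grid <- expand.grid(sigma_pr = sigma_pr, sigma_po = sigma_po,
                      KEEP.OUT.ATTRS = FALSE)
  # one split shared by every cell: per-patient quantities are then
  # comparable across the grid; cells retrain from scratch with fresh seeds
  sp <- split_cohort(data, train_fraction,
                     seed = derive_seed(seed, "sweep_split"))
  scaler <- fit_scaler(sp$train)
  x_tr <- apply_scaler(sp$train, scaler)
  x_te <- apply_scaler(sp$test, scaler)
  rows <- purrr::map_dfr(seq_len(nrow(grid)), function(ci) {
    cell_seed <- derive_seed(seed, paste0("sweep_cell_", ci))
    res <- tryCatch({
      spec <- model_spec(variant, sigma_pr = grid$sigma_pr[ci],
                         sigma_po = grid$sigma_po[ci])
      model <- build_model(spec, seed = cell_seed)
      # full-batch steps per cell: the posterior keeps the memory of its
      # initialization scale, so sigma_po stays the experiment's control
      # parameter over the fixed epoch budget
      cfg <- config %||% train_config(variant, batch_size = "full")
      cfg$seed <- cell_seed
      model <- train_model(model, x_tr, sp$train[, model$tasks], cfg)
      val <- validate_model(model, x_te, sp$test[, model$tasks],
                            n_draws = n_draws, tol = tol, seed = cell_seed)
      s <- val$summary
      out <- tibble::tibble(
        sigma_pr = grid$sigma_pr[ci], sigma_po = grid$sigma_po[ci],
        seed = cell_seed, variant = variant,
        precision_hf = s$precision[s$task == "hf"],
        precision_tl = s$precision[s$task == "tl"],
        error_hf = s$error_mean[s$task == "hf"],
        error_tl = s$error_mean[s$task == "tl"],
        mean_sd = mean(val$patients$sd),
        failed = FALSE, message = NA_character_
      )
      if (keep_patient_sd) {
        psd <- val$patients |>
          dplyr::group_by(.data$patient) |>
          dplyr::summarise(sd = mean(.data$sd), .groups = "drop")
        out$patient_sd <- list(psd$sd)
      }
      out
    }, error = function(e) {
      tibble::tibble(
        sigma_pr = grid$sigma_pr[ci], sigma_po = grid$sigma_po[ci],
        seed = cell_seed, variant = variant,
        precision_hf = NA_real_, precision_tl = NA_real_,
        error_hf = NA_real_, error_tl = NA_real_, mean_sd = NA_real_,
        failed = TRUE, message = conditionMessage(e)
      )
    })
    res
  })
  structure(rows, class = c("balonn_sweep", class(rows)))
}

#' @export
tidy.balonn_sweep <- function(x, ...) {
  tibble::as_tibble(x[, setdiff(names(x), "patient_sd")]) |>
    tidyr::pivot_longer(dplyr::all_of(c("precision_hf", "precision_tl",
                                        "error_hf", "error_tl")),
                        names_to = c("metric", "task"), names_sep = "_",
                        values_to = "value")
}

#' Derive a stage seed from a global seed
#'
#' Deterministic fan-out of one user-facing seed into per-stage seeds, so
#' pipeline stages are independently reproducible. The stage name is folded
#' into a 31-bit integer with a polynomial string hash.
#'
#' @param seed Integer base seed.
#' @param stage Stage name (string).
#' @return A positive integer below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((h + as.numeric(seed) * 7919) %% 2147483647)
}
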