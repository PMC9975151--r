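#' Canonical cohort feature names
#'
#' The ten model inputs, in canonical column order: sex, age, creatinine
#' phosphokinase (`cph`, U/L), ejection fraction (`ef`, percent), high blood
#' pressure (`hbp`), platelets (count/uL), serum creatinine (`sc`, mg/dL),
#' serum sodium (`ss`, mEq/L), smoking, anaemia. `sex`, `hbp`, `smoking` and
#' `anemia` are binary; the rest are real-valued.
#'
#' @return Character vector of length 10.
#' @export
feature_names <- function() {
  c("sex", "age", "cph", "ef", "hbp", "platelets", "sc", "ss",
    "smoking", "anemia")
}

binary_features <- function() c("sex", "hbp", "smoking", "anemia")

# accepted aliases (case-insensitive) -> canonical names
cohort_aliases <- function() {
  c(
    creatinine_phosphokinase = "cph", ejection_fraction = "ef",
    high_blood_pressure = "hbp", serum_creatinine = "sc",
    serum_sodium = "ss", anaemia = "anemia", time = "time_months",
    platelets = "platelets"
  )
}

#' Read and validate a cohort CSV
#'
#' Reads a patient table with the canonical schema ([feature_names()] plus
#' `id`, `time_months` and `hf`), accepting the long UCI-style column names
#' (`creatinine_phosphokinase`, `ejection_fraction`, `high_blood_pressure`,
#' `serum_creatinine`, `serum_sodium`, `anaemia`, `time`) case-insensitively.
#' Schema violations are reported with row numbers.
#'
#' The public heart-failure clinical-records file carries follow-up time in
#' days and no systolic-vs-preserved heart-failure label; `time_unit =
#' "days"` divides by 30 (rounding down), and `hf_threshold` labels
#' `hf = 1` when the ejection fraction falls below it. Both are explicit
#' interpretations the caller opts into (EF-thresholding makes EF partially
#' encode the label — see the methods vignette).
#'
#' @param path CSV file path.
#' @param time_unit `"months"` (default) or `"days"`.
#' @param hf_threshold Optional EF cutoff used to derive `hf` when the file
#'   has no `hf` column (e.g. 45).
#' @return A validated cohort tibble with canonical columns and a derived
#'   `tl` column ([discretize_time()]).
#' @export
read_cohort <- function(path, time_unit = c("months", "days"),
                        hf_threshold = NULL) {
  time_unit <- match.arg(time_unit)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  names(raw) <- tolower(names(raw))
  al <- cohort_aliases()
  hit <- names(raw) %in% names(al)
  names(raw)[hit] <- unname(al[names(raw)[hit]])
  if (!"hf" %in% names(raw) && !is.null(hf_threshold)) {
    if (!"ef" %in% names(raw)) {
      stop("Missing required column 'ejection_fraction' (ef).",
           call. = FALSE)
    }
    raw$hf <- as.integer(raw$ef < hf_threshold)
  }
  if (time_unit == "days" && "time_months" %in% names(raw)) {
    raw$time_months <- floor(raw$time_months / 30)
  }
  required <- c(feature_names(), "time_months", "hf")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("Missing required column(s): ", paste(missing, collapse = ", "),
         ".", call. = FALSE)
  }
  if (!"id" %in% names(raw)) raw$id <- as.character(seq_len(nrow(raw)))
  for (col in required) {
    if (!is.numeric(raw[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(raw[[col]]))))
      stop("Column '", col, "' is non-numeric (e.g. row ",
           bad[1] %||% 1, ").", call. = FALSE)
    }
  }
  cohort <- dplyr::select(raw, dplyr::all_of(c("id", required)))
  validate_cohort(cohort)
  cohort$id <- as.character(cohort$id)
  cohort$hf <- as.integer(cohort$hf)
  cohort$tl <- discretize_time(cohort$time_months)
  tibble::as_tibble(cohort)
}

#' Validate cohort invariants
#'
#' Checks: no missing values; binary columns (including `hf`) in {0, 1};
#' `ef` in (0, 100]; `age` > 0; `time_months` >= 0. Violations are reported
#' with their row indices.
#'
#' @param cohort A cohort data frame.
#' @return The cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  fail <- function(col, rows) {
    stop("Invalid '", col, "' at row(s) ",
         paste(utils::head(rows, 5), collapse = ", "),
         if (length(rows) > 5) " ..." else "", ".", call. = FALSE)
  }
  required <- c(feature_names(), "time_months", "hf")
  for (col in required) {
    rows <- which(is.na(cohort[[col]]))
    if (length(rows)) fail(col, rows)
  }
  for (col in c(binary_features(), "hf")) {
    rows <- which(!cohort[[col]] %in% c(0, 1))
    if (length(rows)) fail(col, rows)
  }
  rows <- which(cohort$ef <= 0 | cohort$ef > 100)
  if (length(rows)) fail("ef", rows)
  rows <- which(cohort$age <= 0)
  if (length(rows)) fail("age", rows)
  rows <- which(cohort$time_months < 0)
  if (length(rows)) fail("time_months", rows)
  invisible(cohort)
}

#' Write a cohort CSV
#'
#' @param cohort Cohort tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' Discretize follow-up time into therapy-length classes
#'
#' Maps months of follow-up onto the ordinal therapy-length scale: 0-1
#' month -> TL 0 (short), 2 months -> TL 1, 3-4 months -> TL 2, 5 or more
#' -> TL 3 (long). The 2-4 month band spans two classes; the even split at
#' 2 vs 3-4 months is the package's reading and can be overridden via
#' `breaks` (upper bounds of classes 0..2).
#'
#' @param time_months Non-negative integer vector of months.
#' @param breaks Upper bounds (inclusive) of TL classes 0, 1 and 2; default
#'   `c(1, 2, 4)`.
#' @return Integer vector of TL classes in {0, 1, 2, 3}.
#' @examples
#' discretize_time(c(0, 2, 3, 7))  # 0 1 2 3
#' @export
discretize_time <- function(time_months, breaks = c(1, 2, 4)) {
  if (any(is.na(time_months)) || any(time_months < 0)) {
    stop("`time_months` must be non-negative.", call. = FALSE)
  }
  stopifnot(length(breaks) == 3, !is.unsorted(breaks))
  findInterval(time_months, breaks + 0.5)
}

#' Min-max scaler fitted on training rows
#'
#' `fit_scaler()` learns per-column minima and maxima of the real-valued
#' features on the training rows; binary features pass through untouched.
#' `apply_scaler()` re-applies the stored parameters, so test rows outside
#' the training range map outside `[0, 1]` (no clipping — the leakage guard
#' is that test statistics never enter the scaler). A constant column gets
#' range 1 with a warning instead of dividing by zero.
#'
#' @param cohort Cohort data frame holding the feature columns.
#' @return `fit_scaler()`: a `balonn_scaler` (tibble of column, min, range);
#'   `apply_scaler()`: tibble of the 10 scaled feature columns.
#' @export
fit_scaler <- function(cohort) {
  stopifnot(nrow(cohort) >= 1)
  real <- setdiff(feature_names(), binary_features())
  sc <- purrr::map_dfr(real, function(col) {
    lo <- min(cohort[[col]]); hi <- max(cohort[[col]])
    if (hi == lo) {
      warning("Feature '", col, "' is constant on the training rows; ",
              "using range 1.", call. = FALSE)
      rng <- 1
    } else {
      rng <- hi - lo
    }
    tibble::tibble(column = col, min = lo, range = rng)
  })
  structure(sc, class = c("balonn_scaler", class(sc)))
}

#' @rdname fit_scaler
#' @param scaler A fitted `balonn_scaler`.
#' @export
apply_scaler <- function(cohort, scaler) {
  stopifnot(inherits(scaler, "balonn_scaler"))
  out <- cohort[, feature_names()]
  for (i in seq_len(nrow(scaler))) {
    col <- scaler$column[i]
    out[[col]] <- (out[[col]] - scaler$min[i]) / scaler$range[i]
  }
  tibble::as_tibble(out)
}

#' Balance classes with SMOTE
#'
#' Synthetic Minority Oversampling: every class is raised to the majority
#' count by adding interpolated rows `x + u * (x_nn - x)` with
#' `u ~ Uniform(0, 1)` and `x_nn` one of the `k` nearest same-class
#' neighbours (Euclidean distance over the numeric feature columns). With
#' two targets the composite label `(hf, tl)` is balanced, which improves
#' both marginals regardless of ordering.
#'
#' A class with a single member admits no interpolation; by default this is
#' an error advising to merge the class or duplicate the row
#' (`singleton = "duplicate"` opts into plain duplication).
#'
#' @param data Data frame of numeric features plus the class column(s).
#' @param class_cols Column(s) forming the class label (default
#'   `c("hf", "tl")`).
#' @param k Number of nearest neighbours (default 5; capped at class size
#'   minus 1).
#' @param seed Optional seed.
#' @param singleton `"error"` (default) or `"duplicate"`.
#' @return Tibble with the same columns, classes balanced to the majority
#'   count. Already balanced input is returned unchanged.
#' @export
smote_balance <- function(data, class_cols = c("hf", "tl"), k = 5,
                          seed = NULL, singleton = c("error", "duplicate")) {
  singleton <- match.arg(singleton)
  stopifnot(k >= 1, all(class_cols %in% names(data)))
  if (!is.null(seed)) set.seed(seed)
  data <- tibble::as_tibble(data)
  has_id <- "id" %in% names(data)
  label <- do.call(paste, c(data[class_cols], sep = "/"))
  counts <- table(label)
  target <- max(counts)
  num_cols <- setdiff(names(data)[vapply(data, is.numeric, logical(1))],
                      class_cols)
  new_rows <- list()
  for (cls in names(counts)) {
    need <- target - counts[[cls]]
    if (need == 0) next
    members <- which(label == cls)
    if (length(members) < 2) {
      if (singleton == "error") {
        stop("Class '", cls, "' has a single member; SMOTE needs >= 2. ",
             "Merge the class or duplicate the row ",
             "(singleton = \"duplicate\").", call. = FALSE)
      }
      rows <- data[rep(members, need), ]
      new_rows[[cls]] <- rows
      next
    }
    Xc <- as.matrix(data[members, num_cols])
    D <- as.matrix(stats::dist(Xc))
    diag(D) <- Inf
    kk <- min(k, length(members) - 1)
    base <- sample(seq_along(members), need, replace = TRUE)
    rows <- data[members[base], ]
    synth_feats <- matrix(NA_real_, need, length(num_cols))
    for (r in seq_len(need)) {
      nn_order <- order(D[base[r], ])[seq_len(kk)]
      nb <- nn_order[sample.int(kk, 1)]
      u <- stats::runif(1)
      synth_feats[r, ] <- Xc[base[r], ] + u * (Xc[nb, ] - Xc[base[r], ])
    }
    rows[num_cols] <- as.data.frame(synth_feats)
    new_rows[[cls]] <- rows
  }
  if (!length(new_rows)) return(data)
  synth <- dplyr::bind_rows(new_rows)
  if (has_id) synth$id <- paste0("smote_", seq_len(nrow(synth)))
  dplyr::bind_rows(data, synth)
}

#' Seeded train/test split
#'
#' Disjoint, exhaustive random partition. Scaler fitting and SMOTE must use
#' only the training part (see [fit_scaler()]).
#'
#' @param data Cohort data frame.
#' @param train_fraction Fraction in (0, 1), default 0.8.
#' @param seed Optional seed.
#' @return List with `train` and `test` tibbles.
#' @export
split_cohort <- function(data, train_fraction = 0.8, seed = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1.",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  n_train <- round(n * train_fraction)
  idx <- sample.int(n)
  list(train = tibble::as_tibble(data[sort(idx[seq_len(n_train)]), ]),
       test = tibble::as_tibble(data[sort(idx[-seq_len(n_train)]), ]))
}
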