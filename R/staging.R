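# Feature selection and the SHG B-index.
#
# The B-index is an ordinary-least-squares linear combination of selected
# collagen features predicting Brunt stage on a continuous scale, clamped
# below at 0 (no upper clamp: cirrhotic livers may score above 4). Features
# are chosen by greedy sequential forward selection minimizing the residual
# sum of squares of the OLS fit at each step.

rss_of_fit <- function(X, y) {
  # returns NA for rank-deficient designs (collinear candidate)
  fit <- stats::.lm.fit(X, y)
  if (fit$rank < ncol(X)) return(NA_real_)
  sum(fit$residuals^2)
}

#' Sequential forward feature selection by residual sum of squares
#'
#' Greedily grows a feature set for a linear model of `response`: at each
#' step the candidate whose inclusion gives the smallest residual sum of
#' squares (RSS) of the OLS fit is added. Stops after `k_max` inclusions, or
#' earlier when the best available RSS improvement falls below `tol` (when
#' `tol` is given). Candidates whose inclusion makes the design singular are
#' skipped with a warning.
#'
#' @param data Data frame with the response and candidate feature columns.
#' @param response Name of the response column (default `"stage"`).
#' @param features Character vector of candidate feature names; defaults to
#'   all columns of [feature_names()] present in `data`.
#' @param k_max Maximum number of features to select (default 14).
#' @param tol Optional minimum RSS improvement; `NULL` (default) disables
#'   early stopping so exactly `k_max` features are selected.
#' @param standardize Z-score the candidate columns before selection
#'   (default `TRUE`). Selection order is scale-dependent only through
#'   numerical conditioning; RSS itself is invariant to column scaling.
#' @return An object of class `"shg_sfs"` with elements `selected` (ordered
#'   character vector) and `path` (tibble: `step`, `feature`, `rss`).
#'   `tidy()` returns the path.
#' @export
#' @examples
#' tab <- generate_feature_table(feature_spec(n_subjects = 40, seed = 1))
#' sel <- sfs_select(tab, k_max = 5)
#' tidy(sel)
sfs_select <- function(data, response = "stage",
                       features = intersect(feature_names(), names(data)),
                       k_max = 14, tol = NULL, standardize = TRUE) {
  if (!response %in% names(data)) abort("`response` column not found.")
  if (length(features) == 0) abort("No candidate features found in `data`.")
  y <- as.numeric(data[[response]])
  n <- length(y)
  if (n <= k_max) abort("Need more observations than `k_max`.")
  X <- as.matrix(data[features])
  if (!is.numeric(X)) abort("Feature columns must be numeric.")
  if (standardize) {
    s <- apply(X, 2, sd)
    s[s == 0] <- 1
    X <- scale(X, center = TRUE, scale = s)
  }

  selected <- character(0)
  path <- list()
  rss_prev <- sum((y - mean(y))^2)
  remaining <- features
  skipped <- character(0)
  for (step in seq_len(min(k_max, length(features)))) {
    rss_cand <- vapply(remaining, function(f) {
      rss_of_fit(cbind(1, X[, c(selected, f), drop = FALSE]), y)
    }, numeric(1))
    if (any(is.na(rss_cand))) {
      skipped <- union(skipped, remaining[is.na(rss_cand)])
      remaining <- remaining[!is.na(rss_cand)]
      rss_cand <- rss_cand[!is.na(rss_cand)]
    }
    if (length(rss_cand) == 0) break
    best <- which.min(rss_cand)
    if (!is.null(tol) && rss_prev - rss_cand[best] < tol) break
    selected <- c(selected, remaining[best])
    path[[step]] <- tibble(step = step, feature = remaining[best],
                           rss = unname(rss_cand[best]))
    rss_prev <- rss_cand[best]
    remaining <- setdiff(remaining, selected)
  }
  if (length(skipped) > 0) {
    warn(paste0("Skipped collinear candidate feature(s): ",
                paste(skipped, collapse = ", ")))
  }
  structure(
    list(selected = selected, path = dplyr::bind_rows(path),
         response = response, standardize = standardize),
    class = "shg_sfs"
  )
}

#' @export
tidy.shg_sfs <- function(x, ...) x$path

#' @export
print.shg_sfs <- function(x, ...) {
  cat("Sequential forward selection (", length(x$selected), " features)\n",
      sep = "")
  print(x$path)
  invisible(x)
}

#' Fit the SHG B-index linear model
#'
#' Ordinary least squares of `response` (Brunt stage) on the selected
#' collagen features, over all subjects. Predictions from the fitted model
#' are clamped below at 0 (see [predict_b_index()]).
#'
#' @param data Data frame holding the response and feature columns.
#' @param response Response column name (default `"stage"`).
#' @param features Character vector of feature names to fit on, e.g.
#'   `selected_feature_names()` or the `selected` element of [sfs_select()].
#' @return Object of class `"b_index_model"`: `intercept`, named
#'   `coefficients`, `features`, `n`, `rss`, `fitted` (clamped in-sample
#'   scores). Supports `predict()`, `tidy()`, `glance()`.
#' @export
#' @examples
#' tab <- generate_feature_table(feature_spec(n_subjects = 40, seed = 1))
#' fit <- fit_b_index(tab, features = selected_feature_names())
#' glance(fit)
fit_b_index <- function(data, response = "stage", features) {
  if (!response %in% names(data)) abort("`response` column not found.")
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    abort(paste0("Missing feature column(s): ", paste(missing, collapse = ", ")))
  }
  y <- as.numeric(data[[response]])
  n <- length(y)
  if (length(features) >= n) abort("Need fewer features than observations.")
  X <- cbind(`(Intercept)` = 1, as.matrix(data[features]))
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    abort("Singular design: selected features are collinear; drop one.")
  }
  cf <- fit$coefficients
  model <- structure(
    list(intercept = unname(cf[1]),
         coefficients = cf[-1],
         features = features,
         n = n,
         rss = sum(fit$residuals^2),
         tss = sum((y - mean(y))^2)),
    class = "b_index_model"
  )
  model$fitted <- predict_b_index(model, data)
  model
}

#' Predict SHG B-index scores
#'
#' Evaluates the linear model on new subjects and clamps negative scores to
#' 0. Scores are continuous fibrosis severities; they are not clamped above
#' and may exceed 4.
#'
#' @param model A [fit_b_index()] model.
#' @param newdata Data frame containing every selected feature column.
#' @return Numeric vector of nonnegative B-index scores.
#' @export
predict_b_index <- function(model, newdata) {
  stopifnot(inherits(model, "b_index_model"))
  missing <- setdiff(model$features, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("`newdata` lacks selected feature(s): ",
                 paste(missing, collapse = ", ")))
  }
  X <- as.matrix(newdata[model$features])
  raw <- drop(model$intercept + X %*% model$coefficients)
  pmax(raw, 0)
}

#' @export
predict.b_index_model <- function(object, newdata, ...) {
  predict_b_index(object, newdata)
}

#' @export
tidy.b_index_model <- function(x, ...) {
  tibble(term = c("(Intercept)", names(x$coefficients)),
         estimate = c(x$intercept, unname(x$coefficients)))
}

#' @export
glance.b_index_model <- function(x, ...) {
  tibble(n = x$n, k = length(x$coefficients), rss = x$rss,
         r.squared = 1 - x$rss / x$tss)
}

#' @export
print.b_index_model <- function(x, ...) {
  cat("SHG B-index model:", length(x$coefficients), "features, n =", x$n, "\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Serialize / restore a B-index model as JSON
#'
#' @param model A `b_index_model`.
#' @param path File path.
#' @return `write_b_index()` returns `path` invisibly; `read_b_index()`
#'   returns the restored model.
#' @export
write_b_index <- function(model, path) {
  stopifnot(inherits(model, "b_index_model"))
  obj <- list(intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              features = model$features, n = model$n)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_b_index
#' @export
read_b_index <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(intercept = obj$intercept,
         coefficients = unlist(obj$coefficients),
         features = obj$features,
         n = obj$n, rss = NA_real_, tss = NA_real_),
    class = "b_index_model"
  )
}

#' Leave-one-out cross-validated B-index scores
#'
#' For each subject, refits the B-index on the remaining subjects and
#' predicts the held-out one; repeated once per subject so every score is an
#' out-of-sample prediction. By default the feature set is fixed (selection
#' performed once, on the full table, before calling this); with
#' `reselect = TRUE` sequential forward selection is re-run inside every
#' fold, which is slower but leaks no selection information.
#'
#' @param data Data frame with response and feature columns.
#' @param response Response column name.
#' @param features Feature set to refit in each fold (ignored when
#'   `reselect = TRUE`).
#' @param reselect Re-run [sfs_select()] within each fold.
#' @param k_max,tol Passed to [sfs_select()] when `reselect = TRUE`.
#' @return Tibble with one row per subject, in input order: `stage` (the
#'   response), `b_index` (clamped LOOCV score). Folds with singular designs
#'   yield `NA` scores with a warning.
#' @export
#' @examples
#' tab <- generate_feature_table(feature_spec(n_subjects = 30, seed = 2))
#' cv <- loocv_b_index(tab, features = selected_feature_names())
#' head(cv)
loocv_b_index <- function(data, response = "stage", features = NULL,
                          reselect = FALSE, k_max = 14, tol = NULL) {
  n <- nrow(data)
  if (n < 3) abort("Need at least 3 subjects for leave-one-out validation.")
  if (is.null(features) && !reselect) {
    abort("Provide `features`, or set `reselect = TRUE`.")
  }
  scores <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    train <- data[-i, , drop = FALSE]
    feats <- if (reselect) {
      sfs_select(train, response = response, k_max = k_max, tol = tol)$selected
    } else {
      features
    }
    fit <- tryCatch(fit_b_index(train, response = response, features = feats),
                    error = function(e) NULL)
    if (is.null(fit)) next
    scores[i] <- predict_b_index(fit, data[i, , drop = FALSE])
  }
  if (anyNA(scores)) {
    warn(sprintf("%d leave-one-out fold(s) had singular designs; scores NA.",
                 sum(is.na(scores))))
  }
  out <- tibble(stage = as.numeric(data[[response]]), b_index = scores)
  if ("subject_id" %in% names(data)) {
    out <- dplyr::bind_cols(tibble(subject_id = data$subject_id), out)
  }
  out
}
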