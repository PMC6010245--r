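# Fast cohort-level feature-table simulator. Emulates the statistical shape
# of an extracted collagen feature table (n subjects x 100 named features plus
# a Brunt stage) without rendering images, so the selection / regression /
# diagnostic layers can be exercised at full cohort size in milliseconds.

default_informative_coefficients <- function() {
  setNames(
    c(0.30, -0.20, 0.25, 0.15, -0.10, 0.20, 0.10,
      -0.15, 0.20, 0.10, 0.15, -0.20, 0.25, 0.30),
    selected_feature_names()
  )
}

#' Specification for a synthetic collagen feature table
#'
#' Describes a cohort-level simulation: `n_subjects` Brunt stages drawn from
#' `stage_probabilities`, 14 informative feature columns carrying a linear
#' stage signal plus between-subject biological spread, and `n_nuisance`
#' stage-independent columns. The informative columns are constructed so that
#' `stage = intercept + X %*% informative_coefficients + e`, with
#' `e ~ N(0, noise_sd^2)`: at `noise_sd = 0` the linear identity is exact and
#' ordinary least squares recovers the generating coefficients.
#'
#' @param n_subjects Number of subjects (rows).
#' @param stage_probabilities Probabilities of Brunt stages 0-4; must sum
#'   to 1. Default is the observed NAFLD cohort distribution
#'   (22.9/30.1/8.4/16.9/21.7 percent).
#' @param informative_coefficients Named numeric vector of length 14 keyed by
#'   [selected_feature_names()]: the generating B-index coefficients.
#' @param intercept Generating intercept.
#' @param noise_sd Standard deviation of the measurement noise that breaks
#'   the exact linear stage identity; `>= 0`.
#' @param between_sd Standard deviation of the between-subject spread within
#'   each informative feature (always present; keeps the design full rank).
#' @param n_nuisance Number of stage-independent feature columns
#'   (default 86, for 100 columns in total).
#' @param seed Integer seed; fixed seed gives bit-identical tables.
#' @return A list of class `"feature_spec"`.
#' @export
feature_spec <- function(n_subjects = 83,
                         stage_probabilities = c(0.229, 0.301, 0.084, 0.169, 0.217),
                         informative_coefficients = default_informative_coefficients(),
                         intercept = 0.2,
                         noise_sd = 0.5,
                         between_sd = 1,
                         n_nuisance = 86,
                         seed = 1L) {
  if (n_subjects < 1) abort("`n_subjects` must be >= 1.")
  check_stage_probabilities(stage_probabilities)
  sel <- selected_feature_names()
  if (length(informative_coefficients) != length(sel) ||
      !setequal(names(informative_coefficients), sel)) {
    abort("`informative_coefficients` must be named by the 14 selected features.")
  }
  if (any(informative_coefficients == 0)) {
    abort("`informative_coefficients` must all be nonzero.")
  }
  if (noise_sd < 0 || between_sd < 0) abort("Noise sds must be >= 0.")
  if (length(sel) + n_nuisance != length(feature_names())) {
    abort("14 informative + `n_nuisance` columns must total 100.")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      stage_probabilities = stage_probabilities,
      informative_coefficients = informative_coefficients[sel],
      intercept = intercept,
      noise_sd = noise_sd,
      between_sd = between_sd,
      n_nuisance = as.integer(n_nuisance),
      seed = as.integer(seed)
    ),
    class = "feature_spec"
  )
}

check_stage_probabilities <- function(p) {
  if (length(p) != 5 || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort("`stage_probabilities` must be 5 nonnegative values summing to 1.")
  }
  invisible(p)
}

#' Simulate a subject-by-feature collagen table
#'
#' Draws Brunt stages and a 100-column feature table according to a
#' [feature_spec()]. Informative columns are linear in stage with Gaussian
#' between-subject spread; one informative column closes the linear identity
#' so that `stage - intercept - X %*% coefficients` is pure `N(0, noise_sd^2)`
#' measurement noise. Nuisance columns are independent standard normals.
#'
#' @param spec A [feature_spec()].
#' @return A tibble with columns `subject_id`, `stage`, and the 100 features
#'   of [feature_names()]; the generating coefficient vector and intercept
#'   are attached as attributes `"informative_coefficients"` and
#'   `"intercept"`.
#' @export
#' @examples
#' tab <- generate_feature_table(feature_spec(n_subjects = 20, seed = 3))
#' dim(tab)
generate_feature_table <- function(spec) {
  stopifnot(inherits(spec, "feature_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  sel <- names(spec$informative_coefficients)
  beta <- spec$informative_coefficients

  stage <- sample(0:4, n, replace = TRUE, prob = spec$stage_probabilities)

  # free informative columns: fixed per-feature slopes/offsets + subject spread
  k <- length(sel)
  slopes <- seq(0.4, 1.2, length.out = k - 1)
  offsets <- seq(-1, 1, length.out = k - 1)
  X <- matrix(0, n, k, dimnames = list(NULL, sel))
  for (j in seq_len(k - 1)) {
    X[, j] <- offsets[j] + slopes[j] * stage + rnorm(n, sd = spec$between_sd)
  }
  # closing column: makes stage = intercept + X beta exact up to noise_sd
  eps <- rnorm(n, sd = spec$noise_sd)
  X[, k] <- (stage + eps - spec$intercept -
               X[, -k, drop = FALSE] %*% beta[-k]) / beta[k]

  nuisance_names <- setdiff(feature_names(), sel)
  Z <- matrix(rnorm(n * spec$n_nuisance), n, spec$n_nuisance,
              dimnames = list(NULL, nuisance_names))

  out <- as_tibble(cbind(as.data.frame(X), as.data.frame(Z)))
  out <- out[, feature_names()]
  out <- dplyr::bind_cols(
    tibble(subject_id = sprintf("S%03d", seq_len(n)), stage = stage),
    out
  )
  attr(out, "informative_coefficients") <- beta
  attr(out, "intercept") <- spec$intercept
  out
}
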