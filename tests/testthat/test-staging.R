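# Sequential forward selection, the B-index fit, clamping and LOOCV.

test_that("selection finds a noiseless dominant feature first", {
  set.seed(1)
  df <- tibble::tibble(
    f1 = rnorm(40), f2 = rnorm(40), f3 = rnorm(40), f4 = rnorm(40),
    f5 = rnorm(40)
  )
  df$stage <- 2 * df$f3
  sel <- sfs_select(df, features = paste0("f", 1:5), k_max = 3)
  expect_identical(sel$selected[1], "f3")
  expect_lt(sel$path$rss[1], 1e-16)
})

test_that("selecting all features keeps the RSS trajectory non-increasing", {
  set.seed(2)
  df <- tibble::as_tibble(as.data.frame(matrix(rnorm(50 * 8), 50, 8)))
  names(df) <- paste0("f", 1:8)
  df$stage <- rnorm(50)
  sel <- sfs_select(df, features = paste0("f", 1:8), k_max = 8)
  expect_setequal(sel$selected, paste0("f", 1:8))
  expect_true(all(diff(sel$path$rss) <= 1e-10))
  expect_identical(tidy(sel), sel$path)
})

test_that("collinear candidates are skipped with a warning", {
  set.seed(3)
  df <- tibble::tibble(f1 = rnorm(30), stage = rnorm(30))
  df$f2 <- df$f1  # exact duplicate
  expect_warning(sel <- sfs_select(df, features = c("f1", "f2"), k_max = 2,
                                   standardize = FALSE), "collinear")
  expect_length(sel$selected, 1)
})

test_that("selection recovers informative features from synthetic tables", {
  hits <- sapply(1:10, function(s) {
    tab <- generate_feature_table(feature_spec(n_subjects = 83,
                                               noise_sd = 0.05, seed = s))
    sel <- suppressWarnings(sfs_select(tab, k_max = 14))
    sum(sel$selected %in% selected_feature_names())
  })
  expect_true(all(hits >= 12))
})

test_that("the B-index fit is exact OLS", {
  # exact line
  df <- tibble::tibble(x = c(0, 1, 2, 3, 4))
  df$stage <- 1 + 2 * df$x
  fit <- fit_b_index(df, features = "x")
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(unname(fit$coefficients["x"]), 2, tolerance = 1e-12)
  # row-permutation invariance
  set.seed(4)
  tab <- generate_feature_table(feature_spec(n_subjects = 30, seed = 5))
  f <- selected_feature_names()[1:4]
  fit1 <- fit_b_index(tab, features = f)
  fit2 <- fit_b_index(tab[sample.int(30), ], features = f)
  expect_equal(fit1$coefficients, fit2$coefficients, tolerance = 1e-10)
  # normal-equations oracle on a random 10 x 3 design
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(10)
  df2 <- tibble::as_tibble(as.data.frame(X)); df2$stage <- y
  fit3 <- fit_b_index(df2, features = c("a", "b", "c"))
  oracle <- ols_normal_equations(X, y)
  expect_lt(max(abs(c(fit3$intercept, fit3$coefficients) - oracle)), 1e-8)
  # residual orthogonality to the design
  resid <- y - (fit3$intercept + drop(X %*% fit3$coefficients))
  expect_lt(max(abs(crossprod(cbind(1, X), resid))), 1e-8)
  # singular design rejected
  df2$d <- df2$a
  expect_error(fit_b_index(df2, features = c("a", "b", "c", "d")),
               "Singular")
})

test_that("predictions clamp at zero and never above", {
  model <- structure(
    list(intercept = -0.3, coefficients = c(x = 1), features = "x",
         n = 10, rss = 0, tss = 1),
    class = "b_index_model")
  expect_equal(predict_b_index(model, tibble::tibble(x = 0)), 0)
  model$intercept <- 4.6
  expect_equal(predict_b_index(model, tibble::tibble(x = 0)), 4.6)
  expect_equal(predict_b_index(model, tibble::tibble(x = -10)), 0)
  expect_error(predict_b_index(model, tibble::tibble(z = 1)), "lacks")
})

test_that("B-index models round-trip through JSON", {
  tab <- generate_feature_table(feature_spec(n_subjects = 25, seed = 6))
  fit <- fit_b_index(tab, features = selected_feature_names()[1:5])
  path <- withr::local_tempfile(fileext = ".json")
  write_b_index(fit, path)
  back <- read_b_index(path)
  expect_equal(predict_b_index(back, tab), predict_b_index(fit, tab),
               tolerance = 1e-12)
  td <- tidy(fit)
  expect_identical(td$term[1], "(Intercept)")
  expect_equal(nrow(td), 6)
  expect_equal(glance(fit)$k, 5)
})

test_that("LOOCV equals the closed-form leverage oracle", {
  set.seed(7)
  for (k in 1:100) {
    n <- sample(10:20, 1)
    X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- drop(X %*% c(1, -0.5, 0.25)) + rnorm(n)
    df <- tibble::as_tibble(as.data.frame(X)); df$stage <- y
    cv <- loocv_b_index(df, features = c("a", "b", "c"))
    oracle <- pmax(loocv_hat_oracle(X, y), 0)
    expect_equal(cv$b_index, oracle, tolerance = 1e-8)
    expect_true(all(cv$b_index >= 0))
  }
})

test_that("LOOCV predictions ignore the held-out response", {
  tab <- generate_feature_table(feature_spec(n_subjects = 20, seed = 8))
  f <- selected_feature_names()[1:3]
  cv <- loocv_b_index(tab, features = f)
  expect_equal(nrow(cv), 20)
  tab2 <- tab
  tab2$stage[1] <- tab2$stage[1] + 100
  cv2 <- loocv_b_index(tab2, features = f)
  expect_equal(cv2$b_index[1], cv$b_index[1], tolerance = 1e-10)
  # a perfect linear response is recovered exactly
  lin <- tibble::tibble(x = seq(1, 4, length.out = 12))
  lin$stage <- lin$x
  cvl <- loocv_b_index(lin, features = "x")
  expect_equal(cvl$b_index, lin$stage, tolerance = 1e-8)
  # duplicated subjects get identical scores
  dup <- tab[c(1, 1, 2:10), ]
  cvd <- loocv_b_index(dup, features = f)
  expect_equal(cvd$b_index[1], cvd$b_index[2], tolerance = 1e-10)
  expect_error(loocv_b_index(tab[1:2, ], features = f), "at least 3")
  expect_error(loocv_b_index(tab), "reselect")
})

test_that("per-fold reselection produces a full score vector", {
  tab <- generate_feature_table(feature_spec(n_subjects = 24, seed = 9))
  cv <- suppressWarnings(loocv_b_index(tab, reselect = TRUE, k_max = 3))
  expect_equal(nrow(cv), 24)
  expect_true(all(is.finite(cv$b_index)))
})
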