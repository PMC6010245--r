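# Spearman, AUROC, Youden cutoffs, confusion metrics and the report.

test_that("spearman matches the rank-then-Pearson oracle", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1)
  expect_equal(spearman_rho(1:3, c(30, 20, 10)), -1)
  x <- c(1, 1, 2); y <- c(1, 2, 3)
  expect_equal(spearman_rho(x, y), cor(rank(x), rank(y)))
  set.seed(1)
  for (i in 1:20) {
    a <- sample(0:4, 15, replace = TRUE)
    b <- rnorm(15)
    expect_equal(spearman_rho(b, a),
                 suppressWarnings(cor(b, a, method = "spearman")))
  }
  expect_warning(r <- spearman_rho(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
  expect_error(spearman_rho(1:2, 1:3), "equal length")
})

test_that("AUROC equals brute-force pair counting", {
  expect_equal(auroc(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auc, 1)
  expect_equal(auroc(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  expect_equal(auroc(c(3, 1, 2, 4), c(0, 1, 0, 1))$auc, 0.5)
  set.seed(2)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    labels <- c(0, 0, 1, 1, sample(0:1, n - 4, replace = TRUE))
    scores <- sample(1:8, n, replace = TRUE)  # ties guaranteed
    a <- auroc(scores, labels)
    expect_equal(a$auc, auc_brute(scores, labels), tolerance = 1e-12)
    expect_lte(a$ci_low, a$auc + 1e-12)
    expect_gte(a$ci_high, a$auc - 1e-12)
  }
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "Both classes")
})

test_that("Youden cutoffs equal the exhaustive scan", {
  c0 <- youden_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(as.numeric(c0), 0.2)
  expect_equal(attr(c0, "youden"), 2)
  # anti-separated data still returns the J-maximizing cutoff
  anti <- youden_cutoff(c(0.9, 0.8, 0.1, 0.2), c(0, 0, 1, 1))
  expect_lte(attr(anti, "youden"), 2)
  set.seed(3)
  for (i in 1:100) {
    n <- sample(6:25, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n, 0, 4), 1)
    expect_equal(as.numeric(youden_cutoff(scores, labels)),
                 youden_brute(scores, labels), tolerance = 1e-12)
  }
})

test_that("diagnostic metrics follow the 2x2 definitions", {
  m <- diagnostic_metrics(tp = 28, fp = 1, fn = 4, tn = 50)
  expect_equal(m$sensitivity, 28 / 32)
  expect_equal(m$specificity, 50 / 51)
  expect_equal(m$ppv, 28 / 29)
  expect_equal(m$npv, 50 / 54)
  expect_equal(m$plr, m$sensitivity / (1 - m$specificity))
  expect_equal(m$nlr, (1 - m$sensitivity) / m$specificity)
  expect_equal(m$accuracy, 78 / 83)
  # symmetric table gives 0.5 / 0.5
  s <- diagnostic_metrics(tp = 5, fp = 7, fn = 5, tn = 7)
  expect_equal(s$sensitivity, 0.5)
  expect_equal(s$specificity, 0.5)
  # perfect specificity flags an infinite positive likelihood ratio
  expect_warning(inf <- diagnostic_metrics(tp = 5, fp = 0, fn = 1, tn = 10),
                 "infinite")
  expect_identical(inf$plr, Inf)
  expect_error(diagnostic_metrics(tp = 0, fp = 1, fn = 0, tn = 1), "margins")
  # PPV via Bayes from (sens, spec, prevalence) agrees exactly
  set.seed(4)
  for (i in 1:20) {
    tab <- as.list(1 + stats::rpois(4, 10))
    names(tab) <- c("tp", "fp", "fn", "tn")
    mm <- do.call(diagnostic_metrics, tab)
    n <- sum(unlist(tab))
    prev <- (tab$tp + tab$fn) / n
    bayes_ppv <- mm$sensitivity * prev /
      (mm$sensitivity * prev + (1 - mm$specificity) * (1 - prev))
    expect_equal(mm$ppv, bayes_ppv, tolerance = 1e-12)
  }
})

test_that("confusion tables respect the strict score > cutoff rule", {
  ct <- confusion_table(c(1, 2, 2, 3), c(0, 0, 1, 1), cutoff = 2)
  expect_equal(unlist(ct), c(tp = 1, fp = 0, fn = 1, tn = 2))
})

test_that("the staging report has one well-formed row per grouping", {
  g <- fibrosis_groupings()
  expect_equal(nrow(g), 4)
  expect_identical(g$stages, c("0 vs 1/2/3/4", "0/1 vs 2/3/4",
                               "0/1/2 vs 3/4", "0/1/2/3 vs 4"))
  tab <- generate_feature_table(feature_spec(n_subjects = 60, seed = 10))
  cv <- loocv_b_index(tab, features = selected_feature_names())
  # a well-separated cohort legitimately reaches specificity 1 (+LR Inf)
  rep <- suppressWarnings(staging_report(cv))
  expect_equal(nrow(rep), 4)
  expect_true(all(rep$estimable))
  # dichotomization conserves n
  for (i in seq_len(4)) {
    lab <- as.integer(cv$stage >= g$min_positive_stage[i])
    expect_equal(sum(lab) + sum(1 - lab), nrow(cv))
  }
  expect_true(all(rep$auroc >= 0 & rep$auroc <= 1))
  expect_true(is.numeric(attr(rep, "spearman")))
  # report round-trips through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(rep, path, row.names = FALSE)
  back <- read.csv(path)
  expect_equal(back$auroc, rep$auroc, tolerance = 1e-12)
  expect_equal(back$cutoff, rep$cutoff, tolerance = 1e-12)
})

test_that("degenerate cohorts yield non-estimable rows", {
  cv <- tibble::tibble(stage = rep(2, 12), b_index = runif(12))
  rep <- suppressWarnings(staging_report(cv))
  expect_true(all(!rep$estimable))
  expect_true(all(is.na(rep$auroc)))
})

test_that("report formatting mirrors percent/ratio conventions", {
  rep <- tibble::tibble(
    group = "bridging", stages = "0/1/2 vs 3/4", estimable = TRUE,
    auroc = 0.985, ci_low = 0.966, ci_high = 1, cutoff = 1.76,
    sensitivity = 0.875, specificity = 0.98, ppv = 0.9655, npv = 0.9259,
    plr = 43.75, nlr = 0.1276, accuracy = 0.94
  )
  f <- format_staging_report(rep)
  expect_identical(f$sens, "87.5%")
  expect_identical(f$plr, "43.75")
  md <- report_to_markdown(rep)
  expect_match(md[1], "^\\| group")
  expect_length(md, 3)
})

test_that("plot constructors return ggplot objects", {
  tab <- generate_feature_table(feature_spec(n_subjects = 40, seed = 11))
  cv <- loocv_b_index(tab, features = selected_feature_names())
  expect_s3_class(plot_stage_boxplot(cv), "ggplot")
  expect_s3_class(plot_roc_curves(cv), "ggplot")
})
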