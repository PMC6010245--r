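# Diagnostic-accuracy layer: correlation of the B-index with Brunt stage,
# AUROC per dichotomized fibrosis grouping, Youden-optimal cutoffs, and 2x2
# confusion metrics. A test call is positive iff score > cutoff (strict).

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks on ties).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`; `NA` with a warning when either vector
#'   is constant (undefined ranks spread).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    warn("Spearman correlation undefined for a constant vector; returning NA.")
    return(NA_real_)
  }
  cor(rank(x), rank(y), method = "pearson")
}

#' Area under the ROC curve with 95% confidence interval
#'
#' AUC computed as the Mann-Whitney U statistic divided by the number of
#' positive-negative pairs, with half credit for ties, via the mid-rank
#' formula. The 95% confidence interval is DeLong's (default) or stratified
#' bootstrap, delegated to \pkg{pROC}; bounds are truncated to `[0, 1]`.
#'
#' @param scores Numeric test scores (higher = more diseased).
#' @param labels Binary labels (0/1, logical, or two-level factor); both
#'   classes must be present.
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param boot_n Bootstrap replicates when `ci_method = "bootstrap"`.
#' @return One-row tibble: `auc`, `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#'   The DeLong variance is undefined when a class has a single
#'   observation; the bounds are then `NA`.
#' @export
#' @examples
#' auroc(c(0.1, 0.4, 0.8, 0.9), c(0, 0, 1, 1))
auroc <- function(scores, labels, ci_method = c("delong", "bootstrap"),
                  boot_n = 2000) {
  ci_method <- match.arg(ci_method)
  lab <- as_binary_labels(labels)
  if (length(scores) != length(lab)) abort("Length mismatch.")
  n_pos <- sum(lab == 1)
  n_neg <- sum(lab == 0)
  if (n_pos == 0 || n_neg == 0) {
    abort("Both classes must be present to compute an AUROC.")
  }
  r <- rank(scores)            # mid-ranks give ties half credit
  auc <- (sum(r[lab == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  roc <- pROC::roc(response = lab, predictor = as.numeric(scores),
                   levels = c(0, 1), direction = "<", quiet = TRUE)
  # pROC warns when AUC is exactly 1 (degenerate CI); bounds are truncated
  ci <- suppressWarnings(if (ci_method == "delong") {
    pROC::ci.auc(roc, method = "delong")
  } else {
    pROC::ci.auc(roc, method = "bootstrap", boot.n = boot_n, progress = "none")
  })
  tibble(auc = auc,
         ci_low = max(0, as.numeric(ci)[1]),
         ci_high = min(1, as.numeric(ci)[3]),
         n_pos = n_pos, n_neg = n_neg)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) {
    if (nlevels(labels) > 2) abort("Labels must be binary.")
    return(as.integer(labels) - 1L)
  }
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1))) abort("Labels must be 0/1, logical, or 2-level factor.")
  as.integer(labels)
}

#' Youden-optimal cutoff
#'
#' Scans every observed score value `c` as a candidate cutoff, calling
#' positive when `score > c`, and returns the candidate maximizing Youden's
#' J = sensitivity + specificity - 1. Ties are broken toward the smallest
#' cutoff.
#'
#' @inheritParams auroc
#' @return The cutoff (double) with attribute `"youden"` holding max
#'   sensitivity + specificity.
#' @export
#' @examples
#' youden_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
youden_cutoff <- function(scores, labels) {
  lab <- as_binary_labels(labels)
  if (sum(lab == 1) == 0 || sum(lab == 0) == 0) {
    abort("Both classes must be present to choose a cutoff.")
  }
  cand <- sort(unique(as.numeric(scores)))
  pos <- scores[lab == 1]
  neg <- scores[lab == 0]
  sens <- vapply(cand, function(c) mean(pos > c), numeric(1))
  spec <- vapply(cand, function(c) mean(neg <= c), numeric(1))
  j <- sens + spec
  # ties (within float tolerance) break toward the smallest cutoff
  best <- which(j >= max(j) - 1e-9)[1]
  structure(cand[best], youden = j[best])
}

#' Confusion table at a cutoff
#'
#' @inheritParams auroc
#' @param cutoff Score cutoff; positive call iff `score > cutoff`.
#' @return One-row tibble: `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_table <- function(scores, labels, cutoff) {
  lab <- as_binary_labels(labels)
  call_pos <- scores > cutoff
  tibble(tp = sum(call_pos & lab == 1),
         fp = sum(call_pos & lab == 0),
         fn = sum(!call_pos & lab == 1),
         tn = sum(!call_pos & lab == 0))
}

#' Diagnostic metrics from a 2x2 confusion table
#'
#' Sensitivity, specificity, predictive values, likelihood ratios and
#' accuracy from true/false positive/negative counts. When specificity is 1
#' the positive likelihood ratio is infinite and a warning flags it; the
#' symmetric case holds for the negative likelihood ratio at sensitivity 1
#' with specificity 0 handled analogously.
#'
#' @param tp,fp,fn,tn Nonnegative counts; alternatively pass a one-row data
#'   frame with those columns as `tp`.
#' @return One-row tibble: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `plr`, `nlr`, `accuracy`.
#' @export
#' @examples
#' diagnostic_metrics(tp = 28, fp = 1, fn = 4, tn = 50)
diagnostic_metrics <- function(tp, fp = NULL, fn = NULL, tn = NULL) {
  if (is.data.frame(tp)) {
    tab <- tp
    tp <- tab$tp; fp <- tab$fp; fn <- tab$fn; tn <- tab$tn
  }
  counts <- c(tp, fp, fn, tn)
  if (length(counts) != 4 || any(counts < 0)) abort("Need 4 nonnegative counts.")
  if (tp + fn == 0 || tn + fp == 0) abort("Both margins must be positive.")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  if (spec == 1) {
    warn("Specificity is 1: positive likelihood ratio is infinite.")
    plr <- Inf
  } else {
    plr <- sens / (1 - spec)
  }
  nlr <- if (spec == 0) {
    warn("Specificity is 0: negative likelihood ratio is undefined (NaN).")
    NaN
  } else {
    (1 - sens) / spec
  }
  tibble(sensitivity = sens, specificity = spec,
         ppv = if (tp + fp > 0) tp / (tp + fp) else NaN,
         npv = if (tn + fn > 0) tn / (tn + fn) else NaN,
         plr = plr, nlr = nlr,
         accuracy = (tp + tn) / sum(counts))
}

#' Likelihood ratios from sensitivity and specificity
#'
#' `+LR = sens / (1 - spec)` and `-LR = (1 - sens) / spec`, useful for
#' recomputing likelihood ratios from reported (possibly rounded)
#' sensitivity and specificity.
#'
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @return One-row tibble: `plr`, `nlr`.
#' @export
#' @examples
#' likelihood_ratios(0.875, 0.98)
likelihood_ratios <- function(sensitivity, specificity) {
  if (any(c(sensitivity, specificity) < 0 | c(sensitivity, specificity) > 1)) {
    abort("Sensitivity and specificity must be proportions in [0, 1].")
  }
  tibble(
    plr = ifelse(specificity == 1, Inf, sensitivity / (1 - specificity)),
    nlr = ifelse(specificity == 0, NaN, (1 - sensitivity) / specificity)
  )
}

#' The four Brunt-stage dichotomizations
#'
#' The standard NAFLD fibrosis groupings: mild fibrosis (stage 0 vs 1-4),
#' significant fibrosis (0-1 vs 2-4), bridging fibrosis (0-2 vs 3-4) and
#' cirrhosis (0-3 vs 4). A subject is positive when its Brunt stage is at
#' least `min_positive_stage`.
#'
#' @return Tibble: `group`, `stages`, `min_positive_stage`.
#' @export
fibrosis_groupings <- function() {
  tibble(
    group = c("mild", "significant", "bridging", "cirrhosis"),
    stages = c("0 vs 1/2/3/4", "0/1 vs 2/3/4", "0/1/2 vs 3/4", "0/1/2/3 vs 4"),
    min_positive_stage = c(1L, 2L, 3L, 4L)
  )
}

#' Per-grouping AUROC, Youden cutoff and diagnostic metrics
#'
#' For each Brunt dichotomization, computes the AUROC of the B-index with a
#' 95% confidence interval, the Youden-optimal cutoff, and the diagnostic
#' metrics of the strict `b_index > cutoff` call. With cross-validated
#' scores this reproduces the layout of a leave-one-out validation table.
#' Groupings with an empty class are returned with `estimable = FALSE` and
#' `NA` statistics.
#'
#' @param data Data frame with a score column and a Brunt stage column.
#' @param score,stage Column names (defaults `"b_index"`, `"stage"`).
#' @param groupings Tibble as from [fibrosis_groupings()].
#' @param cutoffs Optional numeric vector (one per grouping) of fixed
#'   cutoffs; default `NULL` chooses each by Youden's index.
#' @return Tibble with one row per grouping: AUROC with CI, cutoff, and the
#'   [diagnostic_metrics()] columns, plus `spearman_rho` attached as
#'   attribute `"spearman"`.
#' @export
#' @examples
#' tab <- generate_feature_table(feature_spec(n_subjects = 60, seed = 4))
#' cv <- loocv_b_index(tab, features = selected_feature_names())
#' staging_report(cv)
staging_report <- function(data, score = "b_index", stage = "stage",
                           groupings = fibrosis_groupings(), cutoffs = NULL) {
  s <- as.numeric(data[[score]])
  st <- as.numeric(data[[stage]])
  keep <- !is.na(s) & !is.na(st)
  s <- s[keep]; st <- st[keep]
  if (length(s) < 3) abort("Need at least 3 scored subjects.")
  if (!is.null(cutoffs) && length(cutoffs) != nrow(groupings)) {
    abort("`cutoffs` must have one value per grouping.")
  }
  rows <- purrr::pmap(
    list(groupings$group, groupings$stages, groupings$min_positive_stage,
         seq_len(nrow(groupings))),
    function(group, stages, min_pos, idx) {
      lab <- as.integer(st >= min_pos)
      if (sum(lab) == 0 || sum(lab) == length(lab)) {
        return(tibble(group = group, stages = stages, estimable = FALSE,
                      auroc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      cutoff = NA_real_, sensitivity = NA_real_,
                      specificity = NA_real_, ppv = NA_real_, npv = NA_real_,
                      plr = NA_real_, nlr = NA_real_, accuracy = NA_real_))
      }
      a <- auroc(s, lab)
      cut <- if (is.null(cutoffs)) as.numeric(youden_cutoff(s, lab)) else cutoffs[idx]
      m <- diagnostic_metrics(confusion_table(s, lab, cut))
      dplyr::bind_cols(
        tibble(group = group, stages = stages, estimable = TRUE,
               auroc = a$auc, ci_low = a$ci_low, ci_high = a$ci_high,
               cutoff = cut),
        m
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  attr(out, "spearman") <- if (sd(st) > 0) spearman_rho(s, st) else NA_real_
  out
}

#' Format a staging report for export
#'
#' Percentages to one decimal place and likelihood ratios to two, matching
#' conventional diagnostic-table formatting; full precision is retained in
#' the unformatted report.
#'
#' @param report Output of [staging_report()].
#' @return Tibble of character columns.
#' @export
format_staging_report <- function(report) {
  pct <- function(x) ifelse(is.na(x), "-", sprintf("%.1f%%", 100 * x))
  lr <- function(x) ifelse(is.na(x), "-",
                           ifelse(is.infinite(x), "Inf", sprintf("%.2f", x)))
  tibble(
    group = report$group,
    stages = report$stages,
    auroc = ifelse(is.na(report$auroc), "-", sprintf("%.3f", report$auroc)),
    ci_95 = ifelse(is.na(report$auroc), "-",
                   sprintf("%.3f-%.3f", report$ci_low, report$ci_high)),
    cutoff = ifelse(is.na(report$cutoff), "-", sprintf("%.2f", report$cutoff)),
    sens = pct(report$sensitivity), spec = pct(report$specificity),
    plr = lr(report$plr), nlr = lr(report$nlr),
    ppv = pct(report$ppv), npv = pct(report$npv)
  )
}

#' Render a staging report as a Markdown table
#'
#' @param report Output of [staging_report()].
#' @param path Optional file to write to.
#' @return Character vector of Markdown lines (invisibly when written).
#' @export
report_to_markdown <- function(report, path = NULL) {
  f <- format_staging_report(report)
  header <- paste0("| ", paste(names(f), collapse = " | "), " |")
  rule <- paste0("|", paste(rep("---", ncol(f)), collapse = "|"), "|")
  body <- apply(f, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  lines <- c(header, rule, body)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Boxplot of B-index by Brunt stage
#'
#' @param data Data frame with score and stage columns.
#' @param score,stage Column names.
#' @return A ggplot object.
#' @export
plot_stage_boxplot <- function(data, score = "b_index", stage = "stage") {
  ggplot2::ggplot(data, ggplot2::aes(x = factor(.data[[stage]]),
                                     y = .data[[score]])) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::labs(x = "Brunt fibrosis stage", y = "SHG B-index") +
    ggplot2::theme_minimal()
}

#' ROC curves of the B-index for each fibrosis grouping
#'
#' @inheritParams staging_report
#' @return A ggplot object with one ROC curve per estimable grouping.
#' @export
plot_roc_curves <- function(data, score = "b_index", stage = "stage",
                            groupings = fibrosis_groupings()) {
  s <- as.numeric(data[[score]])
  st <- as.numeric(data[[stage]])
  curves <- purrr::pmap(
    list(groupings$group, groupings$min_positive_stage),
    function(group, min_pos) {
      lab <- as.integer(st >= min_pos)
      if (sum(lab) == 0 || sum(lab) == length(lab)) return(NULL)
      cand <- c(-Inf, sort(unique(s)))
      tibble(
        group = group,
        fpr = vapply(cand, function(c) mean(s[lab == 0] > c), numeric(1)),
        tpr = vapply(cand, function(c) mean(s[lab == 1] > c), numeric(1))
      )
    }
  )
  df <- dplyr::bind_rows(curves)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr,
                                   colour = .data$group)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL) +
    ggplot2::theme_minimal()
}
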