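feature_columns <- function(df) {
  setdiff(names(df), c("id", "label", "split"))
}

#' Zero-mean, unit-variance feature standardization
#'
#' Fits per-feature center and scale (population SD) on the training
#' rows only and applies them to every row, so test rows are transformed
#' with training parameters. With no `split` column all rows are
#' training rows.
#'
#' @param table data.frame with `label` (and optionally `id`, `split`
#'   with values `"train"`/`"test"`) plus numeric feature columns.
#' @return The table with standardized feature columns; the fitted
#'   scaler is attached as `attr(, "scaler")` (list of `center`,
#'   `scale`).
#' @export
standardize <- function(table) {
  feats <- feature_columns(table)
  train <- if ("split" %in% names(table)) table$split == "train"
           else rep(TRUE, nrow(table))
  if (sum(train) < 2) stop("standardize: fewer than 2 training rows")
  center <- scale_ <- stats::setNames(numeric(length(feats)), feats)
  for (f in feats) {
    x <- table[[f]][train]
    if (anyNA(x)) stop(sprintf("standardize: missing values in '%s'", f))
    center[f] <- mean(x)
    scale_[f] <- sqrt(mean((x - center[f])^2))
    if (scale_[f] < 1e-12)
      stop(sprintf("standardize: zero-variance training feature '%s'", f))
    table[[f]] <- (table[[f]] - center[f]) / scale_[f]
  }
  attr(table, "scaler") <- list(center = center, scale = scale_)
  table
}

kde_overlap <- function(x_b, x_m, n_grid = 512) {
  pooled <- c(x_b, x_m)
  bw <- stats::bw.nrd0(pooled)
  lo <- min(pooled) - 3 * bw; hi <- max(pooled) + 3 * bw
  fb <- stats::density(x_b, bw = bw, from = lo, to = hi, n = n_grid)
  fm <- stats::density(x_m, bw = bw, from = lo, to = hi, n = n_grid)
  dx <- fb$x[2] - fb$x[1]
  sum(pmin(fb$y, fm$y)) * dx
}

#' Three-step univariate feature selection
#'
#' Step 1: two-sided Welch t test per feature between the benign and
#' malignant training rows; keep `p < p_thresh`. Step 2: among pairs
#' with `|Pearson r| > r_thresh` keep only the member with the smaller p
#' value (ties broken by name). Step 3: estimate per-class densities
#' (Gaussian KDE, Silverman bandwidth on the pooled sample, shared
#' 512-point grid) and keep features whose density overlap area is below
#' `overlap_thresh`.
#'
#' @param table feature data.frame (training rows are used when a
#'   `split` column is present).
#' @param p_thresh,r_thresh,overlap_thresh the three thresholds.
#' @return List: `retained` (character), `diagnostics` data.frame with
#'   per-feature p value, dropped-at step, correlated partner and
#'   overlap area.
#' @export
select_features <- function(table, p_thresh = 0.01, r_thresh = 0.85,
                            overlap_thresh = 0.75) {
  feats <- feature_columns(table)
  rows <- if ("split" %in% names(table)) table$split == "train"
          else rep(TRUE, nrow(table))
  df <- table[rows, , drop = FALSE]
  lab <- df$label
  if (length(unique(lab)) < 2)
    stop("select_features: both classes must be present")
  mal <- lab == "malignant"
  pv <- vapply(feats, function(f) {
    stats::t.test(df[[f]][mal], df[[f]][!mal])$p.value
  }, 1)
  diag_df <- data.frame(feature = feats, p_value = pv,
                        dropped_at = NA_character_,
                        partner = NA_character_, overlap = NA_real_,
                        stringsAsFactors = FALSE, row.names = NULL)
  keep1 <- feats[pv < p_thresh]
  diag_df$dropped_at[!feats %in% keep1] <- "t_test"
  # step 2: greedy dedup in order of increasing p (then name)
  ord <- keep1[order(pv[keep1], keep1)]
  kept2 <- character(0)
  for (f in ord) {
    partner <- NULL
    for (g in kept2) {
      r <- stats::cor(df[[f]], df[[g]])
      if (is.finite(r) && abs(r) > r_thresh) { partner <- g; break }
    }
    if (is.null(partner)) kept2 <- c(kept2, f)
    else {
      diag_df$dropped_at[diag_df$feature == f] <- "correlation"
      diag_df$partner[diag_df$feature == f] <- partner
    }
  }
  # step 3: per-class density overlap
  retained <- character(0)
  for (f in kept2) {
    ov <- kde_overlap(df[[f]][!mal], df[[f]][mal])
    diag_df$overlap[diag_df$feature == f] <- ov
    if (ov < overlap_thresh) retained <- c(retained, f)
    else diag_df$dropped_at[diag_df$feature == f] <- "overlap"
  }
  list(retained = feats[feats %in% retained], diagnostics = diag_df)
}

auc_rank <- function(pom, positive) {
  r <- rank(pom)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) stop("auc: both classes required")
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Empirical ROC, AUC and sensitivity-constrained threshold
#'
#' Sweeps all distinct probability-of-malignancy values as thresholds
#' (predict malignant when `pom >= threshold`), computes the empirical
#' ROC and its AUC (rank/Mann-Whitney form, tie-aware), and picks the
#' operating point as the largest threshold whose sensitivity is at
#' least `min_sensitivity`.
#'
#' @param pom numeric probabilities in `[0, 1]`.
#' @param labels class labels; `"malignant"` (or `TRUE`/1) is positive.
#' @param min_sensitivity required sensitivity at the operating point.
#' @return List: `roc` (threshold/sensitivity/specificity), `auc`,
#'   `threshold`, `sensitivity`, `specificity`, `counts`
#'   (tp, fn, tn, fp at the threshold).
#' @export
roc_and_threshold <- function(pom, labels, min_sensitivity = 0.95) {
  positive <- if (is.character(labels) || is.factor(labels))
    as.character(labels) == "malignant" else as.logical(labels)
  if (length(unique(positive)) < 2)
    stop("roc_and_threshold: both classes must be present")
  thr <- sort(unique(c(0, pom)), decreasing = FALSE)
  sens <- vapply(thr, function(t) mean(pom[positive] >= t), 1)
  spec <- vapply(thr, function(t) mean(pom[!positive] < t), 1)
  auc <- auc_rank(pom, positive)
  ok <- which(sens >= min_sensitivity)
  t_star <- max(thr[ok])
  pred <- pom >= t_star
  counts <- c(tp = sum(pred & positive), fn = sum(!pred & positive),
              tn = sum(!pred & !positive), fp = sum(pred & !positive))
  list(roc = data.frame(threshold = thr, sensitivity = sens,
                        specificity = spec),
       auc = auc, threshold = t_star,
       sensitivity = sens[thr == t_star], specificity = spec[thr == t_star],
       counts = counts)
}

#' Permutation feature importance
#'
#' Mean drop in test AUC when a feature column is randomly permuted
#' (seeded), repeated `n_repeats` times per feature.
#'
#' @param model a fitted [train_cnn()] model.
#' @param table standardized feature table (rows to evaluate on).
#' @param n_repeats permutations per feature.
#' @param seed RNG seed.
#' @param permutations optional list of fixed index vectors to use
#'   instead of random permutations (one AUC per entry, applied to every
#'   feature) - used for reproducibility checks.
#' @return data.frame: feature, `delta_auc`.
#' @export
permutation_importance <- function(model, table, n_repeats = 10,
                                   seed = 1L, permutations = NULL) {
  feats <- model$features
  positive <- table$label == "malignant"
  base <- auc_rank(predict(model, table), positive)
  set.seed(seed)
  res <- vapply(feats, function(f) {
    perms <- permutations %||% replicate(n_repeats,
                                         sample.int(nrow(table)),
                                         simplify = FALSE)
    drops <- vapply(perms, function(pm) {
      tb <- table
      tb[[f]] <- tb[[f]][pm]
      base - auc_rank(predict(model, tb), positive)
    }, 1)
    mean(drops)
  }, 1)
  data.frame(feature = feats, delta_auc = unname(res),
             stringsAsFactors = FALSE)
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' Two-sided interval from the beta-quantile closed form of the binomial
#' tail inversion; lower bound 0 at `x = 0`, upper bound 1 at `x = n`.
#'
#' @param x successes, `n` trials, `level` confidence level.
#' @return `c(lower, upper)` proportions.
#' @export
clopper_pearson <- function(x, n, level = 0.99) {
  a <- (1 - level) / 2
  c(lower = if (x == 0) 0 else stats::qbeta(a, x, n - x + 1),
    upper = if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x))
}

#' Sensitivity and specificity with exact confidence intervals
#'
#' Computes sensitivity `tp/(tp+fn)` and specificity `tn/(tn+fp)` from a
#' confusion table with exact two-sided Clopper-Pearson intervals, and
#' reports percentages to one decimal.
#'
#' @param counts named vector or list with `tp`, `fn`, `tn`, `fp`.
#' @param level confidence level (default 0.99).
#' @return A `confusion_stats` object (proportions, intervals, and
#'   percentage fields rounded to 0.1).
#' @export
confusion_interval_stats <- function(counts, level = 0.99) {
  counts <- as.list(counts)
  tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  if (any(c(tp, fn, tn, fp) < 0)) stop("confusion: negative counts")
  if (tp + fn == 0 || tn + fp == 0)
    stop("confusion: zero positives or negatives")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  ci_sens <- clopper_pearson(tp, tp + fn, level)
  ci_spec <- clopper_pearson(tn, tn + fp, level)
  structure(list(
    counts = c(tp = tp, fn = fn, tn = tn, fp = fp), level = level,
    sensitivity = sens, specificity = spec,
    sensitivity_ci = ci_sens, specificity_ci = ci_spec,
    sensitivity_pct = round(100 * sens, 1),
    specificity_pct = round(100 * spec, 1),
    sensitivity_ci_pct = round(100 * ci_sens, 1),
    specificity_ci_pct = round(100 * ci_spec, 1)
  ), class = "confusion_stats")
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf("Sensitivity %.1f%% [%d of %d; %d%% CI, %.1f to %.1f%%]\n",
              x$sensitivity_pct, x$counts["tp"],
              x$counts["tp"] + x$counts["fn"], round(100 * x$level),
              x$sensitivity_ci_pct[1], x$sensitivity_ci_pct[2]))
  cat(sprintf("Specificity %.1f%% [%d of %d; %d%% CI, %.1f to %.1f%%]\n",
              x$specificity_pct, x$counts["tn"],
              x$counts["tn"] + x$counts["fp"], round(100 * x$level),
              x$specificity_ci_pct[1], x$specificity_ci_pct[2]))
  invisible(x)
}

#' Exact McNemar test on discordant pairs
#'
#' Compares two paired classifiers (e.g. specificities on the same
#' masses) by an exact binomial test on the discordant-pair counts.
#'
#' @param n01 pairs correct only under the first classifier.
#' @param n10 pairs correct only under the second.
#' @return p value.
#' @export
exact_mcnemar <- function(n01, n10) {
  if (n01 + n10 == 0) return(1)
  stats::binom.test(n01, n01 + n10, 0.5)$p.value
}
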