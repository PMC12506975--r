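test_that("standardization uses the training scaler with population SD", {
  df <- data.frame(id = 1:3, label = c("benign", "benign", "malignant"),
                   f = c(1, 2, 3))
  out <- standardize(df)
  expect_equal(out$f, c(-1, 0, 1) / sqrt(2 / 3), tolerance = 1e-9)
  # idempotence on already-standardized data
  again <- standardize(out)
  expect_equal(again$f, out$f, tolerance = 1e-9)

  # test rows use the training parameters only
  df2 <- data.frame(id = 1:4, label = c("benign", "malignant", "benign",
                                        "malignant"),
                    split = c("train", "train", "test", "test"),
                    f = c(1, 3, 2, 10))
  out2 <- standardize(df2)
  expect_equal(out2$f[3], 0)  # equals the training mean
  expect_equal(out2$f[4], (10 - 2) / 1, tolerance = 1e-9)

  dfz <- data.frame(id = 1:4, label = rep(c("a", "b"), 2), f = rep(2, 4))
  expect_error(standardize(dfz), "zero-variance.*'f'")
})

test_that("feature selection drops null, duplicated and overlapping features", {
  set.seed(10)
  n <- 200
  lab <- rep(c("benign", "malignant"), each = n / 2)
  inform <- stats::rnorm(n) + 3 * (lab == "malignant")
  df <- data.frame(
    id = seq_len(n), label = lab,
    informative = inform,
    duplicate = inform,               # |r| = 1 > 0.85
    null_feat = stats::rnorm(n),      # identical class distributions
    weak = stats::rnorm(n) + 0.1 * (lab == "malignant"))
  sel <- select_features(df)
  expect_true("informative" %in% sel$retained ||
                "duplicate" %in% sel$retained)
  expect_length(intersect(c("informative", "duplicate"), sel$retained), 1)
  d <- sel$diagnostics
  expect_equal(d$dropped_at[d$feature == "null_feat"], "t_test")
  # the twin not retained is dropped at the correlation step, naming the
  # retained member as its partner (p ties break by name)
  kept <- intersect(c("informative", "duplicate"), sel$retained)
  dropped <- setdiff(c("informative", "duplicate"), kept)
  expect_equal(d$dropped_at[d$feature == dropped], "correlation")
  expect_equal(d$partner[d$feature == dropped], kept)
  # N(0,1) vs N(3,1) has ~13% density overlap, well below 75%
  ov <- d$overlap[d$feature %in% c("informative", "duplicate")]
  ov <- ov[!is.na(ov)]
  expect_lt(ov, 0.25)
  expect_gt(ov, 0.05)
})

test_that("feature selection is stable under column permutation", {
  df <- sep_cohort(n = 120, k = 6, split = FALSE)
  sel1 <- select_features(df)
  perm <- df[, c("id", "label", paste0("f", c(4, 2, 6, 1, 3, 5)))]
  sel2 <- select_features(perm)
  expect_setequal(sel1$retained, sel2$retained)
})

test_that("the CNN learns a separable cohort and is seed-deterministic", {
  df <- standardize(sep_cohort(n = 80, seed = 3))
  m1 <- train_cnn(df, paste0("f", 1:6), list(epochs = 150), seed = 5)
  m2 <- train_cnn(df, paste0("f", 1:6), list(epochs = 150), seed = 5)
  expect_identical(m1$params, m2$params)
  train_rows <- df[df$split == "train", ]
  pom <- predict(m1, train_rows)
  expect_gte(duotomo:::auc_rank(pom, train_rows$label == "malignant"), 0.99)
  # loss decreases on a solvable problem
  expect_lt(mean(tail(m1$loss, 10)), mean(head(m1$loss, 10)))
  # class-conditional POM ordering on held-out rows
  test_rows <- df[df$split == "test", ]
  pom_t <- predict(m1, test_rows)
  expect_gt(mean(pom_t[test_rows$label == "malignant"]),
            mean(pom_t[test_rows$label == "benign"]))

  single <- df[df$label == "benign", ]
  expect_error(train_cnn(single, paste0("f", 1:6)), "both classes")
})

test_that("POM predictions are bounded, batch-invariant and row-stable", {
  df <- standardize(sep_cohort(n = 40, seed = 7))
  m <- train_cnn(df, paste0("f", 1:6), list(epochs = 30), seed = 2)
  set.seed(11)
  wild <- df[sample(nrow(df), 200, replace = TRUE), ]
  for (j in paste0("f", 1:6)) wild[[j]] <- stats::rnorm(200, 0, 10)
  pom <- predict(m, wild)
  expect_true(all(pom >= 0 & pom <= 1))
  # duplicated row gets an identical POM; order does not matter
  two <- df[c(1, 1), ]
  expect_equal(predict(m, two)[1], predict(m, two)[2])
  ord <- sample(nrow(df))
  expect_equal(predict(m, df)[ord], predict(m, df[ord, ]), tolerance = 1e-12)
  expect_error(predict(m, df[, 1:3]), "feature-set mismatch")
})

test_that("labels carry no signal after permutation (null behavior)", {
  set.seed(21)
  df <- sep_cohort(n = 120, seed = 21, split = FALSE)
  df$label <- sample(df$label)
  df$split <- duotomo:::split_cohort(df$label, 0.5, 21)
  dfs <- standardize(df)
  m <- train_cnn(dfs, paste0("f", 1:6), list(epochs = 100), seed = 3)
  test_rows <- dfs[dfs$split == "test", ]
  auc <- duotomo:::auc_rank(predict(m, test_rows),
                            test_rows$label == "malignant")
  expect_lt(abs(auc - 0.5), 0.15)
})

test_that("ROC analysis matches the rank-statistic oracle and is monotone", {
  set.seed(12)
  lab <- rep(c("benign", "malignant"), each = 30)
  pom <- stats::runif(60) + 0.4 * (lab == "malignant")
  pom <- pmin(pom, 1)
  r <- roc_and_threshold(pom, lab)
  u <- suppressWarnings(stats::wilcox.test(
    pom[lab == "malignant"], pom[lab == "benign"]))$statistic
  expect_equal(r$auc, unname(u) / (30 * 30), tolerance = 1e-12)
  # ROC curve is monotone
  expect_true(all(diff(r$roc$sensitivity) <= 1e-12))
  expect_true(all(diff(r$roc$specificity) >= -1e-12))
  # AUC invariant under strictly increasing transforms
  r2 <- roc_and_threshold(stats::plogis(5 * pom), lab)
  expect_equal(r2$auc, r$auc, tolerance = 1e-12)
  # threshold achieves the sensitivity floor
  expect_gte(r$sensitivity, 0.95)
  expect_equal(sum(r$counts), 60)

  perfect <- roc_and_threshold(c(rep(0.1, 20), rep(0.9, 20)),
                               rep(c("benign", "malignant"), each = 20))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$specificity, 1)
  set.seed(13)
  noise <- roc_and_threshold(stats::runif(400),
                             sample(rep(c("benign", "malignant"), 200)))
  expect_lt(abs(noise$auc - 0.5), 0.1)
  expect_error(roc_and_threshold(stats::runif(5), rep("benign", 5)),
               "both classes")
})

test_that("permutation importance isolates the informative feature", {
  set.seed(14)
  n <- 120
  lab <- rep(c("benign", "malignant"), each = n / 2)
  df <- data.frame(id = seq_len(n), label = lab,
                   signal = stats::rnorm(n) + 3 * (lab == "malignant"),
                   noise = stats::rnorm(n))
  df$split <- rep("train", n)
  dfs <- standardize(df)
  m <- train_cnn(dfs, c("signal", "noise"), list(epochs = 120), seed = 4)
  imp <- permutation_importance(m, dfs, n_repeats = 10, seed = 9)
  expect_gt(imp$delta_auc[imp$feature == "signal"],
            imp$delta_auc[imp$feature == "noise"])
  expect_lt(abs(imp$delta_auc[imp$feature == "noise"]), 0.05)
  # identity permutation changes nothing, exactly
  imp0 <- permutation_importance(m, dfs,
                                 permutations = list(seq_len(n)))
  expect_true(all(imp0$delta_auc == 0))
})

test_that("exact binomial intervals agree with tail-equation bisection", {
  for (case in list(c(43, 44), c(30, 40), c(9, 40), c(0, 17), c(17, 17),
                    c(5, 123))) {
    x <- case[1]; n <- case[2]
    cp <- clopper_pearson(x, n, 0.99)
    bi <- cp_bisect(x, n, 0.99)
    expect_equal(unname(cp), unname(bi), tolerance = 1e-10)
  }
  expect_equal(clopper_pearson(17, 17, 0.99)[["upper"]], 1)
  expect_equal(clopper_pearson(0, 17, 0.99)[["lower"]], 0)
})

test_that("confusion statistics print the clinical operating points", {
  s <- confusion_interval_stats(list(tp = 43, fn = 1, tn = 30, fp = 10),
                                level = 0.99)
  expect_equal(s$sensitivity_pct, 97.7)
  expect_equal(s$sensitivity_ci_pct[[1]], 84.3)
  expect_equal(s$specificity_pct, 75.0)
  expect_equal(unname(s$specificity_ci_pct), c(53.9, 90.0))
  expect_error(confusion_interval_stats(list(tp = 0, fn = 0, tn = 3, fp = 1)),
               "zero positives")
})

test_that("99% intervals cover the truth in at least 98% of simulations", {
  set.seed(2024)
  n <- 40; p <- 0.75; n_sim <- 2000
  x <- stats::rbinom(n_sim, n, p)
  covered <- vapply(x, function(xi) {
    ci <- clopper_pearson(xi, n, 0.99)
    ci[["lower"]] <= p && p <= ci[["upper"]]
  }, TRUE)
  expect_gte(mean(covered), 0.98)
})

test_that("the exact McNemar test behaves at its boundaries", {
  expect_equal(exact_mcnemar(0, 0), 1)
  expect_equal(exact_mcnemar(5, 5), 1)
  expect_lt(exact_mcnemar(21, 0), 0.001)
  expect_equal(exact_mcnemar(3, 10),
               stats::binom.test(3, 13, 0.5)$p.value)
})
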