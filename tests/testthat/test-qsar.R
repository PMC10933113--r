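fpFixture <- function(n = 120, p = 15, or = 8, n_enr = 3, frac = 0.3,
                      seed = 1) {
  simulateFingerprintSet(n, n_features = p, n_enriched = n_enr,
                         odds_ratio = or, base_prevalence = 0.15,
                         active_fraction = frac, seed = seed)
}

test_that("train/test split is an exact stratified partition", {
  sim <- fpFixture(n = 100, seed = 2)
  sp <- splitFingerprintSet(sim$dataset, 0.7, seed = 2)
  expect_equal(ncol(sp$train), 70)
  expect_equal(ncol(sp$test), 30)
  expect_setequal(c(colnames(sp$train), colnames(sp$test)),
                  colnames(sim$dataset))
  expect_length(intersect(colnames(sp$train), colnames(sp$test)), 0)
  # stratification preserves the class ratio
  expect_equal(sum(activityLabels(sp$train) == "active"), 21)

  sim10 <- simulateFingerprintSet(10, n_features = 5, active_fraction = 0.5,
                                  seed = 3)
  sp10 <- splitFingerprintSet(sim10$dataset, 0.7, seed = 3)
  expect_equal(c(ncol(sp10$train), ncol(sp10$test)), c(7, 3))
  expect_error(splitFingerprintSet(sim$dataset, 1.2, seed = 1),
               "invalid argument")
})

test_that("Fisher selection agrees with hypergeometric enumeration", {
  sim <- fpFixture(n = 40, p = 12, seed = 4)
  fs <- fisherFeatureSelect(sim$dataset, p_cutoff = 0.05)
  m <- fingerprintMatrix(sim$dataset)
  act <- activityLabels(sim$dataset) == "active"
  for (f in colnames(m)) {
    a <- sum(m[act, f] == 1); b <- sum(m[!act, f] == 1)
    cc <- sum(m[act, f] == 0); d <- sum(m[!act, f] == 0)
    expect_equal(fs$p_values[[f]], enumFisherP(a, b, cc, d),
                 tolerance = 1e-10)
  }
  expect_setequal(fs$selected, names(fs$p_values)[fs$p_values <= 0.05])

  # a feature with identical prevalence in both classes gets p = 1
  x <- cbind(f1 = rep(c(1, 0), 20), f2 = rep(c(1, 0), each = 20))
  ds <- FingerprintDataset(x, rep(c("active", "inactive"), each = 20))
  expect_equal(fisherFeatureSelect(ds, 0.05)$p_values[["f1"]], 1)
  # constant features are never selected
  x2 <- cbind(x, f3 = rep(1, 40))
  ds2 <- FingerprintDataset(x2, rep(c("active", "inactive"), each = 20))
  expect_equal(fisherFeatureSelect(ds2, 1)$p_values[["f3"]], 1)
})

test_that("per-feature AUC equals the binary closed form", {
  # TPR 0.8, FPR 0.2 -> AUC 0.8
  act <- rep(c("active", "inactive"), each = 10)
  f <- c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8))
  ds <- FingerprintDataset(cbind(f = f, g = rep(c(0, 1), 10)), act)
  sel <- aucFeatureSelect(ds, 0.52)
  expect_equal(sel$auc[["f"]], 0.8)
  expect_equal(sel$selected, "f")

  # cross-check against a rank-based ROC oracle
  oracle <- as.numeric(pROC::auc(pROC::roc(
    response = act, predictor = f, levels = c("inactive", "active"),
    direction = "<", quiet = TRUE)))
  expect_equal(sel$auc[["f"]], oracle)

  # feature equal to the label scores AUC 1; direction folding rescues
  # depletion-coded features
  ds2 <- FingerprintDataset(
    cbind(eq = as.numeric(act == "active"),
          inv = as.numeric(act != "active")), act)
  sel2 <- aucFeatureSelect(ds2, 0.9)
  expect_equal(unname(sel2$auc[c("eq", "inv")]), c(1, 1))
  expect_equal(aucFeatureSelect(ds2, 0.9, fold_direction = FALSE)$selected,
               "eq")
})

test_that("importance selection finds a planted deterministic feature", {
  set.seed(5)
  n <- 80
  lab <- rep(c("active", "inactive"), each = n / 2)
  x <- matrix(rbinom(n * 10, 1, 0.3), n, 10,
              dimnames = list(NULL, sprintf("F%02d", 1:10)))
  x[, "F01"] <- as.numeric(lab == "active")   # perfectly predictive
  ds <- FingerprintDataset(x, lab)
  for (fam in c("random_forest", "gradient_boosted_trees")) {
    sel <- importanceFeatureSelect(ds, fam, top_k = 3, seed = 6)
    expect_equal(sel$selected[1], "F01")
    expect_length(sel$selected, 3)
  }
  expect_length(importanceFeatureSelect(ds, "random_forest",
                                        top_k = 10, seed = 1)$selected, 10)
  expect_error(importanceFeatureSelect(ds, "random_forest", top_k = 11,
                                       seed = 1), "invalid argument")
})

test_that("rebalancing yields the documented class counts", {
  sim <- fpFixture(n = 100, frac = 0.3, seed = 7)
  x <- fingerprintMatrix(sim$dataset)
  y <- activityLabels(sim$dataset)            # 30 active / 70 inactive
  up <- rebalanceTrainingSet(x, y, "up", seed = 8)
  expect_equal(as.integer(table(up$labels)[c("active", "inactive")]),
               c(70L, 70L))
  dn <- rebalanceTrainingSet(x, y, "down", seed = 8)
  expect_equal(as.integer(table(dn$labels)[c("active", "inactive")]),
               c(30L, 30L))
  rs <- rebalanceTrainingSet(x, y, "rose", seed = 8)
  expect_equal(nrow(rs$x), 100)
  expect_false(all(rs$x %in% c(0, 1)))        # smoothed, not resampled
  none <- rebalanceTrainingSet(x, y, "none", seed = 8)
  expect_identical(none$x, x)
})

test_that("SMOTE synthesizes interpolated minority samples", {
  sim <- fpFixture(n = 60, frac = 0.25, seed = 9)
  x <- fingerprintMatrix(sim$dataset)
  y <- activityLabels(sim$dataset)
  sm <- rebalanceTrainingSet(x, y, "smote", k = 5, seed = 10)
  expect_equal(sum(sm$labels == "active"), sum(sm$labels == "inactive"))
  # originals retained
  expect_true(all(sm$x[seq_len(nrow(x)), ] == x))
  syn <- sm$x[-seq_len(nrow(x)), , drop = FALSE]
  xm <- x[y == "active", , drop = FALSE]
  # each synthetic point lies on a segment between two minority samples:
  # coordinate-wise within the minority hull and expressible as
  # base + lambda * (neighbour - base) for a consistent lambda
  for (i in seq_len(min(nrow(syn), 10))) {
    s <- syn[i, ]
    expect_true(all(s >= apply(xm, 2, min) - 1e-9))
    expect_true(all(s <= apply(xm, 2, max) + 1e-9))
    found <- FALSE
    for (a in seq_len(nrow(xm))) {
      da <- s - xm[a, ]
      for (b in seq_len(nrow(xm))) {
        dir <- xm[b, ] - xm[a, ]
        j <- which(abs(dir) > 1e-12)
        if (!length(j)) next
        lam <- da[j[1]] / dir[j[1]]
        if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
            max(abs(da - lam * dir)) < 1e-8) { found <- TRUE; break }
      }
      if (found) break
    }
    expect_true(found)
  }
  # tiny minority class: neighbours reduced with a warning
  small <- rbind(x[y == "inactive", ][1:10, ], xm[1:3, ])
  expect_warning(
    rebalanceTrainingSet(small, rep(c("inactive", "active"), c(10, 3)),
                         "smote", k = 5, seed = 1),
    "reducing")
})

test_that("classifier families fit, score and are reproducible", {
  sim <- fpFixture(n = 120, seed = 11)
  x <- fingerprintMatrix(sim$dataset)
  y <- activityLabels(sim$dataset)
  for (fam in c("naive_bayes", "neural_net", "random_forest", "svm_rbf",
                "gradient_boosted_trees")) {
    m1 <- trainClassifier(x, y, fam, seed = 12)
    m2 <- trainClassifier(x, y, fam, seed = 12)
    s1 <- predictClassifier(m1, x)
    expect_identical(s1, predictClassifier(m2, x))
    expect_true(all(s1 >= 0 & s1 <= 1))
  }
  expect_error(trainClassifier(cbind(x, bad = NaN), y, "naive_bayes"),
               "invalid data")
})

test_that("tree ensembles separate linearly separable planted data", {
  set.seed(13)
  n <- 60
  lab <- rep(c("active", "inactive"), each = n / 2)
  x <- matrix(rbinom(n * 5, 1, 0.5), n, 5,
              dimnames = list(NULL, paste0("F", 1:5)))
  x[, 1] <- as.numeric(lab == "active")
  m <- trainClassifier(x, lab, "random_forest", seed = 14)
  sc <- predictClassifier(m, x)
  st <- computeEvalMetrics(sc, lab)
  expect_equal(st$balanced_accuracy, 1)
  expect_equal(st$auc_roc, 1)
})

test_that("evaluation metrics behave at the extremes", {
  lab <- rep(c("active", "inactive"), each = 10)
  perfect <- computeEvalMetrics(as.numeric(lab == "active"), lab)
  expect_equal(perfect$auc_roc, 1)
  expect_equal(perfect$balanced_accuracy, 1)
  expect_equal(perfect$mcc, 1)
  const <- computeEvalMetrics(rep(0.7, 20), lab)
  expect_equal(const$mcc, 0)
  expect_error(computeEvalMetrics(runif(5), rep("active", 5)),
               "AUC undefined")
})

test_that("cross-validation grid has the right shape and signal ordering", {
  sim <- fpFixture(n = 150, p = 20, or = 8, n_enr = 5, seed = 15)
  specs <- data.frame(method = c("fisher", "auc"), cutoff = c(0.05, 0.52))
  grid <- crossValidateGrid(sim$dataset, specs,
                            rebalancers = c("none", "up"),
                            families = "naive_bayes",
                            n_folds = 3, n_repeats = 2, seed = 16)
  expect_equal(nrow(grid), 2 * 2 * 1)
  expect_true(all(grid$auc_mean > 0.5))

  one <- crossValidateGrid(sim$dataset, specs[1, , drop = FALSE],
                           rebalancers = "none", families = "naive_bayes",
                           n_folds = 3, n_repeats = 1, seed = 17)
  expect_true(is.na(one$auc_sd) || one$auc_sd == 0)

  # planted signal beats the shuffled-label null decisively
  set.seed(18)
  shuf <- FingerprintDataset(fingerprintMatrix(sim$dataset),
                             sample(activityLabels(sim$dataset)))
  null_grid <- crossValidateGrid(shuf, specs[1, , drop = FALSE],
                                 rebalancers = "none",
                                 families = "naive_bayes",
                                 n_folds = 3, n_repeats = 3, seed = 19)
  expect_gt(grid$auc_mean[1] - null_grid$auc_mean[1], 0.2)
})

test_that("external validation on a held-out partition", {
  sim <- fpFixture(n = 200, p = 20, or = 10, n_enr = 5, seed = 20)
  sp <- splitFingerprintSet(sim$dataset, 0.7, seed = 20)
  feats <- fisherFeatureSelect(sp$train, 0.05)$selected
  xtr <- fingerprintMatrix(sp$train)[, feats, drop = FALSE]
  m <- trainClassifier(xtr, activityLabels(sp$train), "random_forest",
                       seed = 21)
  ext <- evaluateExternal(m, sp$test)
  expect_true(ext$auc_roc > 0.6)
  expect_true(abs(ext$mcc) <= 1)
})
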