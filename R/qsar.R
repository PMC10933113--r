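#' Split a fingerprint dataset into training and test sets
#'
#' Random, by default label-stratified, partition into a training fraction
#' and the complementary test set. The training size is exactly
#' \code{round(n * train_fraction)}; with stratification, per-class counts
#' are allocated by largest remainder so the total is exact and the class
#' imbalance is preserved in both partitions.
#'
#' @param dataset a \code{\link{FingerprintDataset}}.
#' @param train_fraction fraction in (0, 1); default 0.7.
#' @param stratify stratify by activity label (default \code{TRUE}).
#' @param seed integer seed.
#' @return list with \code{train} and \code{test}
#'   (\code{FingerprintDataset}s forming a disjoint, exhaustive partition).
#' @examples
#' sim <- simulateFingerprintSet(100, n_features = 20, seed = 1)
#' sp <- splitFingerprintSet(sim$dataset, seed = 1)
#' c(ncol(sp$train), ncol(sp$test))
#' @export
splitFingerprintSet <- function(dataset, train_fraction = 0.7,
                                stratify = TRUE, seed = 1L) {
  stopifnot(is(dataset, "FingerprintDataset"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("invalid argument: train_fraction must be in (0, 1)")
  set.seed(seed)
  n <- ncol(dataset)
  labels <- activityLabels(dataset)
  n_train <- round(n * train_fraction)

  draw <- function() {
    if (stratify) {
      idx <- integer(0)
      classes <- split(seq_len(n), labels)
      raw <- vapply(classes, length, 0) * train_fraction
      k <- floor(raw)
      short <- n_train - sum(k)
      if (short > 0) {
        ord <- order(raw - k, decreasing = TRUE)
        k[ord[seq_len(short)]] <- k[ord[seq_len(short)]] + 1
      } else if (short < 0) {
        ord <- order(raw - k)
        k[ord[seq_len(-short)]] <- k[ord[seq_len(-short)]] - 1
      }
      for (cl in names(classes))
        idx <- c(idx, sample(classes[[cl]], k[[cl]]))
      sort(idx)
    } else {
      sort(sample.int(n, n_train))
    }
  }
  idx <- draw()
  tries <- 0
  while ((length(unique(labels[idx])) < 2 ||
          length(unique(labels[-idx])) < 2) && tries < 20) {
    warning("single-class partition; re-drawing split")
    idx <- draw(); tries <- tries + 1
  }
  list(train = dataset[, idx], test = dataset[, -idx])
}

.fp_xy <- function(dataset) {
  list(x = fingerprintMatrix(dataset), y = activityLabels(dataset))
}

#' Fisher's exact test feature selection
#'
#' For each fingerprint bit, tests the 2x2 association between feature
#' presence and compound activity with a two-sided Fisher's exact test and
#' keeps features with p <= \code{p_cutoff}. Constant features obtain p = 1
#' and are never selected.
#'
#' @param dataset a \code{\link{FingerprintDataset}} (training data only).
#' @param p_cutoff p-value threshold (the conventional grid is 0.01-0.05).
#' @param alternative sidedness of the test; default \code{"two.sided"},
#'   \code{"greater"} restricts to enrichment in actives.
#' @return list with \code{selected} (feature ids) and \code{p_values}
#'   (named numeric, all features).
#' @export
fisherFeatureSelect <- function(dataset, p_cutoff = 0.05,
                                alternative = "two.sided") {
  d <- .fp_xy(dataset)
  act <- d$y == "active"
  pv <- apply(d$x, 2, function(f) {
    if (length(unique(f)) < 2L) return(1)
    tab <- matrix(c(sum(f == 1 & act), sum(f == 1 & !act),
                    sum(f == 0 & act), sum(f == 0 & !act)), 2, 2)
    fisher.test(tab, alternative = alternative)$p.value
  })
  list(selected = names(pv)[pv <= p_cutoff], p_values = pv)
}

#' Per-feature AUC-ROC feature selection
#'
#' Treats each binary feature as a classifier score for the activity label.
#' For a binary predictor the AUC has the closed form
#' (TPR + TNR) / 2, where TPR is the feature prevalence in actives and TNR
#' the absence rate in inactives. AUCs are direction-folded with
#' \code{max(AUC, 1 - AUC)} so that depletion-type features remain
#' selectable; features with folded AUC >= \code{auc_cutoff} are kept.
#'
#' @param dataset a \code{\link{FingerprintDataset}} (training data only).
#' @param auc_cutoff AUC threshold (conventional grid 0.52-0.60).
#' @param fold_direction apply direction folding (default \code{TRUE}).
#' @return list with \code{selected} and \code{auc} (named numeric).
#' @export
aucFeatureSelect <- function(dataset, auc_cutoff = 0.52,
                             fold_direction = TRUE) {
  d <- .fp_xy(dataset)
  act <- d$y == "active"
  auc <- apply(d$x, 2, function(f) {
    tpr <- mean(f[act] == 1)
    fpr <- mean(f[!act] == 1)
    (tpr + (1 - fpr)) / 2
  })
  if (fold_direction) auc <- pmax(auc, 1 - auc)
  list(selected = names(auc)[auc >= auc_cutoff], auc = auc)
}

#' Ensemble-importance feature selection
#'
#' Fits a random forest (Gini impurity-decrease importance) or gradient
#' boosted trees (gain importance) on the training data and returns the
#' top-k ranked features. Features the ensemble never uses rank last in
#' their original column order, so the returned set always has exactly
#' \code{top_k} members.
#'
#' @param dataset a \code{\link{FingerprintDataset}} (training data only).
#' @param model_family \code{"random_forest"} or
#'   \code{"gradient_boosted_trees"}.
#' @param top_k number of features to keep (conventional grid 10-50).
#' @param seed integer seed for the ensemble fit.
#' @return list with \code{selected} (length \code{top_k}) and
#'   \code{importance} (named numeric, all features).
#' @export
importanceFeatureSelect <- function(dataset,
                                    model_family = c("random_forest",
                                                     "gradient_boosted_trees"),
                                    top_k = 50L, seed = 1L) {
  model_family <- match.arg(model_family)
  d <- .fp_xy(dataset)
  if (top_k > ncol(d$x))
    stop("invalid argument: top_k must be <= number of features")
  set.seed(seed)
  imp <- setNames(numeric(ncol(d$x)), colnames(d$x))
  if (model_family == "random_forest") {
    rf <- randomForest::randomForest(x = d$x, y = factor(d$y),
                                     ntree = 300, importance = FALSE)
    gi <- rf$importance[, "MeanDecreaseGini"]
    imp[names(gi)] <- gi
  } else {
    dm <- xgboost::xgb.DMatrix(d$x, label = as.numeric(d$y == "active"))
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = 0.01,
                    max_depth = 3, colsample_bytree = 0.5, nthread = 1),
      data = dm, nrounds = 100, verbose = 0)
    it <- xgboost::xgb.importance(model = bst)
    imp[it$Feature] <- it$Gain
  }
  ord <- order(-imp, seq_along(imp))
  list(selected = names(imp)[ord[seq_len(top_k)]], importance = imp)
}

#' Rebalance a training set
#'
#' Addresses class imbalance before model fitting. \code{"down"} samples
#' the majority class down to the minority count; \code{"up"} samples the
#' minority class with replacement up to the majority count; \code{"rose"}
#' draws a fresh balanced dataset by smoothed bootstrap (a synthetic sample
#' is a Gaussian perturbation of a randomly chosen seed point, with
#' per-coordinate Silverman bandwidth within its class); \code{"smote"}
#' keeps all original samples and synthesizes minority examples by linear
#' interpolation between a minority sample and one of its k nearest
#' minority neighbours. ROSE and SMOTE produce fractional feature values
#' on binary fingerprints; these are kept fractional.
#'
#' @param x numeric matrix, samples x features.
#' @param labels character/factor class labels (two classes).
#' @param method one of \code{"none"}, \code{"down"}, \code{"up"},
#'   \code{"rose"}, \code{"smote"}.
#' @param k number of SMOTE neighbours (reduced with a warning when the
#'   minority class is too small).
#' @param seed integer seed.
#' @return list with rebalanced \code{x} and \code{labels}.
#' @examples
#' sim <- simulateFingerprintSet(100, n_features = 10, active_fraction = 0.3,
#'                               seed = 1)
#' rb <- rebalanceTrainingSet(fingerprintMatrix(sim$dataset),
#'                            activityLabels(sim$dataset), "up", seed = 1)
#' table(rb$labels)
#' @export
rebalanceTrainingSet <- function(x, labels,
                                 method = c("none", "down", "up", "rose",
                                            "smote"),
                                 k = 5L, seed = 1L) {
  method <- match.arg(method)
  labels <- as.character(labels)
  stopifnot(nrow(x) == length(labels), length(unique(labels)) == 2L)
  if (method == "none") return(list(x = x, labels = labels))
  set.seed(seed)
  cnt <- table(labels)
  minority <- names(cnt)[which.min(cnt)]
  majority <- names(cnt)[which.max(cnt)]
  idx_min <- which(labels == minority)
  idx_maj <- which(labels == majority)

  if (method == "down") {
    keep <- c(sample(idx_maj, length(idx_min)), idx_min)
    keep <- sort(keep)
    return(list(x = x[keep, , drop = FALSE], labels = labels[keep]))
  }
  if (method == "up") {
    extra <- sample(idx_min, length(idx_maj) - length(idx_min),
                    replace = TRUE)
    keep <- c(seq_len(nrow(x)), extra)
    return(list(x = x[keep, , drop = FALSE], labels = labels[keep]))
  }
  if (method == "rose") {
    n <- nrow(x); d <- ncol(x)
    new_lab <- sample(c(minority, majority), n, replace = TRUE)
    out <- matrix(0, n, d, dimnames = list(NULL, colnames(x)))
    for (cl in c(minority, majority)) {
      xs <- x[labels == cl, , drop = FALSE]
      nc <- nrow(xs)
      h <- (4 / ((d + 2) * nc))^(1 / (d + 4)) * apply(xs, 2, sd)
      rows <- which(new_lab == cl)
      seeds <- xs[sample.int(nc, length(rows), replace = TRUE), ,
                  drop = FALSE]
      noise <- matrix(rnorm(length(rows) * d), length(rows), d) *
        rep(h, each = length(rows))
      out[rows, ] <- seeds + noise
    }
    return(list(x = out, labels = new_lab))
  }
  # smote
  n_syn <- length(idx_maj) - length(idx_min)
  if (n_syn == 0) return(list(x = x, labels = labels))
  xm <- x[idx_min, , drop = FALSE]
  if (nrow(xm) - 1L < k) {
    warning("minority class smaller than k + 1; reducing SMOTE neighbours")
    k <- max(1L, nrow(xm) - 1L)
  }
  dmat <- as.matrix(dist(xm))
  diag(dmat) <- Inf
  nn <- t(apply(dmat, 1, function(r) order(r)[seq_len(k)]))
  base_i <- sample.int(nrow(xm), n_syn, replace = TRUE)
  nbr_i <- nn[cbind(base_i, sample.int(k, n_syn, replace = TRUE))]
  lam <- runif(n_syn)
  syn <- xm[base_i, , drop = FALSE] +
    lam * (xm[nbr_i, , drop = FALSE] - xm[base_i, , drop = FALSE])
  list(x = rbind(x, syn), labels = c(labels, rep(minority, n_syn)))
}

#' Train a classifier on fingerprint features
#'
#' Supported families: naive Bayes with Laplace smoothing
#' (\code{"naive_bayes"}), a single-hidden-layer neural network with
#' \code{round(sqrt(p))} hidden units and at most 500 iterations
#' (\code{"neural_net"}), random forest (\code{"random_forest"}), an SVM
#' with Gaussian radial-basis kernel (\code{"svm_rbf"}), and gradient
#' boosted trees with learning rate 0.01, maximum depth 3 and column
#' subsample ratio 0.5 (\code{"gradient_boosted_trees"}). All models emit a
#' continuous activity score in [0, 1] via \code{\link{predictClassifier}};
#' binary calls use a 0.5 threshold. Zero-variance features are dropped
#' before fitting.
#'
#' @param x numeric matrix, samples x features.
#' @param labels class labels (\code{"active"}/\code{"inactive"}).
#' @param family classifier family (see above).
#' @param seed integer seed.
#' @return an object of class \code{"qsarModel"}.
#' @export
trainClassifier <- function(x, labels,
                            family = c("naive_bayes", "neural_net",
                                       "random_forest", "svm_rbf",
                                       "gradient_boosted_trees"),
                            seed = 1L) {
  family <- match.arg(family)
  labels <- as.character(labels)
  if (any(!is.finite(x))) stop("invalid data: non-finite feature values")
  stopifnot(nrow(x) == length(labels), length(unique(labels)) == 2L)
  keep <- apply(x, 2, function(col) var(col) > 0)
  if (!any(keep)) stop("invalid data: all features are constant")
  x <- x[, keep, drop = FALSE]
  set.seed(seed)
  yfac <- factor(labels, levels = c("inactive", "active"))
  model <- switch(family,
    naive_bayes = e1071::naiveBayes(x = as.data.frame(x), y = yfac,
                                    laplace = 1),
    neural_net = nnet::nnet(x = x, y = as.numeric(yfac == "active"),
                            size = max(1L, round(sqrt(ncol(x)))),
                            maxit = 500, trace = FALSE,
                            MaxNWts = 100000),
    random_forest = randomForest::randomForest(x = x, y = yfac,
                                               ntree = 300),
    svm_rbf = e1071::svm(x = x, y = yfac, kernel = "radial",
                         probability = TRUE),
    gradient_boosted_trees = xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = 0.01,
                    max_depth = 3, colsample_bytree = 0.5, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = as.numeric(yfac == "active")),
      nrounds = 100, verbose = 0))
  structure(list(family = family, model = model, features = colnames(x)),
            class = "qsarModel")
}

#' Predict activity scores from a fitted classifier
#'
#' @param object a \code{"qsarModel"} from \code{\link{trainClassifier}}.
#' @param newx numeric matrix with (at least) the model's feature columns.
#' @return numeric vector of activity scores in [0, 1].
#' @export
predictClassifier <- function(object, newx) {
  stopifnot(inherits(object, "qsarModel"))
  newx <- newx[, object$features, drop = FALSE]
  switch(object$family,
    naive_bayes = predict(object$model, as.data.frame(newx),
                          type = "raw")[, "active"],
    neural_net = as.numeric(predict(object$model, newx)),
    random_forest = predict(object$model, newx,
                            type = "prob")[, "active"],
    svm_rbf = {
      pr <- predict(object$model, newx, probability = TRUE)
      attr(pr, "probabilities")[, "active"]
    },
    gradient_boosted_trees =
      predict(object$model, xgboost::xgb.DMatrix(newx)))
}

#' Classification metrics: AUC-ROC, balanced accuracy, MCC
#'
#' AUC-ROC is computed from the continuous scores (via \pkg{pROC});
#' balanced accuracy and the Matthews correlation coefficient are computed
#' from binary calls at the given score threshold.
#'
#' @param scores numeric activity scores.
#' @param labels true labels (\code{"active"}/\code{"inactive"}).
#' @param threshold decision threshold on the score (default 0.5).
#' @return list with \code{auc_roc}, \code{balanced_accuracy}, \code{mcc}.
#' @export
computeEvalMetrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("AUC undefined: a class is missing from the evaluation set")
  auc <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores,
    levels = c("inactive", "active"), direction = "<", quiet = TRUE)))
  call <- ifelse(scores >= threshold, "positive", "negative")
  truth <- ifelse(labels == "active", "positive", "negative")
  stats <- binaryAgreementStats(call, truth)
  list(auc_roc = auc, balanced_accuracy = stats$balanced_accuracy,
       mcc = stats$mcc)
}

.select_features <- function(train_ds, method, cutoff, seed) {
  sel <- switch(method,
    fisher = fisherFeatureSelect(train_ds, p_cutoff = cutoff)$selected,
    auc = aucFeatureSelect(train_ds, auc_cutoff = cutoff)$selected,
    rf_importance = importanceFeatureSelect(
      train_ds, "random_forest", top_k = cutoff, seed = seed)$selected,
    boost_importance = importanceFeatureSelect(
      train_ds, "gradient_boosted_trees", top_k = cutoff,
      seed = seed)$selected,
    stop("unknown feature selection method: ", method))
  if (length(sel) == 0L) {
    # degenerate selection (e.g. null data at a strict cutoff): fall back
    # to the single best-ranked feature so the model stage stays defined
    rank_stat <- switch(method,
      fisher = -log(fisherFeatureSelect(train_ds, 1)$p_values + 1e-300),
      auc = aucFeatureSelect(train_ds, 0)$auc,
      importanceFeatureSelect(train_ds,
        if (method == "rf_importance") "random_forest"
        else "gradient_boosted_trees", top_k = 1, seed = seed)$importance)
    sel <- names(which.max(rank_stat))
  }
  sel
}

#' Repeated cross-validated modeling grid
#'
#' Runs the full modeling grid — feature-selection specification x
#' rebalancing method x classifier family — under repeated stratified
#' k-fold cross-validation. Feature selection and rebalancing are performed
#' inside each training fold only, never on held-out data, so the reported
#' metrics are leakage-free. Out-of-fold scores are pooled per repeat and
#' summarized as mean and SD over repeats.
#'
#' @param dataset a \code{\link{FingerprintDataset}} (the training
#'   partition).
#' @param specs data.frame of feature-selection specifications with columns
#'   \code{method} (\code{"fisher"}, \code{"auc"}, \code{"rf_importance"},
#'   \code{"boost_importance"}) and \code{cutoff} (p-value, AUC threshold
#'   or top-k count, per method).
#' @param rebalancers character vector of rebalancing methods (see
#'   \code{\link{rebalanceTrainingSet}}).
#' @param families character vector of classifier families (see
#'   \code{\link{trainClassifier}}).
#' @param n_folds folds per repeat (default 3).
#' @param n_repeats repeats (default 20).
#' @param seed integer seed.
#' @return data.frame with one row per grid combination: \code{method},
#'   \code{cutoff}, \code{rebalance}, \code{family}, and mean/sd columns
#'   for AUC-ROC, balanced accuracy and MCC across repeats.
#' @export
crossValidateGrid <- function(dataset, specs, rebalancers = "none",
                              families = "naive_bayes", n_folds = 3L,
                              n_repeats = 20L, seed = 1L) {
  stopifnot(is(dataset, "FingerprintDataset"), nrow(specs) >= 1)
  labels <- activityLabels(dataset)
  n <- ncol(dataset)
  grid <- expand.grid(spec = seq_len(nrow(specs)),
                      rebalance = rebalancers, family = families,
                      stringsAsFactors = FALSE)
  res <- vector("list", nrow(grid))

  set.seed(seed)
  fold_plans <- lapply(seq_len(n_repeats), function(r) {
    fold <- integer(n)
    for (cl in unique(labels)) {
      i <- which(labels == cl)
      fold[i] <- sample(rep_len(seq_len(n_folds), length(i)))
    }
    fold
  })

  for (g in seq_len(nrow(grid))) {
    sp <- specs[grid$spec[g], ]
    per_rep <- matrix(NA_real_, n_repeats, 3)
    for (r in seq_len(n_repeats)) {
      fold <- fold_plans[[r]]
      scores <- numeric(n)
      for (f in seq_len(n_folds)) {
        tr <- which(fold != f); te <- which(fold == f)
        tr_ds <- dataset[, tr]
        feats <- .select_features(tr_ds, sp$method, sp$cutoff,
                                  seed = seed + 1000L * r + f)
        xtr <- fingerprintMatrix(tr_ds)[, feats, drop = FALSE]
        rb <- rebalanceTrainingSet(xtr, labels[tr], grid$rebalance[g],
                                   seed = seed + 2000L * r + f)
        fitted <- trainClassifier(rb$x, rb$labels, grid$family[g],
                                  seed = seed + 3000L * r + f)
        xte <- fingerprintMatrix(dataset[, te])[, feats, drop = FALSE]
        scores[te] <- predictClassifier(fitted, xte)
      }
      m <- computeEvalMetrics(scores, labels)
      per_rep[r, ] <- c(m$auc_roc, m$balanced_accuracy, m$mcc)
    }
    res[[g]] <- data.frame(
      method = sp$method, cutoff = sp$cutoff,
      rebalance = grid$rebalance[g], family = grid$family[g],
      auc_mean = mean(per_rep[, 1]), auc_sd = sd(per_rep[, 1]),
      ba_mean = mean(per_rep[, 2]), ba_sd = sd(per_rep[, 2]),
      mcc_mean = mean(per_rep[, 3]), mcc_sd = sd(per_rep[, 3]))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' External validation of a fitted model
#'
#' Applies a trained classifier (with its selected features) to an
#' untouched test partition and reports AUC-ROC, balanced accuracy and MCC.
#'
#' @param model a \code{"qsarModel"}.
#' @param test a \code{\link{FingerprintDataset}} held out from feature
#'   selection, rebalancing and training.
#' @return list with \code{auc_roc}, \code{balanced_accuracy}, \code{mcc}.
#' @export
evaluateExternal <- function(model, test) {
  stopifnot(is(test, "FingerprintDataset"))
  scores <- predictClassifier(model, fingerprintMatrix(test))
  computeEvalMetrics(scores, activityLabels(test))
}
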