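# Rupture-status prediction: Wilcoxon pre-filter, greedy stepwise
# augmentation of a morphological baseline, repeated-split linear-SVM
# evaluation, and exact linear SHAP attributions.

.baselineFeatures <- c("location", "VesselDiameter", "OstiumMin", "NRV2")

#' Morphological baseline feature names
#'
#' Aneurysm location plus parent vessel diameter, ostium minimum and NRV2 —
#' the morphology-only model the velocity-informatics features are asked to
#' improve on.
#'
#' @return character vector.
#' @export
baselineFeatures <- function() .baselineFeatures

# numeric design matrix (one-hot location) for the requested feature columns
buildDesign <- function(cohort, features) {
  miss <- setdiff(features, names(cohort))
  if (length(miss)) stop("missing feature column(s): ", paste(miss, collapse = ", "))
  df <- cohort[, features, drop = FALSE]
  X <- model.matrix(~ ., data = df)
  X[, -1, drop = FALSE]
}

# rank (Mann-Whitney) AUC of scores for the positive class
aucFromScores <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

scaleTrainTest <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sg <- apply(Xtr, 2, sd)
  sg[sg == 0] <- 1
  list(train = sweep(sweep(Xtr, 2, mu), 2, sg, "/"),
       test = sweep(sweep(Xte, 2, mu), 2, sg, "/"))
}

fitLinearSvm <- function(X, y, cost) {
  e1071::svm(x = X, y = y, kernel = "linear", cost = cost, scale = FALSE)
}

# the class a positive decision value favors (e1071 orders classes by first
# appearance in the training data; fit$labels maps that order to levels)
svmPositiveClass <- function(fit) {
  fit$levels[fit$labels][1]
}

# decision scores oriented so larger = more ruptured. e1071 orders the
# decision value by first appearance of the classes in the training data;
# the "A/B" column name of the decision values states which class a
# positive value favors.
svmScores <- function(fit, X) {
  dv <- attr(predict(fit, X, decision.values = TRUE), "decision.values")
  s <- as.numeric(dv)
  posClass <- strsplit(colnames(dv)[1], "/")[[1]][1]
  if (posClass != "ruptured") s <- -s
  s
}

stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# pooled cross-validated decision scores -> AUC, on pre-chosen folds
cvAuc <- function(X, y, cost, fold) {
  scores <- numeric(length(y))
  for (k in sort(unique(fold))) {
    te <- fold == k
    if (all(y[!te] == y[!te][1])) return(NA_real_)
    sc <- scaleTrainTest(X[!te, , drop = FALSE], X[te, , drop = FALSE])
    fit <- fitLinearSvm(sc$train, droplevels(y[!te]), cost)
    scores[te] <- svmScores(fit, sc$test)
  }
  aucFromScores(scores, y == "ruptured")
}

#' Wilcoxon pre-filter of candidate features
#'
#' Tests every candidate feature between the ruptured and unruptured groups
#' with the two-sided Wilcoxon rank-sum test and drops features whose
#' p-value exceeds `pCut` (features with p > 0.8 carry essentially no group
#' signal). Constant columns are retained but flagged with a message.
#'
#' @param cohort a cohort table (see [makeCohort()]) with a `label` column.
#' @param features candidate column names (default: the 74 velocity
#'   features).
#' @param pCut retention threshold on the p-value (default 0.8).
#' @return character vector of retained feature names.
#' @export
prefilterFeatures <- function(cohort, features = velocityFeatureNames(),
                              pCut = 0.8) {
  g1 <- cohort$label == "ruptured"
  if (sum(g1) < 2 || sum(!g1) < 2) stop("need at least 2 cases per class")
  keep <- vapply(features, function(f) {
    x <- cohort[[f]]
    if (sd(x) == 0) {
      message("constant feature retained: ", f)
      return(TRUE)
    }
    wilcoxonRankSum(x[g1], x[!g1])$p.value <= pCut
  }, logical(1))
  features[keep]
}

#' Greedy stepwise augmentation of the baseline model
#'
#' Forward selection: starting from the baseline feature set, repeatedly
#' adds the candidate that most improves the pooled 10-fold cross-validated
#' AUC of the linear SVM, stopping when no candidate improves it by at
#' least `tol` or `maxAdd` features have been added. The fold assignment is
#' drawn once per step so all candidates in a step compete on identical
#' folds.
#'
#' @param cohort cohort table with `label`.
#' @param baseline baseline feature names (default [baselineFeatures()]).
#' @param candidates candidate feature names.
#' @param maxAdd maximum number of features to add (default 3).
#' @param tol minimum AUC improvement to accept a feature (default 0.002).
#' @param cvFolds folds for the selection criterion (default 10).
#' @param cost SVM cost used during selection (default 1).
#' @param seed integer seed.
#' @return character vector of selected candidates, in selection order.
#' @export
stepwiseAugment <- function(cohort, baseline = baselineFeatures(), candidates,
                            maxAdd = 3, tol = 0.002, cvFolds = 10, cost = 1,
                            seed = 1) {
  y <- droplevels(cohort$label)
  selected <- character()
  if (maxAdd < 1 || length(candidates) == 0) return(selected)
  withSeed(seed, {
    repeat {
      fold <- stratifiedFolds(y, cvFolds)
      current <- cvAuc(buildDesign(cohort, c(baseline, selected)), y, cost, fold)
      gains <- vapply(setdiff(candidates, selected), function(f) {
        cvAuc(buildDesign(cohort, c(baseline, selected, f)), y, cost, fold)
      }, numeric(1))
      if (!length(gains) || all(is.na(gains))) break
      best <- names(gains)[which.max(gains)]
      if (is.na(current) || max(gains, na.rm = TRUE) - current >= tol) {
        selected <- c(selected, best)
      } else break
      if (length(selected) >= maxAdd) break
    }
  })
  selected
}

#' Repeated-split SVM evaluation
#'
#' The evaluation protocol: per repeat, a stratified 9:1 train/test split;
#' features standardized on the training data; linear-kernel SVM with cost
#' tuned over `costGrid` by `cvFolds`-fold cross-validated AUC on the
#' training set; AUC and per-class accuracy measured on the held-out test
#' set. Averages over `nRepeats` repeats are reported. A final model is
#' fitted on the full cohort (at the median selected cost) and interpreted
#' with exact linear SHAP attributions.
#'
#' @param cohort cohort table with `label`.
#' @param features feature column names used by the model.
#' @param nRepeats number of train/test repeats (default 100).
#' @param testFraction held-out fraction (default 0.1).
#' @param cvFolds tuning folds (default 10).
#' @param costGrid SVM cost grid (default `2^(-5:5)`).
#' @param seed master seed; the whole evaluation is deterministic given it.
#' @return list with `auc`, `rupturedAccuracy` and `unrupturedAccuracy`
#'   (percent), `features`, `perRepeat` (one row per repeat), `cost`
#'   (median tuned cost), `weights`, `bias` and `shap` (per-case,
#'   per-feature attribution matrix with `baseValue` attribute) of the
#'   full-cohort model.
#' @examples
#' coh <- makeCohort(nCases = 60, nRuptured = 24,
#'                   effectSizes = c(FirstOrder.Mean = 2), seed = 3)
#' rep <- evaluateRupture(coh, c(baselineFeatures(), "FirstOrder.Mean"),
#'                        nRepeats = 3, costGrid = 1, seed = 1)
#' rep$auc
#' @export
evaluateRupture <- function(cohort, features, nRepeats = 100,
                            testFraction = 0.1, cvFolds = 10,
                            costGrid = 2^(-5:5), seed = 1) {
  y <- droplevels(cohort$label)
  if (nlevels(y) != 2 || length(y) < 20)
    stop("need at least 20 cases with both classes present")
  X <- buildDesign(cohort, features)
  pos <- y == "ruptured"

  withSeed(seed, {
    perRepeat <- vector("list", nRepeats)
    for (r in seq_len(nRepeats)) {
      for (try in 1:100) {
        teIdx <- unlist(lapply(levels(y), function(cl) {
          idx <- which(y == cl)
          sample(idx, max(1, round(length(idx) * testFraction)))
        }))
        tr <- setdiff(seq_along(y), teIdx)
        if (nlevels(droplevels(y[tr])) == 2 &&
            nlevels(droplevels(y[teIdx])) == 2) break
        message("resampling split: a class was absent")
      }
      fold <- stratifiedFolds(droplevels(y[tr]), cvFolds)
      aucs <- vapply(costGrid, function(cc)
        cvAuc(X[tr, , drop = FALSE], droplevels(y[tr]), cc, fold), numeric(1))
      cost <- costGrid[which.max(aucs)]
      sc <- scaleTrainTest(X[tr, , drop = FALSE], X[teIdx, , drop = FALSE])
      fit <- fitLinearSvm(sc$train, droplevels(y[tr]), cost)
      scores <- svmScores(fit, sc$test)
      pred <- factor(ifelse(scores > 0, "ruptured", "unruptured"),
                     levels = levels(y))
      truth <- y[teIdx]
      perRepeat[[r]] <- data.frame(
        repeatId = r, cost = cost,
        auc = aucFromScores(scores, truth == "ruptured"),
        rupturedAccuracy = 100 * mean(pred[truth == "ruptured"] == "ruptured"),
        unrupturedAccuracy = 100 * mean(pred[truth == "unruptured"] == "unruptured"))
    }
    perRepeat <- do.call(rbind, perRepeat)

    # full-cohort model for interpretation
    finalCost <- median(perRepeat$cost)
    mu <- colMeans(X); sg <- apply(X, 2, sd); sg[sg == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
    finalFit <- fitLinearSvm(Xs, y, finalCost)
    w <- as.numeric(t(finalFit$coefs) %*% finalFit$SV)
    b <- -finalFit$rho
    if (svmPositiveClass(finalFit) != "ruptured") { w <- -w; b <- -b }
    names(w) <- colnames(X)
    shap <- linearShap(list(weights = w, bias = b), Xs)

    list(auc = mean(perRepeat$auc, na.rm = TRUE),
         rupturedAccuracy = mean(perRepeat$rupturedAccuracy, na.rm = TRUE),
         unrupturedAccuracy = mean(perRepeat$unrupturedAccuracy, na.rm = TRUE),
         features = features, perRepeat = perRepeat, cost = finalCost,
         weights = w, bias = b, shap = shap)
  })
}

#' Exact SHAP attributions for a linear decision function
#'
#' For a linear decision `f(x) = w . x + b`, the Shapley attribution of
#' feature j for case x is `phi_j(x) = w_j (x_j - mean_j)` with base value
#' `f(mean)`; attributions are exact and satisfy
#' `sum_j phi_j(x) + base = f(x)` identically. Positive attributions push
#' toward the ruptured class.
#'
#' @param model an `e1071::svm` fit with a linear kernel, or a list with
#'   `weights` and `bias`.
#' @param X numeric case matrix (cases x features) on the model's scale.
#' @param featureMeans reference point (default column means of `X`).
#' @return attribution matrix (cases x features) with attributes
#'   `baseValue` and `decision`.
#' @export
linearShap <- function(model, X, featureMeans = colMeans(X)) {
  if (inherits(model, "svm")) {
    if (model$kernel != 0)
      stop("linear SHAP requires a linear-kernel SVM")
    w <- as.numeric(t(model$coefs) %*% model$SV)
    b <- -model$rho
    if (svmPositiveClass(model) != "ruptured") { w <- -w; b <- -b }
  } else {
    w <- model$weights; b <- model$bias
  }
  phi <- sweep(X, 2, featureMeans) * rep(w, each = nrow(X))
  base <- sum(w * featureMeans) + b
  attr(phi, "baseValue") <- base
  attr(phi, "decision") <- as.numeric(X %*% w + b)
  phi
}
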