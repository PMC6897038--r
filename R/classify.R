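#' The canonical 36-combination experiment grid
#'
#' Nine feature sets (the four singletons plus HOG+CNN, ExHOG+CNN, CNN+LBP,
#' ExHOG+CNN+LBP and HOG+CNN+LBP) crossed with four classifiers (SVM, KNN,
#' DT, RF). Combination names follow the published convention
#' \code{CLASSIFIER_FEATURESET}, e.g. \code{SVM_ExHOG_CNN}.
#'
#' @return data.frame with columns \code{combo}, \code{classifier},
#'   \code{featureSet} (list column of character vectors); 36 rows.
#' @export
canonicalCombos <- function() {
  sets <- list(
    LBP = "LBP", HOG = "HOG", ExHOG = "ExHOG", CNN = "CNN",
    HOG_CNN = c("HOG", "CNN"), ExHOG_CNN = c("ExHOG", "CNN"),
    CNN_LBP = c("CNN", "LBP"),
    ExHOG_CNN_LBP = c("ExHOG", "CNN", "LBP"),
    HOG_CNN_LBP = c("HOG", "CNN", "LBP"))
  clf <- c("SVM", "KNN", "DT", "RF")
  grid <- expand.grid(set = names(sets), classifier = clf,
                      stringsAsFactors = FALSE)
  data.frame(
    combo = paste(grid$classifier, grid$set, sep = "_"),
    classifier = grid$classifier,
    featureSet = I(unname(sets[grid$set])),
    stringsAsFactors = FALSE)
}

#' Five-split validation scheme constructor
#'
#' @param trainFractions train percentages, default \code{c(10, 20, 30, 40,
#'   50)} (the held-out complements are 90 ... 50 percent).
#' @param stratified preserve class proportions in each split (default TRUE).
#' @param seed integer seed for the split randomness (default 0).
#' @return a [SplitScheme-class].
#' @export
splitScheme <- function(trainFractions = c(10, 20, 30, 40, 50),
                        stratified = TRUE, seed = 0L) {
  new("SplitScheme", trainFractions = as.numeric(trainFractions),
      stratified = as.logical(stratified), seed = as.integer(seed))
}

# Stratified train indices for one fraction (percent). Errors when a class
# would be left empty in the training split.
stratifiedTrainIndex <- function(labels, fraction) {
  idx <- integer()
  for (lv in levels(labels)) {
    pool <- which(labels == lv)
    k <- round(length(pool) * fraction / 100)
    if (k < 1L)
      stop("train fraction ", fraction, "% leaves class '", lv, "' empty")
    if (k >= length(pool))
      stop("train fraction ", fraction, "% leaves no test samples for class '", lv, "'")
    idx <- c(idx, sample(pool, k))
  }
  sort(idx)
}

standardizeFit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  list(center = mu, scale = sdv)
}

standardizeApply <- function(x, fit) {
  sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
}

#' Train one classifier on labelled feature vectors
#'
#' The four classifiers of the grid: \describe{
#'   \item{SVM}{RBF-kernel support vector machine, cost 1, gamma =
#'     1 / (n_features * var(x)) (1 / n_features for unit-variance input);
#'     via \pkg{e1071}.}
#'   \item{KNN}{nearest neighbour with k = 1 and Euclidean distance (the
#'     training set is stored; \pkg{class} does the lookup at predict time).}
#'   \item{DT}{CART decision tree with Gini impurity via \pkg{rpart}.}
#'   \item{RF}{random forest of 100 trees via \pkg{randomForest}, seeded.}
#' }
#' Features are expected already standardized (the grid harness z-scores
#' using train-split statistics only).
#'
#' @param x numeric matrix, samples x features.
#' @param y factor with both classes present.
#' @param kind one of "SVM", "KNN", "DT", "RF".
#' @param seed integer seed for the stochastic learners (default 0).
#' @param hyper optional named list overriding defaults (\code{cost},
#'   \code{gamma}, \code{k}, \code{ntree}).
#' @return an object of class \code{noduleClassifier}; use
#'   [predictClassifier()].
#' @export
trainClassifier <- function(x, y, kind = c("SVM", "KNN", "DT", "RF"),
                            seed = 0L, hyper = list()) {
  kind <- match.arg(kind)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2L) stop("training needs at least one sample per class")
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("x and y sizes differ")
  fit <- withSeed(seed, switch(kind,
    SVM = {
      v <- stats::var(as.vector(x))
      gamma <- if (!is.null(hyper$gamma)) hyper$gamma
               else if (is.finite(v) && v > 0) 1 / (ncol(x) * v) else 1 / ncol(x)
      e1071::svm(x, y, kernel = "radial",
                 cost = if (is.null(hyper$cost)) 1 else hyper$cost,
                 gamma = gamma, scale = FALSE)
    },
    KNN = list(train = x, cl = y, k = if (is.null(hyper$k)) 1L else hyper$k),
    DT = {
      df <- as.data.frame(x)
      df$.label <- y
      rpart::rpart(.label ~ ., data = df, method = "class",
                   parms = list(split = "gini"))
    },
    RF = randomForest::randomForest(
      x, y, ntree = if (is.null(hyper$ntree)) 100L else hyper$ntree)
  ))
  structure(list(kind = kind, fit = fit, levels = levels(y)),
            class = "noduleClassifier")
}

#' Predict labels from a trained classifier
#'
#' @param model a \code{noduleClassifier} from [trainClassifier()].
#' @param x numeric matrix, samples x features (same standardization as the
#'   training features).
#' @return factor of predicted labels.
#' @export
predictClassifier <- function(model, x) {
  stopifnot(inherits(model, "noduleClassifier"))
  if (!is.matrix(x)) x <- as.matrix(x)
  pred <- switch(model$kind,
    SVM = predict(model$fit, x),
    KNN = class::knn(model$fit$train, x, model$fit$cl, k = model$fit$k),
    DT = predict(model$fit, as.data.frame(x), type = "class"),
    RF = predict(model$fit, x))
  factor(as.character(pred), levels = model$levels)
}

#' Run the feature-set x classifier evaluation grid
#'
#' For each combination: at every train fraction of the scheme, fit on a
#' stratified seeded train split (features z-scored with train statistics
#' only) and predict the held-out complement; the held-out predictions of the
#' five splits are pooled into a single confusion matrix, from which the full
#' metric panel is computed. All combinations share the same five splits, so
#' hybrid and singleton feature sets are compared on identical partitions.
#'
#' @param features a \code{SummarizedExperiment} from [extractFeatures()]
#'   containing every descriptor used by \code{combos} and a \code{label}
#'   column in its colData.
#' @param scheme a [SplitScheme-class] (default [splitScheme()]).
#' @param combos data.frame as from [canonicalCombos()] (default: the full
#'   36-combination grid), or a subset of it.
#' @param seed integer seed for classifier randomness (default: the scheme
#'   seed).
#' @param classifiers optional named list overriding classifier
#'   implementations, each element a list with functions
#'   \code{fit(x, y, seed)} and \code{predict(model, x)}; intended for
#'   testing the harness with reference classifiers.
#' @return data.frame with one row per combination: combo, classifier,
#'   featureSet, the pooled counts tp/fp/fn/tn (published layout), the metric
#'   panel in percent, wall-clock seconds and the seed. The counts of each
#'   row sum to the total number of held-out predictions.
#' @export
runGrid <- function(features, scheme = splitScheme(),
                    combos = canonicalCombos(), seed = NULL,
                    classifiers = NULL) {
  stopifnot(is(scheme, "SplitScheme"))
  validObject(scheme)
  if (!nrow(combos)) stop("combos must be non-empty")
  if (is.null(seed)) seed <- scheme@seed
  labels <- factor(SummarizedExperiment::colData(features)$label,
                   levels = c("nodule", "nonnodule"))
  if (any(is.na(labels))) stop("labels must be 'nodule' or 'nonnodule'")
  if (nlevels(droplevels(labels)) < 2L) stop("dataset must contain both classes")

  splits <- withSeed(scheme@seed, lapply(scheme@trainFractions, function(f) {
    if (scheme@stratified) stratifiedTrainIndex(labels, f)
    else {
      k <- max(1L, round(length(labels) * f / 100))
      sort(sample(seq_along(labels), k))
    }
  }))

  # fuse each distinct feature set once
  setKey <- vapply(combos$featureSet, paste, "", collapse = "+")
  fused <- lapply(combos$featureSet[!duplicated(setKey)],
                  function(s) t(fuseFeatures(features, s)))
  names(fused) <- setKey[!duplicated(setKey)]

  rows <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    kind <- combos$classifier[i]
    X <- fused[[setKey[i]]]
    t0 <- proc.time()[["elapsed"]]
    truthAll <- factor(character(), levels = levels(labels))
    predAll <- factor(character(), levels = levels(labels))
    for (si in seq_along(splits)) {
      tr <- splits[[si]]
      te <- setdiff(seq_along(labels), tr)
      sfit <- standardizeFit(X[tr, , drop = FALSE])
      xtr <- standardizeApply(X[tr, , drop = FALSE], sfit)
      xte <- standardizeApply(X[te, , drop = FALSE], sfit)
      runSeed <- seed + 97L * si + i
      if (!is.null(classifiers) && kind %in% names(classifiers)) {
        mdl <- classifiers[[kind]]$fit(xtr, labels[tr], runSeed)
        pred <- classifiers[[kind]]$predict(mdl, xte)
      } else {
        mdl <- trainClassifier(xtr, labels[tr], kind, seed = runSeed)
        pred <- predictClassifier(mdl, xte)
      }
      truthAll <- unlist(list(truthAll, labels[te]))
      predAll <- unlist(list(predAll, factor(as.character(pred),
                                             levels = levels(labels))))
    }
    cc <- confusionCounts(truthAll, predAll)
    panel <- metricsPanel(cc)
    rows[[i]] <- data.frame(
      combo = combos$combo[i], classifier = kind,
      featureSet = paste(combos$featureSet[[i]], collapse = "_"),
      tp = cc@tp, fp = cc@fp, fn = cc@fn, tn = cc@tn,
      panel,
      seconds = proc.time()[["elapsed"]] - t0,
      seed = seed,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
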