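# run expr under a temporary RNG state seeded with `seed`
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

isPositiveLabel <- function(label) {
  tolower(as.character(label)) %in% c("dba", "positive", "pathogenic", "1",
                                      "true")
}

#' Stratified fold assignment
#'
#' @param labels class labels.
#' @param k number of folds.
#' @param seed RNG seed fixing the assignment.
#' @return integer vector of fold ids in 1..k.
#' @export
makeStratifiedFolds <- function(labels, k = 5, seed = 1) {
  pos <- isPositiveLabel(labels)
  if (sum(pos) < k || sum(!pos) < k)
    stop("need at least ", k, " samples per class for ", k, " folds")
  fold <- integer(length(labels))
  withSeed(seed, {
    for (cls in c(TRUE, FALSE)) {
      idx <- which(pos == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Training protocol configuration
#'
#' @param candidate_features ordered feature names to select from.
#' @param min_features minimum feature-subset size enumerated (5).
#' @param c_grid,gamma_grid hyper-parameter grids
#'   (`0.001, 0.01, 0.1, 1, 100`).
#' @param folds cross-validation folds (5).
#' @param seed RNG seed for the fold assignment.
#' @param budget maximum number of SVM fits allowed without `force`.
#' @param force evaluate even above the budget.
#' @return named list.
#' @export
trainingConfig <- function(candidate_features, min_features = 5,
                           c_grid = c(0.001, 0.01, 0.1, 1, 100),
                           gamma_grid = c(0.001, 0.01, 0.1, 1, 100),
                           folds = 5, seed = 1, budget = 1e6,
                           force = FALSE) {
  stopifnot(length(candidate_features) >= 1,
            min_features <= length(candidate_features),
            length(c_grid) >= 1, length(gamma_grid) >= 1)
  list(candidate_features = candidate_features,
       min_features = min_features, c_grid = sort(c_grid),
       gamma_grid = sort(gamma_grid), folds = folds, seed = seed,
       budget = budget, force = force)
}

scaleApply <- function(x, center, scale) {
  sweep(sweep(as.matrix(x), 2, center), 2, scale, "/")
}

fitScaler <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | is.na(scale)] <- 1
  list(center = center, scale = scale)
}

#' Stratified k-fold cross-validation of an RBF SVM
#'
#' Features are z-scored using training-fold statistics only (no leakage
#' into the held-out fold); held-out predictions are pooled into a single
#' confusion matrix whose MCC is the selection objective.
#'
#' @param table data.frame holding the feature columns and a `label`
#'   column (positive class `"dba"`).
#' @param features feature column names to use.
#' @param C,gamma RBF SVM hyper-parameters.
#' @param folds number of folds.
#' @param seed seed fixing the fold assignment.
#' @return list: `cv_mcc`, pooled `confusion` (from [confusionMetrics()]),
#'   `per_fold` confusion counts, `fold` assignment,
#'   `correct_positives` (pooled TP count) and `mean_fold_mcc`.
#' @export
crossValidate <- function(table, features, C, gamma, folds = 5, seed = 1) {
  x <- as.matrix(table[, features, drop = FALSE])
  if (anyNA(x)) stop("NA feature values; complete the table first")
  y <- factor(ifelse(isPositiveLabel(table$label), "pos", "neg"),
              levels = c("neg", "pos"))
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present")
  fold <- makeStratifiedFolds(table$label, folds, seed)
  pooled <- c(tp = 0, fp = 0, tn = 0, fn = 0)
  perFold <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    sc <- fitScaler(x[tr, , drop = FALSE])
    fit <- e1071::svm(scaleApply(x[tr, , drop = FALSE], sc$center,
                                 sc$scale),
                      y[tr], kernel = "radial", cost = C, gamma = gamma,
                      scale = FALSE)
    pred <- predict(fit, scaleApply(x[!tr, , drop = FALSE], sc$center,
                                    sc$scale))
    truth <- y[!tr]
    cm <- c(tp = sum(pred == "pos" & truth == "pos"),
            fp = sum(pred == "pos" & truth == "neg"),
            tn = sum(pred == "neg" & truth == "neg"),
            fn = sum(pred == "neg" & truth == "pos"))
    perFold[[f]] <- cm
    pooled <- pooled + cm
  }
  conf <- confusionMetrics(pooled["tp"], pooled["fp"], pooled["tn"],
                           pooled["fn"])
  foldMcc <- vapply(perFold, function(cm)
    confusionMetrics(cm["tp"], cm["fp"], cm["tn"], cm["fn"])$mcc,
    numeric(1))
  list(cv_mcc = conf$mcc, confusion = conf, per_fold = perFold,
       fold = fold, correct_positives = unname(pooled["tp"]),
       mean_fold_mcc = mean(foldMcc))
}

#' Exhaustive feature-combination and hyper-parameter selection
#'
#' Enumerates every feature subset of size `min_features` or larger and
#' every (C, gamma) grid pair, runs the stratified cross-validation of
#' [crossValidate()] for each, and returns the combination maximising the
#' cross-validation MCC.  Ties are broken deterministically in favour of
#' fewer features, then smaller C, then smaller gamma, then earlier subset
#' in enumeration order.
#'
#' @param table feature table with `label` column.
#' @param config a [trainingConfig()].
#' @return list: `features`, `C`, `gamma`, `cv_mcc`, `n_evaluated`.
#' @export
selectFeaturesAndHyperparams <- function(table, config) {
  cand <- config$candidate_features
  sizes <- seq(config$min_features, length(cand))
  combos <- unlist(lapply(sizes, function(s)
    utils::combn(cand, s, simplify = FALSE)), recursive = FALSE)
  nFits <- length(combos) * length(config$c_grid) *
    length(config$gamma_grid) * config$folds
  if (nFits > config$budget && !config$force)
    stop("enumeration requires ", nFits, " SVM fits, above the budget of ",
         config$budget, "; reduce the candidate pool or set force = TRUE")
  if (nFits > config$budget)
    warning("enumeration above budget: ", nFits, " fits")

  best <- NULL
  for (feats in combos) {
    for (C in config$c_grid) {
      for (gamma in config$gamma_grid) {
        cv <- crossValidate(table, feats, C, gamma, config$folds,
                            config$seed)
        if (is.null(best) || cv$cv_mcc > best$cv_mcc + 1e-12) {
          best <- list(features = feats, C = C, gamma = gamma,
                       cv_mcc = cv$cv_mcc)
        }
      }
    }
  }
  best$n_evaluated <- length(combos) * length(config$c_grid) *
    length(config$gamma_grid)
  best
}

# Platt-style sigmoid calibration: minimise the regularised logistic loss
# of targets t on decision values f; returns c(A, B) for
# p = 1 / (1 + exp(A * f + B))
fitPlatt <- function(f, yPos) {
  nPos <- sum(yPos)
  nNeg <- sum(!yPos)
  t <- ifelse(yPos, (nPos + 1) / (nPos + 2), 1 / (nNeg + 2))
  nll <- function(par) {
    z <- par[1] * f + par[2]
    # stable log(1 + exp(z)) and cross-entropy
    lse <- ifelse(z > 0, z + log1p(exp(-z)), log1p(exp(z)))
    sum(t * lse + (1 - t) * (lse - z))
  }
  opt <- stats::optim(c(A = -1, B = 0), nll, method = "BFGS")
  opt$par
}

#' Train the final predictor on the full table
#'
#' Refits the RBF SVM on all samples with the selected features and
#' hyper-parameters, stores the z-score scaler, and calibrates decision
#' values onto [0, 1] pathogenicity scores with a monotone Platt-style
#' sigmoid.
#'
#' @param table feature table with `label` column.
#' @param features selected feature names.
#' @param C,gamma hyper-parameters.
#' @param cvMcc optionally, the selection-stage MCC to record.
#' @return a [TrainedModel-class].
#' @export
trainFinal <- function(table, features, C, gamma, cvMcc = NA_real_) {
  x <- as.matrix(table[, features, drop = FALSE])
  y <- factor(ifelse(isPositiveLabel(table$label), "pos", "neg"),
              levels = c("neg", "pos"))
  sc <- fitScaler(x)
  xs <- scaleApply(x, sc$center, sc$scale)
  fit <- e1071::svm(xs, y, kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE)
  dv <- attr(predict(fit, xs, decision.values = TRUE), "decision.values")
  f <- dv[, 1]
  # orient decision values so larger means more pathogenic
  if (mean(f[y == "pos"]) < mean(f[y == "neg"])) f <- -f
  flip <- mean(dv[, 1][y == "pos"]) < mean(dv[, 1][y == "neg"])
  ab <- fitPlatt(f, y == "pos")
  if (flip) ab[1] <- -ab[1]
  new("TrainedModel", features = features, cost = C, gamma = gamma,
      fit = fit, center = sc$center, scale = sc$scale,
      calibration = unname(ab), cvMcc = cvMcc)
}

#' Pathogenicity scores of a trained model
#'
#' @param model a [TrainedModel-class].
#' @param newdata data.frame or matrix containing the model's feature
#'   columns.
#' @return numeric scores in [0, 1]; larger means more pathogenic.
#' @export
predictScore <- function(model, newdata) {
  x <- as.matrix(as.data.frame(newdata)[, model@features, drop = FALSE])
  xs <- scaleApply(x, model@center, model@scale)
  dv <- attr(predict(model@fit, xs, decision.values = TRUE),
             "decision.values")
  f <- dv[, 1]
  1 / (1 + exp(model@calibration[1] * f + model@calibration[2]))
}

#' Saturation-scan prediction over a whole protein sequence
#'
#' Scores every possible single-residue substitution: for a protein of
#' length L this is L x 19 predictions (wild-type cells are NA).
#'
#' @param model a [TrainedModel-class].
#' @param featureizer function(position, wt, mut) returning a named feature
#'   vector covering the model's features.
#' @param sequence one-letter protein sequence.
#' @return numeric matrix, rows = positions (named `wt+position`),
#'   columns = the 20 amino acids; wild-type cells NA, all scores in [0, 1].
#' @export
saturationScan <- function(model, featureizer, sequence) {
  aas <- BLOSUM62_AA
  seqv <- strsplit(sequence, "")[[1]]
  L <- length(seqv)
  rows <- vector("list", L)
  for (p in seq_len(L)) {
    wt <- seqv[p]
    feats <- lapply(setdiff(aas, wt), function(m) featureizer(p, wt, m))
    fm <- as.data.frame(do.call(rbind, feats))
    sc <- predictScore(model, fm)
    row <- rep(NA_real_, length(aas))
    names(row) <- aas
    row[setdiff(aas, wt)] <- sc
    rows[[p]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- paste0(seqv, seq_len(L))
  out
}
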