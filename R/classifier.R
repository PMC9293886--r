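# Candidate classification and evaluation: Matthews correlation coefficient,
# sixfold cross-validation MCC, RBF-SVM training and hyperparameter grid
# search, the random-quantifier baseline, and the parametric threshold
# pipeline for unambiguous foci.

#' Confusion matrix of two binary label vectors
#' @param truth,pred vectors of 0/1 labels.
#' @return named list with TP, TN, FP, FN.
#' @export
confusion_matrix <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  truth <- as.integer(truth); pred <- as.integer(pred)
  list(TP = sum(truth == 1 & pred == 1), TN = sum(truth == 0 & pred == 0),
       FP = sum(truth == 0 & pred == 1), FN = sum(truth == 1 & pred == 0))
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, ranging
#' from -1 (perfect misclassification) through 0 (no correlation, e.g. a
#' coin toss) to 1 (perfect classification). It is robust to the heavy class
#' imbalance typical of foci candidates (several times fewer foci than
#' non-foci). A zero factor in the denominator returns 0 by convention.
#'
#' @param cm confusion matrix from [confusion_matrix()] (or any list with
#'   TP, TN, FP, FN).
#' @return numeric in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  tp <- as.numeric(cm$TP); tn <- as.numeric(cm$TN)
  fp <- as.numeric(cm$FP); fn <- as.numeric(cm$FN)
  n <- tp + tn + fp + fn
  if (n == 0) stop("empty confusion matrix")
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

mcc_labels <- function(truth, pred) mcc(confusion_matrix(truth, pred))

#' Train the RBF-SVM foci classifier
#'
#' Fits a C-classification SVM with radial-basis-function kernel
#' (via \pkg{e1071}/libsvm) on whitened/rescaled features. Features are
#' scaled here with [whiten_rescale()] and the fitted scaler is stored in
#' the model so prediction-time data is scaled identically.
#'
#' @param features numeric matrix (candidates x features), unscaled.
#' @param labels 0/1 vector; both classes must be present.
#' @param C regularization parameter.
#' @param gamma RBF kernel width; `"scale"` uses `1 / (p * var(x))` on the
#'   scaled features (the libsvm/sklearn default).
#' @return object of class `foci_svm` (SVM fit + scaler + settings).
#' @export
train_foci_svm <- function(features, labels, C = 1, gamma = "scale") {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("single-class data: an SVM requires negative examples to learn as well; ",
         "use threshold_classify() for unambiguous datasets")
  ws <- whiten_rescale(features)
  x <- ws$scaled
  g <- if (identical(gamma, "scale")) 1 / (ncol(x) * max(var(as.vector(x)), 1e-12))
  else as.numeric(gamma)
  fit <- e1071::svm(x = x, y = factor(labels, levels = c(0, 1)),
                    kernel = "radial", cost = C, gamma = g, scale = FALSE)
  structure(list(fit = fit, scaler = ws$scaler, C = C, gamma = g,
                 n_train = nrow(x)), class = "foci_svm")
}

#' @export
print.foci_svm <- function(x, ...) {
  cat(sprintf("foci_svm: RBF SVM, C = %g, gamma = %g, %d support vectors, n = %d\n",
              x$C, x$gamma, x$fit$tot.nSV, x$n_train))
  invisible(x)
}

#' Predict candidate labels with a trained model
#'
#' Features are scaled with the model's stored scaler before prediction.
#' Manual corrections are applied after prediction via `overrides`, a named
#' list/vector mapping candidate index to forced label.
#'
#' @param model a `foci_svm`.
#' @param features unscaled feature matrix with the training columns.
#' @param overrides optional named vector of label overrides
#'   (names = row indices).
#' @return integer vector of 0/1 labels.
#' @export
predict_foci <- function(model, features, overrides = NULL) {
  features <- as.matrix(features)
  if (ncol(features) != length(model$scaler$mean))
    stop("feature dimension mismatch: model expects ",
         length(model$scaler$mean), " features")
  x <- apply_scaler(model$scaler, features)
  raw <- if (inherits(model, "foci_svm_json")) {
    d <- model$decision(x)
    pos <- model$positive
    ifelse(d > 0, pos, setdiff(model$levels, pos)[1])
  } else {
    as.character(predict(model$fit, x))
  }
  out <- as.integer(as.character(raw))
  if (!is.null(overrides) && length(overrides)) {
    idx <- as.integer(names(overrides))
    out[idx] <- as.integer(unlist(overrides))
  }
  out
}

# Stratified, seeded k-fold assignment; fold sizes differ by <= 1 per class.
make_folds <- function(labels, k, seed = 1L) {
  n <- length(labels)
  if (k > n) stop("more folds than observations")
  folds <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Sixfold cross-validation MCC
#'
#' Splits the dataset into `k` disjoint, label-stratified folds; for each
#' fold trains on the remainder and scores the held-out predictions against
#' the labels with the MCC; returns the mean of the k fold MCCs. This is the
#' generalization-aware score used when a model is compared to the data it
#' was trained on.
#'
#' @param features unscaled feature matrix.
#' @param labels 0/1 labels.
#' @param k number of folds (default 6).
#' @param C,gamma SVM hyperparameters.
#' @param seed fold-assignment seed.
#' @return mean MCC over folds.
#' @export
cv_mcc <- function(features, labels, k = 6L, C = 1, gamma = "scale", seed = 1L) {
  labels <- as.integer(labels)
  if (k > length(labels)) stop("more folds than observations")
  if (min(table(labels)) < k)
    stop("every fold needs both classes; reduce k or rebalance")
  folds <- make_folds(labels, k, seed)
  scores <- numeric(k)
  for (i in seq_len(k)) {
    tr <- folds != i
    model <- train_foci_svm(features[tr, , drop = FALSE], labels[tr],
                            C = C, gamma = gamma)
    pred <- predict_foci(model, features[!tr, , drop = FALSE])
    scores[i] <- mcc_labels(labels[!tr], pred)
  }
  mean(scores)
}

#' Logarithmic grid search for C and gamma
#'
#' Evaluates the cross-validation MCC on a log-spaced grid (defaults:
#' C from 1e-3 to 1e3, gamma from 1e-8 to 10) and returns the maximizing
#' pair; ties prefer smaller C, then smaller gamma. Grid points whose
#' training fails are skipped.
#'
#' @param features,labels the dataset.
#' @param C_grid,gamma_grid numeric grids.
#' @param k folds (default 6).
#' @param seed fold seed.
#' @return list with `C`, `gamma`, `cv_mcc` and the full `results` frame.
#' @export
grid_search <- function(features, labels,
                        C_grid = 10^seq(-3, 3, by = 1),
                        gamma_grid = 10^seq(-8, 1, by = 1),
                        k = 6L, seed = 1L) {
  res <- expand.grid(C = sort(C_grid), gamma = sort(gamma_grid))
  res$cv_mcc <- NA_real_
  for (i in seq_len(nrow(res))) {
    res$cv_mcc[i] <- tryCatch(
      cv_mcc(features, labels, k = k, C = res$C[i], gamma = res$gamma[i],
             seed = seed),
      error = function(e) NA_real_)
  }
  ok <- which(!is.na(res$cv_mcc))
  if (!length(ok)) stop("no grid point could be evaluated")
  # ties -> smaller C, then smaller gamma (rows are ordered that way)
  ord <- ok[order(-res$cv_mcc[ok], res$C[ok], res$gamma[ok])]
  best <- ord[1]
  list(C = res$C[best], gamma = res$gamma[best], cv_mcc = res$cv_mcc[best],
       results = res)
}

#' Random-quantifier baseline
#'
#' For each cell, picks uniformly at random (without replacement) the same
#' number of candidates that the reference selected in that cell, pools all
#' cells, and scores the random selection against the reference with the
#' MCC; the mean over `n_reps` repetitions is returned. Two randomized
#' selections correlate at ~0, so this baseline anchors the low end of the
#' MCC scale for a given selection profile.
#'
#' @param reference list of per-cell 0/1 vectors (the reference selection).
#' @param n_reps repetitions (default 50).
#' @param seed RNG seed.
#' @return list with `mean_mcc` and the per-repetition `mcc` vector.
#' @export
random_quantifier <- function(reference, n_reps = 50L, seed = 1L) {
  truth <- unlist(reference, use.names = FALSE)
  ks <- vapply(reference, function(v) sum(v == 1), integer(1))
  ns <- lengths(reference)
  stopifnot(all(ks <= ns))
  scores <- with_seed(seed, {
    vapply(seq_len(n_reps), function(rep) {
      pred <- unlist(lapply(seq_along(reference), function(i) {
        v <- integer(ns[i])
        if (ks[i] > 0) v[sample.int(ns[i], ks[i])] <- 1L
        v
      }), use.names = FALSE)
      mcc_labels(truth, pred)
    }, numeric(1))
  })
  list(mean_mcc = mean(scores), mcc = scores)
}

#' Threshold-based classification
#'
#' Labels a candidate 1 iff every bounded feature lies within its `[lo, hi]`
#' interval — the parametric pipeline for unambiguous datasets (bright
#' P-bodies, spindle pole bodies, ...) where an SVM cannot be trained for
#' lack of negative examples. Geometrically each bound is an axis-aligned
#' separating plane in feature space.
#'
#' @param features feature matrix with named columns.
#' @param bounds named list of `c(lo, hi)` per bounded feature; an empty
#'   list labels everything 1.
#' @return integer 0/1 labels.
#' @export
threshold_classify <- function(features, bounds = list()) {
  features <- as.matrix(features)
  out <- rep(1L, nrow(features))
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (b[1] > b[2]) stop("bound for ", nm, " has lo > hi")
    v <- features[, nm]
    out[v < b[1] | v > b[2]] <- 0L
  }
  out
}

#' Serialize / restore a trained model
#'
#' Writes the SVM (support vectors, coefficients, rho), the feature scaler
#' and the settings to a single JSON file so models can be shared and
#' results reproduced across machines.
#'
#' @param model a `foci_svm`.
#' @param path file path.
#' @return `save_model`: the path, invisibly. `load_model`: a `foci_svm`.
#' @export
save_model <- function(model, path) {
  fit <- model$fit
  sv <- unname(as.matrix(fit$SV))
  coefs <- as.numeric(fit$coefs)
  rho <- fit$rho
  # calibrate the sign of the reconstructed decision function against
  # libsvm's own decision values, and record which class is positive
  dv <- attr(predict(fit, sv, decision.values = TRUE), "decision.values")
  pos <- strsplit(colnames(dv)[1], "/")[[1]][1]
  kx <- exp(-model$gamma * outer(rowSums(sv^2), rowSums(sv^2), "+") +
              2 * model$gamma * (sv %*% t(sv)))
  mine <- as.numeric(t(coefs) %*% kx) - rho
  if (stats::cor(mine, as.numeric(dv[, 1])) < 0) {
    coefs <- -coefs; rho <- -rho
  }
  obj <- list(
    type = "foci_svm", C = model$C, gamma = model$gamma,
    n_train = model$n_train,
    scaler = unclass(model$scaler),
    SV = sv, coefs = coefs,
    rho = rho, levels = fit$levels, positive = pos,
    nSV = fit$nSV)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(obj$type, "foci_svm"))
  scaler <- obj$scaler
  class(scaler) <- "feature_scaler"
  sv <- as.matrix(obj$SV)
  decision <- function(x) {
    # RBF decision function: sum_i coef_i K(sv_i, x) - rho
    kx <- exp(-obj$gamma * outer(rowSums(sv^2), rowSums(x^2), "+") +
                2 * obj$gamma * (sv %*% t(x)))
    as.numeric(t(obj$coefs) %*% kx) - obj$rho
  }
  structure(list(fit = NULL, decision = decision, scaler = scaler,
                 C = obj$C, gamma = obj$gamma, n_train = obj$n_train,
                 levels = obj$levels, positive = obj$positive),
            class = c("foci_svm_json", "foci_svm"))
}
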