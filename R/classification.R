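#' @include AllClasses.R AllGenerics.R features.R
NULL

# primal objective and gradient of the L2-regularized squared-hinge SVM:
# f(w, b) = 0.5 ||w||^2 + (C/2) sum_i max(0, 1 - y_i (w.x_i + b))^2
# The bias is unregularized, exactly as in the printed problem.
.svmObjective <- function(theta, X, y, C) {
    p <- ncol(X)
    w <- theta[seq_len(p)]
    b <- theta[p + 1L]
    xi <- pmax(0, 1 - y * (drop(X %*% w) + b))
    0.5 * sum(w^2) + (C / 2) * sum(xi^2)
}

.svmGradient <- function(theta, X, y, C) {
    p <- ncol(X)
    w <- theta[seq_len(p)]
    b <- theta[p + 1L]
    xi <- pmax(0, 1 - y * (drop(X %*% w) + b))
    g <- -C * (y * xi)
    c(w + drop(crossprod(X, g)), sum(g))
}

#' Train a linear soft-margin SVM (squared hinge)
#'
#' Solves min_{W,b,xi} (1/2)||W||^2 + (C/2) sum xi_i^2 subject to
#' y_i (W'x_i + b) + xi_i >= 1 -- the L2-regularized squared-hinge primal
#' with unregularized bias -- by BFGS on the (smooth, convex)
#' unconstrained equivalent with analytic gradient.  Decision rule
#' sign(W'x + b); ties (exactly 0) predict +1.  Deterministic: no solver
#' randomness.
#'
#' @param X samples x features matrix, or a \linkS4class{FeatureMatrix}.
#' @param y labels in -1/+1 (ignored when X is a FeatureMatrix).
#' @param C soft-margin cost (default 1).
#' @param reltol solver relative tolerance (default 1e-12).
#' @param maxit iteration cap.
#' @return a \linkS4class{LinearSvmModel}.
#' @export
trainLinearSvm <- function(X, y = NULL, C = 1, reltol = 1e-12,
                           maxit = 5000L) {
    if (is(X, "FeatureMatrix")) { y <- X@y; X <- X@X }
    X <- as.matrix(X)
    if (any(!is.finite(X)))
        stop(errorCondition("non-finite feature values",
                            class = "nonFiniteError"))
    if (length(unique(y)) < 2L)
        stop(errorCondition("training labels contain a single class",
                            class = "singleClassError"))
    fit <- stats::optim(rep(0, ncol(X) + 1L), .svmObjective, .svmGradient,
                        X = X, y = y, C = C, method = "BFGS",
                        control = list(maxit = maxit, reltol = reltol))
    w <- fit$par[seq_len(ncol(X))]
    names(w) <- colnames(X)
    new("LinearSvmModel", weights = w, bias = fit$par[ncol(X) + 1L],
        cost = C,
        featureIds = if (is.null(colnames(X))) character(0) else colnames(X))
}

#' Predict with a linear SVM
#'
#' @param object a \linkS4class{LinearSvmModel}.
#' @param newdata samples x features matrix or
#'   \linkS4class{FeatureMatrix}.
#' @param ... unused.
#' @return numeric vector of -1/+1 predictions.
#' @export
setMethod("predict", "LinearSvmModel", function(object, newdata, ...) {
    if (is(newdata, "FeatureMatrix")) newdata <- newdata@X
    s <- drop(as.matrix(newdata) %*% object@weights) + object@bias
    ifelse(s >= 0, 1, -1)
})

#' Leave-one-out cross-validation
#'
#' n rounds; round i trains on all samples but i and scores sample i
#' (1 correct / 0 wrong); accuracy is the average.  Fold order is sample
#' order and the procedure is deterministic.  A training fold that loses a
#' whole class predicts the training majority class, with a warning.
#'
#' Note that under the "unpair" scheme the held-out sample's subject still
#' contributes its other-condition row to training (the protocol followed
#' here); use \code{loocvBySubject} for a leakage-free subject-level
#' alternative.
#'
#' @param fm a \linkS4class{FeatureMatrix} (or matrix with \code{y}).
#' @param y labels if \code{fm} is a plain matrix.
#' @param C soft-margin cost (default 1).
#' @return an \linkS4class{EvaluationResult}; its \code{model} slot holds
#'   the model trained on all samples.
#' @export
loocv <- function(fm, y = NULL, C = 1) {
    if (is(fm, "FeatureMatrix")) {
        X <- fm@X; y <- fm@y
        scheme <- fm@scheme
    } else { X <- as.matrix(fm); scheme <- "pair" }
    n <- nrow(X)
    if (n < 3L) stop("need at least 3 samples for LOOCV")
    if (length(unique(y)) < 2L)
        stop(errorCondition("both classes must be present",
                            class = "singleClassError"))
    correct <- logical(n)
    for (i in seq_len(n)) {
        Xtr <- X[-i, , drop = FALSE]; ytr <- y[-i]
        if (length(unique(ytr)) < 2L) {
            warning(warningCondition(
                "single-class training fold; predicting majority class",
                class = "singleClassFoldWarning"))
            pred <- as.numeric(names(which.max(table(ytr))))
        } else {
            mod <- trainLinearSvm(Xtr, ytr, C = C)
            pred <- predict(mod, X[i, , drop = FALSE])
        }
        correct[i] <- pred == y[i]
    }
    full <- trainLinearSvm(X, y, C = C)
    new("EvaluationResult", scheme = scheme, method = "", band = "",
        accuracy = mean(correct), correct = correct, model = full)
}

#' Leave-one-subject-out cross-validation (unpair scheme)
#'
#' Like \code{\link{loocv}} but holds out both condition rows of a subject
#' at once, removing the subject-level leakage of per-sample LOOCV on
#' stacked condition data.
#'
#' @param fm an "unpair" \linkS4class{FeatureMatrix} whose first m rows
#'   are EC and last m rows EO, subject-aligned.
#' @param C soft-margin cost.
#' @return an \linkS4class{EvaluationResult}.
#' @export
loocvBySubject <- function(fm, C = 1) {
    stopifnot(is(fm, "FeatureMatrix"), fm@scheme == "unpair")
    n <- nrow(fm@X); m <- n %/% 2L
    correct <- logical(n)
    for (s in seq_len(m)) {
        hold <- c(s, s + m)
        mod <- trainLinearSvm(fm@X[-hold, , drop = FALSE], fm@y[-hold], C = C)
        correct[hold] <- predict(mod, fm@X[hold, , drop = FALSE]) == fm@y[hold]
    }
    full <- trainLinearSvm(fm@X, fm@y, C = C)
    new("EvaluationResult", scheme = "unpair", method = "", band = "",
        accuracy = mean(correct), correct = correct, model = full)
}

#' Apply a frozen classifier to another dataset
#'
#' Cross-dataset validation: target features are extracted at the SOURCE
#' dataset's locations (the spec), transformed per the scheme (the pair
#' scheme draws the target's own sign vector), then scored by the frozen
#' model -- no refitting.
#'
#' @param model the frozen \linkS4class{LinearSvmModel} trained on the
#'   source dataset.
#' @param specSource the source dataset's \linkS4class{FeatureSpec}.
#' @param targetMapsC,targetMapsO per-subject \linkS4class{AlffMap} lists
#'   of the target dataset.
#' @param scheme "pair" or "unpair".
#' @param seed seed for the target's sign vector (pair scheme).
#' @return an \linkS4class{EvaluationResult}.
#' @export
crossDatasetApply <- function(model, specSource, targetMapsC, targetMapsO,
                              scheme = c("pair", "unpair"), seed = 1L) {
    scheme <- match.arg(scheme)
    cFeat <- extractColumns(targetMapsC, specSource)
    oFeat <- extractColumns(targetMapsO, specSource)
    fm <- if (scheme == "pair")
        pairTransform(cFeat, oFeat, makeSignVector(nrow(cFeat), seed))
    else unpairStack(cFeat, oFeat)
    correct <- predict(model, fm) == fm@y
    new("EvaluationResult", scheme = scheme, method = specSource@method,
        band = specSource@band@name, accuracy = mean(correct),
        correct = correct, model = model)
}

#' Pearson correlation between feature weights and cluster t values
#'
#' @param weights per-region SVM weights.
#' @param roiMeanT per-region ROI mean t values (same order).
#' @return the sample Pearson correlation coefficient.
#' @export
weightTCorrelation <- function(weights, roiMeanT) {
    if (length(weights) != length(roiMeanT) || length(weights) < 3L)
        stop("need equal-length vectors of at least 3 regions")
    if (stats::sd(weights) == 0 || stats::sd(roiMeanT) == 0)
        stop(errorCondition("zero variance in weights or t values",
                            class = "zeroVarianceError"))
    stats::cor(weights, roiMeanT)
}
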