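## Classifier contract, repeated stratified cross-validation, final
## model training and prediction.

#' Describe a classifier
#'
#' Defaults reproduce the study settings: an RBF-kernel SVM with
#' `C = 1` and `epsilon = 0.1` (epsilon is recorded and passed through
#' for fidelity; it only affects regression-mode solvers), or k-NN
#' with `k = 10`.  The `plugin` kind wraps any estimator exposing
#' `fit(x, y)` and `predict(model, x)` (the latter returning
#' `list(label=, score=)`), which is how additional classifiers are
#' compared under the same protocol.
#'
#' @param kind One of `"svm_rbf"`, `"knn"`, `"plugin"`.
#' @param C SVM cost of constraint violation.
#' @param epsilon Recorded SVM epsilon.
#' @param sigma RBF kernel width; `NULL` = median-pairwise-distance
#'   heuristic, computed from the training data and recorded.
#' @param k Neighbour count for k-NN.
#' @param fit,predict Plugin functions.
#' @return A `ClassifierSpec` list.
#' @export
classifierSpec <- function(kind = c("svm_rbf", "knn", "plugin"),
                           C = 1, epsilon = 0.1, sigma = NULL, k = 10L,
                           fit = NULL, predict = NULL) {
    kind <- match.arg(kind)
    if (kind == "plugin" && (is.null(fit) || is.null(predict)))
        stop("plugin classifiers need 'fit' and 'predict' functions")
    structure(list(kind = kind, C = C, epsilon = epsilon, sigma = sigma,
                   k = as.integer(k), fit = fit, predict = predict),
              class = "ClassifierSpec")
}

## Median heuristic for the RBF width: sigma = 1 / median squared
## pairwise distance, over a deterministic subset of rows.
.medianSigma <- function(x, max_rows = 500L) {
    n <- nrow(x)
    idx <- if (n > max_rows)
        seq(1L, n, length.out = max_rows) else seq_len(n)
    d2 <- as.numeric(stats::dist(x[idx, , drop = FALSE]))^2
    d2 <- d2[d2 > 0]
    if (!length(d2)) return(1)
    1 / stats::median(d2)
}

.fitClassifier <- function(spec, x, y) {
    y <- factor(as.character(y), levels = c("inside", "outside"))
    if (spec$kind == "svm_rbf") {
        sigma <- if (is.null(spec$sigma)) .medianSigma(x) else spec$sigma
        m <- kernlab::ksvm(x, y, type = "C-svc", kernel = "rbfdot",
                           kpar = list(sigma = sigma), C = spec$C,
                           scaled = FALSE)
        ## kernlab's decision-value sign depends on label encounter
        ## order; orient using the training data only.
        dec <- kernlab::predict(m, x, type = "decision")[, 1L]
        orient <- if (mean(dec[y == "inside"]) >= mean(dec[y == "outside"]))
            1 else -1
        list(kind = "svm_rbf", model = m, orient = orient, sigma = sigma)
    } else if (spec$kind == "knn") {
        if (min(table(y)) < 1L) stop("empty class")
        list(kind = "knn", x = x, y = y, k = spec$k)
    } else {
        list(kind = "plugin", model = spec$fit(x, y),
             predict = spec$predict)
    }
}

.predictClassifier <- function(fit, x) {
    if (fit$kind == "svm_rbf") {
        lab <- as.character(kernlab::predict(fit$model, x))
        score <- fit$orient *
            kernlab::predict(fit$model, x, type = "decision")[, 1L]
        list(label = lab, score = score)
    } else if (fit$kind == "knn") {
        pr <- class::knn(fit$x, x, fit$y, k = min(fit$k, nrow(fit$x)),
                         prob = TRUE)
        p <- attr(pr, "prob")
        lab <- as.character(pr)
        list(label = lab, score = ifelse(lab == "inside", p, 1 - p))
    } else {
        fit$predict(fit$model, x)
    }
}

## Stratified fold ids for one iteration; depends on (seed, row id)
## through the caller ordering rows by id, not on row position.
.stratifiedFolds <- function(y, folds) {
    f <- integer(length(y))
    for (cl in levels(y)) {
        i <- which(y == cl)
        f[i[sample.int(length(i))]] <-
            rep_len(seq_len(folds), length(i))
    }
    f
}

#' Repeated stratified cross-validation
#'
#' Ten (by default) independent iterations of stratified 5-fold
#' cross-validation.  Within an iteration the five test folds'
#' predictions are pooled into one confusion table and one score-based
#' AUC; measures are then averaged over iterations with their standard
#' deviation.  Fold assignment is derived from the window ids (rows
#' are ordered by id before fold generation), so results are invariant
#' to row order, and the whole procedure is deterministic given
#' `seed`.
#'
#' @param fm A labeled [FeatureMatrix-class].
#' @param spec A [classifierSpec()].
#' @param folds Fold count (default 5).
#' @param iterations Number of independent CV repeats (default 10).
#' @param seed Integer seed.
#' @return A `CvResult` list: `per_iteration` (data.frame of ACC, MCC,
#'   PPV, F1, Sn, Sp, FPR, FNR, AUC, CPS per iteration), `mean`, `sd`,
#'   and the call parameters.
#' @export
crossValidate <- function(fm, spec = classifierSpec(), folds = 5L,
                          iterations = 10L, seed = 1L) {
    stopifnot(is(fm, "FeatureMatrix"))
    y <- fm@labels
    if (anyNA(y)) stop("cross-validation needs fully labeled data")
    if (min(table(y)) < folds)
        stop("each class needs at least 'folds' members")
    ord <- order(rownames(fm@data))
    x <- fm@data[ord, , drop = FALSE]
    y <- y[ord]
    rows <- list()
    for (it in seq_len(iterations)) {
        res <- withr::with_seed(as.integer(seed) + it, {
            fold <- .stratifiedFolds(y, folds)
            pred <- character(length(y))
            score <- numeric(length(y))
            for (k in seq_len(folds)) {
                test <- fold == k
                fit <- .fitClassifier(spec, x[!test, , drop = FALSE],
                                      y[!test])
                p <- .predictClassifier(fit, x[test, , drop = FALSE])
                pred[test] <- p$label
                score[test] <- p$score
            }
            m <- computeMetrics(confusionCounts(y, pred))
            auc <- aucScore(y, score)
            c(m, AUC = auc, CPS = unname(m[["ACC"]] + auc + m[["MCC"]]))
        })
        rows[[it]] <- res
    }
    per <- as.data.frame(do.call(rbind, rows))
    per <- cbind(iteration = seq_len(iterations), per)
    metric_cols <- setdiff(names(per), "iteration")
    structure(list(per_iteration = per,
                   mean = colMeans(per[metric_cols]),
                   sd = apply(per[metric_cols], 2L, stats::sd),
                   folds = folds, iterations = iterations, seed = seed,
                   classifier = spec$kind),
              class = "CvResult")
}

#' @export
print.CvResult <- function(x, ...) {
    cat(sprintf("%d x %d-fold cross-validation (%s, seed %d)\n",
                x$iterations, x$folds, x$classifier, x$seed))
    tab <- rbind(mean = x$mean, sd = x$sd)
    print(round(tab, 4))
    invisible(x)
}

.fingerprint <- function(x)
    sprintf("%dx%d/%s", nrow(x), ncol(x),
            format(sum(x * seq_len(ncol(x))[col(x)]), digits = 12))

#' Train a final predictive model
#'
#' Fits the classifier on every labeled row and records the exact
#' ordered feature manifest (index accessions and feature ids) so that
#' prediction can refuse mismatched inputs.
#'
#' @param fm A labeled [FeatureMatrix-class].
#' @param spec A [classifierSpec()].
#' @param mod_type Optional modification type tag for the bundle.
#' @return A `ModelBundle` list.
#' @export
trainModel <- function(fm, spec = classifierSpec(), mod_type = NA_character_) {
    stopifnot(is(fm, "FeatureMatrix"))
    y <- fm@labels
    if (anyNA(y)) stop("training needs fully labeled data")
    if (nlevels(droplevels(y)) < 2L) stop("single-class input")
    fit <- .fitClassifier(spec, fm@data, y)
    structure(list(fit = fit, spec = spec,
                   manifest = featureInfo(fm),
                   indices = indexAccessions(fm),
                   fingerprint = .fingerprint(fm@data),
                   mod_type = mod_type,
                   version = as.character(utils::packageVersion("ppirpredict"))),
              class = "ModelBundle")
}

#' @export
print.ModelBundle <- function(x, ...) {
    cat(sprintf("ModelBundle (%s%s): %d features over %d indices, v%s\n",
                x$spec$kind,
                if (is.na(x$mod_type)) "" else paste0(", ", x$mod_type),
                nrow(x$manifest), length(x$indices), x$version))
    invisible(x)
}

#' Persist / restore a model bundle
#'
#' @param bundle A `ModelBundle`.
#' @param file Path.
#' @return `loadModelBundle` returns the bundle.
#' @export
saveModelBundle <- function(bundle, file) {
    stopifnot(inherits(bundle, "ModelBundle"))
    saveRDS(bundle, file)
    invisible(file)
}

#' @rdname saveModelBundle
#' @export
loadModelBundle <- function(file) {
    bundle <- readRDS(file)
    if (!inherits(bundle, "ModelBundle")) stop("not a model bundle")
    bundle
}

#' Predict interface localization for new windows
#'
#' Windows are encoded with exactly the bundle's feature manifest
#' (same indices, features and column order) and classified.  Input
#' order is preserved; windows that cannot be encoded (wrong length or
#' residues undefined in the manifest's indices) are returned with
#' `NA` label and a `note`, never silently dropped.
#'
#' @param bundle A `ModelBundle` from [trainModel()].
#' @param ws Window data.frame.
#' @param indices List of [AminoAcidIndex-class] covering the bundle's
#'   accessions.
#' @return data.frame: the window columns plus `label` (predicted) and
#'   `score` (decision value, larger = more `inside`-like) and `note`.
#' @export
predictWindows <- function(bundle, ws, indices) {
    stopifnot(inherits(bundle, "ModelBundle"))
    .checkWindows(ws)
    if (is(indices, "AminoAcidIndex")) indices <- list(indices)
    accs <- vapply(indices, accession, character(1))
    names(indices) <- accs
    missing_idx <- setdiff(bundle$indices, accs)
    if (length(missing_idx))
        stop("feature manifest mismatch: missing index ",
             paste(missing_idx, collapse = ", "))
    out <- ws
    out$label <- rep(NA_character_, nrow(ws))
    out$score <- rep(NA_real_, nrow(ws))
    out$note <- rep("", nrow(ws))
    if (!nrow(ws)) return(out)
    encodable <- logical(nrow(ws))
    why <- character(nrow(ws))
    alphabet <- paste(.AA, collapse = "")
    for (i in seq_len(nrow(ws))) {
        if (nchar(ws$sequence[i]) != 15L) {
            why[i] <- "not a 15-mer"
        } else if (!grepl(paste0("^[", alphabet, "]+$"), ws$sequence[i])) {
            why[i] <- "non-standard residue"
        } else encodable[i] <- TRUE
    }
    out$note <- why
    if (any(encodable)) {
        sub <- ws[encodable, , drop = FALSE]
        fm <- encodeDataset(sub, indices[bundle$indices])
        if (!identical(featureInfo(fm)$feature_id,
                       bundle$manifest$feature_id)) {
            fm <- fm[, bundle$manifest$feature_id]
            if (!identical(featureInfo(fm)$feature_id,
                           bundle$manifest$feature_id))
                stop("feature manifest mismatch")
        }
        p <- .predictClassifier(bundle$fit, featureData(fm))
        out$label[encodable] <- p$label
        out$score[encodable] <- p$score
    }
    out
}
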