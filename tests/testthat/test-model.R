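test_that("cross-validation separates a strong planted signal and not a null", {
    idx <- syntheticIndexSet(3, seed = 12)
    ws <- simulateWindows(120, 120, idx, signal_indices = "SYNTH0001",
                          effect_size = 8, seed = 5)
    cv <- crossValidate(encodeDataset(ws, idx), classifierSpec(),
                        folds = 5, iterations = 2, seed = 6)
    expect_gte(cv$mean[["ACC"]], 0.95)
    ws0 <- simulateWindows(250, 250, idx, effect_size = 0, seed = 8)
    cv0 <- crossValidate(encodeDataset(ws0, idx), classifierSpec(),
                         folds = 5, iterations = 2, seed = 6)
    expect_gt(cv0$mean[["AUC"]], 0.4)
    expect_lt(cv0$mean[["AUC"]], 0.6)
})

test_that("cross-validation is deterministic and row-order invariant", {
    idx <- syntheticIndexSet(2, seed = 13)
    ws <- simulateWindows(40, 40, idx, signal_indices = "SYNTH0001",
                          effect_size = 1.5, seed = 9)
    fm <- encodeDataset(ws, idx)
    a <- crossValidate(fm, classifierSpec(), folds = 5, iterations = 3,
                       seed = 17)
    b <- crossValidate(fm, classifierSpec(), folds = 5, iterations = 3,
                       seed = 17)
    expect_identical(a$per_iteration, b$per_iteration)
    perm <- withr::with_seed(1, sample(nrow(featureData(fm))))
    c2 <- crossValidate(fm[perm, ], classifierSpec(), folds = 5,
                        iterations = 3, seed = 17)
    expect_identical(a$per_iteration, c2$per_iteration)
    ## mean/SD recomputable from the per-iteration list
    expect_equal(unname(a$mean["CPS"]), mean(a$per_iteration$CPS))
    expect_equal(unname(a$sd["AUC"]), sd(a$per_iteration$AUC))
    expect_error(crossValidate(fm[1:6, ], classifierSpec(), folds = 5),
                 "folds")
})

test_that("test folds are never touched during fitting (leakage canary)", {
    idx <- syntheticIndexSet(1, seed = 3)
    ws <- simulateWindows(30, 30, idx, seed = 4)
    fm <- encodeDataset(ws, idx)
    seen <- new.env()
    spec <- classifierSpec("plugin",
        fit = function(x, y) {
            list(rows = rownames(x),
                 maj = names(sort(table(y), decreasing = TRUE))[1])
        },
        predict = function(model, x) {
            overlap <- intersect(rownames(x), model$rows)
            assign("leak", c(get0("leak", envir = seen, ifnotfound = 0),
                             length(overlap)), envir = seen)
            list(label = rep(model$maj, nrow(x)), score = rep(0, nrow(x)))
        })
    cv <- crossValidate(fm, spec, folds = 5, iterations = 2, seed = 21)
    expect_true(all(get("leak", envir = seen) == 0))
    ## the all-majority plugin scores exactly the class prior on
    ## pooled folds, confirming every row is predicted exactly once
    expect_equal(cv$per_iteration$ACC, rep(0.5, 2))
})

test_that("the selection pipeline never leaks test rows either", {
    idx <- syntheticIndexSet(2, seed = 6)
    ws <- simulateWindows(25, 25, idx, seed = 7)
    fm <- encodeDataset(ws, idx)
    seen <- new.env(); assign("leak", 0, envir = seen)
    spec <- classifierSpec("plugin",
        fit = function(x, y) list(rows = rownames(x), maj = "outside"),
        predict = function(model, x) {
            if (length(intersect(rownames(x), model$rows)))
                assign("leak", 1, envir = seen)
            list(label = rep(model$maj, nrow(x)),
                 score = seq_len(nrow(x)))
        })
    rk <- rankIndices(fm, spec, folds = 5, seed = 2)
    invisible(forwardIndexSelection(fm, rk, spec, folds = 5, seed = 2))
    expect_equal(get("leak", envir = seen), 0)
})

test_that("an RBF SVM with C=1 separates linearly separable toy data", {
    withr::with_seed(2, {
        x <- rbind(matrix(rnorm(100, 3), ncol = 2),
                   matrix(rnorm(100, -3), ncol = 2))
    })
    rownames(x) <- sprintf("t%03d", 1:100)
    colnames(x) <- c("T@+1", "T@+2")
    fm <- new("FeatureMatrix", data = x,
              features = data.frame(feature_id = colnames(x),
                                    accession = "T", position = 1:2),
              labels = factor(rep(c("inside", "outside"), each = 50),
                              levels = c("inside", "outside")))
    bundle <- trainModel(fm, classifierSpec())
    pred <- ppirpredict:::.predictClassifier(bundle$fit, x)
    expect_equal(mean(pred$label == as.character(windowLabels(fm))), 1)
})

test_that("model bundles train, round-trip and refuse manifest mismatches", {
    idx <- syntheticIndexSet(2, seed = 31)
    ws <- simulateWindows(40, 40, idx, signal_indices = "SYNTH0001",
                          effect_size = 8, seed = 32)
    fm <- encodeDataset(ws, idx)
    bundle <- trainModel(fm, classifierSpec(), mod_type = "phosphorylation")
    expect_identical(nrow(bundle$manifest), 28L)
    p <- predictWindows(bundle, ws, idx)
    expect_gte(mean(p$label == ws$label), 0.99)
    f <- withr::local_tempfile(fileext = ".rds")
    saveModelBundle(bundle, f)
    p2 <- predictWindows(loadModelBundle(f), ws, idx)
    expect_identical(p2, p)
    expect_error(predictWindows(bundle, ws, idx[1]),
                 "feature manifest mismatch")
    ## single-class training is refused
    fm1 <- fm[which(ws$label == "inside"), ]
    expect_error(trainModel(fm1, classifierSpec()), "single-class")
})

test_that("prediction preserves order and reports un-encodable windows", {
    idx <- syntheticIndexSet(1, seed = 41)
    ws <- simulateWindows(20, 20, idx, signal_indices = "SYNTH0001",
                          effect_size = 2, seed = 42)
    bundle <- trainModel(encodeDataset(ws, idx), classifierSpec())
    batch <- ws[1:6, ]
    batch$sequence[3] <- substr(batch$sequence[3], 1, 10)
    batch$sequence[5] <- sub("^.", "B", batch$sequence[5])
    p <- predictWindows(bundle, batch, idx)
    expect_identical(p$protein_id, batch$protein_id)
    expect_true(is.na(p$label[3]) && is.na(p$label[5]))
    expect_match(p$note[3], "15-mer")
    expect_match(p$note[5], "non-standard")
    expect_false(anyNA(p$label[c(1, 2, 4, 6)]))
    empty <- predictWindows(bundle, ws[0, ], idx)
    expect_equal(nrow(empty), 0L)
})

test_that("k-NN classifier runs under the same CV contract", {
    idx <- syntheticIndexSet(1, seed = 51)
    ws <- simulateWindows(60, 60, idx, signal_indices = "SYNTH0001",
                          effect_size = 6, seed = 52)
    fm <- encodeDataset(ws, idx)
    a <- crossValidate(fm, classifierSpec("knn", k = 10), folds = 5,
                       iterations = 2, seed = 3)
    b <- crossValidate(fm, classifierSpec("knn", k = 10), folds = 5,
                       iterations = 2, seed = 3)
    expect_identical(a$per_iteration, b$per_iteration)
    expect_gte(a$mean[["AUC"]], 0.9)
})
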