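## Small planted-signal dataset shared across selection tests.
plantedFm <- function(n_per_class = 150, n_idx = 5, effect = 3, seed = 1) {
    idx <- syntheticIndexSet(n_idx, seed = 100)
    ws <- simulateWindows(n_per_class, n_per_class, idx,
                          signal_indices = "SYNTH0001",
                          effect_size = effect, seed = seed)
    encodeDataset(ws, idx)
}

test_that("rankIndices is deterministic with accession tie-breaks", {
    fm <- plantedFm(30, 2, effect = 0, seed = 2)
    ## duplicate block content: second index cloned from the first
    d <- featureData(fm)
    d[, 15:28] <- d[, 1:14]
    fm2 <- new("FeatureMatrix", data = d, features = featureInfo(fm),
               labels = windowLabels(fm))
    r <- rankIndices(fm2, folds = 3, seed = 5)
    expect_identical(r$accession, c("SYNTH0001", "SYNTH0002"))
    expect_equal(r$CPS[1], r$CPS[2])
    single <- rankIndices(indexBlock(fm, "SYNTH0001"), folds = 3, seed = 5)
    expect_identical(nrow(single), 1L)
    expect_identical(rankIndices(fm, folds = 3, seed = 5),
                     rankIndices(fm, folds = 3, seed = 5))
})

test_that("the planted signal index ranks first and survives forward selection", {
    fm <- plantedFm(150, 5, effect = 3, seed = 7)
    rk <- rankIndices(fm, seed = 7)
    expect_identical(rk$accession[1], "SYNTH0001")
    sel <- forwardIndexSelection(fm, rk, seed = 7)
    expect_true("SYNTH0001" %in% sel$optimal_indices)
    expect_gte(sel$optimal_cps, rk$CPS[1] - 1e-9)
    expect_equal(sel$optimal_cps, max(sel$trajectory$CPS))
})

test_that("forward index selection matches an exhaustive prefix scan", {
    fm <- plantedFm(40, 4, effect = 1, seed = 3)
    rk <- rankIndices(fm, folds = 4, seed = 9)
    sel <- forwardIndexSelection(fm, rk, folds = 4, seed = 9)
    brute <- vapply(seq_len(4), function(p) {
        cv <- crossValidate(indexBlock(fm, rk$accession[seq_len(p)]),
                            classifierSpec(), folds = 4, iterations = 1,
                            seed = 9)
        unname(cv$mean[["CPS"]])
    }, numeric(1))
    expect_equal(sel$trajectory$CPS, brute)
    expect_equal(length(sel$optimal_indices), which.max(brute))
})

test_that("Relief-F ranks a label-copy feature first and zeroes constants", {
    hits <- vapply(1:10, function(seed) {
        withr::with_seed(seed, {
            y <- rep(c("inside", "outside"), each = 40)
            d <- cbind(labelcopy = as.numeric(y == "inside"),
                       noise1 = runif(80), noise2 = runif(80),
                       constant = rep(2, 80))
        })
        rownames(d) <- sprintf("w%03d", 1:80)
        colnames(d) <- paste0(colnames(d), "@+1")
        fm <- new("FeatureMatrix", data = d,
                  features = data.frame(feature_id = colnames(d),
                                        accession = sub("@.*", "", colnames(d)),
                                        position = 1L),
                  labels = factor(y, levels = c("inside", "outside")))
        rf <- reliefF(fm, k = 5)
        expect_equal(rf$weight[rf$feature_id == "constant@+1"], 0)
        rf$feature_id[1] == "labelcopy@+1"
    }, logical(1))
    expect_gte(sum(hits), 9L)
})

test_that("Relief-F weights are affine-invariant and symmetric for duplicates", {
    fm <- plantedFm(40, 2, effect = 2, seed = 4)
    d <- featureData(fm)
    rf0 <- reliefF(fm, k = 5)
    d2 <- d
    d2[, 3] <- d2[, 3] * 40 - 7          # affine rescale of one feature
    fm2 <- new("FeatureMatrix", data = d2, features = featureInfo(fm),
               labels = windowLabels(fm))
    rf2 <- reliefF(fm2, k = 5)
    expect_equal(rf2$weight, rf0$weight, tolerance = 1e-12)
    ## duplicated columns get equal weights
    d3 <- d
    d3[, 2] <- d3[, 1]
    fm3 <- new("FeatureMatrix", data = d3, features = featureInfo(fm),
               labels = windowLabels(fm))
    rf3 <- reliefF(fm3, k = 5)
    w <- setNames(rf3$weight, rf3$feature_id)
    expect_equal(unname(w[featureInfo(fm)$feature_id[1]]),
                 unname(w[featureInfo(fm)$feature_id[2]]))
    expect_error(reliefF(plantedFm(8, 1, seed = 2), k = 10), "k\\+1")
})

test_that("information gain matches hand-computed entropies and is bounded", {
    y <- rep(c("inside", "outside"), c(11, 9))
    x1 <- c(rep(0, 9), rep(1, 2), rep(0, 1), rep(1, 8))  # 2-bin split at .5
    x2 <- as.numeric(y == "inside")                       # label copy
    d <- cbind(`F1@+1` = x1, `F2@+2` = x2, `F3@+3` = rep(1, 20))
    rownames(d) <- sprintf("w%02d", 1:20)
    fm <- new("FeatureMatrix", data = d,
              features = data.frame(feature_id = colnames(d),
                                    accession = c("F1", "F2", "F3"),
                                    position = 1:3),
              labels = factor(y, levels = c("inside", "outside")))
    ig <- informationGain(fm)
    w <- setNames(ig$weight, ig$feature_id)
    H <- function(p) {
        p <- p[p > 0]
        -sum(p * log2(p))
    }
    Hy <- H(c(11, 9) / 20)
    ## bin x1 <= .5: 10 instances (9+1 inside split 9in/1out? recompute)
    left <- y[x1 == 0]; right <- y[x1 == 1]
    Hcond <- (length(left) * H(table(left) / length(left)) +
              length(right) * H(table(right) / length(right))) / 20
    expect_equal(unname(w["F1@+1"]), Hy - Hcond)
    expect_equal(unname(w["F2@+2"]), Hy)        # perfect predictor
    expect_equal(unname(w["F3@+3"]), 0)         # constant, never split
    expect_true(all(ig$weight >= 0 & ig$weight <= Hy + 1e-12))
    expect_error(informationGain(
        new("FeatureMatrix", data = d,
            features = data.frame(feature_id = colnames(d),
                                  accession = c("F1", "F2", "F3"),
                                  position = 1:3),
            labels = factor(rep("inside", 20),
                            levels = c("inside", "outside")))),
        "single-class")
})

test_that("forward feature selection recovers planted features and is consistent", {
    idx <- syntheticIndexSet(4, seed = 55)
    recovered <- vapply(1:10, function(seed) {
        ws <- simulateWindows(60, 60, idx, signal_indices = "SYNTH0001",
                              effect_size = 3, seed = seed)
        fm <- encodeDataset(ws, idx)
        rf <- reliefF(fm, k = 5)
        sel <- forwardFeatureSelection(fm, rf, folds = 3, seed = seed,
                                       step = 8)
        planted <- featureInfo(fm)$feature_id[
            featureInfo(fm)$accession == "SYNTH0001"]
        expect_equal(sel$cps, max(sel$trajectory$CPS))
        mean(planted %in% sel$features)
    }, numeric(1))
    expect_gte(sum(recovered >= 4 / 14), 8L)
    ## single feature: best subset is that feature
    fm1 <- plantedFm(20, 1, effect = 1, seed = 6)[, 1]
    rf1 <- reliefF(fm1, k = 5)
    sel1 <- forwardFeatureSelection(fm1, rf1, folds = 3, seed = 2)
    expect_identical(sel1$features, featureInfo(fm1)$feature_id)
})
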