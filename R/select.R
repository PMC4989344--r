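## Two-stage refinement: CPS-ranked greedy index selection over the
## 14-column blocks, then Relief-F / Information-Gain sequential
## best-feature construction.

#' Rank amino-acid indices by standalone cross-validated CPS
#'
#' The feature array is divided into its per-index 14-column blocks;
#' the classifier is cross-validated on each block alone and indices
#' are sorted by mean CPS, descending, ties broken by accession so the
#' ranking is deterministic.
#'
#' @param fm A labeled [FeatureMatrix-class].
#' @param spec A [classifierSpec()].
#' @param folds,iterations CV effort per block.  Ranking defaults to a
#'   single 5-fold pass to keep the sweep tractable; final model
#'   evaluation uses the full 10 iterations.
#' @param seed Integer seed.
#' @return An `IndexRanking` data.frame (`accession`, `CPS`), sorted.
#' @export
rankIndices <- function(fm, spec = classifierSpec(), folds = 5L,
                        iterations = 1L, seed = 1L) {
    stopifnot(is(fm, "FeatureMatrix"))
    accs <- indexAccessions(fm)
    cps_vals <- vapply(accs, function(a) {
        cv <- crossValidate(indexBlock(fm, a), spec, folds = folds,
                            iterations = iterations, seed = seed)
        unname(cv$mean[["CPS"]])
    }, numeric(1))
    out <- data.frame(accession = accs, CPS = unname(cps_vals),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$CPS, out$accession), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- c("IndexRanking", "data.frame")
    out
}

#' Greedy forward accumulation of ranked index blocks
#'
#' Evaluates the ranking prefixes 1..m (each prefix = the union of the
#' top-ranked 14-column blocks) and returns the prefix with maximal
#' cross-validated CPS (global argmax over all prefixes; first
#' attained on ties).  The full trajectory is returned for audit.
#'
#' @param fm A labeled [FeatureMatrix-class].
#' @param ranking An `IndexRanking` from [rankIndices()] (or any
#'   data.frame with an `accession` column ordering the sweep).
#' @param spec,folds,iterations,seed As in [rankIndices()].
#' @return List: `optimal_indices` (accessions of the best prefix),
#'   `optimal_cps`, `trajectory` (data.frame `prefix`, `accession`,
#'   `CPS`).
#' @export
forwardIndexSelection <- function(fm, ranking, spec = classifierSpec(),
                                  folds = 5L, iterations = 1L, seed = 1L) {
    accs <- ranking$accession
    if (!length(accs)) stop("empty ranking")
    traj <- vapply(seq_along(accs), function(p) {
        cv <- crossValidate(indexBlock(fm, accs[seq_len(p)]), spec,
                            folds = folds, iterations = iterations,
                            seed = seed)
        unname(cv$mean[["CPS"]])
    }, numeric(1))
    best <- which.max(traj)
    list(optimal_indices = accs[seq_len(best)],
         optimal_cps = traj[best],
         trajectory = data.frame(prefix = seq_along(accs),
                                 accession = accs, CPS = traj,
                                 stringsAsFactors = FALSE))
}

#' Relief-F feature weights
#'
#' Instance-based weighting: for each of `m` sampled instances, find
#' its `k` nearest hits (same class) and `k` nearest misses (other
#' class) by Manhattan distance on min-max-normalized features, and
#' accumulate per-feature weight `miss-differences/(m k)` minus
#' `hit-differences/(m k)`.  Weights are invariant to affine rescaling
#' of any feature; constant features get weight 0.
#'
#' @param fm A labeled [FeatureMatrix-class].
#' @param k Neighbour count (default 10).
#' @param m Instances to sample; `NULL` (default) uses all instances
#'   in order.
#' @param seed Integer seed (used only when `m` is given).
#' @return A `FeatureRanking` data.frame (`feature_id`, `weight`),
#'   sorted by weight descending, ties by feature id;
#'   `attr(, "method") == "relief_f"`.
#' @export
reliefF <- function(fm, k = 10L, m = NULL, seed = 1L) {
    stopifnot(is(fm, "FeatureMatrix"))
    y <- as.character(fm@labels)
    if (anyNA(y)) stop("Relief-F needs fully labeled data")
    if (min(table(y)) < k + 1L)
        stop("each class needs at least k+1 = ", k + 1L, " members")
    x <- fm@data
    rng <- apply(x, 2L, range)
    span <- rng[2L, ] - rng[1L, ]
    span[span == 0] <- 1
    xn <- sweep(sweep(x, 2L, rng[1L, ], "-"), 2L, span, "/")
    n <- nrow(xn)
    D <- as.matrix(stats::dist(xn, method = "manhattan"))
    sampled <- if (is.null(m)) seq_len(n)
               else withr::with_seed(as.integer(seed),
                                     sample.int(n, min(m, n)))
    mEff <- length(sampled)
    w <- numeric(ncol(xn))
    for (i in sampled) {
        same <- setdiff(which(y == y[i]), i)
        other <- which(y != y[i])
        hits <- same[order(D[i, same], same)[seq_len(k)]]
        misses <- other[order(D[i, other], other)[seq_len(k)]]
        dh <- abs(sweep(xn[hits, , drop = FALSE], 2L, xn[i, ], "-"))
        dm <- abs(sweep(xn[misses, , drop = FALSE], 2L, xn[i, ], "-"))
        w <- w + (colSums(dm) - colSums(dh)) / (mEff * k)
    }
    out <- data.frame(feature_id = featureInfo(fm)$feature_id,
                      weight = w, stringsAsFactors = FALSE)
    out <- out[order(-out$weight, out$feature_id), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "method") <- "relief_f"
    class(out) <- c("FeatureRanking", "data.frame")
    out
}

.entropy <- function(y) {
    p <- table(y) / length(y)
    p <- p[p > 0]
    -sum(p * log2(p))
}

## Fayyad-Irani entropy discretization with the MDL stopping rule;
## returns the accepted cut points (possibly none).
.mdlCuts <- function(x, y) {
    recurse <- function(idx) {
        xo <- x[idx]; yo <- y[idx]
        o <- order(xo)
        xo <- xo[o]; yo <- yo[o]
        n <- length(xo)
        if (n < 2L) return(numeric(0))
        cand <- which(diff(xo) > 0)
        if (!length(cand)) return(numeric(0))
        E <- .entropy(yo)
        bestGain <- -Inf; bestCut <- NA_real_; bestSplit <- NA_integer_
        for (ci in cand) {
            e1 <- .entropy(yo[seq_len(ci)])
            e2 <- .entropy(yo[(ci + 1L):n])
            gain <- E - (ci * e1 + (n - ci) * e2) / n
            if (gain > bestGain) {
                bestGain <- gain
                bestCut <- (xo[ci] + xo[ci + 1L]) / 2
                bestSplit <- ci
            }
        }
        k <- length(unique(yo))
        y1 <- yo[seq_len(bestSplit)]; y2 <- yo[(bestSplit + 1L):n]
        k1 <- length(unique(y1)); k2 <- length(unique(y2))
        delta <- log2(3^k - 2) -
            (k * E - k1 * .entropy(y1) - k2 * .entropy(y2))
        threshold <- (log2(n - 1) + delta) / n
        if (bestGain <= threshold) return(numeric(0))
        left <- idx[x[idx] <= bestCut]
        right <- idx[x[idx] > bestCut]
        c(recurse(left), bestCut, recurse(right))
    }
    sort(recurse(seq_along(x)))
}

#' Information-gain feature weights
#'
#' `IG(f) = H(class) - H(class | f)` with each continuous feature
#' discretized by entropy-based recursive binary splitting under the
#' MDL stopping criterion.  Features for which no split is accepted
#' get IG 0.  Deterministic.
#'
#' @param fm A labeled [FeatureMatrix-class].
#' @return A `FeatureRanking` data.frame (`feature_id`, `weight`),
#'   sorted; `attr(, "method") == "information_gain"`.
#' @export
informationGain <- function(fm) {
    stopifnot(is(fm, "FeatureMatrix"))
    y <- as.character(fm@labels)
    if (anyNA(y)) stop("information gain needs fully labeled data")
    if (length(unique(y)) < 2L) stop("single-class input")
    H <- .entropy(y)
    ig <- apply(fm@data, 2L, function(x) {
        cuts <- .mdlCuts(x, y)
        if (!length(cuts)) return(0)
        bins <- findInterval(x, cuts)
        Hc <- sum(vapply(split(y, bins), function(yy)
            length(yy) * .entropy(yy), numeric(1))) / length(y)
        H - Hc
    })
    out <- data.frame(feature_id = featureInfo(fm)$feature_id,
                      weight = unname(ig), stringsAsFactors = FALSE)
    out <- out[order(-out$weight, out$feature_id), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "method") <- "information_gain"
    class(out) <- c("FeatureRanking", "data.frame")
    out
}

#' Sequential best-feature construction over a feature ranking
#'
#' Features are added one by one from the top of the ranking; the
#' cross-validated CPS trajectory over prefixes is recorded and the
#' prefix attaining the maximum CPS is returned (features beyond that
#' point are considered irrelevant).  `step` thins the evaluated
#' prefix sizes for desk-scale runs; the full feature set is always
#' evaluated as the final prefix.
#'
#' @param fm A labeled [FeatureMatrix-class].
#' @param ranking A `FeatureRanking` from [reliefF()] or
#'   [informationGain()].
#' @param spec,folds,iterations,seed As in [rankIndices()].
#' @param step Evaluate every `step`-th prefix size (default 1).
#' @return List: `features` (feature ids of the best prefix), `cps`,
#'   `trajectory` (data.frame `prefix`, `CPS`).
#' @export
forwardFeatureSelection <- function(fm, ranking, spec = classifierSpec(),
                                    folds = 5L, iterations = 1L,
                                    seed = 1L, step = 1L) {
    fid <- ranking$feature_id
    if (!length(fid)) stop("empty ranking")
    sizes <- unique(c(seq(step, length(fid), by = step), length(fid)))
    traj <- vapply(sizes, function(p) {
        cv <- crossValidate(fm[, fid[seq_len(p)]], spec, folds = folds,
                            iterations = iterations, seed = seed)
        unname(cv$mean[["CPS"]])
    }, numeric(1))
    best <- which.max(traj)
    list(features = fid[seq_len(sizes[best])],
         cps = traj[best],
         trajectory = data.frame(prefix = sizes, CPS = traj))
}
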