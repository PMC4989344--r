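## Motif clustering of fixed-length windows by Gibbs sampling over
## position-specific scoring matrices, and cluster-aware
## under-sampling of the majority class.

.seqMatrix <- function(seqs) {
    if (any(nchar(seqs) != 15L))
        stop("all windows must be 15-mers")
    m <- matrix(match(unlist(strsplit(seqs, "")), .AA),
                nrow = length(seqs), byrow = TRUE)
    if (anyNA(m))
        stop("windows must use the standard 20-letter alphabet")
    m
}

## Pseudocounted column probabilities for one cluster: 20 x 15.
.clusterPssm <- function(sm, members, bg, beta) {
    counts <- matrix(0, 20L, ncol(sm))
    if (length(members)) {
        sub <- sm[members, , drop = FALSE]
        for (j in seq_len(ncol(sm)))
            counts[, j] <- tabulate(sub[, j], nbins = 20L)
    }
    sweep(counts + beta * bg, 2L, length(members) + beta, "/")
}

## Sum over clusters and positions of KL divergence of the
## pseudocounted column distribution from the background (bits).
.clusterObjective <- function(pssms, bg) {
    sum(vapply(pssms, function(p) {
        lr <- log2(p / bg)
        sum(p * lr)
    }, numeric(1)))
}

#' Cluster 15-mers into motif groups by Gibbs sampling
#'
#' Re-implementation of PSSM-based ungapped motif clustering: windows
#' start in random clusters; sweeps reassign every window by sampling
#' from the cluster posterior (proportional to the exponential of its
#' PSSM log-odds score over a temperature), with the temperature
#' annealed linearly from `t_start` to `t_end`, followed by a greedy
#' polish.  The assignment with the highest information-content
#' objective seen during the run is returned.  Deterministic given
#' `seed`.
#'
#' @param seqs Character vector of 15-mers (or a window data.frame).
#' @param K Number of clusters (study default 10).
#' @param iters Sampling sweeps (default 100).
#' @param seed Integer seed.
#' @param beta Pseudocount weight distributed by the background
#'   (default 50).
#' @param t_start,t_end Linear temperature schedule.
#' @return A `ClusterAssignment` list: `cluster` (integer per window),
#'   `pssms` (per-cluster 20 x 15 probability matrices), `objective`
#'   (summed per-position KL divergence from background, bits), `K`,
#'   `background`.
#' @export
clusterSequences <- function(seqs, K = 10L, iters = 100L, seed = 1L,
                             beta = 50, t_start = 1.5, t_end = 0.1) {
    if (is.data.frame(seqs)) seqs <- seqs$sequence
    K <- as.integer(K)
    if (K < 1L) stop("K must be at least 1")
    n <- length(seqs)
    if (n < K) stop("need at least K windows (", K, "), got ", n)
    sm <- .seqMatrix(seqs)
    bg <- tabulate(as.vector(sm), nbins = 20L)
    bg <- bg / sum(bg)
    bg[bg == 0] <- 1e-6           # guard rare absent residues
    bg <- bg / sum(bg)
    posIdx <- cbind(as.vector(sm), rep(seq_len(ncol(sm)), each = n))
    scoreAll <- function(assign) {
        pssms <- lapply(seq_len(K), function(k)
            .clusterPssm(sm, which(assign == k), bg, beta))
        lods <- lapply(pssms, function(p) log2(p / bg))
        sc <- vapply(lods, function(L)
            rowSums(matrix(L[posIdx], nrow = n)), numeric(n))
        list(pssms = pssms, scores = matrix(sc, nrow = n))
    }
    withr::with_seed(as.integer(seed), {
        assign <- sample.int(K, n, replace = TRUE)
        ## guarantee no empty start cluster
        assign[sample.int(n, K)] <- seq_len(K)
        best <- list(objective = -Inf, assign = assign, pssms = NULL)
        temps <- if (iters > 1L)
            seq(t_start, t_end, length.out = iters) else t_end
        track <- function(assign, st) {
            obj <- .clusterObjective(st$pssms, bg)
            if (obj > best$objective)
                best <<- list(objective = obj, assign = assign,
                              pssms = st$pssms)
        }
        for (it in seq_len(iters)) {
            st <- scoreAll(assign)
            track(assign, st)
            p <- exp((st$scores - apply(st$scores, 1L, max)) / temps[it])
            p <- p / rowSums(p)
            if (K > 1L) {
                cum <- p
                for (k in 2L:K) cum[, k] <- cum[, k - 1L] + cum[, k]
                u <- stats::runif(n) * cum[, K]
                assign <- K + 1L - rowSums(cum >= u)
            }
        }
        ## greedy polish: argmax reassignment until stable
        for (it in seq_len(25L)) {
            st <- scoreAll(assign)
            track(assign, st)
            newa <- max.col(st$scores, ties.method = "first")
            if (all(newa == assign)) break
            assign <- newa
        }
        st <- scoreAll(assign)
        track(assign, st)
    })
    structure(list(cluster = best$assign, pssms = best$pssms,
                   objective = best$objective, K = K, background = bg),
              class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
    cat(sprintf("ClusterAssignment: %d windows in %d clusters, objective %.2f bits\n",
                length(x$cluster), x$K, x$objective))
    print(table(cluster = x$cluster))
    invisible(x)
}

## Integer quotas summing exactly to `target` by largest remainder.
.largestRemainder <- function(weights, target) {
    raw <- target * weights / sum(weights)
    q <- floor(raw)
    rem <- target - sum(q)
    if (rem > 0) {
        ord <- order(raw - q, seq_along(raw), decreasing = c(TRUE, FALSE),
                     method = "radix")
        q[ord[seq_len(rem)]] <- q[ord[seq_len(rem)]] + 1
    }
    as.integer(q)
}

#' Cluster-aware under-sampling
#'
#' Draws, without replacement, a fixed total from the majority class
#' while preserving either each cluster's share (`proportional`,
#' default) or drawing equal counts per cluster (`equal`).  Quotas are
#' made to sum exactly to `target` by the largest-remainder method;
#' quotas exceeding a cluster's size spill over to the remaining
#' clusters.
#'
#' @param items Indices (or any vector) identifying the majority
#'   windows, parallel to `assignment$cluster`.
#' @param assignment A `ClusterAssignment` over the same windows.
#' @param target Number of items to keep; must not exceed
#'   `length(items)`.
#' @param seed Integer seed.
#' @param mode `"proportional"` or `"equal"` per-cluster quotas.
#' @return A subset of `items` of length exactly `target`.
#' @export
undersample <- function(items, assignment, target,
                        seed = 1L, mode = c("proportional", "equal")) {
    mode <- match.arg(mode)
    cl <- assignment$cluster
    if (length(items) != length(cl))
        stop("items and cluster assignment differ in length")
    if (target > length(items))
        stop("target exceeds the majority size")
    sizes <- tabulate(cl, nbins = assignment$K)
    weights <- if (mode == "proportional") sizes
               else as.numeric(sizes > 0L)
    quota <- .largestRemainder(weights, target)
    ## spill quota exceeding cluster size over to the other clusters
    repeat {
        over <- pmax(quota - sizes, 0L)
        if (sum(over) == 0L) break
        quota <- pmin(quota, sizes)
        room <- sizes - quota
        if (sum(room) == 0L) break
        add <- .largestRemainder(ifelse(room > 0, weights + 1e-9, 0),
                                 sum(over))
        quota <- quota + pmin(add, room)
    }
    withr::with_seed(as.integer(seed), {
        picked <- unlist(lapply(seq_len(assignment$K), function(k) {
            i <- which(cl == k)
            if (!quota[k]) return(integer(0))
            i[sample.int(length(i), quota[k])]
        }))
    })
    items[sort(picked)]
}

#' Balance a labeled dataset by clustered under-sampling
#'
#' The minority class (normally `inside`) is kept whole; the majority
#' class is clustered into `K` motif groups and under-sampled to the
#' minority size, so the two classes end up exactly equal.  The result
#' is shuffled (seeded).
#'
#' @param ws Labeled window data.frame (labels `inside`/`outside`).
#' @param K Cluster count (default 10).
#' @param seed Integer seed driving clustering, sampling and the final
#'   shuffle.
#' @param mode Per-cluster quota mode, see [undersample()].
#' @param iters Gibbs sweeps for the clustering step.
#' @return A balanced window data.frame.
#' @export
balanceDataset <- function(ws, K = 10L, seed = 1L,
                           mode = c("proportional", "equal"),
                           iters = 100L) {
    mode <- match.arg(mode)
    .checkWindows(ws, c("protein_id", "site_position", "mod_type",
                        "sequence", "label"))
    counts <- table(factor(ws$label, levels = c("inside", "outside")))
    if (any(counts == 0L))
        stop("degenerate class distribution: both classes must be non-empty")
    minority <- names(counts)[which.min(counts)]
    majority <- setdiff(c("inside", "outside"), minority)
    if (counts[[minority]] == counts[[majority]]) {
        keep <- seq_len(nrow(ws))
    } else {
        maj_idx <- which(ws$label == majority)
        cl <- clusterSequences(ws$sequence[maj_idx],
                               K = min(K, length(maj_idx)),
                               iters = iters, seed = seed)
        kept_maj <- undersample(maj_idx, cl, counts[[minority]],
                                seed = seed + 1L, mode = mode)
        keep <- sort(c(which(ws$label == minority), kept_maj))
    }
    out <- withr::with_seed(as.integer(seed) + 2L,
                            ws[sample(keep), , drop = FALSE])
    rownames(out) <- NULL
    out
}
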