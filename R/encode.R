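## Centre-subtraction encoding of 15-mers under amino-acid indices.

.REL_POS <- c(-7:-1, 1:7)          # flank positions relative to the site

.featureIds <- function(acc)
    paste0(acc, "@", ifelse(.REL_POS > 0, paste0("+", .REL_POS), .REL_POS))

#' Encode one window under one index
#'
#' Per property scale, the window's 15 residue values are reduced to
#' 14 features: the value at each flank position (1-7 and 9-15) minus
#' the value at position 8, the modified site.  The difference removes
#' the site's own contribution, leaving the flank's property relative
#' to the site.
#'
#' @param sequence A 15-residue string (or a window data.frame row's
#'   `sequence`).
#' @param idx An [AminoAcidIndex-class].
#' @return Numeric vector of length 14, named by feature id
#'   (`ACCESSION@-7` ... `ACCESSION@+7`).
#' @examples
#' encodeWindow(strrep("A", 15), kdHydropathy())   # all zeros
#' @export
encodeWindow <- function(sequence, idx) {
    stopifnot(is(idx, "AminoAcidIndex"))
    if (nchar(sequence) != 15L)
        stop("window must have exactly 15 residues, got ", nchar(sequence))
    aa <- strsplit(sequence, "")[[1L]]
    v <- indexValues(idx)[aa]
    if (anyNA(v))
        stop("residue '", aa[which(is.na(v))[1L]],
             "' undefined in index ", accession(idx))
    out <- unname(v[c(1:7, 9:15)] - v[8L])
    names(out) <- .featureIds(accession(idx))
    out
}

#' Encode a window dataset under a set of indices
#'
#' Produces the n x (14 m) feature array: one contiguous 14-column
#' block per index, blocks in the order the indices are supplied.
#' With 102 complete indices the width is 1428.  Windows containing a
#' residue undefined in any selected index are dropped with a logged
#' count rather than imputed.
#'
#' @param ws Labeled (or unlabeled) window data.frame of 15-mers.
#' @param indices List of [AminoAcidIndex-class] objects.
#' @param verbose Log the dropped-window count.
#' @return A [FeatureMatrix-class].
#' @export
encodeDataset <- function(ws, indices, verbose = FALSE) {
    .checkWindows(ws)
    if (is(indices, "AminoAcidIndex")) indices <- list(indices)
    if (!length(indices)) stop("no indices supplied")
    accs <- vapply(indices, accession, character(1))
    if (anyDuplicated(accs)) stop("duplicate index accessions")
    if (any(nchar(ws$sequence) != 15L))
        stop("all windows must be 15-mers; run filterShortWindows() first")
    aam <- do.call(rbind, strsplit(ws$sequence, ""))
    covered <- Reduce(`&`, lapply(indices, function(idx)
        matrix(aam %in% names(indexValues(idx)), nrow(aam))),
        matrix(TRUE, nrow(aam), ncol(aam)))
    ok <- rowSums(covered) == 15L
    if (verbose && any(!ok))
        message("dropping ", sum(!ok),
                " window(s) with residues undefined in the index set")
    ws <- ws[ok, , drop = FALSE]
    aam <- aam[ok, , drop = FALSE]
    blocks <- lapply(indices, function(idx) {
        v <- matrix(indexValues(idx)[aam], nrow(aam))
        v[, c(1:7, 9:15), drop = FALSE] - v[, 8L]
    })
    data <- do.call(cbind, blocks)
    features <- data.frame(
        feature_id = unlist(lapply(accs, .featureIds)),
        accession = rep(accs, each = 14L),
        position = rep(.REL_POS, length(accs)),
        stringsAsFactors = FALSE)
    rownames(features) <- NULL
    colnames(data) <- features$feature_id
    rownames(data) <- .windowId(ws)
    labels <- if ("label" %in% names(ws))
        factor(ws$label, levels = c("inside", "outside"))
    else factor(rep(NA_character_, nrow(ws)),
                levels = c("inside", "outside"))
    new("FeatureMatrix", data = data, features = features, labels = labels)
}

#' Kyte-Doolittle per-position hydropathy features
#'
#' The conventional baseline feature set: raw per-position hydropathy
#' values of the window, without centre subtraction.
#'
#' @param sequence A window sequence (any length over the standard
#'   alphabet; 15 in normal use).
#' @return Numeric vector, one hydropathy value per position.
#' @export
kdHydropathyFeatures <- function(sequence) {
    aa <- strsplit(sequence, "")[[1L]]
    v <- .KD_VALUES[aa]
    if (anyNA(v))
        stop("residue '", aa[which(is.na(v))[1L]],
             "' undefined in the Kyte-Doolittle scale")
    unname(v)
}

#' Serialize / restore a FeatureMatrix as TSV
#'
#' Header: `window_id`, `label`, then one column per feature named
#' `ACCESSION@POS`.  Values are written at full precision; column
#' identity round-trips bit-exactly.
#'
#' @param fm A [FeatureMatrix-class].
#' @param file Path.
#' @return `writeFeatureMatrix` invisibly returns `file`;
#'   `readFeatureMatrix` returns the [FeatureMatrix-class].
#' @export
writeFeatureMatrix <- function(fm, file) {
    stopifnot(is(fm, "FeatureMatrix"))
    d <- featureData(fm)
    txt <- apply(d, 2L, function(col) format(col, digits = 17L,
                                             trim = TRUE, scientific = TRUE))
    if (nrow(d) == 1L) txt <- matrix(txt, nrow = 1L)
    out <- cbind(window_id = rownames(d),
                 label = as.character(windowLabels(fm)), txt)
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(file) {
    tab <- utils::read.delim(file, stringsAsFactors = FALSE,
                             check.names = FALSE)
    fid <- setdiff(names(tab), c("window_id", "label"))
    data <- as.matrix(tab[, fid, drop = FALSE])
    rownames(data) <- tab$window_id
    at <- regmatches(fid, regexpr("@[+-]?[0-9]+$", fid))
    features <- data.frame(feature_id = fid,
                           accession = sub("@[+-]?[0-9]+$", "", fid),
                           position = as.integer(sub("@", "", at)),
                           stringsAsFactors = FALSE)
    new("FeatureMatrix", data = data, features = features,
        labels = factor(tab$label, levels = c("inside", "outside")))
}
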