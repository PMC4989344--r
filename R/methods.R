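## Accessors and show methods for the S4 containers.

#' @rdname AminoAcidIndex-class
#' @export
setMethod("accession", "AminoAcidIndex", function(object) object@accession)

#' @rdname AminoAcidIndex-class
#' @export
setMethod("indexValues", "AminoAcidIndex", function(object) object@values)

setMethod("show", "AminoAcidIndex", function(object) {
    cat("AminoAcidIndex", object@accession, "\n")
    cat(" ", object@description, "\n")
    if (!is.na(object@category))
        cat("  category:", object@category, "\n")
    print(round(object@values[.AA], 3))
})

#' @rdname Structure-class
#' @export
setMethod("structureId", "Structure", function(object) object@structureId)

#' @rdname Structure-class
#' @export
setMethod("atomTable", "Structure", function(object) object@atoms)

#' @rdname Structure-class
#' @export
setMethod("chainIds", "Structure", function(object)
    sort(unique(object@atoms$chain)))

#' One row per residue, in chain order then author numbering.
#' @rdname Structure-class
#' @export
setMethod("residueTable", "Structure", function(object) {
    a <- object@atoms
    key <- paste(a$chain, a$resno, a$insert, sep = "\r")
    first <- !duplicated(key)
    r <- a[first, c("chain", "resno", "insert", "resid")]
    r <- r[order(r$chain, r$resno, r$insert), , drop = FALSE]
    rownames(r) <- NULL
    r
})

#' @rdname Structure-class
#' @export
setMethod("chainSequences", "Structure", function(object) {
    r <- residueTable(object)
    vapply(split(r, r$chain), function(ch)
        paste(threeToOne(ch$resid), collapse = ""), character(1))
})

setMethod("show", "Structure", function(object) {
    r <- residueTable(object)
    cat("Structure", object@structureId, "--",
        nrow(object@atoms), "atoms,",
        nrow(r), "residues,",
        length(unique(r$chain)), "chain(s):",
        paste(sort(unique(r$chain)), collapse = " "), "\n")
})

#' @rdname PpirMap-class
#' @export
setMethod("residueMap", "PpirMap", function(object) object@residues)

#' @rdname PpirMap-class
#' @export
setMethod("contactPairs", "PpirMap", function(object) object@contacts)

#' @rdname PpirMap-class
#' @export
setMethod("chainSequences", "PpirMap", function(object) object@sequences)

setMethod("show", "PpirMap", function(object) {
    r <- object@residues
    cat("PpirMap:", length(unique(r$structure_id)), "structure(s),",
        length(object@sequences), "chain(s),", nrow(r), "residues;",
        sum(r$interacting), "interacting",
        sprintf("(%.1f%%)\n", 100 * mean(r$interacting)))
})

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureInfo", "FeatureMatrix", function(object) object@features)

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureData", "FeatureMatrix", function(object) object@data)

#' @rdname FeatureMatrix-class
#' @export
setMethod("windowLabels", "FeatureMatrix", function(object) {
    structure(object@labels, names = rownames(object@data))
})

#' @rdname FeatureMatrix-class
#' @export
setMethod("indexAccessions", "FeatureMatrix", function(object)
    unique(object@features$accession))

#' @rdname FeatureMatrix-class
#' @export
setMethod("dim", "FeatureMatrix", function(x) dim(x@data))

#' Subset windows (i) and features (j); drops nothing silently.
#' @rdname FeatureMatrix-class
#' @param i,j Row (window) and column (feature) indices.
#' @param ...,drop Ignored; kept for generic compatibility.
#' @export
setMethod("[", "FeatureMatrix", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@data))
    if (missing(j)) j <- seq_len(ncol(x@data))
    if (is.character(j)) j <- match(j, x@features$feature_id)
    new("FeatureMatrix",
        data = x@data[i, j, drop = FALSE],
        features = {
            f <- x@features[j, , drop = FALSE]
            rownames(f) <- NULL
            f
        },
        labels = x@labels[if (is.character(i)) match(i, rownames(x@data)) else i])
})

#' Restrict to the contiguous 14-column blocks of the given accessions,
#' preserving the original block order.
#' @rdname FeatureMatrix-class
#' @export
setMethod("indexBlock", "FeatureMatrix", function(object, accessions) {
    miss <- setdiff(accessions, object@features$accession)
    if (length(miss))
        stop("unknown index accession(s): ", paste(miss, collapse = ", "))
    object[, which(object@features$accession %in% accessions)]
})

setMethod("show", "FeatureMatrix", function(object) {
    lab <- table(object@labels, useNA = "ifany")
    cat("FeatureMatrix:", nrow(object@data), "windows x",
        ncol(object@data), "features",
        sprintf("(%d indices x 14 positions)\n",
                length(unique(object@features$accession))))
    cat("  labels:", paste(names(lab), lab, sep = "=", collapse = " "), "\n")
})
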