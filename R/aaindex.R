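#' Parse an AAindex1 flat file
#'
#' Reads records delimited by `//`.  Each record must carry an `H`
#' (accession), `D` (description) and `I` line; the two rows following
#' the `I` header hold 10 values each in the standard column order
#' (A R N D C Q E G H I / L K M F P S T W Y V).
#'
#' Scales with missing (`NA`) cells cannot feed the centre-subtraction
#' encoding; by default they are silently excluded, matching the use of
#' complete property scales throughout the pipeline.
#'
#' @param file Path to an AAindex1 flat file, or a character vector of
#'   lines.
#' @param drop_na If `TRUE` (default), records containing `NA` values
#'   are excluded; if `FALSE`, such a record raises an error.
#' @return A named list of [AminoAcidIndex-class] objects, in file
#'   order, named by accession.
#' @examples
#' kd <- parseAAindex(system.file("extdata", "kyte_doolittle.aaindex",
#'                                package = "ppirpredict"))
#' indexValues(kd[[1]])[["I"]]   # 4.5
#' @export
parseAAindex <- function(file, drop_na = TRUE) {
    lines <- if (length(file) == 1L && file.exists(file))
        readLines(file) else file
    recs <- split(lines, cumsum(c(0L, head(trimws(lines) == "//", -1L))))
    out <- list()
    for (rec in recs) {
        rec <- rec[trimws(rec) != "//"]
        if (!any(grepl("^H ", rec))) next
        acc <- trimws(sub("^H ", "", rec[grep("^H ", rec)[1L]]))
        dlin <- grep("^D ", rec)
        desc <- if (length(dlin)) trimws(sub("^D ", "", rec[dlin[1L]])) else ""
        ipos <- grep("^I ", rec)
        if (!length(ipos) || ipos[1L] + 2L > length(rec))
            stop("malformed record (no I value rows): ", acc)
        cells <- unlist(strsplit(trimws(rec[ipos[1L] + (1:2)]), "[[:space:]]+"))
        if (length(cells) != 20L)
            stop("malformed I line for ", acc, ": expected 20 cells, got ",
                 length(cells))
        vals <- suppressWarnings(as.numeric(cells))
        bad <- is.na(vals) & !(cells %in% c("NA", "na", "-"))
        if (any(bad))
            stop("malformed I line for ", acc, ": unparseable cell '",
                 cells[which(bad)[1L]], "'")
        names(vals) <- .AAINDEX_ORDER
        if (anyNA(vals)) {
            if (drop_na) next
            stop("index ", acc, " contains NA values")
        }
        if (acc %in% names(out))
            stop("duplicate accession: ", acc)
        out[[acc]] <- new("AminoAcidIndex", accession = acc,
                          description = desc, values = vals[.AA],
                          category = NA_character_)
    }
    out
}

#' Write amino-acid indices in AAindex1 flat-file format
#'
#' Values are written at full precision so that
#' `parseAAindex(writeAAindex(x))` round-trips exactly.
#'
#' @param indices List of [AminoAcidIndex-class] objects.
#' @param file Output path; when `NULL` the lines are returned.
#' @return Invisibly (or visibly for `file = NULL`), the lines written.
#' @export
writeAAindex <- function(indices, file = NULL) {
    fmt <- function(x) vapply(x, function(v) format(v, digits = 17L),
                              character(1))
    lines <- unlist(lapply(indices, function(idx) {
        v <- indexValues(idx)[.AAINDEX_ORDER]
        c(paste("H", accession(idx)),
          paste("D", idx@description),
          "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
          paste0("     ", paste(fmt(v[1:10]), collapse = "  ")),
          paste0("     ", paste(fmt(v[11:20]), collapse = "  ")),
          "//")
    }))
    if (is.null(file)) return(lines)
    writeLines(lines, file)
    invisible(lines)
}

## Kyte-Doolittle hydropathy scale (KYTJ820101).
.KD_VALUES <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
                Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
                L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
                S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

#' The Kyte-Doolittle hydropathy scale
#'
#' Shipped as the conventional per-position hydropathy baseline and as
#' a real, complete property scale for examples.
#'
#' @return An [AminoAcidIndex-class] (accession `KYTJ820101`).
#' @export
kdHydropathy <- function() {
    new("AminoAcidIndex", accession = "KYTJ820101",
        description = "Hydropathy index (Kyte-Doolittle, 1982)",
        values = .KD_VALUES[.AA], category = "hydrophobicity")
}
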