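## Modification-site window tables.
##
## Windows are plain data.frames with the column contract
##   protein_id, site_position, mod_type, sequence, label
## (label optional / NA when unknown).  The modified residue sits at
## window position 8 with up to +/-7 flanking residues.

.windowId <- function(ws)
    paste(ws$protein_id, ws$site_position, ws$mod_type, sep = "|")

.checkWindows <- function(ws, need = c("protein_id", "site_position",
                                       "mod_type", "sequence")) {
    if (!is.data.frame(ws))
        stop("windows must be a data.frame")
    miss <- setdiff(need, names(ws))
    if (length(miss))
        stop("window table lacks column(s): ", paste(miss, collapse = ", "))
    invisible(ws)
}

#' Read a PTM window table
#'
#' Reads a tab-separated modification-site export (PhosphoSitePlus
#' style).  Column names vary across exports, so the mapping from file
#' columns to the internal contract is configuration.  The reader does
#' not filter: short windows, padding characters and unknown residues
#' are passed through verbatim (see [filterShortWindows()]); sequences
#' are uppercased.
#'
#' @param file Path to a TSV file with a header row.
#' @param columns Named character vector mapping internal names
#'   (`protein_id`, `position`, `mod_type`, `sequence`, optionally
#'   `label`) to the file's column names.
#' @return A window data.frame (`protein_id`, `site_position`,
#'   `mod_type`, `sequence`, `label`).
#' @export
readPtmWindows <- function(file,
                           columns = c(protein_id = "protein_id",
                                       position = "site_position",
                                       mod_type = "mod_type",
                                       sequence = "sequence",
                                       label = "label")) {
    tab <- utils::read.delim(file, stringsAsFactors = FALSE,
                             check.names = FALSE)
    need <- c("protein_id", "position", "mod_type", "sequence")
    miss <- setdiff(need, names(columns))
    if (length(miss))
        stop("column mapping lacks: ", paste(miss, collapse = ", "))
    absent <- setdiff(unname(columns[need]), names(tab))
    if (length(absent))
        stop("mapped column(s) not in file: ", paste(absent, collapse = ", "))
    out <- data.frame(
        protein_id = as.character(tab[[columns[["protein_id"]]]]),
        site_position = as.integer(tab[[columns[["position"]]]]),
        mod_type = as.character(tab[[columns[["mod_type"]]]]),
        sequence = toupper(as.character(tab[[columns[["sequence"]]]])),
        stringsAsFactors = FALSE)
    out$label <- if ("label" %in% names(columns) &&
                     columns[["label"]] %in% names(tab))
        as.character(tab[[columns[["label"]]]]) else NA_character_
    out
}

#' Write / read the internal labeled-window TSV
#'
#' Fixed five-column format: `protein_id`, `site_position`, `mod_type`,
#' `sequence`, `label`.
#'
#' @param ws Window data.frame.
#' @param file Path.
#' @return `writeWindows` invisibly returns `file`; `readWindows`
#'   returns the window data.frame.
#' @export
writeWindows <- function(ws, file) {
    .checkWindows(ws)
    cols <- c("protein_id", "site_position", "mod_type", "sequence", "label")
    if (!"label" %in% names(ws)) ws$label <- NA_character_
    utils::write.table(ws[, cols], file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname writeWindows
#' @export
readWindows <- function(file) {
    ws <- utils::read.delim(file, stringsAsFactors = FALSE)
    ws$label[ws$label %in% c("", "NA")] <- NA_character_
    .checkWindows(ws)
}

#' Keep only complete 15-residue windows
#'
#' Sites near protein termini yield windows shorter than 15 residues
#' or padded with placeholder characters; these cannot be encoded and
#' are removed.  Order is preserved.
#'
#' @param ws Window data.frame.
#' @return The subset with 15-residue sequences over the standard
#'   20-letter alphabet.
#' @export
filterShortWindows <- function(ws) {
    .checkWindows(ws)
    ok <- nchar(ws$sequence) == 15L &
        grepl(paste0("^[", paste(.AA, collapse = ""), "]+$"), ws$sequence)
    out <- ws[ok, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Split labeled windows into per-modification datasets
#'
#' @param ws Window data.frame.
#' @return Named list of window data.frames, one per `mod_type`
#'   present; part sizes sum to `nrow(ws)`.
#' @export
segregateByModType <- function(ws) {
    .checkWindows(ws)
    lapply(split(seq_len(nrow(ws)), ws$mod_type), function(i) {
        out <- ws[i, , drop = FALSE]
        rownames(out) <- NULL
        out
    })
}
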