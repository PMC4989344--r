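## Van der Waals contact detection and the per-residue interface map.

#' Default per-element Van der Waals radii (Angstrom)
#'
#' A single published per-element table (Bondi radii for the elements
#' that occur in protein heavy atoms) makes the overlap rule explicit
#' and reproducible; both the table and the tolerance are arguments of
#' the contact detector.
#'
#' @return Named numeric vector of radii in Angstrom.
#' @export
vdwRadii <- function() {
    c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, SE = 1.90)
}

#' Detect inter-chain Van der Waals contacts
#'
#' A residue pair (on *different* chains) is a contact when some pair
#' of heavy atoms sits closer than the sum of their Van der Waals radii
#' plus `tolerance`.  Contacts within a single polypeptide chain are
#' never reported; each unordered pair is reported once.
#'
#' @param s A [Structure-class].
#' @param radii Named per-element radii table (Angstrom).
#' @param tolerance Slack added to the summed radii (Angstrom);
#'   0 means strict surface overlap.
#' @return data.frame of contact pairs: `chain_a`, `resno_a`,
#'   `insert_a`, `chain_b`, `resno_b`, `insert_b`, `min_gap` where
#'   `min_gap` is the minimum over atom pairs of distance minus summed
#'   radii (negative = overlapping surfaces).
#' @export
detectContacts <- function(s, radii = vdwRadii(), tolerance = 0) {
    a <- atomTable(s)
    unknown <- setdiff(unique(a$element), names(radii))
    if (length(unknown))
        stop("no Van der Waals radius for element(s): ",
             paste(unknown, collapse = ", "))
    a$radius <- radii[a$element]
    chains <- sort(unique(a$chain))
    empty <- data.frame(chain_a = character(0), resno_a = integer(0),
                        insert_a = character(0), chain_b = character(0),
                        resno_b = integer(0), insert_b = character(0),
                        min_gap = numeric(0), stringsAsFactors = FALSE)
    if (length(chains) < 2L) return(empty)
    out <- list()
    for (i in seq_along(chains)[-length(chains)]) {
        ai <- a[a$chain == chains[i], , drop = FALSE]
        for (j in (i + 1L):length(chains)) {
            aj <- a[a$chain == chains[j], , drop = FALSE]
            dx <- outer(ai$x, aj$x, "-")
            dy <- outer(ai$y, aj$y, "-")
            dz <- outer(ai$z, aj$z, "-")
            gap <- sqrt(dx * dx + dy * dy + dz * dz) -
                outer(ai$radius, aj$radius, "+")
            hit <- which(gap < tolerance, arr.ind = TRUE)
            if (!nrow(hit)) next
            pairs <- data.frame(
                chain_a = chains[i],
                resno_a = ai$resno[hit[, 1L]],
                insert_a = ai$insert[hit[, 1L]],
                chain_b = chains[j],
                resno_b = aj$resno[hit[, 2L]],
                insert_b = aj$insert[hit[, 2L]],
                gap = gap[hit], stringsAsFactors = FALSE)
            key <- paste(pairs$resno_a, pairs$insert_a,
                         pairs$resno_b, pairs$insert_b, sep = "\r")
            agg <- tapply(pairs$gap, key, min)
            first <- pairs[!duplicated(key), , drop = FALSE]
            first$min_gap <- as.numeric(agg[paste(first$resno_a, first$insert_a,
                                                  first$resno_b, first$insert_b,
                                                  sep = "\r")])
            first$gap <- NULL
            out[[length(out) + 1L]] <- first
        }
    }
    if (!length(out)) return(empty)
    res <- do.call(rbind, out)
    res <- res[order(res$chain_a, res$resno_a, res$insert_a,
                     res$chain_b, res$resno_b, res$insert_b), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Build the protein-protein interacting-region map
#'
#' Structures with fewer than two chains have no interacting partner
#' and are dropped.  Every residue of every retained chain is recorded
#' with an interacting flag: `TRUE` when it participates in at least
#' one inter-chain Van der Waals contact.  Supplying the same
#' structure twice is idempotent.
#'
#' @param structures List of [Structure-class] objects (pre-validated;
#'   see [validateStructure()]).
#' @param radii,tolerance Passed to [detectContacts()].
#' @param verbose Log retention counts with `message()`.
#' @return A [PpirMap-class].
#' @export
buildPpirMap <- function(structures, radii = vdwRadii(), tolerance = 0,
                         verbose = FALSE) {
    if (is(structures, "Structure")) structures <- list(structures)
    seen <- character(0)
    res_list <- list()
    con_list <- list()
    seqs <- character(0)
    n_dropped <- 0L
    for (s in structures) {
        sid <- structureId(s)
        if (sid %in% seen) next        # idempotent union
        r <- residueTable(s)
        if (length(unique(r$chain)) < 2L) {
            n_dropped <- n_dropped + 1L
            next
        }
        seen <- c(seen, sid)
        cc <- detectContacts(s, radii, tolerance)
        ckey <- c(paste(cc$chain_a, cc$resno_a, cc$insert_a, sep = "\r"),
                  paste(cc$chain_b, cc$resno_b, cc$insert_b, sep = "\r"))
        pos <- unlist(lapply(split(seq_len(nrow(r)), r$chain), seq_along),
                      use.names = FALSE)
        resdf <- data.frame(structure_id = sid,
                            chain = r$chain, resno = r$resno,
                            insert = r$insert,
                            aa = threeToOne(r$resid),
                            seq_pos = pos,
                            interacting = paste(r$chain, r$resno, r$insert,
                                                sep = "\r") %in% ckey,
                            stringsAsFactors = FALSE)
        res_list[[sid]] <- resdf
        if (nrow(cc))
            con_list[[sid]] <- cbind(structure_id = sid, cc,
                                     stringsAsFactors = FALSE)
        sq <- vapply(split(resdf$aa, resdf$chain), paste,
                     character(1), collapse = "")
        names(sq) <- paste(sid, names(sq), sep = "|")
        seqs <- c(seqs, sq)
    }
    if (!length(res_list))
        stop("no interacting structures (every input has < 2 chains)")
    residues <- do.call(rbind, res_list)
    rownames(residues) <- NULL
    contacts <- if (length(con_list)) {
        x <- do.call(rbind, con_list)
        rownames(x) <- NULL
        x
    } else data.frame(structure_id = character(0), chain_a = character(0),
                      resno_a = integer(0), insert_a = character(0),
                      chain_b = character(0), resno_b = integer(0),
                      insert_b = character(0), min_gap = numeric(0),
                      stringsAsFactors = FALSE)
    if (verbose)
        message(sprintf(
            "PPIR map: %d structure(s) retained, %d dropped; %d/%d residues interacting (%.1f%%)",
            length(res_list), n_dropped, sum(residues$interacting),
            nrow(residues), 100 * mean(residues$interacting)))
    new("PpirMap", residues = residues, contacts = contacts,
        sequences = seqs)
}

#' Label windows by exact matching against the PPIR map
#'
#' A window is retained when its 15-mer occurs as an exact contiguous
#' substring of at least one chain sequence in the map (windows with
#' no structural match are removed).  The label is `inside` when, in
#' at least one match, the residue aligned with window position 8 is
#' flagged interacting; otherwise `outside`.  Output is non-redundant
#' per (protein, position, modification type).
#'
#' @param ws Length-filtered window data.frame (see
#'   [filterShortWindows()]).
#' @param map A [PpirMap-class].
#' @return Labeled window data.frame with a `provenance` column
#'   listing the matched centre residues
#'   (`structure|chain:resno` entries, `;`-separated).
#' @export
labelWindows <- function(ws, map) {
    .checkWindows(ws)
    stopifnot(is(map, "PpirMap"))
    seqs <- map@sequences
    r <- map@residues
    flag <- split(r$interacting,
                  paste(r$structure_id, r$chain, sep = "|"))
    rno <- split(paste0(r$resno, r$insert),
                 paste(r$structure_id, r$chain, sep = "|"))
    aaset <- Biostrings::AAStringSet(seqs)
    keep <- logical(nrow(ws))
    lab <- character(nrow(ws))
    prov <- character(nrow(ws))
    for (i in seq_len(nrow(ws))) {
        w <- ws$sequence[i]
        hits <- Biostrings::vmatchPattern(w, aaset)
        starts <- S4Vectors::elementNROWS(hits)
        if (!any(starts > 0L)) next
        inside <- FALSE
        pv <- character(0)
        for (ch in which(starts > 0L)) {
            chkey <- names(seqs)[ch]
            for (st in BiocGenerics::start(hits[[ch]])) {
                centre <- st + 7L
                if (flag[[chkey]][centre]) inside <- TRUE
                pv <- c(pv, paste0(chkey, ":", rno[[chkey]][centre]))
            }
        }
        keep[i] <- TRUE
        lab[i] <- if (inside) "inside" else "outside"
        prov[i] <- paste(pv, collapse = ";")
    }
    out <- ws[keep, , drop = FALSE]
    out$label <- lab[keep]
    out$provenance <- prov[keep]
    out <- out[!duplicated(.windowId(out)), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Export / import a PPIR map as TSV
#'
#' BED-like per-residue table: `structure_id`, `chain`,
#' `residue_number` (author number with insertion code appended),
#' `residue` (one-letter), `interacting` (0/1).  Contact pairs are not
#' serialized; a reloaded map supports window labeling but not contact
#' inspection.
#'
#' @param map A [PpirMap-class].
#' @param file Path.
#' @return `writePpirMap` invisibly returns `file`; `readPpirMap`
#'   returns a [PpirMap-class].
#' @export
writePpirMap <- function(map, file) {
    r <- residueMap(map)
    out <- data.frame(structure_id = r$structure_id, chain = r$chain,
                      residue_number = paste0(r$resno, r$insert),
                      residue = r$aa,
                      interacting = as.integer(r$interacting))
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' @rdname writePpirMap
#' @export
readPpirMap <- function(file) {
    tab <- utils::read.delim(file, stringsAsFactors = FALSE,
                             colClasses = c(residue_number = "character"))
    resno <- as.integer(sub("([0-9-]+).*", "\\1", tab$residue_number))
    insert <- sub("^[0-9-]+", "", tab$residue_number)
    ckey <- paste(tab$structure_id, tab$chain, sep = "|")
    pos <- unlist(lapply(split(seq_len(nrow(tab)), ckey)[unique(ckey)],
                         seq_along), use.names = FALSE)
    residues <- data.frame(structure_id = tab$structure_id,
                           chain = tab$chain, resno = resno,
                           insert = insert, aa = tab$residue,
                           seq_pos = pos,
                           interacting = tab$interacting == 1L,
                           stringsAsFactors = FALSE)
    seqs <- vapply(split(residues$aa, ckey)[unique(ckey)], paste,
                   character(1), collapse = "")
    new("PpirMap", residues = residues,
        contacts = data.frame(structure_id = character(0),
                              chain_a = character(0), resno_a = integer(0),
                              insert_a = character(0), chain_b = character(0),
                              resno_b = integer(0), insert_b = character(0),
                              min_gap = numeric(0), stringsAsFactors = FALSE),
        sequences = seqs)
}
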