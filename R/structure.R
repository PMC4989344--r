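## PDB coordinate handling.  Parsing is delegated to bio3d; this layer
## applies the pipeline's own retention rules: first model only, heavy
## atoms only, no waters, altLoc resolved to the highest-occupancy
## conformer (ties: first seen).

.AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Map 3-letter residue names to one-letter codes
#'
#' Non-standard names map to `"X"`, which deliberately breaks exact
#' 15-mer matching at that position.
#'
#' @param resid Character vector of 3-letter residue names.
#' @return Character vector of one-letter codes.
#' @export
threeToOne <- function(resid) {
    out <- .AA3TO1[toupper(resid)]
    out[is.na(out)] <- "X"
    unname(out)
}

.WATER <- c("HOH", "DOD", "WAT", "H2O")

#' Read a PDB coordinate file into a Structure
#'
#' Only the first MODEL is read; hydrogens (and deuterium) and water
#' molecules are excluded; for alternate locations the
#' highest-occupancy conformer of each atom is kept (ties broken by
#' file order).  Residues are keyed by author chain id, author residue
#' number and insertion code.
#'
#' @param file Path to a PDB-format file.
#' @param structure_id Identifier; defaults to the file stem.
#' @return A [Structure-class].
#' @export
readStructure <- function(file, structure_id = NULL) {
    if (is.null(structure_id))
        structure_id <- sub("\\.(pdb|ent)$", "", basename(file),
                            ignore.case = TRUE)
    pdb <- try(suppressWarnings(suppressMessages(
        bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE,
                        rm.insert = FALSE, verbose = FALSE))),
        silent = TRUE)
    if (inherits(pdb, "try-error") || nrow(pdb$atom) == 0L)
        stop("empty structure: no ATOM records in ", file)
    a <- pdb$atom
    bad <- which(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z))
    if (length(bad))
        stop("unparseable coordinate field at atom record ",
             a$eleno[bad[1L]], " of ", file)
    element <- toupper(a$elesy)
    guess <- is.na(element) | element == ""
    if (any(guess)) {
        nm <- gsub("[0-9']", "", a$elety[guess])
        element[guess] <- toupper(substr(nm, 1L, 1L))
    }
    a$element <- element
    keep <- !(a$element %in% c("H", "D")) & !(a$resid %in% .WATER)
    a <- a[keep, , drop = FALSE]
    if (nrow(a) == 0L)
        stop("empty structure: no heavy protein/ligand atoms in ", file)
    a$insert[is.na(a$insert)] <- ""
    a$alt[is.na(a$alt)] <- ""
    a$o[is.na(a$o)] <- 1
    ## altLoc: among labelled conformers of one atom site keep the
    ## highest-occupancy record (ties: first seen).  Unlabelled
    ## duplicates are retained for validateStructure() to flag.
    has_alt <- a$alt != ""
    if (any(has_alt)) {
        akey <- paste(a$chain, a$resno, a$insert, a$elety, sep = "\r")
        pos <- seq_len(nrow(a))
        ord <- order(akey, -a$o, pos)
        dup_alt <- pos %in% pos[ord][duplicated(akey[ord]) & has_alt[ord]]
        a <- a[!(has_alt & dup_alt), , drop = FALSE]
    }
    atoms <- data.frame(chain = as.character(a$chain),
                        resno = as.integer(a$resno),
                        insert = as.character(a$insert),
                        resid = as.character(a$resid),
                        elety = as.character(a$elety),
                        element = as.character(a$element),
                        x = a$x, y = a$y, z = a$z,
                        occupancy = a$o,
                        stringsAsFactors = FALSE)
    rownames(atoms) <- NULL
    new("Structure", structureId = structure_id, atoms = atoms)
}

#' Check a Structure for usable format
#'
#' Reporting operation (never throws): flags duplicated residue keys
#' (same chain/number/insert under two residue names), chains without
#' a single standard protein residue, and structures whose residue
#' names are all unknown.  Single-chain structures pass here; the
#' interacting-partner requirement is applied by [buildPpirMap()].
#'
#' @param s A [Structure-class].
#' @return A list with elements `pass` (logical) and `reasons`
#'   (character vector, empty when passing).
#' @export
validateStructure <- function(s) {
    stopifnot(is(s, "Structure"))
    r <- residueTable(s)
    reasons <- character(0)
    ## same residue key carrying two residue names = mislabeled chain
    a <- s@atoms
    combo <- unique(paste(a$chain, a$resno, a$insert, a$resid, sep = "\r"))
    key <- sub("\r[^\r]*$", "", combo)
    if (anyDuplicated(key))
        reasons <- c(reasons, "duplicate residue key")
    known <- r$resid %in% names(.AA3TO1)
    if (!any(known))
        reasons <- c(reasons, "all residue names unknown")
    perchain <- tapply(known, r$chain, sum)
    if (any(perchain < 1L))
        reasons <- c(reasons,
                     paste0("chain without protein residues: ",
                            paste(names(perchain)[perchain < 1L],
                                  collapse = ",")))
    list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Write a Structure as PDB-format text
#'
#' Minimal ATOM-record writer (element column included) so synthetic
#' complexes can round-trip through [readStructure()].
#'
#' @param s A [Structure-class].
#' @param file Output path, or `NULL` to return the lines.
#' @return The lines, invisibly when written to a file.
#' @export
writeStructurePDB <- function(s, file = NULL) {
    a <- atomTable(s)
    lines <- sprintf(
        "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        seq_len(nrow(a)),
        ifelse(nchar(a$elety) < 4L, paste0(" ", a$elety), a$elety),
        a$resid, a$chain, a$resno,
        ifelse(a$insert == "", " ", a$insert),
        a$x, a$y, a$z, a$occupancy, 0, a$element)
    lines <- c(lines, "END")
    if (is.null(file)) return(lines)
    writeLines(lines, file)
    invisible(lines)
}
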