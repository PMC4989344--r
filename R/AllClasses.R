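#' @import methods
NULL

## Standard one-letter residue alphabet, alphabetical order.
.AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## AAindex1 I-line column order: first row A R N D C Q E G H I,
## second row L K M F P S T W Y V.
.AAINDEX_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.MOD_TYPES <- c("acetylation", "methylation", "O-GalNAc", "O-GlcNAc",
                "phosphorylation", "sumoylation", "ubiquitylation")

#' AminoAcidIndex: one numeric amino-acid property scale
#'
#' A single AAindex1-style scale: one real value per standard residue.
#' Scales carrying missing values are rejected by the validity method,
#' because the centre-subtraction encoding is undefined for them.
#'
#' @slot accession Short identifier (e.g. \code{"KYTJ820101"}).
#' @slot description Free-text description of the property.
#' @slot values Named numeric vector of length 20, names the standard
#'   one-letter residue codes, all values finite.
#' @slot category Optional property tag (e.g. \code{"hydrophobicity"});
#'   \code{NA} when untagged.
#'
#' @seealso [parseAAindex()], [indexValues()]
#' @export
setClass("AminoAcidIndex",
    representation(accession = "character",
                   description = "character",
                   values = "numeric",
                   category = "character"))

setValidity("AminoAcidIndex", function(object) {
    v <- object@values
    if (length(v) != 20L)
        return("'values' must hold exactly 20 residues")
    if (!setequal(names(v), .AA))
        return("'values' must be named by the 20 standard one-letter codes")
    if (anyNA(v) || any(!is.finite(v)))
        return("all index values must be finite")
    if (length(object@accession) != 1L || !nzchar(object@accession))
        return("'accession' must be a single non-empty string")
    TRUE
})

#' Structure: heavy-atom coordinates grouped into chains and residues
#'
#' A minimal coordinate model: the heavy atoms of the first model of a
#' PDB entry, with author chain identifiers and author residue
#' numbering (plus insertion codes) as the authoritative residue keys.
#'
#' @slot structureId Identifier (usually the file stem).
#' @slot atoms A data.frame with one row per retained atom and columns
#'   \code{chain}, \code{resno}, \code{insert}, \code{resid} (3-letter
#'   residue name), \code{elety} (atom name), \code{element},
#'   \code{x}, \code{y}, \code{z} (Angstrom), \code{occupancy}.
#'
#' @seealso [readStructure()], [chainSequences()], [detectContacts()]
#' @export
setClass("Structure",
    representation(structureId = "character",
                   atoms = "data.frame"))

setValidity("Structure", function(object) {
    a <- object@atoms
    need <- c("chain", "resno", "insert", "resid", "elety", "element",
              "x", "y", "z", "occupancy")
    if (!all(need %in% names(a)))
        return(paste("atoms must have columns:", paste(need, collapse = ", ")))
    if (nrow(a) == 0L)
        return("empty structure")
    if (any(!is.finite(a$x)) || any(!is.finite(a$y)) || any(!is.finite(a$z)))
        return("all coordinates must be finite")
    TRUE
})

#' PpirMap: per-residue interface assignments across structures
#'
#' For every residue of every retained chain, records whether the
#' residue participates in at least one inter-chain Van der Waals
#' contact, together with the derived one-letter chain sequences used
#' for exact window matching.
#'
#' @slot residues data.frame: \code{structure_id}, \code{chain},
#'   \code{resno}, \code{insert}, \code{aa} (one-letter, \code{X} for
#'   non-standard residue names), \code{seq_pos} (1-based position in
#'   the chain sequence), \code{interacting} (logical).
#' @slot contacts data.frame of unordered inter-chain residue pairs:
#'   \code{structure_id}, \code{chain_a}, \code{resno_a},
#'   \code{insert_a}, \code{chain_b}, \code{resno_b}, \code{insert_b},
#'   \code{min_gap} (Angstrom; minimum over heavy-atom pairs of
#'   distance minus summed radii).  May be empty for maps restored
#'   from disk.
#' @slot sequences Named character vector of chain sequences, names
#'   \code{"<structure_id>|<chain>"}.
#'
#' @seealso [buildPpirMap()], [labelWindows()], [writePpirMap()]
#' @export
setClass("PpirMap",
    representation(residues = "data.frame",
                   contacts = "data.frame",
                   sequences = "character"))

setValidity("PpirMap", function(object) {
    r <- object@residues
    need <- c("structure_id", "chain", "resno", "insert", "aa",
              "seq_pos", "interacting")
    if (!all(need %in% names(r)))
        return(paste("residues must have columns:", paste(need, collapse = ", ")))
    key <- paste(r$structure_id, r$chain, r$resno, r$insert)
    if (anyDuplicated(key))
        return("duplicate residue key in map")
    cc <- object@contacts
    if (nrow(cc) > 0L) {
        if (any(cc$chain_a == cc$chain_b))
            return("contacts must join residues on different chains")
        ckey <- c(paste(cc$structure_id, cc$chain_a, cc$resno_a, cc$insert_a),
                  paste(cc$structure_id, cc$chain_b, cc$resno_b, cc$insert_b))
        flagged <- key[r$interacting]
        if (!all(flagged %in% ckey))
            return("every interacting residue needs a stored contact partner")
    }
    TRUE
})

#' FeatureMatrix: encoded windows with feature provenance
#'
#' Rows are modification-site windows; columns are
#' (index accession, relative position) features from the
#' centre-subtraction encoding.  Column order is index order times
#' position order (-7..-1, +1..+7) and travels with the matrix.
#'
#' @slot data Numeric matrix, rownames = window ids
#'   (\code{protein|position|modtype}), colnames = feature ids
#'   (\code{ACCESSION@POS}).
#' @slot features data.frame with one row per column: \code{feature_id},
#'   \code{accession}, \code{position} (integer in -7..-1, 1..7).
#' @slot labels Factor with levels \code{inside}, \code{outside}
#'   (positive class first); may contain \code{NA} for unlabeled rows.
#'
#' @seealso [encodeDataset()], [indexBlock()], [writeFeatureMatrix()]
#' @export
setClass("FeatureMatrix",
    representation(data = "matrix",
                   features = "data.frame",
                   labels = "factor"))

setValidity("FeatureMatrix", function(object) {
    d <- object@data
    f <- object@features
    if (ncol(d) != nrow(f))
        return("feature table must describe every column")
    if (!identical(colnames(d), f$feature_id))
        return("colnames must equal the feature_id column, in order")
    if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
        return("rows must carry unique window ids")
    if (length(object@labels) != nrow(d))
        return("one label per row required")
    if (!identical(levels(object@labels), c("inside", "outside")))
        return("label levels must be c('inside', 'outside')")
    TRUE
})
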