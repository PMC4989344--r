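## Shared fixture builders; everything is generated in code.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## A complete toy index: constant `base` except for named overrides.
toyIndex <- function(accession, base = 1, ...) {
    v <- stats::setNames(rep(base, 20), AA20)
    ov <- c(...)
    v[names(ov)] <- ov
    new("AminoAcidIndex", accession = accession, description = "toy",
        values = v, category = NA_character_)
}

## Hand-written 3-record AAindex fixture, one record with an NA cell.
aaindexFixtureLines <- function() {
    c("H TOYA000001",
      "D constant unit index",
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      "     1.0  1.0  1.0  1.0  1.0  1.0  1.0  1.0  1.0  1.0",
      "     1.0  1.0  1.0  1.0  1.0  1.0  1.0  1.0  1.0  1.0",
      "//",
      "H TOYB000001",
      "D ramp index",
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      "     1  2  3  4  5  6  7  8  9  10",
      "     11  12  13  14  15  16  17  18  19  20",
      "//",
      "H TOYC000001",
      "D incomplete index",
      "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
      "     1.0  NA  1.0  1.0  1.0  1.0  1.0  1.0  1.0  1.0",
      "     1.0  1.0  1.0  1.0  1.0  1.0  1.0  1.0  1.0  1.0",
      "//")
}

## Toy 2-chain / 2-residues-per-chain PDB text with a water, an altLoc
## pair and a second MODEL.
toyPdbLines <- function() {
    c("MODEL        1",
      "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
      "ATOM      2  CA  GLY A   2       8.000   0.000   0.000  1.00  0.00           C",
      "ATOM      3  CA ALYS B   1       0.000   3.000   0.000  0.40  0.00           C",
      "ATOM      4  CA BLYS B   1       0.500   3.000   0.000  0.60  0.00           C",
      "ATOM      5  CA  SER B   2       8.000   3.000   0.000  1.00  0.00           C",
      "ATOM      6  H   ALA A   1       0.000   1.000   0.000  1.00  0.00           H",
      "HETATM    7  O   HOH A   9      20.000  20.000  20.000  1.00  0.00           O",
      "ENDMDL",
      "MODEL        2",
      "ATOM      8  CA  ALA A   1      50.000   0.000   0.000  1.00  0.00           C",
      "ENDMDL",
      "END")
}

writeToyPdb <- function(lines = toyPdbLines()) {
    f <- withr::local_tempfile(fileext = ".pdb",
                               .local_envir = parent.frame())
    writeLines(lines, f)
    f
}

## Brute-force O(atoms^2) contact oracle, independent of detectContacts.
bruteForceContacts <- function(s, radii = vdwRadii(), tolerance = 0) {
    a <- atomTable(s)
    a$radius <- radii[a$element]
    hits <- list()
    for (i in seq_len(nrow(a) - 1L)) {
        for (j in (i + 1L):nrow(a)) {
            if (a$chain[i] == a$chain[j]) next
            d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 +
                      (a$z[i] - a$z[j])^2)
            if (d < a$radius[i] + a$radius[j] + tolerance) {
                swap <- a$chain[i] > a$chain[j]
                p <- if (swap) c(j, i) else c(i, j)
                hits[[length(hits) + 1L]] <-
                    paste(a$chain[p[1]], a$resno[p[1]],
                          a$chain[p[2]], a$resno[p[2]])
            }
        }
    }
    sort(unique(unlist(hits)))
}

contactKeys <- function(cc)
    sort(paste(cc$chain_a, cc$resno_a, cc$chain_b, cc$resno_b))

## Windows sliding along a map chain, centres `centers`.
windowsFromMap <- function(map, chain_key, centers,
                           mod_type = "phosphorylation") {
    s <- chainSequences(map)[[chain_key]]
    data.frame(protein_id = paste0("P", chain_key, centers),
               site_position = centers, mod_type = mod_type,
               sequence = vapply(centers, function(cc)
                   substr(s, cc - 7L, cc + 7L), character(1)),
               label = NA_character_, stringsAsFactors = FALSE)
}

randomWindows <- function(n, seed = 1, mod_type = "phosphorylation") {
    withr::with_seed(seed, {
        data.frame(protein_id = sprintf("RW%04d", seq_len(n)),
                   site_position = 8L, mod_type = mod_type,
                   sequence = vapply(seq_len(n), function(i)
                       paste(sample(AA20, 15, replace = TRUE),
                             collapse = ""), character(1)),
                   label = NA_character_, stringsAsFactors = FALSE)
    })
}
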