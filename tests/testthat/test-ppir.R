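test_that("validateStructure reports the documented failure modes", {
    s <- readStructure(writeToyPdb())
    v <- validateStructure(s)
    expect_true(v$pass)
    expect_length(v$reasons, 0L)

    dup <- toyPdbLines()
    dup[3] <- sub("GLY A   2", "SER A   1", dup[3])   # A1 twice, two names
    vd <- validateStructure(readStructure(writeToyPdb(dup)))
    expect_false(vd$pass)
    expect_match(vd$reasons, "duplicate residue key", all = FALSE)

    single <- toyPdbLines()[c(1, 2, 3, 9)]            # chain A only
    vs <- validateStructure(readStructure(writeToyPdb(single)))
    expect_true(vs$pass)                              # partner rule lives downstream
})

test_that("contact geometry follows the vdW overlap rule", {
    mk <- function(d) new("Structure", structureId = "T",
        atoms = data.frame(chain = c("A", "B"), resno = 1L, insert = "",
                           resid = "GLY", elety = "CA", element = "C",
                           x = c(0, d), y = 0, z = 0, occupancy = 1,
                           stringsAsFactors = FALSE))
    expect_equal(nrow(detectContacts(mk(3.0))), 1L)   # 3.0 < 1.7 + 1.7
    expect_equal(nrow(detectContacts(mk(5.0))), 0L)
    expect_equal(detectContacts(mk(3.0))$min_gap, 3.0 - 3.4)
    expect_error(detectContacts(mk(3.0), radii = c(N = 1.55)), "C")
})

test_that("detectContacts equals the brute-force all-pairs oracle", {
    for (seed in 1:3) {
        sim <- simulateComplex(n_chains = 3L, residues_per_chain = 40L,
                               contact_pairs = 9L, seed = seed)
        got <- detectContacts(sim$structure)
        expect_identical(contactKeys(got), bruteForceContacts(sim$structure))
        expect_setequal(contactKeys(got),
                        paste(sim$truth$chain_a, sim$truth$resno_a,
                              sim$truth$chain_b, sim$truth$resno_b))
    }
})

test_that("contacts are inter-chain only, unordered-unique, and monotone in tolerance", {
    sim <- simulateComplex(2L, 30L, 5L, seed = 4)
    cc0 <- detectContacts(sim$structure, tolerance = 0)
    expect_true(all(cc0$chain_a != cc0$chain_b))
    expect_false(anyDuplicated(contactKeys(cc0)) > 0)
    for (tol in c(0.5, 2, 5)) {
        cct <- detectContacts(sim$structure, tolerance = tol)
        expect_true(all(contactKeys(cc0) %in% contactKeys(cct)))
    }
})

test_that("buildPpirMap flags planted residues, drops loners, and is idempotent", {
    ## 4 planted pairs spanning 6 distinct residues (targets shared)
    pairs <- data.frame(chain_a = "A", resno_a = c(3, 3, 8, 8),
                        chain_b = "B", resno_b = c(2, 5, 9, 12))
    sim <- simulateComplex(2L, 15L, pairs, seed = 2)
    map <- buildPpirMap(list(sim$structure))
    r <- residueMap(map)
    expect_equal(sum(r$interacting), 6L)
    flagged <- paste(r$chain, r$resno)[r$interacting]
    expect_setequal(flagged, c("A 3", "A 8", "B 2", "B 5", "B 9", "B 12"))

    single <- simulateComplex(1L, 10L, 0L, seed = 1)$structure
    expect_error(buildPpirMap(list(single)), "no interacting structures")

    twice <- buildPpirMap(list(sim$structure, sim$structure))
    expect_identical(residueMap(twice), residueMap(map))
})

test_that("filterShortWindows keeps exactly the clean 15-mers, in order", {
    ws <- randomWindows(8, seed = 3)
    ws$sequence[2] <- substr(ws$sequence[2], 1, 11)
    ws$sequence[5] <- sub("^.", "_", ws$sequence[5])
    ws$sequence[7] <- substr(ws$sequence[7], 1, 13)
    out <- filterShortWindows(ws)
    expect_identical(out$protein_id, ws$protein_id[-c(2, 5, 7)])
    expect_identical(filterShortWindows(out), out)
})

test_that("labelWindows applies the at-least-one-interface rule and removes unmatched", {
    pairs <- data.frame(chain_a = "A", resno_a = c(10, 20, 30),
                        chain_b = "B", resno_b = c(4, 8, 16))
    sim <- simulateComplex(2L, 45L, pairs, seed = 7)
    map <- buildPpirMap(list(sim$structure))
    r <- residueMap(map)
    ws <- rbind(windowsFromMap(map, "SYNTH|A", 8:38),
                windowsFromMap(map, "SYNTH|B", 8:38),
                randomWindows(5, seed = 99))      # no structural match
    lab <- labelWindows(ws, map)
    expect_equal(nrow(lab), 62L)                  # the 5 unmatched removed
    truth <- c(r$interacting[r$chain == "A"][8:38],
               r$interacting[r$chain == "B"][8:38])
    expect_identical(lab$label == "inside", truth)
    ## labels invariant to structure order in the map
    sim2 <- simulateComplex(2L, 45L, 2L, seed = 8, structure_id = "OTHER")
    m12 <- buildPpirMap(list(sim$structure, sim2$structure))
    m21 <- buildPpirMap(list(sim2$structure, sim$structure))
    l12 <- labelWindows(ws, m12)
    l21 <- labelWindows(ws, m21)
    expect_identical(l12[order(l12$protein_id), c("protein_id", "label")],
                     l21[order(l21$protein_id), c("protein_id", "label")])
})

test_that("a multi-match window is inside if any match centres on an interface residue", {
    ## two structures sharing chain sequence; centre flagged in one only
    pairs <- data.frame(chain_a = "A", resno_a = 10, chain_b = "B", resno_b = 10)
    s1 <- simulateComplex(2L, 25L, pairs, seed = 11, structure_id = "S1")
    s2 <- simulateComplex(2L, 25L, 0L, seed = 11, structure_id = "S2")
    expect_identical(chainSequences(s1$structure)[["A"]],
                     chainSequences(s2$structure)[["A"]])
    map <- buildPpirMap(list(s1$structure, s2$structure))
    w <- windowsFromMap(map, "S1|A", 10)
    lab <- labelWindows(w, map)
    expect_equal(nrow(lab), 1L)
    expect_identical(lab$label, "inside")
    expect_match(lab$provenance, "S1\\|A")
    expect_match(lab$provenance, "S2\\|A")
})

test_that("segregateByModType partitions without loss", {
    ws <- randomWindows(10, seed = 2)
    ws$mod_type <- rep(c("phosphorylation", "ubiquitylation"), c(7, 3))
    ws$label <- "outside"
    parts <- segregateByModType(ws)
    expect_identical(sort(names(parts)),
                     c("phosphorylation", "ubiquitylation"))
    expect_equal(vapply(parts, nrow, integer(1))[["phosphorylation"]], 7L)
    expect_equal(sum(vapply(parts, nrow, integer(1))), nrow(ws))
    expect_length(segregateByModType(ws[0, ]), 0L)
})

test_that("PPIR map TSV round-trips labeling behaviour", {
    sim <- simulateComplex(2L, 40L, 8L, seed = 13)
    map <- buildPpirMap(list(sim$structure))
    f <- withr::local_tempfile(fileext = ".tsv")
    writePpirMap(map, f)
    back <- readPpirMap(f)
    expect_identical(chainSequences(back), chainSequences(map))
    ws <- windowsFromMap(map, "SYNTH|B", 8:30)
    expect_identical(labelWindows(ws, back)$label,
                     labelWindows(ws, map)$label)
})
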